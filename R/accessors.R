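#' Construct a GenotypeData object
#'
#' @param dosage animals x SNPs matrix of 0/1/2 dosages (NA = missing call),
#'   with animal ids as rownames and SNP ids as colnames.
#' @param chrom chromosome per SNP.
#' @param bp 1-based position per SNP.
#' @param allele1,allele2 allele labels; dosage counts copies of `allele2`.
#' @return a [GenotypeData-class] object.
#' @export
genotypeData <- function(dosage, chrom, bp, allele1 = "A", allele2 = "B") {
  dosage <- as.matrix(dosage)
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("snp", seq_len(ncol(dosage)))
  map <- GRanges(chrom, IRanges(bp, width = 1L))
  names(map) <- colnames(dosage)
  map$allele1 <- rep_len(allele1, length(map))
  map$allele2 <- rep_len(allele2, length(map))
  new("GenotypeData", dosage = dosage, map = map)
}

#' Extract the dosage matrix (animals x SNPs)
#' @param x a GenotypeData object
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname dosage
#' @export
setMethod("dosage", "GenotypeData", function(x) x@dosage)

#' SNP map accessors
#'
#' `snpMap()` returns the map as a `GRanges`; `snpTable()` as a data.frame
#' with columns snp, chrom, bp.
#' @param x a GenotypeData object
#' @export
setGeneric("snpMap", function(x) standardGeneric("snpMap"))

#' @rdname snpMap
#' @export
setMethod("snpMap", "GenotypeData", function(x) x@map)

#' @rdname snpMap
#' @export
snpTable <- function(x) {
  m <- snpMap(x)
  data.frame(snp = names(m), chrom = as.character(seqnames(m)),
             bp = start(m), stringsAsFactors = FALSE)
}

#' @rdname dosage
#' @export
setGeneric("nAnimals", function(x) standardGeneric("nAnimals"))
#' @rdname dosage
#' @export
setMethod("nAnimals", "GenotypeData", function(x) nrow(x@dosage))
#' @rdname dosage
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))
#' @rdname dosage
#' @export
setMethod("nSnps", "GenotypeData", function(x) ncol(x@dosage))

#' Subset genotypes by animal and/or SNP
#' @param x GenotypeData
#' @param i animal index/ids
#' @param j SNP index/ids
#' @param ... unused
#' @param drop ignored
#' @export
setMethod("[", "GenotypeData", function(x, i, j, ..., drop = FALSE) {
  d <- x@dosage; m <- x@map
  if (!missing(i)) d <- d[i, , drop = FALSE]
  if (!missing(j)) { d <- d[, j, drop = FALSE]; m <- m[j] }
  new("GenotypeData", dosage = d, map = m)
})

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nrow(object@dosage), "animals x",
      ncol(object@dosage), "SNPs on",
      length(unique(as.character(seqnames(object@map)))), "chromosome(s)\n")
  nm <- sum(is.na(object@dosage))
  if (nm > 0) cat("  missing calls:", nm, "\n")
})

#' Access the pedigree table
#' @param x an AnimalPedigree object
#' @export
setGeneric("pedTable", function(x) standardGeneric("pedTable"))
#' @rdname pedTable
#' @export
setMethod("pedTable", "AnimalPedigree", function(x) x@df)

#' Construct an AnimalPedigree from a data.frame
#' @param df data.frame with id, sire, dam and optional covariate columns
#' @export
animalPedigree <- function(df) {
  df$id <- as.character(df$id)
  df$sire <- as.character(df$sire); df$dam <- as.character(df$dam)
  new("AnimalPedigree", df = df)
}

setMethod("show", "AnimalPedigree", function(object) {
  df <- object@df
  cat("AnimalPedigree:", nrow(df), "animals,",
      sum(is.na(df$sire) & is.na(df$dam)), "founders\n")
})

#' Construct a PhenotypeData object
#' @param traits animals x traits matrix (NA = unmeasured)
#' @param covariates data.frame of per-animal covariates
#' @export
phenotypeData <- function(traits, covariates) {
  traits <- as.matrix(traits)
  covariates <- as.data.frame(covariates)
  rownames(covariates) <- rownames(traits)
  new("PhenotypeData", traits = traits, covariates = covariates)
}

#' @rdname phenotypeData
#' @param x PhenotypeData
#' @export
setGeneric("traitMatrix", function(x) standardGeneric("traitMatrix"))
#' @rdname phenotypeData
#' @export
setMethod("traitMatrix", "PhenotypeData", function(x) x@traits)
#' @rdname phenotypeData
#' @export
setGeneric("covariateTable", function(x) standardGeneric("covariateTable"))
#' @rdname phenotypeData
#' @export
setMethod("covariateTable", "PhenotypeData", function(x) x@covariates)

setMethod("show", "PhenotypeData", function(object) {
  cat("PhenotypeData:", nrow(object@traits), "animals x",
      ncol(object@traits), "traits;",
      sum(is.na(object@traits)), "missing cells\n")
})

setMethod("show", "VarComp", function(object) {
  cat("VarComp for", object@trait, "\n")
  print(round(object@sigma2, 5))
  cat("  h2 =", round(object@h2, 4),
      if (!object@converged) " (REML NOT converged)" else "", "\n")
})

#' Accessors for adjusted phenotypes
#' @param x AdjustedPheno
#' @export
setGeneric("adjustedResiduals", function(x) standardGeneric("adjustedResiduals"))
#' @rdname adjustedResiduals
#' @export
setMethod("adjustedResiduals", "AdjustedPheno", function(x) x@residuals)
#' @rdname adjustedResiduals
#' @export
setGeneric("phenoSd", function(x) standardGeneric("phenoSd"))
#' @rdname adjustedResiduals
#' @export
setMethod("phenoSd", "AdjustedPheno", function(x) x@phenoSd)

setMethod("show", "AdjustedPheno", function(object) {
  cat("AdjustedPheno:", nrow(object@residuals), "animals x",
      ncol(object@residuals), "traits (fixed/breed/sire-by-flock removed)\n")
})

#' Accessors for BayesR fits
#' @param x BayesRFit
#' @export
setGeneric("snpEffects", function(x) standardGeneric("snpEffects"))
#' @rdname snpEffects
#' @export
setMethod("snpEffects", "BayesRFit", function(x) setNames(x@snpEffects, x@snpIds))
#' @rdname snpEffects
#' @export
setGeneric("classProb", function(x) standardGeneric("classProb"))
#' @rdname snpEffects
#' @export
setMethod("classProb", "BayesRFit", function(x) {
  m <- x@classProb; rownames(m) <- x@snpIds
  colnames(m) <- paste0("class", 0:3); m
})
#' @rdname snpEffects
#' @export
setGeneric("ppNonzero", function(x) standardGeneric("ppNonzero"))
#' @rdname snpEffects
#' @export
setMethod("ppNonzero", "BayesRFit", function(x) setNames(x@ppNonzero, x@snpIds))

setMethod("show", "BayesRFit", function(object) {
  cat("BayesRFit for", object@trait, ":", length(object@snpEffects), "SNPs;",
      sum(object@ppNonzero > 0.5), "SNPs with pp_nonzero > 0.5\n")
})

#' Accessors for local GEBV
#' @param x LocalGebvMatrix
#' @export
setGeneric("windowRanges", function(x) standardGeneric("windowRanges"))
#' @rdname windowRanges
#' @export
setMethod("windowRanges", "LocalGebvMatrix", function(x) x@windows)
#' @rdname windowRanges
#' @export
setMethod("windowRanges", "WindowPcaSet", function(x) x@windows)
#' @rdname windowRanges
#' @export
setGeneric("localValues", function(x, trait) standardGeneric("localValues"))
#' @rdname windowRanges
#' @param trait trait name
#' @export
setMethod("localValues", "LocalGebvMatrix", function(x, trait) x@values[[trait]])

setMethod("show", "LocalGebvMatrix", function(object) {
  cat("LocalGebvMatrix:", length(object@traits), "trait(s) x",
      length(object@windows), "windows\n")
})

#' Accessors for window PCA results
#' @param x WindowPcaSet
#' @export
setGeneric("lambda1", function(x) standardGeneric("lambda1"))
#' @rdname lambda1
#' @export
setMethod("lambda1", "WindowPcaSet", function(x) x@lambda1)
#' @rdname lambda1
#' @export
setGeneric("prop1", function(x) standardGeneric("prop1"))
#' @rdname lambda1
#' @export
setMethod("prop1", "WindowPcaSet", function(x) x@prop1)

setMethod("show", "WindowPcaSet", function(object) {
  cat("WindowPcaSet:", length(object@windows), "windows,",
      length(object@traits), "traits; top lambda1 =",
      signif(max(object@lambda1), 4), "\n")
})
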