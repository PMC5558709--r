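#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   tileGenome distance
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom stats var cor sd cov rnorm runif rbinom rpois rchisq rbeta
#'   pnorm pchisq qnorm optimize optim setNames complete.cases ks.test
#'   p.adjust quantile median aov anova lm residuals fitted coef
#' @importFrom utils read.table write.table head tail
NULL

#' Genotype dosages with a genomic SNP map
#'
#' Container for an animals x SNPs allele-dosage matrix (0/1/2, `NA` for a
#' missing call) together with its SNP map held as a [GenomicRanges::GRanges]
#' of width-1 positions (1-based bp). Column order of the dosage matrix and
#' the order of the map are locked together by the validity method.
#'
#' @slot dosage numeric matrix, animals in rows (rownames = animal ids), SNPs
#'   in columns (colnames = SNP ids).
#' @slot map `GRanges`, one range per SNP, `names(map) == colnames(dosage)`.
#'   Metadata columns `allele1`/`allele2` record the allele order so that the
#'   dosage counts copies of `allele2`.
#' @export
setClass("GenotypeData", representation(dosage = "matrix", map = "GRanges"))

setValidity("GenotypeData", function(object) {
  msg <- NULL
  if (ncol(object@dosage) != length(object@map))
    msg <- c(msg, "number of SNPs in dosage and map differ")
  if (!identical(colnames(object@dosage), names(object@map)))
    msg <- c(msg, "SNP ids of dosage columns and map names differ")
  if (is.null(rownames(object@dosage)))
    msg <- c(msg, "dosage must carry animal ids as rownames")
  d <- object@dosage
  if (any(!is.na(d) & (d < 0 | d > 2)))
    msg <- c(msg, "dosages must lie in [0, 2]")
  if (anyDuplicated(colnames(object@dosage)))
    msg <- c(msg, "duplicate SNP ids")
  if (is.null(msg)) TRUE else msg
})

#' Pedigree with covariates used by the mixed models
#'
#' @slot df data.frame with columns `id`, `sire`, `dam` (`NA` for unknown
#'   founder parents), `generation`, and optionally `sex`, `flock`, `age`,
#'   `breedQ` (straightbred proportion in \[0, 1\]).
#' @export
setClass("AnimalPedigree", representation(df = "data.frame"))

setValidity("AnimalPedigree", function(object) {
  df <- object@df
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(df))) return("pedigree needs id, sire, dam columns")
  if (anyDuplicated(df$id)) return("duplicate animal ids")
  known <- c(NA, df$id)
  if (!all(df$sire %in% known) || !all(df$dam %in% known))
    return("sire/dam ids missing from pedigree")
  pos <- match(df$id, df$id)
  ps <- match(df$sire, df$id); pd <- match(df$dam, df$id)
  if (any(ps >= pos, na.rm = TRUE) || any(pd >= pos, na.rm = TRUE))
    return("parents must precede offspring")
  TRUE
})

#' Multi-trait phenotypes plus model covariates
#'
#' @slot traits numeric matrix animals x traits (`NA` = unmeasured).
#' @slot covariates data.frame of per-animal fixed-effect terms and breed
#'   proportion, rownames matching `rownames(traits)`.
#' @export
setClass("PhenotypeData", representation(traits = "matrix", covariates = "data.frame"))

setValidity("PhenotypeData", function(object) {
  if (!identical(rownames(object@traits), rownames(object@covariates)))
    return("traits and covariates must cover the same animals in order")
  if (is.null(colnames(object@traits))) return("traits need names")
  TRUE
})

#' Variance components of one trait under the pedigree mixed model
#'
#' Heritability follows the narrow definition used throughout:
#' `h2 = sigma2_a / (sigma2_a + sigma2_sf + sigma2_e)`; the breed variance is
#' a between-strain component and is excluded from the denominator.
#'
#' @slot trait trait name.
#' @slot sigma2 named numeric: `a` (additive polygenic), `sf` (sire-by-flock),
#'   `q` (breed), `e` (residual). Components absent from the model are 0.
#' @slot h2 numeric heritability in \[0, 1\].
#' @slot converged logical REML convergence flag.
#' @slot niter iterations used.
#' @export
setClass("VarComp", representation(trait = "character", sigma2 = "numeric",
                                   h2 = "numeric", converged = "logical",
                                   niter = "integer"))

setValidity("VarComp", function(object) {
  if (any(object@sigma2 < 0)) return("variance components must be >= 0")
  if (object@h2 < 0 || object@h2 > 1) return("h2 outside [0, 1]")
  TRUE
})

#' Phenotypes adjusted for fixed, breed and sire-by-flock effects
#'
#' Residuals keep the polygenic + residual part of each trait (the polygenic
#' effect is deliberately not removed: downstream stages re-fit it).
#'
#' @slot residuals matrix animals x traits, `NA` where the phenotype was
#'   missing.
#' @slot phenoSd per-trait phenotypic standard deviation (of the raw trait).
#' @slot varcomp list of [VarComp-class] per trait.
#' @export
setClass("AdjustedPheno", representation(residuals = "matrix", phenoSd = "numeric",
                                         varcomp = "list"))

setValidity("AdjustedPheno", function(object) {
  if (length(object@phenoSd) != ncol(object@residuals))
    return("one phenotypic SD per trait required")
  ok <- vapply(seq_len(ncol(object@residuals)), function(j) {
    r <- object@residuals[, j]; r <- r[!is.na(r)]
    length(r) == 0 || abs(mean(r)) < 1e-8 * max(sd(r), 1e-12)
  }, logical(1))
  if (!all(ok)) return("adjusted residuals must be centered per trait")
  TRUE
})

#' Posterior summaries of a single-trait BayesR fit
#'
#' @slot trait trait name.
#' @slot snpEffects posterior-mean SNP effects (length = SNPs).
#' @slot classProb SNPs x 4 posterior mixture-class probabilities; rows sum
#'   to 1. Class variances are 0, 0.0001, 0.001 and 0.01 of the genetic
#'   variance.
#' @slot ppNonzero per-SNP posterior probability of a nonzero effect
#'   (1 - class-0 probability).
#' @slot traces matrix of thinned post-burn-in draws of `sigma2_g`,
#'   `sigma2_e` and (when fitted) the polygenic variance, with a chain column.
#' @slot snpIds SNP ids matching the genotype map used in the fit.
#' @slot config list of sampler settings used.
#' @export
setClass("BayesRFit", representation(trait = "character", snpEffects = "numeric",
                                     classProb = "matrix", ppNonzero = "numeric",
                                     traces = "matrix", snpIds = "character",
                                     config = "list"))

setValidity("BayesRFit", function(object) {
  if (length(object@snpEffects) != nrow(object@classProb))
    return("one class-probability row per SNP required")
  if (ncol(object@classProb) != 4L) return("four mixture classes expected")
  s <- rowSums(object@classProb)
  if (any(abs(s - 1) > 1e-9)) return("class probabilities must sum to 1")
  if (any(object@ppNonzero < -1e-12 | object@ppNonzero > 1 + 1e-12))
    return("ppNonzero outside [0, 1]")
  TRUE
})

#' Local (per-window) GEBV for a set of traits
#'
#' Windows tile each chromosome as 0-based half-open intervals
#' `[k*w, (k+1)*w)`; a SNP at 1-based position bp falls in window
#' `floor((bp - 1)/w)`. The sum of local GEBV over windows equals the
#' whole-genome SNP-based GEBV.
#'
#' @slot values list (one element per trait) of animals x windows matrices.
#' @slot windows `GRanges` of the window tiles (1-based inclusive display
#'   coordinates of the half-open tiles).
#' @slot traits trait names, `names(values)`.
#' @export
setClass("LocalGebvMatrix", representation(values = "list", windows = "GRanges",
                                           traits = "character"))

setValidity("LocalGebvMatrix", function(object) {
  if (!identical(names(object@values), object@traits))
    return("values must be named by trait")
  nw <- length(object@windows)
  ok <- vapply(object@values, function(m) ncol(m) == nw, logical(1))
  if (!all(ok)) return("each trait matrix needs one column per window")
  TRUE
})

#' Per-window eigen-analysis of standardized local GEBV covariance
#'
#' @slot windows `GRanges` of windows analysed.
#' @slot lambda1 largest eigenvalue per window (phenotypic-SD^2 units).
#' @slot prop1 fraction of the trace explained by PC1 (0 for all-zero
#'   windows).
#' @slot eig list per window with elements `values` (descending) and
#'   `vectors` (columns are eigenvectors; PC1 first).
#' @slot traits trait order of the covariance matrices.
#' @export
setClass("WindowPcaSet", representation(windows = "GRanges", lambda1 = "numeric",
                                        prop1 = "numeric", eig = "list",
                                        traits = "character"))

setValidity("WindowPcaSet", function(object) {
  n <- length(object@windows)
  if (length(object@lambda1) != n || length(object@prop1) != n ||
      length(object@eig) != n)
    return("per-window slots must have one entry per window")
  if (any(object@prop1 < -1e-12 | object@prop1 > 1 + 1e-9))
    return("prop1 outside [0, 1]")
  TRUE
})
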