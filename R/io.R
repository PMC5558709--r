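#' Genotype quality-control thresholds
#'
#' Defaults mirror stringent SNP-array practice: SNP call rate >= 95%,
#' MAF >= 0.01, Hardy-Weinberg P >= 1e-5, animal call rate >= 90%.
#' @param snp_call_rate_min,maf_min,hwe_p_min,animal_call_rate_min
#'   thresholds, all in (0, 1)
#' @export
qcThresholds <- function(snp_call_rate_min = 0.95, maf_min = 0.01,
                         hwe_p_min = 1e-5, animal_call_rate_min = 0.90) {
  thr <- list(snp_call_rate_min = snp_call_rate_min, maf_min = maf_min,
              hwe_p_min = hwe_p_min, animal_call_rate_min = animal_call_rate_min)
  if (any(unlist(thr) <= 0 | unlist(thr) >= 1))
    stop("thresholds must lie in (0, 1)")
  class(thr) <- "QcThresholds"
  thr
}

# Hardy-Weinberg chi-square P-value from dosage counts (1 df)
.hweP <- function(d) {
  d <- d[!is.na(d)]
  n <- length(d)
  if (n == 0) return(NA_real_)
  n2 <- sum(d == 2); n1 <- sum(d == 1); n0 <- n - n1 - n2
  p <- (2 * n2 + n1) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  E <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  O <- c(n0, n1, n2)
  chi2 <- sum((O - E)^2 / E)
  pchisq(chi2, 1, lower.tail = FALSE)
}

#' Genotype quality control
#'
#' SNP filters first (call rate, then MAF, then Hardy-Weinberg), then
#' animals failing the call-rate threshold are removed; the order matters
#' for the counts, so the report lists filters in application order.
#'
#' @param geno a [GenotypeData-class] (missing calls as `NA`)
#' @param thr a [qcThresholds()] object
#' @param batch optional factor splitting SNP-filter evaluation into
#'   genotyping batches; a SNP failing in any batch is removed.
#' @return list: `geno` (filtered [GenotypeData-class]), `report`
#'   (data.frame of removal counts in order).
#' @export
qcGenotypes <- function(geno, thr = qcThresholds(), batch = NULL) {
  M <- dosage(geno)
  groups <- if (is.null(batch)) list(seq_len(nrow(M)))
            else split(seq_len(nrow(M)), batch)

  failAny <- function(fun) {
    Reduce(`|`, lapply(groups, function(i) fun(M[i, , drop = FALSE])))
  }
  callRate <- failAny(function(B) colMeans(!is.na(B)) < thr$snp_call_rate_min)
  keep1 <- !callRate
  mafFail <- failAny(function(B) {
    p <- colMeans(B, na.rm = TRUE) / 2
    pmin(p, 1 - p) < thr$maf_min
  })
  mafFail <- mafFail & keep1
  keep2 <- keep1 & !mafFail
  hweFail <- failAny(function(B)
    vapply(seq_len(ncol(B)), function(j) {
      p <- .hweP(B[, j]); !is.na(p) && p < thr$hwe_p_min
    }, logical(1)))
  hweFail <- hweFail & keep2
  keepSnp <- keep2 & !hweFail
  if (!any(keepSnp)) stop("all SNPs removed by quality control")

  M2 <- M[, keepSnp, drop = FALSE]
  animFail <- rowMeans(!is.na(M2)) < thr$animal_call_rate_min
  report <- data.frame(
    filter = c("snp_call_rate", "snp_maf", "snp_hwe", "animal_call_rate"),
    removed = c(sum(callRate), sum(mafFail), sum(hweFail), sum(animFail)),
    stringsAsFactors = FALSE)
  g2 <- geno[!animFail, keepSnp]
  list(geno = g2, report = report)
}

#' Write genotypes to disk
#'
#' Formats: `"ped-map"` (PLINK text pair `<prefix>.ped` / `<prefix>.map`,
#' alleles from the map's allele labels, missing as `0 0`), `"dosage-tsv"`
#' (`<prefix>.dose.tsv` one line per animal plus `<prefix>.map.tsv`), and
#' `"vcf"` (`<prefix>.vcf`, sites + GT only; dosage counts the ALT allele).
#'
#' @param geno a [GenotypeData-class]
#' @param prefix output path prefix
#' @param format one of ped-map, dosage-tsv, vcf
#' @return the paths written, invisibly.
#' @export
writeGenotypes <- function(geno, prefix, format = c("ped-map", "dosage-tsv", "vcf")) {
  format <- match.arg(format)
  M <- dosage(geno)
  tab <- snpTable(geno)
  a1 <- snpMap(geno)$allele1; a2 <- snpMap(geno)$allele2
  if (format == "ped-map") {
    mapPath <- paste0(prefix, ".map"); pedPath <- paste0(prefix, ".ped")
    write.table(data.frame(tab$chrom, tab$snp, 0, tab$bp), mapPath,
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    con <- file(pedPath, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(M))) {
      d <- M[i, ]
      g <- character(2 * length(d))
      g[seq(1, length(g), 2)] <- ifelse(is.na(d), "0", ifelse(d >= 1, a2, a1))
      g[seq(2, length(g), 2)] <- ifelse(is.na(d), "0", ifelse(d == 2, a2, a1))
      cat("FAM", rownames(M)[i], "0", "0", "0", "-9", g, "\n",
          file = con, sep = " ")
    }
    return(invisible(c(pedPath, mapPath)))
  }
  if (format == "dosage-tsv") {
    dosePath <- paste0(prefix, ".dose.tsv"); mapPath <- paste0(prefix, ".map.tsv")
    dt <- data.table::data.table(animal = rownames(M))
    dt <- cbind(dt, data.table::as.data.table(M))
    data.table::fwrite(dt, dosePath, sep = "\t", na = "NA")
    data.table::fwrite(tab, mapPath, sep = "\t")
    return(invisible(c(dosePath, mapPath)))
  }
  vcfPath <- paste0(prefix, ".vcf")
  con <- file(vcfPath, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(M)), collapse = "\t")), con)
  gtcode <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(M))) {
    d <- M[, j]
    gt <- ifelse(is.na(d), "./.", gtcode[d + 1])
    writeLines(paste(c(tab$chrom[j], tab$bp[j], tab$snp[j], a1[j], a2[j],
                       ".", "PASS", ".", "GT", gt), collapse = "\t"), con)
  }
  invisible(vcfPath)
}

#' Read genotypes from disk
#'
#' Dosages are coded 0/1/2 counting the alternate allele (`allele2`); the
#' allele order is recorded in the map. For PLINK text input the alternate
#' allele of each SNP is the lexicographically later of the observed
#' alleles. Duplicate SNP ids are an error; unsorted positions are sorted
#' with a warning.
#'
#' @param path file path (prefix for ped-map / dosage-tsv)
#' @param format one of ped-map, dosage-tsv, vcf
#' @return a [GenotypeData-class]
#' @export
readGenotypes <- function(path, format = c("ped-map", "dosage-tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "ped-map") {
    map <- read.table(paste0(path, ".map"), sep = "\t",
                      col.names = c("chrom", "snp", "cm", "bp"),
                      colClasses = c("character", "character", "numeric", "integer"))
    ped <- read.table(paste0(path, ".ped"), colClasses = "character")
    ids <- ped[[2]]
    al <- as.matrix(ped[, -(1:6), drop = FALSE])
    m <- nrow(map)
    A1 <- al[, seq(1, 2 * m, 2), drop = FALSE]
    A2 <- al[, seq(2, 2 * m, 2), drop = FALSE]
    dose <- matrix(NA_integer_, length(ids), m)
    a1v <- character(m); a2v <- character(m)
    for (j in seq_len(m)) {
      obs <- sort(unique(c(A1[, j], A2[, j])))
      obs <- setdiff(obs, "0")
      alt <- if (length(obs) >= 1) obs[length(obs)] else "B"
      ref <- if (length(obs) >= 2) obs[1] else alt
      a1v[j] <- ref; a2v[j] <- alt
      missing <- A1[, j] == "0" | A2[, j] == "0"
      dose[, j] <- (A1[, j] == alt) + (A2[, j] == alt)
      dose[missing, j] <- NA_integer_
    }
    rownames(dose) <- ids; colnames(dose) <- map$snp
    return(.finishGeno(dose, map$chrom, map$bp, a1v, a2v, map$snp))
  }
  if (format == "dosage-tsv") {
    dt <- data.table::fread(paste0(path, ".dose.tsv"), sep = "\t")
    map <- data.table::fread(paste0(path, ".map.tsv"), sep = "\t")
    dose <- as.matrix(dt[, -1])
    rownames(dose) <- dt[[1]]
    return(.finishGeno(dose, map$chrom, map$bp, "A", "B", map$snp))
  }
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("vcfR is required to read VCF files")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, "GT")
  # phase separator (/ or |) is irrelevant for dosage
  a <- substr(gt, 1, 1); b <- substr(gt, 3, 3)
  dose <- suppressWarnings(matrix(as.integer(a) + as.integer(b),
                                  nrow = nrow(gt)))
  dose <- t(dose)
  fix <- v@fix
  snp <- fix[, "ID"]
  dimnames(dose) <- list(colnames(gt), snp)
  .finishGeno(dose, fix[, "CHROM"], as.integer(fix[, "POS"]),
              fix[, "REF"], fix[, "ALT"], snp)
}

.finishGeno <- function(dose, chrom, bp, a1, a2, snp) {
  if (anyDuplicated(snp)) stop("duplicate SNP ids")
  ord <- order(chrom, bp)
  if (is.unsorted(ord)) {
    if (!identical(ord, seq_along(snp)))
      warning("positions not sorted; sorting")
  }
  if (!identical(ord, seq_along(snp))) {
    dose <- dose[, ord, drop = FALSE]
    chrom <- chrom[ord]; bp <- bp[ord]
    a1 <- rep_len(a1, length(snp))[ord]; a2 <- rep_len(a2, length(snp))[ord]
  }
  genotypeData(dose, chrom, bp,
               allele1 = rep_len(a1, length(chrom)),
               allele2 = rep_len(a2, length(chrom)))
}

#' Read and write pedigree / phenotype tables as TSV
#'
#' Plain tab-separated files with a header line carrying the column schema.
#' @param ped,pheno objects to write
#' @param path file path
#' @export
writePedigree <- function(ped, path) {
  data.table::fwrite(pedTable(ped), path, sep = "\t", na = "NA")
  invisible(path)
}

#' @rdname writePedigree
#' @export
readPedigree <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  animalPedigree(df)
}

#' @rdname writePedigree
#' @export
writePhenotypes <- function(pheno, path) {
  out <- cbind(data.frame(animal = rownames(traitMatrix(pheno))),
               covariateTable(pheno), traitMatrix(pheno))
  data.table::fwrite(out, path, sep = "\t", na = "NA")
  invisible(path)
}

#' @rdname writePedigree
#' @param trait_cols columns holding traits (default: names starting with
#'   "trait")
#' @export
readPhenotypes <- function(path, trait_cols = NULL) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  rownames(df) <- df$animal
  if (is.null(trait_cols)) trait_cols <- grep("^trait", names(df), value = TRUE)
  Y <- as.matrix(df[, trait_cols, drop = FALSE])
  cov <- df[, setdiff(names(df), c("animal", trait_cols)), drop = FALSE]
  phenotypeData(Y, cov)
}

#' Read gene annotation as 1-based inclusive intervals
#'
#' GFF3 (`.gff`, `.gff3`) or BED (`.bed`, 0-based half-open, converted) via
#' rtracklayer. Returns a GRanges with a `gene` column.
#' @param path annotation file
#' @param feature GFF3 feature type to keep (default "gene"; ignored for
#'   BED)
#' @export
readAnnotation <- function(path, feature = "gene") {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required to read annotation files")
  gr <- rtracklayer::import(path)
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (!is.null(gr$type) && feature %in% gr$type) gr <- gr[gr$type == feature]
    gr$gene <- if (!is.null(gr$Name)) gr$Name else gr$ID
  } else {
    gr$gene <- if (!is.null(gr$name)) gr$name else names(gr)
  }
  gr
}
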