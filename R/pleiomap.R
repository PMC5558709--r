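#' Assemble the SNP x trait signed t-value matrix and its correlation
#'
#' The trait x trait matrix V is the correlation of signed t-values
#' computed over all SNPs with finite statistics in every trait. When V is
#' near-singular (smallest eigenvalue below `eig_floor`) it is shrunk
#' towards the identity, `V <- (1 - eps) V + eps I`, with the smallest
#' `eps` restoring the bound; the amount is recorded.
#'
#' @param gwas named list of [singleTraitGwas()] tables over the same SNPs
#' @param eig_floor smallest admissible eigenvalue of V
#' @return list: `t` (SNP x trait matrix), `v` (trait correlation),
#'   `map` (snp/chrom/bp), `epsilon` (shrinkage applied, 0 if none).
#' @export
buildTmatrixV <- function(gwas, eig_floor = 1e-6) {
  snps <- gwas[[1]]$snp
  for (g in gwas) if (!identical(g$snp, snps))
    stop("GWAS tables must cover the same SNP set in the same order")
  tmat <- vapply(gwas, function(g) g$t, numeric(length(snps)))
  rownames(tmat) <- snps
  ok <- rowSums(!is.finite(tmat)) == 0
  zv <- apply(tmat[ok, , drop = FALSE], 2, sd)
  if (any(zv == 0))
    stop("trait(s) with zero t-variance: ",
         paste(colnames(tmat)[zv == 0], collapse = ", "))
  V <- cor(tmat[ok, , drop = FALSE])
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  eps <- 0
  if (min(ev) < eig_floor) {
    eps <- (eig_floor - min(ev)) / (1 - min(ev))
    V <- (1 - eps) * V + eps * diag(ncol(V))
  }
  map <- gwas[[1]][, c("snp", "chrom", "bp")]
  list(t = tmat, v = V, map = map, epsilon = eps)
}

#' Multi-trait chi-square statistic from signed t-values
#'
#' `chi2_i = t_i' V^-1 t_i` for each SNP, with degrees of freedom equal to
#' the number of traits. SNPs with a non-finite t-value in any trait are
#' flagged and excluded.
#'
#' @param t SNP x trait matrix of signed t-values (or the list returned by
#'   [buildTmatrixV()], in which case `v` and `map` are taken from it)
#' @param v trait x trait correlation matrix (positive definite)
#' @param map optional snp/chrom/bp table aligned with `t`
#' @return data.frame: snp, chrom, bp, chi2, df, p, flag.
#' @export
multiGwasChi2 <- function(t, v = NULL, map = NULL) {
  if (is.list(t) && !is.matrix(t)) { v <- t$v; map <- t$map; t <- t$t }
  Vi <- tryCatch(chol2inv(chol(v)),
                 error = function(e) stop("V is not positive definite"))
  ok <- rowSums(!is.finite(t)) == 0
  chi2 <- rep(NA_real_, nrow(t))
  tt <- t[ok, , drop = FALSE]
  chi2[ok] <- rowSums((tt %*% Vi) * tt)
  df <- ncol(t)
  out <- data.frame(snp = rownames(t), chi2 = chi2, df = df,
                    p = pchisq(chi2, df, lower.tail = FALSE),
                    flag = ifelse(ok, "", "nonfinite"),
                    stringsAsFactors = FALSE)
  if (!is.null(map)) out <- cbind(map[match(out$snp, map$snp), c("chrom", "bp")], out)
  rownames(out) <- NULL
  out[, intersect(c("snp", "chrom", "bp", "chi2", "df", "p", "flag"), names(out))]
}

#' Select the most significant SNP per genomic tile
#'
#' Half-open tiles of `window_bp` anchored at position 0; within each tile
#' the single most significant SNP passing the threshold is kept (ties
#' resolved towards the smaller position).
#'
#' @param chi2 a [multiGwasChi2()] table (needs chrom, bp, p and a
#'   statistic column)
#' @param threshold P-value threshold
#' @param window_bp tile width
#' @return QTL call set: method, snp, chrom, bp, statistic, p.
#' @export
topSnpPerMb <- function(chi2, threshold = 5e-7, window_bp = 1e6) {
  d <- chi2[!is.na(chi2$p) & chi2$p < threshold, , drop = FALSE]
  if (nrow(d) == 0)
    return(data.frame(method = character(), snp = character(),
                      chrom = character(), bp = numeric(),
                      statistic = numeric(), p = numeric(),
                      stringsAsFactors = FALSE))
  tile <- paste0(d$chrom, ":", floor((d$bp - 1) / window_bp))
  pick <- unlist(lapply(split(seq_len(nrow(d)), tile), function(i) {
    i[order(d$p[i], d$bp[i])][1]
  }), use.names = FALSE)
  d <- d[pick, , drop = FALSE]
  d <- d[order(d$chrom, d$bp), ]
  stat <- if ("chi2" %in% names(d)) d$chi2 else d[[setdiff(names(d), c("snp", "chrom", "bp", "p", "df", "flag"))[1]]]
  data.frame(method = "multi-GWAS", snp = d$snp, chrom = d$chrom, bp = d$bp,
             statistic = stat, p = d$p, stringsAsFactors = FALSE)
}

#' Combine BayesR posterior probabilities across traits
#'
#' The probability that a SNP affects at least one trait is one minus the
#' product over traits of the posterior probability of a zero effect. SNPs
#' above the threshold are returned; contributing traits are those with a
#' per-trait nonzero probability above `trait_pp`.
#'
#' @param fits named list of [BayesRFit-class], one per trait, sharing a map
#' @param map snp/chrom/bp table for the shared SNP set
#' @param threshold combined-probability call threshold
#' @param trait_pp per-trait probability defining a contributing trait
#' @return QTL call set: method, snp, chrom, bp, statistic (combined pp),
#'   traits (comma-separated contributing traits).
#' @export
multiPP <- function(fits, map, threshold = 0.3, trait_pp = 0.05) {
  ids <- fits[[1]]@snpIds
  for (f in fits) if (!identical(f@snpIds, ids)) stop("SNP map mismatch across fits")
  pp0 <- vapply(fits, function(f) f@classProb[, 1], numeric(length(ids)))
  if (any(pp0 < -1e-12 | pp0 > 1 + 1e-12)) stop("posterior probabilities outside [0, 1]")
  pp0 <- pmin(pmax(pp0, 0), 1)
  combined <- 1 - exp(rowSums(log(pp0)))
  ppnz <- 1 - pp0
  sel <- which(combined > threshold)
  contrib <- vapply(sel, function(i)
    paste(names(fits)[ppnz[i, ] > trait_pp], collapse = ","), character(1))
  d <- map[match(ids[sel], map$snp), ]
  out <- data.frame(method = "multi-PP", snp = ids[sel], chrom = d$chrom,
                    bp = d$bp, statistic = combined[sel], traits = contrib,
                    stringsAsFactors = FALSE)
  out[order(out$chrom, out$bp), ]
}

#' Eigen-analysis of standardized local GEBV covariance per window
#'
#' For each window, the trait x trait covariance of local GEBV across
#' animals is standardized by the product of the traits' phenotypic SDs
#' (`t_(y,x) = cov_LGEBV(y,x) / (sigma_y sigma_x)`) and
#' eigen-decomposed. A window containing a single pleiotropic QTL is
#' dominated by its first principal component.
#'
#' @param lgm a [LocalGebvMatrix-class]
#' @param sds per-trait phenotypic SD named by trait (e.g. [phenoSd()])
#' @return a [WindowPcaSet-class]
#' @export
windowCovPca <- function(lgm, sds) {
  traits <- lgm@traits
  sds <- sds[traits]
  nA <- nrow(lgm@values[[1]])
  if (nA < 2) stop("at least two animals required")
  nw <- length(lgm@windows)
  lam1 <- numeric(nw); pr1 <- numeric(nw); eigs <- vector("list", nw)
  for (wi in seq_len(nw)) {
    Lw <- vapply(traits, function(tr) lgm@values[[tr]][, wi], numeric(nA))
    Lw <- sweep(Lw, 2, sds, "/")
    Cw <- cov(Lw)
    if (all(abs(Cw) < 1e-300)) {
      ev <- list(values = rep(0, length(traits)),
                 vectors = diag(length(traits)))
    } else {
      ev <- eigen(Cw, symmetric = TRUE)
    }
    # deterministic eigenvector sign: largest-magnitude loading positive
    for (k in seq_along(traits)) {
      j <- which.max(abs(ev$vectors[, k]))
      if (ev$vectors[j, k] < 0) ev$vectors[, k] <- -ev$vectors[, k]
    }
    rownames(ev$vectors) <- traits
    lam1[wi] <- ev$values[1]
    tr <- sum(ev$values)
    pr1[wi] <- if (tr > 0) ev$values[1] / tr else 0
    eigs[[wi]] <- ev
  }
  new("WindowPcaSet", windows = lgm@windows, lambda1 = lam1, prop1 = pr1,
      eig = eigs, traits = traits)
}

#' Select the windows with the highest first eigenvalues
#'
#' @param wp a [WindowPcaSet-class]
#' @param k number of windows to keep (ties broken by chromosome, then
#'   position)
#' @return data.frame: window, chrom, start, end, lambda1, prop1, ranked by
#'   descending lambda1.
#' @export
selectTopWindows <- function(wp, k = 120) {
  if (k > length(wp@windows)) stop("k exceeds the number of windows")
  w <- wp@windows
  d <- data.frame(window = names(w), chrom = as.character(seqnames(w)),
                  start = start(w), end = end(w), lambda1 = wp@lambda1,
                  prop1 = wp@prop1, stringsAsFactors = FALSE)
  d <- d[order(-d$lambda1, d$chrom, d$start), ]
  head(d, k)
}

#' Pseudo-trait from the PC1 linear combination of local GEBV
#'
#' `S_LC = y' x` per animal, where `y` is the vector of local GEBV
#' standardized by each trait's phenotypic SD and `x` the window's PC1
#' eigenvector. For animals without a phenotype for some trait, that
#' trait's local GEBV is replaced by its mean over the measured animals.
#'
#' @param lgm a [LocalGebvMatrix-class]
#' @param wp a [WindowPcaSet-class] from the same local GEBV
#' @param window window id (name in `windowRanges(wp)`)
#' @param adj an [AdjustedPheno-class] supplying phenotypic SDs and the
#'   missingness pattern
#' @return named numeric vector of S_LC per animal.
#' @export
pseudoTraitSlc <- function(lgm, wp, window, adj) {
  wi <- match(window, names(wp@windows))
  if (is.na(wi)) stop("window not found: ", window)
  ev <- wp@eig[[wi]]
  if (is.null(ev)) stop("eigenvector absent for window ", window)
  x <- ev$vectors[, 1]
  traits <- wp@traits
  sds <- phenoSd(adj)[traits]
  res <- adjustedResiduals(adj)
  animals <- rownames(lgm@values[[1]])
  Y <- vapply(traits, function(tr) {
    l <- lgm@values[[tr]][, wi]
    measured <- animals %in% rownames(res)[!is.na(res[, tr])]
    if (any(!measured)) l[!measured] <- mean(l[measured])
    l
  }, numeric(length(animals)))
  Y <- sweep(Y, 2, sds, "/")
  setNames(drop(Y %*% x), animals)
}

#' Best SNP in a window for the PC1 pseudo-trait
#'
#' Fits `S_LC = mean + SNP_i + animal + error` with the animal effect
#' random under the pedigree covariance A, one SNP at a time within the
#' window; the SNP with the highest F value wins (ties towards the smaller
#' position). The variance ratio comes from a one-time REML on S_LC.
#'
#' @param slc [pseudoTraitSlc()] output
#' @param geno a [GenotypeData-class]
#' @param ped an [AnimalPedigree-class]
#' @param window GRanges of the window (or its id in `windows`)
#' @param windows GRanges of all windows (for id lookup)
#' @param rot optional [polygenicRotation()] over `names(slc)`
#' @return one-row data.frame snp, chrom, bp, Fval, p; NULL (with a
#'   warning) when the window holds no polymorphic SNP.
#' @export
bestSnpInWindow <- function(slc, geno, ped, window, windows = NULL, rot = NULL) {
  if (is.character(window)) {
    if (is.null(windows)) stop("windows required to look up a window id")
    window <- windows[window]
  }
  map <- snpMap(geno)
  hit <- queryHits(findOverlaps(map, window))
  if (length(hit) == 0) {
    warning("no SNPs in window; skipped")
    return(NULL)
  }
  ids <- names(slc)
  Z <- dosage(geno)[ids, hit, drop = FALSE]
  poly <- matrixStats_colVars(Z) > 0
  if (!any(poly)) {
    warning("no polymorphic SNPs in window; skipped")
    return(NULL)
  }
  if (is.null(rot) || !identical(rot$ids, ids)) rot <- polygenicRotation(ped, ids)
  vc <- .remlEigenLambda(slc, rot)
  w <- 1 / (vc$sigma2a * rot$lambda + vc$sigma2e)
  Ut <- t(rot$U)
  yStar <- drop(Ut %*% slc)
  oneStar <- drop(Ut %*% rep(1, length(ids)))
  SStar <- Ut %*% Z[, poly, drop = FALSE]
  sc <- .rotatedScan(yStar, oneStar, SStar, w)
  Fv <- sc$Fwald
  tab <- snpTable(geno)[hit[poly], ]
  best <- order(-Fv, tab$bp)[1]
  data.frame(snp = tab$snp[best], chrom = tab$chrom[best], bp = tab$bp[best],
             Fval = Fv[best],
             p = pf(Fv[best], 1, length(ids) - 2, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

# 1-component REML (animal + error) in a precomputed eigenbasis
.remlEigenLambda <- function(y, rot) {
  ys <- drop(crossprod(rot$U, y))
  os <- drop(crossprod(rot$U, rep(1, length(y))))
  lam <- rot$lambda
  n <- length(y)
  nll <- function(logit) {
    h <- 1 / (1 + exp(-logit))
    d <- h * lam + (1 - h)
    w <- 1 / d
    mu <- sum(w * os * ys) / sum(w * os^2)
    rss <- sum((ys - mu * os)^2 / d)
    0.5 * (sum(log(d)) + n * log(rss))
  }
  opt <- optimize(nll, c(-8, 8))
  h <- 1 / (1 + exp(-opt$minimum))
  d <- h * lam + (1 - h)
  w <- 1 / d
  mu <- sum(w * os * ys) / sum(w * os^2)
  s2 <- sum((ys - mu * os)^2 / d) / (n - 1)
  list(sigma2a = h * s2, sigma2e = (1 - h) * s2)
}

#' Overlap of QTL call sets across methods
#'
#' By default regions are identified by exact SNP identity; with
#' `proximity_bp > 0`, calls within that distance on the same chromosome
#' are merged into one region (single linkage) before computing
#' memberships.
#'
#' @param calls named list of QTL call sets (data.frames with snp, chrom,
#'   bp)
#' @param proximity_bp merge distance (0 = exact SNP identity)
#' @return list: `venn` (named counts per membership cell, names are
#'   binary masks over the methods in order), `union_size`, `regions`
#'   (per-region membership table).
#' @export
compareMethods <- function(calls, proximity_bp = 0) {
  methods <- names(calls)
  all <- do.call(rbind, lapply(methods, function(m) {
    d <- calls[[m]]
    if (nrow(d) == 0) return(NULL)
    data.frame(method = m, snp = d$snp, chrom = d$chrom, bp = d$bp,
               stringsAsFactors = FALSE)
  }))
  if (is.null(all) || nrow(all) == 0)
    return(list(venn = setNames(integer(0), character(0)), union_size = 0L,
                regions = data.frame()))
  if (proximity_bp <= 0) {
    all$region <- all$snp
  } else {
    all <- all[order(all$chrom, all$bp), ]
    reg <- character(nrow(all))
    cur <- 0
    for (i in seq_len(nrow(all))) {
      if (i == 1 || all$chrom[i] != all$chrom[i - 1] ||
          all$bp[i] - all$bp[i - 1] > proximity_bp)
        cur <- cur + 1
      reg[i] <- paste0("region", cur)
    }
    all$region <- reg
  }
  memb <- vapply(methods, function(m)
    tapply(all$method == m, all$region, any), logical(length(unique(all$region))))
  if (is.null(dim(memb))) memb <- matrix(memb, nrow = 1, dimnames = list(unique(all$region), methods))
  mask <- apply(memb, 1, function(r) paste(as.integer(r), collapse = ""))
  venn <- table(mask)
  regions <- data.frame(region = rownames(memb), memb, mask = mask,
                        stringsAsFactors = FALSE, check.names = FALSE)
  list(venn = setNames(as.integer(venn), names(venn)),
       union_size = nrow(memb), regions = regions)
}

#' Correlation of SNP effects across traits between selected SNPs
#'
#' Pearson correlation of the per-trait effect vectors of each SNP pair —
#' similar patterns suggest the SNPs tag the same (or a physiologically
#' related) QTL.
#'
#' @param gwas named list of GWAS tables (one per trait)
#' @param snps SNP ids to correlate
#' @return SNP x SNP correlation matrix; SNPs with zero-variance effect
#'   vectors give NA rows and are reported via the `flagged` attribute.
#' @export
snpEffectCorrelation <- function(gwas, snps) {
  if (length(gwas) < 3) stop("at least three traits required")
  E <- vapply(gwas, function(g) g$effect[match(snps, g$snp)], numeric(length(snps)))
  E <- t(E) # traits x snps -> snps in columns
  colnames(E) <- snps
  zv <- apply(E, 2, function(x) sd(x, na.rm = TRUE) == 0 || all(is.na(x)))
  R <- suppressWarnings(cor(E, use = "pairwise.complete.obs"))
  diag(R) <- 1
  if (any(zv)) { R[zv, ] <- NA; R[, zv] <- NA }
  attr(R, "flagged") <- snps[zv]
  R
}

#' Candidate genes within a flank of each called SNP
#'
#' Genes whose 1-based inclusive span comes within `flank_bp` of the SNP
#' (closed bound: an edge exactly at the flank is included). When several
#' genes qualify, the nearest by edge distance is marked primary.
#'
#' @param calls QTL call set (snp, chrom, bp)
#' @param annotation gene intervals: a GRanges with a `gene` (or `Name`)
#'   column, or a data.frame chrom/start/end/gene (1-based inclusive)
#' @param flank_bp search flank either side of the SNP
#' @return data.frame: snp, gene, gene_start, gene_end, distance, primary.
#' @export
candidateGenes <- function(calls, annotation, flank_bp = 50e3) {
  if (is.data.frame(annotation)) {
    bad <- annotation$start > annotation$end
    if (any(bad)) {
      warning(sum(bad), " malformed gene interval(s) rejected")
      annotation <- annotation[!bad, , drop = FALSE]
    }
    gr <- GRanges(annotation$chrom, IRanges(annotation$start, annotation$end))
    gr$gene <- annotation$gene
  } else {
    gr <- annotation
    if (is.null(gr$gene)) gr$gene <- if (!is.null(gr$Name)) gr$Name else names(gr)
  }
  q <- GRanges(calls$chrom, IRanges(pmax(1, calls$bp - flank_bp),
                                    calls$bp + flank_bp))
  hits <- findOverlaps(q, gr)
  if (length(hits) == 0)
    return(data.frame(snp = character(), gene = character(),
                      gene_start = numeric(), gene_end = numeric(),
                      distance = numeric(), primary = logical()))
  qi <- queryHits(hits); si <- subjectHits(hits)
  dist <- pmax(0, pmax(start(gr)[si] - calls$bp[qi], calls$bp[qi] - end(gr)[si]))
  out <- data.frame(snp = calls$snp[qi], gene = gr$gene[si],
                    gene_start = start(gr)[si], gene_end = end(gr)[si],
                    distance = dist, stringsAsFactors = FALSE)
  out$primary <- FALSE
  for (s in unique(out$snp)) {
    i <- which(out$snp == s)
    out$primary[i[which.min(out$distance[i])]] <- TRUE
  }
  out
}
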