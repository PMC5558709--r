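#' Sampler settings for the BayesR mixture model
#'
#' SNP effects are drawn from a mixture of four normal distributions with
#' variances equal to 0, 0.01, 0.1 and 1 percent of the genetic variance.
#' The reference analysis runs 40,000 iterations with 20,000 of burn-in
#' averaged over five chains; the desk-scale defaults here (10,000 / 4,000,
#' two chains) keep a full multi-trait analysis in the minutes range and are
#' overridable.
#'
#' @param n_iter,burn_in,n_chains,thin Gibbs controls
#' @param class_var_fracs mixture-class variances as fractions of the
#'   genetic variance; ascending, first element 0.
#' @param dirichlet_alpha prior concentration for the class proportions
#' @param polygenic fit a residual polygenic effect with pedigree covariance
#' @param seed chain seeds are derived from this via [splitSeed()]
#' @return list of class `BayesRConfig`
#' @export
bayesRConfig <- function(n_iter = 10000, burn_in = 4000, n_chains = 2,
                         thin = 10, class_var_fracs = c(0, 1e-4, 1e-3, 1e-2),
                         dirichlet_alpha = c(1, 1, 1, 1), polygenic = TRUE,
                         seed = 1) {
  if (burn_in >= n_iter) stop("configuration error: burn_in must be < n_iter")
  if (class_var_fracs[1] != 0)
    stop("configuration error: first mixture class must have zero variance")
  if (is.unsorted(class_var_fracs))
    stop("configuration error: class_var_fracs must be ascending")
  cfg <- list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
              n_chains = as.integer(n_chains), thin = as.integer(thin),
              class_var_fracs = class_var_fracs,
              dirichlet_alpha = dirichlet_alpha,
              polygenic = polygenic, seed = seed)
  class(cfg) <- "BayesRConfig"
  cfg
}

#' Fit the BayesR mixture model for one trait
#'
#' Single-site Gibbs sampling over SNP effects (class membership, then an
#' effect draw for nonzero classes), a Dirichlet update of the class
#' proportions, scaled-inverse-chi-square updates of the genetic and
#' residual variance levels (class variances stay tied to the current
#' genetic variance), and a residual polygenic effect sampled under the
#' pedigree covariance A. Phenotypes must already be adjusted for fixed,
#' breed and sire-by-flock effects. Posterior means and class probabilities
#' are averaged over post-burn-in draws of all chains.
#'
#' Between-chain agreement of the genetic-variance draws is reported as a
#' warning when the chains disagree strongly (split-R-hat style ratio).
#'
#' @param geno a [GenotypeData-class]
#' @param adj an [AdjustedPheno-class]
#' @param ped an [AnimalPedigree-class] (used for the polygenic term)
#' @param cfg a [bayesRConfig()]
#' @param trait trait name
#' @param rot optional [polygenicRotation()] over the analysis animals
#' @return a [BayesRFit-class]
#' @export
bayesR <- function(geno, adj, ped, cfg = bayesRConfig(), trait, rot = NULL) {
  res <- adjustedResiduals(adj)
  ids <- intersect(rownames(dosage(geno)), rownames(res)[!is.na(res[, trait])])
  if (length(ids) == 0) stop("no overlap between genotyped and phenotyped animals")
  y <- res[ids, trait]
  M <- dosage(geno)[ids, , drop = FALSE]
  p <- colMeans(M) / 2
  Z <- sweep(M, 2, 2 * p, "-")
  storage.mode(Z) <- "double"

  usePoly <- isTRUE(cfg$polygenic)
  if (usePoly && (is.null(rot) || !identical(rot$ids, ids)))
    rot <- polygenicRotation(ped, ids)
  U <- if (usePoly) rot$U else matrix(0, 0, 0)
  lam <- if (usePoly) rot$lambda else numeric(0)

  vy <- var(y)
  nkeep <- cfg$n_iter - cfg$burn_in
  eff <- 0; cp <- 0; traces <- list()
  for (ch in seq_len(cfg$n_chains)) {
    set.seed(splitSeed(cfg$seed + 7 * ch, "bayesr"))
    fit <- .bayesrGibbs(Z, y, cfg$class_var_fracs, cfg$dirichlet_alpha,
                        cfg$n_iter, cfg$burn_in, cfg$thin, usePoly, U, lam,
                        4.0, 0.5 * vy, 0.5 * vy,
                        if (usePoly) 0.25 * vy else 0.0)
    eff <- eff + fit$effMean
    cp <- cp + fit$classProb
    tr <- as.data.frame(fit$traces)
    names(tr) <- c("sigma2_g", "sigma2_e", "sigma2_poly", "n_nonzero")
    tr$chain <- ch
    traces[[ch]] <- tr
  }
  eff <- eff / cfg$n_chains
  cp <- cp / cfg$n_chains
  traces <- as.matrix(do.call(rbind, traces))

  if (cfg$n_chains > 1) {
    bymean <- tapply(traces[, "sigma2_g"], traces[, "chain"], mean)
    byvar <- tapply(traces[, "sigma2_g"], traces[, "chain"], var)
    B <- var(bymean); W <- mean(byvar)
    if (is.finite(B) && W > 0 && sqrt(1 + B / W) > 1.2)
      warning("chains disagree on sigma2_g (split R-hat style ratio > 1.2); ",
              "consider more iterations")
  }

  new("BayesRFit", trait = trait, snpEffects = as.numeric(eff),
      classProb = cp, ppNonzero = as.numeric(1 - cp[, 1]),
      traces = traces, snpIds = colnames(M),
      config = c(cfg, list(n_animals = length(ids), allele_freq_centered = TRUE)))
}

#' GEBV from posterior-mean SNP effects
#'
#' `GEBV = Z beta` with `Z` the allele-frequency-centered dosage matrix and
#' `beta` the posterior-mean effects. The polygenic term is excluded: for
#' validation animals only marker information carries over.
#'
#' @param fit a [BayesRFit-class]
#' @param geno a [GenotypeData-class] sharing the fit's SNP map
#' @return named numeric vector of GEBV for all genotyped animals.
#' @export
gebvFromSnpEffects <- function(fit, geno) {
  if (!identical(fit@snpIds, colnames(dosage(geno))))
    stop("SNP map mismatch between fit and genotypes")
  M <- dosage(geno)
  p <- colMeans(M) / 2
  Z <- sweep(M, 2, 2 * p, "-")
  drop(Z %*% fit@snpEffects)
}

#' Local GEBV in non-overlapping genomic windows
#'
#' Chromosomes are tiled with half-open windows `[k*w, (k+1)*w)` anchored at
#' position 0; each window's GEBV is the centered-dosage product with the
#' posterior-mean effects of the SNPs inside it. Windows without SNPs carry
#' zeros, and the sum over windows reproduces the whole-genome GEBV.
#'
#' @param fits a [BayesRFit-class] or list of them (one per trait)
#' @param geno a [GenotypeData-class]
#' @param window_bp window size in bp
#' @return a [LocalGebvMatrix-class]
#' @export
localGebv <- function(fits, geno, window_bp = 250e3) {
  if (is(fits, "BayesRFit")) fits <- setNames(list(fits), fits@trait)
  if (window_bp <= 0) stop("window_bp must be positive")
  M <- dosage(geno)
  p <- colMeans(M) / 2
  Z <- sweep(M, 2, 2 * p, "-")
  map <- snpTable(geno)
  widx <- floor((map$bp - 1) / window_bp)
  key <- paste0(map$chrom, ":", widx)

  chroms <- unique(map$chrom)
  wdf <- do.call(rbind, lapply(chroms, function(cc) {
    mx <- max(widx[map$chrom == cc])
    data.frame(chrom = cc, widx = 0:mx)
  }))
  wkey <- paste0(wdf$chrom, ":", wdf$widx)
  windows <- GRanges(wdf$chrom,
                     IRanges(start = wdf$widx * window_bp + 1,
                             end = (wdf$widx + 1) * window_bp))
  names(windows) <- wkey

  snpGroups <- split(seq_len(nrow(map)), key)
  vals <- lapply(fits, function(f) {
    if (!identical(f@snpIds, colnames(M)))
      stop("SNP map mismatch between fit and genotypes")
    out <- matrix(0, nrow(M), length(wkey),
                  dimnames = list(rownames(M), wkey))
    for (k in names(snpGroups)) {
      j <- snpGroups[[k]]
      out[, k] <- Z[, j, drop = FALSE] %*% f@snpEffects[j]
    }
    out
  })
  names(vals) <- vapply(fits, function(f) f@trait, character(1))
  new("LocalGebvMatrix", values = vals, windows = windows,
      traits = names(vals))
}

#' Variance of local GEBV as a fraction of phenotypic variance
#'
#' A high variance of local GEBV in a window indicates a QTL for that trait
#' in the window. Values are fractions of the phenotypic variance (multiply
#' by 100 for the percent scale).
#'
#' @param lgm a [LocalGebvMatrix-class]
#' @param adj an [AdjustedPheno-class] supplying per-trait phenotypic SD
#' @return matrix windows x traits of variance fractions.
#' @export
localGebvVariance <- function(lgm, adj) {
  sds <- phenoSd(adj)[lgm@traits]
  if (any(is.na(sds) | sds <= 0)) stop("zero or missing phenotypic variance")
  out <- vapply(lgm@traits, function(tr) {
    v <- apply(lgm@values[[tr]], 2, var)
    v / sds[tr]^2
  }, numeric(length(lgm@windows)))
  rownames(out) <- names(lgm@windows)
  out
}
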