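#' Declare the mixed model used for adjustment and association
#'
#' The full model is
#' `y = mu + X b + Z1 a + Z1 Q q + Z2 s.f + e`
#' with fixed effects `b` (flock, sex, age covariates, and any user-declared
#' categorical or interaction terms such as a birth-by-rearing-type group),
#' a pedigree polygenic effect `a ~ N(0, A sigma2_a)`, a breed random effect
#' `q` acting through pedigree breed proportions, a sire-by-flock
#' interaction `s.f`, and residual `e`.
#'
#' @param fixed_terms character vector of covariate-table columns (may
#'   include interaction terms like `"flock:sex"`); categorical vs covariate
#'   is decided by column type.
#' @param breed_random,sire_flock_random,polygenic logical switches for the
#'   random terms.
#' @return a list of class `ModelSpec`.
#' @export
modelSpec <- function(fixed_terms = c("flock", "sex", "age"),
                      breed_random = TRUE, sire_flock_random = TRUE,
                      polygenic = TRUE) {
  spec <- list(fixed_terms = fixed_terms, breed_random = breed_random,
               sire_flock_random = sire_flock_random, polygenic = polygenic)
  class(spec) <- "ModelSpec"
  spec
}

.checkSpecColumns <- function(spec, covariates) {
  vars <- unique(unlist(strsplit(spec$fixed_terms, ":", fixed = TRUE)))
  need <- vars
  if (isTRUE(spec$sire_flock_random)) need <- c(need, "sire", "flock")
  if (isTRUE(spec$breed_random)) need <- c(need, "breedQ")
  miss <- setdiff(need, colnames(covariates))
  if (length(miss)) stop("phenotype table lacks model columns: ",
                         paste(miss, collapse = ", "))
}

#' REML variance components for one trait
#'
#' Average-information REML for the pedigree mixed model declared by
#' [modelSpec()]. Heritability is `sigma2_a / (sigma2_a + sigma2_sf +
#' sigma2_e)`; the breed component, a between-strain variance, is excluded
#' from the denominator.
#'
#' @param pheno a [PhenotypeData-class]
#' @param ped an [AnimalPedigree-class]
#' @param spec a [modelSpec()]
#' @param trait trait name
#' @param maxit,tol REML controls
#' @return a [VarComp-class]; non-convergence is flagged, not an error.
#' @export
estimateVarianceComponents <- function(pheno, ped, spec, trait,
                                       maxit = 50, tol = 1e-8) {
  Y <- traitMatrix(pheno); cov <- covariateTable(pheno)
  .checkSpecColumns(spec, cov)
  y <- Y[, trait]
  keep <- rownames(Y)[!is.na(y)]
  if (length(keep) < 50)
    warning("fewer than 50 records for trait ", trait)
  if (length(keep) < 10) stop("too few records for REML: ", length(keep))
  X <- .fixedDesign(spec, cov, keep)
  K <- .buildKernels(spec, ped, cov, keep)
  fit <- .aiReml(y[keep], X, K, maxit = maxit, tol = tol)
  th <- fit$theta
  sig <- c(a = unname(th["a"] %||% 0), sf = unname(th["sf"] %||% 0),
           q = unname(th["q"] %||% 0), e = unname(th[["e"]]))
  sig[is.na(sig)] <- 0
  h2 <- unname(sig["a"] / (sig["a"] + sig["sf"] + sig["e"]))
  new("VarComp", trait = trait, sigma2 = sig, h2 = h2,
      converged = fit$converged, niter = as.integer(fit$niter))
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || all(is.na(a))) b else a

#' Adjust phenotypes for fixed, breed and sire-by-flock effects
#'
#' Removes the GLS fixed-effect fit and the BLUPs of the breed and
#' sire-by-flock random effects; the polygenic effect is deliberately left
#' in the residual (downstream stages re-fit it). With an empty model the
#' residuals are the centered phenotypes. Missing phenotypes stay missing.
#'
#' @inheritParams estimateVarianceComponents
#' @param vc optional list of [VarComp-class] per trait (named); estimated
#'   by REML when absent.
#' @return an [AdjustedPheno-class]. The per-trait phenotypic SD stored is
#'   `sqrt(sigma2_a + sigma2_sf + sigma2_e)`, the phenotypic variance net of
#'   fixed effects.
#' @export
adjustPhenotypes <- function(pheno, ped, spec, vc = NULL) {
  Y <- traitMatrix(pheno); cov <- covariateTable(pheno)
  traits <- colnames(Y)
  res <- Y; res[] <- NA_real_
  sds <- numeric(length(traits)); names(sds) <- traits
  vcl <- vector("list", length(traits)); names(vcl) <- traits

  noTerms <- length(spec$fixed_terms) == 0 &&
    !isTRUE(spec$breed_random) && !isTRUE(spec$sire_flock_random)

  for (tr in traits) {
    y <- Y[, tr]
    keep <- rownames(Y)[!is.na(y)]
    if (noTerms) {
      res[keep, tr] <- y[keep] - mean(y[keep])
      sds[tr] <- sd(y[keep])
      vcl[[tr]] <- NULL
      next
    }
    v <- if (!is.null(vc) && !is.null(vc[[tr]])) vc[[tr]] else
      estimateVarianceComponents(pheno, ped, spec, tr)
    X <- .fixedDesign(spec, cov, keep)
    K <- .buildKernels(spec, ped, cov, keep)
    th <- c(v@sigma2[names(K)], e = unname(v@sigma2["e"]))
    gb <- .glsBlup(y[keep], X, K, as.list(th))
    r <- y[keep] - gb$fitted_fixed
    for (nm in intersect(c("sf", "q"), names(gb$blup))) r <- r - gb$blup[[nm]]
    res[keep, tr] <- r - mean(r)
    sds[tr] <- sqrt(sum(v@sigma2[c("a", "sf", "e")]))
    vcl[[tr]] <- v
  }
  new("AdjustedPheno", residuals = res, phenoSd = sds, varcomp = vcl)
}

#' Single-trait GWAS with a polygenic random effect
#'
#' Tests each SNP one at a time on the adjusted phenotype under
#' `y_adj = mu + s_i alpha_i + a + e`, `a ~ N(0, A sigma2_a)`. The model is
#' rotated once into the eigenbasis of A, after which every SNP is an exact
#' generalized-least-squares fit at the REML variances. P-values use the
#' normal reference (appropriate at these sample sizes). SNPs monomorphic
#' among the tested animals are returned flagged with no statistics.
#'
#' @param geno a [GenotypeData-class]
#' @param adj an [AdjustedPheno-class]
#' @param ped an [AnimalPedigree-class]
#' @param trait trait name
#' @param rot optional precomputed [polygenicRotation()] over exactly the
#'   animals with data (recomputed if absent or mismatched).
#' @return data.frame: snp, chrom, bp, effect, se, t, p, n, flag.
#' @export
singleTraitGwas <- function(geno, adj, ped, trait, rot = NULL) {
  res <- adjustedResiduals(adj)
  ids <- intersect(rownames(dosage(geno)), rownames(res)[!is.na(res[, trait])])
  if (length(ids) == 0) stop("no overlap between genotyped and phenotyped animals")
  v <- adj@varcomp[[trait]]
  s2a <- if (!is.null(v)) unname(v@sigma2["a"]) else 0
  s2e <- if (!is.null(v)) unname(v@sigma2["e"]) else var(res[ids, trait])

  if (is.null(rot) || !identical(rot$ids, ids)) rot <- polygenicRotation(ped, ids)
  w <- 1 / (s2a * rot$lambda + s2e)
  Ut <- t(rot$U)
  yStar <- drop(Ut %*% res[ids, trait])
  oneStar <- drop(Ut %*% rep(1, length(ids)))

  Z <- dosage(geno)[ids, , drop = FALSE]
  poly <- matrixStats_colVars(Z) > 0
  out <- snpTable(geno)
  out$effect <- NA_real_; out$se <- NA_real_; out$t <- NA_real_
  out$p <- NA_real_; out$n <- length(ids)
  out$flag <- ifelse(poly, "", "monomorphic")
  if (any(poly)) {
    SStar <- Ut %*% Z[, poly, drop = FALSE]
    sc <- .rotatedScan(yStar, oneStar, SStar, w)
    out$effect[poly] <- sc$effect
    out$se[poly] <- sc$se
    out$t[poly] <- sc$t
    out$p[poly] <- 2 * pnorm(-abs(sc$t))
  }
  out
}

# column variances without an extra dependency (NA-free integer/numeric)
matrixStats_colVars <- function(Z) {
  n <- nrow(Z)
  cm <- colMeans(Z)
  (colSums(Z^2) - n * cm^2) / (n - 1)
}

#' Analytical false discovery rate for a GWAS threshold
#'
#' `FDR% = 100 * P(1 - A/T) / ((A/T)(1 - P))` with `P` the significance
#' threshold, `A` the number of significant tests and `T` the number of
#' tests: the expected share of false positives among the declared
#' discoveries. Values above 100% (or `A = 0`) are not meaningful and are
#' reported as `NA` ("unavailable"). The estimate is rounded to one decimal
#' for reporting.
#'
#' @param p_threshold significance threshold in (0, 1)
#' @param n_significant number of tests significant at the threshold
#' @param n_tests total number of tests
#' @return FDR in percent, rounded to one decimal; `NA` when unavailable.
#' @export
fdrEstimate <- function(p_threshold, n_significant, n_tests) {
  if (p_threshold <= 0 || p_threshold >= 1) stop("p_threshold must be in (0, 1)")
  if (n_significant > n_tests) stop("n_significant exceeds n_tests")
  if (n_significant < 0) stop("counts must be non-negative")
  if (n_significant == 0) return(NA_real_)
  at <- n_significant / n_tests
  fdr <- 100 * p_threshold * (1 - at) / (at * (1 - p_threshold))
  if (fdr > 100) return(NA_real_)
  round(fdr, 1)
}
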