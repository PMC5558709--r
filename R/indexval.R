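#' Phenotypic covariance of adjusted traits, made positive definite
#'
#' Pairwise-complete estimation can leave the matrix indefinite; eigenvalues
#' are floored at `eig_floor` times the largest (nearest-PD projection) and
#' the shrinkage applied is recorded in the `adjusted` attribute.
#'
#' @param adj an [AdjustedPheno-class]
#' @param eig_floor relative eigenvalue floor
#' @return trait x trait covariance matrix `U` with attribute `adjusted`.
#' @export
phenoCovariance <- function(adj, eig_floor = 1e-8) {
  R <- adjustedResiduals(adj)
  U <- cov(R, use = "pairwise.complete.obs")
  if (anyNA(U)) stop("trait pair with no common records")
  e <- eigen(U, symmetric = TRUE)
  floorv <- eig_floor * max(e$values)
  adjAmt <- 0
  if (min(e$values) < floorv) {
    vals <- pmax(e$values, floorv)
    adjAmt <- max(vals - e$values)
    U <- e$vectors %*% (vals * t(e$vectors))
    dimnames(U) <- list(colnames(R), colnames(R))
  }
  attr(U, "adjusted") <- adjAmt
  U
}

#' Predict missing phenotypes by multiple regression on measured traits
#'
#' For each animal, traits are ordered measured-first and the missing block
#' is predicted as `yhat_n = -(U^nn)^-1 U^nm y_m`, where `U^nn` and `U^nm`
#' are blocks of the inverse of the full trait covariance. This equals the
#' conditional expectation `Sigma_nm Sigma_mm^-1 y_m` of a multivariate
#' normal by the partitioned-inverse identity. Measured cells are returned
#' untouched.
#'
#' @param adj an [AdjustedPheno-class]
#' @param u trait covariance from [phenoCovariance()] (computed if absent)
#' @return completed animals x traits matrix.
#' @export
imputeMissingPhenotypes <- function(adj, u = NULL) {
  R <- adjustedResiduals(adj)
  if (is.null(u)) u <- phenoCovariance(adj)
  none <- rownames(R)[rowSums(!is.na(R)) == 0]
  if (length(none))
    stop("animal(s) with no measured trait: ", paste(head(none, 5), collapse = ", "))
  Ui <- chol2inv(chol(u))
  out <- R
  miss <- is.na(R)
  patterns <- apply(miss, 1, function(m) paste(as.integer(m), collapse = ""))
  for (pat in unique(patterns)) {
    rows <- which(patterns == pat)
    m <- miss[rows[1], ]
    if (!any(m)) next
    Unn <- Ui[m, m, drop = FALSE]
    Unm <- Ui[m, !m, drop = FALSE]
    ym <- t(R[rows, !m, drop = FALSE])
    out[rows, m] <- t(-solve(Unn, Unm %*% ym))
  }
  out
}

#' Covariance of estimated SNP effects across traits
#'
#' `C` is the trait x trait covariance of the raw estimated SNP effects
#' (not t-values) over all SNPs, computed in the training population.
#'
#' @param gwas named list of GWAS tables (training population)
#' @return trait x trait covariance matrix.
#' @export
effectCovariance <- function(gwas) {
  snps <- gwas[[1]]$snp
  E <- vapply(gwas, function(g) g$effect[match(snps, g$snp)],
              numeric(length(snps)))
  cov(E, use = "complete.obs")
}

#' Linear index combining trait phenotypes for one putative QTL
#'
#' `y_I = b' C^-1 y` per animal, with `b` the SNP's estimated effects on
#' the traits (training only), `C` the effect covariance from
#' [effectCovariance()], and `y` the completed adjusted phenotypes. A
#' singular `C` is shrunk by an eigenvalue floor (recorded).
#'
#' @param effects_b named per-trait effects of the SNP
#' @param c_mat effect covariance `C`
#' @param completed completed phenotype matrix ([imputeMissingPhenotypes()])
#' @return named per-animal index values.
#' @export
linearIndex <- function(effects_b, c_mat, completed) {
  traits <- colnames(completed)
  b <- effects_b[traits]
  C <- c_mat[traits, traits]
  e <- eigen(C, symmetric = TRUE)
  floorv <- 1e-8 * max(e$values)
  if (min(e$values) < floorv) {
    vals <- pmax(e$values, floorv)
    C <- e$vectors %*% (vals * t(e$vectors))
    message("singular effect covariance; eigenvalue floor applied")
  }
  w <- solve(C, b)
  setNames(drop(completed %*% w), rownames(completed))
}

#' Validate selected SNPs through their linear indices
#'
#' For each selected SNP, the SNP's own linear index is computed for the
#' validation animals (from training effects and effect covariance) and
#' regressed on the SNP under `y_I = mean + SNP + animal + error` with the
#' animal effect random under pedigree covariance. Reported per SNP: the
#' validation effect, P-value and whether its sign matches the training
#' direction; plus summary counts of significant SNPs (P < 0.05), the
#' percent with matching direction, and the analytical FDR at 0.05.
#'
#' @param snps SNP ids to validate
#' @param trainGwas named list of training GWAS tables (supplies b and C)
#' @param completedValid completed adjusted phenotypes of validation
#'   animals
#' @param geno a [GenotypeData-class]
#' @param ped an [AnimalPedigree-class]
#' @param rot optional [polygenicRotation()] over the validation animals
#' @return list: `table` per SNP, `summary` (n_tested, n_significant,
#'   pct_same_direction, pct_same_direction_significant, fdr_pct).
#' @export
validateIndexSnps <- function(snps, trainGwas, completedValid, geno, ped,
                              rot = NULL) {
  C <- effectCovariance(trainGwas)
  ids <- intersect(rownames(completedValid), rownames(dosage(geno)))
  if (length(ids) == 0) stop("no genotyped validation animals")
  Yv <- completedValid[ids, , drop = FALSE]
  if (is.null(rot) || !identical(rot$ids, ids)) rot <- polygenicRotation(ped, ids)
  Ut <- t(rot$U)
  oneStar <- drop(Ut %*% rep(1, length(ids)))
  M <- dosage(geno)[ids, , drop = FALSE]

  rows <- lapply(snps, function(s) {
    bvec <- vapply(trainGwas, function(g) g$effect[match(s, g$snp)], numeric(1))
    z <- M[, s]
    if (var(z) == 0)
      return(data.frame(snp = s, effect_valid = NA_real_, p_valid = NA_real_,
                        same_direction = NA, flag = "monomorphic"))
    yI <- linearIndex(bvec, C, Yv)
    vc <- .remlEigenLambda(yI, rot)
    w <- 1 / (vc$sigma2a * rot$lambda + vc$sigma2e)
    sc <- .rotatedScan(drop(Ut %*% yI), oneStar,
                       Ut %*% matrix(z, ncol = 1), w)
    # the index is built so that the training effect direction is positive
    data.frame(snp = s, effect_valid = sc$effect, p_valid = 2 * pnorm(-abs(sc$t)),
               same_direction = sign(sc$effect) > 0, flag = "",
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  ok <- tab$flag == ""
  nTested <- sum(ok)
  nSig <- sum(ok & tab$p_valid < 0.05)
  sig <- ok & tab$p_valid < 0.05
  summary <- data.frame(
    n_tested = nTested,
    n_significant = nSig,
    pct_same_direction = 100 * mean(tab$same_direction[ok]),
    pct_same_direction_significant =
      if (nSig > 0) 100 * mean(tab$same_direction[sig]) else NA_real_,
    fdr_pct = fdrEstimate(0.05, nSig, max(nTested, 1)))
  list(table = tab, summary = summary)
}
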