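#' Genomic relationship matrix container
#'
#' @slot mat animal x animal relationship values.
#' @slot nSnps SNPs used after the MAF filter.
#' @slot mafMin MAF threshold applied (SNPs with MAF <= threshold excluded).
#' @slot nExcluded SNPs removed by the filter.
#' @export
setClass("Grm", representation(mat = "matrix", nSnps = "integer",
                               mafMin = "numeric", nExcluded = "integer"))

#' @rdname buildGrm
#' @param x a Grm object
#' @export
setGeneric("grmMatrix", function(x) standardGeneric("grmMatrix"))
#' @rdname buildGrm
#' @export
setMethod("grmMatrix", "Grm", function(x) x@mat)

setMethod("show", "Grm", function(object) {
  cat("Grm:", nrow(object@mat), "animals from", object@nSnps,
      "SNPs (", object@nExcluded, "excluded at MAF <=", object@mafMin, ")\n")
  cat("  diagonal mean:", round(mean(diag(object@mat)), 3), "\n")
})

#' Pedigree numerator relationship matrix (tabular method)
#'
#' @param ped an [AnimalPedigree-class] (parents precede offspring; an
#'   animal appearing among its own ancestors is rejected by the class
#'   validity).
#' @return dense symmetric matrix with inbreeding on the diagonal, rows and
#'   columns named by animal id.
#' @export
buildAMatrix <- function(ped) .fullA(ped)

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with the Mendelian-sampling variance corrected for
#' parental inbreeding (Meuwissen-Luo style).
#' @inheritParams buildAMatrix
#' @return a sparse symmetric [Matrix::Matrix] with id dimnames.
#' @export
buildAInverse <- function(ped) {
  df <- pedTable(ped)
  s <- match(df$sire, df$id); s[is.na(s)] <- 0L
  d <- match(df$dam, df$id); d[is.na(d)] <- 0L
  Fcoef <- diag(.fullA(ped)) - 1
  tri <- .ainverseTriplets(as.integer(s), as.integer(d), Fcoef)
  Matrix::sparseMatrix(i = tri$i, j = tri$j, x = tri$x, symmetric = TRUE,
                       dims = c(nrow(df), nrow(df)),
                       dimnames = list(df$id, df$id))
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / (2 sum p_j (1 - p_j))` with `Z` the dosages centered by twice
#' the allele frequency computed over all animals supplied. SNPs with minor
#' allele frequency at or below `maf_min` are excluded; missing dosages are
#' mean-imputed for the purpose of G.
#'
#' @param geno a [GenotypeData-class]
#' @param maf_min MAF exclusion threshold
#' @return a [Grm-class]
#' @export
buildGrm <- function(geno, maf_min = 0.005) {
  M <- dosage(geno)
  if (nrow(M) < 2) stop("at least two animals required")
  p <- colMeans(M, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf > maf_min
  if (!any(keep)) stop("all SNPs excluded by the MAF filter")
  M <- M[, keep, drop = FALSE]; p <- p[keep]
  Z <- sweep(M, 2, 2 * p, "-")
  if (anyNA(Z)) Z[is.na(Z)] <- 0 # missing -> population mean after centering
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Z) / denom
  new("Grm", mat = G, nSnps = as.integer(sum(keep)), mafMin = maf_min,
      nExcluded = as.integer(sum(!keep)))
}

#' Cross-validation folds by whole sire families
#'
#' Crossbred animals (0.25 < Q <= 0.90) and straightbred animals sharing a
#' sire with a crossbred are assigned to every training set (fold 0). The
#' remaining straightbred animals (Q > 0.90) are split into `k` folds by
#' allocating whole sire families at random, so no validation animal has a
#' paternal half-sib in training.
#'
#' @param ped an [AnimalPedigree-class]; only the youngest generation is
#'   assigned.
#' @param seed integer seed for the family shuffle
#' @param k number of folds
#' @return data.frame `id`, `sire`, `fold` (0 = always-training).
#' @export
makeCvFolds <- function(ped, seed, k = 5) {
  df <- pedTable(ped)
  off <- df[df$generation == max(df$generation), ]
  xb <- off$breedQ > 0.25 & off$breedQ <= 0.90
  xbSires <- unique(off$sire[xb])
  always <- xb | off$sire %in% xbSires
  elig <- unique(off$sire[!always])
  if (length(elig) < k)
    stop("fewer than ", k, " eligible straightbred sire families")
  set.seed(splitSeed(seed, "folds"))
  elig <- sample(elig) # round-robin over the shuffled family order
  fold <- setNames(rep_len(seq_len(k), length(elig)), elig)
  out <- data.frame(id = off$id, sire = off$sire,
                    fold = ifelse(always, 0L, unname(fold[off$sire])),
                    stringsAsFactors = FALSE)
  out
}

# single-fit GBLUP: all animals' GEBV from a training subset, given
# variances. Validation animals are in G but contribute no phenotype.
.gblupSolve <- function(G, y, trainIds, sigma2g, sigma2e, ridge = 1e-8) {
  tr <- trainIds
  Vt <- sigma2g * G[tr, tr] + diag(sigma2e, length(tr))
  ch <- tryCatch(chol(Vt), error = function(e) {
    warning("singular GBLUP coefficient matrix; ridge added")
    chol(Vt + diag(ridge, length(tr)))
  })
  Vi <- chol2inv(ch)
  one <- rep(1, length(tr))
  mu <- sum(Vi %*% y[tr]) / sum(Vi %*% one)
  drop(sigma2g * G[, tr] %*% (Vi %*% (y[tr] - mu)))
}

# REML for y = mu + g + e, g ~ N(0, G sigma2g), via the eigen trick
.remlEigenG <- function(y, G) {
  e <- eigen(G, symmetric = TRUE)
  U <- e$vectors; lam <- pmax(e$values, 0)
  ys <- drop(crossprod(U, y)); os <- drop(crossprod(U, rep(1, length(y))))
  vy <- var(y)
  nll <- function(logit) {
    h <- 1 / (1 + exp(-logit)) # fraction of variance genetic
    s2 <- vy
    d <- s2 * (h * lam + (1 - h))
    w <- 1 / d
    mu <- sum(w * os * ys) / sum(w * os^2)
    r <- ys - mu * os
    # profile the scale out
    n <- length(y)
    rss <- sum(r^2 / (h * lam + (1 - h)))
    0.5 * (sum(log(h * lam + (1 - h))) + n * log(rss))
  }
  opt <- optimize(nll, c(-8, 8))
  h <- 1 / (1 + exp(-opt$minimum))
  d0 <- h * lam + (1 - h)
  w <- 1 / d0
  ys2 <- ys; os2 <- os
  mu <- sum(w * os2 * ys2) / sum(w * os2^2)
  r <- ys2 - mu * os2
  s2tot <- sum(r^2 / d0) / (length(y) - 1)
  list(sigma2g = h * s2tot, sigma2e = (1 - h) * s2tot)
}

#' GBLUP genomic prediction with family cross-validation
#'
#' For each fold, validation animals keep their place in the GRM but their
#' phenotypes are treated as unknown; variance components are re-estimated
#' by REML on the training animals of that fold unless supplied. GEBV of the
#' validation animals are collected across folds.
#'
#' @param grm a [buildGrm()] result
#' @param adj an [AdjustedPheno-class]
#' @param folds a [makeCvFolds()] assignment
#' @param trait trait name
#' @param vc optional list(sigma2g, sigma2e) fixed across folds
#' @return data.frame animal, trait, gebv, fold, method = "GBLUP".
#' @export
gblupFit <- function(grm, adj, folds, trait, vc = NULL) {
  G <- grmMatrix(grm)
  res <- adjustedResiduals(adj)[, trait]
  ids <- intersect(rownames(G), names(res)[!is.na(res)])
  folds <- folds[folds$id %in% rownames(G), ]
  out <- list()
  for (f in sort(unique(folds$fold[folds$fold > 0]))) {
    valid <- folds$id[folds$fold == f]
    train <- intersect(ids, folds$id[folds$fold != f])
    v <- if (is.null(vc)) .remlEigenG(res[train], G[train, train]) else vc
    gebv <- .gblupSolve(G, res, train, v$sigma2g, v$sigma2e)
    out[[length(out) + 1]] <- data.frame(
      animal = valid, trait = trait, gebv = gebv[valid], fold = f,
      method = "GBLUP", stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Accuracy of GEBV from family cross-validation
#'
#' Per fold, accuracy is the correlation between GEBV and the adjusted
#' phenotype of the validation animals divided by the square root of the
#' trait heritability, an estimate of the correlation between GEBV and true
#' breeding values. The mean and its standard error over folds are
#' reported.
#'
#' @param gebv a [gblupFit()]-style table (animal, gebv, fold)
#' @param adj an [AdjustedPheno-class]
#' @param trait trait name
#' @param h2 trait heritability (> 0)
#' @return list: `per_fold` data.frame, `mean`, `se`.
#' @export
gebvAccuracy <- function(gebv, adj, trait, h2) {
  if (h2 <= 0) stop("h2 must be positive")
  res <- adjustedResiduals(adj)[, trait]
  pf <- lapply(split(gebv, gebv$fold), function(g) {
    y <- res[g$animal]
    ok <- !is.na(y)
    if (sum(ok) < 10) warning("fewer than 10 validation animals in a fold")
    if (sd(g$gebv[ok]) == 0) {
      warning("zero-variance GEBV in fold ", g$fold[1], "; fold excluded")
      return(data.frame(fold = g$fold[1], n = sum(ok), accuracy = NA_real_))
    }
    data.frame(fold = g$fold[1], n = sum(ok),
               accuracy = cor(g$gebv[ok], y[ok]) / sqrt(h2))
  })
  pf <- do.call(rbind, pf)
  acc <- pf$accuracy[!is.na(pf$accuracy)]
  list(per_fold = pf, mean = mean(acc), se = sd(acc) / sqrt(length(acc)))
}
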