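# Dense REML machinery shared by variance-component estimation, phenotype
# adjustment, GBLUP and the polygenic-aware association tests.
#
# The model is y = Xb + sum_r u_r + e with u_r ~ N(0, theta_r K_r) for
# precomputed n x n covariance kernels K_r (pedigree A, sire-by-flock
# incidence, breed proportions) and e ~ N(0, theta_e I). Estimation is
# average-information REML with step-halving and a positivity floor.

# full-pedigree numerator relationship matrix, rows/cols named by id
.fullA <- function(ped) {
  df <- pedTable(ped)
  s <- match(df$sire, df$id); s[is.na(s)] <- 0L
  d <- match(df$dam, df$id); d[is.na(d)] <- 0L
  A <- .tabularA(as.integer(s), as.integer(d))
  dimnames(A) <- list(df$id, df$id)
  A
}

# covariance kernels over a given animal subset, in covariate row order
.buildKernels <- function(spec, ped, covariates, animals) {
  K <- list()
  if (isTRUE(spec$polygenic)) {
    A <- .fullA(ped)
    miss <- setdiff(animals, rownames(A))
    if (length(miss)) stop("pedigree does not cover animals: ",
                           paste(head(miss, 5), collapse = ", "))
    K$a <- A[animals, animals]
  }
  if (isTRUE(spec$sire_flock_random)) {
    key <- paste(covariates[animals, "sire"], covariates[animals, "flock"], sep = ":")
    Z <- outer(key, unique(key), "==") * 1
    K$sf <- tcrossprod(Z)
  }
  if (isTRUE(spec$breed_random)) {
    Q <- covariates[animals, "breedQ"]
    Q2 <- cbind(Q, 1 - Q)
    K$q <- tcrossprod(Q2)
  }
  K
}

# fixed-effect design matrix; aliased columns dropped with a warning
.fixedDesign <- function(spec, covariates, animals) {
  terms <- spec$fixed_terms
  if (length(terms) == 0) {
    X <- matrix(1, length(animals), 1, dimnames = list(animals, "(Intercept)"))
    return(X)
  }
  fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  mf <- covariates[animals, , drop = FALSE]
  for (v in all.vars(fml))
    if (is.character(mf[[v]])) mf[[v]] <- factor(mf[[v]])
  X <- stats::model.matrix(fml, mf)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    drop <- colnames(X)[-qrx$pivot[seq_len(qrx$rank)]]
    warning("rank-deficient fixed-effect design; dropping aliased columns: ",
            paste(drop, collapse = ", "))
    X <- X[, qrx$pivot[seq_len(qrx$rank)], drop = FALSE]
  }
  X
}

# restricted log-likelihood at a given component vector (kernels then "e")
.remlLL <- function(theta, y, X, kernels) {
  n <- length(y); R <- length(kernels)
  V <- diag(theta[R + 1], n)
  for (r in seq_len(R)) V <- V + theta[r] * kernels[[r]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(-Inf)
  Vi <- chol2inv(ch)
  W <- Vi %*% X
  XtViX <- crossprod(X, W)
  chx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chx)) return(-Inf)
  P <- Vi - W %*% chol2inv(chx) %*% t(W)
  -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) + sum(y * (P %*% y)))
}

# Average-information REML with a direct-likelihood polish when the AI
# updates stall (typically with a component pinned at the zero boundary).
# Returns named variance components (kernels then "e"), convergence flag
# and iteration count.
.aiReml <- function(y, X, kernels, maxit = 50, tol = 1e-8) {
  n <- length(y)
  R <- length(kernels)
  vy <- var(y)
  theta <- c(rep(vy / (2 * max(R, 1)), R), vy / 2)
  names(theta) <- c(names(kernels), "e")
  floorv <- 1e-8 * vy

  logdet <- function(ch) 2 * sum(log(diag(ch)))
  relLL <- -Inf; converged <- FALSE; it <- 0

  repeat {
    it <- it + 1
    V <- diag(theta[R + 1], n)
    for (r in seq_len(R)) V <- V + theta[r] * kernels[[r]]
    ch <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(ch)) { # ridge and retry
      V <- V + diag(1e-6 * vy, n)
      ch <- chol(V)
    }
    Vi <- chol2inv(ch)
    W <- Vi %*% X
    XtViX <- crossprod(X, W)
    chx <- chol(XtViX)
    P <- Vi - W %*% chol2inv(chx) %*% t(W)
    Py <- P %*% y
    ll <- -0.5 * (logdet(ch) + logdet(chx) + sum(y * Py))

    score <- numeric(R + 1)
    KPy <- vector("list", R + 1)
    for (r in seq_len(R)) {
      score[r] <- -0.5 * (sum(P * kernels[[r]]) - sum(Py * (kernels[[r]] %*% Py)))
      KPy[[r]] <- kernels[[r]] %*% Py
    }
    score[R + 1] <- -0.5 * (sum(diag(P)) - sum(Py * Py))
    KPy[[R + 1]] <- Py

    AI <- matrix(0, R + 1, R + 1)
    for (r in seq_len(R + 1))
      for (s in r:(R + 1)) {
        AI[r, s] <- 0.5 * sum(KPy[[r]] * (P %*% KPy[[s]]))
        AI[s, r] <- AI[r, s]
      }
    delta <- tryCatch(solve(AI + diag(1e-10, R + 1), score),
                      error = function(e) score / max(abs(score), 1))
    # step-halve until positive
    step <- 1
    repeat {
      thNew <- theta + step * delta
      if (all(thNew > 0) || step < 1e-4) break
      step <- step / 2
    }
    thNew[thNew <= 0] <- floorv
    chg <- max(abs(thNew - theta) / (abs(theta) + floorv))
    theta <- thNew
    if (chg < tol || abs(ll - relLL) < 1e-10) { converged <- TRUE; break }
    relLL <- ll
    if (it >= maxit) break
  }
  if (!converged) {
    # boundary cases leave AI short of the optimum; polish on log scale
    opt <- tryCatch(
      optim(log(pmax(theta, floorv)),
            function(lt) -.remlLL(exp(lt), y, X, kernels),
            method = "Nelder-Mead",
            control = list(maxit = 300, reltol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(opt) &&
        -opt$value >= .remlLL(theta, y, X, kernels) - 1e-9) {
      theta <- setNames(exp(opt$par), names(theta))
      converged <- opt$convergence == 0
    }
  }
  list(theta = theta, converged = converged, niter = it)
}

# GLS fixed effects and per-kernel BLUP contributions on the observation
# scale, at given variance components
.glsBlup <- function(y, X, kernels, theta) {
  n <- length(y); R <- length(kernels)
  V <- diag(theta[["e"]], n)
  for (r in seq_len(R)) V <- V + theta[[names(kernels)[r]]] * kernels[[r]]
  Vi <- chol2inv(chol(V))
  XtViX <- crossprod(X, Vi %*% X)
  b <- solve(XtViX, crossprod(X, Vi %*% y))
  r0 <- y - X %*% b
  Vir <- Vi %*% r0
  blup <- lapply(seq_len(R), function(r)
    drop(theta[[names(kernels)[r]]] * kernels[[r]] %*% Vir))
  names(blup) <- names(kernels)
  list(b = drop(b), fitted_fixed = drop(X %*% b), blup = blup)
}

#' Eigen-rotation of the pedigree relationship among a set of animals
#'
#' Precomputes the eigen-decomposition of the numerator relationship matrix
#' restricted to `animals`, which diagonalizes the polygenic mixed model and
#' makes per-SNP generalized least squares a vectorized weighted regression.
#'
#' @param ped an [AnimalPedigree-class]
#' @param animals animal ids (order defines the rotation's row order)
#' @return list with `U` (eigenvectors), `lambda` (eigenvalues), `ids`.
#' @export
polygenicRotation <- function(ped, animals) {
  A <- .fullA(ped)
  miss <- setdiff(animals, rownames(A))
  if (length(miss)) stop("pedigree does not cover animals: ",
                         paste(head(miss, 5), collapse = ", "))
  e <- eigen(A[animals, animals], symmetric = TRUE)
  list(U = e$vectors, lambda = pmax(e$values, 0), ids = animals)
}

# Vectorized GLS single-marker scan in a rotated basis.
# yStar, oneStar: rotated response and intercept; SStar: rotated markers
# (n x m); w: per-observation weights 1/(sigma2_a * lambda + sigma2_e).
# Returns effect, se, t per marker (exact GLS at the given variances).
.rotatedScan <- function(yStar, oneStar, SStar, w) {
  a <- sum(w * oneStar^2)
  d <- sum(w * oneStar * yStar)
  syy <- sum(w * yStar^2)
  b <- colSums(w * oneStar * SStar)
  cc <- colSums(w * SStar^2)
  ee <- colSums(w * SStar * yStar)
  det <- a * cc - b^2
  eff <- (a * ee - b * d) / det
  mu <- (cc * d - b * ee) / det
  se <- sqrt(a / det)
  rss <- pmax(syy - mu * d - eff * ee, 0)
  n <- length(yStar)
  # Wald F with the residual scale re-estimated per marker (matches an
  # ordinary ANOVA when the weights are equal)
  Fwald <- eff^2 / (se^2 * rss / (n - 2))
  list(effect = eff, se = se, t = eff / se, Fwald = Fwald, rss = rss)
}
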