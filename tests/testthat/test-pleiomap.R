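test_that("multi-trait chi-square reduces to forced special cases", {
  t1 <- matrix(2, 1, 1, dimnames = list("s1", "t1"))
  r1 <- multiGwasChi2(t1, matrix(1, 1, 1))
  expect_equal(r1$chi2, 4)

  t2 <- matrix(c(3, 4), 1, 2, dimnames = list("s1", c("t1", "t2")))
  r2 <- multiGwasChi2(t2, diag(2))
  expect_equal(r2$chi2, 25)
  expect_equal(r2$df, 2)

  # non-finite rows are flagged and excluded
  t3 <- rbind(t2, c(NA, 1))
  rownames(t3) <- c("s1", "s2")
  r3 <- multiGwasChi2(t3, diag(2))
  expect_equal(r3$flag, c("", "nonfinite"))
  expect_true(is.na(r3$chi2[2]))
})

test_that("V is the brute-force correlation of signed t-values", {
  gw <- fixSmallGwas()
  sub <- lapply(gw, function(g) g[1:100, ])
  tv <- buildTmatrixV(sub)
  # brute force from sums
  T <- tv$t
  ok <- rowSums(!is.finite(T)) == 0
  T <- T[ok, ]
  n <- nrow(T)
  for (i in 1:3) for (j in 1:3) {
    x <- T[, i]; y <- T[, j]
    r <- (sum(x * y) - n * mean(x) * mean(y)) /
      sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
    expect_equal(tv$v[i, j], r, tolerance = 1e-12)
  }
  expect_equal(tv$epsilon, 0)
})

test_that("duplicated traits trigger recorded shrinkage of V", {
  gw <- fixSmallGwas()
  gw$dup <- gw[[1]]
  tv <- buildTmatrixV(gw)
  expect_gt(tv$epsilon, 0)
  ev <- eigen(tv$v, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 1e-6 - 1e-12)

  gw$flat <- gw[[1]]
  gw$flat$t <- 0
  expect_error(buildTmatrixV(gw), "zero t-variance")
})

test_that("null chi-square is calibrated against MVN draws", {
  set.seed(123)
  k <- 6
  V <- 0.3 + diag(0.7, k)
  L <- chol(V)
  Tm <- matrix(rnorm(10000 * k), 10000, k) %*% L
  rownames(Tm) <- paste0("s", 1:10000)
  colnames(Tm) <- paste0("t", 1:k)
  r <- multiGwasChi2(Tm, V)
  expect_lt(abs(mean(r$chi2) - k), 3 * sqrt(2 * k / 10000))
  expect_gt(ks.test(r$p, "punif")$p.value, 0.01)
})

test_that("top-SNP-per-tile selection matches a brute-force oracle", {
  set.seed(7)
  n <- 300
  d <- data.frame(snp = paste0("s", 1:n),
                  chrom = sample(c("chr1", "chr2"), n, TRUE),
                  bp = sample.int(5e6, n),
                  chi2 = rchisq(n, 3))
  d$p <- 10^-runif(n, 0, 9)
  calls <- topSnpPerMb(d, threshold = 1e-4, window_bp = 1e6)
  # oracle: per-tile argmin of P among passers
  pass <- d[d$p < 1e-4, ]
  tile <- paste0(pass$chrom, ":", floor((pass$bp - 1) / 1e6))
  oracle <- do.call(rbind, lapply(split(pass, tile), function(g)
    g[order(g$p, g$bp)[1], ]))
  expect_setequal(calls$snp, oracle$snp)

  # two passers in one tile keep one; passers in adjacent tiles both stay
  d2 <- data.frame(snp = c("a", "b", "c"), chrom = "chr1",
                   bp = c(1e5, 2e5, 1.5e6), chi2 = 1,
                   p = c(1e-9, 1e-8, 1e-9))
  c2 <- topSnpPerMb(d2, threshold = 1e-6, window_bp = 1e6)
  expect_setequal(c2$snp, c("a", "c"))
})

test_that("multi-PP combination follows the product rule", {
  g <- tinyGeno(5, 4, seed = 1)
  map <- snpTable(g)
  mkFit <- function(pp0, tr) {
    cp <- cbind(pp0, (1 - pp0) / 3, (1 - pp0) / 3, (1 - pp0) / 3)
    new("BayesRFit", trait = tr, snpEffects = rep(0, 4), classProb = cp,
        ppNonzero = 1 - pp0, traces = matrix(0, 1, 5),
        snpIds = map$snp, config = list())
  }
  # SNP1: all traits certain zero; SNP2: one trait certain nonzero;
  # SNP3: two traits at 0.8 zero -> combined 0.36; SNP4: 0.95^2 -> 0.0975
  f1 <- mkFit(c(1, 0, 0.8, 0.95), "t1")
  f2 <- mkFit(c(1, 1, 0.8, 0.95), "t2")
  calls <- multiPP(list(t1 = f1, t2 = f2), map, threshold = 0.3)
  expect_false("s1" %in% calls$snp)
  expect_true("s2" %in% calls$snp)
  expect_equal(calls$statistic[calls$snp == "s2"], 1)
  expect_true("s3" %in% calls$snp)
  expect_equal(calls$statistic[calls$snp == "s3"], 0.36, tolerance = 1e-12)
  expect_false("s4" %in% calls$snp)
  # contributing traits: per-trait pp_nonzero above 0.05
  expect_equal(calls$traits[calls$snp == "s3"], "t1,t2")
})

test_that("window covariance PCA matches a dense eigen oracle", {
  set.seed(11)
  nA <- 40; k <- 5
  sds <- setNames(runif(k, 0.8, 1.2), paste0("t", 1:k))
  vals <- lapply(seq_len(k), function(i) {
    m <- matrix(rnorm(nA * 3), nA, 3,
                dimnames = list(paste0("a", 1:nA), NULL))
    colnames(m) <- c("chr1:0", "chr1:1", "chr1:2")
    m
  })
  names(vals) <- names(sds)
  w <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 250001, 500001),
                                                       width = 250000))
  names(w) <- colnames(vals[[1]])
  lgm <- new("LocalGebvMatrix", values = vals, windows = w,
             traits = names(sds))
  wp <- windowCovPca(lgm, sds)
  for (wi in 1:3) {
    Lw <- sapply(names(sds), function(tr) vals[[tr]][, wi] / sds[tr])
    ev <- eigen(cov(Lw), symmetric = TRUE)
    expect_equal(wp@lambda1[wi], ev$values[1], tolerance = 1e-10)
    expect_equal(wp@prop1[wi], ev$values[1] / sum(ev$values),
                 tolerance = 1e-10)
    # trace conservation and dominance of lambda1 over the diagonal
    expect_equal(sum(wp@eig[[wi]]$values), sum(diag(cov(Lw))),
                 tolerance = 1e-8)
    expect_gte(wp@lambda1[wi], max(diag(cov(Lw))) - 1e-10)
  }
})

test_that("degenerate windows give forced eigen results", {
  nA <- 20
  a <- c(rep(1, nA / 2), rep(-1, nA / 2))
  b <- rep(c(1, -1), nA / 2)
  vals <- list(t1 = cbind(`chr1:0` = a, `chr1:1` = rep(0, nA)),
               t2 = cbind(`chr1:0` = b, `chr1:1` = rep(0, nA)))
  for (i in 1:2) rownames(vals[[i]]) <- paste0("x", 1:nA)
  w <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 250001), width = 250000))
  names(w) <- c("chr1:0", "chr1:1")
  lgm <- new("LocalGebvMatrix", values = vals, windows = w,
             traits = c("t1", "t2"))
  wp <- windowCovPca(lgm, c(t1 = 1, t2 = 2))
  # exactly orthogonal traits: diagonal covariance, lambda1 = max diagonal
  cw <- cov(cbind(a / 1, b / 2))
  expect_equal(wp@lambda1[1], max(diag(cw)), tolerance = 1e-12)
  # all-zero window: zero eigenvalues, PC1 proportion defined as 0
  expect_equal(wp@lambda1[2], 0)
  expect_equal(wp@prop1[2], 0)

  # single trait: lambda1 equals the standardized variance
  lgm1 <- new("LocalGebvMatrix", values = vals["t1"], windows = w,
              traits = "t1")
  wp1 <- windowCovPca(lgm1, c(t1 = 2))
  expect_equal(wp1@lambda1[1], var(a / 2), tolerance = 1e-12)
})

test_that("top-window selection is a sort with deterministic ties", {
  set.seed(3)
  nw <- 30
  w <- GenomicRanges::GRanges("chr1", IRanges::IRanges(seq(1, by = 250000,
                                                           length.out = nw),
                                                       width = 250000))
  names(w) <- paste0("chr1:", seq_len(nw) - 1)
  lam <- runif(nw)
  wp <- new("WindowPcaSet", windows = w, lambda1 = lam,
            prop1 = rep(0.9, nw), eig = vector("list", nw), traits = "t1")
  top <- selectTopWindows(wp, nw)
  expect_equal(top$lambda1, sort(lam, decreasing = TRUE))
  expect_equal(nrow(selectTopWindows(wp, 0)), 0)
  expect_error(selectTopWindows(wp, nw + 1), "exceeds")
})

test_that("S_LC is the PC1 linear combination of standardized local GEBV", {
  f <- fixStrongQtl()
  ids <- rownames(adjustedResiduals(f$adj))
  lgm <- localGebv(f$fit, f$geno[ids, ], 250e3)
  wp <- windowCovPca(lgm, phenoSd(f$adj))
  top <- selectTopWindows(wp, 1)
  slc <- pseudoTraitSlc(lgm, wp, top$window[1], f$adj)
  # single trait: S_LC is the standardized local GEBV (PC1 loading = 1)
  wi <- match(top$window[1], names(windowRanges(wp)))
  expect_equal(unname(slc),
               unname(localValues(lgm, "trait1")[, wi] / phenoSd(f$adj)["trait1"]),
               tolerance = 1e-10)
  expect_error(pseudoTraitSlc(lgm, wp, "chr9:99", f$adj), "not found")
})

test_that("S_LC matches an explicit dot-product oracle with missing traits", {
  set.seed(17)
  nA <- 30
  ids <- paste0("a", 1:nA)
  vals <- list(t1 = matrix(rnorm(nA), nA, 1, dimnames = list(ids, "chr1:0")),
               t2 = matrix(rnorm(nA), nA, 1, dimnames = list(ids, "chr1:0")))
  w <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 250000))
  names(w) <- "chr1:0"
  lgm <- new("LocalGebvMatrix", values = vals, windows = w,
             traits = c("t1", "t2"))
  sds <- c(t1 = 1.5, t2 = 0.5)
  wp <- windowCovPca(lgm, sds)
  R <- matrix(rnorm(nA * 2), nA, 2, dimnames = list(ids, c("t1", "t2")))
  R[1:5, 2] <- NA # first five animals unmeasured for t2
  adj <- adjFromMatrix(R, sds = sds)
  slc <- pseudoTraitSlc(lgm, wp, "chr1:0", adj)
  x <- wp@eig[[1]]$vectors[, 1]
  l2 <- vals$t2[, 1]
  l2[1:5] <- mean(l2[-(1:5)]) # mean replacement over measured animals
  oracle <- (vals$t1[, 1] / sds["t1"]) * x["t1"] + (l2 / sds["t2"]) * x["t2"]
  expect_equal(unname(slc), unname(oracle), tolerance = 1e-12)
})

test_that("best SNP in a window matches an ANOVA oracle for A = I", {
  set.seed(23)
  n <- 60
  g <- tinyGeno(n, 20, seed = 23)
  ids <- rownames(dosage(g))
  ped <- founderPed(ids)
  y <- setNames(rnorm(n) + 0.8 * dosage(g)[, 7], ids)
  w <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 3e6))
  best <- bestSnpInWindow(y, g, ped, w)
  # with unrelated animals the weights are equal, so F = OLS anova F
  Fv <- sapply(colnames(dosage(g))[snpTable(g)$bp <= 3e6], function(s) {
    anova(lm(y ~ dosage(g)[, s]))$`F value`[1]
  })
  expect_equal(best$snp, names(which.max(Fv)))
  expect_equal(best$Fval, unname(max(Fv)), tolerance = 1e-6)

  # monomorphic-only window is skipped with a warning
  D <- dosage(g); D[, 1] <- 1
  g2 <- genotypeData(D[, 1, drop = FALSE], "chr1", 100)
  expect_warning(r <- bestSnpInWindow(y, g2, ped,
                                      GenomicRanges::GRanges("chr1",
                                        IRanges::IRanges(1, 1000))),
                 "skipped")
  expect_null(r)
})

test_that("the single causal SNP wins its window", {
  f <- fixStrongQtl()
  ids <- rownames(adjustedResiduals(f$adj))
  g <- f$geno[ids, ]
  eff <- rep(0, nSnps(g))
  j <- match(f$truth$qtl_table$snp[1], snpTable(g)$snp)
  eff[j] <- 0.4
  fit1 <- f$fit; fit1@snpEffects <- eff
  lgm <- localGebv(fit1, g, 250e3)
  wp <- windowCovPca(lgm, phenoSd(f$adj))
  top <- selectTopWindows(wp, 1)
  slc <- pseudoTraitSlc(lgm, wp, top$window[1], f$adj)
  best <- bestSnpInWindow(slc, g, f$ped, top$window[1],
                          windows = windowRanges(wp))
  expect_equal(best$snp, f$truth$qtl_table$snp[1])
})

test_that("method overlap comparison performs exact set algebra", {
  mk <- function(snps) data.frame(snp = snps, chrom = "chr1",
                                  bp = seq_along(snps) * 1e5)
  same <- mk(c("a", "b", "c"))
  ov <- compareMethods(list(x = same, y = same, z = same))
  expect_equal(unname(ov$venn["111"]), 3L)
  expect_equal(ov$union_size, 3L)

  ov2 <- compareMethods(list(x = mk(c("a", "b")),
                             y = mk(c("c", "d", "e")),
                             z = mk(c("f", "g", "h", "i"))))
  expect_equal(ov2$union_size, 9L)
  expect_equal(sort(unname(ov2$venn)), c(2L, 3L, 4L))

  set.seed(4)
  pool <- paste0("s", 1:30)
  sets <- lapply(1:3, function(i) mk(sample(pool, 12)))
  names(sets) <- c("x", "y", "z")
  ov3 <- compareMethods(sets)
  inx <- sapply(sets, function(d) pool %in% d$snp)
  mask <- apply(inx, 1, function(r) paste(as.integer(r), collapse = ""))
  mask <- mask[mask != "000"]
  expect_equal(ov3$union_size, length(mask))
  for (cell in names(ov3$venn))
    expect_equal(unname(ov3$venn[cell]), sum(mask == cell))
})

test_that("SNP-effect correlations across traits behave as correlations", {
  gw <- fixSmallGwas()
  snps <- gw[[1]]$snp[c(10, 20, 30)]
  R <- snpEffectCorrelation(gw, snps)
  expect_equal(diag(R), rep(1, 3), ignore_attr = TRUE)
  E <- sapply(gw, function(g) g$effect[match(snps, g$snp)])
  expect_equal(R[1, 2], cor(E[1, ], E[2, ]), tolerance = 1e-12)
  # a SNP against itself and against its negation
  gwNeg <- lapply(gw, function(g) { g$effect <- -g$effect; g })
  both <- Map(function(a, b) {
    a2 <- a
    a2$effect[match(snps[2], a$snp)] <- -a$effect[match(snps[2], a$snp)]
    a2
  }, gw, gwNeg)
  R2 <- snpEffectCorrelation(gw, c(snps[1], snps[1]))
  expect_equal(R2[1, 2], 1, tolerance = 1e-12)
  expect_error(snpEffectCorrelation(gw[1:2], snps), "three traits")
})

test_that("candidate gene lookup honors the 50-kb closed bound", {
  genes <- data.frame(
    chrom = c("OAR3", "OAR3", "OAR3"),
    start = c(58986758, 59069274, 59119275),
    end = c(58990671, 59071000, 59121000),
    gene = c("FOXI3", "EDGE50K", "FAR60K"))
  calls <- data.frame(snp = "topSnp", chrom = "OAR3", bp = 59019274)
  hits <- candidateGenes(calls, genes, flank_bp = 50e3)
  # gene ending 28,603 bp away is reported
  expect_true("FOXI3" %in% hits$gene)
  expect_equal(hits$distance[hits$gene == "FOXI3"], 59019274 - 58990671)
  # gene edge exactly 50,000 bp away is included (closed bound)
  expect_true("EDGE50K" %in% hits$gene)
  # a gene 100 kb away is excluded
  expect_false("FAR60K" %in% hits$gene)
  # nearest gene is primary
  expect_true(hits$primary[hits$gene == "FOXI3"])
  expect_false(hits$primary[hits$gene == "EDGE50K"])

  bad <- rbind(genes, data.frame(chrom = "OAR3", start = 10, end = 5,
                                 gene = "BROKEN"))
  expect_warning(candidateGenes(calls, bad), "malformed")
})
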