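test_that("A matrix: founders, full sibs, and the recursive oracle", {
  ped <- founderPed(paste0("f", 1:4))
  expect_equal(unname(buildAMatrix(ped)), diag(4))

  sib <- animalPedigree(data.frame(
    id = c("s", "d", "k1", "k2"), sire = c(NA, NA, "s", "s"),
    dam = c(NA, NA, "d", "d"), generation = c(0, 0, 1, 1)))
  A <- buildAMatrix(sib)
  expect_equal(A["k1", "k2"], 0.5)
  expect_equal(A["k1", "k1"], 1.0)

  # 3-generation, 20 animals: compare to the recursive definition
  set.seed(5)
  f <- fixSmall()
  df <- head(pedTable(f$ped)[order(pedTable(f$ped)$generation), ], 20)
  ped20 <- animalPedigree(within(df, {
    sire[!sire %in% id] <- NA
    dam[!dam %in% id] <- NA
  }))
  A20 <- buildAMatrix(ped20)
  dfl <- pedTable(ped20)
  rec <- function(i, j) {
    if (i == j) {
      s <- dfl$sire[i]; d <- dfl$dam[i]
      if (is.na(s) || is.na(d)) return(1)
      return(1 + 0.5 * rec(match(s, dfl$id), match(d, dfl$id)))
    }
    if (i < j) { t <- i; i <- j; j <- t } # i is the later-born
    s <- dfl$sire[i]; d <- dfl$dam[i]
    0.5 * ((if (is.na(s)) 0 else rec(match(s, dfl$id), j)) +
           (if (is.na(d)) 0 else rec(match(d, dfl$id), j)))
  }
  for (i in seq_len(20)) for (j in seq_len(i))
    expect_equal(A20[i, j], rec(i, j), tolerance = 1e-12)
})

test_that("sparse A-inverse matches the dense inverse", {
  f <- fixSmall()
  df <- head(pedTable(f$ped)[order(pedTable(f$ped)$generation), ], 40)
  ped40 <- animalPedigree(within(df, {
    sire[!sire %in% id] <- NA
    dam[!dam %in% id] <- NA
  }))
  A <- buildAMatrix(ped40)
  Ai <- as.matrix(buildAInverse(ped40))
  expect_equal(Ai, solve(A), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("pedigree cycles are rejected", {
  expect_error(animalPedigree(data.frame(
    id = c("a", "b"), sire = c("b", "a"), dam = c(NA, NA),
    generation = c(0, 0))), "precede")
})

test_that("GRM matches the VanRaden formula on a fixture", {
  g <- tinyGeno(10, 50, seed = 3)
  grm <- buildGrm(g, maf_min = 0.005)
  M <- dosage(g)
  p <- colMeans(M) / 2
  keep <- pmin(p, 1 - p) > 0.005
  Z <- sweep(M[, keep], 2, 2 * p[keep], "-")
  G <- tcrossprod(Z) / (2 * sum(p[keep] * (1 - p[keep])))
  expect_equal(grmMatrix(grm), G, tolerance = 1e-12)
  expect_true(mean(diag(grmMatrix(grm))) > 0.7 &&
              mean(diag(grmMatrix(grm))) < 1.3)
})

test_that("GRM degenerate cases behave as forced by the formula", {
  # single kept SNP, everyone heterozygous: centered dosage is zero
  D <- matrix(1, 4, 1, dimnames = list(paste0("a", 1:4), "s1"))
  g <- genotypeData(D, "chr1", 100)
  expect_equal(unname(grmMatrix(buildGrm(g))), matrix(0, 4, 4))

  # duplicate animal rows are identical in G
  g2 <- tinyGeno(6, 40, seed = 9)
  D2 <- dosage(g2); D2[2, ] <- D2[1, ]
  g2 <- genotypeData(D2, as.character(seqnames(snpMap(g2))), start(snpMap(g2)))
  G2 <- grmMatrix(buildGrm(g2))
  expect_equal(G2[1, 2], G2[1, 1])

  # all SNPs below the MAF threshold is an error
  D3 <- matrix(0, 5, 3, dimnames = list(paste0("a", 1:5), paste0("s", 1:3)))
  expect_error(buildGrm(genotypeData(D3, rep("chr1", 3), 1:3)), "excluded")
})

test_that("relationship matrices are positive semi-definite", {
  f <- fixSmall()
  ids <- rownames(adjustedResiduals(f$adj))
  A <- buildAMatrix(f$ped)[ids, ids]
  G <- grmMatrix(buildGrm(f$geno[ids, ]))
  expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
})

test_that("cross-validation folds keep sire families intact", {
  f <- fixSmall()
  folds <- makeCvFolds(f$ped, seed = 7)
  # no validation animal shares a sire with any training animal
  for (k in 1:5) {
    vs <- folds$sire[folds$fold == k]
    ts <- folds$sire[folds$fold != k]
    expect_length(intersect(vs, ts), 0)
  }
  # crossbreds (and their sires' straightbred offspring) always train
  off <- pedTable(f$ped)
  off <- off[off$generation == 2, ]
  xb <- off$id[off$breedQ > 0.25 & off$breedQ <= 0.90]
  expect_true(all(folds$fold[folds$id %in% xb] == 0))
  # reproducible, and family counts balanced within one family
  folds2 <- makeCvFolds(f$ped, seed = 7)
  expect_identical(folds, folds2)
  fam <- unique(folds[folds$fold > 0, c("sire", "fold")])
  expect_lte(diff(range(table(fam$fold))), 1)
})

test_that("fold construction fails without eligible straightbred families", {
  cfg <- simConfig(n_sires = 6, n_dams_per_sire = 2, n_offspring_per_dam = 2,
                   crossbred_frac = 1, seed = 3)
  ped <- simulatePedigree(cfg)
  expect_error(makeCvFolds(ped, 1), "eligible")
})

test_that("GBLUP equals SNP-BLUP ridge regression on a fixture", {
  set.seed(21)
  g <- tinyGeno(20, 50, seed = 21)
  M <- dosage(g)
  p <- colMeans(M) / 2
  Z <- sweep(M, 2, 2 * p, "-")
  cdenom <- 2 * sum(p * (1 - p))
  y <- setNames(rnorm(20), rownames(M))
  s2g <- 0.5; s2e <- 0.5
  grm <- buildGrm(g, maf_min = 1e-6)
  train <- rownames(M)[1:15]
  R <- matrix(NA_real_, 20, 1, dimnames = list(rownames(M), "t1"))
  R[train, 1] <- y[train] - mean(y[train])
  adj <- adjFromMatrix(R)
  folds <- data.frame(id = rownames(M),
                      sire = "x",
                      fold = ifelse(rownames(M) %in% train, 0L, 1L))
  gt <- gblupFit(grm, adj, folds, "t1", vc = list(sigma2g = s2g, sigma2e = s2e))

  # SNP-BLUP oracle: ridge regression with lambda = c * s2e / s2g
  yt <- R[train, 1]
  Vt <- s2g * grmMatrix(grm)[train, train] + s2e * diag(15)
  Vi <- solve(Vt)
  mu <- sum(Vi %*% yt) / sum(Vi)
  lambda <- cdenom * s2e / s2g
  beta <- solve(crossprod(Z[train, ]) + lambda * diag(50),
                crossprod(Z[train, ], yt - mu))
  oracle <- drop(Z %*% beta)
  expect_equal(gt$gebv, oracle[gt$animal], tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("GBLUP limits and invariances", {
  g <- tinyGeno(12, 30, seed = 33)
  grm <- buildGrm(g, maf_min = 1e-6)
  ids <- rownames(dosage(g))
  y <- setNames(rnorm(12), ids)
  train <- ids[1:8]
  # vanishing genetic variance drives all GEBV to zero
  gz <- flockQTL:::.gblupSolve(grmMatrix(grm), y, train, 1e-12, 1)
  expect_lt(max(abs(gz)), 1e-8)
  # adding a constant to phenotypes leaves GEBV unchanged
  g1 <- flockQTL:::.gblupSolve(grmMatrix(grm), y, train, 0.5, 0.5)
  g2 <- flockQTL:::.gblupSolve(grmMatrix(grm), y + 100, train, 0.5, 0.5)
  expect_equal(g1, g2, tolerance = 1e-8)
  # duplicate animals receive equal GEBV
  D <- dosage(g); D[2, ] <- D[1, ]
  gd <- genotypeData(D, as.character(seqnames(snpMap(g))), start(snpMap(g)))
  Gd <- grmMatrix(buildGrm(gd, maf_min = 1e-6))
  y2 <- y; y2[2] <- y2[1]
  gg <- flockQTL:::.gblupSolve(Gd, y2, ids[3:10], 0.5, 0.5)
  expect_equal(unname(gg[1]), unname(gg[2]), tolerance = 1e-10)
})

test_that("accuracy estimator behaves at its boundaries", {
  set.seed(9)
  ids <- paste0("a", 1:100)
  R <- matrix(rnorm(100), 100, 1, dimnames = list(ids, "t1"))
  adj <- adjFromMatrix(R)
  gt <- data.frame(animal = ids, trait = "t1",
                   gebv = adjustedResiduals(adj)[, 1],
                   fold = rep(1:5, each = 20))
  acc <- gebvAccuracy(gt, adj, "t1", h2 = 1)
  expect_equal(acc$mean, 1.0, tolerance = 1e-12)

  gt$gebv <- rnorm(100) # independent of phenotype
  acc0 <- gebvAccuracy(gt, adj, "t1", h2 = 0.5)
  expect_lt(abs(acc0$mean), 3 / sqrt(20) / sqrt(0.5))

  gt$gebv <- 1 # zero variance: folds flagged and excluded
  w <- capture_warnings(gebvAccuracy(gt, adj, "t1", h2 = 0.5))
  expect_true(any(grepl("zero-variance", w)))
  expect_error(gebvAccuracy(gt, adj, "t1", h2 = 0), "positive")
})
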