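test_that("pedigree structure follows the configured family design", {
  cfg <- simConfig(n_sires = 2, n_dams_per_sire = 2, n_offspring_per_dam = 1,
                   n_chromosomes = 1, chrom_length_bp = 1e6, n_snps = 10,
                   n_qtl = 1, n_traits = 1, h2_per_trait = 0.3, seed = 1)
  ped <- simulatePedigree(cfg)
  df <- pedTable(ped)
  off <- df[df$generation == 2, ]
  expect_equal(nrow(off), 4)
  expect_true(all(off$sire %in% df$id & off$dam %in% df$id))

  cfg0 <- simConfig(n_sires = 10, n_dams_per_sire = 2, n_offspring_per_dam = 2,
                    crossbred_frac = 0, seed = 2)
  off0 <- pedTable(simulatePedigree(cfg0))
  off0 <- off0[off0$generation == 2, ]
  expect_true(all(off0$breedQ > 0.90))

  expect_error(simConfig(n_sires = 0), "positive")
})

test_that("pedigree is reproducible and family sizes tally", {
  cfg <- simConfig(n_sires = 50, n_dams_per_sire = 2, n_offspring_per_dam = 3,
                   seed = 99)
  p1 <- pedTable(simulatePedigree(cfg))
  p2 <- pedTable(simulatePedigree(cfg))
  expect_identical(p1, p2)
  off <- p1[p1$generation == 2, ]
  # brute-force tally of family sizes
  expect_equal(sum(table(off$sire)), 50 * 2 * 3)
  expect_true(all(table(off$sire) == 6))
})

test_that("gene-dropped genotypes are Mendelian-consistent and reproducible", {
  f <- fixSmall()
  D <- dosage(f$geno)
  df <- pedTable(f$ped)
  kids <- df[!is.na(df$sire), ]
  # a parent-offspring pair must share an allele at every SNP:
  # dosage 0 in one and 2 in the other is impossible without mutation
  for (who in c("sire", "dam")) {
    dk <- D[kids$id, , drop = FALSE]
    dp <- D[kids[[who]], , drop = FALSE]
    expect_equal(sum((dk == 0 & dp == 2) | (dk == 2 & dp == 0)), 0)
  }
  g2 <- simulateGenotypes(f$ped, f$cfg)
  expect_identical(dosage(g2), D)
})

test_that("recombination produces LD that decays with distance", {
  f <- fixSmall()
  D <- dosage(f$geno)
  map <- snpTable(f$geno)
  i1 <- which(map$chrom == "chr1")
  r2 <- function(a, b) suppressWarnings(cor(a, b))^2
  adj <- vapply(head(i1, -1), function(j) r2(D[, j], D[, j + 1]), numeric(1))
  set.seed(1)
  far <- replicate(400, {
    j <- sample(i1, 2)
    if (abs(map$bp[j[1]] - map$bp[j[2]]) > 5e6) r2(D[, j[1]], D[, j[2]]) else NA
  })
  expect_gt(mean(adj, na.rm = TRUE), mean(far, na.rm = TRUE))
})

test_that("allele frequencies drift little from founders through the drop", {
  cfg <- simConfig(n_sires = 100, n_dams_per_sire = 1, n_offspring_per_dam = 2,
                   n_chromosomes = 1, chrom_length_bp = 10e6, n_snps = 300,
                   n_qtl = 2, n_traits = 1, h2_per_trait = 0.3, seed = 31)
  ped <- simulatePedigree(cfg)
  geno <- simulateGenotypes(ped, cfg)
  df <- pedTable(ped)
  D <- dosage(geno)
  pF <- colMeans(D[df$id[df$generation == 0], ]) / 2
  pO <- colMeans(D[df$id[df$generation == 2], ]) / 2
  nOff <- sum(df$generation == 2)
  se <- sqrt(pF * (1 - pF) / (2 * nOff))
  expect_gt(mean(abs(pO - pF) <= 3 * se), 0.90)
})

test_that("trait variance partition matches the configuration", {
  # h2 = 0: the sire-by-flock intraclass correlation is the only clustering
  cfg <- simConfig(n_sires = 25, n_dams_per_sire = 8, n_offspring_per_dam = 5,
                   n_chromosomes = 2, chrom_length_bp = 20e6, n_snps = 400,
                   n_qtl = 2, n_traits = 1, h2_per_trait = 0,
                   sire_flock_var_frac = 0.12, fixed_effect_sd = 0,
                   missing_rate_per_trait = 0, crossbred_frac = 0, seed = 41)
  ped <- simulatePedigree(cfg)
  geno <- simulateGenotypes(ped, cfg)
  st <- simulateTraits(geno, ped, cfg)
  y <- traitMatrix(st$pheno)[, 1]
  grp <- factor(paste(covariateTable(st$pheno)$sire,
                      covariateTable(st$pheno)$flock))
  # one-way ANOVA oracle for the intraclass variance component
  fit <- aov(y ~ grp)
  ms <- summary(fit)[[1]]$`Mean Sq`
  ns <- table(grp)
  n0 <- (sum(ns) - sum(ns^2) / sum(ns)) / (length(ns) - 1)
  icc <- (ms[1] - ms[2]) / n0
  expect_lt(abs(icc - 0.12), 0.08)
  expect_lt(abs(var(y) - 1), 0.2) # total variance near 1 without fixed effects

  # missing_rate = 0 leaves no masked cells
  expect_equal(sum(is.na(traitMatrix(st$pheno))), 0)
})

test_that("simulated heritability is recovered by downstream REML", {
  for (seed in c(51, 52)) {
    cfg <- simConfig(n_sires = 25, n_dams_per_sire = 8, n_offspring_per_dam = 5,
                     n_chromosomes = 2, chrom_length_bp = 20e6, n_snps = 500,
                     n_qtl = 4, n_traits = 1, h2_per_trait = 0.5,
                     missing_rate_per_trait = 0, seed = seed)
    ped <- simulatePedigree(cfg)
    st <- simulateTraits(simulateGenotypes(ped, cfg), ped, cfg)
    vc <- estimateVarianceComponents(st$pheno, ped, modelSpec(), "trait1")
    expect_true(vc@converged)
    expect_lt(abs(vc@h2 - 0.5), 0.12)
  }
})

test_that("realized genetic correlations track the configured matrix", {
  # private (single-trait) QTL deliberately dilute the total-TBV
  # correlation below the configured value, so the configured matrix is
  # asserted (i) on the polygenic component, which carries it exactly,
  # and (ii) on the total TBV of an architecture without private QTL
  f <- fixDesk()
  Cp <- cor(f$truth$tbv_polygenic)
  expect_true(all(abs(Cp[upper.tri(Cp)] - 0.4) < 0.1))

  cfg <- simConfig(qtl_private_frac = 0, missing_rate_per_trait = 0, seed = 19)
  ped <- simulatePedigree(cfg)
  st <- simulateTraits(simulateGenotypes(ped, cfg), ped, cfg)
  C <- cor(st$truth$true_breeding_values)
  expect_true(all(abs(C[upper.tri(C)] - 0.4) < 0.1))
})

test_that("realized additive variance matches h2 within tolerance", {
  # a seed-averaged calibration property: single-seed realized variance
  # carries family-sampling noise of several percent
  f <- fixDesk()
  h2 <- f$cfg$h2_per_trait
  vas <- list(apply(f$truth$true_breeding_values, 2, var))
  for (seed in c(12, 13)) {
    cfg <- simConfig(seed = seed)
    ped <- simulatePedigree(cfg)
    st <- simulateTraits(simulateGenotypes(ped, cfg), ped, cfg)
    vas[[length(vas) + 1]] <- apply(st$truth$true_breeding_values, 2, var)
  }
  va <- colMeans(do.call(rbind, vas))
  keep <- h2 >= 0.2
  expect_true(all(abs(va[keep] - h2[keep]) / h2[keep] < 0.15))
})

test_that("truthReport scores recovery and false calls correctly", {
  f <- fixSmall()
  qt <- f$truth$qtl_table
  exact <- data.frame(chrom = qt$chrom, bp = qt$bp)
  r <- truthReport(f$truth, list(m = exact), 250e3)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$false_calls, 0)

  none <- data.frame(chrom = character(0), bp = numeric(0))
  r0 <- truthReport(f$truth, list(m = none), 250e3)
  expect_equal(r0$sensitivity, 0)

  expect_error(truthReport(list(qtl_table = qt[0, ]), list(m = exact)), "empty")

  # random calls: false-call rate consistent with genome coverage of the
  # truth windows
  set.seed(5)
  w <- 1e5
  rnd <- data.frame(chrom = sample(c("chr1", "chr2"), 400, replace = TRUE),
                    bp = sample.int(20e6, 400))
  rr <- truthReport(f$truth, list(m = rnd), w)
  cover <- nrow(qt) * 2 * w / (2 * 20e6) # fraction of genome near a QTL
  expect_lt(abs(rr$false_calls / 400 - (1 - cover)),
            4 * sqrt(cover * (1 - cover) / 400) + 0.02)
})

test_that("configuration invariants are enforced", {
  expect_error(simConfig(n_qtl = 100, n_snps = 50), "n_qtl")
  G <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(simConfig(n_traits = 2, h2_per_trait = 0.3, genetic_corr = G),
               "positive semi-definite")
  expect_error(simConfig(crossbred_frac = 1.5), "proportion")
})
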