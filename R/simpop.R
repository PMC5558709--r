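#' Derive a stage seed from the global simulation seed
#'
#' One global seed governs every stochastic stage. Each stage draws from its
#' own stream obtained as `(seed * 7919 + offset) mod (2^31 - 1)` with a
#' fixed per-stage offset, so adding stages never perturbs earlier ones.
#' @param seed integer global seed
#' @param stage stage name
#' @return integer seed for the stage
#' @export
splitSeed <- function(seed, stage = c("pedigree", "genotypes", "traits",
                                      "folds", "bayesr", "pipeline", "other")) {
  stage <- match.arg(stage)
  offset <- c(pedigree = 101L, genotypes = 211L, traits = 307L,
              folds = 401L, bayesr = 503L, pipeline = 601L, other = 701L)[[stage]]
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483646 + 1)
}

#' Configuration of the synthetic sheep population
#'
#' Defaults give the desk-scale population used throughout the package's
#' examples and tests: 3 chromosomes of 50 Mb, 6000 SNPs, 20 QTL, 8 traits
#' and 2000 phenotyped offspring in 50 paternal half-sib families. Trait
#' heritabilities span the range reported for wool production, quality and
#' breech traits; the sire-by-flock fraction and the crossbred fraction
#' (about a third of animals) mirror a Merino information-nucleus design.
#'
#' @param n_sires,n_dams_per_sire,n_offspring_per_dam family structure
#'   (matings are nested: each dam is mated to a single sire).
#' @param n_chromosomes,chrom_length_bp,n_snps genome layout; SNPs are split
#'   evenly over chromosomes at uniform random positions.
#' @param n_qtl number of causal SNPs (drawn from the SNP panel).
#' @param n_traits number of genetically correlated traits.
#' @param h2_per_trait narrow-sense heritabilities (recycled to `n_traits`).
#' @param sire_flock_var_frac fraction of phenotypic variance from the
#'   sire-by-flock interaction (recycled per trait).
#' @param genetic_corr trait x trait genetic correlation matrix (default
#'   compound symmetry 0.4).
#' @param qtl_var_frac fraction of the genetic variance carried by the
#'   mapped QTL (the rest is pedigree polygenic).
#' @param qtl_private_frac fraction of QTL given an effect on a single trait
#'   only, so pleiotropic and private QTL coexist.
#' @param crossbred_frac fraction of sire families mated to produce
#'   crossbred offspring (breed proportion 0.25 < Q <= 0.90).
#' @param missing_rate_per_trait fraction of phenotypes masked per trait.
#' @param n_flocks number of flocks.
#' @param fixed_effect_sd magnitude (phenotypic SD) of the flock, sex, age
#'   and breed fixed effects.
#' @param seed global seed; see [splitSeed()].
#' @return a validated list of class `SimConfig`.
#' @export
simConfig <- function(n_sires = 50, n_dams_per_sire = 8, n_offspring_per_dam = 5,
                      n_chromosomes = 3, chrom_length_bp = 50e6, n_snps = 6000,
                      n_qtl = 20, n_traits = 8,
                      h2_per_trait = c(0.41, 0.46, 0.62, 0.38, 0.84, 0.60, 0.63, 0.26),
                      sire_flock_var_frac = 0.05,
                      genetic_corr = NULL,
                      qtl_var_frac = 0.5, qtl_private_frac = 0.5,
                      crossbred_frac = 0.3, missing_rate_per_trait = 0.1,
                      n_flocks = 5, fixed_effect_sd = 0.5, seed = 1) {
  if (is.null(genetic_corr)) {
    genetic_corr <- matrix(0.4, n_traits, n_traits)
    diag(genetic_corr) <- 1
  }
  cfg <- list(n_sires = n_sires, n_dams_per_sire = n_dams_per_sire,
              n_offspring_per_dam = n_offspring_per_dam,
              n_chromosomes = n_chromosomes, chrom_length_bp = chrom_length_bp,
              n_snps = n_snps, n_qtl = n_qtl, n_traits = n_traits,
              h2_per_trait = rep_len(h2_per_trait, n_traits),
              sire_flock_var_frac = rep_len(sire_flock_var_frac, n_traits),
              genetic_corr = genetic_corr, qtl_var_frac = qtl_var_frac,
              qtl_private_frac = qtl_private_frac,
              crossbred_frac = crossbred_frac,
              missing_rate_per_trait = rep_len(missing_rate_per_trait, n_traits),
              n_flocks = n_flocks, fixed_effect_sd = fixed_effect_sd,
              seed = seed)
  class(cfg) <- "SimConfig"
  validateSimConfig(cfg)
  cfg
}

validateSimConfig <- function(cfg) {
  if (cfg$n_sires < 1 || cfg$n_dams_per_sire < 1 || cfg$n_offspring_per_dam < 1)
    stop("configuration error: counts of sires, dams and offspring must be positive")
  props <- c(cfg$h2_per_trait, cfg$sire_flock_var_frac, cfg$qtl_var_frac,
             cfg$qtl_private_frac, cfg$crossbred_frac, cfg$missing_rate_per_trait)
  if (any(props < 0 | props > 1))
    stop("configuration error: all proportions must lie in [0, 1]")
  if (cfg$n_qtl > cfg$n_snps)
    stop("configuration error: n_qtl must not exceed n_snps")
  G <- cfg$genetic_corr
  if (!isSymmetric(unname(G)) || any(abs(diag(G) - 1) > 1e-12))
    stop("configuration error: genetic_corr must be symmetric with unit diagonal")
  if (min(eigen(G, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("configuration error: genetic_corr must be positive semi-definite")
  if (any(cfg$h2_per_trait + cfg$sire_flock_var_frac >= 1))
    stop("configuration error: h2 + sire_flock_var_frac must be < 1 per trait")
  invisible(TRUE)
}

#' Simulate a three-generation half-sib pedigree
#'
#' Grandparent founders, sires and dams, and phenotyped offspring. Each dam
#' is mated to one sire. Offspring receive a flock, sex, measurement age and
#' a pedigree breed proportion Q: a `crossbred_frac` share of sire families
#' are crossbred-mated (offspring 0.25 < Q <= 0.90), the remainder are
#' straightbred (Q > 0.90). Assigning breed type by whole sire family keeps
#' family-based cross-validation feasible.
#'
#' @param cfg a [simConfig()] object
#' @return an [AnimalPedigree-class]; offspring have `generation == 2`.
#' @export
simulatePedigree <- function(cfg) {
  validateSimConfig(cfg)
  set.seed(splitSeed(cfg$seed, "pedigree"))
  ns <- cfg$n_sires; nd <- ns * cfg$n_dams_per_sire
  no <- nd * cfg$n_offspring_per_dam

  gpar <- paste0("g", seq_len(2 * (ns + nd)))
  sires <- paste0("s", seq_len(ns))
  dams <- paste0("d", seq_len(nd))
  offs <- paste0("o", seq_len(no))

  gp <- data.frame(id = gpar, sire = NA_character_, dam = NA_character_,
                   generation = 0L)
  par <- data.frame(id = c(sires, dams),
                    sire = gpar[seq(1, 2 * (ns + nd), by = 2)],
                    dam = gpar[seq(2, 2 * (ns + nd), by = 2)],
                    generation = 1L)
  damSire <- rep(sires, each = cfg$n_dams_per_sire)
  off <- data.frame(id = offs,
                    sire = rep(damSire, each = cfg$n_offspring_per_dam),
                    dam = rep(dams, each = cfg$n_offspring_per_dam),
                    generation = 2L)

  df <- rbind(gp, par, off)
  df$sex <- NA_character_
  df$flock <- NA_integer_
  df$age <- NA_real_
  df$breedQ <- 1.0

  io <- df$generation == 2L
  df$sex[io] <- sample(c("M", "F"), no, replace = TRUE)
  df$flock[io] <- sample.int(cfg$n_flocks, no, replace = TRUE)
  df$age[io] <- round(rnorm(no, 365, 30))

  nxb <- round(cfg$crossbred_frac * ns)
  xbSires <- sample(sires, nxb)
  isXb <- io & df$sire %in% xbSires
  df$breedQ[isXb] <- runif(sum(isXb), 0.30, 0.90)
  df$breedQ[io & !isXb] <- runif(sum(io & !isXb), 0.905, 1.0)
  animalPedigree(df)
}

#' Simulate genotypes by gene dropping
#'
#' Founder haplotypes are drawn from allele frequencies in \[0.05, 0.5\]
#' with linkage disequilibrium built in through a latent Gaussian process
#' whose correlation decays as `exp(-distance / ld_decay_bp)` — marginal
#' frequencies are exact while nearby SNPs are correlated within
#' haplotypes, as in a population descended from a finite ancestral pool.
#' Descendants inherit gametes through meiosis with Poisson crossovers at
#' 1 cM/Mb (no interference, no mutation), so LD decays further down the
#' pedigree. Dosages are coded 0/1/2 counting the alternate allele.
#'
#' @param ped an [AnimalPedigree-class]
#' @param cfg a [simConfig()] object
#' @param ld_decay_bp decay length of the founder-haplotype LD (latent
#'   correlation `exp(-d/ld_decay_bp)`)
#' @return a [GenotypeData-class] covering every pedigree animal.
#' @export
simulateGenotypes <- function(ped, cfg, ld_decay_bp = 500e3) {
  set.seed(splitSeed(cfg$seed, "genotypes"))
  df <- pedTable(ped)
  n <- nrow(df)
  sireIdx <- match(df$sire, df$id); sireIdx[is.na(sireIdx)] <- 0L
  damIdx <- match(df$dam, df$id); damIdx[is.na(damIdx)] <- 0L
  nPoolHap <- sum(sireIdx == 0) + sum(damIdx == 0)

  mPer <- diff(round(seq(0, cfg$n_snps, length.out = cfg$n_chromosomes + 1)))
  if (any(mPer > cfg$chrom_length_bp))
    stop("configuration error: chromosome length shorter than SNP spacing")

  doseList <- vector("list", cfg$n_chromosomes)
  mapList <- vector("list", cfg$n_chromosomes)
  for (cc in seq_len(cfg$n_chromosomes)) {
    m <- mPer[cc]
    pos <- sort(sample.int(cfg$chrom_length_bp, m))
    freq <- runif(m, 0.05, 0.5)
    # latent AR(1) haplotype pool: correlation decays with bp distance
    rho <- c(0, exp(-diff(pos) / ld_decay_bp))
    U <- matrix(0, nPoolHap, m)
    U[, 1] <- rnorm(nPoolHap)
    for (j in seq_len(m)[-1])
      U[, j] <- rho[j] * U[, j - 1] + sqrt(1 - rho[j]^2) * rnorm(nPoolHap)
    pool <- matrix(0L, nPoolHap, m)
    pool[sweep(U, 2, qnorm(freq), "<")] <- 1L
    doseList[[cc]] <- .geneDropChr(sireIdx, damIdx, as.numeric(pos), pool,
                                   1e-8, cfg$chrom_length_bp)
    mapList[[cc]] <- data.frame(chrom = paste0("chr", cc), bp = pos)
  }
  dose <- do.call(cbind, doseList)
  map <- do.call(rbind, mapList)
  rownames(dose) <- df$id
  colnames(dose) <- paste0("snp", seq_len(ncol(dose)))
  genotypeData(dose, map$chrom, map$bp)
}

#' Simulate correlated multi-trait phenotypes with known QTL
#'
#' Inverts the analysis model: phenotype = mean + fixed effects (flock, sex,
#' age) + breed-proportion effect + QTL effects + pedigree polygenic effect
#' + sire-by-flock effect + residual, on a per-trait phenotypic-SD scale
#' (total random variance a + s.f. + e is 1). QTL carry `qtl_var_frac` of
#' the genetic variance; a `qtl_private_frac` share affect one trait only,
#' the rest are pleiotropic with cross-trait effects drawn under
#' `genetic_corr`. The polygenic term flows through the full pedigree with
#' exact cross-trait correlation `genetic_corr`.
#'
#' @param geno [GenotypeData-class] from [simulateGenotypes()]
#' @param ped [AnimalPedigree-class]
#' @param cfg [simConfig()] object
#' @return list with elements `pheno` (a [PhenotypeData-class] over the
#'   offspring) and `truth` (list: `qtl_table` with snp/chrom/bp,
#'   `qtl_effects` QTL x trait matrix in phenotypic-SD units,
#'   `true_breeding_values` offspring x trait (with its `tbv_qtl` and
#'   `tbv_polygenic` components), `true_h2`).
#' @export
simulateTraits <- function(geno, ped, cfg) {
  validateSimConfig(cfg)
  set.seed(splitSeed(cfg$seed, "traits"))
  df <- pedTable(ped)
  io <- df$generation == max(df$generation)
  offIds <- df$id[io]
  no <- length(offIds); t <- cfg$n_traits
  h2 <- cfg$h2_per_trait; sf <- cfg$sire_flock_var_frac
  G <- cfg$genetic_corr

  map <- snpTable(geno)
  doseOff <- dosage(geno)[offIds, , drop = FALSE]
  p <- colMeans(doseOff) / 2

  # QTL: polymorphic, mutually separated by >= 2.5 Mb so each lands in its
  # own mapping window
  cand <- which(p > 0.05 & p < 0.95)
  cand <- cand[sample.int(length(cand))]
  qtl <- integer(0)
  for (j in cand) {
    if (length(qtl) >= cfg$n_qtl) break
    ok <- !any(map$chrom[qtl] == map$chrom[j] & abs(map$bp[qtl] - map$bp[j]) < 2.5e6)
    if (ok) qtl <- c(qtl, j)
  }
  if (length(qtl) < cfg$n_qtl)
    stop("could not place ", cfg$n_qtl, " QTL at the required spacing")
  qtl <- sort(qtl)

  nPriv <- round(cfg$qtl_private_frac * cfg$n_qtl)
  nPleio <- cfg$n_qtl - nPriv
  isPleio <- rep(FALSE, cfg$n_qtl)
  if (nPleio > 0) isPleio[sample.int(cfg$n_qtl, nPleio)] <- TRUE

  # pleiotropic effects: correlated draws, equalized in magnitude, then
  # transformed so the realized (empirical) QTL covariance matches the
  # target exactly; private QTL get one trait each at an equal variance
  # share. Pleiotropic and private shares per trait are proportional to
  # the QTL counts involved.
  L <- chol(G + diag(1e-10, t))
  beta <- matrix(0, cfg$n_qtl, t)
  privTrait <- integer(cfg$n_qtl)
  for (q in which(!isPleio)) {
    privTrait[q] <- ((q - 1) %% t) + 1
    beta[q, privTrait[q]] <- sample(c(-1, 1), 1)
  }
  Zq <- sweep(doseOff[, qtl, drop = FALSE], 2, 2 * p[qtl], "-")
  targetTot <- cfg$qtl_var_frac * h2
  nPrivK <- tabulate(privTrait[privTrait > 0], t)
  shareP <- nPleio / (nPleio + nPrivK) # pleiotropic share per trait

  if (nPleio >= t) {
    B <- vapply(seq_len(nPleio), function(q) {
      b <- drop(crossprod(L, rnorm(t)))
      b * sqrt(t) / sqrt(sum(b^2))
    }, numeric(t))
    B <- matrix(B, nrow = t) # traits x QTL regardless of t
    B <- t(B)
    Sz <- cov(Zq[, isPleio, drop = FALSE])
    M <- crossprod(B, Sz %*% B)
    D <- diag(sqrt(targetTot * shareP), t)
    SigmaP <- D %*% G %*% D
    B <- B %*% solve(chol(M + diag(1e-12, t))) %*% chol(SigmaP + diag(1e-12, t))
    beta[isPleio, ] <- B
  } else if (nPleio > 0) {
    # too few pleiotropic QTL for exact moment matching; scale per trait
    for (q in which(isPleio)) {
      b <- drop(crossprod(L, rnorm(t)))
      beta[q, ] <- b * sqrt(t) / sqrt(sum(b^2))
    }
    for (k in seq_len(t)) {
      v <- var(drop(Zq[, isPleio, drop = FALSE] %*% beta[isPleio, k]))
      if (v > 0) beta[isPleio, k] <- beta[isPleio, k] *
          sqrt(targetTot[k] * shareP[k] / v)
    }
  }
  # private QTL: equal per-QTL share of the remaining budget, exact in the
  # empirical dosage variance
  for (q in which(!isPleio)) {
    k <- privTrait[q]
    vz <- var(Zq[, q])
    shareQ <- targetTot[k] * (1 - shareP[k]) / max(nPrivK[k], 1)
    beta[q, k] <- beta[q, k] * sqrt(shareQ / vz)
  }

  tbvQtl <- Zq %*% beta

  # polygenic gene flow with exact cross-trait correlation
  polySd <- sqrt((1 - cfg$qtl_var_frac) * h2)
  Dp <- diag(polySd, t)
  Lp <- chol(crossprod(L %*% Dp) + diag(1e-12, t)) # chol of Dp G Dp
  nAll <- nrow(df)
  a <- matrix(0, nAll, t)
  sireIdx <- match(df$sire, df$id); damIdx <- match(df$dam, df$id)
  for (i in seq_len(nAll)) {
    z <- drop(crossprod(Lp, rnorm(t)))
    if (is.na(sireIdx[i]) && is.na(damIdx[i])) {
      a[i, ] <- z
    } else {
      as_ <- if (is.na(sireIdx[i])) rep(0, t) else a[sireIdx[i], ]
      ad_ <- if (is.na(damIdx[i])) rep(0, t) else a[damIdx[i], ]
      a[i, ] <- 0.5 * (as_ + ad_) + sqrt(0.5) * z
    }
  }
  tbvPoly <- a[match(offIds, df$id), , drop = FALSE]
  tbv <- tbvQtl + tbvPoly

  # sire-by-flock interaction
  sfKey <- paste(df$sire[io], df$flock[io], sep = ":")
  uKey <- unique(sfKey)
  sfMat <- matrix(0, no, t)
  for (k in seq_len(t)) {
    eff <- rnorm(length(uKey), 0, sqrt(sf[k]))
    sfMat[, k] <- eff[match(sfKey, uKey)]
  }

  # fixed effects, common structure across traits with per-trait draws
  fe <- cfg$fixed_effect_sd
  flockF <- factor(df$flock[io])
  sexM <- as.numeric(df$sex[io] == "M")
  ageStd <- as.numeric(scale(df$age[io]))
  Q <- df$breedQ[io]
  fixedMat <- matrix(0, no, t)
  for (k in seq_len(t)) {
    flockEff <- rnorm(nlevels(flockF), 0, fe)
    fixedMat[, k] <- 1 + flockEff[as.integer(flockF)] + fe * sexM +
      fe * ageStd + fe * Q
  }

  resid <- matrix(0, no, t)
  for (k in seq_len(t))
    resid[, k] <- rnorm(no, 0, sqrt(1 - h2[k] - sf[k]))

  y <- fixedMat + tbv + sfMat + resid
  for (k in seq_len(t)) {
    mr <- cfg$missing_rate_per_trait[k]
    if (mr > 0) y[sample.int(no, round(mr * no)), k] <- NA
  }
  colnames(y) <- paste0("trait", seq_len(t))
  rownames(y) <- offIds
  colnames(tbv) <- colnames(y)
  rownames(tbv) <- offIds

  cov <- data.frame(flock = flockF, sex = df$sex[io], age = df$age[io],
                    breedQ = Q, sire = df$sire[io],
                    stringsAsFactors = FALSE)
  rownames(cov) <- offIds

  dimnames(tbvQtl) <- dimnames(tbv)
  dimnames(tbvPoly) <- dimnames(tbv)
  truth <- list(
    qtl_table = data.frame(snp = map$snp[qtl], chrom = map$chrom[qtl],
                           bp = map$bp[qtl], pleiotropic = isPleio,
                           private_trait = ifelse(isPleio, NA_integer_, privTrait),
                           stringsAsFactors = FALSE),
    qtl_effects = beta,
    true_breeding_values = tbv,
    tbv_qtl = tbvQtl,
    tbv_polygenic = tbvPoly,
    true_h2 = h2)
  list(pheno = phenotypeData(y, cov), truth = truth)
}

#' Score QTL recovery of a call set against simulation truth
#'
#' @param truth the `truth` element of [simulateTraits()] output
#' @param calls a data.frame of calls with columns `chrom`, `bp` and
#'   optionally `method`; or a named list of such data.frames
#' @param window_bp maximum distance from a true QTL for a call to count as
#'   a recovery
#' @return data.frame per method: QTL recovered, total QTL, sensitivity,
#'   and count of false calls (calls not within `window_bp` of any QTL).
#' @export
truthReport <- function(truth, calls, window_bp = 250e3) {
  if (is.null(truth$qtl_table) || nrow(truth$qtl_table) == 0)
    stop("empty truth set")
  if (is.data.frame(calls)) {
    calls <- if ("method" %in% names(calls)) split(calls, calls$method)
             else list(calls = calls)
  }
  qt <- truth$qtl_table
  res <- lapply(names(calls), function(mn) {
    cs <- calls[[mn]]
    hit <- vapply(seq_len(nrow(qt)), function(q) {
      any(cs$chrom == qt$chrom[q] & abs(cs$bp - qt$bp[q]) <= window_bp)
    }, logical(1))
    false <- if (nrow(cs) == 0) 0L else sum(vapply(seq_len(nrow(cs)), function(i) {
      !any(qt$chrom == cs$chrom[i] & abs(qt$bp - cs$bp[i]) <= window_bp)
    }, logical(1)))
    data.frame(method = mn, recovered = sum(hit), total_qtl = nrow(qt),
               sensitivity = mean(hit), false_calls = false,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
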