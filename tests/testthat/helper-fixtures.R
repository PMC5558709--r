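# Shared fixtures, built once per test session and cached.
.fixCache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixCache)) assign(name, build(), envir = .fixCache)
  get(name, envir = .fixCache)
}

# small population: 240 offspring, 2 chromosomes, 500 SNPs, 4 QTL, 3 traits
fixSmall <- function() fixture("small", function() {
  cfg <- simConfig(n_sires = 12, n_dams_per_sire = 4, n_offspring_per_dam = 5,
                   n_chromosomes = 2, chrom_length_bp = 20e6, n_snps = 500,
                   n_qtl = 4, n_traits = 3, h2_per_trait = c(0.5, 0.4, 0.6),
                   missing_rate_per_trait = 0.1, crossbred_frac = 0.25, seed = 7)
  ped <- simulatePedigree(cfg)
  geno <- simulateGenotypes(ped, cfg)
  st <- simulateTraits(geno, ped, cfg)
  adj <- adjustPhenotypes(st$pheno, ped, modelSpec())
  list(cfg = cfg, ped = ped, geno = geno, pheno = st$pheno,
       truth = st$truth, adj = adj)
})

fixSmallGwas <- function() fixture("smallGwas", function() {
  f <- fixSmall()
  traits <- colnames(adjustedResiduals(f$adj))
  gw <- lapply(traits, function(tr) singleTraitGwas(f$geno, f$adj, f$ped, tr))
  setNames(gw, traits)
})

# one strong QTL (30% of phenotypic variance), 400 animals, 800 SNPs —
# shared by the BayesR detection and local-GEBV variance checks
fixStrongQtl <- function() fixture("strongQtl", function() {
  cfg <- simConfig(n_sires = 20, n_dams_per_sire = 4, n_offspring_per_dam = 5,
                   n_chromosomes = 2, chrom_length_bp = 20e6, n_snps = 800,
                   n_qtl = 1, n_traits = 1, h2_per_trait = 0.5,
                   qtl_var_frac = 0.6, qtl_private_frac = 0,
                   missing_rate_per_trait = 0, crossbred_frac = 0, seed = 13)
  ped <- simulatePedigree(cfg)
  geno <- simulateGenotypes(ped, cfg)
  st <- simulateTraits(geno, ped, cfg)
  adj <- adjustPhenotypes(st$pheno, ped, modelSpec())
  fit <- bayesR(geno, adj, ped,
                bayesRConfig(n_iter = 4000, burn_in = 1500, n_chains = 1,
                             seed = 13), "trait1")
  list(cfg = cfg, ped = ped, geno = geno, truth = st$truth, adj = adj,
       fit = fit)
})

# desk-scale study population: 2000 offspring, 3 x 50 Mb, 6000 SNPs, 20 QTL,
# 8 traits (the package defaults); used by the acceptance-level checks
fixDesk <- function() fixture("desk", function() {
  cfg <- simConfig(seed = 11)
  ped <- simulatePedigree(cfg)
  geno <- simulateGenotypes(ped, cfg)
  st <- simulateTraits(geno, ped, cfg)
  adj <- adjustPhenotypes(st$pheno, ped, modelSpec())
  list(cfg = cfg, ped = ped, geno = geno, pheno = st$pheno,
       truth = st$truth, adj = adj)
})

fixDeskBayesR <- function() fixture("deskBayesR", function() {
  f <- fixDesk()
  traits <- colnames(adjustedResiduals(f$adj))
  bcfg <- bayesRConfig(n_iter = 2000, burn_in = 800, n_chains = 1, seed = 11)
  fits <- lapply(traits, function(tr) bayesR(f$geno, f$adj, f$ped, bcfg, tr))
  setNames(fits, traits)
})

# tiny deterministic genotype fixture with ids
tinyGeno <- function(n = 10, m = 20, seed = 1) {
  set.seed(seed)
  d <- matrix(rbinom(n * m, 2, runif(m, 0.2, 0.8)[rep(seq_len(m), each = n)]),
              n, m, dimnames = list(paste0("a", seq_len(n)),
                                    paste0("s", seq_len(m))))
  genotypeData(d, chrom = rep("chr1", m), bp = seq(1e5, by = 1e5, length.out = m))
}

# unrelated-founder pedigree (A = I) over given animal ids
founderPed <- function(ids) {
  animalPedigree(data.frame(id = ids, sire = NA, dam = NA, generation = 0L))
}

# build an AdjustedPheno directly from a residual matrix (tests only)
adjFromMatrix <- function(R, sds = NULL, vcs = NULL) {
  R <- sweep(R, 2, colMeans(R, na.rm = TRUE), "-")
  if (is.null(sds)) sds <- apply(R, 2, sd, na.rm = TRUE)
  new("AdjustedPheno", residuals = R, phenoSd = sds,
      varcomp = vcs %||% setNames(vector("list", ncol(R)), colnames(R)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
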