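#' Run the full analysis pipeline from a configuration
#'
#' Executes, as requested, simulate -> qc -> adjust -> gwas -> gblup ->
#' bayesr -> multitrait -> validate. Every completed stage writes its
#' outputs plus a JSON manifest (inputs, parameters, seed, MD5 hashes of
#' the outputs) under the output directory, so a rerun with the same
#' configuration and seed reproduces identical hashes for deterministic
#' stages. A stage failure halts the run, naming the stage; manifests of
#' completed stages remain.
#'
#' @param config a list, or the path of a YAML file, with elements
#'   `stages` (character vector), `seed`, and optional blocks `sim`
#'   (arguments to [simConfig()]), `qc` (arguments to [qcThresholds()]),
#'   `bayesr` (arguments to [bayesRConfig()]), and `multitrait`
#'   (`chi2_threshold`, `pp_threshold`, `k_top_windows`, `window_bp`).
#' @param out_dir output directory (created if needed)
#' @return invisibly, a list of in-memory stage results.
#' @export
runPipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- config$stages %||% c("simulate", "qc", "adjust", "gwas")
  seed <- config$seed %||% 1
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list()

  manifest <- function(stage, params, files) {
    files <- files[file.exists(files)]
    m <- list(stage = stage, seed = seed, parameters = params,
              inputs = as.list(state$manifested %||% character(0)),
              outputs = as.list(setNames(unname(tools::md5sum(files)),
                                         basename(files))))
    jsonlite::write_json(m, file.path(out_dir, paste0("manifest_", stage, ".json")),
                         auto_unbox = TRUE, pretty = TRUE)
    state$manifested <<- c(state$manifested, stage)
  }

  runStage <- function(stage, fun) {
    message("[", stage, "] running")
    tryCatch(fun(), error = function(e) {
      stop("pipeline halted at stage '", stage, "': ", conditionMessage(e),
           "\ncompleted stages: ",
           paste(state$manifested %||% "none", collapse = ", "),
           call. = FALSE)
    })
  }

  if ("simulate" %in% stages) runStage("simulate", function() {
    cfg <- do.call(simConfig, c(config$sim %||% list(), list(seed = seed)))
    ped <- simulatePedigree(cfg)
    geno <- simulateGenotypes(ped, cfg)
    st <- simulateTraits(geno, ped, cfg)
    writePedigree(ped, file.path(out_dir, "pedigree.tsv"))
    writePhenotypes(st$pheno, file.path(out_dir, "phenotypes.tsv"))
    writeGenotypes(geno, file.path(out_dir, "genotypes"), "dosage-tsv")
    jsonlite::write_json(st$truth[c("qtl_table", "true_h2")],
                         file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, dataframe = "columns", digits = NA)
    state$ped <<- ped; state$geno <<- geno; state$pheno <<- st$pheno
    state$truth <<- st$truth; state$cfg <<- cfg
    manifest("simulate", unclass(cfg),
             file.path(out_dir, c("pedigree.tsv", "phenotypes.tsv",
                                  "genotypes.dose.tsv", "genotypes.map.tsv",
                                  "truth.json")))
  })

  if ("qc" %in% stages) runStage("qc", function() {
    thr <- do.call(qcThresholds, config$qc %||% list())
    q <- qcGenotypes(state$geno, thr)
    state$geno <<- q$geno
    write.table(q$report, file.path(out_dir, "qc_report.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    manifest("qc", unclass(thr), file.path(out_dir, "qc_report.tsv"))
  })

  if ("adjust" %in% stages) runStage("adjust", function() {
    spec <- modelSpec()
    adj <- adjustPhenotypes(state$pheno, state$ped, spec)
    state$adj <<- adj
    out <- cbind(animal = rownames(adjustedResiduals(adj)),
                 as.data.frame(adjustedResiduals(adj)))
    data.table::fwrite(out, file.path(out_dir, "adjusted.tsv"), sep = "\t", na = "NA")
    manifest("adjust", list(model = unclass(spec)), file.path(out_dir, "adjusted.tsv"))
  })

  if ("gwas" %in% stages) runStage("gwas", function() {
    traits <- colnames(adjustedResiduals(state$adj))
    gw <- lapply(traits, function(tr)
      singleTraitGwas(state$geno, state$adj, state$ped, tr))
    names(gw) <- traits
    state$gwas <<- gw
    files <- vapply(traits, function(tr) {
      f <- file.path(out_dir, paste0("gwas_", tr, ".tsv"))
      data.table::fwrite(gw[[tr]], f, sep = "\t", na = "NA"); f
    }, character(1))
    manifest("gwas", list(traits = traits), files)
  })

  if ("gblup" %in% stages) runStage("gblup", function() {
    grm <- buildGrm(state$geno)
    folds <- makeCvFolds(state$ped, seed)
    traits <- colnames(adjustedResiduals(state$adj))
    tabs <- lapply(traits, function(tr) gblupFit(grm, state$adj, folds, tr))
    gebv <- do.call(rbind, tabs)
    state$gebv <<- gebv; state$folds <<- folds; state$grm <<- grm
    f <- file.path(out_dir, "gebv_gblup.tsv")
    data.table::fwrite(gebv, f, sep = "\t")
    manifest("gblup", list(folds = 5), f)
  })

  if ("bayesr" %in% stages) runStage("bayesr", function() {
    bcfg <- do.call(bayesRConfig, c(config$bayesr %||% list(), list(seed = seed)))
    traits <- colnames(adjustedResiduals(state$adj))
    fits <- lapply(traits, function(tr)
      bayesR(state$geno, state$adj, state$ped, bcfg, tr))
    names(fits) <- traits
    state$bayesr <<- fits
    files <- vapply(traits, function(tr) {
      f <- file.path(out_dir, paste0("bayesr_", tr, ".tsv"))
      out <- data.frame(snp = fits[[tr]]@snpIds,
                        mean_effect = fits[[tr]]@snpEffects,
                        classProb(fits[[tr]]),
                        pp_nonzero = fits[[tr]]@ppNonzero)
      data.table::fwrite(out, f, sep = "\t"); f
    }, character(1))
    manifest("bayesr", bcfg[c("n_iter", "burn_in", "n_chains")], files)
  })

  if ("multitrait" %in% stages) runStage("multitrait", function() {
    mt <- config$multitrait %||% list()
    tv <- buildTmatrixV(state$gwas)
    chi2 <- multiGwasChi2(tv)
    callsGwas <- topSnpPerMb(chi2, mt$chi2_threshold %||% 5e-7,
                             mt$window_bp_tile %||% 1e6)
    map <- snpTable(state$geno)
    callsPp <- multiPP(state$bayesr, map, mt$pp_threshold %||% 0.3)
    lgm <- localGebv(state$bayesr, state$geno, mt$window_bp %||% 250e3)
    wp <- windowCovPca(lgm, phenoSd(state$adj))
    top <- selectTopWindows(wp, min(mt$k_top_windows %||% 120,
                                    length(windowRanges(wp))))
    ids <- rownames(dosage(state$geno))
    phenoIds <- rownames(adjustedResiduals(state$adj))
    rot <- polygenicRotation(state$ped, intersect(ids, phenoIds))
    best <- do.call(rbind, lapply(top$window, function(wn) {
      slc <- pseudoTraitSlc(lgm, wp, wn, state$adj)
      slc <- slc[rot$ids]
      bestSnpInWindow(slc, state$geno, state$ped, wn,
                      windows = windowRanges(wp), rot = rot)
    }))
    callsLg <- data.frame(method = "multi-LGEBV", snp = best$snp,
                          chrom = best$chrom, bp = best$bp,
                          statistic = best$Fval, stringsAsFactors = FALSE)
    calls <- list(`multi-GWAS` = callsGwas, `multi-PP` = callsPp,
                  `multi-LGEBV` = callsLg)
    state$calls <<- calls
    ov <- compareMethods(calls)
    f1 <- file.path(out_dir, "multitrait_calls.tsv")
    allCalls <- do.call(rbind, lapply(calls, function(d)
      d[, c("method", "snp", "chrom", "bp", "statistic")]))
    data.table::fwrite(allCalls, f1, sep = "\t")
    f2 <- file.path(out_dir, "venn.json")
    jsonlite::write_json(list(venn = as.list(ov$venn),
                              union_size = ov$union_size), f2,
                         auto_unbox = TRUE)
    manifest("multitrait", mt, c(f1, f2))
  })

  if ("validate" %in% stages) runStage("validate", function() {
    folds <- state$folds %||% makeCvFolds(state$ped, seed)
    validIds <- folds$id[folds$fold == 1]
    trainIds <- folds$id[folds$fold != 1]
    res <- adjustedResiduals(state$adj)
    trainIds <- intersect(trainIds, rownames(res))
    gwTrain <- lapply(colnames(res), function(tr)
      singleTraitGwas(state$geno[trainIds, ], state$adj, state$ped, tr))
    names(gwTrain) <- colnames(res)
    u <- phenoCovariance(state$adj)
    completed <- imputeMissingPhenotypes(state$adj, u)
    snps <- unique(unlist(lapply(state$calls, function(d) d$snp)))
    vr <- validateIndexSnps(snps, gwTrain,
                            completed[intersect(validIds, rownames(completed)), ,
                                      drop = FALSE],
                            state$geno, state$ped)
    state$validation <<- vr
    f <- file.path(out_dir, "validation.tsv")
    data.table::fwrite(vr$table, f, sep = "\t", na = "NA")
    manifest("validate", list(n_snps = length(snps)), f)
  })

  invisible(state)
}
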