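#' @include assoc-stats.R
NULL

.defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    sim = list(),                     # simConfig() overrides
    rdcv = list(nRep = 3L, nOuter = 6L, nInner = 5L, nTrees = 100L,
                keepRatio = 0.75, varSel = FALSE),
    screens = list(regression = TRUE, classification = TRUE,
                   provocation = TRUE, nPerm = 20L, minN = 8L,
                   nReruns = 5L, alpha = 0.05,
                   maxRegression = NULL, maxClassification = NULL,
                   maxProvocation = NULL),
    parafac = list(run = TRUE, scheme = "sd_one", components = 2:4,
                   imputeRank = 5L, method = "hierarchical", scaled = TRUE)
  )
}

.mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]]))
      .mergeConfig(base[[nm]], user[[nm]]) else user[[nm]]
  }
  base
}

.configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run the full screening pipeline on a synthetic trial
#'
#' Config-driven end-to-end run in the analysis order of the framework:
#' simulate the trial and provocation tensor, enumerate and fit the
#' baseline regression and classification screens and the provocation
#' screen, impute/preprocess/decompose the tensor and run the ANOVA
#' linkage, then write result TSVs and a JSON run manifest with the
#' model-count accounting (enumerated, evaluated, eligible, passing the a
#' priori filter, significant after permutation — non-increasing along
#' each chain). Every stochastic step is seeded from the master seed, so a
#' rerun with the same configuration reproduces the manifest.
#'
#' Desk-scale defaults (nPerm = 20, nRep = 3, variable selection off)
#' keep a full run in the minutes range; `paperScale = TRUE` restores the
#' full protocol (nPerm = 100, nRep = 5, variable selection on).
#'
#' @param config named list (sections `seed`, `sim`, `rdcv`, `screens`,
#'   `parafac`) or the path to a YAML file with those sections. Any field
#'   omitted falls back to the defaults.
#' @param outDir output directory for result files (default: tempdir).
#' @param paperScale restore full protocol settings.
#' @return list with `manifest` (also written as JSON) and the result
#'   data.frames.
#' @export
runPipeline <- function(config = list(), outDir = tempfile("pipeline"),
                        paperScale = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .mergeConfig(.defaultPipelineConfig(), config)
  if (paperScale) {
    cfg$rdcv$nRep <- 5L
    cfg$rdcv$nTrees <- 300L
    cfg$rdcv$varSel <- TRUE
    cfg$screens$nPerm <- 100L
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hash <- .configHash(cfg)
  seed <- as.integer(cfg$seed)

  simCfg <- do.call(simConfig, c(cfg$sim, list(seed = seed)))
  dataset <- simulateTrial(simCfg)
  tensor <- simulateProvocationTensor(simCfg, dataset)
  files <- c(writeTrialDataset(dataset, file.path(outDir, "data")),
             writeProvocationTensor(tensor, file.path(outDir, "data")))

  params <- do.call(rdcvParams, c(cfg$rdcv, list(seed = seed)))
  alpha <- cfg$screens$alpha
  counts <- list()
  results <- list()

  takeHead <- function(df, k) {
    if (is.null(k) || nrow(df) <= k) df else df[seq_len(k), , drop = FALSE]
  }
  if (isTRUE(cfg$screens$regression)) {
    configs <- enumerateBaselineScreens("regression")
    run <- takeHead(configs, cfg$screens$maxRegression)
    res <- screenRegression(dataset, params, configs = run,
                            nPerm = cfg$screens$nPerm)
    results$regression <- res
    counts$regression <- list(
      enumerated = nrow(configs), evaluated = nrow(run),
      passing = sum(res$threshold_pass),
      significant = sum(res$p_perm < alpha, na.rm = TRUE))
    f <- file.path(outDir, "screen_regression.tsv")
    .writeTsv(res, f); files <- c(files, f)
  }
  if (isTRUE(cfg$screens$classification)) {
    configs <- enumerateBaselineScreens("classification")
    run <- takeHead(configs, cfg$screens$maxClassification)
    res <- screenClassification(dataset, params, configs = run,
                                minN = cfg$screens$minN,
                                nReruns = cfg$screens$nReruns,
                                nPerm = cfg$screens$nPerm)
    results$classification <- res
    counts$classification <- list(
      enumerated = nrow(configs), evaluated = nrow(run),
      eligible = sum(res$eligible),
      passing = sum(res$threshold_pass),
      significant = sum(res$p_perm < alpha, na.rm = TRUE))
    f <- file.path(outDir, "screen_classification.tsv")
    .writeTsv(res, f); files <- c(files, f)
  }

  tensorC <- imputeTensor(tensor, rank = cfg$parafac$imputeRank)
  if (isTRUE(cfg$screens$provocation)) {
    configs <- enumerateProvocationScreens(simCfg@timepoints)
    run <- takeHead(configs, cfg$screens$maxProvocation)
    res <- screenProvocation(dataset, tensorC, params, configs = run,
                             nPerm = cfg$screens$nPerm)
    results$provocation <- res
    counts$provocation <- list(
      enumerated = nrow(configs), evaluated = nrow(run),
      passing = sum(res$threshold_pass),
      significant = sum(res$p_perm < alpha, na.rm = TRUE))
    f <- file.path(outDir, "screen_provocation.tsv")
    .writeTsv(res, f); files <- c(files, f)
  }

  if (isTRUE(cfg$parafac$run)) {
    comps <- cfg$parafac$components
    pre <- preprocessTensor(tensorC, cfg$parafac$scheme)
    models <- lapply(comps, function(C)
      parafacALS(pre, C, init = "svd", seed = seed))
    link <- linkageScreen(models, dataset, cfg$parafac$method,
                          cfg$parafac$scaled, minN = cfg$screens$minN,
                          seed = seed)
    results$linkage <- link
    enr <- enrichmentSummary(link, alpha = alpha)
    results$enrichment <- enr
    counts$parafacLinkage <- list(
      enumerated = nrow(enumerateLinkageScreen(componentRange = comps)),
      evaluated = nrow(link),
      eligible = sum(link$eligible),
      significant = enr$total)
    f <- file.path(outDir, "parafac_linkage.tsv")
    .writeTsv(link, f); files <- c(files, f)
  }

  manifest <- list(
    configHash = hash, seed = seed,
    packageVersion = as.character(utils::packageVersion("metabotypeR")),
    counts = counts,
    files = basename(files))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  c(list(manifest = manifest, outDir = outDir), results)
}

#' Format the classification report table
#'
#' The reporting shape of the classification screen: one row per model
#' above the CR floor, columns for the IBS-SSS variable, clustering
#' method, cluster count, predictor block, mean CR +/- SD over the
#' re-runs, and the permutation p, sorted by p.
#'
#' @param results output of [screenClassification()].
#' @param crFloor minimum CR to report (default 0.6; 0 lists everything).
#' @return data.frame with columns `ibs_sss_variable`, `method`,
#'   `n_clusters`, `predictor_data`, `cr_sd`, `p_perm`.
#' @export
reportTable <- function(results, crFloor = 0.6) {
  cr <- ifelse(is.na(results$rerun_mean_cr), results$CR,
               results$rerun_mean_cr)
  keep <- !is.na(cr) & cr > crFloor
  r <- results[keep, , drop = FALSE]
  cr <- cr[keep]
  sd <- ifelse(is.na(r$rerun_sd_cr), 0, r$rerun_sd_cr)
  out <- data.frame(
    ibs_sss_variable = r$item,
    method = ifelse(r$method == "hierarchical", "Hclust", "Kmeans"),
    n_clusters = r$k,
    predictor_data = r$predictor,
    cr_sd = sprintf("%.2f ± %.2f", cr, sd),
    p_perm = r$p_perm)
  out[order(out$p_perm, -cr), , drop = FALSE]
}
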