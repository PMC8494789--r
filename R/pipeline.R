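# End-to-end orchestration: preprocess -> seed maps -> spatial ICA -> dual
# regression -> primary (network-thalamus) inference -> seed-based analysis,
# with a reproducibility manifest.

#' Default pipeline configuration
#'
#' Defaults follow the pipeline's standard operating point: discard 4
#' initial frames, highpass above 0.01 Hz, 20 components, cluster-level
#' correction of the primary analysis and TFCE for seed extraction and the
#' seed-based group comparison.
#'
#' @return nested list of configuration values.
#' @export
defaultPipelineConfig <- function() {
  list(
    data_dir = NULL, out_dir = NULL,
    thalamus_mask = NULL, brain_mask = NULL,
    labels = NULL, label_table = NULL,
    preprocess = list(trim = 4L, highpass_hz = 0.01, tr_s = 3.5),
    ica = list(n_components = 20L, seed = 1L, controls_only = FALSE),
    inference = list(n_perm = 1000L, enhancement = "cluster_extent",
                     forming_t = 2.3, seed = 1L, alpha = 0.05),
    seed_analysis = list(n_perm = 1000L, seed = 1L, alpha = 0.05)
  )
}

mergeConfig <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- mergeConfig(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a pipeline configuration file
#'
#' YAML key-values merged over [defaultPipelineConfig()].
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  mergeConfig(defaultPipelineConfig(), yaml::read_yaml(path))
}

validateConfig <- function(config) {
  if (is.null(config$data_dir) || !dir.exists(config$data_dir))
    stop("config: data_dir must exist")
  if (is.null(config$out_dir)) stop("config: out_dir is required")
  if (is.null(config$thalamus_mask))
    config$thalamus_mask <- file.path(config$data_dir, "thalamus_mask.nii.gz")
  if (is.null(config$brain_mask))
    config$brain_mask <- file.path(config$data_dir, "brain_mask.nii.gz")
  for (p in c(config$thalamus_mask, config$brain_mask))
    if (!file.exists(p)) stop(sprintf("config: mask file not found: %s", p))
  config
}

#' Run the full thalamocortical connectivity pipeline
#'
#' Executes the stages in order on a cohort directory (as written by
#' [simulateCohort()], or any directory with the same layout:
#' `design.tsv`, `data/<subject>_bold.nii.gz`,
#' `data/<subject>_confounds.tsv`, plus thalamus and brain masks). Any
#' stage failure aborts with the stage and the offending subject or
#' component named. A manifest with every seed and a hash of the
#' configuration is written alongside the outputs, so a rerun with the same
#' manifest reproduces all outputs.
#'
#' @param config configuration list (see [defaultPipelineConfig()]) or path
#'   to a YAML file.
#' @return invisibly, a list with the decomposition, subdivision maps,
#'   per-component primary and seed-analysis results, and output paths.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  config <- mergeConfig(defaultPipelineConfig(), config)
  config <- validateConfig(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  design <- utils::read.table(file.path(config$data_dir, "design.tsv"),
                              header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  if (min(table(design$group)) < 2L)
    stop("stage design: need at least 2 subjects per group")
  thal <- readMask(config$thalamus_mask)
  brain <- readMask(config$brain_mask)
  labels <- NULL
  if (!is.null(config$labels))
    labels <- readLabelVolume(config$labels, config$label_table)

  # preprocess + seed maps ---------------------------------------------
  mapsets <- vector("list", nrow(design))
  bolds <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    id <- design$subject[i]
    boldPath <- file.path(config$data_dir, "data", paste0(id, "_bold.nii.gz"))
    confPath <- file.path(config$data_dir, "data",
                          paste0(id, "_confounds.tsv"))
    if (!file.exists(boldPath))
      stop(sprintf("stage preprocess: missing bold file for subject %s", id))
    if (!file.exists(confPath))
      stop(sprintf("stage preprocess: missing confound file for subject %s",
                   id))
    bold <- readVolume(boldPath)
    conf <- readConfoundTable(confPath)
    pp <- config$preprocess
    bolds[[i]] <- preprocessSubject(bold, conf, trim = pp$trim,
                                    highpassHz = pp$highpass_hz,
                                    trS = pp$tr_s)
    mapsets[[i]] <- thalamicSeedMaps(bolds[[i]], thal, brain, subject = id)
  }

  # group ICA ----------------------------------------------------------
  icaSets <- mapsets
  if (isTRUE(config$ica$controls_only))
    icaSets <- mapsets[design$group == "control"]
  stack <- concatenateGroup(icaSets)
  dec <- fitSpatialICA(stack, brain,
                       nComponents = config$ica$n_components,
                       seed = config$ica$seed)
  K <- nComponents(dec)
  icaDir <- file.path(out, "ica")
  dir.create(icaDir, showWarnings = FALSE)
  for (k in seq_len(K))
    writeVolume(new("Volume4D",
                    data = array(dec@maps[, , , k], c(dim(brain@data), 1L)),
                    voxelSize = voxelSize(brain),
                    affine = affineMatrix(brain),
                    frameMeaning = "stacked_maps"),
                file.path(icaDir, sprintf("component_%02d_zmap.nii.gz", k)))
  utils::write.table(mixingMatrix(dec), file.path(icaDir, "mixing.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  # dual regression ----------------------------------------------------
  drDir <- file.path(out, "dualreg")
  dir.create(drDir, showWarnings = FALSE)
  subdivisions <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    id <- design$subject[i]
    dr <- tryCatch(dualRegression(bolds[[i]], dec, thal, brain, subject = id),
                   error = function(e) stop(sprintf(
                     "stage dualreg: subject %s: %s", id, conditionMessage(e))))
    subdivisions[[i]] <- dr$subdivisions
    utils::write.table(dr$timecourses,
                       file.path(drDir, paste0(id, "_timecourses.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    writeVolume(dr$subdivisions@betas,
                file.path(drDir, paste0(id, "_subdivisions.nii.gz")))
  }

  # primary analysis: network-thalamus connectivity per component ------
  inf <- config$inference
  gdes <- groupDesign(design$group,
                      covariates = design[, c("age", "sex"), drop = FALSE])
  primDir <- file.path(out, "primary")
  dir.create(primDir, showWarnings = FALSE)
  primary <- vector("list", K)
  for (k in seq_len(K)) {
    Yk <- do.call(rbind, lapply(subdivisions, function(s)
      thalamicBetas(s)[k, ]))
    res <- tryCatch(
      permutationTest(Yk, gdes, thal, enhancement = inf$enhancement,
                      nPerm = inf$n_perm, seed = inf$seed + k,
                      formingT = inf$forming_t, alpha = inf$alpha),
      error = function(e) stop(sprintf(
        "stage primary inference: component %d: %s", k,
        conditionMessage(e))))
    primary[[k]] <- res
    writePermutationResult(res, primDir, sprintf("component_%02d", k), labels)
  }

  # seed-based analysis per component ----------------------------------
  sa <- config$seed_analysis
  seedDir <- file.path(out, "seeds")
  dir.create(seedDir, showWarnings = FALSE)
  seedResults <- vector("list", K)
  for (k in seq_len(K)) {
    res <- tryCatch({
      sd <- extractSeed(subdivisions, k, nPerm = sa$n_perm,
                        seed = sa$seed + k, alpha = sa$alpha)
      maps <- lapply(bolds, function(b) seedConnectivityMap(b, sd, brain))
      grp <- compareSeedMaps(maps, gdes, brain, nPerm = sa$n_perm,
                             seed = sa$seed + k, alpha = sa$alpha)
      writeVolume(sd@mask,
                  file.path(seedDir, sprintf("component_%02d_seed.nii.gz", k)))
      writePermutationResult(grp, seedDir, sprintf("component_%02d", k),
                             labels)
      list(seed = sd, comparison = grp)
    }, error = function(e) {
      message(sprintf("seed analysis: component %d skipped: %s", k,
                      conditionMessage(e)))
      NULL
    })
    seedResults[[k]] <- res
  }

  # manifest ------------------------------------------------------------
  cfgFile <- file.path(out, "config_used.yaml")
  yaml::write_yaml(config, cfgFile)
  manifest <- list(config_hash = unname(tools::md5sum(cfgFile)),
                   ica_seed = config$ica$seed,
                   inference_seed = config$inference$seed,
                   seed_analysis_seed = config$seed_analysis$seed,
                   n_components = K,
                   subjects = design$subject)
  yaml::write_yaml(manifest, file.path(out, "manifest.yaml"))

  invisible(list(design = design, decomposition = dec,
                 subdivisions = subdivisions, primary = primary,
                 seedAnalysis = seedResults, outDir = out,
                 manifest = manifest))
}

writePermutationResult <- function(res, dir, prefix, labels = NULL) {
  mask <- res@observed@mask
  pm <- res@pMap
  pm[is.na(pm)] <- 1
  writeVolume(new("Volume4D",
                  data = array(1 - pm, c(dim(mask@data), 1L)),
                  voxelSize = voxelSize(mask), affine = affineMatrix(mask),
                  frameMeaning = "stacked_maps"),
              file.path(dir, paste0(prefix, "_corrp.nii.gz")))
  ct <- if (!is.null(labels)) annotateClusters(res, labels)
        else clusterTable(res)
  utils::write.table(ct, file.path(dir, paste0(prefix, "_clusters.tsv")),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(NULL)
}
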