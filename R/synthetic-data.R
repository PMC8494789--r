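# Synthetic two-group cohorts with planted thalamocortical networks.
#
# Every downstream stage of the pipeline is validated against the ground
# truth planted here: K cortical networks (Gaussian blobs), each driven by a
# thalamic subregion (Gaussian weight map inside a central ellipsoidal
# thalamus) through a shared AR(1) time course. Patients have designated
# network-thalamus couplings scaled by a multiplicative factor.

gaussianBlob <- function(dims, center, sd) {
  gx <- exp(-0.5 * ((seq_len(dims[1]) - center[1]) / sd)^2)
  gy <- exp(-0.5 * ((seq_len(dims[2]) - center[2]) / sd)^2)
  gz <- exp(-0.5 * ((seq_len(dims[3]) - center[3]) / sd)^2)
  outer(outer(gx, gy), gz)
}

ellipsoidMask <- function(dims, center, radii) {
  gx <- ((seq_len(dims[1]) - center[1]) / radii[1])^2
  gy <- ((seq_len(dims[2]) - center[2]) / radii[2])^2
  gz <- ((seq_len(dims[3]) - center[3]) / radii[3])^2
  outer(outer(gx, gy, `+`), gz, `+`) <= 1
}

#' Construct the ground truth of a synthetic thalamocortical cohort
#'
#' The thalamus is a central ellipsoid; the K networks are peripheral
#' Gaussian blobs well separated in space (pairwise spatial correlation
#' below 0.2); each network's thalamic weight map is a Gaussian blob inside
#' the thalamus, plus a small baseline so that every thalamic voxel carries
#' some total weight (overlapping subdivisions, as in real thalamic
#' functional anatomy).
#'
#' @param dims grid dimensions (each >= 12 so distinct blobs fit).
#' @param K number of planted networks (>= 2).
#' @param voxelSize voxel size in mm (default 3, the working resolution of
#'   the pipeline).
#' @param nTimepoints frames per subject.
#' @param trS repetition time, seconds.
#' @param arCoef AR(1) coefficient of network time courses (default 0.3).
#' @param noiseSd white-noise standard deviation (signal amplitudes are of
#'   order 1).
#' @param groupEffect data.frame (`component`, `factor`): multiplicative
#'   factor applied to the listed components' thalamic weights in patients.
#' @param thalBaseline baseline thalamic weight (fraction of the blob peak)
#'   added to every component inside the thalamus.
#' @param seed reproducibility seed.
#' @return a [GroundTruth].
#' @export
makeGroundTruth <- function(dims = c(18L, 22L, 18L), K = 3L,
                            voxelSize = c(3, 3, 3),
                            nTimepoints = 150L, trS = 3.5, arCoef = 0.3,
                            noiseSd = 1,
                            groupEffect = data.frame(component = 1L,
                                                     factor = 0.5),
                            thalBaseline = 0.02, seed = 1L) {
  dims <- as.integer(dims)
  if (any(dims < 12L))
    stop("grid must be at least 12 voxels per axis to fit distinct blobs")
  if (K < 2L) stop("K must be >= 2")
  set.seed(seed)
  center <- (dims + 1) / 2
  affine <- rbind(cbind(diag(voxelSize), -voxelSize * (dims - 1) / 2),
                  c(0, 0, 0, 1))
  brain <- ellipsoidMask(dims, center, (dims - 1) / 2)
  thalRadii <- pmax(dims / 7, 2)
  thal <- ellipsoidMask(dims, center, thalRadii) & brain
  # cortical networks: blobs on a ring outside the thalamus
  netMaps <- array(0, dim = c(dims, K))
  ang <- 2 * pi * (seq_len(K) - 1) / K + pi / (2 * K)
  ringR <- 0.62 * (dims[1:2] - 1) / 2
  blobSd <- mean(dims) / 9
  nearThal <- ellipsoidMask(dims, center, thalRadii + blobSd)
  for (k in seq_len(K)) {
    ctr <- c(center[1] + ringR[1] * cos(ang[k]),
             center[2] + ringR[2] * sin(ang[k]),
             center[3] + (if (k %% 2 == 0) 1 else -1) * dims[3] / 8)
    if (any(ctr < 2) || any(ctr > dims - 1))
      stop("network blob does not fit the grid")
    b <- gaussianBlob(dims, ctr, blobSd)
    b[b < 0.05 * max(b)] <- 0
    b[nearThal | !brain] <- 0
    netMaps[, , , k] <- b
  }
  # thalamic weight maps: blobs spread along the thalamus long axis
  thalWeights <- array(0, dim = c(dims, K))
  off <- seq(-0.55, 0.55, length.out = K)
  for (k in seq_len(K)) {
    ctr <- center + c(0, off[k] * thalRadii[2], 0)
    w <- gaussianBlob(dims, ctr, 1.3)
    w <- w / max(w[thal])
    w <- w + thalBaseline
    w[!thal] <- 0
    thalWeights[, , , k] <- w
  }
  new("GroundTruth", dims = dims, voxelSize = as.numeric(voxelSize),
      affine = affine,
      thalamus = new("BrainMask", data = thal,
                     voxelSize = as.numeric(voxelSize), affine = affine),
      brain = new("BrainMask", data = brain,
                  voxelSize = as.numeric(voxelSize), affine = affine),
      networkMaps = netMaps, thalWeights = thalWeights,
      arCoef = rep(arCoef, length.out = K),
      groupEffect = groupEffect, noiseSd = noiseSd,
      nTimepoints = as.integer(nTimepoints), trS = trS,
      seed = as.numeric(seed))
}

#' Amplitude maps of the planted networks
#'
#' For each component, the voxel amplitude is the thalamic weight inside the
#' thalamus and the cortical network value outside it (`groupFactors` scales
#' the thalamic side for patients).
#' @keywords internal
groundTruthAmplitudes <- function(gt, groupFactors) {
  K <- nComponents(gt)
  idx <- which(gt@brain@data)
  thal <- gt@thalamus@data[idx]
  n3 <- prod(gt@dims)
  A <- matrix(0, length(idx), K)
  for (k in seq_len(K)) {
    net <- gt@networkMaps[, , , k][idx]
    w <- gt@thalWeights[, , , k][idx]
    A[, k] <- ifelse(thal, w * groupFactors[k], net)
  }
  A
}

groupFactors <- function(gt, group) {
  g <- rep(1, nComponents(gt))
  if (group == "patient" && nrow(gt@groupEffect))
    g[gt@groupEffect$component] <- gt@groupEffect$factor
  g
}

smoothSeries <- function(n, ar = 0.95) {
  as.numeric(stats::arima.sim(list(ar = ar), n = n, sd = sqrt(1 - ar^2)))
}

#' Simulate one subject's 4D volume and confound table
#'
#' Voxel series are sums over components of amplitude x group factor x AR(1)
#' time course, plus white noise, plus a small leak of the confound series
#' into the data (scaled with `noiseSd`, so noiseless simulations are
#' exactly low-rank).
#'
#' @param gt a [GroundTruth].
#' @param group `"control"` or `"patient"`.
#' @param seed subject seed.
#' @return list with `bold` ([Volume4D]), `confounds` (data.frame: six
#'   motion parameters, white-matter and CSF means), `group`, `seed`.
#' @export
simulateSubject <- function(gt, group = c("control", "patient"), seed = 1L) {
  group <- match.arg(group)
  set.seed(seed)
  K <- nComponents(gt)
  nt <- gt@nTimepoints
  tc <- vapply(seq_len(K), function(k) smoothSeries(nt, gt@arCoef[k]),
               numeric(nt))
  A <- groundTruthAmplitudes(gt, groupFactors(gt, group))
  y <- tc %*% t(A)
  if (gt@noiseSd > 0)
    y <- y + matrix(stats::rnorm(length(y), sd = gt@noiseSd), nrow = nt)
  conf <- vapply(1:8, function(j) smoothSeries(nt), numeric(nt))
  colnames(conf) <- c(paste0("motion", 1:6), "wm", "csf")
  if (gt@noiseSd > 0) {
    leak <- matrix(stats::rnorm(ncol(y) * 8, sd = 0.15 * gt@noiseSd),
                   ncol(y), 8)
    y <- y + conf %*% t(leak)
  }
  data <- array(0, dim = c(gt@dims, nt))
  idx <- which(gt@brain@data)
  n3 <- prod(gt@dims)
  for (t in seq_len(nt)) data[idx + (t - 1L) * n3] <- y[t, ]
  list(bold = new("Volume4D", data = data, voxelSize = gt@voxelSize,
                  affine = gt@affine, frameMeaning = "time"),
       confounds = as.data.frame(conf), group = group, seed = seed)
}

#' Create a cohort sampling plan
#'
#' Demographics default to a young adult two-group cohort: ages near 23
#' years with slightly wider spread in patients, and a balanced sex ratio.
#'
#' @param nPerGroup subjects per group (>= 3).
#' @param ageMean,ageSd length-2 numeric, order (control, patient).
#' @param pFemale length-2 probability of female sex.
#' @param seed master seed.
#' @return a [CohortSpec].
#' @export
cohortSpec <- function(nPerGroup, ageMean = c(22.58, 22.88),
                       ageSd = c(3.94, 5.64), pFemale = c(0.5, 0.55),
                       seed = 1L) {
  new("CohortSpec", nPerGroup = as.integer(nPerGroup), ageMean = ageMean,
      ageSd = ageSd, pFemale = pFemale, seed = as.numeric(seed))
}

#' Simulate a two-group cohort to disk
#'
#' Writes `data/sub-XX_bold.nii.gz` and `data/sub-XX_confounds.tsv` per
#' subject, the thalamus/brain masks, the ground-truth network and thalamic
#' weight maps (stacked NIfTI), a `design.tsv` (subject, group, age, sex)
#' and a `manifest.yaml` recording every seed so the dataset can be rebuilt
#' bit for bit.
#'
#' @param gt a [GroundTruth].
#' @param spec a [CohortSpec].
#' @param dir output directory (created if needed).
#' @return list with `dir`, `design` (data.frame) and the manifest list.
#' @export
simulateCohort <- function(gt, spec, dir) {
  dir.create(file.path(dir, "data"), recursive = TRUE, showWarnings = FALSE)
  n <- 2L * spec@nPerGroup
  subjSeeds <- deriveSeeds(spec@seed, n)
  set.seed(spec@seed)
  groups <- rep(c("control", "patient"), each = spec@nPerGroup)
  gi <- as.integer(groups == "patient") + 1L
  age <- round(stats::rnorm(n, spec@ageMean[gi], spec@ageSd[gi]), 1)
  sex <- ifelse(stats::rbinom(n, 1, spec@pFemale[gi]) == 1, "F", "M")
  ids <- sprintf("sub-%02d", seq_len(n))
  design <- data.frame(subject = ids, group = groups, age = age, sex = sex,
                       stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    sub <- simulateSubject(gt, groups[i], subjSeeds[i])
    writeVolume(sub$bold, file.path(dir, "data",
                                    paste0(ids[i], "_bold.nii.gz")))
    utils::write.table(sub$confounds,
                       file.path(dir, "data", paste0(ids[i], "_confounds.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  writeVolume(gt@thalamus, file.path(dir, "thalamus_mask.nii.gz"))
  writeVolume(gt@brain, file.path(dir, "brain_mask.nii.gz"))
  writeVolume(new("Volume4D", data = gt@networkMaps,
                  voxelSize = gt@voxelSize, affine = gt@affine,
                  frameMeaning = "stacked_maps"),
              file.path(dir, "groundtruth_networks.nii.gz"))
  writeVolume(new("Volume4D", data = gt@thalWeights,
                  voxelSize = gt@voxelSize, affine = gt@affine,
                  frameMeaning = "stacked_maps"),
              file.path(dir, "groundtruth_thalweights.nii.gz"))
  utils::write.table(design, file.path(dir, "design.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  manifest <- list(master_seed = spec@seed,
                   ground_truth_seed = gt@seed,
                   n_per_group = spec@nPerGroup,
                   n_timepoints = gt@nTimepoints,
                   tr_s = gt@trS,
                   noise_sd = gt@noiseSd,
                   n_components = nComponents(gt),
                   group_effect = as.list(gt@groupEffect),
                   subjects = stats::setNames(as.list(subjSeeds), ids))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  list(dir = dir, design = design, manifest = manifest)
}
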