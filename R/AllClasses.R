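# S4 classes for the thalamocortical connectivity pipeline.

#' Volume4D: a 4D brain image
#'
#' A 3D grid of voxels by a frame axis, with voxel size and a 4x4
#' voxel-to-world affine. Frames are timepoints (`frameMeaning = "time"`) or
#' stacked statistical maps (`frameMeaning = "stacked_maps"`). Voxel indices
#' are 1-based throughout the package; world (MNI) coordinates are obtained
#' only through the affine, which follows the NIfTI 0-based convention
#' internally.
#'
#' @slot data four-dimensional numeric array (x, y, z, frame).
#' @slot voxelSize numeric length-3, voxel edge lengths in mm.
#' @slot affine 4x4 voxel-to-world transform.
#' @slot frameMeaning `"time"` or `"stacked_maps"`.
#' @export
setClass("Volume4D",
  representation(data = "array", voxelSize = "numeric",
                 affine = "matrix", frameMeaning = "character"),
  validity = function(object) {
    d <- dim(object@data)
    if (length(d) != 4L) return("data must be a 4D array")
    if (any(d < 1L)) return("all dimensions must be >= 1")
    if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
      return("voxelSize must be 3 positive values")
    if (!all(dim(object@affine) == c(4L, 4L)))
      return("affine must be 4x4")
    if (abs(det(object@affine)) < 1e-12)
      return("affine must be invertible")
    if (!object@frameMeaning %in% c("time", "stacked_maps"))
      return("frameMeaning must be 'time' or 'stacked_maps'")
    TRUE
  })

#' BrainMask: a 3D binary mask
#'
#' @slot data 3D logical array.
#' @slot voxelSize numeric length-3 (mm).
#' @slot affine 4x4 voxel-to-world transform.
#' @export
setClass("BrainMask",
  representation(data = "array", voxelSize = "numeric", affine = "matrix"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L) return("mask data must be 3D")
    if (!is.logical(object@data)) return("mask data must be logical")
    if (sum(object@data) < 1L) return("mask must contain at least one voxel")
    if (!all(dim(object@affine) == c(4L, 4L)) ||
        abs(det(object@affine)) < 1e-12)
      return("affine must be an invertible 4x4 matrix")
    TRUE
  })

#' LabelVolume: an integer-labelled atlas volume
#'
#' @slot data 3D integer array; 0 means unlabeled.
#' @slot labelTable data.frame with columns `value` (integer) and `name`.
#' @slot voxelSize numeric length-3 (mm).
#' @slot affine 4x4 voxel-to-world transform.
#' @export
setClass("LabelVolume",
  representation(data = "array", labelTable = "data.frame",
                 voxelSize = "numeric", affine = "matrix"),
  validity = function(object) {
    if (length(dim(object@data)) != 3L) return("label data must be 3D")
    if (!all(c("value", "name") %in% names(object@labelTable)))
      return("labelTable needs columns 'value' and 'name'")
    vals <- unique(as.vector(object@data))
    vals <- vals[vals != 0]
    if (!all(vals %in% object@labelTable$value))
      return("every nonzero label value must appear in labelTable")
    TRUE
  })

#' ConnectivityMapSet: one subject's thalamic seed-correlation maps
#'
#' A 4D stack holding, for every thalamic voxel, the Fisher-z whole-brain
#' correlation map of that voxel's time series.
#'
#' @slot subject subject identifier.
#' @slot maps [Volume4D] with `frameMeaning = "stacked_maps"`.
#' @slot thalVoxels integer matrix (n x 3) of 1-based thalamic voxel indices,
#'   row i corresponding to frame i of `maps`, in ascending column-major
#'   (linear index) order.
#' @export
setClass("ConnectivityMapSet",
  representation(subject = "character", maps = "Volume4D",
                 thalVoxels = "matrix"),
  validity = function(object) {
    if (dim(object@maps@data)[4] != nrow(object@thalVoxels))
      return("frame count must equal the number of thalamic voxels")
    if (ncol(object@thalVoxels) != 3L)
      return("thalVoxels must have 3 columns")
    TRUE
  })

#' GroupStack: concatenated seed-map sets of all subjects
#'
#' @slot maps [Volume4D] stack, frames ordered subject-major.
#' @slot subjects character vector of subject ids in concatenation order.
#' @slot boundaries integer matrix (n_subjects x 2) of first/last frame
#'   per subject.
#' @slot thalVoxels the shared thalamic voxel ordering.
#' @export
setClass("GroupStack",
  representation(maps = "Volume4D", subjects = "character",
                 boundaries = "matrix", thalVoxels = "matrix"),
  validity = function(object) {
    nf <- dim(object@maps@data)[4]
    if (nf != nrow(object@thalVoxels) * length(object@subjects))
      return("frame count must be n_thalamic_voxels * n_subjects")
    if (nrow(object@boundaries) != length(object@subjects))
      return("one boundary row per subject required")
    TRUE
  })

#' ICADecomposition: spatial ICA of a group seed-map stack
#'
#' @slot maps 4D array (x, y, z, component) of z-scored spatial maps.
#' @slot mixing numeric matrix (frames x components).
#' @slot mask [BrainMask] the decomposition was computed on.
#' @slot varianceRetained fraction of stack variance kept by the principal
#'   component reduction.
#' @slot convergence list with `iterations`, `tolerance`, `restarts`.
#' @slot seed random seed used.
#' @export
setClass("ICADecomposition",
  representation(maps = "array", mixing = "matrix", mask = "BrainMask",
                 varianceRetained = "numeric", convergence = "list",
                 seed = "numeric"),
  validity = function(object) {
    if (length(dim(object@maps)) != 4L) return("maps must be 4D")
    if (dim(object@maps)[4] != ncol(object@mixing))
      return("number of maps must match mixing columns")
    TRUE
  })

#' SubdivisionMaps: per-subject dual-regression beta maps
#'
#' Stage-2 dual-regression betas, one whole-brain map per component; the
#' thalamus-restricted stack is the subject's set of functional thalamic
#' subdivisions.
#'
#' @slot subject subject identifier.
#' @slot betas [Volume4D] stack (one frame per component) over the brain.
#' @slot thalMask [BrainMask] delimiting the thalamic subdivisions.
#' @export
setClass("SubdivisionMaps",
  representation(subject = "character", betas = "Volume4D",
                 thalMask = "BrainMask"),
  validity = function(object) {
    if (!all(is.finite(object@betas@data)))
      return("beta maps must be finite")
    TRUE
  })

#' GroupDesign: design matrix, contrast and exchangeability scheme
#'
#' @slot X design matrix (subjects x regressors), full column rank.
#' @slot contrast numeric contrast vector, one weight per regressor.
#' @slot scheme `"label_permutation"` or `"sign_flip"`.
#' @export
setClass("GroupDesign",
  representation(X = "matrix", contrast = "numeric", scheme = "character"),
  validity = function(object) {
    if (length(object@contrast) != ncol(object@X))
      return("contrast length must equal the number of regressors")
    if (qr(object@X)$rank < ncol(object@X))
      return("design matrix must have full column rank")
    if (!object@scheme %in% c("label_permutation", "sign_flip"))
      return("scheme must be 'label_permutation' or 'sign_flip'")
    if (all(object@contrast == 0)) return("contrast must be nonzero")
    TRUE
  })

#' StatMap: a 3D map of t statistics
#'
#' @slot stat 3D numeric array (0 outside the mask).
#' @slot df residual degrees of freedom.
#' @slot mask [BrainMask] of valid voxels.
#' @export
setClass("StatMap",
  representation(stat = "array", df = "numeric", mask = "BrainMask"),
  validity = function(object) {
    if (length(dim(object@stat)) != 3L) return("stat must be 3D")
    if (any(!is.finite(object@stat[object@mask@data])))
      return("statistics must be finite inside the mask")
    TRUE
  })

#' PermutationResult: output of nonparametric permutation inference
#'
#' @slot observed [StatMap] of the observed t statistics.
#' @slot enhanced 3D array of the enhanced observed statistic (TFCE value,
#'   cluster size, or |t| depending on the enhancement).
#' @slot pMap 3D array of family-wise-error corrected p-values (NA outside
#'   the mask).
#' @slot clusterTable data.frame of significant clusters (label, size, peak
#'   voxel, peak t, corrected p), sorted by corrected p.
#' @slot nullMax numeric vector: permutation distribution of the maximum
#'   enhanced statistic.
#' @slot nPerm number of permutations (actual; may be exhaustive).
#' @slot seed random seed.
#' @slot enhancement `"tfce"`, `"cluster_extent"` or `"voxel"`.
#' @slot scheme exchangeability scheme used.
#' @export
setClass("PermutationResult",
  representation(observed = "StatMap", enhanced = "array", pMap = "array",
                 clusterTable = "data.frame", nullMax = "numeric",
                 nPerm = "numeric", seed = "numeric",
                 enhancement = "character", scheme = "character"),
  validity = function(object) {
    p <- object@pMap[object@observed@mask@data]
    p <- p[is.finite(p)]
    if (length(p) && (min(p) < 1 / (object@nPerm + 1) - 1e-12 ||
                      max(p) > 1 + 1e-12))
      return("corrected p must lie in [1/(nPerm+1), 1]")
    TRUE
  })

#' SeedDefinition: a thalamic seed derived from subdivision maps
#'
#' @slot component index of the network component the seed belongs to.
#' @slot mask [BrainMask] of the seed voxels (subset of the thalamus).
#' @slot provenance list recording how the seed was obtained (test,
#'   enhancement, threshold, permutations, seed).
#' @export
setClass("SeedDefinition",
  representation(component = "integer", mask = "BrainMask",
                 provenance = "list"))

#' GroundTruth: parameters of a planted thalamocortical cohort
#'
#' @slot dims grid dimensions.
#' @slot voxelSize voxel size (mm).
#' @slot affine voxel-to-world transform.
#' @slot thalamus [BrainMask] central ellipsoidal thalamus.
#' @slot brain [BrainMask] whole-brain ellipsoid.
#' @slot networkMaps 4D array (x, y, z, K): nonnegative cortical network maps.
#' @slot thalWeights 4D array (x, y, z, K): thalamic weight maps (support
#'   inside the thalamus).
#' @slot arCoef AR(1) coefficient(s) of the network time courses.
#' @slot groupEffect data.frame (`component`, `factor`): multiplicative
#'   connectivity factor applied to patients on the listed components.
#' @slot noiseSd standard deviation of the additive white noise.
#' @slot nTimepoints,trS frames and repetition time (s).
#' @slot seed seed the ground truth was generated with.
#' @export
setClass("GroundTruth",
  representation(dims = "integer", voxelSize = "numeric", affine = "matrix",
                 thalamus = "BrainMask", brain = "BrainMask",
                 networkMaps = "array", thalWeights = "array",
                 arCoef = "numeric", groupEffect = "data.frame",
                 noiseSd = "numeric", nTimepoints = "integer",
                 trS = "numeric", seed = "numeric"),
  validity = function(object) {
    K <- dim(object@networkMaps)[4]
    if (K < 2L) return("at least 2 network components are required")
    if (dim(object@thalWeights)[4] != K)
      return("one thalamic weight map per network is required")
    for (k in seq_len(K)) {
      if (max(object@networkMaps[, , , k]) <= 0)
        return("every network map needs at least one suprathreshold voxel")
      if (max(object@thalWeights[, , , k]) <= 0)
        return("every thalamic weight map must be nonzero")
    }
    if (nrow(object@groupEffect) &&
        (any(object@groupEffect$factor <= 0) ||
         any(!object@groupEffect$component %in% seq_len(K))))
      return("group effect factors must be > 0 on valid components")
    TRUE
  })

#' CohortSpec: sampling plan for a synthetic two-group cohort
#'
#' @slot nPerGroup subjects per group (>= 3 for any inference).
#' @slot ageMean,ageSd length-2 (control, patient) age distribution (years).
#' @slot pFemale length-2 probability of female sex per group.
#' @slot seed master seed; per-subject seeds are drawn from it and recorded
#'   in the cohort manifest.
#' @export
setClass("CohortSpec",
  representation(nPerGroup = "integer", ageMean = "numeric",
                 ageSd = "numeric", pFemale = "numeric", seed = "numeric"),
  validity = function(object) {
    if (object@nPerGroup < 3L)
      return("nPerGroup must be >= 3 for group inference")
    if (length(object@ageMean) != 2L || length(object@ageSd) != 2L ||
        length(object@pFemale) != 2L)
      return("ageMean, ageSd and pFemale must have one entry per group")
    if (any(object@pFemale < 0 | object@pFemale > 1))
      return("pFemale must be probabilities")
    TRUE
  })
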