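# Secondary analysis: thalamic seeds from subdivision maps, seed-to-brain
# connectivity per subject, group comparison.

#' Extract a thalamic seed for one component
#'
#' Voxelwise one-sample t test of the component's thalamic beta maps across
#' subjects (all subjects pooled), sign-flip permutation null, TFCE
#' enhancement; the seed is the set of voxels with corrected p below
#' `alpha`. An empty seed is an error suggesting threshold relaxation.
#'
#' @param subdivisions list of [SubdivisionMaps] (one per subject).
#' @param component component index.
#' @param nPerm permutations (sign flips; exhaustive when 2^n <= nPerm).
#' @param seed random seed.
#' @param alpha corrected significance threshold (default 0.05).
#' @return a [SeedDefinition].
#' @export
extractSeed <- function(subdivisions, component, nPerm = 1000L, seed = 1L,
                        alpha = 0.05) {
  if (length(subdivisions) < 5L)
    stop("seed extraction needs at least 5 subjects")
  thal <- subdivisions[[1]]@thalMask
  Y <- do.call(rbind, lapply(subdivisions, function(s)
    thalamicBetas(s)[component, ]))
  des <- oneSampleDesign(nrow(Y))
  res <- permutationTest(Y, des, thal, enhancement = "tfce", nPerm = nPerm,
                         seed = seed, alternative = "greater", alpha = alpha)
  sig <- !is.na(res@pMap) & res@pMap <= alpha
  if (!any(sig))
    stop(sprintf(
      "component %d: no thalamic voxel survives corrected p <= %g; consider relaxing the threshold",
      component, alpha))
  new("SeedDefinition", component = as.integer(component),
      mask = new("BrainMask", data = sig, voxelSize = voxelSize(thal),
                 affine = affineMatrix(thal)),
      provenance = list(test = "one-sample t (sign-flip permutation)",
                        enhancement = "tfce", alpha = alpha,
                        nPerm = nPerm, seed = seed,
                        nSubjects = length(subdivisions)))
}

#' Seed-to-whole-brain connectivity map of one subject
#'
#' The mean time series over the seed voxels is entered into a per-voxel
#' GLM [intercept | seed mean]; the seed-regressor beta map is returned
#' (the GLM-native effect carried to the group level).
#'
#' @param bold preprocessed time-series [Volume4D].
#' @param seedDef a [SeedDefinition].
#' @param brain [BrainMask].
#' @return single-frame [Volume4D] of betas (0 outside `brain`).
#' @export
seedConnectivityMap <- function(bold, seedDef, brain) {
  stopIfGridMismatch(bold, brain, "bold and brain mask")
  stopIfGridMismatch(bold, seedDef@mask, "bold and seed mask")
  Y <- maskMatrix(bold, brain)
  seedInBrain <- match(which(seedDef@mask@data), which(brain@data))
  if (anyNA(seedInBrain)) stop("seed mask must lie inside the brain mask")
  s <- rowMeans(Y[, seedInBrain, drop = FALSE])
  if (stats::sd(s) == 0) stop("seed mean series has zero variance")
  X <- cbind(1, seed = s)
  beta <- qr.coef(qr(X), Y)[2, ]
  new("Volume4D",
      data = array(unmaskMap(beta, brain), dim = c(dim(brain@data), 1L)),
      voxelSize = voxelSize(bold), affine = affineMatrix(bold),
      frameMeaning = "stacked_maps")
}

#' Group comparison of seed connectivity maps
#'
#' Stacks the subjects' seed beta maps and delegates to [permutationTest()]
#' with TFCE enhancement.
#'
#' @param maps list of single-frame [Volume4D] beta maps (subject order
#'   must match the design rows) or a subjects x voxels matrix.
#' @param design a [GroupDesign].
#' @param brain [BrainMask].
#' @inheritParams permutationTest
#' @return a [PermutationResult].
#' @export
compareSeedMaps <- function(maps, design, brain, nPerm = 1000L, seed = 1L,
                            alternative = "two.sided", alpha = 0.05) {
  Y <- if (is.matrix(maps)) maps
       else do.call(rbind, lapply(maps, function(m) maskMatrix(m, brain)))
  permutationTest(Y, design, brain, enhancement = "tfce", nPerm = nPerm,
                  seed = seed, alternative = alternative, alpha = alpha)
}
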