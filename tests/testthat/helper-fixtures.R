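# Shared fixture builders. Everything is generated in code; no binary files.

idAffine <- function(voxelSize = c(3, 3, 3)) {
  rbind(cbind(diag(voxelSize), 0), c(0, 0, 0, 1))
}

makeVol <- function(data, voxelSize = c(3, 3, 3),
                    frameMeaning = "time", affine = idAffine(voxelSize)) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  new("Volume4D", data = data, voxelSize = voxelSize, affine = affine,
      frameMeaning = frameMeaning)
}

fullMask <- function(dims, voxelSize = c(3, 3, 3),
                     affine = idAffine(voxelSize)) {
  new("BrainMask", data = array(TRUE, dims), voxelSize = voxelSize,
      affine = affine)
}

# small standard ground truth used across modules
tinyGroundTruth <- function(noiseSd = 1, nTimepoints = 100, K = 3,
                            dims = c(14, 16, 14), seed = 2, ...) {
  makeGroundTruth(dims = dims, K = K, nTimepoints = nTimepoints,
                  noiseSd = noiseSd, seed = seed, ...)
}

# an ICADecomposition built directly from ground-truth amplitude maps, for
# tests that need perfect spatial regressors
gtDecomposition <- function(gt) {
  K <- nComponents(gt)
  amps <- array(0, c(dim(gt@brain@data), K))
  for (k in seq_len(K)) {
    a <- gt@networkMaps[, , , k]
    a[gt@thalamus@data] <- gt@thalWeights[, , , k][gt@thalamus@data]
    amps[, , , k] <- a
  }
  new("ICADecomposition", maps = amps, mixing = matrix(0, 1, K),
      mask = gt@brain, varianceRetained = 1,
      convergence = list(iterations = 0L, tolerance = 0, restarts = 0L),
      seed = 0)
}

# planted thalamic weight vectors over the thalamus mask
gtThalWeightMatrix <- function(gt) {
  vapply(seq_len(nComponents(gt)),
         function(k) gt@thalWeights[, , , k][gt@thalamus@data],
         numeric(nVoxels(gt@thalamus)))
}

# sparse super-Gaussian spatial sources mixed into a stacked-map volume
plantedSourceStack <- function(dims = c(12, 12, 12), K = 3, nFrames = 40,
                               sparsity = 60, noiseSd = 0, seed = 42) {
  set.seed(seed)
  nv <- prod(dims)
  S <- matrix(0, K, nv)
  for (k in seq_len(K)) S[k, sample(nv, sparsity)] <- stats::rexp(sparsity)
  A <- matrix(stats::rnorm(nFrames * K), nFrames, K)
  X <- A %*% S
  if (noiseSd > 0)
    X <- X + matrix(stats::rnorm(length(X), sd = noiseSd), nrow(X))
  list(vol = makeVol(array(t(X), c(dims, nFrames)),
                     frameMeaning = "stacked_maps"),
       mask = fullMask(dims), sources = S,
       refs = array(t(S), c(dims, K)), mixing = A)
}
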