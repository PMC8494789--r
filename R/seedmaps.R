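# Thalamic-voxel seed connectivity maps and the concatenated group stack
# that is the input to spatial ICA.

#' Whole-brain connectivity map of every thalamic voxel
#'
#' For each voxel of the thalamus mask, computes the Pearson correlation of
#' its time series with every brain voxel's series and Fisher-transforms the
#' result to z (`atanh`). Correlations are clipped to +/-(1 - 1e-7) before
#' the transform so the seed's self-correlation stays finite. Zero-variance
#' series yield r = 0 with a warning rather than an error, keeping the
#' pipeline total on masked edge voxels. Thalamic voxels are ordered by
#' ascending column-major linear index, which fixes the frame order of the
#' output deterministically.
#'
#' @param vol preprocessed time-series [Volume4D].
#' @param thal thalamus [BrainMask] (subset of `brain`).
#' @param brain whole-brain [BrainMask] on the same grid.
#' @param subject subject identifier stored with the map set.
#' @return a [ConnectivityMapSet] (voxels outside `brain` are 0).
#' @export
thalamicSeedMaps <- function(vol, thal, brain, subject = "subject") {
  stopIfGridMismatch(vol, brain, "volume and brain mask")
  stopIfGridMismatch(vol, thal, "volume and thalamus mask")
  if (vol@frameMeaning != "time")
    stop("thalamicSeedMaps requires a time-series volume")
  Y <- maskMatrix(vol, brain)            # time x brain voxels
  nt <- nrow(Y)
  if (nt < 3L) stop("need at least 3 timepoints to correlate")
  sds <- apply(Y, 2, stats::sd)
  nzero <- sum(sds == 0)
  if (nzero > 0L)
    warning(sprintf("%d zero-variance series; their correlations are set to 0",
                    nzero))
  Z <- sweep(Y, 2, colMeans(Y))
  scl <- ifelse(sds > 0, 1 / (sds * sqrt(nt - 1)), 0)
  Z <- sweep(Z, 2, scl, `*`)
  thalIdxInBrain <- match(which(thal@data), which(brain@data))
  if (anyNA(thalIdxInBrain))
    stop("thalamus mask must be a subset of the brain mask")
  r <- crossprod(Z[, thalIdxInBrain, drop = FALSE], Z)  # thal x brain
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  d3 <- dim(vol@data)[1:3]
  arr <- array(0, dim = c(d3, nrow(z)))
  bIdx <- which(brain@data)
  n3 <- prod(d3)
  for (i in seq_len(nrow(z))) arr[bIdx + (i - 1L) * n3] <- z[i, ]
  new("ConnectivityMapSet", subject = subject,
      maps = new("Volume4D", data = arr, voxelSize = voxelSize(vol),
                 affine = affineMatrix(vol), frameMeaning = "stacked_maps"),
      thalVoxels = maskCoords(thal))
}

#' Concatenate subjects' seed-map sets into one group stack
#'
#' Frames are ordered subject-major: all maps of subject 1, then subject 2,
#' and so on; subject boundaries are recorded. All map sets must share the
#' grid and the thalamic voxel ordering.
#'
#' @param mapsets list of [ConnectivityMapSet] objects.
#' @return a [GroupStack].
#' @export
concatenateGroup <- function(mapsets) {
  if (length(mapsets) < 1L) stop("no map sets supplied")
  ref <- mapsets[[1]]
  for (m in mapsets[-1]) {
    stopIfGridMismatch(m@maps, ref@maps, "map sets")
    if (!identical(dim(m@thalVoxels), dim(ref@thalVoxels)) ||
        any(m@thalVoxels != ref@thalVoxels))
      stop("map sets disagree on the thalamic voxel ordering")
  }
  nmap <- nrow(ref@thalVoxels)
  d3 <- dim(ref@maps@data)[1:3]
  n <- length(mapsets)
  arr <- array(0, dim = c(d3, nmap * n))
  bnd <- matrix(0L, n, 2, dimnames = list(NULL, c("first", "last")))
  for (i in seq_len(n)) {
    a <- (i - 1L) * nmap + 1L
    arr[, , , a:(a + nmap - 1L)] <- mapsets[[i]]@maps@data
    bnd[i, ] <- c(a, a + nmap - 1L)
  }
  new("GroupStack",
      maps = new("Volume4D", data = arr, voxelSize = voxelSize(ref@maps),
                 affine = affineMatrix(ref@maps),
                 frameMeaning = "stacked_maps"),
      subjects = vapply(mapsets, function(m) m@subject, character(1)),
      boundaries = bnd, thalVoxels = ref@thalVoxels)
}
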