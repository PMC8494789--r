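# Per-subject preprocessing: frame trimming, highpass temporal filtering,
# nuisance (confound) regression. The pipeline order is fixed:
# trim -> highpass -> confound regression. No spatial smoothing stage exists.

#' Discard initial frames of a time series volume
#'
#' Removes the first `k` frames (dummy echo-planar volumes acquired before
#' steady-state magnetization).
#'
#' @param vol a [Volume4D] with `frameMeaning = "time"`.
#' @param k number of leading frames to drop (`0 <= k < nFrames`).
#' @return the trimmed [Volume4D].
#' @export
trimInitialFrames <- function(vol, k) {
  k <- as.integer(k)
  if (k < 0L) stop("k must be nonnegative")
  nf <- nFrames(vol)
  if (k >= nf)
    stop(sprintf("cannot drop %d frames from a %d-frame series", k, nf))
  if (k == 0L) return(vol)
  new("Volume4D", data = vol@data[, , , -seq_len(k), drop = FALSE],
      voxelSize = voxelSize(vol), affine = affineMatrix(vol),
      frameMeaning = vol@frameMeaning)
}

#' Highpass temporal filter
#'
#' Removes fluctuations slower than `cutoffHz` from every voxel's time
#' series. Implemented as a frequency-domain filter with a raised-cosine
#' transition band of width `rolloffHz` centred on the cutoff; the voxel
#' mean (DC) is restored after filtering, so a constant series passes
#' through unchanged.
#'
#' @param vol a [Volume4D] with `frameMeaning = "time"`.
#' @param cutoffHz highpass cutoff in Hz (e.g. 0.01); must be below Nyquist.
#' @param trS repetition time in seconds.
#' @param rolloffHz transition band width in Hz (default 0.002).
#' @return the filtered [Volume4D].
#' @export
highpassFilter <- function(vol, cutoffHz, trS, rolloffHz = 0.002) {
  if (vol@frameMeaning != "time")
    stop("highpassFilter requires a time-series volume")
  if (cutoffHz <= 0 || trS <= 0) stop("cutoffHz and trS must be positive")
  nyquist <- 1 / (2 * trS)
  if (cutoffHz >= nyquist)
    stop(sprintf("cutoff %.4g Hz is not below Nyquist %.4g Hz",
                 cutoffHz, nyquist))
  d <- dim(vol@data)
  nt <- d[4]
  y <- t(matrix(vol@data, prod(d[1:3]), nt))  # time x voxels
  mu <- colMeans(y)
  y <- sweep(y, 2, mu)
  bin <- seq_len(nt) - 1L
  f <- pmin(bin, nt - bin) / (nt * trS)       # two-sided frequency axis
  lo <- cutoffHz - rolloffHz / 2
  hi <- cutoffHz + rolloffHz / 2
  gain <- ifelse(f <= lo, 0,
                 ifelse(f >= hi, 1, 0.5 * (1 - cos(pi * (f - lo) / (hi - lo)))))
  gain[1] <- 0  # DC removed here, mean restored below
  yf <- Re(stats::mvfft(stats::mvfft(y) * gain, inverse = TRUE)) / nt
  yf <- sweep(yf, 2, mu, `+`)
  new("Volume4D", data = array(t(yf), dim = d),
      voxelSize = voxelSize(vol), affine = affineMatrix(vol),
      frameMeaning = "time")
}

#' Read a confound table
#'
#' Whitespace- or tab-delimited text with a header row; expected columns are
#' six motion parameters plus mean white-matter and CSF signals, but any set
#' of numeric columns is accepted.
#'
#' @param path text file path.
#' @return data.frame of confound series.
#' @export
readConfoundTable <- function(path) {
  if (!file.exists(path)) stop(sprintf("confound file not found: %s", path))
  conf <- utils::read.table(path, header = TRUE)
  if (!all(vapply(conf, is.numeric, logical(1))))
    stop("confound columns must be numeric")
  if (anyNA(conf)) stop("confound table contains missing values")
  conf
}

#' Regress confound series out of every voxel
#'
#' Replaces each voxel's series by the residuals of an ordinary
#' least-squares fit on an intercept plus the confound columns. Residuals
#' are orthogonal to every confound column; applying the operation twice
#' with the same table changes nothing (projection idempotence).
#'
#' @param vol a [Volume4D] with `frameMeaning = "time"`.
#' @param conf data.frame or matrix of confound series (rows = timepoints).
#' @return the residual [Volume4D].
#' @export
regressConfounds <- function(vol, conf) {
  conf <- as.matrix(conf)
  d <- dim(vol@data)
  if (nrow(conf) != d[4])
    stop(sprintf("confound rows (%d) must equal frame count (%d)",
                 nrow(conf), d[4]))
  keep <- apply(conf, 2, function(x) stats::sd(x) > 0)
  X <- cbind(intercept = 1, conf[, keep, drop = FALSE])
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1L, ncol(X))]]
    stop(sprintf("confound matrix is rank deficient; collinear column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  y <- t(matrix(vol@data, prod(d[1:3]), d[4]))
  res <- qr.resid(qx, y)
  new("Volume4D", data = array(t(res), dim = d),
      voxelSize = voxelSize(vol), affine = affineMatrix(vol),
      frameMeaning = "time")
}

#' Standard per-subject preprocessing
#'
#' Applies the fixed stage order: trim initial frames, highpass filter,
#' confound regression.
#'
#' @param vol a time-series [Volume4D].
#' @param conf confound table (or NULL to skip).
#' @param trim frames to discard (default 4).
#' @param highpassHz highpass cutoff in Hz (default 0.01; 0 disables).
#' @param trS repetition time in seconds.
#' @return preprocessed [Volume4D].
#' @export
preprocessSubject <- function(vol, conf = NULL, trim = 4, highpassHz = 0.01,
                              trS = 3.5) {
  out <- trimInitialFrames(vol, trim)
  if (highpassHz > 0) out <- highpassFilter(out, highpassHz, trS)
  if (!is.null(conf)) {
    conf <- as.matrix(conf)
    if (trim > 0) conf <- conf[-seq_len(trim), , drop = FALSE]
    out <- regressConfounds(out, conf)
  }
  out
}
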