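# Spatial ICA of the group seed-map stack: the "network ROI" decomposition.

#' Spatial independent component analysis of a group stack
#'
#' Frames are treated as observations and brain voxels as variables. Each
#' frame is optionally scaled to unit standard deviation within the brain
#' (equalizing subjects' global correlation levels), row-centred, reduced to
#' `nComponents` dimensions by principal components, and rotated to maximal
#' spatial independence with a symmetric fixed-point iteration under a tanh
#' contrast. Component maps are converted to z-scores by dividing out a
#' robust (MAD-based) estimate of the residual noise spread, the sign is
#' fixed so each map's largest-magnitude voxel is positive, and components
#' are ordered by explained mixing variance. The fit is deterministic given
#' `seed`; on non-convergence the rotation restarts from up to
#' `nRestarts` fresh initializations before failing.
#'
#' @param stack a [GroupStack] (or any stacked-map [Volume4D]).
#' @param brain [BrainMask] defining the analysis voxels.
#' @param nComponents number of components (default 20).
#' @param seed random seed for the rotation start.
#' @param tol convergence tolerance of the fixed-point iteration (1e-6).
#' @param maxIter maximum iterations per start (1000).
#' @param nRestarts maximum fresh restarts on non-convergence (5).
#' @param varNorm scale each frame to unit SD within the brain first.
#' @return an [ICADecomposition].
#' @export
fitSpatialICA <- function(stack, brain, nComponents = 20L, seed = 1L,
                          tol = 1e-6, maxIter = 1000L, nRestarts = 5L,
                          varNorm = TRUE) {
  vol <- if (is(stack, "GroupStack")) stack@maps else stack
  stopIfGridMismatch(vol, brain, "stack and brain mask")
  X <- maskMatrix(vol, brain)            # frames x voxels
  nf <- nrow(X); nv <- ncol(X)
  K <- as.integer(nComponents)
  if (K >= min(nf, nv))
    stop(sprintf("nComponents (%d) must be below min(frames, voxels) = %d",
                 K, min(nf, nv)))
  if (varNorm) {
    s <- apply(X, 1, stats::sd)
    s[s == 0] <- 1
    X <- X / s
  }
  X <- X - rowMeans(X)
  sv <- svd(X, nu = 0, nv = K)
  # rows of t(v) are exactly zero-mean (rows of X are centred) and unit
  # norm; scaling by sqrt(nv) whitens them to unit variance
  Z <- t(sv$v) * sqrt(nv)
  varRetained <- sum(sv$d[seq_len(K)]^2) / sum(sv$d^2)

  W <- NULL; iters <- NA_integer_; restarts <- 0L
  for (attempt in 0:nRestarts) {
    set.seed(seed + attempt)
    W0 <- matrix(stats::rnorm(K * K), K, K)
    W0 <- symDecorrelate(W0)
    res <- fastIcaSymm(Z, W0, tol, maxIter)
    if (res$converged) {
      W <- res$W; iters <- res$iterations; restarts <- attempt
      break
    }
  }
  if (is.null(W))
    stop(sprintf(
      "spatial ICA did not converge within %d iterations (tol %g) after %d restarts",
      maxIter, tol, nRestarts + 1L))
  S <- W %*% Z                           # K x voxels raw maps
  # robust z-scoring and sign convention
  signs <- numeric(K)
  for (k in seq_len(K)) {
    s <- S[k, ]
    # robust residual-noise spread; a map that is mostly exact zeros
    # (degenerate MAD) falls back to the plain SD
    scl <- stats::mad(s)
    if (scl < 1e-12) scl <- stats::sd(s)
    if (scl < 1e-12) scl <- 1
    z <- (s - stats::median(s)) / scl
    sgn <- if (z[which.max(abs(z))] < 0) -1 else 1
    S[k, ] <- sgn * z
    signs[k] <- sgn
  }
  # least-squares mixing weights of the z-scored maps
  A <- t(solve(tcrossprod(S), S %*% t(X)))
  ord <- order(colSums(A^2), decreasing = TRUE)
  S <- S[ord, , drop = FALSE]
  A <- A[, ord, drop = FALSE]
  new("ICADecomposition",
      maps = unmaskStack(S, brain),
      mixing = A, mask = brain,
      varianceRetained = varRetained,
      convergence = list(iterations = iters, tolerance = tol,
                         restarts = restarts, signs = signs[ord],
                         order = ord),
      seed = as.numeric(seed))
}

# Symmetric decorrelation: W <- (W W')^{-1/2} W.
symDecorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-12)), nrow(W)) %*%
    t(e$vectors) %*% W
}

# Fixed-point symmetric FastICA with tanh contrast on whitened data Z (K x V).
fastIcaSymm <- function(Z, W, tol, maxIter) {
  nv <- ncol(Z)
  for (it in seq_len(maxIter)) {
    U <- W %*% Z
    G <- tanh(U)
    W1 <- G %*% t(Z) / nv - diag(rowMeans(1 - G^2), nrow(W)) %*% W
    W1 <- symDecorrelate(W1)
    conv <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (conv < tol)
      return(list(W = W, converged = TRUE, iterations = it))
  }
  list(W = W, converged = FALSE, iterations = maxIter)
}

#' Match components to reference maps
#'
#' One-to-one assignment of each reference map to a distinct component,
#' maximizing the total absolute spatial correlation over the analysis
#' mask (exact assignment, not greedy). Signed correlations are reported so
#' anticorrelated (sign-flipped) matches are visible.
#'
#' @param dec an [ICADecomposition] (or a 4D array of maps plus `mask`).
#' @param referenceMaps 4D array (x, y, z, R) or list of 3D arrays, R <= the
#'   number of components.
#' @param mask optional [BrainMask]; defaults to the decomposition's mask.
#' @return data.frame (`reference`, `component`, `r`) in reference order.
#' @export
matchComponents <- function(dec, referenceMaps, mask = NULL) {
  if (is(dec, "ICADecomposition")) {
    maps <- dec@maps
    if (is.null(mask)) mask <- dec@mask
  } else {
    maps <- dec
    if (is.null(mask)) stop("a mask is required when passing a raw array")
  }
  if (is.list(referenceMaps))
    referenceMaps <- array(unlist(referenceMaps),
                           dim = c(dim(referenceMaps[[1]]),
                                   length(referenceMaps)))
  K <- dim(maps)[4]; R <- dim(referenceMaps)[4]
  if (R > K) stop("fewer components than reference maps")
  m <- mask@data
  rmat <- matrix(0, K, R)
  for (i in seq_len(K))
    for (j in seq_len(R)) {
      a <- maps[, , , i][m]; b <- referenceMaps[, , , j][m]
      rmat[i, j] <- if (stats::sd(a) == 0 || stats::sd(b) == 0) 0
                    else stats::cor(a, b)
    }
  comp <- assignComponents(abs(rmat))
  data.frame(reference = seq_len(R), component = comp,
             r = rmat[cbind(comp, seq_len(R))])
}
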