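# Nonparametric group inference on voxel maps: GLM contrasts, permutation /
# sign-flip null distributions with Freedman-Lane residualization of
# nuisance covariates, TFCE and cluster-extent correction via the
# max-statistic.

#' Build a group design
#'
#' Constructs the design matrix [group indicator | covariates | intercept],
#' the contrast and the exchangeability scheme for a two-sample comparison
#' with nuisance covariates. The group indicator is 1 for the second factor
#' level; covariates are centred. The default contrast (+1 on the group
#' column) tests level2 > level1; negate it for the opposite direction.
#'
#' @param group factor or character vector with exactly two levels.
#' @param covariates data.frame or matrix of nuisance covariates (e.g. age,
#'   sex); character/factor columns are converted to indicators.
#' @param contrast optional full contrast vector (group, covariates...,
#'   intercept); default c(1, 0, ..., 0).
#' @return a [GroupDesign] with `scheme = "label_permutation"`.
#' @export
groupDesign <- function(group, covariates = NULL, contrast = NULL) {
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly two levels")
  g <- as.numeric(group == levels(group)[2])
  X <- cbind(group = g)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    for (nm in names(covariates)) {
      v <- covariates[[nm]]
      if (is.character(v) || is.factor(v)) v <- as.numeric(as.factor(v)) - 1
      X <- cbind(X, scale(v, scale = FALSE))
      colnames(X)[ncol(X)] <- nm
    }
  }
  X <- cbind(X, intercept = 1)
  if (is.null(contrast)) contrast <- c(1, rep(0, ncol(X) - 1L))
  new("GroupDesign", X = X, contrast = as.numeric(contrast),
      scheme = "label_permutation")
}

#' One-sample design for sign-flip inference
#'
#' Intercept-only design (plus optional centred covariates), contrast on
#' the intercept, exchangeability by sign flipping of residuals.
#'
#' @param n number of subjects.
#' @param covariates optional nuisance covariates.
#' @return a [GroupDesign] with `scheme = "sign_flip"`.
#' @export
oneSampleDesign <- function(n, covariates = NULL) {
  X <- cbind(intercept = rep(1, n))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    for (nm in names(covariates)) {
      v <- covariates[[nm]]
      if (is.character(v) || is.factor(v)) v <- as.numeric(as.factor(v)) - 1
      X <- cbind(X, scale(v, scale = FALSE))
      colnames(X)[ncol(X)] <- nm
    }
  }
  new("GroupDesign", X = X,
      contrast = c(1, rep(0, ncol(X) - 1L)), scheme = "sign_flip")
}

# Fast voxelwise t statistics for a fixed design; Y is n x voxels.
# Returns list(t, df). 0/0 voxels (no residual variance, no effect) give 0.
tStatistics <- function(Y, X, contrast) {
  n <- nrow(X)
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("design matrix is rank deficient")
  df <- n - qx$rank
  if (df < 1L) stop("no residual degrees of freedom")
  B <- qr.coef(qx, Y)
  res <- qr.resid(qx, Y)
  sigma2 <- .colSums(res * res, n, ncol(Y)) / df
  cvar <- drop(t(contrast) %*% solve(crossprod(X), contrast))
  num <- drop(t(contrast) %*% B)
  se <- sqrt(cvar * sigma2)
  # degenerate voxels: zero residual variance with zero effect gives t = 0;
  # a saturated effect is capped at a large finite value
  t <- ifelse(se > 0, num / se, ifelse(num == 0, 0, sign(num) * 1e6))
  list(t = t, df = df)
}

#' Voxelwise GLM t-statistic map
#'
#' Ordinary least squares per voxel; t = c'beta / SE(c'beta) with
#' df = n - rank(design).
#'
#' @param Y numeric matrix (subjects x voxels), e.g. stacked subject maps
#'   restricted to `mask`.
#' @param design a [GroupDesign].
#' @param mask [BrainMask] mapping the columns of `Y` back to the grid
#'   (ascending column-major order).
#' @return a [StatMap].
#' @export
glmTMap <- function(Y, design, mask) {
  if (nrow(Y) != nrow(design@X))
    stop(sprintf("data rows (%d) must equal design rows (%d)",
                 nrow(Y), nrow(design@X)))
  if (ncol(Y) != nVoxels(mask))
    stop("data columns must equal the mask voxel count")
  ts <- tStatistics(Y, design@X, design@contrast)
  new("StatMap", stat = unmaskMap(ts$t, mask), df = ts$df, mask = mask)
}

#' Threshold-free cluster enhancement
#'
#' For each voxel p, integrates extent^E x height^H over suprathreshold
#' clusters: TFCE(p) = sum_h e(h,p)^E h^H dh for h = dh, 2dh, ..., up to the
#' map maximum. The negative tail is enhanced by applying the same to the
#' negated map and subtracting, so the output carries the sign of the input.
#'
#' @param stat a [StatMap] or 3D numeric array.
#' @param E extent exponent (default 0.5).
#' @param H height exponent (default 2).
#' @param dh integration step; default `max|stat|`/100.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return 3D array of signed enhanced values.
#' @export
tfce <- function(stat, E = 0.5, H = 2, dh = NULL, connectivity = 26) {
  arr <- if (is(stat, "StatMap")) stat@stat else stat
  if (E < 0 || H < 0) stop("E and H must be nonnegative")
  if (!connectivity %in% c(6, 18, 26)) stop("connectivity must be 6, 18 or 26")
  hmax <- max(abs(arr))
  if (hmax == 0) return(array(0, dim = dim(arr)))
  if (is.null(dh)) dh <- hmax / 100
  if (dh <= 0) stop("dh must be positive")
  dims <- as.integer(dim(arr))
  pos <- .tfceCpp(pmax(arr, 0), dims, E, H, dh, as.integer(connectivity))
  neg <- .tfceCpp(pmax(-arr, 0), dims, E, H, dh, as.integer(connectivity))
  pos - neg
}

#' Connected components of a logical 3D array
#'
#' @param mask 3D logical array.
#' @param connectivity 6, 18 or 26.
#' @return 3D integer array of component labels (0 = background).
#' @export
labelClusters <- function(mask, connectivity = 26) {
  .labelComponentsCpp(mask, as.integer(dim(mask)), as.integer(connectivity))
}

# Split the design for Freedman-Lane: interest columns carry nonzero
# contrast weight, the rest are nuisance.
flPartition <- function(design) {
  interest <- which(design@contrast != 0)
  nuisance <- setdiff(seq_len(ncol(design@X)), interest)
  list(interest = interest, nuisance = nuisance)
}

#' Permutation inference with max-statistic FWE correction
#'
#' Fits the GLM contrast, enhances the statistic map (TFCE, cluster extent,
#' or plain voxelwise |t|), and builds the null distribution of the maximum
#' enhanced statistic over permutations. Nuisance covariates are handled by
#' the Freedman-Lane scheme: data are residualized against the nuisance
#' regressors, the residuals are permuted (or sign-flipped) and the nuisance
#' fit re-added before refitting the full model. With no covariates this
#' reduces exactly to simple label permutation. Corrected p-values follow
#' the (1 + count)/(nPerm + 1) convention, so p >= 1/(nPerm+1) always.
#' For sign flipping with 2^n <= nPerm the full sign-flip space is
#' enumerated and p-values are exact.
#'
#' @param Y numeric matrix (subjects x voxels in `mask`).
#' @param design a [GroupDesign].
#' @param mask [BrainMask].
#' @param enhancement `"tfce"`, `"cluster_extent"` or `"voxel"`.
#' @param nPerm number of permutations (>= 100; a warning is issued below
#'   1000).
#' @param seed random seed for the permutation draw.
#' @param alternative `"two.sided"` (enhances |t|) or `"greater"` (enhances
#'   the contrast direction only).
#' @param formingT cluster-forming threshold for `"cluster_extent"`
#'   (default 2.3).
#' @param E,H,dh,connectivity TFCE parameters, see [tfce()].
#' @param alpha significance level used to populate the cluster table.
#' @return a [PermutationResult].
#' @export
permutationTest <- function(Y, design, mask,
                            enhancement = c("tfce", "cluster_extent", "voxel"),
                            nPerm = 1000L, seed = 1L,
                            alternative = c("two.sided", "greater"),
                            formingT = 2.3, E = 0.5, H = 2, dh = NULL,
                            connectivity = 26, alpha = 0.05) {
  enhancement <- match.arg(enhancement)
  alternative <- match.arg(alternative)
  nPerm <- as.integer(nPerm)
  if (nPerm < 100L) stop("nPerm must be at least 100")
  if (nPerm < 1000L)
    warning(sprintf("nPerm = %d is low; p-value resolution is %.4g",
                    nPerm, 1 / (nPerm + 1)))
  X <- design@X
  n <- nrow(X)
  if (nrow(Y) != n) stop("data rows must equal design rows")
  part <- flPartition(design)
  if (design@scheme == "sign_flip") {
    Xint <- X[, part$interest, drop = FALSE]
    if (any(apply(Xint, 2, function(v) stats::sd(v) > 0)))
      stop(paste("sign_flip exchangeability requires a constant (intercept)",
                 "interest regressor; use label_permutation for group",
                 "contrasts"))
  }

  obs <- tStatistics(Y, X, design@contrast)
  tObs <- obs$t
  dims <- as.integer(dim(mask@data))

  enhanceFun <- switch(enhancement,
    voxel = function(tvec) {
      v <- if (alternative == "two.sided") abs(tvec) else tvec
      unmaskMap(v, mask)
    },
    tfce = function(tvec) {
      arr <- unmaskMap(tvec, mask)
      v <- if (alternative == "two.sided") abs(arr) else pmax(arr, 0)
      .tfceCpp(v, dims, E, H, dhUse, as.integer(connectivity))
    },
    cluster_extent = function(tvec) {
      arr <- unmaskMap(tvec, mask)
      supra <- if (alternative == "two.sided") abs(arr) >= formingT
               else arr >= formingT
      lab <- .labelComponentsCpp(supra, dims, as.integer(connectivity))
      if (max(lab) == 0L) return(array(0, dim = dims))
      sizes <- tabulate(lab[lab > 0L])
      out <- array(0, dim = dims)
      out[lab > 0L] <- sizes[lab[lab > 0L]]
      out
    })
  # a common TFCE step across observed and permuted maps keeps the
  # enhancement comparable; scale it to the observed map
  dhUse <- if (is.null(dh)) max(abs(tObs)) / 100 else dh
  if (!is.finite(dhUse) || dhUse <= 0) dhUse <- 0.1

  enhObs <- enhanceFun(tObs)

  # Freedman-Lane pieces
  if (length(part$nuisance)) {
    qz <- qr(X[, part$nuisance, drop = FALSE])
    Ez <- qr.resid(qz, Y)
    Fz <- Y - Ez
  } else {
    Ez <- Y
    Fz <- matrix(0, n, ncol(Y))
  }

  exhaustive <- design@scheme == "sign_flip" && 2^n <= nPerm
  if (exhaustive) {
    signsMat <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    nEff <- nrow(signsMat)
  } else {
    nEff <- nPerm
  }
  set.seed(seed)
  nullMax <- numeric(nEff)
  for (j in seq_len(nEff)) {
    if (design@scheme == "sign_flip") {
      s <- if (exhaustive) signsMat[j, ] else sample(c(-1, 1), n, replace = TRUE)
      Yp <- Fz + Ez * s
    } else {
      Yp <- Fz + Ez[sample.int(n), , drop = FALSE]
    }
    tp <- tStatistics(Yp, X, design@contrast)$t
    nullMax[j] <- max(enhanceFun(tp))
  }

  # corrected p: for sampled nulls (1 + count)/(nPerm + 1); exhaustive
  # enumeration (which includes the identity flip) gives exact p.
  countGE <- function(values) {
    s <- sort(nullMax)
    length(nullMax) - findInterval(values, s, left.open = TRUE)
  }
  denom <- if (exhaustive) nEff else nEff + 1L
  addOne <- if (exhaustive) 0L else 1L

  mvals <- enhObs[mask@data]
  pvals <- pmin((addOne + countGE(mvals)) / denom, 1)
  pMap <- unmaskMap(pvals, mask, fill = NA_real_)

  statMap <- new("StatMap", stat = unmaskMap(tObs, mask), df = obs$df,
                 mask = mask)
  ct <- buildClusterTable(enhancement, statMap, enhObs, pMap, mask,
                          formingT, alternative, connectivity, alpha)
  new("PermutationResult", observed = statMap, enhanced = enhObs,
      pMap = pMap, clusterTable = ct, nullMax = nullMax,
      nPerm = as.numeric(nEff), seed = as.numeric(seed),
      enhancement = enhancement, scheme = design@scheme)
}

# Cluster table: connected components of significant voxels (tfce/voxel) or
# of the suprathreshold map (cluster_extent), with peak location and the
# cluster's corrected p; sorted by p then size.
buildClusterTable <- function(enhancement, statMap, enhObs, pMap, mask,
                              formingT, alternative, connectivity, alpha) {
  tArr <- statMap@stat
  if (enhancement == "cluster_extent") {
    supra <- if (alternative == "two.sided") abs(tArr) >= formingT
             else tArr >= formingT
    supra <- supra & mask@data
  } else {
    supra <- !is.na(pMap) & pMap <= alpha
  }
  empty <- data.frame(cluster = integer(0), size = integer(0),
                      peakX = integer(0), peakY = integer(0),
                      peakZ = integer(0), peakT = numeric(0), p = numeric(0))
  if (!any(supra)) return(empty)
  lab <- .labelComponentsCpp(supra, as.integer(dim(tArr)),
                             as.integer(connectivity))
  ncl <- max(lab)
  rows <- lapply(seq_len(ncl), function(cl) {
    idx <- which(lab == cl)
    sz <- length(idx)
    peak <- idx[which.max(abs(tArr[idx]))]
    co <- arrayInd(peak, dim(tArr))
    p <- min(pMap[idx], na.rm = TRUE)
    data.frame(cluster = cl, size = sz, peakX = co[1], peakY = co[2],
               peakZ = co[3], peakT = tArr[peak], p = p)
  })
  ct <- do.call(rbind, rows)
  if (enhancement == "cluster_extent") ct <- ct[ct$p <= alpha, , drop = FALSE]
  ct <- ct[order(ct$p, -ct$size), , drop = FALSE]
  ct$cluster <- seq_len(nrow(ct))
  rownames(ct) <- NULL
  ct
}

#' Cluster-extent corrected group inference
#'
#' Clusters of |t| >= `formingT` are tested against the permutation null of
#' the maximum cluster size.
#'
#' @inheritParams permutationTest
#' @param formingT cluster-forming threshold on t (default 2.3).
#' @return a [PermutationResult].
#' @export
clusterExtentCorrect <- function(Y, design, mask, formingT = 2.3,
                                 nPerm = 1000L, seed = 1L,
                                 alternative = c("two.sided", "greater"),
                                 connectivity = 26, alpha = 0.05) {
  if (formingT <= 0) stop("formingT must be positive")
  permutationTest(Y, design, mask, enhancement = "cluster_extent",
                  nPerm = nPerm, seed = seed,
                  alternative = match.arg(alternative),
                  formingT = formingT, connectivity = connectivity,
                  alpha = alpha)
}

#' Annotate a cluster table with atlas labels
#'
#' Adds the dominant nucleus/region name of each cluster's voxels via
#' [lookupLabels()].
#'
#' @param result a [PermutationResult].
#' @param labels a [LabelVolume] on the same grid.
#' @return the cluster table with a `label` column.
#' @export
annotateClusters <- function(result, labels) {
  ct <- clusterTable(result)
  if (nrow(ct) == 0) {
    ct$label <- character(0)
    return(ct)
  }
  ct$label <- vapply(seq_len(nrow(ct)), function(i) {
    co <- as.matrix(ct[i, c("peakX", "peakY", "peakZ")])
    lookupLabels(co, labels)$name[1]
  }, character(1))
  ct
}
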