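# Dual regression: localize, per subject, the thalamic voxels associated
# with each network ROI (the functional thalamic subdivisions).

#' Stage 1: per-subject component time courses
#'
#' For each timepoint, the brain-masked image is regressed on a design whose
#' columns are the group-level component spatial maps plus an intercept,
#' giving one temporal weight per component. Stage 1 uses the whole brain:
#' the components are whole-brain maps and restricting the fit would discard
#' the defining cortical signal. Output columns are variance-normalized
#' (the usual dual-regression convention) so stage-2 betas are comparable
#' across subjects, which the group analysis requires.
#'
#' @param bold preprocessed time-series [Volume4D] on the decomposition grid.
#' @param dec an [ICADecomposition].
#' @param brain [BrainMask]; defaults to the decomposition's mask.
#' @param normalize scale each time course to unit SD (default TRUE).
#' @return numeric matrix (timepoints x components) with attribute
#'   `normalized`.
#' @export
stage1Timecourses <- function(bold, dec, brain = NULL, normalize = TRUE) {
  if (is.null(brain)) brain <- dec@mask
  stopIfGridMismatch(bold, brain, "bold and brain mask")
  K <- nComponents(dec)
  d3 <- prod(dim(bold@data)[1:3])
  Smat <- t(matrix(dec@maps, d3, K)[which(brain@data), , drop = FALSE])
  M <- cbind(1, t(Smat))                 # voxels x (1 + K)
  qm <- qr(M)
  if (qm$rank < ncol(M))
    stop("rank-deficient spatial design: component maps are collinear")
  Y <- maskMatrix(bold, brain)           # time x voxels
  tc <- t(qr.coef(qm, t(Y)))[, -1, drop = FALSE]
  colnames(tc) <- paste0("IC", seq_len(K))
  if (normalize) {
    s <- apply(tc, 2, stats::sd)
    tc <- sweep(tc, 2, ifelse(s > 0, s, 1), `/`)
  }
  attr(tc, "normalized") <- normalize
  tc
}

#' Stage 2: subject-specific subdivision beta maps
#'
#' Each voxel's series is regressed jointly on an intercept plus all
#' component time courses; the per-component betas restricted to the
#' thalamus are the subject's functional thalamic subdivisions. The joint
#' fit matters: with correlated time courses, joint betas differ from
#' marginal (per-component) ones.
#'
#' @param bold preprocessed time-series [Volume4D].
#' @param tc matrix (timepoints x components) from [stage1Timecourses()].
#' @param thal thalamus [BrainMask].
#' @param brain [BrainMask] over which betas are computed (the whole-brain
#'   beta stack is retained in the result).
#' @param condMax condition-number threshold above which the time-course
#'   design is rejected as collinear.
#' @return a [SubdivisionMaps].
#' @export
stage2Subdivisions <- function(bold, tc, thal, brain, subject = "subject",
                               condMax = 1e8) {
  tc <- as.matrix(tc)
  d <- dim(bold@data)
  if (nrow(tc) != d[4])
    stop(sprintf("time course rows (%d) must equal frame count (%d)",
                 nrow(tc), d[4]))
  sv <- svd(scale(tc, center = TRUE, scale = FALSE), nu = 0, nv = 0)$d
  if (sv[length(sv)] <= 0 || sv[1] / sv[length(sv)] > condMax) {
    cc <- stats::cor(tc)
    diag(cc) <- 0
    worst <- which(abs(cc) == max(abs(cc)), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "collinear time courses (condition > %g); worst pair: components %d and %d (r = %.4f)",
      condMax, worst[1], worst[2], cc[worst[1], worst[2]]))
  }
  X <- cbind(1, tc)
  qx <- qr(X)
  Y <- maskMatrix(bold, brain)
  B <- qr.coef(qx, Y)[-1, , drop = FALSE]  # components x voxels
  B[is.na(B)] <- 0
  new("SubdivisionMaps", subject = subject,
      betas = new("Volume4D", data = unmaskStack(B, brain),
                  voxelSize = voxelSize(bold), affine = affineMatrix(bold),
                  frameMeaning = "stacked_maps"),
      thalMask = thal)
}

#' Dual regression of one subject
#'
#' Convenience wrapper running [stage1Timecourses()] then
#' [stage2Subdivisions()].
#'
#' @inheritParams stage1Timecourses
#' @inheritParams stage2Subdivisions
#' @return list with `timecourses` and `subdivisions`.
#' @export
dualRegression <- function(bold, dec, thal, brain = NULL,
                           subject = "subject", normalize = TRUE) {
  if (is.null(brain)) brain <- dec@mask
  tc <- stage1Timecourses(bold, dec, brain, normalize = normalize)
  sub <- stage2Subdivisions(bold, tc, thal, brain, subject = subject)
  list(timecourses = tc, subdivisions = sub)
}
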