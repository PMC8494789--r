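# NIfTI input/output, mask resampling and label lookup.

#' Read a NIfTI volume
#'
#' Reads a 3D or 4D NIfTI-1 image. 3D images are promoted to single-frame
#' 4D volumes. Non-finite voxel values are refused with an error naming the
#' offending voxel count (masked maps should be stored with 0, not NaN).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param frameMeaning `"time"` (default) or `"stacked_maps"`.
#' @return a [Volume4D].
#' @export
readVolume <- function(path, frameMeaning = c("time", "stacked_maps")) {
  frameMeaning <- match.arg(frameMeaning)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  data <- array(as.vector(img), dim = dim(img))
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L)
    stop(sprintf("expected a 3D or 4D image, got %dD", length(dim(data))))
  nbad <- sum(!is.finite(data))
  if (nbad > 0L)
    stop(sprintf("%d non-finite voxel value(s) in %s", nbad, path))
  aff <- matrix(as.numeric(unclass(RNifti::xform(img))), 4, 4)
  vs <- sqrt(colSums(aff[1:3, 1:3]^2))
  new("Volume4D", data = data, voxelSize = as.numeric(vs),
      affine = aff, frameMeaning = frameMeaning)
}

#' Write a volume, mask or label image as NIfTI
#'
#' Maps are stored as 32-bit float, masks as 8-bit unsigned integer.
#'
#' @param x a [Volume4D], [BrainMask] or [LabelVolume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
writeVolume <- function(x, path) {
  if (is(x, "BrainMask")) {
    data <- array(as.integer(x@data), dim = dim(x@data))
    dtype <- "uint8"
  } else if (is(x, "LabelVolume")) {
    data <- array(as.integer(x@data), dim = dim(x@data))
    dtype <- "int16"
  } else {
    data <- x@data
    if (dim(data)[4] == 1L) dim(data) <- dim(data)[1:3]
    dtype <- "float"
  }
  img <- RNifti::asNifti(data, datatype = dtype,
                         pixdim = c(voxelSize(x), 1)[seq_along(dim(data))])
  img <- RNifti::`sform<-`(img, structure(affineMatrix(x), code = 2L))
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' Read a binary mask
#'
#' Values above `threshold` become TRUE.
#'
#' @param path NIfTI file.
#' @param threshold binarization threshold (default 0.5).
#' @return a [BrainMask].
#' @export
readMask <- function(path, threshold = 0.5) {
  vol <- readVolume(path)
  if (dim(vol)[4] != 1L) stop("a mask must be a single-frame image")
  new("BrainMask", data = array(vol@data[, , , 1] > threshold,
                                dim = dim(vol)[1:3]),
      voxelSize = voxelSize(vol), affine = affineMatrix(vol))
}

#' Read an integer label volume with its label table
#'
#' @param path NIfTI file of integer labels (0 = unlabeled).
#' @param tablePath 2-column TSV (integer value, region name), no header
#'   required; a header line `value<TAB>name` is tolerated.
#' @return a [LabelVolume].
#' @export
readLabelVolume <- function(path, tablePath) {
  vol <- readVolume(path)
  tab <- readLabelTable(tablePath)
  new("LabelVolume",
      data = array(as.integer(round(vol@data[, , , 1])), dim = dim(vol)[1:3]),
      labelTable = tab, voxelSize = voxelSize(vol),
      affine = affineMatrix(vol))
}

#' @rdname readLabelVolume
#' @export
readLabelTable <- function(tablePath) {
  tab <- utils::read.table(tablePath, sep = "\t", header = FALSE,
                           col.names = c("value", "name"),
                           stringsAsFactors = FALSE)
  if (is.character(tab$value)) {   # header present
    tab <- tab[-1, , drop = FALSE]
    tab$value <- as.integer(tab$value)
  }
  tab$value <- as.integer(tab$value)
  tab
}

#' Resample a mask onto a target grid (nearest neighbour)
#'
#' Each target voxel centre is mapped through the composed affines into the
#' source grid and takes the value of the nearest source voxel. Only
#' nearest-neighbour assignment is offered, the conservative choice for
#' binary masks and labels.
#'
#' @param mask a [BrainMask].
#' @param target an object carrying the target grid (a [Volume4D],
#'   [BrainMask], or a list with `dims`, `voxelSize`, `affine`).
#' @param method resampling method; only `"nearest"`.
#' @return a [BrainMask] on the target grid.
#' @export
resampleMask <- function(mask, target, method = c("nearest")) {
  method <- match.arg(method)
  if (is.list(target)) {
    tdims <- as.integer(target$dims)
    taff <- target$affine
    tvs <- target$voxelSize
  } else {
    tdims <- dim(target)[1:3]
    taff <- affineMatrix(target)
    tvs <- voxelSize(target)
  }
  if (abs(det(taff)) < 1e-12 || abs(det(mask@affine)) < 1e-12)
    stop("non-invertible affine")
  # target voxel centres (0-based) -> world -> source voxel (0-based)
  grid <- as.matrix(expand.grid(x = seq_len(tdims[1]) - 1L,
                                y = seq_len(tdims[2]) - 1L,
                                z = seq_len(tdims[3]) - 1L))
  world <- taff %*% rbind(t(grid), 1)
  src <- solve(mask@affine, world)[1:3, , drop = FALSE]
  src <- round(t(src)) + 1L  # back to 1-based indices
  sdims <- dim(mask@data)
  inb <- src[, 1] >= 1L & src[, 1] <= sdims[1] &
         src[, 2] >= 1L & src[, 2] <= sdims[2] &
         src[, 3] >= 1L & src[, 3] <= sdims[3]
  vals <- logical(nrow(src))
  if (any(inb)) {
    lin <- (src[inb, 3] - 1L) * sdims[1] * sdims[2] +
           (src[inb, 2] - 1L) * sdims[1] + src[inb, 1]
    vals[inb] <- mask@data[lin]
  }
  if (!any(vals))
    stop("resampled mask is empty: target grid does not overlap the mask")
  new("BrainMask", data = array(vals, dim = tdims),
      voxelSize = as.numeric(tvs), affine = taff)
}

#' Tally atlas labels at a set of voxel coordinates
#'
#' Used to name the thalamic nuclei overlapped by significant clusters or
#' seeds, in the manner of a nucleus label atlas lookup.
#'
#' @param coords integer matrix (n x 3) of 1-based voxel indices.
#' @param labels a [LabelVolume] on the same grid.
#' @return data.frame (`name`, `count`), sorted by count descending;
#'   zero-valued voxels are reported as `"unlabeled"`.
#' @export
lookupLabels <- function(coords, labels) {
  coords <- matrix(as.integer(coords), ncol = 3)
  d <- dim(labels@data)
  if (any(coords < 1L) || any(coords[, 1] > d[1]) ||
      any(coords[, 2] > d[2]) || any(coords[, 3] > d[3]))
    stop("coordinate outside the label grid")
  vals <- labels@data[coords]
  known <- c(0L, labels@labelTable$value)
  if (!all(vals %in% known))
    stop(sprintf("label value(s) %s absent from the label table",
                 paste(unique(vals[!vals %in% known]), collapse = ", ")))
  nm <- c("unlabeled", labels@labelTable$name)[match(vals, known)]
  tab <- sort(table(nm), decreasing = TRUE)
  data.frame(name = names(tab), count = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}
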