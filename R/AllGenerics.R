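# Generics, accessors and show methods.

#' Voxel size in mm
#' @param x a volume-like object.
#' @return numeric length-3.
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))

#' Voxel-to-world affine transform
#' @param x a volume-like object.
#' @return 4x4 matrix.
#' @export
setGeneric("affineMatrix", function(x) standardGeneric("affineMatrix"))

#' Number of frames of a 4D object
#' @param x a [Volume4D] or object wrapping one.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of voxels inside a mask
#' @param x a [BrainMask].
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))

#' Component spatial maps of a decomposition
#' @param x an [ICADecomposition].
#' @return 4D array (x, y, z, component) of z-scored maps.
#' @export
setGeneric("componentMaps", function(x) standardGeneric("componentMaps"))

#' Mixing matrix of a decomposition
#' @param x an [ICADecomposition].
#' @return matrix (frames x components).
#' @export
setGeneric("mixingMatrix", function(x) standardGeneric("mixingMatrix"))

#' Number of components
#' @param x an [ICADecomposition] or [GroundTruth].
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' Thalamus-restricted beta maps
#'
#' @param x a [SubdivisionMaps] object.
#' @return matrix (components x thalamic voxels), columns in ascending
#'   column-major voxel order of the thalamus mask.
#' @export
setGeneric("thalamicBetas", function(x) standardGeneric("thalamicBetas"))

#' Significant-cluster table of a permutation result
#' @param x a [PermutationResult].
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))

#' Corrected p-value map
#' @param x a [PermutationResult].
#' @return 3D array of FWE-corrected p (NA outside the mask).
#' @export
setGeneric("correctedPMap", function(x) standardGeneric("correctedPMap"))

#' @describeIn Volume4D-class voxel size
#' @param x object.
#' @export
setMethod("voxelSize", "Volume4D", function(x) x@voxelSize)
#' @export
setMethod("voxelSize", "BrainMask", function(x) x@voxelSize)
#' @export
setMethod("voxelSize", "LabelVolume", function(x) x@voxelSize)

#' @export
setMethod("affineMatrix", "Volume4D", function(x) x@affine)
#' @export
setMethod("affineMatrix", "BrainMask", function(x) x@affine)
#' @export
setMethod("affineMatrix", "LabelVolume", function(x) x@affine)

#' @export
setMethod("nFrames", "Volume4D", function(x) dim(x@data)[4])
#' @export
setMethod("nFrames", "ConnectivityMapSet", function(x) nFrames(x@maps))
#' @export
setMethod("nFrames", "GroupStack", function(x) nFrames(x@maps))

#' @export
setMethod("nVoxels", "BrainMask", function(x) sum(x@data))

#' @export
setMethod("dim", "Volume4D", function(x) dim(x@data))
#' @export
setMethod("dim", "BrainMask", function(x) dim(x@data))

#' @export
setMethod("componentMaps", "ICADecomposition", function(x) x@maps)
#' @export
setMethod("mixingMatrix", "ICADecomposition", function(x) x@mixing)
#' @export
setMethod("nComponents", "ICADecomposition", function(x) dim(x@maps)[4])
#' @export
setMethod("nComponents", "GroundTruth", function(x) dim(x@networkMaps)[4])

#' @export
setMethod("thalamicBetas", "SubdivisionMaps", function(x) {
  idx <- which(x@thalMask@data)
  d <- dim(x@betas@data)
  m <- matrix(x@betas@data, prod(d[1:3]), d[4])
  t(m[idx, , drop = FALSE])
})

#' @export
setMethod("clusterTable", "PermutationResult", function(x) x@clusterTable)
#' @export
setMethod("correctedPMap", "PermutationResult", function(x) x@pMap)

setMethod("show", "Volume4D", function(object) {
  d <- dim(object@data)
  cat(sprintf("Volume4D: %d x %d x %d voxels, %d frame(s) [%s]\n",
              d[1], d[2], d[3], d[4], object@frameMeaning))
  cat(sprintf("  voxel size: %s mm\n",
              paste(format(object@voxelSize, digits = 3), collapse = " x ")))
})

setMethod("show", "BrainMask", function(object) {
  d <- dim(object@data)
  cat(sprintf("BrainMask: %d x %d x %d grid, %d voxels in mask\n",
              d[1], d[2], d[3], sum(object@data)))
})

setMethod("show", "ConnectivityMapSet", function(object) {
  cat(sprintf(
    "ConnectivityMapSet: subject '%s', %d thalamic seed maps (Fisher z)\n",
    object@subject, nFrames(object)))
})

setMethod("show", "GroupStack", function(object) {
  cat(sprintf(
    "GroupStack: %d subjects x %d thalamic maps = %d frames\n",
    length(object@subjects), nrow(object@thalVoxels), nFrames(object)))
})

setMethod("show", "ICADecomposition", function(object) {
  cat(sprintf(
    "ICADecomposition: %d components, %.1f%% of stack variance retained\n",
    nComponents(object), 100 * object@varianceRetained))
  cat(sprintf("  converged in %d iteration(s), %d restart(s)\n",
              object@convergence$iterations, object@convergence$restarts))
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf("PermutationResult: %s enhancement, %d permutations (%s)\n",
              object@enhancement, object@nPerm, object@scheme))
  ct <- object@clusterTable
  if (nrow(ct) == 0) {
    cat("  no significant clusters\n")
  } else {
    cat(sprintf("  %d significant cluster(s); best corrected p = %.4g\n",
                nrow(ct), min(ct$p)))
  }
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %s grid, K = %d networks, thalamus %d voxels, brain %d voxels\n",
    paste(object@dims, collapse = " x "), nComponents(object),
    nVoxels(object@thalamus), nVoxels(object@brain)))
  if (nrow(object@groupEffect))
    cat(sprintf("  patient effect: component %s x %s\n",
                paste(object@groupEffect$component, collapse = ","),
                paste(object@groupEffect$factor, collapse = ",")))
})
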