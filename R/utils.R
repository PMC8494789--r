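# Internal grid/matrix helpers shared across modules.

# 1-based (i,j,k) coordinates of TRUE voxels, ascending column-major order.
maskCoords <- function(mask) {
  which(mask@data, arr.ind = TRUE)
}

# frames x voxels matrix of a Volume4D restricted to a mask.
maskMatrix <- function(vol, mask) {
  d <- dim(vol@data)
  idx <- which(mask@data)
  m <- matrix(vol@data, prod(d[1:3]), d[4])
  t(m[idx, , drop = FALSE])
}

# Scatter a value vector back into a 3D array (0 elsewhere).
unmaskMap <- function(values, mask, fill = 0) {
  arr <- array(fill, dim = dim(mask@data))
  arr[mask@data] <- values
  arr
}

# Scatter a k x voxels matrix into a 4D array (x, y, z, k).
unmaskStack <- function(values, mask, fill = 0) {
  k <- nrow(values)
  arr <- array(fill, dim = c(dim(mask@data), k))
  idx <- which(mask@data)
  n3 <- prod(dim(mask@data))
  for (i in seq_len(k)) arr[idx + (i - 1L) * n3] <- values[i, ]
  arr
}

sameGrid <- function(a, b, tol = 1e-4) {
  da <- dim(a); db <- dim(b)
  all(da[1:3] == db[1:3]) &&
    max(abs(affineMatrix(a) - affineMatrix(b))) < tol
}

stopIfGridMismatch <- function(a, b, what = "volumes") {
  if (!sameGrid(a, b))
    stop(sprintf("%s are not on the same grid (dims/affine differ)", what))
  invisible(TRUE)
}

# Pearson correlation between two maps over a logical mask.
maskedCor <- function(a, b, mask) {
  stats::cor(a[mask], b[mask])
}

# Draw sub-seeds (< 2^31) deterministically from a master seed.
deriveSeeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Exact maximum-|r| one-to-one assignment of references to components by
# bitmask dynamic programming (references <= 16).
assignComponents <- function(absR) {
  nc <- nrow(absR); nr <- ncol(absR)
  if (nr > nc) stop("fewer components than reference maps")
  if (nr > 16L) stop("assignment supports at most 16 reference maps")
  full <- bitwShiftL(1L, nr) - 1L
  nmask <- full + 1L
  f <- matrix(-Inf, nc + 1L, nmask)
  f[1L, 1L] <- 0
  choice <- matrix(0L, nc + 1L, nmask)
  for (i in seq_len(nc)) {
    for (m in 0:full) {
      base <- f[i, m + 1L]
      if (is.finite(base) && base > f[i + 1L, m + 1L]) {
        f[i + 1L, m + 1L] <- base        # component i unassigned
        choice[i + 1L, m + 1L] <- -1L
      }
      for (r in seq_len(nr)) {
        bit <- bitwShiftL(1L, r - 1L)
        if (bitwAnd(m, bit) > 0L) {
          prev <- f[i, bitwXor(m, bit) + 1L]
          v <- prev + absR[i, r]
          if (is.finite(prev) && v > f[i + 1L, m + 1L]) {
            f[i + 1L, m + 1L] <- v
            choice[i + 1L, m + 1L] <- r
          }
        }
      }
    }
  }
  # backtrack
  comp <- integer(nr)
  m <- full
  for (i in rev(seq_len(nc))) {
    r <- choice[i + 1L, m + 1L]
    if (r > 0L) {
      comp[r] <- i
      m <- bitwXor(m, bitwShiftL(1L, r - 1L))
    }
  }
  comp
}
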