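# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so that seeded package
#' operations do not perturb the global random stream.
#' @keywords internal
#' @noRd
local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Voxel-to-world affine for an axis-aligned grid
#'
#' World coordinates are in mm; the grid centre maps to the world origin.
#' Voxel indices are 1-based (R convention); `affine %*% c(i,j,k,1)` gives
#' the world position of the centre of voxel (i,j,k).
#' @keywords internal
#' @noRd
centered_affine <- function(dim, voxel_mm) {
  a <- diag(4)
  a[1, 1] <- a[2, 2] <- a[3, 3] <- voxel_mm
  a[1:3, 4] <- -voxel_mm * (dim + 1) / 2
  a
}

# pts: n x 3 world mm -> n x 3 (fractional, 1-based) voxel indices
world_to_voxel <- function(affine, pts) {
  pts <- rbind(t(pts), 1)
  out <- solve(affine) %*% pts
  t(out[1:3, , drop = FALSE])
}

voxel_to_world <- function(affine, idx) {
  idx <- rbind(t(idx), 1)
  t((affine %*% idx)[1:3, , drop = FALSE])
}

#' Trilinear interpolation weights for world-free voxel coordinates
#'
#' @param pts n x 3 fractional 1-based voxel coordinates
#' @param dim length-3 grid dimensions
#' @return list(idx = n x 8 linear voxel indices, w = n x 8 weights,
#'   inside = logical n). Out-of-bounds points get weight NA.
#' @keywords internal
#' @noRd
trilinear_weights <- function(pts, dim) {
  n <- nrow(pts)
  lo <- floor(pts)
  fr <- pts - lo
  inside <- pts[, 1] >= 1 & pts[, 1] <= dim[1] &
    pts[, 2] >= 1 & pts[, 2] <= dim[2] &
    pts[, 3] >= 1 & pts[, 3] <= dim[3]
  # clamp so corner indices are valid; weights of clamped corners -> 0/1
  lo[, 1] <- pmin(pmax(lo[, 1], 1), dim[1] - 1)
  lo[, 2] <- pmin(pmax(lo[, 2], 1), dim[2] - 1)
  lo[, 3] <- pmin(pmax(lo[, 3], 1), dim[3] - 1)
  fr <- pts - lo
  fr[fr < 0] <- 0
  fr[fr > 1] <- 1
  idx <- matrix(0L, n, 8)
  w <- matrix(0, n, 8)
  corner <- 0L
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    corner <- corner + 1L
    ii <- lo[, 1] + dx
    jj <- lo[, 2] + dy
    kk <- lo[, 3] + dz
    idx[, corner] <- as.integer(ii + (jj - 1) * dim[1] + (kk - 1) * dim[1] * dim[2])
    wx <- if (dx == 1) fr[, 1] else 1 - fr[, 1]
    wy <- if (dy == 1) fr[, 2] else 1 - fr[, 2]
    wz <- if (dz == 1) fr[, 3] else 1 - fr[, 3]
    w[, corner] <- wx * wy * wz
  }
  w[!inside, ] <- NA_real_
  list(idx = idx, w = w, inside = inside)
}

# Apply precomputed trilinear weights to a (nvox x t) matrix.
# Returns n x t matrix; rows for out-of-bounds points are NA.
trilinear_apply <- function(tw, mat) {
  n <- nrow(tw$idx)
  t_dim <- ncol(mat)
  out <- matrix(0, n, t_dim)
  for (corner in 1:8) {
    out <- out + tw$w[, corner] * mat[tw$idx[, corner], , drop = FALSE]
  }
  out
}

# Shift a 3D array by s voxels along an axis, zero-filling.
shift3d <- function(arr, s, axis) {
  if (s == 0) return(arr)
  d <- dim(arr)
  out <- array(0, d)
  n <- d[axis]
  if (abs(s) >= n) return(out)
  src <- if (s > 0) 1:(n - s) else (1 - s):n
  dst <- if (s > 0) (1 + s):n else 1:(n + s)
  ix <- function(which) switch(axis, `1` = which, `2` = which, `3` = which)
  if (axis == 1) out[dst, , ] <- arr[src, , ]
  else if (axis == 2) out[, dst, ] <- arr[, src, ]
  else out[, , dst] <- arr[, , src]
  out
}

gaussian_kernel_1d <- function(sigma_vox) {
  r <- max(1L, ceiling(3 * sigma_vox))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

#' Separable 3D Gaussian smoothing with zero padding
#' @keywords internal
#' @noRd
smooth3d_gaussian <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  k <- gaussian_kernel_1d(sigma_vox)
  r <- (length(k) - 1L) / 2L
  for (axis in 1:3) {
    acc <- array(0, dim(arr))
    for (j in seq_along(k)) {
      acc <- acc + k[j] * shift3d(arr, j - r - 1L, axis)
    }
    arr <- acc
  }
  arr
}

# Remove a linear trend per column of a t x n matrix; returns residuals.
detrend_columns <- function(y) {
  t_dim <- nrow(y)
  x <- cbind(1, seq_len(t_dim) - (t_dim + 1) / 2)
  y - x %*% solve(crossprod(x), crossprod(x, y))
}

#' Discrete cosine transform drift basis
#'
#' Columns are cos(pi * k * (2i - 1) / (2n)), k = 1..K, the standard
#' high-pass drift basis for equally spaced fMRI volumes.
#' @keywords internal
#' @noRd
dct_basis <- function(n, K) {
  if (K < 1) return(matrix(0, n, 0))
  i <- seq_len(n)
  sapply(seq_len(K), function(k) cos(pi * k * (2 * i - 1) / (2 * n)))
}

# 18-connectivity offsets (faces + edges).
offsets_18 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  m <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  as.matrix(g[m >= 1 & m <= 2, ])
})

#' Connected components of a 3D logical mask (18-connectivity)
#'
#' Iterative breadth-first flood fill; returns an integer array of
#' component labels (0 = background).
#' @keywords internal
#' @noRd
connected_components_18 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  todo <- which(mask)
  seen <- logical(length(mask))
  off <- offsets_18
  for (v0 in todo) {
    if (seen[v0]) next
    nxt <- nxt + 1L
    queue <- v0
    seen[v0] <- TRUE
    while (length(queue)) {
      cur <- queue
      queue <- integer(0)
      lab[cur] <- nxt
      k0 <- (cur - 1L) %/% (d[1] * d[2])
      j0 <- ((cur - 1L) %/% d[1]) %% d[2]
      i0 <- (cur - 1L) %% d[1]
      for (o in seq_len(nrow(off))) {
        i <- i0 + off[o, 1]; j <- j0 + off[o, 2]; k <- k0 + off[o, 3]
        ok <- i >= 0 & i < d[1] & j >= 0 & j < d[2] & k >= 0 & k < d[3]
        nb <- (i + j * d[1] + k * d[1] * d[2])[ok] + 1L
        nb <- nb[mask[nb] & !seen[nb]]
        if (length(nb)) {
          seen[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
      queue <- unique(queue)
    }
  }
  lab
}

# column skewness used for the deterministic PCA sign convention
col_skew <- function(m) {
  mu <- colMeans(m)
  s <- sqrt(colMeans(sweep(m, 2, mu)^2))
  s[s == 0] <- 1
  colMeans(sweep(m, 2, mu)^3) / s^3
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
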