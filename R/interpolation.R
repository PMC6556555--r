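#' Trilinear interpolation of a 3D volume at continuous voxel coordinates
#'
#' Coordinates are 0-based voxel indices (0 = centre of the first voxel).
#' Points outside the volume are clamped to the boundary (edge-value
#' extension); the number of such points is returned in the attribute
#' `n_clamped`.
#'
#' @param vol 3D numeric array.
#' @param pts n x 3 matrix of 0-based voxel coordinates.
#' @return Numeric vector of interpolated values.
#' @export
trilinear_interp <- function(vol, pts) {
  d <- dim(vol)
  pts <- as.matrix(pts)
  clamped <- pts[, 1] < 0 | pts[, 1] > d[1] - 1 |
    pts[, 2] < 0 | pts[, 2] > d[2] - 1 |
    pts[, 3] < 0 | pts[, 3] > d[3] - 1
  p <- pts
  for (k in 1:3) p[, k] <- pmin(pmax(p[, k], 0), d[k] - 1)
  i0 <- pmin(floor(p), matrix(rep(d - 1, each = nrow(p)), ncol = 3))
  f <- p - i0
  i0 <- i0 + 1 # to 1-based corner index
  i1 <- pmin(i0 + 1, matrix(rep(d, each = nrow(p)), ncol = 3))
  val <- numeric(nrow(p))
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- if (cx == 0) i0[, 1] else i1[, 1]
    iy <- if (cy == 0) i0[, 2] else i1[, 2]
    iz <- if (cz == 0) i0[, 3] else i1[, 3]
    w <- (if (cx == 0) 1 - f[, 1] else f[, 1]) *
      (if (cy == 0) 1 - f[, 2] else f[, 2]) *
      (if (cz == 0) 1 - f[, 3] else f[, 3])
    val <- val + w * vol[cbind(ix, iy, iz)]
  }
  attr(val, "n_clamped") <- sum(clamped)
  val
}

# cubic-convolution kernel (Catmull-Rom, a = -0.5)
.cubic_kernel <- function(x) {
  ax <- abs(x)
  ifelse(ax <= 1, 1.5 * ax^3 - 2.5 * ax^2 + 1,
         ifelse(ax < 2, -0.5 * ax^3 + 2.5 * ax^2 - 4 * ax + 2, 0))
}

#' Tricubic (cubic-convolution) interpolation of a 3D volume
#'
#' Separable cubic convolution with the Catmull-Rom kernel (a = -0.5), the
#' standard "cubic interpolation" of image processing. Edge handling by
#' index clamping. Coordinates as in [trilinear_interp()].
#'
#' @param vol 3D numeric array.
#' @param pts n x 3 matrix of 0-based voxel coordinates.
#' @return Numeric vector of interpolated values.
#' @export
tricubic_interp <- function(vol, pts) {
  d <- dim(vol)
  p <- as.matrix(pts)
  for (k in 1:3) p[, k] <- pmin(pmax(p[, k], 0), d[k] - 1)
  base <- floor(p)
  f <- p - base
  val <- numeric(nrow(p))
  wx <- lapply(-1:2, function(o) .cubic_kernel(f[, 1] - o))
  wy <- lapply(-1:2, function(o) .cubic_kernel(f[, 2] - o))
  wz <- lapply(-1:2, function(o) .cubic_kernel(f[, 3] - o))
  for (ox in -1:2) for (oy in -1:2) for (oz in -1:2) {
    ix <- pmin(pmax(base[, 1] + ox, 0), d[1] - 1) + 1
    iy <- pmin(pmax(base[, 2] + oy, 0), d[2] - 1) + 1
    iz <- pmin(pmax(base[, 3] + oz, 0), d[3] - 1) + 1
    w <- wx[[ox + 2]] * wy[[oy + 2]] * wz[[oz + 2]]
    val <- val + w * vol[cbind(ix, iy, iz)]
  }
  val
}

#' Grid geometry of an image
#'
#' @param x A [dwi_stack()], or pass `dim` and `affine` directly.
#' @param dim,affine Grid shape and 4 x 4 voxel-to-world matrix.
#' @return List of class `grid_geometry` with `dim`, `affine`,
#'   `voxel_size`.
#' @export
grid_geometry <- function(x = NULL, dim = NULL, affine = NULL) {
  if (!is.null(x) && inherits(x, "dwi_stack")) {
    dim <- spatial_dim(x); affine <- x$affine
  }
  stopifnot(length(dim) == 3, all(base::dim(affine) == c(4, 4)))
  structure(list(dim = as.integer(dim), affine = unname(as.matrix(affine)),
                 voxel_size = sqrt(colSums(affine[1:3, 1:3]^2))),
            class = "grid_geometry")
}

#' Upsampled grid covering the same field of view
#'
#' Splits every voxel into `factor^3` subvoxels; subvoxel centres tile the
#' original voxel, so the world-space field of view is preserved.
#'
#' @param grid A [grid_geometry()].
#' @param factor Integer upsampling factor per axis.
#' @return A finer [grid_geometry()].
#' @export
upsample_grid <- function(grid, factor = 2L) {
  factor <- as.integer(factor)
  A <- grid$affine
  Af <- A
  Af[1:3, 1:3] <- A[1:3, 1:3] / factor
  # first fine-voxel centre sits at coarse coordinate -(factor-1)/(2*factor)
  shift <- -(factor - 1) / (2 * factor)
  Af[1:3, 4] <- A[1:3, 4] + A[1:3, 1:3] %*% rep(shift, 3)
  grid_geometry(dim = grid$dim * factor, affine = Af)
}

# map target-grid 0-based voxel indices (n x 3) to source 0-based voxel coords
.voxel_to_voxel <- function(target_grid, src_affine, idx) {
  world <- target_grid$affine %*% rbind(t(idx), 1)
  src <- solve(src_affine, world)
  t(src[1:3, , drop = FALSE])
}

# all 0-based voxel indices of a grid, x fastest
.grid_indices <- function(dim3) {
  as.matrix(expand.grid(x = 0:(dim3[1] - 1), y = 0:(dim3[2] - 1),
                        z = 0:(dim3[3] - 1)))
}

#' Reference harmonisation predictor: trilinear + SH interpolation
#'
#' The non-learning baseline: b0-normalised source signals are trilinearly
#' resampled at the target voxel centres, fitted with an order-`L` SH basis
#' (Laplace-Beltrami weight `lambda`) at the source gradient directions,
#' evaluated at the target directions, and re-scaled by the trilinearly
#' interpolated mean b = 0 signal. Use `L = 6` for matched-resolution
#' targets and `L = 8` for the high-angular-resolution targets; an order-8
#' fit from 30 directions is underdetermined, so this path requires
#' `lambda > 0`.
#'
#' @param src Source [dwi_stack()] (single shell + b = 0), co-registered
#'   with the target grid (shared world frame).
#' @param target_grid A [grid_geometry()].
#' @param target_scheme Target [gradient_scheme()].
#' @param L Even SH order (6 or 8 in the standard settings).
#' @param lambda Laplace-Beltrami weight; default 0.006.
#' @param eps Minimum usable interpolated b0.
#' @return Predicted [dwi_stack()] on the target grid/scheme. Attribute
#'   `n_clamped` counts target centres outside the source volume (edge
#'   extension applied).
#' @export
predict_reference <- function(src, target_grid, target_scheme, L = 6,
                              lambda = 0.006, eps = 1e-8) {
  if (L %% 2 != 0) stop("SH order must be even")
  if (lambda == 0 && sum(!is_b0(src$scheme)) < sh_ncoef(L)) {
    stop("order-", L, " fit from ", sum(!is_b0(src$scheme)),
         " directions is underdetermined; use lambda > 0 (default 0.006)")
  }
  sd3 <- spatial_dim(src)
  b0 <- mean_b0(src)
  dwi_idx <- which(!is_b0(src$scheme))
  b0_safe <- pmax(b0, eps)
  idx <- .grid_indices(target_grid$dim)
  pts <- .voxel_to_voxel(target_grid, src$affine, idx)
  b0_t <- trilinear_interp(b0, pts)
  n_clamped <- attr(b0_t, "n_clamped")
  sig_t <- matrix(0, nrow(pts), length(dwi_idx))
  for (k in seq_along(dwi_idx)) {
    nv <- array(src$data[, , , dwi_idx[k], drop = FALSE], dim = sd3) /
      b0_safe
    sig_t[, k] <- trilinear_interp(nv, pts)
  }
  coefs <- sh_fit(sig_t, src$scheme$bvecs[dwi_idx, , drop = FALSE],
                  L = L, lambda = lambda)
  t_dwi <- which(!is_b0(target_scheme))
  pred_norm <- sh_resample(coefs, target_scheme$bvecs[t_dwi, , drop = FALSE])
  nvol <- length(target_scheme$bvals)
  out <- array(0, dim = c(target_grid$dim, nvol))
  flat <- matrix(out, ncol = nvol)
  flat[, t_dwi] <- pred_norm * b0_t
  for (j in which(is_b0(target_scheme))) flat[, j] <- b0_t
  out <- array(flat, dim = c(target_grid$dim, nvol))
  res <- dwi_stack(out, target_scheme,
                   voxel_size = target_grid$voxel_size,
                   affine = target_grid$affine)
  attr(res, "n_clamped") <- n_clamped
  res
}
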