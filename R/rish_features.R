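#' Per-order RISH energy of SH coefficients
#'
#' The rotationally invariant SH (RISH) feature of order l is the energy
#' R_l = sum_m c_{l,m}^2 of the order-l coefficients, invariant under joint
#' rotation of the signal and gradient scheme and under any permutation of
#' the m-index ordering.
#'
#' @param coefs n_vox x n_coef SH coefficient matrix (from [sh_fit()] of
#'   b0-normalised signals).
#' @param l Even order, `l <= attr(coefs, "order")`.
#' @return Numeric vector of per-voxel energies (>= 0).
#' @export
rish <- function(coefs, l) {
  L <- attr(coefs, "order")
  if (is.null(L)) stop("`coefs` must carry an `order` attribute (sh_fit)")
  if (l %% 2 != 0 || l < 0) stop("RISH order must be even and >= 0")
  if (l > L) stop("RISH order ", l, " exceeds the fitted SH order ", L)
  tab <- sh_index_table(L)
  cols <- tab$j[tab$l == l]
  rowSums(unclass(coefs)[, cols, drop = FALSE]^2)
}

#' R0 and R2 RISH maps of a DWI stack
#'
#' Normalises the shell signals per voxel by the mean b = 0 signal, fits a
#' Laplace-Beltrami-regularised SH representation, and returns the order-0
#' and order-2 energy maps. Voxels with mean b0 below `eps` are excluded
#' (NaN in the maps, counted in the attribute `n_excluded_b0`).
#'
#' @param stack A [dwi_stack()] (single shell plus b = 0).
#' @param mask Optional 3D 0/1 array.
#' @param order Even SH fitting order (default 4).
#' @param lambda Laplace-Beltrami weight (default 0.006).
#' @param eps Minimum usable mean b0 signal.
#' @return List with 3D arrays `R0` and `R2` (NaN outside usable voxels)
#'   and `n_excluded_b0`.
#' @export
rish_maps <- function(stack, mask = NULL, order = 4, lambda = 0.006,
                      eps = 1e-8) {
  ns <- normalised_signals(stack, mask, eps = eps)
  coefs <- sh_fit(ns$signals, ns$dirs, L = order, lambda = lambda)
  sd3 <- spatial_dim(stack)
  list(R0 = .scatter_map(rish(coefs, 0), ns$voxels, sd3, fill = NaN),
       R2 = .scatter_map(rish(coefs, 2), ns$voxels, sd3, fill = NaN),
       n_excluded_b0 = ns$n_excluded_b0)
}
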