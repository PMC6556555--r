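#' Diffusion-tensor design matrix for a gradient scheme
#'
#' Row per volume: (1, -b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz,
#' -2b gy gz), so that X beta = ln S with beta = (ln S0, Dxx, Dyy, Dzz,
#' Dxy, Dxz, Dyz).
#'
#' @param scheme A [gradient_scheme()].
#' @return n_vol x 7 design matrix.
#' @export
dti_design <- function(scheme) {
  b <- scheme$bvals
  g <- scheme$bvecs
  cbind(1,
        -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
        -2 * b * g[, 1] * g[, 2],
        -2 * b * g[, 1] * g[, 3],
        -2 * b * g[, 2] * g[, 3])
}

#' Weighted linear least-squares diffusion tensor fit
#'
#' Per in-mask voxel: ordinary least squares on the log-signal initialises
#' the fit; `n_reweight` re-weighted passes (weights = squared predicted
#' signals, the standard WLLS scheme) refine it. Non-positive signals are
#' clamped to `eps` times the voxel's maximum signal before the log.
#'
#' @param stack A [dwi_stack()] with at least 7 volumes spanning b = 0 and
#'   one shell.
#' @param mask Optional 3D 0/1 array.
#' @param n_reweight Number of re-weighting passes (default 1).
#' @param eps Relative clamp for non-positive signals.
#' @return Object of class `tensor_field`: list with `tensors` (n_vox x 6:
#'   Dxx, Dyy, Dzz, Dxy, Dxz, Dyz in mm^2/s), `log_s0`, `voxels` (1-based
#'   indices), `spatial_dim`, `n_clamped` QC count.
#' @export
fit_wlls <- function(stack, mask = NULL, n_reweight = 1L, eps = 1e-6) {
  X <- dti_design(stack$scheme)
  if (nrow(X) < 7) stop("tensor fit needs at least 7 volumes")
  if (qr(X)$rank < 7) {
    stop("rank-deficient design: gradient scheme does not determine a ",
         "tensor (need b = 0 plus >= 6 non-collinear directions)")
  }
  sd3 <- spatial_dim(stack)
  if (is.null(mask)) mask <- array(1L, dim = sd3)
  vox <- which(mask > 0, arr.ind = TRUE)
  if (nrow(vox) == 0) stop("mask is empty")
  flat <- matrix(stack$data, ncol = dim(stack$data)[4])
  lin <- vox[, 1] + (vox[, 2] - 1L) * sd3[1] + (vox[, 3] - 1L) * sd3[1] * sd3[2]
  S <- flat[lin, , drop = FALSE]
  floor_val <- eps * pmax(apply(S, 1, max), .Machine$double.xmin)
  n_clamped <- sum(S < floor_val)
  S <- pmax(S, floor_val)
  Y <- log(S)
  # shared OLS initialisation for all voxels
  beta <- t(solve(crossprod(X), crossprod(X, t(Y))))
  for (pass in seq_len(n_reweight)) {
    pred <- beta %*% t(X) # log-predictions
    w <- exp(2 * pred)    # weights = squared predicted signals
    for (v in seq_len(nrow(beta))) {
      Xw <- X * w[v, ]
      beta[v, ] <- solve(crossprod(X, Xw), crossprod(Xw, Y[v, ]))
    }
  }
  structure(list(tensors = beta[, 2:7, drop = FALSE],
                 log_s0 = beta[, 1],
                 voxels = vox, spatial_dim = sd3, n_clamped = n_clamped),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat("<tensor_field> ", nrow(x$tensors), " voxels on a ",
      paste(x$spatial_dim, collapse = " x "), " grid; ",
      x$n_clamped, " clamped signal(s)\n", sep = "")
  invisible(x)
}

# eigenvalues (descending) for each row of a n x 6 tensor matrix
tensor_eigenvalues <- function(tensors) {
  n <- nrow(tensors)
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    d <- tensors[i, ]
    M <- matrix(c(d[1], d[4], d[5],
                  d[4], d[2], d[6],
                  d[5], d[6], d[3]), 3, 3)
    out[i, ] <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
                     decreasing = TRUE)
  }
  out
}

# FA from rows of eigenvalues; zero tensor -> FA 0 by convention
fa_from_eigenvalues <- function(ev) {
  ev <- pmax(ev, 0) # negative eigenvalues from noisy fits clamped
  mb <- rowMeans(ev)
  num <- sqrt(rowSums((ev - mb)^2))
  den <- sqrt(rowSums(ev^2))
  fa <- sqrt(3 / 2) * ifelse(den > 0, num / den, 0)
  pmin(pmax(fa, 0), 1)
}

#' Fractional anisotropy map from a tensor field
#'
#' FA = sqrt(3/2) ||lambda - mean(lambda)|| / ||lambda|| over the (clamped
#' non-negative) eigenvalues; a zero tensor gives FA = 0. Values clipped to
#' `[0, 1]`.
#'
#' @param t A `tensor_field` from [fit_wlls()].
#' @return 3D array (NA outside the fitted voxels), attribute `n_negative`
#'   counts voxels whose fits had negative eigenvalues.
#' @export
fa_map <- function(t) {
  ev <- tensor_eigenvalues(t$tensors)
  out <- .scatter_map(fa_from_eigenvalues(ev), t$voxels, t$spatial_dim)
  attr(out, "n_negative") <- sum(apply(ev < 0, 1, any))
  out
}

#' Mean diffusivity map from a tensor field
#'
#' MD = (lambda1 + lambda2 + lambda3) / 3 in mm^2/s, eigenvalues clamped to
#' be non-negative.
#'
#' @param t A `tensor_field` from [fit_wlls()].
#' @return 3D array (NA outside the fitted voxels).
#' @export
md_map <- function(t) {
  ev <- pmax(tensor_eigenvalues(t$tensors), 0)
  .scatter_map(rowMeans(ev), t$voxels, t$spatial_dim)
}
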