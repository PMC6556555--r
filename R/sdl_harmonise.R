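#' Fixed representative directions used as SDL angular channels
#'
#' Raw 30-direction schemes differ across scanners, so patches use the
#' b0-normalised signal SH-resampled onto `n` fixed directions shared by
#' all acquisitions. The set is generated once by electrostatic repulsion
#' from a fixed seed and is therefore identical across sessions.
#'
#' @param n Number of angular channels (default 5).
#' @return n x 3 unit directions.
#' @export
sdl_channel_dirs <- function(n = 5) hemisphere_dirs(n, seed = 20L)

#' Angular channel array of a DWI stack
#'
#' b0-normalises the stack, fits an SH representation per voxel, and
#' evaluates it at `channel_dirs`, yielding an (x, y, z, k) array (NA
#' outside usable voxels). Also returns the per-voxel SH coefficients so
#' harmonisers can rebuild full angular profiles.
#'
#' @param stack A [dwi_stack()].
#' @param mask Optional 3D 0/1 array.
#' @param channel_dirs k x 3 unit directions; default [sdl_channel_dirs()].
#' @param order,lambda SH fit settings (default order 4, lambda 0.006).
#' @return List: `channels` 4D array, `coefs` (n_vox x n_coef), `voxels`,
#'   `b0`, `channel_dirs`.
#' @export
dwi_channels <- function(stack, mask = NULL, channel_dirs = sdl_channel_dirs(),
                         order = 4, lambda = 0.006) {
  ns <- normalised_signals(stack, mask)
  coefs <- sh_fit(ns$signals, ns$dirs, L = order, lambda = lambda)
  ch_vals <- sh_resample(coefs, channel_dirs)
  sd3 <- spatial_dim(stack)
  k <- nrow(.as_dir_matrix(channel_dirs))
  channels <- array(NA_real_, dim = c(sd3, k))
  for (j in seq_len(k)) {
    channels[, , , j] <- .scatter_map(ch_vals[, j], ns$voxels, sd3)
  }
  list(channels = channels, coefs = coefs, voxels = ns$voxels, b0 = ns$b0,
       channel_dirs = .as_dir_matrix(channel_dirs))
}

# per-channel mean/sd over finite voxels of an (x,y,z,k) array
.channel_stats <- function(channels) {
  k <- dim(channels)[4]
  t(vapply(seq_len(k), function(j) {
    v <- channels[, , , j]
    v <- v[is.finite(v)]
    c(mean = mean(v), sd = max(stats::sd(v), 1e-12))
  }, c(mean = 0, sd = 0)))
}

.apply_standardise <- function(channels, stats) {
  for (j in seq_len(dim(channels)[4])) {
    channels[, , , j] <- (channels[, , , j] - stats[j, "mean"]) / stats[j, "sd"]
  }
  channels
}

.undo_standardise <- function(channels, stats) {
  for (j in seq_len(dim(channels)[4])) {
    channels[, , , j] <- channels[, , , j] * stats[j, "sd"] + stats[j, "mean"]
  }
  channels
}

#' Extract vectorised spatio-angular patches
#'
#' Slides a `spatial` window with stride 1 over the grid and keeps every
#' patch that lies fully inside the mask with finite channel values. Each
#' patch is vectorised x-fastest, then y, z, then channel, giving column
#' vectors of length `prod(spatial) * k`.
#'
#' @param channels (x, y, z, k) array (e.g. from [dwi_channels()], usually
#'   standardised first).
#' @param mask Optional 3D 0/1 array.
#' @param spatial Integer length-3 patch shape, default `c(3, 3, 3)`.
#' @return Object of class `patch_set`: list with `X` (m x N matrix),
#'   `corners` (N x 3, 1-based patch corner indices), `spatial`,
#'   `n_channels`.
#' @export
extract_patches <- function(channels, mask = NULL, spatial = c(3, 3, 3)) {
  d <- dim(channels)
  k <- d[4]
  if (is.null(mask)) mask <- array(1L, dim = d[1:3])
  ok <- mask > 0 & apply(is.finite(channels), 1:3, all)
  a <- as.integer(spatial)
  nx <- d[1] - a[1] + 1; ny <- d[2] - a[2] + 1; nz <- d[3] - a[3] + 1
  if (nx < 1 || ny < 1 || nz < 1) stop("grid smaller than one patch")
  # patch is usable iff every voxel of its window is usable
  cnt <- .box_sum(ok * 1, a)
  full <- which(cnt > prod(a) - 0.5, arr.ind = TRUE) # corners, 1-based
  if (nrow(full) == 0) stop("mask too small: no fully-in-mask patch")
  m <- prod(a) * k
  X <- matrix(0, m, nrow(full))
  offs <- as.matrix(expand.grid(ox = 0:(a[1] - 1), oy = 0:(a[2] - 1),
                                oz = 0:(a[3] - 1)))
  for (j in seq_len(k)) {
    vol <- channels[, , , j]
    for (r in seq_len(nrow(offs))) {
      row_idx <- (j - 1) * prod(a) + r
      X[row_idx, ] <- vol[cbind(full[, 1] + offs[r, 1],
                                full[, 2] + offs[r, 2],
                                full[, 3] + offs[r, 3])]
    }
  }
  structure(list(X = X, corners = full, spatial = a, n_channels = k),
            class = "patch_set")
}

# sum of vol over each a1 x a2 x a3 window; result dim = dim - a + 1
.box_sum <- function(vol, a) {
  d <- dim(vol)
  out <- array(0, dim = d - a + 1L)
  offs <- as.matrix(expand.grid(0:(a[1] - 1), 0:(a[2] - 1), 0:(a[3] - 1)))
  for (r in seq_len(nrow(offs))) {
    out <- out + vol[(1 + offs[r, 1]):(d[1] - a[1] + 1 + offs[r, 1]),
                     (1 + offs[r, 2]):(d[2] - a[2] + 1 + offs[r, 2]),
                     (1 + offs[r, 3]):(d[3] - a[3] + 1 + offs[r, 3]),
                     drop = FALSE]
  }
  out
}

#' Restore a patch matrix into a volume by overlap-averaging
#'
#' Inverse of [extract_patches()] up to averaging: every voxel-channel
#' value is the mean of all patch predictions covering it.
#'
#' @param X m x N patch matrix.
#' @param corners N x 3 1-based corner indices.
#' @param spatial Patch shape.
#' @param dim4 Output array dimensions (x, y, z, k).
#' @return 4D array; voxels covered by no patch are NA.
#' @export
patches_to_volume <- function(X, corners, spatial, dim4) {
  a <- as.integer(spatial)
  k <- dim4[4]
  acc <- array(0, dim = dim4)
  cnt <- array(0, dim = dim4[1:3])
  offs <- as.matrix(expand.grid(0:(a[1] - 1), 0:(a[2] - 1), 0:(a[3] - 1)))
  for (r in seq_len(nrow(offs))) {
    ind3 <- cbind(corners[, 1] + offs[r, 1], corners[, 2] + offs[r, 2],
                  corners[, 3] + offs[r, 3])
    cnt[ind3] <- cnt[ind3] + 1
    for (j in seq_len(k)) {
      row_idx <- (j - 1) * prod(a) + r
      ind4 <- cbind(ind3, j)
      acc[ind4] <- acc[ind4] + X[row_idx, ]
    }
  }
  cnt[cnt == 0] <- NA
  for (j in seq_len(k)) acc[, , , j] <- acc[, , , j] / cnt
  acc
}

#' Learn an over-complete non-negative sparse dictionary
#'
#' Minimises sum_n ||X_n - D alpha_n||^2 + lambda ||alpha_n||_1 subject to
#' unit-norm dictionary columns and alpha_n >= 0, by alternating
#' optimisation: the code step is non-negative lasso by cyclic coordinate
#' descent; the dictionary step applies blockwise-optimal unit-norm column
#' updates at fixed codes. Each iteration works on a random batch of
#' patches; with `batch = N` every iteration uses all patches and the
#' objective is non-increasing across alternations. The dictionary has
#' `p = 2 m` atoms (twice over-complete) initialised from randomly drawn
#' patches; atoms unused in a batch are re-seeded from random patches.
#'
#' @param patches A [extract_patches()] `patch_set`, or an m x N matrix.
#' @param lambda Sparsity weight (> 0).
#' @param iterations Alternations (default 1000).
#' @param batch Patches per iteration (default 128, capped at N).
#' @param seed Integer seed for initialisation and batch sampling.
#' @param p Number of atoms; default `2 * m`.
#' @param max_sweeps,tol Coordinate-descent stopping rule (relative change
#'   below `tol` or `max_sweeps` sweeps).
#' @return Object of class `sdl_dictionary`: `D` (m x p, unit-norm
#'   columns), `lambda`, `spatial`, `n_channels`, `objective` trace (batch
#'   objective per iteration), `n_reseeded`, `seed`.
#' @export
learn_dictionary <- function(patches, lambda, iterations = 1000L,
                             batch = 128L, seed = 1L, p = NULL,
                             max_sweeps = 200L, tol = 1e-7) {
  X <- if (inherits(patches, "patch_set")) patches$X else as.matrix(patches)
  if (lambda <= 0) stop("lambda must be > 0")
  m <- nrow(X); N <- ncol(X)
  if (is.null(p)) p <- 2L * m
  batch <- min(as.integer(batch), N)
  rng <- .seeded_rng(seed)
  draw <- function(k) pmin(floor(rng$unif(k) * N) + 1L, N)
  D <- X[, draw(p), drop = FALSE]
  D <- .normalise_atoms(D, X, draw)
  objective <- numeric(iterations)
  n_reseeded <- 0L
  A_warm <- NULL # full-batch mode: warm start guarantees monotonicity
  full_batch <- batch == N
  if (!full_batch) { # online mode: accumulated sufficient statistics
    Acc <- matrix(0, p, p)
    Bcc <- matrix(0, m, p)
  }
  # exploration phase: discount old statistics and replace weak atoms;
  # stabilisation phase (last quarter): plain averaging, no replacement
  explore_until <- floor(0.75 * iterations)
  n_update_passes <- if (p > 1000L) 1L else 3L # m p^2 cost per pass
  for (it in seq_len(iterations)) {
    idx <- if (full_batch) seq_len(N) else draw(batch)
    Xb <- X[, idx, drop = FALSE]
    G <- crossprod(D) # shared by the coder and the support refit
    A <- .cpp_nnlasso(D, Xb, lambda, max_sweeps, tol, A_warm, G)
    if (full_batch) {
      A_warm <- A
      upd <- .cpp_dict_update(D, Xb, A)
      D <- upd$D
      reseed <- upd$dead
    } else {
      forget <- if (it <= explore_until) 0.98 else 1
      # dictionary statistics use support-refitted (debiased) codes so the
      # atom directions are not dragged by the lasso shrinkage
      Adb <- .cpp_nnls_refit(D, Xb, A, gram = G)
      Acc <- forget * Acc + tcrossprod(Adb)
      Bcc <- forget * Bcc + tcrossprod(Xb, Adb)
      for (pass in seq_len(n_update_passes)) {
        upd <- .cpp_dict_update_stats(D, Acc, Bcc)
        D <- upd$D
      }
      reseed <- upd$dead
      if (it %% 5 == 0 && it <= explore_until) {
        # near-duplicate atoms carry no extra representation power:
        # fold each pair and re-seed one member
        C <- abs(crossprod(D)); diag(C) <- 0
        kept <- rep(FALSE, p)
        for (j in order(-apply(C, 2, max))) {
          if (max(C[, j]) > 0.99 && !kept[j]) {
            kept[which.max(C[, j])] <- TRUE
            reseed <- c(reseed, j)
          }
        }
      }
    }
    reseed <- unique(reseed)
    if (length(reseed) > 0) {
      # re-seed from the worst-reconstructed patches of the batch
      err <- colSums((Xb - D %*% A)^2)
      src <- idx[order(-err)][seq_along(reseed)]
      src[is.na(src)] <- draw(sum(is.na(src)))
      D[, reseed] <- X[, src, drop = FALSE]
      D <- .normalise_atoms(D, X, draw, cols = reseed)
      if (!full_batch) {
        Acc[reseed, ] <- 0; Acc[, reseed] <- 0; Bcc[, reseed] <- 0
      }
      n_reseeded <- n_reseeded + length(reseed)
    }
    R <- Xb - D %*% A
    objective[it] <- sum(R^2) + lambda * sum(A)
  }
  structure(list(D = D, lambda = lambda,
                 spatial = if (inherits(patches, "patch_set"))
                   patches$spatial else NULL,
                 n_channels = if (inherits(patches, "patch_set"))
                   patches$n_channels else NULL,
                 objective = objective, n_reseeded = n_reseeded,
                 iterations = iterations, batch = batch, seed = seed),
            class = "sdl_dictionary")
}

.normalise_atoms <- function(D, X, draw, cols = seq_len(ncol(D))) {
  for (j in cols) {
    nj <- sqrt(sum(D[, j]^2))
    tries <- 0
    while (nj < 1e-10 && tries < 50) { # all-zero patch drawn: redraw
      D[, j] <- X[, draw(1)]
      nj <- sqrt(sum(D[, j]^2))
      tries <- tries + 1
    }
    if (nj < 1e-10) {
      D[, j] <- stats::rnorm(nrow(D)) # degenerate all-zero data
      nj <- sqrt(sum(D[, j]^2))
    }
    D[, j] <- D[, j] / nj
  }
  D
}

#' @export
print.sdl_dictionary <- function(x, ...) {
  cat("<sdl_dictionary> ", nrow(x$D), " x ", ncol(x$D),
      " atoms; lambda = ", x$lambda, "; final batch objective = ",
      signif(utils::tail(x$objective, 1), 4), "\n", sep = "")
  invisible(x)
}

#' Sparse-code patches on a dictionary
#'
#' Non-negative lasso coding of each column of `X` at fixed dictionary.
#'
#' @param dict An `sdl_dictionary` (or plain matrix D).
#' @param X m x N patch matrix (or `patch_set`).
#' @param lambda Sparsity weight; default the dictionary's.
#' @param debias Refit the selected support by non-negative least squares
#'   (removes the lasso shrinkage from the reconstruction).
#' @param max_sweeps,tol Coordinate-descent controls.
#' @return p x N non-negative code matrix.
#' @export
sdl_code <- function(dict, X, lambda = NULL, debias = FALSE,
                     max_sweeps = 200L, tol = 1e-7) {
  D <- if (inherits(dict, "sdl_dictionary")) dict$D else as.matrix(dict)
  if (is.null(lambda)) lambda <- dict$lambda
  if (inherits(X, "patch_set")) X <- X$X
  A <- .cpp_nnlasso(D, as.matrix(X), lambda, max_sweeps, tol, NULL)
  if (debias) A <- .cpp_nnls_refit(D, as.matrix(X), A)
  A
}

#' Select the sparsity weight by AIC
#'
#' For each lambda in the grid, learns a dictionary, codes all patches and
#' evaluates AIC = N m ln(RSS / (N m)) + 2 nnz, with nnz the number of
#' non-zero code entries (the degrees of freedom of the sparse model).
#' Ties are broken toward the larger (sparser) lambda. A degenerate
#' RSS = 0 fit returns the largest lambda achieving it.
#'
#' @param patches `patch_set` or m x N matrix.
#' @param lambda_grid Positive candidate values.
#' @param iterations,batch,seed Passed to [learn_dictionary()].
#' @return List: `lambda` (the argmin), `table` (tibble with lambda, rss,
#'   nnz, aic).
#' @export
select_lambda_aic <- function(patches, lambda_grid, iterations = 200L,
                              batch = 128L, seed = 1L) {
  X <- if (inherits(patches, "patch_set")) patches$X else as.matrix(patches)
  if (length(lambda_grid) == 0 || any(lambda_grid <= 0)) {
    stop("lambda_grid must be non-empty and positive")
  }
  m <- nrow(X); N <- ncol(X)
  rows <- lapply(lambda_grid, function(lam) {
    dict <- learn_dictionary(X, lam, iterations = iterations, batch = batch,
                             seed = seed)
    A <- sdl_code(dict, X)
    rss <- sum((X - dict$D %*% A)^2)
    nnz <- sum(A != 0)
    aic <- if (rss <= 0) -Inf else N * m * log(rss / (N * m)) + 2 * nnz
    tibble::tibble(lambda = lam, rss = rss, nnz = nnz, aic = aic)
  })
  tab <- dplyr::bind_rows(rows)
  # argmin AIC; ties (including RSS = 0 degeneracy) toward larger lambda
  best <- tab$lambda[tab$aic <= min(tab$aic) + 1e-12]
  list(lambda = max(best), table = tab)
}

#' Train the matched-resolution SDL harmoniser
#'
#' Learns the sparse dictionary from target-scanner acquisitions: each
#' image is reduced to the fixed angular channels, standardised per image
#' and per channel, cut into `spatial` patches and pooled; the dictionary
#' is then learned on the pooled patches. The recorded target channel
#' statistics (averaged over training images) are used to un-standardise
#' predictions, which is what maps source intensities into the target
#' scanner's frame.
#'
#' @param stacks List of target [dwi_stack()]s (training subjects).
#' @param masks List of 3D masks (same order).
#' @param src_stacks Optional list of co-registered source-protocol
#'   [dwi_stack()]s for the same training subjects. When given, the model
#'   records the average source channel statistics as well, and prediction
#'   maps each test subject's own statistics through the training-set
#'   source-to-target ratio instead of imposing the training-average
#'   target statistics (which would erase subject-level variation).
#' @param lambda Sparsity weight, or `NULL` to select by
#'   [select_lambda_aic()] over `lambda_grid`.
#' @param lambda_grid Grid used when `lambda` is `NULL`.
#' @param spatial Patch shape (default 3 x 3 x 3).
#' @param channel_dirs Angular channel directions.
#' @param order,lambda_sh SH settings for channel computation.
#' @param iterations,batch,seed Dictionary-learning controls.
#' @return Object of class `sdl_model`: the dictionary plus channel
#'   geometry and target standardisation statistics.
#' @export
sdl_train <- function(stacks, masks, lambda = NULL,
                      lambda_grid = c(0.05, 0.1, 0.2, 0.4),
                      spatial = c(3, 3, 3),
                      channel_dirs = sdl_channel_dirs(),
                      order = 4, lambda_sh = 0.006,
                      iterations = 1000L, batch = 128L, seed = 1L,
                      src_stacks = NULL) {
  pooled <- .pool_patches(stacks, masks, spatial, channel_dirs, order,
                          lambda_sh)
  src_stats <- NULL
  if (!is.null(src_stacks)) {
    src_list <- lapply(seq_along(src_stacks), function(i) {
      ch <- dwi_channels(src_stacks[[i]], masks[[i]],
                         channel_dirs = channel_dirs, order = order,
                         lambda = lambda_sh)
      .channel_stats(ch$channels)
    })
    src_stats <- Reduce(`+`, src_list) / length(src_list)
    colnames(src_stats) <- c("mean", "sd")
  }
  if (is.null(lambda)) {
    sel <- select_lambda_aic(pooled$X, lambda_grid,
                             iterations = min(iterations, 200L),
                             batch = batch, seed = seed)
    lambda <- sel$lambda
  }
  dict <- learn_dictionary(pooled$X, lambda, iterations = iterations,
                           batch = batch, seed = seed)
  dict$spatial <- as.integer(spatial)
  dict$n_channels <- nrow(.as_dir_matrix(channel_dirs))
  structure(list(dict = dict, channel_dirs = .as_dir_matrix(channel_dirs),
                 order = order, lambda_sh = lambda_sh,
                 target_stats = pooled$mean_stats,
                 src_stats = src_stats,
                 spatial = as.integer(spatial), task = "matched",
                 seed = seed),
            class = "sdl_model")
}

.pool_patches <- function(stacks, masks, spatial, channel_dirs, order,
                          lambda_sh) {
  stopifnot(length(stacks) == length(masks))
  stats_list <- list()
  X_list <- list()
  for (i in seq_along(stacks)) {
    ch <- dwi_channels(stacks[[i]], masks[[i]], channel_dirs = channel_dirs,
                       order = order, lambda = lambda_sh)
    st <- .channel_stats(ch$channels)
    stats_list[[i]] <- st
    std <- .apply_standardise(ch$channels, st)
    ps <- extract_patches(std, masks[[i]], spatial = spatial)
    X_list[[i]] <- ps$X
  }
  mean_stats <- Reduce(`+`, stats_list) / length(stats_list)
  colnames(mean_stats) <- c("mean", "sd")
  list(X = do.call(cbind, X_list), mean_stats = mean_stats)
}

#' @export
print.sdl_model <- function(x, ...) {
  cat("<sdl_model> task = ", x$task, "; patches ",
      paste(x$spatial, collapse = "x"), " x ", length(x$channel_dirs[, 1]),
      " channels; lambda = ", x$dict$lambda, "\n", sep = "")
  invisible(x)
}

# per-subject output statistics: with recorded source-training statistics
# the training source-to-target ratio is applied to the subject's own
# statistics; otherwise the training-average target statistics are used
.transfer_stats <- function(model, subject_src_stats) {
  if (is.null(model$src_stats)) return(model$target_stats)
  out <- subject_src_stats * (model$target_stats / model$src_stats)
  colnames(out) <- c("mean", "sd")
  out
}

# minimum-norm SH coefficient update matching predicted channel values:
# c' = c + (y - B c) (B B')^{-1} B, rowwise over voxels — the smallest
# coefficient change consistent with the predicted channels
.sh_minnorm_update <- function(coefs, channel_dirs, y) {
  L <- attr(coefs, "order")
  B <- sh_basis(channel_dirs, L)
  M <- tcrossprod(B)
  pred <- unclass(coefs) %*% t(B)
  upd <- (y - pred) %*% solve(M, B)
  out <- unclass(coefs) + upd
  attr(out, "order") <- L
  class(out) <- c("sh_coefs", class(out))
  out
}

#' Matched-resolution harmonisation with a trained SDL model
#'
#' Each source patch (standardised with the source image's own channel
#' statistics) is sparse-coded on the target dictionary, reconstructed as
#' D alpha, un-standardised with the model's recorded target statistics,
#' and overlap-averaged per voxel. The corrected channel values then drive
#' a minimum-norm update of the source SH field, which is resampled at the
#' target gradient directions and re-scaled by the source mean b = 0
#' signal. Voxels not covered by any full patch fall back to the
#' channel-statistics mapping alone (counted in `n_uncovered`).
#'
#' @param src Source [dwi_stack()] on the target grid.
#' @param model An `sdl_model` from [sdl_train()].
#' @param target_scheme Output [gradient_scheme()]; default the source's.
#' @param mask Optional 3D 0/1 array.
#' @param lambda Coding sparsity weight; default the model's training
#'   lambda. A smaller value with `debias = TRUE` reconstructs more
#'   faithfully ("unscaled" coefficients).
#' @param debias Support-refit the codes before reconstruction.
#' @return Predicted [dwi_stack()]; attribute `n_uncovered`.
#' @export
harmonise_matched <- function(src, model, target_scheme = src$scheme,
                              mask = NULL, lambda = NULL, debias = TRUE) {
  ch <- dwi_channels(src, mask, channel_dirs = model$channel_dirs,
                     order = model$order, lambda = model$lambda_sh)
  k <- dim(ch$channels)[4]
  if (k != model$dict$n_channels) {
    stop("source has ", k, " channels but the model was trained with ",
         model$dict$n_channels)
  }
  src_stats <- .channel_stats(ch$channels)
  out_stats <- .transfer_stats(model, src_stats)
  std <- .apply_standardise(ch$channels, src_stats)
  ps <- extract_patches(std, mask, spatial = model$spatial)
  A <- sdl_code(model$dict, ps$X, lambda = lambda, debias = debias)
  recon <- model$dict$D %*% A
  vol_std <- patches_to_volume(recon, ps$corners, model$spatial,
                               dim4 = dim(ch$channels))
  vol <- .undo_standardise(vol_std, out_stats)
  # fallback for in-mask voxels no full patch covered: stats mapping only
  fallback <- .undo_standardise(std, out_stats)
  n_uncovered <- 0L
  for (j in seq_len(k)) {
    v <- vol[, , , j]
    miss <- is.na(v) & is.finite(fallback[, , , j])
    if (j == 1) n_uncovered <- sum(miss)
    v[miss] <- fallback[, , , j][miss]
    vol[, , , j] <- v
  }
  # corrected channel values at the fitted voxels
  lin <- ch$voxels[, 1] + (ch$voxels[, 2] - 1L) * dim(vol)[1] +
    (ch$voxels[, 3] - 1L) * dim(vol)[1] * dim(vol)[2]
  y <- vapply(seq_len(k), function(j) {
    as.vector(vol[, , , j])[lin]
  }, numeric(length(lin)))
  coefs <- .sh_minnorm_update(ch$coefs, model$channel_dirs, y)
  out <- .stack_from_coefs(coefs, ch$voxels, ch$b0, src, target_scheme,
                           grid_geometry(src))
  attr(out, "n_uncovered") <- n_uncovered
  out
}

# build a dwi_stack on `grid` from per-voxel SH coefs + b0 values
.stack_from_coefs <- function(coefs, voxels, b0, src, scheme, grid) {
  t_dwi <- which(!is_b0(scheme))
  pred <- sh_resample(coefs, scheme$bvecs[t_dwi, , drop = FALSE])
  nvol <- length(scheme$bvals)
  out <- array(0, dim = c(grid$dim, nvol))
  for (j in seq_along(t_dwi)) {
    out[cbind(voxels, t_dwi[j])] <- pmax(pred[, j] * b0, 0)
  }
  for (j in which(is_b0(scheme))) out[cbind(voxels, j)] <- b0
  dwi_stack(out, scheme, voxel_size = grid$voxel_size, affine = grid$affine)
}

#' Block-average downsampling of a high-resolution dictionary
#'
#' Maps each atom from the high-resolution patch lattice (shape
#' `factor * spatial_low` per axis, same channels) onto the low-resolution
#' lattice by averaging `factor^3` blocks, channel by channel.
#'
#' @param D m_high x p dictionary matrix.
#' @param spatial_high High-resolution patch shape.
#' @param factor Integer per-axis ratio between the lattices.
#' @param n_channels Angular channel count.
#' @return m_low x p matrix.
#' @export
downsample_dictionary <- function(D, spatial_high, factor, n_channels) {
  a_h <- as.integer(spatial_high)
  if (any(a_h %% factor != 0)) {
    stop("incompatible patch-size pair: ", paste(a_h, collapse = "x"),
         " does not divide by factor ", factor)
  }
  a_l <- a_h %/% factor
  m_l <- prod(a_l) * n_channels
  P <- matrix(0, m_l, nrow(D))
  offs_l <- as.matrix(expand.grid(0:(a_l[1] - 1), 0:(a_l[2] - 1),
                                  0:(a_l[3] - 1)))
  offs_b <- as.matrix(expand.grid(0:(factor - 1), 0:(factor - 1),
                                  0:(factor - 1)))
  for (j in seq_len(n_channels)) {
    for (r in seq_len(nrow(offs_l))) {
      row_l <- (j - 1) * prod(a_l) + r
      for (s in seq_len(nrow(offs_b))) {
        hx <- offs_l[r, 1] * factor + offs_b[s, 1]
        hy <- offs_l[r, 2] * factor + offs_b[s, 2]
        hz <- offs_l[r, 3] * factor + offs_b[s, 3]
        row_h <- (j - 1) * prod(a_h) +
          hx + hy * a_h[1] + hz * a_h[1] * a_h[2] + 1
        P[row_l, row_h] <- 1 / nrow(offs_b)
      }
    }
  }
  P %*% D
}

#' Train the super-resolution SDL harmoniser
#'
#' Learns the dictionary on high-resolution target acquisitions with
#' patches of shape `spatial_high` (= `factor` times the low-resolution
#' 3 x 3 x 3 patch per axis). At prediction time codes are computed on the
#' block-average-downsampled dictionary and reconstruction uses the
#' original high-resolution dictionary.
#'
#' @inheritParams sdl_train
#' @param spatial_high High-res patch shape (default 6 x 6 x 6).
#' @param factor Integer resolution ratio (default 2).
#' @return An `sdl_model` with `task = "superres"`.
#' @export
sdl_train_superres <- function(stacks, masks, lambda = NULL,
                               lambda_grid = c(0.05, 0.1, 0.2, 0.4),
                               spatial_high = c(6, 6, 6), factor = 2L,
                               channel_dirs = sdl_channel_dirs(),
                               order = 4, lambda_sh = 0.006,
                               iterations = 1000L, batch = 128L,
                               seed = 1L, src_stacks = NULL) {
  if (any(as.integer(spatial_high) %% factor != 0)) {
    stop("incompatible patch-size pair: spatial_high must divide by factor")
  }
  model <- sdl_train(stacks, masks, lambda = lambda,
                     lambda_grid = lambda_grid, spatial = spatial_high,
                     channel_dirs = channel_dirs, order = order,
                     lambda_sh = lambda_sh, iterations = iterations,
                     batch = batch, seed = seed)
  if (!is.null(src_stacks)) {
    src_list <- lapply(seq_along(src_stacks), function(i) {
      msk <- attr(src_stacks[[i]], "mask")
      ch <- dwi_channels(src_stacks[[i]], msk, channel_dirs = channel_dirs,
                         order = order, lambda = lambda_sh)
      .channel_stats(ch$channels)
    })
    model$src_stats <- Reduce(`+`, src_list) / length(src_list)
    colnames(model$src_stats) <- c("mean", "sd")
  }
  model$task <- "superres"
  model$factor <- as.integer(factor)
  model$D_low <- downsample_dictionary(model$dict$D, spatial_high, factor,
                                       nrow(.as_dir_matrix(channel_dirs)))
  model
}

#' Super-resolution harmonisation with a trained SDL model
#'
#' Source patches (3 x 3 x 3 at low resolution) are coded on the
#' downsampled dictionary; reconstruction uses the original
#' high-resolution dictionary, producing `factor`-times finer patches that
#' are overlap-averaged on the upsampled grid. Direction matching uses the
#' truncated SH basis: the source SH field is trilinearly upsampled, given
#' a minimum-norm update to the predicted channel values, and resampled at
#' the target directions.
#'
#' @param src Low-resolution source [dwi_stack()].
#' @param model An `sdl_model` from [sdl_train_superres()].
#' @param target_scheme Output [gradient_scheme()].
#' @param mask Optional low-resolution 3D mask.
#' @return Predicted [dwi_stack()] on the `factor`-upsampled grid.
#' @export
harmonise_superres <- function(src, model, target_scheme, mask = NULL) {
  if (!identical(model$task, "superres")) {
    stop("model was not trained for super-resolution")
  }
  f <- model$factor
  a_h <- model$spatial
  a_l <- a_h %/% f
  ch <- dwi_channels(src, mask, channel_dirs = model$channel_dirs,
                     order = model$order, lambda = model$lambda_sh)
  k <- dim(ch$channels)[4]
  src_stats <- .channel_stats(ch$channels)
  out_stats <- .transfer_stats(model, src_stats)
  std <- .apply_standardise(ch$channels, src_stats)
  ps <- extract_patches(std, mask, spatial = a_l)
  A <- .cpp_nnlasso(model$D_low, ps$X, model$dict$lambda, 200L, 1e-7, NULL,
                    NULL)
  # support refit on the downsampled dictionary removes the lasso
  # shrinkage ("unscaled" coefficients) before high-resolution synthesis
  A <- .cpp_nnls_refit(model$D_low, ps$X, A)
  recon <- model$dict$D %*% A # high-resolution patches
  grid_h <- upsample_grid(grid_geometry(src), f)
  corners_h <- (ps$corners - 1L) * f + 1L
  vol_std <- patches_to_volume(recon, corners_h, a_h,
                               dim4 = c(grid_h$dim, k))
  vol <- .undo_standardise(vol_std, out_stats)
  # high-resolution base field: trilinear upsampling of SH coefs and b0
  sd3 <- spatial_dim(src)
  cov3 <- !is.na(vol[, , , 1])
  vox_h <- which(cov3, arr.ind = TRUE)
  pts <- .voxel_to_voxel(grid_h, src$affine, vox_h - 1L)
  ncoef <- ncol(ch$coefs)
  coef_vols <- lapply(seq_len(ncoef), function(j)
    .scatter_map(unclass(ch$coefs)[, j], ch$voxels, sd3, fill = 0))
  b0_vol <- .scatter_map(ch$b0, ch$voxels, sd3, fill = 0)
  coefs_h <- vapply(coef_vols, function(v) trilinear_interp(v, pts),
                    numeric(nrow(pts)))
  attr(coefs_h, "order") <- attr(ch$coefs, "order")
  class(coefs_h) <- c("sh_coefs", class(coefs_h))
  b0_h <- trilinear_interp(b0_vol, pts)
  y <- vapply(seq_len(k), function(j) vol[, , , j][vox_h],
              numeric(nrow(vox_h)))
  coefs_h <- .sh_minnorm_update(coefs_h, model$channel_dirs, y)
  .stack_from_coefs(coefs_h, vox_h, b0_h, src, target_scheme, grid_h)
}

#' Save / load a harmonisation model archive
#'
#' Serialises the model (dictionary or network, geometry, standardisation
#' statistics, seeds, package version) to a single file.
#'
#' @param model An `sdl_model` or `shnet_model`.
#' @param path Output path.
#' @return `path` (write) or the model (read), invisibly/visibly.
#' @export
save_model <- function(model, path) {
  model$dwiharm_version <- as.character(utils::packageVersion("dwiharm"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
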