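#' Training configuration for the voxel-wise SH network
#'
#' Defaults follow the published schedule: Adam (learning rate 0.001,
#' batch 128) for the first five epochs, then plain SGD at the inherited
#' learning rate; the learning rate is multiplied by 0.9 whenever the
#' validation loss fails to improve for more than `plateau` epochs. One of
#' the training subjects is held out as the validation subject (9/1 split
#' for ten subjects).
#'
#' @param lr Initial learning rate (> 0).
#' @param batch Mini-batch size.
#' @param switch_epoch Epoch after which Adam is replaced by SGD.
#' @param plateau Non-improving epochs tolerated before the learning rate
#'   is reduced.
#' @param lr_factor Multiplicative learning-rate decay (0.9 = "decreased
#'   by ten percent").
#' @param epochs Maximum epochs.
#' @param early_stop Stop after this many consecutive non-improving
#'   validation epochs.
#' @param sgd_lr Learning rate for the SGD phase (the published schedule
#'   names the optimiser switch but no SGD step size; plain SGD on a
#'   batch-normalised network supports a much larger step than Adam).
#' @param sgd_momentum Heavy-ball momentum for the SGD phase; averages
#'   the batch-statistics gradient noise.
#' @param seed Integer seed controlling initialisation and shuffling.
#' @return List of class `shnet_config`.
#' @export
shnet_config <- function(lr = 0.001, batch = 128L, switch_epoch = 5L,
                         plateau = 5L, lr_factor = 0.9, epochs = 100L,
                         early_stop = 20L, sgd_lr = 0.1,
                         sgd_momentum = 0.9, seed = 1L) {
  stopifnot(lr > 0, sgd_lr > 0, lr_factor > 0, lr_factor <= 1,
            sgd_momentum >= 0, sgd_momentum < 1)
  structure(list(lr = lr, batch = as.integer(batch),
                 switch_epoch = as.integer(switch_epoch),
                 plateau = as.integer(plateau), lr_factor = lr_factor,
                 epochs = as.integer(epochs),
                 early_stop = as.integer(early_stop),
                 sgd_lr = sgd_lr, sgd_momentum = sgd_momentum,
                 seed = as.integer(seed)),
            class = "shnet_config")
}

# network topology: BN -> FC(d->150)+ReLU -> BN -> FC+ReLU -> BN ->
# FC+ReLU -> BN -> FC(150->d). He-initialised weights, BN gamma=1 beta=0.
shnet_init <- function(n_coef = 15L, hidden = 150L, seed = 1L) {
  rng <- .seeded_rng(seed + 7L)
  widths <- c(n_coef, hidden, hidden, hidden, n_coef)
  layers <- list()
  for (i in 1:4) {
    d_in <- widths[i]; d_out <- widths[i + 1]
    layers[[2 * i - 1]] <- list(
      type = "bn", gamma = rep(1, d_in), beta = rep(0, d_in),
      run_mean = rep(0, d_in), run_var = rep(1, d_in), momentum = 0.1,
      eps = 1e-5)
    layers[[2 * i]] <- list(
      type = "fc",
      W = matrix(rng$norm(d_in * d_out) * sqrt(2 / d_in), d_in, d_out),
      b = rep(0, d_out),
      relu = i < 4)
    }
  structure(list(layers = layers, n_coef = n_coef, hidden = hidden),
            class = "shnet_net")
}

# fast column-wise ops (sweep() is an order of magnitude slower here)
.csub <- function(H, v) H - rep(v, each = nrow(H))
.cmul <- function(H, v) H * rep(v, each = nrow(H))
.caff <- function(H, scale, shift) {
  H * rep(scale, each = nrow(H)) + rep(shift, each = nrow(H))
}

# exact batch-norm recalibration: recompute every BN layer's population
# mean/variance over the full data set with frozen weights (removes the
# noise of the EMA running estimates)
.shnet_recalibrate <- function(net, X) {
  H <- X
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "bn") {
      mu <- colMeans(H)
      v <- colMeans(.csub(H, mu)^2) * nrow(H) / max(nrow(H) - 1, 1)
      net$layers[[i]]$run_mean <- mu
      net$layers[[i]]$run_var <- v
      Xhat <- .cmul(.csub(H, mu), 1 / sqrt(v + ly$eps))
      H <- .caff(Xhat, ly$gamma, ly$beta)
    } else {
      Z <- .csub(H %*% ly$W, -ly$b)
      H <- if (ly$relu) Z * (Z > 0) else Z
    }
  }
  net
}

# backward pass with frozen BN statistics: normalisation is a fixed
# affine map, so no batch-statistics correction terms appear
.shnet_backward_frozen <- function(net, cache, dOut) {
  grads <- vector("list", length(net$layers))
  dH <- dOut
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    cc <- cache[[i]]
    if (ly$type == "fc") {
      dZ <- if (ly$relu) dH * (cc$Z > 0) else dH
      grads[[i]] <- list(W = crossprod(cc$X, dZ), b = colSums(dZ))
      dH <- dZ %*% t(ly$W)
    } else {
      grads[[i]] <- list(gamma = colSums(dH * cc$Xhat), beta = colSums(dH))
      dH <- .cmul(dH, ly$gamma * cc$inv_sd)
    }
  }
  grads
}

# flatten / restore trainable parameters (BN statistics excluded)
.shnet_flatten <- function(net) {
  unlist(lapply(net$layers, function(ly)
    lapply(ly[.shnet_params(ly)], as.numeric)), use.names = FALSE)
}

.shnet_unflatten <- function(net, par) {
  pos <- 1L
  for (i in seq_along(net$layers)) {
    for (p in .shnet_params(net$layers[[i]])) {
      len <- length(net$layers[[i]][[p]])
      val <- par[pos:(pos + len - 1L)]
      if (is.matrix(net$layers[[i]][[p]])) {
        dim(val) <- dim(net$layers[[i]][[p]])
      }
      net$layers[[i]][[p]] <- val
      pos <- pos + len
    }
  }
  net
}

# deterministic fine-tuning of the deployed function: full-batch L-BFGS
# with BN statistics frozen at their recalibrated population values,
# validated between chunks. Removes the bias left by optimising under
# batch-statistics noise (the training-mode network is not the network
# used at prediction).
.shnet_polish <- function(net, Xtr, Ttr, Xva, Tva, chunks = 6L,
                          chunk_iter = 100L) {
  fc_idx <- which(vapply(net$layers, `[[`, "", "type") == "fc")
  bn_idx <- fc_idx - 1L # each FC is preceded by its BN layer
  scales <- lapply(bn_idx, function(i) {
    ly <- net$layers[[i]]
    ly$gamma / sqrt(ly$run_var + ly$eps)
  })
  shifts <- lapply(seq_along(bn_idx), function(k) {
    ly <- net$layers[[bn_idx[k]]]
    ly$beta - ly$run_mean * scales[[k]]
  })
  pack <- function(n2) {
    unlist(lapply(fc_idx, function(i)
      c(as.numeric(n2$layers[[i]]$W), n2$layers[[i]]$b)),
      use.names = FALSE)
  }
  unpack <- function(par) {
    Ws <- list(); bs <- list(); pos <- 1L
    for (k in seq_along(fc_idx)) {
      W0 <- net$layers[[fc_idx[k]]]$W
      nW <- length(W0)
      Ws[[k]] <- matrix(par[pos:(pos + nW - 1L)], nrow(W0), ncol(W0))
      pos <- pos + nW
      nb <- length(net$layers[[fc_idx[k]]]$b)
      bs[[k]] <- par[pos:(pos + nb - 1L)]
      pos <- pos + nb
    }
    list(Ws = Ws, bs = bs)
  }
  loss_fn <- function(par) {
    p <- unpack(par)
    .cpp_mlp_loss_grad(p$Ws, p$bs, scales, shifts, Xtr, Ttr,
                       want_grad = FALSE)$loss
  }
  grad_fn <- function(par) {
    p <- unpack(par)
    g <- .cpp_mlp_loss_grad(p$Ws, p$bs, scales, shifts, Xtr, Ttr)
    unlist(lapply(seq_along(g$gW), function(k)
      c(as.numeric(g$gW[[k]]), as.numeric(g$gb[[k]]))),
      use.names = FALSE)
  }
  val_of <- function(par) {
    p <- unpack(par)
    .cpp_mlp_loss_grad(p$Ws, p$bs, scales, shifts, Xva, Tva,
                       want_grad = FALSE)$loss
  }
  par <- pack(net)
  best_par <- par
  best_val <- val_of(par)
  bad <- 0L
  for (ch in seq_len(chunks)) {
    opt <- stats::optim(par, loss_fn, grad_fn, method = "L-BFGS-B",
                        control = list(maxit = chunk_iter))
    par <- opt$par
    val <- val_of(par)
    if (val < best_val) {
      best_val <- val; best_par <- par; bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= 2L) break
    }
    if (opt$convergence == 0) break # local optimum reached
  }
  p <- unpack(best_par)
  for (k in seq_along(fc_idx)) {
    net$layers[[fc_idx[k]]]$W <- p$Ws[[k]]
    net$layers[[fc_idx[k]]]$b <- p$bs[[k]]
  }
  list(net = net, val = best_val)
}

# forward pass; training=TRUE uses batch statistics and returns a cache
.shnet_forward <- function(net, X, training = FALSE) {
  cache <- list()
  H <- X
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    if (ly$type == "bn") {
      if (training) {
        mu <- colMeans(H)
        v <- colMeans(.csub(H, mu)^2)
        net$layers[[i]]$run_mean <- (1 - ly$momentum) * ly$run_mean +
          ly$momentum * mu
        net$layers[[i]]$run_var <- (1 - ly$momentum) * ly$run_var +
          ly$momentum * v * nrow(H) / max(nrow(H) - 1, 1)
      } else {
        mu <- ly$run_mean
        v <- ly$run_var
      }
      inv_sd <- 1 / sqrt(v + ly$eps)
      Xhat <- .cmul(.csub(H, mu), inv_sd)
      cache[[i]] <- list(X = H, Xhat = Xhat, inv_sd = inv_sd)
      H <- .caff(Xhat, ly$gamma, ly$beta)
    } else {
      Z <- .csub(H %*% ly$W, -ly$b)
      A <- if (ly$relu) Z * (Z > 0) else Z
      cache[[i]] <- list(X = H, Z = Z)
      H <- A
    }
  }
  list(out = H, cache = cache, net = net)
}

# backward pass: returns gradient list parallel to layers
.shnet_backward <- function(net, cache, dOut) {
  grads <- vector("list", length(net$layers))
  dH <- dOut
  for (i in rev(seq_along(net$layers))) {
    ly <- net$layers[[i]]
    cc <- cache[[i]]
    if (ly$type == "fc") {
      dZ <- if (ly$relu) dH * (cc$Z > 0) else dH
      grads[[i]] <- list(W = crossprod(cc$X, dZ), b = colSums(dZ))
      dH <- dZ %*% t(ly$W)
    } else {
      n <- nrow(cc$X)
      dXhat <- .cmul(dH, ly$gamma)
      grads[[i]] <- list(gamma = colSums(dH * cc$Xhat), beta = colSums(dH))
      # batch-norm backward (batch statistics)
      dH <- .cmul(dXhat - rep(colMeans(dXhat), each = n) -
                    .cmul(cc$Xhat, colMeans(dXhat * cc$Xhat)),
                  cc$inv_sd)
    }
  }
  grads
}

.shnet_params <- function(ly) {
  if (ly$type == "fc") c("W", "b") else c("gamma", "beta")
}

#' Train the voxel-wise SH harmonisation network
#'
#' Fits the fully connected network (four BatchNorm/linear blocks, three
#' hidden ReLU layers of width 150) mapping source order-4 SH coefficient
#' vectors to target coefficients, minimising the mean squared coefficient
#' error. One subject is held out for validation; the weights with the
#' best validation loss are kept. Deterministic given `cfg$seed`.
#'
#' @param src_coefs N x n_coef matrix of source SH vectors.
#' @param tgt_coefs N x n_coef matrix of paired target SH vectors (same
#'   voxels, co-registered acquisitions).
#' @param subject_ids Length-N vector assigning voxels to subjects (>= 2
#'   subjects required for the split).
#' @param cfg A [shnet_config()].
#' @param hidden Hidden-layer width (default 150).
#' @return Object of class `shnet_model`: the network plus a training
#'   `history` tibble (epoch, phase, lr, train_loss, val_loss).
#' @export
shnet_train <- function(src_coefs, tgt_coefs, subject_ids,
                        cfg = shnet_config(), hidden = 150L) {
  X <- unclass(as.matrix(src_coefs)); Tt <- unclass(as.matrix(tgt_coefs))
  stopifnot(nrow(X) == nrow(Tt), nrow(X) == length(subject_ids))
  subs <- sort(unique(subject_ids))
  if (length(subs) < 2) stop("need >= 2 subjects to form a train/validation split")
  val_sub <- subs[length(subs)]
  val <- subject_ids == val_sub
  # per-coefficient z-scoring (training-set statistics, recorded in the
  # model archive); the network operates in standardised space
  x_stats <- list(mean = colMeans(X[!val, , drop = FALSE]),
                  sd = pmax(apply(X[!val, , drop = FALSE], 2, stats::sd),
                            1e-8))
  t_stats <- list(mean = colMeans(Tt[!val, , drop = FALSE]),
                  sd = pmax(apply(Tt[!val, , drop = FALSE], 2, stats::sd),
                            1e-8))
  zx <- function(M) .cmul(.csub(M, x_stats$mean), 1 / x_stats$sd)
  zt <- function(M) .cmul(.csub(M, t_stats$mean), 1 / t_stats$sd)
  X <- zx(X); Tt <- zt(Tt)
  Xtr <- X[!val, , drop = FALSE]; Ttr <- Tt[!val, , drop = FALSE]
  Xva <- X[val, , drop = FALSE]; Tva <- Tt[val, , drop = FALSE]
  net <- shnet_init(ncol(X), hidden, seed = cfg$seed)
  rng <- .seeded_rng(cfg$seed)
  # Adam state
  mstate <- vstate <- lapply(net$layers, function(ly)
    lapply(ly[.shnet_params(ly)], function(p) p * 0))
  adam_t <- 0
  lr <- cfg$lr
  n <- nrow(Xtr)
  d <- ncol(X)
  best_val <- Inf; best_net <- net
  bad_epochs <- 0L    # strict counter (early stopping)
  plateau_epochs <- 0L # relative counter (learning-rate decay)
  hist <- list()
  # averaged-SGD tail: uniform weight average over the last quarter of
  # the epoch budget damps the stochastic wander of the iterates
  avg_from <- max(cfg$switch_epoch + 1L, floor(0.75 * cfg$epochs) + 1L)
  avg_net <- NULL; avg_n <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    phase <- if (epoch <= cfg$switch_epoch) "adam" else "sgd"
    if (epoch == cfg$switch_epoch + 1L) lr <- cfg$sgd_lr
    perm <- order(rng$unif(n))
    ep_loss <- 0; nb <- 0
    for (start in seq(1, n, by = cfg$batch)) {
      idx <- perm[start:min(start + cfg$batch - 1, n)]
      if (length(idx) < 2) next # BN needs >= 2 samples
      fw <- .shnet_forward(net, Xtr[idx, , drop = FALSE], training = TRUE)
      net <- fw$net
      diff <- fw$out - Ttr[idx, , drop = FALSE]
      loss <- mean(diff^2)
      ep_loss <- ep_loss + loss; nb <- nb + 1
      dOut <- 2 * diff / length(diff)
      grads <- .shnet_backward(net, fw$cache, dOut)
      if (phase == "adam") {
        adam_t <- adam_t + 1
        b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8
        for (i in seq_along(net$layers)) {
          for (p in .shnet_params(net$layers[[i]])) {
            g <- grads[[i]][[p]]
            mstate[[i]][[p]] <- b1 * mstate[[i]][[p]] + (1 - b1) * g
            vstate[[i]][[p]] <- b2 * vstate[[i]][[p]] + (1 - b2) * g^2
            mhat <- mstate[[i]][[p]] / (1 - b1^adam_t)
            vhat <- vstate[[i]][[p]] / (1 - b2^adam_t)
            net$layers[[i]][[p]] <- net$layers[[i]][[p]] -
              lr * mhat / (sqrt(vhat) + aeps)
          }
        }
      } else {
        for (i in seq_along(net$layers)) {
          for (p in .shnet_params(net$layers[[i]])) {
            vel <- cfg$sgd_momentum * mstate[[i]][[p]] + grads[[i]][[p]]
            mstate[[i]][[p]] <- vel
            net$layers[[i]][[p]] <- net$layers[[i]][[p]] - lr * vel
          }
        }
      }
    }
    if (epoch >= avg_from) {
      if (is.null(avg_net)) {
        avg_net <- net
      } else {
        for (i in seq_along(net$layers)) {
          for (p in .shnet_params(net$layers[[i]])) {
            avg_net$layers[[i]][[p]] <- avg_net$layers[[i]][[p]] +
              net$layers[[i]][[p]]
          }
        }
      }
      avg_n <- avg_n + 1L
    }
    val_loss <- mean((.shnet_forward(.shnet_recalibrate(net, Xtr),
                                     Xva)$out - Tva)^2)
    hist[[epoch]] <- tibble::tibble(epoch = epoch, phase = phase, lr = lr,
                                    train_loss = ep_loss / max(nb, 1),
                                    val_loss = val_loss)
    improved <- val_loss < best_val
    # a "real" improvement must beat the best by a relative margin,
    # otherwise validation noise (batch-norm stochasticity) masks plateaus
    real_improvement <- val_loss < best_val * (1 - 1e-3)
    if (improved) {
      best_val <- val_loss
      best_net <- .shnet_recalibrate(net, Xtr)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= cfg$early_stop) break
    }
    plateau_epochs <- if (real_improvement) 0L else plateau_epochs + 1L
    if (epoch > cfg$switch_epoch && plateau_epochs > cfg$plateau) {
      lr <- lr * cfg$lr_factor
      plateau_epochs <- 0L # cooldown: re-arm the plateau detector
    }
  }
  if (!is.null(avg_net)) {
    for (i in seq_along(avg_net$layers)) {
      for (p in .shnet_params(avg_net$layers[[i]])) {
        avg_net$layers[[i]][[p]] <- avg_net$layers[[i]][[p]] / avg_n
      }
    }
    avg_net <- .shnet_recalibrate(avg_net, Xtr)
    avg_val <- mean((.shnet_forward(avg_net, Xva)$out - Tva)^2)
    if (avg_val < best_val) {
      best_net <- avg_net; best_val <- avg_val
    }
  }
  # cap the fine-tuning set so the deterministic phase stays cheap
  pr <- if (nrow(Xtr) > 4000) {
    seq(1, nrow(Xtr), length.out = 4000)
  } else {
    seq_len(nrow(Xtr))
  }
  pol <- .shnet_polish(best_net, Xtr[pr, , drop = FALSE],
                       Ttr[pr, , drop = FALSE], Xva, Tva)
  best_net <- pol$net; best_val <- pol$val
  # deterministic readout refit: with all earlier layers frozen in
  # population-statistics mode, the final fully connected layer is a
  # linear least-squares problem on the training set; solving it exactly
  # removes the residual bias left by training under batch-statistics
  # noise (same objective, one exact block-coordinate step)
  n_layers <- length(best_net$layers)
  H <- Xtr
  for (i in seq_len(n_layers - 1)) {
    ly <- best_net$layers[[i]]
    if (ly$type == "bn") {
      Xhat <- .cmul(.csub(H, ly$run_mean), 1 / sqrt(ly$run_var + ly$eps))
      H <- .caff(Xhat, ly$gamma, ly$beta)
    } else {
      Z <- .csub(H %*% ly$W, -ly$b)
      H <- if (ly$relu) Z * (Z > 0) else Z
    }
  }
  Haug <- cbind(H, 1)
  ridge <- diag(1e-8, ncol(Haug))
  Wb <- solve(crossprod(Haug) + ridge, crossprod(Haug, Ttr))
  best_net$layers[[n_layers]]$W <- Wb[-nrow(Wb), , drop = FALSE]
  best_net$layers[[n_layers]]$b <- Wb[nrow(Wb), ]
  best_val <- mean((.shnet_forward(best_net, Xva)$out - Tva)^2)
  structure(list(net = best_net, config = cfg,
                 x_stats = x_stats, t_stats = t_stats,
                 val_subject = val_sub, best_val = best_val,
                 history = dplyr::bind_rows(hist),
                 n_coef = ncol(X)),
            class = "shnet_model")
}

#' @export
print.shnet_model <- function(x, ...) {
  cat("<shnet_model> ", x$n_coef, " -> 150 x3 -> ", x$n_coef,
      "; best validation MSE = ", signif(x$best_val, 4), " after ",
      nrow(x$history), " epochs\n", sep = "")
  invisible(x)
}

#' Apply the network to SH coefficient vectors
#'
#' Inference mode: batch normalisation uses the stored population
#' (running) statistics, so prediction is purely voxel-wise and
#' permutation-equivariant.
#'
#' @param model A `shnet_model`.
#' @param coefs N x n_coef matrix.
#' @return N x n_coef matrix of mapped coefficients.
#' @export
shnet_apply <- function(model, coefs) {
  Z <- .cmul(.csub(unclass(as.matrix(coefs)), model$x_stats$mean),
             1 / model$x_stats$sd)
  out <- .shnet_forward(model$net, Z)$out
  .caff(out, model$t_stats$sd, model$t_stats$mean)
}

#' Per-voxel order-4 SH preprocessing for the network
#'
#' Divides each in-mask voxel's shell signals by its mean b = 0 signal and
#' converts them to order-4 SH coefficients with Laplace-Beltrami weight
#' 0.006 (15 coefficients per voxel). Voxels with unusable b0 are excluded
#' and counted.
#'
#' @param stack A [dwi_stack()].
#' @param mask 3D 0/1 array (training and prediction are mask-restricted).
#' @param order,lambda SH settings.
#' @return List: `coefs` (n_vox x 15), `voxels`, `b0`, `n_excluded_b0`.
#' @export
preprocess_voxels <- function(stack, mask = NULL, order = 4,
                              lambda = 0.006) {
  ns <- normalised_signals(stack, mask)
  coefs <- sh_fit(ns$signals, ns$dirs, L = order, lambda = lambda)
  list(coefs = coefs, voxels = ns$voxels, b0 = ns$b0,
       n_excluded_b0 = ns$n_excluded_b0)
}

#' Build paired training data and train the network from stacks
#'
#' Convenience wrapper: preprocesses co-registered source/target stacks
#' subject by subject, pairs the SH vectors at shared in-mask voxels, and
#' calls [shnet_train()].
#'
#' @param src_stacks,tgt_stacks Lists of co-registered [dwi_stack()]s.
#' @param masks List of 3D masks.
#' @param cfg A [shnet_config()].
#' @param order,lambda SH preprocessing settings.
#' @return A `shnet_model`.
#' @export
shnet_train_stacks <- function(src_stacks, tgt_stacks, masks,
                               cfg = shnet_config(), order = 4,
                               lambda = 0.006) {
  stopifnot(length(src_stacks) == length(tgt_stacks))
  Xs <- list(); Ts <- list(); ids <- list()
  for (i in seq_along(src_stacks)) {
    ps <- preprocess_voxels(src_stacks[[i]], masks[[i]], order, lambda)
    pt <- preprocess_voxels(tgt_stacks[[i]], masks[[i]], order, lambda)
    sd3 <- spatial_dim(src_stacks[[i]])
    lin_s <- ps$voxels[, 1] + (ps$voxels[, 2] - 1L) * sd3[1] +
      (ps$voxels[, 3] - 1L) * sd3[1] * sd3[2]
    lin_t <- pt$voxels[, 1] + (pt$voxels[, 2] - 1L) * sd3[1] +
      (pt$voxels[, 3] - 1L) * sd3[1] * sd3[2]
    shared <- intersect(lin_s, lin_t)
    Xs[[i]] <- unclass(ps$coefs)[match(shared, lin_s), , drop = FALSE]
    Ts[[i]] <- unclass(pt$coefs)[match(shared, lin_t), , drop = FALSE]
    ids[[i]] <- rep.int(i, length(shared))
  }
  shnet_train(do.call(rbind, Xs), do.call(rbind, Ts), unlist(ids), cfg)
}

#' Matched-resolution harmonisation with a trained network
#'
#' Maps each in-mask voxel's order-4 SH vector through the network,
#' resamples the mapped coefficients at the target gradient directions and
#' re-scales by the source mean b = 0 signal (the network predicts the
#' normalised signal shape only).
#'
#' @param src Source [dwi_stack()] (must share the target grid).
#' @param model A `shnet_model`.
#' @param target_scheme Output [gradient_scheme()]; default the source's.
#' @param mask Optional 3D mask.
#' @return Predicted [dwi_stack()].
#' @export
shnet_harmonise_matched <- function(src, model, target_scheme = src$scheme,
                                    mask = NULL) {
  pv <- preprocess_voxels(src, mask)
  mapped <- shnet_apply(model, pv$coefs)
  attr(mapped, "order") <- attr(pv$coefs, "order")
  .stack_from_coefs(mapped, pv$voxels, pv$b0, src, target_scheme,
                    grid_geometry(src))
}

#' Super-resolution harmonisation with a trained network
#'
#' The source SH coefficient channels and mean b = 0 map are cubically
#' interpolated (separable cubic convolution) onto the target grid; the
#' network then maps each fine-grid SH vector, and the result is resampled
#' at the target directions.
#'
#' @param src Low-resolution source [dwi_stack()].
#' @param model A `shnet_model`.
#' @param target_grid A [grid_geometry()] covering the same field of view.
#' @param target_scheme Output [gradient_scheme()].
#' @param mask Optional low-resolution 3D mask.
#' @return Predicted [dwi_stack()] on the target grid.
#' @export
shnet_harmonise_superres <- function(src, model, target_grid,
                                     target_scheme, mask = NULL) {
  pv <- preprocess_voxels(src, mask)
  sd3 <- spatial_dim(src)
  ncoef <- ncol(pv$coefs)
  idx <- .grid_indices(target_grid$dim)
  pts <- .voxel_to_voxel(target_grid, src$affine, idx)
  coef_h <- vapply(seq_len(ncoef), function(j) {
    vol <- .scatter_map(unclass(pv$coefs)[, j], pv$voxels, sd3, fill = 0)
    tricubic_interp(vol, pts)
  }, numeric(nrow(pts)))
  b0_h <- tricubic_interp(.scatter_map(pv$b0, pv$voxels, sd3, fill = 0), pts)
  # restrict to voxels inside the (interpolated) mask
  if (is.null(mask)) mask <- array(1L, dim = sd3)
  inside <- trilinear_interp(mask + 0, pts) > 0.5 & b0_h > 1e-8
  mapped <- shnet_apply(model, coef_h[inside, , drop = FALSE])
  attr(mapped, "order") <- attr(pv$coefs, "order")
  vox_h <- idx[inside, , drop = FALSE] + 1L
  .stack_from_coefs(mapped, vox_h, b0_h[inside], src, target_scheme,
                    target_grid)
}
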