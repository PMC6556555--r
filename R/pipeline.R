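#' Apply a protocol's parametric scanner effect to a stack
#'
#' Multiplies the per-order SH coefficients of the normalised signal by
#' the protocol's attenuation factors and the b = 0 signal by its gain —
#' the forward ground-truth transform of the simulator. Applying the
#' source acquisition through the target protocol's effect is the oracle
#' prediction whose residual is the noise + truncation floor.
#'
#' @param stack A [dwi_stack()].
#' @param proto A [scanner_protocol()] whose effect to apply.
#' @param target_scheme Output scheme (default the stack's own).
#' @param mask Optional 3D mask.
#' @param order SH order (default 4).
#' @param lambda Laplace-Beltrami weight of the SH step (default 0.006,
#'   as everywhere else in the package).
#' @return A [dwi_stack()].
#' @export
apply_scanner_effect <- function(stack, proto, target_scheme = stack$scheme,
                                 mask = NULL, order = 4, lambda = 0.006) {
  ns <- normalised_signals(stack, mask)
  coefs <- sh_fit(ns$signals, ns$dirs, L = order, lambda = lambda)
  coefs <- .apply_order_atten(coefs, proto$order_atten)
  .stack_from_coefs(coefs, ns$voxels, ns$b0 * proto$gain, stack,
                    target_scheme, grid_geometry(stack))
}

# average f x f x f blocks of every volume; scheme unchanged
downsample_stack <- function(stack, factor) {
  d <- dim(stack$data)
  dn <- c(d[1:3] %/% factor, d[4])
  out <- array(0, dim = dn)
  for (j in seq_len(d[4])) {
    out[, , , j] <- .block_average(stack$data[, , , j], factor)
  }
  A <- stack$affine
  Af <- A
  Af[1:3, 1:3] <- A[1:3, 1:3] * factor
  Af[1:3, 4] <- A[1:3, 4] + A[1:3, 1:3] %*% rep((factor - 1) / 2, 3)
  dwi_stack(out, stack$scheme, voxel_size = stack$voxel_size * factor,
            affine = Af)
}

#' Run harmonisation methods on a benchmark and evaluate them
#'
#' End-to-end orchestration on a [make_benchmark()] dataset: trains the
#' learning methods on the training subjects, predicts the target
#' acquisition of every test subject from its source acquisition, and
#' evaluates FA/MD/R0/R2 errors at the three scales against the acquired
#' target data. The `"oracle"` method applies the simulator's recorded
#' ground-truth transform and lower-bounds the learnable error.
#'
#' @param bench A [make_benchmark()] dataset.
#' @param task `"matched"` (source -> matched-resolution target) or
#'   `"superres"` (source -> high-resolution, high-angular target).
#' @param methods Subset of `"reference"`, `"sdl"`, `"shnet"`, `"oracle"`.
#' @param source,target Protocol names in `bench$protocols`; defaults
#'   `source_st` and (by task) `target_st` / `target_sa`.
#' @param sdl_args List of overrides for [sdl_train()] /
#'   [sdl_train_superres()] (e.g. `iterations`, `lambda`).
#' @param shnet_cfg A [shnet_config()].
#' @param features Features to evaluate.
#' @param seed Seed for the learning methods.
#' @return List of class `harmonisation_run`: `reports` (named
#'   `dwi_error_report`s), `comparison` (tibble: algorithm x feature x
#'   scale x error type), `models`, `task`.
#' @export
run_benchmark <- function(bench, task = c("matched", "superres"),
                          methods = c("reference", "sdl", "shnet",
                                      "oracle"),
                          source = "source_st", target = NULL,
                          sdl_args = list(), shnet_cfg = shnet_config(),
                          features = c("fa", "md", "r0", "r2"),
                          seed = 1L) {
  task <- match.arg(task)
  if (is.null(target)) {
    target <- if (task == "matched") "target_st" else "target_sa"
  }
  bad <- setdiff(methods, c("reference", "sdl", "shnet", "oracle"))
  if (length(bad) > 0) {
    stop("unknown method(s) ", paste(bad, collapse = ", "),
         "; valid: reference, sdl, shnet, oracle")
  }
  tr <- bench$split$train; te <- bench$split$test
  get_stack <- function(s, pn) bench$subjects[[s]]$stacks[[pn]]
  src_tr <- lapply(tr, get_stack, source)
  tgt_tr <- lapply(tr, get_stack, target)
  src_te <- lapply(te, get_stack, source)
  tgt_te <- lapply(te, get_stack, target)
  tgt_proto <- bench$protocols[[target]]
  masks_tr_src <- lapply(src_tr, attr, "mask")
  masks_tr_tgt <- lapply(tgt_tr, attr, "mask")
  masks_te_src <- lapply(src_te, attr, "mask")
  masks_te <- lapply(tgt_te, attr, "mask")
  labels_te <- lapply(tgt_te, attr, "labels")
  models <- list()
  reports <- list()
  for (method in methods) {
    preds <- switch(
      method,
      reference = lapply(seq_along(te), function(i) {
        predict_reference(src_te[[i]], grid_geometry(tgt_te[[i]]),
                          tgt_te[[i]]$scheme,
                          L = if (task == "matched") 6 else 8,
                          lambda = 0.006)
      }),
      oracle = lapply(seq_along(te), function(i) {
        # the noise floor: the ground-truth transform applied to the
        # noise-free signal, i.e. a noise-free rendering of the target
        # protocol. Any predictor's error decomposes into method error
        # plus this floor (acquired-side noise + truncation).
        proto_nf <- tgt_proto
        proto_nf$snr <- Inf
        nf <- render_acquisition(bench$subjects[[te[i]]]$anatomy, proto_nf)
        dwi_stack(nf$data, tgt_te[[i]]$scheme, nf$voxel_size, nf$affine)
      }),
      sdl = {
        if (task == "matched") {
          model <- do.call(sdl_train, c(list(tgt_tr, masks_tr_tgt,
                                             seed = seed,
                                             src_stacks = src_tr),
                                        sdl_args))
          models$sdl <- model
          lapply(seq_along(te), function(i) {
            harmonise_matched(src_te[[i]], model,
                              target_scheme = tgt_te[[i]]$scheme,
                              mask = masks_te_src[[i]])
          })
        } else {
          model <- do.call(sdl_train_superres,
                           c(list(tgt_tr, masks_tr_tgt, seed = seed,
                                  src_stacks = src_tr),
                             sdl_args))
          models$sdl <- model
          lapply(seq_along(te), function(i) {
            harmonise_superres(src_te[[i]], model, tgt_te[[i]]$scheme,
                               mask = masks_te_src[[i]])
          })
        }
      },
      shnet = {
        pair_tgt <- if (task == "matched") tgt_tr else {
          # pair at the source grid: block-average the fine target data
          f <- as.integer(round(bench$protocols[[source]]$voxel_size /
                                  tgt_proto$voxel_size))
          lapply(tgt_tr, downsample_stack, f)
        }
        model <- shnet_train_stacks(src_tr, pair_tgt, masks_tr_src,
                                    cfg = shnet_cfg)
        models$shnet <- model
        if (task == "matched") {
          lapply(seq_along(te), function(i) {
            shnet_harmonise_matched(src_te[[i]], model,
                                    target_scheme = tgt_te[[i]]$scheme,
                                    mask = masks_te_src[[i]])
          })
        } else {
          lapply(seq_along(te), function(i) {
            shnet_harmonise_superres(src_te[[i]], model,
                                     grid_geometry(tgt_te[[i]]),
                                     tgt_te[[i]]$scheme,
                                     mask = masks_te_src[[i]])
          })
        }
      })
    reports[[method]] <- evaluate_harmonisation(
      preds, tgt_te, masks_te, labels = labels_te,
      features = features, algorithm = method)
  }
  comparison <- dplyr::bind_rows(
    lapply(reports, function(r) {
      g <- r$global |>
        dplyr::group_by(.data$algorithm, .data$feature,
                        .data$error_type) |>
        dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
        dplyr::mutate(scale = "global")
      l <- r$local_summary |>
        dplyr::transmute(algorithm = .data$algorithm,
                         feature = .data$feature,
                         error_type = .data$error_type,
                         value = .data$median, scale = "local_median")
      dplyr::bind_rows(g, l)
    }))
  structure(list(reports = reports, comparison = comparison,
                 models = models, task = task),
            class = "harmonisation_run")
}

#' @export
print.harmonisation_run <- function(x, ...) {
  cat("<harmonisation_run> task = ", x$task, "; methods: ",
      paste(names(x$reports), collapse = ", "), "\n", sep = "")
  tab <- x$comparison |>
    dplyr::filter(.data$error_type == "mse", .data$scale == "global") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "value")
  print(as.data.frame(tab), row.names = FALSE)
  invisible(x)
}

#' Run the full simulate/train/harmonise/evaluate pipeline from a config
#'
#' Flat-YAML-configurable entry point: simulates (or regenerates from a
#' manifest) the benchmark, runs the requested methods and task, and
#' writes the harmonised feature errors, comparison table (CSV), a JSON
#' summary, and the run configuration (with a content hash) under
#' `out_dir`. Inputs are never mutated.
#'
#' @param config A named list or path to a YAML file. Recognised keys:
#'   `seed`, `task` (matched|superres), `methods` (character vector),
#'   `n_train`, `n_test`, `out_dir`, `sdl_iterations`, `sdl_lambda`,
#'   `shnet_epochs`, `dim`, `voxel_size`.
#' @param ... Individual key overrides (override config-file values).
#' @return The [run_benchmark()] result, invisibly, with `out_dir`
#'   attached.
#' @export
run_pipeline <- function(config = list(), ...) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- utils::modifyList(config, list(...))
  defaults <- list(seed = 1L, task = "matched",
                   methods = c("reference", "sdl", "shnet", "oracle"),
                   n_train = 10L, n_test = 4L, out_dir = NULL,
                   sdl_iterations = 1000L, sdl_lambda = NULL,
                   shnet_epochs = 100L, dim = 24L, voxel_size = 1.2)
  cfg <- utils::modifyList(defaults, config)
  bench <- make_benchmark(n_train = cfg$n_train, n_test = cfg$n_test,
                          seed = cfg$seed,
                          dim3 = rep(cfg$dim, 3),
                          voxel_size = cfg$voxel_size)
  run <- run_benchmark(
    bench, task = cfg$task, methods = cfg$methods,
    sdl_args = list(iterations = cfg$sdl_iterations,
                    lambda = cfg$sdl_lambda),
    shnet_cfg = shnet_config(epochs = cfg$shnet_epochs, seed = cfg$seed),
    seed = cfg$seed)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(run$comparison,
                     file.path(cfg$out_dir, "comparison.csv"),
                     row.names = FALSE)
    for (m in names(run$reports)) {
      utils::write.csv(run$reports[[m]]$global,
                       file.path(cfg$out_dir, paste0("global_", m, ".csv")),
                       row.names = FALSE)
    }
    cfg_hash <- paste(format(as.hexmode(
      as.integer(utils::head(serialize(cfg, NULL), 8)))), collapse = "")
    jsonlite::write_json(list(config = cfg, config_hash = cfg_hash),
                         file.path(cfg$out_dir, "run_config.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    attr(run, "out_dir") <- cfg$out_dir
  }
  invisible(run)
}
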