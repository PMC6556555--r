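#' Voxel-wise error maps between predicted and acquired feature maps
#'
#' Computes, per voxel, the error e = predicted - acquired (ME field), the
#' normalised error e / acquired (MNE field; voxels with |acquired| below
#' `eps` are excluded and counted) and the squared error e^2 (MSE field).
#'
#' @param pred,acq 3D feature maps on a shared grid (e.g. FA, MD, R0, R2).
#' @param mask Optional 3D 0/1 array.
#' @param eps MNE denominator guard (feature units).
#' @return Object of class `error_maps`: list of 3D arrays `me`, `mne`,
#'   `mse` (NA outside the evaluated voxels) plus an exclusion ledger
#'   (`n_mask`, `n_nonfinite`, `n_zero_denominator`).
#' @export
error_maps <- function(pred, acq, mask = NULL, eps = 1e-6) {
  if (!all(dim(pred) == dim(acq))) {
    stop("grid mismatch: predicted ", paste(dim(pred), collapse = "x"),
         " vs acquired ", paste(dim(acq), collapse = "x"))
  }
  if (is.null(mask)) mask <- array(1L, dim = dim(pred))
  if (!all(dim(mask) == dim(pred))) stop("mask grid mismatch")
  use <- mask > 0 & is.finite(pred) & is.finite(acq)
  n_nonfinite <- sum(mask > 0) - sum(use)
  e <- ifelse(use, pred - acq, NA_real_)
  denom_ok <- use & abs(acq) >= eps
  mne <- ifelse(denom_ok, e / acq, NA_real_)
  structure(list(me = e, mne = mne, mse = e^2,
                 n_mask = sum(mask > 0), n_nonfinite = n_nonfinite,
                 n_zero_denominator = sum(use) - sum(denom_ok)),
            class = "error_maps")
}

#' Global (whole-mask) mean errors
#'
#' Arithmetic mean of each error field over its evaluated voxels.
#'
#' @param maps An [error_maps()] object.
#' @return Tibble with one row per error type (`me`, `mne`, `mse`):
#'   columns `error_type`, `value`, `n_voxels`.
#' @export
global_error <- function(maps) {
  one <- function(field, name) {
    v <- field[is.finite(field)]
    if (length(v) == 0) stop("empty mask after exclusions for ", name)
    tibble::tibble(error_type = name, value = mean(v),
                   n_voxels = length(v))
  }
  dplyr::bind_rows(one(maps$me, "me"), one(maps$mne, "mne"),
                   one(maps$mse, "mse"))
}

#' Regional errors: per-ROI mean within subject, median across subjects
#'
#' @param maps_by_subject List (one per subject) of [error_maps()].
#' @param labels_by_subject List of 3D integer label maps (label 0 =
#'   background, ignored).
#' @return Tibble: `label`, `error_type`, `value` (median across subjects
#'   of the per-ROI mean), `n_subjects` (subjects contributing; a label
#'   absent or fully excluded in a subject is recorded as missing and
#'   excluded from the median).
#' @export
regional_error <- function(maps_by_subject, labels_by_subject) {
  stopifnot(length(maps_by_subject) >= 1,
            length(maps_by_subject) == length(labels_by_subject))
  per_subj <- list()
  for (s in seq_along(maps_by_subject)) {
    maps <- maps_by_subject[[s]]
    labels <- labels_by_subject[[s]]
    for (et in c("me", "mne", "mse")) {
      field <- maps[[et]]
      ok <- is.finite(field) & labels > 0
      if (!any(ok)) next
      agg <- tapply(field[ok], labels[ok], mean)
      per_subj[[length(per_subj) + 1L]] <- tibble::tibble(
        subject = s, label = as.integer(names(agg)), error_type = et,
        roi_mean = as.numeric(agg))
    }
  }
  dplyr::bind_rows(per_subj) |>
    dplyr::group_by(.data$label, .data$error_type) |>
    dplyr::summarise(value = stats::median(.data$roi_mean),
                     n_subjects = dplyr::n(), .groups = "drop")
}

#' Local errors: sliding-window neighbourhood means
#'
#' Means of an error field over every fully-in-mask `window`^3
#' neighbourhood (stride 1). `window = 1` reduces to the per-voxel field.
#'
#' @param maps An [error_maps()] object.
#' @param mask 3D 0/1 array (NA voxels of the field also invalidate a
#'   window).
#' @param window Odd window edge length (default 3).
#' @return Tibble: `error_type`, `value` (one row per valid window per
#'   error type), pooled-ready across subjects.
#' @export
local_error <- function(maps, mask = NULL, window = 3L) {
  window <- as.integer(window)
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  if (is.null(mask)) mask <- array(1L, dim = dim(maps$me))
  if (any(dim(maps$me) < window)) stop("grid smaller than the window")
  a <- rep(window, 3)
  mask_cnt <- .box_sum((mask > 0) * 1, a)
  if (!any(mask_cnt > prod(a) - 0.5)) {
    stop("no complete ", window, "^3 neighbourhood in mask")
  }
  out <- list()
  for (et in c("me", "mne", "mse")) {
    field <- maps[[et]]
    ok <- (mask > 0 & is.finite(field)) * 1
    cnt <- .box_sum(ok, a)
    f0 <- field; f0[ok == 0] <- 0
    sums <- .box_sum(f0, a)
    # windows touching excluded voxels (e.g. MNE zero denominators) drop
    valid <- cnt > prod(a) - 0.5
    out[[et]] <- tibble::tibble(error_type = et,
                                value = sums[valid] / prod(a))
  }
  dplyr::bind_rows(out)
}

#' Median and 95th-percentile summary of a local error distribution
#'
#' Quantiles use the linear-interpolation definition (R type 7).
#'
#' @param values Numeric vector (e.g. `value` column of [local_error()]).
#' @return Named vector `c(median, p95)`.
#' @export
summarise_local <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("empty distribution")
  c(median = stats::median(values),
    p95 = unname(stats::quantile(values, 0.95, type = 7)))
}

#' Flag systematically poor regions across algorithms
#'
#' A ROI is flagged when its median MSE lies in its tissue class's (WM or
#' GM) 90th percentile for at least `min_algorithms` algorithms, in at
#' least one feature. "In the 90th percentile" is evaluated strictly
#' (value > the type-7 90th-percentile threshold of its tissue class), so
#' a degenerate class where all ROIs are identical flags nothing.
#'
#' @param regional_tbl Tibble with columns `algorithm`, `feature`, `label`,
#'   `value` (median MSE per ROI; e.g. stacked [regional_error()] results
#'   filtered to `error_type == "mse"`).
#' @param tissue Data frame with columns `label`, `class` ("WM"/"GM");
#'   every label must be assigned.
#' @param min_algorithms Minimum algorithms agreeing (default 3).
#' @param prob Percentile level (default 0.9).
#' @return Integer vector of flagged labels (possibly empty).
#' @export
flag_poor_regions <- function(regional_tbl, tissue, min_algorithms = 3L,
                              prob = 0.9) {
  n_alg <- length(unique(regional_tbl$algorithm))
  if (n_alg < min_algorithms) {
    stop("need >= ", min_algorithms, " algorithms, got ", n_alg)
  }
  missing_lab <- setdiff(unique(regional_tbl$label), tissue$label)
  if (length(missing_lab) > 0) {
    stop("labels without tissue-class assignment: ",
         paste(missing_lab, collapse = ", "))
  }
  tab <- dplyr::left_join(regional_tbl,
                          dplyr::distinct(tissue[, c("label", "class")]),
                          by = "label") |>
    dplyr::group_by(.data$algorithm, .data$feature, .data$class) |>
    dplyr::mutate(thresh = stats::quantile(.data$value, prob, type = 7)) |>
    dplyr::ungroup() |>
    dplyr::mutate(in_tail = .data$value > .data$thresh) |>
    dplyr::group_by(.data$label, .data$feature) |>
    dplyr::summarise(n_alg_tail = sum(.data$in_tail), .groups = "drop") |>
    dplyr::filter(.data$n_alg_tail >= min_algorithms)
  sort(unique(tab$label))
}

#' One-voxel (or wider) morphological erosion of a mask
#'
#' A voxel survives if it and its 6-connected neighbours are all inside
#' the mask; repeated `width` times. Used to drop brain-edge voxels before
#' evaluation.
#'
#' @param mask 3D 0/1 array.
#' @param width Erosion repetitions (default 1).
#' @return Eroded 3D 0/1 integer array.
#' @export
erode_mask <- function(mask, width = 1L) {
  m <- mask > 0
  d <- dim(m)
  for (w in seq_len(width)) {
    keep <- m
    shift <- function(arr, ax, by) {
      out <- array(FALSE, dim = d)
      src <- lapply(d, seq_len)
      dst <- src
      if (by > 0) { dst[[ax]] <- (1 + by):d[ax]; src[[ax]] <- 1:(d[ax] - by) }
      else { dst[[ax]] <- 1:(d[ax] + by); src[[ax]] <- (1 - by):d[ax] }
      out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
      out
    }
    for (ax in 1:3) for (by in c(-1, 1)) keep <- keep & shift(m, ax, by)
    m <- keep
  }
  storage.mode(m) <- "integer"
  m
}

#' Three-scale evaluation of predicted against acquired stacks
#'
#' Computes FA, MD (weighted linear least squares tensor), R0 and R2
#' (order-4 RISH of b0-normalised signals) for predicted and acquired
#' data, then ME/MNE/MSE globally (eroded brain mask), regionally (per-ROI
#' mean within subject, median across subjects) and locally (sliding
#' 3 x 3 x 3 neighbourhoods, pooled across subjects). One-voxel mask
#' erosion drops brain-edge voxels; an exclusion ledger accounts for every
#' dropped voxel. Optionally restricts to given tissue classes (e.g. WM
#' only) and excludes flagged ROIs.
#'
#' @param pred_stacks,acq_stacks Lists of predicted / acquired
#'   [dwi_stack()]s (one per subject, shared grids).
#' @param masks List of 3D brain masks.
#' @param labels List of 3D ROI label maps (optional; enables the
#'   regional scale).
#' @param tissue Optional `label`/`class` data frame; with
#'   `restrict_class` non-NULL, evaluation masks keep only those classes.
#' @param restrict_class Character vector of tissue classes to keep (e.g.
#'   "WM"), or NULL for all.
#' @param exclude_labels Integer labels excluded from evaluation (e.g.
#'   flagged poor regions).
#' @param features Feature subset (default FA, MD, R0, R2).
#' @param erode_width Mask erosion width (default 1).
#' @param window Local window (default 3).
#' @param algorithm Name recorded in the output tables.
#' @return Object of class `dwi_error_report`: tibbles `global` (subject x
#'   feature x error type), `regional`, `local_summary` (median and p95 of
#'   the pooled local distributions), `exclusions`, plus the pooled
#'   `local` distributions.
#' @export
evaluate_harmonisation <- function(pred_stacks, acq_stacks, masks,
                                   labels = NULL, tissue = NULL,
                                   restrict_class = NULL,
                                   exclude_labels = integer(0),
                                   features = c("fa", "md", "r0", "r2"),
                                   erode_width = 1L, window = 3L,
                                   algorithm = "method") {
  if (inherits(pred_stacks, "dwi_stack")) pred_stacks <- list(pred_stacks)
  if (inherits(acq_stacks, "dwi_stack")) acq_stacks <- list(acq_stacks)
  if (!is.null(masks) && is.array(masks)) masks <- list(masks)
  if (!is.null(labels) && is.array(labels)) labels <- list(labels)
  n_sub <- length(pred_stacks)
  stopifnot(length(acq_stacks) == n_sub)
  global_rows <- list(); excl_rows <- list()
  maps_store <- list() # [[feature]][[subject]] -> error_maps
  local_vals <- list()
  for (s in seq_len(n_sub)) {
    mask0 <- masks[[s]]
    mask <- erode_mask(mask0, erode_width)
    n_edge <- sum(mask0 > 0) - sum(mask > 0)
    n_class_excl <- 0L; n_flagged <- 0L
    if (!is.null(labels)) {
      lab <- labels[[s]]
      if (length(exclude_labels) > 0) {
        drop <- lab %in% exclude_labels & mask > 0
        n_flagged <- sum(drop)
        mask[drop] <- 0L
      }
      if (!is.null(restrict_class) && !is.null(tissue)) {
        keep_labs <- tissue$label[tissue$class %in% restrict_class]
        drop <- !(lab %in% keep_labs) & mask > 0
        n_class_excl <- sum(drop)
        mask[drop] <- 0L
      }
    }
    fp <- compute_features(pred_stacks[[s]], mask)
    fa_ <- compute_features(acq_stacks[[s]], mask)
    for (feat in features) {
      em <- error_maps(fp[[feat]], fa_[[feat]], mask)
      maps_store[[feat]][[s]] <- em
      ge <- global_error(em)
      global_rows[[length(global_rows) + 1L]] <- dplyr::mutate(
        ge, subject = s, feature = feat, algorithm = algorithm,
        .before = 1)
      le <- local_error(em, mask, window = window)
      le$subject <- s; le$feature <- feat
      local_vals[[length(local_vals) + 1L]] <- le
      excl_rows[[length(excl_rows) + 1L]] <- tibble::tibble(
        subject = s, feature = feat, n_mask_full = sum(mask0 > 0),
        n_edge_excluded = n_edge, n_class_excluded = n_class_excl,
        n_flagged_excluded = n_flagged,
        n_nonfinite = em$n_nonfinite,
        n_zero_denominator = em$n_zero_denominator,
        n_evaluated = sum(is.finite(em$me)))
    }
  }
  regional <- NULL
  if (!is.null(labels)) {
    reg_rows <- lapply(features, function(feat) {
      lab_masked <- lapply(seq_len(n_sub), function(s) labels[[s]])
      tab <- regional_error(maps_store[[feat]], lab_masked)
      tab$feature <- feat; tab$algorithm <- algorithm
      tab
    })
    regional <- dplyr::bind_rows(reg_rows)
  }
  local_tbl <- dplyr::bind_rows(local_vals)
  local_summary <- local_tbl |>
    dplyr::group_by(.data$feature, .data$error_type) |>
    dplyr::summarise(median = stats::median(.data$value),
                     p95 = unname(stats::quantile(.data$value, 0.95,
                                                  type = 7)),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(algorithm = algorithm)
  structure(list(global = dplyr::bind_rows(global_rows),
                 regional = regional,
                 local = local_tbl,
                 local_summary = local_summary,
                 exclusions = dplyr::bind_rows(excl_rows),
                 algorithm = algorithm),
            class = "dwi_error_report")
}

#' Feature maps (FA, MD, R0, R2) of a stack
#'
#' @param stack A [dwi_stack()].
#' @param mask Optional 3D mask.
#' @param order,lambda RISH SH settings.
#' @param include_b0_in_fit Include b = 0 volumes in the tensor fit
#'   (default TRUE, also for predicted stacks).
#' @return List of 3D arrays `fa`, `md`, `r0`, `r2`.
#' @export
compute_features <- function(stack, mask = NULL, order = 4,
                             lambda = 0.006, include_b0_in_fit = TRUE) {
  fit_stack <- stack
  if (!include_b0_in_fit) {
    keep <- !is_b0(stack$scheme)
    fit_stack <- dwi_stack(stack$data[, , , keep, drop = FALSE],
                           gradient_scheme(stack$scheme$bvals[keep],
                                           stack$scheme$bvecs[keep, ],
                                           stack$scheme$b0_thresh),
                           stack$voxel_size, stack$affine)
  }
  tf <- fit_wlls(fit_stack, mask)
  rm_ <- rish_maps(stack, mask, order = order, lambda = lambda)
  list(fa = fa_map(tf), md = md_map(tf), r0 = rm_$R0, r2 = rm_$R2)
}

#' @export
print.dwi_error_report <- function(x, ...) {
  cat("<dwi_error_report> algorithm = ", x$algorithm, "\n", sep = "")
  g <- x$global |>
    dplyr::filter(.data$error_type == "mse") |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(mean_global_mse = mean(.data$value))
  print(as.data.frame(g), row.names = FALSE)
  invisible(x)
}
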