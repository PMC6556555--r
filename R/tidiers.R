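#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an evaluation report
#'
#' One row per subject x feature x error type (global scale) plus the
#' pooled local summaries, in long format.
#'
#' @param x A `dwi_error_report`.
#' @param scale `"global"`, `"regional"`, `"local"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.dwi_error_report <- function(x, scale = c("global", "regional",
                                               "local"), ...) {
  scale <- match.arg(scale)
  switch(scale,
         global = x$global,
         regional = {
           if (is.null(x$regional)) stop("report has no regional table")
           x$regional
         },
         local = x$local_summary)
}

#' @rdname tidy.dwi_error_report
#' @export
glance.dwi_error_report <- function(x, ...) {
  x$global |>
    dplyr::filter(.data$error_type == "mse") |>
    dplyr::group_by(.data$algorithm, .data$feature) |>
    dplyr::summarise(mean_mse = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "mean_mse",
                       names_prefix = "mse_")
}

#' Tidy a learned sparse dictionary
#'
#' One row per atom with its norm (1 by construction) and final-batch
#' usage statistics are not retained; this summarises the objective trace
#' instead: one row per iteration.
#'
#' @param x An `sdl_dictionary`.
#' @param ... Unused.
#' @return Tibble with `iteration`, `objective`.
#' @export
tidy.sdl_dictionary <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$objective),
                 objective = x$objective)
}

#' @rdname tidy.sdl_dictionary
#' @export
glance.sdl_dictionary <- function(x, ...) {
  tibble::tibble(m = nrow(x$D), p = ncol(x$D), lambda = x$lambda,
                 iterations = x$iterations, batch = x$batch,
                 final_objective = utils::tail(x$objective, 1),
                 n_reseeded = x$n_reseeded)
}

#' Tidy a trained SH network
#'
#' @param x A `shnet_model`.
#' @param ... Unused.
#' @return The training history tibble (epoch, phase, lr, train and
#'   validation loss).
#' @export
tidy.shnet_model <- function(x, ...) x$history

#' @rdname tidy.shnet_model
#' @export
glance.shnet_model <- function(x, ...) {
  n_par <- sum(vapply(x$net$layers, function(ly)
    sum(vapply(ly[.shnet_params(ly)], length, 0L)), 0L))
  tibble::tibble(n_coef = x$n_coef, n_parameters = n_par,
                 epochs = nrow(x$history), best_val_loss = x$best_val,
                 val_subject = x$val_subject)
}

#' Plot an evaluation report
#'
#' Bar chart of global MSE per feature (mean over subjects), the primary
#' comparison view.
#'
#' @param object A `dwi_error_report`.
#' @param error_type Which error to show (default `"mse"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dwi_error_report <- function(object, error_type = "mse", ...) {
  dat <- object$global |>
    dplyr::filter(.data$error_type == !!error_type)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$feature, y = .data$value)) +
    ggplot2::stat_summary(fun = mean, geom = "col",
                          fill = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(group = .data$subject), alpha = 0.6) +
    ggplot2::labs(x = NULL, y = paste("global", error_type),
                  title = object$algorithm) +
    ggplot2::theme_minimal()
}

#' Plot a method comparison
#'
#' @param object A `harmonisation_run`.
#' @param error_type,scale Filter for the comparison table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.harmonisation_run <- function(object, error_type = "mse",
                                       scale = "global", ...) {
  dat <- object$comparison |>
    dplyr::filter(.data$error_type == !!error_type,
                  .data$scale == !!scale)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$feature, y = .data$value,
                                    fill = .data$algorithm)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = paste(scale, error_type),
                  title = paste("Harmonisation comparison:",
                                object$task, "task")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
#' @importFrom Rcpp evalCpp
#' @useDynLib dwiharm, .registration = TRUE
#' @keywords internal
"_PACKAGE"
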