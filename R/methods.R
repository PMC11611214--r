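#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an assortativity estimate table
#'
#' @param x A `transmix_estimates` object.
#' @param ... Unused.
#' @return A plain tibble with one row per group.
#' @method tidy transmix_estimates
#' @export
tidy.transmix_estimates <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' One-line summary of an assortativity estimate table
#'
#' @param x A `transmix_estimates` object.
#' @param ... Unused.
#' @return A one-row tibble: number of groups, number with a defined
#'   estimate, total emitted transmissions, the significance level, and how
#'   many groups are significantly assortative / disassortative (CI excluding
#'   0 above / below).
#' @method glance transmix_estimates
#' @export
glance.transmix_estimates <- function(x, ...) {
  ok <- x$status == "ok"
  tibble::tibble(
    n_groups = nrow(x),
    n_estimated = sum(ok),
    n_emitted_total = sum(x$n_emitted),
    alpha = x$alpha[1],
    n_assortative = sum(ok & x$ci_low > 0),
    n_disassortative = sum(ok & x$ci_high < 0)
  )
}

#' Forest plot of per-group assortativity estimates
#'
#' Point estimates of delta with their confidence intervals, one row per
#' group; the dashed line at 0 is homogeneous mixing.
#'
#' @param object A `transmix_estimates` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot transmix_estimates
#' @export
autoplot.transmix_estimates <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$status == "ok", ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta_hat, y = .data$group)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::xlim(-1, 1) +
    ggplot2::labs(
      x = expression(hat(delta) ~ "(rescaled assortativity)"), y = NULL,
      title = "Transmission assortativity by group",
      subtitle = paste0(100 * (1 - object$alpha[1]), "% Clopper-Pearson interval")
    ) +
    ggplot2::theme_minimal()
}

#' Overall performance summary of a simulation study
#'
#' @param x A `transmix_study` report.
#' @param ... Unused.
#' @return A tibble with one row per (epsilon, alpha): mean bias, mean
#'   absolute bias, mean coverage and coverage error, mean sensitivity and
#'   specificity, and the number of contributing cells.
#' @method glance transmix_study
#' @export
glance.transmix_study <- function(x, ...) {
  x |>
    dplyr::group_by(.data$epsilon, .data$alpha) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      mean_bias = mean(.data$bias, na.rm = TRUE),
      mean_abs_bias = mean(abs(.data$bias), na.rm = TRUE),
      mean_coverage = mean(.data$coverage, na.rm = TRUE),
      mean_coverage_error = mean(.data$coverage_error, na.rm = TRUE),
      mean_sensitivity = mean(.data$sensitivity, na.rm = TRUE),
      mean_specificity = mean(.data$specificity, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Performance-by-peak-coefficient plot for a simulation study
#'
#' Mean bias (with the zero target) and mean coverage (with its `1 - alpha`
#' target) as a function of the peak coefficient epsilon.
#'
#' @param object A `transmix_study` report.
#' @param metric `"bias"` or `"coverage"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot transmix_study
#' @export
autoplot.transmix_study <- function(object, metric = c("bias", "coverage"), ...) {
  metric <- match.arg(metric)
  g <- glance(object)
  if (metric == "bias") {
    ggplot2::ggplot(g, ggplot2::aes(x = .data$epsilon, y = .data$mean_bias)) +
      ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
      ggplot2::geom_point() + ggplot2::geom_line() +
      ggplot2::labs(x = expression(epsilon ~ "(peak coefficient)"),
                    y = expression("mean bias" ~ (delta - hat(delta))),
                    title = "Estimator bias by analysis window") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(g, ggplot2::aes(x = .data$epsilon, y = .data$mean_coverage,
                                    colour = factor(.data$alpha))) +
      ggplot2::geom_hline(ggplot2::aes(yintercept = 1 - .data$alpha,
                                       colour = factor(.data$alpha)),
                          linetype = "dashed") +
      ggplot2::geom_point() + ggplot2::geom_line() +
      ggplot2::labs(x = expression(epsilon ~ "(peak coefficient)"),
                    y = "mean coverage", colour = expression(alpha),
                    title = "Interval coverage by analysis window") +
      ggplot2::theme_minimal()
  }
}

#' @export
print.transmix_estimates <- function(x, ...) {
  cat("# Transmission assortativity estimates (alpha = ", x$alpha[1], ")\n", sep = "")
  NextMethod()
}
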