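#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a borrowing fit
#'
#' @param x A `borrow_fit` from [borrow_posterior()] or [pooled_estimate()].
#' @param ... Unused.
#' @return A one-row tibble: `term`, `estimate`, `std.error`, `conf.low`,
#'   `conf.high` (equal-tailed credible bounds at the fit's level).
#' @method tidy borrow_fit
#' @export
tidy.borrow_fit <- function(x, ...) {
  tibble::tibble(term = "theta_target", estimate = x$mean, std.error = x$sd,
                 conf.low = x$cri_lower, conf.high = x$cri_upper)
}

#' Glance at a borrowing fit
#'
#' @param x A `borrow_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the model-level quantities: `sigma_delta`,
#'   `weight_source`, `level` and the two input summaries echoed.
#' @export
glance.borrow_fit <- function(x, ...) {
  tgt <- x$data[x$data$label == "target", ]
  src <- x$data[x$data$label == "source", ]
  tibble::tibble(sigma_delta = x$sigma_delta,
                 weight_source = x$weight_source,
                 level = x$level,
                 estimate_target = tgt$estimate, se_target = tgt$se,
                 estimate_source = src$estimate, se_source = src$se)
}

#' @export
print.borrow_fit <- function(x, digits = 3, ...) {
  kind <- if (x$sigma_delta == 0) "inverse-variance pooled"
          else "commensurate-prior borrowing"
  cat(sprintf("<borrow_fit> %s analysis\n", kind))
  cat(sprintf("  sigma_delta = %.*g, source weight = %.1f%%\n",
              digits + 1, x$sigma_delta, 100 * x$weight_source))
  cat(sprintf("  posterior: %.*f (sd %.*f), %d%% CrI (%.*f, %.*f)\n",
              digits, x$mean, digits, x$sd, round(100 * x$level),
              digits, x$cri_lower, digits, x$cri_upper))
  invisible(x)
}

#' Forest-style plot of a borrowing fit
#'
#' Shows the two subgroup inputs (normal-theory intervals) and the posterior
#' for the target subgroup on one axis.
#'
#' @param object A `borrow_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot borrow_fit
#' @export
autoplot.borrow_fit <- function(object, ...) {
  z <- z_level(object$level)
  rows <- dplyr::bind_rows(
    dplyr::transmute(object$data,
                     analysis = paste0(.data$label, " (data)"),
                     estimate = .data$estimate,
                     lower = .data$estimate - z * .data$se,
                     upper = .data$estimate + z * .data$se),
    tibble::tibble(analysis = "target (posterior)",
                   estimate = object$mean,
                   lower = object$cri_lower, upper = object$cri_upper))
  forest_plot(rows, xlab = "Risk difference (DTG - SOC)")
}

forest_plot <- function(rows, xlab) {
  rows$analysis <- factor(rows$analysis, levels = rev(rows$analysis))
  ggplot2::ggplot(rows, ggplot2::aes(x = .data$estimate, y = .data$analysis)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lower, xmax = .data$upper), height = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = xlab, y = NULL) +
    ggplot2::theme_minimal()
}
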