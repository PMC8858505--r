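#' Assemble subgroup risk-difference summaries
#'
#' Builds the two-row tibble of subgroup-level summaries that the borrowing
#' analyses consume: one row for the small *target* subgroup in which the
#' treatment effect is to be estimated, one row for the larger *source*
#' subgroup whose information may be borrowed. Each subgroup is summarised by
#' an estimated risk difference (treatment minus control, on the proportion
#' scale) together with either its standard error or a symmetric confidence
#' interval from which the standard error is reconstructed with
#' [se_from_ci()].
#'
#' @param target,source Named list (or one-row data frame) with elements
#'   `estimate` and either `se` or `ci_lower` and `ci_upper`. Estimates are
#'   risk differences in `[-1, 1]` on the proportion scale.
#' @param level Coverage of the supplied confidence intervals (default 0.95).
#'
#' @return A tibble with columns `label` (`"target"`, `"source"`), `estimate`
#'   and `se`, validated so that `se > 0` and `|estimate| <= 1`.
#'
#' @examples
#' subgroup_data(
#'   target = list(estimate = 0.07, ci_lower = -0.10, ci_upper = 0.24),
#'   source = list(estimate = -0.02, ci_lower = -0.08, ci_upper = 0.04)
#' )
#' @export
subgroup_data <- function(target, source, level = 0.95) {
  one <- function(x, label) {
    x <- as.list(x)
    abort_if(is.null(x$estimate), "subgroup '%s' needs an `estimate`.", label)
    est <- x$estimate
    check_number(est, paste0(label, "$estimate"), -1, 1)
    if (!is.null(x$se)) {
      se <- x$se
    } else if (!is.null(x$ci_lower) && !is.null(x$ci_upper)) {
      se <- se_from_ci(x$ci_lower, x$ci_upper, level = level)
    } else {
      rlang::abort(sprintf(
        "subgroup '%s' needs either `se` or both `ci_lower` and `ci_upper`.",
        label))
    }
    check_number(se, paste0(label, "$se"), lower = 0, allow_boundary = FALSE)
    tibble::tibble(label = label, estimate = est, se = se)
  }
  dplyr::bind_rows(one(target, "target"), one(source, "source"))
}

# Validate a subgroup-summary data frame and return it with the target row
# first. Accepts any data frame with label/estimate/se columns and exactly one
# "target" and one "source" row.
validate_subgroup_data <- function(data) {
  abort_if(!is.data.frame(data), "`data` must be a data frame.")
  missing <- setdiff(c("label", "estimate", "se"), names(data))
  abort_if(length(missing) > 0,
           "`data` is missing column(s): %s.", paste(missing, collapse = ", "))
  abort_if(nrow(data) != 2L || !setequal(data$label, c("target", "source")),
           "`data` must have exactly one 'target' and one 'source' row.")
  abort_if(any(!is.finite(data$estimate)) || any(abs(data$estimate) > 1),
           "subgroup estimates must be finite risk differences in [-1, 1].")
  abort_if(any(!is.finite(data$se)) || any(data$se <= 0),
           "subgroup standard errors must be finite and > 0 (se = 0 is outside the model's fixed-and-known variance assumption).")
  dplyr::arrange(data, dplyr::desc(.data$label == "target"))
}

#' Standard error from a symmetric confidence interval
#'
#' Reconstructs the standard error of a normally distributed estimate from a
#' central confidence interval, assuming the interval is `estimate +/- z * se`.
#'
#' @param lower,upper Interval endpoints (vectorised).
#' @param level Interval coverage in (0, 1); default 0.95.
#'
#' @return Numeric vector of standard errors, `(upper - lower) / (2 * z)`.
#'
#' @examples
#' se_from_ci(-0.10, 0.24)  # 0.0867
#' @export
se_from_ci <- function(lower, upper, level = 0.95) {
  check_number(level, "level", 0, 1, allow_boundary = FALSE)
  abort_if(length(lower) != length(upper),
           "`lower` and `upper` must have the same length.")
  abort_if(any(!is.finite(lower)) || any(!is.finite(upper)),
           "interval endpoints must be finite.")
  abort_if(any(upper <= lower),
           "degenerate interval: `upper` must exceed `lower`.")
  (upper - lower) / (2 * z_level(level))
}

#' Planning standard error of a risk difference
#'
#' The anticipated standard error of the between-arm difference in failure
#' proportions for a subgroup of `n_total` participants randomised between two
#' arms, when both arms are assumed to share failure probability `p_fail`:
#' `sqrt(p(1-p) * (1/(alloc*n) + 1/((1-alloc)*n)))`, which reduces to
#' `sqrt(4 p (1-p) / n)` under 1:1 allocation. Fractional arm sizes are
#' allowed (no rounding), so loss to follow-up can be handled by deflating
#' `n_total`.
#'
#' @param n_total Total subgroup sample size (>= 2; may be fractional).
#' @param p_fail Assumed common failure probability, in (0, 1).
#' @param alloc Fraction allocated to the first arm, in (0, 1); default 0.5.
#'
#' @return The planning standard error (proportion scale). Vectorised over
#'   `n_total`.
#'
#' @examples
#' planning_se(85, 0.18)   # 0.0833
#' planning_se(707, 0.18)  # 0.0289
#' @export
planning_se <- function(n_total, p_fail, alloc = 0.5) {
  check_number(p_fail, "p_fail", 0, 1, allow_boundary = FALSE)
  check_number(alloc, "alloc", 0, 1, allow_boundary = FALSE)
  abort_if(any(!is.finite(n_total)) || any(n_total < 2),
           "`n_total` must be >= 2.")
  sqrt(p_fail * (1 - p_fail) * (1 / (alloc * n_total) + 1 / ((1 - alloc) * n_total)))
}

#' Specify a planned subgroup design
#'
#' Collects the planning assumptions under which the borrowing analysis is
#' evaluated: subgroup sample sizes, the assumed common failure probability,
#' the anticipated loss to follow-up, and the non-inferiority margin.
#'
#' @param n_target,n_source Planned sample sizes of the target and source
#'   subgroups (each >= 2).
#' @param p_fail Assumed failure probability shared by both arms, in (0, 1).
#' @param ltfu Anticipated loss-to-follow-up fraction, in `[0, 1)`; default 0.
#' @param margin Non-inferiority margin on the risk-difference scale (> 0).
#' @param alloc Per-arm allocation fraction, in (0, 1); default 0.5 (1:1).
#'
#' @return An object of class `borrow_design`: a validated list with the
#'   above fields plus `se_target` and `se_source`, the planning standard
#'   errors at the full (not LTFU-deflated) sample sizes.
#'
#' @examples
#' plan_design(n_target = 85, n_source = 707, p_fail = 0.18,
#'             ltfu = 0.10, margin = 0.10)
#' @export
plan_design <- function(n_target, n_source, p_fail, ltfu = 0, margin = 0.10,
                        alloc = 0.5) {
  check_number(n_target, "n_target", lower = 2)
  check_number(n_source, "n_source", lower = 2)
  check_number(p_fail, "p_fail", 0, 1, allow_boundary = FALSE)
  check_number(ltfu, "ltfu", 0, 1)
  abort_if(ltfu >= 1, "`ltfu` must be < 1.")
  check_number(margin, "margin", lower = 0, allow_boundary = FALSE)
  check_number(alloc, "alloc", 0, 1, allow_boundary = FALSE)
  structure(
    list(n_target = n_target, n_source = n_source, p_fail = p_fail,
         ltfu = ltfu, margin = margin, alloc = alloc,
         se_target = planning_se(n_target, p_fail, alloc),
         se_source = planning_se(n_source, p_fail, alloc)),
    class = "borrow_design")
}

#' @export
print.borrow_design <- function(x, ...) {
  cat(sprintf(
    "<borrow_design> target n=%g, source n=%g, p_fail=%g, ltfu=%g, margin=%g, alloc=%g\n",
    x$n_target, x$n_source, x$p_fail, x$ltfu, x$margin, x$alloc))
  cat(sprintf("  planning SEs: target %.5f, source %.5f\n",
              x$se_target, x$se_source))
  invisible(x)
}

# Planning summaries implied by a design: the subgroup_data tibble a design
# would yield if both subgroups observed estimate 0 at their planning SEs,
# optionally LTFU-deflated.
design_summaries <- function(design, deflate_ltfu = FALSE) {
  stopifnot(inherits(design, "borrow_design"))
  f <- if (deflate_ltfu) 1 - design$ltfu else 1
  tibble::tibble(
    label = c("target", "source"),
    estimate = c(0, 0),
    se = c(planning_se(design$n_target * f, design$p_fail, design$alloc),
           planning_se(design$n_source * f, design$p_fail, design$alloc)))
}
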