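#' Relative weight allocated to the source subgroup
#'
#' Under the commensurate-prior model the posterior precision for the target
#' subgroup treatment effect is the sum of the target data precision
#' `1/se_target^2` and the borrowed precision `1/(se_source^2 + sigma_delta^2)`,
#' where `sigma_delta` is the prior standard deviation of the
#' treatment-by-subgroup interaction. The relative weight of the source
#' subgroup is the borrowed share of that total precision. It equals
#' `se_target^2 / (se_source^2 + se_target^2)` at `sigma_delta = 0` (full
#' pooling) and decreases strictly to 0 as `sigma_delta` grows.
#'
#' @param sigma_delta Prior standard deviation of the interaction (>= 0);
#'   vectorised.
#' @param se_target,se_source Standard errors of the subgroup estimates (> 0).
#'
#' @return Numeric vector of weights in `[0, 1]`.
#'
#' @examples
#' relative_weight(0, se_target = planning_se(80, 0.18),
#'                 se_source = planning_se(700, 0.18))  # ~0.897
#' @export
relative_weight <- function(sigma_delta, se_target, se_source) {
  check_number(se_target, "se_target", lower = 0, allow_boundary = FALSE)
  check_number(se_source, "se_source", lower = 0, allow_boundary = FALSE)
  abort_if(any(!is.finite(sigma_delta) & !is.infinite(sigma_delta)) ||
             any(sigma_delta < 0),
           "`sigma_delta` must be >= 0.")
  prec_source <- 1 / (se_source^2 + sigma_delta^2)
  prec_target <- 1 / se_target^2
  prec_source / (prec_target + prec_source)
}

#' Interaction prior standard deviation implied by a relative weight
#'
#' Inverts [relative_weight()]: finds the `sigma_delta` at which the source
#' subgroup receives the stated share of the posterior precision. Used to
#' translate an elicited weight into the analysis prior. The weight cannot
#' exceed the full-pooling bound `w_max = se_target^2 / (se_source^2 +
#' se_target^2)` attained at `sigma_delta = 0`.
#'
#' @inheritParams relative_weight
#' @param weight Desired source-subgroup weight, in `(0, w_max]`; vectorised.
#'
#' @return `sigma_delta = sqrt(se_target^2 * (1 - w) / w - se_source^2)`,
#'   satisfying the round-trip identity
#'   `relative_weight(sigma_delta_from_weight(w)) == w`.
#'
#' @examples
#' sigma_delta_from_weight(0.78, se_target = planning_se(85, 0.18),
#'                         se_source = planning_se(707, 0.18))  # ~0.0335
#' @export
sigma_delta_from_weight <- function(weight, se_target, se_source) {
  check_number(se_target, "se_target", lower = 0, allow_boundary = FALSE)
  check_number(se_source, "se_source", lower = 0, allow_boundary = FALSE)
  abort_if(any(!is.finite(weight)) || any(weight <= 0),
           "`weight` must be > 0.")
  w_max <- se_target^2 / (se_source^2 + se_target^2)
  abort_if(any(weight > w_max + 1e-12),
           "`weight` exceeds the full-pooling bound w_max = %.6f; no nonnegative sigma_delta borrows that much.",
           w_max)
  v <- se_target^2 * (1 - weight) / weight - se_source^2
  sqrt(pmax(v, 0))
}

#' Combine subgroup summaries under the commensurate prior
#'
#' Closed-form conjugate-normal posterior for the treatment effect in the
#' target subgroup when the source subgroup's estimate is borrowed through a
#' zero-mean normal prior on the treatment-by-subgroup interaction. The
#' posterior mean is the precision-weighted average of the two estimates, with
#' the source precision discounted from `1/se^2` to `1/(se^2 + sigma_delta^2)`;
#' the posterior variance is the inverse total precision. Subgroup standard
#' errors are treated as fixed and known.
#'
#' Either `sigma_delta` or `weight` (but not both) selects the degree of
#' borrowing; a `weight` is converted with [sigma_delta_from_weight()] using
#' the standard errors in `data` unless planning standard errors are supplied
#' via `design`.
#'
#' @param data Subgroup summaries: a data frame with columns `label`
#'   (`"target"`/`"source"`), `estimate`, `se`, e.g. from [subgroup_data()] or
#'   [simulate_trial()].
#' @param sigma_delta Prior standard deviation of the interaction (>= 0).
#' @param weight Alternative to `sigma_delta`: elicited source-subgroup weight.
#' @param design Optional [plan_design()]; when given together with `weight`,
#'   the weight-to-`sigma_delta` conversion uses the design's planning
#'   standard errors (the elicitation-time convention) rather than the
#'   observed ones.
#' @param level Credible-interval coverage (default 0.95).
#' @param flat_prior_variance Variance of the vague normal prior on the source
#'   subgroup's true effect (default `1e6`, effectively flat; the closed form
#'   is the exact limit and is insensitive to this value beyond `1e6`).
#'
#' @return An object of class `borrow_fit` with [generics::tidy()],
#'   [generics::glance()], `print()` and [ggplot2::autoplot()] methods.
#'   `tidy()` yields one row with the posterior mean, sd and equal-tailed
#'   credible bounds; `glance()` adds `sigma_delta` and the realized
#'   `weight_source`.
#'
#' @examples
#' dat <- subgroup_data(
#'   target = list(estimate = 0.07, ci_lower = -0.10, ci_upper = 0.24),
#'   source = list(estimate = -0.02, ci_lower = -0.08, ci_upper = 0.04)
#' )
#' fit <- borrow_posterior(dat, sigma_delta = 0.0335)
#' generics::tidy(fit)
#' @export
borrow_posterior <- function(data, sigma_delta = NULL, weight = NULL,
                             design = NULL, level = 0.95,
                             flat_prior_variance = 1e6) {
  data <- validate_subgroup_data(data)
  check_number(level, "level", 0, 1, allow_boundary = FALSE)
  check_number(flat_prior_variance, "flat_prior_variance", lower = 0,
               allow_boundary = FALSE)
  abort_if(!is.null(sigma_delta) && !is.null(weight),
           "supply `sigma_delta` or `weight`, not both (ambiguous).")
  abort_if(is.null(sigma_delta) && is.null(weight),
           "supply one of `sigma_delta` or `weight`.")
  tgt <- data[data$label == "target", ]
  src <- data[data$label == "source", ]
  if (!is.null(weight)) {
    check_number(weight, "weight", 0, 1, allow_boundary = FALSE)
    if (!is.null(design)) {
      stopifnot(inherits(design, "borrow_design"))
      sigma_delta <- sigma_delta_from_weight(weight, design$se_target,
                                             design$se_source)
    } else {
      sigma_delta <- sigma_delta_from_weight(weight, tgt$se, src$se)
    }
  }
  abort_if(!is.numeric(sigma_delta) || length(sigma_delta) != 1L ||
             is.na(sigma_delta) || sigma_delta < 0,
           "`sigma_delta` must be a single number >= 0.")

  post <- posterior_moments(tgt$estimate, tgt$se, src$estimate, src$se,
                            sigma_delta, flat_prior_variance)
  z <- z_level(level)
  structure(
    list(data = data, sigma_delta = sigma_delta, level = level,
         flat_prior_variance = flat_prior_variance,
         mean = post$mean, sd = post$sd,
         cri_lower = post$mean - z * post$sd,
         cri_upper = post$mean + z * post$sd,
         weight_source = post$weight_source),
    class = "borrow_fit")
}

# Vectorised posterior moments under the commensurate-prior model with a
# flat-but-proper N(0, V) prior on the source subgroup's true effect. With
# V -> Inf this reduces to the familiar precision-weighted form; the exact
# finite-V expression is kept so that sensitivity to the vague prior is a
# statement about the model, not about numerics. Marginally,
#   theta_target | y ~ N(m, v) with borrowed precision through the source
# posterior N(y0 * V/(V + s0^2), (1/V + 1/s0^2)^-1) plus interaction variance.
posterior_moments <- function(y1, s1, y0, s0, sigma_delta,
                              flat_prior_variance = 1e6) {
  v0 <- 1 / (1 / flat_prior_variance + 1 / s0^2)     # source posterior var
  m0 <- y0 * v0 / s0^2                               # source posterior mean
  prior_var <- v0 + sigma_delta^2                    # prior for theta_target
  prec <- 1 / s1^2 + 1 / prior_var
  mean <- (y1 / s1^2 + m0 / prior_var) / prec
  list(mean = mean, sd = sqrt(1 / prec),
       weight_source = (1 / prior_var) / prec)
}

#' Inverse-variance pooled analysis of both subgroups
#'
#' The conventional combined analysis that would be appropriate if the
#' treatment effects in the two subgroups were believed identical: the special
#' case of [borrow_posterior()] with `sigma_delta = 0`.
#'
#' @inheritParams borrow_posterior
#' @return A `borrow_fit`, as for [borrow_posterior()].
#'
#' @examples
#' dat <- subgroup_data(
#'   target = list(estimate = 0.07, ci_lower = -0.10, ci_upper = 0.24),
#'   source = list(estimate = -0.02, ci_lower = -0.08, ci_upper = 0.04)
#' )
#' generics::tidy(pooled_estimate(dat))
#' @export
pooled_estimate <- function(data, level = 0.95, flat_prior_variance = 1e6) {
  borrow_posterior(data, sigma_delta = 0, level = level,
                   flat_prior_variance = flat_prior_variance)
}

#' Effective sample size of the borrowed information
#'
#' Expresses the discounted source-subgroup information as the number of
#' target-population participants carrying the same precision: the `N` whose
#' planning variance `4 p (1-p) / N` (1:1 allocation) equals the borrowed
#' variance `se_source^2 + sigma_delta^2`, rounded to the nearest integer.
#' The total effective sample size adds the target subgroup itself.
#'
#' @param sigma_delta Prior standard deviation of the interaction (>= 0).
#' @param design A [plan_design()]; its planning source standard error and
#'   `p_fail` define the variance scale.
#'
#' @return A tibble with columns `ess_borrowed` and `ess_total`.
#'
#' @examples
#' d <- plan_design(85, 707, p_fail = 0.18, ltfu = 0.10, margin = 0.10)
#' effective_sample_size(sigma_delta_from_weight(0.78, d$se_target, d$se_source), d)
#' @export
effective_sample_size <- function(sigma_delta, design) {
  stopifnot(inherits(design, "borrow_design"))
  check_number(sigma_delta, "sigma_delta", lower = 0)
  borrowed_var <- design$se_source^2 + sigma_delta^2
  abort_if(borrowed_var <= 0, "borrowed variance must be positive.")
  p <- design$p_fail
  var_unit <- p * (1 - p) * (1 / design$alloc + 1 / (1 - design$alloc))
  ess <- as.integer(round(var_unit / borrowed_var))
  tibble::tibble(ess_borrowed = ess,
                 ess_total = ess + as.integer(round(design$n_target)))
}

#' Conditional prior range implied by the interaction prior
#'
#' The feedback quantity shown to experts: if the source-subgroup treatment
#' effect were known exactly to be `theta0_assumed` (the "very large trial"
#' framing), the interaction prior implies a central `level` range
#' `theta0_assumed +/- z * sigma_delta` for the target-subgroup effect.
#'
#' @param theta0_assumed Assumed source-subgroup risk difference (proportion
#'   scale).
#' @param sigma_delta Prior standard deviation of the interaction (>= 0);
#'   vectorised.
#' @param level Range coverage (default 0.95).
#'
#' @return A tibble with columns `lower` and `upper`.
#'
#' @examples
#' implied_prior_range(-0.05, 0.0335)  # about -11.6% to 1.6%
#' @export
implied_prior_range <- function(theta0_assumed, sigma_delta, level = 0.95) {
  check_number(theta0_assumed, "theta0_assumed", -1, 1)
  check_number(level, "level", 0, 1, allow_boundary = FALSE)
  abort_if(any(!is.finite(sigma_delta)) || any(sigma_delta < 0),
           "`sigma_delta` must be >= 0.")
  z <- z_level(level)
  tibble::tibble(lower = theta0_assumed - z * sigma_delta,
                 upper = theta0_assumed + z * sigma_delta)
}
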