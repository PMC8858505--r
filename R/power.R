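#' Specify the true state of nature for trial simulation
#'
#' @param p_fail_soc,p_fail_dtg True failure probabilities in the control
#'   (SOC) and treatment (DTG) arms, shared by both subgroups.
#' @param delta_true True treatment-by-subgroup interaction: added to the DTG
#'   failure probability in the target subgroup only, so the target-subgroup
#'   risk difference is `(p_fail_dtg + delta_true) - p_fail_soc`.
#'
#' @return An object of class `truth_scenario`.
#' @examples
#' truth_scenario(0.18, 0.18)                      # effects identical
#' truth_scenario(0.18, 0.18, delta_true = 0.10)   # target effect at the margin
#' @export
truth_scenario <- function(p_fail_soc = 0.18, p_fail_dtg = p_fail_soc,
                           delta_true = 0) {
  check_number(p_fail_soc, "p_fail_soc", 0, 1, allow_boundary = FALSE)
  check_number(p_fail_dtg, "p_fail_dtg", 0, 1, allow_boundary = FALSE)
  check_number(delta_true, "delta_true", -1, 1)
  p_dtg_target <- p_fail_dtg + delta_true
  abort_if(p_dtg_target <= 0 || p_dtg_target >= 1,
           "implied target-subgroup DTG failure probability %.3f is outside (0, 1).",
           p_dtg_target)
  structure(list(p_fail_soc = p_fail_soc, p_fail_dtg = p_fail_dtg,
                 delta_true = delta_true, p_dtg_target = p_dtg_target),
            class = "truth_scenario")
}

# Run code under a caller-supplied seed without disturbing the session RNG
# state; seed = NULL draws from the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  check_number(seed, "seed")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Vectorised simulation of one subgroup over n_reps trials.
# Per rep and arm: followed ~ Binomial(n_arm, 1 - ltfu) (dropouts excluded,
# complete case), failures ~ Binomial(followed, p_arm). Wald estimate and SE
# of the DTG - SOC difference in observed failure proportions; arms with a
# zero cell get 0.5 added to both failures and non-failures (for the SE only).
# Reps in which an arm has no analysed participants are redrawn (counted in
# attr "n_resimulated").
simulate_subgroup <- function(n_reps, n_total, p_dtg, p_soc, ltfu, alloc) {
  n_dtg <- round(alloc * n_total)
  n_soc <- round(n_total) - n_dtg
  abort_if(n_dtg < 1 || n_soc < 1, "allocation leaves an empty arm.")
  draw <- function(k) {
    f_dtg <- stats::rbinom(k, n_dtg, 1 - ltfu)
    f_soc <- stats::rbinom(k, n_soc, 1 - ltfu)
    list(f_dtg = f_dtg, f_soc = f_soc,
         x_dtg = stats::rbinom(k, f_dtg, p_dtg),
         x_soc = stats::rbinom(k, f_soc, p_soc))
  }
  d <- draw(n_reps)
  n_resim <- 0L
  repeat {
    bad <- which(d$f_dtg == 0 | d$f_soc == 0)
    if (length(bad) == 0) break
    n_resim <- n_resim + length(bad)
    r <- draw(length(bad))
    for (nm in names(d)) d[[nm]][bad] <- r[[nm]]
  }
  wald_arm <- function(x, n) {
    zero <- x == 0 | x == n
    xa <- x + 0.5 * zero
    na <- n + 1 * zero
    ph <- xa / na
    ph * (1 - ph) / na
  }
  est <- d$x_dtg / d$f_dtg - d$x_soc / d$f_soc
  se <- sqrt(wald_arm(d$x_dtg, d$f_dtg) + wald_arm(d$x_soc, d$f_soc))
  out <- list(estimate = est, se = se)
  attr(out, "n_resimulated") <- n_resim
  out
}

simulate_summaries <- function(n_reps, design, truth) {
  stopifnot(inherits(design, "borrow_design"), inherits(truth, "truth_scenario"))
  list(
    target = simulate_subgroup(n_reps, design$n_target, truth$p_dtg_target,
                               truth$p_fail_soc, design$ltfu, design$alloc),
    source = simulate_subgroup(n_reps, design$n_source, truth$p_fail_dtg,
                               truth$p_fail_soc, design$ltfu, design$alloc))
}

#' Simulate one trial under planning assumptions
#'
#' Draws one realisation of both subgroups: participants are randomised
#' between arms per `alloc`, an independent Bernoulli loss-to-follow-up
#' process removes participants (complete-case analysis), failures are
#' binomial among those followed, and each subgroup is summarised by the Wald
#' risk difference (DTG − SOC) and its standard error (0.5 added to both
#' cells of any arm with a zero cell). The result feeds directly into
#' [borrow_posterior()].
#'
#' @param design A [plan_design()].
#' @param truth A [truth_scenario()].
#' @param seed Optional integer seed; the session RNG state is preserved.
#'
#' @return A subgroup-summary tibble (`label`, `estimate`, `se`).
#' @examples
#' d <- plan_design(85, 707, p_fail = 0.18, ltfu = 0.10, margin = 0.10)
#' simulate_trial(d, truth_scenario(0.18), seed = 1)
#' @export
simulate_trial <- function(design, truth = truth_scenario(design$p_fail),
                           seed = NULL) {
  with_seed(seed, {
    s <- simulate_summaries(1L, design, truth)
    tibble::tibble(label = c("target", "source"),
                   estimate = c(s$target$estimate, s$source$estimate),
                   se = c(s$target$se, s$source$se))
  })
}

#' Non-inferiority decision rule
#'
#' The treatment is judged non-inferior when the upper bound of the 95%
#' interval for the risk difference (DTG − SOC) lies strictly below the
#' margin.
#'
#' @param result A `borrow_fit` (its credible upper bound is used) or a
#'   numeric vector of interval upper bounds.
#' @param margin Non-inferiority margin (> 0).
#' @return Logical vector.
#' @examples
#' dat <- subgroup_data(
#'   target = list(estimate = 0.07, ci_lower = -0.10, ci_upper = 0.24),
#'   source = list(estimate = -0.02, ci_lower = -0.08, ci_upper = 0.04)
#' )
#' declare_noninferior(borrow_posterior(dat, sigma_delta = 0.0335), 0.10)
#' @export
declare_noninferior <- function(result, margin) {
  check_number(margin, "margin", lower = 0, allow_boundary = FALSE)
  upper <- if (inherits(result, "borrow_fit")) result$cri_upper else result
  abort_if(!is.numeric(upper), "`result` must be a borrow_fit or numeric.")
  upper < margin
}

power_result <- function(method, hits, n_reps, seed, settings) {
  power <- hits / n_reps
  tibble::tibble(method = method, power = power,
                 mc_se = sqrt(power * (1 - power) / n_reps),
                 n_reps = as.integer(n_reps),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
                 !!!settings)
}

#' Predictive power of the planned borrowing analysis
#'
#' Monte-Carlo estimate of the probability that the planned Bayesian
#' borrowing analysis declares non-inferiority: each simulated trial
#' ([simulate_trial()]) is analysed with [borrow_posterior()] at the fixed,
#' elicitation-derived `sigma_delta` (the realised weight varies with the
#' simulated standard errors), and the proportion of trials whose 95%
#' credible upper bound falls below the design margin is reported.
#'
#' @param design A [plan_design()].
#' @param sigma_delta Interaction prior standard deviation, held fixed across
#'   replicates.
#' @param truth A [truth_scenario()]; defaults to equal failure rates
#'   `design$p_fail` in all arms.
#' @param n_reps Number of simulated trials (default 20000; at least 1000 for
#'   reporting).
#' @param seed Optional integer seed (session RNG preserved).
#' @param level Credible level (default 0.95).
#'
#' @return A one-row tibble: `method`, `power`, `mc_se`, `n_reps`, `seed`,
#'   `margin`, `sigma_delta`.
#' @examples
#' d <- plan_design(85, 707, p_fail = 0.18, ltfu = 0.10, margin = 0.10)
#' predictive_power(d, sigma_delta = 0.0335, n_reps = 2000, seed = 1)
#' @export
predictive_power <- function(design, sigma_delta,
                             truth = truth_scenario(design$p_fail),
                             n_reps = 20000, seed = NULL, level = 0.95) {
  stopifnot(inherits(design, "borrow_design"))
  check_number(sigma_delta, "sigma_delta", lower = 0)
  check_number(n_reps, "n_reps", lower = 1)
  with_seed(seed, {
    s <- simulate_summaries(n_reps, design, truth)
    post <- posterior_moments(s$target$estimate, s$target$se,
                              s$source$estimate, s$source$se, sigma_delta)
    upper <- post$mean + z_level(level) * post$sd
    power_result("bayesian_borrowing", sum(upper < design$margin), n_reps,
                 seed, list(margin = design$margin, sigma_delta = sigma_delta))
  })
}

#' Power of the standalone frequentist target-subgroup analysis
#'
#' Monte-Carlo estimate of the probability that the target subgroup alone
#' satisfies the non-inferiority criterion `estimate + z * se < margin`.
#'
#' @inheritParams predictive_power
#' @return A one-row tibble: `method`, `power`, `mc_se`, `n_reps`, `seed`,
#'   `margin`.
#' @examples
#' d <- plan_design(85, 707, p_fail = 0.18, ltfu = 0.10, margin = 0.10)
#' standalone_power(d, n_reps = 2000, seed = 1)
#' @export
standalone_power <- function(design, truth = truth_scenario(design$p_fail),
                             n_reps = 20000, seed = NULL, level = 0.95) {
  stopifnot(inherits(design, "borrow_design"))
  check_number(n_reps, "n_reps", lower = 1)
  with_seed(seed, {
    s <- simulate_subgroup(n_reps, design$n_target,
                           truth$p_dtg_target, truth$p_fail_soc,
                           design$ltfu, design$alloc)
    upper <- s$estimate + z_level(level) * s$se
    power_result("standalone_frequentist", sum(upper < design$margin), n_reps,
                 seed, list(margin = design$margin))
  })
}

#' Closed-form normal approximation to the standalone power
#'
#' Deterministic cross-check for [standalone_power()]: with the true risk
#' difference in the target subgroup equal to `delta_true` and the standard
#' error fixed at its planning value for the LTFU-deflated sample size,
#' the power is `pnorm((margin - delta_true) / se_plan - z)`.
#'
#' @param design A [plan_design()].
#' @param delta_true True target-subgroup risk difference (default 0).
#' @param level Confidence level (default 0.95).
#' @return A single probability.
#' @examples
#' analytic_standalone_power(
#'   plan_design(85, 707, p_fail = 0.18, ltfu = 0.10, margin = 0.10))
#' @export
analytic_standalone_power <- function(design, delta_true = 0, level = 0.95) {
  stopifnot(inherits(design, "borrow_design"))
  se_plan <- planning_se(design$n_target * (1 - design$ltfu), design$p_fail,
                         design$alloc)
  stats::pnorm((design$margin - delta_true) / se_plan - z_level(level))
}
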