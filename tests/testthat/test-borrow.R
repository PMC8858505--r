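test_that("relative_weight reproduces the sample-size-only and elicited weights", {
  # at sigma_delta = 0 the weight is a pure sample-size ratio: 700/780
  w0 <- relative_weight(0, se_target = planning_se(80, 0.18),
                        se_source = planning_se(700, 0.18))
  expect_equal(w0, 700 / 780, tolerance = 1e-12)
  expect_equal(round(100 * w0), 90)
  # published elicited weight at the final sample sizes
  d <- odyssey_design()
  expect_equal(relative_weight(0.03353, d$se_target, d$se_source), 0.780,
               tolerance = 5e-4)
  # infinite interaction uncertainty removes all borrowing
  expect_equal(relative_weight(Inf, d$se_target, d$se_source), 0)
  expect_error(relative_weight(-0.1, d$se_target, d$se_source))
})

test_that("weight <-> sigma_delta conversion is a round-trip identity", {
  d <- odyssey_design()
  sd78 <- sigma_delta_from_weight(0.78, d$se_target, d$se_source)
  expect_equal(sd78, 0.03352637, tolerance = 1e-6)  # frozen: root of weight eqn
  w_max <- d$se_target^2 / (d$se_source^2 + d$se_target^2)
  # full pooling bound
  expect_equal(sigma_delta_from_weight(w_max, d$se_target, d$se_source), 0)
  expect_error(sigma_delta_from_weight(0.95, d$se_target, d$se_source),
               "w_max")
  expect_error(sigma_delta_from_weight(0, d$se_target, d$se_source))
  # identity on (0, w_max) to 1e-10
  ws <- seq(0.01, 1, length.out = 50) * w_max
  back <- relative_weight(sigma_delta_from_weight(ws, d$se_target, d$se_source),
                          d$se_target, d$se_source)
  expect_equal(back, ws, tolerance = 1e-10)
})

example_data <- function(which) {
  source <- list(estimate = -0.02, ci_lower = -0.08, ci_upper = 0.04)
  target <- if (which == 1) {
    list(estimate = 0.07, ci_lower = -0.10, ci_upper = 0.24)
  } else {
    list(estimate = -0.10, ci_lower = -0.25, ci_upper = 0.05)
  }
  subgroup_data(target = target, source = source)
}

test_that("borrow_posterior reproduces the published worked examples", {
  d <- odyssey_design()
  sd78 <- sigma_delta_from_weight(0.78, d$se_target, d$se_source)

  fit1 <- borrow_posterior(example_data(1), sigma_delta = sd78)
  expect_equal(to_pct(fit1$mean), 0)        # published: 0%
  expect_equal(to_pct(fit1$cri_lower), -8)  # published: -8%
  expect_equal(to_pct(fit1$cri_upper), 8)   # published: 8%

  fit2 <- borrow_posterior(example_data(2), sigma_delta = sd78)
  expect_equal(to_pct(fit2$mean), -4)       # published: -4%

  # agreement case: identical inputs pass through unchanged at sigma_delta = 0
  same <- subgroup_data(target = list(estimate = 0.03, se = 0.08),
                        source = list(estimate = 0.03, se = 0.03))
  expect_equal(borrow_posterior(same, sigma_delta = 0)$mean, 0.03,
               tolerance = 1e-9)

  # weight and sigma_delta are mutually exclusive
  expect_error(borrow_posterior(example_data(1), sigma_delta = 0.1,
                                weight = 0.5), "not both")
  expect_error(borrow_posterior(example_data(1)), "one of")
})

test_that("pooled_estimate reproduces the published pooled results", {
  fit1 <- pooled_estimate(example_data(1))
  expect_equal(to_pct(fit1$mean), -1)       # published: -1%
  fit2 <- pooled_estimate(example_data(2))
  expect_equal(to_pct(fit2$mean), -3)       # published: -3%
  # equal standard errors pool to the simple average
  eq <- subgroup_data(target = list(estimate = 0.10, se = 0.05),
                      source = list(estimate = -0.02, se = 0.05))
  expect_equal(pooled_estimate(eq)$mean, 0.04, tolerance = 1e-8)
})

test_that("inverse-variance pooling agrees with a fixed-effect meta-analysis", {
  dat <- example_data(2)
  fit <- pooled_estimate(dat)
  rma <- metafor::rma(yi = dat$estimate, sei = dat$se, method = "FE")
  expect_equal(fit$mean, as.numeric(rma$beta), tolerance = 1e-6)
  expect_equal(fit$sd, as.numeric(rma$se), tolerance = 1e-6)
})

test_that("posterior matches the 2-D grid-integration oracle", {
  set.seed(20220220)
  for (i in 1:50) {
    y1 <- runif(1, -0.3, 0.3); y0 <- runif(1, -0.3, 0.3)
    s1 <- runif(1, 0.03, 0.15); s0 <- runif(1, 0.02, 0.08)
    sdl <- runif(1, 0.005, 0.10)
    dat <- subgroup_data(target = list(estimate = y1, se = s1),
                         source = list(estimate = y0, se = s0))
    fit <- borrow_posterior(dat, sigma_delta = sdl)
    orc <- grid_posterior(y1, s1, y0, s0, sdl)
    expect_equal(fit$mean, orc$mean, tolerance = 1e-4)
    expect_equal(fit$sd, orc$sd, tolerance = 1e-4)
  }
  # sigma_delta = 0 path against the 1-D grid
  fit0 <- borrow_posterior(example_data(1), sigma_delta = 0)
  orc0 <- grid_posterior(0.07, se_from_ci(-0.10, 0.24),
                         -0.02, se_from_ci(-0.08, 0.04), 0)
  expect_equal(fit0$mean, orc0$mean, tolerance = 1e-4)
  expect_equal(fit0$sd, orc0$sd, tolerance = 1e-4)
})

test_that("posterior structural invariants hold", {
  set.seed(7)
  d <- odyssey_design()
  for (i in 1:25) {
    y1 <- runif(1, -0.3, 0.3); y0 <- runif(1, -0.3, 0.3)
    s1 <- runif(1, 0.03, 0.15); s0 <- runif(1, 0.02, 0.08)
    sdl <- runif(1, 0, 0.15)
    dat <- subgroup_data(target = list(estimate = y1, se = s1),
                         source = list(estimate = y0, se = s0))
    fit <- borrow_posterior(dat, sigma_delta = sdl)
    # precision additivity (to the flat-prior approximation)
    expect_equal(1 / fit$sd^2, 1 / s1^2 + 1 / (s0^2 + sdl^2),
                 tolerance = 1e-7)
    # convexity: the posterior mean lies between the inputs
    expect_gte(fit$mean, min(y0, y1) - 1e-12)
    expect_lte(fit$mean, max(y0, y1) + 1e-12)
    # interval brackets the mean, weight in [0, 1]
    expect_lt(fit$cri_lower, fit$mean)
    expect_gt(fit$cri_upper, fit$mean)
    expect_gte(fit$weight_source, 0)
    expect_lte(fit$weight_source, 1)
  }
})

test_that("borrowing is monotone in sigma_delta and has the right limits", {
  dat <- example_data(1)
  grid <- c(0, 0.005, 0.01, 0.02, 0.05, 0.1, 0.5)
  fits <- lapply(grid, function(s) borrow_posterior(dat, sigma_delta = s))
  w <- vapply(fits, function(f) f$weight_source, numeric(1))
  s <- vapply(fits, function(f) f$sd, numeric(1))
  expect_true(all(diff(w) < 0))  # strictly decreasing weight
  expect_true(all(diff(s) > 0))  # strictly increasing posterior sd
  d <- odyssey_design()
  ess <- vapply(grid, function(x) {
    effective_sample_size(x, d)$ess_borrowed
  }, integer(1))
  expect_true(all(diff(ess) < 0))

  # sigma_delta = 0 reproduces the pooled analysis exactly
  f0 <- borrow_posterior(dat, sigma_delta = 0)
  fp <- pooled_estimate(dat)
  expect_identical(f0$mean, fp$mean)
  expect_identical(f0$sd, fp$sd)
  # sigma_delta = 1e3 reproduces the standalone target summary
  f_inf <- borrow_posterior(dat, sigma_delta = 1e3)
  tgt <- dat[dat$label == "target", ]
  expect_equal(f_inf$mean, tgt$estimate, tolerance = 1e-6)
  expect_equal(f_inf$sd, tgt$se, tolerance = 1e-6)
})

test_that("results are insensitive to the vague-prior variance", {
  dat <- example_data(2)
  f6 <- borrow_posterior(dat, sigma_delta = 0.03, flat_prior_variance = 1e6)
  f9 <- borrow_posterior(dat, sigma_delta = 0.03, flat_prior_variance = 1e9)
  expect_equal(f6$mean, f9$mean, tolerance = 1e-6)
  expect_equal(f6$sd, f9$sd, tolerance = 1e-6)
})

test_that("effective sample size reproduces the published planning values", {
  d <- odyssey_design()
  sd78 <- sigma_delta_from_weight(0.78, d$se_target, d$se_source)
  ess <- effective_sample_size(sd78, d)
  expect_identical(ess$ess_borrowed, 301L)  # published
  expect_identical(ess$ess_total, 386L)     # published: 301 + 85
  # full pooling borrows the whole source subgroup
  expect_identical(effective_sample_size(0, d)$ess_borrowed, 707L)
  # vague interaction prior borrows nobody
  expect_identical(effective_sample_size(10, d)$ess_borrowed, 0L)
})

test_that("implied prior range matches the elicitation feedback values", {
  d <- odyssey_design()
  sd78 <- sigma_delta_from_weight(0.78, d$se_target, d$se_source)
  rng <- implied_prior_range(-0.05, sd78)
  expect_equal(rng$lower, -0.1157105, tolerance = 1e-4)
  expect_equal(rng$upper, 0.0157105, tolerance = 1e-4)
  expect_equal(to_pct(rng$lower), -12)  # published
  expect_equal(to_pct(rng$upper), 2)    # published
  # point mass at sigma_delta = 0; symmetric half-width z * sigma_delta
  expect_equal(unlist(implied_prior_range(-0.05, 0)), c(lower = -0.05, upper = -0.05))
  rng0 <- implied_prior_range(0, 0.0335)
  expect_equal(rng0$upper, 0.0656588, tolerance = 1e-4)
  expect_equal(rng0$lower, -rng0$upper)
})

test_that("tidy and glance expose the fit in broom conventions", {
  fit <- borrow_posterior(example_data(1), weight = 0.78,
                          design = odyssey_design())
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "conf.low", "conf.high"))
  expect_equal(td$estimate, fit$mean)
  gl <- glance(fit)
  expect_equal(gl$sigma_delta, 0.03352637, tolerance = 1e-6)
  # realized weight uses the observed SEs, so it is near (not at) the
  # planning-derived 0.78
  expect_equal(gl$weight_source, 0.78, tolerance = 0.02)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
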