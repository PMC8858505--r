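test_that("fit_opinions maps ranges to central normal distributions", {
  fo <- fit_opinions(tibble::tibble(range_lower = -0.10, range_upper = 0.00,
                                    coverage = 0.90))
  expect_equal(fo$mu, -0.05)
  expect_equal(fo$sigma, 0.0303978416, tolerance = 1e-6)  # 0.05 / 1.6448536
  # quartiles are consistent with the fitted sigma
  expect_equal(fo$q75 - fo$q25, 2 * qnorm(0.75) * fo$sigma, tolerance = 1e-9)

  # symmetric range: zero mean regardless of the coverage assigned
  for (p in c(0.5, 0.7, 0.9, 0.98)) {
    expect_equal(fit_opinions(tibble::tibble(range_lower = -0.2,
                                             range_upper = 0.2,
                                             coverage = p))$mu, 0)
  }
  # p = 0.5 means the elicited range IS the inter-quartile range
  fo50 <- fit_opinions(tibble::tibble(range_lower = -0.08, range_upper = 0.02,
                                      coverage = 0.5))
  expect_equal(fo50$sigma, 0.10 / (2 * qnorm(0.75)), tolerance = 1e-9)
  expect_equal(c(fo50$q25, fo50$q75), c(-0.08, 0.02), tolerance = 1e-9)

  expect_error(fit_opinions(tibble::tibble(range_lower = 0.1,
                                           range_upper = 0.1,
                                           coverage = 0.9)), "range_upper")
  expect_error(fit_opinions(tibble::tibble(range_lower = -0.1,
                                           range_upper = 0.1,
                                           coverage = 1)), "coverage")
})

test_that("fitted normals assign exactly the elicited probability to the range", {
  set.seed(11)
  resp <- tibble::tibble(range_lower = runif(20, -0.3, -0.01),
                         range_upper = runif(20, 0.0, 0.3),
                         coverage = runif(20, 0.55, 0.98))
  fo <- fit_opinions(resp)
  achieved <- pnorm(resp$range_upper, fo$mu, fo$sigma) -
    pnorm(resp$range_lower, fo$mu, fo$sigma)
  expect_equal(achieved, resp$coverage, tolerance = 1e-10)
})

test_that("fit_normal mapping is scale-equivariant", {
  prop <- fit_opinions(tibble::tibble(range_lower = -0.12, range_upper = 0.02,
                                      coverage = 0.9))
  pct <- fit_opinions(tibble::tibble(range_lower = -12, range_upper = 2,
                                     coverage = 0.9))
  expect_equal(pct$mu / 100, prop$mu)
  expect_equal(pct$sigma / 100, prop$sigma)
})

test_that("opinion_to_weight treats the fitted spread as interaction uncertainty", {
  d <- odyssey_design()
  # an expert whose fitted sigma equals the panel sigma_delta maps back to 78%
  half <- qnorm(0.975) * 0.03352637
  ow <- opinion_to_weight(tibble::tibble(range_lower = -0.05 - half,
                                         range_upper = -0.05 + half,
                                         coverage = 0.95), d)
  expect_equal(ow$implied_weight, 0.78, tolerance = 1e-4)
  # certainty gives the full-pooling weight; vagueness kills borrowing
  w_max <- d$se_target^2 / (d$se_source^2 + d$se_target^2)
  ow0 <- opinion_to_weight(tibble::tibble(sigma = c(0, 10)), d)
  expect_equal(ow0$implied_weight, c(w_max, 0), tolerance = 1e-3)
})

test_that("pool_weights pools by the median of a typical expert", {
  expect_equal(pool_weights(0.78)$median_weight, 0.78)
  expect_equal(pool_weights(c(0.6, 0.7, 0.8))$median_weight, 0.7)
  set.seed(3)
  for (i in 1:10) {
    w <- runif(13, 0.3, 0.95)
    expect_equal(pool_weights(w)$median_weight, median_oracle(w))
  }
  # even panel size uses interpolation; ties are deterministic
  expect_equal(pool_weights(c(0.7, 0.7, 0.8, 0.9))$median_weight, 0.75)
  expect_equal(pool_weights(rep(0.5, 6))$median_weight, 0.5)
  ps <- pool_weights(c(0.6, 0.7, 0.8))
  expect_true(ps$q25 <= ps$median_weight && ps$median_weight <= ps$q75)
  expect_error(pool_weights(numeric(0)), "at least one")
})

test_that("consensus_check agrees with exhaustive window enumeration", {
  # concordant panel: any 0.30 window around the bulk suffices
  expect_true(consensus_check(c(0.70, 0.75, 0.78, 0.80, 0.90))$met)
  # two extremes cannot share a 0.30 window
  expect_false(consensus_check(c(0, 1))$met)
  set.seed(5)
  for (i in 1:40) {
    n <- sample(1:15, 1)
    w <- runif(n)
    got <- consensus_check(w)
    expect_identical(got$met, consensus_oracle(w))
    # the reported window really contains the reported count
    expect_equal(got$n_in_window,
                 sum(w >= got$window_lower & w <= got$window_upper + 1e-12))
  }
  # boundary: exactly 80% of 5 inside a window of exactly 0.30
  expect_true(consensus_check(c(0.5, 0.6, 0.7, 0.8, 0.99))$met)
})

test_that("feedback_table reproduces the published feedback row and nests", {
  d <- odyssey_design()
  tab <- feedback_table(d, theta0_assumed = -0.05,
                        weights = c(0.78, seq(0.05, 0.85, by = 0.05)))
  row78 <- tab[tab$weight == 0.78, ]
  expect_equal(to_pct(row78$range_lower), -12)  # published
  expect_equal(to_pct(row78$range_upper), 2)    # published
  # ranges are strictly nested as the weight grows
  valid <- tab[tab$valid, ]
  valid <- valid[order(valid$weight), ]
  expect_true(all(diff(valid$range_lower) > 0))
  expect_true(all(diff(valid$range_upper) < 0))
  # weights beyond the pooling bound are flagged, not dropped
  tab2 <- feedback_table(d, -0.05, weights = c(0.5, 0.95))
  expect_identical(tab2$valid, c(TRUE, FALSE))
  expect_true(is.na(tab2$sigma_delta[2]))
  # the full-pooling limit collapses onto theta0
  w_max <- d$se_target^2 / (d$se_source^2 + d$se_target^2)
  tabmax <- feedback_table(d, -0.05, weights = w_max)
  expect_equal(c(tabmax$range_lower, tabmax$range_upper), c(-0.05, -0.05),
               tolerance = 1e-7)
})

test_that("elicitation CSV round-trips with strict schema and percent handling", {
  panel <- generate_elicitation_panel(7, seed = 42)
  path <- withr::local_tempfile(fileext = ".csv")
  write_elicitation(panel, path)
  back <- read_elicitation(path)
  expect_equal(as.data.frame(back), as.data.frame(panel), tolerance = 1e-12)

  # percent-scale rows are converted on read
  pct <- panel
  pct$range_lower <- pct$range_lower * 100
  pct$range_upper <- pct$range_upper * 100
  pct$assumed_theta0 <- pct$assumed_theta0 * 100
  pct$scale <- "percent"
  write_elicitation(pct, path)
  back2 <- read_elicitation(path)
  expect_equal(back2$range_lower, panel$range_lower, tolerance = 1e-12)
  expect_identical(unique(back2$scale), "proportion")

  # header and content validation are strict
  writeLines("a,b\n1,2", path)
  expect_error(suppressWarnings(read_elicitation(path)))
  bad <- panel
  bad$coverage[1] <- 1.2
  write_elicitation(bad, path)
  expect_error(read_elicitation(path), "coverage")
})
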