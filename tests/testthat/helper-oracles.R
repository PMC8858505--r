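# Independent numerical oracles used by the test suite. These deliberately
# avoid the package's closed-form code paths: the posterior oracle integrates
# the full two-parameter model on a grid, and the consensus oracle enumerates
# candidate windows directly.

# Posterior mean/sd of theta_target = theta_source + delta by 2-D grid
# integration of the joint posterior under
#   y1 ~ N(theta_source + delta, s1^2), y0 ~ N(theta_source, s0^2),
#   theta_source ~ N(0, V), delta ~ N(0, sigma_delta^2).
# Falls back to a 1-D grid when sigma_delta = 0 (delta degenerate at 0).
grid_posterior <- function(y1, s1, y0, s0, sigma_delta, V = 1e6,
                           n_grid = 601, span = 10) {
  if (sigma_delta == 0) {
    centre <- (y0 / s0^2 + y1 / s1^2) / (1 / s0^2 + 1 / s1^2)
    half <- span * sqrt(1 / (1 / s0^2 + 1 / s1^2))
    th <- seq(centre - half, centre + half, length.out = n_grid)
    logd <- stats::dnorm(y1, th, s1, log = TRUE) +
      stats::dnorm(y0, th, s0, log = TRUE) +
      stats::dnorm(th, 0, sqrt(V), log = TRUE)
    w <- exp(logd - max(logd))
    w <- w / sum(w)
    m <- sum(w * th)
    return(list(mean = m, sd = sqrt(sum(w * (th - m)^2))))
  }
  th0 <- seq(y0 - span * s0, y0 + span * s0, length.out = n_grid)
  # delta is informed by the prior and (weakly) by y1 - y0
  dl <- seq(-span * sigma_delta + min(0, y1 - y0),
            span * sigma_delta + max(0, y1 - y0), length.out = n_grid)
  logd <- outer(th0, dl, function(a, d) {
    stats::dnorm(y1, a + d, s1, log = TRUE) +
      stats::dnorm(y0, a, s0, log = TRUE) +
      stats::dnorm(a, 0, sqrt(V), log = TRUE) +
      stats::dnorm(d, 0, sigma_delta, log = TRUE)
  })
  w <- exp(logd - max(logd))
  w <- w / sum(w)
  t1 <- outer(th0, dl, `+`)
  m <- sum(w * t1)
  list(mean = m, sd = sqrt(sum(w * (t1 - m)^2)))
}

# Exhaustive consensus oracle: every closed window of the stated width that
# contains a maximal number of weights can be anchored at a data point, so
# enumerate pairs directly with outer().
consensus_oracle <- function(weights, window = 0.30, frac = 0.80) {
  s <- sort(weights)
  inside <- outer(s, s, function(a, b) b >= a & b <= a + window + 1e-12)
  max(rowSums(inside)) >= ceiling(frac * length(s))
}

# Sort-based median, independent of stats::quantile.
median_oracle <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

odyssey_design <- function() {
  plan_design(n_target = 85, n_source = 707, p_fail = 0.18,
              ltfu = 0.10, margin = 0.10)
}

# Percent rounding used when comparing to published whole-percent values.
to_pct <- function(x) sign(x) * floor(abs(x) * 100 + 0.5)
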