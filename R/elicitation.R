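#' Fit normal opinion distributions to elicited ranges
#'
#' Maps each expert's elicited uncertainty range `(a, b)` with coverage
#' probability `p` to a normal distribution, interpreting the range as a
#' central (equal-tailed) interval: `mu = (a + b)/2` and
#' `sigma = (b - a) / (2 * qnorm((p + 1)/2))`. Reporting the fitted means and
#' inter-quartile ranges makes opinions comparable across experts who
#' assigned different probabilities to their ranges.
#'
#' @param responses A data frame of elicitation responses with columns
#'   `range_lower`, `range_upper` and `coverage` (other columns, e.g.
#'   `expert_id`, `stage`, are carried through). See [read_elicitation()] for
#'   the full schema.
#'
#' @return The input tibble with columns `mu`, `sigma`, `q25`, `q75`
#'   appended (`q25`/`q75` are the fitted quartiles,
#'   `mu -/+ 0.67449 * sigma`).
#'
#' @examples
#' fit_opinions(tibble::tibble(expert_id = "A", range_lower = -0.10,
#'                             range_upper = 0.00, coverage = 0.90))
#' @export
fit_opinions <- function(responses) {
  abort_if(!is.data.frame(responses), "`responses` must be a data frame.")
  missing <- setdiff(c("range_lower", "range_upper", "coverage"),
                     names(responses))
  abort_if(length(missing) > 0, "`responses` is missing column(s): %s.",
           paste(missing, collapse = ", "))
  a <- responses$range_lower
  b <- responses$range_upper
  p <- responses$coverage
  abort_if(any(!is.finite(a)) || any(!is.finite(b)) || any(b <= a),
           "each range must have finite bounds with range_upper > range_lower.")
  abort_if(any(!is.finite(p)) || any(p <= 0) || any(p >= 1),
           "`coverage` must lie strictly in (0, 1).")
  zc <- stats::qnorm((p + 1) / 2)
  abort_if(any(zc <= 0) || any(!is.finite(zc)),
           "`coverage` too extreme: central-interval quantile degenerates.")
  q <- stats::qnorm(0.75)
  dplyr::mutate(tibble::as_tibble(responses),
                mu = (a + b) / 2,
                sigma = (b - a) / (2 * zc),
                q25 = .data$mu - q * .data$sigma,
                q75 = .data$mu + q * .data$sigma)
}

#' Convert fitted opinions to source-subgroup weights
#'
#' When an expert's range was elicited conditional on the source-subgroup
#' effect being known exactly (the "very large trial" framing), all of the
#' fitted spread is uncertainty about the treatment-by-subgroup interaction.
#' The fitted `sigma` is therefore taken as that expert's `sigma_delta` and
#' converted to the relative weight the source subgroup would receive under
#' the design's planning standard errors.
#'
#' @param responses A data frame of responses (see [fit_opinions()]); fitted
#'   with [fit_opinions()] first if the `sigma` column is absent.
#' @param design A [plan_design()] providing the planning standard errors.
#'
#' @return The input tibble with columns `sigma` (fitted, if not already
#'   present) and `implied_weight` appended.
#'
#' @examples
#' d <- plan_design(85, 707, p_fail = 0.18, ltfu = 0.10)
#' opinion_to_weight(tibble::tibble(range_lower = -0.1157, range_upper = 0.0157,
#'                                  coverage = 0.95), d)
#' @export
opinion_to_weight <- function(responses, design) {
  stopifnot(inherits(design, "borrow_design"))
  if (!"sigma" %in% names(responses)) responses <- fit_opinions(responses)
  dplyr::mutate(tibble::as_tibble(responses),
                implied_weight = relative_weight(.data$sigma,
                                                 design$se_target,
                                                 design$se_source))
}

#' Pool expert weights by the panel median
#'
#' Pools the weights chosen by a panel of experts using the median, so that
#' the pooled weight represents a "typical" expert and is not pulled by
#' extreme opinions, and reports the inter-quartile range and the
#' pre-specified consensus check.
#'
#' @param weights Numeric vector of chosen weights in `[0, 1]` (at least one),
#'   or a data frame with a `chosen_weight` column.
#' @param window,frac Consensus rule parameters passed to
#'   [consensus_check()]: default a 0.30 absolute window required to contain
#'   at least 80% of the panel.
#'
#' @return A one-row tibble: `n_experts`, `median_weight`, `q25`, `q75`
#'   (linear-interpolation quantiles), `consensus_met`, `window_lower`,
#'   `window_upper`.
#'
#' @examples
#' pool_weights(c(0.6, 0.7, 0.8))
#' @export
pool_weights <- function(weights, window = 0.30, frac = 0.80) {
  if (is.data.frame(weights)) {
    abort_if(!"chosen_weight" %in% names(weights),
             "`weights` data frame needs a `chosen_weight` column.")
    weights <- weights$chosen_weight
  }
  weights <- weights[!is.na(weights)]
  abort_if(length(weights) == 0, "at least one weight is required.")
  abort_if(any(weights < 0) || any(weights > 1),
           "weights must lie in [0, 1].")
  qs <- stats::quantile(weights, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  cons <- consensus_check(weights, window = window, frac = frac)
  tibble::tibble(n_experts = length(weights),
                 median_weight = qs[2], q25 = qs[1], q75 = qs[3],
                 consensus_met = cons$met,
                 window_lower = cons$window_lower,
                 window_upper = cons$window_upper)
}

#' Check the pre-specified consensus rule on elicited weights
#'
#' The borrowing analysis is pre-specified as primary only if expert opinion
#' is sufficiently concordant: at least `frac` of the experts must have chosen
#' weights within some closed window of absolute width `window`. The scan
#' anchors candidate windows at each sorted weight; among maximising windows
#' the leftmost anchor wins.
#'
#' @param weights Numeric vector of chosen weights (at least one).
#' @param window Absolute window width (default 0.30).
#' @param frac Required fraction of experts inside the window (default 0.80);
#'   the count threshold is `ceiling(frac * n)`.
#'
#' @return A one-row tibble: `met` (logical), `window_lower`, `window_upper`,
#'   `n_in_window`, `n_required`.
#'
#' @examples
#' consensus_check(c(0.70, 0.75, 0.78, 0.80, 0.90))
#' consensus_check(c(0, 1))  # no 0.30 window can hold 80%
#' @export
consensus_check <- function(weights, window = 0.30, frac = 0.80) {
  abort_if(length(weights) == 0, "at least one weight is required.")
  abort_if(any(!is.finite(weights)), "weights must be finite.")
  check_number(window, "window", lower = 0, allow_boundary = FALSE)
  check_number(frac, "frac", 0, 1, allow_boundary = FALSE)
  s <- sort(weights)
  n <- length(s)
  # number of weights in [s[i], s[i] + window] for each anchor i
  counts <- purrr::map_int(seq_len(n),
                           function(i) sum(s >= s[i] & s <= s[i] + window + 1e-12))
  best <- which.max(counts)  # leftmost maximiser by which.max semantics
  need <- ceiling(frac * n)
  tibble::tibble(met = counts[best] >= need,
                 window_lower = s[best],
                 window_upper = s[best] + window,
                 n_in_window = counts[best],
                 n_required = as.integer(need))
}

#' Weight-to-uncertainty feedback table
#'
#' Reproduces the feedback spreadsheet shown to experts during elicitation:
#' for a grid of candidate source-subgroup weights, the implied interaction
#' prior standard deviation and the conditional 95% range for the
#' target-subgroup treatment effect given an assumed source effect. Larger
#' weights imply tighter, strictly nested ranges.
#'
#' @param design A [plan_design()] providing planning standard errors.
#' @param theta0_assumed Assumed source-subgroup risk difference (proportion
#'   scale).
#' @param weights Grid of candidate weights; weights outside `(0, w_max]` are
#'   kept in the table but flagged `valid = FALSE` with `NA` ranges.
#' @param level Range coverage (default 0.95).
#'
#' @return A tibble with columns `weight`, `valid`, `sigma_delta`,
#'   `range_lower`, `range_upper`.
#'
#' @examples
#' d <- plan_design(85, 707, p_fail = 0.18, ltfu = 0.10)
#' feedback_table(d, theta0_assumed = -0.05, weights = seq(0.1, 0.8, 0.1))
#' @export
feedback_table <- function(design, theta0_assumed,
                           weights = seq(0.05, 0.85, by = 0.05),
                           level = 0.95) {
  stopifnot(inherits(design, "borrow_design"))
  check_number(theta0_assumed, "theta0_assumed", -1, 1)
  abort_if(length(weights) == 0 || any(!is.finite(weights)),
           "`weights` must be a non-empty finite grid.")
  w_max <- design$se_target^2 / (design$se_source^2 + design$se_target^2)
  valid <- weights > 0 & weights <= w_max
  sd_out <- rep(NA_real_, length(weights))
  lo <- rep(NA_real_, length(weights))
  hi <- rep(NA_real_, length(weights))
  if (any(valid)) {
    sd_out[valid] <- sigma_delta_from_weight(weights[valid],
                                             design$se_target,
                                             design$se_source)
    rng <- implied_prior_range(theta0_assumed, sd_out[valid], level = level)
    lo[valid] <- rng$lower
    hi[valid] <- rng$upper
  }
  tibble::tibble(weight = weights, valid = valid, sigma_delta = sd_out,
                 range_lower = lo, range_upper = hi)
}

# Canonical elicitation CSV schema, one row per expert per stage.
elicitation_columns <- c("expert_id", "stage", "range_lower", "range_upper",
                         "coverage", "chosen_weight", "assumed_theta0",
                         "scale")

#' Read an elicitation-responses CSV
#'
#' Reads the canonical elicitation schema: one row per expert per stage with
#' columns `expert_id`, `stage` (1, 2 or 3), `range_lower`, `range_upper`,
#' `coverage`, `chosen_weight`, `assumed_theta0` and `scale` (`"percent"` or
#' `"proportion"`). The header is validated strictly; percent-scale rows are
#' converted to proportions on read (weights and coverages are always
#' fractions and are not rescaled).
#'
#' @param path Path to the CSV file.
#' @return A tibble on the proportion scale with `scale == "proportion"`.
#' @seealso [write_elicitation()]
#' @export
read_elicitation <- function(path) {
  abort_if(!file.exists(path), "elicitation file not found: %s", path)
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          expert_id = readr::col_character(),
                          stage = readr::col_integer(),
                          range_lower = readr::col_double(),
                          range_upper = readr::col_double(),
                          coverage = readr::col_double(),
                          chosen_weight = readr::col_double(),
                          assumed_theta0 = readr::col_double(),
                          scale = readr::col_character()))
  abort_if(!identical(names(df), elicitation_columns),
           "elicitation CSV header must be exactly: %s",
           paste(elicitation_columns, collapse = ","))
  abort_if(any(!df$scale %in% c("percent", "proportion")),
           "`scale` must be 'percent' or 'proportion'.")
  abort_if(any(!df$stage %in% 1:3), "`stage` must be 1, 2 or 3.")
  pct <- df$scale == "percent"
  for (col in c("range_lower", "range_upper", "assumed_theta0")) {
    df[[col]][pct] <- df[[col]][pct] / 100
  }
  df$scale <- "proportion"
  has_range <- !is.na(df$range_lower) | !is.na(df$range_upper)
  abort_if(any(has_range & !(df$range_upper > df$range_lower)),
           "each elicited range needs range_upper > range_lower.")
  abort_if(any(!is.na(df$coverage) & (df$coverage <= 0 | df$coverage >= 1)),
           "`coverage` must lie strictly in (0, 1).")
  abort_if(any(df$stage == 3 & is.na(df$chosen_weight) & !has_range),
           "stage-3 rows must carry a chosen_weight (or a fallback range).")
  df
}

#' Write an elicitation-responses CSV
#'
#' @param responses Tibble in the schema of [read_elicitation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_elicitation <- function(responses, path) {
  missing <- setdiff(elicitation_columns, names(responses))
  abort_if(length(missing) > 0, "`responses` is missing column(s): %s.",
           paste(missing, collapse = ", "))
  readr::write_csv(responses[elicitation_columns], path)
  invisible(path)
}
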