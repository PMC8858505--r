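# Internal helpers shared across the package.

# Two-sided standard-normal quantile for a central interval of the given
# coverage. level = 0.95 gives the exact 0.975 quantile (~1.959964), used
# everywhere in preference to the rounded 1.96.
z_level <- function(level = 0.95) {
  stopifnot(is.numeric(level), level > 0, level < 1)
  stats::qnorm((1 + level) / 2)
}

# Round half away from zero (base round() rounds half to even). Display-side
# only; internal values are never rounded.
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Percent <-> proportion. Internal scale is always proportions.
as_proportion <- function(x, scale = c("proportion", "percent")) {
  scale <- match.arg(scale)
  if (scale == "percent") x / 100 else x
}

abort_if <- function(cond, msg, ...) {
  if (cond) rlang::abort(sprintf(msg, ...))
  invisible(TRUE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_boundary = TRUE) {
  abort_if(!is.numeric(x) || length(x) != 1L || is.na(x),
           "`%s` must be a single non-missing number.", name)
  if (allow_boundary) {
    abort_if(x < lower || x > upper,
             "`%s` must be in [%g, %g], got %g.", name, lower, upper, x)
  } else {
    abort_if(x <= lower || x >= upper,
             "`%s` must be in (%g, %g), got %g.", name, lower, upper, x)
  }
  invisible(x)
}
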