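#' Load and validate an analysis configuration
#'
#' Reads a YAML configuration describing a borrowing analysis. Schema (keys
#' outside this schema are rejected):
#'
#' ```yaml
#' planning:            # optional unless `analysis.weight` is given
#'   n_target: 85
#'   n_source: 707
#'   p_fail: 0.18
#'   ltfu: 0.10
#'   margin: 0.10
#'   alloc: 0.5         # optional
#' analysis:
#'   scale: percent     # "percent" or "proportion" for estimates/CIs
#'   target: {estimate: 7, ci_lower: -10, ci_upper: 24}   # or se:
#'   source: {estimate: -2, ci_lower: -8, ci_upper: 4}
#'   weight: 0.78       # XOR sigma_delta (weight uses planning SEs)
#' elicitation_file: panel.csv   # optional
#' reporting:           # optional
#'   scale: percent     # display scale
#' seed: 20220220       # optional, echoed into reports
#' n_reps: 20000        # optional, power simulations
#' ```
#'
#' @param path Path to the YAML file.
#' @return A validated list of class `borrow_config` with proportions
#'   internally (percent inputs converted on load).
#' @export
load_config <- function(path) {
  abort_if(!file.exists(path), "config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  known <- c("planning", "analysis", "elicitation_file", "reporting",
             "seed", "n_reps")
  unknown <- setdiff(names(raw), known)
  abort_if(length(unknown) > 0, "unknown config key(s): %s.",
           paste(unknown, collapse = ", "))
  abort_if(is.null(raw$analysis), "config needs an `analysis` block.")

  design <- NULL
  if (!is.null(raw$planning)) {
    pl <- raw$planning
    unknown <- setdiff(names(pl),
                       c("n_target", "n_source", "p_fail", "ltfu", "margin",
                         "alloc"))
    abort_if(length(unknown) > 0, "unknown planning key(s): %s.",
             paste(unknown, collapse = ", "))
    abort_if(is.null(pl$n_target) || is.null(pl$n_source) || is.null(pl$p_fail),
             "planning block needs n_target, n_source and p_fail.")
    design <- plan_design(n_target = pl$n_target, n_source = pl$n_source,
                          p_fail = pl$p_fail,
                          ltfu = pl$ltfu %||% 0,
                          margin = pl$margin %||% 0.10,
                          alloc = pl$alloc %||% 0.5)
  }

  an <- raw$analysis
  unknown <- setdiff(names(an),
                     c("scale", "target", "source", "weight", "sigma_delta"))
  abort_if(length(unknown) > 0, "unknown analysis key(s): %s.",
           paste(unknown, collapse = ", "))
  scale <- an$scale %||% "proportion"
  abort_if(!scale %in% c("percent", "proportion"),
           "analysis.scale must be 'percent' or 'proportion'.")
  conv <- function(x) if (is.null(x)) NULL else as_proportion(x, scale)
  block <- function(b, name) {
    abort_if(is.null(b), "analysis block needs `%s`.", name)
    unknown <- setdiff(names(b), c("estimate", "se", "ci_lower", "ci_upper"))
    abort_if(length(unknown) > 0, "unknown analysis.%s key(s): %s.", name,
             paste(unknown, collapse = ", "))
    list(estimate = conv(b$estimate), se = conv(b$se),
         ci_lower = conv(b$ci_lower), ci_upper = conv(b$ci_upper))
  }
  data <- subgroup_data(target = block(an$target, "target"),
                        source = block(an$source, "source"))
  abort_if(!is.null(an$weight) && !is.null(an$sigma_delta),
           "config sets both `weight` and `sigma_delta`; they are mutually exclusive.")
  abort_if(is.null(an$weight) && is.null(an$sigma_delta),
           "analysis block needs `weight` or `sigma_delta`.")
  if (!is.null(an$weight)) {
    check_number(an$weight, "analysis.weight", 0, 1, allow_boundary = FALSE)
    abort_if(is.null(design),
             "a `planning` block is required to convert `weight` to sigma_delta.")
    sigma_delta <- sigma_delta_from_weight(an$weight, design$se_target,
                                           design$se_source)
  } else {
    sigma_delta <- as_proportion(an$sigma_delta, scale)
    check_number(sigma_delta, "analysis.sigma_delta", lower = 0)
  }

  rep_scale <- (raw$reporting$scale %||% "percent")
  abort_if(!rep_scale %in% c("percent", "proportion"),
           "reporting.scale must be 'percent' or 'proportion'.")
  if (!is.null(raw$elicitation_file)) {
    abort_if(!file.exists(raw$elicitation_file),
             "elicitation_file not found: %s", raw$elicitation_file)
  }
  structure(list(design = design, data = data, sigma_delta = sigma_delta,
                 weight = an$weight, elicitation_file = raw$elicitation_file,
                 reporting_scale = rep_scale,
                 seed = raw$seed, n_reps = raw$n_reps %||% 20000),
            class = "borrow_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the three recommended analyses side by side
#'
#' For transparency, the borrowing analysis should be reported alongside the
#' standalone analysis of the target subgroup and a conventional combined
#' (inverse-variance pooled) analysis. This computes all three from a
#' configuration (or from its parts) and assembles a report.
#'
#' @param config A `borrow_config` from [load_config()], or `NULL` if the
#'   parts are supplied directly.
#' @param data,sigma_delta,design Used when `config` is `NULL`: a
#'   subgroup-summary tibble, the interaction prior sd and (optionally) a
#'   [plan_design()] supplying the margin.
#' @param margin Non-inferiority margin; defaults to the design's (or 0.10).
#' @param level Interval coverage (default 0.95).
#'
#' @return An object of class `borrow_report`: a list with `analyses` (tibble
#'   with one row each for `standalone`, `pooled`, `borrowing`: estimate, sd,
#'   interval, source weight, non-inferiority flag) and `meta` (package
#'   version, seed, timestamp, config hash). Has `print()` and `autoplot()`
#'   methods; serialise with [write_report()].
#'
#' @examples
#' fx <- example_fixture(1)
#' run_report(data = fx$data, sigma_delta = fx$sigma_delta,
#'            design = fx$design)
#' @export
run_report <- function(config = NULL, data = NULL, sigma_delta = NULL,
                       design = NULL, margin = NULL, level = 0.95) {
  if (!is.null(config)) {
    stopifnot(inherits(config, "borrow_config"))
    data <- config$data
    sigma_delta <- config$sigma_delta
    design <- config$design
  }
  data <- validate_subgroup_data(data)
  check_number(sigma_delta, "sigma_delta", lower = 0)
  margin <- margin %||% (if (!is.null(design)) design$margin else 0.10)
  z <- z_level(level)
  tgt <- data[data$label == "target", ]

  borrow <- borrow_posterior(data, sigma_delta = sigma_delta, level = level)
  pooled <- pooled_estimate(data, level = level)
  analyses <- dplyr::bind_rows(
    tibble::tibble(analysis = "standalone", estimate = tgt$estimate,
                   sd = tgt$se, lower = tgt$estimate - z * tgt$se,
                   upper = tgt$estimate + z * tgt$se, weight_source = 0),
    tibble::tibble(analysis = "pooled", estimate = pooled$mean,
                   sd = pooled$sd, lower = pooled$cri_lower,
                   upper = pooled$cri_upper,
                   weight_source = pooled$weight_source),
    tibble::tibble(analysis = "borrowing", estimate = borrow$mean,
                   sd = borrow$sd, lower = borrow$cri_lower,
                   upper = borrow$cri_upper,
                   weight_source = borrow$weight_source))
  analyses$noninferior <- declare_noninferior(analyses$upper, margin)

  meta <- list(
    package_version = as.character(utils::packageVersion("subborrow")),
    sigma_delta = sigma_delta, margin = margin, level = level,
    seed = if (!is.null(config)) config$seed else NULL,
    reporting_scale = if (!is.null(config)) config$reporting_scale else "percent",
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config_hash = config_hash(list(data = as.data.frame(data),
                                   sigma_delta = sigma_delta,
                                   margin = margin, level = level)))
  structure(list(analyses = analyses, data = data, meta = meta),
            class = "borrow_report")
}

# Small order-sensitive polynomial rolling hash of the deparsed inputs;
# enough to tag a report with the configuration that produced it without new
# dependencies.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' @export
print.borrow_report <- function(x, ...) {
  scale <- x$meta$reporting_scale
  f <- if (scale == "percent") {
    function(v) sprintf("%.0f%%", round_half_away(100 * v) + 0)  # +0 drops -0
  } else {
    function(v) sprintf("%.3f", v)
  }
  cat("Risk difference (DTG - SOC), three analyses of the target subgroup\n")
  cat(sprintf("  margin %s, sigma_delta %.4f\n\n", f(x$meta$margin),
              x$meta$sigma_delta))
  a <- x$analyses
  for (i in seq_len(nrow(a))) {
    cat(sprintf("  %-11s %6s  (95%% int %6s to %6s)  weight %3.0f%%  %s\n",
                a$analysis[i], f(a$estimate[i]), f(a$lower[i]), f(a$upper[i]),
                100 * a$weight_source[i],
                if (a$noninferior[i]) "non-inferior" else "not non-inferior"))
  }
  invisible(x)
}

#' Forest-style plot of a report
#'
#' @param object A `borrow_report`.
#' @param ... Unused.
#' @return A ggplot of the three analyses with their 95% intervals and the
#'   non-inferiority margin.
#' @method autoplot borrow_report
#' @export
autoplot.borrow_report <- function(object, ...) {
  rows <- dplyr::transmute(object$analyses, analysis = .data$analysis,
                           estimate = .data$estimate, lower = .data$lower,
                           upper = .data$upper)
  forest_plot(rows, xlab = "Risk difference (DTG - SOC)") +
    ggplot2::geom_vline(xintercept = object$meta$margin,
                        linetype = "dashed", colour = "firebrick")
}

#' Serialise a report to JSON or CSV
#'
#' JSON output carries the analyses, the input summaries and the metadata;
#' CSV output carries the analyses table only. Machine output is unrounded
#' and on the proportion scale.
#'
#' @param report A `borrow_report`.
#' @param path Output path; format from the extension (`.json` or `.csv`)
#'   unless `format` is given.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path,
                         format = c("auto", "json", "csv")) {
  stopifnot(inherits(report, "borrow_report"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  }
  if (format == "csv") {
    readr::write_csv(report$analyses, path)
  } else {
    jsonlite::write_json(
      list(analyses = report$analyses, inputs = report$data,
           meta = report$meta[!vapply(report$meta, is.null, logical(1))]),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Write a fixture as a config file (plus elicitation CSV)
#'
#' Dumps one of the built-in fixtures as a ready-to-run YAML configuration,
#' so every worked scenario can be reproduced from plain-text inputs.
#'
#' @param name `"odyssey"`, `"example1"` or `"example2"`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the path(s) written.
#' @export
dump_fixture <- function(name = c("odyssey", "example1", "example2"),
                         dir = ".") {
  name <- match.arg(name)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fx <- switch(name,
               odyssey = odyssey_planning_fixture(),
               example1 = example_fixture(1),
               example2 = example_fixture(2))
  d <- fx$design
  cfg <- list(planning = list(n_target = d$n_target, n_source = d$n_source,
                              p_fail = d$p_fail, ltfu = d$ltfu,
                              margin = d$margin),
              analysis = list(scale = "proportion",
                              weight = fx$elicited_weight %||% 0.78))
  if (!is.null(fx$data)) {
    rows <- split(fx$data, fx$data$label)
    cfg$analysis$target <- list(estimate = rows$target$estimate,
                                se = rows$target$se)
    cfg$analysis$source <- list(estimate = rows$source$estimate,
                                se = rows$source$se)
  } else {
    # planning-only fixture: planning summaries stand in for the data block
    ds <- design_summaries(d)
    cfg$analysis$target <- list(estimate = 0, se = ds$se[ds$label == "target"])
    cfg$analysis$source <- list(estimate = 0, se = ds$se[ds$label == "source"])
  }
  path <- file.path(dir, paste0(name, ".yaml"))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
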