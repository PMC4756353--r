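#' Paired one-tailed t-test on log-transformed values
#'
#' Per-donor control/treated values are compared on the natural-log scale
#' (the log transform normalises the right-skewed intensity and volume
#' measures; the base is immaterial for the statistic). Differences are
#' `d_i = ln(control_i) - ln(treated_i)`, `t = mean(d) / (sd(d) / sqrt(n))`
#' with `n - 1` degrees of freedom, and the p-value is one-tailed in the
#' stated direction (or two-sided).
#'
#' @param control,treated Positive numeric vectors of equal length
#'   (`n >= 2`), one element per donor pair.
#' @param direction `"control_gt_treated"` (default; e.g. F-actin measures
#'   expected lower after treatment), `"treated_gt_control"` (e.g. pore
#'   measures), or `"two_sided"`.
#' @return A list with `t`, `p_value`, `df`, `n`, `direction`.
#' @export
paired_log_t_test <- function(control, treated,
                              direction = c("control_gt_treated",
                                            "treated_gt_control",
                                            "two_sided")) {
  direction <- match.arg(direction)
  if (length(control) != length(treated))
    stop("control and treated must be paired (equal length)")
  n <- length(control)
  if (n < 2) stop("need at least 2 pairs")
  if (any(control <= 0) || any(treated <= 0))
    stop("all values must be positive for the log transform")
  d <- log(control) - log(treated)
  s <- stats::sd(d)
  # constant ratios give sd(d) at floating-point noise level; treat as zero
  if (s <= sqrt(.Machine$double.eps) * max(1, abs(mean(d))))
    stop("log-differences are constant (zero variance); t undefined")
  t <- mean(d) / (s / sqrt(n))
  df <- n - 1
  p <- switch(direction,
              control_gt_treated = stats::pt(t, df, lower.tail = FALSE),
              treated_gt_control = stats::pt(t, df, lower.tail = TRUE),
              two_sided = 2 * stats::pt(-abs(t), df))
  list(t = t, p_value = p, df = df, n = n, direction = direction)
}

#' Percent change between conditions
#'
#' Two conventions: `per_pair` computes `100 * (treated_i - control_i) /
#' control_i` for each donor and reports their mean and SD; `group_means`
#' computes `100 * (mean(treated) - mean(control)) / mean(control)` from
#' the condition means. The two agree exactly when all control values are
#' equal. Negative values are reductions.
#'
#' @param pairs A data.frame (or 2-column matrix) with columns `control`
#'   and `treated`, for `per_pair` mode.
#' @param group_means Numeric vector `c(control = , treated = )`, for
#'   `group_means` mode.
#' @return For `per_pair`: a list with `per_pair` (vector), `mean`, `sd`.
#'   For `group_means`: a single percent value.
#' @export
percent_change <- function(pairs = NULL, group_means = NULL) {
  if (!is.null(group_means)) {
    gm <- group_means
    if (is.null(names(gm))) names(gm) <- c("control", "treated")
    if (gm[["control"]] == 0) stop("zero control mean")
    return(unname(100 * (gm[["treated"]] - gm[["control"]]) /
                    gm[["control"]]))
  }
  if (is.null(pairs)) stop("supply pairs or group_means")
  pairs <- as.data.frame(pairs)
  if (any(pairs$control == 0)) stop("zero control value in pairs")
  pc <- 100 * (pairs$treated - pairs$control) / pairs$control
  list(per_pair = pc, mean = mean(pc), sd = stats::sd(pc))
}

#' Full paired condition comparison
#'
#' Bundles the quantities reported for a paired control/treated measure:
#' group means and SDs, per-pair and group-mean percent change, and the
#' paired log-transformed t-test. Headline percent changes are reported
#' rounded to the nearest integer alongside full precision.
#'
#' @inheritParams paired_log_t_test
#' @param label Name of the measure (used in report tables).
#' @return An object of class `"paired_comparison"`.
#' @export
paired_comparison <- function(control, treated,
                              direction = "control_gt_treated",
                              label = "measure") {
  tt <- paired_log_t_test(control, treated, direction)
  pp <- percent_change(pairs = data.frame(control = control,
                                          treated = treated))
  gm <- percent_change(group_means = c(control = mean(control),
                                       treated = mean(treated)))
  structure(list(
    label = label, pairs = data.frame(control = control, treated = treated),
    control_mean = mean(control), control_sd = stats::sd(control),
    treated_mean = mean(treated), treated_sd = stats::sd(treated),
    per_pair_pct_mean = pp$mean, per_pair_pct_sd = pp$sd,
    group_mean_pct = gm, group_mean_pct_rounded = round(gm),
    t = tt$t, p_value = tt$p_value, n = tt$n, direction = tt$direction),
    class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf(
    "<paired_comparison> %s: control %.4g +/- %.4g, treated %.4g +/- %.4g (n = %d)\n",
    x$label, x$control_mean, x$control_sd, x$treated_mean, x$treated_sd,
    x$n))
  cat(sprintf("  per-pair change %.1f%% +/- %.1f%%; group-mean change %.1f%% (%d%%)\n",
              x$per_pair_pct_mean, x$per_pair_pct_sd, x$group_mean_pct,
              x$group_mean_pct_rounded))
  cat(sprintf("  paired log t = %.4g, one-tailed p = %.4g (%s)\n",
              x$t, x$p_value, x$direction))
  invisible(x)
}

#' @export
as.data.frame.paired_comparison <- function(x, ...) {
  data.frame(measure = x$label,
             control_mean = x$control_mean, control_sd = x$control_sd,
             treated_mean = x$treated_mean, treated_sd = x$treated_sd,
             n = x$n,
             per_pair_pct_mean = x$per_pair_pct_mean,
             per_pair_pct_sd = x$per_pair_pct_sd,
             group_mean_pct = x$group_mean_pct,
             group_mean_pct_rounded = x$group_mean_pct_rounded,
             t = x$t, p_value = x$p_value, direction = x$direction)
}

#' Assemble analysis tables and a provenance log
#'
#' Writes whichever result tables are supplied as CSV files plus a plain
#' run log (package version, configuration, seed). Output is byte-identical
#' across reruns with the same inputs.
#'
#' @param results Named list; recognised elements: `density` and
#'   `distribution` ([paired_comparison()] objects or data.frames),
#'   `autofluorescence` (data.frame), `pores` (a [pore_summary()] result or
#'   data.frame), `viability` (data.frame).
#' @param dir Output directory (created if needed).
#' @param config Named list recorded in the run log.
#' @param seed Seed recorded in the run log.
#' @return Character vector of files written, invisibly.
#' @export
build_report <- function(results, dir, config = list(), seed = NULL) {
  if (!length(results)) stop("no results to report")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(obj, file) {
    if (is.null(obj)) return()
    df <- if (inherits(obj, "paired_comparison")) as.data.frame(obj)
          else if (is.list(obj) && !is.data.frame(obj) && !is.null(obj$table))
            obj$table
          else as.data.frame(obj)
    path <- file.path(dir, file)
    utils::write.csv(df, path, row.names = FALSE)
    written <<- c(written, path)
  }
  emit(results$density, "density_table.csv")
  emit(results$distribution, "distribution_table.csv")
  emit(results$autofluorescence, "autofluorescence_table.csv")
  emit(results$pores, "pore_summary.csv")
  emit(results$viability, "viability_summary.csv")
  log_path <- file.path(dir, "run_log.txt")
  lines <- c(
    sprintf("tmquant version: %s",
            as.character(utils::packageVersion("tmquant"))),
    sprintf("seed: %s", if (is.null(seed)) "NA" else format(seed)),
    "config:",
    if (length(config)) paste0("  ", names(config), ": ",
                               vapply(config, function(v)
                                 paste(format(v), collapse = " "),
                                 character(1)))
    else "  (defaults)",
    paste("tables:", paste(basename(written), collapse = ", ")))
  writeLines(lines, log_path)
  invisible(c(written, log_path))
}
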