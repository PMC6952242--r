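#' Phantom accuracy/precision summary
#'
#' Summarises phantom sizing records per insert size, profile axis and
#' tool: mean and sample SD (n - 1 denominator) across users, the error of
#' the mean against the true diameter, and per (size, axis) row flags for
#' the best accuracy (smallest absolute mean error) and best precision
#' (smallest SD). A cell with identical values has SD exactly 0; a cell
#' with a single record has its SD reported as `NA` (undefined).
#'
#' Phantom task names produced by [build_session_plan()] are parsed for
#' size and axis; invalid records are dropped.
#'
#' @param records A measurement-records tibble (phantom tasks).
#' @param truth Optional tibble (`size_mm`, `truth_mm`) overriding the
#'   parsed sizes as ground truth; by default the parsed size is the
#'   truth.
#' @return A tibble (class `phantom_summary`) with columns `size_mm`,
#'   `axis`, `tool`, `n`, `mean_mm`, `sd_mm`, `error_mm`, `best_accuracy`,
#'   `best_precision`.
#' @export
summarize_phantom <- function(records, truth = NULL) {
  ph <- records |>
    dplyr::filter(.data$valid,
                  grepl("^low scatter cyst ", .data$measurement)) |>
    dplyr::mutate(
      size_mm = as.numeric(sub("^low scatter cyst ([0-9.]+) mm.*$", "\\1",
                               .data$measurement)),
      axis = sub("^.* ([HV]) diameter$", "\\1", .data$measurement)
    )
  if (nrow(ph) == 0L) {
    rlang::abort("no valid phantom records", class = "caliper3d_empty_error")
  }
  if (is.null(truth)) {
    ph$truth_mm <- ph$size_mm
  } else {
    ph <- dplyr::left_join(ph, truth, by = "size_mm")
  }
  out <- ph |>
    dplyr::group_by(.data$size_mm, .data$axis, .data$tool) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_mm = mean(.data$value_mm),
      sd_mm = ifelse(dplyr::n() >= 2L, stats::sd(.data$value_mm), NA_real_),
      error_mm = abs(mean(.data$value_mm) - .data$truth_mm[1]),
      .groups = "drop"
    ) |>
    dplyr::group_by(.data$size_mm, .data$axis) |>
    dplyr::mutate(
      best_accuracy = .data$error_mm == min(.data$error_mm),
      best_precision = !is.na(.data$sd_mm) & !all(is.na(.data$sd_mm)) &
        .data$sd_mm == suppressWarnings(min(.data$sd_mm, na.rm = TRUE))
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$size_mm, .data$axis, .data$tool)
  class(out) <- c("phantom_summary", class(out))
  out
}

#' Agreement between a tool and a reference tool
#'
#' Pairs each tool measurement with the reference tool's measurement of
#' the same (user, dataset, measurement) instance, dropping invalid or
#' unpaired records (counted), and summarises the differences
#' `tool - reference`: mean, sample SD, the number of pairs whose absolute
#' difference is strictly below the threshold (2 mm by default), and an
#' ordinary least-squares regression of the tool's values on the
#' reference's. A constant reference makes the regression degenerate; it
#' is then flagged and its coefficients reported as `NA`.
#'
#' @param records A measurement-records tibble.
#' @param tool,reference_tool Tool names present in `records`.
#' @param threshold_mm Agreement threshold, mm (strict inequality).
#' @return An `agreement_stats` object: list with `tool`, `reference`,
#'   `n_pairs`, `n_dropped`, `mean_diff_mm`, `sd_diff_mm`,
#'   `n_within_threshold`, `threshold_mm`, `slope`, `intercept`,
#'   `correlation`, `degenerate`, and `pairs` (tibble with `value_mm`,
#'   `reference_mm`, `diff_mm`).
#' @export
agreement <- function(records, tool, reference_tool, threshold_mm = 2.0) {
  key <- c("user", "dataset", "measurement")
  a <- records |>
    dplyr::filter(.data$tool == !!tool, .data$valid) |>
    dplyr::select(dplyr::all_of(key), value_mm = "value_mm")
  b <- records |>
    dplyr::filter(.data$tool == !!reference_tool, .data$valid) |>
    dplyr::select(dplyr::all_of(key), reference_mm = "value_mm")
  pairs <- dplyr::inner_join(a, b, by = key)
  n_dropped <- nrow(a) + nrow(b) - 2L * nrow(pairs)
  if (nrow(pairs) == 0L) {
    rlang::abort(sprintf("no pairable records for %s vs %s", tool, reference_tool),
                 class = "caliper3d_empty_error")
  }
  pairs$diff_mm <- pairs$value_mm - pairs$reference_mm
  degenerate <- stats::var(pairs$reference_mm) == 0 || nrow(pairs) < 2L
  if (degenerate) {
    slope <- intercept <- correlation <- NA_real_
  } else {
    fit <- stats::lm(value_mm ~ reference_mm, data = pairs)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    correlation <- stats::cor(pairs$value_mm, pairs$reference_mm)
  }
  structure(
    list(
      tool = tool, reference = reference_tool,
      n_pairs = nrow(pairs), n_dropped = n_dropped,
      mean_diff_mm = mean(pairs$diff_mm),
      sd_diff_mm = if (nrow(pairs) >= 2L) stats::sd(pairs$diff_mm) else NA_real_,
      n_within_threshold = sum(abs(pairs$diff_mm) < threshold_mm),
      threshold_mm = threshold_mm,
      slope = slope, intercept = intercept, correlation = correlation,
      degenerate = degenerate,
      pairs = pairs
    ),
    class = "agreement_stats"
  )
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat(sprintf("<agreement_stats> %s vs %s (reference)\n", x$tool, x$reference))
  cat(sprintf("  mean difference %.2f mm +/- %.2f mm over %d pairs\n",
              x$mean_diff_mm, x$sd_diff_mm, x$n_pairs))
  cat(sprintf("  %d of %d pairs within %g mm\n",
              x$n_within_threshold, x$n_pairs, x$threshold_mm))
  if (!x$degenerate) {
    cat(sprintf("  OLS: slope %.3f, intercept %.3f, r = %.3f\n",
                x$slope, x$intercept, x$correlation))
  } else {
    cat("  regression degenerate (constant reference)\n")
  }
  invisible(x)
}

#' Paired-samples t-test
#'
#' The paired t statistic on differences `d = a - b`:
#' `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of freedom and a
#' two-sided p-value, plus each sample's mean and SD (the "(M = ..., SD =
#' ...)" reporting convention). Degenerate inputs are handled explicitly:
#' all-zero differences give a "no variation" result (t undefined), and
#' zero-variance differences with non-zero mean give an infinite t.
#'
#' @param a,b Equal-length numeric vectors of paired measurements; pairs
#'   containing `NA` are dropped.
#' @return A `paired_ttest_result`: list with `t`, `df`, `p_value`, `n`,
#'   `mean_diff`, `sd_diff`, `mean_a`, `sd_a`, `mean_b`, `sd_b`,
#'   `no_variation`.
#' @export
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 2L) {
    rlang::abort("paired t-test needs at least 2 complete pairs",
                 class = "caliper3d_empty_error")
  }
  d <- a - b
  md <- mean(d); sdd <- stats::sd(d)
  no_var <- sdd == 0
  if (no_var && md == 0) {
    t <- NA_real_; p <- NA_real_
  } else if (no_var) {
    t <- sign(md) * Inf; p <- 0
  } else {
    t <- md / (sdd / sqrt(n))
    p <- 2 * stats::pt(-abs(t), df = n - 1L)
  }
  structure(
    list(t = t, df = n - 1L, p_value = p, n = n,
         mean_diff = md, sd_diff = sdd,
         mean_a = mean(a), sd_a = stats::sd(a),
         mean_b = mean(b), sd_b = stats::sd(b),
         no_variation = no_var),
    class = "paired_ttest_result"
  )
}

#' @export
print.paired_ttest_result <- function(x, ...) {
  if (x$no_variation && is.na(x$t)) {
    cat(sprintf("<paired_ttest_result> no variation: samples identical (n = %d)\n", x$n))
  } else {
    cat(sprintf("<paired_ttest_result> t(%d) = %.3f, p = %.3g\n", x$df, x$t, x$p_value))
    cat(sprintf("  a: M = %.3f, SD = %.3f; b: M = %.3f, SD = %.3f\n",
                x$mean_a, x$sd_a, x$mean_b, x$sd_b))
  }
  invisible(x)
}

#' Paired t-test between two tools' records
#'
#' Convenience wrapper: pairs the two tools' valid records on
#' (user, dataset, measurement) — pairwise deletion of instances either
#' tool is missing — and runs [paired_ttest()] on the paired values.
#'
#' @param records A measurement-records tibble.
#' @param tool,reference_tool Tool names.
#' @return A `paired_ttest_result` (see [paired_ttest()]).
#' @export
tool_ttest <- function(records, tool, reference_tool) {
  key <- c("user", "dataset", "measurement")
  a <- records |>
    dplyr::filter(.data$tool == !!tool, .data$valid) |>
    dplyr::select(dplyr::all_of(key), a = "value_mm")
  b <- records |>
    dplyr::filter(.data$tool == !!reference_tool, .data$valid) |>
    dplyr::select(dplyr::all_of(key), b = "value_mm")
  pairs <- dplyr::inner_join(a, b, by = key)
  paired_ttest(pairs$a, pairs$b)
}

#' Intra-user variability
#'
#' For every (user, dataset, measurement) instance measured with at least
#' two tools, each tool's value is compared to the mean over all tools for
#' that instance; per (user, tool), the sample SD of those differences is
#' the user's consistency with that tool. Instances seen by only one tool
#' carry no cross-tool information and are excluded (counted in the
#' `n_excluded` attribute).
#'
#' @param records A measurement-records tibble.
#' @return A tibble (class `intra_user_variability`) with columns `user`,
#'   `tool`, `n`, `sd_mm` (`NA` when fewer than two differences);
#'   attribute `n_excluded`.
#' @export
intra_user_variability <- function(records) {
  valid <- dplyr::filter(records, .data$valid)
  grouped <- valid |>
    dplyr::group_by(.data$user, .data$dataset, .data$measurement) |>
    dplyr::mutate(n_tools = dplyr::n_distinct(.data$tool),
                  diff_mm = .data$value_mm - mean(.data$value_mm)) |>
    dplyr::ungroup()
  excluded <- dplyr::filter(grouped, .data$n_tools < 2L)
  out <- grouped |>
    dplyr::filter(.data$n_tools >= 2L) |>
    dplyr::group_by(.data$user, .data$tool) |>
    dplyr::summarise(
      n = dplyr::n(),
      sd_mm = ifelse(dplyr::n() >= 2L, stats::sd(.data$diff_mm), NA_real_),
      .groups = "drop"
    )
  attr(out, "n_excluded") <- nrow(excluded)
  class(out) <- c("intra_user_variability", class(out))
  out
}

#' Full study evaluation
#'
#' Runs the complete analysis of a records table against a reference tool:
#' the phantom accuracy/precision summary, per-tool agreement with the
#' reference, paired t-tests of every tool against the reference, and the
#' intra-user variability table.
#'
#' @param records A measurement-records tibble.
#' @param reference_tool Reference tool name (default "QLAB").
#' @param threshold_mm Agreement threshold, mm.
#' @return A `study_evaluation`: list with `phantom_summary` (or `NULL` if
#'   no phantom records), `agreement` (named list), `ttests` (named list),
#'   `intra_user`.
#' @export
evaluate_study <- function(records, reference_tool = "QLAB",
                           threshold_mm = 2.0) {
  tools <- setdiff(unique(records$tool), reference_tool)
  has_phantom <- any(grepl("^low scatter cyst ", records$measurement) & records$valid)
  structure(
    list(
      phantom_summary = if (has_phantom) summarize_phantom(records) else NULL,
      agreement = stats::setNames(
        lapply(tools, function(t) agreement(records, t, reference_tool, threshold_mm)),
        tools),
      ttests = stats::setNames(
        lapply(tools, function(t) tool_ttest(records, t, reference_tool)),
        tools),
      intra_user = intra_user_variability(records),
      reference_tool = reference_tool
    ),
    class = "study_evaluation"
  )
}

#' @export
print.study_evaluation <- function(x, ...) {
  cat(sprintf("<study_evaluation> reference tool: %s\n", x$reference_tool))
  if (!is.null(x$phantom_summary)) {
    cat(sprintf("  phantom summary: %d cells\n", nrow(x$phantom_summary)))
  }
  for (t in names(x$ttests)) {
    tt <- x$ttests[[t]]
    ag <- x$agreement[[t]]
    cat(sprintf("  %s vs %s: mean diff %.2f +/- %.2f mm; t(%d) = %.3f, p = %.3g\n",
                t, x$reference_tool, ag$mean_diff_mm, ag$sd_diff_mm,
                tt$df, tt$t, tt$p_value))
  }
  invisible(x)
}
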