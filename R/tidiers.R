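#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a paired t-test result
#'
#' @param x A `paired_ttest_result`.
#' @param ... Unused.
#' @return A one-row tibble with `estimate` (mean difference), `statistic`,
#'   `p.value`, `parameter` (df), `n`, `no.variation`.
#' @method tidy paired_ttest_result
#' @export
tidy.paired_ttest_result <- function(x, ...) {
  tibble::tibble(
    estimate = x$mean_diff,
    statistic = x$t,
    p.value = x$p_value,
    parameter = x$df,
    n = x$n,
    no.variation = x$no_variation
  )
}

#' @rdname tidy.paired_ttest_result
#' @method glance paired_ttest_result
#' @export
glance.paired_ttest_result <- function(x, ...) {
  tibble::tibble(
    statistic = x$t, p.value = x$p_value, parameter = x$df, n = x$n,
    mean.a = x$mean_a, sd.a = x$sd_a, mean.b = x$mean_b, sd.b = x$sd_b
  )
}

#' Tidy agreement statistics
#'
#' `tidy()` returns the per-pair differences; `glance()` the one-row
#' summary (mean/SD of differences, within-threshold count, regression).
#'
#' @param x An `agreement_stats` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy agreement_stats
#' @export
tidy.agreement_stats <- function(x, ...) {
  tibble::as_tibble(x$pairs)
}

#' @rdname tidy.agreement_stats
#' @method glance agreement_stats
#' @export
glance.agreement_stats <- function(x, ...) {
  tibble::tibble(
    tool = x$tool, reference = x$reference,
    n.pairs = x$n_pairs, n.dropped = x$n_dropped,
    mean.diff = x$mean_diff_mm, sd.diff = x$sd_diff_mm,
    n.within = x$n_within_threshold, threshold = x$threshold_mm,
    slope = x$slope, intercept = x$intercept, r = x$correlation,
    degenerate = x$degenerate
  )
}

#' Tidy a full study evaluation
#'
#' One row per tool-vs-reference comparison, combining the agreement
#' summary and the paired t-test.
#'
#' @param x A `study_evaluation`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy study_evaluation
#' @export
tidy.study_evaluation <- function(x, ...) {
  purrr::map_dfr(names(x$ttests), function(t) {
    dplyr::bind_cols(
      glance(x$agreement[[t]]),
      dplyr::select(tidy(x$ttests[[t]]), statistic = "statistic",
                    p.value = "p.value", df = "parameter")
    )
  })
}
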