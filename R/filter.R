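#' Parameters of the two-step abundance filter
#'
#' Defaults mirror the profiled design of ten biological libraries: a site is
#' dropped when at least 6 of the 10 samples have zero counts, and again when
#' at least 6 have counts below the global median (`Ymax`). Control libraries
#' never participate in filtering.
#'
#' @param max_zero_samples Sites with at least this many zero-count samples
#'   are removed by the first filter.
#' @param max_below_median Sites with at least this many samples strictly
#'   below `Ymax` are removed by the second filter.
#' @param median_override Optional fixed `Ymax`, bypassing the global-median
#'   computation (e.g. to impose a previously realised threshold).
#' @return A list of class `rrhp_filter_params`.
#' @export
filter_params <- function(max_zero_samples = 6L, max_below_median = 6L,
                          median_override = NULL) {
  stopifnot(max_zero_samples >= 0, max_below_median >= 0)
  structure(
    list(
      max_zero_samples = as.integer(max_zero_samples),
      max_below_median = as.integer(max_below_median),
      median_override = median_override
    ),
    class = "rrhp_filter_params"
  )
}

biological_samples <- function(sample_sheet) {
  sample_sheet$sample_id[!sample_sheet$is_control]
}

#' First filter: drop sites that are zero in too many samples
#'
#' A site is removed iff the number of biological samples with count 0 is
#' greater than or equal to `max_zero_samples`. Survivors pass through
#' unchanged.
#'
#' @param counts Wide count matrix from [assemble_matrix()].
#' @param sample_sheet Sample sheet tibble (controls are excluded).
#' @param params A [filter_params()].
#' @return The filtered count tibble.
#' @export
zero_count_filter <- function(counts, sample_sheet, params = filter_params()) {
  bio <- biological_samples(sample_sheet)
  m <- count_matrix_values(counts, bio)
  keep <- rowSums(m == 0) < params$max_zero_samples
  counts[keep, , drop = FALSE]
}

#' Global median of the count matrix (Ymax)
#'
#' Median over every entry (all sites x all biological samples) of the
#' matrix handed to the second filter; for an even number of entries the
#' mean of the two central order statistics.
#'
#' @inheritParams zero_count_filter
#' @return A single numeric, `Ymax`.
#' @export
compute_global_median <- function(counts, sample_sheet) {
  bio <- biological_samples(sample_sheet)
  median(count_matrix_values(counts, bio))
}

#' Second filter: drop sites below the median in too many samples
#'
#' A site is removed iff the number of biological samples with count strictly
#' below `ymax` is greater than or equal to `max_below_median`.
#'
#' @inheritParams zero_count_filter
#' @param ymax The threshold, usually from [compute_global_median()].
#' @return The filtered count tibble.
#' @export
median_filter <- function(counts, sample_sheet, ymax,
                          params = filter_params()) {
  bio <- biological_samples(sample_sheet)
  m <- count_matrix_values(counts, bio)
  keep <- rowSums(m < ymax) < params$max_below_median
  counts[keep, , drop = FALSE]
}

#' Apply the full two-step filter cascade
#'
#' Composition of [zero_count_filter()], [compute_global_median()] (unless
#' overridden) and [median_filter()], with an audit report of the cascade.
#'
#' @inheritParams zero_count_filter
#' @return A list with `counts` (the analysis-ready matrix) and `report`
#'   (one-row tibble `input_sites`, `after_zero_filter`, `ymax_used`,
#'   `after_median_filter`).
#' @export
apply_filters <- function(counts, sample_sheet, params = filter_params()) {
  step1 <- zero_count_filter(counts, sample_sheet, params)
  ymax <- params$median_override %||%
    (if (nrow(step1)) compute_global_median(step1, sample_sheet) else NA_real_)
  step2 <- if (nrow(step1)) {
    median_filter(step1, sample_sheet, ymax, params)
  } else {
    step1
  }
  list(
    counts = step2,
    report = tibble(
      input_sites = nrow(counts),
      after_zero_filter = nrow(step1),
      ymax_used = as.numeric(ymax),
      after_median_filter = nrow(step2)
    )
  )
}
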