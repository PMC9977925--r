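#' Two-group sample-size calculation for a quantitative endpoint
#'
#' Evaluates `n = 2 * (SD * (z_alpha + z_power) / d)^2`, where `SD` is the
#' standard deviation over the pooled individuals of both groups with
#' divisor `N` (population form), `d` the absolute difference between group
#' means, `z_alpha` the two-sided standard-normal quantile
#' `qnorm(1 - alpha/2)` and `z_power` the quantile `qnorm(power)`.
#'
#' @param weights_a,weights_b Numeric measurements (e.g. body weights in
#'   grams) for the two groups, at least two values each.
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @return A one-row tibble with `n` (rounded to 2 decimals, individuals per
#'   group), `sd_pooled`, `mean_diff`, `z_alpha`, `z_power`.
#' @examples
#' power_sample_size(c(512, 634, 587, 584, 556), c(191, 113, 138, 192, 129))
#' @export
power_sample_size <- function(weights_a, weights_b, alpha = 0.05,
                              power = 0.8) {
  stopifnot(length(weights_a) >= 2, length(weights_b) >= 2,
            alpha > 0, alpha < 1, power > 0, power < 1)
  d <- abs(mean(weights_a) - mean(weights_b))
  if (d == 0) abort("group means are equal; sample size is undefined (d = 0)")
  pooled <- c(weights_a, weights_b)
  sd_pop <- sqrt(mean((pooled - mean(pooled))^2))
  z0 <- qnorm(1 - alpha / 2)
  zb <- qnorm(power)
  tibble(
    n = round(2 * (sd_pop * (z0 + zb) / d)^2, 2),
    sd_pooled = sd_pop, mean_diff = d, z_alpha = z0, z_power = zb
  )
}

#' Per-cycle base composition of a FASTQ file
#'
#' Summarises base frequencies at every sequencing cycle, the minimal
#' QC view in which RRHP libraries show their hallmark low-complexity CCGG
#' start (cycles 1-4 nearly pure C, C, G, G).
#'
#' @param fastq FASTQ path.
#' @return A tibble `cycle`, `base`, `count`, `freq`; frequencies at a cycle
#'   sum to 1 over the reads covering that cycle.
#' @export
per_base_composition <- function(fastq) {
  empty <- tibble(cycle = integer(), base = character(),
                  count = integer(), freq = numeric())
  if (file.size(fastq) == 0) return(empty)
  reads <- as.character(Biostrings::readDNAStringSet(fastq, format = "fastq"))
  if (length(reads) == 0) return(empty)
  widths <- nchar(reads)
  bases <- c("A", "C", "G", "T", "N")
  purrr::map(seq_len(max(widths)), function(k) {
    at <- substring(reads[widths >= k], k, k)
    tab <- table(factor(at, levels = bases))
    tibble(cycle = k, base = bases, count = as.integer(tab),
           freq = as.integer(tab) / length(at))
  }) |>
    bind_rows()
}

#' Plot per-cycle base composition
#'
#' @param composition Result of [per_base_composition()].
#' @return A ggplot object.
#' @export
plot_base_composition <- function(composition) {
  ggplot2::ggplot(
    composition,
    ggplot2::aes(x = .data$cycle, y = .data$freq, colour = .data$base)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Sequencing cycle", y = "Base frequency") +
    ggplot2::theme_minimal()
}
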