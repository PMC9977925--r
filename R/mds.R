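#' Multidimensional scaling of libraries
#'
#' Computes, for every pair of libraries, the root-mean-square of the
#' `top_sites` largest absolute log2-CPM differences (the "leading" log fold
#' changes for that pair), then projects the resulting distance matrix to two
#' dimensions by classical metric scaling. Control libraries are included by
#' default, as a lane-bias diagnostic: well-behaved controls co-locate even
#' though they never enter the differential design.
#'
#' @param counts Wide count matrix (typically unfiltered or lightly
#'   filtered), including control columns.
#' @param sample_sheet Sample sheet tibble.
#' @param top_sites Number of leading sites per pair.
#' @param include_controls Drop control libraries when `FALSE`.
#' @return A tibble of class `rrhp_mds` with columns `sample_id`, `group`,
#'   `is_control`, `dim1`, `dim2`; the distance matrix is attached as
#'   attribute `"distances"`.
#' @export
mds_coordinates <- function(counts, sample_sheet, top_sites = 500,
                            include_controls = TRUE) {
  sheet <- if (include_controls) sample_sheet else
    filter(sample_sheet, !.data$is_control)
  ids <- sheet$sample_id
  m <- count_matrix_values(counts, ids)
  lib <- colSums(m)
  y <- t(log2(t(m + 0.5) / (lib + 1) * 1e6))

  k <- min(top_sites, nrow(y))
  n <- length(ids)
  dd <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dif2 <- (y[, i] - y[, j])^2
      top <- sort(dif2, decreasing = TRUE)[seq_len(k)]
      dd[i, j] <- dd[j, i] <- sqrt(mean(top))
    }
  }
  xy <- cmdscale(stats::as.dist(dd), k = 2)
  out <- tibble(
    sample_id = ids, group = sheet$group, is_control = sheet$is_control,
    dim1 = xy[, 1], dim2 = xy[, 2]
  )
  attr(out, "distances") <- dd
  class(out) <- c("rrhp_mds", class(out))
  out
}

#' Plot MDS coordinates of RRHP libraries
#'
#' @param mds Result of [mds_coordinates()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_mds <- function(mds, ...) {
  ggplot2::ggplot(
    mds, ggplot2::aes(x = .data$dim1, y = .data$dim2, colour = .data$group,
                      label = .data$sample_id)
  ) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_text(vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "Leading logFC dim 1", y = "Leading logFC dim 2") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.rrhp_mds <- function(object, ...) plot_mds(object, ...)
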