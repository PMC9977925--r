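#' Two-group design matrix from a sample sheet
#'
#' Intercept plus a group indicator (1 for the `large_group`). Control
#' libraries are excluded; the contrast is always between the two biological
#' groups.
#'
#' @param sample_sheet Sample sheet tibble.
#' @param large_group Group label coded 1 in the indicator column.
#' @return A numeric matrix with rownames `sample_id` and columns
#'   `(Intercept, group)`.
#' @export
design_matrix <- function(sample_sheet, large_group = "large") {
  bio <- filter(sample_sheet, !.data$is_control)
  groups <- unique(bio$group)
  if (length(groups) != 2L || !large_group %in% groups) {
    abort("sample sheet must contain exactly two biological groups, one of which is `large_group`")
  }
  X <- cbind(`(Intercept)` = 1, group = as.numeric(bio$group == large_group))
  rownames(X) <- bio$sample_id
  X
}

# Unweighted per-site OLS for a common design; returns coefficients, fitted
# values, residual SDs and df.
ols_fit_rows <- function(y, X) {
  qrX <- qr(X)
  coef <- t(qr.coef(qrX, t(y)))
  fitted <- coef %*% t(X)
  res <- y - fitted
  df <- nrow(X) - qrX$rank
  sigma <- sqrt(rowSums(res^2) / df)
  list(coef = coef, fitted = fitted, sigma = sigma, df = df)
}

#' Log2-CPM transform with mean-variance precision weights
#'
#' Converts counts to `log2((count + 0.5) / (libsize + 1) * 1e6)`, fits an
#' unweighted first-pass linear model per site, estimates the mean-variance
#' trend by lowess of the square-root residual standard deviation on average
#' log2 count, and assigns each observation the precision weight
#' `predicted_sd^-4` evaluated at its fitted log2 count. Degenerate trends
#' (zero residual SD everywhere) yield weights capped at `weight_ceiling`
#' rather than infinities.
#'
#' @param counts Filtered wide count matrix from [apply_filters()].
#' @param sample_sheet Sample sheet tibble; controls are excluded.
#' @param design Optional design matrix; defaults to
#'   [design_matrix()] on the sheet.
#' @param span Lowess span of the mean-variance trend.
#' @param weight_ceiling Upper bound on any precision weight.
#' @return An object of class `rrhp_voom`: a list with `logcpm` and
#'   `weights` (site x sample matrices), `design`, `lib_size`, `trend`
#'   (the lowess curve), `sites` (key tibble) and `sample_ids`.
#' @export
voom_transform <- function(counts, sample_sheet, design = NULL, span = 0.5,
                           weight_ceiling = 1e6) {
  design <- design %||% design_matrix(sample_sheet)
  ids <- rownames(design)
  m <- count_matrix_values(counts, ids)
  if (nrow(m) < 2L) abort("need at least two sites to fit a mean-variance trend")
  lib <- colSums(m)
  if (any(lib == 0)) {
    abort(sprintf("library size is zero for sample(s): %s",
                  paste(ids[lib == 0], collapse = ", ")))
  }
  y <- t(log2(t(m + 0.5) / (lib + 1) * 1e6))

  fit <- ols_fit_rows(y, design)
  amean <- rowMeans(y)
  sx <- amean + mean(log2(lib + 1)) - log2(1e6)
  sy <- sqrt(fit$sigma)

  if (all(sy == sy[1])) {
    # constant residual SD: flat trend
    trend <- list(x = range(sx), y = rep(sy[1], 2))
  } else {
    trend <- lowess(sx, sy, f = span)
  }
  f <- if (length(unique(trend$x)) < 2L) {
    sd0 <- mean(trend$y)
    function(z) rep(sd0, length(z))
  } else {
    approxfun(trend$x, trend$y, rule = 2, ties = mean)
  }

  fitted_logcount <- sweep(fit$fitted, 2, log2(lib + 1) - log2(1e6), "+")
  pred_sd <- f(fitted_logcount)
  w <- 1 / pmax(pred_sd, 0)^4
  w <- pmin(w, weight_ceiling)
  dim(w) <- dim(y)
  dimnames(w) <- dimnames(y) <- list(NULL, ids)

  structure(
    list(
      logcpm = y, weights = w, design = design, lib_size = lib,
      trend = trend, span = span,
      sites = select(counts, "contig", "site_start", "strand"),
      sample_ids = ids, amean = amean
    ),
    class = "rrhp_voom"
  )
}

#' Per-site weighted least squares fit
#'
#' Fits the design to each site's log2-CPM values by weighted least squares
#' with the voom precision weights, so each observation's estimated variance
#' enters the regression.
#'
#' @param voom An `rrhp_voom` object from [voom_transform()].
#' @param design Optional design matrix overriding the one stored in `voom`.
#' @return A tibble with one row per site: key columns, `amean`, `logFC`
#'   (the group coefficient, log2 units), `stdev_unscaled`, `sigma` and
#'   `df_residual`.
#' @export
weighted_lm_fit <- function(voom, design = NULL) {
  X <- design %||% voom$design
  y <- voom$logcpm
  w <- voom$weights
  p <- ncol(X)
  n <- nrow(X)
  res <- matrix(NA_real_, nrow(y), 3L)
  for (i in seq_len(nrow(y))) {
    fit <- lm.wfit(X, y[i, ], w[i, ])
    xtx_inv <- chol2inv(chol(crossprod(X * sqrt(w[i, ]))))
    rss <- sum(w[i, ] * fit$residuals^2)
    res[i, ] <- c(fit$coefficients[p], sqrt(xtx_inv[p, p]),
                  sqrt(rss / (n - p)))
  }
  bind_cols(
    voom$sites,
    tibble(
      amean = voom$amean,
      logFC = res[, 1],
      stdev_unscaled = res[, 2],
      sigma = res[, 3],
      df_residual = n - p
    )
  )
}

# Inverse of the trigamma function (Newton iteration on a monotone
# decreasing function; converges in a handful of steps).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (iter in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-12) break
  }
  x
}

#' Empirical-Bayes moderation of per-site variances
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0^2` by
#' method of moments on `log(s^2)` (matching the mean and variance of the
#' log chi-square distribution via digamma/trigamma), shrinks each site's
#' residual variance to the posterior `s2_post = (d0*s0^2 + d*s^2)/(d0 + d)`,
#' and forms moderated t statistics `logFC / (sqrt(s2_post) *
#' stdev_unscaled)` on `d0 + d` degrees of freedom with two-sided p values
#' and Benjamini-Hochberg adjusted q values. When the observed variance of
#' `log(s^2)` does not exceed its sampling expectation, `d0 = Inf` and every
#' posterior variance equals `s0^2`.
#'
#' @param fits Per-site fit tibble from [weighted_lm_fit()].
#' @param d0_override Optional fixed prior degrees of freedom (`0` disables
#'   shrinkage entirely, giving ordinary t statistics; `Inf` shrinks every
#'   variance to the prior).
#' @return An object of class `rrhp_dhmc_fit`: a list with `table` (per-site
#'   tibble adding `s2_post`, `t`, `p_value`, `q_value`), `d0`, `s0_sq` and
#'   `df_total`.
#' @export
ebayes_moderate <- function(fits, d0_override = NULL) {
  s2 <- fits$sigma^2
  d <- fits$df_residual
  usable <- is.finite(s2) & s2 > 0
  if (sum(usable) < 2L) {
    abort("need at least two sites with finite positive variance to moderate")
  }

  df1 <- d[usable]
  z <- log(s2[usable])
  e <- z - digamma(df1 / 2) + log(df1 / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(df1 / 2))

  if (!is.null(d0_override)) {
    d0 <- d0_override
    s0_sq <- if (is.finite(d0) && d0 > 0) {
      exp(emean + digamma(d0 / 2) - log(d0 / 2))
    } else {
      mean(s2[usable])
    }
  } else if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess variability in log s^2: infinite prior df, arithmetic-mean prior
    d0 <- Inf
    s0_sq <- mean(s2[usable])
  }

  s2_safe <- ifelse(is.finite(s2), s2, 0)
  s2_post <- if (is.infinite(d0)) {
    rep(s0_sq, length(s2))
  } else if (d0 == 0) {
    s2_safe
  } else {
    (d0 * s0_sq + d * s2_safe) / (d0 + d)
  }
  # total df capped at the pooled residual df across sites
  df_total <- pmin(d0 + d, sum(d))
  tstat <- fits$logFC / (sqrt(s2_post) * fits$stdev_unscaled)
  p <- 2 * pt(-abs(tstat), df = df_total)
  q <- bh_adjust(p)

  structure(
    list(
      table = bind_cols(fits, tibble(s2_post = s2_post, t = tstat,
                                     p_value = p, q_value = q)),
      d0 = d0, s0_sq = s0_sq, df_total = df_total
    ),
    class = "rrhp_dhmc_fit"
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q[i] = min_{j >= i} p[(j)] * m / j` over the sorted p values, capped at
#' 1 and mapped back to input order.
#'
#' @param p Numeric vector of p values.
#' @return Adjusted q values in the input order.
#' @export
bh_adjust <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric())
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Call differentially hydroxymethylated cytosines
#'
#' Sites with `q < q_max` (strict), split by the sign of the group log fold
#' change and sorted by `q` then decreasing `|logFC|`. No fold-change
#' threshold is applied; the call is q-only.
#'
#' @param fit An `rrhp_dhmc_fit` from [ebayes_moderate()].
#' @param q_max Significance threshold on the adjusted p value.
#' @return A tibble of DhmC calls with a `direction` column
#'   (`"higher_in_large"` / `"higher_in_small"`).
#' @export
call_dhmc <- function(fit, q_max = 0.05) {
  fit$table |>
    filter(.data$q_value < q_max) |>
    mutate(direction = ifelse(.data$logFC > 0,
                              "higher_in_large", "higher_in_small")) |>
    arrange(.data$q_value, dplyr::desc(abs(.data$logFC)))
}

#' @exportS3Method generics::tidy
tidy.rrhp_dhmc_fit <- function(x, ...) {
  x$table
}

#' @exportS3Method generics::glance
glance.rrhp_dhmc_fit <- function(x, q_max = 0.05, ...) {
  tibble(
    n_sites = nrow(x$table),
    d0 = x$d0,
    s0_sq = x$s0_sq,
    n_dhmc = sum(x$table$q_value < q_max),
    n_higher_in_large = sum(x$table$q_value < q_max & x$table$logFC > 0),
    n_higher_in_small = sum(x$table$q_value < q_max & x$table$logFC < 0)
  )
}

#' @export
print.rrhp_dhmc_fit <- function(x, ...) {
  cat(sprintf(
    "Moderated differential hydroxymethylation fit: %d sites, d0 = %.4g, s0^2 = %.4g, %d DhmCs (q < 0.05)\n",
    nrow(x$table), x$d0, x$s0_sq, sum(x$table$q_value < 0.05)
  ))
  invisible(x)
}

#' Volcano plot of a moderated fit
#'
#' @param object An `rrhp_dhmc_fit`.
#' @param q_max Highlight threshold.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.rrhp_dhmc_fit <- function(object, q_max = 0.05, ...) {
  ggplot2::ggplot(
    object$table,
    ggplot2::aes(x = .data$logFC, y = -log10(.data$q_value),
                 colour = .data$q_value < q_max)
  ) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey50"),
      name = sprintf("q < %.2g", q_max)
    ) +
    ggplot2::labs(x = "log2 fold change (large vs small)",
                  y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}

#' Full differential hydroxymethylation analysis
#'
#' Convenience wrapper chaining [voom_transform()], [weighted_lm_fit()] and
#' [ebayes_moderate()] on a filtered count matrix.
#'
#' @inheritParams voom_transform
#' @param ... Passed to [voom_transform()].
#' @return An `rrhp_dhmc_fit`.
#' @export
diff_hmc_test <- function(counts, sample_sheet, ...) {
  voom_transform(counts, sample_sheet, ...) |>
    weighted_lm_fit() |>
    ebayes_moderate()
}
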