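test_that("log2-CPM transform matches its closed form and yields positive weights", {
  toy <- toy_counts(n_sites = 40)
  # plant a zero count in a library engineered to total 999,999
  toy$counts$BL1 <- c(0L, rep(0L, 39))
  toy$counts$BL1[2:40] <- as.integer(round(999999 / 39))
  toy$counts$BL1[2] <- toy$counts$BL1[2] + 999999L - sum(toy$counts$BL1)
  expect_equal(sum(toy$counts$BL1), 999999)

  v <- voom_transform(toy$counts, toy$sheet)
  expect_equal(unname(v$logcpm[1, "BL1"]), log2(0.5), tolerance = 1e-12)
  expect_true(all(is.finite(v$logcpm)))
  expect_true(all(v$weights > 0))
})

test_that("constant-count matrices hit the weight ceiling instead of Inf", {
  ids <- c(paste0("BL", 1:3), paste0("SL", 1:3))
  counts <- tibble::tibble(contig = "c", site_start = 1:5 * 4L, strand = "+")
  for (id in ids) counts[[id]] <- 10L
  sheet <- tibble::tibble(sample_id = ids,
                          group = rep(c("large", "small"), each = 3),
                          is_control = FALSE)
  v <- voom_transform(counts, sheet, weight_ceiling = 1e6)
  expect_true(all(v$weights == 1e6))

  counts0 <- counts
  counts0$BL1 <- 0L
  expect_error(voom_transform(counts0, sheet), "BL1")
})

test_that("weighted least squares reduces to group means and is scale invariant", {
  toy <- toy_counts(n_sites = 30)
  v <- voom_transform(toy$counts, toy$sheet)
  v1 <- v
  v1$weights[] <- 1
  f1 <- weighted_lm_fit(v1)
  large <- rowMeans(v$logcpm[, 1:5])
  small <- rowMeans(v$logcpm[, 6:10])
  expect_equal(f1$logFC, large - small, tolerance = 1e-12)

  v2 <- v
  v2$weights <- v$weights * 2
  f <- weighted_lm_fit(v)
  f2 <- weighted_lm_fit(v2)
  expect_equal(f$logFC, f2$logFC, tolerance = 1e-12)
  expect_equal(f$stdev_unscaled / f2$stdev_unscaled,
               rep(sqrt(2), nrow(f)), tolerance = 1e-12)
})

test_that("weighted fit agrees with a normal-equations oracle to 1e-8", {
  toy <- toy_counts(n_sites = 50)
  v <- voom_transform(toy$counts, toy$sheet)
  f <- weighted_lm_fit(v)
  X <- design_matrix(toy$sheet)
  for (i in seq_len(nrow(f))) {
    o <- wls_oracle(v$logcpm[i, ], X, v$weights[i, ])
    expect_equal(f$logFC[i], o$coef[2], tolerance = 1e-8)
    expect_equal(f$stdev_unscaled[i], o$stdev_unscaled[2], tolerance = 1e-8)
    expect_equal(f$sigma[i], o$sigma, tolerance = 1e-8)
  }
})

test_that("empirical-Bayes moderation matches its shrinkage limits", {
  toy <- toy_counts(n_sites = 50)
  f <- weighted_lm_fit(voom_transform(toy$counts, toy$sheet))

  inf <- ebayes_moderate(f, d0_override = Inf)
  expect_equal(inf$table$s2_post, rep(inf$s0_sq, nrow(f)))

  none <- ebayes_moderate(f, d0_override = 0)
  t_ordinary <- f$logFC / (f$sigma * f$stdev_unscaled)
  expect_equal(none$table$t, t_ordinary, tolerance = 1e-12)

  eb <- ebayes_moderate(f)
  lo <- pmin(f$sigma^2, eb$s0_sq)
  hi <- pmax(f$sigma^2, eb$s0_sq)
  expect_true(all(eb$table$s2_post >= lo - 1e-12 & eb$table$s2_post <= hi + 1e-12))

  expect_error(ebayes_moderate(f[1, ]), "at least two")
})

test_that("transform, fit and moderation agree with limma to near machine precision", {
  skip_if_not_installed("limma")
  for (seed in c(31, 32)) {
    toy <- toy_counts(n_sites = 50, seed = seed)
    m <- as.matrix(toy$counts[, toy$sheet$sample_id])
    X <- design_matrix(toy$sheet)
    v <- voom_transform(toy$counts, toy$sheet)
    vl <- limma::voom(m, design = X, lib.size = colSums(m))
    expect_equal(unname(v$logcpm), unname(vl$E), tolerance = 1e-10)
    expect_equal(unname(v$weights), unname(vl$weights), tolerance = 1e-8)

    eb <- ebayes_moderate(weighted_lm_fit(v))
    ebl <- limma::eBayes(limma::lmFit(vl$E, X, weights = vl$weights))
    expect_equal(eb$d0, ebl$df.prior, tolerance = 1e-8)
    expect_equal(eb$s0_sq, ebl$s2.prior, tolerance = 1e-8)
    expect_equal(eb$table$t, unname(ebl$t[, 2]), tolerance = 1e-8)
    expect_equal(eb$table$p_value, unname(ebl$p.value[, 2]), tolerance = 1e-8)
  }
})

test_that("BH adjustment implements the step-up minimum and matches p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(numeric()), numeric())

  withr::with_seed(1, {
    for (i in 1:20) {
      p <- runif(sample(1:200, 1))^sample(1:3, 1)
      expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
      # monotone: significance decisions respect the p ordering
      q <- bh_adjust(p)
      o <- order(p)
      expect_true(all(diff(q[o]) >= -1e-15))
    }
  })
})

test_that("DhmC calling is strict at the threshold and splits by direction", {
  fake <- structure(list(table = tibble::tibble(
    contig = "c", site_start = 1:4 * 4L, strand = "+",
    logFC = c(2, -1, -0.5, -3),
    q_value = c(0.01, 0.05, 0.049, 0.2)
  )), class = "rrhp_dhmc_fit")
  calls <- call_dhmc(fake, q_max = 0.05)
  expect_equal(nrow(calls), 2L)
  expect_false(any(calls$q_value >= 0.05))
  expect_setequal(calls$direction, c("higher_in_large", "higher_in_small"))
  expect_equal(sum(calls$direction == "higher_in_large") +
                 sum(calls$direction == "higher_in_small"), nrow(calls))

  empty <- structure(list(table = fake$table[0, ]), class = "rrhp_dhmc_fit")
  expect_equal(nrow(call_dhmc(empty)), 0L)
})

test_that("MDS distances are metric-sane and separate planted groups", {
  toy <- toy_counts(n_sites = 200, seed = 44)
  # duplicated sample columns have zero distance and identical coordinates
  toy$counts$SL5 <- toy$counts$BL1
  mds <- mds_coordinates(toy$counts, toy$sheet, top_sites = 100)
  dd <- attr(mds, "distances")
  expect_true(isSymmetric(dd))
  expect_equal(diag(dd), setNames(rep(0, 10), toy$sheet$sample_id))
  expect_equal(dd["BL1", "SL5"], 0)
  expect_equal(unname(mds$dim1[mds$sample_id == "BL1"]),
               unname(mds$dim1[mds$sample_id == "SL5"]))

  # planted shared effect: first coordinate separates groups by more than the
  # within-group spread
  cfg <- rrhp_sim_config(genome_length = 100000, n_contigs = 1,
                         target_site_count = 400, diff_fraction = 0.3,
                         effect_logit_shift = log(6), nb_dispersion = 0.05,
                         depth_factor = 300,
                         baseline_level_params = c(2, 18), seed = 45)
  sim <- simulate_rrhp_experiment(cfg)
  mds2 <- mds_coordinates(sim$counts, sim$sample_sheet,
                          include_controls = FALSE)
  d1 <- split(mds2$dim1, mds2$group)
  gap <- abs(mean(d1$large) - mean(d1$small))
  spread <- max(sd(d1$large), sd(d1$small))
  expect_gt(gap, spread)
})

test_that("tidy and glance expose the fit table and hyperparameters", {
  toy <- toy_counts(n_sites = 40)
  fit <- diff_hmc_test(toy$counts, toy$sheet)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("logFC", "t", "p_value", "q_value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n_sites, 40L)
  expect_equal(gl$n_dhmc, gl$n_higher_in_large + gl$n_higher_in_small)
})
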