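test_that("fit_increments matches direct arithmetic", {
  expect_equal(fit_increments(rep(0.5, 4), 0:3), rep(0, 3))
  expect_equal(fit_increments(c(0.5, 1.0), c(0, 1)), 0.5 / sqrt(2 * 0.25))
  expect_equal(fit_increments(c(0.5, 0.6, 0.7), c(0, 1, 2)),
               c(0.1 / sqrt(2 * 0.25), 0.1 / sqrt(2 * 0.24)),
               tolerance = 1e-12)
  # unequal intervals rescale by sqrt(dt)
  expect_equal(fit_increments(c(0.5, 0.6), c(0, 4)),
               0.1 / sqrt(2 * 0.25 * 4))
  expect_error(fit_increments(c(0.5, 1, 0.5), 0:2),
               class = "fitr_focal_degenerate")
  expect_error(fit_increments(c(0.5, 0.6), c(0, 0)), "increasing")
})

test_that("fit_test equals the one-sample t-test on the increments", {
  set.seed(1)
  for (L in c(2, 5, 20)) {
    x <- cumsum(c(0.5, rnorm(L, 0, 0.02)))
    times <- cumsum(c(0, sample(1:3, L, replace = TRUE)))
    res <- fit_test(x, times)
    oracle <- t.test(fit_increments(x, times))
    expect_equal(res$statistic, unname(oracle$statistic), tolerance = 1e-10)
    expect_equal(res$p_value, oracle$p.value, tolerance = 1e-10)
    expect_equal(res$df, L - 1)
  }
})

test_that("fit_test degenerate cases error distinctly", {
  expect_error(fit_test(c(0.5, 0.6), c(0, 1)), "L = 2")
  # symmetric increments: t = 0, p = 1
  res <- fit_test(c(0.5, 0.6, 0.5), c(0, 1, 2))
  expect_lt(abs(res$statistic), 0.3)  # near-symmetric (denominators differ)
  expect_error(fit_test(c(0.25, 0.5, 1, 1), 0:3),
               class = "fitr_focal_degenerate")
})

test_that("fitr_increments computes per-locus standardized increments and flags fixation", {
  x <- cbind(locus_0 = c(0.5, 0.75), locus_1 = c(0.2, 0.3))
  inc <- fitr_increments(x, times = c(0, 10))
  expect_equal(unname(inc$d[1, ]), c(0.25 / 0.5, 0.1 / sqrt(0.16)))
  expect_true(all(inc$valid))
  # reference fixed at an intermediate time is flagged, not dropped
  x3 <- cbind(c(0.5, 0.6, 0.7), c(0.1, 0, 0), c(0.4, 0.5, 0.6))
  inc3 <- fitr_increments(x3, times = 0:2)
  expect_equal(unname(inc3$valid), c(TRUE, FALSE, TRUE))
  expect_equal(ncol(inc3$d), 3L)
  # focal fixation before the last time errors
  expect_error(fitr_increments(cbind(c(0.5, 1, 1), c(0.4, 0.5, 0.6)), 0:2),
               class = "fitr_focal_degenerate")
  # focal fixation exactly at the last time is fine
  expect_silent(fitr_increments(cbind(c(0.5, 0.9, 1), c(0.4, 0.5, 0.6)), 0:2))
  # reference fixing exactly at the last time is flagged for removal
  inc_last <- fitr_increments(cbind(c(0.5, 0.6, 0.7), c(0.4, 0.5, 1)), 0:2)
  expect_equal(unname(inc_last$valid), c(TRUE, FALSE))
})

test_that("filter_reference_loci removes flagged references and errors when none survive", {
  x <- cbind(c(0.5, 0.6, 0.7), c(0.1, 0, 0), c(0.4, 0.5, 0.6))
  colnames(x) <- paste0("locus_", 0:2)
  f <- filter_reference_loci(fitr_increments(x, 0:2))
  expect_equal(colnames(f$d), c("locus_0", "locus_2"))
  expect_equal(f$removed, "locus_1")
  all_fixed <- cbind(c(0.5, 0.6, 0.7), c(0.1, 0, 0), c(0.9, 1, 1))
  expect_error(filter_reference_loci(fitr_increments(all_fixed, 0:2)),
               class = "fitr_no_reference")
  ok <- fitr_increments(cbind(c(0.5, 0.6), c(0.4, 0.3)), c(0, 1))
  expect_equal(filter_reference_loci(ok)$d, ok$d)
})

test_that("fitr_component is exact arithmetic and scale-invariant", {
  expect_equal(fitr_component(0, c(0.3, -0.1)), 0)
  expect_equal(fitr_component(0.7, 0.7), 1)
  expect_equal(fitr_component(0.3, c(0.1, -0.2, 0.2)),
               0.3 / sqrt(0.09 / 3), tolerance = 1e-12)
  expect_error(fitr_component(0.3, c(0, 0)), class = "fitr_zero_denominator")
  # rescaling a whole interval (focal and references) cancels: the per-step
  # effective population size and interval length drop out
  set.seed(2)
  d0 <- rnorm(1); dref <- rnorm(8)
  for (c_ in c(0.01, 3, -2)) {
    expect_equal(abs(fitr_component(c_ * d0, c_ * dref)),
                 abs(fitr_component(d0, dref)), tolerance = 1e-12)
  }
})

test_that("fitr_statistic agrees with its summation form and a brute-force oracle", {
  set.seed(3)
  for (rep in 1:20) {
    L <- sample(1:6, 1); R <- sample(1:8, 1)
    x <- matrix(runif((L + 1) * (R + 1), 0.05, 0.95), L + 1, R + 1)
    inc <- filter_reference_loci(fitr_increments(x, 0:L))
    t5 <- fitr_statistic(inc)  # component-sum form
    # summation form: sum_i d0_i / sqrt((L/R) sum_h dref_hi^2)
    d <- inc$d
    t6 <- sum(d[, 1] / sqrt(L / R * rowSums(d[, -1, drop = FALSE]^2)))
    expect_equal(t5, t6, tolerance = 1e-12)
    expect_equal(t5, fitr_stat_oracle(x), tolerance = 1e-12)
  }
  # L = 1 reduces to the single component
  x1 <- matrix(c(0.5, 0.75, 0.2, 0.4), 2, 2)
  inc1 <- filter_reference_loci(fitr_increments(x1, 0:1))
  expect_equal(fitr_statistic(inc1), fitr_component(inc1$d[1, 1], inc1$d[1, 2]))
})

test_that("fitr_null has Student-t building blocks and is cached", {
  n1 <- fitr_null(1, 10, M = 1e5, seed = 5)
  expect_gt(ks.test(n1, pt, df = 10)$p.value, 0.01)
  n2 <- fitr_null(4, 10, M = 1e5, seed = 5)
  expect_lt(abs(mean(n2)), 3 * sqrt(1.25 / 1e5))
  expect_lt(abs(var(n2) - 10 / 8), 3 * 1.25 * sqrt(2 / 1e5))
  # cache: same key returns the identical vector without burning RNG state
  set.seed(123); before <- rnorm(1)
  expect_identical(fitr_null(4, 10, M = 1e5, seed = 5), n2)
  set.seed(123)
  expect_identical(rnorm(1), before)
})

test_that("per-interval statistic and FIT statistic follow their Student-t nulls on normal increments", {
  set.seed(8)
  M <- 1e5; R <- 7
  d0 <- rnorm(M)
  dref <- matrix(rnorm(M * R), M, R)
  ti <- d0 / sqrt(rowMeans(dref^2))
  expect_gt(ks.test(ti, pt, df = R)$p.value, 0.01)
  L <- 5
  Y <- matrix(rnorm(M * L), M, L)
  tfit <- rowMeans(Y) / sqrt(apply(Y, 1, var) / L)
  expect_gt(ks.test(tfit, pt, df = L - 1)$p.value, 0.01)
})

test_that("fitr_test runs the full pipeline with empirical and analytic nulls", {
  set.seed(9)
  x <- matrix(runif(4 * 6, 0.2, 0.8), 4, 6)
  res <- fitr_test(x, times = c(0, 2, 4, 6), M = 2e4)
  expect_s3_class(res, "fitr_test_result")
  expect_equal(res$R_used, 5)
  expect_true(res$p_value > 0 && res$p_value <= 1)
  expect_equal(res$statistic, fitr_stat_oracle(x), tolerance = 1e-12)
  # L = 1: analytic Student-t p-value
  x1 <- matrix(c(0.5, 0.75, 0.3, 0.35, 0.6, 0.5), 2, 3)
  r1 <- fitr_test(x1, times = c(0, 5))
  expect_equal(r1$p_value, 2 * pt(-abs(r1$statistic), df = 2), tolerance = 1e-12)
  # degenerate signals are distinct
  expect_error(fitr_test(cbind(c(0.5, 0, 0), c(0.3, 0.4, 0.5)), 0:2),
               class = "fitr_focal_degenerate")
  expect_error(fitr_test(cbind(c(0.4, 0.5, 0.6), c(0.1, 0, 0)), 0:2),
               class = "fitr_no_reference")
  nochange <- cbind(c(0.5, 0.6, 0.7), c(0.3, 0.3, 0.4), c(0.2, 0.2, 0.25))
  expect_error(fitr_test(nochange, 0:2), class = "fitr_zero_denominator")
})

test_that("batch test paths agree with the per-dataset functions", {
  set.seed(10)
  cfg <- sim_config(builtin_model("model1p", 20), x0 = 0.5,
                    s = c(0.05, rep(0, 6)), sample_times = seq(0, 20, 4),
                    method = "binomial")
  arr <- simulate_trajectories(cfg, replicates = 60, seed = 14)
  bat <- fitr:::fitr_test_batch(arr, cfg$sample_times, M = 1e4)
  for (k in seq_len(60)) {
    x <- arr[k, , ]
    single <- tryCatch(fitr_test(x, cfg$sample_times, M = 1e4),
                       fitr_error = function(e) NULL)
    if (is.null(single)) {
      expect_true(bat$degenerate[k])
    } else {
      expect_false(bat$degenerate[k])
      expect_equal(bat$statistic[k], single$statistic, tolerance = 1e-10)
      expect_equal(bat$p[k], single$p_value, tolerance = 1e-12)
      expect_equal(bat$R_used[k], single$R_used)
    }
  }
  fb <- fitr:::fit_test_batch(matrix(arr[, , 1], 60), cfg$sample_times)
  for (k in seq_len(60)) {
    single <- tryCatch(fit_test(arr[k, , 1], cfg$sample_times),
                       fitr_error = function(e) NULL)
    if (is.null(single)) {
      expect_true(fb$degenerate[k])
    } else {
      expect_equal(fb$statistic[k], single$statistic, tolerance = 1e-10)
      expect_equal(fb$p[k], single$p_value, tolerance = 1e-12)
    }
  }
})
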