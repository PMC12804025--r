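test_that("median normalization undoes sample-level scale shifts and is idempotent", {
  set.seed(1)
  m <- matrix(2^rnorm(60, 10), 20, 3)
  tab <- make_tab(m, rep("LPS", 3), c(0L, 15L, 30L))
  ref <- median_normalize(tab)   # all sample medians now equal
  # scale one sample by 2: normalization restores the reference values
  m2 <- ref$intensities; m2[, 2] <- m2[, 2] * 2
  tab2 <- make_tab(m2, rep("LPS", 3), c(0L, 15L, 30L))
  expect_equal(median_normalize(tab2)$intensities, ref$intensities,
               tolerance = 1e-9)
  # idempotence
  expect_equal(median_normalize(ref)$intensities, ref$intensities,
               tolerance = 1e-12)
  # samples already sharing a median stay put
  same <- make_tab(matrix(c(1, 2, 4, 1, 2, 4), 3), c("LPS", "CONTROL"),
                   c(0L, 0L))
  expect_equal(median_normalize(same)$intensities, same$intensities,
               tolerance = 1e-12)
  # single-sample table is identity
  one <- make_tab(matrix(c(1, 5, 9), 3), "LPS", 0L)
  expect_equal(median_normalize(one)$intensities, one$intensities,
               tolerance = 1e-12)
  # all-missing sample is an error naming it
  bad <- m; bad[, 3] <- NA
  expect_error(median_normalize(make_tab(bad, rep("LPS", 3), c(0L, 15L, 30L))),
               "s03")
})

test_that("spike-in normalization flattens the standard and is idempotent", {
  m <- rbind(c(10, 20, 10), c(4, 8, 4), c(100, 200, 100))
  tab <- make_tab(m, rep("LPS", 3), c(0L, 15L, 30L),
                  proteins = c("P01", "P02", "SPIKE"), spikein_id = "SPIKE")
  norm <- spikein_normalize(tab)
  s <- norm$intensities["SPIKE", ]
  expect_equal(stats::sd(s) / mean(s), 0)  # CV exactly 0
  # the sample with a doubled spike-in is halved relative to the others
  expect_equal(norm$intensities["P01", 2] / norm$intensities["P01", 1], 1)
  expect_equal(unname(norm$intensities["P01", ] / norm$intensities["P01", 1]),
               rep(1, 3))
  # constant spike-in leaves the table untouched
  flat <- make_tab(rbind(c(1, 2), c(5, 5)), c("LPS", "CONTROL"), c(0L, 0L),
                   proteins = c("P01", "SPIKE"), spikein_id = "SPIKE")
  expect_equal(spikein_normalize(flat)$intensities, flat$intensities,
               tolerance = 1e-12)
  # idempotence
  expect_equal(spikein_normalize(norm)$intensities, norm$intensities,
               tolerance = 1e-12)
  # spike-in missing in a sample is an error naming the sample
  m2 <- m; m2[3, 2] <- NA
  expect_error(spikein_normalize(make_tab(m2, rep("LPS", 3), c(0L, 15L, 30L),
                                          proteins = c("P01", "P02", "SPIKE"),
                                          spikein_id = "SPIKE")), "s02")
})

test_that("spike-in normalization recovers planted fold changes from scaled runs", {
  cfg <- sim_config(seed = 13, n_proteins = 50, noise_cv = 0, dropout_rate = 0,
                    run_scale_range = c(0.5, 2))
  sup <- simulate_secretome(cfg)
  norm <- spikein_normalize(sup$table)
  ts <- cfg$secretome_times_min
  fc <- trajectory_matrix(fold_change_timecourse(norm, "LPS"))
  for (p in released_truth(sup$truth)[1:3]) {
    expect_equal(unname(fc[p, ]), 1 + 2 * ts / (ts + 30), tolerance = 1e-9)
  }
})

test_that("relative percentage is 100 at baseline and tracks replicate means", {
  # replicates {8,10,12} at t=30 vs {10,10,10} at baseline -> 100%
  m <- cbind(matrix(10, 1, 3), matrix(c(8, 10, 12), 1, 3))
  tab <- make_tab(m, rep("LPS", 6), rep(c(0L, 30L), each = 3),
                  replicates = rep(1:3, 2), compartment = "cell")
  tr <- relative_percentage(tab, "LPS")
  expect_equal(tr$value[tr$time_min == 0], 100)
  expect_equal(tr$value[tr$time_min == 30], 100)
  # halved LFQ -> 50%
  m2 <- cbind(matrix(10, 1, 3), matrix(5, 1, 3))
  tab2 <- make_tab(m2, rep("LPS", 6), rep(c(0L, 30L), each = 3),
                   replicates = rep(1:3, 2), compartment = "cell")
  expect_equal(relative_percentage(tab2, "LPS")$value, c(100, 50))
  # zero/missing baseline leaves the trajectory undefined, not an error
  m3 <- cbind(matrix(NA_real_, 1, 3), matrix(5, 1, 3))
  tab3 <- make_tab(m3, rep("LPS", 6), rep(c(0L, 30L), each = 3),
                   replicates = rep(1:3, 2), compartment = "cell")
  expect_true(all(is.na(relative_percentage(tab3, "LPS")$value)))
})

test_that("fold-change trajectories ratio stimulated over matched-time control", {
  m <- cbind(c(10, 3), c(10, 6), c(10, 3), c(30, 3))
  tab <- make_tab(m, c("CONTROL", "CONTROL", "PMA", "PMA"),
                  c(0L, 120L, 0L, 120L))
  tr <- fold_change_timecourse(tab, "PMA")
  fc <- trajectory_matrix(tr)
  expect_equal(unname(fc["P01", ]), c(1, 3))
  expect_equal(unname(fc["P02", ]), c(1, 0.5))
  # missing in either arm makes the point missing
  m[2, 4] <- NA
  tab <- make_tab(m, c("CONTROL", "CONTROL", "PMA", "PMA"),
                  c(0L, 120L, 0L, 120L))
  fc <- trajectory_matrix(fold_change_timecourse(tab, "PMA"))
  expect_true(is.na(fc["P02", "120"]))
  # disjoint grids are an error
  tab2 <- make_tab(matrix(1, 1, 2), c("CONTROL", "PMA"), c(0L, 15L))
  expect_error(fold_change_timecourse(tab2, "PMA"), "shared time")
})

test_that("differential test flags planted shifts and not identical arms", {
  set.seed(21)
  n <- 200
  noise <- function(k) matrix(2^rnorm(n * k, 0, log2(1 + 0.05)), n, k)
  base <- 2^rnorm(n, 12, 1)
  shift <- rep(1, n); shift[1:20] <- 4  # planted 4-fold
  x <- base * shift * noise(3)
  y <- base * noise(3)
  tab <- make_tab(cbind(x, y), rep(c("LPS", "CONTROL"), each = 3),
                  rep(60L, 6), replicates = rep(1:3, 2), compartment = "cell")
  de <- differential_test(tab, "LPS", 60L)
  # a moderation-free 3 v 3 Welch test has high but not perfect power after
  # FDR adjustment even for a 4-fold shift at 5% CV: the df are tiny
  expect_true(all(de$p[1:20] < 0.01))
  expect_gte(mean(de$significant[1:20]), 0.8)
  expect_lt(sum(de$significant[-(1:20)]), 3)
  expect_true(all(de$adj_p >= de$p, na.rm = TRUE))
  # identical arms: p = 1, never significant
  same <- make_tab(cbind(matrix(5, 2, 3), matrix(5, 2, 3)),
                   rep(c("LPS", "CONTROL"), each = 3), rep(60L, 6),
                   replicates = rep(1:3, 2), compartment = "cell")
  de0 <- differential_test(same, "LPS", 60L)
  expect_equal(de0$p, c(1, 1))
  expect_false(any(de0$significant))
  # under-replicated proteins are flagged untested
  xm <- cbind(x, y); xm[1, 1:2] <- NA
  de1 <- differential_test(make_tab(xm, rep(c("LPS", "CONTROL"), each = 3),
                                    rep(60L, 6), replicates = rep(1:3, 2),
                                    compartment = "cell"), "LPS", 60L)
  expect_false(de1$tested[1])
  expect_true(is.na(de1$p[1]))
})

test_that("BH adjustment matches the textbook step-up on a hand example", {
  p <- c(0.01, 0.02, 0.03, 0.2, 0.9)
  expect_equal(bh_oracle(p), c(0.05, 0.05, 0.05, 0.25, 0.9))
  expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p))
})
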