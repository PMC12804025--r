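test_that("linear trend slope matches the closed form", {
  t <- c(0L, 5L, 15L, 30L, 60L, 120L)
  expect_equal(fit_linear_trend(t, rep(1, 6)), 0)
  expect_equal(fit_linear_trend(t, 1 + 0.5 * t / 60), 0.5, tolerance = 1e-12)
  set.seed(4)
  for (i in 1:25) {
    y <- runif(6, 0.5, 4)
    y[sample(6, sample(0:2, 1))] <- NA
    if (sum(!is.na(y)) < 2) next
    expect_equal(fit_linear_trend(t, y), slope_oracle(t / 60, y),
                 tolerance = 1e-12)
  }
  expect_true(is.na(fit_linear_trend(t, c(1, rep(NA, 5)))))
})

test_that("release rule: strict thresholds then exclusions, with reasons", {
  calls <- data.frame(protein = c("A", "B", "C", "D", "E"), condition = "LPS",
                      slope = c(0.2, -0.1, 0.3, 0.2, NA),
                      max_fc = c(1.6, 2.0, 1.6, 1.5, 2.0))
  ann <- as_annotations(data.frame(accession = "C", exclusion_class = "histone"))
  out <- classify_released(calls, ann)
  expect_equal(out$released, c(TRUE, FALSE, FALSE, FALSE, FALSE))
  expect_equal(out$reason[out$protein == "C"], "histone")
  expect_true(out$excluded[out$protein == "C"])
  # D fails the strict > 1.5; E has undefined slope
  expect_equal(out$reason[out$protein == "E"], "undefined_slope")
  # boundary: slope exactly 0 is not released
  out0 <- classify_released(data.frame(protein = "F", condition = "LPS",
                                       slope = 0, max_fc = 2), NULL)
  expect_false(out0$released)
})

test_that("raising the fold-change threshold never adds released proteins", {
  cfg <- sim_config(seed = 17, n_proteins = 150)
  sup <- simulate_secretome(cfg)
  tab <- spikein_normalize(median_normalize(sup$table))
  prev <- NULL
  for (thr in c(1.2, 1.5, 2, 2.5)) {
    rel <- release_screen(tab, "LPS", annotations = sup$truth$annotations,
                          fc_threshold = thr)[["LPS"]]
    cur <- rel$protein[rel$released]
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("condition union builds the catalog; dropping a condition never adds", {
  mk <- function(p, cond) data.frame(protein = p, condition = cond,
                                     slope = 1, max_fc = 2, excluded = FALSE,
                                     reason = "", released = TRUE)
  calls <- list(LPS = mk(c("A", "B"), "LPS"), TNFA = mk(c("B", "C"), "TNFA"),
                PMA = mk("C", "PMA"))
  ann <- as_annotations(data.frame(accession = "A", granule_subsets = "AG"))
  cat3 <- combine_conditions(calls, ann)
  expect_setequal(cat3$protein, c("A", "B", "C"))
  expect_equal(sum(cat3$class == "canonical_granule"), 1L)
  expect_equal(sum(cat3$class == "non_canonical"), 2L)
  expect_true(cat3$released_LPS[cat3$protein == "A"])
  expect_false(cat3$released_PMA[cat3$protein == "A"])
  cat2 <- combine_conditions(calls[c("LPS", "TNFA")], ann)
  expect_true(all(cat2$protein %in% cat3$protein))
})

test_that("granule-subset counts honor multi-membership", {
  ann <- as_annotations(data.frame(
    accession = c("A", "B", "C"),
    granule_subsets = c("AG", "AG;GG", "SV")))
  calls <- list(LPS = data.frame(protein = c("A", "B", "C"), condition = "LPS",
                                 slope = 1, max_fc = 2, excluded = FALSE,
                                 reason = "", released = TRUE))
  catal <- combine_conditions(calls, ann)
  s <- summarize_granule_subsets(catal, ann)
  expect_equal(s$subset_counts[["AG"]], 2L)
  expect_equal(s$subset_counts[["GG"]], 1L)
  expect_equal(s$subset_counts[["SV"]], 1L)
  expect_equal(s$subset_counts[["SG"]], 0L)
  expect_gte(sum(s$subset_counts), sum(catal$class == "canonical_granule"))
  expect_equal(s$condition_counts[["LPS"]], 3L)
  # empty catalog -> zeros
  empty <- combine_conditions(list(LPS = calls$LPS[0, ]), ann)
  s0 <- summarize_granule_subsets(empty, ann)
  expect_true(all(s0$subset_counts == 0))
})

test_that("subset counts equal a brute-force tally on synthetic annotations", {
  cfg <- sim_config(seed = 23, n_proteins = 300)
  truth <- simulation_truth(cfg)
  ann <- truth$annotations
  canon <- ann$accession[nzchar(ann$granule_subsets)]
  calls <- list(X = data.frame(protein = canon, condition = "X", slope = 1,
                               max_fc = 2, excluded = FALSE, reason = "",
                               released = TRUE))
  s <- summarize_granule_subsets(combine_conditions(calls, ann), ann)
  for (g in c("AG", "SG", "GG", "SV")) {
    tally <- sum(vapply(strsplit(ann$granule_subsets[match(canon, ann$accession)],
                                 ";"), function(x) g %in% x, TRUE))
    expect_equal(s$subset_counts[[g]], tally)
  }
})

test_that("2 h release level passes through observed fold changes", {
  traj <- list(LPS = data.frame(protein = rep(c("A", "B"), each = 2),
                                condition = "LPS", kind = "fold_change",
                                time_min = c(60L, 120L, 60L, 120L),
                                value = c(2, 2.4, 1.1, NA)))
  calls <- list(LPS = data.frame(protein = c("A", "B"), condition = "LPS",
                                 slope = 1, max_fc = 2, excluded = FALSE,
                                 reason = "", released = TRUE))
  catal <- combine_conditions(calls, NULL)
  lvl <- release_level_2h(traj, catal)
  expect_equal(lvl$fc_2h_LPS[lvl$protein == "A"], 2.4)
  expect_true(is.na(lvl$fc_2h_LPS[lvl$protein == "B"]))
})

test_that("secretion-route aggregation ORs the four routes", {
  n <- 242L
  flagged <- 177L
  acc <- sprintf("N%03d", 1:n)
  ann <- as_annotations(data.frame(accession = acc,
                                   signal_peptide = c(rep(TRUE, flagged),
                                                      rep(FALSE, n - flagged))))
  calls <- list(X = data.frame(protein = acc, condition = "X", slope = 1,
                               max_fc = 2, excluded = FALSE, reason = "",
                               released = TRUE))
  r <- aggregate_secretion_routes(combine_conditions(calls, ann), ann)
  expect_equal(r$n, 242L)
  expect_equal(r$n_secreted, 177L)
  expect_equal(r$percent_secreted, 73)
  # all-false flags
  ann0 <- as_annotations(data.frame(accession = acc))
  r0 <- aggregate_secretion_routes(combine_conditions(calls, ann0), ann0)
  expect_equal(r0$percent_secreted, 0)
  expect_length(r0$secreted, 0)
  # random flags match brute-force counting
  set.seed(6)
  rand <- as_annotations(data.frame(accession = acc,
                                    signal_peptide = runif(n) < 0.2,
                                    nonclassical = runif(n) < 0.3,
                                    transmembrane = runif(n) < 0.1,
                                    vesicle = runif(n) < 0.5))
  rr <- aggregate_secretion_routes(combine_conditions(calls, rand), rand)
  manual <- with(as.data.frame(rand),
                 signal_peptide | nonclassical | transmembrane | vesicle)
  expect_equal(rr$n_secreted, sum(manual))
  expect_equal(rr$route_fractions[["vesicle"]], mean(rand$vesicle))
})

test_that("consistent core set needs significance and one sign in all conditions", {
  mk <- function(adj, lfc) data.frame(protein = c("A", "B", "C"),
                                      condition = "x", time_min = 240L,
                                      log2_fc = lfc, p = adj / 2, adj_p = adj,
                                      significant = TRUE, tested = TRUE)
  de <- list(LPS = mk(c(0.01, 0.01, 0.2), c(1, 1, 1)),
             TNFA = mk(c(0.02, 0.01, 0.01), c(2, -1, 1)),
             PMA = mk(c(0.04, 0.01, 0.01), c(0.5, 1, 1)))
  core <- consistent_core_set(de, alpha = 0.05)
  expect_equal(core$protein, "A")  # B flips sign, C not significant in LPS
  expect_equal(core$direction, "up")
})

test_that("planted consistent responders are recovered at low noise", {
  cfg <- sim_config(seed = 31, n_proteins = 400, noise_cv = 0.05,
                    dropout_rate = 0)
  cell <- simulate_cell_proteome(cfg)
  tmax <- max(cfg$cell_times_min)
  de <- lapply(c("LPS", "TNFA", "PMA"), function(cc)
    differential_test(cell$table, cc, tmax))
  names(de) <- c("LPS", "TNFA", "PMA")
  core <- consistent_core_set(de, alpha = 0.05)
  planted <- names(cell$truth$classes)[cell$truth$classes %in%
    c("released_with_depletion", "induced_cellular")]
  expect_setequal(core$protein, planted)
  up <- names(cell$truth$classes)[cell$truth$classes == "induced_cellular"]
  expect_true(all(core$direction[core$protein %in% up] == "up"))
  expect_true(all(core$direction[!core$protein %in% up] == "down"))
})
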