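test_that("identical configs give bit-identical simulations", {
  cfg <- sim_config(seed = 11, n_proteins = 60)
  a <- simulate_secretome(cfg); b <- simulate_secretome(cfg)
  expect_identical(a$table$intensities, b$table$intensities)
  expect_identical(a$truth$classes, b$truth$classes)
  a <- simulate_cell_proteome(cfg); b <- simulate_cell_proteome(cfg)
  expect_identical(a$table$intensities, b$table$intensities)
  a <- simulate_shedding_experiment(cfg); b <- simulate_shedding_experiment(cfg)
  expect_identical(a$table$intensities, b$table$intensities)
})

test_that("zero-noise simulations reproduce the class templates exactly", {
  cfg <- sim_config(seed = 1, n_proteins = 80, noise_cv = 0, dropout_rate = 0,
                    release_amplitude = 3, depletion_floor = 40)
  cell <- simulate_cell_proteome(cfg)
  rp <- trajectory_matrix(relative_percentage(cell$table, "LPS"))
  t <- cfg$cell_times_min
  dep <- names(cell$truth$classes)[cell$truth$classes == "released_with_depletion"]
  ind <- names(cell$truth$classes)[cell$truth$classes == "induced_cellular"]
  bg <- names(cell$truth$classes)[cell$truth$classes == "background"]
  expect_equal(unname(rp[dep[1], ]), 100 - 60 * t / max(t), tolerance = 1e-9)
  expect_equal(unname(rp[ind[1], ]), 100 + 200 * t / max(t), tolerance = 1e-9)
  expect_equal(unname(rp[bg[1], ]), rep(100, length(t)), tolerance = 1e-9)
  # monotone decline / rise
  expect_true(all(diff(rp[dep[1], ]) < 0))
  expect_true(all(diff(rp[ind[1], ]) > 0))

  sup <- simulate_secretome(cfg)
  fc <- trajectory_matrix(fold_change_timecourse(spikein_normalize(sup$table), "PMA"))
  ts <- cfg$secretome_times_min
  rel <- released_truth(sup$truth)[1]
  expect_equal(unname(fc[rel, ]), 1 + 2 * ts / (ts + 30), tolerance = 1e-9)
  expect_equal(max(fc[rel, ]), 1 + 2 * 120 / (120 + 30), tolerance = 1e-9)
  expect_equal(unname(fc[bg[1], ]), rep(1, length(ts)), tolerance = 1e-9)
})

test_that("planted class counts follow the configured fractions", {
  cfg <- sim_config(seed = 3, n_proteins = 1000,
                    class_fractions = c(background = 0.85,
                                        released_with_depletion = 0.15))
  truth <- simulation_truth(cfg)
  expect_equal(sum(truth$classes == "released_with_depletion"), 150L)
  expect_equal(length(released_truth(truth)), 150L)
  expect_equal(length(truth$classes), 1000L)
  # every protein gets exactly one label
  expect_true(all(truth$classes %in% c("background", "released_with_depletion")))
})

test_that("spike-in row is constant when run scales are off", {
  cfg <- sim_config(seed = 5, n_proteins = 30, run_scale_range = c(1, 1))
  sup <- simulate_secretome(cfg)
  s <- sup$table$intensities[sup$table$spikein_id, ]
  expect_equal(unname(s), rep(cfg$spikein_level, length(s)))
})

test_that("shedding arms differ exactly by the inhibitor effect when noise-free", {
  cfg <- sim_config(seed = 2, n_proteins = 40, noise_cv = 0, dropout_rate = 0,
                    inhibitor_effect = 2,
                    class_fractions = c(shed_membrane = 0.5, background = 0.5))
  shed <- simulate_shedding_experiment(cfg)
  tab <- shed$table
  sub <- rownames(tab$intensities)[shed$truth$substrates[, "LPS"]][1]
  bg <- setdiff(rownames(tab$intensities),
                rownames(shed$truth$substrates)[shed$truth$substrates[, "LPS"]])[1]
  jx <- tab$samples$condition == "LPS" & !tab$samples$inhibitor
  jy <- tab$samples$condition == "LPS" & tab$samples$inhibitor
  expect_equal(mean(tab$intensities[sub, jx]) / mean(tab$intensities[sub, jy]), 2,
               tolerance = 1e-12)
  expect_equal(mean(tab$intensities[bg, jx]), mean(tab$intensities[bg, jy]),
               tolerance = 1e-12)
  expect_error(sim_config(inhibitor_effect = 1), "inhibitor_effect")
})

test_that("noisy shedding log2 ratios average to the planted effect", {
  cfg <- sim_config(seed = 42, n_proteins = 1000, noise_cv = 0.1,
                    dropout_rate = 0, inhibitor_effect = 2,
                    class_fractions = c(shed_membrane = 0.5, background = 0.5))
  shed <- simulate_shedding_experiment(cfg)
  tab <- shed$table
  subs <- rownames(shed$truth$substrates)[shed$truth$substrates[, "TNFA"]]
  expect_gte(length(subs), 500L)
  jx <- tab$samples$condition == "TNFA" & !tab$samples$inhibitor
  jy <- tab$samples$condition == "TNFA" & tab$samples$inhibitor
  lr <- log2(rowMeans(tab$intensities[subs, jx]) /
             rowMeans(tab$intensities[subs, jy]))
  expect_lt(abs(mean(lr) - 1), 0.05)
})

test_that("simulated peptides stay in bounds with per-residue truth labels", {
  cfg <- sim_config(seed = 9, n_proteins = 120,
                    class_fractions = c(shed_membrane = 0.25, background = 0.75))
  truth <- simulation_truth(cfg)
  pep <- simulate_peptides(truth, peptides_per_protein = 12, seed = 4)
  topo <- truth$topology
  expect_true(all(pep$start >= 1))
  L <- topo$length[match(pep$protein, topo$accession)]
  expect_true(all(pep$end <= L))
  expect_true(all(pep$end - pep$start + 1 >= 7 & pep$end - pep$start + 1 <= 30))
  ok <- vapply(seq_len(nrow(pep)), function(i) {
    tr <- topo[topo$accession == pep$protein[i], ]
    spans <- matrix(as.integer(unlist(strsplit(strsplit(tr$tm_spans, ";")[[1]],
                                               "-"))), ncol = 2, byrow = TRUE)
    domain_oracle(tr$length, tr$orientation, spans, pep$start[i],
                  pep$end[i]) == pep$domain_truth[i]
  }, TRUE)
  expect_true(all(ok))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(class_fractions = c(background = 0.9)), "sum to 1")
  expect_error(sim_config(cell_times_min = c(15, 30)), "start at 0")
  expect_error(sim_config(cell_times_min = c(0, 30, 30)), "strictly increasing")
  expect_error(sim_config(dropout_rate = 1), "dropout")
  expect_error(sim_config(noise_cv = -0.1), "noise_cv")
  expect_error(sim_config(spikein_level = 0), "spikein_level")
  expect_error(sim_config(n_replicates_cell = 0), "replicate")
})

test_that("written simulations are read back equal through the report dialect", {
  cfg <- sim_config(seed = 8, n_proteins = 40)
  d <- withr::local_tempdir()
  paths <- write_simulation(cfg, d)
  sup <- simulate_secretome(cfg)
  back <- read_dia_report(paths$report_secretome,
                          read_samples(paths$samples_secretome),
                          spikein_id = sup$table$spikein_id)
  expect_equal(back$intensities[rownames(sup$table$intensities), ],
               sup$table$intensities, tolerance = 1e-12)
})
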