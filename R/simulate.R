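#' Simulation configuration
#'
#' Defines the synthetic study: a stimulated-neutrophil time course with a
#' cellular compartment (4 conditions x 6 time points x replicates), a
#' secretome compartment (control + 3 stimuli x 6 time points, one sample
#' each, with a constant-amount spike-in standard), and a sheddase-inhibitor
#' experiment (stimulus with/without inhibitor, 3 replicates per arm). Every
#' protein carries exactly one planted class label, the downstream ground
#' truth.
#'
#' Class templates: released proteins follow a saturating supernatant
#' fold-change curve FC(t) = 1 + (A - 1) t / (t + t_half) with
#' `t_half = release_halftime_min`; cellular depletion declines linearly from
#' 100% of baseline to `depletion_floor`; induced proteins rise linearly to
#' `induction_peak`; background stays flat. Noise is multiplicative
#' log-normal with coefficient of variation `noise_cv`; missingness is
#' completely at random at `dropout_rate`.
#'
#' @param seed Integer RNG seed; all outputs are reproducible from it.
#' @param n_proteins Number of simulated proteins.
#' @param class_fractions Named fractions over
#'   `released_with_depletion`, `released_without_depletion`,
#'   `induced_cellular`, `shed_membrane`, `background`; must sum to 1.
#' @param noise_cv CV of the multiplicative log-normal noise (>= 0).
#' @param dropout_rate Fraction of intensities set missing, in \[0, 1).
#' @param n_replicates_cell Biological replicates per cell condition/time.
#' @param cell_times_min,secretome_times_min Ordered minutes, starting at 0.
#' @param release_amplitude Peak supernatant fold-change of released proteins.
#' @param release_halftime_min Half-saturation time of the release curve.
#' @param depletion_floor Final cellular relative percentage of depleted
#'   proteins (percent of the 0-min baseline).
#' @param induction_peak Final cellular relative percentage of induced
#'   proteins.
#' @param spikein_level Spike-in intensity before run-level scaling (> 0).
#' @param run_scale_range Interval of multiplicative run-level distortions
#'   applied to every secretome run (what spike-in normalization corrects).
#' @param inhibitor_effect Fold reduction of the soluble level of shed
#'   substrates under the MMP/ADAM inhibitor (> 1).
#' @param canonical_fraction Fraction of planted released proteins annotated
#'   with granule-subset membership (the canonical arm of the catalog).
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_proteins = 1000L,
                       class_fractions = c(released_with_depletion = 0.10,
                                           released_without_depletion = 0.05,
                                           induced_cellular = 0.05,
                                           shed_membrane = 0.02,
                                           background = 0.78),
                       noise_cv = 0.2,
                       dropout_rate = 0.1,
                       n_replicates_cell = 3L,
                       cell_times_min = c(0L, 15L, 30L, 60L, 120L, 240L),
                       secretome_times_min = c(0L, 5L, 15L, 30L, 60L, 120L),
                       release_amplitude = 3,
                       release_halftime_min = 30,
                       depletion_floor = 40,
                       induction_peak = 300,
                       spikein_level = 1e6,
                       run_scale_range = c(0.8, 1.25),
                       inhibitor_effect = 2,
                       canonical_fraction = 0.5) {
  classes <- c("released_with_depletion", "released_without_depletion",
               "induced_cellular", "shed_membrane", "background")
  cf <- numeric(length(classes)); names(cf) <- classes
  cf[names(class_fractions)] <- class_fractions
  bad <- setdiff(names(class_fractions), classes)
  if (length(bad)) stop("unknown class(es): ", paste(bad, collapse = ", "))
  if (abs(sum(cf) - 1) > 1e-9) stop("class fractions must sum to 1")
  for (tv in list(cell_times_min, secretome_times_min)) {
    if (length(tv) == 0) stop("empty time grid")
    if (tv[1] != 0 || any(diff(tv) <= 0)) {
      stop("time grids must start at 0 and be strictly increasing")
    }
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  if (n_replicates_cell < 1) stop("need at least one cellular replicate")
  if (spikein_level <= 0) stop("spikein_level must be positive")
  if (inhibitor_effect <= 1) stop("inhibitor_effect must exceed 1 (substrates must be reduced)")
  if (length(run_scale_range) != 2 || any(run_scale_range <= 0) ||
      diff(run_scale_range) < 0) stop("invalid run_scale_range")
  structure(list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
                 class_fractions = cf, noise_cv = noise_cv,
                 dropout_rate = dropout_rate,
                 n_replicates_cell = as.integer(n_replicates_cell),
                 cell_times_min = as.integer(cell_times_min),
                 secretome_times_min = as.integer(secretome_times_min),
                 release_amplitude = release_amplitude,
                 release_halftime_min = release_halftime_min,
                 depletion_floor = depletion_floor,
                 induction_peak = induction_peak,
                 spikein_level = spikein_level,
                 run_scale_range = run_scale_range,
                 inhibitor_effect = inhibitor_effect,
                 canonical_fraction = canonical_fraction),
            class = "sim_config")
}

.SIM_STIMULI <- c("LPS", "TNFA", "PMA")
.SPIKEIN_ACC <- "SPIKEIN_PROTA"

# lognormal noise factors with unit median and stated CV
.noise_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  exp(stats::rnorm(n, 0, sqrt(log(1 + cv^2))))
}

.apply_dropout <- function(m, rate, keep_rows = character(0)) {
  if (rate == 0) return(m)
  drop <- matrix(stats::runif(length(m)) < rate, nrow(m))
  drop[rownames(m) %in% keep_rows, ] <- FALSE
  m[drop] <- NA_real_
  m
}

# integer class counts that sum exactly to n (cumulative rounding)
.class_counts <- function(fracs, n) {
  cum <- round(cumsum(fracs) * n)
  cnt <- diff(c(0L, cum))
  names(cnt) <- names(fracs)
  cnt
}

#' Planted ground truth for a simulation
#'
#' Deterministic in `config$seed`; [simulate_cell_proteome],
#' [simulate_secretome] and [simulate_shedding_experiment] all derive the
#' same truth from the same config, so their protein labels agree.
#'
#' @param config A [sim_config].
#' @return A list of class `sim_truth` with elements `classes` (named class
#'   label per protein), `annotations` (a `protein_annotation` table),
#'   `topology` (single-pass membrane models for shed proteins),
#'   `substrates` (protein x stimulus logical matrix), `base` (baseline
#'   intensities) and `config`.
#' @export
simulation_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  prot <- sprintf("P%04d", seq_len(n))
  cnt <- .class_counts(config$class_fractions, n)
  classes <- sample(rep(names(cnt), cnt))
  names(classes) <- prot

  base <- stats::rlnorm(n, meanlog = log(1e6), sdlog = 1)
  names(base) <- prot

  ann <- data.frame(accession = prot, granule_subsets = "",
                    exclusion_class = "none", is_membrane = FALSE,
                    signal_peptide = FALSE, nonclassical = FALSE,
                    transmembrane = FALSE, vesicle = FALSE,
                    stringsAsFactors = FALSE)
  released <- classes %in% c("released_with_depletion", "released_without_depletion")
  # canonical arm: granule-subset membership, occasionally in two subsets
  canon <- released & (stats::runif(n) < config$canonical_fraction)
  ann$granule_subsets[canon] <- vapply(which(canon), function(i) {
    k <- if (stats::runif(1) < 0.25) 2L else 1L
    paste(sort(sample(.GRANULE_SUBSETS, k)), collapse = ";")
  }, "")
  # shed membrane proteins sit in granule/secretory-vesicle membranes
  shed <- classes == "shed_membrane"
  ann$granule_subsets[shed] <- sample(c("SV", "GG", "SG"), sum(shed), replace = TRUE)
  ann$is_membrane[shed] <- TRUE
  # a slice of the background is membrane but not a sheddase substrate
  bg <- classes == "background"
  ann$is_membrane[bg & stats::runif(n) < 0.05] <- TRUE
  # excluded housekeeping classes live in the background only
  excl_pool <- which(bg & !ann$is_membrane)
  n_excl <- min(length(excl_pool), round(0.06 * n))
  if (n_excl > 0) {
    pick <- sample(excl_pool, n_excl)
    ann$exclusion_class[pick] <- sample(c("mitochondrial", "ribosomal", "histone"),
                                        n_excl, replace = TRUE)
  }
  # secretion-route predictions for released proteins (per-route rates match
  # the published per-route prediction fractions for non-canonical proteins)
  rates <- c(signal_peptide = 0.204, nonclassical = 0.331,
             transmembrane = 0.107, vesicle = 0.591)
  for (f in names(rates)) {
    ann[[f]][released] <- stats::runif(sum(released)) < rates[[f]]
  }
  ann$transmembrane[shed] <- TRUE

  # single-pass topology models for shed membrane proteins
  shed_ids <- prot[shed]
  len <- sample(200:800, length(shed_ids), replace = TRUE)
  tm_start <- vapply(len, function(L) sample(seq(30L, L - 50L), 1L), 1L)
  topo <- data.frame(accession = shed_ids, length = len,
                     orientation = sample(c("type_I", "type_II"),
                                          length(shed_ids), replace = TRUE),
                     tm_spans = sprintf("%d-%d", tm_start, tm_start + 20L),
                     stringsAsFactors = FALSE)

  subs <- matrix(FALSE, n, length(.SIM_STIMULI),
                 dimnames = list(prot, .SIM_STIMULI))
  subs[shed, ] <- TRUE

  structure(list(classes = classes, annotations = as_annotations(ann),
                 topology = topo, substrates = subs, base = base,
                 config = config),
            class = "sim_truth")
}

#' Accessions of planted released proteins
#' @param truth A `sim_truth`.
#' @return Character vector of released (with or without depletion) proteins.
#' @export
released_truth <- function(truth) {
  names(truth$classes)[truth$classes %in%
    c("released_with_depletion", "released_without_depletion")]
}

# cellular relative-percentage template (percent of 0-min baseline)
.cell_template <- function(class, times, config) {
  tmax <- max(times)
  switch(class,
    released_with_depletion = 100 - (100 - config$depletion_floor) * times / tmax,
    induced_cellular = 100 + (config$induction_peak - 100) * times / tmax,
    rep(100, length(times)))
}

# supernatant fold-change template vs control
.secretome_template <- function(class, times, config) {
  if (class %in% c("released_with_depletion", "released_without_depletion")) {
    1 + (config$release_amplitude - 1) * times / (times + config$release_halftime_min)
  } else rep(1, length(times))
}

#' Simulate the cellular time-course proteome
#'
#' Conditions are CONTROL plus the three inflammatory stimuli; each condition
#' is measured at every cellular time point with `n_replicates_cell`
#' replicates. Depleted classes decline monotonically from 100% of baseline
#' toward `depletion_floor` under the stimuli; induced classes rise; the
#' background and all CONTROL samples stay flat.
#'
#' @param config A [sim_config].
#' @return List with elements `table` (a [quant_table]) and `truth`
#'   (a `sim_truth`).
#' @export
simulate_cell_proteome <- function(config) {
  truth <- simulation_truth(config)
  set.seed(config$seed + 1L)
  times <- config$cell_times_min
  conds <- c("CONTROL", .SIM_STIMULI)
  grid <- expand.grid(replicate = seq_len(config$n_replicates_cell),
                      time_min = times, condition = conds,
                      stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("cell_%s_t%03d_r%d", grid$condition, grid$time_min,
                        grid$replicate),
    compartment = "cell", condition = grid$condition,
    time_min = grid$time_min, replicate = grid$replicate,
    stringsAsFactors = FALSE)
  prot <- names(truth$classes)
  m <- matrix(NA_real_, length(prot), nrow(samples),
              dimnames = list(prot, samples$sample_id))
  pct <- matrix(100, length(prot), length(times))
  for (cl in unique(truth$classes)) {
    pct[truth$classes == cl, ] <- rep(.cell_template(cl, times, config),
                                      each = sum(truth$classes == cl))
  }
  for (j in seq_len(nrow(samples))) {
    ti <- match(samples$time_min[j], times)
    tmpl <- if (samples$condition[j] == "CONTROL") rep(100, length(prot)) else pct[, ti]
    m[, j] <- truth$base * tmpl / 100 * .noise_factors(length(prot), config$noise_cv)
  }
  m <- .apply_dropout(m, config$dropout_rate)
  list(table = quant_table(m, samples), truth = truth)
}

#' Simulate the conditioned-media secretome
#'
#' One supernatant sample per condition (CONTROL, LPS, TNFA, PMA) and time
#' point. Released classes rise toward `release_amplitude`-fold over control
#' following the saturating release curve; a spike-in row is added at
#' `spikein_level` times a per-run scale drawn uniformly from
#' `run_scale_range` (the scale multiplies the whole run, which is what
#' spike-in normalization corrects). The spike-in itself carries no
#' biological noise and is never dropped out.
#'
#' @param config A [sim_config].
#' @return List with elements `table` (a [quant_table] whose `spikein_id`
#'   names the standard row) and `truth`.
#' @export
simulate_secretome <- function(config) {
  truth <- simulation_truth(config)
  set.seed(config$seed + 2L)
  times <- config$secretome_times_min
  conds <- c("CONTROL", .SIM_STIMULI)
  grid <- expand.grid(time_min = times, condition = conds,
                      stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("sup_%s_t%03d", grid$condition, grid$time_min),
    compartment = "supernatant", condition = grid$condition,
    time_min = grid$time_min, replicate = 1L, stringsAsFactors = FALSE)
  prot <- names(truth$classes)
  scales <- stats::runif(nrow(samples), config$run_scale_range[1],
                         config$run_scale_range[2])
  fc <- matrix(1, length(prot), length(times))
  for (cl in unique(truth$classes)) {
    fc[truth$classes == cl, ] <- rep(.secretome_template(cl, times, config),
                                     each = sum(truth$classes == cl))
  }
  m <- matrix(NA_real_, length(prot), nrow(samples),
              dimnames = list(prot, samples$sample_id))
  sup_base <- truth$base / 50  # conditioned media carry far less material
  for (j in seq_len(nrow(samples))) {
    ti <- match(samples$time_min[j], times)
    tmpl <- if (samples$condition[j] == "CONTROL") rep(1, length(prot)) else fc[, ti]
    m[, j] <- sup_base * tmpl * scales[j] *
      .noise_factors(length(prot), config$noise_cv)
  }
  m <- .apply_dropout(m, config$dropout_rate)
  m <- rbind(m, matrix(config$spikein_level * scales, 1,
                       dimnames = list(.SPIKEIN_ACC, NULL)))
  list(table = quant_table(m, samples, spikein_id = .SPIKEIN_ACC),
       truth = truth)
}

#' Simulate the sheddase-inhibitor experiment
#'
#' For each stimulus, two arms (stimulus alone and stimulus plus the broad
#' MMP/ADAM inhibitor) with three replicates of the 1-h conditioned media.
#' Planted substrates are reduced `inhibitor_effect`-fold under the
#' inhibitor; all other proteins are unchanged in expectation.
#'
#' @param config A [sim_config].
#' @param n_replicates Replicates per arm (default 3).
#' @return List with elements `table` (a [quant_table] whose sample metadata
#'   carries the `inhibitor` flag) and `truth`.
#' @export
simulate_shedding_experiment <- function(config, n_replicates = 3L) {
  truth <- simulation_truth(config)
  set.seed(config$seed + 3L)
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      inhibitor = c(FALSE, TRUE), condition = .SIM_STIMULI,
                      stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("shed_%s_%s_r%d", grid$condition,
                        ifelse(grid$inhibitor, "gm", "veh"), grid$replicate),
    compartment = "supernatant", condition = grid$condition, time_min = 60L,
    replicate = grid$replicate, inhibitor = grid$inhibitor,
    stringsAsFactors = FALSE)
  prot <- names(truth$classes)
  m <- matrix(NA_real_, length(prot), nrow(samples),
              dimnames = list(prot, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    red <- ifelse(samples$inhibitor[j] & truth$substrates[, samples$condition[j]],
                  config$inhibitor_effect, 1)
    m[, j] <- truth$base / red * .noise_factors(length(prot), config$noise_cv)
  }
  m <- .apply_dropout(m, config$dropout_rate)
  list(table = quant_table(m, samples), truth = truth)
}

# residue-level domain classes for one model; used to label peptide truth
.residue_classes <- function(length, orientation, spans) {
  cls <- rep(NA_character_, length)
  first <- min(spans[, 1]); last <- max(spans[, 2])
  n_side <- if (orientation == "type_I") "extracellular" else "intracellular"
  c_side <- if (orientation == "type_I") "intracellular" else "extracellular"
  if (first > 1) cls[1:(first - 1)] <- n_side
  if (last < length) cls[(last + 1):length] <- c_side
  for (k in seq_len(nrow(spans))) cls[spans[k, 1]:spans[k, 2]] <- "transmembrane"
  cls[is.na(cls)] <- "loop"  # interior loops of multi-pass models
  cls
}

.parse_spans <- function(s) {
  pieces <- strsplit(s, ";", fixed = TRUE)[[1]]
  sp <- t(vapply(strsplit(pieces, "-", fixed = TRUE),
                 function(x) as.integer(x), integer(2)))
  sp[order(sp[, 1]), , drop = FALSE]
}

#' Simulate MS-detected peptides over membrane protein models
#'
#' Draws tryptic-scale peptides (7-30 residues, 1-based inclusive
#' coordinates) uniformly over each membrane protein in the truth's topology
#' table, and records each peptide's true domain by per-residue
#' classification: a peptide whose residues all fall in one of
#' extracellular / transmembrane / intracellular gets that label, anything
#' crossing a boundary (or touching an interior loop) is `spanning`.
#'
#' @param truth A `sim_truth` with topology models.
#' @param peptides_per_protein Peptides drawn per protein.
#' @param seed RNG seed.
#' @return Data frame with `protein`, `start`, `end`, `domain_truth`.
#' @export
simulate_peptides <- function(truth, peptides_per_protein = 10L, seed = 1L) {
  topo <- truth$topology
  if (nrow(topo) == 0) stop("no topology models in ground truth")
  set.seed(seed)
  out <- vector("list", nrow(topo))
  for (i in seq_len(nrow(topo))) {
    L <- topo$length[i]
    if (L < 7) stop("protein ", topo$accession[i], " shorter than a peptide")
    spans <- .parse_spans(topo$tm_spans[i])
    cls <- .residue_classes(L, topo$orientation[i], spans)
    len <- sample(7:30, peptides_per_protein, replace = TRUE)
    len <- pmin(len, L)
    start <- vapply(len, function(l) sample.int(L - l + 1L, 1L), 1L)
    end <- start + len - 1L
    dom <- vapply(seq_along(start), function(k) {
      u <- unique(cls[start[k]:end[k]])
      if (length(u) == 1L && u != "loop") u else "spanning"
    }, "")
    out[[i]] <- data.frame(protein = topo$accession[i], start = start,
                           end = end, domain_truth = dom,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Write a simulated study to disk in pipeline input formats
#'
#' Emits the long DIA-NN report dialect (`Protein.Group`, `Run`,
#' `PG.MaxLFQ`; missing intensities are omitted rows) for each compartment,
#' plus sample metadata, annotation, topology, peptide and ground-truth
#' label TSVs.
#'
#' @param config A [sim_config].
#' @param out_dir Output directory.
#' @param peptides_per_protein Peptides per membrane protein.
#' @return Invisibly, the named list of written file paths.
#' @export
write_simulation <- function(config, out_dir, peptides_per_protein = 10L) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cell <- simulate_cell_proteome(config)
  sup <- simulate_secretome(config)
  shed <- simulate_shedding_experiment(config)
  pep <- simulate_peptides(sup$truth, peptides_per_protein,
                           seed = config$seed + 4L)
  long <- function(tab) {
    m <- tab$intensities
    df <- data.frame(Protein.Group = rownames(m)[row(m)],
                     Run = colnames(m)[col(m)],
                     PG.MaxLFQ = as.vector(m), stringsAsFactors = FALSE)
    df <- df[!is.na(df$PG.MaxLFQ), , drop = FALSE]
    df[order(df$Protein.Group, df$Run), , drop = FALSE]
  }
  paths <- list(
    report_cell = file.path(out_dir, "report_cell.tsv"),
    report_secretome = file.path(out_dir, "report_secretome.tsv"),
    report_shedding = file.path(out_dir, "report_shedding.tsv"),
    samples_cell = file.path(out_dir, "samples_cell.tsv"),
    samples_secretome = file.path(out_dir, "samples_secretome.tsv"),
    samples_shedding = file.path(out_dir, "samples_shedding.tsv"),
    annotations = file.path(out_dir, "annotations.tsv"),
    topology = file.path(out_dir, "topology.tsv"),
    peptides = file.path(out_dir, "peptides.tsv"),
    truth = file.path(out_dir, "truth.tsv"))
  .write_tsv(long(cell$table), paths$report_cell)
  .write_tsv(long(sup$table), paths$report_secretome)
  .write_tsv(long(shed$table), paths$report_shedding)
  .write_tsv(cell$table$samples, paths$samples_cell)
  .write_tsv(sup$table$samples, paths$samples_secretome)
  .write_tsv(shed$table$samples, paths$samples_shedding)
  .write_tsv(as.data.frame(sup$truth$annotations), paths$annotations)
  .write_tsv(sup$truth$topology, paths$topology)
  .write_tsv(pep, paths$peptides)
  .write_tsv(data.frame(accession = names(sup$truth$classes),
                        class = unname(sup$truth$classes),
                        stringsAsFactors = FALSE), paths$truth)
  invisible(paths)
}
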