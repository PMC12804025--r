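#' Default pipeline run configuration
#'
#' A flat list of every tunable the pipeline exposes. Thresholds default to
#' the analysis' printed values: release rule FC > 1.5 with slope > 0,
#' differential screen at adjusted p <= 0.01 and |FC| >= 1.5, conserved core
#' set at adjusted p < 0.05, sheddase substrates at p < 0.05 with
#' log2 FC > 0.6. Pattern-labelling deltas and the kinetic-similarity
#' threshold are this package's documented stand-ins for visual judgements.
#'
#' @param seed Master seed; every stochastic stage derives from it.
#' @param sim A [sim_config] used when `inputs` is `NULL` (synthetic mode).
#' @param inputs Optional named list of file paths (as written by
#'   [write_simulation]) to run from disk instead of simulating.
#' @param ... Overrides for any configuration entry.
#' @return List of class `run_config`.
#' @export
default_run_config <- function(seed = 1L, sim = NULL, inputs = NULL, ...) {
  cfg <- list(seed = as.integer(seed), sim = sim, inputs = inputs,
              fc_threshold = 1.5, slope_min = 0, alpha_de = 0.01,
              alpha_core = 0.05, shed_p = 0.05, shed_log2fc = 0.6,
              depletion_delta = 20, induction_delta = 50, r_threshold = 0.8,
              c_range = 2:6, fuzzifier = 2, cluster_condition = "PMA",
              control_condition = "CONTROL")
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  if (is.null(cfg$sim)) cfg$sim <- sim_config(seed = cfg$seed)
  stopifnot(cfg$fc_threshold > 0, cfg$shed_p > 0, cfg$shed_log2fc > 0,
            cfg$alpha_de > 0, cfg$alpha_core > 0)
  structure(cfg, class = "run_config")
}

#' Read a flat key=value run configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Numeric values are
#' parsed as numbers, `true`/`false` as logicals, comma-separated values as
#' vectors; keys prefixed `input.` populate the `inputs` path list.
#'
#' @param path Configuration file.
#' @param ... Further overrides, applied after the file.
#' @return List of class `run_config`.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lines[vapply(kv, length, 0L) != 2L]
  if (length(bad)) stop("malformed config line: ", bad[1])
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- lapply(trimws(vapply(kv, `[`, "", 2)), function(v) {
    parts <- trimws(strsplit(v, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) return(num)
    if (all(tolower(parts) %in% c("true", "false"))) {
      return(tolower(parts) == "true")
    }
    if (length(parts) == 1) parts else parts
  })
  names(vals) <- keys
  inputs <- vals[startsWith(keys, "input.")]
  names(inputs) <- sub("^input\\.", "", names(inputs))
  vals <- vals[!startsWith(keys, "input.")]
  args <- c(vals, if (length(inputs)) list(inputs = inputs), list(...))
  do.call(default_run_config, args)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> normalize -> release -> cluster ->
#' integrate -> shed -> report, writing every module's output table plus a
#' run manifest under `out_dir`. Re-running with the same configuration
#' reproduces byte-identical files; any stage failure aborts with the stage
#' name and cause.
#'
#' @param config A `run_config` ([default_run_config]/[read_run_config]).
#' @param out_dir Output directory.
#' @return Invisibly, a list with the main results (`catalog`, `patterns`,
#'   `clusters`, `shedding`, `manifest`, ...).
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stages <- character(0)
  done <- function(s) stages <<- c(stages, s)

  dat <- .stage("simulate", {
    if (is.null(config$inputs)) {
      cell <- simulate_cell_proteome(config$sim)
      sup <- simulate_secretome(config$sim)
      shed <- simulate_shedding_experiment(config$sim)
      pep <- simulate_peptides(sup$truth, seed = config$seed + 4L)
      list(cell = cell$table, sup = sup$table, shed = shed$table,
           peptides = pep, annotations = sup$truth$annotations,
           topology = sup$truth$topology, digests = NULL)
    } else {
      paths <- config$inputs
      need <- c("report_cell", "report_secretome", "report_shedding",
                "samples_cell", "samples_secretome", "samples_shedding",
                "annotations", "topology", "peptides")
      for (k in need) {
        if (is.null(paths[[k]]) || !file.exists(paths[[k]])) {
          stop("required input '", k, "' missing: ",
               if (is.null(paths[[k]])) "not configured" else paths[[k]])
        }
      }
      list(cell = read_dia_report(paths$report_cell,
                                  read_samples(paths$samples_cell)),
           sup = read_dia_report(paths$report_secretome,
                                 read_samples(paths$samples_secretome),
                                 spikein_id = .SPIKEIN_ACC),
           shed = read_dia_report(paths$report_shedding,
                                  read_samples(paths$samples_shedding)),
           peptides = utils::read.delim(paths$peptides,
                                        stringsAsFactors = FALSE),
           annotations = read_annotations(paths$annotations),
           topology = utils::read.delim(paths$topology,
                                        stringsAsFactors = FALSE),
           digests = tools::md5sum(unlist(paths)))
    }
  })
  done("simulate")

  sup <- .stage("normalize", {
    s <- median_normalize(dat$sup)
    if (!is.null(s$spikein_id)) s <- spikein_normalize(s) else s
  })
  done("normalize")

  stimuli <- setdiff(unique(sup$samples$condition), config$control_condition)
  rel <- .stage("release", {
    calls <- release_screen(sup, stimuli, config$control_condition,
                            dat$annotations, config$fc_threshold,
                            config$slope_min)
    catalog <- combine_conditions(calls, dat$annotations)
    traj <- lapply(stimuli, function(cc)
      fold_change_timecourse(sup, cc, config$control_condition))
    names(traj) <- stimuli
    tmax <- max(dat$cell$samples$time_min)
    de_final <- lapply(stimuli, function(cc)
      differential_test(dat$cell, cc, tmax, config$control_condition,
                        alpha = config$alpha_de,
                        fc_threshold = config$fc_threshold))
    names(de_final) <- stimuli
    list(calls = calls, catalog = catalog, traj = traj,
         subsets = summarize_granule_subsets(catalog, dat$annotations),
         level2h = release_level_2h(traj, catalog),
         routes = aggregate_secretion_routes(catalog, dat$annotations),
         core = consistent_core_set(de_final, alpha = config$alpha_core))
  })
  done("release")

  clus <- .stage("cluster", {
    cluster_condition(dat$cell, config$cluster_condition,
                      config$control_condition, alpha = config$alpha_de,
                      fc_threshold = config$fc_threshold,
                      c_range = config$c_range, m = config$fuzzifier,
                      seed = config$seed)
  })
  done("cluster")

  integ <- .stage("integrate", {
    pat <- do.call(rbind, lapply(stimuli, function(cc)
      label_patterns(relative_percentage(dat$cell, cc), rel$calls[[cc]],
                     config$depletion_delta, config$induction_delta)))
    # synthetic marker panels: canonical catalog proteins per subset
    canon <- rel$catalog$protein[rel$catalog$class == "canonical_granule"]
    ann <- annotation_for(dat$annotations, canon)
    mk <- do.call(rbind, lapply(.GRANULE_SUBSETS, function(s) {
      hits <- canon[vapply(strsplit(ann$granule_subsets, ";"), function(x)
        s %in% x, TRUE)]
      if (!length(hits)) return(NULL)
      data.frame(subset = s, marker = utils::head(hits, 5),
                 stringsAsFactors = FALSE)
    }))
    kin <- if (!is.null(mk) && length(stimuli)) {
      m <- trajectory_matrix(rel$traj[[stimuli[1]]])
      kinetic_similarity(m[stats::complete.cases(m), , drop = FALSE], mk,
                         config$r_threshold)
    }
    list(patterns = pat, kinetics = kin, markers = mk)
  })
  done("integrate")

  shed <- .stage("shed", {
    membrane <- dat$annotations$accession[dat$annotations$is_membrane]
    shed_stimuli <- intersect(stimuli, unique(dat$shed$samples$condition))
    calls <- lapply(shed_stimuli, function(ss)
      call_substrates(dat$shed, membrane, ss, config$shed_p,
                      config$shed_log2fc))
    names(calls) <- shed_stimuli
    models <- lapply(seq_len(nrow(dat$topology)), function(i)
      topology_model(dat$topology$accession[i], dat$topology$length[i],
                     dat$topology$orientation[i], dat$topology$tm_spans[i]))
    names(models) <- dat$topology$accession
    pep <- dat$peptides[dat$peptides$protein %in% names(models), , drop = FALSE]
    pep$domain <- vapply(seq_len(nrow(pep)), function(i)
      assign_peptide_domain(models[[pep$protein[i]]], pep$start[i],
                            pep$end[i]), "")
    list(calls = calls, sensitivity = compare_conditions(calls),
         topology_calls = ectodomain_summary(pep), peptide_domains = pep)
  })
  done("shed")

  manifest <- .stage("report", {
    clusters_df <- data.frame(protein = rownames(clus$fit$membership),
                              cluster = clus$fit$cluster,
                              max_membership = apply(clus$fit$membership, 1, max),
                              stringsAsFactors = FALSE)
    out <- list(
      release_calls = do.call(rbind, rel$calls),
      release_catalog = as.data.frame(rel$catalog),
      release_level_2h = rel$level2h,
      route_summary = data.frame(route = names(rel$routes$route_fractions),
                                 fraction = unname(rel$routes$route_fractions)),
      core_set = rel$core,
      clusters = clusters_df,
      centroids = data.frame(cluster = rownames(clus$fit$centroids),
                             clus$fit$centroids, check.names = FALSE),
      patterns = integ$patterns,
      shedding_calls = do.call(rbind, shed$calls),
      sensitivity_matrix = shed$sensitivity,
      topology_calls = shed$topology_calls)
    if (!is.null(integ$kinetics)) out$kinetic_assignments <- integ$kinetics
    write_results(out, out_dir)
    man <- data.frame(stage = c(stages, "report"), status = "completed",
                      stringsAsFactors = FALSE)
    params <- data.frame(
      key = c("seed", "fc_threshold", "slope_min", "alpha_de", "alpha_core",
              "shed_p", "shed_log2fc", "depletion_delta", "induction_delta",
              "r_threshold", "fuzzifier", "selected_clusters"),
      value = c(config$seed, config$fc_threshold, config$slope_min,
                config$alpha_de, config$alpha_core, config$shed_p,
                config$shed_log2fc, config$depletion_delta,
                config$induction_delta, config$r_threshold, config$fuzzifier,
                clus$selection$c),
      stringsAsFactors = FALSE)
    .write_tsv(man, file.path(out_dir, "manifest.tsv"))
    .write_tsv(params, file.path(out_dir, "run_params.tsv"))
    if (!is.null(dat$digests)) {
      .write_tsv(data.frame(file = names(dat$digests),
                            md5 = unname(dat$digests),
                            stringsAsFactors = FALSE),
                 file.path(out_dir, "input_digests.tsv"))
    }
    man
  })

  invisible(list(manifest = manifest, catalog = rel$catalog,
                 calls = rel$calls, routes = rel$routes,
                 subsets = rel$subsets, core = rel$core,
                 clustering = clus, patterns = integ$patterns,
                 kinetics = integ$kinetics, shedding = shed,
                 out_dir = out_dir))
}
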