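#' Ordinary least-squares slope of a trajectory
#'
#' Slope of value versus time in hours, missing points dropped. Fewer than
#' two usable points gives `NA` (the protein is flagged rather than erroring).
#'
#' @param time_min Time points in minutes.
#' @param value Trajectory values (fold changes or percentages).
#' @return Slope per hour, or `NA` if undefined.
#' @export
fit_linear_trend <- function(time_min, value) {
  ok <- !is.na(value) & !is.na(time_min)
  if (sum(ok) < 2) return(NA_real_)
  h <- time_min[ok] / 60
  if (length(unique(h)) < 2) return(NA_real_)
  unname(stats::lm.fit(cbind(1, h), value[ok])$coefficients[2])
}

# per-protein slope + max observed FC (t > 0) for one condition's FC set
.release_stats <- function(traj) {
  m <- trajectory_matrix(traj)
  times <- as.integer(colnames(m))
  slope <- apply(m, 1, function(v) fit_linear_trend(times, v))
  post <- m[, times > 0, drop = FALSE]
  max_fc <- suppressWarnings(apply(post, 1, max, na.rm = TRUE))
  max_fc[!is.finite(max_fc)] <- NA_real_
  data.frame(protein = rownames(m), condition = traj$condition[1],
             slope = slope, max_fc = max_fc, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Classify released proteins in one condition
#'
#' The release rule: (1) the OLS slope of the fold-change trajectory is
#' strictly positive and (2) the observed fold change exceeds `fc_threshold`
#' at one or more post-baseline time points. Proteins annotated as
#' mitochondrial, ribosomal or histone related are then excluded; exclusion
#' is applied after the threshold rule and every call carries its reason.
#'
#' @param calls Data frame with `protein`, `condition`, `slope`, `max_fc`
#'   (from [release_screen] internals, or hand-built).
#' @param annotations Optional `protein_annotation` table; unlisted
#'   accessions default to `exclusion_class = "none"`.
#' @param fc_threshold Fold-change threshold (default 1.5, strict `>`).
#' @param slope_min Slope threshold (default 0, strict `>`).
#' @return The calls with added `excluded`, `reason` and `released` columns.
#' @export
classify_released <- function(calls, annotations = NULL, fc_threshold = 1.5,
                              slope_min = 0) {
  ann <- annotation_for(annotations, calls$protein)
  excl <- ann$exclusion_class != "none"
  pass <- !is.na(calls$slope) & calls$slope > slope_min &
    !is.na(calls$max_fc) & calls$max_fc > fc_threshold
  reason <- rep("", nrow(calls))
  reason[is.na(calls$slope)] <- "undefined_slope"
  reason[excl] <- ann$exclusion_class[excl]
  calls$excluded <- excl
  calls$reason <- reason
  calls$released <- pass & !excl
  calls
}

#' Screen released proteins across conditions
#'
#' Runs [fold_change_timecourse] per stimulated condition, fits the linear
#' trend, applies the release rule and the exclusion screen.
#'
#' @param tab Secretome [quant_table] (normalized).
#' @param conditions Stimulated conditions (default the three inflammatory
#'   stimuli present in the table).
#' @param control_condition Control condition.
#' @param annotations Optional `protein_annotation` table.
#' @param fc_threshold,slope_min Release rule thresholds.
#' @return Named list of per-condition release-call data frames.
#' @export
release_screen <- function(tab, conditions = NULL,
                           control_condition = "CONTROL",
                           annotations = NULL, fc_threshold = 1.5,
                           slope_min = 0) {
  if (is.null(conditions)) {
    conditions <- setdiff(unique(tab$samples$condition), control_condition)
  }
  calls <- lapply(conditions, function(cond) {
    traj <- fold_change_timecourse(tab, cond, control_condition)
    classify_released(.release_stats(traj), annotations,
                      fc_threshold = fc_threshold, slope_min = slope_min)
  })
  names(calls) <- conditions
  calls
}

#' Combine per-condition release calls into a catalog
#'
#' The catalog is the set union of released proteins over conditions; each
#' member is classed canonical (non-empty granule-subset annotation) or
#' non-canonical (no previously reported granule membership).
#'
#' @param calls Named list of per-condition call data frames from
#'   [classify_released]/[release_screen].
#' @param annotations Optional `protein_annotation` table used for the
#'   canonical/non-canonical split.
#' @return A data frame of class `release_catalog`: `protein`, `class`
#'   (`canonical_granule` / `non_canonical`) and one logical
#'   `released_<condition>` column per input condition.
#' @export
combine_conditions <- function(calls, annotations = NULL) {
  stopifnot(length(calls) >= 1, !is.null(names(calls)))
  released_sets <- lapply(calls, function(d) d$protein[d$released])
  prot <- sort(unique(unlist(released_sets)))
  ann <- annotation_for(annotations, prot)
  cat <- data.frame(protein = prot,
                    class = ifelse(nzchar(ann$granule_subsets),
                                   "canonical_granule", "non_canonical"),
                    stringsAsFactors = FALSE)
  for (cond in names(calls)) {
    cat[[paste0("released_", cond)]] <- prot %in% released_sets[[cond]]
  }
  class(cat) <- c("release_catalog", "data.frame")
  cat
}

#' @export
print.release_catalog <- function(x, ...) {
  cat("release catalog:", nrow(x), "proteins (",
      sum(x$class == "canonical_granule"), "canonical granule,",
      sum(x$class == "non_canonical"), "non-canonical )\n")
  for (cc in grep("^released_", names(x), value = TRUE)) {
    cat(sprintf("  %-18s %d released\n", sub("released_", "", cc), sum(x[[cc]])))
  }
  invisible(x)
}

#' Granule-subset membership counts of the catalog's canonical arm
#'
#' Multi-membership is honored: a protein reported in two subsets counts in
#' both, so subset counts may sum to more than the canonical total.
#'
#' @param catalog A `release_catalog`.
#' @param annotations `protein_annotation` table with `granule_subsets`.
#' @return List with `subset_counts` (named counts over AG/SG/GG/SV) and
#'   `condition_counts` (canonical proteins released per condition).
#' @export
summarize_granule_subsets <- function(catalog, annotations = NULL) {
  canon <- catalog$protein[catalog$class == "canonical_granule"]
  ann <- annotation_for(annotations, canon)
  subsets <- strsplit(ann$granule_subsets, ";", fixed = TRUE)
  counts <- vapply(.GRANULE_SUBSETS, function(s)
    sum(vapply(subsets, function(x) s %in% x, TRUE)), 0L)
  cond_cols <- grep("^released_", names(catalog), value = TRUE)
  cond_counts <- vapply(cond_cols, function(cc)
    sum(catalog[[cc]] & catalog$class == "canonical_granule"), 0L)
  names(cond_counts) <- sub("released_", "", cond_cols)
  list(subset_counts = counts, condition_counts = cond_counts)
}

#' Release level at 2 h
#'
#' The fold change at 120 min per catalog protein and condition — the
#' longest secretome time point, used as the quantitative release level. A
#' missing 120-min point gives a missing entry.
#'
#' @param trajectories Named list (by condition) of fold-change trajectory
#'   data frames.
#' @param catalog A `release_catalog`.
#' @return Data frame `protein` x one `fc_2h_<condition>` column each.
#' @export
release_level_2h <- function(trajectories, catalog) {
  out <- data.frame(protein = catalog$protein, stringsAsFactors = FALSE)
  for (cond in names(trajectories)) {
    tr <- trajectories[[cond]]
    at2h <- tr[tr$time_min == 120L, , drop = FALSE]
    out[[paste0("fc_2h_", cond)]] <-
      at2h$value[match(catalog$protein, at2h$protein)]
  }
  out
}

#' Secretion-route summary of the non-canonical arm
#'
#' Aggregates external route predictions (classical signal peptide,
#' nonclassical secretion, transmembrane domain, vesicle evidence) over the
#' catalog's non-canonical proteins. A protein is predicted secreted when
#' any route flag is set; the headline percentage is rounded to the nearest
#' integer.
#'
#' @param catalog A `release_catalog` (its non-canonical arm is summarized).
#' @param annotations `protein_annotation` table with the route flags.
#' @return List with `n`, `n_secreted`, `percent_secreted`,
#'   `route_fractions` (named) and `secreted` (accessions).
#' @export
aggregate_secretion_routes <- function(catalog, annotations = NULL) {
  nc <- catalog$protein[catalog$class == "non_canonical"]
  ann <- annotation_for(annotations, nc)
  flags <- as.matrix(as.data.frame(ann)[, .ROUTE_FLAGS, drop = FALSE])
  any_route <- rowSums(flags) > 0
  list(n = length(nc), n_secreted = sum(any_route),
       percent_secreted = if (length(nc)) round(100 * sum(any_route) / length(nc)) else 0,
       route_fractions = if (length(nc)) colMeans(flags) else
         stats::setNames(rep(0, length(.ROUTE_FLAGS)), .ROUTE_FLAGS),
       secreted = nc[any_route])
}

#' Consistent core set across three conditions
#'
#' Proteins differentially abundant (adjusted p below `alpha`) in every
#' condition at the final time point with the same sign of log2 fold change
#' in all of them — the conserved response program shared by the stimuli.
#'
#' @param de_list Named list (by condition) of [differential_test] results
#'   at the final time point.
#' @param alpha Adjusted-p threshold (default 0.05, strict `<`).
#' @return Data frame `protein`, `direction` (`"up"`/`"down"`) plus the
#'   per-condition log2 fold changes.
#' @export
consistent_core_set <- function(de_list, alpha = 0.05) {
  stopifnot(length(de_list) >= 2)
  prot <- Reduce(intersect, lapply(de_list, function(d) d$protein))
  sig <- rep(TRUE, length(prot))
  lfc <- matrix(NA_real_, length(prot), length(de_list),
                dimnames = list(prot, names(de_list)))
  for (k in seq_along(de_list)) {
    d <- de_list[[k]]
    i <- match(prot, d$protein)
    sig <- sig & !is.na(d$adj_p[i]) & d$adj_p[i] < alpha
    lfc[, k] <- d$log2_fc[i]
  }
  same_sign <- apply(lfc, 1, function(v) all(v > 0) || all(v < 0))
  keep <- sig & same_sign & !apply(lfc, 1, anyNA)
  out <- data.frame(protein = prot[keep],
                    direction = ifelse(lfc[keep, 1] > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(lfc[keep, , drop = FALSE], row.names = NULL))
}
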