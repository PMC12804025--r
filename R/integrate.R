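#' Default granule marker proteins
#'
#' The marker panels used to build per-subset kinetic consensus profiles:
#' azurophilic granules (AZU1, MPO, ELANE, PRTN3), specific granules (LCN2,
#' LTF, MMP8, CHI3L1, CRISP3, TCN1, LRG1, OLFM4), gelatinase granules (FCN1,
#' FGL2, MMP9, CAMP, CHIT1, CD93, PGLYRP1) and secretory vesicles (FCGR3B,
#' CD14, ITGAM/CD11b). Editable: pass your own table anywhere a marker set
#' is accepted.
#'
#' @return Data frame with columns `subset` and `marker`.
#' @export
granule_markers <- function() {
  data.frame(
    subset = rep(c("AG", "SG", "GG", "SV"), c(4L, 8L, 7L, 3L)),
    marker = c("AZU1", "MPO", "ELANE", "PRTN3",
               "LCN2", "LTF", "MMP8", "CHI3L1", "CRISP3", "TCN1", "LRG1", "OLFM4",
               "FCN1", "FGL2", "MMP9", "CAMP", "CHIT1", "CD93", "PGLYRP1",
               "FCGR3B", "CD14", "ITGAM"),
    stringsAsFactors = FALSE)
}

#' Label the joint cellular/supernatant release pattern
#'
#' Combines a protein's cellular relative-percentage trajectory with its
#' supernatant release call into one of five patterns. Cellular depletion is
#' a strictly negative OLS slope together with a minimum at or below
#' `100 - depletion_delta` percent; cellular induction is a strictly
#' positive slope with a maximum at or above `100 + induction_delta`. The
#' decision table: released + depletion = `released_with_depletion`;
#' released without depletion = `released_without_depletion`; not released +
#' induction = `induced_cellular`; not released + depletion =
#' `depletion_only`; otherwise `unchanged`. The visual "concordant
#' decrease" of the source analysis has no numeric definition, so the
#' deltas are explicit, configurable stand-ins.
#'
#' @param cell_time_min,cell_value Cellular relative-percentage trajectory.
#' @param released Logical release flag for this protein/condition (from the
#'   secretome screen).
#' @param depletion_delta Percent drop below baseline counted as depletion
#'   (default 20).
#' @param induction_delta Percent rise above baseline counted as induction
#'   (default 50).
#' @return List with `label` and `evidence` (cell slope, min, max).
#' @export
label_pattern <- function(cell_time_min, cell_value, released,
                          depletion_delta = 20, induction_delta = 50) {
  ok <- !is.na(cell_value)
  if (sum(ok) < 2) {
    return(list(label = "unscored",
                evidence = c(slope = NA_real_, min = NA_real_, max = NA_real_)))
  }
  slope <- fit_linear_trend(cell_time_min, cell_value)
  vmin <- min(cell_value[ok]); vmax <- max(cell_value[ok])
  depleted <- slope < 0 && vmin <= 100 - depletion_delta
  induced <- slope > 0 && vmax >= 100 + induction_delta
  label <- if (isTRUE(released)) {
    if (depleted) "released_with_depletion" else "released_without_depletion"
  } else if (induced) "induced_cellular"
  else if (depleted) "depletion_only"
  else "unchanged"
  list(label = label, evidence = c(slope = slope, min = vmin, max = vmax))
}

#' Label release patterns for all proteins of one condition
#'
#' @param cell_traj Cellular relative-percentage trajectory data frame.
#' @param calls Release calls for the same condition ([classify_released]).
#' @param depletion_delta,induction_delta See [label_pattern].
#' @return Data frame `protein`, `condition`, `label`, `cell_slope`,
#'   `cell_min`, `cell_max`.
#' @export
label_patterns <- function(cell_traj, calls, depletion_delta = 20,
                           induction_delta = 50) {
  m <- trajectory_matrix(cell_traj)
  times <- as.integer(colnames(m))
  rel <- calls$released[match(rownames(m), calls$protein)]
  rel[is.na(rel)] <- FALSE
  res <- lapply(seq_len(nrow(m)), function(i)
    label_pattern(times, m[i, ], rel[i], depletion_delta, induction_delta))
  data.frame(protein = rownames(m), condition = cell_traj$condition[1],
             label = vapply(res, `[[`, "", "label"),
             cell_slope = vapply(res, function(r) r$evidence[["slope"]], 0),
             cell_min = vapply(res, function(r) r$evidence[["min"]], 0),
             cell_max = vapply(res, function(r) r$evidence[["max"]], 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assign candidate granule subsets by kinetic similarity
#'
#' Proteins sharing a granule subtype tend to share secretion kinetics. For
#' each subset a consensus profile is built as the mean of its markers'
#' z-scored supernatant fold-change trajectories; every protein is scored by
#' Pearson correlation of its z-scored trajectory against each consensus and
#' assigned to its best subset when the correlation reaches `r_threshold`.
#' Z-scoring makes the score invariant to affine rescaling of the input
#' trajectory. Zero-variance trajectories are left unscored.
#'
#' @param fc_mat Protein x time fold-change matrix (>= 3 time points), e.g.
#'   from [trajectory_matrix].
#' @param markers Marker table (`subset`, `marker`) as from
#'   [granule_markers]; markers must be row names of `fc_mat`.
#' @param r_threshold Assignment threshold on Pearson r (default 0.8).
#' @return Data frame `protein`, `subset` (best match), `similarity`,
#'   `assigned`; unscored proteins carry `NA` similarity.
#' @export
kinetic_similarity <- function(fc_mat, markers = granule_markers(),
                               r_threshold = 0.8) {
  fc_mat <- as.matrix(fc_mat)
  if (ncol(fc_mat) < 3) stop("need at least three shared time points")
  subsets <- unique(markers$subset)
  have <- vapply(subsets, function(s)
    any(markers$marker[markers$subset == s] %in% rownames(fc_mat)), TRUE)
  if (!any(have)) stop("no marker present in the trajectory matrix")
  subsets <- subsets[have]
  zrow <- function(v) {
    if (anyNA(v) || stats::sd(v) == 0) return(rep(NA_real_, length(v)))
    (v - mean(v)) / stats::sd(v)
  }
  z <- t(apply(fc_mat, 1, zrow))
  consensus <- vapply(subsets, function(s) {
    rows <- intersect(markers$marker[markers$subset == s], rownames(z))
    colMeans(z[rows, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(z)))
  r <- matrix(NA_real_, nrow(z), length(subsets),
              dimnames = list(rownames(z), subsets))
  scored <- !apply(z, 1, anyNA)
  for (s in subsets) {
    if (stats::sd(consensus[, s]) == 0) next
    r[scored, s] <- apply(z[scored, , drop = FALSE], 1, stats::cor,
                          y = consensus[, s])
  }
  best <- apply(r, 1, function(v) if (all(is.na(v))) NA_integer_ else which.max(v))
  sim <- r[cbind(seq_len(nrow(r)), best)]
  data.frame(protein = rownames(z),
             subset = ifelse(is.na(best), NA_character_, subsets[best]),
             similarity = sim,
             assigned = !is.na(sim) & sim >= r_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Paired-axis release profile plot
#'
#' Cellular relative percentage (left axis) and supernatant fold change
#' (right axis) against time, the standard way to read depletion and
#' release off one panel.
#'
#' @param cell_traj,sup_traj Tidy trajectories for one protein/condition.
#' @param main Plot title.
#' @return Invisibly `NULL`.
#' @export
plot_release_profile <- function(cell_traj, sup_traj, main = NULL) {
  op <- graphics::par(mar = c(5, 4, 3, 4))
  on.exit(graphics::par(op))
  graphics::plot(cell_traj$time_min, cell_traj$value, type = "b", col = "red3",
                 pch = 16, xlab = "time (min)", ylab = "relative percentage (%)",
                 main = main)
  graphics::abline(h = 100, lty = 3, col = "grey60")
  graphics::par(new = TRUE)
  graphics::plot(sup_traj$time_min, sup_traj$value, type = "b", col = "blue3",
                 pch = 17, axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4, col.axis = "blue3")
  graphics::mtext("supernatant fold change", side = 4, line = 2.5,
                  col = "blue3")
  invisible(NULL)
}
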