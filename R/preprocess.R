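#' Median normalization
#'
#' Shifts each sample's non-missing log2 intensities so its median equals the
#' grand median of the sample medians. Missing values are preserved. The
#' operation is idempotent.
#'
#' @param tab A [quant_table] with at least one non-missing value per sample.
#' @return The normalized `quant_table`.
#' @export
median_normalize <- function(tab) {
  m <- tab$intensities
  l <- log2(m)
  med <- apply(l, 2, stats::median, na.rm = TRUE)
  if (any(!is.finite(med))) {
    stop("sample(s) with no usable intensities: ",
         paste(colnames(m)[!is.finite(med)], collapse = ", "))
  }
  target <- stats::median(med)
  tab$intensities <- 2^sweep(l, 2, med - target)
  tab
}

#' Spike-in (external standard) normalization
#'
#' Divides each sample by its spike-in intensity relative to the geometric
#' mean of the spike-in across samples, correcting run-level technical
#' variation while keeping the table on its original intensity scale. After
#' normalization the spike-in row is constant (CV = 0); applying the
#' operation twice equals applying it once.
#'
#' @param tab A [quant_table].
#' @param spikein_id Accession of the spike-in row; defaults to the table's
#'   recorded `spikein_id`.
#' @return The normalized `quant_table`.
#' @export
spikein_normalize <- function(tab, spikein_id = tab$spikein_id) {
  if (is.null(spikein_id)) stop("no spike-in accession given")
  m <- tab$intensities
  if (!spikein_id %in% rownames(m)) {
    stop("spike-in row '", spikein_id, "' not present")
  }
  s <- m[spikein_id, ]
  if (anyNA(s) || any(s <= 0)) {
    stop("spike-in missing or non-positive in sample(s): ",
         paste(colnames(m)[is.na(s) | s <= 0], collapse = ", "))
  }
  tab$intensities <- sweep(m, 2, s / exp(mean(log(s))), `/`)
  tab$spikein_id <- spikein_id
  tab
}

# replicate-mean intensity per (protein, time) for one condition
.time_means <- function(tab, condition, compartment = NULL) {
  j <- .select_samples(tab, compartment = compartment, condition = condition,
                       inhibitor = FALSE)
  if (!length(j)) stop("no samples for condition ", condition)
  sm <- tab$samples[j, , drop = FALSE]
  times <- sort(unique(sm$time_min))
  out <- vapply(times, function(t0) {
    cols <- j[sm$time_min == t0]
    rowMeans(tab$intensities[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(tab$intensities)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  out[is.nan(out)] <- NA_real_
  dimnames(out) <- list(rownames(tab$intensities), times)
  out
}

.traj_df <- function(mat, condition, kind) {
  times <- as.integer(colnames(mat))
  data.frame(protein = rownames(mat)[row(mat)], condition = condition,
             kind = kind, time_min = times[col(mat)], value = as.vector(mat),
             stringsAsFactors = FALSE)
}

#' Cellular relative-percentage trajectories
#'
#' For each protein, the replicate-mean intensity at every time point as a
#' percentage of the replicate-mean at the 0-min baseline of the same
#' condition; 100 at time 0 by construction. A zero or missing baseline
#' leaves the protein's trajectory undefined (all `NA`), not an error.
#'
#' @param tab A [quant_table].
#' @param condition Condition whose trajectories are computed.
#' @return Tidy trajectory data frame (`protein`, `condition`, `kind`,
#'   `time_min`, `value`), `kind = "relative_percentage"`.
#' @export
relative_percentage <- function(tab, condition) {
  mu <- .time_means(tab, condition)
  if (!"0" %in% colnames(mu)) stop("baseline (0 min) absent for ", condition)
  base <- mu[, "0"]
  pct <- 100 * mu / base
  pct[is.na(base) | base == 0, ] <- NA_real_
  .traj_df(pct, condition, "relative_percentage")
}

#' Supernatant fold-change trajectories
#'
#' FC(t) = replicate-mean stimulated intensity / replicate-mean control
#' intensity at the matched time point. A value missing in either arm gives
#' a missing point.
#'
#' @param tab A [quant_table].
#' @param condition Stimulated condition.
#' @param control_condition Control condition (default `"CONTROL"`).
#' @return Tidy trajectory data frame, `kind = "fold_change"`.
#' @export
fold_change_timecourse <- function(tab, condition,
                                   control_condition = "CONTROL") {
  stim <- .time_means(tab, condition)
  ctrl <- .time_means(tab, control_condition)
  shared <- intersect(colnames(stim), colnames(ctrl))
  if (!length(shared)) stop("no shared time points between ", condition,
                            " and ", control_condition)
  fc <- stim[, shared, drop = FALSE] / ctrl[, shared, drop = FALSE]
  fc[!is.finite(fc)] <- NA_real_
  .traj_df(fc, condition, "fold_change")
}

#' Convert a tidy trajectory set to a protein x time matrix
#'
#' @param traj Tidy trajectory data frame from [relative_percentage] or
#'   [fold_change_timecourse].
#' @return Numeric matrix, rows = proteins, columns = time points (minutes).
#' @export
trajectory_matrix <- function(traj) {
  times <- sort(unique(traj$time_min))
  prot <- unique(traj$protein)
  m <- matrix(NA_real_, length(prot), length(times),
              dimnames = list(prot, times))
  m[cbind(match(traj$protein, prot), match(traj$time_min, times))] <- traj$value
  m
}

# vectorized Welch t over matrix rows; returns t, df, p (two-tailed)
.welch_rows <- function(x, y) {
  nx <- rowSums(!is.na(x)); ny <- rowSums(!is.na(y))
  mx <- rowMeans(x, na.rm = TRUE); my <- rowMeans(y, na.rm = TRUE)
  vx <- rowSums((x - mx)^2, na.rm = TRUE) / pmax(nx - 1, 1)
  vy <- rowSums((y - my)^2, na.rm = TRUE) / pmax(ny - 1, 1)
  se2 <- vx / nx + vy / ny
  tt <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / pmax(nx - 1, 1) + (vy / ny)^2 / pmax(ny - 1, 1))
  p <- 2 * stats::pt(-abs(tt), df)
  # degenerate arms: zero variance in both
  flat <- se2 == 0
  tt[flat & mx == my] <- 0
  p[flat & mx == my] <- 1
  p[flat & mx != my] <- 0
  tested <- nx >= 2 & ny >= 2
  p[!tested] <- NA_real_
  tt[!tested] <- NA_real_
  list(t = tt, df = df, p = p, tested = tested,
       delta = mx - my, nx = nx, ny = ny)
}

#' Differential abundance test at one condition/time stratum
#'
#' Two-tailed Welch t on log2 intensities of stimulated versus control
#' replicates, Benjamini-Hochberg adjusted across the proteins tested in the
#' stratum. A protein is significant when its adjusted p-value is at most
#' `alpha` and its absolute fold change is at least `fc_threshold`. This is
#' a plain moderation-free test; the upstream search pipeline's
#' variance-moderated statistic is deliberately not reimplemented, since the
#' screens here are driven by the thresholds, not the moderation.
#'
#' @param tab A [quant_table] (cell compartment, replicated).
#' @param condition Stimulated condition.
#' @param time_min Time point (minutes).
#' @param control_condition Control condition.
#' @param alpha Adjusted-p cut-off (default 0.01).
#' @param fc_threshold Fold-change cut-off on the natural scale (default 1.5).
#' @return Data frame with `protein`, `condition`, `time_min`, `log2_fc`,
#'   `p`, `adj_p`, `significant`, `tested`. Proteins with fewer than two
#'   complete replicates in an arm are flagged `tested = FALSE`.
#' @export
differential_test <- function(tab, condition, time_min,
                              control_condition = "CONTROL",
                              alpha = 0.01, fc_threshold = 1.5) {
  jx <- .select_samples(tab, condition = condition, time_min = time_min,
                        inhibitor = FALSE)
  jy <- .select_samples(tab, condition = control_condition,
                        time_min = time_min, inhibitor = FALSE)
  if (!length(jx) || !length(jy)) stop("no samples in one of the arms")
  w <- .welch_rows(log2(tab$intensities[, jx, drop = FALSE]),
                   log2(tab$intensities[, jy, drop = FALSE]))
  adj <- rep(NA_real_, length(w$p))
  adj[w$tested] <- stats::p.adjust(w$p[w$tested], method = "BH")
  data.frame(protein = rownames(tab$intensities), condition = condition,
             time_min = time_min, log2_fc = w$delta, p = w$p, adj_p = adj,
             significant = !is.na(adj) & adj <= alpha &
               abs(w$delta) >= log2(fc_threshold),
             tested = w$tested, row.names = NULL, stringsAsFactors = FALSE)
}
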