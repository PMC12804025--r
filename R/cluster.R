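#' Standardize temporal profiles
#'
#' Scales each protein's profile to mean 0 and unit spread across time
#' points, using the population standard deviation (the profile is the whole
#' trajectory, not a sample from it). Zero-variance (flat) profiles carry no
#' temporal information and are dropped with a message.
#'
#' @param x Numeric matrix, proteins in rows, time points in columns
#'   (at least two).
#' @return The standardized matrix, possibly with fewer rows; dropped
#'   accessions are attached as attribute `"dropped"`.
#' @export
zscore_profiles <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("need at least two time points")
  mu <- rowMeans(x)
  s <- sqrt(rowMeans((x - mu)^2))
  keep <- !is.na(s) & s > 0
  if (!any(keep)) stop("all profiles are constant or incomplete")
  if (any(!keep)) {
    message(sum(!keep), " constant/incomplete profile(s) dropped")
  }
  z <- (x - mu)[keep, , drop = FALSE] / s[keep]
  attr(z, "dropped") <- rownames(x)[!keep]
  z
}

#' Fuzzy c-means clustering
#'
#' Soft clustering of standardized temporal profiles by alternating
#' optimization of the fuzzy objective
#' J = sum_ij u_ij^m ||x_i - c_j||^2:
#' memberships u_ij = 1 / sum_k (d_ij / d_ik)^(2/(m-1)) followed by
#' membership-weighted centroid updates. Centroids are initialized by seeded
#' sampling of input rows, making runs deterministic given the seed. A point
#' coincident with a centroid takes full membership in it (the limit
#' convention). Iteration stops when the largest membership change falls
#' below `tol` or after `max_iter` sweeps; the recorded objective trace is
#' non-increasing.
#'
#' @param x Profile matrix (rows clustered).
#' @param c Number of clusters (>= 2).
#' @param m Fuzzifier (> 1); 2 is the usual default for omics profiles, and
#'   values near 1 approach hard k-means.
#' @param max_iter Maximum sweeps.
#' @param tol Convergence tolerance on memberships.
#' @param seed RNG seed for centroid initialization.
#' @return List of class `fuzzy_cmeans` with `membership` (rows sum to 1),
#'   `centroids`, `cluster` (hardened assignment), `objective` (final J),
#'   `objective_trace`, `iterations`, `c`, `m`.
#' @export
fuzzy_cmeans <- function(x, c, m = 2, max_iter = 200L, tol = 1e-6, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (c < 2) stop("c must be at least 2")
  if (c >= n) stop("c must be smaller than the number of profiles")
  if (m <= 1) stop("fuzzifier m must exceed 1")
  set.seed(seed)
  centers <- x[sample.int(n, c), , drop = FALSE]
  u_prev <- matrix(0, n, c)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    d2 <- .sqdist(x, centers)
    u <- .fcm_membership(d2, m)
    trace[it] <- sum(u^m * d2)
    w <- u^m
    centers <- crossprod(w, x) / colSums(w)
    if (max(abs(u - u_prev)) < tol) { u_prev <- u; break }
    u_prev <- u
  }
  rownames(u_prev) <- rownames(x)
  rownames(centers) <- paste0("cluster", seq_len(c))
  structure(list(membership = u_prev, centroids = centers,
                 cluster = max.col(u_prev, ties.method = "first"),
                 objective = trace[length(trace)], objective_trace = trace,
                 iterations = length(trace), c = c, m = m),
            class = "fuzzy_cmeans")
}

# squared Euclidean distances between rows of x and rows of centers
.sqdist <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) -
    2 * x %*% t(centers) +
    outer(rep(1, nrow(x)), rowSums(centers^2))
  pmax(d2, 0)
}

.fcm_membership <- function(d2, m) {
  pow <- d2^(-1 / (m - 1))
  zero <- d2 < .Machine$double.eps
  hit <- rowSums(zero) > 0
  u <- pow / rowSums(pow)
  if (any(hit)) u[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero)[hit]
  u
}

#' @export
print.fuzzy_cmeans <- function(x, ...) {
  cat("fuzzy c-means:", nrow(x$membership), "profiles,", x$c,
      "clusters, m =", x$m, "\n")
  cat("  objective", format(x$objective), "after", x$iterations, "iterations\n")
  cat("  hardened sizes:", paste(tabulate(x$cluster, x$c), collapse = ", "), "\n")
  invisible(x)
}

# mean silhouette width of a hard partition (squared-free Euclidean)
.mean_silhouette <- function(x, cluster) {
  k <- length(unique(cluster))
  if (k < 2) return(-Inf)
  D <- as.matrix(stats::dist(x))
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- cluster == cluster[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- sum(D[i, own]) / (sum(own) - 1)
    b <- min(vapply(setdiff(unique(cluster), cluster[i]),
                    function(g) mean(D[i, cluster == g]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Select the number of clusters
#'
#' Fits [fuzzy_cmeans] for each candidate cluster count and picks the one
#' maximizing the mean silhouette width of the hardened assignment; ties
#' break toward the smaller count. Deterministic given the seed.
#'
#' @param x Profile matrix.
#' @param c_range Candidate counts (within `[2, nrow(x) - 1]`).
#' @param m Fuzzifier.
#' @param seed RNG seed.
#' @return List with `c` (the selected count), `silhouette` (named vector
#'   over candidates) and `fits` (the fitted `fuzzy_cmeans` objects).
#' @export
select_cluster_number <- function(x, c_range = 2:8, m = 2, seed = 1L) {
  x <- as.matrix(x)
  c_range <- sort(unique(as.integer(c_range)))
  if (any(c_range < 2) || any(c_range >= nrow(x))) {
    stop("c_range must lie within [2, n - 1]")
  }
  if (all(stats::dist(x) < .Machine$double.eps)) {
    stop("degenerate input: all profiles identical")
  }
  fits <- lapply(c_range, function(cc) fuzzy_cmeans(x, cc, m = m, seed = seed))
  sil <- vapply(fits, function(f) .mean_silhouette(x, f$cluster), 0)
  names(sil) <- c_range
  best <- which.max(sil)  # first max = smallest c on ties
  list(c = c_range[best], silhouette = sil, fits = stats::setNames(fits, c_range))
}

#' Cluster the differential proteins of a condition
#'
#' The clustering input set is the union of differentially abundant proteins
#' over the post-baseline time points of one condition; their replicate-mean
#' log2 profiles are z-scored and clustered.
#'
#' @param tab Cellular [quant_table].
#' @param condition Stimulated condition.
#' @param control_condition Control condition.
#' @param alpha,fc_threshold Differential thresholds (see
#'   [differential_test]).
#' @param c_range Candidate cluster counts; the count is selected by
#'   [select_cluster_number].
#' @param m Fuzzifier.
#' @param seed RNG seed.
#'
#' @details A moderation-free Welch test at three replicates is conservative
#' after FDR control: its attainable p-values are bounded by the low degrees
#' of freedom, so the strict differential set can be empty at realistic
#' noise even for strong planted effects. When it is too small to cluster,
#' the input falls back (with a message) to the union of proteins passing
#' the unadjusted p threshold together with the fold-change gate.
#'
#' @return List with `fit` (`fuzzy_cmeans`), `selection`, `profiles`
#'   (z-scored matrix) and `proteins`.
#' @export
cluster_condition <- function(tab, condition, control_condition = "CONTROL",
                              alpha = 0.01, fc_threshold = 1.5,
                              c_range = 2:6, m = 2, seed = 1L) {
  times <- sort(unique(tab$samples$time_min[tab$samples$condition == condition]))
  de <- lapply(setdiff(times, 0), function(t0)
    differential_test(tab, condition, t0, control_condition,
                      alpha = alpha, fc_threshold = fc_threshold))
  prot <- sort(unique(unlist(lapply(de, function(d) d$protein[d$significant]))))
  if (length(prot) < max(c_range) + 2) {
    prot <- sort(unique(unlist(lapply(de, function(d)
      d$protein[d$tested & !is.na(d$p) & d$p < alpha &
                  abs(d$log2_fc) >= log2(fc_threshold)]))))
    message("strict differential set too small; clustering input falls ",
            "back to unadjusted p < ", alpha, " (n = ", length(prot), ")")
  }
  if (length(prot) < max(c_range) + 2) {
    stop("too few differential proteins (", length(prot), ") to cluster")
  }
  mu <- .time_means(tab, condition)
  z <- zscore_profiles(log2(mu[prot, , drop = FALSE]))
  sel <- select_cluster_number(z, c_range = c_range, m = m, seed = seed)
  list(fit = sel$fits[[as.character(sel$c)]], selection = sel,
       profiles = z, proteins = rownames(z))
}

#' Plot cluster centroid trajectories
#'
#' @param fit A `fuzzy_cmeans` object whose centroid columns are time points.
#' @param time_min Optional numeric time points for the x axis.
#' @param ... Passed to [graphics::matplot].
#' @return Invisibly, `fit`.
#' @export
plot_centroids <- function(fit, time_min = NULL, ...) {
  ce <- fit$centroids
  xv <- if (is.null(time_min)) seq_len(ncol(ce)) else time_min
  graphics::matplot(xv, t(ce), type = "b", lty = 1, pch = 16,
                    xlab = "time (min)", ylab = "z-scored expression", ...)
  graphics::legend("topleft", legend = rownames(ce), col = seq_len(nrow(ce)),
                   lty = 1, bty = "n", cex = 0.8)
  invisible(fit)
}
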