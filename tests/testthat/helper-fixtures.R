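# small in-code fixtures shared across test files

# minimal quant table: values[i, j] for proteins x samples
make_tab <- function(values, conditions, times, replicates = NULL,
                     compartment = "supernatant", proteins = NULL,
                     spikein_id = NULL, inhibitor = NULL) {
  values <- as.matrix(values)
  n <- ncol(values)
  if (is.null(replicates)) replicates <- rep(1L, n)
  if (is.null(proteins)) proteins <- sprintf("P%02d", seq_len(nrow(values)))
  if (is.null(inhibitor)) inhibitor <- rep(FALSE, n)
  ids <- sprintf("s%02d", seq_len(n))
  dimnames(values) <- list(proteins, ids)
  quant_table(values,
              data.frame(sample_id = ids, compartment = compartment,
                         condition = conditions, time_min = times,
                         replicate = replicates, inhibitor = inhibitor,
                         stringsAsFactors = FALSE),
              spikein_id = spikein_id)
}

# brute-force Benjamini-Hochberg step-up, independent of p.adjust
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# per-residue brute-force peptide domain classifier
domain_oracle <- function(length, orientation, spans, start, end) {
  cls <- rep("loop", length)
  first <- min(spans[, 1]); last <- max(spans[, 2])
  if (first > 1) cls[1:(first - 1)] <-
    if (orientation == "type_I") "extracellular" else "intracellular"
  if (last < length) cls[(last + 1):length] <-
    if (orientation == "type_I") "intracellular" else "extracellular"
  for (k in seq_len(nrow(spans))) cls[spans[k, 1]:spans[k, 2]] <- "transmembrane"
  u <- unique(cls[start:end])
  if (length(u) == 1 && u != "loop") u else "spanning"
}

# closed-form OLS slope
slope_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# a separated Gaussian instance for the hard-limit comparison of fuzzy
# c-means against k-means; the init seed is searched deterministically so the
# seeded row-sampling places one starting centroid in each cloud (the regime
# where the m -> 1 limit is well defined)
kmeans_limit_instance <- function(i) {
  set.seed(i)
  n <- sample(20:40, 1); p <- sample(2:4, 1); k <- sample(2:3, 1)
  centers <- matrix(rnorm(k * p, sd = 4), k, p)
  while (min(dist(centers)) < 5) centers <- matrix(rnorm(k * p, sd = 4), k, p)
  g <- c(seq_len(k), sample(k, n - k, replace = TRUE))
  x <- matrix(rnorm(n * p, sd = 0.4), n, p) + centers[g, , drop = FALSE]
  seed <- NA
  for (s in i * 1000 + 1:500) {
    set.seed(s)
    if (length(unique(g[sample.int(n, k)])) == k) { seed <- s; break }
  }
  list(x = x, k = k, n = n, seed = seed)
}

# random single- or multi-pass topology model plus a peptide inside it
random_model_peptide <- function() {
  L <- sample(80:500, 1)
  nspan <- sample(1:3, 1, prob = c(0.7, 0.2, 0.1))
  starts <- sort(sample(seq(10L, L - 30L), nspan))
  spans <- cbind(starts, pmin(starts + sample(15:25, nspan, replace = TRUE), L - 5L))
  while (nrow(spans) > 1 && any(spans[-1, 1] <= spans[-nrow(spans), 2] + 1)) {
    starts <- sort(sample(seq(10L, L - 30L), nspan))
    spans <- cbind(starts, pmin(starts + sample(15:25, nspan, replace = TRUE), L - 5L))
  }
  len <- min(sample(7:30, 1), L)
  start <- sample.int(L - len + 1L, 1)
  list(model = topology_model("X", L, sample(c("type_I", "type_II"), 1), spans),
       spans = spans, start = start, end = start + len - 1L, L = L)
}
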