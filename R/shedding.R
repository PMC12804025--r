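#' Single-pass membrane topology model
#'
#' @param protein Accession.
#' @param length Protein length in residues.
#' @param orientation `"type_I"` (extracellular N-terminus) or `"type_II"`
#'   (extracellular C-terminus).
#' @param tm_spans Matrix/list of 1-based inclusive transmembrane intervals,
#'   or a string like `"601-621"` (`;`-separated for multi-pass).
#' @return List of class `topology_model`.
#' @export
topology_model <- function(protein, length, orientation, tm_spans) {
  if (is.character(tm_spans)) tm_spans <- .parse_spans(tm_spans)
  tm_spans <- matrix(as.integer(tm_spans), ncol = 2)
  tm_spans <- tm_spans[order(tm_spans[, 1]), , drop = FALSE]
  if (!orientation %in% c("type_I", "type_II")) {
    stop("orientation must be type_I or type_II")
  }
  if (any(tm_spans[, 1] > tm_spans[, 2]) || any(tm_spans < 1) ||
      any(tm_spans > length)) stop("TM spans must lie within [1, length]")
  if (nrow(tm_spans) > 1 &&
      any(tm_spans[-1, 1] <= tm_spans[-nrow(tm_spans), 2])) {
    stop("TM spans must not overlap")
  }
  structure(list(protein = protein, length = as.integer(length),
                 orientation = orientation, tm_spans = tm_spans),
            class = "topology_model")
}

#' Read topology models
#'
#' @param path TSV with columns `accession`, `length`, `orientation`,
#'   `tm_spans` (e.g. `"601-621"`).
#' @return Named list of [topology_model]s.
#' @export
read_topologies <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  mods <- lapply(seq_len(nrow(df)), function(i)
    topology_model(df$accession[i], df$length[i], df$orientation[i],
                   df$tm_spans[i]))
  stats::setNames(mods, df$accession)
}

#' Assign a detected peptide to a topological domain
#'
#' Interval logic against a single- or multi-pass model: the N-terminal side
#' of the first transmembrane span is extracellular for a type I protein and
#' intracellular for type II (the C-terminal side is the opposite). A
#' peptide lying entirely in one region gets that region's label; a peptide
#' entirely inside one TM span is `transmembrane`; anything overlapping a
#' span boundary, crossing regions, or falling in an interior loop of a
#' multi-pass model is `spanning`.
#'
#' @param model A [topology_model].
#' @param start,end 1-based inclusive peptide coordinates.
#' @return One of `"extracellular"`, `"transmembrane"`, `"intracellular"`,
#'   `"spanning"`.
#' @export
assign_peptide_domain <- function(model, start, end) {
  if (start < 1 || end > model$length || start > end) {
    stop("peptide interval out of bounds for ", model$protein)
  }
  sp <- model$tm_spans
  first <- sp[1, 1]; last <- sp[nrow(sp), 2]
  n_side <- if (model$orientation == "type_I") "extracellular" else "intracellular"
  c_side <- if (model$orientation == "type_I") "intracellular" else "extracellular"
  if (end < first) return(n_side)
  if (start > last) return(c_side)
  for (k in seq_len(nrow(sp))) {
    if (start >= sp[k, 1] && end <= sp[k, 2]) return("transmembrane")
  }
  "spanning"
}

#' Call MMP/ADAM sheddase substrates from an inhibitor experiment
#'
#' Soluble levels of membrane proteins in stimulated conditioned media are
#' compared between the stimulus and stimulus-plus-inhibitor arms by a
#' two-tailed Welch t test on log2 intensities. A substrate must show a
#' statistically significant (`p < p_threshold`) reduction under the
#' inhibitor exceeding the effect gate: `log2_fc > log2fc_threshold` with
#' FC = mean(stimulus) / mean(stimulus + inhibitor), so the direction
#' (inhibitor reduces) is part of the rule. No multiplicity adjustment is
#' applied by default (a plain per-protein test); set `adjust = TRUE` for
#' Benjamini-Hochberg.
#'
#' @param tab Shedding-experiment [quant_table]; sample metadata must carry
#'   the `inhibitor` flag.
#' @param membrane Character vector of membrane protein accessions to test.
#' @param stimulus Condition to test.
#' @param p_threshold p-value gate (default 0.05, strict `<`).
#' @param log2fc_threshold Effect gate on log2 FC (default 0.6, strict `>`).
#' @param adjust Apply BH across tested proteins before gating (default
#'   `FALSE`).
#' @return Data frame `protein`, `stimulus`, `log2_fc`, `p`, `substrate`,
#'   `tested`. Proteins with fewer than 2 complete replicates per arm are
#'   flagged untested.
#' @export
call_substrates <- function(tab, membrane, stimulus, p_threshold = 0.05,
                            log2fc_threshold = 0.6, adjust = FALSE) {
  rows <- intersect(membrane, rownames(tab$intensities))
  if (!length(rows)) stop("no membrane proteins present in the table")
  jx <- .select_samples(tab, condition = stimulus, inhibitor = FALSE)
  jy <- .select_samples(tab, condition = stimulus, inhibitor = TRUE)
  if (length(jx) < 2 || length(jy) < 2) {
    stop("need replicated stimulus and inhibitor arms for ", stimulus)
  }
  x <- tab$intensities[rows, jx, drop = FALSE]
  y <- tab$intensities[rows, jy, drop = FALSE]
  w <- .welch_rows(log2(x), log2(y))
  lfc <- log2(rowMeans(x, na.rm = TRUE) / rowMeans(y, na.rm = TRUE))
  p <- w$p
  if (adjust) p[w$tested] <- stats::p.adjust(p[w$tested], method = "BH")
  data.frame(protein = rows, stimulus = stimulus, log2_fc = lfc, p = p,
             substrate = w$tested & !is.na(p) & p < p_threshold &
               !is.na(lfc) & lfc > log2fc_threshold,
             tested = w$tested, row.names = NULL, stringsAsFactors = FALSE)
}

#' Ectodomain evidence summary per protein
#'
#' Fraction of a membrane protein's classified (non-spanning) detected
#' peptides that map to the extracellular domain, and whether that fraction
#' exceeds one half (`majority_extracellular`). Proteins whose peptides are
#' all spanning are unscored (`NA` fraction).
#'
#' @param domains Data frame `protein`, `domain` — one row per detected
#'   peptide, domains as returned by [assign_peptide_domain].
#' @return Data frame `protein`, `n_peptides`, `n_classified`,
#'   `ectodomain_fraction`, `majority_extracellular`.
#' @export
ectodomain_summary <- function(domains) {
  stopifnot(all(c("protein", "domain") %in% names(domains)))
  sp <- split(domains$domain, domains$protein)
  out <- data.frame(protein = names(sp), stringsAsFactors = FALSE)
  out$n_peptides <- vapply(sp, length, 0L)
  out$n_classified <- vapply(sp, function(d) sum(d != "spanning"), 0L)
  frac <- vapply(sp, function(d) {
    cl <- d[d != "spanning"]
    if (!length(cl)) return(NA_real_)
    mean(cl == "extracellular")
  }, 0)
  out$ectodomain_fraction <- frac
  out$majority_extracellular <- !is.na(frac) & frac > 0.5
  rownames(out) <- NULL
  out
}

#' Cross-stimulus sheddase sensitivity matrix
#'
#' @param calls Named list (by stimulus) of [call_substrates] results.
#' @return Data frame: one row per protein tested in any stimulus, one
#'   logical `substrate_<stimulus>` column each (`NA` where untested).
#' @export
compare_conditions <- function(calls) {
  if (!length(calls)) {
    return(data.frame(protein = character(0), stringsAsFactors = FALSE))
  }
  stopifnot(!is.null(names(calls)))
  prot <- sort(unique(unlist(lapply(calls, function(d) d$protein[d$tested]))))
  out <- data.frame(protein = prot, stringsAsFactors = FALSE)
  for (s in names(calls)) {
    d <- calls[[s]]
    i <- match(prot, d$protein)
    v <- d$substrate[i]
    v[!is.na(i) & !d$tested[i]] <- NA
    out[[paste0("substrate_", s)]] <- v
  }
  out
}
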