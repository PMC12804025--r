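#' Protein-by-sample quantification table
#'
#' The pipeline's universal carrier: a positive intensity matrix (proteins in
#' rows, samples in columns; `NA` = not quantified) bound to a per-sample
#' metadata table. Row names are protein accessions, column names sample ids.
#'
#' @param intensities Numeric matrix of LFQ intensities with protein
#'   accessions as row names and sample ids as column names. Values must be
#'   positive or `NA`.
#' @param samples Data frame of sample metadata with at least the columns
#'   `sample_id`, `compartment` (`"cell"` or `"supernatant"`), `condition`,
#'   `time_min` (non-negative integer minutes) and `replicate`. An optional
#'   logical `inhibitor` column marks sheddase-inhibitor arms. Rows must match
#'   the matrix columns one-to-one (matched by `sample_id`).
#' @param spikein_id Optional accession of a spike-in standard row (e.g.
#'   staphylococcal protein A added in equal amounts to every supernatant
#'   sample).
#'
#' @return An object of class `quant_table`: a list with elements
#'   `intensities`, `samples` and `spikein_id`.
#' @export
quant_table <- function(intensities, samples, spikein_id = NULL) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(rownames(intensities))) {
    stop("intensities must have protein accessions as row names")
  }
  if (anyDuplicated(rownames(intensities))) {
    stop("duplicate protein ids: ",
         paste(unique(rownames(intensities)[duplicated(rownames(intensities))]),
               collapse = ", "))
  }
  req <- c("sample_id", "compartment", "condition", "time_min", "replicate")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop("sample metadata lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id in metadata")
  if (is.null(colnames(intensities))) colnames(intensities) <- samples$sample_id
  if (!setequal(colnames(intensities), samples$sample_id)) {
    stop("matrix columns and sample metadata do not describe the same samples")
  }
  samples <- samples[match(colnames(intensities), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  if (!"inhibitor" %in% names(samples)) samples$inhibitor <- FALSE
  if (any(intensities < 0, na.rm = TRUE)) stop("negative intensities are not allowed")
  if (any(samples$time_min < 0)) stop("time_min must be non-negative")
  if (!is.null(spikein_id) && !spikein_id %in% rownames(intensities)) {
    stop("spike-in accession '", spikein_id, "' is not a row of the table")
  }
  structure(list(intensities = intensities, samples = samples,
                 spikein_id = spikein_id),
            class = "quant_table")
}

#' @export
print.quant_table <- function(x, ...) {
  cat("quant_table:", nrow(x$intensities), "proteins x",
      ncol(x$intensities), "samples\n")
  cat("  compartment(s):", paste(unique(x$samples$compartment), collapse = ", "), "\n")
  cat("  condition(s):  ", paste(unique(x$samples$condition), collapse = ", "), "\n")
  cat("  times (min):   ", paste(sort(unique(x$samples$time_min)), collapse = ", "), "\n")
  nmiss <- sum(is.na(x$intensities))
  cat(sprintf("  missing: %d/%d (%.1f%%)\n", nmiss, length(x$intensities),
              100 * nmiss / length(x$intensities)))
  if (!is.null(x$spikein_id)) cat("  spike-in:", x$spikein_id, "\n")
  invisible(x)
}

#' @export
dim.quant_table <- function(x) dim(x$intensities)

#' Subset a quantification table
#'
#' @param x A [quant_table].
#' @param i Protein (row) index: integer, logical or accession character.
#' @param j Sample (column) index: integer, logical or sample-id character.
#' @param ... Ignored.
#' @return A `quant_table` restricted to the selected proteins/samples.
#' @export
`[.quant_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$intensities))
  if (missing(j)) j <- seq_len(ncol(x$intensities))
  m <- x$intensities[i, j, drop = FALSE]
  s <- x$samples[match(colnames(m), x$samples$sample_id), , drop = FALSE]
  spike <- if (!is.null(x$spikein_id) && x$spikein_id %in% rownames(m)) x$spikein_id
  quant_table(m, s, spikein_id = spike)
}

# internal: columns of a table matching metadata predicates
.select_samples <- function(tab, compartment = NULL, condition = NULL,
                            time_min = NULL, inhibitor = NULL) {
  keep <- rep(TRUE, nrow(tab$samples))
  if (!is.null(compartment)) keep <- keep & tab$samples$compartment %in% compartment
  if (!is.null(condition)) keep <- keep & tab$samples$condition %in% condition
  if (!is.null(time_min)) keep <- keep & tab$samples$time_min %in% time_min
  if (!is.null(inhibitor)) keep <- keep & tab$samples$inhibitor %in% inhibitor
  which(keep)
}
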