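#' Read a long-format DIA-NN style report into a quantification table
#'
#' Pivots a tab-separated long report (one row per protein group x run) to a
#' wide protein x sample matrix. Only three columns are contractual:
#' `Protein.Group`, `Run` and the quantity column (default `PG.MaxLFQ`); any
#' further columns are ignored. A protein-run pair absent from the report
#' becomes a missing value.
#'
#' @param path Path to the report TSV.
#' @param samples Sample metadata data frame (see [quant_table]); its
#'   `sample_id` values must cover every run name in the report.
#' @param quantity_column Name of the quantity column. Default `"PG.MaxLFQ"`.
#' @param spikein_id Optional spike-in accession, forwarded to [quant_table].
#'
#' @return A [quant_table].
#' @export
read_dia_report <- function(path, samples, quantity_column = "PG.MaxLFQ",
                            spikein_id = NULL) {
  if (!file.exists(path)) stop("report file not found: ", path)
  rep <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("Protein.Group", "Run", quantity_column)
  miss <- setdiff(need, names(rep))
  if (length(miss)) stop("report lacks column(s): ", paste(miss, collapse = ", "))
  key <- paste(rep[["Protein.Group"]], rep[["Run"]], sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    val <- rep[[quantity_column]][key == d]
    if (length(unique(val)) > 1L) {
      pr <- strsplit(d, "\r", fixed = TRUE)[[1]]
      stop("conflicting duplicate rows for protein '", pr[1],
           "', run '", pr[2], "'")
    }
    rep <- rep[!duplicated(key), , drop = FALSE]
  }
  unknown <- setdiff(unique(rep$Run), samples$sample_id)
  if (length(unknown)) {
    stop("run(s) absent from sample metadata: ", paste(unknown, collapse = ", "))
  }
  prot <- sort(unique(rep[["Protein.Group"]]))
  m <- matrix(NA_real_, length(prot), nrow(samples),
              dimnames = list(prot, samples$sample_id))
  m[cbind(match(rep[["Protein.Group"]], prot), match(rep$Run, colnames(m)))] <-
    rep[[quantity_column]]
  quant_table(m, samples, spikein_id = spikein_id)
}

#' Read sample metadata
#'
#' @param path TSV with columns `sample_id`, `compartment`, `condition`,
#'   `time_min`, `replicate` and optionally `inhibitor`.
#' @return Data frame suitable for [quant_table].
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop("sample metadata file not found: ", path)
  s <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("inhibitor" %in% names(s)) s$inhibitor <- as.logical(s$inhibitor)
  s
}

.GRANULE_SUBSETS <- c("AG", "SG", "GG", "SV")
.EXCLUSION_CLASSES <- c("mitochondrial", "ribosomal", "histone", "none")
.ROUTE_FLAGS <- c("signal_peptide", "nonclassical", "transmembrane", "vesicle")

#' Read a protein annotation table
#'
#' Expected columns: `accession`, `granule_subsets` (semicolon-separated
#' tokens among AG, SG, GG, SV; empty or `"none"` for non-canonical proteins),
#' `exclusion_class` (mitochondrial / ribosomal / histone / none),
#' `is_membrane` (logical) and the four secretion-route flags
#' `signal_peptide`, `nonclassical`, `transmembrane`, `vesicle` (logical).
#' Missing columns get their defaults (empty subsets, `none`, all-false flags).
#' Accessions never listed in the table are handled downstream by
#' [annotation_for()], which returns the same defaults.
#'
#' @param path Annotation TSV.
#' @return Data frame of class `protein_annotation`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  a <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"accession" %in% names(a)) stop("annotation table lacks 'accession'")
  as_annotations(a)
}

#' Coerce a data frame to a validated annotation table
#'
#' @param a Data frame with at least `accession`; see [read_annotations] for
#'   the recognized columns.
#' @return Data frame of class `protein_annotation` with all columns filled.
#' @export
as_annotations <- function(a) {
  a <- as.data.frame(a, stringsAsFactors = FALSE)
  if (anyDuplicated(a$accession)) stop("duplicate accessions in annotation table")
  if (!"granule_subsets" %in% names(a)) a$granule_subsets <- ""
  a$granule_subsets[is.na(a$granule_subsets)] <- ""
  toks <- strsplit(a$granule_subsets, ";", fixed = TRUE)
  bad <- unique(unlist(toks))
  bad <- setdiff(bad, c(.GRANULE_SUBSETS, "", "none"))
  if (length(bad)) stop("malformed granule subset token(s): ", paste(bad, collapse = ", "))
  a$granule_subsets <- vapply(toks, function(t)
    paste(intersect(.GRANULE_SUBSETS, t), collapse = ";"), "")
  if (!"exclusion_class" %in% names(a)) a$exclusion_class <- "none"
  a$exclusion_class[is.na(a$exclusion_class) | a$exclusion_class == ""] <- "none"
  bad <- setdiff(unique(a$exclusion_class), .EXCLUSION_CLASSES)
  if (length(bad)) stop("unknown exclusion class(es): ", paste(bad, collapse = ", "))
  if (!"is_membrane" %in% names(a)) a$is_membrane <- FALSE
  a$is_membrane <- as.logical(a$is_membrane) %in% TRUE
  for (f in .ROUTE_FLAGS) {
    if (!f %in% names(a)) a[[f]] <- FALSE
    a[[f]] <- as.logical(a[[f]]) %in% TRUE
  }
  class(a) <- c("protein_annotation", "data.frame")
  a
}

#' Look up annotations with defaults for unlisted accessions
#'
#' @param annotations A `protein_annotation` table (or `NULL` for all-default).
#' @param accessions Character vector of accessions to look up.
#' @return Annotation data frame with one row per requested accession, in
#'   request order; unlisted accessions receive the default annotation
#'   (no subsets, `exclusion_class = "none"`, non-membrane, all route flags
#'   false).
#' @export
annotation_for <- function(annotations, accessions) {
  k <- length(accessions)
  out <- data.frame(accession = accessions,
                    granule_subsets = rep("", k),
                    exclusion_class = rep("none", k),
                    is_membrane = rep(FALSE, k),
                    stringsAsFactors = FALSE)
  for (f in .ROUTE_FLAGS) out[[f]] <- rep(FALSE, k)
  if (!is.null(annotations)) {
    i <- match(accessions, annotations$accession)
    hit <- !is.na(i)
    cols <- c("granule_subsets", "exclusion_class", "is_membrane", .ROUTE_FLAGS)
    out[hit, cols] <- as.data.frame(annotations)[i[hit], cols]
  }
  class(out) <- c("protein_annotation", "data.frame")
  out
}

#' Infer an exclusion class from a gene symbol
#'
#' Default keyword screen for the classes removed from the release catalog:
#' ribosomal (RPL/RPS prefixes), histone (H1/H2A/H2B/H3/H4 and HIST families)
#' and mitochondrially encoded (MT- prefix) proteins. The screen is a
#' convenience for building annotation tables and can always be overridden by
#' an explicit `exclusion_class` column.
#'
#' @param symbol Character vector of gene symbols.
#' @return Character vector over mitochondrial/ribosomal/histone/none.
#' @export
infer_exclusion_class <- function(symbol) {
  out <- rep("none", length(symbol))
  out[grepl("^RP[LS]", symbol)] <- "ribosomal"
  out[grepl("^(HIST|H1-|H2A|H2B|H3|H4)", symbol)] <- "histone"
  out[grepl("^MT-", symbol)] <- "mitochondrial"
  out
}

#' Filter proteins by peptide support
#'
#' Identification requires at least one unique peptide; differential detection
#' conventionally requires at least two. Both are expressed as a per-protein
#' peptide-count filter.
#'
#' @param tab A [quant_table].
#' @param peptide_counts Named integer vector (accession -> peptide count);
#'   proteins absent from the vector are treated as count 0.
#' @param min_peptides Minimum count to keep (default 1).
#' @return The filtered `quant_table`.
#' @export
filter_by_peptides <- function(tab, peptide_counts, min_peptides = 1L) {
  n <- peptide_counts[rownames(tab$intensities)]
  n[is.na(n)] <- 0L
  tab[n >= min_peptides, ]
}

#' Write result tables deterministically
#'
#' Writes each element of a named list as a TSV under `out_dir` with fixed
#' column order and no quoting, so that re-running a pipeline with the same
#' inputs reproduces byte-identical files. A `quant_table` element is written
#' as two files (`<name>.tsv` matrix with an `accession` first column and
#' `<name>_samples.tsv` metadata).
#'
#' @param tables Named list of data frames and/or `quant_table`s.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the character vector of files written.
#' @export
write_results <- function(tables, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stopifnot(!is.null(names(tables)), all(nzchar(names(tables))))
  files <- character(0)
  for (nm in names(tables)) {
    x <- tables[[nm]]
    if (inherits(x, "quant_table")) {
      f1 <- file.path(out_dir, paste0(nm, ".tsv"))
      df <- data.frame(accession = rownames(x$intensities),
                       x$intensities, check.names = FALSE,
                       stringsAsFactors = FALSE)
      .write_tsv(df, f1)
      f2 <- file.path(out_dir, paste0(nm, "_samples.tsv"))
      .write_tsv(x$samples, f2)
      files <- c(files, f1, f2)
    } else {
      f <- file.path(out_dir, paste0(nm, ".tsv"))
      .write_tsv(as.data.frame(x), f)
      files <- c(files, f)
    }
  }
  invisible(files)
}

# fixed text representation: full double precision, no quotes, unix newlines
.write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      v <- sprintf("%.15g", df[[j]])
      v[is.na(df[[j]])] <- "NA"
      df[[j]] <- v
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
}

#' Read back a matrix written by [write_results]
#'
#' @param path Matrix TSV with an `accession` first column.
#' @param samples_path Optional matching `_samples.tsv`; when given, a
#'   [quant_table] is returned instead of a bare matrix.
#' @param spikein_id Optional spike-in accession.
#' @return Numeric matrix or `quant_table`.
#' @export
read_quant_matrix <- function(path, samples_path = NULL, spikein_id = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  if (is.null(samples_path)) return(m)
  quant_table(m, read_samples(samples_path), spikein_id = spikein_id)
}
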