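#' Read and write chromatogram trace tables
#'
#' The interchange format for traces is a TSV with columns `pos` (1-based
#' position), `A`, `C`, `G`, `T` (non-negative channel intensities) and
#' `base` (called base). [read_trace_tsv()] validates the schema on read.
#'
#' @param path File path.
#' @param trace A trace tibble as produced by [gen_traces()].
#' @return [read_trace_tsv()] returns the validated trace tibble;
#'   [write_trace_tsv()] returns `path` invisibly.
#' @export
read_trace_tsv <- function(path) {
  tr <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  validate_trace(tr)
}

#' @rdname read_trace_tsv
#' @export
write_trace_tsv <- function(trace, path) {
  validate_trace(trace)
  readr::write_tsv(trace, path)
  invisible(path)
}

validate_trace <- function(trace) {
  need <- c("pos", "A", "C", "G", "T", "base")
  miss <- setdiff(need, names(trace))
  if (length(miss)) {
    abort(paste0("trace table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  sig <- as.matrix(trace[, c("A", "C", "G", "T")])
  if (any(!is.finite(sig)) || any(sig < 0)) {
    abort("trace signal must be finite and non-negative.")
  }
  if (length(trace$base) != nrow(sig)) abort("base_calls length mismatch.")
  as_tibble(trace)
}

trace_signal <- function(trace) {
  as.matrix(trace[order(trace$pos), c("A", "C", "G", "T")])
}

#' Read a long-format qPCR Ct table
#'
#' Expects at least the columns `sample`, `group`, `target`, `bio_rep`,
#' `tech_rep`, `ct` (the RT-stop assay additionally carries `condition`,
#' `"CMC"` or `"untreated"`). Ct values must lie in (0, 45).
#'
#' @param path File path.
#' @return A validated tibble.
#' @export
read_ct_tsv <- function(path) {
  ct <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  validate_ct(ct)
}

validate_ct <- function(ct) {
  need <- c("sample", "group", "target", "bio_rep", "tech_rep", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss)) {
    abort(paste0("Ct table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0 | ct$ct >= 45)) {
    abort("Ct values must be finite and in (0, 45).")
  }
  as_tibble(ct)
}

#' Read a transcript count table and its sample-group map
#'
#' The count TSV carries `transcript_id`, `gene_id`, `biotype`, then one
#' column per sample with non-negative integer counts. The groups TSV
#' carries `sample` and `group`.
#'
#' @param path,groups_path File paths.
#' @return A tibble ([read_counts_tsv()]) or a `sample`/`group` tibble
#'   ([read_groups_tsv()]).
#' @export
read_counts_tsv <- function(path) {
  counts <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  validate_counts(counts)
}

#' @rdname read_counts_tsv
#' @export
read_groups_tsv <- function(groups_path) {
  g <- readr::read_tsv(groups_path, show_col_types = FALSE, comment = "#")
  if (!all(c("sample", "group") %in% names(g))) {
    abort("groups table needs columns `sample` and `group`.")
  }
  as_tibble(g)
}

validate_counts <- function(counts) {
  need <- c("transcript_id", "gene_id")
  miss <- setdiff(need, names(counts))
  if (length(miss)) {
    abort(paste0("count table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  m <- counts_matrix(counts)
  if (any(m < 0)) abort("counts must be non-negative.")
  if (anyDuplicated(counts$transcript_id)) {
    abort("transcript_id values must be unique.")
  }
  as_tibble(counts)
}

# numeric sample-count matrix from the annotated tibble
counts_matrix <- function(counts) {
  meta <- intersect(c("transcript_id", "gene_id", "biotype"), names(counts))
  m <- as.matrix(counts[, setdiff(names(counts), meta), drop = FALSE])
  rownames(m) <- counts$transcript_id
  storage.mode(m) <- "double"
  m
}

#' Read a category-to-gene annotation table
#'
#' Two-column TSV mapping `category` to `gene`, one pair per row.
#'
#' @param path File path.
#' @return A tibble with columns `category`, `gene`.
#' @export
read_annotation_tsv <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  if (!all(c("category", "gene") %in% names(ann))) {
    abort("annotation table needs columns `category` and `gene`.")
  }
  as_tibble(ann)
}

#' Read reference sequences from FASTA
#'
#' Thin wrapper over `Biostrings::readDNAStringSet()` returning a tibble
#' so reference sets compose with the rest of the pipeline. Coordinates
#' used downstream are 1-based and fully closed.
#'
#' @param path FASTA file path.
#' @return A tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  tibble(id = sub("\\s.*$", "", names(ss)), sequence = as.character(ss))
}
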