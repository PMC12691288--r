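#' Locate protospacer + PAM sites in a reference sequence
#'
#' Searches both strands for the protospacer with the PAM pattern
#' immediately 3' of it on the matched strand. All coordinates reported
#' are 1-based, fully closed, on the reference (sense) strand. IUPAC
#' degenerate codes in the query/PAM pattern match their expansions; `N`
#' in the reference matches nothing (conservative against false hits).
#'
#' @param ref Reference: a character DNA string, optionally named, or a
#'   one-row tibble with `id` and `sequence` (see [read_fasta()]).
#' @param protospacer Protospacer sequence, length >= 17 (printed guide
#'   sequences are used as-is, even when longer than the canonical
#'   20-mer).
#' @param pam_pattern Degenerate PAM, default `"NGG"`.
#' @param max_hits Abort (naming the count) when more hits are found.
#' @param max_mismatch Mismatches tolerated in the protospacer+PAM match
#'   (default 0).
#' @return A tibble sorted by coordinate with `ref_id`, `start`, `end`
#'   (protospacer span), `strand` (`sense`/`antisense`), `pam_start`,
#'   `pam_end` (sense coordinates of the PAM) and `pam` (PAM as read on
#'   the protospacer strand). Zero hits yield an empty tibble with a
#'   warning.
#' @export
#' @examples
#' ref <- paste0(strrep("T", 10), "GATTACAGATTACAGATTAC", "AGG",
#'               strrep("C", 27))
#' find_protospacer(ref, "GATTACAGATTACAGATTAC")
find_protospacer <- function(ref, protospacer, pam_pattern = "NGG",
                             max_hits = 10, max_mismatch = 0) {
  r <- as_reference(ref)
  if (nchar(protospacer) < 17) abort("protospacer must be >= 17 nt.")
  subject <- Biostrings::DNAString(r$sequence)
  pat <- Biostrings::DNAString(paste0(protospacer, pam_pattern))
  L <- length(pat)
  lp <- nchar(protospacer)

  hit_tbl <- function(m, strand) {
    s <- Biostrings::start(m)
    if (!length(s)) return(NULL)
    if (strand == "sense") {
      tibble(start = s, end = s + lp - 1L,
             pam_start = s + lp, pam_end = s + lp + 2L, strand = strand)
    } else {
      tibble(start = s + 3L, end = s + L - 1L,
             pam_start = s, pam_end = s + 2L, strand = strand)
    }
  }

  fx <- c(pattern = FALSE, subject = TRUE)  # pattern codes degenerate
  sense <- Biostrings::matchPattern(pat, subject, fixed = fx,
                                    max.mismatch = max_mismatch)
  anti <- Biostrings::matchPattern(Biostrings::reverseComplement(pat),
                                   subject, fixed = fx,
                                   max.mismatch = max_mismatch)
  hits <- bind_rows(hit_tbl(sense, "sense"), hit_tbl(anti, "antisense"))
  if (is.null(hits) || !nrow(hits)) {
    warn(paste0("no protospacer hit in reference ", r$id, "."))
    return(tibble(ref_id = character(), start = integer(), end = integer(),
                  strand = character(), pam_start = integer(),
                  pam_end = integer(), pam = character()))
  }
  # a reference N never supports a hit
  seq_chars <- strsplit(r$sequence, "")[[1]]
  span_ok <- purrr::map2_lgl(
    pmin(hits$start, hits$pam_start), pmax(hits$end, hits$pam_end),
    function(a, b) all(seq_chars[a:b] %in% c("A", "C", "G", "T"))
  )
  hits <- hits[span_ok, ]
  if (!nrow(hits)) {
    warn(paste0("no protospacer hit in reference ", r$id, "."))
  }
  if (nrow(hits) > max_hits) {
    abort(sprintf("ambiguous protospacer: %d hits exceed max_hits = %d.",
                  nrow(hits), max_hits))
  }
  hits |>
    mutate(ref_id = r$id,
           pam = substr(rep(r$sequence, dplyr::n()),
                        .data$pam_start, .data$pam_end),
           pam = ifelse(.data$strand == "antisense",
                        revcomp(.data$pam), .data$pam)) |>
    arrange(.data$start) |>
    select("ref_id", "start", "end", "strand", "pam_start", "pam_end", "pam")
}

as_reference <- function(ref) {
  if (is.list(ref) && !is.data.frame(ref) &&
      all(c("id", "sequence") %in% names(ref))) {
    return(list(id = ref$id, sequence = toupper(ref$sequence)))
  }
  if (is.data.frame(ref)) {
    stopifnot(all(c("id", "sequence") %in% names(ref)), nrow(ref) == 1)
    list(id = ref$id[[1]], sequence = toupper(ref$sequence[[1]]))
  } else {
    list(id = names(ref) %||% "ref", sequence = toupper(unname(ref)))
  }
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Predicted Cas9 cut coordinates for protospacer hits
#'
#' Blunt SpCas9 cuts are estimated 3 bp upstream of the PAM: the reported
#' coordinate is the base 3 positions 5' of the PAM start on the
#' protospacer-containing strand, converted to sense coordinates (the cut
#' falls between this base and the next PAM-proximal base).
#'
#' @param hits Tibble from [find_protospacer()].
#' @param ref_length Reference length in bp (bounds check).
#' @return `hits` with a `cut_site` column (1-based sense coordinate).
#' @export
cut_site <- function(hits, ref_length) {
  if (!nrow(hits)) return(mutate(hits, cut_site = integer()))
  cut <- ifelse(hits$strand == "sense",
                hits$pam_start - 3L,
                hits$pam_end + 3L)
  if (any(cut < 1 | cut > ref_length)) {
    abort("cut site out of bounds: PAM within 3 bp of the sequence end.")
  }
  mutate(hits, cut_site = as.integer(cut))
}

#' Locate a guide sheet against a reference
#'
#' Runs [find_protospacer()] and [cut_site()] for every guide in a sheet.
#'
#' @param ref Reference (see [find_protospacer()]).
#' @param guides Tibble with `name` and `sequence` (optionally `pam`).
#' @param ... Passed to [find_protospacer()].
#' @return Tibble of hits with a `name` column and `cut_site`.
#' @export
locate_guides <- function(ref, guides, ...) {
  r <- as_reference(ref)
  purrr::pmap(guides, function(name, sequence, pam = "NGG", ...) {
    h <- find_protospacer(r, sequence, pam_pattern = pam, ...)
    if (!nrow(h)) return(NULL)
    cut_site(h, nchar(r$sequence)) |> mutate(name = name, .before = 1)
  }) |> purrr::list_rbind()
}

#' In-silico PCR amplicon sizing
#'
#' Finds forward-primer matches on the sense strand and reverse-primer
#' matches as its reverse complement downstream, and sizes each
#' productive pairing: `length = reverse-site 3' edge - forward-site 5'
#' coordinate + 1` (1-based, fully closed).
#'
#' @param ref Reference (see [find_protospacer()]).
#' @param forward Forward primer (sense, 5'->3').
#' @param reverse Reverse primer (written 5'->3' on the antisense strand).
#' @param max_mismatch Mismatches tolerated per primer site (default 0).
#' @return A tibble with `ref_id`, `fwd_start`, `fwd_end`, `rev_start`,
#'   `rev_end`, `length`, `ambiguous`. Errors when no productive pairing
#'   exists; warns and flags all pairings when several are productive.
#' @export
#' @examples
#' ref <- paste0(strrep("ACGT", 25))
#' insilico_pcr(ref, substr(ref, 1, 20), revcomp_chr(substr(ref, 81, 100)))
insilico_pcr <- function(ref, forward, reverse, max_mismatch = 0) {
  r <- as_reference(ref)
  if (nchar(forward) < 15 || nchar(reverse) < 15) {
    abort("both primers must be at least 15 nt.")
  }
  subject <- Biostrings::DNAString(r$sequence)
  fx <- c(pattern = FALSE, subject = TRUE)
  fm <- Biostrings::matchPattern(Biostrings::DNAString(forward), subject,
                                 fixed = fx, max.mismatch = max_mismatch)
  rm_ <- Biostrings::matchPattern(
    Biostrings::reverseComplement(Biostrings::DNAString(reverse)), subject,
    fixed = fx, max.mismatch = max_mismatch)
  if (!length(fm) || !length(rm_)) {
    abort("no productive primer pairing found (a primer has no binding site).")
  }
  pairs <- tidyr::expand_grid(
    f = seq_along(fm), rv = seq_along(rm_)
  ) |>
    mutate(fwd_start = Biostrings::start(fm)[.data$f],
           fwd_end = Biostrings::end(fm)[.data$f],
           rev_start = Biostrings::start(rm_)[.data$rv],
           rev_end = Biostrings::end(rm_)[.data$rv]) |>
    filter(.data$rev_start > .data$fwd_end) |>
    mutate(length = .data$rev_end - .data$fwd_start + 1L)
  if (!nrow(pairs)) abort("no productive primer pairing found.")
  ambiguous <- nrow(pairs) > 1
  if (ambiguous) {
    warn(sprintf("%d productive pairings found; all reported.", nrow(pairs)))
  }
  pairs |>
    mutate(ref_id = r$id, ambiguous = ambiguous, .before = 1) |>
    select("ref_id", "fwd_start", "fwd_end", "rev_start", "rev_end",
           "length", "ambiguous")
}

#' Reverse complement of a DNA string
#'
#' @param x Character DNA string(s).
#' @return Reverse complement(s).
#' @export
revcomp_chr <- function(x) revcomp(x)
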