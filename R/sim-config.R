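#' Simulation configuration
#'
#' Builds the configuration object consumed by the synthetic-data
#' generators ([gen_traces()], [gen_ct_table()], [gen_counts()],
#' [gen_annotation()]) and by [simulate_all()]. Defaults encode the study
#' conditions the pipeline is designed around: a scaRNA1-editing
#' experiment with two edited clones ("6A1"-like and "3B2"-like), a
#' wild-type control, qPCR with three technical replicates nested in
#' biological replicates, and transcript-level RNA-seq counts with
#' reciprocal isoform switches.
#'
#' Each block can be partially overridden; unspecified entries keep their
#' defaults. The single `seed` is expanded into independent per-generator
#' substreams so any one artifact can be regenerated on its own.
#'
#' @param seed Integer seed; mandatory, drives every generator substream.
#' @param trace Overrides for the chromatogram-trace block:
#'   `seq_length` (bases, default 600), `peak_width` (Gaussian peak sd in
#'   base units, default 0.5), `amplitude` (peak height, default 1000),
#'   `noise_sd` (additive channel noise as a fraction of amplitude,
#'   default 0.02), `indel_start` (first base affected by the edit,
#'   default 115), and `spectrum`, a named numeric vector mapping indel
#'   size to allele fraction (must sum to 1). The default spectrum is the
#'   compound-deletion profile of an edited clone: deletions of 20, 15,
#'   10 and 5 bp at equal fractions totalling 0.66, plus 0.34 unedited.
#' @param qpcr Overrides for the expression-assay block: `target`,
#'   `normalizer`, `baseline_ct` (named, cycles), `ratios` (named planted
#'   expression ratios per edited group, wild type is 1), `bio_reps`,
#'   `tech_reps`, `noise_sd` (cycles, default 0.15).
#' @param psi Overrides for the pseudouridylation-assay block: `long` and
#'   `short` amplicon ids, `baseline_ct` (named, cycles), `groups` a
#'   tibble-coercible list with `group`, `psi` (true modified fraction)
#'   and `n` (biological replicates) — defaults are control 0.93 (n = 9),
#'   clone A 0.70 (n = 5), clone B 0.88 (n = 6) — plus `tech_reps` and
#'   `noise_sd` (cycles, default 0.15).
#' @param counts Overrides for the count-matrix block: `n_genes` (1000),
#'   `transcripts_per_gene` (2), `samples_per_group` (3),
#'   `mean_log`/`sd_log` (log-normal baseline expression, defaults
#'   log(50) and 1), `lib_factors` (optional named per-sample depth
#'   multipliers), `n_switch` (planted switch genes, 40), `switch_fold`
#'   (reciprocal swap magnitude, 3), `dispersion` (gamma over-dispersion,
#'   0 = pure Poisson).
#' @param annotation Overrides for the annotation block: `n_genes`
#'   (universe size, 1000), `n_categories` (50), `size_range` (category
#'   sizes, uniform in 10–100), `planted_size` (planted category size,
#'   60), `query_size` (100), `odds` (sampling odds multiplier for
#'   planted-category genes in the query, 10).
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, trace = list(noise_sd = 0))
#' cfg$trace$spectrum
sim_config <- function(seed,
                       trace = list(),
                       qpcr = list(),
                       psi = list(),
                       counts = list(),
                       annotation = list()) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` is mandatory and must be a single integer.")
  }
  seed <- as.integer(seed)

  defaults <- list(
    trace = list(
      seq_length = 600,
      peak_width = 0.5,
      amplitude = 1000,
      noise_sd = 0.02,
      indel_start = 115,
      spectrum = c(`0` = 0.34, `-20` = 0.165, `-15` = 0.165,
                   `-10` = 0.165, `-5` = 0.165)
    ),
    qpcr = list(
      target = "scaRNA1",
      normalizer = "RN7SL",
      baseline_ct = c(scaRNA1 = 24, RN7SL = 18),
      ratios = c(cloneA = 0.60, cloneB = 0.53),
      control_group = "WT",
      bio_reps = 3,
      tech_reps = 3,
      noise_sd = 0.15
    ),
    psi = list(
      long = "U2_long",
      short = "U2_short",
      baseline_ct = c(U2_long = 23, U2_short = 22),
      groups = list(group = c("WT", "cloneA", "cloneB"),
                    psi = c(0.93, 0.70, 0.88),
                    n = c(9L, 5L, 6L)),
      tech_reps = 3,
      noise_sd = 0.15
    ),
    counts = list(
      n_genes = 1000,
      transcripts_per_gene = 2,
      samples_per_group = 3,
      mean_log = log(50),
      sd_log = 1,
      lib_factors = NULL,
      n_switch = 40,
      switch_fold = 3,
      dispersion = 0
    ),
    annotation = list(
      n_genes = 1000,
      n_categories = 50,
      size_range = c(10, 100),
      planted_size = 60,
      query_size = 100,
      odds = 10
    )
  )

  cfg <- list(
    seed = seed,
    trace = utils::modifyList(defaults$trace, trace),
    qpcr = utils::modifyList(defaults$qpcr, qpcr),
    psi = utils::modifyList(defaults$psi, psi),
    counts = utils::modifyList(defaults$counts, counts),
    annotation = utils::modifyList(defaults$annotation, annotation)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  tr <- cfg$trace
  if (is.null(names(tr$spectrum)) || any(names(tr$spectrum) == "")) {
    abort("trace$spectrum must be a named vector (names are indel sizes).")
  }
  if (any(tr$spectrum < 0) || abs(sum(tr$spectrum) - 1) > 1e-8) {
    abort("trace$spectrum fractions must be non-negative and sum to 1.")
  }
  sizes <- as.integer(names(tr$spectrum))
  if (anyNA(sizes)) abort("trace$spectrum names must be integer indel sizes.")
  if (any(-sizes >= tr$seq_length - tr$indel_start)) {
    abort("a planted deletion is larger than the sequence downstream of the cut.")
  }
  if (any(cfg$qpcr$ratios <= 0)) abort("qpcr$ratios must be positive.")
  ps <- cfg$psi$groups$psi
  if (any(ps < 0 | ps >= 1)) abort("psi group fractions must lie in [0, 1).")
  if (cfg$counts$transcripts_per_gene < 2 && cfg$counts$n_switch > 0) {
    abort("planted switch genes need at least 2 transcripts per gene.")
  }
  with(cfg$annotation, {
    if (planted_size >= n_genes) abort("planted category must be smaller than the universe.")
  })
  invisible(cfg)
}

# deterministic substream seeds (kept well below 2^31)
sub_seed <- function(seed, stream) {
  (abs(as.integer(seed)) + 97L * stream_index(stream)) %% 2000000011L
}

stream_index <- function(stream) {
  idx <- c(trace = 1L, qpcr = 2L, psi = 3L, counts = 4L, annotation = 5L)
  i <- idx[[stream]]
  if (is.null(i)) abort(paste0("unknown generator stream: ", stream))
  i
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed =", x$seed, "\n")
  cat("  trace: length", x$trace$seq_length, "| spectrum:",
      paste(names(x$trace$spectrum), collapse = ", "), "\n")
  cat("  qpcr ratios:", paste(names(x$qpcr$ratios), round(x$qpcr$ratios, 3),
                              sep = "=", collapse = ", "), "\n")
  cat("  psi fractions:", paste(x$psi$groups$group, x$psi$groups$psi,
                                sep = "=", collapse = ", "), "\n")
  cat("  counts:", x$counts$n_genes, "genes x",
      x$counts$transcripts_per_gene, "tx,", x$counts$n_switch,
      "planted switches\n")
  invisible(x)
}
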