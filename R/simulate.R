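#' Synthetic chromatogram traces with a planted indel spectrum
#'
#' Simulates an aligned pair of Sanger-style traces: a clean control trace
#' rendered from a random reference sequence, and an "edited" trace that is
#' a fraction-weighted mixture of allele traces, each allele carrying one
#' indel applied at `indel_start`, plus additive Gaussian channel noise.
#' Each called base contributes a Gaussian peak (sd `peak_width` in base
#' units) to its own channel, sampled at integer positions, so a deletion
#' of k bases shifts the downstream signal k positions to the left.
#'
#' @param config A [sim_config()] object; the `trace` block is used.
#' @return A list with `control` and `edited` trace tibbles
#'   (`pos`, `A`, `C`, `G`, `T`, `base`) and `truth`, a list echoing the
#'   planted spectrum and the implied editing efficiency
#'   (100 x (1 - unedited fraction)).
#' @export
#' @examples
#' tr <- gen_traces(sim_config(seed = 17, trace = list(
#'   spectrum = c(`0` = 0.5, `-25` = 0.5))))
#' tr$truth$efficiency_pct
gen_traces <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$trace
  set.seed(sub_seed(config$seed, "trace"))

  bases <- c("A", "C", "G", "T")
  seq0 <- sample(bases, p$seq_length, replace = TRUE)
  control_sig <- render_trace(seq0, p$seq_length, p$peak_width, p$amplitude)

  sizes <- as.integer(names(p$spectrum))
  edited_sig <- matrix(0, nrow = p$seq_length, ncol = 4)
  for (i in seq_along(sizes)) {
    aseq <- apply_indel(seq0, sizes[i], p$indel_start, bases)
    edited_sig <- edited_sig +
      p$spectrum[i] * render_trace(aseq, p$seq_length, p$peak_width, p$amplitude)
  }
  if (p$noise_sd > 0) {
    edited_sig <- edited_sig +
      matrix(rnorm(length(edited_sig), 0, p$noise_sd * p$amplitude),
             nrow = p$seq_length)
    edited_sig <- pmax(edited_sig, 0)
  }

  list(
    control = signal_to_trace(control_sig),
    edited = signal_to_trace(edited_sig),
    truth = list(
      spectrum = setNames(as.numeric(p$spectrum), names(p$spectrum)),
      indel_start = p$indel_start,
      efficiency_pct = 100 * (1 - unname(p$spectrum["0"] %|na|% 0))
    )
  )
}

`%|na|%` <- function(x, y) if (length(x) == 0 || is.na(x)) y else x

# place one Gaussian peak per base in its own channel, sampled at integer
# positions; bases beyond the allele's end contribute nothing (signal decays
# to zero there, as at the end of a real read)
render_trace <- function(seq_chars, out_len, peak_width, amplitude) {
  sig <- matrix(0, nrow = out_len, ncol = 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  half <- max(1L, ceiling(5 * peak_width))
  offs <- -half:half
  kern <- amplitude * exp(-offs^2 / (2 * peak_width^2))
  n <- min(length(seq_chars), out_len + half)
  ch <- match(seq_chars, c("A", "C", "G", "T"))
  for (j in seq_along(offs)) {
    i <- seq_len(n)
    pos <- i + offs[j]
    keep <- pos >= 1L & pos <= out_len
    idx <- cbind(pos[keep], ch[i[keep]])
    sig[idx] <- sig[idx] + kern[j]
  }
  sig
}

apply_indel <- function(seq_chars, size, indel_start, bases) {
  L <- length(seq_chars)
  if (size == 0) return(seq_chars)
  if (size < 0) {
    k <- -size
    if (indel_start + k - 1 > L) abort("deletion extends past the sequence end.")
    c(seq_chars[seq_len(indel_start - 1)], seq_chars[(indel_start + k):L])
  } else {
    ins <- sample(bases, size, replace = TRUE)
    head(c(seq_chars[seq_len(indel_start - 1)], ins, seq_chars[indel_start:L]), L)
  }
}

signal_to_trace <- function(sig) {
  base <- c("A", "C", "G", "T")[max.col(sig, ties.method = "first")]
  tibble(pos = seq_len(nrow(sig)),
         A = sig[, 1], C = sig[, 2], G = sig[, 3], T = sig[, 4],
         base = base)
}

#' Synthetic qPCR cycle-threshold tables with planted truth
#'
#' Generates long-format Ct tables for either the expression assay
#' (target + reference gene across a control group and edited clones with
#' planted expression ratios) or the pseudouridylation RT-stop assay
#' (long/short amplicons under CMC-treated and untreated conditions, with
#' planted modified fractions). The generative model is
#' `Ct = baseline - log2(relative template) + N(0, noise_sd)` per technical
#' replicate; for the stop assay, CMC treatment multiplies the long
#' amplicon's template by `(1 - psi)` while untreated reactions and the
#' short internal-control amplicon are unaffected.
#'
#' @param config A [sim_config()] object.
#' @param assay `"expression"` (uses the `qpcr` block) or `"psi"` (uses the
#'   `psi` block).
#' @return A list with `ct`, the Ct tibble (`sample`, `group`, `target`,
#'   `bio_rep`, `tech_rep`, `ct`, plus `condition` for the stop assay),
#'   and `truth`, echoing the planted ratios or modified fractions.
#' @export
gen_ct_table <- function(config, assay = c("expression", "psi")) {
  stopifnot(inherits(config, "sim_config"))
  assay <- match.arg(assay)
  if (assay == "expression") gen_ct_expression(config) else gen_ct_psi(config)
}

gen_ct_expression <- function(config) {
  p <- config$qpcr
  set.seed(sub_seed(config$seed, "qpcr"))
  groups <- c(setNames(1, p$control_group), p$ratios)
  grid <- tidyr::expand_grid(
    group = names(groups),
    target = c(p$target, p$normalizer),
    bio_rep = seq_len(p$bio_reps),
    tech_rep = seq_len(p$tech_reps)
  )
  rel <- ifelse(grid$target == p$target, groups[grid$group], 1)
  ct <- p$baseline_ct[grid$target] - log2(rel) +
    rnorm(nrow(grid), 0, p$noise_sd)
  out <- grid |>
    mutate(sample = paste(.data$group, .data$bio_rep, sep = "_"),
           ct = unname(ct)) |>
    select("sample", "group", "target", "bio_rep", "tech_rep", "ct")
  list(ct = out,
       truth = list(ratios = as.list(groups),
                    target = p$target, normalizer = p$normalizer,
                    control_group = p$control_group))
}

gen_ct_psi <- function(config) {
  p <- config$psi
  set.seed(sub_seed(config$seed, "psi"))
  g <- as_tibble(p$groups)
  grid <- g |>
    mutate(bio = purrr::map(.data$n, seq_len)) |>
    tidyr::unnest("bio") |>
    tidyr::expand_grid(condition = c("untreated", "CMC"),
                       target = c(p$long, p$short),
                       tech_rep = seq_len(p$tech_reps))
  rel <- ifelse(grid$condition == "CMC" & grid$target == p$long,
                1 - grid$psi, 1)
  ct <- p$baseline_ct[grid$target] - log2(rel) +
    rnorm(nrow(grid), 0, p$noise_sd)
  out <- grid |>
    mutate(sample = paste(.data$group, .data$bio, sep = "_"),
           bio_rep = .data$bio, ct = unname(ct)) |>
    select("sample", "group", "condition", "target", "bio_rep",
           "tech_rep", "ct")
  list(ct = out,
       truth = list(psi = setNames(as.list(g$psi), g$group),
                    n = setNames(as.list(g$n), g$group),
                    long = p$long, short = p$short))
}

#' Synthetic transcript count matrix with planted isoform switches
#'
#' Draws baseline per-transcript expression from a log-normal, then counts
#' from a Poisson (optionally gamma-mixed to demonstrate over-dispersion)
#' with per-sample library-depth multipliers. A random subset of genes
#' receives a reciprocal isoform swap in the clone group: one transcript's
#' rate is multiplied by `switch_fold`, a second's divided by it.
#'
#' @param config A [sim_config()] object; the `counts` block is used.
#' @return A list with `counts` (tibble: `transcript_id`, `gene_id`,
#'   `biotype`, then one column per sample), `groups` (tibble: `sample`,
#'   `group`), and `truth` (planted switch gene ids, fold, baselines).
#' @export
gen_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$counts
  set.seed(sub_seed(config$seed, "counts"))

  n_tx <- p$n_genes * p$transcripts_per_gene
  gene_id <- rep(sprintf("G%04d", seq_len(p$n_genes)),
                 each = p$transcripts_per_gene)
  transcript_id <- paste0(gene_id, ".", seq_len(p$transcripts_per_gene))
  mu <- rlnorm(n_tx, p$mean_log, p$sd_log)

  samples <- c(paste0("control_", seq_len(p$samples_per_group)),
               paste0("clone_", seq_len(p$samples_per_group)))
  group <- rep(c("control", "clone"), each = p$samples_per_group)
  lf <- p$lib_factors %||% setNames(rep(1, length(samples)), samples)

  switch_genes <- sort(sample(unique(gene_id), p$n_switch))
  mult <- rep(1, n_tx)
  tx_index <- stats::ave(seq_len(n_tx), gene_id, FUN = seq_along)
  mult[gene_id %in% switch_genes & tx_index == 1] <- p$switch_fold
  mult[gene_id %in% switch_genes & tx_index == 2] <- 1 / p$switch_fold

  cnt <- matrix(0L, nrow = n_tx, ncol = length(samples),
                dimnames = list(transcript_id, samples))
  for (j in seq_along(samples)) {
    rate <- mu * lf[samples[j]] * (if (group[j] == "clone") mult else 1)
    if (p$dispersion > 0) {
      rate <- rate * stats::rgamma(n_tx, shape = 1 / p$dispersion,
                                   scale = p$dispersion)
    }
    cnt[, j] <- rpois(n_tx, rate)
  }

  counts <- bind_cols(
    tibble(transcript_id = transcript_id, gene_id = gene_id,
           biotype = "protein_coding"),
    as_tibble(cnt)
  )
  list(counts = counts,
       groups = tibble(sample = samples, group = group),
       truth = list(switch_genes = switch_genes,
                    switch_fold = p$switch_fold,
                    baseline_means = setNames(mu, transcript_id)))
}

#' Synthetic annotation map and query with a planted enriched category
#'
#' Assigns genes to categories at random (sizes uniform in `size_range`),
#' plants one category of fixed size, then draws a query gene set in which
#' planted-category members are over-sampled by the odds multiplier
#' `odds`, emulating a gene list genuinely enriched for one function.
#'
#' @param config A [sim_config()] object; the `annotation` block is used.
#' @return A list with `annotation` (tibble: `category`, `gene`),
#'   `universe` (character vector), `query` (character vector), and
#'   `truth` (the planted category id and odds).
#' @export
gen_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- config$annotation
  set.seed(sub_seed(config$seed, "annotation"))

  universe <- sprintf("G%04d", seq_len(p$n_genes))
  planted <- "CAT_planted"
  others <- sprintf("CAT%03d", seq_len(p$n_categories - 1))
  sizes <- c(p$planted_size,
             sample(seq(p$size_range[1], p$size_range[2]),
                    p$n_categories - 1, replace = TRUE))
  ids <- c(planted, others)
  annotation <- purrr::map2(ids, sizes, function(id, s) {
    tibble(category = id, gene = sample(universe, s))
  }) |> purrr::list_rbind()

  in_planted <- universe %in% annotation$gene[annotation$category == planted]
  w <- ifelse(in_planted, p$odds, 1)
  query <- sample(universe, p$query_size, prob = w)

  list(annotation = annotation, universe = universe, query = query,
       truth = list(planted_category = planted, odds = p$odds))
}

#' Generate the full synthetic input bundle on disk
#'
#' Runs every generator under one [sim_config()] and writes plain-text
#' artifacts to `out_dir`: control/edited trace TSVs, expression and
#' RT-stop Ct TSVs, the transcript count and sample-group TSVs, the
#' annotation TSV and query gene list, and `truth.json` with every
#' planted parameter. All files are deterministic functions of the config
#' (identical seed, byte-identical output).
#'
#' @param config A [sim_config()] object.
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a named list of the file paths written.
#' @export
simulate_all <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  path <- function(f) file.path(out_dir, f)

  tr <- gen_traces(config)
  expr <- gen_ct_table(config, "expression")
  psi <- gen_ct_table(config, "psi")
  cm <- gen_counts(config)
  ann <- gen_annotation(config)

  write_trace_tsv(tr$control, path("trace_control.tsv"))
  write_trace_tsv(tr$edited, path("trace_edited.tsv"))
  readr::write_tsv(expr$ct, path("ct_expression.tsv"))
  readr::write_tsv(psi$ct, path("ct_psi.tsv"))
  readr::write_tsv(cm$counts, path("counts.tsv"))
  readr::write_tsv(cm$groups, path("groups.tsv"))
  readr::write_tsv(ann$annotation, path("annotation.tsv"))
  writeLines(ann$query, path("query_genes.txt"))
  writeLines(ann$universe, path("universe_genes.txt"))

  truth <- list(seed = config$seed, trace = tr$truth, expression = expr$truth,
                psi = psi$truth, counts = cm$truth["switch_genes"],
                annotation = ann$truth)
  truth$counts$switch_fold <- cm$truth$switch_fold
  jsonlite::write_json(truth, path("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(
    trace_control = path("trace_control.tsv"),
    trace_edited = path("trace_edited.tsv"),
    ct_expression = path("ct_expression.tsv"),
    ct_psi = path("ct_psi.tsv"),
    counts = path("counts.tsv"),
    groups = path("groups.tsv"),
    annotation = path("annotation.tsv"),
    query = path("query_genes.txt"),
    universe = path("universe_genes.txt"),
    truth = path("truth.json")
  ))
}
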