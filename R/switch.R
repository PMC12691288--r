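#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values scaling factors for between-sample
#' normalization of a transcript count matrix: the reference sample is
#' the one whose upper-quartile count fraction is closest to the mean;
#' per sample, M (log2 ratio) and A (average log2 abundance) statistics
#' are computed on transcripts expressed in both members of the pair,
#' symmetrically trimmed (`trim_m` on M, `trim_a` on A), and the factor is
#' 2 to the precision-weighted mean of the retained M values, rescaled so
#' factors have geometric mean 1. Computation is delegated to
#' `edgeR::calcNormFactors(method = "TMM")`, the standard implementation
#' of this estimator.
#'
#' @param counts Count tibble (see [read_counts_tsv()]) or numeric matrix
#'   (transcripts x samples).
#' @param trim_m,trim_a Trim fractions for the M and A statistics
#'   (defaults 0.30 and 0.05).
#' @return A tibble with `sample`, `lib_size`, `norm_factor`.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  m <- if (is.matrix(counts)) counts else counts_matrix(validate_counts(counts))
  lib <- colSums(m)
  if (any(lib <= 0)) abort("every sample must have a positive library size.")
  # reference column as edgeR picks it: upper-quartile count fraction
  # closest to the mean; a sample sharing no expressed transcript with it
  # has no M values at all, and the estimator is undefined for it.
  f75 <- apply(m, 2, function(x) stats::quantile(x / sum(x), 0.75))
  ref <- which.min(abs(f75 - mean(f75)))
  shared <- colSums(m > 0 & m[, ref] > 0)
  if (any(shared == 0)) {
    abort("TMM failed: a sample shares no expressed transcripts with the reference.")
  }
  f <- edgeR::calcNormFactors(m, method = "TMM", refColumn = ref,
                              logratioTrim = trim_m, sumTrim = trim_a)
  tibble(sample = colnames(m), lib_size = unname(lib),
         norm_factor = unname(f))
}

#' Per-transcript differential expression by Poisson likelihood-ratio test
#'
#' Fits, per transcript, the Poisson log-linear model with a two-group
#' indicator and offset `log(lib_size * norm_factor)`, and tests it
#' against the intercept-only model with a 1-df likelihood-ratio test.
#' For this model the maximum-likelihood rates have closed form (group
#' count sums over group offset sums), which is used directly; the
#' equivalence with `glm(family = poisson)` is exercised in the test
#' suite. Fold change is the clone/control rate ratio mapped through the
#' signed convention of [fold_change_signed()]. Transcripts with zero
#' counts in every sample are excluded with a message. When a `biotype`
#' column is present, only `protein_coding` transcripts are tested
#' (library sizes are still computed on the full matrix).
#'
#' A single sample per group is permitted — the test is then driven purely
#' by counting noise — and triggers a prominent warning.
#'
#' @param counts Count tibble or matrix.
#' @param groups Tibble with `sample`, `group` (exactly two groups).
#' @param factors Optional output of [tmm_factors()]; computed if NULL.
#' @param control_group Baseline group id; defaults to `"control"` when
#'   present, otherwise the first group in `groups`.
#' @param alpha Adjusted-p threshold for direction labels (default 0.05).
#' @param fc_threshold Signed fold-change threshold (default 1.5).
#' @return A tibble with `transcript_id`, `gene_id`, `rate_ratio`,
#'   `fold_change`, `lrt`, `p_value`, `q_value`
#'   (Benjamini-Hochberg step-up) and `direction` (`up`/`down`/`ns`).
#' @export
transcript_de <- function(counts, groups, factors = NULL,
                          control_group = NULL,
                          alpha = 0.05, fc_threshold = 1.5) {
  tbl <- if (is.matrix(counts)) {
    tibble(transcript_id = rownames(counts) %||%
             sprintf("tx%05d", seq_len(nrow(counts))),
           gene_id = NA_character_) |>
      bind_cols(as_tibble(counts))
  } else validate_counts(counts)
  m <- counts_matrix(tbl)

  gl <- unique(groups$group)
  if (length(gl) != 2) abort("exactly two sample groups are required.")
  control_group <- control_group %||%
    (if ("control" %in% gl) "control" else gl[1])
  clone_group <- setdiff(gl, control_group)
  smp <- groups$sample
  if (!all(smp %in% colnames(m))) {
    abort("groups table names samples absent from the count matrix.")
  }
  if (min(table(groups$group)) < 2) {
    warn(paste("a group has a single sample: Poisson p-values reflect",
               "counting noise only, not biological variability."))
  }

  if (is.null(factors)) factors <- tmm_factors(m[, smp, drop = FALSE])
  off <- factors$lib_size * factors$norm_factor
  names(off) <- factors$sample

  keep_bio <- if ("biotype" %in% names(tbl)) {
    tbl$biotype == "protein_coding"
  } else rep(TRUE, nrow(tbl))
  nonzero <- rowSums(m[, smp, drop = FALSE]) > 0
  if (any(keep_bio & !nonzero)) {
    inform(sprintf("%d all-zero transcript(s) excluded from testing.",
                   sum(keep_bio & !nonzero)))
  }
  keep <- keep_bio & nonzero

  ctrl_s <- groups$sample[groups$group == control_group]
  clone_s <- groups$sample[groups$group == clone_group]
  y1 <- rowSums(m[keep, ctrl_s, drop = FALSE])
  y2 <- rowSums(m[keep, clone_s, drop = FALSE])
  o1 <- sum(off[ctrl_s])
  o2 <- sum(off[clone_s])

  lam1 <- y1 / o1
  lam2 <- y2 / o2
  lam0 <- (y1 + y2) / (o1 + o2)
  xlogx <- function(y, num, den) ifelse(y == 0, 0, y * log(num / den))
  lrt <- 2 * (xlogx(y1, lam1, lam0) + xlogx(y2, lam2, lam0))
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)

  rate_ratio <- lam2 / lam1
  fc <- dplyr::case_when(
    rate_ratio >= 1 ~ rate_ratio,
    TRUE ~ -1 / rate_ratio
  )
  q <- fdr_step_up(p)
  out <- tibble(
    transcript_id = tbl$transcript_id[keep],
    gene_id = tbl$gene_id[keep],
    rate_ratio = unname(rate_ratio),
    fold_change = unname(fc),
    lrt = unname(lrt),
    p_value = unname(p),
    q_value = unname(q)
  )
  out$direction <- de_direction(out$q_value, out$fold_change,
                                alpha, fc_threshold)
  out
}

de_direction <- function(q, fc, alpha, fc_threshold) {
  dplyr::case_when(
    q < alpha & fc > fc_threshold ~ "up",
    q < alpha & fc < -fc_threshold ~ "down",
    TRUE ~ "ns"
  )
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' FDR step-up correction with enforced monotonicity, capped at 1
#' (delegates to `stats::p.adjust(method = "BH")`; equivalence with the
#' exhaustive min-over-tails definition is exercised in the test suite).
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order.
#' @export
fdr_step_up <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' Call isoform-switch genes
#'
#' Labels each tested transcript up/down/ns by the adjusted-p and signed
#' fold-change thresholds, then calls a gene an isoform switch iff it has
#' at least one significantly upregulated and one significantly
#' downregulated transcript.
#'
#' @param de Output of [transcript_de()] (needs `q_value`, `fold_change`,
#'   `gene_id`).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param fc_threshold Signed fold-change threshold (default 1.5).
#' @return A tibble sorted by `gene_id` with list-columns
#'   `up_transcripts` and `down_transcripts` (both non-empty by
#'   construction) and counts `n_up`, `n_down`.
#' @export
#' @examples
#' sim <- gen_counts(sim_config(seed = 11))
#' de <- transcript_de(sim$counts, sim$groups)
#' calls <- call_switches(de)
#' nrow(calls)
call_switches <- function(de, alpha = 0.05, fc_threshold = 1.5) {
  stopifnot(all(c("gene_id", "q_value", "fold_change") %in% names(de)))
  de$direction <- de_direction(de$q_value, de$fold_change,
                               alpha, fc_threshold)
  de |>
    filter(.data$direction != "ns") |>
    summarise(
      up_transcripts = list(.data$transcript_id[.data$direction == "up"]),
      down_transcripts = list(.data$transcript_id[.data$direction == "down"]),
      .by = "gene_id"
    ) |>
    mutate(n_up = lengths(.data$up_transcripts),
           n_down = lengths(.data$down_transcripts)) |>
    filter(.data$n_up > 0, .data$n_down > 0) |>
    arrange(.data$gene_id)
}
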