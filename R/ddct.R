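#' Per-replicate delta-Ct against a reference gene
#'
#' Averages technical replicates within each biological replicate and
#' subtracts the reference-gene mean from the target mean:
#' `dCt = mean Ct(target) - mean Ct(normalizer)` per (sample, bio_rep).
#'
#' @param ct Long-format Ct tibble (see [read_ct_tsv()]).
#' @param target Target amplicon/gene id.
#' @param normalizer Reference gene id measured in every sample.
#' @return A tibble with `sample`, `group`, `bio_rep`, `delta_ct` and a
#'   `target` attribute recording the target id.
#' @export
#' @examples
#' sim <- gen_ct_table(sim_config(seed = 1), "expression")
#' delta_ct(sim$ct, "scaRNA1", "RN7SL")
delta_ct <- function(ct, target, normalizer) {
  ct <- validate_ct(ct)
  if (!target %in% ct$target) abort(paste0("target not in table: ", target))
  means <- ct |>
    filter(.data$target %in% c(.env$target, .env$normalizer)) |>
    summarise(ct = mean(.data$ct),
              .by = c("sample", "group", "bio_rep", "target")) |>
    tidyr::pivot_wider(names_from = "target", values_from = "ct")
  if (!normalizer %in% names(means) || anyNA(means[[normalizer]])) {
    missing_samples <- means$sample[
      if (normalizer %in% names(means)) is.na(means[[normalizer]]) else TRUE]
    abort(paste0("normalizer `", normalizer, "` missing for sample(s): ",
                 paste(unique(missing_samples), collapse = ", ")))
  }
  out <- means |>
    mutate(delta_ct = .data[[target]] - .data[[normalizer]]) |>
    select("sample", "group", "bio_rep", "delta_ct")
  attr(out, "target") <- target
  out
}

#' Relative expression by the delta-delta-Ct method
#'
#' For each non-calibrator group, `ddCt = mean dCt(group) - mean
#' dCt(calibrator)`; relative expression is `efficiency^-ddCt` (default
#' efficiency 2, perfect doubling); the signed fold change is the ratio
#' itself when at least 1, and `-1/ratio` otherwise, so a 40% reduction
#' (ratio 0.60) reports as -1.67. The p-value comes from [nested_test()]
#' applied to the per-biological-replicate dCt values (technical
#' replicates were already averaged by [delta_ct()]).
#'
#' @param deltas Output of [delta_ct()].
#' @param calibrator_group Group id used as the baseline (e.g. `"WT"`).
#' @param efficiency Amplification efficiency per cycle (default 2).
#' @return A tibble with one row per non-calibrator group: `group`,
#'   `ddct`, `ratio`, `fold_change`, `p_value`, `n_bio`.
#' @export
relative_expression <- function(deltas, calibrator_group, efficiency = 2) {
  if (!calibrator_group %in% deltas$group) {
    abort(paste0("calibrator group not present: ", calibrator_group))
  }
  if (n_distinct(deltas$group) < 2) {
    abort("need at least one non-calibrator group.")
  }
  cal <- deltas$delta_ct[deltas$group == calibrator_group]
  deltas |>
    filter(.data$group != calibrator_group) |>
    summarise(ddct = mean(.data$delta_ct) - mean(cal),
              p_value = welch_p(.data$delta_ct, cal),
              n_bio = dplyr::n(),
              .by = "group") |>
    mutate(ratio = efficiency^-.data$ddct,
           fold_change = fold_change_signed(.data$ratio)) |>
    select("group", "ddct", "ratio", "fold_change", "p_value", "n_bio")
}

#' Signed fold change from an expression ratio
#'
#' Maps a positive expression ratio r to the signed convention used in
#' qPCR reporting: the ratio when it is at least 1 and its negative reciprocal otherwise, so
#' |fold change| >= 1 always and a ratio of 0.60 becomes -1.67.
#'
#' @param ratio Positive expression ratio(s).
#' @return Signed fold change(s).
#' @export
fold_change_signed <- function(ratio) {
  if (any(is.na(ratio)) || any(ratio <= 0)) {
    abort("ratio must be positive.")
  }
  ifelse(ratio >= 1, ratio, -1 / ratio)
}

#' Nested replicate test on delta-Ct values
#'
#' Realizes a two-level nested comparison by its summary-statistic
#' equivalent: technical replicates are averaged within biological
#' replicate, then a two-sided Welch t test is applied to the
#' biological-replicate dCt means of the two groups. A warning is issued
#' when a group has fewer than 3 biological replicates.
#'
#' @param ct Long-format Ct tibble.
#' @param target,normalizer Amplicon ids passed to [delta_ct()].
#' @param groups Character vector of the two group ids to compare.
#' @return Two-sided p-value.
#' @export
nested_test <- function(ct, target, normalizer, groups) {
  stopifnot(length(groups) == 2)
  deltas <- delta_ct(ct, target, normalizer)
  a <- deltas$delta_ct[deltas$group == groups[1]]
  b <- deltas$delta_ct[deltas$group == groups[2]]
  if (length(a) < 2 && length(b) < 2) {
    abort("need at least 2 biological replicates in one group.")
  }
  if (min(length(a), length(b)) < 3) {
    warn("a group has fewer than 3 biological replicates; p-value is fragile.")
  }
  welch_p(a, b)
}

# Welch two-sample two-sided p; constant equal groups give p = 1
welch_p <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) return(NA_real_)
  if (sd(a) == 0 && sd(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  t.test(a, b, var.equal = FALSE)$p.value
}

#' One-call delta-delta-Ct analysis
#'
#' Convenience wrapper chaining [delta_ct()] and [relative_expression()].
#'
#' @inheritParams delta_ct
#' @inheritParams relative_expression
#' @return See [relative_expression()]; a `target` column is prepended.
#' @export
ddct_analysis <- function(ct, target, normalizer, calibrator_group,
                          efficiency = 2) {
  delta_ct(ct, target, normalizer) |>
    relative_expression(calibrator_group, efficiency) |>
    mutate(target = target, .before = 1)
}
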