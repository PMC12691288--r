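#' RT-stop ratio for site-specific pseudouridylation
#'
#' Computes the reverse-transcription stop index R from a CMC-treated vs
#' untreated qPCR design with two amplicons: a long fragment spanning the
#' modified site (its amplification drops when CMC adducts block reverse
#' transcription) and a short fragment downstream that serves as the
#' internal control. With per-cell mean Ct values,
#' \deqn{R = 2^{(\bar{Ct}_{untreated,long} - \bar{Ct}_{CMC,long})} /
#'          2^{(\bar{Ct}_{untreated,short} - \bar{Ct}_{CMC,short})}}
#' Higher R means less pseudouridylation.
#'
#' @param ct Ct tibble with a `condition` column (`"CMC"`/`"untreated"`).
#' @param long,short Amplicon ids of the site-spanning and control
#'   fragments.
#' @param samples Optional sample id(s) to restrict to; default uses all
#'   rows (e.g. one call per sample, or one pooled call per group).
#' @return The RT-stop ratio R (positive scalar).
#' @export
#' @examples
#' sim <- gen_ct_table(sim_config(seed = 2), "psi")
#' rt_stop_ratio(dplyr::filter(sim$ct, group == "WT"))
rt_stop_ratio <- function(ct, long = "U2_long", short = "U2_short",
                          samples = NULL) {
  ct <- validate_ct(ct)
  if (!"condition" %in% names(ct)) {
    abort("RT-stop tables need a `condition` column (CMC / untreated).")
  }
  if (!is.null(samples)) ct <- filter(ct, .data$sample %in% samples)
  cell_mean <- function(cond, tgt) {
    v <- ct$ct[ct$condition == cond & ct$target == tgt]
    if (!length(v)) {
      abort(sprintf("no Ct observations for cell (%s, %s).", cond, tgt))
    }
    mean(v)
  }
  num <- 2^(cell_mean("untreated", long) - cell_mean("CMC", long))
  den <- 2^(cell_mean("untreated", short) - cell_mean("CMC", short))
  num / den
}

#' Percent pseudouridylation from the RT-stop ratio
#'
#' Converts the stop index to a percentage: `100 * (1 - R)`. Ratios above
#' 1 (more amplification after CMC than without) give negative
#' percentages; they are returned as-is with a warning rather than
#' clamped, since clamping would bias downstream group comparisons.
#'
#' @param r_index Positive RT-stop ratio(s).
#' @return Percent pseudouridylation (<= 100).
#' @export
percent_pseudouridylation <- function(r_index) {
  if (any(!is.finite(r_index)) || any(r_index <= 0)) {
    abort("r_index must be positive and finite.")
  }
  if (any(r_index > 1)) {
    warn("R > 1 yields negative percent pseudouridylation; returned unclamped.")
  }
  100 * (1 - r_index)
}

#' Per-sample pseudouridylation estimates
#'
#' Applies [rt_stop_ratio()] and [percent_pseudouridylation()] to each
#' sample of an RT-stop Ct table (technical replicates averaged within
#' the four condition-by-amplicon cells).
#'
#' @inheritParams rt_stop_ratio
#' @return A tibble with `sample`, `group`, `r_index`, `percent_psi`.
#' @export
psi_per_sample <- function(ct, long = "U2_long", short = "U2_short") {
  ct <- validate_ct(ct)
  ct |>
    distinct(.data$sample, .data$group) |>
    mutate(r_index = purrr::map_dbl(.data$sample,
                                    ~ rt_stop_ratio(ct, long, short, .x)),
           percent_psi = suppressWarnings(
             percent_pseudouridylation(.data$r_index)))
}

#' Group comparison of pseudouridylation levels
#'
#' Two-sided Welch t test of each clone group against the control group
#' on per-replicate percent-pseudouridylation values (one value per
#' biological replicate).
#'
#' @param psi_tbl Tibble with `group` and `percent_psi` columns, e.g. from
#'   [psi_per_sample()].
#' @param control_group Id of the reference group.
#' @return A tibble with `group`, `n`, `mean_percent_psi`, `p_value`
#'   (NA for the control row is omitted; only clone rows are returned).
#' @export
compare_psi <- function(psi_tbl, control_group) {
  if (!control_group %in% psi_tbl$group) {
    abort(paste0("control group not present: ", control_group))
  }
  ns <- psi_tbl |> count(.data$group)
  too_small <- ns$group[ns$n < 2]
  if (length(too_small)) {
    abort(paste0("group(s) with fewer than 2 replicates: ",
                 paste(too_small, collapse = ", ")))
  }
  ctrl <- psi_tbl$percent_psi[psi_tbl$group == control_group]
  psi_tbl |>
    filter(.data$group != control_group) |>
    summarise(n = dplyr::n(),
              mean_percent_psi = mean(.data$percent_psi),
              p_value = welch_p(.data$percent_psi, ctrl),
              .by = "group")
}
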