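#' Run the analysis pipeline from a config
#'
#' Executes the enabled stages in dependency order — trace decomposition,
#' expression (delta-delta-Ct), pseudouridylation (RT-stop), isoform
#' switches, then enrichment on the switch genes — communicating only
#' through files so any stage can be re-run standalone. A stage failure
#' halts its dependents but independent stages still run; failures are
#' collected in the report.
#'
#' The config is a YAML file (or equivalent list) with optional blocks
#' `decompose` (`control`, `edited` trace TSVs plus any
#' [tide_decompose()] parameter), `expression` (`ct`, `target`,
#' `normalizer`, `calibrator`), `psi` (`ct`, `long`, `short`,
#' `control_group`), `switch` (`counts`, `groups`, `alpha`,
#' `fc_threshold`) and `enrich` (`annotation`, optional `universe`,
#' optional `query` — defaults to the switch stage's gene calls). Omitted
#' blocks are skipped. Relative paths are resolved against the config
#' file's directory.
#'
#' @param config Path to a YAML config or a named list.
#' @param out_dir Output directory for stage outputs, `report.json` and
#'   `summary.txt`.
#' @return Invisibly, the report list (class `psipipe_report`), with
#'   per-stage summaries and any stage errors under `$failures`.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  base <- if (is.character(config)) dirname(config) else "."
  rel <- function(p) if (is.null(p) || file.exists(p)) p else file.path(base, p)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  report <- list(stages = list(), failures = list())
  log_stage <- function(stage, msg) {
    message(sprintf("[%s] %s", stage, msg))
  }
  try_stage <- function(stage, expr) {
    res <- tryCatch(expr, error = function(e) {
      log_stage(stage, paste("FAILED:", conditionMessage(e)))
      report$failures[[stage]] <<- conditionMessage(e)
      NULL
    })
    if (!is.null(res)) report$stages[[stage]] <<- res
    res
  }

  if (!is.null(cfg$decompose)) {
    try_stage("decompose", {
      d <- cfg$decompose
      ctrl <- read_trace_tsv(rel(d$control))
      ed <- read_trace_tsv(rel(d$edited))
      args <- d[intersect(names(d),
                          setdiff(names(formals(tide_decompose)),
                                  c("control", "edited")))]
      fit <- do.call(tide_decompose, c(list(ctrl, ed), args))
      out <- list(r2 = fit$r2, efficiency_pct = fit$efficiency_pct,
                  efficiency_significant_pct = fit$efficiency_significant_pct,
                  interpretable = fit$interpretable)
      readr::write_tsv(tidy(fit), file.path(out_dir, "indel_spectrum.tsv"))
      log_stage("decompose", sprintf("efficiency %.1f%% (R² %.3f)",
                                     fit$efficiency_pct, fit$r2))
      out
    })
  }

  if (!is.null(cfg$expression)) {
    try_stage("expression", {
      e <- cfg$expression
      ct <- read_ct_tsv(rel(e$ct))
      res <- ddct_analysis(ct, e$target, e$normalizer, e$calibrator,
                           efficiency = e$efficiency %||% 2)
      readr::write_tsv(res, file.path(out_dir, "expression.tsv"))
      log_stage("expression", sprintf("%d group(s) vs %s", nrow(res),
                                      e$calibrator))
      res
    })
  }

  if (!is.null(cfg$psi)) {
    try_stage("psi", {
      p <- cfg$psi
      ct <- read_ct_tsv(rel(p$ct))
      per <- psi_per_sample(ct, p$long %||% "U2_long",
                            p$short %||% "U2_short")
      grp <- per |>
        summarise(n = dplyr::n(),
                  mean_percent_psi = mean(.data$percent_psi),
                  .by = "group") |>
        left_join(compare_psi(per, p$control_group)[, c("group", "p_value")],
                  by = "group")
      readr::write_tsv(per, file.path(out_dir, "psi_per_sample.tsv"))
      readr::write_tsv(grp, file.path(out_dir, "psi_groups.tsv"))
      log_stage("psi", sprintf("%d group(s)", nrow(grp)))
      grp
    })
  }

  switch_res <- NULL
  if (!is.null(cfg$switch)) {
    switch_res <- try_stage("switch", {
      s <- cfg$switch
      counts <- read_counts_tsv(rel(s$counts))
      groups <- read_groups_tsv(rel(s$groups))
      de <- transcript_de(counts, groups,
                          control_group = s$control_group,
                          alpha = s$alpha %||% 0.05,
                          fc_threshold = s$fc_threshold %||% 1.5)
      calls <- call_switches(de, alpha = s$alpha %||% 0.05,
                             fc_threshold = s$fc_threshold %||% 1.5)
      readr::write_tsv(de, file.path(out_dir, "transcript_de.tsv"))
      flat <- calls |>
        mutate(up_transcripts = purrr::map_chr(.data$up_transcripts,
                                               paste, collapse = ","),
               down_transcripts = purrr::map_chr(.data$down_transcripts,
                                                 paste, collapse = ","))
      readr::write_tsv(flat, file.path(out_dir, "switch_genes.tsv"))
      log_stage("switch", sprintf("%d switch gene(s)", nrow(calls)))
      list(n_switch_genes = nrow(calls), genes = calls$gene_id,
           universe = unique(de$gene_id))
    })
  }

  if (!is.null(cfg$enrich)) {
    try_stage("enrich", {
      en <- cfg$enrich
      ann <- read_annotation_tsv(rel(en$annotation))
      query <- if (!is.null(en$query)) readLines(rel(en$query))
               else if (!is.null(switch_res)) switch_res$genes
               else abort("no query: switch stage failed and none supplied.")
      universe <- if (!is.null(en$universe)) readLines(rel(en$universe))
                  else if (!is.null(switch_res)) switch_res$universe
                  else NULL
      res <- enrich(query, ann, universe)
      readr::write_tsv(res, file.path(out_dir, "enrichment.tsv"))
      log_stage("enrich", sprintf("top category %s (score %.2f)",
                                  res$category[1], res$enrichment_score[1]))
      head(res, 10)
    })
  }

  report$n_failures <- length(report$failures)
  class(report) <- "psipipe_report"
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  writeLines(utils::capture.output(print(report)),
             file.path(out_dir, "summary.txt"))
  if (report$n_failures > 0) {
    warn(paste("pipeline finished with failed stage(s):",
               paste(names(report$failures), collapse = ", ")))
  }
  invisible(report)
}

#' @export
print.psipipe_report <- function(x, ...) {
  cat("psipipe run report\n==================\n")
  for (nm in names(x$stages)) {
    cat("\n--", nm, "--\n")
    s <- x$stages[[nm]]
    if (is.data.frame(s)) {
      print(as.data.frame(s), digits = 4, row.names = FALSE)
    } else {
      for (k in names(s)) {
        v <- s[[k]]
        if (length(v) > 12) v <- c(head(v, 12), "...")
        cat(" ", k, ":", paste(format(v, digits = 4), collapse = " "), "\n")
      }
    }
  }
  if (length(x$failures)) {
    cat("\nFAILED stages:\n")
    for (nm in names(x$failures)) cat(" ", nm, ":", x$failures[[nm]], "\n")
  }
  invisible(x)
}
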