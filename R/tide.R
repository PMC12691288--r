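#' Shifted-template bank for indel decomposition
#'
#' Builds the design matrix used by [tide_decompose()]: one column per
#' candidate indel size d in `[-max_indel, +max_indel]`, whose entries are
#' the control trace's four-channel signal shifted by d within the
#' decomposition window. A deletion of k bases (d = -k) moves downstream
#' signal k positions to the left, so the template for d at window
#' position p is the control signal at p - d. The four channels are
#' stacked, giving `4 * length(window)` rows.
#'
#' @param control Control trace tibble (see [read_trace_tsv()]).
#' @param window Closed position interval `c(start, end)` to decompose
#'   over (default 115-560).
#' @param max_indel Largest indel size modelled (default 27).
#' @return A numeric matrix with one named column per indel size.
#' @export
tide_templates <- function(control, window = c(115, 560), max_indel = 27) {
  control <- validate_trace(control)
  sig <- trace_signal(control)
  L <- nrow(sig)
  if (window[2] + max_indel > L) {
    abort(sprintf(paste0("control trace too short: window end %d + max ",
                         "indel %d exceeds trace length %d."),
                  window[2], max_indel, L))
  }
  if (window[1] - max_indel < 1) {
    abort("window start must exceed max_indel.")
  }
  pos <- window[1]:window[2]
  shifts <- (-max_indel):max_indel
  X <- vapply(shifts, function(d) as.vector(sig[pos - d, , drop = FALSE]),
              numeric(length(pos) * 4L))
  colnames(X) <- as.character(shifts)
  X
}

#' Indel-spectrum decomposition of an edited Sanger trace
#'
#' Estimates the indel spectrum of an edited cell population by
#' decomposing the edited trace over shifted copies of a control trace
#' (the approach of indel-tracking-by-decomposition tools). Traces are
#' first rigidly aligned by integer-lag cross-correlation over the
#' pre-cut region `[1, left_boundary]` (an error is raised if no lag
#' reaches 0.9 correlation). The window signal is then fit by
#' non-negativity-constrained least squares on the template bank, the
#' coefficients normalized to sum to one, and per-coefficient p-values
#' obtained by refitting the non-negative active set with ordinary least
#' squares and applying two-sided t tests (an approximation, documented
#' in the methods vignette). Aggregate editing efficiency is
#' `100 * (1 - c0)` with `c0` the normalized zero-shift coefficient; the
#' summed significant-indel fraction is also reported. Fits with
#' R-squared below `r2_gate` are flagged uninterpretable.
#'
#' @param control,edited Trace tibbles of equal length.
#' @param left_boundary Last position of the alignment region (default 100).
#' @param window Decomposition window, closed interval (default 115-560).
#' @param max_indel Largest modelled indel (default 27).
#' @param min_indel_reported Smallest |d| kept by [significant_spectrum()]
#'   (default 2).
#' @param p_threshold Significance level for reported indels (default 0.001).
#' @param r2_gate Minimum R-squared for an interpretable fit (default 0.90).
#' @return An object of class `tide_fit`: coefficient table, R-squared,
#'   efficiency, interpretability flag and echoed parameters. Use
#'   [tidy()] / [glance()] to extract tibbles, [significant_spectrum()]
#'   for the thresholded spectrum.
#' @export
#' @examples
#' tr <- gen_traces(sim_config(seed = 17, trace = list(
#'   spectrum = c(`0` = 0.5, `-25` = 0.5), noise_sd = 0.02)))
#' fit <- tide_decompose(tr$control, tr$edited)
#' glance(fit)
tide_decompose <- function(control, edited,
                           left_boundary = 100,
                           window = c(115, 560),
                           max_indel = 27,
                           min_indel_reported = 2,
                           p_threshold = 0.001,
                           r2_gate = 0.90) {
  control <- validate_trace(control)
  edited <- validate_trace(edited)
  if (window[1] <= left_boundary) {
    abort("window start must lie beyond the left alignment boundary.")
  }
  stopifnot(max_indel >= min_indel_reported, min_indel_reported >= 0,
            p_threshold > 0, p_threshold < 1, r2_gate > 0, r2_gate <= 1)

  aln <- align_traces(control, edited, left_boundary)
  edited_sig <- aln$edited_sig

  X <- tide_templates(control, window, max_indel)
  pos <- window[1]:window[2]
  if (max(pos) > nrow(edited_sig)) {
    abort("edited trace shorter than the decomposition window.")
  }
  y <- as.vector(edited_sig[pos, , drop = FALSE])
  if (all(y == 0)) abort("decomposition window has all-zero signal.")

  nn <- pracma::lsqnonneg(X, y)
  x <- nn$x
  if (sum(x) <= 0) abort("non-negative fit degenerate: all coefficients zero.")
  coefs <- x / sum(x)
  names(coefs) <- colnames(X)

  fitted <- as.vector(X %*% x)
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)

  pvals <- active_set_pvalues(X, y, x)

  shifts <- as.integer(colnames(X))
  coef_tbl <- tibble(
    indel = shifts,
    fraction = unname(coefs),
    p_value = unname(pvals)
  )
  c0 <- coefs[["0"]]
  sig_mask <- coef_tbl$p_value < p_threshold &
    abs(coef_tbl$indel) >= min_indel_reported
  out <- list(
    coefficients = coef_tbl,
    r2 = r2,
    efficiency_pct = 100 * (1 - c0),
    efficiency_significant_pct = 100 * sum(coef_tbl$fraction[sig_mask]),
    interpretable = r2 >= r2_gate,
    lag = aln$lag,
    params = list(left_boundary = left_boundary, window = window,
                  max_indel = max_indel,
                  min_indel_reported = min_indel_reported,
                  p_threshold = p_threshold, r2_gate = r2_gate)
  )
  class(out) <- "tide_fit"
  out
}

# rigid integer-lag alignment on the pre-cut region; returns the possibly
# shifted edited signal and the lag applied
align_traces <- function(control, edited, left_boundary, max_lag = 10) {
  cs <- trace_signal(control)
  es <- trace_signal(edited)
  idx <- seq_len(min(left_boundary, nrow(cs) - max_lag, nrow(es) - max_lag))
  best <- list(lag = 0L, cor = -Inf)
  for (lag in -max_lag:max_lag) {
    shifted <- idx + lag
    ok <- shifted >= 1 & shifted <= nrow(es)
    if (sum(ok) < 10) next
    r <- suppressWarnings(cor(as.vector(cs[idx[ok], ]),
                              as.vector(es[shifted[ok], ])))
    if (is.finite(r) && r > best$cor) best <- list(lag = lag, cor = r)
  }
  if (best$cor < 0.9) {
    abort(sprintf(paste0("traces fail to align upstream of the cut ",
                         "(best correlation %.3f over [1, %d])."),
                  best$cor, left_boundary))
  }
  if (best$lag != 0L) {
    L <- nrow(es)
    src <- seq_len(L) + best$lag
    ok <- src >= 1 & src <= L
    shifted <- matrix(0, nrow = L, ncol = 4)
    shifted[ok, ] <- es[src[ok], ]
    es <- shifted
  }
  list(edited_sig = es, lag = best$lag, cor = best$cor)
}

# two-sided t tests from an OLS refit restricted to the non-negative
# active set; inactive coefficients get p = 1
active_set_pvalues <- function(X, y, x) {
  p <- rep(1, ncol(X))
  active <- which(x > 0)
  if (length(active)) {
    fit <- lm(y ~ 0 + X[, active, drop = FALSE])
    # noise-free traces fit exactly; the perfect-fit warning is expected
    sm <- withCallingHandlers(
      summary(fit)$coefficients,
      warning = function(w) {
        if (grepl("essentially perfect fit", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    p[active] <- sm[, "Pr(>|t|)"]
  }
  names(p) <- colnames(X)
  p
}

#' Thresholded indel spectrum from a decomposition fit
#'
#' Keeps coefficients with p below the fit's significance threshold and
#' |indel| at or above `min_indel_reported`; the zero-shift (unedited)
#' entry is always retained. Fractions are reported as fit, without
#' renormalization.
#'
#' @param fit A `tide_fit` from [tide_decompose()].
#' @param p_threshold,min_indel_reported Override the fit's parameters.
#' @return A tibble with columns `indel`, `fraction`, `p_value`.
#' @export
significant_spectrum <- function(fit,
                                 p_threshold = fit$params$p_threshold,
                                 min_indel_reported =
                                   fit$params$min_indel_reported) {
  stopifnot(inherits(fit, "tide_fit"))
  fit$coefficients |>
    filter(.data$indel == 0 |
             (.data$p_value < p_threshold &
                abs(.data$indel) >= min_indel_reported))
}

#' @export
print.tide_fit <- function(x, ...) {
  cat("<tide_fit>  R² =", signif(x$r2, 4),
      if (x$interpretable) "(interpretable)" else "(below R² gate)", "\n")
  cat("  editing efficiency:", sprintf("%.1f%%", x$efficiency_pct),
      sprintf("(significant indels: %.1f%%)", x$efficiency_significant_pct),
      "\n")
  top <- significant_spectrum(x) |> arrange(desc(.data$fraction))
  print(head(top, 8))
  invisible(x)
}

#' @rdname tide_decompose
#' @param x A `tide_fit` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.tide_fit <- function(x, ...) {
  x$coefficients |>
    mutate(significant = .data$p_value < x$params$p_threshold &
             abs(.data$indel) >= x$params$min_indel_reported)
}

#' @rdname tide_decompose
#' @exportS3Method generics::glance
glance.tide_fit <- function(x, ...) {
  tibble(
    r2 = x$r2,
    efficiency_pct = x$efficiency_pct,
    efficiency_significant_pct = x$efficiency_significant_pct,
    interpretable = x$interpretable,
    lag = x$lag
  )
}
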