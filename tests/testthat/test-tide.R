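# helper: clean single-deletion config
del_cfg <- function(seed, spectrum, noise_sd) {
  sim_config(seed = seed, trace = list(spectrum = spectrum,
                                       noise_sd = noise_sd))
}

test_that("template bank realizes the shift definition", {
  tr <- gen_traces(del_cfg(1, c(`0` = 1), 0))
  X <- tide_templates(tr$control, window = c(115, 560), max_indel = 27)
  sig <- as.matrix(tr$control[, c("A", "C", "G", "T")])
  pos <- 115:560
  # zero-shift column is the window verbatim
  expect_equal(X[, "0"], as.vector(sig[pos, ]))
  # a 2-bp deletion template reads the control 2 positions downstream
  expect_equal(X[, "-2"], as.vector(sig[pos + 2, ]))
  # columns pairwise distinct on a non-repetitive sequence
  expect_equal(anyDuplicated(t(X)), 0L)
})

test_that("template construction rejects a window beyond the trace", {
  tr <- gen_traces(del_cfg(1, c(`0` = 1), 0))
  expect_error(tide_templates(tr$control, window = c(115, 590)),
               "too short")
})

test_that("decomposing a trace against itself gives zero editing", {
  tr <- gen_traces(del_cfg(2, c(`0` = 1), 0))
  fit <- tide_decompose(tr$control, tr$control)
  expect_equal(fit$efficiency_pct, 0, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
  expect_equal(fit$coefficients$fraction[fit$coefficients$indel == 0], 1,
               tolerance = 1e-9)
  expect_true(fit$interpretable)
})

test_that("noise-free two-allele mixtures are recovered exactly", {
  for (case in list(c(`0` = 0.3, `-7` = 0.7),
                    c(`0` = 0.55, `-25` = 0.45),
                    c(`0` = 0.8, `-3` = 0.2))) {
    tr <- gen_traces(del_cfg(5, case, 0))
    # window fully inside the shifted region (junction smear excluded)
    fit <- tide_decompose(tr$control, tr$edited, window = c(120, 560))
    got <- setNames(fit$coefficients$fraction,
                    as.character(fit$coefficients$indel))
    expect_equal(got[names(case)], case, tolerance = 1e-6)
    expect_equal(sum(fit$coefficients$fraction), 1, tolerance = 1e-9)
  }
})

test_that("a 50/50 mixture with a 25-bp deletion is quantified to within 3 points", {
  tr <- gen_traces(del_cfg(17, c(`0` = 0.5, `-25` = 0.5), 0.02))
  fit <- tide_decompose(tr$control, tr$edited)
  c25 <- fit$coefficients$fraction[fit$coefficients$indel == -25]
  expect_equal(c25, 0.50, tolerance = 0.03 / 0.50)
  expect_equal(fit$efficiency_pct, 50, tolerance = 3 / 50)
  expect_gte(fit$r2, 0.95)
})

test_that("random planted spectra are recovered within 3 efficiency points", {
  set.seed(99)
  sizes_pool <- setdiff(-27:10, -1:1)
  for (i in 1:50) {
    k <- sample(1:4, 1)
    sizes <- sample(sizes_pool, k)
    fr <- as.numeric(stats::rgamma(k + 1, 1))  # Dirichlet via gamma
    fr <- fr / sum(fr)
    spectrum <- setNames(c(fr[1], fr[-1]), c("0", sizes))
    sigma <- runif(1, 0, 0.05)
    tr <- gen_traces(del_cfg(1000 + i, spectrum, sigma))
    fit <- tide_decompose(tr$control, tr$edited)
    truth_eff <- 100 * (1 - fr[1])
    expect_lte(abs(fit$efficiency_pct - truth_eff), 3)
    expect_gte(fit$r2, 0.95)
    expect_true(all(fit$coefficients$fraction >= 0))
    expect_equal(sum(fit$coefficients$fraction), 1, tolerance = 1e-9)
  }
})

test_that("fit quality degrades monotonically with injected noise", {
  spectrum <- c(`0` = 0.4, `-12` = 0.6)
  r2s <- vapply(c(0, 0.03, 0.08, 0.15), function(s) {
    tr <- gen_traces(del_cfg(31, spectrum, s))
    tide_decompose(tr$control, tr$edited)$r2
  }, numeric(1))
  expect_true(all(diff(r2s) <= 0))
})

test_that("the R-squared gate controls the interpretable flag", {
  spectrum <- c(`0` = 0.4, `-12` = 0.6)
  tr <- gen_traces(del_cfg(31, spectrum, 0.02))
  fit_hi <- tide_decompose(tr$control, tr$edited, r2_gate = 0.9999)
  fit_lo <- tide_decompose(tr$control, tr$edited, r2_gate = 0.90)
  expect_false(fit_hi$interpretable)
  expect_true(fit_lo$interpretable)
})

test_that("significant_spectrum applies the p and size thresholds", {
  tr <- gen_traces(del_cfg(17, c(`0` = 0.5, `-25` = 0.5), 0.02))
  fit <- tide_decompose(tr$control, tr$edited)
  sig <- significant_spectrum(fit)
  expect_true(all(c(0, -25) %in% sig$indel))
  # any extra retained entries are trace artifacts, not planted alleles
  extra <- setdiff(sig$indel, c(0, -25))
  expect_true(all(abs(sig$fraction[sig$indel %in% extra]) < 0.05))

  # hand-built coefficient table exercises the retention rules directly
  fake <- fit
  fake$coefficients <- tibble::tibble(
    indel = c(-25, -1, 0, 3),
    fraction = c(0.2, 0.3, 0.4, 0.1),
    p_value = c(1, 1e-6, 1e-9, 1)
  )
  kept <- significant_spectrum(fake)
  expect_equal(kept$indel, 0)  # p = 1 excluded; |d| = 1 excluded even at tiny p
})

test_that("misaligned traces are re-registered; unrelated traces abort", {
  tr <- gen_traces(del_cfg(8, c(`0` = 0.6, `-10` = 0.4), 0.01))
  # rigid 3-position shift of the edited trace
  ed <- tr$edited
  sig <- as.matrix(ed[, c("A", "C", "G", "T")])
  shifted <- rbind(matrix(0, 3, 4), sig[1:(nrow(sig) - 3), ])
  ed[, c("A", "C", "G", "T")] <- shifted
  fit <- tide_decompose(tr$control, ed)
  expect_equal(fit$lag, 3L)  # edited content displaced 3 positions downstream
  expect_equal(fit$efficiency_pct, 40, tolerance = 3 / 40)

  other <- gen_traces(del_cfg(909, c(`0` = 1), 0))
  expect_error(tide_decompose(tr$control, other$edited), "fail to align")
})

test_that("degenerate inputs raise informative errors", {
  tr <- gen_traces(del_cfg(2, c(`0` = 1), 0))
  zero <- tr$control
  zero[, c("A", "C", "G", "T")] <- 0
  expect_error(tide_decompose(zero, zero), "all-zero|align")
  expect_error(tide_decompose(tr$control, tr$control, window = c(90, 560)),
               "left alignment boundary")
})

test_that("tidy and glance expose the fit as tibbles", {
  tr <- gen_traces(del_cfg(17, c(`0` = 0.5, `-25` = 0.5), 0.02))
  fit <- tide_decompose(tr$control, tr$edited)
  td <- generics::tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(td$significant[td$indel == -25])
  gl <- generics::glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_named(gl, c("r2", "efficiency_pct", "efficiency_significant_pct",
                     "interpretable", "lag"))
})
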