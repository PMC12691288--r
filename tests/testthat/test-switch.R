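test_that("TMM factors are 1 for identical columns and pure depth changes", {
  set.seed(1)
  x <- rpois(300, 60)
  m_same <- matrix(rep(x, 4), ncol = 4,
                   dimnames = list(NULL, paste0("s", 1:4)))
  f <- tmm_factors(m_same)
  expect_equal(f$norm_factor, rep(1, 4))
  expect_equal(f$lib_size, rep(sum(x), 4))

  # doubling sequencing depth changes the library size, not the factor
  m_depth <- cbind(s1 = x, s2 = 2L * x)
  f2 <- tmm_factors(m_depth)
  expect_equal(f2$norm_factor, c(1, 1), tolerance = 1e-12)
  expect_equal(f2$lib_size[2], 2 * f2$lib_size[1])
})

test_that("untrimmed TMM matches the written-out M/A formula on a spiked pair", {
  set.seed(21)
  for (i in 1:10) {
    base <- rpois(400, rlnorm(400, log(60), 0.7))
    spike <- base
    hot <- sample(400, 25)
    spike[hot] <- spike[hot] * sample(3:8, 25, replace = TRUE)
    m <- cbind(a = base + 1L, b = spike + rpois(400, 5))
    got <- tmm_factors(m, trim_m = 0, trim_a = 0)$norm_factor
    expect_equal(got, tmm_oracle_two_sample(m), tolerance = 1e-10)
  }
})

test_that("TMM rejects empty libraries and disjoint supports", {
  expect_error(tmm_factors(cbind(a = c(0L, 0L), b = c(3L, 4L))),
               "positive library size")
  expect_error(tmm_factors(cbind(a = c(10L, 0L), b = c(0L, 10L))),
               "TMM failed|no expressed")
})

test_that("the Poisson LRT has the expected closed form", {
  groups <- tibble::tibble(sample = c("c1", "k1"),
                           group = c("control", "clone"))
  factors <- tibble::tibble(sample = c("c1", "k1"),
                            lib_size = 1, norm_factor = 1)
  m <- matrix(c(10L, 30L), nrow = 1,
              dimnames = list("tx1", c("c1", "k1")))
  expect_warning(
    de <- transcript_de(m, groups, factors = factors),
    "single sample")
  expect_equal(de$lrt, 10.46, tolerance = 5e-4)
  expect_equal(de$p_value, 0.0012, tolerance = 2e-2)
  expect_equal(de$rate_ratio, 3)
  expect_equal(de$fold_change, 3)

  # equal counts at equal offsets: no evidence at all
  m0 <- matrix(c(25L, 25L), nrow = 1,
               dimnames = list("tx1", c("c1", "k1")))
  de0 <- suppressWarnings(transcript_de(m0, groups, factors = factors))
  expect_equal(de0$lrt, 0)
  expect_equal(de0$p_value, 1)
  expect_equal(de0$rate_ratio, 1)
})

test_that("the closed-form LRT agrees with the glm fit on random instances", {
  set.seed(33)
  samples <- c("c1", "c2", "c3", "k1", "k2")
  groups <- tibble::tibble(sample = samples,
                           group = rep(c("control", "clone"), c(3, 2)))
  for (i in 1:30) {
    lib <- runif(5, 0.5e6, 2e6)
    factors <- tibble::tibble(sample = samples, lib_size = lib,
                              norm_factor = 1)
    y <- rpois(5, runif(1, 5, 400) * lib / 1e6 *
                 ifelse(groups$group == "clone", runif(1, 0.2, 5), 1))
    if (sum(y) == 0) next
    m <- matrix(y, nrow = 1, dimnames = list("tx1", samples))
    de <- suppressWarnings(transcript_de(m, groups, factors = factors))
    expect_equal(de$lrt, poisson_lrt_glm(y, groups$group, lib),
                 tolerance = 1e-8)
  }
})

test_that("non-coding transcripts and all-zero rows are excluded from testing", {
  groups <- tibble::tibble(sample = c("c1", "c2", "k1", "k2"),
                           group = rep(c("control", "clone"), each = 2))
  counts <- tibble::tibble(
    transcript_id = c("t1", "t2", "t3"),
    gene_id = c("g1", "g1", "g2"),
    biotype = c("protein_coding", "lncRNA", "protein_coding"),
    c1 = c(50L, 500L, 0L), c2 = c(55L, 480L, 0L),
    k1 = c(48L, 5L, 0L), k2 = c(52L, 8L, 0L)
  )
  expect_message(de <- transcript_de(counts, groups), "all-zero")
  expect_equal(de$transcript_id, "t1")
})

test_that("p-values are near-uniform when nothing is planted", {
  sim <- gen_counts(sim_config(seed = 5, counts = list(n_switch = 0)))
  de <- transcript_de(sim$counts, sim$groups)
  d <- suppressWarnings(
    stats::ks.test(de$p_value, "punif"))$statistic
  expect_lt(as.numeric(d), 0.05)
  expect_equal(nrow(de), 2000L)
})

test_that("BH step-up matches worked examples and the literal definition", {
  expect_equal(fdr_step_up(c(0.002, 0.01, 0.03, 0.04)),
               c(0.008, 0.02, 0.04, 0.04))
  expect_equal(fdr_step_up(rep(1, 5)), rep(1, 5))
  expect_equal(fdr_step_up(0.37), 0.37)
  expect_error(fdr_step_up(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(fdr_step_up(c(0.1, NA)), "\\[0, 1\\]")

  set.seed(8)
  for (i in 1:1000) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(fdr_step_up(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("switch calls require one significant transcript in each direction", {
  de <- tibble::tibble(
    transcript_id = paste0("t", 1:8),
    gene_id = rep(c("gA", "gB", "gC", "gD"), each = 2),
    fold_change = c(3, -3,   3, 3,   -3, -3,   1.5, -3),
    q_value = c(0.001, 0.001,  0.001, 0.001,
                0.001, 0.001,  0.001, 0.001)
  )
  calls <- call_switches(de)
  # gA: up + down; gB: both up; gC: both down; gD: fc exactly at the
  # threshold is not "up" (strict inequality)
  expect_equal(calls$gene_id, "gA")
  expect_equal(calls$n_up, 1L)
  expect_equal(calls$n_down, 1L)
  expect_equal(calls$up_transcripts[[1]], "t1")
  expect_equal(calls$down_transcripts[[1]], "t2")

  # q at the alpha boundary is not significant (strict inequality)
  de2 <- dplyr::mutate(de, q_value = ifelse(gene_id == "gA", 0.05, q_value))
  expect_equal(nrow(call_switches(de2, alpha = 0.05)), 0L)
  expect_equal(call_switches(de2, alpha = 0.06)$gene_id, "gA")
})

test_that("results are invariant to sample order and count rescaling", {
  sim <- gen_counts(sim_config(seed = 14))
  de1 <- transcript_de(sim$counts, sim$groups)

  # permute the sample rows/columns
  perm <- c(4, 1, 6, 3, 2, 5)
  groups_p <- sim$groups[perm, ]
  counts_p <- sim$counts[, c("transcript_id", "gene_id", "biotype",
                             groups_p$sample)]
  de2 <- transcript_de(counts_p, groups_p)
  expect_equal(de1$p_value, de2$p_value)
  expect_equal(de1$rate_ratio, de2$rate_ratio)

  # multiplying every count by an integer leaves rate ratios unchanged
  counts_k <- dplyr::mutate(
    sim$counts, dplyr::across(dplyr::where(is.numeric), \(x) 7L * x))
  de3 <- transcript_de(counts_k, sim$groups)
  expect_equal(de3$rate_ratio, de1$rate_ratio, tolerance = 1e-12)
})

test_that("planted isoform switches are recovered with few false calls", {
  sim <- gen_counts(sim_config(seed = 11))
  de <- transcript_de(sim$counts, sim$groups)
  calls <- call_switches(de)
  truth <- sim$truth$switch_genes
  sens <- mean(truth %in% calls$gene_id)
  false_calls <- setdiff(calls$gene_id, truth)
  expect_gte(sens, 0.90)
  expect_lte(length(false_calls), ceiling(0.05 * nrow(calls)))
})
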