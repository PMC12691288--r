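proto <- "GATTACAGATTACAGATTAC"
# CCT upstream so the same locus is discoverable from the antisense side
toy_ref <- paste0(strrep("T", 7), "CCT", proto, "AGG", strrep("C", 27))

test_that("exact protospacer hits are found on both strands at the same locus", {
  h <- find_protospacer(toy_ref, proto)
  h <- h[h$strand == "sense", ]
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 11L)
  expect_equal(h$end, 30L)
  expect_equal(h$pam, "AGG")

  # searching the reverse complement finds the same locus, antisense
  h2 <- find_protospacer(toy_ref, revcomp_chr(proto))
  h2 <- h2[h2$strand == "antisense", ]
  expect_equal(nrow(h2), 1L)
  expect_equal(c(h2$start, h2$end), c(11L, 30L))
})

test_that("cut sites sit 3 bp upstream of the PAM on the protospacer strand", {
  h <- find_protospacer(toy_ref, proto)
  h <- cut_site(h[h$strand == "sense", ], nchar(toy_ref))
  expect_equal(h$cut_site, 28L)  # pam_start 31 - 3

  # a cut landing outside the reference triggers the bounds check
  h3 <- tibble::tibble(ref_id = "x", start = 4L, end = 23L,
                       strand = "sense", pam_start = 2L, pam_end = 4L,
                       pam = "AGG")
  expect_error(cut_site(h3, 23L), "out of bounds")
})

test_that("cut coordinates mirror under reference reverse-complement", {
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  for (i in 1:200) {
    L <- 500
    ref <- sample(bases, L, replace = TRUE)
    g <- sample(bases, 20, replace = TRUE)
    pos <- sample(50:(L - 50), 1)
    ref[pos:(pos + 19)] <- g
    ref[(pos + 20):(pos + 22)] <- c(sample(bases, 1), "G", "G")
    ref_chr <- paste(ref, collapse = "")
    h <- suppressWarnings(find_protospacer(ref_chr, paste(g, collapse = ""),
                                           max_hits = 5))
    if (nrow(h) != 1) next  # chance second hit: skip the rare ambiguous draw
    cut <- cut_site(h, L)$cut_site
    h2 <- suppressWarnings(find_protospacer(revcomp_chr(ref_chr),
                                            paste(g, collapse = ""),
                                            max_hits = 5))
    if (nrow(h2) != 1) next
    cut2 <- cut_site(h2, L)$cut_site
    expect_equal(cut2, L - cut + 1L)
  }
})

test_that("degenerate matching: N in pattern is a wildcard, N in reference is inert", {
  # NGG PAM accepts any PAM first base
  for (p1 in c("A", "C", "G", "T")) {
    ref <- paste0(strrep("T", 10), proto, p1, "GG", strrep("C", 27))
    h <- find_protospacer(ref, proto)
    expect_equal(nrow(h[h$strand == "sense", ]), 1L)
  }
  # an N inside the reference protospacer region kills the hit
  ref_n <- paste0(strrep("T", 10), sub("C", "N", proto), "AGG", strrep("C", 27))
  expect_warning(h <- find_protospacer(ref_n, proto), "no protospacer hit")
  expect_equal(nrow(h), 0L)
})

test_that("hits at zero mismatches reconstruct the query exactly", {
  set.seed(7)
  bases <- c("A", "C", "G", "T")
  for (i in 1:50) {
    g <- paste(sample(bases, 20, replace = TRUE), collapse = "")
    site <- paste0(g, sample(bases, 1), "GG")
    if (runif(1) < 0.5) site <- revcomp_chr(site)
    ref <- paste0(paste(sample(bases, sample(20:120, 1), TRUE), collapse = ""),
                  site,
                  paste(sample(bases, sample(20:120, 1), TRUE), collapse = ""))
    h <- suppressWarnings(find_protospacer(ref, g, max_hits = 20))
    if (!nrow(h)) next
    for (j in seq_len(nrow(h))) {
      seen <- substr(ref, h$start[j], h$end[j])
      if (h$strand[j] == "antisense") seen <- revcomp_chr(seen)
      expect_identical(seen, g)
      expect_match(h$pam[j], "^[ACGT]GG$")
    }
  }
})

test_that("too many hits raise an ambiguity error naming the count", {
  ref <- strrep(paste0(proto, "AGG"), 4)
  expect_error(find_protospacer(ref, proto, max_hits = 2), "4 hits")
})

test_that("in-silico PCR sizes amplicons per the closed-coordinate rule", {
  set.seed(11)
  ref <- paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE),
               collapse = "")
  # end-to-end amplicon
  amp <- insilico_pcr(ref, substr(ref, 1, 20), revcomp_chr(substr(ref, 81, 100)))
  expect_equal(amp$length, 100L)
  # internal amplicon
  amp2 <- insilico_pcr(ref, substr(ref, 1, 20), revcomp_chr(substr(ref, 41, 60)))
  expect_equal(amp2$length, 60L)
})

test_that("amplicon lengths agree with a naive substring-search oracle", {
  set.seed(23)
  bases <- c("A", "C", "G", "T")
  for (i in 1:30) {
    ref <- paste(sample(bases, 400, replace = TRUE), collapse = "")
    a <- sample(1:150, 1)
    b <- sample(220:380, 1)
    fwd <- substr(ref, a, a + 17)
    rev_site <- substr(ref, b - 17, b)
    amp <- insilico_pcr(ref, fwd, revcomp_chr(rev_site))
    if (amp$ambiguous[1]) next
    expect_equal(amp$fwd_start, naive_find(ref, fwd))
    expect_equal(amp$length,
                 naive_find(ref, rev_site) + nchar(rev_site) - 1L -
                   naive_find(ref, fwd) + 1L)
  }
})

test_that("PCR failure modes: no pairing errors, multiple pairings are flagged", {
  ref <- paste0(strrep("A", 30), "CCTGACCTTGAACCTGAGGA", strrep("T", 50))
  expect_error(insilico_pcr(ref, "CCTGACCTTGAACCTGAGGA",
                            "GGGGGGGGGGGGGGGG"),
               "no productive")
  # duplicated reverse site -> two pairings, ambiguity flagged
  site <- "CCTGACCTTGAACCTGAGGA"
  ref2 <- paste0(site, strrep("A", 20), "TTTTGGGGCCCCAAAATTTT",
                 strrep("C", 10), "TTTTGGGGCCCCAAAATTTT")
  expect_warning(
    amp <- insilico_pcr(ref2, site, revcomp_chr("TTTTGGGGCCCCAAAATTTT")),
    "2 productive")
  expect_equal(nrow(amp), 2L)
  expect_true(all(amp$ambiguous))
})

test_that("locate_guides runs a guide sheet end to end", {
  guides <- tibble::tibble(name = c("g1", "g2"),
                           sequence = c(proto, revcomp_chr(proto)))
  res <- locate_guides(toy_ref, guides)
  expect_true(all(c("name", "cut_site") %in% names(res)))
  expect_setequal(unique(res$name), c("g1", "g2"))
})
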