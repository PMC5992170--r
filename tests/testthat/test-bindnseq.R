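construct <- library_construct()

test_that("the default construct reproduces the printed library layout", {
  expect_identical(paste0(construct$flank5, strrep("N", 10),
                          construct$flank3),
                   "CTTTATCCAGCCCTCACNNNNNNNNNNCTATAGTGTCACCTAAATC")
})

test_that("anchored trimming keeps exact-length inserts and tallies the rest", {
  good <- paste0(construct$flank5, "TTAGGGTTAG", construct$flank3)
  short <- paste0(construct$flank5, "TTAGGGTTA", construct$flank3)
  long <- paste0(construct$flank5, "TTAGGGTTAGA", construct$flank3)
  noflank <- strrep("A", nchar(good))
  one_mm <- paste0(sub("^C", "A", construct$flank5), "ACGTACGTAC",
                   construct$flank3)
  two_mm <- paste0(sub("^CT", "AG", construct$flank5), "ACGTACGTAC",
                   construct$flank3)

  res <- trim_and_filter(c(good, short, long, noflank, one_mm, two_mm),
                         construct)
  expect_identical(res$inserts, c("TTAGGGTTAG", "ACGTACGTAC"))
  expect_identical(res$rejected[["flank"]], 2L)  # noflank, two_mm
  expect_identical(res$rejected[["length"]], 2L) # short, long
  expect_identical(res$n_input, 6L)

  # stricter flank matching drops the 1-mismatch read too
  strict <- trim_and_filter(c(good, one_mm), construct,
                            max_flank_mismatch = 0)
  expect_identical(strict$inserts, "TTAGGGTTAG")

  # reads shorter than the flanks are flank-rejected, not an error
  stub <- trim_and_filter("ACGT", construct)
  expect_identical(length(stub$inserts), 0L)
  expect_identical(stub$rejected[["flank"]], 1L)
})

test_that("position matrix counts, normalises and scores information", {
  m <- position_base_matrix(c("A", "C", "G", "T"))
  expect_equal(unname(m$freq[, 1]), rep(0.25, 4))
  expect_equal(m$bits, 0)

  m2 <- position_base_matrix(rep("TTAGGGTTAG", 10))
  tb <- strsplit("TTAGGGTTAG", "")[[1]]
  expect_equal(unname(m2$freq[cbind(tb, 1:10)]), rep(1, 10))
  expect_equal(m2$bits, rep(2, 10))

  m3 <- position_base_matrix(c(rep("AA", 6), rep("CA", 4)))
  expect_equal(unname(m3$freq[c("A", "C"), 1]), c(0.6, 0.4))
  expect_equal(colSums(m3$freq), c(`1` = 1, `2` = 1))

  expect_error(position_base_matrix(c("AC", "ACG")), "mixed")
  expect_error(position_base_matrix(character(0)), "no inserts")
})

test_that("logo information content matches the closed form", {
  expect_equal(logo_information(matrix(c(0.5, 0.5, 0, 0), 4)), 1)
  expect_equal(logo_information(matrix(c(0.5, 0.25, 0.25, 0), 4)), 0.5)
  f <- matrix(c(0.7, 0.1, 0.1, 0.1), 4)
  expect_equal(logo_information(f),
               2 + sum(f * log2(f)))
  expect_error(logo_information(matrix(c(0.5, 0.5, 0.5, 0), 4)), "sum")
})

test_that("exact test equals brute-force hypergeometric enumeration", {
  expect_equal(exact_enrichment_test(5, 5, 0, 5), 1 / choose(10, 5))
  expect_equal(exact_enrichment_test(1, 2, 1, 2), 1 - 1 / choose(4, 2))
  expect_equal(exact_enrichment_test(0, 5, 5, 5), 1)

  # oracle equivalence on every table with totals <= 12
  for (ts in 1:12) for (tb in 1:(12 - ts + 1)) {
    if (ts + tb > 12) next
    for (cs in 0:ts) for (cb in 0:tb) {
      expect_equal(exact_enrichment_test(cs, ts, cb, tb),
                   enumerate_enrichment_p(cs, ts, cb, tb),
                   tolerance = 1e-12,
                   info = paste(cs, ts, cb, tb))
    }
  }
  expect_error(exact_enrichment_test(-1, 5, 0, 5), "non-negative")
  expect_error(exact_enrichment_test(6, 5, 0, 5), "exceed")
})

test_that("exact test agrees with one-sided fisher.test", {
  set.seed(19)
  for (i in 1:20) {
    ts <- sample(5:40, 1); tb <- sample(5:40, 1)
    cs <- sample(0:ts, 1); cb <- sample(0:tb, 1)
    ft <- stats::fisher.test(matrix(c(cs, ts - cs, cb, tb - cb), 2,
                                    byrow = TRUE),
                             alternative = "greater")
    expect_equal(exact_enrichment_test(cs, ts, cb, tb), ft$p.value,
                 tolerance = 1e-9)
  }
})

test_that("kmer enrichment ranks a spiked motif first with a tiny p", {
  set.seed(23)
  rand <- replicate(100, random_target(10))
  selected <- c(rep("TTAGGGTTAG", 90), rand[1:10])
  res <- kmer_enrichment(selected, rand, k = 10)
  expect_identical(res$kmer[1], "TTAGGGTTAG")
  expect_identical(res$count_selected[1],
                   90L + sum(rand[1:10] == "TTAGGGTTAG"))
  expect_identical(res$total_selected[1], 100L)
  expect_equal(res$p_value[1],
               enumerate_enrichment_p(res$count_selected[1], 100,
                                      res$count_background[1], 100))
  expect_equal(res$e_value, res$p_value * nrow(res))
  expect_true(all(res$e_value >= res$p_value))
})

test_that("identical pools show no significant enrichment", {
  set.seed(29)
  pool <- replicate(60, random_target(10))
  res <- kmer_enrichment(pool, pool, k = 10)
  expect_true(all(res$e_value >= 0.05))
})

test_that("kmer enrichment is invariant to read order and window-counts k < L", {
  set.seed(31)
  sel <- replicate(40, random_target(10))
  bg <- replicate(40, random_target(10))
  a <- kmer_enrichment(sel, bg, k = 6)
  b <- kmer_enrichment(sample(sel), sample(bg), k = 6)
  expect_identical(a, b)
  # 5 windows of width 6 per 10-nt insert
  expect_identical(a$total_selected[1], 40L * 5L)
  expect_error(kmer_enrichment(sel, bg, k = 11), "exceeds")
})
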