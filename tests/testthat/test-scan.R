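test_that("intervals without the operator core yield no hits", {
  m <- default_sos_matrix()
  g <- genome_record("polyA", strrep("A", 500))
  expect_equal(nrow(scan_region(m, g)), 0L)
  # interval shorter than the motif is empty, not an error
  g2 <- make_plain_genome(len = 100L)
  expect_equal(nrow(scan_region(m, g2, interval = c(10L, 20L))), 0L)
})

test_that("a planted consensus box gives one deduplicated zero-HI hit", {
  m <- default_sos_matrix()
  g <- plant(make_plain_genome(len = 1000L, seed = 11), 100L, m$consensus)
  hits <- scan_region(m, g)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 100L)
  expect_equal(hits$end, 120L)
  expect_equal(hits$hi, 0)
  # the box is palindromic: both strands tie and the + orientation is kept
  expect_equal(hits$strand, "+")
  expect_equal(hits$sequence, m$consensus)
})

test_that("planted designed boxes are recovered at their designed HI", {
  m <- default_sos_matrix()
  b5 <- design_sequence_for_hi(m, 5, seed = 1)
  b18 <- design_sequence_for_hi(m, 18, seed = 2)
  g <- plant(plant(make_plain_genome(len = 2000L, seed = 12), 300L, b5), 1200L, b18)
  hits <- scan_region(m, g)
  expect_equal(hits$start, c(300L, 1200L))
  expect_true(all(abs(hits$hi - c(5, 18)) <= 0.5))
})

test_that("hi_cap and mismatch allowance control candidacy", {
  m <- default_sos_matrix()
  b5 <- design_sequence_for_hi(m, 5, seed = 3)
  b18 <- design_sequence_for_hi(m, 18, seed = 4)
  g <- plant(plant(make_plain_genome(len = 2000L, seed = 13), 300L, b5), 1200L, b18)
  capped <- scan_region(m, g, hi_cap = 10)
  expect_equal(capped$start, 300L)

  # break one core base: invisible at allowance 0, found at allowance 1
  broken <- b5
  substr(broken, 3, 3) <- "A"
  g2 <- plant(make_plain_genome(len = 1000L, seed = 14), 400L, broken)
  expect_equal(nrow(scan_region(m, g2)), 0L)
  relaxed <- scan_region(m, g2, mismatch_allowance = 1L)
  expect_equal(relaxed$start, 400L)
})

test_that("windows containing N are skipped", {
  m <- default_sos_matrix()
  box <- m$consensus
  substr(box, 10, 10) <- "N"
  g <- plant(make_plain_genome(len = 600L, seed = 15), 200L, box)
  expect_equal(nrow(scan_region(m, g)), 0L)
})

test_that("scan_region agrees with the brute-force all-windows oracle", {
  m <- default_sos_matrix()
  for (i in 1:10) {
    s <- random_seq(5000, seed = 400 + i)
    # plant a couple of designed boxes so agreement is non-vacuous
    g <- plant(plant(genome_record("r", s), 1000L,
                     design_sequence_for_hi(m, 6, seed = i)),
               3000L, design_sequence_for_hi(m, 21, seed = 100 + i))
    hits <- scan_region(m, g)
    oracle <- brute_scan(m, g$sequence)
    expect_equal(hits$start, oracle$start)
    expect_equal(hits$strand, oracle$strand)
    expect_equal(hits$hi, oracle$hi, tolerance = 1e-12)
  }
})

test_that("circular scanning finds an operator spanning the origin", {
  m <- default_sos_matrix()
  g0 <- make_plain_genome(len = 800L, seed = 16)
  # place the box across the origin: last 12 bases + first 8 bases
  s <- g0$sequence
  substr(s, 800 - 12 + 1, 800) <- substr(m$consensus, 1, 12)
  substr(s, 1, 8) <- substr(m$consensus, 13, 20)
  g <- genome_record("circ", s)
  expect_equal(nrow(scan_region(m, g)), 0L)  # linear scan misses it
  hits <- scan_region(m, g, circular = TRUE)
  expect_equal(hits$start, 788L)
  expect_equal(hits$hi, 0)
})

test_that("promoter-scope surveys deduplicate hits shared by overlapping windows", {
  m <- default_sos_matrix()
  cds <- tibble::tibble(feature_id = c("a", "b"),
                        start = c(500L, 560L), end = c(530L, 590L),
                        strand = c("+", "+"),
                        product = NA_character_, translation = NA_character_)
  g <- plant(make_plain_genome(len = 1200L, cds = cds, seed = 17),
             300L, m$consensus)
  hits <- survey_psbs(g, m, scope = "promoters")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 300L)
  # whole-genome scope sees the same operator set here
  expect_equal(survey_psbs(g, m)$start, hits$start)
})
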