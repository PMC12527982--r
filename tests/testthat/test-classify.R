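test_that("the induction trichotomy has inclusive boundaries", {
  prof <- fake_profile(hi_c1 = 10, hi_c2 = 20)
  expect_equal(classify_induction(10, prof), "SdP")   # at hi_c1
  expect_equal(classify_induction(9.99, prof), "SdP")
  expect_equal(classify_induction(10.01, prof), "SuP")
  expect_equal(classify_induction(19.99, prof), "SuP")
  expect_equal(classify_induction(20, prof), "SiP")   # at hi_c2
  expect_equal(classify_induction(25, prof), "SiP")
  expect_equal(classify_induction(NA_real_, prof), "SiP")  # no operator at all
})

test_that("classification is refused when the host profile is not OK", {
  bad <- fake_profile(NA, NA, status = "NO_CSB")
  expect_error(classify_induction(5, bad), "NO_CSB")
})

test_that("the label is a monotone step function of hi_min", {
  prof <- fake_profile(hi_c1 = 10, hi_c2 = 20)
  grid <- seq(0, 30, by = 0.25)
  labels <- vapply(grid, classify_induction, character(1), profile = prof)
  rank <- c(SdP = 1L, SuP = 2L, SiP = 3L)
  expect_true(all(diff(rank[labels]) >= 0))
  expect_setequal(unique(labels), c("SdP", "SuP", "SiP"))
})

test_that("prophage hi_min recovers designed operators and flags empty promoters", {
  fx <- shared_fixture()
  m <- default_sos_matrix()
  designed <- fx$regions$designed_hi_min
  for (i in seq_len(nrow(fx$regions))) {
    res <- prophage_hi_min(fx$genome, fx$regions[i, ], m)
    expect_true(abs(res$hi_min - designed[i]) <= 0.5)
    expect_gte(res$n_psbs, 1L)
  }
  # a region devoid of CDS annotations warns and yields NA
  bare <- make_plain_genome(len = 2000L)
  expect_warning(
    res <- prophage_hi_min(bare, list(prophage_id = "x", start = 0L, end = 1000L), m),
    "no CDS")
  expect_true(is.na(res$hi_min))
  expect_equal(res$n_psbs, 0L)
})

test_that("end-to-end classification reproduces the planted truth labels", {
  fx <- shared_fixture()
  prof <- build_host_profile(fx$genome)
  calls <- classify_prophages(fx$genome, fx$regions, prof)
  expect_equal(calls$class, vapply(fx$truth$prophages, `[[`, character(1),
                                   "truth_label"))
  expect_false(any(calls$no_psb_flag))
  expect_true(all(calls$host_status == "OK"))

  # a prophage without any operator is called SiP with the no-PSB flag
  spec <- fixture_spec(seed = 77, prophages = list(
    list(designed_hi_min = NA, truth_label = "SiP"),
    list(designed_hi_min = 4, truth_label = "SdP")))
  fx2 <- generate_fixture(spec, withr::local_tempdir())
  prof2 <- build_host_profile(fx2$genome)
  calls2 <- classify_prophages(fx2$genome, fx2$regions, prof2)
  expect_equal(calls2$class, c("SiP", "SdP"))
  expect_equal(calls2$no_psb_flag, c(TRUE, FALSE))
  expect_true(is.na(calls2$hi_min[1]))
})

test_that("hosts that cannot be profiled yield NA calls, not forced labels", {
  fx <- shared_fixture()
  g <- fx$genome
  g$cds <- g$cds[g$cds$feature_id != "lexA", , drop = FALSE]
  prof <- build_host_profile(g)
  calls <- classify_prophages(g, fx$regions, prof)
  expect_true(all(is.na(calls$class)))
  expect_true(all(calls$host_status == "NO_LEXA"))
})

test_that("class summaries count and round as reported percentages", {
  # one call of each class: thirds that sum to 99.99 under 2-decimal rounding
  calls <- tibble::tibble(class = c("SdP", "SiP", "SuP"))
  s <- summarize_calls(calls)
  expect_equal(c(s$pct_sdp, s$pct_sip, s$pct_sup), rep(33.33, 3))
  expect_equal(s$pct_sdp + s$pct_sip + s$pct_sup, 99.99)

  single <- summarize_calls(tibble::tibble(class = "SdP"))
  expect_equal(single$pct_sdp, 100)
  expect_equal(single$n_sip, 0L)

  empty <- summarize_calls(tibble::tibble(class = character()))
  expect_true(empty$empty_flag)
  expect_equal(empty$pct_sdp, 0)

  na_mixed <- summarize_calls(tibble::tibble(class = c("SdP", NA, "SiP")))
  expect_equal(na_mixed$n_na, 1L)
  expect_equal(na_mixed$pct_sdp, 50)
})
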