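test_that("find_lexa recovers the planted lexA and rejects genomes without it", {
  fx <- shared_fixture()
  lex <- find_lexa(fx$genome)
  expect_equal(lex$feature_id, "lexA")
  expect_equal(c(lex$start, lex$end), unlist(fx$truth$lexa_interval))
  expect_gt(lex$detection_score, 1)

  # no CDS at all
  expect_null(find_lexa(make_plain_genome(len = 500L)))

  # CDSs present but none resembling LexA
  g <- fx$genome
  g$cds <- g$cds[g$cds$feature_id != "lexA", , drop = FALSE]
  expect_null(find_lexa(g))
})

test_that("find_csb confirms the canonical box and applies its HI ceiling", {
  fx <- shared_fixture()
  m <- default_sos_matrix()
  lex <- find_lexa(fx$genome)
  csb <- find_csb(fx$genome, lex, m)
  expect_equal(csb$hit$hi, 0)
  expect_equal(csb$distance_to_lexa_start, 80L)

  csb_start <- fx$truth$csb_interval[[1]]
  # designed HI ~ 10 passes the default ceiling, ~ 20 does not
  g10 <- plant(fx$genome, csb_start, design_sequence_for_hi(m, 10, seed = 9))
  got <- find_csb(g10, lex, m)
  expect_true(abs(got$hit$hi - 10) <= 0.5)
  g20 <- plant(fx$genome, csb_start, design_sequence_for_hi(m, 20, seed = 9))
  expect_null(find_csb(g20, lex, m))

  # scrambling the core kills the candidate entirely
  broken <- fx$genome
  s <- broken$sequence
  substr(s, csb_start + 3L, csb_start + 3L) <- "A"
  broken <- genome_record(broken$replicon_id, s, broken$cds)
  expect_null(find_csb(broken, lex, m))
})

test_that("threshold derivation splits a bimodal HI sample at the gap", {
  his <- hi_mixture(n = 200L, seed = 21)
  th <- derive_thresholds(his)
  expect_equal(th$status, "OK")
  expect_gte(th$hi_c1, 8); expect_lte(th$hi_c1, 14)
  expect_gt(th$hi_c2, th$hi_c1)
  expect_true(all(th$low_cluster <= th$hi_c1))
  expect_true(all(th$high_cluster >= th$hi_c2))
  expect_setequal(c(th$low_cluster, th$high_cluster), his)
  expect_equal(max(th$low_cluster), th$hi_c1)
  expect_equal(min(th$high_cluster), th$hi_c2)
})

test_that("threshold derivation guards degenerate inputs", {
  expect_equal(derive_thresholds(rep(7, 50))$status, "AMBIGUOUS")
  th <- derive_thresholds(c(5, 25))
  expect_equal(th$status, "AMBIGUOUS")
  expect_match(th$reason, "fewer than")
})

test_that("thresholds are order-invariant and stable under interior additions", {
  his <- hi_mixture(n = 150L, seed = 22)
  th1 <- derive_thresholds(his)
  th2 <- derive_thresholds(rev(his))
  th3 <- derive_thresholds(sample(his))
  expect_equal(th1$hi_c1, th2$hi_c1)
  expect_equal(th1$hi_c2, th2$hi_c2)
  expect_equal(th1$hi_c1, th3$hi_c1)
  # adding a value strictly inside the low cluster keeps the ordering
  inner <- mean(range(th1$low_cluster))
  th4 <- derive_thresholds(c(his, inner))
  expect_equal(th4$status, "OK")
  expect_lt(th4$hi_c1, th4$hi_c2)
  expect_equal(th4$hi_c1, th1$hi_c1)
})

test_that("mean shift matches the KDE-valley oracle on separated mixtures", {
  for (seed in c(31, 32, 33)) {
    his <- hi_mixture(n = 200L, seed = seed)
    th <- derive_thresholds(his, method = "meanshift")
    expect_equal(th$status, "OK")
    oracle <- kde_valley_partition(his)
    expect_equal(th$cluster_id, oracle)
  }
})

test_that("the kmeans2 and otsu baselines also separate clean mixtures", {
  his <- hi_mixture(n = 200L, seed = 34)
  for (method in c("kmeans2", "otsu")) {
    th <- derive_thresholds(his, method = method)
    expect_equal(th$status, "OK")
    expect_lt(th$hi_c1, 15)
    expect_gt(th$hi_c2, 15)
  }
})

test_that("build_host_profile chains the steps and reports the first failure", {
  fx <- shared_fixture()
  prof <- build_host_profile(fx$genome)
  expect_equal(prof$status, "OK")
  expect_lt(prof$thresholds$hi_c1, prof$thresholds$hi_c2)
  # thresholds bracket the planted mixture gap (targets 5-9 vs 19-25)
  expect_gte(prof$thresholds$hi_c1, 5)
  expect_lte(prof$thresholds$hi_c1, 14)
  expect_gte(prof$thresholds$hi_c2, 14)

  g <- fx$genome
  g$cds <- g$cds[g$cds$feature_id != "lexA", , drop = FALSE]
  expect_equal(build_host_profile(g)$status, "NO_LEXA")

  s <- fx$genome$sequence
  csb_start <- fx$truth$csb_interval[[1]]
  substr(s, csb_start + 3L, csb_start + 3L) <- "A"
  g2 <- genome_record(fx$genome$replicon_id, s, fx$genome$cds)
  expect_equal(build_host_profile(g2)$status, "NO_CSB")
})

test_that("host profiles expose tidy, glance and autoplot views", {
  fx <- shared_fixture()
  prof <- build_host_profile(fx$genome)
  td <- tidy(prof)
  expect_true(all(c("hi", "cluster") %in% names(td)))
  expect_equal(nrow(td), nrow(prof$psb_hits))
  expect_true(all(td$cluster[td$hi <= prof$thresholds$hi_c1] == "low"))
  gl <- glance(prof)
  expect_equal(gl$status, "OK")
  expect_equal(gl$n_psbs, nrow(prof$psb_hits))
  p <- autoplot(prof)
  expect_s3_class(p, "ggplot")
})
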