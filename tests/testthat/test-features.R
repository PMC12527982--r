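test_that("GC content and coverage statistics follow the definitions", {
  expect_equal(feature_vector(genome_record("a", "ATAT"))$gc, 0)
  expect_equal(feature_vector(genome_record("g", "GCGC"))$gc, 1)

  cds <- tibble::tibble(feature_id = c("x", "y"),
                        start = c(0L, 50L), end = c(100L, 150L),
                        strand = c("+", "+"),
                        product = NA_character_, translation = NA_character_)
  g <- make_plain_genome(len = 200L, cds = cds)
  fv <- feature_vector(g)
  expect_equal(fv$pcd, 150 / 200)        # union of [0,100) and [50,150)
  expect_equal(fv$pco, 50 / 200)         # 50 overlapping bases / 200 CDS bases
  expect_equal(fv$genome_size, 200L)
  expect_equal(fv$n_cds, 2L)
})

test_that("feature_vector matches an independent base-wise recount", {
  fx <- shared_fixture()
  g <- fx$genome
  fv <- feature_vector(g)

  # naive recount: per-base coverage vector
  cov <- integer(g$length)
  for (i in seq_len(nrow(g$cds))) {
    idx <- (g$cds$start[i] + 1L):g$cds$end[i]
    cov[idx] <- cov[idx] + 1L
  }
  bases <- strsplit(g$sequence, "")[[1]]
  expect_equal(fv$gc, mean(bases %in% c("G", "C")))
  expect_equal(fv$pcd, mean(cov >= 1))
  total_cds <- sum(g$cds$end - g$cds$start)
  expect_equal(fv$pco, (total_cds - sum(cov >= 1)) / total_cds)
  ig <- bases[cov == 0]
  expect_equal(fv$ir_gc, mean(ig %in% c("G", "C")))
  expect_equal(fv$mean_protein_size, mean((g$cds$end - g$cds$start) / 3 - 1))

  # region slice: clipped coverage, contained CDSs only for protein stats
  reg <- fx$regions[1, ]
  fvr <- feature_vector(g, reg)
  idx <- (reg$start + 1L):reg$end
  expect_equal(fvr$pcd, mean(cov[idx] >= 1))
  expect_equal(fvr$gc, mean(bases[idx] %in% c("G", "C")))
})

test_that("pcd is permutation-invariant and monotone under CDS addition", {
  cds <- tibble::tibble(feature_id = c("x", "y"),
                        start = c(10L, 120L), end = c(100L, 180L),
                        strand = c("+", "+"),
                        product = NA_character_, translation = NA_character_)
  g1 <- make_plain_genome(len = 300L, cds = cds)
  g2 <- make_plain_genome(len = 300L, cds = cds[2:1, ])
  expect_equal(feature_vector(g1)$pcd, feature_vector(g2)$pcd)
  more <- rbind(cds, tibble::tibble(feature_id = "z", start = 200L, end = 260L,
                                    strand = "+", product = NA_character_,
                                    translation = NA_character_))
  g3 <- make_plain_genome(len = 300L, cds = more)
  expect_gte(feature_vector(g3)$pcd, feature_vector(g1)$pcd)
})

test_that("codon distances behave at the identity and orthogonal extremes", {
  mk <- function(seq) genome_record("c", seq,
    tibble::tibble(feature_id = "cds", start = 0L, end = nchar(seq),
                   strand = "+", product = NA_character_,
                   translation = NA_character_))
  a <- mk("AAAAAACAACAA")
  expect_equal(codon_cosine_distance(a, a), 0)
  b <- mk("CCCCCCGGGGGG")
  expect_equal(codon_cosine_distance(a, b), 1)

  # hand-computed small pair: a = {AAA:2/4, CAA:2/4}; c = {AAA:1/2, GGG:1/2}
  cc <- mk("AAAGGG")
  expected <- 1 - (0.5 * 0.5) / (sqrt(0.5^2 + 0.5^2) * sqrt(0.5^2 + 0.5^2))
  expect_equal(codon_cosine_distance(a, cc), expected, tolerance = 1e-9)

  # symmetry and bounds
  expect_equal(codon_cosine_distance(a, cc), codon_cosine_distance(cc, a))
  expect_error(codon_cosine_distance(make_plain_genome(100L), a), "no complete CDS")
})

test_that("codon counting respects strand, frame and partial codons", {
  # minus-strand CDS: genome carries the reverse complement of the coding seq
  coding <- "ATGAAATTTTAA"
  g <- genome_record("m", paste0("AT", revcomp_chr(coding), "GG"),
                     tibble::tibble(feature_id = "cds", start = 2L,
                                    end = 2L + nchar(coding), strand = "-",
                                    product = NA_character_,
                                    translation = NA_character_))
  cf <- codon_frequencies(g)
  expect_equal(unname(cf["ATG"]), 0.25)
  expect_equal(unname(cf["AAA"]), 0.25)
  expect_equal(unname(cf["TTT"]), 0.25)
  expect_equal(unname(cf["TAA"]), 0.25)
  expect_equal(sum(cf), 1)
})

test_that("nucleotide divergence is a cosine distance on k-mer frequencies", {
  s <- random_seq(500, seed = 61)
  expect_equal(nt_divergence(s, s, k = 1), 0)
  expect_equal(nt_divergence(s, s, k = 2), 0)
  expect_equal(nt_divergence("AAAA", "TTTT", k = 1), 1)

  # brute-force recount oracle
  a <- random_seq(400, seed = 62); b <- random_seq(400, seed = 63)
  for (k in 1:3) {
    all_kmers <- apply(do.call(expand.grid,
                               rep(list(c("A", "C", "G", "T")), k)),
                       1, function(r) paste(rev(r), collapse = ""))
    count_k <- function(x) {
      kmers <- substring(x, 1:(nchar(x) - k + 1), k:nchar(x))
      v <- as.numeric(table(factor(kmers, levels = sort(all_kmers))))
      v / sum(v)
    }
    va <- count_k(a); vb <- count_k(b)
    expected <- 1 - sum(va * vb) / (sqrt(sum(va^2)) * sqrt(sum(vb^2)))
    expect_equal(nt_divergence(a, b, k = k), expected, tolerance = 1e-12)
  }
  expect_error(nt_divergence("AC", "AC", k = 5), "k must be")
  expect_error(nt_divergence("A", "ACGT", k = 2), "shorter")
})

test_that("phage_host_distance bundles the composition metrics", {
  fx <- shared_fixture()
  d <- phage_host_distance(fx$genome, fx$regions[1, ])
  expect_true(d$codon_distance >= 0 && d$codon_distance <= 1)
  expect_gte(d$nt_divergence_k1, 0)
  expect_gte(d$nt_divergence_k2, 0)
})
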