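make_gbk <- function(path) {
  # 120 bp replicon, two CDSs: 1-based 11..40 (+) and 61..90 (-)
  seq60 <- "atgaaatttggctaatttttacgtacgtacgtatgcccgggtaacatatatatatatata"
  lines <- c(
    "LOCUS       toyrep                 120 bp    DNA     linear   UNK 01-JAN-2000",
    "DEFINITION  hand-written test record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "     CDS             11..40",
    "                     /locus_tag=\"gene1\"",
    "                     /product=\"first protein\"",
    "     CDS             complement(61..90)",
    "                     /locus_tag=\"gene2\"",
    "                     /product=\"second protein\"",
    "ORIGIN",
    sprintf("%9d %s", 1, paste(substring(seq60, seq(1, 60, 10), seq(10, 60, 10)), collapse = " ")),
    sprintf("%9d %s", 61, paste(substring(seq60, seq(1, 60, 10), seq(10, 60, 10)), collapse = " ")),
    "//")
  writeLines(lines, path)
  path
}

test_that("GenBank parsing converts 1-based inclusive to 0-based half-open", {
  gbk <- make_gbk(withr::local_tempfile(fileext = ".gbk"))
  recs <- read_genome(gbk)
  expect_length(recs, 1)
  g <- recs[[1]]
  expect_equal(g$replicon_id, "toyrep")
  expect_equal(g$length, 120L)
  expect_equal(nrow(g$cds), 2L)
  expect_equal(g$cds$start, c(10L, 60L))
  expect_equal(g$cds$end, c(40L, 90L))
  expect_equal(g$cds$strand, c("+", "-"))
  expect_equal(g$cds$feature_id, c("gene1", "gene2"))
})

test_that("FASTA + GFF3 parsing matches the GenBank convention", {
  fa <- withr::local_tempfile(fileext = ".fa")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(">chrA some description", random_seq(300, seed = 5)), fa)
  writeLines(c("##gff-version 3",
               "chrA\ttest\tCDS\t101\t160\t.\t+\t0\tID=cdsA;product=thing"),
             gff)
  recs <- read_genome(fa, gff)
  g <- recs[["chrA"]]
  expect_equal(g$cds$start, 100L)
  expect_equal(g$cds$end, 160L)
  expect_equal(g$cds$feature_id, "cdsA")

  # annotation naming a replicon absent from the FASTA is an error
  writeLines(c("##gff-version 3",
               "chrB\ttest\tCDS\t101\t160\t.\t+\t0\tID=x"), gff)
  expect_error(read_genome(fa, gff), "not in FASTA")
})

test_that("genome records reject out-of-bounds or malformed CDSs", {
  expect_error(genome_record("x", "ACGTACGT",
                             tibble::tibble(feature_id = "a", start = 0L, end = 20L,
                                            strand = "+", product = NA, translation = NA)),
               "outside")
  expect_error(genome_record("x", "ACGTACGT",
                             tibble::tibble(feature_id = "a", start = 2L, end = 6L,
                                            strand = "*", product = NA, translation = NA)),
               "strand")
  expect_error(genome_record("x", ""), "empty")
})

test_that("BED and GFF3 prophage regions map to identical internal coordinates", {
  fx <- shared_fixture()
  genomes <- list(fx$genome)
  names(genomes) <- fx$genome$replicon_id
  bed <- withr::local_tempfile(fileext = ".bed")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(sprintf("%s\t100\t200\tpp1", fx$genome$replicon_id), bed)
  writeLines(c("##gff-version 3",
               sprintf("%s\ttest\tprophage\t101\t200\t.\t+\t.\tID=pp1",
                       fx$genome$replicon_id)), gff)
  from_bed <- read_prophage_regions(bed, genomes)
  from_gff <- read_prophage_regions(gff, genomes)
  expect_equal(from_bed$start, 100L)
  expect_equal(from_bed$end, 200L)
  expect_equal(from_bed[, c("replicon_id", "start", "end")],
               from_gff[, c("replicon_id", "start", "end")])

  writeLines(sprintf("%s\t100\t99999999\tpp1", fx$genome$replicon_id), bed)
  expect_error(read_prophage_regions(bed, genomes), "bounds")
  writeLines("nosuchreplicon\t1\t10\tpp1", bed)
  expect_error(read_prophage_regions(bed, genomes), "unknown")
})

test_that("GenBank write/read round-trips the CDS set and sequence", {
  fx <- shared_fixture()
  path <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(fx$genome, path)
  back <- read_genome(path)[[1]]
  expect_equal(back$sequence, fx$genome$sequence)
  expect_equal(back$cds[, c("feature_id", "start", "end", "strand")],
               fx$genome$cds[, c("feature_id", "start", "end", "strand")])
  expect_equal(back$cds$translation, fx$genome$cds$translation)
})

test_that("promoter windows follow strand and truncate at replicon edges", {
  cds <- tibble::tibble(
    feature_id = c("p", "m", "edge"),
    start = c(500L, 500L, 10L), end = c(800L, 800L, 200L),
    strand = c("+", "-", "+"),
    product = NA_character_, translation = NA_character_)
  g <- make_plain_genome(len = 1000L, cds = cds)
  pr <- extract_promoters(g, upstream_len = 300L, into_gene_len = 50L)
  expect_equal(pr$start[pr$parent_feature_id == "p"], 200L)
  expect_equal(pr$end[pr$parent_feature_id == "p"], 550L)
  expect_equal(pr$start[pr$parent_feature_id == "m"], 750L)
  expect_equal(pr$end[pr$parent_feature_id == "m"], 1000L)  # truncated
  expect_equal(pr$start[pr$parent_feature_id == "edge"], 0L)
  expect_equal(pr$end[pr$parent_feature_id == "edge"], 60L)

  # circular mode wraps instead of truncating
  prc <- extract_promoters(g, upstream_len = 300L, into_gene_len = 50L,
                           circular = TRUE)
  expect_equal(prc$start[prc$parent_feature_id == "edge"], 710L)
  expect_equal(prc$end[prc$parent_feature_id == "edge"], 1060L)

  # region restriction: only overlapping CDSs contribute
  reg <- list(prophage_id = "r", start = 0L, end = 300L)
  pr2 <- extract_promoters(g, region = reg)
  expect_equal(pr2$parent_feature_id, "edge")

  expect_equal(nrow(extract_promoters(make_plain_genome(len = 500L))), 0L)
})
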