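#' Per-sequence genomic feature vector
#'
#' The statistics compared between SOS-independent and SOS-dependent
#' prophages and their hosts: GC content, protein-coding density (PCD,
#' fraction of bases covered by at least one CDS), proportion of CDS
#' overlap (PCO, defined here as pairwise-overlapping CDS bases over total
#' CDS bases, i.e. `(sum of CDS lengths - bases in the CDS union) / sum of
#' CDS lengths`), GC of the intergenic regions (IR), mean protein size,
#' and the 64-codon usage vector. When `region` is given, the slice of the
#' replicon it covers is analyzed: CDS intervals are clipped to the region
#' for the coverage statistics, while codon and protein statistics use
#' only CDSs fully contained in it (a clipped CDS has no defined frame).
#'
#' @param genome a `genome_record`.
#' @param region optional one-row prophage region (`start`, `end`,
#'   optionally `prophage_id`).
#' @return one-row tibble: `seq_id`, `genome_size`, `gc`, `pcd`, `pco`,
#'   `ir_gc`, `mean_protein_size`, `n_cds`, and `codon_freq` (list column
#'   holding the named 64-vector; `NA` entries where annotations are
#'   missing).
#' @export
feature_vector <- function(genome, region = NULL) {
  stopifnot(inherits(genome, "genome_record"))
  if (is.null(region)) {
    seq_id <- genome$replicon_id
    lo <- 0L; hi <- genome$length
  } else {
    seq_id <- region$prophage_id %||% sprintf("%s:%d-%d", genome$replicon_id,
                                              region$start + 1L, region$end)
    lo <- region$start; hi <- region$end
  }
  size <- hi - lo
  s <- substr(genome$sequence, lo + 1L, hi)
  gc <- gc_fraction(s)

  cds <- genome$cds[genome$cds$start < hi & genome$cds$end > lo, , drop = FALSE]
  clipped_start <- pmax(cds$start, lo)
  clipped_end <- pmin(cds$end, hi)
  if (nrow(cds)) {
    ir <- IRanges::IRanges(start = clipped_start + 1L, end = clipped_end)
    covered <- sum(IRanges::width(IRanges::reduce(ir)))
    total_cds <- sum(IRanges::width(ir))
    pcd <- covered / size
    pco <- if (total_cds > 0) (total_cds - covered) / total_cds else NA_real_
    # intergenic = region minus CDS union
    gaps <- IRanges::gaps(IRanges::reduce(ir), start = lo + 1L, end = hi)
    ir_gc <- if (length(gaps) && sum(IRanges::width(gaps)) > 0) {
      chunks <- substring(genome$sequence, BiocGenerics::start(gaps), BiocGenerics::end(gaps))
      gc_fraction(paste(chunks, collapse = ""))
    } else NA_real_
  } else {
    pcd <- 0; pco <- NA_real_; ir_gc <- gc
  }

  contained <- genome$cds[genome$cds$start >= lo & genome$cds$end <= hi, , drop = FALSE]
  mean_prot <- if (nrow(contained)) {
    mean((contained$end - contained$start) / 3 - 1)  # minus the stop codon
  } else NA_real_
  cf <- if (nrow(contained)) codon_frequencies(genome, contained) else NULL

  tibble(seq_id = seq_id, genome_size = as.integer(size), gc = gc,
         pcd = pcd, pco = pco, ir_gc = ir_gc,
         mean_protein_size = mean_prot, n_cds = nrow(cds),
         codon_freq = list(cf))
}

gc_fraction <- function(s) {
  n <- nchar(s) - lengths(regmatches(s, gregexpr("N", s, fixed = TRUE)))
  if (n == 0) return(NA_real_)
  gc <- lengths(regmatches(s, gregexpr("[GC]", s)))
  gc / n
}

#' Codon usage frequencies of a CDS set
#'
#' Counts in-frame codons over strand-oriented CDS sequences; partial
#' terminal codons are dropped and codons containing N are skipped.
#'
#' @param genome a `genome_record`.
#' @param cds tibble of CDS rows (default: all CDSs of the genome).
#' @return named numeric vector over the 64 codons, summing to 1 (all
#'   zeros if no codon could be counted).
#' @export
codon_frequencies <- function(genome, cds = genome$cds) {
  codons <- mkAllStrings_codons()
  counts <- stats::setNames(numeric(64), codons)
  if (!nrow(cds)) return(counts)
  for (i in seq_len(nrow(cds))) {
    s <- get_subseq(genome, cds$start[i], cds$end[i])
    if (cds$strand[i] == "-") s <- revcomp(s)
    usable <- nchar(s) - nchar(s) %% 3L
    if (usable < 3L) next
    tri <- substring(s, seq(1L, usable, 3L), seq(3L, usable, 3L))
    tri <- tri[!grepl("N", tri, fixed = TRUE)]
    tab <- table(tri)
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
  }
  tot <- sum(counts)
  if (tot > 0) counts / tot else counts
}

mkAllStrings_codons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

#' Cosine distance between codon usage vectors
#'
#' `Dc(phage, host) = 1 - cos(theta)` between the 64-dimensional codon
#' frequency vectors; 0 for identical usage, 1 for orthogonal (disjoint)
#' usage. Arguments may be precomputed frequency vectors or
#' `genome_record`s (optionally with a region) from which frequencies are
#' derived via [codon_frequencies()].
#'
#' @param phage,host named 64-vectors of codon frequencies, or
#'   `genome_record`s.
#' @param phage_region,host_region optional regions restricting the CDS
#'   sets when genome records are given.
#' @return cosine distance in `[0, 1]`.
#' @export
codon_cosine_distance <- function(phage, host, phage_region = NULL,
                                  host_region = NULL) {
  as_freq <- function(x, region) {
    if (inherits(x, "genome_record")) {
      cds <- x$cds
      if (!is.null(region))
        cds <- cds[cds$start >= region$start & cds$end <= region$end, , drop = FALSE]
      if (!nrow(cds)) stop("no complete CDS available for codon counting")
      codon_frequencies(x, cds)
    } else as.numeric(x)
  }
  a <- as_freq(phage, phage_region)
  b <- as_freq(host, host_region)
  cosine_distance(a, b)
}

#' Nucleotide k-mer frequency divergence
#'
#' Cosine distance between the normalized k-mer frequency vectors of two
#' sequences (strand-naive, overlapping k-mers). Used to quantify
#' phage-host nucleotide composition divergence; k = 1 and 2 are the
#' conventional reports.
#'
#' @param phage_seq,host_seq DNA strings or `genome_record`s.
#' @param k k-mer size (1-4).
#' @return cosine distance, >= 0 (0 for identical composition).
#' @export
nt_divergence <- function(phage_seq, host_seq, k = 1L) {
  if (!k %in% 1:4) stop("k must be 1, 2, 3 or 4")
  as_seq <- function(x) if (inherits(x, "genome_record")) x$sequence else toupper(x)
  a <- as_seq(phage_seq); b <- as_seq(host_seq)
  if (nchar(a) < k || nchar(b) < k) stop("sequence shorter than k")
  fa <- kmer_freq(a, k); fb <- kmer_freq(b, k)
  cosine_distance(fa, fb)
}

kmer_freq <- function(s, k) {
  v <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(s), width = k,
                                            as.prob = FALSE)
  tot <- sum(v)
  if (tot == 0) stop("no countable k-mers (sequence all N?)")
  v / tot
}

#' Phage-host composition distances
#'
#' Convenience wrapper combining [codon_cosine_distance()] and
#' [nt_divergence()] for a prophage region against its host replicon.
#'
#' @param genome host `genome_record`.
#' @param region one-row prophage region.
#' @param k k-mer sizes for the nucleotide divergence (default `c(1, 2)`).
#' @return one-row tibble: `prophage_id`, `codon_distance`, and one
#'   `nt_divergence_k<k>` column per requested k.
#' @export
phage_host_distance <- function(genome, region, k = c(1L, 2L)) {
  phage_seq <- substr(genome$sequence, region$start + 1L, region$end)
  out <- tibble(prophage_id = region$prophage_id %||% NA_character_,
                codon_distance = tryCatch(
                  codon_cosine_distance(genome, genome, phage_region = region),
                  error = function(e) NA_real_))
  for (kk in k) {
    out[[paste0("nt_divergence_k", kk)]] <- nt_divergence(phage_seq, genome, k = kk)
  }
  out
}
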