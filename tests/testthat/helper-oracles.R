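# Independent oracles used across the suite. These deliberately avoid the
# package's scanning/scoring internals: HI is summed term by term from the
# raw counts, and candidate windows are found by plain substring checks.

# heterology index by explicit per-position summation from the raw counts
brute_hi <- function(mat, window) {
  bases <- c("A", "C", "G", "T")
  cons <- strsplit(mat$consensus, "")[[1]]
  win <- strsplit(window, "")[[1]]
  p <- mat$pseudocount
  total <- 0
  for (i in seq_len(mat$length)) {
    n_max <- mat$counts[i, cons[i]]
    n_b <- mat$counts[i, win[i]]
    total <- total + log((n_max + p) / (n_b + p))
  }
  total
}

# all-windows scan oracle: every offset is tested against the core by
# direct character comparison on both strands; HI via brute_hi
brute_scan <- function(mat, seq_string, mismatch_allowance = 0L) {
  L <- mat$length
  n <- nchar(seq_string)
  rows <- list()
  if (n < L) {
    return(data.frame(start = integer(), strand = character(), hi = double()))
  }
  rc_string <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  for (s in 1:(n - L + 1)) {
    w <- substr(seq_string, s, s + L - 1)
    if (grepl("N", w, fixed = TRUE)) next
    mm <- 0L
    for (k in seq_len(nrow(mat$core))) {
      if (substr(w, mat$core$pos[k], mat$core$pos[k]) != mat$core$base[k])
        mm <- mm + 1L
    }
    if (mm > mismatch_allowance) next
    w_rc <- rc_string(w)
    hi_f <- brute_hi(mat, w)
    hi_r <- brute_hi(mat, w_rc)
    # the symmetrized matrix scores both strands identically; only a real
    # (not round-off) difference counts as a minus-strand preference
    rows[[length(rows) + 1L]] <- data.frame(
      start = s - 1L,
      strand = if (hi_r < hi_f - 1e-9) "-" else "+",
      hi = min(hi_f, hi_r))
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), strand = character(), hi = double()))
  }
  do.call(rbind, rows)
}

# KDE-valley split of a 1-D two-component sample: the cut point is the
# density minimum between the two highest modes of a kernel density
# estimate, found on the density grid
kde_valley_partition <- function(x) {
  d <- stats::density(x)
  y <- d$y
  is_peak <- which(diff(sign(diff(y))) == -2) + 1L
  stopifnot(length(is_peak) >= 2L)
  top2 <- sort(is_peak[order(y[is_peak], decreasing = TRUE)][1:2])
  valley_idx <- top2[1] + which.min(y[top2[1]:top2[2]]) - 1L
  cut <- d$x[valley_idx]
  ifelse(x <= cut, 1L, 2L)
}

# plain genome for interval arithmetic tests; background is A/T only so no
# scan core can occur by accident
make_plain_genome <- function(len = 2000L, cds = NULL, seed = 1L,
                              replicon_id = "toy") {
  seq <- with_test_seed(seed,
    paste(sample(c("A", "T"), len, replace = TRUE), collapse = ""))
  genome_record(replicon_id, seq, cds)
}

with_test_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# overwrite a slice of a genome's sequence (0-based offset), revalidating
plant <- function(genome, at0, insert) {
  s <- genome$sequence
  substr(s, at0 + 1L, at0 + nchar(insert)) <- insert
  genome_record(genome$replicon_id, s, genome$cds, genome$source_path)
}

revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# random A/C/G/T string
random_seq <- function(n, seed = NULL) {
  gen <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                          collapse = "")
  if (is.null(seed)) gen() else with_test_seed(seed, gen())
}

# two-component HI mixture mirroring the E. coli peaks
hi_mixture <- function(n = 200L, seed = 1L) {
  with_test_seed(seed, {
    k <- stats::rbinom(1, n, 0.5)
    c(stats::rnorm(k, 7, 1), stats::rnorm(n - k, 22, 2))
  })
}

# minimal OK host profile for boundary tests
fake_profile <- function(hi_c1, hi_c2, status = "OK") {
  structure(list(genome_id = "fake", status = status,
                 thresholds = list(status = status, hi_c1 = hi_c1,
                                   hi_c2 = hi_c2)),
            class = "host_profile")
}
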