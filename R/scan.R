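#' Scan an interval for potential SOS boxes
#'
#' Slides a motif-length window over both strands of the interval. A window
#' is a PSB candidate when it matches the matrix's invariant core (CTG at
#' positions 3-5 and CAG at 16-18 for the canonical box) with at most
#' `mismatch_allowance` mismatches. Because that core is palindromic, the
#' forward and reverse-strand windows over the same interval are candidates
#' together; each interval is reported once, keeping the lower-HI
#' orientation (ties go to `+`). Windows containing N are skipped.
#'
#' @param matrix an `sos_matrix`.
#' @param genome a `genome_record`.
#' @param interval 0-based half-open `c(start, end)`; default the whole
#'   replicon. With `circular = TRUE`, `end` may exceed the replicon length
#'   to scan across the origin (hit coordinates are reported mod length).
#' @param mismatch_allowance core mismatches tolerated (default 0).
#' @param hi_cap optional ceiling; hits with HI above it are dropped.
#' @param circular scan across the origin of a circular replicon.
#' @param annotate_context attach `context_feature_id`, the nearest CDS
#'   whose translation start lies downstream of the hit on the hit strand.
#' @return tibble of hits sorted by `start`: `replicon_id`, `start`, `end`,
#'   `strand`, `sequence` (strand-oriented), `hi`, `context_feature_id`.
#' @export
scan_region <- function(matrix, genome, interval = NULL,
                        mismatch_allowance = 0L, hi_cap = NULL,
                        circular = FALSE, annotate_context = FALSE) {
  stopifnot(inherits(matrix, "sos_matrix"), inherits(genome, "genome_record"))
  L <- matrix$length
  len <- genome$length
  if (is.null(interval)) {
    interval <- c(0L, if (circular) len + L - 1L else len)
  }
  if (interval[1] < 0 || (!circular && interval[2] > len))
    stop("interval outside replicon bounds")
  empty <- tibble(replicon_id = character(), start = integer(), end = integer(),
                  strand = character(), sequence = character(), hi = double(),
                  context_feature_id = character())
  n <- interval[2] - interval[1]
  if (n < L) return(empty)
  s <- get_subseq(genome, interval[1], interval[2])
  enc <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))  # N -> NA
  starts <- seq_len(n - L + 1L)

  core <- matrix$core
  if (!nrow(core)) stop("matrix has no core positions; scanning all windows is unsupported")
  req <- match(core$base, c("A", "C", "G", "T"))
  mm <- integer(length(starts))
  for (k in seq_len(nrow(core))) {
    v <- enc[starts + core$pos[k] - 1L]
    mm <- mm + as.integer(is.na(v) | v != req[k])
  }
  hasN <- is.na(enc)
  csN <- c(0L, cumsum(hasN))
  windowN <- (csN[starts + L] - csN[starts]) > 0L
  cand <- which(mm <= mismatch_allowance & !windowN)
  if (!length(cand)) return(empty)

  win <- substring(s, cand, cand + L - 1L)
  hi_f <- hi_score(matrix, win)
  rc <- revcomp(win)
  hi_r <- hi_score(matrix, rc)
  # strict preference only: round-off ties (e.g. under a palindromically
  # symmetrized matrix) resolve to the + strand
  minus <- hi_r < hi_f - 1e-9
  start0 <- as.integer((interval[1] + cand - 1L) %% len)
  hits <- tibble(
    replicon_id = genome$replicon_id,
    start = start0,
    end = start0 + L,  # may exceed the replicon length for origin-spanning hits
    strand = ifelse(minus, "-", "+"),
    sequence = ifelse(minus, rc, win),
    hi = pmin(hi_f, hi_r),
    context_feature_id = NA_character_)
  if (!is.null(hi_cap)) hits <- hits[hits$hi <= hi_cap, , drop = FALSE]
  hits <- arrange(hits, .data$start)
  if (annotate_context && nrow(hits) && nrow(genome$cds)) {
    hits$context_feature_id <- nearest_downstream_cds(genome, hits)
  }
  hits
}

# nearest CDS translation start downstream of the hit, on the hit's strand
nearest_downstream_cds <- function(genome, hits) {
  cds <- genome$cds
  plus <- cds[cds$strand == "+", , drop = FALSE]
  minus <- cds[cds$strand == "-", , drop = FALSE]
  vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    if (h$strand == "+") {
      ok <- plus$start >= h$start
      if (!any(ok)) return(NA_character_)
      plus$feature_id[ok][which.min(plus$start[ok])]
    } else {
      ok <- minus$end <= h$end
      if (!any(ok)) return(NA_character_)
      minus$feature_id[ok][which.max(minus$end[ok])]
    }
  }, character(1))
}

#' Survey a genome's potential SOS boxes
#'
#' Collects all deduplicated PSB hits in the chosen scope and their HI
#' values; the HI column of the result is the genome-wide distribution fed
#' to [derive_thresholds()]. `scope = "whole_genome"` scans the entire
#' replicon; `scope = "promoters"` scans only promoter windows of
#' annotated CDSs (hits landing in overlapping windows are reported once,
#' keyed by interval).
#'
#' @inheritParams scan_region
#' @param scope `"whole_genome"` or `"promoters"`.
#' @param upstream_len,into_gene_len promoter window geometry when
#'   `scope = "promoters"`.
#' @return tibble of hits as in [scan_region()], ordered by coordinate.
#' @export
survey_psbs <- function(genome, matrix = default_sos_matrix(),
                        scope = c("whole_genome", "promoters"),
                        mismatch_allowance = 0L, hi_cap = NULL,
                        upstream_len = 300L, into_gene_len = 50L,
                        circular = FALSE) {
  scope <- match.arg(scope)
  if (scope == "whole_genome") {
    return(scan_region(matrix, genome, mismatch_allowance = mismatch_allowance,
                       hi_cap = hi_cap, circular = circular))
  }
  proms <- extract_promoters(genome, upstream_len = upstream_len,
                             into_gene_len = into_gene_len, circular = circular)
  if (!nrow(proms)) {
    return(scan_region(matrix, genome, interval = c(0L, 0L)))
  }
  hit_list <- lapply(seq_len(nrow(proms)), function(i)
    scan_region(matrix, genome, c(proms$start[i], proms$end[i]),
                mismatch_allowance = mismatch_allowance, hi_cap = hi_cap,
                circular = circular))
  hits <- bind_rows(hit_list)
  if (!nrow(hits)) return(hits)
  hits <- hits[!duplicated(hits[, c("start", "end")]), , drop = FALSE]
  arrange(hits, .data$start)
}
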