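#' Minimum heterology index over a prophage's promoters
#'
#' Extracts the promoter window of every CDS overlapping the prophage
#' region, scans each for potential SOS boxes, and returns the minimum HI
#' over all hits together with the hit table. A prophage whose promoters
#' contain no candidate operator returns `hi_min = NA`.
#'
#' @param genome a `genome_record`.
#' @param region one-row tibble/list with `prophage_id`, `start`, `end`.
#' @param matrix an `sos_matrix`.
#' @param upstream_len,into_gene_len promoter window geometry.
#' @param mismatch_allowance core mismatches tolerated.
#' @param circular treat the replicon as circular.
#' @return list with `hi_min` (numeric or NA), `hits` (tibble), and
#'   `n_psbs`.
#' @export
prophage_hi_min <- function(genome, region, matrix = default_sos_matrix(),
                            upstream_len = 300L, into_gene_len = 50L,
                            mismatch_allowance = 0L, circular = FALSE) {
  proms <- extract_promoters(genome, region = region,
                             upstream_len = upstream_len,
                             into_gene_len = into_gene_len,
                             circular = circular)
  if (!nrow(proms)) {
    warning("prophage region ", region$prophage_id %||% "?",
            " has no CDS annotations; hi_min is undefined")
    return(list(hi_min = NA_real_, hits = scan_region(matrix, genome, c(0L, 0L)),
                n_psbs = 0L))
  }
  hits <- bind_rows(lapply(seq_len(nrow(proms)), function(i)
    scan_region(matrix, genome, c(proms$start[i], proms$end[i]),
                mismatch_allowance = mismatch_allowance, circular = circular)))
  if (nrow(hits)) {
    hits <- hits[!duplicated(hits[, c("start", "end")]), , drop = FALSE]
    hits <- arrange(hits, .data$start)
  }
  list(hi_min = if (nrow(hits)) min(hits$hi) else NA_real_,
       hits = hits, n_psbs = nrow(hits))
}

#' Classify a prophage's induction mode
#'
#' The trichotomy at the heart of the predictor: a prophage whose minimum
#' promoter HI is at or below the host's low-cluster edge (`hi_c1`) can be
#' bound by LexA and is SOS-dependent (SdP); one at or above the
#' high-cluster edge (`hi_c2`) cannot and is SOS-independent (SiP);
#' anything strictly between is uncertain (SuP). The boundaries are
#' inclusive because the thresholds are themselves cluster extrema. A
#' prophage with no candidate operator at all (`hi_min = NA`) is called
#' SiP: under the model, repression by LexA is impossible without an
#' operator. Callers should carry the `no_psb_flag` for auditability.
#'
#' @param hi_min minimum promoter HI, or NA when the prophage has no PSB.
#' @param profile a `host_profile` with `status == "OK"`.
#' @return one of `"SdP"`, `"SiP"`, `"SuP"`.
#' @export
classify_induction <- function(hi_min, profile) {
  stopifnot(inherits(profile, "host_profile"))
  if (!identical(profile$status, "OK"))
    stop("classification refused: host profile status is ", profile$status)
  th <- profile$thresholds
  if (is.na(hi_min)) return("SiP")
  if (hi_min <= th$hi_c1) "SdP"
  else if (hi_min >= th$hi_c2) "SiP"
  else "SuP"
}

#' Classify all prophages of a genome
#'
#' Applies [prophage_hi_min()] and [classify_induction()] to each region.
#' When the host profile is not `OK` the prophages are still emitted, with
#' `class = NA` and the host status recorded, mirroring how hosts lacking
#' LexA or a canonical SOS box are excluded rather than force-called.
#'
#' @param genome a `genome_record`.
#' @param regions tibble of prophage regions (see
#'   [read_prophage_regions()]).
#' @param profile a `host_profile`.
#' @param matrix an `sos_matrix`.
#' @param upstream_len,into_gene_len,mismatch_allowance,circular scan
#'   controls as in [prophage_hi_min()].
#' @return tibble: `prophage_id`, `replicon_id`, `start`, `end`, `n_psbs`,
#'   `hi_min`, `hi_c1`, `hi_c2`, `class`, `no_psb_flag`, `host_status`.
#' @export
classify_prophages <- function(genome, regions, profile,
                               matrix = default_sos_matrix(),
                               upstream_len = 300L, into_gene_len = 50L,
                               mismatch_allowance = 0L, circular = FALSE) {
  stopifnot(inherits(profile, "host_profile"))
  ok <- identical(profile$status, "OK")
  th <- profile$thresholds
  if (!nrow(regions)) {
    return(tibble(prophage_id = character(), replicon_id = character(),
                  start = integer(), end = integer(), n_psbs = integer(),
                  hi_min = double(), hi_c1 = double(), hi_c2 = double(),
                  class = character(), no_psb_flag = logical(),
                  host_status = character()))
  }
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    reg <- regions[i, ]
    res <- prophage_hi_min(genome, reg, matrix, upstream_len = upstream_len,
                           into_gene_len = into_gene_len,
                           mismatch_allowance = mismatch_allowance,
                           circular = circular)
    tibble(prophage_id = reg$prophage_id,
           replicon_id = reg$replicon_id,
           start = reg$start, end = reg$end,
           n_psbs = res$n_psbs,
           hi_min = res$hi_min,
           hi_c1 = if (ok) th$hi_c1 else NA_real_,
           hi_c2 = if (ok) th$hi_c2 else NA_real_,
           class = if (ok) classify_induction(res$hi_min, profile) else NA_character_,
           no_psb_flag = res$n_psbs == 0L,
           host_status = profile$status)
  })
  bind_rows(rows)
}

#' Summarize prophage calls
#'
#' Counts and percentage shares of SdP/SiP/SuP calls. Percentages are
#' `100 * count / total` rounded half-up to two decimals, so they sum to
#' 100 within rounding.
#'
#' @param calls tibble with a `class` column (`NA` classes are dropped
#'   with their count reported in `n_na`).
#' @return one-row tibble: `n_sdp`, `n_sip`, `n_sup`, `n_na`, `pct_sdp`,
#'   `pct_sip`, `pct_sup`, `empty_flag`.
#' @export
summarize_calls <- function(calls) {
  cls <- calls$class
  class_summary(n_sdp = sum(cls == "SdP", na.rm = TRUE),
                n_sip = sum(cls == "SiP", na.rm = TRUE),
                n_sup = sum(cls == "SuP", na.rm = TRUE),
                n_na = sum(is.na(cls)))
}

#' @rdname summarize_calls
#' @param n_sdp,n_sip,n_sup,n_na class counts (e.g. from an external
#'   tally); percentages are computed over the three called classes.
#' @export
class_summary <- function(n_sdp, n_sip, n_sup, n_na = 0L) {
  total <- n_sdp + n_sip + n_sup
  pct <- function(x) if (total == 0) 0 else round_half_up(100 * x / total, 2)
  tibble(n_sdp = as.integer(n_sdp), n_sip = as.integer(n_sip),
         n_sup = as.integer(n_sup), n_na = as.integer(n_na),
         pct_sdp = pct(n_sdp), pct_sip = pct(n_sip), pct_sup = pct(n_sup),
         empty_flag = total == 0)
}
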