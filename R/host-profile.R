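#' Locate the lexA gene in a genome
#'
#' Scores every CDS translation by local alignment (BLOSUM62) against the
#' packaged reference LexA sequence and returns the best-scoring CDS above
#' the detection threshold. The detection score is the alignment score
#' divided by the reference length, so a full-length identical match scores
#' around 5 and unrelated proteins stay well below 1. Ties break to the
#' lowest start coordinate. Absence is a value, not an error: hosts without
#' LexA simply cannot be profiled.
#'
#' @param genome a `genome_record`; CDSs without a stored `translation`
#'   are translated on the fly.
#' @param reference `AAStringSet` of reference LexA proteins; default the
#'   packaged E. coli sequence.
#' @param min_score detection threshold on score-per-reference-length
#'   (default 1.0).
#' @return a `lexa_locus` (list with `feature_id`, `start`, `end`,
#'   `strand`, `detection_score`, `detection_method`) or `NULL`.
#' @export
find_lexa <- function(genome, reference = NULL, min_score = 1.0) {
  stopifnot(inherits(genome, "genome_record"))
  cds <- genome$cds
  if (!nrow(cds)) return(NULL)
  if (is.null(reference)) {
    reference <- Biostrings::readAAStringSet(sosdep_extdata("lexa_reference.faa"))
  }
  data("BLOSUM62", package = "Biostrings", envir = environment())
  blosum <- get("BLOSUM62", envir = environment())
  scores <- vapply(seq_len(nrow(cds)), function(i) {
    aa <- cds$translation[i]
    if (is.na(aa)) aa <- translate_cds(genome, cds[i, ])
    if (is.na(aa) || !nzchar(aa)) return(-Inf)
    aa <- gsub("[^A-Z]", "", toupper(aa))
    aa <- gsub("[JUOB*]", "X", aa)
    max(vapply(seq_along(reference), function(r) {
      al <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(aa), reference[[r]], type = "local",
        substitutionMatrix = blosum, gapOpening = 10, gapExtension = 0.5,
        scoreOnly = TRUE)
      al / length(reference[[r]])
    }, numeric(1)))
  }, numeric(1))
  best <- max(scores)
  if (!is.finite(best) || best < min_score) return(NULL)
  i <- which(scores == best)
  i <- i[which.min(cds$start[i])]
  structure(list(feature_id = cds$feature_id[i], start = cds$start[i],
                 end = cds$end[i], strand = cds$strand[i],
                 detection_score = best, detection_method = "similarity"),
            class = "lexa_locus")
}

#' Confirm the canonical SOS box upstream of lexA
#'
#' LexA autoregulates through an operator in its own promoter; finding that
#' canonical SOS box (CSB) is the precondition for trusting the
#' heterology-index model in a genome. The lexA promoter window is scanned
#' and the lowest-HI hit is returned, provided its HI does not exceed
#' `csb_cutoff`. The cutoff only confirms CSB presence; it plays no role in
#' prophage classification.
#'
#' @param genome a `genome_record`.
#' @param lexa a `lexa_locus` from [find_lexa()].
#' @param matrix an `sos_matrix`.
#' @param upstream_len,into_gene_len promoter window geometry.
#' @param csb_cutoff maximum HI accepted as a CSB (default 12).
#' @param circular treat the replicon as circular.
#' @return a `csb_evidence` (list with `hit`, a one-row hits tibble, and
#'   `distance_to_lexa_start`) or `NULL`.
#' @export
find_csb <- function(genome, lexa, matrix = default_sos_matrix(),
                     upstream_len = 300L, into_gene_len = 50L,
                     csb_cutoff = 12, circular = FALSE) {
  if (is.null(lexa)) stop("find_csb requires a detected lexA locus")
  len <- genome$length
  if (lexa$strand == "+") {
    start <- lexa$start - upstream_len
    end <- lexa$start + into_gene_len
  } else {
    start <- lexa$end - into_gene_len
    end <- lexa$end + upstream_len
  }
  if (!circular) {
    start <- max(start, 0L); end <- min(end, len)
  } else if (start < 0) {
    start <- start + len; end <- end + len
  }
  hits <- scan_region(matrix, genome, c(start, end), circular = circular)
  if (!nrow(hits)) return(NULL)
  best <- hits[which.min(hits$hi), , drop = FALSE]
  if (best$hi > csb_cutoff) return(NULL)
  dist <- if (lexa$strand == "+") lexa$start - best$end else best$start - lexa$end
  structure(list(hit = best, distance_to_lexa_start = as.integer(dist)),
            class = "csb_evidence")
}

#' Derive genome-specific HI thresholds by 1-D clustering
#'
#' Splits a genome's PSB heterology-index values into a low-HI cluster
#' (predicted LexA binders) and a high-HI cluster (non-binders). The
#' thresholds are the cluster edges: `hi_c1` is the maximum of the low
#' cluster and `hi_c2` the minimum of the high cluster; with more than two
#' clusters the extreme clusters define the thresholds and intermediate
#' points belong to neither. The default method is mean shift with a
#' Gaussian kernel and Silverman's rule-of-thumb bandwidth; `kmeans2`
#' (2-means with deterministic quantile starts) and `otsu` (between-class
#' variance maximizer) are baseline alternatives.
#'
#' @param his numeric vector of HI values.
#' @param method `"meanshift"`, `"kmeans2"`, or `"otsu"`.
#' @param bandwidth mean-shift kernel bandwidth; default Silverman's rule.
#' @param min_psb_count minimum number of values before clustering is
#'   attempted (default 10).
#' @return an `hi_thresholds` object: list with `status` (`"OK"` or
#'   `"AMBIGUOUS"`), `reason`, `hi_c1`, `hi_c2`, `low_cluster`,
#'   `high_cluster`, `cluster_id` (per input value; intermediate clusters
#'   numbered between the extremes), `method`, `bandwidth`, `n`.
#' @export
derive_thresholds <- function(his, method = c("meanshift", "kmeans2", "otsu"),
                              bandwidth = NULL, min_psb_count = 10L) {
  method <- match.arg(method)
  his <- as.numeric(his)
  ambiguous <- function(reason) {
    structure(list(status = "AMBIGUOUS", reason = reason, hi_c1 = NA_real_,
                   hi_c2 = NA_real_, low_cluster = numeric(),
                   high_cluster = numeric(), cluster_id = rep(NA_integer_, length(his)),
                   method = method, bandwidth = bandwidth, n = length(his)),
              class = "hi_thresholds")
  }
  if (length(his) < min_psb_count)
    return(ambiguous(sprintf("fewer than %d PSB values (%d)",
                             min_psb_count, length(his))))
  if (stats::sd(his) == 0) return(ambiguous("all HI values identical"))
  cl <- switch(method,
               meanshift = meanshift_1d(his, bandwidth),
               kmeans2 = kmeans2_1d(his),
               otsu = otsu_1d(his))
  if (is.null(cl)) return(ambiguous("clustering did not separate the values"))
  k <- max(cl$id)
  if (k < 2L) return(ambiguous("a single cluster was found"))
  low <- his[cl$id == 1L]
  high <- his[cl$id == k]
  hi_c1 <- max(low); hi_c2 <- min(high)
  if (!(hi_c1 < hi_c2)) return(ambiguous("cluster edges do not separate (hi_c1 >= hi_c2)"))
  structure(list(status = "OK", reason = NA_character_, hi_c1 = hi_c1,
                 hi_c2 = hi_c2, low_cluster = low, high_cluster = high,
                 cluster_id = cl$id, method = method,
                 bandwidth = cl$bandwidth, n = length(his)),
            class = "hi_thresholds")
}

#' @export
print.hi_thresholds <- function(x, ...) {
  if (x$status == "OK") {
    cat(sprintf("<hi_thresholds> %s on %d values: hi_c1=%.3f hi_c2=%.3f (low n=%d, high n=%d)\n",
                x$method, x$n, x$hi_c1, x$hi_c2,
                length(x$low_cluster), length(x$high_cluster)))
  } else {
    cat(sprintf("<hi_thresholds> AMBIGUOUS (%s)\n", x$reason))
  }
  invisible(x)
}

#' Silverman's rule-of-thumb bandwidth
#'
#' `0.9 * min(sd, IQR/1.34) * n^(-1/5)`, the standard kernel bandwidth for
#' 1-D density work; used as the default mean-shift bandwidth.
#'
#' @param x numeric vector.
#' @return a positive bandwidth.
#' @export
silverman_bandwidth <- function(x) {
  n <- length(x)
  s <- stats::sd(x)
  iqr <- stats::IQR(x) / 1.34
  spread <- min(s, if (iqr > 0) iqr else s)
  if (spread <= 0) spread <- s
  0.9 * spread * n^(-1 / 5)
}

# 1-D mean shift: each point ascends the Gaussian-kernel density; points
# whose modes coincide (within bandwidth/2 after sorting) share a cluster.
# Returns ids numbered by ascending cluster mean. Order-independent.
meanshift_1d <- function(x, bandwidth = NULL, max_iter = 500L, tol = 1e-8) {
  h <- bandwidth %||% silverman_bandwidth(x)
  if (!is.finite(h) || h <= 0) return(NULL)
  ux <- sort(unique(x))
  modes <- vapply(ux, function(m) {
    for (i in seq_len(max_iter)) {
      w <- dnorm((m - x) / h)
      m_new <- sum(w * x) / sum(w)
      if (abs(m_new - m) < tol * max(1, abs(m))) { m <- m_new; break }
      m <- m_new
    }
    m
  }, numeric(1))
  # group converged modes separated by less than h/2
  ord <- order(modes)
  sorted <- modes[ord]
  grp_sorted <- cumsum(c(1, diff(sorted) > h / 2))
  grp <- integer(length(modes)); grp[ord] <- grp_sorted
  id_by_value <- grp[match(x, ux)]
  relabel_by_mean(x, id_by_value, bandwidth = h)
}

kmeans2_1d <- function(x) {
  centers <- unique(stats::quantile(x, c(0.25, 0.75), names = FALSE))
  if (length(centers) < 2L) return(NULL)
  km <- stats::kmeans(x, centers = matrix(centers, ncol = 1), iter.max = 100L)
  relabel_by_mean(x, km$cluster, bandwidth = NULL)
}

# classic 1-D Otsu: threshold between sorted values maximizing
# between-class variance
otsu_1d <- function(x) {
  ux <- sort(unique(x))
  if (length(ux) < 2L) return(NULL)
  cuts <- (ux[-1] + ux[-length(ux)]) / 2
  crit <- vapply(cuts, function(t) {
    lo <- x[x <= t]; hi <- x[x > t]
    length(lo) * length(hi) * (mean(lo) - mean(hi))^2
  }, numeric(1))
  t <- cuts[which.max(crit)]
  relabel_by_mean(x, ifelse(x <= t, 1L, 2L), bandwidth = NULL)
}

relabel_by_mean <- function(x, id, bandwidth) {
  means <- tapply(x, id, mean)
  rank_of <- rank(means, ties.method = "first")
  new_id <- as.integer(rank_of[as.character(id)])
  list(id = new_id, bandwidth = bandwidth)
}

#' Build a host profile
#'
#' Runs the host-side half of the pipeline: detect lexA, confirm its
#' canonical SOS box, survey genome-wide PSBs, and derive the
#' classification thresholds. `status` records the first failure
#' (`NO_LEXA`, `NO_CSB`, `AMBIGUOUS_CLUSTERING`) or `OK`. Thresholds are
#' always derived per genome; HI distributions are genome-specific and are
#' never pooled across genomes.
#'
#' @param genome a `genome_record`.
#' @param matrix an `sos_matrix`.
#' @param scope PSB survey scope, see [survey_psbs()].
#' @param upstream_len,into_gene_len promoter window geometry.
#' @param csb_cutoff CSB confirmation ceiling, see [find_csb()].
#' @param method,bandwidth,min_psb_count clustering controls, see
#'   [derive_thresholds()].
#' @param lexa_reference,lexa_min_score LexA detection controls, see
#'   [find_lexa()].
#' @param mismatch_allowance core mismatches tolerated in scans.
#' @param circular treat the replicon as circular.
#' @return a `host_profile` object.
#' @export
build_host_profile <- function(genome, matrix = default_sos_matrix(),
                               scope = "whole_genome",
                               upstream_len = 300L, into_gene_len = 50L,
                               csb_cutoff = 12, method = "meanshift",
                               bandwidth = NULL, min_psb_count = 10L,
                               lexa_reference = NULL, lexa_min_score = 1.0,
                               mismatch_allowance = 0L, circular = FALSE) {
  stopifnot(inherits(genome, "genome_record"))
  prof <- structure(list(genome_id = genome$replicon_id, status = NA_character_,
                         lexa = NULL, csb = NULL,
                         psb_hits = NULL, thresholds = NULL,
                         params = list(scope = scope, upstream_len = upstream_len,
                                       into_gene_len = into_gene_len,
                                       csb_cutoff = csb_cutoff, method = method,
                                       bandwidth = bandwidth,
                                       min_psb_count = min_psb_count,
                                       lexa_min_score = lexa_min_score,
                                       mismatch_allowance = mismatch_allowance,
                                       circular = circular)),
                    class = "host_profile")
  prof$lexa <- find_lexa(genome, reference = lexa_reference,
                         min_score = lexa_min_score)
  if (is.null(prof$lexa)) { prof$status <- "NO_LEXA"; return(prof) }
  prof$csb <- find_csb(genome, prof$lexa, matrix, upstream_len = upstream_len,
                       into_gene_len = into_gene_len, csb_cutoff = csb_cutoff,
                       circular = circular)
  if (is.null(prof$csb)) { prof$status <- "NO_CSB"; return(prof) }
  prof$psb_hits <- survey_psbs(genome, matrix, scope = scope,
                               mismatch_allowance = mismatch_allowance,
                               upstream_len = upstream_len,
                               into_gene_len = into_gene_len,
                               circular = circular)
  prof$thresholds <- derive_thresholds(prof$psb_hits$hi, method = method,
                                       bandwidth = bandwidth,
                                       min_psb_count = min_psb_count)
  prof$status <- if (prof$thresholds$status == "OK") "OK" else "AMBIGUOUS_CLUSTERING"
  prof
}

#' @export
print.host_profile <- function(x, ...) {
  cat(sprintf("<host_profile> %s: status %s\n", x$genome_id, x$status))
  if (!is.null(x$lexa))
    cat(sprintf("  lexA: %s [%d, %d) %s, score %.2f\n", x$lexa$feature_id,
                x$lexa$start, x$lexa$end, x$lexa$strand, x$lexa$detection_score))
  if (!is.null(x$csb))
    cat(sprintf("  CSB: HI %.3f, %d bp from lexA start\n",
                x$csb$hit$hi, x$csb$distance_to_lexa_start))
  if (!is.null(x$psb_hits)) cat(sprintf("  PSBs: %d\n", nrow(x$psb_hits)))
  if (!is.null(x$thresholds) && x$thresholds$status == "OK")
    cat(sprintf("  thresholds: hi_c1 %.3f, hi_c2 %.3f\n",
                x$thresholds$hi_c1, x$thresholds$hi_c2))
  invisible(x)
}

#' @rdname build_host_profile
#' @param x a `host_profile`.
#' @param ... unused.
#' @export
tidy.host_profile <- function(x, ...) {
  if (is.null(x$psb_hits) || !nrow(x$psb_hits)) {
    return(tibble(replicon_id = character(), start = integer(),
                  end = integer(), strand = character(),
                  sequence = character(), hi = double(),
                  cluster = character()))
  }
  hits <- x$psb_hits
  cluster <- rep(NA_character_, nrow(hits))
  th <- x$thresholds
  if (!is.null(th) && th$status == "OK") {
    cluster <- dplyr::case_when(hits$hi <= th$hi_c1 ~ "low",
                                hits$hi >= th$hi_c2 ~ "high",
                                TRUE ~ "intermediate")
  }
  mutate(select(hits, -"context_feature_id"), cluster = cluster)
}

#' @rdname build_host_profile
#' @export
glance.host_profile <- function(x, ...) {
  th <- x$thresholds
  tibble(genome_id = x$genome_id,
         status = x$status,
         lexa_found = !is.null(x$lexa),
         lexa_feature = if (is.null(x$lexa)) NA_character_ else x$lexa$feature_id,
         csb_found = !is.null(x$csb),
         csb_hi = if (is.null(x$csb)) NA_real_ else x$csb$hit$hi,
         n_psbs = if (is.null(x$psb_hits)) 0L else nrow(x$psb_hits),
         hi_c1 = if (is.null(th)) NA_real_ else th$hi_c1,
         hi_c2 = if (is.null(th)) NA_real_ else th$hi_c2,
         cluster_method = if (is.null(th)) NA_character_ else th$method)
}

#' Plot a host profile's HI distribution
#'
#' Histogram of the genome-wide PSB heterology indices with the derived
#' thresholds drawn as dashed lines (when available).
#'
#' @param object a `host_profile`.
#' @param binwidth histogram bin width in HI units.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.host_profile <- function(object, binwidth = 1, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$hi)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey60",
                            colour = "grey30") +
    ggplot2::labs(x = "Heterology index (HI)", y = "PSB count",
                  title = object$genome_id,
                  subtitle = paste("status:", object$status)) +
    ggplot2::theme_minimal()
  th <- object$thresholds
  if (!is.null(th) && th$status == "OK") {
    p <- p + ggplot2::geom_vline(xintercept = c(th$hi_c1, th$hi_c2),
                                 linetype = "dashed", colour = "red")
  }
  p
}
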