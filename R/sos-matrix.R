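#' The canonical E. coli SOS box
#'
#' The 20-bp LexA operator consensus 5'-TACTG(TA)5CAGTA-3'. The motif is
#' palindromic (it equals its own reverse complement), which is why a
#' forward-strand core scan finds operators on both strands.
#'
#' @return a length-one character string.
#' @export
canonical_sos_box <- function() "TACTGTATATATATACAGTA"

# core constraint of the canonical box: CTG at motif positions 3-5 and CAG
# at 16-18 (1-based). Stored as integer offsets + required base.
sos_core_default <- function() {
  tibble(pos = c(3L, 4L, 5L, 16L, 17L, 18L),
         base = c("C", "T", "G", "C", "A", "G"))
}

new_sos_matrix <- function(counts, pseudocount, core, n_sites) {
  L <- nrow(counts)
  stopifnot(ncol(counts) == 4L, L >= 1L, pseudocount > 0)
  colnames(counts) <- c("A", "C", "G", "T")
  structure(
    list(length = L,
         counts = counts,
         pseudocount = pseudocount,
         n_sites = n_sites,
         core = core,
         consensus = consensus_from_counts(counts)),
    class = "sos_matrix")
}

# per-column argmax; ties resolved toward the canonical box base (when the
# motif length matches), then alphabetically
consensus_from_counts <- function(counts) {
  L <- nrow(counts)
  canon <- if (L == 20L) strsplit(canonical_sos_box(), "")[[1]] else rep(NA_character_, L)
  bases <- colnames(counts)
  out <- character(L)
  for (i in seq_len(L)) {
    mx <- max(counts[i, ])
    cand <- bases[counts[i, ] == mx]
    out[i] <- if (!is.na(canon[i]) && canon[i] %in% cand) canon[i] else sort(cand)[1]
  }
  paste(out, collapse = "")
}

#' Build an SOS-box count matrix from aligned sites
#'
#' Tallies base counts per position over a set of equal-length aligned
#' operator sites. The consensus is the per-column majority base, with ties
#' broken toward the canonical E. coli box and then alphabetically.
#'
#' @param aligned_sites character vector of equal-length DNA strings
#'   (at least two).
#' @param pseudocount positive smoothing constant added to every count when
#'   scoring (default 0.5, the classical heterology-index formulation).
#' @param core tibble with columns `pos`, `base` giving the invariant core
#'   a scan window must match; defaults to CTG at 3-5 and CAG at 16-18.
#' @return an object of class `sos_matrix`.
#' @examples
#' m <- build_sos_matrix(rep(canonical_sos_box(), 10))
#' m$consensus
#' @export
build_sos_matrix <- function(aligned_sites, pseudocount = 0.5,
                             core = sos_core_default()) {
  if (length(aligned_sites) < 2L) stop("need at least two aligned sites")
  lens <- nchar(aligned_sites)
  if (length(unique(lens)) != 1L) stop("aligned sites have unequal lengths")
  L <- lens[1]
  chars <- matrix(unlist(strsplit(toupper(aligned_sites), "")),
                  nrow = length(aligned_sites), byrow = TRUE)
  if (!all(chars %in% c("A", "C", "G", "T")))
    stop("sites must contain only A/C/G/T")
  counts <- sapply(c("A", "C", "G", "T"),
                   function(b) colSums(matrix(chars == b, nrow = nrow(chars))))
  counts <- matrix(as.integer(counts), nrow = L, ncol = 4L,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  if (!is.null(core) && nrow(core) > 0 && any(core$pos > L))
    core <- core[core$pos <= L, , drop = FALSE]
  new_sos_matrix(counts, pseudocount, core, n_sites = length(aligned_sites))
}

#' Read an SOS-box matrix from a TSV file
#'
#' The format is a tab-separated table with header `pos A C G T`, one row
#' per motif position, preceded by comment metadata lines
#' `#length=`, `#pseudocount=`, `#n_sites=` and
#' `#core=3-5:CTG,16-18:CAG`. The consensus is always recomputed from the
#' counts, never trusted from the file.
#'
#' @param path file path; `"default"` loads the packaged symmetrized matrix.
#' @return an `sos_matrix`.
#' @export
read_sos_matrix <- function(path = "default") {
  if (identical(path, "default")) path <- sosdep_extdata("sosbox_matrix_synthetic.tsv")
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key, default = NULL) {
    hit <- grep(paste0("^#", key, "="), meta, value = TRUE)
    if (!length(hit)) return(default)
    sub(paste0("^#", key, "="), "", hit[1])
  }
  pseudocount <- as.numeric(get_meta("pseudocount", "0.5"))
  core_spec <- get_meta("core", "3-5:CTG,16-18:CAG")
  tab <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
  need <- c("pos", "A", "C", "G", "T")
  if (!all(need %in% names(tab))) stop("matrix file must have columns pos A C G T")
  tab <- tab[order(tab$pos), ]
  counts <- as.matrix(tab[, c("A", "C", "G", "T")])
  if (any(counts < 0)) stop("negative counts in matrix file")
  sums <- rowSums(counts)
  if (length(unique(sums)) != 1L)
    stop("matrix columns must all sum to the same number of sites")
  new_sos_matrix(counts, pseudocount, parse_core_spec(core_spec), n_sites = sums[1])
}

parse_core_spec <- function(spec) {
  if (is.null(spec) || !nzchar(spec)) return(sos_core_default()[0, ])
  parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
  out <- lapply(parts, function(p) {
    m <- regmatches(p, regexec("^(\\d+)-(\\d+):([ACGT]+)$", p))[[1]]
    if (length(m) != 4L) stop("bad #core= entry: ", p)
    pos <- seq(as.integer(m[2]), as.integer(m[3]))
    base <- strsplit(m[4], "")[[1]]
    if (length(base) != length(pos)) stop("core span and bases disagree: ", p)
    tibble(pos = pos, base = base)
  })
  bind_rows(out)
}

#' Write an SOS-box matrix to the package TSV format
#'
#' @param matrix an `sos_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sos_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "sos_matrix"))
  core <- matrix$core
  core_str <- if (nrow(core)) {
    runs <- split(core, cumsum(c(1, diff(core$pos) != 1)))
    paste(vapply(runs, function(r)
      sprintf("%d-%d:%s", min(r$pos), max(r$pos), paste(r$base, collapse = "")),
      character(1)), collapse = ",")
  } else ""
  hdr <- c(sprintf("#length=%d", matrix$length),
           sprintf("#pseudocount=%g", matrix$pseudocount),
           sprintf("#n_sites=%d", as.integer(matrix$n_sites)),
           sprintf("#core=%s", core_str),
           paste(c("pos", "A", "C", "G", "T"), collapse = "\t"))
  rows <- vapply(seq_len(matrix$length), function(i)
    paste(c(i, matrix$counts[i, ]), collapse = "\t"), character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' The packaged default scoring matrix
#'
#' A palindromically symmetrized count matrix around the canonical E. coli
#' SOS box (see `inst/extdata/sosbox_matrix_synthetic.tsv`). It is a
#' constructed stand-in with realistic position-wise degeneracy, intended
#' as a documented, user-replaceable default.
#'
#' @return an `sos_matrix`.
#' @export
default_sos_matrix <- function() {
  read_sos_matrix("default")
}

#' @export
print.sos_matrix <- function(x, ...) {
  cat(sprintf("<sos_matrix> L=%d, n_sites=%d, pseudocount=%g\n",
              x$length, as.integer(x$n_sites), x$pseudocount))
  cat("consensus:", x$consensus, "\n")
  if (nrow(x$core))
    cat("core:", paste(sprintf("%d:%s", x$core$pos, x$core$base), collapse = " "), "\n")
  invisible(x)
}

# L x 4 matrix of per-position, per-base HI contributions:
# S[i, b] = ln((n_consensus + p) / (n_b + p)); zero at the consensus base.
hi_contributions <- function(matrix) {
  cons <- strsplit(matrix$consensus, "")[[1]]
  cons_idx <- match(cons, c("A", "C", "G", "T"))
  n_max <- matrix$counts[cbind(seq_len(matrix$length), cons_idx)]
  log((n_max + matrix$pseudocount) / (matrix$counts + matrix$pseudocount))
}

#' Heterology index of a window
#'
#' The heterology index (HI) measures how far a DNA window diverges from the
#' operator consensus under the count-matrix model:
#' \deqn{HI(w) = \sum_i \ln\frac{n_i(\mathrm{consensus}_i) + p}{n_i(w_i) + p}}
#' where \eqn{n_i(b)} is the count of base \eqn{b} at position \eqn{i} and
#' \eqn{p} the pseudocount. HI is zero for the consensus, non-negative
#' everywhere, and additive over positions; lower HI means stronger
#' predicted LexA binding.
#'
#' @param matrix an `sos_matrix`.
#' @param window character vector of DNA strings, each exactly the motif
#'   length and free of N.
#' @return numeric vector of HI values, one per window.
#' @examples
#' m <- default_sos_matrix()
#' hi_score(m, m$consensus)
#' @export
hi_score <- function(matrix, window) {
  stopifnot(inherits(matrix, "sos_matrix"))
  window <- toupper(window)
  L <- matrix$length
  if (any(nchar(window) != L))
    stop("window length must equal the motif length (", L, ")")
  S <- hi_contributions(matrix)
  chars <- matrix(unlist(strsplit(window, "")), nrow = length(window), byrow = TRUE)
  idx <- match(chars, c("A", "C", "G", "T"))
  if (anyNA(idx)) stop("window contains characters other than A/C/G/T")
  idx <- matrix(idx, nrow = length(window))
  vapply(seq_along(window), function(j) sum(S[cbind(seq_len(L), idx[j, ])]),
         numeric(1))
}

# fast path used by the scanner: windows already integer-encoded as an
# n x L matrix of indices into A,C,G,T
hi_score_encoded <- function(matrix, enc) {
  S <- hi_contributions(matrix)
  L <- matrix$length
  n <- nrow(enc)
  tot <- numeric(n)
  for (i in seq_len(L)) tot <- tot + S[i, ][enc[, i]]
  tot
}
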