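#' Round half up
#'
#' Fixed-point rounding with ties going away from zero, the convention used
#' in the package's percentage reports (base `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return numeric vector rounded to `digits` places.
#' @examples
#' round_half_up(c(0.125, 0.135), 2)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# reverse complement of plain character strings (vectorized)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# cosine distance between two non-negative frequency vectors
cosine_distance <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine distance undefined for a zero vector")
  d <- 1 - sum(a * b) / (na * nb)
  # clamp tiny negative round-off
  max(d, 0)
}

# 0-based half-open -> 1-based inclusive (for reports)
to_1based <- function(start0, end0) list(start = start0 + 1L, end = end0)

# path to a packaged file
sosdep_extdata <- function(file) {
  p <- system.file("extdata", file, package = "sosdep")
  if (!nzchar(p)) stop("packaged file not found: ", file)
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
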