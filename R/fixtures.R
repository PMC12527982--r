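# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Design a core-preserving operator with a target heterology index
#'
#' Greedy hill-climb from the consensus: at each step every single-base
#' substitution at a non-core position is evaluated (HI is additive, so
#' the update is exact) and the move bringing the running HI closest to
#' the target is applied; the climb stops inside the tolerance band.
#' Errors if the target is unreachable with the core fixed.
#'
#' @param matrix an `sos_matrix`.
#' @param target_hi desired HI (>= 0).
#' @param tolerance acceptance half-width (default 0.25).
#' @param seed optional; shuffles tie-breaking among equally good moves so
#'   different seeds yield different sequences with the same HI.
#' @return a motif-length DNA string whose [hi_score()] is within
#'   `tolerance` of `target_hi`.
#' @examples
#' m <- default_sos_matrix()
#' s <- design_sequence_for_hi(m, 10)
#' hi_score(m, s)
#' @export
design_sequence_for_hi <- function(matrix, target_hi, tolerance = 0.25,
                                   seed = NULL) {
  stopifnot(inherits(matrix, "sos_matrix"), target_hi >= 0)
  S <- hi_contributions(matrix)
  L <- matrix$length
  free <- setdiff(seq_len(L), matrix$core$pos)
  max_hi <- sum(apply(S[free, , drop = FALSE], 1, max))
  if (target_hi > max_hi + tolerance)
    stop(sprintf("target HI %.2f unreachable (max %.2f with core fixed)",
                 target_hi, max_hi))
  cur <- match(strsplit(matrix$consensus, "")[[1]], c("A", "C", "G", "T"))
  run <- function() {
    state <- cur
    hi <- sum(S[cbind(seq_len(L), state)])
    moves <- expand.grid(pos = free, base = 1:4)
    moves <- moves[order(moves$pos, moves$base), ]
    if (!is.null(seed)) moves <- moves[sample.int(nrow(moves)), ]
    repeat {
      if (abs(hi - target_hi) <= tolerance) break
      deltas <- S[cbind(moves$pos, moves$base)] - S[cbind(moves$pos, state[moves$pos])]
      gaps <- abs(hi + deltas - target_hi)
      best <- which.min(gaps)
      if (gaps[best] < abs(hi - target_hi) - 1e-12) {
        state[moves$pos[best]] <- moves$base[best]
        hi <- hi + deltas[best]
        next
      }
      # single substitutions stalled: search pairs of substitutions at two
      # distinct positions (HI additivity makes the combined update exact)
      improved <- FALSE
      best_pair <- NULL; best_gap <- abs(hi - target_hi) - 1e-12
      for (a in seq_len(nrow(moves))) {
        da <- deltas[a]
        ok <- moves$pos != moves$pos[a]
        gaps2 <- abs(hi + da + deltas[ok] - target_hi)
        b <- which.min(gaps2)
        if (gaps2[b] < best_gap) {
          best_gap <- gaps2[b]
          best_pair <- c(a, which(ok)[b])
          improved <- TRUE
        }
      }
      if (!improved)
        stop(sprintf("cannot reach HI %.2f within +/- %.2f from the consensus",
                     target_hi, tolerance))
      for (mv in best_pair) {
        hi <- hi + (S[cbind(moves$pos[mv], moves$base[mv])] -
                      S[cbind(moves$pos[mv], state[moves$pos[mv]])])
        state[moves$pos[mv]] <- moves$base[mv]
      }
    }
    paste(c("A", "C", "G", "T")[state], collapse = "")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Specify a synthetic fixture genome
#'
#' Describes a fully annotated synthetic replicon with known truth: a
#' planted lexA gene carrying the packaged reference LexA translation with
#' a consensus SOS box 80 bp upstream; background CDSs whose promoters
#' carry operators designed to a low/high HI mixture (defaults mirror the
#' E. coli peaks near 7 and 22); and prophage regions whose promoter boxes
#' are designed to a chosen minimum HI (or omitted entirely). The
#' background sequence is scrubbed of accidental core motifs, so the only
#' scannable operators are the planted ones and truth tables are exact.
#'
#' @param seed integer driving all randomness; the same spec and seed
#'   reproduce byte-identical files.
#' @param n_background_cds background genes outside prophages (default 30).
#' @param low_hi_targets,high_hi_targets designed HI values for planted
#'   background operators; `NULL` draws `n_low`/`n_high` values from
#'   normal mixtures centered at 7 (sd 1, clamped to `[5, 9]`) and 22
#'   (sd 2, clamped to `[19, 25]`).
#' @param n_low,n_high mixture sizes when targets are drawn (default 15).
#' @param prophages list of `list(designed_hi_min =, truth_label =)`
#'   entries (`designed_hi_min = NA` plants no operator). The default four
#'   prophages carry boxes at HI 3 and 4 (SdP truth) and 25 and 26 (SiP
#'   truth), well clear of both thresholds.
#' @param gc_background background GC fraction (default 0.5).
#' @param replicon_id name of the synthetic replicon.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_background_cds = 30L,
                         low_hi_targets = NULL, high_hi_targets = NULL,
                         n_low = 15L, n_high = 15L,
                         prophages = list(
                           list(designed_hi_min = 3, truth_label = "SdP"),
                           list(designed_hi_min = 4, truth_label = "SdP"),
                           list(designed_hi_min = 25, truth_label = "SiP"),
                           list(designed_hi_min = 26, truth_label = "SiP")),
                         gc_background = 0.5,
                         replicon_id = sprintf("synfix%05d", seed)) {
  structure(list(seed = as.integer(seed), n_background_cds = n_background_cds,
                 low_hi_targets = low_hi_targets,
                 high_hi_targets = high_hi_targets,
                 n_low = n_low, n_high = n_high, prophages = prophages,
                 gc_background = gc_background, replicon_id = replicon_id),
            class = "fixture_spec")
}

# most-used-first E. coli codon options per amino acid; the lexA gene body
# is built from these, swapping synonyms whenever a choice would create an
# accidental CTG-N10-CAG core
codon_options <- function() {
  list(A = c("GCG", "GCC", "GCA"), R = c("CGT", "CGC", "CGA"),
       N = c("AAC", "AAT"), D = c("GAT", "GAC"), C = c("TGC", "TGT"),
       Q = c("CAG", "CAA"), E = c("GAA", "GAG"), G = c("GGC", "GGT"),
       H = c("CAT", "CAC"), I = c("ATT", "ATC"), L = c("CTG", "CTC", "TTA"),
       K = c("AAA", "AAG"), M = "ATG", F = c("TTT", "TTC"),
       P = c("CCG", "CCA"), S = c("AGC", "TCT"), T = c("ACC", "ACG"),
       W = "TGG", Y = c("TAT", "TAC"), V = c("GTG", "GTT"))
}

core_regex <- function() "CTG.{10}CAG"

# encode a protein as DNA without introducing the scan core
encode_protein <- function(protein) {
  opts <- codon_options()
  aas <- strsplit(protein, "")[[1]]
  out <- character(length(aas) + 1L)
  built <- ""
  for (i in seq_along(aas)) {
    cands <- opts[[aas[i]]]
    if (is.null(cands)) stop("no codon for residue ", aas[i])
    chosen <- NA_character_
    for (cand in cands) {
      tail_ctx <- substr(built, max(1L, nchar(built) - 15L), nchar(built))
      if (!grepl(core_regex(), paste0(tail_ctx, cand))) { chosen <- cand; break }
    }
    if (is.na(chosen)) chosen <- cands[length(cands)]
    out[i] <- chosen
    built <- paste0(built, chosen)
  }
  out[length(aas) + 1L] <- "TAA"
  paste(out, collapse = "")
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

# random CDS: ATG + (n_codons - 2) sense codons + TAA
random_cds <- function(n_codons) {
  sense <- setdiff(mkAllStrings_codons(), c("TAA", "TAG", "TGA"))
  paste(c("ATG", sample(sense, n_codons - 2L, replace = TRUE), "TAA"),
        collapse = "")
}

#' Generate a synthetic fixture genome with known truth
#'
#' Materializes a [fixture_spec()]: builds the replicon, writes it as a
#' GenBank flat file plus a BED of prophage regions and a truth JSON, and
#' verifies by rescanning that every planted operator is recovered at its
#' planted interval with an HI within tolerance of its design target.
#'
#' @param spec a `fixture_spec`.
#' @param dir output directory (created if needed).
#' @param tolerance design tolerance passed to [design_sequence_for_hi()].
#' @return list with `genome` (a `genome_record`), `regions` (prophage
#'   tibble), `truth` (list), and `paths` (genbank/bed/truth files).
#' @export
generate_fixture <- function(spec, dir, tolerance = 0.25) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mat <- default_sos_matrix()
  with_seed(spec$seed, {
    low <- spec$low_hi_targets %||%
      pmin(pmax(stats::rnorm(spec$n_low, 7, 1), 5), 9)
    high <- spec$high_hi_targets %||%
      pmin(pmax(stats::rnorm(spec$n_high, 22, 2), 19), 25)
    targets <- as.vector(rbind(c(low, rep(NA, max(0, length(high) - length(low)))),
                               c(high, rep(NA, max(0, length(low) - length(high))))))
    targets <- targets[!is.na(targets)]
    if (length(targets) > spec$n_background_cds)
      stop("more HI targets than background CDSs to host them")

    chunks <- character(0)
    at <- 0L
    add <- function(s) {
      chunks[[length(chunks) + 1L]] <<- s
      start <- at
      at <<- at + nchar(s)
      start
    }
    cds_rows <- list()
    psb_truth <- list()
    prophage_rows <- list()

    add(random_dna(200L, spec$gc_background))

    # lexA cassette: 350 bp upstream with the consensus CSB ending 80 bp
    # before the start codon, then the lexA CDS
    lexa_prot <- as.character(Biostrings::readAAStringSet(
      sosdep_extdata("lexa_reference.faa"))[[1]])
    up <- random_dna(350L, spec$gc_background)
    csb_off <- 350L - 80L - mat$length
    substr(up, csb_off + 1L, csb_off + mat$length) <- mat$consensus
    up_start <- add(up)
    csb_interval <- c(up_start + csb_off, up_start + csb_off + mat$length)
    psb_truth[[length(psb_truth) + 1L]] <-
      list(start = csb_interval[1], end = csb_interval[2], designed_hi = 0,
           role = "csb")
    lexa_dna <- encode_protein(lexa_prot)
    lexa_start <- add(lexa_dna)
    cds_rows[[length(cds_rows) + 1L]] <- tibble(
      feature_id = "lexA", start = lexa_start,
      end = lexa_start + nchar(lexa_dna), strand = "+",
      product = "LexA repressor", translation = lexa_prot)

    # background cassettes; the first length(targets) carry planted PSBs
    for (i in seq_len(spec$n_background_cds)) {
      up <- random_dna(350L, spec$gc_background)
      planted <- i <= length(targets)
      if (planted) {
        box <- design_sequence_for_hi(mat, targets[i], tolerance = tolerance,
                                      seed = spec$seed * 1000L + i)
        off <- 350L - 100L - mat$length
        substr(up, off + 1L, off + mat$length) <- box
      }
      up_start <- add(up)
      if (planted) {
        psb_truth[[length(psb_truth) + 1L]] <-
          list(start = up_start + 350L - 100L - mat$length,
               end = up_start + 350L - 100L, designed_hi = targets[i],
               role = "background_psb")
      }
      strand <- if (!planted && i %% 5L == 0L) "-" else "+"
      coding <- random_cds(150L)
      dna <- if (strand == "-") revcomp(coding) else coding
      cds_start <- add(dna)
      cds_rows[[length(cds_rows) + 1L]] <- tibble(
        feature_id = sprintf("bg%03d", i), start = cds_start,
        end = cds_start + nchar(dna), strand = strand,
        product = "hypothetical protein", translation = NA_character_)
    }

    # prophage blocks: margin, cassette with the designed box, plain
    # cassette, margin
    for (p in seq_along(spec$prophages)) {
      ph <- spec$prophages[[p]]
      add(random_dna(100L, spec$gc_background))
      block_start <- at
      up <- random_dna(350L, spec$gc_background)
      if (!is.na(ph$designed_hi_min)) {
        box <- design_sequence_for_hi(mat, ph$designed_hi_min,
                                      tolerance = tolerance,
                                      seed = spec$seed * 1000L + 500L + p)
        off <- 350L - 100L - mat$length
        substr(up, off + 1L, off + mat$length) <- box
      }
      up_start <- add(up)
      if (!is.na(ph$designed_hi_min)) {
        psb_truth[[length(psb_truth) + 1L]] <-
          list(start = up_start + 350L - 100L - mat$length,
               end = up_start + 350L - 100L, designed_hi = ph$designed_hi_min,
               role = sprintf("prophage_%02d_psb", p))
      }
      for (g in 1:2) {
        if (g == 2L) add(random_dna(350L, spec$gc_background))
        coding <- random_cds(150L)
        cds_start <- add(coding)
        cds_rows[[length(cds_rows) + 1L]] <- tibble(
          feature_id = sprintf("pp%02d_g%d", p, g), start = cds_start,
          end = cds_start + 450L, strand = "+",
          product = "phage protein", translation = NA_character_)
      }
      block_end <- at
      add(random_dna(100L, spec$gc_background))
      prophage_rows[[length(prophage_rows) + 1L]] <- tibble(
        prophage_id = sprintf("prophage_%02d", p),
        replicon_id = spec$replicon_id,
        start = block_start, end = block_end,
        designed_hi_min = ph$designed_hi_min,
        truth_label = ph$truth_label)
    }
    add(random_dna(200L, spec$gc_background))

    sequence <- paste(chunks, collapse = "")
    cds <- bind_rows(cds_rows)
    planted_boxes <- bind_rows(lapply(psb_truth, function(x)
      tibble(start = x$start, end = x$end)))
    lexa_iv <- c(lexa_start, lexa_start + nchar(lexa_dna))
    sequence <- scrub_core_motifs(sequence, planted_boxes, lexa_iv)

    genome <- genome_record(spec$replicon_id, sequence, cds,
                            source_path = "synthetic")
    # fill in translations for the GenBank file
    genome$cds$translation <- vapply(seq_len(nrow(genome$cds)), function(i) {
      if (!is.na(genome$cds$translation[i])) genome$cds$translation[i]
      else translate_cds(genome, genome$cds[i, ])
    }, character(1))

    # verify planted truth by rescanning
    hits <- scan_region(mat, genome)
    want <- sort(planted_boxes$start)
    if (!identical(sort(hits$start), as.integer(want)))
      stop("fixture verification failed: scan does not recover exactly the planted boxes")
    for (x in psb_truth) {
      got <- hits$hi[hits$start == x$start]
      if (abs(got - x$designed_hi) > tolerance + 1e-9)
        stop("fixture verification failed: planted box HI off target")
    }

    regions <- bind_rows(prophage_rows)
    gb <- file.path(dir, sprintf("%s.gbk", spec$replicon_id))
    bed <- file.path(dir, sprintf("%s_prophages.bed", spec$replicon_id))
    truth_path <- file.path(dir, sprintf("%s_truth.json", spec$replicon_id))
    write_genbank(genome, gb)
    write_prophage_bed(regions, bed)
    truth <- list(seed = spec$seed, replicon_id = spec$replicon_id,
                  lexa_interval = lexa_iv, csb_interval = csb_interval,
                  psbs = psb_truth,
                  prophages = lapply(seq_len(nrow(regions)), function(i)
                    as.list(regions[i, ])))
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    list(genome = genome, regions = regions, truth = truth,
         paths = list(genbank = gb, bed = bed, truth = truth_path))
  })
}

# mutate away accidental CTG-N10-CAG occurrences, leaving planted boxes and
# the lexA CDS untouched
scrub_core_motifs <- function(sequence, planted_boxes, lexa_interval) {
  protected <- function(pos1) {
    # pos1 is 1-based; planted intervals are 0-based half-open
    inside_box <- any(pos1 > planted_boxes$start & pos1 <= planted_boxes$end)
    inside_lexa <- pos1 > lexa_interval[1] && pos1 <= lexa_interval[2]
    inside_box || inside_lexa
  }
  planted_match_starts <- planted_boxes$start + 3L  # 1-based core start within a box
  for (round in 1:50) {
    m <- gregexpr(paste0("(?=", core_regex(), ")"), sequence, perl = TRUE)[[1]]
    if (m[1] == -1L) return(sequence)
    starts <- as.integer(m)
    starts <- starts[!starts %in% planted_match_starts]
    if (!length(starts)) return(sequence)
    for (st in starts) {
      core_pos <- c(st, st + 1L, st + 2L, st + 13L, st + 14L, st + 15L)
      free <- core_pos[!vapply(core_pos, protected, logical(1))]
      if (!length(free)) next
      pos <- free[1]
      old <- substr(sequence, pos, pos)
      substr(sequence, pos, pos) <- if (old == "A") "C" else "A"
    }
  }
  stop("could not scrub accidental core motifs from the background")
}
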