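#' Construct a genome record
#'
#' The internal unit of analysis: one replicon with its CDS annotations.
#' All internal coordinates are 0-based half-open; report writers convert
#' to 1-based inclusive.
#'
#' @param replicon_id sequence identifier.
#' @param sequence nucleotide string over A/C/G/T/N.
#' @param cds tibble with columns `feature_id`, `start`, `end` (0-based
#'   half-open), `strand` (`+`/`-`), `product`, `translation` (may be NA).
#' @param source_path provenance string.
#' @return an object of class `genome_record`.
#' @export
genome_record <- function(replicon_id, sequence, cds = NULL, source_path = "") {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("empty sequence")
  if (grepl("[^ACGTN]", sequence)) stop("sequence contains characters outside A/C/G/T/N")
  len <- nchar(sequence)
  if (is.null(cds)) {
    cds <- tibble(feature_id = character(), start = integer(), end = integer(),
                  strand = character(), product = character(),
                  translation = character())
  }
  cds <- as_tibble(cds)
  if (nrow(cds)) {
    if (any(cds$start < 0 | cds$end > len | cds$start >= cds$end))
      stop("CDS interval outside [0, replicon length) or empty")
    if (!all(cds$strand %in% c("+", "-"))) stop("CDS strand must be + or -")
    cds <- arrange(cds, .data$start, .data$end)
  }
  structure(list(replicon_id = replicon_id, sequence = sequence,
                 cds = cds, length = len, source_path = source_path),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp, %d CDS\n",
              x$replicon_id, x$length, nrow(x$cds)))
  invisible(x)
}

#' Read a genome with CDS annotations
#'
#' Accepts either a GenBank flat file (sequence + features in one file) or
#' a FASTA file paired with a GFF3 annotation. GenBank/GFF3 1-based
#' inclusive coordinates are shifted to the internal 0-based half-open
#' convention.
#'
#' @param path FASTA or GenBank file.
#' @param annotation_path GFF3 file with CDS features; required when `path`
#'   is FASTA.
#' @return named list of `genome_record`, one per replicon.
#' @export
read_genome <- function(path, annotation_path = NULL) {
  if (!file.exists(path)) stop("cannot read genome file: ", path)
  first <- readLines(path, n = 1L)
  if (grepl("^LOCUS", first)) {
    recs <- read_genbank(path)
  } else if (grepl("^>", first)) {
    if (is.null(annotation_path))
      stop("FASTA input requires a GFF3 annotation_path with CDS features")
    recs <- read_fasta_gff(path, annotation_path)
  } else {
    stop("unrecognized genome format (expected GenBank LOCUS or FASTA '>'): ", path)
  }
  stats::setNames(recs, vapply(recs, `[[`, character(1), "replicon_id"))
}

read_fasta_gff <- function(fasta_path, gff_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (!file.exists(gff_path)) stop("cannot read annotation file: ", gff_path)
  gr <- rtracklayer::import(gff_path)
  gr <- gr[!is.na(gr$type) & gr$type == "CDS"]
  ids <- as.character(GenomeInfoDb::seqnames(gr))
  unknown <- setdiff(unique(ids), names(seqs))
  if (length(unknown))
    stop("annotation replicon IDs not in FASTA: ", paste(unknown, collapse = ", "))
  lapply(seq_along(seqs), function(i) {
    nm <- names(seqs)[i]
    sel <- ids == nm
    sub_gr <- gr[sel]
    pick <- function(col) {
      v <- S4Vectors::mcols(sub_gr)[[col]]
      if (is.null(v)) rep(NA_character_, length(sub_gr)) else as.character(v)
    }
    fid <- pick("ID")
    if (all(is.na(fid))) fid <- pick("Name")
    fid[is.na(fid)] <- sprintf("%s_cds%04d", nm, which(is.na(fid)))
    cds <- tibble(
      feature_id = fid,
      start = BiocGenerics::start(sub_gr) - 1L,  # 1-based inclusive -> 0-based
      end = BiocGenerics::end(sub_gr),
      strand = as.character(BiocGenerics::strand(sub_gr)),
      product = pick("product"),
      translation = NA_character_)
    if (any(!cds$strand %in% c("+", "-")))
      stop("CDS with undefined strand in ", gff_path)
    genome_record(nm, as.character(seqs[[i]]), cds, source_path = fasta_path)
  })
}

# ---- GenBank flat files ------------------------------------------------
# Minimal reader for the subset this package consumes and its fixture
# generator emits: LOCUS, FEATURES with CDS entries located as a..b or
# complement(a..b), /locus_tag /product /translation qualifiers, ORIGIN.
read_genbank <- function(path) {
  lines <- readLines(path)
  starts <- grep("^LOCUS", lines)
  if (!length(starts)) stop("no LOCUS line in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  lapply(seq_along(starts), function(i)
    parse_genbank_record(lines[starts[i]:ends[i]], path))
}

parse_genbank_record <- function(lines, path) {
  locus <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  replicon_id <- locus[2]
  feat_at <- grep("^FEATURES", lines)
  orig_at <- grep("^ORIGIN", lines)
  if (!length(orig_at)) stop("GenBank record without ORIGIN sequence: ", path)
  seq_lines <- lines[(orig_at[1] + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  cds <- tibble(feature_id = character(), start = integer(), end = integer(),
                strand = character(), product = character(),
                translation = character())
  if (length(feat_at)) {
    flines <- lines[(feat_at[1] + 1L):(orig_at[1] - 1L)]
    is_key <- grepl("^ {5}\\S", flines)
    key_idx <- which(is_key)
    keys <- sub("^ {5}(\\S+).*$", "\\1", flines[key_idx])
    cds_rows <- list()
    for (j in seq_along(key_idx)) {
      if (keys[j] != "CDS") next
      from <- key_idx[j]
      to <- if (j < length(key_idx)) key_idx[j + 1] - 1L else length(flines)
      block <- flines[from:to]
      loc <- sub("^ {5}\\S+\\s+", "", block[1])
      quals <- parse_genbank_qualifiers(block[-1])
      strand <- if (grepl("^complement\\(", loc)) "-" else "+"
      loc2 <- gsub("complement\\(|\\)", "", loc)
      if (grepl("join|order", loc2)) {
        warning("skipping compound-location CDS in ", path, ": ", loc)
        next
      }
      m <- regmatches(loc2, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", loc2))[[1]]
      if (length(m) != 3L) {
        warning("skipping unparseable CDS location in ", path, ": ", loc)
        next
      }
      cds_rows[[length(cds_rows) + 1L]] <- tibble(
        feature_id = quals[["locus_tag"]] %||% sprintf("cds%04d", j),
        start = as.integer(m[2]) - 1L,   # 1-based inclusive -> 0-based
        end = as.integer(m[3]),
        strand = strand,
        product = quals[["product"]] %||% NA_character_,
        translation = quals[["translation"]] %||% NA_character_)
    }
    if (length(cds_rows)) cds <- bind_rows(cds_rows)
  }
  genome_record(replicon_id, sequence, cds, source_path = path)
}

parse_genbank_qualifiers <- function(lines) {
  lines <- sub("^ {21}", "", lines)
  out <- list(); cur <- NULL
  for (ln in lines) {
    if (grepl("^/", ln)) {
      eq <- regexpr("=", ln, fixed = TRUE)
      if (eq > 0) {
        cur <- substr(ln, 2, eq - 1)
        out[[cur]] <- gsub("\"", "", substr(ln, eq + 1, nchar(ln)))
      } else {
        cur <- sub("^/", "", ln); out[[cur]] <- ""
      }
    } else if (!is.null(cur)) {
      sep <- if (cur == "translation") "" else " "
      out[[cur]] <- paste0(out[[cur]], sep, gsub("\"", "", trimws(ln)))
    }
  }
  out
}

#' Write a genome record as a GenBank flat file
#'
#' Emits the subset of GenBank that [read_genome()] parses (LOCUS, CDS
#' features with locus_tag/product/translation, ORIGIN); coordinates are
#' converted back to 1-based inclusive. Round-trips with [read_genome()].
#'
#' @param record a `genome_record`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(record, path) {
  stopifnot(inherits(record, "genome_record"))
  con <- file(path, open = "wt"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("LOCUS       %-17s %d bp    DNA     linear   UNK 01-JAN-2000",
    record$replicon_id, record$length)
  w("DEFINITION  synthetic record written by sosdep.")
  w("FEATURES             Location/Qualifiers")
  w("     source          1..%d", record$length)
  if (nrow(record$cds)) {
    for (i in seq_len(nrow(record$cds))) {
      r <- record$cds[i, ]
      loc <- sprintf("%d..%d", r$start + 1L, r$end)
      if (r$strand == "-") loc <- sprintf("complement(%s)", loc)
      w("     CDS             %s", loc)
      w("                     /locus_tag=\"%s\"", r$feature_id)
      if (!is.na(r$product)) w("                     /product=\"%s\"", r$product)
      if (!is.na(r$translation)) {
        txt <- sprintf("/translation=\"%s\"", r$translation)
        wrapped <- substring(txt, seq(1, nchar(txt), 58), pmin(seq(58, nchar(txt) + 57, 58), nchar(txt)))
        for (piece in wrapped) w("                     %s", piece)
      }
    }
  }
  w("ORIGIN")
  s <- record$sequence
  for (off in seq(1, nchar(s), 60)) {
    chunk <- substr(s, off, min(off + 59, nchar(s)))
    groups <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    w("%9d %s", off, tolower(paste(groups, collapse = " ")))
  }
  w("//")
  invisible(path)
}

#' Read prophage regions from BED or GFF3
#'
#' BED intervals are 0-based half-open and pass through unchanged; GFF3
#' 1-based inclusive intervals are shifted so that the same genomic
#' interval yields identical internal coordinates from either format.
#' Regions are validated against the supplied genomes.
#'
#' @param path BED (4+ columns) or GFF3 file.
#' @param genomes named list of `genome_record` (output of [read_genome()]).
#' @return tibble with columns `prophage_id`, `replicon_id`, `start`,
#'   `end` (0-based half-open), `completeness_label`.
#' @export
read_prophage_regions <- function(path, genomes) {
  if (!file.exists(path)) stop("cannot read prophage region file: ", path)
  is_gff <- grepl("\\.gff3?$", path, ignore.case = TRUE) ||
    any(grepl("^##gff-version", readLines(path, n = 5L)))
  if (is_gff) {
    gr <- rtracklayer::import(path)
    ids <- S4Vectors::mcols(gr)$ID
    if (is.null(ids)) ids <- S4Vectors::mcols(gr)$Name
    if (is.null(ids)) ids <- sprintf("prophage_%03d", seq_along(gr))
    out <- tibble(prophage_id = as.character(ids),
                  replicon_id = as.character(GenomeInfoDb::seqnames(gr)),
                  start = BiocGenerics::start(gr) - 1L,
                  end = BiocGenerics::end(gr),
                  completeness_label = NA_character_)
  } else {
    gr <- rtracklayer::import(path, format = "BED")
    nm <- S4Vectors::mcols(gr)$name
    if (is.null(nm) || all(is.na(nm))) nm <- sprintf("prophage_%03d", seq_along(gr))
    out <- tibble(prophage_id = as.character(nm),
                  replicon_id = as.character(GenomeInfoDb::seqnames(gr)),
                  start = BiocGenerics::start(gr) - 1L,  # rtracklayer re-1-bases BED
                  end = BiocGenerics::end(gr),
                  completeness_label = NA_character_)
  }
  unknown <- setdiff(unique(out$replicon_id), names(genomes))
  if (length(unknown))
    stop("prophage regions reference unknown replicons: ",
         paste(unknown, collapse = ", "))
  lens <- vapply(genomes, `[[`, integer(1), "length")
  bad <- out$start < 0 | out$end > lens[out$replicon_id] | out$start >= out$end
  if (any(bad))
    stop("prophage region out of replicon bounds: ",
         paste(out$prophage_id[bad], collapse = ", "))
  out
}

#' Write prophage regions to BED
#'
#' @param regions tibble as returned by [read_prophage_regions()].
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_prophage_bed <- function(regions, path) {
  df <- data.frame(regions$replicon_id, regions$start, regions$end,
                   regions$prophage_id)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract promoter windows for CDS features
#'
#' For each CDS the window runs from `upstream_len` bases upstream of the
#' translation start to `into_gene_len` bases into the gene, on the CDS
#' strand. Windows are truncated at replicon boundaries unless
#' `circular = TRUE`, in which case they wrap (coordinates are then
#' reported modulo the replicon length and the window is returned as an
#' explicit sequence by the scanner). Overlapping windows from different
#' CDSs are not merged.
#'
#' @param genome a `genome_record`.
#' @param region optional one-row prophage region (tibble/list with
#'   `start`, `end`): restricts to CDSs overlapping it.
#' @param upstream_len bases upstream of the start codon (default 300).
#' @param into_gene_len bases into the CDS (default 50).
#' @param circular treat the replicon as circular (windows wrap).
#' @return tibble `parent_feature_id`, `start`, `end`, `strand`
#'   (0-based half-open; when a circular window wraps the origin,
#'   `end` may exceed the replicon length and is interpreted mod length).
#' @export
extract_promoters <- function(genome, region = NULL, upstream_len = 300L,
                              into_gene_len = 50L, circular = FALSE) {
  stopifnot(inherits(genome, "genome_record"))
  cds <- genome$cds
  if (!is.null(region)) {
    cds <- cds[cds$start < region$end & cds$end > region$start, , drop = FALSE]
  }
  if (!nrow(cds)) {
    return(tibble(parent_feature_id = character(), start = integer(),
                  end = integer(), strand = character()))
  }
  len <- genome$length
  plus <- cds$strand == "+"
  start <- ifelse(plus, cds$start - upstream_len, cds$end - into_gene_len)
  end <- ifelse(plus, cds$start + into_gene_len, cds$end + upstream_len)
  if (!circular) {
    start <- pmax(start, 0L)
    end <- pmin(end, len)
  } else {
    # wrap: normalize start into [0, len); keep end > start (may exceed len)
    shift <- ifelse(start < 0, len, 0L)
    start <- start + shift
    end <- end + shift
    too_long <- end - start > len
    end[too_long] <- start[too_long] + len
  }
  out <- tibble(parent_feature_id = cds$feature_id,
                start = as.integer(start), end = as.integer(end),
                strand = cds$strand)
  out[out$end > out$start, , drop = FALSE]
}

# substring of the replicon; supports end > length for circular wrap
get_subseq <- function(genome, start0, end0) {
  len <- genome$length
  if (end0 <= len) return(substr(genome$sequence, start0 + 1L, end0))
  paste0(substr(genome$sequence, start0 + 1L, len),
         substr(genome$sequence, 1L, end0 - len))
}

# translate a CDS row to protein (used when annotations lack /translation)
translate_cds <- function(genome, cds_row) {
  s <- get_subseq(genome, cds_row$start, cds_row$end)
  if (cds_row$strand == "-") s <- revcomp(s)
  usable <- nchar(s) - nchar(s) %% 3L
  if (usable < 3L) return(NA_character_)
  dna <- Biostrings::DNAString(substr(s, 1L, usable))
  aa <- if (grepl("N", s, fixed = TRUE)) {
    suppressWarnings(as.character(Biostrings::translate(dna, if.fuzzy.codon = "solve")))
  } else {
    suppressWarnings(as.character(Biostrings::translate(dna)))
  }
  sub("\\*$", "", aa)
}
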