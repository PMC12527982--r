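# exit codes shared with the command-line front end: biological outcomes
# are reportable results, not crashes, and get their own codes
sosdep_exit_codes <- function() {
  c(OK = 0L, NO_LEXA = 10L, NO_CSB = 11L, AMBIGUOUS_CLUSTERING = 12L,
    IO_ERROR = 2L)
}

#' Run the full predictor on one genome
#'
#' Reads the genome (and prophage regions when given), builds the host
#' profile, classifies every prophage, computes genomic features, and
#' writes the six report files into `out_dir`: `host_profile.json`,
#' `psb_hits.tsv`, `prophage_calls.tsv`, `summary.tsv`, `features.tsv`
#' and `run_log.txt`. Input/parse failures raise errors before any TSV is
#' written; biological outcomes (no LexA, no canonical SOS box, ambiguous
#' clustering) still produce all files, with prophage classes `NA`.
#' All coordinates in TSV reports are 1-based inclusive, marked by a
#' `# coords=1-based` header comment.
#'
#' @param genome_path GenBank file, or FASTA (then `annotation_path` is
#'   required).
#' @param out_dir output directory, created if needed.
#' @param prophage_path optional BED/GFF3 of prophage regions.
#' @param annotation_path optional GFF3 when `genome_path` is FASTA.
#' @param matrix_path scoring matrix TSV or `"default"`.
#' @param upstream_len,into_gene_len,mismatch_allowance,scope,csb_cutoff,method,bandwidth,min_psb_count,circular
#'   pipeline parameters, see [build_host_profile()].
#' @param seed integer recorded in the log and used for any stochastic
#'   step (none in the default configuration; clustering is
#'   deterministic).
#' @param timestamp write a timestamp line into the log (disable for
#'   byte-identical re-runs).
#' @return invisibly, a list with `status`, `exit_code`, `profile`,
#'   `calls`, `summary`, `features` and `files`.
#' @export
run_single <- function(genome_path, out_dir, prophage_path = NULL,
                       annotation_path = NULL, matrix_path = "default",
                       upstream_len = 300L, into_gene_len = 50L,
                       mismatch_allowance = 0L, scope = "whole_genome",
                       csb_cutoff = 12, method = "meanshift",
                       bandwidth = NULL, min_psb_count = 10L,
                       circular = FALSE, seed = 1L, timestamp = TRUE) {
  genomes <- read_genome(genome_path, annotation_path)
  regions <- if (!is.null(prophage_path))
    read_prophage_regions(prophage_path, genomes)
  else tibble(prophage_id = character(), replicon_id = character(),
              start = integer(), end = integer(),
              completeness_label = character())
  matrix <- read_sos_matrix(matrix_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)

  # profile the largest replicon (the chromosome carries lexA); classify
  # prophages on whichever replicon they sit on
  lens <- vapply(genomes, `[[`, integer(1), "length")
  host <- genomes[[which.max(lens)]]
  profile <- build_host_profile(host, matrix, scope = scope,
                                upstream_len = upstream_len,
                                into_gene_len = into_gene_len,
                                csb_cutoff = csb_cutoff, method = method,
                                bandwidth = bandwidth,
                                min_psb_count = min_psb_count,
                                mismatch_allowance = mismatch_allowance,
                                circular = circular)
  calls <- bind_rows(lapply(names(genomes), function(nm) {
    regs <- regions[regions$replicon_id == nm, , drop = FALSE]
    if (!nrow(regs)) return(NULL)
    classify_prophages(genomes[[nm]], regs, profile, matrix,
                       upstream_len = upstream_len,
                       into_gene_len = into_gene_len,
                       mismatch_allowance = mismatch_allowance,
                       circular = circular)
  }))
  if (is.null(calls) || !nrow(calls)) {
    calls <- classify_prophages(host, regions[0, ], profile, matrix)
  }
  summary <- summarize_calls(calls)
  feats <- bind_rows(c(list(feature_vector(host)),
                       lapply(seq_len(nrow(regions)), function(i) {
                         g <- genomes[[regions$replicon_id[i]]]
                         feature_vector(g, regions[i, ])
                       })))

  files <- write_reports(out_dir, profile, calls, summary, feats,
                         params = list(genome_path = genome_path,
                                       prophage_path = prophage_path,
                                       annotation_path = annotation_path,
                                       matrix_path = matrix_path,
                                       upstream_len = upstream_len,
                                       into_gene_len = into_gene_len,
                                       mismatch_allowance = mismatch_allowance,
                                       scope = scope, csb_cutoff = csb_cutoff,
                                       method = method,
                                       bandwidth = bandwidth,
                                       min_psb_count = min_psb_count,
                                       circular = circular, seed = seed),
                         timestamp = timestamp)
  invisible(list(status = profile$status,
                 exit_code = unname(sosdep_exit_codes()[profile$status]),
                 profile = profile, calls = calls, summary = summary,
                 features = feats, files = files))
}

write_tsv_report <- function(df, path, comment = "# coords=1-based") {
  con <- file(path, open = "wt"); on.exit(close(con))
  if (!is.null(comment)) writeLines(comment, con)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) ifelse(is.na(x), NA, sprintf("%.2f", x)))
  suppressWarnings(write.table(df, con, sep = "\t", quote = FALSE,
                               row.names = FALSE, na = "NA"))
  path
}

write_reports <- function(out_dir, profile, calls, summary, feats, params,
                          timestamp = TRUE) {
  th <- profile$thresholds
  hp <- list(genome_id = profile$genome_id, status = profile$status,
             lexa = if (is.null(profile$lexa)) NULL else {
               l <- unclass(profile$lexa)
               l$start <- l$start + 1L  # report 1-based inclusive
               l
             },
             csb = if (is.null(profile$csb)) NULL else
               list(start = profile$csb$hit$start + 1L,
                    end = profile$csb$hit$end,
                    strand = profile$csb$hit$strand,
                    hi = profile$csb$hit$hi,
                    distance_to_lexa_start = profile$csb$distance_to_lexa_start),
             n_psbs = if (is.null(profile$psb_hits)) 0L else nrow(profile$psb_hits),
             hi_c1 = if (is.null(th)) NULL else th$hi_c1,
             hi_c2 = if (is.null(th)) NULL else th$hi_c2,
             cluster_method = if (is.null(th)) NULL else th$method)
  f_profile <- file.path(out_dir, "host_profile.json")
  jsonlite::write_json(hp, f_profile, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")

  hits <- if (is.null(profile$psb_hits)) {
    tibble(replicon_id = character(), start = integer(), end = integer(),
           strand = character(), sequence = character(), hi = double())
  } else select(profile$psb_hits, -"context_feature_id")
  hits$start <- hits$start + 1L
  f_hits <- write_tsv_report(hits, file.path(out_dir, "psb_hits.tsv"))

  calls_out <- calls
  calls_out$start <- calls_out$start + 1L
  f_calls <- write_tsv_report(calls_out, file.path(out_dir, "prophage_calls.tsv"))
  f_summary <- write_tsv_report(summary, file.path(out_dir, "summary.tsv"),
                                comment = NULL)
  feats_out <- feats[, setdiff(names(feats), "codon_freq")]
  f_feats <- write_tsv_report(feats_out, file.path(out_dir, "features.tsv"),
                              comment = NULL)

  log_lines <- c(
    if (timestamp) sprintf("time\t%s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    sprintf("sosdep_version\t%s", as.character(utils::packageVersion("sosdep"))),
    vapply(names(params), function(k)
      sprintf("%s\t%s", k, paste(format(params[[k]] %||% "NULL"), collapse = ",")),
      character(1)),
    sprintf("status\t%s", profile$status),
    sprintf("n_psbs\t%d", hp$n_psbs))
  f_log <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, f_log)
  list(host_profile = f_profile, psb_hits = f_hits, prophage_calls = f_calls,
       summary = f_summary, features = f_feats, run_log = f_log)
}

#' Run the predictor over a manifest of genomes
#'
#' The manifest is a TSV (or tibble) with columns `genome` and optionally
#' `prophages` and `annotation` (file paths). Each genome is processed
#' independently in its own subdirectory of `out_dir`; failures are
#' recorded and do not abort the batch. An aggregate class summary over
#' all successful runs is written to `batch_summary.tsv`.
#'
#' @param manifest path to a TSV manifest, or a tibble.
#' @param out_dir output directory.
#' @param ... parameters forwarded to [run_single()].
#' @return invisibly, list with `results` (per-genome run results or error
#'   messages), `summary` (aggregate tibble), `failures` (tibble).
#' @export
run_batch <- function(manifest, out_dir, ...) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stop("cannot read manifest: ", manifest)
    manifest <- as_tibble(read.table(manifest, header = TRUE, sep = "\t",
                                     stringsAsFactors = FALSE))
  }
  if (!nrow(manifest)) stop("empty manifest")
  if (!"genome" %in% names(manifest)) stop("manifest needs a 'genome' column")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list(); fails <- list()
  for (i in seq_len(nrow(manifest))) {
    gpath <- manifest$genome[i]
    tag <- sprintf("genome_%03d", i)
    res <- tryCatch(
      run_single(gpath, file.path(out_dir, tag),
                 prophage_path = if ("prophages" %in% names(manifest))
                   manifest$prophages[i] else NULL,
                 annotation_path = if ("annotation" %in% names(manifest))
                   manifest$annotation[i] else NULL, ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- tibble(genome = gpath,
                                            error = conditionMessage(res))
    } else {
      results[[tag]] <- res
    }
  }
  all_calls <- bind_rows(lapply(results, `[[`, "calls"))
  agg <- summarize_calls(if (nrow(all_calls)) all_calls else
    tibble(class = character()))
  write_tsv_report(agg, file.path(out_dir, "batch_summary.tsv"), comment = NULL)
  failures <- if (length(fails)) bind_rows(fails) else
    tibble(genome = character(), error = character())
  if (nrow(failures))
    write_tsv_report(failures, file.path(out_dir, "batch_failures.tsv"),
                     comment = NULL)
  invisible(list(results = results, summary = agg, failures = failures))
}
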