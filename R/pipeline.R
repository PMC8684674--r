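#' Pipeline tunables
#'
#' All thresholds of the insertion-site pipeline in one place.  Defaults
#' are the published operating point: target-screen E-value cutoff 1e-3,
#' flanks and genomic alignments longer than 200 bp at 80 percent identity
#' or better, neighbor genes within 2000 bp, and a minimum site support of
#' one read.
#'
#' @param evalue_max E-value cutoff for both alignment stages.
#' @param min_flank_len Minimum extracted flank length (bp).
#' @param min_len Minimum genomic aligned length, strict (bp).
#' @param min_identity Minimum genomic percent identity, inclusive.
#' @param merge_dist Breakpoint clustering distance (bp).
#' @param neighbor_window Gene neighborhood distance (bp).
#' @param min_reads Minimum distinct supporting reads per site.
#' @param window_size Window size for the ZIP background model (bp).
#' @param span_merge_gap Same-strand target hits within this many bp on a
#'   read are merged into one span.
#' @param unique_mode Flank uniqueness rule, `"strict"` or `"ratio"`.
#' @param align Alignment engine parameters ([align_params()]).  The
#'   pipeline default raises the seed word length to 28, the word size the
#'   standard BLASTN binary uses for its default (megablast) task: at
#'   genome scale, shorter words let chance 13-15 bp exact matches pass
#'   the permissive E-value cutoff during the target screen and fabricate
#'   insertion evidence, while a 28 bp exact seed is still found hundreds
#'   of times across a multi-kilobase element even at ten percent read
#'   error.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(evalue_max = 1e-3, min_flank_len = 200,
                            min_len = 200, min_identity = 80,
                            merge_dist = 50, neighbor_window = 2000,
                            min_reads = 1, window_size = 1000,
                            span_merge_gap = 100,
                            unique_mode = c("strict", "ratio"),
                            align = align_params(seed_k = 28)) {
  unique_mode <- match.arg(unique_mode)
  structure(list(evalue_max = evalue_max, min_flank_len = min_flank_len,
                 min_len = min_len, min_identity = min_identity,
                 merge_dist = merge_dist, neighbor_window = neighbor_window,
                 min_reads = min_reads, window_size = window_size,
                 span_merge_gap = span_merge_gap, unique_mode = unique_mode,
                 align = align),
            class = "pipeline_config")
}

#' Run the insertion-site pipeline on in-memory data
#'
#' Executes the five stages in order: (i) screen the target against the
#' reads, (ii) extract oriented flanking sequences, (iii) map flanks to
#' the reference genome with the length/identity/uniqueness filters,
#' (iv) cluster breakpoints into supported sites and annotate neighbor
#' genes, (v) fit the zero-inflated Poisson background to windowed counts
#' and attach per-site upper-tail P-values.  Per-stage counts are logged
#' with [message()].
#'
#' @param reads,target,genome Sequence tables ([read_seqs()]).
#' @param genes Gene table ([read_gff()]); may have zero rows.
#' @param config A [pipeline_config()].
#' @param blast_hits Optional list with elements `target` and/or `flank`:
#'   precomputed hit tables (e.g. [parse_blast_tab()]) replacing the
#'   built-in aligner at the corresponding stage.
#' @return List: `sites` (annotated, scored insertion-site table),
#'   `tagged`, `flanks`, `mapped`, `zip` (the `zip_fit` or `NULL`), and
#'   `summary` (stage counts and read-set statistics).
#' @export
run_insertion_pipeline <- function(reads, target, genome, genes,
                                   config = pipeline_config(),
                                   blast_hits = NULL) {
  stats_raw <- compute_read_stats(reads)
  message(sprintf("reads in: %d (mean %.0f bp, N50 %d bp)",
                  stats_raw$n_reads, stats_raw$mean_length, stats_raw$n50))

  if (is.null(blast_hits$target)) {
    tagged <- find_tagged_reads(reads, target,
                                evalue_max = config$evalue_max,
                                params = config$align,
                                merge_gap = config$span_merge_gap)
  } else {
    tagged <- spans_from_hits(blast_hits$target, config$span_merge_gap)
  }
  tagged_ids <- unique(tagged$read_id)
  stats_tagged <- compute_read_stats(reads[reads$id %in% tagged_ids, ])
  message(sprintf("tag-inserted reads: %d (mean %.0f bp, N50 %d bp)",
                  stats_tagged$n_reads, stats_tagged$mean_length,
                  stats_tagged$n50))

  flanks <- extract_flanks(tagged, reads,
                           min_flank_len = config$min_flank_len)
  stats_flank <- compute_read_stats(nchar(flanks$sequence))
  message(sprintf("flanking sequences: %d (mean %.0f bp, N50 %d bp)",
                  stats_flank$n_reads, stats_flank$mean_length,
                  stats_flank$n50))

  mapped <- map_flanks(flanks, genome, params = config$align,
                       min_len = config$min_len,
                       min_identity = config$min_identity,
                       evalue_max = config$evalue_max,
                       unique_mode = config$unique_mode,
                       hits = blast_hits$flank)
  message(sprintf("uniquely mapped flanks: %d", nrow(mapped)))

  sites <- cluster_breakpoints(mapped, merge_dist = config$merge_dist) %>%
    annotate_genes(genes, window = config$neighbor_window) %>%
    filter_sites(min_reads = config$min_reads)

  zip <- NULL
  if (nrow(sites) > 0) {
    counts <- windowed_counts(sites, genome,
                              window_size = config$window_size)
    zip <- fit_zip(counts)
    sites <- add_site_pvalues(sites, zip)
  } else {
    sites$p_value <- double(0)
  }
  message(sprintf("insertion sites: %d", nrow(sites)))

  list(
    sites = sites, tagged = tagged, flanks = flanks, mapped = mapped,
    zip = zip,
    summary = list(
      raw_reads = as.list(stats_raw),
      tagged_reads = as.list(stats_tagged),
      flanking_sequences = as.list(stats_flank),
      mapped_flanks = nrow(mapped),
      insertion_sites = nrow(sites),
      zip = if (is.null(zip)) NULL else
        list(pi = zip$pi, lambda = zip$lambda, n_obs = zip$n_obs,
             loglik = zip$loglik)
    )
  )
}

spans_from_hits <- function(hits, merge_gap) {
  # reuse the span-merging path of find_tagged_reads for external hits
  spans <- hits %>%
    mutate(read_id = .data$subject_id) %>%
    select("read_id", "s_start", "s_end", "strand", "identity_pct",
           "aligned_len") %>%
    arrange(.data$read_id, .data$strand, .data$s_start) %>%
    group_by(.data$read_id, .data$strand) %>%
    mutate(new_grp = cumsum(
      dplyr::lag(cummax(as.numeric(.data$s_end)), default = -Inf) + merge_gap < .data$s_start
    )) %>%
    group_by(.data$read_id, .data$strand, .data$new_grp) %>%
    summarise(span_start = min(.data$s_start), span_end = max(.data$s_end),
              identity_pct = sum(.data$identity_pct * .data$aligned_len) /
                sum(.data$aligned_len),
              .groups = "drop") %>%
    select("read_id", "span_start", "span_end", "strand", "identity_pct") %>%
    arrange(.data$read_id, .data$span_start)
  spans
}

#' Run the pipeline from files to files
#'
#' Reads the four inputs (target element FASTA, long reads FASTA/FASTQ,
#' reference genome FASTA, gene annotation GFF3), runs
#' [run_insertion_pipeline()], and writes the two output files - the
#' insertion-site summary table and the supporting flank FASTA - plus a
#' JSON run summary with the stage statistics.
#'
#' @param target,reads,genome,gff Paths of the four required inputs.
#' @param out_dir Output directory (created if missing).
#' @param config A [pipeline_config()].
#' @param blast_target,blast_flank Optional BLAST tabular files replacing
#'   the built-in aligner at the target-screen / flank-map stage.
#' @return The [run_insertion_pipeline()] result list, with `paths` added,
#'   invisibly.
#' @export
cmd_run <- function(target, reads, genome, gff, out_dir,
                    config = pipeline_config(),
                    blast_target = NULL, blast_flank = NULL) {
  inputs <- c(target = target, reads = reads, genome = genome, gff = gff)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing) > 0)
    abort(paste0("missing input file(s): ",
                 paste(names(missing), "=", missing, collapse = ", "),
                 "\nfour inputs are required: target FASTA, reads ",
                 "FASTA/FASTQ, genome FASTA, annotation GFF3"))
  target_tbl <- read_seqs(target)
  reads_tbl <- read_seqs(reads)
  genome_tbl <- read_seqs(genome, format = "fasta")
  genes_tbl <- read_gff(gff)
  bad_chroms <- setdiff(unique(genes_tbl$chrom), genome_tbl$id)
  if (length(bad_chroms) > 0)
    abort(paste0("annotation chromosomes absent from the genome: ",
                 paste(bad_chroms, collapse = ", ")))
  bh <- list(
    target = if (is.null(blast_target)) NULL else parse_blast_tab(blast_target),
    flank = if (is.null(blast_flank)) NULL else parse_blast_tab(blast_flank)
  )
  res <- run_insertion_pipeline(reads_tbl, target_tbl, genome_tbl,
                                genes_tbl, config = config,
                                blast_hits = bh)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    sites = file.path(out_dir, "insertion_sites.tsv"),
    flanks = file.path(out_dir, "insertion_flanks.fa"),
    summary = file.path(out_dir, "run_summary.json")
  )
  write_site_table(res$sites, paths$sites)
  write_flank_fasta(res$sites, res$flanks, paths$flanks)
  jsonlite::write_json(res$summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  res$paths <- paths
  invisible(res)
}

#' Generate a synthetic fixture directory
#'
#' Wraps [sim_insertion_experiment()]: writes the four pipeline inputs plus
#' the truth TSV.
#'
#' @param cfg A [sim_config()], or a path to a YAML file whose fields are
#'   [sim_config()] arguments.
#' @param out_dir Output directory.
#' @return The experiment list, invisibly.
#' @export
cmd_simulate <- function(cfg, out_dir) {
  if (is.character(cfg)) {
    vals <- yaml::read_yaml(cfg)
    bad <- setdiff(names(vals), names(formals(sim_config)))
    if (length(bad) > 0)
      abort(paste0("unknown simulation config field(s): ",
                   paste(bad, collapse = ", ")))
    cfg <- do.call(sim_config, vals)
  }
  stopifnot(inherits(cfg, "sim_config"))
  invisible(sim_insertion_experiment(cfg, out_dir = out_dir))
}

#' Decode per-barcode site tables against a pooling design
#'
#' @param design_path Design TSV (`sample`, `barcode1`, `barcode2`).
#' @param call_paths Character vector of per-barcode site-table paths
#'   ([write_site_table()] format); names are barcode ids, unnamed paths
#'   use the file name without extension.
#' @param out_path Output TSV (`sample`, `chrom`, `position`, `status`).
#' @param match_dist Position unification distance, bp.
#' @return The decoded tibble, invisibly.
#' @export
cmd_decode <- function(design_path, call_paths, out_path,
                       match_dist = 50) {
  design <- read_design(design_path)
  bc <- names(call_paths)
  if (is.null(bc)) bc <- rep(NA_character_, length(call_paths))
  bc[is.na(bc) | !nzchar(bc)] <-
    tools::file_path_sans_ext(basename(call_paths[is.na(bc) | !nzchar(bc)]))
  calls <- bind_rows(lapply(seq_along(call_paths), function(i) {
    st <- read_site_table(call_paths[i])
    tibble(barcode = bc[i], chrom = st$chrom, position = st$position)
  }))
  decoded <- decode(calls, design, match_dist = match_dist)
  readr::write_tsv(decoded[, c("sample", "chrom", "position", "status")],
                   out_path, progress = FALSE)
  invisible(decoded)
}
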