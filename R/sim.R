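#' Configuration for the synthetic insertion experiment
#'
#' Defaults emulate a Nanopore whole-genome resequencing run of a mutant
#' line: mean read length 7307 bp at 44-fold depth, a 5334 bp target
#' element, and per-base error rates around 10 percent split across
#' substitutions, insertions and deletions.  Planted insertions are spaced
#' at least two mean read lengths apart and kept one mean read length from
#' chromosome ends, so that individual reads can span a junction cleanly.
#'
#' @param genome_len Total reference length in bp.
#' @param n_chroms Number of chromosomes (equal lengths).
#' @param gc GC fraction of the simulated genome.
#' @param n_insertions Number of planted insertions.
#' @param target_seq Optional target element sequence (string); a random
#'   sequence of `target_len` bp is generated when `NULL`.
#' @param target_len Length of the generated target element in bp.
#' @param tsd_len Target-site duplication length in bp (default 0: clean
#'   junctions on both sides).
#' @param depth Fold coverage of the simulated read set.
#' @param read_len_mean,read_len_sd Log-normal read length model, in bp.
#' @param err_sub,err_ins,err_del Per-base substitution / insertion /
#'   deletion rates (each at most 0.2).
#' @param genic_fraction Fraction of the genome covered by gene models.
#' @param seed RNG seed; every generator is deterministic given it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(genome_len = 5e5, n_chroms = 1, gc = 0.42,
                       n_insertions = 10, target_seq = NULL,
                       target_len = 5334, tsd_len = 0, depth = 44,
                       read_len_mean = 7307, read_len_sd = 5000,
                       err_sub = 0.04, err_ins = 0.03, err_del = 0.03,
                       genic_fraction = 0.3, seed = 1) {
  rates <- c(err_sub = err_sub, err_ins = err_ins, err_del = err_del)
  if (any(rates < 0 | rates > 0.2))
    abort("error rates must lie in [0, 0.2]")
  if (depth <= 0) abort("depth must be > 0")
  if (gc <= 0 || gc >= 1) abort("gc must lie in (0, 1)")
  if (tsd_len < 0) abort("tsd_len must be >= 0")
  if (!is.null(target_seq)) target_seq <- toupper(target_seq)
  structure(list(genome_len = genome_len, n_chroms = n_chroms, gc = gc,
                 n_insertions = n_insertions, target_seq = target_seq,
                 target_len = target_len, tsd_len = tsd_len, depth = depth,
                 read_len_mean = read_len_mean, read_len_sd = read_len_sd,
                 err_sub = err_sub, err_ins = err_ins, err_del = err_del,
                 genic_fraction = genic_fraction, seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a random reference genome with gene models
#'
#' i.i.d. bases at the configured GC content; non-overlapping gene
#' intervals laid down left to right with exponentially distributed
#' intergenic gaps tuned so that genes cover about `genic_fraction` of the
#' genome.  Deterministic given the config seed.
#'
#' @param cfg A [sim_config()].
#' @return List with `genome` (sequence table) and `genes` (gene table as
#'   from [read_gff()]).
#' @export
make_genome <- function(cfg) {
  set.seed(cfg$seed)
  chrom_len <- rep(floor(cfg$genome_len / cfg$n_chroms), cfg$n_chroms)
  chrom_len[cfg$n_chroms] <- cfg$genome_len - sum(chrom_len[-cfg$n_chroms])
  ids <- sprintf("chr%d", seq_len(cfg$n_chroms))
  seqs <- vapply(chrom_len, function(l) random_dna_cpp(as.integer(l), cfg$gc),
                 character(1))
  gene_mean <- 2500
  gap_mean <- gene_mean * (1 - cfg$genic_fraction) / cfg$genic_fraction
  genes <- list()
  gi <- 0L
  for (ci in seq_len(cfg$n_chroms)) {
    pos <- 1
    repeat {
      pos <- pos + round(rexp(1, 1 / gap_mean))
      glen <- round(runif(1, gene_mean * 0.4, gene_mean * 1.6))
      if (pos + glen - 1 > chrom_len[ci]) break
      gi <- gi + 1L
      genes[[gi]] <- tibble(gene_id = sprintf("g%04d", gi),
                            chrom = ids[ci],
                            start = as.integer(pos),
                            end = as.integer(pos + glen - 1),
                            strand = sample(c("+", "-"), 1))
      pos <- pos + glen
    }
  }
  list(genome = tibble(id = ids, seq = seqs, qual = NA_character_),
       genes = if (gi > 0) bind_rows(genes) else
         tibble(gene_id = character(), chrom = character(),
                start = integer(), end = integer(), strand = character()))
}

#' Plant target-element insertions into a reference genome
#'
#' Insertion breakpoints are drawn uniformly subject to the spacing
#' constraints (at least `2 * read_len_mean` between insertions, at least
#' `read_len_mean` from chromosome ends), each insertion gets a random
#' orientation, and the element (or its reverse complement) is spliced in.
#' With `tsd_len > 0` the `tsd_len` reference bases immediately left of
#' the breakpoint are duplicated after the element, mimicking a
#' target-site duplication.
#'
#' @param reference Sequence table of the reference genome.
#' @param cfg A [sim_config()]; `cfg$target_seq` must be set (see
#'   [sim_insertion_experiment()] for the usual entry point).
#' @return List with `mutant` (sequence table) and `truth` (tibble
#'   `chrom`, `position` - the 0-based pre-insertion reference coordinate -
#'   `orientation`, `tsd_len`).
#' @export
plant_insertions <- function(reference, cfg) {
  if (is.null(cfg$target_seq)) abort("cfg$target_seq is not set")
  set.seed(cfg$seed + 1L)
  target <- cfg$target_seq
  rc_target <- revcomp_cpp(target)
  margin <- cfg$read_len_mean
  min_space <- 2 * cfg$read_len_mean
  chrom_len <- nchar(reference$seq)
  # allocate insertions to chromosomes proportionally to length
  alloc <- floor(cfg$n_insertions * chrom_len / sum(chrom_len))
  rem <- cfg$n_insertions - sum(alloc)
  if (rem > 0) alloc[order(chrom_len, decreasing = TRUE)[seq_len(rem)]] <-
      alloc[order(chrom_len, decreasing = TRUE)[seq_len(rem)]] + 1
  truth <- list()
  mutant_seq <- character(nrow(reference))
  for (ci in seq_len(nrow(reference))) {
    n_ins <- alloc[ci]
    len <- chrom_len[ci]
    if (n_ins == 0) { mutant_seq[ci] <- reference$seq[ci]; next }
    span <- (len - 2 * margin) - (n_ins - 1) * min_space
    if (span < 0)
      abort(paste0("cannot place ", n_ins, " insertions on ",
                   reference$id[ci], " (", len, " bp) with spacing ",
                   min_space, " bp and end margin ", margin, " bp"))
    u <- sort(runif(n_ins, 0, span))
    pos <- round(margin + u + (seq_len(n_ins) - 1) * min_space)
    orient <- sample(c("+", "-"), n_ins, replace = TRUE)
    ref <- reference$seq[ci]
    pieces <- character(2 * n_ins + 1)
    prev <- 0
    for (j in seq_len(n_ins)) {
      p <- pos[j]
      pieces[2 * j - 1] <- substr(ref, prev + 1, p)
      ins <- if (orient[j] == "+") target else rc_target
      if (cfg$tsd_len > 0)
        ins <- paste0(ins, substr(ref, p - cfg$tsd_len + 1, p))
      pieces[2 * j] <- ins
      prev <- p
    }
    pieces[2 * n_ins + 1] <- substr(ref, prev + 1, len)
    mutant_seq[ci] <- paste(pieces, collapse = "")
    truth[[ci]] <- tibble(chrom = reference$id[ci],
                          position = as.integer(pos),
                          orientation = orient,
                          tsd_len = as.integer(cfg$tsd_len))
  }
  truth <- bind_rows(truth)
  stopifnot(sum(nchar(mutant_seq)) ==
              sum(chrom_len) + nrow(truth) * (nchar(target) + cfg$tsd_len))
  list(mutant = tibble(id = reference$id, seq = mutant_seq,
                       qual = NA_character_),
       truth = truth)
}

#' Simulate noisy long reads from a (mutant) genome
#'
#' Read lengths are log-normal (parameterized by mean and sd in bp,
#' truncated to `[500, chrom_len]`), start positions uniform along each
#' chromosome, strands uniform, and per-base substitution / insertion /
#' deletion errors applied independently.  Reads are drawn until the total
#' sequenced bases reach `depth` times the genome length.  Read ids encode
#' the true origin (`rd000001;chrom;start;strand`) for debugging.
#'
#' @param mutant Sequence table to sequence from.
#' @param cfg A [sim_config()].
#' @return A read sequence table (`id`, `seq`, `qual`), FASTQ-ready.
#' @export
simulate_reads <- function(mutant, cfg) {
  set.seed(cfg$seed + 2L)
  mu <- cfg$read_len_mean; sd <- cfg$read_len_sd
  meanlog <- log(mu^2 / sqrt(mu^2 + sd^2))
  sdlog <- sqrt(log(1 + sd^2 / mu^2))
  reads <- list()
  counter <- 0L
  for (ci in seq_len(nrow(mutant))) {
    clen <- nchar(mutant$seq[ci])
    target_bases <- cfg$depth * clen
    n_est <- ceiling(target_bases / mu * 1.5) + 10
    lens <- pmin(pmax(round(rlnorm(n_est, meanlog, sdlog)), 500), clen)
    n_use <- which(cumsum(lens) >= target_bases)[1]
    if (is.na(n_use)) n_use <- n_est
    lens <- lens[seq_len(n_use)]
    starts <- floor(runif(n_use, 1, clen - lens + 1 + 1))
    strands <- sample(c("+", "-"), n_use, replace = TRUE)
    raw <- substring(mutant$seq[ci], starts, starts + lens - 1)
    raw[strands == "-"] <- revcomp_cpp(raw[strands == "-"])
    if (cfg$err_sub + cfg$err_ins + cfg$err_del > 0)
      raw <- as.character(mutate_seqs_cpp(raw, cfg$err_sub, cfg$err_ins,
                                          cfg$err_del))
    ids <- sprintf("rd%06d;%s;%d;%s", counter + seq_len(n_use),
                   mutant$id[ci], starts, strands)
    counter <- counter + n_use
    reads[[ci]] <- tibble(id = ids, seq = raw,
                          qual = strrep("I", nchar(raw)))
  }
  bind_rows(reads)
}

#' Run the full synthetic experiment
#'
#' Generates the reference genome with gene annotation, the target
#' element, the mutant genome with planted insertions, and the noisy read
#' set - everything the pipeline needs plus the machine-readable truth
#' table.  Optionally writes the five files (target FASTA, reads FASTQ,
#' reference FASTA, genes GFF3, truth TSV) to a directory.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Optional output directory (created if missing).
#' @return List with `genome`, `genes`, `target` (sequence table),
#'   `mutant`, `truth`, `reads`, and `paths` (when written).
#' @export
sim_insertion_experiment <- function(cfg, out_dir = NULL) {
  g <- make_genome(cfg)
  if (is.null(cfg$target_seq)) {
    set.seed(cfg$seed + 3L)
    cfg$target_seq <- random_dna_cpp(as.integer(cfg$target_len), cfg$gc)
  }
  planted <- plant_insertions(g$genome, cfg)
  reads <- simulate_reads(planted$mutant, cfg)
  target_tbl <- tibble(id = "target_element", seq = cfg$target_seq,
                       qual = NA_character_)
  res <- list(genome = g$genome, genes = g$genes, target = target_tbl,
              mutant = planted$mutant, truth = planted$truth, reads = reads)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      target = file.path(out_dir, "target.fa"),
      reads = file.path(out_dir, "reads.fq"),
      genome = file.path(out_dir, "genome.fa"),
      gff = file.path(out_dir, "genes.gff3"),
      truth = file.path(out_dir, "truth.tsv")
    )
    write_seqs(target_tbl, paths$target, "fasta")
    write_seqs(reads, paths$reads, "fastq")
    write_seqs(res$genome, paths$genome, "fasta")
    write_gff(res$genes, paths$gff)
    readr::write_tsv(res$truth, paths$truth, progress = FALSE)
    res$paths <- paths
  }
  res
}

#' Compare called insertion sites with the planted truth
#'
#' Greedy nearest-first one-to-one matching of calls to truth records
#' within `tol` bp on the same chromosome; each truth record matches at
#' most one call.  Site positions are 1-based table coordinates; truth
#' positions are 0-based pre-insertion reference coordinates, and the
#' one-off difference is handled internally.
#'
#' @param sites Insertion-site table ([cluster_breakpoints()]).
#' @param truth Truth table from [plant_insertions()].
#' @param tol Maximum positional error for a match, in bp (default 20).
#' @return One-row tibble: `recall`, `precision`,
#'   `median_abs_positional_error` (over matched pairs, `NA` when none),
#'   `n_truth`, `n_calls`, `n_matched`.
#' @export
evaluate_calls <- function(sites, truth, tol = 20) {
  n_truth <- nrow(truth)
  n_calls <- nrow(sites)
  if (n_truth == 0 || n_calls == 0)
    return(tibble(recall = ifelse(n_truth == 0, NA_real_, 0),
                  precision = ifelse(n_calls == 0, NA_real_, 0),
                  median_abs_positional_error = NA_real_,
                  n_truth = n_truth, n_calls = n_calls, n_matched = 0L))
  call_pos <- sites$position - 1L  # back to 0-based junction coordinates
  pairs <- list()
  k <- 0L
  for (i in seq_len(n_truth)) {
    same <- which(sites$chrom == truth$chrom[i])
    if (length(same) == 0) next
    d <- abs(call_pos[same] - truth$position[i])
    ok <- d <= tol
    if (any(ok)) {
      k <- k + 1L
      pairs[[k]] <- tibble(truth_idx = i, call_idx = same[ok], dist = d[ok])
    }
  }
  if (k == 0)
    return(tibble(recall = 0, precision = 0,
                  median_abs_positional_error = NA_real_,
                  n_truth = n_truth, n_calls = n_calls, n_matched = 0L))
  pairs <- bind_rows(pairs) %>%
    arrange(.data$dist, .data$truth_idx, .data$call_idx)
  used_t <- logical(n_truth); used_c <- logical(n_calls)
  matched <- numeric(0)
  for (r in seq_len(nrow(pairs))) {
    ti <- pairs$truth_idx[r]; ci <- pairs$call_idx[r]
    if (!used_t[ti] && !used_c[ci]) {
      used_t[ti] <- TRUE; used_c[ci] <- TRUE
      matched <- c(matched, pairs$dist[r])
    }
  }
  tibble(recall = sum(used_t) / n_truth,
         precision = sum(used_c) / n_calls,
         median_abs_positional_error = median(matched),
         n_truth = n_truth, n_calls = n_calls,
         n_matched = length(matched))
}
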