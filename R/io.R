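#' Read sequences from FASTA or FASTQ
#'
#' Loads long reads or reference sequences into a tidy sequence table.
#' The format is auto-detected from the first non-blank character of the
#' file (`>` for FASTA, `@` for FASTQ) unless given explicitly.  Plain
#' gzip-compressed files are accepted.
#'
#' @param path Path to a FASTA or FASTQ file.
#' @param format One of `"auto"`, `"fasta"`, `"fastq"`.
#' @return A tibble with columns `id` (first whitespace-delimited token of
#'   the record header, unique within the file), `seq` (uppercase DNA) and
#'   `qual` (Phred+33 quality string, `NA` for FASTA input).
#' @details Qualities are carried along but not used by the insertion-site
#'   pipeline itself; no quality filtering is applied.
#' @export
read_seqs <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (file.size(path) == 0) return(empty_seq_tbl())
  if (format == "auto") {
    con <- gzfile(path, "rt")
    on.exit(close(con), add = TRUE)
    first <- ""
    while (!nzchar(trimws(first))) {
      first <- readLines(con, n = 1L)
      if (length(first) == 0) return(empty_seq_tbl())
    }
    ch <- substr(trimws(first), 1, 1)
    format <- switch(ch, ">" = "fasta", "@" = "fastq",
                     abort(paste0("cannot detect sequence format of ", path,
                                  ": first character is '", ch, "'")))
  }
  out <- if (format == "fasta") read_fasta_file(path) else read_fastq_file(path)
  dup <- out$id[duplicated(out$id)]
  if (length(dup) > 0)
    abort(paste0("duplicate sequence ids in ", path, ": ",
                 paste(unique(dup), collapse = ", ")))
  if (any(nchar(out$seq) == 0))
    abort(paste0("zero-length sequence record in ", path))
  out
}

empty_seq_tbl <- function() {
  tibble(id = character(), seq = character(), qual = character())
}

read_fasta_file <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fasta")
  tibble(
    id   = unname(vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1)),
    seq  = unname(toupper(as.character(ss))),
    qual = NA_character_
  )
}

read_fastq_file <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con), add = TRUE)
  lines <- readLines(con)
  lines <- lines[seq_len(max(which(nzchar(lines)), 0))]
  if (length(lines) == 0) return(empty_seq_tbl())
  if (length(lines) %% 4 != 0)
    abort(paste0("FASTQ parse error in ", path, ": line ", length(lines) + 1,
                 " (truncated record, ", length(lines), " lines total)"))
  n <- length(lines) / 4
  hdr <- lines[seq(1, by = 4, length.out = n)]
  seq <- lines[seq(2, by = 4, length.out = n)]
  plus <- lines[seq(3, by = 4, length.out = n)]
  qual <- lines[seq(4, by = 4, length.out = n)]
  bad_hdr <- which(substr(hdr, 1, 1) != "@")
  if (length(bad_hdr) > 0)
    abort(paste0("FASTQ parse error in ", path, ": line ",
                 (bad_hdr[1] - 1) * 4 + 1, " (header must start with '@')"))
  bad_plus <- which(substr(plus, 1, 1) != "+")
  if (length(bad_plus) > 0)
    abort(paste0("FASTQ parse error in ", path, ": line ",
                 (bad_plus[1] - 1) * 4 + 3, " (separator must start with '+')"))
  mism <- which(nchar(seq) != nchar(qual))
  if (length(mism) > 0)
    abort(paste0("FASTQ parse error in ", path, ": line ",
                 (mism[1] - 1) * 4 + 4,
                 " (quality length differs from sequence length)"))
  tibble(
    id   = unname(vapply(strsplit(sub("^@", "", hdr), "\\s+"),
                         `[`, character(1), 1)),
    seq  = toupper(seq),
    qual = qual
  )
}

#' Write sequences to FASTA or FASTQ
#'
#' @param seqs Sequence table as returned by [read_seqs()] (columns `id`,
#'   `seq`, optionally `qual`).
#' @param path Output path.
#' @param format `"fasta"` or `"fastq"`.  FASTQ requires a `qual` column;
#'   missing qualities are filled with Phred 40 (`"I"`).
#' @return `path`, invisibly.
#' @export
write_seqs <- function(seqs, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "fasta") {
    writeLines(as.vector(rbind(paste0(">", seqs$id), seqs$seq)), path)
  } else {
    qual <- if ("qual" %in% names(seqs)) seqs$qual else rep(NA_character_, nrow(seqs))
    qual <- ifelse(is.na(qual), strrep("I", nchar(seqs$seq)), qual)
    writeLines(as.vector(rbind(paste0("@", seqs$id), seqs$seq, "+", qual)), path)
  }
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Only features of type `gene` (case-insensitive) are consumed; mRNA, exon
#' and other feature lines are ignored.  The gene identifier is taken from
#' the `ID=` attribute; records without one get a synthesized
#' `chrom:start-end` identifier with a warning.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive, as in GFF) and `strand` (`+`/`-`).
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) abort(paste0("GFF parse error in ", path, ": ",
                                     conditionMessage(e)))
  )
  gr <- gr[tolower(as.character(gr$type)) == "gene"]
  if (length(gr) == 0)
    return(tibble(gene_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character()))
  ids <- if ("ID" %in% names(S4Vectors::mcols(gr))) as.character(gr$ID) else
    rep(NA_character_, length(gr))
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start <- GenomicRanges::start(gr)
  end <- GenomicRanges::end(gr)
  missing_id <- is.na(ids) | !nzchar(ids)
  if (any(missing_id)) {
    ids[missing_id] <- paste0(chrom[missing_id], ":", start[missing_id],
                              "-", end[missing_id])
    warn(paste0(sum(missing_id), " gene record(s) in ", path,
                " lack an ID attribute; synthesized chrom:start-end ids"))
  }
  strand <- as.character(GenomicRanges::strand(gr))
  strand[!strand %in% c("+", "-")] <- "+"
  tibble(gene_id = ids, chrom = chrom,
         start = as.integer(start), end = as.integer(end), strand = strand)
}

#' Write gene models to a GFF3 file
#'
#' @param genes Gene table as returned by [read_gff()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand
  )
  gr$type <- "gene"
  gr$source <- "insertscout"
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Summary statistics of a read set
#'
#' Computes the read count, arithmetic mean length and N50 of a sequence
#' table.  N50 is the length `L` such that reads of length `>= L` together
#' contain at least half of all sequenced bases (computed by sorting lengths
#' in decreasing order and taking the first length at which the cumulative
#' sum reaches half the total).
#'
#' @param seqs Sequence table ([read_seqs()]) or a numeric vector of read
#'   lengths.
#' @return One-row tibble with `n_reads`, `total_bases`, `mean_length`,
#'   `n50`.  An empty input yields zeros.
#' @export
compute_read_stats <- function(seqs) {
  lens <- if (is.numeric(seqs)) as.numeric(seqs) else nchar(seqs$seq)
  if (length(lens) == 0)
    return(tibble(n_reads = 0L, total_bases = 0, mean_length = 0, n50 = 0L))
  lens_sorted <- sort(lens, decreasing = TRUE)
  total <- sum(lens_sorted)
  n50 <- lens_sorted[which(cumsum(lens_sorted) >= total / 2)[1]]
  tibble(n_reads = length(lens), total_bases = total,
         mean_length = mean(lens), n50 = as.integer(n50))
}

site_table_cols <- c("chrom", "position", "extent_start", "extent_end",
                     "read_count", "sides", "neighbor_genes", "p_value")

#' Write the insertion-site summary table
#'
#' The first of the two pipeline output files: one row per insertion site
#' with its genomic coordinate, the extent spanned by clustered breakpoints,
#' the number of supporting reads, which element sides (5'/3') are covered,
#' neighbor genes within the annotation window, and the upper-tail P-value
#' under the fitted zero-inflated Poisson background.
#'
#' @param sites Insertion-site table ([cluster_breakpoints()], optionally
#'   annotated and scored).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @details P-values are rendered with six significant digits so that a
#'   write/read/write cycle is byte-identical and preserves site ordering.
#' @export
write_site_table <- function(sites, path) {
  con <- tryCatch(file(path, "wt"),
                  error = function(e) abort(paste0("cannot write ", path, ": ",
                                                   conditionMessage(e))))
  on.exit(close(con), add = TRUE)
  writeLines(paste(site_table_cols, collapse = "\t"), con)
  if (nrow(sites) > 0) {
    ng <- if ("neighbor_genes_str" %in% names(sites)) sites$neighbor_genes_str
          else rep(".", nrow(sites))
    ng[is.na(ng) | !nzchar(ng)] <- "."
    pv <- if ("p_value" %in% names(sites)) sites$p_value else rep(NA_real_, nrow(sites))
    pv_chr <- ifelse(is.na(pv), "NA", sprintf("%.6g", pv))
    writeLines(paste(sites$chrom, sites$position, sites$extent_start,
                     sites$extent_end, sites$read_count, sites$sides,
                     ng, pv_chr, sep = "\t"), con)
  }
  invisible(path)
}

#' Read an insertion-site summary table
#'
#' Inverse of [write_site_table()].
#'
#' @param path TSV path written by [write_site_table()].
#' @return Tibble with the site-table columns; `neighbor_genes` keeps the
#'   comma-joined gene id string (`"."` for none) as `neighbor_genes_str`.
#' @export
read_site_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    chrom = readr::col_character(),
    position = readr::col_integer(),
    extent_start = readr::col_integer(),
    extent_end = readr::col_integer(),
    read_count = readr::col_integer(),
    sides = readr::col_character(),
    neighbor_genes = readr::col_character(),
    p_value = readr::col_double()
  ), progress = FALSE)
  df %>%
    rename(neighbor_genes_str = "neighbor_genes") %>%
    as_tibble()
}

#' Write supporting flank sequences of each site as FASTA
#'
#' The second pipeline output file: the raw read-derived 5' and 3' flanking
#' sequences supporting each insertion site, usable for primer design.
#' Headers encode `chrom|position|side|read_id`.
#'
#' @param sites Insertion-site table with a `members` list-column
#'   ([cluster_breakpoints()]).
#' @param flanks Flank table ([extract_flanks()]) holding the sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_flank_fasta <- function(sites, flanks, path) {
  recs <- flank_fasta_records(sites, flanks)
  write_flank_records(recs, path)
}

flank_fasta_records <- function(sites, flanks) {
  if (nrow(sites) == 0)
    return(tibble(chrom = character(), position = integer(),
                  side = character(), read_id = character(),
                  seq = character()))
  members <- dplyr::bind_rows(lapply(seq_len(nrow(sites)), function(i) {
    m <- sites$members[[i]]
    m$chrom_site <- sites$chrom[i]
    m$position_site <- sites$position[i]
    m
  }))
  members %>%
    left_join(flanks %>% select("flank_id", "sequence"), by = "flank_id") %>%
    mutate(chrom = .data$chrom_site, position = .data$position_site,
           side = .data$element_side, seq = .data$sequence) %>%
    select("chrom", "position", "side", "read_id", "seq")
}

#' @rdname write_flank_fasta
#' @param records Flank record table as returned by [read_flank_fasta()].
#' @export
write_flank_records <- function(records, path) {
  hdr <- paste0(">", records$chrom, "|", records$position, "|",
                records$side, "|", records$read_id)
  writeLines(as.vector(rbind(hdr, records$seq)), path)
  invisible(path)
}

#' Read a flank FASTA file back into a record table
#'
#' Parses the `chrom|position|side|read_id` headers written by
#' [write_flank_fasta()].
#'
#' @param path Flank FASTA path.
#' @return Tibble with columns `chrom`, `position`, `side`, `read_id`, `seq`.
#' @export
read_flank_fasta <- function(path) {
  if (file.size(path) == 0)
    return(tibble(chrom = character(), position = integer(),
                  side = character(), read_id = character(), seq = character()))
  ss <- Biostrings::readDNAStringSet(path, format = "fasta")
  parts <- stringr::str_split_fixed(names(ss), stringr::fixed("|"), 4)
  tibble(
    chrom = parts[, 1],
    position = as.integer(parts[, 2]),
    side = parts[, 3],
    read_id = parts[, 4],
    seq = unname(as.character(ss))
  )
}
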