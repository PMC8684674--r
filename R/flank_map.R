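#' Map flanking sequences to the reference genome
#'
#' Aligns each flank against the genome, keeps hits passing the length and
#' identity filters (aligned length strictly greater than `min_len`,
#' identity at least `min_identity`), requires the flank to map uniquely,
#' and derives the genomic breakpoint - the coordinate where host sequence
#' meets the inserted element - from the flank's junction end and the
#' orientation of the genomic alignment.
#'
#' Uniqueness has two modes: `"strict"` (default) keeps a flank only when
#' exactly one distinct genomic locus passes the filters; `"ratio"` also
#' accepts the best locus when its bitscore is at least `ratio` times the
#' second best.
#'
#' @param flanks Flank table from [extract_flanks()].
#' @param genome Reference sequence table ([read_seqs()]).
#' @param params [align_params()].
#' @param min_len Minimum aligned length in bp, strict inequality
#'   (default 200).
#' @param min_identity Minimum percent identity, inclusive (default 80).
#' @param evalue_max E-value cutoff for genomic hits.
#' @param unique_mode `"strict"` or `"ratio"`, see Details.
#' @param ratio Bitscore ratio for `unique_mode = "ratio"`.
#' @param hits Optional precomputed hit table (e.g. from
#'   [parse_blast_tab()], with flank ids as `query_id`); skips the built-in
#'   alignment when supplied.
#' @return A tibble of uniquely placed flanks: `flank_id`, `read_id`,
#'   `chrom`, `s_start`, `s_end` (0-based half-open), `genome_strand`,
#'   `identity_pct`, `aligned_len`, `breakpoint` (0-based genomic
#'   coordinate of the junction), `element_side`, `junction_end`,
#'   `discordant_pair` (`TRUE` when the two flanks of one read map to
#'   different chromosomes).
#' @export
map_flanks <- function(flanks, genome, params = align_params(),
                       min_len = 200, min_identity = 80,
                       evalue_max = 1e-3,
                       unique_mode = c("strict", "ratio"), ratio = 1.2,
                       hits = NULL) {
  unique_mode <- match.arg(unique_mode)
  empty <- tibble(flank_id = character(), read_id = character(),
                  chrom = character(), s_start = integer(),
                  s_end = integer(), genome_strand = character(),
                  identity_pct = double(), aligned_len = integer(),
                  breakpoint = integer(), element_side = character(),
                  junction_end = character(), discordant_pair = logical())
  if (nrow(flanks) == 0) return(empty)
  if (is.null(hits))
    hits <- local_align(flanks, genome, params = params,
                        evalue_max = evalue_max)
  passing <- hits %>%
    filter(.data$aligned_len > min_len, .data$identity_pct >= min_identity)
  if (nrow(passing) == 0) {
    inform(paste0("0 of ", nrow(flanks),
                  " flanks passed the genomic alignment filters"))
    return(empty)
  }
  # collapse hits at one genomic locus (same chrom/strand, within 1 kb)
  # to their best-scoring representative before judging uniqueness: a
  # fragmented alignment of one placement is not multi-mapping evidence
  passing <- passing %>%
    group_by(.data$query_id, .data$subject_id, .data$strand) %>%
    arrange(.data$s_start, .by_group = TRUE) %>%
    mutate(locus = cumsum(
      dplyr::lag(cummax(as.numeric(.data$s_end)), default = -Inf) + 1000 <
        .data$s_start
    )) %>%
    group_by(.data$query_id, .data$subject_id, .data$strand, .data$locus) %>%
    arrange(desc(.data$bitscore), .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    select(-"locus")
  uniq <- passing %>%
    group_by(.data$query_id) %>%
    arrange(desc(.data$bitscore), .by_group = TRUE)
  if (unique_mode == "strict") {
    uniq <- uniq %>% filter(n() == 1) %>% ungroup()
  } else {
    uniq <- uniq %>%
      filter(n() == 1 |
               (row_number() == 1 & n() >= 2 &
                  first(.data$bitscore) >= ratio * dplyr::nth(.data$bitscore, 2))) %>%
      ungroup()
  }
  n_ambiguous <- dplyr::n_distinct(passing$query_id) -
    dplyr::n_distinct(uniq$query_id)
  n_unmapped <- nrow(flanks) - dplyr::n_distinct(passing$query_id)
  if (n_ambiguous > 0 || n_unmapped > 0)
    inform(paste0(n_unmapped, " flank(s) without a passing genomic hit, ",
                  n_ambiguous, " discarded as multi-mapping"))
  mapped <- uniq %>%
    rename(flank_id = "query_id", chrom = "subject_id",
           genome_strand = "strand") %>%
    left_join(flanks %>%
                select("flank_id", "read_id", "junction_end", "element_side"),
              by = "flank_id") %>%
    mutate(breakpoint = breakpoint_of(.data$junction_end,
                                      .data$genome_strand,
                                      .data$s_start, .data$s_end)) %>%
    select("flank_id", "read_id", "chrom", "s_start", "s_end",
           "genome_strand", "identity_pct", "aligned_len", "breakpoint",
           "element_side", "junction_end")
  mapped <- mapped %>%
    group_by(.data$read_id) %>%
    mutate(discordant_pair = n_distinct(.data$chrom) > 1) %>%
    ungroup() %>%
    arrange(.data$chrom, .data$breakpoint, .data$flank_id)
  if (any(mapped$discordant_pair))
    inform(paste0(sum(mapped$discordant_pair),
                  " flank(s) belong to reads whose flanks map to different ",
                  "chromosomes (flagged discordant_pair)"))
  mapped
}

#' Genomic breakpoint implied by a mapped flank
#'
#' The flank end that touched the target in the read (`junction_end`) is
#' carried through the genomic alignment orientation: a flank whose right
#' end is the junction, mapped to the forward strand, places the breakpoint
#' at the alignment end; mapped reversed, at the alignment start - and
#' mirror-image for left-junction flanks.
#'
#' @param junction_end `"left"` or `"right"` (vectorized).
#' @param genome_strand `"+"` or `"-"` (vectorized).
#' @param s_start,s_end 0-based half-open subject coordinates of the hit.
#' @return Integer vector of 0-based genomic breakpoint coordinates.
#' @export
breakpoint_of <- function(junction_end, genome_strand, s_start, s_end) {
  as.integer(dplyr::case_when(
    junction_end == "right" & genome_strand == "+" ~ s_end,
    junction_end == "right" & genome_strand == "-" ~ s_start,
    junction_end == "left" & genome_strand == "+" ~ s_start,
    junction_end == "left" & genome_strand == "-" ~ s_end
  ))
}
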