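#' Identify reads that carry the target element
#'
#' Screens the target (transposon/T-DNA) sequence against the read set with
#' the local aligner and reports, per read, the merged target spans on the
#' read.  Hits on the same strand whose read intervals lie within
#' `merge_gap` bp are merged into one span: sequencing indels fragment
#' alignments of one physical element copy, and merging prevents the
#' fragments from spawning spurious between-span flanks.
#'
#' @param reads Sequence table of long reads ([read_seqs()]).
#' @param target Target element sequence (single-record table or string).
#' @param evalue_max E-value cutoff for target hits (default 1e-3).
#' @param params [align_params()]; defaults here to a 28 bp seed word
#'   (the standard BLASTN default-task word size), since with shorter
#'   words chance exact matches of 13-15 bp already pass the permissive
#'   E-value cutoff and masquerade as target spans.
#' @param merge_gap Same-strand hits within this many bp on the read are
#'   merged into one span (default 100).
#' @return A tibble of target spans, one row per span: `read_id`,
#'   `span_start`, `span_end` (0-based half-open on the read), `strand`
#'   (orientation of the target in the read), `identity_pct` (alignment-
#'   length-weighted mean over merged hits).  Reads without a passing hit
#'   are absent; each read id appears once per span.
#' @export
find_tagged_reads <- function(reads, target, evalue_max = 1e-3,
                              params = align_params(seed_k = 28),
                              merge_gap = 100) {
  tgt <- as_seq_tbl(target, "target")
  if (nrow(tgt) != 1) abort("target must be a single sequence")
  if (!nzchar(tgt$seq)) abort("target sequence is empty")
  hits <- local_align(tgt, reads, params = params, evalue_max = evalue_max)
  if (nrow(hits) == 0)
    return(tibble(read_id = character(), span_start = integer(),
                  span_end = integer(), strand = character(),
                  identity_pct = double()))
  # spans live on the read (the alignment subject)
  spans <- hits %>%
    mutate(read_id = .data$subject_id) %>%
    select("read_id", "s_start", "s_end", "strand", "identity_pct",
           "aligned_len") %>%
    arrange(.data$read_id, .data$strand, .data$s_start)
  merged <- spans %>%
    group_by(.data$read_id, .data$strand) %>%
    mutate(new_grp = cumsum(
      dplyr::lag(cummax(as.numeric(.data$s_end)), default = -Inf) + merge_gap < .data$s_start
    )) %>%
    group_by(.data$read_id, .data$strand, .data$new_grp) %>%
    summarise(
      span_start = min(.data$s_start),
      span_end = max(.data$s_end),
      identity_pct = sum(.data$identity_pct * .data$aligned_len) /
        sum(.data$aligned_len),
      .groups = "drop"
    ) %>%
    select("read_id", "span_start", "span_end", "strand", "identity_pct") %>%
    arrange(.data$read_id, .data$span_start)
  n_chimeric <- merged %>%
    group_by(.data$read_id) %>%
    summarise(both = n_distinct(.data$strand) > 1, .groups = "drop") %>%
    pull(.data$both) %>% sum()
  if (n_chimeric > 0)
    inform(paste0(n_chimeric, " read(s) carry target spans on both strands ",
                  "(possible chimeras); spans processed independently"))
  merged
}

#' Extract flanking sequences from tagged reads
#'
#' For every target span on a read, the read segment to its left (back to
#' the previous span or the read start) and to its right (up to the next
#' span or the read end) become candidate flanks.  Segments shorter than
#' `min_flank_len` are dropped; a segment sandwiched between two spans is
#' attached to both neighboring spans when long enough, otherwise dropped.
#'
#' Junction bookkeeping: a flank lying left of its span touches the target
#' with its right end (`junction_end = "right"`), and vice versa.  Which
#' end of the element the flank abuts follows from flank position and span
#' strand: left-of-span with a `+` span (or right-of-span with `-`) abuts
#' the element's 5' end, the other two cases the 3' end.
#'
#' @param tagged Target-span table from [find_tagged_reads()].
#' @param reads The read sequence table the spans refer to.
#' @param min_flank_len Minimum flank length in bp (default 200, matching
#'   the downstream genomic alignment-length filter).
#' @return A tibble of flanks: `flank_id`, `read_id`, `sequence`,
#'   `read_start`, `read_end` (0-based half-open on the read),
#'   `junction_end` (`left`/`right`), `target_strand`, `element_side`
#'   (`5p`/`3p`).
#' @export
extract_flanks <- function(tagged, reads, min_flank_len = 200) {
  empty <- tibble(flank_id = character(), read_id = character(),
                  sequence = character(), read_start = integer(),
                  read_end = integer(), junction_end = character(),
                  target_strand = character(), element_side = character())
  if (nrow(tagged) == 0) return(empty)
  read_seq <- setNames(reads$seq, reads$id)
  missing <- setdiff(unique(tagged$read_id), names(read_seq))
  if (length(missing) > 0)
    abort(paste0("tagged spans reference reads absent from the read set: ",
                 paste(head(missing, 5), collapse = ", ")))
  out <- vector("list", length(unique(tagged$read_id)))
  i <- 0L
  for (rid in unique(tagged$read_id)) {
    sp <- tagged[tagged$read_id == rid, ]
    sp <- sp[order(sp$span_start), ]
    rlen <- nchar(read_seq[[rid]])
    n <- nrow(sp)
    segs <- list()
    for (j in seq_len(n)) {
      left_bound <- if (j == 1) 0L else sp$span_end[j - 1]
      right_bound <- if (j == n) rlen else sp$span_start[j + 1]
      lseg_len <- sp$span_start[j] - left_bound
      rseg_len <- right_bound - sp$span_end[j]
      if (lseg_len >= min_flank_len)
        segs[[length(segs) + 1]] <- list(
          start = left_bound, end = sp$span_start[j],
          junction_end = "right", strand = sp$strand[j])
      if (rseg_len >= min_flank_len)
        segs[[length(segs) + 1]] <- list(
          start = sp$span_end[j], end = right_bound,
          junction_end = "left", strand = sp$strand[j])
    }
    if (length(segs) == 0) next
    i <- i + 1L
    out[[i]] <- tibble(
      read_id = rid,
      read_start = vapply(segs, function(x) as.integer(x$start), integer(1)),
      read_end = vapply(segs, function(x) as.integer(x$end), integer(1)),
      junction_end = vapply(segs, function(x) x$junction_end, character(1)),
      target_strand = vapply(segs, function(x) x$strand, character(1))
    )
  }
  if (i == 0) return(empty)
  fl <- bind_rows(out[seq_len(i)]) %>%
    mutate(
      sequence = unname(substr(read_seq[.data$read_id],
                               .data$read_start + 1L, .data$read_end)),
      element_side = element_side_of(.data$junction_end, .data$target_strand)
    ) %>%
    group_by(.data$read_id) %>%
    mutate(flank_id = paste0(.data$read_id, "_f", row_number())) %>%
    ungroup() %>%
    select("flank_id", "read_id", "sequence", "read_start", "read_end",
           "junction_end", "target_strand", "element_side")
  fl
}

# The flank-orientation truth table, isolated so the convention lives in one
# place: a flank left of its span (junction_end "right") abuts the element's
# 5' end when the element lies forward in the read, its 3' end when reversed;
# mirror-image for flanks right of the span.
element_side_of <- function(junction_end, target_strand) {
  dplyr::case_when(
    junction_end == "right" & target_strand == "+" ~ "5p",
    junction_end == "right" & target_strand == "-" ~ "3p",
    junction_end == "left" & target_strand == "+" ~ "3p",
    junction_end == "left" & target_strand == "-" ~ "5p"
  )
}
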