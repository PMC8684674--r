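#' Alignment scoring and E-value parameters
#'
#' Parameters of the built-in seed-and-extend local aligner.  The scoring
#' scheme defaults (+2/-3, gap open -5, gap extend -2) follow common BLASTN
#' practice; the Karlin-Altschul constants default to the ungapped
#' nucleotide values (lambda = 1.28, K = 0.46).  Exact E-value calibration
#' is not required downstream - only thresholding at a permissive cutoff -
#' so the ungapped constants are an acceptable approximation for gapped
#' scores.
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (< 0).
#' @param gap_open Gap-open penalty (<= 0); a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @param gap_extend Gap-extension penalty (<= 0).
#' @param seed_k Exact-match seed word length (>= 8).
#' @param band Half-width of the extension band around seeded diagonals, in
#'   bp.  A band at least as large as both sequences makes the extension an
#'   exhaustive Smith-Waterman.
#' @param karlin_lambda,karlin_k Karlin-Altschul E-value constants.
#' @param search_space Effective search space (query length x database
#'   length).  `NULL` (default) computes it per query as
#'   `query_len * total_subject_len`.
#' @return An `align_params` list.
#' @export
align_params <- function(match = 2L, mismatch = -3L, gap_open = -5L,
                         gap_extend = -2L, seed_k = 13L, band = 50L,
                         karlin_lambda = 1.28, karlin_k = 0.46,
                         search_space = NULL) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend <= 0,
            seed_k >= 8, band >= 1)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 seed_k = as.integer(seed_k), band = as.integer(band),
                 karlin_lambda = karlin_lambda, karlin_k = karlin_k,
                 search_space = search_space),
            class = "align_params")
}

as_seq_tbl <- function(x, what = "sequences") {
  if (is.data.frame(x)) {
    seq_col <- intersect(c("seq", "sequence"), names(x))[1]
    id_col <- intersect(c("id", "flank_id", "read_id"), names(x))[1]
    if (is.na(seq_col) || is.na(id_col))
      abort(paste0(what, " must have an id and a seq/sequence column"))
    return(tibble(id = x[[id_col]], seq = toupper(x[[seq_col]])))
  }
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- paste0("seq", seq_along(x))
    return(tibble(id = ids, seq = toupper(unname(x))))
  }
  abort(paste0(what, " must be a data frame or a (named) character vector"))
}

empty_hits <- function() {
  tibble(query_id = character(), subject_id = character(),
         q_start = integer(), q_end = integer(),
         s_start = integer(), s_end = integer(),
         strand = character(), identity_pct = double(),
         aligned_len = integer(), score = integer(),
         bitscore = double(), evalue = double())
}

#' Local alignment of queries against subjects
#'
#' Built-in seed-and-extend local aligner: exact k-mer seeds on both strands
#' of each query are clustered by diagonal and extended with banded
#' affine-gap dynamic programming.  Hits are filtered by E-value and
#' returned sorted by ascending E-value, then descending bitscore.
#'
#' Coordinates are 0-based half-open.  For minus-strand hits the query
#' coordinates stay on the query's forward orientation and `strand`
#' records the flip; subject coordinates are always on the forward strand.
#'
#' @param query Query sequences: a sequence table ([read_seqs()]), a tibble
#'   with id and sequence columns, or a (named) character vector.
#' @param subjects Subject sequences, same accepted forms.
#' @param params [align_params()].
#' @param evalue_max Keep hits with E-value at or below this cutoff.
#' @return A hit tibble: `query_id`, `subject_id`, `q_start`, `q_end`,
#'   `s_start`, `s_end`, `strand`, `identity_pct`, `aligned_len` (alignment
#'   columns including gaps), `score`, `bitscore`, `evalue`.
#' @export
local_align <- function(query, subjects, params = align_params(),
                        evalue_max = 1e-3) {
  q <- as_seq_tbl(query, "query")
  s <- as_seq_tbl(subjects, "subjects")
  if (nrow(q) == 0 || nrow(s) == 0) return(empty_hits())
  space <- if (is.null(params$search_space)) -1 else params$search_space
  hits <- seed_align_cpp(q$id, q$seq, s$id, s$seq,
                         params$seed_k, params$band,
                         params$match, params$mismatch,
                         params$gap_open, params$gap_extend,
                         params$karlin_lambda, params$karlin_k,
                         evalue_max, space)
  as_tibble(hits) %>% arrange(.data$evalue, desc(.data$bitscore))
}

#' Exhaustive Smith-Waterman local alignment score
#'
#' Full quadratic-time affine-gap dynamic program over a pair of sequences,
#' with no seeding, banding or heuristics.  This is the reference scorer the
#' seeded engine is validated against; it only returns the optimal score.
#'
#' @param a,b DNA strings.
#' @param params [align_params()] supplying the scoring scheme.
#' @return Integer optimal local alignment score.
#' @export
sw_score <- function(a, b, params = align_params()) {
  sw_score_cpp(toupper(a), toupper(b), params$match, params$mismatch,
               params$gap_open, params$gap_extend)
}

#' Karlin-Altschul E-value of a raw alignment score
#'
#' `E = K * m * n * exp(-lambda * S)` with `m * n` the effective search
#' space.  E decreases strictly with score and scales linearly with the
#' search space.
#'
#' @param score Raw alignment score (>= 0), vectorized.
#' @param params [align_params()]; must carry a non-`NULL` `search_space`.
#' @return E-value(s).
#' @export
evalue_of <- function(score, params) {
  if (is.null(params$search_space) || params$search_space <= 0)
    abort("evalue_of() needs params$search_space > 0")
  params$karlin_k * params$search_space * exp(-params$karlin_lambda * score)
}

#' Parse BLASTN tabular output (outfmt 6)
#'
#' Reads the standard 12-column tabular format (`qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore`) and
#' converts it to the internal hit convention: 0-based half-open
#' coordinates on forward strands, with `sstart > send` rows recorded as
#' minus-strand hits.  Hits from an external BLASTN run are interchangeable
#' with the built-in engine's everywhere downstream.
#'
#' @param path Path to a BLAST tabular file.
#' @param params [align_params()] used to back-compute a raw score from the
#'   reported bitscore.
#' @return A hit tibble in the same shape as [local_align()].
#' @export
parse_blast_tab <- function(path, params = align_params()) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(empty_hits())
  nfield <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(nfield != 12)
  if (length(bad) > 0)
    abort(paste0("BLAST tabular parse error in ", path, ": line ", bad[1],
                 " has ", nfield[bad[1]], " columns (12 expected)"))
  f <- strsplit(lines, "\t", fixed = TRUE)
  g <- function(i) vapply(f, `[`, character(1), i)
  qstart <- as.integer(g(7)); qend <- as.integer(g(8))
  sstart <- as.integer(g(9)); send <- as.integer(g(10))
  minus <- sstart > send
  bits <- as.numeric(g(12))
  score <- (bits * log(2) + log(params$karlin_k)) / params$karlin_lambda
  tibble(
    query_id = g(1), subject_id = g(2),
    q_start = qstart - 1L, q_end = qend,
    s_start = ifelse(minus, send, sstart) - 1L,
    s_end = ifelse(minus, sstart, send),
    strand = ifelse(minus, "-", "+"),
    identity_pct = as.numeric(g(3)),
    aligned_len = as.integer(g(4)),
    score = as.integer(round(score)),
    bitscore = bits,
    evalue = as.numeric(g(11))
  )
}
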