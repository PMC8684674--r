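#' Design a two-barcode pooling layout
#'
#' Each sample is sequenced under exactly two distinct barcodes, and every
#' sample gets a different barcode pair, so that an insertion observed in
#' precisely the two barcodes of one sample's pair can be traced back to
#' that sample.  `n_barcodes` barcodes can encode at most
#' `choose(n_barcodes, 2)` samples.  Pairs are chosen by a deterministic
#' greedy rule that always takes the unused pair with the least-loaded
#' barcodes (ties broken lexicographically), which keeps per-barcode sample
#' loads within one of each other.
#'
#' @param n_samples Number of samples (default 56).
#' @param n_barcodes Number of barcodes (default 13).
#' @param sample_ids,barcode_ids Optional identifier vectors; defaults are
#'   `s001...` and `BC01...`.
#' @return A `pool_design` tibble with columns `sample`, `barcode1`,
#'   `barcode2`; the full barcode list is kept in the `"barcodes"`
#'   attribute.
#' @export
make_design <- function(n_samples = 56, n_barcodes = 13,
                        sample_ids = NULL, barcode_ids = NULL) {
  stopifnot(n_samples >= 1, n_barcodes >= 2)
  if (choose(n_barcodes, 2) < n_samples) {
    need <- ceiling((1 + sqrt(1 + 8 * n_samples)) / 2)
    abort(paste0("infeasible design: ", n_barcodes, " barcodes give only ",
                 choose(n_barcodes, 2), " distinct pairs for ", n_samples,
                 " samples; at least ", need, " barcodes are needed"))
  }
  if (is.null(barcode_ids))
    barcode_ids <- sprintf("BC%02d", seq_len(n_barcodes))
  if (is.null(sample_ids))
    sample_ids <- sprintf("s%03d", seq_len(n_samples))
  stopifnot(length(barcode_ids) == n_barcodes,
            length(sample_ids) == n_samples,
            !anyDuplicated(barcode_ids), !anyDuplicated(sample_ids))
  load <- rep(0L, n_barcodes)
  used <- matrix(FALSE, n_barcodes, n_barcodes)
  b1 <- b2 <- integer(n_samples)
  for (s in seq_len(n_samples)) {
    best <- NULL
    best_key <- c(Inf, Inf, Inf, Inf)
    for (i in seq_len(n_barcodes - 1)) {
      for (j in (i + 1):n_barcodes) {
        if (used[i, j]) next
        key <- c(load[i] + load[j], max(load[i], load[j]), i, j)
        if (key[1] < best_key[1] ||
            (key[1] == best_key[1] && key[2] < best_key[2]) ||
            (key[1] == best_key[1] && key[2] == best_key[2] &&
               (key[3] < best_key[3] ||
                  (key[3] == best_key[3] && key[4] < best_key[4])))) {
          best <- c(i, j); best_key <- key
        }
      }
    }
    b1[s] <- best[1]; b2[s] <- best[2]
    used[best[1], best[2]] <- TRUE
    load[best[1]] <- load[best[1]] + 1L
    load[best[2]] <- load[best[2]] + 1L
  }
  design <- tibble(sample = sample_ids,
                   barcode1 = barcode_ids[b1],
                   barcode2 = barcode_ids[b2])
  attr(design, "barcodes") <- barcode_ids
  class(design) <- c("pool_design", class(design))
  design
}

#' Read / write a pooling design TSV
#'
#' Three columns: `sample`, `barcode1`, `barcode2`.  Loading a design from
#' file allows any published layout to be reproduced exactly.
#'
#' @param path TSV path.
#' @return For `read_design`, a `pool_design` tibble.
#' @export
read_design <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (!all(c("sample", "barcode1", "barcode2") %in% names(df)))
    abort("design file must have columns sample, barcode1, barcode2")
  validate_design(df)
  attr(df, "barcodes") <- sort(unique(c(df$barcode1, df$barcode2)))
  class(df) <- c("pool_design", class(df))
  df
}

#' @rdname read_design
#' @param design A `pool_design` tibble.
#' @export
write_design <- function(design, path) {
  readr::write_tsv(design[, c("sample", "barcode1", "barcode2")], path,
                   progress = FALSE)
  invisible(path)
}

validate_design <- function(design) {
  if (any(design$barcode1 == design$barcode2))
    abort("each sample needs two distinct barcodes")
  key <- pair_key(design$barcode1, design$barcode2)
  if (anyDuplicated(key))
    abort("barcode pairs must be distinct across samples (decodability)")
  if (anyDuplicated(design$sample))
    abort("sample ids must be unique")
  invisible(design)
}

pair_key <- function(b1, b2) {
  paste(pmin(b1, b2), pmax(b1, b2), sep = "\r")
}

#' Decode pooled per-barcode insertion calls back to samples
#'
#' Insertions called independently per barcode are first unified across
#' barcodes (single-linkage within `match_dist` bp on each chromosome),
#' then each unified insertion is assigned by its barcode footprint: seen
#' in exactly the two barcodes of one sample's pair, it belongs to that
#' sample; seen in a single barcode it is `unassigned`; seen in three or
#' more barcodes, or in a pair no sample carries, it is `ambiguous`.  The
#' three categories partition the input.
#'
#' @param calls Per-barcode calls: a tibble with columns `barcode`,
#'   `chrom`, `position`, or a named list of site tables (names = barcode
#'   ids).
#' @param design A `pool_design` ([make_design()] / [read_design()]).
#' @param match_dist Positions within this many bp across barcodes are
#'   treated as the same insertion (default 50, the site-clustering
#'   tolerance).
#' @return Tibble with one row per unified insertion: `chrom`, `position`
#'   (lower-median of merged member positions), `barcodes` (comma-joined),
#'   `n_barcodes`, `status` (`assigned`/`unassigned`/`ambiguous`),
#'   `sample` (`NA` unless assigned).
#' @export
decode <- function(calls, design, match_dist = 50) {
  validate_design(design)
  if (is.list(calls) && !is.data.frame(calls)) {
    if (is.null(names(calls))) abort("list of calls must be named by barcode")
    calls <- bind_rows(lapply(names(calls), function(b) {
      tibble(barcode = b, chrom = calls[[b]]$chrom,
             position = calls[[b]]$position)
    }))
  }
  stopifnot(all(c("barcode", "chrom", "position") %in% names(calls)))
  known <- attr(design, "barcodes")
  if (is.null(known)) known <- unique(c(design$barcode1, design$barcode2))
  bad <- setdiff(unique(calls$barcode), known)
  if (length(bad) > 0)
    abort(paste0("calls carry barcode(s) absent from the design: ",
                 paste(bad, collapse = ", ")))
  if (nrow(calls) == 0)
    return(tibble(chrom = character(), position = integer(),
                  barcodes = character(), n_barcodes = integer(),
                  status = character(), sample = character()))
  unified <- calls %>%
    distinct(.data$barcode, .data$chrom, .data$position) %>%
    arrange(.data$chrom, .data$position) %>%
    group_by(.data$chrom) %>%
    mutate(cluster = cumsum(c(TRUE, diff(.data$position) > match_dist))) %>%
    ungroup()
  pair_of <- setNames(design$sample, pair_key(design$barcode1, design$barcode2))
  unified %>%
    group_by(.data$chrom, .data$cluster) %>%
    summarise(
      position = lower_median(.data$position),
      barcodes = paste(sort(unique(.data$barcode)), collapse = ","),
      n_barcodes = n_distinct(.data$barcode),
      .groups = "drop"
    ) %>%
    mutate(
      sample = ifelse(
        .data$n_barcodes == 2,
        unname(pair_of[vapply(strsplit(.data$barcodes, ",", fixed = TRUE),
                              function(b) pair_key(b[1], b[2]),
                              character(1))]),
        NA_character_),
      status = case_when(
        .data$n_barcodes == 1 ~ "unassigned",
        .data$n_barcodes == 2 & !is.na(.data$sample) ~ "assigned",
        TRUE ~ "ambiguous"
      )
    ) %>%
    select("chrom", "position", "barcodes", "n_barcodes", "status",
           "sample") %>%
    arrange(.data$chrom, .data$position)
}
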