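#' Cluster breakpoints into insertion sites
#'
#' Single-linkage clustering of mapped-flank breakpoints per chromosome:
#' consecutive breakpoints at most `merge_dist` bp apart join the same
#' site, so a chain of closely spaced breakpoints forms one site even when
#' its total extent exceeds `merge_dist`.  The representative position is
#' the (lower) median member breakpoint, reported 1-based; the extent is
#' the 1-based inclusive interval spanned by member breakpoints.
#'
#' @param mapped Mapped-flank table from [map_flanks()].
#' @param merge_dist Maximum gap between consecutive breakpoints within one
#'   site, in bp (default 50).
#' @return An insertion-site tibble, one row per site: `site_id`, `chrom`,
#'   `position` (1-based), `extent_start`, `extent_end` (1-based
#'   inclusive), `read_count` (distinct supporting reads), `n_flanks`,
#'   `sides` (`5p`, `3p` or `both`), and a `members` list-column with the
#'   member flank hits.  Output is independent of the input row order.
#' @export
cluster_breakpoints <- function(mapped, merge_dist = 50) {
  empty <- tibble(site_id = character(), chrom = character(),
                  position = integer(), extent_start = integer(),
                  extent_end = integer(), read_count = integer(),
                  n_flanks = integer(), sides = character(),
                  members = list())
  if (nrow(mapped) == 0) return(empty)
  dat <- mapped %>% arrange(.data$chrom, .data$breakpoint, .data$flank_id)
  dat <- dat %>%
    group_by(.data$chrom) %>%
    mutate(cluster = cumsum(
      c(TRUE, diff(.data$breakpoint) > merge_dist)
    )) %>%
    ungroup()
  sites <- dat %>%
    group_by(.data$chrom, .data$cluster) %>%
    summarise(
      position = lower_median(.data$breakpoint) + 1L,
      extent_start = min(.data$breakpoint) + 1L,
      extent_end = max(.data$breakpoint) + 1L,
      read_count = n_distinct(.data$read_id),
      n_flanks = n(),
      sides = sides_label(.data$element_side),
      members = list(dplyr::pick(dplyr::everything()) %>%
                       select(-dplyr::any_of("cluster"))),
      .groups = "drop"
    ) %>%
    mutate(site_id = paste0(.data$chrom, ":", .data$position)) %>%
    select("site_id", "chrom", "position", "extent_start", "extent_end",
           "read_count", "n_flanks", "sides", "members") %>%
    arrange(.data$chrom, .data$position)
  class(sites) <- c("insertion_sites", class(sites))
  sites
}

lower_median <- function(x) {
  sort(x)[ceiling(length(x) / 2)]
}

sides_label <- function(element_side) {
  s <- sort(unique(element_side))
  if (length(s) == 2) "both" else s
}

#' Annotate insertion sites with neighbor genes
#'
#' For each site, genes whose interval contains the site position are its
#' parent genes (relation `contains`, distance 0); otherwise the distance
#' is the gap between the site position and the nearest gene edge.  Genes
#' within `window` bp are listed nearest first.
#'
#' @param sites Insertion-site table from [cluster_breakpoints()].
#' @param genes Gene table from [read_gff()].
#' @param window Neighborhood distance in bp (default 2000).
#' @return `sites` with added columns `neighbor_genes` (list-column of
#'   tibbles `gene_id`, `distance`, `relation`), `n_genes`, and
#'   `neighbor_genes_str` (comma-joined gene ids, `"."` when none).
#' @export
annotate_genes <- function(sites, genes, window = 2000) {
  if (nrow(sites) == 0) {
    sites$neighbor_genes <- list()
    sites$n_genes <- integer(0)
    sites$neighbor_genes_str <- character(0)
    return(sites)
  }
  nb <- lapply(seq_len(nrow(sites)), function(i) {
    g <- genes[genes$chrom == sites$chrom[i], ]
    if (nrow(g) == 0)
      return(tibble(gene_id = character(), distance = integer(),
                    relation = character()))
    pos <- sites$position[i]
    dist <- ifelse(pos >= g$start & pos <= g$end, 0L,
                   ifelse(pos < g$start, g$start - pos, pos - g$end))
    rel <- ifelse(dist == 0L, "contains",
                  ifelse(pos < g$start, "downstream", "upstream"))
    keep <- dist <= window
    tibble(gene_id = g$gene_id[keep], distance = as.integer(dist[keep]),
           relation = rel[keep]) %>% arrange(.data$distance, .data$gene_id)
  })
  sites$neighbor_genes <- nb
  sites$n_genes <- vapply(nb, nrow, integer(1))
  sites$neighbor_genes_str <- vapply(nb, function(x) {
    if (nrow(x) == 0) "." else paste(x$gene_id, collapse = ",")
  }, character(1))
  sites
}

#' Filter insertion sites by read support
#'
#' @param sites Insertion-site table.
#' @param min_reads Minimum number of distinct supporting reads
#'   (default 1, the published cutoff).
#' @return Sites with `read_count >= min_reads`, order preserved.  The
#'   filter is idempotent.
#' @export
filter_sites <- function(sites, min_reads = 1) {
  sites[sites$read_count >= min_reads, , drop = FALSE]
}

#' Classify annotated sites by gene context
#'
#' @param sites Annotated insertion-site table ([annotate_genes()]).
#' @param genes Optional gene table; supplied when `sites` has not been
#'   annotated yet.
#' @param window Neighborhood window forwarded to [annotate_genes()].
#' @return One-row tibble with counts: `genic` (exactly one neighbor
#'   gene), `intergenic` (none), `multi_gene` (two or more).
#' @export
classify_sites <- function(sites, genes = NULL, window = 2000) {
  if (!"n_genes" %in% names(sites)) {
    if (is.null(genes))
      abort("sites are not annotated; supply `genes` or run annotate_genes()")
    sites <- annotate_genes(sites, genes, window = window)
  }
  tibble(
    genic = sum(sites$n_genes == 1L),
    intergenic = sum(sites$n_genes == 0L),
    multi_gene = sum(sites$n_genes >= 2L)
  )
}
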