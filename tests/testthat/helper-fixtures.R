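# shared helpers: tiny sequence generators and independent oracles used to
# cross-check the package implementations

`%>%` <- dplyr::`%>%`

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

rc_dna <- function(s) {
  chartr("ACGT", "TGCA",
         paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

substitute_frac <- function(s, p) {
  v <- strsplit(s, "")[[1]]
  i <- which(runif(length(v)) < p)
  if (length(i) > 0)
    v[i] <- sample(c("A", "C", "G", "T"), length(i), replace = TRUE)
  paste(v, collapse = "")
}

# plain-R affine-gap local alignment score, O(mn) with explicit matrices;
# independent of the compiled scorer (used to validate it on tiny inputs)
sw_score_r <- function(a, b, match = 2, mismatch = -3,
                       gap_open = -5, gap_extend = -2) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  m <- length(av); n <- length(bv)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m) + 1) {
    for (j in seq_len(n) + 1) {
      E[i, j] <- max(H[i, j - 1] + gap_open + gap_extend,
                     E[i, j - 1] + gap_extend)
      F[i, j] <- max(H[i - 1, j] + gap_open + gap_extend,
                     F[i - 1, j] + gap_extend)
      s <- if (av[i - 1] == bv[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# exhaustive maximum bipartite matching size for small call/truth instances
# (every subset ordering tried recursively); oracle for evaluate_calls
max_matching_size <- function(adj) {
  # adj: logical matrix truth x calls
  if (nrow(adj) == 0 || ncol(adj) == 0) return(0L)
  best <- 0L
  recurse <- function(ti, used, count) {
    if (ti > nrow(adj)) {
      best <<- max(best, count)
      return()
    }
    if (count + (nrow(adj) - ti + 1) <= best) return()
    recurse(ti + 1, used, count)  # leave this truth unmatched
    for (ci in which(adj[ti, ] & !used)) {
      used[ci] <- TRUE
      recurse(ti + 1, used, count + 1L)
      used[ci] <- FALSE
    }
  }
  recurse(1L, rep(FALSE, ncol(adj)), 0L)
  best
}

# brute-force pool decoder: tests every sample's pair against the barcode
# footprint of each insertion (oracle for decode())
decode_brute <- function(calls, design, match_dist = 50) {
  unified <- calls %>%
    dplyr::distinct(barcode, chrom, position) %>%
    dplyr::arrange(chrom, position) %>%
    dplyr::group_by(chrom) %>%
    dplyr::mutate(cluster = cumsum(c(TRUE, diff(position) > match_dist))) %>%
    dplyr::group_by(chrom, cluster) %>%
    dplyr::summarise(position = sort(position)[ceiling(dplyr::n() / 2)],
                     bcs = list(sort(unique(barcode))), .groups = "drop")
  res <- lapply(seq_len(nrow(unified)), function(i) {
    bcs <- unified$bcs[[i]]
    if (length(bcs) == 1) return(list(status = "unassigned", sample = NA))
    hit <- NULL
    for (s in seq_len(nrow(design))) {
      pair <- sort(c(design$barcode1[s], design$barcode2[s]))
      if (length(bcs) == 2 && identical(pair, bcs)) hit <- design$sample[s]
    }
    if (length(bcs) == 2 && !is.null(hit))
      list(status = "assigned", sample = hit)
    else list(status = "ambiguous", sample = NA)
  })
  tibble::tibble(
    chrom = unified$chrom, position = unified$position,
    status = vapply(res, function(x) x$status, character(1)),
    sample = vapply(res, function(x)
      if (is.na(x$sample[1])) NA_character_ else x$sample, character(1))
  ) %>% dplyr::arrange(chrom, position)
}

# small simulated experiment reused by several tests
tiny_experiment <- function(seed = 7, ...) {
  cfg <- sim_config(genome_len = 1e5, n_insertions = 2, target_len = 1500,
                    depth = 12, read_len_mean = 6000, read_len_sd = 2500,
                    err_sub = 0, err_ins = 0, err_del = 0, seed = seed, ...)
  sim_insertion_experiment(cfg)
}
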