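mk_hits <- function(chrom, bp, read_id = NULL, side = "5p") {
  n <- length(bp)
  if (is.null(read_id)) read_id <- paste0("r", seq_len(n))
  tibble::tibble(
    flank_id = paste0(read_id, "_f1"), read_id = read_id,
    chrom = rep_len(chrom, n), s_start = as.integer(bp - 300),
    s_end = as.integer(bp), genome_strand = "+",
    identity_pct = 100, aligned_len = 300L,
    breakpoint = as.integer(bp),
    element_side = rep_len(side, n), junction_end = "right",
    discordant_pair = FALSE
  )
}

test_that("tight breakpoint clusters form one site at the lower median", {
  h <- mk_hits("chr1", c(1000, 1004, 1007), side = c("5p", "3p", "5p"))
  s <- cluster_breakpoints(h, merge_dist = 50)
  expect_equal(nrow(s), 1)
  expect_equal(s$position, 1005L)  # lower median 1004, +1 for 1-based output
  expect_equal(s$extent_start, 1001L)
  expect_equal(s$extent_end, 1008L)
  expect_equal(s$read_count, 3L)
  expect_equal(s$sides, "both")
})

test_that("separated breakpoints stay distinct; chains join by single linkage", {
  h <- mk_hits("chr1", c(1000, 2000))
  expect_equal(nrow(cluster_breakpoints(h, merge_dist = 50)), 2)
  # chain 0,40,80,120 with merge_dist 50: consecutive gaps of 40 join all
  h2 <- mk_hits("chr1", c(0, 40, 80, 120))
  s2 <- cluster_breakpoints(h2, merge_dist = 50)
  expect_equal(nrow(s2), 1)
  expect_equal(s2$extent_end - s2$extent_start, 120L)
})

test_that("clustering partitions hits and ignores input order", {
  set.seed(51)
  bp <- sort(sample(1:100000, 30))
  h <- mk_hits("chr1", bp, read_id = paste0("r", 1:30))
  s <- cluster_breakpoints(h, merge_dist = 50)
  expect_equal(sum(s$n_flanks), nrow(h))
  expect_equal(sum(vapply(s$members, nrow, integer(1))), nrow(h))
  sh <- cluster_breakpoints(h[sample(nrow(h)), ], merge_dist = 50)
  expect_equal(sh$position, s$position)
  expect_equal(sh$read_count, s$read_count)
  # read_count counts distinct reads, bounded by member flanks
  expect_true(all(s$read_count <= s$n_flanks))
})

test_that("distinct reads versus flanks are counted correctly", {
  h <- mk_hits("chr1", c(1000, 1001, 1002),
               read_id = c("ra", "ra", "rb"))
  s <- cluster_breakpoints(h)
  expect_equal(s$read_count, 2L)
  expect_equal(s$n_flanks, 3L)
})

test_that("gene annotation windows, relations and ordering are correct", {
  genes <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"), chrom = "chr1",
    start = c(1000L, 7000L, 9000L), end = c(5000L, 7400L, 9400L),
    strand = "+"
  )
  sites <- cluster_breakpoints(mk_hits("chr1", c(1500, 8500, 9600 + 1000)))
  # positions: 1501, 8501, 10601 after the 1-based shift
  sites <- annotate_genes(sites, genes, window = 2000)
  nb1 <- sites$neighbor_genes[[1]]
  expect_equal(nb1$gene_id, "g1")
  expect_equal(nb1$distance, 0L)
  expect_equal(nb1$relation, "contains")

  nb2 <- sites$neighbor_genes[[2]]  # position 8501: g2 ends 7400 -> 1101 away
  expect_setequal(nb2$gene_id, c("g2", "g3"))
  expect_equal(nb2$gene_id[1], "g3")  # 499 away, nearest first
  expect_equal(nb2$distance, c(499L, 1101L))

  nb3 <- sites$neighbor_genes[[3]]  # position 10601: g3 ends 9400 -> 1201 away
  expect_equal(nb3$gene_id, "g3")
  # a site 2600 bp from every gene is intergenic
  far <- annotate_genes(cluster_breakpoints(mk_hits("chr1", 12001)), genes)
  expect_equal(far$n_genes, 0L)
  expect_equal(far$neighbor_genes_str, ".")
})

test_that("site filtering by read support is correct and idempotent", {
  h <- dplyr::bind_rows(
    mk_hits("chr1", c(1000, 1001), read_id = c("r1", "r2")),
    mk_hits("chr1", 5000, read_id = "r3")
  )
  s <- cluster_breakpoints(h)
  expect_equal(nrow(filter_sites(s, min_reads = 1)), 2)  # identity at the default
  expect_equal(filter_sites(s, min_reads = 1), s)
  s2 <- filter_sites(s, min_reads = 2)
  expect_equal(nrow(s2), 1)
  expect_equal(filter_sites(s2, min_reads = 2), s2)
})

test_that("gene-context classification matches a brute-force recount", {
  set.seed(52)
  genes <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:12), chrom = "chr1",
    start = as.integer(seq(1000, 89000, length.out = 12)),
    end = as.integer(seq(1000, 89000, length.out = 12) + 2500),
    strand = "+"
  )
  sites <- cluster_breakpoints(mk_hits("chr1", sort(sample(1:95000, 25))))
  sites <- annotate_genes(sites, genes, window = 2000)
  cls <- classify_sites(sites)
  brute <- table(factor(vapply(seq_len(nrow(sites)), function(i) {
    pos <- sites$position[i]
    d <- ifelse(pos >= genes$start & pos <= genes$end, 0,
                pmin(abs(genes$start - pos), abs(genes$end - pos)))
    n <- sum(d <= 2000)
    if (n == 0) "intergenic" else if (n == 1) "genic" else "multi_gene"
  }, character(1)), levels = c("genic", "intergenic", "multi_gene")))
  expect_equal(cls$genic, unname(brute["genic"]))
  expect_equal(cls$intergenic, unname(brute["intergenic"]))
  expect_equal(cls$multi_gene, unname(brute["multi_gene"]))
  expect_equal(cls$genic + cls$intergenic + cls$multi_gene, nrow(sites))
})
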