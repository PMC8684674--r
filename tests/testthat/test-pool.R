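test_that("the 56-sample 13-barcode design is valid and balanced", {
  d <- make_design(56, 13)
  expect_equal(nrow(d), 56)
  expect_true(all(d$barcode1 != d$barcode2))
  expect_equal(anyDuplicated(paste(pmin(d$barcode1, d$barcode2),
                                   pmax(d$barcode1, d$barcode2))), 0L)
  load <- table(c(d$barcode1, d$barcode2))
  expect_equal(length(load), 13L)
  expect_lte(max(load) - min(load), 1)
  # deterministic
  expect_identical(make_design(56, 13), d)
})

test_that("per-barcode load stays within one across design sizes", {
  for (nb in c(5, 8, 13)) {
    for (ns in unique(pmin(c(3, 7, 12, 20), choose(nb, 2)))) {
      d <- make_design(ns, nb)
      load <- table(factor(c(d$barcode1, d$barcode2),
                           levels = attr(d, "barcodes")))
      expect_lte(max(load) - min(load), 1)
    }
  }
})

test_that("trivial and infeasible designs behave as specified", {
  d1 <- make_design(1, 2)
  expect_equal(unname(unlist(d1[1, c("barcode1", "barcode2")])),
               c("BC01", "BC02"))
  expect_error(make_design(4, 3), "at least 4 barcodes")
})

test_that("design TSV round-trips and invalid designs are rejected", {
  d <- make_design(10, 6)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_design(d, p)
  back <- read_design(p)
  expect_equal(back$sample, d$sample)
  expect_equal(back$barcode1, d$barcode1)

  bad <- tibble::tibble(sample = c("a", "b"),
                        barcode1 = c("BC01", "BC01"),
                        barcode2 = c("BC02", "BC02"))
  readr::write_tsv(bad, p)
  expect_error(read_design(p), "distinct across samples")
})

test_that("the shared-pair example decodes to its sample", {
  # 56-sample flowcell layout with sample a1 sequenced under BC01 and BC09:
  # an insertion common to exactly those two barcodes must decode to a1
  grid <- expand.grid(num = 1:7, letter = letters[1:8])
  samples <- paste0(grid$letter, grid$num)
  pairs <- utils::combn(sprintf("BC%02d", 1:13), 2)
  keep <- which(!(pairs[1, ] == "BC01" & pairs[2, ] == "BC09"))[1:55]
  d <- tibble::tibble(sample = samples,
                      barcode1 = c("BC01", pairs[1, keep]),
                      barcode2 = c("BC09", pairs[2, keep]))
  attr(d, "barcodes") <- sprintf("BC%02d", 1:13)
  calls <- tibble::tibble(barcode = c("BC01", "BC09"),
                          chrom = "chr1", position = c(5000L, 5010L))
  dec <- decode(calls, d)
  expect_equal(dec$status, "assigned")
  expect_equal(dec$sample, "a1")
  expect_equal(dec$position, 5000L)  # lower median of the unified pair
})

test_that("single-barcode and off-design footprints are flagged", {
  d <- make_design(6, 4)
  calls <- tibble::tibble(
    barcode = c("BC01",                      # unassigned
                "BC01", "BC02", "BC03"),     # ambiguous (3 barcodes)
    chrom = "chr1",
    position = c(1000L, 50000L, 50005L, 50010L)
  )
  dec <- decode(calls, d)
  expect_equal(dec$status[dec$position == 1000], "unassigned")
  expect_equal(dec$status[dec$position > 1000], "ambiguous")
  # the three categories partition the insertion universe
  expect_equal(nrow(dec), 2)
  expect_error(decode(tibble::tibble(barcode = "BC99", chrom = "chr1",
                                     position = 1L), d),
               "absent from the design")
})

test_that("decode inverts encoding and matches the brute-force oracle", {
  set.seed(71)
  for (rep in 1:8) {
    nb <- sample(6:13, 1)
    ns <- sample(5:min(20, choose(nb, 2)), 1)
    d <- make_design(ns, nb)
    truth <- tibble::tibble(
      sample = rep(d$sample, each = 5),
      chrom = "chr1",
      position = sample(seq(1000, 5e6, by = 500),
                        5 * ns)  # distinct, well separated
    )
    calls <- dplyr::bind_rows(
      dplyr::transmute(dplyr::left_join(truth, d, by = "sample"),
                       barcode = barcode1, chrom, position),
      dplyr::transmute(dplyr::left_join(truth, d, by = "sample"),
                       barcode = barcode2, chrom, position)
    )
    dec <- decode(calls, d)
    expect_true(all(dec$status == "assigned"))
    got <- dec[order(dec$position), c("position", "sample")]
    want <- truth[order(truth$position), c("position", "sample")]
    expect_equal(got$sample, want$sample)
    oracle <- decode_brute(calls, d)
    expect_equal(dec$status, oracle$status)
    expect_equal(dec$sample, oracle$sample)
  }
})

test_that("an insertion shared by overlapping pairs is ambiguous, not assigned", {
  d <- make_design(6, 4)
  # two samples whose pairs overlap in one barcode: union is 3 barcodes
  s1 <- d[1, ]
  others <- d[(d$barcode1 == s1$barcode1 | d$barcode2 == s1$barcode1 |
                 d$barcode1 == s1$barcode2 | d$barcode2 == s1$barcode2) &
                d$sample != s1$sample, ]
  expect_gt(nrow(others), 0)  # six samples over four barcodes must overlap
  s2 <- others[1, ]
  bcs <- unique(c(s1$barcode1, s1$barcode2, s2$barcode1, s2$barcode2))
  calls <- tibble::tibble(barcode = bcs, chrom = "chr1",
                          position = 1000L + seq_along(bcs))
  dec <- decode(calls, d)
  expect_equal(dec$status, "ambiguous")
  expect_true(is.na(dec$sample))
})
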