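# Genomic-window polymorphism counting and derivation calls.

chrom_lengths <- c(chr1 = 1e6, chr2 = 5.5e5)

test_that("window counting tiles chromosomes and respects the boundary rule", {
  v <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    pos = c(1, 1e5, 999999, 550000),
    line = "tak2"
  )
  wc <- count_window_polymorphisms(v, 1e5, chrom_lengths)
  expect_equal(sum(wc$width[wc$chrom == "chr1"]), 1e6)
  expect_equal(sum(wc$width[wc$chrom == "chr2"]), 5.5e5)
  # pos 1 -> window 1; pos exactly 1e5 -> window 2 (half-open convention)
  w1 <- wc[wc$chrom == "chr1", ]
  expect_equal(w1$tak2[1], 1)
  expect_equal(w1$tak2[2], 1)
  expect_equal(w1$tak2[10], 1)
  # chromosome-end variant stays in the truncated final window
  w2 <- wc[wc$chrom == "chr2", ]
  expect_equal(nrow(w2), 6)
  expect_equal(w2$width[6], 5e4)
  expect_equal(w2$tak2[6], 1)
})

test_that("empty inputs give zero counts and bad positions are named", {
  wc <- count_window_polymorphisms(
    tibble::tibble(chrom = character(), pos = numeric(), line = character()),
    1e5, chrom_lengths)
  expect_true(all(wc$tak2 == 0 & wc$rit1 == 0 & wc$rit2 == 0))

  expect_error(
    count_window_polymorphisms(
      tibble::tibble(chrom = "chr1", pos = 2e6, line = "rit1"),
      1e5, chrom_lengths),
    "chr1:2000000.*rit1"
  )
  expect_error(
    count_window_polymorphisms(
      tibble::tibble(chrom = "chrX", pos = 5, line = "rit1"),
      1e5, chrom_lengths),
    "unknown chromosome"
  )
})

test_that("150 variants in one window land in that window only", {
  v <- tibble::tibble(chrom = "chr1", pos = 3e5 + seq_len(150), line = "rit1")
  wc <- count_window_polymorphisms(v, 1e5, chrom_lengths["chr1"])
  w <- wc[wc$chrom == "chr1", ]
  expect_equal(w$rit1[4], 150)
  expect_equal(sum(w$rit1), 150)
})

test_that("intersection counts positions shared by all three lines", {
  v <- dplyr::bind_rows(lapply(c("tak2", "rit1", "rit2"), function(ln)
    tibble::tibble(chrom = "chr1", pos = c(10, 20, 30), line = ln)))
  v <- dplyr::bind_rows(v, tibble::tibble(chrom = "chr1", pos = 40, line = "tak2"))
  wc <- count_window_polymorphisms(v, 1e5, c(chr1 = 1e6))
  expect_equal(wc$intersection[1], 3)
  expect_true(all(wc$intersection <= pmin(wc$tak2, wc$rit1, wc$rit2)))
})

test_that("significance uses a strict, width-scaled threshold", {
  counts <- tibble::tibble(
    chrom = "chr1", start = c(0, 1e5, 0, 0), end = c(1e5, 2e5, 1e6, 5e4),
    width = c(1e5, 1e5, 1e6, 5e4),
    tak2 = c(100, 101, 1001, 60), rit1 = 0, rit2 = 0, intersection = 0
  )
  fl <- flag_significant(counts)
  expect_equal(fl$sig_tak2, c(FALSE, TRUE, TRUE, TRUE))
  fl2 <- flag_significant(dplyr::mutate(counts, tak2 = c(100, 100, 1000, 50)))
  expect_false(any(fl2$sig_tak2))
})

test_that("derivation calls follow the intersection-pattern rule", {
  flags <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chrV"),
    start = c(0, 1e5, 2e5, 0), end = c(1e5, 2e5, 3e5, 1e5),
    width = 1e5,
    sig_tak2 = c(FALSE, TRUE, TRUE, TRUE),
    sig_rit1 = c(FALSE, TRUE, FALSE, FALSE),
    sig_rit2 = c(FALSE, TRUE, FALSE, FALSE)
  )
  expect_message(calls <- classify_derivation(flags), "chrV")
  expect_equal(calls$call, c("SHARED", "TAK2", "TAK1"))
  # tak2 significant with either rit flag -> TAK2
  flags2 <- flags[2, ]; flags2$sig_rit2 <- FALSE
  expect_equal(classify_derivation(flags2)$call, "TAK2")
})

test_that("planted derivation maps are recovered exactly with exact fractions", {
  lens <- c(chr1 = 1e6)
  plan <- tibble::tibble(
    chrom = "chr1", window = 1:10,
    call = c(rep("SHARED", 5), rep("TAK2", 3), rep("TAK1", 2))
  )
  v <- simulate_ril_variants(plan, 1e5, lens, seed = 8)
  wc <- count_window_polymorphisms(v, 1e5, lens)
  calls <- classify_derivation(flag_significant(wc))
  expect_equal(calls$call, plan$call)
  s <- summarize_derivation(calls, lens)
  expect_equal(s$fraction[match(c("SHARED", "TAK2", "TAK1"), s$call)],
               c(0.5, 0.3, 0.2), tolerance = 1e-12)
  expect_lt(abs(sum(s$fraction) - 1), 1e-9)
})

test_that("Rit-1 and Rit-2 flags agree on synthetic RIL genomes", {
  lens <- c(chr1 = 2e6)
  plan <- tibble::tibble(chrom = "chr1", window = 1:20,
                         call = rep(c("SHARED", "TAK2", "TAK1", "TAK2"), 5))
  v <- simulate_ril_variants(plan, 1e5, lens, seed = 5)
  fl <- flag_significant(count_window_polymorphisms(v, 1e5, lens))
  expect_equal(fl$sig_rit1, fl$sig_rit2)
})

test_that("coverage gaps are detected and tracks round-trip", {
  lens <- c(chr1 = 1e6)
  plan <- tibble::tibble(chrom = "chr1", window = 1:10, call = rep("SHARED", 10))
  v <- simulate_ril_variants(plan, 1e5, lens, seed = 2)
  calls <- classify_derivation(flag_significant(count_window_polymorphisms(v, 1e5, lens)))
  expect_error(summarize_derivation(calls[-3, ], lens), "coverage gap")

  dir <- withr::local_tempdir()
  path <- file.path(dir, "track.tsv")
  write_derivation_track(calls, path)
  track <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "call"),
                           show_col_types = FALSE)
  expect_equal(nrow(track), 10)
  expect_equal(track$call, calls$call)
})

test_that("variant tables load from TSV and minimal VCF", {
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "v.tsv")
  readr::write_tsv(tibble::tibble(chrom = "chr1", pos = c(5, 10), line = "tak2"), tsv)
  v1 <- read_variants(tsv)
  expect_equal(nrow(v1), 2)

  vcf <- file.path(dir, "v.vcf")
  writeLines(c("##fileformat=VCFv4.2", "#CHROM\tPOS\tID\tREF\tALT",
               "chr1\t123\t.\tA\tT", "chr2\t77\t.\tG\tC"), vcf)
  v2 <- read_variants(vcf, line = "rit1")
  expect_equal(v2$pos, c(123, 77))
  expect_equal(unique(v2$line), "rit1")
  expect_error(read_variants(vcf), "line")
})
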