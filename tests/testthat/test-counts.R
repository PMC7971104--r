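# hand-built micro-BAM: 2 regions, controllable reads
make_bam <- function(reads, chrom = "chr1", ln = 5000L) {
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               paste0("@SQ\tSN:", chrom, "\tLN:", ln),
               reads[order(as.integer(vapply(strsplit(reads, "\t"),
                                             `[[`, "", 4L)))]),
             sam)
  Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                   indexDestination = TRUE)
}

sam_read <- function(qname, pos, flag = 0L, mapq = 60L, len = 50L,
                     chrom = "chr1", rx = NULL) {
  paste(c(qname, flag, chrom, pos, mapq, paste0(len, "M"), "*", 0, 0,
          strrep("A", len), strrep("I", len),
          if (!is.null(rx)) paste0("RX:Z:", rx)),
        collapse = "\t")
}

two_region_panel <- function() {
  read_panel(write_bed(c("chr1\t100\t300\tG1", "chr1\t1000\t1200\tG2")))
}

test_that("distinct UMIs are counted once per region; duplicates don't matter", {
  panel <- two_region_panel()
  # 5 reads over region 1 carrying 3 distinct UMIs (2 flagged as PCR dups)
  reads <- c(sam_read("r1_AAAA", 150), sam_read("r2_AAAA", 160, flag = 1024L),
             sam_read("r3_CCCC", 170), sam_read("r4_CCCC", 180, flag = 1024L),
             sam_read("r5_GGGG", 190),
             sam_read("r6_TTTT", 1100))
  bam <- make_bam(reads)
  col <- count_umis(bam, panel)
  expect_equal(col$counts, c(3L, 1L))
  expect_equal(col$read_counts, c(5L, 1L))
  expect_equal(col$total, 4L)
})

test_that("read filters apply: MAPQ, secondary, unmapped, QC-fail", {
  panel <- two_region_panel()
  reads <- c(sam_read("r1_AAAA", 150),
             sam_read("r2_CCCC", 160, mapq = 5L),      # below MAPQ 20
             sam_read("r3_GGGG", 170, flag = 256L),     # secondary
             sam_read("r4_TTTT", 180, flag = 512L))     # QC fail
  col <- count_umis(make_bam(reads), panel)
  expect_equal(col$counts, c(1L, 0L))
  expect_equal(col$total, 1L)
})

test_that("UMIs can be taken from the RX tag", {
  panel <- two_region_panel()
  reads <- c(sam_read("r1", 150, rx = "TTTTGGGGCCCC"),
             sam_read("r2", 160, rx = "TTTTGGGGCCCC"),
             sam_read("r3", 170, rx = "AAAACCCCGGGG"))
  col <- count_umis(make_bam(reads), panel, policy = umi_policy(from = "tag"))
  expect_equal(col$counts, c(2L, 0L))
})

test_that("a UMI overlapping two regions counts in both but once in U", {
  panel <- read_panel(write_bed(c("chr1\t100\t200\tG1",
                                  "chr1\t200\t300\tG1")))
  col <- count_umis(make_bam(sam_read("r1_AAAA", 180, len = 50L)), panel)
  expect_equal(col$counts, c(1L, 1L))
  expect_equal(col$total, 1L)
  # normalized column may therefore sum above 1 per UMI, but never above P
  m <- normalize_counts(assemble_matrix(list(col)))
  expect_lte(sum(m$norm[, 1L]), n_regions(panel))
})

test_that("fixture counts match the brute-force (read x region) oracle", {
  sp <- sim_panel(n_genes = 2, regions_per_gene = 3, seed = 7)
  set.seed(7)
  counts <- sample(0:8, n_regions(sp$panel), replace = TRUE)
  fx <- simulate_bam_fixture(sp, counts, tempfile(), seed = 7)
  col <- count_umis(fx$bam, sp$panel)
  oracle <- sam_count_oracle(fx$sam, sp$panel)
  expect_equal(col$counts, oracle$counts)
  expect_equal(col$counts, counts)
  expect_equal(col$total, oracle$total)
  expect_equal(col$total, sum(counts))
  # read counts exceed UMI counts wherever a UMI was duplicated
  expect_true(all(col$read_counts >= col$counts))
})

test_that("missing index and absent chromosome are handled", {
  panel <- two_region_panel()
  bam <- make_bam(sam_read("r1_AAAA", 150))
  file.remove(paste0(bam, ".bai"))
  expect_error(count_umis(bam, panel), "index")

  p2 <- read_panel(write_bed(c("chr1\t100\t300\tG1", "chrX\t10\t60\tGX")))
  bam2 <- make_bam(sam_read("r1_AAAA", 150))
  expect_warning(col <- count_umis(bam2, p2), "absent")
  expect_equal(col$counts, c(1L, 0L))
})

test_that("matrix assembly preserves order and rejects mixed panels", {
  panel <- two_region_panel()
  a <- make_col(panel, c(10, 20), total = 100, id = "a")
  b <- make_col(panel, c(5, 5), total = 50, id = "b")
  m <- assemble_matrix(list(a, b))
  expect_equal(dim(m$counts), c(2L, 2L))
  expect_equal(m$sample_ids, c("a", "b"))
  expect_equal(m$totals, c(100, 50))
  expect_error(assemble_matrix(list()), "no count columns")
  other <- make_col(tiny_panel(), rep(1, 9))
  expect_error(assemble_matrix(list(a, other)), "different panels")
})

test_that("normalization divides by U once and only once", {
  panel <- two_region_panel()
  m <- assemble_matrix(list(make_col(panel, c(10, 30), total = 100, id = "a"),
                            make_col(panel, c(20, 60), total = 200, id = "b")))
  m <- normalize_counts(m)
  expect_equal(m$norm[, "a"], c(0.10, 0.30))
  # proportional counts and totals give identical normalized columns
  expect_equal(m$norm[, "a"], m$norm[, "b"])
  expect_error(normalize_counts(m), "already normalized")
  bad <- assemble_matrix(list(make_col(panel, c(0, 0), total = 0, id = "z"),
                              make_col(panel, c(1, 1), total = 2, id = "y")))
  expect_error(normalize_counts(bad), "'z'")
})

test_that("count tables round-trip through TSV", {
  sp <- sim_panel(n_genes = 2, regions_per_gene = 4, seed = 3)
  tr <- sim_truth(sp, list(), 1)
  col <- simulate_tumor(sp, tr, mean_depth = 200, seed = 3, sample_id = "rt")
  tsv <- tempfile(fileext = ".tsv")
  write_counts(col, tsv)
  back <- read_counts(tsv)
  expect_equal(back$counts, col$counts)
  expect_equal(back$total, col$total)
  expect_equal(back$sample_id, "rt")
  expect_identical(umicna:::panel_hash(back$panel),
                   umicna:::panel_hash(col$panel))
})
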