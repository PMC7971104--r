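# shared fixtures built in code; nothing on disk beyond tempfiles

write_bed <- function(lines) {
  bed <- tempfile(fileext = ".bed")
  writeLines(lines, bed)
  bed
}

# a 3-gene / 9-region panel on two chromosomes
tiny_panel <- function() {
  read_panel(write_bed(c(
    "chr1\t100\t250\tGENE_A",
    "chr1\t300\t450\tGENE_A",
    "chr1\t500\t650\tGENE_A",
    "chr1\t1000\t1150\tGENE_B",
    "chr1\t1200\t1350\tGENE_B",
    "chr1\t1400\t1550\tGENE_B",
    "chr2\t100\t250\tGENE_C",
    "chr2\t300\t450\tGENE_C",
    "chr2\t500\t650\tGENE_C"
  )))
}

# a count column with a caller-controlled total, bypassing BAM I/O
make_col <- function(panel, counts, total = sum(counts), id = "s") {
  structure(list(counts = as.integer(counts), read_counts = NULL,
                 total = total, sample_id = id, panel = panel,
                 n_skipped = 0L),
            class = "umi_counts_col")
}

# exhaustive weighted max-arc-statistic oracle (independent of src/cbs.cpp)
oracle_max_arc <- function(x, w, min_width) {
  n <- length(x); Wt <- sum(w)
  St <- sum(w * x); TSS <- sum(w * x^2) - St^2 / Wt
  best <- list(t = -1, i = NA, j = NA)
  for (i in 0:(n - 1)) {
    for (j in (i + 1):n) {
      la <- j - i
      if (la < min_width || n - la < min_width) next
      arc <- (i + 1):j
      W1 <- sum(w[arc]); W0 <- Wt - W1
      S1 <- sum(w[arc] * x[arc])
      d <- S1 / W1 - (St - S1) / W0
      B <- d^2 * W1 * W0 / Wt
      tt <- if (TSS - B <= 1e-300) 1e12 else sqrt(B * (n - 2) / (TSS - B))
      if (tt > best$t) best <- list(t = tt, i = i, j = j)
    }
  }
  best
}

# breakpoint set induced by an (i, j) arc split on n points
split_bounds <- function(i, j, n) setdiff(sort(unique(c(i, j))), c(0, n))

# brute-force (read x region) overlap/UMI-union oracle over a SAM text file
sam_count_oracle <- function(sam_path, panel, min_mapq = 20L) {
  lines <- readLines(sam_path)
  lines <- lines[!grepl("^@", lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  qname <- vapply(f, `[[`, "", 1L)
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  rname <- vapply(f, `[[`, "", 3L)
  pos <- as.integer(vapply(f, `[[`, "", 4L))   # 1-based
  mapq <- as.integer(vapply(f, `[[`, "", 5L))
  cigar <- vapply(f, `[[`, "", 6L)
  reflen <- as.integer(sub("M$", "", cigar))   # fixtures are single-M
  umi <- vapply(strsplit(qname, "_", fixed = TRUE),
                function(p) p[[length(p)]], "")
  pass <- mapq >= min_mapq &
    bitwAnd(flag, 4L) == 0L & bitwAnd(flag, 256L) == 0L &
    bitwAnd(flag, 2048L) == 0L & bitwAnd(flag, 512L) == 0L
  reg <- panel$regions
  counts <- integer(nrow(reg))
  for (p in seq_len(nrow(reg))) {
    ov <- pass & rname == reg$chrom[p] &
      (pos - 1L) < reg$end[p] & (pos - 1L + reflen) > reg$start[p]
    counts[p] <- length(unique(umi[ov]))
  }
  list(counts = counts, total = length(unique(umi[pass])))
}
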