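norm_matrix <- function(...) {
  cols <- list(...)
  matrix(unlist(cols), ncol = length(cols))
}

test_that("geometric reference matches the log-space oracle", {
  expect_equal(geometric_reference(norm_matrix(0.01, 0.04))$r, 0.02)
  # identical controls: r equals any single column
  x <- c(0.1, 0.2, 0.7)
  expect_equal(geometric_reference(norm_matrix(x, x, x))$r, x)
  set.seed(11)
  m <- matrix(runif(5 * 5, 0.001, 0.1), 5, 5)
  expect_equal(geometric_reference(m)$r, exp(rowMeans(log(m))),
               tolerance = 1e-12)
})

test_that("zero-coverage regions are excluded, all-zero input errors", {
  m <- norm_matrix(c(0.1, 0), c(0.2, 0.3))
  gr <- geometric_reference(m)
  expect_equal(gr$zero_regions, 2L)
  expect_true(is.na(gr$r[2L]))
  expect_error(geometric_reference(norm_matrix(c(0, 0), c(0, 0))),
               "zero coverage")
})

test_that("single-pair RMSD reduces to the absolute deviation", {
  set.seed(4)
  m <- matrix(runif(12), 4, 3)
  r <- runif(4)
  expect_equal(rmsd_deviations(m, r), sqrt((m - r)^2))
  expect_equal(rmsd_deviations(m, m[, 1L])[, 1L], rep(0, 4))
  expect_equal(unname(rmsd_deviations(matrix(r + 0.05, 4, 1), r)[, 1L]),
               rep(0.05, 4))
})

test_that("Tukey fence uses linear-interpolation quartiles", {
  expect_equal(outlier_threshold(1:8), 6.25 + 1.5 * 3.5)  # Q3=6.25, IQR=3.5
  expect_equal(outlier_threshold(rep(3, 10)), 3)          # IQR=0 -> T=c
  expect_error(outlier_threshold(1:3), "at least 4")
  set.seed(9)
  d <- rexp(500, 10)
  T_ <- outlier_threshold(d)
  expect_gt(T_, stats::quantile(d, 0.75))
  expect_lt(T_, max(d))
})

test_that("segmentation weights are scaled inverse variances with floors", {
  # rows with variances exactly 1, 2, 4
  m <- rbind(c(-1, 0, 1), c(-1, 0, 1) * sqrt(2), c(-1, 0, 1) * 2)
  sw <- segmentation_weights(m)
  expect_equal(sw$variance, c(1, 2, 4))
  expect_equal(sw$w, c(1, 1/3, 0.01), tolerance = 1e-12)
  # equal variances: degenerate scaling, all weights 1
  expect_equal(segmentation_weights(rbind(c(-1, 1), c(0, 2)))$w, c(1, 1))
  # monotone: larger control variance never gets a larger weight
  set.seed(5)
  mm <- matrix(rnorm(40 * 4, 10), 40, 4)
  sw <- segmentation_weights(mm)
  o <- order(sw$variance)
  expect_true(all(diff(sw$w[o]) <= 1e-12))
})

test_that("weights are invariant to a common scaling of all controls", {
  sp <- sim_panel(n_genes = 4, regions_per_gene = 5, seed = 21)
  ctl <- simulate_controls(sp, n_samples = 4, mean_depth = 500, seed = 21)
  m1 <- normalize_counts(ctl)
  # scaling counts and totals together leaves normalized values unchanged
  m3 <- umi_count_matrix(sp$panel, ctl$counts * 3L, totals = ctl$totals * 3,
                         sample_ids = ctl$sample_ids)
  m3 <- normalize_counts(m3)
  expect_equal(segmentation_weights(m1$norm)$w,
               segmentation_weights(m3$norm)$w, tolerance = 1e-12)
})

test_that("identical controls pass all filters untouched", {
  panel <- tiny_panel()
  x <- c(5, 8, 13, 21, 34, 55, 89, 144, 233) * 10L
  m <- assemble_matrix(lapply(1:3, function(i) {
    make_col(panel, x, id = paste0("c", i))
  }))
  ref <- build_reference(m)
  expect_equal(nrow(ref$excluded_samples), 0L)
  expect_equal(nrow(ref$excluded_regions), 0L)
  expect_equal(ref$threshold, 0)
  expect_equal(ref$weights, rep(1, 9))     # zero variance everywhere
  expect_equal(ref$r, x / sum(x))
})

test_that("a corrupted control is excluded and the baseline rebuilt", {
  sp <- sim_panel(n_genes = 8, regions_per_gene = 8, seed = 31)
  ctl <- simulate_controls(sp, n_samples = 5, mean_depth = 1000, seed = 31)
  bad <- ctl$counts[, 3L]
  idx <- seq_len(round(0.4 * length(bad)))      # 40% of regions scaled 3x
  bad[idx] <- bad[idx] * 3L
  # corrupted counts, totals left at the clean value: the excess is regional
  m <- umi_count_matrix(sp$panel,
                        cbind(ctl$counts[, 1:2], bad, ctl$counts[, 4:5]),
                        totals = ctl$totals,
                        sample_ids = c("c1", "c2", "corrupt", "c4", "c5"))
  ref <- build_reference(m)
  expect_equal(ref$excluded_samples$sample, "corrupt")
  expect_equal(ref$n_controls, 4L)
  # baseline is rebuilt without the corrupted column: on clean regions it
  # matches the 4-control geometric mean
  clean <- normalize_counts(umi_count_matrix(
    sp$panel, ctl$counts[, c(1, 2, 4, 5)],
    totals = ctl$totals[c(1, 2, 4, 5)], sample_ids = paste0("k", 1:4)))
  gm4 <- geometric_reference(clean$norm)$r
  keep <- ref$retained
  expect_equal(ref$r[keep], gm4[keep], tolerance = 1e-12)
})

test_that("a region noisy in most controls is excluded", {
  panel <- tiny_panel()
  set.seed(6)
  base <- matrix(rep(c(100, 110, 120, 130, 140, 150, 160, 170, 180), 5),
                 ncol = 5) + matrix(rpois(45, 3), ncol = 5)
  totals <- colSums(base)
  base[4L, c(1, 2, 3)] <- base[4L, c(1, 2, 3)] * 5L   # blown up in 3/5
  m <- assemble_matrix(lapply(1:5, function(i) {
    make_col(panel, base[, i], total = totals[i], id = paste0("c", i))
  }))
  ref <- build_reference(m)
  expect_true(4L %in% ref$excluded_regions$index)
  expect_equal(nrow(ref$excluded_samples), 0L)
  expect_false(ref$retained[4L])
  expect_true(is.na(ref$weights[4L]))
})

test_that("sample exclusion is independent of input column order", {
  sp <- sim_panel(n_genes = 6, regions_per_gene = 6, seed = 13)
  ctl <- simulate_controls(sp, n_samples = 4, mean_depth = 800, seed = 13)
  bad <- as.integer(ctl$counts[, 2L] * c(3, 1)[1 + (seq_len(36) %% 2)])
  build <- function(perm) {
    cts <- cbind(ctl$counts[, 1L], bad, ctl$counts[, 3:4])[, perm]
    ids <- c("a", "corrupt", "c", "d")[perm]
    m <- umi_count_matrix(sp$panel, cts, totals = ctl$totals[perm],
                          sample_ids = ids)
    build_reference(m)
  }
  r1 <- build(1:4)
  r2 <- build(c(3, 2, 4, 1))
  expect_equal(r1$excluded_samples$sample, "corrupt")
  expect_equal(r2$excluded_samples$sample, "corrupt")
  expect_equal(r1$r, r2$r)
})

test_that("reference bundles round-trip through disk", {
  sp <- sim_panel(n_genes = 5, regions_per_gene = 6, seed = 41)
  ctl <- simulate_controls(sp, n_samples = 5, mean_depth = 500, seed = 41)
  ref <- build_reference(ctl)
  dir <- tempfile()
  write_reference(ref, dir)
  back <- read_reference(dir)
  expect_equal(back$r, ref$r)
  expect_equal(back$weights, ref$weights)
  expect_equal(back$retained, ref$retained)
  expect_equal(back$threshold, ref$threshold)
  expect_equal(back$panel_md5, ref$panel_md5)
  expect_equal(back$excluded_regions$index, ref$excluded_regions$index)
})
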