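# build a segments object directly from member-value vectors
make_segments <- function(members, genes = sprintf("g%02d",
                                                   seq_along(members))) {
  first <- cumsum(c(1L, head(lengths(members), -1L)))
  tab <- data.frame(
    gene = genes, chrom = "chrS",
    start = 0L, end = 1L,
    first = first, last = first + lengths(members) - 1L,
    n_regions = lengths(members),
    seg_mean = vapply(members, mean, 0),
    flags = "", stringsAsFactors = FALSE)
  structure(list(table = tab, members = members, sample_id = "t",
                 params = seg_params()),
            class = "umicna_segments")
}

test_that("segment t-test matches the closed form and assigns status", {
  v <- c(0.55, 0.60, 0.58, 0.62, 0.57)
  calls <- test_segments(make_segments(list(v)))
  t_ref <- mean(v) / (sd(v) / sqrt(5))
  expect_equal(calls$table$t_statistic, t_ref, tolerance = 1e-12)
  expect_lt(calls$table$p_value, 1e-4)
  expect_equal(calls$table$status, "gain")

  zero <- test_segments(make_segments(list(rep(0, 6))))
  expect_equal(zero$table$status, "normal")
  expect_equal(zero$table$p_value, 1)
})

test_that("degenerate segments get the documented conventions", {
  calls <- test_segments(make_segments(list(rep(0.4, 5), 0.9)))
  expect_equal(calls$table$p_value[1L], 0)       # zero variance, mean != 0
  expect_match(calls$table$flags[1L], "zero-variance")
  expect_equal(calls$table$status[1L], "gain")
  expect_equal(calls$table$status[2L], "untested")  # single region
  expect_true(is.na(calls$table$q_value[2L]))
})

test_that("status direction is correct with untested segments interleaved", {
  # single-region (untested) segments must not shift the gain/loss signs
  set.seed(70)
  members <- list(rep(0.5, 6) + rnorm(6, 0, 0.01), 0.2,
                  rep(-0.5, 6) + rnorm(6, 0, 0.01), -0.1,
                  rnorm(6, 0, 0.01))
  calls <- test_segments(make_segments(members))
  expect_equal(calls$table$status,
               c("gain", "untested", "loss", "untested", "normal"))
})

test_that("BH keeps q monotone in p and never adds calls", {
  set.seed(71)
  for (rep in 1:20) {
    members <- replicate(15, rnorm(sample(3:10, 1), 0, 0.2),
                         simplify = FALSE)
    members[[1L]] <- rnorm(8, 0.8, 0.1)
    calls <- test_segments(make_segments(members))
    tab <- calls$table
    expect_true(all(tab$q_value >= tab$p_value - 1e-12, na.rm = TRUE))
    expect_lte(sum(tab$q_value < 0.05, na.rm = TRUE),
               sum(tab$p_value < 0.05, na.rm = TRUE))
    o <- order(tab$p_value)
    expect_true(all(diff(tab$q_value[o]) >= -1e-12))
  }
})

test_that("FDR control: one true gain among nulls is kept, few false calls", {
  set.seed(72)
  n_false <- 0L; n_true <- 0L; reps <- 200L
  for (rep in seq_len(reps)) {
    members <- replicate(20, rnorm(6, 0, 0.1), simplify = FALSE)
    members[[7L]] <- rnorm(6, 0.6, 0.1)
    calls <- test_segments(make_segments(members))
    st <- calls$table$status
    n_true <- n_true + (st[7L] == "gain")
    n_false <- n_false + sum(st[-7L] != "normal")
  }
  expect_gte(n_true / reps, 0.95)
  # false discoveries stay near the nominal FDR among ~1 call per repeat
  expect_lte(n_false / reps, 0.05 * 2)
})

test_that("purity inversion reproduces the single-copy identities", {
  # pure tumor: gain of one copy -> log2(3/2), c = 1
  calls <- test_segments(make_segments(list(
    rep(log2(3/2), 8) + c(-1, 1) * 1e-12)))
  pur <- estimate_purity(calls)
  expect_equal(pur$c_gain, 1, tolerance = 1e-9)
  expect_equal(pur$c_mean, pur$c_gain)
  expect_true(is.na(pur$c_del))
  # pure tumor: loss of one copy -> log2(1/2) = -1, c = 1
  calls <- test_segments(make_segments(list(rep(-1, 8) + c(-1, 1) * 1e-12)))
  expect_equal(estimate_purity(calls)$c_del, 1, tolerance = 1e-9)
  # half tumor fraction
  g <- test_segments(make_segments(list(rep(log2(1.25), 8) + c(-1, 1) * 1e-12)))
  expect_equal(estimate_purity(g)$c_gain, 0.5, tolerance = 1e-9)
  d <- test_segments(make_segments(list(rep(log2(0.75), 8) + c(-1, 1) * 1e-12)))
  expect_equal(estimate_purity(d)$c_del, 0.5, tolerance = 1e-9)
})

test_that("forward mixture / inverse purity round-trip is exact", {
  for (c_star in seq(0.1, 1, by = 0.1)) {
    expect_equal(purity_from_logratio(expected_log_ratio(c_star, 3), "gain"),
                 c_star, tolerance = 1e-10)
    expect_equal(purity_from_logratio(expected_log_ratio(c_star, 1), "loss"),
                 c_star, tolerance = 1e-10)
  }
})

test_that("multi-copy events clamp the estimate with a flag", {
  calls <- test_segments(make_segments(list(rep(1, 8) + c(-1, 1) * 1e-9)))
  pur <- estimate_purity(calls)  # CN=4 pure: raw c = 2
  expect_equal(pur$c_gain, 1)
  expect_true(pur$clamped)
})

test_that("no significant segments yields an undefined estimate", {
  set.seed(73)
  calls <- test_segments(make_segments(replicate(5, rnorm(6, 0, 0.3),
                                                 simplify = FALSE)))
  pur <- estimate_purity(calls)
  expect_true(is.na(pur$c_mean) ||
                pur$n_gain_segments + pur$n_del_segments > 0)
})

test_that("gain and loss estimates agree on a dual-event synthetic tumor", {
  sp <- sim_panel(seed = 81)
  ctl <- simulate_controls(sp, dispersion = 200, seed = 81)
  ref <- build_reference(ctl)
  tr <- sim_truth(sp, list(gene_05 = 3, gene_15 = 1), tumor_fraction = 0.6)
  tum <- simulate_tumor(sp, tr, dispersion = 200, seed = 82)
  fit <- cnv_call(tum, ref, params = seg_params(n_perm = 2000))
  expect_lt(abs(fit$purity$c_gain - fit$purity$c_del), 0.15)
  expect_lt(abs(fit$purity$c_mean - 0.6), 0.1)
})

test_that("reports round-trip through CSV", {
  sp <- sim_panel(n_genes = 3, regions_per_gene = 8, seed = 91)
  ctl <- simulate_controls(sp, n_samples = 3, seed = 91)
  ref <- build_reference(ctl)
  tr <- sim_truth(sp, list(gene_02 = 0), tumor_fraction = 1)
  tum <- simulate_tumor(sp, tr, seed = 92, sample_id = "rt")
  fit <- cnv_call(tum, ref, params = seg_params(n_perm = 500))
  dir <- tempfile()
  paths <- write_report(fit, dir, plot_format = "none")
  rep_ <- read_report(paths[["csv"]])
  expect_equal(nrow(rep_$table), nrow(fit$calls$table))
  expect_equal(rep_$table$seg_mean, fit$calls$table$seg_mean,
               tolerance = 1e-12)
  expect_equal(rep_$table$status, fit$calls$table$status)
  expect_equal(rep_$meta$c_mean, fit$purity$c_mean, tolerance = 1e-12)

  # empty call table still writes a parseable header-only CSV
  empty <- fit
  empty$calls$table <- fit$calls$table[0L, ]
  empty$calls$members <- list()
  p2 <- write_report(empty, tempfile(), plot_format = "none")
  rep2 <- read_report(p2[["csv"]])
  expect_equal(nrow(rep2$table), 0L)
})

test_that("model accessor methods are coherent", {
  sp <- sim_panel(n_genes = 3, regions_per_gene = 8, seed = 95)
  ctl <- simulate_controls(sp, n_samples = 3, seed = 95)
  ref <- build_reference(ctl)
  tum <- simulate_tumor(sp, sim_truth(sp, list(gene_01 = 4), 1), seed = 96)
  fit <- cnv_call(tum, ref, params = seg_params(n_perm = 500))
  expect_equal(length(coef(fit)), nrow(fit$calls$table))
  f <- fitted(fit); r <- residuals(fit)
  ok <- is.finite(fit$profile$l)
  expect_equal(fit$profile$l[ok], (f + r)[ok], tolerance = 1e-12)
  expect_output(print(fit), "CNA calls")
  expect_output(print(summary(fit)), "Significant segments|No significant")
})
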