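#' Geometric-mean baseline over control samples
#'
#' Computes, region by region, the geometric mean of the normalized control
#' values (`counts/U`), giving the pseudo-reference vector. Regions where any
#' control has a zero count are flagged: in a deep targeted control a zero
#' indicates assay failure, and the geometric mean is undefined at zero, so
#' these regions are excluded from the baseline rather than pseudocounted.
#'
#' @param norm Matrix of normalized control values, regions x samples.
#' @return List with `r` (baseline, `NA` on zero-coverage regions) and
#'   `zero_regions` (indices with at least one zero control value).
#' @export
geometric_reference <- function(norm) {
  stopifnot(is.matrix(norm), ncol(norm) >= 2L)
  zero_regions <- which(apply(norm <= 0, 1L, any))
  if (length(zero_regions) == nrow(norm)) {
    stop("all regions have zero coverage in at least one control")
  }
  r <- rep(NA_real_, nrow(norm))
  ok <- setdiff(seq_len(nrow(norm)), zero_regions)
  r[ok] <- exp(rowMeans(log(norm[ok, , drop = FALSE])))
  list(r = r, zero_regions = zero_regions)
}

#' Per-region, per-sample deviation from the baseline
#'
#' The root-mean-square deviation between a single control value and the
#' baseline at one region reduces to the absolute deviation
#' `|x[p, s] - r[p]|`.
#'
#' @param norm Normalized control matrix.
#' @param r Baseline vector from [geometric_reference()].
#' @return Matrix of deviations, `NA` where `r` is `NA`.
#' @export
rmsd_deviations <- function(norm, r) {
  stopifnot(is.matrix(norm), length(r) == nrow(norm))
  abs(norm - r)
}

#' Tukey-fence outlier threshold for pooled deviations
#'
#' `T = Q3 + 1.5 * IQR` over the pooled distribution of all (region, sample)
#' deviations of the control set, with linear-interpolation quartiles
#' (`stats::quantile` type 7).
#'
#' @param deviations Numeric deviations (matrix or vector; `NA` dropped).
#' @return The scalar threshold T.
#' @export
outlier_threshold <- function(deviations) {
  d <- as.numeric(deviations)
  d <- d[!is.na(d)]
  if (length(d) < 4L) stop("need at least 4 deviation values to set T")
  q <- stats::quantile(d, c(0.25, 0.75), type = 7, names = FALSE)
  q[2L] + 1.5 * (q[2L] - q[1L])
}

# numerical guard: the exp(mean(log .)) round trip leaves ~1 ulp of error,
# which would register as a "deviation" on perfectly concordant controls;
# anything below ~1e-12 relative is identically zero for filtering purposes
dev_floor <- function(dev, r) {
  dev[dev <= abs(r) * 1e-12] <- 0
  dev
}

#' Inverse-variance segmentation weights
#'
#' Per-region weights for segmentation: the reciprocal of the control-sample
#' variance of the normalized values (denominator S-1), min-max scaled to
#' `[0, 1]`. The variance is floored at `eps` and the scaled weight at
#' `w_min` so that even the noisiest retained region keeps a small positive
#' influence instead of being silently deleted. With equal variances the
#' scaling is degenerate and all weights are 1.
#'
#' @param norm Normalized control matrix restricted to retained samples.
#' @param eps Variance floor (default 1e-12).
#' @param w_min Weight floor after scaling (default 0.01).
#' @return List with `w` (scaled weights) and `variance` (per-region).
#' @export
segmentation_weights <- function(norm, eps = 1e-12, w_min = 0.01) {
  stopifnot(is.matrix(norm), ncol(norm) >= 2L)
  v <- apply(norm, 1L, stats::var)
  w_raw <- 1 / pmax(v, eps)
  rng <- range(w_raw)
  w <- if (rng[2L] == rng[1L]) rep(1, length(w_raw)) else {
    pmax((w_raw - rng[1L]) / (rng[2L] - rng[1L]), w_min)
  }
  list(w = w, variance = v)
}

#' Build a filtered pseudo-reference from control samples
#'
#' The control baseline is the per-region geometric mean of normalized
#' control values. Outliers are then excluded in two passes mirroring the
#' construction narrative: (1) samples whose fraction of regions with
#' deviation above the Tukey fence `T` is at least `sample_frac` are dropped
#' and, if any were, the baseline, deviations and `T` are recomputed from
#' the passing samples; (2) regions with deviation above the (recomputed)
#' `T` in at least `region_frac` of the retained controls are excluded.
#' Segmentation weights are finally derived from the retained controls on
#' retained regions.
#'
#' @param m A `umi_counts` matrix of >= 2 control samples (raw or already
#'   normalized).
#' @param sample_frac Sample exclusion fraction (default 0.20).
#' @param region_frac Region exclusion fraction (default 0.50).
#' @return A `umicna_reference` object.
#' @export
build_reference <- function(m, sample_frac = 0.20, region_frac = 0.50) {
  stopifnot(inherits(m, "umi_counts"))
  if (ncol(m$counts) < 2L) {
    stop("pseudo-reference construction needs at least 2 control samples")
  }
  if (!isTRUE(m$normalized)) m <- normalize_counts(m)
  norm <- m$norm
  P <- nrow(norm)

  gr <- geometric_reference(norm)
  excluded_regions <- data.frame(index = gr$zero_regions,
                                 reason = rep("zero-coverage",
                                              length(gr$zero_regions)),
                                 stringsAsFactors = FALSE)
  retained_regions <- setdiff(seq_len(P), gr$zero_regions)

  dev <- dev_floor(rmsd_deviations(norm, gr$r), gr$r)
  T_val <- outlier_threshold(dev[retained_regions, , drop = FALSE])
  frac_bad <- colMeans(dev[retained_regions, , drop = FALSE] > T_val)
  bad_samples <- which(frac_bad >= sample_frac)
  if (length(bad_samples) == ncol(norm)) {
    stop("every control sample failed the RMSD filter; ",
         "supply more or more concordant controls")
  }
  keep_samples <- setdiff(seq_len(ncol(norm)), bad_samples)
  excluded_samples <- data.frame(
    sample = m$sample_ids[bad_samples],
    reason = rep(sprintf(">=%.0f%% regions with RMSD > T",
                         100 * sample_frac), length(bad_samples)),
    stringsAsFactors = FALSE)

  if (length(bad_samples)) {
    if (length(keep_samples) < 2L) {
      stop("fewer than 2 control samples remain after the RMSD filter; ",
           "supply more or more concordant controls")
    }
    norm_kept <- norm[, keep_samples, drop = FALSE]
    gr <- geometric_reference(norm_kept)
    new_zero <- setdiff(gr$zero_regions, excluded_regions$index)
    if (length(new_zero)) {
      excluded_regions <- rbind(excluded_regions,
                                data.frame(index = new_zero,
                                           reason = "zero-coverage",
                                           stringsAsFactors = FALSE))
    }
    retained_regions <- setdiff(seq_len(P), excluded_regions$index)
    dev <- dev_floor(rmsd_deviations(norm_kept, gr$r), gr$r)
    T_val <- outlier_threshold(dev[retained_regions, , drop = FALSE])
  } else {
    norm_kept <- norm
  }

  frac_noisy <- rowMeans(dev > T_val)
  noisy <- setdiff(which(frac_noisy >= region_frac), excluded_regions$index)
  if (length(noisy)) {
    excluded_regions <- rbind(excluded_regions,
                              data.frame(index = noisy,
                                         reason = sprintf(
                                           "RMSD > T in >=%.0f%% of controls",
                                           100 * region_frac),
                                         stringsAsFactors = FALSE))
  }
  retained_regions <- setdiff(seq_len(P), excluded_regions$index)
  if (length(retained_regions) == 0L) stop("no regions survive the filters")

  r <- rep(NA_real_, P)
  r[retained_regions] <- gr$r[retained_regions]
  sw <- segmentation_weights(norm_kept[retained_regions, , drop = FALSE])
  weights <- rep(NA_real_, P)
  weights[retained_regions] <- sw$w
  variance <- rep(NA_real_, P)
  variance[retained_regions] <- sw$variance

  excluded_regions <- excluded_regions[order(excluded_regions$index), ,
                                       drop = FALSE]
  rownames(excluded_regions) <- NULL
  structure(list(panel = m$panel, r = r, weights = weights,
                 control_variance = variance,
                 retained = seq_len(P) %in% retained_regions,
                 excluded_regions = excluded_regions,
                 excluded_samples = excluded_samples,
                 threshold = T_val,
                 n_controls = length(keep_samples),
                 control_ids = m$sample_ids[keep_samples],
                 params = list(sample_frac = sample_frac,
                               region_frac = region_frac),
                 panel_md5 = panel_hash(m$panel)),
            class = "umicna_reference")
}

#' @export
print.umicna_reference <- function(x, ...) {
  cat("Pseudo-reference over", x$n_controls, "control samples\n")
  cat("  regions:", sum(x$retained), "retained /",
      length(x$retained), "total",
      sprintf("(%d excluded)\n", nrow(x$excluded_regions)))
  if (nrow(x$excluded_samples)) {
    cat("  excluded controls:",
        paste(x$excluded_samples$sample, collapse = ", "), "\n")
  }
  cat("  RMSD threshold T:", format(x$threshold, digits = 4), "\n")
  invisible(x)
}

#' Serialize a pseudo-reference bundle to a directory
#'
#' Writes `reference.tsv` (per-region baseline, variance, weight, exclusion
#' flag and reason) and `meta.json` (thresholds, excluded samples, panel
#' fingerprint, package version). [read_reference()] restores the bundle.
#'
#' @param ref A `umicna_reference`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference <- function(ref, dir) {
  stopifnot(inherits(ref, "umicna_reference"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reg <- ref$panel$regions
  reason <- rep("", nrow(reg))
  reason[ref$excluded_regions$index] <- ref$excluded_regions$reason
  df <- data.frame(chrom = reg$chrom, start = reg$start, end = reg$end,
                   gene = reg$gene, r = ref$r, variance = ref$control_variance,
                   weight = ref$weights, excluded = !ref$retained,
                   reason = reason, stringsAsFactors = FALSE)
  utils::write.table(df, file.path(dir, "reference.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- list(threshold = ref$threshold,
               sample_frac = ref$params$sample_frac,
               region_frac = ref$params$region_frac,
               n_controls = ref$n_controls,
               control_ids = as.list(ref$control_ids),
               excluded_samples = ref$excluded_samples,
               panel_md5 = ref$panel_md5,
               package_version = as.character(
                 utils::packageVersion("umicna")))
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a pseudo-reference bundle written by [write_reference()]
#'
#' @param dir Bundle directory.
#' @return A `umicna_reference`.
#' @export
read_reference <- function(dir) {
  tsv <- file.path(dir, "reference.tsv")
  mj <- file.path(dir, "meta.json")
  if (!file.exists(tsv) || !file.exists(mj)) {
    stop("not a reference bundle (missing reference.tsv/meta.json): ", dir)
  }
  df <- utils::read.table(tsv, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(mj, simplifyVector = TRUE)
  bed <- tempfile(fileext = ".bed")
  on.exit(unlink(bed))
  writeLines(paste(df$chrom, df$start, df$end, df$gene, sep = "\t"), bed)
  panel <- read_panel(bed)
  excl <- data.frame(index = which(df$excluded),
                     reason = df$reason[df$excluded],
                     stringsAsFactors = FALSE)
  exs <- meta$excluded_samples
  if (is.null(exs) || length(exs) == 0L) {
    exs <- data.frame(sample = character(0), reason = character(0))
  }
  structure(list(panel = panel, r = df$r, weights = df$weight,
                 control_variance = df$variance,
                 retained = !df$excluded,
                 excluded_regions = excl,
                 excluded_samples = as.data.frame(exs),
                 threshold = meta$threshold,
                 n_controls = meta$n_controls,
                 control_ids = unlist(meta$control_ids),
                 params = list(sample_frac = meta$sample_frac,
                               region_frac = meta$region_frac),
                 panel_md5 = meta$panel_md5),
            class = "umicna_reference")
}
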