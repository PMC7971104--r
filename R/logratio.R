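#' Per-region log2 ratios of a tumor sample against the pseudo-reference
#'
#' `l[p] = log2(x[p] / r[p])` where `x` is the tumor sample's normalized
#' UMI fraction (`counts/U`) and `r` the pseudo-reference baseline. Regions
#' excluded by the reference filters are carried as `NA`. A tumor count of
#' zero is informative (homozygous deletion), so such regions receive a
#' half-count pseudocount `0.5/U` rather than being dropped, and are
#' flagged.
#'
#' @param tumor A `umi_counts_col` for the tumor sample.
#' @param reference A [build_reference()] result on the same panel.
#' @return A `umicna_profile` object: `l` (log-ratios, `NA` on excluded
#'   regions), `shift` (0 until centered), `zero_regions`, `sample_id`,
#'   `panel`, and later `mixture` once centered.
#' @export
log_ratios <- function(tumor, reference) {
  stopifnot(inherits(tumor, "umi_counts_col"),
            inherits(reference, "umicna_reference"))
  if (panel_hash(tumor$panel) != reference$panel_md5) {
    stop("tumor counts and reference were built on different panels")
  }
  if (tumor$total <= 0) stop("tumor sample has zero total UMI count")
  x <- tumor$counts / tumor$total
  zero_regions <- which(tumor$counts == 0 & reference$retained)
  x[zero_regions] <- 0.5 / tumor$total
  l <- rep(NA_real_, length(x))
  keep <- reference$retained
  l[keep] <- log2(x[keep] / reference$r[keep])
  structure(list(panel = tumor$panel, sample_id = tumor$sample_id,
                 l = l, shift = 0, centered = FALSE,
                 zero_regions = zero_regions, mixture = NULL,
                 reference_md5 = reference$panel_md5),
            class = "umicna_profile")
}

#' Fit a 1-3 component Gaussian mixture to log-ratios
#'
#' Model-based clustering of the finite log-ratio values with one to three
#' univariate Gaussian components with free variances, the number of
#' components chosen by BIC (via \pkg{mclust}). The component whose mean is
#' closest to 0 is taken as the diploid component (ties broken toward the
#' larger mixing proportion). mclust's hierarchical initialization is
#' deterministic, so repeated fits on the same data are identical.
#'
#' Degenerate inputs (fewer than `kmax` distinct values, or a component
#' standard deviation collapsing below `sd_floor`) are handled by flooring
#' the standard deviation and flagging the fit.
#'
#' @param l Numeric log-ratio values (`NA` ignored; >= 10 finite values
#'   required).
#' @param kmax Maximum number of components (default 3).
#' @param sd_floor Lower bound on component standard deviations
#'   (default 1e-6).
#' @return A `umicna_mixture` list: `k`, `means`, `sds`, `pro`, `selected`,
#'   `bic` (per fitted k), `degenerate`.
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_mixture <- function(l, kmax = 3L, sd_floor = 1e-6) {
  x <- l[is.finite(l)]
  if (length(x) < 10L) {
    stop("need at least 10 finite log-ratio values to fit the mixture")
  }
  if (stats::sd(x) < sd_floor || length(unique(x)) < 2L) {
    # constant signal: single degenerate component
    return(structure(list(k = 1L, means = mean(x), sds = sd_floor,
                          pro = 1, selected = 1L, bic = NA_real_,
                          degenerate = TRUE),
                     class = "umicna_mixture"))
  }
  fit <- mclust::Mclust(x, G = seq_len(kmax), modelNames = "V",
                        verbose = FALSE)
  if (is.null(fit)) {
    return(structure(list(k = 1L, means = mean(x),
                          sds = max(stats::sd(x), sd_floor), pro = 1,
                          selected = 1L, bic = NA_real_, degenerate = TRUE),
                     class = "umicna_mixture"))
  }
  means <- as.numeric(fit$parameters$mean)
  sds <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
  if (length(sds) == 1L) sds <- rep(sds, fit$G)
  pro <- as.numeric(fit$parameters$pro)
  degenerate <- any(sds < sd_floor)
  sds <- pmax(sds, sd_floor)
  # diploid component: |mean| minimal, ties to the larger mixing proportion
  cand <- which(abs(means) == min(abs(means)))
  selected <- cand[which.max(pro[cand])]
  structure(list(k = fit$G, means = means, sds = sds, pro = pro,
                 selected = selected,
                 bic = fit$BIC[, 1L], degenerate = degenerate),
            class = "umicna_mixture")
}

#' @export
print.umicna_mixture <- function(x, ...) {
  cat("Gaussian mixture, k =", x$k, "\n")
  for (i in seq_len(x$k)) {
    cat(sprintf("  %scomponent %d: mean %+.4f, sd %.4f, pro %.3f\n",
                if (i == x$selected) "*" else " ", i,
                x$means[i], x$sds[i], x$pro[i]))
  }
  invisible(x)
}

#' Center a log-ratio profile on its diploid mixture component
#'
#' Under the assumption that the mixture component closest to 0 is the
#' diploid state, subtracts that component's mean from every log-ratio, so
#' diploid regions sit at 0. Centering can be disabled (`enabled = FALSE`),
#' in which case the profile is returned unchanged with `shift = 0`
#' recorded.
#'
#' @param profile A [log_ratios()] result.
#' @param mixture Optional pre-fitted [fit_mixture()] result; fitted from
#'   the profile when `NULL`.
#' @param enabled Apply the centering (default `TRUE`).
#' @return The centered `umicna_profile` (with `shift` and `mixture`
#'   recorded).
#' @export
center_profile <- function(profile, mixture = NULL, enabled = TRUE) {
  stopifnot(inherits(profile, "umicna_profile"))
  if (!enabled) {
    profile$shift <- 0
    profile$centered <- TRUE
    return(profile)
  }
  if (is.null(mixture)) mixture <- fit_mixture(profile$l)
  stopifnot(inherits(mixture, "umicna_mixture"))
  shift <- mixture$means[mixture$selected]
  profile$l <- profile$l - shift
  profile$shift <- shift
  profile$mixture <- mixture
  profile$centered <- TRUE
  profile
}

#' @export
print.umicna_profile <- function(x, ...) {
  cat("Log-ratio profile for sample", x$sample_id, "\n")
  cat("  regions:", sum(is.finite(x$l)), "with log-ratios,",
      sum(is.na(x$l)), "excluded\n")
  cat("  centered:", x$centered,
      if (x$centered) sprintf("(shift %+.4f)", x$shift) else "", "\n")
  invisible(x)
}

#' Write a per-region log-ratio table as TSV
#'
#' @param profile A centered (or raw) `umicna_profile`.
#' @param raw Optional uncentered profile supplying the `l_raw` column.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_logratios <- function(profile, path, raw = NULL) {
  reg <- profile$panel$regions
  flags <- rep("", nrow(reg))
  flags[profile$zero_regions] <- "zero-count"
  flags[is.na(profile$l)] <- "excluded"
  df <- data.frame(chrom = reg$chrom, start = reg$start, end = reg$end,
                   gene = reg$gene,
                   l_raw = if (is.null(raw)) profile$l + profile$shift
                           else raw$l,
                   l_centered = profile$l, flags = flags,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
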