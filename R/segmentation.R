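#' Segmentation parameters
#'
#' Tuning parameters of the weighted circular binary segmentation.
#'
#' @param alpha Split significance level on the permutation p-value
#'   (default 0.01).
#' @param n_perm Number of permutations per split test (default 10000; a
#'   sequential early stop abandons a test as soon as the exceedance count
#'   already forces p > alpha).
#' @param min_width Minimum number of regions per segment (default 2).
#' @param undo_sd Merge adjacent segments whose weighted-mean difference is
#'   below `undo_sd` pooled weighted residual SDs (default 1.0).
#' @param seed Base RNG seed; each (sample, gene) segmentation derives its
#'   own stream so results do not depend on gene processing order
#'   (default 17).
#' @return A `seg_params` list.
#' @export
seg_params <- function(alpha = 0.01, n_perm = 10000L, min_width = 2L,
                       undo_sd = 1.0, seed = 17L) {
  stopifnot(alpha > 0, alpha < 1, n_perm >= 1, min_width >= 1, undo_sd >= 0)
  structure(list(alpha = alpha, n_perm = as.integer(n_perm),
                 min_width = as.integer(min_width), undo_sd = undo_sd,
                 seed = as.integer(seed)),
            class = "seg_params")
}

weighted_mean <- function(x, w) sum(w * x) / sum(w)

# weighted residual SD about the current segment means
pooled_weighted_sd <- function(x, w, bounds) {
  fitted <- numeric(length(x))
  for (k in seq_len(length(bounds) - 1L)) {
    idx <- (bounds[k] + 1L):bounds[k + 1L]
    fitted[idx] <- weighted_mean(x[idx], w[idx])
  }
  sqrt(sum(w * (x - fitted)^2) / sum(w))
}

# recursive split search; returns sorted boundary positions 0..n (absolute
# within the supplied vector)
cbs_boundaries <- function(x, w, params) {
  n <- length(x)
  if (n < 2L * params$min_width) return(c(0L, n))
  if (max(x) == min(x)) return(c(0L, n))  # no permutations on flat signal
  sp <- cbs_best_split_cpp(x, w, params$min_width, params$n_perm,
                           params$alpha)
  if (sp$p >= params$alpha) return(c(0L, n))
  cuts <- sort(unique(c(0L, sp$i, sp$j, n)))
  bounds <- 0L
  for (k in seq_len(length(cuts) - 1L)) {
    lo <- cuts[k]; hi <- cuts[k + 1L]
    sub <- cbs_boundaries(x[(lo + 1L):hi], w[(lo + 1L):hi], params)
    bounds <- c(bounds, lo + sub[-1L])
  }
  sort(unique(bounds))
}

# prune over-segmentation: merge neighbours whose weighted-mean difference
# is below undo_sd pooled weighted SDs
cbs_undo <- function(x, w, bounds, undo_sd) {
  if (undo_sd <= 0) return(bounds)
  repeat {
    k <- length(bounds) - 1L
    if (k < 2L) return(bounds)
    means <- vapply(seq_len(k), function(s) {
      idx <- (bounds[s] + 1L):bounds[s + 1L]
      weighted_mean(x[idx], w[idx])
    }, 0)
    sd_hat <- pooled_weighted_sd(x, w, bounds)
    diffs <- abs(diff(means))
    if (all(diffs >= undo_sd * sd_hat)) return(bounds)
    drop <- which.min(diffs) + 1L  # boundary between the closest pair
    bounds <- bounds[-drop]
  }
}

#' Segment one gene's log-ratio vector with weighted CBS
#'
#' Circular binary segmentation: the weighted two-sample t-statistic between
#' each circular arc and its complement is maximized, the maximal statistic
#' is tested by permuting the values while keeping the weights fixed to
#' their positions (the weights describe per-region assay variance, a
#' property of the position, not of the observation), and splitting recurses
#' while the permutation p-value is below `alpha`. Adjacent segments closer
#' than `undo_sd` pooled weighted SDs are merged back. Genes with fewer than
#' `2 * min_width` regions are returned as a single segment.
#'
#' @param v Numeric log-ratio vector of one gene's consecutive regions.
#' @param w Positive weights aligned with `v`.
#' @param params A [seg_params()] list.
#' @return A data.frame with one row per segment: `first`, `last` (1-based
#'   positions within `v`), `n_regions`, `seg_mean` (weighted mean).
#' @export
segment_gene <- function(v, w = rep(1, length(v)), params = seg_params()) {
  if (length(v) == 0L) stop("empty gene signal")
  stopifnot(length(v) == length(w), all(is.finite(v)), all(w > 0))
  bounds <- cbs_boundaries(v, w, params)
  bounds <- cbs_undo(v, w, bounds, params$undo_sd)
  k <- length(bounds) - 1L
  data.frame(
    first = bounds[-length(bounds)] + 1L,
    last = bounds[-1L],
    n_regions = diff(bounds),
    seg_mean = vapply(seq_len(k), function(s) {
      idx <- (bounds[s] + 1L):bounds[s + 1L]
      weighted_mean(v[idx], w[idx])
    }, 0)
  )
}

#' Segment every gene of a centered log-ratio profile
#'
#' Applies [segment_gene()] to each gene block of the panel, using the
#' reference's segmentation weights and skipping regions excluded by the
#' reference filters. Each (sample, gene) pair gets its own deterministic
#' RNG stream derived from `params$seed`, so the output is independent of
#' gene processing order. Genes reduced to a single retained region are
#' emitted as one-region segments and flagged (`short`); the recommended
#' minimum for a reliable call is 6 non-overlapping regions per gene.
#'
#' @param profile A centered `umicna_profile`.
#' @param reference The matching `umicna_reference`.
#' @param params A [seg_params()] list.
#' @return A `umicna_segments` object: data.frame with columns `gene`
#'   (block label), `chrom`, `start`, `end`, `first`, `last` (panel region
#'   indices), `n_regions`, `seg_mean`, `flags`, plus a `members` list of
#'   per-segment member log-ratio vectors.
#' @export
segment_sample <- function(profile, reference, params = seg_params()) {
  stopifnot(inherits(profile, "umicna_profile"),
            inherits(reference, "umicna_reference"))
  if (!isTRUE(profile$centered)) {
    warning("profile is not centered; segmenting raw log-ratios")
  }
  genes <- profile$panel$genes
  reg <- profile$panel$regions
  out <- list(); members <- list()
  for (g in seq_len(nrow(genes))) {
    idx <- genes$first[g]:genes$last[g]
    idx <- idx[reference$retained[idx] & is.finite(profile$l[idx])]
    if (length(idx) == 0L) next
    v <- profile$l[idx]
    w <- reference$weights[idx]
    seed_g <- (params$seed + 1009L * g) %% 2147483647L
    segs <- local({
      old <- save_rng()
      on.exit(restore_rng(old))
      set.seed(seed_g)
      segment_gene(v, w, params)
    })
    short_gene <- length(idx) < 6L
    for (s in seq_len(nrow(segs))) {
      pid <- idx[segs$first[s]:segs$last[s]]
      out[[length(out) + 1L]] <- data.frame(
        gene = genes$block[g],
        chrom = reg$chrom[pid[1L]],
        start = reg$start[pid[1L]],
        end = reg$end[pid[length(pid)]],
        first = pid[1L], last = pid[length(pid)],
        n_regions = segs$n_regions[s],
        seg_mean = segs$seg_mean[s],
        flags = paste(c(if (short_gene) "short-gene",
                        if (any(pid %in% profile$zero_regions))
                          "zero-count-member"),
                      collapse = ";"),
        stringsAsFactors = FALSE)
      members[[length(members) + 1L]] <- v[segs$first[s]:segs$last[s]]
    }
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  structure(list(table = df, members = members,
                 sample_id = profile$sample_id, params = params),
            class = "umicna_segments")
}

#' @export
print.umicna_segments <- function(x, ...) {
  cat("Segmentation of sample", x$sample_id, ":", nrow(x$table),
      "segments over", length(unique(x$table$gene)), "genes\n")
  invisible(x)
}
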