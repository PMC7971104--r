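#' Test segments against a log-ratio of zero and assign status
#'
#' Each segment with at least two member regions gets a two-sided one-sample
#' Student t-test of its member log-ratios against 0. p-values are adjusted
#' across all tested segments of the sample with the Benjamini-Hochberg
#' step-up procedure, and status is assigned from the adjusted values:
#' `gain` (q < alpha, mean > 0), `loss` (q < alpha, mean < 0), `normal`
#' otherwise; one-region segments are `untested`. A zero-variance segment
#' with nonzero mean is treated as p = 0 and flagged; with zero mean, p = 1.
#'
#' @param segments A [segment_sample()] result.
#' @param alpha FDR level on adjusted p-values (default 0.05).
#' @return A `umicna_calls` object: the segment table augmented with
#'   `t_statistic`, `p_value`, `q_value`, `status`, plus the member lists.
#' @export
test_segments <- function(segments, alpha = 0.05) {
  stopifnot(inherits(segments, "umicna_segments"), alpha > 0, alpha < 1)
  df <- segments$table
  n <- nrow(df)
  tval <- pval <- rep(NA_real_, n)
  flags <- df$flags
  for (s in seq_len(n)) {
    v <- segments$members[[s]]
    if (length(v) < 2L) next
    if (stats::sd(v) == 0) {
      pval[s] <- if (mean(v) == 0) 1 else 0
      tval[s] <- if (mean(v) == 0) 0 else Inf * sign(mean(v))
      if (mean(v) != 0) {
        flags[s] <- paste(c(flags[s][nzchar(flags[s])], "zero-variance"),
                          collapse = ";")
      }
      next
    }
    tt <- stats::t.test(v, mu = 0)
    tval[s] <- unname(tt$statistic)
    pval[s] <- tt$p.value
  }
  qval <- rep(NA_real_, n)
  tested <- !is.na(pval)
  qval[tested] <- stats::p.adjust(pval[tested], method = "BH")
  status <- rep("untested", n)
  status[tested] <- ifelse(qval[tested] < alpha,
                           ifelse(df$seg_mean[tested] > 0, "gain", "loss"),
                           "normal")
  df$t_statistic <- tval
  df$p_value <- pval
  df$q_value <- qval
  df$status <- status
  df$flags <- flags
  structure(list(table = df, members = segments$members,
                 sample_id = segments$sample_id, alpha = alpha),
            class = "umicna_calls")
}

#' Estimate tumor content from significant segments
#'
#' Assuming significant segments carry single-copy events and that observed
#' log-ratios mix tumor and normal signal as
#' `L = log2(c * CN/2 + (1 - c))`, two independent estimates of the tumor
#' fraction c are inverted from the mean log-ratio of the pooled member
#' regions of gain segments (`c = 2 (2^L - 1)`) and of loss segments
#' (`c = -2 (2^L - 1)`). The reported value is the mean of the available
#' estimates. Raw estimates above 1 arise from multi-copy events violating
#' the single-copy assumption; they are clamped to 1 and flagged.
#'
#' @param calls A [test_segments()] result.
#' @return A `umicna_purity` list: `c_gain`, `c_del`, `c_mean` (any of them
#'   `NA` when the corresponding side has no significant segments),
#'   `n_gain_segments`, `n_del_segments`, `clamped`.
#' @export
estimate_purity <- function(calls) {
  stopifnot(inherits(calls, "umicna_calls"))
  pool <- function(st) {
    idx <- which(calls$table$status == st)
    if (!length(idx)) return(NULL)
    unlist(calls$members[idx])
  }
  g <- pool("gain"); d <- pool("loss")
  clamped <- FALSE
  c_gain <- c_del <- NA_real_
  clamp01 <- function(v) {
    if (v > 1 || v < 0) clamped <<- TRUE
    min(max(v, 0), 1)
  }
  if (!is.null(g)) c_gain <- clamp01(2 * (2^mean(g) - 1))
  if (!is.null(d)) c_del <- clamp01(-2 * (2^mean(d) - 1))
  ests <- c(c_gain, c_del)
  c_mean <- if (all(is.na(ests))) NA_real_ else mean(ests, na.rm = TRUE)
  structure(list(c_gain = c_gain, c_del = c_del, c_mean = c_mean,
                 n_gain_segments = sum(calls$table$status == "gain"),
                 n_del_segments = sum(calls$table$status == "loss"),
                 clamped = clamped),
            class = "umicna_purity")
}

#' @export
print.umicna_purity <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.3f", v)
  cat("Tumor content estimate:", fmt(x$c_mean),
      sprintf("(gain side %s over %d segments, loss side %s over %d)\n",
              fmt(x$c_gain), x$n_gain_segments,
              fmt(x$c_del), x$n_del_segments))
  if (x$clamped) cat("  note: a raw estimate exceeded 1 and was clamped\n")
  invisible(x)
}

#' Call copy-number alterations in one tumor sample
#'
#' The main entry point: runs the full per-sample analysis against a built
#' pseudo-reference — normalization, per-region log2 ratios, Gaussian-mixture
#' diploid centering, weighted per-gene circular binary segmentation,
#' FDR-corrected per-segment t-tests, and tumor-content estimation.
#'
#' @param tumor A `umi_counts_col` for the tumor sample (from [count_umis()]
#'   or [read_counts()]).
#' @param reference A `umicna_reference` built on the same panel.
#' @param alpha FDR level for segment calls (default 0.05).
#' @param centering Center the log-ratios on the diploid mixture component
#'   (default `TRUE`).
#' @param params Segmentation parameters, see [seg_params()].
#' @return A `umicna_call` object with components `calls` (segment table),
#'   `profile` (centered log-ratio profile), `purity`, `reference_summary`,
#'   and supporting metadata. Methods: `print`, `summary`, `plot`, `coef`
#'   (segment means), `fitted` (per-region segment mean), `residuals`
#'   (log-ratio minus fitted segment mean).
#' @examples
#' sp <- sim_panel(n_genes = 6, regions_per_gene = 8, seed = 1)
#' ctl <- simulate_controls(sp, n_samples = 3, seed = 2)
#' ref <- build_reference(ctl)
#' tr <- sim_truth(sp, events = list(gene_3 = 0), tumor_fraction = 1)
#' tum <- simulate_tumor(sp, tr, seed = 3)
#' fit <- cnv_call(tum, ref, params = seg_params(n_perm = 500))
#' summary(fit)
#' @export
cnv_call <- function(tumor, reference, alpha = 0.05, centering = TRUE,
                     params = seg_params()) {
  stopifnot(inherits(tumor, "umi_counts_col"),
            inherits(reference, "umicna_reference"))
  raw <- log_ratios(tumor, reference)
  profile <- center_profile(raw, enabled = centering)
  segs <- segment_sample(profile, reference, params)
  calls <- test_segments(segs, alpha = alpha)
  purity <- estimate_purity(calls)
  structure(list(calls = calls, profile = profile, raw_profile = raw,
                 purity = purity, reference = reference,
                 sample_id = tumor$sample_id, alpha = alpha,
                 params = params, centering = centering),
            class = "umicna_call")
}

#' @export
print.umicna_call <- function(x, ...) {
  tab <- x$calls$table
  cat("CNA calls for sample", x$sample_id, "\n")
  cat(sprintf("  %d segments: %d gain, %d loss, %d normal, %d untested\n",
              nrow(tab), sum(tab$status == "gain"),
              sum(tab$status == "loss"), sum(tab$status == "normal"),
              sum(tab$status == "untested")))
  cat(sprintf("  centering shift: %+.4f\n", x$profile$shift))
  print(x$purity)
  invisible(x)
}

#' @export
summary.umicna_call <- function(object, ...) {
  tab <- object$calls$table
  hits <- tab[tab$status %in% c("gain", "loss"), , drop = FALSE]
  structure(list(sample_id = object$sample_id, n_segments = nrow(tab),
                 hits = hits, purity = object$purity,
                 shift = object$profile$shift, alpha = object$alpha),
            class = "summary.umicna_call")
}

#' @export
print.summary.umicna_call <- function(x, ...) {
  cat("Sample:", x$sample_id, " |  segments:", x$n_segments,
      " |  alpha:", x$alpha, "\n")
  cat(sprintf("Centering shift: %+.4f\n", x$shift))
  if (nrow(x$hits)) {
    cat("Significant segments:\n")
    print(x$hits[, c("gene", "chrom", "start", "end", "n_regions",
                     "seg_mean", "q_value", "status")],
          row.names = FALSE, digits = 4)
  } else {
    cat("No significant segments.\n")
  }
  print(x$purity)
  invisible(x)
}

#' @export
coef.umicna_call <- function(object, ...) {
  stats::setNames(object$calls$table$seg_mean,
                  paste0(object$calls$table$gene, ":",
                         object$calls$table$first, "-",
                         object$calls$table$last))
}

#' @export
fitted.umicna_call <- function(object, ...) {
  f <- rep(NA_real_, length(object$profile$l))
  tab <- object$calls$table
  for (s in seq_len(nrow(tab))) {
    f[tab$first[s]:tab$last[s]] <- tab$seg_mean[s]
  }
  f
}

#' @export
residuals.umicna_call <- function(object, ...) {
  object$profile$l - fitted(object)
}

#' Plot a copy-number profile
#'
#' Regions as points in panel order, segment means as horizontal bars
#' colored by status (gain blue, loss red), vertical lines at gene
#' boundaries and gene labels along the axis.
#'
#' @param x A `umicna_call`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.umicna_call <- function(x, ...) {
  l <- x$profile$l
  p <- seq_along(l)
  graphics::plot(p, l, pch = 16, cex = 0.5, col = "grey40",
                 xlab = "panel region", ylab = "centered log2 ratio",
                 main = paste("CNA profile:", x$sample_id), ...)
  graphics::abline(h = 0, col = "grey70")
  genes <- x$profile$panel$genes
  graphics::abline(v = genes$first - 0.5, col = "grey85")
  graphics::axis(3, at = (genes$first + genes$last) / 2,
                 labels = genes$block, las = 2, cex.axis = 0.5, tick = FALSE)
  tab <- x$calls$table
  cols <- c(gain = "#2166AC", loss = "#B2182B", normal = "grey20",
            untested = "grey60")
  graphics::segments(tab$first - 0.4, tab$seg_mean, tab$last + 0.4,
                     tab$seg_mean, col = cols[tab$status], lwd = 2.5)
  invisible(x)
}

#' Write the per-segment report and profile plot
#'
#' Emits `<sample>.segments.csv` — a comma-separated table with one row per
#' segment (gene, coordinates, size, mean, t, p, q, status, flags) preceded
#' by a commented header block (sample id, centering shift, purity
#' estimates) — and `<sample>.profile.png` with the profile plot.
#'
#' @param fit A [cnv_call()] result.
#' @param dir Output directory (created if needed).
#' @param plot_format `"png"`, `"svg"`, or `"none"`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_report <- function(fit, dir, plot_format = c("png", "svg", "none")) {
  stopifnot(inherits(fit, "umicna_call"))
  plot_format <- match.arg(plot_format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(fit$sample_id, ".segments.csv"))
  fmt <- function(v) if (is.na(v)) "NA" else format(v, digits = 15)
  hdr <- c(paste0("#sample_id=", fit$sample_id),
           paste0("#centering_shift=", fmt(fit$profile$shift)),
           paste0("#c_gain=", fmt(fit$purity$c_gain)),
           paste0("#c_del=", fmt(fit$purity$c_del)),
           paste0("#c_mean=", fmt(fit$purity$c_mean)),
           paste0("#alpha=", fit$alpha))
  tab <- fit$calls$table[, c("gene", "chrom", "start", "end", "n_regions",
                             "seg_mean", "t_statistic", "p_value",
                             "q_value", "status", "flags")]
  con <- file(csv, "w")
  writeLines(hdr, con)
  writeLines(paste(colnames(tab), collapse = ","), con)
  close(con)
  utils::write.table(tab, csv, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, append = TRUE, dec = ".")
  paths <- c(csv = csv)
  if (plot_format != "none") {
    img <- file.path(dir, paste0(fit$sample_id, ".profile.", plot_format))
    ok <- tryCatch({
      if (plot_format == "png") {
        grDevices::png(img, width = 1400, height = 500, res = 110)
      } else {
        grDevices::svg(img, width = 13, height = 4.5)
      }
      plot(fit)
      grDevices::dev.off()
      TRUE
    }, error = function(e) {
      warning("profile plot could not be written: ", conditionMessage(e))
      FALSE
    })
    if (ok) paths <- c(paths, plot = img)
  }
  invisible(paths)
}

#' Read back a segment report CSV
#'
#' @param path A `.segments.csv` written by [write_report()].
#' @return List with `table` (segment data.frame) and `meta` (header fields).
#' @export
read_report <- function(path) {
  lines <- readLines(path)
  hdr <- lines[grepl("^#", lines)]
  kv <- strsplit(sub("^#", "", hdr), "=", fixed = TRUE)
  meta <- stats::setNames(
    lapply(kv, function(x) {
      v <- x[2L]
      if (x[1L] %in% c("sample_id")) v else suppressWarnings(as.numeric(v))
    }),
    vapply(kv, `[[`, "", 1L))
  tab <- utils::read.csv(text = lines[!grepl("^#", lines)],
                         stringsAsFactors = FALSE)
  list(table = tab, meta = meta)
}
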