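#' Expected log2 ratio under the tumor/normal mixture model
#'
#' A region at copy number `cn` in a tumor fraction `c` mixes tumor and
#' diploid normal signal, giving `log2(c * cn/2 + (1 - c))`.
#'
#' @param tumor_fraction Tumor cell fraction c in `[0, 1]`.
#' @param copy_number Integer copy number (2 = diploid).
#' @return Expected log2 ratio.
#' @examples
#' expected_log_ratio(1, 3)    # single-copy gain in a pure tumor: ~0.585
#' expected_log_ratio(1, 1)    # single-copy loss in a pure tumor: -1
#' @export
expected_log_ratio <- function(tumor_fraction, copy_number) {
  stopifnot(all(tumor_fraction >= 0), all(tumor_fraction <= 1),
            all(copy_number >= 0))
  log2(tumor_fraction * copy_number / 2 + (1 - tumor_fraction))
}

#' Invert a mean log-ratio to a tumor-fraction estimate
#'
#' Inverts the single-copy mixture model: for gains
#' `c = 2 (2^L - 1)`, for losses `c = -2 (2^L - 1)`.
#'
#' @param l Mean log2 ratio of the significant segments.
#' @param side `"gain"` or `"loss"`.
#' @return Tumor-fraction estimate (unclamped).
#' @export
purity_from_logratio <- function(l, side = c("gain", "loss")) {
  side <- match.arg(side)
  if (side == "gain") 2 * (2^l - 1) else -2 * (2^l - 1)
}

#' Size of the UMI sequence space
#'
#' Number of distinct nucleotide barcodes of a given length: `4^length`.
#' With the standard 12-nt UMIs this is 16,777,216 possible indices per
#' adapter, which is why each input molecule in a targeted library receives
#' a practically unique barcode.
#'
#' @param length UMI length in nucleotides (default 12).
#' @return Number of possible UMI sequences.
#' @export
umi_space <- function(length = 12L) {
  stopifnot(length >= 1)
  4^length
}

#' Simulate a targeted panel with per-region capture efficiencies
#'
#' Emulates the structure of a multi-gene amplicon panel, scaled to desk
#' size: `n_genes` genes of `regions_per_gene` consecutive regions each,
#' laid out along one synthetic chromosome, with log-normal per-region
#' capture efficiencies reproducing the systematic region-to-region depth
#' differences of real panels.
#'
#' @param n_genes Number of genes (default 20).
#' @param regions_per_gene Regions per gene (default 15).
#' @param region_len Region length in bp (default 150).
#' @param gap Gap between consecutive regions in bp (default 50).
#' @param efficiency_sdlog SD of log capture efficiency (default 0.5).
#' @param seed RNG seed for the efficiencies.
#' @return A `umicna_sim_panel`: list with `panel` (a `umicna_panel`),
#'   `efficiencies` (length P), and the shape parameters.
#' @export
sim_panel <- function(n_genes = 20L, regions_per_gene = 15L,
                      region_len = 150L, gap = 50L,
                      efficiency_sdlog = 0.5, seed = 1L) {
  stopifnot(n_genes >= 1, regions_per_gene >= 1)
  P <- n_genes * regions_per_gene
  gene <- rep(sprintf("gene_%02d", seq_len(n_genes)),
              each = regions_per_gene)
  start <- seq(0L, by = region_len + gap, length.out = P)
  bed <- tempfile(fileext = ".bed")
  on.exit(unlink(bed))
  writeLines(paste("chrS", start, start + region_len, gene, sep = "\t"), bed)
  panel <- read_panel(bed)
  old <- save_rng()
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  eff <- stats::rlnorm(P, meanlog = 0, sdlog = efficiency_sdlog)
  structure(list(panel = panel, efficiencies = eff,
                 n_genes = as.integer(n_genes),
                 regions_per_gene = as.integer(regions_per_gene),
                 seed = as.integer(seed)),
            class = "umicna_sim_panel")
}

#' Ground truth for a simulated tumor sample
#'
#' @param sim_panel A [sim_panel()] result.
#' @param events Named list mapping gene labels (e.g. `"gene_03"`) to copy
#'   numbers in `{0, 1, 3, 4, ...}`; regions outside events are diploid.
#'   Sub-gene events can be given as `list(gene = , cn = , regions = )`
#'   entries with region positions within the gene.
#' @param tumor_fraction Tumor cell fraction c in `(0, 1]`.
#' @return A `umicna_sim_truth`: per-region copy number `cn`, expected
#'   log-ratios, the event table and `tumor_fraction`.
#' @export
sim_truth <- function(sim_panel, events, tumor_fraction) {
  stopifnot(inherits(sim_panel, "umicna_sim_panel"),
            tumor_fraction >= 0, tumor_fraction <= 1)
  panel <- sim_panel$panel
  cn <- rep(2, n_regions(panel))
  ev <- list()
  for (nm in names(events)) {
    e <- events[[nm]]
    g <- match(nm, panel$genes$block)
    if (is.na(g)) stop("unknown gene in events: ", nm)
    idx <- panel$genes$first[g]:panel$genes$last[g]
    if (is.list(e)) {
      idx <- idx[e$regions]
      e <- e$cn
    }
    stopifnot(e >= 0)
    cn[idx] <- e
    ev[[length(ev) + 1L]] <- data.frame(gene = nm, cn = e,
                                        stringsAsFactors = FALSE)
  }
  structure(list(events = do.call(rbind, ev), cn = cn,
                 tumor_fraction = tumor_fraction,
                 expected_lr = expected_log_ratio(tumor_fraction, cn)),
            class = "umicna_sim_truth")
}

nb_draw <- function(n, mu, dispersion) {
  if (!is.finite(dispersion)) return(stats::rpois(n, mu))
  if (dispersion <= 0) stop("dispersion (NB size) must be positive")
  stats::rnbinom(n, mu = mu, size = dispersion)
}

#' Simulate a control cohort of UMI counts
#'
#' Per-region counts are negative binomial around `mean_depth` scaled by
#' the region's capture efficiency; `size = dispersion` reproduces the
#' residual overdispersion seen in UMI counts across control samples
#' (`dispersion = Inf` gives the Poisson limit). Per-sample totals `U` are
#' the summed panel counts, hence close to `mean_depth * P`.
#'
#' @param sim_panel A [sim_panel()] result.
#' @param n_samples Number of controls (default 5).
#' @param mean_depth Mean UMI depth per region (default 2000).
#' @param dispersion NB size parameter (default 50).
#' @param seed RNG seed.
#' @return A `umi_counts` matrix of the controls.
#' @export
simulate_controls <- function(sim_panel, n_samples = 5L, mean_depth = 2000,
                              dispersion = 50, seed = 1L) {
  stopifnot(inherits(sim_panel, "umicna_sim_panel"),
            n_samples >= 1, mean_depth > 0)
  P <- n_regions(sim_panel$panel)
  mu <- mean_depth * sim_panel$efficiencies / mean(sim_panel$efficiencies)
  old <- save_rng()
  on.exit(restore_rng(old))
  set.seed(seed %% 2147483647L)
  counts <- vapply(seq_len(n_samples),
                   function(s) nb_draw(P, mu, dispersion),
                   numeric(P))
  counts <- matrix(as.integer(counts), nrow = P)
  umi_count_matrix(sim_panel$panel, counts,
                   totals = colSums(counts),
                   sample_ids = sprintf("control_%02d", seq_len(n_samples)))
}

#' Simulate one tumor sample with spiked CNV events
#'
#' Expected counts are the control model scaled per region by the
#' tumor/normal mixture `c * cn/2 + (1 - c)` from the ground truth.
#'
#' @param sim_panel A [sim_panel()] result.
#' @param truth A [sim_truth()] result.
#' @param mean_depth,dispersion As in [simulate_controls()].
#' @param seed RNG seed.
#' @param sample_id Sample label.
#' @return A `umi_counts_col`.
#' @export
simulate_tumor <- function(sim_panel, truth, mean_depth = 2000,
                           dispersion = 50, seed = 1L,
                           sample_id = "tumor") {
  stopifnot(inherits(sim_panel, "umicna_sim_panel"),
            inherits(truth, "umicna_sim_truth"))
  P <- n_regions(sim_panel$panel)
  mix <- truth$tumor_fraction * truth$cn / 2 + (1 - truth$tumor_fraction)
  mu <- mean_depth * sim_panel$efficiencies /
    mean(sim_panel$efficiencies) * mix
  old <- save_rng()
  on.exit(restore_rng(old))
  set.seed(seed %% 2147483647L)
  counts <- as.integer(nb_draw(P, mu, dispersion))
  structure(list(counts = counts, read_counts = NULL,
                 total = sum(counts), sample_id = sample_id,
                 panel = sim_panel$panel, n_skipped = 0L),
            class = "umi_counts_col")
}

#' Write a micro-BAM fixture realizing a given UMI count vector
#'
#' Emits a sorted, indexed BAM (plus the matching BED and a toy reference
#' FASTA) on the synthetic panel in which region `p` is covered by exactly
#' `counts[p]` distinct 12-mer UMIs carried as read-name suffixes (and as
#' `RX` tags), each UMI appearing as 1-3 duplicate reads contained in the
#' region. All UMIs are globally distinct, so [count_umis()] must
#' round-trip both the per-region counts and the total `U = sum(counts)`
#' exactly.
#'
#' @param sim_panel A [sim_panel()] result (keep it tiny).
#' @param counts Integer vector of UMI counts per region.
#' @param out_prefix Path prefix for the emitted files.
#' @param read_len Read length (default 80, truncated to the region).
#' @param max_dups Maximum duplicate reads per UMI (default 3).
#' @param seed RNG seed.
#' @return List of paths: `bam`, `bed`, `fasta`.
#' @export
simulate_bam_fixture <- function(sim_panel, counts, out_prefix,
                                 read_len = 80L, max_dups = 3L, seed = 1L) {
  stopifnot(inherits(sim_panel, "umicna_sim_panel"),
            length(counts) == n_regions(sim_panel$panel),
            sum(counts) <= 1e4)
  panel <- sim_panel$panel
  reg <- panel$regions
  old <- save_rng()
  on.exit(restore_rng(old))
  set.seed(seed %% 2147483647L)

  n_umis <- sum(counts)
  umis <- unique_umis(n_umis, 12L)
  u0 <- 0L
  recs <- list()
  for (p in seq_len(nrow(reg))) {
    if (counts[p] == 0L) next
    len <- min(read_len, reg$end[p] - reg$start[p])
    for (u in seq_len(counts[p])) {
      umi <- umis[u0 + u]
      qname <- sprintf("sim:%d:%d_%s", p, u, umi)
      ndup <- sample.int(max_dups, 1L)
      maxoff <- reg$end[p] - reg$start[p] - len
      for (d in seq_len(ndup)) {
        pos <- reg$start[p] + sample.int(maxoff + 1L, 1L) - 1L
        recs[[length(recs) + 1L]] <- data.frame(
          qname = qname, flag = if (d == 1L) 0L else 1024L,
          rname = reg$chrom[p], pos = pos + 1L, mapq = 60L,
          cigar = paste0(len, "M"), len = len, umi = umi,
          stringsAsFactors = FALSE)
      }
    }
    u0 <- u0 + counts[p]
  }
  recs <- do.call(rbind, recs)
  recs <- recs[order(recs$rname, recs$pos), , drop = FALSE]

  chrom_len <- max(reg$end) + read_len + 10L
  sam <- paste0(out_prefix, ".sam")
  sam_lines <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    paste0("@SQ\tSN:", unique(reg$chrom), "\tLN:", chrom_len),
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tRX:Z:%s",
            recs$qname, recs$flag, recs$rname, recs$pos, recs$mapq,
            recs$cigar, strrep("A", recs$len), strrep("I", recs$len),
            recs$umi))
  writeLines(sam_lines, sam)
  bam <- Rsamtools::asBam(sam, out_prefix, overwrite = TRUE,
                          indexDestination = TRUE)

  bed <- paste0(out_prefix, ".bed")
  writeLines(paste(reg$chrom, reg$start, reg$end, reg$gene, sep = "\t"), bed)
  fasta <- paste0(out_prefix, ".fa")
  writeLines(c(paste0(">", unique(reg$chrom)[1L]),
               strrep("A", chrom_len)), fasta)
  list(bam = bam, bed = bed, fasta = fasta, sam = sam)
}

unique_umis <- function(n, len = 12L) {
  out <- character(0)
  while (length(out) < n) {
    cand <- vapply(seq_len(n - length(out) + 8L), function(i) {
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = "")
    }, "")
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}

#' Default spiked events for sensitivity experiments
#'
#' Four whole-gene events spread across the panel: a high-level
#' amplification (CN 4), a single-copy gain (CN 3), a heterozygous deletion
#' (CN 1) and a homozygous deletion (CN 0).
#'
#' @param sim_panel A [sim_panel()] result with >= 4 genes.
#' @return Named list of copy numbers keyed by gene label.
#' @export
default_events <- function(sim_panel) {
  stopifnot(inherits(sim_panel, "umicna_sim_panel"),
            sim_panel$n_genes >= 4L)
  g <- sim_panel$panel$genes$block
  pick <- unique(pmax(1L, round(seq(0.15, 0.9, length.out = 4L) *
                                  length(g))))
  stats::setNames(list(4, 3, 1, 0), g[pick[1:4]])
}

#' In-silico dilution experiment
#'
#' Runs the full pipeline (control simulation, reference construction,
#' tumor simulation, calling) over a grid of tumor fractions and
#' replicates, recording for each spiked event whether it was called
#' significant with the correct direction and what tumor content was
#' estimated. This is the synthetic analog of diluting an aberrant sample
#' into normal DNA to probe the detection limit.
#'
#' @param fractions Tumor fractions to test
#'   (default `c(1, 0.5, 0.2, 0.1, 0.05)`).
#' @param n_reps Replicates per fraction (default 10).
#' @param sim A [sim_panel()] result (default desk-scale panel).
#' @param events Named event list (default [default_events()]).
#' @param n_controls Control cohort size (default 5).
#' @param mean_depth,dispersion Count model, see [simulate_controls()].
#' @param alpha FDR level (default 0.05).
#' @param params Segmentation parameters.
#' @param seed Master seed; every simulation derives from it.
#' @return A data.frame with one row per (fraction, replicate, event):
#'   `fraction`, `rep`, `gene`, `cn`, `detected`, `c_gain`, `c_del`,
#'   `c_mean`.
#' @export
dilution_experiment <- function(fractions = c(1, 0.5, 0.2, 0.1, 0.05),
                                n_reps = 10L,
                                sim = sim_panel(),
                                events = default_events(sim),
                                n_controls = 5L, mean_depth = 2000,
                                dispersion = 50, alpha = 0.05,
                                params = seg_params(), seed = 1L) {
  ctl <- simulate_controls(sim, n_samples = n_controls,
                           mean_depth = mean_depth,
                           dispersion = dispersion, seed = seed)
  ref <- build_reference(ctl)
  out <- list()
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    truth <- sim_truth(sim, events, tumor_fraction = f)
    for (r in seq_len(n_reps)) {
      seed_t <- (seed + 97L * fi + 10007L * r) %% 2147483647L
      tum <- simulate_tumor(sim, truth, mean_depth = mean_depth,
                            dispersion = dispersion, seed = seed_t,
                            sample_id = sprintf("t_f%03d_r%02d",
                                                round(100 * f), r))
      fit <- cnv_call(tum, ref, alpha = alpha, centering = TRUE,
                      params = params)
      tab <- fit$calls$table
      for (nm in names(events)) {
        cn <- events[[nm]]
        want <- if (cn > 2) "gain" else "loss"
        hit <- any(tab$gene == nm & tab$status == want)
        out[[length(out) + 1L]] <- data.frame(
          fraction = f, rep = r, gene = nm, cn = cn, detected = hit,
          c_gain = fit$purity$c_gain, c_del = fit$purity$c_del,
          c_mean = fit$purity$c_mean, stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

# preserve the caller's RNG stream around seeded simulation
save_rng <- function() {
  if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
}
restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  else if (exists(".Random.seed", .GlobalEnv)) {
    rm(".Random.seed", envir = .GlobalEnv)
  }
}
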