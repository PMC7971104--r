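#' Count unique UMIs per targeted region in one BAM file
#'
#' Scans an indexed BAM and, for every panel region, counts the number of
#' distinct UMI sequences among passing reads whose aligned span overlaps the
#' region by at least one base (the aligned span runs from POS through the
#' CIGAR reference length, which is how BAM range queries resolve overlap).
#' Passing reads are primary, mapped, not QC-fail alignments with
#' MAPQ >= `min_mapq`. Reads flagged as positional PCR duplicates are kept:
#' UMI deduplication supersedes positional deduplication, and two fragments
#' at identical coordinates with distinct UMIs are distinct molecules. A UMI
#' seen on both mates or on several reads within one region counts once.
#' The per-sample total `U` is the number of distinct UMIs across all
#' passing reads in the whole file (not the sum over regions, which would
#' double-count UMIs spanning two regions).
#'
#' @param bam_path Path to a coordinate-sorted, indexed BAM.
#' @param panel A [read_panel()] result.
#' @param min_mapq Minimum mapping quality (default 20).
#' @param policy A [umi_policy()] locating the UMI.
#' @param sample_id Sample label; defaults to the BAM basename.
#' @return A `umi_counts_col` list: `counts` (distinct-UMI count per region),
#'   `read_counts` (passing reads per region), `total` (U), `sample_id`,
#'   `panel`, `n_skipped` (lenient mode only).
#' @export
count_umis <- function(bam_path, panel, min_mapq = 20L,
                       policy = umi_policy(),
                       sample_id = sub("\\.bam$", "", basename(bam_path))) {
  stopifnot(inherits(panel, "umicna_panel"), n_regions(panel) >= 1L)
  if (!file.exists(bam_path)) stop("BAM not found: ", bam_path)
  bai <- c(paste0(bam_path, ".bai"), sub("\\.bam$", ".bai", bam_path))
  if (!any(file.exists(bai))) {
    stop("BAM index (.bai) not found for ", bam_path,
         "; sort and index the BAM first")
  }

  flags <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE,
    isNotPassingQualityControls = FALSE
  )
  what <- c("qname", "mapq")
  tag <- if (policy$from == "tag") policy$tag else character(0)

  header_chroms <- names(Rsamtools::scanBamHeader(bam_path)[[1L]]$targets)
  present <- panel$regions$chrom %in% header_chroms
  if (any(!present)) {
    warning(sum(!present), " panel region(s) on chromosome(s) absent from ",
            "the BAM header; their counts are 0")
  }

  counts <- integer(n_regions(panel))
  read_counts <- integer(n_regions(panel))
  n_skipped <- 0L

  if (any(present)) {
    sub <- panel$regions[present, , drop = FALSE]
    gr <- GenomicRanges::GRanges(
      seqnames = sub$chrom,
      ranges = IRanges::IRanges(start = sub$start + 1L, end = sub$end))
    param <- Rsamtools::ScanBamParam(flag = flags, what = what, tag = tag,
                                     which = gr)
    res <- Rsamtools::scanBam(bam_path, param = param)
    idx_present <- which(present)
    for (k in seq_along(res)) {
      rec <- res[[k]]
      keep <- !is.na(rec$mapq) & rec$mapq >= min_mapq
      umis <- region_umis(rec, keep, policy)
      n_skipped <- n_skipped + (attr(umis, "n_skipped") %||% 0L)
      counts[idx_present[k]] <- length(unique(umis[!is.na(umis)]))
      read_counts[idx_present[k]] <- sum(keep)
    }
  }

  # genome-wide distinct UMI total, streamed
  bf <- Rsamtools::BamFile(bam_path, yieldSize = 500000L)
  param_all <- Rsamtools::ScanBamParam(flag = flags, what = what, tag = tag)
  open(bf)
  on.exit(close(bf))
  all_umis <- character(0)
  repeat {
    rec <- Rsamtools::scanBam(bf, param = param_all)[[1L]]
    if (length(rec$qname) == 0L) break
    keep <- !is.na(rec$mapq) & rec$mapq >= min_mapq
    umis <- region_umis(rec, keep, policy)
    n_skipped <- n_skipped + (attr(umis, "n_skipped") %||% 0L)
    all_umis <- unique(c(all_umis, umis[!is.na(umis)]))
  }

  structure(list(counts = counts, read_counts = read_counts,
                 total = length(all_umis), sample_id = sample_id,
                 panel = panel, n_skipped = n_skipped),
            class = "umi_counts_col")
}

region_umis <- function(rec, keep, policy) {
  if (policy$from == "name") {
    extract_umi(rec$qname[keep], policy)
  } else {
    umi <- rec$tag[[policy$tag]][keep]
    if (is.null(umi)) umi <- rep(NA_character_, sum(keep))
    if (anyNA(umi) && policy$strict) {
      stop("read without ", policy$tag, " tag: ",
           rec$qname[keep][which(is.na(umi))[1L]])
    }
    if (anyNA(umi)) attr(umi, "n_skipped") <- sum(is.na(umi))
    umi
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble per-sample UMI count columns into a matrix
#'
#' @param columns List of [count_umis()] results sharing one panel.
#' @return A `umi_counts` object: `panel`, integer `counts` matrix (P x S),
#'   `read_counts`, per-sample `totals` (U), `sample_ids`.
#' @export
assemble_matrix <- function(columns) {
  if (length(columns) == 0L) stop("no count columns supplied")
  stopifnot(all(vapply(columns, inherits, TRUE, "umi_counts_col")))
  hashes <- vapply(columns, function(co) panel_hash(co$panel), "")
  if (length(unique(hashes)) != 1L) {
    stop("count columns were produced against different panels")
  }
  P <- n_regions(columns[[1L]]$panel)
  counts <- matrix(as.integer(vapply(columns, `[[`, numeric(P), "counts")),
                   nrow = P)
  rc <- lapply(columns, `[[`, "read_counts")
  read_counts <- if (any(vapply(rc, is.null, TRUE))) NULL else {
    matrix(as.integer(unlist(rc)), nrow = P)
  }
  umi_count_matrix(
    panel = columns[[1L]]$panel,
    counts = counts,
    totals = vapply(columns, `[[`, numeric(1), "total"),
    sample_ids = vapply(columns, `[[`, "", "sample_id"),
    read_counts = read_counts
  )
}

#' Construct a UMI count matrix from raw components
#'
#' Lower-level constructor used by [assemble_matrix()] and the synthetic-data
#' generator.
#'
#' @param panel A `umicna_panel`.
#' @param counts Integer matrix, regions x samples.
#' @param totals Per-sample genome-wide distinct-UMI totals U.
#' @param sample_ids Character vector of sample labels.
#' @param read_counts Optional matching matrix of passing-read counts.
#' @return A `umi_counts` object.
#' @export
umi_count_matrix <- function(panel, counts, totals, sample_ids,
                             read_counts = NULL) {
  stopifnot(inherits(panel, "umicna_panel"),
            is.matrix(counts),
            nrow(counts) == n_regions(panel),
            length(totals) == ncol(counts),
            length(sample_ids) == ncol(counts),
            all(counts >= 0))
  dimnames(counts) <- list(NULL, sample_ids)
  structure(list(panel = panel, counts = counts, totals = as.numeric(totals),
                 sample_ids = as.character(sample_ids),
                 read_counts = read_counts, normalized = FALSE, norm = NULL),
            class = "umi_counts")
}

#' Normalize a UMI count matrix by per-sample totals
#'
#' Divides each sample's per-region counts by that sample's genome-wide
#' distinct-UMI total `U`, making samples of different depth comparable.
#' Raw counts are retained alongside. Normalization is applied once; a guard
#' flag prevents renormalizing an already-normalized matrix.
#'
#' @param m A `umi_counts` object.
#' @return The same object with a `norm` matrix of fractions and
#'   `normalized = TRUE`.
#' @export
normalize_counts <- function(m) {
  stopifnot(inherits(m, "umi_counts"))
  if (isTRUE(m$normalized)) {
    stop("matrix is already normalized; normalization must not be repeated")
  }
  zero <- which(m$totals <= 0)
  if (length(zero)) {
    stop("sample '", m$sample_ids[zero[1L]], "' has zero total UMI count")
  }
  m$norm <- sweep(m$counts, 2L, m$totals, "/")
  m$normalized <- TRUE
  m
}

#' @export
print.umi_counts <- function(x, ...) {
  cat("UMI count matrix:", nrow(x$counts), "regions x",
      ncol(x$counts), "samples",
      if (isTRUE(x$normalized)) "(normalized)" else "(raw)", "\n")
  cat("  totals (U):", paste(format(x$totals, big.mark = ","),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Write a per-sample UMI count table as TSV
#'
#' @param column A [count_umis()] result (or one sample of a `umi_counts`
#'   via [counts_column()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(column, path) {
  stopifnot(inherits(column, "umi_counts_col"))
  reg <- column$panel$regions
  hdr <- c(paste0("#sample_id=", column$sample_id),
           paste0("#total_umis=", column$total),
           paste0("#panel_md5=", panel_hash(column$panel)))
  df <- data.frame(chrom = reg$chrom, start = reg$start, end = reg$end,
                   gene = reg$gene, umi_count = column$counts,
                   read_count = if (is.null(column$read_counts)) NA_integer_
                                else column$read_counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(colnames(df), collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-sample UMI count table written by [write_counts()]
#'
#' @param path TSV path.
#' @param panel Optional panel to validate against (md5 of regions).
#' @return A `umi_counts_col`.
#' @export
read_counts <- function(path, panel = NULL) {
  lines <- readLines(path)
  hdr <- lines[grepl("^#", lines)]
  get <- function(key) sub(paste0("^#", key, "="), "",
                           hdr[grepl(paste0("^#", key, "="), hdr)][1L])
  df <- utils::read.table(text = lines[!grepl("^#", lines)], sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  if (is.null(panel)) {
    bed <- tempfile(fileext = ".bed")
    on.exit(unlink(bed))
    writeLines(paste(df$chrom, df$start, df$end, df$gene, sep = "\t"), bed)
    panel <- read_panel(bed)
  } else if (panel_hash(panel) != get("panel_md5")) {
    stop("count table ", path, " was produced against a different panel")
  }
  ord <- order(df$chrom, df$start, df$end)
  df <- df[ord, , drop = FALSE]
  structure(list(counts = as.integer(df$umi_count),
                 read_counts = if (all(is.na(df$read_count))) NULL
                               else as.integer(df$read_count),
                 total = as.numeric(get("total_umis")),
                 sample_id = get("sample_id"),
                 panel = panel, n_skipped = 0L),
            class = "umi_counts_col")
}

#' Extract one sample of a count matrix as a count column
#' @param m A `umi_counts`.
#' @param sample Sample id or column index.
#' @return A `umi_counts_col`.
#' @export
counts_column <- function(m, sample) {
  stopifnot(inherits(m, "umi_counts"))
  s <- if (is.character(sample)) match(sample, m$sample_ids) else sample
  if (is.na(s) || s < 1L || s > ncol(m$counts)) stop("unknown sample: ", sample)
  structure(list(counts = m$counts[, s],
                 read_counts = if (is.null(m$read_counts)) NULL
                               else m$read_counts[, s],
                 total = m$totals[s], sample_id = m$sample_ids[s],
                 panel = m$panel, n_skipped = 0L),
            class = "umi_counts_col")
}
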