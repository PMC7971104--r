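#' Read a targeted-panel BED file
#'
#' Parses a BED file (4+ tab-separated columns: chromosome, start, end, gene
#' name) describing the targeted regions of a gene panel. Coordinates follow
#' the BED convention: 0-based, half-open `[start, end)`. Regions are sorted
#' by `(chrom, start, end)` and contiguous runs of regions sharing a gene
#' symbol are grouped into gene blocks — the unit later used for per-gene
#' segmentation. A gene whose regions occur in two non-adjacent coordinate
#' runs yields two distinct blocks labelled `gene#1`, `gene#2`, ...
#'
#' @param bed_path Path to the BED file.
#' @return A `umicna_panel` object: a list with `regions` (data.frame with
#'   columns `chrom`, `start`, `end`, `gene`, `block`, `index`) and `genes`
#'   (data.frame with one row per gene block: `block`, `gene`, `first`,
#'   `last`, regions indexed 1..P in panel order).
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr1\t100\t200\tTP53", "chr1\t300\t400\tTP53",
#'              "chr2\t10\t90\tMYC"), bed)
#' p <- read_panel(bed)
#' p$genes
#' @export
read_panel <- function(bed_path) {
  if (!file.exists(bed_path)) {
    stop("BED file not found: ", bed_path)
  }
  lines <- readLines(bed_path)
  lines <- lines[!grepl("^(#|track\\b|browser\\b)", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("BED file is empty: ", bed_path)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    stop("BED line ", which(nf < 4L)[1L],
         ": expected >= 4 tab-separated columns (chrom, start, end, gene)")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end   <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  gene  <- vapply(fields, `[[`, "", 4L)
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop("BED line ", bad[1L], ": non-integer start/end coordinate")
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop("BED line ", bad[1L], ": start >= end (BED is 0-based half-open)")
  }
  df <- data.frame(chrom = chrom, start = start, end = end, gene = gene,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL

  # contiguous runs of one gene symbol form a block
  run <- cumsum(c(TRUE, df$gene[-1L] != df$gene[-nrow(df)]))
  block <- df$gene
  for (g in unique(df$gene)) {
    runs_g <- unique(run[df$gene == g])
    if (length(runs_g) > 1L) {
      for (k in seq_along(runs_g)) {
        block[run == runs_g[k]] <- paste0(g, "#", k)
      }
    }
  }
  df$block <- block
  df$index <- seq_len(nrow(df))

  first <- tapply(df$index, df$block, min)
  genes <- data.frame(
    block = names(first),
    gene  = df$gene[match(names(first), df$block)],
    first = as.integer(first),
    last  = as.integer(tapply(df$index, df$block, max)),
    stringsAsFactors = FALSE
  )
  genes <- genes[order(genes$first), , drop = FALSE]
  rownames(genes) <- NULL
  structure(list(regions = df, genes = genes), class = "umicna_panel")
}

#' Number of regions in a panel
#' @param panel A `umicna_panel`.
#' @return Integer region count P.
#' @export
n_regions <- function(panel) {
  stopifnot(inherits(panel, "umicna_panel"))
  nrow(panel$regions)
}

#' @export
print.umicna_panel <- function(x, ...) {
  cat("Targeted panel:", nrow(x$regions), "regions in",
      nrow(x$genes), "gene blocks\n")
  cat("  chromosomes:", paste(unique(x$regions$chrom), collapse = ", "), "\n")
  invisible(x)
}

# identity fingerprint of the panel content, used to detect reference/tumor
# panel mismatches across serialized bundles
panel_hash <- function(panel) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(with(panel$regions,
                  paste(chrom, start, end, gene, sep = "\t")), tmp)
  unname(tools::md5sum(tmp))
}

panel_granges <- function(panel) {
  GenomicRanges::GRanges(
    seqnames = panel$regions$chrom,
    ranges = IRanges::IRanges(start = panel$regions$start + 1L,
                              end = panel$regions$end)
  )
}
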