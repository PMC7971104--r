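#' UMI extraction policy
#'
#' Describes where the unique molecular identifier of each read lives. The
#' usual convention (UMI-tools `extract`) appends the UMI to the read name
#' after a delimiter; alternatively the UMI may be stored in an alignment tag
#' (default `RX`).
#'
#' @param from `"name"` (read-name suffix) or `"tag"` (alignment record tag).
#' @param delim Delimiter for `from = "name"`; the last delimited field is
#'   taken as the UMI. Default `"_"`.
#' @param tag Tag name for `from = "tag"`. Default `"RX"`.
#' @param strict If `TRUE` (default) a read without an extractable UMI is an
#'   error; if `FALSE` such reads are skipped and counted.
#' @return A `umi_policy` object.
#' @export
umi_policy <- function(from = c("name", "tag"), delim = "_", tag = "RX",
                       strict = TRUE) {
  from <- match.arg(from)
  stopifnot(nchar(delim) >= 1L, nchar(tag) >= 1L, is.logical(strict))
  structure(list(from = from, delim = delim, tag = tag, strict = strict),
            class = "umi_policy")
}

#' Extract UMI sequences from read names
#'
#' For the `"name"` policy, splits each read name on the delimiter and
#' returns the last field. (Both mates of a pair share the read name, hence
#' the same UMI.) Reads without the delimiter raise an error in strict mode,
#' otherwise yield `NA` and are tallied in the `n_skipped` attribute.
#'
#' @param read_names Character vector of read names.
#' @param policy A [umi_policy()] with `from = "name"`.
#' @return Character vector of UMIs (possibly with `NA` in lenient mode and
#'   an `n_skipped` attribute).
#' @examples
#' extract_umi("M01234:55:000:1:1101:1234:5678_AACGTTACGGTA", umi_policy())
#' @export
extract_umi <- function(read_names, policy = umi_policy()) {
  stopifnot(inherits(policy, "umi_policy"))
  if (policy$from != "name") {
    stop("extract_umi() applies to the read-name policy; ",
         "tag UMIs are read directly from the alignment records")
  }
  parts <- strsplit(read_names, policy$delim, fixed = TRUE)
  has_umi <- lengths(parts) >= 2L
  umi <- rep(NA_character_, length(read_names))
  umi[has_umi] <- vapply(parts[has_umi], function(p) p[[length(p)]], "")
  if (any(!has_umi)) {
    if (policy$strict) {
      stop("read name without UMI delimiter '", policy$delim, "': ",
           read_names[which(!has_umi)[1L]])
    }
    attr(umi, "n_skipped") <- sum(!has_umi)
  }
  umi
}
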