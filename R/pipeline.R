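#' Run configuration with defaults and precedence
#'
#' Collects every tunable of the two workflows. Values given in `...`
#' override the config file, which overrides the defaults. Unknown keys are
#' rejected. The full resolved configuration is serialized into each run's
#' `meta.json` so a run can be reproduced from its output directory alone.
#'
#' @param ... Named overrides.
#' @param config_file Optional JSON or YAML file of overrides.
#' @return A `umicna_config` list.
#' @export
run_config <- function(..., config_file = NULL) {
  defaults <- list(
    min_mapq = 20L, umi_from = "name", umi_delim = "_", umi_tag = "RX",
    sample_frac = 0.20, region_frac = 0.50,
    seg_alpha = 0.01, seg_n_perm = 10000L, seg_min_width = 2L,
    seg_undo_sd = 1.0, alpha = 0.05, centering = TRUE, seed = 17L)
  cfg <- defaults
  apply_over <- function(cfg, over, src) {
    unknown <- setdiff(names(over), names(defaults))
    if (length(unknown)) {
      stop("unknown configuration key(s) in ", src, ": ",
           paste(unknown, collapse = ", "))
    }
    utils::modifyList(cfg, over)
  }
  if (!is.null(config_file)) {
    over <- if (grepl("\\.ya?ml$", config_file)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("YAML config requires the yaml package; use JSON instead")
      }
      yaml::read_yaml(config_file)
    } else {
      jsonlite::read_json(config_file, simplifyVector = TRUE)
    }
    cfg <- apply_over(cfg, over, config_file)
  }
  cfg <- apply_over(cfg, list(...), "arguments")
  structure(cfg, class = "umicna_config")
}

config_seg_params <- function(cfg) {
  seg_params(alpha = cfg$seg_alpha, n_perm = cfg$seg_n_perm,
             min_width = cfg$seg_min_width, undo_sd = cfg$seg_undo_sd,
             seed = cfg$seed)
}

write_run_meta <- function(dir, cfg, inputs, extra = list()) {
  hashes <- tools::md5sum(inputs[file.exists(inputs)])
  meta <- c(list(config = unclass(cfg),
                 inputs = as.list(hashes),
                 package_version = as.character(
                   utils::packageVersion("umicna")),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            extra)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Build a pseudo-reference bundle from control count tables
#'
#' Reads per-sample count TSVs (written by [write_counts()]), assembles and
#' normalizes the control matrix, builds the filtered pseudo-reference and
#' serializes the bundle. Exclusions are logged to stderr with reasons.
#'
#' @param count_paths Character vector of >= 2 control count TSVs.
#' @param out_dir Output bundle directory.
#' @param config A [run_config()].
#' @return The `umicna_reference`, invisibly.
#' @export
run_build_ref <- function(count_paths, out_dir, config = run_config()) {
  if (length(count_paths) < 2L) {
    stop("[build-ref] need at least 2 control count tables")
  }
  cols <- lapply(count_paths, read_counts)
  m <- assemble_matrix(cols)
  ref <- tryCatch(
    build_reference(m, sample_frac = config$sample_frac,
                    region_frac = config$region_frac),
    error = function(e) stop("[build-ref] ", conditionMessage(e)))
  for (i in seq_len(nrow(ref$excluded_samples))) {
    message("excluded control ", ref$excluded_samples$sample[i], ": ",
            ref$excluded_samples$reason[i])
  }
  message(nrow(ref$excluded_regions), " region(s) excluded; ",
          sum(ref$retained), " retained")
  write_reference(ref, out_dir)
  write_run_meta(out_dir, config, count_paths,
                 extra = list(stage = "build-ref",
                              panel_md5 = ref$panel_md5))
  invisible(ref)
}

#' Call CNAs for one tumor count table against a reference bundle
#'
#' Loads the bundle, checks that the tumor counts were produced on the same
#' panel (md5 of the region table), runs [cnv_call()] and writes the segment
#' CSV, profile plot, log-ratio TSV and `meta.json`.
#'
#' @param tumor_counts Path to the tumor count TSV.
#' @param ref_dir Reference bundle directory.
#' @param out_dir Output directory.
#' @param config A [run_config()].
#' @return The `umicna_call`, invisibly.
#' @export
run_call <- function(tumor_counts, ref_dir, out_dir,
                     config = run_config()) {
  ref <- read_reference(ref_dir)
  tumor <- read_counts(tumor_counts)
  if (panel_hash(tumor$panel) != ref$panel_md5) {
    stop("[call] tumor counts and reference bundle use different panels")
  }
  fit <- cnv_call(tumor, ref, alpha = config$alpha,
                  centering = config$centering,
                  params = config_seg_params(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_report(fit, out_dir)
  write_logratios(fit$profile,
                  file.path(out_dir, paste0(fit$sample_id, ".logratios.tsv")),
                  raw = fit$raw_profile)
  mix <- fit$profile$mixture
  write_run_meta(out_dir, config, c(tumor_counts,
                                    file.path(ref_dir, "reference.tsv")),
                 extra = list(stage = "call",
                              sample_id = fit$sample_id,
                              centering_shift = fit$profile$shift,
                              mixture = if (!is.null(mix)) {
                                list(k = mix$k, means = mix$means,
                                     sds = mix$sds, pro = mix$pro,
                                     selected = mix$selected)
                              },
                              purity = unclass(fit$purity)))
  message("[call] ", fit$sample_id, ": ",
          sum(fit$calls$table$status %in% c("gain", "loss")),
          " significant segment(s)")
  invisible(fit)
}
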