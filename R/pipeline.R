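# End-to-end orchestration: calibrate -> fit -> qc -> rescale/aggregate ->
# call -> network, with a machine-readable run manifest. Each stage is an
# exported function, so stage-wise invocation and run_pipeline() produce
# identical artifacts for identical configs.

#' Assemble a run configuration
#'
#' @param counts,bins,library,promoters Input paths (`bins` may be a
#'   named list of per-replicate paths).
#' @param outdir Output directory (created if absent).
#' @param condition Growth-condition label for the network stage.
#' @param calibration A [calibration_config()].
#' @param fit A [fit_config()].
#' @param replicates List with `reference_replicate`, and optionally
#'   `s_max` (default 0.7), `controls_exclude`, `iqr_multiplier`
#'   (default 1.5).
#' @param thresholds A [call_thresholds()].
#' @param seed Integer seed recorded in the manifest (the pipeline itself
#'   is deterministic; the seed feeds any simulation upstream).
#' @return A list of class `pptp_run_config`.
#' @export
run_config <- function(counts, bins, library, promoters = NULL,
                       outdir = ".", condition = "condition1",
                       calibration = calibration_config(),
                       fit = fit_config(),
                       replicates = list(reference_replicate = NULL),
                       thresholds = call_thresholds(),
                       seed = 1L) {
  reps <- utils::modifyList(
    list(s_max = 0.7, controls_exclude = character(0),
         iqr_multiplier = 1.5, reference_replicate = NULL),
    replicates)
  structure(list(counts = counts, bins = bins, library = library,
                 promoters = promoters, outdir = outdir,
                 condition = condition, calibration = calibration,
                 fit = fit, replicates = reps, thresholds = thresholds,
                 seed = seed),
            class = "pptp_run_config")
}

#' Run the full pipeline
#'
#' Reads the inputs, fits every variant, rescales and aggregates across
#' replicates, calls differential activity, builds the signed network,
#' and writes `fits.tsv`, `aggregates.tsv`, `calls.tsv`, `edges.tsv` and
#' `manifest.json` (package version, config hash, and a filter ledger
#' counting variants entering and failing each quality filter) to the
#' output directory.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all intermediate tables and the
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pptp_run_config"))
  if (!dir.exists(config$outdir))
    dir.create(config$outdir, recursive = TRUE)
  bins <- if (is.list(config$bins) && !is.data.frame(config$bins)) {
    lapply(config$bins, read_bin_spec)
  } else if (is.character(config$bins)) {
    read_bin_spec(config$bins)
  } else config$bins
  first_bins <- if (is.data.frame(bins)) bins else bins[[1]]
  counts <- if (is.character(config$counts))
    read_counts(config$counts, first_bins) else config$counts
  lib <- if (is.character(config$library))
    read_library(config$library) else config$library
  promoters <- if (is.character(config$promoters))
    read_promoters(config$promoters) else config$promoters

  fits <- fit_variants(counts, bins, config$calibration, config$fit)
  ref <- config$replicates$reference_replicate
  if (is.null(ref)) ref <- sort(unique(fits$replicate_id))[1]
  maps <- fit_rescale(fits, ref)
  fits <- apply_rescale(fits, maps)
  aggregates <- aggregate_activity(
    fits, lib,
    controls_exclude = config$replicates$controls_exclude,
    s_max = config$replicates$s_max,
    iqr_multiplier = config$replicates$iqr_multiplier)
  calls <- call_differential(aggregates, lib, config$thresholds)
  edges <- build_network(calls, config$condition)

  ledger <- filter_ledger(fits, aggregates, calls)
  manifest <- list(package = "pptpseq",
                   version = as.character(utils::packageVersion("pptpseq")),
                   condition = config$condition,
                   seed = config$seed,
                   config_hash = config_hash(config),
                   filter_ledger = ledger)
  write_table(fits, file.path(config$outdir, "fits.tsv"))
  write_table(aggregates, file.path(config$outdir, "aggregates.tsv"))
  write_table(calls, file.path(config$outdir, "calls.tsv"))
  write_table(edges, file.path(config$outdir, "edges.tsv"))
  jsonlite::write_json(manifest,
                       file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(fits = fits, rescale_maps = maps,
                 aggregates = aggregates, calls = calls, edges = edges,
                 manifest = manifest))
}

#' Count variants entering and failing each filter
#'
#' @param fits,aggregates,calls Stage outputs of [run_pipeline()].
#' @return A named list of counts: variants fitted, failing each QC flag,
#'   usable; aggregates excluded by reason; calls by category.
#' @export
filter_ledger <- function(fits, aggregates, calls) {
  flags <- c("out_of_range", "low_cells", "poor_fit", "single_bin",
             "degenerate_occupancy")
  flag_counts <- vapply(flags, function(f)
    sum(grepl(f, fits$qc_flags, fixed = TRUE)), integer(1))
  pert <- aggregates[aggregates$role == "perturbation", , drop = FALSE]
  list(
    variants_fitted = nrow(fits),
    qc_failures = as.list(flag_counts),
    variants_usable = sum(fits$usable %in% TRUE),
    aggregates_perturbation = nrow(pert),
    aggregates_excluded = as.list(table(
      pert$exclude_reason[pert$excluded])),
    calls = as.list(table(calls$call)))
}

# stable hash of the configuration (md5 of its canonical JSON)
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  plain <- rapply(unclass(config),
                  function(x) if (is.function(x)) NULL else x,
                  how = "replace")
  jsonlite::write_json(plain, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}
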