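# Run manifests and machine-readable output emission. Every stochastic
# output produced by the analysis drivers is tied to a manifest that
# records the fully resolved parameter bundle, the seed, and any
# moment-fit repairs or non-tabulated defaults, so a run can be reproduced
# bit-for-bit.

#' Build a run manifest
#'
#' @param bundle The fully resolved `param_bundle` used by the run.
#' @param command Short name of the analysis (e.g. `"psa"`).
#' @param seed Seed used for any randomness (`NA` for deterministic runs).
#' @param flags Named list of provenance flags (repaired fits, overrides).
#' @return A list of class `"run_manifest"`.
#' @export
run_manifest <- function(bundle, command, seed = NA_integer_, flags = list()) {
  fits <- psa_fits(bundle)
  structure(list(
    command = command,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("bnpcea")),
    repaired_fits = names(fits)[vapply(fits, `[[`, logical(1), "repaired")],
    rr_log_sd_is_default = bundle$effect$rr_log_sd == 0.1,
    flags = flags,
    bundle = unclass_bundle(bundle)
  ), class = "run_manifest")
}

# Bundle snapshot as plain lists for JSON serialisation.
unclass_bundle <- function(bundle) {
  x <- unclass(bundle)
  x$transitions <- as.list(x$transitions)
  x$transition_sds <- as.list(x$transition_sds)
  x$costs <- lapply(x$costs, as.list)
  x$cost_sds <- lapply(x$cost_sds, as.list)
  x$utilities <- as.list(x$utilities)
  x$utility_sds <- as.list(x$utility_sds)
  x$config <- x$config[!vapply(x$config, is.null, logical(1))]
  x
}

#' Write a manifest (or any result list) as JSON
#'
#' @param x A `run_manifest` or plain list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' Emit a CEA result as CSV and JSON
#'
#' Writes `<stem>.csv` (table layout: per-arm cost/QALYs, increments,
#' classification) and `<stem>.json` (full structure).
#'
#' @param results A `cea_result` or labelled result list (see
#'   [cea_table()]).
#' @param stem Output path without extension.
#' @return The table, invisibly.
#' @export
emit_cea <- function(results, stem) {
  tab <- cea_table(results)
  utils::write.csv(tab, paste0(stem, ".csv"), row.names = FALSE)
  jsonlite::write_json(tab, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(tab)
}
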