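#' @title Run manifests and publication-shaped exports
#'
#' @description
#' Thin output layer used by the analysis scripts: a JSON run manifest
#' written before results so every completed run is reproducible from its
#' manifest, and CSV exports mirroring the published table layouts.
#'
#' @name cli_reporting
NULL

#' Write a run manifest
#'
#' @param path Output JSON path.
#' @param config_path Configuration file the run used.
#' @param seed Master seed.
#' @param horizon Horizon setting (years or "lifetime").
#' @param engine `"cohort"` or `"microsim"`.
#' @param out_dir Output directory of the run.
#' @param extra Optional named list merged into the manifest.
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(path, config_path, seed, horizon,
                               engine = "cohort", out_dir = dirname(path),
                               extra = list()) {
  manifest <- c(list(
    package = "ofaffcea",
    version = as.character(utils::packageVersion("ofaffcea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_path = config_path,
    seed = seed,
    horizon = horizon,
    engine = engine,
    out_dir = out_dir
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Export the pairwise results table
#'
#' @param ce_list List of `ce_result` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_ce_table <- function(ce_list, path) {
  utils::write.csv(ce_table(ce_list), path, row.names = FALSE)
  invisible(path)
}

#' Export a tornado table
#'
#' @param tornado_df Output of [tornado()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_tornado <- function(tornado_df, path) {
  utils::write.csv(tornado_df, path, row.names = FALSE)
  invisible(path)
}

#' Export an acceptability curve
#'
#' @param curve A `ceac_curve`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_ceac <- function(curve, path) {
  df <- as.data.frame(curve)
  df$intervention <- attr(curve, "intervention")
  df$comparator <- attr(curve, "comparator")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export the incremental scatter
#'
#' @param scatter Output of [incremental_scatter()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_scatter <- function(scatter, path) {
  df <- as.data.frame(scatter)
  df$intervention <- attr(scatter, "intervention")
  df$comparator <- attr(scatter, "comparator")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
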