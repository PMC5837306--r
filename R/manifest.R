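#' Build and write a run manifest
#'
#' A manifest records everything needed to re-run a command-line invocation:
#' the subcommand, the fully resolved configuration, the master seed, the
#' package version, start/end timestamps and the output paths. It is written
#' once, as JSON, beside the outputs of each run.
#'
#' @param subcommand Name of the subcommand run.
#' @param config Named list (or `scenario_config`) of resolved settings.
#' @param seed Master seed used.
#' @param outputs Character vector of files the run wrote.
#' @param started,finished POSIXct timestamps.
#' @return A list of class `"run_manifest"`.
#' @export
run_manifest <- function(subcommand, config, seed, outputs,
                         started = Sys.time(), finished = Sys.time()) {
  structure(
    list(
      subcommand = subcommand,
      config = unclass(config),
      seed = as.integer(seed),
      package_version = as.character(utils::packageVersion("collidersim")),
      started = format(started, "%Y-%m-%dT%H:%M:%S%z"),
      finished = format(finished, "%Y-%m-%dT%H:%M:%S%z"),
      outputs = as.character(outputs)
    ),
    class = "run_manifest"
  )
}

#' @rdname run_manifest
#' @param manifest A `run_manifest`.
#' @param path Destination JSON file.
#' @export
write_run_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname run_manifest
#' @export
read_run_manifest <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "run_manifest")
}
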