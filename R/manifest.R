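# Run manifests: every CLI output raster is accompanied by a small JSON
# record of the command, configuration hash, seed and file paths, so a run
# can be reproduced exactly (identical manifest minus timestamps implies
# identical outputs in single-threaded mode).

#' Build a run manifest
#'
#' @param command name of the pipeline step (e.g. "simulate", "train").
#' @param seed integer seed the step was run with.
#' @param inputs,outputs character vectors of file paths.
#' @param config configuration object; hashed (MD5 of its serialization)
#'   into `config_hash`.
#' @return a `run_manifest` list.
#' @export
run_manifest <- function(command, seed, inputs = character(),
                         outputs = character(), config = NULL) {
  hash <- NA_character_
  if (!is.null(config)) {
    tf <- tempfile()
    on.exit(unlink(tf))
    saveRDS(config, tf)
    hash <- unname(tools::md5sum(tf))
  }
  structure(
    list(command = command, seed = as.integer(seed),
         config_hash = hash,
         inputs = as.character(inputs), outputs = as.character(outputs),
         package_version = as.character(utils::packageVersion("rarefynet")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path output JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}
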