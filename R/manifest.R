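#' Build a run manifest for reproducibility
#'
#' Records everything needed to reproduce a simulation output: package
#' version, seed, input-file MD5 digests, and a timestamp. Simulation
#' outputs written by the command-line interface embed their manifest;
#' identical manifests (up to timestamp) imply identical outputs.
#'
#' @param config_paths Character vector of input/config file paths.
#' @param seed Integer seed used for the run.
#' @return A list of class `run_manifest`.
#' @export
build_run_manifest <- function(config_paths = character(0), seed = NA_integer_) {
  existing <- config_paths[file.exists(config_paths)]
  digests <- if (length(existing) > 0) {
    as.list(tools::md5sum(existing))
  } else {
    list()
  }
  structure(
    list(
      package = "mlatsim",
      version = as.character(utils::packageVersion("mlatsim")),
      seed = seed,
      inputs = digests,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    ),
    class = "run_manifest"
  )
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf(
    "<run_manifest> mlatsim %s, seed %s, %d input digest(s), %s\n",
    x$version, x$seed, length(x$inputs), x$timestamp
  ))
  invisible(x)
}

#' Write a contact summary as CSV
#'
#' @param summary A [summarize_contacts()] result.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_contact_summary <- function(summary, path) {
  stopifnot(inherits(summary, "contact_summary"))
  utils::write.csv(summary$table, path, row.names = FALSE)
  invisible(path)
}
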