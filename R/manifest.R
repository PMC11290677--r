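#' Run manifest for reproducible protocol optimization
#'
#' Records everything needed to reproduce a run — input files with MD5
#' hashes, the configuration actually used, the master seed, the package
#' version and a timestamp. Publishing these parameters alongside a proposed
#' protocol is what lets other teams replicate it.
#'
#' @param inputs Character vector of input file paths (must exist).
#' @param config List echoing the run configuration (seeds, runs, pools...).
#' @param seed Master seed of the run.
#' @return Object of class \code{"run_manifest"} (a list).
#' @export
run_manifest <- function(inputs = character(0), config = list(), seed = NA_integer_) {
  inputs <- as.character(inputs)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing)) stop("input file(s) not found: ", paste(missing, collapse = ", "))
  hashes <- if (length(inputs)) unname(tools::md5sum(inputs)) else character(0)
  structure(list(
    inputs = data.frame(path = inputs, md5 = hashes),
    config = config,
    seed = seed,
    package_version = as.character(utils::packageVersion("divopt")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest A \code{"run_manifest"}.
#' @param path Output YAML path.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  yaml::write_yaml(list(
    inputs = if (nrow(manifest$inputs)) apply(manifest$inputs, 1L, as.list, simplify = FALSE) else list(),
    config = manifest$config,
    seed = manifest$seed,
    package_version = manifest$package_version,
    timestamp = manifest$timestamp
  ), path)
  invisible(path)
}
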