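# Ground-truth manifests: the per-object truth emitted by every generator.

new_manifest <- function(kind, objects, config, extra = list()) {
  structure(
    c(list(kind = kind, objects = objects,
           config = unclass(config)), extra),
    class = "ground_truth"
  )
}

#' Objects table of a ground-truth manifest
#'
#' @param manifest A `ground_truth` object emitted by a generator.
#' @return The per-object truth table (a data frame).
#' @export
manifest_objects <- function(manifest) {
  stopifnot(inherits(manifest, "ground_truth"))
  manifest$objects
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %s: %d object(s)\n", x$kind,
              if (is.data.frame(x$objects)) nrow(x$objects) else 0L))
  invisible(x)
}

#' Write / read a ground-truth manifest as JSON
#'
#' @param manifest A `ground_truth` object.
#' @param path Output path (`.json`).
#' @return `write_manifest` returns `path` invisibly; `read_manifest` returns
#'   the reconstructed `ground_truth` object.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "ground_truth"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$objects <- as.data.frame(x$objects, stringsAsFactors = FALSE)
  structure(x, class = "ground_truth")
}
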