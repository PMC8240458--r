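#' Write a transmission matrix to a JSON container
#'
#' The container stores the real and imaginary parts of the elements
#' (row-major nested arrays, full double precision) together with the
#' provenance attributes `n_inputs`, `n_outputs`, `seed`, `rayleigh_scale`
#' and a schema version, in a single language-neutral JSON file.
#'
#' @param tm A `transmission_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_tm()]
#' @export
write_tm <- function(tm, path) {
  stopifnot(inherits(tm, "transmission_matrix"))
  obj <- list(
    schema = "fibrefocus/tm",
    version = 1L,
    n_inputs = tm$n_inputs,
    n_outputs = tm$n_outputs,
    seed = tm$seed,
    rayleigh_scale = tm$rayleigh_scale,
    re = Re(tm$elements),
    im = Im(tm$elements)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a transmission matrix from a JSON container
#'
#' @param path File written by [write_tm()].
#' @return A `transmission_matrix`.
#' @export
read_tm <- function(path) {
  obj <- read_container(path, "fibrefocus/tm")
  el <- matrix(complex(real = as.vector(obj$re), imaginary = as.vector(obj$im)),
               nrow = obj$n_outputs, ncol = obj$n_inputs)
  structure(
    list(elements = el, n_inputs = as.integer(obj$n_inputs),
         n_outputs = as.integer(obj$n_outputs),
         rayleigh_scale = obj$rayleigh_scale, seed = as.integer(obj$seed)),
    class = "transmission_matrix"
  )
}

#' Bundle probes and their measured intensities
#'
#' A measurement set is the only information the non-oracle algorithms may
#' consume: the displayed binary patterns and the recorded output
#' intensities, in matched order.
#'
#' @param probes A `probe_set`.
#' @param intensities Intensity stack from [characterize()] (M x K, one
#'   column per probe).
#' @param seed Optional provenance seed.
#' @return An object of class `measurement_set`.
#' @export
measurement_set <- function(probes, intensities, seed = NA_integer_) {
  stopifnot(inherits(probes, "probe_set"))
  if (is.null(dim(intensities))) intensities <- matrix(intensities, nrow = 1)
  if (ncol(intensities) != nrow(probes$patterns)) {
    stop("one intensity column per probe required")
  }
  structure(
    list(patterns = probes$patterns, intensities = intensities,
         probe_type = probes$type, n_inputs = probes$n_inputs,
         seed = seed),
    class = "measurement_set"
  )
}

#' @export
print.measurement_set <- function(x, ...) {
  cat(sprintf(
    "<measurement_set> %d %s probes, %d output pixel(s)\n",
    nrow(x$patterns), x$probe_type, nrow(x$intensities)
  ))
  invisible(x)
}

#' Write / read a measurement set container
#'
#' Lossless JSON round-trip of the probe patterns (integers) and intensities
#' (full double precision), with the probe type and seed as attributes.
#'
#' @param mset A `measurement_set`.
#' @param path File path.
#' @return `write_measurement_set()` returns `path` invisibly;
#'   `read_measurement_set()` returns a `measurement_set`.
#' @export
write_measurement_set <- function(mset, path) {
  stopifnot(inherits(mset, "measurement_set"))
  obj <- list(
    schema = "fibrefocus/measurement_set",
    version = 1L,
    probe_type = mset$probe_type,
    n_inputs = mset$n_inputs,
    seed = mset$seed,
    patterns = mset$patterns,
    intensities = mset$intensities
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_measurement_set
#' @export
read_measurement_set <- function(path) {
  obj <- read_container(path, "fibrefocus/measurement_set")
  patterns <- as.matrix(obj$patterns)
  storage.mode(patterns) <- "integer"
  intensities <- as.matrix(obj$intensities)
  structure(
    list(patterns = patterns, intensities = intensities,
         probe_type = obj$probe_type, n_inputs = as.integer(obj$n_inputs),
         seed = obj$seed),
    class = "measurement_set"
  )
}

# Shared container reader with schema validation.
read_container <- function(path, schema) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  obj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) {
      stop(sprintf("cannot parse container %s: %s", path,
                   conditionMessage(e)), call. = FALSE)
    }
  )
  if (!identical(obj$schema, schema)) {
    stop(sprintf("container schema mismatch: expected %s, found %s",
                 schema, if (is.null(obj$schema)) "<none>" else obj$schema))
  }
  if (!identical(as.integer(obj$version), 1L)) {
    stop(sprintf("unsupported container version %s", obj$version))
  }
  obj
}

#' Replay a stored measurement set as a measurement callback
#'
#' Returns a callback with the same interface as [tm_measure()] that looks
#' up each requested pattern in the stored set and returns its recorded
#' intensities, so that characterisation code can run unchanged on saved
#' (e.g. experimental) data.
#'
#' @param mset A `measurement_set`.
#' @return A function `f(patterns)`; requesting a pattern that was not
#'   recorded is an error.
#' @export
replay_measure <- function(mset) {
  stopifnot(inherits(mset, "measurement_set"))
  keys <- apply(mset$patterns, 1, paste, collapse = "")
  count <- 0L
  f <- function(patterns) {
    single <- is.null(dim(patterns))
    pats <- if (single) matrix(patterns, nrow = 1) else patterns
    k <- match(apply(pats, 1, paste, collapse = ""), keys)
    if (anyNA(k)) stop("pattern not present in the measurement set")
    count <<- count + length(k)
    out <- mset$intensities[, k, drop = FALSE]
    if (single) as.vector(out) else out
  }
  class(f) <- c("tm_measure", "function")
  f
}

#' Export an intensity frame as a 32-bit float TIFF
#'
#' Writes the frame as 32-bit samples via the `tiff` package, whose storage
#' is defined on `[0, 1]`; intensities are therefore normalised by their
#' maximum before writing (the stated normalisation), and the scale factor
#' is returned so the caller can record it.
#'
#' @param intensity Non-negative numeric vector with a square length, or a
#'   matrix.
#' @param path Output TIFF path.
#' @param normalize Divide by the maximum before writing (default TRUE).
#'   With `normalize = FALSE` the values must already lie in `[0, 1]`.
#' @return `path`, invisibly, with attribute `scale` (the maximum divided
#'   out, or 1). Requires the `tiff` package.
#' @export
write_intensity_tiff <- function(intensity, path, normalize = TRUE) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    stop("package 'tiff' is required for TIFF export")
  }
  img <- if (is.null(dim(intensity))) {
    side <- sqrt(length(intensity))
    if (side != floor(side)) stop("vector intensity must have square length")
    matrix(intensity, side, side)
  } else {
    intensity
  }
  scale <- 1
  if (normalize && max(img) > 0) {
    scale <- max(img)
    img <- img / scale
  } else if (max(img) > 1 || min(img) < 0) {
    stop("with normalize = FALSE, intensities must lie in [0, 1]")
  }
  tiff::writeTIFF(img, path, bits.per.sample = 32L, reduce = FALSE)
  out <- path
  attr(out, "scale") <- scale
  invisible(out)
}
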