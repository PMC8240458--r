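#' Random transmission-matrix model of a multimode fibre
#'
#' A multimode fibre (or any strongly scattering medium) is modelled as a
#' complex transmission matrix \eqn{T} with `n_outputs` rows (output speckle
#' pixels) and `n_inputs` columns (controllable input segments, i.e. DMD
#' micromirror groups). Element \eqn{t_{mn}} carries the field amplitude and
#' phase change from input mode *n* to output mode *m*. Phases are i.i.d.
#' uniform on \eqn{(-\pi, \pi]}; amplitudes are i.i.d. Rayleigh with scale
#' `rayleigh_scale`, resampled until they fall in \eqn{[0, 1]}.
#'
#' @param n_inputs Number of input modes N (columns). Must be a power of two
#'   for Hadamard characterisation, but any positive integer is accepted here.
#' @param n_outputs Number of output pixels M (rows).
#' @param rayleigh_scale Rayleigh scale parameter of the amplitude
#'   distribution; draws above 1 are resampled. Default 0.3 keeps the
#'   truncation mass negligible (< 0.4%).
#' @param seed Integer seed; sampling is deterministic given the seed.
#' @return An object of class `transmission_matrix` with fields `elements`
#'   (complex `n_outputs` x `n_inputs` matrix), `n_inputs`, `n_outputs`,
#'   `seed`, `rayleigh_scale`.
#' @examples
#' tm <- sample_tm(16, 64, seed = 1)
#' dim(tm$elements)
#' @export
sample_tm <- function(n_inputs, n_outputs, rayleigh_scale = 0.3, seed) {
  if (!is.numeric(n_inputs) || length(n_inputs) != 1 || n_inputs < 1 ||
      n_inputs != round(n_inputs)) {
    stop("`n_inputs` must be a positive integer")
  }
  if (!is.numeric(n_outputs) || length(n_outputs) != 1 || n_outputs < 1 ||
      n_outputs != round(n_outputs)) {
    stop("`n_outputs` must be a positive integer")
  }
  if (!is.numeric(rayleigh_scale) || rayleigh_scale <= 0) {
    stop("`rayleigh_scale` must be positive")
  }
  if (missing(seed)) stop("`seed` is required for reproducibility")
  n_el <- n_outputs * n_inputs
  el <- with_stream_seed(as.integer(seed), {
    phases <- stats::runif(n_el, 0, 2 * pi)
    amps <- rayleigh_unit(n_el, rayleigh_scale)
    amps * exp(1i * wrap_phase(phases))
  })
  structure(
    list(
      elements = matrix(el, nrow = n_outputs, ncol = n_inputs),
      n_inputs = as.integer(n_inputs),
      n_outputs = as.integer(n_outputs),
      rayleigh_scale = rayleigh_scale,
      seed = as.integer(seed)
    ),
    class = "transmission_matrix"
  )
}

# Rayleigh(scale) draws restricted to [0, 1] by resampling, so the shape on
# [0, 1] is the (renormalised) Rayleigh density.
rayleigh_unit <- function(n, scale) {
  x <- scale * sqrt(-2 * log(stats::runif(n)))
  bad <- which(x > 1)
  while (length(bad)) {
    x[bad] <- scale * sqrt(-2 * log(stats::runif(length(bad))))
    bad <- bad[x[bad] > 1]
  }
  x
}

#' @export
print.transmission_matrix <- function(x, ...) {
  cat(sprintf(
    "<transmission_matrix> %d outputs x %d inputs (rayleigh_scale = %g, seed = %d)\n",
    x$n_outputs, x$n_inputs, x$rayleigh_scale, x$seed
  ))
  invisible(x)
}

#' Wrap phases into (-pi, pi]
#'
#' @param x Numeric vector of angles in radians.
#' @return Angles wrapped into the half-open interval \eqn{(-\pi, \pi]}.
#' @examples
#' wrap_phase(c(0, 3 * pi, -pi))
#' @export
wrap_phase <- function(x) {
  y <- -((-x + pi) %% (2 * pi) - pi) # maps to [-pi, pi), open at +pi side...
  # the formula above lands in (-pi, pi]: values equal to -pi map to +pi
  y[y == -pi] <- pi
  y
}

#' Propagate binary patterns through a transmission matrix
#'
#' Computes the output field \eqn{E_m = \sum_{n\,\mathrm{ON}} t_{mn}} and
#' intensity \eqn{I_m = |E_m|^2} for one or more binary DMD patterns. The
#' incident field is uniform with unit amplitude across ON mirrors; OFF
#' mirrors contribute nothing.
#'
#' @param tm A `transmission_matrix`.
#' @param pattern Binary vector of length `n_inputs` (1 = mirror ON), or a
#'   matrix with one pattern per column (`n_inputs` x B).
#' @return For a single pattern, a list with `field` (complex length-M vector)
#'   and `intensity` (non-negative length-M vector). For a pattern matrix, the
#'   same with M x B matrices.
#' @examples
#' tm <- sample_tm(8, 16, seed = 1)
#' out <- propagate(tm, rep(1, 8))
#' all(out$intensity >= 0)
#' @export
propagate <- function(tm, pattern) {
  stopifnot(inherits(tm, "transmission_matrix"))
  single <- is.null(dim(pattern))
  pat <- if (single) matrix(pattern, ncol = 1) else pattern
  if (nrow(pat) != tm$n_inputs) {
    stop(sprintf(
      "pattern length %d does not match n_inputs %d", nrow(pat), tm$n_inputs
    ))
  }
  if (!all(pat %in% c(0, 1))) stop("pattern entries must be 0 or 1")
  field <- tm$elements %*% pat
  intensity <- Mod(field)^2
  if (single) {
    list(field = as.vector(field), intensity = as.vector(intensity))
  } else {
    list(field = field, intensity = intensity)
  }
}

#' Additive Gaussian measurement-noise model
#'
#' The signal-to-noise ratio is defined as the mean intensity of the
#' (noiseless) frame divided by the noise standard deviation. Noise is
#' additive, zero-mean Gaussian on intensities, and negative results are
#' clipped to zero.
#'
#' @param snr Positive signal-to-noise ratio.
#' @param seed Integer seed for the noise stream.
#' @return An object of class `noise_model`.
#' @examples
#' nm <- noise_model(33.3, seed = 2)
#' @export
noise_model <- function(snr, seed = 0) {
  if (!is.numeric(snr) || length(snr) != 1 || !is.finite(snr) || snr <= 0) {
    stop("`snr` must be a positive number")
  }
  structure(list(snr = snr, seed = as.integer(seed)), class = "noise_model")
}

#' Add measurement noise to an intensity record
#'
#' @param intensity Non-negative numeric vector or matrix of intensities.
#' @param noise A `noise_model`.
#' @param draw Integer draw index; successive measurement frames should use
#'   successive draw indices so that each frame's noise is independent yet
#'   reproducible.
#' @return Intensities with i.i.d. Gaussian noise of standard deviation
#'   `mean(intensity) / snr` added and negative values clipped to 0.
#' @examples
#' nm <- noise_model(10, seed = 1)
#' add_noise(rep(1, 5), nm)
#' @export
add_noise <- function(intensity, noise, draw = 0) {
  stopifnot(inherits(noise, "noise_model"))
  if (any(intensity < 0)) stop("intensity must be non-negative")
  sd <- mean(intensity) / noise$snr
  if (sd == 0) return(intensity) # a dark frame stays dark
  eps <- with_stream_seed(
    derive_seed(noise$seed, "noise", draw),
    stats::rnorm(length(intensity), mean = 0, sd = sd)
  )
  out <- intensity + eps
  out[out < 0] <- 0
  out
}

#' Peak-to-background ratio of an output intensity pattern
#'
#' The PBR is the intensity at the focus pixel divided by the mean intensity
#' over the background, i.e. all other pixels outside an optional exclusion
#' window around the focus.
#'
#' @param intensity Non-negative numeric vector (optionally with a `dim`
#'   attribute giving the 2-D frame shape).
#' @param target_index Index of the focus pixel (column-major if `intensity`
#'   is a matrix).
#' @param exclusion_radius Chebyshev radius of the window excluded from the
#'   background around the focus; 0 (default) excludes only the focus pixel.
#'   Radii > 0 require a 2-D `intensity`.
#' @return A single positive number.
#' @examples
#' pbr(c(10, 1, 1, 1), target_index = 1)
#' @export
pbr <- function(intensity, target_index, exclusion_radius = 0) {
  n <- length(intensity)
  if (n < 2) stop("need more than one pixel to define a background")
  if (target_index < 1 || target_index > n) stop("invalid target_index")
  excl <- target_index
  if (exclusion_radius > 0) {
    if (is.null(dim(intensity))) {
      stop("exclusion_radius > 0 requires a 2-D intensity (set dim())")
    }
    d <- dim(intensity)
    rc <- arrayInd(target_index, d)
    rows <- pmax(1, rc[1] - exclusion_radius):pmin(d[1], rc[1] + exclusion_radius)
    cols <- pmax(1, rc[2] - exclusion_radius):pmin(d[2], rc[2] + exclusion_radius)
    excl <- as.vector(outer(rows, cols, function(r, c) r + (c - 1) * d[1]))
  }
  bg <- mean(intensity[-excl])
  if (bg == 0) stop("background mean is zero; PBR undefined")
  as.numeric(intensity[target_index]) / bg
}

#' Output field with all mirrors ON (the reference field)
#'
#' The all-ON output field at the target pixel defines the reference
#' amplitude \eqn{A_R} and phase \eqn{\phi_R} against which per-mirror phases
#' are compared by the phase-criterion masks.
#'
#' @param tm A `transmission_matrix`.
#' @param target_index Output pixel index.
#' @return A list with `amplitude` (\eqn{A_R = |\sum_n t_{mn}|}) and `phase`
#'   (\eqn{\phi_R = \arg \sum_n t_{mn}}, in \eqn{(-\pi, \pi]}).
#' @examples
#' tm <- sample_tm(8, 4, seed = 1)
#' reference_field(tm, 2)
#' @export
reference_field <- function(tm, target_index) {
  stopifnot(inherits(tm, "transmission_matrix"))
  if (target_index < 1 || target_index > tm$n_outputs) {
    stop("invalid target_index")
  }
  s <- sum(tm$elements[target_index, ])
  list(amplitude = Mod(s), phase = wrap_phase(Arg(s)))
}

#' Ground-truth phase-criterion mask
#'
#' Using the known transmission matrix, switches ON every mirror whose phase
#' lies within `phase_bound` of the all-ON reference phase \eqn{\phi_R}:
#' mirror *n* is ON iff \eqn{|\theta_{mn} - \phi_R|} (wrapped into
#' \eqn{(-\pi, \pi]}) is `< phase_bound`. This is the oracle that estimation
#' algorithms try to match; `phase_bound = pi/2` maximises peak intensity and
#' `optimal_phase_bound()` maximises the PBR.
#'
#' @param tm A `transmission_matrix`.
#' @param target_index Output pixel to focus on.
#' @param phase_bound Phase half-window in radians, in \eqn{(0, \pi]}.
#' @return Integer 0/1 vector of length `n_inputs`.
#' @examples
#' tm <- sample_tm(16, 8, seed = 1)
#' mask <- oracle_mask(tm, 4, pi / 2)
#' mean(mask) # about one half for uniform phases
#' @export
oracle_mask <- function(tm, target_index, phase_bound) {
  stopifnot(inherits(tm, "transmission_matrix"))
  if (!is.numeric(phase_bound) || phase_bound <= 0 || phase_bound > pi) {
    stop("`phase_bound` must be in (0, pi]")
  }
  ref <- reference_field(tm, target_index)
  theta <- Arg(tm$elements[target_index, ])
  as.integer(abs(wrap_phase(theta - ref$phase)) < phase_bound)
}

#' Default focus target: the central output pixel
#'
#' @param tm A `transmission_matrix`, or the number of output pixels.
#' @return The column-major index of the centre of the (assumed square)
#'   output frame, or simply `floor(M/2) + 1` if M is not a perfect square.
#' @examples
#' central_target(sample_tm(4, 16, seed = 1))
#' @export
central_target <- function(tm) {
  m <- if (inherits(tm, "transmission_matrix")) tm$n_outputs else as.integer(tm)
  side <- sqrt(m)
  if (side == floor(side)) {
    mid <- ceiling(side / 2)
    as.integer((mid - 1) * side + mid)
  } else {
    as.integer(m %/% 2 + 1)
  }
}

#' Measurement callback for a simulated medium
#'
#' Builds the function that every characterisation and optimisation routine
#' uses to "display" DMD patterns and record output intensities. The callback
#' accepts a single pattern (length-N vector) or a probe matrix with one
#' pattern per row (K x N) and returns intensities: a vector (or M x K
#' matrix) over all output pixels, or over `rows` only when a subset is
#' requested (e.g. the target row during characterisation). Optionally adds
#' measurement noise per frame. The callback counts how many patterns it has
#' measured; read the count with [measurement_count()].
#'
#' @param tm A `transmission_matrix`.
#' @param rows Optional integer vector of output pixels to record; `NULL`
#'   records the full frame.
#' @param noise Optional `noise_model` applied independently to each frame.
#' @return A function `f(patterns)` as described.
#' @examples
#' tm <- sample_tm(8, 16, seed = 1)
#' measure <- tm_measure(tm)
#' i <- measure(rep(1, 8))
#' measurement_count(measure)
#' @export
tm_measure <- function(tm, rows = NULL, noise = NULL) {
  stopifnot(inherits(tm, "transmission_matrix"))
  if (!is.null(noise)) stopifnot(inherits(noise, "noise_model"))
  # Noise is referenced to the mean of the full camera frame, so noisy
  # measurements always propagate every output pixel; the row restriction
  # then only selects what is returned.
  el <- if (is.null(rows) || !is.null(noise)) {
    tm$elements
  } else {
    tm$elements[rows, , drop = FALSE]
  }
  count <- 0L
  f <- function(patterns) {
    single <- is.null(dim(patterns))
    pat <- if (single) matrix(patterns, ncol = 1) else t(patterns)
    if (nrow(pat) != ncol(el)) stop("pattern length does not match n_inputs")
    intensity <- Mod(el %*% pat)^2
    if (!is.null(noise)) {
      for (k in seq_len(ncol(intensity))) {
        intensity[, k] <- add_noise(intensity[, k], noise, draw = count + k)
      }
      if (!is.null(rows)) intensity <- intensity[rows, , drop = FALSE]
    }
    count <<- count + ncol(pat)
    if (single) as.vector(intensity) else intensity
  }
  class(f) <- c("tm_measure", "function")
  f
}

#' Number of patterns measured so far by a callback
#'
#' @param measure A callback created by [tm_measure()] or [replay_measure()].
#' @return Integer count of measured patterns.
#' @export
measurement_count <- function(measure) {
  environment(measure)$count
}
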