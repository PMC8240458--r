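#' Random binary probe set
#'
#' Generates i.i.d. Bernoulli binary patterns for reference-less
#' characterisation. The default budget used by both the intensity-only
#' phase-retrieval and conditional-probability methods is 6N patterns with
#' 50% of mirrors ON.
#'
#' @param n_inputs Number of input modes N.
#' @param count Number of patterns K (default `6 * n_inputs`).
#' @param on_fraction Probability that a mirror is ON, in (0, 1).
#' @param seed Integer seed.
#' @return A `probe_set` with `patterns` (K x N 0/1 matrix, one pattern per
#'   row), `type = "random_binary"`, `on_fraction`, `seed`.
#' @examples
#' p <- random_probes(32, seed = 1)
#' nrow(p$patterns) # 192
#' @export
random_probes <- function(n_inputs, count = 6 * n_inputs, on_fraction = 0.5,
                          seed) {
  stopifnot(is.numeric(n_inputs), n_inputs >= 1)
  if (!is.numeric(count) || count < 1) stop("`count` must be >= 1")
  if (!is.numeric(on_fraction) || on_fraction <= 0 || on_fraction >= 1) {
    stop("`on_fraction` must be in (0, 1)")
  }
  if (missing(seed)) stop("`seed` is required for reproducibility")
  patterns <- with_stream_seed(
    derive_seed(seed, "patterns"),
    matrix(stats::rbinom(count * n_inputs, 1L, on_fraction),
           nrow = count, ncol = n_inputs)
  )
  storage.mode(patterns) <- "integer"
  structure(
    list(patterns = patterns, n_inputs = as.integer(n_inputs),
         type = "random_binary", on_fraction = on_fraction,
         seed = as.integer(seed)),
    class = "probe_set"
  )
}

#' Intensity-only retrieval of a transmission-matrix row
#'
#' Estimates the complex row \eqn{t_{m\cdot}} of the transmission matrix from
#' intensity-only measurements \eqn{y_k = |p_k \cdot t|^2} under binary
#' probes, by alternating projections (error reduction): given a current
#' estimate, the measured amplitudes \eqn{\sqrt{y_k}} are imposed on the
#' predicted fields keeping their phases, and the row is re-fitted by least
#' squares. The iterate starts from a spectral initialisation (leading
#' eigenvector of the intensity-weighted covariance of the centred probes)
#' plus a small seeded complex perturbation; because the probe vectors are
#' real, a purely real iterate would be a fixed subspace, and the recovered
#' row carries both a global-phase and a complex-conjugation ambiguity,
#' neither of which affects the focusing masks built from it.
#'
#' If the final fit residual exceeds `tol` (relative to the mean intensity),
#' the solve is repeated from random complex starts (up to `n_restarts`) and
#' the best run is kept.
#'
#' @param probes A `probe_set` (rows = patterns).
#' @param target_intensities Numeric vector, one intensity per probe, at the
#'   target output pixel.
#' @param n_iterations Iteration budget per start (default 200, at which the
#'   estimate has converged for the default 6N probe budget).
#' @param n_restarts Maximum extra random starts on poor convergence.
#' @param tol Relative residual threshold that triggers a restart.
#' @param seed Integer seed for the perturbation/restarts.
#' @return An object of class `estimated_row`: list with `values` (complex
#'   length-N vector), `n_iterations`, `trace` (fit objective per iteration,
#'   non-increasing within each start), `restarts`, `converged`.
#' @examples
#' tm <- sample_tm(16, 4, seed = 1)
#' probes <- random_probes(16, seed = 2)
#' y <- as.vector(characterize(tm_measure(tm, rows = 2), probes))
#' est <- retrieve_row(probes, y, n_iterations = 100, seed = 3)
#' @export
retrieve_row <- function(probes, target_intensities, n_iterations = 200,
                         n_restarts = 2, tol = 1e-6, seed = 1) {
  stopifnot(inherits(probes, "probe_set"))
  a <- probes$patterns
  storage.mode(a) <- "double"
  y <- as.numeric(target_intensities)
  if (length(y) != nrow(a)) {
    stop("need exactly one target intensity per probe")
  }
  if (n_iterations < 1) stop("`n_iterations` must be >= 1")
  scale_y <- mean(y)
  if (scale_y == 0) stop("all target intensities are zero")

  # Precompute the normal equations once; each iteration then costs two
  # real GEMMs plus two triangular solves. A singular Gram matrix means the
  # probes do not span the input modes (e.g. all probes identical).
  ata <- crossprod(a)
  rchol <- tryCatch(
    chol(ata),
    error = function(e) {
      stop("probe patterns are rank deficient; cannot retrieve the row",
           call. = FALSE)
    }
  )
  amp <- sqrt(y)

  run_from <- function(t0) {
    tt <- cbind(Re(t0), Im(t0)) # N x 2, real arithmetic throughout
    trace <- numeric(n_iterations)
    for (it in seq_len(n_iterations)) {
      f <- a %*% tt # K x 2: Re and Im of predicted fields
      fm <- sqrt(f[, 1]^2 + f[, 2]^2)
      fm[fm == 0] <- 1
      z <- (amp / fm) * f # measured amplitude, predicted phase
      trace[it] <- mean((f[, 1] - z[, 1])^2 + (f[, 2] - z[, 2])^2)
      tt <- backsolve(rchol, backsolve(rchol, crossprod(a, z),
                                       transpose = TRUE))
    }
    list(values = complex(real = tt[, 1], imaginary = tt[, 2]),
         trace = trace)
  }

  # Spectral start: leading eigenvector of the centred, intensity-weighted
  # probe covariance, complexified by a small seeded perturbation.
  ac <- sweep(a, 2, colMeans(a))
  cm <- crossprod(ac, (y - scale_y) * ac) / nrow(a)
  v <- eigen(cm, symmetric = TRUE)$vectors[, 1]
  starts <- c(
    list(with_stream_seed(
      derive_seed(seed, "pr-init"),
      v + 1i * 0.3 * sqrt(sum(v^2) / length(v)) * stats::rnorm(length(v))
    )),
    lapply(seq_len(n_restarts), function(r) {
      with_stream_seed(
        derive_seed(seed, "pr-restart", r),
        complex(real = stats::rnorm(ncol(a)),
                imaginary = stats::rnorm(ncol(a)))
      )
    })
  )

  best <- NULL
  restarts_used <- -1L
  for (t0 in starts) {
    res <- run_from(t0)
    restarts_used <- restarts_used + 1L
    if (is.null(best) ||
        res$trace[n_iterations] < best$trace[n_iterations]) {
      best <- res
    }
    if (best$trace[n_iterations] / scale_y <= tol) break
  }
  structure(
    list(values = best$values, n_iterations = as.integer(n_iterations),
         trace = best$trace, restarts = restarts_used,
         converged = best$trace[n_iterations] / scale_y <= tol),
    class = "estimated_row"
  )
}

#' @export
print.estimated_row <- function(x, ...) {
  cat(sprintf(
    "<estimated_row> N = %d, %d iterations, final residual %.3g%s\n",
    length(x$values), x$n_iterations, x$trace[length(x$trace)],
    if (x$converged) "" else " (not converged)"
  ))
  invisible(x)
}

#' Recovery quality of an estimated row
#'
#' Normalised modulus of the inner product between estimate and truth,
#' \eqn{|\langle \hat t, t\rangle| / (\|\hat t\| \|t\|) \in [0, 1]}, which is
#' invariant to the global-phase ambiguity of intensity-only data. With real
#' probe vectors the conjugate of the truth produces identical intensities,
#' so by default the better of the direct and conjugated comparisons is
#' returned.
#'
#' @param estimate Complex vector or `estimated_row`.
#' @param truth Complex vector of the same length.
#' @param allow_conjugate Also consider `Conj(truth)` (default TRUE).
#' @return A number in `[0, 1]`.
#' @export
row_recovery_quality <- function(estimate, truth, allow_conjugate = TRUE) {
  est <- if (inherits(estimate, "estimated_row")) estimate$values else estimate
  stopifnot(length(est) == length(truth))
  denom <- sqrt(sum(Mod(est)^2) * sum(Mod(truth)^2))
  if (denom == 0) return(0)
  q <- Mod(sum(Conj(est) * truth)) / denom
  if (allow_conjugate) q <- max(q, Mod(sum(est * truth)) / denom)
  q
}

#' Rotate an estimate onto a reference row
#'
#' Multiplies the estimate by the unit complex number that minimises the L2
#' distance to the reference (the phase of their inner product), removing the
#' global-phase ambiguity for element-wise comparison.
#'
#' @param estimate Complex vector or `estimated_row`.
#' @param reference_row Complex vector of the same length.
#' @return The rotated complex vector. If the inner product is exactly zero
#'   the estimate is returned unchanged with attribute `aligned = FALSE` and
#'   a warning.
#' @examples
#' ref <- c(1 + 0i, 2i)
#' align_global_phase(1i * ref, ref)
#' @export
align_global_phase <- function(estimate, reference_row) {
  est <- if (inherits(estimate, "estimated_row")) estimate$values else estimate
  stopifnot(length(est) == length(reference_row))
  ip <- sum(Conj(est) * reference_row)
  if (Mod(ip) == 0) {
    warning("estimate is orthogonal to the reference; no rotation applied")
    attr(est, "aligned") <- FALSE
    return(est)
  }
  est * exp(1i * Arg(ip))
}

#' Phase-criterion mask from an estimated row
#'
#' Switches ON every mirror whose estimated phase lies within `phase_bound`
#' of a reference phase. With `reference_phase_mode = "all-on"` (default) the
#' reference is the phase of the estimated all-ON field,
#' \eqn{\arg \sum_n \hat t_{mn}}, matching the convention of
#' [oracle_mask()]; this also makes the mask invariant to the global-phase
#' (and conjugation) ambiguity of the estimate. `"zero"` uses reference phase
#' 0, i.e. the classic \eqn{\mathrm{Re}(\hat t_{mn}) > 0} criterion at
#' `phase_bound = pi/2` in the estimate's own gauge.
#'
#' @param estimated_row An `estimated_row` or complex vector.
#' @param phase_bound Phase half-window in radians, in \eqn{(0, \pi]}.
#' @param reference_phase_mode `"all-on"` (default) or `"zero"`.
#' @return Integer 0/1 mask.
#' @examples
#' mask_from_phase(c(1 + 0i, -1 + 0i, 1i), pi / 2, "zero")
#' @export
mask_from_phase <- function(estimated_row, phase_bound,
                            reference_phase_mode = c("all-on", "zero")) {
  values <- if (inherits(estimated_row, "estimated_row")) {
    estimated_row$values
  } else {
    estimated_row
  }
  if (!is.numeric(phase_bound) || phase_bound <= 0 || phase_bound > pi) {
    stop("`phase_bound` must be in (0, pi]")
  }
  mode <- match.arg(reference_phase_mode)
  phi_ref <- if (mode == "all-on") Arg(sum(values)) else 0
  as.integer(abs(wrap_phase(Arg(values) - phi_ref)) < phase_bound)
}
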