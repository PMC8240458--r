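#' Complementary Hadamard probe set
#'
#' Builds the 2N binary probe patterns of the real-valued intensity
#' transmission matrix (RVITM) characterisation. From the Sylvester-ordered
#' Hadamard matrix \eqn{H \in \{-1, +1\}^{N \times N}} two binary pattern
#' sets are formed, \eqn{H_1 = (H + 1)/2} and \eqn{H_2 = (-H + 1)/2}; pattern
#' *k* of \eqn{H_2} is the mirror-wise complement of pattern *k* of
#' \eqn{H_1}. The first pattern of \eqn{H_1} is all-ON and the first of
#' \eqn{H_2} all-OFF.
#'
#' @param n_inputs Number of input modes N; must be a power of two.
#' @return An object of class `probe_set` with fields `patterns` (2N x N 0/1
#'   matrix, one pattern per row: the N rows of \eqn{H_1} then the N rows of
#'   \eqn{H_2}), `hadamard` (the N x N \eqn{\pm 1} matrix), `n_inputs`, and
#'   `type = "hadamard"`.
#' @examples
#' p <- hadamard_probes(4)
#' dim(p$patterns)
#' @export
hadamard_probes <- function(n_inputs) {
  n <- as.integer(n_inputs)
  if (n < 1 || bitwAnd(n, n - 1L) != 0L) {
    stop("`n_inputs` must be a power of 2 for Hadamard characterisation")
  }
  h <- matrix(1, 1, 1)
  while (nrow(h) < n) h <- rbind(cbind(h, h), cbind(h, -h))
  patterns <- rbind((h + 1) / 2, (-h + 1) / 2)
  storage.mode(patterns) <- "integer"
  structure(
    list(patterns = patterns, hadamard = h, n_inputs = n, type = "hadamard"),
    class = "probe_set"
  )
}

#' @export
print.probe_set <- function(x, ...) {
  cat(sprintf(
    "<probe_set> %d %s patterns of length %d\n",
    nrow(x$patterns), x$type, x$n_inputs
  ))
  invisible(x)
}

#' Record output intensities for a probe set
#'
#' Displays every probe pattern through a measurement callback and collects
#' the responses column-by-column, preserving probe order. The callback is
#' typically [tm_measure()] (simulation, optionally noisy) or
#' [replay_measure()] (stored data).
#'
#' @param measure A measurement callback mapping patterns to intensities.
#' @param probes A `probe_set`.
#' @return An intensity stack: matrix with one column per probe (M x K, where
#'   M is the number of recorded output pixels).
#' @examples
#' tm <- sample_tm(8, 4, seed = 1)
#' stack <- characterize(tm_measure(tm), hadamard_probes(8))
#' dim(stack)
#' @export
characterize <- function(measure, probes) {
  stopifnot(inherits(probes, "probe_set"))
  out <- tryCatch(
    measure(probes$patterns),
    error = function(e) {
      # replay one-by-one to attribute the failure to a probe index
      for (k in seq_len(nrow(probes$patterns))) {
        ok <- tryCatch({
          measure(probes$patterns[k, ])
          TRUE
        }, error = function(e2) FALSE)
        if (!ok) stop(sprintf("measurement failed at probe %d: %s",
                              k, conditionMessage(e)), call. = FALSE)
      }
      stop(e)
    }
  )
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  out
}

#' RVITM row from complementary Hadamard intensities
#'
#' Reconstructs the intensity-transmission constants
#' \eqn{rvit_{mn} = A_{mn} A_R \cos(\theta_{mn} - \phi_R)} of one output mode
#' from the 2N Hadamard probe intensities, via the complementary-pair
#' differential
#' \deqn{rvit_{mn} = \frac{1}{N} \sum_{k=1}^{N}
#'   \left(I_m^{H_1,k} - I_m^{H_2,k}\right) h_{nk}.}
#' On noiseless simulated data this equals the product form above exactly
#' (Hadamard orthogonality); under noise the differential cancels
#' common-mode errors of the complementary pair.
#'
#' @param intensity_stack Matrix with 2N columns as returned by
#'   [characterize()] on [hadamard_probes()].
#' @param probes The `probe_set` used for the measurement.
#' @param target_index Row of the stack to reconstruct (output pixel). When
#'   the stack was recorded with a row-restricted callback, this indexes the
#'   recorded rows.
#' @return An object of class `rvitm_row`: list with `values` (numeric length
#'   N) and `target_index`.
#' @examples
#' tm <- sample_tm(8, 4, seed = 1)
#' probes <- hadamard_probes(8)
#' stack <- characterize(tm_measure(tm), probes)
#' row <- compute_rvitm(stack, probes, 2)
#' @export
compute_rvitm <- function(intensity_stack, probes, target_index) {
  stopifnot(inherits(probes, "probe_set"))
  if (probes$type != "hadamard") {
    stop("RVITM reconstruction requires Hadamard probes")
  }
  n <- probes$n_inputs
  if (is.null(dim(intensity_stack))) {
    intensity_stack <- matrix(intensity_stack, nrow = 1)
  }
  if (ncol(intensity_stack) != 2 * n) {
    stop(sprintf("intensity stack has %d columns; expected 2N = %d",
                 ncol(intensity_stack), 2 * n))
  }
  if (target_index < 1 || target_index > nrow(intensity_stack)) {
    stop("invalid target_index")
  }
  i1 <- intensity_stack[target_index, seq_len(n)]
  i2 <- intensity_stack[target_index, n + seq_len(n)]
  values <- as.vector((i1 - i2) %*% probes$hadamard) / n
  structure(
    list(values = values, target_index = as.integer(target_index)),
    class = "rvitm_row"
  )
}

#' Top-P threshold mask from an RVITM row
#'
#' Ranks mirrors by their \eqn{rvit_{mn}} value (descending, ties broken by
#' mirror index) and switches ON the top `round(P/100 * N)` mirrors
#' (round-half-up). `p = 50` reproduces, for a symmetric rvit distribution,
#' the classic positive-rvit criterion; smaller P trades peak intensity for
#' background suppression.
#'
#' @param row An `rvitm_row`, or a plain numeric vector of rvit values.
#' @param p Percentage of mirrors to switch ON, in (0, 100].
#' @return Integer 0/1 mask of length N.
#' @examples
#' mask_top_p(c(3, 1, -2, -5), 50) # mirrors 1 and 2 ON
#' @export
mask_top_p <- function(row, p) {
  values <- if (inherits(row, "rvitm_row")) row$values else row
  if (!is.numeric(p) || length(p) != 1 || p <= 0 || p > 100) {
    stop("`p` must be in (0, 100]")
  }
  n <- length(values)
  k <- floor(p / 100 * n + 0.5) # round half up
  mask <- integer(n)
  if (k > 0) mask[order(-values, seq_len(n))[seq_len(k)]] <- 1L
  mask
}

#' Sweep the ON-percentage of the RVITM mask
#'
#' Evaluates [mask_top_p()] for each P on a grid, propagates each mask
#' through the medium via the measurement callback (which must record the
#' full output frame) and reports peak intensity and PBR per P.
#'
#' @param row An `rvitm_row` or numeric vector of rvit values.
#' @param measure Full-frame measurement callback (e.g. [tm_measure()]).
#' @param target_index Focus pixel index in the measured frame.
#' @param p_grid Percentages to evaluate (default 5, 10, ..., 100).
#' @return A data frame with columns `p`, `peak`, `pbr`, with attribute
#'   `argmax_p`, the grid P maximising PBR.
#' @examples
#' tm <- sample_tm(16, 64, seed = 1)
#' probes <- hadamard_probes(16)
#' row <- compute_rvitm(characterize(tm_measure(tm), probes), probes, 5)
#' sweep <- p_sweep(row, tm_measure(tm), 5, p_grid = c(30, 50))
#' @export
p_sweep <- function(row, measure, target_index, p_grid = seq(5, 100, by = 5)) {
  if (any(p_grid <= 0 | p_grid > 100)) stop("p_grid must lie in (0, 100]")
  masks <- vapply(
    p_grid, function(p) mask_top_p(row, p),
    integer(if (inherits(row, "rvitm_row")) length(row$values) else length(row))
  )
  intensity <- measure(t(masks)) # one column per P
  res <- data.frame(
    p = p_grid,
    peak = intensity[target_index, ],
    pbr = apply(intensity, 2, pbr, target_index = target_index)
  )
  attr(res, "argmax_p") <- p_grid[which.max(res$pbr)]
  res
}
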