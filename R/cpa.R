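#' Split probes into focusing and non-focusing groups
#'
#' First stage of the conditional-probability algorithm (CPA): probes whose
#' target intensity exceeds the `focus_percentile` percentile (linear
#' interpolation) are flagged as "focusing". At the default 80th percentile
#' about 20% of probes are flagged.
#'
#' @param target_intensities Numeric vector, one intensity per probe.
#' @param focus_percentile Percentile in (0, 100) (default 80).
#' @return Logical vector, `TRUE` for probes in the focusing group.
#' @examples
#' split_focus_group(1:100, 80) # flags the 20 probes above 80.2
#' @export
split_focus_group <- function(target_intensities, focus_percentile = 80) {
  y <- as.numeric(target_intensities)
  if (length(y) < 2) stop("need at least two probes")
  if (!is.numeric(focus_percentile) || focus_percentile <= 0 ||
      focus_percentile >= 100) {
    stop("`focus_percentile` must be in (0, 100)")
  }
  if (max(y) == min(y)) {
    stop("target intensities are constant; cannot split into groups")
  }
  y > stats::quantile(y, focus_percentile / 100, names = FALSE, type = 7)
}

#' Per-mirror conditional probability of focusing
#'
#' For each mirror *n*, estimates \eqn{P(\mathrm{focusing} \mid n\;\mathrm{ON})}
#' from the empirical counts over all probes:
#' (number of probes with mirror *n* ON that landed in the focusing group) /
#' (number of probes with mirror *n* ON). This is what Bayes' rule reduces to
#' when the marginals are taken from the same counts. A mirror that is never
#' ON has an undefined probability; it is reported via the `undefined`
#' attribute and assigned the mean of the defined probabilities.
#'
#' @param probe_patterns K x N 0/1 matrix (one pattern per row) or a
#'   `probe_set`.
#' @param focus_indicator Logical (or 0/1) vector of length K, e.g. from
#'   [split_focus_group()].
#' @return Numeric vector of length N of probabilities in `[0, 1]`, with
#'   attribute `undefined` (integer indices of never-ON mirrors, possibly
#'   empty).
#' @examples
#' pats <- rbind(c(1, 0), c(1, 1), c(0, 1))
#' conditional_probabilities(pats, c(TRUE, FALSE, FALSE))
#' @export
conditional_probabilities <- function(probe_patterns, focus_indicator) {
  pats <- if (inherits(probe_patterns, "probe_set")) {
    probe_patterns$patterns
  } else {
    probe_patterns
  }
  ind <- as.logical(focus_indicator)
  if (length(ind) != nrow(pats)) {
    stop("focus indicator length must equal the number of probes")
  }
  on_counts <- colSums(pats)
  on_and_focus <- as.vector(crossprod(pats, as.numeric(ind)))
  p <- on_and_focus / on_counts
  undefined <- which(on_counts == 0)
  if (length(undefined)) {
    warning(sprintf("%d mirror(s) never ON; assigned the mean probability",
                    length(undefined)))
    p[undefined] <- mean(p[-undefined])
  }
  attr(p, "undefined") <- as.integer(undefined)
  p
}

#' Threshold conditional probabilities into a DMD mask
#'
#' Switches ON mirrors whose conditional probability strictly exceeds the
#' threshold: the median of all probabilities (`mode = "median"`, the
#' default) or an explicit numeric value. With continuous-valued
#' probabilities the median rule switches ON close to half of the mirrors;
#' if all probabilities are equal the strict inequality yields an empty
#' mask.
#'
#' @param probabilities Numeric vector from [conditional_probabilities()].
#' @param mode `"median"` or a numeric threshold.
#' @return Integer 0/1 mask.
#' @examples
#' mask_from_probabilities(c(0.1, 0.4, 0.6, 0.9))
#' @export
mask_from_probabilities <- function(probabilities, mode = "median") {
  p <- as.numeric(probabilities)
  thr <- if (identical(mode, "median")) {
    stats::median(p)
  } else if (is.numeric(mode) && length(mode) == 1) {
    mode
  } else {
    stop('`mode` must be "median" or a single numeric threshold')
  }
  as.integer(p > thr)
}

#' Full conditional-probability pipeline
#'
#' Convenience wrapper running the three CPA stages on a probe set and its
#' target intensities: focus split, conditional probabilities, and
#' probability thresholding.
#'
#' @param probes A `probe_set` (random binary probes).
#' @param target_intensities Intensity at the target pixel for each probe.
#' @param focus_percentile Percentile for the focus split (default 80).
#' @param threshold_mode `"median"` or a numeric probability threshold.
#' @return Integer 0/1 mask with attribute `probabilities`.
#' @examples
#' tm <- sample_tm(16, 4, seed = 1)
#' probes <- random_probes(16, seed = 2)
#' y <- as.vector(characterize(tm_measure(tm, rows = 2), probes))
#' mask <- cpa_mask(probes, y)
#' @export
cpa_mask <- function(probes, target_intensities, focus_percentile = 80,
                     threshold_mode = "median") {
  stopifnot(inherits(probes, "probe_set"))
  focus <- split_focus_group(target_intensities, focus_percentile)
  p <- conditional_probabilities(probes$patterns, focus)
  mask <- mask_from_probabilities(p, threshold_mode)
  attr(mask, "probabilities") <- as.numeric(p)
  mask
}
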