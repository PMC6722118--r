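#' Global two-class Otsu base threshold of a DAB intensity map
#'
#' Computes the histogram cut maximising between-class variance over a 256-bin
#' histogram of candidate pixels. Candidates are pixels that are not excluded
#' and whose intensity is at least `bg_epsilon`, so that (near-)white
#' background does not dominate the class statistics. Ties are broken toward
#' the lowest cut. The returned value is the base threshold that mask
#' correction factors multiply.
#'
#' @param intensity Numeric matrix of nonnegative DAB intensities
#'   (see [compute_brown_intensity()]).
#' @param exclusion_mask Optional logical matrix, `TRUE` where pixels are
#'   excluded from analysis.
#' @param n_bins Number of histogram bins.
#' @param bg_epsilon Background cutoff: pixels with intensity below this are
#'   treated as unstained background and left out of the histogram.
#' @return The threshold (scalar, in intensity units): the upper edge of the
#'   lower class, so a pixel belongs to the upper class iff
#'   `intensity >= threshold`.
#' @export
otsu_base_threshold <- function(intensity, exclusion_mask = NULL,
                                n_bins = 256, bg_epsilon = 0.02) {
  check_intensity(intensity)
  vals <- candidate_values(intensity, exclusion_mask, bg_epsilon)
  if (length(vals) < 2 || diff(range(vals)) == 0) {
    abort("Degenerate intensity histogram: core is unevaluable.",
          class = "mosaicquant_degenerate_core")
  }
  h <- bin_values(vals, n_bins)
  otsu_from_histogram(h$counts, h$breaks)
}

check_intensity <- function(intensity) {
  if (!is.matrix(intensity) || !all(is.finite(intensity)) || any(intensity < 0)) {
    abort("`intensity` must be a finite nonnegative numeric matrix.",
          class = "mosaicquant_validation_error")
  }
  invisible(intensity)
}

candidate_values <- function(intensity, exclusion_mask, bg_epsilon) {
  keep <- intensity >= bg_epsilon
  if (!is.null(exclusion_mask)) {
    if (!identical(dim(exclusion_mask), dim(intensity))) {
      abort("Exclusion mask dimensions do not match the intensity map.",
            class = "mosaicquant_shape_error")
    }
    keep <- keep & !exclusion_mask
  }
  intensity[keep]
}

bin_values <- function(vals, n_bins) {
  rng <- range(vals)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  idx <- pmin(pmax(findInterval(vals, breaks, rightmost.closed = TRUE), 1L), n_bins)
  list(counts = tabulate(idx, n_bins), breaks = breaks)
}

# Otsu on binned counts: between-class variance for every cut, lowest argmax.
# Threshold is the bin edge separating classes [1..k] and [k+1..n].
otsu_from_histogram <- function(counts, breaks) {
  n <- length(counts)
  mids <- (breaks[-1] + breaks[-(n + 1)]) / 2
  p <- counts / sum(counts)
  w1 <- cumsum(p)[-n]
  mu1 <- cumsum(p * mids)[-n]
  mu_t <- sum(p * mids)
  w2 <- 1 - w1
  valid <- w1 > 0 & w2 > 0
  sigma_b <- rep(-Inf, n - 1)
  sigma_b[valid] <- (mu_t * w1[valid] - mu1[valid])^2 / (w1[valid] * w2[valid])
  if (!any(is.finite(sigma_b))) {
    abort("Degenerate intensity histogram: core is unevaluable.",
          class = "mosaicquant_degenerate_core")
  }
  k <- which.max(sigma_b)  # which.max returns the first (lowest) maximiser
  breaks[k + 1]
}
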