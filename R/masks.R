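#' Threshold a DAB intensity map into a binary mask
#'
#' A pixel is in the mask iff its intensity is at least
#' `correction_factor * base_threshold` and it is not excluded. The size
#' filter is deliberately *not* applied here; see [filter_small_objects()].
#'
#' @inheritParams otsu_base_threshold
#' @param base_threshold Positive scalar from [otsu_base_threshold()].
#' @param correction_factor Positive multiplier on the base threshold
#'   (CellProfiler-style threshold correction factor).
#' @return Logical matrix with attributes `correction_factor` and
#'   `base_threshold`.
#' @export
build_mask <- function(intensity, base_threshold, correction_factor,
                       exclusion_mask = NULL) {
  check_intensity(intensity)
  if (!is.numeric(correction_factor) || length(correction_factor) != 1 ||
      !is.finite(correction_factor) || correction_factor <= 0) {
    abort("`correction_factor` must be a positive scalar.",
          class = "mosaicquant_validation_error")
  }
  if (!is.numeric(base_threshold) || base_threshold <= 0) {
    abort("`base_threshold` must be positive.",
          class = "mosaicquant_validation_error")
  }
  m <- intensity >= correction_factor * base_threshold
  if (!is.null(exclusion_mask)) {
    if (!identical(dim(exclusion_mask), dim(intensity))) {
      abort("Exclusion mask dimensions do not match the intensity map.",
            class = "mosaicquant_shape_error")
    }
    m <- m & !exclusion_mask
  }
  structure(m, correction_factor = correction_factor,
            base_threshold = base_threshold)
}

#' Quantification settings
#'
#' Bundles the tunable parameters of the mosaicism quantifier. Defaults
#' reproduce the published workflow: 11 MYL4 correction factors from 1.5 to
#' 2.75 in steps of 0.125, an all-myocyte mask at factor 0.5, a 50-pixel
#' minimum object size, and 8-connectivity.
#'
#' @param factors Strictly increasing positive correction factors for the
#'   MYL4-positive mask ladder.
#' @param myocyte_factor Correction factor of the all-myocyte mask; must be
#'   below `min(factors)` so the positive masks nest inside the myocyte mask.
#' @param min_size_px Minimum connected-component size kept (debris filter).
#' @param connectivity 4 or 8.
#' @param bg_epsilon Background optical-density cutoff for the Otsu histogram.
#' @param intensity_mode Passed to [compute_brown_intensity()].
#' @param selection `"auto"` picks the correction factor maximising the
#'   between-class separation of within-myocyte intensities; `"manual"`
#'   requires `manual_index`.
#' @param manual_index Integer index into `factors` when `selection="manual"`.
#' @param smooth_sigma If positive, Gaussian-smooth the intensity map with
#'   this sigma (pixels) before thresholding.
#' @return A list of class `quant_config`.
#' @export
quant_config <- function(factors = seq(1.5, 2.75, by = 0.125),
                         myocyte_factor = 0.5,
                         min_size_px = 50,
                         connectivity = 8,
                         bg_epsilon = 0.02,
                         intensity_mode = c("deconvolution", "blue_ratio"),
                         selection = c("auto", "manual"),
                         manual_index = NULL,
                         smooth_sigma = 0) {
  intensity_mode <- match.arg(intensity_mode)
  selection <- match.arg(selection)
  if (length(factors) < 1 || any(!is.finite(factors)) || any(factors <= 0) ||
      is.unsorted(factors, strictly = TRUE)) {
    abort("`factors` must be strictly increasing and positive.",
          class = "mosaicquant_validation_error")
  }
  if (myocyte_factor <= 0 || myocyte_factor >= min(factors)) {
    abort("`myocyte_factor` must be positive and below min(factors).",
          class = "mosaicquant_validation_error")
  }
  if (selection == "manual" &&
      (is.null(manual_index) || !manual_index %in% seq_along(factors))) {
    abort("`manual_index` must index into `factors` when selection is manual.",
          class = "mosaicquant_validation_error")
  }
  structure(list(factors = factors, myocyte_factor = myocyte_factor,
                 min_size_px = min_size_px, connectivity = connectivity,
                 bg_epsilon = bg_epsilon, intensity_mode = intensity_mode,
                 selection = selection, manual_index = manual_index,
                 smooth_sigma = smooth_sigma),
            class = "quant_config")
}

#' Build the full mask series for one core
#'
#' Computes the shared Otsu base threshold, one size-filtered MYL4 mask per
#' correction factor, and the size-filtered all-myocyte mask. Pre-filter masks
#' are retained for nesting checks and for automatic threshold selection.
#'
#' @inheritParams otsu_base_threshold
#' @param config A [quant_config()].
#' @param base_threshold Optional override of the Otsu base threshold.
#' @return An object of class `mask_series`: list with `base_threshold`,
#'   `factors`, `myl4_masks` / `myl4_prefilter` (lists of logical matrices),
#'   `myocyte_mask` / `myocyte_prefilter`, and the `intensity` map.
#' @export
generate_mask_series <- function(intensity, exclusion_mask = NULL,
                                 config = quant_config(),
                                 base_threshold = NULL) {
  stopifnot(inherits(config, "quant_config"))
  check_intensity(intensity)
  if (config$smooth_sigma > 0) {
    intensity <- EBImage::imageData(EBImage::gblur(intensity, config$smooth_sigma))
  }
  if (is.null(base_threshold)) {
    base_threshold <- otsu_base_threshold(intensity, exclusion_mask,
                                          bg_epsilon = config$bg_epsilon)
  }
  pre <- lapply(config$factors, function(f) {
    build_mask(intensity, base_threshold, f, exclusion_mask)
  })
  post <- lapply(pre, filter_small_objects, min_size_px = config$min_size_px,
                 connectivity = config$connectivity)
  myo_pre <- build_mask(intensity, base_threshold, config$myocyte_factor,
                        exclusion_mask)
  myo_post <- filter_small_objects(myo_pre, min_size_px = config$min_size_px,
                                   connectivity = config$connectivity)
  structure(list(base_threshold = base_threshold,
                 factors = config$factors,
                 myocyte_factor = config$myocyte_factor,
                 myl4_masks = post,
                 myl4_prefilter = pre,
                 myocyte_mask = myo_post,
                 myocyte_prefilter = myo_pre,
                 intensity = intensity,
                 config = config),
            class = "mask_series")
}

#' @export
print.mask_series <- function(x, ...) {
  cat("<mask_series>", length(x$factors), "MYL4 masks, factors",
      min(x$factors), "-", max(x$factors),
      "| myocyte factor", x$myocyte_factor,
      "| Otsu base", signif(x$base_threshold, 4), "\n")
  invisible(x)
}
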