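#' Score percent mosaicism from a mask series
#'
#' The mosaicism statistic is the area ratio
#' `100 * area(selected MYL4+ mask) / area(all-myocyte mask)`: the percent of
#' total myocyte area occupied by strongly DAB-positive (dark brown) myocytes.
#' With `selection = "auto"` the correction factor is chosen as the one whose
#' mask best splits the within-myocyte intensity distribution (maximal
#' between-class variance of the induced two-class partition, computed on
#' pre-filter masks; ties go to the lowest factor), emulating the blinded
#' manual choice of the best threshold. `selection = "manual"` with
#' `manual_index` reproduces a recorded manual choice.
#'
#' @param series A [generate_mask_series()] result.
#' @param selection `"auto"` or `"manual"`; defaults to the mode recorded in
#'   the series' config.
#' @param manual_index Index into `series$factors` for manual selection.
#' @return One-row tibble: `percent_positive`, `positive_area_px`,
#'   `myocyte_area_px`, `selected_factor`, `selection_mode`, `base_threshold`,
#'   `qc_flags` (comma-separated string, `""` if clean).
#' @export
score_mosaicism <- function(series, selection = NULL, manual_index = NULL) {
  stopifnot(inherits(series, "mask_series"))
  selection <- selection %||% series$config$selection
  manual_index <- manual_index %||% series$config$manual_index
  myo_area <- sum(series$myocyte_mask)
  if (myo_area == 0) {
    abort("Zero myocyte area: core is unevaluable.",
          class = "mosaicquant_degenerate_core")
  }
  qc <- character()
  if (selection == "manual") {
    if (is.null(manual_index) || !manual_index %in% seq_along(series$factors)) {
      abort("`manual_index` must index into the factor ladder.",
            class = "mosaicquant_validation_error")
    }
    idx <- as.integer(manual_index)
    mode <- "manual_index"
  } else {
    idx <- select_factor_auto(series)
    mode <- "auto_rule"
    if (is.na(idx)) {
      # every candidate mask is empty (or full): no DAB-high class present
      idx <- 1L
      qc <- c(qc, "no_separable_positive_class")
    }
  }
  pos_area <- sum(series$myl4_masks[[idx]])
  tibble(
    percent_positive = 100 * pos_area / myo_area,
    positive_area_px = as.integer(pos_area),
    myocyte_area_px = as.integer(myo_area),
    selected_factor = series$factors[idx],
    selection_mode = mode,
    base_threshold = series$base_threshold,
    qc_flags = paste(qc, collapse = ",")
  )
}

# Between-class variance of within-myocyte intensities split by each
# candidate pre-filter mask; NA when no factor induces a proper 2-class split.
select_factor_auto <- function(series) {
  vals <- series$intensity[series$myocyte_prefilter]
  if (length(vals) == 0) return(NA_integer_)
  crit <- vapply(series$myl4_prefilter, function(m) {
    inside <- m[series$myocyte_prefilter]
    w1 <- mean(inside)
    if (w1 == 0 || w1 == 1) return(-Inf)
    m1 <- mean(vals[inside])
    m0 <- mean(vals[!inside])
    w1 * (1 - w1) * (m1 - m0)^2
  }, numeric(1))
  if (!any(is.finite(crit))) return(NA_integer_)
  which.max(crit)
}

#' Blank out manually excluded regions of a core image
#'
#' Sets excluded pixels to pure white so they carry zero optical density and
#' are ignored by histogramming, masking and area counting — the digital
#' equivalent of manually erasing blood vessels, adipose and fibrosis from a
#' core image before quantification.
#'
#' @param img RGB array `height x width x 3` in `[0, 1]`.
#' @param exclusion_mask Logical matrix (`TRUE` = exclude) matching the image.
#' @return The image with excluded pixels white.
#' @export
apply_manual_exclusion <- function(img, exclusion_mask) {
  if (!(is.array(img) && length(dim(img)) == 3 && dim(img)[3] == 3)) {
    abort("`img` must be a height x width x 3 RGB array.",
          class = "mosaicquant_format_error")
  }
  if (!identical(dim(exclusion_mask), dim(img)[1:2])) {
    abort("Exclusion mask dimensions do not match the image.",
          class = "mosaicquant_shape_error")
  }
  ex <- as.logical(exclusion_mask)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[ex] <- 1
    img[, , ch] <- plane
  }
  img
}

#' Quantify one core image
#'
#' Full single-core pipeline: manual exclusion, DAB extraction by colour
#' deconvolution, Otsu base threshold, correction-factor mask ladder,
#' 50-pixel size filter, and the percent-mosaicism area ratio.
#'
#' @param img RGB array `height x width x 3` in `[0, 1]`.
#' @param exclusion_mask Optional logical matrix (`TRUE` = exclude).
#' @param config A [quant_config()].
#' @return One-row tibble as [score_mosaicism()].
#' @export
quantify_core <- function(img, exclusion_mask = NULL, config = quant_config()) {
  if (!is.null(exclusion_mask)) {
    img <- apply_manual_exclusion(img, exclusion_mask)
  }
  intensity <- compute_brown_intensity(img, mode = config$intensity_mode)
  series <- generate_mask_series(intensity, exclusion_mask, config)
  score_mosaicism(series)
}

#' Quantify a set of cores into a tidy score table
#'
#' Applies [quantify_core()] to each element of a named list of cores.
#' Unevaluable cores (blank, fully excluded, degenerate histogram) are not
#' errors at the set level: they yield a row with `NA` score and
#' `qc_flags = "unevaluable"`, mirroring the removal of unevaluable images
#' from full analysis.
#'
#' @param cores Named list; each element either an RGB array or a list with
#'   elements `image` and (optionally) `exclusion_mask`.
#' @param config A [quant_config()].
#' @return Tibble with one row per core (`core_id` first column).
#' @export
quantify_cores <- function(cores, config = quant_config()) {
  if (length(cores) == 0) {
    return(tibble(core_id = character(), percent_positive = numeric()))
  }
  if (is.null(names(cores)) || anyDuplicated(names(cores))) {
    abort("`cores` must be a uniquely named list keyed by core id.",
          class = "mosaicquant_validation_error")
  }
  purrr::imap_dfr(cores, function(core, id) {
    img <- if (is.list(core) && !is.null(core$image)) core$image else core
    ex <- if (is.list(core)) core$exclusion_mask else NULL
    row <- tryCatch(
      quantify_core(img, ex, config),
      mosaicquant_degenerate_core = function(e) {
        tibble(percent_positive = NA_real_, positive_area_px = NA_integer_,
               myocyte_area_px = NA_integer_, selected_factor = NA_real_,
               selection_mode = NA_character_, base_threshold = NA_real_,
               qc_flags = "unevaluable")
      }
    )
    dplyr::bind_cols(tibble(core_id = id), row)
  })
}
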