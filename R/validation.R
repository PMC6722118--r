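#' Manual cell counts from synthetic ground truth
#'
#' Converts per-core ground truth into the cell-count comparator: the percent
#' of myocytes (cells, not area) flagged positive, as a blinded human counter
#' would report.
#'
#' @param truths Named list of `core_ground_truth` objects (or
#'   `synthetic_core` objects), keyed by core id.
#' @return Tibble: `core_id`, `n_positive_cells`, `n_total_cells`,
#'   `percent_positive_cells`.
#' @export
manual_counts_from_truth <- function(truths) {
  purrr::imap_dfr(truths, function(x, id) {
    gt <- if (inherits(x, "synthetic_core")) x$ground_truth else x
    npos <- sum(gt$positive_flags)
    ntot <- length(gt$positive_flags)
    tibble(core_id = id, n_positive_cells = npos, n_total_cells = ntot,
           percent_positive_cells = 100 * npos / ntot)
  })
}

#' Concordance between manual cell counts and area-based scores
#'
#' Pearson correlation between percent-positive-by-cell-count and
#' percent-positive-by-area, matched by core id. This is the validation that
#' an area-ratio score tracks what a human counting cells would report.
#'
#' @param manual Tibble with `core_id` and either `percent_positive_cells` or
#'   both `n_positive_cells` and `n_total_cells`.
#' @param scores Tibble with `core_id` and `percent_positive`
#'   (e.g. from [quantify_cores()]).
#' @return Object of class `mosaic_concordance`: list with `r`, `n_pairs`,
#'   `pairs` (matched tibble) and `unmatched_ids`.
#' @export
manual_vs_area_correlation <- function(manual, scores) {
  if (!"percent_positive_cells" %in% names(manual)) {
    manual <- dplyr::mutate(
      manual,
      percent_positive_cells = 100 * .data$n_positive_cells / .data$n_total_cells)
  }
  pairs <- dplyr::inner_join(
    dplyr::select(manual, "core_id", "percent_positive_cells"),
    dplyr::select(scores, "core_id", "percent_positive"),
    by = "core_id")
  pairs <- pairs[complete.cases(pairs), ]
  unmatched <- setdiff(union(manual$core_id, scores$core_id), pairs$core_id)
  if (nrow(pairs) < 3) {
    abort("Need at least 3 matched cores for a correlation.",
          class = "mosaicquant_insufficient_data")
  }
  if (sd(pairs$percent_positive_cells) == 0 || sd(pairs$percent_positive) == 0) {
    abort("Correlation undefined: one method has zero variance.",
          class = "mosaicquant_degenerate_input")
  }
  structure(list(r = cor(pairs$percent_positive_cells, pairs$percent_positive),
                 n_pairs = nrow(pairs), pairs = pairs,
                 unmatched_ids = unmatched),
            class = "mosaic_concordance")
}

#' @export
print.mosaic_concordance <- function(x, ...) {
  cat(sprintf("<mosaic_concordance> Pearson r = %.3f over %d matched cores",
              x$r, x$n_pairs),
      if (length(x$unmatched_ids)) sprintf("(%d unmatched)", length(x$unmatched_ids)),
      "\n")
  invisible(x)
}

#' Replicate-core variation
#'
#' For each subject with 2 or more scored cores, the mean absolute pairwise
#' difference of percent-positive scores (or the range, `max - min`, with
#' `mode = "range"`); the overall statistic is the across-subject mean. This
#' is the reproducibility check that small cores sampled from the same heart
#' score alike.
#'
#' @param scores Tibble with `subject_id` and `percent_positive` (one row per
#'   core); subjects with a single core raise an error — filter them first.
#' @param mode `"mean_pairwise"` (default) or `"range"`.
#' @return Object of class `mosaic_replicate_variation`: list with `overall`
#'   (mean across subjects, percentage points) and `per_subject` tibble.
#' @export
replicate_variation <- function(scores, mode = c("mean_pairwise", "range")) {
  mode <- match.arg(mode)
  grp <- dplyr::group_by(scores, .data$subject_id)
  sizes <- dplyr::summarise(grp, n = dplyr::n())
  if (nrow(sizes) == 0) {
    abort("No replicate sets supplied.", class = "mosaicquant_insufficient_data")
  }
  if (any(sizes$n < 2)) {
    abort("Every subject must contribute at least 2 cores; singleton sets found.",
          class = "mosaicquant_validation_error")
  }
  per <- dplyr::summarise(
    grp,
    n_cores = dplyr::n(),
    variation = if (mode == "range") {
      max(.data$percent_positive) - min(.data$percent_positive)
    } else {
      mean(as.numeric(stats::dist(.data$percent_positive)))
    },
    .groups = "drop")
  structure(list(overall = mean(per$variation), per_subject = per, mode = mode),
            class = "mosaic_replicate_variation")
}

#' @export
print.mosaic_replicate_variation <- function(x, ...) {
  cat(sprintf(
    "<mosaic_replicate_variation> mean %s variation %.2f points over %d subjects\n",
    if (x$mode == "range") "range" else "absolute pairwise",
    x$overall, nrow(x$per_subject)))
  invisible(x)
}

#' Paired areas from synthetic ground truth
#'
#' Long table of per-myocyte areas with their DAB status, for the cell-size
#' comparison between positive and negative myocytes.
#'
#' @inheritParams manual_counts_from_truth
#' @return Tibble: `core_id`, `cell_id`, `group` (positive/negative), `area`.
#' @export
paired_areas_from_truth <- function(truths) {
  purrr::imap_dfr(truths, function(x, id) {
    gt <- if (inherits(x, "synthetic_core")) x$ground_truth else x
    tibble(core_id = id,
           cell_id = seq_along(gt$per_myocyte_area_px),
           group = ifelse(gt$positive_flags, "positive", "negative"),
           area = as.numeric(gt$per_myocyte_area_px))
  })
}

#' Compare cell areas of DAB-positive and DAB-negative myocytes
#'
#' Tests whether positive myocytes differ in size from their negative
#' neighbours. Default mode pairs at the core level: for each core
#' contributing both groups, the mean positive area is compared to the mean
#' negative area with a paired t-test on the per-core differences. The
#' `"pooled_welch"` mode instead pools all cells and runs an unpaired Welch
#' t-test.
#'
#' @param paired Long tibble with `core_id`, `group`
#'   (`"positive"`/`"negative"`) and `area`.
#' @param mode `"paired_core"` (default) or `"pooled_welch"`.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `mean_difference`
#'   (positive minus negative), `n_cores`, `mode`; the per-core difference
#'   table is attached as attribute `"per_core"` in paired mode.
#' @export
compare_cell_areas <- function(paired, mode = c("paired_core", "pooled_welch")) {
  mode <- match.arg(mode)
  if (mode == "pooled_welch") {
    pos <- paired$area[paired$group == "positive"]
    neg <- paired$area[paired$group == "negative"]
    if (length(pos) < 2 || length(neg) < 2) {
      abort("Need at least 2 cells per group.",
            class = "mosaicquant_insufficient_data")
    }
    tt <- stats::t.test(pos, neg)
    return(tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                  p_value = tt$p.value, mean_difference = mean(pos) - mean(neg),
                  n_cores = dplyr::n_distinct(paired$core_id), mode = mode))
  }
  per <- paired |>
    dplyr::group_by(.data$core_id, .data$group) |>
    dplyr::summarise(mean_area = mean(.data$area), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group", values_from = "mean_area")
  per <- per[complete.cases(per), ]
  if (nrow(per) < 2) {
    abort("Need at least 2 cores contributing both groups.",
          class = "mosaicquant_insufficient_data")
  }
  d <- per$positive - per$negative
  if (sd(d) == 0) {
    # degenerate all-equal differences: t = 0 by convention, p = 1
    res <- tibble(statistic = 0, df = length(d) - 1, p_value = 1,
                  mean_difference = mean(d), n_cores = nrow(per), mode = mode)
  } else {
    tt <- stats::t.test(d)
    res <- tibble(statistic = unname(tt$statistic), df = unname(tt$parameter),
                  p_value = tt$p.value, mean_difference = mean(d),
                  n_cores = nrow(per), mode = mode)
  }
  attr(res, "per_core") <- per
  res
}
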