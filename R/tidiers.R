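#' Tidy a mixed-model fit
#'
#' @param x A `mosaic_fit`.
#' @param effects `"fixed"` (coefficient table) or `"ran_pars"` (variance
#'   components).
#' @param ... Unused.
#' @return A tibble in broom column conventions.
#' @method tidy mosaic_fit
#' @export
tidy.mosaic_fit <- function(x, effects = c("fixed", "ran_pars"), ...) {
  effects <- match.arg(effects)
  if (effects == "ran_pars") {
    return(dplyr::mutate(x$variance_components, effect = "ran_pars",
                         .before = 1))
  }
  dplyr::mutate(x$coefficients, effect = "fixed", .before = 1)
}

#' One-row model summary of a mixed-model fit
#'
#' @param x A `mosaic_fit`.
#' @param ... Unused.
#' @return One-row tibble: `n_obs`, `n_subjects`, `n_dropped`, `sigma`,
#'   `REML`, `converged`, `singular`.
#' @method glance mosaic_fit
#' @export
glance.mosaic_fit <- function(x, ...) {
  tibble(n_obs = x$n_obs, n_subjects = x$n_subjects, n_dropped = x$n_dropped,
         sigma = x$variance_components$sd[
           x$variance_components$group == "Residual"],
         REML = x$REML, converged = x$converged, singular = x$singular)
}

#' Tidy a model suite into one stacked coefficient table
#'
#' @param x A `mosaic_model_suite`.
#' @param ... Unused.
#' @return Tibble of coefficients across models, with `model` and `label`.
#' @method tidy mosaic_model_suite
#' @export
tidy.mosaic_model_suite <- function(x, ...) {
  purrr::pmap_dfr(list(x$model, x$label, x$fit), function(m, l, f) {
    if (is.null(f)) return(tibble())
    dplyr::mutate(tidy(f), model = m, label = l, .before = 1)
  })
}

#' Tidy a concordance result
#'
#' @param x A `mosaic_concordance`.
#' @param ... Unused.
#' @return One-row tibble: `estimate` (Pearson r), `n_pairs`, `n_unmatched`.
#' @method tidy mosaic_concordance
#' @export
tidy.mosaic_concordance <- function(x, ...) {
  tibble(estimate = x$r, n_pairs = x$n_pairs,
         n_unmatched = length(x$unmatched_ids))
}

#' Tidy a replicate-variation result
#'
#' @param x A `mosaic_replicate_variation`.
#' @param ... Unused.
#' @return Per-subject tibble with `subject_id`, `n_cores`, `variation`.
#' @method tidy mosaic_replicate_variation
#' @export
tidy.mosaic_replicate_variation <- function(x, ...) x$per_subject

#' @rdname tidy.mosaic_replicate_variation
#' @method glance mosaic_replicate_variation
#' @export
glance.mosaic_replicate_variation <- function(x, ...) {
  tibble(overall = x$overall, n_subjects = nrow(x$per_subject), mode = x$mode)
}
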