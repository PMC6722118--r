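#' Apply the study exclusion rules to a cohort table
#'
#' Removes rows for subjects under 18 years, rows missing sex or age, and
#' rows flagged unevaluable, logging counts per reason. Reasons are assessed
#' in that order, so each removed row is attributed to exactly one reason.
#'
#' @param cohort Tibble with at least `subject_id`, `sex`, `age`; an optional
#'   logical `unevaluable` column marks cores whose images could not be
#'   scored.
#' @param min_age Age threshold in years (rows with `age < min_age` removed).
#' @return The filtered tibble with the exclusion log attached as attribute
#'   `"exclusion_log"` (see [exclusion_log()]): one row per reason with
#'   `n_rows` and `n_subjects`.
#' @export
apply_exclusions <- function(cohort, min_age = 18) {
  uneval <- if ("unevaluable" %in% names(cohort)) {
    !is.na(cohort$unevaluable) & cohort$unevaluable
  } else rep(FALSE, nrow(cohort))
  minor <- !is.na(cohort$age) & cohort$age < min_age
  missing_sa <- (is.na(cohort$sex) | is.na(cohort$age)) & !minor
  missing_or_uneval <- (missing_sa | uneval) & !minor
  reason <- dplyr::case_when(
    minor ~ "age_under_18",
    missing_or_uneval ~ "missing_sex_age_or_unevaluable",
    TRUE ~ NA_character_
  )
  log <- tibble(
    reason = c("age_under_18", "missing_sex_age_or_unevaluable"),
    n_rows = c(sum(minor), sum(missing_or_uneval)),
    n_subjects = c(dplyr::n_distinct(cohort$subject_id[minor]),
                   dplyr::n_distinct(cohort$subject_id[missing_or_uneval]))
  )
  out <- cohort[is.na(reason), , drop = FALSE]
  if (nrow(out) == 0) warn("All rows excluded; empty cohort returned.")
  attr(out, "exclusion_log") <- log
  out
}

#' Retrieve the exclusion log of a filtered cohort
#'
#' @param cohort A tibble returned by [apply_exclusions()].
#' @return Tibble with columns `reason`, `n_rows`, `n_subjects`.
#' @export
exclusion_log <- function(cohort) {
  log <- attr(cohort, "exclusion_log")
  if (is.null(log)) {
    abort("No exclusion log found; run apply_exclusions() first.",
          class = "mosaicquant_validation_error")
  }
  log
}

#' Add the modelling transforms to a cohort table
#'
#' Adds `sqrt_fraction = sqrt(percent/100)` (the modelling outcome),
#' `log_heart_weight` and `log_bmi` (natural logs). Missing values propagate.
#'
#' @param cohort Cohort tibble.
#' @param percent_col Name of the percent-positive column (`"percent_positive"`
#'   for measured scores, `"true_percent"` for generator truth).
#' @return The tibble with the transform columns appended.
#' @export
transform_variables <- function(cohort, percent_col = "percent_positive") {
  if (!percent_col %in% names(cohort)) {
    abort(sprintf("Column `%s` not found.", percent_col),
          class = "mosaicquant_validation_error")
  }
  pct <- cohort[[percent_col]]
  if (any(pct < 0, na.rm = TRUE)) {
    abort("Negative percent values are invalid.",
          class = "mosaicquant_validation_error")
  }
  cohort$sqrt_fraction <- sqrt(pct / 100)
  cohort$log_heart_weight <- if ("heart_weight" %in% names(cohort)) {
    log(cohort$heart_weight)
  } else NA_real_
  cohort$log_bmi <- if ("bmi" %in% names(cohort)) log(cohort$bmi) else NA_real_
  cohort
}

#' Mixed-model specification
#'
#' @param fixed_effects Character vector of fixed-effect terms (columns of the
#'   cohort, or expressions like `disease`).
#' @param random_intercepts Character vector of grouping columns, each getting
#'   a random intercept; must be non-empty.
#' @param outcome Outcome column (default the sqrt-fraction transform).
#' @param tma_subset Optional character vector of `tma_id` levels to keep.
#' @param label Free-text label used in suite output.
#' @return List of class `mosaic_model_spec`.
#' @export
model_spec <- function(fixed_effects = c("age", "sex"),
                       random_intercepts = c("subject_id", "tma_id"),
                       outcome = "sqrt_fraction",
                       tma_subset = NULL,
                       label = NULL) {
  if (length(random_intercepts) == 0) {
    abort("At least one random intercept is required.",
          class = "mosaicquant_validation_error")
  }
  structure(list(fixed_effects = fixed_effects,
                 random_intercepts = random_intercepts,
                 outcome = outcome, tma_subset = tma_subset,
                 label = label %||% paste(fixed_effects, collapse = "+")),
            class = "mosaic_model_spec")
}

#' Fit a linear mixed model for percent mosaicism
#'
#' REML fit (via lme4) of the transformed outcome on the fixed effects with
#' crossed random intercepts, the study's model for repeated cores per
#' subject across multiple TMAs. p-values use the normal approximation on the
#' t statistic by default (the "p.z" convention); Satterthwaite degrees of
#' freedom are available with `df_method = "satterthwaite"` when lmerTest is
#' installed.
#'
#' @param cohort Prepared cohort tibble (after [apply_exclusions()] and
#'   [transform_variables()]); rows with missing model variables are dropped
#'   (listwise deletion) and counted.
#' @param spec A [model_spec()].
#' @param REML Use REML (default) or ML.
#' @param df_method `"z"` or `"satterthwaite"`.
#' @return Object of class `mosaic_fit`: list with `coefficients` tibble
#'   (`term`, `estimate`, `std.error`, `statistic`, `p.value`),
#'   `variance_components` tibble (`group`, `sd`, `variance`), `n_obs`,
#'   `n_subjects`, `n_dropped`, `converged`, `singular`, the underlying
#'   `fit` (lmerMod) and the `spec`.
#' @export
fit_mixed_model <- function(cohort, spec = model_spec(), REML = TRUE,
                            df_method = c("z", "satterthwaite")) {
  stopifnot(inherits(spec, "mosaic_model_spec"))
  df_method <- match.arg(df_method)
  if (!is.null(spec$tma_subset)) {
    cohort <- cohort[cohort$tma_id %in% spec$tma_subset, , drop = FALSE]
    cohort$tma_id <- droplevels(factor(cohort$tma_id))
  }
  vars <- unique(c(spec$outcome, all.vars(
    stats::as.formula(paste("~", paste(spec$fixed_effects, collapse = "+")))),
    spec$random_intercepts))
  missing_any <- !complete.cases(cohort[, intersect(vars, names(cohort))])
  n_dropped <- sum(missing_any)
  dat <- cohort[!missing_any, , drop = FALSE]
  if (dplyr::n_distinct(dat$subject_id) < 2) {
    abort("Need at least 2 subjects to fit the random-intercept model.",
          class = "mosaicquant_insufficient_data")
  }
  fml <- stats::as.formula(paste(
    spec$outcome, "~", paste(spec$fixed_effects, collapse = " + "), "+",
    paste(sprintf("(1 | %s)", spec$random_intercepts), collapse = " + ")))
  # permit degenerate designs (e.g. a single TMA level): the variance
  # component is then reported as ~0 with the singularity flag set
  ctrl <- lme4::lmerControl(check.nlev.gtr.1 = "ignore",
                            check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.nRE = "ignore")
  fit <- withCallingHandlers(
    lme4::lmer(fml, data = dat, REML = REML, control = ctrl),
    message = function(m) invokeRestart("muffleMessage"),
    warning = function(w) invokeRestart("muffleWarning"))
  # a grouping factor with a single observed level cannot identify its
  # variance: report the fit as singular rather than dropping the term
  n_levels <- vapply(fit@flist, nlevels, integer(1))
  singular <- lme4::isSingular(fit, tol = 1e-5) || any(n_levels < 2)
  conv <- fit@optinfo$conv$lme4
  converged <- is.null(conv$code) || conv$code == 0

  co <- as.data.frame(summary(fit)$coefficients)
  coef_tbl <- tibble(term = rownames(co), estimate = co[, "Estimate"],
                     std.error = co[, "Std. Error"],
                     statistic = co[, "t value"])
  if (df_method == "satterthwaite") {
    if (!requireNamespace("lmerTest", quietly = TRUE)) {
      abort("lmerTest is required for Satterthwaite p-values.",
            class = "mosaicquant_validation_error")
    }
    fit_t <- lmerTest::as_lmerModLmerTest(fit)
    co_t <- as.data.frame(summary(fit_t)$coefficients)
    coef_tbl$df <- co_t[, "df"]
    coef_tbl$p.value <- co_t[, "Pr(>|t|)"]
  } else {
    coef_tbl$p.value <- 2 * pnorm(-abs(coef_tbl$statistic))
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  vc_tbl <- tibble(group = vc$grp, sd = vc$sdcor, variance = vc$vcov)
  structure(list(coefficients = coef_tbl, variance_components = vc_tbl,
                 n_obs = nrow(dat),
                 n_subjects = dplyr::n_distinct(dat$subject_id),
                 n_dropped = n_dropped, converged = converged,
                 singular = singular, REML = REML, df_method = df_method,
                 fit = fit, spec = spec),
            class = "mosaic_fit")
}

#' @export
print.mosaic_fit <- function(x, ...) {
  cat(sprintf("<mosaic_fit> %s | %d obs, %d subjects%s%s\n",
              x$spec$label, x$n_obs, x$n_subjects,
              if (!x$converged) " | NOT CONVERGED" else "",
              if (x$singular) " | singular random effects" else ""))
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' Residualise the outcome against an adjustment model
#'
#' Fits the adjustment mixed model (by default age + sex with subject and TMA
#' random intercepts) and appends a `residual` column, the adjusted outcome
#' used for disease-group comparisons.
#'
#' Two residual types are offered. The default `"adjusted"` subtracts the
#' fixed-effect predictions and the TMA random intercepts but *retains* each
#' subject's own deviation: repeated measures per individual are accounted
#' for in estimating the adjustment (via the subject random intercept) without
#' being removed from the displayed values, so subject-level group contrasts
#' (e.g. a disease shift) stay visible. `"conditional"` subtracts the full
#' conditional fit including subject BLUPs (the classic `residuals()` of the
#' mixed model); these are orthogonal to the fixed-effect design but shrink
#' away any subject-level signal not in the model.
#'
#' @inheritParams fit_mixed_model
#' @param adjust_for Fixed effects of the adjustment model.
#' @param type `"adjusted"` (default) or `"conditional"`; see Details.
#' @return The cohort tibble (rows used in the fit) with a `residual` column;
#'   the underlying `mosaic_fit` is attached as attribute `"fit"`.
#' @export
compute_residuals <- function(cohort, adjust_for = c("age", "sex"),
                              spec = NULL, type = c("adjusted", "conditional"),
                              ...) {
  type <- match.arg(type)
  spec <- spec %||% model_spec(fixed_effects = adjust_for,
                               label = "adjustment")
  fit <- fit_mixed_model(cohort, spec, ...)
  dat <- cohort
  if (!is.null(spec$tma_subset)) {
    dat <- dat[dat$tma_id %in% spec$tma_subset, , drop = FALSE]
  }
  vars <- unique(c(spec$outcome, all.vars(stats::as.formula(
    paste("~", paste(spec$fixed_effects, collapse = "+")))),
    spec$random_intercepts))
  dat <- dat[complete.cases(dat[, intersect(vars, names(dat))]), , drop = FALSE]
  if (type == "conditional") {
    dat$residual <- unname(residuals(fit$fit))
  } else {
    keep_re <- setdiff(spec$random_intercepts, "subject_id")
    re_form <- if (length(keep_re) == 0) NA else stats::as.formula(
      paste("~", paste(sprintf("(1 | %s)", keep_re), collapse = " + ")))
    pred <- if (length(keep_re) == 0) {
      stats::predict(fit$fit, re.form = NA)
    } else {
      stats::predict(fit$fit, re.form = re_form)
    }
    dat$residual <- dat[[spec$outcome]] - unname(pred)
  }
  attr(dat, "fit") <- fit
  dat
}

#' Fit the study's standard suite of mixed models
#'
#' Four analyses: (1) age + sex on the full cohort; (2) age + sex + disease
#' on the first two TMAs (treatment contrasts, Control reference); (3) age +
#' sex + log heart weight on the rows where heart weight is recorded; (4) age
#' + sex + an HCM indicator on the full cohort. Per-model failures are
#' isolated and reported, not propagated.
#'
#' @param cohort Prepared cohort tibble (transforms applied).
#' @param tma_pair Levels of `tma_id` used for the disease model.
#' @return Object of class `mosaic_model_suite`: tibble with columns `model`,
#'   `label`, `status`, `n_dropped` and a list-column `fit` of `mosaic_fit`
#'   objects (or `NULL` on failure).
#' @export
run_model_suite <- function(cohort, tma_pair = c("TMA1", "TMA2")) {
  cohort <- dplyr::mutate(cohort, is_hcm = .data$disease == "HCM")
  specs <- list(
    main = model_spec(c("age", "sex"), label = "age + sex, all TMAs"),
    disease = model_spec(c("age", "sex", "disease"), tma_subset = tma_pair,
                         label = sprintf("age + sex + disease, %s",
                                         paste(tma_pair, collapse = "&"))),
    heart_weight = model_spec(c("age", "sex", "log_heart_weight"),
                              label = "age + sex + log heart weight"),
    hcm = model_spec(c("age", "sex", "is_hcm"),
                     label = "age + sex + HCM indicator, all TMAs")
  )
  rows <- purrr::imap(specs, function(sp, nm) {
    fit <- tryCatch(fit_mixed_model(cohort, sp),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      tibble(model = nm, label = sp$label,
             status = paste("failed:", conditionMessage(fit)),
             n_dropped = NA_integer_, fit = list(NULL))
    } else {
      tibble(model = nm, label = sp$label,
             status = if (fit$converged) "converged" else "not_converged",
             n_dropped = fit$n_dropped, fit = list(fit))
    }
  })
  structure(dplyr::bind_rows(rows), class = c("mosaic_model_suite",
                                              class(tibble())))
}
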