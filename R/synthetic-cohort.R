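#' Specification of a synthetic multi-TMA cohort
#'
#' Describes a cohort of subjects contributing one or more tissue-microarray
#' cores each, with a sex effect, an age effect, disease effects, and crossed
#' random intercepts for subject and TMA, all on the square-root-of-fraction
#' scale. The linear predictor per core is
#' `intercept + sex_effect*male + age_effect*age + disease_effect +
#'  b_subject + b_tma + noise`, clipped to `[0, 1]` and squared into a
#' fraction; `true_percent` is 100 times that fraction. Replicate cores of a
#' subject share the subject's random intercept.
#'
#' Fixed-effect defaults are the cohort-scale estimates of the study being
#' emulated (intercept 0.29, sex 0.097, age -0.00013 on the sqrt scale;
#' disease effects: HCM 0.21, SCD-CAD -0.049, SCD+CAD-Thrombosis 0.011,
#' SCD+CAD+Thrombosis -0.031, ACM -0.028). Variance components are package
#' defaults: subject SD 0.10, TMA SD 0.02, residual SD 0.04 (the residual SD
#' is set so replicate cores differ by ~3.5 percentage points on average).
#'
#' @param n_subjects,n_tmas Cohort dimensions.
#' @param replicate_core_probability Probability a subject contributes a
#'   second core (a small fraction of those get a third).
#' @param sex_effect_sqrt_scale,age_effect_sqrt_scale,intercept_sqrt_scale
#'   Fixed effects on the sqrt-fraction scale; sex is coded female=0, male=1.
#' @param disease_effects_sqrt_scale Named numeric vector of per-disease
#'   shifts; names define the disease categories, `Control` must be present
#'   with effect 0.
#' @param disease_probs Named sampling probabilities over the same categories.
#' @param subject_sd,tma_sd,residual_sd Random-intercept and residual SDs.
#' @param sex_ratio_male Fraction of male subjects.
#' @param age_mean_sd Length-2 vector: mean and SD of subject age (years).
#' @param n_underage_subjects Number of planted under-18 subjects (for
#'   exclusion-bookkeeping tests).
#' @param n_missing_or_unevaluable Number of planted rows with missing sex,
#'   missing age, or an unevaluable flag.
#' @param seed Integer RNG seed.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 668, n_tmas = 5,
                        replicate_core_probability = 0.12,
                        sex_effect_sqrt_scale = 0.097,
                        age_effect_sqrt_scale = -0.00013,
                        disease_effects_sqrt_scale = c(
                          Control = 0,
                          `SCD + CAD - Thrombosis` = 0.011,
                          `SCD - CAD` = -0.049,
                          `SCD + CAD + Thrombosis` = -0.031,
                          HCM = 0.21, DCM = 0, IHD = 0, ACM = -0.028,
                          Other = 0),
                        disease_probs = c(
                          Control = 0.37, `SCD + CAD - Thrombosis` = 0.18,
                          `SCD - CAD` = 0.13, `SCD + CAD + Thrombosis` = 0.10,
                          HCM = 0.08, DCM = 0.06, IHD = 0.05, ACM = 0.01,
                          Other = 0.02),
                        intercept_sqrt_scale = 0.29,
                        subject_sd = 0.10, tma_sd = 0.02, residual_sd = 0.04,
                        sex_ratio_male = 0.692,
                        age_mean_sd = c(55, 16),
                        n_underage_subjects = 0,
                        n_missing_or_unevaluable = 0,
                        seed = 1L) {
  # tolerate YAML round-trips that turn named vectors into lists
  disease_effects_sqrt_scale <- unlist(disease_effects_sqrt_scale)
  disease_probs <- unlist(disease_probs)
  age_mean_sd <- unlist(age_mean_sd)
  spec <- list(n_subjects = n_subjects, n_tmas = n_tmas,
               replicate_core_probability = replicate_core_probability,
               sex_effect_sqrt_scale = sex_effect_sqrt_scale,
               age_effect_sqrt_scale = age_effect_sqrt_scale,
               disease_effects_sqrt_scale = disease_effects_sqrt_scale,
               disease_probs = disease_probs,
               intercept_sqrt_scale = intercept_sqrt_scale,
               subject_sd = subject_sd, tma_sd = tma_sd,
               residual_sd = residual_sd,
               sex_ratio_male = sex_ratio_male, age_mean_sd = age_mean_sd,
               n_underage_subjects = n_underage_subjects,
               n_missing_or_unevaluable = n_missing_or_unevaluable,
               seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(s) {
  chk <- function(ok, field, msg) {
    if (!ok) abort(sprintf("Invalid `%s`: %s", field, msg),
                   class = "mosaicquant_validation_error")
  }
  chk(s$n_subjects >= 1, "n_subjects", "must be positive")
  chk(s$n_tmas >= 1, "n_tmas", "must be positive")
  chk(s$replicate_core_probability >= 0 && s$replicate_core_probability <= 1,
      "replicate_core_probability", "must lie in [0, 1]")
  chk(s$subject_sd >= 0, "subject_sd", "must be nonnegative")
  chk(s$tma_sd >= 0, "tma_sd", "must be nonnegative")
  chk(s$residual_sd >= 0, "residual_sd", "must be nonnegative")
  chk(s$sex_ratio_male >= 0 && s$sex_ratio_male <= 1,
      "sex_ratio_male", "must lie in [0, 1]")
  chk("Control" %in% names(s$disease_effects_sqrt_scale),
      "disease_effects_sqrt_scale", "must name a Control category")
  chk(setequal(names(s$disease_probs), names(s$disease_effects_sqrt_scale)),
      "disease_probs", "categories must match disease_effects_sqrt_scale")
  chk(s$n_underage_subjects + ceiling(s$n_missing_or_unevaluable / 1) <
        s$n_subjects, "n_underage_subjects", "too many planted exclusions")
  invisible(s)
}

#' Generate a synthetic cohort table
#'
#' One row per core. Some subjects contribute 2-3 cores; replicate cores
#' share the subject's random intercept and may sit on a different TMA, so
#' subjects cross TMAs (matching a design where control cores are replicated
#' across arrays). Optionally plants under-18 subjects and
#' missing/unevaluable rows for exclusion bookkeeping.
#'
#' @param spec A [cohort_spec()].
#' @param noise_sign `+1` or `-1`: multiplies every random draw on the
#'   outcome scale (subject and TMA intercepts, residuals) while leaving the
#'   design (subjects, ages, sexes, diseases, TMA layout) unchanged for the
#'   same seed. Antithetic (`-1`) replicates support variance-reduced
#'   Monte-Carlo bias estimation.
#' @return Tibble with columns `core_id`, `subject_id`, `tma_id`, `sex`
#'   (factor female/male), `age`, `ethnicity`, `disease` (factor, Control
#'   reference), `site`, `heart_weight`, `bmi`, `true_percent`,
#'   `unevaluable`.
#' @export
generate_cohort <- function(spec, noise_sign = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!noise_sign %in% c(-1, 1)) {
    abort("`noise_sign` must be +1 or -1.", class = "mosaicquant_validation_error")
  }
  set.seed(spec$seed)
  n <- spec$n_subjects
  diseases <- names(spec$disease_effects_sqrt_scale)
  subj <- tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    sex = factor(ifelse(runif(n) < spec$sex_ratio_male, "male", "female"),
                 levels = c("female", "male")),
    age = pmax(rnorm(n, spec$age_mean_sd[1], spec$age_mean_sd[2]), 18.5),
    ethnicity = sample(c("Caucasian", "African American", "Other"), n,
                       replace = TRUE, prob = c(0.61, 0.3, 0.09)),
    disease = factor(sample(diseases, n, replace = TRUE,
                            prob = spec$disease_probs[diseases]),
                     levels = c("Control", setdiff(diseases, "Control"))),
    heart_weight = exp(rnorm(n, log(420), 0.25)),
    bmi = exp(rnorm(n, log(27), 0.2)),
    b_subject = noise_sign * rnorm(n, 0, spec$subject_sd),
    primary_tma = sample(spec$n_tmas, n, replace = TRUE)
  )
  # ~46% of subjects lack heart weight, mirroring chart-review missingness
  subj$heart_weight[runif(n) < 0.46] <- NA_real_
  subj$bmi[runif(n) < 0.3] <- NA_real_

  n_cores <- 1L + (runif(n) < spec$replicate_core_probability) +
    (runif(n) < spec$replicate_core_probability * 0.05)
  b_tma <- noise_sign * rnorm(spec$n_tmas, 0, spec$tma_sd)

  rows <- subj[rep(seq_len(n), n_cores), ]
  rows$core_index <- unlist(lapply(n_cores, seq_len))
  # replicate cores move to a random (possibly different) TMA half the time
  move <- rows$core_index > 1 & runif(nrow(rows)) < 0.5
  rows$tma_id <- rows$primary_tma
  rows$tma_id[move] <- sample(spec$n_tmas, sum(move), replace = TRUE)
  rows$site <- ifelse(rows$tma_id == pmin(4, spec$n_tmas) &
                        runif(nrow(rows)) < 0.8, "septum", "left_ventricle")

  eta <- spec$intercept_sqrt_scale +
    spec$sex_effect_sqrt_scale * (rows$sex == "male") +
    spec$age_effect_sqrt_scale * rows$age +
    spec$disease_effects_sqrt_scale[as.character(rows$disease)] +
    rows$b_subject + b_tma[rows$tma_id] +
    noise_sign * rnorm(nrow(rows), 0, spec$residual_sd)
  s <- pmin(pmax(eta, 0), 1)

  out <- tibble(
    core_id = sprintf("%s_c%d", rows$subject_id, rows$core_index),
    subject_id = rows$subject_id,
    tma_id = factor(paste0("TMA", rows$tma_id),
                    levels = paste0("TMA", seq_len(spec$n_tmas))),
    sex = rows$sex,
    age = rows$age,
    ethnicity = rows$ethnicity,
    disease = rows$disease,
    site = rows$site,
    heart_weight = rows$heart_weight,
    bmi = rows$bmi,
    true_percent = 100 * s^2,
    unevaluable = FALSE
  )
  plant_exclusions(out, spec)
}

# Plant under-18 subjects and missing/unevaluable rows in disjoint positions.
plant_exclusions <- function(cohort, spec) {
  n_minor <- spec$n_underage_subjects
  n_miss <- spec$n_missing_or_unevaluable
  if (n_minor == 0 && n_miss == 0) return(cohort)
  single <- names(which(table(cohort$subject_id) == 1))
  if (length(single) < n_minor + n_miss) {
    abort("Not enough single-core subjects to plant the requested exclusions.",
          class = "mosaicquant_validation_error")
  }
  picked <- sample(single, n_minor + n_miss)
  minors <- picked[seq_len(n_minor)]
  missers <- picked[n_minor + seq_len(n_miss)]
  cohort$age[cohort$subject_id %in% minors] <- runif(n_minor, 1, 17.5)
  if (n_miss > 0) {
    kind <- rep(c("sex", "age", "uneval"), length.out = n_miss)
    idx <- match(missers, cohort$subject_id)
    cohort$sex[idx[kind == "sex"]] <- NA
    cohort$age[idx[kind == "age"]] <- NA_real_
    cohort$unevaluable[idx[kind == "uneval"]] <- TRUE
  }
  cohort
}

#' Derive a per-core seed from a master seed and a core id
#'
#' Deterministic polynomial rolling hash (base 31, modulus the prime
#' 2147483629) over the UTF-8 bytes of the core id, seeded with the master
#' seed. Always below 2^31 so it is a valid R RNG seed.
#'
#' @param master_seed Integer master seed.
#' @param id Character scalar.
#' @return Integer seed in `[0, 2147483628]`.
#' @export
derive_seed <- function(master_seed, id) {
  m <- 2147483629
  h <- as.numeric(master_seed) %% m
  for (b in utf8ToInt(as.character(id))) h <- (h * 31 + b) %% m
  as.integer(h)
}

#' Render a synthetic image for every core of a cohort
#'
#' Each core's image uses `true_mosaic_fraction = true_percent / 100`; its
#' RNG seed is derived deterministically from `(master_seed, core_id)` by
#' [derive_seed()]. Ground truth is recorded from rendered pixels, so per-core
#' truth can differ from the cohort table by rendering granularity (about one
#' myocyte's area).
#'
#' @param cohort Tibble from [generate_cohort()] (needs `core_id`,
#'   `true_percent`, `unevaluable`).
#' @param base_spec An [image_spec()] providing all fields except the mosaic
#'   fraction and seed.
#' @param master_seed Integer master seed.
#' @return Named list (keyed by `core_id`) of [generate_core_image()] results.
#'   Cores flagged unevaluable are rendered as blank white images.
#' @export
render_cohort_images <- function(cohort, base_spec = image_spec(),
                                 master_seed = 1L) {
  stopifnot(inherits(base_spec, "image_spec"))
  if (nrow(cohort) == 0) return(setNames(list(), character()))
  if (anyDuplicated(cohort$core_id)) {
    abort("Duplicate core ids in cohort.", class = "mosaicquant_validation_error")
  }
  out <- purrr::map2(cohort$core_id, cohort$true_percent, function(id, pct) {
    sp <- base_spec
    sp$true_mosaic_fraction <- pct / 100
    sp$seed <- derive_seed(master_seed, id)
    generate_core_image(sp)
  })
  names(out) <- cohort$core_id
  if (any(cohort$unevaluable)) {
    blank <- array(1, c(base_spec$height_px, base_spec$width_px, 3))
    for (id in cohort$core_id[cohort$unevaluable]) {
      out[[id]]$image <- blank
    }
  }
  out
}
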