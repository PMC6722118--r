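#' Configuration of a full synthetic study run
#'
#' Bundles seed, output location and per-stage settings for
#' [run_full_study()]. All stage randomness derives from the single `seed`.
#' Invalid settings (e.g. a non-increasing correction-factor ladder) are
#' rejected here, before any computation.
#'
#' @param seed Integer master seed.
#' @param out_dir Run directory (created if needed).
#' @param cohort List of overrides for [cohort_spec()] fields. The default
#'   study runs 30 subjects with a raised replicate probability so the
#'   replicate statistics have data at demonstration scale.
#' @param image List of overrides for [image_spec()] fields (the per-core
#'   mosaic fraction and seed are always set from the cohort).
#' @param quant List of overrides for [quant_config()] arguments.
#' @param tma_pair `tma_id` levels for the disease model of the suite.
#' @param write_images Write PNG images/masks to disk (disable to save time
#'   when only the numbers matter).
#' @return List of class `run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = tempfile("mosaicquant_run_"),
                       cohort = list(), image = list(), quant = list(),
                       tma_pair = c("TMA1", "TMA2"), write_images = TRUE) {
  cohort_defaults <- list(n_subjects = 30, replicate_core_probability = 0.25)
  cohort <- utils::modifyList(cohort_defaults, cohort)
  image_defaults <- list(width_px = 256, height_px = 256, n_myocytes = 40,
                         myocyte_area_px_mean = 700, myocyte_area_px_sd = 150,
                         n_debris = 10, n_vessels = 1)
  image <- utils::modifyList(image_defaults, image)
  cohort$seed <- cohort$seed %||% seed
  cfg <- structure(list(
    seed = as.integer(seed), out_dir = out_dir,
    cohort_spec = do.call(cohort_spec, cohort),
    image_spec = do.call(image_spec, image),
    quant_config = do.call(quant_config, quant),
    tma_pair = tma_pair, write_images = isTRUE(write_images)
  ), class = "run_config")
  cfg
}

#' Read a run configuration from YAML
#'
#' The YAML file may contain top-level `seed`, `out_dir`, `tma_pair`,
#' `write_images` and nested `cohort`, `image`, `quant` blocks whose keys are
#' the corresponding spec fields.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(seed = y$seed %||% 1L,
             out_dir = y$out_dir %||% tempfile("mosaicquant_run_"),
             cohort = y$cohort %||% list(),
             image = y$image %||% list(),
             quant = y$quant %||% list(),
             tma_pair = y$tma_pair %||% c("TMA1", "TMA2"),
             write_images = y$write_images %||% TRUE)
}

#' Run the full synthetic study end to end
#'
#' simulate -> quantify -> validate -> analyze, fully deterministic given the
#' config seed. Generates a multi-TMA cohort and a synthetic image per core,
#' scores every core, runs the validation statistics (manual-count
#' concordance, replicate variation, paired cell areas), applies the
#' exclusion rules and transforms, and fits the standard model suite.
#' Artifacts (CSV/JSON, optional PNGs) are written under the config's
#' `out_dir`, each run stamped with the seed and the MD5 hash of the written
#' config. A stage failure is recorded in the summary and downstream stages
#' are skipped with explicit status.
#'
#' @param config A [run_config()] or path to a YAML config.
#' @return Invisibly, a list with the run directory, per-stage status, and
#'   the in-memory artifacts (`cohort`, `scores`, `validation`, `suite`,
#'   `residuals`, `summary`).
#' @export
run_full_study <- function(config = run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(serialize_config(config), cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))

  status <- c(simulate = "pending", quantify = "pending",
              validate = "pending", analyze = "pending")
  arts <- list()
  log_path <- file.path(config$out_dir, "run_log.jsonl")
  if (file.exists(log_path)) unlink(log_path)
  log_line <- function(...) {
    cat(jsonlite::toJSON(list(...), auto_unbox = TRUE), "\n",
        file = log_path, append = TRUE, sep = "")
  }

  run_stage <- function(name, fn) {
    if (any(status == "failed")) {
      status[name] <<- "skipped"
      log_line(stage = name, status = "skipped")
      return(invisible(NULL))
    }
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      status[name] <<- "failed"
      log_line(stage = name, status = "failed",
               message = conditionMessage(res))
    } else {
      status[name] <<- "ok"
      log_line(stage = name, status = "ok")
    }
    invisible(res)
  }

  run_stage("simulate", function() {
    cohort <- generate_cohort(config$cohort_spec)
    cores <- render_cohort_images(cohort, config$image_spec,
                                  master_seed = config$seed)
    readr::write_csv(cohort, file.path(config$out_dir, "cohort.csv"))
    if (config$write_images) {
      img_dir <- file.path(config$out_dir, "images")
      msk_dir <- file.path(config$out_dir, "masks")
      dir.create(img_dir, showWarnings = FALSE)
      dir.create(msk_dir, showWarnings = FALSE)
      for (id in names(cores)) {
        write_core_image(cores[[id]]$image,
                         file.path(img_dir, paste0(id, ".png")))
        write_exclusion_mask(cores[[id]]$exclusion_mask,
                             file.path(msk_dir, paste0(id, ".png")))
      }
    }
    arts$cohort <<- cohort
    arts$cores <<- cores
  })

  run_stage("quantify", function() {
    scores <- quantify_cores(arts$cores, config$quant_config)
    for (i in seq_len(nrow(scores))) {
      log_line(stage = "quantify", core_id = scores$core_id[i],
               selected_factor = scores$selected_factor[i],
               percent_positive = scores$percent_positive[i],
               qc = scores$qc_flags[i])
    }
    readr::write_csv(scores, file.path(config$out_dir, "scores.csv"))
    arts$scores <<- scores
  })

  run_stage("validate", function() {
    eval_cores <- arts$cores[!arts$cohort$unevaluable]
    manual <- manual_counts_from_truth(eval_cores)
    conc <- manual_vs_area_correlation(manual, arts$scores)
    reps <- arts$scores |>
      dplyr::inner_join(dplyr::select(arts$cohort, "core_id", "subject_id"),
                        by = "core_id") |>
      dplyr::filter(!is.na(.data$percent_positive)) |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::filter(dplyr::n() >= 2) |>
      dplyr::ungroup()
    repvar <- if (nrow(reps) > 0) replicate_variation(reps) else NULL
    areas <- compare_cell_areas(paired_areas_from_truth(eval_cores))
    validation <- list(
      concordance_r = conc$r, concordance_n = conc$n_pairs,
      replicate_variation = if (is.null(repvar)) NA else repvar$overall,
      replicate_subjects = if (is.null(repvar)) 0 else nrow(repvar$per_subject),
      cell_area_t = areas$statistic, cell_area_p = areas$p_value)
    jsonlite::write_json(validation,
                         file.path(config$out_dir, "validation.json"),
                         auto_unbox = TRUE, digits = NA)
    arts$validation <<- validation
  })

  run_stage("analyze", function() {
    joined <- dplyr::left_join(
      arts$cohort,
      dplyr::select(arts$scores, "core_id", "percent_positive",
                    "selected_factor", "qc_flags"),
      by = "core_id")
    joined$unevaluable <- joined$unevaluable | is.na(joined$percent_positive)
    kept <- apply_exclusions(joined)
    readr::write_csv(exclusion_log(kept),
                     file.path(config$out_dir, "exclusions.csv"))
    prepared <- transform_variables(kept)
    suite <- run_model_suite(prepared, tma_pair = config$tma_pair)
    readr::write_csv(tidy(suite), file.path(config$out_dir, "models.csv"))
    resid <- compute_residuals(prepared)
    readr::write_csv(
      dplyr::select(resid, "core_id", "subject_id", "disease", "residual"),
      file.path(config$out_dir, "residuals.csv"))
    arts$suite <<- suite
    arts$residuals <<- resid
    arts$prepared <<- prepared
  })

  recovery <- NULL
  if (!is.null(arts$scores)) {
    truth <- purrr::imap_dfr(arts$cores, function(core, id) {
      tibble(core_id = id,
             true_percent_rendered = core$ground_truth$true_mosaic_percent)
    })
    cmp <- dplyr::inner_join(arts$scores, truth, by = "core_id")
    cmp <- cmp[!arts$cohort$unevaluable[match(cmp$core_id,
                                              arts$cohort$core_id)], ]
    err <- cmp$percent_positive - cmp$true_percent_rendered
    recovery <- list(mean_abs_error_pp = mean(abs(err), na.rm = TRUE),
                     mean_signed_error_pp = mean(err, na.rm = TRUE),
                     n_cores = sum(!is.na(err)))
  }

  summary <- list(seed = config$seed, config_hash = cfg_hash,
                  status = as.list(status),
                  n_cores = if (is.null(arts$cohort)) 0 else nrow(arts$cohort),
                  n_subjects = if (is.null(arts$cohort)) 0 else
                    dplyr::n_distinct(arts$cohort$subject_id),
                  recovery = recovery,
                  validation = arts$validation)
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(list(run_dir = config$out_dir, status = status,
                   summary = summary), arts))
}

# plain-list view of a run_config for YAML round-tripping
serialize_config <- function(config) {
  list(seed = config$seed,
       tma_pair = config$tma_pair,
       write_images = config$write_images,
       cohort = unclass_spec(config$cohort_spec),
       image = unclass_spec(config$image_spec),
       quant = unclass_spec(config$quant_config))
}

unclass_spec <- function(x) {
  x <- unclass(x)
  lapply(x, function(v) if (is.null(names(v))) v else as.list(v))
}
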