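# Shared synthetic fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

# uniform image of known stain concentrations, built directly from the
# documented optical-density model (independent of the package's renderer)
render_conc <- function(c_dab, c_hema, n = 4) {
  sv <- stain_vectors()
  od <- c_hema * sv["hematoxylin", ] + c_dab * sv["dab", ]
  rgb <- round(exp(-od) * 255) / 255
  array(rep(rgb, each = n * n), c(n, n, 3))
}

# small, fast core for unit tests
small_core_spec <- function(fraction = 0.15, seed = 42, ...) {
  args <- utils::modifyList(
    list(width_px = 220, height_px = 220, n_myocytes = 30,
         myocyte_area_px_mean = 700, myocyte_area_px_sd = 150,
         n_debris = 8, debris_area_px_max = 15, n_vessels = 1,
         true_mosaic_fraction = fraction, seed = seed),
    list(...))
  do.call(image_spec, args)
}

# cohort with a single disease category: isolates fixed effects from
# disease-induced subject heterogeneity
control_only_spec <- function(...) {
  args <- utils::modifyList(
    list(disease_effects_sqrt_scale = c(Control = 0),
         disease_probs = c(Control = 1)),
    list(...))
  do.call(cohort_spec, args)
}

cached_core <- function(key, spec) {
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_core_image(spec)
  }
  .fixture_cache[[key]]
}

cached_series <- function(key, core, config = quant_config()) {
  skey <- paste0(key, "_series")
  if (is.null(.fixture_cache[[skey]])) {
    intensity <- compute_brown_intensity(core$image)
    .fixture_cache[[skey]] <- generate_mask_series(intensity,
                                                   core$exclusion_mask, config)
  }
  .fixture_cache[[skey]]
}
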