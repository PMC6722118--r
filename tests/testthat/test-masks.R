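test_that("build_mask thresholds at factor x base and validates inputs", {
  m <- matrix(seq(0, 1, length.out = 100), 10, 10)
  mk <- build_mask(m, base_threshold = 0.4, correction_factor = 1.5)
  expect_identical(unclass(mk)[1:100], (m >= 0.6)[1:100])
  expect_error(build_mask(m, 0.4, 0), class = "mosaicquant_validation_error")
  expect_error(build_mask(m, 0.4, -1), class = "mosaicquant_validation_error")
  # huge factor -> empty; vanishing factor -> every stained pixel
  expect_equal(sum(build_mask(m, 0.4, 100)), 0)
  expect_equal(sum(build_mask(m, 0.4, 1e-9)), sum(m > 0))
})

test_that("mask series has the published structure and nests across factors", {
  core <- cached_core("mid", small_core_spec())
  ser <- cached_series("mid", core)
  expect_length(ser$myl4_masks, 11)
  expect_equal(ser$factors, seq(1.5, 2.75, by = 0.125))
  expect_equal(ser$myocyte_factor, 0.5)
  for (i in 2:11) {
    # pre-filter masks strictly nested as the factor tightens
    expect_true(all(ser$myl4_prefilter[[i - 1]][ser$myl4_prefilter[[i]]]),
                label = sprintf("prefilter nesting %d", i))
    # nesting survives the size filter
    expect_true(all(ser$myl4_masks[[i - 1]][ser$myl4_masks[[i]]]),
                label = sprintf("postfilter nesting %d", i))
  }
  # every MYL4 mask nests inside the all-myocyte mask
  for (i in 1:11) {
    expect_true(all(ser$myocyte_prefilter[ser$myl4_prefilter[[i]]]))
  }
  areas <- vapply(ser$myl4_masks, sum, numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("config validation rejects malformed factor ladders", {
  expect_error(quant_config(factors = c(2, 1.5)),
               class = "mosaicquant_validation_error")
  expect_error(quant_config(factors = c(1.5, 1.5, 2)),
               class = "mosaicquant_validation_error")
  expect_error(quant_config(myocyte_factor = 1.6),
               class = "mosaicquant_validation_error")
  expect_error(quant_config(selection = "manual"),
               class = "mosaicquant_validation_error")
})

test_that("score arithmetic follows the defining area ratio", {
  mk <- function(n_true, base = 0.4, f = 1.5) {
    m <- matrix(FALSE, 50, 50)
    m[seq_len(n_true)] <- TRUE
    structure(m, correction_factor = f, base_threshold = base)
  }
  fake_series <- function(pos_px, myo_px) {
    structure(list(base_threshold = 0.4, factors = seq(1.5, 2.75, 0.125),
                   myocyte_factor = 0.5,
                   myl4_masks = c(list(mk(pos_px)), rep(list(mk(0)), 10)),
                   myl4_prefilter = c(list(mk(pos_px)), rep(list(mk(0)), 10)),
                   myocyte_mask = mk(myo_px, f = 0.5),
                   myocyte_prefilter = mk(myo_px, f = 0.5),
                   intensity = matrix(0.5, 50, 50),
                   config = quant_config()),
              class = "mask_series")
  }
  expect_equal(score_mosaicism(fake_series(300, 2000), "manual", 1)$percent_positive, 15)
  expect_equal(score_mosaicism(fake_series(0, 2000), "manual", 1)$percent_positive, 0)
  expect_equal(score_mosaicism(fake_series(2000, 2000), "manual", 1)$percent_positive, 100)
  expect_error(score_mosaicism(fake_series(10, 0), "manual", 1),
               class = "mosaicquant_degenerate_core")
})

test_that("manual exclusion is a no-op when empty and fatal when total", {
  core <- cached_core("mid", small_core_spec())
  cfg <- quant_config()
  none <- matrix(FALSE, nrow(core$image), ncol(core$image))
  s_plain <- quantify_core(core$image, NULL, cfg)
  s_zero <- quantify_core(core$image, none, cfg)
  expect_equal(s_zero$percent_positive, s_plain$percent_positive)
  expect_error(quantify_core(core$image, !none, cfg),
               class = "mosaicquant_degenerate_core")
  expect_error(apply_manual_exclusion(core$image, matrix(FALSE, 2, 2)),
               class = "mosaicquant_shape_error")
})

test_that("excluding an unstained vessel leaves the score unchanged", {
  core <- cached_core("mid", small_core_spec())
  with_ex <- quantify_core(core$image, core$exclusion_mask)
  without <- quantify_core(core$image, NULL)
  expect_equal(with_ex$percent_positive, without$percent_positive,
               tolerance = 1e-10)
})

test_that("quantification is deterministic and exact on synthetic cores", {
  core <- cached_core("mid", small_core_spec())
  s1 <- quantify_core(core$image, core$exclusion_mask)
  s2 <- quantify_core(core$image, core$exclusion_mask)
  expect_identical(s1, s2)
  expect_lt(abs(s1$percent_positive - core$ground_truth$true_mosaic_percent), 2)
  expect_true(s1$percent_positive >= 0 && s1$percent_positive <= 100)
})

test_that("unevaluable cores become NA rows in the score table, not errors", {
  blank <- array(1, c(64, 64, 3))
  core <- cached_core("mid", small_core_spec())
  out <- quantify_cores(list(a = core$image, b = blank))
  expect_equal(nrow(out), 2)
  expect_true(is.na(out$percent_positive[out$core_id == "b"]))
  expect_equal(out$qc_flags[out$core_id == "b"], "unevaluable")
  expect_error(quantify_cores(list(blank, blank)),
               class = "mosaicquant_validation_error")
})
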