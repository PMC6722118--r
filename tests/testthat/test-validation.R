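make_scores <- function(ids, pct) tibble::tibble(core_id = ids, percent_positive = pct)
make_manual <- function(ids, pct) {
  tibble::tibble(core_id = ids, n_positive_cells = round(pct),
                 n_total_cells = 100, percent_positive_cells = pct)
}

test_that("concordance hits the exact endpoints", {
  ids <- paste0("c", 1:5)
  expect_equal(manual_vs_area_correlation(make_manual(ids, c(1, 5, 10, 20, 40)),
                                          make_scores(ids, c(1, 5, 10, 20, 40)))$r, 1)
  expect_equal(manual_vs_area_correlation(make_manual(ids[1:3], c(1, 2, 3)),
                                          make_scores(ids[1:3], c(3, 2, 1)))$r, -1)
})

test_that("concordance validates pairing and variance", {
  ids <- paste0("c", 1:5)
  expect_error(manual_vs_area_correlation(make_manual(ids[1:2], c(1, 2)),
                                          make_scores(ids[1:2], c(1, 2))),
               class = "mosaicquant_insufficient_data")
  expect_error(manual_vs_area_correlation(make_manual(ids, rep(5, 5)),
                                          make_scores(ids, 1:5)),
               class = "mosaicquant_degenerate_input")
  res <- manual_vs_area_correlation(make_manual(ids, c(1, 2, 3, 4, 5)),
                                    make_scores(c(ids[1:4], "zz"), c(2, 3, 4, 5, 6)))
  expect_equal(res$n_pairs, 4)
  expect_setequal(res$unmatched_ids, c("c5", "zz"))
})

test_that("concordance is symmetric and affine invariant", {
  set.seed(50)
  for (i in 1:10) {
    ids <- paste0("c", 1:8)
    x <- runif(8, 0, 50)
    y <- x + rnorm(8, 0, 5)
    r <- manual_vs_area_correlation(make_manual(ids, x), make_scores(ids, y))$r
    # swap roles
    r_swap <- manual_vs_area_correlation(make_manual(ids, y), make_scores(ids, x))$r
    expect_equal(r, r_swap, tolerance = 1e-12)
    # rescale one vector: r unchanged
    r_scaled <- manual_vs_area_correlation(make_manual(ids, 3 * x + 7),
                                           make_scores(ids, y))$r
    expect_equal(r, r_scaled, tolerance = 1e-12)
  }
})

test_that("replicate variation matches hand-computed pairwise means", {
  tb <- tibble::tibble(subject_id = c("a", "a"), percent_positive = c(10, 14))
  expect_equal(replicate_variation(tb)$overall, 4)
  tb3 <- tibble::tibble(subject_id = "a", percent_positive = c(10, 14, 18))
  expect_equal(replicate_variation(tb3)$overall, 16 / 3)
  same <- tibble::tibble(subject_id = rep(c("a", "b"), each = 2),
                         percent_positive = c(5, 5, 9, 9))
  expect_equal(replicate_variation(same)$overall, 0)
  expect_error(replicate_variation(tibble::tibble(subject_id = "a",
                                                  percent_positive = 3)),
               class = "mosaicquant_validation_error")
})

test_that("replicate variation ignores subject order and supports range mode", {
  set.seed(8)
  tb <- tibble::tibble(subject_id = rep(paste0("s", 1:20), each = 2),
                       percent_positive = runif(40, 0, 30))
  shuffled <- tb[sample(nrow(tb)), ]
  expect_equal(replicate_variation(tb)$overall,
               replicate_variation(shuffled)$overall)
  expect_gte(replicate_variation(tb, mode = "range")$overall,
             replicate_variation(tb)$overall)
})

test_that("paired cell-area test matches the textbook formula", {
  paired <- tibble::tibble(
    core_id = rep(paste0("c", 1:3), each = 2),
    group = rep(c("positive", "negative"), 3),
    area = c(11, 10, 12, 10, 13, 10))  # per-core differences 1, 2, 3
  res <- compare_cell_areas(paired)
  oracle <- oracle_paired_t(c(1, 2, 3))
  expect_equal(res$statistic, oracle$t, tolerance = 1e-10)
  expect_equal(res$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, oracle$p, tolerance = 1e-10)
  set.seed(17)
  for (i in 1:10) {
    n <- sample(4:12, 1)
    pr <- tibble::tibble(core_id = rep(paste0("c", 1:n), each = 4),
                         group = rep(c("positive", "positive",
                                       "negative", "negative"), n),
                         area = rnorm(4 * n, 100, 15))
    res <- compare_cell_areas(pr)
    per <- attr(res, "per_core")
    oc <- oracle_paired_t(per$positive - per$negative)
    expect_equal(res$statistic, oc$t, tolerance = 1e-10)
    expect_equal(res$p_value, oc$p, tolerance = 1e-10)
  }
})

test_that("degenerate and undersized paired designs are handled", {
  allsame <- tibble::tibble(core_id = rep(c("a", "b"), each = 2),
                            group = rep(c("positive", "negative"), 2),
                            area = c(10, 10, 20, 20))
  res <- compare_cell_areas(allsame)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(compare_cell_areas(allsame[1:2, ]),
               class = "mosaicquant_insufficient_data")
})

test_that("equal area distributions rarely reject (type-I behaviour)", {
  set.seed(99)
  pvals <- replicate(200, {
    pr <- tibble::tibble(core_id = rep(paste0("c", 1:13), each = 20),
                         group = rep(rep(c("positive", "negative"), each = 10), 13),
                         area = rnorm(260, 900, 120))
    compare_cell_areas(pr)$p_value
  })
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("welch mode pools cells across cores", {
  set.seed(3)
  pr <- tibble::tibble(core_id = rep(paste0("c", 1:5), each = 8),
                       group = rep(c("positive", "negative"), 20),
                       area = rnorm(40, 500, 50))
  res <- compare_cell_areas(pr, mode = "pooled_welch")
  expect_equal(res$mode, "pooled_welch")
  expect_true(res$p_value > 0 && res$p_value <= 1)
})

test_that("truth-derived manual counts and paired areas are consistent", {
  core <- cached_core("mid", small_core_spec())
  mc <- manual_counts_from_truth(list(x = core))
  gt <- core$ground_truth
  expect_equal(mc$n_positive_cells, sum(gt$positive_flags))
  expect_equal(mc$n_total_cells, length(gt$positive_flags))
  pa <- paired_areas_from_truth(list(x = core))
  expect_equal(nrow(pa), length(gt$per_myocyte_area_px))
  expect_equal(sum(pa$area), sum(gt$per_myocyte_area_px))
})
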