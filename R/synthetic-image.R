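#' Specification of a synthetic DAB-stained core image
#'
#' Describes one synthetic tissue-microarray core: mosaic DAB staining (a
#' minority of strongly brown myocytes among blush-stained ones on a
#' hematoxylin background), sub-50-pixel debris specks, and vessel-shaped
#' unstained regions. Myocytes are convex elliptical blobs placed on a
#' jittered grid without overlap; staining is rendered through the two-stain
#' optical-density model of [stain_vectors()] so the quantifier's colour
#' deconvolution has a physically sensible inverse.
#'
#' Intensity defaults place the blush (negative) and dark-brown (positive)
#' DAB levels so that the Otsu base threshold lands just above the blush
#' mode: the all-myocyte mask at factor 0.5 then retains essentially all
#' myocyte pixels while at least one correction factor in 1.5-2.75 falls in
#' the empty gap below the dark-brown mode. `dab_intensity_sd` is split into
#' a cell-level component (0.8 sd) and a pixel-level component (0.6 sd).
#'
#' @param width_px,height_px Image size in pixels.
#' @param n_myocytes Number of myocyte blobs.
#' @param true_mosaic_fraction Target fraction of myocyte area rendered
#'   DAB-positive, in `[0, 1]`.
#' @param myocyte_area_px_mean,myocyte_area_px_sd Blob area distribution in
#'   pixels. With `myocyte_area_px_sd = 0` every myocyte is an identical
#'   integer-centred circle, so all blobs have exactly equal pixel area.
#' @param dab_pos_intensity_mean,dab_neg_intensity_mean Mean DAB
#'   concentration of positive (dark brown) and negative (blush) myocytes;
#'   positives must exceed negatives.
#' @param dab_intensity_sd Total DAB concentration SD across and within cells.
#' @param hematoxylin_intensity_mean Mean hematoxylin concentration in tissue.
#' @param n_debris Number of small DAB-dark debris specks on background.
#' @param debris_area_px_max Maximum debris speck area (pixels); keep below
#'   the 50-pixel size filter for clean fixtures.
#' @param n_vessels Number of vessel-shaped unstained regions (hematoxylin
#'   ring around a white lumen); these are marked in the exclusion mask.
#' @param seed Integer RNG seed; identical specs yield bit-identical images.
#' @return A validated list of class `image_spec`.
#' @export
image_spec <- function(width_px = 512, height_px = 512,
                       n_myocytes = 120,
                       true_mosaic_fraction = 0.15,
                       myocyte_area_px_mean = 900,
                       myocyte_area_px_sd = 250,
                       dab_pos_intensity_mean = 0.85,
                       dab_neg_intensity_mean = 0.30,
                       dab_intensity_sd = 0.025,
                       hematoxylin_intensity_mean = 0.6,
                       n_debris = 25,
                       debris_area_px_max = 20,
                       n_vessels = 2,
                       seed = 1L) {
  spec <- list(width_px = width_px, height_px = height_px,
               n_myocytes = n_myocytes,
               true_mosaic_fraction = true_mosaic_fraction,
               myocyte_area_px_mean = myocyte_area_px_mean,
               myocyte_area_px_sd = myocyte_area_px_sd,
               dab_pos_intensity_mean = dab_pos_intensity_mean,
               dab_neg_intensity_mean = dab_neg_intensity_mean,
               dab_intensity_sd = dab_intensity_sd,
               hematoxylin_intensity_mean = hematoxylin_intensity_mean,
               n_debris = n_debris, debris_area_px_max = debris_area_px_max,
               n_vessels = n_vessels, seed = as.integer(seed))
  validate_image_spec(spec)
  structure(spec, class = "image_spec")
}

validate_image_spec <- function(s) {
  chk <- function(ok, field, msg) {
    if (!ok) abort(sprintf("Invalid `%s`: %s", field, msg),
                   class = "mosaicquant_validation_error")
  }
  chk(s$width_px >= 32 && s$height_px >= 32, "width_px", "image must be at least 32 x 32")
  chk(s$n_myocytes >= 1, "n_myocytes", "need at least one myocyte")
  chk(s$true_mosaic_fraction >= 0 && s$true_mosaic_fraction <= 1,
      "true_mosaic_fraction", "must lie in [0, 1]")
  chk(s$myocyte_area_px_mean > 0, "myocyte_area_px_mean", "must be positive")
  chk(s$myocyte_area_px_sd >= 0, "myocyte_area_px_sd", "must be nonnegative")
  chk(s$dab_pos_intensity_mean > 0 && s$dab_pos_intensity_mean <= 1,
      "dab_pos_intensity_mean", "must lie in (0, 1]")
  chk(s$dab_neg_intensity_mean >= 0 && s$dab_neg_intensity_mean < 1,
      "dab_neg_intensity_mean", "must lie in [0, 1)")
  chk(s$dab_pos_intensity_mean > s$dab_neg_intensity_mean,
      "dab_pos_intensity_mean", "positive stain must be darker than negative")
  chk(s$dab_intensity_sd >= 0, "dab_intensity_sd", "must be nonnegative")
  chk(s$hematoxylin_intensity_mean >= 0 && s$hematoxylin_intensity_mean <= 1,
      "hematoxylin_intensity_mean", "must lie in [0, 1]")
  chk(s$n_debris >= 0, "n_debris", "must be nonnegative")
  chk(s$debris_area_px_max >= 1 || s$n_debris == 0,
      "debris_area_px_max", "must be >= 1 when debris are requested")
  chk(s$n_vessels >= 0, "n_vessels", "must be nonnegative")
  invisible(s)
}

#' Generate one synthetic core image with exact ground truth
#'
#' Renders the core described by an [image_spec()] and records ground truth
#' from the rendered pixels (not the requested fraction), so downstream
#' recovery tests compare against exact pixel counts.
#'
#' @param spec An [image_spec()].
#' @return List of class `synthetic_core` with elements:
#'   * `image`: `height x width x 3` RGB array, 8-bit quantised, in `[0,1]`;
#'   * `ground_truth`: list of class `core_ground_truth` with
#'     `true_mosaic_percent`, `true_positive_area_px`, `true_myocyte_area_px`,
#'     `myocyte_labels` (integer matrix), `positive_flags`,
#'     `per_myocyte_area_px`;
#'   * `exclusion_mask`: logical matrix marking vessel regions;
#'   * `spec`: the input spec.
#' @export
generate_core_image <- function(spec) {
  stopifnot(inherits(spec, "image_spec"))
  validate_image_spec(spec)
  set.seed(spec$seed)
  W <- spec$width_px; H <- spec$height_px
  need <- spec$n_myocytes + spec$n_vessels

  # jittered grid: disjoint square cells guarantee non-overlap
  ncols <- ceiling(sqrt(need * W / H))
  nrows <- ceiling(need / ncols)
  cs <- floor(min(W / ncols, H / nrows))
  capacity <- floor(W / cs) * floor(H / cs)
  if (cs < 8 || capacity < need) {
    abort(sprintf("Image %dx%d too small to place %d myocytes and %d vessels.",
                  W, H, spec$n_myocytes, spec$n_vessels),
          class = "mosaicquant_capacity_error")
  }
  ncols <- floor(W / cs); nrows <- floor(H / cs)
  cells <- sample(capacity, need)  # which grid cells are used
  r_max <- cs / 2 - 1.5
  a_max <- 0.95 * pi * r_max^2

  labels <- matrix(0L, H, W)
  c_dab <- matrix(0, H, W)
  c_hema <- matrix(0, H, W)
  exclusion <- matrix(FALSE, H, W)

  equal_area <- spec$myocyte_area_px_sd == 0
  areas <- if (equal_area) {
    rep(min(spec$myocyte_area_px_mean, a_max), spec$n_myocytes)
  } else {
    pmin(pmax(rnorm(spec$n_myocytes, spec$myocyte_area_px_mean,
                    spec$myocyte_area_px_sd), 300), a_max)
  }

  for (i in seq_len(need)) {
    cell <- cells[i] - 1L
    ox <- (cell %% ncols) * cs      # cell origin (0-based)
    oy <- (cell %/% ncols) * cs
    is_vessel <- i > spec$n_myocytes
    if (is_vessel) {
      a <- runif(1, 0.5, 0.9) * r_max
      b <- runif(1, 0.5, 1) * a
      theta <- runif(1, 0, pi)
    } else if (equal_area) {
      a <- b <- sqrt(areas[i] / pi)
      theta <- 0
    } else {
      ratio <- runif(1, 0.55, 0.95)
      a <- min(sqrt(areas[i] / (pi * ratio)), r_max)
      b <- areas[i] / (pi * a)
      theta <- runif(1, 0, pi)
    }
    jit <- r_max - max(a, b)
    cx <- round(ox + cs / 2 + runif(1, -jit, jit))
    cy <- round(oy + cs / 2 + runif(1, -jit, jit))
    xs <- (ox + 1):min(ox + cs, W)
    ys <- (oy + 1):min(oy + cs, H)
    dx <- outer(rep(1, length(ys)), xs - cx)
    dy <- outer(ys - cy, rep(1, length(xs)))
    u <- (dx * cos(theta) + dy * sin(theta)) / a
    v <- (-dx * sin(theta) + dy * cos(theta)) / b
    inside <- u^2 + v^2 <= 1
    if (is_vessel) {
      ring <- inside & (u^2 + v^2 >= 0.45)
      blk <- c_hema[ys, xs]; blk[ring] <- 0.7; c_hema[ys, xs] <- blk
      ex <- exclusion[ys, xs]; ex[inside] <- TRUE; exclusion[ys, xs] <- ex
    } else {
      blk <- labels[ys, xs]; blk[inside] <- i; labels[ys, xs] <- blk
    }
  }

  n_myo <- spec$n_myocytes
  per_area <- tabulate(labels[labels > 0L], n_myo)
  total_area <- sum(per_area)
  positive_flags <- choose_positive_myocytes(per_area, spec$true_mosaic_fraction)

  # per-cell then per-pixel stain concentration; sd split 0.8/0.6 cell/pixel
  cell_sd <- 0.8 * spec$dab_intensity_sd
  px_sd <- 0.6 * spec$dab_intensity_sd
  cell_mean <- ifelse(positive_flags, spec$dab_pos_intensity_mean,
                      spec$dab_neg_intensity_mean)
  cell_dab <- pmax(rnorm(n_myo, cell_mean, cell_sd), 0.02)
  cell_hema <- pmax(rnorm(n_myo, spec$hematoxylin_intensity_mean, 0.05), 0)
  myo_px <- labels > 0L
  c_dab[myo_px] <- pmax(cell_dab[labels[myo_px]] +
                          rnorm(total_area, 0, px_sd), 0.02)
  c_hema[myo_px] <- pmax(cell_hema[labels[myo_px]] +
                           rnorm(total_area, 0, 0.03), 0)

  # debris: dark sub-filter specks on background, not touching tissue
  occupied <- myo_px | exclusion
  if (spec$n_debris > 0) {
    deb <- place_debris(occupied, spec$n_debris, spec$debris_area_px_max, W, H)
    c_dab[deb] <- pmax(rnorm(sum(deb), spec$dab_pos_intensity_mean, px_sd), 0.02)
    c_hema[deb] <- 0.2
  }

  img <- render_stains(c_hema, c_dab)
  pos_area <- sum(per_area[positive_flags])
  truth <- structure(list(
    true_mosaic_percent = 100 * pos_area / total_area,
    true_positive_area_px = as.integer(pos_area),
    true_myocyte_area_px = as.integer(total_area),
    myocyte_labels = labels,
    positive_flags = positive_flags,
    per_myocyte_area_px = as.integer(per_area)
  ), class = "core_ground_truth")
  structure(list(image = img, ground_truth = truth,
                 exclusion_mask = exclusion, spec = spec),
            class = "synthetic_core")
}

# Randomised greedy subset whose area sums closest to the target fraction:
# add shuffled myocytes until the running total brackets the target, then
# keep whichever endpoint is nearer.
choose_positive_myocytes <- function(per_area, fraction) {
  n <- length(per_area)
  flags <- rep(FALSE, n)
  if (fraction <= 0) return(flags)
  if (fraction >= 1) return(rep(TRUE, n))
  target <- fraction * sum(per_area)
  ord <- sample(n)
  csum <- cumsum(per_area[ord])
  k <- findInterval(target, csum) # csum[k] <= target < csum[k+1]
  k <- if (k >= n) n
  else if (k == 0) 1L
  else if (abs(csum[k] - target) <= abs(csum[k + 1] - target)) k
  else k + 1L
  flags[ord[seq_len(k)]] <- TRUE
  flags
}

place_debris <- function(occupied, n_debris, area_max, W, H) {
  deb <- matrix(FALSE, H, W)
  forbidden <- occupied
  for (i in seq_len(n_debris)) {
    area <- runif(1, min(4, area_max), area_max)
    r <- max(1, sqrt(area / pi))
    m <- ceiling(r) + 2L
    placed <- FALSE
    for (try in 1:50) {
      cx <- sample(seq(m + 1L, W - m), 1)
      cy <- sample(seq(m + 1L, H - m), 1)
      ys <- (cy - m):(cy + m); xs <- (cx - m):(cx + m)
      if (any(forbidden[ys, xs]) || any(deb[ys, xs])) next
      dy <- outer(ys - cy, rep(1, length(xs)))
      dx <- outer(rep(1, length(ys)), xs - cx)
      disk <- dx^2 + dy^2 <= r^2
      blk <- deb[ys, xs]; blk[disk] <- TRUE; deb[ys, xs] <- blk
      placed <- TRUE
      break
    }
    # crowded image: silently place fewer specks than requested
    if (!placed) break
  }
  deb
}

#' @export
print.synthetic_core <- function(x, ...) {
  gt <- x$ground_truth
  cat(sprintf("<synthetic_core> %dx%d, %d myocytes, true mosaicism %.2f%%\n",
              x$spec$width_px, x$spec$height_px,
              length(gt$per_myocyte_area_px), gt$true_mosaic_percent))
  invisible(x)
}
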