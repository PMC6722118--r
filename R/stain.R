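#' Hematoxylin/DAB stain vector matrix
#'
#' Unit optical-density colour vectors for the two brightfield stains:
#' hematoxylin (blue-purple nuclear counterstain) and DAB (brown chromogen).
#' Defaults are the standard published H-DAB vectors used throughout
#' histology colour deconvolution; rows are normalised to unit length.
#'
#' @param hematoxylin,dab Length-3 numeric OD vectors (R, G, B absorbance).
#' @return A 2 x 3 matrix with rows `hematoxylin` and `dab`.
#' @export
stain_vectors <- function(hematoxylin = c(0.650, 0.704, 0.286),
                          dab = c(0.269, 0.568, 0.778)) {
  m <- rbind(hematoxylin = hematoxylin, dab = dab)
  if (ncol(m) != 3 || any(!is.finite(m)) || any(rowSums(m^2) == 0)) {
    abort("Stain vectors must be finite length-3 vectors of nonzero norm.",
          class = "mosaicquant_validation_error")
  }
  m / sqrt(rowSums(m^2))
}

# Beer-Lambert transforms between transmitted intensity in [0,1] and OD.
# Intensities are clamped at 1/255 so 8-bit black maps to a finite OD.
rgb_to_od <- function(x) -log(pmax(x, 1 / 255))
od_to_rgb <- function(od) exp(-od)

#' Extract per-pixel DAB (brown) intensity from an RGB image
#'
#' Converts an 8-bit RGB brightfield image to optical density and unmixes the
#' two-stain hematoxylin/DAB model by least squares against the stain matrix,
#' returning the DAB coefficient per pixel. Pure white background maps to ~0
#' and hematoxylin-only pixels map to ~0 DAB. An alternative `"blue_ratio"`
#' mode (OD blue minus OD red, floored at zero) is provided for sensitivity
#' analysis of the unmixing step.
#'
#' @param img Numeric array `height x width x 3` with values in `[0, 1]`.
#' @param stains Stain matrix from [stain_vectors()].
#' @param mode `"deconvolution"` (default) or `"blue_ratio"`.
#' @return Numeric `height x width` matrix of nonnegative DAB intensities
#'   (optical-density-like units).
#' @export
compute_brown_intensity <- function(img, stains = stain_vectors(),
                                    mode = c("deconvolution", "blue_ratio")) {
  mode <- match.arg(mode)
  if (!(is.array(img) && length(dim(img)) == 3 && dim(img)[3] == 3)) {
    abort("`img` must be a height x width x 3 RGB array.",
          class = "mosaicquant_format_error")
  }
  if (max(img) <= 1 / 255) {
    abort("Image is entirely black; stain intensities are undefined.",
          class = "mosaicquant_degenerate_core")
  }
  d <- dim(img)
  od <- rgb_to_od(matrix(img, d[1] * d[2], 3))
  if (mode == "blue_ratio") {
    dab <- pmax(od[, 3] - od[, 1], 0)
  } else {
    # minimum-norm unmixing: coefficients = OD %*% pinv(M)
    pinv <- t(stains) %*% solve(stains %*% t(stains))
    dab <- pmax(od %*% pinv[, 2], 0)
  }
  matrix(dab, d[1], d[2])
}

# Forward render: per-pixel stain concentrations -> 8-bit-quantised RGB array.
# Inverse of compute_brown_intensity() up to quantisation.
render_stains <- function(c_hema, c_dab, stains = stain_vectors()) {
  stopifnot(identical(dim(c_hema), dim(c_dab)))
  od <- cbind(as.vector(c_hema), as.vector(c_dab)) %*% stains
  rgb <- od_to_rgb(od)
  rgb <- round(rgb * 255) / 255
  array(rgb, c(nrow(c_hema), ncol(c_hema), 3))
}
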