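#' Pixel-to-micron calibration scales
#'
#' The calibration contexts used for carbon-area quantification:
#' `brightfield_100x` for light-microscope cytospin images (146 pixels =
#' 10 um), `confocal_2d` for 2D femtosecond-microscopy images (75 pixels =
#' 10 um) and `confocal_3d_montage` for maximum-intensity projections of 3D
#' z-stacks (158 pixels = 41 um).
#'
#' @param context One of `"brightfield_100x"`, `"confocal_2d"`,
#'   `"confocal_3d_montage"`, or `"custom"` (then give `pixels_per_unit`).
#' @param pixels_per_unit Pixels per micrometre along one axis; required for
#'   `"custom"`, ignored otherwise.
#' @return A list of class `amclear_calibration` with `pixels_per_unit` and
#'   `context`.
#' @examples
#' calibration_scale("brightfield_100x")$pixels_per_unit # 14.6
#' @export
calibration_scale <- function(context = c("brightfield_100x", "confocal_2d",
                                          "confocal_3d_montage", "custom"),
                              pixels_per_unit = NULL) {
  context <- match.arg(context)
  ppu <- switch(context,
                brightfield_100x = 146 / 10,
                confocal_2d = 75 / 10,
                confocal_3d_montage = 158 / 41,
                custom = pixels_per_unit)
  if (is.null(ppu) || !is.finite(ppu) || ppu <= 0) {
    stop("pixels_per_unit must be a positive number", call. = FALSE)
  }
  structure(list(pixels_per_unit = ppu, context = context),
            class = "amclear_calibration")
}

#' Convert a pixel count to an area in square micrometres
#'
#' `n_pixels * (1 / pixels_per_unit)^2`: each pixel covers a square of side
#' `1/pixels_per_unit` micrometres.
#'
#' @param n_pixels Non-negative integer pixel count (vectorised).
#' @param cal A [calibration_scale()].
#' @return Area in um^2.
#' @examples
#' pixels_to_area(21316, calibration_scale("brightfield_100x")) # 100
#' @export
pixels_to_area <- function(n_pixels, cal) {
  if (!inherits(cal, "amclear_calibration")) {
    stop("cal must come from calibration_scale()", call. = FALSE)
  }
  if (any(n_pixels < 0)) stop("pixel counts must be >= 0", call. = FALSE)
  n_pixels * (1 / cal$pixels_per_unit)^2
}

#' Otsu threshold of an intensity sample
#'
#' Maximises between-class variance over a 256-bin histogram of the supplied
#' intensities (values in `[0, 1]`). Returned as the upper edge of the
#' optimal bin, so `x <= threshold` selects the dark class.
#'
#' @param x Numeric vector of intensities in `[0, 1]`.
#' @param n_bins Histogram resolution.
#' @return Scalar threshold, or `NA` if the sample is uniform.
#' @export
threshold_otsu <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2L) return(NA_real_)
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  # the criterion plateaus across empty histogram gaps; take the plateau
  # midpoint so the threshold sits between the classes
  top <- which(sigma_b >= max(sigma_b) * (1 - 1e-10))
  k <- round(mean(range(top)))
  breaks[k + 1L]
}

#' IsoData (intermeans) threshold of an intensity sample
#'
#' The iterative intermeans algorithm behind ImageJ's default automatic
#' threshold: starting from the overall mean, repeatedly set the threshold to
#' the average of the means of the two classes it induces, until stable.
#'
#' @inheritParams threshold_otsu
#' @return Scalar threshold (dark class is `x <= threshold`), or `NA` if the
#'   sample is uniform.
#' @export
threshold_isodata <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2L) return(NA_real_)
  thr <- mean(x)
  for (iter in 1:100) {
    lo <- x[x <= thr]; hi <- x[x > thr]
    if (!length(lo) || !length(hi)) break
    new_thr <- (mean(lo) + mean(hi)) / 2
    if (abs(new_thr - thr) < 1 / (2 * n_bins)) { thr <- new_thr; break }
    thr <- new_thr
  }
  thr
}

#' Collapse an RGB array to grey-scale intensity
#'
#' Rec. 709 luminance weighting (0.2126 R + 0.7152 G + 0.0722 B). Grey
#' matrices pass through unchanged; an alpha channel is ignored.
#'
#' @param img Numeric matrix, or height x width x channels array.
#' @return Numeric matrix of intensities.
#' @export
rgb_to_gray <- function(img) {
  if (is.matrix(img)) return(img)
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    if (nc == 1L) return(img[, , 1])
    return(0.2126 * img[, , 1] + 0.7152 * img[, , 2] + 0.0722 * img[, , 3])
  }
  stop("unsupported image shape", call. = FALSE)
}

#' Measure the black-carbon area within one cell
#'
#' Reproduces the per-cell measurement step: the image is collapsed to
#' grey-scale, an automatic threshold is computed from the intensities inside
#' the cell mask, pixels at or below the threshold (dark inclusions) are
#' counted, and the count is converted to um^2 through the calibration. A
#' mask whose intensities are uniform has no separable dark class and yields
#' zero foreground by convention.
#'
#' @param image Grey matrix or RGB array with values in `[0, 1]`.
#' @param mask Logical (or 0/1) matrix of the same height/width marking the
#'   cell; the threshold is computed from, and counts restricted to, this
#'   region.
#' @param cal A [calibration_scale()].
#' @param threshold_method `"otsu"` (default) or `"isodata"`.
#' @param slide_id,cell_id Identifiers carried into the result.
#' @return One-row data frame: `slide_id`, `cell_id`, `n_foreground_pixels`,
#'   `bc_area_um2`, `threshold`, `threshold_method`.
#' @export
quantify_cell <- function(image, mask, cal,
                          threshold_method = c("otsu", "isodata"),
                          slide_id = NA_character_, cell_id = NA_character_) {
  threshold_method <- match.arg(threshold_method)
  gray <- rgb_to_gray(image)
  mask <- mask > 0
  if (!identical(dim(gray), dim(mask))) {
    stop("mask and image dimensions differ", call. = FALSE)
  }
  if (!any(mask)) stop("empty cell mask", call. = FALSE)
  vals <- gray[mask]
  thr <- switch(threshold_method,
                otsu = threshold_otsu(vals),
                isodata = threshold_isodata(vals))
  n_fg <- if (is.na(thr)) 0L else sum(vals <= thr)
  data.frame(slide_id = slide_id, cell_id = cell_id,
             n_foreground_pixels = as.integer(n_fg),
             bc_area_um2 = pixels_to_area(n_fg, cal),
             threshold = thr, threshold_method = threshold_method,
             stringsAsFactors = FALSE)
}

#' Summarise per-cell measurements into a slide summary
#'
#' Median and 90th percentile of the per-cell carbon areas, computed with
#' linear interpolation between order statistics (R quantile type 7) — the
#' single percentile rule used throughout the package, kinetics inputs
#' included. Slides with fewer than `min_cells` measured cells are flagged
#' invalid rather than silently summarised.
#'
#' @param measurements Data frame with a `bc_area_um2` column (e.g. rows from
#'   [quantify_cell()]).
#' @param min_cells Minimum cell count for a valid slide.
#' @param slide_id Identifier carried into the result.
#' @return One-row data frame: `slide_id`, `n_cells`, `median_bc_um2`,
#'   `p90_bc_um2`, `valid`. Summaries are `NA` for invalid slides.
#' @examples
#' summarize_slide(data.frame(bc_area_um2 = 1:25))
#' @export
summarize_slide <- function(measurements, min_cells = 25L,
                            slide_id = NA_character_) {
  areas <- measurements$bc_area_um2
  if (is.null(areas)) stop("measurements need a bc_area_um2 column",
                           call. = FALSE)
  n <- length(areas)
  if (n < min_cells) {
    return(data.frame(slide_id = slide_id, n_cells = n,
                      median_bc_um2 = NA_real_, p90_bc_um2 = NA_real_,
                      valid = FALSE, stringsAsFactors = FALSE))
  }
  qs <- stats::quantile(areas, c(0.5, 0.9), type = 7, names = FALSE)
  data.frame(slide_id = slide_id, n_cells = n,
             median_bc_um2 = qs[1], p90_bc_um2 = qs[2], valid = TRUE,
             stringsAsFactors = FALSE)
}

#' Read a grey-scale image from PNG or TIFF
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @return Numeric intensity matrix in `[0, 1]` (RGB collapsed by
#'   [rgb_to_gray()]).
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext, call. = FALSE))
  rgb_to_gray(img)
}

#' Write a grey-scale matrix as PNG or TIFF
#'
#' @param img Numeric matrix with values in `[0, 1]`.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return Invisibly, `path`.
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(img, path),
         tif = ,
         tiff = tiff::writeTIFF(img, path),
         stop("unsupported image format: .", ext, call. = FALSE))
  invisible(path)
}
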