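#' Synthetic micrograph with dark carbon-like blobs
#'
#' Renders circular dark inclusions on a lighter cell-toned background, the
#' fixture used to validate the quantification pipeline against an exact
#' pixel-count oracle. Each blob is a discrete disk: a pixel belongs to the
#' blob iff its centre lies within `radius` of the blob centre (Euclidean,
#' inclusive). Ground truth records the exact foreground pixel count per blob
#' by direct enumeration, before any noise is added, so noise never changes
#' the truth.
#'
#' @param blobs Data frame with columns `x`, `y` (centre, 1-based pixel
#'   coordinates, top-left origin), `radius` (pixels) and optionally
#'   `intensity` (foreground grey level, default 0.1). An empty or `NULL`
#'   data frame yields a blank background.
#' @param width,height Image size in pixels (columns, rows).
#' @param background Background grey level in `[0, 1]`.
#' @param noise_sd SD of additive Gaussian pixel noise (0 = noiseless).
#'   Noisy images are clipped back to `[0, 1]`.
#' @param allow_overlap Permit overlapping blobs; overlapping pixels are
#'   attributed to the earlier blob in `blobs` for the ground-truth count.
#' @param seed Optional seed for the noise field only.
#' @return List with `image` (height x width numeric matrix in `[0, 1]`),
#'   `truth` (data frame `blob`, `n_pixels`) and `mask` (logical matrix of
#'   all foreground pixels).
#' @examples
#' im <- generate_synthetic_image(data.frame(x = 32, y = 32, radius = 10),
#'                                width = 64, height = 64)
#' im$truth$n_pixels
#' @export
generate_synthetic_image <- function(blobs = NULL, width = 128, height = 128,
                                     background = 0.8, noise_sd = 0,
                                     allow_overlap = FALSE, seed = NULL) {
  img <- matrix(background, nrow = height, ncol = width)
  owner <- matrix(0L, nrow = height, ncol = width)
  if (is.null(blobs) || nrow(blobs) == 0L) {
    truth <- data.frame(blob = integer(0), n_pixels = integer(0))
  } else {
    if (is.null(blobs$intensity)) blobs$intensity <- 0.1
    for (b in seq_len(nrow(blobs))) {
      cx <- blobs$x[b]; cy <- blobs$y[b]; r <- blobs$radius[b]
      if (cx - r < 1 || cx + r > width || cy - r < 1 || cy + r > height) {
        stop("blob ", b, " extends outside the image", call. = FALSE)
      }
      xs <- max(1L, floor(cx - r)):min(width, ceiling(cx + r))
      ys <- max(1L, floor(cy - r)):min(height, ceiling(cy + r))
      for (x in xs) for (y in ys) {
        if ((x - cx)^2 + (y - cy)^2 <= r^2) {
          if (owner[y, x] != 0L && !allow_overlap) {
            stop("blobs ", owner[y, x], " and ", b,
                 " overlap; set allow_overlap = TRUE", call. = FALSE)
          }
          if (owner[y, x] == 0L) owner[y, x] <- b
          img[y, x] <- blobs$intensity[b]
        }
      }
    }
    truth <- data.frame(blob = seq_len(nrow(blobs)),
                        n_pixels = vapply(seq_len(nrow(blobs)),
                                          function(b) sum(owner == b),
                                          integer(1)))
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                        nrow = height)
    img <- pmin(pmax(img, 0), 1)
  }
  list(image = img, truth = truth, mask = owner > 0L)
}
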