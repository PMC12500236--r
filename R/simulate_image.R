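#' Configuration for the synthetic fluorescence image generator
#'
#' Describes a three-channel (RGB) fluorescence image of a tissue section:
#' a tissue region built from overlapping disc blobs, DAPI-stained nuclei
#' (blue channel) scattered inside the tissue, and two signal channels
#' (red, green) with distinct mean intensities inside and outside the tissue
#' plus Gaussian noise. The ground-truth tissue mask is returned alongside
#' the image so mask-recovery can be scored.
#'
#' @param width,height Image size in pixels.
#' @param n_nuclei Number of nuclei to place inside the tissue region.
#' @param nucleus_radius Length-2 range (pixels) of nucleus radii.
#' @param blobs Data frame with columns `x`, `y`, `r`: disc centers and radii
#'   (pixels, 1-based image coordinates) whose union is the tissue region.
#' @param in_tissue_mean,out_tissue_mean Named vectors with entries `red` and
#'   `green`: mean channel intensity (0-1 scale) inside / outside the tissue.
#' @param noise_sd Gaussian pixel noise sd added to the signal channels.
#' @param seed Integer seed.
#'
#' @return A list of class `image_sim_config`.
#' @export
image_sim_config <- function(width = 256, height = 256,
                             n_nuclei = 180,
                             nucleus_radius = c(4, 7),
                             blobs = data.frame(
                               x = c(90, 170, 128),
                               y = c(100, 150, 85),
                               r = c(60, 55, 45)),
                             in_tissue_mean = c(red = 0.8, green = 0.5),
                             out_tissue_mean = c(red = 0.1, green = 0.05),
                             noise_sd = 0.02,
                             seed = 1L) {
  if (width < 1 || height < 1) {
    stop("invalid image config: `width`/`height` must be positive",
         call. = FALSE)
  }
  if (any(c(in_tissue_mean, out_tissue_mean) < 0) ||
      any(c(in_tissue_mean, out_tissue_mean) > 1)) {
    stop("invalid image config: channel means must lie in [0, 1]",
         call. = FALSE)
  }
  if (n_nuclei < 0) {
    stop("invalid image config: `n_nuclei` must be non-negative",
         call. = FALSE)
  }
  structure(
    list(width = width, height = height, n_nuclei = n_nuclei,
         nucleus_radius = nucleus_radius, blobs = blobs,
         in_tissue_mean = in_tissue_mean, out_tissue_mean = out_tissue_mean,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "image_sim_config")
}

disc_mask <- function(width, height, cx, cy, r) {
  xs <- matrix(seq_len(height), height, width)          # rows
  ys <- matrix(seq_len(width), height, width, byrow = TRUE)  # cols
  (xs - cy)^2 + (ys - cx)^2 <= r^2
}

#' Generate a synthetic immunofluorescence image with known tissue mask
#'
#' The blue channel holds nuclei (bright discs with soft edges) restricted to
#' the tissue region; the red and green channels take the configured
#' inside/outside means over the ground-truth mask plus Gaussian noise,
#' clipped to the 0-1 range.
#'
#' @param config An [image_sim_config()].
#' @return A list with `image` (height x width x 3 array, channels
#'   red/green/blue in 0-1) and `mask` (logical matrix, the ground-truth
#'   tissue region; empty when `n_nuclei = 0`).
#' @export
simulate_if_image <- function(config) {
  stopifnot(inherits(config, "image_sim_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)
  h <- config$height; w <- config$width
  tissue <- matrix(FALSE, h, w)
  if (config$n_nuclei > 0) {
    for (k in seq_len(nrow(config$blobs))) {
      tissue <- tissue | disc_mask(w, h, config$blobs$x[k], config$blobs$y[k],
                                   config$blobs$r[k])
    }
  }
  blue <- matrix(0, h, w)
  if (config$n_nuclei > 0 && any(tissue)) {
    inside <- which(tissue, arr.ind = TRUE)
    pick <- inside[sample(nrow(inside), config$n_nuclei, replace = TRUE), ,
                   drop = FALSE]
    radii <- stats::runif(config$n_nuclei, config$nucleus_radius[1],
                          config$nucleus_radius[2])
    for (k in seq_len(config$n_nuclei)) {
      cy <- pick[k, 1]; cx <- pick[k, 2]; r <- radii[k]
      rows <- max(1, floor(cy - r - 2)):min(h, ceiling(cy + r + 2))
      cols <- max(1, floor(cx - r - 2)):min(w, ceiling(cx + r + 2))
      dd <- outer(rows - cy, cols - cx, function(a, b) sqrt(a^2 + b^2))
      bump <- pmax(pmin((r - dd) / 1.5 + 1, 1), 0)  # soft-edged disc
      blue[rows, cols] <- pmax(blue[rows, cols],
                               bump * stats::runif(1, 0.7, 1))
    }
    blue[!tissue] <- 0  # nuclei are restricted to the tissue region
  }
  mk_channel <- function(name) {
    base <- ifelse(tissue, config$in_tissue_mean[[name]],
                   config$out_tissue_mean[[name]])
    pmin(pmax(base + stats::rnorm(h * w, 0, config$noise_sd), 0), 1)
  }
  img <- array(0, dim = c(h, w, 3))
  img[, , 1] <- mk_channel("red")
  img[, , 2] <- mk_channel("green")
  img[, , 3] <- blue
  list(image = img, mask = tissue)
}
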