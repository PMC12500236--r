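#' Split a fluorescence image into unit-scaled RGB channels
#'
#' @param image Either a height x width x 3 numeric array (channel order
#'   red, green, blue) or a list with elements `red`, `green`, `blue` of
#'   identical dimensions. Integer-valued inputs are rescaled by the maximum
#'   of their storage type (255 for 8-bit, 65535 for 16-bit).
#' @param bit_depth Optional explicit bit depth (8 or 16) forcing the
#'   integer rescaling; by default inferred: values all within [0, 1] are
#'   taken as already scaled, values <= 255 as 8-bit, else 16-bit.
#' @return A list with matrices `red`, `green`, `blue`, each in [0, 1].
#' @export
split_channels <- function(image, bit_depth = NULL) {
  if (is.list(image) && !is.null(image$red)) {
    chans <- image[c("red", "green", "blue")]
    dims <- lapply(chans, dim)
    if (!all(vapply(dims, identical, logical(1), dims[[1]]))) {
      stop("channel shape mismatch", call. = FALSE)
    }
  } else {
    if (length(dim(image)) != 3 || dim(image)[3] < 3) {
      stop("`image` must be an RGB array or a list of red/green/blue channels",
           call. = FALSE)
    }
    chans <- list(red = image[, , 1], green = image[, , 2],
                  blue = image[, , 3])
  }
  mx <- max(vapply(chans, max, numeric(1)))
  scale <- if (!is.null(bit_depth)) {
    2^bit_depth - 1
  } else if (mx <= 1) 1 else if (mx <= 255) 255 else 65535
  lapply(chans, function(ch) {
    ch <- ch / scale
    pmin(pmax(ch, 0), 1)  # matrix first: pmin/pmax keep dims of arg 1
  })
}

#' Build a DAPI map (binary tissue mask) from the nuclear channel
#'
#' Re-implements the tissue-approximation procedure used for
#' immunofluorescence quantification: the blue (DAPI) channel is
#' contrast-stretched to balance its saturation, binarized at a fixed
#' intensity threshold to suppress background noise, size-filtered to remove
#' non-nuclei debris, and the remaining nuclei blobs are dilated then eroded
#' (morphological closing) with a disk structuring element so that adjacent
#' nuclei merge into a contiguous approximation of the underlying tissue.
#'
#' @param blue_channel Numeric matrix in [0, 1] (the DAPI channel).
#' @param threshold Binarization threshold on the stretched channel, in
#'   [0, 1]. Default 0.15.
#' @param min_size Minimum connected-component size (pixels) kept after
#'   binarization. Default 50.
#' @param disk_radius Radius (pixels) of the disk structuring element used
#'   for the closing. Default 25.
#' @param stretch_percentiles Length-2 percentile pair used for the contrast
#'   stretch. Default `c(0.01, 0.99)`.
#' @return A list of class `tissue_map`: `mask` (logical matrix), `area`
#'   (pixel count), and the parameters used.
#' @export
build_dapi_map <- function(blue_channel, threshold = 0.15, min_size = 50,
                           disk_radius = 25,
                           stretch_percentiles = c(0.01, 0.99)) {
  if (threshold < 0 || threshold > 1) {
    stop("`threshold` must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(is.matrix(blue_channel))
  lo <- stats::quantile(blue_channel, stretch_percentiles[1], names = FALSE)
  hi <- stats::quantile(blue_channel, stretch_percentiles[2], names = FALSE)
  stretched <- if (hi > lo) {
    pmin(pmax((blue_channel - lo) / (hi - lo), 0), 1)
  } else {
    blue_channel
  }
  bin <- stretched > threshold
  # size filtration on 8-connected components
  if (any(bin) && min_size > 1) {
    lab <- EBImage::bwlabel(EBImage::Image(bin * 1))
    sizes <- tabulate(as.integer(EBImage::imageData(lab)))
    keep <- which(sizes >= min_size)
    bin <- matrix(as.integer(EBImage::imageData(lab)) %in% keep,
                  nrow(blue_channel), ncol(blue_channel))
  }
  closed <- bin
  if (any(bin) && disk_radius > 0) {
    brush <- EBImage::makeBrush(2 * disk_radius + 1, shape = "disc")
    img <- EBImage::Image(bin * 1)
    img <- EBImage::erode(EBImage::dilate(img, brush), brush)
    closed <- EBImage::imageData(img) > 0.5
  }
  structure(
    list(mask = closed, area = sum(closed), threshold = threshold,
         min_size = min_size, disk_radius = disk_radius,
         stretch_percentiles = stretch_percentiles,
         premorphology = bin),
    class = "tissue_map")
}

#' @export
print.tissue_map <- function(x, ...) {
  cat(sprintf(
    "<tissue_map> %d x %d, area %d px (%.1f%%); threshold %.2f, min_size %d, disk %d\n",
    nrow(x$mask), ncol(x$mask), x$area,
    100 * x$area / length(x$mask), x$threshold, x$min_size, x$disk_radius))
  invisible(x)
}

#' Mean channel intensity inside and outside a tissue map
#'
#' @param channel Numeric matrix in [0, 1].
#' @param tissue_map A `tissue_map` (from [build_dapi_map()]) or a logical
#'   matrix of the same dimensions as `channel`.
#' @return A list of class `region_intensity` with `inside_mean`,
#'   `outside_mean` (NA-flagged when the region is empty), and pixel counts
#'   `inside_n`, `outside_n`.
#' @export
region_mean_intensity <- function(channel, tissue_map) {
  mask <- if (inherits(tissue_map, "tissue_map")) tissue_map$mask else
    tissue_map
  if (!identical(dim(channel), dim(mask))) {
    stop("channel and mask dimensions differ", call. = FALSE)
  }
  n_in <- sum(mask)
  n_out <- length(mask) - n_in
  structure(
    list(
      inside_mean = if (n_in > 0) mean(channel[mask]) else NA_real_,
      outside_mean = if (n_out > 0) mean(channel[!mask]) else NA_real_,
      inside_n = n_in, outside_n = n_out),
    class = "region_intensity")
}

#' Normalize a signal channel's tissue intensity
#'
#' Two normalization modes used in immunofluorescence quantification:
#' `"area"` divides the summed in-tissue signal by the tissue area (which
#' equals the in-tissue mean intensity), and `"reference"` divides the
#' in-tissue mean of the signal channel by the in-tissue mean of a reference
#' channel (e.g. a membrane marker).
#'
#' @param region A `region_intensity` for the signal channel.
#' @param reference For `mode = "reference"`, a `region_intensity` of the
#'   reference channel; ignored for `mode = "area"`.
#' @param mode `"area"` or `"reference"`.
#' @return A single numeric value; `NA` (flagged undefined) when the tissue
#'   area or reference intensity is zero.
#' @export
normalized_signal <- function(region, reference = NULL,
                              mode = c("area", "reference")) {
  mode <- match.arg(mode)
  if (mode == "area") {
    if (region$inside_n == 0) return(NA_real_)
    return(region$inside_mean)
  }
  if (is.null(reference) || !inherits(reference, "region_intensity")) {
    stop("`reference` must be a region_intensity in reference mode",
         call. = FALSE)
  }
  if (region$inside_n == 0 || is.na(reference$inside_mean) ||
      reference$inside_mean == 0) {
    return(NA_real_)
  }
  region$inside_mean / reference$inside_mean
}

#' Paired in/out tissue intensity report for a batch of images
#'
#' For each image, each requested channel's mean intensity is computed inside
#' the DAPI-defined tissue area and in the cell-free remainder, producing the
#' long-format table consumed by paired t-tests of in-versus-out contrast.
#'
#' @param images List of images accepted by [split_channels()].
#' @param masks List of `tissue_map`s or logical matrices, parallel to
#'   `images`.
#' @param channels Character vector of channels to report (subset of
#'   `c("red", "green")`).
#' @return Tibble with columns `image`, `channel`, `region` (`"in"`/`"out"`),
#'   `mean` and `n_pixels`; empty regions yield `NA` means.
#' @export
paired_region_report <- function(images, masks, channels = c("red", "green")) {
  stopifnot(length(images) == length(masks))
  ids <- names(images)
  if (is.null(ids)) ids <- sprintf("image%02d", seq_along(images))
  rows <- list()
  for (i in seq_along(images)) {
    chans <- split_channels(images[[i]])
    for (ch in channels) {
      reg <- region_mean_intensity(chans[[ch]], masks[[i]])
      rows[[length(rows) + 1]] <- tibble::tibble(
        image = ids[i], channel = ch,
        region = c("in", "out"),
        mean = c(reg$inside_mean, reg$outside_mean),
        n_pixels = c(reg$inside_n, reg$outside_n))
    }
  }
  dplyr::bind_rows(rows)
}

#' Dice overlap between two binary masks
#'
#' @param a,b Logical matrices of identical dimensions.
#' @return Dice coefficient in [0, 1]; 1 when both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
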