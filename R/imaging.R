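#' Two-channel synapse image container
#'
#' Named 2D intensity channels on a common pixel grid with a physical
#' pixel size, e.g. TIRF images of ligand and costimulatory channels at a
#' cell--bilayer or vesicle--bilayer interface.
#'
#' @param channels named list of numeric matrices (same dimensions,
#'   finite, nonnegative).
#' @param pixel_size pixel edge length in micrometer.
#' @param mask optional logical matrix, same dimensions.
#' @return object of class `synapse_image`.
#' @export
synapse_image <- function(channels, pixel_size, mask = NULL) {
  if (!length(channels) || is.null(names(channels)))
    stopf("channels must be a named list of matrices")
  dm <- dim(channels[[1]])
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.matrix(ch) || !identical(dim(ch), dm))
      stopf("channel '%s' has mismatched dimensions", nm)
    if (!all(is.finite(ch)) || any(ch < 0))
      stopf("channel '%s' has non-finite or negative intensities", nm)
  }
  if (!is.null(mask) && !identical(dim(mask), dm))
    stopf("mask dimensions differ from channels")
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stopf("pixel_size must be positive (micrometer)")
  structure(list(channels = channels, pixel_size = pixel_size, mask = mask),
            class = "synapse_image")
}

#' @export
print.synapse_image <- function(x, ...) {
  dm <- dim(x$channels[[1]])
  cat(sprintf("synapse image: %d x %d px (%.3g um/px), channels: %s\n",
              dm[1], dm[2], x$pixel_size,
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Read a multi-page TIFF as a synapse image
#'
#' One page per channel, in the order of `channel_names`.
#'
#' @param path TIFF path.
#' @param channel_names names for the pages.
#' @param pixel_size pixel size in micrometer.
#' @return a [synapse_image()].
#' @export
read_synapse_tiff <- function(path, channel_names, pixel_size) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(channel_names))
    stopf("'%s': %d page(s) but %d channel name(s)", path, length(pages),
          length(channel_names))
  chans <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    p
  })
  names(chans) <- channel_names
  synapse_image(chans, pixel_size)
}

#' Write a synapse image as a multi-page float TIFF
#'
#' Intensities are rescaled to \[0, 1\] by the global maximum across
#' channels (TIFF float convention); the scale factor is returned.
#'
#' @param image a [synapse_image()].
#' @param path output path.
#' @return the rescale factor, invisibly.
#' @export
write_synapse_tiff <- function(image, path) {
  mx <- max(1e-12, max(vapply(image$channels, max, numeric(1))))
  tiff::writeTIFF(lapply(image$channels, function(ch) ch / mx), path,
                  bits.per.sample = 32L, reduce = FALSE)
  invisible(mx)
}

#' Segment cell footprints in one channel
#'
#' Thresholds the chosen channel (Otsu or a fixed value), labels connected
#' components, and keeps components of at least `min_area_um2`. Each kept
#' component is returned as its own logical mask — one prospective cell
#' contact per component, matching per-contact quantification.
#'
#' @param image a [synapse_image()].
#' @param channel channel name to segment on.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold intensity threshold, required for `method = "fixed"`.
#' @param min_area_um2 minimum component area in square micrometer.
#' @return list of logical masks (possibly empty, with a warning), with
#'   attribute `areas_um2`.
#' @export
footprint_mask <- function(image, channel, method = c("otsu", "fixed"),
                           threshold = NULL, min_area_um2 = 1) {
  method <- match.arg(method)
  if (!channel %in% names(image$channels))
    stopf("no channel named '%s'", channel)
  ch <- image$channels[[channel]]
  thr <- if (method == "otsu") {
    mx <- max(ch)
    if (mx <= 0) Inf else EBImage::otsu(EBImage::Image(ch / mx),
                                        range = c(0, 1)) * mx
  } else {
    if (is.null(threshold)) stopf("method 'fixed' needs a threshold")
    threshold
  }
  bw <- ch > thr
  if (!any(bw)) {
    warning("no pixels above threshold; no cells found", call. = FALSE)
    return(structure(list(), areas_um2 = numeric(0)))
  }
  lab <- EBImage::bwlabel(EBImage::Image(bw * 1))
  lab <- round(EBImage::imageData(lab))
  px_area <- image$pixel_size^2
  counts <- table(lab[lab > 0])
  keep <- as.integer(names(counts))[counts * px_area >= min_area_um2]
  if (!length(keep)) {
    warning("all components below min_area_um2; no cells kept",
            call. = FALSE)
    return(structure(list(), areas_um2 = numeric(0)))
  }
  masks <- lapply(keep, function(k) lab == k)
  structure(masks,
            areas_um2 = vapply(masks, sum, numeric(1)) * px_area)
}

#' Pearson colocalization of two channels within a mask
#'
#' Sample Pearson correlation of the two channels over the mask pixels —
#' the per-contact colocalization statistic. Invariant under positive
#' affine rescaling of either channel. A channel that is constant within
#' the mask has no defined correlation and is reported as an error
#' (never silently as 0).
#'
#' @param image a [synapse_image()].
#' @param channel_a,channel_b channel names.
#' @param mask logical matrix with >= 10 `TRUE` pixels.
#' @return Pearson r in \[-1, 1\].
#' @export
pearson_colocalization <- function(image, channel_a, channel_b, mask) {
  for (nm in c(channel_a, channel_b))
    if (!nm %in% names(image$channels)) stopf("no channel named '%s'", nm)
  if (sum(mask) < 10) stopf("mask has fewer than 10 pixels")
  a <- image$channels[[channel_a]][mask]
  b <- image$channels[[channel_b]][mask]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stopf("channel constant within mask; correlation undefined")
  stats::cor(a, b)
}

#' Background region outside all cell footprints
#'
#' Complement of the union of all cell masks after dilating each by
#' `dilate_um` (default 2 um), excluding a halo of spilled signal around
#' every contact.
#'
#' @param image a [synapse_image()].
#' @param masks list of logical cell masks.
#' @param dilate_um dilation radius in micrometer.
#' @return logical matrix of background pixels.
#' @export
background_region <- function(image, masks, dilate_um = 2) {
  dm <- dim(image$channels[[1]])
  un <- Reduce(`|`, masks, matrix(FALSE, dm[1], dm[2]))
  r <- max(1L, round(dilate_um / image$pixel_size))
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(un * 1),
                                            brush)) > 0
  bg <- !dil
  if (!any(bg)) stopf("no background pixels remain after dilation")
  bg
}

#' Background-subtracted, reference-normalized signal level
#'
#' `(mean(channel[mask]) - mean(channel[background])) / reference_scale`.
#' The reference scale is the per-batch median of the same
#' background-subtracted quantity over a declared reference condition
#' (see [raw_level()]); dividing by it cancels any global gain applied to
#' the whole batch.
#'
#' @param image a [synapse_image()].
#' @param channel channel name.
#' @param mask logical cell mask.
#' @param background logical background region, disjoint from `mask`.
#' @param reference_scale positive normalizer.
#' @return unitless normalized level.
#' @export
normalized_level <- function(image, channel, mask, background,
                             reference_scale) {
  if (!is.numeric(reference_scale) || reference_scale <= 0)
    stopf("reference_scale must be positive")
  raw_level(image, channel, mask, background) / reference_scale
}

#' Background-subtracted mean signal in a mask
#'
#' @inheritParams normalized_level
#' @return mean mask intensity minus mean background intensity.
#' @export
raw_level <- function(image, channel, mask, background) {
  if (!channel %in% names(image$channels))
    stopf("no channel named '%s'", channel)
  if (any(mask & background))
    stopf("background region overlaps the cell mask")
  ch <- image$channels[[channel]]
  mean(ch[mask]) - mean(ch[background])
}

#' Per-cell quantification of a two-channel image
#'
#' Segments cell footprints on `mask_channel`, then reports one row per
#' cell: Pearson colocalization of the two channels, background-subtracted
#' raw levels for both, and the footprint area.
#'
#' @param image a [synapse_image()].
#' @param channel_a,channel_b channel names to correlate.
#' @param mask_channel channel used for segmentation (default
#'   `channel_a`).
#' @param min_area_um2 minimum footprint area.
#' @param dilate_um background exclusion radius around cells.
#' @return `data.frame` with columns `cell`, `pearson_r`,
#'   `level_<channel_a>`, `level_<channel_b>`, `area_um2`.
#' @export
quantify_synapses <- function(image, channel_a, channel_b,
                              mask_channel = channel_a, min_area_um2 = 1,
                              dilate_um = 2) {
  masks <- footprint_mask(image, mask_channel, min_area_um2 = min_area_um2)
  if (!length(masks))
    return(data.frame(cell = integer(0), pearson_r = numeric(0),
                      area_um2 = numeric(0)))
  bg <- background_region(image, masks, dilate_um = dilate_um)
  rows <- lapply(seq_along(masks), function(i) {
    r <- tryCatch(pearson_colocalization(image, channel_a, channel_b,
                                         masks[[i]]),
                  error = function(e) NA_real_)
    out <- data.frame(cell = i, pearson_r = r,
                      area_um2 = attr(masks, "areas_um2")[i])
    out[[paste0("level_", channel_a)]] <-
      raw_level(image, channel_a, masks[[i]], bg)
    out[[paste0("level_", channel_b)]] <-
      raw_level(image, channel_b, masks[[i]], bg)
    out
  })
  do.call(rbind, rows)
}
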