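#' Slide raster I/O
#'
#' Slides and tiles are represented throughout the package as numeric arrays
#' `H x W x 3` with values in `[0, 1]`, origin at the top-left, row-major.
#' `read_slide_image` reads a PNG raster into this form; grayscale inputs
#' are replicated across channels. Pyramidal scanner formats are out of
#' scope: callers hand the package a raster at their chosen working
#' magnification (the study design works at 20x).
#'
#' @param path PNG file path.
#' @return numeric array `H x W x 3` in `[0, 1]`.
#' @export
read_slide_image <- function(path) {
  if (!file.exists(path)) stop("unreadable image: ", path, call. = FALSE)
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' @rdname read_slide_image
#' @param img array `H x W x 3` in `[0, 1]`.
#' @export
write_slide_image <- function(img, path) {
  png::writePNG(img, path)
  invisible(path)
}

rgb_to_gray <- function(img) (img[, , 1] + img[, , 2] + img[, , 3]) / 3

#' Foreground (tissue) detection at low resolution
#'
#' Downscales the slide by block averaging and thresholds mean brightness:
#' stained tissue is darker than the white scanner background. This mirrors
#' the usual practice of computing the foreground map on an 8x downscale of
#' the working-resolution slide.
#'
#' @param slide_image array `H x W x 3` in `[0, 1]`.
#' @param downscale_factor integer >= 1; mask dimensions are
#'   `ceiling(dim / factor)`.
#' @param gray_threshold brightness below which a downscaled pixel counts as
#'   tissue (default 0.85; white background is ~1).
#' @return logical matrix, `TRUE` = tissue candidate.
#' @export
detect_foreground <- function(slide_image, downscale_factor = 8L,
                              gray_threshold = 0.85) {
  stopifnot(downscale_factor >= 1)
  gray <- rgb_to_gray(slide_image)
  small <- block_reduce(gray, as.integer(downscale_factor))
  small < gray_threshold
}

# block-mean downscale; partial edge blocks are averaged over the pixels
# they actually contain, so output dims are ceiling(dim / f)
block_reduce <- function(m, f) {
  if (f == 1L) return(m)
  h <- nrow(m); w <- ncol(m)
  ri <- (seq_len(h) - 1L) %/% f
  ci <- (seq_len(w) - 1L) %/% f
  sums <- rowsum(m, ri, reorder = TRUE)            # collapse rows
  sums <- t(rowsum(t(sums), ci, reorder = TRUE))   # collapse cols
  cnt <- outer(tabulate(ri + 1L), tabulate(ci + 1L))
  sums / cnt
}

#' Extract fixed-size tiles over detected foreground
#'
#' Lays a regular grid of `tile_size` squares over the slide (top-left
#' anchored, half-open extents) and emits a record for every grid cell that
#' intersects the foreground mask. Partial edge cells smaller than
#' `tile_size` are dropped, not padded. `tissue_fraction` is the foreground
#' fraction of the cell footprint measured on the mask.
#'
#' @param slide_image array `H x W x 3`.
#' @param foreground_mask logical matrix from [detect_foreground()].
#' @param tile_size tile side in pixels at slide resolution (default 1520).
#' @param slide_id identifier stamped on the records.
#' @param keep_pixels if `TRUE`, each record carries its pixel array.
#' @return data.frame of tile records (`tile_id`, `slide_id`, `origin_row`,
#'   `origin_col`, `size`, `tissue_fraction`), with pixel arrays in
#'   `attr(, "pixels")` when requested.
#' @export
extract_tiles <- function(slide_image, foreground_mask, tile_size = 1520L,
                          slide_id = "slide", keep_pixels = TRUE) {
  stopifnot(tile_size > 0)
  tile_size <- as.integer(tile_size)
  h <- dim(slide_image)[1]; w <- dim(slide_image)[2]
  fh <- nrow(foreground_mask); fw <- ncol(foreground_mask)
  fr <- h / fh; fc <- w / fw   # mask-to-slide scale
  rows0 <- seq(0L, h - tile_size, by = tile_size)
  cols0 <- seq(0L, w - tile_size, by = tile_size)
  if (h < tile_size) rows0 <- integer(0)
  if (w < tile_size) cols0 <- integer(0)
  recs <- list(); pix <- list(); k <- 0L
  for (r0 in rows0) for (c0 in cols0) {
    mr <- unique(pmin(fh, floor(c(r0, r0 + tile_size - 1L) / fr) + 1L))
    mc <- unique(pmin(fw, floor(c(c0, c0 + tile_size - 1L) / fc) + 1L))
    sub <- foreground_mask[seq(mr[1], mr[length(mr)]),
                           seq(mc[1], mc[length(mc)]), drop = FALSE]
    tf <- mean(sub)
    if (tf <= 0) next
    k <- k + 1L
    id <- sprintf("%s_r%06d_c%06d", slide_id, r0, c0)
    recs[[k]] <- data.frame(tile_id = id, slide_id = slide_id,
                            origin_row = r0, origin_col = c0,
                            size = tile_size, tissue_fraction = tf,
                            stringsAsFactors = FALSE)
    if (keep_pixels)
      pix[[id]] <- slide_image[(r0 + 1L):(r0 + tile_size),
                               (c0 + 1L):(c0 + tile_size), , drop = FALSE]
  }
  out <- if (k) do.call(rbind, recs)
         else data.frame(tile_id = character(), slide_id = character(),
                         origin_row = integer(), origin_col = integer(),
                         size = integer(), tissue_fraction = numeric(),
                         stringsAsFactors = FALSE)
  if (keep_pixels) attr(out, "pixels") <- pix
  out
}

#' Tile quality-control metrics
#'
#' brightness = mean grayscale; saturation and hue = means of the HSV
#' channels; `laplacian_variance` = variance of the 4-neighbour Laplacian of
#' the grayscale image (a standard sharpness proxy — blurred tiles score
#' low).
#'
#' @param tile array `H x W x 3` in `[0, 1]`.
#' @return named list with `brightness`, `saturation`, `hue`,
#'   `laplacian_variance`.
#' @export
qc_metrics <- function(tile) {
  gray <- rgb_to_gray(tile)
  hsv <- grDevices::rgb2hsv(r = as.vector(tile[, , 1]),
                            g = as.vector(tile[, , 2]),
                            b = as.vector(tile[, , 3]), maxColorValue = 1)
  h <- nrow(gray); w <- ncol(gray)
  lap_var <- if (h >= 3L && w >= 3L) {
    ctr <- gray[2:(h - 1L), 2:(w - 1L)]
    lap <- gray[1:(h - 2L), 2:(w - 1L)] + gray[3:h, 2:(w - 1L)] +
           gray[2:(h - 1L), 1:(w - 2L)] + gray[2:(h - 1L), 3:w] - 4 * ctr
    stats::var(as.vector(lap))
  } else 0
  list(brightness = mean(gray), saturation = mean(hsv["s", ]),
       hue = mean(hsv["h", ]), laplacian_variance = lap_var)
}

#' Default tile QC thresholds
#'
#' The minimum tissue fraction (5%) follows the published preprocessing
#' rule; the remaining cut-offs are unpublished and these defaults are
#' package choices, exposed in config and logged per slide. Bounds are
#' `NULL` to disable a check.
#'
#' @param min_tissue minimum tissue fraction (tiles with less are removed).
#' @param min_brightness,max_brightness grayscale mean bounds.
#' @param min_saturation minimum mean HSV saturation.
#' @param hue_range length-2 allowed mean-hue interval, or `NULL`.
#' @param min_laplacian_variance minimum sharpness.
#' @return named list of thresholds for [qc_filter()].
#' @export
default_qc_thresholds <- function(min_tissue = 0.05, min_brightness = 0.10,
                                  max_brightness = 0.97, min_saturation = 0.02,
                                  hue_range = NULL,
                                  min_laplacian_variance = 1e-5) {
  list(min_tissue = min_tissue, min_brightness = min_brightness,
       max_brightness = max_brightness, min_saturation = min_saturation,
       hue_range = hue_range,
       min_laplacian_variance = min_laplacian_variance)
}

#' Tile quality filter
#'
#' Applies the QC checks in a fixed order — tissue, brightness, saturation,
#' hue, Laplacian sharpness — and rejects on the first failure, so each
#' rejected tile carries exactly one primary reason. A tile with less than
#' `min_tissue` tissue (default 5%) is rejected; exactly 5% is kept
#' (the removal rule is "less than").
#'
#' @param tile array `H x W x 3`, or `NULL` if `metrics` supplied.
#' @param tissue_fraction foreground fraction of the tile footprint.
#' @param thresholds from [default_qc_thresholds()].
#' @param metrics optional precomputed [qc_metrics()].
#' @return list with `status` (`"kept"` or `"rejected"`), `reason` (`NA` or
#'   one of `"tissue"`, `"brightness"`, `"saturation"`, `"hue"`,
#'   `"laplacian"`), and the metrics.
#' @export
qc_filter <- function(tile, tissue_fraction,
                      thresholds = default_qc_thresholds(), metrics = NULL) {
  if (is.null(metrics)) metrics <- qc_metrics(tile)
  th <- thresholds
  fail <- function(reason) list(status = "rejected", reason = reason,
                                metrics = metrics,
                                tissue_fraction = tissue_fraction)
  if (!is.null(th$min_tissue) && tissue_fraction < th$min_tissue)
    return(fail("tissue"))
  if ((!is.null(th$min_brightness) && metrics$brightness < th$min_brightness) ||
      (!is.null(th$max_brightness) && metrics$brightness > th$max_brightness))
    return(fail("brightness"))
  if (!is.null(th$min_saturation) && metrics$saturation < th$min_saturation)
    return(fail("saturation"))
  if (!is.null(th$hue_range) &&
      (metrics$hue < th$hue_range[1] || metrics$hue > th$hue_range[2]))
    return(fail("hue"))
  if (!is.null(th$min_laplacian_variance) &&
      metrics$laplacian_variance < th$min_laplacian_variance)
    return(fail("laplacian"))
  list(status = "kept", reason = NA_character_, metrics = metrics,
       tissue_fraction = tissue_fraction)
}

#' Tile a slide with quality control
#'
#' Convenience wrapper: foreground detection, grid tiling and per-tile QC in
#' one call. Returns the tile manifest with QC columns (`status`, `reason`,
#' and the four QC metrics).
#'
#' @inheritParams detect_foreground
#' @inheritParams extract_tiles
#' @param thresholds from [default_qc_thresholds()].
#' @return tile manifest data.frame; kept tiles' pixels in
#'   `attr(, "pixels")` when `keep_pixels`.
#' @export
tile_slide <- function(slide_image, tile_size = 1520L, downscale_factor = 8L,
                       gray_threshold = 0.85,
                       thresholds = default_qc_thresholds(),
                       slide_id = "slide", keep_pixels = TRUE) {
  mask <- detect_foreground(slide_image, downscale_factor, gray_threshold)
  tiles <- extract_tiles(slide_image, mask, tile_size, slide_id, keep_pixels)
  pix <- attr(tiles, "pixels")
  n <- nrow(tiles)
  status <- character(n); reason <- character(n)
  bright <- sat <- hue <- lapv <- numeric(n)
  for (i in seq_len(n)) {
    tp <- if (keep_pixels) pix[[tiles$tile_id[i]]] else {
      r0 <- tiles$origin_row[i]; c0 <- tiles$origin_col[i]
      slide_image[(r0 + 1L):(r0 + tile_size),
                  (c0 + 1L):(c0 + tile_size), , drop = FALSE]
    }
    res <- qc_filter(tp, tiles$tissue_fraction[i], thresholds)
    status[i] <- res$status; reason[i] <- res$reason
    bright[i] <- res$metrics$brightness; sat[i] <- res$metrics$saturation
    hue[i] <- res$metrics$hue; lapv[i] <- res$metrics$laplacian_variance
  }
  tiles$status <- status; tiles$reason <- reason
  tiles$brightness <- bright; tiles$saturation <- sat
  tiles$hue <- hue; tiles$laplacian_variance <- lapv
  if (keep_pixels) attr(tiles, "pixels") <- pix[tiles$tile_id[status == "kept"]]
  tiles
}
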