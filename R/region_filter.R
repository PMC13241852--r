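#' Tissue-driven tile retention rule
#'
#' Decides whether a tile is informative for weakly supervised grading from
#' its tissue type map: the tile is kept when (a) at least `tau_ref` of its
#' pixels (all pixels, background included in the denominator) belong to
#' the baseline reference classes stroma or normal epithelium, summed over
#' the two, and (b) at least one pixel of any disease-indicating class —
#' abnormal epithelium, inflammatory tissue, or debris — is present. The
#' default threshold is 10%.
#'
#' @param tissue_type integer tissue map.
#' @param vocabulary a [label_vocabulary()]; must name the five classes the
#'   rule uses.
#' @param tau_ref minimum reference-tissue fraction (default 0.10; the
#'   boundary value exactly 0.10 is kept: the rule is "at least").
#' @param tile_id identifier for the decision record.
#' @return list (`filter_decision`): `tile_id`, `kept`,
#'   `reference_fraction`, `ibd_presence` (named logical for the three
#'   disease classes), `reason`.
#' @export
tile_filter <- function(tissue_type, vocabulary = default_vocabulary(),
                        tau_ref = 0.10, tile_id = "tile") {
  ref_codes <- c(vocab_code(vocabulary, "tissue_classes", "stroma"),
                 vocab_code(vocabulary, "tissue_classes", "normal_epithelium"))
  ibd_names <- c("abnormal_epithelium", "inflammatory", "debris")
  ibd_codes <- vapply(ibd_names, function(nm)
    vocab_code(vocabulary, "tissue_classes", nm), 1L)
  n <- length(tissue_type)
  ref_frac <- sum(tissue_type %in% ref_codes) / n
  presence <- vapply(ibd_codes, function(cd) any(tissue_type == cd), TRUE)
  names(presence) <- ibd_names
  kept <- ref_frac >= tau_ref && any(presence)
  reason <- if (kept) "kept"
            else if (ref_frac < tau_ref && !any(presence))
              "insufficient reference tissue; no disease-indicating class"
            else if (ref_frac < tau_ref) "insufficient reference tissue"
            else "no disease-indicating class present"
  structure(list(tile_id = tile_id, kept = kept,
                 reference_fraction = ref_frac, ibd_presence = presence,
                 reason = reason), class = "filter_decision")
}

#' Subdivide a tile into encoder-ready patches
#'
#' Splits a square tile into non-overlapping `patch_size` patches on a
#' row-major grid; a 1250-pixel tile at the default patch size yields 25
#' patches. When `center_crop` is given (e.g. 1250 for tiles extracted at
#' 1520), the tile is first center-cropped deterministically so the grid
#' arithmetic stays exact. Non-divisible geometry is an error — never
#' silently padded.
#'
#' Patch ids are a deterministic function of slide id, tile origin, and
#' grid position, which is what keys the embedding store.
#'
#' @param tile array `H x W x 3` (or `H x W` matrix, e.g. a tissue map).
#' @param patch_size patch side in pixels (default 250).
#' @param slide_id,tile_origin identity of the parent tile (origin in slide
#'   pixels, 0-based).
#' @param center_crop optional side length to center-crop to before
#'   subdividing.
#' @param keep_pixels attach per-patch pixel data.
#' @return data.frame of patch records: `patch_id`, `tile_id`, `grid_i`,
#'   `grid_j` (0-based), `origin_row`, `origin_col` (slide pixels), `size`;
#'   pixel arrays in `attr(, "pixels")` when requested.
#' @export
subdivide_tile <- function(tile, patch_size = 250L, slide_id = "slide",
                           tile_origin = c(0L, 0L), center_crop = NULL,
                           keep_pixels = TRUE) {
  d <- dim(tile)
  h <- d[1]; w <- d[2]
  tile_origin <- as.integer(tile_origin)
  if (!is.null(center_crop)) {
    center_crop <- as.integer(center_crop)
    if (center_crop > h || center_crop > w)
      stop("center_crop ", center_crop, " exceeds tile dimensions ",
           h, "x", w, call. = FALSE)
    r0 <- (h - center_crop) %/% 2L
    c0 <- (w - center_crop) %/% 2L
    tile <- if (length(d) == 3L)
      tile[(r0 + 1L):(r0 + center_crop), (c0 + 1L):(c0 + center_crop), ,
           drop = FALSE]
    else tile[(r0 + 1L):(r0 + center_crop), (c0 + 1L):(c0 + center_crop),
              drop = FALSE]
    tile_origin <- tile_origin + c(r0, c0)
    h <- w <- center_crop
  }
  patch_size <- as.integer(patch_size)
  if (h %% patch_size != 0L || w %% patch_size != 0L)
    stop("tile ", h, "x", w, " not divisible by patch size ", patch_size,
         call. = FALSE)
  ni <- h %/% patch_size; nj <- w %/% patch_size
  grid <- expand.grid(j = seq_len(nj) - 1L, i = seq_len(ni) - 1L)
  grid <- grid[order(grid$i, grid$j), ]
  origin_row <- tile_origin[1] + grid$i * patch_size
  origin_col <- tile_origin[2] + grid$j * patch_size
  tid <- sprintf("%s_r%06d_c%06d", slide_id, tile_origin[1], tile_origin[2])
  out <- data.frame(
    patch_id = sprintf("%s_p%02d_%02d", tid, grid$i, grid$j),
    tile_id = tid, grid_i = grid$i, grid_j = grid$j,
    origin_row = origin_row, origin_col = origin_col,
    size = patch_size, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (keep_pixels) {
    pix <- vector("list", nrow(out))
    names(pix) <- out$patch_id
    for (k in seq_len(nrow(out))) {
      rr <- grid$i[k] * patch_size; cc <- grid$j[k] * patch_size
      pix[[k]] <- if (length(dim(tile)) == 3L)
        tile[(rr + 1L):(rr + patch_size), (cc + 1L):(cc + patch_size), ,
             drop = FALSE]
      else tile[(rr + 1L):(rr + patch_size), (cc + 1L):(cc + patch_size),
                drop = FALSE]
    }
    attr(out, "pixels") <- pix
  }
  out
}

#' Background-based patch exclusion
#'
#' A patch is excluded when its background fraction reaches `tau_bg`
#' (default 60%; the boundary value excludes, since the exclusion rule is
#' ">= 60% background"). Background evidence comes from the tissue map
#' (code 0) when available, else from a brightness threshold on the patch
#' pixels.
#'
#' @param patch_tissue integer tissue map of the patch, or `NULL`.
#' @param patch_pixels RGB array of the patch, or `NULL`.
#' @param tau_bg exclusion threshold (default 0.60).
#' @param brightness_threshold grayscale value above which a pixel counts
#'   as background in the intensity fallback.
#' @return list with `kept` and `background_fraction`.
#' @export
patch_background_filter <- function(patch_tissue = NULL, patch_pixels = NULL,
                                    tau_bg = 0.60,
                                    brightness_threshold = 0.85) {
  bg_frac <- if (!is.null(patch_tissue)) {
    mean(patch_tissue == 0L)
  } else if (!is.null(patch_pixels)) {
    mean(rgb_to_gray(patch_pixels) >= brightness_threshold)
  } else {
    stop("no background evidence: supply a tissue map or patch pixels",
         call. = FALSE)
  }
  list(kept = bg_frac < tau_bg, background_fraction = bg_frac)
}

#' Run the region-filtering stage over a slide's tiles
#'
#' Applies the tile retention rule, subdivides retained tiles into patches
#' (with an optional deterministic center-crop reconciling the tiling size
#' with the subdivision size), and applies the patch-level background
#' exclusion. In unfiltered mode (`filter = FALSE`, the ablation baseline)
#' every tile is subdivided and only the background rule applies.
#'
#' @param tiles tile manifest data.frame (needs `tile_id`, `slide_id`,
#'   `origin_row`, `origin_col`); pixel arrays in `attr(tiles, "pixels")`
#'   are propagated to patches when present.
#' @param bundles named list of [annotation_bundle()]s keyed by `tile_id`;
#'   required when `filter = TRUE` (filtering needs segmentation).
#' @param config list: `tau_ref`, `tau_bg`, `patch_size`, `center_crop`,
#'   `filter`, `vocabulary`.
#' @return list with `patches` (manifest of all patch records with `kept`
#'   and `background_fraction`), `decisions` (per-tile filter decisions),
#'   and `summary` (kept/total patch counts and the reduction fraction
#'   relative to the unfiltered non-background patch set).
#' @export
run_filter_stage <- function(tiles, bundles = NULL, config = list()) {
  cfg <- utils::modifyList(list(tau_ref = 0.10, tau_bg = 0.60,
                                patch_size = 250L, center_crop = NULL,
                                filter = TRUE,
                                vocabulary = default_vocabulary()), config)
  pix <- attr(tiles, "pixels")
  if (cfg$filter) {
    missing_b <- setdiff(tiles$tile_id, names(bundles))
    if (length(missing_b))
      stop("filtering requires a segmentation bundle per tile; missing: ",
           paste(missing_b, collapse = ", "), call. = FALSE)
  }
  decisions <- list()
  patch_rows <- list()
  patch_pix <- list()
  for (i in seq_len(nrow(tiles))) {
    tid <- tiles$tile_id[i]
    bundle <- bundles[[tid]]
    if (cfg$filter) {
      dec <- tile_filter(bundle$tissue_type, cfg$vocabulary, cfg$tau_ref, tid)
    } else {
      dec <- structure(list(tile_id = tid, kept = TRUE,
                            reference_fraction = NA_real_,
                            ibd_presence = NULL, reason = "unfiltered mode"),
                       class = "filter_decision")
    }
    decisions[[tid]] <- dec
    if (!dec$kept) next
    origin <- c(tiles$origin_row[i], tiles$origin_col[i])
    tmap <- if (!is.null(bundle)) bundle$tissue_type else NULL
    src <- if (!is.null(tmap)) tmap else pix[[tid]]
    if (is.null(src))
      stop("tile ", tid, " has neither bundle nor pixels", call. = FALSE)
    pr <- subdivide_tile(src, cfg$patch_size, tiles$slide_id[i], origin,
                         center_crop = cfg$center_crop, keep_pixels = TRUE)
    ppix <- attr(pr, "pixels")
    pr$tile_id <- tid   # keep the manifest's tile identity
    kept <- logical(nrow(pr)); bgf <- numeric(nrow(pr))
    for (k in seq_len(nrow(pr))) {
      res <- if (!is.null(tmap))
        patch_background_filter(patch_tissue = ppix[[k]], tau_bg = cfg$tau_bg)
      else
        patch_background_filter(patch_pixels = ppix[[k]], tau_bg = cfg$tau_bg)
      kept[k] <- res$kept; bgf[k] <- res$background_fraction
    }
    pr$kept <- kept
    pr$background_fraction <- bgf
    patch_rows[[tid]] <- pr
    if (!is.null(pix[[tid]])) {
      img_patches <- subdivide_tile(pix[[tid]], cfg$patch_size,
                                    tiles$slide_id[i], origin,
                                    center_crop = cfg$center_crop)
      patch_pix <- c(patch_pix, attr(img_patches, "pixels")[pr$kept])
    }
  }
  patches <- if (length(patch_rows)) do.call(rbind, patch_rows) else
    data.frame(patch_id = character(), tile_id = character(),
               grid_i = integer(), grid_j = integer(),
               origin_row = integer(), origin_col = integer(),
               size = integer(), kept = logical(),
               background_fraction = numeric(), stringsAsFactors = FALSE)
  rownames(patches) <- NULL
  n_grid <- if (is.null(cfg$center_crop)) NA_integer_ else
    as.integer((cfg$center_crop %/% cfg$patch_size)^2)
  total_possible <- nrow(tiles) *
    (if (!is.na(n_grid)) n_grid else
       if (nrow(patches)) max(table(patches$tile_id)) else 0L)
  summary <- list(n_tiles = nrow(tiles),
                  n_tiles_kept = sum(vapply(decisions, `[[`, TRUE, "kept")),
                  n_patches = nrow(patches),
                  n_patches_kept = sum(patches$kept),
                  total_grid_patches = total_possible,
                  reduction = if (total_possible > 0)
                    1 - sum(patches$kept) / total_possible else NA_real_)
  out <- list(patches = patches, decisions = decisions, summary = summary)
  if (length(patch_pix)) attr(out, "pixels") <- patch_pix
  out
}
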