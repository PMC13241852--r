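#' Multi-level segmentation annotation bundle
#'
#' An annotation bundle holds the co-registered integer label maps produced
#' by a tissue/nucleus segmenter for one tile: nucleus instance, type and
#' boundary maps; gland instance and type maps (the type map separates
#' glandular from surface epithelium); a lumen instance map; and a tissue
#' type map. All maps share the tile's pixel dimensions. Maps may be
#' individually absent (`NULL`) — a lumen level has an instance map only and
#' the tissue level a type map only — and absence is recorded explicitly
#' rather than zero-filled.
#'
#' Conventions: matrices are row-major views of the tile with origin at the
#' top-left, 0-based slide coordinates, and half-open tile extents. In
#' instance maps every positive id labels one connected component; 0 means
#' "no instance". `nucleus_type` must be nonzero only where
#' `nucleus_instance` is nonzero.
#'
#' @param tile_id,slide_id identifier strings.
#' @param origin integer `(row, col)` offset of the tile in the slide,
#'   0-based.
#' @param nucleus_instance,nucleus_type,nucleus_boundary,gland_instance,gland_type,lumen_instance,tissue_type
#'   integer matrices of identical dimensions, or `NULL` for an absent map.
#' @param vocabulary a [label_vocabulary()].
#' @return an object of class `annotation_bundle`.
#' @export
annotation_bundle <- function(tile_id, slide_id, origin = c(0L, 0L),
                              nucleus_instance = NULL, nucleus_type = NULL,
                              nucleus_boundary = NULL, gland_instance = NULL,
                              gland_type = NULL, lumen_instance = NULL,
                              tissue_type = NULL,
                              vocabulary = default_vocabulary()) {
  maps <- list(nucleus_instance = nucleus_instance, nucleus_type = nucleus_type,
               nucleus_boundary = nucleus_boundary,
               gland_instance = gland_instance, gland_type = gland_type,
               lumen_instance = lumen_instance, tissue_type = tissue_type)
  maps <- lapply(maps, function(m) {
    if (is.null(m)) return(NULL)
    storage.mode(m) <- "integer"
    m
  })
  structure(c(list(tile_id = as.character(tile_id),
                   slide_id = as.character(slide_id),
                   origin = as.integer(origin)),
              maps, list(vocabulary = vocabulary)),
            class = "annotation_bundle")
}

BUNDLE_MAP_NAMES <- c("nucleus_instance", "nucleus_type", "nucleus_boundary",
                      "gland_instance", "gland_type", "lumen_instance",
                      "tissue_type")

bundle_maps <- function(bundle) {
  m <- bundle[BUNDLE_MAP_NAMES]
  m[!vapply(m, is.null, logical(1))]
}

#' @export
print.annotation_bundle <- function(x, ...) {
  present <- names(bundle_maps(x))
  dims <- if (length(present)) paste(dim(x[[present[1]]]), collapse = "x")
          else "empty"
  cat("<annotation_bundle> tile ", x$tile_id, " (slide ", x$slide_id,
      ", origin ", x$origin[1], ",", x$origin[2], ")\n",
      "  maps [", dims, "]: ", paste(present, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Validate an annotation bundle
#'
#' Checks the structural invariants of the bundle and returns the violations
#' found instead of raising: all present maps share one height x width; every
#' code on a typed map exists in the vocabulary for that family; instance ids
#' are non-negative; `nucleus_type` is nonzero only where `nucleus_instance`
#' is nonzero.
#'
#' @param bundle an [annotation_bundle()].
#' @return character vector of violation messages, each naming the offending
#'   map and rule; empty when the bundle is consistent.
#' @export
validate_bundle <- function(bundle) {
  if (!inherits(bundle, "annotation_bundle"))
    return("not an annotation_bundle")
  v <- character()
  maps <- bundle_maps(bundle)
  if (!length(maps)) return(v)
  dims <- lapply(maps, dim)
  ref <- dims[[1]]
  for (nm in names(maps)) {
    if (!is.matrix(maps[[nm]]))
      v <- c(v, paste0(nm, ": not a matrix"))
    else if (!identical(dim(maps[[nm]]), ref) && nm != names(maps)[1])
      v <- c(v, paste0(nm, ": dimensions ", paste(dim(maps[[nm]]), collapse = "x"),
                       " differ from ", paste(ref, collapse = "x")))
  }
  for (nm in names(maps)) {
    if (is.matrix(maps[[nm]]) && any(maps[[nm]] < 0L, na.rm = TRUE))
      v <- c(v, paste0(nm, ": negative codes present"))
    if (anyNA(maps[[nm]]))
      v <- c(v, paste0(nm, ": missing values present"))
  }
  vocab <- bundle$vocabulary
  typed <- c(nucleus_type = "nucleus_types", gland_type = "gland_types",
             tissue_type = "tissue_classes")
  for (nm in names(typed)) {
    m <- maps[[nm]]
    if (is.null(m)) next
    bad <- setdiff(unique(as.vector(m)), unname(vocab[[typed[[nm]]]]))
    bad <- bad[bad >= 0L]
    if (length(bad))
      v <- c(v, paste0(nm, ": codes not in vocabulary: ",
                       paste(sort(bad), collapse = ", ")))
  }
  ni <- maps$nucleus_instance; nt <- maps$nucleus_type
  if (!is.null(ni) && !is.null(nt) && identical(dim(ni), dim(nt))) {
    if (any(nt != 0L & ni == 0L))
      v <- c(v, "nucleus_type: nonzero outside nucleus_instance support")
  }
  v
}

H5_MAP_PREFIX <- "maps/"

#' Write / read an annotation bundle as an HDF5 container
#'
#' One HDF5 file per tile: each present map is stored as an integer dataset
#' under `maps/<name>`, the vocabulary under `vocabulary/<family>` (codes)
#' with category names as a companion dataset, and tile identity and origin
#' under `meta/`. The round trip `read_bundle(write_bundle(b))` is bit-exact
#' on every field; absent maps stay absent.
#'
#' @param bundle an [annotation_bundle()] passing [validate_bundle()].
#' @param path output `.h5` path (overwritten if it exists).
#' @return `write_bundle` returns `path` invisibly; `read_bundle` returns the
#'   bundle.
#' @export
write_bundle <- function(bundle, path) {
  v <- validate_bundle(bundle)
  if (length(v))
    stop("invalid bundle: ", paste(v, collapse = "; "), call. = FALSE)
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, "maps")
  rhdf5::h5createGroup(path, "meta")
  rhdf5::h5createGroup(path, "vocabulary")
  for (nm in names(bundle_maps(bundle)))
    rhdf5::h5write(bundle[[nm]], path, paste0(H5_MAP_PREFIX, nm))
  rhdf5::h5write(bundle$tile_id, path, "meta/tile_id")
  rhdf5::h5write(bundle$slide_id, path, "meta/slide_id")
  rhdf5::h5write(as.integer(bundle$origin), path, "meta/origin")
  for (fam in names(bundle$vocabulary)) {
    rhdf5::h5write(unname(bundle$vocabulary[[fam]]), path,
                   paste0("vocabulary/", fam))
    rhdf5::h5write(names(bundle$vocabulary[[fam]]), path,
                   paste0("vocabulary/", fam, "_names"))
  }
  invisible(path)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(path) {
  if (!file.exists(path)) stop("no such bundle file: ", path, call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  ls <- rhdf5::h5ls(path)
  have <- ls$name[ls$group == "/maps"]
  meta <- ls$name[ls$group == "/meta"]
  for (req in c("tile_id", "slide_id", "origin"))
    if (!req %in% meta)
      stop("bundle container missing meta/", req, call. = FALSE)
  vfam <- c("tissue_classes", "nucleus_types", "gland_types")
  for (fam in vfam)
    if (!fam %in% ls$name[ls$group == "/vocabulary"])
      stop("bundle container missing vocabulary/", fam, call. = FALSE)
  rd <- function(name) rhdf5::h5read(path, name)
  vocab_args <- lapply(vfam, function(fam)
    stats::setNames(as.integer(rd(paste0("vocabulary/", fam))),
                    as.character(rd(paste0("vocabulary/", fam, "_names")))))
  names(vocab_args) <- vfam
  vocab <- label_vocabulary(tissue_classes = vocab_args$tissue_classes,
                            nucleus_types = vocab_args$nucleus_types,
                            gland_types = vocab_args$gland_types)
  maps <- stats::setNames(vector("list", length(BUNDLE_MAP_NAMES)),
                          BUNDLE_MAP_NAMES)
  for (nm in intersect(BUNDLE_MAP_NAMES, have)) {
    m <- rd(paste0(H5_MAP_PREFIX, nm))
    storage.mode(m) <- "integer"
    maps[[nm]] <- m
  }
  b <- do.call(annotation_bundle,
               c(list(tile_id = as.character(rd("meta/tile_id")),
                      slide_id = as.character(rd("meta/slide_id")),
                      origin = as.integer(rd("meta/origin")),
                      vocabulary = vocab),
                 maps))
  v <- validate_bundle(b)
  if (length(v))
    stop("bundle read from ", path, " is invalid: ",
         paste(v, collapse = "; "), call. = FALSE)
  b
}

#' Run a segmenter adapter on a tile
#'
#' The segmenter is a pluggable contract: any function taking an RGB tile
#' array (H x W x 3, values in `[0, 1]`) and returning an
#' [annotation_bundle()] with matching map dimensions. The package does not
#' ship a trained segmentation network; [make_mock_segmenter()] provides a
#' deterministic stand-in so the full pipeline runs offline.
#'
#' @param tile RGB array `H x W x 3` in `[0, 1]`.
#' @param adapter a segmenter function, or `NULL` when none is configured.
#' @param tile_id,slide_id,origin identity metadata stamped onto the result.
#' @return an [annotation_bundle()] passing validation.
#' @export
run_segmenter <- function(tile, adapter, tile_id = "tile", slide_id = "slide",
                          origin = c(0L, 0L)) {
  if (is.null(adapter))
    stop("external segmenter not configured", call. = FALSE)
  stopifnot(is.array(tile), length(dim(tile)) == 3L, dim(tile)[3] == 3L)
  b <- adapter(tile)
  if (!inherits(b, "annotation_bundle"))
    stop("segmenter adapter did not return an annotation_bundle", call. = FALSE)
  b$tile_id <- as.character(tile_id)
  b$slide_id <- as.character(slide_id)
  b$origin <- as.integer(origin)
  if (length(bundle_maps(b))) {
    d <- dim(bundle_maps(b)[[1]])
    if (!identical(d, dim(tile)[1:2]))
      stop("segmenter output dimensions ", paste(d, collapse = "x"),
           " do not match tile ", paste(dim(tile)[1:2], collapse = "x"),
           call. = FALSE)
  }
  v <- validate_bundle(b)
  if (length(v))
    stop("segmenter adapter produced an invalid bundle: ",
         paste(v, collapse = "; "), call. = FALSE)
  b
}

#' Deterministic mock segmenter
#'
#' Returns an adapter for [run_segmenter()] that derives label maps from the
#' tile pixels alone, deterministically for a given seed: pixels darker than
#' `background_brightness` become tissue, split into stroma vs inflammatory
#' tissue by a seeded spatial hash; sufficiently dark compact spots become
#' nuclei with types assigned by the same hash. A blank (white) tile yields
#' an all-background bundle. The mock exists so pipelines and tests can run
#' with no external model; it is not a histology model.
#'
#' @param seed integer seed fixing the spatial hash.
#' @param background_brightness grayscale threshold above which a pixel is
#'   background.
#' @param vocabulary a [label_vocabulary()].
#' @return a function `(tile) -> annotation_bundle`.
#' @export
make_mock_segmenter <- function(seed = 1L, background_brightness = 0.9,
                                vocabulary = default_vocabulary()) {
  seed <- as.integer(seed)
  force(background_brightness); force(vocabulary)
  function(tile) {
    h <- dim(tile)[1]; w <- dim(tile)[2]
    gray <- (tile[, , 1] + tile[, , 2] + tile[, , 3]) / 3
    tissue <- gray < background_brightness
    rowi <- matrix(seq_len(h), h, w)
    coli <- matrix(seq_len(w), h, w, byrow = TRUE)
    # seeded spatial hash: coarse blocks assigned pseudo-randomly but
    # reproducibly from (seed, block index)
    block <- (rowi - 1L) %/% 16L * 7919L + (coli - 1L) %/% 16L
    hash <- (block * 2654435761 + seed * 40503) %% 97
    tt <- matrix(0L, h, w)
    tt[tissue] <- ifelse(hash[tissue] < 55, vocab_code(vocabulary, "tissue_classes", "stroma"),
                  ifelse(hash[tissue] < 80, vocab_code(vocabulary, "tissue_classes", "normal_epithelium"),
                         vocab_code(vocabulary, "tissue_classes", "inflammatory")))
    dark <- gray < background_brightness * 0.45 & tissue
    ni <- label_components(dark)
    nt <- matrix(0L, h, w)
    if (max(ni) > 0L) {
      types <- c(vocab_code(vocabulary, "nucleus_types", "epithelial"),
                 vocab_code(vocabulary, "nucleus_types", "lymphocyte"),
                 vocab_code(vocabulary, "nucleus_types", "neutrophil"))
      per_inst <- types[((seq_len(max(ni)) * 131L + seed) %% 3L) + 1L]
      nt[ni > 0L] <- per_inst[ni[ni > 0L]]
    }
    nb <- boundary_map(ni)
    annotation_bundle(tile_id = "tile", slide_id = "slide",
                      nucleus_instance = ni, nucleus_type = nt,
                      nucleus_boundary = nb,
                      gland_instance = matrix(0L, h, w),
                      gland_type = matrix(0L, h, w),
                      lumen_instance = matrix(0L, h, w),
                      tissue_type = tt, vocabulary = vocabulary)
  }
}

# 4-connected component labelling of a logical matrix (two-pass union-find)
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  if (!any(mask)) return(lab)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  nxt <- 0L
  for (j in seq_len(w)) for (i in seq_len(h)) {
    if (!mask[i, j]) next
    up <- if (i > 1L) lab[i - 1L, j] else 0L
    lf <- if (j > 1L) lab[i, j - 1L] else 0L
    if (up == 0L && lf == 0L) {
      nxt <- nxt + 1L; parent[nxt] <- nxt; lab[i, j] <- nxt
    } else if (up != 0L && lf != 0L) {
      ru <- find(up); rl <- find(lf)
      if (ru != rl) parent[ru] <- rl
      lab[i, j] <- rl
    } else {
      lab[i, j] <- max(up, lf)
    }
  }
  roots <- vapply(seq_len(nxt), find, 1L)
  remap <- match(roots, unique(roots))
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  lab
}

# boundary map: instance pixels with a 4-neighbour outside their instance
boundary_map <- function(inst) {
  h <- nrow(inst); w <- ncol(inst)
  if (h < 2L || w < 2L) return((inst > 0L) * 1L)
  pad <- matrix(0L, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- inst
  ctr <- pad[2:(h + 1L), 2:(w + 1L)]
  up <- pad[1:h, 2:(w + 1L)]; dn <- pad[3:(h + 2L), 2:(w + 1L)]
  lf <- pad[2:(h + 1L), 1:w]; rt <- pad[2:(h + 1L), 3:(w + 2L)]
  b <- ctr > 0L & (up != ctr | dn != ctr | lf != ctr | rt != ctr)
  m <- matrix(0L, h, w)
  m[b] <- ctr[b]
  m
}
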