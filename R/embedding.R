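#' Mock frozen-encoder adapter
#'
#' The package treats patch encoders as pluggable frozen feature
#' extractors: any function mapping an RGB patch to a fixed-length numeric
#' vector. Published histology foundation models emit embeddings of 1024
#' or 2560 dimensions; the dimension is configuration, not code.
#'
#' `make_mock_encoder` builds a deterministic stand-in: the patch is
#' block-averaged to an `8 x 8 x 3` summary and passed through a fixed
#' seeded random linear map. It is deterministic in (patch pixels, seed)
#' and sensitive to single-pixel changes, which is all the pipeline
#' plumbing needs; it carries no histology knowledge.
#'
#' @param dim embedding dimension (e.g. 1024 or 2560).
#' @param seed integer seed fixing the projection matrix.
#' @return function `(patch) -> numeric(dim)` with attribute
#'   `embedding_dim`.
#' @export
make_mock_encoder <- function(dim = 1024L, seed = 1L) {
  dim <- as.integer(dim)
  p <- 8L * 8L * 3L
  W <- with_seed(derive_seed(seed, "mock-encoder"),
                 matrix(stats::rnorm(dim * p) / sqrt(p), dim, p))
  f <- function(patch) {
    stopifnot(is.array(patch), length(dim(patch)) == 3L)
    g <- vapply(1:3, function(ch) as.vector(block_reduce_to(patch[, , ch], 8L)),
                numeric(64L))
    as.numeric(W %*% as.vector(g))
  }
  attr(f, "embedding_dim") <- dim
  f
}

# block-average a matrix onto a fixed g x g grid
block_reduce_to <- function(m, g) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(((seq_len(h) - 1L) * g) %/% h, g - 1L)
  ci <- pmin(((seq_len(w) - 1L) * g) %/% w, g - 1L)
  sums <- rowsum(m, ri, reorder = TRUE)
  sums <- t(rowsum(t(sums), ci, reorder = TRUE))
  cnt <- outer(tabulate(ri + 1L, g), tabulate(ci + 1L, g))
  sums / cnt
}

#' Encode a set of patches
#'
#' @param patches named list of RGB patch arrays (names = patch ids, the
#'   deterministic ids from [subdivide_tile()]).
#' @param encoder an encoder adapter, e.g. [make_mock_encoder()].
#' @return matrix `n_patches x dim`, rownames = patch ids.
#' @export
encode_patches <- function(patches, encoder) {
  stopifnot(length(patches) > 0, !is.null(names(patches)))
  vecs <- lapply(patches, encoder)
  d <- unique(lengths(vecs))
  if (length(d) != 1L)
    stop("encoder returned inconsistent dimensions", call. = FALSE)
  out <- do.call(rbind, vecs)
  rownames(out) <- names(patches)
  out
}

#' Per-slide embedding store
#'
#' Embeddings are stored one HDF5 container per slide under `dir`, indexed
#' by patient id and patch base name so the patch-patient correspondence is
#' preserved and patient-level splits induce disjoint embedding sets. Bags
#' load back in the exact row order they were stored in (the deterministic
#' patch-manifest order).
#'
#' @param dir directory for the containers (created if missing).
#' @return an `embedding_store` handle.
#' @export
embedding_store <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  structure(list(dir = dir), class = "embedding_store")
}

slide_h5_path <- function(store, slide_id)
  file.path(store$dir, paste0(slide_id, ".h5"))

#' Store a slide's patch embeddings
#'
#' @param store an [embedding_store()].
#' @param slide_id,patient_id identity of the bag.
#' @param embeddings matrix `n x dim`, rownames = unique patch ids.
#' @param origins integer matrix `n x 2` of patch origins (slide pixels,
#'   0-based), for attention mapping.
#' @param label slide NHI grade 0-4 (or `NA` for unlabeled slides).
#' @return the store, invisibly.
#' @export
store_embeddings <- function(store, slide_id, patient_id, embeddings,
                             origins, label = NA_integer_) {
  stopifnot(inherits(store, "embedding_store"), is.matrix(embeddings))
  ids <- rownames(embeddings)
  if (is.null(ids) || anyDuplicated(ids))
    stop("embeddings must carry unique patch ids as rownames", call. = FALSE)
  if (!all(is.finite(embeddings)))
    stop("embeddings contain non-finite values", call. = FALSE)
  path <- slide_h5_path(store, slide_id)
  if (file.exists(path))
    stop("slide ", slide_id, " already stored (duplicate key)", call. = FALSE)
  existing <- list.files(store$dir, pattern = "\\.h5$", full.names = TRUE)
  if (length(existing)) {
    d0 <- NULL
    on.exit(rhdf5::h5closeAll(), add = TRUE)
    d0 <- tryCatch(length(rhdf5::h5read(existing[1], "meta/dim")) * 0 +
                     as.integer(rhdf5::h5read(existing[1], "meta/dim")),
                   error = function(e) NULL)
    if (!is.null(d0) && d0 != ncol(embeddings))
      stop("dimension mismatch: store holds ", d0, "-D embeddings, got ",
           ncol(embeddings), "-D", call. = FALSE)
  }
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5createGroup(path, "meta")
  rhdf5::h5write(embeddings, path, "embeddings")
  rhdf5::h5write(ids, path, "patch_ids")
  rhdf5::h5write(as.integer(origins), path, "origins")
  rhdf5::h5write(as.character(patient_id), path, "meta/patient_id")
  rhdf5::h5write(as.character(slide_id), path, "meta/slide_id")
  rhdf5::h5write(as.integer(label), path, "meta/label")
  rhdf5::h5write(as.integer(ncol(embeddings)), path, "meta/dim")
  invisible(store)
}

#' Load one slide's bag of embeddings
#'
#' @param store an [embedding_store()].
#' @param slide_id slide to load.
#' @return an `embedding_bag`: list with `slide_id`, `patient_id`, `label`,
#'   `embeddings` (n x dim, rownames = patch ids), `origins` (n x 2).
#' @export
load_bag <- function(store, slide_id) {
  path <- slide_h5_path(store, slide_id)
  if (!file.exists(path))
    stop("unknown slide: ", slide_id, call. = FALSE)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  emb <- rhdf5::h5read(path, "embeddings")
  ids <- as.character(rhdf5::h5read(path, "patch_ids"))
  rownames(emb) <- ids
  origins <- matrix(as.integer(rhdf5::h5read(path, "origins")), ncol = 2L)
  new_bag(slide_id = as.character(rhdf5::h5read(path, "meta/slide_id")),
          patient_id = as.character(rhdf5::h5read(path, "meta/patient_id")),
          label = as.integer(rhdf5::h5read(path, "meta/label")),
          embeddings = emb, origins = origins)
}

#' @rdname load_bag
#' @export
list_slides <- function(store) {
  sub("\\.h5$", "", list.files(store$dir, pattern = "\\.h5$"))
}

new_bag <- function(slide_id, patient_id, label, embeddings, origins = NULL) {
  stopifnot(nrow(embeddings) >= 1)
  structure(list(slide_id = slide_id, patient_id = patient_id,
                 label = label, embeddings = embeddings, origins = origins),
            class = "embedding_bag")
}

#' @export
print.embedding_bag <- function(x, ...) {
  cat("<embedding_bag> slide ", x$slide_id, " (patient ", x$patient_id,
      ", label ", x$label, "): ", nrow(x$embeddings), " x ",
      ncol(x$embeddings), " embeddings\n", sep = "")
  invisible(x)
}
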