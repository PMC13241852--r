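#' Label vocabulary for segmentation maps
#'
#' A vocabulary binds integer label codes to named categories for each map
#' family of an annotation bundle: tissue classes on the `tissue_type` map,
#' nuclear categories on the `nucleus_type` map, and gland categories on the
#' `gland_type` map (glandular vs surface epithelium). Code 0 is reserved for
#' background in every family.
#'
#' @param tissue_classes named integer vector of tissue codes. Must contain
#'   `background = 0` plus the categories the region filter and statistics
#'   depend on: `normal_epithelium`, `abnormal_epithelium`, `inflammatory`,
#'   `debris`, `stroma`, `muscle`, `mucous`, `adipose`.
#' @param nucleus_types named integer vector of nuclear type codes. Must
#'   contain `background = 0`, `epithelial`, `lymphocyte` and `neutrophil`;
#'   extra categories emitted by a segmenter are allowed.
#' @param gland_types named integer vector of gland category codes; must
#'   contain `background = 0`, `gland` and `surface_epithelium`.
#' @return an object of class `label_vocabulary`.
#' @seealso [default_vocabulary()]
#' @export
label_vocabulary <- function(tissue_classes, nucleus_types,
                             gland_types = c(background = 0L, gland = 1L,
                                             surface_epithelium = 2L)) {
  families <- list(tissue_classes = tissue_classes,
                   nucleus_types  = nucleus_types,
                   gland_types    = gland_types)
  required <- list(
    tissue_classes = c("background", "normal_epithelium", "abnormal_epithelium",
                       "inflammatory", "debris", "stroma", "muscle", "mucous",
                       "adipose"),
    nucleus_types  = c("background", "epithelial", "lymphocyte", "neutrophil"),
    gland_types    = c("background", "gland", "surface_epithelium"))
  for (fam in names(families)) {
    x <- families[[fam]]
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop(fam, " must be a fully named integer vector", call. = FALSE)
    if (anyDuplicated(names(x)))
      stop(fam, ": duplicated category names", call. = FALSE)
    x <- stats::setNames(as.integer(x), names(x))
    if (anyNA(x) || any(x < 0L))
      stop(fam, ": codes must be non-negative integers", call. = FALSE)
    if (anyDuplicated(x))
      stop(fam, ": codes must be unique", call. = FALSE)
    miss <- setdiff(required[[fam]], names(x))
    if (length(miss))
      stop(fam, ": missing required categories: ",
           paste(miss, collapse = ", "), call. = FALSE)
    bg <- x[names(x) == "background"]
    if (bg != 0L)
      stop(fam, ": background must carry code 0", call. = FALSE)
    families[[fam]] <- stats::setNames(x, names(families[[fam]]))
  }
  structure(families, class = "label_vocabulary")
}

#' Default label vocabulary
#'
#' Tissue classes follow the categories a colorectal multitask segmenter
#' emits and that the downstream filtering rule names (normal and abnormal
#' epithelium, inflammatory tissue, debris, stroma, muscle, mucous, adipose).
#' The nuclear inventory covers the epithelial/immune/stromal types relevant
#' to grading intestinal inflammation. Both are overridable because published
#' segmenters differ in their full class lists.
#'
#' @return a [label_vocabulary()].
#' @export
default_vocabulary <- function() {
  label_vocabulary(
    tissue_classes = c(background = 0L, normal_epithelium = 1L,
                       abnormal_epithelium = 2L, inflammatory = 3L,
                       debris = 4L, stroma = 5L, muscle = 6L,
                       mucous = 7L, adipose = 8L),
    nucleus_types = c(background = 0L, epithelial = 1L, lymphocyte = 2L,
                      neutrophil = 3L, plasma = 4L, eosinophil = 5L,
                      connective = 6L))
}

#' @export
print.label_vocabulary <- function(x, ...) {
  cat("<label_vocabulary>\n")
  for (fam in names(x))
    cat(" ", fam, ": ",
        paste0(names(x[[fam]]), "=", x[[fam]], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read or write a vocabulary as YAML/JSON config
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @param vocab a [label_vocabulary()].
#' @return `read_vocabulary` returns a [label_vocabulary()];
#'   `write_vocabulary` returns `path` invisibly.
#' @export
write_vocabulary <- function(vocab, path) {
  stopifnot(inherits(vocab, "label_vocabulary"))
  lst <- lapply(unclass(vocab), as.list)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(lst, path)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path)
  as_named_int <- function(x) stats::setNames(vapply(x, as.integer, 1L), names(x))
  label_vocabulary(tissue_classes = as_named_int(lst$tissue_classes),
                   nucleus_types  = as_named_int(lst$nucleus_types),
                   gland_types    = as_named_int(lst$gland_types))
}

# code lookup with a clear error when the config lacks a class the caller needs
vocab_code <- function(vocab, family, name) {
  x <- vocab[[family]]
  if (!name %in% names(x))
    stop("vocabulary has no ", family, " category named '", name, "'",
         call. = FALSE)
  unname(x[[name]])
}
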