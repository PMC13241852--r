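#' Confusion matrix
#'
#' @param truth,predicted integer class indices (0-based).
#' @param K number of classes.
#' @return integer `K x K` matrix, rows = truth, columns = prediction.
#' @export
confusion_matrix <- function(truth, predicted, K) {
  tab <- table(factor(truth, levels = 0:(K - 1)),
               factor(predicted, levels = 0:(K - 1)))
  m <- matrix(as.integer(tab), K, K,
              dimnames = list(truth = 0:(K - 1), predicted = 0:(K - 1)))
  m
}

per_class_f1 <- function(truth, predicted, K) {
  vapply(0:(K - 1), function(k) {
    tp <- sum(truth == k & predicted == k)
    fp <- sum(truth != k & predicted == k)
    fn <- sum(truth == k & predicted != k)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
}

macro_f1 <- function(truth, predicted, K) mean(per_class_f1(truth, predicted, K))

weighted_f1 <- function(truth, predicted, K) {
  f1 <- per_class_f1(truth, predicted, K)
  support <- vapply(0:(K - 1), function(k) sum(truth == k), numeric(1))
  if (sum(support) == 0) return(0)
  sum(f1 * support) / sum(support)
}

# one-vs-rest AUC by the rank statistic with midrank ties
ovr_auc <- function(truth_bin, score) {
  n1 <- sum(truth_bin); n0 <- sum(!truth_bin)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[truth_bin]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Multiclass evaluation report
#'
#' Accuracy, per-class F1 (0/0 defined as 0), macro F1 (unweighted mean),
#' weighted F1 (weighted by truth support), per-class one-vs-rest AUC
#' (midrank convention for ties), and the confusion matrix. A class absent
#' from the truth has an undefined AUC: it is reported as `NA`, excluded
#' from the macro AUC, and flagged with a warning.
#'
#' @param truth integer class indices (0-based).
#' @param predicted integer class indices (0-based).
#' @param probabilities matrix `n x K`, rows summing to 1 (within 1e-6);
#'   may be `NULL` to skip AUC.
#' @param K number of classes.
#' @param grouping optional [grouping_scheme()] tagged on the report.
#' @param condition optional ablation condition tag.
#' @return an `eval_report`: list with `accuracy`, `macro_f1`,
#'   `weighted_f1`, `per_class_f1`, `per_class_auc`, `confusion`,
#'   `n_per_class`, `n`, `grouping`, `condition`.
#' @export
compute_metrics <- function(truth, predicted, probabilities = NULL, K,
                            grouping = NULL, condition = NULL) {
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  stopifnot(length(truth) == length(predicted))
  if (!is.null(probabilities)) {
    stopifnot(nrow(probabilities) == length(truth), ncol(probabilities) == K)
    if (any(abs(rowSums(probabilities) - 1) > 1e-6))
      stop("probability rows must sum to 1", call. = FALSE)
  }
  cm <- confusion_matrix(truth, predicted, K)
  auc <- rep(NA_real_, K)
  if (!is.null(probabilities)) {
    for (k in 0:(K - 1))
      auc[k + 1] <- ovr_auc(truth == k, probabilities[, k + 1])
    if (anyNA(auc))
      warning("AUC undefined for class(es) absent from truth: ",
              paste(which(is.na(auc)) - 1, collapse = ", "), call. = FALSE)
  }
  structure(list(
    accuracy = sum(diag(cm)) / length(truth),
    macro_f1 = macro_f1(truth, predicted, K),
    weighted_f1 = weighted_f1(truth, predicted, K),
    per_class_f1 = per_class_f1(truth, predicted, K),
    per_class_auc = auc,
    macro_auc = if (all(is.na(auc))) NA_real_ else mean(auc, na.rm = TRUE),
    confusion = cm,
    n_per_class = rowSums(cm),
    n = length(truth),
    grouping = if (!is.null(grouping)) as_grouping_scheme(grouping)$name,
    condition = condition), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>", if (!is.null(x$condition))
    paste0("condition ", x$condition), "n =", x$n, "\n")
  cat(sprintf("  accuracy %.3f | macro F1 %.3f | weighted F1 %.3f\n",
              x$accuracy, x$macro_f1, x$weighted_f1))
  cat("  per-class F1: ", paste(sprintf("%.3f", x$per_class_f1),
                                collapse = " "), "\n")
  if (!all(is.na(x$per_class_auc)))
    cat("  per-class AUC:", paste(sprintf("%.3f", x$per_class_auc),
                                  collapse = " "), "\n")
  invisible(x)
}

#' Collapse an evaluation to a coarser grouping after the fact
#'
#' Regroups 5-class truth/predictions through a scheme and recomputes the
#' metrics; the confusion-matrix grand total is conserved.
#'
#' @param truth,predicted 0-4 grades.
#' @param probabilities optional `n x 5` probabilities; columns are summed
#'   within grouped classes.
#' @param scheme target [grouping_scheme()].
#' @return an `eval_report` at the grouped granularity.
#' @export
regroup_metrics <- function(truth, predicted, probabilities = NULL, scheme) {
  scheme <- as_grouping_scheme(scheme)
  gt <- group_labels(truth, scheme)
  gp <- group_labels(predicted, scheme)
  probs <- NULL
  if (!is.null(probabilities)) {
    probs <- matrix(0, nrow(probabilities), scheme$n_classes)
    for (g in 0:4) probs[, scheme$map[g + 1] + 1] <-
      probs[, scheme$map[g + 1] + 1] + probabilities[, g + 1]
  }
  compute_metrics(gt, gp, probs, scheme$n_classes, grouping = scheme)
}

#' Render a slide-level attention map
#'
#' Paints each kept patch's footprint with its attention weight on a
#' downscaled raster of the slide; cells outside any patch are `NA`. The
#' top-k highest-attention patches are exported with their coordinates for
#' review.
#'
#' @param origins integer matrix `n x 2` of patch origins (slide pixels,
#'   0-based row, col).
#' @param weights attention weights, length n.
#' @param patch_size patch side in slide pixels.
#' @param slide_dims integer `(height, width)` of the slide.
#' @param downscale integer raster downscale factor (default `patch_size`,
#'   i.e. one raster cell per patch footprint).
#' @param top_k how many high-attention patches to list.
#' @return an `attention_map`: list with `raster` (numeric matrix, `NA`
#'   outside patches), `top_patches` (data.frame of the k highest-weight
#'   patches), `downscale`.
#' @export
render_attention <- function(origins, weights, patch_size, slide_dims,
                             downscale = NULL, top_k = 5L) {
  stopifnot(nrow(origins) == length(weights))
  if (is.null(downscale)) downscale <- patch_size
  bad <- origins[, 1] < 0 | origins[, 2] < 0 |
    origins[, 1] + patch_size > slide_dims[1] |
    origins[, 2] + patch_size > slide_dims[2]
  if (any(bad))
    stop("patch origins out of slide bounds at rows: ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  rh <- ceiling(slide_dims[1] / downscale)
  rw <- ceiling(slide_dims[2] / downscale)
  raster <- matrix(NA_real_, rh, rw)
  for (i in seq_len(nrow(origins))) {
    r0 <- floor(origins[i, 1] / downscale) + 1L
    c0 <- floor(origins[i, 2] / downscale) + 1L
    r1 <- min(rh, ceiling((origins[i, 1] + patch_size) / downscale))
    c1 <- min(rw, ceiling((origins[i, 2] + patch_size) / downscale))
    raster[r0:r1, c0:c1] <- weights[i]
  }
  ord <- order(weights, decreasing = TRUE)[seq_len(min(top_k, length(weights)))]
  structure(list(
    raster = raster,
    top_patches = data.frame(rank = seq_along(ord),
                             origin_row = origins[ord, 1],
                             origin_col = origins[ord, 2],
                             weight = weights[ord]),
    downscale = downscale), class = "attention_map")
}
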