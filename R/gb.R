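#' Gradient-boosted baseline on slide statistics
#'
#' A non-MIL baseline: multinomial gradient boosting over the slide-level
#' feature table, evaluated with stratified 5-fold cross-validation and a
#' small grid search. No gradient-boosting package ships with the
#' environment, so the booster here is a self-contained implementation of
#' multinomial boosting with depth-limited exhaustive-split regression
#' trees and Friedman leaf updates.
#'
#' Folds are stratified by class at the patient level (all slides of one
#' patient share a fold). For each grid point the full CV is run and the
#' point with the best pooled macro F1 is retained; its per-fold and pooled
#' metrics are reported and a final model is refit on all data.
#'
#' @param stats_table data.frame from [slide_stats_table()] (column
#'   `slide_id` plus numeric features).
#' @param labels integer NHI grades 0-4, one per row of `stats_table`.
#' @param grouping a [grouping_scheme()] or name.
#' @param patient_id patient identifier per row (defaults to one patient
#'   per slide).
#' @param cv_config list: `folds` (default 5), `grid` (data.frame over
#'   `n_trees`, `depth`, `learning_rate`), `seed`.
#' @return list with `best_params`, `fold_metrics` (per-fold accuracy and
#'   F1), `pooled` (pooled accuracy, macro/weighted F1, confusion matrix),
#'   `model` (final fit usable with [predict_gbt()]), `grouping`.
#' @export
gb_baseline <- function(stats_table, labels, grouping = "type_A",
                        patient_id = NULL, cv_config = list()) {
  scheme <- as_grouping_scheme(grouping)
  y <- group_labels(labels, scheme)
  X <- as.matrix(stats_table[, setdiff(colnames(stats_table), "slide_id"),
                             drop = FALSE])
  X[is.na(X)] <- 0   # flagged-undefined ratios enter as 0
  if (is.null(patient_id)) patient_id <- stats_table$slide_id
  if (length(unique(y)) < 2L)
    stop("need >= 2 classes present to fit the baseline", call. = FALSE)
  folds <- cv_config$folds %||% 5L
  seed <- cv_config$seed %||% 1L
  grid <- cv_config$grid %||% expand.grid(n_trees = c(50L, 100L),
                                          depth = c(1L, 2L),
                                          learning_rate = c(0.1, 0.3))
  K <- scheme$n_classes
  fold_of <- patient_stratified_folds(patient_id, y, folds, seed)
  folds <- max(fold_of)
  eval_grid_point <- function(par) {
    pred <- integer(length(y)); prob <- matrix(NA_real_, length(y), K)
    fm <- vector("list", folds)
    for (f in seq_len(folds)) {
      tr <- fold_of != f; te <- !tr
      fit <- fit_gbt(X[tr, , drop = FALSE], y[tr], K,
                     n_trees = par$n_trees, depth = par$depth,
                     learning_rate = par$learning_rate)
      p <- predict_gbt(fit, X[te, , drop = FALSE])
      prob[te, ] <- p
      pred[te] <- max.col(p, ties.method = "first") - 1L
      fm[[f]] <- data.frame(fold = f, accuracy = mean(pred[te] == y[te]),
                            macro_f1 = macro_f1(y[te], pred[te], K),
                            weighted_f1 = weighted_f1(y[te], pred[te], K))
    }
    list(fold_metrics = do.call(rbind, fm),
         pooled = list(accuracy = mean(pred == y),
                       macro_f1 = macro_f1(y, pred, K),
                       weighted_f1 = weighted_f1(y, pred, K),
                       confusion = confusion_matrix(y, pred, K)),
         pred = pred, prob = prob)
  }
  best <- NULL; best_score <- -Inf; best_par <- NULL
  for (g in seq_len(nrow(grid))) {
    par <- as.list(grid[g, ])
    res <- eval_grid_point(par)
    if (res$pooled$macro_f1 > best_score) {
      best <- res; best_score <- res$pooled$macro_f1; best_par <- par
    }
  }
  final <- fit_gbt(X, y, K, n_trees = best_par$n_trees,
                   depth = best_par$depth,
                   learning_rate = best_par$learning_rate)
  list(best_params = best_par, fold_metrics = best$fold_metrics,
       pooled = best$pooled, model = final, grouping = scheme,
       feature_names = colnames(X))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# patient-level stratified fold assignment; patients stratified by their
# max class; shrinks fold count (with a warning) if a class has too few
# patients to appear in every fold
patient_stratified_folds <- function(patient_id, y, folds, seed) {
  pmax_cls <- tapply(y, patient_id, max)
  pats <- names(pmax_cls)
  min_per_class <- min(table(pmax_cls))
  if (min_per_class < folds) {
    folds <- max(2L, min_per_class)
    warning("class with too few patients for requested folds; using ",
            folds, "-fold CV", call. = FALSE)
  }
  fold_pat <- stats::setNames(integer(length(pats)), pats)
  with_seed(seed, {
    for (cls in unique(pmax_cls)) {
      p <- pats[pmax_cls == cls]
      p <- p[sample.int(length(p))]
      fold_pat[p] <- rep_len(seq_len(folds), length(p))
    }
  })
  unname(fold_pat[as.character(patient_id)])
}

# ---- multinomial gradient boosting with regression trees ----

fit_gbt <- function(X, y, K, n_trees = 100L, depth = 2L,
                    learning_rate = 0.1, min_obs = 5L) {
  n <- nrow(X)
  Fm <- matrix(0, n, K)
  trees <- vector("list", n_trees)
  Y <- matrix(0, n, K); Y[cbind(seq_len(n), y + 1L)] <- 1
  for (m in seq_len(n_trees)) {
    P <- softmax_rows(Fm)
    round_trees <- vector("list", K)
    for (k in seq_len(K)) {
      r <- Y[, k] - P[, k]
      tree <- fit_reg_tree(X, r, depth, min_obs)
      leaf <- tree_leaf_of(tree, X)
      # Friedman multinomial leaf value
      gamma <- vapply(seq_along(tree$leaves), function(l) {
        idx <- leaf == l
        num <- sum(r[idx])
        den <- sum(abs(r[idx]) * (1 - abs(r[idx])))
        if (den < 1e-10) 0 else (K - 1) / K * num / den
      }, numeric(1))
      tree$gamma <- gamma
      Fm[, k] <- Fm[, k] + learning_rate * gamma[leaf]
      round_trees[[k]] <- tree
    }
    trees[[m]] <- round_trees
  }
  list(trees = trees, K = K, learning_rate = learning_rate)
}

#' @rdname gb_baseline
#' @param fit a fitted booster from `gb_baseline()$model`.
#' @param X numeric feature matrix.
#' @export
predict_gbt <- function(fit, X) {
  n <- nrow(X); K <- fit$K
  Fm <- matrix(0, n, K)
  for (round_trees in fit$trees)
    for (k in seq_len(K)) {
      tree <- round_trees[[k]]
      Fm[, k] <- Fm[, k] + fit$learning_rate * tree$gamma[tree_leaf_of(tree, X)]
    }
  softmax_rows(Fm)
}

softmax_rows <- function(Fm) {
  e <- exp(Fm - apply(Fm, 1, max))
  e / rowSums(e)
}

# exhaustive greedy SSE-minimizing regression tree (nodes as a flat list)
fit_reg_tree <- function(X, r, depth, min_obs) {
  nodes <- list(); leaves <- integer(0)
  grow <- function(idx, d) {
    node_id <- length(nodes) + 1L
    nodes[node_id] <<- list(NULL)  # reserve slot
    if (d >= depth || length(idx) < 2L * min_obs || stats::var(r[idx]) < 1e-12) {
      leaves <<- c(leaves, node_id)
      nodes[[node_id]] <<- list(leaf = match(node_id, leaves))
      return(node_id)
    }
    best <- NULL; best_sse <- Inf
    for (j in seq_len(ncol(X))) {
      xs <- X[idx, j]
      cand <- unique(stats::quantile(xs, probs = seq(0.1, 0.9, length.out = 15),
                                     names = FALSE, type = 1))
      for (cut in cand) {
        left <- xs <= cut
        nl <- sum(left); nr <- length(idx) - nl
        if (nl < min_obs || nr < min_obs) next
        rl <- r[idx[left]]; rr <- r[idx[!left]]
        sse <- sum((rl - mean(rl))^2) + sum((rr - mean(rr))^2)
        if (sse < best_sse) { best_sse <- sse; best <- list(j = j, cut = cut) }
      }
    }
    if (is.null(best)) {
      leaves <<- c(leaves, node_id)
      nodes[[node_id]] <<- list(leaf = match(node_id, leaves))
      return(node_id)
    }
    left_idx <- idx[X[idx, best$j] <= best$cut]
    right_idx <- setdiff(idx, left_idx)
    l_id <- grow(left_idx, d + 1L)
    r_id <- grow(right_idx, d + 1L)
    nodes[[node_id]] <<- list(j = best$j, cut = best$cut,
                              left = l_id, right = r_id)
    node_id
  }
  root <- grow(seq_len(nrow(X)), 0L)
  list(nodes = nodes, root = root, leaves = leaves)
}

tree_leaf_of <- function(tree, X) {
  n <- nrow(X)
  out <- integer(n)
  for (i in seq_len(n)) {
    id <- tree$root
    repeat {
      nd <- tree$nodes[[id]]
      if (!is.null(nd$leaf)) { out[i] <- nd$leaf; break }
      id <- if (X[i, nd$j] <= nd$cut) nd$left else nd$right
    }
  }
  out
}
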