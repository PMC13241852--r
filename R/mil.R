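#' Grade-grouping schemes
#'
#' The 0-4 histological activity scale is evaluated at three granularities:
#' the identity five-class scheme; the conventional three-class grouping
#' (`type_A`: 0-1 = no active colitis, 2 = mild active colitis, 3-4 =
#' severe active colitis); a remission-separating alternative (`type_B`:
#' 0 = no disease, 1-2 = low-grade inflammation, 3-4 = severe active
#' colitis); and the binary inactive (< 2) vs active (>= 2) split.
#'
#' @param name one of `"five_class"`, `"type_A"`, `"type_B"`, `"binary"`.
#' @return a `grouping_scheme`: list with `name`, `map` (class index for
#'   grades 0-4), `n_classes`, `class_names`.
#' @export
grouping_scheme <- function(name = c("five_class", "type_A", "type_B",
                                     "binary")) {
  name <- match.arg(name)
  spec <- switch(name,
    five_class = list(map = 0:4,
                      class_names = paste0("NHI-", 0:4)),
    type_A = list(map = c(0L, 0L, 1L, 2L, 2L),
                  class_names = c("no_active_colitis", "mild_active_colitis",
                                  "severe_active_colitis")),
    type_B = list(map = c(0L, 1L, 1L, 2L, 2L),
                  class_names = c("no_disease", "low_grade_inflammation",
                                  "severe_active_colitis")),
    binary = list(map = c(0L, 0L, 1L, 1L, 1L),
                  class_names = c("inactive", "active")))
  structure(list(name = name, map = spec$map,
                 n_classes = max(spec$map) + 1L,
                 class_names = spec$class_names),
            class = "grouping_scheme")
}

as_grouping_scheme <- function(x) {
  if (inherits(x, "grouping_scheme")) x else grouping_scheme(x)
}

#' Map NHI grades to grouped class indices
#'
#' @param nhi integer vector of grades in 0-4.
#' @param scheme a [grouping_scheme()] or name.
#' @return integer class indices (0-based).
#' @export
group_labels <- function(nhi, scheme) {
  scheme <- as_grouping_scheme(scheme)
  nhi <- as.integer(nhi)
  if (anyNA(nhi) || any(nhi < 0L | nhi > 4L))
    stop("NHI grades must be integers in 0..4", call. = FALSE)
  scheme$map[nhi + 1L]
}

#' Patient-level label: the worst slide
#'
#' Clinical grading considers the slide with the highest inflammation among
#' a patient's biopsy locations; the patient-level label is therefore the
#' max grade over the patient's slides.
#'
#' @param slide_labels integer grades of one patient's slides (>= 1).
#' @return the maximum grade.
#' @export
patient_max_label <- function(slide_labels) {
  stopifnot(length(slide_labels) >= 1)
  max(as.integer(slide_labels))
}

#' Patient-level stratified train/validation/test split
#'
#' Every patient's slides land in exactly one subset (no patient-level
#' leakage). Patients are stratified by their patient-level max label and
#' allocated to subsets by largest-remainder apportionment within each
#' stratum, deterministically for a given seed. Strata with fewer than 3
#' patients trigger a warning and are assigned in train, validation, test
#' priority order.
#'
#' @param manifest data.frame with `slide_id`, `patient_id`, `nhi`.
#' @param fractions named numeric `(train, val, test)` summing to 1.
#' @param seed integer seed.
#' @return the manifest with an added `subset` column.
#' @export
patient_level_split <- function(manifest,
                                fractions = c(train = 0.7, val = 0.15,
                                              test = 0.15),
                                seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9,
            all(c("train", "val", "test") %in% names(fractions)))
  pmax_lab <- tapply(manifest$nhi, manifest$patient_id, patient_max_label)
  pats <- names(pmax_lab)
  subset_of <- stats::setNames(character(length(pats)), pats)
  with_seed(seed, {
    for (cls in sort(unique(pmax_lab))) {
      p <- pats[pmax_lab == cls]
      p <- p[sample.int(length(p))]
      n <- length(p)
      if (n < 3L) {
        warning("stratum with max label ", cls, " has only ", n,
                " patient(s); assigning in train/val/test priority order",
                call. = FALSE)
        subset_of[p] <- c("train", "val", "test")[seq_len(n)]
        next
      }
      quota <- fractions[c("train", "val", "test")] * n
      base <- floor(quota)
      rem <- n - sum(base)
      if (rem > 0) {
        extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
      }
      subset_of[p] <- rep(c("train", "val", "test"), times = base)
    }
  })
  manifest$subset <- unname(subset_of[as.character(manifest$patient_id)])
  manifest
}

#' Initialize the MIL model state
#'
#' The model has three parts: an encoder MLP (two fully connected layers
#' with ReLU and dropout, then layer normalization) projecting patch
#' embeddings to `hidden` = 256 dimensions; gated attention pooling with a
#' tanh branch and a sigmoid gate of width `attn_dim`; and a linear
#' classifier to `n_classes` logits.
#'
#' @param input_dim embedding dimension.
#' @param n_classes number of output classes (2, 3 or 5 per grouping).
#' @param hidden encoder output width (default 256).
#' @param attn_dim attention hidden width (default 128).
#' @param dropout encoder dropout rate (default 0.3).
#' @param seed initialization seed.
#' @return a `mil_state` with parameter matrices and training metadata.
#' @export
mil_state <- function(input_dim, n_classes, hidden = 256L, attn_dim = 128L,
                      dropout = 0.3, seed = 1L) {
  he <- function(nin, nout) matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)),
                                   nin, nout)
  par <- with_seed(derive_seed(seed, "mil-init"), list(
    W1 = he(input_dim, hidden), b1 = numeric(hidden),
    W2 = he(hidden, hidden), b2 = numeric(hidden),
    gamma = rep(1, hidden), beta = numeric(hidden),
    V = he(hidden, attn_dim), U = he(hidden, attn_dim),
    w = stats::rnorm(attn_dim, sd = sqrt(1 / attn_dim)),
    Wc = he(hidden, n_classes), bc = numeric(n_classes)))
  structure(list(par = par, input_dim = as.integer(input_dim),
                 n_classes = as.integer(n_classes),
                 hidden = as.integer(hidden), attn_dim = as.integer(attn_dim),
                 dropout = dropout, meta = list(seed = seed)),
            class = "mil_state")
}

#' Assemble a padded bag batch
#'
#' Bags vary in length, so a mini-batch is zero-padded to the longest bag
#' in the batch and carries a mask (1 = real patch, 0 = pad).
#'
#' @param bag_matrices list of `n_i x dim` embedding matrices.
#' @param labels optional integer class indices (0-based), one per bag.
#' @return a `bag_batch`: list with `X` (stacked `(B*L) x dim`, bag-major,
#'   zero rows at pads), `mask` (`B x L`, 1/0), `B`, `L`, `dim`, `labels`.
#' @export
bag_batch <- function(bag_matrices, labels = NULL) {
  stopifnot(length(bag_matrices) >= 1)
  d <- unique(vapply(bag_matrices, ncol, 1L))
  if (length(d) != 1L) stop("bags have mixed embedding dimensions",
                            call. = FALSE)
  lens <- vapply(bag_matrices, nrow, 1L)
  if (any(lens < 1L)) stop("every bag needs >= 1 instance", call. = FALSE)
  B <- length(bag_matrices); L <- max(lens)
  X <- matrix(0, B * L, d)
  mask <- matrix(0, B, L)
  for (b in seq_len(B)) {
    n <- lens[b]
    X[(b - 1L) * L + seq_len(n), ] <- bag_matrices[[b]]
    mask[b, seq_len(n)] <- 1
  }
  structure(list(X = X, mask = mask, B = B, L = L, dim = d,
                 labels = if (!is.null(labels)) as.integer(labels) else NULL),
            class = "bag_batch")
}

# internal forward pass; returns cache for backprop when training
mil_forward <- function(state, batch, training = FALSE) {
  p <- state$par
  X <- batch$X; B <- batch$B; L <- batch$L
  mvec <- as.vector(t(batch$mask))          # bag-major instance mask
  keep <- 1 - state$dropout
  Z1 <- sweep(X %*% p$W1, 2, p$b1, `+`)
  A1 <- pmax(Z1, 0)
  M1 <- if (training && state$dropout > 0)
    matrix(stats::rbinom(length(A1), 1, keep) / keep, nrow(A1), ncol(A1))
  else 1
  D1 <- A1 * M1
  Z2 <- sweep(D1 %*% p$W2, 2, p$b2, `+`)
  A2 <- pmax(Z2, 0)
  M2 <- if (training && state$dropout > 0)
    matrix(stats::rbinom(length(A2), 1, keep) / keep, nrow(A2), ncol(A2))
  else 1
  D2 <- A2 * M2
  mu <- rowMeans(D2)
  ctr <- D2 - mu
  sd <- sqrt(rowMeans(ctr^2) + 1e-5)
  Xhat <- ctr / sd
  H <- sweep(Xhat, 2, p$gamma, `*`)
  H <- sweep(H, 2, p$beta, `+`)
  Tm <- tanh(H %*% p$V)
  G <- 1 / (1 + exp(-(H %*% p$U)))
  S <- as.vector((Tm * G) %*% p$w)
  # masked softmax per bag
  Smat <- matrix(S, L, B)                   # column = one bag
  Mmat <- t(batch$mask)                     # L x B
  if (any(colSums(Mmat) < 1))
    stop("all-masked bag in batch", call. = FALSE)
  Smat[Mmat == 0] <- -Inf
  mx <- apply(Smat, 2, max)
  E <- exp(sweep(Smat, 2, mx))
  E[Mmat == 0] <- 0
  Amat <- sweep(E, 2, colSums(E), `/`)
  a <- as.vector(Amat)                      # bag-major instance weights
  grp <- rep(seq_len(B), each = L)
  Z <- rowsum(H * a, grp)                   # B x hidden bag vectors
  logits <- sweep(Z %*% p$Wc, 2, p$bc, `+`)
  list(logits = logits, attention = t(Amat), bag_vectors = Z,
       cache = list(X = X, Z1 = Z1, A1 = A1, M1 = M1, D1 = D1, Z2 = Z2,
                    A2 = A2, M2 = M2, Xhat = Xhat, sd = sd, H = H, Tm = Tm,
                    G = G, a = a, mvec = mvec, grp = grp, B = B, L = L))
}

#' Encode instances through the MLP encoder
#'
#' Layer order: linear, ReLU, dropout, linear, ReLU, dropout, layer
#' normalization. Dropout is inactive outside training, so evaluation is
#' deterministic.
#'
#' @param batch a [bag_batch()].
#' @param state a [mil_state()].
#' @param training apply dropout.
#' @return array `(B, L, hidden)` of per-instance hidden vectors.
#' @export
encode_instances <- function(batch, state, training = FALSE) {
  if (ncol(batch$X) != state$input_dim)
    stop("embedding dimension ", ncol(batch$X), " does not match model (",
         state$input_dim, ")", call. = FALSE)
  fw <- mil_forward(state, batch, training = training)
  H <- fw$cache$H
  out <- array(0, c(batch$B, batch$L, state$hidden))
  for (b in seq_len(batch$B))
    out[b, , ] <- H[(b - 1L) * batch$L + seq_len(batch$L), ]
  out
}

#' Gated attention pooling with padding masks
#'
#' Per-instance scores `s_k = w' (tanh(V' h_k) * sigmoid(U' h_k))` are
#' softmax-normalized over the real (unmasked) instances of each bag;
#' padded positions get weight exactly 0. The bag representation is the
#' attention-weighted sum of hidden vectors, hence permutation-invariant in
#' the instances.
#'
#' @param hidden array `(B, L, hidden)` from [encode_instances()].
#' @param mask matrix `B x L` (1 = real, 0 = pad); each bag needs >= 1 real
#'   instance.
#' @param state a [mil_state()].
#' @return list with `bag_vectors` (`B x hidden`) and `attention`
#'   (`B x L`, rows summing to 1 over real instances).
#' @export
gated_attention_pool <- function(hidden, mask, state) {
  B <- dim(hidden)[1]; L <- dim(hidden)[2]
  if (any(rowSums(mask) < 1)) stop("all-masked bag", call. = FALSE)
  p <- state$par
  H <- matrix(0, B * L, dim(hidden)[3])
  for (b in seq_len(B)) H[(b - 1L) * L + seq_len(L), ] <- hidden[b, , ]
  Tm <- tanh(H %*% p$V)
  G <- 1 / (1 + exp(-(H %*% p$U)))
  S <- matrix(as.vector((Tm * G) %*% p$w), L, B)
  Mmat <- t(mask)
  S[Mmat == 0] <- -Inf
  E <- exp(sweep(S, 2, apply(S, 2, max)))
  E[Mmat == 0] <- 0
  A <- sweep(E, 2, colSums(E), `/`)
  a <- as.vector(A)
  Z <- rowsum(H * a, rep(seq_len(B), each = L))
  list(bag_vectors = Z, attention = t(A))
}

#' Linear classification head
#'
#' @param bag_vectors matrix `B x hidden`.
#' @param state a [mil_state()].
#' @return logits matrix `B x n_classes`.
#' @export
classify_bag <- function(bag_vectors, state) {
  sweep(bag_vectors %*% state$par$Wc, 2, state$par$bc, `+`)
}

#' Focal loss
#'
#' Mean over the batch of `-w_y (1 - p_y)^gamma log p_y` with `p` the
#' softmax of the logits; at `gamma = 0` it reduces exactly to weighted
#' cross-entropy. Class weights down-weight frequent classes (see
#' [dynamic_class_weights()]).
#'
#' @param logits matrix `B x K`.
#' @param labels integer class indices (0-based), length B.
#' @param class_weights positive weights per class (default all 1).
#' @param gamma focusing parameter >= 0 (default 2).
#' @return scalar loss.
#' @export
focal_loss <- function(logits, labels, class_weights = NULL, gamma = 2) {
  stopifnot(gamma >= 0)
  K <- ncol(logits)
  if (is.null(class_weights)) class_weights <- rep(1, K)
  stopifnot(all(class_weights > 0))
  P <- softmax_rows(logits)
  q <- pmin(pmax(P[cbind(seq_len(nrow(P)), labels + 1L)], 1e-12), 1 - 1e-12)
  wts <- class_weights[labels + 1L]
  mean(-wts * (1 - q)^gamma * log(q))
}

# gradient of focal_loss wrt logits (mean reduction)
focal_loss_grad <- function(logits, labels, class_weights = NULL, gamma = 2) {
  K <- ncol(logits); B <- nrow(logits)
  if (is.null(class_weights)) class_weights <- rep(1, K)
  P <- softmax_rows(logits)
  q <- pmin(pmax(P[cbind(seq_len(B), labels + 1L)], 1e-12), 1 - 1e-12)
  wts <- class_weights[labels + 1L]
  t1 <- if (gamma > 0) gamma * (1 - q)^(gamma - 1) * log(q) else 0
  dLdq <- wts * (t1 - (1 - q)^gamma / q)
  onehot <- matrix(0, B, K); onehot[cbind(seq_len(B), labels + 1L)] <- 1
  (dLdq * q) * (onehot - P) / B
}

#' Dynamic class weights
#'
#' Inverse-frequency weights recomputed each epoch from that epoch's
#' training label counts: `w_c` proportional to `1 / (n_c + eps)`,
#' normalized to mean 1 so balanced counts give unit weights and the loss
#' scale stays comparable across epochs. The smoothing `eps` keeps weights
#' finite for empty classes.
#'
#' @param counts integer label counts per class (length K).
#' @param eps smoothing constant (default 1).
#' @return numeric weights, mean 1.
#' @export
dynamic_class_weights <- function(counts, eps = 1) {
  stopifnot(all(counts >= 0))
  w <- 1 / (counts + eps)
  w / mean(w)
}

# full backward pass; returns gradient list matching state$par
mil_backward <- function(state, batch, fw, class_weights, gamma) {
  p <- state$par; cc <- fw$cache
  B <- cc$B; L <- cc$L
  dlogits <- focal_loss_grad(fw$logits, batch$labels, class_weights, gamma)
  Z <- fw$bag_vectors
  dWc <- crossprod(Z, dlogits)
  dbc <- colSums(dlogits)
  dZ <- dlogits %*% t(p$Wc)                       # B x hidden
  dZexp <- dZ[cc$grp, , drop = FALSE]             # N x hidden
  a <- cc$a
  H <- cc$H
  da <- rowSums(dZexp * H)
  dH <- a * dZexp
  ada <- a * da
  bag_dot <- rowsum(ada, cc$grp)                  # sum_j a_j da_j per bag
  ds <- a * (da - bag_dot[cc$grp, 1])
  TG <- cc$Tm * cc$G
  dw <- as.vector(crossprod(TG, ds))
  dTG <- outer(ds, p$w)
  dT <- dTG * cc$G
  dG <- dTG * cc$Tm
  dZt <- dT * (1 - cc$Tm^2)
  dZg <- dG * cc$G * (1 - cc$G)
  dV <- crossprod(H, dZt)
  dU <- crossprod(H, dZg)
  dH <- dH + dZt %*% t(p$V) + dZg %*% t(p$U)
  # layer norm backward
  Xhat <- cc$Xhat
  dXhat <- sweep(dH, 2, p$gamma, `*`)
  dgamma <- colSums(dH * Xhat)
  dbeta <- colSums(dH)
  rm1 <- rowMeans(dXhat)
  rm2 <- rowMeans(dXhat * Xhat)
  dD2 <- (dXhat - rm1 - Xhat * rm2) / cc$sd
  dA2 <- dD2 * cc$M2
  dZ2 <- dA2 * (cc$Z2 > 0)
  dW2 <- crossprod(cc$D1, dZ2)
  db2 <- colSums(dZ2)
  dD1 <- dZ2 %*% t(p$W2)
  dA1 <- dD1 * cc$M1
  dZ1 <- dA1 * (cc$Z1 > 0)
  dW1 <- crossprod(cc$X, dZ1)
  db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, gamma = dgamma, beta = dbeta,
       V = dV, U = dU, w = dw, Wc = dWc, bc = dbc)
}

adam_init <- function(par) {
  list(m = lapply(par, function(x) x * 0), v = lapply(par, function(x) x * 0),
       t = 0L)
}

adam_step <- function(par, grad, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t; bc2 <- 1 - beta2^opt$t
  for (nm in names(par)) {
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * grad[[nm]]
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * grad[[nm]]^2
    par[[nm]] <- par[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(par = par, opt = opt)
}

#' Default MIL training hyperparameters
#'
#' The optimizer and architecture defaults follow the published setup
#' (Adam at learning rate 1e-5, encoder dropout 0.3, 256-d projection);
#' the focal `gamma`, attention width, early-stopping patience and the
#' class-weight formula are unpublished and are package choices. Desk-scale
#' synthetic problems train with a larger learning rate than cohort-scale
#' data; pass `learning_rate` explicitly in that case.
#'
#' @param ... overrides of `learning_rate` (1e-5), `epochs` (100),
#'   `batch_size` (8), `gamma` (2), `patience` (10), `hidden` (256),
#'   `attn_dim` (128), `dropout` (0.3), `weight_eps` (1).
#' @return named list of hyperparameters.
#' @export
mil_hyperparams <- function(...) {
  utils::modifyList(list(learning_rate = 1e-5, epochs = 100L, batch_size = 8L,
                         gamma = 2, patience = 10L, hidden = 256L,
                         attn_dim = 128L, dropout = 0.3, weight_eps = 1),
                    list(...))
}

#' Train the gated-attention MIL classifier
#'
#' Mini-batch training with per-batch zero padding, focal loss with
#' epoch-wise dynamic class weights, Adam, per-epoch validation, and early
#' stopping with best-checkpoint restoration (monitored metric: validation
#' macro F1). Deterministic for a fixed seed under single-threaded BLAS.
#'
#' @param train_bags,val_bags lists of `n_i x dim` embedding matrices (or
#'   `embedding_bag` objects).
#' @param train_labels,val_labels integer grouped class indices (0-based).
#' @param n_classes number of classes K.
#' @param hyper from [mil_hyperparams()].
#' @param seed training seed (shuffling, dropout, init).
#' @return a trained [mil_state()]; `$meta` records the best epoch, metric
#'   history and hyperparameters.
#' @export
mil_train <- function(train_bags, train_labels, val_bags, val_labels,
                      n_classes, hyper = mil_hyperparams(), seed = 1L) {
  as_mat <- function(b) if (inherits(b, "embedding_bag")) b$embeddings else b
  train_bags <- lapply(train_bags, as_mat)
  val_bags <- lapply(val_bags, as_mat)
  if (!length(train_bags)) stop("empty training set", call. = FALSE)
  train_labels <- as.integer(train_labels)
  val_labels <- as.integer(val_labels)
  d <- ncol(train_bags[[1]])
  K <- as.integer(n_classes)
  state <- mil_state(d, K, hidden = hyper$hidden, attn_dim = hyper$attn_dim,
                     dropout = hyper$dropout, seed = seed)
  opt <- adam_init(state$par)
  best_par <- state$par; best_f1 <- -Inf; best_epoch <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_macro_f1 = numeric(), val_accuracy = numeric())
  n <- length(train_bags)
  with_seed(derive_seed(seed, "mil-train"), {
    for (epoch in seq_len(hyper$epochs)) {
      counts <- tabulate(train_labels + 1L, nbins = K)
      cw <- dynamic_class_weights(counts, hyper$weight_eps)
      ord <- sample.int(n)
      losses <- numeric(0)
      for (start in seq(1L, n, by = hyper$batch_size)) {
        idx <- ord[start:min(start + hyper$batch_size - 1L, n)]
        batch <- bag_batch(train_bags[idx], train_labels[idx])
        fw <- mil_forward(state, batch, training = TRUE)
        loss <- focal_loss(fw$logits, batch$labels, cw, hyper$gamma)
        if (!is.finite(loss))
          stop("non-finite loss at epoch ", epoch,
               " (lr too high or degenerate inputs)", call. = FALSE)
        losses <- c(losses, loss)
        grad <- mil_backward(state, batch, fw, cw, hyper$gamma)
        upd <- adam_step(state$par, grad, opt, hyper$learning_rate)
        state$par <- upd$par; opt <- upd$opt
      }
      val <- mil_predict(state, val_bags)
      vpred <- max.col(val$probabilities, ties.method = "first") - 1L
      vf1 <- macro_f1(val_labels, vpred, K)
      vacc <- mean(vpred == val_labels)
      history[nrow(history) + 1L, ] <- list(epoch, mean(losses), vf1, vacc)
      if (vf1 > best_f1 + 1e-12) {
        best_f1 <- vf1; best_par <- state$par; best_epoch <- epoch
      }
      if (epoch - best_epoch >= hyper$patience) break
    }
  })
  state$par <- best_par
  state$meta <- list(seed = seed, best_epoch = best_epoch,
                     best_val_macro_f1 = best_f1, history = history,
                     hyper = hyper, n_classes = K)
  state
}

#' Predict bags with a trained model
#'
#' @param state a trained [mil_state()].
#' @param bags list of `n_i x dim` matrices or `embedding_bag`s.
#' @param chunk_size bags per forward pass.
#' @return list with `probabilities` (`B x K`), `predicted` (0-based class
#'   indices), and `attention` (list of per-bag weight vectors, pads
#'   removed).
#' @export
mil_predict <- function(state, bags, chunk_size = 64L) {
  as_mat <- function(b) if (inherits(b, "embedding_bag")) b$embeddings else b
  bags <- lapply(bags, as_mat)
  B <- length(bags)
  probs <- matrix(NA_real_, B, state$n_classes)
  attn <- vector("list", B)
  for (start in seq(1L, B, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, B)
    batch <- bag_batch(bags[idx])
    fw <- mil_forward(state, batch, training = FALSE)
    probs[idx, ] <- softmax_rows(fw$logits)
    for (k in seq_along(idx))
      attn[[idx[k]]] <- fw$attention[k, seq_len(nrow(bags[[idx[k]]]))]
  }
  list(probabilities = probs,
       predicted = max.col(probs, ties.method = "first") - 1L,
       attention = attn)
}

#' Ablation conditions for region filtering
#'
#' Labels the four train/evaluation filtering combinations: A = filtered
#' throughout, B = filtered training but unfiltered evaluation, C =
#' unfiltered training but filtered evaluation, D = fully unfiltered.
#'
#' @param filter_train,filter_eval logical.
#' @return condition label, one of `"A"`, `"B"`, `"C"`, `"D"`.
#' @export
ablation_conditions <- function(filter_train, filter_eval) {
  if (filter_train && filter_eval) "A"
  else if (filter_train && !filter_eval) "B"
  else if (!filter_train && filter_eval) "C"
  else "D"
}

#' Run the region-filtering ablation harness
#'
#' Trains and evaluates the MIL classifier under the four filtering
#' conditions on a cohort that provides both variants of every bag: the
#' full (unfiltered) instance matrix and a keep-mask marking instances the
#' region filter would retain.
#'
#' @param bags list of `n_i x dim` matrices (unfiltered).
#' @param keep_masks list of logical vectors, `TRUE` = instance survives
#'   filtering; every bag must keep >= 1 instance.
#' @param labels integer grouped class indices (0-based).
#' @param split factor/character of `"train"`, `"val"`, `"test"` per bag.
#' @param n_classes K.
#' @param hyper from [mil_hyperparams()].
#' @param seed training seed (shared across conditions).
#' @param conditions subset of `c("A","B","C","D")` to run.
#' @return named list per condition: `condition`, `filter_train`,
#'   `filter_eval`, `report` (an [compute_metrics()] report on the test
#'   subset), `state`.
#' @export
run_ablation <- function(bags, keep_masks, labels, split, n_classes,
                         hyper = mil_hyperparams(), seed = 1L,
                         conditions = c("A", "B", "C", "D")) {
  stopifnot(length(bags) == length(keep_masks),
            length(bags) == length(labels), length(bags) == length(split))
  filt <- function(i) bags[[i]][keep_masks[[i]], , drop = FALSE]
  pick <- function(subset, filtered) {
    idx <- which(split == subset)
    list(bags = lapply(idx, function(i) if (filtered) filt(i) else bags[[i]]),
         labels = labels[idx])
  }
  out <- list()
  for (ft in c(TRUE, FALSE)) for (fe in c(TRUE, FALSE)) {
    cond <- ablation_conditions(ft, fe)
    if (!cond %in% conditions) next
    tr <- pick("train", ft); va <- pick("val", ft); te <- pick("test", fe)
    state <- mil_train(tr$bags, tr$labels, va$bags, va$labels, n_classes,
                       hyper = hyper, seed = seed)
    pred <- mil_predict(state, te$bags)
    report <- compute_metrics(te$labels, pred$predicted, pred$probabilities,
                              n_classes, condition = cond)
    out[[cond]] <- list(condition = cond, filter_train = ft, filter_eval = fe,
                        report = report, state = state)
  }
  out
}
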