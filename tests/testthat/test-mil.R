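test_that("grouping schemes implement the published mappings", {
  # conventional three-class: 0-1 no active, 2 mild, 3-4 severe
  expect_identical(group_labels(0:4, "type_A"), c(0L, 0L, 1L, 2L, 2L))
  expect_identical(group_labels(1L, "type_A"), 0L)
  # remission-separating alternative: 0 no disease, 1-2 low grade
  expect_identical(group_labels(0:4, "type_B"), c(0L, 1L, 1L, 2L, 2L))
  expect_identical(group_labels(1L, "type_B"), 1L)
  # binary: inactive (< 2) vs active (>= 2)
  expect_identical(group_labels(0:4, "binary"), c(0L, 0L, 1L, 1L, 1L))
  expect_identical(group_labels(2L, "binary"), 1L)
  expect_identical(group_labels(0:4, "five_class"), 0:4)
  expect_error(group_labels(5L, "type_A"), "0..4")
  sch <- grouping_scheme("type_A")
  expect_identical(sch$n_classes, 3L)
  # mapping is total and surjective
  expect_setequal(sch$map, 0:2)
})

test_that("patient-level label is the max across slides", {
  expect_identical(patient_max_label(c(0, 2, 1, 0)), 2L)
  expect_identical(patient_max_label(4L), 4L)
  # manifest aggregation against a brute-force oracle
  man <- histomil:::with_seed(11, data.frame(
    patient_id = sample(sprintf("p%02d", 1:20), 60, replace = TRUE),
    nhi = sample(0:4, 60, replace = TRUE)))
  got <- tapply(man$nhi, man$patient_id, patient_max_label)
  want <- tapply(man$nhi, man$patient_id, function(x) max(x))
  expect_identical(as.integer(got), as.integer(want))
})

test_that("patient_level_split never splits a patient and is deterministic", {
  man <- histomil:::with_seed(3, data.frame(
    slide_id = sprintf("s%03d", 1:300),
    patient_id = rep(sprintf("p%03d", 1:100), each = 3),
    nhi = sample(0:4, 300, replace = TRUE, prob = c(0.4, 0.1, 0.3, 0.15,
                                                    0.05))))
  for (seed in 1:5) {
    sp <- patient_level_split(man, seed = seed)
    per_pat <- tapply(sp$subset, sp$patient_id,
                      function(x) length(unique(x)))
    expect_true(all(per_pat == 1L))
  }
  s1 <- patient_level_split(man, seed = 9)
  s2 <- patient_level_split(man, seed = 9)
  expect_identical(s1$subset, s2$subset)
  expect_false(identical(patient_level_split(man, seed = 10)$subset,
                         s1$subset))
  # two-patient degenerate manifest: still no straddling, with a warning
  tiny <- data.frame(slide_id = c("a1", "a2", "b1"),
                     patient_id = c("pa", "pa", "pb"), nhi = c(0, 1, 3))
  w <- capture_warnings(sp2 <- patient_level_split(tiny, seed = 1))
  expect_true(length(w) >= 1 && all(grepl("stratum", w)))
  expect_identical(length(unique(sp2$subset[sp2$patient_id == "pa"])), 1L)
})

test_that("stratified split tracks global class frequencies", {
  man <- histomil:::with_seed(8, data.frame(
    slide_id = sprintf("s%04d", 1:500),
    patient_id = sprintf("p%04d", 1:500),
    nhi = sample(0:4, 500, replace = TRUE,
                 prob = c(0.45, 0.1, 0.28, 0.13, 0.04))))
  sp <- patient_level_split(man, seed = 21)
  glob <- prop.table(table(factor(man$nhi, 0:4)))
  for (sub in c("train", "val", "test")) {
    frac <- prop.table(table(factor(man$nhi[sp$subset == sub], 0:4)))
    expect_true(all(abs(frac - glob) <= 0.10),
                info = paste("subset", sub))
  }
})

test_that("encoder output is deterministic in eval mode with correct shape", {
  st <- mil_state(input_dim = 16, n_classes = 3, hidden = 32, attn_dim = 8,
                  dropout = 0.3, seed = 1)
  bags <- histomil:::with_seed(2, list(matrix(rnorm(64), 4, 16),
                                       matrix(rnorm(32), 2, 16)))
  batch <- bag_batch(bags, labels = c(0L, 1L))
  H1 <- encode_instances(batch, st, training = FALSE)
  H2 <- encode_instances(batch, st, training = FALSE)
  expect_identical(dim(H1), c(2L, 4L, 32L))
  expect_identical(H1, H2)
  expect_true(all(is.finite(H1)))   # zero-padded rows stay finite
  expect_error(encode_instances(bag_batch(list(matrix(0, 2, 7))), st),
               "dimension")
})

test_that("gated attention masks pads exactly and normalizes over real patches", {
  st <- mil_state(input_dim = 8, n_classes = 2, hidden = 16, attn_dim = 4,
                  dropout = 0, seed = 5)
  # single real patch: weight 1, bag vector equals its hidden vector
  one <- histomil:::with_seed(1, list(matrix(rnorm(8), 1, 8),
                                      matrix(rnorm(24), 3, 8)))
  batch <- bag_batch(one, labels = c(0L, 1L))
  H <- encode_instances(batch, st)
  pool <- gated_attention_pool(H, batch$mask, st)
  expect_equal(pool$attention[1, 1], 1)
  expect_equal(pool$attention[1, 2:3], c(0, 0))
  expect_equal(pool$bag_vectors[1, ], H[1, 1, ], tolerance = 1e-12)

  # identical hidden vectors share the weight equally
  same <- list(matrix(rep(1:8, each = 2), 2, 8, byrow = FALSE))
  bs <- bag_batch(same)
  Hs <- encode_instances(bs, st)
  ps <- gated_attention_pool(Hs, bs$mask, st)
  expect_equal(unname(ps$attention[1, ]), c(0.5, 0.5), tolerance = 1e-12)

  # random batches: pads exactly 0, real weights sum to 1
  bags <- histomil:::with_seed(7, lapply(1:6, function(i)
    matrix(rnorm(8 * sample(1:5, 1)), ncol = 8)))
  bb <- bag_batch(bags)
  Hb <- encode_instances(bb, st)
  pb <- gated_attention_pool(Hb, bb$mask, st)
  expect_true(all(pb$attention[bb$mask == 0] == 0))
  expect_equal(rowSums(pb$attention), rep(1, 6), tolerance = 1e-6)
  expect_error(gated_attention_pool(Hb, bb$mask * 0, st), "all-masked")
})

test_that("pooling is permutation-invariant and padding-invariant", {
  st <- mil_state(input_dim = 12, n_classes = 3, hidden = 24, attn_dim = 6,
                  dropout = 0, seed = 2)
  X <- histomil:::with_seed(3, matrix(rnorm(7 * 12), 7, 12))
  fw1 <- histomil:::mil_forward(st, bag_batch(list(X)), training = FALSE)
  perm <- c(4, 1, 7, 3, 6, 2, 5)
  fw2 <- histomil:::mil_forward(st, bag_batch(list(X[perm, ])),
                                training = FALSE)
  expect_equal(fw1$logits, fw2$logits, tolerance = 1e-9)
  expect_equal(fw1$attention[1, perm], fw2$attention[1, ], tolerance = 1e-9)
  # forcing extra zero-padded slots (by batching with a longer bag) does
  # not change the short bag's output
  Y <- histomil:::with_seed(4, matrix(rnorm(15 * 12), 15, 12))
  fw3 <- histomil:::mil_forward(st, bag_batch(list(X, Y)), training = FALSE)
  expect_equal(fw3$logits[1, ], fw1$logits[1, ], tolerance = 1e-6)
})

test_that("classifier head is affine with the grouping's class count", {
  st <- mil_state(input_dim = 4, n_classes = 3, hidden = 6, attn_dim = 3,
                  dropout = 0, seed = 1)
  # identity-like toy head: logits read out selected hidden entries
  st$par$Wc <- diag(1, 6, 3)
  st$par$bc <- c(0, 0, 0)
  z <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6)
  expect_equal(as.vector(classify_bag(z, st)), c(1, 2, 3))
  expect_identical(dim(classify_bag(matrix(0, 5, 6), st)), c(5L, 3L))
  expect_identical(grouping_scheme("type_A")$n_classes, 3L)
})

test_that("focal loss identities and closed-form value", {
  lg <- histomil:::with_seed(5, matrix(rnorm(30), 10, 3))
  y <- histomil:::with_seed(6, sample(0:2, 10, replace = TRUE))
  w <- c(1.5, 0.8, 0.7)
  # gamma = 0 reduces to weighted cross-entropy
  P <- exp(lg - apply(lg, 1, max)); P <- P / rowSums(P)
  ce <- mean(-w[y + 1] * log(P[cbind(1:10, y + 1)]))
  expect_equal(focal_loss(lg, y, w, gamma = 0), ce, tolerance = 1e-9)
  # p_y -> 1 drives the loss to 0
  sure <- matrix(c(50, 0, 0), 1, 3)
  expect_lt(focal_loss(sure, 0L, gamma = 2), 1e-12)
  # single sample at p_y = 0.5, unit weight, gamma 2: 0.25 * ln 2
  half <- matrix(c(0, 0), 1, 2)
  expect_equal(focal_loss(half, 0L, gamma = 2), 0.25 * log(2),
               tolerance = 1e-12)
})

test_that("analytic gradients match numerical differentiation", {
  st <- mil_state(input_dim = 5, n_classes = 3, hidden = 7, attn_dim = 4,
                  dropout = 0, seed = 2)
  bags <- histomil:::with_seed(1, list(matrix(rnorm(15), 3, 5),
                                       matrix(rnorm(25), 5, 5),
                                       matrix(rnorm(10), 2, 5)))
  batch <- bag_batch(bags, labels = c(0L, 2L, 1L))
  cw <- c(1.2, 0.8, 1.0)
  fw <- histomil:::mil_forward(st, batch, training = FALSE)
  gr <- histomil:::mil_backward(st, batch, fw, cw, gamma = 2)
  loss_of <- function(par) {
    s <- st; s$par <- par
    f <- histomil:::mil_forward(s, batch, training = FALSE)
    focal_loss(f$logits, batch$labels, cw, 2)
  }
  eps <- 1e-6
  for (nm in names(st$par)) {
    idx <- histomil:::with_seed(match(nm, names(st$par)),
                                sample(length(st$par[[nm]]),
                                       min(4, length(st$par[[nm]]))))
    for (i in idx) {
      pp <- st$par; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- st$par; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (loss_of(pp) - loss_of(pm)) / (2 * eps)
      expect_equal(gr[[nm]][i], num, tolerance = 1e-4,
                   info = paste("param", nm, "index", i))
    }
  }
})

test_that("dynamic class weights are inverse-frequency, mean 1, finite", {
  expect_equal(dynamic_class_weights(c(50, 50)), c(1, 1))
  w <- dynamic_class_weights(c(90, 10), eps = 0)
  expect_equal(w, c(1 / 90, 1 / 10) / mean(c(1 / 90, 1 / 10)))
  expect_equal(mean(w), 1)
  w0 <- dynamic_class_weights(c(100, 0, 20))
  expect_true(all(is.finite(w0)))
  expect_gt(w0[2], w0[3])   # empty class gets the largest weight
})

test_that("bag batches zero-pad exactly at masked positions", {
  bags <- list(matrix(1, 2, 4), matrix(2, 5, 4))
  b <- bag_batch(bags, labels = c(0L, 1L))
  expect_identical(dim(b$X), c(10L, 4L))
  expect_identical(b$mask[1, ], c(1, 1, 0, 0, 0))
  # padded rows are exactly zero
  expect_true(all(b$X[as.vector(t(b$mask)) == 0, ] == 0))
  expect_error(bag_batch(list(matrix(1, 0, 4))), ">= 1 instance")
  expect_error(bag_batch(list(matrix(1, 2, 4), matrix(1, 2, 5))), "mixed")
})

test_that("training is seed-deterministic and aborts on empty input", {
  gb <- gen_bags(list(n_per_class = c(12L, 12L), bag_size = c(5L, 10L),
                      dim = 8L, separation = 4), seed = 2)
  idx_tr <- c(1:8, 13:20); idx_va <- c(9:12, 21:24)
  hy <- mil_hyperparams(learning_rate = 1e-3, epochs = 4L, hidden = 16L,
                        attn_dim = 8L)
  s1 <- mil_train(gb$bags[idx_tr], gb$labels[idx_tr], gb$bags[idx_va],
                  gb$labels[idx_va], 2L, hyper = hy, seed = 3)
  s2 <- mil_train(gb$bags[idx_tr], gb$labels[idx_tr], gb$bags[idx_va],
                  gb$labels[idx_va], 2L, hyper = hy, seed = 3)
  expect_identical(s1$par, s2$par)
  expect_identical(s1$meta$best_epoch, s2$meta$best_epoch)
  expect_identical(s1$meta$history, s2$meta$history)
  expect_error(mil_train(list(), integer(0), gb$bags[idx_va],
                         gb$labels[idx_va], 2L), "empty training set")
})

test_that("ablation condition labels follow the train/eval wiring", {
  expect_identical(ablation_conditions(TRUE, TRUE), "A")
  expect_identical(ablation_conditions(TRUE, FALSE), "B")
  expect_identical(ablation_conditions(FALSE, TRUE), "C")
  expect_identical(ablation_conditions(FALSE, FALSE), "D")
})
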