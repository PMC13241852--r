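# build a tissue map with exact pixel counts per class, in vocabulary codes
composition_map <- function(n, fracs, vocab = default_vocabulary()) {
  total <- n * n
  counts <- round(fracs * total)
  stopifnot(sum(counts) <= total)
  codes <- vapply(names(fracs), function(nm)
    histomil:::vocab_code(vocab, "tissue_classes", nm), 1L)
  matrix(c(rep(codes, counts), rep(0L, total - sum(counts))), n, n)
}

test_that("retention rule: worked instance, pure muscle, no-disease tile", {
  # 15% stroma + 5% normal epithelium + one inflammatory pixel + muscle
  tm <- composition_map(100L, c(stroma = 0.15, normal_epithelium = 0.05,
                                muscle = 0.7999))
  tm[100, 100] <- histomil:::vocab_code(default_vocabulary(),
                                        "tissue_classes", "inflammatory")
  d <- tile_filter(tm)
  expect_true(d$kept)
  expect_equal(d$reference_fraction, 0.20, tolerance = 1e-3)
  expect_true(d$ibd_presence[["inflammatory"]])

  d2 <- tile_filter(composition_map(100L, c(muscle = 1)))
  expect_false(d2$kept)

  d3 <- tile_filter(composition_map(100L, c(stroma = 0.5)))
  expect_false(d3$kept)
  expect_match(d3$reason, "no disease-indicating class")
})

test_that("retention and background rules agree with an exhaustive oracle", {
  vocab <- default_vocabulary()
  # grid of composition vectors spanning the 10% boundary exactly
  ref_fracs <- c(0, 0.05, 0.0999, 0.10, 0.1001, 0.2, 0.5)
  ibd_fracs <- c(0, 0.0001, 0.01, 0.2)
  n <- 100L
  for (rf in ref_fracs) for (ib in ibd_fracs) {
    if (rf + ib > 1) next
    tm <- composition_map(n, c(stroma = rf / 2, normal_epithelium = rf / 2,
                               debris = ib))
    d <- tile_filter(tm, vocab)
    # oracle recomputed from raw pixel counts and the written rule
    ref_px <- sum(tm == vocab$tissue_classes[["stroma"]] |
                  tm == vocab$tissue_classes[["normal_epithelium"]])
    ibd_any <- any(tm == vocab$tissue_classes[["debris"]] |
                   tm == vocab$tissue_classes[["abnormal_epithelium"]] |
                   tm == vocab$tissue_classes[["inflammatory"]])
    expect_identical(d$kept, ref_px / (n * n) >= 0.10 && ibd_any,
                     info = sprintf("ref=%g ibd=%g", rf, ib))
  }

  # background rule across the 60% boundary
  for (bg in c(0, 0.3, 0.5999, 0.60, 0.6001, 0.9, 1)) {
    total <- 10000L
    nbg <- round(bg * total)
    pm <- matrix(c(rep(0L, nbg), rep(5L, total - nbg)), 100L, 100L)
    res <- patch_background_filter(patch_tissue = pm)
    expect_identical(res$kept, nbg / total < 0.60, info = paste("bg", bg))
    expect_equal(res$background_fraction, nbg / total)
  }
})

test_that("subdividing 1250 at 250 yields 25 patches; 250 yields itself", {
  p <- subdivide_tile(matrix(0L, 1250, 1250), 250L, "sl", c(0L, 0L),
                      keep_pixels = FALSE)
  expect_identical(nrow(p), 25L)
  expect_identical(sort(unique(p$grid_i)), 0:4)
  expect_false(any(duplicated(p[, c("origin_row", "origin_col")])))

  one <- subdivide_tile(matrix(1L, 250, 250), 250L, keep_pixels = TRUE)
  expect_identical(nrow(one), 1L)
  expect_identical(attr(one, "pixels")[[1]], matrix(1L, 250, 250))

  expect_error(subdivide_tile(matrix(0L, 300, 300), 250L), "not divisible")
})

test_that("center-crop of a 1520-tile gives 25 patches covering the core", {
  tile <- matrix(0L, 1520, 1520)
  p <- subdivide_tile(tile, 250L, "sl", c(100L, 200L), center_crop = 1250L,
                      keep_pixels = FALSE)
  expect_identical(nrow(p), 25L)
  # union of footprints is the centred 1250 square, offset by the crop
  expect_identical(min(p$origin_row), 100L + 135L)
  expect_identical(max(p$origin_row) + 250L, 100L + 135L + 1250L)
  expect_identical(min(p$origin_col), 200L + 135L)
})

test_that("patch ids are deterministic and patches partition the tile", {
  tile <- matrix(seq_len(500 * 500), 500, 500)
  p1 <- subdivide_tile(tile, 100L, "slideZ", c(1000L, 2000L))
  p2 <- subdivide_tile(tile, 100L, "slideZ", c(1000L, 2000L))
  expect_identical(p1$patch_id, p2$patch_id)
  expect_identical(nrow(p1), 25L)
  # conservation: every tile pixel appears in exactly one patch
  pix <- attr(p1, "pixels")
  expect_identical(sort(unlist(lapply(pix, as.vector), use.names = FALSE)), seq_len(500 * 500))
})

test_that("patch_background_filter needs evidence and prefers the tissue map", {
  expect_error(patch_background_filter(), "no background evidence")
  px <- array(1, c(20, 20, 3))  # all white
  res <- patch_background_filter(patch_pixels = px)
  expect_false(res$kept)
  expect_equal(res$background_fraction, 1)
  res2 <- patch_background_filter(patch_tissue = matrix(5L, 20, 20))
  expect_true(res2$kept)
  expect_equal(res2$background_fraction, 0)
})

test_that("raising tau_ref never adds a kept tile (monotonicity)", {
  with_seed_maps <- lapply(1:12, function(i) {
    rf <- runif(1, 0, 0.4); ib <- runif(1, 0, 0.1)
    composition_map(60L, c(stroma = rf, debris = ib))
  })
  taus <- c(0.02, 0.05, 0.10, 0.20, 0.40)
  for (tm in with_seed_maps) {
    kept <- vapply(taus, function(tau) tile_filter(tm, tau_ref = tau)$kept,
                   TRUE)
    expect_true(all(diff(kept) <= 0))  # monotone non-increasing in tau
  }
})

test_that("run_filter_stage bookkeeping: rejection, reduction, bypass", {
  vocab <- default_vocabulary()
  mk_tile <- function(id, fracs) {
    b <- annotation_bundle(id, "slide",
                           tissue_type = composition_map(100L, fracs),
                           vocabulary = vocab)
    b
  }
  # 3 informative tiles, 2 uninformative (no disease class)
  specs <- list(t1 = c(stroma = 0.5, inflammatory = 0.2),
                t2 = c(stroma = 0.3, debris = 0.1),
                t3 = c(stroma = 0.2, abnormal_epithelium = 0.05),
                t4 = c(muscle = 0.9),
                t5 = c(stroma = 0.5))
  bundles <- lapply(names(specs), function(id) mk_tile(id, specs[[id]]))
  names(bundles) <- names(specs)
  for (i in seq_along(bundles)) bundles[[i]]$tile_id <- names(specs)[i]
  tiles <- data.frame(tile_id = names(specs), slide_id = "slide",
                      origin_row = (seq_along(specs) - 1L) * 100L,
                      origin_col = 0L, stringsAsFactors = FALSE)
  res <- run_filter_stage(tiles, bundles,
                          config = list(patch_size = 20L))
  expect_identical(res$summary$n_tiles_kept, 3L)
  expect_identical(sort(unique(res$patches$tile_id)), c("t1", "t2", "t3"))
  # per kept tile: kept + excluded = 25 grid patches
  expect_true(all(table(res$patches$tile_id) == 25L))

  # all tiles rejected -> empty manifest, reduction 100%
  res0 <- run_filter_stage(tiles[4:5, ], bundles[4:5],
                           config = list(patch_size = 20L,
                                         center_crop = 100L))
  expect_identical(nrow(res0$patches), 0L)
  expect_equal(res0$summary$reduction, 1)

  # unfiltered mode keeps every non-background patch
  resU <- run_filter_stage(tiles, bundles,
                           config = list(patch_size = 20L, filter = FALSE))
  expect_identical(res$summary$n_tiles, 5L)
  expect_identical(length(unique(resU$patches$tile_id)), 5L)

  # filtered mode without bundles is an error
  expect_error(run_filter_stage(tiles, bundles[1:3]), "t4")
})
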