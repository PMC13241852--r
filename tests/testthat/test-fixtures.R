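test_that("generators are pure functions of (spec, seed)", {
  s1 <- gen_bundle(seed = 13); s2 <- gen_bundle(seed = 13)
  expect_identical(s1$bundle$tissue_type, s2$bundle$tissue_type)
  expect_identical(s1$ledger, s2$ledger)
  expect_false(identical(gen_bundle(seed = 14)$bundle$nucleus_instance,
                         s1$bundle$nucleus_instance))

  i1 <- gen_slide_image(seed = 4); i2 <- gen_slide_image(seed = 4)
  expect_identical(i1$image, i2$image)

  b1 <- gen_bags(seed = 5); b2 <- gen_bags(seed = 5)
  expect_identical(b1$bags, b2$bags)
  expect_identical(b1$labels, b2$labels)
})

test_that("ledgers are exact for counts and areas across many seeds", {
  shapes <- c("disc", "square", "ellipse")
  for (seed in 1:10) {
    spec <- list(
      tile_size = 160L,
      composition = c(stroma = 0.35, normal_epithelium = 0.15,
                      inflammatory = 0.05 * (seed %% 3)),
      glands = list(count = 1L + seed %% 3,
                    shape = shapes[1 + seed %% 3], size = 12L, aspect = 2),
      surface_epithelium_rows = if (seed %% 2) 10L else 0L,
      nuclei = list(list(type = "lymphocyte", count = 3L + seed %% 4,
                         tissue = "stroma"),
                    list(type = "epithelial", count = 2L,
                         tissue = "normal_epithelium")))
    gb <- gen_bundle(spec, seed = seed)
    ts <- compute_tile_stats(gb$bundle)
    expect_identical(as.integer(ts$tissue_areas),
                     as.integer(gb$ledger$tissue_areas), info = seed)
    expect_identical(as.integer(ts$nuclear_counts),
                     as.integer(gb$ledger$nuclear_counts), info = seed)
    expect_identical(ts$nuclear_counts_by_tissue,
                     gb$ledger$nuclear_counts_by_tissue, info = seed)
    expect_identical(ts$gland_count, gb$ledger$gland_count, info = seed)
    expect_identical(ts$surface_epithelium_area,
                     gb$ledger$surface_epithelium_area, info = seed)
    expect_identical(ts$nuclei_in_glands, gb$ledger$nuclei_in_glands,
                     info = seed)
  }
})

test_that("a single disc gland's rasterized area is recovered exactly", {
  gb <- gen_bundle(list(tile_size = 200L, composition = c(stroma = 0.3),
                        glands = list(count = 1L, shape = "disc",
                                      size = 20L),
                        nuclei = list()), seed = 3)
  expect_identical(gb$ledger$gland_areas,
                   sum(gb$bundle$gland_instance == 1L))
  ts <- compute_tile_stats(gb$bundle)
  expect_identical(ts$gland_count, 1L)
  expect_equal(ts$gland_circularities, 1, tolerance = 0.05)
})

test_that("infeasible packing raises an error", {
  expect_error(gen_bundle(list(tile_size = 50L,
                               glands = list(count = 1L, shape = "disc",
                                             size = 40L)),
                          seed = 1), "infeasible")
  expect_error(gen_bundle(list(tile_size = 60L,
                               composition = c(stroma = 0.001),
                               glands = list(count = 0L),
                               nuclei = list(list(type = "lymphocyte",
                                                  count = 500L,
                                                  tissue = "stroma"))),
                          seed = 1), "infeasible")
})

test_that("slide image generator: blank, blob geometry, determinism", {
  blank <- gen_slide_image(list(blobs = list(), noise = 0), seed = 1)
  expect_false(any(blank$foreground))
  expect_true(all(blank$image == 1))

  sl <- gen_slide_image(list(height = 200, width = 200,
                             blobs = list(list(row = 100, col = 100,
                                               radius = 50)), noise = 0),
                        seed = 2)
  expect_equal(sum(sl$foreground), sum(disc_mask(50, 200)), tolerance = 2)
  # foreground is exactly where the tint was painted
  dark <- (sl$image[, , 1] + sl$image[, , 2] + sl$image[, , 3]) / 3 < 0.9
  expect_identical(dark, sl$foreground)
})

test_that("bag generator plants signal at the configured rate", {
  spec <- list(n_per_class = c(40L, 40L), bag_size = c(30L, 50L),
               signal_rate = 0.10, dim = 16L, separation = 3)
  gb <- gen_bags(spec, seed = 9)
  pos <- gb$labels == 1L
  expect_false(any(unlist(gb$signal_masks[!pos])))
  n_sig <- sum(unlist(gb$signal_masks[pos]))
  n_inst <- sum(lengths(gb$signal_masks[pos]))
  # binomial CI around the planted rate (min-1 enforcement inflates
  # slightly)
  p_hat <- n_sig / n_inst
  expect_lt(abs(p_hat - 0.10), 3 * sqrt(0.1 * 0.9 / n_inst) + 0.01)
  # every positive bag carries at least one signal instance
  expect_true(all(vapply(gb$signal_masks[pos], any, TRUE)))
  expect_error(gen_bags(list(signal_rate = 0), seed = 1), "undefined")
})

test_that("zero separation is uninformative: training stays at chance", {
  gb <- gen_bags(list(n_per_class = c(30L, 30L), bag_size = c(10L, 20L),
                      dim = 16L, separation = 0, signal_rate = 0.1),
                 seed = 31)
  idx_tr <- c(1:20, 31:50); idx_va <- c(21:25, 51:55)
  idx_te <- c(26:30, 56:60)
  hy <- mil_hyperparams(learning_rate = 1e-3, epochs = 15L, patience = 5L,
                        hidden = 16L, attn_dim = 8L)
  st <- mil_train(gb$bags[idx_tr], gb$labels[idx_tr], gb$bags[idx_va],
                  gb$labels[idx_va], 2L, hyper = hy, seed = 2)
  acc <- mean(mil_predict(st, gb$bags[idx_te])$predicted ==
                gb$labels[idx_te])
  expect_lte(acc, 0.5 + 3 * sqrt(0.25 / length(idx_te)))
})

test_that("fixture cohort emits a consistent miniature pipeline input set", {
  dir <- withr::local_tempdir()
  man <- gen_fixture_cohort(dir, n_patients = 3L, seed = 6)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(all(c("slide_id", "patient_id", "location", "nhi") %in%
                    names(man)))
  store <- embedding_store(file.path(dir, "embeddings"))
  expect_setequal(list_slides(store), man$slide_id)
  bag <- load_bag(store, man$slide_id[1])
  expect_identical(bag$patient_id, man$patient_id[1])
  expect_identical(bag$label, man$nhi[1])
  bfiles <- list.files(file.path(dir, "bundles"), full.names = TRUE)
  expect_identical(length(bfiles), nrow(man))
  b <- read_bundle(bfiles[1])
  expect_length(validate_bundle(b), 0L)
  # rerun with the same seed reproduces the manifest
  dir2 <- withr::local_tempdir()
  man2 <- gen_fixture_cohort(dir2, n_patients = 3L, seed = 6)
  expect_identical(man, man2)
})

test_that("command-line wrappers drive the pipeline end to end", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "cohort")
  expect_output(cli_main(c("fixtures", "--out", out, "--patients", "3",
                           "--seed", "2")), "wrote cohort")
  slide <- list.files(file.path(out, "slides"), full.names = TRUE)[1]
  tcsv <- file.path(dir, "tiles.csv")
  expect_output(cli_main(c("tile", "--slide", slide, "--out", tcsv,
                           "--tile-size", "160")), "tiles:")
  expect_true(file.exists(tcsv))
  scsv <- file.path(dir, "stats.csv")
  expect_output(cli_main(c("stats", "--bundles", file.path(out, "bundles"),
                           "--out", scsv)), "slides:")
  stats_tab <- utils::read.csv(scsv)
  expect_true("tissue_fraction.inflammatory" %in% names(stats_tab))
  bundle <- list.files(file.path(out, "bundles"), full.names = TRUE)[1]
  pcsv <- file.path(dir, "patches.csv")
  expect_output(cli_main(c("filter", "--bundle", bundle, "--out", pcsv,
                           "--patch-size", "40")), "patches:")
  expect_true(file.exists(pcsv))
  expect_error(cli_main(c("frobnicate")), "unknown subcommand")
})
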