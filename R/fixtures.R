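#' Synthetic annotation bundle with ground-truth ledger
#'
#' Rasterizes a tile whose pixel-level truths are known by construction, so
#' the statistics module can be tested against an exact ledger: a tissue
#' type map with prescribed class fractions (filled as exact pixel runs),
#' optional glands (disc, square or ellipse) with a lumen and a surface
#' epithelium band on the gland-type map, and non-overlapping nuclei
#' (rasterized as small discs) of prescribed types placed with their
#' centers in prescribed tissue classes.
#'
#' @param spec list with elements:
#'   * `tile_size`: side in pixels (default 200);
#'   * `composition`: named non-background tissue fractions summing to
#'     <= 1 (remainder is background);
#'   * `glands`: list(`count`, `shape` in disc/square/ellipse, `size`
#'     radius or half-side, `aspect` for ellipses);
#'   * `surface_epithelium_rows`: thickness of the top surface-epithelium
#'     band (0 = none);
#'   * `nuclei`: list of list(`type`, `count`, `tissue`, `radius`).
#' @param seed integer seed; the generator is a pure function of
#'   (spec, seed).
#' @param vocabulary a [label_vocabulary()].
#' @return list with `bundle` (an [annotation_bundle()]) and `ledger`
#'   (exact truths: `tissue_areas`, `nuclear_counts`,
#'   `nuclear_counts_by_tissue`, `gland_count`, `gland_areas`,
#'   `gland_circularity_truth` (continuous-formula values),
#'   `surface_epithelium_area`, `nuclei_in_glands`,
#'   `nuclei_in_surface_epithelium`).
#' @export
gen_bundle <- function(spec = list(), seed = 1L,
                       vocabulary = default_vocabulary()) {
  spec <- merge_spec(list(
    tile_size = 200L,
    composition = c(stroma = 0.4, normal_epithelium = 0.2,
                    inflammatory = 0.1),
    glands = list(count = 2L, shape = "disc", size = 15L, aspect = 2),
    surface_epithelium_rows = 0L,
    nuclei = list(list(type = "lymphocyte", count = 5L, tissue = "stroma",
                       radius = 2L))), spec)
  n <- as.integer(spec$tile_size)
  stopifnot(sum(spec$composition) <= 1 + 1e-9)
  with_seed(derive_seed(seed, "gen-bundle"), {
    total <- n * n
    counts <- round(spec$composition * total)
    if (sum(counts) > total) counts[1] <- counts[1] - (sum(counts) - total)
    codes <- vapply(names(counts), function(nm)
      vocab_code(vocabulary, "tissue_classes", nm), 1L)
    tt <- matrix(c(unlist(mapply(rep, codes, counts, SIMPLIFY = FALSE),
                          use.names = FALSE),
                   rep(0L, total - sum(counts))), n, n)
    gi <- matrix(0L, n, n); gt <- matrix(0L, n, n); lu <- matrix(0L, n, n)
    gland_areas <- integer(0); circ_truth <- numeric(0)
    g <- spec$glands
    if (!is.null(g) && g$count > 0L) {
      shape_mask <- switch(g$shape,
        disc = {
          r <- g$size
          outer(-r:r, -r:r, function(i, j) i^2 + j^2 <= r^2)
        },
        square = matrix(TRUE, 2L * g$size, 2L * g$size),
        ellipse = {
          a <- g$size * g$aspect; b <- g$size
          outer(-ceiling(b):ceiling(b), -ceiling(a):ceiling(a),
                function(i, j) (i / b)^2 + (j / a)^2 <= 1)
        },
        stop("unknown gland shape: ", g$shape, call. = FALSE))
      truth <- switch(g$shape,
        disc = 1,
        square = pi / 4,
        ellipse = {
          a <- g$size * g$aspect; b <- g$size
          hh <- ((a - b) / (a + b))^2
          P <- pi * (a + b) * (1 + 3 * hh / (10 + sqrt(4 - 3 * hh)))
          4 * pi * (pi * a * b) / P^2
        })
      sh <- nrow(shape_mask); sw <- ncol(shape_mask)
      if (sh > n || sw > n)
        stop("infeasible packing: gland larger than tile", call. = FALSE)
      placed <- 0L; tries <- 0L
      occupied <- matrix(FALSE, n, n)
      while (placed < g$count) {
        tries <- tries + 1L
        if (tries > 200L * g$count)
          stop("infeasible packing: cannot place ", g$count, " glands",
               call. = FALSE)
        r0 <- sample.int(n - sh + 1L, 1L); c0 <- sample.int(n - sw + 1L, 1L)
        rows <- r0:(r0 + sh - 1L); cols <- c0:(c0 + sw - 1L)
        if (any(occupied[rows, cols][shape_mask])) next
        placed <- placed + 1L
        sub <- gi[rows, cols]; sub[shape_mask] <- placed
        gi[rows, cols] <- sub
        subt <- gt[rows, cols]
        subt[shape_mask] <- vocab_code(vocabulary, "gland_types", "gland")
        gt[rows, cols] <- subt
        occupied[rows, cols] <- occupied[rows, cols] | shape_mask
        # small central lumen
        lr <- max(2L, floor(g$size / 3))
        lmask <- outer(-lr:lr, -lr:lr, function(i, j) i^2 + j^2 <= lr^2)
        cr <- r0 + sh %/% 2L; ccx <- c0 + sw %/% 2L
        lrows <- (cr - lr):(cr + lr); lcols <- (ccx - lr):(ccx + lr)
        subl <- lu[lrows, lcols]; subl[lmask] <- placed
        lu[lrows, lcols] <- subl
        gland_areas <- c(gland_areas, sum(shape_mask))
        circ_truth <- c(circ_truth, truth)
      }
    }
    se_area <- 0L
    if (spec$surface_epithelium_rows > 0L) {
      se_rows <- seq_len(min(spec$surface_epithelium_rows, n))
      band <- gt[se_rows, , drop = FALSE]
      band[band == 0L] <- vocab_code(vocabulary, "gland_types",
                                     "surface_epithelium")
      gt[se_rows, ] <- band
      se_area <- sum(gt == vocab_code(vocabulary, "gland_types",
                                      "surface_epithelium"))
    }
    ni <- matrix(0L, n, n); nt <- matrix(0L, n, n)
    nuc_occupied <- matrix(FALSE, n, n)
    ntype_names <- setdiff(names(vocabulary$nucleus_types), "background")
    tis_names <- setdiff(names(vocabulary$tissue_classes), "background")
    ncounts <- stats::setNames(integer(length(ntype_names)), ntype_names)
    cross <- matrix(0L, length(ntype_names), length(tis_names),
                    dimnames = list(ntype_names, tis_names))
    nig <- 0L; nise <- 0L
    inst <- 0L
    for (nu in spec$nuclei) {
      rad <- nu$radius %||% 2L
      type_code <- vocab_code(vocabulary, "nucleus_types", nu$type)
      tis_code <- vocab_code(vocabulary, "tissue_classes", nu$tissue)
      dmask <- outer(-rad:rad, -rad:rad, function(i, j) i^2 + j^2 <= rad^2)
      cand <- which(tt == tis_code)
      placed_n <- 0L; tries <- 0L
      while (placed_n < nu$count) {
        tries <- tries + 1L
        if (tries > 500L * max(1L, nu$count))
          stop("infeasible packing: cannot place ", nu$count, " ", nu$type,
               " nuclei on ", nu$tissue, call. = FALSE)
        if (!length(cand))
          stop("infeasible packing: no ", nu$tissue, " pixels for nuclei",
               call. = FALSE)
        idx <- cand[sample.int(length(cand), 1L)]
        cr <- (idx - 1L) %% n + 1L; ccx <- (idx - 1L) %/% n + 1L
        if (cr - rad < 1L || cr + rad > n || ccx - rad < 1L || ccx + rad > n)
          next
        rows <- (cr - rad):(cr + rad); cols <- (ccx - rad):(ccx + rad)
        if (any(nuc_occupied[rows, cols][dmask])) next
        inst <- inst + 1L; placed_n <- placed_n + 1L
        sub <- ni[rows, cols]; sub[dmask] <- inst; ni[rows, cols] <- sub
        subt <- nt[rows, cols]; subt[dmask] <- type_code
        nt[rows, cols] <- subt
        nuc_occupied[rows, cols] <- nuc_occupied[rows, cols] | dmask
        ncounts[nu$type] <- ncounts[nu$type] + 1L
        cross[nu$type, nu$tissue] <- cross[nu$type, nu$tissue] + 1L
        gcode <- gt[cr, ccx]
        if (gi[cr, ccx] > 0L &&
            gcode == vocab_code(vocabulary, "gland_types", "gland"))
          nig <- nig + 1L
        if (gcode == vocab_code(vocabulary, "gland_types",
                                "surface_epithelium"))
          nise <- nise + 1L
      }
    }
    nb <- boundary_map(ni)
    bundle <- annotation_bundle(
      tile_id = sprintf("fixture_s%d", seed), slide_id = "fixture",
      nucleus_instance = ni, nucleus_type = nt, nucleus_boundary = nb,
      gland_instance = gi, gland_type = gt, lumen_instance = lu,
      tissue_type = tt, vocabulary = vocabulary)
    tissue_areas <- vapply(
      c(background = 0L,
        stats::setNames(vocabulary$tissue_classes[tis_names], tis_names)),
      function(cd) sum(tt == cd), 1L)
    list(bundle = bundle,
         ledger = list(tissue_areas = tissue_areas,
                       nuclear_counts = ncounts,
                       nuclear_counts_by_tissue = cross,
                       gland_count = length(gland_areas),
                       gland_areas = gland_areas,
                       gland_circularity_truth = circ_truth,
                       surface_epithelium_area = as.integer(se_area),
                       nuclei_in_glands = nig,
                       nuclei_in_surface_epithelium = nise))
  })
}

#' Synthetic slide-like raster with foreground truth
#'
#' Tissue blobs (discs of an eosin-like tint) on a white background, with
#' controllable brightness and box blur, plus the exact foreground mask for
#' oracle tests of tissue detection and tiling.
#'
#' @param spec list: `height`, `width` (default 640), `blobs` list of
#'   list(`row`, `col`, `radius` in pixels), `brightness` multiplier of the
#'   tissue tint (default 1), `blur` box-blur half-width (0 = sharp),
#'   `noise` pixel noise sd (default 0.02).
#' @param seed integer seed.
#' @return list with `image` (`H x W x 3` in `[0, 1]`) and `foreground`
#'   (logical truth mask at full resolution).
#' @export
gen_slide_image <- function(spec = list(), seed = 1L) {
  spec <- merge_spec(list(
    height = 640L, width = 640L,
    blobs = list(list(row = 320, col = 320, radius = 200)),
    brightness = 1, blur = 0L, noise = 0.02), spec)
  h <- spec$height; w <- spec$width
  with_seed(derive_seed(seed, "gen-slide"), {
    fg <- matrix(FALSE, h, w)
    for (b in spec$blobs) {
      rows <- matrix(seq_len(h), h, w); cols <- matrix(seq_len(w), h, w,
                                                       byrow = TRUE)
      fg <- fg | ((rows - b$row)^2 + (cols - b$col)^2 <= b$radius^2)
    }
    tint <- c(0.78, 0.45, 0.65) * spec$brightness   # eosin-like
    img <- array(1, c(h, w, 3))
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[fg] <- tint[ch]
      if (spec$noise > 0)
        plane <- plane + matrix(stats::rnorm(h * w, sd = spec$noise), h, w)
      img[, , ch] <- plane
    }
    if (spec$blur > 0) {
      k <- 2L * as.integer(spec$blur) + 1L
      for (ch in 1:3) img[, , ch] <- box_blur(img[, , ch], k)
    }
    img[img < 0] <- 0; img[img > 1] <- 1
    list(image = img, foreground = fg)
  })
}

# separable box blur with edge replication
box_blur <- function(m, k) {
  half <- k %/% 2L
  smooth_dim <- function(x) {
    n <- nrow(x)
    idx <- pmin(pmax(outer(seq_len(n), -half:half, `+`), 1L), n)
    out <- x * 0
    for (o in seq_len(k)) out <- out + x[idx[, o], , drop = FALSE]
    out / k
  }
  t(smooth_dim(t(smooth_dim(m))))
}

#' Synthetic embedding bags with planted class structure
#'
#' Emulates the statistical structure a weakly supervised slide grader
#' faces: each bag (slide) is a set of patch embeddings, most drawn from a
#' shared background distribution, with the slide label driven by a sparse
#' minority of class-specific signal instances — mirroring how sparse but
#' diagnostically important lesions determine a slide grade. Class 0 is
#' the null class (no signal instances). Optional "confuser" instances
#' drawn from *other* classes' signal distributions model the non-informative
#' or misleading patches that region filtering removes; the returned
#' `keep_masks` flag the instances a filter would retain.
#'
#' @param spec list: `n_per_class` bags per class (vector, length =
#'   number of classes), `bag_size` length-2 range, `signal_rate` expected
#'   signal fraction per non-null bag (default 0.10), `dim` embedding
#'   dimension (default 32), `separation` mean shift of signal instances in
#'   noise-sd units (default 3), `noise_sd` (default 1), `confuser_rate`
#'   fraction of instances replaced by off-class signals (default 0).
#' @param seed integer seed.
#' @return list with `bags` (list of `n_i x dim` matrices), `labels`
#'   (0-based classes), `signal_masks`, `confuser_masks`, `keep_masks`
#'   (logical per instance), and `class_means`.
#' @export
gen_bags <- function(spec = list(), seed = 1L) {
  spec <- merge_spec(list(
    n_per_class = c(50L, 50L), bag_size = c(30L, 60L), signal_rate = 0.10,
    dim = 32L, separation = 3, noise_sd = 1, confuser_rate = 0,
    confuser_strength = 6), spec)
  K <- length(spec$n_per_class)
  stopifnot(spec$dim >= 2L, K >= 2L)
  if (spec$signal_rate <= 0 && any(spec$n_per_class[-1] > 0))
    stop("signal rate 0 for a non-null class: labels would be undefined",
         call. = FALSE)
  with_seed(derive_seed(seed, "gen-bags"), {
    means <- matrix(0, K, spec$dim)
    for (k in 2:K) {
      v <- stats::rnorm(spec$dim)
      means[k, ] <- v / sqrt(sum(v^2)) * spec$separation * spec$noise_sd
    }
    bags <- list(); labels <- integer(0)
    signal_masks <- list(); confuser_masks <- list(); keep_masks <- list()
    bi <- 0L
    for (k in seq_len(K)) for (rep_i in seq_len(spec$n_per_class[k])) {
      bi <- bi + 1L
      sz <- sample(spec$bag_size[1]:spec$bag_size[2], 1L)
      X <- matrix(stats::rnorm(sz * spec$dim, sd = spec$noise_sd), sz,
                  spec$dim)
      sig <- rep(FALSE, sz)
      if (k > 1L) {
        n_sig <- max(1L, stats::rbinom(1L, sz, spec$signal_rate))
        sig[sample.int(sz, n_sig)] <- TRUE
        X[sig, ] <- X[sig, , drop = FALSE] +
          matrix(means[k, ], n_sig, spec$dim, byrow = TRUE)
      }
      conf <- rep(FALSE, sz)
      if (spec$confuser_rate > 0) {
        conf <- stats::runif(sz) < spec$confuser_rate & !sig
        for (i in which(conf)) {
          # pure-noise patch: a fresh random direction per instance, so it
          # carries no class information but drowns out the sparse signal
          v <- stats::rnorm(spec$dim)
          mu <- v / sqrt(sum(v^2)) * spec$confuser_strength * spec$noise_sd
          X[i, ] <- stats::rnorm(spec$dim, sd = spec$noise_sd) + mu
        }
        if (!any(!conf))
          conf[1] <- FALSE  # keep >= 1 instance after filtering
      }
      bags[[bi]] <- X
      labels[bi] <- k - 1L
      signal_masks[[bi]] <- sig
      confuser_masks[[bi]] <- conf
      keep_masks[[bi]] <- !conf
    }
    list(bags = bags, labels = labels, signal_masks = signal_masks,
         confuser_masks = confuser_masks, keep_masks = keep_masks,
         class_means = means)
  })
}

#' Generate a miniature end-to-end fixture cohort on disk
#'
#' Emits everything the pipeline consumes, at desk scale: slide rasters
#' (PNG), per-tile annotation bundles (HDF5), per-slide embedding
#' containers (HDF5, via the mock encoder), and a slide manifest CSV with
#' patient ids, locations and grades. Intended for the `fixtures` CLI
#' subcommand and for smoke-testing the full pipeline offline.
#'
#' @param dir output directory.
#' @param n_patients number of synthetic patients (default 6).
#' @param seed integer seed.
#' @param tile_size,patch_size pipeline geometry (defaults 160 and 40 at
#'   fixture scale).
#' @return the manifest data.frame, invisibly; files under `dir`.
#' @export
gen_fixture_cohort <- function(dir, n_patients = 6L, seed = 1L,
                               tile_size = 160L, patch_size = 40L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "slides"), showWarnings = FALSE)
  dir.create(file.path(dir, "bundles"), showWarnings = FALSE)
  store <- embedding_store(file.path(dir, "embeddings"))
  encoder <- make_mock_encoder(dim = 64L, seed = derive_seed(seed, "enc"))
  locations <- c("terminal_ileum", "right_colon", "left_colon", "rectum")
  rows <- list()
  with_seed(derive_seed(seed, "cohort"), {
    for (p in seq_len(n_patients)) {
      patient_id <- sprintf("P%03d", p)
      n_slides <- sample(2:3, 1L)
      locs <- sample(locations, n_slides)
      for (s in seq_len(n_slides)) {
        slide_id <- sprintf("%s_S%d", patient_id, s)
        nhi <- sample(0:4, 1L)
        inflamed <- 0.05 + 0.08 * nhi
        sl <- gen_slide_image(list(height = 2L * tile_size,
                                   width = 2L * tile_size,
                                   blobs = list(list(row = tile_size,
                                                     col = tile_size,
                                                     radius = tile_size))),
                              seed = derive_seed(seed, slide_id))
        write_slide_image(sl$image,
                          file.path(dir, "slides", paste0(slide_id, ".png")))
        gb <- gen_bundle(list(
          tile_size = tile_size,
          composition = c(stroma = 0.35, normal_epithelium = 0.2,
                          inflammatory = inflamed, debris = 0.03),
          glands = list(count = max(0L, 3L - nhi %/% 2L), shape = "disc",
                        size = 12L),
          nuclei = list(list(type = "lymphocyte",
                             count = 4L + 4L * nhi, tissue = "stroma"),
                        list(type = "neutrophil",
                             count = if (nhi >= 3) 8L else 1L,
                             tissue = "inflammatory"))),
          seed = derive_seed(seed, paste0(slide_id, "-bundle")))
        gb$bundle$slide_id <- slide_id
        gb$bundle$tile_id <- paste0(slide_id, "_t0")
        write_bundle(gb$bundle,
                     file.path(dir, "bundles", paste0(slide_id, "_t0.h5")))
        patches <- subdivide_tile(sl$image[seq_len(tile_size),
                                           seq_len(tile_size), ,
                                           drop = FALSE],
                                  patch_size, slide_id, c(0L, 0L))
        emb <- encode_patches(attr(patches, "pixels"), encoder)
        store_embeddings(store, slide_id, patient_id, emb,
                         as.matrix(patches[, c("origin_row", "origin_col")]),
                         label = nhi)
        rows[[slide_id]] <- data.frame(
          slide_id = slide_id, patient_id = patient_id,
          location = locs[s], nhi = nhi, stringsAsFactors = FALSE)
      }
    }
  })
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
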