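test_that("zero requested counts give an empty scene and a uniform image", {
  p <- small_scene(counts = c(beta_mature = 0L, alpha = 0L, delta = 0L,
                              beta_immature = 0L))
  sc <- sample_scene(p)
  expect_equal(nrow(sc), 0L)
  pn <- noiseless(p)
  scn <- render_scene(sc, pn)
  expect_true(all(scn$image == pn$intensity[["cytoplasm"]]))
  expect_true(all(scn$truth$semantic_mask == 0L))
  expect_true(all(scn$truth$instance_mask == 0L))
})

test_that("sampled scenes honor counts, spacing and class morphology invariants", {
  p <- small_scene(seed = 42L)
  sc <- sample_scene(p)
  expect_equal(as.integer(table(factor(sc$granule_class, levels = names(p$counts)))),
               unname(as.integer(p$counts)))
  expect_true(all(sc$core_radius <= sc$outer_radius))
  expect_true(all(sc$outer_radius > 2))
  h <- 1 - sc$core_radius / sc$outer_radius
  expect_true(all(h[sc$granule_class == "alpha"] <= 0.15))
  expect_true(all(h[sc$granule_class == "beta_mature"] >= 0.25))
  expect_true(all(h[sc$granule_class == "beta_immature"] >= 0.05 &
                  h[sc$granule_class == "beta_immature"] < 0.25))
  expect_true(all(h[sc$granule_class == "delta"] == 0))
  d <- as.matrix(dist(sc[, c("center_x", "center_y")]))
  rs <- outer(sc$outer_radius, sc$outer_radius, "+")
  diag(d) <- Inf
  expect_true(all(d >= rs + p$min_center_spacing - 1e-9))
})

test_that("beta outer diameter sampling matches the 350 nm / 4 nm-per-px design", {
  p <- scene_params(image_shape = c(6000L, 6000L),
                    counts = c(beta_mature = 500L, alpha = 0L, delta = 0L,
                               beta_immature = 0L),
                    seed = 3L)
  sc <- sample_scene(p)
  expect_equal(mean(2 * sc$outer_radius), 87.5, tolerance = 2 / 87.5)
})

test_that("same params and seed give bit-identical scenes and renders", {
  p <- small_scene(seed = 7L)
  s1 <- generate_scene(p); s2 <- generate_scene(p)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$truth, s2$truth)
  p2 <- small_scene(seed = 8L)
  expect_false(identical(generate_scene(p2)$image, s1$image))
})

test_that("rendered core/halo areas equal the pixel-enumeration oracle", {
  p <- noiseless(small_scene(side = 220L,
                             counts = c(beta_mature = 0L, alpha = 0L,
                                        delta = 0L, beta_immature = 0L)))
  cases <- list(
    one_granule(cx = 110, cy = 110, outer = 40, core = 24),
    one_granule(cx = 60.3, cy = 90.7, outer = 35, core = 21, ecc = 0.5,
                theta = 0.8),
    one_granule(class = "alpha", cx = 110, cy = 110, outer = 30, core = 27))
  for (g in cases) {
    scn <- render_scene(g, p)
    oracle <- oracle_ellipse_areas(g, 220L, 220L)
    expect_equal(scn$truth$granules$core_area_px, unname(oracle["core"]))
    expect_equal(scn$truth$granules$halo_area_px, unname(oracle["halo"]))
    lv <- sort(unique(as.vector(scn$image)))
    expect_true(all(lv %in% p$intensity))
  }
})

test_that("delta granules render with zero halo pixels", {
  p <- noiseless(small_scene(side = 200L))
  g <- one_granule(class = "delta", outer = 30, core = 30)
  scn <- render_scene(g, p)
  expect_equal(scn$truth$granules$halo_area_px, 0L)
  expect_gt(scn$truth$granules$core_area_px, 0L)
})

test_that("granules extending past the edge are clipped with areas to match", {
  p <- noiseless(small_scene(side = 200L))
  g <- one_granule(cx = 5, cy = 100, outer = 40, core = 24)
  scn <- render_scene(g, p)
  oracle <- oracle_ellipse_areas(g, 200L, 200L)  # oracle only counts in-image pixels
  expect_equal(scn$truth$granules$core_area_px, unname(oracle["core"]))
  expect_equal(scn$truth$granules$halo_area_px, unname(oracle["halo"]))
  expect_lt(scn$truth$granules$area_px, pi * 40^2)
})

test_that("semantic and instance masks partition pixels consistently", {
  scn <- generate_scene(small_scene(seed = 5L))
  sem <- scn$truth$semantic_mask
  inst <- scn$truth$instance_mask
  expect_true(all(sem %in% 0:3))
  expect_true(all((inst > 0) == (sem > 0)))
  ids <- sort(unique(as.vector(inst[inst > 0])))
  expect_identical(ids, seq_along(ids))
  g <- scn$truth$granules
  ann <- g[g$granule_class != "beta_immature", ]
  # semantic class at any instance pixel equals that granule's class
  for (i in seq_len(nrow(ann))) {
    px <- which(inst == i)
    expect_true(all(sem[px] == semantic_code(ann$granule_class[i])))
  }
})

test_that("a disk's realized area matches its ideal area within discretization", {
  # 350 nm diameter at 4 nm/px: ideal px area pi * 43.75^2
  p <- noiseless(small_scene(side = 140L))
  g <- one_granule(cx = 70, cy = 70, outer = 43.75, core = 43.75 * 0.6)
  scn <- render_scene(g, p)
  expect_equal(scn$truth$granules$area_px, pi * 43.75^2,
               tolerance = 0.03)
  # nm^2 companion scale
  expect_equal(scn$truth$granules$area_px * p$nm_per_px^2,
               scn$truth$granules$area_px * 16)
})

test_that("increasing core radius at fixed outer radius strictly increases core area", {
  p <- noiseless(small_scene(side = 160L))
  cores <- c(20, 24, 28, 32, 36)
  areas <- vapply(cores, function(cr) {
    render_scene(one_granule(cx = 80, cy = 80, outer = 40, core = cr),
                 p)$truth$granules$core_area_px
  }, numeric(1))
  expect_true(all(diff(areas) > 0))
})

test_that("immature beta granules appear in the image but not in ground-truth masks", {
  p <- noiseless(small_scene(side = 256L,
                             counts = c(beta_mature = 0L, alpha = 0L,
                                        delta = 0L, beta_immature = 3L)))
  scn <- generate_scene(p)
  expect_true(all(scn$truth$semantic_mask == 0L))
  expect_true(all(scn$truth$instance_mask == 0L))
  expect_gt(sum(scn$image != p$intensity[["cytoplasm"]]), 0)
  expect_equal(nrow(scn$truth$granules), 3L)
})

test_that("scene params round-trip through YAML", {
  p <- small_scene(seed = 9L, allow_touching = TRUE, noise_sd = 0.01)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_scene_params(p, path)
  q <- read_scene_params(path)
  expect_equal(unclass(q), unclass(p), tolerance = 1e-12)
  expect_identical(generate_scene(q)$image, generate_scene(p)$image)
})

test_that("invalid scene parameters are rejected", {
  expect_error(scene_params(intensity = c(core = 0.4, cytoplasm = 0.5, halo = 0.1)),
               "core > cytoplasm > halo")
  expect_error(scene_params(core_fraction = list(
    beta_mature = c(0.9, 0.95), alpha = c(0.86, 0.9),
    delta = c(1, 1), beta_immature = c(0.78, 0.94))),
    "beta_mature")
  expect_error(scene_params(texture_amplitude = 0.5), "texture_amplitude")
  # unplaceable request: too many big granules in a tiny image
  p <- small_scene(side = 128L,
                   counts = c(beta_mature = 40L, alpha = 0L, delta = 0L,
                              beta_immature = 0L))
  expect_error(sample_scene(p, max_tries = 50L), "could not place")
})

test_that("masks and images round-trip through disk formats", {
  scn <- generate_scene(small_scene(seed = 2L, side = 512L))
  dir <- withr::local_tempdir()
  paths <- write_scene(scn, dir)
  expect_true(all(file.exists(paths)))
  expect_identical(read_label_mask(paths[["semantic"]]),
                   scn$truth$semantic_mask)
  expect_identical(read_label_mask(paths[["instance"]]),
                   scn$truth$instance_mask)
  img <- read_micrograph(paths[["image"]])
  expect_equal(dim(img), dim(scn$image))
  expect_lt(max(abs(img - scn$image)), 1 / 65535)
  gt <- read.csv(paths[["granules"]])
  expect_equal(gt$core_area_px, scn$truth$granules$core_area_px)
})
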