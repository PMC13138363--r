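test_that("blank and constant tiles segment to all background", {
  p <- segmenter_params()
  const <- matrix(0.5, 128L, 128L)
  expect_true(all(segment_tile(const, p) == 0L))
  set.seed(1)
  noise <- matrix(0.45 + rnorm(128^2, 0, 0.03), 128L, 128L)
  stats <- list(core_thr = 0.67, halo_thr = 0.27)
  expect_true(all(segment_tile(noise, p, stats) == 0L))
})

test_that("single granules are segmented with the right class and high overlap", {
  p <- noiseless(small_scene(side = 256L))
  p$noise_sd <- 0.02  # mild noise; thresholds fixed at histogram midpoints
  sp <- segmenter_params(
    core_threshold = list(method = "fixed", value = 0.675),
    halo_threshold = list(method = "fixed", value = 0.275))
  cases <- list(
    list(g = one_granule(cx = 128, cy = 128, outer = 44, core = 26), code = 2L),
    list(g = one_granule(class = "alpha", cx = 128, cy = 128, outer = 31,
                         core = 27.5), code = 1L),
    list(g = one_granule(class = "delta", cx = 128, cy = 128, outer = 28,
                         core = 28), code = 3L))
  for (cs in cases) {
    scn <- render_scene(cs$g, p)
    mask <- segment_tile(scn$image, sp)
    expect_setequal(unique(as.vector(mask)), c(0L, cs$code))
    gt <- scn$truth$semantic_mask == semantic_code(cs$g$granule_class)
    pred <- mask == cs$code
    jacc <- sum(gt & pred) / sum(gt | pred)
    expect_gte(jacc, 0.8)
  }
})

test_that("whole-image segmentation recovers per-class component counts on default-style scenes", {
  hits <- 0L
  n_scenes <- 6L
  for (s in seq_len(n_scenes)) {
    p <- small_scene(seed = 100L + s, side = 1024L,
                     counts = c(beta_mature = 25L, alpha = 10L, delta = 6L,
                                beta_immature = 2L))
    scn <- generate_scene(p)
    sem <- segment_image(scn$image)
    ok <- TRUE
    for (code in 1:3) {
      det <- max(EBImage::bwlabel(EBImage::Image((sem == code) * 1)))
      gtc <- sum(semantic_code(scn$truth$granules$granule_class) == code)
      ok <- ok && det == gtc
    }
    hits <- hits + ok
  }
  expect_gte(hits, n_scenes - 1L)
})

test_that("labels stay in the four-class set and the segmenter is deterministic", {
  scn <- generate_scene(small_scene(seed = 21L, side = 512L))
  m1 <- segment_image(scn$image)
  m2 <- segment_image(scn$image)
  expect_identical(m1, m2)
  expect_true(all(m1 %in% 0:3))
})

test_that("global thresholds make segmentation insensitive to tile overlap away from borders", {
  p <- small_scene(seed = 31L, side = 1200L,
                   counts = c(beta_mature = 30L, alpha = 12L, delta = 8L,
                              beta_immature = 2L))
  scn <- generate_scene(p)
  m256 <- segment_image(scn$image, tile_shape = c(1024L, 512L), overlap = 256L)
  m128 <- segment_image(scn$image, tile_shape = c(1024L, 512L), overlap = 128L)
  mar <- 16L
  core <- (mar + 1):(1200L - mar)
  expect_identical(m256[core, core], m128[core, core])
})

test_that("dark-core polarity segments the inverted rendering identically", {
  p <- small_scene(seed = 41L, side = 512L)
  scn <- generate_scene(p)
  p_inv <- p; p_inv$invert <- TRUE
  scn_inv <- generate_scene(p_inv)
  m <- segment_image(scn$image, segmenter_params())
  m_inv <- segment_image(scn_inv$image, segmenter_params(polarity = "dark_core"))
  expect_identical(m, m_inv)
})

test_that("fixed thresholds are validated and degenerate halo histograms handled", {
  expect_error(segmenter_params(core_threshold = list(method = "fixed", value = 2)),
               "\\[0, 1\\]")
  expect_error(segmenter_params(core_threshold = list(method = "quantile")),
               "otsu_global")
  # image with cores but (almost) no sub-core spread: halo threshold falls back
  img <- matrix(0.2, 64L, 64L); img[20:30, 20:30] <- 0.9
  gs <- compute_global_stats(img, segmenter_params(smoothing_sigma = 0.3))
  expect_true(gs$halo_thr < gs$core_thr)
})

test_that("trainable backend satisfies the tile contract on scaled-down synthetic data", {
  skip_if_not_installed("nnet")
  mk <- function(seed) {
    p <- noiseless(small_scene(seed = seed, side = 64L,
                               counts = c(beta_mature = 1L, alpha = 0L,
                                          delta = 0L, beta_immature = 0L),
                               radius_nm = list(beta_mature = c(mean = 60, sd = 6),
                                                alpha = c(mean = 125, sd = 15),
                                                delta = c(mean = 110, sd = 12),
                                                beta_immature = c(mean = 165, sd = 20))))
    p$noise_sd <- 0.02
    generate_scene(p)
  }
  train <- lapply(1:8, mk)
  held <- mk(99L)
  bk <- train_backend(lapply(train, `[[`, "image"),
                      lapply(train, function(s) s$truth$semantic_mask),
                      epochs = 200L, seed = 1L)
  pred <- predict_backend(bk, held$image)
  expect_equal(dim(pred), dim(held$image))
  expect_true(all(pred %in% 0:3))
  acc <- mean((pred > 0) == (held$truth$semantic_mask > 0))
  expect_gt(acc, 0.9)
  # zero epochs: untrained handle still runs end-to-end
  bk0 <- train_backend(list(train[[1]]$image),
                       list(train[[1]]$truth$semantic_mask), epochs = 0L)
  m0 <- segment_image(held$image, segmenter = backend_segmenter(bk0))
  expect_true(all(m0 == 0L))
})
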