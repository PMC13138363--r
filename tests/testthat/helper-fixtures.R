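# Small, fast scene configurations and hand-built masks used across tests.

small_scene <- function(seed = 1L, side = 512L,
                        counts = c(beta_mature = 6L, alpha = 3L,
                                   delta = 2L, beta_immature = 1L), ...) {
  scene_params(image_shape = c(side, side), counts = counts, seed = seed, ...)
}

# binary disk mask builder (0-based centers), class code painted into matrix
disk_mask <- function(w, h, centers, radii, code = 2L) {
  m <- matrix(0L, w, h)
  xs <- matrix(0:(w - 1L), w, h)
  ys <- matrix(rep(0:(h - 1L), each = w), w, h)
  for (i in seq_len(nrow(centers))) {
    hit <- (xs - centers[i, 1])^2 + (ys - centers[i, 2])^2 <= radii[i]^2
    m[hit] <- code
  }
  m
}

# brute-force point-in-ellipse pixel enumeration over the full image grid:
# the independent oracle for rendered areas
oracle_ellipse_areas <- function(g, w, h) {
  xs <- matrix(0:(w - 1L), w, h)
  ys <- matrix(rep(0:(h - 1L), each = w), w, h)
  a <- g$outer_radius
  b <- a * sqrt(1 - g$eccentricity^2)
  ct <- cos(g$orientation); st <- sin(g$orientation)
  u <- (xs - g$center_x) * ct + (ys - g$center_y) * st
  v <- -(xs - g$center_x) * st + (ys - g$center_y) * ct
  q <- (u / a)^2 + (v / b)^2
  s <- (g$core_radius / g$outer_radius)^2
  c(core = sum(q <= s), halo = sum(q <= 1) - sum(q <= s))
}

# one-granule scene data.frame row
one_granule <- function(class = "beta_mature", cx = 100, cy = 100,
                        outer = 40, core = 24, ecc = 0, theta = 0) {
  data.frame(id = 1L, granule_class = class, center_x = cx, center_y = cy,
             outer_radius = outer, core_radius = core,
             eccentricity = ecc, orientation = theta,
             stringsAsFactors = FALSE)
}

noiseless <- function(p) {
  p$noise_sd <- 0
  p$texture_amplitude <- 0
  p
}
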