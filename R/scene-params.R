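#' Granule class codes used throughout the package
#'
#' Semantic masks use integer codes 0 = background, 1 = alpha, 2 = beta,
#' 3 = delta. Immature beta granules are rendered in images but annotated as
#' background in semantic ground truth (they carry no output class of their
#' own), mirroring four-channel granule annotation practice.
#'
#' @export
GRANULE_CLASSES <- c(background = 0L, alpha = 1L, beta = 2L, delta = 3L)

.granule_class_names <- c("alpha", "beta_mature", "beta_immature", "delta")

#' Semantic class code for a generator granule class
#' @param granule_class character vector of generator class names.
#' @return integer semantic codes (beta_immature maps to background).
#' @export
semantic_code <- function(granule_class) {
  unname(c(alpha = 1L, beta_mature = 2L, beta_immature = 0L, delta = 3L)[granule_class])
}

#' Scene parameters for the synthetic STEM islet generator
#'
#' Defines the study-like conditions emulated by [sample_scene()] and
#' [render_scene()]: image geometry at a physical scale of 4 nm per pixel,
#' per-class granule counts, class-specific size and core-fraction
#' distributions, rendering intensities and noise. Defaults describe a
#' 2048 x 2048 px islet section containing beta granules of ~350 nm diameter
#' with a dense core and wide electron-lucent halo, alpha granules with a thin
#' halo, delta granules without a halo, and a few immature beta granules
#' rendered at reduced contrast (dense-core condensation is what makes a
#' granule "mature"; immature granules are paler with an indistinct halo).
#'
#' @param image_shape integer c(width, height) in pixels.
#' @param nm_per_px physical scale, nanometres per pixel (default 4).
#' @param counts named integer vector of granules per class
#'   (`beta_mature`, `alpha`, `delta`, `beta_immature`).
#' @param radius_nm named list of c(mean, sd) outer-radius distributions in
#'   nm per class. The beta_mature default mean of 175 nm corresponds to a
#'   350 nm diameter.
#' @param core_fraction named list of c(lo, hi) uniform ranges for
#'   core_radius / outer_radius per class. Class invariants are enforced:
#'   alpha halo fraction <= 0.15, mature beta >= 0.25, immature beta in
#'   [0.05, 0.25), delta exactly 0 (core = outer).
#' @param eccentricity_range c(lo, hi) within [0, 0.6).
#' @param intensity named vector c(core, cytoplasm, halo) on [0, 1];
#'   must satisfy core > cytoplasm > halo (dense core bright, penetrable halo
#'   dark, intermediate cytoplasm).
#' @param immature_contrast named vector c(core, halo): intensity of immature
#'   beta core/halo expressed as a fraction of the core-cytoplasm contrast
#'   above cytoplasm. Defaults render immature granules visibly but at low
#'   contrast with indistinct core/halo separation.
#' @param invert render with inverted polarity (dark core / bright halo), for
#'   the opposite microscope contrast convention.
#' @param noise_sd additive Gaussian pixel noise sd.
#' @param texture_scale length scale (px) of the low-frequency background
#'   texture field.
#' @param texture_amplitude maximum texture excursion; capped at 30% of the
#'   core-halo contrast.
#' @param min_center_spacing minimum gap (px) between granule boundaries when
#'   `allow_touching = FALSE`.
#' @param allow_touching permit tangency / slight overlap (pairwise overlap
#'   bounded at roughly 10% of a granule's area).
#' @param islet_region optional polygon (matrix with columns x, y, 0-based px
#'   coordinates) delimiting the islet; granule centers are restricted to it
#'   and ground-truth islet area is computed from it.
#' @param seed integer seed; identical params + seed give bit-identical scenes.
#' @return object of class `scene_params`.
#' @export
scene_params <- function(image_shape = c(2048L, 2048L),
                         nm_per_px = 4,
                         counts = c(beta_mature = 70L, alpha = 30L,
                                    delta = 15L, beta_immature = 5L),
                         radius_nm = list(
                           beta_mature   = c(mean = 175, sd = 20),
                           alpha         = c(mean = 125, sd = 15),
                           delta         = c(mean = 110, sd = 12),
                           beta_immature = c(mean = 165, sd = 20)),
                         core_fraction = list(
                           beta_mature   = c(0.55, 0.70),
                           alpha         = c(0.86, 0.90),
                           delta         = c(1.00, 1.00),
                           beta_immature = c(0.78, 0.94)),
                         eccentricity_range = c(0, 0.4),
                         intensity = c(core = 0.9, cytoplasm = 0.45, halo = 0.1),
                         immature_contrast = c(core = 0.40, halo = 0.20),
                         invert = FALSE,
                         noise_sd = 0.03,
                         texture_scale = 40,
                         texture_amplitude = 0.08,
                         min_center_spacing = 8,
                         allow_touching = FALSE,
                         islet_region = NULL,
                         seed = 1L) {
  p <- list(image_shape = as.integer(image_shape), nm_per_px = nm_per_px,
            counts = counts, radius_nm = radius_nm,
            core_fraction = core_fraction,
            eccentricity_range = eccentricity_range, intensity = intensity,
            immature_contrast = immature_contrast, invert = invert,
            noise_sd = noise_sd, texture_scale = texture_scale,
            texture_amplitude = texture_amplitude,
            min_center_spacing = min_center_spacing,
            allow_touching = allow_touching, islet_region = islet_region,
            seed = as.integer(seed))
  class(p) <- "scene_params"
  validate_scene_params(p)
  p
}

#' Validate scene parameters
#' @param p a `scene_params` object.
#' @return `p`, invisibly, or an error.
#' @export
validate_scene_params <- function(p) {
  if (length(p$image_shape) != 2L || any(p$image_shape < 8L))
    stopf("image_shape must be c(width, height), each >= 8 px")
  if (!is_number(p$nm_per_px) || p$nm_per_px <= 0)
    stopf("nm_per_px must be a positive number")
  cls <- .granule_class_names
  if (!all(names(p$counts) %in% cls) || any(p$counts < 0))
    stopf("counts must be named by granule class and be >= 0")
  for (cl in names(p$counts)) {
    if (is.null(p$radius_nm[[cl]]) || is.null(p$core_fraction[[cl]]))
      stopf("missing radius_nm or core_fraction for class '%s'", cl)
  }
  it <- p$intensity
  if (!(it["core"] > it["cytoplasm"] && it["cytoplasm"] > it["halo"]))
    stopf("intensity must satisfy core > cytoplasm > halo")
  if (any(it < 0) || any(it > 1)) stopf("intensity levels must lie in [0, 1]")
  e <- p$eccentricity_range
  if (e[1] < 0 || e[2] >= 0.6) stopf("eccentricity range must lie in [0, 0.6)")
  contrast <- it["core"] - it["halo"]
  if (p$texture_amplitude > 0.3 * contrast)
    stopf("texture_amplitude must be <= 30%% of the core-halo contrast (%.3f)",
          0.3 * contrast)
  # class morphology invariants on halo fraction 1 - core_fraction
  chk <- function(cl, ok, msg) {
    f <- p$core_fraction[[cl]]
    if (!is.null(f) && !all(ok(1 - f))) stopf("core_fraction[%s]: %s", cl, msg)
  }
  chk("alpha", function(h) h <= 0.15 & h >= 0, "halo fraction must be <= 0.15")
  chk("beta_mature", function(h) h >= 0.25, "halo fraction must be >= 0.25")
  chk("beta_immature", function(h) h >= 0.05 & h < 0.25,
      "halo fraction must lie in [0.05, 0.25)")
  chk("delta", function(h) h == 0, "delta has no halo (core = outer)")
  if (!is.null(p$islet_region)) {
    ir <- p$islet_region
    if (!is.matrix(ir) || ncol(ir) != 2L || nrow(ir) < 3L)
      stopf("islet_region must be a polygon matrix with columns x, y")
  }
  invisible(p)
}

#' Write scene parameters to a YAML file
#' @param params `scene_params` object.
#' @param path output file path.
#' @export
write_scene_params <- function(params, path) {
  validate_scene_params(params)
  x <- unclass(params)
  x$counts <- as.list(x$counts)
  x$intensity <- as.list(x$intensity)
  x$immature_contrast <- as.list(x$immature_contrast)
  x$radius_nm <- lapply(x$radius_nm, as.list)
  if (!is.null(x$islet_region)) {
    x$islet_region <- list(x = x$islet_region[, 1], y = x$islet_region[, 2])
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read scene parameters from a YAML file
#' @param path YAML file written by [write_scene_params()].
#' @return a `scene_params` object.
#' @export
read_scene_params <- function(path) {
  x <- yaml::read_yaml(path)
  scene_params_from_list(x)
}

#' Build scene parameters from a plain list (e.g. parsed YAML)
#' @param x named list of overrides over the [scene_params()] defaults.
#' @return a `scene_params` object.
#' @export
scene_params_from_list <- function(x) {
  d <- formals(scene_params)
  args <- list()
  if (!is.null(x$image_shape)) args$image_shape <- unlist(x$image_shape)
  for (nm in c("nm_per_px", "invert", "noise_sd", "texture_scale",
               "texture_amplitude", "min_center_spacing", "allow_touching",
               "seed", "eccentricity_range")) {
    if (!is.null(x[[nm]])) args[[nm]] <- unlist(x[[nm]])
  }
  if (!is.null(x$counts)) {
    v <- unlist(x$counts); storage.mode(v) <- "integer"; args$counts <- v
  }
  for (nm in c("intensity", "immature_contrast")) {
    if (!is.null(x[[nm]])) args[[nm]] <- unlist(x[[nm]])
  }
  for (nm in c("radius_nm", "core_fraction")) {
    if (!is.null(x[[nm]])) args[[nm]] <- lapply(x[[nm]], unlist)
  }
  if (!is.null(x$islet_region)) {
    args$islet_region <- cbind(x = unlist(x$islet_region$x),
                               y = unlist(x$islet_region$y))
  }
  # partial overrides of list-valued params keep the remaining class defaults
  for (nm in c("radius_nm", "core_fraction")) {
    if (!is.null(args[[nm]])) {
      def <- eval(d[[nm]])
      def[names(args[[nm]])] <- args[[nm]]
      args[[nm]] <- def
    }
  }
  if (!is.null(args$counts)) {
    def <- eval(d$counts)
    def[names(args$counts)] <- args$counts
    args$counts <- def
  }
  do.call(scene_params, args)
}
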