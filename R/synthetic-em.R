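#' Sample a granule scene
#'
#' Draws a set of granules (class, center, outer/core radius, eccentricity,
#' orientation) satisfying the class morphology invariants and the placement
#' constraints of `params`. Placement is rejection sampling with bounded
#' retries; an error is raised if the requested counts cannot be placed.
#'
#' Granules are listed with all annotated classes (beta_mature, alpha, delta)
#' first and immature beta granules last, so annotated instance ids are
#' consecutive from 1.
#'
#' @param params a [scene_params()] object.
#' @param max_tries placement attempts per granule before giving up.
#' @return data.frame with one row per granule: `id`, `granule_class`,
#'   `center_x`, `center_y` (0-based px), `outer_radius`, `core_radius` (px),
#'   `eccentricity`, `orientation` (radians).
#' @export
sample_scene <- function(params, max_tries = 2000L) {
  validate_scene_params(params)
  with_local_seed(derive_seed(params$seed, 1L), {
    w <- params$image_shape[1]; h <- params$image_shape[2]
    order_cls <- c("beta_mature", "alpha", "delta", "beta_immature")
    order_cls <- order_cls[order_cls %in% names(params$counts)]
    rows <- list()
    cx <- numeric(0); cy <- numeric(0); rr <- numeric(0)
    for (cl in order_cls) {
      n <- params$counts[[cl]]
      if (n == 0) next
      rd <- params$radius_nm[[cl]]
      fr <- params$core_fraction[[cl]]
      for (i in seq_len(n)) {
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          r_px <- rnorm(1, rd[["mean"]], rd[["sd"]]) / params$nm_per_px
          if (r_px <= 2) next  # radii truncated at > 2 px
          x <- runif(1, r_px + 1, w - r_px - 2)
          y <- runif(1, r_px + 1, h - r_px - 2)
          if (x <= r_px || y <= r_px) next  # image smaller than granule
          if (!is.null(params$islet_region) &&
              !point_in_polygon(x, y, params$islet_region)) next
          if (length(cx)) {
            d <- sqrt((cx - x)^2 + (cy - y)^2)
            lim <- if (params$allow_touching) 0.8 * (rr + r_px)
                   else rr + r_px + params$min_center_spacing
            if (any(d < lim)) next
          }
          f <- runif(1, fr[1], fr[2])
          e <- runif(1, params$eccentricity_range[1], params$eccentricity_range[2])
          th <- runif(1, 0, pi)
          rows[[length(rows) + 1L]] <- data.frame(
            granule_class = cl, center_x = x, center_y = y,
            outer_radius = r_px, core_radius = f * r_px,
            eccentricity = e, orientation = th,
            stringsAsFactors = FALSE)
          cx <- c(cx, x); cy <- c(cy, y); rr <- c(rr, r_px)
          placed <- TRUE
          break
        }
        if (!placed)
          stopf("could not place %s granule %d within %d tries; reduce counts or spacing",
                cl, i, max_tries)
      }
    }
    scene <- if (length(rows)) do.call(rbind, rows) else
      data.frame(granule_class = character(0), center_x = numeric(0),
                 center_y = numeric(0), outer_radius = numeric(0),
                 core_radius = numeric(0), eccentricity = numeric(0),
                 orientation = numeric(0), stringsAsFactors = FALSE)
    scene <- cbind(id = seq_len(nrow(scene)), scene)
    attr(scene, "seed") <- params$seed
    scene
  })
}

point_in_polygon <- function(x, y, poly) {
  # even-odd rule
  n <- nrow(poly); inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > y) != (yj > y) &&
        x < (xj - xi) * (y - yi) / (yj - yi) + xi) inside <- !inside
    j <- i
  }
  inside
}

polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Rasterize one granule onto owner/part arrays
#'
#' @return list of integer index vectors `core`, `halo` (column-major pixel
#'   indices into the image matrix), restricted to the image.
#' @keywords internal
rasterize_granule <- function(g, w, h) {
  a <- g$outer_radius
  b <- a * sqrt(1 - g$eccentricity^2)
  x0 <- max(0L, floor(g$center_x - a)); x1 <- min(w - 1L, ceiling(g$center_x + a))
  y0 <- max(0L, floor(g$center_y - a)); y1 <- min(h - 1L, ceiling(g$center_y + a))
  if (x1 < x0 || y1 < y0) return(list(core = integer(0), halo = integer(0)))
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(xs - g$center_x, rep(1, length(ys)))
  dy <- outer(rep(1, length(xs)), ys - g$center_y)
  ct <- cos(g$orientation); st <- sin(g$orientation)
  u <- dx * ct + dy * st
  v <- -dx * st + dy * ct
  q <- (u / a)^2 + (v / b)^2
  s <- g$core_radius / g$outer_radius
  inside <- q <= 1
  core <- q <= s^2
  # column-major indices into w x h matrix indexed [x+1, y+1]
  ix <- outer(xs + 1L, rep(1L, length(ys)))
  iy <- outer(rep(1L, length(xs)), ys + 1L)
  lin <- ix + (iy - 1L) * w
  list(core = lin[core], halo = lin[inside & !core])
}

#' Render a granule scene into an image with full ground truth
#'
#' Paints granules in scene order (later granules win contested pixels, which
#' only arises under `allow_touching`), composes the background texture and
#' additive noise, and tabulates realized per-granule core/halo pixel areas
#' from the final label arrays so they equal rendered pixel counts exactly.
#' Granules extending past the image edge are clipped and their realized
#' areas reflect the clipping.
#'
#' @param scene data.frame from [sample_scene()] (or hand-built with the same
#'   columns).
#' @param params the [scene_params()] used for geometry, intensities and noise.
#' @return list of class `islet_scene` with elements:
#'   \describe{
#'     \item{image}{numeric matrix (width x height), intensities in [0, 1].}
#'     \item{truth}{list: `semantic_mask` (integer matrix, codes
#'       [GRANULE_CLASSES]), `instance_mask` (integer matrix, 0 background,
#'       annotated granules labeled consecutively from 1), `granules`
#'       (scene data.frame augmented with realized `core_area_px`,
#'       `halo_area_px`, `area_px`), `islet_area_px`.}
#'   }
#' @export
render_scene <- function(scene, params) {
  validate_scene_params(params)
  w <- params$image_shape[1]; h <- params$image_shape[2]
  owner <- matrix(0L, w, h)
  part <- matrix(0L, w, h)  # 1 = core, 2 = halo
  n <- nrow(scene)
  for (i in seq_len(n)) {
    px <- rasterize_granule(scene[i, ], w, h)
    owner[px$core] <- i; part[px$core] <- 1L
    owner[px$halo] <- i; part[px$halo] <- 2L
  }
  cls <- scene$granule_class
  annotated <- cls != "beta_immature"
  # realized areas from the final owner/part arrays
  core_area <- tabulate(owner[part == 1L], nbins = max(n, 1L))
  halo_area <- tabulate(owner[part == 2L], nbins = max(n, 1L))
  granules <- scene
  granules$core_area_px <- if (n) core_area[seq_len(n)] else integer(0)
  granules$halo_area_px <- if (n) halo_area[seq_len(n)] else integer(0)
  granules$area_px <- granules$core_area_px + granules$halo_area_px

  sem_code <- semantic_code(cls)
  semantic <- matrix(0L, w, h)
  nz <- owner > 0L
  semantic[nz] <- sem_code[owner[nz]]
  instance <- matrix(0L, w, h)
  if (n) {
    id_map <- integer(n)
    id_map[annotated] <- seq_len(sum(annotated))
    keep <- nz & annotated[pmax(owner, 1L)]
    instance[keep] <- id_map[owner[keep]]
  }

  it <- params$intensity
  img <- matrix(it[["cytoplasm"]], w, h)
  with_local_seed(derive_seed(params$seed, 2L), {
    if (params$texture_amplitude > 0 && params$texture_scale > 0) {
      # low-frequency field: smooth coarse noise, upsample (the field has no
      # energy above the coarse Nyquist, so this equals full-res smoothing)
      ds <- max(1L, min(8L, floor(params$texture_scale / 4)))
      cw <- ceiling(w / ds); ch <- ceiling(h / ds)
      field <- matrix(rnorm(cw * ch), cw, ch)
      field <- as.matrix(EBImage::gblur(EBImage::Image(field),
                                        sigma = params$texture_scale / ds))
      if (ds > 1L) {
        field <- as.matrix(EBImage::resize(EBImage::Image(field), w = w, h = h))
      }
      field <- field[seq_len(w), seq_len(h), drop = FALSE]
      s <- stats::sd(field)
      if (s > 0) field <- field * (params$texture_amplitude / 2 / s)
      field <- pmin(pmax(field, -params$texture_amplitude),
                    params$texture_amplitude)
      bg <- owner == 0L
      img[bg] <- img[bg] + field[bg]
    }
    mature_core <- part == 1L & nz & annotated[pmax(owner, 1L)]
    mature_halo <- part == 2L & nz & annotated[pmax(owner, 1L)]
    img[mature_core] <- it[["core"]]
    img[mature_halo] <- it[["halo"]]
    if (any(!annotated)) {
      contrast <- it[["core"]] - it[["cytoplasm"]]
      imm_core_lv <- it[["cytoplasm"]] + params$immature_contrast[["core"]] * contrast
      imm_halo_lv <- it[["cytoplasm"]] + params$immature_contrast[["halo"]] * contrast
      imm <- nz & !annotated[pmax(owner, 1L)]
      img[imm & part == 1L] <- imm_core_lv
      img[imm & part == 2L] <- imm_halo_lv
    }
    if (params$noise_sd > 0) {
      img <- img + matrix(rnorm(w * h, 0, params$noise_sd), w, h)
      img <- pmin(pmax(img, 0), 1)
    }
  })
  if (params$invert) img <- 1 - img

  islet_area_px <- if (!is.null(params$islet_region)) {
    as.integer(round(polygon_area(params$islet_region)))
  } else as.integer(w) * as.integer(h)

  out <- list(image = img,
              truth = list(semantic_mask = semantic, instance_mask = instance,
                           granules = granules, islet_area_px = islet_area_px))
  class(out) <- "islet_scene"
  out
}

#' Generate a complete synthetic scene (sample + render)
#' @inheritParams sample_scene
#' @return an `islet_scene` (see [render_scene()]).
#' @export
generate_scene <- function(params) {
  render_scene(sample_scene(params), params)
}

#' Write a rendered scene to disk
#'
#' Writes the image as 16-bit grayscale TIFF, the semantic mask as an indexed
#' PNG (codes 0-3), the instance mask as 16-bit TIFF, and the granule ground
#' truth as CSV.
#'
#' @param scene an `islet_scene` from [render_scene()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the named vector of written paths.
#' @export
write_scene <- function(scene, dir, prefix = "scene") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    image = file.path(dir, paste0(prefix, "_image.tiff")),
    semantic = file.path(dir, paste0(prefix, "_semantic.png")),
    instance = file.path(dir, paste0(prefix, "_instance.tiff")),
    granules = file.path(dir, paste0(prefix, "_granules.csv")))
  EBImage::writeImage(EBImage::Image(scene$image), paths["image"],
                      type = "tiff", bits.per.sample = 16L)
  write_label_mask(scene$truth$semantic_mask, paths["semantic"])
  write_label_mask(scene$truth$instance_mask, paths["instance"])
  g <- scene$truth$granules
  gt <- data.frame(id = g$id, class = g$granule_class,
                   center_x = g$center_x, center_y = g$center_y,
                   outer_radius_px = g$outer_radius,
                   core_radius_px = g$core_radius,
                   core_area_px = g$core_area_px,
                   halo_area_px = g$halo_area_px)
  utils::write.csv(gt, paths["granules"], row.names = FALSE)
  invisible(paths)
}

#' Write / read integer label masks as images
#'
#' Labels are stored as gray levels: 8-bit PNG (value = label / 255, for
#' small code ranges such as semantic masks) or 16-bit TIFF
#' (value = label / 65535, for instance labels). Both round-trip exactly
#' within their label capacity; the scale is chosen by file extension.
#'
#' @param mask integer matrix.
#' @param path output path ending in .png or .tif/.tiff.
#' @export
write_label_mask <- function(mask, path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (max(mask) > 255L) stopf("PNG label masks hold at most 255 labels; use TIFF")
    EBImage::writeImage(EBImage::Image(mask / 255), path, type = "png")
  } else {
    if (max(mask) > 65535L) stopf("more than 65535 labels cannot be stored")
    EBImage::writeImage(EBImage::Image(mask / 65535), path, type = "tiff",
                        bits.per.sample = 16L)
  }
  invisible(path)
}

#' @rdname write_label_mask
#' @return `read_label_mask`: the integer label matrix.
#' @export
read_label_mask <- function(path) {
  img <- EBImage::readImage(path)
  m <- EBImage::imageData(img)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  scale <- if (grepl("\\.png$", path, ignore.case = TRUE)) 255 else 65535
  m <- round(m * scale)
  storage.mode(m) <- "integer"
  m
}

#' Read a grayscale micrograph
#'
#' Reads an 8- or 16-bit grayscale TIFF/PNG into a numeric matrix with
#' intensities on [0, 1]. Multi-channel images are averaged to grayscale.
#'
#' @param path image path.
#' @return numeric matrix (width x height).
#' @export
read_micrograph <- function(path) {
  if (!file.exists(path)) stopf("image not found: %s", path)
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) == 3L) img <- EBImage::Image(apply(img, c(1, 2), mean))
  as.matrix(img)
}
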