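#' Decompose one granule into core and halo pixels
#'
#' The dense core and the electron-lucent halo are separated by an Otsu
#' threshold over the granule's own intensity histogram (local, so shading
#' across the acquisition cannot bias the decomposition). Core and halo
#' partition the granule pixel set exactly. Granules whose intensity spread is
#' below `low_contrast_eps` are assigned entirely to the core and flagged.
#'
#' @param image numeric matrix.
#' @param granule_pixels integer vector of (column-major) pixel indices of one
#'   granule; must be nonempty.
#' @param polarity "bright_core" or "dark_core".
#' @param low_contrast_eps minimum intensity spread for a bimodal split.
#' @return list(core, halo, low_contrast): index vectors partitioning
#'   `granule_pixels`, and a flag.
#' @export
decompose_core_halo <- function(image, granule_pixels,
                                polarity = c("bright_core", "dark_core"),
                                low_contrast_eps = 0.05) {
  polarity <- match.arg(polarity)
  if (!length(granule_pixels)) stopf("granule_pixels must be nonempty")
  vals <- image[granule_pixels]
  if (polarity == "dark_core") vals <- 1 - vals
  if (diff(range(vals)) < low_contrast_eps) {
    return(list(core = granule_pixels, halo = integer(0), low_contrast = TRUE))
  }
  thr <- otsu_vec(vals)
  core <- vals > thr
  list(core = granule_pixels[core], halo = granule_pixels[!core],
       low_contrast = FALSE)
}

#' Per-granule morphometric records
#'
#' Computes, for every labeled instance, its class, area, core/halo
#' decomposition, core-to-halo ratio and centroid. Delta granules have no halo
#' by class definition (halo area 0, ratio undefined). Core and halo areas sum
#' to the granule area exactly. The core-to-halo ratio is area-based
#' (core area / halo area) and is reported as `NA` with `ratio_undefined =
#' TRUE` when the halo is empty.
#'
#' @param image numeric matrix the instances were segmented from.
#' @param instances an `instance_mask` from [watershed_split()], or a plain
#'   integer label matrix plus `classes` data.frame.
#' @param nm_per_px physical scale (> 0).
#' @param polarity intensity polarity, see [decompose_core_halo()].
#' @return data.frame with one row per granule: `id`, `granule_class`,
#'   `area_px2`, `area_nm2`, `core_area_px2`, `halo_area_px2`,
#'   `core_to_halo_ratio`, `ratio_undefined`, `low_contrast`,
#'   `centroid_x`, `centroid_y` (0-based px).
#' @export
granule_features <- function(image, instances, nm_per_px = 4,
                             polarity = c("bright_core", "dark_core")) {
  polarity <- match.arg(polarity)
  if (!is_number(nm_per_px) || nm_per_px <= 0)
    stopf("nm_per_px must be a positive number")
  mask <- if (inherits(instances, "instance_mask")) instances$mask else instances
  classes <- if (inherits(instances, "instance_mask")) instances$classes
             else attr(instances, "classes")
  if (is.null(classes)) stopf("instances must carry an id-to-class table")
  if (!all(dim(mask) == dim(image)))
    stopf("instance mask and image shapes differ")
  nz <- which(mask > 0L)
  if (!length(nz)) {
    return(data.frame(id = integer(0), granule_class = character(0),
                      area_px2 = numeric(0), area_nm2 = numeric(0),
                      core_area_px2 = numeric(0), halo_area_px2 = numeric(0),
                      core_to_halo_ratio = numeric(0),
                      ratio_undefined = logical(0), low_contrast = logical(0),
                      centroid_x = numeric(0), centroid_y = numeric(0)))
  }
  w <- nrow(mask)
  by_id <- split(nz, mask[nz])
  ids <- as.integer(names(by_id))
  cls <- classes$class[match(ids, classes$id)]
  rows <- lapply(seq_along(ids), function(k) {
    px <- by_id[[k]]
    area <- length(px)
    if (identical(cls[k], "delta")) {
      core_a <- area; halo_a <- 0L; lowc <- FALSE
    } else {
      dec <- decompose_core_halo(image, px, polarity)
      core_a <- length(dec$core); halo_a <- length(dec$halo)
      lowc <- dec$low_contrast
    }
    xs <- ((px - 1L) %% w)          # 0-based x
    ys <- ((px - 1L) %/% w)         # 0-based y
    data.frame(id = ids[k], granule_class = cls[k],
               area_px2 = area, area_nm2 = area * nm_per_px^2,
               core_area_px2 = core_a, halo_area_px2 = halo_a,
               core_to_halo_ratio = if (halo_a > 0) core_a / halo_a else NA_real_,
               ratio_undefined = halo_a == 0L, low_contrast = lowc,
               centroid_x = mean(xs), centroid_y = mean(ys),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-islet aggregate morphometrics
#'
#' Aggregates granule records into the standard per-islet quantities: islet
#' area, per-class granule counts, beta-granule density per square micron,
#' beta-to-alpha and delta-to-beta granule count ratios, and mean beta granule
#' area / core area / halo area / core-to-halo ratio. Ratios with a zero
#' denominator are reported `NA` with the corresponding `*_undefined` flag;
#' an empty record set yields zero counts without error.
#'
#' @param records data.frame from [granule_features()].
#' @param islet_area_px2 islet area in px^2 (> 0); use a delineated islet
#'   region when available, else [islet_area_from_mask()].
#' @param nm_per_px physical scale.
#' @return one-row data.frame (an islet summary).
#' @export
islet_summary <- function(records, islet_area_px2, nm_per_px = 4) {
  if (!is_number(islet_area_px2) || islet_area_px2 <= 0)
    stopf("islet_area_px2 must be positive")
  nm2 <- nm_per_px^2
  islet_area_um2 <- islet_area_px2 * nm2 / 1e6
  n_cls <- function(cl) sum(records$granule_class == cl)
  na <- n_cls("alpha"); nb <- n_cls("beta"); nd <- n_cls("delta")
  b <- records[records$granule_class == "beta", , drop = FALSE]
  mean_or_na <- function(x) if (length(x)) mean(x, na.rm = TRUE) else NA_real_
  data.frame(
    islet_area_px2 = islet_area_px2,
    islet_area_um2 = islet_area_um2,
    n_alpha = na, n_beta = nb, n_delta = nd,
    beta_density_per_um2 = nb / islet_area_um2,
    beta_to_alpha_ratio = if (na > 0) nb / na else NA_real_,
    beta_to_alpha_undefined = na == 0L,
    delta_to_beta_ratio = if (nb > 0) nd / nb else NA_real_,
    delta_to_beta_undefined = nb == 0L,
    mean_beta_area_px2 = mean_or_na(b$area_px2),
    mean_beta_area_nm2 = mean_or_na(b$area_px2) * nm2,
    mean_beta_core_area_px2 = mean_or_na(b$core_area_px2),
    mean_beta_core_area_nm2 = mean_or_na(b$core_area_px2) * nm2,
    mean_beta_halo_area_px2 = mean_or_na(b$halo_area_px2),
    mean_beta_halo_area_nm2 = mean_or_na(b$halo_area_px2) * nm2,
    mean_beta_core_to_halo_ratio =
      mean_or_na(b$core_to_halo_ratio[!b$ratio_undefined]))
}

#' Islet area from granule pixels
#'
#' Default islet delineation when no region-of-interest polygon is provided:
#' area (px^2) of the convex hull of all granule pixels. The hull of pixel
#' centers is computed from per-row extremal pixels (shoelace formula), a
#' close approximation at granule scale.
#'
#' @param mask semantic or instance mask; nonzero pixels are granule pixels.
#' @return area in px^2 (0 when the mask is empty).
#' @export
islet_area_from_mask <- function(mask) {
  nz <- which(mask > 0L)
  if (!length(nz)) return(0)
  w <- nrow(mask)
  xs <- ((nz - 1L) %% w)
  ys <- ((nz - 1L) %/% w)
  pts <- do.call(rbind, lapply(split(xs, ys), function(v) {
    cbind(x = c(min(v), max(v)), y = NA)
  }))
  pts[, "y"] <- rep(as.integer(names(split(xs, ys))), each = 2L)
  hull <- grDevices::chull(pts)
  polygon_area(pts[hull, , drop = FALSE])
}
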