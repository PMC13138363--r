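#' Parameters for the reference granule segmenter
#'
#' The reference segmenter is a deterministic classical operator implementing
#' the class definitions directly: a granule is an electron-dense core with an
#' optional electron-lucent halo, and the class follows from halo thickness
#' (none = delta, thin = alpha, wide = beta). Thresholds are computed once per
#' image (`otsu_global`) and passed to every tile so the operator is
#' tile-position invariant; `fixed` thresholds may be supplied instead.
#'
#' @param smoothing_sigma Gaussian smoothing sigma (px) applied before
#'   thresholding.
#' @param core_threshold list(method = "otsu_global" | "fixed", value): pixels
#'   above it (after smoothing) are core candidates.
#' @param halo_threshold list(method, value): pixels below it are halo
#'   candidates. The `otsu_global` method thresholds the sub-core-threshold
#'   intensity histogram, separating halo from cytoplasm.
#' @param min_granule_area components smaller than this (px^2) are discarded;
#'   default is the area of a 100 nm-diameter disk at 4 nm/px.
#' @param halo_fraction_thin class boundary on the equivalent-radius halo
#'   fraction: components at or below it are alpha, above it beta.
#' @param halo_fraction_none components at or below this halo fraction are
#'   delta (numerically "no halo").
#' @param closing_radius morphological closing radius (px) applied to granule
#'   candidates.
#' @param grow_radius dilation radius (px) used to attach the surrounding halo
#'   annulus to its core.
#' @param polarity "bright_core" (dense core high intensity) or "dark_core";
#'   images are flipped internally for the latter.
#' @return object of class `segmenter_params`.
#' @export
segmenter_params <- function(smoothing_sigma = 1,
                             core_threshold = list(method = "otsu_global", value = NULL),
                             halo_threshold = list(method = "otsu_global", value = NULL),
                             min_granule_area = granule_min_area(4),
                             halo_fraction_thin = 0.20,
                             halo_fraction_none = 0.05,
                             closing_radius = 2L,
                             grow_radius = 2L,
                             polarity = c("bright_core", "dark_core")) {
  polarity <- match.arg(polarity)
  for (thr in list(core_threshold, halo_threshold)) {
    if (!thr$method %in% c("otsu_global", "fixed"))
      stopf("threshold method must be 'otsu_global' or 'fixed'")
    if (thr$method == "fixed" &&
        (!is_number(thr$value) || thr$value < 0 || thr$value > 1))
      stopf("fixed thresholds must lie in the [0, 1] intensity range")
  }
  if (!is_number(min_granule_area) || min_granule_area < 1)
    stopf("min_granule_area must be >= 1 px^2")
  p <- list(smoothing_sigma = smoothing_sigma, core_threshold = core_threshold,
            halo_threshold = halo_threshold,
            min_granule_area = min_granule_area,
            halo_fraction_thin = halo_fraction_thin,
            halo_fraction_none = halo_fraction_none,
            closing_radius = as.integer(closing_radius),
            grow_radius = as.integer(grow_radius), polarity = polarity)
  class(p) <- "segmenter_params"
  p
}

#' Default minimum granule area at a given physical scale
#'
#' Area (px^2) of a disk of `min_diameter_nm` at `nm_per_px`; structures
#' smaller than ~100 nm are sub-granule debris at STEM islet scale.
#'
#' @param nm_per_px physical scale.
#' @param min_diameter_nm smallest plausible granule diameter.
#' @export
granule_min_area <- function(nm_per_px, min_diameter_nm = 100) {
  pi * (min_diameter_nm / 2 / nm_per_px)^2
}

#' Compute whole-image threshold statistics
#'
#' Thresholds are derived from the full (smoothed) image so that tiles share
#' one contract and segmentation is invariant to tile placement: the core
#' threshold is the Otsu split of the whole intensity histogram (cytoplasm vs
#' dense cores) and the halo threshold is the Otsu split of the sub-core
#' histogram (electron-lucent halos vs cytoplasm).
#'
#' @param image numeric matrix, intensities in [0, 1].
#' @param params a [segmenter_params()].
#' @return list(core_thr, halo_thr).
#' @export
compute_global_stats <- function(image, params = segmenter_params()) {
  img <- if (params$polarity == "dark_core") 1 - image else image
  sm <- as.matrix(EBImage::gblur(EBImage::Image(img),
                                 sigma = params$smoothing_sigma))
  # two-stage Otsu: the first split isolates whichever minority mode (dense
  # cores above, or lucent halos below) is farther from the dominant
  # cytoplasm mode; the second split runs on the cytoplasm side. Deciding by
  # mass keeps the scheme valid whichever mode the first split peels off.
  v <- as.vector(sm)
  t1 <- otsu_vec(v)
  second <- function(x, fallback) {
    if (length(x) > 1L && diff(range(x)) > 1e-6) otsu_vec(x) else fallback
  }
  if (mean(v > t1) >= 0.5) {   # halos were split off below t1
    halo_thr0 <- t1
    core_thr0 <- second(v[v > t1], 2 * t1)
  } else {                     # cores were split off above t1
    core_thr0 <- t1
    halo_thr0 <- second(v[v < t1], t1 / 2)
  }
  core_thr <- if (params$core_threshold$method == "fixed")
    params$core_threshold$value else core_thr0
  halo_thr <- if (params$halo_threshold$method == "fixed")
    params$halo_threshold$value else halo_thr0
  list(core_thr = core_thr, halo_thr = halo_thr)
}

#' Segment one tile into a four-class semantic mask
#'
#' Reference algorithm: smooth; core mask = intensity above the core
#' threshold; halo mask = intensity below the halo threshold; halo components
#' are attached to cores by a bounded dilation; the candidate granule
#' (core plus attached halo) is morphologically closed and hole-filled; each
#' connected component is classified from its equivalent-radius halo fraction
#' `1 - sqrt(core_area / area)` (none = delta, thin = alpha, wide = beta);
#' components below `min_granule_area` are dropped. Degenerate (constant)
#' tiles yield an all-background mask.
#'
#' @param tile numeric matrix (a tile of the image).
#' @param params a [segmenter_params()].
#' @param global_stats thresholds from [compute_global_stats()] on the whole
#'   image, so the operator is tile-position invariant.
#' @return integer matrix of the tile's shape with codes [GRANULE_CLASSES].
#' @export
segment_tile <- function(tile, params = segmenter_params(),
                         global_stats = compute_global_stats(tile, params)) {
  out <- matrix(0L, nrow(tile), ncol(tile))
  if (diff(range(tile)) <= .Machine$double.eps) return(out)
  img <- if (params$polarity == "dark_core") 1 - tile else tile
  sm <- as.matrix(EBImage::gblur(EBImage::Image(img),
                                 sigma = params$smoothing_sigma))
  core <- sm > global_stats$core_thr
  if (!any(core)) return(out)
  halo <- sm < global_stats$halo_thr

  grown <- as.matrix(EBImage::dilate(
    EBImage::Image(core * 1),
    EBImage::makeBrush(2L * params$grow_radius + 1L, "disc"))) > 0
  halo_lab <- as.matrix(EBImage::bwlabel(EBImage::Image(halo * 1)))
  attached <- setdiff(unique(halo_lab[grown & halo]), 0)
  cand <- core | (halo & halo_lab %in% attached)
  dim(cand) <- dim(core)

  closed <- as.matrix(EBImage::closing(
    EBImage::Image(cand * 1),
    EBImage::makeBrush(2L * params$closing_radius + 1L, "disc"))) > 0
  filled <- as.matrix(EBImage::fillHull(EBImage::Image(closed * 1))) > 0
  comps <- as.matrix(EBImage::bwlabel(EBImage::Image(filled * 1)))
  ncomp <- max(comps)
  if (ncomp == 0) return(out)

  area <- tabulate(comps[comps > 0], nbins = ncomp)
  core_area <- tabulate(comps[comps > 0 & core], nbins = ncomp)
  halo_frac <- 1 - sqrt(pmin(core_area / pmax(area, 1), 1))
  cls <- ifelse(halo_frac <= params$halo_fraction_none, 3L,
                ifelse(halo_frac <= params$halo_fraction_thin, 1L, 2L))
  cls[area < params$min_granule_area] <- 0L
  cls[core_area == 0L] <- 0L
  nzc <- comps > 0
  out[nzc] <- cls[comps[nzc]]
  out
}

#' Segment a whole image via overlapping tiles
#'
#' Splits the image into overlapping tiles, segments each tile with the
#' per-image global thresholds, and reassembles tile masks into a full
#' semantic mask by center-crop priority.
#'
#' @param image numeric matrix (width x height), intensities in [0, 1].
#' @param params a [segmenter_params()].
#' @param tile_shape,overlap tiling geometry (see [make_tile_grid()]).
#' @param segmenter function(tile, params, global_stats) returning a
#'   tile-sized semantic mask; defaults to the reference [segment_tile()].
#'   A trained backend from [train_backend()] can be plugged in via
#'   [backend_segmenter()].
#' @return integer matrix of the image's shape with codes [GRANULE_CLASSES].
#' @export
segment_image <- function(image, params = segmenter_params(),
                          tile_shape = c(2024L, 1024L), overlap = 256L,
                          segmenter = segment_tile) {
  grid <- make_tile_grid(dim(image), tile_shape, overlap)
  stats <- compute_global_stats(image, params)
  masks <- lapply(seq_len(nrow(grid$offsets)), function(i) {
    segmenter(crop_tile(image, grid, i), params, stats)
  })
  reassemble(masks, grid)
}
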