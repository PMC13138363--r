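#' Split a semantic mask into labeled granule instances
#'
#' Runs a seeded watershed independently per granule class (the semantic
#' classes already partition the pixels, so per-class splitting prevents
#' cross-class merging): the Euclidean distance transform of the class
#' foreground is computed, seeds are placed at its local maxima with a
#' minimum separation (deterministic greedy selection ordered by decreasing
#' distance value, ties broken by lowest (row, column)), and labels are grown
#' from the seeds over the negated-distance topography within the class mask.
#' Every connected component retains at least one seed so no region is lost.
#' Components smaller than `min_area` are removed and ids renumbered
#' consecutively.
#'
#' @param mask integer semantic mask (codes [GRANULE_CLASSES]).
#' @param min_area smallest retained instance, px^2; default is the area of a
#'   100 nm-diameter disk at 4 nm/px (sub-granule debris rejection).
#' @param min_seed_distance minimum px distance between watershed seeds;
#'   default 0.6 x the expected beta-granule radius (350 nm diameter) at
#'   4 nm/px.
#' @return object of class `instance_mask`: list with `mask` (integer matrix,
#'   ids consecutive from 1, 0 = background) and `classes` (data.frame id,
#'   class code, class name).
#' @export
watershed_split <- function(mask, min_area = granule_min_area(4),
                            min_seed_distance = 0.6 * (350 / 2 / 4)) {
  w <- nrow(mask); h <- ncol(mask)
  out <- matrix(0L, w, h)
  cls_of <- integer(0)
  next_id <- 0L
  for (code in c(1L, 2L, 3L)) {
    bw <- mask == code
    if (!any(bw)) next
    lab <- split_class(bw, min_seed_distance)
    if (max(lab) == 0L) next
    areas <- tabulate(lab[lab > 0L], nbins = max(lab))
    keep <- which(areas >= min_area)
    if (!length(keep)) next
    remap <- integer(max(lab))
    remap[keep] <- next_id + seq_along(keep)
    nz <- lab > 0L
    out[nz] <- remap[lab[nz]]
    cls_of <- c(cls_of, rep(code, length(keep)))
    next_id <- next_id + length(keep)
  }
  classes <- data.frame(
    id = seq_len(next_id),
    class_code = cls_of,
    class = names(GRANULE_CLASSES)[match(cls_of, GRANULE_CLASSES)],
    stringsAsFactors = FALSE)
  structure(list(mask = out, classes = classes), class = "instance_mask")
}

# Seeded watershed of one binary class mask; returns integer label matrix.
split_class <- function(bw, min_seed_distance) {
  w <- nrow(bw); h <- ncol(bw)
  dimg <- EBImage::distmap(EBImage::Image(bw * 1))
  d <- as.matrix(dimg)
  # local maxima of the distance transform within a min_seed_distance window
  win <- max(3L, 2L * floor(min_seed_distance / 2) + 1L)
  dmax <- as.matrix(EBImage::dilate(dimg, EBImage::makeBrush(win, "box")))
  cand <- which(bw & d >= dmax - 1e-9)
  if (!length(cand)) return(matrix(0L, w, h))
  comp <- as.matrix(EBImage::bwlabel(EBImage::Image(bw * 1)))
  cx <- ((cand - 1L) %% w) + 1L          # column index in image = x
  cy <- ((cand - 1L) %/% w) + 1L         # row index = y
  # deterministic order: decreasing depth, then lowest (row, column)
  ord <- order(-d[cand], cy, cx)
  cand <- cand[ord]; cx <- cx[ord]; cy <- cy[ord]
  ccomp <- comp[cand]
  seeds <- matrix(0L, w, h)
  k <- 0L
  for (cid in unique(ccomp)) {
    sel <- which(ccomp == cid)
    ax <- numeric(0); ay <- numeric(0)
    for (j in sel) {
      if (length(ax)) {
        if (any((ax - cx[j])^2 + (ay - cy[j])^2 < min_seed_distance^2)) next
      }
      ax <- c(ax, cx[j]); ay <- c(ay, cy[j])
      k <- k + 1L
      seeds[cand[j]] <- k
    }
  }
  lab <- EBImage::propagate(dimg, EBImage::Image(seeds), mask = bw, lambda = 1e8)
  m <- as.matrix(lab)
  storage.mode(m) <- "integer"
  m
}

#' Write an instance mask to disk
#'
#' Label image as 16-bit TIFF plus an id-to-class CSV table.
#'
#' @param instances an `instance_mask` from [watershed_split()].
#' @param mask_path output TIFF path.
#' @param classes_path output CSV path (default: mask path with .csv).
#' @export
write_instance_mask <- function(instances, mask_path,
                                classes_path = sub("\\.tiff?$", ".csv", mask_path)) {
  write_label_mask(instances$mask, mask_path)
  utils::write.csv(instances$classes, classes_path, row.names = FALSE)
  invisible(c(mask = mask_path, classes = classes_path))
}
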