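#' Train a pluggable pixel-classification segmentation backend
#'
#' Optional trainable alternative to the reference segmenter, behind the same
#' tile contract: the returned handle segments a tile into the four semantic
#' classes. The bundled backend is a multinomial logistic pixel classifier on
#' multi-scale Gaussian intensity features (raw intensity plus smoothed
#' intensity at two scales): a single-hidden-layer network with softmax
#' output, fitted with `epochs` as the optimizer's iteration budget. The
#' hidden layer matters: granule pixels are bimodal in intensity (dense core
#' above, lucent halo below the cytoplasm level), which no linear classifier
#' can separate. It is intended for scaled-down synthetic training
#' demonstrations, not full-acquisition fine-tuning.
#'
#' With `epochs = 0` the handle performs no fitting and predicts background
#' everywhere, so a pipeline wired to an untrained backend still runs
#' end-to-end.
#'
#' @param images list of numeric matrices (annotated training images).
#' @param masks list of integer semantic masks aligned to `images`.
#' @param epochs optimizer iteration budget (>= 0).
#' @param learning_rate accepted for backend-API compatibility; the bundled
#'   quasi-Newton fit has no step-size parameter.
#' @param hidden hidden-layer width.
#' @param max_pixels training pixels subsampled per fit.
#' @param seed RNG seed for weight initialization and pixel subsampling.
#' @return object of class `segmentation_backend`.
#' @export
train_backend <- function(images, masks, epochs = 100L, learning_rate = 1e-4,
                          hidden = 8L, max_pixels = 50000L, seed = 1L) {
  if (!requireNamespace("nnet", quietly = TRUE))
    stopf(paste("the trainable backend requires the 'nnet' package;",
                "the reference segmenter (segment_tile) needs no backend"))
  if (!length(images) || length(images) != length(masks))
    stopf("need >= 1 annotated (image, mask) pair")
  for (i in seq_along(images)) {
    if (!all(dim(images[[i]]) == dim(masks[[i]])))
      stopf("image/mask %d shapes differ", i)
  }
  handle <- list(fit = NULL, epochs = as.integer(epochs),
                 learning_rate = learning_rate)
  if (epochs > 0L) {
    feats <- do.call(rbind, lapply(images, backend_features))
    y <- factor(unlist(lapply(masks, as.vector)), levels = 0:3)
    with_local_seed(seed, {
      idx <- sample.int(nrow(feats), min(max_pixels, nrow(feats)))
      yy <- droplevels(y[idx])
      if (nlevels(yy) >= 2L) {
        targets <- nnet::class.ind(yy)
        fit <- nnet::nnet(feats[idx, , drop = FALSE], targets,
                          size = as.integer(hidden), softmax = TRUE,
                          maxit = as.integer(epochs), trace = FALSE,
                          MaxNWts = 5000L)
        handle$fit <- fit
        handle$levels <- colnames(targets)
      } else {
        handle$constant <- as.integer(as.character(yy[1]))
      }
    })
  }
  class(handle) <- "segmentation_backend"
  handle
}

backend_features <- function(img) {
  i1 <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = 1))
  i3 <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = 3))
  cbind(raw = as.vector(img), s1 = as.vector(i1), s3 = as.vector(i3))
}

#' Segment a tile with a trained backend
#'
#' Same contract as [segment_tile()]: tile in, tile-sized four-class mask out.
#'
#' @param handle a `segmentation_backend` from [train_backend()].
#' @param tile numeric matrix.
#' @return integer semantic mask of the tile's shape.
#' @export
predict_backend <- function(handle, tile) {
  stopifnot(inherits(handle, "segmentation_backend"))
  if (!is.null(handle$constant))
    return(matrix(handle$constant, nrow(tile), ncol(tile)))
  if (is.null(handle$fit)) return(matrix(0L, nrow(tile), ncol(tile)))
  feats <- backend_features(tile)
  prob <- stats::predict(handle$fit, feats)
  pred <- handle$levels[max.col(prob, ties.method = "first")]
  matrix(as.integer(pred), nrow(tile), ncol(tile))
}

#' Adapt a backend to the `segment_image()` segmenter interface
#'
#' @param handle a `segmentation_backend`.
#' @return function(tile, params, global_stats) suitable for the `segmenter`
#'   argument of [segment_image()] (params and stats are ignored; the backend
#'   is self-contained).
#' @export
backend_segmenter <- function(handle) {
  force(handle)
  function(tile, params, global_stats) predict_backend(handle, tile)
}
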