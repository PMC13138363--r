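`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a locally seeded RNG
#'
#' Saves and restores the global RNG state so seeded package code never
#' perturbs the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

#' Derive a sub-seed from a master seed
#'
#' All pipeline randomness flows from one top-level seed; each stage draws
#' from a deterministic sub-seed so stages can be re-run independently.
#' Result stays inside the 32-bit signed integer range.
#'
#' @param seed master seed (integer).
#' @param k stage index (integer).
#' @return integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(seed, k) {
  s <- (as.double(seed) * 48271 + as.double(k) * 16807) %% 2147483646
  as.integer(s) + 1L
}

#' Otsu threshold of a numeric vector
#'
#' Thin wrapper packing the values into an [EBImage::Image] so EBImage's
#' histogram-based Otsu implementation can be reused for arbitrary pixel
#' subsets (whole-image, sub-threshold, or per-granule histograms).
#'
#' @param values numeric vector of intensities.
#' @param levels number of histogram bins.
#' @return threshold value.
#' @keywords internal
otsu_vec <- function(values, levels = 256L) {
  r <- range(values)
  if (diff(r) <= .Machine$double.eps) return(r[1])
  img <- EBImage::Image(matrix(values, ncol = 1L))
  EBImage::otsu(img, range = r, levels = levels)
}

#' Test that a value is a single finite number
#' @keywords internal
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
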