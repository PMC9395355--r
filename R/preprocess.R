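#' Gradient-based sharpness score
#'
#' Mean magnitude of the 2D finite-difference intensity gradient, the
#' quality measure used to tell sharp captures from blurred ones (blur
#' suppresses edges and hence the mean gradient). Multi-channel input is
#' converted to grayscale as the channel mean. Central differences are
#' used in the interior and one-sided differences at the borders, so the
#' score is translation invariant and defined on every pixel.
#'
#' @param image a numeric matrix or an `H x W x 3` array in `[0, 1]`.
#' @return scalar sharpness (`>= 0`).
#' @export
sharpness_score <- function(image) {
  if (length(dim(image)) == 3) {
    image <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  }
  assert_that(is.matrix(image), "image must be a matrix or H x W x 3 array")
  h <- nrow(image); w <- ncol(image)
  assert_that(h >= 2 && w >= 2,
              "gradient undefined: image must be at least 2 x 2")
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  if (w > 2) gx[, 2:(w - 1)] <- (image[, 3:w] - image[, 1:(w - 2)]) / 2
  gx[, 1] <- image[, 2] - image[, 1]
  gx[, w] <- image[, w] - image[, w - 1]
  if (h > 2) gy[2:(h - 1), ] <- (image[3:h, ] - image[1:(h - 2), ]) / 2
  gy[1, ] <- image[2, ] - image[1, ]
  gy[h, ] <- image[h, ] - image[h - 1, ]
  mean(sqrt(gx^2 + gy^2))
}

#' Image-quality gate for a dual-mode pair
#'
#' Mirrors the capture-time check used in the field: the white-light
#' image's sharpness must reach a threshold, otherwise the pair is
#' flagged for recapture (never silently dropped). An optional
#' no-reference scorer (see [niqe_score()]) can be plugged in; the
#' pass/fail decision is by sharpness alone.
#'
#' @param pair a [dual_mode_image()].
#' @param threshold minimum acceptable WLI sharpness (`>= 0`).
#' @param scorer optional function `(image_array) -> numeric` providing a
#'   no-reference quality score (lower is better), recorded as `niqe`.
#' @return an object of class `quality_score` with fields `sharpness`,
#'   `niqe`, `passed`, `threshold`.
#' @export
quality_gate <- function(pair, threshold = 0.005, scorer = NULL) {
  assert_that(inherits(pair, "dual_mode_image"),
              "pair must be a dual_mode_image")
  assert_that(threshold >= 0, "threshold must be >= 0")
  assert_that(all(dim(pair$wli)[1:2] == dim(pair$afi)[1:2]),
              "WLI/AFI shapes differ")
  s <- sharpness_score(pair$wli)
  q <- if (is.null(scorer)) NA_real_ else scorer(pair$wli)
  structure(list(sharpness = s, niqe = q, passed = s >= threshold,
                 threshold = threshold),
            class = "quality_score")
}

#' @export
print.quality_score <- function(x, ...) {
  cat(sprintf("<quality_score> sharpness %.4f (threshold %.4f) -> %s\n",
              x$sharpness, x$threshold,
              if (x$passed) "pass" else "recapture"))
  invisible(x)
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Per-tile adaptive equalization used to lift brightness and contrast of
#' the WLI channels before fusion. Delegates to `EBImage::clahe()`; the
#' clip limit is expressed as a fraction of tile pixels and converted to
#' EBImage's multiple-of-mean-bin-count parameterization
#' (`limit = clip_limit * bins`). Images whose sides are not multiples of
#' the tile count are padded by edge replication and cropped back.
#' Exactly constant input is returned unchanged (no contrast to
#' amplify). Output is clipped to `[0, 1]`. Idempotence is not promised.
#'
#' @param image single-channel numeric matrix in `[0, 1]`.
#' @param n_tiles tiles per side (default 8).
#' @param clip_limit histogram clip limit as a fraction of tile pixels
#'   (default 0.01).
#' @param bins histogram bins (default 256).
#' @return equalized matrix in `[0, 1]`, same size as the input.
#' @export
equalize <- function(image, n_tiles = 8, clip_limit = 0.01, bins = 256) {
  assert_that(is.matrix(image), "equalize expects a single-channel matrix")
  rng <- range(image)
  assert_that(rng[1] >= 0 && rng[2] <= 1, "intensities must lie in [0,1]")
  if (rng[1] == rng[2]) return(image)
  h <- nrow(image); w <- ncol(image)
  ph <- ceiling(h / n_tiles) * n_tiles
  pw <- ceiling(w / n_tiles) * n_tiles
  x <- image
  if (ph > h) x <- rbind(x, x[rep(h, ph - h), , drop = FALSE])
  if (pw > w) x <- cbind(x, x[, rep(w, pw - w), drop = FALSE])
  y <- EBImage::clahe(x, nx = n_tiles, ny = n_tiles, bins = bins,
                      limit = clip_limit * bins)
  clip01(y[seq_len(h), seq_len(w)])
}

#' Fuse a WLI/AFI pair into the three-channel classifier input
#'
#' Builds the combinatorial input tensor: channel 1 is the equalized WLI
#' green channel, channel 2 the equalized WLI red channel, and channel 3
#' the normalized AFI red/green ratio. The WLI blue channel is never
#' read — in the physical device a long-pass filter blocks the 405 nm
#' excitation light, leaving blue uninformative.
#'
#' Two ratio conventions are available:
#' * `"rplus"` (default): `r = R / (R + G + eps)`, bounded in `[0, 1]`
#'   without per-image statistics; an all-zero AFI gives 0, never NaN.
#' * `"rg"`: `r = R / (G + eps)` rescaled to `[0, 1]` by per-image
#'   min-max (a constant ratio maps to 0).
#'
#' Fluorescence loss depresses G inside the lesion, so the ratio rises
#' there under either convention — the contrast the classifier learns
#' from.
#'
#' @param pair a [dual_mode_image()] (assumed to have passed the quality
#'   gate).
#' @param ratio_mode `"rplus"` or `"rg"`.
#' @param eps ratio regularizer (default `1e-6`).
#' @param equalize_wli apply [equalize()] to the WLI channels (default
#'   `TRUE`); the AFI ratio is contrast-carrying already and is never
#'   equalized.
#' @param n_tiles,clip_limit CLAHE parameters passed to [equalize()].
#' @return an object of class `fused_image`: list with `channels`
#'   (`H x W x 3` array in `[0, 1]`) and `provenance`.
#' @export
fuse_channels <- function(pair, ratio_mode = c("rplus", "rg"), eps = 1e-6,
                          equalize_wli = TRUE, n_tiles = 8,
                          clip_limit = 0.01) {
  assert_that(inherits(pair, "dual_mode_image"),
              "pair must be a dual_mode_image")
  ratio_mode <- match.arg(ratio_mode)
  g <- pair$wli[, , 2]
  r <- pair$wli[, , 1]
  if (equalize_wli) {
    g <- equalize(g, n_tiles, clip_limit)
    r <- equalize(r, n_tiles, clip_limit)
  }
  ar <- pair$afi[, , 1]
  ag <- pair$afi[, , 2]
  ratio <- if (ratio_mode == "rplus") {
    ar / (ar + ag + eps)
  } else {
    raw <- ar / (ag + eps)
    rng <- range(raw)
    if (rng[2] > rng[1]) (raw - rng[1]) / (rng[2] - rng[1]) else raw * 0
  }
  ch <- array(c(g, r, clip01(ratio)), c(dim(g), 3))
  structure(list(channels = ch,
                 provenance = list(subject_id = pair$subject_id,
                                   lesion_id = pair$lesion_id,
                                   view = pair$view,
                                   ratio_mode = ratio_mode, eps = eps)),
            class = "fused_image")
}

#' Cache a fused tensor to disk with a JSON provenance sidecar
#'
#' The channel array is stored as a compressed serialized array
#' (`<name>.fused`) next to a JSON sidecar (`<name>.json`) recording the
#' provenance (subject, view, ratio mode and epsilon) so cached tensors
#' remain auditable without loading them.
#'
#' @param fused a [fuse_channels()] result.
#' @param path output path without extension.
#' @return invisibly, the two paths written.
#' @export
write_fused_cache <- function(fused, path) {
  assert_that(inherits(fused, "fused_image"), "fused must be a fused_image")
  data_path <- paste0(path, ".fused")
  saveRDS(fused$channels, data_path, compress = "gzip")
  jsonlite::write_json(fused$provenance, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(data_path, paste0(path, ".json")))
}

#' @rdname write_fused_cache
#' @export
read_fused_cache <- function(path) {
  ch <- readRDS(paste0(path, ".fused"))
  prov <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  structure(list(channels = ch, provenance = prov),
            class = "fused_image")
}

#' @export
print.fused_image <- function(x, ...) {
  d <- dim(x$channels)
  cat(sprintf("<fused_image> %dx%dx3 (ratio %s), subject %s\n", d[1], d[2],
              x$provenance$ratio_mode, x$provenance$subject_id))
  invisible(x)
}
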