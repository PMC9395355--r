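# No-reference image quality: a compact NIQE-style scorer built from
# mean-subtracted contrast-normalized (MSCN) coefficient statistics and a
# Mahalanobis-type distance to a multivariate Gaussian fitted on sharp
# images. The canonical NIQE numeric scale is not promised; the scorer is
# pluggable into quality_gate() wherever a "lower is better" quality
# number is wanted.

# MSCN coefficients of a grayscale matrix.
mscn_coefficients <- function(gray, sigma = 7 / 6, C = 1 / 255) {
  mu <- EBImage::gblur(gray, sigma = sigma)
  sig <- sqrt(pmax(EBImage::gblur(gray^2, sigma = sigma) - mu^2, 0))
  (gray - mu) / (sig + C)
}

# Feature vector: spread/shape of the MSCN field plus first-order
# statistics of horizontally and vertically adjacent coefficient products.
quality_features <- function(image) {
  if (length(dim(image)) == 3) {
    image <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  }
  m <- mscn_coefficients(image)
  h <- nrow(m); w <- ncol(m)
  ph <- m[, 1:(w - 1)] * m[, 2:w]
  pv <- m[1:(h - 1), ] * m[2:h, ]
  c(sd = sd(as.vector(m)),
    skew = e1071::skewness(as.vector(m)),
    kurt = e1071::kurtosis(as.vector(m)),
    h_mean = mean(ph), h_sd = sd(as.vector(ph)),
    v_mean = mean(pv), v_sd = sd(as.vector(pv)))
}

#' Fit the reference model for the no-reference quality scorer
#'
#' Fits a multivariate Gaussian (mean and regularized covariance) to MSCN
#' feature vectors of a bundle of pristine (sharp) images. Used as the
#' reference against which [niqe_score()] measures distance.
#'
#' @param images list of image arrays/matrices regarded as good quality.
#' @return list with `mu`, `cov` (class `quality_reference`).
#' @export
fit_quality_reference <- function(images) {
  assert_that(length(images) >= 3,
              "need at least 3 reference images to fit a covariance")
  f <- t(vapply(images, quality_features, numeric(7)))
  structure(list(mu = colMeans(f),
                 cov = cov(f) + diag(1e-8, ncol(f))),
            class = "quality_reference")
}

# Default reference: fitted once per session on synthetic sharp frames.
.quality_env <- new.env(parent = emptyenv())

default_quality_reference <- function() {
  if (is.null(.quality_env$ref)) {
    imgs <- lapply(1:12, function(i) {
      cls <- c("normal", "benign", "opmd", "oscc")[(i - 1) %% 4 + 1]
      spec <- default_phenotype(cls, 64, seed = 1000 + i,
                                noise_sd = 0.02, blur_sigma = 0)
      generate_image_pair(spec, seed = 2000 + i)$wli
    })
    .quality_env$ref <- fit_quality_reference(imgs)
  }
  .quality_env$ref
}

#' No-reference quality score (NIQE-style stand-in)
#'
#' Square-root Mahalanobis distance between the image's MSCN feature
#' vector and a reference Gaussian fitted on sharp images. Lower is
#' better. This is a simplified scorer sharing NIQE's construction
#' (MSCN statistics against a pristine-image model), not a reimplementation
#' of the canonical NIQE scale.
#'
#' @param image an image array or matrix in `[0, 1]`.
#' @param reference a [fit_quality_reference()] model; defaults to one
#'   fitted on bundled synthetic sharp frames.
#' @return scalar score (`>= 0`, lower is better).
#' @export
niqe_score <- function(image, reference = NULL) {
  if (is.null(reference)) reference <- default_quality_reference()
  assert_that(inherits(reference, "quality_reference"),
              "reference must come from fit_quality_reference()")
  f <- quality_features(image)
  sqrt(mahalanobis(matrix(f, 1), reference$mu, reference$cov))
}
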