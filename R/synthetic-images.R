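#' Lesion phenotype specification
#'
#' Describes how one subject's lesion (if any) renders in the paired
#' white-light (WLI) and autofluorescence (AFI) images. Suspicious disease
#' (OPMD, OSCC) typically presents as a white or white-red mucosal patch
#' under white light and as loss of green autofluorescence, sometimes with
#' red porphyrin gain, under 405 nm excitation; benign lesions retain
#' normal fluorescence.
#'
#' @param class_label one of `"normal"`, `"benign"`, `"opmd"`, `"oscc"`.
#' @param lesion_shape `NULL` for no lesion, otherwise a list with fields
#'   `cx`, `cy` (center, pixels), `a`, `b` (semi-axes, pixels) and `theta`
#'   (rotation, radians).
#' @param wli_patch_color length-3 mean RGB of the lesion patch in WLI,
#'   values in `[0, 1]`.
#' @param afi_fluorescence_mode one of `"normal"`, `"loss"`, `"gain"`:
#'   behaviour of the lesion region under autofluorescence.
#' @param loss_depth for mode `"loss"`, the fraction of green signal
#'   removed inside the lesion, in `[0, 1]` (default 0.5). Severity is
#'   graded in real tissue: deep loss in carcinoma, intermediate in
#'   dysplasia, and mild loss in some inflamed benign lesions — the
#'   classic AFI confounder.
#' @param noise_sd per-channel Gaussian pixel noise sd (intensity units,
#'   `>= 0`).
#' @param blur_sigma Gaussian blur radius in pixels (`>= 0`).
#' @return an object of class `phenotype_spec`.
#' @seealso [default_phenotype()], [generate_image_pair()]
#' @export
phenotype_spec <- function(class_label,
                           lesion_shape = NULL,
                           wli_patch_color = c(0.92, 0.88, 0.80),
                           afi_fluorescence_mode = c("normal", "loss", "gain"),
                           loss_depth = 0.5,
                           noise_sd = 0.02,
                           blur_sigma = 0.8) {
  class_label <- match.arg(class_label, c("normal", "benign", "opmd", "oscc"))
  afi_fluorescence_mode <- match.arg(afi_fluorescence_mode)
  assert_that(loss_depth >= 0 && loss_depth <= 1,
              "loss_depth must lie in [0,1]")
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  assert_that(blur_sigma >= 0, "blur_sigma must be >= 0")
  if (!is.null(lesion_shape)) {
    assert_that(all(c("cx", "cy", "a", "b") %in% names(lesion_shape)),
                "lesion_shape needs fields cx, cy, a, b (and optional theta)")
    if (is.null(lesion_shape$theta)) lesion_shape$theta <- 0
    assert_that(lesion_shape$a > 0 && lesion_shape$b > 0,
                "lesion semi-axes must be positive")
  }
  assert_that(length(wli_patch_color) == 3 &&
                all(wli_patch_color >= 0 & wli_patch_color <= 1),
              "wli_patch_color must be 3 RGB values in [0,1]")
  structure(
    list(class_label = class_label, lesion_shape = lesion_shape,
         wli_patch_color = wli_patch_color,
         afi_fluorescence_mode = afi_fluorescence_mode,
         loss_depth = loss_depth,
         noise_sd = noise_sd, blur_sigma = blur_sigma),
    class = "phenotype_spec")
}

#' Default phenotype for a diagnostic class
#'
#' Maps the four-way class taxonomy onto rendering defaults: `normal` has
#' no lesion; `benign` has a pale patch, usually with retained (normal)
#' fluorescence; `opmd` a white patch with fluorescence loss; `oscc` a
#' red-white patch with deeper fluorescence loss. Lesion geometry and
#' the fluorescence-loss depth are sampled from the seed.
#'
#' Loss depth is graded, mirroring real autofluorescence biology:
#' carcinoma draws depth from U(0.35, 0.7), dysplastic OPMD from
#' U(0.2, 0.6), and 30 percent of benign lesions are "inflamed" with a
#' mild loss from U(0.05, 0.45). The overlap between mild dysplasia and
#' inflamed benign tissue is deliberate — it reproduces the classic AFI
#' false-positive source and gives the classification task an
#' irreducible error floor, so a trained model operates in the
#' imperfect-accuracy regime where uncertainty-based referral matters.
#'
#' @param class_label diagnostic class (see [phenotype_spec()]).
#' @param image_size image side in pixels.
#' @param seed integer seed for the sampled geometry and severity.
#' @param noise_sd,blur_sigma passed to [phenotype_spec()].
#' @return a `phenotype_spec`.
#' @export
default_phenotype <- function(class_label, image_size = 64, seed = 1,
                              noise_sd = 0.02, blur_sigma = 0.8) {
  class_label <- match.arg(class_label, c("normal", "benign", "opmd", "oscc"))
  if (class_label == "normal") {
    return(phenotype_spec("normal", NULL, noise_sd = noise_sd,
                          blur_sigma = blur_sigma))
  }
  drawn <- withr::with_seed(seed, {
    a <- runif(1, image_size / 8, image_size / 4)
    b <- runif(1, image_size / 10, image_size / 5)
    r <- max(a, b)
    shape <- list(cx = runif(1, r + 2, image_size - r - 1),
                  cy = runif(1, r + 2, image_size - r - 1),
                  a = a, b = b, theta = runif(1, 0, pi))
    depth <- switch(class_label,
                    oscc = runif(1, 0.35, 0.7),
                    opmd = runif(1, 0.25, 0.6),
                    benign = if (runif(1) < 0.2) runif(1, 0.05, 0.35) else 0)
    # A minority of neoplastic lesions present atypically: a flat,
    # benign-looking (non-keratotic) patch whose only autofluorescence
    # sign is moderate red porphyrin gain rather than green loss — a
    # recognized but uncommon presentation. Such cases are thinly
    # covered in any training set, which makes them both error-prone
    # and exactly where Monte-Carlo-dropout uncertainty concentrates.
    gain <- switch(class_label,
                   oscc = runif(1) < 0.08,
                   opmd = runif(1) < 0.05,
                   FALSE)
    # Patch colour is a second, partially overlapping cue: benign
    # lesions trend pinker (higher green), dysplastic patches trend
    # keratotic white-red (lower green); the distributions overlap so
    # neither colour nor fluorescence alone settles a borderline case.
    # Atypical gain-mode lesions take the benign colour range.
    col <- if (isTRUE(gain)) {
      c(runif(1, 0.86, 0.96), runif(1, 0.88, 0.96), 0.86)
    } else {
      switch(class_label,
             benign = c(runif(1, 0.86, 0.96), runif(1, 0.88, 0.96),
                        0.86),
             opmd   = c(runif(1, 0.90, 0.98), runif(1, 0.82, 0.92),
                        0.80),
             oscc   = c(runif(1, 0.78, 0.88), runif(1, 0.40, 0.52),
                        0.42))
    }
    list(shape = shape, depth = depth, col = col, gain = gain)
  })
  mode <- if (drawn$gain) "gain" else if (drawn$depth > 0) "loss" else
    "normal"
  phenotype_spec(class_label, drawn$shape, drawn$col, mode,
                 loss_depth = if (drawn$gain) 0 else drawn$depth,
                 noise_sd = noise_sd, blur_sigma = blur_sigma)
}

#' Dual-mode image pair container
#'
#' @param wli,afi `H x W x 3` arrays of intensities in `[0, 1]`, same
#'   spatial size.
#' @param view `"phone"` (wide field of view) or `"probe"` (focused).
#' @param subject_id,lesion_id identifiers carried as metadata.
#' @return an object of class `dual_mode_image`.
#' @export
dual_mode_image <- function(wli, afi, view = c("probe", "phone"),
                            subject_id = NA_character_,
                            lesion_id = NA_character_) {
  view <- match.arg(view)
  assert_that(length(dim(wli)) == 3 && dim(wli)[3] == 3,
              "wli must be an H x W x 3 array")
  assert_that(length(dim(afi)) == 3 && dim(afi)[3] == 3,
              "afi must be an H x W x 3 array")
  assert_that(all(dim(wli)[1:2] == dim(afi)[1:2]),
              "wli and afi must share the same H x W")
  rng <- range(wli, afi)
  assert_that(rng[1] >= 0 && rng[2] <= 1, "intensities must lie in [0,1]")
  structure(list(wli = wli, afi = afi, view = view,
                 subject_id = subject_id, lesion_id = lesion_id),
            class = "dual_mode_image")
}

#' @export
print.dual_mode_image <- function(x, ...) {
  d <- dim(x$wli)
  cat(sprintf("<dual_mode_image> %dx%d %s view, subject %s\n",
              d[1], d[2], x$view, x$subject_id))
  invisible(x)
}

# Low-frequency background texture: a coarse uniform grid bilinearly
# upsampled to the image size. Values in [-1, 1].
perlin_field <- function(h, w, cell = 8) {
  gh <- ceiling(h / cell) + 1L
  gw <- ceiling(w / cell) + 1L
  g <- matrix(runif(gh * gw, -1, 1), gh, gw)
  ys <- (seq_len(h) - 1) / cell
  xs <- (seq_len(w) - 1) / cell
  y0 <- pmin(floor(ys), gh - 2L); fy <- ys - y0
  x0 <- pmin(floor(xs), gw - 2L); fx <- xs - x0
  # smoothstep easing for a softer field
  fy <- fy * fy * (3 - 2 * fy); fx <- fx * fx * (3 - 2 * fx)
  a <- g[cbind(rep(y0 + 1L, w), rep(x0 + 1L, each = h))]
  b <- g[cbind(rep(y0 + 1L, w), rep(x0 + 2L, each = h))]
  cc <- g[cbind(rep(y0 + 2L, w), rep(x0 + 1L, each = h))]
  d <- g[cbind(rep(y0 + 2L, w), rep(x0 + 2L, each = h))]
  wy <- rep(fy, w); wx <- rep(fx, each = h)
  matrix((a * (1 - wx) + b * wx) * (1 - wy) + (cc * (1 - wx) + d * wx) * wy,
         h, w)
}

# Elliptical lesion mask (logical H x W).
ellipse_mask <- function(h, w, shape) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  ct <- cos(shape$theta); st <- sin(shape$theta)
  dx <- xx - shape$cx; dy <- yy - shape$cy
  u <- (dx * ct + dy * st) / shape$a
  v <- (-dx * st + dy * ct) / shape$b
  u * u + v * v <= 1
}

#' Generate one paired WLI/AFI image
#'
#' Renders a synthetic dual-mode view of oral mucosa: the white-light
#' image has a pinkish tissue background with the lesion patch coloured
#' per the phenotype; the autofluorescence image has a green-dominant
#' background where fluorescence `"loss"` removes a `loss_depth`
#' fraction (default one half) of the green signal inside the lesion and
#' `"gain"` adds red (porphyrin-like) signal. Backgrounds
#' carry a low-frequency texture plus per-pixel Gaussian noise; optional
#' Gaussian blur emulates focus.
#'
#' The synthesis reads only the phenotype — never any rater decision — so
#' no label information can leak into the pixels beyond the phenotype
#' itself.
#'
#' @param spec a [phenotype_spec()].
#' @param seed integer seed; the pair is bit-identical for a fixed
#'   `(spec, seed, image_size)`.
#' @param image_size image side in pixels (default 64).
#' @param view,subject_id,lesion_id metadata for the returned pair.
#' @return a [dual_mode_image()].
#' @export
generate_image_pair <- function(spec, seed = 1, image_size = 64,
                                view = "probe",
                                subject_id = NA_character_,
                                lesion_id = NA_character_) {
  assert_that(inherits(spec, "phenotype_spec"), "spec must be a phenotype_spec")
  h <- w <- as.integer(image_size)
  shape <- spec$lesion_shape
  if (!is.null(shape)) {
    r <- max(shape$a, shape$b)
    if (shape$cx - r < 1 || shape$cx + r > w ||
        shape$cy - r < 1 || shape$cy + r > h) {
      stop("lesion geometry does not fit inside the image frame",
           call. = FALSE)
    }
  }
  res <- withr::with_seed(seed, {
    field <- perlin_field(h, w, cell = max(4L, h %/% 8L))
    wli_base <- c(0.78, 0.55, 0.52)   # pinkish mucosa
    afi_base <- c(0.10, 0.62, 0.10)   # green-dominant fluorescence
    wli <- array(0, c(h, w, 3)); afi <- array(0, c(h, w, 3))
    famp <- 0.05
    for (k in 1:3) {
      wli[, , k] <- wli_base[k] + famp * field
      afi[, , k] <- afi_base[k] + famp * field * (if (k == 2) 1 else 0.4)
    }
    if (!is.null(shape)) {
      mask <- ellipse_mask(h, w, shape)
      for (k in 1:3) {
        ch <- wli[, , k]
        ch[mask] <- spec$wli_patch_color[k] + 0.03 * field[mask]
        wli[, , k] <- ch
      }
      if (spec$afi_fluorescence_mode == "loss") {
        g <- afi[, , 2]
        g[mask] <- g[mask] * (1 - spec$loss_depth)
        afi[, , 2] <- g
      } else if (spec$afi_fluorescence_mode == "gain") {
        rch <- afi[, , 1]; rch[mask] <- rch[mask] + 0.25; afi[, , 1] <- rch
      }
    }
    if (spec$blur_sigma > 0) {
      for (k in 1:3) {
        wli[, , k] <- EBImage::gblur(wli[, , k], sigma = spec$blur_sigma)
        afi[, , k] <- EBImage::gblur(afi[, , k], sigma = spec$blur_sigma)
      }
    }
    if (spec$noise_sd > 0) {
      wli <- wli + array(rnorm(length(wli), sd = spec$noise_sd), dim(wli))
      afi <- afi + array(rnorm(length(afi), sd = spec$noise_sd), dim(afi))
    }
    list(wli = clip01(wli), afi = clip01(afi))
  })
  dual_mode_image(res$wli, res$afi, view = view,
                  subject_id = subject_id, lesion_id = lesion_id)
}

#' Write / read an image pair as 8-bit PNG files
#'
#' Files are named `<subject>_<view>_wli.png` and `<subject>_<view>_afi.png`.
#'
#' @param pair a [dual_mode_image()].
#' @param dir output directory (created if absent).
#' @return invisibly, the two file paths.
#' @export
write_image_pair <- function(pair, dir) {
  assert_that(inherits(pair, "dual_mode_image"), "pair must be a dual_mode_image")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sid <- if (is.na(pair$subject_id)) "subject" else pair$subject_id
  paths <- file.path(dir, sprintf("%s_%s_%s.png", sid, pair$view,
                                  c("wli", "afi")))
  png::writePNG(pair$wli, paths[1])
  png::writePNG(pair$afi, paths[2])
  invisible(paths)
}

#' @rdname write_image_pair
#' @param subject_id,view identify the pair to read back.
#' @export
read_image_pair <- function(dir, subject_id, view = "probe") {
  paths <- file.path(dir, sprintf("%s_%s_%s.png", subject_id, view,
                                  c("wli", "afi")))
  assert_that(all(file.exists(paths)),
              paste("missing image files for subject", subject_id))
  dual_mode_image(png::readPNG(paths[1]), png::readPNG(paths[2]),
                  view = view, subject_id = subject_id)
}
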