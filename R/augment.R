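# Bounding-box-consistent geometric augmentation (flips, 90-degree
# rotations) and a photometric subset (brightness/contrast, gamma,
# multiplicative noise, blur/sharpen, downscale).
#
# Images are numeric H x W matrices or H x W x C arrays with 8-bit channel
# values in [0, 255]; rows index y (downward), columns x (rightward).
# rot90 is counterclockwise, mapping points (x, y) -> (y, W - x);
# rot270 = rot90 applied three times. Only these exact rotations are
# supported: arbitrary angles would require padding that introduces
# artificial borders absent from real slides.

GEOM_TRANSFORMS <- c("hflip", "vflip", "rot90", "rot180", "rot270")

#' Augmentation plan
#'
#' Per-operation probabilities and parameter ranges for
#' [generateVariants()]. Defaults: brightness/contrast +-20% (p = 0.7),
#' gamma in \[0.8, 1.2\] (p = 0.4), multiplicative noise in \[0.9, 1.1\]
#' (p = 0.3), one of blur or sharpen (p = 0.6), downscale to 0.75-0.95
#' (p = 0.2), horizontal and vertical flips (p = 0.5 each) and a random
#' 90-degree-multiple rotation (p = 0.5).
#'
#' @param brightness_contrast,gamma,mult_noise,blur_sharpen,downscale
#'   lists with a probability `p` and parameter ranges.
#' @param hflip,vflip,rot90 probabilities of the geometric ops.
#' @return a list of class `"AugmentationPlan"`.
#' @export
augmentationPlan <- function(
    brightness_contrast = list(p = 0.7, alpha = c(0.8, 1.2), beta = c(-51, 51)),
    gamma = list(p = 0.4, range = c(0.8, 1.2)),
    mult_noise = list(p = 0.3, range = c(0.9, 1.1), per_pixel = TRUE),
    blur_sharpen = list(p = 0.6, sigma = c(0.5, 1.5)),
    downscale = list(p = 0.2, range = c(0.75, 0.95)),
    hflip = 0.5, vflip = 0.5, rot90 = 0.5) {
  plan <- list(brightness_contrast = brightness_contrast, gamma = gamma,
               mult_noise = mult_noise, blur_sharpen = blur_sharpen,
               downscale = downscale, hflip = hflip, vflip = vflip,
               rot90 = rot90)
  probs <- c(brightness_contrast$p, gamma$p, mult_noise$p, blur_sharpen$p,
             downscale$p, hflip, vflip, rot90)
  if (any(probs < 0) || any(probs > 1))
    stop("augmentationPlan: probabilities must lie in [0, 1]")
  structure(plan, class = "AugmentationPlan")
}

#' A plan with all probabilities zero (identity variants)
#' @return an `AugmentationPlan` that never applies any operation.
#' @export
nullAugmentationPlan <- function() {
  augmentationPlan(
    brightness_contrast = list(p = 0, alpha = c(1, 1), beta = c(0, 0)),
    gamma = list(p = 0, range = c(1, 1)),
    mult_noise = list(p = 0, range = c(1, 1), per_pixel = TRUE),
    blur_sharpen = list(p = 0, sigma = c(1, 1)),
    downscale = list(p = 0, range = c(1, 1)),
    hflip = 0, vflip = 0, rot90 = 0)
}

perChannel <- function(image, f) {
  if (length(dim(image)) == 3) {
    out <- image
    for (ch in seq_len(dim(image)[3])) out[, , ch] <- f(image[, , ch])
    out
  } else f(image)
}

rot90ccwRaster <- function(image) {
  perm <- function(m) {
    tm <- t(m)
    tm[rev(seq_len(nrow(tm))), , drop = FALSE]
  }
  if (length(dim(image)) == 3) {
    out <- array(0, dim = c(dim(image)[2], dim(image)[1], dim(image)[3]))
    for (ch in seq_len(dim(image)[3])) out[, , ch] <- perm(image[, , ch])
    out
  } else perm(image)
}

mapBoxes <- function(b, W, H, transform) {
  switch(transform,
    hflip = cbind(xmin = W - b[, "xmax"], ymin = b[, "ymin"],
                  xmax = W - b[, "xmin"], ymax = b[, "ymax"]),
    vflip = cbind(xmin = b[, "xmin"], ymin = H - b[, "ymax"],
                  xmax = b[, "xmax"], ymax = H - b[, "ymin"]),
    # (x, y) -> (y, W - x); tight box of the mapped corners
    rot90 = cbind(xmin = b[, "ymin"], ymin = W - b[, "xmax"],
                  xmax = b[, "ymax"], ymax = W - b[, "xmin"]),
    stop("unknown transform"))
}

#' Apply a geometric transform to an image and its annotations
#'
#' Every output box is the tight axis-aligned image of the input box under
#' the point map; no padding pixels are introduced. `rot90`/`rot270` swap
#' the output dimensions.
#'
#' @param image H x W matrix or H x W x C array.
#' @param annotations a [DetectionSet-class] in the image's pixel frame.
#' @param transform one of `"hflip"`, `"vflip"`, `"rot90"`, `"rot180"`,
#'   `"rot270"` (rot90 counterclockwise).
#' @return `list(image =, annotations =)`.
#' @export
applyGeometric <- function(image, annotations, transform) {
  if (!transform %in% GEOM_TRANSFORMS)
    stop(sprintf("applyGeometric: unknown transform '%s'", transform))
  steps <- switch(transform,
    hflip = "hflip", vflip = "vflip",
    rot90 = "rot90", rot180 = c("rot90", "rot90"),
    rot270 = c("rot90", "rot90", "rot90"))
  img <- image
  b <- boxes(annotations)
  for (s in steps) {
    H <- dim(img)[1]; W <- dim(img)[2]
    if (nrow(b) > 0 &&
        (any(b[, "xmax"] > W + 1e-9) || any(b[, "ymax"] > H + 1e-9)))
      stop("applyGeometric: boxes must lie within the image")
    b <- if (nrow(b) > 0) asBoxMatrix(mapBoxes(b, W, H, s))
         else b
    img <- switch(s,
      hflip = perChannel(img, function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]),
      vflip = perChannel(img, function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]),
      rot90 = rot90ccwRaster(img))
  }
  out <- annotations
  out@boxes <- asBoxMatrix(b)
  list(image = img, annotations = out)
}

#' Apply a photometric operation
#'
#' Geometry and annotations are untouched; the output is clipped to
#' \[0, 255\] and rounded back to 8-bit levels. `downscale` resamples to
#' `floor(s * W) x floor(s * H)` and back, emulating mild resolution loss.
#'
#' @param image H x W matrix or H x W x C array, 8-bit values.
#' @param op one of `"brightness_contrast"`, `"gamma"`, `"mult_noise"`,
#'   `"gaussian_blur"`, `"sharpen"`, `"downscale"`.
#' @param params named list of parameters: `alpha`/`beta` (contrast scale
#'   about mid-grey / brightness offset), `gamma`, `range` + `per_pixel`
#'   (multiplicative noise), `sigma` (blur), `s` (downscale factor).
#' @param seed seed for the stochastic ops (multiplicative noise).
#' @return the transformed image, same dimensions as the input.
#' @examples
#' applyPhotometric(matrix(128, 2, 2), "gamma", list(gamma = 2))  # all 64
#' @export
applyPhotometric <- function(image, op, params = list(), seed = 1L) {
  out <- switch(op,
    brightness_contrast = {
      a <- params$alpha %||% 1; b <- params$beta %||% 0
      a * (image - 127.5) + 127.5 + b
    },
    gamma = {
      g <- params$gamma %||% 1
      255 * (image / 255)^g
    },
    mult_noise = {
      rng <- params$range %||% c(0.9, 1.1)
      perPix <- params$per_pixel %||% TRUE
      withr::with_seed(seed, {
        if (perPix) image * array(stats::runif(length(image), rng[1], rng[2]),
                                  dim = dim(image))
        else image * stats::runif(1, rng[1], rng[2])
      })
    },
    gaussian_blur = {
      sg <- params$sigma %||% 1
      if (sg < 0) stop("applyPhotometric: sigma must be >= 0")
      if (sg == 0) image
      else perChannel(image, function(m) EBImage::gblur(m, sigma = sg))
    },
    sharpen = {
      sg <- params$sigma %||% 1
      amount <- params$amount %||% 1
      blurred <- perChannel(image, function(m) EBImage::gblur(m, sigma = sg))
      image + amount * (image - blurred)
    },
    downscale = {
      s <- params$s %||% 0.9
      if (s <= 0 || s > 1) stop("applyPhotometric: s must lie in (0, 1]")
      perChannel(image, function(m) {
        dn <- EBImage::resize(m, w = max(1, floor(s * nrow(m))),
                              h = max(1, floor(s * ncol(m))))
        EBImage::resize(dn, w = nrow(m), h = ncol(m))
      })
    },
    stop(sprintf("applyPhotometric: unknown op '%s'", op)))
  round(clamp(out, 0, 255))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate augmented variants of an image
#'
#' Samples operations per variant from the plan's probabilities using one
#' seeded stream per (seed, image id, variant index) so that parallel and
#' repeated runs are reproducible. Annotations follow the geometry exactly.
#'
#' @param image H x W matrix or H x W x C array.
#' @param annotations a [DetectionSet-class].
#' @param plan an [augmentationPlan()].
#' @param n_variants number of variants (>= 0).
#' @param seed global seed.
#' @param image_id id used to key the per-image stream.
#' @return list of `list(image =, annotations =)` of length `n_variants`.
#' @export
generateVariants <- function(image, annotations, plan = augmentationPlan(),
                             n_variants = 5, seed = 1L,
                             image_id = "image") {
  stopifnot(n_variants >= 0)
  lapply(seq_len(n_variants), function(v) {
    vseed <- deriveSeed(seed, image_id, v)
    draws <- withr::with_seed(vseed, stats::runif(16))
    cur <- list(image = image, annotations = annotations)
    if (draws[1] < plan$hflip)
      cur <- applyGeometric(cur$image, cur$annotations, "hflip")
    if (draws[2] < plan$vflip)
      cur <- applyGeometric(cur$image, cur$annotations, "vflip")
    if (draws[3] < plan$rot90) {
      rot <- c("rot90", "rot180", "rot270")[1 + floor(draws[4] * 3)]
      cur <- applyGeometric(cur$image, cur$annotations, rot)
    }
    img <- cur$image
    p <- plan$brightness_contrast
    if (draws[5] < p$p)
      img <- applyPhotometric(img, "brightness_contrast",
        list(alpha = p$alpha[1] + draws[6] * diff(p$alpha),
             beta  = p$beta[1] + draws[7] * diff(p$beta)))
    p <- plan$gamma
    if (draws[8] < p$p)
      img <- applyPhotometric(img, "gamma",
        list(gamma = p$range[1] + draws[9] * diff(p$range)))
    p <- plan$mult_noise
    if (draws[10] < p$p)
      img <- applyPhotometric(img, "mult_noise",
        list(range = p$range, per_pixel = p$per_pixel),
        seed = deriveSeed(vseed, "noise"))
    p <- plan$blur_sharpen
    if (draws[11] < p$p) {
      sg <- p$sigma[1] + draws[13] * diff(p$sigma)
      img <- applyPhotometric(img, if (draws[12] < 0.5) "gaussian_blur"
                              else "sharpen", list(sigma = sg))
    }
    p <- plan$downscale
    if (draws[14] < p$p)
      img <- applyPhotometric(img, "downscale",
        list(s = p$range[1] + draws[15] * diff(p$range)))
    list(image = img, annotations = cur$annotations)
  })
}
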