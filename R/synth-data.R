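# Synthetic fixtures with known ground truth: rendered slides, noisy
# detector output, clustered unit-norm embeddings and calibrated
# predictions. Every generator is a pure function of (spec, seed).
#
# The slide generator emulates single-taxon light-microscopy photographs:
# a bright speckled background with darker elliptical grains at the
# acquisition geometry of the study (2576 x 1932 canvas; mean densities 49
# grains/image for dandelion, 39 for hazel). Grain sizes follow loosely
# the observed bounding-box size distributions (configuration, not a
# claim); realism beyond what the downstream geometry and photometric ops
# need is a non-goal.

#' Slide specification
#'
#' @param width,height canvas in pixels (defaults 2576 x 1932).
#' @param mean_grains expected grain count per image, one per class
#'   (defaults: dandelion 49, hazel 39).
#' @param axis_mean,axis_sd per-class normal parameters for the ellipse
#'   axis lengths in pixels.
#' @param max_overlap maximum allowed pairwise box IoU when placing grains.
#' @param noise_sd background speckle standard deviation (8-bit units).
#' @param class_names class names indexed by class id + 1.
#' @return a list of class `"SlideSpec"`.
#' @export
slideSpec <- function(width = 2576, height = 1932,
                      mean_grains = c(49, 39),
                      axis_mean = c(130, 105), axis_sd = c(15, 12),
                      max_overlap = 0.05, noise_sd = 6,
                      class_names = c("dandelion", "hazel")) {
  stopifnot(all(mean_grains > 0), all(axis_mean > 0), all(axis_sd >= 0))
  structure(list(width = width, height = height, mean_grains = mean_grains,
                 axis_mean = axis_mean, axis_sd = axis_sd,
                 max_overlap = max_overlap, noise_sd = noise_sd,
                 class_names = class_names),
            class = "SlideSpec")
}

#' Render a synthetic single-taxon slide
#'
#' The grain count is Poisson with the class's expected density; each
#' grain is a filled, textured ellipse (radial shading plus speckle) with
#' random orientation, placed by rejection sampling so that no two
#' annotation boxes overlap beyond `max_overlap` (after 200 failed
#' attempts the grain is accepted anyway, with a warning, mirroring real
#' grain overlap). Each annotation box is tight around the grain's
#' rendered pixels.
#'
#' @param spec a [slideSpec()].
#' @param class_id 0-based class index.
#' @param seed integer seed; identical seeds give identical output.
#' @param image_id id stored with the annotations.
#' @return `list(image = H x W matrix in [0, 255], annotations =
#'   [DetectionSet-class], class_id =)`.
#' @export
generateSlide <- function(spec, class_id, seed, image_id = "slide") {
  stopifnot(inherits(spec, "SlideSpec"))
  k <- class_id + 1L
  if (spec$width < 4 * spec$axis_mean[k] || spec$height < 4 * spec$axis_mean[k])
    stop("generateSlide: canvas too small for the grain size distribution")
  withr::with_seed(as.integer(seed), {
    H <- spec$height; W <- spec$width
    img <- matrix(220 + stats::rnorm(H * W, 0, spec$noise_sd), H, W)
    n <- stats::rpois(1, spec$mean_grains[k])
    boxesAcc <- matrix(numeric(0), 0, 4, dimnames = list(NULL, BOX_COLS))
    annBoxes <- list()
    for (g in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(200)) {
        a <- max(abs(stats::rnorm(1, spec$axis_mean[k], spec$axis_sd[k])) / 2, 4)
        b <- max(abs(stats::rnorm(1, spec$axis_mean[k] * 0.85,
                                  spec$axis_sd[k])) / 2, 4)
        phi <- stats::runif(1, 0, pi)
        ex <- sqrt((a * cos(phi))^2 + (b * sin(phi))^2)
        ey <- sqrt((a * sin(phi))^2 + (b * cos(phi))^2)
        cx <- stats::runif(1, ex + 1, W - ex - 1)
        cy <- stats::runif(1, ey + 1, H - ey - 1)
        cand <- c(xmin = cx - ex, ymin = cy - ey, xmax = cx + ex, ymax = cy + ey)
        if (nrow(boxesAcc) == 0 ||
            all(iouMatrix(matrix(cand, 1, dimnames = list(NULL, BOX_COLS)),
                          boxesAcc) <= spec$max_overlap)) {
          placed <- TRUE
          break
        }
      }
      if (!placed)
        warning("generateSlide: overlap cap not satisfiable; accepting grain")
      # rasterize into the bounding window; pixel centers at (c-0.5, r-0.5)
      c0 <- max(floor(cx - ex), 0); c1 <- min(ceiling(cx + ex), W)
      r0 <- max(floor(cy - ey), 0); r1 <- min(ceiling(cy + ey), H)
      rows <- (r0 + 1):r1; cols <- (c0 + 1):c1
      px <- outer(rep(1, length(rows)), cols - 0.5) - cx
      py <- outer(rows - 0.5, rep(1, length(cols))) - cy
      u <- ((px * cos(phi) + py * sin(phi)) / a)^2 +
           ((-px * sin(phi) + py * cos(phi)) / b)^2
      mask <- u <= 1
      if (!any(mask)) next
      shade <- 70 + 70 * u + matrix(stats::rnorm(length(u), 0, 6),
                                    nrow(u), ncol(u))
      win <- img[rows, cols]
      win[mask] <- pmin(win[mask], shade[mask])
      img[rows, cols] <- win
      # tight box around the rendered pixels, in continuous coordinates
      hit <- which(mask, arr.ind = TRUE)
      tight <- c(xmin = min(cols[hit[, 2]]) - 1, ymin = min(rows[hit[, 1]]) - 1,
                 xmax = max(cols[hit[, 2]]), ymax = max(rows[hit[, 1]]))
      annBoxes[[length(annBoxes) + 1]] <- tight
      boxesAcc <- rbind(boxesAcc, tight)
    }
    img <- clamp(round(img), 0, 255)
    ann <- if (length(annBoxes))
      annotationSet(image_id, class_id, do.call(rbind, annBoxes))
    else emptyDetectionSet()
    list(image = img, annotations = ann, class_id = class_id)
  })
}

#' Detector-noise specification
#'
#' Emulates the error modes of a real detector: localization jitter,
#' missed objects, duplicate boxes that survive upstream of NMS, and
#' background false positives, with separate confidence distributions for
#' true and false detections.
#'
#' @param jitter_sd Gaussian corner jitter in pixels.
#' @param miss_prob per-object miss probability.
#' @param fp_rate expected false positives per image (Poisson).
#' @param dup_prob per-object duplicate probability.
#' @param tp_conf_beta,fp_conf_beta Beta(a, b) parameters of the
#'   confidence distributions for true and false detections.
#' @return a list of class `"DetectorNoiseSpec"`.
#' @export
detectorNoiseSpec <- function(jitter_sd = 2, miss_prob = 0.05, fp_rate = 2,
                              dup_prob = 0.05, tp_conf_beta = c(8, 2),
                              fp_conf_beta = c(2, 6)) {
  stopifnot(jitter_sd >= 0, miss_prob >= 0, miss_prob <= 1,
            fp_rate >= 0, dup_prob >= 0, dup_prob <= 1)
  structure(list(jitter_sd = jitter_sd, miss_prob = miss_prob,
                 fp_rate = fp_rate, dup_prob = dup_prob,
                 tp_conf_beta = tp_conf_beta, fp_conf_beta = fp_conf_beta),
            class = "DetectorNoiseSpec")
}

jitterBoxes <- function(b, sd, W, H) {
  if (sd == 0) return(b)
  j <- b + matrix(stats::rnorm(length(b), 0, sd), nrow(b), 4)
  # keep boxes valid and inside the canvas
  out <- cbind(xmin = pmin(j[, 1], j[, 3] - 2), ymin = pmin(j[, 2], j[, 4] - 2),
               xmax = pmax(j[, 3], j[, 1] + 2), ymax = pmax(j[, 4], j[, 2] + 2))
  cbind(xmin = clamp(out[, 1], 0, W - 2), ymin = clamp(out[, 2], 0, H - 2),
        xmax = clamp(out[, 3], 2, W), ymax = clamp(out[, 4], 2, H))
}

#' Simulate detector output from ground truth
#'
#' Each ground-truth object is independently missed with `miss_prob`;
#' survivors are jittered and given a true-positive confidence; duplicates
#' are cloned with doubled jitter and a slightly degraded confidence;
#' false positives are placed uniformly with sizes resampled from the
#' ground-truth boxes.
#'
#' @param ground_truths ground-truth [DetectionSet-class].
#' @param noise a [detectorNoiseSpec()].
#' @param seed integer seed.
#' @param image_width,image_height canvas bounds for placement/clamping.
#' @return a scored [DetectionSet-class].
#' @export
generateDetectorOutput <- function(ground_truths, noise = detectorNoiseSpec(),
                                   seed = 1L, image_width = 2576,
                                   image_height = 1932) {
  stopifnot(inherits(noise, "DetectorNoiseSpec"))
  W <- image_width; H <- image_height
  withr::with_seed(as.integer(seed), {
    out <- list()
    gb <- boxes(ground_truths)
    meanW <- if (nrow(gb)) mean(gb[, "xmax"] - gb[, "xmin"]) else 100
    meanH <- if (nrow(gb)) mean(gb[, "ymax"] - gb[, "ymin"]) else 100
    classes <- if (length(ground_truths)) sort(unique(classIds(ground_truths)))
               else 0L
    for (img in unique(c(imageIds(ground_truths)))) {
      gi <- which(imageIds(ground_truths) == img)
      kept <- gi[stats::runif(length(gi)) >= noise$miss_prob]
      if (length(kept)) {
        jb <- jitterBoxes(gb[kept, , drop = FALSE], noise$jitter_sd, W, H)
        sc <- stats::rbeta(length(kept), noise$tp_conf_beta[1],
                           noise$tp_conf_beta[2])
        out[[length(out) + 1]] <- DetectionSet(img, classIds(ground_truths)[kept],
                                               sc, jb)
        dup <- kept[stats::runif(length(kept)) < noise$dup_prob]
        if (length(dup)) {
          db <- jitterBoxes(gb[dup, , drop = FALSE], 2 * noise$jitter_sd +
                              .Machine$double.eps, W, H)
          dsc <- stats::rbeta(length(dup), noise$tp_conf_beta[1],
                              noise$tp_conf_beta[2]) * 0.9
          out[[length(out) + 1]] <- DetectionSet(img,
                                                 classIds(ground_truths)[dup],
                                                 dsc, db)
        }
      }
      nfp <- stats::rpois(1, noise$fp_rate)
      if (nfp > 0) {
        w <- pmax(abs(stats::rnorm(nfp, meanW, meanW / 4)), 8)
        h <- pmax(abs(stats::rnorm(nfp, meanH, meanH / 4)), 8)
        w <- pmin(w, W - 2); h <- pmin(h, H - 2)
        x0 <- stats::runif(nfp, 0, W - w); y0 <- stats::runif(nfp, 0, H - h)
        out[[length(out) + 1]] <- DetectionSet(
          img, classes[sample.int(length(classes), nfp, replace = TRUE)],
          stats::rbeta(nfp, noise$fp_conf_beta[1], noise$fp_conf_beta[2]),
          cbind(xmin = x0, ymin = y0, xmax = x0 + w, ymax = y0 + h))
      }
    }
    if (length(out) == 0) emptyDetectionSet() else do.call(c, out)
  })
}

#' Embedding-cluster specification
#'
#' Clustered unit-norm embeddings emulating a separable feature space:
#' each class has a mean direction on the unit hypersphere, consecutive
#' class directions separated by `separation` degrees, and samples are
#' `normalize(direction + N(0, sigma^2 I))`.
#'
#' @param D embedding dimension (default 1024).
#' @param K number of classes (default 2).
#' @param separation angular separation between consecutive class
#'   directions, in degrees (0-180).
#' @param sigma isotropic noise standard deviation before renormalization.
#' @param per_class samples per class.
#' @return a list of class `"EmbeddingClusterSpec"`.
#' @export
embeddingClusterSpec <- function(D = 1024, K = 2, separation = 90,
                                 sigma = 0.1, per_class = 500) {
  stopifnot(D >= 2, K >= 2, separation >= 0, separation <= 180, sigma >= 0)
  if (sigma == 0 && separation == 0)
    stop("embeddingClusterSpec: sigma and separation cannot both be 0")
  structure(list(D = D, K = K, separation = separation, sigma = sigma,
                 per_class = per_class),
            class = "EmbeddingClusterSpec")
}

classDirections <- function(spec) {
  theta <- (seq_len(spec$K) - 1) * spec$separation * pi / 180
  dirs <- matrix(0, spec$K, spec$D)
  dirs[, 1] <- cos(theta)
  dirs[, 2] <- sin(theta)
  dirs
}

#' Generate clustered unit-norm embeddings
#'
#' @param spec an [embeddingClusterSpec()].
#' @param seed integer seed.
#' @return `list(embeddings = [PollenEmbeddings-class] (raw, but rows
#'   unit-norm by construction), labels = integer class ids)`.
#' @export
generateEmbeddingClusters <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "EmbeddingClusterSpec"))
  withr::with_seed(as.integer(seed), {
    dirs <- classDirections(spec)
    n <- spec$K * spec$per_class
    labels <- rep(seq_len(spec$K) - 1L, each = spec$per_class)
    raw <- dirs[labels + 1L, , drop = FALSE] +
      matrix(stats::rnorm(n * spec$D, 0, spec$sigma), n, spec$D)
    norms <- sqrt(rowSums(raw^2))
    list(embeddings = PollenEmbeddings(raw / norms, state = "raw"),
         labels = labels)
  })
}

#' Sample one embedding per requested class from a cluster spec
#'
#' The class-keyed fixture "embedder": deterministic given (spec, seed),
#' used by the pipeline to stand in for a neural feature extractor.
#'
#' @param spec an [embeddingClusterSpec()].
#' @param class_keys integer vector: class id per requested embedding, or
#'   `NA` for a background (uniformly random direction) embedding.
#' @param seed integer seed.
#' @return a raw [PollenEmbeddings-class], one row per key.
#' @export
sampleClassEmbeddings <- function(spec, class_keys, seed = 1L) {
  stopifnot(inherits(spec, "EmbeddingClusterSpec"))
  withr::with_seed(as.integer(seed), {
    dirs <- classDirections(spec)
    n <- length(class_keys)
    raw <- matrix(stats::rnorm(n * spec$D, 0, spec$sigma), n, spec$D)
    for (i in seq_len(n)) {
      if (is.na(class_keys[i])) {
        v <- stats::rnorm(spec$D)
        raw[i, ] <- v / sqrt(sum(v^2)) + raw[i, ]
      } else {
        raw[i, ] <- raw[i, ] + dirs[class_keys[i] + 1L, ]
      }
    }
    PollenEmbeddings(raw, state = "raw")
  })
}

#' Generate calibrated (or miscalibrated) predictions
#'
#' Confidence is Uniform(0.5, 1); correctness is Bernoulli with success
#' probability `clip(confidence + miscalibration, 0, 1)`, so
#' `miscalibration = 0` yields perfectly calibrated predictions and a
#' negative value makes the classifier overconfident by that amount.
#'
#' @param n number of predictions (>= 1).
#' @param miscalibration shift added to the Bernoulli parameter.
#' @param seed integer seed.
#' @return `list(confidences =, correct = logical)`.
#' @export
generateCalibratedPredictions <- function(n, miscalibration = 0, seed = 1L) {
  stopifnot(n >= 1)
  withr::with_seed(as.integer(seed), {
    conf <- stats::runif(n, 0.5, 1)
    p <- clamp(conf + miscalibration, 0, 1)
    list(confidences = conf, correct = stats::rbinom(n, 1, p) == 1)
  })
}
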