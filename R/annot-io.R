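# YOLO-format annotation I/O, image-level dataset splitting and
# minority-class oversampling.
#
# YOLO label files hold one line per object:
#   "<class> <cx> <cy> <w> <h>"
# with center/size normalized to [0, 1] by the image dimensions, '.' as
# decimal separator. Pixel coordinates here are continuous with origin at
# the top-left corner.

#' Read YOLO-format labels
#'
#' Converts normalized center format to pixel boxes:
#' `xmin = (cx - w/2) * W`, `xmax = (cx + w/2) * W`, and likewise for y.
#' Line order is preserved.
#'
#' @param labels path to a `.txt` label file, or a character vector of
#'   label lines.
#' @param image_width,image_height image dimensions in pixels.
#' @param image_id id stored with each annotation (default the file name).
#' @return a [DetectionSet-class] of ground-truth annotations (`NA` scores).
#' @examples
#' readYoloLabels("0 0.5 0.5 0.1 0.2", 2576, 1932, image_id = "img")
#' @export
readYoloLabels <- function(labels, image_width, image_height,
                           image_id = NULL) {
  if (length(labels) == 1 && file.exists(labels)) {
    if (is.null(image_id))
      image_id <- sub("\\.txt$", "", basename(labels))
    labels <- readLines(labels)
  }
  if (is.null(image_id)) image_id <- "image"
  labels <- labels[nzchar(trimws(labels))]
  if (length(labels) == 0) return(emptyDetectionSet())
  parsed <- lapply(seq_along(labels), function(i) {
    fields <- strsplit(trimws(labels[i]), "\\s+")[[1]]
    if (length(fields) != 5)
      stop(sprintf("readYoloLabels: line %d has %d fields, expected 5",
                   i, length(fields)))
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals)))
      stop(sprintf("readYoloLabels: line %d contains a non-numeric field", i))
    if (vals[1] < 0 || vals[1] != floor(vals[1]))
      stop(sprintf("readYoloLabels: line %d has an invalid class id", i))
    if (any(vals[2:5] < 0) || any(vals[2:5] > 1))
      stop(sprintf(
        "readYoloLabels: line %d has a normalized value outside [0, 1]", i))
    vals
  })
  m <- do.call(rbind, parsed)
  cx <- m[, 2] * image_width;  w <- m[, 4] * image_width
  cy <- m[, 3] * image_height; h <- m[, 5] * image_height
  annotationSet(image_id, as.integer(m[, 1]),
                cbind(xmin = cx - w / 2, ymin = cy - h / 2,
                      xmax = cx + w / 2, ymax = cy + h / 2))
}

#' Write YOLO-format labels
#'
#' Inverse of [readYoloLabels()]: pixel boxes back to normalized center
#' format. Round-tripping reproduces pixel coordinates within
#' `1e-6 * max(W, H)`.
#'
#' @param annotations a [DetectionSet-class].
#' @param image_width,image_height image dimensions in pixels.
#' @param path optional output file; when `NULL` the lines are returned.
#' @return the label lines, invisibly when written to `path`.
#' @export
writeYoloLabels <- function(annotations, image_width, image_height,
                            path = NULL) {
  b <- boxes(annotations)
  if (nrow(b) > 0 &&
      (any(b[, "xmin"] < 0) || any(b[, "ymin"] < 0) ||
       any(b[, "xmax"] > image_width) || any(b[, "ymax"] > image_height)))
    stop("writeYoloLabels: box outside image bounds")
  lines <- vapply(seq_len(nrow(b)), function(i) {
    sprintf("%d %.8f %.8f %.8f %.8f",
            classIds(annotations)[i],
            (b[i, "xmin"] + b[i, "xmax"]) / 2 / image_width,
            (b[i, "ymin"] + b[i, "ymax"]) / 2 / image_height,
            (b[i, "xmax"] - b[i, "xmin"]) / image_width,
            (b[i, "ymax"] - b[i, "ymin"]) / image_height)
  }, character(1))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Leakage-free image-level dataset split
#'
#' Splitting happens at the level of whole images so that no augmented or
#' oversampled variant of an image can cross subset boundaries. The policy
#' is a seeded shuffle followed by slicing; with `stratify_by` given
#' (e.g. the slide's single taxon), each stratum is sliced separately with
#' proportional allocation (largest-remainder rounding).
#'
#' Counts may sum to fewer images than available; the remainder is
#' returned in the `unused` component so that the four components always
#' partition the input.
#'
#' @param image_ids character vector of image ids.
#' @param counts integer vector `c(train, val, test)`; mutually exclusive
#'   with `fractions`.
#' @param fractions numeric vector `c(train, val, test)` summing to <= 1.
#' @param seed integer seed; identical seed and input order give an
#'   identical split.
#' @param stratify_by optional factor parallel to `image_ids`.
#' @return a list with components `train`, `val`, `test`, `unused`
#'   (character vectors), plus the `seed` and `policy` used.
#' @export
splitDataset <- function(image_ids, counts = NULL, fractions = NULL,
                         seed = 1L, stratify_by = NULL) {
  n <- length(image_ids)
  if (anyDuplicated(image_ids)) stop("splitDataset: duplicate image ids")
  if (is.null(counts) == is.null(fractions))
    stop("splitDataset: give exactly one of counts or fractions")
  if (!is.null(fractions)) {
    if (sum(fractions) > 1 + 1e-9)
      stop("splitDataset: fractions must sum to <= 1")
    counts <- largestRemainder(fractions * n, round(sum(fractions) * n))
  }
  counts <- as.integer(counts)
  stopifnot(length(counts) == 3)
  if (sum(counts) > n)
    stop("splitDataset: requested counts exceed available images")

  sliceIds <- function(ids, cnt) {
    ord <- ids[withr::with_seed(deriveSeed(seed, "split", ids[1]),
                                sample.int(length(ids)))]
    list(train = ord[seq_len(cnt[1])],
         val   = ord[cnt[1] + seq_len(cnt[2])],
         test  = ord[cnt[1] + cnt[2] + seq_len(cnt[3])],
         unused = if (sum(cnt) < length(ids))
           ord[(sum(cnt) + 1):length(ids)] else character(0))
  }

  if (is.null(stratify_by)) {
    parts <- sliceIds(image_ids, counts)
  } else {
    stopifnot(length(stratify_by) == n)
    strata <- split(image_ids, stratify_by)
    sizes <- vapply(strata, length, integer(1))
    alloc <- vapply(seq_along(counts), function(k)
      largestRemainder(sizes / n * counts[k], counts[k]), integer(length(strata)))
    if (length(strata) == 1) alloc <- matrix(alloc, nrow = 1)
    parts <- list(train = character(0), val = character(0),
                  test = character(0), unused = character(0))
    for (s in seq_along(strata)) {
      p <- sliceIds(strata[[s]], alloc[s, ])
      parts <- Map(c, parts, p)
    }
  }
  c(parts, list(seed = as.integer(seed),
                policy = if (is.null(stratify_by)) "shuffle-slice"
                         else "stratified-shuffle-slice"))
}

# Integer allocation with the given total, by largest remainder.
largestRemainder <- function(x, total) {
  fl <- floor(x)
  rem <- as.integer(total) - sum(fl)
  if (rem > 0) {
    extra <- order(x - fl, decreasing = TRUE)[seq_len(rem)]
    fl[extra] <- fl[extra] + 1
  } else if (rem < 0) {
    cut <- order(x - fl)[seq_len(-rem)]
    fl[cut] <- fl[cut] - 1
  }
  as.integer(fl)
}

#' Write a split manifest as JSON
#'
#' @param split result of [splitDataset()].
#' @param path output path.
#' @export
writeSplitManifest <- function(split, path) {
  jsonlite::write_json(split, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Minority-class oversampling by whole-image repetition
#'
#' Balances training classes by repeating whole source images before
#' augmentation, so that each class ends up with
#' `target_per_class = (sources + repeats) * (1 + variants_per_image)`
#' training images once every image (original or repeat) receives its
#' augmented variants. Repeats are drawn uniformly with the seed. Applied
#' to the training set only; validation and test sets are never touched.
#'
#' @param image_ids training image ids.
#' @param class_ids class of each image (single-taxon slides).
#' @param target_per_class desired per-class image count after variant
#'   generation.
#' @param variants_per_image augmented variants generated per image
#'   (default 5).
#' @param seed integer seed.
#' @return a list per class: character vector of image-id slots (sources
#'   followed by repeats); attribute `repeats` gives the repeat counts.
#' @export
oversampleMinority <- function(image_ids, class_ids, target_per_class,
                               variants_per_image = 5, seed = 1L) {
  mult <- 1 + variants_per_image
  out <- list()
  for (cl in sort(unique(class_ids))) {
    src <- image_ids[class_ids == cl]
    slots <- target_per_class / mult
    if (abs(slots - round(slots)) > 1e-9) {
      warning(sprintf(
        "oversampleMinority: class %s target %d not divisible by %d; rounding down",
        cl, target_per_class, mult))
      slots <- floor(slots)
    }
    slots <- as.integer(round(slots))
    if (slots < length(src))
      stop(sprintf(
        "oversampleMinority: class %s already has %d sources, target allows %d",
        cl, length(src), slots))
    nrep <- slots - length(src)
    reps <- if (nrep > 0)
      src[withr::with_seed(deriveSeed(seed, "oversample", cl),
                           sample.int(length(src), nrep, replace = TRUE))]
    else character(0)
    slot_ids <- c(src, reps)
    attr(slot_ids, "repeats") <- table(reps)
    out[[as.character(cl)]] <- slot_ids
  }
  out
}

#' Per-class dataset summary
#'
#' Tabulates, per class, the number of images containing the class, the
#' total grain (annotation) count, and the mean grain density per image
#' (total grains / number of images).
#'
#' @param annotations a [DetectionSet-class] over the whole dataset.
#' @param class_names optional names indexed by class id + 1.
#' @return a data.frame with columns `class`, `n_images`, `n_grains`,
#'   `mean_density`.
#' @export
datasetSummary <- function(annotations, class_names = NULL) {
  cls <- sort(unique(classIds(annotations)))
  rows <- lapply(cls, function(cl) {
    sel <- classIds(annotations) == cl
    data.frame(
      class = if (is.null(class_names)) as.character(cl)
              else class_names[cl + 1L],
      n_images = length(unique(imageIds(annotations)[sel])),
      n_grains = sum(sel),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$mean_density <- out$n_grains / out$n_images
  out
}
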