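# Detection-to-classification interface: IoU, greedy NMS, context-aware
# box expansion and ROI cropping.

#' Area of bounding boxes
#'
#' @param boxes 4-column box matrix (`xmin, ymin, xmax, ymax`) or a single
#'   box as a length-4 vector.
#' @return numeric vector of areas.
#' @export
boxArea <- function(boxes) {
  boxes <- asBoxMatrix(boxes)
  (boxes[, "xmax"] - boxes[, "xmin"]) * (boxes[, "ymax"] - boxes[, "ymin"])
}

#' Intersection over Union of two boxes
#'
#' The overlap measure used throughout detection post-processing and
#' evaluation: `IoU = |A intersect B| / |A union B|`, with the union
#' computed as `area(A) + area(B) - intersection`.
#'
#' @param a,b boxes as length-4 vectors or 1-row matrices
#'   (`xmin, ymin, xmax, ymax`).
#' @return a value in \[0, 1\]; 0 for disjoint boxes, 1 iff identical.
#' @examples
#' iou(c(0, 0, 10, 10), c(5, 0, 15, 10))  # 1/3
#' @export
iou <- function(a, b) {
  a <- asBoxMatrix(a); b <- asBoxMatrix(b)
  stopifnot(nrow(a) == 1, nrow(b) == 1)
  if (boxArea(a) <= 0 || boxArea(b) <= 0)
    stop("iou: degenerate zero-area box")
  iouMatrix(a, b)[1, 1]
}

#' Pairwise IoU matrix between two sets of boxes
#'
#' @param a n x 4 box matrix.
#' @param b m x 4 box matrix.
#' @return n x m matrix of IoU values.
#' @export
iouMatrix <- function(a, b) {
  a <- asBoxMatrix(a); b <- asBoxMatrix(b)
  n <- nrow(a); m <- nrow(b)
  if (n == 0 || m == 0) return(matrix(numeric(0), n, m))
  ix1 <- outer(a[, "xmin"], b[, "xmin"], pmax)
  iy1 <- outer(a[, "ymin"], b[, "ymin"], pmax)
  ix2 <- outer(a[, "xmax"], b[, "xmax"], pmin)
  iy2 <- outer(a[, "ymax"], b[, "ymax"], pmin)
  inter <- pmax(ix2 - ix1, 0) * pmax(iy2 - iy1, 0)
  uni <- outer(boxArea(a), boxArea(b), `+`) - inter
  inter / uni
}

#' Greedy non-maximum suppression
#'
#' Removes duplicate detections: detections are visited in order of
#' descending confidence (ties broken by input order), and any detection
#' whose IoU with an already kept detection reaches `nms_iou` is dropped.
#' The default threshold 0.65 keeps only the highest-confidence box among
#' near-coincident candidates while preserving genuinely close neighbours,
#' which matters on dense microscopy slides.
#'
#' @param detections a [DetectionSet-class].
#' @param nms_iou suppression threshold in \[0, 1\] (default 0.65).
#' @param class_aware if `TRUE` (default) only detections of the same class
#'   suppress each other.
#' @return the surviving [DetectionSet-class], sorted by descending score.
#' @export
nms <- function(detections, nms_iou = 0.65, class_aware = TRUE) {
  stopifnot(is(detections, "DetectionSet"),
            nms_iou >= 0, nms_iou <= 1)
  n <- length(detections)
  if (n == 0) return(detections)
  if (any(is.na(scores(detections))))
    stop("nms: detections must carry confidence scores")
  keep <- integer(0)
  for (img in unique(imageIds(detections))) {
    idx <- which(imageIds(detections) == img)
    ord <- idx[order(-scores(detections)[idx])]  # stable: input order on ties
    bx <- boxes(detections)
    cl <- classIds(detections)
    kept <- integer(0)
    for (i in ord) {
      rivals <- kept
      if (class_aware) rivals <- kept[cl[kept] == cl[i]]
      if (length(rivals) == 0 ||
          all(iouMatrix(bx[i, , drop = FALSE],
                        bx[rivals, , drop = FALSE]) < nms_iou)) {
        kept <- c(kept, i)
      }
    }
    keep <- c(keep, kept)
  }
  out <- detections[keep]
  out[order(-scores(out))]
}

#' Context-aware bounding-box expansion
#'
#' Grows a box by `pad_ratio` of its width and height in total (half on
#' each side), preserving the center, then clamps to the image. The
#' default 0.12 retains peripheral morphology (e.g. exine ornamentation at
#' the grain boundary) in the cropped region handed to the feature
#' extractor; clamping happens after expansion so context is maximal at
#' image borders.
#'
#' @param box length-4 vector or n x 4 matrix (`xmin, ymin, xmax, ymax`).
#' @param pad_ratio total relative growth of each dimension (default 0.12).
#' @param image_width,image_height clamping bounds in pixels.
#' @return expanded (and clamped) boxes, same shape semantics as input.
#' @examples
#' expandBox(c(100, 100, 200, 200), 0.12, 1000, 1000)  # (94, 94, 206, 206)
#' @export
expandBox <- function(box, pad_ratio = 0.12, image_width, image_height) {
  if (pad_ratio < 0) stop("expandBox: pad_ratio must be >= 0")
  b <- asBoxMatrix(box)
  dx <- (b[, "xmax"] - b[, "xmin"]) * pad_ratio / 2
  dy <- (b[, "ymax"] - b[, "ymin"]) * pad_ratio / 2
  out <- cbind(xmin = clamp(b[, "xmin"] - dx, 0, image_width),
               ymin = clamp(b[, "ymin"] - dy, 0, image_height),
               xmax = clamp(b[, "xmax"] + dx, 0, image_width),
               ymax = clamp(b[, "ymax"] + dy, 0, image_height))
  if (is.null(dim(box))) out[1, ] else out
}

#' Crop a region of interest from a raster image
#'
#' Continuous box coordinates are rasterized to the half-open integer
#' window `[floor(xmin), ceiling(xmax)) x [floor(ymin), ceiling(ymax))`,
#' guaranteeing at least a 1x1 crop for any valid box overlapping the
#' image.
#'
#' @param image numeric matrix (rows = y, columns = x) or H x W x C array.
#' @param box length-4 box vector in pixel coordinates.
#' @return the cropped sub-image (same number of channels as the input).
#' @export
cropRoi <- function(image, box) {
  b <- asBoxMatrix(box)
  H <- dim(image)[1]; W <- dim(image)[2]
  if (b[1, "xmin"] >= W || b[1, "xmax"] <= 0 ||
      b[1, "ymin"] >= H || b[1, "ymax"] <= 0)
    stop("cropRoi: box lies entirely outside the image")
  x0 <- max(floor(b[1, "xmin"]), 0)
  x1 <- min(ceiling(b[1, "xmax"]), W)
  y0 <- max(floor(b[1, "ymin"]), 0)
  y1 <- min(ceiling(b[1, "ymax"]), H)
  rows <- (y0 + 1):y1
  cols <- (x0 + 1):x1
  if (length(dim(image)) == 3) image[rows, cols, , drop = FALSE]
  else image[rows, cols, drop = FALSE]
}

#' Read / write detections as JSON lines
#'
#' One JSON object per line:
#' `{"image_id": ..., "class_id": ..., "score": ..., "box": [xmin, ymin, xmax, ymax]}`.
#'
#' @param path file path.
#' @return `readDetectionsJsonl` returns a [DetectionSet-class].
#' @export
readDetectionsJsonl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(emptyDetectionSet())
  recs <- lapply(lines, jsonlite::fromJSON)
  DetectionSet(
    imageId = vapply(recs, function(r) as.character(r$image_id), character(1)),
    classId = vapply(recs, function(r) as.integer(r$class_id), integer(1)),
    score   = vapply(recs, function(r) as.numeric(r$score), numeric(1)),
    boxes   = do.call(rbind, lapply(recs, function(r) as.numeric(r$box))))
}

#' @rdname readDetectionsJsonl
#' @param detections a [DetectionSet-class].
#' @export
writeDetectionsJsonl <- function(detections, path) {
  n <- length(detections)
  lines <- vapply(seq_len(n), function(i) {
    jsonlite::toJSON(list(image_id = imageIds(detections)[i],
                          class_id = classIds(detections)[i],
                          score = scores(detections)[i],
                          box = unname(boxes(detections)[i, ])),
                     auto_unbox = TRUE, digits = NA, na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
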