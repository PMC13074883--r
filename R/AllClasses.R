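#' @import methods
NULL

BOX_COLS <- c("xmin", "ymin", "xmax", "ymax")

#' DetectionSet: boxes with class labels and (optional) confidence scores
#'
#' The common container for both detector output and ground-truth
#' annotations. Boxes are axis-aligned pixel rectangles in continuous
#' coordinates, origin at the top-left corner, x rightward, y downward.
#' Ground-truth sets carry `NA` scores (see [annotationSet()]).
#'
#' @slot imageId character, one id per box.
#' @slot classId integer class indices (0-based, YOLO convention).
#' @slot score numeric confidence in \[0, 1\], or `NA` for ground truth.
#' @slot boxes numeric matrix with columns `xmin, ymin, xmax, ymax`.
#'
#' @aliases DetectionSet-class
#' @exportClass DetectionSet
setClass("DetectionSet",
  representation(
    imageId = "character",
    classId = "integer",
    score   = "numeric",
    boxes   = "matrix"
  )
)

setValidity("DetectionSet", function(object) {
  n <- nrow(object@boxes)
  msg <- character()
  if (length(object@imageId) != n) msg <- c(msg, "imageId length != number of boxes")
  if (length(object@classId) != n) msg <- c(msg, "classId length != number of boxes")
  if (length(object@score) != n)   msg <- c(msg, "score length != number of boxes")
  if (ncol(object@boxes) != 4 || !identical(colnames(object@boxes), BOX_COLS))
    msg <- c(msg, "boxes must have columns xmin, ymin, xmax, ymax")
  if (n > 0) {
    if (any(!is.finite(object@boxes))) msg <- c(msg, "box coordinates must be finite")
    else {
      if (any(object@boxes[, "xmin"] >= object@boxes[, "xmax"]) ||
          any(object@boxes[, "ymin"] >= object@boxes[, "ymax"]))
        msg <- c(msg, "degenerate box: require xmin < xmax and ymin < ymax")
      if (any(object@boxes < 0)) msg <- c(msg, "box coordinates must be >= 0")
    }
    sc <- object@score[!is.na(object@score)]
    if (length(sc) && (any(sc < 0) || any(sc > 1)))
      msg <- c(msg, "scores must lie in [0, 1]")
    if (any(is.na(object@classId)) || any(object@classId < 0L))
      msg <- c(msg, "classId must be a non-negative integer")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DetectionSet
#'
#' @param imageId character vector (recycled if length 1).
#' @param classId integer class ids (0-based).
#' @param score confidences in \[0, 1\]; `NA` marks ground-truth boxes.
#' @param boxes 4-column matrix `xmin, ymin, xmax, ymax`, or a vector of
#'   length 4 for a single box.
#' @return A [DetectionSet-class] object.
#' @examples
#' DetectionSet("img1", 0L, 0.9, c(10, 20, 50, 60))
#' @export
DetectionSet <- function(imageId, classId, score, boxes) {
  boxes <- asBoxMatrix(boxes)
  n <- nrow(boxes)
  if (length(imageId) == 1L) imageId <- rep(imageId, n)
  if (length(classId) == 1L) classId <- rep(classId, n)
  if (length(score) == 1L)   score <- rep(score, n)
  new("DetectionSet",
      imageId = as.character(imageId),
      classId = as.integer(classId),
      score   = as.numeric(score),
      boxes   = boxes)
}

#' Construct a ground-truth annotation set (a DetectionSet without scores)
#'
#' @inheritParams DetectionSet
#' @return A [DetectionSet-class] with `NA` scores.
#' @export
annotationSet <- function(imageId, classId, boxes) {
  boxes <- asBoxMatrix(boxes)
  DetectionSet(imageId, classId, rep(NA_real_, nrow(boxes)), boxes)
}

emptyDetectionSet <- function() {
  m <- matrix(numeric(0), ncol = 4, dimnames = list(NULL, BOX_COLS))
  new("DetectionSet", imageId = character(0), classId = integer(0),
      score = numeric(0), boxes = m)
}

asBoxMatrix <- function(boxes) {
  if (is.null(dim(boxes))) {
    if (length(boxes) == 0)
      return(matrix(numeric(0), ncol = 4, dimnames = list(NULL, BOX_COLS)))
    stopifnot(length(boxes) == 4)
    boxes <- matrix(boxes, ncol = 4)
  }
  boxes <- as.matrix(boxes)
  storage.mode(boxes) <- "double"
  colnames(boxes) <- BOX_COLS
  rownames(boxes) <- NULL
  boxes
}

#' @describeIn DetectionSet-class number of boxes
#' @param x a DetectionSet
#' @export
setMethod("length", "DetectionSet", function(x) nrow(x@boxes))

#' Accessors for DetectionSet
#'
#' @param x a [DetectionSet-class].
#' @return `imageIds`, `classIds`, `scores` return vectors; `boxes` the
#'   4-column coordinate matrix.
#' @name DetectionSet-accessors
NULL

#' @rdname DetectionSet-accessors
#' @export
setGeneric("imageIds", function(x) standardGeneric("imageIds"))
#' @rdname DetectionSet-accessors
#' @export
setMethod("imageIds", "DetectionSet", function(x) x@imageId)

#' @rdname DetectionSet-accessors
#' @export
setGeneric("classIds", function(x) standardGeneric("classIds"))
#' @rdname DetectionSet-accessors
#' @export
setMethod("classIds", "DetectionSet", function(x) x@classId)

#' @rdname DetectionSet-accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @rdname DetectionSet-accessors
#' @export
setMethod("scores", "DetectionSet", function(x) x@score)

#' @rdname DetectionSet-accessors
#' @export
setGeneric("boxes", function(x) standardGeneric("boxes"))
#' @rdname DetectionSet-accessors
#' @export
setMethod("boxes", "DetectionSet", function(x) x@boxes)

#' @describeIn DetectionSet-class subset by index
#' @param i index vector
#' @param j,drop,... ignored
#' @export
setMethod("[", "DetectionSet", function(x, i, j, ..., drop = FALSE) {
  new("DetectionSet",
      imageId = x@imageId[i],
      classId = x@classId[i],
      score   = x@score[i],
      boxes   = x@boxes[i, , drop = FALSE])
})

setMethod("show", "DetectionSet", function(object) {
  n <- length(object)
  kind <- if (n > 0 && all(is.na(object@score))) "annotations" else "detections"
  cat(sprintf("DetectionSet with %d %s over %d image(s), %d class(es)\n",
              n, kind, length(unique(object@imageId)),
              length(unique(object@classId))))
  if (n > 0) {
    k <- min(n, 5L)
    df <- data.frame(imageId = object@imageId[seq_len(k)],
                     classId = object@classId[seq_len(k)],
                     score = object@score[seq_len(k)],
                     object@boxes[seq_len(k), , drop = FALSE])
    print(df, row.names = FALSE)
    if (n > k) cat("...", n - k, "more\n")
  }
})

#' Combine DetectionSets
#' @param x,... DetectionSet objects.
#' @return the row-concatenated [DetectionSet-class].
#' @export
setMethod("c", "DetectionSet", function(x, ...) {
  sets <- c(list(x), list(...))
  new("DetectionSet",
      imageId = unlist(lapply(sets, slot, "imageId")),
      classId = unlist(lapply(sets, slot, "classId")),
      score   = unlist(lapply(sets, slot, "score")),
      boxes   = do.call(rbind, lapply(sets, slot, "boxes")))
})

#' PollenEmbeddings: per-ROI feature vectors with a processing-state flag
#'
#' Rows are samples (one per cropped region of interest), columns the
#' feature components of the extractor's embedding (1024 for the reference
#' backbone). The `state` flag tracks the fixed processing order
#' raw -> l2_normalized -> standardized, each applied exactly once.
#'
#' @slot values numeric sample-by-component matrix; rownames are sample ids.
#' @slot state one of "raw", "l2_normalized", "standardized".
#'
#' @aliases PollenEmbeddings-class
#' @exportClass PollenEmbeddings
setClass("PollenEmbeddings",
  representation(values = "matrix", state = "character"))

setValidity("PollenEmbeddings", function(object) {
  msg <- character()
  if (!object@state %in% c("raw", "l2_normalized", "standardized"))
    msg <- c(msg, "state must be raw, l2_normalized or standardized")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "embedding values must be finite")
  if (object@state == "l2_normalized" && nrow(object@values) > 0) {
    norms <- sqrt(rowSums(object@values^2))
    if (any(abs(norms - 1) > 1e-9))
      msg <- c(msg, "l2_normalized embeddings must have unit row norms (1e-9)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PollenEmbeddings object
#'
#' @param values numeric matrix, rows = samples, columns = components.
#' @param state processing state flag (default `"raw"`).
#' @param ids optional sample ids (stored as rownames).
#' @return A [PollenEmbeddings-class] object.
#' @export
PollenEmbeddings <- function(values, state = "raw", ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(ids)) rownames(values) <- ids
  new("PollenEmbeddings", values = values, state = state)
}

#' Accessors for PollenEmbeddings
#' @param x a [PollenEmbeddings-class].
#' @name PollenEmbeddings-accessors
NULL

#' @rdname PollenEmbeddings-accessors
#' @export
setGeneric("embMatrix", function(x) standardGeneric("embMatrix"))
#' @rdname PollenEmbeddings-accessors
#' @export
setMethod("embMatrix", "PollenEmbeddings", function(x) x@values)

#' @rdname PollenEmbeddings-accessors
#' @export
setGeneric("embState", function(x) standardGeneric("embState"))
#' @rdname PollenEmbeddings-accessors
#' @export
setMethod("embState", "PollenEmbeddings", function(x) x@state)

#' @rdname PollenEmbeddings-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname PollenEmbeddings-accessors
#' @export
setMethod("sampleIds", "PollenEmbeddings", function(x) rownames(x@values))

#' @describeIn PollenEmbeddings-class number of samples
#' @param x a PollenEmbeddings
#' @export
setMethod("nrow", "PollenEmbeddings", function(x) base::nrow(x@values))

setMethod("show", "PollenEmbeddings", function(object) {
  cat(sprintf("PollenEmbeddings: %d sample(s) x %d component(s), state = %s\n",
              base::nrow(object@values), ncol(object@values), object@state))
})

#' Standardizer: per-component z-score statistics fitted on training data
#'
#' Holds the per-component mean and standard deviation estimated on the
#' training embeddings only, so that applying them to held-out data cannot
#' leak test information.
#'
#' @slot mu per-component means.
#' @slot sigma per-component standard deviations (>= 0).
#' @slot kind "population" (1/N, the default) or "sample" (1/(N-1)).
#'
#' @aliases Standardizer-class
#' @exportClass Standardizer
setClass("Standardizer",
  representation(mu = "numeric", sigma = "numeric", kind = "character"))

setValidity("Standardizer", function(object) {
  msg <- character()
  if (length(object@mu) != length(object@sigma))
    msg <- c(msg, "mu and sigma must have equal length")
  if (any(object@sigma < 0)) msg <- c(msg, "sigma must be >= 0")
  if (!object@kind %in% c("population", "sample"))
    msg <- c(msg, "kind must be 'population' or 'sample'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "Standardizer", function(object) {
  cat(sprintf("Standardizer over %d components (%s sd); %d zero-variance component(s)\n",
              length(object@mu), object@kind, sum(object@sigma == 0)))
})

#' LinearProbe: multinomial logistic-regression weights over embeddings
#'
#' The linear probe of the pipeline's third stage: class scores are
#' `w_j' x + b_j` turned into probabilities by the softmax. The probe
#' carries the [Standardizer-class] it was trained with, so prediction can
#' enforce identical preprocessing.
#'
#' @slot W K x D weight matrix (one row per class).
#' @slot b length-K bias vector.
#' @slot classes class names, length K.
#' @slot standardizer the training-set [Standardizer-class].
#' @slot lambda L2 penalty strength used during fitting.
#' @slot seed integer seed recorded for provenance.
#' @slot gradNorm gradient norm at the returned optimum.
#'
#' @aliases LinearProbe-class
#' @exportClass LinearProbe
setClass("LinearProbe",
  representation(W = "matrix", b = "numeric", classes = "character",
                 standardizer = "Standardizer", lambda = "numeric",
                 seed = "integer", gradNorm = "numeric"))

setValidity("LinearProbe", function(object) {
  msg <- character()
  K <- length(object@classes)
  if (K < 2) msg <- c(msg, "need at least 2 classes")
  if (nrow(object@W) != K) msg <- c(msg, "W must have one row per class")
  if (length(object@b) != K) msg <- c(msg, "b must have one entry per class")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LinearProbe", function(object) {
  cat(sprintf("LinearProbe: %d classes x %d features (lambda = %g, |grad| = %.2e)\n",
              nrow(object@W), ncol(object@W), object@lambda, object@gradNorm))
  cat("  classes:", paste(object@classes, collapse = ", "), "\n")
})

#' Accessors for LinearProbe
#' @param x a [LinearProbe-class].
#' @name LinearProbe-accessors
NULL

#' @rdname LinearProbe-accessors
#' @export
setGeneric("probeWeights", function(x) standardGeneric("probeWeights"))
#' @rdname LinearProbe-accessors
#' @export
setMethod("probeWeights", "LinearProbe", function(x) x@W)

#' @rdname LinearProbe-accessors
#' @export
setGeneric("probeBiases", function(x) standardGeneric("probeBiases"))
#' @rdname LinearProbe-accessors
#' @export
setMethod("probeBiases", "LinearProbe", function(x) x@b)

#' @rdname LinearProbe-accessors
#' @export
setGeneric("probeClasses", function(x) standardGeneric("probeClasses"))
#' @rdname LinearProbe-accessors
#' @export
setMethod("probeClasses", "LinearProbe", function(x) x@classes)

#' @rdname LinearProbe-accessors
#' @export
setGeneric("probeStandardizer", function(x) standardGeneric("probeStandardizer"))
#' @rdname LinearProbe-accessors
#' @export
setMethod("probeStandardizer", "LinearProbe", function(x) x@standardizer)

#' PredictionSet: per-sample class probabilities from a linear probe
#'
#' @slot probabilities sample-by-class matrix; rows sum to 1.
#' @slot label predicted class names (argmax, lowest index on ties).
#' @slot confidence maximum class probability per sample.
#'
#' @aliases PredictionSet-class
#' @exportClass PredictionSet
setClass("PredictionSet",
  representation(probabilities = "matrix", label = "character",
                 confidence = "numeric"))

setValidity("PredictionSet", function(object) {
  msg <- character()
  p <- object@probabilities
  if (nrow(p) != length(object@label) || nrow(p) != length(object@confidence))
    msg <- c(msg, "label/confidence length must match probability rows")
  if (nrow(p) > 0) {
    if (any(p < 0) || any(p > 1)) msg <- c(msg, "probabilities must lie in [0, 1]")
    if (any(abs(rowSums(p) - 1) > 1e-9))
      msg <- c(msg, "probability rows must sum to 1 (1e-9)")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PredictionSet", function(object) {
  cat(sprintf("PredictionSet: %d sample(s) x %d class(es); median confidence %.3f\n",
              nrow(object@probabilities), ncol(object@probabilities),
              stats::median(object@confidence)))
})

#' Accessors for PredictionSet
#' @param x a [PredictionSet-class].
#' @name PredictionSet-accessors
NULL

#' @rdname PredictionSet-accessors
#' @export
setGeneric("probabilities", function(x) standardGeneric("probabilities"))
#' @rdname PredictionSet-accessors
#' @export
setMethod("probabilities", "PredictionSet", function(x) x@probabilities)

#' @rdname PredictionSet-accessors
#' @export
setGeneric("predictedLabels", function(x) standardGeneric("predictedLabels"))
#' @rdname PredictionSet-accessors
#' @export
setMethod("predictedLabels", "PredictionSet", function(x) x@label)

#' @rdname PredictionSet-accessors
#' @export
setGeneric("confidences", function(x) standardGeneric("confidences"))
#' @rdname PredictionSet-accessors
#' @export
setMethod("confidences", "PredictionSet", function(x) x@confidence)
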