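# Detection and classification evaluation: greedy matching, confidence
# curves and threshold optimization, average precision, background-aware
# detector confusion, duplicates-per-ground-truth, classifier report and
# calibration (reliability bins, expected calibration error).

#' Greedily match detections to ground truths
#'
#' Detections are visited in descending score order (input order on ties);
#' each claims the still-unmatched ground truth of the same class, in the
#' same image, with the highest IoU at or above the threshold (lowest
#' ground-truth index on ties). Leftover detections are false positives,
#' leftover ground truths false negatives.
#'
#' @param detections scored [DetectionSet-class].
#' @param ground_truths ground-truth [DetectionSet-class].
#' @param iou_threshold match tolerance in (0, 1\] (default 0.5).
#' @return a list of class `"MatchResult"`: `matches` (data.frame with
#'   `det`, `gt`, `iou` indices into the inputs), `fp` and `fn` index
#'   vectors, and the `iou_threshold` used.
#' @export
matchDetections <- function(detections, ground_truths, iou_threshold = 0.5) {
  stopifnot(iou_threshold > 0, iou_threshold <= 1)
  nd <- length(detections); ng <- length(ground_truths)
  matches <- list()
  gtFree <- rep(TRUE, ng)
  if (nd > 0) {
    ord <- order(-scores(detections))
    db <- boxes(detections); gb <- boxes(ground_truths)
    for (i in ord) {
      cand <- which(gtFree &
                    imageIds(ground_truths) == imageIds(detections)[i] &
                    classIds(ground_truths) == classIds(detections)[i])
      if (length(cand) == 0) next
      ious <- iouMatrix(db[i, , drop = FALSE], gb[cand, , drop = FALSE])[1, ]
      ok <- ious >= iou_threshold
      if (!any(ok)) next
      best <- cand[ok][which.max(ious[ok])]  # which.max: lowest index on ties
      gtFree[best] <- FALSE
      matches[[length(matches) + 1]] <- c(det = i, gt = best,
                                          iou = ious[cand == best])
    }
  }
  m <- if (length(matches)) as.data.frame(do.call(rbind, matches))
       else data.frame(det = integer(0), gt = integer(0), iou = numeric(0))
  structure(list(matches = m,
                 fp = setdiff(seq_len(nd), m$det),
                 fn = which(gtFree),
                 iou_threshold = iou_threshold),
            class = "MatchResult")
}

prfFromCounts <- function(tp, fp, fn) {
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f1)
}

#' Default confidence grid for threshold curves
#'
#' All distinct detection scores plus the endpoints 0 and 1 (optionally a
#' regular grid of the given step), so that any reported optimum is
#' exactly representable.
#'
#' @param scores detection confidences.
#' @param step optional regular step to add (e.g. 0.001).
#' @return sorted ascending unique thresholds.
#' @export
confidenceGrid <- function(scores, step = NULL) {
  g <- c(0, scores, 1)
  if (!is.null(step)) g <- c(g, seq(0, 1, by = step))
  sort(unique(g))
}

#' F1 / precision / recall versus confidence threshold
#'
#' At each cutoff the detections with score >= cutoff are re-matched
#' against the ground truths and precision, recall and F1 = 2PR/(P+R)
#' (defined 0 when P + R = 0) are recorded, aggregated over classes and
#' per class.
#'
#' @inheritParams matchDetections
#' @param thresholds ascending confidence grid (default
#'   [confidenceGrid()] of the scores).
#' @return a list of class `"ConfidenceCurve"`: `aggregate` data.frame
#'   (`threshold`, `precision`, `recall`, `f1`) and `per_class`, a named
#'   list of such data.frames.
#' @export
f1ConfidenceCurve <- function(detections, ground_truths, iou_threshold = 0.5,
                              thresholds = NULL) {
  if (is.null(thresholds)) thresholds <- confidenceGrid(scores(detections))
  if (length(thresholds) == 0) stop("f1ConfidenceCurve: empty threshold grid")
  if (is.unsorted(thresholds)) stop("f1ConfidenceCurve: grid must be ascending")
  classes <- sort(unique(c(classIds(detections), classIds(ground_truths))))
  agg <- matrix(0, length(thresholds), 3)
  per <- lapply(classes, function(cl) matrix(0, length(thresholds), 3))
  names(per) <- as.character(classes)
  for (t in seq_along(thresholds)) {
    keep <- scores(detections) >= thresholds[t]
    sub <- detections[which(keep)]
    mr <- matchDetections(sub, ground_truths, iou_threshold)
    tp <- nrow(mr$matches)
    agg[t, ] <- prfFromCounts(tp, length(mr$fp), length(mr$fn))
    for (cl in classes) {
      tpc <- sum(classIds(sub)[mr$matches$det] == cl)
      fpc <- sum(classIds(sub)[mr$fp] == cl)
      fnc <- sum(classIds(ground_truths)[mr$fn] == cl)
      per[[as.character(cl)]][t, ] <- prfFromCounts(tpc, fpc, fnc)
    }
  }
  toDf <- function(m) data.frame(threshold = thresholds, precision = m[, 1],
                                 recall = m[, 2], f1 = m[, 3])
  structure(list(aggregate = toDf(agg), per_class = lapply(per, toDf)),
            class = "ConfidenceCurve")
}

curveDf <- function(curve) {
  if (inherits(curve, "ConfidenceCurve")) curve$aggregate else curve
}

#' Operating threshold by maximum F1
#'
#' @param curve a `"ConfidenceCurve"` (its aggregate is used) or a
#'   data.frame with `threshold` and `f1` columns.
#' @return `c(confidence =, f1 =)`; lowest threshold on ties.
#' @export
bestThresholdMaxF1 <- function(curve) {
  df <- curveDf(curve)
  if (nrow(df) == 0) stop("bestThresholdMaxF1: empty curve")
  i <- which.max(df$f1)  # which.max takes the first (lowest threshold) tie
  c(confidence = df$threshold[i], f1 = df$f1[i])
}

#' Operating threshold by distance to the ideal point (1, 1)
#'
#' Chooses the curve point minimizing
#' `d = sqrt((1 - confidence)^2 + (1 - F1)^2)`, a compromise between high
#' prediction quality and high model confidence.
#'
#' @inheritParams bestThresholdMaxF1
#' @return `c(confidence =, f1 =, d =)`; lowest threshold on ties.
#' @export
bestThresholdIdealPoint <- function(curve) {
  df <- curveDf(curve)
  if (nrow(df) == 0) stop("bestThresholdIdealPoint: empty curve")
  d <- sqrt((1 - df$threshold)^2 + (1 - df$f1)^2)
  i <- which.min(d)
  c(confidence = df$threshold[i], f1 = df$f1[i], d = d[i])
}

# Ranked TP/FP flags and per-class GT count for one class.
rankedFlags <- function(detections, ground_truths, cl, iou_threshold) {
  di <- which(classIds(detections) == cl)
  gi <- which(classIds(ground_truths) == cl)
  di <- di[order(-scores(detections)[di])]  # stable
  gtFree <- rep(TRUE, length(gi))
  tp <- logical(length(di))
  db <- boxes(detections); gb <- boxes(ground_truths)
  for (k in seq_along(di)) {
    i <- di[k]
    cand <- which(gtFree & imageIds(ground_truths)[gi] == imageIds(detections)[i])
    if (length(cand)) {
      ious <- iouMatrix(db[i, , drop = FALSE],
                        gb[gi[cand], , drop = FALSE])[1, ]
      ok <- ious >= iou_threshold
      if (any(ok)) {
        best <- cand[ok][which.max(ious[ok])]
        gtFree[best] <- FALSE
        tp[k] <- TRUE
      }
    }
  }
  list(tp = tp, n_gt = length(gi))
}

apFromFlags <- function(tp, n_gt, interpolation) {
  if (n_gt == 0) return(NA_real_)
  if (length(tp) == 0) return(0)
  cumtp <- cumsum(tp)
  prec <- cumtp / seq_along(tp)
  rec <- cumtp / n_gt
  # precision envelope: max precision at recall >= r
  env <- rev(cummax(rev(prec)))
  if (interpolation == "101") {
    grid <- seq(0, 1, by = 0.01)
    idx <- findInterval(grid, rec, left.open = TRUE) + 1
    p <- ifelse(idx > length(env), 0, env[pmin(idx, length(env))])
    mean(p)
  } else {
    dr <- diff(c(0, rec))
    sum(dr * env)
  }
}

#' Average precision and mean average precision
#'
#' Detections of each class are ranked by descending score (stable) and
#' matched greedily; AP is the area under the precision envelope of the
#' resulting precision-recall curve, by default with COCO-style 101-point
#' interpolation (`interpolation = "all"` gives the exact all-points
#' area). `averagePrecision` returns per-class APs; classes without ground
#' truth are excluded with a warning. `meanAveragePrecision` averages the
#' per-class APs (unweighted), optionally over several IoU thresholds
#' (e.g. `seq(0.5, 0.95, 0.05)` for the strict COCO metric).
#'
#' @inheritParams matchDetections
#' @param interpolation `"101"` (default) or `"all"`.
#' @return `averagePrecision`: named numeric vector of per-class APs.
#' @export
averagePrecision <- function(detections, ground_truths, iou_threshold = 0.5,
                             interpolation = c("101", "all")) {
  interpolation <- match.arg(interpolation)
  classes <- sort(unique(c(classIds(detections), classIds(ground_truths))))
  ap <- vapply(classes, function(cl) {
    f <- rankedFlags(detections, ground_truths, cl, iou_threshold)
    apFromFlags(f$tp, f$n_gt, interpolation)
  }, numeric(1))
  names(ap) <- as.character(classes)
  if (anyNA(ap)) {
    warning("averagePrecision: class(es) without ground truth excluded: ",
            paste(names(ap)[is.na(ap)], collapse = ", "))
    ap <- ap[!is.na(ap)]
  }
  ap
}

#' @rdname averagePrecision
#' @param iou_thresholds one or more IoU thresholds to average over.
#' @return `meanAveragePrecision`: a single number.
#' @export
meanAveragePrecision <- function(detections, ground_truths,
                                 iou_thresholds = 0.5,
                                 interpolation = c("101", "all")) {
  interpolation <- match.arg(interpolation)
  mean(vapply(iou_thresholds, function(th)
    mean(averagePrecision(detections, ground_truths, th, interpolation)),
    numeric(1)))
}

#' Detector confusion matrix with an explicit background category
#'
#' Matched pairs land in the (true class, predicted class) cell; missed
#' ground truths in (true class, background); unmatched detections in
#' (background, predicted class). The (background, background) cell is
#' undefined and left 0. Rows are true categories, columns predicted.
#'
#' @param match a `"MatchResult"` from [matchDetections()] computed at the
#'   operating confidence.
#' @param detections,ground_truths the sets the matching was computed on.
#' @param class_names optional names indexed by class id + 1.
#' @return an integer matrix with a final `"background"` row and column.
#' @export
detectorConfusion <- function(match, detections, ground_truths,
                              class_names = NULL) {
  classes <- sort(unique(c(classIds(detections), classIds(ground_truths))))
  labs <- if (is.null(class_names)) as.character(classes)
          else class_names[classes + 1L]
  k <- length(classes)
  cm <- matrix(0L, k + 1, k + 1,
               dimnames = list(true = c(labs, "background"),
                               predicted = c(labs, "background")))
  idx <- function(cl) base::match(cl, classes)  # `match` arg shadows base
  m <- match$matches
  for (r in seq_len(nrow(m)))
    cm[idx(classIds(ground_truths)[m$gt[r]]),
       idx(classIds(detections)[m$det[r]])] <-
      cm[idx(classIds(ground_truths)[m$gt[r]]),
         idx(classIds(detections)[m$det[r]])] + 1L
  for (i in match$fn)
    cm[idx(classIds(ground_truths)[i]), k + 1] <-
      cm[idx(classIds(ground_truths)[i]), k + 1] + 1L
  for (i in match$fp)
    cm[k + 1, idx(classIds(detections)[i])] <-
      cm[k + 1, idx(classIds(detections)[i])] + 1L
  cm
}

#' Average number of duplicate detections per ground-truth object
#'
#' For each ground truth, counts the detections (in the same image) whose
#' IoU with it reaches `overlap_iou`, and averages over all ground truths.
#' A perfectly deduplicated detector scores 1.0. Computed on post-NMS
#' detections at the operating confidence.
#'
#' @param detections post-NMS [DetectionSet-class].
#' @param ground_truths ground-truth [DetectionSet-class] (>= 1 box).
#' @param overlap_iou counting threshold in (0, 1\] (default 0.5).
#' @return the average count.
#' @export
duplicatesPerGt <- function(detections, ground_truths, overlap_iou = 0.5) {
  stopifnot(overlap_iou > 0, overlap_iou <= 1)
  ng <- length(ground_truths)
  if (ng == 0) stop("duplicatesPerGt: no ground truths")
  if (length(detections) == 0) return(0)
  counts <- vapply(seq_len(ng), function(g) {
    di <- which(imageIds(detections) == imageIds(ground_truths)[g])
    if (length(di) == 0) return(0L)
    ious <- iouMatrix(boxes(ground_truths)[g, , drop = FALSE],
                      boxes(detections)[di, , drop = FALSE])[1, ]
    sum(ious >= overlap_iou)
  }, integer(1))
  mean(counts)
}

#' Classifier report: confusion matrix, per-class precision/recall, accuracy
#'
#' `classifierReport` tallies label pairs; `confusionStats` computes the
#' same summary directly from a confusion matrix with rows = true class,
#' columns = predicted class. Accuracy is trace/total; per-class recall is
#' diagonal/row-sum and precision diagonal/column-sum. A class absent from
#' the truth gets `NA` recall.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param classes optional class ordering (default: sorted union).
#' @return a list: `confusion`, `accuracy`, `precision`, `recall`,
#'   `n_errors`, `n`.
#' @export
classifierReport <- function(y_true, y_pred, classes = NULL) {
  if (length(y_true) != length(y_pred))
    stop("classifierReport: label vectors differ in length")
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  cm <- table(factor(y_true, classes), factor(y_pred, classes))
  cm <- matrix(as.integer(cm), nrow(cm),
               dimnames = list(true = classes, predicted = classes))
  confusionStats(cm)
}

#' @rdname classifierReport
#' @param cm square confusion matrix, rows = true, columns = predicted.
#' @export
confusionStats <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0))
  total <- sum(cm)
  diagv <- diag(cm)
  rowS <- rowSums(cm); colS <- colSums(cm)
  recall <- ifelse(rowS > 0, diagv / rowS, NA_real_)
  precision <- ifelse(colS > 0, diagv / colS, NA_real_)
  list(confusion = cm,
       accuracy = sum(diagv) / total,
       precision = precision,
       recall = recall,
       n_errors = as.integer(total - sum(diagv)),
       n = as.integer(total))
}

#' Expected calibration error and reliability bins
#'
#' Confidences are binned into `n_bins` equal-width bins on \[0, 1\]
#' (right-closed; 0 falls in the first bin). Per bin, the mean confidence
#' and empirical accuracy are compared:
#' `ECE = sum_b (n_b / N) |acc_b - conf_b|`; empty bins contribute 0.
#'
#' @param confidences predicted confidences in \[0, 1\].
#' @param correct logical (or 0/1) correctness flags.
#' @param n_bins number of bins (default 10).
#' @return a list of class `"CalibrationResult"`: `bin_edges`,
#'   `bin_confidence`, `bin_accuracy`, `bin_count`, `ece`.
#' @export
expectedCalibrationError <- function(confidences, correct, n_bins = 10) {
  n <- length(confidences)
  if (n == 0) stop("expectedCalibrationError: empty input")
  stopifnot(length(correct) == n, n_bins >= 1,
            all(confidences >= 0), all(confidences <= 1))
  correct <- as.numeric(correct)
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- clamp(ceiling(confidences * n_bins), 1, n_bins)
  cnt <- tabulate(bin, n_bins)
  conf_b <- acc_b <- rep(NA_real_, n_bins)
  occupied <- which(cnt > 0)
  for (b in occupied) {
    sel <- bin == b
    conf_b[b] <- mean(confidences[sel])
    acc_b[b] <- mean(correct[sel])
  }
  ece <- sum((cnt[occupied] / n) * abs(acc_b[occupied] - conf_b[occupied]))
  structure(list(bin_edges = edges, bin_confidence = conf_b,
                 bin_accuracy = acc_b, bin_count = cnt, ece = ece),
            class = "CalibrationResult")
}
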