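test_that("greedy matching assigns each detection and truth at most once", {
  gt <- annotationSet("i", 0L, rbind(c(0, 0, 10, 10), c(50, 50, 70, 70)))
  # detections identical to ground truths -> all TP
  det <- DetectionSet("i", 0L, c(0.9, 0.8), boxes(gt))
  mr <- matchDetections(det, gt, 0.5)
  expect_equal(nrow(mr$matches), 2)
  expect_length(mr$fp, 0); expect_length(mr$fn, 0)

  # two detections over one GT: 1 TP + 1 FP
  d2 <- DetectionSet("i", 0L, c(0.9, 0.7),
                     rbind(c(0, 0, 10, 10), c(1, 0, 11, 10)))
  g1 <- annotationSet("i", 0L, c(0, 0, 10, 10))
  mr2 <- matchDetections(d2, g1, 0.5)
  expect_equal(nrow(mr2$matches), 1)
  expect_equal(mr2$matches$det, 1)  # higher score claims the GT
  expect_equal(mr2$fp, 2L)

  # IoU below threshold -> 1 FP and 1 FN
  d3 <- DetectionSet("i", 0L, 0.9, c(0, 0, 10, 9))
  g3 <- annotationSet("i", 0L, c(0, 4.9, 10, 15))
  expect_lt(iou(boxes(d3)[1, ], boxes(g3)[1, ]), 0.5)
  mr3 <- matchDetections(d3, g3, 0.5)
  expect_equal(nrow(mr3$matches), 0)
  expect_equal(mr3$fp, 1L); expect_equal(mr3$fn, 1L)

  # class- and image-aware: same box, different class or image, no match
  d4 <- DetectionSet(c("i", "j"), c(1L, 0L), c(0.9, 0.8),
                     rbind(c(0, 0, 10, 10), c(0, 0, 10, 10)))
  expect_equal(nrow(matchDetections(d4, g1, 0.5)$matches), 0)
})

test_that("matching agrees with the brute-force reference on random instances", {
  withr::with_seed(23, {
    for (rep in 1:60) {
      det <- randomInstance(sample(1:50, 1), n_classes = sample(1:3, 1))
      gt <- randomInstance(sample(1:30, 1), n_classes = sample(1:3, 1))
      gt@score <- rep(NA_real_, length(gt))
      thr <- runif(1, 0.3, 0.8)
      mr <- matchDetections(det, gt, thr)
      ref <- matchRef(det, gt, thr)
      if (is.null(ref)) {
        expect_equal(nrow(mr$matches), 0)
      } else {
        expect_equal(mr$matches$det[order(mr$matches$det)], sort(ref[, 1]))
        expect_equal(mr$matches$gt[order(mr$matches$det)],
                     ref[order(ref[, 1]), 2])
      }
      expect_true(all(mr$matches$iou >= thr))
      expect_equal(anyDuplicated(mr$matches$gt), 0L)
    }
  })
})

test_that("F1-confidence curve rematches at each cutoff", {
  gt <- annotationSet("i", 0L, c(0, 0, 10, 10))
  det <- DetectionSet("i", 0L, c(0.9, 0.3),
                      rbind(c(0, 0, 10, 10), c(80, 80, 95, 95)))
  curve <- f1ConfidenceCurve(det, gt, 0.5, thresholds = c(0.2, 0.5))
  expect_equal(curve$aggregate$f1[curve$aggregate$threshold == 0.5], 1)
  expect_equal(curve$aggregate$precision[curve$aggregate$threshold == 0.2], 0.5)
  expect_equal(curve$aggregate$f1[curve$aggregate$threshold == 0.2], 2 / 3,
               tolerance = 1e-12)
  expect_error(f1ConfidenceCurve(det, gt, 0.5, thresholds = numeric(0)),
               "empty")

  # recall is non-increasing in the threshold; F1 maximal at the optimum
  withr::with_seed(29, {
    for (rep in 1:10) {
      det <- randomInstance(sample(5:40, 1))
      gtr <- randomInstance(sample(5:20, 1))
      gtr@score <- rep(NA_real_, length(gtr))
      cv <- f1ConfidenceCurve(det, gtr, 0.5)
      expect_false(is.unsorted(rev(cv$aggregate$recall)))
      best <- bestThresholdMaxF1(cv)
      expect_true(all(cv$aggregate$f1 <= best["f1"] + 1e-12))
    }
  })
})

test_that("threshold optimizers pick max F1 and nearest-to-ideal points", {
  curve <- data.frame(threshold = c(0.2, 0.8), precision = NA, recall = NA,
                      f1 = c(0.9, 0.6))
  expect_equal(unname(bestThresholdMaxF1(curve)), c(0.2, 0.9))
  # d: sqrt(0.8^2 + 0.1^2) = 0.8062 vs sqrt(0.2^2 + 0.4^2) = 0.4472
  ideal <- bestThresholdIdealPoint(curve)
  expect_equal(unname(ideal), c(0.8, 0.6, sqrt(0.04 + 0.16)),
               tolerance = 1e-6)

  one <- data.frame(threshold = 0.4, f1 = 0.7)
  expect_equal(unname(bestThresholdMaxF1(one)), c(0.4, 0.7))
  tie <- data.frame(threshold = c(0.3, 0.5), f1 = c(0.8, 0.8))
  expect_equal(unname(bestThresholdMaxF1(tie)["confidence"]), 0.3)
  perfect <- data.frame(threshold = c(0.5, 1), f1 = c(0.9, 1))
  expect_equal(unname(bestThresholdIdealPoint(perfect)["d"]), 0)

  # when the max-F1 point is nearest to (1,1), the optimizers coincide
  withr::with_seed(33, {
    for (rep in 1:10) {
      det <- randomInstance(30)
      gtr <- randomInstance(15)
      gtr@score <- rep(NA_real_, length(gtr))
      cv <- f1ConfidenceCurve(det, gtr, 0.5)
      mf <- bestThresholdMaxF1(cv)
      ip <- bestThresholdIdealPoint(cv)
      d_mf <- sqrt((1 - mf["confidence"])^2 + (1 - mf["f1"])^2)
      if (abs(d_mf - ip["d"]) < 1e-12 && mf["confidence"] == ip["confidence"])
        expect_equal(unname(mf["confidence"]), unname(ip["confidence"]))
      expect_lte(unname(ip["d"]), unname(d_mf) + 1e-12)
    }
  })
})

test_that("average precision matches hand cases and the all-points oracle", {
  gt <- annotationSet("i", 0L, c(0, 0, 10, 10))
  perfect <- DetectionSet("i", 0L, 0.9, c(0, 0, 10, 10))
  expect_equal(unname(averagePrecision(perfect, gt, 0.5)), 1)

  # FP ranked above the TP: precision envelope 0.5 everywhere
  mixed <- DetectionSet("i", 0L, c(0.9, 0.8),
                        rbind(c(50, 50, 60, 60), c(0, 0, 10, 10)))
  expect_equal(unname(averagePrecision(mixed, gt, 0.5)), 0.5)
  expect_equal(unname(averagePrecision(mixed, gt, 0.5, "all")), 0.5)

  expect_warning(
    ap <- averagePrecision(DetectionSet("i", 1L, 0.9, c(0, 0, 5, 5)),
                           gt, 0.5),
    "without ground truth")

  withr::with_seed(37, {
    for (rep in 1:60) {
      gtr <- randomInstance(sample(20:40, 1), n_classes = 2)
      gtr@score <- rep(NA_real_, length(gtr))
      det <- generateDetectorOutput(gtr,
        detectorNoiseSpec(jitter_sd = 6, miss_prob = 0.2, fp_rate = 3,
                          dup_prob = 0.1), seed = rep, 200, 200)
      for (cl in unique(classIds(gtr))) {
        refAp <- apRef(det, gtr, cl, 0.5)
        got <- averagePrecision(det, gtr, 0.5, "all")[as.character(cl)]
        expect_equal(unname(got), refAp, tolerance = 1e-9)
        got101 <- averagePrecision(det, gtr, 0.5, "101")[as.character(cl)]
        expect_lt(abs(unname(got101) - refAp), 0.01)
      }
    }
  })
})

test_that("detector confusion books matches, misses and strays correctly", {
  # 3 GTs of class A: 2 matched, 1 missed, plus 1 stray detection
  gt <- annotationSet("i", 0L, rbind(c(0, 0, 10, 10), c(20, 20, 30, 30),
                                     c(40, 40, 50, 50)))
  det <- DetectionSet("i", 0L, c(0.9, 0.8, 0.7),
                      rbind(c(0, 0, 10, 10), c(20, 20, 30, 30),
                            c(80, 80, 95, 95)))
  mr <- matchDetections(det, gt, 0.5)
  cm <- detectorConfusion(mr, det, gt, class_names = c("A"))
  expect_equal(cm["A", "A"], 2L)
  expect_equal(cm["A", "background"], 1L)
  expect_equal(cm["background", "A"], 1L)
  expect_equal(cm["background", "background"], 0L)
  # row sums conserve GTs, column sums detections (background row/col aside)
  expect_equal(sum(cm["A", ]), 3L)
  expect_equal(sum(cm[, "A"]), 3L)

  withr::with_seed(43, {
    det <- randomInstance(25, 2)
    gtr <- randomInstance(18, 2)
    gtr@score <- rep(NA_real_, length(gtr))
    mr <- matchDetections(det, gtr, 0.5)
    cm <- detectorConfusion(mr, det, gtr)
    k <- nrow(cm) - 1
    expect_equal(sum(cm[seq_len(k), ]), length(gtr))
    expect_equal(sum(cm[, seq_len(k)]), length(det))
  })
})

test_that("duplicates per ground truth averages overlap counts", {
  gt <- annotationSet("i", 0L, rbind(c(0, 0, 10, 10), c(50, 50, 60, 60)))
  one <- DetectionSet("i", 0L, c(0.9, 0.8), boxes(gt))
  expect_equal(duplicatesPerGt(one, gt, 0.5), 1)
  # GT1 overlapped by 3, GT2 by 1 -> (3+1)/2
  multi <- DetectionSet("i", 0L, c(0.9, 0.8, 0.7, 0.6),
                        rbind(c(0, 0, 10, 10), c(0.5, 0, 10.5, 10),
                              c(0, 0.5, 10, 10.5), c(50, 50, 60, 60)))
  expect_equal(duplicatesPerGt(multi, gt, 0.5), 2)
  # adding a detection that overlaps nothing changes nothing
  plus <- c(multi, DetectionSet("i", 0L, 0.5, c(500, 500, 510, 510)))
  expect_equal(duplicatesPerGt(plus, gt, 0.5), 2)
  expect_error(duplicatesPerGt(one, annotationSet(character(0), integer(0),
                                                  matrix(numeric(0), 0, 4))),
               "no ground truths")
})

test_that("classifier report reproduces hand-tallied statistics", {
  r <- classifierReport(c(0, 0, 1, 1), c(0, 1, 1, 1))
  expect_equal(r$accuracy, 0.75)
  expect_equal(unname(r$recall), c(0.5, 1))
  expect_equal(unname(r$precision), c(1, 2 / 3), tolerance = 1e-12)
  expect_equal(r$n_errors, 1L)

  perfect <- classifierReport(c("a", "b", "b"), c("a", "b", "b"))
  expect_equal(perfect$accuracy, 1)
  expect_equal(unname(perfect$precision), c(1, 1))

  expect_error(classifierReport(1:3, 1:4), "length")
  # class never present in the truth: NA recall
  miss <- classifierReport(c("a", "a"), c("a", "b"), classes = c("a", "b"))
  expect_true(is.na(miss$recall["b"]))
})

test_that("expected calibration error matches hand binning and simulation", {
  expect_equal(expectedCalibrationError(rep(1, 5), rep(TRUE, 5))$ece, 0)
  # one bin at confidence 0.8, accuracy 0.5
  e <- expectedCalibrationError(c(0.8, 0.8), c(TRUE, FALSE), 10)
  expect_equal(e$ece, 0.3, tolerance = 1e-12)
  expect_equal(sum(e$bin_count), 2)
  expect_error(expectedCalibrationError(numeric(0), logical(0)), "empty")

  sim <- generateCalibratedPredictions(10000, 0, seed = 21)
  expect_lt(expectedCalibrationError(sim$confidences, sim$correct, 10)$ece,
            0.02)
})

test_that("ECE decreases as simulated predictions become better calibrated", {
  eces <- vapply(c(0.3, 0.15, 0), function(mis) {
    sim <- generateCalibratedPredictions(8000, -mis, seed = 31)
    expectedCalibrationError(sim$confidences, sim$correct, 10)$ece
  }, numeric(1))
  expect_false(is.unsorted(rev(eces)))
})

test_that("measured precision/recall recover injected detector error rates", {
  withr::with_seed(47, {
    nimg <- 50
    gt <- do.call(c, lapply(seq_len(nimg), function(i) {
      n <- 40
      x0 <- runif(n, 0, 2400); y0 <- runif(n, 0, 1700)
      annotationSet(sprintf("im%02d", i), 0L,
                    cbind(x0, y0, x0 + runif(n, 60, 140),
                          y0 + runif(n, 60, 140)))
    }))
  })
  expect_equal(length(gt), 2000L)
  miss <- 0.2
  det <- generateDetectorOutput(gt, detectorNoiseSpec(
    jitter_sd = 2, miss_prob = miss, fp_rate = 0, dup_prob = 0), seed = 11)
  mr <- matchDetections(det, gt, 0.5)
  recall <- nrow(mr$matches) / length(gt)
  se <- sqrt(miss * (1 - miss) / length(gt))
  expect_lt(abs(recall - (1 - miss)), 3 * se)

  # with false positives, precision approaches TP / (TP + FP)
  det2 <- generateDetectorOutput(gt, detectorNoiseSpec(
    jitter_sd = 2, miss_prob = 0, fp_rate = 8, dup_prob = 0), seed = 13)
  mr2 <- matchDetections(det2, gt, 0.5)
  prec <- nrow(mr2$matches) / length(det2)
  nfp <- length(det2) - 2000
  expect_equal(prec, 2000 / (2000 + nfp), tolerance = 0.01)
})
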