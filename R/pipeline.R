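# Config-driven orchestration of the three-stage pipeline with fixture
# backends: synthetic slides -> fixture detector (ground truth + noise) ->
# NMS -> context expansion -> ROI crop -> fixture embedder (class-keyed
# cluster draw) -> L2 -> standardize -> linear probe -> evaluation.
#
# Neural backends (the real detector and feature extractor) live outside
# this package; the fixture backends exercise every stage contract at desk
# scale with known ground truth.

#' Pipeline configuration
#'
#' All randomness is funnelled through `seed`; rerunning with an identical
#' configuration and seed reproduces every artifact byte for byte.
#'
#' @param seed master integer seed.
#' @param out_dir run directory (default: fresh temporary directory).
#' @param images_per_class synthetic slides generated per class.
#' @param slide a [slideSpec()].
#' @param noise a [detectorNoiseSpec()] for the fixture detector.
#' @param embed an [embeddingClusterSpec()] for the fixture embedder.
#' @param post post-processing: `nms_iou` (default 0.65), `pad_ratio`
#'   (default 0.12), `class_aware`, `operating_confidence` (default 0.25;
#'   specific to the fixture backend and recalibrated per real backend).
#' @param probe probe hyperparameters: `lambda`.
#' @param eval evaluation settings: `match_iou`, `ece_bins`.
#' @param split train/val/test fractions at the image level.
#' @param evaluate write evaluation reports (default `TRUE`).
#' @param write_rois write cropped ROIs as flat CSV rasters (default
#'   `FALSE`; crops are still computed).
#' @return a list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(seed = 1L, out_dir = NULL, images_per_class = 6,
                           slide = slideSpec(),
                           noise = detectorNoiseSpec(),
                           embed = embeddingClusterSpec(),
                           post = list(),
                           probe = list(),
                           eval = list(),
                           split = c(train = 0.5, val = 0, test = 0.5),
                           evaluate = TRUE, write_rois = FALSE) {
  post <- utils::modifyList(list(nms_iou = 0.65, pad_ratio = 0.12,
                                 class_aware = TRUE,
                                 operating_confidence = 0.25), post)
  probe <- utils::modifyList(list(lambda = 1), probe)
  eval <- utils::modifyList(list(match_iou = 0.5, ece_bins = 10), eval)
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 images_per_class = images_per_class, slide = slide,
                 noise = noise, embed = embed, post = post, probe = probe,
                 eval = eval, split = unname(split), evaluate = evaluate,
                 write_rois = write_rois),
            class = "PipelineConfig")
}

#' Run the three-stage pipeline on fixture backends
#'
#' Executes detect -> NMS -> expand -> crop -> embed -> L2 -> standardize
#' -> probe -> evaluate, writing the run directory layout
#' `detections.jsonl`, `embeddings.csv`, `model.json`, `preds.csv`,
#' `report.json`, `curves.csv`, `config.resolved.yaml`, `run.log`.
#'
#' @param config a [pipelineConfig()].
#' @return the report list, invisibly; its `out_dir` element names the run
#'   directory.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  out_dir <- config$out_dir
  if (is.null(out_dir)) out_dir <- tempfile("melissoscan-run-")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))
  cfg_hash <- contentHash(config[setdiff(names(config), "out_dir")])
  say("run start: seed=%d config=%s", config$seed, cfg_hash)

  spec <- config$slide
  K <- length(spec$mean_grains)
  W <- spec$width; H <- spec$height
  seed <- config$seed

  # stage 1: slides + fixture detector + NMS + expansion + crop, per image
  gt <- list(); postnms <- list(); opdets <- list()
  roiOwner <- list()  # per operating detection: image id
  imgIds <- character(0); imgClass <- integer(0)
  nRois <- 0
  for (cl in seq_len(K) - 1L) {
    for (i in seq_len(config$images_per_class)) {
      id <- sprintf("%s_%02d", spec$class_names[cl + 1], i)
      slide <- generateSlide(spec, cl, deriveSeed(seed, "slide", id), id)
      dets <- generateDetectorOutput(slide$annotations, config$noise,
                                     deriveSeed(seed, "detect", id), W, H)
      kept <- nms(dets, config$post$nms_iou, config$post$class_aware)
      op <- kept[which(scores(kept) >= config$post$operating_confidence)]
      if (length(op) > 0) {
        eb <- expandBox(boxes(op), config$post$pad_ratio, W, H)
        op@boxes <- asBoxMatrix(eb)
        for (r in seq_len(length(op))) {
          roi <- cropRoi(slide$image, boxes(op)[r, ])
          nRois <- nRois + 1
          if (config$write_rois) {
            utils::write.csv(roi, file.path(out_dir, sprintf(
              "roi_%s_%03d.csv", id, r)), row.names = FALSE)
          }
        }
      }
      gt[[id]] <- slide$annotations
      postnms[[id]] <- kept
      opdets[[id]] <- op
      imgIds <- c(imgIds, id); imgClass <- c(imgClass, cl)
      say("image %s: %d gt, %d raw, %d post-nms, %d operating",
          id, length(slide$annotations), length(dets), length(kept),
          length(op))
    }
  }
  gtAll <- do.call(c, unname(gt))
  postAll <- do.call(c, unname(postnms))
  opAll <- do.call(c, unname(opdets))
  writeDetectionsJsonl(postAll, file.path(out_dir, "detections.jsonl"))

  # image-level split (stratified by the slide's single taxon)
  sp <- splitDataset(imgIds, fractions = config$split,
                     seed = deriveSeed(seed, "split"),
                     stratify_by = imgClass)
  say("split: %d train / %d val / %d test images",
      length(sp$train), length(sp$val), length(sp$test))

  # stage 2: fixture embedder, keyed by the matched ground-truth class
  keys <- rep(NA_integer_, length(opAll))
  for (j in seq_len(length(opAll))) {
    gi <- which(imageIds(gtAll) == imageIds(opAll)[j])
    if (length(gi) == 0) next
    ious <- iouMatrix(boxes(opAll)[j, , drop = FALSE],
                      boxes(gtAll)[gi, , drop = FALSE])[1, ]
    if (max(ious) >= config$eval$match_iou)
      keys[j] <- classIds(gtAll)[gi[which.max(ious)]]
  }
  embRaw <- sampleClassEmbeddings(config$embed, keys,
                                  deriveSeed(seed, "embed"))
  embL2 <- l2Normalize(embRaw)
  say("embedded %d ROIs (%d matched to ground truth)",
      length(keys), sum(!is.na(keys)))

  # stage 3: standardize (train statistics only) + linear probe
  inTrain <- imageIds(opAll) %in% sp$train & !is.na(keys)
  inTest <- imageIds(opAll) %in% sp$test & !is.na(keys)
  zstats <- fitStandardizer(embMatrix(embL2)[inTrain, , drop = FALSE])
  embStd <- applyStandardizer(embL2, zstats)
  classNames <- spec$class_names[seq_len(K)]
  probe <- fitLinearProbe(embMatrix(embStd)[inTrain, , drop = FALSE],
                          factor(classNames[keys[inTrain] + 1L],
                                 levels = classNames),
                          lambda = config$probe$lambda,
                          standardizer = zstats, seed = seed)
  writeProbeModel(probe, file.path(out_dir, "model.json"))
  preds <- predictProba(probe, embMatrix(embStd))
  utils::write.csv(
    data.frame(image_id = imageIds(opAll), score = scores(opAll),
               matched_class = keys, label = predictedLabels(preds),
               confidence = confidences(preds)),
    file.path(out_dir, "preds.csv"), row.names = FALSE)
  embOut <- embMatrix(embL2)
  colnames(embOut) <- sprintf("f_%04d", seq_len(ncol(embOut)))
  utils::write.csv(cbind(data.frame(id = seq_len(nrow(embOut))), embOut),
                   file.path(out_dir, "embeddings.csv"), row.names = FALSE)

  report <- list(schema_version = 1L, seed = config$seed,
                 config_hash = cfg_hash,
                 n_images = length(imgIds), n_rois = nRois,
                 split = sp[c("train", "val", "test")])

  if (isTRUE(config$evaluate)) {
    testImgs <- sp$test
    gtTest <- gtAll[which(imageIds(gtAll) %in% testImgs)]
    postTest <- postAll[which(imageIds(postAll) %in% testImgs)]
    opTest <- opAll[which(imageIds(opAll) %in% testImgs)]

    curve <- f1ConfidenceCurve(postTest, gtTest, config$eval$match_iou)
    maxf1 <- bestThresholdMaxF1(curve)
    ideal <- bestThresholdIdealPoint(curve)
    ap <- averagePrecision(postTest, gtTest, config$eval$match_iou)
    mr <- matchDetections(opTest, gtTest, config$eval$match_iou)
    conf_bg <- detectorConfusion(mr, opTest, gtTest, classNames)
    tp <- nrow(mr$matches)
    det_prf <- prfFromCounts(tp, length(mr$fp), length(mr$fn))
    dup <- duplicatesPerGt(opTest, gtTest, config$eval$match_iou)

    testSel <- which(inTest)
    clsTruth <- classNames[keys[testSel] + 1L]
    clsPred <- predictedLabels(preds)[testSel]
    clsReport <- classifierReport(clsTruth, clsPred, classNames)
    sil <- if (length(unique(clsTruth)) >= 2)
      silhouetteCosine(embMatrix(embL2)[testSel, , drop = FALSE], clsTruth)
    else list(values = numeric(0), mean = NA_real_)
    cal <- expectedCalibrationError(confidences(preds)[testSel],
                                    clsPred == clsTruth,
                                    config$eval$ece_bins)
    hist <- confidenceHistogram(new("PredictionSet",
      probabilities = probabilities(preds)[testSel, , drop = FALSE],
      label = clsPred, confidence = confidences(preds)[testSel]))

    report$detection <- list(
      map50 = mean(ap), ap_per_class = as.list(ap),
      best_threshold_max_f1 = as.list(maxf1),
      best_threshold_ideal_point = as.list(ideal),
      operating = c(as.list(det_prf),
                    list(confidence = config$post$operating_confidence)),
      duplicates_per_gt = dup,
      confusion_with_background = unname(apply(conf_bg, 1, as.list)))
    report$classification <- list(
      accuracy = clsReport$accuracy,
      n = clsReport$n, n_errors = clsReport$n_errors,
      precision = as.list(clsReport$precision),
      recall = as.list(clsReport$recall),
      confusion = unname(apply(clsReport$confusion, 1, as.list)),
      silhouette_mean = sil$mean,
      ece = cal$ece,
      confidence_histogram = hist$counts)
    utils::write.csv(curve$aggregate, file.path(out_dir, "curves.csv"),
                     row.names = FALSE)
    say("evaluation: mAP@%.2f=%.4f, probe accuracy=%.4f, ece=%.4f",
        config$eval$match_iou, mean(ap), clsReport$accuracy, cal$ece)
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  yaml::write_yaml(config, file.path(out_dir, "config.resolved.yaml"))
  writeLines(log, file.path(out_dir, "run.log"))
  report$out_dir <- out_dir
  invisible(report)
}

#' Parameter ablation over the pipeline
#'
#' Re-runs the full pipeline for each value of one post-processing
#' parameter, everything else (including the seed) held fixed.
#' For `nms_iou` the table reports detection recall and duplicates per
#' ground truth at the operating confidence; for `pad_ratio` the
#' classification accuracy on correctly matched ROIs.
#'
#' @param config a [pipelineConfig()].
#' @param parameter `"nms_iou"` or `"pad_ratio"`.
#' @param values non-empty numeric vector to sweep.
#' @return a data.frame, one row per value.
#' @export
runAblation <- function(config, parameter = c("nms_iou", "pad_ratio"),
                        values) {
  parameter <- match.arg(parameter)
  if (length(values) == 0) stop("runAblation: empty value list")
  base_dir <- config$out_dir
  if (is.null(base_dir)) base_dir <- tempfile("melissoscan-ablation-")
  rows <- lapply(values, function(v) {
    cfg <- config
    cfg$post[[parameter]] <- v
    cfg$out_dir <- file.path(base_dir, sprintf("%s_%g", parameter, v))
    rep <- runPipeline(cfg)
    if (parameter == "nms_iou")
      data.frame(nms_iou = v,
                 recall = rep$detection$operating$recall,
                 duplicates_per_gt = rep$detection$duplicates_per_gt)
    else
      data.frame(pad_ratio = v,
                 matched_accuracy = rep$classification$accuracy)
  })
  out <- do.call(rbind, rows)
  attr(out, "out_dir") <- base_dir
  out
}
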