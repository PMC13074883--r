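test_that("YOLO labels parse to pixel boxes with order preserved", {
  ann <- readYoloLabels(c("0 0.5 0.5 0.1 0.2", "1 0.25 0.25 0.1 0.1"),
                        2576, 1932, image_id = "img")
  expect_equal(length(ann), 2L)
  expect_equal(classIds(ann), c(0L, 1L))
  expect_equal(unname(boxes(ann)[1, ]),
               c(1159.2, 772.8, 1416.8, 1159.2), tolerance = 1e-12)
  # center comes out where the format says it should
  expect_equal(unname((boxes(ann)[1, c(1, 2)] + boxes(ann)[1, c(3, 4)]) / 2),
               c(1288, 966))
  expect_equal(length(readYoloLabels(character(0), 100, 100)), 0L)
})

test_that("malformed YOLO lines are rejected with the line number", {
  expect_error(readYoloLabels("0 0.5 0.5 1.5 0.2", 100, 100), "line 1")
  expect_error(readYoloLabels(c("0 0.5 0.5 0.1 0.1", "0 0.5 0.5"), 100, 100),
               "line 2")
  expect_error(readYoloLabels("0 a 0.5 0.1 0.1", 100, 100), "non-numeric")
  expect_error(readYoloLabels("-1 0.5 0.5 0.1 0.1", 100, 100), "class")
})

test_that("YOLO write/read round-trips boxes and rejects out-of-bounds", {
  full <- annotationSet("im", 1L, c(0, 0, 2576, 1932))
  line <- writeYoloLabels(full, 2576, 1932)
  expect_equal(as.numeric(strsplit(line, " ")[[1]]), c(1, 0.5, 0.5, 1, 1))

  withr::with_seed(42, {
    for (rep in 1:20) {
      W <- sample(500:3000, 1); H <- sample(400:2000, 1)
      n <- sample(1:30, 1)
      x0 <- runif(n, 0, W - 50); y0 <- runif(n, 0, H - 50)
      ann <- annotationSet("im", sample(0:2, n, replace = TRUE),
                           cbind(x0, y0, x0 + runif(n, 1, 50),
                                 y0 + runif(n, 1, 50)))
      back <- readYoloLabels(writeYoloLabels(ann, W, H), W, H)
      expect_lt(max(abs(boxes(back) - boxes(ann))), 1e-6 * max(W, H))
      expect_equal(classIds(back), classIds(ann))
    }
  })
  expect_error(writeYoloLabels(annotationSet("im", 0L, c(0, 0, 200, 50)),
                               100, 100), "bounds")
  expect_length(writeYoloLabels(emptyAnn <- annotationSet(character(0),
                                integer(0), matrix(numeric(0), 0, 4)),
                                100, 100), 0)
})

test_that("dataset split is a seeded partition honoring counts and strata", {
  ids <- sprintf("img%03d", 1:101)
  taxon <- rep(c("hazel", "dandelion"), c(50, 51))
  sp <- splitDataset(ids, counts = c(54, 16, 12), seed = 7,
                     stratify_by = taxon)
  expect_length(sp$train, 54)
  expect_length(sp$val, 16)
  expect_length(sp$test, 12)
  all_ids <- c(sp$train, sp$val, sp$test, sp$unused)
  expect_setequal(all_ids, ids)          # coverage
  expect_equal(anyDuplicated(all_ids), 0L)  # disjointness
  # same seed, same input order -> identical assignment
  sp2 <- splitDataset(ids, counts = c(54, 16, 12), seed = 7,
                      stratify_by = taxon)
  expect_identical(sp[1:4], sp2[1:4])

  spAll <- splitDataset(ids, fractions = c(1, 0, 0), seed = 1)
  expect_setequal(spAll$train, ids)
  expect_length(spAll$val, 0)
  expect_length(spAll$test, 0)

  expect_error(splitDataset(ids, counts = c(200, 0, 0)), "exceed")
})

test_that("split partition property holds across random instances", {
  withr::with_seed(11, {
    for (rep in 1:15) {
      n <- sample(10:200, 1)
      ids <- sprintf("i%04d", seq_len(n))
      fr <- c(0.6, 0.2, 0.2)
      sp <- splitDataset(ids, fractions = fr, seed = rep)
      got <- c(sp$train, sp$val, sp$test, sp$unused)
      expect_setequal(got, ids)
      expect_equal(anyDuplicated(got), 0L)
      expect_equal(length(sp$train) + length(sp$val) + length(sp$test), n)
    }
  })
})

test_that("oversampling balances classes by whole-image repetition", {
  # majority class needs no repetition: 35 sources x (1+5 variants) = 210
  ids <- c(sprintf("dand%02d", 1:35), sprintf("haz%02d", 1:19))
  cls <- rep(c("dandelion", "hazel"), c(35, 19))
  os <- oversampleMinority(ids, cls, target_per_class = 210,
                           variants_per_image = 5, seed = 3)
  expect_length(os$dandelion, 35)
  expect_equal(sum(attr(os$dandelion, "repeats")), 0L)
  expect_equal(length(os$dandelion) * 6, 210)
  # minority: 19 sources + 16 repeated slots, all drawn from the sources
  expect_length(os$hazel, 35)
  expect_equal(sum(attr(os$hazel, "repeats")), 16L)
  expect_true(all(os$hazel %in% ids[cls == "hazel"]))
  expect_equal(length(os$hazel) * 6, 210)

  # target equal to existing count, 0 variants -> identity multiset
  osId <- oversampleMinority(ids[1:5], rep("a", 5), 5, 0, seed = 1)
  expect_identical(as.character(osId$a), ids[1:5])

  expect_error(oversampleMinority(ids[1:5], rep("a", 5), 3, 0, seed = 1),
               "already has")
  expect_warning(oversampleMinority(ids[1:5], rep("a", 5), 31, 1, seed = 1),
                 "divisible")
})

test_that("oversampling never crosses split boundaries (leakage check)", {
  ids <- sprintf("i%03d", 1:40)
  cls <- rep(c("a", "b"), each = 20)
  sp <- splitDataset(ids, fractions = c(0.5, 0.25, 0.25), seed = 5,
                     stratify_by = cls)
  trainCls <- cls[match(sp$train, ids)]
  os <- oversampleMinority(sp$train, trainCls, target_per_class = 30,
                           variants_per_image = 2, seed = 5)
  sampled <- unlist(lapply(os, as.character))
  expect_length(intersect(sampled, sp$val), 0)
  expect_length(intersect(sampled, sp$test), 0)
})

test_that("dataset summary tabulates per-class density", {
  ann <- c(annotationSet(rep(c("a", "b"), c(3, 2)), 0L,
                         cbind(0, 0, 1:5 * 10, 1:5 * 10)),
           annotationSet("c", 1L, c(0, 0, 10, 10)))
  ds <- datasetSummary(ann, class_names = c("dandelion", "hazel"))
  expect_equal(ds$n_images, c(2, 1))
  expect_equal(ds$n_grains, c(5, 1))
  expect_equal(ds$mean_density, c(2.5, 1))
  expect_equal(ds$class, c("dandelion", "hazel"))
})
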