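# Independent brute-force reference implementations and random-instance
# generators. Deliberately written as plain loops over box pairs, separate
# from the package's vectorized code paths.

iouRef <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  areaA <- (a[3] - a[1]) * (a[4] - a[2])
  areaB <- (b[3] - b[1]) * (b[4] - b[2])
  inter / (areaA + areaB - inter)
}

# Greedy NMS, literal transcription: repeatedly take the highest-scoring
# remaining detection, discard all same-class overlapping ones.
nmsRef <- function(det, thr, class_aware = TRUE) {
  n <- length(det)
  if (n == 0) return(integer(0))
  remaining <- seq_len(n)
  kept <- integer(0)
  sc <- scores(det); bx <- boxes(det); cl <- classIds(det); im <- imageIds(det)
  while (length(remaining) > 0) {
    best <- remaining[order(-sc[remaining])[1]]
    kept <- c(kept, best)
    drop <- best
    for (j in remaining) {
      if (j == best) next
      if (im[j] != im[best]) next
      if (class_aware && cl[j] != cl[best]) next
      if (iouRef(bx[best, ], bx[j, ]) >= thr) drop <- c(drop, j)
    }
    remaining <- setdiff(remaining, drop)
  }
  sort(kept)
}

# Greedy score-ordered matching, literal transcription.
matchRef <- function(det, gt, thr) {
  sc <- scores(det); db <- boxes(det); gb <- boxes(gt)
  ord <- order(-sc)
  used <- rep(FALSE, length(gt))
  pairs <- NULL
  for (i in ord) {
    bestIou <- -1; bestG <- 0
    for (g in seq_len(length(gt))) {
      if (used[g]) next
      if (imageIds(gt)[g] != imageIds(det)[i]) next
      if (classIds(gt)[g] != classIds(det)[i]) next
      v <- iouRef(db[i, ], gb[g, ])
      if (v >= thr && v > bestIou) { bestIou <- v; bestG <- g }
    }
    if (bestG > 0) {
      used[bestG] <- TRUE
      pairs <- rbind(pairs, c(i, bestG))
    }
  }
  pairs
}

# All-points AP from scratch: rank, flag TPs by greedy matching within a
# class, then integrate the precision envelope step by step.
apRef <- function(det, gt, cl, thr) {
  di <- which(classIds(det) == cl)
  gi <- which(classIds(gt) == cl)
  if (length(gi) == 0) return(NA_real_)
  di <- di[order(-scores(det)[di])]
  used <- rep(FALSE, length(gi))
  tp <- numeric(0)
  for (i in di) {
    bestIou <- -1; bestG <- 0
    for (k in seq_along(gi)) {
      if (used[k]) next
      if (imageIds(gt)[gi[k]] != imageIds(det)[i]) next
      v <- iouRef(boxes(det)[i, ], boxes(gt)[gi[k], ])
      if (v >= thr && v > bestIou) { bestIou <- v; bestG <- k }
    }
    if (bestG > 0) { used[bestG] <- TRUE; tp <- c(tp, 1) } else tp <- c(tp, 0)
  }
  if (length(tp) == 0) return(0)
  prec <- cumsum(tp) / seq_along(tp)
  rec <- cumsum(tp) / length(gi)
  ap <- 0; prevR <- 0
  for (k in seq_along(tp)) {
    envP <- max(prec[k:length(tp)])
    ap <- ap + (rec[k] - prevR) * envP
    prevR <- rec[k]
  }
  ap
}

# O(n^2) silhouette with cosine distance, explicit loops.
silhouetteRef <- function(m, labels) {
  n <- nrow(m)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    dOwn <- c(); dOther <- list()
    for (j in seq_len(n)) {
      if (j == i) next
      dij <- 1 - sum(m[i, ] * m[j, ])
      if (labels[j] == own) dOwn <- c(dOwn, dij)
      else {
        key <- as.character(labels[j])
        dOther[[key]] <- c(dOther[[key]], dij)
      }
    }
    if (length(dOwn) == 0) { s[i] <- 0; next }
    a <- mean(dOwn)
    b <- min(vapply(dOther, mean, numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}

# Random scored detection instance on one image: boxes loosely clustered
# so that overlaps actually occur.
randomInstance <- function(n, n_classes = 2, canvas = 200, img = "i") {
  x0 <- runif(n, 0, canvas - 40)
  y0 <- runif(n, 0, canvas - 40)
  w <- runif(n, 10, 40); h <- runif(n, 10, 40)
  DetectionSet(img, sample.int(n_classes, n, replace = TRUE) - 1L,
               runif(n), cbind(x0, y0, x0 + w, y0 + h))
}

unitRows <- function(m) m / sqrt(rowSums(m^2))
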