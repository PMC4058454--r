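four_spike_values <- function(n_per = 50) {
  rep(c(0.05, 0.35, 0.65, 0.95), each = n_per)
}

test_that("three thresholds separate four well-spaced intensity spikes", {
  thr <- multilevel_otsu(four_spike_values(), k = 3)
  expect_length(thr, 3L)
  expect_true(thr[1] >= 0.05 && thr[1] < 0.35)
  expect_true(thr[2] >= 0.35 && thr[2] < 0.65)
  expect_true(thr[3] >= 0.65 && thr[3] < 0.95)
})

test_that("k = 1 agrees with a textbook single-threshold Otsu", {
  for (seed in 1:5) {
    set.seed(seed)
    v <- c(rnorm(300, 0.3, 0.05), rnorm(200, 0.7, 0.08))
    v <- pmin(pmax(v, 0), 1)
    expect_identical(multilevel_otsu(v, k = 1), single_otsu_textbook(v))
  }
})

test_that("k = 3 agrees with the exhaustive brute-force maximizer", {
  for (seed in 1:3) {
    set.seed(seed)
    v <- runif(500)
    expect_identical(multilevel_otsu(v, k = 3), otsu_bruteforce(v, 3L))
  }
})

test_that("degenerate inputs raise a typed error", {
  expect_error(multilevel_otsu(c(0.2, 0.2, 0.5, 0.8), k = 3),
               class = "hma_degenerate_error")
  expect_error(multilevel_otsu(rep(0.5, 100), k = 1),
               class = "hma_degenerate_error")
  expect_error(multilevel_otsu(runif(10), k = 4), "k must be")
})

make_tiny_roi <- function(labels) {
  structure(list(mask = labels > 0L, labels = labels, n = max(labels)),
            class = "hma_roi")
}

test_that("each ROI region is thresholded locally and independently", {
  # one region holding the four-spike fixture: classes follow the spikes
  labels <- matrix(0L, 20, 20)
  labels[3:12, 3:22 - 2] <- 1L
  ref <- matrix(0, 20, 20)
  ref[labels == 1L] <- four_spike_values(sum(labels == 1L) / 4)
  cm <- local_otsu_classify(ref, make_tiny_roi(labels), k = 3)
  expect_identical(sort(unique(cm$labels[labels == 1L])), 1:4)
  expect_true(all(cm$labels[ref == 0.05 & labels == 1L] == 1L))
  expect_true(all(cm$labels[ref == 0.95 & labels == 1L] == 4L))
  expect_true(all(cm$labels[labels == 0L] == 0L))

  # empty ROI: all-zero class map
  cm0 <- local_otsu_classify(ref, make_tiny_roi(matrix(0L, 20, 20)))
  expect_true(all(cm0$labels == 0L))
  expect_error(local_otsu_classify(matrix(0, 4, 4), make_tiny_roi(labels)),
               "shapes differ")
})

test_that("local thresholds beat a global split on shifted two-region histograms", {
  set.seed(3)
  labels <- matrix(0L, 24, 48)
  labels[4:20, 4:20] <- 1L
  labels[4:20, 28:44] <- 2L
  ref <- matrix(0.5, 24, 48)
  n1 <- sum(labels == 1L); n2 <- sum(labels == 2L)
  ref[labels == 1L] <- sample(c(0.05, 0.15, 0.25, 0.35), n1, replace = TRUE)
  ref[labels == 2L] <- sample(c(0.55, 0.65, 0.75, 0.85), n2, replace = TRUE)
  cm <- local_otsu_classify(ref, make_tiny_roi(labels), k = 3)
  expect_false(identical(cm$thresholds[["1"]], cm$thresholds[["2"]]))
  # a single global threshold set must misclass at least one pixel relative
  # to the per-region partition
  glob <- multilevel_otsu(ref[labels > 0L], k = 3)
  glob_class <- rep(1L, sum(labels > 0L))
  for (t in glob) glob_class <- glob_class + (ref[labels > 0L] > t)
  expect_gt(sum(glob_class != cm$labels[labels > 0L]), 0)

  # locality: shifting one region's intensities leaves the other untouched
  ref2 <- ref
  ref2[labels == 2L] <- pmin(ref2[labels == 2L] + 0.1, 1)
  cm2 <- local_otsu_classify(ref2, make_tiny_roi(labels), k = 3)
  expect_identical(cm$labels[labels == 1L], cm2$labels[labels == 1L])
  expect_identical(cm$thresholds[["1"]], cm2$thresholds[["1"]])
})

test_that("degenerate regions map wholly to the dark class", {
  labels <- matrix(0L, 12, 12)
  labels[3:6, 3:6] <- 1L
  ref <- matrix(0.5, 12, 12)
  cm <- local_otsu_classify(ref, make_tiny_roi(labels), k = 3)
  expect_true(all(cm$labels[labels == 1L] == 1L))
  expect_null(cm$thresholds[["1"]])
})

test_that("class masks partition the ROI exactly", {
  sc <- generate_scene(small_scene_params(5L), seed = 4)
  roi <- compute_roi(sc$image, hma_config(roi = list(min_region_area = 200)))
  ref <- iterated_gaussian(sc$image, 1, 20, 5)
  cm <- local_otsu_classify(ref, roi, k = 3)
  masks <- lapply(1:4, function(k) class_select(cm, k))
  total <- Reduce(`+`, lapply(masks, function(m) m * 1))
  expect_true(all(total[roi$mask] == 1))
  expect_true(all(total[!roi$mask] == 0))
  expect_identical(class_select(cm, 1:4), roi$mask)
  expect_identical(class_select(cm, c(3, 4)),
                   roi$mask & !class_select(cm, c(1, 2)))
  expect_true(all(!class_select(cm, integer(0))))
  expect_error(class_select(cm, 5), "class ids")
})

test_that("watershed splits a dumbbell into two labels partitioning the mask", {
  disk <- make_disk_mask(40, 12)
  ws <- watershed_split(disk, min_seed_distance = 10)
  expect_equal(max(ws), 1L)
  expect_true(all((ws > 0L) == disk))

  db <- make_dumbbell_mask()
  ws <- watershed_split(db, min_seed_distance = 10)
  expect_equal(max(ws), 2L)
  expect_true(all((ws > 0L) == db))
  a1 <- sum(ws == 1L); a2 <- sum(ws == 2L)
  expect_gt(min(a1, a2) / max(a1, a2), 0.7)  # split near the neck

  expect_equal(max(watershed_split(matrix(FALSE, 16, 16))), 0L)
})

test_that("watershed conserves areas and keeps labels connected", {
  set.seed(5)
  m <- matrix(FALSE, 64, 64)
  for (i in 1:4) {
    r <- sample(10:50, 1); cc <- sample(10:50, 1)
    m <- m | make_disk_mask(64, sample(5:9, 1), c(r, cc))
  }
  ws <- watershed_split(m, min_seed_distance = 8)
  expect_equal(sum(tabulate(ws[ws > 0L])), sum(m))
  expect_true(all((ws > 0L) == m))
  for (id in seq_len(max(ws)))
    expect_equal(max(hmacell:::label_mask(ws == id, 8L)), 1L)
})
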