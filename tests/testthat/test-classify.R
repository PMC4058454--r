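test_that("raw results split into candidate patches", {
  a <- matrix(FALSE, 48, 48); a[5:15, 5:15] <- TRUE
  b <- matrix(FALSE, 48, 48); b[30:40, 30:40] <- TRUE
  expect_equal(max(split_raw(a | b)), 2L)
  expect_equal(max(split_raw(make_dumbbell_mask())), 2L)
  expect_equal(max(split_raw(matrix(FALSE, 16, 16))), 0L)
})

test_that("patch features are finite and geometrically sensible", {
  img <- matrix(0.5, 64, 64)
  labels <- matrix(0L, 64, 64)
  labels[10:19, 10:19] <- 1L                       # constant square
  disk <- make_disk_mask(64, 11, c(44, 44))
  labels[disk] <- 2L                               # disk
  labels[3, 60] <- 3L                              # single pixel
  set.seed(1)
  img[disk] <- 0.5 + rnorm(sum(disk), 0, 0.05)
  f <- compute_features(labels, img)
  expect_equal(nrow(f), 3L)
  expect_true(all(is.finite(as.matrix(f[hmacell:::feature_names()]))))
  # constant square: no intensity variation, LBP mass on one flat bin
  expect_equal(f$sd_intensity[1], 0)
  expect_gte(max(f[1, paste0("lbp", 1:10)]), 0.99)
  expect_equal(f$extent[1], 1)
  # disk geometry
  expect_gt(f$solidity[2], 0.95)
  expect_lt(f$eccentricity[2], 0.3)
  expect_equal(f$area[2], sum(disk))
  # single pixel: perimeter 4
  expect_equal(f$perimeter[3], 4)
  # LBP histograms sum to one
  expect_equal(rowSums(f[paste0("lbp", 1:10)]), rep(1, 3), tolerance = 1e-9)

  expect_error(compute_features(labels, matrix(0, 4, 4)), "shapes differ")
})

test_that("lbp_histogram is normalized and concentrated for flat patches", {
  img <- matrix(0.3, 20, 20)
  mask <- matrix(FALSE, 20, 20); mask[5:15, 5:15] <- TRUE
  h <- lbp_histogram(img, mask)
  expect_equal(sum(h), 1, tolerance = 1e-9)
  expect_gte(max(h), 0.99)
})

test_that("accept-all and reject-all filters are identity and annihilator", {
  sc <- generate_scene(small_scene_params(4L), seed = 6)
  labels <- split_raw(sc$gt_labels > 0L, min_seed_distance = 24)
  f <- compute_features(labels, sc$image)
  keep_all <- filter_patches(labels, f, mock_filter_model("1"))
  expect_identical(keep_all, labels)
  none <- filter_patches(labels, f, mock_filter_model("0"))
  expect_true(all(none == 0L))
  expect_error(filter_patches(labels, f[-1, ], mock_filter_model("1")),
               "one row per label")
})

test_that("filtering never adds pixels and preserves surviving geometry", {
  sc <- generate_scene(small_scene_params(5L), seed = 8)
  labels <- split_raw(sc$gt_labels > 0L, min_seed_distance = 24)
  f <- compute_features(labels, sc$image)
  # deterministic pseudo-filter: drop even labels
  fake <- mock_filter_model("1")
  fake$svm <- structure(list(), class = "parity_classifier")
  predict.parity_classifier <<- function(object, newdata, ...)
    factor(ifelse(seq_len(nrow(newdata)) %% 2 == 0, "0", "1"), c("0", "1"))
  out <- filter_patches(labels, f, fake)
  expect_true(all(out[labels == 0L] == 0L))
  odd <- which(seq_len(max(labels)) %% 2 == 1)
  for (i in seq_along(odd))
    expect_identical(out == i, labels == odd[i])
  rm(predict.parity_classifier, envir = globalenv())
})

test_that("a trained filter persists, reloads and reproduces predictions", {
  cfg <- hma_config(roi = list(min_region_area = 200))
  scenes <- lapply(21:24, function(s) generate_scene(small_scene_params(8L), s))
  model <- train_patch_filter(scenes, cfg, seed = 7)
  expect_s3_class(model, "hma_filter_model")
  expect_true(is.finite(model$meta$heldout_accuracy))
  expect_named(model$center, hmacell:::feature_names())
  expect_true(all(model$scale > 0))

  held <- generate_scene(small_scene_params(8L), 99)
  res <- run_pipeline(held, cfg)
  preds <- predict_patches(model, res$features)
  path <- tempfile(fileext = ".rds")
  save_filter_model(model, path)
  reloaded <- load_filter_model(path)
  expect_identical(predict_patches(reloaded, res$features), preds)
  # training is deterministic under a fixed seed
  model2 <- train_patch_filter(scenes, cfg, seed = 7)
  expect_identical(predict_patches(model2, res$features), preds)

  expect_error(train_patch_filter(scenes[1], cfg), "at least 2")
})
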