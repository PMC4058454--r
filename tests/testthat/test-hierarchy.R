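test_that("strategy expressions parse, validate and round-trip", {
  e <- parse_strategy("sel(1)")
  expect_equal(e$kind, "sel")
  expect_equal(e$path, 1L)

  e <- parse_strategy("holes(union(sel(2.3), sel(2.4)))")
  expect_equal(e$kind, "holes")
  expect_equal(e$child$kind, "union")
  expect_equal(e$child$children[[2]]$path, c(2L, 4L))

  e <- parse_strategy("sel(3.1@original)")
  expect_equal(e$layer, "original")

  s <- "union(sel(1), ws(holes(sel(4.4))))"
  expect_equal(format_strategy(parse_strategy(" union( sel(1),ws( holes(sel(4.4)) ) ) ")),
               format_strategy(parse_strategy(s)))

  expect_error(parse_strategy("sel(1.2.3.4)"), "deeper than 3")
  expect_error(parse_strategy("sel(5)"), "1..4")
  expect_error(parse_strategy("blend(sel(1))"), "unknown operator")
  expect_error(parse_strategy("sel(1) sel(2)"), "trailing")
})

test_that("hole extraction matches a border flood-fill oracle", {
  # solid disk: no holes
  expect_true(all(!extract_holes(make_disk_mask(40, 12))))
  # annulus: exactly the interior disk
  ann <- make_disk_mask(41, 15) & !make_disk_mask(41, 10)
  h <- extract_holes(ann)
  expect_identical(h, holes_floodfill_oracle(ann))
  expect_true(all(h[make_disk_mask(41, 9)]))
  expect_true(all(!(h & ann)))
  # two rings: both interiors
  two <- (make_disk_mask(81, 14, c(22, 22)) & !make_disk_mask(81, 9, c(22, 22))) |
         (make_disk_mask(81, 14, c(58, 58)) & !make_disk_mask(81, 9, c(58, 58)))
  expect_identical(extract_holes(two), holes_floodfill_oracle(two))
  expect_equal(max(hmacell:::label_mask(extract_holes(two), 8L)), 2L)
  # random masks
  for (seed in 1:5) {
    set.seed(seed)
    m <- matrix(runif(48 * 48) < 0.45, 48, 48)
    expect_identical(extract_holes(m), holes_floodfill_oracle(m))
  }
})

scene_context <- function(seed = 4) {
  sc <- generate_scene(small_scene_params(5L), seed = seed)
  cfg <- hma_config(roi = list(min_region_area = 200))
  roi <- compute_roi(sc$image, cfg)
  refs <- build_reference_stack(sc$image)
  base <- local_otsu_classify(refs$gauss20$image, roi, k = 3)
  list(scene = sc, cfg = cfg, roi = roi,
       ctx = layer_context(base, refs, roi))
}

test_that("re-partitions are local, cached and reproducible", {
  sx <- scene_context()
  ctx <- sx$ctx
  a2 <- class_select(ctx$base, 2)
  cm <- repartition(ctx, 2L)
  # classes of the re-partition exactly cover the parent class pixels
  expect_true(all(cm$labels[a2] >= 1L & cm$labels[a2] <= 4L))
  expect_true(all(cm$labels[!a2] == 0L))
  # determinism / cache contract
  cm2 <- repartition(ctx, 2L)
  expect_identical(cm$labels, cm2$labels)
  fresh <- scene_context()$ctx
  expect_identical(repartition(fresh, 2L)$labels, cm$labels)
  # empty parent class: all-zero map
  empty_cm <- local_otsu_classify(matrix(0.5, 8, 8),
                                  list(mask = matrix(FALSE, 8, 8),
                                       labels = matrix(0L, 8, 8)))
  expect_true(all(empty_cm$labels == 0L))
  # the depth limit is enforced
  expect_error(repartition(ctx, c(1L, 2L, 3L)), "depth limit")
})

test_that("strategy evaluation follows the algebra laws", {
  sx <- scene_context()
  ctx <- sx$ctx
  # base case: sel(i) is class selection
  expect_identical(evaluate_strategy("sel(1)", ctx),
                   class_select(ctx$base, 1) & sx$roi$mask)
  # union idempotence
  expect_identical(evaluate_strategy("union(sel(2), sel(2))", ctx),
                   evaluate_strategy("sel(2)", ctx))
  # union commutes
  expect_identical(evaluate_strategy("union(sel(1), sel(3))", ctx),
                   evaluate_strategy("union(sel(3), sel(1))", ctx))
  # the composite strategy equals the OR of its six sub-evaluations
  subs <- c("sel(1)", "holes(union(sel(3.3), sel(3.4)))", "sel(3.1)",
            "holes(union(sel(4.3), sel(4.4)))", "sel(4.1)", "sel(4.2)")
  ored <- Reduce(`|`, lapply(subs, evaluate_strategy, ctx = ctx))
  expect_identical(evaluate_strategy(composite_strategy(), ctx), ored)
  # every evaluation stays inside the ROI
  for (s in subs) expect_true(all(!(evaluate_strategy(s, ctx) & !sx$roi$mask)))
})

test_that("layer mergence respects priority, containment and fragments", {
  sx <- scene_context()
  roi <- sx$roi
  m1 <- evaluate_strategy("sel(1)", sx$ctx)
  raw <- merge_to_raw(list(list(expr = "sel(1)", mask = m1)), roi,
                      min_fragment = 0)
  expect_identical(raw$mask, m1 & roi$mask)

  # two disjoint layers: union with per-layer attribution
  a <- matrix(FALSE, 16, 16); a[2:5, 2:5] <- TRUE
  b <- matrix(FALSE, 16, 16); b[10:14, 10:14] <- TRUE
  roi16 <- structure(list(mask = matrix(TRUE, 16, 16),
                          labels = matrix(1L, 16, 16), n = 1L),
                     class = "hma_roi")
  raw <- merge_to_raw(list(list(expr = "a", mask = a),
                           list(expr = "b", mask = b)),
                      roi16, min_fragment = 0)
  expect_identical(raw$mask, a | b)
  expect_true(all(raw$attribution[a] == 1L))
  expect_true(all(raw$attribution[b] == 2L))

  # overlap goes to the earlier layer
  raw <- merge_to_raw(list(list(expr = "a", mask = a),
                           list(expr = "a2", mask = a)),
                      roi16, min_fragment = 0)
  expect_true(all(raw$attribution[a] == 1L))

  # dilated hole layers never escape the ROI
  hole <- matrix(FALSE, 16, 16); hole[7:9, 7:9] <- TRUE
  roi_small <- structure(list(mask = make_disk_mask(16, 5, c(8, 8)),
                              labels = matrix(1L, 16, 16), n = 1L),
                         class = "hma_roi")
  raw <- merge_to_raw(list(list(expr = "h", mask = hole, is_hole = TRUE)),
                      roi_small, dilate_holes = 2, min_fragment = 0)
  expect_true(all(!(raw$mask & !roi_small$mask)))
  expect_gte(sum(raw$mask), sum(hole & roi_small$mask))
})

test_that("hole dilation grows patches without merging them", {
  two <- matrix(FALSE, 32, 32)
  two[10:14, 8:12] <- TRUE
  two[10:14, 17:21] <- TRUE   # 4 px apart
  grown <- hmacell:::dilate_preserving_separation(two, 2L)
  expect_true(all(grown[two]))
  expect_gt(sum(grown), sum(two))
  expect_equal(max(hmacell:::label_mask(grown, 8L)), 2L)
})

test_that("different strategies yield different raw results inside the ROI", {
  sx <- scene_context()
  strategies <- c(composite_strategy(),
                  "union(sel(1), sel(2))",
                  "ws(union(sel(3), sel(4)))")
  res <- run_strategies(sx$scene$image, strategies, sx$cfg,
                        roi = sx$roi)
  expect_length(res, 3L)
  expect_false(identical(res[[1]]$mask, res[[2]]$mask))
  expect_false(identical(res[[1]]$mask, res[[3]]$mask))
  for (r in res) expect_true(all(!(r$mask & !sx$roi$mask)))
  expect_error(run_strategies(sx$scene$image, character(0)), "at least one")
})
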