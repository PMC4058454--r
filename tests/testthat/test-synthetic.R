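# The generator's appearance contracts are what make the pipeline testable:
# cell interiors at background intensity but texture-rich, bright halo
# rings, smooth background, controllable adhesion.

measure_scene_contracts <- function(sc) {
  bg <- sc$gt_labels == 0L
  bg_mean <- mean(sc$image[bg])
  g <- finite_difference_gradient(sc$image)
  gmag <- matrix(0, nrow(sc$image), ncol(sc$image))
  gmag[seq_len(nrow(gmag) - 1L), seq_len(ncol(gmag) - 1L)] <- g$magnitude
  bg_grad <- mean(gmag[bg])
  per_cell <- lapply(sc$cell_records$label, function(i) {
    m <- sc$gt_labels == i
    ring <- m & !hmacell:::binary_erode(m, 2L)
    interior <- m & !ring
    touching <- any(hmacell:::binary_dilate(m, 1L) & sc$gt_labels > 0L &
                    sc$gt_labels != i)
    list(interior_offset = mean(sc$image[interior]) - bg_mean,
         ring_excess = mean(sc$image[ring]) - bg_mean,
         grad_ratio = mean(gmag[interior]) / bg_grad,
         touching = touching)
  })
  list(bg_mean = bg_mean, cells = per_cell)
}

test_that("an empty scene is pure background and generation is deterministic", {
  p <- scene_params(n_cells = 0L, height = 64, width = 64)
  sc <- generate_scene(p, seed = 3)
  expect_true(all(sc$gt_labels == 0L))
  expect_equal(nrow(sc$cell_records), 0L)
  expect_equal(mean(sc$image), p$background_mean, tolerance = 0.01)

  a <- generate_scene(scene_params(), seed = 11)
  b <- generate_scene(scene_params(), seed = 11)
  expect_identical(a$image, b$image)
  expect_identical(a$gt_labels, b$gt_labels)
})

test_that("scene parameters are validated", {
  expect_error(scene_params(background_sd = 0.1, speckle_sd = 0.05), "smoother")
  expect_error(scene_params(adhesion_fraction = 1.5), "adhesion_fraction")
})

test_that("appearance contracts hold measurably at high adhesion", {
  p <- scene_params(n_cells = 20L, adhesion_fraction = 0.5)
  sc <- generate_scene(p, seed = 1)
  mc <- measure_scene_contracts(sc)
  for (cell in mc$cells) {
    expect_lte(abs(cell$interior_offset), 0.05)
    expect_gte(cell$ring_excess, p$halo_gain / 2)
    expect_gte(cell$grad_ratio, 2)
  }
  expect_gte(sum(vapply(mc$cells, `[[`, TRUE, "touching")), 8)
})

test_that("contracts, label integrity and minimum areas hold across seeds", {
  for (seed in 1:20) {
    sc <- generate_scene(scene_params(), seed = seed)
    labs <- sort(unique(sc$gt_labels[sc$gt_labels > 0L]))
    expect_identical(labs, sc$cell_records$label)
    areas <- tabulate(sc$gt_labels[sc$gt_labels > 0L])
    expect_true(all(areas >= 30))
    expect_identical(areas, sc$cell_records$area)
    # each label is a single 8-connected component
    for (i in sc$cell_records$label)
      expect_equal(max(hmacell:::label_mask(sc$gt_labels == i, 8L)), 1L)
    mc <- measure_scene_contracts(sc)
    expect_true(all(vapply(mc$cells, function(x) abs(x$interior_offset) <= 0.05, TRUE)))
    expect_true(all(vapply(mc$cells, function(x) x$ring_excess >= sc$params$halo_gain / 2, TRUE)))
    expect_true(all(vapply(mc$cells, function(x) x$grad_ratio >= 2, TRUE)))
  }
})

test_that("sequences share placement, bound jitter, and reproduce", {
  p <- scene_params(n_cells = 8L, height = 320, width = 320)
  seq1 <- generate_sequence(p, n_frames = 3, seed = 5)
  expect_length(seq1, 3L)
  # frame 1 is the single-scene output for the same seed
  solo <- generate_scene(p, seed = 5)
  expect_identical(seq1[[1]]$image, solo$image)
  expect_identical(seq1[[1]]$gt_labels, solo$gt_labels)
  # reproducibility
  seq2 <- generate_sequence(p, n_frames = 3, seed = 5)
  for (f in 1:3) expect_identical(seq1[[f]]$image, seq2[[f]]$image)
  # centroid displacement between consecutive frames is at most 3 px
  for (f in 2:3) {
    a <- seq1[[f - 1]]$cell_records
    b <- seq1[[f]]$cell_records
    d <- sqrt((a$centroid_row - b$centroid_row)^2 +
              (a$centroid_col - b$centroid_col)^2)
    expect_true(all(d <= 3))
  }
  expect_identical(generate_sequence(p, n_frames = 1, seed = 5)[[1]]$image,
                   solo$image)
})

test_that("scenes export to TIFF + JSON-lines and ground truth round-trips", {
  sc <- generate_scene(small_scene_params(3L), seed = 2)
  dir <- tempfile()
  paths <- write_scene(sc, dir)
  expect_true(all(file.exists(paths)))
  expect_identical(read_label_map(paths[["gt"]]), sc$gt_labels)
  rec <- lapply(readLines(paths[["records"]]), jsonlite::fromJSON)
  expect_length(rec, nrow(sc$cell_records))
  expect_equal(rec[[1]]$label, sc$cell_records$label[1])
})

test_that("unplaceable configurations raise a placement error", {
  p <- scene_params(height = 96, width = 96, n_cells = 30L,
                    radius_range = c(20, 24))
  expect_error(generate_scene(p, seed = 1), "place|realize")
})
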