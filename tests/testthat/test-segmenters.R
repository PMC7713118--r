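# shared fixture: one processed lesion scene reused across segmenter tests
seg_scene <- lesion_scene(scene_spec(seed = 7))
seg_proc <- tip_process(seg_scene$image,
                        default_params(seg_scene$image, seed = 7))

test_that("Chan-Vese splits a two-valued image exactly and is pure", {
  img <- matrix(0.8, 40, 40); img[, 1:20] <- 0.2
  cv <- chan_vese(img)
  expect_identical(unclass(cv$mask), img == 0.2)
  expect_true(cv$converged)
  expect_identical(unclass(chan_vese(img)$mask), unclass(cv$mask))
  # constant image: degenerate, empty, never an error
  flat <- chan_vese(matrix(0.5, 20, 20))
  expect_equal(sum(flat$mask), 0)
  expect_true(flat$degenerate)
  # processed lesion: the segmentation nails the lesion and stays inside
  # the marked region (which deliberately over-covers the object)
  got <- unclass(chan_vese(seg_proc$values)$mask)
  marked <- unclass(seg_proc$marking$masks[[1]])
  expect_gt(sum(got & marked) / sum(got), 0.95)
  expect_gt(evaluate_mask(got, seg_scene$truth)$dice, 0.9)
})

test_that("ISODATA thresholding finds the between-class fixpoint", {
  h <- matrix(c(rep(0.1, 100), rep(0.9, 100)), 20, 10)
  iso <- isodata_threshold(h)
  expect_equal(iso$threshold, 0.5) # (mean(0.1)+mean(0.9))/2 is the fixpoint
  expect_identical(unclass(iso$mask), unclass(h) < 0.5)
  bi <- isodata_threshold(matrix(c(rep(0.2, 50), rep(0.7, 30)), 8, 10))
  expect_equal(bi$threshold, 0.45)
  flat <- isodata_threshold(matrix(0.3, 5, 5))
  expect_true(flat$degenerate)
  expect_equal(sum(flat$mask), 0)
})

test_that("isocontour fill covers enclosed lighter patches and skips open contours", {
  m <- matrix(0.9, 48, 48)
  d <- sqrt((row(m) - 24)^2 + (col(m) - 24)^2)
  m[d <= 10] <- 0.3
  m[d <= 4] <- 0.6 # lighter core inside the disk
  ic <- isocontour_segment(m)
  expect_true(all(ic$mask[d <= 4]))  # core filled by the outer contour
  expect_gt(evaluate_mask(ic$mask, d <= 10)$dice, 0.95)
  expect_equal(sum(isocontour_segment(m, level = 2)$mask), 0)
  expect_equal(sum(isocontour_segment(m, level = -1)$mask), 0)
  # a dark half-plane touching the border yields only open contours
  hp <- matrix(0.8, 30, 30); hp[, 1:10] <- 0.2
  expect_equal(sum(isocontour_segment(hp)$mask), 0)
})

test_that("superpixels reduce to a binary mask through the marking", {
  sp <- superpixels(seg_proc$values, marking = seg_proc$marking, seed = 7)
  expect_equal(dim(sp$labels), dim(seg_proc$values))
  expect_gt(evaluate_mask(sp$mask, seg_scene$truth)$dice, 0.4)
  sp_again <- superpixels(seg_proc$values, marking = seg_proc$marking,
                          seed = 7)
  expect_identical(sp$labels, sp_again$labels)
  # without a marking only the label image is produced
  expect_null(superpixels(matrix(runif(100), 10, 10), n = 4)$mask)
  one <- superpixels(matrix(runif(100), 10, 10), n = 1)
  expect_true(all(one$labels == 1)) # single superpixel covers everything
})

test_that("Roberts edges threshold at the mean magnitude", {
  expect_equal(sum(roberts_edges(matrix(0.5, 20, 20))$mask), 0)
  m <- matrix(0.9, 20, 20); m[8:12, 8:12] <- 0.1
  rb <- roberts_edges(m)
  expect_gt(sum(rb$mask), 0)
  # edges concentrate on the square's boundary ring
  ring <- abs(row(m) - 10) <= 3 & abs(col(m) - 10) <= 3 &
    !(abs(row(m) - 10) <= 1 & abs(col(m) - 10) <= 1)
  expect_true(all(which(rb$mask) %in% which(ring | m < 0.5)))
})

test_that("snakes initialized at the marked hull converge to the blob boundary", {
  sc <- lesion_scene(scene_spec(hairs = list(count = 0L),
                                border_distractor = list(enabled = FALSE),
                                seed = 7))
  pr <- tip_process(sc$image, default_params(sc$image, seed = 7))
  snk <- active_contour_segment(pr$values, pr$marking)
  expect_gt(evaluate_mask(snk$mask, sc$truth)$dice, 0.8)
  expect_error(active_contour_segment(pr$values, list(masks = list())),
               "non-empty")
})

test_that("every binary segmenter beats its raw-image self after processing", {
  for (seg in list(chan_vese, isodata_threshold, isocontour_segment)) {
    d_raw <- evaluate_mask(seg(seg_scene$image)$mask, seg_scene$truth)$dice
    d_tip <- evaluate_mask(seg(seg_proc$values)$mask, seg_scene$truth)$dice
    expect_gt(d_tip, d_raw)
  }
})
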