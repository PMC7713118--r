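test_that("largest-gap threshold selection matches hand enumeration", {
  r <- select_threshold(c(10, 9.5, 4, 3.8, 3.5))
  expect_equal(r$tau, 6.75)
  expect_equal(r$largest_gap, 5.5)
  expect_equal(r$mean_gap, 1.625)
  expect_equal(r$n_selected, 2L)
  expect_equal(r$stability_ratio, 5.5 / 1.625, tolerance = 1e-12)
  expect_true(r$low_contrast) # 3.3846 < 4

  single <- select_threshold(7)
  expect_equal(single$n_selected, 1L)
  expect_equal(single$stability_ratio, Inf)

  flat <- select_threshold(c(5, 5, 5)) # degenerate: no empty band at all
  expect_equal(flat$n_selected, 3L)
  expect_true(is.nan(flat$stability_ratio))

  expect_error(select_threshold(numeric(0)), "no finite")
  expect_error(select_threshold(c(1, Inf)), "finite")

  # first occurrence wins on tied gaps, scanning from the largest lifetime
  tied <- select_threshold(c(9, 6, 3))
  expect_equal(tied$tau, 7.5)
  expect_equal(tied$n_selected, 1L)
})

test_that("quantized stability ratio is scale-robust, raw ratio is exact", {
  # hundreds of near-diagonal points with one clear outlier
  lt <- c(0.5, withr::with_seed(1, runif(400, 0, 0.02)))
  raw <- select_threshold(lt)
  quant <- select_threshold(lt, resolution = 1 / 255)
  expect_gt(raw$stability_ratio, 100) # raw mean gap collapses
  expect_gt(quant$stability_ratio, 4) # outlier still dominates
  expect_equal(raw$tau, quant$tau)    # selection itself is unchanged
  expect_equal(raw$n_selected, quant$n_selected)
})

test_that("object marking extracts components right before the lowest death", {
  m <- matrix(0.9, 12, 12)
  m[3:4, 3:4] <- 0.1
  m[8:9, 8:9] <- 0.2
  bm <- border_modify(gray_image(m), 1)
  d <- compute_h0(bm)
  mk <- mark_objects(bm, d, tau = 0.5)
  expect_equal(length(mk$masks), 2L)
  expect_equal(mk$status, "ok")
  expect_equal(mk$extraction_level, 0.9)
  blob1 <- matrix(FALSE, 12, 12); blob1[3:4, 3:4] <- TRUE
  blob2 <- matrix(FALSE, 12, 12); blob2[8:9, 8:9] <- TRUE
  got <- lapply(mk$masks, unclass)
  expect_true(identical(got[[1]], blob1) && identical(got[[2]], blob2))
  expect_false(any(got[[1]] & got[[2]]))
  # each mask contains its own birth pixel
  for (i in 1:2)
    expect_true(got[[i]][mk$points$birth_row[i], mk$points$birth_col[i]])

  # tau above all finite lifetimes: explicit empty marking
  none <- mark_objects(bm, d, tau = 10)
  expect_equal(none$status, "no_objects")
  expect_equal(length(none$masks), 0L)

  # without border modification a constant image has no finite points
  expect_error(mark_objects(gray_image(m * 0 + 1), compute_h0(m * 0 + 1), 0.1),
               "no finite")
})

test_that("inverse distance weighting reproduces hand arithmetic", {
  # two single-pixel components at distances 1 and 2 from the probe pixel
  vals <- gray_image(matrix(c(0.2, 0.5, 0.9, 0.8), 1))
  mask_a <- matrix(c(TRUE, FALSE, FALSE, FALSE), 1)
  mask_b <- matrix(c(FALSE, FALSE, FALSE, TRUE), 1)
  marking <- list(masks = list(binary_mask(mask_a), binary_mask(mask_b)))
  out <- unclass(idw_fill(vals, marking, power = 2))
  expect_equal(out[1, 2], (0.2 * 1 + 0.8 * 0.25) / 1.25, tolerance = 1e-12)
  expect_equal(out[1, 3], (0.2 * 0.25 + 0.8 * 1) / 1.25, tolerance = 1e-12)
  expect_equal(out[1, 1], 0.2) # marked pixels keep their values
  expect_equal(out[1, 4], 0.8)

  # equidistant pixel gets the plain average regardless of power
  vals3 <- gray_image(matrix(c(0.2, 0.5, 0.8), 1))
  mk3 <- list(masks = list(binary_mask(matrix(c(TRUE, FALSE, FALSE), 1)),
                           binary_mask(matrix(c(FALSE, FALSE, TRUE), 1))))
  for (p in c(0.5, 1, 2, 5))
    expect_equal(unclass(idw_fill(vals3, mk3, power = p))[1, 2], 0.5,
                 tolerance = 1e-12)

  # single component: every background pixel copies its nearest value
  img <- rand_image(9, 9, 21)
  one <- matrix(FALSE, 9, 9); one[4:6, 4:6] <- TRUE
  filled <- unclass(idw_fill(gray_image(img), list(masks = list(binary_mask(one)))))
  expect_identical(filled[one], img[one])
  expect_equal(filled[1, 1], img[4, 4]) # nearest component pixel to corner
  expect_true(all(filled >= min(img[one]) - 1e-12 &
                  filled <= max(img[one]) + 1e-12 | one))
  expect_error(idw_fill(gray_image(img), list(masks = list())), "empty")
  expect_error(idw_fill(gray_image(img), list(masks = list(binary_mask(one))),
                        power = 0), "positive")
})

test_that("the end-to-end pipeline marks the lesion and only the lesion", {
  sc <- lesion_scene(scene_spec(seed = 12))
  res <- tip_process(sc$image, default_params(sc$image, seed = 12))
  expect_equal(res$status, "ok")
  expect_equal(length(res$marking$masks), 1L)
  m <- res$marking$masks[[1]]
  ctr <- mask_centroid(sc$truth)
  expect_true(unclass(m)[ctr[1], ctr[2]])
  expect_gte(inclusion(confusion(m, sc$truth)), 0.95)
  # masks never touch the border band
  l <- res$params$l
  H <- nrow(m); W <- ncol(m)
  band <- row(matrix(0, H, W)) <= l | row(matrix(0, H, W)) > H - l |
    col(matrix(0, H, W)) <= l | col(matrix(0, H, W)) > W - l
  expect_false(any(unclass(m) & band))
  # determinism
  res2 <- tip_process(sc$image, default_params(sc$image, seed = 12))
  expect_identical(unclass(res$values), unclass(res2$values))
  expect_identical(unclass(res$marking$masks[[1]]),
                   unclass(res2$marking$masks[[1]]))
  # diagnostics are JSON-serializable
  js <- jsonlite::toJSON(tip_diagnostics(res), auto_unbox = TRUE)
  expect_true(jsonlite::validate(js))
})

test_that("flat images yield an explicit no-objects status", {
  res <- tip_process(matrix(0.5, 40, 40),
                     tim_params(k = 3, l = 2, sigma = 0))
  expect_equal(res$status, "no_objects")
  expect_true(res$low_contrast)
})

test_that("a two-lobed lesion is marked as two objects", {
  sc <- lesion_scene(scene_spec(lesion = list(lobes = 2L), seed = 4))
  res <- tip_process(sc$image, default_params(sc$image, seed = 4))
  expect_equal(length(res$marking$masks), 2L)
  expect_false(any(unclass(res$marking$masks[[1]]) &
                   unclass(res$marking$masks[[2]])))
})

test_that("processing time grows near-linearly with pixel count", {
  times <- sapply(c(64, 128, 256), function(n) {
    sc <- lesion_scene(scene_spec(size = c(n, n), seed = 1))
    t0 <- proc.time()[["elapsed"]]
    invisible(tip_process(sc$image, default_params(sc$image, seed = 1)))
    proc.time()[["elapsed"]] - t0
  })
  slope <- coef(lm(log(pmax(times, 1e-3)) ~ log(c(64, 128, 256)^2)))[[2]]
  expect_lt(slope, 1.7)
})
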