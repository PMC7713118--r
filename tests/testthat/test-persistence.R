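test_that("H0 matches hand-enumerated sublevel filtrations", {
  d <- compute_h0(matrix(c(0.2, 0.8, 0.3), 1))
  expect_equal(nrow(d), 2L)
  inf_pt <- d[is.infinite(d$death), ]
  fin_pt <- d[is.finite(d$death), ]
  expect_equal(inf_pt$birth, 0.2)
  expect_equal(c(fin_pt$birth, fin_pt$death), c(0.3, 0.8))
  expect_equal(c(fin_pt$birth_row, fin_pt$birth_col), c(1L, 3L))
  expect_equal(c(fin_pt$death_row, fin_pt$death_col), c(1L, 2L))

  # constant image: a single never-dying component
  dc <- compute_h0(matrix(0.4, 5, 5))
  expect_equal(nrow(dc), 1L)
  expect_true(is.infinite(dc$death))
  expect_equal(dc$birth, 0.4)

  expect_error(compute_h0(matrix(c(1, NA), 1)), "finite")
})

test_that("H0 point count equals the number of tie-broken local minima", {
  for (seed in 1:5) {
    img <- rand_image(12, 12, seed)
    d <- compute_h0(img)
    H <- nrow(img); W <- ncol(img)
    n_min <- 0L
    for (r in seq_len(H)) for (c in seq_len(W)) {
      is_min <- TRUE
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- c + dc
        if ((dr | dc) && rr >= 1 && rr <= H && cc >= 1 && cc <= W &&
            img[rr, cc] < img[r, c]) is_min <- FALSE
      }
      n_min <- n_min + is_min
    }
    expect_equal(nrow(d), n_min)
    # exactly one infinite point, born at the global minimum pixel
    inf_pt <- d[is.infinite(d$death), ]
    expect_equal(nrow(inf_pt), 1L)
    expect_equal(inf_pt$birth, min(img))
    expect_equal(img[inf_pt$birth_row, inf_pt$birth_col], min(img))
    # elder rule: nothing is born before the infinite component
    expect_true(all(d$birth >= inf_pt$birth))
  }
})

test_that("H1 by duality matches hand-derived loop examples", {
  expect_equal(nrow(compute_h1(matrix(0.7, 6, 6))), 0L)
  # dark annulus: one loop born when the ring completes (0.1), dying when
  # the interior fills (0.9)
  m <- matrix(0.9, 9, 9)
  m[3:7, 3] <- m[3:7, 7] <- m[3, 3:7] <- m[7, 3:7] <- 0.1
  d1 <- compute_h1(gray_image(m))
  expect_equal(nrow(d1), 1L)
  expect_equal(c(d1$birth, d1$death), c(0.1, 0.9))
})

test_that("alive counts of both engines match the BFS Betti oracle", {
  for (seed in 1:8) {
    img <- rand_image(10, 10, seed + 100)
    th <- mid_thresholds(img, 10)
    d0 <- compute_h0(img); d1 <- compute_h1(img)
    expect_identical(vapply(th, function(t) alive_count(d0, t), numeric(1)),
                     as.numeric(betti_curve_oracle(img, 0L, th)))
    expect_identical(vapply(th, function(t) alive_count(d1, t), numeric(1)),
                     as.numeric(betti_curve_oracle(img, 1L, th)))
  }
})

test_that("Betti oracle reproduces hand counts on a binary '8' glyph", {
  m <- matrix(0.9, 13, 8)
  ring <- function(m, r0, c0, rad) {
    d <- sqrt((row(m) - r0)^2 + (col(m) - c0)^2)
    m[d <= rad & d >= rad - 1.5] <- 0.1
    m
  }
  m <- ring(ring(m, 4, 4, 3), 10, 4, 3)
  expect_equal(betti_curve_oracle(m, 0L, 0.5), 1L)
  expect_equal(betti_curve_oracle(m, 1L, 0.5), 2L)
  expect_equal(betti_curve_oracle(m, 0L, 0.05), 0L)  # below global min
  expect_equal(betti_curve_oracle(m, 0L, 1), 1L)     # everything included
  expect_equal(betti_curve_oracle(m, 1L, 1), 0L)
})

test_that("diagrams are invariant under monotone intensity relabeling", {
  g <- function(x) x^3 + 2 * x # strictly increasing
  for (seed in 1:3) {
    img <- rand_image(8, 8, seed + 40)
    d1 <- compute_h0(img)
    d2 <- compute_h0(g(img))
    expect_equal(nrow(d1), nrow(d2))
    o1 <- order(d1$birth_row, d1$birth_col)
    o2 <- order(d2$birth_row, d2$birth_col)
    # same birth pixels, coordinates mapped through g
    expect_equal(d1[o1, c("birth_row", "birth_col")],
                 d2[o2, c("birth_row", "birth_col")],
                 ignore_attr = TRUE)
    expect_equal(g(d1$birth[o1]), d2$birth[o2], tolerance = 1e-12)
    expect_equal(g(d1$death[o1]), d2$death[o2], tolerance = 1e-12)
  }
})

test_that("diagram CSV serialization round-trips, including INF deaths", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  d <- compute_h0(rand_image(8, 8, 3))
  write_diagram(d, tmp)
  back <- read_diagram(tmp)
  expect_equal(as.data.frame(back), as.data.frame(d), tolerance = 1e-12)
  expect_true(any(grepl("INF", readLines(tmp))))
})
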