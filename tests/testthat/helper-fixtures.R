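# shared helpers: tiny diagram builder, random test images, centroid

make_diagram <- function(birth, death, dimension = 0L) {
  n <- length(birth)
  topimg:::new_diagram(data.frame(
    dimension = rep(as.integer(dimension), n),
    birth = as.numeric(birth), death = as.numeric(death),
    birth_row = rep(NA_integer_, n), birth_col = rep(NA_integer_, n),
    death_row = rep(NA_integer_, n), death_col = rep(NA_integer_, n)))
}

rand_image <- function(h, w, seed) {
  withr::with_seed(seed, matrix(runif(h * w), h, w))
}

# thresholds strictly between consecutive pixel values (so strict and
# non-strict sublevel sets coincide)
mid_thresholds <- function(img, k) {
  v <- sort(unique(as.vector(img)))
  mids <- (head(v, -1) + tail(v, -1)) / 2
  mids[round(seq(1, length(mids), length.out = min(k, length(mids))))]
}

alive_count <- function(d, t) sum(d$birth <= t & d$death > t)

mask_centroid <- function(mask) {
  round(colMeans(which(unclass(mask), arr.ind = TRUE)))
}
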