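# Procedural synthetic scenes with ground truth. These emulate, at desk
# scale, the situations the method is designed for: a dark lesion-like
# blob away from the border, thin dark hair-like curves, a dark distractor
# touching the border, background texture and (optionally) an illumination
# gradient, plus a two-glyph digit scene with known Betti numbers. All
# generators are deterministic given their seed.

#' Scene specification for the lesion-like generator
#'
#' Defaults describe the standard test scene: a 256 x 256 image with a
#' centred dark elliptical lesion (intensity 0.3, background 0.75), mild
#' Gaussian background texture (sd 0.02), six dark hair-like curves of
#' thickness 1 px (intensity 0.2; at this resolution and smoothing window
#' a 1 px hair matches the relative hair/window scale of high-resolution
#' dermoscopy), and a dark half-disk distractor
#' clipped by the image border (intensity 0.35). The lesion never touches
#' the border band.
#'
#' @param size integer (H, W).
#' @param lesion list: `center` (row, col; `NULL` = image centre), `radii`
#'   (semi-axes in px), `intensity`, `gradient` (logical: radial
#'   inflammation-like brightening towards the rim), `lobes` (1 or 2).
#' @param hairs list: `count`, `thickness` (px), `intensity`.
#' @param border_distractor list: `enabled`, `intensity`, `radius`.
#' @param background list: `base`, `texture_sigma`, `gradient` (logical
#'   horizontal illumination gradient of amplitude 0.1).
#' @param seed integer.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(size = c(256L, 256L),
                       lesion = list(),
                       hairs = list(),
                       border_distractor = list(),
                       background = list(),
                       seed = 0L) {
  merge_defaults <- function(given, defaults) {
    defaults[names(given)] <- given
    defaults
  }
  s <- min(size)
  spec <- list(
    size = as.integer(size),
    lesion = merge_defaults(lesion, list(
      center = NULL, radii = round(c(0.17, 0.14) * s), intensity = 0.3,
      gradient = FALSE, lobes = 1L)),
    hairs = merge_defaults(hairs, list(count = 6L, thickness = 1L,
                                       intensity = 0.2)),
    border_distractor = merge_defaults(border_distractor, list(
      enabled = TRUE, intensity = 0.35, radius = round(0.14 * s))),
    background = merge_defaults(background, list(
      base = 0.75, texture_sigma = 0.02, gradient = FALSE)),
    seed = as.integer(seed))
  if (any(spec$size < 32L)) stop("scene must be at least 32 x 32")
  if (spec$lesion$intensity >= spec$background$base)
    stop("lesion must be darker than the background base")
  class(spec) <- "scene_spec"
  spec
}

ellipse_mask <- function(H, W, center, radii, angle = 0) {
  rr <- row(matrix(0, H, W)) - center[1]
  cc <- col(matrix(0, H, W)) - center[2]
  u <- rr * cos(angle) + cc * sin(angle)
  v <- -rr * sin(angle) + cc * cos(angle)
  (u / radii[1])^2 + (v / radii[2])^2 <= 1
}

# rasterize a quadratic Bezier curve with given thickness
draw_curve <- function(mask, p0, p1, p2, thickness) {
  H <- nrow(mask); W <- ncol(mask)
  tseq <- seq(0, 1, length.out = 4L * max(H, W))
  r <- (1 - tseq)^2 * p0[1] + 2 * tseq * (1 - tseq) * p1[1] + tseq^2 * p2[1]
  c <- (1 - tseq)^2 * p0[2] + 2 * tseq * (1 - tseq) * p1[2] + tseq^2 * p2[2]
  offs <- expand.grid(dr = 0:(thickness - 1L), dc = 0:(thickness - 1L))
  for (k in seq_len(nrow(offs))) {
    ri <- round(r) + offs$dr[k]; ci <- round(c) + offs$dc[k]
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    mask[cbind(ri[ok], ci[ok])] <- TRUE
  }
  mask
}

#' Lesion-like scene with ground truth
#'
#' Renders the scene described by a [scene_spec()]: background texture and
#' optional gradient, hair-like curves, an optional border-touching
#' half-disk distractor, and finally the lesion (one ellipse, or two
#' disjoint lobes emulating a lesion split by scarring). The ground-truth
#' mask marks the lesion only — never hairs or the distractor.
#'
#' @param spec a [scene_spec()].
#' @return List with `image` (a [gray_image]), `truth` (a [binary_mask]),
#'   and `spec`.
#' @export
lesion_scene <- function(spec = scene_spec()) {
  H <- spec$size[1]; W <- spec$size[2]
  withr::with_seed(spec$seed, {
    bg <- spec$background$base +
      matrix(rnorm(H * W, 0, spec$background$texture_sigma), H, W)
    if (isTRUE(spec$background$gradient)) {
      bg <- bg + 0.1 * (col(bg) - (W + 1) / 2) / W * 2
    }
    img <- bg
    # hairs: quadratic arcs with random endpoints and control point
    for (i in seq_len(spec$hairs$count)) {
      p0 <- c(runif(1, 1, H), runif(1, 1, W))
      p2 <- c(runif(1, 1, H), runif(1, 1, W))
      p1 <- (p0 + p2) / 2 + runif(2, -0.3, 0.3) * c(H, W)
      hm <- draw_curve(matrix(FALSE, H, W), p0, p1, p2,
                       spec$hairs$thickness)
      img[hm] <- spec$hairs$intensity
    }
    if (isTRUE(spec$border_distractor$enabled)) {
      side <- sample(4L, 1)
      pos <- runif(1, 0.2, 0.8)
      center <- switch(side,
                       c(1, pos * W), c(H, pos * W),
                       c(pos * H, 1), c(pos * H, W))
      dm <- ellipse_mask(H, W, center,
                         rep(spec$border_distractor$radius, 2))
      img[dm] <- spec$border_distractor$intensity
    }
    angle <- runif(1, 0, pi)
    center <- spec$lesion$center
    if (is.null(center)) center <- c((H + 1) / 2, (W + 1) / 2)
    if (spec$lesion$lobes >= 2L) {
      gap <- spec$lesion$radii[1]
      truth <- ellipse_mask(H, W, center - c(0, gap + 2),
                            spec$lesion$radii * 0.7, angle) |
        ellipse_mask(H, W, center + c(0, gap + 2),
                     spec$lesion$radii * 0.7, angle + pi / 3)
    } else {
      truth <- ellipse_mask(H, W, center, spec$lesion$radii, angle)
    }
    fill <- spec$lesion$intensity
    img[truth] <- fill
    if (isTRUE(spec$lesion$gradient)) {
      # inflammation-like rim: brighten towards the lesion boundary
      dt <- .nearest_site_cpp(!truth)
      depth <- pmin(dt$dist / max(spec$lesion$radii), 1)
      img[truth] <- fill + 0.15 * (1 - depth[truth])
    }
    img <- img + matrix(rnorm(H * W, 0, 1e-4), H, W) # tie breaking
    list(image = gray_image(pmin(pmax(img, 0.01), 0.99)),
         truth = binary_mask(truth), spec = spec)
  })
}

#' Two-glyph digit scene with known topology
#'
#' Renders a '1' (a bar with a serif foot) and an '8' (two stacked,
#' slightly overlapping annuli) dark on a light textured background. The
#' scene has exactly two significant connected components and exactly two
#' significant loops (the holes of the '8'), which is what the expected
#' counts record.
#'
#' @param size integer (H, W), at least 64 x 64.
#' @param seed integer.
#' @return List with `image` and `expected = list(h0 = 2, h1 = 2)`.
#' @export
digits_scene <- function(size = c(96L, 96L), seed = 0L) {
  H <- size[1]; W <- size[2]
  if (H < 64 || W < 64) stop("digit scene needs at least 64 x 64")
  s <- min(H, W)
  withr::with_seed(as.integer(seed), {
    img <- 0.9 + matrix(rnorm(H * W, 0, 0.01), H, W)
    dark <- matrix(FALSE, H, W)
    # '1': vertical bar with a foot
    bar_w <- max(2L, round(0.05 * s))
    c1 <- round(0.3 * W)
    dark[round(0.2 * H):round(0.8 * H), c1:(c1 + bar_w - 1L)] <- TRUE
    dark[round(0.76 * H):round(0.8 * H),
         (c1 - round(0.05 * s)):(c1 + bar_w - 1L + round(0.05 * s))] <- TRUE
    # '8': two stacked annuli, overlapping so they form one component
    th <- max(2L, round(0.05 * s))
    rad <- round(0.14 * s)
    cx <- round(0.65 * W)
    for (cy in c(round(0.34 * H), round(0.34 * H) + 2L * rad - th)) {
      rr <- row(img) - cy; cc <- col(img) - cx
      d <- sqrt(rr^2 + cc^2)
      dark[d <= rad & d >= rad - th] <- TRUE
    }
    img[dark] <- 0.1 + matrix(rnorm(H * W, 0, 0.01), H, W)[dark]
    list(image = gray_image(pmin(pmax(img, 0.01), 0.99)),
         expected = list(h0 = 2L, h1 = 2L))
  })
}

#' Low-contrast scene
#'
#' The standard lesion scene with the lesion intensity within the texture
#' noise of the background (contrast = one texture standard deviation by
#' default) and no hairs or distractor: the situation in which no reliable
#' lifetime threshold exists and the stability ratio is expected to fall
#' below 4. Increasing `contrast` tenfold produces a clearly separated
#' lesion and clears the flag.
#'
#' @param size integer (H, W).
#' @param seed integer.
#' @param contrast intensity difference between background and lesion.
#' @return List with `image`, `truth`, `spec`.
#' @export
low_contrast_scene <- function(size = c(256L, 256L), seed = 0L,
                               contrast = 0.02) {
  spec <- scene_spec(
    size = size,
    lesion = list(intensity = 0.75 - contrast),
    hairs = list(count = 0L),
    border_distractor = list(enabled = FALSE),
    seed = seed)
  lesion_scene(spec)
}
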