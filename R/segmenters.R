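# Six generic unsupervised segmenters. These are established published
# algorithms (none of them this package's contribution); no installed R
# package provides them, so they are implemented natively with
# standard-settings defaults. Each is a pure function of (image, params).

new_segmentation <- function(mask, method, params, ...) {
  structure(list(mask = if (is.null(mask)) NULL else binary_mask(mask),
                 method = method, params = params, ...),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  npix <- if (is.null(x$mask)) NA_integer_ else sum(x$mask)
  cat(sprintf("segmentation (%s): %s positive pixels\n", x$method,
              ifelse(is.na(npix), "label image,", npix)))
  invisible(x)
}

shift_mat <- function(m, dr, dc, fill = NA) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(fill, H, W)
  rs <- seq_len(H) - dr; cs <- seq_len(W) - dc
  ok_r <- rs >= 1 & rs <= H; ok_c <- cs >= 1 & cs <= W
  out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
  out
}

# morphological curvature smoothing (sup-inf / inf-sup over the four
# length-3 line segments through each pixel)
acwe_smooth <- function(u) {
  segs <- list(rbind(c(0, -1), c(0, 0), c(0, 1)),
               rbind(c(-1, 0), c(0, 0), c(1, 0)),
               rbind(c(-1, -1), c(0, 0), c(1, 1)),
               rbind(c(-1, 1), c(0, 0), c(1, -1)))
  line_op <- function(m, inner, outer, fill) {
    per_seg <- lapply(segs, function(s) {
      acc <- shift_mat(m, s[1, 1], s[1, 2], fill)
      for (i in 2:3) acc <- inner(acc, shift_mat(m, s[i, 1], s[i, 2], fill))
      acc
    })
    Reduce(outer, per_seg)
  }
  u <- line_op(u, pmin, pmax, 1) # IS: sup over lines of inf along line
  line_op(u, pmax, pmin, 0)      # SI
}

#' Chan-Vese segmentation (morphological active contours without edges)
#'
#' Two-phase piecewise-constant Chan-Vese energy minimized with the
#' morphological active-contours-without-edges scheme: starting from a
#' checkerboard level set, the region indicator is updated towards the
#' closer of the two region means and regularized by a morphological
#' curvature operator. Parameter-light and unconditionally stable;
#' non-convergence within `max_iter` is permitted (the result is returned
#' as-is, checkerboard artifacts and all), never an error. The returned
#' binary mask marks the phase with the lower mean intensity (the dark
#' object, matching the sublevel convention used throughout).
#'
#' @param img a [gray_image] or numeric matrix.
#' @param max_iter iteration cap.
#' @param smoothing number of curvature-smoothing passes per iteration.
#' @param lambda1,lambda2 inside/outside data-term weights.
#' @return A `segmentation_result`.
#' @export
chan_vese <- function(img, max_iter = 120, smoothing = 1,
                      lambda1 = 1, lambda2 = 1) {
  f <- unclass(as_gray_image(img))
  H <- nrow(f); W <- ncol(f)
  if (diff(range(f)) == 0) { # flat image: no contour to find
    return(new_segmentation(matrix(FALSE, H, W), "chan_vese",
                            list(max_iter = max_iter, smoothing = smoothing,
                                 lambda1 = lambda1, lambda2 = lambda2),
                            converged = TRUE, degenerate = TRUE))
  }
  # initial level set: mean threshold (a piecewise-constant-optimal start
  # for two-valued images; a plain checkerboard deadlocks on symmetric
  # inputs because both phase means coincide exactly)
  u <- 1 * (f < mean(f))
  if (all(u == u[1]))
    u <- (((row(f) - 1) %/% 5 + (col(f) - 1) %/% 5) %% 2)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    a1 <- mean(f[u == 1]); a2 <- mean(f[u == 0])
    if (is.nan(a1) || is.nan(a2)) break # one phase vanished
    # evolve only the interface band (morphological ACWE update)
    dil <- u; ero <- u
    for (s in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                   c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))) {
      sh <- shift_mat(u, s[1], s[2], NA)
      dil <- pmax(dil, sh, na.rm = TRUE)
      ero <- pmin(ero, sh, na.rm = TRUE)
    }
    interface <- dil != ero
    aux <- lambda1 * (f - a1)^2 - lambda2 * (f - a2)^2
    u_new <- u
    u_new[interface & aux < 0] <- 1
    u_new[interface & aux > 0] <- 0
    for (s in seq_len(smoothing)) u_new <- acwe_smooth(u_new)
    if (identical(u_new, u)) { converged <- TRUE; break }
    u <- u_new
  }
  inside <- u == 1
  if (!any(inside) || all(inside)) {
    mask <- matrix(FALSE, H, W) # degenerate: flat image or vanished phase
  } else if (mean(f[inside]) <= mean(f[!inside])) {
    mask <- inside
  } else {
    mask <- !inside
  }
  new_segmentation(mask, "chan_vese",
                   list(max_iter = max_iter, smoothing = smoothing,
                        lambda1 = lambda1, lambda2 = lambda2),
                   converged = converged)
}

#' ISODATA threshold segmentation
#'
#' Iterates the threshold to the midpoint of the means of the two classes
#' it induces, starting from the image mean; the segmentation is the set
#' of pixels strictly darker than the converged threshold. A constant
#' image yields an empty mask flagged `degenerate`.
#'
#' @param img a [gray_image] or numeric matrix.
#' @return A `segmentation_result` with an extra `threshold` field.
#' @export
isodata_threshold <- function(img) {
  f <- unclass(as_gray_image(img))
  if (diff(range(f)) == 0) {
    return(new_segmentation(matrix(FALSE, nrow(f), ncol(f)), "isodata",
                            list(), threshold = NA_real_, degenerate = TRUE))
  }
  t_old <- -Inf
  t_new <- mean(f)
  for (i in 1:200) {
    lo <- f[f < t_new]; hi <- f[f >= t_new]
    if (!length(lo) || !length(hi)) break
    t_old <- t_new
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t_old) < 1e-12) break
  }
  new_segmentation(f < t_new, "isodata", list(),
                   threshold = t_new, degenerate = FALSE)
}

#' Isocontour segmentation
#'
#' Extracts isovalued contours at the given level (default: the image
#' mean) via marching squares, treats every closed contour as a polygon in
#' the plane, and returns the union of their filled interiors. Lighter
#' patches enclosed by a contour are filled in; contours that intersect
#' the image border are open and contribute nothing. A level outside the
#' image range yields an empty mask.
#'
#' @param img a [gray_image] or numeric matrix.
#' @param level contour level; `NULL` means the image mean.
#' @return A `segmentation_result` with extra `level`, `n_contours`.
#' @export
isocontour_segment <- function(img, level = NULL) {
  f <- unclass(as_gray_image(img))
  if (is.null(level)) level <- mean(f)
  H <- nrow(f); W <- ncol(f)
  mask <- matrix(FALSE, H, W)
  n_closed <- 0L
  if (level > min(f) && level < max(f)) {
    cl <- grDevices::contourLines(seq_len(H), seq_len(W), f, levels = level)
    for (cont in cl) {
      x <- cont$x; y <- cont$y
      closed <- abs(x[1] - x[length(x)]) < 1e-9 &&
        abs(y[1] - y[length(y)]) < 1e-9
      if (!closed) next
      n_closed <- n_closed + 1L
      mask <- mask | polygon_fill(x, y, H, W)
    }
  }
  new_segmentation(mask, "isocontour", list(level = level),
                   level = level, n_contours = n_closed)
}

# even-odd scanline rasterization of a polygon given in (row, col)
# vertex coordinates; marks pixels whose integer center lies inside
polygon_fill <- function(vr, vc, H, W) {
  n <- length(vr)
  if (abs(vr[1] - vr[n]) < 1e-12 && abs(vc[1] - vc[n]) < 1e-12) {
    vr <- vr[-n]; vc <- vc[-n]; n <- n - 1L
  }
  mask <- matrix(FALSE, H, W)
  if (n < 3) return(mask)
  nxt <- c(2:n, 1L)
  for (r in max(1L, floor(min(vr))):min(H, ceiling(max(vr)))) {
    r1 <- vr; r2 <- vr[nxt]
    crosses <- (r1 <= r & r2 > r) | (r2 <= r & r1 > r) # half-open rule
    if (!any(crosses)) next
    tt <- (r - r1[crosses]) / (r2[crosses] - r1[crosses])
    xs <- sort(vc[crosses] + tt * (vc[nxt][crosses] - vc[crosses]))
    for (i in seq(1, length(xs) - 1, by = 2)) {
      c1 <- ceiling(xs[i] - 1e-9); c2 <- floor(xs[i + 1] + 1e-9)
      if (c2 >= c1) mask[r, max(1L, c1):min(W, c2)] <- TRUE
    }
  }
  mask
}

#' k-means superpixel segmentation
#'
#' Clusters pixels in (row, col, intensity) feature space into `n`
#' superpixels with k-means. Without a marking the label image is
#' returned (`mask = NULL`); with an [mark_objects()] marking the result
#' is reduced to a binary mask as the union of the clusters that overlap
#' the marked objects in the majority of their pixels.
#'
#' @param img a [gray_image] or numeric matrix.
#' @param n number of superpixels.
#' @param marking optional `object_marking` used to binarize.
#' @param weight relative weight of intensity against normalized position.
#' @param seed RNG seed for the k-means initialization.
#' @return A `segmentation_result` with extra `labels` matrix.
#' @export
superpixels <- function(img, n = 20, marking = NULL, weight = 2, seed = 0L) {
  f <- unclass(as_gray_image(img))
  H <- nrow(f); W <- ncol(f)
  n <- min(n, H * W)
  feats <- cbind(as.vector(row(f)) / max(H, W),
                 as.vector(col(f)) / max(H, W),
                 as.vector(f) * weight)
  km <- withr::with_seed(as.integer(seed), {
    if (n == 1L) list(cluster = rep(1L, H * W))
    else kmeans(feats, centers = n, nstart = 3, iter.max = 300,
                algorithm = "MacQueen")
  })
  labels <- matrix(km$cluster, H, W)
  mask <- NULL
  if (!is.null(marking) && length(marking$masks)) {
    marked <- Reduce(`|`, lapply(marking$masks, unclass))
    keep <- vapply(seq_len(n), function(k) {
      inside <- labels == k
      mean(marked[inside]) > 0.5
    }, logical(1))
    mask <- matrix(keep[labels], H, W)
  }
  new_segmentation(mask, "superpixels", list(n = n, weight = weight,
                                             seed = seed),
                   labels = labels)
}

#' Roberts cross edge detection
#'
#' Convolves the image with the two 2x2 Roberts kernels, takes the
#' gradient magnitude, and thresholds it strictly at its mean. A constant
#' image has an empty edge map.
#'
#' @param img a [gray_image] or numeric matrix.
#' @return A `segmentation_result` with extra `magnitude` matrix.
#' @export
roberts_edges <- function(img) {
  f <- unclass(as_gray_image(img))
  g1 <- f - shift_mat(f, -1, -1, fill = NA)
  g2 <- shift_mat(f, 0, -1, fill = NA) - shift_mat(f, -1, 0, fill = NA)
  mag <- sqrt(ifelse(is.na(g1), 0, g1)^2 + ifelse(is.na(g2), 0, g2)^2)
  new_segmentation(mag > mean(mag), "roberts", list(), magnitude = mag)
}

#' Active contour (snake) segmentation initialized from a marking
#'
#' Fits one closed parametric snake per marked object, initialized at the
#' (slightly dilated) convex hull of the mask so it encloses the object,
#' and evolved with the classic implicit scheme: internal elasticity and
#' rigidity terms solved through a circulant pentadiagonal system, and an
#' external force pulling the contour towards maxima of the smoothed
#' squared gradient magnitude. The segmentation is the union of the snake
#' interiors. Requires a non-empty marking (there is no sensible
#' unsupervised initialization without one).
#'
#' @param img a [gray_image] or numeric matrix.
#' @param marking an `object_marking` with at least one mask.
#' @param alpha elasticity weight (shrinks the contour).
#' @param beta rigidity weight.
#' @param gamma implicit step size.
#' @param w_edge weight of the edge attraction force.
#' @param n_points number of snake vertices.
#' @param iterations evolution steps.
#' @return A `segmentation_result` with extra `snakes` (list of vertex
#'   matrices).
#' @export
active_contour_segment <- function(img, marking, alpha = 1, beta = 1,
                                   gamma = 1, w_edge = 8, n_points = 150,
                                   iterations = 500) {
  if (is.null(marking) || length(marking$masks) == 0)
    stop("active contour segmentation requires a non-empty object marking")
  f <- unclass(as_gray_image(img))
  H <- nrow(f); W <- ncol(f)
  # edge map: squared gradient magnitude of a lightly smoothed image
  fs <- unclass(smooth_image(f, 3))
  gr <- (shift_mat(fs, -1, 0, NA) - shift_mat(fs, 1, 0, NA)) / 2
  gc <- (shift_mat(fs, 0, -1, NA) - shift_mat(fs, 0, 1, NA)) / 2
  e <- ifelse(is.na(gr), 0, gr)^2 + ifelse(is.na(gc), 0, gc)^2
  if (max(e) > 0) e <- e / max(e) # scale-free edge attraction
  er <- (shift_mat(e, -1, 0, NA) - shift_mat(e, 1, 0, NA)) / 2
  ec <- (shift_mat(e, 0, -1, NA) - shift_mat(e, 0, 1, NA)) / 2
  er[is.na(er)] <- 0; ec[is.na(ec)] <- 0
  # implicit internal-energy operator (circulant pentadiagonal)
  n <- n_points
  a <- alpha; b <- beta
  row0 <- numeric(n)
  row0[1] <- 2 * a + 6 * b
  row0[2] <- -a - 4 * b; row0[n] <- -a - 4 * b
  row0[3] <- b; row0[n - 1] <- b
  A <- matrix(0, n, n)
  for (i in seq_len(n)) A[i, ] <- row0[((seq_len(n) - i) %% n) + 1]
  Minv <- solve(A + gamma * diag(n))
  bilinear <- function(m, r, c) {
    r <- pmin(pmax(r, 1), H); c <- pmin(pmax(c, 1), W)
    r0 <- pmin(floor(r), H - 1); c0 <- pmin(floor(c), W - 1)
    fr <- r - r0; fc <- c - c0
    m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
      m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
      m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
      m[cbind(r0 + 1, c0 + 1)] * fr * fc
  }
  masks <- list()
  snakes <- list()
  for (msk in marking$masks) {
    init <- snake_init(unclass(msk), n)
    xr <- init[, 1]; xc <- init[, 2]
    for (it in seq_len(iterations)) {
      fr <- w_edge * bilinear(er, xr, xc)
      fc <- w_edge * bilinear(ec, xr, xc)
      xr <- Minv %*% (gamma * xr + fr)
      xc <- Minv %*% (gamma * xc + fc)
    }
    snakes[[length(snakes) + 1L]] <- cbind(xr, xc)
    masks[[length(masks) + 1L]] <- polygon_fill(as.vector(xr),
                                                as.vector(xc), H, W)
  }
  new_segmentation(Reduce(`|`, masks), "active_contour",
                   list(alpha = alpha, beta = beta, gamma = gamma,
                        w_edge = w_edge, n_points = n_points,
                        iterations = iterations),
                   snakes = snakes)
}

# convex hull of the 1-pixel-dilated mask, resampled to n points by arc
# length
snake_init <- function(mask, n) {
  dil <- mask
  for (s in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1)))
    dil <- dil | shift_mat(mask, s[1], s[2], FALSE)
  pts <- which(dil, arr.ind = TRUE)
  hull <- pts[grDevices::chull(pts[, 1], pts[, 2]), , drop = FALSE]
  hull <- rbind(hull, hull[1, ])
  seg <- sqrt(diff(hull[, 1])^2 + diff(hull[, 2])^2)
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  at <- seq(0, total, length.out = n + 1)[-(n + 1)]
  cbind(approx(s, hull[, 1], xout = at)$y,
        approx(s, hull[, 2], xout = at)$y)
}
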