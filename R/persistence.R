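#' Persistence diagrams of grayscale images
#'
#' `compute_h0()` computes the 0-dimensional persistence diagram of the
#' sublevel-set filtration \eqn{\{f \le t\}} of a grayscale image, with
#' pixels joined to their eight horizontal, vertical and diagonal
#' neighbours. It runs a union-find sweep over pixels in increasing
#' (value, row, col) order: a component is born at its minimum pixel and,
#' when two components merge, the younger one (larger birth, elder rule,
#' lexicographic tie-break) dies at the merging pixel. Exactly one
#' component never dies; its birth is the global minimum intensity.
#'
#' `compute_h1()` computes the 1-dimensional diagram by digital duality:
#' loops of the 8-connected sublevel set correspond to bounded 4-connected
#' components of the strict superlevel complement, so H1 is obtained as H0
#' of the negated image under 4-connectivity with a virtual node joining
#' all border pixels (whose component — the unbounded background — is
#' discarded). A dual point \eqn{(b', d')} maps back to the loop
#' \eqn{(-d', -b')}: the loop is born when it closes and dies when its
#' interior fills in.
#'
#' @param img a [gray_image] or numeric matrix with finite values.
#' @return A `persistence_diagram`: a data frame with columns `dimension`,
#'   `birth`, `death` (`Inf` allowed), `birth_row`, `birth_col`,
#'   `death_row`, `death_col`, `lifetime`.
#' @examples
#' d <- compute_h0(gray_image(matrix(c(0.2, 0.8, 0.3), 1)))
#' d$birth  # 0.2 (infinite component) and 0.3 (dies at 0.8)
#' @export
compute_h0 <- function(img) {
  img <- as_gray_image(img)
  raw <- .ph0_cpp(unclass(img), 8L, FALSE)
  new_diagram(data.frame(
    dimension = 0L, birth = raw$birth, death = raw$death,
    birth_row = raw$birth_row, birth_col = raw$birth_col,
    death_row = raw$death_row, death_col = raw$death_col
  ))
}

#' @rdname compute_h0
#' @export
compute_h1 <- function(img) {
  img <- as_gray_image(img)
  raw <- .ph0_cpp(-unclass(img), 4L, TRUE)
  keep <- !raw$virtual & is.finite(raw$death)
  new_diagram(data.frame(
    dimension = rep(1L, sum(keep)),
    birth = -raw$death[keep], death = -raw$birth[keep],
    birth_row = raw$death_row[keep], birth_col = raw$death_col[keep],
    death_row = raw$birth_row[keep], death_col = raw$birth_col[keep]
  ))
}

new_diagram <- function(df) {
  df$lifetime <- df$death - df$birth
  o <- order(-df$lifetime, df$birth, df$birth_row, df$birth_col)
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("persistence_diagram", "data.frame")
  df
}

#' @export
print.persistence_diagram <- function(x, ...) {
  cat(sprintf("persistence diagram (dimension %s): %d points, %d infinite\n",
              paste(unique(x$dimension), collapse = "/"),
              nrow(x), sum(is.infinite(x$death))))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Finite lifetimes of a diagram
#'
#' @param diagram a `persistence_diagram`.
#' @return Numeric vector of lifetimes of the finitely-persisting points.
#' @export
finite_lifetimes <- function(diagram) {
  diagram$lifetime[is.finite(diagram$death)]
}

#' Serialize / deserialize a persistence diagram to CSV
#'
#' Infinite deaths are written as the token `INF`.
#'
#' @param diagram a `persistence_diagram`.
#' @param path CSV file path.
#' @export
write_diagram <- function(diagram, path) {
  out <- as.data.frame(diagram)
  for (col in c("death", "lifetime"))
    out[[col]] <- ifelse(is.infinite(out[[col]]), "INF", out[[col]])
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_diagram
#' @export
read_diagram <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in c("death", "lifetime"))
    df[[col]] <- ifelse(df[[col]] == "INF", Inf, as.numeric(df[[col]]))
  df$lifetime <- NULL
  new_diagram(df)
}

#' Brute-force Betti curve oracle
#'
#' Independent re-derivation of the Betti numbers of the filtration by
#' breadth-first search, used to validate the union-find engine: for each
#' threshold `t`, \eqn{\beta_0} is the number of 8-connected components of
#' \eqn{\{f \le t\}} and \eqn{\beta_1} the number of bounded 4-connected
#' components of \eqn{\{f > t\}}. Intended for small images.
#'
#' @param img a [gray_image] or numeric matrix.
#' @param dimension 0 or 1.
#' @param thresholds numeric vector of filtration values.
#' @return Integer vector of Betti numbers, one per threshold.
#' @export
betti_curve_oracle <- function(img, dimension, thresholds) {
  img <- unclass(as_gray_image(img))
  stopifnot(dimension %in% c(0L, 1L))
  vapply(thresholds, function(t) {
    if (dimension == 0L) {
      bfs_component_count(img <= t, eight = TRUE, bounded_only = FALSE)
    } else {
      bfs_component_count(img > t, eight = FALSE, bounded_only = TRUE)
    }
  }, integer(1))
}

# pure-R BFS component counter, deliberately independent of the C++ engine
bfs_component_count <- function(mask, eight, bounded_only) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  offs <- if (eight) rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                           c(0, 1), c(1, -1), c(1, 0), c(1, 1))
          else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  count <- 0L
  for (r0 in seq_len(H)) for (c0 in seq_len(W)) {
    if (!mask[r0, c0] || seen[r0, c0]) next
    queue <- list(c(r0, c0))
    seen[r0, c0] <- TRUE
    touches_border <- FALSE
    while (length(queue)) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      if (p[1] == 1 || p[1] == H || p[2] == 1 || p[2] == W)
        touches_border <- TRUE
      for (k in seq_len(nrow(offs))) {
        r <- p[1] + offs[k, 1]; c <- p[2] + offs[k, 2]
        if (r >= 1 && r <= H && c >= 1 && c <= W &&
            mask[r, c] && !seen[r, c]) {
          seen[r, c] <- TRUE
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
    if (!bounded_only || !touches_border) count <- count + 1L
  }
  count
}
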