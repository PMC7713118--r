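#' Bottleneck distance between persistence diagrams
#'
#' Exact bottleneck distance
#' \eqn{d_b(D, D') = \inf_\varphi \sup_x \lVert x - \varphi(x)\rVert_\infty}
#' where \eqn{\varphi} ranges over bijections between the diagrams augmented
#' with the diagonal. Points with infinite death must be matched to each
#' other (convention \eqn{\infty - \infty = 0}, so their cost is the birth
#' difference); if the two diagrams have different numbers of infinite
#' points the distance is `Inf`. Finite points may be matched to the
#' diagonal at cost \eqn{(d - b)/2}. The optimum is found by binary search
#' over the finite set of candidate costs with a bipartite-matching
#' feasibility test, exact for the small diagrams this package produces.
#'
#' @param d1,d2 `persistence_diagram` objects of the same dimension.
#' @return Non-negative real (possibly `Inf`).
#' @examples
#' a <- compute_h0(matrix(c(0.2, 0.8, 0.3), 1))
#' bottleneck_distance(a, a) # 0
#' @export
bottleneck_distance <- function(d1, d2) {
  if (length(unique(c(d1$dimension, d2$dimension))) > 1)
    stop("diagrams must be of the same dimension")
  i1 <- d1[is.infinite(d1$death), , drop = FALSE]
  i2 <- d2[is.infinite(d2$death), , drop = FALSE]
  if (nrow(i1) != nrow(i2)) return(Inf)
  inf_cost <- if (nrow(i1)) max(abs(sort(i1$birth) - sort(i2$birth))) else 0
  f1 <- d1[is.finite(d1$death), , drop = FALSE]
  f2 <- d2[is.finite(d2$death), , drop = FALSE]
  n1 <- nrow(f1); n2 <- nrow(f2)
  if (n1 == 0 && n2 == 0) return(inf_cost)
  diag1 <- (f1$death - f1$birth) / 2
  diag2 <- (f2$death - f2$birth) / 2
  cost <- if (n1 && n2) {
    pmax(abs(outer(f1$birth, f2$birth, "-")),
         abs(outer(f1$death, f2$death, "-")))
  } else {
    matrix(numeric(0), n1, n2)
  }
  cand <- sort(unique(c(0, diag1, diag2, as.numeric(cost))))
  lo <- 1L; hi <- length(cand)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (bottleneck_feasible(cand[mid], cost, diag1, diag2)) hi <- mid
    else lo <- mid + 1L
  }
  max(inf_cost, cand[lo])
}

# Feasibility at radius r. Every finite point must go to a partner point
# (infinity-distance <= r) or to the diagonal (half-lifetime <= r); points
# with half-lifetime > r are "forced" to find a partner. A perfect matching
# of the diagonal-augmented diagrams exists iff some single point-to-point
# matching covers all forced points of BOTH sides; by the Mendelsohn-Dulmage
# theorem that holds iff each side's forced set can be saturated on its own.
bottleneck_feasible <- function(r, cost, diag1, diag2) {
  eps <- 1e-12
  r <- r + eps
  saturates <- function(forced, cost_rows) {
    # Kuhn's augmenting-path matching from each forced row into columns
    st <- new.env(parent = emptyenv())
    st$match_col <- integer(ncol(cost_rows))
    for (u in forced) {
      st$visited <- logical(ncol(cost_rows))
      if (!kuhn_augment(u, cost_rows, r, st)) return(FALSE)
    }
    TRUE
  }
  if (!saturates(which(diag1 > r), cost)) return(FALSE)
  saturates(which(diag2 > r), t(cost))
}

kuhn_augment <- function(u, cost_rows, r, st) {
  for (v in which(cost_rows[u, ] <= r)) {
    if (st$visited[v]) next
    st$visited[v] <- TRUE
    if (st$match_col[v] == 0L || kuhn_augment(st$match_col[v], cost_rows, r, st)) {
      st$match_col[v] <- u
      return(TRUE)
    }
  }
  FALSE
}
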