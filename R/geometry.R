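#' @importFrom stats coef lm median predict quantile rnorm runif sd setNames
#' @importFrom utils head modifyList tail
NULL

# ---- small vector helpers -------------------------------------------------

#' Cross product of two 3-vectors
#' @param u,v numeric length-3 vectors.
#' @return numeric length-3 vector `u x v`.
#' @keywords internal
#' @noRd
cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# row-wise cross product for n x 3 matrices
cross_rows <- function(U, V) {
  cbind(U[, 2] * V[, 3] - U[, 3] * V[, 2],
        U[, 3] * V[, 1] - U[, 1] * V[, 3],
        U[, 1] * V[, 2] - U[, 2] * V[, 1])
}

norm3 <- function(u) sqrt(sum(u * u))

as_row3 <- function(x, n) {
  x <- as.numeric(x)
  stopifnot(length(x) == 3L)
  matrix(x, nrow = n, ncol = 3L, byrow = TRUE)
}

# ---- sightlines -----------------------------------------------------------

#' Construct a sightline
#'
#' A sightline is the infinite 3D line through the pupil center (`anchor`)
#' and the line-of-sight convergence point (`through`), in millimetres in
#' the rig (leftmost virtual camera) frame.
#'
#' @param anchor numeric length-3, the pupil center (mm).
#' @param through numeric length-3, a second point on the line, normally the
#'   convergence point (mm).
#' @param tol minimum admissible direction norm (mm).
#' @return an object of class `sight_line` with fields `anchor`, `through`,
#'   `direction`.
#' @examples
#' sight_line(c(0, 0, 0), c(0, 0, -1))
#' @export
sight_line <- function(anchor, through, tol = 1e-9) {
  anchor <- as.numeric(anchor)
  through <- as.numeric(through)
  stopifnot(length(anchor) == 3L, length(through) == 3L)
  direction <- through - anchor
  if (norm3(direction) <= tol) {
    stop("sight_line(): anchor and through point coincide (degenerate line)")
  }
  structure(list(anchor = anchor, through = through, direction = direction),
            class = "sight_line")
}

#' Nearest points of two sightlines
#'
#' Closed-form common-perpendicular construction: with line directions
#' `a` and `b`, the common normal is `n = a x b`; each nearest point is the
#' intersection of one line with the plane spanned by the other line and
#' `n` (whose normals are `n x a` and `n x b`). The result satisfies
#' `(p1 - p2)` perpendicular to both directions.
#'
#' @param line_l,line_r `sight_line` objects (conventionally the left and
#'   right eye sightlines).
#' @param tol dimensionless parallelism tolerance: the lines are declared
#'   parallel when `||a x b|| / (||a|| ||b||)` falls below it.
#' @return a list of class `nearest_point_pair`: `p1`, `p2` (mm), `gap`
#'   (mm, distance between them), `normal` (the common normal vector).
#' @examples
#' l1 <- sight_line(c(0, 0, 0), c(1, 0, 0))
#' l2 <- sight_line(c(0, 1, 1), c(0, 1, 2))
#' nearest_points(l1, l2)$gap # 1
#' @export
nearest_points <- function(line_l, line_r, tol = 1e-12) {
  stopifnot(inherits(line_l, "sight_line"), inherits(line_r, "sight_line"))
  a <- line_l$direction
  b <- line_r$direction
  n <- cross3(a, b)
  if (norm3(n) / (norm3(a) * norm3(b)) < tol) {
    stop("nearest_points(): parallel sightlines, PoR at infinity")
  }
  k123 <- cross3(n, a)
  k456 <- cross3(n, b)
  pL <- line_l$through
  pR <- line_r$through
  t1 <- sum(k456 * (pL - line_r$anchor)) / sum(k456 * a)
  p1 <- pL - t1 * a
  t2 <- sum(k123 * (pR - line_l$anchor)) / sum(k123 * b)
  p2 <- pR - t2 * b
  structure(list(p1 = p1, p2 = p2, gap = norm3(p1 - p2), normal = n),
            class = "nearest_point_pair")
}

#' Midpoint Point-of-Regard from a nearest-point pair
#'
#' The 3D Point-of-Regard estimate is the midpoint of the segment joining
#' the nearest points of the two sightlines; the length of that segment
#' (`gap`) is carried through as a quality indicator.
#'
#' @param pair a `nearest_point_pair` from [nearest_points()].
#' @return a list of class `por_estimate`: `point` (mm), `gap` (mm).
#' @export
midpoint_por <- function(pair) {
  stopifnot(inherits(pair, "nearest_point_pair"))
  structure(list(point = (pair$p1 + pair$p2) / 2, gap = pair$gap),
            class = "por_estimate")
}

# ---- vectorized core used by the calibration search -----------------------

# Nearest points for many line pairs at once.
# PL, PR: n x 3 candidate convergence points; AnchL, AnchR: n x 3 (or length-3)
# pupil centers. Returns list(pe = n x 3 midpoints, gap = n, ok = logical).
nearest_points_many <- function(PL, PR, AnchL, AnchR, tol = 1e-12) {
  n_row <- nrow(PL)
  if (!is.matrix(AnchL)) AnchL <- as_row3(AnchL, n_row)
  if (!is.matrix(AnchR)) AnchR <- as_row3(AnchR, n_row)
  A <- PL - AnchL
  B <- PR - AnchR
  N <- cross_rows(A, B)
  nn <- sqrt(rowSums(N^2))
  ok <- nn / (sqrt(rowSums(A^2)) * sqrt(rowSums(B^2))) >= tol
  K123 <- cross_rows(N, A)
  K456 <- cross_rows(N, B)
  t1 <- rowSums(K456 * (PL - AnchR)) / rowSums(K456 * A)
  t2 <- rowSums(K123 * (PR - AnchL)) / rowSums(K123 * B)
  P1 <- PL - A * t1
  P2 <- PR - B * t2
  gap <- sqrt(rowSums((P1 - P2)^2))
  gap[!ok] <- Inf
  list(pe = (P1 + P2) / 2, gap = gap, ok = ok, p1 = P1, p2 = P2)
}
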