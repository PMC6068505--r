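# Stereo feature matching, triangulation, and 3D pupil-circle fitting.
#
# Cameras are pinhole models after epipolar rectification: per camera an
# intrinsic matrix K (px, 0-based principal point), zero distortion, a
# rotation R (rig -> camera) and the camera center C (mm, rig frame).
# Within a pair the baseline lies along the camera x-axis, so
# corresponding points share the image row.

#' Project rig-frame points into a camera
#'
#' @param X `n x 3` matrix (or length-3 vector) of rig-frame points (mm).
#' @param cam one camera of a [default_rig()] (`K`, `R`, `C`).
#' @return `n x 2` matrix of 0-based pixel coordinates.
#' @export
project_points <- function(X, cam) {
  if (!is.matrix(X)) X <- matrix(X, ncol = 3)
  Xc <- (X - matrix(cam$C, nrow(X), 3, byrow = TRUE)) %*% t(cam$R)
  if (any(Xc[, 3] <= 0)) stop("project_points(): point behind the camera")
  u <- cam$K[1, 1] * Xc[, 1] / Xc[, 3] + cam$K[1, 3]
  v <- cam$K[2, 2] * Xc[, 2] / Xc[, 3] + cam$K[2, 3]
  cbind(x = u, y = v)
}

# back-projected ray directions (rig frame) for 0-based pixels
backproject_dirs <- function(P, cam) {
  if (!is.matrix(P)) P <- matrix(P, ncol = 2)
  d <- cbind((P[, 1] - cam$K[1, 3]) / cam$K[1, 1],
             (P[, 2] - cam$K[2, 3]) / cam$K[2, 2],
             rep(1, nrow(P)))
  d %*% cam$R
}

#' Triangulate index-paired rectified points
#'
#' Rows of `points1` and `points2` are corresponding observations of the
#' same 3D points (no matching step); each pair is triangulated as the
#' midpoint of the nearest points of the two back-projected rays. Used
#' for singular landmarks such as the inner eye corner.
#'
#' @inheritParams match_and_triangulate
#' @return tibble: `x`, `y`, `z` (mm), `gap` (mm).
#' @export
triangulate_points <- function(points1, points2, cam1, cam2,
                               min_disparity = 1e-6) {
  q1 <- as.matrix(points1); q2 <- as.matrix(points2)
  stopifnot(nrow(q1) == nrow(q2))
  if (any(abs(q1[, 1] - q2[, 1]) < min_disparity)) {
    stop("triangulate_points(): point at infinity (near-zero disparity)")
  }
  d1 <- backproject_dirs(q1, cam1)
  d2 <- backproject_dirs(q2, cam2)
  n <- nrow(q1)
  res <- nearest_points_many(
    PL = matrix(cam1$C, n, 3, byrow = TRUE) + d1,
    PR = matrix(cam2$C, n, 3, byrow = TRUE) + d2,
    AnchL = matrix(cam1$C, n, 3, byrow = TRUE),
    AnchR = matrix(cam2$C, n, 3, byrow = TRUE))
  tibble::tibble(x = res$pe[, 1], y = res$pe[, 2], z = res$pe[, 3],
                 gap = res$gap)
}

#' Match rectified points across a camera pair and triangulate
#'
#' Points are grouped into epipolar rows (`round(y / row_tol)`); within a
#' row both sides are ordered left-to-right and paired by rank (the pupil
#' boundary is textureless, so the x-order along the epipolar line is the
#' correspondence rule). Unpaired points are dropped with a warning.
#' Each pair is triangulated as the midpoint of the nearest points of the
#' two back-projected rays; near-zero disparity raises/drops "point at
#' infinity".
#'
#' @param points1,points2 `n x 2` matrices of 0-based pixel coordinates.
#' @param cam1,cam2 the two cameras.
#' @param row_tol epipolar row tolerance (px).
#' @param min_disparity minimum |x1 - x2| (px).
#' @return tibble: `x`, `y`, `z` (mm), `x1`, `y1`, `x2`, `y2` (px),
#'   `gap` (ray miss distance, mm); attribute `n_dropped`.
#' @export
match_and_triangulate <- function(points1, points2, cam1, cam2,
                                  row_tol = 1, min_disparity = 1e-6) {
  p1 <- as.matrix(points1); p2 <- as.matrix(points2)
  b1 <- round(p1[, 2] / row_tol)
  b2 <- round(p2[, 2] / row_tol)
  i1 <- order(b1, p1[, 1]); i2 <- order(b2, p2[, 1])
  m1 <- integer(0); m2 <- integer(0)
  for (b in intersect(unique(b1), unique(b2))) {
    a <- i1[b1[i1] == b]
    c <- i2[b2[i2] == b]
    k <- min(length(a), length(c))
    m1 <- c(m1, a[seq_len(k)])
    m2 <- c(m2, c[seq_len(k)])
  }
  n_dropped <- (nrow(p1) - length(m1)) + (nrow(p2) - length(m2))
  if (!length(m1)) {
    out <- tibble::tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                          x1 = numeric(0), y1 = numeric(0),
                          x2 = numeric(0), y2 = numeric(0), gap = numeric(0))
    attr(out, "n_dropped") <- n_dropped
    return(out)
  }
  q1 <- p1[m1, , drop = FALSE]; q2 <- p2[m2, , drop = FALSE]
  disp <- abs(q1[, 1] - q2[, 1])
  far <- disp < min_disparity
  if (any(far)) {
    warning(sprintf("match_and_triangulate(): %d point(s) at infinity (near-zero disparity) dropped",
                    sum(far)))
    n_dropped <- n_dropped + sum(far)
    q1 <- q1[!far, , drop = FALSE]; q2 <- q2[!far, , drop = FALSE]
  }
  if (!nrow(q1)) {
    out <- tibble::tibble(x = numeric(0), y = numeric(0), z = numeric(0),
                          x1 = numeric(0), y1 = numeric(0),
                          x2 = numeric(0), y2 = numeric(0), gap = numeric(0))
    attr(out, "n_dropped") <- n_dropped
    return(out)
  }
  d1 <- backproject_dirs(q1, cam1)
  d2 <- backproject_dirs(q2, cam2)
  n <- nrow(q1)
  res <- nearest_points_many(
    PL = matrix(cam1$C, n, 3, byrow = TRUE) + d1,
    PR = matrix(cam2$C, n, 3, byrow = TRUE) + d2,
    AnchL = matrix(cam1$C, n, 3, byrow = TRUE),
    AnchR = matrix(cam2$C, n, 3, byrow = TRUE))
  out <- tibble::tibble(x = res$pe[, 1], y = res$pe[, 2], z = res$pe[, 3],
                        x1 = q1[, 1], y1 = q1[, 2],
                        x2 = q2[, 1], y2 = q2[, 2], gap = res$gap)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Least-squares 3D circle fit
#'
#' Fits the plane by total least squares (SVD of the centered points),
#' projects the points into the plane, fits a 2D circle algebraically,
#' and lifts the center back to 3D. The plane normal is returned with a
#' positive Z component. The pupil size is the circle's diameter.
#'
#' @param points `n x 3` matrix of 3D points (mm), `n >= 3`,
#'   non-collinear.
#' @param tol collinearity tolerance on the second singular value.
#' @return list of class `pupil_circle`: `center` (mm), `radius` (mm),
#'   `normal` (unit), `size` (`= 2 * radius`, mm), `rms` (mm).
#' @export
fit_circle_3d <- function(points, tol = 1e-9) {
  P <- as.matrix(points)
  if (nrow(P) < 3) stop("fit_circle_3d(): need >= 3 points")
  ctr <- colMeans(P)
  Q <- sweep(P, 2, ctr)
  sv <- svd(Q)
  if (sv$d[2] < tol * max(sv$d[1], 1)) {
    stop("fit_circle_3d(): degenerate circle (collinear points)")
  }
  e1 <- sv$v[, 1]; e2 <- sv$v[, 2]; nrm <- sv$v[, 3]
  u <- Q %*% e1
  v <- Q %*% e2
  # algebraic (Kasa) circle fit in-plane
  A <- cbind(2 * u, 2 * v, 1)
  b <- u^2 + v^2
  sol <- qr.solve(A, b)
  r <- sqrt(sol[3] + sol[1]^2 + sol[2]^2)
  center <- ctr + sol[1] * e1 + sol[2] * e2
  if (nrm[3] < 0) nrm <- -nrm
  rms <- sqrt(mean((sqrt((u - sol[1])^2 + (v - sol[2])^2) - r)^2))
  structure(list(center = as.numeric(center), radius = r,
                 normal = as.numeric(nrm), size = 2 * r, rms = rms),
            class = "pupil_circle")
}

# x-coordinates where an ellipse crosses image row y (2 solutions);
# returns NULL if the row misses the ellipse
ellipse_row_crossings <- function(e, yr) {
  ca <- cos(e$alpha); sa <- sin(e$alpha)
  # conic coefficients of the ellipse
  a2 <- e$a^2; b2 <- e$b^2
  A <- ca^2 / a2 + sa^2 / b2
  B <- 2 * ca * sa * (1 / a2 - 1 / b2)
  C <- sa^2 / a2 + ca^2 / b2
  dy <- yr - e$y0
  disc <- B^2 * dy^2 - 4 * A * (C * dy^2 - 1)
  if (disc <= 0) return(NULL)
  sq <- sqrt(disc)
  xs <- c((-B * dy - sq) / (2 * A), (-B * dy + sq) / (2 * A))
  sort(xs) + e$x0
}

#' Reconstruct the 3D pupil circle from a stereo ellipse pair
#'
#' Samples the two fitted pupil ellipses along common epipolar rows (each
#' row crosses the boundary twice; crossings are matched left-to-left and
#' right-to-right), triangulates the crossings, and fits the spatial
#' circle.
#'
#' @param e1,e2 `ellipse2d` objects from the two cameras of one pair.
#' @param cam1,cam2 the cameras.
#' @param n_rows number of epipolar rows sampled.
#' @param row_margin fraction of the vertical extent skipped at the top
#'   and bottom (crossings near tangency are ill-conditioned).
#' @return a `pupil_circle`.
#' @export
reconstruct_pupil_circle <- function(e1, e2, cam1, cam2, n_rows = 40,
                                     row_margin = 0.15) {
  yext <- function(e) {
    # vertical half-extent of the ellipse
    sqrt((e$a * sin(e$alpha))^2 + (e$b * cos(e$alpha))^2)
  }
  lo <- max(e1$y0 - yext(e1), e2$y0 - yext(e2))
  hi <- min(e1$y0 + yext(e1), e2$y0 + yext(e2))
  span <- hi - lo
  rows <- seq(lo + row_margin * span, hi - row_margin * span,
              length.out = n_rows)
  p1 <- NULL; p2 <- NULL
  for (yr in rows) {
    c1 <- ellipse_row_crossings(e1, yr)
    c2 <- ellipse_row_crossings(e2, yr)
    if (is.null(c1) || is.null(c2)) next
    p1 <- rbind(p1, cbind(c1, yr))
    p2 <- rbind(p2, cbind(c2, yr))
  }
  if (is.null(p1) || nrow(p1) < 6) {
    stop("reconstruct_pupil_circle(): too few common epipolar rows")
  }
  tri <- match_and_triangulate(p1, p2, cam1, cam2)
  fit_circle_3d(cbind(tri$x, tri$y, tri$z))
}

#' Assemble a binocular feature record
#'
#' @param left,right per-eye lists with `circle` (a `pupil_circle`) and
#'   `corner` (length-3 position, mm, rig frame); `NULL` marks a missing
#'   eye and raises an error naming the side.
#' @param placement,fixation labels carried into the record.
#' @return one-row tibble in the standard feature schema (pupil centers,
#'   pupil sizes, corners; mm, rig frame).
#' @export
assemble_features <- function(left, right, placement = NA_integer_,
                              fixation = NA_integer_) {
  if (is.null(left)) stop("assemble_features(): left eye missing")
  if (is.null(right)) stop("assemble_features(): right eye missing")
  tibble::tibble(
    placement = placement, fixation = fixation,
    pupil_lx = left$circle$center[1], pupil_ly = left$circle$center[2],
    pupil_lz = left$circle$center[3],
    pupil_rx = right$circle$center[1], pupil_ry = right$circle$center[2],
    pupil_rz = right$circle$center[3],
    s_left = left$circle$size, s_right = right$circle$size,
    corner_lx = left$corner[1], corner_ly = left$corner[2],
    corner_lz = left$corner[3],
    corner_rx = right$corner[1], corner_ry = right$corner[2],
    corner_rz = right$corner[3])
}

#' Detect and reconstruct binocular features from a four-camera frame set
#'
#' Runs the single-camera pipeline ([detect_eye_features()]) on each of
#' the four images, triangulates the inner corners, reconstructs the 3D
#' pupil circles from the stereo ellipse pairs, and assembles the feature
#' record.
#'
#' @param frames named list of grayscale matrices `L1`, `L2`, `R1`, `R2`.
#' @param rig a [default_rig()].
#' @param seed RANSAC seed.
#' @param placement,fixation labels carried through.
#' @param ... passed to [detect_eye_features()].
#' @return one-row feature tibble (see [assemble_features()]).
#' @export
extract_frame_features <- function(frames, rig, seed = 1,
                                   placement = NA_integer_,
                                   fixation = NA_integer_, ...) {
  stopifnot(all(c("L1", "L2", "R1", "R2") %in% names(frames)))
  one_eye <- function(ids, side) {
    f1 <- detect_eye_features(frames[[ids[1]]], side = side, seed = seed, ...)
    f2 <- detect_eye_features(frames[[ids[2]]], side = side, seed = seed, ...)
    cam1 <- rig$cameras[[ids[1]]]; cam2 <- rig$cameras[[ids[2]]]
    circle <- reconstruct_pupil_circle(f1$ellipse, f2$ellipse, cam1, cam2)
    tri <- triangulate_points(cbind(f1$corner$x, f1$corner$y),
                              cbind(f2$corner$x, f2$corner$y), cam1, cam2)
    list(circle = circle, corner = c(tri$x[1], tri$y[1], tri$z[1]))
  }
  left <- one_eye(c("L1", "L2"), "left")
  right <- one_eye(c("R1", "R2"), "right")
  assemble_features(left, right, placement = placement, fixation = fixation)
}
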