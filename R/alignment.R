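# Eye coordinate frame anchored on the inner eye corners, and the
# corner-vector based transfer of calibrated convergence points.

#' Build the eye coordinate frame from the two inner eye corners
#'
#' The eye frame has its origin at the right inner eye corner; its axes and
#' scale are those of the rig (camera) frame, so the frame is a pure
#' translation. The inner-corner vector `v` runs from the right corner to
#' the left corner (direction fixed project-wide as `left - right`).
#'
#' @param corner_left,corner_right numeric length-3 inner-corner positions
#'   (mm, rig frame).
#' @param tol minimum corner separation (mm).
#' @return list of class `eye_frame`: `origin` (right corner), `v`
#'   (corner vector, mm).
#' @export
build_eye_frame <- function(corner_left, corner_right, tol = 1e-9) {
  corner_left <- as.numeric(corner_left)
  corner_right <- as.numeric(corner_right)
  stopifnot(length(corner_left) == 3L, length(corner_right) == 3L)
  v <- corner_left - corner_right
  if (norm3(v) <= tol) stop("build_eye_frame(): coincident inner corners")
  structure(list(origin = corner_right, v = v), class = "eye_frame")
}

#' Minimal (geodesic) rotation carrying one vector's direction onto another's
#'
#' Returns the rotation about the axis `u x w` by the angle between `u` and
#' `w` — the unique smallest rotation with `R u/||u|| = w/||w||`. The
#' rotation between two vectors is one degree of freedom short of unique;
#' the geodesic choice is the only canonical continuous one. For
#' anti-parallel inputs the axis is the smallest-index coordinate axis
#' orthogonal to `u` (deterministic).
#'
#' @param u,w numeric length-3 vectors (non-zero).
#' @return 3x3 rotation matrix.
#' @export
minimal_rotation <- function(u, w) {
  u <- as.numeric(u); w <- as.numeric(w)
  nu <- norm3(u); nw <- norm3(w)
  if (nu == 0 || nw == 0) stop("minimal_rotation(): zero vector")
  u <- u / nu; w <- w / nw
  c_ <- sum(u * w)
  axis <- cross3(u, w)
  s_ <- norm3(axis)
  if (s_ < 1e-15) {
    if (c_ > 0) return(diag(3))
    # anti-parallel: rotate by pi about a deterministic axis orthogonal to u
    k <- which.min(abs(u))[1]
    e <- c(0, 0, 0); e[k] <- 1
    axis <- e - sum(e * u) * u
    axis <- axis / norm3(axis)
    return(2 * tcrossprod(axis) - diag(3))
  }
  axis <- axis / s_
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + s_ * K + (1 - c_) * (K %*% K)
}

# unit quaternion (w, x, y, z) <-> rotation matrix; used for serialization
rotation_to_quaternion <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    j <- (i %% 3) + 1L; k <- (j %% 3) + 1L
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- s / 4
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  q / sqrt(sum(q^2))
}

quaternion_to_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

#' Record the convergence reference for a calibrated session
#'
#' Stores, in the eye frame of the calibration session, everything needed to
#' re-express the calibrated pair of line-of-sight convergence points under a
#' later head/device micro-shift: the reference corner vector `v0`, the
#' reference right-corner position, and for each eye the minimal rotation
#' carrying `v0` onto the convergence-point vector plus that vector's norm.
#'
#' @param frame `eye_frame` at calibration time.
#' @param p_left,p_right calibrated convergence points (mm, rig frame).
#' @return list of class `convergence_reference`: `v0`, `origin`, and per
#'   eye `R` (rotation), `norm` (mm).
#' @export
record_reference <- function(frame, p_left, p_right) {
  stopifnot(inherits(frame, "eye_frame"))
  mk <- function(p) {
    v <- as.numeric(p) - frame$origin
    if (norm3(v) <= 1e-12) {
      stop("record_reference(): convergence point coincides with the eye-frame origin")
    }
    list(R = minimal_rotation(frame$v, v), norm = norm3(v))
  }
  structure(list(v0 = frame$v, origin = frame$origin,
                 left = mk(p_left), right = mk(p_right)),
            class = "convergence_reference")
}

#' Transfer the calibrated convergence pair into a new eye frame
#'
#' The current corner vector `v_i` determines the minimal rotation
#' `R' = minimal_rotation(v0, v_i)`; each calibrated convergence vector is
#' rotated by `R'` and re-anchored at the current right corner, preserving
#' its calibrated norm. Head roll about the corner vector itself is
#' unobservable from the two corners and is (by construction) not corrected.
#'
#' @param reference `convergence_reference` from [record_reference()].
#' @param frame current `eye_frame`.
#' @return list with `p_left`, `p_right` (mm, rig frame) and `r_prime`
#'   (the applied 3x3 rotation).
#' @export
transfer_convergence <- function(reference, frame) {
  stopifnot(inherits(reference, "convergence_reference"),
            inherits(frame, "eye_frame"))
  if (norm3(frame$v) <= 1e-12) stop("transfer_convergence(): degenerate corner vector")
  r_prime <- minimal_rotation(reference$v0, frame$v)
  one <- function(eye) {
    w <- r_prime %*% (eye$R %*% reference$v0)
    as.numeric(frame$origin + w * (eye$norm / norm3(w)))
  }
  list(p_left = one(reference$left), p_right = one(reference$right),
       r_prime = r_prime)
}

# Express a rig-frame point in the reference eye frame (inverse of the
# transfer): rotate the corner-relative offset back by R'^T.
align_to_reference <- function(reference, frame, p) {
  r_prime <- minimal_rotation(reference$v0, frame$v)
  as.numeric(crossprod(r_prime, as.numeric(p) - frame$origin))
}

# Map a reference-frame offset vector into the current rig frame.
reference_to_rig <- function(reference, frame, u) {
  r_prime <- minimal_rotation(reference$v0, frame$v)
  as.numeric(frame$origin + r_prime %*% as.numeric(u))
}
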