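# Single-camera eye-image analysis: eye-region localization, adaptive
# gradient pupil edge extraction, two-step ellipse fitting, and
# multi-scale Harris inner-corner detection.
#
# Images are numeric matrices with intensities in [0, 255], indexed
# img[y + 1, x + 1]; all public pixel coordinates are 0-based with
# x = column and y = row.

# ---- low-level kernels ----------------------------------------------------

# gradient magnitude by central differences (zero on the 1-px border)
gradient_magnitude <- function(img) {
  n <- nrow(img); m <- ncol(img)
  gx <- matrix(0, n, m)
  gy <- matrix(0, n, m)
  if (m >= 3) gx[, 2:(m - 1)] <- (img[, 3:m] - img[, 1:(m - 2)]) / 2
  if (n >= 3) gy[2:(n - 1), ] <- (img[3:n, ] - img[1:(n - 2), ]) / 2
  g <- sqrt(gx^2 + gy^2)
  g[c(1, n), ] <- 0
  g[, c(1, m)] <- 0
  g
}

# 3x3 neighborhood sums, zero padding
box3_sum <- function(img) {
  n <- nrow(img); m <- ncol(img)
  p <- matrix(0, n + 2, m + 2)
  p[2:(n + 1), 2:(m + 1)] <- img
  p[1:n, 1:m] + p[1:n, 2:(m + 1)] + p[1:n, 3:(m + 2)] +
    p[2:(n + 1), 1:m] + p[2:(n + 1), 2:(m + 1)] + p[2:(n + 1), 3:(m + 2)] +
    p[3:(n + 2), 1:m] + p[3:(n + 2), 2:(m + 1)] + p[3:(n + 2), 3:(m + 2)]
}

# binary dilation by a (2r+1)x(2r+1) square (Chebyshev radius r)
dilate_square <- function(mask, r) {
  if (r <= 0) return(mask)
  n <- nrow(mask); m <- ncol(mask)
  p <- matrix(FALSE, n + 2 * r, m + 2 * r)
  p[(r + 1):(r + n), (r + 1):(r + m)] <- mask
  out <- matrix(FALSE, n, m)
  for (dy in -r:r) for (dx in -r:r) {
    out <- out | p[(r + 1 + dy):(r + n + dy), (r + 1 + dx):(r + m + dx)]
  }
  out
}

# separable Gaussian smoothing with edge replication
gaussian_smooth <- function(img, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  n <- nrow(img); m <- ncol(img)
  # rows (y direction)
  pad <- img[c(rep(1, r), 1:n, rep(n, r)), , drop = FALSE]
  tmp <- matrix(0, n, m)
  for (i in seq_along(k)) tmp <- tmp + k[i] * pad[i:(i + n - 1), , drop = FALSE]
  pad <- tmp[, c(rep(1, r), 1:m, rep(m, r)), drop = FALSE]
  out <- matrix(0, n, m)
  for (i in seq_along(k)) out <- out + k[i] * pad[, i:(i + m - 1), drop = FALSE]
  out
}

# ---- eye region -----------------------------------------------------------

#' Locate the eye region by intensity projections
#'
#' Computes smoothed horizontal and vertical mean-intensity projections;
#' the dark eye structures (pupil, iris, lids) produce a low-intensity
#' trough in both. The region is the contiguous span around each
#' projection's global minimum where the projection stays below
#' `min + depth_frac * range`, padded by `pad_frac` of the image size.
#'
#' @param img grayscale matrix (`img[y+1, x+1]`, 0..255).
#' @param depth_frac trough depth fraction defining the span.
#' @param pad_frac padding added around the span.
#' @param flat_tol minimum projection range (intensity units); flatter
#'   images raise a "no eye found" error.
#' @return list of class `eye_box`: `x0`, `y0`, `x1`, `y1` (0-based,
#'   inclusive).
#' @export
locate_eye_region <- function(img, depth_frac = 0.5, pad_frac = 0.1,
                              flat_tol = 2) {
  stopifnot(is.matrix(img), nrow(img) > 0, ncol(img) > 0)
  span_of <- function(proj) {
    w <- max(3L, round(length(proj) * 0.05))
    k <- rep(1 / w, w)
    sm <- stats::filter(proj, k, sides = 2)
    sm[is.na(sm)] <- proj[is.na(sm)]
    sm <- as.numeric(sm)
    rng <- max(sm) - min(sm)
    if (rng < flat_tol) stop("locate_eye_region(): no eye found (flat image)")
    thr <- min(sm) + depth_frac * rng
    lo <- hi <- which.min(sm)
    while (lo > 1 && sm[lo - 1] < thr) lo <- lo - 1
    while (hi < length(sm) && sm[hi + 1] < thr) hi <- hi + 1
    pad <- round(length(proj) * pad_frac)
    c(max(1L, lo - pad), min(length(proj), hi + pad))
  }
  xs <- span_of(colMeans(img))
  ys <- span_of(rowMeans(img))
  structure(list(x0 = xs[1] - 1L, y0 = ys[1] - 1L,
                 x1 = xs[2] - 1L, y1 = ys[2] - 1L),
            class = "eye_box")
}

crop_box <- function(img, box) {
  img[(box$y0 + 1L):(box$y1 + 1L), (box$x0 + 1L):(box$x1 + 1L), drop = FALSE]
}

# ---- pupil edge map -------------------------------------------------------

#' Adaptive gradient pupil edge map
#'
#' Computes the gradient amplitude map of the (eye-region) image and
#' retains pupil-edge candidates: (i) the amplitude is zeroed near the
#' image center and the four corners; (ii) the map is divided into 3x3
#' blocks and only values above each block's mean (over its surviving
#' non-zero values) are kept; (iii) the amplitude is zeroed inside the
#' dilated specular-spot mask; (iv) a pixel is retained iff its 3x3
#' neighborhood sum of surviving gradient values exceeds the global
#' threshold `0.6 * sum(neighborhood sums) / (6 m n)`; pixels inside the
#' zeroed margins or the spot mask are never retained.
#'
#' @param img grayscale matrix cropped to the eye region.
#' @param center_margin,corner_margin margins (fraction of each image
#'   dimension) zeroed around the center and at the four corners.
#' @param spot_threshold intensity above which a pixel counts as a
#'   specular bright spot.
#' @param spot_dilate dilation radius (px) of the spot mask.
#' @param threshold_scale scale of the global retention threshold.
#' @return list of class `edge_map`: `amplitude` (surviving gradient
#'   values g), `retained` (binary matrix GG), `points` (k x 2 matrix of
#'   0-based x, y of retained pixels), `block_grid`.
#' @export
pupil_edge_map <- function(img, center_margin = 0.05, corner_margin = 0.05,
                           spot_threshold = 250, spot_dilate = 3,
                           threshold_scale = 0.6) {
  stopifnot(is.matrix(img))
  n <- nrow(img); m <- ncol(img)
  g <- gradient_magnitude(img)

  # zero near the center and at the four corners
  zeroed <- matrix(FALSE, n, m)
  cx <- (m + 1) / 2; cy <- (n + 1) / 2
  wx <- max(1, round(m * center_margin)); wy <- max(1, round(n * center_margin))
  zeroed[max(1, round(cy - wy)):min(n, round(cy + wy)),
         max(1, round(cx - wx)):min(m, round(cx + wx))] <- TRUE
  kx <- max(1, round(m * corner_margin)); ky <- max(1, round(n * corner_margin))
  zeroed[1:ky, 1:kx] <- TRUE
  zeroed[1:ky, (m - kx + 1):m] <- TRUE
  zeroed[(n - ky + 1):n, 1:kx] <- TRUE
  zeroed[(n - ky + 1):n, (m - kx + 1):m] <- TRUE
  g[zeroed] <- 0

  # 3x3 blocks: keep values above the block mean of surviving values
  rb <- floor(seq(0, n, length.out = 4))
  cb <- floor(seq(0, m, length.out = 4))
  for (i in 1:3) for (j in 1:3) {
    rows <- (rb[i] + 1):rb[i + 1]
    cols <- (cb[j] + 1):cb[j + 1]
    blk <- g[rows, cols]
    nz <- blk[blk > 0]
    if (length(nz)) {
      blk[blk <= mean(nz)] <- 0
      g[rows, cols] <- blk
    }
  }

  # zero near bright spots
  spot <- dilate_square(img > spot_threshold, spot_dilate)
  g[spot] <- 0

  s <- box3_sum(g)
  thr <- threshold_scale * sum(s) / (6 * m * n)
  gg <- (s > thr) * 1L
  # retained is 0 wherever the amplitude was zeroed by the margin and
  # spot rules (the neighborhood sum can otherwise leak across them)
  gg[zeroed] <- 0L
  gg[spot] <- 0L

  idx <- which(gg == 1L, arr.ind = TRUE)
  points <- cbind(x = idx[, 2] - 1L, y = idx[, 1] - 1L)
  structure(list(amplitude = g, retained = gg, points = points,
                 block_grid = list(rows = rb, cols = cb)),
            class = "edge_map")
}

# ---- ellipse model --------------------------------------------------------

ellipse2d <- function(x0, y0, a, b, alpha) {
  # canonical form: A >= B > 0, alpha in (-pi/2, pi/2]
  if (b > a) {
    tmp <- a; a <- b; b <- tmp
    alpha <- alpha + pi / 2
  }
  alpha <- ((alpha + pi / 2) %% pi) - pi / 2
  if (alpha == -pi / 2) alpha <- pi / 2
  structure(list(x0 = x0, y0 = y0, a = a, b = b, alpha = alpha),
            class = "ellipse2d")
}

#' Parametric points on an ellipse
#'
#' @param e an `ellipse2d` (center, semi-axes `a >= b`, tilt `alpha`).
#' @param theta point parameters (radians).
#' @return `length(theta) x 2` matrix of x, y.
#' @export
ellipse_points <- function(e, theta) {
  ca <- cos(e$alpha); sa <- sin(e$alpha)
  u <- e$a * cos(theta); v <- e$b * sin(theta)
  cbind(x = e$x0 + ca * u - sa * v, y = e$y0 + sa * u + ca * v)
}

# conic (a b c d e f) for a x^2 + b xy + c y^2 + d x + e y + f = 0 -> ellipse
conic_to_ellipse <- function(cf) {
  a <- cf[1]; b <- cf[2] / 2; c <- cf[3]; d <- cf[4] / 2; e <- cf[5] / 2; f <- cf[6]
  den <- a * c - b^2
  if (!is.finite(den) || den <= 0) return(NULL)
  x0 <- (b * e - c * d) / den
  y0 <- (b * d - a * e) / den
  mu <- a * x0^2 + 2 * b * x0 * y0 + c * y0^2 + 2 * d * x0 + 2 * e * y0 + f
  M <- matrix(c(a, b, b, c), 2, 2) / (-mu)
  ev <- eigen(M, symmetric = TRUE)
  if (any(ev$values <= 0)) return(NULL)
  axes <- 1 / sqrt(ev$values)      # decreasing eigenvalues -> increasing axes
  major_vec <- ev$vectors[, which.min(ev$values)]
  alpha <- atan2(major_vec[2], major_vec[1])
  ellipse2d(x0, y0, max(axes), min(axes), alpha)
}

# direct least-squares ellipse fit (Halir & Flusser stabilization)
fit_ellipse_lsq <- function(x, y) {
  if (length(x) < 5) stop("fit_pupil_ellipse(): insufficient edge support (< 5 points)")
  mx <- mean(x); my <- mean(y)
  sc <- mean(c(stats::sd(x), stats::sd(y)))
  if (!is.finite(sc) || sc == 0) sc <- 1
  xs <- (x - mx) / sc; ys <- (y - my) / sc
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T_ <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(T_)) stop("fit_pupil_ellipse(): fit failed (degenerate design)")
  M <- S1 + S2 %*% T_
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  evec <- Re(ev$vectors)
  cond <- 4 * evec[1, ] * evec[3, ] - evec[2, ]^2
  ok <- which(cond > 0)
  if (!length(ok)) stop("fit_pupil_ellipse(): fit failed (non-elliptical solution)")
  a1 <- evec[, ok[1]]
  cf_s <- c(a1, as.numeric(T_ %*% a1))
  # un-scale the conic back to original coordinates
  A <- cf_s[1]; B <- cf_s[2]; C <- cf_s[3]; D <- cf_s[4]; E <- cf_s[5]; F <- cf_s[6]
  cf <- c(A / sc^2,
          B / sc^2,
          C / sc^2,
          (-2 * A * mx - B * my) / sc^2 + D / sc,
          (-B * mx - 2 * C * my) / sc^2 + E / sc,
          (A * mx^2 + B * mx * my + C * my^2) / sc^2 - (D * mx + E * my) / sc + F)
  e <- conic_to_ellipse(cf)
  if (is.null(e)) stop("fit_pupil_ellipse(): fit failed (non-elliptical solution)")
  e
}

# exact conic through 5 points (nullspace of the design); NULL if degenerate
conic_through_5 <- function(x, y) {
  D <- cbind(x^2, x * y, y^2, x, y, 1)
  sv <- svd(D, nu = 0, nv = 6)
  cf <- sv$v[, 6]
  conic_to_ellipse(cf)
}

#' Metric distance from points to an ellipse
#'
#' Orthogonal (nearest-point) distance, computed by Newton iteration on
#' the parametric angle in the ellipse frame (first-quadrant reduction;
#' tolerance 1e-9).
#'
#' @param e an `ellipse2d`.
#' @param x,y point coordinates (vectors).
#' @return vector of distances (px).
#' @export
point_ellipse_distance <- function(e, x, y) {
  ca <- cos(e$alpha); sa <- sin(e$alpha)
  dx <- x - e$x0; dy <- y - e$y0
  u <- abs(ca * dx + sa * dy)
  v <- abs(-sa * dx + ca * dy)
  a <- e$a; b <- e$b
  th <- atan2(a * v, b * u)
  for (i in 1:60) {
    ct <- cos(th); st <- sin(th)
    f <- (b^2 - a^2) * st * ct + u * a * st - v * b * ct
    fp <- (b^2 - a^2) * (ct^2 - st^2) + u * a * ct + v * b * st
    step <- f / fp
    step[!is.finite(step)] <- 0
    th <- pmin(pmax(th - step, 0), pi / 2)
    if (max(abs(step)) < 1e-9) break
  }
  sqrt((a * cos(th) - u)^2 + (b * sin(th) - v)^2)
}

#' Two-step pupil ellipse fit (RANSAC then trimmed least squares)
#'
#' Step 1 runs RANSAC over exact 5-point conics (500 iterations, 1.5 px
#' metric inlier tolerance, explicit seed) and refits the consensus set;
#' step 2 discards points whose metric distance to the step-1 ellipse
#' exceeds 1/8 of its major semi-axis length and refits the survivors by
#' direct least squares. The returned ellipse is canonical (`a >= b`,
#' tilt in `(-pi/2, pi/2]`).
#'
#' @param edge an `edge_map` (its `points` are used) or a `k x 2` matrix
#'   of 0-based x, y coordinates.
#' @param seed RANSAC seed (integer).
#' @param n_iter RANSAC iterations.
#' @param inlier_tol RANSAC inlier distance (px).
#' @return an `ellipse2d` with an `inliers` attribute (logical vector
#'   over the input points marking the final fitting set).
#' @export
fit_pupil_ellipse <- function(edge, seed = 1, n_iter = 500, inlier_tol = 1.5) {
  pts <- if (inherits(edge, "edge_map")) edge$points else as.matrix(edge)
  if (nrow(pts) < 5) stop("fit_pupil_ellipse(): insufficient edge support (< 5 points)")
  x <- as.numeric(pts[, 1]); y <- as.numeric(pts[, 2])
  n <- length(x)
  with_seed(seed, {
    best_inl <- NULL
    best_count <- -1L
    for (it in seq_len(n_iter)) {
      idx <- sample.int(n, 5L)
      e <- tryCatch(conic_through_5(x[idx], y[idx]), error = function(err) NULL)
      if (is.null(e)) next
      d <- point_ellipse_distance(e, x, y)
      inl <- d <= inlier_tol
      cnt <- sum(inl)
      if (cnt > best_count) {
        best_count <- cnt
        best_inl <- inl
      }
    }
    if (is.null(best_inl) || best_count < 5) {
      stop("fit_pupil_ellipse(): fit failed (no RANSAC consensus)")
    }
    e1 <- fit_ellipse_lsq(x[best_inl], y[best_inl])
    d <- point_ellipse_distance(e1, x, y)
    keep <- d <= e1$a / 8
    if (sum(keep) < 5) keep <- best_inl
    e2 <- fit_ellipse_lsq(x[keep], y[keep])
    attr(e2, "inliers") <- keep
    e2
  })
}

#' @export
print.ellipse2d <- function(x, ...) {
  cat(sprintf("ellipse: center (%.3f, %.3f) px, semi-axes %.3f x %.3f px, tilt %.4f rad\n",
              x$x0, x$y0, x$a, x$b, x$alpha))
  invisible(x)
}

# ---- inner eye corner -----------------------------------------------------

#' Multi-scale Harris inner-corner detection
#'
#' Computes the Harris corner response at several Gaussian smoothing
#' scales, combines the per-scale responses (each normalized by its
#' maximum) with configured weights, takes the arg-max inside the search
#' region, and refines it to sub-pixel precision by a 2D quadratic fit on
#' the 3x3 response neighborhood.
#'
#' @param img grayscale matrix.
#' @param region an `eye_box` restricting the search (default: whole
#'   image).
#' @param scales Gaussian sigmas (px) of the >= 3 smoothing scales.
#' @param weights per-scale weights (same length as `scales`).
#' @param k Harris trace weight.
#' @param response_threshold minimum combined response at the maximum;
#'   below it a "no corner" error is raised.
#' @return list of class `corner_point`: `x`, `y` (0-based, sub-pixel),
#'   `response`.
#' @export
detect_inner_corner <- function(img, region = NULL,
                                scales = c(1, 2, 4),
                                weights = c(0.5, 0.3, 0.2),
                                k = 0.06, response_threshold = 1e-3) {
  stopifnot(length(scales) >= 3, length(weights) == length(scales))
  if (!is.null(region)) {
    # compute on the (already padded) region crop; responses and the
    # threshold are then local to the search region
    sub <- crop_box(img, region)
    cp <- detect_inner_corner(sub, region = NULL, scales = scales,
                              weights = weights, k = k,
                              response_threshold = response_threshold)
    cp$x <- cp$x + region$x0
    cp$y <- cp$y + region$y0
    return(cp)
  }
  n <- nrow(img); m <- ncol(img)
  combined <- matrix(0, n, m)
  for (i in seq_along(scales)) {
    sm <- gaussian_smooth(img, scales[i])
    gx <- matrix(0, n, m); gy <- matrix(0, n, m)
    gx[, 2:(m - 1)] <- (sm[, 3:m] - sm[, 1:(m - 2)]) / 2
    gy[2:(n - 1), ] <- (sm[3:n, ] - sm[1:(n - 2), ]) / 2
    ixx <- gaussian_smooth(gx * gx, 1.5 * scales[i])
    iyy <- gaussian_smooth(gy * gy, 1.5 * scales[i])
    ixy <- gaussian_smooth(gx * gy, 1.5 * scales[i])
    r <- ixx * iyy - ixy^2 - k * (ixx + iyy)^2
    mx <- max(r)
    if (mx > 0) combined <- combined + weights[i] * r / mx
  }
  mask <- matrix(FALSE, n, m)
  mask[2:(n - 1), 2:(m - 1)] <- TRUE
  rmask <- combined
  rmask[!mask] <- -Inf
  b <- arrayInd(which.max(rmask), dim(rmask))
  if (!is.finite(rmask[b]) || rmask[b] < response_threshold) {
    stop("detect_inner_corner(): no corner (response below threshold)")
  }
  iy <- b[1]; ix <- b[2]
  # sub-pixel quadratic refinement
  patch <- combined[(iy - 1):(iy + 1), (ix - 1):(ix + 1)]
  dx <- (patch[2, 3] - patch[2, 1]) / 2
  dy <- (patch[3, 2] - patch[1, 2]) / 2
  dxx <- patch[2, 3] - 2 * patch[2, 2] + patch[2, 1]
  dyy <- patch[3, 2] - 2 * patch[2, 2] + patch[1, 2]
  dxy <- (patch[3, 3] - patch[3, 1] - patch[1, 3] + patch[1, 1]) / 4
  H <- matrix(c(dxx, dxy, dxy, dyy), 2, 2)
  off <- tryCatch(-solve(H, c(dx, dy)), error = function(e) c(0, 0))
  if (any(!is.finite(off)) || any(abs(off) > 1)) off <- c(0, 0)
  structure(list(x = ix - 1 + off[1], y = iy - 1 + off[2],
                 response = combined[iy, ix]),
            class = "corner_point")
}

# ---- single-camera pipeline ----------------------------------------------

#' Extract pupil ellipse and inner corner from one eye image
#'
#' Full single-camera pipeline: locate the eye region, build the pupil
#' edge map on the crop, fit the pupil ellipse, and detect the inner eye
#' corner in the medial half of the eye box (`side` gives which eye is
#' imaged; the medial canthus of the left eye lies toward smaller x in
#' the image, for the right eye toward larger x).
#'
#' @param img grayscale matrix (full camera frame).
#' @param side `"left"` or `"right"` (which eye the camera images).
#' @param seed RANSAC seed.
#' @param ... passed to [pupil_edge_map()].
#' @return list with `ellipse` (`ellipse2d`, full-image coordinates),
#'   `corner` (`corner_point`), `box` (`eye_box`).
#' @export
detect_eye_features <- function(img, side = c("left", "right"), seed = 1,
                                box_depth = 0.35, box_pad = 0.03, ...) {
  side <- match.arg(side)
  box <- locate_eye_region(img, depth_frac = box_depth, pad_frac = box_pad)
  crop <- crop_box(img, box)
  edge <- pupil_edge_map(crop, ...)
  e <- fit_pupil_ellipse(edge, seed = seed)
  e$x0 <- e$x0 + box$x0
  e$y0 <- e$y0 + box$y0
  cregion <- corner_region_by_segmentation(img, side)
  corner <- detect_inner_corner(img, region = cregion)
  list(ellipse = e, corner = corner, box = box)
}

# Threshold segmentation of the dark eye structures (lid shadows,
# iris, pupil); the inner canthus is the medial extreme of the
# segmented mask. Returns a small search box around it for the Harris
# detector ("left"/"right" is which eye is imaged; the medial side of a
# left eye is at smaller x).
corner_region_by_segmentation <- function(img, side, drop = 15, pad = 25) {
  sm <- gaussian_smooth(img, 2)
  thr <- max(sm) - drop
  mask <- sm < thr
  cols <- which(colSums(mask) >= 2)
  if (!length(cols)) stop("detect_inner_corner(): no corner (segmentation empty)")
  xm <- if (side == "left") min(cols) else max(cols)
  near <- if (side == "left") xm:min(xm + 15, ncol(img)) else
    max(1, xm - 15):xm
  rows <- which(rowSums(mask[, near, drop = FALSE]) > 0)
  ym <- round(mean(range(rows)))
  list(x0 = max(0L, xm - 1L - pad), y0 = max(0L, ym - 1L - pad),
       x1 = min(ncol(img) - 1L, xm - 1L + pad),
       y1 = min(nrow(img) - 1L, ym - 1L + pad))
}
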