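# Independent reference implementations used as oracles. They are kept
# deliberately naive (loops, direct formulas) and share no code with the
# package internals they check.

# literal re-implementation of the adaptive gradient edge map
eq1_oracle <- function(img, center_margin = 0.05, corner_margin = 0.05,
                       spot_threshold = 250, spot_dilate = 3,
                       threshold_scale = 0.6) {
  n <- nrow(img); m <- ncol(img)
  g <- matrix(0, n, m)
  for (y in 2:(n - 1)) for (x in 2:(m - 1)) {
    gx <- (img[y, x + 1] - img[y, x - 1]) / 2
    gy <- (img[y + 1, x] - img[y - 1, x]) / 2
    g[y, x] <- sqrt(gx^2 + gy^2)
  }
  cx <- (m + 1) / 2; cy <- (n + 1) / 2
  wx <- max(1, round(m * center_margin)); wy <- max(1, round(n * center_margin))
  for (y in max(1, round(cy - wy)):min(n, round(cy + wy))) {
    for (x in max(1, round(cx - wx)):min(m, round(cx + wx))) g[y, x] <- 0
  }
  kx <- max(1, round(m * corner_margin)); ky <- max(1, round(n * corner_margin))
  for (y in 1:ky) for (x in 1:kx) g[y, x] <- 0
  for (y in 1:ky) for (x in (m - kx + 1):m) g[y, x] <- 0
  for (y in (n - ky + 1):n) for (x in 1:kx) g[y, x] <- 0
  for (y in (n - ky + 1):n) for (x in (m - kx + 1):m) g[y, x] <- 0
  rb <- floor(seq(0, n, length.out = 4))
  cb <- floor(seq(0, m, length.out = 4))
  for (i in 1:3) for (j in 1:3) {
    vals <- c()
    # column-major collection so the mean accumulates in storage order
    for (x in (cb[j] + 1):cb[j + 1]) for (y in (rb[i] + 1):rb[i + 1]) {
      if (g[y, x] > 0) vals <- c(vals, g[y, x])
    }
    if (length(vals)) {
      mu <- mean(vals)
      for (x in (cb[j] + 1):cb[j + 1]) for (y in (rb[i] + 1):rb[i + 1]) {
        if (g[y, x] <= mu) g[y, x] <- 0
      }
    }
  }
  spot <- img > spot_threshold
  r <- spot_dilate
  dil <- matrix(FALSE, n, m)
  for (y in 1:n) for (x in 1:m) {
    if (spot[y, x]) {
      for (dy in -r:r) for (dx in -r:r) {
        yy <- y + dy; xx <- x + dx
        if (yy >= 1 && yy <= n && xx >= 1 && xx <= m) dil[yy, xx] <- TRUE
      }
    }
  }
  g[dil] <- 0
  s <- matrix(0, n, m)
  for (y in 1:n) for (x in 1:m) {
    acc <- 0
    for (dy in -1:1) for (dx in -1:1) {
      yy <- y + dy; xx <- x + dx
      if (yy >= 1 && yy <= n && xx >= 1 && xx <= m) acc <- acc + g[yy, xx]
    }
    s[y, x] <- acc
  }
  thr <- threshold_scale * sum(s) / (6 * m * n)
  gg <- (s > thr) * 1L
  for (y in max(1, round(cy - wy)):min(n, round(cy + wy))) {
    for (x in max(1, round(cx - wx)):min(m, round(cx + wx))) gg[y, x] <- 0L
  }
  for (y in 1:ky) for (x in 1:kx) gg[y, x] <- 0L
  for (y in 1:ky) for (x in (m - kx + 1):m) gg[y, x] <- 0L
  for (y in (n - ky + 1):n) for (x in 1:kx) gg[y, x] <- 0L
  for (y in (n - ky + 1):n) for (x in (m - kx + 1):m) gg[y, x] <- 0L
  gg[dil] <- 0L
  gg
}

# textbook two-unknown least-squares solve for nearest points of lines
# p = a1 + t d1, q = a2 + u d2
nearest_points_2x2 <- function(a1, d1, a2, d2) {
  A <- matrix(c(sum(d1 * d1), sum(d1 * d2),
                -sum(d1 * d2), -sum(d2 * d2)), 2, 2)
  b <- c(sum((a2 - a1) * d1), sum((a2 - a1) * d2))
  ts <- solve(A, b)
  list(p1 = a1 + ts[1] * d1, p2 = a2 + ts[2] * d2)
}

# plain normal-equations polynomial fit
normal_eq_fit <- function(X, y) as.numeric(solve(crossprod(X), crossprod(X, y)))

# quaternion construction of the minimal rotation u -> w (directions)
quaternion_min_rotation <- function(u, w) {
  u <- u / sqrt(sum(u^2)); w <- w / sqrt(sum(w^2))
  axis <- c(u[2] * w[3] - u[3] * w[2],
            u[3] * w[1] - u[1] * w[3],
            u[1] * w[2] - u[2] * w[1])
  s <- sqrt(sum(axis^2))
  th <- atan2(s, sum(u * w))
  if (s < 1e-14) return(diag(3))
  axis <- axis / s
  q <- c(cos(th / 2), sin(th / 2) * axis)
  w_ <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w_ * z), 2 * (x * z - w_ * y),
           2 * (x * y - w_ * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w_ * x),
           2 * (x * z + w_ * y), 2 * (y * z - w_ * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# direct nonlinear 3D circle fit (center, axis angles, radius)
circle3d_nls_oracle <- function(P, start) {
  objective <- function(par) {
    ctr <- par[1:3]
    nrm <- c(sin(par[4]) * cos(par[5]), sin(par[4]) * sin(par[5]), cos(par[4]))
    r <- par[6]
    Q <- sweep(P, 2, ctr)
    axial <- Q %*% nrm
    radial <- sqrt(pmax(rowSums(Q^2) - axial^2, 0))
    sum((radial - r)^2 + axial^2)
  }
  fit <- optim(start, objective, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  fit <- optim(fit$par, objective, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-14))
  nrm <- c(sin(fit$par[4]) * cos(fit$par[5]),
           sin(fit$par[4]) * sin(fit$par[5]), cos(fit$par[4]))
  list(center = fit$par[1:3], normal = nrm, radius = fit$par[6])
}

expect_close <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected)), tol)
}
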