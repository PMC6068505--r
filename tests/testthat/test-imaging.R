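# Eye-image analysis: edge map (with literal oracle), ellipse fitting,
# eye-region localization, Harris corner detection.

test_that("the edge map is bit-identical to a literal re-evaluation of its definition", {
  imgs <- list(
    disk_image(64, 64, r = 20),
    disk_image(64, 64, cx = 25.2, cy = 37.8, r = 14, edge = 2),
    matrix(150, 64, 64),
    {
      img <- disk_image(64, 64, r = 18)
      img[10:14, 40:44] <- 255     # saturated specular spot
      img
    },
    {
      set.seed(8)
      img <- disk_image(64, 64, r = 16) + matrix(rnorm(64 * 64, 0, 3), 64)
      pmin(pmax(img, 0), 255)
    })
  for (img in imgs) {
    em <- pupil_edge_map(img)
    expect_identical(em$retained, eq1_oracle(img))
  }
})

test_that("edge-map cases: constant image empty, disk boundary localized, spot masked", {
  em <- pupil_edge_map(matrix(120, 64, 64))
  expect_equal(nrow(em$points), 0L)

  img <- disk_image(128, 128, cx = 63.5, cy = 63.5, r = 40)
  em <- pupil_edge_map(img)
  d <- abs(sqrt((em$points[, 1] - 63.5)^2 + (em$points[, 2] - 63.5)^2) - 40)
  expect_gt(mean(d <= 2), 0.9)

  img <- disk_image(128, 128, cx = 63.5, cy = 63.5, r = 40)
  img[20:24, 90:94] <- 255
  em <- pupil_edge_map(img)
  spot_mask <- gaze3d:::dilate_square(img > 250, 3)
  inside <- spot_mask[cbind(em$points[, 2] + 1, em$points[, 1] + 1)]
  expect_equal(sum(inside), 0L)
})

test_that("ellipse fitting: exact round-trip, noiseless circle, canonical form", {
  # round-trip property over random ellipses
  set.seed(21)
  for (i in 1:40) {
    e0 <- gaze3d:::ellipse2d(runif(1, -5, 5), runif(1, -5, 5),
                             runif(1, 20, 60), runif(1, 5, 19),
                             runif(1, -1.5, 1.5))
    pts <- ellipse_points(e0, seq(0, 2 * pi, length.out = 13)[-13])
    e1 <- gaze3d:::fit_ellipse_lsq(pts[, 1], pts[, 2])
    expect_close(c(e1$x0, e1$y0, e1$a, e1$b) / c(e0$x0, e0$y0, e0$a, e0$b),
                 1, 1e-6)
    expect_lt(abs(e1$alpha - e0$alpha), 1e-6)
  }

  # 60 exact points on a circle of radius 30
  th <- seq(0, 2 * pi, length.out = 61)[-61]
  pts <- cbind(10 + 30 * cos(th), -4 + 30 * sin(th))
  e <- fit_pupil_ellipse(pts, seed = 1)
  expect_close(c(e$x0, e$y0, e$a, e$b), c(10, -4, 30, 30), 1e-6)

  # generator labelled with B > A: output is canonicalized
  e0 <- list(x0 = 0, y0 = 0, a = 10, b = 25, alpha = 0.4)
  ca <- cos(e0$alpha); sa <- sin(e0$alpha)
  u <- e0$a * cos(th); v <- e0$b * sin(th)
  pts <- cbind(ca * u - sa * v, sa * u + ca * v)
  e <- fit_pupil_ellipse(pts, seed = 1)
  expect_gte(e$a, e$b)
  expect_true(e$alpha > -pi / 2 && e$alpha <= pi / 2)
  expect_close(c(e$a, e$b), c(25, 10), 1e-6)

  expect_error(fit_pupil_ellipse(pts[1:4, ], seed = 1), "insufficient")
})

test_that("two-step RANSAC fit resists outliers and degrades monotonically", {
  e0 <- gaze3d:::ellipse2d(100, 80, 40, 25, 0.3)
  set.seed(5)
  th <- runif(100, 0, 2 * pi)
  good <- ellipse_points(e0, th)
  out <- cbind(runif(25, 40, 160), runif(25, 20, 140))
  e <- fit_pupil_ellipse(rbind(good, out), seed = 4)
  expect_close(c(e$x0, e$y0, e$a, e$b), c(100, 80, 40, 25), 0.5)
  expect_lt(abs(e$alpha - 0.3), 0.02)

  # center error non-increasing as the outlier fraction drops 0.3 -> 0
  errs <- sapply(c(0.3, 0.15, 0), function(fr) {
    n_out <- round(100 * fr)
    pts <- rbind(good,
                 if (n_out) cbind(runif(n_out, 40, 160), runif(n_out, 20, 140)))
    e <- fit_pupil_ellipse(pts, seed = 4)
    sqrt((e$x0 - 100)^2 + (e$y0 - 80)^2)
  })
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("point-to-ellipse distance is a true metric orthogonal distance", {
  e <- gaze3d:::ellipse2d(3, -2, 30, 12, 0.7)
  on_e <- ellipse_points(e, seq(0.1, 6, by = 0.35))
  expect_lt(max(point_ellipse_distance(e, on_e[, 1], on_e[, 2])), 1e-8)
  # circle: distance is |r - 30|
  ec <- gaze3d:::ellipse2d(0, 0, 30, 30, 0)
  expect_close(point_ellipse_distance(ec, c(40, 0, 10), c(0, 35, 0)),
               c(10, 5, 20), 1e-8)
})

test_that("projection-based eye localization finds dark structures and rejects flat frames", {
  img <- matrix(230, 200, 240)
  img[81:120, 101:140] <- 60    # dark blob
  box <- locate_eye_region(img)
  expect_true(box$x0 <= 100 && box$x1 >= 139 && box$y0 <= 80 && box$y1 >= 119)
  expect_error(locate_eye_region(matrix(128, 100, 100)), "no eye found")
})

test_that("multi-scale Harris finds junctions and rejects flat regions", {
  img <- matrix(200, 140, 120)
  img[72:140, 62:120] <- 80
  cp <- detect_inner_corner(img)
  # quadratic-refined arg-max carries the known inward Harris bias (< 2.5 px)
  expect_lt(sqrt((cp$x - 60.5)^2 + (cp$y - 70.5)^2), 2.5)
  expect_error(detect_inner_corner(matrix(100, 80, 80)), "no corner")
})

test_that("the rendered canthus wedge is detected near its apex", {
  sc <- rig_scenario()
  fx <- simulate_fixations(sc, distances = 2000, n_per_distance = 1,
                           lateral_sd = 0, seed = 1)
  # steeper (more open) lids localize better; the default acute wedge
  # carries a larger, stable lateral bias
  for (cfg in list(list(sl = c(-0.9, 1.0), tol = 3.5),
                   list(sl = c(-0.4, 0.45), tol = 5.5))) {
    rd <- render_eye_pair(fx$truth[1, ],
                          appearance = render_appearance(lid_slopes = cfg$sl),
                          seed = 3)
    f <- detect_eye_features(rd$frames$L1, side = "left", seed = 2)
    ct <- rd$truth$L1$corner
    expect_lt(sqrt((f$corner$x - ct[1])^2 + (f$corner$y - ct[2])^2), cfg$tol)
  }
})
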