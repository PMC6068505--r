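# Stereo matching, triangulation, and the 3D pupil circle.

left_pair <- function(rig = default_rig()) {
  list(cam1 = rig$cameras$L1, cam2 = rig$cameras$L2)
}

test_that("triangulation inverts projection exactly in the working volume", {
  rig <- default_rig()
  p <- left_pair(rig)
  set.seed(31)
  for (i in 1:100) {
    X <- c(runif(1, 60, 85), runif(1, -12, 12), runif(1, 60, 110))
    u1 <- project_points(X, p$cam1)
    u2 <- project_points(X, p$cam2)
    tri <- match_and_triangulate(u1, u2, p$cam1, p$cam2)
    expect_close(c(tri$x, tri$y, tri$z), X, 1e-9)
    expect_lt(tri$gap, 1e-9)
  }
})

test_that("near-zero disparity is flagged as a point at infinity", {
  rig <- default_rig()
  p <- left_pair(rig)
  expect_warning(
    out <- match_and_triangulate(cbind(300, 290), cbind(300, 290),
                                 p$cam1, p$cam2),
    "infinity")
  expect_equal(nrow(out), 0L)
})

test_that("row-rank matching pairs boundary crossings left-to-right", {
  rig <- default_rig()
  p <- left_pair(rig)
  # two 3D points at the same height project to the same rectified row
  X1 <- c(68, 0, 80); X2 <- c(76, 0, 80)
  u1 <- rbind(project_points(X1, p$cam1), project_points(X2, p$cam1))
  u2 <- rbind(project_points(X2, p$cam2), project_points(X1, p$cam2))  # shuffled
  tri <- match_and_triangulate(u1, u2, p$cam1, p$cam2)
  got <- tri[order(tri$x), ]
  expect_close(c(got$x[1], got$y[1], got$z[1]), X1, 1e-9)
  expect_close(c(got$x[2], got$y[2], got$z[2]), X2, 1e-9)
})

test_that("3D circle fit: exact planar recovery, canonical normal, degeneracies", {
  th <- seq(0, 2 * pi, length.out = 25)[-25]
  pts <- cbind(1 + 3 * cos(th), 2 + 3 * sin(th), 5)
  circ <- fit_circle_3d(pts)
  expect_close(circ$center, c(1, 2, 5), 1e-9)
  expect_equal(circ$radius, 3, tolerance = 1e-9)
  expect_equal(circ$size, 6, tolerance = 1e-9)
  expect_gt(circ$normal[3], 0)       # +Z convention
  expect_close(abs(circ$normal), c(0, 0, 1), 1e-9)

  line <- cbind(1:10, 2 * (1:10), 3 * (1:10))
  expect_error(fit_circle_3d(line), "degenerate")
  expect_error(fit_circle_3d(pts[1:2, ]), ">= 3")
})

test_that("plane-projection circle fit agrees with a direct nonlinear oracle", {
  nrm <- c(0.3, -0.2, 1); nrm <- nrm / sqrt(sum(nrm^2))
  e1 <- c(1, 0, 0) - nrm[1] * nrm; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
          nrm[3] * e1[1] - nrm[1] * e1[3],
          nrm[1] * e1[2] - nrm[2] * e1[1])
  th <- seq(0, 2 * pi, length.out = 41)[-41]
  ctr <- c(70, 1, 85); r <- 1.8
  pts <- matrix(ctr, 40, 3, byrow = TRUE) +
    r * (outer(cos(th), e1) + outer(sin(th), e2))
  start <- c(ctr + 0.1, acos(nrm[3]) + 0.05, atan2(nrm[2], nrm[1]) + 0.05,
             r * 1.05)

  circ <- fit_circle_3d(pts)
  orac <- circle3d_nls_oracle(pts, start)
  expect_close(circ$center, orac$center, 1e-6)
  expect_lt(abs(circ$radius - orac$radius), 1e-6)

  set.seed(13)
  noisy <- pts + matrix(rnorm(120, 0, 0.05), 40, 3)
  circ_n <- fit_circle_3d(noisy)
  orac_n <- circle3d_nls_oracle(noisy, start)
  expect_lt(abs(circ_n$radius - orac_n$radius) / orac_n$radius, 0.02)
  expect_lt(sqrt(sum((circ_n$center - orac_n$center)^2)) / orac_n$radius, 0.02)
})

test_that("assemble_features builds complete records and names missing sides", {
  circle <- list(center = c(70, 0, 85), radius = 1.5, normal = c(0, 0, 1),
                 size = 3)
  eye <- list(circle = circle, corner = c(57, 2, 78))
  rec <- assemble_features(eye, eye, placement = 2L, fixation = 3L)
  expect_equal(rec$s_left, 3)
  expect_equal(rec$placement, 2L)
  expect_error(assemble_features(NULL, eye), "left eye missing")
  expect_error(assemble_features(eye, NULL), "right eye missing")
})

test_that("corner-vector length stability scales with injected pixel noise", {
  rig <- default_rig()
  sc <- rig_scenario()
  sigma_px <- 0.2
  pairs <- list(list(ids = c("L1", "L2"), X = sc$corner_left),
                list(ids = c("R1", "R2"), X = sc$corner_right))
  set.seed(17)
  dists <- replicate(80, {
    xyz <- lapply(pairs, function(p) {
      c1 <- rig$cameras[[p$ids[1]]]; c2 <- rig$cameras[[p$ids[2]]]
      u1 <- project_points(p$X, c1) + rnorm(2, 0, sigma_px)
      u2 <- project_points(p$X, c2) + rnorm(2, 0, sigma_px)
      tri <- triangulate_points(u1, u2, c1, c2)
      c(tri$x, tri$y, tri$z)
    })
    sqrt(sum((xyz[[1]] - xyz[[2]])^2))
  })
  # noise-propagated bound: the corner vector is lateral (along x), so the
  # distance picks up mostly the lateral error Z/f * sigma / sqrt(2) per
  # corner plus second-order depth terms; 3x the first-order propagation
  # is a comfortable bound
  z <- sc$corner_left[3]
  bound <- 3 * sqrt(2) * z / 640 * sigma_px / sqrt(2)
  expect_lt(sd(dists), bound)
  expect_lt(sd(dists), 0.10)   # the stability level reported for real hardware
})

test_that("rendered four-camera frames reconstruct the planted features", {
  sc <- rig_scenario()
  fx <- simulate_fixations(sc, distances = 2000, n_per_distance = 1,
                           lateral_sd = 0, seed = 1)
  tr <- fx$truth[1, ]
  rd <- render_eye_pair(tr, sc$rig, seed = 3)
  feat <- extract_frame_features(rd$frames, sc$rig, seed = 2)
  expect_lt(sqrt((feat$pupil_lx - tr$pupil_lx)^2 +
                   (feat$pupil_ly - tr$pupil_ly)^2 +
                   (feat$pupil_lz - tr$pupil_lz)^2), 0.3)
  expect_lt(abs(feat$s_left - tr$s_left), 0.15)
  expect_lt(abs(feat$s_right - tr$s_right), 0.15)
  # corners carry the stable lateral Harris bias; they stay within 1.5 mm
  expect_lt(sqrt((feat$corner_lx - tr$corner_lx)^2 +
                   (feat$corner_ly - tr$corner_ly)^2 +
                   (feat$corner_lz - tr$corner_lz)^2), 1.5)
})
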