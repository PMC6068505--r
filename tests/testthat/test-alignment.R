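# Eye frame, minimal rotations, and corner-vector transfer of the
# calibrated convergence points.

test_that("the eye frame anchors on the right corner with v = left - right", {
  fr <- build_eye_frame(c(30, 0, 0), c(0, 0, 0))
  expect_equal(fr$origin, c(0, 0, 0))
  expect_equal(fr$v, c(30, 0, 0))
  fr2 <- build_eye_frame(c(35, 1, 7), c(5, 1, 7))
  expect_equal(fr2$v, c(30, 0, 0))      # translation invariance of v
  expect_equal(fr2$origin, c(5, 1, 7))
  expect_error(build_eye_frame(c(1, 1, 1), c(1, 1, 1)), "coincident")

  sc <- rig_scenario()
  s <- simulate_session(sc, seed = 1)
  f <- s$captures[1, ]
  fr3 <- build_eye_frame(c(f$corner_lx, f$corner_ly, f$corner_lz),
                         c(f$corner_rx, f$corner_ry, f$corner_rz))
  expect_equal(sqrt(sum(fr3$v^2)),
               sqrt(sum((sc$corner_left - sc$corner_right)^2)),
               tolerance = 1e-12)
})

test_that("minimal rotation is the geodesic map between directions", {
  expect_equal(minimal_rotation(c(1, 2, 3), c(2, 4, 6)), diag(3))
  R <- minimal_rotation(c(1, 0, 0), c(0, 1, 0))
  expect_close(R %*% c(1, 0, 0), c(0, 1, 0), 1e-12)
  expect_close(R, matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3), 1e-12)

  set.seed(23)
  for (i in 1:300) {
    u <- rnorm(3); w <- rnorm(3)
    R <- minimal_rotation(u, w)
    expect_close(crossprod(R), diag(3), 1e-10)
    expect_gt(det(R), 0.999999)
    expect_close(R %*% (u / sqrt(sum(u^2))), w / sqrt(sum(w^2)), 1e-10)
    expect_close(R, quaternion_min_rotation(u, w), 1e-9)
  }

  # anti-parallel: a deterministic half-turn
  R1 <- minimal_rotation(c(1, 0, 0), c(-1, 0, 0))
  R2 <- minimal_rotation(c(1, 0, 0), c(-2, 0, 0))
  expect_identical(R1, R2)
  expect_close(R1 %*% c(1, 0, 0), c(-1, 0, 0), 1e-12)
  expect_close(crossprod(R1), diag(3), 1e-12)
  expect_error(minimal_rotation(c(0, 0, 0), c(1, 0, 0)), "zero vector")
})

test_that("the reference stores norms and reproduces the calibrated pair", {
  fr <- build_eye_frame(c(30, 0, 0), c(0, 0, 0))
  p_l <- c(25, -3, 14)
  p_r <- c(0, 0, 12)
  ref <- record_reference(fr, p_l, p_r)
  expect_equal(ref$right$norm, 12)
  expect_equal(ref$left$norm, sqrt(sum(p_l^2)))
  # definition round-trip: R_e v0 rescaled to the stored norm hits the point
  for (eye in c("left", "right")) {
    w <- ref[[eye]]$R %*% ref$v0
    p <- fr$origin + w * (ref[[eye]]$norm / sqrt(sum(w^2)))
    expect_close(p, if (eye == "left") p_l else p_r, 1e-9)
  }
  expect_error(record_reference(fr, fr$origin, p_r), "coincides")
})

test_that("transfer is exact under translations and minimal corner-vector rotations", {
  set.seed(29)
  fr0 <- build_eye_frame(c(57, 2, 78), c(27, 2, 78))
  p_l0 <- c(71, -1, 95); p_r0 <- c(13, -1, 94)
  ref <- record_reference(fr0, p_l0, p_r0)

  # identity transfer returns the calibrated pair
  tr0 <- transfer_convergence(ref, fr0)
  expect_close(tr0$p_left, p_l0, 1e-9)
  expect_close(tr0$p_right, p_r0, 1e-9)

  # pure translation
  t_ <- c(3, -4, 10)
  fr_t <- build_eye_frame(c(57, 2, 78) + t_, c(27, 2, 78) + t_)
  tr_t <- transfer_convergence(ref, fr_t)
  expect_close(tr_t$p_left, p_l0 + t_, 1e-9)

  for (i in 1:1000) {
    # random minimal rotation of the corner vector composed with a translation
    w <- rnorm(3)
    Rstar <- minimal_rotation(fr0$v, w)
    t_ <- rnorm(3, sd = 20)
    cl <- as.numeric(Rstar %*% (c(57, 2, 78) - fr0$origin)) + fr0$origin + t_
    cr <- fr0$origin + t_
    fr_i <- build_eye_frame(cl, cr)
    tr_i <- transfer_convergence(ref, fr_i)
    true_l <- as.numeric(Rstar %*% (p_l0 - fr0$origin)) + fr0$origin + t_
    true_r <- as.numeric(Rstar %*% (p_r0 - fr0$origin)) + fr0$origin + t_
    expect_close(tr_i$p_left, true_l, 1e-9)
    expect_close(tr_i$p_right, true_r, 1e-9)
    # norm preservation
    expect_lt(abs(sqrt(sum((tr_i$p_left - cr)^2)) - ref$left$norm), 1e-9)
    expect_lt(abs(sqrt(sum((tr_i$p_right - cr)^2)) - ref$right$norm), 1e-9)
  }
})

test_that("head roll about the corner vector is unobservable (a model property)", {
  fr0 <- build_eye_frame(c(57, 2, 78), c(27, 2, 78))
  p_l0 <- c(71, -1, 95); p_r0 <- c(13, -1, 94)
  ref <- record_reference(fr0, p_l0, p_r0)
  # roll the rig about the corner-vector axis: corners are unchanged
  axis <- fr0$v / sqrt(sum(fr0$v^2))
  th <- 0.2
  K <- matrix(c(0, axis[3], -axis[2], -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  Rroll <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  true_l <- as.numeric(Rroll %*% (p_l0 - fr0$origin)) + fr0$origin
  tr <- transfer_convergence(ref, fr0)   # frame looks identical
  err <- sqrt(sum((tr$p_left - true_l)^2))
  expect_gt(err, 0.5)   # the induced error is real and uncorrected
})

test_that("rotation matrices round-trip through their quaternions", {
  set.seed(37)
  for (i in 1:100) {
    R <- minimal_rotation(rnorm(3), rnorm(3))
    q <- gaze3d:::rotation_to_quaternion(R)
    expect_close(gaze3d:::quaternion_to_rotation(q), R, 1e-10)
  }
})
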