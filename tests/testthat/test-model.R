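# Pupil-size law fitting and 3D Point-of-Regard estimation.

make_samples <- function(gamma, alpha, beta, s, eye = "left", noise = 0) {
  z <- gamma[1] + gamma[2] * s + gamma[3] * s^2 + rnorm(length(s), 0, noise)
  tibble::tibble(eye = eye, placement = seq_along(s), s = s,
                 x = alpha[1] + alpha[2] * z + rnorm(length(s), 0, noise),
                 y = beta[1] + beta[2] * z + rnorm(length(s), 0, noise),
                 z = z)
}

test_that("exact planted polynomial laws are recovered to numerical precision", {
  s <- c(3, 3.4, 3.8, 4.2, 4.6)
  gl <- c(23, -1.8, 0.06); al <- c(44, 0.12); bl <- c(-3.5, 0.09)
  samples <- dplyr::bind_rows(
    make_samples(gl, al, bl, s, "left"),
    make_samples(c(22, -1.7, 0.05), c(-14, -0.12), c(-3.3, 0.08), s, "right"))
  m <- fit_convergence_model(samples)
  expect_close(m$left$gamma, gl, 1e-9)
  expect_close(m$left$alpha, al, 1e-9)
  expect_close(m$left$beta, bl, 1e-9)
  expect_equal(m$left$s_range, c(3, 4.6))
})

test_that("constant-depth samples give a constant depth law", {
  s <- c(3, 3.5, 4, 4.5)
  samples <- dplyr::bind_rows(
    tibble::tibble(eye = "left", placement = 1:4, s = s, x = 1, y = 2, z = 15),
    tibble::tibble(eye = "right", placement = 1:4, s = s, x = 1, y = 2, z = 15))
  m <- fit_convergence_model(samples)
  expect_close(m$left$gamma, c(15, 0, 0), 1e-9)
})

test_that("noisy fits equal the normal-equations solution", {
  set.seed(41)
  s <- seq(3, 4.5, length.out = 8)
  samples <- dplyr::bind_rows(
    make_samples(c(23, -1.8, 0.06), c(44, 0.12), c(-3.5, 0.09), s, "left", 0.2),
    make_samples(c(22, -1.7, 0.05), c(-14, -0.12), c(-3.3, 0.08), s, "right", 0.2))
  m <- fit_convergence_model(samples)
  d <- samples[samples$eye == "left", ]
  expect_close(m$left$gamma, normal_eq_fit(cbind(1, d$s, d$s^2), d$z), 1e-9)
  expect_close(m$left$alpha, normal_eq_fit(cbind(1, d$z), d$x), 1e-9)
  expect_close(m$left$beta, normal_eq_fit(cbind(1, d$z), d$y), 1e-9)
})

test_that("degenerate calibration designs are rejected", {
  s <- c(3, 3.4)
  short <- dplyr::bind_rows(
    make_samples(c(23, -1.8, 0.06), c(44, 0.12), c(-3.5, 0.09), s, "left"),
    make_samples(c(22, -1.7, 0.05), c(-14, -0.12), c(-3.3, 0.08), s, "right"))
  expect_error(fit_convergence_model(short), "insufficient")
  same_s <- dplyr::bind_rows(
    make_samples(c(23, -1.8, 0.06), c(44, 0.12), c(-3.5, 0.09),
                 rep(3.5, 4), "left"),
    make_samples(c(22, -1.7, 0.05), c(-14, -0.12), c(-3.3, 0.08),
                 rep(3.5, 4), "right"))
  expect_error(fit_convergence_model(same_s), "rank-deficient")
})

test_that("prediction evaluates the law, warns outside range, and moves with S", {
  sc <- rig_scenario()
  model <- planted_gaze_model(sc)
  # literal polynomial evaluation at mid-range S
  s_mid <- 3.7
  pred <- predict_convergence(model, s_mid, s_mid)
  z <- sc$gamma_left[1] + sc$gamma_left[2] * s_mid + sc$gamma_left[3] * s_mid^2
  u <- c(sc$alpha_left[1] + sc$alpha_left[2] * z,
         sc$beta_left[1] + sc$beta_left[2] * z, z)
  expect_close(pred$p_left, u + sc$corner_right, 1e-9)
  # larger pupil -> convergence point closer to the pupil (smaller Z)
  zs <- sapply(seq(3, 4.5, by = 0.25), function(s_) {
    predict_convergence(model, s_, s_)$p_left[3]
  })
  expect_true(all(diff(zs) < 0))
  expect_warning(predict_convergence(model, 6.5, 3.7), "extrapolating")
})

test_that("noiseless closed-loop estimation hits the targets exactly", {
  sc <- rig_scenario()
  model <- planted_gaze_model(sc)
  s <- simulate_session(sc, seed = 1)
  est <- estimate_por(s$tests, model)
  err <- sqrt((est$por_x - est$target_x)^2 + (est$por_y - est$target_y)^2 +
                (est$por_z - est$target_z)^2)
  expect_lt(max(err), 1e-6)
  expect_lt(max(est$gap), 1e-6)
})

test_that("bilaterally symmetric geometry gives a PoR on the midline", {
  sc <- rig_scenario(
    corner_left = c(15, 0, 78), corner_right = c(-15, 0, 78),
    eye_left = c(31, 0, 85), eye_right = c(-31, 0, 85),
    gamma_right = c(23, -1.8, 0.06),
    alpha_left = c(30, 0), alpha_right = c(-30, 0),
    beta_left = c(0, 0), beta_right = c(0, 0))
  model <- planted_gaze_model(sc)
  fx <- simulate_fixations(sc, distances = c(700, 900), n_per_distance = 1,
                           lateral_sd = 0, seed = 2)
  est <- estimate_por(fx$features, model)
  expect_close(est$por_x, fx$features$target_x, 1e-6)
})

test_that("isotropic feature noise produces depth-dominated PoR errors", {
  sc <- rig_scenario(noise_feature = 0.05)
  model <- planted_gaze_model(rig_scenario())
  fx <- simulate_fixations(sc, distances = c(800, 1500, 2000),
                           n_per_distance = 20, seed = 19)
  est <- suppressWarnings(estimate_por(fx$features, model))
  est$distance <- fx$features$distance
  agg <- est |>
    dplyr::mutate(ex = abs(por_x - target_x), ey = abs(por_y - target_y),
                  ez = abs(por_z - target_z)) |>
    dplyr::group_by(distance) |>
    dplyr::summarise(ex = mean(ex), ey = mean(ey), ez = mean(ez))
  expect_true(all(agg$ez > agg$ex))
  expect_true(all(agg$ez > agg$ey))
  # depth error grows with distance while lateral errors stay comparable
  expect_gt(agg$ez[3], agg$ez[1])
})

test_that("fixation-window averaging returns a single mean estimate", {
  sc <- rig_scenario(noise_feature = 0.02)
  model <- planted_gaze_model(rig_scenario())
  fx <- simulate_fixations(sc, distances = 800, n_per_distance = 10,
                           lateral_sd = 0, seed = 4)
  est <- estimate_por(fx$features, model)
  avg <- estimate_por(fx$features, model, average = TRUE)
  expect_equal(nrow(avg), 1L)
  expect_equal(avg$por_x, mean(est$por_x))
})

test_that("broom-style and plot methods have the expected shapes", {
  model <- planted_gaze_model(rig_scenario())
  td <- tidy(model)
  expect_equal(nrow(td), 14L)
  expect_setequal(unique(td$eye), c("left", "right"))
  gl <- glance(model)
  expect_equal(nrow(gl), 1L)
  expect_true("n_placements" %in% names(gl))
  p <- autoplot(model)
  expect_s3_class(p, "ggplot")
  fx <- simulate_fixations(rig_scenario(noise_feature = 0.05),
                           distances = c(800, 1500), n_per_distance = 5,
                           seed = 6)
  est <- suppressWarnings(estimate_por(fx$features, model))
  est$distance <- fx$features$distance
  expect_s3_class(plot_por_errors(est), "ggplot")
})
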