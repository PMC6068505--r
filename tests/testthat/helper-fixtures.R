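# Shared fixtures built in code.

# Gaze model assembled directly from a scenario's planted laws (no
# calibration search); the exact model for closed-loop estimation tests.
planted_gaze_model <- function(sc, s_range = c(3, 4.5)) {
  frame <- build_eye_frame(sc$corner_left, sc$corner_right)
  s_mid <- mean(s_range)
  ref <- record_reference(
    frame,
    gaze3d:::planted_convergence_ref(sc, "left", s_mid) + sc$corner_right,
    gaze3d:::planted_convergence_ref(sc, "right", s_mid) + sc$corner_right)
  eye_fit <- function(eye) {
    list(gamma = sc[[paste0("gamma_", eye)]],
         alpha = sc[[paste0("alpha_", eye)]],
         beta = sc[[paste0("beta_", eye)]],
         s_range = s_range, n = 5L, sigma_z = 0)
  }
  ss <- seq(s_range[1], s_range[2], length.out = 5)
  samples <- dplyr::bind_rows(lapply(c("left", "right"), function(eye) {
    u <- t(vapply(ss, function(s) gaze3d:::planted_convergence_ref(sc, eye, s),
                  numeric(3)))
    tibble::tibble(eye = eye, placement = 1:5, s = ss,
                   x = u[, 1], y = u[, 2], z = u[, 3])
  }))
  cm <- structure(list(left = eye_fit("left"), right = eye_fit("right"),
                       samples = samples),
                  class = "convergence_model")
  structure(list(model = cm, reference = ref,
                 calibration = tibble::tibble(placement = 1:5,
                                              score = rep(1, 5)),
                 cfg = objective_config()),
            class = "gaze_model")
}

# simple dark-disk-on-bright-field image (0-based center coordinates)
disk_image <- function(n = 64, m = 64, cx = 31.5, cy = 31.5, r = 20,
                       bg = 220, fg = 40, edge = 1) {
  xs <- matrix(0:(m - 1), n, m, byrow = TRUE)
  ys <- matrix(0:(n - 1), n, m)
  d <- sqrt((xs - cx)^2 + (ys - cy)^2)
  t <- pmin(pmax((d - r) / (2 * edge) + 0.5, 0), 1)
  w <- t * t * (3 - 2 * t)
  fg * (1 - w) + bg * w
}
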