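# Pupil-size -> convergence-point model and 3D Point-of-Regard estimation.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Fit the pupil-size to convergence-point law
#'
#' Per eye, ordinary least squares in the initial corner-vector reference
#' frame: depth first (`Z = g0 + g1 S + g2 S^2`, the depth coordinate is
#' the one sensitive to pupil size), then the spatial line through the
#' convergence points (`X = a0 + a1 Z`, `Y = b0 + b1 Z`). Any
#' direction-vector parameterization of that line reduces to the same two
#' linear equations.
#'
#' @param samples tibble of calibration samples with columns `eye`
#'   (`"left"`/`"right"`), `s` (pupil size, mm), `x`, `y`, `z`
#'   (convergence point, mm, reference frame).
#' @return list of class `convergence_model`: per eye `gamma` (3),
#'   `alpha` (2), `beta` (2), `s_range`, `n`.
#' @export
fit_convergence_model <- function(samples) {
  stopifnot(all(c("eye", "s", "x", "y", "z") %in% names(samples)))
  fit_eye <- function(d) {
    if (nrow(d) < 3L) {
      stop("fit_convergence_model(): insufficient calibration (< 3 samples per eye)")
    }
    if (sd(d$s) < 1e-12) {
      stop("fit_convergence_model(): rank-deficient design (all pupil sizes equal)")
    }
    fz <- lm(z ~ s + I(s^2), data = d)
    fx <- lm(x ~ z, data = d)
    fy <- lm(y ~ z, data = d)
    list(gamma = unname(coef(fz)), alpha = unname(coef(fx)),
         beta = unname(coef(fy)), s_range = range(d$s), n = nrow(d),
         sigma_z = suppressWarnings(summary(fz)$sigma))
  }
  eyes <- split(samples, samples$eye)
  stopifnot(all(c("left", "right") %in% names(eyes)))
  structure(list(left = fit_eye(eyes$left), right = fit_eye(eyes$right),
                 samples = tibble::as_tibble(samples)),
            class = "convergence_model")
}

eval_convergence_law <- function(eye_fit, s) {
  z <- eye_fit$gamma[1] + eye_fit$gamma[2] * s + eye_fit$gamma[3] * s^2
  c(eye_fit$alpha[1] + eye_fit$alpha[2] * z,
    eye_fit$beta[1] + eye_fit$beta[2] * z,
    z)
}

#' Calibrate the full gaze model from a session
#'
#' End-to-end calibration: searches the convergence pair of every board
#' placement ([calibrate_session()]), anchors the reference eye frame on
#' the first placement's inner corners, aligns all placements'
#' convergence points into that reference via the corner-vector minimal
#' rotation, and fits the pupil-size law ([fit_convergence_model()]).
#' One calibration sample per placement and eye is used (the four crosses
#' of a placement share a distance; their pupil sizes are averaged).
#'
#' @param session a `gaze_session` (or a calibration feature tibble with
#'   `placement`, `fixation`, pupil, corner and pupil-size columns).
#' @param cfg an [objective_config()].
#' @return object of class `gaze_model`: `model` (the fitted
#'   `convergence_model`), `reference` (the `convergence_reference`),
#'   `calibration` (per-placement search results tibble), `cfg`.
#' @export
calibrate_gaze <- function(session, cfg = objective_config()) {
  features <- if (inherits(session, "gaze_session")) session$captures else session
  calib <- calibrate_session(features, cfg)
  frames <- purrr::map(seq_len(nrow(calib)), function(j) {
    build_eye_frame(c(calib$corner_lx[j], calib$corner_ly[j], calib$corner_lz[j]),
                    c(calib$corner_rx[j], calib$corner_ry[j], calib$corner_rz[j]))
  })
  reference <- record_reference(frames[[1]],
                                c(calib$p_left_x[1], calib$p_left_y[1], calib$p_left_z[1]),
                                c(calib$p_right_x[1], calib$p_right_y[1], calib$p_right_z[1]))
  samples <- purrr::map_dfr(seq_len(nrow(calib)), function(j) {
    ul <- align_to_reference(reference, frames[[j]],
                             c(calib$p_left_x[j], calib$p_left_y[j], calib$p_left_z[j]))
    ur <- align_to_reference(reference, frames[[j]],
                             c(calib$p_right_x[j], calib$p_right_y[j], calib$p_right_z[j]))
    tibble::tibble(eye = c("left", "right"),
                   placement = calib$placement[j],
                   s = c(calib$s_left[j], calib$s_right[j]),
                   x = c(ul[1], ur[1]), y = c(ul[2], ur[2]),
                   z = c(ul[3], ur[3]))
  })
  structure(list(model = fit_convergence_model(samples),
                 reference = reference, calibration = calib, cfg = cfg),
            class = "gaze_model")
}

#' Predict the convergence pair from pupil sizes
#'
#' Evaluates the fitted per-eye polynomial law at the given pupil sizes
#' (reference frame) and carries the points into the current eye frame by
#' the corner-vector minimal rotation. Pupil sizes outside the calibrated
#' range (plus `margin`) trigger a warning but are still evaluated.
#'
#' @param model a `gaze_model` from [calibrate_gaze()].
#' @param s_left,s_right pupil sizes (mm).
#' @param frame current `eye_frame` (default: the calibration reference
#'   frame itself).
#' @param margin relative extrapolation margin on the calibrated range.
#' @return list with `p_left`, `p_right` (mm, rig frame).
#' @export
predict_convergence <- function(model, s_left, s_right, frame = NULL,
                                margin = 0.1) {
  stopifnot(inherits(model, "gaze_model"))
  if (is.null(frame)) {
    frame <- build_eye_frame(model$reference$origin + model$reference$v0,
                             model$reference$origin)
  }
  check_range <- function(s, eye) {
    rg <- model$model[[eye]]$s_range
    w <- diff(rg) * margin
    if (s < rg[1] - w || s > rg[2] + w) {
      warning(sprintf("pupil size %.3f mm outside calibrated range [%.3f, %.3f] for %s eye; extrapolating",
                      s, rg[1], rg[2], eye))
    }
  }
  check_range(s_left, "left"); check_range(s_right, "right")
  ul <- eval_convergence_law(model$model$left, s_left)
  ur <- eval_convergence_law(model$model$right, s_right)
  list(p_left = reference_to_rig(model$reference, frame, ul),
       p_right = reference_to_rig(model$reference, frame, ur))
}

#' Estimate 3D Points-of-Regard from feature records
#'
#' For each feature row: predict the per-eye convergence points from the
#' pupil sizes, form the two sightlines (pupil center through convergence
#' point), and return the midpoint of their nearest points together with
#' the nearest-point gap (a per-frame quality indicator). Optionally
#' averages the PoR over all rows (the fixation-window average).
#'
#' @param features tibble with pupil (`pupil_lx`..`pupil_rz`), corner
#'   (`corner_lx`..`corner_rz`) and pupil-size (`s_left`, `s_right`)
#'   columns; extra columns are carried through.
#' @param model a `gaze_model`.
#' @param average if `TRUE`, additionally collapse the estimates to their
#'   coordinate-wise mean (one row).
#' @param margin extrapolation margin passed to [predict_convergence()].
#' @return tibble with `por_x`, `por_y`, `por_z`, `gap` (mm) plus the
#'   input's identifying columns; parallel sightlines yield an error.
#' @export
estimate_por <- function(features, model, average = FALSE, margin = 0.1) {
  stopifnot(inherits(model, "gaze_model"))
  est <- purrr::map_dfr(seq_len(nrow(features)), function(i) {
    f <- features[i, ]
    frame <- build_eye_frame(c(f$corner_lx, f$corner_ly, f$corner_lz),
                             c(f$corner_rx, f$corner_ry, f$corner_rz))
    conv <- predict_convergence(model, f$s_left, f$s_right, frame, margin)
    pair <- nearest_points(
      sight_line(c(f$pupil_lx, f$pupil_ly, f$pupil_lz), conv$p_left),
      sight_line(c(f$pupil_rx, f$pupil_ry, f$pupil_rz), conv$p_right))
    por <- midpoint_por(pair)
    tibble::tibble(por_x = por$point[1], por_y = por$point[2],
                   por_z = por$point[3], gap = por$gap)
  })
  keep <- intersect(c("placement", "fixation", "distance",
                      "target_x", "target_y", "target_z"), names(features))
  out <- dplyr::bind_cols(features[, keep, drop = FALSE], est)
  if (average) {
    out <- out |>
      dplyr::summarise(dplyr::across(dplyr::any_of(
        c("por_x", "por_y", "por_z", "gap",
          "target_x", "target_y", "target_z")), mean))
  }
  out
}

# ---- broom-style and plotting methods -------------------------------------

#' @export
print.gaze_model <- function(x, ...) {
  cat("Gaze model: pupil-size -> line-of-sight convergence law\n")
  for (eye in c("left", "right")) {
    m <- x$model[[eye]]
    cat(sprintf("  %s eye:  Z = %.4f %+.4f S %+.4f S^2   (S in [%.2f, %.2f] mm)\n",
                eye, m$gamma[1], m$gamma[2], m$gamma[3],
                m$s_range[1], m$s_range[2]))
    cat(sprintf("            X = %.4f %+.4f Z,  Y = %.4f %+.4f Z\n",
                m$alpha[1], m$alpha[2], m$beta[1], m$beta[2]))
  }
  invisible(x)
}

#' Tidy a fitted gaze model
#'
#' @param x a `gaze_model`.
#' @param ... unused.
#' @return tibble with one row per coefficient: `eye`, `term`, `estimate`.
#' @export
tidy.gaze_model <- function(x, ...) {
  purrr::map_dfr(c("left", "right"), function(eye) {
    m <- x$model[[eye]]
    tibble::tibble(
      eye = eye,
      term = c("gamma0", "gamma1", "gamma2", "alpha0", "alpha1",
               "beta0", "beta1"),
      estimate = c(m$gamma, m$alpha, m$beta))
  })
}

#' Model-level summary of a fitted gaze model
#'
#' @param x a `gaze_model`.
#' @param ... unused.
#' @return one-row tibble: placements used, pupil-size ranges, residual
#'   depth sigma per eye, mean merged search score.
#' @export
glance.gaze_model <- function(x, ...) {
  tibble::tibble(
    n_placements = nrow(x$calibration),
    s_min_left = x$model$left$s_range[1], s_max_left = x$model$left$s_range[2],
    s_min_right = x$model$right$s_range[1], s_max_right = x$model$right$s_range[2],
    sigma_z_left = x$model$left$sigma_z, sigma_z_right = x$model$right$sigma_z,
    mean_search_score = mean(x$calibration$score))
}

#' Plot the fitted pupil-size law against the calibration samples
#'
#' @param object a `gaze_model`.
#' @param ... unused.
#' @return a ggplot: per-eye calibrated convergence coordinates against
#'   pupil size with the fitted law overlaid.
#' @export
autoplot.gaze_model <- function(object, ...) {
  samples <- object$model$samples |>
    tidyr::pivot_longer(c("x", "y", "z"), names_to = "coordinate",
                        values_to = "value")
  grid <- purrr::map_dfr(c("left", "right"), function(eye) {
    rg <- object$model[[eye]]$s_range
    s <- seq(rg[1], rg[2], length.out = 80)
    u <- t(vapply(s, function(si) eval_convergence_law(object$model[[eye]], si),
                  numeric(3)))
    tibble::tibble(eye = eye, s = s, x = u[, 1], y = u[, 2], z = u[, 3]) |>
      tidyr::pivot_longer(c("x", "y", "z"), names_to = "coordinate",
                          values_to = "value")
  })
  ggplot2::ggplot(samples, ggplot2::aes(x = .data$s, y = .data$value)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::facet_grid(coordinate ~ eye, scales = "free_y") +
    ggplot2::labs(x = "pupil size S (mm)",
                  y = "convergence-point coordinate (mm, reference frame)",
                  title = "Calibrated line-of-sight convergence law")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot Point-of-Regard error components by distance
#'
#' @param estimates output of [estimate_por()] containing `target_*`
#'   columns and (optionally) `distance`.
#' @return a ggplot of absolute X/Y/Z errors.
#' @export
plot_por_errors <- function(estimates) {
  stopifnot(all(c("target_x", "target_y", "target_z") %in% names(estimates)))
  d <- estimates |>
    dplyr::mutate(
      x = abs(.data$por_x - .data$target_x),
      y = abs(.data$por_y - .data$target_y),
      z = abs(.data$por_z - .data$target_z),
      distance = if ("distance" %in% names(estimates)) {
        factor(.data$distance)
      } else {
        factor("all")
      }) |>
    tidyr::pivot_longer(c("x", "y", "z"), names_to = "axis",
                        values_to = "abs_error")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$distance, y = .data$abs_error,
                                  fill = .data$axis)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(x = "target distance (mm)", y = "absolute error (mm)",
                  title = "PoR error components (depth dominates with distance)")
}
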