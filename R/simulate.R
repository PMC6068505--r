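# Synthetic binocular rig: ground-truthed calibration sessions and test
# fixations with planted convergence geometry.

# run expr with a temporary RNG state seeded by `seed` (NULL = leave RNG alone)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

#' Default stereo rig mirroring the four-camera gaze tracker
#'
#' Two rectified vertical-geometry camera pairs (one per eye), 22 mm
#' baseline, 640 x 580 px, expressed after rectification with the baseline
#' along the camera x-axis. The rig frame is the leftmost virtual camera
#' frame, +Z pointing from the cameras toward the eyes.
#'
#' @param baseline stereo baseline within a pair (mm).
#' @param fx,fy focal length in pixels.
#' @param cx,cy principal point (0-based px).
#' @param width,height image size (px).
#' @return list of class `stereo_rig` with one entry per camera
#'   (`R1`, `R2`, `L1`, `L2`): intrinsics `K`, distortion `dist` (zeros:
#'   rectified), rotation `R` (rig -> camera) and camera center `C` (mm,
#'   rig frame), plus `baseline`, `width`, `height`.
#' @export
default_rig <- function(baseline = 22, fx = 640, fy = 640,
                        cx = 320, cy = 290, width = 640, height = 580) {
  K <- matrix(c(fx, 0, 0, 0, fy, 0, cx, cy, 1), 3, 3)
  cam <- function(C) list(K = K, dist = numeric(5), R = diag(3), C = C)
  structure(list(
    cameras = list(
      R1 = cam(c(0, 0, 0)), R2 = cam(c(baseline, 0, 0)),
      L1 = cam(c(56, 0, 0)), L2 = cam(c(56 + baseline, 0, 0))),
    baseline = baseline, width = width, height = height),
    class = "stereo_rig")
}

#' Synthetic rig scenario: planted laws and study-protocol constants
#'
#' Defines the ground truth for a simulated calibration session: the inner
#' eye corner geometry, the planted per-eye quadratic/linear convergence
#' laws (in the initial corner-vector reference frame, origin at the right
#' inner corner), the pupil-size law `S(d)` (mm, strictly increasing with
#' target distance — the pupil contracts for near targets under fixed
#' illumination), the board placement distances of the calibration
#' protocol, and the feature/pixel noise levels.
#'
#' @param corner_left,corner_right inner eye corner positions (mm, rig
#'   frame).
#' @param eye_left,eye_right nominal eye positions (mm) used to evaluate
#'   the pupil-size law.
#' @param gamma_left,gamma_right length-3: planted `Z = g0 + g1 S + g2 S^2`
#'   (reference frame, mm).
#' @param alpha_left,alpha_right length-2: planted `X = a0 + a1 Z`.
#' @param beta_left,beta_right length-2: planted `Y = b0 + b1 Z`.
#' @param pupil_size_law function of distance (mm) returning pupil size
#'   `S` (mm); must be strictly increasing on the working range.
#' @param placement_distances board distances of the 5 calibration
#'   placements (mm from the eye midline).
#' @param board_spacing cross spacing of the board (mm).
#' @param anatomical_offset pupil-center-to-convergence-point distance
#'   (mm) along the sightline.
#' @param noise_feature Gaussian sigma (mm) added to 3D features and
#'   pupil sizes.
#' @param noise_px Gaussian sigma (px) for rendered images.
#' @param rig a [default_rig()].
#' @return list of class `rig_scenario`.
#' @export
rig_scenario <- function(corner_left = c(57, 2, 78),
                         corner_right = c(27, 2, 78),
                         eye_left = c(73, 0, 85),
                         eye_right = c(11, 0, 85),
                         gamma_left = c(23, -1.8, 0.06),
                         gamma_right = c(22.5, -1.7, 0.05),
                         alpha_left = c(44, 0.12),
                         alpha_right = c(-14, -0.12),
                         beta_left = c(-3.5, 0.09),
                         beta_right = c(-3.3, 0.08),
                         pupil_size_law = function(d) 3 + 1.5 * (d - 400) / 800,
                         placement_distances = c(400, 600, 800, 1000, 1200),
                         board_spacing = 150,
                         anatomical_offset = 10,
                         noise_feature = 0,
                         noise_px = 0,
                         rig = default_rig()) {
  stopifnot(noise_feature >= 0, noise_px >= 0, anatomical_offset > 0,
            board_spacing > 0, all(placement_distances > 0))
  dd <- seq(400, 1200, by = 50)
  s_check <- vapply(dd, pupil_size_law, numeric(1))
  if (any(diff(s_check) <= 0) || any(s_check <= 0)) {
    stop(paste("rig_scenario(): pupil_size_law must be positive and strictly",
               "increasing with distance on [400, 1200] mm (the pupil",
               "contracts for near targets)"))
  }
  structure(list(
    corner_left = corner_left, corner_right = corner_right,
    eye_left = eye_left, eye_right = eye_right,
    gamma_left = gamma_left, gamma_right = gamma_right,
    alpha_left = alpha_left, alpha_right = alpha_right,
    beta_left = beta_left, beta_right = beta_right,
    pupil_size_law = pupil_size_law,
    placement_distances = placement_distances,
    board_spacing = board_spacing,
    anatomical_offset = anatomical_offset,
    noise_feature = noise_feature, noise_px = noise_px,
    rig = rig), class = "rig_scenario")
}

# planted convergence point (reference frame) for pupil size s
planted_convergence_ref <- function(scenario, eye, s) {
  g <- scenario[[paste0("gamma_", eye)]]
  a <- scenario[[paste0("alpha_", eye)]]
  b <- scenario[[paste0("beta_", eye)]]
  z <- g[1] + g[2] * s + g[3] * s^2
  c(a[1] + a[2] * z, b[1] + b[2] * z, z)
}

# Exact features for one fixation target; returns a one-row tibble.
# `s_at` is the point whose distance drives the pupil size: the board
# center for calibration placements (one accommodation state, hence one
# convergence pair, per placement) or the target itself for free
# fixations.
simulate_fixation_exact <- function(scenario, target, s_at = target) {
  target <- as.numeric(target)
  rows <- lapply(c("left", "right"), function(eye) {
    eye_pos <- scenario[[paste0("eye_", eye)]]
    if (target[3] >= eye_pos[3]) {
      stop("simulate_fixation(): target behind the eyes")
    }
    s <- scenario$pupil_size_law(norm3(as.numeric(s_at) - eye_pos))
    conv <- planted_convergence_ref(scenario, eye, s) + scenario$corner_right
    dir <- target - conv
    pupil <- conv + scenario$anatomical_offset * dir / norm3(dir)
    list(s = s, conv = conv, pupil = pupil)
  })
  l <- rows[[1]]; r <- rows[[2]]
  tibble::tibble(
    pupil_lx = l$pupil[1], pupil_ly = l$pupil[2], pupil_lz = l$pupil[3],
    pupil_rx = r$pupil[1], pupil_ry = r$pupil[2], pupil_rz = r$pupil[3],
    s_left = l$s, s_right = r$s,
    corner_lx = scenario$corner_left[1], corner_ly = scenario$corner_left[2],
    corner_lz = scenario$corner_left[3],
    corner_rx = scenario$corner_right[1], corner_ry = scenario$corner_right[2],
    corner_rz = scenario$corner_right[3],
    conv_lx = l$conv[1], conv_ly = l$conv[2], conv_lz = l$conv[3],
    conv_rx = r$conv[1], conv_ry = r$conv[2], conv_rz = r$conv[3],
    target_x = target[1], target_y = target[2], target_z = target[3])
}

feature_noise_cols <- c(
  "pupil_lx", "pupil_ly", "pupil_lz", "pupil_rx", "pupil_ry", "pupil_rz",
  "s_left", "s_right",
  "corner_lx", "corner_ly", "corner_lz", "corner_rx", "corner_ry", "corner_rz")

add_feature_noise <- function(exact, sigma) {
  noisy <- exact
  if (sigma > 0) {
    for (cl in feature_noise_cols) {
      noisy[[cl]] <- noisy[[cl]] + rnorm(nrow(noisy), 0, sigma)
    }
  }
  noisy[, setdiff(names(noisy), c("conv_lx", "conv_ly", "conv_lz",
                                  "conv_rx", "conv_ry", "conv_rz",
                                  "target_x", "target_y", "target_z"))]
}

# board cross targets for one placement (cyclic corner order 1..4)
board_targets <- function(scenario, distance) {
  mid <- (scenario$eye_left + scenario$eye_right) / 2
  center <- c(mid[1], mid[2], mid[3] - distance)
  h <- scenario$board_spacing / 2
  off <- rbind(c(-h, h, 0), c(h, h, 0), c(h, -h, 0), c(-h, -h, 0))
  sweep(off, 2L, center, "+")
}

#' Simulate a full calibration session
#'
#' Reproduces the calibration protocol: the four-cross board (150 mm
#' spacing) is placed at each of the five configured distances and the
#' subject fixates every cross, giving 20 capture records. For each
#' fixation the planted laws yield the true convergence points, the pupil
#' centers are placed on the convergence-to-target segment at the
#' anatomical offset, and the pupil size follows the pupil-size law;
#' Gaussian feature noise is then added. Held-out test fixations (board
#' centers at `test_distances`) are generated the same way.
#'
#' @param scenario a [rig_scenario()].
#' @param seed integer seed driving all randomness (determinism: same
#'   seed, same session).
#' @param test_distances distances (mm) of held-out test fixations.
#' @return list of class `gaze_session`: `captures` (noisy calibration
#'   features, columns `placement`, `fixation`, pupil/corner/pupil-size),
#'   `tests` (noisy test features + `target_*`), `truth` (exact features,
#'   targets and planted convergence points for both sets), `scenario`,
#'   `seed`, `schema_version`.
#' @export
simulate_session <- function(scenario = rig_scenario(), seed = 1,
                             test_distances = c(450, 575, 700, 850, 1000, 1150)) {
  stopifnot(inherits(scenario, "rig_scenario"))
  with_seed(seed, {
    cap_exact <- purrr::map_dfr(seq_along(scenario$placement_distances), function(j) {
      d_j <- scenario$placement_distances[j]
      tg <- board_targets(scenario, d_j)
      mid <- (scenario$eye_left + scenario$eye_right) / 2
      board_center <- c(mid[1], mid[2], mid[3] - d_j)
      purrr::map_dfr(1:4, function(i) {
        dplyr::bind_cols(tibble::tibble(placement = j, fixation = i),
                         simulate_fixation_exact(scenario, tg[i, ],
                                                 s_at = board_center))
      })
    })
    test_exact <- purrr::map_dfr(seq_along(test_distances), function(j) {
      mid <- (scenario$eye_left + scenario$eye_right) / 2
      target <- c(mid[1], mid[2], mid[3] - test_distances[j])
      dplyr::bind_cols(tibble::tibble(placement = NA_integer_, fixation = j),
                       simulate_fixation_exact(scenario, target))
    })
    captures <- add_feature_noise(cap_exact, scenario$noise_feature)
    tests_noisy <- add_feature_noise(test_exact, scenario$noise_feature)
    tests <- dplyr::bind_cols(
      tests_noisy, test_exact[, c("target_x", "target_y", "target_z")])
    structure(list(captures = captures, tests = tests,
                   truth = list(captures = cap_exact, tests = test_exact),
                   scenario = scenario, seed = seed, schema_version = "1.0"),
              class = "gaze_session")
  })
}

#' Simulate standalone test fixations
#'
#' Generates `n_per_distance` fixations at each requested distance with
#' optional lateral jitter of the target on the frontal plane, using the
#' same planted laws as [simulate_session()].
#'
#' @param scenario a [rig_scenario()].
#' @param distances target distances (mm).
#' @param n_per_distance fixations per distance.
#' @param lateral_sd Gaussian sigma (mm) of target jitter in X and Y.
#' @param seed integer seed.
#' @return list with `features` (noisy tibble incl. `target_*`, `distance`)
#'   and `truth` (exact tibble).
#' @export
simulate_fixations <- function(scenario = rig_scenario(),
                               distances = c(800, 1500, 2000),
                               n_per_distance = 20, lateral_sd = 40,
                               seed = 1) {
  with_seed(seed, {
    mid <- (scenario$eye_left + scenario$eye_right) / 2
    exact <- purrr::map_dfr(seq_along(distances), function(j) {
      purrr::map_dfr(seq_len(n_per_distance), function(i) {
        target <- c(mid[1] + rnorm(1, 0, lateral_sd),
                    mid[2] + rnorm(1, 0, lateral_sd),
                    mid[3] - distances[j])
        dplyr::bind_cols(tibble::tibble(distance = distances[j], fixation = i),
                         simulate_fixation_exact(scenario, target))
      })
    })
    noisy <- add_feature_noise(exact, scenario$noise_feature)
    noisy <- dplyr::bind_cols(noisy,
                              exact[, c("target_x", "target_y", "target_z")])
    list(features = noisy, truth = exact)
  })
}

#' @export
print.gaze_session <- function(x, ...) {
  cat("Simulated gaze calibration session\n")
  cat(sprintf("  %d captures (%d placements x 4 crosses), %d test fixations\n",
              nrow(x$captures), length(unique(x$captures$placement)),
              nrow(x$tests)))
  cat(sprintf("  feature noise sigma = %g mm, seed = %s\n",
              x$scenario$noise_feature, format(x$seed)))
  invisible(x)
}
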