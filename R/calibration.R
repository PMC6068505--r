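# Calibration of the per-eye line-of-sight convergence points by a
# shrinking search against the four-cross calibration board.

#' Objective / search configuration for convergence-point calibration
#'
#' @param board_spacing cross-to-cross spacing of the calibration board
#'   (mm); the board carries four crosses at the corners of a square of
#'   this side.
#' @param epsilon sensitivity coefficient down-weighting the shape-error
#'   basis in the merged objective (dimensionless).
#' @param depth_offset initial-guess offset (mm): the search starts at the
#'   mean of the four pupil centers pushed `depth_offset` mm along +Z,
#'   into the eyeball.
#' @param half_width half-width (mm) of the initial cubic search region
#'   (a 4 mm cube by default).
#' @param step initial lattice step (mm) of the halving schedule.
#' @param step_min termination threshold (mm): scales are halved until the
#'   scan step falls below it.
#' @param pairing `"sections"` (default) refines seeds by shrinking scans
#'   of structured 1D sections (shared/differential direction fans plus
#'   pattern moves) of the joint region — the tractable realization of
#'   the joint search; `"product"` scores the full Cartesian product of
#'   the two cube lattices each round (only tractable for coarse
#'   lattices, e.g. the printed 125-point example).
#' @param max_passes cap on direction sweeps per scale.
#' @param seed_step lattice step (mm) of the coarse full-product seeding
#'   pass over the initial cubes.
#' @param n_seeds number of diverse seeds refined (the initial guess is
#'   always one of them).
#' @param seed_separation minimal joint distance (mm) between seeds.
#' @param fan_step angular spacing (degrees) of the section-direction
#'   fans.
#' @param product_max guard on the number of product-lattice pairs.
#' @return list of class `objective_config`.
#' @export
objective_config <- function(board_spacing = 150, epsilon = 10,
                             depth_offset = 10, half_width = 2,
                             step = 0.2, step_min = 0.0005,
                             pairing = c("sections", "product"),
                             max_passes = 50, seed_step = 1,
                             n_seeds = 4, seed_separation = 0.8,
                             fan_step = 15, product_max = 4e6) {
  pairing <- match.arg(pairing)
  stopifnot(board_spacing > 0, epsilon > 0, depth_offset > 0,
            half_width > 0, step > 0, step <= 2 * half_width, step_min > 0,
            max_passes >= 1, n_seeds >= 1, seed_step > 0)
  structure(list(board_spacing = board_spacing, epsilon = epsilon,
                 depth_offset = depth_offset, half_width = half_width,
                 step = step, step_min = step_min, pairing = pairing,
                 max_passes = max_passes, seed_step = seed_step,
                 n_seeds = n_seeds, seed_separation = seed_separation,
                 fan_step = fan_step, product_max = product_max),
            class = "objective_config")
}

#' Cubic search region lattice
#'
#' Inclusive lattice over a cube: `floor(side / step) + 1` points per axis,
#' boundaries included (`side = 2 * half_width`). A 4 mm cube at a 1 mm
#' step therefore enumerates `5^3 = 125` candidates.
#'
#' @param center numeric length-3 cube center (mm).
#' @param half_width cube half-width (mm).
#' @param step lattice step (mm); must not exceed the side.
#' @return `n x 3` matrix of candidate points, x-axis index fastest.
#' @export
grid_candidates <- function(center, half_width, step) {
  stopifnot(half_width > 0, step > 0, step <= 2 * half_width)
  g <- lattice_offsets(half_width, step)
  sweep(g, 2L, as.numeric(center), "+")
}

# cubic lattice offsets, boundaries included
lattice_offsets <- function(hw, st) {
  k <- floor(2 * hw / st) + 1L
  if (k == 1L) return(matrix(0, 1, 3))
  o <- seq(-hw, hw, length.out = k)
  g <- as.matrix(expand.grid(o, o, o, KEEP.OUT.ATTRS = FALSE))
  dimnames(g) <- NULL
  g
}

#' Shape error of four Point-of-Regard estimates against the board
#'
#' The four crosses of the calibration board form a square of side `L`;
#' the shape error sums the absolute deviations of the four adjacent
#' estimated cross-to-cross distances from `L` (the diagonal is not
#' used): `sum_{i=1..3} | ||Pe_i - Pe_{i+1}|| - L | + | ||Pe_1 - Pe_4|| - L |`.
#'
#' @param por_points `4 x 3` matrix of PoR estimates, rows in cross order
#'   1..4 around the square.
#' @param board_spacing the known spacing `L` (mm).
#' @return shape error (mm).
#' @export
shape_error <- function(por_points, board_spacing = 150) {
  por_points <- as.matrix(por_points)
  stopifnot(nrow(por_points) == 4L, ncol(por_points) == 3L)
  d <- function(i, j) norm3(por_points[i, ] - por_points[j, ])
  abs(d(1, 2) - board_spacing) + abs(d(2, 3) - board_spacing) +
    abs(d(3, 4) - board_spacing) + abs(d(1, 4) - board_spacing)
}

# ---- vectorized candidate evaluation --------------------------------------

# Pupil-center matrices (4 x 3) per eye from a 4-row placement tibble.
placement_pupils <- function(features) {
  features <- features[order(features$fixation), , drop = FALSE]
  stopifnot(nrow(features) == 4L)
  list(
    left = cbind(features$pupil_lx, features$pupil_ly, features$pupil_lz),
    right = cbind(features$pupil_rx, features$pupil_ry, features$pupil_rz)
  )
}

# For rowwise-paired candidate matrices CL, CR (n x 3) return total gap and
# shape error per candidate pair, given 4 x 3 pupil-center matrices.
eval_candidate_pairs <- function(CL, CR, pup_left, pup_right, board_spacing) {
  n <- nrow(CL)
  total_gap <- numeric(n)
  pe <- vector("list", 4L)
  for (i in 1:4) {
    res <- nearest_points_many(CL, CR, pup_left[i, ], pup_right[i, ])
    total_gap <- total_gap + res$gap
    pe[[i]] <- res$pe
  }
  seg <- function(U, V) sqrt(rowSums((U - V)^2))
  shape_err <- abs(seg(pe[[1]], pe[[2]]) - board_spacing) +
    abs(seg(pe[[2]], pe[[3]]) - board_spacing) +
    abs(seg(pe[[3]], pe[[4]]) - board_spacing) +
    abs(seg(pe[[1]], pe[[4]]) - board_spacing)
  shape_err[!is.finite(shape_err)] <- Inf
  list(total_gap = total_gap, shape_err = shape_err)
}

# Dispersions of the two judgment bases over a candidate region. Medians
# are used because both error surfaces have extremely heavy upper tails
# (near-parallel sightline geometry blows the nearest points to infinity),
# which would otherwise flatten every score onto a plateau.
region_dispersions <- function(total_gap, shape_err) {
  list(gap = median(total_gap[is.finite(total_gap)]),
       shape = median(shape_err[is.finite(shape_err)]))
}

merged_scores <- function(total_gap, shape_err, epsilon, disp) {
  gap_term <- if (disp$gap == 0) ifelse(total_gap > 0, Inf, 0) else total_gap / disp$gap
  shape_term <- if (disp$shape == 0) ifelse(shape_err > 0, Inf, 0) else {
    shape_err / (epsilon * disp$shape)
  }
  exp(-(gap_term + shape_term))
}

#' Merged search objective for one candidate convergence pair
#'
#' Combines the two calibration judgment bases into one score:
#' `exp(-TotalGap / D_gap - ShapeError / (epsilon * D_shape))`, where
#' `TotalGap` is the summed sightline gap over the four fixations,
#' `ShapeError` is [shape_error()] of the four PoR midpoints, and
#' `D_gap`, `D_shape` are the dispersions (medians) of the two bases over
#' all `n` candidates of the current search region. The dispersion
#' normalization unifies the two bases onto one dimensionless scale;
#' `epsilon` down-weights the shape basis. A perfect candidate (zero gap,
#' zero shape error) scores 1; a zero dispersion with a positive error
#' scores 0 by convention.
#'
#' @param p_left,p_right candidate convergence points (mm, rig frame).
#' @param features 4-row placement tibble with pupil-center columns
#'   `pupil_lx..pupil_rz` and a `fixation` column (cross order 1..4).
#' @param region_total_gaps,region_shape_errors total gaps and shape
#'   errors of all candidates in the current region (length >= 2).
#' @param cfg an [objective_config()].
#' @return scalar score in `[0, 1]`.
#' @export
merged_objective <- function(p_left, p_right, features, region_total_gaps,
                             region_shape_errors, cfg = objective_config()) {
  if (length(region_shape_errors) < 2L || length(region_total_gaps) < 2L) {
    stop("merged_objective(): region stats must contain >= 2 candidates")
  }
  pup <- placement_pupils(features)
  ev <- eval_candidate_pairs(matrix(as.numeric(p_left), 1),
                             matrix(as.numeric(p_right), 1),
                             pup$left, pup$right, cfg$board_spacing)
  disp <- region_dispersions(region_total_gaps, region_shape_errors)
  merged_scores(ev$total_gap, ev$shape_err, cfg$epsilon, disp)
}

# ---- the shrinking search --------------------------------------------------

# direction set for the section scans: for each coordinate plane, a fan of
# unit directions applied either to both cubes (shared) or with opposite
# sign (differential). Shared moves span the sloppy directions of the
# objective, differential moves the stiff vergence directions.
section_directions <- function(fan_step) {
  angs <- seq(0, 180 - fan_step, by = fan_step) * pi / 180
  dirs <- list()
  for (plane in list(c(1, 3), c(1, 2), c(2, 3))) {
    for (a in angs) {
      v <- numeric(3)
      v[plane[1]] <- cos(a)
      v[plane[2]] <- sin(a)
      dirs[[length(dirs) + 1L]] <- list(v = v, shared = TRUE)
      dirs[[length(dirs) + 1L]] <- list(v = v, shared = FALSE)
    }
  }
  dirs
}

# Refine one seed pair by shrinking section scans: at each scale, sweep
# fine 1D scans over the direction fans (plus a pattern move along the
# sweep's net displacement) to a fixed point, then halve the scan span
# and step. Scoring uses the merged objective with dispersions frozen at
# the placement level (disp0).
refine_sections <- function(pup, cl, cr, disp0, cfg) {
  dirs <- section_directions(cfg$fan_step)
  score_of <- function(CL, CR) {
    ev <- eval_candidate_pairs(CL, CR, pup$left, pup$right, cfg$board_spacing)
    merged_scores(ev$total_gap, ev$shape_err, cfg$epsilon, disp0)
  }
  span <- cfg$half_width
  n_pts <- 401L
  traj <- list()
  scale_i <- 0L
  best <- NA_real_
  repeat {
    scale_i <- scale_i + 1L
    tl <- seq(-span, span, length.out = n_pts)
    i0 <- (n_pts + 1L) %/% 2L
    for (pass in seq_len(cfg$max_passes)) {
      moved <- FALSE
      prev6 <- c(cl, cr)
      for (d in dirs) {
        M <- outer(tl, d$v)
        CL <- sweep(M, 2L, cl, "+")
        CR <- if (d$shared) sweep(M, 2L, cr, "+") else sweep(-M, 2L, cr, "+")
        sc <- score_of(CL, CR)
        b <- which.max(sc)
        if (sc[b] > sc[i0] * (1 + 1e-12)) {
          cl <- CL[b, ]; cr <- CR[b, ]
          best <- sc[b]
          moved <- TRUE
        } else if (is.na(best)) best <- sc[i0]
      }
      d6 <- c(cl, cr) - prev6
      if (sqrt(sum(d6^2)) > 1e-12) {
        tp <- seq(-1, 10, by = 0.05)
        CL <- sweep(outer(tp, d6[1:3]), 2L, cl, "+")
        CR <- sweep(outer(tp, d6[4:6]), 2L, cr, "+")
        sc <- score_of(CL, CR)
        b <- which.max(sc)
        if (sc[b] > sc[which(tp == 0)] * (1 + 1e-12)) {
          cl <- CL[b, ]; cr <- CR[b, ]
          best <- sc[b]
          moved <- TRUE
        }
      }
      if (!moved) break
    }
    traj[[scale_i]] <- tibble::tibble(
      round = scale_i, step = 2 * span / (n_pts - 1L), half_width = span,
      score = best,
      p_left_x = cl[1], p_left_y = cl[2], p_left_z = cl[3],
      p_right_x = cr[1], p_right_y = cr[2], p_right_z = cr[3])
    span <- span / 2
    if (2 * span / (n_pts - 1L) < cfg$step_min) break
  }
  list(p_left = cl, p_right = cr, score = best, rounds = scale_i,
       trajectory = dplyr::bind_rows(traj))
}

# Full-product shrinking schedule (the printed coarse-lattice form):
# every round scores all pairs of the two cube lattices, recenters on the
# best pair, then halves the region and the step.
run_product_schedule <- function(pup, cl, cr, cfg) {
  hw <- cfg$half_width
  st <- cfg$step
  round_i <- 0L
  traj <- list()
  best <- NA_real_
  repeat {
    round_i <- round_i + 1L
    off <- lattice_offsets(hw, st)
    n_off <- nrow(off)
    n_pairs <- as.double(n_off)^2
    if (n_pairs > cfg$product_max) {
      stop(sprintf(paste0("search_convergence(): product lattice has %.3g pairs ",
                          "(> product_max = %.3g); use pairing = 'sections' ",
                          "or a coarser lattice"), n_pairs, cfg$product_max))
    }
    iL <- rep(seq_len(n_off), times = n_off)
    iR <- rep(seq_len(n_off), each = n_off)
    CL <- sweep(off[iL, , drop = FALSE], 2L, cl, "+")
    CR <- sweep(off[iR, , drop = FALSE], 2L, cr, "+")
    ev <- eval_candidate_pairs(CL, CR, pup$left, pup$right, cfg$board_spacing)
    disp <- region_dispersions(ev$total_gap, ev$shape_err)
    sc <- merged_scores(ev$total_gap, ev$shape_err, cfg$epsilon, disp)
    b <- which.max(sc)
    cl <- CL[b, ]; cr <- CR[b, ]
    best <- sc[b]
    traj[[round_i]] <- tibble::tibble(
      round = round_i, step = st, half_width = hw, score = best,
      p_left_x = cl[1], p_left_y = cl[2], p_left_z = cl[3],
      p_right_x = cr[1], p_right_y = cr[2], p_right_z = cr[3])
    hw <- hw / 2
    st <- st / 2
    if (st < cfg$step_min) break
  }
  list(p_left = cl, p_right = cr, score = best, rounds = round_i,
       trajectory = dplyr::bind_rows(traj))
}

#' Search the line-of-sight convergence points for one board placement
#'
#' Implements the shrinking search for the convergence pair: both points
#' start at the mean of the four pupil centers pushed `depth_offset` mm
#' along +Z (into the eyeball) inside a cubic initial region. A coarse
#' full-product pass over the two initial cubes (the printed 125-point
#' lattice per cube) fixes the merged objective's dispersion
#' normalization and proposes diverse seed pairs; each seed is then
#' refined by scans over structured 1D sections of the joint region whose
#' span and step are halved each scale until the step drops below
#' `step_min`. The finalist with the best merged score wins. The search
#' is fully deterministic (fixed direction fans, ties break to the lowest
#' index).
#'
#' The merged objective is strongly multi-modal (shape-consistent
#' impostor pairs with a residual sightline gap coexist with the true
#' pair behind a near-parallel-geometry barrier), which is what the
#' seeding pass addresses; identifiability weakens with board distance,
#' so recovered pairs at far placements carry larger errors along the
#' objective's sloppy directions.
#'
#' @param features 4-row tibble of one placement's fixations (columns
#'   `fixation`, `pupil_lx`..`pupil_rz`).
#' @param cfg an [objective_config()].
#' @return object of class `gaze_convergence`: `p_left`, `p_right` (mm),
#'   `score`, `rounds`, and a `trajectory` tibble (scale, step, span,
#'   score, best pair) for the winning seed.
#' @export
search_convergence <- function(features, cfg = objective_config()) {
  stopifnot(inherits(cfg, "objective_config"))
  pup <- placement_pupils(features)
  cl0 <- colMeans(pup$left) + c(0, 0, cfg$depth_offset)
  cr0 <- colMeans(pup$right) + c(0, 0, cfg$depth_offset)

  if (cfg$pairing == "product") {
    out <- run_product_schedule(pup, cl0, cr0, cfg)
    if (!is.finite(out$score) || out$score <= 0) {
      stop("search_convergence(): search failed (all candidate scores zero)")
    }
    return(structure(c(out, list(cfg = cfg)), class = "gaze_convergence"))
  }

  # seeding: coarse full product over the initial cubes
  off <- lattice_offsets(cfg$half_width, cfg$seed_step)
  n_off <- nrow(off)
  iL <- rep(seq_len(n_off), times = n_off)
  iR <- rep(seq_len(n_off), each = n_off)
  CL <- sweep(off[iL, , drop = FALSE], 2L, cl0, "+")
  CR <- sweep(off[iR, , drop = FALSE], 2L, cr0, "+")
  ev <- eval_candidate_pairs(CL, CR, pup$left, pup$right, cfg$board_spacing)
  disp0 <- region_dispersions(ev$total_gap, ev$shape_err)
  sc <- merged_scores(ev$total_gap, ev$shape_err, cfg$epsilon, disp0)

  seeds <- list(list(cl = cl0, cr = cr0))
  for (i in order(sc, decreasing = TRUE)) {
    if (length(seeds) >= cfg$n_seeds) break
    ok <- TRUE
    for (sd in seeds) {
      if (sqrt(sum((CL[i, ] - sd$cl)^2) + sum((CR[i, ] - sd$cr)^2)) <
          cfg$seed_separation) {
        ok <- FALSE
        break
      }
    }
    if (ok) seeds <- c(seeds, list(list(cl = CL[i, ], cr = CR[i, ])))
  }

  runs <- lapply(seeds, function(sd) refine_sections(pup, sd$cl, sd$cr, disp0, cfg))
  scores <- vapply(runs, function(r) r$score, numeric(1))
  if (!any(is.finite(scores) & scores > 0)) {
    stop("search_convergence(): search failed (all candidate scores zero)")
  }
  best <- runs[[which.max(scores)]]
  structure(c(best, list(cfg = cfg)), class = "gaze_convergence")
}

#' @export
print.gaze_convergence <- function(x, ...) {
  cat("Line-of-sight convergence pair (", x$rounds, " search scales)\n", sep = "")
  cat(sprintf("  P_L = (%.4f, %.4f, %.4f) mm\n", x$p_left[1], x$p_left[2], x$p_left[3]))
  cat(sprintf("  P_R = (%.4f, %.4f, %.4f) mm\n", x$p_right[1], x$p_right[2], x$p_right[3]))
  cat(sprintf("  merged score = %.6f\n", x$score))
  invisible(x)
}

#' Calibrate all board placements of a session
#'
#' Runs [search_convergence()] on each placement of a calibration feature
#' table and returns one row per placement with the recovered convergence
#' pair, the merged score, the placement-mean pupil sizes (the four
#' crosses of one placement share a viewing distance, so their pupil
#' sizes are averaged into the placement's calibration sample) and the
#' placement-mean inner corners.
#'
#' @param features calibration feature tibble (20 rows for the standard
#'   5-placement protocol) with columns `placement`, `fixation`,
#'   `pupil_lx`..`pupil_rz`, `s_left`, `s_right`, `corner_lx`..`corner_rz`.
#' @param cfg an [objective_config()].
#' @return tibble, one row per placement: convergence pair coordinates,
#'   `score`, `rounds`, `s_left`, `s_right`, mean corners.
#' @export
calibrate_session <- function(features, cfg = objective_config()) {
  stopifnot(all(c("placement", "fixation") %in% names(features)))
  features |>
    dplyr::group_by(.data$placement) |>
    dplyr::group_modify(function(g, key) {
      fit <- search_convergence(g, cfg)
      tibble::tibble(
        p_left_x = fit$p_left[1], p_left_y = fit$p_left[2], p_left_z = fit$p_left[3],
        p_right_x = fit$p_right[1], p_right_y = fit$p_right[2], p_right_z = fit$p_right[3],
        score = fit$score, rounds = fit$rounds,
        s_left = mean(g$s_left), s_right = mean(g$s_right),
        corner_lx = mean(g$corner_lx), corner_ly = mean(g$corner_ly),
        corner_lz = mean(g$corner_lz), corner_rx = mean(g$corner_rx),
        corner_ry = mean(g$corner_ry), corner_rz = mean(g$corner_rz))
    }) |>
    dplyr::ungroup()
}
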