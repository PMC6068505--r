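# Synthetic dark-pupil eye-image rendering with exact per-camera ground
# truth, used to exercise the imaging pipeline.

#' Appearance configuration for the synthetic renderer
#'
#' @param skin,iris,pupil base intensity levels (0..255) of the
#'   surround, iris disk and pupil.
#' @param iris_scale iris radius as a multiple of the pupil radius.
#' @param edge_px width (px) of the smooth intensity transition at the
#'   pupil boundary.
#' @param iris_edge_px width (px) of the (much softer) iris-to-surround
#'   transition; near-infrared dark-pupil imaging yields a sharp pupil
#'   boundary and a soft iris margin.
#' @param lid_fade unused placeholder kept for configs (lid shading is
#'   uniform).
#' @param lid shade everything outside the palpebral fissure wedge whose
#'   apex is the inner corner.
#' @param lid_depth intensity drop outside the fissure.
#' @param lid_width width (px) of the lid step edges.
#' @param lid_slopes image-space slopes of the upper and lower lid
#'   boundaries leaving the canthus (sign convention: negative opens
#'   upward).
#' @param occlusion_frac fraction of the pupil's vertical extent covered
#'   by the upper lid (0 = unoccluded).
#' @param spot add a saturated specular spot near the pupil center.
#' @param spot_offset spot offset from the pupil center (px).
#' @param spot_sigma spot Gaussian radius (px).
#' @param noise_sd Gaussian intensity noise (levels).
#' @return list of class `render_appearance`.
#' @export
render_appearance <- function(skin = 205, iris = 198, pupil = 30,
                              iris_scale = 3, edge_px = 1,
                              iris_edge_px = 25, lid_fade = 0.35,
                              lid = TRUE, lid_depth = 25, lid_width = 2,
                              lid_slopes = c(-0.40, 0.45),
                              occlusion_frac = 0,
                              spot = FALSE, spot_offset = c(6, -5),
                              spot_sigma = 2.5, noise_sd = 0) {
  structure(list(skin = skin, iris = iris, pupil = pupil,
                 iris_scale = iris_scale, edge_px = edge_px,
                 iris_edge_px = iris_edge_px, lid_fade = lid_fade,
                 lid = lid, lid_depth = lid_depth, lid_width = lid_width,
                 lid_slopes = lid_slopes,
                 occlusion_frac = occlusion_frac, spot = spot,
                 spot_offset = spot_offset, spot_sigma = spot_sigma,
                 noise_sd = noise_sd),
            class = "render_appearance")
}

# points on a 3D circle (n x 3)
circle_points_3d <- function(center, radius, normal, n = 256) {
  normal <- normal / norm3(normal)
  ref <- if (abs(normal[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- cross3(normal, ref); e1 <- e1 / norm3(e1)
  e2 <- cross3(normal, e1)
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  matrix(center, n, 3, byrow = TRUE) +
    radius * (outer(cos(th), e1) + outer(sin(th), e2))
}

# exact projected ellipse of a 3D circle in one camera
project_circle_ellipse <- function(center, radius, normal, cam) {
  pts <- project_points(circle_points_3d(center, radius, normal, 64), cam)
  fit_ellipse_lsq(pts[, 1], pts[, 2])
}

#' Render one camera's view of an eye
#'
#' Draws the dark pupil (the exact projection of the 3D pupil circle,
#' with a smooth boundary), an iris disk, optional eyelid lines meeting
#' at the projected inner corner (with optional upper-lid occlusion of
#' the pupil), an optional specular spot, and Gaussian intensity noise.
#'
#' @param circle a `pupil_circle`-like list: `center`, `radius`,
#'   `normal` (mm, rig frame).
#' @param corner3 inner-corner position (mm, rig frame).
#' @param cam one camera of a [default_rig()].
#' @param width,height image size (px).
#' @param side `"left"` or `"right"` (lateral direction of the lids).
#' @param appearance a [render_appearance()].
#' @return list: `img` (matrix), `truth` (list with `ellipse`
#'   (`ellipse2d`, exact projected pupil boundary) and `corner` (0-based
#'   px)).
#' @export
render_eye_view <- function(circle, corner3, cam, width = 640, height = 580,
                            side = "left", appearance = render_appearance()) {
  ap <- appearance
  e <- project_circle_ellipse(circle$center, circle$radius, circle$normal, cam)
  crn <- project_points(corner3, cam)
  xs <- matrix(0:(width - 1), height, width, byrow = TRUE)
  ys <- matrix(0:(height - 1), height, width)

  img <- matrix(ap$skin, height, width)
  smoothstep <- function(t) {
    t <- pmin(pmax(t, 0), 1)
    t * t * (3 - 2 * t)
  }
  # iris disk (smooth edge)
  r_iris <- ap$iris_scale * e$a
  d_ir <- sqrt((xs - e$x0)^2 + (ys - e$y0)^2)
  w_ir <- smoothstep((r_iris - d_ir) / (2 * ap$iris_edge_px) + 0.5)
  img <- img * (1 - w_ir) + ap$iris * w_ir
  # pupil: normalized ellipse radius; boundary at r = 1
  ca <- cos(e$alpha); sa <- sin(e$alpha)
  u <- ca * (xs - e$x0) + sa * (ys - e$y0)
  v <- -sa * (xs - e$x0) + ca * (ys - e$y0)
  r_ell <- sqrt((u / e$a)^2 + (v / e$b)^2)
  # convert the normalized offset to approximate pixels via the local radius
  loc <- sqrt(u^2 + v^2) / pmax(r_ell, 1e-9)
  w_pu <- smoothstep(((1 - r_ell) * loc) / (2 * ap$edge_px) + 0.5)
  img <- img * (1 - w_pu) + ap$pupil * w_pu

  if (ap$lid) {
    # Palpebral fissure with lid-margin shadows: two shadow bands just
    # outside the fissure boundaries (sharp edge at the boundary, soft
    # outward fade) meeting at the inner canthus, which is the corner
    # ground truth. Skin far from the fissure stays bright, so the
    # projection-based eye localization sees the usual dark trough.
    lat <- if (side == "left") 1 else -1
    t_par <- lat * (xs - crn[1])
    y_u <- crn[2] + ap$lid_slopes[1] * t_par
    if (ap$occlusion_frac > 0) {
      # drop the upper lid so it covers the top fraction of the pupil
      yext <- sqrt((e$a * sin(e$alpha))^2 + (e$b * cos(e$alpha))^2)
      y_cut <- e$y0 - yext + ap$occlusion_frac * 2 * yext
      y_u <- pmax(y_u, pmin(y_cut, crn[2] + 0.05 * t_par))
    }
    y_l <- crn[2] + ap$lid_slopes[2] * t_par
    ew <- ap$lid_width
    band <- 12
    du <- y_u - ys            # > 0 above the upper boundary
    dl <- ys - y_l            # > 0 below the lower boundary
    shade <- function(d) smoothstep(d / ew + 0.5) * exp(-pmax(d, 0) / band)
    w_lat <- smoothstep(t_par / (2 * ew) + 0.5) *
      smoothstep((0.45 * width - t_par) / (2 * ew) + 0.5)
    sh <- pmax(shade(du) * w_lat, shade(dl) * w_lat)
    img <- img - ap$lid_depth * sh
  }
  if (ap$spot) {
    d2 <- (xs - e$x0 - ap$spot_offset[1])^2 + (ys - e$y0 - ap$spot_offset[2])^2
    img <- img + (300 - img) * exp(-d2 / (2 * ap$spot_sigma^2))
  }
  if (ap$noise_sd > 0) {
    img <- img + matrix(rnorm(height * width, 0, ap$noise_sd), height, width)
  }
  img <- pmin(pmax(img, 0), 255)
  list(img = img, truth = list(ellipse = e,
                               corner = c(x = crn[1], y = crn[2])))
}

#' Render the four-camera frame set for one fixation
#'
#' Takes one exact ground-truth feature row from the simulator, builds
#' the per-eye 3D pupil circles (normal along the sightline), and renders
#' all four camera views with exact per-camera ground truth.
#'
#' @param truth_row one row of a simulated session's exact truth tibble
#'   (`simulate_session()$truth$captures` or `$tests`).
#' @param rig a [default_rig()].
#' @param appearance a [render_appearance()].
#' @param seed seed for the pixel noise.
#' @return list of class `rendered_frames`: `frames` (named list `L1`,
#'   `L2`, `R1`, `R2` of matrices) and `truth` (per camera the exact
#'   projected ellipse and corner).
#' @export
render_eye_pair <- function(truth_row, rig = default_rig(),
                            appearance = render_appearance(), seed = 1) {
  f <- truth_row
  circ <- function(eye) {
    p <- if (eye == "left") c(f$pupil_lx, f$pupil_ly, f$pupil_lz) else
      c(f$pupil_rx, f$pupil_ry, f$pupil_rz)
    cv <- if (eye == "left") c(f$conv_lx, f$conv_ly, f$conv_lz) else
      c(f$conv_rx, f$conv_ry, f$conv_rz)
    s <- if (eye == "left") f$s_left else f$s_right
    list(center = p, radius = s / 2, normal = (p - cv) / norm3(p - cv))
  }
  corners <- list(left = c(f$corner_lx, f$corner_ly, f$corner_lz),
                  right = c(f$corner_rx, f$corner_ry, f$corner_rz))
  with_seed(seed, {
    out <- list(frames = list(), truth = list())
    for (id in c("L1", "L2", "R1", "R2")) {
      side <- if (substr(id, 1, 1) == "L") "left" else "right"
      rv <- render_eye_view(circ(side), corners[[side]], rig$cameras[[id]],
                            width = rig$width, height = rig$height,
                            side = side, appearance = appearance)
      out$frames[[id]] <- rv$img
      out$truth[[id]] <- rv$truth
    }
    structure(out, class = "rendered_frames")
  })
}
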