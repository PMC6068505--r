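# Serialization (sessions, features, models), configuration, and the
# command-line umbrella. JSON for models and ground truth, CSV for
# tabular feature tracks, YAML for configuration; all files carry a
# schema_version and declare their units (mm, px).

SCHEMA_VERSION <- "1.0"

feature_columns <- c("placement", "fixation",
                     "pupil_lx", "pupil_ly", "pupil_lz",
                     "pupil_rx", "pupil_ry", "pupil_rz",
                     "s_left", "s_right",
                     "corner_lx", "corner_ly", "corner_lz",
                     "corner_rx", "corner_ry", "corner_rz")

#' Write / read a session to JSON
#'
#' Numeric fields round-trip at full double precision. Files carry
#' `schema_version` and `units`; reading rejects unknown versions and
#' non-mm units.
#'
#' @param session a `gaze_session` (or a list with `captures` and
#'   optionally `tests`, `truth`).
#' @param path output path.
#' @return `write_session()` returns `path` invisibly; `read_session()`
#'   returns the session list.
#' @export
write_session <- function(session, path) {
  payload <- list(
    schema_version = SCHEMA_VERSION,
    units = "mm",
    seed = session$seed,
    captures = session$captures,
    tests = session$tests,
    truth = session$truth)
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  if (!file.exists(path)) stop("read_session(): file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$schema_version) || raw$schema_version != SCHEMA_VERSION) {
    stop(sprintf("read_session(): schema version mismatch (got %s, expected %s)",
                 raw$schema_version %||% "<none>", SCHEMA_VERSION))
  }
  if (is.null(raw$units) || raw$units != "mm") {
    stop(sprintf("read_session(): unit mismatch (got '%s', expected 'mm')",
                 raw$units %||% "<none>"))
  }
  out <- list(captures = tibble::as_tibble(raw$captures),
              seed = raw$seed, schema_version = raw$schema_version)
  if (!is.null(raw$tests)) out$tests <- tibble::as_tibble(raw$tests)
  if (!is.null(raw$truth)) {
    out$truth <- lapply(raw$truth, tibble::as_tibble)
  }
  missing <- setdiff(feature_columns, names(out$captures))
  if (length(missing)) {
    stop("read_session(): captures missing columns: ",
         paste(missing, collapse = ", "))
  }
  structure(out, class = "gaze_session")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write / read a feature table to CSV
#'
#' @param features feature tibble (standard schema, mm).
#' @param path file path.
#' @return the features tibble (invisibly for the writer).
#' @export
write_features_csv <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  if (!file.exists(path)) stop("read_features_csv(): file not found: ", path)
  x <- suppressWarnings(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
  pr <- readr::problems(x)
  if (nrow(pr)) {
    stop(sprintf("read_features_csv(): malformed CSV at row %d (%s)",
                 pr$row[1], pr$expected[1]))
  }
  missing <- setdiff(setdiff(feature_columns, c("placement", "fixation")),
                     names(x))
  if (length(missing)) {
    stop("read_features_csv(): missing columns: ",
         paste(missing, collapse = ", "))
  }
  tibble::as_tibble(x)
}

#' Write / read a fitted gaze model to JSON
#'
#' The model file stores, per eye, the polynomial coefficients and the
#' calibrated pupil-size range, plus the corner-vector reference (`v0`,
#' the reference right-corner position, per-eye rotations as unit
#' quaternions and vector norms), the calibration samples, and a
#' `schema_version`.
#'
#' @param model a `gaze_model` from [calibrate_gaze()].
#' @param path file path.
#' @return `read_model_json()` returns a `gaze_model`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "gaze_model"))
  eye_out <- function(eye) {
    m <- model$model[[eye]]
    list(gamma = m$gamma, alpha = m$alpha, beta = m$beta,
         s_range = m$s_range, n = m$n, sigma_z = m$sigma_z)
  }
  ref <- model$reference
  payload <- list(
    schema_version = SCHEMA_VERSION,
    units = "mm",
    left = eye_out("left"), right = eye_out("right"),
    reference = list(
      v0 = ref$v0, origin = ref$origin,
      q_left = rotation_to_quaternion(ref$left$R),
      q_right = rotation_to_quaternion(ref$right$R),
      norm_left = ref$left$norm, norm_right = ref$right$norm),
    samples = model$model$samples,
    calibration = model$calibration)
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop("read_model_json(): file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$schema_version) || raw$schema_version != SCHEMA_VERSION) {
    stop("read_model_json(): schema version mismatch")
  }
  if (is.null(raw$units) || raw$units != "mm") {
    stop("read_model_json(): unit mismatch (expected mm)")
  }
  eye_in <- function(e) {
    list(gamma = as.numeric(e$gamma), alpha = as.numeric(e$alpha),
         beta = as.numeric(e$beta), s_range = as.numeric(e$s_range),
         n = e$n, sigma_z = e$sigma_z)
  }
  reference <- structure(list(
    v0 = as.numeric(raw$reference$v0),
    origin = as.numeric(raw$reference$origin),
    left = list(R = quaternion_to_rotation(as.numeric(raw$reference$q_left)),
                norm = raw$reference$norm_left),
    right = list(R = quaternion_to_rotation(as.numeric(raw$reference$q_right)),
                 norm = raw$reference$norm_right)),
    class = "convergence_reference")
  cm <- structure(list(left = eye_in(raw$left), right = eye_in(raw$right),
                       samples = tibble::as_tibble(raw$samples)),
                  class = "convergence_model")
  structure(list(model = cm, reference = reference,
                 calibration = tibble::as_tibble(raw$calibration),
                 cfg = objective_config()),
            class = "gaze_model")
}

#' Read a configuration YAML
#'
#' Recognized keys mirror [objective_config()] and the noise fields of
#' [rig_scenario()]; unknown keys raise an error.
#'
#' @param path YAML file.
#' @return list with `objective` (an `objective_config`) and `scenario`
#'   overrides.
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  known_obj <- names(formals(objective_config))
  known_sc <- c("noise_feature", "noise_px", "anatomical_offset",
                "placement_distances", "board_spacing")
  unknown <- setdiff(names(raw), c(known_obj, known_sc))
  if (length(unknown)) {
    stop("read_config_yaml(): unknown keys: ", paste(unknown, collapse = ", "))
  }
  obj <- do.call(objective_config, raw[intersect(names(raw), known_obj)])
  list(objective = obj, scenario = raw[intersect(names(raw), known_sc)])
}

# ---- command-line interface ----------------------------------------------

cli_usage <- function() {
  paste(
    "usage: gaze3d <command> [options]",
    "",
    "commands:",
    "  simulate  --out DIR [--seed N] [--noise MM] [--images]",
    "  detect    --images DIR --out FILE.csv [--seed N]",
    "  calibrate --session FILE.json --out model.json",
    "  estimate  --model model.json --features FILE.csv --out por.csv",
    "",
    "common options: --help",
    sep = "\n")
}

cli_args <- function(argv) {
  out <- list(flags = character(0), opts = list())
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (i < length(argv) && !startsWith(argv[i + 1], "--")) {
        out$opts[[key]] <- argv[i + 1]
        i <- i + 2L
      } else {
        out$flags <- c(out$flags, key)
        i <- i + 1L
      }
    } else {
      stop("unexpected argument: ", a)
    }
  }
  out
}

#' Command-line dispatcher
#'
#' Subcommands: `simulate` (write a synthetic session), `detect` (run
#' the imaging pipeline on rendered four-camera PNG frames), `calibrate`
#' (fit the gaze model from a session), `estimate` (predict 3D
#' Points-of-Regard from a features CSV). Returns the process exit
#' status instead of quitting so it can be driven in-process; the
#' installed `gaze3d` script forwards `commandArgs()` and quits with the
#' returned status.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit status (0 on success), invisibly.
#' @export
gaze3d_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv) || argv[1] %in% c("--help", "help")) {
    cat(cli_usage(), "\n")
    return(invisible(0L))
  }
  cmd <- argv[1]
  res <- tryCatch({
    pa <- cli_args(argv[-1])
    if ("help" %in% pa$flags) {
      cat(cli_usage(), "\n")
      return(invisible(0L))
    }
    opts <- pa$opts
    need <- function(k) {
      if (is.null(opts[[k]])) stop(sprintf("missing required option --%s", k))
      opts[[k]]
    }
    switch(cmd,
      simulate = {
        dir.create(need("out"), showWarnings = FALSE, recursive = TRUE)
        seed <- as.integer(opts$seed %||% 1)
        noise <- as.numeric(opts$noise %||% 0)
        sc <- rig_scenario(noise_feature = noise)
        session <- simulate_session(sc, seed = seed)
        write_session(session, file.path(opts$out, "session.json"))
        write_features_csv(session$captures, file.path(opts$out, "features.csv"))
        if ("images" %in% pa$flags) {
          for (i in seq_len(nrow(session$truth$captures))) {
            rd <- render_eye_pair(session$truth$captures[i, ], sc$rig, seed = seed + i)
            for (id in names(rd$frames)) {
              png::writePNG(rd$frames[[id]] / 255,
                            file.path(opts$out, sprintf("frame%02d_%s.png", i, id)))
            }
          }
        }
        message("wrote session to ", opts$out)
        0L
      },
      detect = {
        dir <- need("images")
        seed <- as.integer(opts$seed %||% 1)
        files <- list.files(dir, pattern = "^frame[0-9]+_(L1|L2|R1|R2)\\.png$")
        if (!length(files)) stop("no frame PNGs found in ", dir)
        ids <- unique(sub("_(L1|L2|R1|R2)\\.png$", "", files))
        rig <- default_rig()
        rows <- lapply(seq_along(ids), function(i) {
          frames <- lapply(c("L1", "L2", "R1", "R2"), function(camid) {
            png::readPNG(file.path(dir, paste0(ids[i], "_", camid, ".png"))) * 255
          })
          names(frames) <- c("L1", "L2", "R1", "R2")
          extract_frame_features(frames, rig, seed = seed, fixation = i)
        })
        write_features_csv(dplyr::bind_rows(rows), need("out"))
        message("wrote features to ", opts$out)
        0L
      },
      calibrate = {
        session <- read_session(need("session"))
        model <- calibrate_gaze(session)
        write_model_json(model, need("out"))
        message("wrote model to ", opts$out)
        0L
      },
      estimate = {
        model <- read_model_json(need("model"))
        features <- read_features_csv(need("features"))
        est <- estimate_por(features, model)
        readr::write_csv(est, need("out"))
        message("wrote PoR estimates to ", opts$out)
        0L
      },
      {
        cat(cli_usage(), "\n")
        stop("unknown command: ", cmd)
      })
  }, error = function(e) {
    message("gaze3d: error: ", conditionMessage(e))
    1L
  })
  invisible(as.integer(res))
}
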