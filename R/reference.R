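#' Backward-difference velocities with boundary rule
#'
#' Joint velocities are derived from sampled positions by a backward
#' difference divided by the sampling interval,
#' `v[i] = (p[i] - p[i-1]) / dt`, with the initial velocity set equal to
#' the first computable one (`v[1] = v[2]`).
#'
#' @param positions Numeric series (>= 2 samples) or a matrix (one series
#'   per column).
#' @param dt Sampling interval (s), > 0.
#' @return Velocity series of the same length/shape.
#' @export
finite_diff_velocity <- function(positions, dt) {
  if (dt <= 0) stop("dt must be > 0")
  if (is.matrix(positions)) {
    return(apply(positions, 2, finite_diff_velocity, dt = dt))
  }
  n <- length(positions)
  if (n < 2) stop("finite_diff_velocity: need at least two samples")
  v <- c(NA_real_, diff(positions) / dt)
  v[1] <- v[2]
  v
}

#' Reference trajectory container
#'
#' Time-gridded joint positions with derived velocities, used as the
#' imitation target. Velocities follow the backward-difference rule of
#' [finite_diff_velocity()]; the pelvis translational velocity series is
#' kept separately for the goal reward.
#'
#' @param times Uniform time grid (s).
#' @param joint_pos Matrix of joint positions (rad or m), one named column
#'   per degree of freedom.
#' @return Object of class `reference_trajectory` with fields `times`,
#'   `dt`, `joint_pos`, `joint_vel`, `pelvis_vel`.
#' @export
reference_trajectory <- function(times, joint_pos) {
  times <- as.numeric(times)
  joint_pos <- as.matrix(joint_pos)
  if (nrow(joint_pos) != length(times)) stop("times/positions length mismatch")
  if (length(times) < 2) stop("need at least two samples")
  dts <- diff(times)
  dt <- stats::median(dts)
  if (any(abs(dts - dt) > 1e-6 * max(1, dt))) {
    stop("time grid is not uniform")
  }
  if (is.null(colnames(joint_pos))) stop("joint_pos must have named columns")
  joint_vel <- finite_diff_velocity(joint_pos, dt)
  pv_cols <- intersect(c("pelvis_tx", "pelvis_ty"), colnames(joint_pos))
  pelvis_vel <- joint_vel[, pv_cols, drop = FALSE]
  structure(list(times = times, dt = dt, joint_pos = joint_pos,
                 joint_vel = joint_vel, pelvis_vel = pelvis_vel),
            class = "reference_trajectory")
}

#' @export
print.reference_trajectory <- function(x, ...) {
  cat(sprintf("reference_trajectory: %d samples at %.4g s, %d DOFs (%s)\n",
              length(x$times), x$dt, ncol(x$joint_pos),
              paste(utils::head(colnames(x$joint_pos), 4), collapse = ", ")))
  invisible(x)
}

# index of the reference sample nearest to time t (NA past the end)
ref_index <- function(ref, t, tol = 0.5) {
  i <- round((t - ref$times[1]) / ref$dt) + 1
  if (i < 1) i <- 1
  if (i > length(ref$times)) return(NA_integer_)
  as.integer(i)
}

#' Write a reference trajectory to CSV
#'
#' Plain-CSV dialect: a `time` column followed by one column per DOF, SI
#' units (m, rad).
#'
#' @param ref A `reference_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(ref, path) {
  df <- data.frame(time = ref$times, ref$joint_pos, check.names = FALSE)
  utils::write.csv(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a reference trajectory in the TRC-like dialect
#'
#' Tab-separated with the standard two header lines (`DataRate`,
#' `NumFrames`, ...) followed by `Frame#`, `Time` and one column per DOF.
#' Translational DOFs (names ending `_tx`/`_ty`/`_tz`) are written in the
#' declared length units; rotational DOFs in degrees.
#'
#' @param ref A `reference_trajectory`.
#' @param path Output path.
#' @param units `"m"` or `"mm"` for translational columns.
#' @return `path`, invisibly.
#' @export
write_trajectory_trc <- function(ref, path, units = c("m", "mm")) {
  units <- match.arg(units)
  rate <- 1 / ref$dt
  n <- length(ref$times)
  dat <- ref$joint_pos
  trans <- grepl("_t[xyz]$", colnames(dat))
  dat[, trans] <- dat[, trans] * if (units == "mm") 1000 else 1
  dat[, !trans] <- dat[, !trans] * 180 / pi
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("PathFileType", "4", "(X/Y/Z)", basename(path), sep = "\t"),
    paste("DataRate", "CameraRate", "NumFrames", "NumMarkers", "Units",
          "OrigDataRate", "OrigDataStartFrame", "OrigNumFrames", sep = "\t"),
    paste(sprintf("%.6f", rate), sprintf("%.6f", rate), n,
          ncol(dat), units, sprintf("%.6f", rate), 1, n, sep = "\t"),
    paste(c("Frame#", "Time", colnames(dat)), collapse = "\t")
  ), con)
  body <- cbind(seq_len(n), sprintf("%.12g", ref$times),
                matrix(sprintf("%.12g", dat), nrow = n))
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a reference trajectory
#'
#' Reads either the plain-CSV dialect (a `time` column plus one SI-unit
#' column per DOF) or the TRC-like tab-separated dialect (two header
#' lines, `Frame#`/`Time` columns, translations in the declared units,
#' rotations in degrees; units normalized to m and rad on read). Ragged
#' rows and non-monotone time stamps are rejected with the offending row
#' number; a TRC `DataRate` inconsistent with the time column is rejected.
#'
#' @param path Input file.
#' @param dialect `"csv"` or `"trc"`; guessed from the extension by
#'   default.
#' @return A `reference_trajectory`.
#' @export
read_trajectory <- function(path, dialect = NULL) {
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.trc$", path, ignore.case = TRUE)) "trc" else "csv"
  }
  dialect <- match.arg(dialect, c("csv", "trc"))
  if (dialect == "csv") {
    nf <- utils::count.fields(path, sep = ",")
    if (length(unique(nf)) != 1) {
      stop("ragged row at line ", which(nf != nf[1])[1] + 0)
    }
    df <- utils::read.csv(path, check.names = FALSE)
    if (!"time" %in% names(df)) stop("CSV trajectory needs a 'time' column")
    times <- df$time
    check_monotone(times)
    pos <- as.matrix(df[setdiff(names(df), "time")])
    return(reference_trajectory(times, pos))
  }
  lines <- readLines(path)
  if (length(lines) < 5) stop("TRC file too short")
  hdr_names <- strsplit(lines[2], "\t")[[1]]
  hdr_vals <- strsplit(lines[3], "\t")[[1]]
  hdr <- stats::setNames(as.list(hdr_vals), hdr_names)
  rate <- as.numeric(hdr$DataRate)
  units <- hdr$Units
  cols <- strsplit(lines[4], "\t")[[1]]
  body <- lines[-(1:4)]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t")
  nf <- lengths(fields)
  if (any(nf != length(cols))) {
    stop("ragged row at line ", which(nf != length(cols))[1] + 4)
  }
  mat <- do.call(rbind, lapply(fields, as.numeric))
  colnames(mat) <- cols
  times <- mat[, "Time"]
  check_monotone(times)
  dt <- stats::median(diff(times))
  if (abs(1 / dt - rate) > 0.01 * rate) {
    stop("TRC DataRate (", rate, " Hz) inconsistent with the time column (",
         sprintf("%.4g", 1 / dt), " Hz)")
  }
  dat <- mat[, setdiff(cols, c("Frame#", "Time")), drop = FALSE]
  trans <- grepl("_t[xyz]$", colnames(dat))
  dat[, trans] <- dat[, trans] / if (identical(units, "mm")) 1000 else 1
  dat[, !trans] <- dat[, !trans] * pi / 180
  reference_trajectory(times, dat)
}

check_monotone <- function(times) {
  bad <- which(diff(times) <= 0)
  if (length(bad) > 0) {
    stop("non-monotone time at row ", bad[1] + 1)
  }
  invisible(TRUE)
}

#' Synthetic gait specification
#'
#' Parameters of the synthetic stair/ramp reference-gait generator that
#' stands in for motion-capture imitation data: cycle timing, terrain
#' progression, per-DOF two-harmonic joint templates, optional seeded
#' noise.
#'
#' @param terrain_kind `"stairs"` or `"ramp"`.
#' @param cycle_duration Gait-cycle duration (s). Default 1.4 s.
#' @param n_cycles Number of cycles. Default 2.
#' @param stand_time Stand-still lead-in before gait initiation (s).
#' @param dt Sampling interval (s). Default 0.01 s.
#' @param stride_length Advance per cycle along the slope for the ramp
#'   task (m).
#' @param noise_sd Standard deviation of seeded Gaussian noise added to
#'   the joint series (rad). Default 0 (inverse-kinematics references are
#'   smooth at this scale).
#' @param seed RNG seed for the noise.
#' @return Object of class `synthetic_gait_spec`.
#' @export
synthetic_gait_spec <- function(terrain_kind = c("stairs", "ramp"),
                                cycle_duration = 1.4, n_cycles = 2,
                                stand_time = 0.4, dt = 0.01,
                                stride_length = 0.6, noise_sd = 0,
                                seed = 1) {
  terrain_kind <- match.arg(terrain_kind)
  stopifnot(cycle_duration > 0, n_cycles >= 1, stand_time >= 0, dt > 0,
            stride_length > 0, noise_sd >= 0)
  structure(list(terrain_kind = terrain_kind,
                 cycle_duration = cycle_duration,
                 n_cycles = as.integer(n_cycles), stand_time = stand_time,
                 dt = dt, stride_length = stride_length,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_gait_spec")
}

# Two-harmonic joint templates (rad) as a function of cycle phase in
# [0, 1). Phase 0 is heel strike; the swing phase occupies roughly
# phi in [0.6, 1). Shapes mimic stair/ramp ascent kinematics (strong
# stance knee extension after weight acceptance, swing knee flexion for
# clearance, ankle plantarflexion at push-off); exact shapes are
# configuration, not claims about any subject.
gait_templates <- function(kind) {
  if (kind == "stairs") {
    list(
      hip = function(phi) 0.55 + 0.40 * cos(2 * pi * phi + 0.4) +
        0.05 * cos(4 * pi * phi + 1.0),
      knee = function(phi) -0.75 + 0.50 * cos(2 * pi * phi + 0.2) -
        0.30 * cos(4 * pi * phi + 2.2),
      ankle = function(phi) 0.05 + 0.22 * cos(2 * pi * phi + 1.0) +
        0.08 * cos(4 * pi * phi + 0.5)
    )
  } else {
    list(
      hip = function(phi) 0.40 + 0.30 * cos(2 * pi * phi + 0.4) +
        0.04 * cos(4 * pi * phi + 1.0),
      knee = function(phi) -0.45 + 0.35 * cos(2 * pi * phi + 0.3) -
        0.18 * cos(4 * pi * phi + 2.0),
      ankle = function(phi) 0.12 + 0.18 * cos(2 * pi * phi + 1.2) +
        0.05 * cos(4 * pi * phi + 0.4)
    )
  }
}

#' Generate a synthetic reference gait
#'
#' Builds the imitation target for the planar model: the pelvis advances
#' one step depth and rises one step height per cycle on stairs (or one
#' stride projected on the slope for the ramp); hip, knee and ankle
#' angles follow smooth two-harmonic periodic templates with the left and
#' right legs half a cycle out of phase, the left leg taking the first
#' swing. A stand-still lead-in precedes gait initiation and the
#' templates are blended in smoothly. Noise, when requested, is Gaussian,
#' seeded and reproducible. All joint series are clamped to the planar
#' model's joint limits.
#'
#' @param spec A [synthetic_gait_spec()].
#' @param terrain A [stair_spec()] or [ramp_spec()] providing the terrain
#'   dimensions; defaults to the task geometry for `spec$terrain_kind`.
#' @param model Optional planar `model_spec` supplying joint limits and
#'   the standing pelvis height.
#' @return A `reference_trajectory` over the planar model's 9 DOFs.
#' @export
synth_gait <- function(spec, terrain = NULL, model = NULL) {
  stopifnot(inherits(spec, "synthetic_gait_spec"))
  if (is.null(terrain)) {
    terrain <- if (spec$terrain_kind == "stairs") stair_spec() else ramp_spec()
  }
  if (is.null(model)) model <- planar_model(spec$terrain_kind)
  cm <- compile_model(model)
  h0 <- cm$init_pelvis_height

  t_end <- spec$stand_time + spec$n_cycles * spec$cycle_duration
  times <- seq(0, t_end, by = spec$dt)
  nt <- length(times)
  tpl <- gait_templates(spec$terrain_kind)

  if (spec$terrain_kind == "stairs") {
    adv_per_cycle <- terrain$step_depth
    rise_per_cycle <- terrain$step_height
  } else {
    grad <- atan(terrain$rise / terrain$run)
    adv_per_cycle <- spec$stride_length * cos(grad)
    rise_per_cycle <- spec$stride_length * sin(grad)
  }

  # cycle progress: 0 during the stand phase, then linear in t
  prog <- pmax(times - spec$stand_time, 0) / spec$cycle_duration
  # blend factor easing from the standing pose into the templates
  ramp_T <- min(0.4 * spec$cycle_duration, 0.5)
  blend <- pmin(pmax(times - spec$stand_time, 0) / ramp_T, 1)
  blend <- (1 - cos(pi * blend)) / 2

  # left leg swings first: phase offset 0.6 puts it at swing onset when
  # gait starts; right leg is half a cycle behind
  phi_l <- (prog + 0.60) %% 1
  phi_r <- (prog + 0.10) %% 1

  stand <- c(hip = 0.0, knee = 0.0, ankle = 0.0)
  leg_series <- function(phi) {
    cbind(hip = stand["hip"] + blend * (tpl$hip(phi) - stand["hip"]),
          knee = stand["knee"] + blend * (tpl$knee(phi) - stand["knee"]),
          ankle = stand["ankle"] + blend * (tpl$ankle(phi) - stand["ankle"]))
  }
  L <- leg_series(phi_l); R <- leg_series(phi_r)

  pelvis_tx <- adv_per_cycle * prog * blend
  osc <- 0.02 * sin(2 * pi * ((2 * prog) %% 1)) * blend
  pelvis_ty <- h0 + rise_per_cycle * prog * blend + osc
  pelvis_tilt <- -0.08 * blend + 0.02 * sin(2 * pi * prog + 0.5) * blend

  pos <- cbind(pelvis_tx = pelvis_tx, pelvis_ty = pelvis_ty,
               pelvis_tilt = pelvis_tilt,
               hip_r = R[, "hip"], knee_r = R[, "knee"],
               ankle_r = R[, "ankle"],
               hip_l = L[, "hip"], knee_l = L[, "knee"],
               ankle_l = L[, "ankle"])

  if (spec$noise_sd > 0) {
    rs <- get_rng_state()
    on.exit(restore_rng_state(rs), add = TRUE)
    set.seed(spec$seed)
    pos <- pos + matrix(stats::rnorm(length(pos), 0, spec$noise_sd),
                        nrow = nt)
  }

  # clamp to the model's joint limits
  for (j in seq_along(cm$dof_names)) {
    nmj <- cm$dof_names[j]
    if (nmj %in% colnames(pos) && is.finite(cm$qmin[j])) {
      pos[, nmj] <- pmin(pmax(pos[, nmj], cm$qmin[j]), cm$qmax[j])
    }
  }
  reference_trajectory(times, pos)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
restore_rng_state <- function(state) {
  if (!is.null(state)) {
    assign(".Random.seed", state, envir = globalenv())
  }
}
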