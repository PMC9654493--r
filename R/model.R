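#' Multibody model specification
#'
#' Describes a muscle-driven rigid-body chain: segments, joints (a tree
#' rooted at the pelvis), Hill-type muscles with body-local path points,
#' and foot contact spheres. The default simulation model is the reduced
#' planar variant built by [planar_model()]; the full 3D topology is
#' available as a configuration preset via [full_model_spec()] but is not
#' simulated.
#'
#' @param name Model name.
#' @param bodies Data frame with columns `name`, `mass` (kg), `inertia`
#'   (kg m^2 about the center of mass), `com_x`, `com_y` (body-local
#'   center-of-mass offset, m), `length` (m).
#' @param joints Data frame with columns `name`, `type` (`"planar"` for
#'   the 3-DOF root, `"pin"` otherwise), `parent`, `child`, `px`, `py`
#'   (anchor in the parent frame), `cx`, `cy` (anchor in the child frame),
#'   `qmin`, `qmax` (coordinate limits, rad; `NA` = unlimited). Joints
#'   must be listed parent-before-child and form a tree.
#' @param muscles List of [muscle_params()] objects, each with a `path`
#'   data frame (`body`, `x`, `y`).
#' @param spheres Data frame of contact spheres: `name`, `body`, `x`, `y`,
#'   `z` (body-local center, m), `diameter` (m), `foot` (grouping label
#'   for ground-reaction reporting).
#' @param gravity Gravitational acceleration (m/s^2).
#' @param trunk_pelvis_angle Fixed pelvis-trunk angle (deg) folded into
#'   the lumped trunk segment's center of mass.
#' @param isometric_scale Multiplier already applied to all `f_max`.
#' @param init_pelvis_height Standing pelvis height (m), used by the fall
#'   detector.
#' @param joint_damping Passive damping on pin joints (N m s/rad).
#' @param limit_stiffness,limit_damping Soft joint-limit torque
#'   coefficients (N m/rad, N m s/rad).
#' @param planar Whether the model can be forward-simulated by this
#'   package's planar dynamics.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(name, bodies, joints, muscles, spheres = NULL,
                       gravity = 9.80665, trunk_pelvis_angle = 0,
                       isometric_scale = 1, init_pelvis_height = 0.94,
                       joint_damping = 0.1, limit_stiffness = 300,
                       limit_damping = 2, planar = TRUE) {
  stopifnot(is.data.frame(bodies), is.data.frame(joints), is.list(muscles))
  if (isometric_scale <= 0) stop("isometric_scale must be > 0")
  # joint graph must be a tree rooted at the first (free) body
  childs <- joints$child
  if (any(duplicated(childs))) stop("joint graph is not a tree")
  structure(list(name = name, bodies = bodies, joints = joints,
                 muscles = muscles, spheres = spheres, gravity = gravity,
                 trunk_pelvis_angle = trunk_pelvis_angle,
                 isometric_scale = isometric_scale,
                 init_pelvis_height = init_pelvis_height,
                 joint_damping = joint_damping,
                 limit_stiffness = limit_stiffness,
                 limit_damping = limit_damping, planar = planar),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec '%s': %d bodies, %d joints, %d muscles%s\n",
              x$name, nrow(x$bodies), nrow(x$joints), length(x$muscles),
              if (x$planar) " (planar)" else " (3D, configuration only)"))
  invisible(x)
}

# Approximate Hill-muscle properties for the simplified lower-limb model
# family: maximum isometric force (N) and optimal fiber length (m) per
# muscle. Tendon slack lengths are calibrated at model build time so that
# the standing posture puts each fiber at its optimal length.
planar_muscle_table <- function() {
  data.frame(
    muscle = c("glut_max", "iliopsoas", "vasti", "bifemsh", "gastroc",
               "soleus", "tib_ant"),
    f_max = c(1944, 2186, 5000, 804, 2500, 3549, 1759),
    l_opt = c(0.16, 0.12, 0.09, 0.17, 0.06, 0.05, 0.098),
    penn = c(0.0, 0.0, 0.0873, 0.4014, 0.2967, 0.4363, 0.0873)
  )
}

planar_muscle_paths <- function(side) {
  s <- side
  th <- paste0("thigh_", s); sh <- paste0("shank_", s)
  ft <- paste0("foot_", s)
  list(
    glut_max = data.frame(body = c("pelvis", th),
                          x = c(-0.080, -0.030), y = c(0.000, -0.120)),
    iliopsoas = data.frame(body = c("pelvis", th),
                           x = c(0.060, 0.020), y = c(-0.020, -0.100)),
    vasti = data.frame(body = c(th, th, sh),
                       x = c(0.040, 0.055, 0.045),
                       y = c(-0.200, -0.400, -0.060)),
    bifemsh = data.frame(body = c(th, sh),
                         x = c(-0.030, -0.035), y = c(-0.200, -0.060)),
    gastroc = data.frame(body = c(th, ft),
                         x = c(-0.020, -0.050), y = c(-0.390, -0.020)),
    soleus = data.frame(body = c(sh, ft),
                        x = c(-0.025, -0.050), y = c(-0.150, -0.020)),
    tib_ant = data.frame(body = c(sh, ft),
                         x = c(0.028, 0.060), y = c(-0.300, -0.010))
  )
}

#' Reduced planar musculoskeletal model
#'
#' A sagittal-plane 7-body chain: a lumped pelvis+trunk+head segment on a
#' 3-DOF planar root, and per leg a thigh, shank and (lumped) foot
#' connected by hip, knee and ankle pin joints (9 DOF total). Each leg
#' carries 7 Hill-type muscles (gluteus maximus, iliopsoas, vasti, biceps
#' femoris short head, gastrocnemius, soleus, tibialis anterior). Each
#' foot has the three task contact spheres (one 50 mm heel, two 25 mm
#' toes) at the standard placements. Positive joint rotations are
#' counterclockwise about +Z in the sagittal (X-forward, Y-up) plane:
#' positive hip flexion, negative knee flexion, positive ankle
#' dorsiflexion.
#'
#' Segment masses/inertias and muscle strengths are approximate values for
#' the simplified lower-limb model family this model descends from; tendon
#' slack lengths are calibrated so the standing posture (all joint angles
#' zero, pelvis at 0.94 m) puts each fiber at its optimal length.
#'
#' @param variant `"stairs"` (trunk-pelvis angle -15 deg, all maximum
#'   isometric forces scaled by 1.8) or `"ramp"` (-5 deg, unscaled).
#' @param isometric_scale Override the variant's strength scaling.
#' @return A planar `model_spec`.
#' @export
planar_model <- function(variant = c("stairs", "ramp"),
                         isometric_scale = NULL) {
  variant <- match.arg(variant)
  trunk_angle <- if (variant == "stairs") -15 else -5
  scale <- if (is.null(isometric_scale)) {
    if (variant == "stairs") 1.8 else 1.0
  } else isometric_scale

  # lumped pelvis+trunk+head: trunk CoM tilted by the fixed trunk angle
  m_pelvis <- 11.8; m_trunk <- 34.2
  a <- trunk_angle * pi / 180
  trunk_com <- c(-sin(a) * 0.28, cos(a) * 0.28)
  com_lumped <- (m_pelvis * c(0, 0.03) + m_trunk * trunk_com) /
    (m_pelvis + m_trunk)
  bodies <- data.frame(
    name = c("pelvis", "thigh_r", "shank_r", "foot_r",
             "thigh_l", "shank_l", "foot_l"),
    mass = c(m_pelvis + m_trunk, 9.30, 3.71, 1.57, 9.30, 3.71, 1.57),
    inertia = c(2.80, 0.140, 0.057, 0.007, 0.140, 0.057, 0.007),
    com_x = c(com_lumped[1], 0, 0, 0.05, 0, 0, 0.05),
    com_y = c(com_lumped[2], -0.17, -0.19, -0.03, -0.17, -0.19, -0.03),
    length = c(0.40, 0.41, 0.43, 0.20, 0.41, 0.43, 0.20)
  )
  leg_joints <- function(s) {
    data.frame(
      name = paste0(c("hip_", "knee_", "ankle_"), s),
      type = "pin",
      parent = c("pelvis", paste0("thigh_", s), paste0("shank_", s)),
      child = paste0(c("thigh_", "shank_", "foot_"), s),
      px = c(0, 0, 0), py = c(-0.053, -0.41, -0.43),
      cx = c(0, 0, 0), cy = c(0, 0, 0),
      qmin = c(-0.60, -2.30, -0.90), qmax = c(2.10, 0.02, 0.90)
    )
  }
  joints <- rbind(
    data.frame(name = "pelvis", type = "planar", parent = "ground",
               child = "pelvis", px = 0, py = 0, cx = 0, cy = 0,
               qmin = NA_real_, qmax = NA_real_),
    leg_joints("r"), leg_joints("l")
  )

  tab <- planar_muscle_table()
  muscles <- list()
  for (s in c("r", "l")) {
    paths <- planar_muscle_paths(s)
    for (i in seq_len(nrow(tab))) {
      nm <- tab$muscle[i]
      muscles[[paste0(nm, "_", s)]] <- muscle_params(
        name = paste0(nm, "_", s),
        f_max = tab$f_max[i] * scale,
        l_opt = tab$l_opt[i],
        l_slack = 0.01,           # calibrated below
        v_max = 10,
        penn = tab$penn[i],
        path = paths[[nm]]
      )
    }
  }

  # foot contact spheres: task placements mapped into the lumped foot
  # frame (origin at the ankle) via the hindfoot/forefoot frame offsets
  sph <- NULL
  calcn <- c(-0.0488, -0.042)   # hindfoot frame origin in the foot frame
  toes <- calcn + c(0.1788, 0.0125)   # forefoot frame origin
  for (s in c("r", "l")) {
    fg <- foot_geometry(if (s == "r") "right" else "left")
    ft <- paste0("foot_", s)
    sph <- rbind(sph, data.frame(
      name = paste0(c("heel_", "toe1_", "toe2_"), s),
      body = ft,
      x = c(calcn[1] + fg$heel$center_offset[1],
            toes[1] + fg$toe1$center_offset[1],
            toes[1] + fg$toe2$center_offset[1]),
      y = c(calcn[2] + fg$heel$center_offset[2],
            toes[2] + fg$toe1$center_offset[2],
            toes[2] + fg$toe2$center_offset[2]),
      z = c(fg$heel$center_offset[3], fg$toe1$center_offset[3],
            fg$toe2$center_offset[3]),
      diameter = c(fg$heel$diameter, fg$toe1$diameter, fg$toe2$diameter),
      foot = ft
    ))
  }

  spec <- model_spec(
    name = paste0("planar_", variant), bodies = bodies, joints = joints,
    muscles = muscles, spheres = sph, trunk_pelvis_angle = trunk_angle,
    isometric_scale = scale, init_pelvis_height = 0.94
  )
  calibrate_slack_lengths(spec)
}

# Set each muscle's tendon slack length so that the standing posture puts
# the fiber at its optimal length: l_slack = L_standing - l_opt*cos(penn).
calibrate_slack_lengths <- function(spec) {
  cm <- compile_model(spec)
  q <- standing_q(spec)
  kin <- planar_fk(cm, q)
  for (i in seq_along(spec$muscles)) {
    m <- spec$muscles[[i]]
    L <- muscle_path_length(cm, kin, i)
    m$l_slack <- max(L - m$l_opt * cos(m$penn), 0.01)
    spec$muscles[[i]] <- m
  }
  spec
}

# Standing generalized coordinates: all joint angles zero, root vertical
# translation at the initial height.
standing_q <- function(spec) {
  cm <- if (inherits(spec, "compiled_model")) spec else compile_model(spec)
  q <- stats::setNames(numeric(cm$nq), cm$dof_names)
  q[cm$root[2]] <- cm$init_pelvis_height
  q
}

#' Full 3D model topology (configuration preset)
#'
#' The complete 14-DOF, 18-muscle lower-limb topology: seven bodies, a
#' 6-DOF pelvis, hip flexion plus ab/adduction, knee flexion and ankle
#' dorsiflexion per leg, and nine muscles per leg (gluteus maximus,
#' iliopsoas, vasti, biceps femoris short head, hamstrings, rectus
#' femoris, gastrocnemius, soleus, tibialis anterior). This specification
#' exists as a configuration object (for serialization and state-layout
#' accounting); forward simulation in this package is restricted to the
#' planar variant.
#'
#' @param variant `"stairs"` or `"ramp"` (trunk angle and strength scaling
#'   as in [planar_model()]).
#' @return A non-planar `model_spec`.
#' @export
full_model_spec <- function(variant = c("stairs", "ramp")) {
  variant <- match.arg(variant)
  trunk_angle <- if (variant == "stairs") -15 else -5
  scale <- if (variant == "stairs") 1.8 else 1.0
  bodies <- data.frame(
    name = c("pelvis", "thigh_r", "shank_r", "foot_r",
             "thigh_l", "shank_l", "foot_l"),
    mass = c(46.0, 9.30, 3.71, 1.57, 9.30, 3.71, 1.57),
    inertia = c(2.80, 0.140, 0.057, 0.007, 0.140, 0.057, 0.007),
    com_x = 0, com_y = c(0.2, -0.17, -0.19, -0.03, -0.17, -0.19, -0.03),
    length = c(0.40, 0.41, 0.43, 0.20, 0.41, 0.43, 0.20)
  )
  leg <- function(s) data.frame(
    name = c(paste0("hip_flexion_", s), paste0("hip_adduction_", s),
             paste0("knee_", s), paste0("ankle_", s)),
    type = c("pin", "pin", "pin", "pin"),
    parent = c("pelvis", "pelvis", paste0("thigh_", s), paste0("shank_", s)),
    child = c(paste0("thigh_", s), paste0("thigh_", s),
              paste0("shank_", s), paste0("foot_", s)),
    px = 0, py = c(-0.053, -0.053, -0.41, -0.43), cx = 0, cy = 0,
    qmin = c(-0.6, -0.5, -2.3, -0.9), qmax = c(2.1, 0.5, 0.02, 0.9)
  )
  joints <- rbind(
    data.frame(name = "pelvis", type = "free6", parent = "ground",
               child = "pelvis", px = 0, py = 0, cx = 0, cy = 0,
               qmin = NA_real_, qmax = NA_real_),
    leg("r"), leg("l")
  )
  nine <- c("glut_max", "iliopsoas", "vasti", "bifemsh", "hamstrings",
            "rect_fem", "gastroc", "soleus", "tib_ant")
  f_max <- c(1944, 2186, 5000, 804, 2594, 1169, 2500, 3549, 1759)
  l_opt <- c(0.16, 0.12, 0.09, 0.17, 0.109, 0.114, 0.06, 0.05, 0.098)
  muscles <- list()
  for (s in c("r", "l")) {
    for (i in seq_along(nine)) {
      muscles[[paste0(nine[i], "_", s)]] <- muscle_params(
        name = paste0(nine[i], "_", s), f_max = f_max[i] * scale,
        l_opt = l_opt[i], l_slack = 0.1)
    }
  }
  # note: duplicated `child` rows in `leg()` describe the 2-DOF hip; the
  # tree check applies to distinct joints, so collapse names first
  spec <- structure(list(
    name = paste0("full_", variant), bodies = bodies, joints = joints,
    muscles = muscles, spheres = NULL, gravity = 9.80665,
    trunk_pelvis_angle = trunk_angle, isometric_scale = scale,
    init_pelvis_height = 0.94, joint_damping = 0.1,
    limit_stiffness = 300, limit_damping = 2, planar = FALSE),
    class = "model_spec")
  spec
}

#' Load a task model preset
#'
#' `"stairs"`: planar model with trunk-pelvis angle -15 deg and all
#' maximum isometric forces scaled by 1.8. `"ramp"`: trunk-pelvis angle
#' -5 deg, default strength.
#'
#' @param preset `"stairs"` or `"ramp"`.
#' @return A planar `model_spec`.
#' @export
preset_model <- function(preset = c("stairs", "ramp")) {
  planar_model(match.arg(preset))
}

#' Serialize a model specification to YAML
#'
#' @param spec A `model_spec`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_yaml <- function(spec, path) {
  ser <- list(
    name = spec$name, planar = spec$planar, gravity = spec$gravity,
    trunk_pelvis_angle = spec$trunk_pelvis_angle,
    isometric_scale = spec$isometric_scale,
    init_pelvis_height = spec$init_pelvis_height,
    joint_damping = spec$joint_damping,
    limit_stiffness = spec$limit_stiffness,
    limit_damping = spec$limit_damping,
    bodies = lapply(seq_len(nrow(spec$bodies)), function(i)
      as.list(spec$bodies[i, ])),
    joints = lapply(seq_len(nrow(spec$joints)), function(i)
      as.list(spec$joints[i, ])),
    muscles = lapply(spec$muscles, function(m) {
      list(name = m$name, f_max = m$f_max, l_opt = m$l_opt,
           l_slack = m$l_slack, v_max = m$v_max, penn = m$penn,
           tau_act = m$tau_act, tau_deact = m$tau_deact,
           path = if (is.null(m$path)) NULL else
             lapply(seq_len(nrow(m$path)), function(i) as.list(m$path[i, ])))
    }),
    spheres = if (is.null(spec$spheres)) NULL else
      lapply(seq_len(nrow(spec$spheres)), function(i)
        as.list(spec$spheres[i, ]))
  )
  yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}

#' Read a model specification from YAML
#'
#' @param path YAML file written by [write_model_yaml()].
#' @return A `model_spec`.
#' @export
read_model_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  bodies <- do.call(rbind, lapply(y$bodies, as.data.frame))
  joints <- do.call(rbind, lapply(y$joints, function(j) {
    j$qmin <- if (is.null(j$qmin)) NA_real_ else j$qmin
    j$qmax <- if (is.null(j$qmax)) NA_real_ else j$qmax
    as.data.frame(j)
  }))
  muscles <- lapply(y$muscles, function(m) {
    muscle_params(name = m$name, f_max = m$f_max, l_opt = m$l_opt,
                  l_slack = m$l_slack, v_max = m$v_max, penn = m$penn,
                  tau_act = m$tau_act, tau_deact = m$tau_deact,
                  path = if (is.null(m$path)) NULL else
                    do.call(rbind, lapply(m$path, as.data.frame)))
  })
  names(muscles) <- vapply(muscles, function(m) m$name, "")
  spheres <- if (is.null(y$spheres)) NULL else
    do.call(rbind, lapply(y$spheres, as.data.frame))
  spec <- model_spec(name = y$name, bodies = bodies, joints = joints,
                     muscles = muscles, spheres = spheres,
                     gravity = y$gravity,
                     trunk_pelvis_angle = y$trunk_pelvis_angle,
                     isometric_scale = y$isometric_scale,
                     init_pelvis_height = y$init_pelvis_height,
                     joint_damping = y$joint_damping,
                     limit_stiffness = y$limit_stiffness,
                     limit_damping = y$limit_damping, planar = y$planar)
  spec
}
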