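# Planar articulated-body dynamics.
#
# Generalized coordinates: the root planar joint contributes (tx, ty, rot),
# every pin joint one angle. Forward kinematics, point Jacobians and the
# velocity-product (Coriolis) terms are evaluated analytically for the
# planar chain; the equations of motion are assembled as
#   M(q) qddot = Q_applied + Q_gravity - Q_bias
# and integrated with a semi-implicit (symplectic) Euler step.

#' Compile a model specification for simulation
#'
#' Precomputes index structures (kinematic chains, DOF maps, stacked
#' muscle path tables, contact-sphere vertex sets) so the simulation
#' loop runs on plain numeric arrays. Called automatically where needed;
#' call it once and reuse when stepping many times.
#'
#' @param spec A planar `model_spec`.
#' @return Object of class `compiled_model`.
#' @export
compile_model <- function(spec) {
  if (inherits(spec, "compiled_model")) return(spec)
  if (!spec$planar) {
    stop("forward simulation supports the planar model variant only; ",
         "'", spec$name, "' is a 3D configuration preset")
  }
  bodies <- spec$bodies; joints <- spec$joints
  nb <- nrow(bodies)
  bidx <- stats::setNames(seq_len(nb), bodies$name)

  dof_names <- character(0); dof_type <- character(0)
  parent <- integer(nb)
  anchor_p <- matrix(0, nb, 2); anchor_c <- matrix(0, nb, 2)
  dof_of_body <- vector("list", nb)
  qmin <- numeric(0); qmax <- numeric(0)
  for (i in seq_len(nrow(joints))) {
    j <- joints[i, ]
    b <- bidx[[j$child]]
    parent[b] <- if (j$parent == "ground") 0L else bidx[[j$parent]]
    anchor_p[b, ] <- c(j$px, j$py); anchor_c[b, ] <- c(j$cx, j$cy)
    if (j$type == "planar") {
      ids <- length(dof_names) + 1:3
      dof_names <- c(dof_names, paste0(j$name, c("_tx", "_ty", "_tilt")))
      dof_type <- c(dof_type, "tx", "ty", "rot")
      qmin <- c(qmin, -Inf, -Inf, if (is.na(j$qmin)) -Inf else j$qmin)
      qmax <- c(qmax, Inf, Inf, if (is.na(j$qmax)) Inf else j$qmax)
    } else if (j$type == "pin") {
      ids <- length(dof_names) + 1L
      dof_names <- c(dof_names, j$name)
      dof_type <- c(dof_type, "rot")
      qmin <- c(qmin, if (is.na(j$qmin)) -Inf else j$qmin)
      qmax <- c(qmax, if (is.na(j$qmax)) Inf else j$qmax)
    } else {
      stop("unsupported joint type for planar simulation: ", j$type)
    }
    dof_of_body[[b]] <- ids
  }
  nq <- length(dof_names)
  rot_dofs <- which(dof_type == "rot")
  rot_chain <- vector("list", nb)
  for (b in seq_len(nb)) {
    chain <- integer(0); cur <- b
    while (cur != 0L) {
      ids <- dof_of_body[[cur]]
      chain <- c(ids[dof_type[ids] == "rot"], chain)
      cur <- parent[cur]
    }
    rot_chain[[b]] <- chain
  }
  rot_body <- integer(nq)
  for (b in seq_len(nb)) {
    ids <- dof_of_body[[b]]
    rot_body[ids[dof_type[ids] == "rot"]] <- b
  }
  # bodies in the subtree moved by each rotational dof
  subtree <- vector("list", nq)
  for (k in rot_dofs) {
    subtree[[k]] <- which(vapply(rot_chain, function(ch) k %in% ch, TRUE))
  }
  root <- dof_of_body[[which(parent == 0L)]]

  # muscle tables, stacked over all path points
  nm <- length(spec$muscles)
  mus <- list(
    f_max = vapply(spec$muscles, function(m) m$f_max, 0),
    l_opt = vapply(spec$muscles, function(m) m$l_opt, 0),
    l_slack = vapply(spec$muscles, function(m) m$l_slack, 0),
    v_max = vapply(spec$muscles, function(m) m$v_max, 0),
    cospenn = vapply(spec$muscles, function(m) cos(m$penn), 0),
    tau_act = vapply(spec$muscles, function(m) m$tau_act, 0),
    tau_deact = vapply(spec$muscles, function(m) m$tau_deact, 0),
    names = unname(vapply(spec$muscles, function(m) m$name, ""))
  )
  pt_body <- integer(0); pt_local <- NULL; pt_mus <- integer(0)
  seg_a <- integer(0); seg_b <- integer(0); seg_mus <- integer(0)
  for (i in seq_len(nm)) {
    m <- spec$muscles[[i]]
    np <- nrow(m$path)
    base <- length(pt_body)
    pt_body <- c(pt_body, unname(bidx[m$path$body]))
    pt_local <- rbind(pt_local, cbind(m$path$x, m$path$y))
    pt_mus <- c(pt_mus, rep(i, np))
    seg_a <- c(seg_a, base + seq_len(np - 1))
    seg_b <- c(seg_b, base + 1 + seq_len(np - 1))
    seg_mus <- c(seg_mus, rep(i, np - 1))
  }
  # per rotational dof: stacked muscle points attached to its subtree
  pt_of_dof <- vector("list", nq)
  for (k in rot_dofs) {
    pt_of_dof[[k]] <- which(pt_body %in% subtree[[k]])
  }

  # contact spheres: local vertex clouds
  spheres <- list()
  if (!is.null(spec$spheres)) {
    for (i in seq_len(nrow(spec$spheres))) {
      sp <- spec$spheres[i, ]
      mesh <- build_contact_sphere(contact_sphere_spec(
        sp$diameter, c(sp$x, sp$y, sp$z)))
      spheres[[sp$name]] <- list(
        body = bidx[[sp$body]], foot = sp$foot,
        verts = mesh$vertices,
        area = sum_face_area(mesh) / nrow(mesh$vertices))
    }
  }
  feet <- unique(vapply(spheres, function(s) s$foot, ""))
  # group sphere vertices per body for a single terrain query per body
  body_sph <- vector("list", nb)
  for (b in seq_len(nb)) {
    idx <- which(vapply(spheres, function(s) s$body == b, TRUE))
    if (length(idx) > 0) {
      body_sph[[b]] <- list(
        verts = do.call(rbind, lapply(spheres[idx], function(s) s$verts)),
        area = rep(vapply(spheres[idx], function(s) s$area, 0),
                   vapply(spheres[idx], function(s) nrow(s$verts), 0L)),
        foot = spheres[[idx[1]]]$foot)
    }
  }

  structure(list(
    spec = spec, nb = nb, nq = nq, nm = nm,
    body_names = bodies$name, dof_names = dof_names, dof_type = dof_type,
    mass = bodies$mass, inertia = bodies$inertia,
    com = cbind(bodies$com_x, bodies$com_y),
    parent = parent, anchor_p = anchor_p, anchor_c = anchor_c,
    dof_of_body = dof_of_body, rot_chain = rot_chain, rot_body = rot_body,
    rot_dofs = rot_dofs, subtree = subtree, root = root,
    qmin = qmin, qmax = qmax,
    muscles = mus, pt_body = pt_body, pt_local = pt_local,
    pt_mus = pt_mus, seg_a = seg_a, seg_b = seg_b, seg_mus = seg_mus,
    pt_of_dof = pt_of_dof,
    spheres = spheres, body_sph = body_sph, feet = feet,
    gravity = spec$gravity, joint_damping = spec$joint_damping,
    limit_stiffness = spec$limit_stiffness,
    limit_damping = spec$limit_damping,
    init_pelvis_height = spec$init_pelvis_height
  ), class = "compiled_model")
}

rot2 <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
perp2 <- function(v) c(-v[2], v[1])

# Forward kinematics: body angles, frame origins (as scalars), cos/sin,
# and rotational-DOF pivots.
planar_fk <- function(cm, q) {
  nb <- cm$nb
  ang <- numeric(nb); ox <- numeric(nb); oy <- numeric(nb)
  ca <- numeric(nb); sa <- numeric(nb)
  pvx <- numeric(cm$nq); pvy <- numeric(cm$nq)
  for (b in seq_len(nb)) {
    ids <- cm$dof_of_body[[b]]
    p <- cm$parent[b]
    if (p == 0L) {
      ang[b] <- q[ids[3]]
      ca[b] <- cos(ang[b]); sa[b] <- sin(ang[b])
      px <- q[ids[1]]; py <- q[ids[2]]
      pvx[ids[3]] <- px; pvy[ids[3]] <- py
      acx <- cm$anchor_c[b, 1]; acy <- cm$anchor_c[b, 2]
      ox[b] <- px - (ca[b] * acx - sa[b] * acy)
      oy[b] <- py - (sa[b] * acx + ca[b] * acy)
    } else {
      ang[b] <- ang[p] + q[ids[1]]
      ca[b] <- cos(ang[b]); sa[b] <- sin(ang[b])
      apx <- cm$anchor_p[b, 1]; apy <- cm$anchor_p[b, 2]
      px <- ox[p] + ca[p] * apx - sa[p] * apy
      py <- oy[p] + sa[p] * apx + ca[p] * apy
      pvx[ids[1]] <- px; pvy[ids[1]] <- py
      acx <- cm$anchor_c[b, 1]; acy <- cm$anchor_c[b, 2]
      ox[b] <- px - (ca[b] * acx - sa[b] * acy)
      oy[b] <- py - (sa[b] * acx + ca[b] * acy)
    }
  }
  list(ang = ang, ox = ox, oy = oy, ca = ca, sa = sa,
       pvx = pvx, pvy = pvy,
       # matrix views kept for the point-based helpers
       orig = cbind(ox, oy), pivot = cbind(pvx, pvy))
}

# Velocities: body angular rates, origin velocities, pivot velocities.
planar_vel <- function(cm, kin, u) {
  nb <- cm$nb
  w <- numeric(nb); vx <- numeric(nb); vy <- numeric(nb)
  pvvx <- numeric(cm$nq); pvvy <- numeric(cm$nq)
  for (b in seq_len(nb)) {
    ids <- cm$dof_of_body[[b]]
    p <- cm$parent[b]
    if (p == 0L) {
      w[b] <- u[ids[3]]
      pvvx[ids[3]] <- u[ids[1]]; pvvy[ids[3]] <- u[ids[2]]
      rx <- kin$ox[b] - kin$pvx[ids[3]]; ry <- kin$oy[b] - kin$pvy[ids[3]]
      vx[b] <- u[ids[1]] - w[b] * ry
      vy[b] <- u[ids[2]] + w[b] * rx
    } else {
      w[b] <- w[p] + u[ids[1]]
      rx <- kin$pvx[ids[1]] - kin$ox[p]; ry <- kin$pvy[ids[1]] - kin$oy[p]
      pvvx[ids[1]] <- vx[p] - w[p] * ry
      pvvy[ids[1]] <- vy[p] + w[p] * rx
      rx <- kin$ox[b] - kin$pvx[ids[1]]; ry <- kin$oy[b] - kin$pvy[ids[1]]
      vx[b] <- pvvx[ids[1]] - w[b] * ry
      vy[b] <- pvvy[ids[1]] + w[b] * rx
    }
  }
  list(angvel = w, vx = vx, vy = vy, pvvx = pvvx, pvvy = pvvy,
       origvel = cbind(vx, vy), pivvel = cbind(pvvx, pvvy))
}

# World position / velocity of a body-local point (test/diagnostic path).
point_world <- function(cm, kin, b, local) {
  c(kin$ox[b] + kin$ca[b] * local[1] - kin$sa[b] * local[2],
    kin$oy[b] + kin$sa[b] * local[1] + kin$ca[b] * local[2])
}
point_vel <- function(cm, kin, vel, b, pw) {
  rx <- pw[1] - kin$ox[b]; ry <- pw[2] - kin$oy[b]
  c(vel$vx[b] - vel$angvel[b] * ry, vel$vy[b] + vel$angvel[b] * rx)
}

# 2 x nq Jacobian of a world point attached to body b.
point_jacobian <- function(cm, kin, b, pw) {
  J <- matrix(0, 2, cm$nq)
  J[1, cm$root[1]] <- 1; J[2, cm$root[2]] <- 1
  for (k in cm$rot_chain[[b]]) {
    J[1, k] <- -(pw[2] - kin$pvy[k])
    J[2, k] <- pw[1] - kin$pvx[k]
  }
  J
}

# Accumulate the generalized force of a world force f at world point pw on
# body b (test/diagnostic path; the step loop uses vectorized variants).
accumulate_point_force <- function(cm, kin, Q, b, pw, f) {
  Q[cm$root[1]] <- Q[cm$root[1]] + f[1]
  Q[cm$root[2]] <- Q[cm$root[2]] + f[2]
  for (k in cm$rot_chain[[b]]) {
    Q[k] <- Q[k] + (pw[1] - kin$pvx[k]) * f[2] - (pw[2] - kin$pvy[k]) * f[1]
  }
  Q
}

# Total path length of muscle i at the given kinematics.
muscle_path_length <- function(cm, kin, i) {
  sel <- which(cm$pt_mus == i)
  b <- cm$pt_body[sel]
  lx <- cm$pt_local[sel, 1]; ly <- cm$pt_local[sel, 2]
  px <- kin$ox[b] + kin$ca[b] * lx - kin$sa[b] * ly
  py <- kin$oy[b] + kin$sa[b] * lx + kin$ca[b] * ly
  sum(sqrt(diff(px)^2 + diff(py)^2))
}

#' Model state
#'
#' Generalized coordinates and speeds, per-muscle activations and the
#' simulation clock, plus cached per-step quantities (accelerations,
#' muscle forces, limit torques, ground reaction forces) filled in by
#' [forward_step()].
#'
#' @param model A `model_spec` or `compiled_model`.
#' @param q Named generalized coordinates (rad, m); defaults to the
#'   standing posture.
#' @param u Generalized speeds (rad/s, m/s); default zero.
#' @param act Per-muscle activations in `[0, 1]`; default zero.
#' @param t Simulation time (s).
#' @return Object of class `model_state`.
#' @export
model_state <- function(model, q = NULL, u = NULL, act = NULL, t = 0) {
  cm <- compile_model(model)
  if (is.null(q)) q <- standing_q(cm$spec)
  q <- as.numeric(q)
  if (length(q) != cm$nq) stop("q has wrong length")
  u <- if (is.null(u)) numeric(cm$nq) else as.numeric(u)
  act <- if (is.null(act)) numeric(cm$nm) else as.numeric(act)
  if (any(!is.finite(q)) || any(!is.finite(u))) {
    stop("model_state: non-finite coordinates")
  }
  if (any(act < 0 | act > 1)) stop("activations outside [0, 1]")
  names(q) <- cm$dof_names; names(u) <- cm$dof_names
  structure(list(
    q = q, u = u, act = act, t = t,
    udot = numeric(cm$nq),
    muscle_forces = stats::setNames(numeric(cm$nm), cm$muscles$names),
    limit_forces = numeric(cm$nq),
    body = NULL, grf = NULL,
    terminated = FALSE, reason = NULL
  ), class = "model_state")
}

#' Advance the model one physics step
#'
#' One semi-implicit (symplectic) Euler step: activations are advanced by
#' the exact first-order excitation-activation update; muscle, gravity,
#' joint-limit and elastic-foundation contact forces are mapped to
#' generalized forces through the point Jacobians; the generalized
#' accelerations solve `M(q) qddot = Q - Q_bias`; speeds are updated
#' first, then coordinates with the new speeds. Non-finite dynamics or a
#' fall (pelvis below 60% of its initial height) set the termination flag
#' rather than propagating NaNs.
#'
#' @param state A [model_state()].
#' @param excitations Per-muscle excitation in `[0, 1]`.
#' @param model A `model_spec` or `compiled_model`.
#' @param terrain A terrain `tri_mesh`, a [height_field()], or `NULL` for
#'   contact-free dynamics.
#' @param contact A [contact_params()].
#' @param dt Physics time step (s), > 0. Default 0.002 s.
#' @return The next `model_state`, with cached accelerations, muscle
#'   forces, limit torques and per-foot ground reactions; `terminated`
#'   and `reason` are set on fall, divergence, or on leaving the terrain
#'   footprint.
#' @export
forward_step <- function(state, excitations, model, terrain = NULL,
                         contact = contact_params(), dt = 0.002) {
  if (dt <= 0) stop("dt must be > 0")
  cm <- compile_model(model)
  if (length(excitations) != cm$nm) stop("excitations: wrong length")
  if (any(!is.finite(excitations))) stop("non-finite excitations")
  excitations <- pmin(pmax(excitations, 0), 1)
  if (state$terminated) return(state)
  q <- as.numeric(state$q); u <- as.numeric(state$u)
  hf <- if (is.null(terrain)) NULL else if (inherits(terrain, "height_field"))
    terrain else height_field(terrain)
  root <- cm$root
  nq <- cm$nq; nb <- cm$nb

  act <- act_step_vec(excitations, state$act, dt,
                      cm$muscles$tau_act, cm$muscles$tau_deact)

  kin <- planar_fk(cm, q)
  vel <- planar_vel(cm, kin, u)
  Q <- numeric(nq)

  # centers of mass (world) and their velocities
  cx <- kin$ox + kin$ca * cm$com[, 1] - kin$sa * cm$com[, 2]
  cy <- kin$oy + kin$sa * cm$com[, 1] + kin$ca * cm$com[, 2]
  cvx <- vel$vx - vel$angvel * (cy - kin$oy)
  cvy <- vel$vy + vel$angvel * (cx - kin$ox)

  # gravity
  g <- cm$gravity
  Q[root[2]] <- Q[root[2]] - g * sum(cm$mass)
  for (k in cm$rot_dofs) {
    sb <- cm$subtree[[k]]
    Q[k] <- Q[k] - g * sum(cm$mass[sb] * (cx[sb] - kin$pvx[k]))
  }

  # velocity-dependent force slopes are treated backward-Euler through
  # the damping matrix D: (M + dt D) u' = M u + dt (Q - Qbias) + dt Dm u
  D <- matrix(0, nq, nq)
  Dm_u_extra <- numeric(nq)

  # muscles: stacked path points, rigid-tendon Hill forces
  mforce <- numeric(cm$nm)
  if (cm$nm > 0) {
    pb <- cm$pt_body
    plx <- cm$pt_local[, 1]; ply <- cm$pt_local[, 2]
    px <- kin$ox[pb] + kin$ca[pb] * plx - kin$sa[pb] * ply
    py <- kin$oy[pb] + kin$sa[pb] * plx + kin$ca[pb] * ply
    pvx_ <- vel$vx[pb] - vel$angvel[pb] * (py - kin$oy[pb])
    pvy_ <- vel$vy[pb] + vel$angvel[pb] * (px - kin$ox[pb])
    dx <- px[cm$seg_b] - px[cm$seg_a]
    dy <- py[cm$seg_b] - py[cm$seg_a]
    lens <- sqrt(dx^2 + dy^2)
    ux <- dx / lens; uy <- dy / lens
    ldot_seg <- ux * (pvx_[cm$seg_b] - pvx_[cm$seg_a]) +
      uy * (pvy_[cm$seg_b] - pvy_[cm$seg_a])
    L <- as.numeric(rowsum(lens, cm$seg_mus))
    Ldot <- as.numeric(rowsum(ldot_seg, cm$seg_mus))
    cp <- cm$muscles$cospenn
    fib_len <- pmax((L - cm$muscles$l_slack) / cp,
                    0.01 * cm$muscles$l_opt)
    lnorm <- fib_len / cm$muscles$l_opt
    vnorm <- (Ldot / cp) / (cm$muscles$v_max * cm$muscles$l_opt)
    mforce <- muscle_force_vec(cm$muscles$f_max, cm$muscles$l_opt,
                               cm$muscles$v_max, cp, act, lnorm, vnorm)
    # unit-tension point forces: each segment pulls its endpoints together
    npts <- length(pb)
    fxu <- numeric(npts); fyu <- numeric(npts)
    for (s in seq_along(cm$seg_a)) {
      a <- cm$seg_a[s]; b2 <- cm$seg_b[s]
      fxu[a] <- fxu[a] + ux[s]; fyu[a] <- fyu[a] + uy[s]
      fxu[b2] <- fxu[b2] - ux[s]; fyu[b2] <- fyu[b2] - uy[s]
    }
    # generalized direction of unit tension, per muscle (nm x nq)
    G <- matrix(0, cm$nm, nq)
    G[, root[1]] <- as.numeric(rowsum(fxu, cm$pt_mus))
    G[, root[2]] <- as.numeric(rowsum(fyu, cm$pt_mus))
    for (k in cm$rot_dofs) {
      sel <- cm$pt_of_dof[[k]]
      if (length(sel) > 0) {
        contrib <- (px[sel] - kin$pvx[k]) * fyu[sel] -
          (py[sel] - kin$pvy[k]) * fxu[sel]
        gs <- rowsum(contrib, cm$pt_mus[sel])
        G[as.integer(rownames(gs)), k] <- as.numeric(gs)
      }
    }
    Q <- Q + as.numeric(crossprod(G, mforce))
    # force-velocity slope (implicit): dF/dLdot, always dissipative
    fl <- exp(-((lnorm - 1)^2) / 0.45)
    dfv <- ifelse(vnorm < 0, 5 / (1 - vnorm / 0.25)^2,
                  0.104 / (vnorm + 0.13)^2)
    dfv[vnorm < -1] <- 0
    s_m <- cm$muscles$f_max * act * fl * dfv /
      (cm$muscles$v_max * cm$muscles$l_opt)
    Dm <- crossprod(G * sqrt(s_m))
    D <- D + Dm
    Dm_u_extra <- as.numeric(Dm %*% u)
  }

  # soft joint limits + passive pin-joint damping
  limf <- numeric(nq)
  for (k in cm$rot_dofs) {
    if (k == root[3]) next
    tau <- -cm$joint_damping * u[k]
    if (q[k] > cm$qmax[k]) {
      lt <- -cm$limit_stiffness * (q[k] - cm$qmax[k]) - cm$limit_damping * u[k]
      tau <- tau + lt; limf[k] <- lt
    } else if (q[k] < cm$qmin[k]) {
      lt <- -cm$limit_stiffness * (q[k] - cm$qmin[k]) - cm$limit_damping * u[k]
      tau <- tau + lt; limf[k] <- lt
    }
    Q[k] <- Q[k] + tau
  }

  # elastic-foundation contact at the foot spheres (one query per body)
  grf <- stats::setNames(vector("list", length(cm$feet)), cm$feet)
  for (ft in cm$feet) {
    grf[[ft]] <- list(force = c(0, 0, 0), cop = c(NA_real_, NA_real_),
                      n_points = 0L)
  }
  if (!is.null(hf)) {
    for (b in seq_len(nb)) {
      bs <- cm$body_sph[[b]]
      if (is.null(bs)) next
      lx <- bs$verts[, 1]; ly <- bs$verts[, 2]
      Pw <- cbind(kin$ox[b] + kin$ca[b] * lx - kin$sa[b] * ly,
                  kin$oy[b] + kin$sa[b] * lx + kin$ca[b] * ly,
                  bs$verts[, 3])
      qh <- hf_query(hf, Pw)
      hit <- which(qh$face > 0L & Pw[, 2] < qh$ysurf)
      if (length(hit) == 0) next
      fidx <- qh$face[hit]
      n <- hf$n[fidx, , drop = FALSE]
      dp <- Pw[hit, , drop = FALSE] - hf$v0[fidx, , drop = FALSE]
      depth <- -rowSums(dp * n)
      keep <- depth > 0
      if (!any(keep)) next
      hit <- hit[keep]; n <- n[keep, , drop = FALSE]; depth <- depth[keep]
      pxh <- Pw[hit, 1]; pyh <- Pw[hit, 2]
      vhx <- vel$vx[b] - vel$angvel[b] * (pyh - kin$oy[b])
      vhy <- vel$vy[b] + vel$angvel[b] * (pxh - kin$ox[b])
      # planar projection of the face normal
      n2x <- n[, 1]; n2y <- n[, 2]
      nn <- sqrt(n2x^2 + n2y^2)
      n2x <- n2x / nn; n2y <- n2y / nn
      t2x <- -n2y; t2y <- n2x
      vn <- vhx * n2x + vhy * n2y
      vt <- vhx * t2x + vhy * t2y
      area <- bs$area[hit]
      # explicit elastic pressure; normal dissipation (slope c*k*x*A) and
      # low-slip friction handled implicitly via D
      f_el <- contact$stiffness * depth * area
      b_n <- contact$dissipation * f_el
      vrel <- abs(vt) / contact$transition_velocity
      fast <- vrel > 1.5
      # fast slip: bounded explicit Coulomb + viscous force
      fT_fast <- ifelse(fast,
                        -(contact$mu_dynamic +
                            contact$mu_viscous * vrel) * f_el * sign(vt),
                        0)
      # slow slip: implicit linear friction with the static-peak slope
      s_t <- ifelse(fast, 0,
                    (contact$mu_static + contact$mu_viscous) * f_el /
                      contact$transition_velocity)
      fx_ex <- f_el * n2x + fT_fast * t2x
      fy_ex <- f_el * n2y + fT_fast * t2y
      Q[root[1]] <- Q[root[1]] + sum(fx_ex)
      Q[root[2]] <- Q[root[2]] + sum(fy_ex)
      for (k in cm$rot_chain[[b]]) {
        Q[k] <- Q[k] + sum((pxh - kin$pvx[k]) * fy_ex -
                             (pyh - kin$pvy[k]) * fx_ex)
      }
      # damping-matrix assembly: rows of the point Jacobians projected on
      # the normal and tangent directions
      np_ <- length(hit)
      Jx <- matrix(0, np_, nq); Jy <- matrix(0, np_, nq)
      Jx[, root[1]] <- 1; Jy[, root[2]] <- 1
      for (k in cm$rot_chain[[b]]) {
        Jx[, k] <- -(pyh - kin$pvy[k])
        Jy[, k] <- pxh - kin$pvx[k]
      }
      Jn <- n2x * Jx + n2y * Jy
      Jt <- t2x * Jx + t2y * Jy
      D <- D + crossprod(Jn * sqrt(b_n)) + crossprod(Jt * sqrt(s_t))
      # logged reaction: elastic + clamped dissipation at current speed
      fac <- pmin(pmax(1 - contact$dissipation * vn, 0), 2)
      fn_log <- f_el * fac
      ft_log <- fT_fast - (!fast) * pmin(s_t * abs(vt),
                                         contact$mu_static * fn_log) * sign(vt)
      g_ <- grf[[bs$foot]]
      g_$force <- g_$force + c(sum(fn_log * n2x + ft_log * t2x),
                               sum(fn_log * n2y + ft_log * t2y), 0)
      g_$n_points <- g_$n_points + length(hit)
      tot_fn <- sum(fn_log)
      if (tot_fn > 0) {
        g_$cop <- c(sum(fn_log * pxh), sum(fn_log * pyh)) / tot_fn
      }
      grf[[bs$foot]] <- g_
    }
  }

  # mass matrix and velocity-product bias
  M <- matrix(0, nq, nq)
  Qbias <- numeric(nq)
  M[root[1], root[1]] <- sum(cm$mass)
  M[root[2], root[2]] <- sum(cm$mass)
  for (b in seq_len(nb)) {
    m <- cm$mass[b]; Ib <- cm$inertia[b]
    ch <- cm$rot_chain[[b]]
    # translation-rotation coupling and rotation-rotation blocks
    for (ii in seq_along(ch)) {
      k <- ch[ii]
      rkx <- cx[b] - kin$pvx[k]; rky <- cy[b] - kin$pvy[k]
      M[root[1], k] <- M[root[1], k] - m * rky
      M[root[2], k] <- M[root[2], k] + m * rkx
      for (jj in ii:length(ch)) {
        l <- ch[jj]
        rlx <- cx[b] - kin$pvx[l]; rly <- cy[b] - kin$pvy[l]
        M[k, l] <- M[k, l] + m * (rkx * rlx + rky * rly) + Ib
      }
    }
    # bias acceleration of the CoM with qddot = 0
    if (any(u[ch] != 0) || vel$angvel[b] != 0) {
      a0x <- 0; a0y <- 0
      for (k in ch) {
        dvx <- cvx[b] - vel$pvvx[k]; dvy <- cvy[b] - vel$pvvy[k]
        a0x <- a0x - u[k] * dvy
        a0y <- a0y + u[k] * dvx
      }
      Qbias[root[1]] <- Qbias[root[1]] + m * a0x
      Qbias[root[2]] <- Qbias[root[2]] + m * a0y
      for (k in ch) {
        Qbias[k] <- Qbias[k] + m * (-(cy[b] - kin$pvy[k]) * a0x +
                                      (cx[b] - kin$pvx[k]) * a0y)
      }
    }
  }
  # symmetrize
  M[lower.tri(M)] <- t(M)[lower.tri(M)]

  # backward-Euler treatment of the velocity-dependent force slopes:
  #   (M + dt D) u' = M u + dt (Q - Qbias) + dt Dm u
  LHS <- M + dt * D
  RHS <- as.numeric(M %*% u) + dt * (Q - Qbias + Dm_u_extra)
  u_new <- tryCatch(solve(LHS, RHS), error = function(e) rep(NaN, nq))
  if (any(!is.finite(u_new))) {
    state$terminated <- TRUE; state$reason <- "divergence"
    return(state)
  }
  qdd <- (u_new - u) / dt
  q_new <- q + dt * u_new
  if (any(!is.finite(q_new)) || any(abs(u_new) > 1e4)) {
    state$terminated <- TRUE; state$reason <- "divergence"
    return(state)
  }

  # cached body kinematics for the observation vector
  kin2 <- planar_fk(cm, q_new)
  vel2 <- planar_vel(cm, kin2, u_new)
  c2x <- kin2$ox + kin2$ca * cm$com[, 1] - kin2$sa * cm$com[, 2]
  c2y <- kin2$oy + kin2$sa * cm$com[, 1] + kin2$ca * cm$com[, 2]
  body_pos <- cbind(c2x, c2y)
  body_vel <- cbind(vel2$vx - vel2$angvel * (c2y - kin2$oy),
                    vel2$vy + vel2$angvel * (c2x - kin2$ox))
  body_acc <- matrix(0, nb, 2)
  ang_acc <- numeric(nb)
  for (b in seq_len(nb)) {
    ch <- cm$rot_chain[[b]]
    a0x <- 0; a0y <- 0
    for (k in ch) {
      dvx <- cvx[b] - vel$pvvx[k]; dvy <- cvy[b] - vel$pvvy[k]
      a0x <- a0x - u[k] * dvy; a0y <- a0y + u[k] * dvx
    }
    ax <- qdd[root[1]] + a0x
    ay <- qdd[root[2]] + a0y
    for (k in ch) {
      ax <- ax - (cy[b] - kin$pvy[k]) * qdd[k]
      ay <- ay + (cx[b] - kin$pvx[k]) * qdd[k]
    }
    body_acc[b, ] <- c(ax, ay)
    ang_acc[b] <- sum(qdd[ch])
  }

  st <- state
  st$q <- stats::setNames(q_new, cm$dof_names)
  st$u <- stats::setNames(u_new, cm$dof_names)
  st$act <- act
  st$t <- state$t + dt
  st$udot <- qdd
  st$muscle_forces <- stats::setNames(mforce, cm$muscles$names)
  st$limit_forces <- limf
  st$body <- list(pos = body_pos, ang = kin2$ang, vel = body_vel,
                  angvel = vel2$angvel, acc = body_acc, angacc = ang_acc)
  st$grf <- grf

  pelvis_ty <- q_new[root[2]]
  if (pelvis_ty < 0.6 * cm$init_pelvis_height) {
    st$terminated <- TRUE; st$reason <- "fall"
  } else if (!is.null(hf)) {
    px_ <- q_new[root[1]]
    if (px_ < hf$xrange[1] - 0.3 || px_ > hf$xrange[2] + 0.3) {
      st$terminated <- TRUE; st$reason <- "left_terrain"
    }
  }
  st
}

#' State-vector layout
#'
#' The observation vector is the concatenation, in a fixed documented
#' order, of: segment positions and rotations, linear and rotational
#' velocities, linear and rotational accelerations, joint positions,
#' velocities and accelerations, muscle forces, and joint-limit forces.
#' `default_layout()` derives the component sizes from a model;
#' `paper_state_layout()` is the 214-entry layout of the full 3D model
#' (13+13 segment positions/rotations, 13+13 velocities, 13+13
#' accelerations, 17+17+17 joint series, 72 muscle entries, 13
#' miscellaneous limit forces), kept as configuration.
#'
#' @param model A `model_spec` or `compiled_model`.
#' @return Named integer vector of component sizes.
#' @export
default_layout <- function(model) {
  cm <- compile_model(model)
  c(seg_pos = 2L * cm$nb, seg_rot = cm$nb,
    seg_linvel = 2L * cm$nb, seg_rotvel = cm$nb,
    seg_linacc = 2L * cm$nb, seg_rotacc = cm$nb,
    joint_pos = cm$nq, joint_vel = cm$nq, joint_acc = cm$nq,
    muscle_force = cm$nm, limit_force = cm$nq)
}

#' @rdname default_layout
#' @export
paper_state_layout <- function() {
  c(seg_pos = 13L, seg_rot = 13L, seg_linvel = 13L, seg_rotvel = 13L,
    seg_linacc = 13L, seg_rotacc = 13L, joint_pos = 17L, joint_vel = 17L,
    joint_acc = 17L, muscle_force = 72L, limit_force = 13L)
}

#' @rdname default_layout
#' @param layout A named layout vector.
#' @return `layout_size()`: total state-vector length.
#' @export
layout_size <- function(layout) sum(layout)

#' Build the observation vector
#'
#' Flattens the model state into the numeric vector consumed by the
#' policy network, following the component order of [default_layout()].
#' The layout must match the model: each declared component size is
#' checked against the model-derived size and a mismatch is rejected
#' naming the offending component.
#'
#' @param state A [model_state()] (a fresh static state reports zero
#'   velocities and accelerations).
#' @param model A `model_spec` or `compiled_model`.
#' @param layout Component-size vector; defaults to the model's layout.
#' @return Numeric vector of length `layout_size(layout)`.
#' @export
observation <- function(state, model, layout = NULL) {
  cm <- compile_model(model)
  expected <- default_layout(cm)
  if (is.null(layout)) layout <- expected
  for (comp in names(layout)) {
    if (!comp %in% names(expected)) {
      stop("observation: unknown layout component '", comp, "'")
    }
    if (layout[[comp]] != expected[[comp]]) {
      stop("observation: layout/model mismatch for component '", comp,
           "' (layout ", layout[[comp]], ", model ", expected[[comp]], ")")
    }
  }
  if (is.null(state$body)) {
    kin <- planar_fk(cm, as.numeric(state$q))
    vel <- planar_vel(cm, kin, as.numeric(state$u))
    cx <- kin$ox + kin$ca * cm$com[, 1] - kin$sa * cm$com[, 2]
    cy <- kin$oy + kin$sa * cm$com[, 1] + kin$ca * cm$com[, 2]
    body <- list(pos = cbind(cx, cy), ang = kin$ang,
                 vel = cbind(vel$vx - vel$angvel * (cy - kin$oy),
                             vel$vy + vel$angvel * (cx - kin$ox)),
                 angvel = vel$angvel,
                 acc = matrix(0, cm$nb, 2), angacc = numeric(cm$nb))
  } else {
    body <- state$body
  }
  c(as.numeric(t(body$pos)), body$ang,
    as.numeric(t(body$vel)), body$angvel,
    as.numeric(t(body$acc)), body$angacc,
    as.numeric(state$q), as.numeric(state$u), as.numeric(state$udot),
    as.numeric(state$muscle_forces), as.numeric(state$limit_forces))
}
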