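#' Elastic-foundation contact coefficients
#'
#' Parameters of the elastic-foundation contact model between the foot
#' spheres and the terrain: a bed of independent springs whose pressure is
#' proportional to local penetration depth, a multiplicative
#' velocity-dependent dissipation factor, and a blended
#' static/dynamic/viscous friction law. Defaults are the foot-ground
#' coefficients used for the stair/ramp tasks: stiffness 50 MPa/m,
#' dissipation 5 s/m, all three friction coefficients 0.9, and a friction
#' transition velocity of 0.1 m/s.
#'
#' @param stiffness Pressure per unit penetration (Pa/m), > 0. The default
#'   5e7 Pa/m corresponds to the tabulated 50 MPa/m.
#' @param dissipation Dissipation coefficient (s/m), >= 0.
#' @param mu_static,mu_dynamic,mu_viscous Friction coefficients, >= 0.
#' @param transition_velocity Slip speed (m/s) at which friction
#'   transitions from the static peak toward the dynamic value, > 0.
#' @return Object of class `contact_params`.
#' @export
contact_params <- function(stiffness = 50e6, dissipation = 5,
                           mu_static = 0.9, mu_dynamic = 0.9,
                           mu_viscous = 0.9, transition_velocity = 0.1) {
  stopifnot(stiffness > 0, dissipation >= 0, mu_static >= 0,
            mu_dynamic >= 0, mu_viscous >= 0, transition_velocity > 0)
  structure(list(stiffness = stiffness, dissipation = dissipation,
                 mu_static = mu_static, mu_dynamic = mu_dynamic,
                 mu_viscous = mu_viscous,
                 transition_velocity = transition_velocity),
            class = "contact_params")
}

#' Precompute a height-field view of a terrain mesh
#'
#' Contact queries treat the terrain as a triangulated height field: only
#' upward-facing faces (unit normal with a Y component above `min_ny`)
#' support the foot, and a query point is matched to the face whose XZ
#' projection contains it. Vertical risers and side walls never carry
#' load. The input mesh must be watertight.
#'
#' @param terrain A watertight `tri_mesh`.
#' @param min_ny Minimum upward normal component for a face to count as
#'   supporting surface.
#' @return Object of class `height_field` used by [detect_contacts()].
#' @export
height_field <- function(terrain, min_ny = 0.1) {
  rep <- validate_mesh(terrain)
  if (!rep$watertight) stop("terrain mesh is not watertight")
  v <- terrain$vertices; f <- terrain$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- cc - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- n / sqrt(rowSums(n^2))
  up <- which(n[, 2] > min_ny)
  det <- e1[up, 1] * e2[up, 3] - e2[up, 1] * e1[up, 3]
  good <- abs(det) > 1e-12
  up <- up[good]; det <- det[good]
  structure(list(
    v0 = a[up, , drop = FALSE],
    e1 = e1[up, , drop = FALSE], e2 = e2[up, , drop = FALSE],
    n = n[up, , drop = FALSE], det = det,
    xrange = range(v[, 1]), zrange = range(v[, 3])
  ), class = "height_field")
}

# For query points (rows of p, world coords), return the supporting face
# index (0 = none), the surface height above each point's (x, z), and the
# face normal. Where several faces cover (x, z), the highest is taken.
hf_query <- function(hf, p) {
  np <- nrow(p); nf <- nrow(hf$v0)
  face <- integer(np); ysurf <- rep(-Inf, np)
  tol <- 1e-9
  dx <- outer(p[, 1], hf$v0[, 1], `-`)       # np x nf
  dz <- outer(p[, 3], hf$v0[, 3], `-`)
  wa <- (dx * matrix(hf$e2[, 3], np, nf, byrow = TRUE) -
           dz * matrix(hf$e2[, 1], np, nf, byrow = TRUE)) /
    matrix(hf$det, np, nf, byrow = TRUE)
  wb <- (dz * matrix(hf$e1[, 1], np, nf, byrow = TRUE) -
           dx * matrix(hf$e1[, 3], np, nf, byrow = TRUE)) /
    matrix(hf$det, np, nf, byrow = TRUE)
  inside <- wa >= -tol & wb >= -tol & (wa + wb) <= 1 + tol
  ys <- matrix(hf$v0[, 2], np, nf, byrow = TRUE) +
    wa * matrix(hf$e1[, 2], np, nf, byrow = TRUE) +
    wb * matrix(hf$e2[, 2], np, nf, byrow = TRUE)
  ys[!inside] <- -Inf
  face <- max.col(ys, ties.method = "first")
  ysurf <- ys[cbind(seq_len(np), face)]
  face[!is.finite(ysurf)] <- 0L
  list(face = face, ysurf = ysurf)
}

#' Detect elastic-foundation contact points
#'
#' One contact candidate per sphere vertex that penetrates the terrain.
#' Depth is measured along the local terrain face normal, the tributary
#' area of each vertex is the sphere surface area divided by the vertex
#' count, and slip velocity is the tangential part of the vertex velocity.
#'
#' @param sphere A placed (world-coordinates) sphere `tri_mesh`.
#' @param terrain A watertight terrain `tri_mesh`, or a precomputed
#'   [height_field()] (used by the simulation loop to avoid re-validation).
#' @param velocities Optional `n x 3` matrix of vertex velocities (m/s);
#'   zero if omitted.
#' @return A data frame with one row per penetrating vertex: position
#'   (`x`, `y`, `z`), face normal (`nx`, `ny`, `nz`), `depth` (m),
#'   `depth_rate` (m/s, positive while penetrating deeper), `area` (m^2),
#'   and slip velocity (`svx`, `svy`, `svz`).
#' @export
detect_contacts <- function(sphere, terrain, velocities = NULL) {
  hf <- if (inherits(terrain, "height_field")) terrain else
    height_field(terrain)
  p <- sphere$vertices
  if (is.null(velocities)) velocities <- matrix(0, nrow(p), 3)
  # tributary area: total sphere surface area / vertex count
  rep_area <- sum_face_area(sphere) / nrow(p)
  q <- hf_query(hf, p)
  hit <- which(q$face > 0L & p[, 2] < q$ysurf)
  out <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                    nx = numeric(0), ny = numeric(0), nz = numeric(0),
                    depth = numeric(0), depth_rate = numeric(0),
                    area = numeric(0), svx = numeric(0), svy = numeric(0),
                    svz = numeric(0))
  if (length(hit) == 0) return(out)
  fidx <- q$face[hit]
  n <- hf$n[fidx, , drop = FALSE]
  dp <- p[hit, , drop = FALSE] - hf$v0[fidx, , drop = FALSE]
  depth <- -(rowSums(dp * n))
  keep <- depth > 0
  hit <- hit[keep]; n <- n[keep, , drop = FALSE]; depth <- depth[keep]
  if (length(hit) == 0) return(out)
  vel <- velocities[hit, , drop = FALSE]
  vn <- rowSums(vel * n)
  depth_rate <- -vn
  slip <- vel - n * vn
  data.frame(x = p[hit, 1], y = p[hit, 2], z = p[hit, 3],
             nx = n[, 1], ny = n[, 2], nz = n[, 3],
             depth = depth, depth_rate = depth_rate,
             area = rep_area,
             svx = slip[, 1], svy = slip[, 2], svz = slip[, 3])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

sum_face_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Elastic-foundation normal pressure
#'
#' The standard elastic-foundation law with multiplicative (Hunt-Crossley
#' style) dissipation, `p = k * x * (1 + c * xdot)`, clamped at zero so
#' the foundation never pulls. Per-point normal force is pressure times
#' the tributary area.
#'
#' @param depth Penetration depth (m), >= 0.
#' @param depth_rate Penetration rate (m/s), positive while deepening.
#' @param params A [contact_params()].
#' @return Pressure (Pa), >= 0.
#' @export
normal_pressure <- function(depth, depth_rate, params) {
  if (any(depth < 0)) stop("depth must be >= 0")
  pmax(params$stiffness * depth * (1 + params$dissipation * depth_rate), 0)
}

#' Blended friction force
#'
#' Stribeck-style blend from the static peak to the dynamic coefficient
#' across the transition velocity, plus a viscous term proportional to the
#' normalized slip speed. With `vrel = |v| / transition_velocity` the
#' effective coefficient is
#' `min(vrel, 1) * (mu_d + 2 (mu_s - mu_d) / (1 + vrel^2)) + mu_v * vrel`,
#' which vanishes at zero slip (continuity at rest), peaks at `mu_s` at the
#' transition velocity, and tends to the dynamic coefficient (plus the
#' viscous term) at high slip speed. The force opposes the slip direction.
#'
#' @param normal_force Normal force magnitude (N), >= 0.
#' @param slip_velocity Length-3 (or length-2) slip velocity vector (m/s).
#' @param params A [contact_params()].
#' @return Tangential force vector (N), same length as `slip_velocity`.
#' @export
friction_force <- function(normal_force, slip_velocity, params) {
  if (normal_force < 0) stop("normal_force must be >= 0")
  v <- sqrt(sum(slip_velocity^2))
  if (v == 0 || normal_force == 0) return(slip_velocity * 0)
  vrel <- v / params$transition_velocity
  mu <- min(vrel, 1) * (params$mu_dynamic +
                          2 * (params$mu_static - params$mu_dynamic) /
                          (1 + vrel^2)) +
    params$mu_viscous * vrel
  -mu * normal_force * slip_velocity / v
}

# Vectorized friction used in the simulation loop: N (n), slip (n x 3).
friction_force_vec <- function(N, slip, params) {
  v <- sqrt(rowSums(slip^2))
  vrel <- v / params$transition_velocity
  mu <- pmin(vrel, 1) * (params$mu_dynamic +
                           2 * (params$mu_static - params$mu_dynamic) /
                           (1 + vrel^2)) +
    params$mu_viscous * vrel
  scale <- ifelse(v > 0, mu * N / v, 0)
  -slip * scale
}

#' Resultant ground reaction force and center of pressure
#'
#' Sums per-point contact forces and locates the center of pressure (zero
#' moment point): the normal-force-weighted mean of the contact positions,
#' about which the net moment of the normal forces vanishes.
#'
#' @param points A contact data frame as returned by [detect_contacts()],
#'   with per-point forces attached in columns `fx`, `fy`, `fz` and normal
#'   force magnitudes in `fn`.
#' @return List with `force` (length-3 total force vector, N), `cop`
#'   (length-3 center of pressure, m; `NA` and `defined = FALSE` when
#'   there is no contact), and `defined`.
#' @export
resultant_grf <- function(points) {
  if (is.null(points) || nrow(points) == 0 || sum(points$fn) <= 0) {
    return(list(force = c(0, 0, 0), cop = c(NA_real_, NA_real_, NA_real_),
                defined = FALSE))
  }
  force <- c(sum(points$fx), sum(points$fy), sum(points$fz))
  w <- points$fn / sum(points$fn)
  cop <- c(sum(w * points$x), sum(w * points$y), sum(w * points$z))
  list(force = force, cop = cop, defined = TRUE)
}

#' Evaluate per-point contact forces
#'
#' Applies the elastic-foundation pressure law and the friction blend to
#' a set of detected contact points, attaching `pressure`, the normal
#' force magnitude `fn`, and the total per-point force components
#' `fx`, `fy`, `fz` — the form [resultant_grf()] consumes.
#'
#' @param points Contact points from [detect_contacts()].
#' @param params A [contact_params()].
#' @return The input data frame with force columns added.
#' @export
contact_forces <- function(points, params) {
  if (nrow(points) == 0) {
    points$pressure <- numeric(0); points$fn <- numeric(0)
    points$fx <- numeric(0); points$fy <- numeric(0); points$fz <- numeric(0)
    return(points)
  }
  pres <- normal_pressure(points$depth, points$depth_rate, params)
  fn <- pres * points$area
  nvec <- cbind(points$nx, points$ny, points$nz)
  fN <- nvec * fn
  fT <- friction_force_vec(fn, cbind(points$svx, points$svy, points$svz),
                           params)
  points$pressure <- pres
  points$fn <- fn
  points$fx <- fN[, 1] + fT[, 1]
  points$fy <- fN[, 2] + fT[, 2]
  points$fz <- fN[, 3] + fT[, 3]
  points
}
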