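test_that("contact detection: clearance, nadir depth, tributary area", {
  slab <- build_slab(-1, 1, 0.2, 1)
  sphere <- build_contact_sphere(contact_sphere_spec(0.05))
  # wholly above the terrain: no contacts
  up <- sphere; up$vertices[, 2] <- up$vertices[, 2] + 0.5
  expect_equal(nrow(detect_contacts(up, slab)), 0)
  # lowered by delta: nadir vertex depth equals delta
  delta <- 0.004
  low <- sphere; low$vertices[, 2] <- low$vertices[, 2] + 0.025 - delta
  pts <- detect_contacts(low, slab)
  expect_gt(nrow(pts), 0)
  expect_equal(max(pts$depth), delta, tolerance = 1e-12)
  expect_equal(pts$ny, rep(1, nrow(pts)))             # flat slab: +Y normal
  # tributary area: total sphere surface area / vertex count
  expect_equal(unique(pts$area), sum_face_area(sphere) / 107)
  # center at depth = radius: nadir depth equals the radius
  half <- sphere   # center exactly at the surface level
  deep <- detect_contacts(half, slab)
  expect_equal(max(deep$depth), 0.025, tolerance = 1e-12)
  # non-watertight terrain rejected
  holed <- slab; holed$faces <- holed$faces[-1, ]
  expect_error(detect_contacts(low, holed), "watertight")
})

test_that("elastic-foundation pressure law with clamping", {
  p <- contact_params()
  expect_equal(normal_pressure(0, 5, p), 0)
  expect_equal(normal_pressure(0, -3, p), 0)
  # 1 mm depth at 50 MPa/m: 50 kPa
  expect_equal(normal_pressure(0.001, 0, p), 50e3)
  # linear in depth at zero rate
  expect_equal(normal_pressure(0.002, 0, p), 2 * normal_pressure(0.001, 0, p))
  # separation rate at -1/c clamps to zero
  expect_equal(normal_pressure(0.01, -1 / p$dissipation, p), 0)
  expect_error(normal_pressure(-0.001, 0, p), "depth")
})

test_that("friction blend: rest continuity, Coulomb limit, bound", {
  p <- contact_params()
  expect_equal(friction_force(0, c(1, 0, 0), p), c(0, 0, 0))
  expect_equal(friction_force(100, c(0, 0, 0), p), c(0, 0, 0))
  # far beyond the transition velocity with zero viscous term: Coulomb
  p0 <- contact_params(mu_viscous = 1e-12)
  f <- friction_force(100, c(50, 0, 0), p0)
  expect_equal(sqrt(sum(f^2)), 0.9 * 100, tolerance = 1e-6)
  expect_lt(f[1], 0)   # opposes slip
  # with all coefficients zero the force is identically zero
  pz <- contact_params(mu_static = 0, mu_dynamic = 0, mu_viscous = 0)
  set.seed(3)
  for (i in 1:20) {
    v <- rnorm(3)
    expect_equal(friction_force(runif(1, 0, 500), v, pz), v * 0)
  }
  # magnitude bound (mu_s + mu_v * v / v_t) * N over random slips
  for (i in 1:50) {
    v <- rnorm(3) * runif(1, 0, 2)
    N <- runif(1, 0, 1000)
    f <- friction_force(N, v, p)
    bound <- (p$mu_static + p$mu_viscous *
                sqrt(sum(v^2)) / p$transition_velocity) * N
    expect_lte(sqrt(sum(f^2)), bound + 1e-9)
  }
})

test_that("resultant GRF and center of pressure", {
  mkpts <- function(x, fn) {
    data.frame(x = x, y = 0, z = 0, fn = fn, fx = 0, fy = fn, fz = 0)
  }
  one <- mkpts(0.3, 10)
  r1 <- resultant_grf(one)
  expect_equal(r1$cop[1], 0.3)
  expect_equal(r1$force, c(0, 10, 0))
  # two equal normal forces: CoP at the midpoint
  two <- mkpts(c(0, 1), c(5, 5))
  expect_equal(resultant_grf(two)$cop[1], 0.5)
  # empty set: zero force, undefined CoP flagged
  r0 <- resultant_grf(NULL)
  expect_equal(r0$force, c(0, 0, 0))
  expect_false(r0$defined)
  expect_true(all(is.na(r0$cop)))
  # zero-moment property: normal-force moment about the CoP vanishes
  set.seed(5)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    pts <- data.frame(x = runif(n), y = 0, z = runif(n),
                      fn = runif(n, 0, 100))
    pts$fx <- 0; pts$fy <- pts$fn; pts$fz <- 0
    res <- resultant_grf(pts)
    mom <- colSums(cbind(
      (pts$y - res$cop[2]) * pts$fz - (pts$z - res$cop[3]) * pts$fy,
      (pts$z - res$cop[3]) * pts$fx - (pts$x - res$cop[1]) * pts$fz,
      (pts$x - res$cop[1]) * pts$fy - (pts$y - res$cop[2]) * pts$fx))
    expect_lt(max(abs(mom)), 1e-9)
  }
})

test_that("a resting sphere settles to static force balance within 1%", {
  mass <- 2
  mdl <- ball_model(mass = mass)
  slab <- height_field(build_slab(-0.5, 0.5, 0.2, 1))
  s <- run_settle(mdl, slab, drop = 0.002, n_steps = 2000)
  expect_false(s$terminated)
  w <- mass * 9.80665
  fy <- s$grf$ball$force[2]
  expect_lt(abs(fy - w) / w, 0.01)
  # and the sphere is at rest
  expect_lt(max(abs(s$u)), 1e-3)
})

test_that("contact force is continuous at initiation", {
  # first-contact force bounded by stiffness x (penetration per step) x area
  mdl <- ball_model(mass = 1)
  cmb <- compile_model(mdl)
  slab <- height_field(build_slab(-0.5, 0.5, 0.2, 1))
  q <- standing_q(cmb$spec)
  q[2] <- q[2] + 0.001   # 1 mm above rest
  s <- model_state(cmb, q = q)
  prev_fy <- 0
  first_fy <- NA
  for (i in 1:200) {
    s <- forward_step(s, numeric(0), cmb, slab, contact_params(), 0.002)
    fy <- s$grf$ball$force[2]
    if (is.na(first_fy) && fy > 0) {
      first_fy <- fy
      v_impact <- abs(s$u[2])
      # all vertices at worst penetrate by v * dt in the first step
      bound <- contact_params()$stiffness * (v_impact * 0.002) *
        sum_face_area(build_contact_sphere(contact_sphere_spec(0.05))) * 2
      expect_lt(first_fy, bound)
      break
    }
    prev_fy <- fy
  }
  expect_false(is.na(first_fy))
})

test_that("drop-test rebound peaks decrease strictly with dissipation", {
  mdl <- ball_model(mass = 0.5)
  cmb <- compile_model(mdl)
  slab <- height_field(build_slab(-0.5, 0.5, 0.2, 1))
  q <- standing_q(cmb$spec); q[2] <- q[2] + 0.05
  s <- model_state(cmb, q = q)
  ys <- numeric(4000)
  for (i in seq_len(4000)) {
    s <- forward_step(s, numeric(0), cmb, slab, contact_params(), 0.001)
    ys[i] <- s$q[2]
  }
  # local maxima of the height series = rebound apexes
  peaks <- which(diff(sign(diff(ys))) == -2) + 1
  apex <- ys[peaks]
  apex <- apex[apex > standing_q(cmb$spec)[2] - 0.04]
  expect_gt(length(apex), 1)
  expect_true(all(diff(apex) < 0))
})

test_that("total energy does not grow during a dissipative drop", {
  mass <- 0.5
  mdl <- ball_model(mass = mass)
  cmb <- compile_model(mdl)
  slabm <- build_slab(-0.5, 0.5, 0.2, 1)
  slab <- height_field(slabm)
  sphere_area <- sum_face_area(build_contact_sphere(contact_sphere_spec(0.05)))
  area_v <- sphere_area / 107
  k <- contact_params()$stiffness
  energy <- function(st) {
    kin <- 0.5 * mass * sum(st$u[1:2]^2) + 0.5 * 1e-3 * st$u[3]^2
    pot <- mass * 9.80665 * st$q[2]
    # elastic foundation potential: 1/2 k x^2 per unit area
    sph <- build_contact_sphere(contact_sphere_spec(0.05))
    sph$vertices[, 1] <- sph$vertices[, 1] + st$q[1]
    sph$vertices[, 2] <- sph$vertices[, 2] + st$q[2]
    pts <- detect_contacts(sph, slabm)
    el <- if (nrow(pts) > 0) sum(0.5 * k * pts$depth^2 * pts$area) else 0
    kin + pot + el
  }
  q <- standing_q(cmb$spec); q[2] <- q[2] + 0.03
  s <- model_state(cmb, q = q)
  e_prev <- energy(s)
  e0 <- e_prev
  max_gain <- 0
  for (i in 1:1200) {
    s <- forward_step(s, numeric(0), cmb, slab, contact_params(), 0.001)
    e <- energy(s)
    max_gain <- max(max_gain, e - e_prev)
    e_prev <- e
  }
  # documented integrator bound: per-step gain below 0.5 m |a_max|^2 dt^2
  # with |a| <= 100 g during impact
  bound <- 0.5 * mass * (100 * 9.80665)^2 * 0.001^2
  expect_lt(max_gain, bound)
  expect_lt(e_prev, e0)   # net dissipation over the drop
})
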