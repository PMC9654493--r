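test_that("zero gravity, zero excitation, no contact: equilibrium", {
  spec <- planar_model("stairs")
  spec$gravity <- 0
  cm <- compile_model(spec)
  s0 <- model_state(cm)
  s <- s0
  for (i in 1:50) s <- forward_step(s, numeric(cm$nm), cm, NULL)
  expect_equal(unname(s$q), unname(s0$q), tolerance = 1e-10)
  expect_equal(unname(s$u), unname(s0$u), tolerance = 1e-10)
  expect_equal(s$t, 0.1, tolerance = 1e-9)
})

test_that("free fall matches the ballistic closed form", {
  spec <- planar_model("ramp")
  spec$init_pelvis_height <- 0.1   # keep the fall detector out of the way
  cm <- compile_model(spec)
  q <- standing_q(cm$spec); q[2] <- 2.0
  s <- model_state(cm, q = q)
  dt <- 0.002
  n <- 250                          # 0.5 s
  for (i in seq_len(n)) s <- forward_step(s, numeric(cm$nm), cm, NULL,
                                          contact_params(), dt)
  t <- n * dt
  # symplectic Euler lands within O(g t dt) of y0 - g t^2 / 2
  expect_equal(unname(s$q[2]), 2.0 - 0.5 * 9.80665 * t^2,
               tolerance = 9.80665 * t * dt * 1.1)
  # uniform gravity induces no joint motion
  expect_lt(max(abs(s$q[4:9])), 1e-12)
})

test_that("horizontal momentum is conserved without contact", {
  spec <- planar_model("stairs")
  spec$init_pelvis_height <- 0.1
  cm <- compile_model(spec)
  q <- standing_q(cm$spec); q[2] <- 3.0
  u <- stats::setNames(numeric(cm$nq), cm$dof_names)
  u[1] <- 1.3    # horizontal drift
  s <- model_state(cm, q = q, u = u)
  px <- function(st) {
    kin <- planar_fk(cm, as.numeric(st$q))
    vel <- planar_vel(cm, kin, as.numeric(st$u))
    cx <- kin$ox + kin$ca * cm$com[, 1] - kin$sa * cm$com[, 2]
    cy <- kin$oy + kin$sa * cm$com[, 1] + kin$ca * cm$com[, 2]
    cvx <- vel$vx - vel$angvel * (cy - kin$oy)
    sum(cm$mass * cvx)
  }
  p0 <- px(s)
  for (i in 1:100) {
    s <- forward_step(s, numeric(cm$nm), cm, NULL, contact_params(), 0.002)
    p1 <- px(s)
    expect_lt(abs(p1 - p0), 1e-8)
    p0 <- p1
  }
})

test_that("observation layout accounting", {
  cm <- compile_model(planar_model("stairs"))
  lay <- default_layout(cm)
  # paper layout sums to the full-model state size
  expect_equal(layout_size(paper_state_layout()), 214)
  # planar layout equals the sum of its declared component sizes
  s <- model_state(cm)
  obs <- observation(s, cm)
  expect_equal(length(obs), layout_size(lay))
  # static upright state: all velocity and acceleration entries zero
  nb <- cm$nb
  vel_idx <- (3 * nb + 1):(9 * nb)   # seg vel + acc blocks
  expect_equal(obs[vel_idx], rep(0, length(vel_idx)))
  # mismatched layout rejected, naming the component
  bad <- lay; bad["muscle_force"] <- 72L
  expect_error(observation(s, cm, bad), "muscle_force")
})

test_that("termination flags: fall and divergence, never silent NaN", {
  cm <- compile_model(planar_model("stairs"))
  terr <- height_field(ascent_terrain("stairs"))
  s <- model_state(cm)
  for (i in 1:3000) {
    s <- forward_step(s, numeric(cm$nm), cm, terr, contact_params(), 0.002)
    expect_false(any(!is.finite(s$q)))
    if (s$terminated) break
  }
  expect_true(s$terminated)
  expect_true(s$reason %in% c("fall", "left_terrain"))
  # stepping a terminated state is a no-op
  s2 <- forward_step(s, numeric(cm$nm), cm, terr)
  expect_identical(s2$q, s$q)
  # non-finite excitations rejected
  expect_error(forward_step(model_state(cm), rep(NaN, cm$nm), cm, NULL),
               "excitations")
})

test_that("model spec YAML round trip preserves the model", {
  spec <- planar_model("stairs")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_yaml(spec, path)
  back <- read_model_yaml(path)
  expect_equal(back$bodies, spec$bodies)
  expect_equal(back$joints, spec$joints)
  expect_equal(length(back$muscles), length(spec$muscles))
  for (nm in names(spec$muscles)) {
    expect_equal(back$muscles[[nm]]$f_max, spec$muscles[[nm]]$f_max)
    expect_equal(back$muscles[[nm]]$l_slack, spec$muscles[[nm]]$l_slack,
                 tolerance = 1e-9)
    expect_equal(back$muscles[[nm]]$path, spec$muscles[[nm]]$path)
  }
  expect_equal(back$spheres, spec$spheres)
  expect_equal(back$trunk_pelvis_angle, spec$trunk_pelvis_angle)
  # the reloaded model simulates identically for a short horizon
  cm1 <- compile_model(spec); cm2 <- compile_model(back)
  s1 <- model_state(cm1); s2 <- model_state(cm2)
  for (i in 1:20) {
    s1 <- forward_step(s1, rep(0.4, cm1$nm), cm1, NULL)
    s2 <- forward_step(s2, rep(0.4, cm2$nm), cm2, NULL)
  }
  expect_equal(s1$q, s2$q, tolerance = 1e-9)
})

test_that("full 3D topology is configuration only and refuses simulation", {
  full <- full_model_spec("stairs")
  expect_false(full$planar)
  expect_equal(length(full$muscles), 18)
  # 14 DOF: 6-DOF pelvis + 2 hip + 1 knee + 1 ankle per leg
  n_dof <- 6 + 2 * 4
  expect_equal(nrow(full$joints) - 1, 8)   # 8 pin rows listed
  expect_error(compile_model(full), "planar")
  expect_equal(full$isometric_scale, 1.8)
})

test_that("standing muscle fibers sit at their optimal length", {
  cm <- compile_model(planar_model("ramp"))
  kin <- planar_fk(cm, standing_q(cm$spec))
  for (i in seq_len(cm$nm)) {
    L <- muscle_path_length(cm, kin, i)
    lnorm <- (L - cm$muscles$l_slack[i]) / cm$muscles$cospenn[i] /
      cm$muscles$l_opt[i]
    expect_equal(unname(lnorm), 1, tolerance = 1e-6)
  }
})
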