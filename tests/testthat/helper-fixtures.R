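# Shared fixtures built in code.

# Unit cube mesh with outward winding (volume 1).
cube_mesh <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(
    c(1, 3, 7), c(1, 7, 5),   # z = 0 ... faces chosen per axis below
    c(2, 8, 4), c(2, 6, 8),
    c(1, 5, 6), c(1, 6, 2),
    c(3, 4, 8), c(3, 8, 7),
    c(1, 2, 4), c(1, 4, 3),
    c(5, 7, 8), c(5, 8, 6)
  )
  m <- tri_mesh(v, f)
  if (mesh_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

# Single rigid ball on a planar root joint, with one contact sphere.
# Used for contact settle/restitution and integrator energy tests.
ball_model <- function(mass = 2, diameter = 0.05, damping = 0) {
  bodies <- data.frame(name = "ball", mass = mass, inertia = 1e-3,
                       com_x = 0, com_y = 0, length = diameter)
  joints <- data.frame(name = "ball", type = "planar", parent = "ground",
                       child = "ball", px = 0, py = 0, cx = 0, cy = 0,
                       qmin = NA_real_, qmax = NA_real_)
  spheres <- data.frame(name = "ball_c", body = "ball", x = 0, y = 0,
                        z = 0, diameter = diameter, foot = "ball")
  model_spec("ball", bodies, joints, muscles = list(), spheres = spheres,
             init_pelvis_height = diameter / 2, joint_damping = damping)
}

# Reference muscle used across the muscle tests.
test_muscle <- function(...) {
  muscle_params(name = "m", f_max = 1000, l_opt = 0.1, l_slack = 0.2,
                v_max = 10, penn = 0.1, ...)
}

# Small synthetic stair reference shared by environment tests.
short_stair_ref <- function(n_cycles = 1, dt = 0.01) {
  synth_gait(synthetic_gait_spec("stairs", cycle_duration = 1.2,
                                 n_cycles = n_cycles, stand_time = 0.3,
                                 dt = dt),
             stair_spec(), planar_model("stairs"))
}

run_settle <- function(model, terrain, drop = 0.02, n_steps = 1500,
                       dt = 0.002, contact = contact_params()) {
  cm <- compile_model(model)
  q <- standing_q(cm$spec)
  q[cm$root[2]] <- q[cm$root[2]] + drop
  s <- model_state(cm, q = q)
  for (i in seq_len(n_steps)) {
    s <- forward_step(s, numeric(cm$nm), cm, terrain, contact, dt)
    if (s$terminated) break
  }
  s
}
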