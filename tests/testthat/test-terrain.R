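test_that("contact sphere triangulation matches the closed-form counts", {
  # default granularity: 15 segments x 8 rings
  m <- build_contact_sphere(contact_sphere_spec(0.05))
  expect_equal(nrow(m$vertices), 107)
  expect_equal(nrow(m$faces), 210)
  # formula check at minimal granularity
  m2 <- build_contact_sphere(contact_sphere_spec(0.025, segments = 3,
                                                 rings = 2))
  expect_equal(nrow(m2$vertices), 5)
  expect_equal(nrow(m2$faces), 6)
  # general formula s*(r-1)+2 vertices, 2*s*(r-1) faces
  for (sr in list(c(6, 4), c(10, 5))) {
    mm <- build_contact_sphere(contact_sphere_spec(0.1, segments = sr[1],
                                                   rings = sr[2]))
    expect_equal(nrow(mm$vertices), sr[1] * (sr[2] - 1) + 2)
    expect_equal(nrow(mm$faces), 2 * sr[1] * (sr[2] - 1))
    expect_true(validate_mesh(mm)$ok)
  }
  expect_true(validate_mesh(m)$ok)
  expect_true(validate_mesh(m2)$ok)
})

test_that("stair mesh: watertight, exact rise and closed-form volume", {
  spec <- stair_spec()   # 3 steps, 0.2 m x 0.25 m, 2 m wide
  m <- build_stairs(spec)
  rep <- validate_mesh(m)
  expect_true(rep$ok)
  expect_equal(diff(range(m$vertices[, 2])), 0.6)   # total rise
  expect_equal(diff(range(m$vertices[, 3])), 2)     # width
  vol_exact <- spec$width * spec$step_depth * spec$step_height *
    spec$n_steps * (spec$n_steps + 1) / 2
  expect_equal(mesh_volume(m), vol_exact, tolerance = 1e-12)
  # single step degenerates to a box
  m1 <- build_stairs(stair_spec(1, 0.3, 0.5, 1.0))
  expect_true(validate_mesh(m1)$ok)
  expect_equal(mesh_volume(m1), 0.3 * 0.5 * 1.0, tolerance = 1e-12)
  # volume formula holds across random specs
  set.seed(7)
  for (i in 1:5) {
    sp <- stair_spec(sample(2:6, 1), runif(1, 0.1, 0.3),
                     runif(1, 0.2, 0.4), runif(1, 0.5, 3))
    mm <- build_stairs(sp)
    expect_true(validate_mesh(mm)$ok)
    expect_equal(mesh_volume(mm),
                 sp$width * sp$step_depth * sp$step_height *
                   sp$n_steps * (sp$n_steps + 1) / 2, tolerance = 1e-12)
  }
})

test_that("ramp mesh: watertight wedge with closed-form volume and slope", {
  spec <- ramp_spec()    # 3.25 m run, 0.45 m rise, 2 m wide
  m <- build_ramp(spec)
  expect_true(validate_mesh(m)$ok)
  expect_equal(mesh_volume(m), 0.5 * spec$run * spec$rise * spec$width,
               tolerance = 1e-12)
  # top-surface normal tilts by exactly the gradient angle
  hf <- height_field(m)
  inclined <- hf$n[hf$n[, 2] < 0.9999, , drop = FALSE]
  if (nrow(inclined) == 0) inclined <- hf$n
  tilt <- acos(max(pmin(inclined[, 2], 1))) * 180 / pi
  expect_equal(tilt, ramp_gradient(spec), tolerance = 1e-6)
  # gradient and length of the task geometry
  expect_equal(ramp_gradient(spec), 7.883, tolerance = 0.01)
  expect_equal(ramp_length(spec), 3.28, tolerance = 0.005)
  # analytic anchors
  expect_equal(ramp_gradient(ramp_spec(1, 1, 1)), 45)
  expect_equal(ramp_length(ramp_spec(3, 4, 1)), 5)
  # rise -> 0 degenerates toward a flat slab
  expect_lt(ramp_gradient(ramp_spec(3.25, 1e-9, 2)), 1e-7)
})

test_that("mesh validator flags holes, flipped faces and duplicates", {
  cube <- cube_mesh()
  rep <- validate_mesh(cube)
  expect_true(rep$ok)
  expect_equal(rep$signed_volume, 1)
  # hole: drop one face
  holed <- cube; holed$faces <- holed$faces[-1, ]
  rh <- validate_mesh(holed)
  expect_false(rh$watertight)
  expect_gt(nrow(rh$boundary_edges), 0)
  # flipped winding on one face
  flipped <- cube; flipped$faces[1, ] <- flipped$faces[1, c(1, 3, 2)]
  rf <- validate_mesh(flipped)
  expect_false(rf$oriented)
  # duplicate vertex
  dup <- cube; dup$vertices <- rbind(dup$vertices, dup$vertices[1, ])
  expect_true(validate_mesh(dup)$duplicate_vertices)
  # degenerate face
  degen <- cube; degen$faces <- rbind(degen$faces, c(1, 1, 2))
  expect_gt(length(validate_mesh(degen)$degenerate_faces), 0)
})

test_that("foot geometry places the task spheres, mirrored left/right", {
  r <- foot_geometry("right")
  l <- foot_geometry("left")
  expect_equal(r$heel$diameter, 0.050)
  expect_equal(r$toe1$diameter, 0.025)
  expect_equal(r$toe2$diameter, 0.025)
  expect_equal(r$heel$center_offset, c(0.030, 0.020, 0))
  expect_equal(r$toe1$center_offset, c(0.020, -0.005, -0.026))
  expect_equal(r$toe2$center_offset, c(0.020, -0.005, 0.026))
  # left toe Z offsets are the negation of right
  expect_equal(l$toe1$center_offset[3], -r$toe1$center_offset[3])
  expect_equal(l$toe2$center_offset[3], -r$toe2$center_offset[3])
  expect_equal(l$heel$center_offset, r$heel$center_offset)
})

test_that("OBJ round trip is bit-identical in vertices and face order", {
  path <- withr::local_tempfile(fileext = ".obj")
  for (m in list(build_stairs(stair_spec()), build_ramp(ramp_spec()),
                 build_contact_sphere(contact_sphere_spec(0.05)))) {
    write_obj(m, path)
    m2 <- read_obj(path)
    expect_identical(m2$faces, m$faces)
    expect_identical(m2$vertices, m$vertices)
  }
})

test_that("composite ascent terrain is valid and steps up from the slab", {
  terr <- ascent_terrain("stairs")
  rep <- validate_mesh(terr)
  expect_true(rep$watertight)
  expect_true(rep$oriented)
  hf <- height_field(terr)
  # level approach at y = 0, first tread at step height
  q <- hf_query(hf, rbind(c(0, -1, 0), c(0.30, -1, 0), c(0.60, -1, 0)))
  expect_equal(q$ysurf, c(0, 0.2, 0.4), tolerance = 1e-12)
})
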