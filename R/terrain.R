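#' Triangle mesh container
#'
#' A minimal watertight triangle mesh: an `n x 3` vertex matrix (m) and an
#' `m x 3` integer face matrix of 1-based vertex indices with consistent
#' (outward) winding.
#'
#' @param vertices Numeric matrix, one 3D point per row.
#' @param faces Integer matrix, one vertex-index triple per row.
#' @return Object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices))) {
    stop("face indices out of range")
  }
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Stair geometry specification
#'
#' @param n_steps Number of steps.
#' @param step_height Riser height (m). Default 0.2 m.
#' @param step_depth Tread depth (m). Default 0.25 m.
#' @param width Stair width (m). Default 2 m.
#' @return Object of class `stair_spec`.
#' @export
stair_spec <- function(n_steps = 3, step_height = 0.2, step_depth = 0.25,
                       width = 2) {
  stopifnot(n_steps >= 1, step_height > 0, step_depth > 0, width > 0)
  structure(list(n_steps = as.integer(n_steps), step_height = step_height,
                 step_depth = step_depth, width = width),
            class = "stair_spec")
}

#' Ramp geometry specification
#'
#' @param run Horizontal run (m). Default 3.25 m.
#' @param rise Vertical rise (m). Default 0.45 m.
#' @param width Ramp width (m). Default 2 m.
#' @return Object of class `ramp_spec`.
#' @export
ramp_spec <- function(run = 3.25, rise = 0.45, width = 2) {
  stopifnot(run > 0, rise > 0, width > 0)
  structure(list(run = run, rise = rise, width = width), class = "ramp_spec")
}

#' Foot contact sphere specification
#'
#' A UV-sphere triangulation placed on a foot segment. The default
#' granularity (15 longitudinal segments, 8 latitudinal rings) yields 107
#' vertices and 210 faces.
#'
#' @param diameter Sphere diameter (m).
#' @param center_offset Length-3 numeric, sphere center in body-local
#'   coordinates (m).
#' @param body Name of the body segment the sphere is attached to.
#' @param segments Longitudinal segment count (>= 3).
#' @param rings Latitudinal ring count (>= 2).
#' @return Object of class `contact_sphere_spec`.
#' @export
contact_sphere_spec <- function(diameter, center_offset = c(0, 0, 0),
                                body = "ground", segments = 15, rings = 8) {
  stopifnot(diameter > 0, length(center_offset) == 3, segments >= 3,
            rings >= 2)
  structure(list(diameter = diameter, center_offset = as.numeric(center_offset),
                 body = body, segments = as.integer(segments),
                 rings = as.integer(rings)),
            class = "contact_sphere_spec")
}

# Extrude a simple (non-self-intersecting) 2D profile polygon along Z into a
# watertight triangular prism. The profile is re-oriented counterclockwise if
# needed (cyclic order preserved, first vertex kept first); both end caps are
# fan-triangulated from the first profile vertex, so the profile must be
# star-shaped as seen from that vertex.
extrude_profile <- function(profile, width) {
  profile <- matrix(as.numeric(profile), ncol = 2)
  k <- nrow(profile)
  stopifnot(k >= 3, width > 0)
  area2 <- sum(profile[, 1] * profile[c(2:k, 1), 2] -
                 profile[c(2:k, 1), 1] * profile[, 2])
  if (area2 < 0) profile <- profile[c(1L, k:2L), , drop = FALSE]
  hw <- width / 2
  verts <- rbind(cbind(profile, hw), cbind(profile, -hw))
  faces <- matrix(0L, nrow = 2 * (k - 2) + 2 * k, ncol = 3)
  r <- 1L
  for (i in 2:(k - 1)) {             # front cap, z = +w/2, outward +Z
    faces[r, ] <- c(1L, i, i + 1L); r <- r + 1L
  }
  for (i in 2:(k - 1)) {             # back cap, mirrored winding
    faces[r, ] <- c(1L + k, i + 1L + k, i + k); r <- r + 1L
  }
  for (i in 1:k) {                   # side walls
    j <- if (i == k) 1L else i + 1L
    faces[r, ] <- c(i, j + k, j); r <- r + 1L
    faces[r, ] <- c(i, i + k, j + k); r <- r + 1L
  }
  tri_mesh(verts, faces)
}

#' Build a watertight staircase mesh
#'
#' The solid staircase profile (risers and treads on top, flat bottom and
#' back) extruded across the stair width and triangulated minimally. The
#' staircase ascends in +X, rises in +Y, and is centered on Z = 0 with its
#' first riser at X = 0 and its base at Y = 0.
#'
#' @param spec A [stair_spec()].
#' @return A watertight `tri_mesh`; total rise is
#'   `n_steps * step_height`.
#' @export
build_stairs <- function(spec) {
  stopifnot(inherits(spec, "stair_spec"))
  n <- spec$n_steps; h <- spec$step_height; d <- spec$step_depth
  # profile starts at the bottom-back corner (star point for the cap fans)
  pts <- matrix(c(n * d, 0, 0, 0), ncol = 2, byrow = TRUE)
  for (i in seq_len(n)) {
    pts <- rbind(pts, c((i - 1) * d, i * h), c(i * d, i * h))
  }
  extrude_profile(pts, spec$width)
}

#' Build a watertight ramp (wedge) mesh
#'
#' A wedge whose inclined top surface runs from the origin up to
#' `(run, rise)`, extruded across the ramp width and centered on Z = 0.
#'
#' @param spec A [ramp_spec()].
#' @return A watertight `tri_mesh`.
#' @export
build_ramp <- function(spec) {
  stopifnot(inherits(spec, "ramp_spec"))
  pts <- matrix(c(spec$run, 0,
                  spec$run, spec$rise,
                  0, 0), ncol = 2, byrow = TRUE)
  extrude_profile(pts, spec$width)
}

#' Build a flat slab mesh
#'
#' Rectangular box with its top surface at Y = 0, spanning `[x0, x1]` in X.
#' Used as the level approach in front of the stairs/ramp and as the flat
#' ground in contact tests.
#'
#' @param x0,x1 X extent (m).
#' @param thickness Slab thickness (m).
#' @param width Z extent (m).
#' @return A watertight `tri_mesh`.
#' @export
build_slab <- function(x0 = -1, x1 = 1, thickness = 0.1, width = 2) {
  stopifnot(x1 > x0, thickness > 0, width > 0)
  pts <- matrix(c(x0, -thickness,
                  x1, -thickness,
                  x1, 0,
                  x0, 0), ncol = 2, byrow = TRUE)
  extrude_profile(pts, width)
}

#' Build a triangulated contact sphere
#'
#' UV-sphere triangulation with `segments` longitudinal segments and
#' `rings` latitudinal rings: two pole vertices plus
#' `segments * (rings - 1)` band vertices, two pole fans plus quad bands
#' split into triangles, giving `segments * (rings - 1) + 2` vertices and
#' `2 * segments * (rings - 1)` faces. The default foot-sphere granularity
#' (15 segments, 8 rings) gives 107 vertices and 210 faces.
#'
#' @param spec A [contact_sphere_spec()].
#' @return A watertight `tri_mesh` centered on `center_offset`.
#' @export
build_contact_sphere <- function(spec) {
  stopifnot(inherits(spec, "contact_sphere_spec"))
  s <- spec$segments; rg <- spec$rings
  R <- spec$diameter / 2
  theta <- pi * seq_len(rg - 1) / rg        # latitudes, pole-to-pole
  phi <- 2 * pi * (seq_len(s) - 1) / s
  verts <- matrix(0, nrow = 2 + s * (rg - 1), ncol = 3)
  verts[1, ] <- c(0, R, 0)                  # top pole
  verts[2, ] <- c(0, -R, 0)                 # bottom pole
  idx <- function(i, j) 2L + (i - 1L) * s + j   # ring i, segment j
  for (i in seq_len(rg - 1)) {
    verts[idx(i, seq_len(s)), ] <- cbind(R * sin(theta[i]) * cos(phi),
                                         R * cos(theta[i]),
                                         R * sin(theta[i]) * sin(phi))
  }
  faces <- matrix(0L, nrow = 2 * s * (rg - 1), ncol = 3)
  r <- 1L
  for (j in seq_len(s)) {                   # top fan
    jn <- if (j == s) 1L else j + 1L
    faces[r, ] <- c(1L, idx(1L, jn), idx(1L, j)); r <- r + 1L
  }
  if (rg > 2) {
    for (i in seq_len(rg - 2)) {            # quad bands
      for (j in seq_len(s)) {
        jn <- if (j == s) 1L else j + 1L
        a <- idx(i, j); b <- idx(i, jn); cc <- idx(i + 1L, jn)
        dd <- idx(i + 1L, j)
        faces[r, ] <- c(a, b, cc); r <- r + 1L
        faces[r, ] <- c(a, cc, dd); r <- r + 1L
      }
    }
  }
  for (j in seq_len(s)) {                   # bottom fan
    jn <- if (j == s) 1L else j + 1L
    faces[r, ] <- c(2L, idx(rg - 1L, j), idx(rg - 1L, jn)); r <- r + 1L
  }
  m <- tri_mesh(verts, faces)
  m$vertices <- sweep(m$vertices, 2, spec$center_offset, `+`)
  m
}

#' Foot contact-sphere placement
#'
#' Returns the three contact spheres of one foot: a 50 mm heel sphere at
#' (30, 20, 0) mm in the hindfoot (calcaneus) frame and two 25 mm toe
#' spheres at (20, -5, -26) mm and (20, -5, 26) mm in the forefoot (toes)
#' frame. The left foot mirrors the right in Z.
#'
#' @param side `"left"` or `"right"`.
#' @return List of three [contact_sphere_spec()] objects named `heel`,
#'   `toe1`, `toe2`.
#' @export
foot_geometry <- function(side = c("right", "left")) {
  side <- match.arg(side)
  zs <- if (side == "right") 1 else -1
  list(
    heel = contact_sphere_spec(0.050, c(0.030, 0.020, 0), body = "hindfoot"),
    toe1 = contact_sphere_spec(0.025, c(0.020, -0.005, -0.026 * zs),
                               body = "forefoot"),
    toe2 = contact_sphere_spec(0.025, c(0.020, -0.005, 0.026 * zs),
                               body = "forefoot")
  )
}

#' Signed volume of a triangle mesh
#'
#' Sum of signed tetrahedron volumes against the origin; positive for a
#' watertight mesh with outward-facing normals.
#'
#' @param mesh A `tri_mesh`.
#' @return Signed enclosed volume (m^3).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
        a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
        a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

#' Validate a triangle mesh
#'
#' Report-only checker for the mesh invariants required of terrain and
#' contact geometry: watertightness (every undirected edge shared by
#' exactly two faces), consistent outward orientation (each directed edge
#' used exactly once and positive signed volume), absence of duplicate
#' vertices, and absence of degenerate (zero-area or repeated-index)
#' faces.
#'
#' @param mesh A `tri_mesh`.
#' @param tol Length tolerance for duplicate-vertex and zero-area checks.
#' @return A list of class `mesh_report` with fields `watertight`,
#'   `oriented`, `outward` (signed volume > 0), `signed_volume`,
#'   `boundary_edges` (matrix of unmatched edges), `duplicate_vertices`,
#'   `degenerate_faces`, and `ok` (all checks passed).
#' @export
validate_mesh <- function(mesh, tol = 1e-12) {
  v <- mesh$vertices; f <- mesh$faces
  ed <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])   # directed edges
  key_dir <- paste(ed[, 1], ed[, 2])
  key_und <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  und_tab <- table(key_und)
  watertight <- length(und_tab) > 0 && all(und_tab == 2L)
  oriented <- !any(duplicated(key_dir))
  boundary <- ed[key_und %in% names(und_tab)[und_tab != 2L], , drop = FALSE]
  vol <- mesh_volume(mesh)
  dup <- any(duplicated(apply(v, 1, paste, collapse = "|")))
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  areas <- sqrt(rowSums(cr^2)) / 2
  degen <- which(areas <= tol | f[, 1] == f[, 2] | f[, 2] == f[, 3] |
                   f[, 1] == f[, 3])
  rep <- list(watertight = watertight, oriented = oriented,
              outward = watertight && vol > 0, signed_volume = vol,
              boundary_edges = boundary, duplicate_vertices = dup,
              degenerate_faces = degen,
              ok = watertight && oriented && vol > 0 && !dup &&
                length(degen) == 0)
  class(rep) <- "mesh_report"
  rep
}

#' @export
print.mesh_report <- function(x, ...) {
  cat(sprintf(
    "mesh_report: watertight=%s oriented=%s outward=%s volume=%.6g dup=%s degen=%d\n",
    x$watertight, x$oriented, x$outward, x$signed_volume,
    x$duplicate_vertices, length(x$degenerate_faces)))
  if (nrow(x$boundary_edges) > 0) {
    cat("boundary edges:\n"); print(x$boundary_edges)
  }
  invisible(x)
}

#' Ramp gradient
#'
#' @param spec A [ramp_spec()].
#' @return Slope angle `atan(rise/run)` in degrees.
#' @export
ramp_gradient <- function(spec) {
  stopifnot(spec$run > 0)
  atan(spec$rise / spec$run) * 180 / pi
}

#' Ramp surface length
#'
#' @param spec A [ramp_spec()].
#' @return Length of the inclined surface, `hypot(run, rise)` (m).
#' @export
ramp_length <- function(spec) sqrt(spec$run^2 + spec$rise^2)

#' Translate a mesh
#'
#' @param mesh A `tri_mesh`.
#' @param offset Length-3 translation (m).
#' @return The translated mesh.
#' @export
translate_mesh <- function(mesh, offset) {
  mesh$vertices <- sweep(mesh$vertices, 2, as.numeric(offset), `+`)
  mesh
}

#' Merge meshes into one
#'
#' Concatenates vertex and face lists (indices re-based). Each input must
#' be watertight on its own; the result encloses the union of the solids
#' as disjoint shells.
#'
#' @param meshes List of `tri_mesh` objects.
#' @return A single `tri_mesh`.
#' @export
merge_meshes <- function(meshes) {
  vs <- list(); fs <- list(); off <- 0L
  for (m in meshes) {
    vs[[length(vs) + 1L]] <- m$vertices
    fs[[length(fs) + 1L]] <- m$faces + off
    off <- off + nrow(m$vertices)
  }
  tri_mesh(do.call(rbind, vs), do.call(rbind, fs))
}

#' Write a mesh to a Wavefront OBJ file
#'
#' Triangles only, 1-based indices, no materials. Vertex coordinates are
#' written with 17 significant digits so a write/read round trip is
#' bit-identical.
#'
#' @param mesh A `tri_mesh`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  lines <- c(sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]),
             sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a triangle mesh from a Wavefront OBJ file
#'
#' Supports `v` and `f` records (plain indices or `i/..` slash forms);
#' faces must be triangles.
#'
#' @param path OBJ file path.
#' @return A `tri_mesh`.
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  verts <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                                 function(x) as.numeric(x[1:3])))
  faces <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"),
                                 function(x) {
                                   if (length(x) != 3) {
                                     stop("read_obj: only triangle faces are supported")
                                   }
                                   as.integer(sub("/.*", "", x))
                                 }))
  tri_mesh(verts, faces)
}

#' Composite ascent terrain
#'
#' The terrain the model trains on: a level approach slab whose top is at
#' Y = 0 followed by the stairs or ramp starting at `x_start`.
#'
#' @param kind `"stairs"` or `"ramp"`.
#' @param spec A [stair_spec()] or [ramp_spec()]; defaults to the task
#'   geometry (3 steps of 0.2 m by 0.25 m, or a 3.25 m by 0.45 m ramp).
#' @param x_start X position where the object begins (m).
#' @param approach Length of level ground before the object (m).
#' @return A `tri_mesh` combining approach slab and object.
#' @export
ascent_terrain <- function(kind = c("stairs", "ramp"), spec = NULL,
                           x_start = 0.25, approach = 1.5) {
  kind <- match.arg(kind)
  if (is.null(spec)) {
    spec <- if (kind == "stairs") stair_spec() else ramp_spec()
  }
  obj <- if (kind == "stairs") build_stairs(spec) else build_ramp(spec)
  slab <- build_slab(x0 = x_start - approach, x1 = x_start, thickness = 0.2,
                     width = spec$width)
  merge_meshes(list(slab, translate_mesh(obj, c(x_start, 0, 0))))
}
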