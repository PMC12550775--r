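## Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

## a small phantom that meshes in well under a second at h = 2.5 mm
tiny_spec <- function(...) {
  phantom_spec(shaft_length = 45, plateau_width = 30, plateau_depth = 20,
               shaft_outer_radius = 6.5,
               cortical_thickness_proximal = 1.0,
               cortical_thickness_distal = 2.0, ...)
}

## implant scaled to the tiny phantom (off-catalog on purpose)
tiny_implant_args <- function()
  list(baseplate_width = 24, baseplate_depth = 15, baseplate_thickness = 3,
       fin_reach = 6, fin_half_thickness = 0.8, fin_height = 4,
       boss_radius = 3, taper_length = 3)

tiny_assembly <- function() fixture("tiny_assembly", function() {
  spec <- tiny_spec()
  tib <- generate_phantom_surface(spec)
  res <- resect_tibia(tib, resection_plan())
  sp <- suppressWarnings(do.call(implant_spec,
                                 c(list(stem_length = 25,
                                        stem_diameter = 5),
                                   tiny_implant_args())))
  imp <- place_implant(build_implant(sp), res)
  cav <- carve_cavity(res, imp)
  mesh <- mesh_assembly(cav, imp, mesh_settings(2.5, 2.5, roi_offset = 2.5))
  ras <- rasterize_phantom(spec, grid = ct_grid(
    bbox = rbind(c(-15, -10, 0), c(15, 10, 45)), spacing = c(1, 1, 1)))
  list(spec = spec, tibia = tib, resected = res, implant = imp,
       cavity = cav, mesh = mesh, ct = ras$ct, truth = ras$truth)
})

## homogeneous box meshed with the background-grid mesher (patch tests);
## bounds lie on grid planes of the h = 2.5 mesher so every boundary
## face is exactly planar
box_solid <- function(lo = c(-1.25, -1.25, -1.25),
                      hi = c(11.25, 11.25, 21.25)) {
  inside <- function(pts) {
    pts <- stemfea:::as_points_matrix(pts)
    pts[, 1] >= lo[1] & pts[, 1] <= hi[1] &
      pts[, 2] >= lo[2] & pts[, 2] <= hi[2] &
      pts[, 3] >= lo[3] & pts[, 3] <= hi[3]
  }
  solid_model(inside, bbox = rbind(lo, hi), region = "bone")
}

box_mesh <- function() fixture("box_mesh", function()
  mesh_assembly(box_solid(), NULL, mesh_settings(2.5, 2.5)))

## cross-section area of a box mesh (for pressure resultants)
box_top_area <- function(mesh) {
  rx <- range(mesh$nodes[, 1]); ry <- range(mesh$nodes[, 2])
  diff(rx) * diff(ry)
}

## consistent nodal loads for uniform -z pressure on the top face of a
## box mesh (independent of apply_loads, which needs implant patches)
box_pressure_loads <- function(mesh, p, z_top) {
  tf <- stemfea:::tet_faces(mesh$conn[, 1:4, drop = FALSE])
  cnt <- tabulate(tf$gid)
  once <- cnt[tf$gid] == 1L
  fc_z <- (mesh$nodes[tf$faces[, 1], 3] + mesh$nodes[tf$faces[, 2], 3] +
           mesh$nodes[tf$faces[, 3], 3]) / 3
  top <- which(once & abs(fc_z - z_top) < 1e-9)
  f <- numeric(3L * nrow(mesh$nodes))
  ep <- rbind(c(1, 2), c(2, 3), c(1, 3), c(1, 4), c(2, 4), c(3, 4))
  for (k in top) {
    tri <- tf$faces[k, ]
    el <- tf$elem[k]
    ec <- mesh$conn[el, ]
    loc <- match(tri, ec[1:4])
    p1 <- mesh$nodes[tri[1], ]; p2 <- mesh$nodes[tri[2], ]
    p3 <- mesh$nodes[tri[3], ]
    area <- 0.5 * sqrt(sum(stemfea:::cross3(matrix(p2 - p1, 1),
                                            matrix(p3 - p1, 1))^2))
    for (pair in list(c(1, 2), c(2, 3), c(1, 3))) {
      a <- min(loc[pair[1]], loc[pair[2]])
      b <- max(loc[pair[1]], loc[pair[2]])
      mid <- ec[4L + which(ep[, 1] == a & ep[, 2] == b)]
      f[3L * mid] <- f[3L * mid] - p * area / 3
    }
  }
  f
}

## 3-2-1 minimal constraints for a box: uniform uniaxial stress states
## remain exactly representable (no Poisson locking at the support)
box_minimal_fixed <- function(mesh) {
  nz <- mesh$nodes[, 3]
  bottom <- which(nz < min(nz) + 1e-9)
  fixed <- 3L * bottom                       # w = 0 on the bottom face
  o <- bottom[which.min(rowSums(mesh$nodes[bottom, 1:2, drop = FALSE]^2))]
  xaxis <- bottom[which.min(abs(mesh$nodes[bottom, 2] -
                                mesh$nodes[o, 2]) +
                            1e3 * (bottom == o))]
  sort(unique(c(fixed, 3L * o - 2L, 3L * o - 1L, 3L * xaxis - 1L)))
}

## brute-force Monte-Carlo per-element density oracle (independent of the
## quadrature path): uniform sampling in each tetrahedron via Dirichlet
## barycentric coordinates
mc_element_density <- function(ct, mesh, calibration, elements,
                               n = 10000, seed = 42) {
  set.seed(seed)
  vapply(elements, function(e) {
    v <- mesh$nodes[mesh$conn[e, 1:4], ]
    g <- matrix(-log(stats::runif(4 * n)), n, 4)
    lam <- g / rowSums(g)
    pts <- lam %*% v
    mean(hu_to_density(calibration, interpolate_hu(ct, pts)))
  }, numeric(1))
}

## random symmetric tensors in 6-component form
random_tensors <- function(n, seed = 1, scale = 1e-3) {
  set.seed(seed)
  matrix(stats::rnorm(6 * n, sd = scale), n, 6)
}

tensor6_to_mat <- function(t6) {
  matrix(c(t6[1], t6[4], t6[6],
           t6[4], t6[2], t6[5],
           t6[6], t6[5], t6[3]), 3, 3)
}
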