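test_that("assembly meshes pass the validity audit", {
  mesh <- tiny_assembly()$mesh
  audit <- mesh_audit(mesh)
  expect_true(audit$ok)
  expect_true(audit$positive_jacobian)
  expect_true(audit$patches_disjoint)
  ## every element references 10 distinct nodes
  expect_true(audit$distinct_nodes)
})

test_that("refining the element size strictly increases element count", {
  fx <- tiny_assembly()
  n_coarse <- nrow(fx$mesh$conn)                      # h = 2.5
  finer <- mesh_assembly(fx$cavity, fx$implant,
                         mesh_settings(1.25, 1.25, roi_offset = 2.5))
  expect_gt(nrow(finer$conn), n_coarse)
  expect_true(mesh_audit(finer)$ok)
})

test_that("bone and implant share every interface node (bonded contact)", {
  mesh <- tiny_assembly()$mesh
  bone_nodes <- unique(as.vector(mesh$conn[mesh$region == "bone", ]))
  imp_nodes <- unique(as.vector(
    mesh$conn[mesh$region %in% c("baseplate", "stem"), ]))
  iface <- mesh$sets$interface
  expect_gt(length(iface), 0)
  expect_true(all(iface %in% bone_nodes))
  expect_true(all(iface %in% imp_nodes))
})

test_that("set tagging matches the geometry", {
  mesh <- tiny_assembly()$mesh
  ## distal fixed nodes all share the minimum z
  zf <- mesh$nodes[mesh$sets$distal_fixed, 3]
  expect_lt(diff(range(zf)), 1e-6)
  expect_equal(min(zf), min(mesh$nodes[, 3]))
  ## ROI elements hug the interface within the configured offset (+ h)
  roi <- mesh$sets$refined_roi
  expect_gt(length(roi), 0)
  cen <- (mesh$nodes[mesh$conn[roi, 1], ] + mesh$nodes[mesh$conn[roi, 2], ] +
          mesh$nodes[mesh$conn[roi, 3], ] +
          mesh$nodes[mesh$conn[roi, 4], ]) / 4
  ip <- mesh$nodes[mesh$sets$interface, , drop = FALSE]
  dmin <- vapply(seq_len(nrow(cen)), function(i)
    sqrt(min(colSums((t(ip) - cen[i, ])^2))), numeric(1))
  expect_lt(max(dmin), 2.5 + 2.5 + 1e-6)   # roi_offset + h slack
})

test_that("an orthogonal-cut assembly has balanced load patches", {
  ## full-size symmetric case (orthogonal cut): one background-grid
  ## column is ~5% of the tray width, so counts balance within 10%
  tib <- generate_phantom_surface(phantom_spec())
  res0 <- resect_tibia(tib, resection_plan(jlo_angle = 0))
  imp0 <- place_implant(build_implant(implant_spec(model_id = 2)), res0)
  cav0 <- carve_cavity(res0, imp0)
  mesh0 <- mesh_assembly(cav0, imp0, mesh_settings(3, 3))
  a_med <- sum(mesh0$patch_faces$medial$proj_area)
  a_lat <- sum(mesh0$patch_faces$lateral$proj_area)
  expect_lt(abs(a_med - a_lat) / max(a_med, a_lat), 0.10)
  nm <- length(mesh0$sets$medial_patch)
  nl <- length(mesh0$sets$lateral_patch)
  expect_lt(abs(nm - nl) / max(nm, nl), 0.10)
})

test_that("meshing a misaligned geometry fails loudly", {
  fx <- tiny_assembly()
  off <- solid_model(function(pts) rep(FALSE, nrow(
    stemfea:::as_points_matrix(pts))),
    bbox = rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_error(mesh_assembly(off, NULL, mesh_settings(3, 3)),
               "no element centroid")
})

test_that("convergence protocol selects and flags correctly", {
  ## constant outputs: the first refinement is accepted
  runs <- list()
  run_const <- function(size) c(stress = 10, strain = 1e-3, rf = 5)
  out <- convergence_study(run_const, c(3, 2, 1.5), tolerance = 0.05)
  expect_true(out$converged)
  expect_equal(out$selected, 2)
  expect_equal(nrow(out$table), 3)
  ## oscillation above tolerance: never converges, finest returned
  flip <- local({ k <- 0; function(size) {
    k <<- k + 1; c(stress = 10 * (1 + 0.2 * (-1)^k)) } })
  out2 <- convergence_study(flip, c(3, 2, 1.5, 1), tolerance = 0.05)
  expect_false(out2$converged)
  expect_equal(out2$selected, 1)
  ## settings validation
  expect_error(mesh_settings(1, 2), "contact_size")
  expect_error(mesh_settings(1, 1, convergence_tolerance = 0.9),
               "tolerance")
})

test_that("region labels alone do not change the mechanical solution", {
  ## the same kept tetrahedra, classified once as bone+implant and once
  ## as a single homogeneous body, give identical displacements: bonded
  ## conformity adds no artificial interface stiffness
  fx <- tiny_assembly()
  union_solid <- solid_model(function(pts) {
    fx$cavity$inside(pts) | fx$implant$inside(pts)
  }, bbox = rbind(pmin(fx$cavity$bbox[1, ], fx$implant$bbox[1, ]),
                  pmax(fx$cavity$bbox[2, ], fx$implant$bbox[2, ])),
  region = "bone")
  mesh_a <- fx$mesh
  mesh_u <- mesh_assembly(union_solid, NULL, mesh_settings(2.5, 2.5))
  expect_equal(nrow(mesh_a$conn), nrow(mesh_u$conn))
  expect_equal(mesh_a$nodes, mesh_u$nodes)
  E0 <- 5000
  mat_a <- data.frame(E = rep(E0, nrow(mesh_a$conn)), nu = 0.3)
  mat_u <- data.frame(E = rep(E0, nrow(mesh_u$conn)), nu = 0.3)
  Ka <- assemble(mesh_a, mat_a)
  Ku <- assemble(mesh_u, mat_u)
  bc <- apply_loads(mesh_a, load_case(3))
  sol_a <- solve_fe(Ka, bc)
  sol_u <- solve_fe(Ku, bc)    # same node numbering: bcs transfer
  rel <- sqrt(sum((sol_a$u - sol_u$u)^2) / sum(sol_a$u^2))
  expect_lt(rel, 0.01)
})

test_that("VTU export writes a well-formed file", {
  mesh <- tiny_assembly()$mesh
  path <- file.path(tempdir(), "mesh-test.vtu")
  write_vtu(mesh, path, cell_data = list(x = seq_len(nrow(mesh$conn))))
  doc <- xml2::read_xml(path)
  expect_identical(xml2::xml_name(doc), "VTKFile")
  piece <- xml2::xml_find_first(doc, ".//Piece")
  expect_equal(as.integer(xml2::xml_attr(piece, "NumberOfCells")),
               nrow(mesh$conn))
  expect_equal(as.integer(xml2::xml_attr(piece, "NumberOfPoints")),
               nrow(mesh$nodes))
  unlink(path)
})
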