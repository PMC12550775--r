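test_that("load cases reproduce the physiological force protocol", {
  cases <- default_load_cases()
  expect_equal(vapply(cases, `[[`, numeric(1), "total_force"),
               c(2250, 3750, 9000))
  expect_true(all(vapply(cases, `[[`, numeric(1),
                         "medial_fraction") == 0.60))
  expect_error(load_case(medial_fraction = 1.2))
})

test_that("stiffness is symmetric, rigid-body-null, and modulus-linear", {
  mesh <- box_mesh()
  mat <- data.frame(E = rep(4000, nrow(mesh$conn)), nu = 0.3)
  K <- assemble(mesh, mat)
  ## symmetry (stored as a symmetric class; verify numerically too)
  expect_lt(max(abs(K - Matrix::t(K))) / max(abs(K)), 1e-12)
  ## rigid translations produce zero force
  n <- nrow(mesh$nodes)
  for (dir in 1:3) {
    u <- numeric(3 * n); u[seq(dir, 3 * n, by = 3)] <- 1
    expect_lt(max(abs(K %*% u)), 1e-8 * max(abs(K)))
  }
  ## rigid rotation about z: u = (-y, x, 0)
  ur <- as.vector(t(cbind(-mesh$nodes[, 2], mesh$nodes[, 1], 0)))
  expect_lt(max(abs(K %*% ur)), 1e-7 * max(abs(K)))
  ## doubling E doubles K
  K2 <- assemble(mesh, data.frame(E = rep(8000, nrow(mesh$conn)),
                                  nu = 0.3))
  expect_lt(max(abs(K2 - 2 * K)) / max(abs(K)), 1e-12)
  ## zero modulus is rejected with the element named
  expect_error(assemble(mesh, data.frame(E = c(0, rep(1, nrow(mesh$conn) -
                                                        1)), nu = 0.3)),
               "modulus")
})

test_that("assembled loads respect totals and the medial share", {
  mesh <- tiny_assembly()$mesh
  bc <- apply_loads(mesh, load_case(3))
  fz <- bc$f[seq(3, length(bc$f), by = 3)]
  ## total applied force magnitude: 3 x 750 = 2250 N
  expect_lt(abs(sum(fz) + 2250), 1e-6)
  ## nothing applied in x or y
  expect_equal(sum(abs(bc$f[seq(1, length(bc$f), by = 3)])), 0)
  expect_equal(sum(abs(bc$f[seq(2, length(bc$f), by = 3)])), 0)
  ## medial share exactly 60% (sum over the medial patch nodes)
  med_dofs <- 3L * mesh$sets$medial_patch
  expect_lt(abs(sum(bc$f[med_dofs]) / sum(fz) - 0.60), 1e-9)
  ## forces act only on patch nodes
  loaded <- which(bc$f != 0)
  patch_dofs <- 3L * c(mesh$sets$medial_patch, mesh$sets$lateral_patch)
  expect_true(all(loaded %in% patch_dofs))
})

test_that("solver satisfies equilibrium and the zero-load identity", {
  mesh <- tiny_assembly()$mesh
  mat <- data.frame(E = rep(3000, nrow(mesh$conn)), nu = 0.3)
  K <- assemble(mesh, mat)
  bc <- apply_loads(mesh, load_case(3))
  sol <- solve_fe(K, bc)
  expect_lt(sol$residual, 1e-8)
  ## zero displacement on fixed dofs
  expect_true(all(sol$u[bc$fixed_dofs] == 0))
  ## global equilibrium: reactions balance applied loads
  R <- reaction_total(sol)
  applied <- c(sum(bc$f[seq(1, length(bc$f), 3)]),
               sum(bc$f[seq(2, length(bc$f), 3)]),
               sum(bc$f[seq(3, length(bc$f), 3)]))
  expect_lt(max(abs(R + applied)) / sum(abs(applied)), 1e-6)
  ## zero load: zero displacement everywhere
  bc0 <- bc; bc0$f <- numeric(length(bc$f))
  sol0 <- solve_fe(K, bc0)
  expect_equal(max(abs(sol0$u)), 0)
})

test_that("prism patch test: uniform compression reproduced exactly", {
  mesh <- box_mesh()            # 12.5 x 12.5 x 22.5 mm prism
  E0 <- 6000; nu0 <- 0.3; p <- 2    # MPa
  mat <- data.frame(E = rep(E0, nrow(mesh$conn)), nu = nu0)
  K <- assemble(mesh, mat)
  f <- box_pressure_loads(mesh, p, z_top = max(mesh$nodes[, 3]))
  ## traction resultant = p * cross-section area
  expect_lt(abs(sum(f) + p * box_top_area(mesh)), 1e-9)
  bc <- list(f = f, fixed_dofs = box_minimal_fixed(mesh))
  sol <- solve_fe(K, bc)
  fields <- recover_fields(mesh, sol$u, mat)
  ## axial stress = -p, axial strain = -p/E in every element (constant
  ## strain state is exactly representable by quadratic tetrahedra)
  expect_lt(max(abs(fields$stress[, 3] + p)) / p, 0.005)
  expect_lt(max(abs(fields$strain[, 3] + p / E0)) / (p / E0), 0.005)
  ## transverse stresses vanish; Poisson expansion nu * p / E
  expect_lt(max(abs(fields$stress[, 1:2])) / p, 0.005)
  expect_lt(max(abs(fields$strain[, 1] - nu0 * p / E0)) / (p / E0), 0.005)
  ## minimum principal strain is the axial compression
  pv <- principal_values(fields$strain)
  expect_lt(max(abs(pv[, 3] + p / E0)) / (p / E0), 0.005)
  ## von Mises equals the uniaxial magnitude; equivalent strain = p/E
  expect_lt(max(abs(von_mises(fields$stress) - p)) / p, 0.005)
  eqv <- equivalent_strain(fields$strain, nu0)
  expect_lt(max(abs(eqv - p / E0)) / (p / E0), 0.005)
})

test_that("response is exactly linear in the applied load", {
  fx <- tiny_assembly()
  mesh <- fx$mesh
  rho <- element_density(fx$ct, mesh)
  mat <- assign_materials(mesh, rho)
  K <- assemble(mesh, mat)
  sol3 <- solve_fe(K, apply_loads(mesh, load_case(3)))
  sol5 <- solve_fe(K, apply_loads(mesh, load_case(5)))
  sol12 <- solve_fe(K, apply_loads(mesh, load_case(12)))
  rel <- function(a, b) sqrt(sum((a - b)^2) / sum(a^2))
  expect_lt(rel(sol12$u, 4 * sol3$u), 1e-9)
  expect_lt(rel(sol5$u, (5 / 3) * sol3$u), 1e-9)
})

test_that("an unconstrained system is reported as singular", {
  mesh <- box_mesh()
  mat <- data.frame(E = rep(1000, nrow(mesh$conn)), nu = 0.3)
  K <- assemble(mesh, mat)
  bc <- list(f = numeric(nrow(K)), fixed_dofs = integer(0))
  expect_error(solve_fe(K, bc), "rigid-body|singular")
  ## one fixed node is not rank-sufficient (rotations remain)
  bc2 <- list(f = box_pressure_loads(mesh, 1, max(mesh$nodes[, 3])),
              fixed_dofs = 1:3)
  suppressWarnings(expect_error(solve_fe(K, bc2), "singular"))
})
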