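## a synthetic volume with a direct functional HU field
field_volume <- function(fun, spacing = c(1, 1, 1), dims = c(20, 20, 20),
                         origin = c(0, 0, 0)) {
  xs <- origin[1] + (seq_len(dims[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(dims[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(dims[3]) - 1) * spacing[3]
  pts <- cbind(rep(xs, times = dims[2] * dims[3]),
               rep(rep(ys, each = dims[1]), times = dims[3]),
               rep(zs, each = dims[1] * dims[2]))
  structure(list(hu = array(fun(pts), dim = dims), spacing = spacing,
                 origin = origin, axis = "xyz", meta = list()),
            class = "ct_volume")
}

test_that("trilinear interpolation is exact where it must be", {
  ct <- field_volume(function(p) p[, 1] + 10 * p[, 2] + 100 * p[, 3])
  ## voxel centre identity
  pts <- cbind(c(3, 7, 11), c(2, 9, 15), c(5, 5, 18))
  expect_equal(interpolate_hu(ct, pts),
               pts[, 1] + 10 * pts[, 2] + 100 * pts[, 3],
               ignore_attr = TRUE, tolerance = 1e-12)
  ## midpoint of two voxel centres along x = mean of the two values
  m <- interpolate_hu(ct, cbind(3.5, 2, 5))
  expect_equal(as.numeric(m), mean(c(3, 4)) + 20 + 500, tolerance = 1e-12)
  ## constant volume is constant anywhere
  cc <- field_volume(function(p) rep(42, nrow(p)))
  expect_equal(as.numeric(interpolate_hu(cc, cbind(4.3, 8.7, 2.2))), 42,
               tolerance = 1e-12)
  ## out-of-bounds points return background and are counted
  v <- interpolate_hu(ct, cbind(-50, 0, 0))
  expect_equal(as.numeric(v), -1000)
  expect_identical(attr(v, "n_outside"), 1L)
})

test_that("quadrature density is exact on constant and affine fields", {
  mesh <- box_mesh()
  calib <- density_calibration(1, 0)   # identity: HU value = density
  ## constant field
  ctc <- field_volume(function(p) rep(0.8, nrow(p)),
                      dims = c(15, 15, 25), origin = c(-2, -2, -2))
  rc <- element_density(ctc, mesh, calib,
                        material_model(density_floor = 0),
                        elements = seq_len(nrow(mesh$conn)))
  expect_lt(max(abs(rc - 0.8)), 1e-9)
  ## affine field: 4-point rule integrates it exactly -> centroid value
  cta <- field_volume(function(p) 0.1 + 0.02 * p[, 1] + 0.015 * p[, 2] +
                        0.01 * p[, 3],
                      dims = c(15, 15, 25), origin = c(-2, -2, -2))
  ra <- element_density(cta, mesh, calib,
                        material_model(density_floor = 0),
                        elements = seq_len(nrow(mesh$conn)))
  cen <- (mesh$nodes[mesh$conn[, 1], ] + mesh$nodes[mesh$conn[, 2], ] +
          mesh$nodes[mesh$conn[, 3], ] + mesh$nodes[mesh$conn[, 4], ]) / 4
  expected <- 0.1 + 0.02 * cen[, 1] + 0.015 * cen[, 2] + 0.01 * cen[, 3]
  expect_lt(max(abs(ra - expected)), 1e-9)
})

test_that("quadrature density matches a dense Monte-Carlo oracle on a
           smooth field", {
  mesh <- box_mesh()
  calib <- density_calibration(1, 0)
  ## smooth radial field centred in the box
  ct <- field_volume(function(p) 0.2 + 0.4 * exp(-((p[, 1] - 5)^2 +
                       (p[, 2] - 5)^2 + (p[, 3] - 10)^2) / 60),
                     dims = c(15, 15, 25), origin = c(-2, -2, -2))
  set.seed(11)
  elems <- sample(nrow(mesh$conn), 40)
  quad <- element_density(ct, mesh, calib,
                          material_model(density_floor = 0),
                          elements = elems)[elems]
  mc <- mc_element_density(ct, mesh, calib, elems, n = 10000)
  expect_lt(max(abs(quad - mc) / mc), 0.01)
})

test_that("density-modulus laws, threshold, and floors behave as specified", {
  m <- material_model()
  ## cancellous law at unit density reads off the coefficient
  expect_equal(density_to_modulus(1.0, m)$E, 6570, tolerance = 1e-12)
  expect_identical(density_to_modulus(1.0, m)$tissue, "cancellous")
  ## zero density hits the modulus floor
  expect_equal(density_to_modulus(0, m)$E, m$modulus_floor)
  ## laws agree at the intersection point
  thr <- find_threshold(m)
  e_cort <- m$cortical_coef * thr^m$cortical_exp
  e_canc <- m$cancellous_coef * thr^m$cancellous_exp
  expect_lt(abs(e_cort - e_canc) / e_canc, 1e-6)
  ## negative density is an error
  expect_error(density_to_modulus(-0.1, m), "negative")
})

test_that("the law intersection reproduces the conventional threshold", {
  ## default laws: close to the 1.68 g/cm^3 cortical/cancellous split
  expect_lt(abs(find_threshold(material_model()) - 1.68) / 1.68, 0.01)
  ## equal coefficients, different exponents: intersection at 1 exactly
  expect_equal(find_threshold(material_model(cortical_coef = 5000,
                                             cancellous_coef = 5000)), 1)
  ## swapping the two laws leaves the intersection unchanged
  m <- material_model()
  ms <- material_model(cortical_coef = m$cancellous_coef,
                       cortical_exp = m$cancellous_exp,
                       cancellous_coef = m$cortical_coef,
                       cancellous_exp = m$cortical_exp)
  expect_equal(find_threshold(ms), find_threshold(m), tolerance = 1e-12)
  ## equal exponents: no unique intersection
  expect_error(find_threshold(material_model(cortical_exp = 1.37)),
               "unique")
})

test_that("modulus law is monotone and threshold = which-law-is-larger", {
  m <- material_model()
  rho <- seq(0, 3, by = 0.002)
  E <- density_to_modulus(rho, m)$E
  expect_true(all(diff(E) >= 0))
  ## classification equivalence for all positive densities
  rho <- rho[rho > 0]
  by_thr <- rho >= m$tissue_threshold
  by_law <- m$cortical_coef * rho^m$cortical_exp >=
    m$cancellous_coef * rho^m$cancellous_exp
  expect_identical(by_thr, by_law)
})

test_that("material assignment fills implant constants exactly", {
  fx <- tiny_assembly()
  mesh <- fx$mesh
  rho <- element_density(fx$ct, mesh)
  mat <- assign_materials(mesh, rho)
  imp <- mesh$region %in% c("baseplate", "stem")
  expect_true(all(mat$E[imp] == 220000))
  expect_true(all(mat$nu[imp] == 0.3))
  expect_true(all(mat$tissue[imp] == "implant"))
  ## dense bone classifies cortical
  expect_identical(density_to_modulus(1.8)$tissue, "cortical")
  ## uniform density -> a single modulus value across bone
  rho_u <- ifelse(mesh$region == "bone", 0.9, NA)
  mat_u <- assign_materials(mesh, rho_u)
  expect_length(unique(mat_u$E[mesh$region == "bone"]), 1L)
  ## missing bone density is an error
  rho_bad <- rho; rho_bad[which(mesh$region == "bone")[1]] <- NA
  expect_error(assign_materials(mesh, rho_bad), "missing")
})
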