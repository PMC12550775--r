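test_that("fracture criterion derives the ultimate strain", {
  fc <- fracture_criterion()
  ## recomputed, never stored independently: 70% of 0.0104
  expect_equal(fc$ultimate_strain,
               fc$fraction * fc$compressive_strain_limit,
               tolerance = 1e-15)
  ## agrees with the conventional rounded value at printed precision
  expect_lt(abs(fc$ultimate_strain - 0.0073), 5e-5)
  fc2 <- fracture_criterion(0.02, 0.5)
  expect_equal(fc2$ultimate_strain, 0.01)
})

test_that("von Mises stress handles canonical states", {
  ## uniaxial
  expect_equal(as.numeric(von_mises(c(7, 0, 0, 0, 0, 0))), 7)
  ## hydrostatic
  expect_equal(as.numeric(von_mises(c(3, 3, 3, 0, 0, 0))), 0)
  ## pure shear tau -> sqrt(3) tau
  expect_equal(as.numeric(von_mises(c(0, 0, 0, 2, 0, 0))), sqrt(3) * 2)
  ## 3x3 input accepted
  expect_equal(as.numeric(von_mises(diag(c(7, 0, 0)))), 7)
})

test_that("principal values agree with a dense eigensolver", {
  t6 <- random_tensors(200, seed = 5)
  pv <- principal_values(t6)
  for (k in sample(200, 25)) {
    ev <- sort(eigen(tensor6_to_mat(t6[k, ]), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    expect_equal(unname(pv[k, ]), ev, tolerance = 1e-10)
  }
  ## sorted descending, trace preserved
  expect_true(all(pv[, 1] >= pv[, 2] & pv[, 2] >= pv[, 3]))
  expect_lt(max(abs(rowSums(pv) - rowSums(t6[, 1:3]))), 1e-12)
  ## simple diagonal case
  expect_equal(unname(principal_values(c(3, 1, 2, 0, 0, 0))[1, ]),
               c(3, 2, 1))
})

test_that("equivalent strain matches its closed forms and is frame
           invariant", {
  expect_equal(as.numeric(equivalent_strain(rep(0, 6))), 0)
  ## uniaxial stress state: equivalent strain = von Mises / E
  E0 <- 9000; nu0 <- 0.3; s <- 4
  eps <- c(s / E0, -nu0 * s / E0, -nu0 * s / E0, 0, 0, 0)
  sig <- c(s, 0, 0, 0, 0, 0)
  expect_equal(as.numeric(equivalent_strain(eps, nu0)),
               as.numeric(von_mises(sig)) / E0, tolerance = 1e-8)
  expect_equal(as.numeric(equivalent_strain(eps, nu0,
                                            method = "stress_ratio",
                                            E = E0, sigma = sig)),
               s / E0, tolerance = 1e-12)
  ## invariance under random rotations
  set.seed(99)
  base <- random_tensors(1, seed = 3)[1, ]
  ref <- as.numeric(equivalent_strain(base, 0.3))
  M <- tensor6_to_mat(base)
  for (k in 1:100) {
    Q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    Mr <- Q %*% M %*% t(Q)
    rot <- c(Mr[1, 1], Mr[2, 2], Mr[3, 3], Mr[1, 2], Mr[2, 3], Mr[1, 3])
    expect_lt(abs(as.numeric(equivalent_strain(rot, 0.3)) - ref) / ref,
              1e-9)
  }
})

test_that("fracture risk is the definitional strain ratio", {
  fc <- fracture_criterion()
  ul <- fc$ultimate_strain
  ## |eps|max at the limit -> 100%; at half the limit -> 50%
  expect_equal(as.numeric(fracture_risk(c(-ul, 0, 0, 0, 0, 0), fc)),
               100, tolerance = 1e-9)
  expect_equal(as.numeric(fracture_risk(c(ul / 2, 0, 0, 0, 0, 0), fc)),
               50, tolerance = 1e-9)
  expect_equal(as.numeric(fracture_risk(rep(0, 6), fc)), 0)
  ## signed option uses the algebraic maximum
  expect_equal(as.numeric(fracture_risk(c(-ul, 0, 0, 0, 0, 0), fc,
                                        signed = "max")), 0,
               tolerance = 1e-9)
})

test_that("strain recovery is consistent and annihilates rigid motion", {
  mesh <- box_mesh()
  mat <- data.frame(E = rep(5000, nrow(mesh$conn)), nu = 0.3)
  ## rigid translation + rotation: zero strain
  n <- nrow(mesh$nodes)
  u <- as.vector(t(cbind(1 - mesh$nodes[, 2] * 0.01,
                         2 + mesh$nodes[, 1] * 0.01,
                         3)))
  f <- recover_fields(mesh, u, mat)
  expect_lt(max(abs(f$strain)), 1e-10)
  ## stress reconstructs from strain through Hooke's law
  set.seed(2)
  ur <- stats::rnorm(3 * n, sd = 1e-3)
  fr <- recover_fields(mesh, ur, mat)
  lam <- 5000 * 0.3 / (1.3 * 0.4); mu <- 5000 / 2.6
  tr <- rowSums(fr$strain[, 1:3])
  expect_lt(max(abs(fr$stress[, 1] - (lam * tr + 2 * mu *
                                        fr$strain[, 1]))), 1e-8)
  expect_lt(max(abs(fr$stress[, 4] - 2 * mu * fr$strain[, 4])), 1e-8)
})

test_that("summary rows scale linearly and respect the ROI", {
  fx <- tiny_assembly()
  mesh <- fx$mesh
  rho <- element_density(fx$ct, mesh)
  mat <- assign_materials(mesh, rho)
  K <- assemble(mesh, mat)
  sol <- solve_fe(K, apply_loads(mesh, load_case(3)))
  fl <- recover_fields(mesh, sol$u, mat)
  cut <- fx$resected$meta$cut
  r1 <- summarize_case(mesh, fl, mat, model_id = 1, case_name = "a",
                       cut = cut)
  ## identical fields give identical rows
  r1b <- summarize_case(mesh, fl, mat, model_id = 2, case_name = "a",
                        cut = cut)
  expect_equal(unlist(r1[, -(1:2)]), unlist(r1b[, -(1:2)]))
  ## scaling the displacement scales every quantity by the same factor
  fl4 <- recover_fields(mesh, 4 * sol$u, mat)
  r4 <- summarize_case(mesh, fl4, mat, model_id = 1, case_name = "a",
                       cut = cut)
  for (q in c("max_von_mises_mpa", "max_equivalent_strain",
              "max_fracture_risk_pct", "roi_median_min_principal_ue",
              "roi_p90_min_principal_ue", "sub_plate_mean_ustrain"))
    expect_equal(r4[[q]], 4 * r1[[q]], tolerance = 1e-9)
  ## ROI percentiles are negative (compressive) micro-strains
  expect_lt(r1$roi_p90_min_principal_ue, 0)
  expect_lte(r1$roi_p90_min_principal_ue, r1$roi_median_min_principal_ue)
})

test_that("a single known tensor summarizes to hand-computed invariants", {
  ## one-element mesh carrying a prescribed strain tensor
  eps <- matrix(c(-1e-3, 2e-4, 5e-4, 1e-4, 0, -2e-4), 1, 6)
  E0 <- 8000; nu0 <- 0.3
  lam <- E0 * nu0 / ((1 + nu0) * (1 - 2 * nu0)); mu <- E0 / (2 * (1 + nu0))
  tr <- sum(eps[1:3])
  sig <- c(lam * tr + 2 * mu * eps[1:3], 2 * mu * eps[4:6])
  ev <- sort(eigen(tensor6_to_mat(eps[1, ]), symmetric = TRUE,
                   only.values = TRUE)$values, decreasing = TRUE)
  expect_equal(as.numeric(principal_values(eps)), ev, tolerance = 1e-12)
  expect_equal(as.numeric(fracture_risk(eps)),
               100 * max(abs(ev)) / fracture_criterion()$ultimate_strain,
               tolerance = 1e-9)
  expect_equal(as.numeric(equivalent_strain(eps, nu0)),
               sqrt(0.5 * ((ev[1] - ev[2])^2 + (ev[2] - ev[3])^2 +
                           (ev[3] - ev[1])^2)) / (1 + nu0),
               tolerance = 1e-12)
  expect_equal(as.numeric(von_mises(matrix(sig, 1))),
               sqrt(0.5 * ((sig[1] - sig[2])^2 + (sig[2] - sig[3])^2 +
                           (sig[3] - sig[1])^2) +
                    3 * sum(sig[4:6]^2)), tolerance = 1e-12)
})
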