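## plane normal of a (near-)planar point loop, via SVD
loop_normal <- function(loop) {
  c0 <- colMeans(loop)
  sv <- svd(sweep(loop, 2, c0))
  n <- sv$v[, 3]
  n / sqrt(sum(n^2))
}

test_that("resection reproduces the configured joint line obliquity", {
  tib <- tiny_assembly()$tibia
  ## orthogonal cut: face normal parallel to the shaft axis
  r0 <- resect_tibia(tib, resection_plan(jlo_angle = 0))
  n0 <- loop_normal(r0$meta$cut$loop)
  expect_lt(abs(abs(sum(n0 * c(0, 0, 1))) - 1), 1e-9)
  ## 3 degree obliquity reproduced within 0.01 degree
  r3 <- resect_tibia(tib, resection_plan(jlo_angle = 3))
  n3 <- loop_normal(r3$meta$cut$loop)
  ang <- acos(abs(sum(n3 * c(0, 0, 1)))) * 180 / pi
  expect_lt(abs(ang - 3), 0.01)
  ## resection removes volume and stays watertight
  a0 <- surface_audit(tib$surface)
  a3 <- surface_audit(r3$surface)
  expect_true(a3$watertight && a3$oriented)
  expect_identical(a3$euler, 2L)
  expect_lt(a3$volume, a0$volume)
})

test_that("resection plan validation and missed-plane errors work", {
  expect_error(resection_plan(depth_below_plateau = 0), "depth")
  expect_error(resection_plan(jlo_angle = 20), "15")
  tib <- tiny_assembly()$tibia
  expect_error(resect_tibia(tib, resection_plan(depth_below_plateau = 500)),
               "does not intersect")
})

test_that("implant geometry honours the configured stem catalog", {
  cat <- implant_catalog()
  expect_identical(cat$stem_length, c(0, 20, 45, 70, 45, 45))
  expect_identical(cat$stem_diameter, c(0, 9, 9, 9, 12.5, 14))
  ## stemless tray: axial extent is exactly the baseplate thickness
  m1 <- build_implant(implant_spec(model_id = 1))
  d1 <- implant_dims(m1)
  expect_equal(d1$axial_extent, m1$meta$spec$baseplate_thickness,
               tolerance = 1e-9)
  expect_identical(d1$stem_extent, 0)
  a1 <- surface_audit(m1$surface)
  expect_true(a1$watertight && a1$oriented)
  ## largest catalog stem: 45 mm x 14 mm read back from the solid
  m6 <- build_implant(implant_spec(model_id = 6))
  d6 <- implant_dims(m6)
  expect_equal(d6$stem_extent, 45, tolerance = 0.01)
  expect_equal(d6$stem_diameter, 14, tolerance = 0.01)
  expect_true(surface_audit(m6$surface)$watertight)
  ## off-catalog pairs warn but proceed; bad ids error
  expect_warning(implant_spec(stem_length = 33, stem_diameter = 8),
                 "off-catalog")
  expect_error(implant_spec(model_id = 9), "valid ids")
})

test_that("doubling the stem diameter quadruples its cross-section", {
  area_at <- function(dia) {
    sp <- suppressWarnings(implant_spec(stem_length = 40,
                                        stem_diameter = dia))
    imp <- build_implant(sp)
    ## sample the mid-stem cross-section (away from fins and taper)
    xs <- seq(-dia, dia, by = 0.02)
    g <- cbind(rep(xs, length(xs)), rep(xs, each = length(xs)), -20)
    sum(imp$inside(g)) * 0.02^2
  }
  a1 <- area_at(6); a2 <- area_at(12)
  expect_equal(a2 / a1, 4, tolerance = 0.02)
})

test_that("cavity volume matches the boolean identity (voxel oracle)", {
  fx <- tiny_assembly()
  h <- 0.4
  bbox <- fx$resected$bbox
  v_bone <- voxel_volume(fx$resected, h, bbox)
  v_cav <- voxel_volume(fx$cavity, h, bbox)
  inter <- function(pts) fx$resected$inside(pts) & fx$implant$inside(pts)
  v_int <- voxel_volume(inter, h, bbox)
  expect_lt(abs(v_cav - (v_bone - v_int)) / v_bone, 0.005)
  ## independent Monte-Carlo volume oracle for the carved solid
  set.seed(7)
  n <- 200000
  pts <- cbind(stats::runif(n, bbox[1, 1], bbox[2, 1]),
               stats::runif(n, bbox[1, 2], bbox[2, 2]),
               stats::runif(n, bbox[1, 3], bbox[2, 3]))
  v_mc <- mean(fx$cavity$inside(pts)) * prod(bbox[2, ] - bbox[1, ])
  expect_lt(abs(v_mc - v_cav) / v_cav, 0.02)
})

test_that("carving is idempotent", {
  fx <- tiny_assembly()
  twice <- carve_cavity(fx$cavity, fx$implant)
  v1 <- voxel_volume(fx$cavity, 0.6, fx$cavity$bbox)
  v2 <- voxel_volume(twice, 0.6, fx$cavity$bbox)
  expect_lt(abs(v1 - v2) / v1, 1e-9)
})

test_that("carved solid boundary extraction is closed and outward", {
  fx <- tiny_assembly()
  surf <- solid_boundary_surface(fx$cavity, h = 1.5)
  a <- surface_audit(surf)
  expect_true(a$watertight)   # closed: bounds a solid, no leaks
  expect_gt(a$volume, 0)      # consistently outward-oriented
  ## its enclosed volume agrees with the implicit voxel oracle
  vox <- voxel_volume(fx$cavity, 1.5, fx$cavity$bbox)
  expect_lt(abs(a$volume - vox) / vox, 0.1)
})

test_that("coverage check flags protrusion and reports the fraction", {
  fx <- tiny_assembly()
  cov <- check_coverage(fx$resected, fx$implant)
  expect_gte(cov$coverage, 0)
  expect_lte(cov$coverage, 1)
  expect_false(cov$protrusion)    # tiny implant well inside the tiny face
  ## implant wider than the cut face protrudes
  wide <- place_implant(build_implant(suppressWarnings(
    implant_spec(stem_length = 0, stem_diameter = 0,
                 baseplate_width = 90, baseplate_depth = 70))),
    fx$resected)
  expect_true(check_coverage(fx$resected, wide)$protrusion)
})

test_that("footprint identical to the cut face gives full coverage", {
  ## synthetic planar cut whose polygon IS the implant footprint outline
  sp <- implant_spec(model_id = 1, baseplate_width = 40,
                     baseplate_depth = 26)
  imp <- build_implant(sp)
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  aw <- 20; ad <- 13; n <- 6
  rb <- ((abs(cos(th)) / aw)^n + (abs(sin(th)) / ad)^n)^(-1 / n)
  loop <- cbind(rb * cos(th), rb * sin(th), 0)
  cut <- list(normal = c(0, 0, 1), centroid = c(0, 0, 0),
              point = c(0, 0, 0), loop = loop)
  cov <- check_coverage(cut, imp)
  expect_equal(cov$coverage, 1, tolerance = 1e-6)
  expect_false(cov$protrusion)
})
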