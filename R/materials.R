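#' HU-to-density calibration
#'
#' Linear quantitative-CT calibration rho = slope * HU + intercept. The
#' default (0.001 g/cm^3 per HU, intercept 1.0) puts water at about
#' 1.0 g/cm^3 and dense cortical bone near 1.8-2.0 g/cm^3; scanner-specific
#' calibrations should be supplied via this constructor.
#'
#' @param slope g/cm^3 per HU (nonzero).
#' @param intercept g/cm^3.
#' @export
density_calibration <- function(slope = 0.001, intercept = 1.0) {
  if (abs(slope) < .Machine$double.eps)
    stop("calibration slope must be nonzero (invertible)")
  structure(list(slope = slope, intercept = intercept),
            class = "density_calibration")
}

#' Apply a calibration to HU values
#' @param calibration a [density_calibration()].
#' @param hu HU values.
#' @return densities in g/cm^3.
#' @export
hu_to_density <- function(calibration, hu)
  calibration$slope * hu + calibration$intercept

#' Density-modulus material model
#'
#' The two power laws map local density (g/cm^3) to Young's modulus (MPa):
#' cortical E = 3890 rho^2.39, cancellous E = 6570 rho^1.37. Tissue above
#' `tissue_threshold` is classified cortical. The default threshold is the
#' density at which the two laws intersect (about 1.68 g/cm^3), which makes
#' threshold classification identical to "whichever law gives the larger
#' modulus". Floors guard against marrow/air voxels caught in the mesh.
#'
#' @param cortical_coef,cortical_exp cortical law parameters (MPa).
#' @param cancellous_coef,cancellous_exp cancellous law parameters (MPa).
#' @param tissue_threshold g/cm^3; NULL (default) uses the law
#'   intersection.
#' @param poisson_bone Poisson ratio for all bone tissue.
#' @param density_floor minimum usable density, g/cm^3.
#' @param modulus_floor minimum usable modulus, MPa.
#' @export
material_model <- function(cortical_coef = 3890, cortical_exp = 2.39,
                           cancellous_coef = 6570, cancellous_exp = 1.37,
                           tissue_threshold = NULL, poisson_bone = 0.3,
                           density_floor = 0.05, modulus_floor = 10) {
  stopifnot(cortical_coef > 0, cancellous_coef > 0,
            poisson_bone > 0, poisson_bone < 0.5)
  m <- structure(list(cortical_coef = cortical_coef,
                      cortical_exp = cortical_exp,
                      cancellous_coef = cancellous_coef,
                      cancellous_exp = cancellous_exp,
                      tissue_threshold = tissue_threshold,
                      poisson_bone = poisson_bone,
                      density_floor = density_floor,
                      modulus_floor = modulus_floor),
                 class = "material_model")
  if (is.null(tissue_threshold)) m$tissue_threshold <- find_threshold(m)
  stopifnot(m$tissue_threshold > 0)
  m
}

#' Implant (CoCrMo) elastic constants
#' @param modulus Young's modulus, MPa (default 220 GPa).
#' @param poisson Poisson ratio.
#' @export
implant_material <- function(modulus = 220e3, poisson = 0.3) {
  stopifnot(modulus > 0)
  structure(list(modulus = modulus, poisson = poisson),
            class = "implant_material")
}

#' Density at which the cortical and cancellous laws intersect
#'
#' Solves cortical_coef * rho^cortical_exp =
#' cancellous_coef * rho^cancellous_exp for the unique positive root,
#' rho* = (cancellous_coef / cortical_coef)^(1 / (cortical_exp -
#' cancellous_exp)). With the default laws rho* is approximately
#' 1.68 g/cm^3, the conventional cortical/cancellous split.
#'
#' @param model a [material_model()].
#' @return rho* in g/cm^3, full precision.
#' @export
find_threshold <- function(model) {
  de <- model$cortical_exp - model$cancellous_exp
  if (abs(de) < 1e-12)
    stop("equal exponents: the laws have no unique intersection")
  (model$cancellous_coef / model$cortical_coef)^(1 / de)
}

#' Map density to Young's modulus
#'
#' @param rho densities, g/cm^3 (non-negative).
#' @param model a [material_model()].
#' @return list with `E` (MPa, floored at `modulus_floor`) and
#'   `tissue` ("cortical"/"cancellous").
#' @export
density_to_modulus <- function(rho, model = material_model()) {
  if (any(rho < 0)) stop("negative density")
  cort <- rho >= model$tissue_threshold
  E <- ifelse(cort, model$cortical_coef * rho^model$cortical_exp,
              model$cancellous_coef * rho^model$cancellous_exp)
  list(E = pmax(E, model$modulus_floor),
       tissue = ifelse(cort, "cortical", "cancellous"))
}

#' Trilinear interpolation of a CT volume at physical points
#'
#' Voxel centres sit at `origin + (index - 1) * spacing`. Points outside
#' the volume (beyond half a voxel from the outer centres) return
#' `background_hu`; an attribute `n_outside` counts them.
#'
#' @param ct a `ct_volume`.
#' @param points n x 3 matrix of physical coordinates, mm.
#' @param background_hu value returned outside the volume.
#' @return numeric HU vector with attribute `n_outside`.
#' @export
interpolate_hu <- function(ct, points, background_hu = -1000) {
  pts <- as_points_matrix(points)
  d <- dim(ct$hu)
  g <- sweep(sweep(pts, 2, ct$origin), 2, ct$spacing, "/") + 1  # voxel coords
  out_of_bounds <- g[, 1] < 0.5 | g[, 1] > d[1] + 0.5 |
                   g[, 2] < 0.5 | g[, 2] > d[2] + 0.5 |
                   g[, 3] < 0.5 | g[, 3] > d[3] + 0.5
  g[, 1] <- pmin(pmax(g[, 1], 1), d[1])
  g[, 2] <- pmin(pmax(g[, 2], 1), d[2])
  g[, 3] <- pmin(pmax(g[, 3], 1), d[3])
  i0 <- pmin(floor(g[, 1]), d[1] - 1); fx <- g[, 1] - i0
  j0 <- pmin(floor(g[, 2]), d[2] - 1); fy <- g[, 2] - j0
  k0 <- pmin(floor(g[, 3]), d[3] - 1); fz <- g[, 3] - k0
  if (d[1] == 1) { i0 <- rep(1, nrow(g)); fx <- 0 }
  if (d[2] == 1) { j0 <- rep(1, nrow(g)); fy <- 0 }
  if (d[3] == 1) { k0 <- rep(1, nrow(g)); fz <- 0 }
  idx <- function(i, j, k) ct$hu[cbind(i, j, k)]
  i1 <- pmin(i0 + 1, d[1]); j1 <- pmin(j0 + 1, d[2]); k1 <- pmin(k0 + 1, d[3])
  v <- idx(i0, j0, k0) * (1 - fx) * (1 - fy) * (1 - fz) +
       idx(i1, j0, k0) * fx * (1 - fy) * (1 - fz) +
       idx(i0, j1, k0) * (1 - fx) * fy * (1 - fz) +
       idx(i1, j1, k0) * fx * fy * (1 - fz) +
       idx(i0, j0, k1) * (1 - fx) * (1 - fy) * fz +
       idx(i1, j0, k1) * fx * (1 - fy) * fz +
       idx(i0, j1, k1) * (1 - fx) * fy * fz +
       idx(i1, j1, k1) * fx * fy * fz
  v[out_of_bounds] <- background_hu
  attr(v, "n_outside") <- sum(out_of_bounds)
  v
}

## Gauss rules on the reference tetrahedron (barycentric points, weights
## summing to 1; multiply by element volume)
tet_gauss_rule <- function(order = 4) {
  if (order == 1) {
    list(pts = matrix(0.25, 1, 4), w = 1)
  } else if (order == 4) {
    a <- (5 + 3 * sqrt(5)) / 20; b <- (5 - sqrt(5)) / 20
    p <- rbind(c(a, b, b, b), c(b, a, b, b), c(b, b, a, b), c(b, b, b, a))
    list(pts = p, w = rep(0.25, 4))
  } else stop("unsupported quadrature order: ", order)
}

#' Per-element density by Gaussian quadrature over the CT volume
#'
#' For each bone element the HU field is sampled at the tetrahedral Gauss
#' points, converted to density by the calibration, and averaged with the
#' quadrature weights: rho_e = sum(w_q rho(x_q)) / sum(w_q). Densities are
#' floored at the model's `density_floor`.
#'
#' @param ct a `ct_volume`.
#' @param mesh a `fea_mesh`.
#' @param calibration a [density_calibration()].
#' @param model a [material_model()] (for the floor).
#' @param order Gauss rule: 1 (centroid) or 4 points (default 4).
#' @param elements element indices to map (default: bone elements).
#' @return numeric per-element density (NA for unmapped elements), with
#'   attribute `n_floored`.
#' @export
element_density <- function(ct, mesh, calibration = density_calibration(),
                            model = material_model(), order = 4,
                            elements = NULL) {
  if (is.null(elements)) elements <- which(mesh$region == "bone")
  rule <- tet_gauss_rule(order)
  conn <- mesh$conn[elements, 1:4, drop = FALSE]
  rho <- rep(NA_real_, nrow(mesh$conn))
  acc <- 0
  for (q in seq_along(rule$w)) {
    lam <- rule$pts[q, ]
    xq <- lam[1] * mesh$nodes[conn[, 1], , drop = FALSE] +
          lam[2] * mesh$nodes[conn[, 2], , drop = FALSE] +
          lam[3] * mesh$nodes[conn[, 3], , drop = FALSE] +
          lam[4] * mesh$nodes[conn[, 4], , drop = FALSE]
    hu <- interpolate_hu(ct, xq)
    acc <- acc + rule$w[q] * hu_to_density(calibration, hu)
  }
  vals <- acc / sum(rule$w)
  floored <- vals < model$density_floor
  vals[floored] <- model$density_floor
  rho[elements] <- vals
  attr(rho, "n_floored") <- sum(floored)
  rho
}

#' Assign per-element elastic properties
#'
#' Bone elements receive the density-mapped modulus and the bone Poisson
#' ratio; baseplate and stem elements receive the implant constants.
#'
#' @param mesh a `fea_mesh`.
#' @param densities per-element density from [element_density()].
#' @param model a [material_model()].
#' @param implant_mat an [implant_material()].
#' @return object of class `element_materials`: data.frame with `E` (MPa),
#'   `nu`, `rho` (g/cm^3), `tissue`.
#' @export
assign_materials <- function(mesh, densities, model = material_model(),
                             implant_mat = implant_material()) {
  ne <- nrow(mesh$conn)
  if (any(is.na(mesh$region))) stop("unlabeled element in mesh")
  bone <- mesh$region == "bone"
  if (any(bone & is.na(densities)))
    stop("density missing for ", sum(bone & is.na(densities)),
         " bone element(s)")
  E <- numeric(ne); nu <- numeric(ne)
  tissue <- character(ne)
  dm <- density_to_modulus(densities[bone], model)
  E[bone] <- dm$E; nu[bone] <- model$poisson_bone; tissue[bone] <- dm$tissue
  E[!bone] <- implant_mat$modulus
  nu[!bone] <- implant_mat$poisson
  tissue[!bone] <- "implant"
  structure(data.frame(E = E, nu = nu, rho = densities, tissue = tissue),
            class = c("element_materials", "data.frame"))
}
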