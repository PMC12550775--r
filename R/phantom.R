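#' Specification of the synthetic tibia phantom
#'
#' The phantom stands in for a patient CT scan: a proximal-tibia-like solid
#' with superelliptical cross-sections lofted along the shaft axis (z,
#' distal at z = 0, plateau at z = shaft_length), a metaphyseal flare, a
#' dense cortical shell and a lower-density cancellous interior with a
#' smooth radial density gradient. Ground-truth density is analytic
#' everywhere, so density-mapping stages can be tested exactly.
#'
#' @param shaft_length total axial length, mm.
#' @param plateau_width medial-lateral width of the plateau, mm.
#' @param plateau_depth antero-posterior depth of the plateau, mm.
#' @param shaft_outer_radius outer radius of the diaphyseal shaft, mm.
#' @param cortical_thickness_proximal shell thickness at the plateau, mm.
#' @param cortical_thickness_distal shell thickness at the distal end, mm.
#' @param cortical_density cortical compartment density, g/cm^3 (must
#'   exceed the cortical/cancellous threshold of 1.68 g/cm^3).
#' @param cancellous_density_center cancellous density on the axis, g/cm^3
#'   (metaphyseal/epiphyseal region).
#' @param cancellous_density_edge cancellous density at the endosteal
#'   boundary, g/cm^3 (both cancellous values must stay below threshold).
#' @param marrow_density apparent bone-equivalent density of the
#'   medullary canal filling the diaphysis, g/cm^3.
#' @param canal_fraction fraction of the length (from distal) fully
#'   occupied by the medullary canal interior.
#' @param canal_transition fraction of the length over which the canal
#'   blends into metaphyseal trabecular bone (smoothstep).
#' @param noise_sd additive CT noise standard deviation, HU (0 disables).
#' @param seed integer RNG seed for the noise field.
#' @param flare_start fraction of the length where the metaphyseal flare
#'   begins (dimensionless, in (0, 1)).
#' @param flare_exponent shape exponent of the flare profile.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shaft_length = 110,
                         plateau_width = 72,
                         plateau_depth = 48,
                         shaft_outer_radius = 13,
                         cortical_thickness_proximal = 1.5,
                         cortical_thickness_distal = 4.5,
                         cortical_density = 1.85,
                         cancellous_density_center = 0.25,
                         cancellous_density_edge = 0.60,
                         marrow_density = 0.08,
                         canal_fraction = 0.55,
                         canal_transition = 0.25,
                         noise_sd = 0,
                         seed = 20250101L,
                         flare_start = 0.60,
                         flare_exponent = 2.5) {
  spec <- list(shaft_length = shaft_length, plateau_width = plateau_width,
               plateau_depth = plateau_depth,
               shaft_outer_radius = shaft_outer_radius,
               cortical_thickness_proximal = cortical_thickness_proximal,
               cortical_thickness_distal = cortical_thickness_distal,
               cortical_density = cortical_density,
               cancellous_density_center = cancellous_density_center,
               cancellous_density_edge = cancellous_density_edge,
               marrow_density = marrow_density,
               canal_fraction = canal_fraction,
               canal_transition = canal_transition,
               noise_sd = noise_sd, seed = as.integer(seed),
               flare_start = flare_start, flare_exponent = flare_exponent)
  validate_phantom_spec(spec)
  structure(spec, class = "phantom_spec")
}

validate_phantom_spec <- function(spec) {
  lens <- c("shaft_length", "plateau_width", "plateau_depth",
            "shaft_outer_radius", "cortical_thickness_proximal",
            "cortical_thickness_distal")
  for (f in lens)
    if (!is.numeric(spec[[f]]) || spec[[f]] <= 0)
      stop("phantom_spec field '", f, "' must be strictly positive")
  if (spec$cortical_thickness_distal >= spec$shaft_outer_radius ||
      spec$cortical_thickness_proximal >= spec$shaft_outer_radius)
    stop("phantom_spec: cortical thickness must be < shaft_outer_radius")
  thr <- 1.68
  if (spec$cortical_density <= thr)
    stop("phantom_spec: cortical_density must exceed the ",
         thr, " g/cm^3 tissue threshold")
  if (spec$cancellous_density_center >= thr ||
      spec$cancellous_density_edge >= thr)
    stop("phantom_spec: cancellous densities must be below the ",
         thr, " g/cm^3 tissue threshold")
  if (spec$marrow_density <= 0 || spec$marrow_density >= thr)
    stop("phantom_spec: marrow_density must be in (0, ", thr, ")")
  if (spec$canal_fraction < 0 || spec$canal_fraction +
      spec$canal_transition > 1)
    stop("phantom_spec: canal profile must fit inside the bone length")
  if (spec$noise_sd < 0) stop("phantom_spec: noise_sd must be >= 0")
  if (spec$flare_start <= 0 || spec$flare_start >= 1)
    stop("phantom_spec: flare_start must be in (0, 1)")
  invisible(spec)
}

#' Scaled-down phantom for fast convergence and CI-style runs
#'
#' Same shape family as [phantom_spec()] at roughly half linear scale, used
#' for mesh-convergence sweeps where the finest sizes would be costly on
#' the full phantom.
#' @param ... overrides passed to [phantom_spec()].
#' @export
coarse_phantom_spec <- function(...) {
  phantom_spec(shaft_length = 55, plateau_width = 36, plateau_depth = 24,
               shaft_outer_radius = 7,
               cortical_thickness_proximal = 1.0,
               cortical_thickness_distal = 2.5, ...)
}

## smooth flare ramp in [0, 1] over z
phantom_ramp <- function(spec, z) {
  s <- (z / spec$shaft_length - spec$flare_start) / (1 - spec$flare_start)
  pmin(pmax(s, 0), 1)^spec$flare_exponent
}

## cross-section half-axes and superellipse exponent at height z
phantom_section <- function(spec, z) {
  f <- phantom_ramp(spec, z)
  list(a = spec$shaft_outer_radius + (spec$plateau_width / 2 - spec$shaft_outer_radius) * f,
       b = spec$shaft_outer_radius + (spec$plateau_depth / 2 - spec$shaft_outer_radius) * f,
       n = 2 + 2 * f)
}

## cortical shell thickness at height z (thick diaphysis, thin metaphysis)
phantom_cortical_thickness <- function(spec, z) {
  f <- phantom_ramp(spec, z)
  spec$cortical_thickness_distal +
    (spec$cortical_thickness_proximal - spec$cortical_thickness_distal) * f
}

## boundary radius along direction theta at height z
phantom_radius <- function(spec, theta, z) {
  sec <- phantom_section(spec, z)
  ((abs(cos(theta)) / sec$a)^sec$n + (abs(sin(theta)) / sec$b)^sec$n)^(-1 / sec$n)
}

## normalized radial coordinate q in [0,1] inside; > 1 outside.
## vectorized over n x 3 point matrix
phantom_q <- function(spec, pts) {
  z <- pts[, 3]
  f <- phantom_ramp(spec, z)
  a <- spec$shaft_outer_radius + (spec$plateau_width / 2 - spec$shaft_outer_radius) * f
  b <- spec$shaft_outer_radius + (spec$plateau_depth / 2 - spec$shaft_outer_radius) * f
  n <- 2 + 2 * f
  ((abs(pts[, 1]) / a)^n + (abs(pts[, 2]) / b)^n)^(1 / n)
}

#' Generate the watertight phantom boundary surface
#'
#' @param spec a [phantom_spec()].
#' @param ntheta angular resolution of the loft.
#' @param nz axial resolution of the loft.
#' @return `fea_solid` with analytic `inside` and a watertight lofted
#'   surface; region tag "bone".
#' @export
generate_phantom_surface <- function(spec, ntheta = 96, nz = 120) {
  validate_phantom_spec(spec)
  th <- seq(0, 2 * pi, length.out = ntheta + 1)[-(ntheta + 1)]
  zs <- seq(0, spec$shaft_length, length.out = nz)
  rings <- lapply(zs, function(z)
    list(z = z, r = phantom_radius(spec, th, z)))
  surf <- polar_loft(rings, ntheta)
  inside <- function(pts) {
    pts <- as_points_matrix(pts)
    ok_z <- pts[, 3] >= 0 & pts[, 3] <= spec$shaft_length
    q <- phantom_q(spec, pts)
    ok_z & q <= 1
  }
  bbox <- rbind(c(-spec$plateau_width / 2, -spec$plateau_depth / 2, 0),
                c(spec$plateau_width / 2, spec$plateau_depth / 2,
                  spec$shaft_length))
  solid_model(inside, surf, region = "bone", bbox = bbox,
              meta = list(spec = spec))
}

#' Ground-truth density field of the phantom
#'
#' Density is `cortical_density` inside the shell (radial distance to the
#' outer boundary below the local shell thickness). Elsewhere inside, the
#' interior blends a smooth quadratic radial gradient (from
#' `cancellous_density_center` on the axis to `cancellous_density_edge`
#' at the endosteal boundary) with the medullary canal: below
#' `canal_fraction` of the length the interior is marrow
#' (`marrow_density`), above `canal_fraction + canal_transition` it is
#' trabecular bone, with a C1 smoothstep blend in between — the axial
#' structure of a long bone. Outside the solid the density is 0.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `density_ground_truth`: list with `density(pts)`
#'   (g/cm^3), `inside(pts)`, and `compartment(pts)` returning
#'   "cortical" / "cancellous" / "outside".
#' @export
phantom_density_field <- function(spec) {
  validate_phantom_spec(spec)
  classify <- function(pts) {
    pts <- as_points_matrix(pts)
    z <- pts[, 3]
    q <- phantom_q(spec, pts)
    inside <- z >= 0 & z <= spec$shaft_length & q <= 1
    theta <- atan2(pts[, 2], pts[, 1])
    rb <- phantom_radius(spec, theta, pmin(pmax(z, 0), spec$shaft_length))
    t <- phantom_cortical_thickness(spec, z)
    depth <- (1 - q) * rb                 # radial distance to outer boundary
    out <- rep("outside", nrow(pts))
    out[inside] <- ifelse(depth[inside] <= t[inside], "cortical", "cancellous")
    out
  }
  density <- function(pts) {
    pts <- as_points_matrix(pts)
    comp <- classify(pts)
    q <- phantom_q(spec, pts)
    rho <- numeric(nrow(pts))
    rho[comp == "cortical"] <- spec$cortical_density
    canc <- comp == "cancellous"
    trabecular <- spec$cancellous_density_center +
      (spec$cancellous_density_edge - spec$cancellous_density_center) *
      pmin(q[canc], 1)^2
    ## medullary canal: smoothstep weight 0 (marrow) -> 1 (trabecular)
    s <- (pts[canc, 3] / spec$shaft_length - spec$canal_fraction) /
      max(spec$canal_transition, 1e-9)
    s <- pmin(pmax(s, 0), 1)
    w <- s * s * (3 - 2 * s)
    rho[canc] <- spec$marrow_density +
      (trabecular - spec$marrow_density) * w
    rho
  }
  structure(list(density = density,
                 inside = function(pts) classify(pts) != "outside",
                 compartment = classify,
                 spec = spec),
            class = "density_ground_truth")
}

#' Describe a CT sampling grid
#'
#' @param dim integer length-3 voxel counts, or NULL to derive from `bbox`.
#' @param spacing voxel size (dx, dy, dz) in mm.
#' @param origin physical coordinate of the centre of voxel (1,1,1), mm.
#' @param bbox optional 2 x 3 bounds used when `dim`/`origin` are NULL.
#' @param margin voxels of padding added around `bbox`.
#' @return list with `dim`, `spacing`, `origin`.
#' @export
ct_grid <- function(dim = NULL, spacing = c(0.449, 0.449, 0.499),
                    origin = NULL, bbox = NULL, margin = 2L) {
  stopifnot(all(spacing > 0))
  if (is.null(dim)) {
    stopifnot(!is.null(bbox))
    ext <- bbox[2, ] - bbox[1, ]
    dim <- as.integer(ceiling(ext / spacing)) + 2L * margin
    origin <- bbox[1, ] - (margin - 0.5) * spacing
  }
  if (is.null(origin)) origin <- c(0, 0, 0)
  list(dim = as.integer(dim), spacing = as.numeric(spacing),
       origin = as.numeric(origin))
}

#' Rasterize the phantom to a CT-like HU volume
#'
#' Inverts the density calibration at every voxel centre inside the
#' phantom (HU = (rho - intercept) / slope), assigns air (-1000 HU)
#' outside, and optionally adds Gaussian HU noise truncated at 4 standard
#' deviations. The paired ground-truth field makes the mapping testable.
#'
#' @param spec a [phantom_spec()].
#' @param calibration a [density_calibration()] (must have nonzero slope).
#' @param grid a [ct_grid()]; default covers the phantom at the standard
#'   0.449 x 0.449 x 0.499 mm voxel spacing.
#' @param background_hu HU value outside the phantom.
#' @return list with `ct` (a `ct_volume`) and `truth`
#'   (a `density_ground_truth`).
#' @export
rasterize_phantom <- function(spec, calibration = density_calibration(),
                              grid = NULL, background_hu = -1000) {
  validate_phantom_spec(spec)
  if (abs(calibration$slope) < .Machine$double.eps)
    stop("density calibration must be invertible (nonzero slope)")
  solid <- NULL
  truth <- phantom_density_field(spec)
  if (is.null(grid)) {
    bbox <- rbind(c(-spec$plateau_width / 2, -spec$plateau_depth / 2, 0),
                  c(spec$plateau_width / 2, spec$plateau_depth / 2,
                    spec$shaft_length))
    grid <- ct_grid(bbox = bbox)
  }
  d <- grid$dim
  xs <- grid$origin[1] + (seq_len(d[1]) - 1) * grid$spacing[1]
  ys <- grid$origin[2] + (seq_len(d[2]) - 1) * grid$spacing[2]
  zs <- grid$origin[3] + (seq_len(d[3]) - 1) * grid$spacing[3]
  hu <- array(background_hu, dim = d)
  set.seed(spec$seed)
  for (k in seq_len(d[3])) {   # slab-wise to bound peak memory
    pts <- cbind(rep(xs, times = d[2]), rep(ys, each = d[1]), zs[k])
    comp <- truth$compartment(pts)
    ins <- comp != "outside"
    slab <- rep(background_hu, nrow(pts))
    if (any(ins)) {
      rho <- truth$density(pts[ins, , drop = FALSE])
      slab[ins] <- (rho - calibration$intercept) / calibration$slope
    }
    if (spec$noise_sd > 0 && any(ins)) {
      ## noise perturbs the tissue voxels; air keeps the exact -1000
      ## convention so downstream masks remain trivial
      nz <- stats::rnorm(sum(ins), sd = spec$noise_sd)
      nz <- pmin(pmax(nz, -4 * spec$noise_sd), 4 * spec$noise_sd)
      slab[ins] <- slab[ins] + nz
    }
    hu[, , k] <- slab
  }
  ct <- structure(list(hu = hu, spacing = grid$spacing,
                       origin = grid$origin, axis = "xyz",
                       meta = list(spec = unclass(spec),
                                   calibration = unclass(calibration),
                                   seed = spec$seed,
                                   background_hu = background_hu)),
                  class = "ct_volume")
  list(ct = ct, truth = truth)
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("<ct_volume>", paste(dim(x$hu), collapse = " x "), "voxels, spacing",
      paste(sprintf("%.3f", x$spacing), collapse = " x "), "mm\n")
  cat("  HU range:", sprintf("%.0f .. %.0f", min(x$hu), max(x$hu)), "\n")
  invisible(x)
}

#' Write a CT volume to NIfTI-1
#' @param ct a `ct_volume`.
#' @param path output path (.nii or .nii.gz).
#' @param sidecar also write a JSON sidecar echoing phantom provenance.
#' @export
write_ct_nifti <- function(ct, path, sidecar = TRUE) {
  img <- RNifti::asNifti(ct$hu)
  RNifti::pixdim(img) <- ct$spacing
  RNifti::writeNifti(img, path)
  if (sidecar && length(ct$meta)) {
    jsonlite::write_json(ct$meta,
                         paste0(sub("\\.nii(\\.gz)?$", "", path), ".json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a NIfTI volume as a `ct_volume`
#' @param path NIfTI file path.
#' @export
read_ct_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  structure(list(hu = array(as.numeric(img), dim = dim(img)),
                 spacing = RNifti::pixdim(img)[1:3],
                 origin = c(0, 0, 0), axis = "xyz", meta = list()),
            class = "ct_volume")
}
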