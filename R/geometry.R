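#' Tibial resection plan
#'
#' The proximal cut removes the damaged plateau: a plane `depth` mm below
#' the plateau at the bone axis, tilted by the joint line obliquity (JLO)
#' about the antero-posterior (y) axis, i.e. in the coronal plane. The cut
#' normal is (sin(jlo), 0, cos(jlo)).
#'
#' @param depth_below_plateau resection depth at the axis, mm (default 2).
#' @param jlo_angle joint line obliquity, degrees (default 3; |angle| < 15).
#' @return object of class `resection_plan`.
#' @export
resection_plan <- function(depth_below_plateau = 2, jlo_angle = 3) {
  if (depth_below_plateau <= 0) stop("resection depth must be > 0")
  if (abs(jlo_angle) >= 15) stop("|jlo_angle| must be < 15 degrees")
  a <- jlo_angle * pi / 180
  structure(list(depth = depth_below_plateau, jlo_angle = jlo_angle,
                 normal = c(sin(a), 0, cos(a))),
            class = "resection_plan")
}

#' Resect the proximal tibia
#'
#' Removes the bone above the oblique cut plane and closes the cut with a
#' planar cap. The cut-face polygon, centroid, and plane are stored in the
#' result's metadata for implant placement and coverage checks.
#'
#' @param tibia `fea_solid` of the intact bone (z up, plateau at max z).
#' @param plan a [resection_plan()].
#' @return resected `fea_solid`; `meta$cut` holds `point`, `normal`,
#'   `centroid`, and the ordered cut polygon (`loop`, k x 3).
#' @export
resect_tibia <- function(tibia, plan) {
  stopifnot(inherits(tibia, "fea_solid"), inherits(plan, "resection_plan"))
  z_top <- tibia$bbox[2, 3]
  p0 <- c(0, 0, z_top - plan$depth)
  n <- plan$normal
  probe <- (tibia$bbox - matrix(p0, 2, 3, byrow = TRUE)) %*% n
  if (all(probe > 0) || all(probe < 0))
    stop("resection plane does not intersect the bone")
  surf <- clip_halfspace(tibia$surface, p0, n)
  loop <- attr(surf, "cap_loop")
  inside0 <- tibia$inside
  inside <- function(pts) {
    pts <- as_points_matrix(pts)
    d <- (pts - matrix(p0, nrow(pts), 3, byrow = TRUE)) %*% n
    inside0(pts) & as.vector(d) <= 0
  }
  centroid <- colMeans(loop)
  bbox <- rbind(apply(surf$vertices, 2, min), apply(surf$vertices, 2, max))
  solid_model(inside, surf, region = "bone", bbox = bbox,
              meta = c(tibia$meta,
                       list(cut = list(point = p0, normal = n,
                                       centroid = centroid, loop = loop,
                                       plan = unclass(plan)))))
}

## ---- implant ---------------------------------------------------------------

#' Extension-stem catalog (the six study configurations)
#'
#' Model 1 is the stemless baseplate; models 2-6 append press-fit stems of
#' 20/45/70 mm length and 9/12.5/14 mm diameter.
#' @return data.frame with `model_id`, `stem_length`, `stem_diameter`.
#' @export
implant_catalog <- function() {
  data.frame(model_id = 1:6,
             stem_length = c(0, 20, 45, 70, 45, 45),
             stem_diameter = c(0, 9, 9, 9, 12.5, 14))
}

#' Parametric implant specification
#'
#' A parametric stand-in for a commercial mobile-bearing tibial tray:
#' rounded-rectangular (superelliptical) baseplate, optional coaxial
#' cylindrical stem with a short distal taper, and four radial fins around
#' a central boss on the stem assembly. Stemless implants (model 1) are a
#' bare baseplate.
#'
#' @param model_id 1-6 selects a catalog row; stem dimensions may also be
#'   given explicitly (off-catalog pairs produce a warning, not an error).
#' @param stem_length stem length below the baseplate, mm.
#' @param stem_diameter stem diameter, mm.
#' @param baseplate_width medial-lateral footprint width, mm. The default
#'   footprint (60 x 40) is the largest tray that maximises coverage of
#'   the default phantom's resection face without protruding (coverage
#'   about 0.82, verified by [check_coverage()]), so the tray rim seats
#'   on the cortical margin as a real tray does.
#' @param baseplate_depth antero-posterior footprint depth, mm.
#' @param baseplate_thickness tray thickness, mm.
#' @param fin_count number of radial fins on the stem boss.
#' @param fin_reach radial extent of the fins from the axis, mm.
#' @param fin_half_thickness fin half-thickness, mm.
#' @param fin_height axial extent of boss + fins below the tray, mm.
#' @param boss_radius radius of the central boss carrying the fins, mm.
#' @param taper_length length of the distal stem taper, mm.
#' @param taper_ratio tip radius as a fraction of the stem radius.
#' @return object of class `implant_spec`.
#' @export
implant_spec <- function(model_id = NULL, stem_length = NULL,
                         stem_diameter = NULL,
                         baseplate_width = 60, baseplate_depth = 40,
                         baseplate_thickness = 4,
                         fin_count = 4, fin_reach = 15,
                         fin_half_thickness = 1.0, fin_height = 9,
                         boss_radius = 8, taper_length = 5,
                         taper_ratio = 0.7) {
  cat <- implant_catalog()
  if (!is.null(model_id)) {
    if (!model_id %in% cat$model_id)
      stop("invalid model_id ", model_id, "; valid ids: ",
           paste(cat$model_id, collapse = ", "))
    row <- cat[cat$model_id == model_id, ]
    if (is.null(stem_length)) stem_length <- row$stem_length
    if (is.null(stem_diameter)) stem_diameter <- row$stem_diameter
  } else {
    if (is.null(stem_length)) stem_length <- 0
    if (is.null(stem_diameter)) stem_diameter <- 0
    hit <- cat$stem_length == stem_length & cat$stem_diameter == stem_diameter
    model_id <- if (any(hit)) cat$model_id[hit][1] else NA_integer_
  }
  if (stem_length > 0) {
    on_cat <- any(cat$stem_length == stem_length &
                  cat$stem_diameter == stem_diameter)
    if (!on_cat)
      warning("stem (", stem_length, " mm x ", stem_diameter,
              " mm) is off-catalog; proceeding")
  }
  if (stem_length > 0 && stem_diameter <= 0)
    stop("a stemmed implant needs stem_diameter > 0")
  structure(list(model_id = model_id, stem_length = stem_length,
                 stem_diameter = stem_diameter,
                 baseplate_width = baseplate_width,
                 baseplate_depth = baseplate_depth,
                 baseplate_thickness = baseplate_thickness,
                 fin_count = fin_count, fin_reach = fin_reach,
                 fin_half_thickness = fin_half_thickness,
                 fin_height = fin_height, boss_radius = boss_radius,
                 taper_length = taper_length, taper_ratio = taper_ratio),
            class = "implant_spec")
}

## radial boundary of the implant cross-section at local height z
## (z = 0 at the baseplate underside, +z toward the tray top)
implant_radius_fun <- function(spec) {
  bp_n <- 6  # superellipse exponent of the tray footprint
  aw <- spec$baseplate_width / 2; ad <- spec$baseplate_depth / 2
  rs <- spec$stem_diameter / 2
  function(theta, z) {
    if (z >= 0) {
      return(((abs(cos(theta)) / aw)^bp_n +
              (abs(sin(theta)) / ad)^bp_n)^(-1 / bp_n))
    }
    if (spec$stem_length <= 0) return(rep(0, length(theta)))
    depth <- -z
    r_stem <- if (depth > spec$stem_length - spec$taper_length) {
      f <- (spec$stem_length - depth) / spec$taper_length
      rs * (spec$taper_ratio + (1 - spec$taper_ratio) * max(f, 0))
    } else rs
    r <- rep(r_stem, length(theta))
    if (depth <= spec$fin_height && spec$fin_count > 0) {
      r <- pmax(r, spec$boss_radius)
      for (k in seq_len(spec$fin_count)) {
        thk <- pi / spec$fin_count + (k - 1) * 2 * pi / spec$fin_count
        dth <- abs(sin(theta - thk))
        rf <- pmin(spec$fin_reach, spec$fin_half_thickness / pmax(dth, 1e-9))
        r <- pmax(r, rf)
      }
    }
    r
  }
}

#' Build the implant solid in its local frame
#'
#' Local frame: origin at the centre of the baseplate underside, +z through
#' the tray, stem extending toward -z. Use [place_implant()] to position it
#' on a resected bone.
#'
#' @param spec an [implant_spec()].
#' @param ntheta angular loft resolution.
#' @return `fea_solid`, region "implant".
#' @export
build_implant <- function(spec, ntheta = 96) {
  stopifnot(inherits(spec, "implant_spec"))
  rf <- implant_radius_fun(spec)
  th <- seq(0, 2 * pi, length.out = ntheta + 1)[-(ntheta + 1)]
  t <- spec$baseplate_thickness
  eps <- 1e-9
  rings <- list()
  add <- function(z, zq = z) rings[[length(rings) + 1L]] <<- list(z = z, r = rf(th, zq))
  if (spec$stem_length > 0) {
    zs <- sort(unique(c(-spec$stem_length,
                        -spec$stem_length + spec$taper_length,
                        seq(-spec$stem_length, -spec$fin_height, length.out = 8),
                        -spec$fin_height)))
    for (z in zs) add(z, z + eps)      # sample just above (stem side)
    add(-spec$fin_height + eps, -spec$fin_height + eps)  # fin band start
    add(-eps, -eps)                    # fin band end
    add(0, 0)                          # jump to tray footprint
  } else {
    add(0, 0)
  }
  add(t, t - eps)
  surf <- polar_loft(rings, ntheta)
  inside <- function(pts) {
    pts <- as_points_matrix(pts)
    r <- sqrt(pts[, 1]^2 + pts[, 2]^2)
    theta <- atan2(pts[, 2], pts[, 1])
    z <- pts[, 3]
    out <- logical(nrow(pts))
    up <- z >= 0 & z <= t
    if (any(up)) out[up] <- r[up] <= rf(theta[up], 0.5 * t)
    if (spec$stem_length > 0) {
      dn <- z < 0 & z >= -spec$stem_length
      if (any(dn)) {
        depth <- -z[dn]
        rs <- spec$stem_diameter / 2
        taper_f <- pmin(pmax((spec$stem_length - depth) / spec$taper_length,
                             0), 1)
        allow <- rs * (spec$taper_ratio + (1 - spec$taper_ratio) * taper_f)
        finband <- depth <= spec$fin_height
        if (any(finband) && spec$fin_count > 0) {
          af <- pmax(allow[finband], spec$boss_radius)
          thf <- theta[dn][finband]
          for (k in seq_len(spec$fin_count)) {
            thk <- pi / spec$fin_count + (k - 1) * 2 * pi / spec$fin_count
            dth <- abs(sin(thf - thk))
            af <- pmax(af, pmin(spec$fin_reach,
                                spec$fin_half_thickness / pmax(dth, 1e-9)))
          }
          allow[finband] <- af
        }
        out[dn] <- r[dn] <= allow
      }
    }
    out
  }
  ext <- max(spec$baseplate_width, spec$baseplate_depth) / 2
  bbox <- rbind(c(-ext, -ext, -spec$stem_length), c(ext, ext, t))
  solid_model(inside, surf, region = "implant", bbox = bbox,
              meta = list(spec = spec))
}

#' Axial extent and stem diameter read back from an implant solid
#' @param implant `fea_solid` from [build_implant()].
#' @return list with `axial_extent`, `stem_extent`, `stem_diameter` (mm;
#'   stem entries 0 for stemless implants), measured from the surface mesh.
#' @export
implant_dims <- function(implant) {
  v <- implant$surface$vertices
  spec <- implant$meta$spec
  zr <- range(v[, 3])
  out <- list(axial_extent = diff(zr), stem_extent = 0, stem_diameter = 0)
  if (spec$stem_length > 0) {
    out$stem_extent <- -zr[1]
    shaft <- v[, 3] < -spec$fin_height - 1e-6 &
             v[, 3] > -(spec$stem_length - spec$taper_length) + 1e-6
    if (any(shaft))
      out$stem_diameter <- 2 * max(sqrt(v[shaft, 1]^2 + v[shaft, 2]^2))
  }
  out
}

#' Place an implant on a resected tibia
#'
#' The implant is rigidly transformed so its baseplate underside lies flush
#' on the resection plane (local +z maps to the cut normal) with the tray
#' centred on the cut-face centroid; the stem extends into the bone.
#'
#' @param implant `fea_solid` from [build_implant()].
#' @param resected resected bone from [resect_tibia()] (provides the cut).
#' @return placed `fea_solid`; `meta$transform` is the 4 x 4 local-to-world
#'   matrix, `meta$cut` echoes the cut plane.
#' @export
place_implant <- function(implant, resected) {
  cut <- resected$meta$cut
  if (is.null(cut)) stop("resected solid carries no cut metadata")
  n <- cut$normal
  ## rotation about +y taking (0,0,1) to n = (sin a, 0, cos a)
  a <- atan2(n[1], n[3])
  R <- rbind(c(cos(a), 0, sin(a)), c(0, 1, 0), c(-sin(a), 0, cos(a)))
  c0 <- cut$centroid
  inside_local <- implant$inside
  inside <- function(pts) {
    pts <- as_points_matrix(pts)
    local <- (pts - matrix(c0, nrow(pts), 3, byrow = TRUE)) %*% R
    inside_local(local)
  }
  v <- implant$surface$vertices %*% t(R) +
    matrix(c0, nrow(implant$surface$vertices), 3, byrow = TRUE)
  surf <- list(vertices = v, faces = implant$surface$faces)
  bbox <- rbind(apply(v, 2, min), apply(v, 2, max))
  tf <- rbind(cbind(R, c0), c(0, 0, 0, 1))
  solid_model(inside, surf, region = "implant", bbox = bbox,
              meta = c(implant$meta,
                       list(transform = tf, cut = cut)))
}

#' Carve the implant cavity out of the resected bone
#'
#' Implicit boolean difference `bone \ implant`; the bone membership test
#' becomes "in resected bone and not in implant", so the cavity conforms
#' exactly to the implant for bonded (conformal) meshing. An explicit
#' watertight boundary surface can be extracted by voxelized boundary
#' reconstruction when requested.
#'
#' @param tibia_cut resected bone `fea_solid`.
#' @param implant placed implant `fea_solid`.
#' @param surface_h if non-NULL, also extract a boundary surface at this
#'   voxel pitch (mm).
#' @return bone-with-cavity `fea_solid`.
#' @export
carve_cavity <- function(tibia_cut, implant, surface_h = NULL) {
  in_bone <- tibia_cut$inside; in_imp <- implant$inside
  inside <- function(pts) {
    pts <- as_points_matrix(pts)
    in_bone(pts) & !in_imp(pts)
  }
  out <- solid_model(inside, surface = NULL, region = "bone",
                     bbox = tibia_cut$bbox,
                     meta = c(tibia_cut$meta,
                              list(implant_spec = implant$meta$spec,
                                   transform = implant$meta$transform)))
  if (!is.null(surface_h)) out$surface <- solid_boundary_surface(out, surface_h)
  out
}

#' Extract a closed boundary surface of an implicit solid by voxelization
#'
#' Tetrahedralizes the voxel interior (Kuhn subdivision) and returns the
#' boundary triangles of the kept tetrahedra — closed and consistently
#' outward-oriented by construction (staircase resolution `h`).
#'
#' @param solid `fea_solid`.
#' @param h voxel pitch, mm.
#' @return surface list (`vertices`, `faces`).
#' @export
solid_boundary_surface <- function(solid, h = 1.5) {
  gm <- grid_tets(solid$bbox, h)
  keep <- solid$inside(gm$centroids)
  tets <- gm$tets[keep, , drop = FALSE]
  ## vertex-/edge-only appendages would pinch the boundary; keep the
  ## dominant face-connected body (same rule as the mesher)
  tets <- tets[in_main_face_component(tets), , drop = FALSE]
  faces <- rbind(tets[, c(1, 3, 2)], tets[, c(1, 2, 4)],
                 tets[, c(2, 3, 4)], tets[, c(1, 4, 3)])
  key <- paste(pmin(pmin(faces[, 1], faces[, 2]), faces[, 3]),
               faces[, 1] + faces[, 2] + faces[, 3],
               pmax(pmax(faces[, 1], faces[, 2]), faces[, 3]))
  tab <- table(key)
  bnd <- faces[key %in% names(tab)[tab == 1L], , drop = FALSE]
  compact_surface(list(vertices = gm$nodes, faces = bnd))
}

#' Check baseplate coverage of the resection face
#'
#' Coverage is the fraction of the cut-face area covered by the implant
#' footprint (deterministic grid sampling in the cut plane); protrusion is
#' flagged iff any footprint boundary point falls more than
#' `protrusion_tol` outside the cut-face polygon (the tolerance absorbs
#' the chordal error of the polygonal cut loop).
#'
#' @param resected resected bone (supplies `meta$cut`); alternatively a
#'   `cut` list with `loop`, `centroid`, `normal`.
#' @param implant placed implant `fea_solid`.
#' @param n_grid sampling resolution across the cut face.
#' @param protrusion_tol allowed overhang, mm.
#' @return list with `coverage` in [0, 1] and `protrusion` logical.
#' @export
check_coverage <- function(resected, implant, n_grid = 160,
                           protrusion_tol = 0.25) {
  cut <- if (inherits(resected, "fea_solid")) resected$meta$cut else resected
  if (is.null(cut)) stop("no cut-face metadata available")
  n <- cut$normal
  e1 <- c(n[3], 0, -n[1]); e1 <- e1 / sqrt(sum(e1^2))  # in-plane medial axis
  e2 <- c(0, 1, 0)
  toplane <- function(p3) {
    rel <- p3 - matrix(cut$centroid, nrow(p3), 3, byrow = TRUE)
    cbind(rel %*% e1, rel %*% e2)
  }
  loop2 <- toplane(cut$loop)
  spec <- implant$meta$spec
  bp_n <- 6; aw <- spec$baseplate_width / 2; ad <- spec$baseplate_depth / 2
  in_foot <- function(uv)
    (abs(uv[, 1]) / aw)^bp_n + (abs(uv[, 2]) / ad)^bp_n <= 1
  rng_u <- range(loop2[, 1]); rng_v <- range(loop2[, 2])
  us <- seq(rng_u[1], rng_u[2], length.out = n_grid)
  vs <- seq(rng_v[1], rng_v[2], length.out = n_grid)
  g <- cbind(rep(us, times = n_grid), rep(vs, each = n_grid))
  in_face <- mgcv::in.out(rbind(loop2, loop2[1, ]), g)
  coverage <- if (any(in_face)) mean(in_foot(g[in_face, , drop = FALSE])) else 0
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  rb <- ((abs(cos(th)) / aw)^bp_n + (abs(sin(th)) / ad)^bp_n)^(-1 / bp_n)
  foot_bnd <- cbind((rb - protrusion_tol) * cos(th),
                    (rb - protrusion_tol) * sin(th))
  protrusion <- !all(mgcv::in.out(rbind(loop2, loop2[1, ]), foot_bnd))
  list(coverage = coverage, protrusion = protrusion)
}
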