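#' Periprosthetic fracture-risk criterion
#'
#' The ultimate strain limit is taken as a fixed fraction (70%) of the
#' compressive strain limit of bone (0.0104), i.e. 0.0073. Fracture risk
#' is the peak principal-strain magnitude over that limit, in percent.
#'
#' @param compressive_strain_limit compressive strain capacity of bone.
#' @param fraction fraction of the compressive limit taken as ultimate.
#' @export
fracture_criterion <- function(compressive_strain_limit = 0.0104,
                               fraction = 0.70) {
  structure(list(compressive_strain_limit = compressive_strain_limit,
                 fraction = fraction,
                 ultimate_strain = fraction * compressive_strain_limit),
            class = "fracture_criterion")
}

#' Recover element strain and stress fields from a solution
#'
#' Strains come from the shape-function gradients at the Gauss points,
#' volume-averaged per element; stresses follow from isotropic Hooke's
#' law with the element's (E, nu). Tensor components are ordered
#' (xx, yy, zz, xy, yz, xz) with tensor (not engineering) shear.
#'
#' @param mesh a `fea_mesh`.
#' @param u displacement vector (3n) from [solve_fe()].
#' @param materials an `element_materials`.
#' @return object of class `tensor_field`: list with `strain` (ne x 6),
#'   `stress` (ne x 6, MPa).
#' @export
recover_fields <- function(mesh, u, materials) {
  eps <- tet10_strains(mesh$nodes, mesh$conn, u)
  E <- materials$E; nu <- materials$nu
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  tr <- eps[, 1] + eps[, 2] + eps[, 3]
  sig <- cbind(lam * tr + 2 * mu * eps[, 1],
               lam * tr + 2 * mu * eps[, 2],
               lam * tr + 2 * mu * eps[, 3],
               2 * mu * eps[, 4], 2 * mu * eps[, 5], 2 * mu * eps[, 6])
  colnames(eps) <- colnames(sig) <- c("xx", "yy", "zz", "xy", "yz", "xz")
  structure(list(strain = eps, stress = sig), class = "tensor_field")
}

as_tensor6 <- function(t) {
  if (is.matrix(t) && ncol(t) == 6) return(t)
  if (is.matrix(t) && all(dim(t) == c(3, 3)))
    return(matrix(c(t[1, 1], t[2, 2], t[3, 3], t[1, 2], t[2, 3], t[1, 3]),
                  1, 6))
  if (is.numeric(t) && length(t) == 6) return(matrix(t, 1, 6))
  stop("expected a 6-component symmetric tensor (or n x 6 matrix)")
}

#' Principal values of symmetric tensors (descending)
#' @param t n x 6 tensor rows (xx, yy, zz, xy, yz, xz), a length-6 vector,
#'   or a 3 x 3 symmetric matrix.
#' @return n x 3 matrix of eigenvalues, columns e1 >= e2 >= e3.
#' @export
principal_values <- function(t) {
  out <- sym3_eigenvalues(as_tensor6(t))
  colnames(out) <- c("e1", "e2", "e3")
  out
}

#' Principal strains (sorted descending)
#' @inheritParams principal_values
#' @export
principal_strains <- principal_values

#' Von Mises equivalent stress
#' @param sigma stress tensor(s): n x 6 rows, length-6 vector, or 3 x 3.
#' @return scalar stress per row, MPa.
#' @export
von_mises <- function(sigma) {
  s <- as_tensor6(sigma)
  sqrt(0.5 * ((s[, 1] - s[, 2])^2 + (s[, 2] - s[, 3])^2 +
              (s[, 3] - s[, 1])^2) +
       3 * (s[, 4]^2 + s[, 5]^2 + s[, 6]^2))
}

#' Equivalent elastic strain
#'
#' Von-Mises-type strain invariant with the customary 1/(1 + nu) factor on
#' the principal-strain differences (the convention of mainstream FE
#' post-processors); `method = "stress_ratio"` instead returns
#' von_mises(sigma)/E, identical for uniaxial stress states.
#'
#' @param eps strain tensor(s): n x 6 rows, length-6 vector, or 3 x 3.
#' @param nu Poisson ratio (scalar or per row).
#' @param method "principal" (default) or "stress_ratio".
#' @param E,sigma required for `method = "stress_ratio"`.
#' @export
equivalent_strain <- function(eps, nu = 0.3, method = c("principal",
                                                        "stress_ratio"),
                              E = NULL, sigma = NULL) {
  method <- match.arg(method)
  if (method == "stress_ratio") {
    stopifnot(!is.null(E), !is.null(sigma))
    return(von_mises(sigma) / E)
  }
  e <- principal_values(eps)
  sqrt(0.5 * ((e[, 1] - e[, 2])^2 + (e[, 2] - e[, 3])^2 +
              (e[, 3] - e[, 1])^2)) / (1 + nu)
}

#' Strain-based fracture risk, percent
#'
#' RF = 100 x |principal strain|_max / ultimate strain. The limit derives
#' from the compressive capacity of bone, and the reference loading is
#' compressive, so the magnitude of the extreme principal strain (tensile
#' or compressive) is used; set `signed = "max"` to use the algebraic
#' maximum principal strain instead.
#'
#' @param eps strain tensor(s), any form accepted by [principal_values()].
#' @param criterion a [fracture_criterion()].
#' @param signed "abs" (default) or "max".
#' @return RF per element, percent.
#' @export
fracture_risk <- function(eps, criterion = fracture_criterion(),
                          signed = c("abs", "max")) {
  signed <- match.arg(signed)
  e <- principal_values(eps)
  peak <- if (signed == "abs") pmax(abs(e[, 1]), abs(e[, 3])) else e[, 1]
  100 * peak / criterion$ultimate_strain
}

#' Summarize one solved model under one load case
#'
#' Computes the per-configuration record: maxima over bone elements of von
#' Mises stress, equivalent elastic strain and fracture risk, plus the
#' median and 90th-percentile (by magnitude, linear-interpolation
#' estimator) minimum principal micro-strain over the refined
#' region-of-interest bone elements, reported as negative (compressive)
#' values. `sub_plate_mean_ustrain` is the mean |minimum principal strain|
#' in bone within `sub_plate_depth` mm below the resection plane, the
#' quantity that makes proximal stress shielding visible.
#'
#' @param mesh a `fea_mesh`.
#' @param fields a `tensor_field` from [recover_fields()].
#' @param materials an `element_materials`.
#' @param criterion a [fracture_criterion()].
#' @param model_id,case_name identifiers copied into the row.
#' @param cut optional cut-plane list (`point`, `normal`) enabling the
#'   sub-baseplate strain summary.
#' @param sub_plate_depth depth of the sub-baseplate band, mm.
#' @param support_margin bone elements whose centroid lies within this
#'   distance (mm) of the distal support plane are excluded from the
#'   reported maxima: the fully fixed truncation boundary carries an
#'   artificial stress concentration (St-Venant margin). Percentile and
#'   band statistics are unaffected.
#' @param min_structural_density reported maxima are taken over elements
#'   of structural bone only: mapped density at or above this value
#'   (g/cm^3, default 0.2 — above marrow, below any trabecular bone). A
#'   strain or fracture-risk extremum inside the medullary marrow is not
#'   a bone-fracture signal, and the near-floor marrow modulus makes such
#'   extrema mesh-divergent at re-entrant implant corners. ROI
#'   percentiles and band statistics keep all bone-region elements.
#' @return one-row data.frame (a summary row).
#' @export
summarize_case <- function(mesh, fields, materials,
                           criterion = fracture_criterion(),
                           model_id = NA, case_name = NA, cut = NULL,
                           sub_plate_depth = 5, support_margin = 6,
                           min_structural_density = 0.2) {
  bone <- mesh$region == "bone"
  if (!any(bone)) stop("no bone elements to summarize")
  cen_z <- (mesh$nodes[mesh$conn[, 1], 3] + mesh$nodes[mesh$conn[, 2], 3] +
            mesh$nodes[mesh$conn[, 3], 3] + mesh$nodes[mesh$conn[, 4], 3]) / 4
  zmin <- min(mesh$nodes[, 3])
  away <- bone & cen_z > zmin + support_margin
  if (!is.null(materials$rho))
    away <- away & !is.na(materials$rho) &
      materials$rho >= min_structural_density
  if (!any(away)) away <- bone
  eps_b <- fields$strain[away, , drop = FALSE]
  sig_b <- fields$stress[away, , drop = FALSE]
  pv <- principal_values(eps_b)
  vm <- von_mises(sig_b)
  eqv <- equivalent_strain(eps_b, nu = materials$nu[away])
  rf <- 100 * pmax(abs(pv[, 1]), abs(pv[, 3])) / criterion$ultimate_strain

  roi <- mesh$sets$refined_roi
  med_ue <- p90_ue <- NA_real_
  if (!is.null(roi) && length(roi)) {
    roi_bone <- intersect(roi, which(bone))
    if (length(roi_bone)) {
      e3 <- principal_values(fields$strain[roi_bone, , drop = FALSE])[, 3]
      mag <- abs(e3) * 1e6
      med_ue <- -unname(stats::quantile(mag, 0.5, type = 7))
      p90_ue <- -unname(stats::quantile(mag, 0.9, type = 7))
    }
  }

  sub_mean <- NA_real_
  if (!is.null(cut)) {
    cen <- (mesh$nodes[mesh$conn[, 1], ] + mesh$nodes[mesh$conn[, 2], ] +
            mesh$nodes[mesh$conn[, 3], ] + mesh$nodes[mesh$conn[, 4], ]) / 4
    dist <- as.vector((cen - matrix(cut$point, nrow(cen), 3,
                                    byrow = TRUE)) %*% cut$normal)
    band <- bone & dist < 0 & dist > -sub_plate_depth
    if (any(band)) {
      e3b <- principal_values(fields$strain[band, , drop = FALSE])[, 3]
      sub_mean <- mean(abs(e3b)) * 1e6
    }
  }

  data.frame(model_id = model_id, case = case_name,
             max_von_mises_mpa = max(vm),
             max_equivalent_strain = max(eqv),
             max_fracture_risk_pct = max(rf),
             roi_median_min_principal_ue = med_ue,
             roi_p90_min_principal_ue = p90_ue,
             sub_plate_mean_ustrain = sub_mean,
             stringsAsFactors = FALSE)
}

#' Arrange summary rows in the reference table layout
#'
#' Cases as row blocks, models as columns, one sub-row per output
#' quantity.
#'
#' @param rows data.frame of summary rows (one per model x case).
#' @return data.frame in wide layout.
#' @export
summary_table <- function(rows) {
  qty <- c(max_von_mises_mpa = "Von Mises stress (max, MPa)",
           max_equivalent_strain = "Equivalent elastic strain (max)",
           max_fracture_risk_pct = "Risk of fracture (max, %)",
           roi_median_min_principal_ue =
             "Min principal micro-strain (ROI median)",
           roi_p90_min_principal_ue =
             "Min principal micro-strain (ROI 90th pct)")
  cases <- unique(rows$case)
  models <- sort(unique(rows$model_id))
  out <- list()
  for (cs in cases) {
    for (q in names(qty)) {
      vals <- vapply(models, function(m) {
        v <- rows[rows$case == cs & rows$model_id == m, q]
        if (length(v)) v else NA_real_
      }, numeric(1))
      out[[length(out) + 1L]] <-
        data.frame(case = cs, quantity = qty[[q]],
                   t(matrix(vals, dimnames = list(paste0("model_", models),
                                                  NULL))),
                   check.names = FALSE)
    }
  }
  do.call(rbind, out)
}
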