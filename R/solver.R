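#' Physiological load case
#'
#' Axial compressive loading expressed as a body-weight multiple: walking
#' single-leg support (3 BW), sit-to-stand / stairs (5 BW), running
#' (12 BW), at 750 N body weight, with 60% of the force on the medial
#' plateau and 40% on the lateral plateau.
#'
#' @param bw_multiple body-weight multiple.
#' @param body_weight body weight, N.
#' @param medial_fraction fraction of the force on the medial plateau.
#' @param name label.
#' @export
load_case <- function(bw_multiple = 3, body_weight = 750,
                      medial_fraction = 0.60,
                      name = paste0(bw_multiple, "BW")) {
  stopifnot(medial_fraction >= 0, medial_fraction <= 1, body_weight > 0)
  structure(list(bw_multiple = bw_multiple, body_weight = body_weight,
                 medial_fraction = medial_fraction, name = name,
                 total_force = bw_multiple * body_weight),
            class = "load_case")
}

#' The three reference load cases (3, 5, 12 BW)
#' @param body_weight body weight, N.
#' @param medial_fraction medial load share.
#' @export
default_load_cases <- function(body_weight = 750, medial_fraction = 0.60)
  lapply(c(3, 5, 12), load_case, body_weight = body_weight,
         medial_fraction = medial_fraction)

#' Assemble the global TET10 stiffness matrix
#'
#' Isoparametric small-strain elasticity with a 4-point Gauss rule;
#' returned as a sparse symmetric matrix over the 3n displacement dofs
#' (dof order: x1, y1, z1, x2, ...).
#'
#' @param mesh a `fea_mesh`.
#' @param materials an `element_materials` (or list with per-element
#'   vectors `E`, `nu`).
#' @param chunk elements per assembly block (bounds the peak size of the
#'   triplet buffers; the result is identical for any chunking).
#' @return `dsCMatrix` stiffness, MPa mm (N/mm).
#' @export
assemble <- function(mesh, materials, chunk = 8000L) {
  E <- materials$E; nu <- materials$nu
  if (any(E <= 0)) stop("zero-modulus element(s): ",
                        paste(utils::head(which(E <= 0)), collapse = ", "))
  ndof <- 3L * nrow(mesh$nodes)
  ne <- nrow(mesh$conn)
  K <- NULL
  for (s in seq(1L, ne, by = chunk)) {
    idx <- s:min(s + chunk - 1L, ne)
    tr <- tet10_stiffness_triplets(mesh$nodes,
                                   mesh$conn[idx, , drop = FALSE],
                                   E[idx], nu[idx])
    Kc <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                               dims = c(ndof, ndof), symmetric = TRUE)
    K <- if (is.null(K)) Kc else K + Kc
    rm(tr, Kc)
  }
  K
}

#' Build boundary conditions for a load case
#'
#' The distal node set is fully fixed. The load-case force is applied as a
#' uniform downward (-z, i.e. along the mechanical axis) pressure on the
#' medial and lateral superior-baseplate patches, scaled so the medial
#' patch carries `medial_fraction` of the total. The pressure acts per
#' unit z-projected face area (statically equivalent to a uniform
#' vertical pressure on the tray footprint, robust to the staircase
#' boundary of the background-grid mesh) and is converted to consistent
#' nodal forces of the quadratic face shape functions (for a
#' straight-edged 6-node triangle under uniform traction: corner weights
#' 0, midside weights A/3). Nodal sums over each patch node set are then
#' renormalised so the medial set carries exactly its configured share
#' (faces adjacent across the sagittal split deposit on shared nodes).
#'
#' @param mesh a `fea_mesh` with tagged patches.
#' @param case a [load_case()].
#' @return object of class `boundary_conditions`: list with `f` (3n force
#'   vector, N), `fixed_dofs`, `case`, and per-patch force sums.
#' @export
apply_loads <- function(mesh, case) {
  if (is.null(mesh$patch_faces$medial) ||
      !nrow(mesh$patch_faces$medial$faces) ||
      is.null(mesh$patch_faces$lateral) ||
      !nrow(mesh$patch_faces$lateral$faces))
    stop("empty load patch; mesh an implanted assembly first")
  ndof <- 3L * nrow(mesh$nodes)
  f <- numeric(ndof)
  add_patch <- function(patch, force) {
    faces <- patch$faces
    area <- patch$proj_area
    ftot <- sum(area)
    for (m in 4:6) {
      dz <- 3L * faces[, m]          # z dof of midside node (1-based)
      contrib <- -force * area / (3 * ftot)   # pressure x A/3 per midside
      ## accumulate (nodes may appear in several faces)
      tap <- tapply(contrib, dz, sum)
      idx <- as.integer(names(tap))
      f[idx] <<- f[idx] + as.numeric(tap)
    }
    ftot
  }
  fm <- case$total_force * case$medial_fraction
  fl <- case$total_force - fm
  area_m <- add_patch(mesh$patch_faces$medial, fm)
  area_l <- add_patch(mesh$patch_faces$lateral, fl)
  ## faces adjacent across the sagittal split deposit on shared midside
  ## nodes; renormalise per node set so each patch carries exactly its
  ## share of the total (the pressure shape is preserved to O(h))
  md <- 3L * mesh$sets$medial_patch
  ld <- 3L * mesh$sets$lateral_patch
  f[md] <- f[md] * (-fm / sum(f[md]))
  f[ld] <- f[ld] * (-fl / sum(f[ld]))
  fixed_dofs <- sort(c(3L * mesh$sets$distal_fixed - 2L,
                       3L * mesh$sets$distal_fixed - 1L,
                       3L * mesh$sets$distal_fixed))
  structure(list(f = f, fixed_dofs = fixed_dofs, case = case,
                 medial_force = fm, lateral_force = fl,
                 medial_area = area_m, lateral_area = area_l),
            class = "boundary_conditions")
}

#' Solve the constrained linear-elastic system
#'
#' Sparse direct (Cholesky) solve of K u = f with the fixed dofs
#' eliminated; verifies the free-dof residual and returns reactions at the
#' fixed dofs.
#'
#' @param K stiffness from [assemble()].
#' @param bcs a `boundary_conditions` (or list with `f`, `fixed_dofs`).
#' @param rtol admissible relative residual on the free dofs.
#' @return list with `u` (3n displacement vector, mm), `reactions`
#'   (named by fixed dof), `residual` (relative), `fixed_dofs`.
#' @export
solve_fe <- function(K, bcs, rtol = 1e-8) {
  ndof <- nrow(K)
  f <- bcs$f
  fixed <- bcs$fixed_dofs
  if (!length(fixed)) stop("no fixed dofs: rigid-body motion unconstrained")
  free <- setdiff(seq_len(ndof), fixed)
  ## extract the free-dof block from the symmetric triplet form (fast and
  ## exact; subscripting the big sparse matrix directly is prohibitive)
  Kt <- methods::as(K, "TsparseMatrix")
  keep <- logical(ndof); keep[free] <- TRUE
  map <- integer(ndof); map[free] <- seq_along(free)
  it <- Kt@i + 1L; jt <- Kt@j + 1L
  sel <- keep[it] & keep[jt]
  Kff <- Matrix::sparseMatrix(i = map[it[sel]], j = map[jt[sel]],
                              x = Kt@x[sel],
                              dims = c(length(free), length(free)),
                              symmetric = TRUE)
  u <- numeric(ndof)
  sol <- tryCatch(
    Matrix::solve(Matrix::Cholesky(Kff, LDL = FALSE, super = TRUE), f[free]),
    error = function(e)
      stop("singular system (insufficient constraints?): ",
           conditionMessage(e)))
  u[free] <- as.numeric(sol)
  if (sum(f[free]^2) > 0) {
    r <- as.numeric(Kff %*% u[free]) - f[free]
    residual <- sqrt(sum(r^2) / sum(f[free]^2))
    if (residual > rtol)
      warning(sprintf("solver residual %.2e exceeds rtol %.2e",
                      residual, rtol))
  } else residual <- 0
  reactions <- as.numeric(K %*% u)[fixed] - f[fixed]
  names(reactions) <- fixed
  list(u = u, reactions = reactions, residual = residual,
       fixed_dofs = fixed)
}

#' Sum of reaction force components as a 3-vector
#' @param solution result of [solve_fe()].
#' @export
reaction_total <- function(solution) {
  dofs <- as.integer(names(solution$reactions))
  comp <- (dofs - 1L) %% 3L + 1L
  vapply(1:3, function(c) sum(solution$reactions[comp == c]), numeric(1))
}
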