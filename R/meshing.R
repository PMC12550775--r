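#' Mesh generation settings
#'
#' @param global_size target element size, mm (default 1, the converged
#'   size of the reference protocol).
#' @param contact_size nominal element size in the bone-implant contact
#'   region, mm; retained for the region-of-interest definition (see
#'   `roi_offset`) — the background-grid mesher itself is uniform at
#'   `global_size`.
#' @param roi_offset half-width of the refined region of interest around
#'   the bone-implant interface, mm.
#' @param convergence_tolerance relative-change threshold of the mesh
#'   convergence protocol (default 0.05, i.e. 5 percent).
#' @return object of class `mesh_settings`.
#' @export
mesh_settings <- function(global_size = 1.0, contact_size = 0.75,
                          roi_offset = 3.0, convergence_tolerance = 0.05) {
  if (!(contact_size > 0 && contact_size <= global_size))
    stop("need 0 < contact_size <= global_size")
  if (!(convergence_tolerance > 0 && convergence_tolerance < 0.5))
    stop("convergence_tolerance must lie in (0, 0.5)")
  structure(list(global_size = global_size, contact_size = contact_size,
                 roi_offset = roi_offset,
                 convergence_tolerance = convergence_tolerance),
            class = "mesh_settings")
}

## Kuhn (Freudenthal) subdivision of a cubic grid: 6 positively oriented
## tetrahedra per cell sharing the main diagonal; conformal across cells.
## Corner labels: offsets (dx,dy,dz); template rows are tet corner orders
## giving det([b-a, c-a, d-a]) > 0.
kuhn_template <- function() {
  lab <- rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(0,0,1),
               c(1,1,0), c(1,0,1), c(0,1,1), c(1,1,1))
  rownames(lab) <- c("000","100","010","001","110","101","011","111")
  tets <- rbind(c("000","100","110","111"),
                c("000","100","111","101"),
                c("000","010","111","110"),
                c("000","010","011","111"),
                c("000","001","101","111"),
                c("000","001","111","011"))
  list(offsets = lab, tets = tets)
}

## Tetrahedralize the grid covering bbox at pitch h.
## Returns full grid nodes, candidate tets (corner ids), tet centroids.
grid_tets <- function(bbox, h) {
  lo <- floor(bbox[1, ] / h) * h - h / 2
  hi <- bbox[2, ] + h / 2
  nc <- pmax(as.integer(ceiling((hi - lo) / h)), 1L)
  nx <- nc[1]; ny <- nc[2]; nz <- nc[3]
  xs <- lo[1] + h * (0:nx); ys <- lo[2] + h * (0:ny); zs <- lo[3] + h * (0:nz)
  nid <- function(i, j, k) 1L + i + (nx + 1L) * (j + (ny + 1L) * k)
  nodes <- cbind(rep(xs, times = (ny + 1) * (nz + 1)),
                 rep(rep(ys, each = nx + 1), times = nz + 1),
                 rep(zs, each = (nx + 1) * (ny + 1)))
  ci <- rep(0:(nx - 1L), times = ny * nz)
  cj <- rep(rep(0:(ny - 1L), each = nx), times = nz)
  ck <- rep(0:(nz - 1L), each = nx * ny)
  tpl <- kuhn_template()
  corner_id <- sapply(rownames(tpl$offsets), function(lb) {
    o <- tpl$offsets[lb, ]
    nid(ci + o[1], cj + o[2], ck + o[3])
  })
  tets <- do.call(rbind, lapply(seq_len(nrow(tpl$tets)), function(t)
    cbind(corner_id[, tpl$tets[t, 1]], corner_id[, tpl$tets[t, 2]],
          corner_id[, tpl$tets[t, 3]], corner_id[, tpl$tets[t, 4]])))
  storage.mode(tets) <- "integer"
  centroids <- (nodes[tets[, 1], , drop = FALSE] +
                nodes[tets[, 2], , drop = FALSE] +
                nodes[tets[, 3], , drop = FALSE] +
                nodes[tets[, 4], , drop = FALSE]) / 4
  list(nodes = nodes, tets = tets, centroids = centroids, h = h)
}

#' Mesh the bone-implant assembly with quadratic tetrahedra
#'
#' Builds a single conformal TET10 mesh on a structured background grid
#' (Kuhn-subdivided cubes at `global_size`): candidate tetrahedra are
#' classified by centroid membership into bone / implant / void, void is
#' discarded, and corner tetrahedra are promoted to 10-node quadratic
#' elements with shared midside nodes. Because bone and implant elements
#' come from the same grid, they share interface nodes exactly — the
#' bonded (osseointegrated) contact condition holds by mesh conformity.
#'
#' @param bone bone-with-cavity `fea_solid` (from [carve_cavity()], or any
#'   bone solid for implant-free meshes).
#' @param implant placed implant `fea_solid`, or NULL for bone-only meshes.
#' @param settings a [mesh_settings()].
#' @return object of class `fea_mesh`: `nodes` (n x 3), `conn` (ne x 10,
#'   VTK TET10 ordering), `region` factor (bone/baseplate/stem), `sets`
#'   (node sets: distal_fixed, medial_patch, lateral_patch, interface;
#'   element set refined_roi), `patch_faces`, `h`, `meta`.
#' @export
mesh_assembly <- function(bone, implant = NULL, settings = mesh_settings()) {
  h <- settings$global_size
  bbox <- bone$bbox
  if (!is.null(implant))
    bbox <- rbind(pmin(bbox[1, ], implant$bbox[1, ]),
                  pmax(bbox[2, ], implant$bbox[2, ]))
  gm <- grid_tets(bbox, h)
  in_bone <- bone$inside(gm$centroids)
  in_imp <- if (is.null(implant)) rep(FALSE, nrow(gm$centroids)) else
    implant$inside(gm$centroids)
  in_imp <- in_imp & !in_bone       # cavity already excludes implant; belt
  keep <- in_bone | in_imp
  if (!any(keep)) stop("meshing failure: no element centroid falls inside ",
                       "either solid (geometry misaligned?)")
  tets <- gm$tets[keep, , drop = FALSE]
  region <- ifelse(in_bone[keep], "bone", "implant")
  cen_keep <- gm$centroids[keep, , drop = FALSE]

  ## centroid classification can leave islands and vertex-/edge-only
  ## contacts (spherical or hinge joints with zero-energy modes); keep
  ## only the dominant FACE-connected component so the assembled system
  ## is free of internal mechanisms
  drop <- !in_main_face_component(tets)
  if (any(drop)) {
    message("dropping ", sum(drop),
            " element(s) not face-connected to the main body")
    tets <- tets[!drop, , drop = FALSE]
    region <- region[!drop]
    cen_keep <- cen_keep[!drop, , drop = FALSE]
  }

  ## split implant into baseplate / stem using the local frame
  if (!is.null(implant) && any(region == "implant")) {
    tf <- implant$meta$transform
    cen <- cen_keep
    R <- tf[1:3, 1:3]; c0 <- tf[1:3, 4]
    lz <- as.vector((cen - matrix(c0, nrow(cen), 3, byrow = TRUE)) %*% R[, 3])
    region[region == "implant" & lz < 0] <- "stem"
    region[region == "implant"] <- "baseplate"
  }

  ## compact corner nodes
  used <- sort(unique(as.vector(tets)))
  remap <- integer(nrow(gm$nodes)); remap[used] <- seq_along(used)
  conn4 <- matrix(remap[tets], ncol = 4)
  nodes <- gm$nodes[used, , drop = FALSE]
  n_corner <- nrow(nodes)

  ## midside nodes: VTK TET10 edge order (1,2),(2,3),(1,3),(1,4),(2,4),(3,4)
  ep <- rbind(c(1, 2), c(2, 3), c(1, 3), c(1, 4), c(2, 4), c(3, 4))
  mids <- matrix(0L, nrow(conn4), 6)
  a_all <- NULL; b_all <- NULL
  for (e in 1:6) {
    a_all <- cbind(a_all, pmin(conn4[, ep[e, 1]], conn4[, ep[e, 2]]))
    b_all <- cbind(b_all, pmax(conn4[, ep[e, 1]], conn4[, ep[e, 2]]))
  }
  key <- as.numeric(a_all) * (n_corner + 1) + as.numeric(b_all)
  uk <- unique(key)
  mid_id <- match(key, uk) + n_corner
  mids[] <- mid_id
  ua <- as.numeric(a_all)[!duplicated(key)]
  ub <- as.numeric(b_all)[!duplicated(key)]
  mid_xyz <- (nodes[ua, , drop = FALSE] + nodes[ub, , drop = FALSE]) / 2
  nodes <- rbind(nodes, mid_xyz)
  conn <- cbind(conn4, mids)
  storage.mode(conn) <- "integer"

  mesh <- structure(list(nodes = nodes, conn = conn,
                         region = factor(region,
                                         levels = c("bone", "baseplate",
                                                    "stem")),
                         sets = list(), patch_faces = list(),
                         h = h, n_corner = n_corner,
                         meta = list(settings = unclass(settings))),
                    class = "fea_mesh")
  tag_sets(mesh, bone, implant, settings)
}

#' @export
print.fea_mesh <- function(x, ...) {
  cat("<fea_mesh>", nrow(x$conn), "TET10 elements,", nrow(x$nodes),
      "nodes (h =", x$h, "mm)\n")
  print(table(x$region))
  if (length(x$sets))
    cat("  sets:", paste(sprintf("%s[%d]", names(x$sets),
                                 lengths(x$sets)), collapse = ", "), "\n")
  invisible(x)
}

## TRUE for tets in the largest face-connected component
in_main_face_component <- function(tets) {
  tfc <- tet_faces(tets)
  ord <- order(tfc$gid)
  go <- tfc$gid[ord]; eo <- tfc$elem[ord]
  pair <- which(go[-length(go)] == go[-1])
  g <- igraph::make_graph(rbind(eo[pair], eo[pair + 1L]),
                          n = nrow(tets), directed = FALSE)
  memb <- igraph::components(g)$membership
  memb == as.integer(names(which.max(table(memb))))
}

## boundary/interface faces of a tet mesh; returns per-face corner triple,
## owning element, opposite corner, and count over the whole assembly
tet_faces <- function(conn4) {
  fidx <- rbind(c(2, 3, 4, 1), c(1, 4, 3, 2), c(1, 2, 4, 3), c(1, 3, 2, 4))
  ne <- nrow(conn4)
  faces <- do.call(rbind, lapply(1:4, function(f)
    cbind(conn4[, fidx[f, 1]], conn4[, fidx[f, 2]], conn4[, fidx[f, 3]])))
  opp <- do.call(c, lapply(1:4, function(f) conn4[, fidx[f, 4]]))
  elem <- rep(seq_len(ne), 4)
  s1 <- pmin(pmin(faces[, 1], faces[, 2]), faces[, 3])
  s3 <- pmax(pmax(faces[, 1], faces[, 2]), faces[, 3])
  s2 <- as.numeric(faces[, 1]) + as.numeric(faces[, 2]) +
    as.numeric(faces[, 3]) - s1 - s3
  ## two-level numeric hashing keeps keys inside exact-double range
  k1 <- as.numeric(s1) * (max(s3) + 1) + s2
  g1 <- match(k1, unique(k1))
  k2 <- as.numeric(g1) * (max(s3) + 1) + s3
  gid <- match(k2, unique(k2))
  list(faces = faces, elem = elem, opp = opp, gid = gid)
}

#' Tag node and element sets on an assembly mesh
#'
#' Defines: `distal_fixed` (nodes on the distal cut plane), the
#' `medial_patch` / `lateral_patch` load faces on the superior baseplate
#' surface split by the sagittal midplane (+x is medial), `interface`
#' (nodes shared by bone and implant elements), and the `refined_roi`
#' element set (elements whose centroid lies within `roi_offset` of the
#' bone-implant interface).
#'
#' @param mesh a `fea_mesh`.
#' @param bone,implant the solids meshed (implant may be NULL).
#' @param settings [mesh_settings()] supplying `roi_offset`.
#' @return the mesh with `sets` and `patch_faces` populated.
#' @export
tag_sets <- function(mesh, bone, implant = NULL,
                     settings = mesh_settings()) {
  nodes <- mesh$nodes; conn <- mesh$conn
  tol <- 1e-6
  zmin <- min(nodes[seq_len(mesh$n_corner), 3])
  distal_fixed <- which(nodes[, 3] <= zmin + tol)
  if (!length(distal_fixed)) stop("empty distal_fixed set")
  sets <- list(distal_fixed = distal_fixed)
  patch_faces <- list()

  is_imp <- mesh$region %in% c("baseplate", "stem")
  if (!is.null(implant) && any(is_imp)) {
    tf <- tet_faces(conn[, 1:4, drop = FALSE])
    cnt <- tabulate(tf$gid)
    once <- cnt[tf$gid] == 1L
    owner_imp <- is_imp[tf$elem]
    iface_nodes <- sort(unique(intersect(
      as.vector(conn[is_imp, ]), as.vector(conn[!is_imp, , drop = FALSE]))))
    if (!length(iface_nodes)) stop("empty bone-implant interface set")
    sets$interface <- iface_nodes

    ## superior baseplate faces: assembly-boundary faces of baseplate
    ## elements with +z outward normal (the tray underside conforms to the
    ## cut plane and faces downward, so upward exterior = superior face)
    owner_bp <- (mesh$region == "baseplate")[tf$elem]
    cand <- which(once & owner_bp)
    if (!length(cand)) stop("no exterior implant faces found")
    f3 <- tf$faces[cand, , drop = FALSE]
    p1 <- nodes[f3[, 1], , drop = FALSE]
    p2 <- nodes[f3[, 2], , drop = FALSE]
    p3 <- nodes[f3[, 3], , drop = FALSE]
    nrm <- cross3(p2 - p1, p3 - p1)
    ## orient outward: away from the opposite corner of the owning element
    po <- nodes[tf$opp[cand], , drop = FALSE]
    fc <- (p1 + p2 + p3) / 3
    sgn <- sign(rowSums(nrm * (fc - po)))
    nrm <- nrm * sgn
    nlen <- sqrt(rowSums(nrm^2))
    ## staircase boundaries include oblique tet faces; any face with an
    ## upward outward component belongs to the superior surface
    upward <- nrm[, 3] / nlen > 0.1
    proj_area <- pmax(nrm[, 3], 0) / 2      # z-projected triangle area
    tfm <- implant$meta$transform
    R <- tfm[1:3, 1:3]; c0 <- tfm[1:3, 4]
    lc <- (fc - matrix(c0, nrow(fc), 3, byrow = TRUE)) %*% R
    top <- upward
    if (!any(top)) stop("empty superior-face patch (geometry misaligned)")
    med <- top & lc[, 1] > 0
    lat <- top & lc[, 1] <= 0
    if (!any(med) || !any(lat)) stop("empty medial or lateral load patch")
    face6 <- function(sel) {
      idx <- cand[sel]
      corners <- tf$faces[idx, , drop = FALSE]
      el <- tf$elem[idx]
      m6 <- t(vapply(seq_along(el), function(i) {
        ec <- conn[el[i], ]
        loc <- match(corners[i, ], ec[1:4])
        midof <- function(a, b) {
          ep <- rbind(c(1,2), c(2,3), c(1,3), c(1,4), c(2,4), c(3,4))
          hit <- which((ep[, 1] == min(a, b)) & (ep[, 2] == max(a, b)))
          ec[4L + hit]
        }
        c(corners[i, ],
          midof(loc[1], loc[2]), midof(loc[2], loc[3]), midof(loc[1], loc[3]))
      }, integer(6)))
      m6
    }
    patch_faces$medial <- list(faces = face6(med),
                               proj_area = proj_area[med])
    patch_faces$lateral <- list(faces = face6(lat),
                                proj_area = proj_area[lat])
    ## node sets split node-wise by the sagittal midplane so they are
    ## disjoint (faces straddling the midplane share boundary nodes)
    sup_nodes <- sort(unique(c(as.vector(patch_faces$medial$faces),
                               as.vector(patch_faces$lateral$faces))))
    lx <- as.vector((nodes[sup_nodes, , drop = FALSE] -
                     matrix(c0, length(sup_nodes), 3, byrow = TRUE)) %*%
                    R[, 1])
    ## nodes on the sagittal midplane alternate sides (deterministic in
    ## node order) so the two sets stay balanced on symmetric trays
    onmid <- abs(lx) < 1e-9
    lx[onmid] <- ifelse(seq_along(lx)[onmid] %% 2L == 0L, 1, -1) * 1e-9
    sets$medial_patch <- sup_nodes[lx > 0]
    sets$lateral_patch <- sup_nodes[lx < 0]

    ## refined ROI: elements with centroid within roi_offset of interface
    cen <- (nodes[conn[, 1], ] + nodes[conn[, 2], ] +
            nodes[conn[, 3], ] + nodes[conn[, 4], ]) / 4
    ## corner interface nodes suffice for an h-resolution distance query
    ipts <- nodes[iface_nodes[iface_nodes <= mesh$n_corner], , drop = FALSE]
    roff <- settings$roi_offset
    near <- logical(nrow(cen))
    block <- 2000L
    for (s in seq(1L, nrow(cen), by = block)) {
      e <- min(s + block - 1L, nrow(cen))
      d2 <- outer(rowSums(cen[s:e, , drop = FALSE]^2), rowSums(ipts^2), "+") -
        2 * cen[s:e, , drop = FALSE] %*% t(ipts)
      mins <- d2[cbind(seq_len(nrow(d2)), max.col(-d2, ties.method = "first"))]
      near[s:e] <- mins <= roff^2
    }
    sets$refined_roi <- which(near)
    if (!length(sets$refined_roi)) stop("empty refined_roi element set")
  }
  mesh$sets <- sets
  mesh$patch_faces <- patch_faces
  mesh
}

#' Audit mesh validity
#'
#' Checks that each element has 10 distinct nodes, every corner Jacobian
#' (6 x signed volume) is strictly positive, no node is orphaned, and the
#' medial/lateral patches are disjoint.
#'
#' @param mesh a `fea_mesh`.
#' @return list with `ok` and individual flags/counts.
#' @export
mesh_audit <- function(mesh) {
  conn <- mesh$conn; nodes <- mesh$nodes
  distinct <- !any(apply(conn, 1, anyDuplicated) > 0)
  a <- nodes[conn[, 1], , drop = FALSE]
  v1 <- nodes[conn[, 2], , drop = FALSE] - a
  v2 <- nodes[conn[, 3], , drop = FALSE] - a
  v3 <- nodes[conn[, 4], , drop = FALSE] - a
  detj <- v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
          v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
          v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1])
  positive_jacobian <- all(detj > 0)
  orphan_free <- length(setdiff(seq_len(nrow(nodes)),
                                unique(as.vector(conn)))) == 0L
  patches_disjoint <- TRUE
  if (!is.null(mesh$sets$medial_patch))
    patches_disjoint <- length(intersect(mesh$sets$medial_patch,
                                         mesh$sets$lateral_patch)) == 0L
  list(ok = distinct && positive_jacobian && orphan_free && patches_disjoint,
       distinct_nodes = distinct, positive_jacobian = positive_jacobian,
       min_jacobian = min(detj), orphan_free = orphan_free,
       patches_disjoint = patches_disjoint, n_elements = nrow(conn))
}

#' Mesh-convergence protocol
#'
#' Runs a user-supplied closure at a descending list of element sizes and
#' accepts the first size at which every monitored output changes by less
#' than `tolerance` relative to the previous (coarser) size.
#'
#' @param run function(size) returning a named numeric vector of monitored
#'   outputs (e.g. max stress, max strain, max fracture risk).
#' @param sizes strictly descending element sizes, mm (>= 2 entries).
#' @param tolerance relative-change acceptance threshold (default 0.05).
#' @return list with `selected` (size), `converged` flag, and `table`
#'   (one row per size with outputs and relative changes).
#' @export
convergence_study <- function(run, sizes, tolerance = 0.05) {
  stopifnot(length(sizes) >= 2, all(diff(sizes) < 0))
  vals <- lapply(sizes, run)
  nm <- names(vals[[1]])
  out <- do.call(rbind, lapply(vals, function(v) v[nm]))
  rel <- rbind(NA, abs(diff(out)) / abs(out[-nrow(out), , drop = FALSE]))
  max_rel <- apply(rel, 1, function(r) if (all(is.na(r))) NA else max(r))
  tab <- data.frame(size = sizes, out, max_rel_change = max_rel,
                    check.names = FALSE)
  conv <- which(!is.na(max_rel) & max_rel < tolerance)
  if (length(conv)) {
    list(selected = sizes[conv[1]], converged = TRUE, table = tab)
  } else {
    list(selected = sizes[length(sizes)], converged = FALSE, table = tab)
  }
}

#' Write a mesh (with optional data arrays) as ASCII VTU
#'
#' @param mesh a `fea_mesh`.
#' @param path output .vtu path.
#' @param cell_data named list of per-element vectors.
#' @param point_data named list of per-node vectors or n x 3 matrices.
#' @export
write_vtu <- function(mesh, path, cell_data = list(), point_data = list()) {
  n <- nrow(mesh$nodes); ne <- nrow(mesh$conn)
  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid><Piece NumberOfPoints="', n,
    '" NumberOfCells="', ne, '">')
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(apply(mesh$nodes, 1, paste, collapse = " "), con)
  w('</DataArray></Points>')
  w('<Cells><DataArray type="Int64" Name="connectivity" format="ascii">')
  writeLines(apply(mesh$conn - 1L, 1, paste, collapse = " "), con)
  w('</DataArray><DataArray type="Int64" Name="offsets" format="ascii">')
  writeLines(paste(seq_len(ne) * 10L), con)
  w('</DataArray><DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(paste(rep(24L, ne)), con)
  w('</DataArray></Cells>')
  w('<CellData>')
  w('<DataArray type="Int32" Name="region" format="ascii">')
  writeLines(paste(as.integer(mesh$region)), con)
  w('</DataArray>')
  for (nmv in names(cell_data)) {
    w('<DataArray type="Float64" Name="', nmv, '" format="ascii">')
    writeLines(paste(cell_data[[nmv]]), con)
    w('</DataArray>')
  }
  w('</CellData><PointData>')
  for (nmv in names(point_data)) {
    v <- point_data[[nmv]]
    nc <- if (is.matrix(v)) ncol(v) else 1L
    w('<DataArray type="Float64" Name="', nmv,
      '" NumberOfComponents="', nc, '" format="ascii">')
    if (is.matrix(v)) writeLines(apply(v, 1, paste, collapse = " "), con)
    else writeLines(paste(v), con)
    w('</DataArray>')
  }
  w('</PointData>')
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(path)
}
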