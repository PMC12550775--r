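#' @useDynLib stemfea, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Construct a solid model
#'
#' A solid couples an implicit membership test (used for voxelization,
#' meshing and booleans) with a watertight triangulated boundary surface
#' (used for export and surface-based checks).
#'
#' @param inside function taking an n x 3 matrix of points (mm) and
#'   returning a logical vector.
#' @param surface list with `vertices` (n x 3) and `faces` (m x 3, 1-based,
#'   outward-oriented), or NULL if no explicit surface is attached.
#' @param region region tag, e.g. "bone" or "implant".
#' @param bbox 2 x 3 matrix of axis-aligned bounds (rows: min, max).
#' @param meta free-form metadata list.
#' @return An object of class `fea_solid`.
#' @export
solid_model <- function(inside, surface = NULL, region = "solid",
                        bbox = NULL, meta = list()) {
  stopifnot(is.function(inside))
  if (is.null(bbox) && !is.null(surface)) {
    bbox <- rbind(apply(surface$vertices, 2, min),
                  apply(surface$vertices, 2, max))
  }
  structure(list(inside = inside, surface = surface, region = region,
                 bbox = bbox, meta = meta),
            class = "fea_solid")
}

#' @export
print.fea_solid <- function(x, ...) {
  cat("<fea_solid>", x$region, "\n")
  if (!is.null(x$surface))
    cat("  surface:", nrow(x$surface$vertices), "vertices,",
        nrow(x$surface$faces), "faces\n")
  if (!is.null(x$bbox))
    cat("  bbox: [", paste(sprintf("%.1f", x$bbox[1, ]), collapse = ", "),
        "] - [", paste(sprintf("%.1f", x$bbox[2, ]), collapse = ", "), "] mm\n")
  invisible(x)
}

as_points_matrix <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  storage.mode(pts) <- "double"
  pts
}

## ---- lofted surfaces -------------------------------------------------------

#' Loft a closed surface through a stack of polar cross-section rings
#'
#' Each ring is a closed polygon sampled at `ntheta` equally spaced angles
#' around a centre line along z. Consecutive rings are joined by triangle
#' strips and both ends are capped by triangle fans, giving a watertight,
#' consistently outward-oriented surface (Euler characteristic 2).
#' Coincident consecutive rings (same z, same radii) create degenerate
#' quads and are collapsed.
#'
#' @param rings list of lists with fields `z` (scalar) and `r` (length
#'   `ntheta` radii); rings ordered by increasing z (equal z allowed, for
#'   radius jumps).
#' @param ntheta number of angular samples.
#' @param center optional function z -> c(cx, cy) centre line (default axis).
#' @return surface list (`vertices`, `faces`).
#' @keywords internal
polar_loft <- function(rings, ntheta, center = NULL) {
  stopifnot(length(rings) >= 2)
  th <- seq(0, 2 * pi, length.out = ntheta + 1)[-(ntheta + 1)]
  ct <- cos(th); st <- sin(th)
  nr <- length(rings)
  verts <- matrix(0, nr * ntheta + 2, 3)
  for (i in seq_len(nr)) {
    cc <- if (is.null(center)) c(0, 0) else center(rings[[i]]$z)
    idx <- (i - 1L) * ntheta + seq_len(ntheta)
    verts[idx, 1] <- cc[1] + rings[[i]]$r * ct
    verts[idx, 2] <- cc[2] + rings[[i]]$r * st
    verts[idx, 3] <- rings[[i]]$z
  }
  ## cap centres
  bot <- nr * ntheta + 1L
  top <- nr * ntheta + 2L
  cb <- if (is.null(center)) c(0, 0) else center(rings[[1]]$z)
  ctp <- if (is.null(center)) c(0, 0) else center(rings[[nr]]$z)
  verts[bot, ] <- c(cb, rings[[1]]$z)
  verts[top, ] <- c(ctp, rings[[nr]]$z)

  faces <- vector("list", nr + 1L)
  for (i in seq_len(nr - 1L)) {
    a <- (i - 1L) * ntheta + seq_len(ntheta)
    b <- i * ntheta + seq_len(ntheta)
    an <- c(a[-1], a[1]); bn <- c(b[-1], b[1])
    ## skip degenerate band (identical rings)
    if (isTRUE(all.equal(verts[a, ], verts[b, ], tolerance = 1e-12))) next
    ## outward orientation: CCW seen from outside
    faces[[i]] <- rbind(cbind(a, bn, b), cbind(a, an, bn))
  }
  a <- seq_len(ntheta); an <- c(a[-1], a[1])
  faces[[nr]] <- cbind(rep(bot, ntheta), an, a)           # bottom cap, -z out
  a <- (nr - 1L) * ntheta + seq_len(ntheta); an <- c(a[-1], a[1])
  faces[[nr + 1L]] <- cbind(rep(top, ntheta), a, an)      # top cap, +z out
  faces <- do.call(rbind, faces)
  dimnames(faces) <- NULL
  ## drop unreferenced vertices (none normally) and exact-duplicate faces
  list(vertices = verts, faces = faces)
}

## ---- surface audits --------------------------------------------------------

#' Audit a triangulated surface for closedness and manifoldness
#'
#' `watertight` (closed): every directed half-edge is balanced by its
#' reverse, so the surface is the boundary of a solid (no holes or
#' leaks). `manifold`: every undirected edge is shared by exactly two
#' faces — voxelized boundaries can be closed yet pinched (non-manifold)
#' along grid edges. `oriented`: manifold with globally consistent
#' winding. The Euler characteristic and the enclosed signed volume
#' (positive iff outward-oriented) are reported alongside.
#'
#' @param surface list with `vertices`, `faces`.
#' @return list with `watertight`, `manifold`, `oriented`, `euler`,
#'   `volume`, `n_vertices`, `n_edges`, `n_faces`.
#' @export
surface_audit <- function(surface) {
  v <- surface$vertices; f <- surface$faces
  ## remove degenerate faces (zero area from collapsed loft rings)
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  cr <- cross3(p2 - p1, p3 - p1)
  area2 <- sqrt(rowSums(cr^2))
  f <- f[area2 > 1e-12, , drop = FALSE]
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])  # directed half-edges
  key_dir <- paste(he[, 1], he[, 2])
  key_rev <- paste(he[, 2], he[, 1])
  dir_tab <- table(key_dir)
  closed <- all(dir_tab[key_dir] == ifelse(is.na(dir_tab[key_rev]), 0L,
                                           dir_tab[key_rev]))
  key_und <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  und_tab <- table(key_und)
  manifold <- all(und_tab == 2L)
  oriented <- manifold && !any(duplicated(key_dir))
  used <- sort(unique(as.vector(f)))
  nv <- length(used); ne <- length(und_tab); nf <- nrow(f)
  list(watertight = closed, manifold = manifold, oriented = oriented,
       euler = nv - ne + nf,
       volume = surface_volume(list(vertices = v, faces = f)),
       n_vertices = nv, n_edges = ne, n_faces = nf)
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Enclosed volume of a closed oriented surface (divergence theorem)
#' @param surface list with `vertices`, `faces`.
#' @return signed volume in mm^3 (positive for outward orientation).
#' @export
surface_volume <- function(surface) {
  v <- surface$vertices; f <- surface$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  sum(rowSums(p1 * cross3(p2, p3))) / 6
}

## ---- half-space clipping ---------------------------------------------------

#' Clip a closed surface by a half-space and cap the cut
#'
#' Keeps the part of the solid with `dot(x - point, normal) <= 0`,
#' splitting straddling triangles exactly and closing the planar cut with a
#' triangle fan about the cut-loop centroid (valid for star-shaped cuts,
#' which all solids in this package produce).
#'
#' @param surface list with `vertices`, `faces` (watertight, outward).
#' @param point point on the clip plane (length 3).
#' @param normal outward normal of the discarded half-space (length 3).
#' @return clipped surface list; attribute `cap_loop` holds the ordered
#'   cut-polygon vertex coordinates (k x 3).
#' @keywords internal
clip_halfspace <- function(surface, point, normal) {
  normal <- normal / sqrt(sum(normal^2))
  v <- surface$vertices; f <- surface$faces
  d <- as.vector((v - matrix(point, nrow(v), 3, byrow = TRUE)) %*% normal)
  tol <- 1e-9 * max(1, max(abs(v)))
  keep_v <- d <= tol
  if (!any(keep_v)) stop("clip plane removes the whole solid")
  if (all(d <= tol)) {
    attr(surface, "cap_loop") <- NULL
    return(surface)
  }

  new_v <- list(); new_f <- list(); edge_cache <- new.env(hash = TRUE)
  nv0 <- nrow(v)
  extra <- 0L
  interp_pt <- function(i, j) {
    key <- paste(min(i, j), max(i, j))
    hit <- edge_cache[[key]]
    if (!is.null(hit)) return(hit)
    t <- d[i] / (d[i] - d[j])
    p <- v[i, ] + t * (v[j, ] - v[i, ])
    extra <<- extra + 1L
    new_v[[extra]] <<- p
    id <- nv0 + extra
    edge_cache[[key]] <- id
    id
  }
  cap_edges <- list(); nce <- 0L
  out_f <- vector("list", nrow(f)); nof <- 0L
  for (k in seq_len(nrow(f))) {
    tri <- f[k, ]
    below <- d[tri] <= tol
    nb <- sum(below)
    if (nb == 3L) { nof <- nof + 1L; out_f[[nof]] <- tri; next }
    if (nb == 0L) next
    ## rotate so pattern starts at a kept vertex
    ord <- tri; bel <- below
    while (!bel[1]) { ord <- ord[c(2, 3, 1)]; bel <- bel[c(2, 3, 1)] }
    if (nb == 1L) {
      a <- ord[1]; b <- ord[2]; c3 <- ord[3]
      pab <- interp_pt(a, b); pca <- interp_pt(c3, a)
      nof <- nof + 1L; out_f[[nof]] <- c(a, pab, pca)
      nce <- nce + 1L; cap_edges[[nce]] <- c(pab, pca)
    } else { # nb == 2: rotate so the single cut vertex is ord[3]
      while (bel[3]) { ord <- ord[c(2, 3, 1)]; bel <- bel[c(2, 3, 1)] }
      a <- ord[1]; b <- ord[2]; c3 <- ord[3]
      pbc <- interp_pt(b, c3); pca <- interp_pt(c3, a)
      nof <- nof + 1L; out_f[[nof]] <- c(a, b, pbc)
      nof <- nof + 1L; out_f[[nof]] <- c(a, pbc, pca)
      nce <- nce + 1L; cap_edges[[nce]] <- c(pbc, pca)
    }
  }
  v2 <- rbind(v, do.call(rbind, new_v))
  ## order cap edges into a loop; they are directed consistently (the cut
  ## boundary of an oriented surface is an oriented polygon)
  ce <- do.call(rbind, cap_edges)
  loop <- integer(nrow(ce))
  nxt <- ce[, 2]; names(nxt) <- as.character(ce[, 1])
  loop[1] <- ce[1, 1]
  for (k in seq_len(nrow(ce) - 1L))
    loop[k + 1L] <- nxt[[as.character(loop[k])]]
  centroid <- colMeans(v2[loop, , drop = FALSE])
  cid <- nrow(v2) + 1L
  v2 <- rbind(v2, centroid)
  lp <- loop; lpn <- c(lp[-1], lp[1])
  ## cap normal must be +normal (outward): boundary loop of kept part runs
  ## CCW seen from -normal side, so fan (centroid, next, cur) faces +normal
  cap <- cbind(rep(cid, length(lp)), lpn, lp)
  capn <- colMeans(cross3(v2[lpn, , drop = FALSE] - matrix(centroid, length(lp), 3, byrow = TRUE),
                          v2[lp, , drop = FALSE] - matrix(centroid, length(lp), 3, byrow = TRUE)))
  if (sum(capn * normal) < 0) cap <- cap[, c(1, 3, 2)]
  fc <- rbind(do.call(rbind, out_f[seq_len(nof)]), cap)
  out <- compact_surface(list(vertices = v2, faces = fc))
  attr(out, "cap_loop") <- v2[loop, , drop = FALSE]
  out
}

## drop vertices not referenced by any face, renumbering faces
compact_surface <- function(surface) {
  used <- sort(unique(as.vector(surface$faces)))
  map <- integer(nrow(surface$vertices)); map[used] <- seq_along(used)
  f <- matrix(map[surface$faces], ncol = 3)
  list(vertices = surface$vertices[used, , drop = FALSE], faces = f)
}

## ---- volume estimation -----------------------------------------------------

#' Voxelized volume of an implicit solid
#'
#' Counts voxel centres inside the solid on a regular grid — the
#' independent volume oracle used for boolean-consistency audits.
#'
#' @param solid `fea_solid` (or bare inside function with `bbox` given).
#' @param h voxel pitch in mm.
#' @param bbox optional 2 x 3 bounds (default: solid bbox padded by h).
#' @return volume in mm^3.
#' @export
voxel_volume <- function(solid, h = 1, bbox = NULL) {
  inside <- if (inherits(solid, "fea_solid")) solid$inside else solid
  if (is.null(bbox)) bbox <- solid$bbox
  stopifnot(!is.null(bbox))
  xs <- seq(bbox[1, 1] - h / 2, bbox[2, 1] + h / 2, by = h)
  ys <- seq(bbox[1, 2] - h / 2, bbox[2, 2] + h / 2, by = h)
  zs <- seq(bbox[1, 3] - h / 2, bbox[2, 3] + h / 2, by = h)
  n <- 0
  for (z in zs) {   # slab-wise to bound memory
    g <- cbind(rep(xs, times = length(ys)),
               rep(ys, each = length(xs)), z)
    n <- n + sum(inside(g))
  }
  n * h^3
}

## ---- STL I/O ---------------------------------------------------------------

#' Write a triangulated surface as ASCII STL
#' @param surface list with `vertices`, `faces`.
#' @param path output file path.
#' @param name solid name recorded in the file.
#' @export
write_stl <- function(surface, path, name = "solid") {
  v <- surface$vertices; f <- surface$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  n <- cross3(p2 - p1, p3 - p1)
  len <- sqrt(rowSums(n^2)); len[len == 0] <- 1
  n <- n / len
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("solid", name), con)
  body <- sprintf(
    "facet normal %g %g %g\nouter loop\nvertex %g %g %g\nvertex %g %g %g\nvertex %g %g %g\nendloop\nendfacet",
    n[, 1], n[, 2], n[, 3],
    p1[, 1], p1[, 2], p1[, 3],
    p2[, 1], p2[, 2], p2[, 3],
    p3[, 1], p3[, 2], p3[, 3])
  writeLines(body, con)
  writeLines(paste("endsolid", name), con)
  invisible(path)
}

#' Read an ASCII STL surface
#' @param path file path.
#' @return surface list (`vertices`, `faces`); coincident vertices merged.
#' @export
read_stl <- function(path) {
  ln <- readLines(path)
  vx <- grep("^\\s*vertex", ln, value = TRUE)
  m <- do.call(rbind, lapply(strsplit(trimws(vx), "\\s+"), function(s)
    as.numeric(s[2:4])))
  key <- paste(m[, 1], m[, 2], m[, 3])
  uid <- match(key, unique(key))
  verts <- m[!duplicated(key), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces)
}
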