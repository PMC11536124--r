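#' Triangle surface mesh
#'
#' Lightweight container for a closed triangle mesh in physical units (um).
#' Faces index rows of `vertices`; orientation is outward (positive signed
#' volume) whenever the mesh encloses a region.
#'
#' @param vertices numeric n x 3 matrix of vertex coordinates, um.
#' @param faces integer F x 3 matrix of vertex indices.
#' @return an object of class `surface_mesh` with fields `vertices`,
#'   `faces` and the derived area-weighted `centroid`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3) .dt_stop("surface_mesh: vertices must be n x 3")
  if (any(!is.finite(vertices))) .dt_stop("surface_mesh: non-finite vertex")
  if (min(faces) < 1 || max(faces) > nrow(vertices))
    .dt_stop("surface_mesh: face index out of range")
  m <- structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
  m$centroid <- mesh_centroid(m)
  m
}

#' @export
print.surface_mesh <- function(x, ...) {
  top <- mesh_topology(x)
  cat(sprintf(
    "surface_mesh: %d vertices, %d faces, %d component(s), Euler chi = %d\n",
    nrow(x$vertices), nrow(x$faces), top$component_count, top$euler))
  invisible(x)
}

# per-face areas and (optionally) normals
mesh_face_geometry <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nrm <- sqrt(rowSums(cr^2))
  list(area = nrm / 2, normal = cr / pmax(nrm, .Machine$double.xmin),
       centroid = (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
                     v[f[, 3], , drop = FALSE]) / 3)
}

#' Surface area, enclosed volume and centroid of a mesh
#'
#' @param mesh a [surface_mesh()].
#' @return `mesh_area`: total area (um^2); `mesh_volume`: enclosed volume
#'   (um^3, absolute value of the divergence-theorem sum); `mesh_centroid`:
#'   area-weighted mean of face centroids (um).
#' @name mesh-measures
#' @export
mesh_area <- function(mesh) sum(mesh_face_geometry(mesh)$area)

#' @rdname mesh-measures
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  abs(sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
            a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
            a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1]))) / 6
}

#' @rdname mesh-measures
#' @export
mesh_centroid <- function(mesh) {
  g <- mesh_face_geometry(mesh)
  colSums(g$centroid * g$area) / sum(g$area)
}

# Barycentric vertex areas (1/3 of incident face area per vertex).
mesh_vertex_areas <- function(mesh) {
  g <- mesh_face_geometry(mesh)
  va <- numeric(nrow(mesh$vertices))
  for (j in 1:3) {
    acc <- rowsum(g$area / 3, mesh$faces[, j])
    va[as.integer(rownames(acc))] <- va[as.integer(rownames(acc))] + acc[, 1]
  }
  va
}

#' Topology report: Euler characteristic, genus flag, components
#'
#' Computes V - E + F on the mesh, the number of connected components
#' (vertex connectivity via shared edges), and whether the largest component
#' is a genus-zero closed surface (Euler characteristic 2). Meshes failing
#' the genus-zero test are flagged `dispersed = TRUE`: they mirror the
#' dispersed nuclear class, which is excluded from SPHARM analysis.
#'
#' @param mesh a [surface_mesh()].
#' @return list with `V`, `E`, `F`, `euler`, `component_count`,
#'   `genus_zero`, `dispersed`.
#' @export
mesh_topology <- function(mesh) {
  f <- mesh$faces
  ed <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  ed <- cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  key <- (ed[, 1] - 1) * (nrow(mesh$vertices) + 1) + ed[, 2]
  E <- length(unique(key))
  V <- length(unique(as.vector(f)))
  g <- igraph::graph_from_edgelist(ed[!duplicated(key), , drop = FALSE],
                                   directed = FALSE)
  comp <- igraph::components(g)
  used <- igraph::degree(g) > 0
  ncomp <- sum(tabulate(comp$membership[used]) > 0)
  euler <- V - E + nrow(f)
  list(V = V, E = E, F = nrow(f), euler = euler,
       component_count = ncomp,
       genus_zero = (ncomp == 1L && euler == 2L),
       dispersed = !(ncomp == 1L && euler == 2L))
}

# Largest connected component (by total face area).
mesh_largest_component <- function(mesh) {
  f <- mesh$faces
  ed <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  g <- igraph::graph_from_edgelist(ed, directed = FALSE)
  memb <- igraph::components(g)$membership
  fm <- memb[f[, 1]]
  areas <- mesh_face_geometry(mesh)$area
  keep_comp <- as.integer(names(which.max(tapply(areas, fm, sum))))
  keep <- fm == keep_comp
  f2 <- f[keep, , drop = FALSE]
  vid <- sort(unique(as.vector(f2)))
  remap <- integer(nrow(mesh$vertices)); remap[vid] <- seq_along(vid)
  surface_mesh(mesh$vertices[vid, , drop = FALSE],
               matrix(remap[f2], ncol = 3))
}

# Ensure outward orientation (positive signed volume); flips all faces if not.
mesh_orient_outward <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]; b <- v[f[, 2], , drop = FALSE]
  cc <- v[f[, 3], , drop = FALSE]
  svol <- sum(a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) +
                a[, 2] * (b[, 3] * cc[, 1] - b[, 1] * cc[, 3]) +
                a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1]))
  if (svol < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

#' Star-shapedness check by ray casting
#'
#' Casts `n_rays` random rays from the mesh centroid and counts
#' surface crossings per ray. A surface that is star-shaped about its
#' centroid is crossed exactly once in every direction, which is the
#' precondition for the radial spherical parameterization.
#'
#' @param mesh a [surface_mesh()].
#' @param n_rays number of random directions.
#' @param seed RNG seed for the directions.
#' @return list with `star_shaped` (logical) and `crossings` (per-ray count).
#' @export
is_star_shaped <- function(mesh, n_rays = 500L, seed = 1L) {
  dirs <- with_seed(seed, {
    d <- matrix(rnorm(3 * n_rays), ncol = 3)
    d / sqrt(rowSums(d^2))
  })
  v <- sweep(mesh$vertices, 2, mesh$centroid)
  f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - p1
  e2 <- v[f[, 3], , drop = FALSE] - p1
  crossings <- integer(n_rays)
  for (r in seq_len(n_rays)) {           # Moller-Trumbore, vectorized over faces
    d <- dirs[r, ]
    h <- cbind(d[2] * e2[, 3] - d[3] * e2[, 2],
               d[3] * e2[, 1] - d[1] * e2[, 3],
               d[1] * e2[, 2] - d[2] * e2[, 1])
    a <- rowSums(e1 * h)
    ok <- abs(a) > 1e-12
    u <- -rowSums(p1 * h) / a
    q <- cbind(-p1[, 2] * e1[, 3] + p1[, 3] * e1[, 2],
               -p1[, 3] * e1[, 1] + p1[, 1] * e1[, 3],
               -p1[, 1] * e1[, 2] + p1[, 2] * e1[, 1])
    vv <- as.vector(q %*% d) / a
    tt <- rowSums(e2 * q) / a
    hit <- ok & u >= 0 & u <= 1 & vv >= 0 & (u + vv) <= 1 & tt > 1e-9
    crossings[r] <- sum(hit)
  }
  list(star_shaped = all(crossings == 1L), crossings = crossings)
}

#' Uniform random rotation matrices
#'
#' Samples rotations uniformly from SO(3) via normalized Gaussian
#' quaternions.
#'
#' @param n number of rotations.
#' @param seed RNG seed.
#' @return list of 3 x 3 rotation matrices.
#' @export
random_rotations <- function(n, seed = 1L) {
  qs <- with_seed(seed, matrix(rnorm(4 * n), ncol = 4))
  qs <- qs / sqrt(rowSums(qs^2))
  lapply(seq_len(n), function(i) {
    q <- qs[i, ]; w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  })
}

#' Apply a rigid rotation (about the centroid) to a mesh
#'
#' @param mesh a [surface_mesh()].
#' @param R 3 x 3 rotation matrix.
#' @param about point to rotate about; default the mesh centroid.
#' @return the rotated `surface_mesh`.
#' @export
rotate_mesh <- function(mesh, R, about = mesh$centroid) {
  v <- sweep(mesh$vertices, 2, about)
  surface_mesh(sweep(v %*% t(R), 2, about, `+`), mesh$faces)
}

#' Triangulated mesh of a star-shaped surface given by a radial function
#'
#' Samples `r = rfun(theta, phi)` on a latitude-longitude grid (plus the two
#' poles) and triangulates it into a closed, outward-oriented genus-zero
#' mesh. This is the exact-mesh counterpart of the voxelized phantoms and
#' the workhorse for analytic fixtures.
#'
#' @param rfun vectorized function of (theta, phi) returning radii, um.
#' @param n_theta,n_phi grid resolution.
#' @param center 3-vector added to all vertices.
#' @return a [surface_mesh()].
#' @export
radial_mesh <- function(rfun, n_theta = 96L, n_phi = 192L, center = c(0, 0, 0)) {
  th <- (seq_len(n_theta) - 0.5) * pi / n_theta
  ph <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  TH <- rep(th, times = n_phi); PH <- rep(ph, each = n_theta)
  r <- rfun(TH, PH)
  if (any(!is.finite(r)) || any(r <= 0))
    .dt_stop("radial_mesh: radial function must be finite and > 0")
  vx <- r * sin(TH) * cos(PH)
  vy <- r * sin(TH) * sin(PH)
  vz <- r * cos(TH)
  vid <- function(i, j) (j - 1L) * n_theta + i
  np <- n_theta * n_phi
  vN <- np + 1L; vS <- np + 2L
  verts <- rbind(cbind(vx, vy, vz),
                 c(0, 0, rfun(1e-6, 0)),
                 c(0, 0, -rfun(pi - 1e-6, 0)))
  jj <- seq_len(n_phi); jn <- c(jj[-1], 1L)
  quads <- NULL
  for (i in seq_len(n_theta - 1L)) {
    a <- vid(i, jj); b <- vid(i + 1L, jj); cc <- vid(i, jn); d <- vid(i + 1L, jn)
    quads <- rbind(quads, cbind(a, b, cc), cbind(cc, b, d))
  }
  capN <- cbind(rep(vN, n_phi), vid(1L, jj), vid(1L, jn))
  capS <- cbind(rep(vS, n_phi), vid(n_theta, jn), vid(n_theta, jj))
  mesh_orient_outward(surface_mesh(sweep(verts, 2, center, `+`),
                                   rbind(quads, capN, capS)))
}
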