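# Internal structured tetrahedral meshing: a box grid is split into six
# tetrahedra per cell (Freudenthal subdivision, conforming across cells) and
# the vertices are mapped onto the target solid (ball or elliptic cylinder).

# Cumulative-offset corner indices (0..7, corner = di + 2*dj + 4*dk) for the
# six tetrahedra sharing the main diagonal of a unit cell.
.FREUDENTHAL_TETS <- matrix(c(
  0L, 1L, 3L, 7L,
  0L, 1L, 5L, 7L,
  0L, 2L, 3L, 7L,
  0L, 2L, 6L, 7L,
  0L, 4L, 5L, 7L,
  0L, 4L, 6L, 7L), ncol = 4L, byrow = TRUE)

# Vertex ids of a structured grid with (nx+1)(ny+1)(nz+1) vertices.
.grid_vertex_id <- function(i, j, k, nx, ny) {
  1L + i + (nx + 1L) * (j + (ny + 1L) * k)
}

# Unit-cube grid vertices in [0,1]^3 and the tetrahedra of all cells.
.grid_tets <- function(nx, ny, nz) {
  ii <- rep.int(0:(nx - 1L), ny * nz)
  jj <- rep.int(rep(0:(ny - 1L), each = nx), nz)
  kk <- rep(0:(nz - 1L), each = nx * ny)
  corner <- function(di, dj, dk) .grid_vertex_id(ii + di, jj + dj, kk + dk, nx, ny)
  corners <- cbind(corner(0L, 0L, 0L), corner(1L, 0L, 0L),
                   corner(0L, 1L, 0L), corner(1L, 1L, 0L),
                   corner(0L, 0L, 1L), corner(1L, 0L, 1L),
                   corner(0L, 1L, 1L), corner(1L, 1L, 1L))
  ncell <- length(ii)
  tets <- matrix(0L, nrow = 6L * ncell, ncol = 4L)
  for (t in 1:6) {
    idx <- seq.int(t, by = 6L, length.out = ncell)
    for (v in 1:4) tets[idx, v] <- corners[, .FREUDENTHAL_TETS[t, v] + 1L]
  }
  g <- expand.grid(i = 0:nx, j = 0:ny, k = 0:nz)
  verts <- cbind(g$i / nx, g$j / ny, g$k / nz)
  list(vertices = verts, tets = tets)
}

# Map the square [-1,1]^2 to the unit disk preserving concentric squares
# (sup-norm radius becomes the Euclidean radius).
.square_to_disk <- function(xy) {
  s <- pmax(abs(xy[, 1]), abs(xy[, 2]))
  r <- sqrt(xy[, 1]^2 + xy[, 2]^2)
  f <- ifelse(r > 0, s / r, 0)
  cbind(xy[, 1] * f, xy[, 2] * f)
}

# Map the cube [-1,1]^3 to the unit ball (sup-norm shells become spheres).
.cube_to_ball <- function(xyz) {
  s <- pmax(abs(xyz[, 1]), abs(xyz[, 2]), abs(xyz[, 3]))
  r <- sqrt(rowSums(xyz^2))
  f <- ifelse(r > 0, s / r, 0)
  xyz * f
}

.tet_signed_volume <- function(vertices, tets) {
  a <- vertices[tets[, 1], , drop = FALSE]
  e1 <- vertices[tets[, 2], , drop = FALSE] - a
  e2 <- vertices[tets[, 3], , drop = FALSE] - a
  e3 <- vertices[tets[, 4], , drop = FALSE] - a
  (e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) +
   e1[, 2] * (e2[, 3] * e3[, 1] - e2[, 1] * e3[, 3]) +
   e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])) / 6
}

# Swap two vertices of negatively oriented tets so all signed volumes are > 0.
.orient_tets <- function(vertices, tets) {
  v <- .tet_signed_volume(vertices, tets)
  neg <- which(v < 0)
  if (length(neg)) {
    tmp <- tets[neg, 3L]
    tets[neg, 3L] <- tets[neg, 4L]
    tets[neg, 4L] <- tmp
  }
  degen <- abs(.tet_signed_volume(vertices, tets)) < 1e-18
  if (any(degen)) tets <- tets[!degen, , drop = FALSE]
  tets
}

# Faces of each tet opposite to local vertex 1..4, ordered so that the face
# normal points away from the opposite vertex when traversed v1->v2->v3.
.tet_faces <- function(tets) {
  rbind(tets[, c(2L, 3L, 4L)],
        tets[, c(1L, 4L, 3L)],
        tets[, c(1L, 2L, 4L)],
        tets[, c(1L, 3L, 2L)])
}

# Extract the boundary surface: faces referenced by exactly one tetrahedron.
# Returns oriented triangles (outward normals), their areas, and owner tets.
.boundary_surface <- function(vertices, tets) {
  nt <- nrow(tets)
  faces <- .tet_faces(tets)
  a <- pmin(faces[, 1], faces[, 2], faces[, 3])
  c3 <- pmax(faces[, 1], faces[, 2], faces[, 3])
  b <- faces[, 1] + faces[, 2] + faces[, 3] - a - c3
  nv <- nrow(vertices)
  key <- (a * (nv + 1) + b) * (nv + 1) + c3
  cnt <- table(key)
  if (any(cnt > 2))
    stop("mesh is not a valid tetrahedral complex (face shared by >2 tets)")
  single <- names(cnt)[cnt == 1L]
  keep <- which(key %in% as.numeric(single))
  tri <- faces[keep, , drop = FALSE]
  owner <- ((keep - 1L) %% nt) + 1L
  p1 <- vertices[tri[, 1], , drop = FALSE]
  e1 <- vertices[tri[, 2], , drop = FALSE] - p1
  e2 <- vertices[tri[, 3], , drop = FALSE] - p1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area2 <- sqrt(rowSums(nrm^2))
  unit_n <- nrm / area2
  list(triangles = tri, normal = unit_n, area = area2 / 2, owner = owner)
}

# Interior/boundary face audit used by validity checks: counts of shared faces.
.face_share_counts <- function(vertices, tets) {
  faces <- .tet_faces(tets)
  a <- pmin(faces[, 1], faces[, 2], faces[, 3])
  c3 <- pmax(faces[, 1], faces[, 2], faces[, 3])
  b <- faces[, 1] + faces[, 2] + faces[, 3] - a - c3
  nv <- nrow(vertices)
  key <- (a * (nv + 1) + b) * (nv + 1) + c3
  tabulate(as.integer(factor(key)))
}
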