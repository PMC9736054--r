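#' Parametric compartment of a synthetic thorax
#'
#' Describes one tissue compartment as a parametric solid: an ellipsoid, an
#' elliptic cylinder with flat end caps, or a half-space cut (used for the
#' sub-diaphragm region).  Compartments are assembled into a torso by
#' [build_synthetic_thorax()].
#'
#' @param name compartment label (character scalar).
#' @param shape one of `"ellipsoid"`, `"elliptic_cylinder"`, `"halfspace_z"`.
#' @param center solid center, metres (3-vector; ignored for `halfspace_z`).
#' @param semi_axes semi-axis lengths, metres.  For `"elliptic_cylinder"` the
#'   third entry is the half-height.  Ignored for `halfspace_z`.
#' @param zmax for `"halfspace_z"`: points with `z < zmax` belong to the
#'   compartment.
#' @param conductivity electrical conductivity, S/m (must be positive).
#' @param parent name of the compartment this one is nested inside, or `NA`
#'   for a top-level compartment.  Nesting (e.g. blood inside the heart wall)
#'   is the only permitted overlap.
#' @return an object of class `"compartment_spec"`.
#' @export
compartment_spec <- function(name, shape = c("ellipsoid", "elliptic_cylinder",
                                             "halfspace_z"),
                             center = c(0, 0, 0), semi_axes = c(1, 1, 1),
                             zmax = 0, conductivity, parent = NA_character_) {
  shape <- match.arg(shape)
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(conductivity), length(conductivity) == 1L)
  if (conductivity <= 0) stop("conductivity must be positive (S/m)")
  if (shape != "halfspace_z" && any(semi_axes <= 0))
    stop("semi-axes must be positive")
  structure(list(name = name, shape = shape, center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes), zmax = zmax,
                 conductivity = conductivity, parent = parent),
            class = "compartment_spec")
}

# Membership test of points (n x 3) in a compartment solid.
.in_compartment <- function(spec, pts) {
  switch(spec$shape,
    ellipsoid = {
      d <- sweep(pts, 2, spec$center)
      (d[, 1] / spec$semi_axes[1])^2 + (d[, 2] / spec$semi_axes[2])^2 +
        (d[, 3] / spec$semi_axes[3])^2 <= 1
    },
    elliptic_cylinder = {
      d <- sweep(pts, 2, spec$center)
      ((d[, 1] / spec$semi_axes[1])^2 + (d[, 2] / spec$semi_axes[2])^2 <= 1) &
        abs(d[, 3]) <= spec$semi_axes[3]
    },
    halfspace_z = pts[, 3] < spec$zmax)
}

# Points on the surface of an ellipsoidal compartment (containment audits).
.ellipsoid_surface_points <- function(spec, n = 200L) {
  k <- seq_len(n)
  z <- (2 * k - 1) / n - 1
  th <- pi * (1 + sqrt(5)) * k          # Fibonacci sphere
  s <- sqrt(pmax(0, 1 - z^2))
  u <- cbind(s * cos(th), s * sin(th), z)
  sweep(u %*% diag(spec$semi_axes), 2, spec$center, "+")
}

.analytic_volume <- function(spec) {
  switch(spec$shape,
    ellipsoid = 4 / 3 * pi * prod(spec$semi_axes),
    elliptic_cylinder = pi * spec$semi_axes[1] * spec$semi_axes[2] *
      2 * spec$semi_axes[3],
    halfspace_z = NA_real_)
}

#' Default thorax compartments
#'
#' Five-tissue torso used throughout: an elliptic-cylinder trunk (thoracic
#' wall), a heart wall ellipsoid filled with a blood ellipsoid, two lung
#' ellipsoids, and a sub-diaphragm (abdominal) region.  Conductivities are
#' 0.2 S/m (heart muscle), 0.1 S/m (thoracic wall), 0.5 S/m (blood),
#' 0.1 S/m (abdomen) and 0.05 S/m (lungs), appropriate for the ECG
#' frequency band.  The frame has x running towards the left shoulder,
#' y from back to front and z upwards; dimensions are chosen so the heart
#' base lands at (0.1, 0.03, 0) m.
#'
#' @return list of [compartment_spec()] objects, outermost first.
#' @export
default_thorax_compartments <- function() {
  list(
    compartment_spec("torso", "elliptic_cylinder", center = c(0, 0, 0),
                     semi_axes = c(0.17, 0.13, 0.2115), conductivity = 0.1),
    compartment_spec("abdomen", "halfspace_z", zmax = -0.12,
                     conductivity = 0.1, parent = "torso"),
    compartment_spec("lung_left", "ellipsoid", center = c(0.095, -0.050, 0.115),
                     semi_axes = c(0.040, 0.046, 0.090), conductivity = 0.05,
                     parent = "torso"),
    compartment_spec("lung_right", "ellipsoid", center = c(-0.08, 0.005, 0.06),
                     semi_axes = c(0.058, 0.070, 0.135), conductivity = 0.05,
                     parent = "torso"),
    compartment_spec("heart", "ellipsoid", center = c(0.08, 0.02, -0.02),
                     semi_axes = c(0.055, 0.050, 0.075), conductivity = 0.2,
                     parent = "torso"),
    compartment_spec("blood", "ellipsoid", center = c(0.08, 0.02, -0.02),
                     semi_axes = c(0.040, 0.036, 0.055), conductivity = 0.5,
                     parent = "heart"))
}

# Assemble the mesh object, extract boundary, and validate orientation.
.new_thorax_mesh <- function(vertices, tets, label, conductivity_map) {
  tets <- .orient_tets(vertices, tets[, , drop = FALSE])
  if (length(label) == 1L) label <- rep(label, nrow(tets))
  if (length(label) != nrow(tets)) stop("one label per tetrahedron required")
  if (!all(unique(label) %in% names(conductivity_map)))
    stop("all tet labels must be present in the conductivity map")
  bnd <- .boundary_surface(vertices, tets)
  structure(list(vertices = vertices, tets = tets, label = label,
                 conductivity = conductivity_map, boundary = bnd,
                 cache = new.env(parent = emptyenv())),
            class = "thorax_mesh")
}

#' Homogeneous ball mesh (analytic oracle geometry)
#'
#' Builds a single-compartment tetrahedral ball centred at the origin by
#' mapping a structured cube grid onto the ball; boundary vertices lie
#' exactly on the sphere of radius `radius`.  Used as an oracle geometry
#' because the surface potential of a central current dipole has a closed
#' form there.
#'
#' @param radius sphere radius, metres.
#' @param conductivity tissue conductivity, S/m.
#' @param resolution target edge length, metres (element count grows as
#'   `resolution^-3`).
#' @return a `"thorax_mesh"` with a single `"sphere"` compartment.
#' @examples
#' m <- build_homogeneous_sphere(0.1, 0.2, resolution = 0.02)
#' sum(mesh_volumes(m))          # close to 4/3*pi*0.1^3
#' @export
build_homogeneous_sphere <- function(radius, conductivity, resolution) {
  stopifnot(radius > 0, conductivity > 0, resolution > 0)
  n <- max(4L, 2L * as.integer(round(radius / resolution)))
  g <- .grid_tets(n, n, n)
  xyz <- radius * .cube_to_ball(2 * g$vertices - 1)
  .new_thorax_mesh(xyz, g$tets, "sphere", c(sphere = conductivity))
}

#' Synthetic multi-compartment thorax mesh
#'
#' Meshes the torso solid (the first, outermost compartment, an elliptic
#' cylinder) with a structured tetrahedral grid and labels each tetrahedron
#' by the innermost compartment containing its centroid.  Compartments other
#' than declared parent/child pairs must not overlap, and every inner
#' compartment must lie inside the torso; both conditions are checked and
#' violations raise an error naming the offending compartment.
#'
#' @param compartments list of [compartment_spec()], outermost first; the
#'   default is [default_thorax_compartments()].
#' @param resolution target edge length, metres (default 0.015 gives on the
#'   order of 1e5 tetrahedra; 0.025 is a fast preset).
#' @return a labelled `"thorax_mesh"`.
#' @export
build_synthetic_thorax <- function(compartments = default_thorax_compartments(),
                                   resolution = 0.015) {
  stopifnot(resolution > 0, length(compartments) >= 1L)
  torso <- compartments[[1L]]
  if (torso$shape != "elliptic_cylinder")
    stop("the first (outermost) compartment must be an elliptic cylinder")
  inner <- compartments[-1L]

  # containment audit: inner solids must stay inside the torso
  for (sp in inner) {
    if (sp$shape != "ellipsoid") next
    pts <- .ellipsoid_surface_points(sp)
    if (!all(.in_compartment(torso, pts)))
      stop("compartment '", sp$name, "' is not contained in the torso solid")
  }

  a <- torso$semi_axes[1]; b <- torso$semi_axes[2]; hh <- torso$semi_axes[3]
  nxy <- max(4L, 2L * as.integer(round(max(a, b) / resolution)))
  nz <- max(2L, as.integer(round(2 * hh / resolution)))
  g <- .grid_tets(nxy, nxy, nz)
  xy <- .square_to_disk(2 * g$vertices[, 1:2] - 1)
  zmin <- torso$center[3] - hh
  zmax <- torso$center[3] + hh
  tz <- g$vertices[, 3]
  # align any half-space cut plane with a grid level so the sub-diaphragm
  # volume is resolution-independent
  zcuts <- vapply(Filter(function(s) s$shape == "halfspace_z", inner),
                  `[[`, 0, "zmax")
  zz <- zmin + (zmax - zmin) * tz
  for (zc in zcuts) {
    if (zc <= zmin || zc >= zmax) next
    td <- (zc - zmin) / (zmax - zmin)
    k <- min(nz - 1L, max(1L, as.integer(round(nz * td))))
    f <- k / nz
    zz <- ifelse(tz <= f, zmin + (zc - zmin) * tz / f,
                 zc + (zmax - zc) * (tz - f) / (1 - f))
  }
  xyz <- cbind(torso$center[1] + a * xy[, 1],
               torso$center[2] + b * xy[, 2], zz)
  tets <- .orient_tets(xyz, g$tets)

  # membership by majority volume fraction: straddling tets are resolved on a
  # barycentric lattice so per-label volumes are stable across resolutions
  cen <- (xyz[tets[, 1], ] + xyz[tets[, 2], ] +
          xyz[tets[, 3], ] + xyz[tets[, 4], ]) / 4
  bc <- as.matrix(expand.grid(i = 0:4, j = 0:4, k = 0:4))
  bc <- bc[rowSums(bc) <= 4, , drop = FALSE]
  bc <- cbind(bc, 4 - rowSums(bc)) / 4            # 35-point simplex lattice
  label <- rep(torso$name, nrow(tets))
  member <- matrix(FALSE, nrow(tets), length(inner))
  for (i in seq_along(inner)) {
    sp <- inner[[i]]
    inside <- .in_compartment(sp, cen)
    vin <- matrix(FALSE, nrow(tets), 4L)
    for (v in 1:4) vin[, v] <- .in_compartment(sp, xyz[tets[, v], , drop = FALSE])
    nin <- rowSums(vin)
    full <- nin == 4L & inside
    mixed <- which((nin > 0L | inside) & !full)
    member[, i] <- full
    if (length(mixed)) {
      frac <- numeric(length(mixed))
      for (q in seq_len(nrow(bc))) {
        pts <- bc[q, 1] * xyz[tets[mixed, 1], , drop = FALSE] +
               bc[q, 2] * xyz[tets[mixed, 2], , drop = FALSE] +
               bc[q, 3] * xyz[tets[mixed, 3], , drop = FALSE] +
               bc[q, 4] * xyz[tets[mixed, 4], , drop = FALSE]
        frac <- frac + .in_compartment(sp, pts)
      }
      frac <- frac / nrow(bc)
      # include mixed tets in decreasing inside-fraction order until the
      # labelled volume matches the quadrature volume of the intersection
      vol <- .tet_signed_volume(xyz, tets[mixed, , drop = FALSE])
      target <- sum(frac * vol)
      ord <- order(-frac, mixed)
      cum <- cumsum(vol[ord])
      k <- which.min(abs(cum - target))
      if (cum[k] > 0 && target > 0) member[mixed[ord[seq_len(k)]], i] <- TRUE
    }
  }

  # overlap audit: simultaneous membership only along declared parent chains
  if (length(inner) >= 2L) {
    nm <- vapply(inner, `[[`, "", "name")
    par <- vapply(inner, `[[`, "", "parent")
    related <- function(i, j) {
      chain <- function(k) {
        out <- nm[k]; p <- par[k]
        while (!is.na(p) && p %in% nm) { out <- c(out, p); p <- par[match(p, nm)] }
        out
      }
      nm[j] %in% chain(i) || nm[i] %in% chain(j)
    }
    for (i in seq_len(length(inner) - 1L)) for (j in (i + 1L):length(inner)) {
      if (!related(i, j) && any(member[, i] & member[, j]))
        stop("compartments '", nm[i], "' and '", nm[j],
             "' overlap without declared nesting")
    }
  }
  for (i in seq_along(inner)) label[member[, i]] <- inner[[i]]$name

  sigma <- vapply(compartments, `[[`, 0, "conductivity")
  names(sigma) <- vapply(compartments, `[[`, "", "name")
  .new_thorax_mesh(xyz, tets, label, sigma)
}

#' Per-compartment tissue volumes
#'
#' @param mesh a `"thorax_mesh"`.
#' @return named numeric vector of volumes (m^3) by compartment label.
#' @export
mesh_volumes <- function(mesh) {
  v <- .tet_signed_volume(mesh$vertices, mesh$tets)
  tapply(v, mesh$label, sum)
}

#' @export
print.thorax_mesh <- function(x, ...) {
  cat("Tetrahedral thorax mesh\n")
  cat("  vertices:", nrow(x$vertices), " tetrahedra:", nrow(x$tets),
      " boundary triangles:", nrow(x$boundary$triangles), "\n")
  vols <- mesh_volumes(x)
  cat("  compartments (sigma S/m, volume cm^3):\n")
  for (nm in names(vols))
    cat(sprintf("    %-10s %5.2f  %8.1f\n", nm, x$conductivity[[nm]],
                vols[[nm]] * 1e6))
  invisible(x)
}

# Per-boundary-vertex lumped area weights (one third of incident triangle
# areas) and area-weighted outward unit normals.
.boundary_vertex_data <- function(mesh, tri_ids = NULL) {
  bnd <- mesh$boundary
  tri <- bnd$triangles
  if (!is.null(tri_ids)) tri <- tri[tri_ids, , drop = FALSE]
  area <- if (is.null(tri_ids)) bnd$area else bnd$area[tri_ids]
  nrm <- if (is.null(tri_ids)) bnd$normal else bnd$normal[tri_ids, , drop = FALSE]
  ids <- sort(unique(as.vector(tri)))
  idx <- match(as.vector(tri), ids)
  w <- rep(area / 3, 3L)
  weights <- as.vector(rowsum(w, idx, reorder = TRUE))
  nsum <- rowsum(nrm[rep(seq_len(nrow(tri)), 3L), , drop = FALSE] *
                   rep(area, 3L), idx, reorder = TRUE)
  nn <- nsum / sqrt(rowSums(nsum^2))
  list(vertex_ids = ids, weights = weights, normal = nn)
}

# End-cap boundary triangles of an extruded solid: all three vertices on the
# extreme z planes.  A sphere has none.
.cap_triangles <- function(mesh) {
  z <- mesh$vertices[, 3]
  tol <- 1e-9 * (max(z) - min(z))
  tri <- mesh$boundary$triangles
  zt <- matrix(z[tri], ncol = 3L)
  top <- rowSums(abs(zt - max(z)) < tol) == 3L
  bot <- rowSums(abs(zt - min(z)) < tol) == 3L
  top | bot
}

#' Extract the dorsal (back) surface patch
#'
#' Selects the boundary vertices whose y-coordinate falls in the lowest
#' `y_fraction` quantile of the trunk boundary (y runs from back to front),
#' excluding flat end caps.  The returned patch carries per-vertex lumped
#' area weights used for surface integrals.
#'
#' @param mesh a `"thorax_mesh"`.
#' @param y_fraction fraction of the boundary to keep, in (0, 0.5].
#' @return an object of class `"surface_patch"` with fields `vertex_ids`,
#'   `tri_ids`, `weights` (m^2), `normal`, and `coords`.
#' @export
extract_back_patch <- function(mesh, y_fraction = 0.5) {
  stopifnot(y_fraction > 0, y_fraction <= 0.5)
  caps <- .cap_triangles(mesh)
  trunk_tris <- which(!caps)
  if (!length(trunk_tris)) stop("no trunk boundary triangles")
  tri <- mesh$boundary$triangles[trunk_tris, , drop = FALSE]
  verts <- sort(unique(as.vector(tri)))
  y <- mesh$vertices[verts, 2]
  thr <- stats::quantile(y, y_fraction, names = FALSE, type = 7)
  keep <- verts[y <= thr + 1e-12]
  if (!length(keep)) stop("empty back patch selection")
  in_patch <- matrix(tri %in% keep, ncol = 3L)
  tri_keep <- trunk_tris[rowSums(in_patch) == 3L]
  if (!length(tri_keep)) stop("back patch contains no complete triangle")
  bd <- .boundary_vertex_data(mesh, tri_keep)
  structure(list(mesh = mesh, vertex_ids = bd$vertex_ids,
                 tri_ids = tri_keep, weights = bd$weights,
                 normal = bd$normal,
                 coords = mesh$vertices[bd$vertex_ids, , drop = FALSE]),
            class = "surface_patch")
}

#' @export
print.surface_patch <- function(x, ...) {
  cat("Surface patch:", length(x$vertex_ids), "vertices,",
      length(x$tri_ids), "triangles, area",
      format(sum(x$weights), digits = 4), "m^2\n")
  invisible(x)
}
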