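# Quasi-static forward ECG problem: div(sigma grad phi) = I_sv inside the
# torso with a homogeneous Neumann condition on the skin.  Piecewise-linear
# (P1) tetrahedral elements, per-element conductivity, direct sparse solve.
# The pure-Neumann solution is fixed by the zero-boundary-mean gauge.

#' Convert heart-axis angles to a dipole moment vector
#'
#' Azimuth is measured in the x-y plane from the +x axis; elevation is the
#' polar angle from the +z axis.
#'
#' @param magnitude dipole moment magnitude, A*m.
#' @param azimuth azimuth angle, radians.
#' @param elevation polar (elevation) angle from +z, radians.
#' @return moment vector (3-vector, A*m) with Euclidean norm `magnitude`.
#' @examples
#' angles_to_moment(2e-5, 5 * pi / 6, 3 * pi / 4)
#' @export
angles_to_moment <- function(magnitude, azimuth, elevation) {
  stopifnot(magnitude >= 0)
  magnitude * c(sin(elevation) * cos(azimuth),
                sin(elevation) * sin(azimuth),
                cos(elevation))
}

#' Cardiac equivalent dipole source
#'
#' A single current dipole standing in for the heart's net electrical
#' activity at one instant.  Either a moment vector or
#' magnitude/azimuth/elevation angles may be given.
#'
#' @param position dipole position, metres (3-vector), strictly inside the
#'   mesh it is used with.
#' @param magnitude moment magnitude, A*m (with `azimuth`/`elevation`).
#' @param azimuth,elevation heart-axis angles, radians (see
#'   [angles_to_moment()]).
#' @param moment moment vector, A*m (alternative to the angle form).
#' @return an object of class `"dipole_source"`.
#' @export
dipole_source <- function(position = c(0.1, 0.03, 0), magnitude = 2e-5,
                          azimuth = 5 * pi / 6, elevation = 3 * pi / 4,
                          moment = NULL) {
  if (is.null(moment)) moment <- angles_to_moment(magnitude, azimuth, elevation)
  structure(list(position = as.numeric(position),
                 moment = as.numeric(moment),
                 magnitude = sqrt(sum(moment^2))),
            class = "dipole_source")
}

#' @export
print.dipole_source <- function(x, ...) {
  cat(sprintf("Dipole source: |m| = %.3g A*m at (%.3g, %.3g, %.3g) m\n",
              x$magnitude, x$position[1], x$position[2], x$position[3]))
  cat(sprintf("  moment = (%.3g, %.3g, %.3g) A*m\n",
              x$moment[1], x$moment[2], x$moment[3]))
  invisible(x)
}

# Per-element P1 shape-function gradients and volumes, cached on the mesh.
.fem_geometry <- function(mesh) {
  cache <- mesh$cache
  if (!is.null(cache$geom)) return(cache$geom)
  V <- mesh$vertices; TT <- mesh$tets
  a <- V[TT[, 1], , drop = FALSE]
  e1 <- V[TT[, 2], , drop = FALSE] - a
  e2 <- V[TT[, 3], , drop = FALSE] - a
  e3 <- V[TT[, 4], , drop = FALSE] - a
  cr <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                             u[, 3] * v[, 1] - u[, 1] * v[, 3],
                             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  c23 <- cr(e2, e3)
  det <- rowSums(e1 * c23)
  g2 <- c23 / det
  g3 <- cr(e3, e1) / det
  g4 <- cr(e1, e2) / det
  g1 <- -(g2 + g3 + g4)
  geom <- list(grad = list(g1, g2, g3, g4), vol = det / 6,
               origin = a)
  cache$geom <- geom
  geom
}

# Assembled stiffness matrix K with K_ij = sum_e sigma_e vol_e grad_i.grad_j,
# cached on the mesh.  Symmetric positive semi-definite with nullspace 1.
.stiffness <- function(mesh) {
  cache <- mesh$cache
  if (!is.null(cache$K)) return(cache$K)
  geom <- .fem_geometry(mesh)
  sigma <- unname(mesh$conductivity[mesh$label])
  sv <- sigma * geom$vol
  TT <- mesh$tets
  nt <- nrow(TT)
  ii <- integer(16L * nt); jj <- integer(16L * nt); xx <- numeric(16L * nt)
  k <- 0L
  for (i in 1:4) for (j in 1:4) {
    idx <- k * nt + seq_len(nt)
    ii[idx] <- TT[, i]
    jj[idx] <- TT[, j]
    xx[idx] <- sv * rowSums(geom$grad[[i]] * geom$grad[[j]])
    k <- k + 1L
  }
  K <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                            dims = c(nrow(mesh$vertices), nrow(mesh$vertices)))
  K <- Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
  cache$K <- K
  K
}

# Cholesky factor of K with vertex 1 pinned (the compatible load makes the
# pinned solution equal to the true one up to a constant).
.stiffness_factor <- function(mesh) {
  cache <- mesh$cache
  if (!is.null(cache$chol)) return(cache$chol)
  K <- .stiffness(mesh)
  cache$chol <- Matrix::Cholesky(K[-1L, -1L], LDL = FALSE, perm = TRUE)
  cache$chol
}

# Barycentric coordinates of point q in every tet; returns the containing tet
# (max-min coordinate) and its barycentric weights.
.locate_point <- function(mesh, q) {
  geom <- .fem_geometry(mesh)
  d <- sweep(geom$origin, 2, q, "-")
  l2 <- -rowSums(d * geom$grad[[2]])
  l3 <- -rowSums(d * geom$grad[[3]])
  l4 <- -rowSums(d * geom$grad[[4]])
  l1 <- 1 - l2 - l3 - l4
  m <- pmin(l1, l2, l3, l4)
  best <- which.max(m)
  if (m[best] < -1e-9)
    return(NULL)
  list(tet = best, bary = c(l1[best], l2[best], l3[best], l4[best]))
}

#' Discrete dipole source load
#'
#' Realizes the dipole as axis-aligned monopole pairs: each Cartesian
#' component m_i of the moment contributes point sources +/- m_i/delta at
#' `position +/- (delta/2) e_i`, distributed to the vertices of the
#' containing tetrahedron by barycentric weights.  The decomposition is
#' exactly linear in the moment vector, so lead-field superposition holds to
#' solver precision.  The entries of the load sum to zero (compatibility
#' with the pure-Neumann problem).
#'
#' @param mesh a `"thorax_mesh"`.
#' @param source a `"dipole_source"` strictly inside the mesh.
#' @param delta monopole separation, metres (default 2 mm; keep below a few
#'   element lengths).
#' @return per-vertex source vector (A).
#' @export
dipole_load <- function(mesh, source, delta = 0.002) {
  stopifnot(delta > 0)
  f <- numeric(nrow(mesh$vertices))
  if (source$magnitude == 0) return(f)
  for (ax in 1:3) {
    mi <- source$moment[ax]
    if (mi == 0) next
    e <- c(0, 0, 0); e[ax] <- 1
    I <- mi / delta
    for (s in c(1, -1)) {
      q <- source$position + s * (delta / 2) * e
      loc <- .locate_point(mesh, q)
      if (is.null(loc))
        stop(sprintf("monopole at (%.4g, %.4g, %.4g) lies outside the mesh",
                     q[1], q[2], q[3]))
      vid <- mesh$tets[loc$tet, ]
      f[vid] <- f[vid] + s * I * loc$bary
    }
  }
  f
}

#' Solve the forward ECG problem
#'
#' P1 finite-element solution of `div(sigma grad phi) = I_sv` with a
#' homogeneous Neumann boundary condition; the additive constant is fixed by
#' the zero-mean-over-boundary-vertices gauge, so potential differences (lead
#' voltages) are gauge-free.
#'
#' @param mesh a `"thorax_mesh"`.
#' @param source a `"dipole_source"` inside the mesh, or a precomputed load
#'   vector from [dipole_load()].
#' @param delta monopole separation passed to [dipole_load()].
#' @return an object of class `"potential_solution"` with per-vertex
#'   potential `phi` (V), the relative residual of the linear solve, and
#'   references to mesh and source.
#' @examples
#' m <- build_homogeneous_sphere(0.1, 0.2, resolution = 0.025)
#' s <- dipole_source(position = c(0, 0, 0), moment = c(0, 0, 2e-5))
#' sol <- solve_forward(m, s)
#' @export
solve_forward <- function(mesh, source, delta = 0.002) {
  if (inherits(source, "dipole_source")) {
    f <- dipole_load(mesh, source, delta)
  } else {
    f <- as.numeric(source)
    source <- NULL
  }
  if (abs(sum(f)) > 1e-12 * max(sum(abs(f)), 1e-300))
    stop("incompatible load: source terms do not sum to zero")
  n <- nrow(mesh$vertices)
  phi <- numeric(n)
  if (any(f != 0)) {
    ch <- .stiffness_factor(mesh)
    phi[-1L] <- as.numeric(Matrix::solve(ch, f[-1L]))
  }
  K <- .stiffness(mesh)
  res <- sqrt(sum(as.numeric(K %*% phi - f)^2))
  nf <- sqrt(sum(f^2))
  rel <- if (nf > 0) res / nf else 0
  if (rel > 1e-8)
    stop(sprintf("linear solve did not converge (relative residual %.3g)", rel))
  bverts <- sort(unique(as.vector(mesh$boundary$triangles)))
  phi <- phi - mean(phi[bverts])
  structure(list(phi = phi, mesh = mesh, source = source,
                 gauge = "zero-boundary-mean", residual = rel),
            class = "potential_solution")
}

#' @export
print.potential_solution <- function(x, ...) {
  bverts <- sort(unique(as.vector(x$mesh$boundary$triangles)))
  cat("Forward-problem potential solution\n")
  cat(sprintf("  surface potential range: [%.3g, %.3g] V\n",
              min(x$phi[bverts]), max(x$phi[bverts])))
  cat(sprintf("  gauge: %s, solve residual %.2g\n", x$gauge, x$residual))
  invisible(x)
}

#' Surface potential and electric-field map
#'
#' Evaluates E = -grad(phi) on each element (constant for P1), averages
#' volume-weighted over the tetrahedra incident to each boundary vertex, and
#' splits off the tangential component with respect to the area-weighted
#' vertex normal.
#'
#' @param solution a `"potential_solution"`.
#' @return an object of class `"surface_field_map"` with boundary
#'   `vertex_ids`, `coords`, potential `V`, field `E` (n x 3, V/m), unit
#'   `normal`, `tangential` field (n x 3), and lumped area `weights` (m^2).
#' @export
surface_field_map <- function(solution) {
  mesh <- solution$mesh
  geom <- .fem_geometry(mesh)
  TT <- mesh$tets
  phi <- solution$phi
  E <- -(geom$grad[[1]] * phi[TT[, 1]] + geom$grad[[2]] * phi[TT[, 2]] +
         geom$grad[[3]] * phi[TT[, 3]] + geom$grad[[4]] * phi[TT[, 4]])
  bd <- .boundary_vertex_data(mesh)
  ids <- bd$vertex_ids
  nv <- nrow(mesh$vertices)
  esum <- matrix(0, nv, 3L)
  vol <- geom$vol
  flat <- as.vector(TT)
  wsum <- numeric(nv)
  acc <- rowsum(cbind(rep(vol, 4L), E[rep(seq_len(nrow(TT)), 4L), ] * rep(vol, 4L)),
                flat, reorder = TRUE)
  present <- sort(unique(flat))
  wsum[present] <- acc[, 1]
  esum[present, ] <- acc[, 2:4]
  Ev <- esum[ids, , drop = FALSE] / wsum[ids]
  nrm <- bd$normal
  en <- rowSums(Ev * nrm)
  tang <- Ev - nrm * en
  structure(list(vertex_ids = ids,
                 coords = mesh$vertices[ids, , drop = FALSE],
                 V = phi[ids], E = Ev, normal = nrm, tangential = tang,
                 weights = bd$weights, mesh = mesh),
            class = "surface_field_map")
}

#' @export
print.surface_field_map <- function(x, ...) {
  cat("Surface field map:", length(x$vertex_ids), "boundary vertices\n")
  cat(sprintf("  V in [%.3g, %.3g] V; |E_t| up to %.3g V/m\n",
              min(x$V), max(x$V), max(sqrt(rowSums(x$tangential^2)))))
  invisible(x)
}

#' Lead-field basis at a source position
#'
#' Solves the forward problem for unit dipole moments along x, y and z at a
#' fixed position.  By linearity, the solution for any moment vector m is
#' `m[1]*phi_x + m[2]*phi_y + m[3]*phi_z`, so time-varying dipoles need no
#' further solves.
#'
#' @param mesh a `"thorax_mesh"`.
#' @param position dipole position, metres.
#' @param delta monopole separation passed to [dipole_load()].
#' @return an object of class `"lead_field_basis"`: list with `phi` (n x 3
#'   matrix of potentials per unit moment), `position`, `mesh`.
#' @export
lead_field_basis <- function(mesh, position, delta = 0.002) {
  phi <- matrix(0, nrow(mesh$vertices), 3L)
  for (ax in 1:3) {
    mom <- c(0, 0, 0); mom[ax] <- 1
    s <- dipole_source(position = position, moment = mom)
    phi[, ax] <- solve_forward(mesh, s, delta = delta)$phi
  }
  structure(list(phi = phi, position = as.numeric(position), mesh = mesh,
                 delta = delta),
            class = "lead_field_basis")
}

#' Combine a lead-field basis with a moment vector
#'
#' @param basis a `"lead_field_basis"`.
#' @param moment moment vector (A*m).
#' @return a `"potential_solution"` for that moment, by superposition.
#' @export
basis_solution <- function(basis, moment) {
  phi <- as.numeric(basis$phi %*% as.numeric(moment))
  structure(list(phi = phi, mesh = basis$mesh,
                 source = dipole_source(position = basis$position,
                                        moment = moment),
                 gauge = "zero-boundary-mean", residual = 0),
            class = "potential_solution")
}
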