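# Capacitive (non-contact) electrode model: the electrode is equipotential
# and couples to the body through a thin gap; its potential is the
# coupling-capacitance-weighted average of the body-surface potential,
#   Ve = (int_Se V Ce dS) / (int_Se Ce dS),
# which is independent of frequency.  Motion-artifact sensitivity follows
# from perturbing either the gap (normal motion) or the patch position
# (tangential slide) in this ratio.

.EPS0 <- 8.8541878128e-12  # vacuum permittivity, F/m

#' Parallel-plate coupling capacitance
#'
#' @param area electrode area, m^2.
#' @param gap electrode-to-body distance, metres.
#' @param eps_r relative permittivity of the gap material (>= 1, default 1:
#'   an air-dominated gap).
#' @return capacitance, farads: `eps0 * eps_r * area / gap`.
#' @examples
#' plate_capacitance(pi * 0.01^2, 1e-3)   # ~2.78 pF
#' @export
plate_capacitance <- function(area, gap, eps_r = 1) {
  stopifnot(area > 0, eps_r >= 1)
  if (any(gap <= 0)) stop("gap must be positive")
  .EPS0 * eps_r * area / gap
}

#' Capacitive electrode specification
#'
#' @param center electrode centre, metres (on or near the boundary surface).
#' @param radius electrode radius, metres (default 0.01, i.e. the 2 cm
#'   diameter disks used throughout).
#' @param gap nominal electrode-body distance, metres (default 1 mm, the
#'   thickness of a cotton layer).
#' @param eps_r relative permittivity of the gap (default 1).
#' @param gap_profile `"uniform"` for a constant gap, or `"plate"` for a
#'   rigid flat plate: the local gap grows with the surface's deviation from
#'   the tangent plane at the electrode centre.
#' @param omega nominal angular frequency, rad/s.  It cancels from the
#'   electrode-potential ratio and is retained only for completeness.
#' @return an object of class `"capacitive_electrode"`.
#' @export
capacitive_electrode <- function(center, radius = 0.01, gap = 1e-3,
                                 eps_r = 1, gap_profile = c("uniform", "plate"),
                                 omega = 2 * pi * 10) {
  gap_profile <- match.arg(gap_profile)
  stopifnot(radius > 0, all(gap > 0), eps_r >= 1)
  structure(list(center = as.numeric(center), radius = radius, gap = gap,
                 eps_r = eps_r, gap_profile = gap_profile, omega = omega),
            class = "capacitive_electrode")
}

#' Electrode-body coupling on a mesh surface
#'
#' Collects the boundary region under the electrode (triangles whose
#' centroid lies within the electrode radius of its centre, falling back to
#' vertices within the radius on coarse meshes) and computes the per-vertex
#' specific capacitance `Ce = eps0*eps_r/d` together with lumped area
#' weights.  The model assumes the plate regime (electrode diameter larger
#' than the gap); a gap of at least the electrode diameter is recorded as a
#' warning in the result.
#'
#' @param mesh a `"thorax_mesh"`.
#' @param electrode a `"capacitive_electrode"` whose centre lies within two
#'   radii of the boundary surface.
#' @return an object of class `"electrode_coupling"` with fields
#'   `vertex_ids`, `weights` (m^2), `gap` (m, per vertex), `Ce` (F/m^2),
#'   `total_capacitance` (F), `area` (m^2), `normal` (patch mean unit
#'   normal), `center_surface` (nearest surface point).
#' @export
electrode_coupling <- function(mesh, electrode) {
  bnd <- mesh$boundary
  bd <- .boundary_vertex_data(mesh)
  bc <- mesh$vertices[bd$vertex_ids, , drop = FALSE]
  d2 <- sqrt(rowSums(sweep(bc, 2, electrode$center)^2))
  near <- which.min(d2)
  if (d2[near] > 2 * electrode$radius)
    stop("electrode centre is too far from the boundary surface")
  # the electrode rests against the body: snap the centre to the surface
  x0 <- bc[near, ]
  tri <- bnd$triangles
  cen <- (mesh$vertices[tri[, 1], , drop = FALSE] +
          mesh$vertices[tri[, 2], , drop = FALSE] +
          mesh$vertices[tri[, 3], , drop = FALSE]) / 3
  tsel <- which(sqrt(rowSums(sweep(cen, 2, x0)^2)) <= electrode$radius)
  if (length(tsel)) {
    pd <- .boundary_vertex_data(mesh, tsel)
    ids <- pd$vertex_ids; w <- pd$weights
  } else {
    d0 <- sqrt(rowSums(sweep(bc, 2, x0)^2))
    ids <- bd$vertex_ids[d0 <= electrode$radius]
    if (!length(ids)) stop("no boundary vertices under the electrode")
    w <- bd$weights[match(ids, bd$vertex_ids)]
  }
  nrm <- bd$normal[match(ids, bd$vertex_ids), , drop = FALSE]
  nbar <- colSums(nrm * w); nbar <- nbar / sqrt(sum(nbar^2))
  pts <- mesh$vertices[ids, , drop = FALSE]
  if (length(electrode$gap) > 1L) {
    gap <- rep_len(electrode$gap, length(ids))
  } else if (electrode$gap_profile == "plate") {
    sag <- as.numeric((matrix(x0, length(ids), 3, byrow = TRUE) - pts) %*% nbar)
    gap <- electrode$gap + pmax(0, sag)
  } else {
    gap <- rep(electrode$gap, length(ids))
  }
  Ce <- .EPS0 * electrode$eps_r / gap
  warn <- NULL
  if (max(gap) >= 2 * electrode$radius)
    warn <- "gap is not small compared with the electrode diameter; the plate-coupling approximation is outside its stated regime"
  structure(list(electrode = electrode, mesh = mesh, vertex_ids = ids,
                 weights = w, gap = gap, Ce = Ce,
                 total_capacitance = sum(Ce * w), area = sum(w),
                 normal = nbar, center_surface = x0, warning = warn),
            class = "electrode_coupling")
}

#' @export
print.electrode_coupling <- function(x, ...) {
  cat(sprintf("Electrode coupling: %d vertices, area %.3g m^2, C = %.3g pF\n",
              length(x$vertex_ids), x$area, x$total_capacitance * 1e12))
  if (!is.null(x$warning)) cat("  note:", x$warning, "\n")
  invisible(x)
}

# Field values at the coupling vertices.
.field_at <- function(field, ids) {
  idx <- match(ids, field$vertex_ids)
  if (anyNA(idx))
    stop("electrode patch is not contained in the field's boundary surface")
  idx
}

#' Capacitive electrode potential
#'
#' The specific-capacitance-weighted surface average of the body potential
#' under the electrode.  For uniform coupling this is the plain area-weighted
#' mean; on an equipotential surface it equals the surface value.  The
#' result does not depend on the excitation frequency.
#'
#' @param field a `"surface_field_map"`.
#' @param coupling an `"electrode_coupling"` on the same mesh.
#' @return electrode potential Ve, volts.
#' @export
electrode_potential <- function(field, coupling) {
  idx <- .field_at(field, coupling$vertex_ids)
  # a uniform specific capacitance cancels exactly from the ratio
  u <- if (diff(range(coupling$Ce)) == 0) coupling$weights
       else coupling$Ce * coupling$weights
  den <- sum(u)
  if (den <= 0 || all(coupling$Ce <= 0)) stop("zero total coupling capacitance")
  sum(field$V[idx] * u) / den
}

#' Motion sensitivity of the electrode potential
#'
#' Finite-difference sensitivity of Ve to a rigid electrode displacement,
#' holding the body-surface potential fixed (quasi-static motion): in
#' `"normal"` mode the gap is increased by `step` everywhere (the coupling
#' profile is re-derived, Ce -> eps0*eps_r/(d+step)); in `"tangential"` mode
#' the electrode centre slides by `step` along the surface-projected
#' `direction` and the patch is rebuilt with the same gap law.
#'
#' @param field a `"surface_field_map"`.
#' @param coupling an `"electrode_coupling"`.
#' @param mode `"normal"` or `"tangential"`.
#' @param direction displacement direction for tangential mode (3-vector;
#'   projected onto the local tangent plane).
#' @param step displacement, metres (small compared with the radius).
#' @return sensitivity dVe/ds, V/m.
#' @export
displacement_sensitivity <- function(field, coupling,
                                     mode = c("normal", "tangential"),
                                     direction = NULL, step = 1e-4) {
  mode <- match.arg(mode)
  stopifnot(step > 0)
  ve0 <- electrode_potential(field, coupling)
  if (mode == "normal") {
    pert <- coupling
    pert$gap <- coupling$gap + step
    pert$Ce <- .EPS0 * coupling$electrode$eps_r / pert$gap
    ve1 <- electrode_potential(field, pert)
  } else {
    if (is.null(direction)) stop("tangential mode needs a direction")
    dirt <- direction - coupling$normal * sum(direction * coupling$normal)
    nd <- sqrt(sum(dirt^2))
    if (nd < 1e-12) stop("direction is normal to the surface")
    dirt <- dirt / nd
    el <- coupling$electrode
    el$center <- el$center + step * dirt
    pert <- electrode_coupling(coupling$mesh, el)
    ve1 <- electrode_potential(field, pert)
  }
  (ve1 - ve0) / step
}

#' Motion-artifact susceptibility score
#'
#' Magnitude of the coupling-weighted mean tangential electric field under
#' the electrode.  Electrodes sitting in regions of high tangential field
#' pick up large potential changes when they slide, so a low score marks a
#' placement that is robust to motion artifacts.
#'
#' @param field a `"surface_field_map"`.
#' @param coupling an `"electrode_coupling"`.
#' @return susceptibility score, V/m (non-negative).
#' @export
artifact_susceptibility <- function(field, coupling) {
  idx <- .field_at(field, coupling$vertex_ids)
  u <- if (diff(range(coupling$Ce)) == 0) coupling$weights
       else coupling$Ce * coupling$weights
  et <- colSums(field$tangential[idx, , drop = FALSE] * u) / sum(u)
  sqrt(sum(et^2))
}
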