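# Lead selection: among candidate electrode positions on the back, find the
# pair maximizing the R-instant lead voltage, optionally penalized by the
# motion-artifact susceptibility of the two sites.

#' Two-electrode lead configuration
#'
#' @param electrode_a,electrode_b `"capacitive_electrode"` objects; the lead
#'   voltage is Ve_A - Ve_B and the lead axis points from B to A.
#' @return an object of class `"lead_config"` with `axis` (unit vector) and
#'   `separation` (m).
#' @export
lead_configuration <- function(electrode_a, electrode_b) {
  d <- electrode_a$center - electrode_b$center
  sep <- sqrt(sum(d^2))
  if (sep < electrode_a$radius + electrode_b$radius)
    stop("electrodes overlap: centre separation below the sum of radii")
  structure(list(A = electrode_a, B = electrode_b, axis = d / sep,
                 separation = sep),
            class = "lead_config")
}

#' @export
print.lead_config <- function(x, ...) {
  cat(sprintf("Lead: A (%.3g, %.3g, %.3g) - B (%.3g, %.3g, %.3g), sep %.3g m\n",
              x$A$center[1], x$A$center[2], x$A$center[3],
              x$B$center[1], x$B$center[2], x$B$center[3], x$separation))
  invisible(x)
}

#' Signed lead voltage
#'
#' @param config a `"lead_config"`.
#' @param field a `"surface_field_map"`.
#' @return Ve_A - Ve_B, volts (gauge-independent).
#' @export
lead_voltage <- function(config, field) {
  ca <- electrode_coupling(field$mesh, config$A)
  cb <- electrode_coupling(field$mesh, config$B)
  electrode_potential(field, ca) - electrode_potential(field, cb)
}

#' Score a lead configuration
#'
#' Amplitude is the absolute lead voltage at the given (R-instant) field;
#' susceptibility is the sum of the two electrodes' motion-artifact scores;
#' the combined objective is `amplitude - lambda * separation *
#' susceptibility` (the separation supplies the length scale making the
#' penalty a voltage).
#'
#' @param config a `"lead_config"`.
#' @param field a `"surface_field_map"`.
#' @param lambda dimensionless penalty weight (>= 0; default 0, pure
#'   amplitude).
#' @return an object of class `"lead_score"` with `amplitude` (V),
#'   `susceptibility` (V/m) and `combined` (V).
#' @export
score_lead <- function(config, field, lambda = 0) {
  stopifnot(lambda >= 0)
  ca <- electrode_coupling(field$mesh, config$A)
  cb <- electrode_coupling(field$mesh, config$B)
  amp <- abs(electrode_potential(field, ca) - electrode_potential(field, cb))
  sus <- artifact_susceptibility(field, ca) + artifact_susceptibility(field, cb)
  structure(list(amplitude = amp, susceptibility = sus,
                 combined = amp - lambda * config$separation * sus,
                 lambda = lambda),
            class = "lead_score")
}

# Deterministic farthest-point subsampling of patch vertices at a target
# spacing; the first site is the lexicographically smallest vertex.
.candidate_sites <- function(coords, spacing) {
  n <- nrow(coords)
  start <- order(coords[, 1], coords[, 2], coords[, 3])[1L]
  chosen <- start
  dmin <- sqrt(rowSums(sweep(coords, 2, coords[start, ])^2))
  repeat {
    i <- which.max(dmin)
    if (dmin[i] < spacing) break
    chosen <- c(chosen, i)
    di <- sqrt(rowSums(sweep(coords, 2, coords[i, ])^2))
    dmin <- pmin(dmin, di)
  }
  chosen
}

#' Exhaustive electrode-pair search on a surface patch
#'
#' Candidate centres are drawn from the patch vertices with a deterministic
#' farthest-point rule at the requested spacing; every admissible
#' (non-overlapping) pair is evaluated at the R-instant field and ranked by
#' the combined score, with ties broken by lower susceptibility and then by
#' lexicographic position.
#'
#' @param field a `"surface_field_map"` (R-instant potential/field).
#' @param patch a `"surface_patch"` (e.g. [extract_back_patch()]) giving the
#'   admissible electrode region.
#' @param spacing candidate grid spacing, metres (default 0.02, the
#'   electrode diameter).
#' @param lambda susceptibility penalty weight (see [score_lead()]).
#' @param radius,gap,eps_r electrode parameters for every candidate.
#' @return an object of class `"lead_ranking"`: a ranked `table`
#'   (data.frame, one row per pair) and the top `"lead_config"` as `best`.
#' @export
optimize_lead <- function(field, patch, spacing = 0.02, lambda = 0,
                          radius = 0.01, gap = 1e-3, eps_r = 1) {
  coords <- patch$coords
  sites <- .candidate_sites(coords, spacing)
  if (length(sites) < 2L) stop("no admissible electrode pair on the patch")
  centers <- coords[sites, , drop = FALSE]
  ve <- numeric(length(sites)); sus <- numeric(length(sites))
  for (i in seq_along(sites)) {
    cp <- electrode_coupling(field$mesh,
                             capacitive_electrode(centers[i, ], radius = radius,
                                                  gap = gap, eps_r = eps_r))
    ve[i] <- electrode_potential(field, cp)
    sus[i] <- artifact_susceptibility(field, cp)
  }
  pairs <- utils::combn(length(sites), 2L)
  sep <- sqrt(rowSums((centers[pairs[1, ], , drop = FALSE] -
                       centers[pairs[2, ], , drop = FALSE])^2))
  ok <- sep >= 2 * radius
  if (!any(ok)) stop("no admissible electrode pair on the patch")
  pairs <- pairs[, ok, drop = FALSE]; sep <- sep[ok]
  dv <- ve[pairs[1, ]] - ve[pairs[2, ]]
  # orient each lead so A is the positive electrode
  swap <- dv < 0
  a <- ifelse(swap, pairs[2, ], pairs[1, ])
  b <- ifelse(swap, pairs[1, ], pairs[2, ])
  amp <- abs(dv)
  ss <- sus[a] + sus[b]
  comb <- amp - lambda * sep * ss
  tab <- data.frame(ax = centers[a, 1], ay = centers[a, 2], az = centers[a, 3],
                    bx = centers[b, 1], by = centers[b, 2], bz = centers[b, 3],
                    separation = sep, amplitude = amp, susceptibility = ss,
                    combined = comb)
  ord <- order(-tab$combined, tab$susceptibility, tab$ax, tab$ay, tab$az,
               tab$bx, tab$by, tab$bz)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  best <- lead_configuration(
    capacitive_electrode(as.numeric(tab[1, c("ax", "ay", "az")]),
                         radius = radius, gap = gap, eps_r = eps_r),
    capacitive_electrode(as.numeric(tab[1, c("bx", "by", "bz")]),
                         radius = radius, gap = gap, eps_r = eps_r))
  structure(list(table = tab, best = best, spacing = spacing,
                 lambda = lambda, n_sites = length(sites)),
            class = "lead_ranking")
}

#' @export
print.lead_ranking <- function(x, ...) {
  cat(sprintf("Lead search: %d candidate sites, %d pairs (spacing %.3g m, lambda %.3g)\n",
              x$n_sites, nrow(x$table), x$spacing, x$lambda))
  cat("Top pairs:\n")
  print(utils::head(cbind(round(x$table[, c("amplitude", "susceptibility",
                                            "combined")], 6),
                          round(x$table[, c("ax", "ay", "az", "bx", "by", "bz")], 3)),
                    5))
  invisible(x)
}

# Rotation of vector v about unit axis k by angle a (Rodrigues formula).
.rotate_about <- function(v, k, a) {
  v * cos(a) + c(k[2] * v[3] - k[3] * v[2],
                 k[3] * v[1] - k[1] * v[3],
                 k[1] * v[2] - k[2] * v[1]) * sin(a) +
    k * sum(k * v) * (1 - cos(a))
}

#' R-wave amplitude at angular deviations from a lead
#'
#' Rotates the lead axis about the surface normal through the lead midpoint
#' (separation fixed) and re-evaluates the lead amplitude, emulating leads
#' deliberately misaligned with the optimal one by e.g. 15 and 30 degrees.
#'
#' @param config the reference `"lead_config"`.
#' @param field a `"surface_field_map"`.
#' @param deviations rotation angles, radians (e.g. `c(0, pi/12, pi/6)`).
#' @param patch optional `"surface_patch"` restricting the electrodes: the
#'   rotated centres are snapped to the nearest patch vertex, and a
#'   rotation whose target leaves the patch by more than half the
#'   separation is an error (the lead would no longer lie on the back).
#' @return numeric vector of amplitudes (V), one per deviation.
#' @export
amplitude_vs_angle <- function(config, field,
                               deviations = c(0, pi / 12, pi / 6),
                               patch = NULL) {
  mid <- (config$A$center + config$B$center) / 2
  bd <- .boundary_vertex_data(field$mesh)
  bc <- field$mesh$vertices[bd$vertex_ids, , drop = FALSE]
  nearest <- which.min(rowSums(sweep(bc, 2, mid)^2))
  nrm <- bd$normal[nearest, ]
  half <- config$separation / 2
  place <- function(x) {
    if (is.null(patch)) return(x)
    d <- sqrt(rowSums(sweep(patch$coords, 2, x)^2))
    if (min(d) > half)
      stop("rotated lead leaves the surface patch")
    patch$coords[which.min(d), ]
  }
  vapply(deviations, function(a) {
    u <- .rotate_about(config$axis, nrm, a)
    ea <- config$A; eb <- config$B
    ea$center <- place(mid + half * u)
    eb$center <- place(mid - half * u)
    abs(lead_voltage(lead_configuration(ea, eb), field))
  }, 0)
}
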