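# Shared fixtures, built once per test session.  Meshes and forward solves
# are the expensive pieces; everything downstream derives from them.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, builder) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- builder()
  .fx_cache[[name]]
}

# Oracle sphere: R = 0.1 m, sigma = 0.2 S/m.
SPHERE_R <- 0.1
SPHERE_SIGMA <- 0.2
DIPOLE_P <- 2e-5

fx_sphere_coarse <- function() fx("sph_coarse", function()
  build_homogeneous_sphere(SPHERE_R, SPHERE_SIGMA, 0.0125))

fx_sphere_fine <- function() fx("sph_fine", function()
  build_homogeneous_sphere(SPHERE_R, SPHERE_SIGMA, 0.01))

fx_sphere_finer <- function() fx("sph_finer", function()
  build_homogeneous_sphere(SPHERE_R, SPHERE_SIGMA, 0.008))

# Electrode-scale sphere: fine enough that a 3 cm electrode patch is
# resolved by many triangles (no forward solve needed on it by default).
fx_sphere_electrode <- function() fx("sph_el", function()
  build_homogeneous_sphere(SPHERE_R, SPHERE_SIGMA, 0.005))

fx_zdipole <- function() dipole_source(position = c(0, 0, 0),
                                       moment = c(0, 0, DIPOLE_P))

# z-dipole field on the fine oracle sphere
fx_sphere_field <- function() fx("sph_field", function()
  surface_field_map(solve_forward(fx_sphere_fine(), fx_zdipole())))

fx_sphere_field_electrode <- function() fx("sph_field_el", function()
  surface_field_map(solve_forward(fx_sphere_electrode(), fx_zdipole())))

# Coarse thorax and its lead-field basis at the heart base.
fx_thorax <- function() fx("thorax", function()
  build_synthetic_thorax(resolution = 0.02))

fx_thorax_basis <- function() fx("thorax_basis", function()
  lead_field_basis(fx_thorax(), c(0.1, 0.03, 0)))

fx_thorax_field <- function() fx("thorax_field", function()
  surface_field_map(basis_solution(fx_thorax_basis(),
                                   angles_to_moment(DIPOLE_P, 5 * pi / 6,
                                                    3 * pi / 4))))

fx_thorax_lead <- function() fx("thorax_lead", function() {
  patch <- extract_back_patch(fx_thorax(), 0.4)
  optimize_lead(fx_thorax_field(), patch, spacing = 0.02)
})

# Closed-form surface potential of a central dipole p*z_hat in a
# homogeneous sphere with insulating boundary: phi = 3 p cos(theta) /
# (4 pi sigma R^2).
sphere_oracle_potential <- function(coords, p = DIPOLE_P,
                                    sigma = SPHERE_SIGMA, R = SPHERE_R) {
  3 * p * (coords[, 3] / R) / (4 * pi * sigma * R^2)
}

# Analytic tangential surface field magnitude: 3 p sin(theta)/(4 pi sigma R^3).
sphere_oracle_tangential <- function(theta, p = DIPOLE_P,
                                     sigma = SPHERE_SIGMA, R = SPHERE_R) {
  3 * p * sin(theta) / (4 * pi * sigma * R^3)
}

# Synthetic surface field map with prescribed potential (and optionally
# field) on a mesh boundary; used to probe the electrode model with known
# inputs.
make_synthetic_field <- function(mesh, vfun, efun = NULL) {
  bd <- cecglead:::.boundary_vertex_data(mesh)
  coords <- mesh$vertices[bd$vertex_ids, , drop = FALSE]
  E <- if (is.null(efun)) matrix(0, nrow(coords), 3) else efun(coords)
  en <- rowSums(E * bd$normal)
  structure(list(vertex_ids = bd$vertex_ids, coords = coords,
                 V = vfun(coords), E = E, normal = bd$normal,
                 tangential = E - bd$normal * en, weights = bd$weights,
                 mesh = mesh),
            class = "surface_field_map")
}

# Full-boundary surface patch (every boundary vertex admissible).
full_boundary_patch <- function(mesh) {
  bd <- cecglead:::.boundary_vertex_data(mesh)
  structure(list(mesh = mesh, vertex_ids = bd$vertex_ids,
                 tri_ids = seq_len(nrow(mesh$boundary$triangles)),
                 weights = bd$weights, normal = bd$normal,
                 coords = mesh$vertices[bd$vertex_ids, , drop = FALSE]),
            class = "surface_patch")
}
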