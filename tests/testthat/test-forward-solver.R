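test_that("heart-axis angles map to moment vectors as declared", {
  p <- 2e-5
  expect_equal(angles_to_moment(p, 0, pi / 2), c(p, 0, 0))
  expect_equal(angles_to_moment(0, 1.2, 2.3), c(0, 0, 0))
  m <- angles_to_moment(p, 5 * pi / 6, 3 * pi / 4)
  expect_equal(sqrt(sum(m^2)), p, tolerance = 1e-12)
  expect_lt(m[1], 0)
  # frozen trigonometric evaluation: p*(sin(el)cos(az), sin(el)sin(az), cos(el))
  expect_equal(m, c(-1.2247448714e-05, 7.0710678119e-06, -1.4142135624e-05),
               tolerance = 1e-9)
})

test_that("dipole load is balanced and linear in the moment", {
  m <- fx_sphere_coarse()
  s <- fx_zdipole()
  f <- dipole_load(m, s)
  I <- s$magnitude / 0.002
  expect_lt(abs(sum(f)), 1e-12 * I)
  s2 <- dipole_source(position = s$position, moment = -s$moment)
  expect_equal(dipole_load(m, s2), -f, tolerance = 1e-12)
  s3 <- dipole_source(position = s$position, moment = c(0, 0, 0))
  expect_equal(dipole_load(m, s3), numeric(nrow(m$vertices)))
  far <- dipole_source(position = c(1, 0, 0), moment = c(0, 0, 1e-5))
  expect_error(dipole_load(m, far), "outside the mesh")
})

test_that("FEM surface potential matches the dipole-in-sphere closed form", {
  fm <- fx_sphere_field()
  an <- sphere_oracle_potential(fm$coords)
  rel_l2 <- sqrt(sum(fm$weights * (fm$V - an)^2) /
                   sum(fm$weights * an^2))
  expect_lt(rel_l2, 0.05)
  pole <- which.max(fm$coords[, 3])
  expect_equal(fm$V[pole], 3 * DIPOLE_P / (4 * pi * SPHERE_SIGMA * SPHERE_R^2),
               tolerance = 0.05)
})

test_that("zero moment yields the zero (gauge) potential", {
  m <- fx_sphere_coarse()
  s <- dipole_source(position = c(0, 0, 0), moment = c(0, 0, 0))
  sol <- solve_forward(m, s)
  expect_equal(sol$phi, numeric(nrow(m$vertices)))
})

test_that("solutions superpose linearly and flip sign with the moment", {
  m <- fx_sphere_coarse()
  s1 <- dipole_source(position = c(0, 0, 0), moment = c(1e-5, 0, 0))
  s2 <- dipole_source(position = c(0, 0, 0), moment = c(0, 5e-6, 1e-5))
  s12 <- dipole_source(position = c(0, 0, 0),
                       moment = s1$moment + s2$moment)
  p1 <- solve_forward(m, s1)$phi
  p2 <- solve_forward(m, s2)$phi
  p12 <- solve_forward(m, s12)$phi
  expect_equal(p12, p1 + p2, tolerance = 1e-8)
  sneg <- dipole_source(position = c(0, 0, 0), moment = -s1$moment)
  expect_equal(solve_forward(m, sneg)$phi, -p1, tolerance = 1e-10)
})

test_that("the default gauge zeroes the boundary mean", {
  sol <- solve_forward(fx_sphere_coarse(), fx_zdipole())
  bids <- sort(unique(as.vector(sol$mesh$boundary$triangles)))
  expect_lt(abs(mean(sol$phi[bids])), 1e-12 * max(abs(sol$phi)))
})

test_that("the assembled operator is symmetric", {
  K <- cecglead:::.stiffness(fx_sphere_coarse())
  asym <- max(abs(K - Matrix::t(K)))
  expect_lt(asym, 1e-12 * max(abs(K)))
})

test_that("halving the monopole separation barely changes far potentials", {
  m <- fx_sphere_coarse()
  s <- fx_zdipole()
  bids <- sort(unique(as.vector(m$boundary$triangles)))
  p1 <- solve_forward(m, s, delta = 0.002)$phi[bids]
  p2 <- solve_forward(m, s, delta = 0.001)$phi[bids]
  # boundary vertices are > 5*delta from the central source
  expect_lt(max(abs(p1 - p2)) / max(abs(p2)), 0.01)
})

test_that("surface field map vanishes for a uniform potential", {
  m <- fx_sphere_coarse()
  sol <- structure(list(phi = rep(3.2, nrow(m$vertices)), mesh = m,
                        source = NULL, gauge = "none", residual = 0),
                   class = "potential_solution")
  fm <- surface_field_map(sol)
  # zero up to cancellation roundoff in the element gradients
  expect_lt(max(abs(fm$E)), 1e-9)
  expect_lt(max(abs(fm$tangential)), 1e-9)
})

test_that("tangential surface field matches the oracle at the equator", {
  fm <- fx_sphere_field()
  eq <- which(abs(fm$coords[, 3]) < 1e-9)
  expect_gt(length(eq), 10)
  et <- sqrt(rowSums(fm$tangential[eq, ]^2))
  expect_equal(mean(et), sphere_oracle_tangential(pi / 2), tolerance = 0.10)
})

test_that("tangential vectors are orthogonal to vertex normals", {
  fm <- fx_sphere_field()
  dots <- abs(rowSums(fm$tangential * fm$normal))
  expect_lt(max(dots) / max(sqrt(rowSums(fm$tangential^2))), 1e-6)
})

test_that("negating the moment negates the surface potential map", {
  m <- fx_sphere_coarse()
  s <- fx_zdipole()
  sneg <- dipole_source(position = s$position, moment = -s$moment)
  f1 <- surface_field_map(solve_forward(m, s))
  f2 <- surface_field_map(solve_forward(m, sneg))
  expect_equal(f2$V, -f1$V, tolerance = 1e-10)
})

test_that("lead-field basis reproduces direct solves by superposition", {
  basis <- fx_thorax_basis()
  mom <- angles_to_moment(2e-5, 5 * pi / 6, 3 * pi / 4)
  rec <- basis_solution(basis, mom)$phi
  dir <- solve_forward(fx_thorax(),
                       dipole_source(position = basis$position,
                                     moment = mom))$phi
  expect_lt(max(abs(rec - dir)) / max(abs(dir)), 1e-6)
  expect_equal(basis_solution(basis, c(0, 0, 0))$phi, rep(0, length(rec)))
  expect_identical(basis_solution(basis, c(1, 0, 0))$phi, basis$phi[, 1])
})

test_that("potential differences are gauge independent", {
  # shifting the potential by any constant leaves lead voltages unchanged
  fm <- fx_sphere_field()
  shifted <- fm
  shifted$V <- fm$V + 0.123
  a <- capacitive_electrode(c(0, 0, SPHERE_R), radius = 0.02)
  b <- capacitive_electrode(c(0, 0, -SPHERE_R), radius = 0.02)
  cfg <- lead_configuration(a, b)
  expect_equal(lead_voltage(cfg, fm), lead_voltage(cfg, shifted),
               tolerance = 1e-10)
})
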