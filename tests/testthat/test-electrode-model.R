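test_that("plate capacitance follows the parallel-plate law", {
  expect_equal(plate_capacitance(pi * 0.01^2, 1e-3, 1), 2.7816e-12,
               tolerance = 1e-4)
  c0 <- plate_capacitance(1e-4, 1e-3)
  expect_equal(plate_capacitance(1e-4, 2e-3), c0 / 2)
  expect_equal(plate_capacitance(1e-4, 1e-3, eps_r = 2), 2 * c0)
  expect_error(plate_capacitance(1e-4, 0), "positive")
  expect_error(plate_capacitance(1e-4, -1e-3), "positive")
})

test_that("uniform gap gives uniform specific capacitance and the plate C", {
  m <- fx_sphere_electrode()
  el <- capacitive_electrode(c(0, -SPHERE_R, 0), radius = 0.03, gap = 1e-3)
  cp <- electrode_coupling(m, el)
  expect_equal(length(unique(cp$Ce)), 1L)
  expect_equal(unique(cp$Ce), 8.8541878128e-12 / 1e-3)
  # discrete sum vs closed form over the nominal disk area
  expect_equal(cp$total_capacitance,
               plate_capacitance(pi * 0.03^2, 1e-3), tolerance = 0.05)
})

test_that("total capacitance shrinks monotonically with the radius", {
  m <- fx_sphere_electrode()
  caps <- vapply(c(0.04, 0.03, 0.02, 0.01), function(r)
    electrode_coupling(m, capacitive_electrode(c(0, -SPHERE_R, 0),
                                               radius = r))$total_capacitance,
    0)
  expect_true(all(diff(caps) < 0))
})

test_that("an electrode far from the surface is rejected", {
  m <- fx_sphere_coarse()
  expect_error(electrode_coupling(m, capacitive_electrode(c(0, -0.3, 0))),
               "too far")
})

test_that("a wide gap outside the plate regime is flagged", {
  m <- fx_sphere_electrode()
  cp <- electrode_coupling(m, capacitive_electrode(c(0, -SPHERE_R, 0),
                                                   radius = 0.01, gap = 0.05))
  expect_match(cp$warning, "plate-coupling")
})

test_that("an equipotential body fixes the electrode potential", {
  m <- fx_sphere_coarse()
  fm <- make_synthetic_field(m, function(x) rep(5, nrow(x)))
  for (gp in c("uniform", "plate")) {
    cp <- electrode_coupling(m, capacitive_electrode(c(0, -SPHERE_R, 0),
                                                     radius = 0.03,
                                                     gap_profile = gp))
    expect_equal(electrode_potential(fm, cp), 5, tolerance = 1e-12)
  }
})

test_that("uniform coupling averages the potential with area weights", {
  m <- fx_sphere_electrode()
  fm <- make_synthetic_field(m, function(x) 1 + 40 * x[, 3])
  cp <- electrode_coupling(m, capacitive_electrode(c(0, -SPHERE_R, 0),
                                                   radius = 0.03))
  idx <- match(cp$vertex_ids, fm$vertex_ids)
  expect_equal(electrode_potential(fm, cp),
               sum(fm$V[idx] * cp$weights) / sum(cp$weights),
               tolerance = 1e-12)
  # linear potential over a (nearly) symmetric patch: Ve ~ value at centre
  expect_equal(electrode_potential(fm, cp), 1 + 40 * 0, tolerance = 0.01)
})

test_that("the electrode potential is bounded by the patch potentials", {
  fm <- fx_sphere_field_electrode()
  cp <- electrode_coupling(fm$mesh,
                           capacitive_electrode(c(0, -0.07, 0.07),
                                                radius = 0.02,
                                                gap_profile = "plate"))
  idx <- match(cp$vertex_ids, fm$vertex_ids)
  ve <- electrode_potential(fm, cp)
  expect_gte(ve, min(fm$V[idx]))
  expect_lte(ve, max(fm$V[idx]))
})

test_that("the electrode potential does not depend on frequency", {
  fm <- fx_sphere_field_electrode()
  ve <- vapply(c(1, 2 * pi * 10, 1e4), function(w)
    electrode_potential(fm, electrode_coupling(fm$mesh,
      capacitive_electrode(c(0, -SPHERE_R, 0), radius = 0.03, omega = w))),
    0)
  expect_equal(ve[2], ve[1])
  expect_equal(ve[3], ve[1])
})

test_that("sensitivities vanish on an equipotential surface", {
  m <- fx_sphere_coarse()
  fm <- make_synthetic_field(m, function(x) rep(2, nrow(x)))
  cp <- electrode_coupling(m, capacitive_electrode(c(0, -SPHERE_R, 0),
                                                   radius = 0.03,
                                                   gap_profile = "plate"))
  expect_equal(displacement_sensitivity(fm, cp, "normal"), 0,
               tolerance = 1e-12)
  expect_equal(displacement_sensitivity(fm, cp, "tangential",
                                        direction = c(0, 0, 1),
                                        step = 5e-3), 0, tolerance = 1e-12)
})

test_that("uniform gap makes the normal sensitivity exactly zero", {
  # with uniform Ce the gap perturbation rescales all weights equally and
  # cancels in the potential ratio, for any potential distribution
  fm <- fx_sphere_field_electrode()
  cp <- electrode_coupling(fm$mesh,
                           capacitive_electrode(c(0, -SPHERE_R, 0),
                                                radius = 0.03))
  expect_identical(displacement_sensitivity(fm, cp, "normal"), 0)
})

test_that("a curved (plate-gap) coupling has nonzero normal sensitivity", {
  fm <- fx_sphere_field_electrode()
  cp <- electrode_coupling(fm$mesh,
                           capacitive_electrode(c(0, -0.07, 0.07),
                                                radius = 0.03,
                                                gap_profile = "plate"))
  expect_gt(abs(displacement_sensitivity(fm, cp, "normal")), 0)
})

test_that("tangential sensitivity tracks the mean tangential field", {
  fm <- fx_sphere_field_electrode()
  cp <- electrode_coupling(fm$mesh,
                           capacitive_electrode(c(0, -SPHERE_R, 0),
                                                radius = 0.03))
  sen <- displacement_sensitivity(fm, cp, "tangential",
                                  direction = c(0, 0, 1), step = 4e-3)
  idx <- match(cp$vertex_ids, fm$vertex_ids)
  u <- cp$Ce * cp$weights
  et_z <- sum(fm$tangential[idx, 3] * u) / sum(u)
  # E = -grad V: sliding up the gradient changes Ve at minus the field
  expect_equal(abs(sen), abs(et_z), tolerance = 0.10)
})

test_that("artifact susceptibility is zero on uniform potential and scales out Ce", {
  m <- fx_sphere_coarse()
  flat <- make_synthetic_field(m, function(x) rep(1, nrow(x)))
  cp <- electrode_coupling(m, capacitive_electrode(c(0, -SPHERE_R, 0),
                                                   radius = 0.03))
  expect_equal(artifact_susceptibility(flat, cp), 0)
  fm <- fx_sphere_field_electrode()
  cpe <- electrode_coupling(fm$mesh,
                            capacitive_electrode(c(0, -SPHERE_R, 0),
                                                 radius = 0.02))
  s1 <- artifact_susceptibility(fm, cpe)
  cps <- cpe; cps$Ce <- 3 * cpe$Ce
  expect_equal(artifact_susceptibility(fm, cps), s1, tolerance = 1e-12)
  expect_gte(s1, 0)
})

test_that("equatorial electrodes are more artifact-prone than polar ones", {
  fm <- fx_sphere_field_electrode()
  eq <- electrode_coupling(fm$mesh, capacitive_electrode(c(0, -SPHERE_R, 0),
                                                         radius = 0.02))
  po <- electrode_coupling(fm$mesh, capacitive_electrode(c(0, 0, SPHERE_R),
                                                         radius = 0.02))
  expect_gt(artifact_susceptibility(fm, eq),
            artifact_susceptibility(fm, po))
})

test_that("Ve bias at the centre value grows with radius on a curved field", {
  m <- fx_sphere_electrode()
  # quadratic potential: the patch average drifts from the centre value as
  # the electrode grows
  fm <- make_synthetic_field(m, function(x) 1e3 * x[, 3]^2)
  center <- c(0, -SPHERE_R, 0)
  dev <- vapply(c(0.01, 0.02, 0.03, 0.04), function(r) {
    cp <- electrode_coupling(m, capacitive_electrode(center, radius = r))
    abs(electrode_potential(fm, cp) - 0)
  }, 0)
  expect_true(all(diff(dev) > 0))
})
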