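test_that("dipole trajectory peaks at the R magnitude and is periodic", {
  mdl <- cardiac_cycle_model(60)
  r_center <- mdl$components$center[mdl$components$name == "R"] * mdl$cycle
  m_r <- dipole_trajectory(mdl, r_center)
  expect_equal(sqrt(sum(m_r^2)), 2e-5, tolerance = 0.01)
  t <- c(0.25, 0.375, 0.8125)   # binary fractions: t + cycle is exact
  expect_identical(dipole_trajectory(mdl, t),
                   dipole_trajectory(mdl, t + mdl$cycle))
  zero <- cardiac_cycle_model(60, r_magnitude = 0)
  expect_equal(dipole_trajectory(zero, seq(0, 2, 0.1)),
               matrix(0, 21, 3))
})

test_that("cycle model validates ordering and dominance of waves", {
  bad <- cardiac_cycle_model(60)$components
  bad$center <- rev(bad$center)
  expect_error(cardiac_cycle_model(60, components = bad), "ordered")
  qdom <- cardiac_cycle_model(60)$components
  qdom$amplitude[qdom$name == "Q"] <- 1
  expect_error(cardiac_cycle_model(60, components = qdom), "dominate")
})

test_that("simulated lead signal agrees with the static R-instant voltage", {
  basis <- fx_thorax_basis()
  lead <- fx_thorax_lead()$best
  mdl <- cardiac_cycle_model(60)
  tr <- simulate_lead_signal(basis, lead, mdl, duration = 10)
  static <- abs(lead_voltage(lead, fx_thorax_field()))
  expect_equal(max(abs(tr$samples)), static, tolerance = 0.02)
})

test_that("the simulator is linear in the moment amplitudes", {
  basis <- fx_thorax_basis()
  lead <- fx_thorax_lead()$best
  t1 <- simulate_lead_signal(basis, lead, cardiac_cycle_model(60), 5)
  t2 <- simulate_lead_signal(basis, lead,
                             cardiac_cycle_model(60, r_magnitude = 4e-5), 5)
  expect_equal(t2$samples, 2 * t1$samples, tolerance = 1e-12)
})

test_that("annotations count beats (one per cycle)", {
  basis <- fx_thorax_basis()
  lead <- fx_thorax_lead()$best
  tr <- simulate_lead_signal(basis, lead, cardiac_cycle_model(60), 60)
  expect_length(tr$annotations, 60)
  expect_true(!is.unsorted(tr$annotations, strictly = TRUE))
  expect_error(simulate_lead_signal(basis, lead, cardiac_cycle_model(60), 0),
               "duration")
})

test_that("motion artifacts are confined to their event windows", {
  basis <- fx_thorax_basis()
  lead <- fx_thorax_lead()$best
  tr <- simulate_lead_signal(basis, lead, cardiac_cycle_model(60), 60)
  ev <- motion_event_model(rate = 2, excursion = 3e-3, duration = 1,
                           seed = 11)
  tr2 <- add_motion_artifact(tr, ev)
  d <- abs(tr2$samples - tr$samples)
  expect_gt(max(d), 0)
  t <- (seq_along(d) - 1) / tr$rate
  inside <- rep(FALSE, length(d))
  for (k in seq_len(nrow(tr2$motion_events)))
    inside <- inside | (t >= tr2$motion_events$start[k] - 1e-9 &
                          t <= tr2$motion_events$end[k] + 1e-9)
  expect_lt(max(d[!inside]), 1e-12)
})

test_that("motion artifacts are reproducible and vanish at zero excursion", {
  basis <- fx_thorax_basis()
  lead <- fx_thorax_lead()$best
  tr <- simulate_lead_signal(basis, lead, cardiac_cycle_model(60), 30)
  z <- add_motion_artifact(tr, motion_event_model(excursion = 0, seed = 3))
  expect_identical(z$samples, tr$samples)
  a <- add_motion_artifact(tr, motion_event_model(excursion = 2e-3, seed = 5))
  b <- add_motion_artifact(tr, motion_event_model(excursion = 2e-3, seed = 5))
  expect_identical(a$samples, b$samples)
  expect_error(add_motion_artifact(tr, motion_event_model(excursion = -2e-3,
                                                          seed = 5)),
               "contact")
})

test_that("motion artifacts vanish on an equipotential surface", {
  basis <- fx_thorax_basis()
  lead <- fx_thorax_lead()$best
  tr <- simulate_lead_signal(basis, lead, cardiac_cycle_model(60), 30)
  # equipotential body: every patch vertex sees the same lead-field row
  st <- tr$lead_state
  row <- st$A$basis$phi[1, , drop = FALSE]
  st$A$basis$phi <- row[rep(1, nrow(st$A$basis$phi)), , drop = FALSE]
  st$A$basis$vec <- as.numeric(row)
  st$B$basis$vec <- c(0, 0, 0)
  tr$lead_state <- st
  tr$samples <- as.numeric(dipole_trajectory(st$model,
                                             (seq_along(tr$samples) - 1) /
                                               tr$rate) %*% as.numeric(row))
  out <- add_motion_artifact(tr, motion_event_model(excursion = 5e-3,
                                                    seed = 2))
  expect_equal(out$samples, tr$samples, tolerance = 1e-14)
})

test_that("additive noise has the requested level and seed determinism", {
  tr <- signal_trace(numeric(2e5), rate = 1000)
  n1 <- add_noise(tr, 0.5, seed = 4)
  n2 <- add_noise(tr, 0.5, seed = 4)
  expect_identical(n1$samples, n2$samples)
  expect_equal(stats::sd(n1$samples - tr$samples), 0.5, tolerance = 0.05)
  expect_identical(add_noise(tr, 0, seed = 4)$samples, tr$samples)
})

test_that("bin-averaging downsampler has the right length and means", {
  tr <- signal_trace(rep(3.5, 2300), rate = 2300)
  d <- downsample_averaging(tr, 72)
  expect_length(d$samples, 72)
  expect_true(all(d$samples == 3.5))
  # integer-ratio case preserves the overall mean exactly
  set.seed(1)
  x <- stats::rnorm(1000)
  tri <- signal_trace(x, rate = 1000)
  di <- downsample_averaging(tri, 100)
  expect_equal(mean(di$samples), mean(x), tolerance = 1e-12)
  expect_error(downsample_averaging(tr, 5000), "below")
})

test_that("downsampling preserves annotations and rate bookkeeping", {
  basis <- fx_thorax_basis()
  lead <- fx_thorax_lead()$best
  tr <- simulate_lead_signal(basis, lead, cardiac_cycle_model(60), 10)
  d <- downsample_averaging(tr, 72)
  expect_identical(d$annotations, tr$annotations)
  expect_equal(d$rate, 72)
  expect_length(d$samples, 720)
})

test_that("noise calibrated from the R amplitude hits the target SNR", {
  basis <- fx_thorax_basis()
  lead <- fx_thorax_lead()$best
  clean <- downsample_averaging(
    simulate_lead_signal(basis, lead, cardiac_cycle_model(60), 120), 72)
  sigma <- noise_sigma_for_snr(clean, 20)
  noisy <- add_noise(clean, sigma, seed = 9)
  est <- estimate_snr(noisy)
  expect_equal(est$snr_db, 20, tolerance = 1)
})
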