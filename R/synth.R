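# Synthetic cECG generation: a time-varying cardiac dipole (sum of Gaussian
# wave components: P, Q, R, S, T) drives the precomputed lead-field basis;
# the acquisition chain adds electrode-gap motion artifacts and Gaussian
# noise, then downsamples by bin averaging (2.3 kHz -> 72 Hz by default).

#' Gaussian-component cardiac cycle model
#'
#' The dipole moment is a sum of Gaussian bumps in cycle phase, one per ECG
#' wave.  The R component has the reference magnitude 2e-5 A*m along the
#' default heart axis (azimuth 5*pi/6, elevation 3*pi/4); P/Q/S/T amplitudes
#' are physiological fractions of it, with Q and S pointing opposite to R.
#' Component centres/widths are fractions of the cycle so the trace scales
#' with heart rate.
#'
#' @param heart_rate beats per minute.
#' @param r_magnitude R-instant dipole magnitude, A*m.
#' @param axis unit 3-vector of the electrical heart axis (default from the
#'   reference azimuth/elevation).
#' @param components optional data.frame overriding the wave set, with
#'   columns `name`, `center` and `width` (fractions of the cycle),
#'   `amplitude` (A*m), and `dx`, `dy`, `dz` (unit direction).
#' @return an object of class `"cardiac_cycle_model"`.
#' @export
cardiac_cycle_model <- function(heart_rate = 60, r_magnitude = 2e-5,
                                axis = NULL, components = NULL) {
  stopifnot(heart_rate > 0, r_magnitude >= 0)
  if (is.null(axis)) axis <- angles_to_moment(1, 5 * pi / 6, 3 * pi / 4)
  axis <- axis / sqrt(sum(axis^2))
  if (is.null(components)) {
    components <- data.frame(
      name = c("P", "Q", "R", "S", "T"),
      center = c(0.15, 0.27, 0.30, 0.33, 0.55),
      width = c(0.025, 0.008, 0.011, 0.008, 0.040),
      amplitude = r_magnitude * c(0.15, 0.10, 1.00, 0.25, 0.30),
      stringsAsFactors = FALSE)
    dirs <- rbind(axis, -axis, axis, -axis, axis)
    components$dx <- dirs[, 1]; components$dy <- dirs[, 2]
    components$dz <- dirs[, 3]
  }
  stopifnot(all(components$width > 0))
  if (!all(diff(components$center) > 0))
    stop("wave component phases must be strictly ordered within the cycle")
  r_amp <- components$amplitude[components$name == "R"]
  if (length(r_amp) == 1L && any(components$amplitude[components$name %in%
                                                      c("Q", "S")] > r_amp))
    stop("the R component must dominate the QRS amplitudes")
  structure(list(heart_rate = heart_rate, cycle = 60 / heart_rate,
                 components = components, axis = axis,
                 r_magnitude = r_magnitude),
            class = "cardiac_cycle_model")
}

#' Dipole moment trajectory
#'
#' @param model a `"cardiac_cycle_model"`.
#' @param t times, seconds (vectorized).
#' @return matrix `length(t)` x 3 of moment vectors (A*m); periodic in the
#'   cycle length.
#' @export
dipole_trajectory <- function(model, t) {
  stopifnot(all(t >= 0))
  phase <- (t %% model$cycle) / model$cycle
  M <- matrix(0, length(t), 3L)
  cmp <- model$components
  for (i in seq_len(nrow(cmp))) {
    g <- cmp$amplitude[i] *
      exp(-(phase - cmp$center[i])^2 / (2 * cmp$width[i]^2))
    M <- M + outer(g, c(cmp$dx[i], cmp$dy[i], cmp$dz[i]))
  }
  M
}

#' True R-instant times of a cycle model
#'
#' @param model a `"cardiac_cycle_model"`.
#' @param duration trace duration, seconds.
#' @return strictly increasing times (s) of the R component centre.
#' @export
r_instants <- function(model, duration) {
  rc <- model$components$center[model$components$name == "R"] * model$cycle
  n <- floor((duration - rc) / model$cycle)
  rc + model$cycle * (0:max(0, n))
}

#' Sampled lead-voltage trace
#'
#' @param samples numeric vector of lead voltages, V.
#' @param rate sampling rate, Hz.
#' @param annotations ground-truth R times, seconds (strictly increasing).
#' @param start start time, seconds.
#' @param provenance list of generator parameters (free-form).
#' @return an object of class `"signal_trace"`.
#' @export
signal_trace <- function(samples, rate, annotations = numeric(),
                         start = 0, provenance = list()) {
  stopifnot(rate > 0, !is.unsorted(annotations, strictly = TRUE))
  structure(list(samples = as.numeric(samples), rate = rate, start = start,
                 annotations = as.numeric(annotations),
                 provenance = provenance),
            class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("Signal trace: %d samples at %g Hz (%.1f s), %d annotated beats\n",
              length(x$samples), x$rate, length(x$samples) / x$rate,
              length(x$annotations)))
  invisible(x)
}

#' @export
plot.signal_trace <- function(x, xlim = NULL, ...) {
  t <- x$start + seq_along(x$samples) / x$rate
  graphics::plot(t, x$samples, type = "l", xlab = "time (s)",
                 ylab = "lead voltage (V)", xlim = xlim, ...)
  ann <- x$annotations
  if (!is.null(xlim)) ann <- ann[ann >= xlim[1] & ann <= xlim[2]]
  graphics::abline(v = ann, col = "red", lty = 3)
  invisible(x)
}

# Per-electrode lead-field weights at the coupling patch.
.electrode_basis <- function(basis, coupling) {
  phi <- basis$phi[coupling$vertex_ids, , drop = FALSE]
  u <- coupling$Ce * coupling$weights
  list(phi = phi, u = u, vec = as.numeric(crossprod(phi, u)) / sum(u))
}

#' Simulate a cECG lead signal
#'
#' Drives a lead (two capacitive electrodes) with the dipole trajectory via
#' the lead-field basis: sample k at t = k/rate has value Ve_A - Ve_B for
#' the instantaneous moment.  Ground-truth annotations are the R-component
#' centre times.  Deterministic.
#'
#' @param basis a `"lead_field_basis"` at the model's dipole position.
#' @param config a `"lead_config"`.
#' @param model a `"cardiac_cycle_model"`.
#' @param duration trace length, seconds.
#' @param rate sampling rate, Hz (default 2300, the acquisition rate before
#'   averaging down to 72 Hz).
#' @return a `"signal_trace"`; it carries the electrode coupling state
#'   needed by [add_motion_artifact()].
#' @export
simulate_lead_signal <- function(basis, config, model, duration,
                                 rate = 2300) {
  if (duration <= 0) stop("duration must be positive")
  ca <- electrode_coupling(basis$mesh, config$A)
  cb <- electrode_coupling(basis$mesh, config$B)
  ea <- .electrode_basis(basis, ca)
  eb <- .electrode_basis(basis, cb)
  lvec <- ea$vec - eb$vec
  t <- (seq_len(round(duration * rate)) - 1L) / rate
  M <- dipole_trajectory(model, t)
  x <- as.numeric(M %*% lvec)
  tr <- signal_trace(x, rate, annotations = r_instants(model, duration),
                     provenance = list(kind = "cecg-forward-model",
                                       heart_rate = model$heart_rate,
                                       duration = duration, rate = rate))
  tr$lead_state <- list(model = model, config = config,
                        A = list(coupling = ca, basis = ea),
                        B = list(coupling = cb, basis = eb))
  tr
}

#' Electrode motion-event model
#'
#' Moderate body movements are modelled as smooth (raised-cosine) excursions
#' of the gap of one electrode away from the body, contact never being lost.
#'
#' @param rate events per minute.
#' @param excursion peak gap excursion, metres (must keep the gap positive).
#' @param duration event duration, seconds.
#' @param seed integer seed controlling event placement.
#' @return an object of class `"motion_event_model"`.
#' @export
motion_event_model <- function(rate = 2, excursion = 2e-3, duration = 1,
                               seed = 1) {
  stopifnot(rate >= 0, duration > 0)
  structure(list(rate = rate, excursion = excursion, duration = duration,
                 seed = as.integer(seed)),
            class = "motion_event_model")
}

# Run fn with a private RNG stream; global .Random.seed is untouched.
.with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

# Event start times: jittered regular grid, deterministic given the seed,
# guaranteed non-overlapping for duration < half the event period.
.motion_event_starts <- function(events, total) {
  n <- floor(events$rate * total / 60)
  if (n < 1L) return(numeric())
  period <- total / n
  .with_seed(events$seed, function() {
    (seq_len(n) - 0.5) * period +
      stats::runif(n, -0.2, 0.2) * pmax(period - events$duration, 0)
  })
}

#' Inject gap-motion artifacts
#'
#' During each motion event the gap of electrode A follows a raised-cosine
#' excursion; the electrode potential is recomputed sample by sample from
#' the perturbed specific capacitance while the body-surface potential
#' distribution stays fixed.  Samples outside events are unchanged.  On an
#' equipotential surface the injected artifact is exactly zero (the
#' capacitance weighting cancels in the potential ratio).
#'
#' @param trace a `"signal_trace"` from [simulate_lead_signal()].
#' @param events a `"motion_event_model"`.
#' @return the trace with perturbed samples; event windows are recorded in
#'   `trace$motion_events`.
#' @export
add_motion_artifact <- function(trace, events) {
  st <- trace$lead_state
  if (is.null(st))
    stop("trace lacks electrode coupling state (not from simulate_lead_signal)")
  gap <- st$A$coupling$gap
  if (any(gap + min(0, events$excursion) <= 0))
    stop("gap excursion would reverse electrode-body contact")
  total <- length(trace$samples) / trace$rate
  starts <- .motion_event_starts(events, total)
  if (!length(starts)) return(trace)
  if (events$excursion == 0) {
    trace$motion_events <- data.frame(start = starts,
                                      end = starts + events$duration)
    return(trace)
  }
  x <- trace$samples
  w <- st$A$coupling$weights
  phiA <- st$A$basis$phi
  vB <- st$B$basis$vec
  for (t0 in starts) {
    i0 <- max(1L, floor(t0 * trace$rate) + 1L)
    i1 <- min(length(x), ceiling((t0 + events$duration) * trace$rate))
    if (i1 < i0) next
    tt <- (i0:i1 - 1L) / trace$rate
    e <- events$excursion * (1 - cos(2 * pi * (tt - t0) / events$duration)) / 2
    M <- dipole_trajectory(st$model, tt)
    P <- phiA %*% t(M)                       # vertex potentials x samples
    U <- w / outer(gap, e, "+")              # Ce*area weights (eps0*epsr cancels)
    veA <- colSums(P * U) / colSums(U)
    x[i0:i1] <- veA - as.numeric(M %*% vB)
  }
  trace$samples <- x
  trace$motion_events <- data.frame(start = starts,
                                    end = starts + events$duration)
  trace
}

#' Additive Gaussian measurement noise
#'
#' @param trace a `"signal_trace"`.
#' @param sigma noise standard deviation, volts.
#' @param seed integer seed (reproducible).
#' @return the trace with zero-mean Gaussian noise added.
#' @export
add_noise <- function(trace, sigma, seed = 1) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(trace)
  n <- length(trace$samples)
  trace$samples <- trace$samples +
    .with_seed(seed, function() stats::rnorm(n, 0, sigma))
  trace
}

#' Noise level for a target signal-to-noise ratio
#'
#' Computes the R amplitude of a (noise-free) trace as the mean peak
#' absolute value within +/-80 ms of each annotated beat and returns
#' `sigma = VR * 10^(-snr_db/20)`, so that adding this noise realizes the
#' requested SNR under the T-to-P-window definition.
#'
#' @param trace a `"signal_trace"` with annotations.
#' @param snr_db target SNR, dB.
#' @return noise standard deviation, volts.
#' @export
noise_sigma_for_snr <- function(trace, snr_db) {
  vr <- mean(.beat_peaks(trace)$peak)
  vr * 10^(-snr_db / 20)
}

# Peak |value| within +/-80 ms of each annotated/detected R time.
.beat_peaks <- function(trace, times = trace$annotations, window = 0.08) {
  if (length(times) < 1L) stop("no beat times available")
  n <- length(trace$samples)
  peak <- vapply(times, function(r) {
    i0 <- max(1L, floor((r - window - trace$start) * trace$rate) + 1L)
    i1 <- min(n, ceiling((r + window - trace$start) * trace$rate) + 1L)
    max(abs(trace$samples[i0:i1]))
  }, 0)
  list(times = times, peak = peak)
}

#' Averaging (bin-mean) downsampler
#'
#' Each output sample is the arithmetic mean of the input samples whose
#' times fall in the half-open interval `[k/target, (k+1)/target)`; this is
#' exact for non-integer rate ratios such as 2300 Hz -> 72 Hz.  Annotations
#' are carried over unchanged.
#'
#' @param trace a `"signal_trace"`.
#' @param target output rate, Hz (below the input rate).
#' @return a `"signal_trace"` at the target rate.
#' @export
downsample_averaging <- function(trace, target) {
  if (target >= trace$rate) stop("target rate must be below the input rate")
  n <- length(trace$samples)
  # guard against 0.999999... products for integer rate ratios
  bin <- floor((seq_len(n) - 1L) * (target / trace$rate) + 1e-9) + 1L
  y <- as.numeric(rowsum(trace$samples, bin, reorder = TRUE) /
                    tabulate(bin))
  out <- signal_trace(y, target, annotations = trace$annotations,
                      start = trace$start,
                      provenance = c(trace$provenance,
                                     list(downsampled_from = trace$rate)))
  out$motion_events <- trace$motion_events
  out
}
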