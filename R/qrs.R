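# QRS detection (Pan-Tompkins), SNR estimation with T-to-P noise windows,
# and beat-detection scoring (TP/FN/FP/TE/SE/PPV).

#' Pan-Tompkins QRS detector
#'
#' Classic stage chain: 5-15 Hz band-pass (zero-phase Butterworth), 5-point
#' derivative, squaring, 150 ms moving-window integration, then dual
#' adaptive thresholds on integration peaks with a 200 ms refractory
#' period, a 360 ms T-wave slope test, and search-back at 1.66x the running
#' average RR interval.  Window lengths are specified in seconds and
#' rounded to the trace rate.
#'
#' @param trace a `"signal_trace"` (rate >= 50 Hz, duration >= 5 s).
#' @return an object of class `"qrs_detection"`: detected R `times` (s),
#'   intermediate traces (`filtered`, `derivative`, `squared`,
#'   `integrated`) and the threshold trajectory.
#' @export
pan_tompkins_detect <- function(trace) {
  fs <- trace$rate
  x <- trace$samples
  n <- length(x)
  if (fs < 50) stop("sampling rate too low for the 5-15 Hz band-pass")
  if (n / fs < 5) stop("trace shorter than 5 s")

  bp <- signal::filtfilt(signal::butter(2, c(5, 15) / (fs / 2), type = "pass"),
                         x)
  # centred 5-point derivative
  d <- c(0, 0, (2 * bp[5:n] + bp[4:(n - 1)] - bp[2:(n - 3)] -
                  2 * bp[1:(n - 4)]) / 8, 0, 0)
  sq <- d^2
  N <- max(1L, round(0.15 * fs))
  mwi <- as.numeric(stats::filter(sq, rep(1 / N, N), sides = 2))
  mwi[is.na(mwi)] <- 0

  # candidate peaks: local maxima of the integrated signal
  pk <- which(diff(sign(diff(mwi))) < 0) + 1L
  if (!length(pk))
    return(structure(list(times = numeric(), filtered = bp, derivative = d,
                          squared = sq, integrated = mwi,
                          thresholds = numeric()),
                     class = "qrs_detection"))
  refr <- round(0.20 * fs)
  twin <- round(0.36 * fs)

  init <- mwi[seq_len(min(n, round(2 * fs)))]
  spki <- max(init)
  npki <- mean(init) / 2
  thr1 <- function() npki + 0.25 * (spki - npki)

  qrs <- integer()
  rr <- numeric()
  thr_trace <- numeric(length(pk))
  slope_at <- function(i) {
    i0 <- max(1L, i - round(0.075 * fs)); i1 <- min(n, i + round(0.075 * fs))
    max(abs(d[i0:i1]))
  }
  noise_peaks <- integer()
  k <- 1L
  while (k <= length(pk)) {
    i <- pk[k]
    thr_trace[k] <- thr1()
    is_qrs <- FALSE
    if (!length(qrs) || i - qrs[length(qrs)] > refr) {
      if (mwi[i] > thr1()) {
        is_qrs <- TRUE
        if (length(qrs) && i - qrs[length(qrs)] < twin &&
            slope_at(i) < 0.5 * slope_at(qrs[length(qrs)]))
          is_qrs <- FALSE                     # T wave
      }
    }
    if (is_qrs) {
      if (length(qrs)) rr <- c(rr, i - qrs[length(qrs)])
      qrs <- c(qrs, i)
      spki <- 0.125 * mwi[i] + 0.875 * spki
    } else {
      noise_peaks <- c(noise_peaks, i)
      npki <- 0.125 * mwi[i] + 0.875 * npki
    }
    # search-back when the expected beat is overdue
    if (length(qrs) && length(rr) >= 2) {
      rr_avg <- mean(utils::tail(rr, 8L))
      if (i - qrs[length(qrs)] > 1.66 * rr_avg) {
        cand <- noise_peaks[noise_peaks > qrs[length(qrs)] + refr &
                              noise_peaks < i]
        cand <- cand[mwi[cand] > 0.5 * thr1()]
        if (length(cand)) {
          j <- cand[which.max(mwi[cand])]
          rr[length(rr)] <- j - qrs[length(qrs)]
          spki <- 0.25 * mwi[j] + 0.75 * spki
          qrs <- sort(c(qrs, j))
          rr <- c(rr, i - j)
        }
      }
    }
    k <- k + 1L
  }

  # refine the fiducial point: largest |band-passed| value near each
  # integration peak (the band-pass is zero-phase, so no group delay)
  half <- round(0.10 * fs)
  times <- vapply(qrs, function(i) {
    i0 <- max(1L, i - half); i1 <- min(n, i + half)
    (i0 + which.max(abs(bp[i0:i1])) - 2L) / fs + trace$start
  }, 0)
  times <- sort(unique(times))
  structure(list(times = times, filtered = bp, derivative = d, squared = sq,
                 integrated = mwi, thresholds = thr_trace),
            class = "qrs_detection")
}

#' @export
print.qrs_detection <- function(x, ...) {
  cat("Pan-Tompkins detection:", length(x$times), "beats\n")
  invisible(x)
}

#' Signal-to-noise ratio of an annotated trace
#'
#' `SNR = 20*log10(VR / sigma_N)` where VR is the mean R-wave amplitude
#' (peak absolute value within +/-80 ms of each beat) and sigma_N the
#' standard deviation of the samples in the inter-beat quiet window,
#' `[R + 0.45*RR, R + 0.80*RR]` of each RR interval — the segment between
#' the T and the following P wave.
#'
#' @param trace a `"signal_trace"`.
#' @param r_times beat times, seconds (>= 2; defaults to the trace
#'   annotations).
#' @param quiet_window fractions of the RR interval bounding the noise
#'   segment.
#' @return an object of class `"snr_estimate"` with `vr` (V), `sigma_n`
#'   (V) and `snr_db`.
#' @export
estimate_snr <- function(trace, r_times = trace$annotations,
                         quiet_window = c(0.45, 0.80)) {
  if (length(r_times) < 2L) stop("at least two beat times are required")
  vr <- mean(.beat_peaks(trace, r_times)$peak)
  n <- length(trace$samples)
  quiet <- unlist(lapply(seq_len(length(r_times) - 1L), function(b) {
    rr <- r_times[b + 1L] - r_times[b]
    i0 <- floor((r_times[b] + quiet_window[1] * rr - trace$start) *
                  trace$rate) + 1L
    i1 <- ceiling((r_times[b] + quiet_window[2] * rr - trace$start) *
                    trace$rate)
    if (i1 < i0 || i0 < 1L || i0 > n) return(numeric())
    trace$samples[i0:min(i1, n)]
  }))
  if (length(quiet) < 2L) stop("empty quiet (T-to-P) windows")
  sigma_n <- stats::sd(quiet)
  structure(list(vr = vr, sigma_n = sigma_n,
                 snr_db = 20 * log10(vr / sigma_n)),
            class = "snr_estimate")
}

#' @export
print.snr_estimate <- function(x, ...) {
  cat(sprintf("SNR: %.2f dB (VR = %.3g V, sigma_N = %.3g V)\n",
              x$snr_db, x$vr, x$sigma_n))
  invisible(x)
}

#' Beat-detection scores from counts
#'
#' Builds the TP/FN/FP summary, with `TE = FN + FP`,
#' `SE = 100*TP/(TP+FN)`, the standard `PPV = 100*TP/(TP+FP)`, and an
#' inclusive variant `100*TP/(TP+FN+FP)` that charges both error types to
#' the denominator (a convention occasionally met in device evaluation
#' reports; both are reported rather than silently choosing one).
#'
#' @param tp,fn,fp non-negative counts.
#' @param tolerance matching tolerance used, seconds (metadata).
#' @return an object of class `"evaluation_stats"`.
#' @export
evaluation_stats <- function(tp, fn, fp, tolerance = NA_real_) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0)
  structure(list(tp = tp, fn = fn, fp = fp, te = fn + fp,
                 actual = tp + fn,
                 se = 100 * tp / (tp + fn),
                 ppv = 100 * tp / (tp + fp),
                 ppv_inclusive = 100 * tp / (tp + fn + fp),
                 tolerance = tolerance),
            class = "evaluation_stats")
}

#' Match detections against ground truth
#'
#' Greedy one-to-one nearest matching: candidate (truth, detection) pairs
#' within the tolerance are accepted in order of increasing time distance,
#' each beat and each detection being used at most once.  Matches are TP,
#' unmatched truths FN, unmatched detections FP.
#'
#' @param detected detected beat times, seconds (strictly increasing).
#' @param truth ground-truth beat times, seconds (strictly increasing).
#' @param tolerance maximum matching distance, seconds (> 0).
#' @return an `"evaluation_stats"` object.
#' @export
evaluate_detection <- function(detected, truth, tolerance = 0.1) {
  stopifnot(tolerance > 0)
  if (is.unsorted(detected, strictly = TRUE) ||
      is.unsorted(truth, strictly = TRUE))
    stop("beat time lists must be strictly increasing")
  if (!length(truth) || !length(detected))
    return(evaluation_stats(0L, length(truth), length(detected), tolerance))
  lo <- findInterval(detected - tolerance, truth) + 1L
  hi <- findInterval(detected + tolerance, truth)
  cand_d <- rep.int(seq_along(detected), pmax(0L, hi - lo + 1L))
  cand_t <- unlist(lapply(seq_along(detected), function(i)
    if (hi[i] >= lo[i]) lo[i]:hi[i] else integer()))
  if (!length(cand_d))
    return(evaluation_stats(0L, length(truth), length(detected), tolerance))
  dd <- abs(detected[cand_d] - truth[cand_t])
  ord <- order(dd, cand_t, cand_d)
  used_d <- logical(length(detected)); used_t <- logical(length(truth))
  tp <- 0L
  for (k in ord) {
    i <- cand_d[k]; j <- cand_t[k]
    if (!used_d[i] && !used_t[j]) {
      used_d[i] <- TRUE; used_t[j] <- TRUE; tp <- tp + 1L
    }
  }
  evaluation_stats(tp, sum(!used_t), sum(!used_d), tolerance)
}

#' @export
print.evaluation_stats <- function(x, ...) {
  cat("QRS detection quality\n")
  cat(sprintf("  beats %d | TP %d FN %d FP %d | TE %d\n",
              x$actual, x$tp, x$fn, x$fp, x$te))
  cat(sprintf("  SE %.2f%% | PPV %.2f%% (inclusive %.2f%%)\n",
              x$se, x$ppv, x$ppv_inclusive))
  invisible(x)
}

#' Formatted summary-table row
#'
#' Emits the row `Actual | TP | FN | FP | TE | SE | PPV` with thousands
#' separators on the counts and the percentages truncated (not rounded) to
#' two decimals, the convention evident in published detection tables
#' (e.g. 97.2257 prints as 97.22).
#'
#' @param stats an `"evaluation_stats"`.
#' @param ppv which PPV variant to print: `"inclusive"`
#'   (`TP/(TP+FN+FP)`) or `"standard"` (`TP/(TP+FP)`).
#' @return a single formatted string.
#' @export
detection_summary_table <- function(stats, ppv = c("inclusive", "standard")) {
  ppv <- match.arg(ppv)
  p <- if (ppv == "inclusive") stats$ppv_inclusive else stats$ppv
  fmt <- function(k) format(k, big.mark = ",", scientific = FALSE)
  pct <- function(x) sprintf("%.2f%%", floor(x * 100 + 1e-9) / 100)
  paste(fmt(stats$actual), fmt(stats$tp), fmt(stats$fn), fmt(stats$fp),
        fmt(stats$te), pct(stats$se), pct(p), sep = " | ")
}
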