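#' Fluorescence trace
#'
#' Mean ROI gray value per frame at uniform sampling (default 0.2 s/frame,
#' i.e. a 200 ms camera frame interval).
#'
#' @param values non-negative raw fluorescence per frame.
#' @param frame_interval seconds per frame.
#' @return An object of class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(values, frame_interval = 0.2) {
  values <- as.numeric(values)
  if (any(values < 0)) stop("fluorescence values must be >= 0")
  if (frame_interval <= 0) stop("frame_interval must be > 0")
  structure(list(values = values, frame_interval = frame_interval),
            class = "fluorescence_trace")
}

#' Local field potential trace
#'
#' @param values field potential (uV) per sample.
#' @param sample_rate sampling rate in Hz (default 6000).
#' @return An object of class `lfp_trace`.
#' @export
lfp_trace <- function(values, sample_rate = 6000) {
  structure(list(values = as.numeric(values), sample_rate = sample_rate),
            class = "lfp_trace")
}

trace_values <- function(trace) {
  if (inherits(trace, "fluorescence_trace") || inherits(trace, "lfp_trace"))
    trace$values
  else as.numeric(trace)
}

#' Asymmetric least squares baseline (Eilers-Boelens)
#'
#' Iteratively minimises `sum(w_i * (y_i - z_i)^2) + lambda * sum(d2(z)^2)`
#' where `d2` are second differences and the weights are `p` where the
#' signal exceeds the baseline and `1 - p` elsewhere, so positive
#' transients are nearly ignored while the smooth baseline is tracked.
#'
#' @param trace a [fluorescence_trace()] or numeric vector, length >= 10.
#' @param lambda smoothness penalty (default 1e7).
#' @param p asymmetry in (0, 1) (default 0.01).
#' @param iterations weight-update iterations (default 10).
#' @return Numeric baseline of the same length.
#' @export
asls_baseline <- function(trace, lambda = 1e7, p = 0.01, iterations = 10) {
  y <- trace_values(trace)
  n <- length(y)
  if (n < 10) stop("trace must have at least 10 samples")
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be > 0")
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)")
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (it in seq_len(iterations)) {
    W <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(W + DtD, w * y))
    w <- ifelse(y > z, p, 1 - p)
  }
  z
}

#' Baseline-normalised fluorescence change
#'
#' `dFF = (R - F0) / F0` elementwise.
#'
#' @param trace raw trace (a [fluorescence_trace()] or numeric vector).
#' @param F0 baseline, strictly positive everywhere.
#' @return Numeric dF/F series.
#' @export
dff <- function(trace, F0) {
  R <- trace_values(trace)
  if (length(F0) != length(R)) stop("baseline length mismatch")
  bad <- which(F0 <= 0)
  if (length(bad))
    stop(sprintf("baseline is not positive at index %d", bad[1]))
  (R - F0) / F0
}

#' Detect activity bursts in a dF/F series
#'
#' The threshold is `threshold_sigma` times a robust standard deviation
#' (1.4826 x MAD) of the whole series, applied about the series median (the
#' same centre the MAD is measured from, so that the small positive offset
#' left by the asymmetric baseline does not count as activity); maximal
#' runs above threshold are bursts. Onset/offset are in seconds; duration
#' is run length times the frame interval; `auc` is the trapezoidal
#' integral of dF/F over the run.
#'
#' @param dff_series numeric dF/F series, length >= 10.
#' @param threshold_sigma multiple of the robust std (default 3).
#' @param frame_interval seconds per frame (default 0.2).
#' @return List with `bursts` (data frame: onset_s, offset_s, duration_s,
#'   peak_dff, auc), `threshold`, and `active_time_fraction`.
#' @export
detect_bursts <- function(dff_series, threshold_sigma = 3,
                          frame_interval = 0.2) {
  y <- as.numeric(dff_series)
  if (length(y) < 10) stop("series must have at least 10 samples")
  sigma <- stats::mad(y)
  if (sigma == 0) {
    warning("zero-variance series: no bursts detectable")
    return(list(bursts = empty_burst_table(), threshold = 0,
                active_time_fraction = 0))
  }
  thr <- threshold_sigma * sigma
  active <- (y - stats::median(y)) > thr
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  onsets <- starts[r$values]
  offsets <- ends[r$values]
  if (length(onsets) == 0) {
    return(list(bursts = empty_burst_table(), threshold = thr,
                active_time_fraction = 0))
  }
  bursts <- data.frame(
    onset_s = (onsets - 1) * frame_interval,
    offset_s = offsets * frame_interval,
    duration_s = (offsets - onsets + 1L) * frame_interval,
    peak_dff = vapply(seq_along(onsets),
                      function(q) max(y[onsets[q]:offsets[q]]), numeric(1)),
    auc = vapply(seq_along(onsets), function(q) {
      seg <- y[onsets[q]:offsets[q]]
      if (length(seg) == 1) return(seg * frame_interval)
      frame_interval * (sum(seg) - (seg[1] + seg[length(seg)]) / 2)
    }, numeric(1)))
  list(bursts = bursts, threshold = thr,
       active_time_fraction = mean(active))
}

empty_burst_table <- function() {
  data.frame(onset_s = numeric(0), offset_s = numeric(0),
             duration_s = numeric(0), peak_dff = numeric(0),
             auc = numeric(0))
}

#' Normalised baseline brightness per culture segment
#'
#' For each segment trace: fit the baseline, detect bursts on dF/F, and
#' average the baseline over the inactive (non-burst) frames. Each
#' segment's mean is divided by the maximum across segments, giving values
#' in (0, 1].
#'
#' @param traces list of [fluorescence_trace()] objects (e.g. the culture's
#'   seven segments, edge to edge).
#' @param lambda,p,iterations passed to [asls_baseline()].
#' @param threshold_sigma passed to [detect_bursts()].
#' @return Numeric vector of normalised baselines, one per segment.
#' @export
segment_baseline_profile <- function(traces, lambda = 1e7, p = 0.01,
                                     iterations = 10, threshold_sigma = 3) {
  stopifnot(length(traces) >= 1)
  means <- vapply(traces, function(tr) {
    y <- trace_values(tr)
    dt <- if (inherits(tr, "fluorescence_trace")) tr$frame_interval else 0.2
    F0 <- asls_baseline(y, lambda = lambda, p = p, iterations = iterations)
    dd <- dff(y, F0)
    det <- suppressWarnings(
      detect_bursts(dd, threshold_sigma = threshold_sigma,
                    frame_interval = dt))
    inactive <- rep(TRUE, length(y))
    if (nrow(det$bursts)) {
      for (q in seq_len(nrow(det$bursts))) {
        a <- round(det$bursts$onset_s[q] / dt) + 1L
        b <- round(det$bursts$offset_s[q] / dt)
        inactive[a:b] <- FALSE
      }
    }
    if (!any(inactive)) stop("segment has no inactive frames")
    mean(F0[inactive])
  }, numeric(1))
  means / max(means)
}

#' Burst initiation times in an LFP trace
#'
#' A sample is an initiation point when the trace stays at or above the
#' threshold for the whole persistence window starting there; once an
#' initiation is registered, no new one is accepted until the trace first
#' falls below threshold.
#'
#' @param trace an [lfp_trace()] or numeric vector (assumed rectified /
#'   preprocessed by the caller).
#' @param threshold detection threshold (uV), > 0.
#' @param persistence required supra-threshold run (s), default 0.010.
#' @param sample_rate Hz; taken from the trace when it is an
#'   [lfp_trace()].
#' @return Numeric vector of initiation times (s, 0-based at the first
#'   sample).
#' @export
burst_initiation_time <- function(trace, threshold, persistence = 0.010,
                                  sample_rate = NULL) {
  y <- trace_values(trace)
  fs <- if (inherits(trace, "lfp_trace")) trace$sample_rate
        else if (!is.null(sample_rate)) sample_rate else 6000
  if (threshold <= 0) stop("threshold must be > 0")
  n_persist <- round(persistence * fs)
  if (n_persist < 1) stop("persistence must cover at least one sample")
  above <- y >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  init_idx <- starts[r$values & r$lengths >= n_persist + 1L]
  (init_idx - 1L) / fs
}

#' Burst-initiation delay between edge and centre channels
#'
#' Detects initiation times on both channels, pairs them greedily (nearest
#' unused partner within the pairing window), and reports per-burst delay
#' `edge - centre` (positive when the centre leads). The centre-leading
#' fraction counts strictly positive delays over all non-tied matched
#' bursts; exact ties count as neither.
#'
#' @param edge,center [lfp_trace()] objects (time-aligned).
#' @param thresholds list with elements `edge` and `center` (uV), or a
#'   single number used for both.
#' @param persistence supra-threshold persistence (s).
#' @param pairing_window maximum |delay| for a match (s), default 5.
#' @return List with `delays` (s), `center_leading_fraction`,
#'   `n_matched`, `unmatched_edge`, `unmatched_center` (times, s).
#' @export
initiation_delay <- function(edge, center, thresholds,
                             persistence = 0.010, pairing_window = 5) {
  if (!is.list(thresholds))
    thresholds <- list(edge = thresholds, center = thresholds)
  te <- burst_initiation_time(edge, thresholds$edge, persistence)
  tc <- burst_initiation_time(center, thresholds$center, persistence)
  used <- rep(FALSE, length(te))
  delays <- numeric(0)
  matched_c <- rep(FALSE, length(tc))
  for (q in seq_along(tc)) {
    if (!length(te)) break
    d <- abs(te - tc[q])
    d[used] <- Inf
    b <- which.min(d)
    if (length(b) && is.finite(d[b]) && d[b] <= pairing_window) {
      used[b] <- TRUE
      matched_c[q] <- TRUE
      delays <- c(delays, te[b] - tc[q])
    }
  }
  nonzero <- delays[delays != 0]
  frac <- if (length(nonzero)) mean(nonzero > 0) else NA_real_
  list(delays = delays,
       center_leading_fraction = frac,
       n_matched = length(delays),
       unmatched_edge = te[!used],
       unmatched_center = tc[!matched_c])
}

#' Band-pass and mains-notch preprocessing of an LFP trace
#'
#' 4th-order Butterworth band pass (default 100-3000 Hz) applied forward
#' and backward, followed by band-stop notches at 60 Hz and its harmonics
#' up to the upper band edge.
#'
#' @param trace an [lfp_trace()].
#' @param band passband (Hz).
#' @param notch_base mains frequency (Hz), default 60.
#' @param notch_halfwidth half-width of each notch (Hz).
#' @return A filtered [lfp_trace()].
#' @export
lfp_preprocess <- function(trace, band = c(100, 3000), notch_base = 60,
                           notch_halfwidth = 2) {
  stopifnot(inherits(trace, "lfp_trace"))
  fs <- trace$sample_rate
  nyq <- fs / 2
  hi <- min(band[2], nyq * 0.999)
  bp <- signal::butter(4, c(band[1], hi) / nyq, type = "pass")
  y <- signal::filtfilt(bp, trace$values)
  harmonics <- seq(notch_base, hi, by = notch_base)
  for (f0 in harmonics) {
    lo <- (f0 - notch_halfwidth) / nyq
    up <- min((f0 + notch_halfwidth) / nyq, 0.999)
    bs <- signal::butter(2, c(lo, up), type = "stop")
    y <- signal::filtfilt(bs, y)
  }
  lfp_trace(y, fs)
}

#' Automatic silent-segment threshold for an LFP channel
#'
#' Selects the window (default 100 ms) with minimal variance across the
#' recording and returns the standard deviation of that segment, the
#' activity-detection threshold for the channel.
#'
#' @param trace an [lfp_trace()].
#' @param window_s window length (s), default 0.1.
#' @return The silent-segment standard deviation (uV).
#' @export
silent_threshold <- function(trace, window_s = 0.1) {
  stopifnot(inherits(trace, "lfp_trace"))
  y <- trace$values
  w <- max(2L, round(window_s * trace$sample_rate))
  if (length(y) < w) stop("trace shorter than the silent window")
  # rolling variance via cumulative sums
  cs <- cumsum(c(0, y))
  cs2 <- cumsum(c(0, y^2))
  n <- length(y) - w + 1L
  idx <- seq_len(n)
  s1 <- cs[idx + w] - cs[idx]
  s2 <- cs2[idx + w] - cs2[idx]
  v <- (s2 - s1^2 / w) / (w - 1)
  sqrt(max(v[which.min(v)], 0))
}
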