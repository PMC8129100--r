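#' Synthetic cell field with known ground truth
#'
#' Seeded generators for post-aggregation cell arrangements, used to
#' exercise the morphometric operations against construction-time truth.
#' Three kinds are available:
#' \describe{
#'   \item{`uniform`}{cells uniform in a box with a given astrocyte
#'     fraction.}
#'   \item{`clusters`}{Gaussian neuron clusters at given x-centres (same
#'     spread in y/z up to the box), plus uniformly scattered astrocytes.}
#'   \item{`shell`}{a slab whose top `shell_thickness` um holds astrocytes
#'     at `shell_fraction` and whose interior holds them at
#'     `core_fraction` (emulating the astrocyte-rich superficial sheath
#'     over a neuron-rich core).}
#' }
#'
#' @param kind one of `"uniform"`, `"clusters"`, `"shell"`.
#' @param n total cells (`uniform`, `shell`) or per-cluster (`clusters`).
#' @param box c(length, width, height) um.
#' @param astrocyte_fraction astrocyte fraction (`uniform`).
#' @param centers cluster x-centres (um) (`clusters`).
#' @param sigma cluster Gaussian spread (um) (`clusters`).
#' @param shell_thickness,shell_fraction,core_fraction shell parameters.
#' @param min_spacing optional hard-core spacing (um); 0 disables.
#' @param seed RNG seed.
#' @return A [cell_population()]; the generator arguments are attached as
#'   the `"truth"` attribute.
#' @export
make_cell_field <- function(kind = c("uniform", "clusters", "shell"),
                            n = 1000, box = c(1000, 200, 100),
                            astrocyte_fraction = 0.2,
                            centers = c(250, 750), sigma = 50,
                            shell_thickness = 10, shell_fraction = 0.4,
                            core_fraction = 0.06,
                            min_spacing = 0, seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "uniform") {
    pos <- if (min_spacing > 0)
      cpp_place_points(n, 0L, box[1], box[2], box[3], 0, min_spacing, 10000L)
    else cbind(runif(n, 0, box[1]), runif(n, 0, box[2]),
               runif(n, 0, box[3]))
    types <- rep("N", n)
    types[sample.int(n, round(astrocyte_fraction * n))] <- "A"
  } else if (kind == "clusters") {
    pos <- do.call(rbind, lapply(centers, function(cx) {
      cbind(rnorm(n, cx, sigma),
            pmin(pmax(rnorm(n, box[2] / 2, sigma), 0), box[2]),
            pmin(pmax(rnorm(n, box[3] / 2, sigma), 0), box[3]))
    }))
    pos[, 1] <- pmin(pmax(pos[, 1], 0), box[1])
    types <- rep("N", nrow(pos))
  } else {
    core_h <- box[3] - shell_thickness
    if (core_h <= 0) stop("shell thicker than the slab")
    n_shell <- round(n * shell_thickness / box[3])
    n_core <- n - n_shell
    pos <- rbind(
      cbind(runif(n_core, 0, box[1]), runif(n_core, 0, box[2]),
            runif(n_core, 0, core_h)),
      cbind(runif(n_shell, 0, box[1]), runif(n_shell, 0, box[2]),
            runif(n_shell, core_h, box[3])))
    types <- c(
      ifelse(runif(n_core) < core_fraction, "A", "N"),
      ifelse(runif(n_shell) < shell_fraction, "A", "N"))
  }
  out <- cell_population(pos, types)
  attr(out, "truth") <- list(kind = kind, n = n, box = box,
                             astrocyte_fraction = astrocyte_fraction,
                             centers = centers, sigma = sigma,
                             shell_thickness = shell_thickness,
                             shell_fraction = shell_fraction,
                             core_fraction = core_fraction, seed = seed)
  out
}

#' Synthetic fibrous ROI image
#'
#' Renders bright line segments at a common orientation (with optional
#' angular jitter) on a dark noisy background, emulating a patch of
#' stained processes.
#'
#' @param angle_deg fiber orientation relative to the x axis (deg).
#' @param angular_jitter_sd per-fiber angular jitter (deg); large values
#'   approach an isotropic patch.
#' @param n_fibers number of segments.
#' @param fiber_width_px fiber thickness (px).
#' @param size_px image side (px).
#' @param fiber_intensity gray value of fiber pixels.
#' @param background_sd Gaussian background noise sd (gray values).
#' @param pixel_pitch um/px.
#' @param seed RNG seed.
#' @return A [roi_image()]; generator arguments attached as `"truth"`.
#' @export
make_fiber_image <- function(angle_deg = 0, angular_jitter_sd = 0,
                             n_fibers = 12, fiber_width_px = 3,
                             size_px = 40, fiber_intensity = 200,
                             background_sd = 10, pixel_pitch = 0.25,
                             seed = 1) {
  set.seed(seed)
  img <- matrix(abs(rnorm(size_px^2, 0, background_sd)), size_px, size_px)
  half_len <- size_px # segments span the patch
  for (f in seq_len(n_fibers)) {
    th <- (angle_deg + rnorm(1, 0, angular_jitter_sd)) * pi / 180
    cx <- runif(1, 1, size_px)
    cy <- runif(1, 1, size_px)
    tseq <- seq(-half_len, half_len, by = 0.4)
    half_w <- (fiber_width_px - 1) / 2
    wseq <- seq(-half_w, half_w, by = 0.4)
    for (w in wseq) { # offset perpendicular to the fiber axis
      xs <- round(cx + tseq * cos(th) - w * sin(th))
      ys <- round(cy + tseq * sin(th) + w * cos(th))
      ok <- xs >= 1 & xs <= size_px & ys >= 1 & ys <= size_px
      img[cbind(ys[ok], xs[ok])] <- fiber_intensity
    }
  }
  out <- roi_image(img, pixel_pitch = pixel_pitch)
  attr(out, "truth") <- list(angle_deg = angle_deg,
                             angular_jitter_sd = angular_jitter_sd,
                             n_fibers = n_fibers, seed = seed)
  out
}

#' Synthetic nucleus z-stack
#'
#' A solid ellipsoid of given semi-axes, rotated in the X-Y plane, voxelised
#' into a cuboid ROI with bright interior and dark background.
#'
#' @param semi_axes c(a, b, c) um along the (pre-rotation) x, y, z axes.
#' @param angle_deg X-Y rotation of the major axis (deg).
#' @param voxel_size um per voxel (isotropic).
#' @param margin background margin around the ellipsoid (um).
#' @param inside,outside gray values.
#' @param noise_sd additive Gaussian noise sd.
#' @param seed RNG seed.
#' @return 3D array (x, y, z); generator arguments attached as `"truth"`.
#' @export
make_nucleus_stack <- function(semi_axes = c(10, 4, 4), angle_deg = 0,
                               voxel_size = 0.5, margin = 3,
                               inside = 200, outside = 20, noise_sd = 0,
                               seed = 1) {
  set.seed(seed)
  ext <- max(semi_axes[1:2]) + margin
  nxy <- ceiling(2 * ext / voxel_size)
  nz <- ceiling(2 * (semi_axes[3] + margin) / voxel_size)
  cx <- (nxy + 1) / 2
  cz <- (nz + 1) / 2
  th <- angle_deg * pi / 180
  idx <- expand.grid(x = seq_len(nxy), y = seq_len(nxy), z = seq_len(nz))
  dx <- (idx$x - cx) * voxel_size
  dy <- (idx$y - cx) * voxel_size
  dz <- (idx$z - cz) * voxel_size
  # rotate back into the ellipsoid frame
  u <- dx * cos(th) + dy * sin(th)
  v <- -dx * sin(th) + dy * cos(th)
  inside_mask <- (u / semi_axes[1])^2 + (v / semi_axes[2])^2 +
    (dz / semi_axes[3])^2 <= 1
  vol <- array(outside, c(nxy, nxy, nz))
  vol[as.matrix(idx)] <- ifelse(inside_mask, inside, outside)
  if (noise_sd > 0) vol <- vol + rnorm(length(vol), 0, noise_sd)
  vol <- pmax(vol, 0)
  attr(vol, "truth") <- list(semi_axes = semi_axes, angle_deg = angle_deg,
                             voxel_size = voxel_size, seed = seed)
  vol
}

#' Synthetic calcium trace with planted bursts
#'
#' Slow sinusoidal drift plus linear trend on a constant baseline, plateau
#' burst transients with one-frame ramps at stated onsets, and Gaussian
#' noise. Burst onsets, durations and amplitudes are returned as ground
#' truth.
#'
#' @param n_frames trace length (frames).
#' @param frame_interval s/frame (default 0.2).
#' @param baseline_level mean raw fluorescence.
#' @param drift_amplitude,drift_period_s sinusoidal drift (gray, s).
#' @param trend_per_s linear trend (gray/s).
#' @param burst_onsets_s,burst_durations_s,burst_amplitudes planted bursts
#'   (vectors of equal length; amplitudes are dF/F units, i.e. the raw
#'   transient is `amplitude * baseline_level`).
#' @param noise_sd Gaussian noise sd (gray).
#' @param seed RNG seed.
#' @return List with `trace` ([fluorescence_trace()]) and `truth`
#'   (data frame of the planted bursts).
#' @export
make_ca_trace <- function(n_frames = 3000, frame_interval = 0.2,
                          baseline_level = 100, drift_amplitude = 5,
                          drift_period_s = 300, trend_per_s = 0.01,
                          burst_onsets_s = c(60, 180, 300, 420, 540),
                          burst_durations_s = c(20, 35, 30, 45, 25),
                          burst_amplitudes = c(1.5, 2, 1.8, 2.5, 1.2),
                          noise_sd = 1, seed = 1) {
  stopifnot(length(burst_onsets_s) == length(burst_durations_s),
            length(burst_onsets_s) == length(burst_amplitudes))
  set.seed(seed)
  t_s <- (seq_len(n_frames) - 1) * frame_interval
  # bursts planted beyond the trace cannot appear in it: drop from truth
  inside <- burst_onsets_s + burst_durations_s <= max(t_s)
  burst_onsets_s <- burst_onsets_s[inside]
  burst_durations_s <- burst_durations_s[inside]
  burst_amplitudes <- burst_amplitudes[inside]
  base <- baseline_level + drift_amplitude *
    sin(2 * pi * t_s / drift_period_s) + trend_per_s * t_s
  y <- base
  for (q in seq_along(burst_onsets_s)) {
    a <- burst_onsets_s[q]
    b <- a + burst_durations_s[q]
    ramp <- frame_interval # one-frame rise and fall
    shape <- pmin(pmax((t_s - a) / ramp, 0), 1) *
      pmin(pmax((b - t_s) / ramp, 0), 1)
    y <- y + burst_amplitudes[q] * baseline_level * shape
  }
  y <- pmax(y + rnorm(n_frames, 0, noise_sd), 0)
  list(trace = fluorescence_trace(y, frame_interval),
       truth = data.frame(onset_s = burst_onsets_s,
                          duration_s = burst_durations_s,
                          amplitude = burst_amplitudes))
}

#' Synthetic edge/centre LFP pair with known initiation order
#'
#' Shared plateau burst envelopes on both channels; per burst, the centre
#' channel leads (or lags) by a stated delay. Traces are rectified-style
#' (non-negative envelope plus noise), suitable for direct thresholding.
#'
#' @param n_bursts number of bursts.
#' @param burst_spacing_s time between burst onsets (s).
#' @param burst_duration_s burst plateau length (s).
#' @param burst_amplitude plateau level (uV).
#' @param center_lead_s per-burst lead of the centre channel (s): positive
#'   means the centre initiates first. Recycled to `n_bursts`; may be
#'   negative for edge-led bursts.
#' @param noise_sd background noise sd (uV).
#' @param sample_rate Hz (default 6000).
#' @param seed RNG seed.
#' @return List with `edge`, `center` ([lfp_trace()]) and `truth`
#'   (data frame: center_time_s, edge_time_s, center_leads).
#' @export
make_lfp_pair <- function(n_bursts = 10, burst_spacing_s = 20,
                          burst_duration_s = 2, burst_amplitude = 50,
                          center_lead_s = 0.03, noise_sd = 1,
                          sample_rate = 6000, seed = 1) {
  set.seed(seed)
  lead <- rep_len(center_lead_s, n_bursts)
  t_center <- 5 + (seq_len(n_bursts) - 1) * burst_spacing_s
  t_edge <- t_center + lead
  total_s <- if (n_bursts > 0)
    max(c(t_center, t_edge)) + burst_duration_s + 5 else 10
  n <- ceiling(total_s * sample_rate)
  mk <- function(onsets) {
    y <- abs(rnorm(n, 0, noise_sd))
    for (a in onsets) {
      i0 <- round(a * sample_rate) + 1L
      i1 <- min(n, i0 + round(burst_duration_s * sample_rate))
      y[i0:i1] <- burst_amplitude + abs(rnorm(i1 - i0 + 1L, 0, noise_sd))
    }
    lfp_trace(y, sample_rate)
  }
  center <- mk(t_center)
  edge <- mk(t_edge)
  list(edge = edge, center = center,
       truth = data.frame(center_time_s = t_center,
                          edge_time_s = t_edge,
                          center_leads = lead > 0))
}
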