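#' Ground truth for synthetic datasets
#'
#' Collects the generating parameters of a synthetic experiment so that
#' recovery tests can compare pipeline output against known truth.
#'
#' @param aggregates Data frame with columns `shape` ("segment" or "blob"),
#'   `x_nm`, `y_nm` (anchor = center), `size_nm` (segment full length or
#'   blob radius, > 0), `orientation` (rad; ignored for blobs).
#' @param fiducials Data frame with `x_nm`, `y_nm`.
#' @param spike_times List (per cell) of 0-based spike frame indices.
#' @param state_weights Named numeric vector of (phosphate, adduct) state
#'   probabilities, names `"p,a"`, summing to 1.
#' @param seed Integer seed.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(aggregates = NULL, fiducials = NULL,
                         spike_times = NULL, state_weights = NULL,
                         seed = 1L) {
  if (!is.null(aggregates)) {
    stopifnot(all(aggregates$size_nm > 0),
              all(aggregates$shape %in% c("segment", "blob")))
  }
  if (!is.null(state_weights))
    stopifnot(abs(sum(state_weights) - 1) < 1e-8)
  structure(list(aggregates = aggregates, fiducials = fiducials,
                 spike_times = spike_times, state_weights = state_weights,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' Blinking-emitter model for SMLM simulation
#'
#' Transient dye binding produces bursts: runs of consecutive frames during
#' which one binding site emits. Burst durations are geometric (simplest
#' model with the temporal structure the burst-grouping stage assumes:
#' intra-burst gaps of at most one frame, inter-burst gaps much larger than
#' the 21 ms temporal epsilon).
#'
#' @param burst_rate Bursts per aggregate per 1000 frames (default 30).
#' @param burst_duration_frames Mean burst duration (default 3).
#' @param locs_per_frame Mean localizations per burst frame (default 1).
#' @param precision_nm Localization error s.d. (default 20).
#' @param exposure_ms Frame exposure (default 20).
#' @param intensity Mean fit signal strength written to the table
#'   (default 10, above the quality-filter cutoff of 3).
#' @return An object of class `emitter_model`.
#' @export
emitter_model <- function(burst_rate = 30, burst_duration_frames = 3,
                          locs_per_frame = 1, precision_nm = 20,
                          exposure_ms = 20, intensity = 10) {
  stopifnot(burst_rate > 0, burst_duration_frames > 0, locs_per_frame > 0,
            precision_nm >= 0, exposure_ms > 0)
  structure(list(burst_rate = burst_rate,
                 burst_duration_frames = burst_duration_frames,
                 locs_per_frame = locs_per_frame,
                 precision_nm = precision_nm, exposure_ms = exposure_ms,
                 intensity = intensity),
            class = "emitter_model")
}

# One random point on an aggregate's support: uniform along a segment,
# uniform in a blob's disc.
.sample_support <- function(agg) {
  if (agg$shape == "segment") {
    u <- stats::runif(1, -0.5, 0.5) * agg$size_nm
    c(agg$x_nm + u * cos(agg$orientation), agg$y_nm + u * sin(agg$orientation))
  } else {
    r <- agg$size_nm * sqrt(stats::runif(1))
    th <- stats::runif(1, 0, 2 * pi)
    c(agg$x_nm + r * cos(th), agg$y_nm + r * sin(th))
  }
}

#' Simulate an SMLM localization stream
#'
#' Each aggregate produces blinking bursts: a binding site is drawn
#' uniformly on the aggregate support (along segments, within blob discs),
#' the burst occupies consecutive frames (geometric duration), and every
#' burst frame yields localizations at the site plus isotropic Gaussian
#' noise of s.d. `precision_nm`. Fiducials emit one localization in every
#' frame at a fixed position. Deterministic given `truth$seed`.
#'
#' @param truth A [ground_truth()] with aggregates and/or fiducials.
#' @param emitter An [emitter_model()].
#' @param n_frames Number of frames (>= 1).
#' @param n_bursts Optional integer vector (per aggregate) fixing the burst
#'   count exactly; default draws Poisson counts from `burst_rate`.
#' @return A [localization_table()] (frame interval = `exposure_ms`).
#' @export
gen_smlm_stream <- function(truth, emitter = emitter_model(), n_frames,
                            n_bursts = NULL) {
  stopifnot(inherits(truth, "ground_truth"), n_frames >= 1)
  na <- if (is.null(truth$aggregates)) 0L else nrow(truth$aggregates)
  nf <- if (is.null(truth$fiducials)) 0L else nrow(truth$fiducials)
  if (na + nf == 0L) stop("empty truth: no aggregates and no fiducials")
  with_seed(truth$seed, {
    frame <- integer(); x <- numeric(); y <- numeric()
    for (i in seq_len(na)) {
      agg <- truth$aggregates[i, ]
      nb <- if (!is.null(n_bursts)) n_bursts[i] else
        stats::rpois(1, emitter$burst_rate * n_frames / 1000)
      for (b in seq_len(nb)) {
        site <- .sample_support(agg)
        dur <- min(1L + stats::rgeom(1, 1 / emitter$burst_duration_frames),
                   n_frames)
        start <- sample.int(n_frames - dur + 1L, 1L) - 1L
        for (f in start:(start + dur - 1L)) {
          nl <- max(1L, stats::rpois(1, emitter$locs_per_frame))
          frame <- c(frame, rep(f, nl))
          x <- c(x, site[1] + stats::rnorm(nl, 0, emitter$precision_nm))
          y <- c(y, site[2] + stats::rnorm(nl, 0, emitter$precision_nm))
        }
      }
    }
    for (i in seq_len(nf)) {
      fid <- truth$fiducials[i, ]
      frame <- c(frame, 0:(n_frames - 1L))
      x <- c(x, fid$x_nm + stats::rnorm(n_frames, 0, emitter$precision_nm / 4))
      y <- c(y, fid$y_nm + stats::rnorm(n_frames, 0, emitter$precision_nm / 4))
    }
    n <- length(frame)
    localization_table(frame = frame, x_nm = x, y_nm = y,
                       intensity = rep(emitter$intensity, n),
                       precision_nm = rep(max(emitter$precision_nm, 1e-6), n),
                       frame_interval_ms = emitter$exposure_ms)
  })
}

#' Render a diffraction-limited image stack of aggregates
#'
#' Each aggregate's support is convolved with a Gaussian point spread
#' function and sampled on the camera grid; frames add Poisson shot noise
#' on the signal plus Gaussian read noise on top of a constant background.
#'
#' @param truth A [ground_truth()] with aggregates (positions within the
#'   field of view).
#' @param psf_sigma_nm PSF sigma in nm (> 0; default 150, a diffraction-
#'   limited 488 nm TIRF spot).
#' @param noise List: `gain` (photons per intensity unit, default 1),
#'   `read_sd` (Gaussian read noise s.d., default 0), `background`
#'   (constant offset, default 0). `gain = 0` disables shot noise.
#' @param n_frames Number of frames.
#' @param fov_px Field of view (square), px.
#' @param pixel_size_nm Camera pixel pitch (default 107.2).
#' @param amplitude Peak signal scale per aggregate sample point.
#' @return An [image_stack()].
#' @export
render_dl_stack <- function(truth, psf_sigma_nm = 150,
                            noise = list(gain = 1, read_sd = 0, background = 0),
                            n_frames = 1, fov_px = 64,
                            pixel_size_nm = 107.2, amplitude = 100) {
  stopifnot(inherits(truth, "ground_truth"), psf_sigma_nm > 0)
  gain <- if (is.null(noise$gain)) 1 else noise$gain
  read_sd <- if (is.null(noise$read_sd)) 0 else noise$read_sd
  background <- if (is.null(noise$background)) 0 else noise$background
  fov_nm <- fov_px * pixel_size_nm
  px_x <- (seq_len(fov_px) - 1) * pixel_size_nm   # center of col j
  px_y <- (seq_len(fov_px) - 1) * pixel_size_nm
  base <- matrix(0, fov_px, fov_px)
  na <- if (is.null(truth$aggregates)) 0L else nrow(truth$aggregates)
  for (i in seq_len(na)) {
    agg <- truth$aggregates[i, ]
    half <- if (agg$shape == "segment") agg$size_nm / 2 else agg$size_nm
    if (agg$x_nm - half < -pixel_size_nm / 2 || agg$x_nm + half > fov_nm ||
        agg$y_nm - half < -pixel_size_nm / 2 || agg$y_nm + half > fov_nm)
      stop("aggregate outside field of view")
    # dense support sampling (one point per quarter pixel of arc/area)
    if (agg$shape == "segment") {
      np <- max(2L, ceiling(agg$size_nm / (pixel_size_nm / 4)))
      u <- seq(-0.5, 0.5, length.out = np) * agg$size_nm
      sx <- agg$x_nm + u * cos(agg$orientation)
      sy <- agg$y_nm + u * sin(agg$orientation)
      wt <- rep(agg$size_nm / np, np)
    } else {
      np <- max(4L, ceiling((agg$size_nm / (pixel_size_nm / 4))^2 * pi))
      rr <- agg$size_nm * sqrt((seq_len(np) - 0.5) / np)
      th <- 2 * pi * (seq_len(np) - 0.5) * (sqrt(5) - 1) / 2  # golden spiral
      sx <- agg$x_nm + rr * cos(th)
      sy <- agg$y_nm + rr * sin(th)
      wt <- rep(agg$size_nm / np, np)
    }
    field <- matrix(0, fov_px, fov_px)
    for (s in seq_along(sx)) {
      gx <- stats::dnorm(px_x, sx[s], psf_sigma_nm)
      gy <- stats::dnorm(px_y, sy[s], psf_sigma_nm)
      field <- field + wt[s] * outer(gy, gx)
    }
    # amplitude = the aggregate's peak signal above background
    base <- base + amplitude * field / max(field)
  }
  base <- base + background
  data <- array(0, c(n_frames, fov_px, fov_px))
  with_seed(truth$seed, {
    for (f in seq_len(n_frames)) {
      m <- base
      if (gain > 0) m <- stats::rpois(length(m), gain * m) / gain
      if (read_sd > 0) m <- m + stats::rnorm(length(m), 0, read_sd)
      data[f, , ] <- pmax(matrix(m, fov_px, fov_px), 0)
    }
  })
  image_stack(data, pixel_size_nm = pixel_size_nm)
}

#' Simulate a deconvolved native mass spectrum
#'
#' The spectrum is a weighted sum of Gaussian peaks centered on the state
#' masses `base + 80 p + 23 a`, plus Gaussian noise truncated at zero.
#'
#' @param base_mass_da Unmodified mass (default 39,900 Da).
#' @param state_weights Named numeric vector, names `"p,a"` (e.g.
#'   `c("10,0" = 1)`), weights summing to 1.
#' @param peak_fwhm_da Peak full width at half maximum (default 2 Da).
#' @param noise_sd Intensity noise s.d. (default 0).
#' @param grid `c(lo, hi, step)` mass grid in Da; must cover all state
#'   masses.
#' @param seed RNG seed for the noise.
#' @return A [mass_spectrum()] with `mass_range = c(lo, hi)`.
#' @export
gen_spectrum <- function(base_mass_da = 39900, state_weights,
                         peak_fwhm_da = 2, noise_sd = 0,
                         grid = c(39800, 44000, 0.5), seed = NULL) {
  stopifnot(abs(sum(state_weights) - 1) < 1e-8)
  m <- seq(grid[1], grid[2], by = grid[3])
  sigma <- peak_fwhm_da / (2 * sqrt(2 * log(2)))
  y <- numeric(length(m))
  for (nm in names(state_weights)) {
    pa <- as.numeric(strsplit(nm, ",")[[1]])
    center <- base_mass_da + 80 * pa[1] + 23 * pa[2]
    if (center < grid[1] || center > grid[2])
      stop("state mass outside grid: ", nm)
    y <- y + state_weights[[nm]] * stats::dnorm(m, center, sigma)
  }
  if (noise_sd > 0)
    y <- with_seed(seed, pmax(y + stats::rnorm(length(y), 0, noise_sd), 0))
  mass_spectrum(m, y, mass_range = grid[1:2])
}

#' Simulate one calcium (or ROS) trace
#'
#' Baseline plus optional linear drift or ramp, plus peak-shaped spikes
#' (linear rise over `rise` frames, exponential decay with time constant
#' `decay`), plus Gaussian noise.
#'
#' @param n_frames Trace length.
#' @param spike_frames 0-based spike onset frames.
#' @param amplitude Spike amplitude over baseline.
#' @param rise Rise time in frames (default 1: instant rise at onset + 1).
#' @param decay Exponential decay constant in frames (default 20).
#' @param baseline Baseline level (default 1).
#' @param drift Linear drift per frame (default 0); a positive value makes
#'   a ROS-style ramp.
#' @param noise_sd Additive Gaussian noise s.d. (default 0).
#' @param seed RNG seed.
#' @return Numeric vector of length `n_frames`.
#' @export
gen_calcium_trace <- function(n_frames, spike_frames = integer(),
                              amplitude = 1, rise = 1, decay = 20,
                              baseline = 1, drift = 0, noise_sd = 0,
                              seed = NULL) {
  tr <- baseline + drift * (0:(n_frames - 1))
  for (s in spike_frames) {
    t <- 0:(n_frames - 1) - s
    kernel <- ifelse(t < 0, 0,
                     ifelse(t < rise, amplitude * (t + 1) / rise,
                            amplitude * exp(-(t - rise) / decay)))
    tr <- tr + kernel
  }
  if (noise_sd > 0)
    tr <- with_seed(seed, tr + stats::rnorm(n_frames, 0, noise_sd))
  tr
}

#' Simulate a dual-channel cell movie with ground truth
#'
#' Cells are bright discs at fixed, non-overlapping positions. Channel 1
#' (calcium) shows baseline plus peak-shaped transients at the true spike
#' times; channel 2 (ROS) shows a linear ramp, for responding cells only.
#' Both channels carry additive Gaussian noise.
#'
#' @param n_cells Number of cells.
#' @param cell_radius_px Cell radius (default 5 px).
#' @param spike_model List: `amplitude` (over baseline, default 2), `rise`
#'   (frames, default 1), `decay` (frames, default 20).
#' @param ros_ramp Ramp slope (intensity per frame) for responding cells.
#' @param n_frames Movie length.
#' @param fov_px Field of view (square), px.
#' @param n_spikes Spikes per responding cell (default 1); spike times are
#'   drawn uniformly after `stimulus_frame`.
#' @param responding Logical vector (per cell) or a single fraction.
#' @param stimulus_frame 0-based stimulus frame (default `n_frames %/% 4`).
#' @param baseline Cell baseline intensity (default 100).
#' @param noise_sd Additive pixel noise s.d. (default 0).
#' @param seed RNG seed.
#' @return List: `calcium` and `ros` ([image_stack()]s, 1000 ms frame
#'   interval) and `truth` (a [ground_truth()] whose `spike_times` is the
#'   per-cell list of onset frames; cell positions as attribute `"cells"`).
#' @export
gen_cell_movie <- function(n_cells, cell_radius_px = 5,
                           spike_model = list(amplitude = 2, rise = 1,
                                              decay = 20),
                           ros_ramp = 0.2, n_frames = 200, fov_px = 96,
                           n_spikes = 1, responding = 1,
                           stimulus_frame = n_frames %/% 4,
                           baseline = 100, noise_sd = 0, seed = 1L) {
  # lay cells on a square lattice with >= 4 radii spacing
  spacing <- 4 * cell_radius_px
  per_row <- floor((fov_px - spacing / 2) / spacing)
  if (per_row < 1 || per_row^2 < n_cells) stop("cells do not fit in frame")
  pos <- cbind(row = spacing * ((seq_len(n_cells) - 1) %/% per_row + 1),
               col = spacing * ((seq_len(n_cells) - 1) %% per_row + 1))
  if (length(responding) == 1 && is.numeric(responding) && responding <= 1 &&
      !is.logical(responding)) {
    n_resp <- round(responding * n_cells)
    responding <- seq_len(n_cells) <= n_resp
  }
  with_seed(seed, {
    spike_times <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      spike_times[[i]] <- if (responding[i] && n_spikes > 0)
        sort(sample((stimulus_frame + 5):(n_frames - 30), n_spikes))
      else integer(0)
    }
    disk <- function() {
      rr <- -cell_radius_px:cell_radius_px
      sel <- outer(rr^2, rr^2, "+") <= cell_radius_px^2
      which(sel, arr.ind = TRUE) - cell_radius_px - 1L
    }
    dk <- disk()
    ca <- array(0, c(n_frames, fov_px, fov_px))
    ro <- array(0, c(n_frames, fov_px, fov_px))
    for (i in seq_len(n_cells)) {
      catr <- gen_calcium_trace(n_frames, spike_times[[i]],
                                amplitude = spike_model$amplitude * baseline,
                                rise = spike_model$rise,
                                decay = spike_model$decay,
                                baseline = baseline)
      rotr <- baseline +
        if (responding[i])
          ros_ramp * pmax(0:(n_frames - 1) - stimulus_frame, 0)
        else 0
      px <- cbind(pos[i, 1] + dk[, 1], pos[i, 2] + dk[, 2])
      ok <- px[, 1] >= 1 & px[, 1] <= fov_px & px[, 2] >= 1 & px[, 2] <= fov_px
      px <- px[ok, , drop = FALSE]
      for (f in seq_len(n_frames)) {
        ca[cbind(f, px[, 1], px[, 2])] <- catr[f]
        ro[cbind(f, px[, 1], px[, 2])] <- if (length(rotr) > 1) rotr[f] else rotr
      }
    }
    if (noise_sd > 0) {
      ca <- pmax(ca + array(stats::rnorm(length(ca), 0, noise_sd), dim(ca)), 0)
      ro <- pmax(ro + array(stats::rnorm(length(ro), 0, noise_sd), dim(ro)), 0)
    }
    truth <- ground_truth(spike_times = spike_times, seed = seed)
    attr(truth, "cells") <- data.frame(cell = seq_len(n_cells),
                                       row = pos[, 1], col = pos[, 2],
                                       responding = responding)
    attr(truth, "stimulus_frame") <- stimulus_frame
    list(calcium = image_stack(ca, frame_interval_ms = 1000,
                               channel_label = "calcium"),
         ros = image_stack(ro, frame_interval_ms = 1000,
                           channel_label = "ros"),
         truth = truth)
  })
}

#' Simulate per-vesicle fluorescence for the calcium influx assay
#'
#' Constructs `F_sample = F_background + frac * (F_ionomycin -
#' F_background)` exactly, plus optional Gaussian noise on F_sample.
#'
#' @param influx_fracs True influx fractions in `[0, 1]`, one per vesicle.
#' @param f_background,f_ionomycin Phase means (ionomycin > background).
#' @param noise_sd Noise s.d. on F_sample (default 0).
#' @param seed RNG seed.
#' @return Data frame: vesicle, F_background, F_sample, F_ionomycin.
#' @export
gen_vesicle_frames <- function(influx_fracs, f_background = 100,
                               f_ionomycin = 1100, noise_sd = 0,
                               seed = NULL) {
  stopifnot(all(influx_fracs >= 0 & influx_fracs <= 1))
  if (f_ionomycin <= f_background) stop("F_ionomycin must exceed F_background")
  n <- length(influx_fracs)
  fs <- f_background + influx_fracs * (f_ionomycin - f_background)
  if (noise_sd > 0)
    fs <- with_seed(seed, fs + stats::rnorm(n, 0, noise_sd))
  data.frame(vesicle = seq_len(n), F_background = rep(f_background, n),
             F_sample = fs, F_ionomycin = rep(f_ionomycin, n))
}
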