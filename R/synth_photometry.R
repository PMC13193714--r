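#' Configuration for a simulated photometry session
#'
#' Defines a generative model for a dual-channel recording: each channel
#' carries its own single-exponential photobleaching decay, both share a
#' slow mean-reverting (Ornstein-Uhlenbeck) motion artifact, and the
#' calcium-dependent channel additionally carries event-locked transients
#' of known amplitude — the ground truth downstream stages must recover.
#'
#' The default bleach time constants are equal (both wavelengths bleach
#' the same fluorophore); per-animal rate differences are introduced at
#' the cohort level (see [simulate_event_session()]). The default
#' `coupling_405` equals the 405/465 brightness ratio, reflecting that
#' fiber-bending artifacts scale with collected light.
#'
#' @param duration_s Session length (s), > 0.
#' @param fs_hz Sampling rate; default 1017.3 (the acquisition rate).
#' @param bleach_tau_s Length-2 bleach time constants (s), signal then
#'   isosbestic channel.
#' @param bleach_level Length-2 initial fluorescence levels (a.u.).
#' @param motion_sd Stationary SD of the shared motion artifact (a.u.).
#' @param motion_tau_s Motion time constant (s).
#' @param noise_sd Length-2 white measurement-noise SD (a.u.) per channel.
#' @param event_times_s Event onset times, all within `[0, duration_s)`.
#' @param kernel_kind `"none"`, `"pause"` (negative transient) or
#'   `"excitation"` (positive transient).
#' @param kernel_amplitude_pct Peak transient amplitude in delta-F/F0 %;
#'   its sign must agree with `kernel_kind` (<= 0 for pause, >= 0 for
#'   excitation, 0 for none).
#' @param kernel_rise_s,kernel_decay_s Rise and decay time constants (s)
#'   of the difference-of-exponentials transient; decay must exceed rise.
#' @param coupling_405 Gain of the shared motion artifact into the
#'   isosbestic channel (1 = fully shared).
#' @param seed Integer RNG seed; identical configs give bit-identical
#'   sessions.
#' @return A validated `photo_sim_config` list.
#' @export
photo_sim_config <- function(duration_s,
                             fs_hz = 1017.3,
                             bleach_tau_s = c(3600, 3600),
                             bleach_level = c(2, 1.5),
                             motion_sd = 0.02,
                             motion_tau_s = 10,
                             noise_sd = c(0.01, 0.01),
                             event_times_s = numeric(),
                             kernel_kind = c("none", "pause", "excitation"),
                             kernel_amplitude_pct = 0,
                             kernel_rise_s = 0.5,
                             kernel_decay_s = 2,
                             coupling_405 = 0.75,
                             seed = 1L) {
  kernel_kind <- match.arg(kernel_kind)
  check_number(duration_s, "duration_s", lower = 0, allow_equal_lower = FALSE)
  check_number(fs_hz, "fs_hz", lower = 0, allow_equal_lower = FALSE)
  if (length(bleach_tau_s) == 1L) bleach_tau_s <- rep(bleach_tau_s, 2L)
  if (length(bleach_level) == 1L) bleach_level <- rep(bleach_level, 2L)
  if (length(noise_sd) == 1L) noise_sd <- rep(noise_sd, 2L)
  if (any(bleach_tau_s <= 0)) stop_field("bleach_tau_s", "must be positive")
  if (any(bleach_level <= 0)) stop_field("bleach_level", "must be positive")
  check_number(motion_sd, "motion_sd", lower = 0)
  check_number(motion_tau_s, "motion_tau_s", lower = 0,
               allow_equal_lower = FALSE)
  if (any(noise_sd < 0)) stop_field("noise_sd", "must be non-negative")
  if (length(event_times_s) &&
      (any(event_times_s < 0) || any(event_times_s >= duration_s))) {
    stop_field("event_times_s", "all events must lie in [0, duration_s)")
  }
  check_number(kernel_amplitude_pct, "kernel_amplitude_pct")
  if (kernel_kind == "pause" && kernel_amplitude_pct > 0) {
    stop_field("kernel_amplitude_pct", "must be <= 0 for a pause kernel")
  }
  if (kernel_kind == "excitation" && kernel_amplitude_pct < 0) {
    stop_field("kernel_amplitude_pct", "must be >= 0 for an excitation kernel")
  }
  if (kernel_kind == "none" && kernel_amplitude_pct != 0) {
    stop_field("kernel_amplitude_pct", "must be 0 when kernel_kind is 'none'")
  }
  check_number(kernel_rise_s, "kernel_rise_s", lower = 0,
               allow_equal_lower = FALSE)
  if (kernel_decay_s <= kernel_rise_s) {
    stop_field("kernel_decay_s", "must exceed kernel_rise_s")
  }
  check_number(coupling_405, "coupling_405")
  structure(list(duration_s = duration_s, fs_hz = fs_hz,
                 bleach_tau_s = bleach_tau_s, bleach_level = bleach_level,
                 motion_sd = motion_sd, motion_tau_s = motion_tau_s,
                 noise_sd = noise_sd,
                 event_times_s = sort(as.numeric(event_times_s)),
                 kernel_kind = kernel_kind,
                 kernel_amplitude_pct = kernel_amplitude_pct,
                 kernel_rise_s = kernel_rise_s,
                 kernel_decay_s = kernel_decay_s,
                 coupling_405 = coupling_405,
                 seed = as.integer(seed)),
            class = "photo_sim_config")
}

#' Unit-peak calcium transient kernel
#'
#' Difference of exponentials `exp(-t/decay) - exp(-t/rise)` for `t >= 0`
#' (0 before onset), normalized so its analytic peak — reached at
#' `t* = rise * decay / (decay - rise) * log(decay / rise)` — equals 1.
#'
#' @param t Times relative to onset (s).
#' @param rise_s,decay_s Time constants (s), `decay_s > rise_s > 0`.
#' @return Kernel values in `[0, 1]`.
#' @export
transient_kernel <- function(t, rise_s, decay_s) {
  if (decay_s <= rise_s || rise_s <= 0) {
    stop_field("decay_s", "requires decay_s > rise_s > 0")
  }
  t_peak <- rise_s * decay_s / (decay_s - rise_s) * log(decay_s / rise_s)
  peak <- exp(-t_peak / decay_s) - exp(-t_peak / rise_s)
  k <- ifelse(t >= 0, exp(-t / decay_s) - exp(-t / rise_s), 0)
  k / peak
}

# Stationary Ornstein-Uhlenbeck sample path on a uniform grid via the
# exact AR(1) discretization (reference implementation; the session
# simulator uses the compiled single-pass equivalent).
ou_process <- function(n, sd, tau_s, fs_hz) {
  if (sd == 0) return(numeric(n))
  a <- exp(-1 / (tau_s * fs_hz))
  innov <- stats::rnorm(n, sd = sd * sqrt(1 - a^2))
  x0 <- stats::rnorm(1L, sd = sd)
  as.numeric(stats::filter(innov, a, method = "recursive", init = x0))
}

#' Simulate a dual-channel photometry session with known ground truth
#'
#' Signal channel: `bleach_s(t) * (1 + dff_true(t)/100) + motion(t) +
#' noise`; isosbestic channel: `bleach_i(t) + coupling_405 * motion(t) +
#' noise`. Event transients are injected into `dff_true` at the configured
#' onsets using [transient_kernel()].
#'
#' @param cfg A [photo_sim_config()].
#' @return List with `session` (a [photometry_session()]) and `truth`
#'   (list: `true_dff_pct`, `event_amplitude_pct`, `motion`, `bleach`
#'   two-column matrix).
#' @export
simulate_photometry_session <- function(cfg) {
  stopifnot(inherits(cfg, "photo_sim_config"))
  n <- floor(cfg$duration_s * cfg$fs_hz)
  t <- (seq_len(n) - 1) / cfg$fs_hz

  dff <- numeric(n)
  amp <- cfg$kernel_amplitude_pct
  if (cfg$kernel_kind != "none" && amp != 0 && length(cfg$event_times_s)) {
    span <- cfg$kernel_decay_s * 12   # beyond this the kernel is ~e-12
    for (ev in cfg$event_times_s) {
      i1 <- max(1L, floor(ev * cfg$fs_hz) + 1L)
      i2 <- min(n, ceiling((ev + span) * cfg$fs_hz))
      idx <- i1:i2
      dff[idx] <- dff[idx] +
        amp * transient_kernel(t[idx] - ev, cfg$kernel_rise_s,
                               cfg$kernel_decay_s)
    }
  }

  sim <- withr::with_seed(cfg$seed, {
    sim_channels_cpp(n, 1 / cfg$fs_hz, cfg$bleach_level, cfg$bleach_tau_s,
                     cfg$motion_sd, cfg$motion_tau_s, cfg$noise_sd,
                     cfg$coupling_405, dff)
  })

  events <- if (length(cfg$event_times_s)) {
    data.frame(time_s = cfg$event_times_s,
               kind = rep(cfg$kernel_kind, length(cfg$event_times_s)),
               trial_id = seq_along(cfg$event_times_s))
  } else NULL

  session <- new_photometry_session(t, sim$f465, sim$f405, cfg$fs_hz,
                                    normalize_events(events))
  truth <- list(true_dff_pct = dff,
                event_amplitude_pct = rep(amp, length(cfg$event_times_s)),
                motion = sim$motion,
                bleach = list(signal = sim$bleach_s, iso = sim$bleach_i))
  list(session = session, truth = truth)
}
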