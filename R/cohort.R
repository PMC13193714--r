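# Cohort-level drivers: simulate a group of animals, run the full
# event-locked pipeline, and extract the paired epoch contrast. These are
# the units the calibration studies (type-I error, parameter recovery,
# motion-correction efficacy, opto classifier) are built from.

#' Simulate one animal's event-locked photometry session
#'
#' Event onsets start after the trimmed 3-min baseline (plus the 10 s
#' pre-event window) and are separated by uniform ITIs. Animals are not
#' clones: expression level and photobleaching rate vary between subjects,
#' so the fluorescence levels and per-channel bleach time constants are
#' drawn per animal as log-normal jitter around the configured values
#' (`tau_jitter_sdlog`, `level_jitter_sdlog`). Bleach-rate differences
#' between the two channels therefore vary in size and sign across a
#' cohort, as they do across real implants.
#'
#' @param n_events Number of events.
#' @param kernel_kind,kernel_amplitude_pct Transient shape and peak
#'   amplitude (see [photo_sim_config()]).
#' @param iti_range_s Uniform ITI bounds (s), default 30-50.
#' @param noise_sd,motion_sd,coupling_405 Noise/artifact levels passed to
#'   the simulator.
#' @param bleach_tau_s,bleach_level Cohort-typical values jittered per
#'   animal.
#' @param tau_jitter_sdlog,level_jitter_sdlog Log-normal jitter SDs.
#' @param seed Integer seed.
#' @param ... Further arguments to [photo_sim_config()].
#' @return As [simulate_photometry_session()].
#' @export
simulate_event_session <- function(n_events = 10,
                                   kernel_kind = "none",
                                   kernel_amplitude_pct = 0,
                                   iti_range_s = c(30, 50),
                                   noise_sd = c(0.01, 0.01),
                                   motion_sd = 0.02,
                                   coupling_405 = 0.75,
                                   bleach_tau_s = c(3600, 3600),
                                   bleach_level = c(2, 1.5),
                                   tau_jitter_sdlog = 0.2,
                                   level_jitter_sdlog = 0.1,
                                   seed = 1L, ...) {
  drawn <- withr::with_seed(derive_seed(seed, 1L), {
    list(events = 190 + c(0, cumsum(stats::runif(n_events - 1L,
                                                 iti_range_s[1],
                                                 iti_range_s[2]))),
         tau = bleach_tau_s * exp(stats::rnorm(2L, sd = tau_jitter_sdlog)),
         level = bleach_level * exp(stats::rnorm(2L, sd = level_jitter_sdlog)))
  })
  duration <- max(drawn$events) + 30
  cfg <- photo_sim_config(duration_s = duration,
                          event_times_s = drawn$events,
                          kernel_kind = kernel_kind,
                          kernel_amplitude_pct = kernel_amplitude_pct,
                          noise_sd = noise_sd,
                          motion_sd = motion_sd,
                          coupling_405 = coupling_405,
                          bleach_tau_s = drawn$tau,
                          bleach_level = drawn$level,
                          seed = derive_seed(seed, 2L), ...)
  simulate_photometry_session(cfg)
}

#' Run the event-locked pipeline for a cohort and extract the contrast
#'
#' Simulates `n_animals` independent sessions, preprocesses each
#' (downsample, low-pass, trim, per-event isosbestic fit, delta-F/F0),
#' stacks and baseline-corrects the trials, computes per-animal epoch
#' metrics and returns the paired baseline-vs-event sample together with
#' its paired t-test.
#'
#' @param n_animals Animals in the cohort.
#' @param statistic Epoch statistic, `"peak_min"` for pause responses,
#'   `"peak_max"` for excitations.
#' @param epochs An [epoch_definition()].
#' @param seed Cohort seed; per-animal seeds are derived from it.
#' @param window,baseline Processing windows (s).
#' @param ... Passed to [simulate_event_session()].
#' @return List: `pairs` ([paired_sample()]), `test` (`stat_result`),
#'   `metrics`, `trials` (the baseline-corrected [align_trials()] object).
#' @export
run_cohort_contrast <- function(n_animals = 8,
                                statistic = "peak_min",
                                epochs = epoch_definition(),
                                seed = 1L,
                                window = c(-10, 20),
                                baseline = c(-10, -1),
                                ...) {
  windows <- vector("list", n_animals)
  names(windows) <- sprintf("animal%02d", seq_len(n_animals))
  for (i in seq_len(n_animals)) {
    sim <- simulate_event_session(seed = derive_seed(seed, 100 + i), ...)
    windows[[i]] <- preprocess_around_events(sim$session, window = window)
  }
  trials <- baseline_correct(align_trials(windows), window = baseline)
  metrics <- epoch_metrics(trials, epochs)
  pairs <- epoch_contrast(metrics, statistic)
  list(pairs = pairs, test = paired_t(pairs), metrics = metrics,
       trials = trials)
}

#' Type-I error of the epoch-contrast pipeline under the null
#'
#' Runs `n_cohorts` independent no-transient cohorts through the full
#' pipeline and reports the fraction whose paired t-test on epoch minima
#' rejects at `alpha`. Well-calibrated behavior is a rejection rate near
#' `alpha`.
#'
#' @param n_cohorts Number of cohorts (default 500).
#' @param n_animals,n_events Cohort composition (defaults 8 and 10).
#' @param alpha Significance level (default 0.05).
#' @param seed Base seed.
#' @param ... Passed to [run_cohort_contrast()].
#' @return List: `rejection_rate`, `p_values`.
#' @export
null_calibration <- function(n_cohorts = 500, n_animals = 8, n_events = 10,
                             alpha = 0.05, seed = 1L, ...) {
  p <- vapply(seq_len(n_cohorts), function(k) {
    run_cohort_contrast(n_animals = n_animals, n_events = n_events,
                        kernel_kind = "none", kernel_amplitude_pct = 0,
                        statistic = "peak_min",
                        seed = derive_seed(seed, 10000 + k), ...)$test$p_raw
  }, numeric(1))
  list(rejection_rate = mean(p < alpha), p_values = p)
}

#' Recovery of a known pause amplitude across seeded cohorts
#'
#' Simulates cohorts with a pause transient of known amplitude and
#' reports, per cohort, the mean event-epoch minimum across animals and
#' the paired-contrast p-value; summarizes the median recovered minimum
#' and the fraction of cohorts detecting the pause at `alpha`.
#'
#' @param n_cohorts Number of cohorts (default 50).
#' @param amplitude_pct True pause amplitude (default -3).
#' @param n_animals,n_events Cohort composition.
#' @param alpha Detection level.
#' @param seed Base seed.
#' @param ... Passed to [run_cohort_contrast()] (e.g. `noise_sd`).
#' @return List: `median_recovered_min`, `detect_rate`, `recovered`, `p_values`.
#' @export
pause_recovery <- function(n_cohorts = 50, amplitude_pct = -3,
                           n_animals = 8, n_events = 10, alpha = 0.05,
                           seed = 1L, ...) {
  rec <- numeric(n_cohorts)
  p <- numeric(n_cohorts)
  for (k in seq_len(n_cohorts)) {
    res <- run_cohort_contrast(n_animals = n_animals, n_events = n_events,
                               kernel_kind = "pause",
                               kernel_amplitude_pct = amplitude_pct,
                               statistic = "peak_min",
                               seed = derive_seed(seed, 20000 + k), ...)
    ev <- res$metrics[res$metrics$epoch == "event", ]
    rec[k] <- mean(ev$peak_min)
    p[k] <- res$test$p_raw
  }
  list(median_recovered_min = stats::median(rec),
       detect_rate = mean(p < alpha), recovered = rec, p_values = p)
}

#' Efficacy of isosbestic motion correction on signal-free data
#'
#' Simulates a transient-free session with a strong shared motion
#' artifact, preprocesses it twice — with the isosbestic fit and with a
#' window-mean baseline — and returns the ratio of the two per-event
#' delta-F/F0 RMS values (mean-baseline RMS over isosbestic RMS; larger
#' means the regression removed more artifact).
#'
#' @param n_events Events per session.
#' @param motion_sd Shared-artifact SD (a.u.); default 0.05 against a
#'   signal-channel level of 2 a.u.
#' @param noise_sd Per-channel measurement noise (a.u.).
#' @param seed Integer seed.
#' @return List: `rms_ratio`, `rms_isosbestic`, `rms_window_mean`.
#' @export
motion_correction_efficacy <- function(n_events = 10, motion_sd = 0.05,
                                       noise_sd = c(0.002, 0.002),
                                       seed = 1L) {
  sim <- simulate_event_session(n_events = n_events, kernel_kind = "none",
                                noise_sd = noise_sd, motion_sd = motion_sd,
                                coupling_405 = 1, seed = seed)
  rms_of <- function(mode) {
    w <- preprocess_around_events(sim$session, baseline_mode = mode)
    sqrt(mean(unlist(lapply(w, function(x) x$dff_pct))^2))
  }
  iso <- rms_of("isosbestic")
  wm <- rms_of("window_mean")
  list(rms_ratio = wm / iso, rms_isosbestic = iso, rms_window_mean = wm)
}

#' Inhibition-classification rate of the opto lick analysis
#'
#' Simulates free-licking block sessions at a given laser suppression
#' factor and reports the fraction of seeds classified as showing
#' consumption inhibition (non-opto minus opto mean rate > 0). At
#' suppression 1 (null) the rate should sit near 0.5; at 0.5 near 1.
#'
#' @param n_seeds Number of simulated sessions.
#' @param suppression_factor Laser-on lick-rate multiplier in `(0, 1]`.
#' @param lick_rate_hz Baseline lick rate (default 2).
#' @param protocol Block design (see [opto_block_plan()]).
#' @param seed Base seed.
#' @return List: `inhibition_rate`, `deltas`.
#' @export
opto_classification_rate <- function(n_seeds = 100, suppression_factor = 0.5,
                                     lick_rate_hz = 2,
                                     protocol = "five_block_5min",
                                     seed = 1L) {
  deltas <- vapply(seq_len(n_seeds), function(k) {
    cfg <- behavior_sim_config(task = "opto_licking",
                               lick_rate_hz = lick_rate_hz,
                               block_plan = opto_block_plan(protocol),
                               suppression_factor = suppression_factor,
                               seed = derive_seed(seed, 30000 + k))
    ses <- simulate_behavior_session(cfg)
    epoch_type_means(licks_per_block(ses$blocks, ses$lick_times_s))$delta
  }, numeric(1))
  list(inhibition_rate = mean(deltas > 0), deltas = deltas)
}
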