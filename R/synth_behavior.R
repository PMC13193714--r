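#' Configuration for a simulated behavioral session
#'
#' Covers the five task variants: unpredicted reward (10 s access windows
#' at uniform random ITIs), unpredicted shock and tail lift (event times
#' only), free-licking optogenetic blocks (homogeneous Poisson lick trains
#' whose rate is multiplied by `suppression_factor` while the laser is
#' on), and the two-chamber real-time place-preference assay (continuous-
#' time two-state chamber dynamics with per-chamber exit rates and a 10 Hz
#' position stream).
#'
#' @param task One of `"reward"`, `"shock"`, `"tail_lift"`,
#'   `"opto_licking"`, `"rtppa"`.
#' @param n_trials Number of trials/events (reward: default 30; shock:
#'   10; tail lift: 5).
#' @param reward_window_s Reward accessibility (s), default 10.
#' @param iti_range_s `(lo, hi)` uniform ITI bounds (s): reward testing
#'   30-50, shock 40-80, tail lift 300.
#' @param start_offset_s Time of the first trial onset (s); default 190
#'   leaves room for the 3-min baseline the photometry pipeline trims.
#' @param lick_rate_hz Poisson lick rate during reward access or
#'   free-licking blocks (default 2).
#' @param p_engage Probability a reward trial is attended (default 0.6,
#'   matching roughly half to two-thirds of trials collected).
#' @param block_plan Data frame `duration_s`, `laser_on` for
#'   `opto_licking`; default the five 5-min on/off/on/off/on design.
#'   `opto_block_plan()` builds the two standard designs.
#' @param suppression_factor Multiplicative lick-rate factor in `(0, 1]`
#'   during laser-on blocks.
#' @param duration_s Session length for `rtppa` (default 900 s = 15 min).
#' @param chamber_exit_rates Named exits/s for chambers A and B (rtppa);
#'   stimulation-induced avoidance is expressed as a higher exit rate from
#'   the paired chamber.
#' @param position_fs_hz Position sampling rate (rtppa), default 10.
#' @param box_size_cm Side of each square chamber (rtppa), default 30.
#' @param seed Integer RNG seed.
#' @return A validated `behavior_sim_config` list.
#' @export
behavior_sim_config <- function(task = c("reward", "shock", "tail_lift",
                                         "opto_licking", "rtppa"),
                                n_trials = NULL,
                                reward_window_s = 10,
                                iti_range_s = NULL,
                                start_offset_s = 190,
                                lick_rate_hz = 2,
                                p_engage = 0.6,
                                block_plan = NULL,
                                suppression_factor = 1,
                                duration_s = 900,
                                chamber_exit_rates = c(A = 1 / 30, B = 1 / 30),
                                position_fs_hz = 10,
                                box_size_cm = 30,
                                seed = 1L) {
  task <- match.arg(task)
  if (is.null(n_trials)) {
    n_trials <- switch(task, reward = 30L, shock = 10L, tail_lift = 5L, 0L)
  }
  if (is.null(iti_range_s)) {
    iti_range_s <- switch(task,
                          reward = c(30, 50),
                          shock = c(40, 80),
                          tail_lift = c(300, 300),
                          c(0, 0))
  }
  if (iti_range_s[1] > iti_range_s[2]) {
    stop_field("iti_range_s", "lo must be <= hi")
  }
  if (task == "reward" && iti_range_s[1] < reward_window_s) {
    stop_field("iti_range_s", "ITIs shorter than the reward window would overlap trials")
  }
  check_number(p_engage, "p_engage", lower = 0, upper = 1)
  check_number(suppression_factor, "suppression_factor", lower = 0, upper = 1,
               allow_equal_lower = FALSE)
  check_number(lick_rate_hz, "lick_rate_hz", lower = 0)
  if (task == "opto_licking") {
    if (is.null(block_plan)) block_plan <- opto_block_plan("five_block_5min")
    stopifnot(is.data.frame(block_plan),
              all(c("duration_s", "laser_on") %in% names(block_plan)))
    if (any(block_plan$duration_s <= 0)) {
      stop_field("block_plan", "block durations must be positive")
    }
  } else if (!is.null(block_plan)) {
    stop_field("block_plan", sprintf("not used by task '%s'", task))
  }
  if (any(chamber_exit_rates <= 0)) {
    stop_field("chamber_exit_rates", "exit rates must be positive")
  }
  structure(list(task = task, n_trials = as.integer(n_trials),
                 reward_window_s = reward_window_s,
                 iti_range_s = iti_range_s, start_offset_s = start_offset_s,
                 lick_rate_hz = lick_rate_hz, p_engage = p_engage,
                 block_plan = block_plan,
                 suppression_factor = suppression_factor,
                 duration_s = duration_s,
                 chamber_exit_rates = chamber_exit_rates,
                 position_fs_hz = position_fs_hz,
                 box_size_cm = box_size_cm,
                 seed = as.integer(seed)),
            class = "behavior_sim_config")
}

#' Standard optogenetic block designs
#'
#' `"three_block_8min"`: 8-min blocks, laser during the middle block
#' (off/on/off). `"five_block_5min"`: 5-min blocks, laser during blocks
#' 1, 3 and 5 (on/off/on/off/on).
#'
#' @param protocol Design name.
#' @return Data frame `duration_s`, `laser_on`.
#' @export
opto_block_plan <- function(protocol = c("five_block_5min",
                                         "three_block_8min")) {
  protocol <- match.arg(protocol)
  if (protocol == "three_block_8min") {
    data.frame(duration_s = rep(480, 3), laser_on = c(FALSE, TRUE, FALSE))
  } else {
    data.frame(duration_s = rep(300, 5),
               laser_on = c(TRUE, FALSE, TRUE, FALSE, TRUE))
  }
}

# Poisson process event times on [a, b) at the given rate.
poisson_times <- function(a, b, rate_hz) {
  if (rate_hz <= 0 || b <= a) return(numeric())
  k <- stats::rpois(1L, rate_hz * (b - a))
  sort(stats::runif(k, a, b))
}

#' Simulate a behavioral session
#'
#' Dispatches on `cfg$task`; identical config (including seed) gives
#' bit-identical output.
#'
#' @param cfg A [behavior_sim_config()].
#' @return A task-specific list:
#' \describe{
#'   \item{reward}{`trial_onsets_s`, `lick_times_s`, `engaged`,
#'     `reward_window_s`.}
#'   \item{shock/tail_lift}{`event_times_s`.}
#'   \item{opto_licking}{`blocks` (`start_s`, `end_s`, `laser_on`),
#'     `lick_times_s`.}
#'   \item{rtppa}{`positions` (`t_s`, `x_cm`, `y_cm`, `chamber`),
#'     `transitions_s`.}
#' }
#' @export
simulate_behavior_session <- function(cfg) {
  stopifnot(inherits(cfg, "behavior_sim_config"))
  withr::with_seed(cfg$seed, switch(
    cfg$task,
    reward = sim_reward(cfg),
    shock = sim_events_only(cfg),
    tail_lift = sim_events_only(cfg),
    opto_licking = sim_opto(cfg),
    rtppa = sim_rtppa(cfg)))
}

sim_trial_onsets <- function(cfg) {
  itis <- stats::runif(cfg$n_trials - 1L, cfg$iti_range_s[1],
                       cfg$iti_range_s[2])
  cfg$start_offset_s + c(0, cumsum(itis))
}

sim_reward <- function(cfg) {
  onsets <- sim_trial_onsets(cfg)
  engaged <- stats::runif(cfg$n_trials) < cfg$p_engage
  licks <- lapply(which(engaged), function(k) {
    # condition on engagement: at least one lick attempt in the window
    tl <- poisson_times(onsets[k], onsets[k] + cfg$reward_window_s,
                        cfg$lick_rate_hz)
    if (!length(tl)) {
      tl <- stats::runif(1L, onsets[k], onsets[k] + cfg$reward_window_s)
    }
    tl
  })
  list(task = "reward", trial_onsets_s = onsets,
       lick_times_s = sort(unlist(c(licks, list(numeric())))),
       engaged = engaged, reward_window_s = cfg$reward_window_s)
}

sim_events_only <- function(cfg) {
  list(task = cfg$task, event_times_s = sim_trial_onsets(cfg))
}

sim_opto <- function(cfg) {
  ends <- cumsum(cfg$block_plan$duration_s)
  starts <- c(0, utils::head(ends, -1L))
  licks <- lapply(seq_along(starts), function(k) {
    rate <- cfg$lick_rate_hz *
      if (cfg$block_plan$laser_on[k]) cfg$suppression_factor else 1
    poisson_times(starts[k], ends[k], rate)
  })
  list(task = "opto_licking",
       blocks = data.frame(start_s = starts, end_s = ends,
                           laser_on = cfg$block_plan$laser_on),
       lick_times_s = sort(unlist(c(licks, list(numeric())))))
}

sim_rtppa <- function(cfg) {
  # alternating exponential dwell times define the chamber sequence
  chambers <- c("A", "B")
  cur <- sample(chambers, 1L)
  t_now <- 0
  trans <- numeric()
  seq_ch <- cur
  while (t_now < cfg$duration_s) {
    dwell <- stats::rexp(1L, rate = cfg$chamber_exit_rates[[cur]])
    t_now <- t_now + dwell
    if (t_now < cfg$duration_s) {
      trans <- c(trans, t_now)
      cur <- setdiff(chambers, cur)
      seq_ch <- c(seq_ch, cur)
    }
  }
  ts <- seq(0, cfg$duration_s, by = 1 / cfg$position_fs_hz)
  ch_idx <- findInterval(ts, c(0, trans))
  chamber <- seq_ch[ch_idx]
  b <- cfg$box_size_cm
  x <- stats::runif(length(ts), 0, b) + ifelse(chamber == "B", b, 0)
  y <- stats::runif(length(ts), 0, b)
  list(task = "rtppa",
       positions = data.frame(t_s = ts, x_cm = x, y_cm = y,
                              chamber = chamber),
       transitions_s = trans)
}
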