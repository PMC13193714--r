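#' Round a success count to the reported percentage
#'
#' `round_half_up(100 * successes / n_trials)`; accepts fractional success
#' counts (cohort means), e.g. 16.2/30 -> 54, 17.67/30 -> 59,
#' 18.5/30 -> 62.
#'
#' @param successes Successful-trial count (may be a cohort mean).
#' @param n_trials Scheduled trials (> 0).
#' @return Integer percentage.
#' @export
success_percentage <- function(successes, n_trials) {
  check_number(n_trials, "n_trials", lower = 0, allow_equal_lower = FALSE)
  if (any(successes < 0) || any(successes > n_trials)) {
    stop_field("successes", "must lie in [0, n_trials]")
  }
  as.integer(round_half_up(100 * successes / n_trials))
}

#' Score an unpredicted-reward session
#'
#' A trial is successful iff at least one lick falls inside its reward
#' window `[onset, onset + reward_window_s]` (closed at both ends: a lick
#' exactly at window end still counts); the first such lick is the
#' alignment event for photometry. During training, licks outside every
#' window trigger timeout events.
#'
#' @param trial_onsets_s Trial onset times (s); windows must not overlap.
#' @param lick_times_s Lick timestamps (s), sorted.
#' @param reward_window_s Reward accessibility (s), default 10.
#' @param phase `"testing"` (default), `"training"` (adds timeout events)
#'   or `"unrestricted"`.
#' @param timeout_s Timeout applied to out-of-window licks in training.
#' @return List: `outcomes` data frame (`trial_id`, `success`,
#'   `first_lick_s`), `success_count`, `success_pct`, and
#'   `timeout_events_s` (training only).
#' @export
score_trials <- function(trial_onsets_s, lick_times_s, reward_window_s = 10,
                         phase = c("testing", "training", "unrestricted"),
                         timeout_s = 60) {
  phase <- match.arg(phase)
  if (!length(trial_onsets_s)) stop_field("trial_onsets_s", "no trials")
  onsets <- sort(as.numeric(trial_onsets_s))
  if (any(diff(onsets) < reward_window_s)) {
    stop_field("trial_onsets_s", "reward windows overlap")
  }
  licks <- sort(as.numeric(lick_times_s))
  n <- length(onsets)
  first_lick <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    inside <- licks[licks >= onsets[k] & licks <= onsets[k] + reward_window_s]
    if (length(inside)) first_lick[k] <- inside[1]
  }
  success <- !is.na(first_lick)
  out <- list(outcomes = data.frame(trial_id = seq_len(n), success = success,
                                    first_lick_s = first_lick),
              success_count = sum(success),
              success_pct = success_percentage(sum(success), n))
  if (phase == "training") {
    in_any <- vapply(licks, function(l) {
      any(l >= onsets & l <= onsets + reward_window_s)
    }, logical(1))
    out$timeout_events_s <- licks[!in_any]
    out$timeout_s <- timeout_s
  }
  out
}

#' Training progression criteria
#'
#' Reward task: pass when the session reaches 10 (tethering stage) or 12
#' (testing stage) successful trials. Free-licking optogenetic task: pass
#' when the relative difference in lick counts across the last two
#' sessions, `|L1 - L2| / mean(L1, L2)`, is below 0.30.
#'
#' @param x For reward stages, the session's successful-trial count; for
#'   the opto stage, a numeric vector of per-session lick totals (>= 2
#'   sessions).
#' @param stage `"tethering"`, `"testing"` or `"opto_stability"`.
#' @return List: `pass` (logical), `reason` (string).
#' @export
training_criterion <- function(x, stage = c("tethering", "testing",
                                            "opto_stability")) {
  stage <- match.arg(stage)
  if (stage %in% c("tethering", "testing")) {
    need <- if (stage == "tethering") 10 else 12
    check_number(x, "x", lower = 0)
    pass <- x >= need
    return(list(pass = pass,
                reason = sprintf("%d successful trials (need >= %d)", x, need)))
  }
  if (length(x) < 2L) stop_field("x", "needs at least two sessions")
  l <- utils::tail(x, 2L)
  v <- abs(l[1] - l[2]) / mean(l)
  list(pass = v < 0.30,
       reason = sprintf("lick-count variability %.3f (need < 0.30)", v))
}

#' Lick counts and rates per optogenetic block
#'
#' Blocks are half-open `[start, end)`, partitioning the session without
#' double counting; licks outside every block are excluded (their count is
#' reported).
#'
#' @param blocks Data frame with `start_s`, `end_s`, `laser_on`; blocks
#'   must be contiguous and non-overlapping.
#' @param lick_times_s Lick timestamps (s).
#' @return Data frame `block`, `laser_on`, `licks`, `licks_per_min`, with
#'   attribute `"excluded"` = licks outside all blocks.
#' @export
licks_per_block <- function(blocks, lick_times_s) {
  stopifnot(is.data.frame(blocks),
            all(c("start_s", "end_s", "laser_on") %in% names(blocks)))
  blocks <- blocks[order(blocks$start_s), ]
  if (any(blocks$end_s <= blocks$start_s)) {
    stop_field("blocks", "each block must have end > start")
  }
  if (nrow(blocks) > 1L &&
      any(abs(blocks$start_s[-1] - blocks$end_s[-nrow(blocks)]) > 1e-9)) {
    stop_field("blocks", "blocks must be contiguous")
  }
  licks <- as.numeric(lick_times_s)
  counts <- vapply(seq_len(nrow(blocks)), function(k) {
    sum(licks >= blocks$start_s[k] & licks < blocks$end_s[k])
  }, numeric(1))
  out <- data.frame(block = seq_len(nrow(blocks)),
                    laser_on = blocks$laser_on,
                    licks = counts,
                    licks_per_min = counts /
                      ((blocks$end_s - blocks$start_s) / 60))
  attr(out, "excluded") <- length(licks) - sum(counts)
  out
}

#' Opto vs non-opto epoch means and inhibition call
#'
#' Averages the per-block lick rates within each laser state (equivalent
#' to pooling for equal-duration blocks, and the generalization for
#' unequal ones). `delta = mean_nonopto - mean_opto`; a session is
#' classified as showing consumption inhibition iff `delta > 0` (strict).
#'
#' @param block_table A [licks_per_block()] result.
#' @return List: `mean_opto`, `mean_nonopto`, `delta`, `inhibition`.
#' @export
epoch_type_means <- function(block_table) {
  stopifnot(is.data.frame(block_table),
            all(c("laser_on", "licks_per_min") %in% names(block_table)))
  on <- block_table$licks_per_min[block_table$laser_on]
  off <- block_table$licks_per_min[!block_table$laser_on]
  if (!length(on) || !length(off)) {
    stop("need at least one block of each laser state", call. = FALSE)
  }
  mo <- mean(on); mn <- mean(off)
  list(mean_opto = mo, mean_nonopto = mn, delta = mn - mo,
       inhibition = (mn - mo) > 0)
}

#' Occupancy and distance metrics for a two-chamber place-preference session
#'
#' Time is attributed by sample-interval membership (the interval between
#' consecutive samples belongs to the chamber of its first sample);
#' distance is the sum of Euclidean steps, attributed to the chamber where
#' each step starts. The two chamber time fractions always sum to 100%.
#'
#' @param positions Data frame with `t_s`, `x_cm`, `y_cm`, `chamber`
#'   (values `"A"`/`"B"`, every sample assigned).
#' @param stim_side `"A"` or `"B"`.
#' @return List: `pct_time_stim`, `pct_time` (named, both chambers),
#'   `distance_cm` (named, both chambers), `total_time_s`.
#' @export
rtppa_metrics <- function(positions, stim_side = c("A", "B")) {
  stim_side <- match.arg(stim_side)
  stopifnot(is.data.frame(positions),
            all(c("t_s", "x_cm", "y_cm", "chamber") %in% names(positions)))
  if (nrow(positions) < 2L) stop_field("positions", "needs >= 2 samples")
  if (!all(positions$chamber %in% c("A", "B"))) {
    bad <- which(!positions$chamber %in% c("A", "B"))
    stop_field("positions", sprintf("unassignable chamber at rows %s",
                                    paste(utils::head(bad, 5), collapse = ", ")))
  }
  positions <- positions[order(positions$t_s), ]
  n <- nrow(positions)
  dt <- diff(positions$t_s)
  step <- sqrt(diff(positions$x_cm)^2 + diff(positions$y_cm)^2)
  start_ch <- positions$chamber[-n]
  time_ch <- vapply(c(A = "A", B = "B"), function(ch) sum(dt[start_ch == ch]),
                    numeric(1))
  dist_ch <- vapply(c(A = "A", B = "B"), function(ch) sum(step[start_ch == ch]),
                    numeric(1))
  total <- sum(dt)
  pct <- 100 * time_ch / total
  list(pct_time_stim = unname(pct[stim_side]),
       pct_time = pct, distance_cm = dist_ch, total_time_s = total)
}

#' Assign the stimulation side from the habituation-day preference
#'
#' The laser is paired with the chamber the animal preferred on day 1; an
#' exact 50/50 tie is broken toward chamber A with a warning (a case the
#' protocol never produces).
#'
#' @param day1_positions Day-1 position data frame (see [rtppa_metrics()]).
#' @return `"A"` or `"B"`.
#' @export
assign_stim_side <- function(day1_positions) {
  m <- rtppa_metrics(day1_positions, stim_side = "A")
  if (m$pct_time["A"] == m$pct_time["B"]) {
    warning("day-1 preference tied at 50%; assigning chamber A")
    return("A")
  }
  names(which.max(m$pct_time))
}

#' Weir energy expenditure
#'
#' `EE = 3.9 * VO2 + 1.1 * VCO2` (kcal), from volumes of O2 consumed and
#' CO2 produced (L).
#'
#' @param vo2,vco2 Non-negative gas volumes (L).
#' @return Energy expenditure (kcal).
#' @export
weir_ee <- function(vo2, vco2) {
  if (any(vo2 < 0) || any(vco2 < 0)) stop_field("vo2", "volumes must be >= 0")
  3.9 * vo2 + 1.1 * vco2
}

#' Respiratory quotient
#'
#' Ratio of CO2 production to O2 consumption, `VCO2 / VO2`.
#'
#' @param vo2 O2 consumed (L), > 0.
#' @param vco2 CO2 produced (L), >= 0.
#' @return Unitless quotient.
#' @export
rq <- function(vo2, vco2) {
  if (any(vo2 <= 0)) stop_field("vo2", "must be > 0")
  if (any(vco2 < 0)) stop_field("vco2", "must be >= 0")
  vco2 / vo2
}
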