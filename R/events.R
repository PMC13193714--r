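#' Stack per-event delta-F/F0 windows into a trial matrix
#'
#' Assembles windows produced by [preprocess_around_events()] (possibly
#' from several animals) into a trials x samples matrix on the shared
#' relative time grid. Windows whose grids disagree are rejected; events
#' dropped upstream (trim exclusion, recording bounds) are simply absent
#' and their count is carried through.
#'
#' @param windows List of per-event windows, or a named list of such lists
#'   (one element per animal; names become animal ids).
#' @param animal_ids Optional vector of animal ids, one per window,
#'   used when `windows` is a flat list.
#' @return An `aligned_trials` object: `rel_time_s`, `matrix`
#'   (trials x samples), `animal` (one id per row), `dropped`.
#' @export
align_trials <- function(windows, animal_ids = NULL) {
  is_window <- function(w) is.list(w) && !is.null(w$rel_time_s)
  if (length(windows) && !is_window(windows[[1]]) &&
      is.list(windows[[1]]) && length(windows[[1]]) &&
      is_window(windows[[1]][[1]])) {
    # nested: one list of windows per animal
    ids <- names(windows)
    if (is.null(ids)) ids <- as.character(seq_along(windows))
    animal_ids <- rep(ids, vapply(windows, length, integer(1)))
    dropped <- sum(vapply(windows, function(w) {
      d <- attr(w, "dropped"); if (is.null(d)) 0L else d
    }, integer(1)))
    windows <- do.call(c, lapply(windows, unclass))
  } else {
    dropped <- attr(windows, "dropped")
    if (is.null(dropped)) dropped <- 0L
  }
  if (!length(windows)) stop("no event windows to align", call. = FALSE)
  if (is.null(animal_ids)) animal_ids <- rep("1", length(windows))
  rel <- windows[[1]]$rel_time_s
  for (w in windows) {
    if (length(w$rel_time_s) != length(rel) ||
        max(abs(w$rel_time_s - rel)) > 1e-9) {
      stop("event windows do not share a common relative time grid",
           call. = FALSE)
    }
  }
  m <- do.call(rbind, lapply(windows, `[[`, "dff_pct"))
  structure(list(rel_time_s = rel, matrix = m,
                 animal = as.character(animal_ids),
                 dropped = dropped),
            class = "aligned_trials")
}

#' @export
print.aligned_trials <- function(x, ...) {
  cat(sprintf("aligned_trials: %d trials x %d samples, %d animals (%d dropped)\n",
              nrow(x$matrix), ncol(x$matrix), length(unique(x$animal)),
              x$dropped))
  invisible(x)
}

#' Baseline-correct aligned trials
#'
#' Subtracts, per trial, the mean delta-F/F0 over the pre-event baseline
#' window (default -10 to -1 s), so every trial's baseline mean is exactly
#' zero afterwards.
#'
#' @param trials An [align_trials()] result.
#' @param window Baseline window `(start, end)` in relative seconds.
#' @return Corrected `aligned_trials`.
#' @export
baseline_correct <- function(trials, window = c(-10, -1)) {
  stopifnot(inherits(trials, "aligned_trials"))
  sel <- trials$rel_time_s >= window[1] & trials$rel_time_s <= window[2]
  if (!any(sel)) stop_field("window", "baseline window contains no samples")
  bl <- rowMeans(trials$matrix[, sel, drop = FALSE])
  trials$matrix <- trials$matrix - bl
  trials
}

#' Peri-stimulus time histogram with hierarchical averaging
#'
#' Averaging respects the experimental hierarchy: trials are averaged
#' within animal, then animal means are averaged into the group mean, so
#' animals with many trials are not over-weighted. The SEM is taken over
#' the averaging units of the requested level.
#'
#' @param trials An [align_trials()] result.
#' @param level `"trial"` (mean/SEM over trials) or `"animal"` (mean/SEM
#'   over per-animal means; this is the group-level curve).
#' @return Data frame with `rel_time_s`, `mean`, `sem`, `n_units`.
#' @export
psth <- function(trials, level = c("animal", "trial")) {
  stopifnot(inherits(trials, "aligned_trials"))
  level <- match.arg(level)
  if (nrow(trials$matrix) < 1L) stop("no trials", call. = FALSE)
  units <- if (level == "trial") {
    trials$matrix
  } else {
    do.call(rbind, lapply(split(seq_len(nrow(trials$matrix)), trials$animal),
                          function(i) colMeans(trials$matrix[i, , drop = FALSE])))
  }
  n <- nrow(units)
  mu <- colMeans(units)
  sem <- if (n > 1L) apply(units, 2L, stats::sd) / sqrt(n) else rep(0, ncol(units))
  data.frame(rel_time_s = trials$rel_time_s, mean = mu, sem = sem,
             n_units = n)
}

#' Per-animal mean traces (heatmap rows)
#'
#' One row per animal (reward-task convention) obtained by averaging that
#' animal's trials; for per-trial heatmaps (aversive tasks) use
#' `trials$matrix` directly.
#'
#' @param trials An [align_trials()] result.
#' @return Matrix, one row per animal, rownames = animal ids.
#' @export
animal_means <- function(trials) {
  stopifnot(inherits(trials, "aligned_trials"))
  idx <- split(seq_len(nrow(trials$matrix)), trials$animal)
  m <- do.call(rbind, lapply(idx, function(i) {
    colMeans(trials$matrix[i, , drop = FALSE])
  }))
  rownames(m) <- names(idx)
  m
}

#' Epoch definition
#'
#' Baseline and event analysis windows in relative seconds; the standard
#' pair is baseline -6..-1 s and event 0..5 s. Boundaries are closed on
#' both ends.
#'
#' @param baseline,event Length-2 `(start, end)` windows; the baseline
#'   must precede the event window and both must have positive length.
#' @return An `epoch_definition` list.
#' @export
epoch_definition <- function(baseline = c(-6, -1), event = c(0, 5)) {
  if (length(baseline) != 2L || baseline[1] >= baseline[2]) {
    stop_field("baseline", "must be (start, end) with start < end")
  }
  if (length(event) != 2L || event[1] >= event[2]) {
    stop_field("event", "must be (start, end) with start < end")
  }
  if (baseline[2] > event[1]) stop_field("baseline", "must precede event epoch")
  structure(list(baseline = baseline, event = event),
            class = "epoch_definition")
}

epoch_samples <- function(rel_time, win) {
  which(rel_time >= win[1] & rel_time <= win[2])
}

#' Epoch AUC and extrema per animal
#'
#' For each animal's trial-averaged trace and each epoch: trapezoidal area
#' under the curve (% * s), peak maximum and peak minimum over the epoch's
#' samples (timestamps t with start <= t <= end).
#'
#' @param trials An [align_trials()] result (normally baseline-corrected).
#' @param epochs An [epoch_definition()].
#' @param per `"animal"` (default: metrics on trial-averaged traces, one
#'   row per animal and epoch) or `"trial"`.
#' @return Data frame: `unit`, `epoch` (baseline/event), `auc`,
#'   `peak_max`, `peak_min`.
#' @export
epoch_metrics <- function(trials, epochs = epoch_definition(),
                          per = c("animal", "trial")) {
  stopifnot(inherits(trials, "aligned_trials"),
            inherits(epochs, "epoch_definition"))
  per <- match.arg(per)
  traces <- if (per == "animal") animal_means(trials) else {
    m <- trials$matrix
    rownames(m) <- paste0("trial_", seq_len(nrow(m)))
    m
  }
  out <- list()
  for (ep in c("baseline", "event")) {
    idx <- epoch_samples(trials$rel_time_s, epochs[[ep]])
    if (length(idx) < 2L) {
      stop_field("epochs", sprintf("%s epoch contains < 2 samples", ep))
    }
    tt <- trials$rel_time_s[idx]
    out[[ep]] <- data.frame(
      unit = rownames(traces),
      epoch = ep,
      auc = apply(traces[, idx, drop = FALSE], 1L,
                  function(v) pracma::trapz(tt, v)),
      peak_max = apply(traces[, idx, drop = FALSE], 1L, max),
      peak_min = apply(traces[, idx, drop = FALSE], 1L, min),
      row.names = NULL)
  }
  rbind(out$baseline, out$event)
}

#' Baseline-vs-event paired samples for one epoch statistic
#'
#' Extracts, per animal, the (baseline value, event value) pair of the
#' chosen statistic — the input to a paired t-test. The pause response to
#' reward uses `"peak_min"`; shock/tail-lift excitations use `"peak_max"`.
#'
#' @param metrics An [epoch_metrics()] result.
#' @param statistic `"peak_min"`, `"peak_max"` or `"auc"`.
#' @return A [paired_sample()].
#' @export
epoch_contrast <- function(metrics,
                           statistic = c("peak_min", "peak_max", "auc")) {
  statistic <- match.arg(statistic)
  base <- metrics[metrics$epoch == "baseline", ]
  ev <- metrics[metrics$epoch == "event", ]
  if (!setequal(base$unit, ev$unit)) {
    stop("baseline and event epochs cover different units", call. = FALSE)
  }
  ord <- order(base$unit)
  base <- base[ord, ]
  ev <- ev[match(base$unit, ev$unit), ]
  paired_sample(unit = base$unit,
                a = ev[[statistic]],
                b = base[[statistic]])
}
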