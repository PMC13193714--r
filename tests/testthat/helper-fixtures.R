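# Small builders shared across test files.

# A session whose channels are arbitrary functions of time.
make_session <- function(n = 1000, fs = 100,
                         f_signal = function(t) rep(2, length(t)),
                         f_iso = function(t) rep(1.5, length(t)),
                         events = NULL) {
  t <- (seq_len(n) - 1) / fs
  photometry_session(t, f_signal(t), f_iso(t), fs, events)
}

# Aligned trials built directly from a list of rows (one per trial).
make_trials <- function(rows, rel_time, animal = NULL) {
  wins <- lapply(seq_along(rows), function(k) {
    list(rel_time_s = rel_time, dff_pct = rows[[k]],
         event_time_s = 0, trial_id = k)
  })
  if (is.null(animal)) animal <- rep("a1", length(rows))
  align_trials(wins, animal_ids = animal)
}

# Long-format balanced mixed-design data from a cell-mean matrix plus
# iid noise, for ANOVA tests.
make_mixed_data <- function(cell_means, n_per_group, sd = 1, seed = 1) {
  groups <- rownames(cell_means)
  levels_w <- colnames(cell_means)
  withr::with_seed(seed, {
    rows <- list()
    uid <- 0
    for (gi in seq_along(groups)) {
      for (s in seq_len(n_per_group[gi])) {
        uid <- uid + 1
        subj_eff <- rnorm(1, sd = sd)
        for (li in seq_along(levels_w)) {
          rows[[length(rows) + 1]] <- data.frame(
            unit = sprintf("u%03d", uid), group = groups[gi],
            within = levels_w[li],
            value = cell_means[gi, li] + subj_eff + rnorm(1, sd = sd))
        }
      }
    }
    do.call(rbind, rows)
  })
}
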