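test_that("align_trials stacks windows and drops out-of-bounds events", {
  cfg <- photo_sim_config(duration_s = 330, fs_hz = 200,
                          event_times_s = c(100, 220, 325),
                          kernel_kind = "none", seed = 3)
  sim <- simulate_photometry_session(cfg)
  w <- preprocess_around_events(sim$session)
  # event at 100 s excluded by trim; event at 325 s window crosses the end
  expect_length(w, 1L)
  expect_equal(attr(w, "dropped"), 2L)
  tr <- align_trials(w)
  expect_equal(nrow(tr$matrix), 1L)
  expect_equal(tr$dropped, 2L)
  expect_equal(range(tr$rel_time_s), c(-10, 20), tolerance = 0.05)
})

test_that("aligned rows peak where the simulated kernels sit", {
  sim <- simulate_event_session(n_events = 10, kernel_kind = "excitation",
                                kernel_amplitude_pct = 5,
                                noise_sd = c(0.001, 0.001), motion_sd = 0,
                                seed = 12)
  w <- preprocess_around_events(sim$session)
  tr <- baseline_correct(align_trials(w))
  expect_equal(nrow(tr$matrix), 10L)
  peak_times <- tr$rel_time_s[apply(tr$matrix, 1L, which.max)]
  # kernel peak is at ~0.92 s post event; the 1 Hz filter shifts nothing
  expect_true(all(peak_times > 0 & peak_times < 3))
})

test_that("baseline correction zeroes the baseline mean per trial", {
  rel <- seq(-10, 20, by = 0.1)
  rows <- list(rep(5, length(rel)),
               sin(rel) + 2,
               ifelse(rel < 0, 1, 3))
  tr <- baseline_correct(make_trials(rows, rel), window = c(-10, -1))
  sel <- rel >= -10 & rel <= -1
  for (k in 1:3) expect_lt(abs(mean(tr$matrix[k, sel])), 1e-9)
  # constant row becomes exactly zero
  expect_equal(tr$matrix[1, ], rep(0, length(rel)))
  # step trace: hand-computed shift (baseline mean is 1)
  expect_equal(unique(tr$matrix[3, rel >= 0]), 2)
  expect_error(baseline_correct(make_trials(rows, rel), window = c(30, 40)),
               "window")
})

test_that("psth respects the trial -> animal -> group hierarchy", {
  rel <- seq(-1, 1, by = 0.5)
  # animal a: 3 identical trials at 1; animal b: 1 trial at 3
  rows <- list(rep(1, 5), rep(1, 5), rep(1, 5), rep(3, 5))
  tr <- make_trials(rows, rel, animal = c("a", "a", "a", "b"))
  p_animal <- psth(tr, level = "animal")
  expect_equal(p_animal$mean, rep(2, 5))  # (1 + 3) / 2, not trial-weighted
  p_trial <- psth(tr, level = "trial")
  expect_equal(p_trial$mean, rep(1.5, 5))
  # identical rows: SEM 0
  tr_same <- make_trials(rows[1:3], rel, animal = c("a", "b", "c"))
  expect_equal(psth(tr_same, level = "animal")$sem, rep(0, 5))
})

test_that("psth equals a brute-force two-stage average", {
  rel <- seq(-2, 2, by = 0.25)
  withr::with_seed(5, {
    animals <- rep(c("a", "b", "c"), times = c(4, 2, 7))
    rows <- lapply(seq_along(animals), function(i) rnorm(length(rel)))
  })
  tr <- make_trials(rows, rel, animal = animals)
  got <- psth(tr, level = "animal")
  # oracle: explicit nested loops
  per_animal <- list()
  for (a in unique(animals)) {
    rs <- rows[animals == a]
    acc <- rep(0, length(rel))
    for (r in rs) acc <- acc + r
    per_animal[[a]] <- acc / length(rs)
  }
  grand <- rep(0, length(rel))
  for (a in names(per_animal)) grand <- grand + per_animal[[a]]
  grand <- grand / length(per_animal)
  expect_equal(got$mean, grand, tolerance = 1e-12)
  sem <- sapply(seq_along(rel), function(j) {
    vals <- sapply(per_animal, `[[`, j)
    sd(vals) / sqrt(length(vals))
  })
  expect_equal(got$sem, sem, tolerance = 1e-12)
})

test_that("hierarchical psth is invariant to duplicating an animal's trial", {
  rel <- seq(0, 1, by = 0.5)
  rows <- list(c(1, 2, 3), c(3, 2, 1), c(5, 5, 5))
  tr <- make_trials(rows, rel, animal = c("a", "a", "b"))
  tr_dup <- make_trials(c(rows, rows[2]), rel,
                        animal = c("a", "a", "b", "a"))
  expect_false(identical(psth(tr, "animal")$mean, psth(tr_dup, "animal")$mean))
  # duplicating ALL of an animal's trials leaves its mean unchanged
  tr_dup_all <- make_trials(c(rows, rows[1], rows[2]), rel,
                            animal = c("a", "a", "b", "a", "a"))
  expect_equal(psth(tr, "animal")$mean, psth(tr_dup_all, "animal")$mean)
})

test_that("epoch metrics match closed-form areas and extrema", {
  rel <- seq(-10, 20, by = 0.01)
  const <- ifelse(rel >= 0 & rel <= 5, 1, 0)
  ramp <- ifelse(rel >= 0 & rel <= 5, rel * 2 / 5, 0)
  tr <- make_trials(list(const), rel)
  m <- epoch_metrics(tr, epoch_definition(baseline = c(-6, -1),
                                          event = c(0, 5)))
  ev <- m[m$epoch == "event", ]
  expect_equal(ev$auc, 5, tolerance = 1e-9)   # rectangle
  expect_equal(ev$peak_max, 1)
  expect_equal(ev$peak_min, 1)
  tr2 <- make_trials(list(ramp), rel)
  ev2 <- epoch_metrics(tr2)[2, ]
  expect_equal(ev2$auc, 5, tolerance = 1e-9)  # trapezoid exact on affine
  expect_equal(ev2$peak_max, 2)
})

test_that("trapezoidal AUC converges quadratically to a fine-grid oracle", {
  f <- function(t) sin(t) + 0.3 * cos(3 * t)
  oracle_grid <- seq(0, 5, length.out = 2e5 + 1)
  oracle <- pracma::trapz(oracle_grid, f(oracle_grid))
  err_at <- function(dt) {
    rel <- seq(-10, 20, by = dt)
    tr <- make_trials(list(f(rel)), rel)
    ev <- epoch_metrics(tr)[2, ]
    abs(ev$auc - oracle)
  }
  e1 <- err_at(0.1)
  e2 <- err_at(0.05)
  expect_lt(e2, e1)
  expect_equal(e1 / e2, 4, tolerance = 0.3)  # halving dt quarters the error
})

test_that("epoch_contrast pairs animals and tracks the kernel sign", {
  rel <- seq(-10, 20, by = 0.1)
  dip <- function(a) ifelse(rel >= 0 & rel <= 5, -a, 0)
  rows <- list(dip(3), dip(2.5))
  tr <- make_trials(rows, rel, animal = c("a1", "a2"))
  pairs <- epoch_contrast(epoch_metrics(tr), statistic = "peak_min")
  expect_s3_class(pairs, "paired_sample")
  expect_equal(pairs$a, c(-3, -2.5))  # event minima
  expect_equal(pairs$b, c(0, 0))      # baseline minima
  # mirrored excitation case
  rows_up <- lapply(rows, function(r) -r)
  pairs_up <- epoch_contrast(epoch_metrics(make_trials(rows_up, rel,
                                                       animal = c("a1", "a2"))),
                             statistic = "peak_max")
  expect_true(all(pairs_up$a > pairs_up$b))
})

test_that("epoch definitions are validated", {
  expect_error(epoch_definition(baseline = c(-1, -6)), "baseline")
  expect_error(epoch_definition(baseline = c(-2, 1), event = c(0, 5)),
               "baseline")
  expect_error(epoch_definition(event = c(5, 0)), "event")
})
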