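#!/usr/bin/env Rscript
# Optogenetic reward-consumption experiment: five 5-min blocks with the
# laser on during blocks 1, 3 and 5. Three groups are simulated (controls
# with no laser effect, a strongly suppressed "rostral" group, a weakly
# suppressed "caudal" group); lick rates per block feed the mixed
# repeated-measures ANOVA (group x epoch) and Sidak post-hoc contrasts,
# plus the per-animal inhibition classification.

library(nacshell)
dir.create("results", showWarnings = FALSE)

groups <- list(control = list(n = 10, suppression = 1.0),
               rostral = list(n = 13, suppression = 0.55),
               caudal = list(n = 11, suppression = 0.88))

rows <- list()
long <- list()
for (g in names(groups)) {
  for (i in seq_len(groups[[g]]$n)) {
    # animals differ in baseline consumption drive
    base_rate <- withr::with_seed(9000 + 100 * match(g, names(groups)) + i,
                                  2 * exp(rnorm(1, sd = 0.25)))
    cfg <- behavior_sim_config(task = "opto_licking",
                               lick_rate_hz = base_rate,
                               suppression_factor = groups[[g]]$suppression,
                               seed = 1000 * match(g, names(groups)) + i)
    ses <- simulate_behavior_session(cfg)
    tab <- licks_per_block(ses$blocks, ses$lick_times_s)
    em <- epoch_type_means(tab)
    unit <- sprintf("%s_%02d", g, i)
    rows[[unit]] <- data.frame(unit = unit, group = g,
                               mean_opto = em$mean_opto,
                               mean_nonopto = em$mean_nonopto,
                               delta = em$delta,
                               inhibition = em$inhibition)
    long[[paste0(unit, "_on")]] <- data.frame(unit = unit, group = g,
                                              within = "opto",
                                              value = em$mean_opto)
    long[[paste0(unit, "_off")]] <- data.frame(unit = unit, group = g,
                                               within = "nonopto",
                                               value = em$mean_nonopto)
  }
}
per_animal <- do.call(rbind, rows)
write.table(per_animal, "results/02_opto_per_animal.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

fit <- mixed_rm_anova(do.call(rbind, long))
print(fit)
capture.output(print(fit), file = "results/02_opto_anova.txt")

cat("\nSidak post-hoc, opto vs non-opto within each group:\n")
ph <- sidak_posthoc(fit, levels = c("opto", "nonopto"))
for (p in ph) print(p)
capture.output(for (p in ph) print(p),
               file = "results/02_opto_posthoc.txt")

cat("\nFraction of animals classified as inhibited (delta > 0):\n")
inh <- tapply(per_animal$inhibition, per_animal$group, mean)
print(round(100 * inh))
write.table(data.frame(group = names(inh), pct_inhibited = 100 * inh),
            "results/02_opto_inhibition.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
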