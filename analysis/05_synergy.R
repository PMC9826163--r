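#!/usr/bin/env Rscript
# Combined-versus-sum synergy analysis of two co-applied agonists.
#
# Emulates the co-application experiment: each subject's tissue responds
# to agonist 1 alone, agonist 2 alone, and both together, on three
# endpoints (tone, amplitude, frequency). The combined response carries a
# super-additive interaction; the paired combined-vs-sum test should
# declare synergy on every endpoint, while an additive control cohort
# should not.

library(gastromot)

dir.create("results", showWarnings = FALSE)

endpoints <- list(
  # endpoint label; mean individual responses in native units
  tone = list(A = 4.0, B = 3.0, sd = 0.8),       # mN
  amplitude = list(A = 1.5, B = 1.0, sd = 0.4),  # mN
  frequency = list(A = 0.6, B = 0.4, sd = 0.15)  # c.p.m.
)

rows <- list()
for (ep in names(endpoints)) {
  p <- endpoints[[ep]]
  co <- simulate_synergy_cohort(n = 5, mean_A = p$A, mean_B = p$B,
                                interaction = 1.6, sd = p$sd,
                                seed = match(ep, names(endpoints)))
  res <- synergy_test(co$A, co$B, co$combined, co$id)
  null_co <- simulate_synergy_cohort(n = 5, mean_A = p$A, mean_B = p$B,
                                     interaction = 1, sd = p$sd,
                                     seed = 100 + match(ep, names(endpoints)))
  null_res <- synergy_test(null_co$A, null_co$B, null_co$combined, null_co$id)
  rows[[ep]] <- data.frame(endpoint = ep,
                           combined = res$combined_mean,
                           sum_individual = res$sum_mean,
                           excess = res$mean_excess,
                           p_value = res$p_value,
                           synergy = res$synergy,
                           additive_control_p = null_res$p_value,
                           additive_control_synergy = null_res$synergy)
  cat(sprintf("%-9s combined %.2f vs sum %.2f (p = %.3g) -> %s\n",
              ep, res$combined_mean, res$sum_mean, res$p_value,
              if (res$synergy) "synergy" else "additive"))
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/synergy_summary.csv", row.names = FALSE)

stopifnot(all(tab$synergy), !any(tab$additive_control_synergy))
cat("\nSuper-additive cohorts flagged on all endpoints; additive controls not.\n")
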