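#!/usr/bin/env Rscript
# Inter-rater agreement (Bland-Altman) on paired rating tables.
#
# Emulates two observers independently scoring receptor immunofluorescence
# intensity on the same cells: rater 2 re-scores rater 1's cells with
# independent error and no systematic offset. Bias should be ~0 with 95%
# limits of agreement ~ +/- 1.96 x error SD.

library(gastromot)

dir.create("results", showWarnings = FALSE)

set.seed(18)
n_cells <- 18
truth <- rnorm(n_cells, 50, 10)
rater1 <- truth + rnorm(n_cells, 0, 2)
rater2 <- truth + rnorm(n_cells, 0, 2)

res <- bland_altman(rater1, rater2)
print(res)

write.csv(cbind(res$points, rater1 = rater1, rater2 = rater2),
          "results/agreement_points.csv", row.names = FALSE)
summary_tab <- data.frame(bias = res$bias, sd_differences = res$sd_differences,
                          lower_limit = res$limits[["lower"]],
                          upper_limit = res$limits[["upper"]], n = n_cells)
write.csv(summary_tab, "results/agreement_summary.csv", row.names = FALSE)
cat(sprintf("Expected limit half-width 1.96*sqrt(2)*2 = %.2f; observed %.2f\n",
            1.96 * sqrt(2) * 2, (res$limits[["upper"]] - res$limits[["lower"]]) / 2))
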