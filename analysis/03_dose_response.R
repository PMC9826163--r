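#!/usr/bin/env Rscript
# Vasopressin-like concentration-response analysis.
#
# Simulates five-replicate cumulative concentration-response datasets for
# the tone endpoint from the AVP-tone-proximal preset (EC50 3.16e-10 M,
# Emax 7.1 % of the carbachol maximum), fits the Hill equation to each,
# and reports pEC50, Emax, slope and the threshold decade. The fitted
# potency should recover pEC50 ~9.5 with sub-nanomolar thresholds.

library(gastromot)

dir.create("results", showWarnings = FALSE)

hp <- preset("AVP-tone-proximal")
concs <- 10^seq(-12, -5, by = 1)

fits <- lapply(1:5, function(s) {
  crc <- simulate_crc_dataset(hp, concs, n_reps = 5, noise_cv = 0.05, seed = s)
  f <- fit_hill(crc)
  crit <- 2 * sd(crc$response[crc$conc_M == min(crc$conc_M)])
  th <- threshold_concentration(crc, max(crit, 0.2))
  data.frame(dataset = s, pEC50 = f$pEC50, Emax = f$Emax,
             hill_slope = f$hill_slope,
             threshold_low_M = th$lower, threshold_high_M = th$upper)
})
tab <- do.call(rbind, fits)
write.csv(tab, "results/hill_fits_avp_tone.csv", row.names = FALSE)
print(tab, digits = 4)

cat(sprintf("\nMean fitted pEC50 %.2f (generating value %.2f), Emax %.2f%% (true 7.1%%)\n",
            mean(tab$pEC50), -log10(hp$EC50), mean(tab$Emax)))
cat(sprintf("Thresholds fall in the %g-%g M decade(s)\n",
            min(tab$threshold_low_M), max(tab$threshold_high_M)))
cat(sprintf("EC75 for combination experiments: %.3g M\n",
            ec_fraction(hp, 0.75)))
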