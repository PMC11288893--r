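#!/usr/bin/env Rscript
# Condensed-phase protein fraction from DOSY gradient decays: a droplet
# sample emulated at several maturation time points with a growing
# condensed pool, quantified with both estimators (endpoint intensity
# ratio and the constrained two-population Stejskal-Tanner fit).

library(condmat)
dir.create("results", showWarnings = FALSE)

acq <- dosy_acquisition()          # Delta = 50 ms, delta = 10 ms, 2-95% gmax
truth <- data.frame(time_h = c(2, 24, 48, 96),
                    condensed = c(0.35, 0.45, 0.55, 0.60))

rows <- lapply(seq_len(nrow(truth)), function(i) {
  d <- make_dosy_decays(condensed_fraction = truth$condensed[i],
                        snr = 100, seed = 300 + i)
  cv <- d$curves[[1]]
  cv$time_stamp <- truth$time_h[i]
  ep <- endpoint_fractions(cv)
  ft <- fit_two_populations(cv, acq)
  data.frame(time_h = truth$time_h[i], true_condensed = truth$condensed[i],
             endpoint_condensed = ep$condensed,
             fit_condensed = ft$fractions$condensed,
             fit_D_fast = ft$fit$D1, fit_D_slow = ft$fit$D2)
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/dosy_fractions.csv", row.names = FALSE)

cat("condensed fraction vs maturation time (SNR 100):\n")
print(round(tab[, 1:4], 4), row.names = FALSE)
cat(sprintf(
  "max |fit - truth| = %.4f; dilute-pool D ~ %.1e m^2/s (condensed pool near-immobile on this gradient range)\n",
  max(abs(tab$fit_condensed - tab$true_condensed)), mean(tab$fit_D_fast)))
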