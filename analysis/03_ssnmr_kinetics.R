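#!/usr/bin/env Rscript
# Real-time solid-state NMR maturation kinetics: CP build-up and INEPT
# decay series for a droplet (biphasic) and a bulk (monophasic) sample,
# integrated per spectral region, normalized to the 48-h spectrum and
# fitted linearly.  The biphasic sample is emulated with the faster
# build-up; the slope ratio quantifies how much faster the droplet
# sample matures.

library(condmat)
dir.create("results", showWarnings = FALSE)

times_h <- seq(4, 48, length.out = 6)
samples <- list(biphasic = 0.25, monophasic = 0.14)  # CP slopes, 1/day

all_slopes <- list()
for (nm in names(samples)) {
  gen <- make_nmr_timeseries(times_hours = times_h, cp_slope = samples[[nm]],
                             inept_slope = -0.06, mult_noise = 0.1,
                             additive_noise = 0, seed = 11)
  carbon_regions <- subset(default_regions(), label != "imino")
  sl_cp <- region_kinetics(gen$cp, carbon_regions)
  sl_in <- region_kinetics(gen$inept, carbon_regions)
  all_slopes[[nm]] <- sl_cp
  tab <- data.frame(
    region = names(sl_cp),
    cp_slope = vapply(sl_cp, function(s) s$slope, numeric(1)),
    cp_se = vapply(sl_cp, function(s) s$se, numeric(1)),
    inept_slope = vapply(sl_in, function(s) s$slope, numeric(1)))
  write.csv(tab, file.path("results", paste0("slopes_", nm, ".csv")),
            row.names = FALSE)
  cat(sprintf("%-11s mean CP slope %+0.3f/day, mean INEPT slope %+0.3f/day\n",
              nm, mean(tab$cp_slope), mean(tab$inept_slope)))
}

cmp <- compare_rates(all_slopes$biphasic, all_slopes$monophasic)
write.csv(cmp, "results/rate_comparison.csv", row.names = FALSE)
cat("biphasic/monophasic CP slope ratios:\n")
print(round(cmp[, c("slope_a", "slope_b", "ratio", "ratio_se")], 3),
      row.names = FALSE)
cat(sprintf("droplet sample matures %.1fx faster on average\n",
            mean(cmp$ratio, na.rm = TRUE)))
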