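#!/usr/bin/env Rscript
# Generate the synthetic batch-fermentation suite standing in for the
# study's bioreactor data: the four flask-scale regimes (glucose C/N 80,
# glucose C/N 8.8, xylose C/N 80, glucose+xylose C/N 80), each with and
# without 150 mM EG, with measurement noise, under a fixed seed.

suppressMessages(library(egflux))

seed <- 20240901L
paths <- write_fixture_suite("results/fermentations", seed = seed)
cat("wrote", length(paths), "time-series fixtures (with ground-truth JSON) under results/fermentations/\n")
cat("master seed:", seed, "\n")

for (p in paths) {
  s <- read_timeseries_csv(p)
  cat(sprintf("  %-22s final OD %5.1f, GA %5.2f g/L, residual EG %5.2f g/L\n",
              basename(p), tail(s$od, 1), tail(s$ga_g_l, 1),
              tail(s$eg_g_l, 1)))
}
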