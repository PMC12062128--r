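#!/usr/bin/env Rscript
# Quantitative physiology of the simulated runs: per-phase growth rates,
# specific rates, GA-on-EG yields, RQ and carbon closure, plus the media
# stoichiometry table (molar C/N ratios, mM <-> g/L conversions, NH4+ from
# ammonium sulfate). Requires 02_simulate.R to have run.

suppressMessages(library(egflux))
dir.create("results/physiology", recursive = TRUE, showWarnings = FALSE)

## media stoichiometry of the study's recipes
media <- data.frame(
  medium = c("glc 10 g/L, AS 0.275 g/L", "glc 20 g/L, AS 5 g/L",
             "glc+xyl 10+10 g/L, AS 0.550 g/L"),
  cn_molar = c(cn_ratio_molar(c(glucose = 10), 0.275),
               cn_ratio_molar(c(glucose = 20), 5),
               cn_ratio_molar(c(glucose = 10, xylose = 10), 0.550)))
write.table(media, "results/physiology/media_cn.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("molar C/N of the media:\n")
print(media, row.names = FALSE)
cat(sprintf("150 mM EG = %.1f g/L; 75 mM EG = %.1f g/L; 275 mg/L AS carries %.0f mg/L NH4+\n",
            mm_to_gl(150, MOLAR_MASS[["eg"]]), mm_to_gl(75, MOLAR_MASS[["eg"]]),
            ammonium_from_as(275)))

## published-value arithmetic: carbon closure and RQ
cat(sprintf("\ncarbon closure, control: %.1f%%; with EG: %.1f%%\n",
            100 * carbon_balance(0.562, 0.366),
            100 * carbon_balance(0.554, 0.377)))
cat(sprintf("RQ, EG condition: %.2f; control: %.2f\n",
            respiratory_quotient(30.63, 22.57),
            respiratory_quotient(29.88, 23.32)))

## per-fixture physiology summaries
fixtures <- list.files("results/fermentations", pattern = "\\.csv$",
                       full.names = TRUE)
if (length(fixtures) == 0)
  stop("no fixtures found; run analysis/02_simulate.R first")
for (p in fixtures) {
  s <- read_timeseries_csv(p)
  ps <- suppressWarnings(summarize_physiology(s))
  stem <- sub("\\.csv$", "", basename(p))
  write_summary_json(ps, file.path("results/physiology",
                                   paste0(stem, "_summary.json")),
                     provenance = list(fixture = basename(p)))
  mu_e <- if (!is.null(ps$mu_exp)) ps$mu_exp$mu else NA
  mu_n <- if (!is.null(ps$mu_nlim)) ps$mu_nlim$mu else NA
  yge <- if (!is.null(ps$yields$y_ga_eg)) ps$yields$y_ga_eg$mol else NA
  cat(sprintf("  %-22s mu_exp %5.3f  mu_nlim %6.4f  Y_GA/EG %5.2f  RQ %5.2f  closure %5.3f\n",
              stem, mu_e, mu_n, yge, ps$rq, ps$carbon_closure))
}
cat("summaries written under results/physiology/\n")
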