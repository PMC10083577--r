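#!/usr/bin/env Rscript
# Compare closed elite programs at quarter scale: cross lists chosen by
# midparent phenotype, midparent GEBV, the usefulness criterion, classical
# OCS or UCPC-based OCS under a declining He trajectory. Writes tidy and
# summary tables under results/closed/.

suppressPackageStartupMessages(library(gsbridge))

n_reps <- 3
n_gens <- 20

spec <- founder_panel_spec(n_markers = 1200, seed = 2024)
map <- generate_genetic_map(10, 160, 1200)
panel <- generate_founder_panel(spec, map)

strategies <- c("PHENO", "GEBV", "UC", "OCS", "UCPC")
tables <- list()
for (st in strategies) {
  cfg <- scheme_config(strategy = st, scale = 4, n_generations = n_gens,
                       n_replicates = n_reps, base_seed = 100,
                       trajectory = "linear_loss",
                       optimizer = optimizer_config(iterations = 8000),
                       n_qtl = 300, n_neutral = 600)
  t0 <- Sys.time()
  tables[[st]] <- run_replicates(cfg, panel = panel, map = map)
  cat(sprintf("%s: %d reps x %d gens in %.0fs | final mu %.1f, He%% %.1f\n",
              st, n_reps, n_gens, as.numeric(Sys.time() - t0, units = "secs"),
              mean(tables[[st]]$mu[tables[[st]]$t_post == n_gens]),
              mean(tables[[st]]$he_percent[tables[[st]]$t_post == n_gens])))
}
paths <- write_report(tables, "results/closed", plots = TRUE)
cat("wrote", paste(paths, collapse = ", "), "\n")

final <- sapply(tables, function(df) mean(df$mu[df$t_post == n_gens]))
cat("\nMean final genetic gain (% of burn-in mean) by strategy:\n")
print(round(final, 1))
cat("Diversity-managed selection pays in the long term; at this 20-generation",
    "horizon truncation GEBV selection can still be ahead (the crossover",
    "occurs later, see the methods vignette).\n")
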