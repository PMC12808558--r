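#!/usr/bin/env Rscript
# Stage 4: derived quantities at three spatial scales - the whole region,
# each forest, and fire strata (unburned / <0.5 / >=0.5 of the cell burned
# at high severity) - plus annual growth rates (lambda-bar), probability of
# direction, and precision (CV) summaries.

suppressPackageStartupMessages(library(pamdyn))
sim <- "results/sim"
out <- "results/trends"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cfg <- read_run_config(file.path(sim, "config.yaml"))

cells <- read_cells_csv(file.path(sim, "cells.csv"))
burns <- read_burns_csv(file.path(sim, "burns.csv"))
h <- read_history_long("results/history/history_long.csv")
cells <- cells[match(h$site_ids, cells$cell_id), ]
design <- build_design(cells, burns, h, season_start = cfg$season_start)

dcsv <- read.csv("results/fit/draws.csv", check.names = FALSE)
draws <- structure(list(draws = as.matrix(dcsv[, -1]), chain = dcsv$chain,
                        dims = list(k_psi = 6, k_gamma = 3, k_eps = 3,
                                    k_p = 6,
                                    n_forests = design$n_forests)),
                   class = "occ_draws")

keep <- seq(1, nrow(draws$draws), by = 2)  # thin for projection speed
po <- project_occupancy(draws, design, draw_ids = keep)
groups <- c(list(region = seq_len(nrow(cells))),
            split(seq_len(nrow(cells)), paste0("forest", design$forest)),
            split(seq_len(nrow(cells)), fire_strata(design)))
tr <- group_trajectory(po, groups)
write_trend_summary(tr, file.path(out, "trend_summary.csv"),
                    file.path(out, "trend_stats.json"))

lb <- lambda_bar(tr$region$draws)
cat(sprintf("regional lambda-bar: %.3f (95%% CrI %.3f-%.3f), P(decline) = %.2f\n",
            lb$summary["mean"], lb$summary["lo95"], lb$summary["hi95"],
            lb$pd_decline))
cat(sprintf("mean CV of forest-level annual occupancy: %.3f\n",
            cv_summary(tr[grep("^forest", names(tr))])))
for (g in names(tr)) {
  l <- lambda_bar(tr[[g]]$draws)
  cat(sprintf("  %-10s lambda-bar %.3f  P(decline) %.2f\n", g,
              l$summary["mean"], l$pd_decline))
}
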