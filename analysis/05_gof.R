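#!/usr/bin/env Rscript
# Stage 5: goodness of fit - the MacKenzie-Bailey chi-square posterior
# predictive check over detection-history cohorts.

suppressPackageStartupMessages(library(pamdyn))
sim <- "results/sim"
out <- "results/gof"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
cfg <- read_run_config(file.path(sim, "config.yaml"))

cells <- read_cells_csv(file.path(sim, "cells.csv"))
burns <- read_burns_csv(file.path(sim, "burns.csv"))
h <- read_history_long("results/history/history_long.csv")
cells <- cells[match(h$site_ids, cells$cell_id), ]
design <- build_design(cells, burns, h, season_start = cfg$season_start)

dcsv <- read.csv("results/fit/draws.csv", check.names = FALSE)
meta <- jsonlite::read_json("results/fit/run_meta.json")
if (length(unique(dcsv$chain)) < 2) {
  stop("goodness of fit requires a multi-chain fit")
}
draws <- structure(list(draws = as.matrix(dcsv[, -1]), chain = dcsv$chain,
                        dims = meta$dims), class = "occ_draws")

g <- mb_chisq_ppc(draws, h, design, n_reps = 150, seed = cfg$seed)
print(g)
jsonlite::write_json(list(p_value = g$p_value,
                          n_reps = length(g$draw_ids),
                          chi2_obs_mean = mean(g$chi2_obs),
                          chi2_rep_mean = mean(g$chi2_rep)),
                     file.path(out, "gof.json"), auto_unbox = TRUE,
                     digits = NA)
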