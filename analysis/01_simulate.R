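#!/usr/bin/env Rscript
# Stage 1: generate a synthetic survey bundle emulating a regional passive
# acoustic monitoring program: a 300-cell landscape across 7 forests, a
# 1985-2023 fire history, four years of latent occupancy dynamics, recorder
# deployments, nightly detections, call-back surveys, and a classifier-style
# prediction table with injected false positives.

suppressPackageStartupMessages(library(pamdyn))
cfg <- run_config(seed = 20240401)
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
set.seed(cfg$seed)

years <- 2021:2024
cells <- gen_landscape(300, 7, seed = cfg$seed)
burns <- gen_fire_history(cells, 1985:2023, fire_rate = 2,
                          seed = cfg$seed + 1)
params <- owl_preset(seed = cfg$seed + 2)
st <- simulate_occupancy(cells, burns, params, years, seed = cfg$seed + 3)
dep <- gen_deployments(cells, years, seed = cfg$seed + 4)
det <- simulate_detections(st, dep, params, seed = cfg$seed + 5)
cb <- gen_callback_surveys(dep, n = 40, seed = cfg$seed + 6)
preds <- gen_prediction_table(det$events, dep, fp_rate = 0.02,
                              callback_surveys = cb,
                              seed = cfg$seed + 7)

write.csv(cells, file.path(out, "cells.csv"), row.names = FALSE)
write.csv(burns, file.path(out, "burns.csv"), row.names = FALSE)
write.csv(dep, file.path(out, "deployments.csv"), row.names = FALSE)
write.csv(cb, file.path(out, "callbacks.csv"), row.names = FALSE)
write.csv(preds, file.path(out, "predictions.csv"), row.names = FALSE)
write_history_long(det$truth, file.path(out, "truth_history_long.csv"))
write_run_config(cfg, file.path(out, "config.yaml"))
jsonlite::write_json(list(
  seed = cfg$seed, n_cells = nrow(cells), n_forests = 7, years = years,
  n_events = nrow(det$events), n_predictions = nrow(preds),
  occupancy_by_year = unname(colMeans(st$z)),
  files = list.files(out)), file.path(out, "manifest.json"),
  auto_unbox = TRUE, digits = NA)

cat(sprintf("simulated %d cells, %d fires rows, %d true events, %d predictions\n",
            nrow(cells), nrow(burns), nrow(det$events), nrow(preds)))
cat(sprintf("latent occupancy by year: %s\n",
            paste(round(colMeans(st$z), 3), collapse = " ")))
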