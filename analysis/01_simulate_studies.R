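#!/usr/bin/env Rscript
# Step 1 - simulate the two synthetic ESM studies the analysis runs on.
#
# Both studies follow the canonical protocol: 7 days x 10 beeps between
# 10:00 and 22:00, stratified random beep times (72-minute mean interval),
# bivariate latent OU affect dynamics on a 0-100 scale, 13% missed beeps.
# Study A is event-free; study B injects on average 2 large external-event
# jumps per person, which subsequently relax under the same dynamics.
# Output: per-study CSV in the package's ESM dialect plus the generating
# parameters as JSON, under results/data/.

suppressPackageStartupMessages(library(affectdyn))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

n_series <- 40  # desk-scale; raise for tighter win-fraction estimates

cfg_free <- study_config(n_series = n_series, seed = 20260101)
cfg_event <- study_config(n_series = n_series, event_rate = 2, seed = 20260102)

for (nm in c("event_free", "events")) {
  cfg <- if (nm == "event_free") cfg_free else cfg_event
  st <- generate_study(cfg)
  write_esm_csv(st$series, file.path("results/data", paste0(nm, ".csv")))
  writeLines(params_to_json(cfg$ou, dim_names = c("PA", "NA")),
             file.path("results/data", paste0(nm, "_truth.json")))
  n_events <- sum(vapply(st$truth$paths, function(p) length(p$event_beeps), 0))
  message(sprintf("study %-10s: %d series x 70 beeps, %d injected events",
                  nm, n_series, n_events))
}
message("wrote results/data/{event_free,events}.csv and *_truth.json")
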