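#!/usr/bin/env Rscript
# Stage 1: simulate the study's two data streams with known ground truth.
#
# Dynamic hyperpolarized runs are generated at the reported operating
# points (T-cell pyruvate and glucose runs; CAR T day-7 and day-14 glucose
# runs, three donor replicates each, sharing the truth and differing in
# noise), plus the 21-day supernatant panel. Everything downstream
# (02-04) works from these files alone.

suppressPackageStartupMessages(library(hpkinetics))

out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
base_seed <- 20260101L

for (preset in c("fig1a_pyruvate", "fig1b_glucose")) {
  ds <- generate_dynamic(hp_preset(preset, seed = base_seed))
  write_dynamic_series(ds, file.path(out, paste0(preset, ".csv")))
}

# three donors per expansion time point
for (preset in c("day7", "day14")) {
  for (donor in 1:3) {
    ds <- generate_dynamic(hp_preset(preset, seed = base_seed + donor))
    write_dynamic_series(
      ds, file.path(out, sprintf("%s_donor%d.csv", preset, donor)))
  }
}

# supernatant panel over the 21-day feed schedule
exp_panel <- generate_expansion(hp_preset("expansion_default",
                                          seed = base_seed))
write_supernatant_panel(exp_panel$panel, file.path(out, "supernatant.csv"))
utils::write.csv(exp_panel$cells, file.path(out, "cell_counts.csv"),
                 row.names = FALSE)

cat("simulated series:", length(list.files(out)), "files in", out, "\n")
cat(sprintf("culture peak density %.2fe6 cells/mL on day %d\n",
            max(exp_panel$cells$pre_feed) / 1e6,
            exp_panel$cells$day[which.max(exp_panel$cells$pre_feed)]))
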