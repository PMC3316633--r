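#!/usr/bin/env Rscript

# Stage 1 — experimental design.
#
# Builds the default scanning session: 216 temporal-discounting trials
# (6 delays x 6 amounts x 3 repetitions x 2 primes) plus 108 perceptual-
# control trials in 6 runs of 54, amounts calibrated to a pre-test discount
# rate so that now/later choices are expected to balance. Writes the
# calibrated amount grid and per-run events tables.

suppressPackageStartupMessages(library(tdprime))

master_seed <- 20260922L
out_dir <- "results/design"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

sch <- build_design(design_config(seed = child_seed(master_seed, "design")),
                    k_pretest = 0.024)
cfg <- attr(sch, "config")

cat(sprintf("TD trials: %d, PC trials: %d, runs: %d x %d trials\n",
            sum(sch$trial_type == "TD"), sum(sch$trial_type == "PC"),
            cfg$n_runs, unique(table(sch$run))))
cat(sprintf("distinct delay-amount combinations: %d\n",
            nrow(unique(sch[sch$trial_type == "TD", c("amount", "delay")]))))
cat(sprintf("scheduled stimulus time per run: %g s\n",
            trial_timeline(cfg)$run_stimulus_s))

amounts <- calibrate_amounts(0.024)
write.csv(data.frame(delay = rownames(amounts), amounts),
          file.path(out_dir, "calibrated_amounts.csv"), row.names = FALSE)
cat("amount envelope: [", min(amounts), ",", max(amounts), "] dollars\n")

for (r in seq_len(cfg$n_runs))
  write_events(sch[sch$run == r, ], file.path(out_dir, sprintf("run-%d_events.tsv", r)))
write_events(sch, file.path(out_dir, "session_events.tsv"))
cat("events tables written to", out_dir, "\n")
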