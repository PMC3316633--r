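#!/usr/bin/env Rscript

# Stage 5 — FIR searchlight decoding.
#
# Same synthetic cohort idea as stage 4, but with planted multivoxel
# pattern regions for the prime condition, the decision outcome and the
# decision difficulty (all mean-free: no univariate signal). Per subject:
# FIR deconvolution (6 bins x 1 TR), searchlight decoding (radius 3,
# linear SVM C = 1, leave-one-run-out, last two bins), then group
# inference on smoothed accuracy-minus-chance maps. Also decodes
# difficulty within each prime condition separately.

suppressPackageStartupMessages(library(tdprime))

master_seed <- 20260922L
out_dir <- "results/searchlight"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

n_subj <- 6
spec <- bold_spec(regions = list(
  prime_region = region_box(4:8, 4:8, 4:7, "prime_pattern"),
  outcome_region = region_box(16:20, 4:8, 4:7, "outcome_pattern"),
  difficulty_region = region_box(9:13, 15:19, 10:13, "difficulty_pattern")))

gen <- discount_params(0.024, 0.06, 0.3)
label_sets <- function(d, fit) list(
  prime = ifelse(d$trial_type == "TD", d$prime, NA),
  outcome = ifelse(d$trial_type == "TD", d$choice, NA),
  difficulty = {
    der <- derive_trial_values(d, fit$params)
    ifelse(d$trial_type == "TD", ifelse(der$hard, "hard", "easy"), NA)
  })

maps <- list(prime = list(), outcome = list(), difficulty = list())
excluded <- list(prime = 0, outcome = 0, difficulty = 0)
for (s in seq_len(n_subj)) {
  sch <- build_design(design_config(seed = child_seed(master_seed, "design", 500 + s)))
  d <- simulate_choices(gen, sch, seed = child_seed(master_seed, "choices", 500 + s))
  b <- simulate_bold(d, gen, spec, seed = child_seed(master_seed, "bold", 500 + s))
  fit <- fit_priming(d)
  for (what in names(maps)) {
    lab <- label_sets(d, fit)[[what]]
    fir <- tryCatch(fit_fir(b, d, lab),
                    td_subject_excluded = function(e) NULL)
    if (is.null(fir)) {
      excluded[[what]] <- excluded[[what]] + 1
      next
    }
    maps[[what]][[length(maps[[what]]) + 1]] <- searchlight_decode(fir)
  }
}

for (what in names(maps)) {
  cat(sprintf("\n== decoding %s (%d subjects used, %d excluded) ==\n",
              what, length(maps[[what]]), excluded[[what]]))
  grand <- Reduce(`+`, lapply(maps[[what]], `[[`, "accuracy")) / length(maps[[what]])
  cat(sprintf("brain-mean accuracy: %.3f\n", mean(grand, na.rm = TRUE)))
  write_volume(grand, file.path(out_dir, paste0(what, "_accuracy.nii")),
               voxel_size_mm = spec$voxel_size_mm)
  res <- group_accuracy_inference(maps[[what]], n_perm = 500,
                                  seed = child_seed(master_seed, "mvpa", 1))
  cat(sprintf("significant clusters: %d\n", nrow(res$significant)))
  if (nrow(res$significant)) print(res$significant, row.names = FALSE)
  write.csv(res$clusters, file.path(out_dir, paste0(what, "_clusters.csv")),
            row.names = FALSE)
}

# difficulty decoding within prime conditions for the first subject
sch <- build_design(design_config(seed = child_seed(master_seed, "design", 501)))
d <- simulate_choices(gen, sch, seed = child_seed(master_seed, "choices", 501))
b <- simulate_bold(d, gen, spec, seed = child_seed(master_seed, "bold", 501))
fit <- fit_priming(d)
wc <- within_condition_difficulty_decode(b, d, fit$params, min_trials = 2)
for (pr in names(wc)) {
  idx <- b$truth$difficulty_region$index
  cat(sprintf("within-%s difficulty decoding, planted-region accuracy: %.3f\n",
              pr, mean(wc[[pr]]$accuracy[idx])))
}
cat("wrote", out_dir, "\n")
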