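#!/usr/bin/env Rscript
# Step 1: simulate the study.  Two triad experiments with the same design
# (a first run and a direct replication) plus a pairwise similarity-rating
# study, all under the default study conditions: 29 participants at 100 ms
# and 17 at 2000 ms, per-block UD probability 0.12 vs 0.02, lapse 5%,
# 2% whole-participant response bias, 24 raters.
#
# Writes results/data/{exp1,exp2}_trials.csv and ratings.csv.

suppressPackageStartupMessages(library(triadfit))

seed <- if (length(a <- commandArgs(TRUE))) as.integer(a[1]) else 2026L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config()
space <- default_space()

exp1 <- generate_participants(cfg, seed = seed, space = space)
exp2 <- generate_participants(cfg, seed = seed + 1L, space = space)
ratings <- generate_ratings(space, cfg, seed = seed + 2L)

write_trials(exp1, file.path(out, "exp1_trials.csv"))
write_trials(exp2, file.path(out, "exp2_trials.csv"))
write_ratings(ratings, file.path(out, "ratings.csv"))

cat(sprintf("simulated %d + %d participants (96 trials each), %d raters\n",
            length(unique(exp1$participant)),
            length(unique(exp2$participant)),
            length(unique(ratings$participant))))
cat(sprintf("root seed %d; outputs under %s/\n", seed, out))
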