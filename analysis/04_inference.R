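#!/usr/bin/env Rscript
# Step 4: the inferential summaries.
#  - Gunel-Dickey contingency BF on participant-level UD vs OS winners
#    (and on the published participant counts, as a fixed reference point)
#  - JZS two-sample BF for the presentation-time effect on per-participant
#    UD block proportions, per experiment
#  - replication BF for experiment 2 with a normal prior centred on the
#    experiment-1 effect (SD = half that effect)
#  - power of the design-stage tests
#  - OLS block-trend regression and quadrant-removal sub-analyses (exp 1)
#
# Writes results/tables/inference.json.

suppressPackageStartupMessages(library(triadfit))

out <- "results/tables"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
space <- default_space()
table <- build_prediction_table(space)

per_exp <- list()
for (exp in c("exp1", "exp2")) {
  trials <- read_trials(file.path("results/data", paste0(exp, "_trials.csv")))
  fits <- fit_participants(trials, table)
  prev <- summarize_prevalence(fits$blocks)
  per <- prev$per_participant
  ud_s <- per$UD[per$condition_ms == 100]
  ud_l <- per$UD[per$condition_ms == 2000]

  pp <- subset(fits$participants, !tied & winner %in% c("UD", "OS"))
  ct <- base::table(factor(pp$condition_ms, c(100, 2000)),
                    factor(pp$winner, c("UD", "OS")))
  bf_ct <- contingency_bf(unclass(ct))
  bf_jzs <- jzs_ttest_bf(ud_s, ud_l)
  cat(sprintf("%s: contingency BF10 = %.3g; JZS BF10 (UD proportion) = %.3g\n",
              exp, bf_ct$bf10, bf_jzs$bf10))

  per_exp[[exp]] <- list(
    effect = mean(ud_s) - mean(ud_l),
    se = sqrt(var(ud_s) / length(ud_s) + var(ud_l) / length(ud_l)),
    contingency_bf10 = bf_ct$bf10, jzs_bf10 = bf_jzs$bf10,
    fits = fits, trials = trials)
}

# replication test: experiment 2's effect against a prior centred on
# experiment 1's observed difference with SD half that difference
bf_rep <- dienes_bf(per_exp$exp2$effect, per_exp$exp2$se,
                    prior_mean = per_exp$exp1$effect)
cat(sprintf("replication BF10 (normal prior %.3f +/- %.3f): %.3g\n",
            per_exp$exp1$effect, per_exp$exp1$effect / 2, bf_rep$bf10))

# published participant-level counts as the fixed reference computation
bf_ref <- contingency_bf(rbind(c(1, 27), c(0, 17)))
cat(sprintf("reference contingency BF10 on the reported counts: %.3g\n",
            bf_ref$bf10))

# design-stage power
pw <- list(
  chisq_w40_n46_df1 = power_chisq(0.40, 46, df = 1),
  chisq_w40_n46_df2 = power_chisq(0.40, 46, df = 2),
  ttest_d083_25_25 = power_ttest(0.83, 25, 25),
  ttest_d083_33_17 = power_ttest(0.83, 33, 17))
cat(sprintf("power: chi-square (w=.40, N=46, df=1) %.3f; t (d=.83, 25/25) %.3f\n",
            pw$chisq_w40_n46_df1, pw$ttest_d083_25_25))

# block trend and quadrant sub-analyses on experiment 1
udd <- ud_distribution(per_exp$exp1$fits$blocks)
trend <- block_trend_ols(udd$trajectory)
cat(sprintf("block-trend OLS (df = %d):\n", trend$df_residual))
print(round(trend$coefficients, 3))

nonbias <- subset(per_exp$exp1$fits$participants, winner != "Bias")$participant
quad <- suppressWarnings(quadrant_subanalyses(
  subset(per_exp$exp1$trials, participant %in% nonbias), table, space))
cat("quadrant-removal sub-analyses (JZS BF10 for the time effect):\n")
print(quad, row.names = FALSE, digits = 3)

jsonlite::write_json(list(
  exp1 = per_exp$exp1[c("effect", "se", "contingency_bf10", "jzs_bf10")],
  exp2 = per_exp$exp2[c("effect", "se", "contingency_bf10", "jzs_bf10")],
  replication_bf10 = bf_rep$bf10,
  reference_contingency_bf10 = bf_ref$bf10,
  power = pw,
  block_trend = list(df = trend$df_residual,
                     coefficients = as.data.frame(trend$coefficients)),
  quadrants = quad),
  file.path(out, "inference.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
cat("written:", file.path(out, "inference.json"), "\n")
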