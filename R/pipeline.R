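#' Restrict a trial table to a subset of logical triads
#'
#' Used by the quadrant-removal sub-analyses: trials whose display belongs
#' to a dropped triad are removed, leaving smaller but still balanced
#' blocks.
#'
#' @param trials trial data frame.
#' @param triads list of logical triads to keep.
#' @return the filtered trial table.
#' @export
subset_trials_to_triads <- function(trials, triads) {
  labels <- vapply(triads, function(m) paste(sort(m), collapse = "-"), "")
  key <- apply(cbind(trials$left, trials$middle, trials$right), 1,
               function(r) paste(sort(r), collapse = "-"))
  trials[key %in% labels, ]
}

#' Quadrant-removal sub-analyses
#'
#' For each quadrant of the design space, removes every triad containing a
#' stimulus of that quadrant, re-runs the by-block fit on the remaining
#' (4-trial) blocks, and computes the JZS Bayes factor for the effect of
#' presentation time on the per-participant proportion of unidimensional
#' blocks.
#'
#' @param trials trial data frame (bias participants should already be
#'   excluded, e.g. via [fit_participants()]).
#' @param table full prediction table.
#' @param space the design [triad_space].
#' @return data frame: quadrant, number of triads kept, BF10, and the two
#'   condition means.
#' @export
quadrant_subanalyses <- function(trials, table, space = default_space()) {
  quads <- quadrants(space)
  rows <- lapply(names(quads), function(q) {
    kept <- filter_triads_excluding_quadrant(design_triads(), quads[[q]], space)
    sub <- subset_trials_to_triads(trials, kept)
    fits <- fit_participants(sub, table)
    prev <- summarize_prevalence(fits$blocks)
    per <- prev$per_participant
    conds <- sort(unique(per$condition_ms))
    g1 <- per$UD[per$condition_ms == conds[1]]
    g2 <- per$UD[per$condition_ms == conds[2]]
    bf <- tryCatch(jzs_ttest_bf(g1, g2)$bf10, error = function(e) NA_real_)
    data.frame(quadrant = q, n_triads = length(kept), bf10 = bf,
               mean_ud_short = mean(g1), mean_ud_long = mean(g2))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline on one (simulated) experiment
#'
#' Simulates a two-condition triad experiment, classifies participants and
#' blocks against the design-space response models, recovers the
#' psychological space by non-metric MDS from a similarity matrix
#' (simulated ratings by default), re-fits the responses in the recovered
#' space, and computes the inferential summaries: the participant-level
#' contingency Bayes factor, the JZS Bayes factor on per-participant
#' unidimensional block proportions, the block-trend regression, and the
#' quadrant-removal sub-analyses.  All outputs carry the seed and a hash
#' of the configuration; identical calls reproduce identical files.
#'
#' @param config a [sim_config()].
#' @param seed integer root seed.
#' @param out_dir optional directory: if given, writes `trials.csv`,
#'   `ratings.csv`, `prevalence.csv`, `mds_coords.csv`, `report.json` and
#'   `manifest.json` there.
#' @param similarity optional similarity matrix for the MDS stage; the
#'   default simulates a rating study under `config` and averages it.
#' @param space generating/design [triad_space].
#' @return (invisibly, when writing) a list with elements `trials`,
#'   `fits`, `prevalence`, `mds` (both metrics + procrustes), `refit`
#'   (prevalence under MDS coordinates), `bayes`, `trend`, `quadrants`.
#' @export
run_pipeline <- function(config = sim_config(), seed = 1L, out_dir = NULL,
                         similarity = NULL, space = default_space()) {
  trials <- generate_participants(config, seed, space)
  table <- build_prediction_table(space)
  fits <- fit_participants(trials, table)
  prev <- summarize_prevalence(fits$blocks)
  udd <- ud_distribution(fits$blocks)

  ratings <- NULL
  if (is.null(similarity)) {
    ratings <- generate_ratings(space, config, subseed(seed, 999L))
    similarity <- ratings_to_matrix(ratings)
  }
  diss <- similarity_to_dissimilarity(similarity)
  mds_e <- nonmetric_mds(diss, metric = "euclidean")
  mds_c <- nonmetric_mds(diss, metric = "cityblock")
  proc <- procrustes_fit(mds_e$points, space$scaled, scale = TRUE)
  misfit <- procrustes_residual_ranking(mds_e$points, space$scaled)

  table_mds <- respace_prediction_table(mds_e, target = space)
  nonbias <- fits$participants$participant[fits$participants$winner != "Bias"]
  refit <- fit_participants(trials[trials$participant %in% nonbias, ],
                            table_mds)
  prev_mds <- summarize_prevalence(refit$blocks)

  # participant-level UD/OS contingency (ties and other winners dropped)
  pp <- fits$participants
  pp <- pp[!pp$tied & pp$winner %in% c("UD", "OS"), ]
  conds <- sort(unique(trials$condition_ms))
  ct <- t(vapply(conds, function(cn) {
    c(UD = sum(pp$winner == "UD" & pp$condition_ms == cn),
      OS = sum(pp$winner == "OS" & pp$condition_ms == cn))
  }, c(UD = 0, OS = 0)))
  rownames(ct) <- conds
  bf_cont <- contingency_bf(ct)

  per <- prev$per_participant
  g_short <- per$UD[per$condition_ms == min(conds)]
  g_long <- per$UD[per$condition_ms == max(conds)]
  bf_jzs <- jzs_ttest_bf(g_short, g_long)
  trend <- block_trend_ols(udd$trajectory)
  quad <- quadrant_subanalyses(trials[trials$participant %in% nonbias, ],
                               table, space)

  result <- list(
    seed = seed, trials = trials, ratings = ratings, fits = fits,
    prevalence = prev, ud_distribution = udd,
    mds = list(euclidean = mds_e, cityblock = mds_c, procrustes = proc,
               misfit_ranking = misfit),
    refit = prev_mds, contingency = list(table = ct, bf = bf_cont),
    jzs = bf_jzs, trend = trend, quadrants = quad)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg_path <- file.path(out_dir, "config.json")
    jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    cfg_hash <- unname(tools::md5sum(cfg_path))
    stamp <- list(seed = seed, config_hash = cfg_hash,
                  package_version = as.character(utils::packageVersion("triadfit")))
    write_trials(trials, file.path(out_dir, "trials.csv"))
    if (!is.null(ratings))
      write_ratings(ratings, file.path(out_dir, "ratings.csv"))
    utils::write.csv(cbind(prev$table, seed = seed, config_hash = cfg_hash),
                     file.path(out_dir, "prevalence.csv"), row.names = FALSE)
    utils::write.csv(data.frame(stimulus = rownames(mds_e$points),
                                dim1 = mds_e$points[, 1],
                                dim2 = mds_e$points[, 2],
                                seed = seed, config_hash = cfg_hash),
                     file.path(out_dir, "mds_coords.csv"), row.names = FALSE)
    report <- c(stamp, list(
      prevalence = prev$table, tie_rate = prev$tie_rate,
      prevalence_mds = prev_mds$table, tie_rate_mds = prev_mds$tie_rate,
      stress_euclidean = mds_e$stress, stress_cityblock = mds_c$stress,
      misfit_ranking = as.list(misfit),
      contingency = list(table = as.data.frame(ct), bf10 = bf_cont$bf10),
      jzs_bf10 = bf_jzs$bf10,
      trend = as.data.frame(trend$coefficients), quadrants = quad))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    jsonlite::write_json(stamp, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(result))
  }
  result
}
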