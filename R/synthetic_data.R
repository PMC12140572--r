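#' Simulation configuration
#'
#' Defaults encode the study design the analysis assumes: a short (100 ms)
#' and a long (2000 ms) presentation-time condition with roughly 2:1
#' allocation (29 vs 17 participants), a per-block strategy mixture in
#' which unidimensional responding is more prevalent under time pressure
#' (total UD probability 0.12 vs 0.02, split evenly over the two
#' dimensions), a small identity component, a 5% lapse rate, and a small
#' probability of a whole-participant response bias.  Rating-study
#' parameters map scaled inter-stimulus distance onto the 1-9 similarity
#' scale affinely with Gaussian noise.
#'
#' @param n_participants named integer vector: participants per condition
#'   (names are presentation times in ms).
#' @param mixture named list (one element per condition) of per-block
#'   strategy probabilities over `UD_CHROMA`, `UD_BRIGHTNESS`, `OS`, `ID`;
#'   each must sum to 1.
#' @param lapse probability that a trial's response is uniform over the
#'   three positions instead of the block strategy's prediction.
#' @param bias_prob probability that a participant presses one fixed key
#'   throughout the session.
#' @param n_raters participants in the simulated similarity-rating study.
#' @param rating_intercept,rating_slope affine map from scaled distance to
#'   mean rating: `mean = intercept - slope * distance`.
#' @param rating_sd Gaussian noise SD added before rounding and clamping
#'   to the 1-9 scale.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_participants = c("100" = 29L, "2000" = 17L),
                       mixture = list(
                         "100" = c(UD_CHROMA = 0.06, UD_BRIGHTNESS = 0.06,
                                   OS = 0.875, ID = 0.005),
                         "2000" = c(UD_CHROMA = 0.01, UD_BRIGHTNESS = 0.01,
                                    OS = 0.97, ID = 0.01)),
                       lapse = 0.05, bias_prob = 0.02,
                       n_raters = 24L, rating_intercept = 9.2,
                       rating_slope = 1.15, rating_sd = 1.0) {
  stopifnot(identical(sort(names(n_participants)), sort(names(mixture))))
  for (m in mixture) {
    stopifnot(all(m >= 0), abs(sum(m) - 1) < 1e-8,
              identical(sort(names(m)),
                        sort(c("UD_CHROMA", "UD_BRIGHTNESS", "OS", "ID"))))
  }
  stopifnot(lapse >= 0, lapse <= 1, bias_prob >= 0, bias_prob <= 1)
  structure(list(n_participants = n_participants, mixture = mixture,
                 lapse = lapse, bias_prob = bias_prob, n_raters = n_raters,
                 rating_intercept = rating_intercept,
                 rating_slope = rating_slope, rating_sd = rating_sd),
            class = "sim_config")
}

# run code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic sub-seed derivation, kept within 32-bit integer range
subseed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}

#' Generate one participant's randomized trial order
#'
#' 96 trials in 12 blocks of 8: every block contains exactly one
#' arrangement of each of the 8 logical triads, and over the session each
#' of the 48 physical arrangements appears exactly twice.
#'
#' @param seed integer seed.
#' @param space a [triad_space] (only the design triads are used).
#' @return data frame `block`, `trial`, `triad`, `left`, `middle`, `right`.
#' @export
generate_design <- function(seed, space = default_space()) {
  instances <- enumerate_instances(design_triads())
  with_seed(seed, {
    per_triad <- lapply(split(seq_len(nrow(instances)), instances$triad),
                        function(rows) sample(rep(rows, 2L)))
    blocks <- lapply(1:12, function(b) {
      rows <- vapply(per_triad, `[[`, integer(1), b)
      rows <- sample(rows)  # order within block
      cbind(block = b, trial = 1:8, instances[rows, ])
    })
    out <- do.call(rbind, blocks)
    rownames(out) <- NULL
    out
  })
}

.strategy_response <- function(pred_row, strategy, lapse) {
  p <- pred_row[[strategy]]
  if (stats::runif(1) < lapse || is.na(p)) sample(3L, 1L) else as.integer(p)
}

#' Simulate one participant's responses
#'
#' Per block, a strategy is drawn from the condition's mixture; each trial
#' is answered with that strategy's predicted odd position, except that
#' with probability `lapse` (and always when the strategy abstains) the
#' response is uniform over the three positions.  Bias participants press
#' one fixed key throughout.
#'
#' @param design trial order from [generate_design()].
#' @param condition_ms presentation time (names `config$mixture`).
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param table prediction table for the generating space.
#' @param bias_key `NULL` for a strategy responder, else 1, 2 or 3.
#' @return the design extended by `response_pos` and a `strategy` column
#'   recording the generating per-block strategy (or `"BIAS"`).
#' @export
generate_responses <- function(design, condition_ms, config, seed, table,
                               bias_key = NULL) {
  mix <- config$mixture[[as.character(condition_ms)]]
  pred <- as.data.frame(table)
  idx <- match(paste(design$left, design$middle, design$right),
               paste(pred$left, pred$middle, pred$right))
  with_seed(seed, {
    out <- design
    if (!is.null(bias_key)) {
      out$strategy <- "BIAS"
      out$response_pos <- as.integer(bias_key)
      return(out)
    }
    block_strat <- sample(names(mix), 12, replace = TRUE, prob = mix)
    out$strategy <- block_strat[design$block]
    out$response_pos <- vapply(seq_len(nrow(out)), function(i) {
      .strategy_response(pred[idx[i], ], out$strategy[i], config$lapse)
    }, integer(1))
    out
  })
}

#' Simulate a full two-condition experiment
#'
#' @param config a [sim_config()].
#' @param seed integer root seed; every participant's design and responses
#'   derive deterministic sub-seeds from it.
#' @param space generating [triad_space].
#' @return trial table with columns `participant`, `condition_ms`, `block`,
#'   `trial`, `left`, `middle`, `right`, `response_pos` plus the hidden
#'   `strategy` column (generating truth, useful for recovery checks).
#' @export
generate_participants <- function(config = sim_config(), seed = 1L,
                                  space = default_space()) {
  table <- build_prediction_table(space)
  conds <- names(config$n_participants)
  k <- 0L
  rows <- list()
  for (cn in conds) {
    for (i in seq_len(config$n_participants[[cn]])) {
      k <- k + 1L
      pid <- sprintf("P%s_%02d", cn, i)
      des <- generate_design(subseed(seed, 2L * k), space)
      bias_key <- with_seed(subseed(seed, 2L * k + 1L), {
        if (stats::runif(1) < config$bias_prob) sample(3L, 1L) else NULL
      })
      resp <- generate_responses(des, cn, config, subseed(seed, 10000L + k),
                                 table, bias_key = bias_key)
      rows[[k]] <- cbind(participant = pid, condition_ms = as.integer(cn),
                         resp)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a pairwise similarity-rating study
#'
#' Two blocks of 56 trials per rater: each of the 28 stimulus pairs is
#' shown twice per block with left/right position counterbalanced.  Each
#' presentation is rated
#' `clamp(round(intercept - slope * scaled_distance + noise), 1, 9)`.
#'
#' @param space a [triad_space].
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return data frame `participant`, `block`, `left`, `right`, `rating`.
#' @export
generate_ratings <- function(space, config = sim_config(), seed = 1L) {
  pairs <- t(utils::combn(1:8, 2))
  sc <- space$scaled
  d <- sqrt(rowSums((sc[pairs[, 1], ] - sc[pairs[, 2], ])^2))
  mu <- config$rating_intercept - config$rating_slope * d
  rows <- list()
  for (r in seq_len(config$n_raters)) {
    rows[[r]] <- with_seed(subseed(seed, 70000L + r), {
      per_block <- lapply(1:2, function(b) {
        # two presentations per pair per block, counterbalanced left-right
        df <- data.frame(
          participant = sprintf("R%02d", r), block = b,
          left = c(pairs[, 1], pairs[, 2]),
          right = c(pairs[, 2], pairs[, 1]),
          mu = c(mu, mu))
        df <- df[sample(nrow(df)), ]
        df$rating <- pmin(9L, pmax(1L, as.integer(round(
          df$mu + stats::rnorm(nrow(df), 0, config$rating_sd)))))
        df$mu <- NULL
        df
      })
      do.call(rbind, per_block)
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Average a long rating table into a symmetric similarity matrix
#'
#' @param ratings data frame `left`, `right`, `rating` (long form, any
#'   number of raters/presentations per pair).
#' @return 8 x 8 symmetric matrix of mean ratings, `NA` diagonal.
#' @export
ratings_to_matrix <- function(ratings) {
  a <- pmin(ratings$left, ratings$right)
  b <- pmax(ratings$left, ratings$right)
  m <- matrix(NA_real_, 8, 8, dimnames = list(1:8, 1:8))
  agg <- stats::aggregate(ratings$rating, by = list(a = a, b = b), FUN = mean)
  for (k in seq_len(nrow(agg))) {
    m[agg$a[k], agg$b[k]] <- m[agg$b[k], agg$a[k]] <- agg$x[k]
  }
  m
}

#' Mean similarity ratings of the eight stimuli from the rating study
#'
#' The 28 pairwise mean ratings (1-9 scale, higher = more similar)
#' collected for these stimuli, shipped as a matrix-form CSV.
#'
#' @return 8 x 8 symmetric matrix, `NA` diagonal.
#' @export
mean_similarity_ratings <- function() {
  path <- system.file("extdata", "mean_similarity_ratings.csv",
                      package = "triadfit", mustWork = TRUE)
  read_similarity(path)
}
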