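#' Best-fit strategy classification
#'
#' Responses are scored against every strategy's predicted odd position;
#' the participant (or block) is assigned the strategy with the highest
#' match count.  Unidimensional counts are collapsed over the two
#' dimensions by taking the maximum (a unidimensional responder uses one
#' dimension, not both), and the three response-bias keys are collapsed
#' the same way.  Abstentions never match.
#'
#' @name strategy_fit
NULL

.collapse_counts <- function(counts) {
  c(UD = max(counts[["UD_CHROMA"]], counts[["UD_BRIGHTNESS"]]),
    OS = counts[["OS"]],
    ID = counts[["ID"]],
    Bias = max(counts[["BIAS_LEFT"]], counts[["BIAS_MIDDLE"]],
               counts[["BIAS_RIGHT"]]))
}

.match_counts <- function(trials, table, strategies = strategy_levels()) {
  pred <- prediction_matrix(trials, table)[, strategies, drop = FALSE]
  hits <- pred == trials$response_pos
  counts <- colSums(hits, na.rm = TRUE)
  names(counts) <- strategies
  counts
}

#' Score one participant's full session
#'
#' @param trials data frame of one participant's trials, columns `left`,
#'   `middle`, `right`, `response_pos` (1, 2 or 3).
#' @param table a `prediction_table` from [build_prediction_table()].
#' @return list with `counts` (7 raw match counts), `collapsed` (UD, OS,
#'   ID, Bias), `winner` (one of `"UD"`, `"OS"`, `"ID"`, `"Bias"`),
#'   `detail` (winning dimension or bias key), and `tied` (logical: the
#'   collapsed maximum is shared between strategy families).
#' @export
score_participant <- function(trials, table) {
  counts <- .match_counts(trials, table)
  coll <- .collapse_counts(counts)
  top <- names(coll)[coll == max(coll)]
  winner <- top[1]
  detail <- switch(winner,
    UD = if (counts[["UD_CHROMA"]] >= counts[["UD_BRIGHTNESS"]])
           "chroma" else "brightness",
    Bias = c("left", "middle", "right")[which.max(
      counts[c("BIAS_LEFT", "BIAS_MIDDLE", "BIAS_RIGHT")])],
    winner)
  list(counts = counts, collapsed = coll, winner = winner,
       detail = detail, tied = length(top) > 1L)
}

#' Score each 8-trial block separately
#'
#' Response-bias strategies are excluded: stimulus positions are only
#' counterbalanced across the whole session, so bias is detectable only at
#' the participant level.  A block whose collapsed maximum is shared
#' between families is marked `"TIED"`.
#'
#' @param trials data frame of one participant's trials; must contain a
#'   `block` column, with exactly `trials_per_block` trials per block.
#' @param trials_per_block expected block size: 8 for the full design,
#'   smaller for quadrant-removal sub-analyses.
#' @inheritParams score_participant
#' @return data frame with one row per block: `block`, the four match
#'   counts, and `winner` (`"UD"`, `"OS"`, `"ID"` or `"TIED"`).
#' @export
score_blocks <- function(trials, table, trials_per_block = 8L) {
  strategies <- c("UD_CHROMA", "UD_BRIGHTNESS", "OS", "ID")
  blocks <- sort(unique(trials$block))
  rows <- lapply(blocks, function(b) {
    tb <- trials[trials$block == b, ]
    if (nrow(tb) != trials_per_block)
      stop("block ", b, " has ", nrow(tb), " trials; expected ",
           trials_per_block)
    counts <- .match_counts(tb, table, strategies)
    coll <- c(UD = max(counts[["UD_CHROMA"]], counts[["UD_BRIGHTNESS"]]),
              OS = counts[["OS"]], ID = counts[["ID"]])
    top <- names(coll)[coll == max(coll)]
    data.frame(block = b, UD_CHROMA = counts[["UD_CHROMA"]],
               UD_BRIGHTNESS = counts[["UD_BRIGHTNESS"]],
               OS = counts[["OS"]], ID = counts[["ID"]],
               winner = if (length(top) > 1L) "TIED" else top[1])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit all participants: whole-session and by-block classification
#'
#' Classifies every participant by best-fitting strategy, then fits the
#' four response models block by block for every participant not best fit
#' by a response-bias model (mirroring the exclusion used in the original
#' analyses).
#'
#' @param trials full trial table (columns `participant`, `condition_ms`,
#'   `block`, `left`, `middle`, `right`, `response_pos`).
#' @inheritParams score_participant
#' @return list with `participants` (one row per participant: condition,
#'   collapsed counts, winner, detail, tied) and `blocks` (block fits of
#'   non-bias participants with participant and condition columns).
#' @export
fit_participants <- function(trials, table) {
  ids <- unique(trials$participant)
  prow <- lapply(ids, function(p) {
    tp <- trials[trials$participant == p, ]
    f <- score_participant(tp, table)
    data.frame(participant = p, condition_ms = tp$condition_ms[1],
               UD = f$collapsed[["UD"]], OS = f$collapsed[["OS"]],
               ID = f$collapsed[["ID"]], Bias = f$collapsed[["Bias"]],
               winner = f$winner, detail = f$detail, tied = f$tied)
  })
  participants <- do.call(rbind, prow)
  keep <- participants$participant[participants$winner != "Bias"]
  brow <- lapply(keep, function(p) {
    tp <- trials[trials$participant == p, ]
    tpb <- nrow(tp) / length(unique(tp$block))
    bf <- score_blocks(tp, table, trials_per_block = tpb)
    cbind(participant = p, condition_ms = tp$condition_ms[1], bf)
  })
  blocks <- if (length(brow)) do.call(rbind, brow) else NULL
  list(participants = participants, blocks = blocks)
}

#' Mean strategy prevalence per condition from block fits
#'
#' Tied blocks are removed; each remaining participant contributes the
#' proportion of their non-tied blocks won by UD, OS and ID (these sum to
#' one), and conditions average participants with equal weight.
#'
#' @param block_fits block-fit data frame from [fit_participants()]
#'   (`$blocks`).
#' @return list with `table` (per condition: mean UD/OS/ID proportions,
#'   `n_participants`), `tie_rate` (proportion of blocks removed), and
#'   `per_participant` (the per-participant proportions, used by
#'   downstream Bayes-factor comparisons).
#' @export
summarize_prevalence <- function(block_fits) {
  n_total <- nrow(block_fits)
  ids <- unique(block_fits$participant)
  rows <- lapply(ids, function(p) {
    bf <- block_fits[block_fits$participant == p, ]
    ok <- bf[bf$winner != "TIED", ]
    if (nrow(ok) == 0L) {
      warning("participant ", p, " has no non-tied blocks; excluded")
      return(NULL)
    }
    data.frame(participant = p, condition_ms = bf$condition_ms[1],
               n_blocks = nrow(ok),
               UD = mean(ok$winner == "UD"),
               OS = mean(ok$winner == "OS"),
               ID = mean(ok$winner == "ID"))
  })
  per <- do.call(rbind, rows)
  conds <- sort(unique(per$condition_ms))
  tab <- do.call(rbind, lapply(conds, function(cn) {
    pc <- per[per$condition_ms == cn, ]
    data.frame(condition_ms = cn, UD = mean(pc$UD), OS = mean(pc$OS),
               ID = mean(pc$ID), n_participants = nrow(pc))
  }))
  list(table = tab,
       tie_rate = sum(block_fits$winner == "TIED") / n_total,
       per_participant = per)
}

#' Distribution and time course of unidimensional responding
#'
#' @inheritParams summarize_prevalence
#' @return list with `per_participant` (number of UD blocks for each
#'   participant, with condition) and `trajectory` (per condition and
#'   block index, the proportion of non-tied blocks won by UD).
#' @export
ud_distribution <- function(block_fits) {
  ids <- unique(block_fits$participant)
  per <- do.call(rbind, lapply(ids, function(p) {
    bf <- block_fits[block_fits$participant == p, ]
    data.frame(participant = p, condition_ms = bf$condition_ms[1],
               ud_blocks = sum(bf$winner == "UD"))
  }))
  cells <- unique(block_fits[c("condition_ms", "block")])
  cells <- cells[order(cells$condition_ms, cells$block), ]
  traj <- do.call(rbind, lapply(seq_len(nrow(cells)), function(k) {
    sel <- block_fits$condition_ms == cells$condition_ms[k] &
      block_fits$block == cells$block[k] & block_fits$winner != "TIED"
    data.frame(condition_ms = cells$condition_ms[k], block = cells$block[k],
               prop_ud = mean(block_fits$winner[sel] == "UD"),
               n = sum(sel))
  }))
  list(per_participant = per, trajectory = traj)
}
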