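#' Response models for the triad task
#'
#' Each strategy predicts, for a given left/middle/right display, which
#' position holds the odd one out (equivalently, which pair "goes
#' together").  Predictions are deterministic; where a strategy cannot
#' decide (an exact distance tie, or no identical pair for the identity
#' model) it abstains, encoded as `NA`.  An abstention never matches an
#' observed response.
#'
#' @name response_models
NULL

strategy_levels <- function() {
  c("UD_CHROMA", "UD_BRIGHTNESS", "OS", "ID",
    "BIAS_LEFT", "BIAS_MIDDLE", "BIAS_RIGHT")
}

# pairwise helper: for display (l, m, r) the three pairs and the position
# of the excluded (odd) stimulus
.pair_idx <- rbind(c(1, 2), c(1, 3), c(2, 3))
.odd_of_pair <- c(3L, 2L, 1L)

#' Overall-similarity prediction
#'
#' The pair grouped is the one with the smallest scaled Euclidean distance
#' in the space; the odd one out is the remaining stimulus.  Abstains on an
#' exact tie for the minimum.
#'
#' @param instance integer vector `c(left, middle, right)` of stimulus ids.
#' @param space a [triad_space].
#' @return predicted odd position (1, 2 or 3) or `NA` on a tie.
#' @export
predict_os <- function(instance, space) {
  xy <- space$scaled[as.character(instance), , drop = FALSE]
  d <- vapply(seq_len(3), function(k) {
    i <- .pair_idx[k, 1]; j <- .pair_idx[k, 2]
    sqrt(sum((xy[i, ] - xy[j, ])^2))
  }, numeric(1))
  .argmin_or_abstain(d)
}

#' Unidimensional prediction
#'
#' Groups the pair closest on one fixed dimension (chroma or brightness),
#' ignoring the other; abstains on an exact tie.
#'
#' @inheritParams predict_os
#' @param dimension `"chroma"` or `"brightness"`.
#' @return predicted odd position or `NA`.
#' @export
predict_ud <- function(instance, space, dimension = c("chroma", "brightness")) {
  dimension <- match.arg(dimension)
  v <- space$coords[[dimension]][match(instance, space$coords$stimulus)]
  d <- abs(v[.pair_idx[, 1]] - v[.pair_idx[, 2]])
  .argmin_or_abstain(d)
}

#' Identity prediction
#'
#' Groups the pair that is exactly identical on one dimension (whichever
#' dimension that is on the trial).  Abstains when no pair is identical on
#' any dimension -- which is always the case for continuous,
#' MDS-derived coordinates.  Two distinct identical pairs violate the
#' design and raise an error.
#'
#' @inheritParams predict_os
#' @return predicted odd position or `NA`.
#' @export
predict_id <- function(instance, space) {
  v <- space$coords[match(instance, space$coords$stimulus), ]
  hit <- integer(0)
  for (k in seq_len(3)) {
    i <- .pair_idx[k, 1]; j <- .pair_idx[k, 2]
    if (v$chroma[i] == v$chroma[j] || v$brightness[i] == v$brightness[j])
      hit <- c(hit, k)
  }
  if (length(hit) == 0L) return(NA_integer_)
  if (length(hit) > 1L)
    stop("design violation: multiple identical pairs in instance ",
         paste(instance, collapse = "-"))
  .odd_of_pair[hit]
}

.argmin_or_abstain <- function(d) {
  m <- min(d)
  if (sum(d == m) > 1L) return(NA_integer_)
  .odd_of_pair[which.min(d)]
}

#' Tabulate every strategy's prediction for a set of displays
#'
#' @param space a [triad_space].
#' @param instances data frame of displays as returned by
#'   [enumerate_instances()].
#' @return a `prediction_table`: the `instances` data frame extended by one
#'   integer column per strategy (`NA` = abstain), with attribute
#'   `strategies`.
#' @export
build_prediction_table <- function(space, instances = enumerate_instances()) {
  if (nrow(instances) == 0L) stop("instances must be nonempty")
  inst <- as.matrix(instances[, c("left", "middle", "right")])
  out <- instances
  out$UD_CHROMA <- apply(inst, 1, predict_ud, space = space, dimension = "chroma")
  out$UD_BRIGHTNESS <- apply(inst, 1, predict_ud, space = space,
                             dimension = "brightness")
  out$OS <- apply(inst, 1, predict_os, space = space)
  out$ID <- apply(inst, 1, predict_id, space = space)
  out$BIAS_LEFT <- 1L
  out$BIAS_MIDDLE <- 2L
  out$BIAS_RIGHT <- 3L
  structure(out, strategies = strategy_levels(), class = c("prediction_table",
                                                           class(out)))
}

#' Export / import a prediction table as CSV
#'
#' Long form `strategy,left,middle,right,predicted_position`; abstentions
#' are written as an empty field.
#'
#' @param table a `prediction_table` from [build_prediction_table()].
#' @param path file path.
#' @export
write_prediction_table <- function(table, path) {
  strat <- attr(table, "strategies")
  long <- do.call(rbind, lapply(strat, function(s) {
    data.frame(strategy = s, left = table$left, middle = table$middle,
               right = table$right, predicted_position = table[[s]])
  }))
  utils::write.csv(long, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Look up predictions for observed displays
#'
#' Matches rows of `trials` (columns `left`, `middle`, `right`) against the
#' prediction table and returns the prediction matrix (one column per
#' strategy).  Unknown displays raise an error.
#'
#' @param trials data frame with `left`, `middle`, `right` columns.
#' @param table a `prediction_table`.
#' @return integer matrix, `nrow(trials)` x 7, `NA` = abstain.
#' @keywords internal
prediction_matrix <- function(trials, table) {
  key <- function(d) paste(d$left, d$middle, d$right)
  idx <- match(key(trials), key(table))
  if (anyNA(idx)) stop("instance not in prediction table: ",
                       key(trials)[which(is.na(idx))[1]])
  as.matrix(as.data.frame(table)[idx, strategy_levels()])
}
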