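# Independent brute-force oracles used across the suite.  These re-derive
# predictions and marginal likelihoods from first principles and must stay
# independent of the package internals they check.

# all three pairwise scaled distances of a display, straight from the
# coordinate table
oracle_pair_distances <- function(instance, space, metric = "euclidean") {
  co <- space$coords
  pt <- function(id) c(co$chroma[co$stimulus == id] * space$chroma_weight,
                       co$brightness[co$stimulus == id])
  xs <- lapply(instance, pt)
  pairs <- list(c(1, 2), c(1, 3), c(2, 3))
  vapply(pairs, function(p) {
    dv <- xs[[p[1]]] - xs[[p[2]]]
    if (metric == "euclidean") sqrt(sum(dv^2)) else sum(abs(dv))
  }, numeric(1))
}

# odd position implied by grouping the closest pair; NA on tie
oracle_os <- function(instance, space) {
  d <- oracle_pair_distances(instance, space)
  odd <- c(3L, 2L, 1L)
  if (sum(d == min(d)) > 1) NA_integer_ else odd[which.min(d)]
}

oracle_ud <- function(instance, space, dim) {
  co <- space$coords
  v <- vapply(instance, function(id) co[[dim]][co$stimulus == id], numeric(1))
  d <- c(abs(v[1] - v[2]), abs(v[1] - v[3]), abs(v[2] - v[3]))
  odd <- c(3L, 2L, 1L)
  if (sum(d == min(d)) > 1) NA_integer_ else odd[which.min(d)]
}

# naive per-trial strategy match recount
oracle_counts <- function(trials, space) {
  strategies <- c("UD_CHROMA", "UD_BRIGHTNESS", "OS", "ID")
  counts <- c(UD_CHROMA = 0, UD_BRIGHTNESS = 0, OS = 0, ID = 0,
              BIAS_LEFT = 0, BIAS_MIDDLE = 0, BIAS_RIGHT = 0)
  for (i in seq_len(nrow(trials))) {
    inst <- c(trials$left[i], trials$middle[i], trials$right[i])
    r <- trials$response_pos[i]
    preds <- c(UD_CHROMA = oracle_ud(inst, space, "chroma"),
               UD_BRIGHTNESS = oracle_ud(inst, space, "brightness"),
               OS = oracle_os(inst, space),
               ID = triadfit::predict_id(inst, space),
               BIAS_LEFT = 1L, BIAS_MIDDLE = 2L, BIAS_RIGHT = 3L)
    for (s in names(counts))
      if (!is.na(preds[[s]]) && preds[[s]] == r)
        counts[[s]] <- counts[[s]] + 1
  }
  counts
}

# marginal likelihood of a 2 x c count row under a flat-ish Dirichlet(a)
# prior, by dense numerical integration (2 columns -> 1-D integral)
oracle_row_marginal <- function(y, a) {
  stopifnot(length(y) == 2)
  f <- function(th) th^(y[1] + a - 1) * (1 - th)^(y[2] + a - 1) / beta(a, a)
  stats::integrate(f, 0, 1, rel.tol = 1e-12)$value
}

oracle_contingency_bf <- function(counts, a = 1) {
  m1 <- prod(apply(counts, 1, oracle_row_marginal, a = a))
  m0 <- oracle_row_marginal(colSums(counts), a)
  m1 / m0
}

# a triad space whose first three stimuli form an equilateral triangle in
# the weighted space (for tie/abstain checks); remaining stimuli far away
equilateral_space <- function() {
  xy <- rbind(c(0, 0), c(2, 0), c(1, sqrt(3)),
              c(10, 10), c(12, 10), c(10, 12), c(14, 14), c(16, 14))
  triadfit::space_from_coords(xy)
}

# pure-strategy simulation config: every block uses `strategy`
pure_config <- function(strategy, lapse = 0, n = c("100" = 1L, "2000" = 1L),
                        bias_prob = 0) {
  mix <- c(UD_CHROMA = 0, UD_BRIGHTNESS = 0, OS = 0, ID = 0)
  mix[strategy] <- 1
  triadfit::sim_config(
    n_participants = n,
    mixture = list("100" = mix, "2000" = mix),
    lapse = lapse, bias_prob = bias_prob)
}
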