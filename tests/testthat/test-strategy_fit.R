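space <- default_space()
table <- build_prediction_table(space)

sim_one <- function(strategy, lapse = 0, seed = 1, bias_key = NULL) {
  cfg <- pure_config(strategy, lapse = lapse)
  des <- generate_design(seed, space)
  tr <- generate_responses(des, 100, cfg, seed + 1, table, bias_key = bias_key)
  tr$participant <- "P1"
  tr$condition_ms <- 100
  tr
}

test_that("a perfect overall-similarity responder is classified OS with 96 matches", {
  tr <- sim_one("OS")
  fit <- score_participant(tr, table)
  expect_identical(unname(fit$counts[["OS"]]), 96)
  expect_identical(fit$winner, "OS")
  expect_false(fit$tied)
})

test_that("always pressing one key is classified as response bias", {
  tr <- sim_one("OS", bias_key = 1)
  fit <- score_participant(tr, table)
  expect_identical(unname(fit$counts[["BIAS_LEFT"]]), 96)
  expect_identical(fit$winner, "Bias")
  expect_identical(fit$detail, "left")
})

test_that("match counts equal an independent per-trial recount, even at high lapse", {
  for (seed in 1:3) {
    tr <- sim_one("OS", lapse = 0.5, seed = seed)
    fit <- score_participant(tr, table)
    expect_equal(fit$counts, oracle_counts(tr, space))
  }
})

test_that("block fits recover the generating strategy and flag ties", {
  tr <- sim_one("UD_BRIGHTNESS")
  bf <- score_blocks(tr, table)
  expect_identical(nrow(bf), 12L)
  expect_true(all(bf$winner == "UD"))
  expect_true(all(bf$UD_BRIGHTNESS == 8))

  # construct a literal tie: on the 4 trials where OS and brightness-UD
  # agree, answer the common prediction (both +4); on the 4 disagreeing
  # trials give OS its prediction twice and brightness-UD twice (6 vs 6)
  des <- tr[tr$block == 1, ]
  pred <- as.data.frame(table)
  idx <- match(paste(des$left, des$middle, des$right),
               paste(pred$left, pred$middle, pred$right))
  agree <- which(pred$OS[idx] == pred$UD_BRIGHTNESS[idx])
  disagree <- setdiff(seq_len(8), agree)
  expect_length(agree, 4L)
  resp <- pred$OS[idx]
  resp[disagree[3:4]] <- pred$UD_BRIGHTNESS[idx][disagree[3:4]]
  des$response_pos <- resp
  bf1 <- score_blocks(des, table)
  expect_identical(max(bf1$UD_CHROMA, bf1$UD_BRIGHTNESS), bf1$OS)
  expect_identical(bf1$winner, "TIED")

  expect_error(score_blocks(des[1:5, ], table), "expected 8")
})

test_that("mixed simulated blocks match a brute-force recount of winners", {
  cfg <- sim_config(n_participants = c("100" = 2L, "2000" = 1L),
                    lapse = 0.3, bias_prob = 0)
  trials <- generate_participants(cfg, seed = 5, space)
  for (p in unique(trials$participant)) {
    tp <- trials[trials$participant == p, ]
    bf <- score_blocks(tp, table)
    for (b in 1:12) {
      tb <- tp[tp$block == b, ]
      oc <- oracle_counts(tb, space)
      coll <- c(UD = max(oc[["UD_CHROMA"]], oc[["UD_BRIGHTNESS"]]),
                OS = oc[["OS"]], ID = oc[["ID"]])
      top <- names(coll)[coll == max(coll)]
      want <- if (length(top) > 1) "TIED" else top
      expect_identical(bf$winner[bf$block == b], want)
    }
  }
})

test_that("collapsing order does not matter without cross-family ties", {
  tr <- sim_one("OS", lapse = 0.6, seed = 9)
  fit <- score_participant(tr, table)
  raw <- fit$counts
  fam <- c(UD_CHROMA = "UD", UD_BRIGHTNESS = "UD", OS = "OS", ID = "ID",
           BIAS_LEFT = "Bias", BIAS_MIDDLE = "Bias", BIAS_RIGHT = "Bias")
  if (!fit$tied) {
    argmax_first <- fam[[names(raw)[which.max(raw)]]]
    expect_identical(argmax_first, fit$winner)
  }
})

test_that("prevalence summarises per-participant proportions that sum to one", {
  cfg <- pure_config("OS", n = c("100" = 3L, "2000" = 2L))
  trials <- generate_participants(cfg, seed = 3, space)
  fits <- fit_participants(trials, table)
  prev <- summarize_prevalence(fits$blocks)
  expect_equal(prev$table$OS, c(1, 1))
  expect_equal(prev$table$UD, c(0, 0))
  expect_identical(prev$table$n_participants, c(3L, 2L))
  expect_equal(prev$per_participant$UD + prev$per_participant$OS +
                 prev$per_participant$ID, rep(1, 5))
  expect_identical(prev$tie_rate, 0)
})

test_that("participants with only tied blocks are excluded with a warning", {
  bf <- data.frame(participant = rep(c("A", "B"), each = 2),
                   condition_ms = 100, block = c(1, 2, 1, 2),
                   UD_CHROMA = 4, UD_BRIGHTNESS = 4, OS = 4, ID = 0,
                   winner = c("TIED", "TIED", "OS", "UD"))
  expect_warning(prev <- summarize_prevalence(bf), "no non-tied blocks")
  expect_identical(prev$table$n_participants, 1L)
  expect_equal(prev$tie_rate, 0.5)
})

test_that("the UD distribution and trajectory are flat for pure-OS data", {
  cfg <- pure_config("OS", n = c("100" = 3L, "2000" = 2L))
  trials <- generate_participants(cfg, seed = 4, space)
  fits <- fit_participants(trials, table)
  ud <- ud_distribution(fits$blocks)
  expect_true(all(ud$per_participant$ud_blocks == 0))
  expect_true(all(ud$trajectory$prop_ud == 0))
  expect_identical(nrow(ud$trajectory), 24L)  # 12 blocks x 2 conditions
})

test_that("winning match counts decrease with lapse rate on average", {
  mean_win <- function(lapse) {
    tot <- 0
    for (seed in 1:6) {
      tr <- sim_one("OS", lapse = lapse, seed = 100 + seed)
      tot <- tot + max(score_participant(tr, table)$collapsed)
    }
    tot / 6
  }
  expect_true(mean_win(0) > mean_win(0.3))
  expect_true(mean_win(0.3) > mean_win(0.8))
})
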