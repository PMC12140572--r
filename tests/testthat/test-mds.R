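space <- default_space()

test_that("similarity-to-dissimilarity conversion maps the scale endpoints", {
  m <- mean_similarity_ratings()
  d <- similarity_to_dissimilarity(m)
  expect_equal(d["1", "2"], 10 - 4.32)
  expect_true(all(diag(d) == 0))
  # strictly decreasing in similarity: rank order reverses
  off <- upper.tri(m)
  expect_identical(order(m[off]), rev(order(d[off])))
  m2 <- m; m2[1, 2] <- m2[2, 1] <- 11
  expect_error(similarity_to_dissimilarity(m2), "1, 9")
  # endpoint check on a synthetic matrix containing a 9
  m3 <- m; m3[1, 2] <- m3[2, 1] <- 9
  expect_equal(similarity_to_dissimilarity(m3)[1, 2], 1)
})

test_that("exact planar distances are recovered with near-zero stress", {
  set.seed(2)
  X <- matrix(runif(16, 0, 5), 8, 2)
  d <- as.matrix(dist(X))
  sol <- nonmetric_mds(d, metric = "euclidean")
  expect_lt(sol$stress, 0.1)  # percent dialect
  fit <- procrustes_fit(sol$points, scale(X, scale = FALSE))
  expect_gt(cor(c(fit$aligned), c(scale(X, scale = FALSE))), 0.999)
})

test_that("stress is invariant to rotation, reflection and uniform scaling", {
  m <- mean_similarity_ratings()
  d <- similarity_to_dissimilarity(m)
  sol <- nonmetric_mds(d, metric = "euclidean")
  th <- 0.83
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  refl <- diag(c(1, -1))
  for (X in list(sol$points %*% R, 3.7 * sol$points %*% R %*% refl)) {
    s0 <- nonmetric_mds(d, metric = "euclidean", init = X,
                        max_iter = 0)$stress
    expect_equal(s0, sol$stress, tolerance = 1e-8)
  }
})

test_that("stress never increases over iterations for either metric", {
  d <- similarity_to_dissimilarity(mean_similarity_ratings())
  for (metric in c("euclidean", "cityblock")) {
    sol <- nonmetric_mds(d, metric = metric)
    expect_true(sol$converged)
    expect_true(all(diff(sol$stress_history) <= 1e-12))
  }
})

test_that("a degenerate all-equal dissimilarity matrix is flagged", {
  d <- matrix(1, 8, 8); diag(d) <- 0
  sol <- suppressWarnings(nonmetric_mds(d))
  expect_false(sol$converged)
  d2 <- d; d2[1, 2] <- d2[2, 1] <- -1
  expect_error(nonmetric_mds(d2), "positive")
})

test_that("the Euclidean loop agrees with the reference isoMDS implementation", {
  d <- similarity_to_dissimilarity(mean_similarity_ratings())
  ref <- MASS::isoMDS(as.dist(d), k = 2, trace = FALSE)
  sol <- nonmetric_mds(d, metric = "euclidean")
  expect_equal(sol$stress, ref$stress, tolerance = 0.01)
  fit <- procrustes_fit(sol$points, scale(ref$points, scale = FALSE))
  expect_gt(cor(c(fit$aligned), c(scale(ref$points, scale = FALSE))), 0.999)
})

test_that("procrustes recovers a rotated, doubled target exactly", {
  X <- space$scaled
  th <- pi / 2
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Y <- 2 * X %*% R + matrix(c(3, -1), 8, 2, byrow = TRUE)
  fit <- procrustes_fit(Y, X)
  expect_lt(fit$rss, 1e-20)
  expect_equal(unname(fit$aligned), unname(X), tolerance = 1e-10)
  expect_equal(fit$scale, 0.5, tolerance = 1e-10)
  # distance-ratio preservation
  expect_equal(dist(fit$aligned) / dist(Y), rep(0.5, 28),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("procrustes residual matches a brute-force rotation grid search", {
  set.seed(31)
  Y <- matrix(rnorm(16), 8, 2)
  X <- space$scaled
  fit <- procrustes_fit(Y, X, scale = TRUE)
  # oracle: for each rotation/reflection angle, closed-form optimal scale
  # and translation of the centred configurations
  Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
  best <- Inf
  for (refl in c(1, -1)) for (th in seq(0, 2 * pi, length.out = 7200)) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2) %*%
      diag(c(1, refl))
    Yr <- Yc %*% R
    s <- sum(Yr * Xc) / sum(Yr^2)
    best <- min(best, sum((s * Yr - Xc)^2))
  }
  expect_equal(fit$rss, best, tolerance = 1e-4)
  expect_error(procrustes_fit(matrix(rep(1:8, 2), 8, 2), X), "rank")
})

test_that("re-spacing on the design coordinates reproduces the design table", {
  inst <- enumerate_instances(design_triads())
  base <- build_prediction_table(space, inst)
  sol <- structure(list(points = space$scaled, stress = 0,
                        metric = "euclidean", iterations = 0L,
                        converged = TRUE),
                   class = "mds_solution")
  re <- respace_prediction_table(sol, inst, target = space)
  for (s in c("OS", "UD_CHROMA", "UD_BRIGHTNESS"))
    expect_identical(re[[s]], base[[s]])
  # design coordinates keep the identity structure intact
  expect_false(anyNA(re$ID))
})

test_that("re-spacing on perturbed coordinates matches the brute-force oracle and disables ID", {
  set.seed(13)
  inst <- enumerate_instances(design_triads())
  pts <- space$scaled + matrix(rnorm(16, 0, 0.05), 8, 2)
  rownames(pts) <- 1:8
  sol <- structure(list(points = pts, stress = 1, metric = "euclidean",
                        iterations = 1L, converged = TRUE),
                   class = "mds_solution")
  re <- respace_prediction_table(sol, inst, target = space)
  expect_true(all(is.na(re$ID)))
  aligned_space <- space_from_coords(procrustes_fit(pts, space$scaled)$aligned)
  for (k in seq_len(nrow(inst))) {
    i3 <- as.integer(inst[k, c("left", "middle", "right")])
    expect_identical(re$OS[k], oracle_os(i3, aligned_space))
    expect_identical(re$UD_BRIGHTNESS[k],
                     oracle_ud(i3, aligned_space, "brightness"))
  }
})
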