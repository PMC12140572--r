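#' Convert mean similarity ratings to dissimilarities
#'
#' Ratings live on a 1-9 scale (9 = very similar).  The default rule
#' `10 - s` maps the endpoints 1 and 9 onto dissimilarities 9 and 1.  A
#' non-metric analysis only uses the rank order of the dissimilarities, so
#' any strictly decreasing rule gives the same final configuration up to
#' the classical-scaling initialisation; the alternatives are exposed for
#' sensitivity checks.
#'
#' @param m symmetric matrix of mean ratings in \[1, 9\] (diagonal ignored).
#' @param rule `"ten_minus"` (default, `10 - s`), `"max_minus"`
#'   (`max(s) - s`), or `"reciprocal"` (`9 / s`).
#' @return a symmetric dissimilarity matrix with zero diagonal.
#' @export
similarity_to_dissimilarity <- function(m, rule = c("ten_minus", "max_minus",
                                                    "reciprocal")) {
  rule <- match.arg(rule)
  off <- m[row(m) != col(m)]
  if (any(is.na(off)) || any(off < 1 | off > 9))
    stop("ratings must lie in [1, 9]")
  if (!isSymmetric(unname(ifelse(is.na(m), 0, m))))
    stop("similarity matrix must be symmetric")
  d <- switch(rule,
              ten_minus = 10 - m,
              max_minus = max(off) - m,
              reciprocal = 9 / m)
  diag(d) <- 0
  d
}

#' Two-dimensional non-metric multidimensional scaling
#'
#' Kruskal's method: configuration distances (Euclidean or city-block) are
#' monotonically regressed on the dissimilarities (isotonic regression on
#' their rank order), and stress-1
#' \eqn{\sqrt{\sum (d - \hat d)^2 / \sum d^2}} is minimised by gradient
#' descent with a backtracking line search, starting from the classical
#' (Torgerson) scaling solution.  Stress never increases across
#' iterations; convergence is declared when the relative stress decrease
#' falls below `tol`.  Stress is reported multiplied by 100, the dialect
#' in which values such as 0.04 are conventionally printed.
#'
#' @param d symmetric dissimilarity matrix (or `dist`), positive off the
#'   diagonal.
#' @param metric `"euclidean"` or `"cityblock"` configuration distances.
#' @param dims number of dimensions (default 2).
#' @param init optional starting configuration (points x dims); default is
#'   classical scaling of `d`.
#' @param tol relative stress-change convergence tolerance.
#' @param max_iter maximum gradient iterations.
#' @return object of class `mds_solution`: list with `points` (centred
#'   configuration, rownames = labels), `stress` (percent), `metric`,
#'   `iterations`, `converged`, and `stress_history`.
#' @export
nonmetric_mds <- function(d, metric = c("euclidean", "cityblock"), dims = 2,
                          init = NULL, tol = 1e-7, max_iter = 1000) {
  metric <- match.arg(metric)
  dd <- stats::as.dist(d)
  n <- attr(dd, "Size")
  labels <- attr(dd, "Labels")
  if (is.null(labels)) labels <- as.character(seq_len(n))
  dv0 <- as.vector(dd)
  if (any(dv0 <= 0)) stop("dissimilarities must be positive off the diagonal")
  degenerate <- stats::sd(dv0) < 1e-12
  ord <- order(dv0)
  # index pairs in the same order as the dist vector
  ii <- unlist(lapply(seq_len(n - 1), function(j) (j + 1):n))
  jj <- rep(seq_len(n - 1), times = (n - 1):1)

  cdist <- function(X) {
    dx <- X[ii, , drop = FALSE] - X[jj, , drop = FALSE]
    if (metric == "euclidean") sqrt(rowSums(dx^2)) else rowSums(abs(dx))
  }
  stress_parts <- function(dv) {
    dhat <- numeric(length(dv))
    dhat[ord] <- stats::isoreg(dv[ord])$yf
    B <- sum(dv^2)
    list(s = sqrt(sum((dv - dhat)^2) / B), dhat = dhat, B = B)
  }

  X <- if (is.null(init)) {
    stats::cmdscale(dd, k = dims)
  } else {
    as.matrix(init)
  }
  X <- scale(X, scale = FALSE)
  dv <- cdist(X)
  sp <- stress_parts(dv)
  s <- sp$s
  history <- s
  step <- 0.1
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    if (s < 1e-12) { converged <- TRUE; break }
    gd <- ((dv - sp$dhat) - s^2 * dv) / (s * sp$B)
    dx <- X[ii, , drop = FALSE] - X[jj, , drop = FALSE]
    u <- if (metric == "euclidean") dx / pmax(dv, 1e-12) else sign(dx)
    gik <- u * gd
    G <- matrix(0, n, dims)
    for (k in seq_len(dims)) {
      G[, k] <- rowsum(c(gik[, k], -gik[, k]), c(ii, jj), reorder = TRUE)[, 1]
    }
    gn <- sqrt(sum(G^2))
    if (gn < 1e-14) { converged <- TRUE; break }
    size <- sqrt(sum(X^2))
    repeat {
      Xn <- X - (step * size / gn) * G
      spn <- stress_parts(cdist(Xn))
      if (spn$s <= s || step < 1e-12) break
      step <- step / 2
    }
    if (spn$s > s) { converged <- TRUE; break }
    rel <- (s - spn$s) / max(s, 1e-12)
    X <- scale(Xn, scale = FALSE)
    dv <- cdist(X)
    sp <- spn
    s <- spn$s
    history <- c(history, s)
    step <- step * 1.3
    if (rel < tol) { converged <- TRUE; break }
  }
  rownames(X) <- labels
  structure(list(points = X, stress = 100 * s, metric = metric,
                 iterations = length(history) - 1L,
                 converged = converged && !degenerate,
                 stress_history = 100 * history),
            class = "mds_solution")
}

#' @export
print.mds_solution <- function(x, ...) {
  cat(sprintf("Non-metric MDS (%s metric): stress = %.4g after %d iterations%s\n",
              x$metric, x$stress, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Procrustes alignment of a configuration to a target
#'
#' Least-squares rotation/reflection, optional uniform scaling, and
#' translation of `config` onto `target` (correspondence by row/stimulus
#' id), delegated to [vegan::procrustes()].  These transformations
#' preserve the ratios of inter-point Euclidean distances.
#'
#' @param config points x 2 matrix (e.g. `mds_solution$points`).
#' @param target points x 2 matrix of target coordinates, same row order
#'   (e.g. `default_space()$scaled`).
#' @param scale allow uniform scaling (default `TRUE`).
#' @return list with `rotation` (2 x 2 orthogonal), `scale`, `translation`,
#'   `aligned` (transformed `config`), `rss` (residual sum of squares) and
#'   `residuals` (per-point distances to the target).
#' @export
procrustes_fit <- function(config, target, scale = TRUE) {
  config <- as.matrix(config)
  target <- as.matrix(target)
  stopifnot(nrow(config) == nrow(target))
  if (qr(scale(config, scale = FALSE))$rank < ncol(config))
    stop("rank-deficient configuration")
  pr <- vegan::procrustes(target, config, scale = scale, symmetric = FALSE)
  aligned <- fitted(pr)
  res <- sqrt(rowSums((aligned - target)^2))
  names(res) <- rownames(target)
  list(rotation = pr$rotation, scale = pr$scale, translation = pr$translation,
       aligned = aligned, rss = pr$ss, residuals = res)
}

#' Per-stimulus misfit between an MDS solution and the design space
#'
#' Aligns the configuration to the design coordinates by the rigid
#' transformation (rotation/reflection + translation, no rescaling: the
#' recovered psychological space and the weighted design space are on
#' commensurate scales) and returns the per-stimulus residual distances,
#' largest first.  Uniform rescaling is deliberately not applied here:
#' it trades a global aspect-ratio mismatch against the extreme-coordinate
#' stimuli and thereby obscures which stimuli were actually displaced.
#'
#' @inheritParams procrustes_fit
#' @return named numeric vector of residuals, sorted decreasing.
#' @export
procrustes_residual_ranking <- function(config, target) {
  fit <- procrustes_fit(config, target, scale = FALSE)
  sort(fit$residuals, decreasing = TRUE)
}

#' Rebuild the prediction table on MDS-derived coordinates
#'
#' The configuration is aligned to the (weighted) design space so its axes
#' can be read as psychological chroma and brightness, then used as the
#' stimulus space for all response models.  MDS coordinates are continuous,
#' so no stimulus pair is exactly identical on either axis and the identity
#' model abstains on every display.
#'
#' @param solution an `mds_solution` (rows labelled by stimulus id).
#' @param instances displays, as for [build_prediction_table()].
#' @param target space whose weighted coordinates define the axis
#'   orientation (default the built-in design space).
#' @return a `prediction_table` built on the aligned MDS coordinates.
#' @export
respace_prediction_table <- function(solution, instances = enumerate_instances(),
                                     target = default_space()) {
  pts <- if (inherits(solution, "mds_solution")) solution$points else solution
  fit <- procrustes_fit(pts, target$scaled, scale = TRUE)
  build_prediction_table(space_from_coords(fit$aligned), instances)
}
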