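#' Bayes factors and power: the inferential toolbox
#'
#' Implements the Bayes factors used throughout the analysis -- the
#' Gunel-Dickey contingency-table Bayes factor (independent multinomial
#' sampling, rows fixed by design), the JZS two-sample Bayes factor
#' (zero-centred Cauchy prior on the standardised effect), and the
#' replication Bayes factor with a normal prior centred on a previously
#' observed effect -- together with noncentral chi-square / t power
#' functions and the block-trend least-squares regression.
#'
#' @name bayes_stats
NULL

bf_result <- function(bf10, method, prior, error = NA_real_) {
  structure(list(bf10 = bf10, method = method, prior = prior, error = error),
            class = "bf_result")
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("BF10 = %.4g  [%s; %s]\n", x$bf10, x$method, x$prior))
  invisible(x)
}

ldirichlet <- function(a) sum(lgamma(a)) - lgamma(sum(a))

#' Gunel-Dickey contingency-table Bayes factor
#'
#' Bayes factor for association in an r x c table of counts under
#' independent multinomial sampling with row totals fixed by design.
#' Under H1 each row has its own cell-probability vector with a
#' Dirichlet(`a`, ..., `a`) prior; under H0 all rows share one vector with
#' the same prior.  Conjugacy gives the marginal likelihood ratio in
#' closed form via Dirichlet normalising constants:
#' \deqn{BF_{10} = \frac{\prod_i B(y_{i\cdot} + a)/B(a)}{B(y_{\cdot +} + a)/B(a)}}
#' where \eqn{B} is the multivariate beta function over the columns.
#'
#' @param counts matrix of non-negative integer counts (rows = groups).
#' @param a prior concentration (default 1, the conventional default).
#' @return a `bf_result` (`$bf10` > 1 favours association).
#' @export
contingency_bf <- function(counts, a = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0)) stop("empty row in contingency table")
  nc <- ncol(counts)
  l1 <- sum(apply(counts, 1, function(y) {
    ldirichlet(y + a) - ldirichlet(rep(a, nc))
  }))
  l0 <- ldirichlet(colSums(counts) + a) - ldirichlet(rep(a, nc))
  bf_result(exp(l1 - l0), "gunel_dickey",
            sprintf("independent multinomial, rows fixed, a = %g", a),
            error = .Machine$double.eps * 100)
}

#' JZS two-sample Bayes factor
#'
#' Default Bayesian two-sample t test: the standardised group difference
#' \eqn{\delta} has a Cauchy(0, `rscale`) prior under H1, and
#' \deqn{BF_{10} = \frac{\int f_{t_\nu}(t \mid \delta\sqrt{n_e})\,
#'   \mathrm{Cauchy}(\delta; 0, r)\, d\delta}{f_{t_\nu}(t \mid 0)}}
#' with \eqn{n_e = n_1 n_2/(n_1+n_2)} and \eqn{\nu = n_1+n_2-2}, evaluated
#' by adaptive quadrature over the noncentral-t likelihood of the observed
#' t statistic.  The directional variant restricts the prior to
#' \eqn{\delta > 0} and renormalises.
#'
#' @param x,y numeric response vectors for the two groups.
#' @param rscale Cauchy prior scale (default \eqn{\sqrt{2}/2}).
#' @param directional if `TRUE`, H1 puts all prior mass on positive
#'   effects (`mean(x) > mean(y)` direction).
#' @return a `bf_result` with the quadrature error estimate.
#' @export
jzs_ttest_bf <- function(x, y, rscale = sqrt(2) / 2, directional = FALSE) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2 || n2 < 2) stop("each group needs n >= 2")
  v <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (v <= 0) stop("zero pooled variance")
  ne <- n1 * n2 / (n1 + n2)
  tstat <- (mean(x) - mean(y)) / sqrt(v * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  # dt() with an ncp warns that only ~1e-12 absolute accuracy is reached;
  # that is ample here and the warning would fire once per quadrature node
  lik <- function(delta)
    suppressWarnings(stats::dt(tstat, df, ncp = delta * sqrt(ne)))
  if (directional) {
    num <- stats::integrate(function(d) lik(d) * 2 * stats::dcauchy(d, 0, rscale),
                            0, Inf, rel.tol = 1e-10)
  } else {
    num <- stats::integrate(function(d) lik(d) * stats::dcauchy(d, 0, rscale),
                            -Inf, Inf, rel.tol = 1e-10)
  }
  bf_result(num$value / stats::dt(tstat, df),
            "jzs",
            sprintf("Cauchy(0, %.4g)%s on standardised effect", rscale,
                    if (directional) ", positive half" else ""),
            error = num$abs.error / stats::dt(tstat, df))
}

#' Replication Bayes factor with a normal prior on the effect
#'
#' Following the replication-test convention, H1's prior on the true
#' effect is normal, centred on the effect observed in the original study
#' with standard deviation half that effect.  The observed replication
#' effect is modelled as normal around the true effect with its standard
#' error, so
#' \deqn{BF_{10} = \frac{\int N(e; \delta, SE)\, N(\delta; m, s)\,
#'   d\delta}{N(e; 0, SE)}.}
#' The numerator is evaluated by quadrature; the conjugate closed form
#' \eqn{N(e; m, \sqrt{SE^2 + s^2})} is computed as an internal
#' cross-check and the discrepancy reported as the numerical error.
#'
#' @param effect observed effect in the new data.
#' @param se standard error of `effect`.
#' @param prior_mean prior centre (the originally observed effect).
#' @param prior_sd prior SD (default `prior_mean / 2`).
#' @param tails 2 for the full normal prior, 1 for the positive half.
#' @return a `bf_result`.
#' @export
dienes_bf <- function(effect, se, prior_mean, prior_sd = abs(prior_mean) / 2,
                      tails = 2) {
  stopifnot(is.finite(effect), is.finite(se), se > 0,
            is.finite(prior_mean), prior_sd > 0, tails %in% c(1, 2))
  prior <- if (tails == 2) {
    function(d) stats::dnorm(d, prior_mean, prior_sd)
  } else {
    function(d) ifelse(d >= 0, stats::dnorm(d, prior_mean, prior_sd) /
                         stats::pnorm(0, prior_mean, prior_sd,
                                      lower.tail = FALSE), 0)
  }
  num <- stats::integrate(function(d) stats::dnorm(effect, d, se) * prior(d),
                          -Inf, Inf, rel.tol = 1e-12)
  bf10 <- num$value / stats::dnorm(effect, 0, se)
  closed <- if (tails == 2) {
    stats::dnorm(effect, prior_mean, sqrt(se^2 + prior_sd^2)) /
      stats::dnorm(effect, 0, se)
  } else NA_real_
  bf_result(bf10, "dienes",
            sprintf("Normal(%.4g, %.4g), %d-tailed", prior_mean, prior_sd,
                    tails),
            error = if (is.na(closed)) num$abs.error else abs(bf10 - closed))
}

#' Power of the chi-square test of association
#'
#' Noncentral chi-square formulation: with effect size `w` and total N the
#' noncentrality parameter is \eqn{N w^2}.
#'
#' @param w Cohen's w effect size.
#' @param N total sample size.
#' @param df degrees of freedom of the test.
#' @param alpha significance level.
#' @return power (probability of rejection).
#' @export
power_chisq <- function(w, N, df, alpha = 0.05) {
  stopifnot(w >= 0, N > 0, df >= 1, alpha > 0, alpha < 1)
  crit <- stats::qchisq(1 - alpha, df)
  stats::pchisq(crit, df, ncp = N * w^2, lower.tail = FALSE)
}

#' Power of the two-sample t test
#'
#' @param d Cohen's d.
#' @param n1,n2 group sizes (`n2` defaults to `n1`).
#' @param alpha significance level (two-sided).
#' @return power.
#' @export
power_ttest <- function(d, n1, n2 = n1, alpha = 0.05) {
  stopifnot(n1 >= 2, n2 >= 2, alpha > 0, alpha < 1)
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  crit <- stats::qt(1 - alpha / 2, df)
  suppressWarnings(stats::pt(crit, df, ncp = ncp, lower.tail = FALSE) +
                     stats::pt(-crit, df, ncp = ncp))
}

#' Linear trend of unidimensional responding over test blocks
#'
#' Ordinary least squares on the condition-level block trajectory: the
#' proportion of (non-tied) blocks won by the unidimensional model,
#' regressed on test block, presentation time, and their interaction
#' (12 blocks x 2 conditions = 24 rows, 4 parameters, residual df 20).
#' Presentation time is entered as a short-vs-long indicator (0 = short,
#' 1 = long) so its coefficient is the long-minus-short difference.
#'
#' @param trajectory data frame `condition_ms`, `block`, `prop_ud` (as
#'   produced by [ud_distribution()]`$trajectory`).
#' @return list with `coefficients` (estimate, SE, t, p per term) and
#'   `df_residual`.
#' @export
block_trend_ols <- function(trajectory) {
  stopifnot(all(c("condition_ms", "block", "prop_ud") %in% names(trajectory)))
  conds <- sort(unique(trajectory$condition_ms))
  if (length(conds) != 2) stop("need exactly two conditions")
  dat <- data.frame(
    prop_ud = trajectory$prop_ud,
    block = trajectory$block,
    long = as.numeric(trajectory$condition_ms == max(conds)))
  fit <- stats::lm(prop_ud ~ block * long, data = dat)
  sm <- summary(fit)
  list(coefficients = sm$coefficients, df_residual = fit$df.residual)
}
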