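#' Bootstrap standard error of a parameter
#'
#' The standard error is the sample standard deviation of the bootstrap
#' replicates,
#' \deqn{se(\hat\theta^*) = \sqrt{\frac{\sum_b (\hat\theta^*_{(b)} -
#'   \bar\theta^*)^2}{B - 1}},}
#' with \eqn{\bar\theta^*} the replicate mean and a \eqn{B - 1} denominator.
#'
#' @param replicates numeric vector of at least two replicate estimates.
#' @return Non-negative standard error.
#' @export
bootstrap_se <- function(replicates) {
  if (length(replicates) < 2)
    stop_spec("bootstrap_se() needs at least 2 replicates")
  m <- mean(replicates)
  sqrt(sum((replicates - m)^2) / (length(replicates) - 1))
}

#' Bootstrap t-test for a loading or path coefficient
#'
#' Tests whether a parameter differs from zero: \eqn{t = \hat\theta /
#' se(\hat\theta)}, with a two-tailed p-value from the Student t
#' distribution with `df` degrees of freedom (the number of observations
#' minus one). For large `df` the 5% critical value approaches 1.96;
#' exact t quantiles are always used here.
#'
#' @param estimate original-sample parameter estimate.
#' @param se bootstrap standard error, strictly positive.
#' @param df degrees of freedom.
#' @param alpha significance level (default 0.05, two-tailed).
#' @return List with `t`, `p` and `significant`.
#' @export
t_test <- function(estimate, se, df, alpha = 0.05) {
  if (!is.finite(se) || se <= 0)
    stop_spec("t_test() requires a strictly positive standard error")
  t <- estimate / se
  p <- 2 * stats::pt(-abs(t), df = df)
  list(t = t, p = p, significant = p < alpha)
}

#' Bootstrap inference for loadings and path coefficients
#'
#' Draws `B` resamples of the `n` observations with replacement, refits the
#' full principal-component estimator on each resample, and computes per
#' parameter the bootstrap standard error, t-statistic and two-tailed
#' p-value (Student t, `n - 1` degrees of freedom).
#'
#' Principal-component directions are sign-ambiguous, so a resample can flip
#' a latent's orientation and corrupt the replicate spread. Each replicate is
#' therefore sign-aligned to the original sample: a latent's orientation is
#' flipped when the dot product of its replicate weight vector with the
#' original weight vector is negative; the flip propagates to that block's
#' loadings and to every path coefficient touching the latent.
#'
#' Resamples on which the estimator degenerates (for example a resampled
#' column with zero variance) are discarded and counted; more than 10%
#' discarded is an error. Given the same seed the resample stream, and hence
#' the result, is fully reproducible.
#'
#' @param data raw indicator table.
#' @param spec a `pls_model`.
#' @param B number of bootstrap resamples (default 2000).
#' @param seed integer RNG seed; required, no hidden global state.
#' @param alpha two-tailed significance level (default 0.05).
#' @return An object of class `pls_bootstrap`: a list with `results` (data
#'   frame: parameter, type, source/target or indicator, estimate, se, t, p,
#'   significant, testable), `replicates` (replicate-by-parameter matrix),
#'   `n_failed`, `B`, `df`, `alpha`, `seed` and the original `fit`.
#' @examples
#' cfg <- default_sim_config(n_obs = 60, seed = 3)
#' dat <- simulate_indicator_data(cfg)
#' bt <- pls_bootstrap(dat, cfg$spec, B = 50, seed = 9)
#' head(bt$results)
#' @export
pls_bootstrap <- function(data, spec, B = 2000, seed, alpha = 0.05) {
  stopifnot(inherits(spec, "pls_model"))
  if (missing(seed)) stop_spec("pls_bootstrap() requires an explicit seed")
  if (B < 2) stop_spec("B must be at least 2")
  fit <- pls_fit(data, spec)
  x <- fit$data
  n <- nrow(x)
  layout <- fit_layout(spec)
  L <- length(layout$blocks)

  orig <- fit_core(x, layout)
  p_ind <- length(layout$indicator_names)
  p_path <- nrow(layout$edges)
  npar <- p_ind + p_path
  param_names <- c(layout$indicator_names,
                   paste0(spec$paths[, 1], " -> ", spec$paths[, 2]))

  set.seed(seed)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n)

  reps <- matrix(NA_real_, B, npar)
  failed <- 0L
  for (b in seq_len(B)) {
    core <- tryCatch(fit_core(x[idx[, b], , drop = FALSE], layout),
                     plsipa_error = function(e) NULL,
                     error = function(e) NULL)
    if (is.null(core)) { failed <- failed + 1L; next }
    # individual sign-change correction against the original solution
    flip <- vapply(seq_len(L), function(j)
      if (sum(core$weights[[j]] * orig$weights[[j]]) < 0) -1 else 1, 0)
    loadings <- core$loadings
    for (j in seq_len(L))
      loadings[layout$blocks[[j]]] <- loadings[layout$blocks[[j]]] * flip[j]
    paths <- core$paths * flip[layout$edges[, 1]] * flip[layout$edges[, 2]]
    reps[b, ] <- c(loadings, paths)
  }
  if (failed > 0.1 * B)
    stop_num("%d of %d bootstrap resamples failed (> 10%%)", failed, B)
  reps <- reps[stats::complete.cases(reps), , drop = FALSE]
  colnames(reps) <- param_names

  estimates <- c(orig$loadings, orig$paths)
  se <- apply(reps, 2, bootstrap_se)
  testable <- se > 1e-12
  tval <- ifelse(testable, estimates / se, NA_real_)
  pval <- ifelse(testable, 2 * stats::pt(-abs(tval), df = n - 1), NA_real_)
  res <- data.frame(
    parameter = param_names,
    type = c(rep("loading", p_ind), rep("path", p_path)),
    estimate = estimates,
    se = se,
    t = tval,
    p = pval,
    significant = ifelse(testable, pval < alpha, NA),
    testable = testable,
    stringsAsFactors = FALSE, row.names = NULL)

  structure(list(results = res, replicates = reps, n_failed = failed,
                 B = B, df = n - 1, alpha = alpha, seed = seed, fit = fit),
            class = "pls_bootstrap")
}

#' @export
print.pls_bootstrap <- function(x, ...) {
  f3 <- function(v) ifelse(is.na(v), "   -  ",
                           formatC(round_half_up(v), format = "f",
                                   digits = 3))
  cat(sprintf("Bootstrap inference: B = %d (%d failed), df = %d, alpha = %g\n",
              x$B, x$n_failed, x$df, x$alpha))
  r <- x$results
  cat(sprintf("  %-28s %-8s %8s %8s %8s  %s\n", "parameter", "type",
              "estimate", "t", "p", ""))
  for (i in seq_len(nrow(r)))
    cat(sprintf("  %-28s %-8s %8s %8s %8s  %s\n", r$parameter[i], r$type[i],
                f3(r$estimate[i]), f3(r$t[i]), f3(r$p[i]),
                if (!r$testable[i]) "non-testable"
                else if (isTRUE(r$significant[i])) "significant" else ""))
  invisible(x)
}
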