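#' Average variance extracted (AVE)
#'
#' Convergent-validity statistic for a reflective block:
#' \deqn{AVE = \frac{\sum_i \lambda_i^2}{\sum_i \lambda_i^2 +
#'   \sum_i \mathrm{var}(\varepsilon_i)}, \qquad
#'   \mathrm{var}(\varepsilon_i) = 1 - \lambda_i^2.}
#' Under that error definition the expression simplifies algebraically to
#' the mean squared loading; the full formula is implemented. The usual
#' acceptance threshold is AVE > 0.5 (the block explains at least half of
#' its indicators' variance).
#'
#' @param loadings numeric vector of outer loadings, each in `[-1, 1]`.
#' @return AVE in `[0, 1]`.
#' @export
average_variance_extracted <- function(loadings) {
  check_loadings(loadings)
  sl2 <- sum(loadings^2)
  sl2 / (sl2 + sum(1 - loadings^2))
}

#' Composite reliability
#'
#' Internal-consistency statistic for a reflective block:
#' \deqn{\rho_c = \frac{(\sum_i \lambda_i)^2}{(\sum_i \lambda_i)^2 +
#'   \sum_i (1 - \lambda_i^2)}.}
#' Unlike Cronbach's alpha it does not assume equal indicator weights.
#' Blocks with \eqn{\rho_c > 0.7} are conventionally considered reliable.
#'
#' @inheritParams average_variance_extracted
#' @return Composite reliability in `[0, 1]`.
#' @export
composite_reliability <- function(loadings) {
  check_loadings(loadings)
  s2 <- sum(loadings)^2
  s2 / (s2 + sum(1 - loadings^2))
}

check_loadings <- function(loadings) {
  if (length(loadings) == 0) stop_spec("loadings vector is empty")
  if (!is.numeric(loadings) || any(!is.finite(loadings)))
    stop_spec("loadings must be finite numerics")
  if (any(abs(loadings) > 1 + 1e-8))
    stop_spec("|loading| > 1: loadings are correlations")
  invisible(loadings)
}

#' Indicator validity by loading threshold
#'
#' An indicator is declared valid when its outer loading strictly exceeds
#' the threshold (default 0.5); a loading exactly at the threshold fails.
#'
#' @param loadings named numeric vector of outer loadings.
#' @param threshold validity cut-off in (0, 1).
#' @return Named logical vector.
#' @export
loading_validity <- function(loadings, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stop_spec("threshold must be in (0, 1)")
  loadings > threshold
}

#' Cross-loadings and discriminant flags
#'
#' Correlates every indicator with every latent score. Discriminant validity
#' at the indicator level requires the own-latent entry to strictly exceed
#' all other entries in the indicator's row; ties fail.
#'
#' @param data standardized indicator matrix.
#' @param scores standardized score matrix.
#' @param spec a `pls_model`.
#' @return List with `table` (indicator x latent correlation matrix) and
#'   `discriminant` (named logical per indicator).
#' @export
cross_loadings <- function(data, scores, spec) {
  data <- as.matrix(data)
  ind <- indicator_names(spec)
  tab <- stats::cor(data[, ind, drop = FALSE], scores)
  map <- indicator_latent_map(spec)
  disc <- stats::setNames(logical(length(ind)), ind)
  for (i in ind) {
    own <- tab[i, map[[i]]]
    disc[i] <- own > max(tab[i, setdiff(colnames(tab), map[[i]])])
  }
  list(table = tab, discriminant = disc)
}

#' Fornell-Larcker discriminant-validity matrix
#'
#' Builds the latent-by-latent matrix whose diagonal holds the square root
#' of each block's AVE and whose off-diagonal holds the latent score
#' correlations. A latent passes when its \eqn{\sqrt{AVE}} strictly exceeds
#' the absolute value of every off-diagonal entry in its row/column.
#'
#' @param ave named numeric vector, latent -> AVE.
#' @param score_correlations symmetric latent score correlation matrix with
#'   unit diagonal, dimnames matching `names(ave)`.
#' @return List with `matrix` and `pass` (named logical per latent).
#' @export
fornell_larcker <- function(ave, score_correlations) {
  R <- as.matrix(score_correlations)
  if (nrow(R) != ncol(R) || max(abs(R - t(R))) > 1e-8 ||
      max(abs(diag(R) - 1)) > 1e-8)
    stop_spec("score_correlations must be symmetric with unit diagonal")
  ln <- rownames(R)
  if (!setequal(names(ave), ln))
    stop_spec("names of `ave` must match the correlation matrix")
  M <- R
  diag(M) <- sqrt(ave[ln])
  pass <- stats::setNames(logical(length(ln)), ln)
  for (j in ln) {
    off <- abs(R[j, setdiff(ln, j)])
    pass[j] <- if (length(off)) sqrt(ave[[j]]) > max(off) else TRUE
  }
  list(matrix = M, pass = pass)
}

#' Coefficients of determination for the structural equations
#'
#' For each endogenous latent, \eqn{R^2 = \sum_h \hat\beta_h \,
#' \mathrm{corr}(parent_h, child)} over its direct parents; on standardized
#' scores this equals the OLS coefficient of determination. Effect-size
#' categories follow the conventional anchors: weak below 0.33, moderate in
#' `[0.33, 0.67)`, strong at or above 0.67.
#'
#' @param scores standardized score matrix.
#' @param spec a `pls_model`.
#' @param coefs data frame from [path_coefficients()].
#' @return Data frame with columns `latent`, `r_squared`, `category`; one
#'   row per endogenous latent with at least one parent.
#' @export
r_squared <- function(scores, spec, coefs) {
  par <- parents_of(spec)
  endo <- names(par)[lengths(par) > 0]
  out <- data.frame(latent = endo, r_squared = NA_real_,
                    category = NA_character_, stringsAsFactors = FALSE)
  for (nm in endo) {
    b <- coefs$estimate[coefs$target == nm]
    b <- b[match(par[[nm]], coefs$source[coefs$target == nm])]
    r2 <- sum(b * stats::cor(scores[, par[[nm]], drop = FALSE], scores[, nm]))
    i <- match(nm, out$latent)
    out$r_squared[i] <- r2
    out$category[i] <- r2_category(r2)
  }
  out
}

r2_category <- function(r2) {
  if (r2 >= 0.67) "strong" else if (r2 >= 0.33) "moderate" else "weak"
}

#' Global goodness of fit
#'
#' \eqn{GoF = \sqrt{\overline{AVE} \times \overline{R^2}}}: the square root
#' of the product of the mean AVE and the mean R-squared. The caller chooses
#' which AVE and R-squared values enter the means.
#'
#' @param ave_values numeric vector of AVE values.
#' @param r2_values numeric vector of R-squared values.
#' @return GoF in `[0, 1]`.
#' @export
gof <- function(ave_values, r2_values) {
  if (!length(ave_values) || !length(r2_values))
    stop_spec("gof() needs non-empty AVE and R-squared vectors")
  sqrt(mean(ave_values) * mean(r2_values))
}

#' Q-squared predictive relevance
#'
#' \eqn{Q^2 = 1 - \prod_j (1 - R_j^2)} over the endogenous latents' R-squared
#' values; values close to 1 indicate good predictive relevance.
#'
#' @param r2_values numeric vector of R-squared values, each in `[0, 1]`.
#' @return Q-squared in `[0, 1]`.
#' @export
q_squared <- function(r2_values) {
  if (!length(r2_values)) stop_spec("q_squared() needs at least one value")
  if (any(r2_values < -1e-12 | r2_values > 1 + 1e-12))
    stop_spec("R-squared values must lie in [0, 1]")
  1 - prod(1 - pmin(pmax(r2_values, 0), 1))
}

#' Evaluate a fitted model
#'
#' Assembles the full measurement- and structural-model evaluation report:
#' outer loadings with validity flags, AVE and composite reliability per
#' reflective block, cross-loadings with discriminant flags, the
#' Fornell-Larcker matrix, per-equation R-squared with effect-size
#' categories, the global GoF (over all reflective blocks' AVEs and all
#' R-squared values) and Q-squared. Formative blocks are skipped for
#' AVE/composite reliability with a warning, since those statistics are
#' defined only for reflective measurement.
#'
#' @param fit a `pls_fit`.
#' @param loading_threshold validity cut-off for loadings (default 0.5).
#' @return An object of class `pls_evaluation`.
#' @export
pls_evaluate <- function(fit, loading_threshold = 0.5) {
  stopifnot(inherits(fit, "pls_fit"))
  spec <- fit$spec
  map <- indicator_latent_map(spec)
  reflective <- vapply(spec$latents, function(l) l$mode == "reflective", TRUE)
  if (!all(reflective))
    warning("AVE/composite reliability are reported for reflective blocks ",
            "only; formative block(s): ",
            paste(latent_names(spec)[!reflective], collapse = ", "),
            call. = FALSE)

  load_tab <- data.frame(indicator = names(fit$loadings),
                         latent = unname(map[names(fit$loadings)]),
                         loading = unname(fit$loadings),
                         valid = unname(loading_validity(fit$loadings,
                                                         loading_threshold)),
                         stringsAsFactors = FALSE)

  refl_names <- latent_names(spec)[reflective]
  ave <- vapply(refl_names, function(nm)
    average_variance_extracted(fit$loadings[spec$latents[[
      match(nm, latent_names(spec))]]$indicators]), 0)
  cr <- vapply(refl_names, function(nm)
    composite_reliability(fit$loadings[spec$latents[[
      match(nm, latent_names(spec))]]$indicators]), 0)

  cl <- cross_loadings(fit$data_std, fit$scores, spec)
  score_cor <- stats::cor(fit$scores)
  fl <- if (all(reflective)) fornell_larcker(ave, score_cor) else NULL

  r2 <- r_squared(fit$scores, spec, fit$path_coefficients)
  g <- if (nrow(r2)) gof(ave, r2$r_squared) else NA_real_
  q2 <- if (nrow(r2)) q_squared(r2$r_squared) else NA_real_

  structure(list(
    loadings = load_tab,
    ave = data.frame(latent = refl_names, ave = unname(ave),
                     valid = unname(ave > 0.5), stringsAsFactors = FALSE),
    composite_reliability = data.frame(latent = refl_names,
                                       rho_c = unname(cr),
                                       reliable = unname(cr > 0.7),
                                       stringsAsFactors = FALSE),
    cross_loadings = cl$table,
    discriminant = cl$discriminant,
    fornell_larcker = fl,
    r_squared = r2,
    gof = g,
    q_squared = q2,
    mean_ave = mean(ave),
    mean_r2 = if (nrow(r2)) mean(r2$r_squared) else NA_real_,
    loading_threshold = loading_threshold), class = "pls_evaluation")
}

#' @export
print.pls_evaluation <- function(x, ...) {
  f3 <- function(v) formatC(round_half_up(v), format = "f", digits = 3)
  cat("Measurement model\n")
  cat("  Outer loadings (valid if >", x$loading_threshold, "):\n")
  for (i in seq_len(nrow(x$loadings)))
    cat(sprintf("    %-10s %-28s %s  %s\n", x$loadings$indicator[i],
                x$loadings$latent[i], f3(x$loadings$loading[i]),
                if (x$loadings$valid[i]) "valid" else "not valid"))
  cat("  AVE (valid if > 0.5) / composite reliability (reliable if > 0.7):\n")
  for (i in seq_len(nrow(x$ave)))
    cat(sprintf("    %-28s AVE %s (%s)   rho_c %s (%s)\n", x$ave$latent[i],
                f3(x$ave$ave[i]),
                if (x$ave$valid[i]) "valid" else "not valid",
                f3(x$composite_reliability$rho_c[i]),
                if (x$composite_reliability$reliable[i]) "reliable"
                else "not reliable"))
  if (nrow(x$r_squared)) {
    cat("Structural model\n")
    for (i in seq_len(nrow(x$r_squared)))
      cat(sprintf("    R2(%s) = %s (%s)\n", x$r_squared$latent[i],
                  f3(x$r_squared$r_squared[i]), x$r_squared$category[i]))
    cat(sprintf("    GoF = %s,  Q2 = %s\n", f3(x$gof), f3(x$q_squared)))
  }
  invisible(x)
}
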