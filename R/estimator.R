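#' Column-standardize an indicator table
#'
#' Centers each column to mean 0 and scales to unit sample variance
#' (denominator \eqn{n - 1}). The estimator works entirely on standardized
#' data; location and scale of raw indicators are absorbed here, which is why
#' latent scores are invariant under affine transformations of the inputs.
#'
#' @param x numeric matrix or data frame (rows = observations).
#' @return Numeric matrix with the same dimnames.
#' @export
standardize_data <- function(x) {
  x <- as_data_matrix(x)
  n <- nrow(x)
  if (n < 2) stop_num("standardization needs at least 2 observations")
  m <- colMeans(x)
  xc <- sweep(x, 2, m)
  v <- colSums(xc^2) / (n - 1)
  if (any(v < 1e-24)) {
    bad <- colnames(x)[which(v < 1e-24)[1]]
    stop_num("column '%s' has zero variance and cannot be standardized",
             if (is.null(bad)) as.character(which.min(v)) else bad)
  }
  xc * rep(1 / sqrt(v), each = n)
}

as_data_matrix <- function(x) {
  if (is.data.frame(x)) {
    nonnum <- !vapply(x, is.numeric, TRUE)
    if (any(nonnum))
      stop_spec("non-numeric column(s): %s",
                paste(names(x)[nonnum], collapse = ", "))
    x <- as.matrix(x)
  }
  if (!is.matrix(x) || !is.numeric(x))
    stop_spec("data must be a numeric matrix or data frame")
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)[1, ]
    stop_spec("missing value at row %d, column '%s': complete cases required",
              idx[1], colnames(x)[idx[2]] %||% as.character(idx[2]))
  }
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic sign convention for an eigenvector: make the first component
# of (numerically) largest magnitude positive. A relative tolerance absorbs
# 1-ulp ties so that different numerical routes to the same direction orient
# identically.
orient_eigenvector <- function(v) {
  k <- which(abs(v) >= max(abs(v)) * (1 - 1e-8))[1]
  if (v[k] < 0) -v else v
}

#' First-principal-component block weights
#'
#' The weighting scheme is one-shot: for a standardized indicator block the
#' outer weight vector is the dominant eigenvector of the block covariance
#' matrix (\eqn{X^\top X w = \lambda w}), normalized so that the sum of the
#' absolute values of its components equals one. There is no inner/outer
#' iteration loop and no convergence threshold; the principal-component
#' direction is the final weight vector.
#'
#' Eigenvectors are sign-ambiguous, so the direction is oriented
#' deterministically: the component of largest absolute value is made
#' positive (first such component on ties).
#'
#' @param block standardized observation-by-indicator matrix (one block).
#' @return List with `weights` (abs-sum-1, named by indicator),
#'   `eigenvector` (unit Euclidean norm), `eigenvalue` and
#'   `explained_proportion` (eigenvalue over the covariance trace).
#' @export
pca_block_weights <- function(block) {
  block <- as.matrix(block)
  n <- nrow(block); p <- ncol(block)
  nm <- colnames(block)
  if (p == 1L) {
    v <- stats::var(block[, 1])
    if (v < 1e-24) stop_num("single-indicator block has zero variance")
    return(list(weights = stats::setNames(1, nm), eigenvector = 1,
                eigenvalue = v, explained_proportion = 1))
  }
  C <- crossprod(block) / (n - 1)
  if (all(abs(C) < 1e-24))
    stop_num("indicator block is rank zero (all-zero covariance)")
  e <- eigen(C, symmetric = TRUE)
  vec <- orient_eigenvector(e$vectors[, 1L])
  vals <- pmax(e$values, 0)
  list(weights = stats::setNames(vec / sum(abs(vec)), nm),
       eigenvector = vec,
       eigenvalue = vals[1],
       explained_proportion = vals[1] / sum(vals))
}

#' Latent variable scores
#'
#' Computes \eqn{t = X w} per block on standardized data, then re-standardizes
#' each score column to mean 0 / unit variance so that downstream loadings and
#' path coefficients are standardized quantities. The abs-sum-1 weights are
#' kept separately for the importance-performance stage.
#'
#' @param data standardized indicator matrix (all blocks).
#' @param spec a `pls_model`.
#' @param weights named list, latent -> abs-sum-1 weight vector.
#' @return Observation-by-latent matrix of standardized scores.
#' @export
latent_scores <- function(data, spec, weights) {
  data <- as.matrix(data)
  n <- nrow(data)
  ln <- latent_names(spec)
  scores <- matrix(0, n, length(ln), dimnames = list(rownames(data), ln))
  for (l in spec$latents) {
    miss <- setdiff(l$indicators, colnames(data))
    if (length(miss))
      stop_spec("indicator(s) missing from data: %s",
                paste(miss, collapse = ", "))
    w <- weights[[l$name]]
    t_raw <- data[, l$indicators, drop = FALSE] %*% w
    sdt <- sqrt(sum((t_raw - mean(t_raw))^2) / (n - 1))
    if (sdt < 1e-12)
      stop_num("latent '%s' has a degenerate (zero-variance) score", l$name)
    scores[, l$name] <- (t_raw - mean(t_raw)) / sdt
  }
  scores
}

#' Outer loadings
#'
#' The outer loading of an indicator is its Pearson correlation with the
#' standardized score of its own latent variable; for reflective blocks this
#' estimates the loading \eqn{\lambda} of the measurement model.
#'
#' @param data standardized indicator matrix.
#' @param scores standardized score matrix from [latent_scores()].
#' @param spec a `pls_model`.
#' @return Named numeric vector over all indicators, values in `[-1, 1]`.
#' @export
outer_loadings <- function(data, scores, spec) {
  data <- as.matrix(data)
  map <- indicator_latent_map(spec)
  out <- stats::setNames(numeric(length(map)), names(map))
  for (i in seq_along(map))
    out[i] <- stats::cor(data[, names(map)[i]], scores[, map[[i]]])
  out
}

#' Structural path coefficients by per-equation OLS
#'
#' For each endogenous latent, its standardized score is regressed jointly on
#' the scores of all its direct parents (one multiple regression per
#' structural equation, no intercept needed on standardized scores). Because
#' the graph is recursive (acyclic), the per-equation fits estimate the full
#' system.
#'
#' @param scores standardized score matrix.
#' @param spec a `pls_model`.
#' @return Data frame with columns `source`, `target`, `estimate`, one row
#'   per declared path.
#' @export
path_coefficients <- function(scores, spec) {
  par <- parents_of(spec)
  out <- data.frame(source = spec$paths[, 1], target = spec$paths[, 2],
                    estimate = rep(NA_real_, nrow(spec$paths)),
                    stringsAsFactors = FALSE)
  for (tgt in unique(out$target)) {
    P <- scores[, par[[tgt]], drop = FALSE]
    qr_p <- qr(P)
    if (qr_p$rank < ncol(P))
      stop_num("parent scores of '%s' are collinear (%s)", tgt,
               paste(par[[tgt]], collapse = ", "))
    b <- qr.coef(qr_p, scores[, tgt])
    out$estimate[out$target == tgt] <-
      b[match(out$source[out$target == tgt], par[[tgt]])]
  }
  out
}

#' Total effects on a recursive structural model
#'
#' The total effect of one latent on another is the sum, over every directed
#' path connecting them, of the product of the path coefficients along that
#' path. On a DAG with coefficient matrix \eqn{A} (source rows, target
#' columns) this is \eqn{A + A^2 + \dots + A^{L-1}}. Pairs connected only by
#' a direct edge have total effect equal to the direct coefficient.
#'
#' @param coefs data frame from [path_coefficients()] (or any data frame with
#'   `source`, `target`, `estimate`).
#' @param spec a `pls_model`.
#' @return Latent-by-latent numeric matrix of total effects.
#' @export
total_effects <- function(coefs, spec) {
  ln <- latent_names(spec)
  L <- length(ln)
  A <- matrix(0, L, L, dimnames = list(ln, ln))
  A[cbind(match(coefs$source, ln), match(coefs$target, ln))] <- coefs$estimate
  total <- A
  Ak <- A
  for (k in seq_len(max(L - 2, 0))) {
    Ak <- Ak %*% A
    total <- total + Ak
  }
  total
}

#' Location parameters for unstandardized scores
#'
#' Standardized latent scores have mean 0 and unit variance by construction;
#' the importance-performance stage instead needs scores on an interpretable
#' 0-100 scale. For each latent the unstandardized score is the weighted sum
#' of its 0-100 rescaled indicators with block-normalized unstandardized
#' weights, which is an exact affine function of the standardized score. This
#' returns that affine map as `(slope, intercept)` per latent, so
#' `unstandardized = slope * standardized + intercept`.
#'
#' @param data raw (unstandardized) indicator matrix.
#' @param spec a `pls_model`.
#' @param weights named list of abs-sum-1 block weights.
#' @param bounds optional theoretical bounds (see [rescale_indicators()]);
#'   defaults to the spec's `scale_bounds`, empirical otherwise.
#' @return Data frame with columns `latent`, `slope`, `intercept`.
#' @export
location_params <- function(data, spec, weights, bounds = NULL) {
  data <- as_data_matrix(data)
  if (is.null(bounds)) bounds <- spec$scale_bounds
  resc <- rescale_indicators(data, bounds)
  nw <- normalized_block_weights(spec, weights, resc$values)
  xs <- standardize_data(data)
  scores <- latent_scores(xs, spec, weights)
  n <- nrow(data)
  out <- data.frame(latent = latent_names(spec), slope = NA_real_,
                    intercept = NA_real_, stringsAsFactors = FALSE)
  for (l in spec$latents) {
    u <- resc$values[, l$indicators, drop = FALSE] %*% nw[l$indicators]
    s <- scores[, l$name]
    i <- match(l$name, out$latent)
    # exact affine relation: slope = cov(s, u) (var(s) = 1), intercept = mean
    out$slope[i] <- sum(s * (u - mean(u))) / (n - 1)
    out$intercept[i] <- mean(u)
  }
  out
}

# shared estimation engine: raw matrix (columns already in spec order) ->
# weights, standardized scores, own-block loadings, path estimates.
# `blocks` and `parents` are integer index lists precomputed by fit_layout().
fit_core <- function(x, layout) {
  n <- nrow(x)
  m <- colMeans(x)
  xc <- x - rep(m, each = n)
  v <- colSums(xc^2) / (n - 1)
  if (any(v < 1e-24)) stop_num("zero-variance column in data")
  xs <- xc * rep(1 / sqrt(v), each = n)

  L <- length(layout$blocks)
  weights <- vector("list", L)
  scores <- matrix(0, n, L)
  loadings <- numeric(ncol(x))
  for (j in seq_len(L)) {
    idx <- layout$blocks[[j]]
    if (length(idx) == 1L) {
      w <- 1
      t_raw <- xs[, idx]
    } else {
      B <- xs[, idx, drop = FALSE]
      C <- crossprod(B) / (n - 1)
      e <- eigen(C, symmetric = TRUE)
      vec <- orient_eigenvector(e$vectors[, 1L])
      w <- vec / sum(abs(vec))
      t_raw <- B %*% w
    }
    sdt <- sqrt(sum(t_raw^2) / (n - 1))
    if (sdt < 1e-12) stop_num("degenerate latent score")
    s <- t_raw / sdt
    weights[[j]] <- w
    scores[, j] <- s
    loadings[idx] <- crossprod(xs[, idx, drop = FALSE], s) / (n - 1)
  }

  paths <- numeric(nrow(layout$edges))
  for (tgt in unique(layout$edges[, 2])) {
    rows <- which(layout$edges[, 2] == tgt)
    pidx <- layout$edges[rows, 1]
    P <- scores[, pidx, drop = FALSE]
    b <- solve(crossprod(P), crossprod(P, scores[, tgt]))
    paths[rows] <- b
  }
  list(weights = weights, scores = scores, loadings = loadings,
       paths = paths)
}

# precompute integer indices for fit_core
fit_layout <- function(spec) {
  ln <- latent_names(spec)
  ind <- indicator_names(spec)
  blocks <- lapply(spec$latents, function(l) match(l$indicators, ind))
  edges <- cbind(match(spec$paths[, 1], ln), match(spec$paths[, 2], ln))
  list(blocks = blocks, edges = edges, latent_names = ln,
       indicator_names = ind)
}

#' Fit the composite path model with principal-component weights
#'
#' Orchestrates the full one-shot estimator: standardize the data, extract
#' first-principal-component weights per block, form standardized latent
#' scores, compute outer loadings, estimate the structural equations by OLS,
#' accumulate total effects and derive the location parameters that map
#' standardized scores onto the 0-100 performance scale. The procedure is
#' fully deterministic: there is no random initialization and no iterative
#' convergence loop.
#'
#' @param data raw indicator table (matrix or data frame); columns are
#'   matched to the model's indicators by name, extra columns are ignored.
#'   Complete cases and at least 3 observations are required.
#' @param spec a `pls_model`.
#' @param bounds optional theoretical rescaling bounds for the location
#'   parameters (defaults to `spec$scale_bounds`, else empirical).
#' @return An object of class `pls_fit` with elements `spec`, `data` (raw,
#'   model column order), `data_std`, `weights`, `pca` (per-block eigen
#'   summaries), `scores`, `loadings`, `path_coefficients`, `total_effects`,
#'   `residual_variances` (1 - R-squared per endogenous latent),
#'   `location_params` and `n_obs`.
#' @examples
#' cfg <- default_sim_config(n_obs = 100, seed = 1)
#' dat <- simulate_indicator_data(cfg)
#' fit <- pls_fit(dat, cfg$spec)
#' fit$path_coefficients
#' @export
pls_fit <- function(data, spec, bounds = NULL) {
  stopifnot(inherits(spec, "pls_model"))
  x <- as_data_matrix(data)
  ind <- indicator_names(spec)
  miss <- setdiff(ind, colnames(x))
  if (length(miss))
    stop_spec("data is missing indicator column(s): %s",
              paste(miss, collapse = ", "))
  x <- x[, ind, drop = FALSE]
  if (nrow(x) < 3) stop_spec("at least 3 observations are required")

  xs <- standardize_data(x)
  weights <- list(); pca <- list()
  for (l in spec$latents) {
    pw <- pca_block_weights(xs[, l$indicators, drop = FALSE])
    weights[[l$name]] <- pw$weights
    pca[[l$name]] <- pw[c("eigenvalue", "explained_proportion")]
  }
  scores <- latent_scores(xs, spec, weights)
  loadings <- outer_loadings(xs, scores, spec)
  coefs <- path_coefficients(scores, spec)
  totals <- total_effects(coefs, spec)

  # residual (disturbance) variance proxy per endogenous latent: 1 - R^2
  par <- parents_of(spec)
  resid <- stats::setNames(numeric(0), character(0))
  for (nm in latent_names(spec)) {
    if (!length(par[[nm]])) next
    b <- coefs$estimate[coefs$target == nm]
    r2 <- sum(b * stats::cor(scores[, par[[nm]], drop = FALSE],
                             scores[, nm]))
    resid[nm] <- 1 - r2
  }

  loc <- tryCatch(location_params(x, spec, weights, bounds = bounds),
                  plsipa_error = function(e) {
                    warning("location parameters unavailable: ",
                            conditionMessage(e), call. = FALSE)
                    NULL
                  })

  structure(list(spec = spec, data = x, data_std = xs, weights = weights,
                 pca = pca, scores = scores, loadings = loadings,
                 path_coefficients = coefs, total_effects = totals,
                 residual_variances = resid, location_params = loc,
                 n_obs = nrow(x), bounds = bounds),
            class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat("Principal-component-weighted composite model fit\n")
  cat(sprintf("  %d observations, %d latent(s), %d indicator(s)\n",
              x$n_obs, length(x$spec$latents), ncol(x$data)))
  cat("  Explained variance by first component, per block:\n")
  for (nm in names(x$pca))
    cat(sprintf("    %-28s %.3f\n", nm, x$pca[[nm]]$explained_proportion))
  if (nrow(x$path_coefficients)) {
    cat("  Path coefficients:\n")
    for (i in seq_len(nrow(x$path_coefficients)))
      cat(sprintf("    %s -> %s: %s\n", x$path_coefficients$source[i],
                  x$path_coefficients$target[i],
                  formatC(round_half_up(x$path_coefficients$estimate[i]),
                          format = "f", digits = 3)))
  }
  invisible(x)
}
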