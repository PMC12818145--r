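#' Rescale indicators to a 0-100 performance scale
#'
#' Applies \eqn{x' = (x - \min)/(\max - \min) \times 100} per indicator.
#' Bounds are empirical (observed column min/max) unless theoretical bounds
#' are supplied; an observation outside its theoretical bounds is an error,
#' as is a degenerate `min == max`.
#'
#' @param data raw indicator matrix or data frame.
#' @param bounds `NULL` for empirical bounds, or a named list
#'   `indicator = c(min, max)` for some or all columns (the rest stay
#'   empirical).
#' @return List with `values` (rescaled matrix) and `bounds_used` (data
#'   frame: indicator, min, max, source).
#' @export
rescale_indicators <- function(data, bounds = NULL) {
  x <- as_data_matrix(data)
  nm <- colnames(x)
  if (is.null(nm)) stop_spec("data must have column names")
  used <- data.frame(indicator = nm, min = NA_real_, max = NA_real_,
                     source = "empirical", stringsAsFactors = FALSE)
  out <- x
  for (j in seq_along(nm)) {
    b <- bounds[[nm[j]]]
    if (is.null(b)) {
      b <- range(x[, j])
    } else {
      b <- as.numeric(b)
      used$source[j] <- "theoretical"
      low <- which(x[, j] < b[1] | x[, j] > b[2])
      if (length(low))
        stop_spec("value of '%s' at row %d lies outside its theoretical bounds [%g, %g]",
                  nm[j], low[1], b[1], b[2])
    }
    if (b[2] - b[1] <= 0)
      stop_num("degenerate rescaling bounds for '%s' (min == max)", nm[j])
    used$min[j] <- b[1]; used$max[j] <- b[2]
    out[, j] <- (x[, j] - b[1]) / (b[2] - b[1]) * 100
  }
  list(values = out, bounds_used = used)
}

# block-normalized unstandardized weights: standardized weight divided by the
# indicator's standard deviation on the rescaled scale, then normalized so
# each block sums to one. Errors when a block sum is not positive (mixed-sign
# weight pathology).
normalized_block_weights <- function(spec, weights, rescaled_values) {
  n <- nrow(rescaled_values)
  out <- stats::setNames(numeric(0), character(0))
  for (l in spec$latents) {
    w <- weights[[l$name]]
    sds <- apply(rescaled_values[, l$indicators, drop = FALSE], 2, stats::sd)
    if (any(sds < 1e-12))
      stop_num("rescaled indicator in block '%s' has zero variance", l$name)
    uw <- w / sds
    s <- sum(uw)
    if (s <= 0)
      stop_num("unstandardized weights of block '%s' sum to %.3g (mixed-sign weights); cannot normalize to one",
               l$name, s)
    out[l$indicators] <- uw / s
  }
  out
}

#' Block-normalized unstandardized outer weights
#'
#' Transforms the standardized (abs-sum-1) outer weights into unstandardized
#' weights by dividing each by its indicator's standard deviation on the
#' rescaled 0-100 scale, then normalizes them to total one within each
#' block. These weights build the unstandardized latent scores and decompose
#' latent importance onto indicators.
#'
#' @param fit a `pls_fit`.
#' @param rescaled output of [rescale_indicators()]; computed from the fit's
#'   data (with the fit's bounds) when omitted.
#' @return Named numeric vector over all indicators; each block sums to 1.
#' @export
normalized_unstandardized_weights <- function(fit, rescaled = NULL) {
  stopifnot(inherits(fit, "pls_fit"))
  if (is.null(rescaled))
    rescaled <- rescale_indicators(fit$data,
                                   fit$bounds %||% fit$spec$scale_bounds)
  normalized_block_weights(fit$spec, fit$weights, rescaled$values)
}

#' Performance scores on the 0-100 scale
#'
#' An indicator's performance is the mean of its rescaled values; a latent's
#' performance is the weighted sum of its indicators' performances with the
#' block-normalized weights (a convex combination when weights are
#' non-negative, hence also in `[0, 100]`).
#'
#' @param rescaled output of [rescale_indicators()].
#' @param norm_weights block-normalized weights from
#'   [normalized_unstandardized_weights()].
#' @param spec a `pls_model`.
#' @return List with `latent` and `indicator` named numeric vectors.
#' @export
performance_scores <- function(rescaled, norm_weights, spec) {
  ind_perf <- colMeans(rescaled$values)
  lat_perf <- vapply(spec$latents, function(l)
    sum(norm_weights[l$indicators] * ind_perf[l$indicators]), 0)
  names(lat_perf) <- latent_names(spec)
  list(latent = lat_perf, indicator = ind_perf)
}

#' Importance scores with respect to a target latent
#'
#' A predecessor latent's importance is its *unstandardized* total effect on
#' the target: the structural equations are re-estimated by OLS (with
#' intercept) on the unstandardized 0-100 latent scores and path products
#' are accumulated over every directed route. An indicator's importance is
#' its block-normalized weight times its latent's importance, so indicator
#' importances within a block sum exactly to the block's latent importance.
#' The target latent and its own indicators are excluded.
#'
#' @param fit a `pls_fit`.
#' @param rescaled output of [rescale_indicators()] on the fit's data.
#' @param norm_weights block-normalized weights.
#' @param target name of the (endogenous) target latent.
#' @return List with `latent` and `indicator` named numeric vectors and
#'   `unstandardized_paths` (data frame of the refitted coefficients).
#' @export
importance_scores <- function(fit, rescaled, norm_weights, target) {
  spec <- fit$spec
  ln <- latent_names(spec)
  if (!target %in% ln) stop_spec("unknown target latent '%s'", target)
  roles <- vapply(spec$latents, `[[`, "", "role")
  if (roles[match(target, ln)] != "endogenous")
    stop_spec("target latent '%s' must be endogenous", target)

  # unstandardized latent scores on the 0-100 scale
  u <- vapply(spec$latents, function(l)
    as.numeric(rescaled$values[, l$indicators, drop = FALSE] %*%
                 norm_weights[l$indicators]),
    numeric(nrow(rescaled$values)))
  colnames(u) <- ln

  par <- parents_of(spec)
  coefs <- data.frame(source = spec$paths[, 1], target = spec$paths[, 2],
                      estimate = rep(NA_real_, nrow(spec$paths)),
                      stringsAsFactors = FALSE)
  for (tgt in unique(coefs$target)) {
    P <- cbind(1, u[, par[[tgt]], drop = FALSE])
    b <- qr.coef(qr(P), u[, tgt])[-1]
    coefs$estimate[coefs$target == tgt] <-
      b[match(coefs$source[coefs$target == tgt], par[[tgt]])]
  }
  totals <- total_effects(coefs, spec)

  lat_imp <- totals[setdiff(ln, target), target]
  names(lat_imp) <- setdiff(ln, target)
  # ancestors of the target in the structural graph
  anc <- character(0); frontier <- target
  while (length(frontier)) {
    new <- setdiff(unlist(par[frontier], use.names = FALSE), anc)
    anc <- c(anc, new); frontier <- new
  }
  if (!length(anc))
    warning("target '", target,
            "' has no predecessors; importance map is empty", call. = FALSE)

  map <- indicator_latent_map(spec)
  keep <- names(map)[map != target]
  ind_imp <- stats::setNames(norm_weights[keep] * lat_imp[map[keep]], keep)
  list(latent = lat_imp, indicator = ind_imp,
       unstandardized_paths = coefs)
}

#' Assign importance-performance quadrants
#'
#' The map is split by a crosshair, by default at the mean importance and
#' mean performance of the plotted items. Labels follow the usual action
#' semantics: high importance & high performance `keep_up` (keep up the good
#' work), high importance & low performance `concentrate_here`, low & low
#' `low_priority`, low importance & high performance `possible_overkill`.
#' Points exactly on a crosshair line go to the high side (`>=` convention).
#'
#' @param importance named numeric vector.
#' @param performance named numeric vector, same names.
#' @param crosshair optional `c(importance, performance)` override.
#' @return List with `quadrant` (named character) and `crosshair`.
#' @export
quadrant_map <- function(importance, performance, crosshair = NULL) {
  if (!length(importance)) stop_spec("no points to classify")
  if (!identical(names(importance), names(performance)))
    stop_spec("importance and performance must share names")
  if (is.null(crosshair))
    crosshair <- c(mean(importance), mean(performance))
  hi_i <- importance >= crosshair[1]
  hi_p <- performance >= crosshair[2]
  q <- ifelse(hi_i & hi_p, "keep_up",
              ifelse(hi_i & !hi_p, "concentrate_here",
                     ifelse(!hi_i & !hi_p, "low_priority",
                            "possible_overkill")))
  list(quadrant = stats::setNames(q, names(importance)),
       crosshair = c(importance = unname(crosshair[1]),
                     performance = unname(crosshair[2])))
}

#' Importance-performance map analysis
#'
#' Combines a fitted model with the 0-100 rescaling to place every
#' predecessor latent and indicator on an importance-performance map with
#' respect to the target latent. Importance is the unstandardized total
#' effect on the target (indicator importance = block-normalized weight
#' times latent importance); performance is the mean rescaled value.
#' Negative importances (from negative total effects) are retained with
#' their sign — interpret such points with care.
#'
#' @param fit a `pls_fit`.
#' @param target target latent; defaults to the spec's `ipma_target`.
#' @param bounds optional theoretical rescaling bounds (default: the fit's,
#'   then the spec's, else empirical).
#' @param crosshair optional fixed `c(importance, performance)` crosshair
#'   applied at both levels; default is the per-level means.
#' @return An object of class `pls_ipma`: `target`, `latent_points` and
#'   `indicator_points` data frames (item, importance, performance,
#'   quadrant), `crosshair` per level, `bounds_used` and `norm_weights`.
#' @examples
#' cfg <- default_sim_config(n_obs = 80, seed = 2)
#' fit <- pls_fit(simulate_indicator_data(cfg), cfg$spec)
#' ipma <- pls_ipma(fit)
#' ipma$latent_points
#' @export
pls_ipma <- function(fit, target = NULL, bounds = NULL, crosshair = NULL) {
  stopifnot(inherits(fit, "pls_fit"))
  spec <- fit$spec
  target <- target %||% spec$ipma_target
  if (is.null(target))
    stop_spec("no target latent: set `target` or the spec's `ipma_target`")
  bounds <- bounds %||% fit$bounds %||% spec$scale_bounds
  resc <- rescale_indicators(fit$data, bounds)
  nw <- normalized_block_weights(spec, fit$weights, resc$values)
  perf <- performance_scores(resc, nw, spec)
  imp <- importance_scores(fit, resc, nw, target)

  lat_q <- quadrant_map(imp$latent, perf$latent[names(imp$latent)],
                        crosshair)
  ind_q <- quadrant_map(imp$indicator, perf$indicator[names(imp$indicator)],
                        crosshair)
  map <- indicator_latent_map(spec)
  structure(list(
    target = target,
    latent_points = data.frame(
      latent = names(imp$latent),
      importance = unname(imp$latent),
      performance = unname(perf$latent[names(imp$latent)]),
      quadrant = unname(lat_q$quadrant),
      stringsAsFactors = FALSE),
    indicator_points = data.frame(
      indicator = names(imp$indicator),
      latent = unname(map[names(imp$indicator)]),
      importance = unname(imp$indicator),
      performance = unname(perf$indicator[names(imp$indicator)]),
      quadrant = unname(ind_q$quadrant),
      stringsAsFactors = FALSE),
    crosshair = list(latent = lat_q$crosshair, indicator = ind_q$crosshair),
    bounds_used = resc$bounds_used,
    norm_weights = nw,
    unstandardized_paths = imp$unstandardized_paths),
    class = "pls_ipma")
}

#' @export
print.pls_ipma <- function(x, ...) {
  cat("Importance-performance map, target:", x$target, "\n")
  cat("Latent level (crosshair ",
      sprintf("%.3f / %.3f", x$crosshair$latent[1], x$crosshair$latent[2]),
      "):\n", sep = "")
  print(transform(x$latent_points,
                  importance = round_half_up(importance),
                  performance = round_half_up(performance)),
        row.names = FALSE)
  cat("Indicator level (crosshair ",
      sprintf("%.3f / %.3f", x$crosshair$indicator[1],
              x$crosshair$indicator[2]), "):\n", sep = "")
  print(transform(x$indicator_points,
                  importance = round_half_up(importance),
                  performance = round_half_up(performance)),
        row.names = FALSE)
  invisible(x)
}

#' Plot an importance-performance map
#'
#' Scatter of items with crosshair lines. By default importance is on the
#' horizontal axis and performance on the vertical axis; `flip_axes = TRUE`
#' gives the classic presentation with importance vertical.
#'
#' @param x a `pls_ipma`.
#' @param level `"indicator"` or `"latent"`.
#' @param flip_axes put importance on the vertical axis.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pls_ipma <- function(x, level = c("indicator", "latent"),
                          flip_axes = FALSE, ...) {
  level <- match.arg(level)
  pts <- if (level == "indicator") x$indicator_points else x$latent_points
  ch <- x$crosshair[[level]]
  labels <- pts[[1]]
  xi <- pts$importance; yi <- pts$performance
  xl <- "importance (unstandardized total effect)"
  yl <- "performance (0-100)"
  if (flip_axes) { tmp <- xi; xi <- yi; yi <- tmp
                   tmp <- xl; xl <- yl; yl <- tmp
                   ch <- rev(ch) }
  graphics::plot(xi, yi, xlab = xl, ylab = yl,
                 main = paste("IPMA, target:", x$target), pch = 19, ...)
  graphics::abline(v = ch[1], h = ch[2], lty = 2, col = "grey40")
  graphics::text(xi, yi, labels, pos = 3, cex = 0.7)
  invisible(x)
}
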