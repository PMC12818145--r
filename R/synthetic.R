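#' Configure a synthetic data-generating process
#'
#' Defines a population that follows the reflective composite model
#' literally: exogenous latents are standard normal, each endogenous latent
#' is the weighted sum of its parents plus a disturbance scaled so its
#' variance is exactly 1, and each indicator is `loading x latent + error`
#' with error variance `1 - loading^2`. Admissibility is checked up front:
#' every implied disturbance variance must be strictly positive and every
#' loading must lie in `(0, 1]`.
#'
#' @param spec a `pls_model` giving the topology and blocks.
#' @param paths named numeric vector of population structural coefficients
#'   with names `"source -> target"` (or a data frame with columns `source`,
#'   `target`, `estimate`); must cover exactly the spec's paths.
#' @param loadings named numeric vector of population loadings per
#'   indicator, each in `(0, 1]`; single-indicator blocks must have
#'   loading 1 (their score is the indicator itself).
#' @param n_obs number of observations to generate.
#' @param seed integer RNG seed (mandatory for reproducibility).
#' @param indicator_scales optional named list `indicator = c(location,
#'   spread)` mapping standardized indicators to an unstandardized scale.
#' @param error_dist `"normal"` (default) or `"lognormal"` for skewed
#'   (standardized shifted-lognormal) disturbances and measurement errors,
#'   exercising the method's distribution-free claim.
#' @return An object of class `sim_config`, including the implied population
#'   latent covariance matrix (`latent_cov`) and disturbance variances.
#' @export
sim_config <- function(spec, paths, loadings, n_obs, seed = 1L,
                       indicator_scales = NULL,
                       error_dist = c("normal", "lognormal")) {
  stopifnot(inherits(spec, "pls_model"))
  error_dist <- match.arg(error_dist)
  edges <- spec$paths
  if (is.data.frame(paths)) {
    pv <- stats::setNames(paths$estimate,
                          paste(paths$source, "->", paths$target))
  } else pv <- paths
  want <- if (nrow(edges)) paste(edges[, 1], "->", edges[, 2])
          else character(0)
  if (!setequal(names(pv), want))
    stop_spec("population paths must cover exactly the spec's paths (%s)",
              paste(setdiff(want, names(pv)), collapse = ", "))
  pv <- pv[want]

  ind <- indicator_names(spec)
  if (!setequal(names(loadings), ind))
    stop_spec("population loadings must cover every indicator")
  loadings <- loadings[ind]
  if (any(loadings <= 0 | loadings > 1))
    stop_spec("population loadings must lie in (0, 1]")
  for (l in spec$latents)
    if (length(l$indicators) == 1 && loadings[[l$indicators]] != 1)
      stop_spec("single-indicator block '%s' must have loading 1", l$name)

  # implied population covariance among unit-variance latents, in
  # topological order, and the admissibility of each disturbance
  ln <- latent_names(spec)
  ord <- topo_order(spec)
  par <- parents_of(spec)
  S <- diag(length(ln)); dimnames(S) <- list(ln, ln)
  dist_var <- stats::setNames(rep(NA_real_, length(ln)), ln)
  for (nm in ord) {
    p <- par[[nm]]
    if (!length(p)) next
    b <- pv[paste(p, "->", nm)]
    v_struct <- drop(t(b) %*% S[p, p, drop = FALSE] %*% b)
    if (v_struct >= 1)
      stop_num("inadmissible config: structural variance of '%s' is %.3f >= 1",
               nm, v_struct)
    dist_var[nm] <- 1 - v_struct
    S[nm, ] <- S[, nm] <- drop(S[, p, drop = FALSE] %*% b)
    S[nm, nm] <- 1
  }

  if (!is.null(indicator_scales)) {
    unknown <- setdiff(names(indicator_scales), ind)
    if (length(unknown))
      stop_spec("indicator_scales for unknown indicator '%s'", unknown[1])
    bad <- vapply(indicator_scales, function(s) s[2] <= 0, TRUE)
    if (any(bad)) stop_spec("indicator_scales spread must be positive")
  }

  structure(list(spec = spec, paths = pv, loadings = loadings,
                 n_obs = as.integer(n_obs), seed = as.integer(seed),
                 indicator_scales = indicator_scales,
                 error_dist = error_dist, latent_cov = S,
                 disturbance_variances = dist_var),
            class = "sim_config")
}

# standardized draws: mean 0, variance 1
rdraw <- function(n, dist) {
  if (dist == "normal") return(stats::rnorm(n))
  z <- stats::rlnorm(n)  # shifted, scaled lognormal -> skewed but standardized
  (z - exp(0.5)) / sqrt((exp(1) - 1) * exp(1))
}

#' Generate a synthetic indicator dataset
#'
#' Draws from the population defined by a [sim_config()]: latents in
#' topological order (exogenous standard normal; endogenous = path-weighted
#' parents + scaled disturbance), then indicators as `loading x latent +
#' error`, optionally affine-mapped to `indicator_scales`. Deterministic
#' given the seed: two calls with identical configs produce identical
#' tables.
#'
#' @param config a `sim_config`.
#' @param n_obs,seed optional overrides of the config's values.
#' @return Data frame, `n_obs` rows by one column per indicator in model
#'   order; the latent draws are attached as attribute `"latents"`.
#' @export
simulate_indicator_data <- function(config, n_obs = config$n_obs,
                                    seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$spec
  set.seed(seed)
  n <- n_obs
  ln <- latent_names(spec)
  par <- parents_of(spec)
  lat <- matrix(0, n, length(ln), dimnames = list(NULL, ln))
  for (nm in topo_order(spec)) {
    p <- par[[nm]]
    if (!length(p)) {
      lat[, nm] <- rdraw(n, config$error_dist)
    } else {
      b <- config$paths[paste(p, "->", nm)]
      lat[, nm] <- lat[, p, drop = FALSE] %*% b +
        sqrt(config$disturbance_variances[[nm]]) * rdraw(n, config$error_dist)
    }
  }
  ind <- indicator_names(spec)
  map <- indicator_latent_map(spec)
  x <- matrix(0, n, length(ind), dimnames = list(NULL, ind))
  for (i in ind) {
    lam <- config$loadings[[i]]
    err_sd <- sqrt(1 - lam^2)
    x[, i] <- lam * lat[, map[[i]]] +
      if (err_sd > 0) err_sd * rdraw(n, config$error_dist) else 0
    sc <- config$indicator_scales[[i]]
    if (!is.null(sc)) x[, i] <- sc[1] + sc[2] * x[, i]
  }
  out <- as.data.frame(x)
  attr(out, "latents") <- lat
  out
}

#' Default five-latent generator configuration
#'
#' The package's reference population: one exogenous socioeconomic latent
#' (3 indicators) influencing three mediators — parenting and food security
#' (single-indicator blocks) and health & environmental services
#' (7 indicators) — which in turn influence a 3-indicator malnutrition
#' target (15 indicators, 6 structural paths in total). Default structural
#' coefficients are 0.464, 0.720 and 0.513 for the three socioeconomic
#' paths and -0.185, 0.178 and -0.011 for the paths into malnutrition — a
#' district-level malnutrition study design with one strong, one moderate
#' and one near-null mediated route, including negative effects. Population
#' loadings default to 0.9 for multi-indicator blocks (1.0 for the
#' single-indicator blocks); the default sample size of 38 matches the
#' district-level cross-section this design emulates.
#'
#' @param n_obs sample size (default 38).
#' @param seed RNG seed (default 1).
#' @param loading population loading for multi-indicator blocks
#'   (default 0.9).
#' @param paths optional named override of the six structural coefficients.
#' @param ... passed on to [sim_config()] (e.g. `error_dist`,
#'   `indicator_scales`).
#' @return A `sim_config`; its `spec` element is the five-latent
#'   `pls_model` with `ipma_target = "malnutrition"`.
#' @export
default_sim_config <- function(n_obs = 38, seed = 1L, loading = 0.9,
                               paths = NULL, ...) {
  spec <- model_spec(
    latents = list(
      list(name = "socioeconomic",
           indicators = c("x1_1", "x1_2", "x1_3")),
      list(name = "parenting", indicators = "y1_1"),
      list(name = "food_security", indicators = "y2_1"),
      list(name = "health_environment",
           indicators = paste0("y3_", 1:7)),
      list(name = "malnutrition",
           indicators = c("y4_1", "y4_2", "y4_3"))),
    paths = list(c("socioeconomic", "parenting"),
                 c("socioeconomic", "food_security"),
                 c("socioeconomic", "health_environment"),
                 c("parenting", "malnutrition"),
                 c("food_security", "malnutrition"),
                 c("health_environment", "malnutrition")),
    ipma_target = "malnutrition")
  default_paths <- c(
    "socioeconomic -> parenting" = 0.464,
    "socioeconomic -> food_security" = 0.720,
    "socioeconomic -> health_environment" = 0.513,
    "parenting -> malnutrition" = -0.185,
    "food_security -> malnutrition" = 0.178,
    "health_environment -> malnutrition" = -0.011)
  if (!is.null(paths)) default_paths[names(paths)] <- paths
  ind <- indicator_names(spec)
  loadings <- stats::setNames(rep(loading, length(ind)), ind)
  loadings[c("y1_1", "y2_1")] <- 1
  sim_config(spec, paths = default_paths, loadings = loadings,
             n_obs = n_obs, seed = seed, ...)
}
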