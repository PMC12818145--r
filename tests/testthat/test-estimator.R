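test_that("standardization centers, scales, and flags degenerate columns", {
  x <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  z <- standardize_data(x)
  expect_equal(unname(z[, "a"]), c(-1, 0, 1))
  expect_equal(colMeans(z), c(a = 0, b = 0))
  expect_equal(apply(z, 2, stats::var), c(a = 1, b = 1))
  # idempotence
  expect_equal(standardize_data(z), z, tolerance = 1e-12)
  expect_error(standardize_data(cbind(a = c(10, 10, 10))),
               "zero variance", class = "plsipa_numeric_error")
})

test_that("block weights match an independent SVD oracle", {
  set.seed(7)
  for (p in 2:4) {
    block <- standardize_data(matrix(stats::rnorm(6 * p), 6, p,
                                     dimnames = list(NULL, paste0("v", 1:p))))
    got <- pca_block_weights(block)
    oracle <- svd_block_weights(block)
    expect_equal(unname(got$weights), oracle$weights, tolerance = 1e-10)
    expect_equal(got$eigenvalue, oracle$eigenvalue, tolerance = 1e-10)
    expect_equal(sum(abs(got$weights)), 1, tolerance = 1e-10)
    expect_equal(sum(got$eigenvector^2), 1, tolerance = 1e-10)
  }
})

test_that("block weights handle degenerate and symmetric blocks", {
  z <- standardize_data(cbind(x = c(1, 4, 2, 5)))
  one <- pca_block_weights(z)
  expect_equal(unname(one$weights), 1)
  expect_equal(one$explained_proportion, 1)
  # two perfectly correlated indicators: symmetry forces equal components
  v <- standardize_data(cbind(p = c(1, 2, 5, 3)))[, 1]
  two <- pca_block_weights(cbind(p = v, q = v))
  expect_equal(unname(two$weights), c(0.5, 0.5), tolerance = 1e-12)
})

test_that("latent scores are re-standardized weighted sums", {
  set.seed(11)
  spec <- model_spec(latents = list(list(name = "A",
                                         indicators = c("a1", "a2", "a3"))))
  xs <- standardize_data(matrix(stats::rnorm(18), 6, 3,
                                dimnames = list(NULL, c("a1", "a2", "a3"))))
  w <- list(A = c(a1 = 0.5, a2 = 0.3, a3 = 0.2))
  sc <- latent_scores(xs, spec, w)
  direct <- xs %*% w$A
  direct <- (direct - mean(direct)) / stats::sd(direct)
  expect_equal(unname(sc[, "A"]), drop(direct), tolerance = 1e-12)
  expect_equal(mean(sc[, "A"]), 0, tolerance = 1e-8)
  expect_equal(stats::var(sc[, "A"]), 1, tolerance = 1e-8)
  # single-indicator block: score equals the standardized indicator
  spec1 <- model_spec(latents = list(list(name = "L", indicators = "a1")))
  sc1 <- latent_scores(xs, spec1, list(L = c(a1 = 1)))
  expect_equal(unname(sc1[, "L"]), unname(xs[, "a1"]), tolerance = 1e-12)
})

test_that("single-block latent score equals the first principal component", {
  set.seed(23)
  x <- matrix(stats::rnorm(120), 30, 4,
              dimnames = list(NULL, paste0("v", 1:4)))
  spec <- model_spec(latents = list(list(name = "L",
                                         indicators = paste0("v", 1:4))))
  # a pure-noise block can have mixed-sign weights, in which case the
  # 0-100 location parameters are (by design) flagged as unavailable
  expect_warning(fit <- pls_fit(x, spec), "mixed-sign")
  pc1 <- stats::prcomp(standardize_data(x))$x[, 1]
  pc1 <- pc1 / stats::sd(pc1)
  agree <- max(abs(abs(fit$scores[, "L"]) - abs(pc1)))
  expect_lt(agree, 1e-10)
})

test_that("scores are invariant under affine transformations of raw data", {
  cfg <- two_block_config(n = 50, seed = 4)
  dat <- simulate_indicator_data(cfg)
  fit1 <- pls_fit(dat, cfg$spec)
  shifted <- sweep(sweep(as.matrix(dat), 2, c(3, 2, 10, 0.5, 7, 1.5), "*"),
                   2, c(100, 5, -40, 0, 2, 9), "+")
  fit2 <- pls_fit(shifted, cfg$spec)
  expect_equal(fit2$scores, fit1$scores, tolerance = 1e-10)
  expect_equal(fit2$loadings, fit1$loadings, tolerance = 1e-10)
})

test_that("outer loadings are own-score correlations with known limits", {
  cfg <- two_block_config(n = 40, seed = 8)
  dat <- simulate_indicator_data(cfg)
  fit <- pls_fit(dat, cfg$spec)
  expect_equal(unname(fit$loadings["a1"]),
               stats::cor(fit$data_std[, "a1"], fit$scores[, "A"]))
  expect_true(all(abs(fit$loadings) <= 1 + 1e-8))
  # single-indicator block loads exactly 1
  spec1 <- model_spec(latents = list(list(name = "L", indicators = "a1"),
                                     list(name = "M", indicators = "a2")),
                      paths = list(c("L", "M")))
  fit1 <- pls_fit(dat[, c("a1", "a2")], spec1)
  expect_equal(unname(fit1$loadings), c(1, 1), tolerance = 1e-12)
  # population-loading recovery at large n
  big <- simulate_indicator_data(two_block_config(n = 5000, seed = 99))
  fitb <- pls_fit(big, cfg$spec)
  expect_lt(max(abs(fitb$loadings - 0.93)), 0.035)
})

test_that("path coefficients are per-equation OLS on standardized scores", {
  cfg <- two_block_config(path = 0.7, n = 5000, seed = 31)
  dat <- simulate_indicator_data(cfg)
  fit <- pls_fit(dat, cfg$spec)
  est <- fit$path_coefficients$estimate
  # attenuation by composite reliability keeps the estimate near 0.7 x rel^2
  expect_lt(abs(est - 0.7), 0.06)
  # cross-check against lm on the scores
  lm_b <- unname(stats::coef(stats::lm(fit$scores[, "B"] ~
                                         fit$scores[, "A"]))[2])
  expect_equal(est, lm_b, tolerance = 1e-10)
  # identical child: coefficient 1; orthogonal child: ~0
  sc <- fit$scores
  spec_id <- two_block_spec()
  expect_equal(
    path_coefficients(cbind(A = sc[, "A"], B = sc[, "A"]), spec_id)$estimate,
    1, tolerance = 1e-12)
  # collinear parents are a singularity error naming the parents
  spec3 <- model_spec(
    latents = list(list(name = "P1", indicators = "p1"),
                   list(name = "P2", indicators = "p2"),
                   list(name = "C", indicators = "c")),
    paths = list(c("P1", "C"), c("P2", "C")))
  s <- cbind(P1 = sc[, "A"], P2 = sc[, "A"], C = sc[, "B"])
  expect_error(path_coefficients(s, spec3), "collinear",
               class = "plsipa_numeric_error")
})

test_that("total effects accumulate path products over all routes", {
  # chain: 0.5 then 0.4 -> 0.20
  spec <- model_spec(latents = list(list(name = "A", indicators = "a"),
                                    list(name = "B", indicators = "b"),
                                    list(name = "C", indicators = "c")),
                     paths = list(c("A", "B"), c("B", "C")))
  coefs <- data.frame(source = c("A", "B"), target = c("B", "C"),
                      estimate = c(0.5, 0.4))
  te <- total_effects(coefs, spec)
  expect_equal(te["A", "C"], 0.2)
  expect_equal(te["A", "B"], 0.5)  # direct-only pair equals the coefficient

  # the reference three-mediator arithmetic:
  # 0.464 * (-0.185) + 0.720 * 0.178 + 0.513 * (-0.011)
  cfg <- default_sim_config()
  coefs5 <- data.frame(source = cfg$spec$paths[, 1],
                       target = cfg$spec$paths[, 2],
                       estimate = unname(cfg$paths))
  te5 <- total_effects(coefs5, cfg$spec)
  expect_equal(te5["socioeconomic", "malnutrition"], 0.036677,
               tolerance = 1e-10)
})

test_that("total effects agree with a path-enumeration oracle on random DAGs", {
  set.seed(99)
  for (rep in 1:15) {
    L <- sample(3:6, 1)
    nm <- paste0("L", 1:L)
    paths <- list()
    for (i in 1:(L - 1)) for (j in (i + 1):L)
      if (stats::runif(1) < 0.5) paths <- c(paths, list(c(nm[i], nm[j])))
    if (!length(paths)) next
    lat <- lapply(nm, function(x) list(name = x, indicators = tolower(x)))
    spec <- model_spec(lat, paths = paths)
    coefs <- data.frame(source = spec$paths[, 1], target = spec$paths[, 2],
                        estimate = stats::runif(nrow(spec$paths), -1, 1))
    te <- total_effects(coefs, spec)
    for (from in nm) for (to in nm)
      if (from != to)
        expect_equal(te[from, to], enumerate_total_effect(coefs, from, to),
                     tolerance = 1e-12)
  }
})

test_that("location parameters reproduce unstandardized scores exactly", {
  cfg <- two_block_config(n = 60, seed = 13)
  dat <- simulate_indicator_data(cfg)
  fit <- pls_fit(dat, cfg$spec)
  loc <- fit$location_params
  resc <- rescale_indicators(fit$data)
  nw <- normalized_unstandardized_weights(fit, resc)
  for (l in cfg$spec$latents) {
    direct <- drop(resc$values[, l$indicators, drop = FALSE] %*%
                     nw[l$indicators])
    i <- match(l$name, loc$latent)
    via_affine <- loc$slope[i] * fit$scores[, l$name] + loc$intercept[i]
    expect_equal(unname(via_affine), direct, tolerance = 1e-8)
  }
  # single-indicator latent on bounded 0-100 data: affine map is exact identity
  x <- cbind(u = c(0, 25, 50, 100), v = c(1, 2, 3, 5))
  spec1 <- model_spec(latents = list(list(name = "U", indicators = "u"),
                                     list(name = "V", indicators = "v")),
                      paths = list(c("U", "V")),
                      scale_bounds = list(u = c(0, 100)))
  fit1 <- pls_fit(x, spec1)
  i <- match("U", fit1$location_params$latent)
  rebuilt <- fit1$location_params$slope[i] * fit1$scores[, "U"] +
    fit1$location_params$intercept[i]
  expect_equal(unname(rebuilt), c(0, 25, 50, 100), tolerance = 1e-10)
})

test_that("the fitted model recovers known population structure", {
  cfg <- default_sim_config(n_obs = 5000, seed = 77)
  dat <- simulate_indicator_data(cfg)
  fit <- pls_fit(dat, cfg$spec)
  err_paths <- abs(fit$path_coefficients$estimate - unname(cfg$paths))
  expect_lt(stats::median(err_paths), 0.05)
  expect_equal(dim(fit$scores), c(5000L, 5L))
  expect_true(all(abs(colMeans(fit$scores)) < 1e-8))
  expect_true(all(abs(apply(fit$scores, 2, stats::var) - 1) < 1e-8))
})
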