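test_that("rescaling maps bounds to 0/100 and is idempotent", {
  x <- cbind(a = c(2, 4, 10))
  r <- rescale_indicators(x)
  expect_equal(unname(r$values[, "a"]), c(0, 25, 100))
  expect_equal(r$bounds_used$source, "empirical")
  # theoretical bounds: endpoints and midpoint
  r2 <- rescale_indicators(cbind(a = c(0, 5, 10)),
                           bounds = list(a = c(0, 10)))
  expect_equal(unname(r2$values[, "a"]), c(0, 50, 100))
  # idempotence on already-[0,100] data with bounds (0, 100)
  r3 <- rescale_indicators(r$values, bounds = list(a = c(0, 100)))
  expect_equal(r3$values, r$values)
  expect_error(rescale_indicators(cbind(a = c(-1, 5)),
                                  bounds = list(a = c(0, 10))),
               "outside its theoretical bounds", class = "plsipa_spec_error")
  expect_error(rescale_indicators(cbind(a = c(3, 3, 3))),
               "min == max", class = "plsipa_numeric_error")
})

test_that("unstandardized weights normalize to one per block", {
  # hand arithmetic: standardized weights (0.6, 0.4), rescaled sds (10, 20)
  # -> unstandardized (0.06, 0.02) -> normalized (0.75, 0.25)
  spec <- model_spec(latents = list(list(name = "L",
                                         indicators = c("p", "q"))))
  set.seed(1)
  base <- stats::rnorm(50)
  vals <- cbind(p = 10 * scale(stats::rnorm(50))[, 1],
                q = 20 * scale(base)[, 1])
  nw <- plsipa:::normalized_block_weights(
    spec, list(L = c(p = 0.6, q = 0.4)), vals)
  expect_equal(unname(nw), c(0.75, 0.25), tolerance = 1e-10)
  # equal weights, equal sds -> (0.5, 0.5); single indicator -> 1
  cfg <- two_block_config(n = 50, seed = 2)
  fit <- pls_fit(simulate_indicator_data(cfg), cfg$spec)
  nw2 <- normalized_unstandardized_weights(fit)
  for (l in cfg$spec$latents)
    expect_equal(sum(nw2[l$indicators]), 1, tolerance = 1e-12)
  # mixed-sign pathology errors
  expect_error(plsipa:::normalized_block_weights(
    spec, list(L = c(p = 0.3, q = -0.7)), vals),
    "mixed-sign", class = "plsipa_numeric_error")
})

test_that("performance scores are rescaled means and block-weighted sums", {
  # block with normalized weights (0.75, 0.25), indicator means (40, 80)
  spec <- model_spec(latents = list(list(name = "L",
                                         indicators = c("p", "q"))))
  resc <- list(values = cbind(p = c(30, 50), q = c(70, 90)))
  perf <- performance_scores(resc, c(p = 0.75, q = 0.25), spec)
  expect_equal(unname(perf$indicator), c(40, 80))
  expect_equal(unname(perf$latent), 50)
  # all observations at the maximum -> performance 100
  cfg <- two_block_config(n = 30, seed = 5)
  fit <- pls_fit(simulate_indicator_data(cfg), cfg$spec)
  resc2 <- rescale_indicators(fit$data)
  nw <- normalized_unstandardized_weights(fit, resc2)
  p2 <- performance_scores(resc2, nw, cfg$spec)
  expect_true(all(p2$indicator >= 0 & p2$indicator <= 100))
  # convexity: latent performance inside its indicators' range
  for (l in cfg$spec$latents) {
    rng <- range(p2$indicator[l$indicators])
    expect_gte(p2$latent[[l$name]], rng[1] - 1e-8)
    expect_lte(p2$latent[[l$name]], rng[2] + 1e-8)
  }
})

test_that("importance decomposes over blocks and follows path products", {
  cfg <- default_sim_config(n_obs = 120, seed = 9)
  fit <- pls_fit(simulate_indicator_data(cfg), cfg$spec)
  ip <- pls_ipma(fit)
  # block indicator importances sum to the latent importance
  for (l in cfg$spec$latents) {
    if (l$name == "malnutrition") next
    block_sum <- sum(ip$indicator_points$importance[
      ip$indicator_points$latent == l$name])
    lat_imp <- ip$latent_points$importance[
      ip$latent_points$latent == l$name]
    expect_equal(block_sum, lat_imp, tolerance = 1e-8)
  }
  # performances all within [0, 100]
  expect_true(all(ip$indicator_points$performance >= -1e-8 &
                    ip$indicator_points$performance <= 100 + 1e-8))
  # chain model: source importance = product of unstandardized coefficients
  spec3 <- model_spec(latents = list(list(name = "A", indicators = "a"),
                                     list(name = "B", indicators = "b"),
                                     list(name = "C", indicators = "c")),
                      paths = list(c("A", "B"), c("B", "C")))
  set.seed(4)
  a <- stats::rnorm(80)
  dat3 <- cbind(a = a, b = 0.5 * a + stats::rnorm(80, sd = 0.1),
                c = stats::rnorm(80))
  dat3[, "c"] <- 0.4 * dat3[, "b"] + stats::rnorm(80, sd = 0.1)
  fit3 <- pls_fit(dat3, spec3)
  ip3 <- pls_ipma(fit3, target = "C")
  up <- ip3$unstandardized_paths
  expect_equal(ip3$latent_points$importance[
    ip3$latent_points$latent == "A"],
    up$estimate[up$source == "A"] * up$estimate[up$source == "B"],
    tolerance = 1e-10)
  # direct-only predecessor: importance equals the direct coefficient
  expect_equal(ip3$latent_points$importance[
    ip3$latent_points$latent == "B"],
    up$estimate[up$source == "B"], tolerance = 1e-12)
})

test_that("quadrants follow the crosshair with the >= boundary convention", {
  imp <- c(a = 1, b = 3, c = 1, d = 3)
  perf <- c(a = 10, b = 10, c = 30, d = 30)
  q <- quadrant_map(imp, perf)
  expect_equal(unname(q$crosshair), c(2, 20))
  expect_equal(unname(q$quadrant),
               c("low_priority", "concentrate_here",
                 "possible_overkill", "keep_up"))
  # single point sits on the crosshair -> keep_up by the >= convention
  q1 <- quadrant_map(c(x = 5), c(x = 50))
  expect_equal(unname(q1$quadrant), "keep_up")
  # invariance under a common affine transform of importances
  q2 <- quadrant_map(10 * imp - 3, perf)
  expect_equal(q2$quadrant, q$quadrant)
  # fixed crosshair override
  q3 <- quadrant_map(imp, perf, crosshair = c(0, 0))
  expect_true(all(q3$quadrant == "keep_up"))
})

test_that("a high-importance low-performance indicator lands in concentrate_here", {
  # construct a strong single-indicator mediator whose rescaled mean is low
  spec <- model_spec(latents = list(list(name = "S", indicators = "s1"),
                                    list(name = "M", indicators = "m1"),
                                    list(name = "T",
                                         indicators = c("t1", "t2"))),
                     paths = list(c("S", "M"), c("M", "T")),
                     ipma_target = "T",
                     scale_bounds = list(m1 = c(0, 100)))
  set.seed(12)
  s <- stats::rnorm(100)
  m <- 30 + 6 * (0.9 * s + 0.44 * stats::rnorm(100))  # low on its 0-100 scale
  t_lat <- 0.9 * scale(m)[, 1] + 0.44 * stats::rnorm(100)
  dat <- cbind(s1 = s, m1 = m,
               t1 = 0.95 * t_lat + 0.31 * stats::rnorm(100),
               t2 = 0.95 * t_lat + 0.31 * stats::rnorm(100))
  fit <- pls_fit(dat, spec)
  ip <- pls_ipma(fit)
  m_row <- ip$indicator_points[ip$indicator_points$indicator == "m1", ]
  expect_equal(m_row$quadrant, "concentrate_here")
  expect_lt(m_row$performance, 50)
})
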