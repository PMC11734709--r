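# Separable signal model, inner linear solves, the anchored global fit,
# gamma estimation, residuals and pattern comparison.

make_small_model <- function(noise = 0, seed = 1L) {
  cfg <- small_scenario(noise = noise, seed = seed)
  map <- generate_map(cfg)
  list(cfg = cfg, map = map, truth = attr(map, "truth"))
}

test_that("model_signal is the exact separable forward model", {
  cfg <- small_scenario()
  net <- cfg$network
  pop <- solve_populations(net, dt_rates(), cfg$irf, cfg$tgrid)
  groups <- stats::setNames(as.list(net$species$name), net$species$name)
  q <- cfg$q

  zero <- model_signal(0, stats::setNames(
    rep(list(rep(1, length(q))), length(groups)), names(groups)), pop, groups)
  expect_true(all(zero$values == 0))

  # single-species exponential: map = gamma * exp(-t/tau) at every q
  net1 <- reaction_network(
    data.frame(name = c("A", "B"), role = c("excited", "product"),
               group = c("A", "B")),
    data.frame(from = "A", to = "B", rate = "k"), "A")
  tg <- seq(100, 5000, length.out = 20)
  pop1 <- solve_populations(net1, c(k = 1), instrument_response(0, 0), tg)
  m <- model_signal(0.05, list(A = rep(1, 5), B = rep(0, 5)), pop1,
                    list(A = "A", B = "B"))
  for (i in 1:5) {
    expect_equal(m$values[i, ], 0.05 * exp(-tg / 1000), tolerance = 1e-9)
  }

  # group covering must partition the species
  expect_error(model_signal(0.05, list(A = rep(1, 5)), pop1, list(A = "A")),
               "partition")
})

test_that("scale degeneracy gamma*S is exact", {
  x <- make_small_model()
  cfg <- x$cfg
  species <- cfg$network$species$name
  groups <- stats::setNames(as.list(species), species)
  pats <- x$truth$patterns
  m1 <- model_signal(cfg$gamma, pats, x$truth$populations, groups)
  # scaling by a power of two is exact in floating point
  pats2 <- lapply(pats, function(p) { p$percent <- p$percent / 2; p })
  m2 <- model_signal(cfg$gamma * 2, pats2, x$truth$populations, groups)
  expect_identical(m1$values, m2$values)
})

test_that("generate_map reproduces model_signal on the same code path", {
  x <- make_small_model(noise = 0)
  species <- x$cfg$network$species$name
  m <- model_signal(x$cfg$gamma, x$truth$patterns, x$truth$populations,
                    stats::setNames(as.list(species), species))
  expect_identical(x$map$values, m$values)
})

test_that("noiseless linear pattern solve is exact on a full-rank grouping", {
  # five pattern groups (merged equilibrium pair) span the full function
  # space of the network: the weighted LS recovers the generating gamma*S
  cfg <- small_scenario()
  net <- default_dt_network(merge_hot = TRUE)
  groups <- split(net$species$name, net$species$group)
  pop <- solve_populations(net, dt_rates(), cfg$irf, cfg$tgrid)
  set.seed(8)
  S <- lapply(groups, function(g) stats::rnorm(length(cfg$q)))
  clean <- model_signal(0.045, S, pop, groups)
  map <- signal_map(cfg$q, cfg$tgrid, clean$values, sigma = 1)
  lin <- solve_patterns_linear(map, pop, groups, cond_threshold = Inf)
  for (g in names(groups)) {
    truthv <- 0.045 * S[[g]]
    expect_lt(max(abs(lin$coef[, g] - truthv)) / max(abs(truthv)), 1e-8)
  }
})

test_that("collinear groupings are flagged with the groups named", {
  # six free singleton courses live in a five-dimensional function space:
  # the design is rank-deficient and must be flagged
  x <- make_small_model(noise = 0)
  species <- x$cfg$network$species$name
  expect_warning(
    solve_patterns_linear(x$map, x$truth$populations,
                          stats::setNames(as.list(species), species)),
    "collinear")
})

test_that("duplicate delay columns equal the deduplicated weighted problem", {
  net1 <- reaction_network(
    data.frame(name = c("A", "B"), role = c("excited", "product"),
               group = c("A", "B")),
    data.frame(from = "A", to = "B", rate = "k"), "A")
  tg <- c(100, 400, 900, 1600)
  pop <- solve_populations(net1, c(k = 1), instrument_response(0, 0), tg)
  q <- c(1, 2)
  vals <- rbind(c(1.0, 0.7, 0.45, 0.3), c(0.5, 0.35, 0.22, 0.15))
  map <- signal_map(q, tg, vals, sigma = 0.1)
  lin <- solve_patterns_linear(map, pop, list(A = "A", B = "B"))

  # duplicating a delay column == doubling its weight in the normal equations
  tg2 <- c(100, 400, 900, 1600, 1600.000001)
  pop2 <- pop; pop2$t <- tg2; pop2$F <- pop$F[c(1:4, 4), ]
  map2 <- signal_map(q, tg2, vals[, c(1:4, 4)], sigma = 0.1)
  lin2 <- solve_patterns_linear(map2, pop2, list(A = "A", B = "B"))

  # dedup with summed weights: weight 2 on the last delay
  sig3 <- matrix(0.1, 2, 4); sig3[, 4] <- 0.1 / sqrt(2)
  map3 <- signal_map(q, tg, vals, sigma = sig3)
  lin3 <- solve_patterns_linear(map3, pop, list(A = "A", B = "B"))
  expect_equal(lin2$coef, lin3$coef, tolerance = 1e-9)
})

test_that("anchored noiseless fit recovers all rates and patterns exactly", {
  x <- make_small_model(noise = 0)
  anchors <- iam_anchor_patterns(x$cfg)
  fit <- global_fit(x$map, x$cfg$network,
                    fit_config(restarts = 8, seed = 3, anchors = anchors),
                    irf = x$cfg$irf)
  ktrue <- unclass(dt_rates())[fit$rate_symbols]
  expect_lt(max(abs(fit$rates_mean - ktrue) / ktrue), 1e-3)
  expect_lt(max(fit$rates_sd / fit$rates_mean), 1e-3)
  expect_equal(fit$gamma_mean, x$cfg$gamma, tolerance = 1e-6)
  # the one free pattern (DT*) is recovered too
  truthv <- x$cfg$gamma * x$truth$patterns[["DT*"]]$percent
  expect_lt(max(abs(fit$patterns[, "DT*"] - truthv)) / max(abs(truthv)), 1e-3)
})

test_that("free-pattern fits are flagged by their restart scatter", {
  # without anchors only the exponential spectrum is identifiable; the
  # restart spread of individual rates is then large even at zero noise
  x <- make_small_model(noise = 0)
  fit <- tryCatch(
    global_fit(x$map, x$cfg$network,
               fit_config(restarts = 6, seed = 5, keep_factor = 2),
               irf = x$cfg$irf),
    error = function(e) e)
  if (inherits(fit, "error")) {
    # every restart stranded on a bound or failed: the gauge freedom shows
    # up as non-convergence diagnostics instead of scatter
    expect_match(conditionMessage(fit), "restart")
  } else {
    ktrue <- unclass(dt_rates())[fit$rate_symbols]
    expect_gt(max(abs(fit$rates_best - ktrue) / ktrue), 0.05)
  }
})

test_that("estimate_gamma recovers scales and mediates conflicting anchors", {
  q <- default_qgrid(n = 20)
  S <- sin(q) + 2
  expect_equal(estimate_gamma(list(g = 0.045 * S), list(g = S))$gamma, 0.045)

  # two anchors with conflicting scales: weighted least-squares compromise
  S2 <- cos(q) + 3
  ex <- list(a = 0.04 * S, b = 0.06 * S2)
  th <- list(a = S, b = S2)
  g <- estimate_gamma(ex, th)
  g_hand <- (sum(0.04 * S * S) + sum(0.06 * S2 * S2)) /
    (sum(S * S) + sum(S2 * S2))
  expect_equal(g$gamma, g_hand, tolerance = 1e-12)
  expect_gt(g$scale_mismatch, 0)
  expect_error(estimate_gamma(list(g = S), list(g = rep(0, 20))), "zero-norm")
})

test_that("residual maps carry their summary statistics", {
  x <- make_small_model(noise = 0.1)
  model <- signal_map(x$map$q, x$map$t, attr(x$map, "truth")$clean,
                      x$map$sigma)
  r <- residual_map(x$map, model)
  expect_equal(dim(r$values), dim(x$map$values))
  n <- length(r$values)
  expect_lt(abs(attr(r, "mean_residual")), 3 * 0.1 / sqrt(n))
  expect_lt(abs(attr(r, "lag1_autocorrelation")), 0.15)

  expect_equal(residual_map(x$map, x$map)$values,
               matrix(0, nrow(x$map$values), ncol(x$map$values)))
  zero <- signal_map(x$map$q, x$map$t, 0 * x$map$values, x$map$sigma)
  expect_equal(residual_map(x$map, zero)$values, x$map$values)
  bad <- signal_map(x$map$q + 0.01, x$map$t, x$map$values, x$map$sigma)
  expect_error(residual_map(x$map, bad), "grids")
})

test_that("pattern comparison scores and ranks candidate structures", {
  cfg <- small_scenario()
  q <- cfg$q
  rs <- reference_structures()
  off <- debye_pattern(rs$DT, q)
  fb0 <- percent_difference(mixture_pattern(reference_structures(z = 0)$FB, q), off)
  fb1 <- percent_difference(mixture_pattern(reference_structures(z = 1)$FB, q), off)

  expect_equal(compare_patterns(fb0, fb0)$chisq_dof, 0)

  # synthetic extraction generated from z = 0 with 1-sigma noise
  set.seed(7)
  sig <- rep(0.3, length(q))
  ex <- diff_pattern(q, fb0$percent + stats::rnorm(length(q), 0, sig[1]),
                     sigma = sig)
  expect_equal(compare_patterns(ex, fb0)$chisq_dof, 1, tolerance = 0.5)
  rk <- rank_candidates(ex, list(z0 = fb0, z1 = fb1))
  expect_equal(rk$candidate[1], "z0")

  shifted <- fb0; shifted$q <- fb0$q + 100
  expect_error(compare_patterns(ex, shifted), "overlap")
})

test_that("signal maps round trip through their text format", {
  x <- make_small_model(noise = 0.1, seed = 3L)
  tf <- withr::local_tempfile(fileext = ".txt")
  write_signal_map(x$map, tf)
  back <- read_signal_map(tf)
  expect_equal(back$q, x$map$q, tolerance = 1e-9)
  expect_equal(back$t, x$map$t, tolerance = 1e-9)
  expect_equal(back$values, x$map$values, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$sigma, x$map$sigma, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$seed, 3L)
})
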