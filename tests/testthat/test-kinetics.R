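# Reaction-network construction, population dynamics, IRF convolution,
# equilibrium and asymptotic product fractions.

test_that("the default dithiane network has the published topology", {
  net <- default_dt_network()
  expect_equal(nrow(net$species), 6)
  expect_equal(nrow(net$edges), 8)
  expect_equal(sum(net$edges$from == "DT*"), 3)
  expect_equal(sum(net$edges$from == "FA-2"), 0)
  expect_equal(sum(net$edges$from == "FB"), 0)
  expect_error(default_dt_network(c("FA-1->FA-2" = "k5",
                                    "DT_hot->FB" = "k5",
                                    "biradical->FA-2" = "k7")),
               "one-to-one")
})

test_that("network invariants are enforced", {
  sp <- data.frame(name = c("A", "B"), role = c("excited", "product"),
                   group = c("A", "B"))
  expect_error(reaction_network(sp, data.frame(from = "B", to = "A", rate = "k"),
                                "A"), "product")
  sp3 <- data.frame(name = c("A", "B", "C"),
                    role = c("excited", "product", "product"),
                    group = c("A", "B", "C"))
  expect_error(reaction_network(sp3, data.frame(from = "A", to = "B", rate = "k"),
                                "A"), "reachable")
})

test_that("a single decay reproduces the exponential closed form", {
  net <- reaction_network(
    data.frame(name = c("A", "B"), role = c("excited", "product"),
               group = c("A", "B")),
    data.frame(from = "A", to = "B", rate = "k1"), "A")
  # k1 = 1/ps; at t = 1 ps the excited fraction is 1/e
  p <- solve_populations(net, c(k1 = 1), instrument_response(0, 0),
                         tgrid = c(500, 1000, 2000))
  expect_equal(unname(p$F[, "A"]), exp(-c(0.5, 1, 2)), tolerance = 1e-9)
  expect_equal(unname(p$F[2, "A"]), exp(-1), tolerance = 1e-9)
})

test_that("the fast-phase decay and branching follow the rate table", {
  net <- default_dt_network()
  r <- dt_rates()
  lam <- (r[["k1"]] + r[["k3"]] + r[["k4"]]) / 1000   # 1/fs
  expect_equal(1 / lam, 100.6, tolerance = 1e-3)      # total decay constant, fs
  p <- solve_populations(net, r, instrument_response(0, 0),
                         tgrid = c(1 / lam, 10000))
  expect_equal(unname(p$F[1, "DT*"]), exp(-1), tolerance = 1e-6)
  # with the slow drains off, the biradical/hot pool ends the fast phase
  # holding the competing-channels branching fraction k1/(k1+k3+k4)
  r0 <- rate_set(4.23, 0.95, 0.31, 2.86, 2.85, 0, 0, 0)
  p0 <- solve_populations(net, r0, instrument_response(0, 0), tgrid = 10000)
  pool <- sum(p0$F[1, c("biradical", "DT_hot")])
  expect_equal(pool, r[["k1"]] / (r[["k1"]] + r[["k3"]] + r[["k4"]]),
               tolerance = 1e-6)
})

test_that("populations conserve the excited subpopulation and stay in [0,1]", {
  tg <- default_delay_grid()
  for (seed in 1:6) {
    rn <- random_network(sample(3:6, 1), seed)
    p <- solve_populations(rn$network, rn$rates, instrument_response(238, 0), tg)
    tot <- rowSums(p$F)
    after <- tg > 600   # well past the IRF onset
    expect_lt(max(abs(tot[after] - 1)), 1e-6)
    expect_gt(min(p$F), -1e-9)
    expect_lt(max(p$F), 1 + 1e-9)
  }
})

test_that("IRF convolution preserves population and has the delta limit", {
  net <- default_dt_network()
  r <- dt_rates()
  tg <- default_delay_grid()
  p_irf <- solve_populations(net, r, instrument_response(238, 0), tg)
  # total population equals the Gaussian CDF of the excitation
  sigma <- 238 / (2 * sqrt(2 * log(2)))
  expect_equal(rowSums(p_irf$F), stats::pnorm(tg / sigma), tolerance = 1e-6)
  # narrow IRF approaches the delta response
  p_nar <- solve_populations(net, r, instrument_response(1e-3, 0), tg)
  p_del <- solve_populations(net, r, instrument_response(0, 0), tg)
  expect_equal(p_nar$F[tg > 5, ], p_del$F[tg > 5, ], tolerance = 1e-7)
})

test_that("analytic and stiff numerical solvers agree to 1e-6", {
  net <- default_dt_network()
  r <- dt_rates()
  tg <- c(10, 100, 500, 1000, 5000, 1e4, 1e5, 1e6, 3e6)   # 10 fs - 3 ns
  pa <- solve_populations(net, r, instrument_response(238, 0), tg,
                          method = "analytic")
  pn <- solve_populations(net, r, instrument_response(238, 0), tg,
                          method = "numeric")
  expect_lt(max(abs(pa$F - pn$F)), 1e-6)
})

test_that("negative rates are rejected", {
  expect_error(rate_set(-1, 1, 1, 1, 1, 1, 1, 1), "finite")
  net <- default_dt_network()
  bad <- unclass(dt_rates()); bad["k1"] <- -2
  expect_error(solve_populations(net, bad), ">= 0")
})

test_that("the biradical/hot equilibrium constant is k2/km2", {
  expect_equal(equilibrium_ratio(rate_set(1, 2, 2, 0, 0, 0, 0, 0)), 1)
  expect_equal(equilibrium_ratio(dt_rates()), 0.95 / 0.31)
  expect_equal(equilibrium_ratio(dt_rates()), 3.06, tolerance = 2e-3)
  expect_error(equilibrium_ratio(rate_set(1, 1, 0, 0, 0, 0, 0, 0)), "km2")

  # detailed-balance limit of the full solution with the drains off
  r0 <- rate_set(4.23, 0.95, 0.31, 2.86, 2.85, 0, 0, 0)
  p <- solve_populations(default_dt_network(), r0, instrument_response(238, 0),
                         tgrid = 2e5)
  expect_equal(unname(p$F[1, "DT_hot"] / p$F[1, "biradical"]), 0.95 / 0.31,
               tolerance = 1e-4)
})

test_that("asymptotic product fractions solve the absorption problem", {
  net1 <- reaction_network(
    data.frame(name = c("DT*", "FB"), role = c("excited", "product"),
               group = c("DT*", "FB")),
    data.frame(from = "DT*", to = "FB", rate = "k4"), "DT*")
  expect_equal(asymptotic_fractions(net1, c(k4 = 1)), c(FB = 1))

  f <- asymptotic_fractions(default_dt_network(), dt_rates())
  expect_equal(sum(f), 1, tolerance = 1e-10)
  expect_gt(f[["FB"]], 0.60)
  expect_lt(f[["FB"]], 0.66)
  expect_equal(f[["FA-2"]], 1 - f[["FB"]], tolerance = 1e-10)

  # conservation across random rate sets
  net <- default_dt_network()
  set.seed(99)
  for (i in 1:100) {
    rr <- rate_set(runif(1, 0.5, 10), runif(1, 0.1, 2), runif(1, 0.1, 2),
                   runif(1, 0.5, 10), runif(1, 0.5, 10),
                   runif(1, 1e-3, 0.1), runif(1, 1e-3, 0.1), runif(1, 1e-3, 0.1))
    expect_equal(sum(asymptotic_fractions(net, rr)), 1, tolerance = 1e-8)
  }
})

test_that("trapped species are reported by name", {
  sp <- data.frame(name = c("A", "B", "P"),
                   role = c("excited", "intermediate", "product"),
                   group = c("A", "B", "P"))
  ed <- data.frame(from = c("A", "A"), to = c("B", "P"), rate = c("k1", "k2"))
  net <- reaction_network(sp, ed, "A")
  expect_error(asymptotic_fractions(net, c(k1 = 1, k2 = 1)), "B")
})

test_that("long-time fractions from the ODE match the closed form", {
  net <- default_dt_network()
  r <- dt_rates()
  f <- asymptotic_fractions(net, r)
  p <- solve_populations(net, r, instrument_response(238, 0), tgrid = 5e7)
  expect_equal(unname(p$F[1, "FB"]), f[["FB"]], tolerance = 1e-4)
  expect_equal(unname(p$F[1, "FA-2"]), f[["FA-2"]], tolerance = 1e-4)
})
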