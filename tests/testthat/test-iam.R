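# Independent atom model: form factors, Debye patterns, mixtures and
# percent differences.

test_that("form factors are normalized to the electron count and decay", {
  for (el in ff_elements()) {
    Z <- atomic_number(el)
    expect_equal(atomic_form_factor(el, 0), Z, tolerance = 1e-3)
  }
  q <- seq(0, 10, length.out = 200)
  for (el in c("H", "C", "S")) {
    f <- atomic_form_factor(el, q)
    expect_true(all(f > 0))
    expect_true(all(diff(f) <= 1e-12))
  }
})

test_that("carbon form factor matches a direct evaluation of the tabulation", {
  # independent hand evaluation of the four-Gaussian sum at q = 2/A
  a <- c(2.31000, 1.02000, 1.58860, 0.865000)
  b <- c(20.8439, 10.2075, 0.568700, 51.6512)
  cc <- 0.215600
  s2 <- (2 / (4 * pi))^2
  f_hand <- sum(a * exp(-b * s2)) + cc
  f_pkg <- atomic_form_factor("C", 2)
  expect_equal(f_pkg, f_hand, tolerance = 1e-12)
  expect_gt(f_pkg, 0)
  expect_lt(f_pkg, 6)
})

test_that("unsupported elements give an informative error", {
  expect_error(atomic_form_factor("Xx", 1), "Xx")
  expect_error(atomic_number("Zz"), "Zz")
})

test_that("one- and two-atom Debye patterns have their closed forms", {
  q <- c(0, 0.5, 1, 2, 4)
  s <- geometry("S", matrix(0, 1, 3), "S")
  p <- debye_pattern(s, q)
  fS <- atomic_form_factor("S", q)
  expect_equal(p$intensity, fS^2)
  expect_equal(p$intensity[1], atomic_number("S")^2, tolerance = 2.1e-4)

  r <- 1.889
  s2 <- geometry(c("S", "S"), rbind(c(0, 0, 0), c(r, 0, 0)), "S2")
  p2 <- debye_pattern(s2, q)
  sinc <- ifelse(q == 0, 1, sin(q * r) / (q * r))
  expect_equal(p2$intensity, 2 * fS^2 * (1 + sinc), tolerance = 1e-12)
})

test_that("coincident atoms hit the sinc limit without error", {
  g <- geometry(c("S", "S"), matrix(0, 2, 3), "2S@origin")
  p <- debye_pattern(g, c(1, 2))
  expect_equal(p$intensity, (2 * atomic_form_factor("S", c(1, 2)))^2)
})

test_that("non-finite coordinates are rejected", {
  expect_error(geometry("S", matrix(NaN, 1, 3)), "finite")
  expect_error(geometry("S", matrix(Inf, 1, 3)), "finite")
})

test_that("Debye pattern matches Monte-Carlo orientational averaging", {
  qv <- c(0.8, 1.7, 3.1)
  for (seed in 1:5) {
    g <- random_geometry(sample(3:6, 1), seed = 100 + seed)
    p <- debye_pattern(g, qv)
    mc <- mc_orientation_average(g, qv, n_orient = 4e4, seed = seed)
    expect_true(all(abs(p$intensity - mc$mean) <= 3 * mc$se),
                info = paste("geometry seed", seed))
  }
})

test_that("forward intensity equals the squared electron count", {
  for (seed in 1:8) {
    g <- random_geometry(sample(2:7, 1), seed = 200 + seed)
    p <- debye_pattern(g, c(0, 1))
    expect_equal(p$intensity[1], electron_count(g)^2, tolerance = 5e-3)
  }
})

test_that("patterns are invariant under rigid rotation and translation", {
  g <- random_geometry(5, seed = 42)
  q <- default_qgrid(n = 20)
  p0 <- debye_pattern(g, q)
  for (seed in 1:4) {
    g2 <- transform_geometry(g, random_rotation(seed),
                             stats::runif(3, -5, 5))
    expect_equal(debye_pattern(g2, q)$intensity, p0$intensity,
                 tolerance = 1e-9)
  }
})

test_that("mixture patterns add incoherently and are permutation invariant", {
  q <- default_qgrid(n = 25)
  s <- geometry("S", matrix(0, 1, 3), "S")
  two_s <- mixture_pattern(list(s, s), q)
  expect_equal(two_s$intensity, 2 * atomic_form_factor("S", q)^2)

  rs <- reference_structures()
  fb <- rs$FB
  m1 <- mixture_pattern(fb, q)
  m2 <- mixture_pattern(rev(fb), q)
  expect_equal(m1$intensity, m2$intensity)
  expect_equal(m1$intensity,
               debye_pattern(fb[[1]], q)$intensity +
                 debye_pattern(fb[[2]], q)$intensity)
  expect_error(mixture_pattern(list(), q), "at least one")
})

test_that("the S2 interference term decays at large q", {
  q <- c(30, 60)
  s2 <- geometry(c("S", "S"), rbind(c(0, 0, 0), c(1.889, 0, 0)), "S2")
  p <- debye_pattern(s2, q)
  base <- 2 * atomic_form_factor("S", q)^2
  expect_lt(max(abs(p$intensity / base - 1)), 0.02)
})

test_that("fragment mixture forward intensity counts electrons per fragment", {
  rs <- reference_structures()
  p <- mixture_pattern(rs$FB, q = c(1e-9, 1))
  # (Z of C4H8)^2 + (Z of S2)^2 = 32^2 + 32^2
  expect_equal(p$intensity[1], 2048, tolerance = 5e-3)
})

test_that("percent difference behaves as a relative signal", {
  q <- default_qgrid(n = 30)
  rs <- reference_structures()
  off <- debye_pattern(rs$DT, q)
  expect_equal(percent_difference(off, off)$percent, rep(0, length(q)))

  on <- off
  on$intensity <- 1.01 * off$intensity
  expect_equal(percent_difference(on, off)$percent, rep(1, length(q)),
               tolerance = 1e-12)

  bad <- debye_pattern(rs$DT, default_qgrid(n = 29))
  expect_error(percent_difference(bad, off), "grid")
  zero <- off
  zero$intensity[3] <- 0
  expect_error(percent_difference(on, zero), "positive")
})

test_that("dissociation gives a negative percent-difference lobe at low q", {
  q <- default_qgrid()
  rs <- reference_structures()
  off <- debye_pattern(rs$DT, q)
  on <- mixture_pattern(rs$FB, q)
  d <- percent_difference(on, off)
  expect_lt(mean(d$percent[q < 1.5]), 0)
})

test_that("built-in reference structures satisfy their invariants", {
  rs <- reference_structures()
  expect_named(rs, c("DT", "biradical", "FA-1", "FA-2", "FB"))

  dt <- rs$DT
  expect_length(dt$elements, 14)           # C4H8S2
  expect_equal(sort(table(dt$elements)), sort(table(c(rep("C", 4), rep("H", 8), rep("S", 2)))))
  d <- pair_distances(dt)
  ss <- d[dt$elements == "S", dt$elements == "S"]
  expect_equal(ss[1, 2], 2.06, tolerance = 0.01)

  fb <- rs$FB
  heavy <- unlist(lapply(fb, function(g) g$elements))
  expect_equal(sum(heavy == "C"), 4)
  expect_equal(sum(heavy == "S"), 2)

  for (entry in rs) {
    gs <- if (inherits(entry, "geometry")) list(entry) else entry
    for (g in gs) {
      expect_true(all(is.finite(g$coords)))
      expect_true(all(g$elements %in% ff_elements()))
      if (length(g$elements) > 1) {
        dd <- pair_distances(g)
        expect_gt(min(dd[upper.tri(dd)]), 0.8)   # no atom collisions
      }
    }
  }
  # hydrogen-transfer variants keep total composition
  rs1 <- reference_structures(x = 1, z = 1)
  for (ch in c("FA-1", "FB")) {
    els <- unlist(lapply(rs1[[ch]], function(g) g$elements))
    expect_equal(sum(els == "H"), 8)
  }
})

test_that("XYZ round trip preserves geometries and multi-frame files", {
  rs <- reference_structures()
  tf <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(list(rs$DT, rs$biradical), tf)
  back <- read_xyz(tf)
  expect_length(back, 2)
  expect_equal(back[[1]]$elements, rs$DT$elements)
  expect_equal(back[[1]]$coords, rs$DT$coords, tolerance = 1e-7)
  expect_equal(back[[2]]$label, "biradical")
})

test_that("pattern text files round trip", {
  q <- default_qgrid(n = 15)
  p <- debye_pattern(reference_structures()$DT, q)
  tf <- withr::local_tempfile(fileext = ".dat")
  write_pattern(p, tf)
  back <- read_pattern(tf)
  expect_s3_class(back, "xs_pattern")
  expect_equal(back$intensity, p$intensity, tolerance = 1e-10)

  d <- percent_difference(mixture_pattern(reference_structures()$FB, q),
                          debye_pattern(reference_structures()$DT, q))
  write_pattern(d, tf)
  back2 <- read_pattern(tf)
  expect_s3_class(back2, "diff_pattern")
  expect_equal(back2$percent, d$percent, tolerance = 1e-10)
})
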