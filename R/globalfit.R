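# Global kinetic analysis of percent-difference scattering maps.
#
# The observable is separable: dI(q,t) = gamma * sum_a S_a(q) F_a(t).
# Fitting uses variable projection: the species-associated patterns (linear
# parameters, with gamma folded in) are solved exactly by weighted linear
# least squares inside a multi-start nonlinear search over the rate
# constants. gamma is recovered afterwards by anchoring extracted product
# patterns to their independent-atom-model simulations.

#' Percent-difference signal map
#'
#' The central observable: a matrix of percent-difference scattering values
#' on a (q, delay) grid with per-point uncertainties.
#'
#' @param q Momentum-transfer grid (1/Angstrom), strictly increasing.
#' @param t Delay grid (fs), strictly increasing.
#' @param values `length(q) x length(t)` matrix of percent differences.
#' @param sigma Per-point standard deviations (same shape, > 0), or a scalar.
#' @param source `"experiment"` or `"synthetic"`.
#' @param seed Optional generating seed (metadata).
#' @return A `signal_map`.
#' @export
signal_map <- function(q, t, values, sigma = 1, source = "synthetic",
                       seed = NULL) {
  .check_qgrid(q)
  if (any(diff(t) <= 0)) stop("delay grid must be strictly increasing")
  values <- as.matrix(values)
  if (!all(dim(values) == c(length(q), length(t)))) {
    stop("values must be a length(q) x length(t) matrix")
  }
  if (length(sigma) == 1L) sigma <- matrix(sigma, length(q), length(t))
  sigma <- as.matrix(sigma)
  if (!all(dim(sigma) == dim(values))) stop("sigma shape must match values")
  if (any(sigma[is.finite(values)] <= 0)) stop("sigma must be > 0 where data present")
  structure(list(q = q, t = t, values = values, sigma = sigma,
                 source = source, seed = seed),
            class = "signal_map")
}

#' @export
print.signal_map <- function(x, ...) {
  cat(sprintf(
    "<signal_map> (%s) %d q x %d delays; q in [%.3g, %.3g] 1/A, t in [%.4g, %.4g] fs\n",
    x$source, length(x$q), length(x$t), min(x$q), max(x$q), min(x$t), max(x$t)))
  invisible(x)
}

#' Write / read a signal map as plain text
#'
#' Self-describing whitespace-separated text: `#`-prefixed metadata, the two
#' axis vectors, then the value and sigma blocks row-per-q.
#'
#' @param map A [signal_map()].
#' @param path File path.
#' @return `path` (write) or a `signal_map` (read).
#' @export
write_signal_map <- function(map, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# signal_map source=%s seed=%s", map$source,
                       if (is.null(map$seed)) "NA" else map$seed),
               paste("# q[1/A]:", paste(format(map$q, digits = 12), collapse = " ")),
               paste("# t[fs]:", paste(format(map$t, digits = 12), collapse = " ")),
               "# values [percent], one row per q"), con)
  utils::write.table(map$values, con, row.names = FALSE, col.names = FALSE)
  writeLines("# sigma [percentage points], one row per q", con)
  utils::write.table(map$sigma, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_signal_map
#' @export
read_signal_map <- function(path) {
  lines <- readLines(path)
  meta <- grep("^# signal_map", lines, value = TRUE)[1]
  q <- scan(text = sub("^# q\\[1/A\\]:", "", grep("^# q\\[1/A\\]:", lines, value = TRUE)),
            quiet = TRUE)
  t <- scan(text = sub("^# t\\[fs\\]:", "", grep("^# t\\[fs\\]:", lines, value = TRUE)),
            quiet = TRUE)
  dat <- lines[!startsWith(lines, "#")]
  vals <- utils::read.table(text = dat[seq_len(length(q))])
  sig <- utils::read.table(text = dat[length(q) + seq_len(length(q))])
  src <- sub(".*source=(\\S+).*", "\\1", meta)
  seed <- sub(".*seed=(\\S+).*", "\\1", meta)
  signal_map(q, t, as.matrix(vals), as.matrix(sig), source = src,
             seed = if (seed == "NA") NULL else as.integer(seed))
}

# Group time-courses G (t x groups) from a population set and a named list of
# species per group. Groups must exactly partition the species set.
.group_courses <- function(populations, groups) {
  sp <- populations$species
  all_g <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(all_g) || !setequal(all_g, sp)) {
    stop("pattern groups must exactly partition the species set")
  }
  G <- vapply(groups, function(g) {
    rowSums(populations$F[, g, drop = FALSE])
  }, numeric(length(populations$t)))
  matrix(G, ncol = length(groups), dimnames = list(NULL, names(groups)))
}

# named list group -> species from a network's species table
.network_groups <- function(network) {
  split(network$species$name, network$species$group)
}

#' Forward model of the percent-difference map
#'
#' The exact separable signal `gamma * sum_g S_g(q) * G_g(t)` where the group
#' time-course `G_g` sums the populations of the species sharing pattern
#' group g. No noise is added.
#'
#' @param gamma Excitation fraction (dimensionless, e.g. 0.045).
#' @param patterns Named list (one entry per group) of per-q pattern values,
#'   or `diff_pattern` objects, on a common q grid.
#' @param populations A `population_set` from [solve_populations()].
#' @param groups Named list mapping group id to the species in it; must
#'   partition the species set.
#' @param sigma Per-point sigma for the returned map (metadata; default 1).
#' @return A [signal_map()].
#' @export
model_signal <- function(gamma, patterns, populations, groups, sigma = 1) {
  G <- .group_courses(populations, groups)
  if (!setequal(names(patterns), names(groups))) {
    stop("patterns must be named by pattern group")
  }
  pv <- lapply(patterns[names(groups)], function(p) {
    if (inherits(p, "diff_pattern")) p$percent else as.numeric(p)
  })
  nq <- unique(lengths(pv))
  if (length(nq) != 1L) stop("patterns must share one q grid")
  qg <- patterns[[1]]
  q <- if (inherits(qg, "diff_pattern")) qg$q else seq_len(nq)
  S <- matrix(unlist(pv), nrow = nq, dimnames = list(NULL, names(groups)))
  signal_map(q, populations$t, gamma * S %*% t(G), sigma = sigma)
}

#' Solve species-associated patterns by weighted linear least squares
#'
#' For each q independently, regresses the measured time trace on the group
#' population time-courses with weights `1/sigma^2`. The coefficients are the
#' products `gamma * S_g(q)` (the excitation fraction is not separable at
#' this stage). Collinear group time-courses (e.g. species locked in a fast
#' equilibrium) are detected via the condition number of the column-scaled
#' weighted design matrix and reported with a warning.
#'
#' @param data A [signal_map()].
#' @param populations A `population_set` on the same delay grid.
#' @param groups Named list of species per pattern group.
#' @param cond_threshold Condition-number threshold above which the design is
#'   flagged as collinear.
#' @return List with `coef` (q x group matrix of `gamma*S`), `cov` (list of
#'   per-q covariance matrices), `condition` (design condition number) and
#'   `collinear` (logical).
#' @export
solve_patterns_linear <- function(data, populations, groups,
                                  cond_threshold = 1e6) {
  stopifnot(inherits(data, "signal_map"))
  if (length(populations$t) != length(data$t) ||
      any(abs(populations$t - data$t) > 1e-9)) {
    stop("population and data delay grids differ")
  }
  G <- .group_courses(populations, groups)
  ng <- ncol(G)
  if (ng > length(data$t)) stop("more pattern groups than delay points")

  # condition number of the column-normalized design (uniform-weight view)
  Gn <- sweep(G, 2, pmax(sqrt(colSums(G^2)), 1e-300), "/")
  kap <- tryCatch(kappa(Gn, exact = TRUE), error = function(e) Inf)
  collinear <- is.finite(cond_threshold) && kap > cond_threshold
  if (collinear) {
    cc <- abs(stats::cor(G))
    diag(cc) <- 0
    worst <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    warning(sprintf(
      "collinear population time-courses (condition number %.3g): groups '%s' and '%s'",
      kap, colnames(G)[worst[1]], colnames(G)[worst[2]]), call. = FALSE)
  }

  nq <- length(data$q)
  coef <- matrix(NA_real_, nq, ng, dimnames = list(NULL, colnames(G)))
  covs <- vector("list", nq)
  # SVD pseudoinverse: returns the minimal-norm solution even when the
  # design is (near-)singular, which the collinearity flag reports above.
  pinv_pieces <- function(X) {
    sv <- svd(X)
    dinv <- ifelse(sv$d > max(sv$d) * 1e-12, 1 / sv$d, 0)
    list(u = sv$u, v = sv$v, dinv = dinv)
  }
  # fast path: weights constant along t for each q -> shared design solve
  row_const <- all(abs(data$sigma - data$sigma[, 1]) < 1e-300)
  if (row_const) {
    pp <- pinv_pieces(G)
    # coef' = V diag(dinv) U' D'
    coef[] <- t(pp$v %*% (pp$dinv * (t(pp$u) %*% t(data$values))))
    XtXi <- pp$v %*% (pp$dinv^2 * t(pp$v))
    for (i in seq_len(nq)) covs[[i]] <- XtXi * data$sigma[i, 1]^2
  } else {
    for (i in seq_len(nq)) {
      sw <- 1 / data$sigma[i, ]
      pp <- pinv_pieces(G * sw)
      coef[i, ] <- pp$v %*% (pp$dinv * crossprod(pp$u, data$values[i, ] * sw))
      covs[[i]] <- pp$v %*% (pp$dinv^2 * t(pp$v))
    }
  }
  list(coef = coef, cov = covs, condition = kap, collinear = collinear,
       q = data$q, groups = names(groups))
}

#' Fit configuration for the global kinetic analysis
#'
#' @param restarts Number of multi-start repeats (random initial rate
#'   guesses). The published analysis used 100; 20 is a desk-scale default.
#' @param seed RNG seed for the initial-guess draws.
#' @param lower,upper Rate bounds in 1/ps (scalar or named per symbol);
#'   initial guesses are drawn log-uniformly inside them.
#' @param anchors Named list of theoretical patterns (`diff_pattern` or
#'   numeric on the data q grid), one per anchored pattern group. Anchored
#'   groups have their pattern fixed to `gamma * theory` with the single
#'   excitation fraction gamma solved linearly inside the fit; the remaining
#'   groups stay free. Anchoring the terminal products (whose structures are
#'   known) is what makes all rate constants identifiable: with every
#'   pattern free, only the exponential spectrum of the network is
#'   constrained by the data and branching ratios are gauge freedom.
#'   `NULL` fits all patterns free.
#' @param init_lower,init_upper Ranges for the log-uniform random initial
#'   guesses, named per rate symbol (may be narrower than the bounds). When
#'   `NULL`, symbols of the dithiane scheme default to their timescale
#'   class -- femtosecond-channel rates (k1, k2, km2, k3, k4) start in
#'   0.05-20 1/ps, slow ground-state rates (k5, k6, k7) in 5e-4-0.2 1/ps,
#'   as a practitioner would set from the visible structure of the map --
#'   and unknown symbols fall back to the bounds.
#' @param fit_t0,fit_irf Free time zero / IRF width (default frozen).
#' @param t0_bounds Bounds for t0 in fs when free.
#' @param irf_bounds Bounds for the IRF FWHM in fs when free.
#' @param cond_threshold Collinearity threshold for the inner linear solve.
#' @param keep_factor Restarts with chi-square above `best * keep_factor`
#'   are excluded from the restart mean/SD. The default keeps only restarts
#'   that reached the best minimum to numerical precision: distinct local
#'   minima, even nearby ones, describe different parameter sets and would
#'   bias the restart statistics.
#' @return A `fit_config` list.
#' @export
fit_config <- function(restarts = 20L, seed = 1L, lower = 1e-4, upper = 50,
                       anchors = NULL, init_lower = NULL, init_upper = NULL,
                       fit_t0 = FALSE, fit_irf = FALSE,
                       t0_bounds = c(-200, 200), irf_bounds = c(50, 600),
                       cond_threshold = 1e6, keep_factor = 1 + 1e-6) {
  stopifnot(restarts >= 1L, all(lower > 0), all(upper > lower),
            keep_factor >= 1)
  structure(list(restarts = as.integer(restarts), seed = as.integer(seed),
                 lower = lower, upper = upper, anchors = anchors,
                 init_lower = init_lower, init_upper = init_upper,
                 fit_t0 = fit_t0, fit_irf = fit_irf, t0_bounds = t0_bounds,
                 irf_bounds = irf_bounds, cond_threshold = cond_threshold,
                 keep_factor = keep_factor),
            class = "fit_config")
}

# class-informed initial-guess ranges (1/ps) for the dithiane rate symbols
.init_range_defaults <- function(rate_syms, lo, up) {
  fast <- c("k1", "k2", "km2", "k3", "k4")
  slow <- c("k5", "k6", "k7")
  il <- ifelse(rate_syms %in% fast, 0.05,
               ifelse(rate_syms %in% slow, 5e-4, lo))
  iu <- ifelse(rate_syms %in% fast, 20,
               ifelse(rate_syms %in% slow, 0.2, up))
  list(lower = pmax(il, lo), upper = pmin(iu, up))
}

# Inner linear solve with anchored groups: model
#   D(q,t) = sum_{g free} c_g(q) G_g(t) + gamma * sum_{g anch} S_g(q) G_g(t)
# Linear in (c, gamma); gamma is profiled out jointly across all q.
.solve_patterns_anchored <- function(data, populations, groups, anchors) {
  G <- .group_courses(populations, groups)
  anames <- names(anchors)
  if (!all(anames %in% colnames(G))) stop("anchor groups not in grouping")
  free <- setdiff(colnames(G), anames)
  Sa <- vapply(anchors, function(p) {
    v <- if (inherits(p, "diff_pattern")) p$percent else as.numeric(p)
    if (length(v) != length(data$q)) stop("anchor pattern q grid mismatch")
    v
  }, numeric(length(data$q)))
  if (any(abs(data$sigma - data$sigma[, 1]) > 1e-300)) {
    stop("anchored solve requires sigma constant along t for each q")
  }
  MA <- Sa %*% t(G[, anames, drop = FALSE])          # q x t fixed course
  X <- G[, free, drop = FALSE]
  if (ncol(X)) {
    sv <- svd(X)
    dinv <- ifelse(sv$d > max(sv$d) * 1e-12, 1 / sv$d, 0)
    # projector onto the orthogonal complement of col(X) in t-space
    proj_perp <- function(Yt) Yt - sv$u %*% (t(sv$u) %*% Yt)   # (t x m)
  } else {
    proj_perp <- identity
  }
  # uniform weights along t (per-q weights constant): valid for the
  # homoscedastic and q-profiled sigma models used throughout
  Dp <- t(proj_perp(t(data$values)))                 # q x t
  Mp <- t(proj_perp(t(MA)))
  wq <- 1 / data$sigma[, 1]^2
  den <- sum(wq * rowSums(Mp^2))
  if (den == 0) stop("anchored course has zero norm")
  gamma <- sum(wq * rowSums(Mp * Dp)) / den
  coef <- matrix(0, length(data$q), ncol(G),
                 dimnames = list(NULL, colnames(G)))
  if (ncol(X)) {
    Dres <- data$values - gamma * MA
    coef[, free] <- t(sv$v %*% (dinv * (t(sv$u) %*% t(Dres))))   # q x free
  }
  coef[, anames] <- gamma * Sa
  model <- coef %*% t(G)
  list(coef = coef, gamma = gamma, model = model, free = free,
       condition = if (ncol(X)) {
         tryCatch(kappa(sweep(X, 2, sqrt(colSums(X^2)), "/"), exact = TRUE),
                  error = function(e) Inf)
       } else 1)
}

# weighted residual vector of one parameter point
.vp_residuals <- function(theta, data, network, groups, irf, rate_syms, config,
                          return_fit = FALSE) {
  nr <- length(rate_syms)
  k <- 10^theta[seq_len(nr)]
  names(k) <- rate_syms
  i <- nr
  t0 <- if (config$fit_t0) theta[[i <- i + 1L]] else irf$t0
  fwhm <- if (config$fit_irf) theta[[i <- i + 1L]] else irf$fwhm
  pop <- solve_populations(network, k, instrument_response(fwhm, t0), data$t)
  if (!is.null(config$anchors)) {
    lin <- .solve_patterns_anchored(data, pop, groups, config$anchors)
    model <- lin$model
  } else {
    lin <- suppressWarnings(
      solve_patterns_linear(data, pop, groups, cond_threshold = Inf))
    lin$gamma <- NA_real_
    G <- .group_courses(pop, groups)
    model <- lin$coef %*% t(G)
  }
  res <- (data$values - model) / data$sigma
  if (return_fit) {
    list(res = res, model = model, lin = lin, pop = pop, rates = k,
         t0 = t0, fwhm = fwhm)
  } else as.numeric(res)
}

#' Global variable-projection fit of a percent-difference map
#'
#' Multi-start nonlinear least squares over the rate constants (and
#' optionally t0 and the IRF width), with the species-associated patterns
#' solved exactly by [solve_patterns_linear()] at every step
#' (variable projection). Initial guesses are drawn log-uniformly within the
#' rate bounds. Restarts that fail to converge or finish hugging a bound are
#' excluded from the reported mean/SD; the best (lowest chi-square) restart
#' supplies the patterns and residual map.
#'
#' @param data A [signal_map()].
#' @param network A [reaction_network()]; its species table defines the
#'   pattern groups.
#' @param config A [fit_config()].
#' @param irf An [instrument_response()] giving the (frozen or initial) IRF.
#' @return A `fit_result`: rate means/SDs over kept restarts (1/ps), the
#'   best-restart patterns `gamma*S` with across-restart SDs, residual map,
#'   weighted chi-square, and per-restart diagnostics.
#' @export
global_fit <- function(data, network, config = fit_config(),
                       irf = instrument_response()) {
  stopifnot(inherits(data, "signal_map"), inherits(network, "reaction_network"))
  if (any(!is.finite(data$values))) stop("non-finite values in data")
  if (length(data$t) < 2L) stop("need at least 2 delays")
  groups <- .network_groups(network)
  rate_syms <- sort(unique(network$edges$rate))
  nr <- length(rate_syms)

  lo <- if (length(config$lower) == 1L) rep(config$lower, nr) else config$lower[rate_syms]
  up <- if (length(config$upper) == 1L) rep(config$upper, nr) else config$upper[rate_syms]
  lo_t <- log10(lo); up_t <- log10(up)
  par_names <- rate_syms
  if (config$fit_t0) {
    lo_t <- c(lo_t, config$t0_bounds[1]); up_t <- c(up_t, config$t0_bounds[2])
    par_names <- c(par_names, "t0")
  }
  if (config$fit_irf) {
    lo_t <- c(lo_t, config$irf_bounds[1]); up_t <- c(up_t, config$irf_bounds[2])
    par_names <- c(par_names, "irf_fwhm")
  }

  ir <- .init_range_defaults(rate_syms, lo, up)
  il <- if (is.null(config$init_lower)) ir$lower else {
    pmax(config$init_lower[rate_syms], lo)
  }
  iu <- if (is.null(config$init_upper)) ir$upper else {
    pmin(config$init_upper[rate_syms], up)
  }
  set.seed(config$seed)
  # Latin-hypercube draws cover the initial-guess box more evenly than
  # independent uniforms, raising the chance that some restart lands in the
  # global basin
  U <- lhs::randomLHS(config$restarts, nr)
  inits <- lapply(seq_len(config$restarts), function(i) {
    th <- log10(il) + U[i, ] * (log10(iu) - log10(il))
    if (config$fit_t0) th <- c(th, stats::runif(1, config$t0_bounds[1], config$t0_bounds[2]))
    if (config$fit_irf) th <- c(th, stats::runif(1, config$irf_bounds[1], config$irf_bounds[2]))
    th
  })

  one_lm <- function(th0, maxiter) {
    # nls.lm warns through its info codes, which are collected in the
    # per-restart diagnostics instead
    suppressWarnings(
      minpack.lm::nls.lm(par = th0, lower = lo_t, upper = up_t,
                         fn = .vp_residuals, data = data, network = network,
                         groups = groups, irf = irf, rate_syms = rate_syms,
                         config = config,
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxiter, ftol = 1e-14, ptol = 1e-12)))
  }
  runs <- lapply(inits, function(th0) {
    fit <- tryCatch({
      f <- one_lm(th0, 200)
      # polish: restarting resets the trust region and escapes shallow
      # stalls; repeat while it still improves
      for (round in 1:3) {
        f2 <- one_lm(f$par, 150)
        improved <- f2$deviance < f$deviance - 1e-9 * (1 + f$deviance)
        if (f2$deviance <= f$deviance) f <- f2
        if (!improved) break
      }
      f
    }, error = function(e) e)
    if (inherits(fit, "error")) {
      return(list(ok = FALSE, reason = conditionMessage(fit)))
    }
    th <- fit$par
    at_bound <- any(th - lo_t < 1e-6) || any(up_t - th < 1e-6)
    converged <- fit$info %in% 1:4
    list(ok = converged && !at_bound, converged = converged,
         theta = th, chisq = fit$deviance,
         info = fit$info, at_bound = at_bound,
         reason = if (!converged) paste("nls.lm info", fit$info)
                  else if (at_bound) "parameter at bound" else "converged")
  })

  kept <- vapply(runs, function(r) isTRUE(r$ok), logical(1))
  if (!any(kept)) {
    # fall back to converged-but-bound-hugging restarts before giving up
    kept <- vapply(runs, function(r) isTRUE(r$converged), logical(1))
    if (any(kept)) {
      warning("all converged restarts finished on a parameter bound; ",
              "results may be unreliable", call. = FALSE)
      for (i in which(kept)) runs[[i]]$ok <- TRUE
    }
  }
  if (!any(kept)) {
    stop("no restart converged cleanly; diagnostics: ",
         paste(vapply(runs, `[[`, character(1), "reason"), collapse = "; "))
  }
  # drop restarts stranded in clearly worse local minima
  chisq_all <- vapply(runs, function(r) {
    if (isTRUE(r$ok)) r$chisq else Inf
  }, numeric(1))
  best_chisq <- min(chisq_all)
  kept <- kept & chisq_all <= best_chisq * config$keep_factor + 1e-12
  for (i in which(chisq_all > best_chisq * config$keep_factor + 1e-12)) {
    if (isTRUE(runs[[i]]$ok)) runs[[i]]$reason <- "local minimum (chi-square off best cluster)"
  }
  thetas <- do.call(rbind, lapply(runs[kept], `[[`, "theta"))
  colnames(thetas) <- par_names
  chisq <- vapply(runs[kept], `[[`, numeric(1), "chisq")
  best <- which.min(chisq)

  rates_all <- 10^thetas[, rate_syms, drop = FALSE]
  fit_best <- .vp_residuals(thetas[best, ], data, network, groups, irf,
                            rate_syms, config, return_fit = TRUE)
  # per-restart patterns (and gamma, when anchored) for across-restart errors
  refits <- lapply(seq_len(nrow(thetas)), function(i) {
    .vp_residuals(thetas[i, ], data, network, groups, irf, rate_syms, config,
                  return_fit = TRUE)$lin
  })
  pat_arr <- simplify2array(lapply(refits, `[[`, "coef"))
  pat_sd <- apply(pat_arr, c(1, 2), stats::sd)
  gammas <- vapply(refits, `[[`, numeric(1), "gamma")

  resid <- signal_map(data$q, data$t, data$values - fit_best$model,
                      data$sigma, source = data$source, seed = data$seed)

  structure(list(
    rate_symbols = rate_syms,
    rates_mean = colMeans(rates_all),
    rates_sd = apply(rates_all, 2, stats::sd),
    rates_best = 10^thetas[best, rate_syms],
    t0 = fit_best$t0, irf_fwhm = fit_best$fwhm,
    gamma = fit_best$lin$gamma,
    gamma_mean = mean(gammas), gamma_sd = stats::sd(gammas),
    patterns = fit_best$lin$coef, patterns_sd = pat_sd,
    pattern_groups = names(groups), q = data$q,
    residuals = resid, chisq = min(chisq),
    n_restarts = config$restarts, n_kept = sum(kept),
    restart_chisq = chisq, restart_rates = rates_all,
    diagnostics = vapply(runs, `[[`, character(1), "reason"),
    condition = fit_best$lin$condition,
    populations = fit_best$pop),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> chi2 = %.4g, %d/%d restarts kept\n",
              x$chisq, x$n_kept, x$n_restarts))
  if (is.finite(x$gamma)) {
    cat(sprintf("  gamma = %.4g +/- %.2g (anchored)\n", x$gamma_mean, x$gamma_sd))
  }
  tc <- 1 / x$rates_mean  # ps
  for (s in x$rate_symbols) {
    cat(sprintf("  %-4s = %.4g +/- %.2g 1/ps   (1/k = %.4g ps)\n",
                s, x$rates_mean[[s]], x$rates_sd[[s]], tc[[s]]))
  }
  invisible(x)
}

#' Anchor extracted patterns to theory: the excitation fraction
#'
#' The fit determines only the products `gamma * S_g(q)` (a scale shared by
#' gamma and the patterns). Given independent-atom-model simulations of the
#' patterns for one or more anchor groups (typically the terminal products,
#' whose structures are well defined), the excitation fraction is the
#' weighted least-squares scale factor between extraction and theory.
#'
#' @param extracted Named list (or q x group matrix) of extracted
#'   `gamma * S` values per anchor group.
#' @param theory Named list of theoretical patterns (`diff_pattern` or
#'   numeric) for the same groups on the same q grid.
#' @param weights Optional per-q weights (default uniform).
#' @return List with `gamma` (scalar), `per_group` (scale per anchor group)
#'   and `scale_mismatch` (max relative spread across groups).
#' @export
estimate_gamma <- function(extracted, theory, weights = NULL) {
  if (is.matrix(extracted)) {
    extracted <- as.list(as.data.frame(extracted))
  }
  anchors <- names(theory)
  if (is.null(anchors) || !all(anchors %in% names(extracted))) {
    stop("theory must be a named list matching extracted groups")
  }
  num <- 0; den <- 0; per <- numeric(0)
  for (g in anchors) {
    Sth <- theory[[g]]
    if (inherits(Sth, "diff_pattern")) Sth <- Sth$percent
    Cg <- as.numeric(extracted[[g]])
    if (length(Sth) != length(Cg)) stop("q grids of extraction and theory differ")
    w <- if (is.null(weights)) rep(1, length(Sth)) else weights
    if (sum(w * Sth^2) == 0) stop("zero-norm theory pattern for group ", g)
    per[g] <- sum(w * Cg * Sth) / sum(w * Sth^2)
    num <- num + sum(w * Cg * Sth)
    den <- den + sum(w * Sth^2)
  }
  gamma <- num / den
  list(gamma = gamma, per_group = per,
       scale_mismatch = if (length(per) > 1) diff(range(per)) / abs(gamma) else 0)
}

#' Residual map and summary statistics
#'
#' @param data,model [signal_map()]s on identical grids.
#' @return A [signal_map()] of `data - model` (sigma carried over) with
#'   attributes `mean_residual` and `lag1_autocorrelation` (mean along t at
#'   fixed q).
#' @export
residual_map <- function(data, model) {
  stopifnot(inherits(data, "signal_map"), inherits(model, "signal_map"))
  if (length(data$q) != length(model$q) || length(data$t) != length(model$t) ||
      any(abs(data$q - model$q) > 1e-9) || any(abs(data$t - model$t) > 1e-9)) {
    stop("data and model grids differ")
  }
  r <- signal_map(data$q, data$t, data$values - model$values, data$sigma,
                  source = data$source, seed = data$seed)
  ac <- apply(r$values, 1, function(v) {
    if (stats::sd(v) == 0) return(0)
    stats::cor(v[-1], v[-length(v)])
  })
  attr(r, "mean_residual") <- mean(r$values)
  attr(r, "lag1_autocorrelation") <- mean(ac)
  r
}

#' Goodness of fit between an extracted and a simulated pattern
#'
#' Error-weighted chi-square per degree of freedom between an extracted
#' species-associated pattern (with error bars) and a candidate simulated
#' pattern. If the q grids differ, the simulation is linearly interpolated
#' onto the extraction grid (the resampling method is recorded).
#'
#' @param extracted A `diff_pattern` with a `sigma` field (per-q error bars).
#' @param simulated A `diff_pattern` (candidate structure).
#' @return List with `chisq_dof`, `n` and `resampled`.
#' @export
compare_patterns <- function(extracted, simulated) {
  stopifnot(inherits(extracted, "diff_pattern"), inherits(simulated, "diff_pattern"))
  qlo <- max(min(extracted$q), min(simulated$q))
  qhi <- min(max(extracted$q), max(simulated$q))
  keep <- extracted$q >= qlo - 1e-9 & extracted$q <= qhi + 1e-9
  if (!any(keep)) stop("no overlapping q support")
  resampled <- !(length(extracted$q) == length(simulated$q) &&
                   all(abs(extracted$q - simulated$q) < 1e-9))
  sim <- if (resampled) {
    stats::approx(simulated$q, simulated$percent, xout = extracted$q[keep])$y
  } else simulated$percent[keep]
  sig <- extracted$sigma
  if (is.null(sig)) sig <- rep(1, length(extracted$q))
  d <- (extracted$percent[keep] - sim) / sig[keep]
  list(chisq_dof = mean(d^2), n = sum(keep), resampled = resampled)
}

#' Rank candidate structures against an extracted pattern
#'
#' @param extracted A `diff_pattern` with error bars.
#' @param candidates Named list of simulated `diff_pattern`s.
#' @return Data frame of candidates ordered by chi-square per dof.
#' @export
rank_candidates <- function(extracted, candidates) {
  sc <- vapply(candidates, function(p) compare_patterns(extracted, p)$chisq_dof,
               numeric(1))
  out <- data.frame(candidate = names(candidates), chisq_dof = sc)
  out[order(out$chisq_dof), , drop = FALSE]
}
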