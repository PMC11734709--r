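# First-order photochemical reaction networks: construction, analytic
# solution of the population rate equations, Gaussian instrument-response
# convolution, and asymptotic product fractions.
#
# Unit conventions: rate constants in 1/ps (i.e. multiples of 1e12 1/s, the
# units of the fitted rate table); delay times in fs.

#' Rate-constant set for the dithiane network
#'
#' @param k1 DT* to biradical rate, 1/ps.
#' @param k2,km2 Forward/backward rates of the biradical / hot-DT equilibrium.
#' @param k3 DT* to FA-1 rate.
#' @param k4 DT* to FB rate.
#' @param k5,k6,k7 Slow ground-state fragmentation rates.
#' @return Named numeric vector of class `rate_set` (all entries >= 0).
#' @export
rate_set <- function(k1, k2, km2, k3, k4, k5, k6, k7) {
  k <- c(k1 = k1, k2 = k2, km2 = km2, k3 = k3, k4 = k4,
         k5 = k5, k6 = k6, k7 = k7)
  if (any(!is.finite(k)) || any(k < 0)) stop("rates must be finite and >= 0")
  structure(k, class = "rate_set")
}

#' Published rate constants of the dithiane photodissociation network
#'
#' The global-fit rate constants of the 200-nm dithiane experiment
#' (time constants 240 fs, 1.05 ps, 3.2 ps, 350 fs, 350 fs, 63 ps, 400 ps,
#' 455 ps).
#'
#' @return A [rate_set()] in 1/ps.
#' @export
dt_rates <- function() {
  rate_set(k1 = 4.23, k2 = 0.95, km2 = 0.31, k3 = 2.86, k4 = 2.85,
           k5 = 0.0158, k6 = 0.0025, k7 = 0.0022)
}

#' Gaussian instrument response (pump-probe cross-correlation)
#'
#' @param fwhm_fs Full width at half maximum in fs (> 0; 0 means an ideal
#'   delta response).
#' @param t0_fs Time-zero offset in fs.
#' @return An `instrument_response` object.
#' @export
instrument_response <- function(fwhm_fs = 238, t0_fs = 0) {
  stopifnot(is.finite(fwhm_fs), fwhm_fs >= 0, is.finite(t0_fs))
  structure(list(fwhm = fwhm_fs, t0 = t0_fs,
                 sigma = fwhm_fs / (2 * sqrt(2 * log(2)))),
            class = "instrument_response")
}

#' Build a first-order reaction network
#'
#' @param species Data frame with columns `name`, `role` (one of `excited`,
#'   `intermediate`, `product`) and `group` (pattern-group id: species sharing
#'   a group share one extracted scattering pattern).
#' @param edges Data frame with columns `from`, `to`, `rate` (a rate-symbol
#'   name present in the [rate_set()] used to solve the network).
#' @param initial Name of the species holding all excited population at t = 0.
#' @return A `reaction_network`.
#' @export
reaction_network <- function(species, edges, initial) {
  species <- as.data.frame(species)
  edges <- as.data.frame(edges)
  stopifnot(all(c("name", "role", "group") %in% names(species)),
            all(c("from", "to", "rate") %in% names(edges)))
  if (anyDuplicated(species$name)) stop("species names must be unique")
  if (!all(edges$from %in% species$name) || !all(edges$to %in% species$name)) {
    stop("edge endpoints must be declared species")
  }
  if (!initial %in% species$name) stop("initial species not in species list")
  prod <- species$name[species$role == "product"]
  if (any(edges$from %in% prod)) {
    stop("product species cannot have outgoing edges: ",
         paste(intersect(edges$from, prod), collapse = ", "))
  }
  # every species must be reachable from the initial one
  reach <- initial
  repeat {
    nxt <- unique(c(reach, edges$to[edges$from %in% reach]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  if (!all(species$name %in% reach)) {
    stop("species not reachable from ", initial, ": ",
         paste(setdiff(species$name, reach), collapse = ", "))
  }
  structure(list(species = species, edges = edges, initial = initial),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat(sprintf("<reaction_network> %d species, %d edges, excitation into %s\n",
              nrow(x$species), nrow(x$edges), x$initial))
  cat(paste(sprintf("  %s -> %s  (%s)", x$edges$from, x$edges$to, x$edges$rate),
            collapse = "\n"), "\n")
  invisible(x)
}

#' The dithiane photodissociation reaction network
#'
#' The six-species scheme of the 200-nm dithiane experiment: the excited
#' reactant DT* branches into the ring-opened biradical (k1), the one-sulfur
#' channel intermediate FA-1 (k3) and the disulfur product FB (k4); the
#' biradical equilibrates with vibrationally hot dithiane DT_hot (k2, km2);
#' three slow ground-state fragmentations drain the intermediates into the
#' final products FA-2 and FB.
#'
#' The published rate table does not state which slow rate symbol belongs to
#' which slow edge; the default assignment (k5: FA-1 to FA-2, k6: DT_hot to
#' FB, k7: biradical to FA-2) best reproduces the reported 35/65 product
#' split and can be overridden.
#'
#' By default the biradical and DT_hot share one pattern group, reflecting
#' that their scattering patterns could not be separated experimentally.
#'
#' @param edge_assignment Named character vector mapping the three slow edges
#'   (names `"FA-1->FA-2"`, `"DT_hot->FB"`, `"biradical->FA-2"`) to three
#'   distinct symbols among `k5`, `k6`, `k7`.
#' @param merge_hot Logical: put biradical and DT_hot in one pattern group.
#' @return A [reaction_network()] with 6 species and 8 edges.
#' @export
default_dt_network <- function(edge_assignment = c("FA-1->FA-2" = "k5",
                                                   "DT_hot->FB" = "k6",
                                                   "biradical->FA-2" = "k7"),
                               merge_hot = TRUE) {
  req <- c("FA-1->FA-2", "DT_hot->FB", "biradical->FA-2")
  if (!setequal(names(edge_assignment), req) ||
      !setequal(unname(edge_assignment), c("k5", "k6", "k7"))) {
    stop("edge_assignment must map the three slow edges one-to-one onto k5, k6, k7")
  }
  species <- data.frame(
    name = c("DT*", "biradical", "DT_hot", "FA-1", "FA-2", "FB"),
    role = c("excited", "intermediate", "intermediate", "intermediate",
             "product", "product"),
    group = c("DT*", "biradical", if (merge_hot) "biradical" else "DT_hot",
              "FA-1", "FA-2", "FB"))
  edges <- data.frame(
    from = c("DT*", "DT*", "DT*", "biradical", "DT_hot",
             "FA-1", "DT_hot", "biradical"),
    to = c("biradical", "FA-1", "FB", "DT_hot", "biradical",
           "FA-2", "FB", "FA-2"),
    rate = c("k1", "k3", "k4", "k2", "km2",
             edge_assignment[["FA-1->FA-2"]],
             edge_assignment[["DT_hot->FB"]],
             edge_assignment[["biradical->FA-2"]]))
  reaction_network(species, edges, "DT*")
}

# Generator matrix K (1/fs) such that dP/dt = K P.
.rate_matrix <- function(network, rates) {
  nm <- network$species$name
  miss <- setdiff(network$edges$rate, names(rates))
  if (length(miss)) stop("rate symbols missing from rate set: ",
                         paste(miss, collapse = ", "))
  K <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
  for (e in seq_len(nrow(network$edges))) {
    k <- unname(rates[[network$edges$rate[e]]]) / 1000  # 1/ps -> 1/fs
    i <- network$edges$from[e]; j <- network$edges$to[e]
    K[j, i] <- K[j, i] + k
    K[i, i] <- K[i, i] - k
  }
  K
}

# Gaussian-convolved exponential decay: (exp(lambda t) theta(t)) * N(0, sigma),
# evaluated stably for lambda <= 0 via the scaled complementary error function.
.emg <- function(lambda, t, sigma) {
  if (sigma <= 0) return(ifelse(t >= 0, exp(lambda * t), 0))
  z <- -(t + lambda * sigma^2) / (sigma * sqrt(2))
  out <- numeric(length(t))
  pos <- z >= 0
  out[pos] <- 0.5 * .erfcx(z[pos]) * exp(-t[pos]^2 / (2 * sigma^2))
  out[!pos] <- 0.5 * exp(pmin(lambda * t[!pos] + lambda^2 * sigma^2 / 2, 700)) *
    .erfc(z[!pos])
  out
}

#' Solve the population rate equations of a reaction network
#'
#' Solves the linear first-order system for the relative populations of all
#' species, starting from a unit delta excitation into the network's initial
#' species, and convolves the response with the Gaussian instrument response.
#' The analytic route uses the eigen-decomposition of the rate matrix (each
#' mode convolves to an exponentially modified Gaussian in closed form); if
#' the decomposition is degenerate or complex, a stiff numerical integration
#' of the IRF-driven system is used instead.
#'
#' Populations are fractions of the excited subpopulation: after the IRF
#' onset they sum to 1.
#'
#' @param network A [reaction_network()].
#' @param rates A [rate_set()] (or named vector) covering all edge symbols,
#'   in 1/ps.
#' @param irf An [instrument_response()].
#' @param tgrid Delay grid in fs (may be irregular).
#' @param method `"auto"`, `"analytic"` or `"numeric"`.
#' @return A `population_set`: list with `t` (fs) and matrix `F`
#'   (time x species).
#' @export
solve_populations <- function(network, rates, irf = instrument_response(),
                              tgrid = default_delay_grid(),
                              method = c("auto", "analytic", "numeric")) {
  method <- match.arg(method)
  if (any(!is.finite(unclass(rates))) || any(unclass(rates) < 0)) {
    stop("rates must be finite and >= 0")
  }
  K <- .rate_matrix(network, rates)
  nm <- colnames(K)
  p0 <- as.numeric(nm == network$initial)
  tt <- tgrid - irf$t0

  use_analytic <- method != "numeric"
  if (use_analytic) {
    eig <- eigen(K)
    ok <- max(abs(Im(eig$values))) < 1e-12 &&
      is.finite(rcond(Re(eig$vectors))) && rcond(Re(eig$vectors)) > 1e-9
    if (!ok && method == "analytic") {
      stop("rate matrix eigen-decomposition is degenerate; use method = 'numeric'")
    }
    use_analytic <- ok
  }
  if (use_analytic) {
    V <- Re(eig$vectors); lam <- pmin(Re(eig$values), 0)
    cc <- solve(V, p0)
    H <- vapply(lam, .emg, numeric(length(tt)), t = tt, sigma = irf$sigma)
    H <- matrix(H, ncol = length(lam))
    F <- H %*% diag(cc, length(cc)) %*% t(V)  # P_s(t) = sum_m V[s,m] c_m H_m(t)
  } else {
    sigma <- irf$sigma
    t_start <- min(min(tt), -6 * max(sigma, 1)) - 1
    g <- if (sigma > 0) {
      function(t) stats::dnorm(t, 0, sigma)
    } else NULL
    if (is.null(g)) {
      deriv <- function(t, y, parms) list(as.numeric(K %*% y))
      times <- sort(unique(c(0, tt[tt >= 0])))
      sol <- deSolve::lsoda(p0, times, deriv, rtol = 1e-10, atol = 1e-12)
      F <- matrix(0, length(tt), length(nm))
      F[tt >= 0, ] <- sol[match(tt[tt >= 0], sol[, 1]), -1, drop = FALSE]
    } else {
      deriv <- function(t, y, parms) list(as.numeric(K %*% y) + g(t) * p0)
      times <- sort(unique(c(t_start, tt)))
      sol <- deSolve::lsoda(rep(0, length(nm)), times, deriv,
                            rtol = 1e-10, atol = 1e-12)
      F <- sol[match(tt, sol[, 1]), -1, drop = FALSE]
    }
  }
  F <- matrix(F, nrow = length(tt), dimnames = list(NULL, nm))
  F[abs(F) < 1e-300] <- 0
  structure(list(t = tgrid, F = F, species = nm, network = network),
            class = "population_set")
}

#' @export
print.population_set <- function(x, ...) {
  cat(sprintf("<population_set> %d delays in [%.4g, %.4g] fs, species: %s\n",
              length(x$t), min(x$t), max(x$t), paste(x$species, collapse = ", ")))
  invisible(x)
}

#' Default pump-probe delay grid
#'
#' Mirrors the experiment's two sampling regimes: linear in the femtosecond
#' window and logarithmic from 1 ps out to 3 ns.
#'
#' @param t_min Start (fs).
#' @param t_switch Boundary between linear and log spacing (fs).
#' @param t_max End (fs).
#' @param n_linear,n_log Points in each regime.
#' @return Increasing numeric vector of delays in fs.
#' @export
default_delay_grid <- function(t_min = -500, t_switch = 1000, t_max = 3e6,
                               n_linear = 40L, n_log = 40L) {
  c(seq(t_min, t_switch, length.out = n_linear),
    exp(seq(log(t_switch), log(t_max), length.out = n_log + 1L))[-1L])
}

#' Equilibrium constant of the biradical / hot-DT exchange
#'
#' @param rates A [rate_set()].
#' @return `k2 / km2`, the long-time DT_hot : biradical population ratio when
#'   the slow drains are switched off.
#' @export
equilibrium_ratio <- function(rates) {
  if (rates[["km2"]] == 0) stop("km2 = 0: no equilibrium is established")
  rates[["k2"]] / rates[["km2"]]
}

#' Asymptotic product fractions of a reaction network
#'
#' Solves the absorption problem of the network in closed form: the fraction
#' of the excited population that ends in each terminal product as t -> Inf.
#' Fractions sum to 1.
#'
#' @param network A [reaction_network()].
#' @param rates A [rate_set()] covering the network's edge symbols.
#' @return Named numeric vector of fractions over the product species.
#' @export
asymptotic_fractions <- function(network, rates) {
  K <- .rate_matrix(network, rates)
  nm <- colnames(K)
  prod <- network$species$name[network$species$role == "product"]
  if (!length(prod)) stop("network has no terminal products")
  tr <- setdiff(nm, prod)
  # every transient must have a path to some product
  reach_prod <- prod
  repeat {
    nxt <- unique(c(reach_prod,
                    network$edges$from[network$edges$to %in% reach_prod]))
    if (length(nxt) == length(reach_prod)) break
    reach_prod <- nxt
  }
  trapped <- setdiff(tr, reach_prod)
  if (length(trapped)) {
    stop("species with no path to any product: ", paste(trapped, collapse = ", "))
  }
  A <- K[tr, tr, drop = FALSE]
  R <- K[prod, tr, drop = FALSE]
  p0 <- as.numeric(tr == network$initial)
  f <- as.numeric(R %*% solve(-A, p0))
  names(f) <- prod
  f
}
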