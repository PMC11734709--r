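# Independent oracles and fixture builders used across the test files.

# Brute-force orientational average of the coherent scattering sum
# |sum_j f_j exp(i q u . r_j)|^2 over uniformly random unit vectors u.
# Returns mean and Monte-Carlo standard error per q value.
mc_orientation_average <- function(geom, qvals, n_orient = 1e5, seed = 1) {
  set.seed(seed)
  u <- matrix(stats::rnorm(3 * n_orient), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  proj <- u %*% t(geom$coords)            # n_orient x atoms
  f <- vapply(geom$elements, atomic_form_factor, numeric(length(qvals)),
              q = qvals)
  f <- matrix(f, nrow = length(qvals))
  mean_I <- se_I <- numeric(length(qvals))
  for (k in seq_along(qvals)) {
    ph <- qvals[k] * proj
    re <- (cos(ph) %*% f[k, ])
    im <- (sin(ph) %*% f[k, ])
    I <- re^2 + im^2
    mean_I[k] <- mean(I)
    se_I[k] <- stats::sd(I) / sqrt(n_orient)
  }
  list(mean = mean_I, se = se_I)
}

# Random small geometry over the supported elements.
random_geometry <- function(n_atoms, seed, spread = 2.5) {
  set.seed(seed)
  geometry(sample(ff_elements(), n_atoms, replace = TRUE),
           matrix(stats::runif(3 * n_atoms, -spread, spread), n_atoms, 3),
           label = paste0("rand", seed))
}

# Random valid first-order network: a chain with random extra forward edges,
# ending in >= 1 absorbing product, all species reachable from the source.
random_network <- function(n_species, seed) {
  set.seed(seed)
  nm <- paste0("S", seq_len(n_species))
  edges <- data.frame(from = nm[-n_species], to = nm[-1],
                      rate = paste0("r", seq_len(n_species - 1)))
  n_extra <- sample(0:2, 1)
  for (i in seq_len(n_extra)) {
    a <- sample(n_species - 1, 1)
    b <- sample(setdiff(seq_len(n_species), seq_len(a)), 1)
    edges <- rbind(edges, data.frame(from = nm[a], to = nm[b],
                                     rate = paste0("x", i)))
  }
  species <- data.frame(name = nm,
                        role = c("excited",
                                 rep("intermediate", n_species - 2), "product"),
                        group = nm)
  list(network = reaction_network(species, edges, nm[1]),
       rates = stats::setNames(stats::runif(nrow(edges), 0.01, 5), edges$rate))
}

# Random 3-D rotation matrix.
random_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(stats::rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Small paper-like scenario with reduced grids for fast fit tests.
small_scenario <- function(noise = 0, seed = 1L, nq = 30L) {
  scenario_config(q = default_qgrid(n = nq),
                  tgrid = default_delay_grid(n_linear = 25L, n_log = 25L),
                  noise = noise, hot_frames = 24L, seed = seed)
}
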