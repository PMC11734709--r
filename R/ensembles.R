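# Ensemble-averaged scattering for vibrationally hot species: geometry pools
# (from multi-frame XYZ trajectories or the built-in toy thermal sampler) and
# their mean IAM patterns.

#' Create a geometry pool
#'
#' A pool of conformers of one species (all frames share the same atomic
#' composition), optionally weighted, used to average scattering patterns
#' over a vibrationally hot ensemble.
#'
#' @param frames List of [geometry()] objects.
#' @param weights Optional non-negative per-frame weights (normalized on use;
#'   default uniform).
#' @param provenance Free-text provenance tag (e.g. a trajectory file name or
#'   `"toy-sampler seed=7"`).
#' @return A `geometry_pool`.
#' @export
geometry_pool <- function(frames, weights = NULL, provenance = "") {
  if (inherits(frames, "geometry")) frames <- list(frames)
  if (!length(frames)) stop("pool needs at least one frame")
  comp <- vapply(frames, function(g) paste(sort(g$elements), collapse = ""),
                 character(1))
  if (length(unique(comp)) != 1L) {
    stop("all frames in a pool must share one atomic composition")
  }
  if (is.null(weights)) weights <- rep(1, length(frames))
  if (length(weights) != length(frames) || any(weights < 0) || sum(weights) == 0) {
    stop("weights must be non-negative, one per frame, not all zero")
  }
  structure(list(frames = frames, weights = weights, provenance = provenance),
            class = "geometry_pool")
}

#' @export
print.geometry_pool <- function(x, ...) {
  cat(sprintf("<geometry_pool> %d frames of %s [%s]\n", length(x$frames),
              x$frames[[1]]$label, x$provenance))
  invisible(x)
}

#' Read a geometry pool from a multi-frame XYZ trajectory
#'
#' @param path Path to a multi-frame XYZ file.
#' @return A [geometry_pool()] with the file recorded as provenance.
#' @export
read_pool_xyz <- function(path) {
  frames <- read_xyz(path)
  message(sprintf("loaded %d frames from %s", length(frames), path))
  geometry_pool(frames, provenance = paste0("file ", path))
}

#' Ensemble-averaged IAM scattering pattern
#'
#' Weighted mean of the per-frame rotationally averaged Debye patterns. The
#' forward intensity I(0) is pool-invariant (the electron count does not
#' depend on geometry); interatomic interference oscillations are damped by
#' the structural spread, never amplified.
#'
#' @param pool A [geometry_pool()].
#' @param q Momentum-transfer grid (1/Angstrom).
#' @return An `xs_pattern`.
#' @export
ensemble_pattern <- function(pool, q = default_qgrid()) {
  stopifnot(inherits(pool, "geometry_pool"))
  w <- pool$weights / sum(pool$weights)
  I <- Reduce(`+`, Map(function(g, wi) wi * debye_pattern(g, q)$intensity,
                       pool$frames, w))
  .new_pattern(q, I, paste0("<", pool$frames[[1]]$label, ">"))
}

#' Toy thermal geometry pool
#'
#' Geometric stand-in for a molecular-dynamics pool of a vibrationally hot
#' species: each frame displaces every Cartesian coordinate of the seed
#' geometry by independent zero-mean Gaussian noise of the stated amplitude.
#' It reproduces the damping of interference oscillations that a physical
#' hot ensemble shows, but none of its mode structure or anharmonicity; real
#' trajectory pools can be supplied via [read_pool_xyz()].
#'
#' @param seed_geometry A [geometry()].
#' @param amplitude Per-coordinate displacement SD in Angstrom (>= 0).
#' @param n Number of frames.
#' @param seed RNG seed (reproducible pools).
#' @return A [geometry_pool()].
#' @export
toy_thermal_pool <- function(seed_geometry, amplitude, n = 100L, seed = 1L) {
  stopifnot(inherits(seed_geometry, "geometry"), amplitude >= 0, n >= 1L)
  na <- length(seed_geometry$elements)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  frames <- lapply(seq_len(n), function(i) {
    geometry(seed_geometry$elements,
             seed_geometry$coords + matrix(stats::rnorm(3 * na, 0, amplitude),
                                           na, 3),
             paste0(seed_geometry$label, "_hot"))
  })
  geometry_pool(frames, provenance = sprintf("toy-sampler amp=%g seed=%d",
                                             amplitude, seed))
}
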