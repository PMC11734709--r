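# Independent atom model scattering: rotationally averaged Debye patterns,
# incoherent fragment mixtures, and percent-difference signals.

#' Default momentum-transfer grid
#'
#' Convention matching the visible q-range of a 9.5-keV gas-phase scattering
#' experiment: 0.5 to 4.5 1/Angstrom in 60 points.
#'
#' @param qmin,qmax Grid limits in 1/Angstrom.
#' @param n Number of points.
#' @return Strictly increasing numeric vector.
#' @export
default_qgrid <- function(qmin = 0.5, qmax = 4.5, n = 60L) {
  seq(qmin, qmax, length.out = n)
}

.check_qgrid <- function(q) {
  if (any(!is.finite(q)) || any(q < 0) || any(diff(q) <= 0)) {
    stop("q grid must be finite, non-negative and strictly increasing")
  }
  q
}

.new_pattern <- function(q, I, label) {
  structure(list(q = q, intensity = I, label = label), class = "xs_pattern")
}

#' @export
print.xs_pattern <- function(x, ...) {
  cat(sprintf("<xs_pattern> %s: %d q-points in [%.3g, %.3g] 1/A\n",
              x$label, length(x$q), min(x$q), max(x$q)))
  invisible(x)
}

#' Rotationally averaged IAM scattering pattern (Debye equation)
#'
#' Computes the elastic scattering intensity of one molecule under the
#' independent atom model, rotationally averaged over molecular orientations:
#' \deqn{I(q) = \sum_{ij} f_i(q) f_j(q) \frac{\sin(q r_{ij})}{q r_{ij}}}
#' with the diagonal and the \eqn{q r_{ij} \to 0} limits handled as
#' \eqn{\mathrm{sinc} \to 1}. At \eqn{q = 0} the intensity equals the squared
#' electron count.
#'
#' @param geom A [geometry()].
#' @param q Momentum-transfer grid, 1/Angstrom (strictly increasing, >= 0).
#' @return An `xs_pattern` with intensities in electron units.
#' @examples
#' s <- geometry("S", matrix(0, 1, 3), "S atom")
#' debye_pattern(s, c(0, 1, 2))$intensity  # f_S(q)^2; 256 at q = 0
#' @export
debye_pattern <- function(geom, q = default_qgrid()) {
  stopifnot(inherits(geom, "geometry"))
  .check_qgrid(q)
  f <- vapply(geom$elements, atomic_form_factor, numeric(length(q)), q = q)
  f <- matrix(f, nrow = length(q))          # q x atoms
  d <- as.matrix(stats::dist(geom$coords))  # atoms x atoms
  n <- length(geom$elements)
  I <- numeric(length(q))
  for (i in seq_len(n)) {
    I <- I + f[, i]^2  # self terms (sinc(0) = 1)
    if (i < n) {
      for (j in seq.int(i + 1L, n)) {
        qr <- q * d[i, j]
        sinc <- ifelse(qr < 1e-12, 1, sin(qr) / ifelse(qr == 0, 1, qr))
        I <- I + 2 * f[, i] * f[, j] * sinc
      }
    }
  }
  .new_pattern(q, I, geom$label)
}

#' Scattering of a mixture of well-separated fragments
#'
#' Incoherent sum of the per-fragment Debye patterns: co-fragments of a
#' dissociation are far apart on the probed length scale, so inter-fragment
#' interference is absent and intensities add.
#'
#' @param geoms Non-empty list of [geometry()] objects.
#' @param q Momentum-transfer grid.
#' @param label Label for the combined pattern.
#' @return An `xs_pattern`.
#' @export
mixture_pattern <- function(geoms, q = default_qgrid(), label = NULL) {
  if (inherits(geoms, "geometry")) geoms <- list(geoms)
  if (!length(geoms)) stop("mixture_pattern needs at least one geometry")
  pats <- lapply(geoms, debye_pattern, q = q)
  I <- Reduce(`+`, lapply(pats, `[[`, "intensity"))
  if (is.null(label)) {
    label <- paste(vapply(geoms, `[[`, character(1), "label"), collapse = " + ")
  }
  .new_pattern(q, I, label)
}

#' Percent-difference scattering signal
#'
#' The pump-probe observable: `100 * (I_on - I_off) / I_off` per q-point,
#' with the unexcited species as reference.
#'
#' @param on,off `xs_pattern` objects on identical q grids; `off` must be
#'   strictly positive everywhere.
#' @return A `diff_pattern` (q grid, percent values, reference label).
#' @export
percent_difference <- function(on, off) {
  stopifnot(inherits(on, "xs_pattern"), inherits(off, "xs_pattern"))
  if (length(on$q) != length(off$q) || any(abs(on$q - off$q) > 1e-12)) {
    stop("q grids of 'on' and 'off' patterns differ")
  }
  if (any(off$intensity <= 0)) stop("reference (off) intensity must be strictly positive")
  structure(list(q = on$q,
                 percent = 100 * (on$intensity - off$intensity) / off$intensity,
                 label = on$label, reference = off$label),
            class = "diff_pattern")
}

#' @export
print.diff_pattern <- function(x, ...) {
  cat(sprintf("<diff_pattern> %s vs %s: %d q-points, range [%.3g, %.3g] %%\n",
              x$label, x$reference, length(x$q), min(x$percent), max(x$percent)))
  invisible(x)
}

#' Construct a diff_pattern from raw values
#'
#' @param q q grid (1/Angstrom).
#' @param percent Percent-difference values.
#' @param label,reference Labels for the species and the reference.
#' @param sigma Optional per-point standard deviation (percentage points).
#' @return A `diff_pattern`.
#' @export
diff_pattern <- function(q, percent, label = "", reference = "", sigma = NULL) {
  .check_qgrid(q)
  stopifnot(length(percent) == length(q), all(is.finite(percent)))
  structure(list(q = q, percent = percent, label = label, reference = reference,
                 sigma = sigma),
            class = "diff_pattern")
}

#' Write a pattern as a plain-text table
#'
#' Two-column (q, value) whitespace-separated table with `#` header lines
#' giving units and labels; readable by [read_pattern()].
#'
#' @param pat An `xs_pattern` or `diff_pattern`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pattern <- function(pat, path) {
  if (inherits(pat, "xs_pattern")) {
    hdr <- c(sprintf("# label: %s", pat$label), "# q[1/A]  I[electron units]")
    tab <- cbind(pat$q, pat$intensity)
  } else if (inherits(pat, "diff_pattern")) {
    hdr <- c(sprintf("# label: %s", pat$label),
             sprintf("# reference: %s", pat$reference),
             "# q[1/A]  dI[percent]")
    tab <- cbind(pat$q, pat$percent)
  } else stop("not a pattern object")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(tab, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a pattern written by [write_pattern()]
#'
#' @param path Input path.
#' @return An `xs_pattern` or `diff_pattern`, depending on the stored header.
#' @export
read_pattern <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")])
  lab <- sub("^# label: ", "", grep("^# label: ", hdr, value = TRUE)[1])
  if (any(grepl("^# reference: ", hdr))) {
    diff_pattern(tab[[1]], tab[[2]], label = lab,
                 reference = sub("^# reference: ", "",
                                 grep("^# reference: ", hdr, value = TRUE)[1]))
  } else {
    .new_pattern(tab[[1]], tab[[2]], lab)
  }
}
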