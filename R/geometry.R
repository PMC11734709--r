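# Molecular geometries: construction, validation, XYZ I/O, and the built-in
# approximate structures of 1,2-dithiane (DT) and its photofragments.

#' Create a molecular geometry
#'
#' A geometry is a set of atoms (element symbols plus Cartesian coordinates in
#' Angstrom) with a free-text label. Coordinates must be finite and every
#' element must be in the supported form-factor set.
#'
#' @param elements Character vector of element symbols.
#' @param coords Numeric matrix with one row per atom and columns x, y, z
#'   (Angstrom).
#' @param label Free-text label for the species.
#' @return An object of class `geometry`.
#' @export
geometry <- function(elements, coords, label = "") {
  coords <- as.matrix(coords)
  if (length(elements) < 1L) stop("geometry needs at least one atom")
  if (nrow(coords) != length(elements) || ncol(coords) != 3L) {
    stop("coords must be a length(elements) x 3 matrix")
  }
  if (any(!is.finite(coords))) stop("non-finite coordinates in geometry")
  bad <- setdiff(unique(elements), ff_elements())
  if (length(bad)) {
    stop("unsupported element(s): ", paste(bad, collapse = ", "))
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(elements = as.character(elements), coords = coords,
                 label = as.character(label)[1]),
            class = "geometry")
}

#' @export
print.geometry <- function(x, ...) {
  cat(sprintf("<geometry> %s: %d atoms (%s)\n", x$label, length(x$elements),
              paste(sprintf("%s%d", names(table(x$elements)),
                            as.integer(table(x$elements))), collapse = " ")))
  invisible(x)
}

#' Number of electrons in a geometry
#'
#' @param geom A [geometry()].
#' @return Total electron count (sum of atomic numbers).
#' @export
electron_count <- function(geom) {
  stopifnot(inherits(geom, "geometry"))
  sum(vapply(geom$elements, atomic_number, integer(1)))
}

#' Pairwise interatomic distances
#'
#' @param geom A [geometry()].
#' @return A symmetric matrix of distances in Angstrom.
#' @export
pair_distances <- function(geom) {
  as.matrix(stats::dist(geom$coords))
}

#' Rigidly transform a geometry
#'
#' Applies a rotation (about the origin) followed by a translation. IAM
#' scattering patterns are invariant under this operation.
#'
#' @param geom A [geometry()].
#' @param rotation 3x3 rotation matrix.
#' @param translation Length-3 numeric shift in Angstrom.
#' @return The transformed [geometry()].
#' @export
transform_geometry <- function(geom, rotation = diag(3), translation = c(0, 0, 0)) {
  stopifnot(inherits(geom, "geometry"))
  geometry(geom$elements,
           geom$coords %*% t(rotation) + matrix(translation, nrow(geom$coords), 3,
                                                byrow = TRUE),
           geom$label)
}

# --- XYZ I/O ----------------------------------------------------------------

#' Read geometries from an XYZ file
#'
#' Reads standard XYZ: atom count, comment line, then `element x y z` rows.
#' Multi-frame (trajectory) files are supported; every frame is returned.
#'
#' @param path Path to an XYZ file.
#' @return A list of [geometry()] objects (length 1 for a single-frame file).
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) > 1 & lines == "" &
                     c("", utils::head(lines, -1)) == "")]
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1L) stop("malformed XYZ atom count at line ", i)
    if (i + 1L + n > length(lines)) stop("truncated XYZ frame at line ", i)
    label <- trimws(lines[i + 1L])
    rows <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "\\s+")
    el <- vapply(rows, `[`, character(1), 1L)
    xyz <- t(vapply(rows, function(r) as.numeric(r[2:4]), numeric(3)))
    frames[[length(frames) + 1L]] <- geometry(el, xyz, label)
    i <- i + 2L + n
  }
  if (!length(frames)) stop("no frames found in ", path)
  frames
}

#' Write geometries to an XYZ file
#'
#' @param geoms A [geometry()] or a list of them (written as a multi-frame
#'   trajectory).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(geoms, path) {
  if (inherits(geoms, "geometry")) geoms <- list(geoms)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in geoms) {
    writeLines(c(as.character(length(g$elements)), g$label,
                 sprintf("%-2s %14.8f %14.8f %14.8f",
                         g$elements, g$coords[, 1], g$coords[, 2], g$coords[, 3])),
               con)
  }
  invisible(path)
}

# --- internal constructive geometry ----------------------------------------

# Place a new atom bonded to atom C with bond length d, bond angle ang
# (new-C-B, degrees) and dihedral dih (new-C-B-A, degrees). a, b, cc are
# coordinates of atoms A, B, C.
.zmat_place <- function(a, b, cc, d, ang, dih) {
  ang <- ang * pi / 180
  dih <- dih * pi / 180
  u <- cc - b; u <- u / sqrt(sum(u^2))
  v <- a - b
  w <- v - sum(v * u) * u
  nw <- sqrt(sum(w^2))
  if (nw < 1e-10) {  # colinear reference frame: pick any perpendicular
    w <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w <- w - sum(w * u) * u
    nw <- sqrt(sum(w^2))
  }
  w <- w / nw
  n <- c(u[2] * w[3] - u[3] * w[2],
         u[3] * w[1] - u[1] * w[3],
         u[1] * w[2] - u[2] * w[1])
  cc + d * (-cos(ang) * u + sin(ang) * (cos(dih) * w + sin(dih) * n))
}

# Two hydrogens completing an sp3 carbon that already has neighbours n1, n2.
.add_ch2 <- function(cpos, n1, n2, d = 1.09, half_angle = 54) {
  u1 <- n1 - cpos; u1 <- u1 / sqrt(sum(u1^2))
  u2 <- n2 - cpos; u2 <- u2 / sqrt(sum(u2^2))
  bis <- -(u1 + u2); bis <- bis / sqrt(sum(bis^2))
  perp <- c(u1[2] * u2[3] - u1[3] * u2[2],
            u1[3] * u2[1] - u1[1] * u2[3],
            u1[1] * u2[2] - u1[2] * u2[1])
  perp <- perp / sqrt(sum(perp^2))
  ha <- half_angle * pi / 180
  rbind(cpos + d * (cos(ha) * bis + sin(ha) * perp),
        cpos + d * (cos(ha) * bis - sin(ha) * perp))
}

# Standard covalent parameters used by all builders (Angstrom, degrees).
.BOND <- list(SS = 2.06, CS = 1.82, CC = 1.53, CCd = 1.34, CH = 1.09,
              SH = 1.34, S2 = 1.889, S2H_SS = 1.95)

# 1,2-dithiane: chair six-ring S-S-C-C-C-C, hydrogens on each carbon.
.build_dt <- function() {
  B <- .BOND
  p <- matrix(0, 6, 3)
  p[1, ] <- c(0, 0, 0)
  p[2, ] <- c(B$SS, 0, 0)
  # ring torsions chosen so the six-ring closes on the last C-S bond
  p[3, ] <- .zmat_place(c(-1, 0, 0), p[1, ], p[2, ], B$CS, 100, 60)
  p[4, ] <- .zmat_place(p[1, ], p[2, ], p[3, ], B$CC, 110, -70)
  p[5, ] <- .zmat_place(p[2, ], p[3, ], p[4, ], B$CC, 110, 70)
  p[6, ] <- .zmat_place(p[3, ], p[4, ], p[5, ], B$CC, 110, -65)
  ring_n <- list(c(2, 4), c(3, 5), c(4, 6), c(5, 1))  # C neighbours in ring
  h <- do.call(rbind, lapply(seq_along(ring_n), function(i) {
    ci <- i + 2L
    .add_ch2(p[ci, ], p[ring_n[[i]][1], ], p[ring_n[[i]][2], ])
  }))
  geometry(c("S", "S", rep("C", 4), rep("H", 8)), rbind(p, h), "DT")
}

# Ring-opened biradical: extended all-anti S-C-C-C-C-S chain, same C4H8S2
# composition as DT.
.build_biradical <- function() {
  B <- .BOND
  p <- matrix(0, 6, 3)
  p[1, ] <- c(0, 0, 0)
  p[2, ] <- c(B$CS, 0, 0)
  p[3, ] <- .zmat_place(c(0, 1, 0), p[1, ], p[2, ], B$CC, 110, 0)
  p[4, ] <- .zmat_place(p[1, ], p[2, ], p[3, ], B$CC, 112, 180)
  p[5, ] <- .zmat_place(p[2, ], p[3, ], p[4, ], B$CC, 112, 180)
  p[6, ] <- .zmat_place(p[3, ], p[4, ], p[5, ], B$CS, 110, 180)
  h <- do.call(rbind, lapply(2:5, function(i) {
    .add_ch2(p[i, ], p[i - 1, ], p[i + 1, ])
  }))
  geometry(c("S", rep("C", 4), "S", rep("H", 8)), rbind(p, h), "biradical")
}

# Tetrahydrothiophene-like C4H8S ring for the one-sulfur fragment; built as a
# planar pentagon with the correct edge lengths, hydrogens above/below.
.build_c4h8s <- function(n_h = 8L) {
  B <- .BOND
  edges <- c(B$CS, B$CC, B$CC, B$CC, B$CS)  # S-C1, C1-C2, C2-C3, C3-C4, C4-S
  fr <- function(R) sum(2 * asin(pmin(edges / (2 * R), 1))) - 2 * pi
  R <- stats::uniroot(fr, c(max(edges) / 2 + 1e-9, 10))$root
  th <- cumsum(c(0, 2 * asin(edges[-5] / (2 * R))))
  p <- cbind(R * cos(th), R * sin(th), 0)
  ring_n <- list(c(1, 3), c(2, 4), c(3, 5), c(4, 1))  # neighbours of C1..C4
  h <- do.call(rbind, lapply(seq_along(ring_n), function(i) {
    .add_ch2(p[i + 1L, ], p[ring_n[[i]][1], ], p[ring_n[[i]][2], ])
  }))
  if (n_h < 8L) h <- h[seq_len(n_h), , drop = FALSE]
  geometry(c("S", rep("C", 4), rep("H", n_h)), rbind(p, h),
           sprintf("C4H%dS", n_h))
}

# 1-butene-like C4H8 skeleton for the sulfur-free co-fragment.
.build_c4h8 <- function(n_h = 8L) {
  B <- .BOND
  p <- matrix(0, 4, 3)
  p[1, ] <- c(0, 0, 0)
  p[2, ] <- c(B$CCd, 0, 0)
  p[3, ] <- .zmat_place(c(0, 1, 0), p[1, ], p[2, ], 1.50, 124, 0)
  p[4, ] <- .zmat_place(p[1, ], p[2, ], p[3, ], B$CC, 112, 180)
  # sp2 hydrogens on C1 (2) and C2 (1), sp3 on C3 (2) and C4 (3)
  h <- rbind(
    .zmat_place(p[3, ], p[2, ], p[1, ], 1.08, 120, 0),
    .zmat_place(p[3, ], p[2, ], p[1, ], 1.08, 120, 180),
    .zmat_place(p[4, ], p[3, ], p[2, ], 1.08, 118, 0),
    .add_ch2(p[3, ], p[2, ], p[4, ]),
    .zmat_place(p[2, ], p[3, ], p[4, ], B$CH, 110, 180),
    .zmat_place(p[2, ], p[3, ], p[4, ], B$CH, 110, 60),
    .zmat_place(p[2, ], p[3, ], p[4, ], B$CH, 110, -60))
  if (n_h < 8L) h <- h[seq_len(n_h), , drop = FALSE]
  geometry(c(rep("C", 4), rep("H", n_h)), rbind(p, h), sprintf("C4H%d", n_h))
}

.build_s2 <- function(n_h = 0L) {
  B <- .BOND
  if (n_h == 0L) {
    return(geometry(c("S", "S"), rbind(c(0, 0, 0), c(B$S2, 0, 0)), "S2"))
  }
  p3 <- .zmat_place(c(0, 1, 0), c(0, 0, 0), c(B$S2H_SS, 0, 0), B$SH, 98, 0)
  geometry(c("S", "S", "H"), rbind(c(0, 0, 0), c(B$S2H_SS, 0, 0), p3), "S2H")
}

.build_sh <- function(n_h = 0L) {
  if (n_h == 0L) return(geometry("S", matrix(0, 1, 3), "S"))
  geometry(c("S", "H"), rbind(c(0, 0, 0), c(.BOND$SH, 0, 0)), "SH")
}

#' Built-in reference structures of dithiane and its photofragments
#'
#' Returns approximate geometries, constructed from standard covalent bond
#' lengths and angles (C-C 1.53, C-S 1.82, S-S 2.06 Angstrom, tetrahedral
#' carbons), for the species of the dithiane photodissociation network:
#' the chair-form reactant `DT`, the ring-opened S-C4-S `biradical`, and the
#' fragmentation channels `FA-1` (C4H(8-x)S + SHx), `FA-2`
#' (C4H(8-x-y) + SHx + SHy) and `FB` (C4H(8-z) + S2Hz). Channels are lists of
#' co-fragment geometries whose scattering adds incoherently.
#'
#' Hydrogen placement on the sulfur fragments is configurable because x-ray
#' scattering barely distinguishes it; the default keeps all hydrogens on the
#' carbon skeletons.
#'
#' @param x,y,z Hydrogen transfer counts (0 or 1) for the FA-1/FA-2 sulfur
#'   fragments (`x`, `y`) and the FB disulfur fragment (`z`).
#' @return Named list with entries `DT`, `biradical` ([geometry()]s) and
#'   `FA-1`, `FA-2`, `FB` (lists of [geometry()]s).
#' @export
reference_structures <- function(x = 0L, y = 0L, z = 0L) {
  stopifnot(x %in% 0:1, y %in% 0:1, z %in% 0:1)
  list(
    "DT" = .build_dt(),
    "biradical" = .build_biradical(),
    "FA-1" = list(.build_c4h8s(8L - x), .build_sh(x)),
    "FA-2" = list(.build_c4h8(8L - x - y), .build_sh(x), .build_sh(y)),
    "FB" = list(.build_c4h8(8L - z), .build_s2(z))
  )
}
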