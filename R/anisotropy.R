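# Simplified 2-D detector images with pump-induced alignment: pixel q/angle
# maps, rendering of S0 + S2*P2 images, and the inverse isotropic/anisotropic
# decomposition.

#' Flat-detector geometry
#'
#' A single flat square detector standing in for the experiment's tiled
#' pixel-array detector. The beam travels along +z and hits the detector
#' plane perpendicularly; the pump polarization and x-ray polarization axes
#' lie in the detector plane.
#'
#' @param distance_mm Sample-detector distance.
#' @param pixel_mm Pixel pitch.
#' @param npix Image size (npix x npix).
#' @param center Beam center in pixel units (defaults to the image center).
#' @param energy_kev X-ray photon energy.
#' @param pump_axis Pump polarization direction in the detector plane
#'   (length-2, normalized internally).
#' @param xray_pol X-ray polarization direction in the detector plane (for
#'   the Thomson polarization factor).
#' @return A `detector_geometry`.
#' @export
detector_geometry <- function(distance_mm = 50, pixel_mm = 2.5, npix = 64L,
                              center = NULL, energy_kev = 9.5,
                              pump_axis = c(0, 1), xray_pol = c(1, 0)) {
  stopifnot(distance_mm > 0, pixel_mm > 0, npix >= 2L, energy_kev > 0)
  if (is.null(center)) center <- rep((npix + 1) / 2, 2)
  pump_axis <- pump_axis / sqrt(sum(pump_axis^2))
  xray_pol <- xray_pol / sqrt(sum(xray_pol^2))
  structure(list(distance = distance_mm, pixel = pixel_mm, npix = as.integer(npix),
                 center = center, energy_kev = energy_kev,
                 wavelength = kev_to_angstrom(energy_kev),
                 pump_axis = pump_axis, xray_pol = xray_pol),
            class = "detector_geometry")
}

#' Per-pixel momentum transfer and azimuthal angle maps
#'
#' For every pixel computes the scattering angle from the flat-detector
#' geometry, the momentum transfer `q = (4 pi / lambda) sin(Theta/2)`, the
#' angle `theta_q` between the exact 3-D q-vector (`k_out - k_in`) and the
#' pump polarization axis, and the Thomson polarization factor
#' `1 - (k_out . eps)^2` for the x-ray polarization. A pixel at the beam
#' center has q = 0 and undefined theta_q and is masked.
#'
#' @param geom A [detector_geometry()].
#' @return List of `npix x npix` matrices: `q` (1/Angstrom), `theta_q`
#'   (radians), `thomson`, and logical `mask` (TRUE = usable).
#' @export
pixel_to_q_theta <- function(geom) {
  stopifnot(inherits(geom, "detector_geometry"))
  n <- geom$npix
  xs <- (seq_len(n) - geom$center[1]) * geom$pixel
  ys <- (seq_len(n) - geom$center[2]) * geom$pixel
  X <- matrix(xs, n, n)            # rows: x index
  Y <- matrix(ys, n, n, byrow = TRUE)
  R <- sqrt(X^2 + Y^2)
  L <- geom$distance
  rr <- sqrt(R^2 + L^2)
  # unit outgoing wavevector components
  kx <- X / rr; ky <- Y / rr; kz <- L / rr
  Theta <- acos(pmin(pmax(kz, -1), 1))
  k <- 2 * pi / geom$wavelength
  # q vector = k (k_out_hat - z_hat); |q| = 2k sin(Theta/2)
  qx <- k * kx; qy <- k * ky; qz <- k * (kz - 1)
  qn <- sqrt(qx^2 + qy^2 + qz^2)
  mask <- qn > 1e-9
  pa <- geom$pump_axis
  ct <- (qx * pa[1] + qy * pa[2]) / ifelse(mask, qn, 1)
  theta_q <- acos(pmin(pmax(ct, -1), 1))
  theta_q[!mask] <- NA_real_
  ep <- geom$xray_pol
  thomson <- 1 - (kx * ep[1] + ky * ep[2])^2
  list(q = qn, theta_q = theta_q, thomson = thomson, mask = mask,
       Theta = Theta)
}

#' q range covered by a detector
#'
#' @param geom A [detector_geometry()].
#' @return Length-2 numeric: smallest and largest unmasked per-pixel q.
#' @export
detector_qrange <- function(geom) {
  px <- pixel_to_q_theta(geom)
  range(px$q[px$mask])
}

.legendre_p2 <- function(x) (3 * x^2 - 1) / 2

#' Render a synthetic detector image
#'
#' Pixelwise `S0(q) + S2(q) * P2(cos theta_q)`, multiplied by the Thomson
#' polarization factor of the x-ray probe, plus optional seeded Gaussian
#' noise. Patterns are linearly interpolated onto the per-pixel q values and
#' must cover the detector's full unmasked q range.
#'
#' @param iso,aniso Isotropic / anisotropic components: `diff_pattern`,
#'   `xs_pattern`, or a function of q. `aniso = NULL` means purely isotropic.
#' @param geom A [detector_geometry()].
#' @param noise Gaussian noise SD per pixel (same units as the patterns).
#' @param seed RNG seed used when `noise > 0`.
#' @return An `image2d`: list with `values` (npix x npix), `mask`, `geom`.
#' @export
render_detector_image <- function(iso, aniso = NULL, geom = detector_geometry(),
                                  noise = 0, seed = 1L) {
  px <- pixel_to_q_theta(geom)
  evalq_at <- function(p, qv) {
    if (is.function(p)) return(p(qv))
    qq <- p$q
    vv <- if (inherits(p, "diff_pattern")) p$percent else p$intensity
    if (min(qv, na.rm = TRUE) < min(qq) - 1e-9 ||
        max(qv, na.rm = TRUE) > max(qq) + 1e-9) {
      stop("pattern q range does not cover the detector q range [",
           signif(min(qv), 4), ", ", signif(max(qv), 4), "]")
    }
    stats::approx(qq, vv, xout = qv, rule = 1)$y
  }
  qv <- px$q[px$mask]
  S0 <- evalq_at(iso, qv)
  S2 <- if (is.null(aniso)) 0 else evalq_at(aniso, qv)
  vals <- matrix(NA_real_, geom$npix, geom$npix)
  vals[px$mask] <- (S0 + S2 * .legendre_p2(cos(px$theta_q[px$mask]))) *
    px$thomson[px$mask]
  if (noise > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
    vals[px$mask] <- vals[px$mask] + stats::rnorm(sum(px$mask), 0, noise)
  }
  structure(list(values = vals, mask = px$mask, geom = geom),
            class = "image2d")
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d> %dx%d pixels, %d masked\n", nrow(x$values),
              ncol(x$values), sum(!x$mask)))
  invisible(x)
}

#' Isotropic / anisotropic decomposition of a detector image
#'
#' Inverts the Thomson polarization factor, then fits, in each q bin, the
#' linear model `I = S0 + S2 * P2(cos theta_q)` over the unmasked pixels of
#' the bin by least squares. Because q and theta_q are correlated within a
#' bin on a flat detector, a nuisance term linear in `q - q_center` is
#' included by default so that the slope of the isotropic signal does not
#' leak into S2. Bins with too few pixels or degenerate angular coverage
#' are flagged (S2 undefined there).
#'
#' @param image An `image2d`.
#' @param geom A [detector_geometry()] (defaults to the image's own).
#' @param qbins Bin edges in 1/Angstrom (default: 40 equal bins over the
#'   detector q range).
#' @param min_pixels Minimum unmasked pixels per usable bin.
#' @param min_p2_spread Minimum standard deviation of `P2(cos theta_q)`
#'   within a bin; bins with weaker angular coverage (e.g. detector
#'   corners) are flagged.
#' @param detrend_q Include the within-bin `q - q_center` nuisance term.
#' @return An `iso_aniso` list: `q` (bin centers), `S0`, `S2`, `sigma0`,
#'   `sigma2` (per-bin fit standard errors), `n`, and logical `flagged`.
#' @export
decompose_iso_aniso <- function(image, geom = image$geom, qbins = NULL,
                                min_pixels = 6L, min_p2_spread = 0.05,
                                detrend_q = TRUE) {
  stopifnot(inherits(image, "image2d"))
  px <- pixel_to_q_theta(geom)
  if (is.null(qbins)) {
    qr <- range(px$q[px$mask])
    qbins <- seq(qr[1], qr[2] + 1e-9, length.out = 41L)
  }
  use <- px$mask & is.finite(image$values)
  Icorr <- image$values / px$thomson
  p2 <- .legendre_p2(cos(px$theta_q))
  bin <- cut(px$q, qbins, include.lowest = TRUE, labels = FALSE)
  nb <- length(qbins) - 1L
  out <- list(q = (qbins[-1] + qbins[-length(qbins)]) / 2,
              S0 = rep(NA_real_, nb), S2 = rep(NA_real_, nb),
              sigma0 = rep(NA_real_, nb), sigma2 = rep(NA_real_, nb),
              n = integer(nb), flagged = rep(TRUE, nb))
  for (b in seq_len(nb)) {
    sel <- use & !is.na(bin) & bin == b
    nbpx <- sum(sel)
    out$n[b] <- nbpx
    if (nbpx < min_pixels) next
    x <- p2[sel]
    if (stats::sd(x) < min_p2_spread) {  # degenerate angular coverage
      next
    }
    X <- cbind(1, x)
    if (detrend_q) {
      dq <- px$q[sel] - out$q[b]
      # only detrend when the q spread is genuinely independent of the
      # angular coordinate; in sparse or partial-ring bins the two are
      # collinear and the nuisance term would destabilize the solve
      if (stats::sd(dq) > 1e-9 && abs(stats::cor(dq, x)) < 0.9) {
        X <- cbind(X, dq)
      }
    }
    np <- ncol(X)
    if (nbpx < np + 1L) next
    fit <- stats::lm.fit(X, Icorr[sel])
    if (fit$rank < np) next
    out$S0[b] <- fit$coefficients[1]
    out$S2[b] <- fit$coefficients[2]
    dof <- nbpx - np
    s2 <- sum(fit$residuals^2) / max(dof, 1L)
    XtXi <- chol2inv(chol(crossprod(X)))
    out$sigma0[b] <- sqrt(s2 * XtXi[1, 1])
    out$sigma2[b] <- sqrt(s2 * XtXi[2, 2])
    out$flagged[b] <- FALSE
  }
  structure(out, class = "iso_aniso")
}

#' @export
print.iso_aniso <- function(x, ...) {
  cat(sprintf("<iso_aniso> %d q bins (%d flagged), q in [%.3g, %.3g] 1/A\n",
              length(x$q), sum(x$flagged), min(x$q), max(x$q)))
  invisible(x)
}
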