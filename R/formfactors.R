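# Atomic x-ray form factors for the independent atom model.
#
# Four-Gaussian-plus-constant (Cromer-Mann) parameterization,
#   f(q) = sum_i a_i exp(-b_i (q/4pi)^2) + c,
# with coefficients from the standard crystallographic tabulation
# (International Tables for Crystallography, Vol. C). q in inverse Angstrom.

.CROMER_MANN <- list(
  H = list(Z = 1L,
           a = c(0.489918, 0.262003, 0.196767, 0.049879),
           b = c(20.6593, 7.74039, 49.5519, 2.20159),
           c = 0.001305),
  C = list(Z = 6L,
           a = c(2.31000, 1.02000, 1.58860, 0.865000),
           b = c(20.8439, 10.2075, 0.568700, 51.6512),
           c = 0.215600),
  N = list(Z = 7L,
           a = c(12.2126, 3.13220, 2.01250, 1.16630),
           b = c(0.005700, 9.89330, 28.9975, 0.582600),
           c = -11.529),
  O = list(Z = 8L,
           a = c(3.04850, 2.28680, 1.54630, 0.867000),
           b = c(13.2771, 5.70110, 0.323900, 32.9089),
           c = 0.250800),
  S = list(Z = 16L,
           a = c(6.90530, 5.20340, 1.43790, 1.58630),
           b = c(1.46790, 22.2151, 0.253600, 56.1720),
           c = 0.866900)
)

#' Supported chemical elements
#'
#' Elements for which tabulated atomic form-factor coefficients are built in.
#'
#' @return Character vector of element symbols.
#' @export
ff_elements <- function() names(.CROMER_MANN)

#' Atomic number of a supported element
#'
#' @param element Element symbol (e.g. `"S"`).
#' @return Integer atomic number Z.
#' @export
atomic_number <- function(element) {
  cf <- .CROMER_MANN[[element]]
  if (is.null(cf)) {
    stop("unsupported element: '", element,
         "' (supported: ", paste(ff_elements(), collapse = ", "), ")")
  }
  cf$Z
}

#' Atomic x-ray form factor f(q)
#'
#' Evaluates the tabulated independent-atom form factor of one element on a
#' grid of momentum-transfer values. By construction `f(0)` equals the atomic
#' number (the number of electrons) to within the accuracy of the tabulation.
#'
#' @param element Element symbol; one of [ff_elements()].
#' @param q Numeric vector of momentum transfer values in 1/Angstrom
#'   (non-negative).
#' @return Numeric vector `f(q)`, in electron units, same length as `q`.
#' @examples
#' atomic_form_factor("S", 0)      # = 16 (electron count)
#' atomic_form_factor("C", c(0, 2, 4))
#' @export
atomic_form_factor <- function(element, q) {
  cf <- .CROMER_MANN[[element]]
  if (is.null(cf)) {
    stop("unsupported element: '", element,
         "' (supported: ", paste(ff_elements(), collapse = ", "), ")")
  }
  if (any(!is.finite(q)) || any(q < 0)) {
    stop("q values must be finite and non-negative")
  }
  s2 <- (q / (4 * pi))^2
  f <- rep(cf$c, length(q))
  for (i in seq_len(4)) f <- f + cf$a[i] * exp(-cf$b[i] * s2)
  f
}
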