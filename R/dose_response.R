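# Hill concentration-response curves, response-addition mixture toxicity,
# and the ion-contribution function in dimensionless form.
#
# Ions and particles are assumed to act through different modes of toxic
# action, so the suspension effect combines the two single-stressor Hill
# effects by response addition: E_tox = 1 - (1 - E_ion)(1 - E_NF).  The
# ion contribution Contr_ion = E_ion / E_tox collapses, after scaling
# concentrations by the two EC50s, to a function of five dimensionless
# quantities: A = C0/EC50_NF, B = C0/EC50_ion, the progress tau = Pt, and
# the two Hill coefficients.

#' Hill concentration-response curve
#'
#' @param ec50 effective concentration inducing a 50% effect, g/L (> 0).
#' @param eta Hill coefficient (steepness), dimensionless (> 0).
#' @return object of class `hill_curve`.
#' @examples
#' hill_effect(0.5, hill_curve(ec50 = 0.5, eta = 2))  # 0.5 by definition
#' @export
hill_curve <- function(ec50, eta) {
  stopifnot(is.numeric(ec50), is.numeric(eta),
            length(ec50) == 1L, length(eta) == 1L)
  if (ec50 <= 0) stop("ec50 must be > 0")
  if (eta <= 0) stop("Hill coefficient eta must be > 0")
  structure(list(ec50 = ec50, eta = eta), class = "hill_curve")
}

#' @export
print.hill_curve <- function(x, ...) {
  cat(sprintf("Hill curve: EC50 = %g g/L, eta = %g\n", x$ec50, x$eta))
  invisible(x)
}

# x^eta / (x^eta + 1) for x >= 0, evaluated in log space so extreme Hill
# coefficients neither overflow nor underflow; x = 0 maps to 0.
.hill_unit <- function(x, eta) {
  stats::plogis(eta * log(x))
}

#' Hill effect at a concentration
#'
#' E(c) = c^eta / (c^eta + EC50^eta), computed in log space for numerical
#' stability at extreme Hill coefficients.  E(0) = 0 and E is strictly
#' increasing in c.
#'
#' @param conc concentration(s), g/L (>= 0, vectorized).
#' @param curve a [hill_curve()].
#' @return effect fraction(s) in \[0, 1\].
#' @export
hill_effect <- function(conc, curve) {
  if (!inherits(curve, "hill_curve")) stop("'curve' must be a hill_curve")
  if (!is.numeric(conc) || any(conc < 0))
    stop("concentration must be numeric and >= 0")
  stats::plogis(curve$eta * (log(conc) - log(curve$ec50)))
}

#' Combine two effects by response addition
#'
#' For stressors with different modes of toxic action the joint effect is
#' one minus the product of the unaffected fractions:
#' E = e1 + e2 - e1 e2.  Symmetric, bounded by \[max(e1, e2), 1\].
#'
#' @param e_ion,e_nf effect fractions in \[0, 1\] (vectorized).
#' @return combined effect fraction(s).
#' @export
response_addition <- function(e_ion, e_nf) {
  if (any(e_ion < 0 | e_ion > 1 | e_nf < 0 | e_nf > 1))
    stop("effect fractions must lie in [0, 1]")
  e_ion + e_nf - e_ion * e_nf
}

#' Ion contribution from its component effects
#'
#' Contr_ion = E_ion / E_tox.  When the suspension has no effect at all
#' (E_tox = 0, i.e. before any dissolution at sub-threshold doses) the
#' contribution is defined as 0: no ions, no ion contribution.
#'
#' @param e_ion ion effect fraction(s).
#' @param e_tox total suspension effect fraction(s), with e_ion <= e_tox.
#' @return fraction(s) in \[0, 1\].
#' @export
contr_ion_from_effects <- function(e_ion, e_tox) {
  if (any(e_ion < 0 | e_ion > 1 | e_tox < 0 | e_tox > 1))
    stop("effect fractions must lie in [0, 1]")
  if (any(e_ion > e_tox + 1e-15))
    stop("e_ion cannot exceed the total suspension effect e_tox")
  ifelse(e_tox == 0, 0, pmin(1, e_ion / e_tox))
}

#' Dimensionless state of a dissolving suspension
#'
#' The reduced coordinates on which the ion contribution depends:
#' `a` = C_NF(0)/EC50_NF, `b` = C_NF(0)/EC50_ion, the dissolution
#' progress `tau` = Pt, and the two Hill coefficients.  This constructor
#' is the single place where the A/B convention lives: under the
#' assumption that particles are at most 5x less toxic than ions
#' (EC50_NF between 1 and 5 EC50_ion), the admissible set is
#' a <= b <= 5a.
#'
#' @param a initial concentration relative to the particle EC50 (> 0).
#' @param b initial concentration relative to the ion EC50 (> 0).
#' @param tau dimensionless dissolution progress Pt (>= 0).
#' @param eta1 Hill coefficient of the ions (> 0).
#' @param eta2 Hill coefficient of the particles (> 0).
#' @return object of class `dimensionless_state`.
#' @export
dimensionless_state <- function(a, b, tau, eta1 = 1, eta2 = 1) {
  stopifnot(length(a) == 1L, length(b) == 1L,
            length(eta1) == 1L, length(eta2) == 1L)
  if (a <= 0 || b <= 0) stop("a and b must be > 0")
  if (any(tau < 0)) stop("tau must be >= 0")
  if (eta1 <= 0 || eta2 <= 0) stop("Hill coefficients must be > 0")
  structure(list(a = a, b = b, tau = tau, eta1 = eta1, eta2 = eta2),
            class = "dimensionless_state")
}

# Core dimensionless ion-contribution kernel, vectorized over tau.
# f = (1 - tau)^3 is the undissolved mass fraction.
.contr_ion_kernel <- function(a, b, tau, eta1, eta2) {
  f <- pmax(0, 1 - tau)^3
  e_n <- .hill_unit(a * f, eta2)
  e_i <- .hill_unit(b * (1 - f), eta1)
  e_tox <- e_i + e_n - e_i * e_n
  ifelse(e_tox == 0, 0, e_i / e_tox)
}

#' Ion contribution to suspension toxicity, dimensionless form
#'
#' With f = (1 - tau)^3 the undissolved mass fraction, the particle and
#' ion effects are E_NF = (a f)^eta2 / ((a f)^eta2 + 1) and
#' E_ion = (b (1 - f))^eta1 / ((b (1 - f))^eta1 + 1), and
#' Contr_ion = E_ion / (E_ion + E_NF - E_ion E_NF).  Equals 0 at tau = 0
#' and 1 for tau >= 1, and is non-decreasing in tau.
#'
#' @param state a [dimensionless_state()] (its `tau` may be a vector).
#' @return fraction(s) in \[0, 1\].
#' @examples
#' contr_ion(dimensionless_state(a = 1, b = 1, tau = 0.52119))  # ~0.900
#' @export
contr_ion <- function(state) {
  if (!inherits(state, "dimensionless_state"))
    stop("'state' must be a dimensionless_state")
  .contr_ion_kernel(state$a, state$b, state$tau, state$eta1, state$eta2)
}

#' Time course of suspension toxicity and ion contribution
#'
#' Runs the full dimensional pipeline: dissolution concentrations
#' through the two Hill curves, combined by response addition.  The
#' resulting ion contribution coincides with [contr_ion()] evaluated at
#' a = C0/EC50_NF, b = C0/EC50_ion, tau = Pt.
#'
#' @param spec a [nanoform()].
#' @param ion_curve,nf_curve [hill_curve()] objects for the ions and the
#'   particles.
#' @param times time points, h (>= 0).
#' @return data frame with columns `t_h`, `e_ion`, `e_nf`, `e_tox`,
#'   `contr_ion`.
#' @export
suspension_effect_timecourse <- function(spec, ion_curve, nf_curve, times) {
  .check_time(times)
  e_ion <- hill_effect(conc_ion(spec, times), ion_curve)
  e_nf <- hill_effect(conc_nf(spec, times), nf_curve)
  e_tox <- response_addition(e_ion, e_nf)
  data.frame(
    t_h = times,
    e_ion = e_ion,
    e_nf = e_nf,
    e_tox = e_tox,
    contr_ion = contr_ion_from_effects(e_ion, e_tox)
  )
}
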