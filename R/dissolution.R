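# Shrinking-sphere dissolution kinetics for a monodisperse suspension of
# spherical soluble nanoforms.
#
# A particle of diameter D loses mass through its surface at a constant
# area-specific rate k (g/cm^2/h), so dD/dt = -2k/rho and the diameter
# shrinks linearly: D(t) = D0 (1 - Pt) with P = 2k/(rho D0).  Mass scales
# with D^3, hence the particle mass concentration follows the cube law
# C_NF(t) = C0 (1 - Pt)^3 and the released-ion concentration is its
# complement.  Pt = 1 marks complete dissolution; all particle quantities
# are clipped to exactly zero beyond it.

#' Specify a nanoform
#'
#' Bundles the physical identity of one nanoform batch: the dissolution
#' rate constant `k`, material density `rho`, initial particle diameter
#' `d0`, and total initial mass concentration `c0`.  Arguments are taken
#' in the field's reporting units (`k` in ng/cm^2/h, `d0` in nm) and
#' stored internally in CGS (g/cm^2/h, cm).
#'
#' @param k dissolution rate constant, ng/cm^2/h (>= 0).
#' @param rho material density, g/cm^3 (> 0); silver 10.49, copper 8.95.
#' @param d0 initial diameter, nm (> 0).
#' @param c0 initial total particle mass concentration, g/L (> 0).
#' @param name optional label.
#' @return An object of class `nanoform` with fields `k` (g/cm^2/h),
#'   `rho` (g/cm^3), `d0` (cm), `c0` (g/L), `name`.
#' @examples
#' ag <- nanoform(k = 37.95, rho = 10.49, d0 = 10, c0 = 1e-3, name = "nAg")
#' rate_parameter(ag) * 72   # dimensionless progress Pt after 72 h
#' @export
nanoform <- function(k, rho, d0, c0, name = NULL) {
  stopifnot(is.numeric(k), is.numeric(rho), is.numeric(d0), is.numeric(c0),
            length(k) == 1L, length(rho) == 1L, length(d0) == 1L,
            length(c0) == 1L)
  if (k < 0) stop("dissolution rate constant k must be >= 0")
  if (rho <= 0) stop("density rho must be > 0")
  if (d0 <= 0) stop("initial diameter d0 must be > 0")
  if (c0 <= 0) stop("initial concentration c0 must be > 0")
  structure(
    list(k = k_ng_to_g(k), rho = rho, d0 = d_nm_to_cm(d0), c0 = c0,
         name = name),
    class = "nanoform")
}

#' @export
print.nanoform <- function(x, ...) {
  cat("Nanoform", if (!is.null(x$name)) paste0("'", x$name, "'"), "\n")
  cat(sprintf("  k   = %g ng/cm^2/h\n", k_g_to_ng(x$k)))
  cat(sprintf("  rho = %g g/cm^3\n", x$rho))
  cat(sprintf("  D0  = %g nm\n", d_cm_to_nm(x$d0)))
  cat(sprintf("  C0  = %g g/L\n", x$c0))
  p <- rate_parameter(x)
  if (p > 0)
    cat(sprintf("  P   = %g 1/h (complete dissolution at t = %g h)\n",
                p, 1 / p))
  else
    cat("  P   = 0 1/h (no dissolution)\n")
  invisible(x)
}

.check_nanoform <- function(spec) {
  if (!inherits(spec, "nanoform")) stop("'spec' must be a nanoform object")
  spec
}

.check_time <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("time t must be finite and >= 0")
  t
}

# remaining linear shrinkage fraction 1 - Pt, exactly 0 from the
# dissolution time onward (clipping guards against round-off residues
# when t is computed as 1/P)
.remaining_fraction <- function(spec, t) {
  p <- rate_parameter(spec)
  frac <- pmax(0, 1 - p * t)
  if (p > 0) frac[t >= 1 / p] <- 0
  frac
}

#' Dissolution rate parameter P = 2k / (rho D0)
#'
#' The single kinetic parameter of the shrinking-sphere model, in 1/h.
#' Multiplying by exposure time gives the dimensionless dissolution
#' progress Pt (Pt = 1 means complete dissolution).
#'
#' @inheritParams diameter_at
#' @return P in 1/h.
#' @export
rate_parameter <- function(spec) {
  .check_nanoform(spec)
  2 * spec$k / (spec$rho * spec$d0)
}

#' Particle diameter over time
#'
#' Linear shrinkage D(t) = D0 (1 - Pt), clipped to 0 once dissolution is
#' complete (t >= 1/P).  The shrinkage rate 2k/rho is independent of D0.
#'
#' @param spec a [nanoform()] object.
#' @param t time(s) since suspension, h (vectorized).
#' @return diameter in cm (same length as `t`).
#' @export
diameter_at <- function(spec, t) {
  .check_nanoform(spec)
  .check_time(t)
  spec$d0 * .remaining_fraction(spec, t)
}

#' Particle mass concentration over time
#'
#' Cube law C_NF(t) = C0 (1 - Pt)^3 for Pt < 1, exactly 0 afterwards.
#'
#' @inheritParams diameter_at
#' @return concentration in g/L.
#' @export
conc_nf <- function(spec, t) {
  .check_nanoform(spec)
  .check_time(t)
  spec$c0 * .remaining_fraction(spec, t)^3
}

#' Released-ion mass concentration over time
#'
#' Complement of the particle concentration (mass conservation):
#' C_ion(t) = C0 (1 - (1 - Pt)^3), clipped to C0.  C_ion(0) = 0.
#'
#' @inheritParams diameter_at
#' @return concentration in g/L.
#' @export
conc_ion <- function(spec, t) {
  .check_nanoform(spec)
  .check_time(t)
  spec$c0 - conc_nf(spec, t)
}

#' Time to complete dissolution
#'
#' Returns 1/P, the time at which the particle concentration reaches 0.
#' A non-dissolving nanoform (k = 0) returns `Inf`.
#'
#' @inheritParams diameter_at
#' @return time in h (`Inf` when k = 0).
#' @export
dissolution_time <- function(spec) {
  p <- rate_parameter(spec)
  if (p == 0) return(Inf)
  1 / p
}

#' Dissolution time course as a data frame
#'
#' @inheritParams diameter_at
#' @param t times, h.
#' @return data frame with columns `t_h`, `diameter_nm`,
#'   `c_nf_g_per_L`, `c_ion_g_per_L`.
#' @export
suspension_state <- function(spec, t) {
  data.frame(
    t_h = t,
    diameter_nm = d_cm_to_nm(diameter_at(spec, t)),
    c_nf_g_per_L = conc_nf(spec, t),
    c_ion_g_per_L = conc_ion(spec, t)
  )
}
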