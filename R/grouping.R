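# Translating Pt boundaries into critical material/exposure parameters
# and classifying nanoforms for read-across.
#
# All inversions follow from Pt = 2kt/(rho D0): fixing any three of
# (k, t, D0, rho) and a boundary value Pt* determines the fourth
# critically.  Critical rate constants are reported in ng/cm^2/h, the
# unit in which dissolution rates are measured and tabulated.

#' Material density presets
#'
#' @param name `"silver"` (10.49 g/cm^3) or `"copper"` (8.95 g/cm^3).
#' @return list with `name` and `rho` (g/cm^3).
#' @export
material_preset <- function(name = c("silver", "copper")) {
  name <- match.arg(name)
  list(name = name, rho = c(silver = 10.49, copper = 8.95)[[name]])
}

#' Dimensionless dissolution progress of a nanoform at a time
#'
#' Pt = 2kt / (rho D0); Pt = 1 marks complete dissolution.
#'
#' @param spec a [nanoform()].
#' @param t exposure duration, h.
#' @return dimensionless Pt.
#' @export
pt_value <- function(spec, t) {
  .check_time(t)
  rate_parameter(spec) * t
}

#' Critical dissolution rate constant for a Pt boundary
#'
#' The rate constant that brings a nanoform of density `rho` and initial
#' diameter `d0` exactly to progress `pt_star` after `t` hours:
#' k = Pt* rho D0 / (2 t).
#'
#' @param pt_star target dimensionless progress (> 0 unless exactly 0).
#' @param rho density, g/cm^3.
#' @param d0 initial diameter, nm.
#' @param t exposure duration, h.
#' @return critical k in ng/cm^2/h.
#' @examples
#' critical_k(0.521, rho = 10.49, d0 = 10, t = 72)   # 37.95 ng/cm^2/h
#' @export
critical_k <- function(pt_star, rho, d0, t) {
  if (any(pt_star < 0) || rho <= 0 || d0 <= 0 || t <= 0)
    stop("critical_k requires pt_star >= 0 and positive rho, d0, t")
  k_g_to_ng(pt_star * rho * d_nm_to_cm(d0) / (2 * t))
}

#' Critical exposure duration for a Pt boundary
#'
#' The time at which a given nanoform reaches progress `pt_star`:
#' t = Pt* / P.  A non-dissolving nanoform (k = 0) never reaches any
#' positive boundary and returns `Inf`.
#'
#' @param pt_star target dimensionless progress.
#' @param spec a [nanoform()].
#' @return time in h (`Inf` when k = 0).
#' @examples
#' ag <- nanoform(k = 18.98, rho = 10.49, d0 = 10, c0 = 1e-3)
#' critical_t(0.521, ag)   # ~144 h
#' @export
critical_t <- function(pt_star, spec) {
  if (any(pt_star < 0)) stop("pt_star must be >= 0")
  p <- rate_parameter(spec)
  if (p == 0) return(if (all(pt_star == 0)) 0 else Inf)
  pt_star / p
}

#' Critical initial diameter for a Pt boundary
#'
#' D0 = 2kt / (rho Pt*): particles larger than this have not yet reached
#' progress `pt_star` at time `t`.
#'
#' @param pt_star target dimensionless progress (> 0).
#' @param k dissolution rate constant, ng/cm^2/h.
#' @param rho density, g/cm^3.
#' @param t exposure duration, h.
#' @return diameter in nm.
#' @export
critical_diameter <- function(pt_star, k, rho, t) {
  if (pt_star <= 0 || k <= 0 || rho <= 0 || t <= 0)
    stop("critical_diameter requires positive arguments")
  d_cm_to_nm(2 * k_ng_to_g(k) * t / (rho * pt_star))
}

#' Critical density for a Pt boundary
#'
#' rho = 2kt / (D0 Pt*).
#'
#' @param pt_star target dimensionless progress (> 0).
#' @param k dissolution rate constant, ng/cm^2/h.
#' @param d0 initial diameter, nm.
#' @param t exposure duration, h.
#' @return density in g/cm^3.
#' @export
critical_density <- function(pt_star, k, d0, t) {
  if (pt_star <= 0 || k <= 0 || d0 <= 0 || t <= 0)
    stop("critical_density requires positive arguments")
  2 * k_ng_to_g(k) * t / (d_nm_to_cm(d0) * pt_star)
}

#' Classify a nanoform into regulatory grouping classes
#'
#' Computes Pt for the nanoform at exposure time `t` and maps it through
#' the regime bands of `thresholds`.  Bands in which several
#' classifications remain possible yield `"indeterminate"` unless the
#' two EC50s are supplied, in which case the ion contribution is
#' evaluated pointwise at A = C0/EC50_NF, B = C0/EC50_ion and compared
#' against the cutoffs (strictly: contribution above the high cutoff is
#' ion-dominated, below the low cutoff particle-dominated, otherwise
#' mixed).
#'
#' @param spec a [nanoform()].
#' @param t exposure duration, h.
#' @param thresholds a [scenario_thresholds()]; default the reference
#'   (1,1) scenario.
#' @param ec50_ion,ec50_nf optional EC50s, g/L, to resolve indeterminate
#'   bands.
#' @return object of class `grouping_result` with fields
#'   `assigned_class` (`"ion_dominated"`, `"particle_dominated"`,
#'   `"mixed"` or `"indeterminate"`), `pt`, `thresholds_used`, `note`.
#' @export
classify_nanoform <- function(spec, t, thresholds = reference_thresholds(1, 1),
                              ec50_ion = NULL, ec50_nf = NULL) {
  pt <- pt_value(spec, t)
  reg <- regime_at(thresholds, pt)
  note <- NULL
  if (length(reg$possibilities) == 1L) {
    cls <- reg$possibilities
  } else if (!is.null(ec50_ion) && !is.null(ec50_nf)) {
    st <- dimensionless_state(a = spec$c0 / ec50_nf, b = spec$c0 / ec50_ion,
                              tau = pt, eta1 = thresholds$eta1,
                              eta2 = thresholds$eta2)
    ci <- contr_ion(st)
    cls <- if (ci > thresholds$cutoffs[2L]) "ion_dominated"
           else if (ci < thresholds$cutoffs[1L]) "particle_dominated"
           else "mixed"
    note <- sprintf("resolved from pointwise ion contribution %.4f", ci)
  } else {
    cls <- "indeterminate"
    note <- paste("Pt band admits several outcomes:",
                  paste(reg$possibilities, collapse = ", "),
                  "- supply EC50s to resolve")
  }
  structure(list(assigned_class = cls, pt = pt, thresholds_used = thresholds,
                 note = note),
            class = "grouping_result")
}

#' @export
print.grouping_result <- function(x, ...) {
  cat(sprintf("Grouping: %s (Pt = %.4g)\n", x$assigned_class, x$pt))
  if (!is.null(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}

# table rounding convention: two decimals in ng/cm^2/h, four when < 0.01
.round_k_table <- function(k) ifelse(k < 0.01, round(k, 4L), round(k, 2L))

#' Critical-rate screening table for a material
#'
#' One row per (scenario, exposure time, diameter): the Pt boundaries of
#' the pure bands and the corresponding critical dissolution rate
#' constants.  A measured k below `k_upper_ng_cm2_h` guarantees particle
#' dominance; a k above `k_lower_ng_cm2_h` guarantees ion dominance.
#' Values are rounded to two decimals (four when below 0.01 ng/cm^2/h,
#' where rates may not be experimentally determinable).
#'
#' @param material a [material_preset()] or a list with `name`, `rho`.
#' @param scenarios list of [scenario_thresholds()]; default the three
#'   reference scenarios (1,1), (1,5), (4,8).
#' @param times exposure durations, h (default 72, 168, 672).
#' @param diameters initial diameters, nm (default 10, 100).
#' @return data frame with columns `scenario`, `time_h`, `diameter_nm`,
#'   `pt_upper_low`, `pt_lower_high`, `k_upper_ng_cm2_h`,
#'   `k_lower_ng_cm2_h`, ordered by (scenario, time, diameter).
#' @examples
#' tab <- generate_table(material_preset("silver"))
#' subset(tab, time_h == 72 & diameter_nm == 10)
#' @export
generate_table <- function(material = material_preset("silver"),
                           scenarios = list(reference_thresholds(1, 1),
                                            reference_thresholds(1, 5),
                                            reference_thresholds(4, 8)),
                           times = c(72, 168, 672),
                           diameters = c(10, 100)) {
  stopifnot(length(scenarios) > 0, length(times) > 0, length(diameters) > 0)
  rows <- list()
  for (sc in scenarios) {
    label <- sprintf("eta1=%g,eta2=%g", sc$eta1, sc$eta2)
    for (tt in sort(times)) for (dd in sort(diameters)) {
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = label, time_h = tt, diameter_nm = dd,
        pt_upper_low = sc$pt_all_below, pt_lower_high = sc$pt_all_above,
        k_upper_ng_cm2_h =
          .round_k_table(critical_k(sc$pt_all_below, material$rho, dd, tt)),
        k_lower_ng_cm2_h =
          .round_k_table(critical_k(sc$pt_all_above, material$rho, dd, tt))
      )
    }
  }
  do.call(rbind, rows)
}
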