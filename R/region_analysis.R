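# Extrema of the ion contribution over an (A, B) assumption region and
# the Pt boundaries that delimit the classification regimes.
#
# The admissible (A, B) set is parameterized by the dose A = C0/EC50_NF
# and the EC50 ratio r = EC50_NF/EC50_ion (so B = r A).  Because the ion
# contribution is monotone in A and B pointwise, its running minimum and
# maximum over a fixed region are themselves non-decreasing in tau, which
# makes each cutoff crossing a well-posed root for bisection.

#' Assumption region in the (A, B) plane
#'
#' Describes the set of dimensionless initial-dose coordinates over
#' which regime boundaries are computed: A in \[dose_lo, dose_hi\] and
#' B = r A with the EC50 ratio r = EC50_NF/EC50_ion in
#' \[ratio_lo, ratio_hi\].  The defaults encode the standard assumptions
#' that particles are between 1 and 5 times less toxic than ions and
#' that test doses span 0.1 to 5 times the particle EC50.  Degenerate
#' (single-point) regions are allowed and useful for analytic checks.
#'
#' @param ratio_lo,ratio_hi bounds on EC50_NF/EC50_ion (defaults 1, 5).
#' @param dose_lo,dose_hi bounds on A = C0/EC50_NF (defaults 0.1, 5).
#' @param grid_n grid points per axis for the scan stage (default 201).
#' @return object of class `region_spec`.
#' @export
region_spec <- function(ratio_lo = 1, ratio_hi = 5,
                        dose_lo = 0.1, dose_hi = 5, grid_n = 201L) {
  if (!(ratio_lo > 0 && ratio_hi >= ratio_lo))
    stop("require 0 < ratio_lo <= ratio_hi")
  if (!(dose_lo > 0 && dose_hi >= dose_lo))
    stop("require 0 < dose_lo <= dose_hi")
  if (grid_n < 2) stop("grid_n must be >= 2")
  structure(list(ratio_lo = ratio_lo, ratio_hi = ratio_hi,
                 dose_lo = dose_lo, dose_hi = dose_hi,
                 grid_n = as.integer(grid_n)),
            class = "region_spec")
}

# log-spaced axis; collapses to a single point when lo == hi
.log_axis <- function(lo, hi, n) {
  if (lo == hi) return(lo)
  exp(seq(log(lo), log(hi), length.out = n))
}

#' Extrema of the ion contribution over a region
#'
#' Scans a log-spaced grid in (A, r) and refines the best cell by
#' golden-section search along each coordinate (via [stats::optimize()]).
#' Extrema of the ion contribution lie on the region boundary because
#' the function is monotone in A and in B; the refinement exploits
#' nothing beyond continuity.
#'
#' @param region a [region_spec()].
#' @param tau dissolution progress Pt (scalar, >= 0).
#' @param eta1,eta2 Hill coefficients of ions and particles.
#' @return named numeric `c(min = ..., max = ...)`, both in \[0, 1\].
#' @export
contr_extrema <- function(region, tau, eta1 = 1, eta2 = 1) {
  if (!inherits(region, "region_spec")) stop("'region' must be a region_spec")
  if (length(tau) != 1L || tau < 0) stop("tau must be a scalar >= 0")
  a_ax <- .log_axis(region$dose_lo, region$dose_hi, region$grid_n)
  r_ax <- .log_axis(region$ratio_lo, region$ratio_hi, region$grid_n)
  grid <- expand.grid(a = a_ax, r = r_ax)
  vals <- .contr_ion_kernel(grid$a, grid$r * grid$a, tau, eta1, eta2)

  refine <- function(which_fun) {
    idx <- which_fun(vals)
    a0 <- grid$a[idx]; r0 <- grid$r[idx]
    best <- vals[idx]
    sgn <- if (identical(which_fun, which.min)) 1 else -1
    obj_a <- function(la) sgn * .contr_ion_kernel(exp(la), r0 * exp(la),
                                                  tau, eta1, eta2)
    obj_r <- function(lr) sgn * .contr_ion_kernel(a0, exp(lr) * a0,
                                                  tau, eta1, eta2)
    bracket <- function(x, ax) {
      i <- which.min(abs(log(ax) - log(x)))
      c(log(ax[max(1L, i - 1L)]), log(ax[min(length(ax), i + 1L)]))
    }
    if (length(a_ax) > 1L) {
      ba <- bracket(a0, a_ax)
      oa <- stats::optimize(obj_a, ba, tol = 1e-10)
      if (sgn * oa$objective < sgn * best) { best <- sgn * oa$objective
                                             a0 <- exp(oa$minimum) }
    }
    if (length(r_ax) > 1L) {
      br <- bracket(r0, r_ax)
      or_ <- stats::optimize(obj_r, br, tol = 1e-10)
      if (sgn * or_$objective < sgn * best) best <- sgn * or_$objective
    }
    best
  }

  c(min = refine(which.min), max = refine(which.max))
}

#' Regime thresholds for one Hill-coefficient scenario
#'
#' Container for the four Pt boundaries that structure the
#' classification: below `pt_all_below` the ion contribution is under
#' the low cutoff everywhere in the region; above `pt_all_above` it is
#' over the high cutoff everywhere; `pt_min_crosses_low` and
#' `pt_max_crosses_high` are the two intermediate breakpoints (where
#' the region minimum leaves the low band and where the region maximum
#' enters the high band).
#'
#' @param eta1,eta2 Hill coefficients the thresholds were computed for.
#' @param pt_all_below,pt_min_crosses_low,pt_max_crosses_high,pt_all_above
#'   the four Pt boundaries, each in (0, 1).
#' @param cutoffs low/high ion-contribution cutoffs, default `c(0.10, 0.90)`.
#' @return object of class `scenario_thresholds`.
#' @export
scenario_thresholds <- function(eta1, eta2, pt_all_below, pt_min_crosses_low,
                                pt_max_crosses_high, pt_all_above,
                                cutoffs = c(0.10, 0.90)) {
  pts <- c(pt_all_below, pt_min_crosses_low, pt_max_crosses_high,
           pt_all_above)
  if (any(pts <= 0 | pts >= 1)) stop("Pt boundaries must lie in (0, 1)")
  if (pt_all_below > min(pt_min_crosses_low, pt_max_crosses_high) ||
      max(pt_min_crosses_low, pt_max_crosses_high) > pt_all_above)
    stop("Pt boundaries must satisfy pt_all_below <= intermediates <= pt_all_above")
  if (!(length(cutoffs) == 2L && 0 < cutoffs[1L] && cutoffs[1L] < cutoffs[2L] &&
        cutoffs[2L] < 1))
    stop("cutoffs must satisfy 0 < low < high < 1")
  structure(list(eta1 = eta1, eta2 = eta2,
                 pt_all_below = pt_all_below,
                 pt_min_crosses_low = pt_min_crosses_low,
                 pt_max_crosses_high = pt_max_crosses_high,
                 pt_all_above = pt_all_above,
                 cutoffs = cutoffs),
            class = "scenario_thresholds")
}

#' @export
print.scenario_thresholds <- function(x, ...) {
  cat(sprintf("Regime thresholds (eta1 = %g, eta2 = %g, cutoffs %g%%/%g%%):\n",
              x$eta1, x$eta2, 100 * x$cutoffs[1L], 100 * x$cutoffs[2L]))
  cat(sprintf("  Pt < %-9.3g : ion contribution < %g%% everywhere\n",
              x$pt_all_below, 100 * x$cutoffs[1L]))
  cat(sprintf("  intermediates  : min crosses low at %.3g, max crosses high at %.3g\n",
              x$pt_min_crosses_low, x$pt_max_crosses_high))
  cat(sprintf("  Pt > %-9.3g : ion contribution > %g%% everywhere\n",
              x$pt_all_above, 100 * x$cutoffs[2L]))
  invisible(x)
}

#' Reference regime thresholds for the three standard scenarios
#'
#' Ships the published boundary constants for the Hill-coefficient
#' scenarios (1,1), (1,5) and (4,8) under the default 10%/90% cutoffs
#' and the standard assumption region.  These are carried as reference
#' data — the defaults used by the grouping layer — while
#' [find_pt_boundaries()] recomputes boundaries from first principles
#' for any user-supplied region.
#'
#' @param eta1,eta2 Hill coefficients; must be one of the pairs (1,1),
#'   (1,5), (4,8).
#' @return a [scenario_thresholds()] object.
#' @examples
#' reference_thresholds(1, 1)$pt_all_above   # 0.521
#' @export
reference_thresholds <- function(eta1 = 1, eta2 = 1) {
  key <- paste(eta1, eta2)
  tab <- list(
    "1 1" = c(0.00067, 0.0295, 0.103, 0.521),
    "1 5" = c(0.000012, 0.022, 0.00095, 0.465),
    "4 8" = c(0.0074, 0.124, 0.02, 0.26)
  )
  if (!key %in% names(tab))
    stop("no reference thresholds for eta1 = ", eta1, ", eta2 = ", eta2,
         "; use find_pt_boundaries() to compute them")
  v <- tab[[key]]
  scenario_thresholds(eta1, eta2,
                      pt_all_below = v[1L], pt_min_crosses_low = v[2L],
                      pt_max_crosses_high = v[3L], pt_all_above = v[4L])
}

#' Locate the Pt regime boundaries for a region by bisection
#'
#' The region minimum and maximum of the ion contribution are monotone
#' non-decreasing maps of tau running from 0 to 1, so each cutoff
#' crossing is found by root bracketing on (0, 1):
#' `pt_all_below` = max crosses low, `pt_min_crosses_low` = min crosses
#' low, `pt_max_crosses_high` = max crosses high, `pt_all_above` = min
#' crosses high.
#'
#' @param region a [region_spec()].
#' @param eta1,eta2 Hill coefficients.
#' @param cutoffs `c(low, high)` with 0 < low < high < 1.
#' @param tol absolute tolerance of the tau bisection.
#' @return a [scenario_thresholds()] object.
#' @examples
#' pt <- find_pt_boundaries(region_spec(1, 1, 1, 1, grid_n = 2),
#'                          eta1 = 1, eta2 = 1)
#' round(pt$pt_all_above, 3)   # 0.521 at the point A = B = 1
#' @export
find_pt_boundaries <- function(region, eta1 = 1, eta2 = 1,
                               cutoffs = c(0.10, 0.90), tol = 1e-6) {
  if (!(length(cutoffs) == 2L && 0 < cutoffs[1L] &&
        cutoffs[1L] < cutoffs[2L] && cutoffs[2L] < 1))
    stop("cutoffs must satisfy 0 < low < high < 1")
  ext <- function(tau) contr_extrema(region, tau, eta1, eta2)
  cross <- function(which, level) {
    g <- function(tau) ext(tau)[[which]] - level
    stats::uniroot(g, interval = c(1e-12, 1 - 1e-12), tol = tol)$root
  }
  th <- scenario_thresholds(
    eta1, eta2,
    pt_all_below = cross("max", cutoffs[1L]),
    pt_min_crosses_low = cross("min", cutoffs[1L]),
    pt_max_crosses_high = cross("max", cutoffs[2L]),
    pt_all_above = cross("min", cutoffs[2L]),
    cutoffs = cutoffs)
  th
}

#' Which regime band does a Pt value fall in?
#'
#' Partitions the Pt axis into five bands and reports which
#' classifications remain possible within each: below `pt_all_below`
#' only particle dominance; above `pt_all_above` only ion dominance
#' (both boundaries closed on the pure side); in between, the mixed
#' class is always possible, particle dominance remains possible while
#' the region minimum is still under the low cutoff, and ion dominance
#' becomes possible once the region maximum exceeds the high cutoff.
#' Depending on the order of the two intermediate breakpoints this
#' yields two- or three-possibility bands.
#'
#' @param thresholds a [scenario_thresholds()].
#' @param tau dissolution progress Pt (scalar >= 0).
#' @return list with elements `band` (1-5), `possibilities` (character
#'   vector drawn from `"particle_dominated"`, `"mixed"`,
#'   `"ion_dominated"`).
#' @export
regime_at <- function(thresholds, tau) {
  if (!inherits(thresholds, "scenario_thresholds"))
    stop("'thresholds' must be a scenario_thresholds object")
  if (length(tau) != 1L || tau < 0) stop("tau must be a scalar >= 0")
  th <- thresholds
  if (tau <= th$pt_all_below)
    return(list(band = 1L, possibilities = "particle_dominated"))
  if (tau >= th$pt_all_above)
    return(list(band = 5L, possibilities = "ion_dominated"))
  poss <- "mixed"
  if (tau < th$pt_min_crosses_low)
    poss <- c("particle_dominated", poss)
  if (tau > th$pt_max_crosses_high)
    poss <- c(poss, "ion_dominated")
  inner <- sort(c(th$pt_min_crosses_low, th$pt_max_crosses_high))
  band <- if (tau < inner[1L]) 2L else if (tau <= inner[2L]) 3L else 4L
  list(band = band, possibilities = poss)
}

#' Grid scan of the ion contribution over the (A, B) plane
#'
#' Evaluates the ion contribution on a rectangular log-spaced grid over
#' the region's bounding box in (A, B), with a mask flagging points
#' inside the admissible wedge B/A in \[ratio_lo, ratio_hi\].  Suitable
#' for rendering classification maps.
#'
#' @inheritParams contr_extrema
#' @return data frame with columns `a`, `b`, `contr_ion`, `in_region`
#'   (0/1).
#' @export
region_scan <- function(region, tau, eta1 = 1, eta2 = 1) {
  if (!inherits(region, "region_spec")) stop("'region' must be a region_spec")
  a_ax <- .log_axis(region$dose_lo, region$dose_hi, region$grid_n)
  b_ax <- .log_axis(region$dose_lo * region$ratio_lo,
                    region$dose_hi * region$ratio_hi, region$grid_n)
  g <- expand.grid(a = a_ax, b = b_ax)
  ratio <- g$b / g$a
  data.frame(
    a = g$a, b = g$b,
    contr_ion = .contr_ion_kernel(g$a, g$b, tau, eta1, eta2),
    in_region = as.integer(ratio >= region$ratio_lo * (1 - 1e-12) &
                           ratio <= region$ratio_hi * (1 + 1e-12))
  )
}
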