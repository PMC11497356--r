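# Unit handling at the package boundary.
#
# Internal convention throughout the package: CGS + hours.
#   k    g/cm^2/h     rho  g/cm^3     d0  cm     c0  g/L     t  h
# Reporting convention (constructors, CLI, tables): k in ng/cm^2/h, D0 in nm.

NG_PER_G <- 1e9
NM_PER_CM <- 1e7

#' Convert a dissolution rate constant between reporting and internal units
#'
#' @param k_ng rate constant in ng/cm^2/h.
#' @return rate constant in g/cm^2/h.
#' @keywords internal
k_ng_to_g <- function(k_ng) k_ng / NG_PER_G

#' @rdname k_ng_to_g
#' @param k_g rate constant in g/cm^2/h.
#' @keywords internal
k_g_to_ng <- function(k_g) k_g * NG_PER_G

#' @rdname k_ng_to_g
#' @param d_nm diameter in nm.
#' @keywords internal
d_nm_to_cm <- function(d_nm) d_nm / NM_PER_CM

#' @rdname k_ng_to_g
#' @param d_cm diameter in cm.
#' @keywords internal
d_cm_to_nm <- function(d_cm) d_cm * NM_PER_CM

# Recognized unit spellings for quantity strings such as "37.95 ng/cm2/h".
# Each entry maps a unit tag to the factor taking it to internal units.
.unit_tables <- list(
  k = c("ng/cm2/h" = 1e-9, "ng/cm^2/h" = 1e-9,
        "g/cm2/h" = 1, "g/cm^2/h" = 1),
  length = c(nm = 1e-7, um = 1e-4, cm = 1),
  time = c(h = 1, d = 24),
  density = c("g/cm3" = 1, "g/cm^3" = 1),
  conc = c("g/L" = 1, "mg/L" = 1e-3)
)

.default_unit <- c(k = "ng/cm2/h", length = "nm", time = "h",
                   density = "g/cm3", conc = "g/L")

#' Parse a number-with-unit string into internal units
#'
#' Accepts a bare number (interpreted in the reporting unit for that
#' quantity kind) or `"<number> <unit>"`.  Unknown units are rejected.
#'
#' @param x numeric, or a character scalar such as `"37.95 ng/cm2/h"`.
#' @param kind one of `"k"`, `"length"`, `"time"`, `"density"`, `"conc"`.
#' @return numeric scalar in internal units (g/cm^2/h, cm, h, g/cm^3, g/L).
#' @examples
#' parse_quantity("37.95 ng/cm2/h", "k")   # 3.795e-8 g/cm^2/h
#' parse_quantity("10 nm", "length")       # 1e-6 cm
#' @export
parse_quantity <- function(x, kind = c("k", "length", "time", "density", "conc")) {
  kind <- match.arg(kind)
  tab <- .unit_tables[[kind]]
  if (is.numeric(x)) {
    if (length(x) != 1L || !is.finite(x))
      stop("expected a single finite number for ", kind, " quantity")
    return(x * tab[[.default_unit[[kind]]]])
  }
  if (!is.character(x) || length(x) != 1L)
    stop("cannot parse ", kind, " quantity from object of class ",
         class(x)[1L])
  x <- trimws(x)
  m <- regmatches(x, regexec("^([-+0-9.eE]+)\\s*(.*)$", x))[[1L]]
  if (length(m) == 0L || is.na(suppressWarnings(val <- as.numeric(m[2L]))))
    stop("non-numeric value in quantity string: '", x, "'")
  unit <- m[3L]
  if (unit == "") unit <- .default_unit[[kind]]
  if (!unit %in% names(tab))
    stop("unrecognized ", kind, " unit '", unit, "' (known: ",
         paste(names(tab), collapse = ", "), ")")
  val * tab[[unit]]
}
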