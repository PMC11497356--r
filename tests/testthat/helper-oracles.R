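# Independent oracles used across the suite.

# Forward-Euler integration of the surface-limited mass loss of a single
# particle, dm/dt = -k * pi * D^2 with D = (6 m / (pi rho))^(1/3); the
# suspension particle concentration scales as m(t)/m(0).  Validates the
# closed-form cube law without using it.
euler_conc_nf <- function(spec, t_end, step_frac = 1e-4) {
  p <- rate_parameter(spec)
  if (p == 0) return(spec$c0)
  h <- step_frac / p
  n <- ceiling(t_end / h)
  h <- t_end / n
  m0 <- spec$rho * pi / 6 * spec$d0^3
  m <- m0
  for (i in seq_len(n)) {
    d <- (6 * m / (pi * spec$rho))^(1 / 3)
    m <- max(0, m - h * spec$k * pi * d^2)
  }
  spec$c0 * m / m0
}

# Dense brute-force grid minimum/maximum of the ion contribution over an
# assumption region, independent of the scan-and-refine search.
brute_force_extrema <- function(region, tau, eta1, eta2, n = 400L) {
  a <- exp(seq(log(region$dose_lo), log(region$dose_hi), length.out = n))
  r <- exp(seq(log(region$ratio_lo), log(region$ratio_hi), length.out = n))
  g <- expand.grid(a = a, r = r)
  v <- vapply(seq_len(nrow(g)), function(i) {
    contr_ion(dimensionless_state(g$a[i], g$r[i] * g$a[i], tau, eta1, eta2))
  }, numeric(1))
  c(min = min(v), max = max(v))
}

# random nanoform within the realistic screening range
random_nanoform <- function() {
  nanoform(k = 10^stats::runif(1, -4, 3),
           rho = stats::runif(1, 2, 12),
           d0 = 10^stats::runif(1, log10(5), log10(200)),
           c0 = 10^stats::runif(1, -4, -1))
}
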