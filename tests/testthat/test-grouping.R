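# Published critical-rate tables for silver and copper (k in ng/cm^2/h,
# printed precision as in the source tables).  Row order: scenarios
# (1,1), (1,5), (4,8); within each, times 72/168/672 h x diameters
# 10/100 nm in the printed arrangement (diameter blocks of three times).
printed_table <- function(material) {
  grid <- expand.grid(time_h = c(72, 168, 672), diameter_nm = c(10, 100))
  grid <- grid[rep(1:6, 3), ]
  grid$eta1 <- rep(c(1, 1, 4), each = 6)
  grid$eta2 <- rep(c(1, 5, 8), each = 6)
  kk <- switch(material,
    silver = list(
      upper = c(0.05, 0.02, 0.01, 0.49, 0.21, 0.05,
                0.0009, 0.0004, 0.0001, 0.01, 0.0037, 0.0009,
                0.54, 0.23, 0.06, 5.39, 2.31, 0.58),
      lower = c(37.95, 16.27, 4.07, 379.53, 162.66, 40.66,
                33.87, 14.52, 3.63, 338.74, 145.17, 36.29,
                18.94, 8.12, 2.03, 189.40, 81.17, 20.29)),
    copper = list(
      upper = c(0.04, 0.02, 0.0045, 0.42, 0.18, 0.04,
                0.0007, 0.0003, 0.0001, 0.01, 0.0032, 0.0008,
                0.46, 0.20, 0.05, 4.59, 1.97, 0.49),
      lower = c(32.35, 13.86, 3.47, 323.45, 138.62, 34.66,
                28.87, 12.37, 3.09, 288.69, 123.72, 30.93,
                16.14, 6.92, 1.73, 161.42, 69.18, 17.29)))
  grid$k_upper <- kk$upper
  grid$k_lower <- kk$lower
  grid
}

# half an ulp of a printed decimal value ("0.0009" -> 5e-5)
half_ulp <- function(x) {
  dp <- vapply(format(x, scientific = FALSE, trim = TRUE, drop0trailing = TRUE),
               function(s) {
                 if (!grepl("\\.", s)) 0L else nchar(sub(".*\\.", "", s))
               }, integer(1), USE.NAMES = FALSE)
  0.5 * 10^(-dp)
}

test_that("Pt of the silver worked example and its linearity in time", {
  ag <- nanoform(37.95, 10.49, 10, 1e-3)
  expect_equal(pt_value(ag, 72), 0.521, tolerance = 0.001 / 0.521)
  expect_identical(pt_value(ag, 0), 0)
  expect_equal(pt_value(ag, 144), 2 * pt_value(ag, 72))
})

test_that("critical rate constant inverts the Pt relation", {
  expect_equal(round(critical_k(0.521, 10.49, 10, 72), 2), 37.95)
  expect_equal(round(critical_k(0.521, 10.49, 100, 168), 2), 162.66)
  expect_identical(critical_k(0, 10.49, 10, 72), 0)
  expect_error(critical_k(0.5, -1, 10, 72), "positive")
  # round trip through pt_value
  k <- critical_k(0.3, 8.95, 25, 96)
  expect_equal(pt_value(nanoform(k, 8.95, 25, 1e-3), 96), 0.3,
               tolerance = 1e-10)
})

test_that("critical exposure time inverts the Pt relation", {
  ag <- nanoform(18.98, 10.49, 10, 1e-3)
  expect_equal(critical_t(0.521, ag), 144, tolerance = 0.5 / 144)
  expect_equal(critical_t(0.521, nanoform(2 * 18.98, 10.49, 10, 1e-3)),
               critical_t(0.521, ag) / 2)
  expect_equal(pt_value(ag, critical_t(0.3333, ag)), 0.3333,
               tolerance = 1e-12)
  expect_identical(critical_t(0.5, nanoform(0, 10.49, 10, 1e-3)), Inf)
})

test_that("critical diameter and density invert the worked example", {
  expect_equal(critical_diameter(0.521, 37.95, 10.49, 72), 10,
               tolerance = 0.05 / 10)
  expect_equal(critical_diameter(0.2, 37.95, 10.49, 72),
               2 * critical_diameter(0.4, 37.95, 10.49, 72))
  expect_equal(critical_density(0.521, 37.95, 10, 72), 10.49,
               tolerance = 0.05 / 10.49)
  k <- 10^stats::runif(1, -2, 2)
  expect_equal(critical_density(0.37, k, critical_diameter(0.37, k, 7.1, 50),
                                50), 7.1, tolerance = 1e-10)
  expect_error(critical_diameter(0, 1, 1, 1), "positive")
})

test_that("classification follows the Pt regime bands", {
  th <- reference_thresholds(1, 1)
  fast <- nanoform(40, 10.49, 10, 1e-3)
  res <- classify_nanoform(fast, 72, th)
  expect_identical(res$assigned_class, "ion_dominated")
  expect_equal(res$pt, 0.549, tolerance = 1e-3)
  slow <- nanoform(0.0001, 10.49, 10, 1e-3)
  expect_identical(classify_nanoform(slow, 72, th)$assigned_class,
                   "particle_dominated")
  # Pt inside (0.0295, 0.103) is unambiguously mixed
  k_mid <- critical_k(0.05, 10.49, 10, 72)
  expect_identical(
    classify_nanoform(nanoform(k_mid, 10.49, 10, 1e-3), 72, th)$assigned_class,
    "mixed")
})

test_that("ambiguous bands are indeterminate unless EC50s resolve them", {
  th <- reference_thresholds(1, 1)
  k_amb <- critical_k(0.3, 10.49, 10, 72)  # in the (0.103, 0.521) band
  spec <- nanoform(k_amb, 10.49, 10, c0 = 0.01)
  expect_identical(classify_nanoform(spec, 72, th)$assigned_class,
                   "indeterminate")
  # strong ions (low ion EC50) push the resolved class to ion dominance
  res <- classify_nanoform(spec, 72, th, ec50_ion = 1e-4, ec50_nf = 0.05)
  expect_identical(res$assigned_class, "ion_dominated")
  # equal, high EC50s at this tau stay mixed
  res2 <- classify_nanoform(spec, 72, th, ec50_ion = 0.01, ec50_nf = 0.01)
  expect_identical(res2$assigned_class, "mixed")
})

test_that("classification is monotone in the dissolution rate constant", {
  th <- reference_thresholds(1, 1)
  rank <- c(particle_dominated = 1L, indeterminate = 2L, mixed = 2L,
            ion_dominated = 3L)
  ks <- 10^seq(-5, 3, length.out = 40)
  cls <- vapply(ks, function(k) {
    classify_nanoform(nanoform(k, 10.49, 10, 1e-3), 72, th)$assigned_class
  }, character(1))
  expect_true(all(diff(rank[cls]) >= 0))
})

test_that("generated screening tables reproduce the published silver and copper tables", {
  for (mat in c("silver", "copper")) {
    ref <- printed_table(mat)
    tab <- generate_table(material_preset(mat))
    expect_equal(nrow(tab), 18L)
    for (i in seq_len(nrow(ref))) {
      sc <- reference_thresholds(ref$eta1[i], ref$eta2[i])
      k_up <- critical_k(sc$pt_all_below, material_preset(mat)$rho,
                         ref$diameter_nm[i], ref$time_h[i])
      k_lo <- critical_k(sc$pt_all_above, material_preset(mat)$rho,
                         ref$diameter_nm[i], ref$time_h[i])
      # printed values carry their own rounding; copper additionally
      # back-computes to a slightly lower density (0.5% allowance)
      tol_up <- half_ulp(ref$k_upper[i])
      tol_lo <- half_ulp(ref$k_lower[i])
      if (mat == "copper") {
        tol_up <- pmax(tol_up, 0.005 * ref$k_upper[i])
        tol_lo <- pmax(tol_lo, 0.005 * ref$k_lower[i])
      }
      expect_lte(abs(k_up - ref$k_upper[i]), tol_up + 1e-12)
      expect_lte(abs(k_lo - ref$k_lower[i]), tol_lo + 1e-12)
      row <- tab[tab$scenario == sprintf("eta1=%g,eta2=%g", ref$eta1[i],
                                         ref$eta2[i]) &
                 tab$time_h == ref$time_h[i] &
                 tab$diameter_nm == ref$diameter_nm[i], ]
      expect_equal(nrow(row), 1L)
      expect_equal(row$k_lower_ng_cm2_h, round(k_lo, 2))
    }
  }
})

test_that("table layout is ordered and applies the sub-0.01 rounding rule", {
  tab <- generate_table(material_preset("silver"))
  expect_identical(names(tab),
                   c("scenario", "time_h", "diameter_nm", "pt_upper_low",
                     "pt_lower_high", "k_upper_ng_cm2_h", "k_lower_ng_cm2_h"))
  # ascending (time, diameter) within each scenario block
  for (s in unique(tab$scenario)) {
    blk <- tab[tab$scenario == s, ]
    expect_false(is.unsorted(blk$time_h))
  }
  # four-decimal path: (1,5) scenario upper bounds are far below 0.01
  blk15 <- tab[tab$scenario == "eta1=1,eta2=5" & tab$diameter_nm == 10, ]
  expect_equal(blk15$k_upper_ng_cm2_h, c(0.0009, 0.0004, 0.0001))
})
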