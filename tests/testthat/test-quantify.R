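spec <- column_spec()
dry_mass_per_m <- 2.65 * (1 - 0.30) * pi * 0.07^2 / 4 * 1000  # kg of medium per m

test_that("solid-profile integration recovers the constant-profile closed form", {
  prof <- solid_fe_profile(c(0, 0.5, 1.0), rep(10, 3))
  m <- integrate_solid_fe(prof, spec)
  expect_equal(as.numeric(m), 10 * dry_mass_per_m * 1.0, tolerance = 1e-12)
  # ~7.14 kg of dry medium at 10 mg/kg => ~71.4 mg
  expect_equal(as.numeric(m), 71.4, tolerance = 1e-3)
})

test_that("a zero profile integrates to zero and short profiles are rejected", {
  expect_equal(as.numeric(integrate_solid_fe(
    solid_fe_profile(c(0, 1), c(0, 0)), spec)), 0)
  expect_error(integrate_solid_fe(solid_fe_profile(0.5, 3), spec), "2 points")
})

test_that("trapezoid equals the analytic integral for piecewise-linear profiles", {
  set.seed(11)
  for (i in 1:10) {
    knots <- sort(c(0, runif(5), 1))
    vals <- runif(7, 0, 500)
    analytic <- sum(diff(knots) * (vals[-7] + vals[-1]) / 2) * dry_mass_per_m
    m <- integrate_solid_fe(solid_fe_profile(knots, vals), spec)
    expect_equal(as.numeric(m), analytic, tolerance = 1e-10)
  }
})

test_that("end samples are extrapolated as constants to the column ends", {
  prof <- solid_fe_profile(c(0.25, 0.75), c(100, 100))
  expect_equal(as.numeric(integrate_solid_fe(prof, spec)),
               100 * dry_mass_per_m * 1.0, tolerance = 1e-12)
})

test_that("the exponential fit integrates a decaying profile analytically", {
  a <- 500; b <- 8
  x <- seq(0, 1, by = 0.02)
  prof <- solid_fe_profile(x, a * exp(-b * x))
  m <- integrate_solid_fe(prof, spec, method = "fit_then_integrate")
  expect_equal(attr(m, "method"), "fit_then_integrate")
  expect_equal(as.numeric(m), a / b * (1 - exp(-b)) * dry_mass_per_m,
               tolerance = 1e-6)
})

test_that("a hopeless exponential fit falls back to the trapezoid with a warning", {
  prof <- solid_fe_profile(c(0, 0.5, 1), c(0, 400, 0))
  expect_warning(m <- integrate_solid_fe(prof, spec, method = "fit_then_integrate"),
                 "fall")
  expect_equal(as.numeric(m),
               as.numeric(integrate_solid_fe(prof, spec)), tolerance = 1e-12)
})

test_that("dissolved flux integral matches the constant-series closed form", {
  days <- 0:10
  tab <- data.frame(column_id = "T1", treatment = "biotic", day = days,
                    distance_m = 0.1, analyte = "fe2_dissolved", value = 1,
                    censored = FALSE, detection_limit = 0.03)
  m <- integrate_dissolved_flux(tab, q_ml_min = 0.05)
  expect_equal(as.numeric(m), 0.72, tolerance = 1e-12)  # 1 mg/L * 72 mL/d * 10 d
  expect_equal(attr(m, "port"), 0.1)
})

test_that("censored observations contribute nothing (or half the limit on request)", {
  days <- c(0, 5, 10)
  tab <- data.frame(column_id = "T1", treatment = "biotic", day = days,
                    distance_m = 0.1, analyte = "fe2_dissolved", value = 0.03,
                    censored = TRUE, detection_limit = 0.03)
  expect_equal(as.numeric(integrate_dissolved_flux(tab, 0.05)), 0)
  m_half <- integrate_dissolved_flux(tab, 0.05, censored_policy = "half_limit")
  expect_equal(as.numeric(m_half), 0.015 * 0.072 * 10, tolerance = 1e-12)
})

test_that("peak mode picks the port with the largest integral", {
  mk <- function(port, conc) {
    data.frame(column_id = "T1", treatment = "biotic", day = 0:10,
               distance_m = port, analyte = "fe2_dissolved", value = conc,
               censored = FALSE, detection_limit = 0.03)
  }
  tab <- rbind(mk(0.1, 2), mk(0.2, 5), mk(0.3, 1))
  m <- integrate_dissolved_flux(tab, 0.05)
  expect_equal(attr(m, "port"), 0.2)
  m1 <- integrate_dissolved_flux(tab, 0.05, port = 0.3)
  expect_equal(as.numeric(m1), 1 * 0.072 * 10, tolerance = 1e-12)
  expect_error(integrate_dissolved_flux(tab, 0.05, port = 0.45), "no data")
})

test_that("mass balance arithmetic reproduces the >10 mg unattributed gap", {
  mb <- mass_balance(12, 0.03, degraded_solid_mg = 1.9,
                     degraded_dissolved_mg = 0.086)
  expect_equal(mb$removed_total, 11.97)
  expect_equal(mb$discrepancy, 10.07, tolerance = 1e-12)
  expect_gt(mb$discrepancy, 10)
  expect_equal(mb$partition_solid_pct + mb$partition_dissolved_pct, 100)
})

test_that("a perfectly conservative column closes its balance at zero", {
  mb <- mass_balance(5, 5, degraded_solid_mg = 0)
  expect_equal(mb$removed_total, 0)
  expect_equal(mb$discrepancy, 0)
})

test_that("conservative mode derives the inflow from the control's late effluent", {
  ctrl <- data.frame(day = c(1, 5, 20, 30, 35, 40, 43),
                     value = c(0.1, 1, 3, 4.0, 4.1, 3.9, 4.0))
  mb <- mass_balance(ctrl, 0.03, degraded_solid_mg = 1.9,
                     q_ml_min = 0.05, duration_days = 43,
                     late_window = c(30, 43))
  expect_equal(mb$inflow_mass, 4.0 * 0.072 * 43, tolerance = 1e-12)
  expect_error(mass_balance(ctrl, 0.03, degraded_solid_mg = 1.9,
                            q_ml_min = 0.05, duration_days = 43,
                            late_window = c(50, 60)),
               "late_window")
})
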