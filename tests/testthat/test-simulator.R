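test_that("scenario factory returns the documented defaults and is deterministic", {
  ctrl <- make_scenario("control")
  expect_false(ctrl$biotic)
  expect_gt(ctrl$sorption_kd, 0)
  trc <- make_scenario("tracer")
  expect_false(trc$biotic)
  expect_equal(trc$sorption_kd, 0)
  a <- make_scenario("treatment", seed = 7)
  b <- make_scenario("treatment", seed = 7)
  expect_identical(a, b)
  expect_equal(attr(make_scenario("treatment", mu_max = 2), "overrides"),
               list(mu_max = 2))
  expect_error(make_scenario("treatment", not_a_field = 1), "unknown")
  expect_error(make_scenario("bogus"), "arg")
})

test_that("configuration invariants are enforced", {
  expect_error(simulation_config(dissolved_fraction = 1.5), "dissolved_fraction")
  expect_error(simulation_config(mu_max = -1), "mu_max")
  expect_error(simulation_config(grid_dx = 0.03), "divide")
  expect_error(simulation_config(sampling_days = c(1, 99)), "sampling_days")
})

test_that("a conservative tracer reaches the influent concentration everywhere", {
  cfg <- make_scenario("tracer", duration = 120, sampling_days = 120,
                       grid_dx = 0.02, dt = 0.1)
  res <- simulate_column(cfg)
  tol <- res$monitoring[res$monitoring$analyte == "toluene", ]
  expect_equal(tol$value, rep(9214, nrow(tol)), tolerance = 1e-3)
  expect_equal(res$ledger$toluene_degraded, 0)
  expect_equal(res$ledger$fe2_solid, 0)
  expect_equal(res$ledger$fe2_dissolved_stored + res$ledger$fe2_dissolved_out, 0)
})

test_that("without reaction the steady profile is monotone within [0, influent]", {
  cfg <- make_scenario("control", duration = 200, sampling_days = 200,
                       grid_dx = 0.02, dt = 0.1)
  res <- simulate_column(cfg)
  prof <- res$state$toluene_mg_l
  expect_true(all(diff(prof) <= 1e-9))
  expect_true(all(prof >= 0 & prof <= 9.214 + 1e-6))
})

test_that("the transport solver matches a dense matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  # small instance: 10 cells over 1 m, 5 days, sorption on, reaction off
  cfg <- make_scenario("control", grid_dx = 0.1, dt = 0.002, duration = 5,
                       sampling_days = 5)
  col <- cfg$column
  hyd <- column_hydraulics(col)
  nx <- 10L
  dx <- col$length / nx
  vw <- hyd$cross_section_area * dx * col$effective_porosity * 1000
  q_l <- hyd$darcy_flux * hyd$cross_section_area * 1000
  r_f <- 1 + hyd$bulk_density * cfg$sorption_kd / col$effective_porosity
  disp <- cfg$dispersivity * hyd$seepage_velocity
  # semi-discrete operator: upwind advection + central dispersion, reflective ends
  adv <- diag(-1, nx)
  adv[cbind(2:nx, 1:(nx - 1))] <- 1
  lap <- diag(-2, nx)
  lap[cbind(1:(nx - 1), 2:nx)] <- 1
  lap[cbind(2:nx, 1:(nx - 1))] <- 1
  lap[1, 1] <- -1; lap[nx, nx] <- -1
  A <- (q_l / (r_f * vw)) * adv + (disp / (r_f * dx^2)) * lap
  b <- numeric(nx); b[1] <- (q_l / (r_f * vw)) * 9.214
  eA <- as.matrix(Matrix::expm(Matrix::Matrix(A * 5)))
  c_oracle <- as.vector(eA %*% numeric(nx) + solve(A, (eA - diag(nx)) %*% b))
  res <- simulate_column(cfg)
  expect_lt(max(abs(res$state$toluene_mg_l - c_oracle)) / max(c_oracle), 0.01)
})

test_that("every run closes its mole ledgers", {
  for (res in list(treatment_sim(), control_sim())) {
    expect_lt(res$balance$toluene_relative, 0.005)     # spec tolerance
    expect_lt(res$balance$toluene_relative, 1e-9)      # scheme is conservative-form
    expect_lt(res$balance$electron_relative, 1e-9)
    led <- res$ledger
    fe_total <- led$fe2_solid + led$fe2_dissolved_stored + led$fe2_dissolved_out
    expect_equal(fe_total, 36 * led$toluene_degraded, tolerance = 1e-12)
  }
})

test_that("the dissolved share of produced Fe(II) equals the configured fraction", {
  res <- treatment_sim()
  led <- res$ledger
  fe_total <- led$fe2_solid + led$fe2_dissolved_stored + led$fe2_dissolved_out
  f_d <- res$config$dissolved_fraction
  expect_equal((led$fe2_dissolved_stored + led$fe2_dissolved_out) / fe_total,
               f_d, tolerance = 1e-9)
})

test_that("treatment port toluene rises then falls with a single maximum", {
  mon <- treatment_sim()$monitoring
  for (p in seq(0.1, 0.9, by = 0.1)) {
    v <- port_series(mon, "toluene", p)$value
    pk <- which.max(v)
    tol <- 1e-3 * max(v)
    if (pk > 1) expect_true(all(diff(v[1:pk]) >= -tol))
    if (pk < length(v)) expect_true(all(diff(v[pk:length(v)]) <= tol))
  }
})

test_that("dissolved Fe2+ at each port rises to a stable plateau after detection", {
  res <- treatment_sim()
  dl <- res$config$detection_limits[["fe2_dissolved"]]
  for (p in seq(0.1, 0.9, by = 0.1)) {
    v <- port_series(res$monitoring, "fe2_dissolved", p)$value
    det <- which(v >= dl)
    expect_gt(length(det), 2)
    tail_v <- v[det[1]:length(v)]
    # rising limb with bounded settling of the early sorbed-inventory pulse
    expect_true(all(tail_v >= 0.7 * cummax(tail_v)))
    late <- utils::tail(tail_v, 3)
    expect_lt(diff(range(late)) / mean(late), 0.02)  # plateau
    expect_gt(utils::tail(v, 1), 0.5 * max(v))
  }
})

test_that("late-time toluene is contained near the inlet while Fe2+ spans the column", {
  res <- treatment_sim()
  ex <- exceedance_matrix(apply_measurement_model(res, noise_cv = 0))
  tol_ext <- plume_metrics(ex, "toluene")$max_extent
  late <- tol_ext$max_extent_m[tol_ext$day >= 33]
  expect_true(length(late) == 0 || all(late < 0.2))
  fe_ext <- plume_metrics(ex, "fe2_dissolved")$max_extent
  expect_equal(max(fe_ext$max_extent_m), 0.9)
})

test_that("tracer arrival matches the theoretical retention time", {
  arr <- cached_fixture("tracer_arrival",
    tracer_arrival_time(make_scenario("tracer", duration = 20, grid_dx = 0.02,
                                      dt = 0.02)))
  expect_equal(arr, 12.5, tolerance = 0.10)
})

test_that("halving the conductivity doubles the tracer arrival time", {
  arr <- cached_fixture("tracer_arrival",
    tracer_arrival_time(make_scenario("tracer", duration = 20, grid_dx = 0.02,
                                      dt = 0.02)))
  slow_col <- column_spec(hydraulic_conductivity = 5)
  arr2 <- tracer_arrival_time(make_scenario("tracer", column = slow_col,
                                            duration = 40, grid_dx = 0.02,
                                            dt = 0.02))
  expect_equal(arr2 / arr, 2, tolerance = 0.02)
})

test_that("the zero-dispersivity tracer converges to plug flow", {
  arr <- tracer_arrival_time(make_scenario("tracer", dispersivity = 0,
                                           duration = 20, dt = 0.02))
  expect_equal(arr, 12.5, tolerance = 0.02)
})

test_that("an unreachable tracer level is reported, not invented", {
  expect_error(tracer_arrival_time(make_scenario("tracer", duration = 3)),
               "never reached")
  expect_error(tracer_arrival_time(make_scenario("treatment")), "tracer")
})

test_that("sterile-control outlet crosses the toluene threshold between days 10 and 20", {
  out <- control_sim()$outlet
  cross <- out$day[which(out$toluene_mg_l >= 0.7)[1]]
  expect_gte(cross, 10)
  expect_lte(cross, 20)
})

test_that("the measurement model is seed-deterministic and censors at the limit", {
  res <- treatment_sim()
  noisy1 <- apply_measurement_model(res, seed = 99)
  noisy2 <- apply_measurement_model(res, seed = 99)
  expect_identical(noisy1, noisy2)
  noisy3 <- apply_measurement_model(res, seed = 100)
  expect_false(identical(noisy1$value, noisy3$value))
  expect_true(all(noisy1$value[noisy1$censored] ==
                    noisy1$detection_limit[noisy1$censored]))
  expect_true(any(noisy1$censored))

  clean <- apply_measurement_model(res, noise_cv = 0)
  raw <- res$monitoring
  uncens <- !clean$censored
  expect_equal(clean$value[uncens], raw$value[uncens])
  # a true value below the limit is censored and reported at the limit
  expect_true(all(raw$value[clean$censored] < clean$detection_limit[clean$censored]))
})

test_that("the measurement model leaves the caller's RNG stream untouched", {
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(apply_measurement_model(treatment_sim(), seed = 5))
  expect_identical(runif(1), before)
})
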