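#' Configuration for the 1D column reactive-transport simulator
#'
#' Parameters of the synthetic-data generator: a one-dimensional
#' advection--dispersion--sorption--reaction model of a flow-through column in
#' which toluene is degraded by an iron-reducing consortium. Transport of the
#' two mobile species (toluene, retarded by linear sorption; dissolved Fe2+,
#' non-sorbing) follows
#' \deqn{R \frac{\partial C}{\partial t} =
#'   -v \frac{\partial C}{\partial x} + D \frac{\partial^2 C}{\partial x^2}
#'   - r(x, t),}
#' with \eqn{R = 1 + \rho_b K_d / n_e}, \eqn{D = \alpha v}, a
#' specified-concentration inlet and free-outflow outlet. The biodegradation
#' rate is dual-Monod in toluene and solid Fe(III),
#' \eqn{r = \mu_{max} B \frac{C}{K_C + C} \frac{Fe^{3+}}{K_{Fe} + Fe^{3+}}},
#' with immobile (attached) biomass growing logistically,
#' \eqn{dB/dt = Y r (1 - B/B_{max}) - k_d B}. Produced Fe(II) splits into a
#' mobile dissolved fraction \code{dissolved_fraction} and an immobile
#' solid-phase pool; there is no Fe(II) re-oxidation sink (anoxic, low-ORP
#' conditions).
#'
#' Defaults emulate the study conditions of a 100 cm iron-amended sand column
#' fed 0.1 mmol/L toluene at ~0.05 mL/min: sampling on days 1--8 then every
#' 5 days to day 43, detection limits of 0.1 ug/L (toluene) and 0.03 mg/L
#' (dissolved Fe), and a 98:2 solid:dissolved Fe(II) split
#' (\code{dissolved_fraction} = 0.017).
#'
#' @param column A \code{\link{column_spec}}.
#' @param influent_toluene Influent toluene, mmol/L.
#' @param dispersivity Longitudinal dispersivity \eqn{\alpha}, m.
#' @param sorption_kd Linear sorption coefficient \eqn{K_d}, L/kg (toluene).
#' @param biotic Logical; \code{FALSE} forces the biodegradation rate to zero
#'   (sterile control).
#' @param mu_max Maximum specific substrate-utilisation rate, mg toluene per
#'   mg biomass per day.
#' @param half_sat_toluene Monod half-saturation for toluene, mg/L.
#' @param half_sat_fe3 Monod half-saturation for solid Fe(III), mg/kg.
#' @param biomass_init Initial attached biomass, mg/L of pore water.
#' @param biomass_max Logistic biomass carrying capacity (attachment-site
#'   limitation), mg/L.
#' @param biomass_yield Biomass yield Y, mg biomass per mg toluene.
#' @param biomass_decay First-order biomass decay, 1/day.
#' @param dissolved_fraction Fraction f_d of produced Fe(II) released as
#'   mobile dissolved Fe2+ (in [0, 1]); the remainder stays solid-phase.
#' @param fe3_init Initial bioavailable solid Fe(III), mg Fe per kg dry
#'   medium; default derived from the column's ferric hydroxide fraction.
#' @param side_sink_rate Optional first-order non-iron toluene sink, 1/day
#'   (default 0); when enabled it emulates degradation pathways that leave no
#'   Fe(II) record.
#' @param grid_dx Grid cell size, m; must divide the port spacing so ports
#'   fall on cell faces.
#' @param dt Transport time step, days.
#' @param duration Simulated time, days.
#' @param sampling_days Days at which ports are sampled; \code{NULL} uses the
#'   study schedule (days 1--8 daily, then every 5 days) clipped to
#'   \code{duration}.
#' @param profile_dx Spacing of the end-of-run solid-phase Fe(II) profile, m.
#' @param noise_cv Default analytical coefficient of variation used by
#'   \code{\link{apply_measurement_model}}.
#' @param detection_limits Named vector: \code{toluene} (ug/L),
#'   \code{fe2_dissolved} (mg/L).
#' @param seed Default seed for the measurement model.
#' @param column_id Label for generated monitoring rows.
#' @return An object of class \code{simulation_config}.
#' @seealso \code{\link{make_scenario}} for named default configurations.
#' @export
simulation_config <- function(column = column_spec(),
                              influent_toluene = 0.1,
                              dispersivity = 0.02,
                              sorption_kd = 0.09,
                              biotic = TRUE,
                              mu_max = 4,
                              half_sat_toluene = 1,
                              half_sat_fe3 = 500,
                              biomass_init = 0.01,
                              biomass_max = 2,
                              biomass_yield = 0.3,
                              biomass_decay = 0,
                              dissolved_fraction = 0.017,
                              fe3_init = NULL,
                              side_sink_rate = 0,
                              grid_dx = 0.01,
                              dt = 0.05,
                              duration = 43,
                              sampling_days = NULL,
                              profile_dx = 0.02,
                              noise_cv = 0.1,
                              detection_limits = c(toluene = 0.1, fe2_dissolved = 0.03),
                              seed = 1L,
                              column_id = "T1") {
  validate_column_spec(column)
  if (is.null(sampling_days)) {
    # the study schedule (daily for the first 8 days, then every 5 days),
    # clipped to the simulated duration
    sampling_days <- c(1:8, seq(13, 43, by = 5))
    sampling_days <- sampling_days[sampling_days <= duration]
    if (length(sampling_days) == 0L) sampling_days <- duration
  }
  if (is.null(fe3_init)) {
    # mg Fe per kg dry medium contributed by the Fe(OH)3 amendment
    m_feoh3 <- 106.867  # g/mol Fe(OH)3
    fe3_init <- column$fe_hydroxide_mass_fraction * 1e6 * 55.845 / m_feoh3
  }
  cfg <- list(
    column = column,
    influent_toluene = influent_toluene,
    dispersivity = dispersivity,
    sorption_kd = sorption_kd,
    biotic = isTRUE(biotic),
    mu_max = mu_max,
    half_sat_toluene = half_sat_toluene,
    half_sat_fe3 = half_sat_fe3,
    biomass_init = biomass_init,
    biomass_max = biomass_max,
    biomass_yield = biomass_yield,
    biomass_decay = biomass_decay,
    dissolved_fraction = dissolved_fraction,
    fe3_init = fe3_init,
    side_sink_rate = side_sink_rate,
    grid_dx = grid_dx,
    dt = dt,
    duration = duration,
    sampling_days = sort(unique(sampling_days)),
    profile_dx = profile_dx,
    noise_cv = noise_cv,
    detection_limits = detection_limits,
    seed = as.integer(seed),
    column_id = column_id
  )
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

#' Validate a simulation configuration
#' @param cfg A \code{simulation_config}.
#' @return The config, invisibly, if valid.
#' @export
validate_simulation_config <- function(cfg) {
  problems <- character(0)
  nonneg <- c("influent_toluene", "dispersivity", "sorption_kd", "mu_max",
              "half_sat_toluene", "half_sat_fe3", "biomass_init", "biomass_max",
              "biomass_yield", "biomass_decay", "fe3_init", "side_sink_rate",
              "noise_cv")
  for (f in nonneg) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || !is.finite(cfg[[f]]) ||
        cfg[[f]] < 0) {
      problems <- c(problems, sprintf("field '%s' must be a finite number >= 0", f))
    }
  }
  if (cfg$dissolved_fraction < 0 || cfg$dissolved_fraction > 1) {
    problems <- c(problems, "field 'dissolved_fraction' must lie in [0, 1]")
  }
  for (f in c("grid_dx", "dt", "duration", "profile_dx")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      problems <- c(problems, sprintf("field '%s' must be > 0", f))
    }
  }
  ratio <- cfg$column$port_spacing / cfg$grid_dx
  if (abs(ratio - round(ratio)) > 1e-9) {
    problems <- c(problems, sprintf(
      "field 'grid_dx' (%g m) must divide the port spacing (%g m) so ports fall on cell faces",
      cfg$grid_dx, cfg$column$port_spacing))
  }
  if (any(cfg$sampling_days < 0) || any(cfg$sampling_days > cfg$duration + 1e-9)) {
    problems <- c(problems, "field 'sampling_days' must lie within [0, duration]")
  }
  if (!all(c("toluene", "fe2_dissolved") %in% names(cfg$detection_limits)) ||
      any(cfg$detection_limits < 0)) {
    problems <- c(problems,
                  "field 'detection_limits' needs non-negative 'toluene' and 'fe2_dissolved' entries")
  }
  if (length(problems) > 0L) {
    stop("invalid simulation_config:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(cfg)
}

#' Named scenario factory
#'
#' Returns the default configuration of one of the three column types run in
#' iron-reduction attenuation experiments: \code{"treatment"} (inoculated,
#' biotic), \code{"control"} (HgCl2-sterilised: sorption and transport only)
#' and \code{"tracer"} (conservative: no sorption, no reaction). Overrides are
#' applied on top of the defaults and recorded in the returned object.
#'
#' @param name One of \code{"treatment"}, \code{"control"}, \code{"tracer"}.
#' @param ... Named overrides of \code{\link{simulation_config}} fields
#'   (unknown names are an error).
#' @return A \code{\link{simulation_config}} with attributes \code{scenario}
#'   and \code{overrides}.
#' @examples
#' cfg <- make_scenario("control")
#' cfg$biotic # FALSE
#' @export
make_scenario <- function(name = c("treatment", "control", "tracer"), ...) {
  name <- match.arg(name)
  defaults <- switch(name,
    treatment = list(biotic = TRUE, column_id = "T1"),
    control   = list(biotic = FALSE, column_id = "C1"),
    tracer    = list(biotic = FALSE, sorption_kd = 0, noise_cv = 0,
                     column_id = "TRACER")
  )
  overrides <- list(...)
  if (length(overrides) > 0L && (is.null(names(overrides)) || any(names(overrides) == ""))) {
    stop("scenario overrides must be named", call. = FALSE)
  }
  allowed <- names(formals(simulation_config))
  unknown <- setdiff(names(overrides), allowed)
  if (length(unknown) > 0L) {
    stop("unknown simulation_config field(s) in overrides: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  args <- utils::modifyList(defaults, overrides)
  cfg <- do.call(simulation_config, args)
  attr(cfg, "scenario") <- name
  attr(cfg, "overrides") <- overrides
  cfg
}

# Run expr with a locally-seeded RNG, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulate a column experiment
#'
#' Integrates the reactive-transport model of a \code{\link{simulation_config}}
#' by operator splitting: flux-form explicit upwind advection (sub-stepped to
#' Courant number <= 0.9 per species), implicit centred dispersion with
#' zero-dispersive-flux boundaries, then a point-wise reaction update in which
#' the toluene consumed per sub-step is capped by the toluene and Fe(III)
#' actually present, so concentrations and the Fe(III) pool can never go
#' negative and Fe(III) exhaustion simply stalls the rate.
#'
#' Every mole is tracked: the returned ledger satisfies, to floating-point
#' round-off, the electron-balance identity
#' \code{fe2_solid + fe2_dissolved_stored + fe2_dissolved_out =
#' 36 * toluene_degraded} (in moles) and a closed toluene balance
#' (in = out + aqueous + sorbed + degraded + side sink).
#'
#' @param config A \code{\link{simulation_config}}.
#' @return An object of class \code{simulation_result}: a list with
#'   \code{monitoring} (noise-free \code{monitoring_table}: toluene in ug/L,
#'   dissolved Fe2+ in mg/L at each port x sampling day),
#'   \code{solid_fe_profile} (end-of-run \code{solid_fe_profile}, mg/kg),
#'   \code{outlet} (per-step outlet concentrations, mg/L),
#'   \code{ledger} (cumulative moles), \code{balance} (closure residuals),
#'   \code{state} (final grid fields) and \code{config}.
#' @export
simulate_column <- function(config) {
  validate_simulation_config(config)
  col <- config$column
  hyd <- column_hydraulics(col)
  st <- stoichiometry()

  nx <- as.integer(round(col$length / config$grid_dx))
  dx <- col$length / nx
  x_centers <- (seq_len(nx) - 0.5) * dx
  area <- hyd$cross_section_area
  q_l_day <- hyd$darcy_flux * area * 1000            # L/day through column
  vw <- area * dx * col$effective_porosity * 1000    # mobile water per cell, L
  ms <- hyd$bulk_density * area * dx * 1000          # dry solid per cell, kg
  v <- hyd$seepage_velocity                          # m/day
  disp <- config$dispersivity * v                    # m2/day
  rho_b <- hyd$bulk_density                          # kg/L
  r_tol <- 1 + rho_b * config$sorption_kd / col$effective_porosity
  c_in <- config$influent_toluene * st$molar_mass_toluene  # mg/L

  nt <- max(1L, as.integer(ceiling(config$duration / config$dt)))
  dt <- config$duration / nt

  # implicit dispersion operators (dense; grids are O(100) cells)
  disp_solver <- function(r_fac) {
    if (disp <= 0 || nx < 3L) return(NULL)
    lap <- diag(-2, nx)
    lap[cbind(seq_len(nx - 1L), seq_len(nx - 1L) + 1L)] <- 1
    lap[cbind(seq_len(nx - 1L) + 1L, seq_len(nx - 1L))] <- 1
    lap[1L, 1L] <- -1       # zero-flux boundaries
    lap[nx, nx] <- -1
    a <- diag(r_fac, nx) - (dt * disp / dx^2) * lap
    solve(a) * r_fac        # maps C_old -> C_new in one matvec
  }
  minv_tol <- disp_solver(r_tol)
  minv_fe <- disp_solver(1)

  mu_eff <- if (config$biotic) config$mu_max else 0
  f_d <- config$dissolved_fraction
  fe_per_tol <- st$electrons_per_toluene / st$electrons_per_fe  # 36 mol Fe / mol tol

  c_tol <- numeric(nx)
  c_fe2 <- numeric(nx)
  biomass <- rep(config$biomass_init, nx)
  fe3 <- rep(config$fe3_init, nx)     # mg Fe / kg
  fe2_solid <- numeric(nx)            # mg Fe / kg

  led <- list(tol_in = 0, tol_out = 0, deg_mmol = 0, side_mmol = 0, fe2_out_mg = 0)

  advect <- function(c_vec, retard, c_inlet) {
    cr <- q_l_day * dt / (retard * vw)
    n_sub <- max(1L, as.integer(ceiling(cr / 0.9)))
    a <- cr / n_sub
    infl <- 0; outfl <- 0
    for (s in seq_len(n_sub)) {
      outfl <- outfl + q_l_day * (dt / n_sub) * c_vec[nx]
      infl <- infl + q_l_day * (dt / n_sub) * c_inlet
      c_vec <- c_vec + a * (c(c_inlet, c_vec[-nx]) - c_vec)
    }
    list(c = c_vec, inflow_mg = infl, outflow_mg = outfl)
  }

  sample_days <- config$sampling_days
  next_sample <- 1L
  ports <- port_positions(col)
  port_face <- as.integer(round(ports / dx))   # ports sit on cell faces
  port_value <- function(c_vec) {
    vapply(port_face, function(j) {
      if (j >= nx) c_vec[nx] else 0.5 * (c_vec[j] + c_vec[j + 1L])
    }, numeric(1))
  }
  mon_rows <- vector("list", length(sample_days))
  outlet_tol <- numeric(nt)
  outlet_fe2 <- numeric(nt)
  times <- numeric(nt)

  n_rsub <- 4L
  dt_r <- dt / n_rsub
  kc <- config$half_sat_toluene
  kfe <- config$half_sat_fe3

  for (step in seq_len(nt)) {
    t_now <- step * dt

    # --- advection ---
    adv_t <- advect(c_tol, r_tol, c_in)
    c_tol <- adv_t$c
    led$tol_in <- led$tol_in + adv_t$inflow_mg
    led$tol_out <- led$tol_out + adv_t$outflow_mg
    adv_f <- advect(c_fe2, 1, 0)
    c_fe2 <- adv_f$c
    led$fe2_out_mg <- led$fe2_out_mg + adv_f$outflow_mg

    # --- dispersion (implicit, conservative) ---
    if (!is.null(minv_tol)) c_tol <- as.vector(minv_tol %*% c_tol)
    if (!is.null(minv_fe)) c_fe2 <- as.vector(minv_fe %*% c_fe2)

    # --- reaction ---
    if (mu_eff > 0) {
      for (s in seq_len(n_rsub)) {
        monod <- (c_tol / (kc + c_tol)) * (fe3 / (kfe + fe3))
        monod[!is.finite(monod)] <- 0
        # delta is the degraded mass per litre of pore water; sorbed toluene
        # re-equilibrates instantly, so the cell holds r_tol * C of it and the
        # aqueous concentration drops by delta / r_tol
        delta <- pmin(mu_eff * biomass * monod * dt_r, r_tol * c_tol)
        # cap by available Fe(III): mg/L toluene whose electrons Fe(III) can accept
        cap_fe <- (fe3 * ms / st$molar_mass_fe / fe_per_tol) *
          st$molar_mass_toluene / vw
        delta <- pmin(delta, cap_fe)
        mg_fe <- delta * vw / st$molar_mass_toluene * fe_per_tol * st$molar_mass_fe
        c_tol <- c_tol - delta / r_tol
        fe3 <- fe3 - mg_fe / ms
        fe2_solid <- fe2_solid + (1 - f_d) * mg_fe / ms
        c_fe2 <- c_fe2 + f_d * mg_fe / vw
        biomass <- biomass +
          config$biomass_yield * delta * pmax(0, 1 - biomass / config$biomass_max) -
          config$biomass_decay * biomass * dt_r
        led$deg_mmol <- led$deg_mmol + sum(delta) * vw / st$molar_mass_toluene
      }
    } else if (config$biomass_decay > 0) {
      biomass <- biomass * exp(-config$biomass_decay * dt)
    }
    if (config$side_sink_rate > 0) {
      # first-order sink on the aqueous phase; sorbed mass drains through R
      removed <- c_tol * (1 - exp(-config$side_sink_rate * dt / r_tol))
      c_tol <- c_tol - removed
      led$side_mmol <- led$side_mmol +
        sum(removed) * r_tol * vw / st$molar_mass_toluene
    }

    if (any(!is.finite(c_tol)) || any(!is.finite(c_fe2)) ||
        any(c_tol < -1e-9 * max(c_in, 1)) || any(c_fe2 < -1e-9)) {
      stop(sprintf("solver instability at step %d (t = %.3f d)", step, t_now),
           call. = FALSE)
    }
    c_tol[c_tol < 0] <- 0
    c_fe2[c_fe2 < 0] <- 0

    times[step] <- t_now
    outlet_tol[step] <- c_tol[nx]
    outlet_fe2[step] <- c_fe2[nx]

    while (next_sample <= length(sample_days) &&
           t_now >= sample_days[next_sample] - 1e-9) {
      d <- sample_days[next_sample]
      mon_rows[[next_sample]] <- data.frame(
        column_id = config$column_id,
        treatment = if (config$biotic) "biotic" else "sterile",
        day = d,
        distance_m = rep(ports, 2L),
        analyte = rep(c("toluene", "fe2_dissolved"), each = length(ports)),
        value = c(port_value(c_tol) * 1000,   # ug/L
                  port_value(c_fe2)),          # mg/L
        censored = FALSE,
        detection_limit = rep(unname(config$detection_limits[c("toluene", "fe2_dissolved")]),
                              each = length(ports)),
        stringsAsFactors = FALSE
      )
      next_sample <- next_sample + 1L
    }
  }

  # --- ledgers (moles) ---
  mmol <- function(mg) mg / st$molar_mass_fe
  ledger <- list(
    toluene_in = led$tol_in / st$molar_mass_toluene / 1000,
    toluene_out = led$tol_out / st$molar_mass_toluene / 1000,
    toluene_aqueous = sum(c_tol) * vw / st$molar_mass_toluene / 1000,
    toluene_sorbed = (r_tol - 1) * sum(c_tol) * vw / st$molar_mass_toluene / 1000,
    toluene_degraded = led$deg_mmol / 1000,
    toluene_side_sink = led$side_mmol / 1000,
    fe2_solid = sum(fe2_solid * ms) / st$molar_mass_fe / 1000,
    fe2_dissolved_stored = sum(c_fe2) * vw / st$molar_mass_fe / 1000,
    fe2_dissolved_out = led$fe2_out_mg / st$molar_mass_fe / 1000
  )
  tol_residual <- ledger$toluene_in - ledger$toluene_out - ledger$toluene_aqueous -
    ledger$toluene_sorbed - ledger$toluene_degraded - ledger$toluene_side_sink
  fe_total <- ledger$fe2_solid + ledger$fe2_dissolved_stored + ledger$fe2_dissolved_out
  balance <- list(
    toluene_residual_mol = tol_residual,
    toluene_relative = if (ledger$toluene_in > 0) abs(tol_residual) / ledger$toluene_in else 0,
    electron_relative = if (ledger$toluene_degraded > 0) {
      abs(fe_total - fe_per_tol * ledger$toluene_degraded) /
        (fe_per_tol * ledger$toluene_degraded)
    } else abs(fe_total)
  )

  prof_x <- seq(0, col$length, by = config$profile_dx)
  prof <- stats::approx(x_centers, fe2_solid, xout = prof_x, rule = 2)$y
  profile <- solid_fe_profile(distance_m = prof_x, fe2_mg_per_kg = prof,
                              column_id = config$column_id, day = config$duration)

  monitoring <- do.call(rbind, mon_rows[!vapply(mon_rows, is.null, logical(1))])
  if (is.null(monitoring)) {
    monitoring <- data.frame(column_id = character(0), treatment = character(0),
                             day = numeric(0), distance_m = numeric(0),
                             analyte = character(0), value = numeric(0),
                             censored = logical(0), detection_limit = numeric(0),
                             stringsAsFactors = FALSE)
  }
  class(monitoring) <- c("monitoring_table", "data.frame")

  out <- list(
    monitoring = monitoring,
    solid_fe_profile = profile,
    outlet = data.frame(day = times, toluene_mg_l = outlet_tol,
                        fe2_mg_l = outlet_fe2),
    ledger = ledger,
    balance = balance,
    state = list(x = x_centers, toluene_mg_l = c_tol, fe2_mg_l = c_fe2,
                 biomass_mg_l = biomass, fe3_mg_kg = fe3,
                 fe2_solid_mg_kg = fe2_solid),
    hydraulics = hyd,
    config = config
  )
  class(out) <- "simulation_result"
  out
}

#' @export
print.simulation_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Column simulation (%s, %s): %.0f days, %d x %.0f cm cells\n",
              cfg$column_id, if (cfg$biotic) "biotic" else "sterile",
              cfg$duration, length(x$state$x), cfg$grid_dx * 100))
  led <- x$ledger
  st <- stoichiometry()
  cat(sprintf("  toluene in/out/degraded: %.3g / %.3g / %.3g mg\n",
              led$toluene_in * 1000 * st$molar_mass_toluene,
              led$toluene_out * 1000 * st$molar_mass_toluene,
              led$toluene_degraded * 1000 * st$molar_mass_toluene))
  cat(sprintf("  Fe(II) solid/dissolved: %.3g / %.3g mg\n",
              led$fe2_solid * 1000 * st$molar_mass_fe,
              (led$fe2_dissolved_stored + led$fe2_dissolved_out) * 1000 * st$molar_mass_fe))
  cat(sprintf("  toluene balance residual: %.2g%% of influent\n",
              100 * x$balance$toluene_relative))
  invisible(x)
}

#' Apply the analytical measurement model to simulated concentrations
#'
#' Multiplies each true concentration by a lognormal factor with unit mean and
#' coefficient of variation \code{noise_cv}, then censors values below the
#' analyte's detection limit: censored observations are flagged and reported
#' at the limit, matching how monitoring laboratories report non-detects.
#' The seed fully determines the output; the caller's RNG state is untouched.
#'
#' @param result A \code{\link{simulate_column}} result or a
#'   \code{monitoring_table} of true values.
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0); defaults to the simulation config's value.
#' @param detection_limits Named vector (\code{toluene} ug/L,
#'   \code{fe2_dissolved} mg/L); defaults to the config's limits.
#' @param seed Integer seed; defaults to the config's seed.
#' @return A \code{monitoring_table} with noisy values and censoring flags.
#' @export
apply_measurement_model <- function(result, noise_cv = NULL,
                                    detection_limits = NULL, seed = NULL) {
  if (inherits(result, "simulation_result")) {
    tab <- result$monitoring
    cfg <- result$config
    if (is.null(noise_cv)) noise_cv <- cfg$noise_cv
    if (is.null(detection_limits)) detection_limits <- cfg$detection_limits
    if (is.null(seed)) seed <- cfg$seed
  } else {
    tab <- result
    if (is.null(noise_cv) || is.null(seed)) {
      stop("noise_cv and seed are required when passing a bare table", call. = FALSE)
    }
    if (is.null(detection_limits)) {
      detection_limits <- c(toluene = 0.1, fe2_dissolved = 0.03)
    }
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (any(detection_limits < 0)) stop("detection limits must be >= 0", call. = FALSE)

  n <- nrow(tab)
  if (noise_cv > 0 && n > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    factors <- with_local_seed(seed,
      stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog))
    tab$value <- tab$value * factors
  }
  lim <- unname(detection_limits[tab$analyte])
  if (any(is.na(lim))) {
    stop("no detection limit for analyte(s): ",
         paste(unique(tab$analyte[is.na(lim)]), collapse = ", "), call. = FALSE)
  }
  tab$detection_limit <- lim
  cens <- tab$value < lim
  tab$censored <- cens
  tab$value[cens] <- lim[cens]
  class(tab) <- c("monitoring_table", "data.frame")
  tab
}

#' Tracer arrival time at the outlet
#'
#' Runs a conservative-tracer simulation and returns the time at which the
#' outlet concentration first reaches 50% of the influent, the operational
#' definition of the hydraulic retention time. In the zero-dispersivity limit
#' this converges to the plug-flow value \eqn{L n_e / (K i)}.
#'
#' @param config A tracer \code{\link{simulation_config}} (non-biotic,
#'   no sorption), e.g. \code{make_scenario("tracer")}.
#' @return Arrival time, days.
#' @export
tracer_arrival_time <- function(config) {
  if (config$biotic || config$sorption_kd > 0) {
    stop("tracer_arrival_time expects a tracer scenario (biotic = FALSE, sorption_kd = 0)",
         call. = FALSE)
  }
  res <- simulate_column(config)
  st <- stoichiometry()
  target <- 0.5 * config$influent_toluene * st$molar_mass_toluene
  first_crossing_day(res$outlet$day, res$outlet$toluene_mg_l, target)
}

# First time a series crosses `level` from below, linearly interpolated.
first_crossing_day <- function(day, value, level) {
  idx <- which(value >= level)
  if (length(idx) == 0L) {
    stop(sprintf("series never reached level %.4g within %.4g days",
                 level, max(day)), call. = FALSE)
  }
  i <- idx[1L]
  if (i == 1L) return(day[1L])
  frac <- (level - value[i - 1L]) / (value[i] - value[i - 1L])
  day[i - 1L] + frac * (day[i] - day[i - 1L])
}
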