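# Shared simulation fixtures, computed once per test run.
.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

treatment_sim <- function() {
  cached_fixture("treatment", simulate_column(make_scenario("treatment")))
}

control_sim <- function() {
  cached_fixture("control", simulate_column(make_scenario("control")))
}

# mol -> mg conversions for ledger comparisons
MG_PER_MOL_FE <- 55.845 * 1000
MG_PER_MOL_TOL <- 92.14 * 1000

port_series <- function(mon, analyte, port) {
  s <- mon[mon$analyte == analyte & abs(mon$distance_m - port) < 1e-9, , drop = FALSE]
  s[order(s$day), , drop = FALSE]
}

# 18-point single-day dissolved-iron fixture: two columns x nine ports with
# exactly one complying port (at 0.7 m) in each column
eighteen_point_fixture <- function(day = 43) {
  ports <- seq(0.1, 0.9, by = 0.1)
  one_col <- function(id) {
    value <- rep(0.8, length(ports))       # mg/L, above the 0.3 limit
    value[abs(ports - 0.7) < 1e-9] <- 0.1  # the complying port
    data.frame(column_id = id, treatment = "biotic", day = day,
               distance_m = ports, analyte = "fe2_dissolved", value = value,
               censored = FALSE, detection_limit = 0.03,
               stringsAsFactors = FALSE)
  }
  rbind(one_col("T1"), one_col("T2"))
}
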