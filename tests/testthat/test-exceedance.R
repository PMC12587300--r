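test_that("the two-column final-day fixture yields 16 of 18 points exceeding", {
  tab <- eighteen_point_fixture()
  rep <- exceedance_matrix(tab)
  frac <- fraction_exceeding(rep, "fe2_dissolved", 43)
  expect_equal(frac, 100 * 16 / 18, tolerance = 1e-12)
  expect_equal(round(frac), 89)
  # the complying port is the 70 cm one in both columns
  comply <- rep$matrix[rep$matrix$status == "comply", ]
  expect_equal(sort(unique(comply$distance_m)), 0.7)
  expect_equal(nrow(comply), 2)
})

test_that("a clean table has no exceedances and no first-arrival days", {
  tab <- eighteen_point_fixture()
  tab$value <- 0.05
  rep <- exceedance_matrix(tab)
  expect_equal(fraction_exceeding(rep, "fe2_dissolved", 43), 0)
  pm <- plume_metrics(rep, "fe2_dissolved")
  expect_equal(nrow(pm$max_extent), 0)
  expect_equal(nrow(pm$first_exceed_day), 0)
})

test_that("a day-23 toy with two hot ports counts exactly two exceedances", {
  ports <- seq(0.1, 0.9, by = 0.1)
  tab <- data.frame(column_id = "T1", treatment = "biotic", day = 23,
                    distance_m = ports, analyte = "fe2_dissolved",
                    value = c(0.5, 0.4, rep(0.1, 7)),
                    censored = FALSE, detection_limit = 0.03)
  rep <- exceedance_matrix(tab)
  expect_equal(sum(rep$matrix$status == "exceed"), 2)
})

test_that("equality with the limit counts as exceeding", {
  tab <- eighteen_point_fixture()[1, ]
  tab$value <- 0.3
  rep <- exceedance_matrix(tab)
  expect_equal(rep$matrix$status, "exceed")
})

test_that("censored observations never count as exceeding", {
  tab <- eighteen_point_fixture()
  tab$value <- tab$detection_limit
  tab$censored <- TRUE
  rep <- exceedance_matrix(tab, threshold_set(fe2_dissolved = 0.01, toluene = 700))
  expect_true(all(rep$matrix$status == "censored"))
  expect_equal(fraction_exceeding(rep, "fe2_dissolved", 43), 0)
})

test_that("raising a limit never increases the exceeding fraction", {
  set.seed(31)
  ports <- seq(0.1, 0.9, by = 0.1)
  tab <- data.frame(column_id = "T1", treatment = "biotic", day = 43,
                    distance_m = ports, analyte = "fe2_dissolved",
                    value = rlnorm(9, log(0.3), 1),
                    censored = FALSE, detection_limit = 0.03)
  limits <- c(0.05, 0.1, 0.3, 1, 5)
  fr <- vapply(limits, function(l) {
    fraction_exceeding(exceedance_matrix(tab, threshold_set(fe2_dissolved = l)),
                       "fe2_dissolved", 43)
  }, numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("row order does not affect any output", {
  tab <- eighteen_point_fixture()
  set.seed(5)
  shuffled <- tab[sample(nrow(tab)), ]
  a <- exceedance_matrix(tab)
  b <- exceedance_matrix(shuffled)
  expect_equal(a$matrix, b$matrix)
  expect_equal(a$fraction_overall, b$fraction_overall)
  expect_equal(a$max_extent, b$max_extent)
})

test_that("pooled and per-column fractions agree when recombined", {
  tab <- eighteen_point_fixture()
  rep <- exceedance_matrix(tab)
  per_col <- rep$fraction_by_column
  per_col <- per_col[per_col$analyte == "fe2_dissolved" & per_col$day == 43, ]
  pooled <- sum(per_col$n_exceed) / sum(per_col$n_points) * 100
  expect_equal(pooled, fraction_exceeding(rep, "fe2_dissolved", 43))
})

test_that("an analyte without a threshold is an explicit error", {
  tab <- eighteen_point_fixture()
  expect_error(exceedance_matrix(tab, structure(c(toluene = 700),
                                               class = "threshold_set")),
               "fe2_dissolved")
  expect_error(threshold_set(toluene = -5), "> 0")
})

test_that("a growing synthetic plume has non-decreasing extent", {
  ports <- seq(0.1, 0.9, by = 0.1)
  rows <- do.call(rbind, lapply(1:9, function(d) {
    data.frame(column_id = "T1", treatment = "biotic", day = d * 5,
               distance_m = ports, analyte = "fe2_dissolved",
               value = ifelse(ports <= d * 0.1, 1, 0.05),
               censored = FALSE, detection_limit = 0.03)
  }))
  pm <- plume_metrics(exceedance_matrix(rows), "fe2_dissolved")
  expect_true(all(diff(pm$max_extent$max_extent_m) >= 0))
  expect_equal(pm$first_exceed_day$first_exceed_day, ports * 50)
})
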