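MONITORING_SCHEMA <- "fecolumn monitoring table v1"
PROFILE_SCHEMA <- "fecolumn solid Fe(II) profile v1"
ANALYTES <- c("toluene", "fe2_dissolved")
ANALYTE_UNITS <- c(toluene = "ug/L", fe2_dissolved = "mg/L")

#' Validate a long-format monitoring table
#'
#' Enforces the monitoring data contract: required columns, known analytes
#' (toluene in ug/L, dissolved Fe2+ in mg/L), non-negative days and values,
#' port distances in (0, L], censored rows reported at their detection limit,
#' and uniqueness of (column, day, port, analyte). All violations are
#' collected and reported together, each with its row number.
#'
#' @param table A data frame.
#' @param column_length Column length, m (upper bound for port distances);
#'   \code{NULL} skips the upper-bound check.
#' @return The table, classed \code{monitoring_table}, invisibly.
#' @export
validate_monitoring_table <- function(table, column_length = NULL) {
  required <- c("column_id", "treatment", "day", "distance_m", "analyte",
                "value", "censored", "detection_limit")
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols) > 0L) {
    stop("monitoring table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  problems <- character(0)
  bad <- function(rows, msg) {
    if (length(rows) > 0L) {
      shown <- utils::head(rows, 5L)
      problems <<- c(problems, sprintf(
        "%s (row%s %s%s)", msg, if (length(rows) > 1L) "s" else "",
        paste(shown, collapse = ", "),
        if (length(rows) > length(shown)) ", ..." else ""))
    }
  }
  rows <- seq_len(nrow(table))
  bad(rows[!table$analyte %in% ANALYTES], "unknown analyte")
  bad(rows[!is.finite(table$day) | table$day < 0], "day must be >= 0")
  bad(rows[!is.finite(table$distance_m) | table$distance_m <= 0],
      "distance_m must be > 0")
  if (!is.null(column_length)) {
    bad(rows[table$distance_m > column_length + 1e-9],
        sprintf("distance_m beyond column length %g m", column_length))
  }
  bad(rows[!is.finite(table$value) | table$value < 0], "value must be >= 0")
  bad(rows[!table$treatment %in% c("biotic", "sterile")],
      "treatment must be 'biotic' or 'sterile'")
  cens <- which(as.logical(table$censored))
  off <- cens[abs(table$value[cens] - table$detection_limit[cens]) >
                1e-9 * pmax(table$detection_limit[cens], 1e-12)]
  bad(off, "censored rows must report value = detection_limit")
  key <- paste(table$column_id, table$day, table$distance_m, table$analyte, sep = "\r")
  bad(rows[duplicated(key)], "duplicate (column, day, port, analyte) key")
  if (length(problems) > 0L) {
    stop("invalid monitoring table:\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  }
  class(table) <- c("monitoring_table", "data.frame")
  invisible(table)
}

csv_header <- function(schema, extra = character(0)) {
  c(paste0("# ", schema),
    paste0("# units: ", paste(sprintf("%s=%s", names(ANALYTE_UNITS), ANALYTE_UNITS),
                              collapse = "; ")),
    extra)
}

#' Write a monitoring table to CSV
#'
#' Writes the long-format monitoring CSV with a comment header carrying the
#' schema version, the analyte units and any provenance entries (seed, config
#' hash) supplied in \code{meta}.
#'
#' @param table A validated monitoring table.
#' @param path Output path.
#' @param meta Named character vector of provenance entries for the header.
#' @return \code{path}, invisibly.
#' @export
write_monitoring_csv <- function(table, path, meta = character(0)) {
  validate_monitoring_table(table)
  hdr <- csv_header(MONITORING_SCHEMA,
                    if (length(meta) > 0L) sprintf("# %s: %s", names(meta), meta))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(table), con, row.names = FALSE)
  invisible(path)
}

#' Read a long-format monitoring CSV
#'
#' Parses and validates a monitoring CSV written by
#' \code{\link{write_monitoring_csv}} (UTF-8, comment header with schema
#' version, ISO decimal point). Any contract violation is reported with its
#' row number; all violations are collected into one error.
#'
#' @param path CSV path.
#' @param column_length Optional column length, m, for the port-range check.
#' @return A \code{monitoring_table} data frame.
#' @export
read_monitoring_csv <- function(path, column_length = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!grepl(MONITORING_SCHEMA, first, fixed = TRUE)) {
    stop("not a monitoring CSV (expected header '# ", MONITORING_SCHEMA, "')",
         call. = FALSE)
  }
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  tab$censored <- as.logical(tab$censored)
  validate_monitoring_table(tab, column_length = column_length)
  class(tab) <- c("monitoring_table", "data.frame")
  tab
}

#' Write a solid-phase Fe(II) profile to CSV
#'
#' @param profile A \code{\link{solid_fe_profile}}.
#' @param path Output path.
#' @param meta Named character vector of provenance header entries.
#' @return \code{path}, invisibly.
#' @export
write_solid_fe_csv <- function(profile, path, meta = character(0)) {
  hdr <- c(paste0("# ", PROFILE_SCHEMA),
           "# units: distance_m=m; fe2_mg_per_kg=mg Fe(II) per kg dry medium",
           if (length(meta) > 0L) sprintf("# %s: %s", names(meta), meta))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(as.data.frame(profile), con, row.names = FALSE)
  invisible(path)
}

#' Read a solid-phase Fe(II) profile CSV
#'
#' Requires the units header line: solid-profile axis units are the classic
#' ambiguity of published data, so files that do not declare
#' \code{fe2_mg_per_kg} units are rejected.
#'
#' @param path CSV path.
#' @return A \code{\link{solid_fe_profile}}.
#' @export
read_solid_fe_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  head_lines <- readLines(path, n = 5L, warn = FALSE)
  if (!any(grepl("fe2_mg_per_kg=mg", head_lines, fixed = TRUE))) {
    stop("solid profile CSV must declare units ('# units: ... fe2_mg_per_kg=mg ...')",
         call. = FALSE)
  }
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("distance_m", "fe2_mg_per_kg")
  if (!all(need %in% names(tab))) {
    stop("solid profile CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  solid_fe_profile(tab$distance_m, tab$fe2_mg_per_kg,
                   column_id = if ("column_id" %in% names(tab)) tab$column_id[1L] else "T1",
                   day = if ("day" %in% names(tab)) tab$day[1L] else NA_real_)
}

#' Read a pipeline configuration file
#'
#' YAML with sections \code{column} (overrides of \code{\link{column_spec}}
#' fields), \code{scenario} (\code{treatment_ids}, \code{control_ids},
#' \code{overrides} of \code{\link{simulation_config}} fields),
#' \code{quantify} (\code{method}, \code{censored_policy},
#' \code{late_window}), \code{exceedance} (analyte limits) and \code{seed}.
#' Missing sections fall back to package defaults.
#'
#' @param path YAML file path.
#' @return A named list (the parsed configuration).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping", call. = FALSE)
  cfg
}

# Stable short hash of a configuration list (for output provenance headers).
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(substr(tools::md5sum(tmp), 1L, 12L))
}
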