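#' Physical specification of a flow-through column
#'
#' Bundles the geometry and medium properties of a laboratory aquifer column
#' from which all hydraulic quantities derive. Defaults describe a 100 cm x
#' 7 cm i.d. transparent column packed with quartz sand amended with 2.5%
#' ferric hydroxide, with nine sampling ports at 10 cm spacing, operated under
#' a hydraulic gradient of 0.002 -- conditions representative of an iron-rich
#' sandy aquifer.
#'
#' @param length Column length, m.
#' @param inner_diameter Inner diameter, m.
#' @param porosity Total porosity (dimensionless, in (0, 1)).
#' @param effective_porosity Effective (flow-connected) porosity; must not
#'   exceed \code{porosity}.
#' @param hydraulic_conductivity Permeability coefficient K, m/day.
#' @param hydraulic_gradient Dimensionless head gradient i.
#' @param fe_hydroxide_mass_fraction Mass fraction of ferric hydroxide in the
#'   dry packing (dimensionless; 0.025 = 2.5%).
#' @param grain_density Solid grain density, g/cm3 (quartz default 2.65).
#' @param n_ports Number of side sampling ports.
#' @param port_spacing Distance between ports (and from inlet to first port), m.
#'
#' @return An object of class \code{column_spec} (a named list).
#' @examples
#' spec <- column_spec()
#' column_hydraulics(spec)
#' @export
column_spec <- function(length = 1.0,
                        inner_diameter = 0.07,
                        porosity = 0.30,
                        effective_porosity = 0.25,
                        hydraulic_conductivity = 10,
                        hydraulic_gradient = 0.002,
                        fe_hydroxide_mass_fraction = 0.025,
                        grain_density = 2.65,
                        n_ports = 9L,
                        port_spacing = 0.1) {
  spec <- list(
    length = length,
    inner_diameter = inner_diameter,
    porosity = porosity,
    effective_porosity = effective_porosity,
    hydraulic_conductivity = hydraulic_conductivity,
    hydraulic_gradient = hydraulic_gradient,
    fe_hydroxide_mass_fraction = fe_hydroxide_mass_fraction,
    grain_density = grain_density,
    n_ports = as.integer(n_ports),
    port_spacing = port_spacing
  )
  class(spec) <- "column_spec"
  validate_column_spec(spec)
  spec
}

#' Validate a column specification
#'
#' Checks every invariant of a \code{\link{column_spec}} and stops with a
#' message naming each offending field; all violations are collected and
#' reported together.
#'
#' @param spec A \code{column_spec}.
#' @return The spec, invisibly, if valid.
#' @export
validate_column_spec <- function(spec) {
  problems <- character(0)
  num_fields <- c("length", "inner_diameter", "porosity", "effective_porosity",
                  "hydraulic_conductivity", "hydraulic_gradient",
                  "fe_hydroxide_mass_fraction", "grain_density", "port_spacing")
  for (f in num_fields) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      problems <- c(problems, sprintf("field '%s' must be a finite number", f))
    }
  }
  if (length(problems) == 0L) {
    pos_fields <- c("length", "inner_diameter", "hydraulic_conductivity",
                    "hydraulic_gradient", "grain_density", "port_spacing")
    for (f in pos_fields) {
      if (spec[[f]] <= 0) {
        problems <- c(problems, sprintf("field '%s' must be > 0 (got %g)", f, spec[[f]]))
      }
    }
    if (!(spec$porosity > 0 && spec$porosity < 1)) {
      problems <- c(problems, sprintf("field 'porosity' must lie in (0, 1) (got %g)", spec$porosity))
    }
    if (!(spec$effective_porosity > 0 && spec$effective_porosity <= spec$porosity)) {
      problems <- c(problems, sprintf(
        "field 'effective_porosity' must satisfy 0 < effective_porosity <= porosity (got %g vs porosity %g)",
        spec$effective_porosity, spec$porosity))
    }
    if (spec$fe_hydroxide_mass_fraction < 0 || spec$fe_hydroxide_mass_fraction >= 1) {
      problems <- c(problems, sprintf(
        "field 'fe_hydroxide_mass_fraction' must lie in [0, 1) (got %g)",
        spec$fe_hydroxide_mass_fraction))
    }
    if (!is.numeric(spec$n_ports) || spec$n_ports < 1L) {
      problems <- c(problems, "field 'n_ports' must be a positive integer")
    } else if (spec$n_ports * spec$port_spacing > spec$length + 1e-12) {
      problems <- c(problems, sprintf(
        "field 'n_ports'/'port_spacing': farthest port at %g m lies beyond column length %g m",
        spec$n_ports * spec$port_spacing, spec$length))
    }
  }
  if (length(problems) > 0L) {
    stop("invalid column_spec:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  invisible(spec)
}

#' Port positions of a column
#'
#' @param spec A \code{\link{column_spec}}.
#' @return Numeric vector of port distances from the inlet, m.
#' @export
port_positions <- function(spec) {
  spec$port_spacing * seq_len(spec$n_ports)
}

#' @export
print.column_spec <- function(x, ...) {
  cat("Column specification\n")
  cat(sprintf("  length x i.d.      : %.2f m x %.3f m\n", x$length, x$inner_diameter))
  cat(sprintf("  porosity (total/eff): %.2f / %.2f\n", x$porosity, x$effective_porosity))
  cat(sprintf("  K, i               : %.3g m/d, %.4g\n",
              x$hydraulic_conductivity, x$hydraulic_gradient))
  cat(sprintf("  Fe(OH)3 fraction   : %.1f%%\n", 100 * x$fe_hydroxide_mass_fraction))
  cat(sprintf("  ports              : %d at %.2f m spacing\n", x$n_ports, x$port_spacing))
  invisible(x)
}
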