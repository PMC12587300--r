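#' Design hydraulics of a flow-through column
#'
#' Derives the steady hydraulic quantities of a column experiment from its
#' physical specification: Darcy flux \eqn{q = K i}, seepage (pore) velocity
#' \eqn{v = K i / n_e}, theoretical hydraulic retention time
#' \eqn{HRT = L n_e / (K i)}, volumetric pumping rate \eqn{Q = K i A},
#' total pore volume \eqn{A L n} and dry bulk density
#' \eqn{\rho_b = \rho_s (1 - n)}.
#'
#' The retention time uses the effective porosity and the full column length;
#' with the default specification (L = 1 m, \eqn{n_e} = 0.25, K = 10 m/d,
#' i = 0.002) this gives 12.5 days and a pumping rate of about 0.05 mL/min.
#'
#' @param spec A \code{\link{column_spec}}; validated before use.
#' @return An object of class \code{hydraulics_result}: a named list with
#'   \code{darcy_flux} (m/day), \code{seepage_velocity} (m/day),
#'   \code{retention_time} (days), \code{pumping_rate} (mL/min),
#'   \code{cross_section_area} (m2), \code{pore_volume} (mL) and
#'   \code{bulk_density} (g/cm3).
#' @examples
#' h <- column_hydraulics(column_spec())
#' h$retention_time # 12.5 days
#' @export
column_hydraulics <- function(spec) {
  validate_column_spec(spec)
  area <- pi * spec$inner_diameter^2 / 4                  # m2
  q <- spec$hydraulic_conductivity * spec$hydraulic_gradient  # m/day
  v <- q / spec$effective_porosity                         # m/day
  hrt <- spec$length / v                                   # days
  q_vol_m3_day <- q * area                                 # m3/day
  pumping_rate <- q_vol_m3_day * 1e6 / (24 * 60)           # mL/min
  pore_volume <- area * spec$length * spec$porosity * 1e6  # mL
  bulk_density <- spec$grain_density * (1 - spec$porosity) # g/cm3
  out <- list(
    darcy_flux = q,
    seepage_velocity = v,
    retention_time = hrt,
    pumping_rate = pumping_rate,
    cross_section_area = area,
    pore_volume = pore_volume,
    bulk_density = bulk_density
  )
  class(out) <- "hydraulics_result"
  out
}

#' @export
print.hydraulics_result <- function(x, ...) {
  cat("Column hydraulics\n")
  cat(sprintf("  Darcy flux        : %.4g m/day\n", x$darcy_flux))
  cat(sprintf("  seepage velocity  : %.4g m/day\n", x$seepage_velocity))
  cat(sprintf("  retention time    : %.4g days\n", x$retention_time))
  cat(sprintf("  pumping rate      : %.4g mL/min\n", x$pumping_rate))
  cat(sprintf("  cross-section area: %.4g m2\n", x$cross_section_area))
  cat(sprintf("  pore volume       : %.4g mL\n", x$pore_volume))
  cat(sprintf("  bulk density      : %.4g g/cm3\n", x$bulk_density))
  invisible(x)
}

#' @export
as.data.frame.hydraulics_result <- function(x, ...) {
  data.frame(quantity = names(unclass(x)),
             value = unlist(unclass(x), use.names = FALSE),
             unit = c("m/day", "m/day", "days", "mL/min", "m2", "mL", "g/cm3"),
             stringsAsFactors = FALSE)
}
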