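#' Groundwater quality threshold set
#'
#' Regulatory limits against which monitoring observations are classified.
#' Defaults are the GB14848 class-III limits relevant here: 700 ug/L for
#' toluene and 0.3 mg/L for (dissolved) iron, in the same units as the
#' monitoring table carries each analyte.
#'
#' @param toluene Limit for toluene, ug/L.
#' @param fe2_dissolved Limit for dissolved iron, mg/L.
#' @param ... Further named analyte limits.
#' @return Named numeric vector of class \code{threshold_set}.
#' @export
threshold_set <- function(toluene = 700, fe2_dissolved = 0.3, ...) {
  out <- c(toluene = toluene, fe2_dissolved = fe2_dissolved, ...)
  if (any(!is.finite(out)) || any(out <= 0)) {
    stop("threshold limits must be finite and > 0", call. = FALSE)
  }
  class(out) <- "threshold_set"
  out
}

#' Classify a monitoring table against threshold values
#'
#' Labels every (column, day, port, analyte) observation as \code{"exceed"}
#' (value at or above the limit), \code{"comply"}, or \code{"censored"}
#' (below detection, hence below both limits; never counted as exceeding),
#' and derives the summary metrics of a plume audit: the fraction of
#' monitoring points exceeding (per analyte, day and column, and pooled
#' across columns per day), the farthest exceeding port per day, and the
#' first exceedance day per port. "Monitoring points" in the pooled summary
#' are (column, port) pairs at a fixed day.
#'
#' Equality with the limit counts as exceeding. Raising a limit can never
#' increase the exceeding fraction, and the classification is invariant to
#' row order.
#'
#' @param table A \code{monitoring_table} (validated shape).
#' @param thresholds A \code{\link{threshold_set}}; every analyte present in
#'   the table must have a limit (an unknown analyte is an error, not a
#'   silent skip).
#' @return An object of class \code{exceedance_report}: list with
#'   \code{matrix} (long classification), \code{fraction_by_column},
#'   \code{fraction_overall} (percent), \code{max_extent} (m, per analyte and
#'   day), \code{first_exceed_day} (per column, analyte, port) and
#'   \code{thresholds}.
#' @export
exceedance_matrix <- function(table, thresholds = threshold_set()) {
  tab <- as.data.frame(table)
  need <- c("column_id", "day", "distance_m", "analyte", "value", "censored")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L) {
    stop("monitoring table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(tab$analyte), names(thresholds))
  if (length(unknown) > 0L) {
    stop("no threshold for analyte(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  tab <- tab[order(tab$analyte, tab$column_id, tab$day, tab$distance_m), , drop = FALSE]
  lim <- unname(unclass(thresholds)[tab$analyte])
  status <- ifelse(tab$censored, "censored",
                   ifelse(tab$value >= lim, "exceed", "comply"))
  mat <- data.frame(column_id = tab$column_id, day = tab$day,
                    distance_m = tab$distance_m, analyte = tab$analyte,
                    value = tab$value, limit = lim, status = status,
                    stringsAsFactors = FALSE)
  rownames(mat) <- NULL

  agg_frac <- function(df, by) {
    n_ex <- stats::aggregate(df$status == "exceed", by = by, FUN = sum)
    n_all <- stats::aggregate(rep(1L, nrow(df)), by = by, FUN = sum)
    out <- n_ex
    names(out)[ncol(out)] <- "n_exceed"
    out$n_points <- n_all$x
    out$fraction_pct <- 100 * out$n_exceed / out$n_points
    out
  }
  frac_col <- agg_frac(mat, list(analyte = mat$analyte, column_id = mat$column_id,
                                 day = mat$day))
  frac_all <- agg_frac(mat, list(analyte = mat$analyte, day = mat$day))

  ex <- mat[mat$status == "exceed", , drop = FALSE]
  max_extent <- if (nrow(ex) > 0L) {
    me <- stats::aggregate(ex$distance_m, by = list(analyte = ex$analyte, day = ex$day),
                           FUN = max)
    names(me)[ncol(me)] <- "max_extent_m"
    me[order(me$analyte, me$day), , drop = FALSE]
  } else {
    data.frame(analyte = character(0), day = numeric(0), max_extent_m = numeric(0))
  }
  first_day <- if (nrow(ex) > 0L) {
    fd <- stats::aggregate(ex$day,
                           by = list(analyte = ex$analyte, column_id = ex$column_id,
                                     distance_m = ex$distance_m),
                           FUN = min)
    names(fd)[ncol(fd)] <- "first_exceed_day"
    fd[order(fd$analyte, fd$column_id, fd$distance_m), , drop = FALSE]
  } else {
    data.frame(analyte = character(0), column_id = character(0),
               distance_m = numeric(0), first_exceed_day = numeric(0))
  }

  out <- list(matrix = mat,
              fraction_by_column = frac_col[order(frac_col$analyte, frac_col$column_id,
                                                  frac_col$day), , drop = FALSE],
              fraction_overall = frac_all[order(frac_all$analyte, frac_all$day), ,
                                          drop = FALSE],
              max_extent = max_extent,
              first_exceed_day = first_day,
              thresholds = thresholds)
  class(out) <- "exceedance_report"
  out
}

#' Pooled exceeding fraction at one day
#'
#' The abstract-style summary: of all (column, port) monitoring points of one
#' analyte at a fixed day, the percentage at or above the threshold.
#'
#' @param report An \code{\link{exceedance_matrix}} result.
#' @param analyte Analyte name.
#' @param day Sampling day.
#' @return Percentage in [0, 100].
#' @export
fraction_exceeding <- function(report, analyte, day) {
  f <- report$fraction_overall
  row <- f[f$analyte == analyte & abs(f$day - day) < 1e-9, , drop = FALSE]
  if (nrow(row) == 0L) {
    stop(sprintf("no observations for analyte '%s' at day %g", analyte, day),
         call. = FALSE)
  }
  row$fraction_pct
}

#' Plume extent and first-arrival metrics
#'
#' @param report An \code{\link{exceedance_matrix}} result.
#' @param analyte Analyte to extract.
#' @return List with \code{max_extent} (data frame day, max_extent_m: the
#'   farthest exceeding port per day, pooled over columns) and
#'   \code{first_exceed_day} (per column and port). Both are empty (zero-row)
#'   when nothing exceeds.
#' @export
plume_metrics <- function(report, analyte) {
  me <- report$max_extent
  me <- me[me$analyte == analyte, c("day", "max_extent_m"), drop = FALSE]
  rownames(me) <- NULL
  fd <- report$first_exceed_day
  fd <- fd[fd$analyte == analyte,
           c("column_id", "distance_m", "first_exceed_day"), drop = FALSE]
  rownames(fd) <- NULL
  list(max_extent = me, first_exceed_day = fd)
}

#' @export
print.exceedance_report <- function(x, ...) {
  cat("Threshold exceedance report\n")
  cat(sprintf("  observations: %d (%d exceed, %d comply, %d censored)\n",
              nrow(x$matrix), sum(x$matrix$status == "exceed"),
              sum(x$matrix$status == "comply"), sum(x$matrix$status == "censored")))
  for (a in unique(x$matrix$analyte)) {
    f <- x$fraction_overall
    f <- f[f$analyte == a, , drop = FALSE]
    last <- f[which.max(f$day), , drop = FALSE]
    cat(sprintf("  %s (limit %g): %.0f%% of points exceed at day %g\n",
                a, unclass(x$thresholds)[[a]], last$fraction_pct, last$day))
  }
  invisible(x)
}
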