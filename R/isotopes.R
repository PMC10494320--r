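# Pedogenic-carbonate stable isotopes and the paleo-shade woody-cover proxy.

#' Summary statistics for an isotope or composition column
#'
#' Mean, sample standard deviation (n-1 denominator), minimum, maximum and
#' range, after dropping missing values (the number dropped is reported).
#'
#' @param values Numeric vector (per-mil or percent).
#' @return List of class `isotope_summary`: `n`, `n_missing`, `mean`, `sd`,
#'   `min`, `max`, `range`.
#' @examples
#' summarize_isotopes(c(-6.8, -9.1, -7.7))
#' @export
summarize_isotopes <- function(values) {
  n_missing <- sum(is.na(values))
  v <- values[!is.na(values)]
  if (length(v) == 0L) stop_invalid("no non-missing values to summarize")
  structure(list(
    n = length(v), n_missing = n_missing,
    mean = mean(v),
    sd = if (length(v) >= 2L) stats::sd(v) else NA_real_,
    min = min(v), max = max(v), range = max(v) - min(v)),
    class = "isotope_summary")
}

#' @export
print.isotope_summary <- function(x, ...) {
  cat(sprintf("n = %d (missing %d): mean %.2f +/- %.2f, range [%.2f, %.2f]\n",
              x$n, x$n_missing, x$mean, x$sd, x$min, x$max))
  invisible(x)
}

#' Squared Pearson correlation
#'
#' @param x,y Numeric vectors of equal length, n >= 3 after pairwise removal
#'   of missing values.
#' @return R-squared, in [0, 1].
#' @export
correlation_r2 <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop_invalid("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_invalid("undefined correlation: zero variance in x or y")
  stats::cor(x, y)^2
}

#' Woody-cover fraction from pedogenic-carbonate delta-13C (paleo-shade proxy)
#'
#' Carbonate delta-13C is first converted to an organic-matter value by
#' subtracting the carbonate--organic enrichment, then mapped to fraction of
#' woody canopy cover with the empirical sine-squared paleo-shade function
#' \eqn{f = \sin^2(-1.06688 - 0.08538\,\delta^{13}C_{om})}, clipped to
#' \[0, 1\].  Soil carbonate forms enriched relative to soil-respired CO2;
#' the documented enrichment range is 13.5--17.0 per mil and the default is
#' its midpoint.
#'
#' @param d13c_carbonate Carbonate delta-13C (per mil, VPDB); vectorized.
#' @param enrichment Carbonate--organic enrichment in per mil (default 15.25).
#'   Values outside \[13.5, 17.0\] trigger a warning, not an error.
#' @return Woody-cover fraction(s) in \[0, 1\].
#' @examples
#' woody_cover(-7.3)          # 0.573: at least 50% woody cover
#' woody_cover(-7.3, 13.5)    # low end of the enrichment range
#' @export
woody_cover <- function(d13c_carbonate, enrichment = 15.25) {
  check_number(enrichment, "enrichment")
  if (enrichment < 13.5 || enrichment > 17.0)
    warning("enrichment outside the documented 13.5-17.0 per-mil range",
            call. = FALSE)
  d13c_om <- d13c_carbonate - enrichment
  f <- sin(-1.06688 - 0.08538 * d13c_om)^2
  pmin(pmax(f, 0), 1)
}

#' Stratigraphic trend test
#'
#' Ordinary least-squares regression of a measured column on stratigraphic
#' height, with the two-sided t-test p-value of the slope.  Detects (or
#' fails to detect) up-section drift in an isotope record.
#'
#' @param samples Data frame with a `height_cm` column.
#' @param column Name of the value column (e.g. `"d13c_vpdb"`).
#' @return List: `slope` (per cm), `se`, `p_value`, `n`.
#' @export
stratigraphic_trend <- function(samples, column) {
  if (!"height_cm" %in% names(samples)) stop_invalid("missing height_cm column")
  if (!column %in% names(samples)) stop_invalid("no column '", column, "'")
  h <- samples$height_cm; v <- samples[[column]]
  ok <- !is.na(h) & !is.na(v)
  h <- h[ok]; v <- v[ok]
  if (length(h) < 3L) stop_invalid("need at least 3 complete rows")
  if (length(unique(h)) < 2L) stop_invalid("all heights equal")
  fit <- stats::lm(v ~ h)
  cf <- summary(fit)$coefficients
  list(slope = cf["h", "Estimate"], se = cf["h", "Std. Error"],
       p_value = cf["h", "Pr(>|t|)"], n = length(h))
}

#' Summarize a pedogenic-carbonate table
#'
#' Convenience wrapper producing the headline numbers of a carbonate stable
#' isotope study: per-column summaries, the delta-13C/delta-18O R-squared,
#' and the woody-cover inference from mean delta-13C.
#'
#' @param table Data frame in the layout of [mazamba_carbonates()].
#' @param enrichment Passed to [woody_cover()].
#' @return List with `d13c`, `d18o`, `carbonate_pct` summaries, `r2`,
#'   `woody_cover`, and trend tests `trend_d13c`, `trend_d18o`.
#' @export
carbonate_report <- function(table, enrichment = 15.25) {
  list(d13c = summarize_isotopes(table$d13c_vpdb),
       d18o = summarize_isotopes(table$d18o_vsmow),
       carbonate_pct = summarize_isotopes(table$carbonate_pct),
       r2 = correlation_r2(table$d13c_vpdb, table$d18o_vsmow),
       woody_cover = woody_cover(mean(table$d13c_vpdb, na.rm = TRUE),
                                 enrichment),
       trend_d13c = stratigraphic_trend(table, "d13c_vpdb"),
       trend_d18o = stratigraphic_trend(table, "d18o_vsmow"))
}

#' Packaged pedogenic-carbonate table (section GPL-1NE)
#'
#' Seventeen pedogenic carbonate nodules with stratigraphic height above the
#' section base (cm), delta-13C (per mil, VPDB), delta-18O (per mil, VSMOW),
#' reacted powder mass (micrograms) and carbonate content (percent).
#'
#' @return Data frame with columns `sample_id`, `height_cm`, `d13c_vpdb`,
#'   `d18o_vsmow`, `powder_mass_ug`, `carbonate_pct`.
#' @export
mazamba_carbonates <- function() {
  utils::read.csv(pk_extdata("mazamba_carbonates.csv"), stringsAsFactors = FALSE)
}
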