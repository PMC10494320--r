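#' @keywords internal
"_PACKAGE"

# shared input checks -------------------------------------------------------

stop_invalid <- function(...) {
  stop(paste0(...), call. = FALSE)
}

check_number <- function(x, name, positive = FALSE, nonneg = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_invalid(name, " must be a single non-missing number")
  if (finite && !is.finite(x)) stop_invalid(name, " must be finite")
  if (positive && x <= 0) stop_invalid(name, " must be > 0")
  if (nonneg && x < 0) stop_invalid(name, " must be >= 0")
  invisible(x)
}

#' Path to a packaged plain-text fixture
#'
#' @param file File name under `extdata`.
#' @return Absolute path to the installed fixture.
#' @keywords internal
pk_extdata <- function(file) {
  p <- system.file("extdata", file, package = "paleokit", mustWork = TRUE)
  p
}
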