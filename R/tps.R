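# TPS and long-format CSV landmark file I/O.

#' Read a TPS landmark file
#'
#' Supports `LM=`/`LM3=` records with whitespace-separated coordinate rows
#' and optional `ID=` and `SCALE=` keys.  Coordinates are multiplied by the
#' scale when present.
#'
#' @param path TPS file path.
#' @return List of configurations, each a list with `points` (k x 2 or
#'   k x 3 matrix), `id`, `scale`.
#' @export
read_tps <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    m <- regmatches(lines[i], regexec("^LM(3?)=([0-9]+)$", lines[i],
                                      ignore.case = TRUE))[[1]]
    if (length(m) == 0L)
      stop_invalid("TPS parse error at line ", i, ": expected LM= record")
    d <- if (m[2] == "3" || tolower(m[2]) == "3") 3L else 2L
    k <- as.integer(m[3])
    if (i + k > length(lines)) stop_invalid("TPS record truncated at line ", i)
    pts <- t(vapply(lines[(i + 1L):(i + k)], function(s)
      as.numeric(strsplit(s, "\\s+")[[1]])[seq_len(d)], numeric(d)))
    dimnames(pts) <- NULL
    i <- i + k + 1L
    id <- NA_character_; scale <- 1
    while (i <= length(lines) &&
           !grepl("^LM3?=", lines[i], ignore.case = TRUE)) {
      kv <- strsplit(lines[i], "=", fixed = TRUE)[[1]]
      key <- toupper(trimws(kv[1]))
      if (key == "ID") id <- trimws(kv[2])
      if (key == "SCALE") scale <- as.numeric(kv[2])
      i <- i + 1L
    }
    out[[length(out) + 1L]] <- list(points = pts * scale, id = id,
                                    scale = scale)
  }
  out
}

#' Write configurations to a TPS file
#'
#' @param configs List of configurations as returned by [read_tps()], or a
#'   list of bare coordinate matrices.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(configs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (j in seq_along(configs)) {
    cf <- configs[[j]]
    pts <- if (is.list(cf)) cf$points else cf
    id <- if (is.list(cf) && !is.na(cf$id %||% NA)) cf$id else
      sprintf("spec%03d", j)
    tag <- if (ncol(pts) == 3L) "LM3" else "LM"
    writeLines(sprintf("%s=%d", tag, nrow(pts)), con)
    utils::write.table(format(pts, digits = 12, trim = TRUE, scientific = FALSE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    writeLines(sprintf("ID=%s", id), con)
  }
  invisible(path)
}

#' Read landmarks from a long-format CSV
#'
#' Expected columns: `specimen_id`, `curve`, `index`, `x`, `y`, optional
#' `z`, optional `fixed` (0/1).
#'
#' @param path CSV path.
#' @return List: `configs` (named list of coordinate matrices, rows ordered
#'   by `index`) and `scheme` (a [semilandmark_scheme()] built from the
#'   `curve`/`fixed` columns of the first specimen, or `NULL` when there is
#'   a single unnamed curve).
#' @export
read_landmark_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("specimen_id", "curve", "index", "x", "y")
  if (!all(need %in% names(d)))
    stop_invalid("landmark CSV must have columns ", paste(need, collapse = ", "))
  has_z <- "z" %in% names(d)
  configs <- lapply(split(d, d$specimen_id), function(s) {
    s <- s[order(s$index), ]
    m <- as.matrix(s[, c("x", "y", if (has_z) "z")])
    rownames(m) <- NULL
    m
  })
  first <- d[d$specimen_id == d$specimen_id[1], ]
  first <- first[order(first$index), ]
  scheme <- NULL
  if (length(unique(first$curve)) >= 1L && !all(is.na(first$curve))) {
    curves <- lapply(split(first$index, first$curve), sort)
    curves <- curves[order(vapply(curves, min, 0))]
    fixed <- if ("fixed" %in% names(first))
      first$index[first$fixed != 0] else NULL
    scheme <- semilandmark_scheme(unname(curves), fixed)
  }
  list(configs = configs, scheme = scheme)
}
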