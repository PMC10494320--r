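# Generalized Procrustes analysis and sliding semilandmarks.

# optimal rotation (no reflection) carrying A onto B, both centered
.procrustes_rotation <- function(a, b) {
  s <- svd(crossprod(a, b))
  r <- s$u %*% t(s$v)
  if (det(r) < 0) {
    u <- s$u
    u[, ncol(u)] <- -u[, ncol(u)]
    r <- u %*% t(s$v)
  }
  r
}

.center_scale <- function(x) {
  x <- sweep(x, 2L, colMeans(x))
  cs <- sqrt(sum(x^2))
  if (cs == 0) stop_invalid("degenerate configuration with zero centroid size")
  list(coords = x / cs, csize = cs)
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition removing translation (centering), scale (unit
#' centroid size) and rotation (orthogonal Procrustes to the evolving
#' consensus, reflections disallowed).  Iterates until the consensus moves
#' less than `tol` (root sum of squares) or `max_iter` is reached.
#'
#' @param shapes List of k x d coordinate matrices (d = 2 or 3), or a
#'   k x d x n array; all configurations must share k.
#' @param tol Convergence tolerance on the consensus (default 1e-10).
#' @param max_iter Iteration cap (default 100).
#' @return Object of class `gpa_fit`: `coords` (k x d x n array of aligned
#'   shapes), `consensus`, `csize` (original centroid sizes), `dists`
#'   (per-shape Procrustes distance to the consensus), `iterations`.
#' @export
gpa <- function(shapes, tol = 1e-10, max_iter = 100L) {
  if (is.array(shapes) && length(dim(shapes)) == 3L)
    shapes <- lapply(seq_len(dim(shapes)[3]), function(i) shapes[, , i])
  if (!is.list(shapes) || length(shapes) < 2L)
    stop_invalid("need at least 2 configurations")
  k <- nrow(shapes[[1]]); d <- ncol(shapes[[1]])
  if (!all(vapply(shapes, nrow, 0L) == k) ||
      !all(vapply(shapes, ncol, 0L) == d))
    stop_invalid("all configurations must share the same dimensions")
  n <- length(shapes)
  cs <- lapply(shapes, .center_scale)
  x <- lapply(cs, `[[`, "coords")
  csize <- vapply(cs, `[[`, 0, "csize")
  consensus <- x[[1]]
  iter <- 0L
  repeat {
    iter <- iter + 1L
    x <- lapply(x, function(a) a %*% .procrustes_rotation(a, consensus))
    new_cons <- Reduce(`+`, x) / n
    new_cons <- .center_scale(new_cons)$coords
    delta <- sqrt(sum((new_cons - consensus)^2))
    consensus <- new_cons
    if (delta < tol || iter >= max_iter) break
  }
  coords <- array(unlist(x), dim = c(k, d, n),
                  dimnames = list(NULL, NULL, names(shapes)))
  dists <- vapply(x, function(a) sqrt(sum((a - consensus)^2)), 0)
  structure(list(coords = coords, consensus = consensus, csize = csize,
                 dists = dists, iterations = iter),
            class = "gpa_fit")
}

#' @export
print.gpa_fit <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("GPA of %d configurations (%d landmarks, %dD), %d iterations\n",
              d[3], d[1], d[2], x$iterations))
  cat(sprintf("Procrustes distances to consensus: %.4g (mean), %.4g (max)\n",
              mean(x$dists), max(x$dists)))
  invisible(x)
}

#' Procrustes sum of squares of an alignment
#'
#' @param fit A `gpa_fit`.
#' @return Sum over shapes of squared distance to the consensus.
#' @export
procrustes_ss <- function(fit) sum(fit$dists^2)

#' Fixed/sliding semilandmark scheme
#'
#' Partitions the landmarks of a configuration into curves; by default the
#' first and last landmark of each curve are fixed and interior landmarks
#' slide.
#'
#' @param curves List of integer index vectors, each ordered along its
#'   curve; curves must be disjoint and have at least 3 points.
#' @param fixed Optional extra fixed indices (merged with curve endpoints).
#' @return Object of class `semilandmark_scheme`: `curves`, `fixed`,
#'   `sliding`.
#' @export
semilandmark_scheme <- function(curves, fixed = NULL) {
  if (!is.list(curves) || length(curves) == 0L)
    stop_invalid("curves must be a non-empty list of index vectors")
  if (any(vapply(curves, length, 0L) < 3L))
    stop_invalid("every curve needs at least 3 points")
  all_idx <- unlist(curves)
  if (anyDuplicated(all_idx)) stop_invalid("curves must be disjoint")
  ends <- unlist(lapply(curves, function(cv) cv[c(1L, length(cv))]))
  fixed <- sort(unique(c(ends, fixed)))
  structure(list(curves = curves, fixed = fixed,
                 sliding = sort(setdiff(all_idx, fixed))),
            class = "semilandmark_scheme")
}

#' Slide semilandmarks by Procrustes-distance minimization
#'
#' Iteratively removes arbitrary along-curve spacing: each sliding landmark
#' moves along its local tangent (central finite difference along the
#' curve's index order) by the tangential component of its deviation from
#' the consensus, after which the sample is re-superimposed.  The total
#' Procrustes sum of squares is non-increasing across outer iterations; the
#' loop stops at relative improvement below `tol`, at `max_iter`, or
#' immediately before any objective increase (the previous state is kept).
#'
#' @param fit A [gpa()] result.
#' @param scheme A [semilandmark_scheme()] consistent with the landmarks.
#' @param max_iter Outer iteration cap (default 20).
#' @param tol Relative-improvement stop (default 1e-8).
#' @return A `gpa_fit` with an extra element `objective`, the Procrustes
#'   sum of squares after each outer iteration (starting value first).
#' @export
slide_semilandmarks <- function(fit, scheme, max_iter = 20L, tol = 1e-8) {
  stopifnot(inherits(fit, "gpa_fit"), inherits(scheme, "semilandmark_scheme"))
  k <- dim(fit$coords)[1]
  if (max(unlist(scheme$curves)) > k)
    stop_invalid("scheme indexes landmarks beyond the configuration")
  obj <- procrustes_ss(fit)
  trace <- obj
  for (it in seq_len(max_iter)) {
    n <- dim(fit$coords)[3]
    shapes <- lapply(seq_len(n), function(i) fit$coords[, , i])
    cons <- fit$consensus
    moved <- 0
    for (i in seq_len(n)) {
      s <- shapes[[i]]
      for (cv in scheme$curves) {
        m <- length(cv)
        for (jj in seq_len(m)) {
          idx <- cv[jj]
          if (idx %in% scheme$fixed) next
          tangent <- s[cv[min(jj + 1L, m)], ] - s[cv[max(jj - 1L, 1L)], ]
          nt <- sqrt(sum(tangent^2))
          if (nt == 0) next
          tangent <- tangent / nt
          step <- tangent * sum(tangent * (cons[idx, ] - s[idx, ]))
          moved <- max(moved, max(abs(step)))
          s[idx, ] <- s[idx, ] + step
        }
      }
      shapes[[i]] <- s
    }
    if (moved < 1e-12) break         # nothing to slide: exact no-op
    new_fit <- gpa(shapes)
    new_obj <- procrustes_ss(new_fit)
    if (new_obj > obj) break                  # keep the previous state
    improved <- (obj - new_obj) / max(obj, .Machine$double.eps)
    fit <- new_fit
    obj <- new_obj
    trace <- c(trace, obj)
    if (improved < tol) break
  }
  fit$objective <- trace
  fit
}
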