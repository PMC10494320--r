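# Elliptical Fourier transform of closed outlines (Kuhl-Giardina
# formulation, arc-length parameterization).

#' Elliptical Fourier transform of a closed outline
#'
#' Decomposes a closed polygon into per-harmonic coefficient quadruples
#' (a_n, b_n, c_n, d_n) plus the offset terms (A0, C0), using the chord
#' (arc-length) parameterization.  The outline's starting point and
#' orientation affect the coefficients and are fixed upstream by
#' [trace_outline()].
#'
#' @param outline k x 2 coordinate matrix, closed, first point not repeated.
#' @param n Number of harmonics; at most `floor(k/2) - 1`.
#' @return Object of class `eft_coefs`: `an`, `bn`, `cn`, `dn` (length n),
#'   `a0`, `c0`, `n_harmonics`, `perimeter`.
#' @export
eft <- function(outline, n = 10L) {
  k <- nrow(outline)
  if (k < 8L) stop_invalid("outline must have at least 8 points")
  if (n < 1L || n > floor(k / 2) - 1L)
    stop_invalid("n must lie in [1, floor(k/2) - 1] = [1, ", floor(k / 2) - 1L,
                 "]")
  p <- rbind(outline, outline[1L, ])
  dxy <- diff(p)
  dt <- sqrt(rowSums(dxy^2))
  keep <- dt > 0
  dxy <- dxy[keep, , drop = FALSE]
  dt <- dt[keep]
  t1 <- cumsum(dt)
  t0 <- c(0, t1[-length(t1)])
  bigt <- t1[length(t1)]
  dx <- dxy[, 1L]; dy <- dxy[, 2L]
  an <- bn <- cn <- dn <- numeric(n)
  for (h in seq_len(n)) {
    w <- 2 * pi * h / bigt
    const <- bigt / (2 * pi^2 * h^2)
    cosd <- cos(w * t1) - cos(w * t0)
    sind <- sin(w * t1) - sin(w * t0)
    an[h] <- const * sum(dx / dt * cosd)
    bn[h] <- const * sum(dx / dt * sind)
    cn[h] <- const * sum(dy / dt * cosd)
    dn[h] <- const * sum(dy / dt * sind)
  }
  # offset (DC) terms: mean position over the arc-length parameterization
  xi <- c(0, cumsum(dx)[-length(dx)]) - dx / dt * t0
  a0 <- unname(p[1L, 1L] +
                 sum(dx / (2 * dt) * (t1^2 - t0^2) + xi * (t1 - t0)) / bigt)
  eta <- c(0, cumsum(dy)[-length(dy)]) - dy / dt * t0
  c0 <- unname(p[1L, 2L] +
                 sum(dy / (2 * dt) * (t1^2 - t0^2) + eta * (t1 - t0)) / bigt)
  structure(list(an = an, bn = bn, cn = cn, dn = dn, a0 = a0, c0 = c0,
                 n_harmonics = n, perimeter = bigt),
            class = "eft_coefs")
}

#' Reconstruct an outline from elliptical Fourier coefficients
#'
#' Evaluates the harmonic series at k uniformly spaced parameter values.
#'
#' @param coefs An `eft_coefs` object (or a list with `an`, `bn`, `cn`,
#'   `dn`, `a0`, `c0`).
#' @param k Number of points; must satisfy `k >= 2 * n_harmonics + 2`.
#' @return k x 2 coordinate matrix.
#' @export
inverse_eft <- function(coefs, k = 100L) {
  n <- length(coefs$an)
  if (k < 2L * n + 2L) stop_invalid("k must be >= 2 * n_harmonics + 2")
  tt <- 2 * pi * (seq_len(k) - 1L) / k
  x <- rep(coefs$a0 %||% 0, k)
  y <- rep(coefs$c0 %||% 0, k)
  for (h in seq_len(n)) {
    x <- x + coefs$an[h] * cos(h * tt) + coefs$bn[h] * sin(h * tt)
    y <- y + coefs$cn[h] * cos(h * tt) + coefs$dn[h] * sin(h * tt)
  }
  cbind(x = x, y = y)
}

#' Per-harmonic power and cumulative power fractions
#'
#' Harmonic power is \eqn{P_n = (a_n^2 + b_n^2 + c_n^2 + d_n^2)/2}.
#'
#' @param coefs An `eft_coefs` object.
#' @return List: `power`, `fraction`, `cumulative` (all length n).
#' @export
harmonic_power <- function(coefs) {
  p <- (coefs$an^2 + coefs$bn^2 + coefs$cn^2 + coefs$dn^2) / 2
  tot <- sum(p)
  if (tot == 0) stop_invalid("all harmonic power is zero")
  list(power = p, fraction = p / tot, cumulative = cumsum(p) / tot)
}

#' Smallest number of harmonics reaching a cumulative power threshold
#'
#' @param coefs An `eft_coefs` object.
#' @param threshold Cumulative power fraction to exceed (default 0.99).
#' @return Integer harmonic count.
#' @export
choose_harmonics <- function(coefs, threshold = 0.99) {
  cum <- harmonic_power(coefs)$cumulative
  idx <- which(cum > threshold)
  if (length(idx) == 0L)
    stop_invalid("threshold not reached within the computed harmonics")
  idx[1L]
}

#' Flatten EFT coefficients into one feature row
#'
#' Orders coefficients as (a1..an, b1..bn, c1..cn, d1..dn); offsets are
#' dropped (position is removed by superimposition upstream).
#'
#' @param coefs An `eft_coefs` object.
#' @param n Number of harmonics to keep (default all).
#' @return Numeric vector of length 4n.
#' @export
eft_as_vector <- function(coefs, n = coefs$n_harmonics) {
  if (n > coefs$n_harmonics) stop_invalid("n exceeds available harmonics")
  c(coefs$an[seq_len(n)], coefs$bn[seq_len(n)],
    coefs$cn[seq_len(n)], coefs$dn[seq_len(n)])
}
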