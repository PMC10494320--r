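# shared fixture builders (all generated in code, no stored data)

rotmat2 <- function(a) matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2L)

# closed ellipse resampled to equal arc-length spacing
ellipse_outline <- function(rx = 3, ry = 1.5, k = 100L, n0 = 400L) {
  th <- seq(0, 2 * pi, length.out = n0 + 1L)[-(n0 + 1L)]
  resample_equidistant(cbind(rx * cos(th), ry * sin(th)), k)
}

disk_image <- function(radius = 50L, size = 2L * radius + 101L) {
  ctr <- (size + 1) / 2
  rr <- matrix(seq_len(size), size, size)
  cc <- t(rr)
  ((rr - ctr)^2 + (cc - ctr)^2 <= radius^2) * 1
}

# two outline class templates separated in coefficient space
outline_templates <- function(sep = 0.25) {
  list(
    roundish = list(an = c(2, 0.1, 0), bn = c(0, 0, 0),
                    cn = c(0, 0, 0), dn = c(1.8, 0, 0.05)),
    elongate = list(an = c(2 + sep, 0.1 + sep, 0), bn = c(0, sep / 2, 0),
                    cn = c(0, 0, sep / 2), dn = c(1.2, 0, 0.05)))
}

# default burial configuration used across tests
test_system <- function(...) nuclide_system(...)
test_site <- function() burial_site(latitude = -18.5, elevation = 160)
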