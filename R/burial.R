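# Two-nuclide (26Al/10Be) burial-duration modelling.
#
# In-situ 26Al and 10Be accumulate in quartz at the surface under a
# steady-state denudation rate eps_pre; on burial the inherited inventory
# decays (26Al about twice as fast as 10Be) while muons may keep producing at
# depth.  Inverting the measured concentration pair for (burial duration,
# pre-burial denudation) is the core operation; the "minimum" model ignores
# post-burial production (infinite burial depth), the "maximum" model keeps
# the sample at its sampling depth under steady post-burial denudation.

# Stone (2000)-type spallation scaling: latitude-banded polynomial in
# atmospheric pressure, normalized to sea level / high latitude.
.stone_coef <- data.frame(
  lat = c(0, 10, 20, 30, 40, 50, 60),
  a = c(31.8518, 34.3699, 40.3153, 42.0983, 56.7733, 69.0720, 71.8733),
  b = c(250.3193, 258.4759, 308.9894, 512.6857, 649.1343, 832.4566, 863.1927),
  c = c(-0.083393, -0.089807, -0.106248, -0.120551, -0.160859, -0.199252,
        -0.207069),
  d = c(7.4260e-5, 7.9457e-5, 9.4508e-5, 1.1752e-4, 1.5463e-4, 1.9391e-4,
        2.0127e-4),
  e = c(-2.2397e-8, -2.3697e-8, -2.8234e-8, -3.8809e-8, -5.0330e-8,
        -6.3653e-8, -6.6043e-8))

#' Spallation scaling factor for latitude and elevation
#'
#' Converts elevation to atmospheric pressure with the standard-atmosphere
#' relation, then evaluates the latitude-banded scaling polynomial for
#' neutron-induced (spallogenic) production, interpolated linearly between
#' the tabulated latitude bands and normalized so that sea level at high
#' latitude gives 1.
#'
#' @param latitude Geographic latitude in degrees (sign ignored).
#' @param elevation Elevation in metres above sea level.
#' @return Dimensionless multiplicative scaling factor.
#' @examples
#' stone_scaling(60, 0)      # ~1 (reference point)
#' stone_scaling(-18.5, 160) # low-latitude site slightly above sea level
#' @export
stone_scaling <- function(latitude, elevation) {
  check_number(latitude, "latitude")
  check_number(elevation, "elevation")
  if (abs(latitude) > 90) stop_invalid("latitude must be within [-90, 90]")
  # standard atmosphere: T0 = 288.15 K, lapse 0.0065 K/m, gM/R = 0.03417 K/m
  p <- 1013.25 * exp((-0.03417 / 0.0065) *
                       (log(288.15) - log(288.15 - 0.0065 * elevation)))
  l <- min(abs(latitude), 60)
  cf <- .stone_coef
  i <- findInterval(l, cf$lat, all.inside = TRUE)
  w <- (l - cf$lat[i]) / (cf$lat[i + 1] - cf$lat[i])
  row <- (1 - w) * cf[i, -1] + w * cf[i + 1, -1]
  with(row, a + b * exp(-p / 150) + c * p + d * p^2 + e * p^3)
}

#' Nuclide production/decay system for 26Al/10Be burial dating
#'
#' Bundles, for each nuclide, a decay model and its production pathways
#' (spallation plus slow- and fast-muon capture), and the surface
#' spallogenic 26Al/10Be production-rate ratio.  Muon parameters are
#' configuration values, not physical constants baked into the algorithms:
#' defaults place total muogenic production at 1.3% of each nuclide's
#' spallation rate with attenuation lengths of 1500 (slow) and 4320 (fast)
#' g cm^-2.
#'
#' @param slhl_be10 Sea-level high-latitude 10Be spallation production rate,
#'   atoms g^-1 a^-1 (default 4.03).
#' @param surface_ratio Surface spallogenic 26Al/10Be production ratio
#'   (default 6.61).
#' @param slow_muon_frac,fast_muon_frac Muon SLHL rates as fractions of each
#'   nuclide's spallation rate (defaults 0.003 and 0.010).
#' @param att_spallation,att_slow_muon,att_fast_muon Attenuation lengths in
#'   g cm^-2 (defaults 160, 1500, 4320).
#' @param be10_half_life,be10_half_life_sigma 10Be half-life (Ma).
#' @param al26_half_life,al26_half_life_sigma 26Al half-life (Ma).
#' @return Object of class `nuclide_system` with elements `be10`, `al26`
#'   (each `decay` + `pathways` data frame) and `surface_spallation_ratio`.
#' @export
nuclide_system <- function(slhl_be10 = 4.03, surface_ratio = 6.61,
                           slow_muon_frac = 0.003, fast_muon_frac = 0.010,
                           att_spallation = 160, att_slow_muon = 1500,
                           att_fast_muon = 4320,
                           be10_half_life = 1.387, be10_half_life_sigma = 0.012,
                           al26_half_life = 0.705, al26_half_life_sigma = 0.024) {
  check_number(slhl_be10, "slhl_be10", positive = TRUE)
  check_number(surface_ratio, "surface_ratio", positive = TRUE)
  pathways <- function(p_spall) data.frame(
    kind = c("spallation", "slow_muon", "fast_muon"),
    slhl_rate = c(p_spall, slow_muon_frac * p_spall, fast_muon_frac * p_spall),
    attenuation_length = c(att_spallation, att_slow_muon, att_fast_muon),
    stringsAsFactors = FALSE)
  structure(list(
    be10 = list(decay = decay_model(be10_half_life, be10_half_life_sigma),
                pathways = pathways(slhl_be10)),
    al26 = list(decay = decay_model(al26_half_life, al26_half_life_sigma),
                pathways = pathways(surface_ratio * slhl_be10)),
    surface_spallation_ratio = surface_ratio),
    class = "nuclide_system")
}

#' Sampling-site description
#'
#' @param latitude Degrees.
#' @param elevation Metres above sea level.
#' @param scaling_factor Spallation scaling; computed with [stone_scaling()]
#'   when `NULL`.
#' @param rock_density g cm^-3, in (1.5, 3.5); default 2.5.
#' @return Object of class `burial_site`.
#' @export
burial_site <- function(latitude, elevation, scaling_factor = NULL,
                        rock_density = 2.5) {
  if (rock_density <= 1.5 || rock_density >= 3.5)
    stop_invalid("rock_density must lie in (1.5, 3.5) g cm^-3")
  if (is.null(scaling_factor)) scaling_factor <- stone_scaling(latitude, elevation)
  check_number(scaling_factor, "scaling_factor", positive = TRUE)
  structure(list(latitude = latitude, elevation = elevation,
                 scaling_factor = scaling_factor, rock_density = rock_density),
            class = "burial_site")
}

# scaling per pathway: spallation scaled, muons unscaled unless requested
.pathway_scaling <- function(kind, site, scale_muons) {
  ifelse(kind == "spallation", site$scaling_factor,
         if (scale_muons) site$scaling_factor else 1)
}

#' Pre-burial steady-state surface concentrations
#'
#' At steady denudation eps the surface inventory of nuclide i is
#' \eqn{N_i = \sum_j P_{ij} S_j / (\lambda_i + \rho\,\varepsilon/\Lambda_j)}
#' summed over production pathways j.  At eps = 0 this is saturation
#' \eqn{\sum_j P_{ij} S_j/\lambda_i}; large eps drives the concentrations to
#' zero and their ratio to the surface production ratio.
#'
#' @param system A [nuclide_system()].
#' @param site A [burial_site()].
#' @param eps_pre Denudation rate, m Ma^-1 (>= 0).
#' @param scale_muons Apply the spallation scaling to muon pathways too
#'   (default `FALSE`).
#' @return Named vector `c(be10 = ..., al26 = ...)`, atoms g^-1.
#' @export
steady_state_surface <- function(system, site, eps_pre, scale_muons = FALSE) {
  stopifnot(inherits(system, "nuclide_system"), inherits(site, "burial_site"))
  check_number(eps_pre, "eps_pre", nonneg = TRUE, finite = FALSE)
  eps_cm_a <- eps_pre * 1e-4                 # m/Ma -> cm/a
  one <- function(nuc) {
    lam_a <- nuc$decay$decay_constant / 1e6  # Ma^-1 -> a^-1
    pw <- nuc$pathways
    s <- .pathway_scaling(pw$kind, site, scale_muons)
    sum(pw$slhl_rate * s /
          (lam_a + site$rock_density * eps_cm_a / pw$attenuation_length))
  }
  c(be10 = one(system$be10), al26 = one(system$al26))
}

#' Post-burial concentration accumulated at depth
#'
#' Integrates production over the burial interval for a sample now at
#' `depth` metres, with the overburden thinning at the steady post-burial
#' denudation rate `eps_post` (linearly decreasing depth): at time u before
#' present the sample sat at depth z(u) = depth + eps_post * u.  Each
#' pathway's depth-attenuated production decays to the present:
#' \deqn{N^{post}_i = \sum_j \int_0^t P_{ij} S_j
#'   e^{-\rho z(u)/\Lambda_j} e^{-\lambda_i u}\, du}
#' evaluated by adaptive quadrature (relative tolerance 1e-8).
#'
#' Only muon pathways produce at depth by default: metres of overburden
#' attenuate the neutron flux to insignificance, and burial-dating practice
#' treats the post-burial term as muogenic.  Set
#' `include_spallation = TRUE` to keep the (exponentially negligible)
#' spallation term.
#'
#' @param t Burial duration, Ma.
#' @param depth Present sampling depth, m (> 0).
#' @param eps_post Post-burial denudation rate, m Ma^-1 (>= 0).
#' @param include_spallation Include the spallation pathway at depth
#'   (default `FALSE`).
#' @inheritParams steady_state_surface
#' @return Named vector `c(be10 = ..., al26 = ...)`, atoms g^-1.
#' @export
postburial_concentration <- function(t, depth, eps_post, system, site,
                                     scale_muons = FALSE,
                                     include_spallation = FALSE) {
  check_number(t, "t", nonneg = TRUE)
  check_number(depth, "depth", positive = TRUE)
  check_number(eps_post, "eps_post", nonneg = TRUE)
  z_cm <- depth * 100
  eps_cm_ma <- eps_post * 100
  rho <- site$rock_density
  one <- function(nuc) {
    lam <- nuc$decay$decay_constant          # Ma^-1
    pw <- nuc$pathways
    if (!include_spallation) pw <- pw[pw$kind != "spallation", , drop = FALSE]
    s <- .pathway_scaling(pw$kind, site, scale_muons)
    tot <- 0
    for (j in seq_len(nrow(pw))) {
      p_ma <- pw$slhl_rate[j] * s[j] * 1e6   # atoms g^-1 Ma^-1
      L <- pw$attenuation_length[j]
      f <- function(u) p_ma * exp(-rho * (z_cm + eps_cm_ma * u) / L) *
        exp(-lam * u)
      if (t > 0)
        tot <- tot + stats::integrate(f, 0, t, rel.tol = 1e-8)$value
    }
    tot
  }
  c(be10 = one(system$be10), al26 = one(system$al26))
}

#' Forward burial model
#'
#' Synthesizes the measured concentration pair for a known history: surface
#' steady state at `eps_pre`, burial for `t` Ma with decay, plus (when
#' `postburial = TRUE`) muogenic accumulation at depth under `eps_post`.
#'
#' @param t Burial duration, Ma.
#' @param eps_pre Pre-burial denudation rate, m Ma^-1.
#' @param depth Present sampling depth, m (required when `postburial`).
#' @param eps_post Post-burial denudation rate, m Ma^-1.
#' @param postburial Include post-burial production.
#' @inheritParams steady_state_surface
#' @return Named vector `c(be10 = ..., al26 = ...)`, atoms g^-1.
#' @export
forward_burial <- function(t, eps_pre, system, site, depth = NULL,
                           eps_post = 0, postburial = !is.null(depth),
                           scale_muons = FALSE) {
  n_pre <- steady_state_surface(system, site, eps_pre, scale_muons)
  lam <- c(be10 = system$be10$decay$decay_constant,
           al26 = system$al26$decay$decay_constant)
  n <- n_pre * exp(-lam * t)
  if (postburial) {
    if (is.null(depth)) stop_invalid("postburial model requires a depth")
    n <- n + postburial_concentration(t, depth, eps_post, system, site,
                                      scale_muons)
  }
  n
}

# solve eps such that the pre-burial Be concentration equals `target`
.eps_for_be <- function(target, system, site, scale_muons) {
  n_sat <- steady_state_surface(system, site, 0, scale_muons)["be10"]
  if (target > n_sat) return(NA_real_)       # above saturation: infeasible
  if (target == n_sat) return(0)
  g <- function(le) log(steady_state_surface(system, site, exp(le),
                                             scale_muons)["be10"]) - log(target)
  lo <- log(1e-8); hi <- log(1e8)
  if (g(lo) <= 0) return(exp(lo))    # target within rounding of saturation
  while (g(hi) > 0 && hi < log(1e15)) hi <- hi + log(100)
  exp(stats::uniroot(g, c(lo, hi), tol = 1e-12)$root)
}

.burial_result <- function(sample_id, model, t, eps_pre, eps_post, frac) {
  structure(list(sample_id = sample_id, model = model,
                 burial_duration_ma = t, sigma_ma = NA_real_,
                 eps_pre = eps_pre, eps_post = eps_post,
                 postburial_fraction = frac),
            class = "burial_result")
}

#' @export
print.burial_result <- function(x, ...) {
  cat(sprintf("%s [%s]: t = %.4f Ma, eps_pre = %.1f m/Ma", x$sample_id,
              x$model, x$burial_duration_ma, x$eps_pre))
  if (x$model == "with_postburial")
    cat(sprintf(", eps_post = %.2f m/Ma, post-burial share Be %.2f / Al %.2f",
                x$eps_post, x$postburial_fraction["be10"],
                x$postburial_fraction["al26"]))
  cat("\n")
  invisible(x)
}

# shared 1-D bracketing solve on burial duration t via the Al residual.
# pred_al(t) and target_be(t) parameterize the min/max variants.
.solve_burial <- function(sample, system, site, target_be, extra_al,
                          scale_muons, model, eps_post) {
  sample$n_be <- unname(sample$n_be)
  sample$n_al <- unname(sample$n_al)
  lam_be <- system$be10$decay$decay_constant
  lam_al <- system$al26$decay$decay_constant
  n_sat <- steady_state_surface(system, site, 0, scale_muons)
  t_max <- 10 * system$al26$decay$half_life

  g <- function(t) {
    tb <- target_be(t)
    if (!is.finite(tb) || tb <= 0) return(NA_real_)
    eps <- .eps_for_be(tb * exp(lam_be * t), system, site, scale_muons)
    if (is.na(eps)) return(NA_real_)
    pre_al <- steady_state_surface(system, site, eps, scale_muons)["al26"]
    log((pre_al * exp(-lam_al * t) + extra_al(t)) / sample$n_al)
  }

  # feasibility and sign scan over a fixed grid, then refine by uniroot
  grid <- seq(0, t_max, length.out = 121)
  vals <- vapply(grid, g, numeric(1))
  ok <- which(is.finite(vals))
  if (length(ok) == 0L)
    stop_invalid("no feasible burial duration: measured 10Be exceeds what ",
                 "any pre-burial steady state can supply")
  if (vals[ok[1]] < -1e-9) {
    r_meas <- sample$n_al / sample$n_be
    stop_invalid(sprintf(
      paste0("no solution: measured 26Al/10Be ratio %.3f exceeds the ",
             "achievable pre-burial ratio (max %.3f at t = %.3f Ma)"),
      r_meas, r_meas * exp(vals[ok[1]]), grid[ok[1]]))
  }
  sgn <- which(diff(sign(vals[ok])) < 0)
  if (length(sgn) == 0L && abs(vals[ok[1]]) <= 1e-9) {
    # root sits exactly at the feasibility boundary (fresh surface sample)
    sgn <- integer(0)
    t_zero <- grid[ok[1]]
  } else t_zero <- NULL
  if (!is.null(t_zero)) {
    t_star <- t_zero
  } else if (length(sgn) == 0L) {
    if (abs(vals[ok[length(ok)]]) < 1e-9) {
      t_star <- grid[ok[length(ok)]]
    } else {
      stop_invalid("no solution within t in [0, ", signif(t_max, 3),
                   "] Ma: the measured ratio is below the modelled range ",
                   sprintf("(achievable log-residual range [%.3g, %.3g])",
                           min(vals[ok]), max(vals[ok])))
    }
  } else {
    i <- ok[sgn[1]]; j <- ok[sgn[1] + 1]
    t_star <- if (abs(vals[i]) < 1e-14) grid[i] else
      stats::uniroot(g, c(grid[i], grid[j]), tol = 1e-8)$root
  }
  tb <- unname(target_be(t_star))
  eps <- .eps_for_be(tb * exp(lam_be * t_star), system, site, scale_muons)
  frac <- c(be10 = (sample$n_be - tb) / sample$n_be,
            al26 = unname(extra_al(t_star)) / sample$n_al)
  frac <- pmin(pmax(frac, 0), 1)
  .burial_result(sample$sample_id, model, t_star, eps, eps_post, frac)
}

#' Minimum burial duration (no post-burial production)
#'
#' Solves the two-equation system
#' \eqn{N_i = N^{pre}_i(\varepsilon)\,e^{-\lambda_i t}} for the burial
#' duration t and the pre-burial denudation rate, assuming infinite burial
#' depth (no accumulation while buried).  The solve brackets t through the
#' two-nuclide ratio equation, which is monotone in t, then recovers
#' eps_pre from the 10Be equation.
#'
#' @param sample List or one-row data frame with `sample_id`, `n_be`, `n_al`
#'   (atoms g^-1); `depth_m` is ignored by this model.
#' @inheritParams steady_state_surface
#' @return A `burial_result`: duration (Ma), `eps_pre` (m Ma^-1), zero
#'   post-burial fractions.
#' @export
solve_burial_min <- function(sample, system, site, scale_muons = FALSE) {
  check_number(sample$n_be, "n_be", positive = TRUE)
  check_number(sample$n_al, "n_al", positive = TRUE)
  .solve_burial(sample, system, site,
                target_be = function(t) sample$n_be,
                extra_al = function(t) 0,
                scale_muons, "no_postburial", eps_post = 0)
}

#' Maximum burial duration (with post-burial muogenic production)
#'
#' As [solve_burial_min()], but the sample remains at its sampling depth
#' (thinning at `eps_post`) and accumulates muon-produced nuclides while
#' buried; the measured concentrations are the decayed inheritance plus the
#' post-burial term.  Reports the share of each measured concentration that
#' was produced after burial.
#'
#' @param sample List or one-row data frame with `sample_id`, `depth_m` (> 0),
#'   `n_be`, `n_al`.
#' @param eps_post Post-burial denudation rate, m Ma^-1.
#' @inheritParams steady_state_surface
#' @return A `burial_result` with model `"with_postburial"`.
#' @export
solve_burial_max <- function(sample, system, site, eps_post = 0,
                             scale_muons = FALSE) {
  check_number(sample$n_be, "n_be", positive = TRUE)
  check_number(sample$n_al, "n_al", positive = TRUE)
  check_number(sample$depth_m, "depth_m", positive = TRUE)
  post <- function(t) if (t <= 0) c(be10 = 0, al26 = 0) else
    postburial_concentration(t, sample$depth_m, eps_post, system, site,
                             scale_muons)
  .solve_burial(sample, system, site,
                target_be = function(t) sample$n_be - post(t)["be10"],
                extra_al = function(t) unname(post(t)["al26"]),
                scale_muons, "with_postburial", eps_post = eps_post)
}

#' Grid search for the post-burial denudation rate
#'
#' For each candidate eps_post, solves every sample's maximum-model burial
#' duration and scores the coherence of the durations: the summed squared
#' normalized residual about their (inverse-variance) mean.  Samples from
#' one deposit buried together should agree on one duration at the true
#' post-burial denudation rate.
#'
#' With a single sample the two-nuclide system is exactly identified at any
#' eps_post, the misfit curve is identically zero, and a warning is issued.
#'
#' @param samples Data frame with columns `sample_id`, `depth_m`, `n_be`,
#'   `n_al` (one row per sample).
#' @param grid Candidate eps_post values, m Ma^-1 (non-empty).
#' @param sigma_t Optional per-sample duration uncertainties used as
#'   normalizers (default 1 for all).
#' @inheritParams steady_state_surface
#' @return List: `best_eps`, `misfit` data frame (`eps_post`, `misfit`,
#'   `n_solved`), and the per-sample duration matrix `durations`.
#' @export
fit_postburial_denudation <- function(samples, system, site, grid,
                                      sigma_t = NULL, scale_muons = FALSE) {
  if (length(grid) == 0L) stop_invalid("grid of eps_post values is empty")
  n <- nrow(samples)
  if (n < 1L) stop_invalid("at least one sample is required")
  if (is.null(sigma_t)) sigma_t <- rep(1, n)
  if (n == 1L)
    warning("single sample: the grid misfit is identically zero", call. = FALSE)
  dur <- matrix(NA_real_, n, length(grid),
                dimnames = list(samples$sample_id, NULL))
  for (j in seq_along(grid)) {
    for (i in seq_len(n)) {
      r <- try(solve_burial_max(as.list(samples[i, ]), system, site,
                                eps_post = grid[j], scale_muons), silent = TRUE)
      if (!inherits(r, "try-error")) dur[i, j] <- r$burial_duration_ma
    }
  }
  misfit <- vapply(seq_along(grid), function(j) {
    t <- dur[, j]
    if (any(is.na(t))) return(NA_real_)
    w <- 1 / sigma_t^2
    tbar <- sum(w * t) / sum(w)
    sum(((t - tbar) / sigma_t)^2)
  }, numeric(1))
  if (all(is.na(misfit))) stop_invalid("no grid point admitted a solution ",
                                       "for every sample")
  best <- grid[which.min(misfit)]
  list(best_eps = best,
       misfit = data.frame(eps_post = grid, misfit = misfit,
                           n_solved = colSums(!is.na(dur))),
       durations = dur)
}

#' Monte Carlo uncertainty for a burial solve
#'
#' Gaussian perturbation of the measured concentrations (and optionally the
#' SLHL spallation rate and the surface production ratio), re-solving each
#' draw, and reporting the sample standard deviation of the recovered
#' durations.  Reproducible for a fixed seed; solver failures among draws
#' are counted, and more than 20% failures downgrades the status.
#'
#' @param sample As for the solvers, including `n_be_sigma`, `n_al_sigma`.
#' @param model `"min"` or `"max"`.
#' @param eps_post Used by the max model.
#' @param n_draws Number of draws (>= 100).
#' @param seed Integer seed.
#' @param perturb_production Also perturb production constants (1-sigma 4.5%
#'   on the SLHL rate, 7.9% on the surface ratio).
#' @inheritParams steady_state_surface
#' @return List: `mean_ma`, `sigma_ma`, `n_ok`, `n_fail`, `status`
#'   (`"ok"` or `"warning"`).
#' @export
propagate_mc <- function(sample, system, site, model = c("min", "max"),
                         eps_post = 0, n_draws = 1000, seed = 1,
                         perturb_production = FALSE, scale_muons = FALSE) {
  model <- match.arg(model)
  if (n_draws < 100) stop_invalid("n_draws must be >= 100")
  sb <- sample$n_be_sigma %||% 0
  sa <- sample$n_al_sigma %||% 0
  set.seed(seed)
  t <- rep(NA_real_, n_draws)
  for (k in seq_len(n_draws)) {
    s <- sample
    s$n_be <- stats::rnorm(1, sample$n_be, sb)
    s$n_al <- stats::rnorm(1, sample$n_al, sa)
    sys_k <- system
    if (perturb_production) {
      sys_k <- nuclide_system(
        slhl_be10 = stats::rnorm(1, 4.03, 0.18),
        surface_ratio = stats::rnorm(1, 6.61, 0.52))
    }
    if (s$n_be <= 0 || s$n_al <= 0) next
    r <- try(switch(model,
                    min = solve_burial_min(s, sys_k, site, scale_muons),
                    max = solve_burial_max(s, sys_k, site, eps_post,
                                           scale_muons)),
             silent = TRUE)
    if (!inherits(r, "try-error")) t[k] <- r$burial_duration_ma
  }
  ok <- t[!is.na(t)]
  n_fail <- n_draws - length(ok)
  list(mean_ma = mean(ok), sigma_ma = stats::sd(ok),
       n_ok = length(ok), n_fail = n_fail,
       status = if (n_fail > 0.2 * n_draws) "warning" else "ok")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a quartz concentration table from CSV
#'
#' @param path CSV with columns `sample_id`, `depth_m`, `n_be`, `n_be_sigma`,
#'   `n_al`, `n_al_sigma` (concentrations in atoms g^-1).
#' @return Data frame with those columns.
#' @export
read_quartz_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "depth_m", "n_be", "n_be_sigma", "n_al", "n_al_sigma")
  if (!all(need %in% names(d)))
    stop_invalid("quartz CSV must have columns ", paste(need, collapse = ", "))
  d
}
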