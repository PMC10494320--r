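# 26Al/10Be burial modelling: scaling, steady states, forward/inverse
# solvers, denudation grid search, Monte Carlo propagation.

test_that("spallation scaling is normalized at SLHL and monotone in elevation", {
  expect_equal(stone_scaling(60, 0), 1.0, tolerance = 0.01)
  expect_equal(stone_scaling(90, 0), 1.0, tolerance = 0.01)
  elevs <- seq(0, 3000, by = 500)
  s <- vapply(elevs, function(e) stone_scaling(30, e), 0)
  expect_true(all(diff(s) > 0))
  # frozen regression value, computed once by an independent implementation
  # of the published polynomial scheme
  expect_equal(stone_scaling(-18.5, 160), 0.748969566098058, tolerance = 1e-9)
  expect_error(stone_scaling(100, 0), "latitude")
})

test_that("steady-state concentrations hit the saturation and erosion limits", {
  site <- test_site()
  # spallation-only system: exact closed forms
  sys <- test_system(slow_muon_frac = 0, fast_muon_frac = 0)
  sat <- steady_state_surface(sys, site, 0)
  lam_be_a <- sys$be10$decay$decay_constant / 1e6
  expect_equal(unname(sat["be10"]),
               4.03 * site$scaling_factor / lam_be_a, tolerance = 1e-12)
  # ratio at any eps follows the closed form 6.61 (lam_be+x)/(lam_al+x)
  for (eps in c(0, 10, 100, 1000)) {
    n <- steady_state_surface(sys, site, eps)
    x <- site$rock_density * eps * 1e-4 / 160
    lam_al_a <- sys$al26$decay$decay_constant / 1e6
    expect_equal(unname(n["al26"] / n["be10"]),
                 6.61 * (lam_be_a + x) / (lam_al_a + x), tolerance = 1e-9)
  }
  # erosion-dominated limit: ratio -> 6.61
  n_hi <- steady_state_surface(sys, site, 1e7)
  expect_equal(unname(n_hi["al26"] / n_hi["be10"]), 6.61, tolerance = 1e-3)
  expect_lt(n_hi["be10"], sat["be10"] * 1e-3)
})

test_that("the pre-burial ratio never exceeds the surface production ratio", {
  site <- test_site()
  sys <- test_system()
  for (eps in c(0, 5, 50, 500, 5000)) {
    for (t in c(0, 0.5, 2)) {
      n <- forward_burial(t, eps, sys, site)
      expect_lte(n["al26"] / n["be10"], 6.61 + 1e-9)
    }
  }
})

test_that("post-burial accumulation matches the analytic linear-depth integral", {
  site <- test_site()
  sys <- test_system()
  t <- 1.2; depth <- 10.5; eps_post <- 21
  num <- postburial_concentration(t, depth, eps_post, sys, site,
                                  include_spallation = TRUE)
  rho <- site$rock_density
  closed <- function(nuc) {
    lam <- nuc$decay$decay_constant
    pw <- nuc$pathways
    tot <- 0
    for (j in seq_len(nrow(pw))) {
      s <- if (pw$kind[j] == "spallation") site$scaling_factor else 1
      p_ma <- pw$slhl_rate[j] * s * 1e6
      kk <- lam + rho * eps_post * 100 / pw$attenuation_length[j]
      tot <- tot + p_ma * exp(-rho * depth * 100 / pw$attenuation_length[j]) *
        (1 - exp(-kk * t)) / kk
    }
    tot
  }
  expect_equal(unname(num["be10"]), closed(sys$be10), tolerance = 1e-6)
  expect_equal(unname(num["al26"]), closed(sys$al26), tolerance = 1e-6)
  # the default (muon-only) term excludes the spallation pathway, which is
  # exponentially negligible at 10 m but not exactly zero
  num_mu <- postburial_concentration(t, depth, eps_post, sys, site)
  expect_lt(unname(num_mu["be10"]), unname(num["be10"]))
  expect_equal(unname(num_mu["be10"]), unname(num["be10"]), tolerance = 1e-4)
})

test_that("minimum-model inversion recovers forward-model histories", {
  site <- test_site()
  sys <- test_system()
  cases <- expand.grid(t = c(0.1, 0.84, 1.0, 2.5, 5),
                       eps = c(10, 100, 1000, 2000))
  for (i in seq_len(nrow(cases))) {
    n <- forward_burial(cases$t[i], cases$eps[i], sys, site)
    r <- solve_burial_min(list(sample_id = "syn", n_be = n["be10"],
                               n_al = n["al26"]), sys, site)
    expect_equal(r$burial_duration_ma, cases$t[i],
                 tolerance = 1e-4 * max(cases$t[i], 1))
    expect_equal(r$eps_pre, cases$eps[i], tolerance = 1e-3 * cases$eps[i])
    expect_equal(unname(r$postburial_fraction), c(0, 0))
  }
})

test_that("a fresh surface sample dates to zero burial", {
  site <- test_site()
  sys <- test_system()
  n <- forward_burial(0, 350, sys, site)
  r <- solve_burial_min(list(sample_id = "fresh", n_be = n["be10"],
                             n_al = n["al26"]), sys, site)
  expect_equal(r$burial_duration_ma, 0, tolerance = 1e-6)
})

test_that("an unachievable 26Al/10Be ratio is rejected with diagnostics", {
  site <- test_site()
  sys <- test_system()
  n <- forward_burial(0, 100, sys, site)
  expect_error(
    solve_burial_min(list(sample_id = "bad", n_be = n["be10"],
                          n_al = 8 * n["be10"]), sys, site),
    "achievable")
})

test_that("maximum model reduces to the minimum model without muons", {
  site <- test_site()
  sys0 <- test_system(slow_muon_frac = 0, fast_muon_frac = 0)
  for (t in c(0.3, 1.0, 3.0)) {
    n <- forward_burial(t, 200, sys0, site)
    smp <- list(sample_id = "x", depth_m = 12, n_be = n["be10"],
                n_al = n["al26"])
    rmin <- solve_burial_min(smp, sys0, site)
    rmax <- solve_burial_max(smp, sys0, site, eps_post = 20)
    expect_equal(rmax$burial_duration_ma, rmin$burial_duration_ma,
                 tolerance = 1e-6)
  }
})

test_that("maximum-model inversion recovers the full burial history", {
  site <- test_site()
  sys <- test_system()
  for (case in list(c(t = 0.9, eps_pre = 800, depth = 10.5, eps_post = 21),
                    c(t = 2.0, eps_pre = 150, depth = 15.0, eps_post = 5))) {
    n <- forward_burial(case["t"], case["eps_pre"], sys, site,
                        depth = case["depth"], eps_post = case["eps_post"])
    r <- solve_burial_max(list(sample_id = "syn", depth_m = case["depth"],
                               n_be = n["be10"], n_al = n["al26"]),
                          sys, site, eps_post = case["eps_post"])
    expect_equal(r$burial_duration_ma, unname(case["t"]), tolerance = 1e-3)
    expect_equal(r$eps_pre, unname(case["eps_pre"]),
                 tolerance = 1e-3 * case["eps_pre"])
    expect_true(all(r$postburial_fraction >= 0 & r$postburial_fraction <= 1))
  }
})

test_that("post-burial fraction grows with burial duration at fixed depth", {
  site <- test_site()
  sys <- test_system()
  fr <- vapply(c(0.5, 1, 2, 4), function(t) {
    n <- forward_burial(t, 500, sys, site, depth = 10, eps_post = 20)
    r <- solve_burial_max(list(sample_id = "x", depth_m = 10,
                               n_be = n["be10"], n_al = n["al26"]),
                          sys, site, eps_post = 20)
    unname(r$postburial_fraction["be10"])
  }, 0)
  expect_true(all(diff(fr) > 0))
})

test_that("burial duration decreases in the measured ratio at fixed 10Be", {
  site <- test_site()
  sys <- test_system()
  n <- forward_burial(1.5, 300, sys, site)
  ratios <- seq(0.9, 1.6, by = 0.1) * unname(n["al26"] / n["be10"])
  t <- vapply(ratios, function(rr) {
    solve_burial_min(list(sample_id = "x", n_be = n["be10"],
                          n_al = rr * n["be10"]),
                     sys, site)$burial_duration_ma
  }, 0)
  expect_true(all(diff(t) < 0))
})

test_that("the denudation grid search recovers a common eps_post", {
  site <- test_site()
  sys <- test_system()
  # two samples buried together (same duration and eps_post, different
  # depths and pre-burial histories)
  mk <- function(depth, eps_pre) {
    n <- forward_burial(1.0, eps_pre, sys, site, depth = depth, eps_post = 21)
    data.frame(sample_id = paste0("d", depth), depth_m = depth,
               n_be = unname(n["be10"]), n_be_sigma = 0,
               n_al = unname(n["al26"]), n_al_sigma = 0)
  }
  samples <- rbind(mk(10.5, 900), mk(15.0, 400))
  grid <- seq(0, 50, by = 7)           # includes the generating value 21
  fit <- fit_postburial_denudation(samples, sys, site, grid)
  expect_equal(fit$best_eps, 21)
  expect_equal(nrow(fit$misfit), length(grid))
  expect_equal(fit$misfit$misfit[fit$misfit$eps_post == 21], 0,
               tolerance = 1e-8)
  expect_error(fit_postburial_denudation(samples, sys, site, numeric(0)),
               "empty")
  expect_warning(fit_postburial_denudation(samples[1, ], sys, site, c(10, 21)),
                 "single sample")
})

test_that("Monte Carlo propagation is seeded, scales with noise, and
           degenerates to zero", {
  site <- test_site()
  sys <- test_system()
  n <- forward_burial(1.0, 500, sys, site)
  smp <- list(sample_id = "mc", n_be = unname(n["be10"]), n_be_sigma = 0,
              n_al = unname(n["al26"]), n_al_sigma = 0)
  r0 <- propagate_mc(smp, sys, site, model = "min", n_draws = 100, seed = 9)
  expect_equal(r0$sigma_ma, 0)
  expect_identical(r0$status, "ok")
  smp$n_be_sigma <- 0.01 * smp$n_be
  smp$n_al_sigma <- 0.01 * smp$n_al
  r1 <- propagate_mc(smp, sys, site, model = "min", n_draws = 200, seed = 9)
  r1b <- propagate_mc(smp, sys, site, model = "min", n_draws = 200, seed = 9)
  expect_identical(r1, r1b)
  smp2 <- smp
  smp2$n_be_sigma <- 2 * smp$n_be_sigma
  smp2$n_al_sigma <- 2 * smp$n_al_sigma
  r2 <- propagate_mc(smp2, sys, site, model = "min", n_draws = 200, seed = 9)
  expect_equal(r2$sigma_ma / r1$sigma_ma, 2, tolerance = 0.25)
  expect_error(propagate_mc(smp, sys, site, n_draws = 50), ">= 100")
})

test_that("quartz CSV reader enforces the column contract", {
  p <- withr::local_tempfile(fileext = ".csv")
  d <- data.frame(sample_id = "q1", depth_m = 10.5, n_be = 2e4,
                  n_be_sigma = 1e3, n_al = 8e4, n_al_sigma = 5e3)
  write.csv(d, p, row.names = FALSE)
  expect_equal(read_quartz_csv(p)$n_be, 2e4)
  write.csv(d[, -2], p, row.names = FALSE)
  expect_error(read_quartz_csv(p), "depth_m")
})
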