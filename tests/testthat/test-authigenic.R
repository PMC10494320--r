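# Authigenic 10Be/9Be dating: decay arithmetic, weighted means, scenario
# tables, and consistency of the packaged multi-scenario age table.

test_that("decay constants follow ln2 / half-life", {
  expect_equal(decay_constant(log(2)), 1.0)
  expect_equal(decay_constant(1.387), 0.499746, tolerance = 1e-6)
  expect_equal(decay_constant(0.705), 0.983187, tolerance = 1e-6)
  dm <- decay_model(1.387)
  expect_equal(dm$decay_constant * dm$half_life, log(2), tolerance = 1e-12)
  expect_error(decay_constant(0), "must be > 0")
  expect_error(decay_constant(-1), "must be > 0")
})

test_that("inverse-variance weighted mean matches hand-computed weights", {
  # single measurement: identity
  w <- weighted_mean_ratio(1.5, 0.2)
  expect_equal(w$value, 1.5)
  expect_equal(w$sigma, 0.2)
  expect_identical(w$method, "single")
  # two equal measurements: same mean, sigma / sqrt(2)
  w2 <- weighted_mean_ratio(c(1.5, 1.5), c(0.2, 0.2))
  expect_equal(w2$value, 1.5)
  expect_equal(w2$sigma, 0.2 / sqrt(2))
  # hand-computed: weights 100 and 25
  w3 <- weighted_mean_ratio(c(1.0, 2.0), c(0.1, 0.2))
  expect_equal(w3$value, 1.2)
  expect_equal(w3$sigma, 1 / sqrt(125), tolerance = 1e-12)
  expect_equal(w3$sigma, 0.0894, tolerance = 1e-3)
  expect_error(weighted_mean_ratio(c(1, 2), c(0.1, 0)), "degenerate")
})

test_that("weighted mean is bounded by extremes and duplication-invariant", {
  set.seed(11)
  for (i in 1:20) {
    x <- runif(5, 0.1, 3)
    s <- runif(5, 0.01, 0.5)
    w <- weighted_mean_ratio(x, s)
    expect_gte(w$value, min(x))
    expect_lte(w$value, max(x))
    # replacing one measurement by two copies with sigma scaled by sqrt(2)
    # leaves the mean and its uncertainty unchanged
    w_dup <- weighted_mean_ratio(c(x[1], x[1], x[-1]),
                                 c(s[1] * sqrt(2), s[1] * sqrt(2), s[-1]))
    expect_equal(w_dup$value, w$value, tolerance = 1e-12)
    expect_equal(w_dup$sigma, w$sigma, tolerance = 1e-12)
  }
})

test_that("ages follow the decay law with propagated uncertainty", {
  dm <- decay_model(1.387)
  n0 <- initial_ratio(0.640e-8, 0.034e-8)
  expect_equal(be10_age(0.640e-8, 0, n0, dm)$age_ma, 0)
  expect_equal(be10_age(0.320e-8, 0, n0, dm)$age_ma, 1.387, tolerance = 1e-12)
  expect_equal(be10_age(0.160e-8, 0, n0, dm)$age_ma, 2.774,
               tolerance = 1e-4)
  expect_equal(be10_age(0.160e-8, 0, n0, dm)$age_ma,
               1.387 / log(2) * log(4), tolerance = 1e-12)
  # a measured ratio above N0 is flagged, not an error
  r <- be10_age(1.0e-8, 0.01e-8, n0, dm)
  expect_identical(r$flag, "future_age")
  expect_lt(r$age_ma, 0)
  # error propagation reduces to the measurement term as sigma_N0 -> 0
  lam <- dm$decay_constant
  n0_exact <- initial_ratio(0.640e-8, 0)
  r2 <- be10_age(0.2e-8, 0.01e-8, n0_exact, dm)
  expect_equal(r2$sigma_ma, (1 / lam) * 0.01 / 0.2, tolerance = 1e-12)
  # the half-life term is off by default and increases sigma when enabled
  r3 <- be10_age(0.2e-8, 0.01e-8, n0, dm)
  r4 <- be10_age(0.2e-8, 0.01e-8, n0, dm, include_lambda_sigma = TRUE)
  expect_gt(r4$sigma_ma, r3$sigma_ma)
  sig_lam_rel <- dm$half_life_sigma / dm$half_life
  expect_equal(r4$sigma_ma^2 - r3$sigma_ma^2,
               r3$age_ma^2 * sig_lam_rel^2, tolerance = 1e-12)
})

test_that("ratio_at_age round-trips through be10_age", {
  dm <- decay_model(1.387)
  n0 <- initial_ratio(0.640e-8, 0.034e-8)
  expect_equal(ratio_at_age(0, n0, dm), n0$value)
  expect_equal(ratio_at_age(1.387, n0, dm), n0$value / 2, tolerance = 1e-12)
  expect_equal(ratio_at_age(8.957, n0, dm), 0.007293e-8, tolerance = 1e-4)
  ages <- seq(0, 25, by = 0.5)
  back <- be10_age(ratio_at_age(ages, n0, dm), 0, n0, dm)$age_ma
  expect_equal(back, ages, tolerance = 1e-10)
})

test_that("age decreases monotonically in the measured ratio", {
  n0 <- initial_ratio(0.640e-8)
  ratios <- sort(runif(50, 0.01e-8, 0.64e-8))
  ages <- be10_age(ratios, 0, n0)$age_ma
  expect_true(all(diff(ages) < 0))
})

test_that("transfer_age shifts ages by the constant log-ratio term", {
  dm <- decay_model(1.387)
  n0a <- initial_ratio(0.640e-8, 0.034e-8)
  n0b <- initial_ratio(0.226e-8, 0.007e-8)
  expect_equal(transfer_age(5, n0a, n0a, dm), 5)
  # antisymmetric
  expect_equal(transfer_age(transfer_age(3.2, n0a, n0b, dm), n0b, n0a, dm),
               3.2, tolerance = 1e-12)
  # the shift is the closed form (1.387/ln2) * ln(0.640/0.226)
  shift <- 1.387 / log(2) * log(0.640 / 0.226)
  expect_equal(shift, 2.0831, tolerance = 1e-4)
  expect_equal(transfer_age(7.043, n0a, n0b, dm), 7.043 - shift)
  # printed-table case: 7.043 Ma under 0.640e-8 -> 4.958 under 0.226e-8
  expect_equal(transfer_age(7.043, n0a, n0b, dm), 4.958, tolerance = 5e-3)
})

test_that("run_scenarios recovers synthesized ages and orders rows", {
  dm <- decay_model(1.387)
  n0 <- initial_ratio(0.5e-8)
  true_ages <- c(2, 8, 15)
  fossils <- data.frame(
    sample_id = c("f1", "f2", "f3"),
    context = c("fluvio-deltaic", "estuarine-lagoonal", "fluvio-deltaic"),
    ratio = ratio_at_age(true_ages, n0, dm), sigma = 0)
  sc_global <- be10_scenario("global", n0)
  sc_ctx <- be10_scenario("by-context", list(
    "fluvio-deltaic" = n0, "estuarine-lagoonal" = initial_ratio(1.0e-8)))
  res <- run_scenarios(fossils, list(sc_global, sc_ctx), dm)
  expect_equal(nrow(res), 6L)
  expect_identical(res$scenario, rep(c("global", "by-context"), 3))
  expect_equal(res$age_ma[res$scenario == "global"], true_ages,
               tolerance = 1e-10)
  # context without an assignment names the sample and scenario
  bad <- fossils
  bad$context[2] <- "coastal-estuarine"
  expect_error(run_scenarios(bad, sc_ctx, dm), "f2")
  expect_error(run_scenarios(bad, sc_ctx, dm), "by-context")
  # N0 equal to the measured ratio gives age zero
  one <- run_scenarios(fossils[1, ],
                       be10_scenario("eq", initial_ratio(fossils$ratio[1])),
                       dm)
  expect_equal(one$age_ma, 0)
})

test_that("ratio CSV I/O rescales the 1e-8 display convention", {
  d <- data.frame(sample_id = c("m1", "f1"), role = c("modern", "fossil"),
                  context = c("estuarine-lagoonal", "estuarine-lagoonal"),
                  ratio_1e8 = c(0.640, 0.064), sigma_1e8 = c(0.034, 0.003))
  p <- withr::local_tempfile(fileext = ".csv")
  write.csv(d, p, row.names = FALSE)
  r <- read_ratio_csv(p)
  expect_equal(r$ratio, c(0.640e-8, 0.064e-8))
  ages <- run_scenarios(r[r$role == "fossil", ],
                        be10_scenario("s", initial_ratio(0.640e-8, 0.034e-8)))
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_age_csv(ages, p2)
  back <- read.csv(p2)
  expect_equal(back$n0_1e8, 0.640)
  expect_equal(back$age_ma, ages$age_ma)
})

test_that("the packaged age table is internally consistent across scenarios", {
  tab <- mazamba_authigenic_ages()
  expect_equal(nrow(tab), 15L)
  dm <- decay_model(1.387)
  shift <- log(0.640 / 0.226) / dm$decay_constant
  # scenario-2 minus scenario-3 is the constant shift, for every sample
  expect_true(all(abs(tab$s2_age_ma - tab$s3_age_ma - shift) < 5e-3))
  # back-computed measured ratios re-dated under scenario 3 match the table
  n0_2 <- initial_ratio(0.640e-8, 0.034e-8)
  n0_3 <- initial_ratio(0.226e-8, 0.007e-8)
  ratios <- ratio_at_age(tab$s2_age_ma, n0_2, dm)
  re3 <- be10_age(ratios, 0, n0_3, dm)$age_ma
  expect_equal(re3, tab$s3_age_ma, tolerance = 5e-3)
})
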