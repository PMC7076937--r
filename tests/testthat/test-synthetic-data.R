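test_that("individual-parameter sampler is reproducible and respects the population law", {
  spec <- default_population_spec()
  phi1 <- sample_individual_params(spec, 50, seed = 9)
  phi2 <- sample_individual_params(spec, 50, seed = 9)
  expect_identical(phi1, phi2)
  expect_true(all(phi1 > 0))
  # degenerate population: every subject at the typical values
  spec0 <- population_spec(spec$model, exp(spec$mu), omega = 0,
                           error = spec$error, regimen = spec$regimen)
  phi0 <- sample_individual_params(spec0, 5, seed = 1)
  expect_equal(unname(phi0),
               matrix(rep(exp(spec$mu), each = 5), 5), tolerance = 1e-12,
               ignore_attr = TRUE)
  # law of large numbers: moments of log phi converge to (mu, Omega)
  big <- sample_individual_params(spec, 1e5, seed = 2)
  lp <- log(big)
  se_mu <- sqrt(diag(spec$Omega) / 1e5)
  expect_true(all(abs(colMeans(lp) - spec$mu) < 3 * sqrt(se_mu^2 + 1e-12)))
  expect_equal(unname(apply(lp, 2, sd)), unname(sqrt(diag(spec$Omega))),
               tolerance = 0.02)
  # sample CV of each component matches the log-normal identity
  cv_emp <- apply(big, 2, sd) / colMeans(big)
  cv_theo <- sqrt(exp(diag(spec$Omega)) - 1)
  expect_equal(unname(cv_emp), unname(cv_theo), tolerance = 0.03)
})

test_that("non-PSD covariance is rejected", {
  om <- matrix(c(1, 2, 2, 1), 2)
  expect_error(
    population_spec("simeoni",
                    c(lambda0 = 0.25, lambda1 = 120, V0 = 200),
                    omega = diag(3) * 0.1 - 0.2),
    "positive semi-definite")
  expect_error(error_params(0, 0), "not both 0")
})

test_that("residual error model has the stated conditional spread", {
  err <- error_params(a = 20, b = 0.1)
  set.seed(33)
  y <- observe_volumes(rep(500, 1e5), err)
  # a + b f = 70; Monte-Carlo check of the conditional sd
  expect_equal(sd(y), 70, tolerance = 1 / 70)
  expect_equal(mean(y), 500, tolerance = 0.005)
  expect_true(all(y > 0))
  # proportional-only spread at f > 0, additive-only at f = 0
  set.seed(34)
  yp <- observe_volumes(rep(200, 2e4), error_params(a = 1e-9, b = 0.2))
  expect_equal(sd(yp), 40, tolerance = 0.03)
  ya <- observe_volumes(rep(0, 2e4), error_params(a = 30, b = 0.5),
                        positive = "truncate")
  expect_lt(max(ya), 30 * 5)
})

test_that("cohorts reproduce the study design", {
  coh <- small_cohort(seed = 21, n_control = 21, n_treated = 19,
                      horizon = 42)
  ids <- unique(coh$subject_id)
  expect_length(ids, 40)
  expect_identical(sort(unique(coh$group)), c("control", "treated"))
  obs_per <- table(coh$subject_id)
  expect_true(all(obs_per >= 1))
  # enrollment: day-0 measurement and true V0 below the cap
  first <- coh$volume_mm3[coh$time_day == 0]
  expect_true(all(first < 700))
  expect_true(all(attr(coh, "phi_true")[, "V0"] < 700))
  # weekend gaps: no day-5 or day-6 of any week on the grid
  expect_true(all(coh$time_day %% 7 < 5))
  # censoring: nothing recorded after the first measurement >= 2500
  for (id in ids) {
    v <- coh$volume_mm3[coh$subject_id == id]
    hit <- which(v >= 2500)
    if (length(hit)) expect_identical(hit[1], length(v))
  }
})

test_that("identical seed and settings give byte-identical cohort files", {
  d <- cohort_design(n_control = 4, n_treated = 3, horizon = 14)
  spec <- default_population_spec()
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cohort(generate_cohort(spec, d, seed = 5), f1)
  write_cohort(generate_cohort(spec, d, seed = 5), f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(
    readLines(f1),
    {
      f3 <- tempfile(fileext = ".csv")
      write_cohort(generate_cohort(spec, d, seed = 6), f3)
      readLines(f3)
    }))
})

test_that("cohort CSV round trip preserves observations and dosing", {
  coh <- small_cohort(seed = 8)
  f <- tempfile(fileext = ".csv")
  write_cohort(coh, f)
  back <- read_cohort(f)
  expect_equal(back$volume_mm3, coh$volume_mm3, tolerance = 1e-10)
  expect_identical(back$subject_id, coh$subject_id)
  reg <- attr(back, "regimens")
  expect_identical(reg$dose_amount > 0,
                   attr(coh, "regimens")$dose_amount > 0)
})

test_that("lowering the euthanasia threshold never adds observations", {
  spec <- default_population_spec()
  d_hi <- cohort_design(n_control = 6, n_treated = 6, horizon = 35,
                        censor_volume = 2500)
  d_lo <- cohort_design(n_control = 6, n_treated = 6, horizon = 35,
                        censor_volume = 1200)
  d_inf <- cohort_design(n_control = 6, n_treated = 6, horizon = 35,
                         censor_volume = Inf)
  hi <- generate_cohort(spec, d_hi, seed = 13)
  lo <- generate_cohort(spec, d_lo, seed = 13)
  inf <- generate_cohort(spec, d_inf, seed = 13)
  n_hi <- table(hi$subject_id); n_lo <- table(lo$subject_id)
  expect_true(all(n_lo[names(n_hi)] <= n_hi))
  # no threshold: every subject observed on the full grid
  expect_true(all(table(inf$subject_id) ==
                    length(observation_days(d_inf))))
})

test_that("treatment separates the arms and vanishing noise recovers the model curve", {
  spec <- default_population_spec()
  coh <- generate_cohort(spec, cohort_design(horizon = 21), seed = 31)
  m7 <- tapply(coh$volume_mm3[coh$time_day == 7],
               coh$group[coh$time_day == 7], mean)
  expect_lt(m7[["treated"]], m7[["control"]])
  # noise-free, homogeneous population: observations equal the solution
  spec0 <- population_spec(spec$model, exp(spec$mu), omega = 0,
                           error = error_params(1e-9, 1e-12),
                           regimen = spec$regimen)
  coh0 <- generate_cohort(spec0, cohort_design(n_control = 1, n_treated = 1,
                                               horizon = 14), seed = 3)
  trt <- coh0[coh0$group == "treated", ]
  pred <- solve_dde(exp(spec$mu), spec$regimen, trt$time_day)$volume
  expect_equal(trt$volume_mm3, pred, tolerance = 1e-6)
})
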