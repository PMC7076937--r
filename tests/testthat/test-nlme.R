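fast_ctl <- function(...) saem_control("fast", n_burn = 25, n_smooth = 15,
                                       n_is = 100, ...)

test_that("individual log-likelihood matches direct normal-density arithmetic", {
  # frozen fixture: saturating Gompertz subject, 3 time points; expected
  # value computed independently from the closed form and dnorm
  subj <- data.frame(time_day = c(0, 3, 7), volume_mm3 = c(110, 140, 260))
  phi <- c(a = 0.1, beta = 1 / 2500, V0 = 100)
  ll <- individual_loglik(subj, phi, "gompertz", error_params(15, 0.08))
  expect_equal(ll, -26.9676991343028, tolerance = 1e-8)
  # zero residual: density is the normalization constant, and doubling
  # the conditional sd costs exactly log 2
  f0 <- 320
  s1 <- data.frame(time_day = 5, volume_mm3 = f0)
  p0 <- c(lambda0 = 0.2, lambda1 = 1e6, V0 = f0 * exp(-0.2 * 5))
  l1 <- individual_loglik(s1, p0, "simeoni", error_params(10, 0))
  expect_equal(l1, -0.5 * log(2 * pi * 100), tolerance = 1e-4)
  l2 <- individual_loglik(s1, p0, "simeoni", error_params(20, 0))
  expect_equal(l1 - l2, log(2), tolerance = 1e-4)
})

test_that("Omega = 0 fit equals direct shared-parameter maximum likelihood", {
  coh <- small_cohort(seed = 61, n_control = 1, n_treated = 0,
                      horizon = 21)
  fit <- tgi_nlme(coh, "gompertz", control = fast_ctl(),
                  random_effects = FALSE)
  # independent oracle: optimize the closed-form objective directly
  s <- coh[order(coh$time_day), ]
  obj <- function(par) {
    f <- classic_volume(s$time_day,
                        list(model_name = "gompertz", a = -exp(par[1]),
                             beta = exp(par[2]), V0 = exp(par[3])))
    -sum(dnorm(s$volume_mm3, f, exp(par[4]) + exp(par[5]) * f, log = TRUE))
  }
  o <- nlminb(log(c(0.1, 1 / (2 * max(s$volume_mm3)), s$volume_mm3[1],
                    10, 0.1)), obj)
  expect_equal(fit$minus2LL, 2 * o$objective, tolerance = 1e-4)
  expect_equal(unname(exp(fit$mu_hat)), unname(exp(o$par[1:3])),
               tolerance = 0.02)
  # exact collapsed likelihood: -2 sum of individual log-likelihoods
  ll <- sum(vapply(unique(coh$subject_id), function(id)
    individual_loglik(coh[coh$subject_id == id, ], exp(fit$mu_hat),
                      "gompertz", fit$error_hat), 0))
  expect_equal(fit$minus2LL, -2 * ll, tolerance = 1e-6)
  m2 <- estimate_minus2LL(fit)
  expect_equal(as.numeric(m2), -2 * ll, tolerance = 1e-6)
  expect_identical(attr(m2, "se"), 0)
})

test_that("noise-free homogeneous data recover the generating parameters", {
  spec <- default_population_spec()
  spec0 <- population_spec("simeoni",
                           c(lambda0 = 0.25, lambda1 = 120, V0 = 200),
                           omega = 1e-8, error = error_params(0.05, 1e-8),
                           regimen = dose_regimen(0))
  coh <- generate_cohort(spec0, cohort_design(n_control = 4, n_treated = 0,
                                              horizon = 28), seed = 5)
  fit <- tgi_nlme(coh, "simeoni", control = fast_ctl(),
                  random_effects = FALSE)
  expect_equal(unname(exp(fit$mu_hat)), c(0.25, 120, 200),
               tolerance = 0.01)
  # fitted curves reproduce the observations to < 0.1 %
  fv <- fitted(fit)
  expect_lt(max(abs(fv$fitted - fv$observed) / fv$observed), 1e-3)
})

test_that("SAEM is a deterministic function of data, settings and seed", {
  coh <- small_cohort(seed = 62, n_control = 3, n_treated = 2,
                      horizon = 14)
  f1 <- tgi_nlme(coh, "simeoni-1", control = fast_ctl(), seed = 77,
                 compute_loglik = FALSE)
  f2 <- tgi_nlme(coh, "simeoni-1", control = fast_ctl(), seed = 77,
                 compute_loglik = FALSE)
  expect_identical(f1$mu_hat, f2$mu_hat)
  expect_identical(f1$Omega_hat, f2$Omega_hat)
  expect_identical(f1$individual_phi, f2$individual_phi)
  f3 <- tgi_nlme(coh, "simeoni-1", control = fast_ctl(), seed = 78,
                 compute_loglik = FALSE)
  expect_false(identical(f1$mu_hat, f3$mu_hat))
})

test_that("smoothed complete-data objective does not decay after burn-in", {
  coh <- small_cohort(seed = 63, n_control = 5, n_treated = 0,
                      horizon = 21)
  fit <- tgi_nlme(coh, "simeoni",
                  control = saem_control("fast", n_burn = 60,
                                         n_smooth = 60, n_is = 100),
                  seed = 3, compute_loglik = FALSE)
  cdll <- fit$diagnostics$trace[, "cdll"]
  sm <- cdll[61:120]
  expect_gt(mean(tail(sm, 15)), mean(head(sm, 15)) - 2)
})

test_that("empirical-Bayes modes depend only on the subject's own data", {
  coh <- small_cohort(seed = 64, n_control = 4, n_treated = 0,
                      horizon = 14)
  fit <- tgi_nlme(coh, "simeoni", control = fast_ctl(), seed = 5,
                  compute_loglik = FALSE)
  parts_all <- tgimix:::.cohort_parts(coh)
  sub <- coh[coh$subject_id %in% unique(coh$subject_id)[c(3, 1)], ]
  class(sub) <- class(coh)
  attr(sub, "regimens") <- attr(coh, "regimens")
  parts_sub <- tgimix:::.cohort_parts(sub)
  mu <- fit$mu_hat; om2 <- diag(fit$Omega_hat)
  L0 <- matrix(rep(mu, each = parts_all$N), parts_all$N,
               dimnames = list(NULL, names(mu)))
  eb_all <- tgimix:::.eb_modes(parts_all, fit$model, mu, om2,
                               fit$error_hat$a, fit$error_hat$b, L0,
                               1e-6, 1e-6)
  L0s <- L0[1:2, , drop = FALSE]
  eb_sub <- tgimix:::.eb_modes(parts_sub, fit$model, mu, om2,
                               fit$error_hat$a, fit$error_hat$b, L0s,
                               1e-6, 1e-6)
  expect_equal(unname(eb_sub$phi[1, ]),
               unname(eb_all$phi[match(parts_sub$ids[1], parts_all$ids), ]),
               tolerance = 1e-6)
})

test_that("importance-sampling marginal likelihood matches 1-D quadrature", {
  # toy: y_j = phi * t_j + N(0, sigma^2), phi = exp(l), l ~ N(mu, om^2)
  tt <- c(1, 2, 3)
  yy <- c(2.3, 3.9, 6.2)
  sig <- 0.5
  mu <- log(2); om <- 0.3
  ll1 <- function(l) sum(dnorm(yy, exp(l) * tt, sig, log = TRUE))
  oracle <- log(integrate(function(l)
    exp(vapply(l, ll1, 0)) * dnorm(l, mu, om), mu - 8 * om, mu + 8 * om,
    rel.tol = 1e-12)$value)
  mode <- optimize(function(l) ll1(l) + dnorm(l, mu, om, log = TRUE),
                   c(mu - 3, mu + 3), maximum = TRUE)$maximum
  ll_fun <- function(L, subj) vapply(seq_len(nrow(L)),
                                     function(r) ll1(L[r, 1]), 0)
  # proposal scaled to the posterior curvature at the mode
  h <- 1e-4
  post <- function(l) ll1(l) + dnorm(l, mu, om, log = TRUE)
  curv <- (post(mode + h) + post(mode - h) - 2 * post(mode)) / h^2
  sd_post <- 1 / sqrt(-curv)
  set.seed(123)
  res <- tgimix:::.importance_logp(ll_fun, matrix(mode, 1, 1),
                                   matrix(sd_post, 1, 1), mu, om^2,
                                   n_is = 20000)
  expect_equal(res$logp, oracle, tolerance = 2e-3)
  expect_lt(res$se_log, 0.005)
})

test_that("Monte-Carlo error of the -2LL estimate shrinks with more draws", {
  coh <- small_cohort(seed = 65, n_control = 3, n_treated = 0,
                      horizon = 14)
  fit <- tgi_nlme(coh, "simeoni", control = fast_ctl(), seed = 9,
                  compute_loglik = FALSE)
  m_small <- estimate_minus2LL(fit, n_is = 150, seed = 21)
  m_big <- estimate_minus2LL(fit, n_is = 1500, seed = 22)
  expect_lt(attr(m_big, "se"), attr(m_small, "se"))
  expect_equal(as.numeric(m_small), as.numeric(m_big),
               tolerance = 10 * attr(m_small, "se") /
                 abs(as.numeric(m_big)))
})

test_that("fit methods expose coherent summaries, predictions and residuals", {
  coh <- small_cohort(seed = 66, n_control = 3, n_treated = 2,
                      horizon = 14)
  fit <- tgi_nlme(coh, "delay", control = fast_ctl(), seed = 2)
  expect_s3_class(fit, "tgi_nlme")
  co <- coef(fit)
  expect_named(co$typical, c("lambda0", "lambda1", "V0", "k1", "k2", "t2"))
  expect_true(all(co$typical > 0))
  expect_equal(attr(logLik(fit), "df"), fit$k)
  expect_identical(fit$k, 14L)
  pr <- predict(fit, times = 0:10)
  expect_identical(nrow(pr), 5L * 11L)
  expect_true(all(is.finite(pr$predicted_volume)))
  res <- residuals(fit)
  expect_length(res, nrow(coh))
  expect_lt(abs(median(res)), 1.5)
  sim <- simulate(fit, seed = 4)
  expect_s3_class(sim, "tgi_cohort")
  expect_identical(length(unique(sim$subject_id)), 5L)
  out <- capture.output({ print(fit); print(summary(fit)) })
  expect_true(any(grepl("delay", out)))
})
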