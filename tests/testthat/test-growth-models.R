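test_that("tumor growth function has the right value and regime limits", {
  # frozen value from arbitrary-precision evaluation of the closed formula
  expect_equal(tgf(1000, 1000, 0.3, 150, 20), 149.999992847446,
               tolerance = 1e-12)
  # no cells, no growth
  expect_identical(tgf(0, 0, 0.3, 150, 20), 0)
  # small-V limit: relative rate -> lambda0
  expect_equal(tgf(1e-6, 1e-6, 0.25, 120, 20) / 1e-6, 0.25,
               tolerance = 0.01)
  # large-V limit: absolute rate -> lambda1
  expect_equal(tgf(1e9, 1e9, 0.25, 120, 20), 120, tolerance = 0.01)
  # huge volumes must not overflow the power term
  expect_true(is.finite(tgf(1e30, 1e30, 0.25, 120, 20)))
  expect_error(tgf(NaN, 1, 0.25, 120, 20), "finite")
  expect_error(tgf(1, 1, -0.1, 120, 20), "lambda0")
})

test_that("drug concentration follows first-order elimination after the bolus", {
  reg <- dose_regimen(2, dose_time = 1, ke = log(2))
  expect_identical(drug_concentration(0.5, reg), 0)
  expect_equal(drug_concentration(1, reg), 2)
  expect_equal(drug_concentration(2, reg), 1)       # half-life identity
  ctrl <- dose_regimen(0)
  expect_identical(drug_concentration(c(-1, 0, 5), ctrl), c(0, 0, 0))
  expect_error(dose_regimen(-1), "dose_amount")
  expect_error(dose_regimen(1, 0, ke = 0), "ke")
})

test_that("caliper volume rule is L * W^2 / 2 with L >= W", {
  expect_equal(caliper_volume(10, 5), 125)
  expect_equal(caliper_volume(2, 1), 1)
  expect_equal(caliper_volume(3, 3), 27 / 2)  # boundary L = W
  expect_error(caliper_volume(5, 10), "width exceeds length")
  expect_error(caliper_volume(5, 0), "width")
})

test_that("transit-chain derivatives telescope to TGF minus terminal outflow", {
  reg <- dose_regimen(1, 0, 1)
  set.seed(4)
  for (rep in 1:10) {
    n_tr <- sample(1:4, 1)
    p <- list(lambda0 = runif(1, 0.1, 0.5), lambda1 = runif(1, 50, 200),
              psi = 20, k1 = runif(1, 0, 2), k2 = runif(1, 0.1, 1),
              n_transit = n_tr)
    state <- runif(n_tr + 1, 0, 800)
    t <- runif(1, 0, 10)
    d <- simeoni_rhs(t, state, p, reg)
    g <- tgf(state[1], sum(state), p$lambda0, p$lambda1, p$psi)
    # mass balance: d/dt sum(Z) = TGF - k2 * Z_last
    expect_equal(sum(d), g - p$k2 * state[n_tr + 1], tolerance = 1e-12)
  }
})

test_that("transit chain truncates correctly and stays empty without drug", {
  p <- list(lambda0 = 0.25, lambda1 = 120, psi = 20, k1 = 1, k2 = 0.5,
            n_transit = 1)
  d <- simeoni_rhs(2, c(300, 50), p, dose_regimen(1, 0, 1))
  expect_length(d, 2)
  conc <- drug_concentration(2, dose_regimen(1, 0, 1))
  expect_equal(d[2], 1 * conc * 300 - 0.5 * 50)
  # no drug: chain compartments stay empty
  p3 <- modifyList(p, list(n_transit = 3))
  d0 <- simeoni_rhs(1, c(400, 0, 0, 0), p3, dose_regimen(0))
  expect_equal(d0[-1], c(0, 0, 0))
  expect_equal(d0[1], tgf(400, 400, 0.25, 120, 20))
  expect_error(simeoni_rhs(0, c(1, 0, 0), p, dose_regimen(0)),
               "state length")
})

test_that("delay derivatives reduce to the one-transit chain at t2 = 0", {
  reg <- dose_regimen(1, 0, 1)
  p <- list(lambda0 = 0.3, lambda1 = 100, psi = 20, k1 = 0.8, k2 = 0.6,
            t2 = 0)
  state <- c(250, 40)
  d_delay <- delay_rhs(1.5, state, Z2_lagged = state[2], p, reg)
  d_ode <- simeoni_rhs(1.5, state, modifyList(p, list(n_transit = 1)), reg)
  expect_equal(d_delay, d_ode, tolerance = 1e-14)
  # zero history before the delay has elapsed: no elimination yet
  d_early <- delay_rhs(0.5, state, Z2_lagged = 0,
                       modifyList(p, list(t2 = 2)), reg)
  conc <- drug_concentration(0.5, reg)
  expect_equal(d_early[2], 0.8 * conc * 250)
  expect_error(delay_rhs(0, state, 0, modifyList(p, list(t2 = -1)), reg),
               "negative lag")
})

test_that("classic closed forms satisfy initial conditions and asymptotes", {
  gl <- list(model_name = "generalized_logistic", a = 0.3, K = 2000,
             nu = 0.8, V0 = 150)
  go <- list(model_name = "gompertz", a = -0.1, beta = 1 / 2500, V0 = 150)
  vb <- list(model_name = "von_bertalanffy", a = 3, b = 0.2, gamma = 2 / 3,
             V0 = 150)
  expect_equal(classic_volume(0, gl), 150)
  expect_equal(classic_volume(0, go), 150)
  expect_equal(classic_volume(0, vb), 150)
  expect_equal(classic_volume(500, gl), 2000, tolerance = 1e-8)
  expect_equal(classic_volume(500, go), 2500, tolerance = 1e-6)
  expect_equal(classic_volume(500, vb), (3 / 0.2)^3, tolerance = 1e-8)
  expect_error(classic_volume(1, list(model_name = "exponential", V0 = 1)),
               "unknown model_name")
  expect_error(classic_volume(-1, gl), "t must be")
})

test_that("Gompertz closed form matches high-accuracy integration at a fixed point", {
  # frozen: adaptive solve of dV/dt = 0.1 V ln(V/2500) at rtol/atol 1e-12
  p <- list(model_name = "gompertz", a = 0.1, beta = 1 / 2500, V0 = 100)
  expect_equal(classic_volume(10, p), 0.396227930219358, tolerance = 1e-9)
})

test_that("model constructor parses ids and rejects invalid ones", {
  m <- tgi_model("simeoni-3")
  expect_identical(m$n_transit, 3L)
  expect_identical(m$n_state, 4L)
  expect_identical(tgi_model("simeoni")$param_names,
                   c("lambda0", "lambda1", "V0"))
  expect_identical(tgi_model("delay")$param_names,
                   c("lambda0", "lambda1", "V0", "k1", "k2", "t2"))
  expect_error(tgi_model("simeoni-0"), "n_transit")
  expect_error(tgi_model("weibull"), "unknown model id")
  expect_error(tgi_model("delay", psi = 0.5), "psi")
})
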