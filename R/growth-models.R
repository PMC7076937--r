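#' Tumor growth function (biphasic exponential-to-linear growth)
#'
#' Growth rate of the proliferating compartment: exponential with rate
#' `lambda0` while the total volume is small, switching smoothly to linear
#' growth with slope `lambda1` as the tumor grows, with switching sharpness
#' `psi`:
#' \deqn{TGF = \frac{\lambda_0 Z_1}{[1 + ((\lambda_0/\lambda_1) V)^\psi]^{1/\psi}}}
#'
#' The relative growth rate tends to `lambda0` as `V -> 0` and the absolute
#' rate tends to `lambda1` as `V -> Inf` (when `Z1 = V`).  Evaluation is done
#' in log space so large `V` cannot overflow the power term.
#'
#' @param Z1 proliferating-compartment volume (mm^3), `>= 0`.
#' @param V total tumor volume (mm^3), `V >= Z1`.
#' @param lambda0 first-order growth rate (1/day), `> 0`.
#' @param lambda1 linear growth rate (mm^3/day), `> 0`.
#' @param psi switching sharpness (dimensionless), `>= 1`.
#' @return Growth rate in mm^3/day (vectorized over `Z1`/`V`).
#' @examples
#' tgf(100, 100, 0.25, 120, 20)       # near-exponential regime: ~ 0.25 * 100
#' tgf(5000, 5000, 0.25, 120, 20)     # linear regime: ~ 120
#' @export
tgf <- function(Z1, V, lambda0, lambda1, psi) {
  if (!all(is.finite(Z1), is.finite(V), is.finite(lambda0),
           is.finite(lambda1), is.finite(psi)))
    stop("tgf(): all inputs must be finite")
  if (lambda0 <= 0 || lambda1 <= 0 || psi < 1)
    stop("tgf(): require lambda0 > 0, lambda1 > 0, psi >= 1")
  if (any(Z1 < 0) || any(V < -1e-12))
    stop("tgf(): negative state")
  u <- (lambda0 / lambda1) * pmax(V, 0)
  lp <- psi * log(u)
  denom <- ifelse(u <= 0, 1,
           ifelse(lp > 700, u, exp(log1p(exp(pmin(lp, 700))) / psi)))
  rate <- lambda0 * Z1 / denom
  rate[Z1 == 0] <- 0
  rate
}

#' Dosing regimen: single bolus with first-order elimination
#'
#' The drug concentration is `dose_amount * exp(-ke * (t - dose_time))` for
#' `t >= dose_time` and 0 before.  Dose is in arbitrary concentration units
#' (the kill constant `k1` of the structural models absorbs the scale); an
#' untreated subject is a regimen with `dose_amount = 0`.
#'
#' @param dose_amount administered amount (arbitrary units), `>= 0`.
#' @param dose_time day of the bolus (days).
#' @param ke first-order elimination rate (1/day), `> 0`.
#' @return An object of class `dose_regimen`.
#' @examples
#' reg <- dose_regimen(1, 0, ke = log(2))  # half-life of one day
#' drug_concentration(1, reg)              # 0.5
#' @export
dose_regimen <- function(dose_amount = 1, dose_time = 0, ke = 1) {
  if (!is.finite(dose_amount) || dose_amount < 0)
    stop("dose_regimen(): dose_amount must be finite and >= 0")
  if (!is.finite(ke) || ke <= 0)
    stop("dose_regimen(): ke must be finite and > 0")
  if (!is.finite(dose_time))
    stop("dose_regimen(): dose_time must be finite")
  structure(list(dose_amount = dose_amount, dose_time = dose_time, ke = ke),
            class = "dose_regimen")
}

#' @export
print.dose_regimen <- function(x, ...) {
  if (x$dose_amount == 0)
    cat("Dose regimen: untreated (no dose)\n")
  else
    cat(sprintf("Dose regimen: bolus %.3g at day %.3g, elimination ke = %.3g /day\n",
                x$dose_amount, x$dose_time, x$ke))
  invisible(x)
}

#' Drug concentration at time t
#'
#' @param t time in days (vectorized).
#' @param regimen a [dose_regimen()].
#' @return Concentration in the same arbitrary units as `dose_amount`.
#' @export
drug_concentration <- function(t, regimen) {
  stopifnot(inherits(regimen, "dose_regimen"))
  ifelse(t >= regimen$dose_time,
         regimen$dose_amount * exp(-regimen$ke * (t - regimen$dose_time)),
         0)
}

#' Caliper (ellipsoid) tumor volume
#'
#' Approximating rule for caliper measurements, `V = L * W^2 / 2` with
#' length at least width; the tumor is taken as the rotation ellipsoid of a
#' semi-ellipse around its long axis, dropping the constant involving pi.
#'
#' @param length_mm tumor length in mm (`L >= W > 0`).
#' @param width_mm tumor width in mm.
#' @return Volume in mm^3.
#' @examples
#' caliper_volume(10, 5)  # 125
#' @export
caliper_volume <- function(length_mm, width_mm) {
  if (any(!is.finite(length_mm)) || any(!is.finite(width_mm)))
    stop("caliper_volume(): non-finite input")
  if (any(width_mm <= 0))
    stop("caliper_volume(): width must be > 0")
  if (any(width_mm > length_mm))
    stop("caliper_volume(): width exceeds length")
  length_mm * width_mm^2 / 2
}

#' Structural model constructor
#'
#' Defines a structural tumor growth model by string id:
#' \describe{
#'   \item{`"simeoni"`}{unperturbed biphasic growth (the tumor growth
#'     function alone); parameters `lambda0`, `lambda1`, `V0`.}
#'   \item{`"simeoni-1"`, `"simeoni-2"`, `"simeoni-3"`, ... (`"simeoni-<n>"`)}{
#'     transit-compartment tumor growth inhibition model with `n` damaged-cell
#'     compartments; parameters `lambda0`, `lambda1`, `V0`, `k1`, `k2`.}
#'   \item{`"delay"`}{single damaged compartment whose elimination acts on
#'     `Z2(t - t2)`; parameters `lambda0`, `lambda1`, `V0`, `k1`, `k2`, `t2`.}
#'   \item{`"generalized_logistic"`}{`dV/dt = a V (1 - (V/K)^nu)`;
#'     parameters `a`, `K`, `nu`, `V0`.}
#'   \item{`"gompertz"`}{`dV/dt = a V ln(beta V)`; fitted in the saturating
#'     orientation with carrying capacity `1/beta` (see Details);
#'     parameters `a`, `beta`, `V0`.}
#'   \item{`"von_bertalanffy"`}{`dV/dt = a V^gamma - b V`;
#'     parameters `a`, `b`, `gamma`, `V0`.}
#' }
#'
#' @details The switching sharpness `psi` of the tumor growth function is a
#' model-level constant (default 20) rather than an estimated parameter: it
#' is weakly identifiable from volume data.  For the Gompertz law, growth
#' toward a plateau requires a negative rate constant in the literal form
#' `a V ln(beta V)`; because the estimation layer makes all parameters
#' log-normal (positive), the fitted model uses
#' `V(t) = (1/beta) (beta V0)^{exp(-a t)}`, the same law with the sign
#' absorbed into `a`, so the estimated `a > 0` is the relaxation rate toward
#' the carrying capacity `1/beta`.
#'
#' @param name model id string (see above).
#' @param psi switching sharpness of the tumor growth function (ignored by
#'   the classic laws).
#' @return An object of class `tgi_model`.
#' @examples
#' tgi_model("simeoni-3")
#' tgi_model("delay")
#' @export
tgi_model <- function(name, psi = 20) {
  classic <- c("generalized_logistic", "gompertz", "von_bertalanffy")
  if (grepl("^simeoni-[0-9]+$", name)) {
    n_tr <- as.integer(sub("^simeoni-", "", name))
    if (n_tr < 1) stop("tgi_model(): transit-chain model needs n_transit >= 1")
    kind <- "transit"
  } else if (name == "simeoni") {
    n_tr <- 0L
    kind <- "tgf"
  } else if (name == "delay") {
    n_tr <- 1L
    kind <- "delay"
  } else if (name %in% classic) {
    n_tr <- 0L
    kind <- "classic"
  } else {
    stop("tgi_model(): unknown model id '", name, "'")
  }
  if (!is.finite(psi) || psi < 1) stop("tgi_model(): psi must be >= 1")
  param_names <- switch(kind,
    tgf     = c("lambda0", "lambda1", "V0"),
    transit = c("lambda0", "lambda1", "V0", "k1", "k2"),
    delay   = c("lambda0", "lambda1", "V0", "k1", "k2", "t2"),
    classic = switch(name,
      generalized_logistic = c("a", "K", "nu", "V0"),
      gompertz             = c("a", "beta", "V0"),
      von_bertalanffy      = c("a", "b", "gamma", "V0")))
  structure(list(name = name, kind = kind, n_transit = n_tr, psi = psi,
                 param_names = param_names,
                 n_state = if (kind == "classic") 1L else 1L + n_tr),
            class = "tgi_model")
}

#' @export
print.tgi_model <- function(x, ...) {
  cat(sprintf("Structural model '%s' (%s)\n", x$name,
              switch(x$kind,
                     tgf = "unperturbed biphasic growth",
                     transit = sprintf("transit-compartment TGI, %d damaged compartment(s)",
                                       x$n_transit),
                     delay = "delayed-elimination TGI (constant-lag DDE)",
                     classic = "classic growth law, analytic solution")))
  cat("  parameters:", paste(x$param_names, collapse = ", "))
  if (x$kind != "classic") cat(sprintf("  (psi fixed at %.3g)", x$psi))
  cat("\n")
  invisible(x)
}

.as_tgi_model <- function(model) {
  if (inherits(model, "tgi_model")) model else tgi_model(model)
}

#' Transit-compartment system right-hand side (reference R implementation)
#'
#' Derivatives of the transit-compartment tumor growth inhibition system:
#' the proliferating compartment grows by the tumor growth function and
#' loses cells to drug kill at rate `k1 * c(t) * Z1`; damaged cells pass
#' through the transit chain at rate `k2` before elimination.  Total volume
#' is the sum of all compartments.  This is the plain-R reference used to
#' validate the compiled solver; [solve_ode()] uses compiled code.
#'
#' @param t time (days).
#' @param state numeric state vector `c(Z1, Z2, ..., Z_{1+n_transit})`.
#' @param params named list/vector with `lambda0`, `lambda1`, `psi`, `k1`,
#'   `k2`, `n_transit`.
#' @param regimen a [dose_regimen()].
#' @return Numeric vector of derivatives, same length as `state`.
#' @export
simeoni_rhs <- function(t, state, params, regimen) {
  p <- as.list(params)
  n_tr <- as.integer(p$n_transit)
  if (length(state) != 1L + n_tr)
    stop("simeoni_rhs(): state length must be 1 + n_transit")
  V <- sum(state)
  conc <- drug_concentration(t, regimen)
  g <- tgf(state[1], V, p$lambda0, p$lambda1, p$psi)
  kill <- p$k1 * conc * state[1]
  d <- numeric(length(state))
  d[1] <- g - kill
  if (n_tr >= 1) {
    d[2] <- kill - p$k2 * state[2]
    if (n_tr >= 2)
      for (j in 3:(n_tr + 1)) d[j] <- p$k2 * (state[j - 1] - state[j])
  }
  d
}

#' Delayed-elimination system right-hand side (reference R implementation)
#'
#' Derivatives of the delay variant: a single damaged compartment whose
#' elimination term acts on the lagged state `Z2(t - t2)` supplied by the
#' DDE integrator; history is `Z2 = 0` before the start of integration.
#' With `t2 = 0` this coincides with the one-transit-compartment system.
#'
#' @param t time (days).
#' @param state numeric `c(Z1, Z2)`.
#' @param Z2_lagged history value `Z2(t - t2)`.
#' @param params named list/vector with `lambda0`, `lambda1`, `psi`, `k1`,
#'   `k2`, `t2`.
#' @param regimen a [dose_regimen()].
#' @return Numeric vector `c(dZ1, dZ2)`.
#' @export
delay_rhs <- function(t, state, Z2_lagged, params, regimen) {
  p <- as.list(params)
  if (p$t2 < 0) stop("delay_rhs(): negative lag")
  if (length(state) != 2L) stop("delay_rhs(): state must be (Z1, Z2)")
  V <- sum(state)
  conc <- drug_concentration(t, regimen)
  g <- tgf(state[1], V, p$lambda0, p$lambda1, p$psi)
  kill <- p$k1 * conc * state[1]
  c(g - kill, kill - p$k2 * Z2_lagged)
}

#' Closed-form solutions of the classic growth laws
#'
#' Analytic solution at time `t` of the named growth ODE with `V(0) = V0`:
#' \describe{
#'   \item{generalized logistic}{`dV/dt = a V (1 - (V/K)^nu)`, solution
#'     `K / (1 + ((K/V0)^nu - 1) exp(-a nu t))^{1/nu}`.}
#'   \item{Gompertz}{`dV/dt = a V ln(beta V)`, solution
#'     `(1/beta) (beta V0)^{exp(a t)}` (literal form: `a` may be negative,
#'     in which case `1/beta` is a carrying capacity).}
#'   \item{von Bertalanffy}{`dV/dt = a V^gamma - b V` with `0 < gamma < 1`,
#'     solution `(a/b + (V0^{1-gamma} - a/b) exp(-b (1-gamma) t))^{1/(1-gamma)}`.}
#' }
#'
#' @param t time(s) in days, `>= 0`.
#' @param params named list with `model_name` plus the law's parameters
#'   (see [tgi_model()]).
#' @return Volume(s) in mm^3.
#' @examples
#' classic_volume(0:5, list(model_name = "generalized_logistic",
#'                          a = 0.3, K = 2000, nu = 1, V0 = 100))
#' @export
classic_volume <- function(t, params) {
  p <- as.list(params)
  if (any(t < 0)) stop("classic_volume(): t must be >= 0")
  if (is.null(p$model_name)) stop("classic_volume(): params$model_name missing")
  if (is.null(p$V0) || p$V0 <= 0) stop("classic_volume(): V0 must be > 0")
  switch(p$model_name,
    generalized_logistic = {
      if (p$a <= 0 || p$K <= 0 || p$nu <= 0)
        stop("classic_volume(): require a, K, nu > 0")
      p$K * (1 + ((p$K / p$V0)^p$nu - 1) * exp(-p$a * p$nu * t))^(-1 / p$nu)
    },
    gompertz = {
      if (p$beta <= 0) stop("classic_volume(): require beta > 0")
      # log V = -log(beta) + exp(a t) * log(beta V0)
      exp(-log(p$beta) + exp(p$a * t) * log(p$beta * p$V0))
    },
    von_bertalanffy = {
      if (p$a <= 0 || p$b <= 0 || p$gamma <= 0 || p$gamma >= 1)
        stop("classic_volume(): require a, b > 0 and 0 < gamma < 1")
      m <- 1 - p$gamma
      (p$a / p$b + (p$V0^m - p$a / p$b) * exp(-p$b * m * t))^(1 / m)
    },
    stop("classic_volume(): unknown model_name '", p$model_name, "'"))
}
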