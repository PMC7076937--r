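# Synthetic preclinical cohorts: log-normal inter-individual variability,
# combined additive + proportional residual error, near-daily sampling with
# weekend gaps, and euthanasia-threshold censoring.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Residual error model parameters
#'
#' Combined additive + proportional residual error: an observation with
#' model prediction `f` is `y = f + (a + b f) e`, `e ~ N(0, sigma^2)`.
#' `sigma` defaults to 1 with the scale absorbed into `a` and `b`, which
#' removes the `a sigma`/`b sigma` indeterminacy of the three-parameter
#' form.
#'
#' @param a additive residual scale (mm^3), `>= 0`.
#' @param b proportional residual scale (dimensionless), `>= 0`; `a` and
#'   `b` must not both be 0.
#' @param sigma standard deviation of the standardized residual.
#' @return An object of class `error_params`.
#' @export
error_params <- function(a = 20, b = 0.1, sigma = 1) {
  if (a < 0 || b < 0 || (a == 0 && b == 0))
    stop("error_params(): need a >= 0, b >= 0, not both 0")
  if (sigma <= 0) stop("error_params(): sigma must be > 0")
  structure(list(a = a, b = b, sigma = sigma), class = "error_params")
}

#' @export
print.error_params <- function(x, ...) {
  cat(sprintf("Residual error: y = f + (%.4g + %.4g f) e, e ~ N(0, %.3g^2)\n",
              x$a, x$b, x$sigma))
  invisible(x)
}

#' Population specification for simulation
#'
#' Describes the population distribution of individual parameters:
#' `phi_i = exp(mu + lambda_i)`, `lambda_i ~ N(0, Omega)` (all structural
#' parameters log-normally distributed across subjects), plus the residual
#' error model and the treated-arm dosing regimen.
#'
#' @param model a [tgi_model()] or model id string.
#' @param typical named vector of typical (median) parameter values on the
#'   natural scale; `mu = log(typical)`.
#' @param omega named vector of log-scale standard deviations (recycled if
#'   scalar), or a full positive-semidefinite covariance matrix `Omega`.
#' @param error an [error_params()].
#' @param regimen a [dose_regimen()] for treated subjects.
#' @return An object of class `population_spec` with elements `model`,
#'   `mu`, `Omega`, `error`, `regimen`.
#' @seealso [default_population_spec()] for the packaged study conditions.
#' @export
population_spec <- function(model, typical, omega, error = error_params(),
                            regimen = dose_regimen(1, 0, 1)) {
  model <- .as_tgi_model(model)
  pn <- model$param_names
  typical <- unlist(typical)[pn]
  if (any(is.na(typical)) || any(typical <= 0))
    stop("population_spec(): typical values must be positive and cover: ",
         paste(pn, collapse = ", "))
  p <- length(pn)
  if (is.matrix(omega)) {
    Omega <- omega
    if (nrow(Omega) != p || ncol(Omega) != p)
      stop("population_spec(): Omega must be ", p, " x ", p)
    if (max(abs(Omega - t(Omega))) > 1e-10)
      stop("population_spec(): Omega must be symmetric")
  } else {
    omega <- if (length(omega) == 1L) rep(omega, p) else unlist(omega)[pn]
    if (any(is.na(omega)) || any(omega < 0))
      stop("population_spec(): omega must be named non-negative sds")
    Omega <- diag(omega^2, p)
  }
  dimnames(Omega) <- list(pn, pn)
  ev <- eigen(Omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("population_spec(): Omega is not positive semi-definite")
  stopifnot(inherits(error, "error_params"), inherits(regimen, "dose_regimen"))
  structure(list(model = model, mu = log(typical), Omega = Omega,
                 error = error, regimen = regimen),
            class = "population_spec")
}

#' Default synthetic study population
#'
#' The packaged stand-in for a cisplatin mammary-tumor mouse study:
#' the delayed-elimination structural model with typical values
#' `lambda0 = 0.25`/day, `lambda1 = 120` mm^3/day, `V0 = 200` mm^3,
#' `k1 = 1` per concentration-unit-day, `k2 = 0.5`/day, `t2 = 2` days,
#' log-scale sds (0.3, 0.3, 0.5, 0.4, 0.3, 0.2), residual error
#' `a = 20` mm^3, `b = 0.1`, and a unit bolus at day 0 with elimination
#' `ke = 1`/day.  Untreated arms simulated from this specification (dose 0)
#' follow the pure biphasic growth function with the same growth
#' parameters.
#'
#' @return A [population_spec()].
#' @export
default_population_spec <- function() {
  population_spec(
    model   = "delay",
    typical = c(lambda0 = 0.25, lambda1 = 120, V0 = 200,
                k1 = 1, k2 = 0.5, t2 = 2),
    omega   = c(lambda0 = 0.3, lambda1 = 0.3, V0 = 0.5,
                k1 = 0.4, k2 = 0.3, t2 = 0.2),
    error   = error_params(a = 20, b = 0.1),
    regimen = dose_regimen(1, 0, 1))
}

#' @export
print.population_spec <- function(x, ...) {
  cat("Population specification\n")
  print(x$model)
  tab <- rbind(typical = exp(x$mu), omega = sqrt(diag(x$Omega)))
  print(round(tab, 4))
  print(x$error)
  print(x$regimen)
  invisible(x)
}

#' Draw individual parameters from a population
#'
#' Samples `phi_i = exp(mu + lambda_i)` with `lambda_i ~ N(0, Omega)`
#' i.i.d. across subjects (componentwise exponentiation; all parameters
#' positive by construction).
#'
#' @param spec a [population_spec()].
#' @param n_subjects number of draws.
#' @param seed optional integer seed (the draw is reproducible given the
#'   seed; the caller's RNG state is untouched).
#' @return `n_subjects x p` matrix of natural-scale parameters with the
#'   log-scale random effects attached as attribute `"lambda"`.
#' @export
sample_individual_params <- function(spec, n_subjects, seed = NULL) {
  stopifnot(inherits(spec, "population_spec"))
  .with_seed(seed, {
    p <- length(spec$mu)
    ed <- eigen(spec$Omega, symmetric = TRUE)
    rt <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), p)
    lambda <- matrix(rnorm(n_subjects * p), n_subjects, p) %*% t(rt)
    colnames(lambda) <- names(spec$mu)
    phi <- exp(sweep(lambda, 2, spec$mu, `+`))
    attr(phi, "lambda") <- lambda
    phi
  })
}

#' Apply the residual error model to predicted volumes
#'
#' Observed volume `y = f + (a + b f) e`, `e ~ N(0, sigma^2)`.  Non-positive
#' draws are handled per `positive`: resampled until positive (default) or
#' truncated at a small floor.
#'
#' @param f vector of model predictions (mm^3), `>= 0`.
#' @param error an [error_params()].
#' @param positive `"resample"` or `"truncate"`.
#' @param upper optional upper bound; draws at or above it are also
#'   resampled (used for the enrollment cap on day-0 measurements).
#' @return Vector of observed volumes, same length as `f`.
#' @export
observe_volumes <- function(f, error, positive = c("resample", "truncate"),
                            upper = Inf) {
  positive <- match.arg(positive)
  stopifnot(inherits(error, "error_params"), all(f >= 0))
  sdv <- (error$a + error$b * f) * error$sigma
  y <- f + sdv * rnorm(length(f))
  if (positive == "truncate") {
    y <- pmax(y, 1e-3)
    y <- pmin(y, upper - 1e-9)
  } else {
    bad <- which(y <= 0 | y >= upper)
    tries <- 0L
    while (length(bad) && tries < 1000L) {
      y[bad] <- f[bad] + sdv[bad] * rnorm(length(bad))
      bad <- bad[y[bad] <= 0 | y[bad] >= upper]
      tries <- tries + 1L
    }
    if (length(bad))
      stop("observe_volumes(): could not draw positive observations")
  }
  y
}

#' Study design for synthetic cohorts
#'
#' Group sizes, follow-up horizon, sampling pattern and welfare rules of
#' the emulated experiment: near-daily caliper measurement with weekend
#' gaps (5 days on / 2 off, starting at day 0), all tumors below
#' `v0_cap` mm^3 at enrollment, and euthanasia once a measured volume
#' reaches `censor_volume` (that measurement is kept, later ones dropped).
#'
#' @param n_control,n_treated arm sizes.
#' @param horizon last possible observation day.
#' @param censor_volume euthanasia threshold (mm^3).
#' @param v0_cap maximum initial volume at enrollment (mm^3).
#' @param weekend_gaps drop 2 of every 7 days from the sampling grid.
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_control = 21, n_treated = 19, horizon = 42,
                          censor_volume = 2500, v0_cap = 700,
                          weekend_gaps = TRUE) {
  if (horizon <= 0) stop("cohort_design(): horizon must be > 0")
  if (n_control + n_treated < 1) stop("cohort_design(): empty design")
  structure(list(n_control = n_control, n_treated = n_treated,
                 horizon = horizon, censor_volume = censor_volume,
                 v0_cap = v0_cap, weekend_gaps = weekend_gaps),
            class = "cohort_design")
}

#' @rdname cohort_design
#' @param design a `cohort_design`.
#' @return `observation_days()`: integer vector of scheduled measurement
#'   days.
#' @export
observation_days <- function(design) {
  days <- 0:design$horizon
  if (design$weekend_gaps) days <- days[days %% 7 < 5]
  days
}

#' Generate a synthetic longitudinal cohort
#'
#' For each subject: draw individual parameters from the population
#' (redrawing any subject whose true initial volume is at or above the
#' enrollment cap), solve the structural model on the sampling grid, apply
#' the residual error model (resampling non-positive observations, and
#' keeping the day-0 measurement below the enrollment cap), and truncate
#' the series at the first observation reaching the euthanasia threshold.
#' Control subjects receive `dose_amount = 0`, so under the perturbed
#' models they follow pure biphasic growth.
#'
#' @param spec a [population_spec()].
#' @param design a [cohort_design()].
#' @param seed integer seed; the cohort is a deterministic function of
#'   `(spec, design, seed)`.
#' @param positive handling of non-positive observations, see
#'   [observe_volumes()].
#' @return A `tgi_cohort`: a data frame with columns `subject_id`, `group`,
#'   `time_day`, `volume_mm3`, with the per-subject dosing table
#'   (`attr "regimens"`), true individual parameters (`attr "phi_true"`,
#'   never used by the fitting code), and generator provenance attached as
#'   attributes.
#' @examples
#' coh <- generate_cohort(default_population_spec(),
#'                        cohort_design(n_control = 3, n_treated = 2,
#'                                      horizon = 14), seed = 1)
#' head(coh)
#' @export
generate_cohort <- function(spec, design = cohort_design(), seed,
                            positive = "resample") {
  stopifnot(inherits(spec, "population_spec"),
            inherits(design, "cohort_design"))
  .with_seed(seed, {
    n_c <- design$n_control
    n_t <- design$n_treated
    n <- n_c + n_t
    group <- rep(c("control", "treated"), c(n_c, n_t))
    ids <- c(sprintf("C%02d", seq_len(n_c)), sprintf("T%02d", seq_len(n_t)))
    phi <- sample_individual_params(spec, n)
    for (tries in seq_len(1000L)) {
      bad <- which(phi[, "V0"] >= design$v0_cap)
      if (!length(bad)) break
      phi[bad, ] <- sample_individual_params(spec, length(bad))
    }
    if (any(phi[, "V0"] >= design$v0_cap))
      stop("generate_cohort(): cannot draw V0 below the enrollment cap")
    reg <- data.frame(subject_id = ids,
                      dose_time_day = spec$regimen$dose_time,
                      dose_amount = ifelse(group == "treated",
                                           spec$regimen$dose_amount, 0),
                      ke = spec$regimen$ke)
    days <- observation_days(design)
    solver_reg <- data.frame(dose_amount = reg$dose_amount, ke = reg$ke,
                             dose_time = reg$dose_time_day)
    vols <- .predict_batch(spec$model, phi, solver_reg, days)
    # subjects whose predicted trajectory leaves the physical range
    # (possible for the literal delay system under extreme kill draws)
    # are redrawn, like the enrollment cap
    n_redrawn <- 0L
    for (tries in seq_len(50L)) {
      bad <- which(apply(vols, 2, min) < 0)
      if (!length(bad)) break
      n_redrawn <- n_redrawn + length(bad)
      for (b in bad) {
        repeat {
          phi[b, ] <- sample_individual_params(spec, 1)
          if (phi[b, "V0"] < design$v0_cap) break
        }
      }
      vols[, bad] <- .predict_batch(spec$model, phi[bad, , drop = FALSE],
                                    solver_reg[bad, , drop = FALSE], days)
    }
    if (any(vols < 0))
      stop("generate_cohort(): population spec persistently produces ",
           "negative predicted volumes")
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      f <- vols[, i]
      y <- observe_volumes(f, spec$error, positive)
      # enrollment: the day-0 measurement must sit below the cap
      y[1] <- observe_volumes(f[1], spec$error, positive,
                              upper = design$v0_cap)
      hit <- which(y >= design$censor_volume)
      keep <- if (length(hit)) seq_len(hit[1]) else seq_along(y)
      rows[[i]] <- data.frame(subject_id = ids[i], group = group[i],
                              time_day = days[keep], volume_mm3 = y[keep])
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "regimens") <- reg
    attr(out, "phi_true") <- phi
    attr(out, "spec") <- spec
    attr(out, "design") <- design
    attr(out, "seed") <- seed
    attr(out, "n_redrawn") <- n_redrawn
    class(out) <- c("tgi_cohort", "data.frame")
    out
  })
}

#' @export
print.tgi_cohort <- function(x, ...) {
  ns <- table(factor(unique(x[c("subject_id", "group")])$group,
                     levels = c("control", "treated")))
  cat(sprintf("Synthetic/longitudinal tumor cohort: %d subjects (%d control, %d treated), %d observations\n",
              length(unique(x$subject_id)), ns[["control"]], ns[["treated"]],
              nrow(x)))
  cat(sprintf("  days %g-%g, volumes %.1f-%.1f mm^3\n",
              min(x$time_day), max(x$time_day),
              min(x$volume_mm3), max(x$volume_mm3)))
  invisible(x)
}

#' @export
plot.tgi_cohort <- function(x, log = "", ...) {
  ids <- unique(x$subject_id)
  cols <- ifelse(x$group[match(ids, x$subject_id)] == "treated",
                 "firebrick", "steelblue")
  plot(x$time_day, x$volume_mm3, type = "n", xlab = "time (days)",
       ylab = expression(volume ~ (mm^3)), log = log, ...)
  for (k in seq_along(ids)) {
    s <- x[x$subject_id == ids[k], ]
    lines(s$time_day, s$volume_mm3, col = adjustcolor(cols[k], 0.6))
  }
  legend("topleft", c("control", "treated"), col = c("steelblue", "firebrick"),
         lty = 1, bty = "n")
  invisible(x)
}

#' Write / read a cohort as tidy CSV
#'
#' The main table has columns `subject_id`, `group`, `time_day`,
#' `volume_mm3`; dosing goes to a sidecar CSV with columns `subject_id`,
#' `dose_time_day`, `dose_amount`, `ke`.
#'
#' @param cohort a `tgi_cohort`.
#' @param file path of the observations CSV.
#' @param dosing_file path of the dosing sidecar CSV (default: `file` with
#'   `_dosing` inserted before the extension).
#' @return `write_cohort()`: the file path, invisibly. `read_cohort()`: a
#'   `tgi_cohort` (without true parameters; subjects absent from the dosing
#'   file are untreated).
#' @export
write_cohort <- function(cohort, file, dosing_file = NULL) {
  if (is.null(dosing_file))
    dosing_file <- sub("(\\.[^.]+)?$", "_dosing\\1", file)
  write.csv(as.data.frame(cohort)[c("subject_id", "group", "time_day",
                                    "volume_mm3")],
            file, row.names = FALSE, quote = FALSE)
  reg <- attr(cohort, "regimens")
  if (!is.null(reg))
    write.csv(reg, dosing_file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(file, dosing_file = NULL) {
  if (is.null(dosing_file)) {
    guess <- sub("(\\.[^.]+)?$", "_dosing\\1", file)
    if (file.exists(guess)) dosing_file <- guess
  }
  out <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "time_day", "volume_mm3")
  if (!all(need %in% names(out)))
    stop("read_cohort(): expected columns ", paste(need, collapse = ", "))
  ids <- unique(out$subject_id)
  if (!is.null(dosing_file)) {
    reg <- read.csv(dosing_file, stringsAsFactors = FALSE)
    reg <- reg[match(ids, reg$subject_id), ]
    reg$subject_id <- ids
    reg$dose_amount[is.na(reg$dose_amount)] <- 0
    reg$dose_time_day[is.na(reg$dose_time_day)] <- 0
    reg$ke[is.na(reg$ke)] <- 1
  } else {
    reg <- data.frame(subject_id = ids, dose_time_day = 0, dose_amount = 0,
                      ke = 1)
  }
  attr(out, "regimens") <- reg
  class(out) <- c("tgi_cohort", "data.frame")
  out
}

# Subset a cohort by arm, keeping attributes consistent.
#' Extract one arm of a cohort
#'
#' @param cohort a `tgi_cohort`.
#' @param group `"control"` or `"treated"`.
#' @return A `tgi_cohort` restricted to that arm.
#' @export
cohort_arm <- function(cohort, group = c("control", "treated")) {
  group <- match.arg(group)
  keep <- cohort$group == group
  out <- as.data.frame(cohort)[keep, , drop = FALSE]
  rownames(out) <- NULL
  ids <- unique(out$subject_id)
  reg <- attr(cohort, "regimens")
  attr(out, "regimens") <- reg[match(ids, reg$subject_id), , drop = FALSE]
  phi <- attr(cohort, "phi_true")
  if (!is.null(phi)) {
    all_ids <- attr(cohort, "regimens")$subject_id
    attr(out, "phi_true") <- phi[match(ids, all_ids), , drop = FALSE]
  }
  attr(out, "spec") <- attr(cohort, "spec")
  attr(out, "design") <- attr(cohort, "design")
  attr(out, "seed") <- attr(cohort, "seed")
  class(out) <- c("tgi_cohort", "data.frame")
  out
}
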