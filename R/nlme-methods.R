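# S3 methods for fitted population models.

#' @export
print.tgi_nlme <- function(x, ...) {
  cat(sprintf("Population tumor growth fit: model '%s'%s\n", x$model$name,
              if (x$degenerate) " (Omega = 0, shared parameters)" else ""))
  cat(sprintf("  %d subjects, %d observations\n", x$N, x$n_obs))
  tab <- rbind(typical = exp(x$mu_hat), omega = sqrt(diag(x$Omega_hat)))
  print(signif(tab, 4))
  cat(sprintf("  residual error: a = %.4g, b = %.4g\n",
              x$error_hat$a, x$error_hat$b))
  if (is.finite(x$minus2LL))
    cat(sprintf("  -2LL = %.2f (MC se %.2g), k = %d\n", x$minus2LL,
                x$minus2LL_se, x$k))
  invisible(x)
}

#' @export
summary.tgi_nlme <- function(object, ...) {
  out <- list(model = object$model$name,
              N = object$N, n_obs = object$n_obs, k = object$k,
              coef = coef(object),
              minus2LL = object$minus2LL, minus2LL_se = object$minus2LL_se,
              converged = isTRUE(object$diagnostics$converged),
              acceptance = if (!object$degenerate)
                mean(object$diagnostics$acceptance) else NA_real_,
              degenerate = object$degenerate)
  class(out) <- "summary.tgi_nlme"
  out
}

#' @export
print.summary.tgi_nlme <- function(x, ...) {
  cat(sprintf("Model '%s': %d subjects, %d observations, k = %d\n",
              x$model, x$N, x$n_obs, x$k))
  est <- rbind(`typical value` = x$coef$typical, omega = x$coef$omega)
  print(signif(est, 4))
  cat(sprintf("residual error: a = %.4g mm^3, b = %.4g\n",
              x$coef$error["a"], x$coef$error["b"]))
  if (is.finite(x$minus2LL))
    cat(sprintf("-2LL (importance sampling) = %.2f, MC se = %.3g\n",
                x$minus2LL, x$minus2LL_se))
  cat(sprintf("converged: %s%s\n", x$converged,
              if (!is.na(x$acceptance))
                sprintf(" (mean MH acceptance %.2f)", x$acceptance) else ""))
  invisible(x)
}

#' @export
coef.tgi_nlme <- function(object, ...) {
  list(typical = exp(object$mu_hat),
       mu = object$mu_hat,
       omega = sqrt(diag(object$Omega_hat)),
       error = c(a = object$error_hat$a, b = object$error_hat$b))
}

#' @export
logLik.tgi_nlme <- function(object, ...) {
  structure(-object$minus2LL / 2, df = object$k, nobs = object$n_obs,
            class = "logLik")
}

#' Individual empirical-Bayes predicted trajectories
#'
#' Dense predicted volume curves per subject at the conditional-mode
#' individual parameters.
#'
#' @param fit a [tgi_nlme()] object.
#' @param times prediction days (default: half-day grid over the observed
#'   span).
#' @return Data frame with columns `subject_id`, `time`,
#'   `predicted_volume`.
#' @export
individual_fits <- function(fit, times = NULL) {
  stopifnot(inherits(fit, "tgi_nlme"))
  if (is.null(times))
    times <- seq(0, max(fit$data$time_day), by = 0.5)
  vols <- .predict_batch(fit$model, fit$individual_phi, fit$regimens,
                         times, fail = "na")
  data.frame(subject_id = rep(fit$subject_ids, each = length(times)),
             time = rep(times, length(fit$subject_ids)),
             predicted_volume = as.vector(vols))
}

#' @export
#' @rdname individual_fits
#' @param object a `tgi_nlme` fit.
#' @param level `"individual"` (empirical-Bayes parameters) or
#'   `"population"` (typical values).
#' @param ... unused.
predict.tgi_nlme <- function(object, times = NULL,
                             level = c("individual", "population"), ...) {
  level <- match.arg(level)
  if (level == "individual") return(individual_fits(object, times))
  if (is.null(times))
    times <- seq(0, max(object$data$time_day), by = 0.5)
  p <- length(object$mu_hat)
  phi <- matrix(exp(object$mu_hat), object$N, p, byrow = TRUE,
                dimnames = list(NULL, names(object$mu_hat)))
  vols <- .predict_batch(object$model, phi, object$regimens, times,
                         fail = "na")
  data.frame(subject_id = rep(object$subject_ids, each = length(times)),
             time = rep(times, object$N),
             predicted_volume = as.vector(vols))
}

#' @export
fitted.tgi_nlme <- function(object, ...) {
  do.call(rbind, lapply(seq_along(object$subject_ids), function(i) {
    s <- object$data[object$data$subject_id == object$subject_ids[i], ]
    s <- s[order(s$time_day), ]
    data.frame(subject_id = s$subject_id, time_day = s$time_day,
               observed = s$volume_mm3,
               fitted = object$fitted_values[[i]])
  }))
}

#' @export
residuals.tgi_nlme <- function(object, type = c("iwres", "response"), ...) {
  type <- match.arg(type)
  fv <- fitted(object)
  r <- fv$observed - fv$fitted
  if (type == "response") return(r)
  r / (object$error_hat$a + object$error_hat$b * fv$fitted)
}

#' @export
plot.tgi_nlme <- function(x, n_panels = 12, ...) {
  ids <- head(x$subject_ids, n_panels)
  pred <- individual_fits(x)
  old <- par(mfrow = c(ceiling(length(ids) / 4), min(4, length(ids))),
             mar = c(3, 3, 2, 0.5), mgp = c(1.8, 0.6, 0))
  on.exit(par(old))
  for (id in ids) {
    s <- x$data[x$data$subject_id == id, ]
    pr <- pred[pred$subject_id == id, ]
    plot(s$time_day, s$volume_mm3, pch = 16, cex = 0.7, main = id,
         xlab = "day", ylab = "volume (mm^3)",
         ylim = range(c(s$volume_mm3, pr$predicted_volume), na.rm = TRUE))
    lines(pr$time, pr$predicted_volume, col = "firebrick")
  }
  invisible(x)
}

#' @export
simulate.tgi_nlme <- function(object, nsim = 1, seed = NULL,
                              design = NULL, ...) {
  if (is.null(seed)) seed <- 1L
  reg <- object$regimens
  treated <- which(reg$dose_amount > 0)
  regimen <- if (length(treated))
    dose_regimen(reg$dose_amount[treated[1]], reg$dose_time[treated[1]],
                 reg$ke[treated[1]])
  else dose_regimen(0)
  spec <- population_spec(object$model, exp(object$mu_hat),
                          sqrt(diag(object$Omega_hat)),
                          error_params(object$error_hat$a,
                                       max(object$error_hat$b, 1e-8), 1),
                          regimen)
  if (is.null(design)) {
    grp <- object$data$group[match(object$subject_ids,
                                   object$data$subject_id)]
    if (is.null(grp)) grp <- rep("control", object$N)
    design <- cohort_design(n_control = sum(grp == "control"),
                            n_treated = sum(grp == "treated"),
                            horizon = max(object$data$time_day))
  }
  out <- lapply(seq_len(nsim), function(s)
    generate_cohort(spec, design, seed = .derive_seed(seed, paste0("sim", s))))
  if (nsim == 1) out[[1]] else out
}
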