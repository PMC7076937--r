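# Information criteria and Akaike-type model weights.

#' Information criteria
#'
#' `aic()` computes `-2LL + 2k`; `aicc()` adds the small-sample correction
#' `2k(k+1)/(n - k - 1)` (undefined for `n <= k + 1`); `bic()` computes
#' `-2LL + k log(sample_size)`.  For hierarchical longitudinal fits the BIC
#' sample size is ambiguous; the comparison tables in this package default
#' to the number of subjects `N` (see [compare_models()]).
#'
#' Following the convention used throughout the package, `k` counts fixed
#' effects, estimated random-effect variances, and residual-error
#' parameters.
#'
#' @param minus2LL `-2 log L` of the fitted model.
#' @param k number of free parameters, `>= 1`.
#' @param AIC an AIC value.
#' @param n number of observations.
#' @param sample_size BIC sample size (observations or subjects).
#' @return Scalar criterion value (vectorized over its inputs).
#' @examples
#' aic(5148.52, 10)
#' aicc(100, 3, 10)   # 104
#' bic(5148.52, 10, 21)
#' @export
aic <- function(minus2LL, k) {
  if (any(k < 1)) stop("aic(): k must be >= 1")
  minus2LL + 2 * k
}

#' @rdname aic
#' @export
aicc <- function(AIC, k, n) {
  if (any(n <= k + 1))
    stop("aicc(): small-sample correction undefined for n <= k + 1")
  AIC + 2 * k * (k + 1) / (n - k - 1)
}

#' @rdname aic
#' @export
bic <- function(minus2LL, k, sample_size) {
  if (any(sample_size < 2)) stop("bic(): sample_size must be >= 2")
  minus2LL + k * log(sample_size)
}

#' Information-criterion model weights
#'
#' Akaike-type weights over a candidate set: `Delta_j = IC_j - min(IC)`,
#' `w_j = exp(-Delta_j/2) / sum_m exp(-Delta_m/2)`.  Computed after
#' shifting by the minimum, so arbitrarily large IC spreads cannot
#' overflow.  Weights sum to one and are interpretable as the probability
#' that each model is the best of the candidates.
#'
#' @param values vector of IC values (all finite).
#' @return Vector of weights in `[0, 1]` summing to 1.
#' @examples
#' ic_weights(c(100, 102))  # c(0.731..., 0.268...)
#' @export
ic_weights <- function(values) {
  if (length(values) < 1L || any(!is.finite(values)))
    stop("ic_weights(): need at least one finite IC value")
  d <- values - min(values)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Round a weight the way comparison tables print it
#'
#' Weights at or above `1e-4` are rounded to `decimals` decimal places;
#' smaller weights are kept at 3 significant digits (scientific range).
#'
#' @param w numeric weight(s).
#' @param decimals decimal places for the non-scientific range.
#' @return Rounded numeric vector.
#' @export
report_weight <- function(w, decimals = 4) {
  ifelse(w >= 1e-4, round(w, decimals), signif(w, 3))
}

#' Assemble an information-criterion comparison table
#'
#' One row per fitted model with `-2LL`, AIC, AICc, BIC and the three
#' weight columns.  All fits must be on the same data.  `AICc` uses
#' `n` = total observations; the BIC sample size defaults to `N` =
#' subjects (`bic_sample = "subjects"`), switchable to observations.
#' Ties in the minimum IC resolve to the first model in input order.
#'
#' @param fits named list of [tgi_nlme()] fits (names become model ids),
#'   or `NULL` when the criteria inputs are given directly.
#' @param minus2LL,k,model_ids direct inputs (used when `fits` is `NULL`).
#' @param n,N observation and subject counts; taken from the fits when
#'   omitted.
#' @param bic_sample `"subjects"` or `"observations"`.
#' @return A `tgi_ictable` data frame with columns `model`, `minus2LL`,
#'   `AIC`, `w_AIC`, `AICc`, `w_AICc`, `BIC`, `w_BIC`, `k`, `n`, `N`.
#' @examples
#' ic_table(minus2LL = c(m1 = 100, m2 = 101), k = c(4, 5), n = 50, N = 10)
#' @export
compare_models <- function(fits, n = NULL, N = NULL,
                           bic_sample = c("subjects", "observations"),
                           k = NULL) {
  bic_sample <- match.arg(bic_sample)
  stopifnot(is.list(fits), length(fits) >= 1)
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, function(f) f$model$name, "")
  if (anyDuplicated(names(fits)))
    stop("compare_models(): model ids must be unique")
  n_obs <- vapply(fits, function(f) as.integer(f$n_obs), 0L)
  n_sub <- vapply(fits, function(f) as.integer(f$N), 0L)
  h <- vapply(fits, function(f)
    paste(f$n_obs, signif(sum(f$data$volume_mm3), 12),
          paste(f$subject_ids, collapse = ",")), "")
  if (length(unique(h)) != 1L)
    stop("compare_models(): all fits must be on the same cohort")
  if (is.null(n)) n <- n_obs[1]
  if (is.null(N)) N <- n_sub[1]
  if (is.null(k)) k <- vapply(fits, function(f) f$k, 0)
  m2 <- vapply(fits, function(f) f$minus2LL, 0)
  ic_table(minus2LL = m2, k = k, n = n, N = N,
           model_ids = names(fits), bic_sample = bic_sample)
}

#' @rdname compare_models
#' @param minus2LL named vector of `-2 log L` values.
#' @export
ic_table <- function(minus2LL, k, n, N, model_ids = names(minus2LL),
                     bic_sample = c("subjects", "observations")) {
  bic_sample <- match.arg(bic_sample)
  if (is.null(model_ids)) model_ids <- paste0("model", seq_along(minus2LL))
  AIC_v <- aic(minus2LL, k)
  AICc_v <- aicc(AIC_v, k, n)
  BIC_v <- bic(minus2LL, k, if (bic_sample == "subjects") N else n)
  out <- data.frame(row.names = NULL,
                    model = unname(model_ids), minus2LL = unname(minus2LL),
                    AIC = unname(AIC_v), w_AIC = unname(ic_weights(AIC_v)),
                    AICc = unname(AICc_v),
                    w_AICc = unname(ic_weights(AICc_v)),
                    BIC = unname(BIC_v), w_BIC = unname(ic_weights(BIC_v)),
                    k = unname(k), n = n, N = N)
  rownames(out) <- NULL
  attr(out, "bic_sample") <- bic_sample
  class(out) <- c("tgi_ictable", "data.frame")
  out
}

#' @export
print.tgi_ictable <- function(x, ...) {
  cat("Model comparison (", nrow(x), " candidates; AICc n = ", x$n[1],
      ", BIC sample = ", attr(x, "bic_sample"), ")\n", sep = "")
  disp <- data.frame(model = x$model,
                     `-2LL` = sprintf("%.2f", x$minus2LL),
                     AIC = sprintf("%.2f", x$AIC),
                     `w(AIC)` = .fmt_w(x$w_AIC),
                     AICc = sprintf("%.2f", x$AICc),
                     `w(AICc)` = .fmt_w(x$w_AICc),
                     BIC = sprintf("%.2f", x$BIC),
                     `w(BIC)` = .fmt_w(x$w_BIC),
                     k = x$k, check.names = FALSE)
  print(disp, row.names = FALSE)
  invisible(x)
}

.fmt_w <- function(w) {
  ifelse(w >= 1e-4, sprintf("%.4f", round(w, 4)),
         sprintf("%.2E", signif(w, 3)))
}

#' Export a comparison table
#'
#' @param x a `tgi_ictable`.
#' @param file output path; `".csv"` writes CSV, anything else Markdown.
#' @return The path, invisibly.
#' @export
write_ic_table <- function(x, file) {
  stopifnot(inherits(x, "tgi_ictable"))
  if (grepl("\\.csv$", file)) {
    write.csv(as.data.frame(x), file, row.names = FALSE, quote = FALSE)
  } else {
    cols <- c("model", "minus2LL", "AIC", "w_AIC", "AICc", "w_AICc",
              "BIC", "w_BIC")
    disp <- as.data.frame(x)[cols]
    for (j in c("minus2LL", "AIC", "AICc", "BIC"))
      disp[[j]] <- sprintf("%.2f", disp[[j]])
    for (j in c("w_AIC", "w_AICc", "w_BIC")) disp[[j]] <- .fmt_w(x[[j]])
    lines <- c(paste("|", paste(names(disp), collapse = " | "), "|"),
               paste("|", paste(rep("---", ncol(disp)), collapse = " | "),
                     "|"),
               apply(disp, 1, function(r)
                 paste("|", paste(r, collapse = " | "), "|")))
    writeLines(lines, file)
  }
  invisible(file)
}

#' Reference information-criterion values from a published study
#'
#' Packaged fixture with the information criteria reported by a published
#' nonlinear mixed-effects comparison of tumor growth models on a cisplatin
#' mouse experiment: an untreated-arm table (four growth laws, 386
#' observations on 21 animals) and a treated-arm table (three
#' transit-compartment variants and the delayed-elimination model, 545
#' observations on 19 animals).  The absolute `-2LL` values depend on that
#' study's animal data and are used here only as fixed inputs for checking
#' the weight and criterion arithmetic.
#'
#' @return A list with data frames `control` and `treated`; columns
#'   `model`, `minus2LL`, `AIC`, `w_AIC`, `AICc`, `w_AICc`, `BIC`, `w_BIC`
#'   (reported weights), plus `n` and `N`.
#' @export
reference_ic_tables <- function() {
  path <- system.file("extdata", "reference_ic_values.csv",
                      package = "tgimix", mustWork = TRUE)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  split(tab[setdiff(names(tab), "cohort")], tab$cohort)[c("control",
                                                          "treated")]
}

#' Recompute the reported weight columns of the reference tables
#'
#' Feeds the published AIC, AICc and BIC values of
#' [reference_ic_tables()] through [ic_weights()] and returns them next to
#' the published weights, rounded the way each table reports them
#' (4 decimals / 3 significant digits for the untreated table, 3 decimals
#' for the treated table).
#'
#' @return A list of two data frames (`control`, `treated`) with recomputed
#'   `w_*` columns and the published `w_*_reported` columns.
#' @examples
#' reproduce_reference_tables()$control
#' @export
reproduce_reference_tables <- function() {
  ref <- reference_ic_tables()
  dec <- c(control = 4, treated = 3)
  out <- lapply(names(ref), function(arm) {
    tab <- ref[[arm]]
    res <- data.frame(model = tab$model)
    for (crit in c("AIC", "AICc", "BIC")) {
      w <- report_weight(ic_weights(tab[[crit]]), dec[[arm]])
      res[[paste0("w_", crit)]] <- w
      res[[paste0("w_", crit, "_reported")]] <- tab[[paste0("w_", crit)]]
    }
    res
  })
  names(out) <- names(ref)
  out
}
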