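# --- survival analysis: Kaplan-Meier, log-rank, Cox + bootstrap -------------

#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()]; the returned curve starts at 1, is
#' non-increasing and steps only at observed event times. Use
#' [km_survival_at()] for right-continuous evaluation at arbitrary times
#' (e.g. 36 months for the 3-year DFS readout).
#'
#' @param times follow-up times (months from surgery), >= 0.
#' @param events event indicators (1/TRUE = event observed, 0/FALSE =
#'   censored).
#' @return Object of class `km_curve`: `table` (time, n_risk, n_event,
#'   n_censor, surv), `n`, `n_events`, and the underlying `survfit` fit.
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) > 0, length(times) == length(events))
  if (anyNA(times) || anyNA(events)) stop("missing values in survival input")
  if (any(times < 0)) stop("negative follow-up time")
  fit <- survival::survfit(
    survival::Surv(times, as.integer(as.logical(events))) ~ 1,
    conf.type = "log-log")
  structure(
    list(table = data.frame(time = fit$time, n_risk = fit$n.risk,
                            n_event = fit$n.event, n_censor = fit$n.censor,
                            surv = fit$surv),
         n = length(times), n_events = sum(as.logical(events)), fit = fit),
    class = "km_curve")
}

#' Evaluate a Kaplan-Meier curve at given times
#'
#' Right-continuous step-function evaluation; times before the first event
#' return 1, times beyond the last observation return the last estimate.
#'
#' @param km a `km_curve` from [km_estimate()].
#' @param t numeric vector of evaluation times.
#' @return Survival probabilities, same length as `t`.
#' @export
km_survival_at <- function(km, t) {
  stopifnot(inherits(km, "km_curve"), all(t >= 0))
  s <- summary(km$fit, times = t, extend = TRUE)
  as.numeric(s$surv)
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve: %d subjects, %d events, %d time points>\n",
              x$n, x$n_events, nrow(x$table)))
  invisible(x)
}

#' Log-rank (Mantel-Cox) test
#'
#' Observed-minus-expected chi-square over the pooled event times; p from
#' the chi-square distribution with k-1 degrees of freedom.
#'
#' @param times,events as in [km_estimate()].
#' @param group group labels (k >= 2 non-empty groups).
#' @return list with `chisq`, `df`, `p_value`, `n_per_group`.
#' @export
logrank_test <- function(times, events, group) {
  stopifnot(length(times) == length(events), length(times) == length(group))
  g <- factor(group)
  if (nlevels(g) < 2L) stop("log-rank test needs at least 2 groups")
  if (any(table(g) == 0L)) stop("log-rank test: empty group")
  sd <- survival::survdiff(
    survival::Surv(times, as.integer(as.logical(events))) ~ g)
  df <- length(sd$n) - 1L
  list(chisq = as.numeric(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       n_per_group = as.vector(table(g)))
}

#' Cox proportional-hazards fit with bootstrap validation
#'
#' Maximizes the Cox partial likelihood (Efron tie handling by default) and
#' reports, per covariate, the hazard ratio, Wald 95% CI and p-value, plus
#' patient-level nonparametric bootstrap percentile CIs and an optimism
#' estimate of the model's concordance index (Harrell's bootstrap optimism
#' correction) as the overfitting control.
#'
#' Rows with missing values in the modelled covariates are dropped with a
#' message (no imputation). Covariates that are constant in the analysis
#' set, and fits showing signs of monotone-likelihood separation
#' (|log HR| > 10), are flagged explicitly rather than silently reported.
#'
#' @param data data.frame holding times, events and covariates.
#' @param covariates character vector of covariate column names.
#' @param time_col,event_col column names of follow-up time and event flag.
#' @param n_bootstrap bootstrap resamples (0 skips the bootstrap).
#' @param seed integer seed for the bootstrap resampling.
#' @param ties tie handling for the partial likelihood.
#' @return Object of class `tam_cox`: `table` (term, hr, ci_lower,
#'   ci_upper, p_value, boot_ci_lower, boot_ci_upper), `n`, `n_events`,
#'   `n_dropped`, `concordance` (apparent, optimism, corrected),
#'   `flags`, and the underlying `coxph` fit.
#' @export
cox_fit <- function(data, covariates, time_col = "dfs_time",
                    event_col = "dfs_event", n_bootstrap = 1000L,
                    seed = 1L, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(is.data.frame(data), length(covariates) >= 1,
            all(c(time_col, event_col, covariates) %in% names(data)))
  d <- data[, c(time_col, event_col, covariates), drop = FALSE]
  keep <- stats::complete.cases(d)
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " record(s) dropped for missing covariate values")
  d <- d[keep, , drop = FALSE]
  if (sum(as.logical(d[[event_col]])) < 1L) stop("no events in analysis set")
  flags <- character(0)
  for (cv in covariates) {
    v <- d[[cv]]
    if (length(unique(v[!is.na(v)])) < 2L)
      flags <- c(flags, paste0("degenerate: covariate '", cv,
                               "' is constant in the analysis set"))
  }
  if (length(flags)) stop(paste(flags, collapse = "; "))
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time_col, ", as.integer(as.logical(", event_col,
    "))) ~ ", paste(covariates, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = d, ties = ties),
    error = function(e) stop("Cox fit failed to converge: ",
                             conditionMessage(e)),
    warning = function(w) {
      f <- suppressWarnings(survival::coxph(fml, data = d, ties = ties))
      attr(f, "fit_warning") <- conditionMessage(w)
      f
    })
  if (!is.null(attr(fit, "fit_warning")))
    flags <- c(flags, paste0("warning: ", attr(fit, "fit_warning")))
  if (any(abs(stats::coef(fit)) > 10))
    flags <- c(flags, "separation: |log HR| > 10 suggests monotone likelihood")
  sm <- summary(fit)
  tab <- data.frame(term = rownames(sm$conf.int),
                    hr = sm$conf.int[, "exp(coef)"],
                    ci_lower = sm$conf.int[, "lower .95"],
                    ci_upper = sm$conf.int[, "upper .95"],
                    p_value = sm$coefficients[, "Pr(>|z|)"],
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  conc_apparent <- as.numeric(sm$concordance[1L])
  boot <- NULL
  conc <- c(apparent = conc_apparent, optimism = NA_real_,
            corrected = NA_real_)
  if (n_bootstrap > 0) {
    nb <- as.integer(n_bootstrap)
    coefs <- matrix(NA_real_, nb, length(stats::coef(fit)))
    optim <- rep(NA_real_, nb)
    withr::with_seed(as.integer(seed), {
      for (b in seq_len(nb)) {
        idx <- sample.int(nrow(d), replace = TRUE)
        db <- d[idx, , drop = FALSE]
        fb <- tryCatch(
          suppressWarnings(survival::coxph(fml, data = db, ties = ties)),
          error = function(e) NULL)
        if (is.null(fb)) next
        cf <- stats::coef(fb)
        if (any(!is.finite(cf)) || any(abs(cf) > 15)) next
        coefs[b, ] <- cf
        c_boot <- as.numeric(summary(fb)$concordance[1L])
        c_orig <- tryCatch(
          as.numeric(survival::concordance(fb, newdata = d)$concordance),
          error = function(e) NA_real_)
        optim[b] <- c_boot - c_orig
      }
    })
    ok <- stats::complete.cases(coefs)
    qs <- apply(coefs[ok, , drop = FALSE], 2L,
                stats::quantile, probs = c(0.025, 0.975))
    tab$boot_ci_lower <- exp(qs[1L, ])
    tab$boot_ci_upper <- exp(qs[2L, ])
    conc["optimism"] <- mean(optim, na.rm = TRUE)
    conc["corrected"] <- conc_apparent - conc["optimism"]
    boot <- list(n_bootstrap = nb, n_used = sum(ok))
  }
  structure(
    list(table = tab, n = nrow(d),
         n_events = sum(as.logical(d[[event_col]])),
         n_dropped = n_dropped, concordance = conc, bootstrap = boot,
         flags = flags, logLik = as.numeric(stats::logLik(fit)), fit = fit),
    class = "tam_cox")
}

#' @export
print.tam_cox <- function(x, digits = 3, ...) {
  cat(sprintf("<tam_cox: n=%d, events=%d, concordance=%.3f%s>\n",
              x$n, x$n_events, x$concordance["apparent"],
              if (!is.na(x$concordance["corrected"]))
                sprintf(" (optimism-corrected %.3f)",
                        x$concordance["corrected"]) else ""))
  print(format(x$table, digits = digits), ...)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}
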