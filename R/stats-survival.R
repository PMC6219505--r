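# Survival statistics: Kaplan-Meier curves, log-rank comparison, classical
# Cox proportional-hazards fits, and the Ki-67 labeling-index calibration.

#' Kaplan-Meier survival estimate per group
#'
#' Product-limit estimator; the median survival of a group is the earliest
#' time at which its curve drops to 0.5 or below, and is undefined (NA)
#' when the curve never does.
#'
#' @param outcomes a [survival_outcome()].
#' @param groups optional vector of group labels aligned with `outcomes`
#'   (a single pooled curve when omitted).
#' @return a `km_estimate` list: per-group data frames (`time`, `n_risk`,
#'   `n_event`, `surv`) and `median_survival` per group.
#' @export
km_estimate <- function(outcomes, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", nrow(outcomes))
  if (length(groups) != nrow(outcomes)) stop("groups not aligned with outcomes")
  groups <- as.character(groups)
  curves <- lapply(split(seq_along(groups), groups), function(idx) {
    oc <- outcomes[idx, , drop = FALSE]
    sf <- survival::survfit(as_surv(oc) ~ 1)
    data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
               surv = sf$surv)
  })
  med <- vapply(curves, function(cv) {
    hit <- which(cv$surv <= 0.5 & cv$n_event > 0)
    if (length(hit)) cv$time[min(hit)] else NA_real_
  }, numeric(1))
  structure(list(curves = curves, median_survival = med,
                 endpoint = attr(outcomes, "endpoint")),
            class = "km_estimate")
}

#' @export
print.km_estimate <- function(x, ...) {
  cat(sprintf("<km_estimate> %s; median survival: %s\n",
              x$endpoint %||% "OS",
              paste(sprintf("%s = %s", names(x$median_survival),
                            ifelse(is.na(x$median_survival), "not reached",
                                   sprintf("%.1f", x$median_survival))),
                    collapse = ", ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Log-rank comparison of two survival curves
#'
#' Standard observed-minus-expected statistic over the pooled event times,
#' referred to the chi-square law with one degree of freedom.
#'
#' @param outcomes a [survival_outcome()].
#' @param groups two-level grouping vector aligned with `outcomes`.
#' @return a `test_result` with the log-rank statistic and two-sided p.
#' @export
logrank_test <- function(outcomes, groups) {
  if (length(unique(groups)) != 2) stop("log-rank comparison needs 2 groups")
  if (sum(outcomes$event) == 0) stop("no events in the pooled sample")
  sd_ <- survival::survdiff(as_surv(outcomes) ~ groups)
  test_result("logrank", unname(sd_$chisq),
              stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE))
}

#' Classical Cox proportional-hazards fit
#'
#' Newton-Raphson maximization of the Breslow partial likelihood via
#' `survival::coxph(ties = "breslow")`. Hazard ratios are reported per
#' stated unit: set `units` to rescale covariates (e.g. age in years with
#' `units = c(age = 10)` gives the HR per 10 years), and `log2_covariates`
#' to log2-transform expression covariates so the HR is per doubling.
#'
#' @param data data frame holding the covariates.
#' @param outcomes a [survival_outcome()] aligned with `data`.
#' @param covariates character vector of covariate names to report.
#' @param adjust_for character vector of additional adjustment covariates
#'   (e.g. `c("age", "grade")` for the multivariable models).
#' @param units named numeric vector of per-unit divisors.
#' @param log2_covariates character vector of covariates to log2-transform
#'   (HR per doubling).
#' @return a `cox_fit` data frame with one row per reported covariate:
#'   `covariate`, `hr`, `ci_low`, `ci_high`, `p` (Wald, two-sided), `unit`
#'   and `adjusted_for`.
#' @export
cox_fit <- function(data, outcomes, covariates, adjust_for = character(0),
                    units = NULL, log2_covariates = character(0)) {
  if (nrow(data) != nrow(outcomes)) stop("data and outcomes are not aligned")
  if (sum(outcomes$event) < length(c(covariates, adjust_for))) {
    stop("fewer events than covariates")
  }
  d <- data
  unit_note <- stats::setNames(rep("per unit", ncol(d)), names(d))
  for (nm in names(units)) {
    d[[nm]] <- d[[nm]] / units[[nm]]
    unit_note[nm] <- sprintf("per %g units", units[[nm]])
  }
  for (nm in log2_covariates) {
    d[[nm]] <- log2(d[[nm]])
    unit_note[nm] <- "per doubling"
  }
  all_cov <- unique(c(covariates, adjust_for))
  fml <- stats::as.formula(paste("srv ~", paste(all_cov, collapse = " + ")))
  d$srv <- as_surv(outcomes)
  fit <- survival::coxph(fml, data = d, ties = "breslow")
  if (!is.null(fit$info) && any(grepl("did not converge", fit$info))) {
    warning("Cox fit did not converge")
  }
  sm <- summary(fit)
  beta <- coef(fit)
  if (any(abs(beta) > 15, na.rm = TRUE)) {
    warning("very large coefficient: possible monotone likelihood ",
            "(perfect separation)")
  }
  keep <- match(covariates, rownames(sm$coefficients))
  structure(
    data.frame(covariate = covariates,
               hr = unname(sm$coefficients[keep, "exp(coef)"]),
               ci_low = unname(sm$conf.int[keep, "lower .95"]),
               ci_high = unname(sm$conf.int[keep, "upper .95"]),
               p = unname(sm$coefficients[keep, "Pr(>|z|)"]),
               unit = unname(unit_note[covariates]),
               adjusted_for = paste(adjust_for, collapse = ","),
               stringsAsFactors = FALSE),
    coxph = fit,
    class = c("cox_fit", "data.frame")
  )
}

#' Calibrate an expression cutoff to a Ki-67 labeling index
#'
#' Least-squares regression of the labeling index (percent) on expression;
#' the inverted threshold is the expression value at which the fitted index
#' equals `target_index` (15% by default, the level the canonical 700
#' cutoff corresponds to). With a (near) zero slope the threshold is
#' undefined and the fixed fallback cutoff is used with a warning.
#'
#' @param pairs data frame with columns `expression` and `labeling_index`
#'   (at least 3 rows), e.g. from [generate_ki67_pairs()].
#' @param target_index labeling index (percent) the threshold corresponds
#'   to.
#' @param fallback_cutoff fixed expression cutoff used when the slope is
#'   degenerate (default 700).
#' @return a `calibration_fit` list: `slope`, `intercept`, `threshold`,
#'   `r_squared`, `target_index`.
#' @export
calibrate_mki67 <- function(pairs, target_index = 15, fallback_cutoff = 700) {
  if (nrow(pairs) < 3) stop("need at least 3 pairs")
  fit <- stats::lm(labeling_index ~ expression, data = pairs)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  if (!is.finite(slope) || abs(slope) < .Machine$double.eps^0.5 / 1e3) {
    warning("zero slope: threshold undefined, falling back to fixed cutoff")
    threshold <- fallback_cutoff
  } else {
    threshold <- (target_index - intercept) / slope
  }
  # a noiseless calibration line is a legitimate input; silence the
  # perfect-fit warning from summary.lm
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = slope, intercept = intercept,
                 threshold = threshold,
                 r_squared = r2,
                 target_index = target_index),
            class = "calibration_fit")
}

#' Dichotomize expression at a calibrated threshold
#'
#' @param expression numeric vector of expression values.
#' @param calibration optional `calibration_fit`; when omitted the fixed
#'   default cutoff of 700 is used.
#' @param cutoff explicit cutoff overriding both.
#' @return character vector `"high"`/`"low"` (high iff at or above the
#'   cutoff).
#' @export
mki67_high <- function(expression, calibration = NULL, cutoff = NULL) {
  thr <- if (!is.null(cutoff)) cutoff
         else if (!is.null(calibration)) calibration$threshold
         else 700
  ifelse(expression >= thr, "high", "low")
}
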