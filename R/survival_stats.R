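# Survival machinery: Kaplan-Meier estimation, log-rank comparison,
# univariate / multivariable Cox proportional-hazards fits (Efron tie
# handling, Wald intervals) and the proportional-hazards check via a
# covariate x time cross-product term. Backed by the survival package;
# every operation is verified against hand-coded oracles in the test
# suite.

#' @importFrom survival Surv
NULL

.check_surv <- function(time, event) {
  if (any(!is.finite(time)) || any(time <= 0))
    stop("survival times must be positive and finite", call. = FALSE)
  if (!all(event %in% c(0, 1, TRUE, FALSE)))
    stop("events must be boolean", call. = FALSE)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimate of the survival function; right-continuous step
#' function with S(0) = 1.
#'
#' @param time positive event/censoring times (months).
#' @param event event indicators (1 = event, 0 = censored).
#' @return List of class `tiic_km`: `time` (event times), `surv` (S(t) at
#'   those times), `n_risk`, `n_event`, and `fn`, a step function usable
#'   as `fn(t)`.
#' @export
#' @examples
#' km <- kaplan_meier(c(1, 2), c(1, 0))
#' km$fn(1) # 0.5
kaplan_meier <- function(time, event) {
  .check_surv(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  fn <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, fn = fn), class = "tiic_km")
}

#' @export
print.tiic_km <- function(x, ...) {
  cat("<tiic_km>", length(x$time), "time points, final S(t) =",
      signif(min(x$surv), 4), "\n")
  invisible(x)
}

#' Log-rank (Mantel-Cox) test for two groups
#'
#' @param time,event pooled survival data.
#' @param group two-level grouping vector.
#' @return List: `statistic` (chi-square, df = 1), `p` (two-sided). With
#'   no events at all the test is undefined; returns p = 1 with a warning.
#' @export
logrank_test <- function(time, event, group) {
  .check_surv(time, event)
  g <- factor(group)
  if (nlevels(g) != 2 || any(table(g) == 0))
    stop("logrank_test requires two non-empty groups", call. = FALSE)
  if (sum(event) == 0) {
    warning("no events in either group; log-rank undefined, p = 1")
    return(list(statistic = 0, df = 1L, p = 1))
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g)
  chisq <- as.numeric(sd_$chisq)
  list(statistic = chisq, df = 1L, p = pchisq(chisq, 1, lower.tail = FALSE))
}

#' Cox proportional-hazards regression
#'
#' Partial-likelihood fits with Efron tie handling; hazard ratios with
#' Wald 95% confidence intervals and p-values. `"univariate"` fits one
#' model per covariate; `"multivariable"` fits the joint model.
#'
#' @param data data.frame with columns `time`, `event` and the covariates.
#' @param covariates covariate column names.
#' @param adjustment `"univariate"` or `"multivariable"`.
#' @return data.frame: `covariate`, `coef`, `hr`, `ci_lo`, `ci_hi`, `p`.
#' @export
cox_fit <- function(data, covariates,
                    adjustment = c("univariate", "multivariable")) {
  adjustment <- match.arg(adjustment)
  .check_surv(data$time, data$event)
  miss <- setdiff(covariates, names(data))
  if (length(miss))
    stop("missing covariate column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyNA(data[, covariates]))
    stop("missing covariate values; drop or impute first", call. = FALSE)
  for (cv in covariates)
    if (var(data[[cv]]) == 0)
      stop("covariate '", cv, "' is constant (degenerate)", call. = FALSE)
  if (adjustment == "multivariable" &&
      sum(data$event) < length(covariates) + 1)
    stop("too few events for a multivariable fit", call. = FALSE)

  fit_one <- function(cvs) {
    f <- as.formula(paste("survival::Surv(time, event) ~",
                          paste(sprintf("`%s`", cvs), collapse = " + ")))
    fit <- survival::coxph(f, data = data, ties = "efron")
    if (any(!is.finite(coef(fit))) ||
        any(sqrt(diag(fit$var)) > 1e3))
      stop("Cox fit did not converge (monotone likelihood?) for: ",
           paste(cvs, collapse = ", "), call. = FALSE)
    s <- summary(fit)
    data.frame(covariate = cvs, coef = as.numeric(coef(fit)),
               hr = as.numeric(exp(coef(fit))),
               ci_lo = s$conf.int[, "lower .95"],
               ci_hi = s$conf.int[, "upper .95"],
               p = s$coefficients[, "Pr(>|z|)"],
               stringsAsFactors = FALSE, row.names = NULL)
  }
  if (adjustment == "multivariable") fit_one(covariates)
  else do.call(rbind, lapply(covariates, fit_one))
}

#' Proportional-hazards assumption check
#'
#' Tests proportionality for one covariate by episode-splitting the data
#' at the unique event times and adding a covariate x time cross-product
#' term to the Cox model; returns the Wald p-value of the product term.
#' The assumption is flagged as satisfied when p > 0.05.
#'
#' @param data data.frame with `time`, `event` and the covariate.
#' @param covariate covariate column name.
#' @return List: `p` (product-term p-value), `satisfied` (p > 0.05),
#'   `coef_interaction`.
#' @export
ph_check <- function(data, covariate) {
  .check_surv(data$time, data$event)
  x <- data[[covariate]]
  if (is.null(x)) stop("unknown covariate: ", covariate, call. = FALSE)
  if (var(x) == 0)
    stop("covariate '", covariate, "' has zero variance", call. = FALSE)
  df <- data.frame(time = data$time, event = as.numeric(data$event),
                   x = x)
  cuts <- sort(unique(df$time[df$event == 1]))
  sp <- survival::survSplit(Surv(time, event) ~ x, data = df,
                            cut = cuts, episode = "ep")
  sp$xt <- sp$x * sp$time # covariate x current analysis time
  fit <- survival::coxph(
    survival::Surv(tstart, time, event) ~ x + xt, data = sp,
    ties = "efron")
  s <- summary(fit)$coefficients
  p <- s["xt", "Pr(>|z|)"]
  list(p = as.numeric(p), satisfied = p > 0.05,
       coef_interaction = as.numeric(coef(fit)["xt"]))
}
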