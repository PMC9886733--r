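#' Quartile grouping of a frailty index
#'
#' Sample quartiles with the linear-interpolation convention (R type 7),
#' computed on the analysis subset; values tied with a cut point go to the
#' lower quartile.
#'
#' @param fi Numeric marker values.
#' @return Factor with levels Q1-Q4.
#' @export
fi_quartiles <- function(fi) {
  qs <- quantile(fi, c(0.25, 0.5, 0.75), type = 7, na.rm = TRUE, names = FALSE)
  cut(fi, breaks = c(-Inf, qs, Inf), labels = paste0("Q", 1:4), right = TRUE)
}

#' Kaplan-Meier curves by group with a log-rank test
#'
#' Product-limit survival estimate per group and the k-group log-rank
#' chi-square test.
#'
#' @param time,event Follow-up time (days) and event indicator (1 =
#'   observed conversion/death, 0 = right-censored).
#' @param groups Group labels (e.g. [fi_quartiles()] of an FI); a single
#'   group is allowed (no test).
#' @return Object of class `km_estimate`: `curves` data frame (group,
#'   time, n_risk, n_event, surv), `logrank` (chisq, df, p or NULL),
#'   `survfit` (the underlying fit).
#' @export
km_logrank <- function(time, event, groups = NULL) {
  stopifnot(all(time >= 0), all(event %in% c(0, 1)))
  if (sum(event) < 1) stopf("need at least one event")
  if (is.null(groups)) groups <- rep("all", length(time))
  groups <- factor(groups)
  if (any(table(groups) == 0)) stopf("empty group")
  df <- data.frame(time = time, event = event, g = groups)
  sf <- survfit(Surv(time, event) ~ g, data = df)
  strata <- if (is.null(sf$strata)) setNames(length(sf$time), levels(groups)[1]) else sf$strata
  curves <- data.frame(
    group = rep(sub("^g=", "", names(strata)), strata),
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event, surv = sf$surv)
  lr <- NULL
  if (nlevels(groups) > 1) {
    sdf <- survdiff(Surv(time, event) ~ g, data = df)
    df_lr <- nlevels(groups) - 1
    lr <- list(chisq = sdf$chisq, df = df_lr,
               p = pchisq(sdf$chisq, df_lr, lower.tail = FALSE))
  }
  structure(list(curves = curves, logrank = lr, survfit = sf),
            class = "km_estimate")
}

#' Cox proportional hazards fit
#'
#' Partial-likelihood fit (Efron tie handling by default, Breslow
#' available) with model-based and, optionally, robust sandwich standard
#' errors, reporting hazard ratios with 95% confidence intervals. Frailty
#' indices should be entered as FI x 100 so the HR refers to a one-unit
#' (0.01) FI increment.
#'
#' @param data Data frame containing `time`, `event` and the covariates.
#' @param covariates Character vector of covariate column names.
#' @param robust Use robust (sandwich) SEs for the CIs (default FALSE).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return Object of class `cox_fit`: `coef`, `se`, `hr`, `ci_lower`,
#'   `ci_upper`, `p`, `loglik`, `ties`, `fit` (the `coxph` object).
#' @export
cox_fit <- function(data, covariates, robust = FALSE,
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(all(c("time", "event") %in% names(data)),
            all(covariates %in% names(data)))
  if (sum(data$event) < 1) stopf("need at least one event")
  for (v in covariates)
    if (length(unique(na.omit(data[[v]]))) < 2)
      stopf("constant covariate '%s'", v)
  fml <- stats::as.formula(paste("Surv(time, event) ~",
                                 paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- coxph(fml, data = data, ties = ties, robust = robust,
               control = coxph.control(iter.max = 100))
  sm <- summary(fit)
  beta <- coef(fit)
  se_col <- if (robust) "robust se" else "se(coef)"
  se <- setNames(as.numeric(sm$coefficients[, se_col]), names(beta))
  structure(list(coef = beta, se = se, hr = exp(beta),
                 ci_lower = exp(beta - 1.96 * se),
                 ci_upper = exp(beta + 1.96 * se),
                 p = 2 * pnorm(-abs(beta / se)),
                 loglik = fit$loglik[2], ties = ties, robust = robust,
                 fit = fit), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> (%s ties%s)\n", x$ties, if (x$robust) ", robust" else ""))
  print(data.frame(HR = x$hr, lower = x$ci_lower, upper = x$ci_upper, p = x$p))
  invisible(x)
}

#' Schoenfeld scaled-residual proportionality tests
#'
#' Correlates the scaled Schoenfeld residuals with transformed event time
#' (Kaplan-Meier transform by default) giving a score-type chi-square per
#' covariate plus a global test; small p-values indicate non-proportional
#' hazards.
#'
#' @param fit A [cox_fit()].
#' @param transform Time transform: `"km"` (default), `"identity"`,
#'   `"rank"`, or `"log"`.
#' @return Data frame with rows per covariate and `GLOBAL`, columns
#'   `chisq`, `df`, `p`.
#' @export
schoenfeld_test <- function(fit, transform = "km") {
  stopifnot(inherits(fit, "cox_fit"))
  if (sum(fit$fit$nevent) < 2) stopf("too few events for residual tests")
  z <- cox.zph(fit$fit, transform = transform, global = TRUE)
  out <- as.data.frame(z$table)
  names(out) <- c("chisq", "df", "p")
  out
}

# left-continuous KM evaluator: returns function(t) = P(X > s) for s just
# below t (product over event times strictly < t)
km_left <- function(time, ind) {
  sf <- survfit(Surv(time, ind) ~ 1)
  tt <- sf$time[sf$n.event > 0]
  ss <- sf$surv[sf$n.event > 0]
  function(t) {
    vapply(t, function(ti) {
      k <- sum(tt < ti)
      if (k == 0) 1 else ss[k]
    }, numeric(1))
  }
}

ipcw_auc_point <- function(marker, time, event, t, Ghat) {
  case <- which(time <= t & event == 1)
  ctrl <- which(time > t)
  if (!length(case) || !length(ctrl)) return(NA_real_)
  gw <- Ghat(time[case])
  gt <- Ghat(t)
  if (any(gw <= 0) || gt <= 0) stopf("censoring-survival estimate reaches 0 at a required time")
  wi <- 1 / gw
  wj <- rep(1 / gt, length(ctrl))
  mc <- marker[case]; mk <- marker[ctrl]
  conc <- outer(mc, mk, function(a, b) (a > b) + 0.5 * (a == b))
  sum(wi * (conc %*% wj)) / (sum(wi) * sum(wj))
}

#' Time-dependent AUC(t) with inverse-probability-of-censoring weights
#'
#' Cumulative-case/dynamic-control discrimination: at each grid time t,
#' cases are subjects with an observed event by t (weighted by the inverse
#' left-continuous KM censoring-survival at their event time) and controls
#' are subjects still event-free beyond t (weighted by 1/G(t)); AUC(t) is
#' the weighted concordance of the marker between cases and controls, ties
#' counted 1/2. Confidence intervals by percentile bootstrap.
#'
#' @param marker Numeric marker (e.g. FI).
#' @param time,event Follow-up time and event indicator.
#' @param times Evaluation time grid (within follow-up support).
#' @param boot Number of bootstrap resamples for 95% CIs (0 = none).
#' @param seed Seed for the bootstrap.
#' @return Object of class `auc_t_estimate`: data frame `table` with
#'   `time`, `auc` and (if `boot > 0`) `lower`, `upper`.
#' @export
auc_t <- function(marker, time, event, times, boot = 0, seed = 1L) {
  stopifnot(length(marker) == length(time), all(event %in% c(0, 1)))
  Ghat <- km_left(time, 1 - event)
  auc <- vapply(times, function(t)
    ipcw_auc_point(marker, time, event, t, Ghat), numeric(1))
  tab <- data.frame(time = times, auc = auc)
  if (boot > 0) {
    n <- length(time)
    bs <- with_seed(seed, {
      vapply(seq_len(boot), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        Gb <- km_left(time[idx], 1 - event[idx])
        vapply(times, function(t)
          tryCatch(ipcw_auc_point(marker[idx], time[idx], event[idx], t, Gb),
                   error = function(e) NA_real_), numeric(1))
      }, numeric(length(times)))
    })
    bs <- matrix(bs, nrow = length(times))
    tab$lower <- apply(bs, 1, quantile, 0.025, na.rm = TRUE)
    tab$upper <- apply(bs, 1, quantile, 0.975, na.rm = TRUE)
  }
  structure(list(table = tab), class = "auc_t_estimate")
}

#' @export
print.auc_t_estimate <- function(x, ...) {
  cat("<auc_t_estimate>\n"); print(x$table); invisible(x)
}

#' Average hazard ratio via weighted Cox estimating equations
#'
#' Solves the Prentice-weighted Cox score equations, weighting each event
#' time t by w(t) = S(t-) / G(t-), where S is the left-continuous KM
#' estimate of event-free survival and G the left-continuous KM estimate of
#' the censoring distribution (censoring correction). The exponentiated
#' solution is an average hazard ratio that remains interpretable under
#' non-proportional hazards. Variance is the robust sandwich from weighted
#' score residuals. With `weight_fn = function(t) rep(1, length(t))` the
#' estimate reduces to the unweighted (Breslow-ties) Cox fit.
#'
#' @param data Data frame with `time`, `event` and covariates.
#' @param covariates Character vector of covariate names.
#' @param weight_fn Optional event-time weight function overriding the
#'   Prentice/censoring-corrected default.
#' @param max_iter,tol Newton iteration controls.
#' @return Object of class `ahr_fit`: `coef`, `se` (robust), `ahr`,
#'   `ci_lower`, `ci_upper`, `p`, `weights` (per event time), `iterations`.
#' @export
ahr_fit <- function(data, covariates, weight_fn = NULL,
                    max_iter = 100, tol = 1e-9) {
  stopifnot(all(c("time", "event") %in% names(data)))
  keep <- complete.cases(data[c("time", "event", covariates)])
  data <- data[keep, , drop = FALSE]
  if (sum(data$event) < 1) stopf("need at least one event")
  o <- order(data$time)
  tt <- data$time[o]; dd <- data$event[o]
  X <- as.matrix(data[o, covariates, drop = FALSE])
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)

  if (is.null(weight_fn)) {
    Sfun <- km_left(tt, dd)
    Gfun <- km_left(tt, 1 - dd)
    weight_fn <- function(t) {
      g <- Gfun(t)
      if (any(g <= 0)) {
        warnf("censoring-survival reached 0 before the last event; weights truncated")
        g[g <= 0] <- min(g[g > 0])
      }
      Sfun(t) / g
    }
  }
  ev <- which(dd == 1)
  w_ev <- weight_fn(tt[ev])

  # weighted partial-likelihood score, information, and per-subject
  # weighted score residuals (for the sandwich), all at a given beta
  eval_score <- function(beta) {
    ex <- exp(drop(X %*% beta))
    U <- rep(0, p); I <- matrix(0, p, p)
    resid <- matrix(0, n, p)
    rs0 <- rev(cumsum(rev(ex)))  # S0(t_i) = sum_{time >= t_i} exp(x beta)
    for (idx in seq_along(ev)) {
      k <- ev[idx]
      at_risk <- tt >= tt[k]
      first <- which.max(at_risk)
      s0 <- rs0[first]
      xe <- X[at_risk, , drop = FALSE]
      ee <- ex[at_risk]
      s1 <- drop(crossprod(xe, ee))
      xbar <- s1 / s0
      w <- w_ev[idx]
      U <- U + w * (X[k, ] - xbar)
      s2 <- crossprod(xe * ee, xe)
      I <- I + w * (s2 / s0 - tcrossprod(xbar))
      resid[k, ] <- resid[k, ] + w * (X[k, ] - xbar)
      centered <- xe - matrix(xbar, nrow(xe), p, byrow = TRUE)
      resid[at_risk, ] <- resid[at_risk, ] - (w * ee / s0) * centered
    }
    list(U = U, I = I, resid = resid)
  }

  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    sc <- eval_score(beta)
    step <- solve(sc$I, sc$U)
    beta <- beta + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stopf("average-hazard-ratio fit did not converge in %d iterations", max_iter)
  sc <- eval_score(beta)
  I <- sc$I
  B <- crossprod(sc$resid)
  Iinv <- solve(I)
  V <- Iinv %*% B %*% Iinv
  se <- sqrt(diag(V))
  names(beta) <- names(se) <- covariates
  structure(list(coef = beta, se = se, ahr = exp(beta),
                 ci_lower = exp(beta - 1.96 * se),
                 ci_upper = exp(beta + 1.96 * se),
                 p = 2 * pnorm(-abs(beta / se)),
                 weights = w_ev, iterations = it), class = "ahr_fit")
}

#' @export
print.ahr_fit <- function(x, ...) {
  cat("<ahr_fit> (Prentice-type weights, robust variance)\n")
  print(data.frame(AHR = x$ahr, lower = x$ci_lower, upper = x$ci_upper, p = x$p))
  invisible(x)
}
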