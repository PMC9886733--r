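sim_surv <- function(n, beta, seed, censor_scale = NULL) {
  set.seed(seed)
  x <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, rate = 0.001 * exp(beta * x))
  if (is.null(censor_scale)) {
    data.frame(time = t_ev, event = 1L, x = x)
  } else {
    cc <- rexp(n, 1 / censor_scale)
    data.frame(time = pmin(t_ev, cc), event = as.integer(t_ev <= cc), x = x)
  }
}

test_that("KM equals the empirical survival function without censoring", {
  set.seed(50)
  tt <- rexp(40)
  km <- km_logrank(tt, rep(1, 40))
  emp <- vapply(km$curves$time, function(t) mean(tt > t), numeric(1))
  expect_equal(km$curves$surv, emp, tolerance = 1e-12)

  one <- km_logrank(c(5, 1, 3, 4), c(0, 1, 0, 0))
  expect_equal(one$curves$surv[one$curves$time == 1], 1 - 1 / 4)
  expect_error(km_logrank(1:3, c(0, 0, 0)), "at least one event")
  expect_no_error(km_logrank(1:4, c(1, 1, 1, 1), rep("a", 4)))
})

test_that("Cox fit matches the explicit partial-likelihood Newton oracle", {
  d <- sim_surv(300, log(2), seed = 51)
  fit <- cox_fit(d, "x", ties = "breslow")
  expect_equal(unname(fit$coef), unname(cox_brute(d$time, d$event, d$x)),
               tolerance = 1e-6)
  expect_lt(abs(fit$coef[["x"]] - log(2)), 3 * fit$se[["x"]])

  # null covariate: CI covers 1
  d0 <- sim_surv(300, 0, seed = 52)
  f0 <- cox_fit(d0, "x")
  expect_true(f0$ci_lower[["x"]] < 1 && 1 < f0$ci_upper[["x"]])
  expect_error(cox_fit(transform(d0, x = 1), "x"), "constant covariate")
})

test_that("rescaling a covariate by 100 rescales beta and keeps the likelihood", {
  d <- sim_surv(200, log(1.8), seed = 53, censor_scale = 2000)
  d$x100 <- 100 * d$x
  f1 <- cox_fit(d, "x")
  f2 <- cox_fit(d, "x100")
  expect_equal(unname(f2$coef) * 100, unname(f1$coef), tolerance = 1e-6)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-8)
})

test_that("Schoenfeld tests flag a strongly time-varying effect", {
  set.seed(54)
  reject <- 0; nsim <- 25
  for (i in 1:nsim) {
    n <- 600
    x <- rbinom(n, 1, 0.5)
    # effect +1 early, -1 late: generate via piecewise hazards
    u <- runif(n)
    t1 <- -log(u) / (0.02 * exp(1.2 * x))      # early phase hazard
    tt <- ifelse(t1 < 40, t1, 40 + (t1 - 40) * exp(2.4 * x))
    d <- data.frame(time = tt, event = 1L, x = x)
    f <- cox_fit(d, "x")
    p <- schoenfeld_test(f)["x", "p"]
    reject <- reject + (p < 0.05)
  }
  expect_gt(reject / nsim, 0.8)
})

test_that("uncensored AUC(t) equals the plain empirical AUC", {
  set.seed(55)
  n <- 120
  marker <- rnorm(n)
  tt <- rexp(n, exp(marker))   # higher marker -> earlier event
  grid <- quantile(tt, c(0.25, 0.5, 0.75), names = FALSE)
  est <- auc_t(marker, tt, rep(1, n), grid)
  for (i in seq_along(grid)) {
    t0 <- grid[i]
    oracle <- auc_mw(marker[c(which(tt <= t0), which(tt > t0))],
                     c(rep(TRUE, sum(tt <= t0)), rep(FALSE, sum(tt > t0))))
    # cases are T <= t, controls T > t; auc_mw over combined vector
    cases <- tt <= t0
    oracle <- auc_mw(marker, cases)
    expect_equal(est$table$auc[i], oracle, tolerance = 1e-12)
  }
  # beyond the last event time AUC(t) compares final status: degenerate
  # (no controls) -> NA
  expect_true(is.na(auc_t(marker, tt, rep(1, n), max(tt) + 1)$table$auc))
})

test_that("perfect and null markers bracket AUC(t)", {
  set.seed(56)
  tt <- rexp(100)
  # marker = -time: earliest converters have the highest marker
  est <- auc_t(-tt, tt, rep(1, 100), median(tt))
  expect_equal(est$table$auc, 1)
  est2 <- auc_t(tt, tt, rep(1, 100), median(tt))
  expect_equal(est2$table$auc, 0)
  null <- auc_t(rnorm(100), tt, rep(1, 100), quantile(tt, c(0.3, 0.6), names = FALSE))
  expect_true(all(abs(null$table$auc - 0.5) < 0.15))
})

test_that("IPCW AUC(t) is close to the uncensored truth under censoring", {
  set.seed(57)
  n <- 1500
  marker <- rnorm(n)
  t_ev <- rexp(n, 0.1 * exp(0.8 * marker))
  cens <- rexp(n, 0.05)
  d_time <- pmin(t_ev, cens); d_event <- as.integer(t_ev <= cens)
  grid <- quantile(t_ev, c(0.3, 0.5), names = FALSE)
  est_c <- auc_t(marker, d_time, d_event, grid)
  est_u <- auc_t(marker, t_ev, rep(1L, n), grid)
  expect_true(all(abs(est_c$table$auc - est_u$table$auc) < 0.04))
  # bootstrap CI brackets the point estimate
  bs <- auc_t(marker[1:300], d_time[1:300], d_event[1:300], grid[1],
              boot = 50, seed = 3)
  expect_true(bs$table$lower <= bs$table$auc && bs$table$auc <= bs$table$upper)
})

test_that("unit-weight AHR equals the Breslow Cox fit", {
  d <- sim_surv(250, log(1.6), seed = 58, censor_scale = 1500)
  ahr <- ahr_fit(d, "x", weight_fn = function(t) rep(1, length(t)))
  cox <- cox_fit(d, "x", ties = "breslow")
  expect_equal(unname(ahr$coef), unname(cox$coef), tolerance = 1e-8)
})

test_that("AHR approximates HR under proportional hazards", {
  d <- sim_surv(800, log(2), seed = 59, censor_scale = 1500)
  ahr <- ahr_fit(d, "x")
  cox <- cox_fit(d, "x", ties = "breslow")
  expect_lt(abs(ahr$coef[["x"]] - cox$coef[["x"]]), 0.12)
  expect_true(ahr$ci_lower[["x"]] < ahr$ahr[["x"]],
              ahr$ahr[["x"]] < ahr$ci_upper[["x"]])
})

test_that("under crossing hazards the AHR lies between the period HRs", {
  set.seed(60)
  n <- 3000
  x <- rbinom(n, 1, 0.5)
  # phase 1 (t < 20): HR = exp(1); phase 2: HR = exp(-1)
  h0 <- 0.02
  t1 <- rexp(n, h0 * exp(1 * x))
  t2 <- 20 + rexp(n, h0 * exp(-1 * x))
  tt <- ifelse(t1 < 20, t1, t2)
  d <- data.frame(time = tt, event = 1L, x = x)
  # period log-HRs are +1 (early) and -1 (late) by construction
  ahr <- ahr_fit(d, "x")
  expect_gt(ahr$coef[["x"]], -1)
  expect_lt(ahr$coef[["x"]], 1)
})

test_that("fi_quartiles uses type-7 cuts with ties to the lower quartile", {
  x <- c(1, 2, 2, 3, 4, 5, 6, 7)
  q <- fi_quartiles(x)
  qs <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  expect_identical(levels(q), paste0("Q", 1:4))
  expect_true(all(x[q == "Q1"] <= qs[1]))
  # a value equal to the first cut point lands in Q1
  expect_identical(as.character(q[x == qs[1]][1]), "Q1")
  # quartile membership depends on ranks only
  expect_identical(fi_quartiles(x), fi_quartiles(rank(x, ties.method = "average")))
})

test_that("two identical exponential groups give a calibrated log-rank test", {
  set.seed(61)
  ps <- replicate(120, {
    tt <- rexp(160); g <- rep(1:2, each = 80)
    km_logrank(tt, rep(1, 160), g)$logrank$p
  })
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.06)
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})
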