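#' Configuration for the synthetic cohort generator
#'
#' Describes a cohort with a two-class latent structure ("fit" vs "frail"),
#' mixed binary/ordinal/continuous health deficits, three-level diagnosis
#' labels linked to the latent class, and right-censored conversion times
#' whose hazard depends log-linearly on the frailty index. Defaults emulate
#' the scale and class balance of a memory-clinic style case-control cohort
#' (n about 800; roughly 25/50/25 HC/MCI/AD; frail subgroup about 28%).
#'
#' @param n_subjects Number of subjects.
#' @param mix Proportion of the latent "frail" class, in (0, 1).
#' @param n_binary,n_ordinal,n_continuous Number of deficits of each kind.
#' @param informative_fraction Proportion of deficits (per kind) whose
#'   distribution differs between latent classes.
#' @param effect_binary Log-odds shift of informative binary deficits in the
#'   frail class.
#' @param effect_continuous Standardized mean shift of informative
#'   continuous deficits in the frail class (also the latent shift of
#'   informative ordinal items on the logistic scale).
#' @param ordinal_levels Number of ordered response levels (default 4,
#'   scored 0/0.25/0.5/1 as for FAQ-style items).
#' @param diag_model 2 x 3 matrix of diagnosis probabilities (rows fit,
#'   frail; columns HC, MCI, AD). The default is calibrated so marginal
#'   class sizes are about 28/49/23 with a frail subgroup depleted of HC.
#' @param surv_shape,surv_scale Weibull baseline shape and scale (days).
#' @param beta_fi Log hazard ratio per unit of FI x 100.
#' @param censor_rate Approximate proportion censored (independent Weibull
#'   censoring with matched shape); 0 disables censoring, 1 censors all.
#' @param missing_rate Per-cell MCAR missingness probability on deficits.
#' @param seed Master seed; all component streams derive from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 800, mix = 0.28,
                       n_binary = 30, n_ordinal = 8, n_continuous = 12,
                       informative_fraction = 0.3,
                       effect_binary = 1.5, effect_continuous = 1.0,
                       ordinal_levels = 4,
                       diag_model = rbind(fit = c(0.38, 0.54, 0.08),
                                          frail = c(0.02, 0.35, 0.63)),
                       surv_shape = 1.2, surv_scale = 2000,
                       beta_fi = log(1.04), censor_rate = 0.4,
                       missing_rate = 0.02, seed = 1L) {
  if (n_subjects <= 0) stopf("n_subjects must be positive")
  if (mix <= 0 || mix >= 1) stopf("mix must lie strictly in (0, 1)")
  for (p in c(informative_fraction, censor_rate, missing_rate))
    if (p < 0 || p > 1) stopf("proportions must lie in [0, 1]")
  if (any(c(n_binary, n_ordinal, n_continuous) < 0)) stopf("counts must be >= 0")
  if (surv_shape <= 0 || surv_scale <= 0) stopf("Weibull parameters must be > 0")
  diag_model <- as.matrix(diag_model)
  stopifnot(nrow(diag_model) == 2, ncol(diag_model) == 3,
            all(abs(rowSums(diag_model) - 1) < 1e-8))
  structure(list(n_subjects = as.integer(n_subjects), mix = mix,
                 n_binary = as.integer(n_binary),
                 n_ordinal = as.integer(n_ordinal),
                 n_continuous = as.integer(n_continuous),
                 informative_fraction = informative_fraction,
                 effect_binary = effect_binary,
                 effect_continuous = effect_continuous,
                 ordinal_levels = as.integer(ordinal_levels),
                 diag_model = diag_model,
                 surv_shape = surv_shape, surv_scale = surv_scale,
                 beta_fi = beta_fi, censor_rate = censor_rate,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_config")
}

ordinal_scores <- function(L) {
  if (L == 4) c(0, 0.25, 0.5, 1) else seq(0, 1, length.out = L)
}

ordinal_labels <- function(L) {
  if (L == 4) c("normal", "difficulty", "requires assistance", "dependent")
  else paste0("grade", seq_len(L) - 1L)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

#' Simulate a mixed-type cohort with known latent frailty structure
#'
#' Draws a cohort under [sim_config()]: binary deficits are Bernoulli with
#' class-dependent prevalence (base prevalences equally spaced on
#' \[0.05, 0.40\]; informative items get a log-odds shift in the frail
#' class), ordinal items follow a proportional-odds latent-logistic model,
#' and continuous items are Gaussian with a class-dependent mean and
#' reference range mean0 +/- 1.96 SD recorded in the generated codebook.
#' Diagnosis is multinomial on the latent class; conversion times come from
#' [simulate_survival()] applied to the pre-missingness standard FI.
#' Missingness is MCAR. All randomness derives from `config$seed` through
#' named per-component streams, so identical seeds give identical cohorts.
#'
#' @param config A [sim_config()].
#' @return A list with elements `cohort` (data frame; deficit columns plus
#'   `age`, `sex`, `education`, `diagnosis`, `cdrsb`, `mmse`, `time`,
#'   `event`), `codebook` (a [codebook()] describing the deficits), and
#'   `truth` (latent labels, informative deficit names, `true_beta_fi`, and
#'   the pre-missingness FI used to generate survival).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  z <- with_seed(derive_seed(config$seed, "latent"),
                 rbinom(n, 1L, config$mix))  # 1 = frail

  informative <- character(0)
  cohort <- list()
  scores <- list()   # coded deficit scores, pre-missingness
  specs <- list()

  n_inf <- function(k) ceiling(config$informative_fraction * k)

  if (config$n_binary > 0) {
    nb <- config$n_binary
    p0 <- seq(0.05, 0.40, length.out = nb)
    inf <- seq_len(n_inf(nb))
    x <- with_seed(derive_seed(config$seed, "binary"), {
      sapply(seq_len(nb), function(j) {
        eta <- qlogis(p0[j]) + if (j %in% inf) config$effect_binary * z else 0
        rbinom(n, 1L, plogis(eta))
      })
    })
    for (j in seq_len(nb)) {
      nm <- sprintf("bin%02d", j)
      cohort[[nm]] <- c("absent", "present")[x[, j] + 1L]
      scores[[nm]] <- as.numeric(x[, j])
      specs[[nm]] <- deficit_spec(nm, "binary", coding = c(absent = 0, present = 1))
      if (j %in% inf) informative <- c(informative, nm)
    }
  }

  if (config$n_ordinal > 0) {
    no <- config$n_ordinal
    L <- config$ordinal_levels
    base_p <- 2^-(seq_len(L) - 1); base_p <- base_p / sum(base_p)
    tau <- qlogis(cumsum(base_p)[-L])
    inf <- seq_len(n_inf(no))
    sc <- ordinal_scores(L); lab <- ordinal_labels(L)
    x <- with_seed(derive_seed(config$seed, "ordinal"), {
      sapply(seq_len(no), function(j) {
        u <- rlogis(n) + if (j %in% inf) config$effect_continuous * z else 0
        colSums(outer(tau, u, `<`))  # 0..L-1
      })
    })
    for (j in seq_len(no)) {
      nm <- sprintf("ord%02d", j)
      cohort[[nm]] <- lab[x[, j] + 1L]
      scores[[nm]] <- sc[x[, j] + 1L]
      specs[[nm]] <- deficit_spec(nm, "ordinal", coding = setNames(sc, lab))
      if (j %in% inf) informative <- c(informative, nm)
    }
  }

  if (config$n_continuous > 0) {
    nc <- config$n_continuous
    inf <- seq_len(n_inf(nc))
    x <- with_seed(derive_seed(config$seed, "continuous"), {
      sapply(seq_len(nc), function(j)
        rnorm(n, mean = if (j %in% inf) config$effect_continuous * z else 0, sd = 1))
    })
    for (j in seq_len(nc)) {
      nm <- sprintf("cont%02d", j)
      cohort[[nm]] <- x[, j]
      scores[[nm]] <- as.numeric(x[, j] < -1.96 | x[, j] > 1.96)
      specs[[nm]] <- deficit_spec(nm, "continuous",
                                  ranges = data.frame(lower = -1.96, upper = 1.96))
      if (j %in% inf) informative <- c(informative, nm)
    }
  }

  if (!length(scores)) stopf("config generates no deficits")
  smat <- do.call(cbind, scores)
  fi_true <- rowMeans(smat)

  diag <- with_seed(derive_seed(config$seed, "diagnosis"), {
    sapply(seq_len(n), function(i)
      sample(c("HC", "MCI", "AD"), 1L, prob = config$diag_model[z[i] + 1L, ]))
  })

  cov <- with_seed(derive_seed(config$seed, "covariates"), {
    age <- pmin(90, pmax(55, round(rnorm(n, 75, 5), 1)))
    sex <- c("M", "F")[rbinom(n, 1L, 0.42) + 1L]
    education <- pmin(20, pmax(6, round(rnorm(n, 16, 2.5))))
    cdrsb <- ifelse(diag == "HC", 0,
             ifelse(diag == "MCI", pmax(0.5, round(rnorm(n, 1.5, 1) * 2) / 2),
                    pmax(1, round(rnorm(n, 4.5, 1.5) * 2) / 2)))
    mmse <- ifelse(diag == "HC", pmin(30, round(rnorm(n, 29, 1))),
            ifelse(diag == "MCI", pmin(30, pmax(24, round(rnorm(n, 27, 1.7)))),
                   pmin(26, pmax(18, round(rnorm(n, 23, 2))))))
    list(age = age, sex = sex, education = education, cdrsb = cdrsb, mmse = mmse)
  })

  surv <- simulate_survival(fi_true, config)

  cohort <- as.data.frame(cohort, optional = TRUE, stringsAsFactors = FALSE)
  if (config$missing_rate > 0) {
    miss <- with_seed(derive_seed(config$seed, "missing"),
                      matrix(runif(n * ncol(cohort)) < config$missing_rate,
                             nrow = n))
    for (j in seq_len(ncol(cohort))) cohort[[j]][miss[, j]] <- NA
  }
  cohort <- cbind(cohort, as.data.frame(cov, stringsAsFactors = FALSE),
                  diagnosis = diag, time = surv$time, event = surv$event)

  list(cohort = cohort,
       codebook = codebook(specs),
       truth = list(latent = c("fit", "frail")[z + 1L],
                    informative_set = informative,
                    true_beta_fi = config$beta_fi,
                    fi_true = fi_true))
}

#' Simulate right-censored conversion times from an FI
#'
#' Event times follow a Weibull baseline (shape `surv_shape`, scale
#' `surv_scale` days) with log hazard shifted by `beta_fi * (100 * fi)`.
#' Censoring times are drawn independently from a Weibull with the same
#' shape and a scale chosen so the baseline censoring probability is
#' `censor_rate`.
#'
#' @param fi Per-subject frailty index values in \[0, 1\].
#' @param config A [sim_config()] (fields `surv_shape`, `surv_scale`,
#'   `beta_fi`, `censor_rate`, `seed` are used).
#' @return Data frame with columns `time` (days) and `event` (1 = observed
#'   conversion, 0 = right-censored).
#' @export
simulate_survival <- function(fi, config) {
  stopifnot(inherits(config, "sim_config"))
  if (any(is.na(fi)) || any(fi < 0 | fi > 1)) stopf("fi values must lie in [0, 1]")
  n <- length(fi)
  with_seed(derive_seed(config$seed, "survival"), {
    lp <- config$beta_fi * 100 * fi
    u <- runif(n)
    t_event <- config$surv_scale * (-log(u) * exp(-lp))^(1 / config$surv_shape)
    cr <- config$censor_rate
    if (cr >= 1) {
      cens <- rweibull(n, config$surv_shape, config$surv_scale)
      return(data.frame(time = cens, event = 0L))
    }
    if (cr <= 0) return(data.frame(time = t_event, event = 1L))
    scale_c <- config$surv_scale * ((1 - cr) / cr)^(1 / config$surv_shape)
    cens <- rweibull(n, config$surv_shape, scale_c)
    data.frame(time = pmin(t_event, cens), event = as.integer(t_event <= cens))
  })
}
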