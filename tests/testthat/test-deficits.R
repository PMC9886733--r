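test_that("ordinal FAQ coding returns the four fractional scores", {
  spec <- faq_spec()
  expect_identical(code_deficit("normal", spec), 0)
  expect_identical(code_deficit("difficulty", spec), 0.25)
  expect_identical(code_deficit("requires assistance", spec), 0.5)
  expect_identical(code_deficit("dependent", spec), 1)
  expect_error(code_deficit("sometimes", spec), "absent from coding map")
})

test_that("continuous coding dichotomizes against (stratified) reference ranges", {
  g <- deficit_spec("glucose", "continuous",
                    ranges = data.frame(lower = 70, upper = 110))
  expect_identical(code_deficit(c(90, 65, 115, NA), g), c(0, 1, 1, NA))

  strat <- deficit_spec("hgb", "continuous",
                        ranges = data.frame(lower = c(12, 13.5), upper = c(16, 17.5),
                                            sex = c("F", "M")))
  expect_identical(code_deficit(c(13, 13), strat, age = c(70, 70),
                                sex = c("F", "M")), c(0, 1))
  expect_error(code_deficit(13, strat), "stratified")
  expect_error(code_deficit(13, strat, age = 70, sex = "X"), "no reference-range stratum")
})

test_that("invalid deficit specs are rejected", {
  expect_error(deficit_spec("a", "binary", coding = c(no = 0, yes = 0.5)), "\\{0, 1\\}")
  expect_error(deficit_spec("a", "ordinal", coding = c(l1 = 0.5, l2 = 0.25)),
               "non-decreasing")
  expect_error(deficit_spec("a", "continuous",
                            ranges = data.frame(lower = 5, upper = 2)), "lower < upper")
})

test_that("screening applies prevalence, missingness and exclusion rules", {
  n <- 1000
  cohort <- data.frame(
    rare = c(rep("present", 5), rep("absent", n - 5)),         # 0.5%
    gappy = c(rep(NA, 60), rep(c("present", "absent"), length.out = n - 60)),
    common = rep(c("present", "absent"), each = n / 2),         # 50%
    ubiquitous = c(rep("present", 0.9 * n), rep("absent", 0.1 * n)),
    banned = rep(c("present", "absent"), length.out = n),
    stringsAsFactors = FALSE)
  cb <- codebook(list(
    deficit_spec("rare", "binary", coding = c(absent = 0, present = 1)),
    deficit_spec("gappy", "binary", coding = c(absent = 0, present = 1)),
    deficit_spec("common", "binary", coding = c(absent = 0, present = 1)),
    deficit_spec("ubiquitous", "binary", coding = c(absent = 0, present = 1)),
    deficit_spec("banned", "binary", coding = c(absent = 0, present = 1),
                 excluded = TRUE, exclude_reason = "dementia-related exclusion")))
  rep <- screen_deficits(cohort, cb)
  expect_identical(rep$keep, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_match(rep$reason[rep$name == "rare"], "prevalence < 1%")
  expect_match(rep$reason[rep$name == "gappy"], "missing > 5%")
  expect_match(rep$reason[rep$name == "ubiquitous"], "prevalence > 80%")
  expect_identical(rep$reason[rep$name == "banned"], "dementia-related exclusion")

  # boundary cases are inclusive: exactly 1%, 80%, 5% all keep
  cb2 <- codebook(list(
    deficit_spec("at1", "binary", coding = c(absent = 0, present = 1)),
    deficit_spec("at80", "binary", coding = c(absent = 0, present = 1)),
    deficit_spec("at5m", "binary", coding = c(absent = 0, present = 1))))
  co2 <- data.frame(
    at1 = c(rep("present", 10), rep("absent", 990)),
    at80 = c(rep("present", 800), rep("absent", 200)),
    at5m = c(rep(NA, 50), rep(c("present", "absent"), length.out = 950)),
    stringsAsFactors = FALSE)
  expect_true(all(screen_deficits(co2, cb2)$keep))

  # idempotence: re-screening the kept set changes nothing
  kept <- rep$name[rep$keep]
  cb_kept <- codebook(cb$deficits[kept])
  rep2 <- screen_deficits(cohort[kept], cb_kept)
  expect_true(all(rep2$keep))

  expect_error(screen_deficits(cohort[-1], cb), "rare")
})

test_that("compute_fi implements the deficit-accumulation ratio and the 20% rule", {
  m <- matrix(0, nrow = 3, ncol = 93, dimnames = list(NULL, paste0("d", 1:93)))
  m[1, 1:10] <- 1
  m[2, 1:20] <- NA                       # 21.5% missing -> undefined
  m[3, 1:18] <- NA                       # 19.4% missing -> defined
  m[3, 19] <- 1
  fi <- compute_fi(m)
  expect_equal(fi[1], 10 / 93)
  expect_true(is.na(fi[2]))
  expect_equal(fi[3], 1 / 75)

  m2 <- matrix(0, 1, 26, dimnames = list(NULL, paste0("d", 1:26)))
  m2[1, 1:3] <- c(1, 0.5, 0.25)
  expect_equal(compute_fi(m2), 1.75 / 26)

  expect_error(compute_fi(m, character(0)), "empty")
  expect_error(compute_fi(m, "nope"), "not in matrix")
})

test_that("FI is monotone in deficit scores and bounded", {
  set.seed(1)
  m <- matrix(runif(40 * 20), 40, 20, dimnames = list(NULL, paste0("d", 1:20)))
  m[sample(length(m), 30)] <- NA
  fi <- compute_fi(m)
  expect_true(all(fi[!is.na(fi)] >= 0 & fi[!is.na(fi)] <= 1))
  m2 <- m
  m2[!is.na(m2[, 3]), 3] <- pmin(1, m2[!is.na(m2[, 3]), 3] + 0.2)
  fi2 <- compute_fi(m2)
  expect_true(all(fi2 >= fi, na.rm = TRUE))
})

test_that("summarize_fi reports the central tendency suite", {
  s <- summarize_fi(rep(0.2, 10))
  expect_equal(s$median, 0.2)
  expect_equal(s$sd, 0)
  expect_equal(s$p99, 0.2)
  expect_equal(summarize_fi(c(0.1, 0.2, 0.3, 0.4))$median, 0.25)
  set.seed(2)
  u <- runif(1000)
  expect_lt(abs(summarize_fi(u)$p99 - 0.99), 0.02)
  expect_error(summarize_fi(c(NA_real_, NA_real_)), "no defined FI")
})

test_that("catalogue codebook scores all-deficit subjects at exactly 1", {
  cat_df <- fi_item_catalogue()
  cb <- catalogue_codebook()
  items_c <- cat_df$name[cat_df$fi_c == 1]
  cohort <- as.data.frame(setNames(lapply(cat_df$name, function(nm) {
    switch(cat_df$kind[match(nm, cat_df$name)],
           binary = "present", ordinal = "dependent", continuous = 5)
  }), cat_df$name), optional = TRUE, check.names = FALSE)
  mat <- build_deficit_matrix(cohort, cb, items_c)
  expect_equal(unname(compute_fi(mat, items_c)), 1.0)
})
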