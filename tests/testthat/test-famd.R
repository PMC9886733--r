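random_mixed <- function(n = 60, ncont = 3, ncat = 2, levels = 3, seed = 1) {
  set.seed(seed)
  df <- as.data.frame(matrix(rnorm(n * ncont), n, ncont))
  names(df) <- paste0("x", seq_len(ncont))
  for (j in seq_len(ncat))
    df[[paste0("c", j)]] <- sample(letters[seq_len(levels)], n, replace = TRUE)
  mixed_table(df, continuous = paste0("x", seq_len(ncont)),
              categorical = paste0("c", seq_len(ncat)))
}

test_that("knn_impute is the identity on complete tables and copies a unique neighbour", {
  mt <- random_mixed(seed = 3)
  expect_identical(knn_impute(mt)$data, mt$data)

  df <- data.frame(x = c(0, 0.01, 10), c = c("a", "a", "b"),
                   stringsAsFactors = FALSE)
  df$x[1] <- NA
  mt2 <- mixed_table(df, "x", "c")
  imp <- knn_impute(mt2, k = 1)
  expect_equal(imp$data$x[1], 0.01)  # nearest by matching category

  df2 <- data.frame(x = c(1, 2, 3), c = c(NA, "a", "b"), stringsAsFactors = FALSE)
  imp2 <- knn_impute(mixed_table(df2, "x", "c"), k = 1)
  expect_equal(imp2$data$c[1], "a")  # nearest numeric neighbour's category
  expect_error(knn_impute(mt2, k = 5), "exceeds")
})

test_that("knn imputation beats column-mean imputation under MCAR", {
  set.seed(10)
  n <- 300
  # correlated continuous block so neighbours carry information
  z <- rnorm(n)
  df <- data.frame(x1 = z + rnorm(n, sd = 0.3), x2 = -z + rnorm(n, sd = 0.3),
                   x3 = z + rnorm(n, sd = 0.3))
  truth <- df
  holes <- matrix(runif(n * 3) < 0.05, n, 3)
  holes[rowSums(holes) == 3, 1] <- FALSE
  df[holes] <- NA
  mt <- mixed_table(df, names(df))
  imp <- knn_impute(mt, k = 10)$data
  rmse_knn <- sqrt(mean((as.matrix(imp)[holes] - as.matrix(truth)[holes])^2))
  colmean <- df
  for (j in 1:3) colmean[[j]][is.na(colmean[[j]])] <- mean(df[[j]], na.rm = TRUE)
  rmse_mean <- sqrt(mean((as.matrix(colmean)[holes] - as.matrix(truth)[holes])^2))
  expect_lt(rmse_knn, rmse_mean)
})

test_that("purely continuous FAMD reduces to correlation-matrix PCA", {
  set.seed(4)
  X <- matrix(rnorm(200), 40, 5)
  df <- as.data.frame(X); names(df) <- paste0("x", 1:5)
  fam <- fit_famd(mixed_table(df, names(df)))
  expect_equal(fam$eigenvalues, eigen(stats::cor(X))$values, tolerance = 1e-10)
})

test_that("total inertia follows the closed form n_cont + sum(k_j - 1)", {
  df <- data.frame(c1 = rep(c("a", "b", "c"), each = 10), stringsAsFactors = FALSE)
  fam <- fit_famd(mixed_table(df, categorical = "c1"))
  expect_equal(sum(fam$eigenvalues), 2, tolerance = 1e-8)

  set.seed(5)
  df2 <- data.frame(x1 = rnorm(30), x2 = rnorm(30),
                    c1 = sample(c("a", "b", "c"), 30, replace = TRUE),
                    stringsAsFactors = FALSE)
  fam2 <- fit_famd(mixed_table(df2, c("x1", "x2"), "c1"))
  expect_equal(sum(fam2$eigenvalues), 4, tolerance = 1e-8)
})

test_that("inertia identity and score moments hold on random mixed tables", {
  for (seed in 1:10) {
    lev <- 2 + seed %% 3
    mt <- random_mixed(n = 50, ncont = 2, ncat = 2, levels = lev, seed = seed)
    fam <- fit_famd(mt)
    k <- vapply(mt$categorical, function(v) length(unique(mt$data[[v]])), numeric(1))
    expect_equal(sum(fam$eigenvalues), 2 + sum(k - 1), tolerance = 1e-8)
    expect_equal(colMeans(fam$scores), rep(0, ncol(fam$scores)), tolerance = 1e-8,
                 ignore_attr = TRUE)
    cov_s <- crossprod(fam$scores) / fam$n
    expect_equal(cov_s, diag(fam$eigenvalues, length(fam$eigenvalues)),
                 tolerance = 1e-8, ignore_attr = TRUE)
    expect_true(all(diff(fam$eigenvalues) <= 1e-12))
  }
})

test_that("two-level balanced categorical FAMD matches PCA of the 0/1 matrix", {
  set.seed(6)
  n <- 40
  df <- data.frame(x = rnorm(n),
                   b1 = rep(c("y", "n"), n / 2),
                   b2 = rep(c("y", "y", "n", "n"), n / 4),
                   stringsAsFactors = FALSE)
  fam <- fit_famd(mixed_table(df, "x", c("b1", "b2")))
  # balanced two-level indicator standardized == FAMD category pair up to
  # rotation in the redundant category dimension; eigenvalues must agree
  M <- cbind(df$x, df$b1 == "y", df$b2 == "y")
  ev <- eigen(stats::cor(M))$values
  nz <- fam$eigenvalues[fam$eigenvalues > 1e-10]
  # each two-level variable contributes one informative dimension (k-1 = 1)
  expect_equal(sort(nz, decreasing = TRUE)[1:3], ev, tolerance = 1e-8)
})

test_that("degenerate columns are rejected", {
  df <- data.frame(x = rep(1, 10), c = rep(c("a", "b"), 5), stringsAsFactors = FALSE)
  expect_error(fit_famd(mixed_table(df, "x", "c")), "zero-variance")
  df2 <- data.frame(x = rnorm(10), c = rep("a", 10), stringsAsFactors = FALSE)
  expect_error(mixed_table(df2, "x", "c"), "fewer than 2")
})

test_that("select_components returns the smallest m reaching the target", {
  fake <- structure(list(eigenvalues = c(0.5, 0.2, 0.1, 0.1, 0.1)),
                    class = "famd_model")
  # cumulative shares 0.5, 0.7, 0.8: the >= rule reaches 0.80 at m = 3
  expect_identical(select_components(fake, 0.8), 3L)
  expect_identical(select_components(structure(list(eigenvalues = 3),
                                               class = "famd_model")), 1L)
  expect_identical(select_components(fake, 0.5), 1L)
  expect_error(select_components(fake, 0), "target")
  expect_identical(formals(select_components)$target, 0.80)
})

test_that("variable contributions aggregate categories and sum to 100", {
  df <- data.frame(x = rnorm(30))
  fam1 <- fit_famd(mixed_table(df, "x"))
  expect_equal(unname(variable_contributions(fam1, 1)), 100)

  mt <- random_mixed(seed = 7)
  fam <- fit_famd(mt)
  for (s in 1:3)
    expect_equal(sum(variable_contributions(fam, s)), 100, tolerance = 1e-6)
  expect_error(variable_contributions(fam, 99), "out of range")

  # a shared signal carries component 1 (u made empirically orthogonal)
  set.seed(8)
  z <- rnorm(100)
  u <- stats::residuals(lm(rnorm(100) ~ z))
  df3 <- data.frame(v1 = z, v2 = z + rnorm(100, sd = 1e-4), u = u)
  fam3 <- fit_famd(mixed_table(df3, names(df3)))
  ctr <- variable_contributions(fam3, 1)
  expect_gt(ctr[["v1"]] + ctr[["v2"]], 99)
})
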