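#' Assemble a mixed table for factor analysis
#'
#' @param data Data frame.
#' @param continuous,categorical Character vectors naming the columns of
#'   each kind. Categorical columns (binary or ordinal deficits treated as
#'   unordered categories) are converted to character.
#' @return An object of class `mixed_table`.
#' @export
mixed_table <- function(data, continuous = character(0),
                        categorical = character(0)) {
  cols <- c(continuous, categorical)
  if (!length(cols)) stopf("mixed table needs at least one column")
  bad <- setdiff(cols, names(data))
  if (length(bad)) stopf("columns absent: %s", paste(bad, collapse = ", "))
  df <- data[cols]
  for (v in continuous) df[[v]] <- as.numeric(df[[v]])
  for (v in categorical) {
    x <- as.character(df[[v]])
    x[!is.na(x) & !nzchar(x)] <- NA
    df[[v]] <- x
  }
  for (v in cols) {
    if (all(is.na(df[[v]]))) stopf("column '%s' is entirely missing", v)
    if (v %in% categorical && length(unique(na.omit(df[[v]]))) < 2)
      stopf("categorical column '%s' has fewer than 2 observed levels", v)
  }
  structure(list(data = df, continuous = continuous,
                 categorical = categorical), class = "mixed_table")
}

#' k-nearest-neighbour imputation for mixed data
#'
#' Fills missing cells using the k nearest rows under a mixed Gower-style
#' distance: squared differences of standardized continuous columns plus
#' simple matching (0/1 mismatch) on categorical columns, averaged over the
#' coordinates observed in both rows. Continuous gaps take the mean of the
#' k neighbours' values; categorical gaps take the modal category among the
#' k neighbours, ties broken deterministically by row order (nearer row
#' first, then earlier category).
#'
#' @param table A [mixed_table()] in which every row has at least one
#'   observed value.
#' @param k Number of neighbours (default 10).
#' @return A complete `mixed_table`.
#' @export
knn_impute <- function(table, k = 10) {
  stopifnot(inherits(table, "mixed_table"), k >= 1)
  df <- table$data
  n <- nrow(df)
  obs_any <- rowSums(!is.na(df)) > 0
  if (!all(obs_any)) stopf("row(s) with no observed values: %s",
                           paste(which(!obs_any), collapse = ", "))
  if (!anyNA(df)) return(table)

  # pairwise average distance over mutually observed coordinates
  num <- matrix(0, n, n); den <- matrix(0, n, n)
  if (length(table$continuous)) {
    X <- as.matrix(df[table$continuous])
    mu <- colMeans(X, na.rm = TRUE)
    sdev <- apply(X, 2, sd, na.rm = TRUE); sdev[sdev == 0] <- 1
    Z <- sweep(sweep(X, 2, mu), 2, sdev, "/")
    M <- !is.na(Z); A <- Z; A[!M] <- 0
    A2 <- A^2; Mn <- M + 0
    num <- num + A2 %*% t(Mn) + Mn %*% t(A2) - 2 * A %*% t(A)
    den <- den + Mn %*% t(Mn)
  }
  if (length(table$categorical)) {
    for (v in table$categorical) {
      x <- df[[v]]
      Mv <- !is.na(x)
      lev <- unique(x[Mv])
      match_ct <- matrix(0, n, n)
      for (l in lev) {
        il <- (Mv & x == l) + 0
        match_ct <- match_ct + outer(il, il)
      }
      obs_pair <- outer(Mv + 0, Mv + 0)
      num <- num + (obs_pair - match_ct)
      den <- den + obs_pair
    }
  }
  D <- ifelse(den > 0, num / den, Inf)
  diag(D) <- Inf

  out <- df
  for (v in names(df)) {
    miss <- which(is.na(df[[v]]))
    if (!length(miss)) next
    donors_all <- which(!is.na(df[[v]]))
    if (length(donors_all) < k)
      stopf("k = %d exceeds the %d candidate neighbours for '%s'",
            k, length(donors_all), v)
    for (i in miss) {
      d <- D[i, donors_all]
      ord <- donors_all[order(d, donors_all)]
      nb <- ord[seq_len(k)]
      if (v %in% table$continuous) {
        out[[v]][i] <- mean(df[[v]][nb])
      } else {
        vals <- df[[v]][nb]
        tab <- table(factor(vals, levels = unique(vals)))  # first-seen order
        out[[v]][i] <- names(tab)[which.max(tab)]
      }
    }
  }
  mixed_table(out, table$continuous, table$categorical)
}

#' Factor analysis of mixed data
#'
#' Joint decomposition of continuous and categorical variables: continuous
#' columns are standardized to mean 0, SD 1 (population SD, divisor n);
#' each category k of a categorical variable contributes the column
#' (indicator - p_k) / sqrt(p_k), where p_k is the category proportion.
#' The combined matrix is decomposed by SVD with uniform row weight 1/n;
#' eigenvalues are the squared singular values and sum to
#' n_continuous + sum_j (k_j - 1). Component signs follow the convention
#' that the largest-magnitude loading of each component is positive.
#'
#' @param table A complete [mixed_table()] (run [knn_impute()] first if
#'   there are gaps).
#' @return An object of class `famd_model` with fields `eigenvalues`,
#'   `scores` (subjects x components, covariance diag(lambda)), `loadings`,
#'   `col_var` (variable owning each loading column), `centers`, `scales`,
#'   `cat_props`, `n`.
#' @export
fit_famd <- function(table) {
  stopifnot(inherits(table, "mixed_table"))
  df <- table$data
  if (anyNA(df)) stopf("table has missing values; impute first")
  n <- nrow(df)
  if (n < 2) stopf("need at least 2 rows")

  blocks <- list(); owner <- character(0)
  centers <- list(); scales <- list(); props <- list()
  for (v in table$continuous) {
    x <- as.numeric(df[[v]])
    mu <- mean(x); s <- sqrt(mean((x - mu)^2))
    if (s == 0) stopf("zero-variance continuous column '%s'", v)
    blocks[[length(blocks) + 1L]] <- matrix((x - mu) / s, ncol = 1,
                                            dimnames = list(NULL, v))
    owner <- c(owner, v)
    centers[[v]] <- mu; scales[[v]] <- s
  }
  for (v in table$categorical) {
    x <- as.character(df[[v]])
    lev <- sort(unique(x))
    if (length(lev) < 2) stopf("single-level categorical column '%s'", v)
    p <- vapply(lev, function(l) mean(x == l), numeric(1))
    Z <- sapply(lev, function(l) ((x == l) - p[l]) / sqrt(p[l]))
    colnames(Z) <- paste(v, lev, sep = "=")
    blocks[[length(blocks) + 1L]] <- Z
    owner <- c(owner, rep(v, length(lev)))
    props[[v]] <- p
  }
  Z <- do.call(cbind, blocks)
  sv <- svd(Z / sqrt(n))
  lambda <- sv$d^2
  keep <- lambda > max(lambda) * 1e-12
  lambda <- lambda[keep]
  U <- sv$u[, keep, drop = FALSE]; V <- sv$v[, keep, drop = FALSE]
  # deterministic sign: largest |loading| per component positive
  for (s in seq_along(lambda)) {
    j <- which.max(abs(V[, s]))
    if (V[j, s] < 0) { V[, s] <- -V[, s]; U[, s] <- -U[, s] }
  }
  scores <- sqrt(n) * U %*% diag(sv$d[keep], nrow = sum(keep))
  colnames(scores) <- paste0("PC", seq_along(lambda))
  rownames(V) <- colnames(Z)
  structure(list(eigenvalues = lambda, scores = scores, loadings = V,
                 col_var = owner, centers = unlist(centers),
                 scales = unlist(scales), cat_props = props, n = n,
                 continuous = table$continuous,
                 categorical = table$categorical),
            class = "famd_model")
}

#' @export
print.famd_model <- function(x, ...) {
  cat(sprintf("<famd_model> n = %d, %d components, total inertia %.4f\n",
              x$n, length(x$eigenvalues), sum(x$eigenvalues)))
  invisible(x)
}

#' Number of components reaching a cumulative-variance target
#'
#' @param model A [fit_famd()] model.
#' @param target Cumulative variance share to reach (default 0.80); the
#'   smallest m whose cumulative share is >= `target` is returned.
#' @return Integer component count.
#' @export
select_components <- function(model, target = 0.80) {
  stopifnot(inherits(model, "famd_model"))
  if (target <= 0 || target > 1) stopf("target must lie in (0, 1]")
  share <- cumsum(model$eigenvalues) / sum(model$eigenvalues)
  as.integer(which(share >= target - 1e-12)[1])
}

#' Per-variable contributions to a component
#'
#' A variable's contribution to component s is 100 x the squared loadings
#' of its column(s) on that component divided by the eigenvalue-normalized
#' total (categorical variables aggregate over their category columns);
#' contributions sum to 100 per component.
#'
#' @param model A [fit_famd()] model.
#' @param component Component index.
#' @return Named numeric vector of percentage contributions.
#' @export
variable_contributions <- function(model, component) {
  stopifnot(inherits(model, "famd_model"))
  if (component < 1 || component > length(model$eigenvalues))
    stopf("component index out of range")
  l2 <- model$loadings[, component]^2
  ctr <- tapply(l2, model$col_var, sum)
  vars <- unique(model$col_var)
  100 * as.numeric(ctr[vars]) / sum(l2) -> out
  setNames(out, vars)
}
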