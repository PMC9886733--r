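#' Association between one deficit and cluster membership
#'
#' Regresses a single health deficit variable on the two-level cluster
#' indicator and tests the cluster term with a likelihood-ratio test:
#' logistic regression for binary deficits, proportional-odds ordinal
#' logistic regression for ordinal deficits, linear regression for
#' continuous deficits. Under quasi-complete separation (logistic/ordinal
#' fits) the p-value falls back to an exact conditional (Fisher) test of
#' the deficit x cluster table, flagged in the result.
#'
#' @param deficit Deficit values: 0/1 for binary, ordered scores/levels for
#'   ordinal, numeric for continuous.
#' @param labels Two-level cluster labels.
#' @param kind `"binary"`, `"ordinal"` or `"continuous"`.
#' @return List with `family`, `effect` (cluster coefficient), `p` (LRT),
#'   and `fallback` (TRUE when the exact test replaced the LRT).
#' @export
deficit_cluster_association <- function(deficit, labels,
                                        kind = c("binary", "ordinal", "continuous")) {
  kind <- match.arg(kind)
  ok <- !is.na(deficit) & !is.na(labels)
  y <- deficit[ok]
  g <- factor(labels[ok])
  if (nlevels(g) != 2) stopf("labels must have exactly two observed levels")
  x <- as.numeric(g == levels(g)[2])
  if (length(unique(y)) < 2) stopf("constant deficit column")

  if (kind == "binary") {
    yb <- as.numeric(as.numeric(y) > 0)
    fit <- suppressWarnings(glm(yb ~ x, family = binomial()))
    effect <- unname(coef(fit)[2])
    separated <- !fit$converged || abs(effect) > 15
    if (separated) {
      p <- fisher.test(table(yb, x))$p.value
      return(list(family = "logistic", effect = effect, p = p, fallback = TRUE))
    }
    p <- pchisq(fit$null.deviance - fit$deviance, df = 1, lower.tail = FALSE)
    return(list(family = "logistic", effect = effect, p = p, fallback = FALSE))
  }

  if (kind == "ordinal") {
    yo <- factor(y, levels = sort(unique(y)), ordered = TRUE)
    res <- tryCatch({
      fit1 <- suppressWarnings(MASS::polr(yo ~ x, method = "logistic", Hess = FALSE))
      fit0 <- suppressWarnings(MASS::polr(yo ~ 1, method = "logistic", Hess = FALSE))
      effect <- unname(coef(fit1)[1])
      if (abs(effect) > 15) stop("separation")
      p <- pchisq(fit0$deviance - fit1$deviance, df = 1, lower.tail = FALSE)
      list(family = "ordinal-logistic", effect = effect, p = p, fallback = FALSE)
    }, error = function(e) {
      p <- fisher.test(table(yo, x), simulate.p.value = nlevels(yo) > 5)$p.value
      list(family = "ordinal-logistic", effect = NA_real_, p = p, fallback = TRUE)
    })
    return(res)
  }

  yn <- as.numeric(y)
  n <- length(yn)
  fit <- lm(yn ~ x)
  rss1 <- sum(fit$residuals^2)
  rss0 <- sum((yn - mean(yn))^2)
  stat <- n * log(rss0 / rss1)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  list(family = "linear", effect = unname(coef(fit)[2]), p = p, fallback = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: q_(i) = min over j >= i of m * p_(j) / j,
#' capped at 1, order-preserving and never smaller than the raw p.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of adjusted values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) stopf("empty p-value vector")
  if (any(is.na(p)) || any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m * p[o] / (m:1)))[ro]
}

#' Rank all deficits against cluster membership
#'
#' Runs [deficit_cluster_association()] for every item (model family from
#' the codebook kind), applies [bh_adjust()], and orders by adjusted q
#' ascending with ties broken by raw p, then absolute effect, then name.
#'
#' @param cohort Cohort data frame (raw-scale deficit columns).
#' @param cb A [codebook()].
#' @param labels Two-level cluster labels.
#' @param items Items to rank (default: all codebook deficits).
#' @return Data frame of class `ranking_table` with columns `rank`, `name`,
#'   `family`, `effect`, `p`, `q`, `fallback`.
#' @export
rank_deficits <- function(cohort, cb, labels, items = deficit_names(cb)) {
  rows <- lapply(items, function(nm) {
    d <- cb$deficits[[nm]]
    raw <- cohort[[nm]]
    val <- if (d$kind == "continuous") as.numeric(raw)
           else code_deficit(raw, d)
    a <- deficit_cluster_association(val, labels, d$kind)
    data.frame(name = nm, family = a$family, effect = a$effect, p = a$p,
               fallback = a$fallback, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  ord <- order(out$q, out$p, -abs(ifelse(is.na(out$effect), 0, out$effect)),
               out$name)
  out <- out[ord, c("name", "family", "effect", "p", "q", "fallback")]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("ranking_table", "data.frame")
  out
}

#' Refined deficit selection at an FDR threshold
#'
#' Keeps the deficits with FDR-adjusted q strictly below `alpha`; the kept
#' list, in rank order, defines the refined FI item set.
#'
#' @param results A `ranking_table` from [rank_deficits()] (or any data
#'   frame with `name`, `p`, `q`, `effect`).
#' @param alpha Selection threshold (default 0.05).
#' @return List of class `refined_selection`: `items` (ordered kept
#'   names), `alpha`, `n_kept`, `table` (kept rows).
#' @export
refine_selection <- function(results, alpha = 0.05) {
  stopifnot(is.data.frame(results), all(c("name", "q") %in% names(results)))
  keep <- results[results$q < alpha, , drop = FALSE]
  if (!nrow(keep)) warnf("no deficits pass FDR < %g", alpha)
  structure(list(items = keep$name, alpha = alpha, n_kept = nrow(keep),
                 table = keep), class = "refined_selection")
}

#' @export
print.refined_selection <- function(x, ...) {
  cat(sprintf("<refined_selection> %d items at FDR < %g\n", x$n_kept, x$alpha))
  if (x$n_kept) print(utils::head(x$table[c("name", "q")], 10))
  invisible(x)
}
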