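#' Screening criteria for candidate deficits
#'
#' Standard inclusion criteria for deficit-accumulation indices: a deficit
#' must be present in at least `min_prevalence` of the sample but in no
#' more than `max_prevalence`, and must be missing in at most `max_missing`
#' of subjects. Bounds are inclusive (keep iff min <= prevalence <= max and
#' missingness <= max_missing).
#'
#' @param min_prevalence Lower prevalence bound (default 0.01).
#' @param max_prevalence Upper prevalence bound (default 0.80).
#' @param max_missing Maximum tolerated missingness fraction (default 0.05).
#' @return An object of class `screen_criteria`.
#' @export
screen_criteria <- function(min_prevalence = 0.01, max_prevalence = 0.80,
                            max_missing = 0.05) {
  stopifnot(0 <= min_prevalence, min_prevalence < max_prevalence,
            max_prevalence <= 1, 0 <= max_missing, max_missing <= 1)
  structure(list(min_prevalence = min_prevalence,
                 max_prevalence = max_prevalence,
                 max_missing = max_missing), class = "screen_criteria")
}

#' Code all deficits of a cohort into a deficit matrix
#'
#' Applies [code_deficit()] column by column, resolving stratified
#' reference ranges with the cohort's age/sex covariates.
#'
#' @param cohort Cohort data frame.
#' @param cb A [codebook()].
#' @param items Optional character vector restricting the columns coded.
#' @return Numeric matrix (subjects x deficits) with entries in \[0, 1\]
#'   and `NA` for missing.
#' @export
build_deficit_matrix <- function(cohort, cb, items = deficit_names(cb)) {
  missing_cols <- setdiff(items, names(cohort))
  if (length(missing_cols))
    stopf("deficit column(s) absent from cohort: %s",
          paste(missing_cols, collapse = ", "))
  age <- cohort[[cb$covariates[["age"]] %||% "age"]] %||% NULL
  sex <- cohort[[cb$covariates[["sex"]] %||% "sex"]] %||% NULL
  out <- sapply(items, function(nm)
    code_deficit(cohort[[nm]], cb$deficits[[nm]], age = age, sex = sex))
  out <- matrix(out, nrow = nrow(cohort), dimnames = list(NULL, items))
  out
}

#' Screen candidate deficits
#'
#' Computes per-variable prevalence (proportion of non-missing coded scores
#' greater than zero) and missingness, and applies [screen_criteria()].
#' Items flagged `excluded` in the codebook are dropped regardless, with
#' their recorded reason (e.g. dementia-related exclusion).
#'
#' @param cohort Cohort data frame.
#' @param cb A [codebook()].
#' @param criteria A [screen_criteria()].
#' @return Data frame of class `screen_report` with columns `name`, `kind`,
#'   `prevalence`, `missing`, `keep`, `reason`.
#' @export
screen_deficits <- function(cohort, cb, criteria = screen_criteria()) {
  stopifnot(inherits(cb, "codebook"), inherits(criteria, "screen_criteria"))
  items <- deficit_names(cb)
  mat <- build_deficit_matrix(cohort, cb, items)
  n <- nrow(mat)
  rep <- data.frame(name = items,
                    kind = vapply(cb$deficits, `[[`, character(1), "kind"),
                    prevalence = NA_real_, missing = NA_real_,
                    keep = NA, reason = "", stringsAsFactors = FALSE,
                    row.names = NULL)
  for (i in seq_along(items)) {
    x <- mat[, i]
    miss <- mean(is.na(x))
    prev <- if (all(is.na(x))) NA_real_ else mean(x[!is.na(x)] > 0)
    rep$prevalence[i] <- prev
    rep$missing[i] <- miss
    d <- cb$deficits[[items[i]]]
    if (d$excluded) {
      rep$keep[i] <- FALSE
      rep$reason[i] <- if (!is.na(d$exclude_reason)) d$exclude_reason
                       else "dementia-related exclusion"
    } else if (miss > criteria$max_missing) {
      rep$keep[i] <- FALSE
      rep$reason[i] <- sprintf("missing > %g%%", 100 * criteria$max_missing)
    } else if (is.na(prev) || prev < criteria$min_prevalence) {
      rep$keep[i] <- FALSE
      rep$reason[i] <- sprintf("prevalence < %g%%", 100 * criteria$min_prevalence)
    } else if (prev > criteria$max_prevalence) {
      rep$keep[i] <- FALSE
      rep$reason[i] <- sprintf("prevalence > %g%%", 100 * criteria$max_prevalence)
    } else {
      rep$keep[i] <- TRUE
      rep$reason[i] <- "kept"
    }
  }
  class(rep) <- c("screen_report", "data.frame")
  rep
}

#' Compute a frailty index
#'
#' The FI of a subject is the sum of their non-missing deficit scores over
#' an item list divided by the number of non-missing items, yielding a
#' value in \[0, 1\] (ordinal items contribute weight 1 to the denominator
#' regardless of fractional score). The FI is only defined for subjects
#' whose fraction of missing items is strictly below `max_missing`.
#'
#' @param matrix Deficit matrix from [build_deficit_matrix()].
#' @param item_list Character vector of columns to aggregate.
#' @param max_missing Missingness threshold (default 0.20; FI defined iff
#'   missing fraction < `max_missing`).
#' @return Numeric vector of FI values with `NA` where undefined.
#' @export
compute_fi <- function(matrix, item_list = colnames(matrix), max_missing = 0.20) {
  if (!length(item_list)) stopf("item_list must not be empty")
  bad <- setdiff(item_list, colnames(matrix))
  if (length(bad)) stopf("items not in matrix: %s", paste(bad, collapse = ", "))
  m <- matrix[, item_list, drop = FALSE]
  n_item <- length(item_list)
  n_miss <- rowSums(is.na(m))
  fi <- rowSums(m, na.rm = TRUE) / (n_item - n_miss)
  fi[n_miss / n_item >= max_missing] <- NA_real_
  fi[n_miss == n_item] <- NA_real_
  unname(fi)
}

#' Summarize FI values
#'
#' Central-tendency report for a frailty index: median, interquartile
#' range, mean, SD and the 99th percentile of the defined values.
#' Quantiles use the linear-interpolation sample-quantile convention
#' (R type 7).
#'
#' @param fi Numeric FI values (NA = undefined).
#' @return Named list with `n`, `median`, `q1`, `q3`, `mean`, `sd`, `p99`.
#' @export
summarize_fi <- function(fi) {
  x <- fi[!is.na(fi)]
  if (!length(x)) stopf("no defined FI values to summarize")
  q <- quantile(x, c(0.25, 0.5, 0.75, 0.99), type = 7, names = FALSE)
  list(n = length(x), median = q[2], q1 = q[1], q3 = q[3],
       mean = mean(x), sd = if (length(x) > 1) sd(x) else 0, p99 = q[4])
}

#' Packaged 93-item deficit catalogue with FI membership flags
#'
#' Loads the packaged catalogue of 93 candidate health deficits spanning
#' medication use, disease history, instrumental activities of daily
#' living (FAQ), neuropsychiatric symptoms (NPI), physical-exam findings,
#' self-reported symptoms, blood tests and vital signs, with membership
#' flags for three FI variants: `fi_s` (93-item standard set), `fi_r`
#' (26-item refined, data-driven set) and `fi_c` (40-item published
#' comparison list).
#'
#' @return Data frame with columns `name`, `kind`, `fi_s`, `fi_r`, `fi_c`.
#' @export
fi_item_catalogue <- function() {
  path <- system.file("extdata", "deficit_catalogue.tsv", package = "frailtykit")
  read.delim(path, stringsAsFactors = FALSE)
}

#' Illustrative codebook for the packaged deficit catalogue
#'
#' Builds a [codebook()] over the packaged 93-item catalogue. Coding
#' parameters (ordinal level maps, reference ranges, cut-points) are
#' illustrative defaults, not the restricted study's laboratory table:
#' binary items map absent/present to 0/1; FAQ items use the four-level
#' ordinal map 0/0.25/0.5/1; continuous items get placeholder unit-interval
#' ranges that a user is expected to override with population-appropriate
#' reference ranges.
#'
#' @return A [codebook()] with 93 deficits.
#' @export
catalogue_codebook <- function() {
  cat_df <- fi_item_catalogue()
  specs <- lapply(seq_len(nrow(cat_df)), function(i) {
    nm <- cat_df$name[i]
    switch(cat_df$kind[i],
      binary = deficit_spec(nm, "binary", coding = c(absent = 0, present = 1)),
      ordinal = deficit_spec(nm, "ordinal",
        coding = c("normal" = 0, "difficulty" = 0.25,
                   "requires assistance" = 0.5, "dependent" = 1)),
      continuous = deficit_spec(nm, "continuous",
        ranges = data.frame(lower = -1.96, upper = 1.96)))
  })
  codebook(specs)
}
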