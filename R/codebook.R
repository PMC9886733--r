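#' Declare a health deficit and its coding rule
#'
#' A `deficit_spec` describes how one raw health variable is converted to a
#' deficit score in \[0, 1\]. Binary items map raw values to 0/1 (deficit
#' present/absent); ordinal items (e.g. instrumental activities of daily
#' living such as the FAQ) map ordered response levels to fractional scores;
#' continuous items (laboratory values, vital signs) are dichotomized
#' against reference ranges, scoring 1 outside the applicable range and 0
#' within. Reference ranges may be stratified by sex and/or age band.
#'
#' @param name Variable name (unique within a codebook).
#' @param kind One of `"binary"`, `"ordinal"`, `"continuous"`.
#' @param coding For binary: named numeric vector mapping raw levels to
#'   0/1. For ordinal: named numeric vector mapping ordered raw levels to
#'   non-decreasing scores in \[0, 1\]. Ignored for continuous.
#' @param ranges For continuous: a data frame with columns `lower`, `upper`
#'   and optional `sex` (`"any"`, `"F"`, `"M"`) and `age_min`/`age_max`
#'   giving non-overlapping, exhaustive strata.
#' @param excluded Logical; drop this item during screening regardless of
#'   prevalence (used for dementia-related exclusions).
#' @param exclude_reason Reason string recorded in the screen report.
#' @return An object of class `deficit_spec`.
#' @examples
#' faq <- deficit_spec("faq_finances", "ordinal",
#'   coding = c("normal" = 0, "difficulty" = 0.25,
#'              "requires assistance" = 0.5, "dependent" = 1))
#' code_deficit("requires assistance", faq)
#' @export
deficit_spec <- function(name, kind = c("binary", "ordinal", "continuous"),
                         coding = NULL, ranges = NULL, excluded = FALSE,
                         exclude_reason = NA_character_) {
  kind <- match.arg(kind)
  if (kind %in% c("binary", "ordinal")) {
    if (is.null(coding) || is.null(names(coding)))
      stopf("deficit '%s': %s coding requires a named level->score map", name, kind)
    coding <- vapply(coding, as.numeric, numeric(1))
    if (any(coding < 0 | coding > 1))
      stopf("deficit '%s': scores must lie in [0, 1]", name)
    if (kind == "binary" && !all(coding %in% c(0, 1)))
      stopf("deficit '%s': binary coding must map to {0, 1}", name)
    if (kind == "ordinal" && is.unsorted(coding))
      stopf("deficit '%s': ordinal scores must be non-decreasing with severity", name)
  } else {
    if (is.null(ranges))
      stopf("deficit '%s': continuous items need reference ranges", name)
    ranges <- as.data.frame(ranges)
    if (!all(c("lower", "upper") %in% names(ranges)))
      stopf("deficit '%s': ranges need 'lower' and 'upper'", name)
    if (is.null(ranges$sex)) ranges$sex <- "any"
    if (is.null(ranges$age_min)) ranges$age_min <- -Inf
    if (is.null(ranges$age_max)) ranges$age_max <- Inf
    if (any(ranges$lower >= ranges$upper))
      stopf("deficit '%s': each reference range needs lower < upper", name)
  }
  structure(list(name = name, kind = kind, coding = coding, ranges = ranges,
                 excluded = isTRUE(excluded), exclude_reason = exclude_reason),
            class = "deficit_spec")
}

#' @export
print.deficit_spec <- function(x, ...) {
  cat(sprintf("<deficit_spec> %s (%s)%s\n", x$name, x$kind,
              if (x$excluded) paste0(" [excluded: ", x$exclude_reason, "]") else ""))
  invisible(x)
}

#' Assemble a codebook
#'
#' The codebook is the single source of truth for variable typing and
#' deficit coding: a list of [deficit_spec()] entries plus the names of the
#' covariate columns carried alongside the deficits.
#'
#' @param deficits List of `deficit_spec` objects with unique names.
#' @param covariates Named character vector (or list) of covariate column
#'   names; recognised roles are `age`, `sex`, `education`, `diagnosis`,
#'   `cdrsb`, `mmse`, `time`, `event`.
#' @return An object of class `codebook`.
#' @export
codebook <- function(deficits, covariates = c(age = "age", sex = "sex",
                     education = "education", diagnosis = "diagnosis",
                     cdrsb = "cdrsb", mmse = "mmse", time = "time",
                     event = "event")) {
  stopifnot(length(deficits) >= 1)
  nms <- vapply(deficits, function(d) d$name, character(1))
  if (anyDuplicated(nms)) stopf("duplicate deficit names in codebook")
  covariates <- unlist(covariates)
  if (any(covariates %in% nms))
    stopf("covariate columns must be disjoint from deficit columns")
  structure(list(deficits = setNames(deficits, nms), covariates = covariates),
            class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  kinds <- table(vapply(x$deficits, `[[`, character(1), "kind"))
  cat(sprintf("<codebook> %d deficits (%s); covariates: %s\n",
              length(x$deficits),
              paste(names(kinds), kinds, sep = "=", collapse = ", "),
              paste(x$covariates, collapse = ", ")))
  invisible(x)
}

deficit_names <- function(cb) names(cb$deficits)

#' Score one deficit
#'
#' Converts raw values of a single health variable to deficit scores under
#' its [deficit_spec()]: binary and ordinal values through their level maps,
#' continuous values to 1 when outside the applicable (age/sex-resolved)
#' reference range and 0 when within. Missing raw values yield missing
#' scores.
#'
#' @param raw Vector of raw values.
#' @param spec A `deficit_spec`.
#' @param age,sex Vectors (recycled) used to resolve stratified reference
#'   ranges; required when the spec's ranges are stratified.
#' @return Numeric vector of scores in \[0, 1\] with `NA` for missing.
#' @export
code_deficit <- function(raw, spec, age = NULL, sex = NULL) {
  stopifnot(inherits(spec, "deficit_spec"))
  n <- length(raw)
  if (spec$kind %in% c("binary", "ordinal")) {
    raw <- as.character(raw)
    out <- rep(NA_real_, n)
    ok <- !is.na(raw) & nzchar(raw)
    bad <- ok & !(raw %in% names(spec$coding))
    if (any(bad))
      stopf("deficit '%s': raw level(s) %s absent from coding map", spec$name,
            paste(unique(raw[bad]), collapse = ", "))
    out[ok] <- unname(spec$coding[raw[ok]])
    return(out)
  }
  x <- suppressWarnings(as.numeric(raw))
  out <- rep(NA_real_, n)
  r <- spec$ranges
  stratified <- any(r$sex != "any") || any(is.finite(r$age_min)) || any(is.finite(r$age_max))
  if (stratified && (is.null(age) || is.null(sex)))
    stopf("deficit '%s': stratified ranges need age and sex", spec$name)
  age <- rep_len(if (is.null(age)) NA_real_ else as.numeric(age), n)
  sex <- rep_len(if (is.null(sex)) "any" else as.character(sex), n)
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    hit <- (r$sex == "any" | r$sex == sex[i]) &
      (!is.finite(r$age_min) | (!is.na(age[i]) & age[i] >= r$age_min)) &
      (!is.finite(r$age_max) | (!is.na(age[i]) & age[i] < r$age_max))
    if (!any(hit))
      stopf("deficit '%s': no reference-range stratum matches age=%s sex=%s",
            spec$name, age[i], sex[i])
    rr <- r[which(hit)[1], ]
    out[i] <- as.numeric(x[i] < rr$lower | x[i] > rr$upper)
  }
  out
}

spec_to_list <- function(d) {
  out <- list(name = d$name, kind = d$kind)
  if (d$kind %in% c("binary", "ordinal"))
    out$coding <- as.list(d$coding)
  else
    out$ranges <- lapply(seq_len(nrow(d$ranges)), function(i) {
      r <- d$ranges[i, ]
      list(lower = r$lower, upper = r$upper, sex = r$sex,
           age_min = if (is.finite(r$age_min)) r$age_min else NULL,
           age_max = if (is.finite(r$age_max)) r$age_max else NULL)
    })
  if (d$excluded) {
    out$excluded <- TRUE
    out$exclude_reason <- d$exclude_reason
  }
  out
}

list_to_spec <- function(x) {
  if (x$kind %in% c("binary", "ordinal")) {
    deficit_spec(x$name, x$kind, coding = unlist(x$coding),
                 excluded = isTRUE(x$excluded),
                 exclude_reason = x$exclude_reason %||% NA_character_)
  } else {
    rg <- do.call(rbind, lapply(x$ranges, function(r)
      data.frame(lower = r$lower, upper = r$upper, sex = r$sex %||% "any",
                 age_min = r$age_min %||% -Inf, age_max = r$age_max %||% Inf)))
    deficit_spec(x$name, "continuous", ranges = rg,
                 excluded = isTRUE(x$excluded),
                 exclude_reason = x$exclude_reason %||% NA_character_)
  }
}

#' Read and write codebooks
#'
#' Codebooks are serialized as YAML (or JSON, by file extension) with a
#' `deficits:` list mirroring [deficit_spec()] and a `covariates:` map.
#'
#' @param cb A `codebook`.
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @return `read_codebook` returns a `codebook`; `write_codebook` returns
#'   `path` invisibly.
#' @export
write_codebook <- function(cb, path) {
  stopifnot(inherits(cb, "codebook"))
  obj <- list(deficits = lapply(unname(cb$deficits), spec_to_list),
              covariates = as.list(cb$covariates))
  if (grepl("\\.json$", path))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  else
    yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  obj <- if (grepl("\\.json$", path)) jsonlite::read_json(path)
         else yaml::read_yaml(path)
  codebook(lapply(obj$deficits, list_to_spec), covariates = unlist(obj$covariates))
}
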