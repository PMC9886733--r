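#' Read a cohort CSV against a codebook
#'
#' One subject per row; empty cells are missing. Columns are typed from the
#' codebook: continuous deficits and the numeric covariates become numeric,
#' binary/ordinal deficits and the remaining covariates stay character.
#' Unknown columns are kept and listed in the `unknown_columns` attribute.
#'
#' @param path CSV file path.
#' @param cb A [codebook()].
#' @return Typed data frame with attribute `unknown_columns`.
#' @export
read_cohort <- function(path, cb) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                 check.names = FALSE)
  declared <- c(deficit_names(cb), unname(cb$covariates))
  absent <- setdiff(declared, names(df))
  if (length(absent))
    stopf("cohort lacks declared column(s): %s", paste(absent, collapse = ", "))
  numeric_cov <- intersect(unname(cb$covariates[c("age", "education", "cdrsb",
                                                  "mmse", "time", "event")]),
                           names(df))
  numeric_cols <- c(names(which(vapply(cb$deficits, `[[`, character(1),
                                       "kind") == "continuous")), numeric_cov)
  for (v in numeric_cols) {
    raw <- df[[v]]
    num <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & is.na(num))
    if (length(bad))
      stopf("unparseable numeric cell in column '%s', row %d (value '%s')",
            v, bad[1], raw[bad[1]])
    df[[v]] <- num
  }
  attr(df, "unknown_columns") <- setdiff(names(df), declared)
  df
}

#' Write a cohort CSV (missing cells as empty strings)
#'
#' @param cohort Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the stage parameters of the full data-driven FI workflow.
#'
#' @param criteria A [screen_criteria()].
#' @param k Imputation neighbour count.
#' @param variance_target Cumulative-variance share for component
#'   retention.
#' @param q Fixed cluster count (default 2, the fit/frail design; `NULL` =
#'   select by relative inertia loss). The criterion's selection is always
#'   recorded in the manifest as `q_selected`.
#' @param q_max Largest cluster count considered.
#' @param alpha FDR threshold for the refined selection.
#' @param famd_input `"raw"` to decompose screened variables on their raw
#'   scale (continuous as continuous, binary/ordinal as categorical) or
#'   `"scores"` to decompose the coded deficit scores as categories.
#' @param cv A [cv_scheme()] for the diagnostic battery, or `NULL` to skip.
#' @param auc_grid Time grid (days) for AUC(t), or `NULL` to skip the
#'   prognostic battery.
#' @param fi_c_items Optional item list for a published comparison FI.
#' @param seed Master seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(criteria = screen_criteria(), k = 10,
                       variance_target = 0.80, q = 2, q_max = 10,
                       alpha = 0.05, famd_input = c("raw", "scores"),
                       cv = cv_scheme(repeats = 20), auc_grid = NULL,
                       fi_c_items = NULL, seed = 1L) {
  structure(list(criteria = criteria, k = k,
                 variance_target = variance_target, q = q, q_max = q_max,
                 alpha = alpha, famd_input = match.arg(famd_input),
                 cv = cv, auc_grid = auc_grid, fi_c_items = fi_c_items,
                 seed = as.integer(seed)), class = "run_config")
}

#' Run the data-driven FI pipeline
#'
#' Executes screen, impute, mixed-data factor decomposition, clustering on
#' the retained components, per-deficit ranking with FDR selection, FI
#' construction (standard `fi_s` over all kept items, refined `fi_r` over
#' the FDR-selected items, optional comparison `fi_c`), and — when the
#' cohort carries diagnosis and follow-up columns — the diagnostic and
#' prognostic evaluation batteries. When `out_dir` is given, every stage
#' artifact is written (TSV/CSV/JSON) together with a manifest recording
#' parameters and seed; reruns with the same config are identical.
#'
#' @param cohort Cohort data frame (from [read_cohort()] or
#'   [simulate_cohort()]).
#' @param cb A [codebook()].
#' @param config A [run_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return List of class `fi_pipeline`: `screen`, `famd`, `m` (components
#'   retained), `clusters`, `ranking`, `selection`, `fi` (data frame of FI
#'   variants), `classify`, `survival`, `manifest`.
#' @export
run_pipeline <- function(cohort, cb, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  screen <- screen_deficits(cohort, cb, config$criteria)
  kept <- screen$name[screen$keep]
  if (length(kept) < 2) stopf("screening kept fewer than 2 deficits")
  kinds <- vapply(cb$deficits[kept], `[[`, character(1), "kind")

  if (config$famd_input == "raw") {
    mt <- mixed_table(cohort, continuous = kept[kinds == "continuous"],
                      categorical = kept[kinds != "continuous"])
  } else {
    sc <- as.data.frame(build_deficit_matrix(cohort, cb, kept))
    mt <- mixed_table(sc, categorical = kept)
  }
  mt <- knn_impute(mt, k = config$k)
  fam <- fit_famd(mt)
  m <- select_components(fam, config$variance_target)

  dm <- build_deficit_matrix(cohort, cb, kept)
  fi_s <- compute_fi(dm, kept)

  retained <- fam$scores[, seq_len(m), drop = FALSE]
  q_selected <- choose_q(ward_tree(retained), q_max = config$q_max)
  sol <- hcpc(retained, q = config$q %||% q_selected, fi = fi_s)

  if (sol$q == 2) {
    ranking <- rank_deficits(cohort, cb, sol$labels, items = kept)
    selection <- refine_selection(ranking, alpha = config$alpha)
  } else {
    # ranking is defined against a binomial cluster indicator: contrast the
    # frailest cluster (highest mean FI) against the rest
    warnf("q = %d clusters; ranking contrasts the frailest cluster vs rest", sol$q)
    bin <- as.integer(sol$labels == sol$q)
    ranking <- rank_deficits(cohort, cb, bin, items = kept)
    selection <- refine_selection(ranking, alpha = config$alpha)
  }

  fi <- data.frame(fi_s = fi_s)
  fi$fi_r <- if (selection$n_kept) compute_fi(dm, selection$items) else NA_real_
  if (!is.null(config$fi_c_items)) {
    cc <- intersect(config$fi_c_items, colnames(dm))
    if (length(cc)) fi$fi_c <- compute_fi(dm, cc)
  }
  fi$cluster <- sol$cluster_names[sol$labels]

  classify <- NULL
  diag_col <- cb$covariates[["diagnosis"]] %||% "diagnosis"
  if (!is.null(config$cv) && diag_col %in% names(cohort)) {
    pairs <- list(c("HC", "AD"), c("MCI", "AD"), c("HC", "MCI"))
    classify <- list()
    for (pr in pairs) {
      sel <- cohort[[diag_col]] %in% pr
      if (sum(sel) < 2 * config$cv$folds) next
      key <- paste(pr, collapse = "_vs_")
      classify[[key]] <- lapply(setdiff(names(fi), "cluster"), function(v) {
        labs <- factor(cohort[[diag_col]][sel], levels = pr)
        ok <- !is.na(fi[[v]][sel])
        if (min(table(labs[ok])) < config$cv$folds) return(NULL)
        repeated_cv(fi[[v]][sel], labs, scheme = config$cv, positive = pr[2])
      })
      names(classify[[key]]) <- setdiff(names(fi), "cluster")
    }
  }

  surv_res <- NULL
  tcol <- cb$covariates[["time"]] %||% "time"
  ecol <- cb$covariates[["event"]] %||% "event"
  if (!is.null(config$auc_grid) && all(c(tcol, ecol) %in% names(cohort))) {
    mci <- cohort[[diag_col]] == "MCI"
    sd0 <- data.frame(time = cohort[[tcol]][mci], event = cohort[[ecol]][mci],
                      fi100 = 100 * fi$fi_r[mci],
                      age = cohort[[cb$covariates[["age"]] %||% "age"]][mci],
                      sex = cohort[[cb$covariates[["sex"]] %||% "sex"]][mci])
    sd0 <- sd0[complete.cases(sd0), ]
    if (sum(sd0$event) >= 2) {
      km <- km_logrank(sd0$time, sd0$event, fi_quartiles(sd0$fi100))
      cox <- cox_fit(sd0, c("fi100", "age", "sex"))
      aucs <- auc_t(sd0$fi100, sd0$time, sd0$event,
                    times = config$auc_grid, boot = 0)
      surv_res <- list(km = km, cox = cox, auc_t = aucs)
    }
  }

  manifest <- list(package_version = as.character(utils::packageVersion("frailtykit")),
                   seed = config$seed,
                   parameters = list(
                     min_prevalence = config$criteria$min_prevalence,
                     max_prevalence = config$criteria$max_prevalence,
                     max_missing = config$criteria$max_missing,
                     k = config$k, variance_target = config$variance_target,
                     q_max = config$q_max, alpha = config$alpha,
                     famd_input = config$famd_input),
                   n_subjects = nrow(cohort),
                   n_screened = length(deficit_names(cb)),
                   n_kept = length(kept),
                   m_components = m,
                   q = sol$q, q_selected = q_selected,
                   cluster_sizes = tabulate(sol$labels, sol$q),
                   n_refined = selection$n_kept,
                   refined_items = selection$items)

  res <- structure(list(screen = screen, famd = fam, m = m, clusters = sol,
                        ranking = ranking, selection = selection, fi = fi,
                        classify = classify, survival = surv_res,
                        manifest = manifest), class = "fi_pipeline")
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

write_pipeline <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) write.table(df, file.path(out_dir, f), sep = "\t",
                                   row.names = FALSE, quote = FALSE)
  w(res$screen, "screen_report.tsv")
  eig <- data.frame(component = seq_along(res$famd$eigenvalues),
                    eigenvalue = res$famd$eigenvalues,
                    share = res$famd$eigenvalues / sum(res$famd$eigenvalues))
  w(eig, "famd_eigenvalues.tsv")
  write.csv(res$famd$scores, file.path(out_dir, "famd_scores.csv"),
            row.names = FALSE)
  write.csv(data.frame(cluster = res$clusters$labels,
                       name = res$clusters$cluster_names[res$clusters$labels]),
            file.path(out_dir, "cluster_labels.csv"), row.names = FALSE)
  w(res$ranking, "deficit_ranking.tsv")
  write.csv(res$fi, file.path(out_dir, "fi_table.csv"), row.names = FALSE)
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.fi_pipeline <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(paste0("<fi_pipeline> n = %d; kept %d/%d deficits; %d components; ",
                     "q = %d (sizes %s); refined set: %d items\n"),
              m$n_subjects, m$n_kept, m$n_screened, m$m_components, m$q,
              paste(m$cluster_sizes, collapse = "/"), m$n_refined))
  invisible(x)
}
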