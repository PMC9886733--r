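#' Mann-Whitney AUC of a score
#'
#' Rank-statistic AUC (concordance of the score between positives and
#' negatives, ties counted 1/2).
#'
#' @param score Numeric marker values.
#' @param positive Logical (or 0/1) vector flagging the positive class.
#' @return AUC in \[0, 1\].
#' @export
auc_mw <- function(score, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Single-feature linear discriminant classifier
#'
#' Gaussian equal-variance discriminant on one feature: class-conditional
#' normals with a pooled within-class variance, class priors from the
#' training proportions, posterior by Bayes' rule, decision threshold at
#' posterior 0.5.
#'
#' @param x Numeric feature (e.g. an FI).
#' @param labels Two-level class labels.
#' @param positive Label of the positive class (default: second factor
#'   level; by convention the more-impaired diagnosis).
#' @return An object of class `lda_model`.
#' @export
lda_train <- function(x, labels, positive = NULL) {
  ok <- !is.na(x) & !is.na(labels)
  x <- x[ok]; labels <- factor(labels[ok])
  if (nlevels(labels) != 2) stopf("need exactly two classes")
  if (is.null(positive)) positive <- levels(labels)[2]
  if (!positive %in% levels(labels)) stopf("positive class not present")
  neg <- setdiff(levels(labels), positive)
  if (any(table(labels) < 2)) stopf("each class needs >= 2 members")
  mu <- c(neg = mean(x[labels == neg]), pos = mean(x[labels == positive]))
  ss <- sum((x[labels == neg] - mu["neg"])^2) +
        sum((x[labels == positive] - mu["pos"])^2)
  s2 <- ss / (length(x) - 2)
  if (s2 <= 0) stopf("zero pooled variance")
  pri <- c(neg = mean(labels == neg), pos = mean(labels == positive))
  structure(list(means = mu, var = s2, priors = pri,
                 positive = positive, negative = neg), class = "lda_model")
}

#' Predict with a single-feature LDA model
#'
#' @param object An `lda_model`.
#' @param newdata Numeric feature values.
#' @param ... Unused.
#' @return Data frame with `posterior` (positive class), `class`
#'   (predicted label at threshold 0.5), and `score` (the feature oriented
#'   so larger means more likely positive; its ranks reproduce the
#'   posterior ranks).
#' @export
predict.lda_model <- function(object, newdata, ...) {
  m <- object
  lp <- log(m$priors["pos"]) - (newdata - m$means["pos"])^2 / (2 * m$var)
  ln <- log(m$priors["neg"]) - (newdata - m$means["neg"])^2 / (2 * m$var)
  post <- 1 / (1 + exp(ln - lp))
  cls <- ifelse(post > 0.5, m$positive, m$negative)
  orient <- sign(m$means["pos"] - m$means["neg"])
  if (orient == 0) orient <- 1
  data.frame(posterior = as.numeric(post), class = cls,
             score = orient * newdata)
}

confusion_metrics <- function(truth_pos, pred_pos) {
  tp <- sum(truth_pos & pred_pos); fn <- sum(truth_pos & !pred_pos)
  fp <- sum(!truth_pos & pred_pos); tn <- sum(!truth_pos & !pred_pos)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  f1 <- if (!is.na(ppv) && !is.na(sens) && (ppv + sens) > 0)
          2 * ppv * sens / (ppv + sens) else NA_real_
  c(sensitivity = sens, specificity = spec, ppv = ppv, npv = npv, f1 = f1)
}

stratified_folds <- function(labels, folds, stratified = TRUE) {
  n <- length(labels)
  fold <- integer(n)
  if (stratified) {
    for (g in unique(labels)) {
      idx <- sample(which(labels == g))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  } else {
    fold[sample(n)] <- rep_len(seq_len(folds), n)
  }
  fold
}

#' Cross-validation scheme
#'
#' @param folds Number of folds (default 10).
#' @param repeats Number of repeats on freshly partitioned data (100).
#' @param stratified Stratify folds by class (default TRUE).
#' @param undersample Subsample the larger class to the smaller before
#'   partitioning, with a fresh draw per repeat (default FALSE).
#' @param seed RNG seed for partitions/undersampling.
#' @return An object of class `cv_scheme`.
#' @export
cv_scheme <- function(folds = 10, repeats = 100, stratified = TRUE,
                      undersample = FALSE, seed = 1L) {
  stopifnot(folds >= 2, repeats >= 1)
  structure(list(folds = folds, repeats = repeats, stratified = stratified,
                 undersample = undersample, seed = as.integer(seed)),
            class = "cv_scheme")
}

metric_names <- c("auc", "sensitivity", "specificity", "ppv", "npv", "f1")

metric_set <- function(per_repeat) {
  structure(list(per_repeat = per_repeat,
                 mean = colMeans(per_repeat, na.rm = TRUE),
                 sd = apply(per_repeat, 2, sd, na.rm = TRUE)),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat("<metric_set>\n")
  for (m in colnames(x$per_repeat))
    cat(sprintf("  %-12s %.3f (%.3f)\n", m, x$mean[m], x$sd[m]))
  invisible(x)
}

#' Repeated cross-validated classification of a single feature
#'
#' Per repeat: (optionally) undersample the larger class to the smaller,
#' partition into stratified folds, train the LDA on the remaining folds,
#' predict the held-out fold, pool the out-of-fold predictions, and compute
#' AUC (rank statistic of the pooled oriented scores), sensitivity,
#' specificity, PPV, NPV and F1 from the pooled confusion counts at the
#' posterior-0.5 threshold. Returns per-repeat values plus mean and SD.
#'
#' @param x Numeric feature (FI values).
#' @param labels Two-level class labels.
#' @param scheme A [cv_scheme()].
#' @param positive Positive-class label (default: more-impaired by factor
#'   order, i.e. the second level).
#' @return A `metric_set` (fields `per_repeat`, `mean`, `sd`).
#' @export
repeated_cv <- function(x, labels, scheme = cv_scheme(), positive = NULL) {
  ok <- !is.na(x) & !is.na(labels)
  x <- x[ok]; labels <- factor(labels[ok])
  if (nlevels(labels) != 2) stopf("need exactly two classes")
  if (is.null(positive)) positive <- levels(labels)[2]
  if (min(table(labels)) < scheme$folds)
    stopf("smallest class (%d) below fold count (%d)",
          min(table(labels)), scheme$folds)
  out <- with_seed(scheme$seed, {
    t(vapply(seq_len(scheme$repeats), function(r) {
      xi <- x; li <- labels
      if (scheme$undersample) {
        tab <- table(li)
        small <- min(tab)
        keep <- unlist(lapply(names(tab), function(g) {
          idx <- which(li == g)
          if (length(idx) > small) sample(idx, small) else idx
        }))
        xi <- xi[keep]; li <- droplevels(li[keep])
      }
      fold <- stratified_folds(as.character(li), scheme$folds, scheme$stratified)
      post <- numeric(length(xi)); scr <- numeric(length(xi))
      for (f in seq_len(scheme$folds)) {
        te <- fold == f
        m <- lda_train(xi[!te], li[!te], positive = positive)
        pr <- predict(m, xi[te])
        post[te] <- pr$posterior; scr[te] <- pr$score
      }
      truth <- li == positive
      c(auc = auc_mw(scr, truth), confusion_metrics(truth, post > 0.5))
    }, numeric(6)))
  })
  colnames(out) <- metric_names
  metric_set(out)
}

#' External pseudo-fold validation
#'
#' Fits a single LDA model on the full development sample, splits the
#' validation sample into `scheme$folds` folds `scheme$repeats` times,
#' scores each fold with the fixed model, and aggregates the per-fold
#' metrics (the repeats only shuffle the fold membership, providing an SD
#' for the fixed-model performance).
#'
#' @param dev_x,dev_labels Development-sample feature and labels.
#' @param val_x,val_labels Validation-sample feature and labels.
#' @param scheme A [cv_scheme()].
#' @param positive Positive-class label.
#' @return A `metric_set` whose rows are fold-level metrics.
#' @export
external_validate <- function(dev_x, dev_labels, val_x, val_labels,
                              scheme = cv_scheme(), positive = NULL) {
  dl <- factor(dev_labels)
  if (is.null(positive)) positive <- levels(dl)[2]
  model <- lda_train(dev_x, dev_labels, positive = positive)
  ok <- !is.na(val_x) & !is.na(val_labels)
  val_x <- val_x[ok]; val_labels <- factor(val_labels[ok])
  if (!positive %in% val_labels) stopf("positive class absent from validation data")
  if (nlevels(droplevels(val_labels)) < 2) stopf("validation data needs both classes")
  pr <- predict(model, val_x)
  truth <- val_labels == positive
  rows <- with_seed(scheme$seed, {
    do.call(rbind, lapply(seq_len(scheme$repeats), function(r) {
      fold <- stratified_folds(as.character(val_labels), scheme$folds,
                               scheme$stratified)
      t(vapply(seq_len(scheme$folds), function(f) {
        te <- fold == f
        c(auc = auc_mw(pr$score[te], truth[te]),
          confusion_metrics(truth[te], pr$posterior[te] > 0.5))
      }, numeric(6)))
    }))
  })
  colnames(rows) <- metric_names
  metric_set(rows)
}

#' Paired comparison of two classifiers
#'
#' Paired t-test over repeat-level metric values (one value per repeat for
#' each classifier, same partitions implied by pairing).
#'
#' @param a,b Equal-length numeric vectors of per-repeat metrics.
#' @return List with `estimate` (mean difference a - b), `t`, `df`, `p`,
#'   and `degenerate` (TRUE when the differences have zero variance, in
#'   which case no p-value is reported).
#' @export
compare_classifiers <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (sd(d) == 0)
    return(list(estimate = mean(d), t = NA_real_, df = length(d) - 1L,
                p = NA_real_, degenerate = TRUE))
  tt <- t.test(a, b, paired = TRUE)
  list(estimate = unname(tt$estimate), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value, degenerate = FALSE)
}
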