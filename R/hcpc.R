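#' Ward agglomeration on component scores
#'
#' Hierarchical clustering with Ward's minimum within-inertia-increase
#' criterion on Euclidean distances over the retained component scores
#' (Lance-Williams update on squared distances). Reported heights are
#' inertia gains: the increase of the within-cluster sum of squares caused
#' by each merge, so two points merge at half their squared distance.
#'
#' @param scores Numeric matrix, subjects x components.
#' @return An object of class `ward_tree` wrapping the `hclust` result with
#'   `gains` (per-merge inertia increase) and the data.
#' @export
ward_tree <- function(scores) {
  scores <- as.matrix(scores)
  if (nrow(scores) < 2) stopf("need at least 2 subjects")
  hc <- hclust(dist(scores)^2, method = "ward.D")
  structure(list(hclust = hc, gains = hc$height / 2, scores = scores),
            class = "ward_tree")
}

within_inertia <- function(scores, labels) {
  sum(vapply(unique(labels), function(g) {
    x <- scores[labels == g, , drop = FALSE]
    sum(sweep(x, 2, colMeans(x))^2)
  }, numeric(1)))
}

#' Choose the cluster count by relative inertia loss
#'
#' Let W(q) be the within-cluster inertia of the q-cluster cut and
#' gain(q) = W(q-1) - W(q) the inertia recovered by allowing a q-th
#' cluster. The selected q in 2..q_max maximizes gain(q) / gain(q + 1):
#' the cut after which further splitting buys comparatively little. Ties
#' break toward smaller q.
#'
#' @param tree A [ward_tree()].
#' @param q_max Largest cluster count considered (default 10).
#' @return Integer cluster count.
#' @export
choose_q <- function(tree, q_max = 10) {
  stopifnot(inherits(tree, "ward_tree"), q_max >= 2)
  n <- length(tree$gains) + 1L
  if (n <= q_max) stopf("need more subjects than q_max")
  gains <- rev(tree$gains)        # gains[q] = W(q-1) - W(q), q = 2..n
  if (sum(gains) <= 0) stopf("zero total inertia: all points identical")
  choose_q_from_gains(gains, q_max)
}

# gains[i] corresponds to q = i + 1
choose_q_from_gains <- function(gains, q_max) {
  qs <- 2:q_max
  ratio <- gains[qs - 1] / gains[qs]
  ratio[!is.finite(ratio)] <- Inf
  as.integer(qs[which.max(ratio)])
}

#' k-means consolidation of a hierarchical partition
#'
#' Lloyd iterations started from the centroids of the initial labels;
#' assignments to the nearest centroid, centroid update, until stable or
#' `max_iter` sweeps. An empty cluster arising mid-iteration is re-seeded
#' with the point farthest from its centroid (logged via a message).
#' Consolidation never increases within-cluster inertia.
#'
#' @param scores Numeric matrix, subjects x components.
#' @param initial_labels Integer labels from a tree cut.
#' @param max_iter Maximum Lloyd sweeps (default 100).
#' @return An object of class `cluster_solution`: `labels`, `q`,
#'   `within_inertia`, `initial_inertia`, `iterations`, `centroids`.
#' @export
consolidate <- function(scores, initial_labels, max_iter = 100) {
  scores <- as.matrix(scores)
  labels <- as.integer(factor(initial_labels))
  q <- max(labels)
  w0 <- within_inertia(scores, labels)
  cent <- t(sapply(seq_len(q), function(g)
    colMeans(scores[labels == g, , drop = FALSE])))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- sapply(seq_len(q), function(g)
      rowSums(sweep(scores, 2, cent[g, ])^2))
    new_labels <- max.col(-d2, ties.method = "first")
    for (g in seq_len(q)) {
      if (!any(new_labels == g)) {
        far <- which.max(d2[cbind(seq_len(nrow(scores)), new_labels)])
        message(sprintf("consolidate: re-seeding empty cluster %d with row %d",
                        g, far))
        new_labels[far] <- g
      }
    }
    cent <- t(sapply(seq_len(q), function(g)
      colMeans(scores[new_labels == g, , drop = FALSE])))
    if (identical(new_labels, labels) || iter >= max_iter) {
      labels <- new_labels
      break
    }
    labels <- new_labels
  }
  structure(list(labels = labels, q = q,
                 within_inertia = within_inertia(scores, labels),
                 initial_inertia = w0, iterations = iter, centroids = cent),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> q = %d, sizes: %s, within-inertia %.4f (%d iterations)\n",
              x$q, paste(tabulate(x$labels, x$q), collapse = "/"),
              x$within_inertia, x$iterations))
  invisible(x)
}

#' Hierarchical clustering on principal components
#'
#' The full HCPC pass: Ward tree on the retained FAMD component scores,
#' cluster-count selection by relative inertia loss (overridable with
#' `q`), tree cut, and k-means consolidation. When `fi` is supplied the
#' clusters are relabelled so cluster 1 ("fit") has the lower mean FI and
#' cluster 2 ("frail") the higher; otherwise cluster 1 is the larger.
#'
#' @param scores Retained component scores (subjects x m).
#' @param q Fixed cluster count, or `NULL` to select via [choose_q()].
#' @param q_max Passed to [choose_q()].
#' @param fi Optional FI vector used to order/name the clusters.
#' @return A `cluster_solution` with an additional `cluster_names` field
#'   (`"fit"`/`"frail"` when q = 2).
#' @export
hcpc <- function(scores, q = NULL, q_max = 10, fi = NULL) {
  tree <- ward_tree(scores)
  if (is.null(q)) q <- choose_q(tree, q_max = q_max)
  init <- cutree(tree$hclust, k = q)
  sol <- consolidate(scores, init)
  # order clusters: by ascending mean FI when available, else by size
  key <- if (!is.null(fi)) {
    vapply(seq_len(sol$q), function(g)
      mean(fi[sol$labels == g], na.rm = TRUE), numeric(1))
  } else {
    -tabulate(sol$labels, sol$q)
  }
  perm <- order(key)
  relab <- match(sol$labels, perm)
  sol$labels <- relab
  sol$centroids <- sol$centroids[perm, , drop = FALSE]
  sol$cluster_names <- if (sol$q == 2) c("fit", "frail")
                       else paste0("cluster", seq_len(sol$q))
  sol
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same subjects;
#' 1 for identical partitions, about 0 for independent ones.
#'
#' @param a,b Two label vectors of equal length.
#' @return Numeric ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
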