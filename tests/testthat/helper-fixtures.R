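# Shared fixture builders (all data generated in code).

faq_spec <- function(name = "faq_finances") {
  deficit_spec(name, "ordinal",
               coding = c("normal" = 0, "difficulty" = 0.25,
                          "requires assistance" = 0.5, "dependent" = 1))
}

tiny_codebook <- function() {
  codebook(list(
    deficit_spec("hyp", "binary", coding = c(absent = 0, present = 1)),
    faq_spec(),
    deficit_spec("glucose", "continuous",
                 ranges = data.frame(lower = 70, upper = 110))))
}

tiny_cohort <- function(n = 8) {
  data.frame(
    hyp = rep(c("absent", "present"), length.out = n),
    faq_finances = rep(c("normal", "difficulty", "requires assistance",
                         "dependent"), length.out = n),
    glucose = seq(60, 130, length.out = n),
    age = seq(60, 88, length.out = n), sex = rep(c("F", "M"), length.out = n),
    education = rep(16, n), diagnosis = rep(c("HC", "MCI", "AD"), length.out = n),
    cdrsb = rep(1, n), mmse = rep(28, n),
    time = seq(100, 1500, length.out = n), event = rep(c(1L, 0L), length.out = n),
    stringsAsFactors = FALSE)
}

# independent brute-force BH step-up (oracle; kept deliberately naive)
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- vapply(i:m, function(j) m * p[o[j]] / j, numeric(1))
    q[o[i]] <- min(1, min(vals))
  }
  q
}

# explicit Breslow partial-likelihood Newton (independent Cox oracle; no ties)
cox_brute <- function(time, event, x) {
  x <- as.matrix(x)
  beta <- rep(0, ncol(x))
  for (it in 1:50) {
    eta <- drop(x %*% beta); ex <- exp(eta)
    U <- rep(0, ncol(x)); I <- matrix(0, ncol(x), ncol(x))
    for (k in which(event == 1)) {
      r <- time >= time[k]
      s0 <- sum(ex[r])
      s1 <- colSums(x[r, , drop = FALSE] * ex[r])
      s2 <- t(x[r, , drop = FALSE] * ex[r]) %*% x[r, , drop = FALSE]
      U <- U + x[k, ] - s1 / s0
      I <- I + s2 / s0 - tcrossprod(s1 / s0)
    }
    step <- solve(I, U)
    beta <- beta + step
    if (max(abs(step)) < 1e-12) break
  }
  beta
}

# greedy Ward agglomeration recomputing within-inertia from member lists
# (independent of the Lance-Williams path)
ward_brute_partitions <- function(x) {
  n <- nrow(x)
  wss <- function(idx) {
    m <- x[idx, , drop = FALSE]
    sum(sweep(m, 2, colMeans(m))^2)
  }
  clusters <- as.list(seq_len(n))
  parts <- list()
  parts[[n]] <- clusters
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- NULL; best_cost <- Inf
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      cost <- wss(c(clusters[[i]], clusters[[j]])) -
        wss(clusters[[i]]) - wss(clusters[[j]])
      if (cost < best_cost - 1e-12) { best_cost <- cost; best <- c(i, j) }
    }
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    parts[[k - 1]] <- clusters
  }
  parts
}

partition_labels <- function(clusters, n) {
  lab <- integer(n)
  for (g in seq_along(clusters)) lab[clusters[[g]]] <- g
  lab
}
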