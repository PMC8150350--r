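# Independent brute-force oracles. Each re-derives a quantity from first
# principles, without calling the package's implementation path.

# product-limit estimator computed step by step from the risk-set definition
oracle_km <- function(times, events) {
  events <- as.logical(events)
  ut <- sort(unique(times[events]))
  surv <- numeric(length(ut))
  s <- 1
  for (i in seq_along(ut)) {
    at_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(times = ut, survival = surv)
}

# log-rank statistic from the per-event-time O-E contingency tables
oracle_logrank <- function(times, events, group) {
  group <- factor(group)
  g <- levels(group)
  ut <- sort(unique(times[as.logical(events)]))
  O <- E <- stats::setNames(numeric(length(g)), g)
  V <- 0 # variance of group-1 observed-minus-expected (2-group case)
  for (t in ut) {
    n_t <- sum(times >= t)
    d_t <- sum(times == t & events)
    for (k in g) {
      n_k <- sum(times >= t & group == k)
      O[k] <- O[k] + sum(times == t & events & group == k)
      E[k] <- E[k] + d_t * n_k / n_t
    }
    if (length(g) == 2) {
      n_1 <- sum(times >= t & group == g[1])
      if (n_t > 1) {
        V <- V + d_t * (n_1 / n_t) * (1 - n_1 / n_t) * (n_t - d_t) / (n_t - 1)
      }
    }
  }
  if (length(g) == 2) (O[g[1]] - E[g[1]])^2 / V else NA_real_
}

# WPGMA agglomeration by exhaustive pairwise merging on the distance matrix;
# returns the flat partition with k clusters
oracle_wpgma_cut <- function(x, k) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  members <- as.list(seq_len(n))
  while (length(members) > k) {
    idx <- which(d == min(d), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- min(idx[1, ]); j <- max(idx[1, ])
    new_d <- (d[i, ] + d[j, ]) / 2
    d[i, ] <- d[, i] <- new_d
    d[i, i] <- Inf
    d <- d[-j, -j, drop = FALSE]
    members[[i]] <- c(members[[i]], members[[j]])
    members[[j]] <- NULL
  }
  cl <- integer(n)
  for (c in seq_along(members)) cl[members[[c]]] <- c
  cl
}

# two flat clusterings describe the same partition (up to label names)
same_partition <- function(a, b) {
  all(!duplicated(unique(cbind(a, b))[, 1])) &&
    all(!duplicated(unique(cbind(a, b))[, 2]))
}

# CPS via exact integer arithmetic on a common denominator scale
oracle_cps <- function(pos_tc, pos_ic, total) {
  num <- 100 * (pos_tc + pos_ic)
  if (num >= 100 * total) 100 else num / total
}

# Cox partial log-likelihood (no ties assumed) for direct maximisation
oracle_cox_loglik <- function(beta, X, times, events) {
  eta <- as.vector(X %*% beta)
  ll <- 0
  for (i in which(as.logical(events))) {
    risk <- times >= times[i]
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  ll
}
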