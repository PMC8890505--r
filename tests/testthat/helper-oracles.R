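# Independent brute-force oracles used across tests. Each recomputes the
# target quantity by a different route than the package implementation.

# Exact two-sided Mann-Whitney p by enumerating all rank assignments
# (no ties assumed); follows the doubled-tail convention capped at 1.
mwu_exact_p_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(n1 + n2, n1)
  u_all <- apply(sets, 2, function(ix) sum(ix) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(p, 1)
}

# Benjamini-Hochberg step-up by the textbook formula:
# q_(i) = min_{j >= i} ( m * p_(j) / j ), mapped back to input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# PerMANOVA pseudo-F by the centroid route (valid for Euclidean distances):
# within-SS as squared deviations from group centroids, total-SS from the
# grand centroid -- independent of the pairwise-distance partition used by
# the package.
permanova_f_oracle <- function(X, g) {
  X <- as.matrix(X)
  g <- as.character(g)
  grand <- colMeans(X)
  ss_total <- sum(sweep(X, 2, grand)^2)
  ss_within <- 0
  for (lev in unique(g)) {
    idx <- g == lev
    ctr <- colMeans(X[idx, , drop = FALSE])
    ss_within <- ss_within + sum(sweep(X[idx, , drop = FALSE], 2, ctr)^2)
  }
  a <- length(unique(g))
  n <- nrow(X)
  ss_between <- ss_total - ss_within
  if (ss_within == 0) return(if (ss_between == 0) 0 else Inf)
  (ss_between / (a - 1)) / (ss_within / (n - a))
}

# All distinct two-group label assignments for an n1 + n2 design.
two_group_assignments <- function(n1, n2, labels = c("a", "b")) {
  n <- n1 + n2
  sets <- utils::combn(n, n1)
  lapply(seq_len(ncol(sets)), function(k) {
    g <- rep(labels[2], n)
    g[sets[, k]] <- labels[1]
    g
  })
}

# Count matrix of one stratum of an activation table.
stratum_counts <- function(tab, sex, condition) {
  as.matrix(tab[tab$sex == sex & tab$condition == condition, sdmn_regions()])
}
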