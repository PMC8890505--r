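## Centrality module: eigencentrality hub ranking on absolute edge weights
## and cross-sex top-k hub intersection.

#' Eigencentrality ranking of a treatment network
#'
#' Scores the regions by the leading (Perron) eigenvector of the network's
#' absolute-weight matrix, computed by power iteration (deterministic
#' uniform start vector, tolerance 1e-10, at most 10,000 iterations; the
#' iteration runs on `A + I`, which shares eigenvectors with `A` but has a
#' strictly dominant leading eigenvalue, so it converges on bipartite-like
#' graphs too). In a disconnected network only the component carrying the
#' largest leading eigenvalue is scored; other regions get 0. Scores are
#' non-negative and normalized to unit Euclidean norm; ranking ties are
#' broken lexicographically by region name.
#'
#' @param network A `treatment_network` (or a symmetric numeric matrix with
#'   region dimnames).
#' @param k Number of top hubs to extract (default 8).
#' @param tol Power-iteration convergence tolerance (default 1e-10).
#' @param max_iter Iteration cap (default 10000).
#' @return Object of class `centrality_ranking`: `scores` (named,
#'   non-negative, unit norm), `ranking` (data.frame `region`, `score`,
#'   `rank`), `top` (top-k region names), `k`, `eigenvalue`, `sex`,
#'   `condition`, `scored_component`.
#' @export
#' @examples
#' W <- matrix(0, 4, 4, dimnames = rep(list(c("hub", "a", "b", "c")), 2))
#' W["hub", c("a", "b", "c")] <- W[c("a", "b", "c"), "hub"] <- 0.5
#' eigencentrality(W, k = 2)$top
eigencentrality <- function(network, k = 8, tol = 1e-10, max_iter = 10000) {
  if (inherits(network, "treatment_network")) {
    A <- abs(network$weights)
    regions <- network$regions
    sex <- network$sex; condition <- network$condition
  } else {
    A <- abs(as.matrix(network))
    regions <- rownames(A)
    if (is.null(regions)) regions <- paste0("R", seq_len(nrow(A)))
    sex <- NA_character_; condition <- NA_character_
  }
  if (!isTRUE(all.equal(A, t(A)))) stop("weight matrix must be symmetric")
  diag(A) <- 0
  p <- nrow(A)
  if (all(A == 0)) stop("network has no nonzero edge")

  comp <- graph_components(A > 0)
  best <- NULL
  for (cid in unique(comp)) {
    idx <- which(comp == cid)
    if (length(idx) == 1) next  # isolated region: eigenvalue 0
    pr <- power_iteration(A[idx, idx, drop = FALSE], tol, max_iter)
    if (is.null(best) || pr$value > best$value)
      best <- list(value = pr$value, vector = pr$vector, idx = idx)
  }
  scores <- numeric(p)
  scores[best$idx] <- best$vector
  scores <- abs(scores)
  scores <- scores / sqrt(sum(scores^2))
  names(scores) <- regions

  ord <- order(-scores, regions)
  ranking <- data.frame(region = regions[ord], score = scores[ord],
                        rank = seq_len(p), stringsAsFactors = FALSE)
  rownames(ranking) <- NULL
  k <- min(k, p)
  structure(list(scores = scores, ranking = ranking,
                 top = ranking$region[seq_len(k)], k = k,
                 eigenvalue = best$value, sex = sex, condition = condition,
                 scored_component = regions[best$idx]),
            class = "centrality_ranking")
}

## power iteration for the leading eigenpair of a symmetric non-negative
## matrix; iterates on A + I so the dominant eigenvalue is strict.
power_iteration <- function(A, tol = 1e-10, max_iter = 10000) {
  n <- nrow(A)
  B <- A + diag(n)
  v <- rep(1 / sqrt(n), n)
  lam <- 1
  for (i in seq_len(max_iter)) {
    w <- B %*% v
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(list(value = 0, vector = v, iterations = i))
    w <- as.vector(w) / nw
    if (max(abs(w - v)) < tol) {
      v <- w
      break
    }
    v <- w
  }
  list(value = sum(v * (A %*% v)), vector = abs(v), iterations = i)
}

## connected components of a logical adjacency matrix (BFS)
graph_components <- function(adj) {
  n <- nrow(adj)
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}

#' @export
print.centrality_ranking <- function(x, ...) {
  cat(sprintf("Eigencentrality ranking (%s %s), leading eigenvalue %.4f\n",
              x$sex, x$condition, x$eigenvalue))
  print(utils::head(x$ranking, x$k), row.names = FALSE)
  invisible(x)
}

#' Intersection of top-k hub sets between two rankings
#'
#' @param a,b [eigencentrality()] rankings with the same `k`.
#' @return Object of class `hub_intersection`: `shared`, `only_a`,
#'   `only_b`, `k`, plus the source labels.
#' @export
#' @examples
#' W <- diag(0, 5); W[upper.tri(W)] <- runif(10); W <- W + t(W)
#' dimnames(W) <- rep(list(letters[1:5]), 2)
#' r <- eigencentrality(W, k = 3)
#' hub_intersection(r, r)$shared
hub_intersection <- function(a, b) {
  stopifnot(inherits(a, "centrality_ranking"),
            inherits(b, "centrality_ranking"))
  if (a$k != b$k)
    stop("rankings use different k (", a$k, " vs ", b$k, ")")
  shared <- intersect(a$top, b$top)
  structure(list(shared = shared,
                 only_a = setdiff(a$top, shared),
                 only_b = setdiff(b$top, shared),
                 k = a$k,
                 label_a = paste(a$sex, a$condition),
                 label_b = paste(b$sex, b$condition)),
            class = "hub_intersection")
}

#' @export
print.hub_intersection <- function(x, ...) {
  cat(sprintf("Top-%d hub intersection: %s vs %s\n", x$k, x$label_a,
              x$label_b))
  cat(sprintf("  shared (%d/%d): %s\n", length(x$shared), x$k,
              paste(x$shared, collapse = ", ")))
  cat("  only", x$label_a, ":", paste(x$only_a, collapse = ", "), "\n")
  cat("  only", x$label_b, ":", paste(x$only_b, collapse = ", "), "\n")
  invisible(x)
}
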