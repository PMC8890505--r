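## Connectivity module: treatment-level weighted functional connectivity by
## subsample bootstrapping of region-region correlations, per-instance
## density thresholding on absolute weights, and averaging; excitation /
## inhibition subnetwork extraction.

#' Configuration for connectivity-network construction
#'
#' @param s Subsample size (default 7). When a stratum has `n <= s` fish the
#'   effective size falls back to `s_eff = min(s, n - 1)` (leave-one-out in
#'   the worst case), unless `strict_s = TRUE`.
#' @param rho Density threshold: fraction of the `p (p - 1) / 2` possible
#'   edges retained per instance, keeping the largest absolute weights
#'   (default 0.23; with 19 regions this retains `round(0.23 * 171) = 39`
#'   edges).
#' @param method Correlation estimator: `"pearson"` (default) or
#'   `"spearman"`.
#' @param policy `"enumerate_all"` (default; all subsamples in lexicographic
#'   order) or `"random_m"` (`m` distinct seeded subsamples).
#' @param m Number of subsamples under `policy = "random_m"`.
#' @param aggregation `"zero"` (default: element-wise mean over instances
#'   with non-retained entries contributing 0, shrinking unstable edges
#'   toward 0) or `"retained"` (mean over the instances retaining the edge).
#' @param rounding Rule mapping `rho * E` to the retained-edge count:
#'   `"round"` (default, round-half-to-even), `"floor"`, `"ceiling"`.
#' @param strict_s Error instead of falling back when `n <= s`.
#' @param seed Seed for the `random_m` policy.
#' @return Object of class `connectivity_config`.
#' @export
connectivity_config <- function(s = 7, rho = 0.23,
                                method = c("pearson", "spearman"),
                                policy = c("enumerate_all", "random_m"),
                                m = 100, aggregation = c("zero", "retained"),
                                rounding = c("round", "floor", "ceiling"),
                                strict_s = FALSE, seed = NULL) {
  if (!is.numeric(s) || s < 2) stop("`s` must be >= 2")
  if (!is.numeric(rho) || rho <= 0 || rho > 1)
    stop("`rho` must lie in (0, 1]")
  structure(list(s = as.integer(s), rho = rho,
                 method = match.arg(method), policy = match.arg(policy),
                 m = as.integer(m), aggregation = match.arg(aggregation),
                 rounding = match.arg(rounding), strict_s = strict_s,
                 seed = seed),
            class = "connectivity_config")
}

#' Enumerate bootstrap subsamples of a stratum
#'
#' Under `enumerate_all`, returns all `choose(n, s_eff)` subsets in
#' lexicographic order with `s_eff = min(s, n - 1)` (so a stratum no larger
#' than `s` still yields at least `n` leave-one-out subsamples); under
#' `random_m`, returns `m` distinct seeded subsets.
#'
#' @param stratum_ids Vector of individual ids (length >= 3).
#' @param config A [connectivity_config()].
#' @return List of id vectors; attribute `s_eff` records the effective
#'   subsample size.
#' @export
#' @examples
#' length(enumerate_subsamples(1:9, connectivity_config(s = 7)))  # 36
#' length(enumerate_subsamples(1:7, connectivity_config(s = 7)))  # 7
enumerate_subsamples <- function(stratum_ids, config = connectivity_config()) {
  n <- length(stratum_ids)
  if (n < 3)
    stop("stratum has ", n, " individuals; >= 3 needed for correlations")
  s_eff <- min(config$s, n - 1L)
  if (config$strict_s && s_eff < config$s)
    stop("stratum size ", n, " does not admit subsamples of size ",
         config$s, " (strict_s = TRUE)")
  if (s_eff < 3) s_eff <- min(3L, n - 1L)
  if (s_eff < 3)
    stop("effective subsample size below 3; stratum too small")
  if (config$policy == "enumerate_all") {
    subs <- utils::combn(stratum_ids, s_eff, simplify = FALSE)
  } else {
    total <- choose(n, s_eff)
    m <- min(config$m, total)
    subs <- with_seed(config$seed, {
      seen <- character(0)
      out <- list()
      while (length(out) < m) {
        cand <- sort(sample(seq_len(n), s_eff))
        key <- paste(cand, collapse = ",")
        if (!key %in% seen) {
          seen <- c(seen, key)
          out[[length(out) + 1L]] <- stratum_ids[cand]
        }
      }
      out
    })
  }
  attr(subs, "s_eff") <- s_eff
  subs
}

#' Build one thresholded network instance from a subsample
#'
#' Computes the pairwise correlation matrix of the subsample's region
#' counts, then retains exactly `k = round(rho * E)` edges of largest
#' absolute weight (`E = p (p - 1) / 2`), zeroing the rest. Ties at the
#' cutoff are broken by lexicographic `(i, j)` edge order. A region with
#' zero variance within the subsample has all its correlations set to 0 and
#' is excluded from retention (recorded in `dropped_regions`); if fewer
#' than `k` nonzero edges exist, all of them are retained.
#'
#' @param counts Numeric subsample x regions matrix (>= 3 rows).
#' @param config A [connectivity_config()].
#' @return Object of class `network_instance`: `weights` (symmetric signed
#'   matrix, zero diagonal), `retained` (logical matrix mask), `k`,
#'   `regions`, `dropped_regions`.
#' @export
instance_network <- function(counts, config = connectivity_config()) {
  X <- as.matrix(counts)
  if (nrow(X) < 3) stop("subsample must have >= 3 rows")
  p <- ncol(X)
  if (p < 2) stop("need >= 2 regions")
  regions <- colnames(X)
  if (is.null(regions)) regions <- paste0("R", seq_len(p))
  sds <- apply(X, 2, stats::sd)
  dropped <- regions[sds == 0]
  C <- suppressWarnings(stats::cor(X, method = config$method))
  C[!is.finite(C)] <- 0
  diag(C) <- 0
  dimnames(C) <- list(regions, regions)

  E <- p * (p - 1) / 2
  k <- switch(config$rounding,
              round = round(config$rho * E),
              floor = floor(config$rho * E),
              ceiling = ceiling(config$rho * E))
  k <- as.integer(k)

  ei <- edge_index(regions)
  w <- C[cbind(ei$i, ei$j)]
  eligible <- which(w != 0)
  ord <- eligible[order(-abs(w[eligible]), ei$i[eligible], ei$j[eligible])]
  keep <- ord[seq_len(min(k, length(ord)))]

  W <- matrix(0, p, p, dimnames = dimnames(C))
  M <- matrix(FALSE, p, p, dimnames = dimnames(C))
  if (length(keep)) {
    W[cbind(ei$i[keep], ei$j[keep])] <- w[keep]
    W[cbind(ei$j[keep], ei$i[keep])] <- w[keep]
    M[cbind(ei$i[keep], ei$j[keep])] <- TRUE
    M[cbind(ei$j[keep], ei$i[keep])] <- TRUE
  }
  structure(list(weights = W, retained = M, k = k, regions = regions,
                 dropped_regions = dropped),
            class = "network_instance")
}

#' Aggregate network instances into a treatment network
#'
#' Default rule: element-wise mean over all instances with non-retained
#' entries contributing 0. Alternative (`aggregation = "retained"`): mean
#' over only the instances retaining the edge (0 where never retained).
#'
#' @param instances List of [instance_network()] objects (>= 1).
#' @param config A [connectivity_config()] (its `aggregation` field is
#'   used).
#' @param sex,condition Optional stratum labels carried on the result.
#' @return Object of class `treatment_network`: `weights` (symmetric signed
#'   matrix), `n_instances`, `regions`, `sex`, `condition`.
#' @export
aggregate_instances <- function(instances, config = connectivity_config(),
                                sex = NA_character_,
                                condition = NA_character_) {
  if (length(instances) < 1) stop("need >= 1 instance")
  regions <- instances[[1]]$regions
  Wsum <- Reduce(`+`, lapply(instances, `[[`, "weights"))
  if (config$aggregation == "zero") {
    W <- Wsum / length(instances)
  } else {
    Mcnt <- Reduce(`+`, lapply(instances, function(x) x$retained * 1))
    W <- ifelse(Mcnt > 0, Wsum / pmax(Mcnt, 1), 0)
  }
  structure(list(weights = W, n_instances = length(instances),
                 regions = regions, sex = sex, condition = condition),
            class = "treatment_network")
}

#' @export
print.treatment_network <- function(x, ...) {
  nz <- sum(x$weights[upper.tri(x$weights)] != 0)
  cat(sprintf("Treatment network (%s %s): %d regions, %d nonzero edges, %d instances aggregated\n",
              x$sex, x$condition, length(x$regions), nz, x$n_instances))
  invisible(x)
}

#' Build a treatment-level functional-connectivity network
#'
#' Full bootstrap construction for one sex x condition stratum: enumerate
#' subsamples of the stratum's fish, build one thresholded correlation
#' network per subsample, and average the instances.
#'
#' @param counts Numeric fish x regions count matrix for one stratum.
#' @param config A [connectivity_config()].
#' @param sex,condition Optional stratum labels.
#' @return A `treatment_network`.
#' @export
#' @examples
#' tab <- generate_activation(activation_model(seed = 5))
#' str <- tab[tab$sex == "F" & tab$condition == "winner", sdmn_regions()]
#' net <- build_treatment_network(as.matrix(str), connectivity_config(),
#'                                sex = "F", condition = "winner")
#' net
build_treatment_network <- function(counts, config = connectivity_config(),
                                    sex = NA_character_,
                                    condition = NA_character_) {
  X <- as.matrix(counts)
  subs <- enumerate_subsamples(seq_len(nrow(X)), config)
  instances <- lapply(subs, function(idx)
    instance_network(X[idx, , drop = FALSE], config))
  aggregate_instances(instances, config, sex = sex, condition = condition)
}

#' Split a treatment network into excitation and inhibition subnetworks
#'
#' The positive-weight edges form the excitation (positive co-activation)
#' subnetwork and the negative-weight edges the inhibition (negative
#' co-activation) subnetwork; zero-weight edges belong to neither.
#'
#' @param network A `treatment_network`.
#' @return Object of class `signed_subnetworks` with `excitation` and
#'   `inhibition` data.frames (`region_i`, `region_j`, `weight`).
#' @export
split_signed <- function(network) {
  stopifnot(inherits(network, "treatment_network"))
  ei <- edge_index(network$regions)
  w <- network$weights[cbind(ei$i, ei$j)]
  edges <- data.frame(region_i = ei$region_i, region_j = ei$region_j,
                      weight = w, stringsAsFactors = FALSE)
  structure(list(excitation = edges[edges$weight > 0, , drop = FALSE],
                 inhibition = edges[edges$weight < 0, , drop = FALSE],
                 sex = network$sex, condition = network$condition),
            class = "signed_subnetworks")
}

#' @export
print.signed_subnetworks <- function(x, ...) {
  cat(sprintf("Signed subnetworks (%s %s): %d excitation, %d inhibition edges\n",
              x$sex, x$condition, nrow(x$excitation), nrow(x$inhibition)))
  invisible(x)
}

#' Robustness of aggregated edge weights to the subsample size
#'
#' Rebuilds the treatment network at each requested subsample size and
#' reports the Spearman rank correlation of the aggregated edge-weight
#' vector between consecutive sizes — high values indicate the network is
#' robust to the choice of `s`.
#'
#' @param counts Fish x regions count matrix for one stratum.
#' @param config Base [connectivity_config()].
#' @param s_values Subsample sizes to scan (default `config$s + 0:2`).
#' @return Data.frame with `s`, `s_next`, `spearman`.
#' @export
robustness_scan <- function(counts, config = connectivity_config(),
                            s_values = config$s + 0:2) {
  X <- as.matrix(counts)
  nets <- lapply(s_values, function(sv) {
    cfg <- config
    cfg$s <- as.integer(sv)
    build_treatment_network(X, cfg)
  })
  ut <- upper.tri(nets[[1]]$weights)
  out <- lapply(seq_len(length(nets) - 1), function(i) {
    data.frame(s = s_values[i], s_next = s_values[i + 1],
               spearman = suppressWarnings(
                 stats::cor(nets[[i]]$weights[ut], nets[[i + 1]]$weights[ut],
                            method = "spearman")))
  })
  do.call(rbind, out)
}
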