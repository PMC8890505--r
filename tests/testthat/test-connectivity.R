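# convenience: a raw instance object built by hand for aggregation tests
manual_instance <- function(W, retained = W != 0) {
  structure(list(weights = W, retained = retained,
                 k = sum(W[upper.tri(W)] != 0),
                 regions = rownames(W), dropped_regions = character(0)),
            class = "network_instance")
}

test_that("subsample enumeration matches the binomial counts", {
  cfg <- connectivity_config(s = 7)
  expect_length(enumerate_subsamples(1:9, cfg), 36)     # C(9, 7)
  s8 <- enumerate_subsamples(1:8, cfg)
  expect_length(s8, 8)                                  # C(8, 7)
  ## n <= s falls back to leave-one-out
  s7 <- enumerate_subsamples(1:7, cfg)
  expect_length(s7, 7)
  expect_equal(attr(s7, "s_eff"), 6)
  expect_equal(s7[[1]], 1:6)                            # lexicographic order
  expect_error(enumerate_subsamples(1:7,
                                    connectivity_config(s = 7,
                                                        strict_s = TRUE)),
               "strict_s")
  expect_error(enumerate_subsamples(1:2, cfg), ">= 3")
})

test_that("random subsampling is seeded, distinct and reproducible", {
  cfg <- connectivity_config(s = 5, policy = "random_m", m = 20, seed = 77)
  a <- enumerate_subsamples(1:10, cfg)
  b <- enumerate_subsamples(1:10, cfg)
  expect_identical(a, b)
  expect_length(a, 20)
  keys <- vapply(a, paste, "", collapse = ",")
  expect_equal(anyDuplicated(keys), 0L)
})

test_that("every 19-region instance retains exactly round(0.23 * 171) = 39 edges", {
  set.seed(81)
  for (i in 1:5) {
    X <- matrix(rnbinom(7 * 19, mu = 30, size = 10), 7, 19,
                dimnames = list(NULL, sdmn_regions()))
    inst <- instance_network(X, connectivity_config())
    expect_equal(inst$k, 39)
    expect_equal(sum(inst$retained[upper.tri(inst$retained)]), 39)
    expect_equal(sum(inst$weights[upper.tri(inst$weights)] != 0), 39)
    expect_true(all(abs(inst$weights) <= 1))
    expect_true(all(diag(inst$weights) == 0))
  }
})

test_that("perfectly collinear regions give a unit edge that is always retained", {
  set.seed(83)
  X <- matrix(rnorm(7 * 19, 50, 10), 7, 19,
              dimnames = list(NULL, sdmn_regions()))
  X[, "Hv"] <- 2 * X[, "Vs"] + 1
  inst <- instance_network(X, connectivity_config())
  expect_equal(inst$weights["Vs", "Hv"], 1)
  expect_true(inst$retained["Vs", "Hv"])
})

test_that("thresholding matches a brute-force absolute-value sort oracle", {
  set.seed(89)
  for (i in 1:10) {
    X <- matrix(rnorm(6 * 4), 6, 4, dimnames = list(NULL, letters[1:4]))
    cfg <- connectivity_config(rho = 0.5)         # k = round(0.5 * 6) = 3
    inst <- instance_network(X, cfg)
    C <- cor(X); diag(C) <- 0
    w <- C[upper.tri(C)]
    keep_oracle <- rank(-abs(w), ties.method = "first") <= 3
    expect_equal(inst$retained[upper.tri(inst$retained)], keep_oracle)
  }
})

test_that("a zero-variance region is dropped from correlation and retention", {
  set.seed(97)
  X <- matrix(rnorm(8 * 5), 8, 5, dimnames = list(NULL, letters[1:5]))
  X[, "c"] <- 3
  inst <- instance_network(X, connectivity_config(rho = 0.5))
  expect_identical(inst$dropped_regions, "c")
  expect_true(all(inst$weights["c", ] == 0))
  expect_true(all(!inst$retained["c", ]))
})

test_that("aggregation rules behave as documented", {
  W1 <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  W2 <- W1
  W1["a", "b"] <- W1["b", "a"] <- 0.8
  i1 <- manual_instance(W1)
  i2 <- manual_instance(W2)
  cfg <- connectivity_config()
  agg1 <- aggregate_instances(list(i1), cfg)
  expect_equal(agg1$weights, W1)                  # single instance: identity
  agg <- aggregate_instances(list(i1, i2), cfg)
  expect_equal(agg$weights["a", "b"], 0.4)        # retained in half
  cfg$aggregation <- "retained"
  aggr <- aggregate_instances(list(i1, i2), cfg)
  expect_equal(aggr$weights["a", "b"], 0.8)       # mean over retainers
  ## aggregated weights are bounded by the max instance weight
  expect_true(all(abs(agg$weights) <= max(abs(W1))))
})

test_that("the pipeline is equivariant under region relabeling", {
  set.seed(101)
  X <- matrix(rnbinom(8 * 19, mu = 40, size = 8), 8, 19,
              dimnames = list(NULL, sdmn_regions()))
  cfg <- connectivity_config()
  net <- build_treatment_network(X, cfg)
  perm <- sample(19)
  net_p <- build_treatment_network(X[, perm], cfg)
  expect_equal(net_p$weights, net$weights[perm, perm], tolerance = 1e-12)
})

test_that("signed split partitions nonzero edges and swaps under negation", {
  set.seed(103)
  X <- matrix(rnorm(8 * 6), 8, 6, dimnames = list(NULL, letters[1:6]))
  net <- build_treatment_network(X, connectivity_config(rho = 0.6))
  sp <- split_signed(net)
  expect_true(all(sp$excitation$weight > 0))
  expect_true(all(sp$inhibition$weight < 0))
  nz <- sum(net$weights[upper.tri(net$weights)] != 0)
  expect_equal(nrow(sp$excitation) + nrow(sp$inhibition), nz)
  neg <- net
  neg$weights <- -net$weights
  sp_neg <- split_signed(neg)
  expect_equal(sp_neg$excitation$weight, -sp$inhibition$weight)
  expect_equal(sp_neg$inhibition$weight, -sp$excitation$weight)
  ## all-positive network has an empty inhibition set
  pos <- net
  pos$weights <- abs(net$weights)
  expect_equal(nrow(split_signed(pos)$inhibition), 0)
})

test_that("planted positive blocks surface as top excitation edges", {
  ## n = 30 so a single seed suffices; at field-realistic n the recovery is
  ## probabilistic and is measured as averaged precision elsewhere
  gs <- matrix(c(30L, rep(0L, 5)), 2, 3, byrow = TRUE,
               dimnames = list(c("M", "F"), sdmn_conditions()))
  am <- activation_model(blocks = list(list(regions = c("Vs", "Hv", "TPp"),
                                            r = 0.9)),
                         group_sizes = gs, seed = 107)
  tab <- generate_activation(am)
  cfg <- connectivity_config(policy = "random_m", m = 100, seed = 1)
  net <- build_treatment_network(stratum_counts(tab, "M", "isolated"), cfg)
  sp <- split_signed(net)
  top3 <- sp$excitation[order(-sp$excitation$weight), ][1:3, ]
  planted <- c("Hv", "TPp", "Vs")
  expect_true(all(top3$region_i %in% planted & top3$region_j %in% planted))
})

test_that("edge weights are rank-stable across neighboring subsample sizes", {
  gs <- matrix(c(9L, rep(0L, 5)), 2, 3, byrow = TRUE,
               dimnames = list(c("M", "F"), sdmn_conditions()))
  am <- activation_model(blocks = list(list(regions = c("Vs", "Hv", "TPp"),
                                            r = 0.9)),
                         group_sizes = gs, seed = 109)
  tab <- generate_activation(am)
  rb <- robustness_scan(stratum_counts(tab, "M", "isolated"),
                        connectivity_config(), s_values = 7:8)
  expect_equal(nrow(rb), 1)
  expect_gt(rb$spearman, 0.5)
})
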