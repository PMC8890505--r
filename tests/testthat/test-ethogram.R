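test_that("dyad summaries get frequencies and latency right", {
  ev <- data.frame(dyad_id = "d1", sex = "M", fish_id = "d1_f1",
                   behavior = rep("bite", 10),
                   t_seconds = seq(30, 300, length.out = 10))
  md <- data.frame(dyad_id = "d1", sex = "M", resolution_time = 5)
  sm <- summarize_dyads(ev, md)
  expect_equal(sm$total_bite, 10)
  expect_equal(sm$freq_bite, 2)          # 10 bites / 5 minutes
  expect_equal(sm$latency, 0.5)          # first bite at 30 s
  expect_equal(sm$aggressive_freq, 2)
  expect_equal(sm$submissive_freq, 0)
})

test_that("unknown behavior labels and degenerate metadata are rejected", {
  ev <- data.frame(dyad_id = "d1", sex = "M", fish_id = "d1_f1",
                   behavior = "headbutt", t_seconds = 10)
  md <- data.frame(dyad_id = "d1", sex = "M", resolution_time = 5)
  expect_error(summarize_dyads(ev, md), "headbutt")
  ev$behavior <- "bite"
  md$resolution_time <- 0
  expect_error(summarize_dyads(ev, md), "positive")
})

test_that("a dyad with no aggressive act has missing latency", {
  ev <- data.frame(dyad_id = "d1", sex = "F", fish_id = "d1_f2",
                   behavior = c("flee", "freeze"), t_seconds = c(20, 40))
  md <- data.frame(dyad_id = "d1", sex = "F", resolution_time = 3)
  sm <- summarize_dyads(ev, md)
  expect_true(is.na(sm$latency))
  expect_equal(sm$submissive_freq, 2 / 3)
})

test_that("summaries of generated events round-trip the generator ledger", {
  d <- generate_dyads(behavior_model(seed = 31), 6)
  md <- d$summaries[c("dyad_id", "sex", "resolution_time")]
  sm <- summarize_dyads(d$events, md)
  cols <- c(paste0("total_", ethogram_behaviors()),
            paste0("freq_", ethogram_behaviors()),
            "aggressive_freq", "submissive_freq")
  expect_equal(sm[cols], d$summaries[cols])
  expect_equal(sm$latency, d$summaries$latency)
})

test_that("identical samples give a null test result", {
  r <- gated_two_group_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$p_value, 1)
  if (r$test == "t") expect_equal(r$statistic, 0)
})

test_that("the gate routes non-normal samples to Mann-Whitney with exact p", {
  x <- c(1, 1.05, 1.1, 1.15, 9)   # strongly skewed: fails Shapiro-Wilk
  y <- c(10, 11, 12, 13, 20)
  r <- gated_two_group_test(x, y)
  expect_identical(r$test, "mann_whitney")
  expect_false(r$gate$x$pass)
  expect_equal(r$u_statistic, 0)
  expect_equal(r$statistic, 0 + 5 * 6 / 2)  # rank-sum W convention
  expect_equal(r$p_value, 2 / choose(10, 5))
})

test_that("a constant sample fails the gate and routes to Mann-Whitney", {
  r <- gated_two_group_test(rep(2, 5), c(1, 2, 3, 4, 5))
  expect_identical(r$test, "mann_whitney")
  expect_false(r$gate$x$pass)
  expect_true(is.na(r$gate$x$p))
})

test_that("Mann-Whitney exact p matches the rank-enumeration oracle (n <= 8)", {
  set.seed(41)
  for (rep in 1:12) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- rnorm(n1); y <- rnorm(n2, sample(c(0, 1.5), 1))
    w <- wilcox.test(x, y, alternative = "two.sided")
    expect_equal(w$p.value, mwu_exact_p_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("behavior PCA has orthonormal loadings and coherent proportions", {
  set.seed(43)
  X <- matrix(rpois(200, 10), 25, 8)
  colnames(X) <- ethogram_behaviors()
  p <- behavior_pca(X)
  expect_equal(t(p$loadings) %*% p$loadings, diag(8), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sum(p$prop_var), 1)
  expect_true(all(diff(p$cum_var) >= -1e-12))
  sc_cov <- cov(p$scores)
  expect_lt(max(abs(sc_cov[upper.tri(sc_cov)])), 1e-8)
  ## sign convention: the dominant loading of each component is negative
  for (j in 1:8) expect_lte(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
})

test_that("PCA puts all variance on a single varying behavior", {
  X <- cbind(bite = c(0, 1, 4, 9, 16, 25), chase = rep(4, 6))
  p <- behavior_pca(X)        # sqrt(bite) is 0..5, chase constant
  expect_equal(p$prop_var[1], 1)
  expect_equal(p$prop_var[2], 0)
})

test_that("an isotropic 2-behavior cloud splits variance evenly", {
  set.seed(47)
  Z <- matrix(rnorm(2 * 2000, mean = 20, sd = 1), ncol = 2)^2
  p <- behavior_pca(Z)        # sqrt undoes the square: isotropic Gaussian
  expect_equal(p$prop_var[1], 0.5, tolerance = 0.05)
})

test_that("PCA matches the prcomp oracle on sqrt-transformed totals", {
  set.seed(53)
  X <- matrix(rpois(160, 15), 20, 8)
  p <- behavior_pca(X)
  o <- prcomp(sqrt(X), center = TRUE, scale. = FALSE)
  expect_equal(p$sdev, o$sdev, tolerance = 1e-10)
  expect_equal(abs(unclass(p$loadings)), abs(unclass(o$rotation)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(abs(p$scores), abs(o$x), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("perMANOVA matches centroid-oracle F and exhaustive enumeration p", {
  set.seed(59)
  X <- matrix(rnorm(12), 6, 2)
  g <- rep(c("a", "b"), each = 3)
  pm <- permanova(X, g, n_perm = 99, seed = 1)
  expect_equal(pm$f_statistic, permanova_f_oracle(X, g), tolerance = 1e-10)
  expect_equal(pm$ss[["between"]] + pm$ss[["within"]], pm$ss[["total"]],
               tolerance = 1e-10)
  ## exhaustive p over all C(6,3) = 20 label assignments, by both routes
  assigns <- two_group_assignments(3, 3)
  f_mine <- vapply(assigns,
                   function(gg) permanova(X, gg, n_perm = 1)$f_statistic, 0)
  f_oracle <- vapply(assigns, function(gg) permanova_f_oracle(X, gg), 0)
  expect_equal(f_mine, f_oracle, tolerance = 1e-10)
  p_exh <- mean(f_oracle >= pm$f_statistic - 1e-12)
  ## full-resolution permutation p converges to the exhaustive value
  pm_big <- permanova(X, g, n_perm = 1999, seed = 2)
  expect_lt(abs(pm_big$p_value - p_exh), 0.05)
})

test_that("perMANOVA agrees with vegan::adonis2 on a fixture", {
  skip_if_not_installed("vegan")
  set.seed(61)
  X <- rbind(matrix(rnorm(30), 10), matrix(rnorm(30, 1), 10))
  g <- rep(c("a", "b"), each = 10)
  pm <- permanova(X, g, n_perm = 199, seed = 3)
  ad <- vegan::adonis2(dist(X) ~ g, permutations = 199)
  expect_equal(pm$f_statistic, ad$F[1], tolerance = 1e-8)
  expect_equal(unname(pm$ss), c(ad$SumOfSqs[1], ad$SumOfSqs[2],
                                ad$SumOfSqs[3]), tolerance = 1e-8)
})

test_that("perMANOVA F is invariant to translation and rotation", {
  set.seed(67)
  X <- matrix(rnorm(40), 10, 4)
  g <- rep(c("a", "b"), each = 5)
  f0 <- permanova(X, g, n_perm = 1)$f_statistic
  f_shift <- permanova(X + 7, g, n_perm = 1)$f_statistic
  Q <- qr.Q(qr(matrix(rnorm(16), 4)))
  f_rot <- permanova(X %*% Q, g, n_perm = 1)$f_statistic
  expect_equal(f_shift, f0, tolerance = 1e-10)
  expect_equal(f_rot, f0, tolerance = 1e-10)
})

test_that("degenerate perMANOVA inputs are guarded", {
  X <- matrix(1, 6, 2)
  pm <- permanova(X, rep(c("a", "b"), each = 3), n_perm = 99)
  expect_equal(pm$f_statistic, 0)
  expect_equal(pm$p_value, 1)
  expect_error(permanova(matrix(rnorm(8), 4), c("a", "a", "a", "b")),
               "size-1")
})

test_that("the behavioral battery runs on generated summaries", {
  d <- generate_dyads(behavior_model(seed = 71), 12)
  bt <- ethogram_test_battery(d$summaries)
  expect_equal(nrow(bt), 12)  # latency, resolution, 8 freqs, 2 aggregates
  expect_true(all(bt$p_value >= 0 & bt$p_value <= 1))
  expect_true(all(bt$test %in% c("t", "mann_whitney")))
})
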