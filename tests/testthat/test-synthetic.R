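test_that("dyad generation is deterministic under a fixed seed", {
  m <- behavior_model(seed = 11)
  a <- generate_dyads(m, 5)
  b <- generate_dyads(m, 5)
  expect_identical(a$events, b$events)
  expect_identical(a$summaries, b$summaries)
})

test_that("all-zero rates yield an empty behavioral process", {
  rates <- default_behavior_rates() * 0
  m <- behavior_model(rates = rates, seed = 3)
  d <- generate_dyads(m, 4)
  expect_equal(nrow(d$events), 0)
  freq_cols <- paste0("freq_", ethogram_behaviors())
  expect_true(all(as.matrix(d$summaries[freq_cols]) == 0))
  expect_true(all(is.na(d$summaries$latency)))
  expect_true(all(d$summaries$aggressive_freq == 0))
})

test_that("invalid behavior rates are rejected at construction", {
  bad <- default_behavior_rates()
  bad["M", "bite"] <- -1
  expect_error(behavior_model(rates = bad), "non-negative")
  bad["M", "bite"] <- Inf
  expect_error(behavior_model(rates = bad), "finite")
  expect_error(behavior_model(dispersion = 0), "dispersion")
})

test_that("generating strike rates are recovered from 200 dyads per sex", {
  rates <- default_behavior_rates()
  rates["M", "strike"] <- 0.9
  rates["F", "strike"] <- 0.3
  m <- behavior_model(
    rates = rates,
    fight_duration = list(M = c(meanlog = log(8), sdlog = 0.4),
                          F = c(meanlog = log(8), sdlog = 0.4)),
    seed = 21)
  d <- generate_dyads(m, 200)
  ratio <- mean(d$summaries$freq_strike[d$summaries$sex == "M"]) /
    mean(d$summaries$freq_strike[d$summaries$sex == "F"])
  expect_gte(ratio, 2.5)
  expect_lte(ratio, 3.5)
})

test_that("activation generation is deterministic and respects the contract", {
  am <- activation_model(seed = 13)
  a <- generate_activation(am)
  b <- generate_activation(am)
  expect_identical(a, b)
  expect_silent(validate_activation_table(a))
  cnt <- as.matrix(a[sdmn_regions()])
  expect_true(all(cnt >= 0))
  expect_true(all(cnt == round(cnt)))
  expect_equal(nrow(a), sum(activation_model(seed = 13)$group_sizes))
})

test_that("without planted blocks, empirical correlations stay near zero at n = 500", {
  gs <- matrix(c(500L, 0L, 0L, 0L, 0L, 0L), 2, 3, byrow = TRUE,
               dimnames = list(c("M", "F"), sdmn_conditions()))
  am <- activation_model(group_sizes = gs, seed = 17)
  tab <- generate_activation(am)
  C <- cor(stratum_counts(tab, "M", "isolated"))
  expect_lt(max(abs(C[upper.tri(C)])), 0.15)
})

test_that("a planted correlation block is recovered at n = 500", {
  gs <- matrix(c(500L, 0L, 0L, 0L, 0L, 0L), 2, 3, byrow = TRUE,
               dimnames = list(c("M", "F"), sdmn_conditions()))
  blk <- c("Vs", "Hv", "TPp")
  am <- activation_model(blocks = list(list(regions = blk, r = 0.9)),
                         group_sizes = gs, seed = 19)
  tab <- generate_activation(am)
  C <- cor(stratum_counts(tab, "M", "isolated"))
  for (pair in list(c("Vs", "Hv"), c("Vs", "TPp"), c("Hv", "TPp"))) {
    expect_gte(C[pair[1], pair[2]], 0.8)
    expect_lte(C[pair[1], pair[2]], 0.95)
  }
})

test_that("signed blocks plant negative correlations and non-PSD blocks are rejected", {
  expect_error(
    activation_model(blocks = list(list(regions = c("Vs", "Hv", "TPp"),
                                        r = -0.9))),
    "block 1.*positive semi-definite")
  gs <- matrix(c(300L, 0L, 0L, 0L, 0L, 0L), 2, 3, byrow = TRUE,
               dimnames = list(c("M", "F"), sdmn_conditions()))
  am <- activation_model(
    blocks = list(list(regions = c("Dm", "Dl", "Vd_r", "Vd_c"), r = 0.9,
                       signs = c(1, 1, -1, -1))),
    group_sizes = gs, seed = 23)
  tab <- generate_activation(am)
  C <- cor(stratum_counts(tab, "M", "isolated"))
  expect_gt(C["Dm", "Dl"], 0.7)
  expect_lt(C["Dm", "Vd_r"], -0.7)
  expect_lt(C["Dl", "Vd_c"], -0.7)
})

test_that("an empty stratum propagates as a hard error downstream", {
  gs <- matrix(c(8L, 8L, 8L, 8L, 0L, 8L), 2, 3, byrow = TRUE,
               dimnames = list(c("M", "F"), sdmn_conditions()))
  am <- activation_model(group_sizes = gs, seed = 29)
  tab <- generate_activation(am)
  expect_equal(sum(tab$sex == "F" & tab$condition == "winner"), 0)
  expect_error(kruskal_fdr(tab, "F"), "F x winner")
})
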