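## Ethogram module: per-dyad contest metrics and the behavioral statistics
## battery (normality-gated two-group tests, PCA of display totals,
## distance-based permutation MANOVA).

#' Summarize dyadic contests from scored events
#'
#' Computes, for each dyad, the latency to the first aggressive act, the
#' per-behavior totals up to conflict resolution, per-minute frequencies
#' (totals / resolution time), and the aggregate aggressive and submissive
#' frequencies. Aggressive displays are antiparallel display, circle, bite,
#' chase and strike; submissive displays are freeze, flee and retreat.
#'
#' @param events Data.frame of scored events with columns `dyad_id`, `sex`,
#'   `fish_id`, `behavior`, `t_seconds` (time from recording start).
#' @param metadata Data.frame with one row per dyad: `dyad_id`, `sex`,
#'   `resolution_time` (minutes, > 0).
#' @return Data.frame with one row per dyad: `dyad_id`, `sex`, `latency`
#'   (minutes; `NA` when the dyad shows no aggressive act, in which case it
#'   is excluded from latency tests), `resolution_time`, `total_<behavior>`
#'   and `freq_<behavior>` for the 8 behaviors, `aggressive_freq`,
#'   `submissive_freq`.
#' @export
#' @examples
#' ev <- data.frame(dyad_id = "d1", sex = "M", fish_id = "d1_f1",
#'                  behavior = rep("bite", 10), t_seconds = seq(10, 100, 10))
#' md <- data.frame(dyad_id = "d1", sex = "M", resolution_time = 5)
#' summarize_dyads(ev, md)$freq_bite  # 2 bites per minute
summarize_dyads <- function(events, metadata) {
  behaviors <- ethogram_behaviors()
  need <- c("dyad_id", "sex", "fish_id", "behavior", "t_seconds")
  if (!all(need %in% names(events)))
    stop("`events` must have columns ", paste(need, collapse = ", "))
  if (!all(c("dyad_id", "sex", "resolution_time") %in% names(metadata)))
    stop("`metadata` must have columns dyad_id, sex, resolution_time")
  unknown <- setdiff(unique(events$behavior), behaviors)
  if (length(unknown))
    stop("unknown behavior label(s): ", paste(unknown, collapse = ", "))
  if (any(!is.finite(metadata$resolution_time) | metadata$resolution_time <= 0))
    stop("resolution_time must be positive for every dyad")

  aggr <- aggressive_behaviors()
  out <- lapply(seq_len(nrow(metadata)), function(i) {
    id <- metadata$dyad_id[i]
    res <- metadata$resolution_time[i]
    ev <- events[events$dyad_id == id & events$t_seconds <= res * 60, ,
                 drop = FALSE]
    totals <- vapply(behaviors, function(b) sum(ev$behavior == b), 0L)
    t_aggr <- ev$t_seconds[ev$behavior %in% aggr]
    sm <- data.frame(dyad_id = id, sex = metadata$sex[i],
                     latency = if (length(t_aggr)) min(t_aggr) / 60 else NA_real_,
                     resolution_time = res, stringsAsFactors = FALSE)
    for (b in behaviors) sm[[paste0("total_", b)]] <- totals[[b]]
    for (b in behaviors) sm[[paste0("freq_", b)]] <- totals[[b]] / res
    sm$aggressive_freq <- sum(totals[aggr]) / res
    sm$submissive_freq <- sum(totals[submissive_behaviors()]) / res
    sm
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Two-group test with a Shapiro-Wilk normality gate
#'
#' Mirrors the contest-statistics convention: each group is screened with
#' the Shapiro-Wilk test; if both pass at `alpha_gate` the groups are
#' compared with a two-sided Welch t-test, otherwise with a two-sided
#' Mann-Whitney U test. For the Mann-Whitney branch both the U statistic
#' (R's `wilcox.test` convention) and the rank-sum statistic
#' `W = U + n1 (n1 + 1) / 2` are reported; `W` is the headline statistic. A
#' constant sample makes Shapiro-Wilk undefined; the gate is then recorded
#' as failed and the Mann-Whitney branch is used.
#'
#' @param x,y Numeric samples (each of size >= 3; `NA`s dropped).
#' @param alpha_gate Significance level of the normality gate (default 0.05).
#' @param labels Length-2 character vector naming the groups.
#' @return An object of class `two_group_test`: fields `test` ("t" or
#'   "mann_whitney"), `statistic` (t, or rank-sum W), `u_statistic` (`NA`
#'   for the t branch), `p_value`, `means`, `se`, `n`, `gate` (per-group
#'   Shapiro-Wilk p and pass flag), `labels`.
#' @export
#' @examples
#' set.seed(1)
#' gated_two_group_test(rnorm(20), rnorm(20, 1))
gated_two_group_test <- function(x, y, alpha_gate = 0.05,
                                 labels = c("x", "y")) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 3 || length(y) < 3)
    stop("each sample must have >= 3 non-missing values")
  gate1 <- .shapiro_gate(x, alpha_gate)
  gate2 <- .shapiro_gate(y, alpha_gate)
  means <- c(mean(x), mean(y))
  se <- c(stats::sd(x) / sqrt(length(x)), stats::sd(y) / sqrt(length(y)))
  if (gate1$pass && gate2$pass) {
    tt <- stats::t.test(x, y, alternative = "two.sided")
    res <- list(test = "t", statistic = unname(tt$statistic),
                u_statistic = NA_real_, p_value = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
    u <- unname(wt$statistic)
    res <- list(test = "mann_whitney",
                statistic = u + length(x) * (length(x) + 1) / 2,
                u_statistic = u, p_value = wt$p.value)
  }
  structure(c(res, list(means = stats::setNames(means, labels),
                        se = stats::setNames(se, labels),
                        n = stats::setNames(c(length(x), length(y)), labels),
                        gate = stats::setNames(list(gate1, gate2), labels),
                        alpha_gate = alpha_gate, labels = labels)),
            class = "two_group_test")
}

.shapiro_gate <- function(x, alpha) {
  p <- tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
  list(p = p, pass = isTRUE(p > alpha))
}

#' @export
print.two_group_test <- function(x, ...) {
  nm <- if (x$test == "t") "Welch two-sample t-test"
        else "Mann-Whitney U test (rank-sum W)"
  cat(nm, "\n", sep = "")
  cat(sprintf("  %s: mean %.4g (SE %.3g, n=%d) vs %s: mean %.4g (SE %.3g, n=%d)\n",
              x$labels[1], x$means[1], x$se[1], x$n[1],
              x$labels[2], x$means[2], x$se[2], x$n[2]))
  cat(sprintf("  statistic = %.4f, p = %.4g\n", x$statistic, x$p_value))
  invisible(x)
}

#' Principal component analysis of behavioral display totals
#'
#' Square-root transforms the totals (variance stabilization for
#' overdispersed counts), column-centers, and eigen-decomposes the
#' covariance matrix (or the correlation matrix with `scale = TRUE`). All
#' components are returned; zero-variance components report a variance
#' proportion of 0. Sign convention: within each component the loading of
#' largest magnitude is made negative (ties: the first such behavior), so
#' repeated runs and reflections are reproducible.
#'
#' @param totals Numeric individuals x behaviors matrix of non-negative
#'   display totals (>= 2 rows and columns).
#' @param scale Logical; `FALSE` (default) uses the covariance matrix,
#'   `TRUE` the correlation matrix.
#' @param transform `"sqrt"` (default) or `"none"`.
#' @return Object of class `behavior_pca`: `loadings` (behaviors x
#'   components, orthonormal), `sdev`, `prop_var`, `cum_var`, `scores`
#'   (individuals x components), `center`, `scale`.
#' @export
behavior_pca <- function(totals, scale = FALSE, transform = c("sqrt", "none")) {
  transform <- match.arg(transform)
  X <- as.matrix(totals)
  if (nrow(X) < 2 || ncol(X) < 2)
    stop("`totals` needs >= 2 individuals and >= 2 behaviors")
  if (any(X < 0)) stop("`totals` must be non-negative")
  if (transform == "sqrt") X <- sqrt(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  if (scale) {
    sds <- apply(X, 2, stats::sd)
    sds[sds == 0] <- 1
    Xc <- sweep(Xc, 2, sds, "/")
  }
  S <- stats::cov(Xc)
  eg <- eigen(S, symmetric = TRUE)
  vals <- pmax(eg$values, 0)
  L <- eg$vectors
  ## sign rule: largest-|loading| entry of each component negative
  for (j in seq_len(ncol(L))) {
    lead <- which.max(abs(L[, j]))
    if (L[lead, j] > 0) L[, j] <- -L[, j]
  }
  dimnames(L) <- list(colnames(X),
                      paste0("PC", seq_len(ncol(L))))
  scores <- Xc %*% L
  prop <- if (sum(vals) > 0) vals / sum(vals) else rep(0, length(vals))
  structure(list(loadings = L, sdev = sqrt(vals), prop_var = prop,
                 cum_var = cumsum(prop), scores = scores, center = ctr,
                 scale = scale, transform = transform),
            class = "behavior_pca")
}

#' @export
print.behavior_pca <- function(x, ...) {
  k <- min(4, length(x$sdev))
  cat("Behavioral PCA (", x$transform, "-transformed, ",
      if (x$scale) "correlation" else "covariance", ")\n", sep = "")
  tab <- rbind(`Standard deviation` = x$sdev[1:k],
               `Proportion of variance` = x$prop_var[1:k],
               `Cumulative proportion` = x$cum_var[1:k])
  colnames(tab) <- colnames(x$loadings)[1:k]
  print(round(tab, 4))
  invisible(x)
}

#' Distance-based permutation MANOVA (pseudo-F)
#'
#' Partitions the sum of squared Euclidean pairwise distances into between-
#' and within-group components (total SS = sum of all pairwise squared
#' distances / n; within SS = within-group pairwise squared distances /
#' group size) and forms the pseudo-F
#' `F = (SS_between / (a - 1)) / (SS_within / (N - a))`. Significance is
#' assessed by permuting the group labels over observations; the p-value
#' uses the add-one correction `p = (1 + #\{F* >= F\}) / (1 + n_perm)` so it
#' is never zero and has resolution `1 / (n_perm + 1)`.
#'
#' @param data Numeric individuals x variables matrix (raw observations are
#'   permuted, not residuals).
#' @param groups Vector of group labels (>= 2 groups, each of size >= 2).
#' @param n_perm Number of random permutations (default 999).
#' @param seed Optional integer seed for the permutation stream.
#' @return Object of class `permanova`: `f_statistic`, `p_value`, `n_perm`,
#'   `ss` (between/within/total), `df`, `groups`, `perm_f` (the permuted
#'   statistics).
#' @export
#' @examples
#' set.seed(2)
#' x <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20, 2), 10))
#' permanova(x, rep(c("a", "b"), each = 10), n_perm = 199, seed = 1)
permanova <- function(data, groups, n_perm = 999, seed = NULL) {
  X <- as.matrix(data)
  groups <- as.character(groups)
  if (nrow(X) != length(groups))
    stop("`groups` must have one label per row of `data`")
  tab <- table(groups)
  if (length(tab) < 2) stop("need >= 2 groups")
  if (any(tab < 2))
    stop("every group must have >= 2 members (got size-1 group: ",
         paste(names(tab)[tab < 2], collapse = ", "), ")")
  if (n_perm < 1) stop("`n_perm` must be >= 1")
  d2 <- as.matrix(stats::dist(X))^2
  n <- nrow(d2)
  a <- length(tab)
  ss_total <- sum(d2) / (2 * n)

  f_stat <- function(g) {
    ss_w <- 0
    for (lev in unique(g)) {
      idx <- which(g == lev)
      ss_w <- ss_w + sum(d2[idx, idx]) / (2 * length(idx))
    }
    ss_b <- ss_total - ss_w
    num <- ss_b / (a - 1)
    den <- ss_w / (n - a)
    if (den == 0) {
      if (num == 0) 0 else Inf
    } else num / den
  }

  f_obs <- f_stat(groups)
  ss_w <- 0
  for (lev in names(tab)) {
    idx <- which(groups == lev)
    ss_w <- ss_w + sum(d2[idx, idx]) / (2 * length(idx))
  }

  if (ss_total <= .Machine$double.eps * n) {
    ## no variance at all: F guarded to 0, p = 1, no permutations needed
    perm_f <- numeric(0)
    p <- 1
    f_obs <- 0
  } else {
    perm_f <- with_seed(seed, vapply(seq_len(n_perm),
                                     function(i) f_stat(sample(groups)),
                                     numeric(1)))
    p <- (1 + sum(perm_f >= f_obs - 1e-12)) / (1 + n_perm)
  }
  structure(list(f_statistic = f_obs, p_value = p, n_perm = n_perm,
                 ss = c(between = ss_total - ss_w, within = ss_w,
                        total = ss_total),
                 df = c(between = a - 1, within = n - a),
                 groups = tab, perm_f = perm_f),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("Permutation MANOVA (Euclidean distances)\n")
  cat(sprintf("  pseudo-F = %.4f on (%d, %d) df; p = %.4g (%d permutations)\n",
              x$f_statistic, x$df["between"], x$df["within"], x$p_value,
              x$n_perm))
  cat(sprintf("  SS between = %.4g, within = %.4g, total = %.4g\n",
              x$ss["between"], x$ss["within"], x$ss["total"]))
  invisible(x)
}

#' Run the full behavioral test battery on dyad summaries
#'
#' Applies [gated_two_group_test()] (males vs females) to latency,
#' resolution time, each per-behavior frequency, and the aggregate
#' aggressive/submissive frequencies; dyads with missing latency are
#' excluded from the latency test.
#'
#' @param summaries Dyad summary data.frame from [summarize_dyads()] or
#'   [generate_dyads()].
#' @param alpha_gate Normality-gate level (default 0.05).
#' @return Data.frame with one row per variable: `variable`, `test`,
#'   `statistic`, `p_value`, `mean_M`, `se_M`, `mean_F`, `se_F`.
#' @export
ethogram_test_battery <- function(summaries, alpha_gate = 0.05) {
  vars <- c("latency", "resolution_time",
            paste0("freq_", ethogram_behaviors()),
            "aggressive_freq", "submissive_freq")
  rows <- lapply(vars, function(v) {
    x <- summaries[[v]][summaries$sex == "M"]
    y <- summaries[[v]][summaries$sex == "F"]
    r <- gated_two_group_test(x, y, alpha_gate, labels = c("M", "F"))
    data.frame(variable = v, test = r$test, statistic = r$statistic,
               p_value = r$p_value,
               mean_M = r$means[["M"]], se_M = r$se[["M"]],
               mean_F = r$means[["F"]], se_F = r$se[["F"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
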