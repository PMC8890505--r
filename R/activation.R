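## Activation module: per-region Kruskal-Wallis testing of pS6 counts
## across social conditions within a sex, Benjamini-Hochberg FDR over
## regions, and Dunn rank-based post hoc pairwise comparisons.

#' Kruskal-Wallis activation testing with FDR control
#'
#' For one sex, tests every region's pS6 counts across the three social
#' conditions (isolated control, winner, loser) with the tie-corrected
#' Kruskal-Wallis test, adjusts the raw p-values across regions with the
#' Benjamini-Hochberg step-up procedure, and, for regions significant at
#' `q <= fdr_alpha`, runs Dunn's rank-based post hoc test on the three
#' condition pairs (BH-adjusted within region). A region whose counts are
#' all identical is guarded to `H = 0`, `p = 1`.
#'
#' @param table Activation data.frame (see [generate_activation()] /
#'   [read_activation_table()] for the column contract).
#' @param sex `"M"` or `"F"`.
#' @param regions Region columns to test (default [sdmn_regions()]).
#' @param fdr_alpha FDR level gating the post hoc step (default 0.05).
#' @return Data.frame with one row per region: `region`, `H`, `df`,
#'   `p_value`, `q_value`, and for each condition pair
#'   `p_<a>_vs_<b>` / `sig_<a>_vs_<b>` (BH-adjusted Dunn p and flag; `NA`
#'   when the region does not pass the FDR gate).
#' @export
#' @examples
#' tab <- generate_activation(activation_model(seed = 3))
#' head(kruskal_fdr(tab, "M")[, 1:5])
kruskal_fdr <- function(table, sex, regions = sdmn_regions(),
                        fdr_alpha = 0.05) {
  validate_activation_table(table, regions)
  if (!sex %in% c("M", "F")) stop("`sex` must be 'M' or 'F'")
  tab <- table[table$sex == sex, , drop = FALSE]
  conds <- sdmn_conditions()
  sizes <- vapply(conds, function(cn) sum(tab$condition == cn), 0L)
  if (any(sizes < 2))
    stop("condition stratum too small for sex ", sex, ": ",
         paste(sprintf("%s x %s (n=%d)", sex, conds[sizes < 2],
                       sizes[sizes < 2]), collapse = ", "))
  g <- factor(tab$condition, levels = conds)

  res <- lapply(regions, function(rg) {
    x <- tab[[rg]]
    if (length(unique(x)) == 1L) {
      data.frame(region = rg, H = 0, df = length(conds) - 1L, p_value = 1,
                 stringsAsFactors = FALSE)
    } else {
      kw <- stats::kruskal.test(x, g)
      data.frame(region = rg, H = unname(kw$statistic),
                 df = unname(kw$parameter), p_value = kw$p.value,
                 stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, res)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")

  pairs <- utils::combn(conds, 2)
  for (k in seq_len(ncol(pairs)))
    res[[sprintf("p_%s_vs_%s", pairs[1, k], pairs[2, k])]] <- NA_real_
  for (k in seq_len(ncol(pairs)))
    res[[sprintf("sig_%s_vs_%s", pairs[1, k], pairs[2, k])]] <- NA
  for (i in which(res$q_value <= fdr_alpha)) {
    dp <- dunn_posthoc(tab[[res$region[i]]], g)
    for (k in seq_len(nrow(dp))) {
      col <- sprintf("p_%s_vs_%s", dp$group1[k], dp$group2[k])
      res[i, col] <- dp$p_adjusted[k]
      res[i, sub("^p_", "sig_", col)] <- dp$p_adjusted[k] <= fdr_alpha
    }
  }
  rownames(res) <- NULL
  res
}

#' Dunn's rank-based post hoc test
#'
#' Pairwise z-tests on mean ranks after a Kruskal-Wallis test, with the
#' tie-corrected variance and BH adjustment over the pairs.
#'
#' @param x Numeric response.
#' @param g Grouping factor.
#' @param adjust p-value adjustment method over the pairs (default `"BH"`).
#' @return Data.frame with `group1`, `group2`, `z`, `p_value`, `p_adjusted`.
#' @export
dunn_posthoc <- function(x, g, adjust = "BH") {
  g <- droplevels(as.factor(g))
  ok <- !is.na(x) & !is.na(g)
  x <- x[ok]; g <- g[ok]
  n <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ng <- tapply(r, g, length)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  v0 <- n * (n + 1) / 12 - tie_term
  levs <- levels(g)
  pairs <- utils::combn(levs, 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1, k]; b <- pairs[2, k]
    se <- sqrt(v0 * (1 / ng[[a]] + 1 / ng[[b]]))
    z <- if (se > 0) (rbar[[a]] - rbar[[b]]) / se else 0
    data.frame(group1 = a, group2 = b, z = z,
               p_value = 2 * stats::pnorm(-abs(z)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = adjust)
  rownames(out) <- NULL
  out
}
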