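## Netstats module: distributional comparisons of edge-weight samples
## between treatments and between the excitation and inhibition subnetworks
## of one treatment (two-sample KS + Mann-Whitney U + Cohen's d).

#' Compare two edge-weight distributions
#'
#' Runs the full battery on two numeric samples: two-sided two-sample
#' Kolmogorov-Smirnov D, two-sided Mann-Whitney U, and Cohen's d with the
#' pooled standard deviation (sign convention: first sample minus second).
#' With fewer than 2 values in a sample (or zero pooled SD with unequal
#' means) d is reported as missing while the defined tests still run; equal
#' constant samples give d = 0.
#'
#' @param a,b Numeric samples (nonempty; `NA`s dropped).
#' @param labels Length-2 character vector naming the samples.
#' @param d_bands Ascending thresholds classifying `|d|` (conventional
#'   Cohen cutoffs by default).
#' @return Object of class `weight_comparison`: `ks_statistic`, `ks_p`,
#'   `mwu_statistic` (U), `mwu_p`, `cohens_d`, `d_label`, `n`, `labels`.
#' @export
#' @examples
#' compare_weight_distributions(rnorm(50), rnorm(50, 0.5))
compare_weight_distributions <- function(a, b, labels = c("a", "b"),
                                         d_bands = c(small = 0.2,
                                                     intermediate = 0.5,
                                                     large = 0.8)) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0 || length(b) == 0) stop("both samples must be nonempty")
  ks <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided"))
  mwu <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  d <- cohens_d(a, b)
  structure(list(ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
                 mwu_statistic = unname(mwu$statistic), mwu_p = mwu$p.value,
                 cohens_d = d, d_label = label_effect_size(d, d_bands),
                 n = stats::setNames(c(length(a), length(b)), labels),
                 labels = labels),
            class = "weight_comparison")
}

#' Cohen's d with pooled standard deviation
#'
#' `d = (mean(a) - mean(b)) / s_pooled`, with
#' `s_pooled = sqrt(((n_a - 1) var(a) + (n_b - 1) var(b)) / (n_a + n_b - 2))`.
#'
#' @param a,b Numeric samples.
#' @return The effect size; `0` for identical constant samples, signed
#'   `Inf` for separated constant samples (zero pooled SD, unequal means),
#'   `NA` when a sample has fewer than 2 values.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) return(NA_real_)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  delta <- mean(a) - mean(b)
  if (sp == 0) return(if (delta == 0) 0 else sign(delta) * Inf)
  delta / sp
}

label_effect_size <- function(d, bands = c(small = 0.2, intermediate = 0.5,
                                           large = 0.8)) {
  if (is.na(d)) return(NA_character_)
  ad <- abs(d)
  lab <- "negligible"
  for (nm in names(bands)) if (ad >= bands[[nm]]) lab <- nm
  lab
}

#' @export
print.weight_comparison <- function(x, ...) {
  cat(sprintf("Edge-weight comparison: %s (n=%d) vs %s (n=%d)\n",
              x$labels[1], x$n[1], x$labels[2], x$n[2]))
  cat(sprintf("  KS D = %.4f, p = %.4g\n", x$ks_statistic, x$ks_p))
  cat(sprintf("  MWU U = %.1f, p = %.4g\n", x$mwu_statistic, x$mwu_p))
  cat(sprintf("  Cohen's d = %.3f (%s)\n", x$cohens_d, x$d_label))
  invisible(x)
}

#' Excitation-inhibition balance of a treatment network
#'
#' Compares the excitation edge weights against the absolute values of the
#' inhibition edge weights with the KS/MWU/Cohen's d battery; a positive d
#' means excitation overcomes inhibition in magnitude. If one subnetwork is
#' empty the result is flagged `one_sided` and no tests are run.
#'
#' @param subnets A [split_signed()] result.
#' @return A `weight_comparison` (with an extra `one_sided` flag when one
#'   side is empty).
#' @export
balance_analysis <- function(subnets) {
  stopifnot(inherits(subnets, "signed_subnetworks"))
  exc <- subnets$excitation$weight
  inh <- abs(subnets$inhibition$weight)
  if (length(exc) == 0 || length(inh) == 0) {
    return(structure(list(ks_statistic = NA_real_, ks_p = NA_real_,
                          mwu_statistic = NA_real_, mwu_p = NA_real_,
                          cohens_d = NA_real_, d_label = NA_character_,
                          n = c(excitation = length(exc),
                                inhibition = length(inh)),
                          labels = c("excitation", "|inhibition|"),
                          one_sided = TRUE),
                     class = "weight_comparison"))
  }
  out <- compare_weight_distributions(exc, inh,
                                      labels = c("excitation", "|inhibition|"))
  out$one_sided <- FALSE
  out
}

#' Pairwise treatment contrasts of subnetwork weight distributions
#'
#' Convenience driver producing the standard contrast table over a set of
#' treatment networks: for each subnetwork sign, male vs female within each
#' condition and all condition pairs within each sex; plus the
#' excitation-inhibition balance per treatment.
#'
#' @param networks Named list of `treatment_network` objects with `sex` and
#'   `condition` fields set.
#' @return Data.frame with `contrast`, `subnetwork`, `group_a`, `group_b`,
#'   `ks_statistic`, `ks_p`, `mwu_statistic`, `mwu_p`, `cohens_d`,
#'   `d_label`, `n_a`, `n_b`.
#' @export
netstat_contrasts <- function(networks) {
  subnets <- lapply(networks, split_signed)
  key <- vapply(networks, function(n) paste(n$sex, n$condition), "")
  names(subnets) <- key
  side <- function(k, sign) {
    if (sign == "excitation") subnets[[k]]$excitation$weight
    else abs(subnets[[k]]$inhibition$weight)
  }
  rows <- list()
  add <- function(contrast, sign, ka, kb, cmp) {
    rows[[length(rows) + 1L]] <<- data.frame(
      contrast = contrast, subnetwork = sign, group_a = ka, group_b = kb,
      ks_statistic = cmp$ks_statistic, ks_p = cmp$ks_p,
      mwu_statistic = cmp$mwu_statistic, mwu_p = cmp$mwu_p,
      cohens_d = cmp$cohens_d, d_label = cmp$d_label,
      n_a = cmp$n[1], n_b = cmp$n[2], stringsAsFactors = FALSE)
  }
  conds <- unique(vapply(networks, `[[`, "", "condition"))
  sexes <- unique(vapply(networks, `[[`, "", "sex"))
  for (sign in c("excitation", "inhibition")) {
    for (cn in conds) {
      ka <- paste("M", cn); kb <- paste("F", cn)
      if (all(c(ka, kb) %in% key)) {
        wa <- side(ka, sign); wb <- side(kb, sign)
        if (length(wa) && length(wb))
          add("sex", sign, ka, kb,
              compare_weight_distributions(wa, wb, c(ka, kb)))
      }
    }
    for (sx in sexes) {
      cc <- conds[paste(sx, conds) %in% key]
      if (length(cc) >= 2) {
        prs <- utils::combn(cc, 2)
        for (k in seq_len(ncol(prs))) {
          ka <- paste(sx, prs[1, k]); kb <- paste(sx, prs[2, k])
          wa <- side(ka, sign); wb <- side(kb, sign)
          if (length(wa) && length(wb))
            add("condition", sign, ka, kb,
                compare_weight_distributions(wa, wb, c(ka, kb)))
        }
      }
    }
  }
  for (k in key) {
    bal <- balance_analysis(subnets[[k]])
    if (!isTRUE(bal$one_sided))
      add("balance", "excitation_vs_inhibition", k, k, bal)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
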