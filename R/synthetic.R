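## Synthetic-data module: generative models for the two input tables the
## pipeline consumes (dyadic contest ethograms; per-region pS6 activation
## counts), with planted, recoverable structure.
##
## Count model: negative binomial (mean, dispersion), with a Gaussian copula
## imposing block correlation structure on activation counts. Latency and
## fight duration are log-normal (positive, right-skewed). These are
## conventions: the generator emulates the statistical shape the downstream
## stages assume, not a mechanistic model of fish behavior.

#' Default sex-specific behavior rates (events per minute)
#'
#' Males show higher overall overt aggression (bites, strikes, chases) and
#' more submissive retreats; females favor antiparallel displays. Values are
#' conventions chosen to mirror the direction of reported sex differences.
#'
#' @return A 2 x 8 numeric matrix, rows `M`/`F`, columns the behaviors of
#'   [ethogram_behaviors()].
#' @export
default_behavior_rates <- function() {
  b <- ethogram_behaviors()
  m <- c(bite = 1.2, antiparallel_display = 0.8, circle = 0.5, chase = 1.0,
         strike = 0.9, flee = 0.8, retreat = 0.7, freeze = 0.3)
  f <- c(bite = 0.9, antiparallel_display = 1.6, circle = 0.5, chase = 0.8,
         strike = 0.35, flee = 0.6, retreat = 0.3, freeze = 0.35)
  rbind(M = m[b], F = f[b])
}

#' Behavioral generative model for dyadic contests
#'
#' Defines per-sex event rates for the 8 ethogram behaviors, log-normal
#' latency and fight-duration distributions, and a negative-binomial
#' dispersion for behavior totals. A fixed seed makes all generator output
#' bit-reproducible.
#'
#' @param rates 2 x 8 matrix of non-negative event rates (events/minute),
#'   rows `M`/`F`, columns [ethogram_behaviors()].
#' @param latency Length-2 vector `c(meanlog, sdlog)` of the log-normal
#'   latency to the first attack, in minutes (shared by the sexes).
#' @param fight_duration Named list with elements `M` and `F`, each
#'   `c(meanlog, sdlog)` of the log-normal fight duration (first attack to
#'   resolution), minutes. Resolution time = latency + fight duration.
#' @param dispersion Negative-binomial size parameter (> 0); smaller values
#'   give more overdispersed behavior totals.
#' @param seed Integer RNG seed.
#' @return An object of class `behavior_model`.
#' @export
#' @examples
#' m <- behavior_model(seed = 42)
#' d <- generate_dyads(m, n_dyads_per_sex = 3)
#' head(d$events)
behavior_model <- function(rates = default_behavior_rates(),
                           latency = c(meanlog = log(2), sdlog = 0.6),
                           fight_duration = list(
                             M = c(meanlog = log(10), sdlog = 0.5),
                             F = c(meanlog = log(5),  sdlog = 0.5)),
                           dispersion = 5,
                           seed = 1L) {
  behaviors <- ethogram_behaviors()
  rates <- as.matrix(rates)
  if (!all(c("M", "F") %in% rownames(rates)))
    stop("`rates` must have rows 'M' and 'F'")
  if (!all(behaviors %in% colnames(rates)))
    stop("`rates` must have one column per ethogram behavior: ",
         paste(setdiff(behaviors, colnames(rates)), collapse = ", "))
  rates <- rates[c("M", "F"), behaviors, drop = FALSE]
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("behavior rates must be finite and non-negative")
  if (!is.finite(dispersion) || dispersion <= 0)
    stop("`dispersion` must be a positive finite number")
  for (s in c("M", "F"))
    if (!is.numeric(fight_duration[[s]]) || length(fight_duration[[s]]) != 2)
      stop("`fight_duration$", s, "` must be c(meanlog, sdlog)")
  structure(list(rates = rates, latency = latency,
                 fight_duration = fight_duration,
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "behavior_model")
}

#' Generate synthetic dyadic contests
#'
#' Simulates `n_dyads_per_sex` same-sex dyads per sex. For each dyad a
#' latency and a fight duration are drawn; per-opponent behavior totals
#' during the contest are negative-binomial with mean rate x duration; event
#' timestamps are uniform over the contest interval (the first aggressive
#' act is pinned to the latency). The opponent with more aggressive acts at
#' resolution wins (ties broken by a coin flip from the dyad's RNG stream);
#' after resolution, during a 2-minute confirmation window, only the winner
#' emits aggressive acts (chases) while the loser flees.
#'
#' @param model A [behavior_model()].
#' @param n_dyads_per_sex Number of dyads per sex (>= 1).
#' @return List with `events` (one row per scored event: `dyad_id`, `sex`,
#'   `fish_id`, `behavior`, `t_seconds`) and `summaries` (one row per dyad,
#'   see [summarize_dyads()] for the column contract). Summary totals count
#'   events up to conflict resolution only.
#' @export
generate_dyads <- function(model, n_dyads_per_sex) {
  stopifnot(inherits(model, "behavior_model"))
  if (!is.numeric(n_dyads_per_sex) || n_dyads_per_sex < 1)
    stop("`n_dyads_per_sex` must be >= 1")
  behaviors <- ethogram_behaviors()
  aggr <- aggressive_behaviors()

  with_seed(model$seed, {
    ev_list <- list()
    sm_list <- list()
    for (sex in c("M", "F")) {
      for (d in seq_len(n_dyads_per_sex)) {
        dyad_id <- sprintf("%s%03d", sex, d)
        lat <- stats::rlnorm(1, model$latency[1], model$latency[2])
        dur <- stats::rlnorm(1, model$fight_duration[[sex]][1],
                             model$fight_duration[[sex]][2])
        res <- lat + dur
        counts <- matrix(0L, nrow = 2, ncol = length(behaviors),
                         dimnames = list(NULL, behaviors))
        for (f in 1:2)
          counts[f, ] <- stats::rnbinom(length(behaviors),
                                        mu = model$rates[sex, ] * dur,
                                        size = model$dispersion)
        agg_by_fish <- rowSums(counts[, aggr, drop = FALSE])
        winner <- if (agg_by_fish[1] != agg_by_fish[2]) {
          which.max(agg_by_fish)
        } else if (stats::runif(1) < 0.5) 1L else 2L

        ## contest-phase events: uniform timestamps over (latency, resolution)
        ev <- vector("list", 0L)
        for (f in 1:2) for (b in behaviors) {
          n <- counts[f, b]
          if (n > 0)
            ev[[length(ev) + 1L]] <- data.frame(
              fish = f, behavior = b,
              t_seconds = sort(stats::runif(n, lat, res)) * 60)
        }
        ev <- if (length(ev)) do.call(rbind, ev) else
          data.frame(fish = integer(), behavior = character(),
                     t_seconds = numeric())
        is_aggr <- ev$behavior %in% aggr
        if (any(is_aggr)) {
          first <- which(is_aggr)[which.min(ev$t_seconds[is_aggr])]
          ev$t_seconds[first] <- lat * 60
        }

        ## post-resolution confirmation window: winner chases, loser flees
        loser <- 3L - winner
        n_chase <- stats::rpois(1, model$rates[sex, "chase"] * 2)
        n_flee  <- stats::rpois(1, model$rates[sex, "flee"] * 2)
        post <- data.frame(
          fish = c(rep(winner, n_chase), rep(loser, n_flee)),
          behavior = c(rep("chase", n_chase), rep("flee", n_flee)),
          t_seconds = stats::runif(n_chase + n_flee, res, res + 2) * 60)
        ev <- rbind(ev, post)

        ev_list[[length(ev_list) + 1L]] <- data.frame(
          dyad_id = rep(dyad_id, nrow(ev)), sex = rep(sex, nrow(ev)),
          fish_id = sprintf("%s_f%d", dyad_id, ev$fish),
          behavior = ev$behavior, t_seconds = ev$t_seconds,
          stringsAsFactors = FALSE)

        totals <- colSums(counts)
        sm <- data.frame(dyad_id = dyad_id, sex = sex,
                         latency = if (any(is_aggr)) lat else NA_real_,
                         resolution_time = res,
                         winner_fish = sprintf("%s_f%d", dyad_id, winner),
                         stringsAsFactors = FALSE)
        for (b in behaviors) sm[[paste0("total_", b)]] <- totals[[b]]
        for (b in behaviors) sm[[paste0("freq_", b)]] <- totals[[b]] / res
        sm$aggressive_freq <- sum(totals[aggr]) / res
        sm$submissive_freq <- sum(totals[submissive_behaviors()]) / res
        sm_list[[length(sm_list) + 1L]] <- sm
      }
    }
    events <- do.call(rbind, ev_list)
    events <- events[order(events$dyad_id, events$t_seconds), , drop = FALSE]
    rownames(events) <- NULL
    summaries <- do.call(rbind, sm_list)
    rownames(summaries) <- NULL
    list(events = events, summaries = summaries)
  })
}

#' Activation generative model for pS6 region counts
#'
#' Defines, per social condition, negative-binomial baseline counts for the
#' 19 SDMN regions and a planted correlation structure imposed through a
#' Gaussian copula: equicorrelated (optionally signed) region blocks and
#' one-factor hub stars. The implied latent correlation matrix of every
#' condition is validated to be positive semi-definite at construction.
#'
#' @param regions Character vector of region names (default [sdmn_regions()]).
#' @param baseline Named numeric vector of mean counts per condition
#'   (recycled over regions), or a conditions x regions matrix. Defaults
#'   reflect elevated activation after an agonistic encounter relative to
#'   isolated controls.
#' @param dispersion Negative-binomial size parameter for counts.
#' @param blocks List of planted correlation blocks; each block is a list
#'   with `regions` (>= 2 region names), `r` (target pairwise correlation in
#'   `[-1, 1]`), optional `signs` (vector of +/-1 per region; the latent
#'   correlation of regions i, j is `r * s_i * s_j`) and optional
#'   `conditions` (default: all).
#' @param hubs List of planted hubs; each is a list with `region`, optional
#'   `partners` (default: all regions not in any block), `r` (hub-partner
#'   correlation, default 0.6; partners correlate at `r^2`, a one-factor
#'   star) and optional `conditions`.
#' @param group_sizes Sexes x conditions matrix of stratum sizes (rows
#'   `M`/`F`); default 8 fish per stratum, within the typical 6-9 range of
#'   immunofluorescence group sizes. A zero entry yields an empty stratum.
#' @param conditions Character vector of condition labels.
#' @param seed Integer RNG seed.
#' @return An object of class `activation_model` carrying the validated
#'   per-condition latent correlation matrices.
#' @export
#' @examples
#' am <- activation_model(
#'   blocks = list(list(regions = c("Vs", "Hv", "TPp"), r = 0.9)),
#'   seed = 7)
#' tab <- generate_activation(am)
#' head(tab[, 1:6])
activation_model <- function(regions = sdmn_regions(),
                             baseline = c(isolated = 30, winner = 55, loser = 50),
                             dispersion = 10,
                             blocks = list(),
                             hubs = list(),
                             group_sizes = NULL,
                             conditions = sdmn_conditions(),
                             seed = 1L) {
  p <- length(regions)
  if (anyDuplicated(regions)) stop("duplicated region names")
  if (is.null(group_sizes)) {
    group_sizes <- matrix(8L, 2, length(conditions),
                          dimnames = list(c("M", "F"), conditions))
  }
  group_sizes <- as.matrix(group_sizes)
  if (!all(c("M", "F") %in% rownames(group_sizes)) ||
      !all(conditions %in% colnames(group_sizes)))
    stop("`group_sizes` must have rows M/F and one column per condition")
  if (any(group_sizes < 0)) stop("group sizes must be non-negative")

  if (is.matrix(baseline)) {
    mu <- baseline[conditions, regions, drop = FALSE]
  } else {
    if (!all(conditions %in% names(baseline)))
      stop("`baseline` must name every condition")
    mu <- matrix(rep(baseline[conditions], p), nrow = length(conditions),
                 dimnames = list(conditions, regions))
  }
  if (any(mu < 0)) stop("baseline means must be non-negative")
  if (!is.finite(dispersion) || dispersion <= 0)
    stop("`dispersion` must be positive")

  block_regions <- unlist(lapply(blocks, `[[`, "regions"))
  sigma <- list()
  for (cond in conditions) {
    S <- diag(p)
    dimnames(S) <- list(regions, regions)
    for (bi in seq_along(blocks)) {
      blk <- blocks[[bi]]
      if (!is.null(blk$conditions) && !(cond %in% blk$conditions)) next
      idx <- match(blk$regions, regions)
      if (anyNA(idx))
        stop("block ", bi, " names unknown regions: ",
             paste(blk$regions[is.na(idx)], collapse = ", "))
      k <- length(idx)
      if (k < 2) stop("block ", bi, " needs >= 2 regions")
      r <- blk$r
      if (!is.finite(r) || abs(r) > 1)
        stop("block ", bi, ": target correlation must lie in [-1, 1]")
      if (r < -1 / (k - 1))
        stop("block ", bi, " (", paste(blk$regions, collapse = ", "),
             "): equicorrelation r = ", r, " with ", k,
             " regions is not positive semi-definite (requires r >= ",
             signif(-1 / (k - 1), 3), "); use a signed block or a pair")
      s <- if (is.null(blk$signs)) rep(1, k) else blk$signs
      if (length(s) != k || !all(s %in% c(-1, 1)))
        stop("block ", bi, ": `signs` must be +/-1 per region")
      B <- r * outer(s, s)
      diag(B) <- 1
      S[idx, idx] <- B
    }
    for (hi in seq_along(hubs)) {
      hub <- hubs[[hi]]
      if (!is.null(hub$conditions) && !(cond %in% hub$conditions)) next
      h <- match(hub$region, regions)
      if (is.na(h)) stop("hub ", hi, " names unknown region ", hub$region)
      partners <- if (is.null(hub$partners))
        setdiff(regions, c(hub$region, block_regions)) else hub$partners
      pidx <- match(partners, regions)
      if (anyNA(pidx)) stop("hub ", hi, " has unknown partner regions")
      r <- if (is.null(hub$r)) 0.6 else hub$r
      if (!is.finite(r) || r < 0 || r > 1)
        stop("hub ", hi, ": `r` must lie in [0, 1]")
      S[h, pidx] <- S[pidx, h] <- r
      S[pidx, pidx] <- r^2
      diag(S) <- 1
    }
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop("latent correlation matrix for condition '", cond,
           "' is not positive semi-definite (min eigenvalue ",
           signif(min(ev), 3), "); planted blocks/hubs are incompatible")
    sigma[[cond]] <- S
  }

  structure(list(regions = regions, conditions = conditions, mu = mu,
                 dispersion = dispersion, blocks = blocks, hubs = hubs,
                 group_sizes = group_sizes, sigma = sigma,
                 seed = as.integer(seed)),
            class = "activation_model")
}

#' Generate a synthetic pS6 activation table
#'
#' Draws, for each sex x condition stratum, latent multivariate-normal
#' vectors with the model's per-condition correlation matrix, maps them
#' through the Gaussian copula (`pnorm` then the negative-binomial quantile
#' function) onto counts with the condition's baseline mean and dispersion.
#' Counts are non-negative integers; within a planted block the empirical
#' count correlation converges to (slightly below, due to discretization)
#' the latent target as the stratum grows.
#'
#' @param model An [activation_model()].
#' @return A data.frame with columns `fish_id`, `sex`, `condition` and one
#'   count column per region. Strata with group size zero contribute no
#'   rows.
#' @export
generate_activation <- function(model) {
  stopifnot(inherits(model, "activation_model"))
  regions <- model$regions
  with_seed(model$seed, {
    rows <- list()
    for (sex in c("M", "F")) {
      for (cond in model$conditions) {
        n <- model$group_sizes[sex, cond]
        if (n == 0) next
        Z <- MASS::mvrnorm(n, mu = rep(0, length(regions)),
                           Sigma = model$sigma[[cond]])
        Z <- matrix(Z, nrow = n)
        U <- stats::pnorm(Z)
        counts <- matrix(0L, n, length(regions))
        for (j in seq_along(regions))
          counts[, j] <- stats::qnbinom(U[, j], size = model$dispersion,
                                        mu = model$mu[cond, regions[j]])
        df <- data.frame(
          fish_id = sprintf("%s_%s_%02d", sex, cond, seq_len(n)),
          sex = sex, condition = cond, stringsAsFactors = FALSE)
        df[regions] <- as.data.frame(counts)
        rows[[length(rows) + 1L]] <- df
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Validate an activation table against the column contract
#'
#' Checks that every region column is present with non-negative integer
#' counts, that `sex`/`condition` levels are recognized, and that each fish
#' appears once. Called by the downstream testing and network stages.
#'
#' @param table Activation data.frame.
#' @param regions Expected region columns.
#' @return The table, invisibly, on success.
#' @export
validate_activation_table <- function(table, regions = sdmn_regions()) {
  miss <- setdiff(c("fish_id", "sex", "condition", regions), names(table))
  if (length(miss))
    stop("activation table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(table) == 0) stop("activation table is empty")
  if (anyDuplicated(table$fish_id))
    stop("duplicated fish_id in activation table")
  cnt <- as.matrix(table[regions])
  if (any(!is.finite(cnt)) || any(cnt < 0))
    stop("region counts must be finite and non-negative")
  invisible(table)
}
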