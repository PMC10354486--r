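#' End-to-end tendency-to-peck analysis
#'
#' Runs the full aggression-network analysis on a validated dataset:
#' observation-window filtering (optionally restricted to the first peck of
#' each dyadic battle), brood-day covariates, observed daily directed
#' counts, Monte Carlo permutation expectations, the deviation table, the
#' bootstrap of the 80\% split with one smooth model per side and
#' iteration, aggregated prediction curves at the minimum / median /
#' maximum observed biomass, and the aggression-pattern classification of
#' every attacker-older curve. Deterministic given \code{seed}.
#'
#' @param dataset a \code{kite_dataset}.
#' @param weights optional prey-category weight table (only needed when some
#'   deliveries lack observer mass estimates).
#' @param n_perm recipient permutations per brood-day (default 10,000).
#' @param n_boot bootstrap iterations of the 80\% split (default 100).
#' @param frac fraction of peck events per bootstrap subset.
#' @param seed master RNG seed for permutations and bootstrap.
#' @param first_peck_only apply [first_peck_filter()] before the analysis.
#' @param battle_gap battle gap in seconds for the first-peck filter.
#' @param include_zero_days retain zero-peck brood-days in model fits.
#' @param k tensor-smooth basis dimension per marginal.
#' @param window observation window, \code{c(start, end)}.
#' @param sides which model sides to fit; the default fits both, but
#'   pattern-recovery analyses that only classify down-rank aggression can
#'   restrict to \code{"attacker_older"} to halve the fitting cost.
#' @param out_dir if given, artifacts are written there: deviations.csv,
#'   curves.csv, patterns.json, network_summary.csv, manifest.json.
#' @param save_bootstrap also write each bootstrap iteration's deviation
#'   table to \code{out_dir/boot_###.csv} (requires \code{out_dir}).
#' @return a list with \code{deviations} (full-data deviation table),
#'   \code{curves} (bootstrap tendency curves), \code{patterns}
#'   (classification per phase and biomass level), \code{summary} (network
#'   summary), \code{n_fits} (successful bootstrap fits per side) and
#'   \code{manifest}.
#' @export
run_tendency_pipeline <- function(dataset, weights = NULL, n_perm = 10000,
                                  n_boot = 100, frac = 0.8, seed = 1L,
                                  first_peck_only = FALSE, battle_gap = 60,
                                  include_zero_days = FALSE, k = 5,
                                  window = c("08:00:00", "14:00:00"),
                                  sides = c("attacker_older", "attacker_younger"),
                                  out_dir = NULL, save_bootstrap = FALSE) {
  stopifnot(inherits(dataset, "kite_dataset"))
  pecks <- filter_observation_window(dataset$pecks, window[1], window[2])
  if (first_peck_only) pecks <- first_peck_filter(pecks, battle_gap)
  pecks <- add_ranks(pecks, dataset$broods)
  cov <- brood_day_covariates(dataset, weights)
  modelled_days <- cov[cov$phase %in% c("1", "2"), c("brood_id", "date")]

  counts <- daily_directed_counts(pecks, dataset$broods,
                                  covered_days = modelled_days)
  full_exp <- expected_counts_mc(counts, n_perm = n_perm,
                                 seed = stream_seed(seed, "perm_full"))
  deviations <- deviation_table(full_exp, cov, dataset$broods)

  sides <- match.arg(sides, several.ok = TRUE)
  ref <- deviations[deviations$phase %in% c("1", "2") & !deviations$zero_day, ]
  levels_of <- function(side) {
    b <- ref$biomass_g[ref$side == side]
    c(min = min(b), median = median(b), max = max(b))
  }
  grid_of <- function(side) {
    d <- ref$delta_days[ref$side == side]
    seq(min(d), max(d))
  }

  boots <- bootstrap_splits(pecks, frac = frac, n_boot = n_boot,
                            seed = stream_seed(seed, "boot"))
  fits <- setNames(vector("list", length(sides)), sides)
  if (save_bootstrap && !is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (b in seq_along(boots)) {
    cb <- daily_directed_counts(boots[[b]], dataset$broods,
                                covered_days = modelled_days)
    eb <- expected_counts_mc(cb, n_perm = n_perm,
                             seed = stream_seed(seed, "perm_boot", b))
    db <- deviation_table(eb, cov, dataset$broods)
    if (save_bootstrap && !is.null(out_dir))
      write.csv(db, file.path(out_dir, sprintf("boot_%03d.csv", b)),
                row.names = FALSE)
    for (side in sides) {
      f <- tryCatch(fit_tendency_model(db, side = side, k = k,
                                       include_zero_days = include_zero_days),
                    kitepeck_fit_error = function(e) NULL)
      if (!is.null(f)) fits[[side]] <- c(fits[[side]], list(f))
    }
  }

  curves <- do.call(rbind, lapply(sides, function(side) {
    if (length(fits[[side]]) < 2) return(NULL)
    predict_tendency_curves(fits[[side]], biomass_levels = levels_of(side),
                            delta_grid = grid_of(side))
  }))

  older <- if (is.null(curves)) NULL else
    curves[curves$side == "attacker_older", ]
  combos <- if (is.null(older)) data.frame() else
    unique(older[, c("phase", "biomass_level")])
  patterns <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    cu <- older[older$phase == combos$phase[i] &
                  older$biomass_level == combos$biomass_level[i], ]
    data.frame(phase = combos$phase[i], biomass_level = combos$biomass_level[i],
               pattern = classify_pattern(cu, ci_scale = if (frac < 1)
                 sqrt(frac / (1 - frac)) else 1),
               stringsAsFactors = FALSE)
  }))

  summary <- export_network_summary(pecks, cov, dataset$broods)
  manifest <- run_manifest(seed, list(
    n_perm = n_perm, n_boot = n_boot, frac = frac,
    first_peck_only = first_peck_only, battle_gap = battle_gap,
    include_zero_days = include_zero_days, k = k, window = window,
    n_pecks = nrow(pecks),
    delta_zero_assignment = "by hatch rank (earlier rank acts as older)",
    delta_grid = "integer days over the observed range per side"))

  out <- list(deviations = deviations, curves = curves, patterns = patterns,
              summary = summary,
              n_fits = vapply(fits, length, integer(1)), manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(deviations, file.path(out_dir, "deviations.csv"), row.names = FALSE)
    write.csv(curves, file.path(out_dir, "curves.csv"), row.names = FALSE)
    write.csv(summary, file.path(out_dir, "network_summary.csv"), row.names = FALSE)
    jsonlite::write_json(patterns, file.path(out_dir, "patterns.json"),
                         dataframe = "rows", auto_unbox = TRUE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  out
}

#' End-to-end food-allocation analysis
#'
#' Computes daily peck log-ratios from window-filtered pecks, joins feeding
#' bouts to brood-day covariates, fits the multinomial additive allocation
#' model and predicts the S/M/J food shares along the biomass and log-ratio
#' grids at a fixed age of the oldest nestling.
#'
#' @inheritParams run_tendency_pipeline
#' @param c zero-handling constant of the peck log-ratio.
#' @param at_age_of_oldest age (days) at which shares are predicted
#'   (defaults to the mean age over modelled bouts).
#' @param k_biomass,k_ratio,k_age smoother basis dimensions.
#' @param n_sim coefficient draws for the share uncertainty bands
#'   (posterior-approximation bands; see [predict_allocation_shares()]).
#' @return a list with \code{ratios}, \code{fit}, \code{shares} (list of
#'   \code{vs_biomass} and \code{vs_ratio} grids) and \code{manifest}.
#' @export
run_allocation_pipeline <- function(dataset, weights = NULL, c = 0.5,
                                    k_biomass = 4, k_ratio = 3, k_age = 5,
                                    at_age_of_oldest = NULL,
                                    window = c("08:00:00", "14:00:00"),
                                    seed = 1L, n_sim = 500, out_dir = NULL) {
  stopifnot(inherits(dataset, "kite_dataset"))
  pecks <- filter_observation_window(dataset$pecks, window[1], window[2])
  pecks <- add_ranks(pecks, dataset$broods)
  cov <- brood_day_covariates(dataset, weights)
  counts <- daily_directed_counts(pecks, dataset$broods,
                                  covered_days = cov[, c("brood_id", "date")])
  ratios <- daily_peck_log_ratio(counts, c = c)
  bouts <- add_ranks(dataset$bouts, dataset$broods, cols = "recipient_id")
  fit <- fit_allocation_model(bouts, cov, ratios, k_biomass = k_biomass,
                              k_ratio = k_ratio, k_age = k_age)
  shares <- predict_allocation_shares(fit, at_age_of_oldest = at_age_of_oldest,
                                      n_sim = n_sim,
                                      seed = stream_seed(seed, "share_bands"))
  manifest <- run_manifest(seed, list(
    c = c, k_biomass = k_biomass, k_ratio = k_ratio, k_age = k_age,
    at_age_of_oldest = at_age_of_oldest %||% fit$age_mean,
    window = window, n_bouts = fit$n))
  out <- list(ratios = ratios, fit = fit, shares = shares, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(shares$vs_biomass, file.path(out_dir, "shares_vs_biomass.csv"),
              row.names = FALSE)
    write.csv(shares$vs_ratio, file.path(out_dir, "shares_vs_ratio.csv"),
              row.names = FALSE)
    write.csv(ratios, file.path(out_dir, "peck_log_ratios.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  out
}

#' Aggression-network summary by phase and food tercile
#'
#' Mean daily peck counts and percentage of total pecks per directed dyad,
#' by post-hatching phase and daily-biomass tercile (poor / average /
#' favourable thirds of the within-phase brood-day biomass distribution);
#' rows with \code{food = "all"} pool the phase. Within each phase-by-food
#' cell the six dyad percentages sum to 100.
#'
#' @param pecks a (window-filtered) peck table.
#' @param covariates brood-day covariates from [brood_day_covariates()].
#' @param broods the brood table.
#' @return a data frame with \code{phase}, \code{food},
#'   \code{attacker_rank}, \code{recipient_rank}, \code{mean_daily_pecks},
#'   \code{pct}.
#' @export
export_network_summary <- function(pecks, covariates, broods) {
  modelled <- covariates[covariates$phase %in% c("1", "2"), , drop = FALSE]
  counts <- daily_directed_counts(pecks, broods,
                                  covered_days = modelled[, c("brood_id", "date")])
  ci <- match(paste(counts$brood_id, counts$date),
              paste(modelled$brood_id, modelled$date))
  counts$phase <- modelled$phase[ci]
  counts$biomass_g <- modelled$biomass_g[ci]
  counts <- counts[!is.na(counts$phase), , drop = FALSE]

  counts$food <- NA_character_
  for (ph in unique(counts$phase)) {
    i <- counts$phase == ph
    days <- unique(counts[i, c("brood_id", "date", "biomass_g")])
    qs <- quantile(days$biomass_g, c(1, 2) / 3, names = FALSE)
    # boundary days fall in the lower class; robust to tied tercile breaks
    idx <- 1L + (counts$biomass_g[i] > qs[1]) + (counts$biomass_g[i] > qs[2])
    counts$food[i] <- c("poor", "average", "favourable")[idx]
  }

  cell <- function(sub, ph, food) {
    n_days <- nrow(unique(sub[, c("brood_id", "date")]))
    agg <- aggregate(sub$count, by = list(attacker_rank = sub$attacker_rank,
                                          recipient_rank = sub$recipient_rank),
                     FUN = sum)
    tot <- sum(agg$x)
    data.frame(phase = ph, food = food,
               attacker_rank = agg$attacker_rank,
               recipient_rank = agg$recipient_rank,
               mean_daily_pecks = agg$x / n_days,
               pct = if (tot > 0) 100 * agg$x / tot else 0)
  }
  out <- list()
  for (ph in sort(unique(counts$phase))) {
    sub_ph <- counts[counts$phase == ph, ]
    out[[length(out) + 1L]] <- cell(sub_ph, ph, "all")
    for (fd in c("poor", "average", "favourable")) {
      sub <- sub_ph[sub_ph$food == fd, ]
      if (nrow(sub)) out[[length(out) + 1L]] <- cell(sub, ph, fd)
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(out$phase, match(out$food, c("all", "poor", "average", "favourable")),
                   rank_order(out$attacker_rank), rank_order(out$recipient_rank)), ]
  rownames(out) <- NULL
  out
}

#' Descriptive statistics of an event-log dataset
#'
#' The headline per-phase descriptive statistics of a dataset, computed with
#' the same filters as the analysis pipelines: total and mean daily peck
#' counts, number of broods contributing pecks and bouts, mean daily
#' delivered biomass, and the per-dyad percentage table. Useful to compare a
#' dataset (field or synthetic) against published summaries.
#'
#' @inheritParams run_tendency_pipeline
#' @return a list with one element per phase (\code{phase1}, \code{phase2}),
#'   each a list of \code{n_pecks}, \code{n_broods_pecks},
#'   \code{mean_daily_pecks}, \code{n_bouts}, \code{n_broods_bouts},
#'   \code{mean_daily_biomass_g} and \code{dyad_pct} (named vector over the
#'   six directed dyads).
#' @export
descriptive_stats <- function(dataset, weights = NULL,
                              window = c("08:00:00", "14:00:00")) {
  stopifnot(inherits(dataset, "kite_dataset"))
  pecks <- add_ranks(filter_observation_window(dataset$pecks, window[1], window[2]),
                     dataset$broods)
  bouts <- filter_observation_window(dataset$bouts, window[1], window[2])
  cov <- brood_day_covariates(dataset, weights)
  out <- list()
  for (ph in c("1", "2")) {
    cd <- cov[cov$phase == ph, ]
    key <- paste(cd$brood_id, cd$date)
    pk <- pecks[paste(pecks$brood_id, pecks$date) %in% key, ]
    bt <- bouts[paste(bouts$brood_id, bouts$date) %in% key, ]
    daily <- if (nrow(pk))
      table(paste(pk$brood_id, pk$date)) else integer(0)
    dyad <- paste0(pk$attacker_rank, ">", pk$recipient_rank)
    lv <- apply(dyad_grid(), 1, paste0, collapse = ">")
    dyad_pct <- if (nrow(pk))
      100 * prop.table(table(factor(dyad, levels = lv))) else
        setNames(rep(NA_real_, 6), lv)
    out[[paste0("phase", ph)]] <- list(
      n_pecks = nrow(pk),
      n_broods_pecks = length(unique(pk$brood_id)),
      mean_daily_pecks = if (length(daily)) mean(daily) else 0,
      n_bouts = nrow(bt),
      n_broods_bouts = length(unique(bt$brood_id)),
      mean_daily_biomass_g = if (nrow(cd)) mean(cd$biomass_g) else NA_real_,
      dyad_pct = round(c(dyad_pct), 3))
  }
  out
}

run_manifest <- function(seed, params) {
  list(package = "kitepeck",
       version = as.character(utils::packageVersion("kitepeck")),
       r_version = R.version.string,
       seed = seed,
       params = params)
}
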