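#' Daily peck log-ratio (prevailing aggression pattern proxy)
#'
#' For each brood-day, the log of the ratio between the pecks received by
#' the middle and by the junior nestling (summed over both possible
#' attackers), with a small constant \code{c} added to numerator and
#' denominator to keep days with zero counts finite
#' (Haldane-Anscombe correction, default \code{c = 0.5}):
#' \deqn{log((received_M + c) / (received_J + c))}
#' A positive value means the middle nestling absorbed most aggression
#' (close-competitor-like), a negative or near-zero value that attacks were
#' spread down the hierarchy (downward-heuristic-like).
#'
#' @param counts a counts table from [daily_directed_counts()].
#' @param c non-negative zero-handling constant; \code{c = 0} is only valid
#'   when no brood-day has a zero received count.
#' @return a data frame with \code{brood_id}, \code{date},
#'   \code{received_M}, \code{received_J}, \code{log_ratio}.
#' @export
daily_peck_log_ratio <- function(counts, c = 0.5) {
  if (c < 0) kite_error("c must be >= 0", "kitepeck_argument_error")
  rec <- function(rank) {
    sub <- counts[counts$recipient_rank == rank, ]
    agg <- aggregate(sub$count, by = list(brood_id = sub$brood_id,
                                          date = sub$date), FUN = sum)
    names(agg)[3] <- paste0("received_", rank)
    agg
  }
  out <- merge(rec("M"), rec("J"), by = c("brood_id", "date"))
  if (c == 0 && any(out$received_M == 0 | out$received_J == 0))
    kite_error("zero received counts present; use c > 0 to keep the log-ratio finite",
               "kitepeck_argument_error")
  out$log_ratio <- log((out$received_M + c) / (out$received_J + c))
  out <- out[order(out$brood_id, out$date), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Multinomial additive model of food allocation
#'
#' Models which nestling (senior, middle or junior) receives each parental
#' feeding bout, as a multinomial additive logit regression (baseline
#' category S) with smooth effects of the day's total delivered biomass
#' (basis dimension \code{k_biomass = 4}), of the daily peck log-ratio
#' (\code{k_ratio = 3}), and of the age of the oldest nestling
#' (\code{k_age = 5}, controlling for age trends in provisioning), plus a
#' brood random intercept. Bouts are used while the oldest nestling is at
#' most 21 d old (feeding bouts are not scored beyond that age). Smoothing
#' parameters are estimated by penalized likelihood (REML).
#'
#' @param bouts a feeding-bout table carrying a \code{recipient_rank} column
#'   (see the \code{broods} mapping helpers; the pipeline adds it).
#' @param covariates brood-day covariates from [brood_day_covariates()].
#' @param ratios daily peck log-ratios from [daily_peck_log_ratio()].
#' @param k_biomass,k_ratio,k_age smoother basis dimensions.
#' @param max_age_of_oldest inclusion cutoff on \code{age_S} in days.
#' @return an \code{allocation_fit}: list with the fitted \code{mgcv::gam}
#'   multinomial model and the covariate summaries used for prediction
#'   defaults.
#' @export
fit_allocation_model <- function(bouts, covariates, ratios,
                                 k_biomass = 4, k_ratio = 3, k_age = 5,
                                 max_age_of_oldest = 21) {
  if (!"recipient_rank" %in% names(bouts))
    kite_error("bouts must carry a recipient_rank column", "kitepeck_argument_error")
  d <- bouts[, c("brood_id", "date", "recipient_rank")]
  ci <- match(paste(d$brood_id, d$date),
              paste(covariates$brood_id, covariates$date))
  d$biomass_g <- covariates$biomass_g[ci]
  d$age_S <- covariates$age_S[ci]
  ri <- match(paste(d$brood_id, d$date),
              paste(ratios$brood_id, ratios$date))
  d$log_ratio <- ratios$log_ratio[ri]
  d <- d[complete.cases(d) & d$age_S <= max_age_of_oldest, , drop = FALSE]
  missing_cat <- setdiff(KITE_RANKS, unique(d$recipient_rank))
  if (length(missing_cat))
    kite_error(sprintf("category never observed among feeding bouts: %s",
                       paste(missing_cat, collapse = ", ")),
               "kitepeck_fit_error")
  d$y <- rank_order(d$recipient_rank) - 1L   # 0 = S (baseline), 1 = M, 2 = J
  d$brood_id <- factor(d$brood_id)
  lp <- sprintf("~ s(biomass_g, k = %d) + s(log_ratio, k = %d) + s(age_S, k = %d) + s(brood_id, bs = 're')",
                k_biomass, k_ratio, k_age)
  form <- list(stats::as.formula(paste("y", lp)), stats::as.formula(lp))
  model <- mgcv::gam(form, family = mgcv::multinom(K = 2), data = d,
                     method = "REML", optimizer = "efs")
  structure(list(model = model,
                 n = nrow(d),
                 biomass_range = range(d$biomass_g),
                 ratio_range = range(d$log_ratio),
                 age_range = range(d$age_S),
                 biomass_mean = mean(d$biomass_g),
                 ratio_mean = mean(d$log_ratio),
                 age_mean = mean(d$age_S),
                 brood_levels = levels(d$brood_id),
                 observed_shares = prop.table(table(factor(d$recipient_rank,
                                                           levels = KITE_RANKS)))),
            class = "allocation_fit")
}

#' @export
print.allocation_fit <- function(x, ...) {
  cat(sprintf("<allocation_fit> n=%d bouts, observed shares S/M/J = %.3f/%.3f/%.3f\n",
              x$n, x$observed_shares[1], x$observed_shares[2], x$observed_shares[3]))
  invisible(x)
}

#' Predicted food shares of the three nestlings
#'
#' Population-level predicted probabilities that a feeding bout goes to the
#' senior, middle or junior nestling (brood random intercepts excluded),
#' along a grid of one covariate with the others held at their observed
#' means. Shares are non-negative and sum to one at every grid point.
#'
#' When \code{n_sim > 0}, 95\% uncertainty bands per category are attached
#' (\code{lo95_S} ... \code{hi95_J}). They are simulation bands from the
#' Gaussian approximation to the penalized-likelihood posterior of the model
#' coefficients (draws from \code{N(coef, Vp)} pushed through the inverse
#' multinomial link), not bootstrap intervals; the point shares themselves
#' are unaffected.
#'
#' @param fit an \code{allocation_fit}.
#' @param biomass_grid,ratio_grid numeric grid over daily biomass (g) or the
#'   peck log-ratio; supply exactly one, or neither to get both default
#'   grids (50 points over the observed range).
#' @param at_age_of_oldest age (days) of the oldest nestling to predict at;
#'   defaults to the observed mean.
#' @param n_sim coefficient draws for the uncertainty bands; 0 skips them.
#' @param seed RNG seed for the coefficient draws.
#' @return a data frame (or, when both default grids are produced, a named
#'   list of two) with the grid variable, \code{share_S}, \code{share_M},
#'   \code{share_J} and, when \code{n_sim > 0}, the per-category bands.
#' @export
predict_allocation_shares <- function(fit, biomass_grid = NULL,
                                      ratio_grid = NULL,
                                      at_age_of_oldest = NULL,
                                      n_sim = 0, seed = NULL) {
  stopifnot(inherits(fit, "allocation_fit"))
  age <- at_age_of_oldest %||% fit$age_mean
  if (is.null(biomass_grid) && is.null(ratio_grid)) {
    return(list(
      vs_biomass = predict_allocation_shares(
        fit, biomass_grid = seq(fit$biomass_range[1], fit$biomass_range[2],
                                length.out = 50), at_age_of_oldest = age,
        n_sim = n_sim, seed = seed),
      vs_ratio = predict_allocation_shares(
        fit, ratio_grid = seq(fit$ratio_range[1], fit$ratio_range[2],
                              length.out = 50), at_age_of_oldest = age,
        n_sim = n_sim, seed = seed)))
  }
  if (!is.null(biomass_grid) && !is.null(ratio_grid))
    kite_error("supply only one of biomass_grid / ratio_grid",
               "kitepeck_argument_error")
  if (!is.null(biomass_grid)) {
    check_range(biomass_grid, fit$biomass_range, "biomass_g")
    nd <- data.frame(biomass_g = biomass_grid, log_ratio = fit$ratio_mean)
    grid_col <- "biomass_g"
  } else {
    check_range(ratio_grid, fit$ratio_range, "log_ratio")
    nd <- data.frame(biomass_g = fit$biomass_mean, log_ratio = ratio_grid)
    grid_col <- "log_ratio"
  }
  nd$age_S <- age
  nd$brood_id <- factor(fit$brood_levels[1], levels = fit$brood_levels)
  excl <- grep("brood_id", vapply(fit$model$smooth, function(s) s$label,
                                  character(1)), value = TRUE)
  p <- predict(fit$model, newdata = nd, type = "response", exclude = excl,
               newdata.guaranteed = TRUE)
  out <- nd[, grid_col, drop = FALSE]
  out$share_S <- p[, 1]; out$share_M <- p[, 2]; out$share_J <- p[, 3]
  if (n_sim > 0) {
    Xp <- predict(fit$model, newdata = nd, type = "lpmatrix", exclude = excl,
                  newdata.guaranteed = TRUE)
    lpi <- attr(Xp, "lpi")
    b <- with_seed(seed,
                   mgcv::rmvn(n_sim, stats::coef(fit$model), fit$model$Vp))
    sims <- array(NA_real_, c(nrow(nd), 3, n_sim))
    for (s in seq_len(n_sim)) {
      e <- cbind(1, exp(Xp[, lpi[[1]], drop = FALSE] %*% b[s, lpi[[1]]]),
                 exp(Xp[, lpi[[2]], drop = FALSE] %*% b[s, lpi[[2]]]))
      sims[, , s] <- e / rowSums(e)
    }
    q <- apply(sims, c(1, 2), quantile, probs = c(0.025, 0.975))
    for (k in 1:3) {
      out[[paste0("lo95_", KITE_RANKS[k])]] <- q[1, , k]
      out[[paste0("hi95_", KITE_RANKS[k])]] <- q[2, , k]
    }
  }
  rownames(out) <- NULL
  out
}

check_range <- function(grid, range, name) {
  if (any(grid < range[1] - 1e-9) || any(grid > range[2] + 1e-9))
    warning(sprintf("%s grid extends beyond the observed range [%.3g, %.3g]; predictions are extrapolations",
                    name, range[1], range[2]))
}
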