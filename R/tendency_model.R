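#' Smooth model of the tendency to peck
#'
#' Fits a penalized additive model of the per-dyad-day deviation from random
#' interactions (Gaussian response) on a tensor-product smooth surface of
#' signed age difference and daily delivered biomass, separately for each
#' post-hatching phase, with the brood identity as a penalized random
#' intercept:
#'
#' \deqn{deviation ~ phase + te(delta, biomass, by = phase) + s(brood, re)}
#'
#' Dyads where the attacker is the older of the pair (\code{side =
#' "attacker_older"}) and where it is the younger are modelled separately,
#' because a nestling's behaviour toward an older versus a younger sibling
#' can differ sharply near an age difference of zero; dyads with equal hatch
#' dates are assigned by hatch rank (earlier rank acts as "older").
#'
#' @param deviations a deviation table from [deviation_table()].
#' @param side \code{"attacker_older"} or \code{"attacker_younger"}.
#' @param k basis dimension per marginal of the tensor smooth (default 5; it
#'   is reduced automatically when fewer distinct age-difference values are
#'   observed).
#' @param include_zero_days retain all-zero brood-days in the fit (default
#'   \code{FALSE}: days without any aggression carry no information about
#'   recipient choice).
#' @return a \code{tendency_fit}: list with the fitted \code{mgcv::gam}
#'   model, the side, and the observed covariate ranges used for prediction
#'   defaults.
#' @export
fit_tendency_model <- function(deviations, side = c("attacker_older", "attacker_younger"),
                               k = 5, include_zero_days = FALSE) {
  side <- match.arg(side)
  d <- deviations[deviations$side == side & deviations$phase %in% c("1", "2"), ,
                  drop = FALSE]
  if (!include_zero_days) d <- d[!d$zero_day, , drop = FALSE]
  if (length(unique(d$brood_id)) < 2)
    kite_error("need at least 2 broods to fit the tendency model",
               "kitepeck_fit_error")
  if (nrow(d) < 20)
    kite_error(sprintf("too few rows (%d) on side %s; need >= 20", nrow(d), side),
               "kitepeck_fit_error")
  n_delta <- length(unique(d$delta_days))
  if (n_delta < 3)
    kite_error("degenerate design: too few distinct age-difference values on this side; pool sides or add data",
               "kitepeck_fit_error")
  d$phase <- factor(d$phase, levels = c("1", "2"))
  d$brood_id <- factor(d$brood_id)
  kd <- min(k, n_delta)
  n_biomass <- length(unique(d$biomass_g))
  kb <- min(k, n_biomass)
  two_phase <- length(unique(droplevels(d$phase))) == 2
  # with (near-)constant biomass the surface degenerates to a curve in delta
  smooth <- if (n_biomass >= 3)
    sprintf("te(delta_days, biomass_g%%s, k = c(%d, %d))", kd, kb)
  else sprintf("s(delta_days%%s, k = %d)", kd)
  form <- stats::as.formula(if (two_phase)
    paste("deviation ~ phase +", sprintf(smooth, ", by = phase"),
          "+ s(brood_id, bs = 're')")
  else paste("deviation ~", sprintf(smooth, ""), "+ s(brood_id, bs = 're')"))
  if (!two_phase) d$phase <- droplevels(d$phase)
  model <- mgcv::gam(form, data = d, method = "REML")
  structure(list(model = model, side = side,
                 phases = levels(droplevels(d$phase)),
                 delta_range = range(d$delta_days),
                 biomass_range = range(d$biomass_g),
                 brood_levels = levels(d$brood_id),
                 n = nrow(d)),
            class = "tendency_fit")
}

#' @export
print.tendency_fit <- function(x, ...) {
  cat(sprintf("<tendency_fit> side=%s, n=%d, delta in [%d, %d], biomass in [%.1f, %.1f] g\n",
              x$side, x$n, x$delta_range[1], x$delta_range[2],
              x$biomass_range[1], x$biomass_range[2]))
  invisible(x)
}

# population-level predictions (brood random intercept excluded) on a
# delta x biomass x phase grid, for one fitted model
predict_tendency <- function(fit, delta_grid, biomass_levels, phases = NULL) {
  stopifnot(inherits(fit, "tendency_fit"))
  phases <- phases %||% fit$phases
  grid <- expand.grid(delta_days = delta_grid,
                      biomass_level = names(biomass_levels),
                      phase = phases, stringsAsFactors = FALSE)
  grid$biomass_g <- as.numeric(biomass_levels[grid$biomass_level])
  nd <- data.frame(delta_days = grid$delta_days, biomass_g = grid$biomass_g,
                   phase = factor(grid$phase, levels = levels(fit$model$model$phase)),
                   brood_id = factor(fit$brood_levels[1], levels = fit$brood_levels))
  grid$pred <- as.numeric(predict(fit$model, newdata = nd,
                                  exclude = "s(brood_id)", newdata.guaranteed = TRUE))
  grid
}

#' Bootstrap tendency-to-peck curves
#'
#' Aggregates the predictions of the model fits from all bootstrap
#' iterations into curves of the tendency to peck versus age difference: at
#' every grid point the curve reports the mean prediction and the 2.5/97.5
#' percentile bounds over the bootstrap set, one curve per side, phase and
#' biomass level (poor = minimum, average = median, favourable = maximum
#' observed daily biomass).
#'
#' @param fits a list of \code{tendency_fit} objects, one per bootstrap
#'   iteration (all on the same side).
#' @param biomass_levels named numeric vector of gram values, typically
#'   \code{c(min = ..., median = ..., max = ...)} computed over the modelled
#'   brood-days before prediction.
#' @param delta_grid integer age differences to predict at (defaults to the
#'   observed range of the first fit).
#' @return a data frame of class \code{tendency_curves} with columns
#'   \code{side}, \code{phase}, \code{biomass_level}, \code{biomass_g},
#'   \code{delta_days}, \code{mean}, \code{lo95}, \code{hi95}.
#' @export
predict_tendency_curves <- function(fits, biomass_levels = NULL, delta_grid = NULL) {
  if (!length(fits)) kite_error("empty fit list", "kitepeck_argument_error")
  if (length(fits) < 2)
    kite_error("need at least 2 bootstrap fits to form intervals",
               "kitepeck_argument_error")
  sides <- unique(vapply(fits, function(f) f$side, character(1)))
  if (length(sides) != 1)
    kite_error("all fits must share the same side", "kitepeck_argument_error")
  f1 <- fits[[1]]
  delta_grid <- delta_grid %||% seq(f1$delta_range[1], f1$delta_range[2])
  if (is.null(biomass_levels)) {
    b <- f1$biomass_range
    biomass_levels <- c(min = b[1], median = mean(b), max = b[2])
  }
  preds <- lapply(fits, predict_tendency, delta_grid = delta_grid,
                  biomass_levels = biomass_levels)
  grid <- preds[[1]][, c("delta_days", "biomass_level", "phase", "biomass_g")]
  mat <- vapply(preds, function(p) p$pred, numeric(nrow(grid)))
  out <- data.frame(side = sides, phase = grid$phase,
                    biomass_level = grid$biomass_level,
                    biomass_g = grid$biomass_g, delta_days = grid$delta_days,
                    mean = rowMeans(mat),
                    lo95 = apply(mat, 1, quantile, probs = 0.025),
                    hi95 = apply(mat, 1, quantile, probs = 0.975))
  out <- out[order(out$phase, out$biomass_level, out$delta_days), ]
  rownames(out) <- NULL
  class(out) <- c("tendency_curves", class(out))
  out
}

#' Classify the aggression pattern of a tendency curve
#'
#' Decision rule applied to one attacker-older curve (a single side, phase
#' and biomass level), using the bootstrap 95\% interval at each age
#' difference on the grid:
#' \describe{
#'   \item{close_competitor}{the interval lies above 0 at some small age
#'     difference (|delta| <= 1) \emph{and} below 0 at the most negative age
#'     difference: similar-aged siblings are targeted, much younger ones
#'     avoided.}
#'   \item{downward_heuristic}{the interval covers 0 over the whole grid:
#'     recipients are chosen indistinguishably from random, i.e. attacks run
#'     down the hierarchy in proportion to opportunity.}
#'   \item{bullying}{the interval lies above 0 only at the most negative age
#'     difference: the youngest sibling is singled out.}
#'   \item{mixed}{anything else.}
#' }
#' The framework is defined for down-rank aggression; curves from the
#' attacker-younger side are rejected.
#'
#' The emitted curves carry the plain percentile interval over the bootstrap
#' prediction set. For deciding whether a curve differs from zero, that
#' interval is known to be anti-conservative: resampling a fixed fraction
#' \code{f} of the events without replacement yields a bootstrap spread of
#' about \code{sqrt(f * (1 - f))} times the sampling standard error, while a
#' calibrated zero-test needs \code{f} times it. \code{ci_scale} widens the
#' interval about the bootstrap mean by that ratio,
#' \code{sqrt(f / (1 - f))} (= 2 at the default 80\% split), the standard
#' m-out-of-n subsampling correction; [run_tendency_pipeline()] passes it
#' automatically. \code{ci_scale = 1} applies the raw percentile interval.
#'
#' In addition, the labels are whole-curve decisions — "zero-consistent
#' everywhere" is an intersection over every grid point — so the zero-test
#' controls the family-wise error across the grid: with
#' \code{simultaneous = TRUE} (the default) the per-point bands are widened
#' by the Bonferroni factor \code{qnorm(1 - 0.025/m) / qnorm(0.975)} for a
#' grid of m points. Pointwise bands would falsely reject the
#' downward-heuristic label on a growing fraction of truly random curves as
#' the grid grows.
#'
#' @param curve a \code{tendency_curves} data frame (or subset thereof)
#'   containing exactly one side/phase/biomass-level combination.
#' @param ci_scale calibration factor applied to the interval half-widths
#'   about the bootstrap mean before testing against zero.
#' @param simultaneous control the family-wise error of the whole-curve
#'   decision (Bonferroni across grid points) instead of using pointwise
#'   bands.
#' @return one of \code{"close_competitor"}, \code{"downward_heuristic"},
#'   \code{"bullying"}, \code{"mixed"}.
#' @export
classify_pattern <- function(curve, ci_scale = 1, simultaneous = TRUE) {
  if (!all(c("delta_days", "lo95", "hi95") %in% names(curve)))
    kite_error("curve must carry delta_days, lo95, hi95",
               "kitepeck_argument_error")
  if ("side" %in% names(curve) && any(curve$side != "attacker_older"))
    kite_error("classification is defined for the attacker_older side only",
               "kitepeck_classification_error")
  if ("phase" %in% names(curve) &&
      (length(unique(curve$phase)) > 1 ||
       length(unique(curve$biomass_level)) > 1))
    kite_error("classify one phase x biomass level curve at a time",
               "kitepeck_argument_error")
  curve <- curve[order(curve$delta_days), , drop = FALSE]
  adj <- ci_scale
  if (isTRUE(simultaneous) && nrow(curve) > 1)
    adj <- adj * stats::qnorm(1 - 0.025 / nrow(curve)) / stats::qnorm(0.975)
  lo <- curve$mean - adj * (curve$mean - curve$lo95)
  hi <- curve$mean + adj * (curve$hi95 - curve$mean)
  above <- lo > 0                   # calibrated interval excludes 0 from above
  below <- hi < 0                   # calibrated interval excludes 0 from below
  at_min <- which.min(curve$delta_days)
  close <- abs(curve$delta_days) <= 1
  if (any(above[close]) && below[at_min]) return("close_competitor")
  if (!any(above) && !any(below)) return("downward_heuristic")
  if (above[at_min] && !any(above[-at_min])) return("bullying")
  "mixed"
}
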