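#' Observed daily directed interaction frequencies
#'
#' Tabulates peck events into one count per ordered dyad per brood-day (six
#' directed dyads in a brood of three; the diagonal is structurally zero and
#' not represented). Covered brood-days without any peck can be retained as
#' all-zero tables flagged \code{zero_day}, so that days when the nest was
#' observed but no aggression occurred remain visible downstream.
#'
#' @param pecks a peck table (typically window-filtered; see
#'   [filter_observation_window()]).
#' @param broods the brood table of a validated dataset.
#' @param covered_days optional data frame (\code{brood_id}, \code{date}) of
#'   observed brood-days; days listed here but absent from \code{pecks} are
#'   emitted as zero-count records.
#' @return a data frame with one row per directed dyad per brood-day:
#'   \code{brood_id}, \code{date}, \code{attacker_rank},
#'   \code{recipient_rank}, \code{count}, \code{zero_day}. The total of
#'   \code{count} equals \code{nrow(pecks)}.
#' @export
daily_directed_counts <- function(pecks, broods, covered_days = NULL) {
  if (nrow(pecks) && !"attacker_rank" %in% names(pecks))
    pecks <- add_ranks(pecks, broods)
  days <- unique(pecks[, c("brood_id", "date")])
  if (!is.null(covered_days))
    days <- unique(rbind(days, covered_days[, c("brood_id", "date")]))
  if (!nrow(days))
    return(data.frame(brood_id = character(0), date = as.Date(character(0)),
                      attacker_rank = character(0), recipient_rank = character(0),
                      count = integer(0), zero_day = logical(0)))
  days <- days[order(days$brood_id, days$date), , drop = FALSE]
  dyads <- dyad_grid()
  grid <- days[rep(seq_len(nrow(days)), each = nrow(dyads)), , drop = FALSE]
  grid$attacker_rank <- rep(dyads$attacker_rank, nrow(days))
  grid$recipient_rank <- rep(dyads$recipient_rank, nrow(days))
  gk <- paste(grid$brood_id, grid$date, grid$attacker_rank, grid$recipient_rank)
  if (nrow(pecks)) {
    pk <- paste(pecks$brood_id, pecks$date, pecks$attacker_rank,
                pecks$recipient_rank)
    tab <- table(pk)
    grid$count <- as.integer(tab[gk])
    grid$count[is.na(grid$count)] <- 0L
  } else grid$count <- 0L
  day_tot <- stats::ave(grid$count, paste(grid$brood_id, grid$date), FUN = sum)
  grid$zero_day <- day_tot == 0L
  rownames(grid) <- NULL
  grid
}

# the six ordered dyads, attacker-major, recipients in rank order
dyad_grid <- function() {
  out <- expand.grid(recipient_rank = KITE_RANKS, attacker_rank = KITE_RANKS,
                     stringsAsFactors = FALSE)[, 2:1]
  out <- out[out$attacker_rank != out$recipient_rank, ]
  out <- out[order(rank_order(out$attacker_rank), rank_order(out$recipient_rank)), ]
  rownames(out) <- NULL
  out
}

#' Expected counts under random recipient reallocation
#'
#' Under the permutation null model, every peck keeps its attacker and day
#' but its recipient is redrawn uniformly from the pool of possible
#' recipients: the actual recipient or the attacker's other sibling. In a
#' brood of three that pool always has two members, so the null expectation
#' for each of an attacker's two dyads is half of the attacker's daily total.
#'
#' \code{expected_counts_mc()} estimates the expectation by Monte Carlo over
#' \code{n_perm} recipient permutations (the per-event redraw is
#' distributionally identical to reallocating the day's recipient multiset);
#' \code{expected_counts_analytic()} returns the closed form
#' \code{row_total / 2}, which is the \code{n_perm} to infinity limit and the
#' oracle against which the Monte Carlo version is validated. Both preserve
#' attacker-day totals exactly: the two expected counts of an attacker-day
#' always sum to the observed total.
#'
#' @param counts a counts table from [daily_directed_counts()].
#' @param n_perm number of recipient permutations (the analysis default is
#'   10,000).
#' @param seed RNG seed; the same seed reproduces the expected table exactly.
#' @return the counts table with an \code{expected} column appended.
#' @export
expected_counts_mc <- function(counts, n_perm = 10000, seed = NULL) {
  if (!is.numeric(n_perm) || n_perm < 1)
    kite_error("n_perm must be >= 1", "kitepeck_argument_error")
  n_perm <- as.integer(n_perm)
  counts <- order_counts(counts)
  first <- seq(1L, nrow(counts), by = 2L)
  n <- counts$count[first] + counts$count[first + 1L]
  with_seed(seed, {
    draws <- matrix(rbinom(length(n) * n_perm, size = rep(n, n_perm), prob = 0.5),
                    nrow = length(n), ncol = n_perm)
    e1 <- rowMeans(draws)
  })
  counts$expected <- NA_real_
  counts$expected[first] <- e1
  counts$expected[first + 1L] <- n - e1
  counts
}

#' @rdname expected_counts_mc
#' @export
expected_counts_analytic <- function(counts) {
  counts <- order_counts(counts)
  first <- seq(1L, nrow(counts), by = 2L)
  n <- counts$count[first] + counts$count[first + 1L]
  counts$expected <- NA_real_
  counts$expected[first] <- n / 2
  counts$expected[first + 1L] <- n / 2
  counts
}

# canonical row order: brood, date, attacker, recipient (rank order); the two
# recipients of an attacker-day are then adjacent rows
order_counts <- function(counts) {
  stopifnot(nrow(counts) %% 2L == 0L)
  counts[order(counts$brood_id, counts$date,
               rank_order(counts$attacker_rank),
               rank_order(counts$recipient_rank)), , drop = FALSE]
}

#' Deviation from random interactions ("tendency to peck")
#'
#' Joins observed and permutation-expected counts into one row per directed
#' dyad per brood-day, with the deviation (observed minus expected), the
#' signed age difference of the dyad, the day's delivered biomass and phase,
#' and the model side (\code{attacker_older} when the attacker hatched
#' earlier, or, at equal hatch dates, holds the earlier hatch rank;
#' \code{attacker_younger} otherwise). Positive deviations mean the recipient
#' was targeted more than expected by chance, negative ones that it was
#' avoided. Under the analytic expectation the two deviations of an
#' attacker-day sum to zero exactly.
#'
#' @param expected a counts table with an \code{expected} column (see
#'   [expected_counts_mc()]).
#' @param covariates brood-day covariates from [brood_day_covariates()].
#' @param broods the brood table (for dyad age differences).
#' @return a data frame with columns \code{brood_id}, \code{date},
#'   \code{attacker_rank}, \code{recipient_rank}, \code{observed},
#'   \code{expected}, \code{deviation}, \code{delta_days}, \code{biomass_g},
#'   \code{phase}, \code{side}, \code{zero_day}.
#' @export
deviation_table <- function(expected, covariates, broods) {
  if (!"expected" %in% names(expected))
    kite_error("counts must carry an 'expected' column; run expected_counts_mc() or expected_counts_analytic() first",
               "kitepeck_argument_error")
  out <- expected
  names(out)[names(out) == "count"] <- "observed"
  out$deviation <- out$observed - out$expected

  ht <- hatch_table(broods)
  hd <- as.matrix(data.frame(S = as.numeric(ht$hatch_S),
                             M = as.numeric(ht$hatch_M),
                             J = as.numeric(ht$hatch_J)))
  rownames(hd) <- ht$brood_id
  bi <- match(out$brood_id, ht$brood_id)
  out$delta_days <- as.integer(hd[cbind(bi, rank_order(out$attacker_rank))] -
                                 hd[cbind(bi, rank_order(out$recipient_rank))])
  out$side <- ifelse(out$delta_days < 0 |
                       (out$delta_days == 0 &
                          rank_order(out$attacker_rank) < rank_order(out$recipient_rank)),
                     "attacker_older", "attacker_younger")

  ci <- match(paste(out$brood_id, out$date),
              paste(covariates$brood_id, covariates$date))
  out$biomass_g <- covariates$biomass_g[ci]
  out$phase <- covariates$phase[ci]
  drop <- is.na(out$biomass_g) | is.na(out$phase)
  if (any(drop)) {
    warning(sprintf("dropping %d dyad-day row(s) without biomass/phase covariates",
                    sum(drop)))
    out <- out[!drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Bootstrap resamples of the 80\% data split
#'
#' The uncertainty of the tendency-to-peck curves comes from repeating the
#' whole analysis on random 80\% subsets of the peck events: each iteration
#' draws \code{floor(frac * N)} events uniformly without replacement, and the
#' split is redrawn \code{n_boot} times.
#'
#' @param pecks the peck table (the sampling unit is the event).
#' @param frac fraction of events per subset, in (0, 1); analysis default 0.8.
#' @param n_boot number of bootstrap iterations; analysis default 100.
#' @param seed RNG seed; the same seed reproduces the whole sequence.
#' @return a list of \code{n_boot} peck tables.
#' @export
bootstrap_splits <- function(pecks, frac = 0.8, n_boot = 100, seed = NULL) {
  n <- nrow(pecks)
  if (n < 2) kite_error("need at least 2 peck events to split",
                        "kitepeck_argument_error")
  if (!(frac > 0 && frac < 1) && frac != 1)
    kite_error("frac must be in (0, 1]", "kitepeck_argument_error")
  if (n_boot < 1) kite_error("n_boot must be >= 1", "kitepeck_argument_error")
  m <- floor(frac * n)
  with_seed(seed, {
    lapply(seq_len(n_boot), function(b)
      pecks[sort(sample.int(n, m)), , drop = FALSE])
  })
}

#' First peck of each dyadic battle
#'
#' Aggression can escalate into sustained exchanges ("battles") in which
#' later strikes are not independent decisions. This sensitivity filter keeps
#' a peck only if no earlier peck of the same ordered dyad (same brood,
#' attacker and recipient) occurred strictly within \code{battle_gap_seconds}
#' before it; a gap of 0 therefore retains every peck. Battle boundaries are
#' not observable directly, so the gap is a tunable construct (default 60 s).
#'
#' @param pecks a peck table with \code{date} and \code{time}/\code{time_s}
#'   columns.
#' @param battle_gap_seconds non-negative gap defining a battle.
#' @return the retained subset of \code{pecks}, in the original row order.
#' @export
first_peck_filter <- function(pecks, battle_gap_seconds = 60) {
  if (battle_gap_seconds < 0)
    kite_error("battle_gap_seconds must be >= 0", "kitepeck_argument_error")
  if (!nrow(pecks) || battle_gap_seconds == 0) return(pecks)
  t <- as.numeric(pecks$date) * 86400 +
    (if ("time_s" %in% names(pecks)) pecks$time_s else parse_time(pecks$time, "pecks"))
  key <- paste(pecks$brood_id, pecks$attacker_id, pecks$recipient_id)
  ord <- order(key, t)
  same <- c(FALSE, key[ord][-1] == key[ord][-length(ord)])
  gap_ok <- c(TRUE, diff(t[ord]) >= battle_gap_seconds)
  keep_sorted <- !same | gap_ok
  keep <- logical(length(ord))
  keep[ord] <- keep_sorted
  pecks[keep, , drop = FALSE]
}
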