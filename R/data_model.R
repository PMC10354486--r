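#' Event-log data model for broods of three
#'
#' The analysis operates on four event-log tables recorded at the nest:
#' \describe{
#'   \item{broods}{one row per nestling: \code{brood_id}, \code{nestling_id},
#'     \code{hatch_date} (ISO date, hatch day = age 0), \code{hatch_rank}
#'     (\code{"S"}, \code{"M"} or \code{"J"} = senior/middle/junior by hatch
#'     order).}
#'   \item{pecks}{one row per directed strike: \code{brood_id}, \code{date},
#'     \code{time} (\code{HH:MM:SS}), \code{attacker_id}, \code{recipient_id}.}
#'   \item{bouts}{one row per parental feeding bout: \code{brood_id},
#'     \code{date}, \code{time}, \code{recipient_id}.}
#'   \item{deliveries}{one row per prey delivery: \code{brood_id},
#'     \code{date}, \code{category} (one of amphibian, anthropogenic, bird,
#'     invertebrate, mammal, unclassified), \code{fraction} (1, 0.5 or 0.25),
#'     \code{observer_mass_g} (grams; may be blank).}
#' }
#'
#' \code{load_dataset()} reads the four CSV files, validates them and returns
#' a \code{kite_dataset}; \code{as_kite_dataset()} does the same for in-memory
#' data frames. Validation enforces referential integrity (every event's
#' nestlings exist in their brood), the rank invariants (exactly one S/M/J per
#' brood, hatch dates non-decreasing in rank order) and the delivery fraction
#' set \{1, 0.5, 0.25\}. Broods whose size differs from three are dropped with
#' a warning (the recipient-permutation null is defined for triads); dropped
#' and flagged rows are listed in the validation report.
#'
#' @param pecks_path,bouts_path,deliveries_path,broods_path paths to the four
#'   CSV files.
#' @param pecks,bouts,deliveries,broods the corresponding data frames.
#' @param relabel_tied_seniors if \code{TRUE}, broods whose S and M nestlings
#'   share a hatch date have the two labels reassigned at random (seeded), the
#'   preprocessing used when the two oldest nestlings are visually
#'   indistinguishable.
#' @param seed RNG seed for \code{relabel_tied_seniors}.
#' @return an object of class \code{kite_dataset}: a list with elements
#'   \code{broods}, \code{pecks}, \code{bouts}, \code{deliveries} and
#'   \code{report} (a data frame of flagged/dropped rows; zero rows when the
#'   input was fully clean).
#' @seealso [write_dataset()], [brood_day_covariates()]
#' @export
load_dataset <- function(pecks_path, bouts_path, deliveries_path, broods_path,
                         relabel_tied_seniors = FALSE, seed = NULL) {
  for (p in c(pecks_path, bouts_path, deliveries_path, broods_path)) {
    if (!file.exists(p)) kite_error(sprintf("input file not found: %s", p),
                                    "kitepeck_schema_error")
  }
  read1 <- function(path) read.csv(path, stringsAsFactors = FALSE,
                                   colClasses = "character")
  as_kite_dataset(pecks = read1(pecks_path), bouts = read1(bouts_path),
                  deliveries = read1(deliveries_path),
                  broods = read1(broods_path),
                  relabel_tied_seniors = relabel_tied_seniors, seed = seed)
}

#' @rdname load_dataset
#' @export
as_kite_dataset <- function(pecks, bouts, deliveries, broods,
                            relabel_tied_seniors = FALSE, seed = NULL) {
  report <- list()
  note <- function(table, row, reason) {
    report[[length(report) + 1L]] <<- data.frame(
      table = table, row = row, reason = reason, stringsAsFactors = FALSE)
  }

  broods <- check_columns(broods, "broods",
                          c("brood_id", "nestling_id", "hatch_date", "hatch_rank"))
  pecks <- check_columns(pecks, "pecks",
                         c("brood_id", "date", "time", "attacker_id", "recipient_id"))
  bouts <- check_columns(bouts, "bouts",
                         c("brood_id", "date", "time", "recipient_id"))
  deliveries <- check_columns(deliveries, "deliveries",
                              c("brood_id", "date", "category", "fraction",
                                "observer_mass_g"))

  broods$hatch_date <- parse_date(broods$hatch_date, "broods", "hatch_date")
  pecks$date <- parse_date(pecks$date, "pecks", "date")
  pecks$time_s <- parse_time(pecks$time, "pecks")
  bouts$date <- parse_date(bouts$date, "bouts", "date")
  bouts$time_s <- parse_time(bouts$time, "bouts")
  deliveries$date <- parse_date(deliveries$date, "deliveries", "date")

  bad_rank <- which(!broods$hatch_rank %in% KITE_RANKS)
  if (length(bad_rank))
    kite_error(sprintf("broods row %d: hatch_rank must be one of S, M, J",
                       bad_rank[1]), "kitepeck_schema_error")

  ## brood size three; others dropped with a warning
  sizes <- table(broods$brood_id)
  small <- names(sizes)[sizes != 3L]
  if (length(small)) {
    warning(sprintf("dropping %d brood(s) with size != 3: %s",
                    length(small), paste(small, collapse = ", ")))
    for (b in small) note("broods", which(broods$brood_id == b)[1],
                          sprintf("brood %s has size %d != 3 (dropped)", b, sizes[[b]]))
    keep <- !(broods$brood_id %in% small)
    broods <- broods[keep, , drop = FALSE]
    drop_events <- function(df, tab) {
      bad <- df$brood_id %in% small
      if (any(bad)) for (r in which(bad)[1])
        note(tab, r, sprintf("event in dropped brood (%d rows)", sum(bad)))
      df[!bad, , drop = FALSE]
    }
    pecks <- drop_events(pecks, "pecks")
    bouts <- drop_events(bouts, "bouts")
    deliveries <- drop_events(deliveries, "deliveries")
  }

  ## one nestling per rank per brood; hatch dates non-decreasing S <= M <= J
  for (b in unique(broods$brood_id)) {
    sub <- broods[broods$brood_id == b, ]
    if (anyDuplicated(sub$hatch_rank) || anyDuplicated(sub$nestling_id))
      kite_error(sprintf("brood %s: ranks/nestling ids must be unique", b),
                 "kitepeck_referential_error")
    hd <- sub$hatch_date[order(rank_order(sub$hatch_rank))]
    if (is.unsorted(hd))
      kite_error(sprintf("brood %s: hatch dates must be non-decreasing S <= M <= J", b),
                 "kitepeck_referential_error")
  }

  if (relabel_tied_seniors)
    broods <- relabel_tied(broods, seed)

  ## referential integrity of events
  key <- paste(broods$brood_id, broods$nestling_id)
  check_ref <- function(df, col, tab) {
    bad <- which(!paste(df$brood_id, df[[col]]) %in% key)
    if (length(bad))
      kite_error(sprintf("%s row %d: %s '%s' not found in brood '%s'",
                         tab, bad[1], col, df[[col]][bad[1]], df$brood_id[bad[1]]),
                 "kitepeck_referential_error")
  }
  if (nrow(pecks)) {
    check_ref(pecks, "attacker_id", "pecks")
    check_ref(pecks, "recipient_id", "pecks")
    self <- which(pecks$attacker_id == pecks$recipient_id)
    if (length(self))
      kite_error(sprintf("pecks row %d: attacker equals recipient ('%s')",
                         self[1], pecks$attacker_id[self[1]]),
                 "kitepeck_referential_error")
  }
  if (nrow(bouts)) check_ref(bouts, "recipient_id", "bouts")

  ## deliveries: category, fraction, observer mass
  if (nrow(deliveries)) {
    bad <- which(!deliveries$category %in% KITE_PREY_CATEGORIES)
    if (length(bad))
      kite_error(sprintf("deliveries row %d: unknown category '%s'",
                         bad[1], deliveries$category[bad[1]]),
                 "kitepeck_schema_error")
    fr <- deliveries$fraction
    blank <- is.na(fr) | fr %in% c("", "NA")
    if (any(blank)) {
      note("deliveries", which(blank)[1],
           sprintf("blank fraction defaulted to 1 (%d rows)", sum(blank)))
      fr[blank] <- "1"
    }
    frn <- suppressWarnings(as.numeric(fr))
    bad <- which(is.na(frn) | !frn %in% KITE_FRACTIONS)
    if (length(bad))
      kite_error(sprintf("deliveries row %d: fraction must be in {1, 0.5, 0.25} (got '%s')",
                         bad[1], fr[bad[1]]), "kitepeck_schema_error")
    deliveries$fraction <- frn
    om <- deliveries$observer_mass_g
    om[is.na(om) | om %in% c("", "NA")] <- NA
    omn <- suppressWarnings(as.numeric(om))
    bad <- which(!is.na(om) & (is.na(omn) | omn <= 0))
    if (length(bad))
      kite_error(sprintf("deliveries row %d: observer_mass_g must be > 0 (got '%s')",
                         bad[1], om[bad[1]]), "kitepeck_schema_error")
    deliveries$observer_mass_g <- omn
  } else {
    deliveries$fraction <- numeric(0)
    deliveries$observer_mass_g <- numeric(0)
  }

  report <- if (length(report)) do.call(rbind, report) else
    data.frame(table = character(0), row = integer(0), reason = character(0))
  structure(list(broods = broods, pecks = pecks, bouts = bouts,
                 deliveries = deliveries, report = report),
            class = "kite_dataset")
}

check_columns <- function(df, name, cols) {
  if (!is.data.frame(df))
    kite_error(sprintf("%s: expected a data frame", name), "kitepeck_schema_error")
  missing <- setdiff(cols, names(df))
  if (length(missing))
    kite_error(sprintf("%s: missing column(s): %s", name,
                       paste(missing, collapse = ", ")), "kitepeck_schema_error")
  df[, cols, drop = FALSE]
}

parse_date <- function(x, table, col) {
  if (inherits(x, "Date")) return(x)
  d <- as.Date(as.character(x), format = "%Y-%m-%d")
  bad <- which(is.na(d) & !is.na(x) & x != "")
  if (length(bad))
    kite_error(sprintf("%s row %d: cannot parse %s '%s' (expected YYYY-MM-DD)",
                       table, bad[1], col, x[bad[1]]), "kitepeck_parse_error")
  d
}

# "HH:MM:SS" -> seconds since midnight (1 s resolution)
parse_time <- function(x, table) {
  if (is.numeric(x)) return(as.integer(x))
  x <- as.character(x)
  ok <- grepl("^([01][0-9]|2[0-3]):[0-5][0-9]:[0-5][0-9]$", x)
  if (any(!ok))
    kite_error(sprintf("%s row %d: cannot parse time '%s' (expected HH:MM:SS)",
                       table, which(!ok)[1], x[which(!ok)[1]]),
               "kitepeck_parse_error")
  h <- as.integer(substr(x, 1, 2)); m <- as.integer(substr(x, 4, 5))
  s <- as.integer(substr(x, 7, 8))
  h * 3600L + m * 60L + s
}

seconds_to_time <- function(s) {
  sprintf("%02d:%02d:%02d", s %/% 3600L, (s %% 3600L) %/% 60L, s %% 60L)
}

relabel_tied <- function(broods, seed) {
  with_seed(stream_seed(seed %||% 1L, "relabel"), {
    for (b in unique(broods$brood_id)) {
      i <- which(broods$brood_id == b)
      sub <- broods[i, ]
      s <- i[sub$hatch_rank == "S"]; m <- i[sub$hatch_rank == "M"]
      if (broods$hatch_date[s] == broods$hatch_date[m] && runif(1) < 0.5) {
        broods$hatch_rank[s] <- "M"; broods$hatch_rank[m] <- "S"
      }
    }
    broods
  })
}

#' @export
print.kite_dataset <- function(x, ...) {
  cat("<kite_dataset>\n")
  cat(sprintf("  broods:     %d nestlings in %d brood(s)\n",
              nrow(x$broods), length(unique(x$broods$brood_id))))
  cat(sprintf("  pecks:      %d events\n", nrow(x$pecks)))
  cat(sprintf("  bouts:      %d events\n", nrow(x$bouts)))
  cat(sprintf("  deliveries: %d events\n", nrow(x$deliveries)))
  cat(sprintf("  validation: %d flagged row group(s)\n", nrow(x$report)))
  invisible(x)
}

#' Write a validated dataset back to CSV
#'
#' Serialises the four tables of a \code{kite_dataset} to
#' \code{pecks.csv}, \code{bouts.csv}, \code{deliveries.csv} and
#' \code{broods.csv} in \code{dir}, in the same dialect accepted by
#' [load_dataset()], plus the validation report as
#' \code{validation_report.json}. Reading the files back reproduces the
#' dataset field for field.
#'
#' @param dataset a \code{kite_dataset}.
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "kite_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name, cols) {
    df <- df[, cols, drop = FALSE]
    write.csv(df, file.path(dir, name), row.names = FALSE, quote = FALSE)
  }
  w(dataset$broods, "broods.csv",
    c("brood_id", "nestling_id", "hatch_date", "hatch_rank"))
  w(dataset$pecks, "pecks.csv",
    c("brood_id", "date", "time", "attacker_id", "recipient_id"))
  w(dataset$bouts, "bouts.csv", c("brood_id", "date", "time", "recipient_id"))
  w(dataset$deliveries, "deliveries.csv",
    c("brood_id", "date", "category", "fraction", "observer_mass_g"))
  jsonlite::write_json(dataset$report, file.path(dir, "validation_report.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(dir)
}

#' Restrict events to the daily observation window
#'
#' Keeps the events whose time of day falls in the half-open interval
#' \code{[start_time, end_time)}. The default window 08:00-14:00 is the
#' interval in which nest recordings are scored; the half-open convention
#' avoids double counting events at the boundary. The operation is
#' idempotent.
#'
#' @param events a data frame with a \code{time} (\code{HH:MM:SS}) or
#'   \code{time_s} (seconds since midnight) column, e.g. the \code{pecks} or
#'   \code{bouts} table of a \code{kite_dataset}.
#' @param start_time,end_time window bounds, \code{"HH:MM:SS"}.
#' @return the filtered data frame.
#' @export
filter_observation_window <- function(events, start_time = "08:00:00",
                                      end_time = "14:00:00") {
  s <- parse_time(start_time, "window"); e <- parse_time(end_time, "window")
  if (s >= e) kite_error("start_time must be earlier than end_time",
                         "kitepeck_argument_error")
  if (!nrow(events)) return(events)
  t <- if ("time_s" %in% names(events)) events$time_s else
    parse_time(events$time, "events")
  events[t >= s & t < e, , drop = FALSE]
}

#' Post-hatching phase of a brood-day
#'
#' The nestling period is split by the age of the junior (last-hatched)
#' nestling: phase 1 runs from its hatching until age 10 d (ages 1-10) and
#' phase 2 from age 11 to 20 d, after which aggression is rare and the
#' brood-day is excluded. Ages are integer days with hatch day = 0.
#'
#' @param age_j integer vector of junior-nestling ages in days.
#' @return character vector: \code{"1"}, \code{"2"} or \code{"excluded"}.
#' @export
assign_phase <- function(age_j) {
  out <- rep("excluded", length(age_j))
  out[!is.na(age_j) & age_j >= 1 & age_j <= 10] <- "1"
  out[!is.na(age_j) & age_j >= 11 & age_j <= 20] <- "2"
  out
}

#' Signed age difference of a directed dyad
#'
#' Defined as \code{hatch_date(attacker) - hatch_date(recipient)} in days
#' (equivalently, recipient age minus attacker age): negative when the
#' attacker is the older of the pair, positive when it is the younger, and
#' antisymmetric under swapping the two roles.
#'
#' @param attacker_hatch,recipient_hatch hatch dates (\code{Date} vectors).
#' @param attacker_brood,recipient_brood optional brood ids; if given, a
#'   mismatch raises an error.
#' @return integer vector of day differences.
#' @export
age_difference <- function(attacker_hatch, recipient_hatch,
                           attacker_brood = NULL, recipient_brood = NULL) {
  if (!is.null(attacker_brood) && !is.null(recipient_brood) &&
      any(attacker_brood != recipient_brood))
    kite_error("age_difference is only defined within a brood",
               "kitepeck_argument_error")
  as.integer(as.Date(attacker_hatch) - as.Date(recipient_hatch))
}

#' Per brood-day covariates: ages, phase and delivered biomass
#'
#' Derives one row per covered brood-day. A brood-day is covered when any
#' event (peck, feeding bout or prey delivery) was recorded for that brood on
#' that date, i.e. the nest was observed. Ages are integer days since hatching
#' (hatch day = 0); the phase is assigned from the junior nestling's age (see
#' [assign_phase()]); daily biomass is the summed per-delivery mass estimate
#' (see [daily_biomass()]), 0 g for covered days without deliveries, or
#' \code{NA} when a needed category weight is unavailable.
#'
#' @param dataset a \code{kite_dataset}.
#' @param weights a category weight table (see [read_prey_weights()]); may be
#'   \code{NULL} when every delivery carries an observer mass estimate.
#' @return a data frame with columns \code{brood_id}, \code{date},
#'   \code{age_S}, \code{age_M}, \code{age_J}, \code{phase},
#'   \code{biomass_g}.
#' @export
brood_day_covariates <- function(dataset, weights = NULL) {
  stopifnot(inherits(dataset, "kite_dataset"))
  days <- unique(rbind(
    dataset$pecks[, c("brood_id", "date")],
    dataset$bouts[, c("brood_id", "date")],
    dataset$deliveries[, c("brood_id", "date")]))
  days <- days[order(days$brood_id, days$date), , drop = FALSE]
  if (!nrow(days))
    return(data.frame(brood_id = character(0), date = as.Date(character(0)),
                      age_S = integer(0), age_M = integer(0), age_J = integer(0),
                      phase = character(0), biomass_g = numeric(0)))
  hatch <- hatch_table(dataset$broods)
  i <- match(days$brood_id, hatch$brood_id)
  days$age_S <- as.integer(days$date - hatch$hatch_S[i])
  days$age_M <- as.integer(days$date - hatch$hatch_M[i])
  days$age_J <- as.integer(days$date - hatch$hatch_J[i])
  days$phase <- assign_phase(days$age_J)
  bm <- daily_biomass(dataset$deliveries, weights = weights)
  j <- match(paste(days$brood_id, days$date), paste(bm$brood_id, bm$date))
  days$biomass_g <- ifelse(is.na(j), 0, bm$biomass_g[j])
  rownames(days) <- NULL
  days
}

# wide per-brood hatch-date/rank lookup
hatch_table <- function(broods) {
  out <- lapply(split(broods, broods$brood_id), function(sub) {
    data.frame(brood_id = sub$brood_id[1],
               hatch_S = sub$hatch_date[sub$hatch_rank == "S"],
               hatch_M = sub$hatch_date[sub$hatch_rank == "M"],
               hatch_J = sub$hatch_date[sub$hatch_rank == "J"],
               id_S = sub$nestling_id[sub$hatch_rank == "S"],
               id_M = sub$nestling_id[sub$hatch_rank == "M"],
               id_J = sub$nestling_id[sub$hatch_rank == "J"],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# map nestling ids of an event table to hatch ranks
add_ranks <- function(events, broods, cols = c("attacker_id", "recipient_id")) {
  key <- paste(broods$brood_id, broods$nestling_id)
  for (col in intersect(cols, names(events))) {
    i <- match(paste(events$brood_id, events[[col]]), key)
    events[[sub("_id$", "_rank", col)]] <- broods$hatch_rank[i]
  }
  events
}
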