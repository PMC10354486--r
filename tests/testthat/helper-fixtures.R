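# Small in-code fixtures and independent brute-force oracles used across tests.

# a hand-built brood of three: S hatched 2020-04-01, M +1 d, J +4 d
tiny_brood <- function(brood_id = "B1") {
  data.frame(brood_id = brood_id,
             nestling_id = paste0(brood_id, c("s", "m", "j")),
             hatch_date = as.Date("2020-04-01") + c(0, 1, 4),
             hatch_rank = c("S", "M", "J"), stringsAsFactors = FALSE)
}

# peck rows in the tiny brood, given attacker/recipient ranks and times
tiny_pecks <- function(attacker, recipient, time = "09:00:00",
                       date = as.Date("2020-04-10"), brood_id = "B1") {
  ids <- setNames(paste0(brood_id, c("s", "m", "j")), c("S", "M", "J"))
  data.frame(brood_id = brood_id, date = date, time = time,
             attacker_id = unname(ids[attacker]),
             recipient_id = unname(ids[recipient]), stringsAsFactors = FALSE)
}

tiny_dataset <- function(pecks = tiny_pecks("S", "M"),
                         bouts = NULL, deliveries = NULL, broods = tiny_brood()) {
  if (is.null(bouts))
    bouts <- data.frame(brood_id = broods$brood_id[1], date = as.Date("2020-04-10"),
                        time = "09:30:00", recipient_id = broods$nestling_id[1],
                        stringsAsFactors = FALSE)
  if (is.null(deliveries))
    deliveries <- data.frame(brood_id = broods$brood_id[1],
                             date = as.Date("2020-04-10"), category = "mammal",
                             fraction = 1, observer_mass_g = 40,
                             stringsAsFactors = FALSE)
  as_kite_dataset(pecks = pecks, bouts = bouts, deliveries = deliveries,
                  broods = broods)
}

# random daily directed count table for one brood-day (long format, 6 dyads)
random_count_table <- function(max_count = 30) {
  g <- kitepeck:::dyad_grid()
  data.frame(brood_id = "B1", date = as.Date("2020-04-10"),
             attacker_rank = g$attacker_rank, recipient_rank = g$recipient_rank,
             count = sample(0:max_count, 6, replace = TRUE),
             zero_day = FALSE, stringsAsFactors = FALSE)
}

## ---- independent brute-force oracles (plain loops, no package code) ----

brute_log_ratio <- function(counts, c) {
  m <- 0; j <- 0
  for (i in seq_len(nrow(counts))) {
    if (counts$recipient_rank[i] == "M") m <- m + counts$count[i]
    if (counts$recipient_rank[i] == "J") j <- j + counts$count[i]
  }
  log((m + c) / (j + c))
}

# deviation under the exact null: expected = attacker total / 2
brute_deviations <- function(counts) {
  out <- numeric(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    tot <- 0
    for (k in seq_len(nrow(counts)))
      if (counts$attacker_rank[k] == counts$attacker_rank[i])
        tot <- tot + counts$count[k]
    out[i] <- counts$count[i] - tot / 2
  }
  out
}

# first-peck rule: keep a peck iff no earlier peck of the same ordered dyad
# lies strictly within `gap` seconds before it
brute_first_peck <- function(t, dyad, gap) {
  keep <- logical(length(t))
  for (i in seq_along(t)) {
    ok <- TRUE
    for (k in seq_along(t))
      if (k != i && dyad[k] == dyad[i] &&
          (t[k] < t[i] || (t[k] == t[i] && k < i)) && t[i] - t[k] < gap)
        ok <- FALSE
    keep[i] <- ok
  }
  keep
}

# per-dyad totals and percentages over a set of peck rows
brute_dyad_pct <- function(attacker, recipient) {
  dy <- paste0(attacker, ">", recipient)
  lv <- c("S>M", "S>J", "M>S", "M>J", "J>S", "J>M")
  n <- sapply(lv, function(l) sum(dy == l))
  100 * n / sum(n)
}
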