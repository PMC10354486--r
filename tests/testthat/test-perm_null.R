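test_that("daily directed counts tabulate pecks and conserve the event total", {
  p <- tiny_pecks(c(rep("S", 12), "M", "M"), c(rep("M", 10), "J", "J", "S", "J"),
                  time = sprintf("09:%02d:00", 1:14))
  cnt <- daily_directed_counts(p, tiny_brood())
  expect_equal(nrow(cnt), 6)
  get <- function(a, r) cnt$count[cnt$attacker_rank == a & cnt$recipient_rank == r]
  expect_equal(get("S", "M"), 10L)
  expect_equal(get("S", "J"), 2L)
  expect_equal(get("M", "S"), 1L)
  expect_equal(get("M", "J"), 1L)
  expect_equal(sum(cnt$count), nrow(p))
  expect_false(any(cnt$zero_day))
  # covered day without pecks becomes a flagged all-zero record
  cov <- data.frame(brood_id = "B1", date = as.Date("2020-04-11"))
  cnt2 <- daily_directed_counts(p, tiny_brood(), covered_days = cov)
  z <- cnt2[cnt2$date == as.Date("2020-04-11"), ]
  expect_equal(sum(z$count), 0L)
  expect_true(all(z$zero_day))
  expect_equal(sum(cnt2$count), nrow(p))
})

test_that("analytic expectation is row_total/2 and deviations cancel per attacker-day", {
  cnt <- random_count_table()
  cnt$count <- c(12L, 0L, 3L, 1L, 0L, 0L)   # S: 12, M: 4, J: 0 row totals
  cnt$count[3:4] <- c(3L, 1L)
  e <- expected_counts_analytic(cnt)
  get <- function(a, r) e$expected[e$attacker_rank == a & e$recipient_rank == r]
  expect_equal(get("S", "M"), 6)
  expect_equal(get("S", "J"), 6)
  expect_equal(get("M", "S"), 2)
  expect_equal(get("M", "J"), 2)
  expect_equal(get("J", "S"), 0)
  expect_equal(get("J", "M"), 0)
  dev <- deviation_table(e, data.frame(brood_id = "B1",
                                       date = as.Date("2020-04-10"),
                                       biomass_g = 50, phase = "1"),
                         tiny_brood())
  # observed S->M = 12, S->J = 0 against 6/6: deviations +6 / -6
  expect_equal(dev$deviation[dev$attacker_rank == "S"], c(6, -6))
  for (a in c("S", "M", "J"))
    expect_equal(sum(dev$deviation[dev$attacker_rank == a]), 0)
  # age differences and sides for the S hatched +0, M +1, J +4 brood
  expect_equal(dev$delta_days[dev$attacker_rank == "S" & dev$recipient_rank == "M"], -1L)
  expect_equal(dev$delta_days[dev$attacker_rank == "J" & dev$recipient_rank == "S"], 4L)
  expect_equal(dev$side[dev$attacker_rank == "M" & dev$recipient_rank == "J"],
               "attacker_older")
})

test_that("Monte Carlo expectation is seeded, conservative and matches the oracle", {
  set.seed(77)
  cnt <- do.call(rbind, lapply(1:25, function(i) {
    x <- random_count_table(max_count = 40)
    x$date <- as.Date("2020-04-01") + i
    x
  }))
  e1 <- expected_counts_mc(cnt, n_perm = 2000, seed = 5)
  e2 <- expected_counts_mc(cnt, n_perm = 2000, seed = 5)
  expect_identical(e1$expected, e2$expected)           # determinism under seed
  # exact conservation of attacker-day totals
  key <- paste(e1$brood_id, e1$date, e1$attacker_rank)
  for (k in unique(key))
    expect_equal(sum(e1$expected[key == k]), sum(e1$count[key == k]))
  # zero rows are exactly zero
  expect_true(all(e1$expected[rep(tapply(e1$count, key, sum)[key], 1) == 0] == 0))
  # agreement with the closed form within Monte Carlo error (3 SE)
  ea <- expected_counts_analytic(cnt)
  tot <- tapply(ea$count, paste(ea$brood_id, ea$date, ea$attacker_rank), sum)[key]
  tol <- 3 * sqrt(pmax(tot, 1) / 4 / 2000)
  expect_lt(mean(abs(e1$expected - ea$expected) > tol), 0.02)
  expect_error(expected_counts_mc(cnt, n_perm = 0), class = "kitepeck_argument_error")
})

test_that("deviations are invariant to peck-event order within a day", {
  p <- tiny_pecks(sample(rep(c("S", "S", "M"), 10)),
                  sample(rep(c("M", "J", "J"), 10)),
                  time = sprintf("09:%02d:%02d", sample(0:59, 30), sample(0:59, 30)))
  cov <- data.frame(brood_id = "B1", date = as.Date("2020-04-10"),
                    biomass_g = 10, phase = "1")
  d1 <- deviation_table(expected_counts_analytic(
    daily_directed_counts(p, tiny_brood())), cov, tiny_brood())
  d2 <- deviation_table(expected_counts_analytic(
    daily_directed_counts(p[sample(nrow(p)), ], tiny_brood())), cov, tiny_brood())
  expect_equal(d1, d2)
})

test_that("bootstrap splits have exact size, differ, and are seed-reproducible", {
  p <- tiny_pecks(rep("S", 1000), rep(c("M", "J"), 500),
                  time = rep("09:00:00", 1000))
  s1 <- bootstrap_splits(p, frac = 0.8, n_boot = 5, seed = 3)
  expect_length(s1, 5)
  for (b in s1) expect_equal(nrow(b), 800)
  expect_false(identical(s1[[1]], s1[[2]]))
  s2 <- bootstrap_splits(p, frac = 0.8, n_boot = 5, seed = 3)
  expect_identical(s1, s2)
  # frac -> 1 limit returns the full data
  expect_equal(nrow(bootstrap_splits(p, frac = 1, n_boot = 1, seed = 1)[[1]]),
               1000)
  expect_error(bootstrap_splits(p[1, , drop = FALSE]),
               class = "kitepeck_argument_error")
})

test_that("first-peck filter keeps battle openers and matches brute force", {
  # worked example: same dyad at t = 0, 3, 6, 200 s with a 60 s gap
  p <- tiny_pecks(rep("S", 4), rep("M", 4),
                  time = c("09:00:00", "09:00:03", "09:00:06", "09:03:20"))
  f <- first_peck_filter(p, 60)
  expect_equal(f$time, c("09:00:00", "09:03:20"))
  # single isolated peck retained; zero gap retains everything
  expect_equal(nrow(first_peck_filter(p[1, ], 60)), 1)
  expect_equal(first_peck_filter(p, 0), p)
  expect_error(first_peck_filter(p, -1), class = "kitepeck_argument_error")
  # randomized property check against the brute-force rule
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    att <- sample(c("S", "S", "M", "J"), n, TRUE)
    rec <- vapply(att, function(a) sample(setdiff(c("S", "M", "J"), a), 1), "")
    secs <- sort(sample(28800:29200, n))
    p <- tiny_pecks(att, rec, time = kitepeck:::seconds_to_time(secs))
    gap <- sample(c(5, 30, 120), 1)
    got <- first_peck_filter(p, gap)
    keep <- brute_first_peck(secs + as.numeric(p$date) * 86400,
                             paste(p$attacker_id, p$recipient_id), gap)
    expect_equal(got, p[keep, ], ignore_attr = TRUE)
  }
})
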