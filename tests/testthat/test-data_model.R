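test_that("a well-formed dataset loads, validates cleanly and round-trips", {
  ds <- tiny_dataset(pecks = tiny_pecks(rep("S", 10), rep(c("M", "J"), 5),
                                        time = sprintf("09:%02d:00", 1:10)))
  expect_s3_class(ds, "kite_dataset")
  expect_equal(nrow(ds$pecks), 10)
  expect_equal(nrow(ds$report), 0)

  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  ds2 <- load_dataset(file.path(dir, "pecks.csv"), file.path(dir, "bouts.csv"),
                      file.path(dir, "deliveries.csv"), file.path(dir, "broods.csv"))
  for (tab in c("broods", "pecks", "bouts", "deliveries"))
    expect_equal(ds2[[tab]], ds[[tab]], ignore_attr = TRUE)
})

test_that("schema and referential violations are rejected with named errors", {
  # recipient equals attacker
  bad <- tiny_pecks("S", "S")
  expect_error(tiny_dataset(pecks = bad), "attacker equals recipient",
               class = "kitepeck_referential_error")
  # unknown nestling id
  bad <- tiny_pecks("S", "M"); bad$recipient_id <- "ghost"
  expect_error(tiny_dataset(pecks = bad), "ghost",
               class = "kitepeck_referential_error")
  # delivery fraction outside {1, 0.5, 0.25}
  del <- data.frame(brood_id = "B1", date = as.Date("2020-04-10"),
                    category = "mammal", fraction = 0.3, observer_mass_g = NA)
  expect_error(tiny_dataset(deliveries = del), "fraction must be in \\{1, 0.5, 0.25\\}",
               class = "kitepeck_schema_error")
  # missing column
  expect_error(as_kite_dataset(pecks = tiny_pecks("S", "M")[, -5],
                               bouts = tiny_dataset()$bouts,
                               deliveries = tiny_dataset()$deliveries,
                               broods = tiny_brood()),
               "recipient_id", class = "kitepeck_schema_error")
  # unparseable date
  br <- tiny_brood(); br$hatch_date <- c("2020-04-01", "bad", "2020-04-05")
  expect_error(as_kite_dataset(pecks = tiny_pecks("S", "M")[0, ],
                               bouts = tiny_dataset()$bouts[0, ],
                               deliveries = tiny_dataset()$deliveries[0, ],
                               broods = br),
               "bad", class = "kitepeck_parse_error")
})

test_that("broods of size other than three are dropped with a warning", {
  br <- rbind(tiny_brood("B1"), tiny_brood("B2")[1:2, ])
  expect_warning(
    ds <- as_kite_dataset(pecks = tiny_pecks("S", "M"),
                          bouts = tiny_dataset()$bouts[0, ],
                          deliveries = tiny_dataset()$deliveries[0, ],
                          broods = br),
    "size != 3")
  expect_equal(unique(ds$broods$brood_id), "B1")
  expect_gt(nrow(ds$report), 0)
})

test_that("tied senior/middle hatch dates can be relabelled reproducibly", {
  br <- tiny_brood()
  br$hatch_date[2] <- br$hatch_date[1]   # S and M hatch together
  mk <- function(seed) as_kite_dataset(
    pecks = tiny_pecks("S", "M")[0, ], bouts = tiny_dataset()$bouts[0, ],
    deliveries = tiny_dataset()$deliveries[0, ], broods = br,
    relabel_tied_seniors = TRUE, seed = seed)
  d1 <- mk(1); d2 <- mk(1)
  expect_identical(d1$broods, d2$broods)
  expect_setequal(d1$broods$hatch_rank, c("S", "M", "J"))
  # over many seeds both assignments occur
  labs <- vapply(1:30, function(s)
    mk(s)$broods$hatch_rank[mk(s)$broods$nestling_id == "B1s"], "")
  expect_setequal(unique(labs), c("S", "M"))
  # untied broods are never relabelled
  d3 <- as_kite_dataset(pecks = tiny_pecks("S", "M")[0, ],
                        bouts = tiny_dataset()$bouts[0, ],
                        deliveries = tiny_dataset()$deliveries[0, ],
                        broods = tiny_brood(),
                        relabel_tied_seniors = TRUE, seed = 1)
  expect_identical(d3$broods, tiny_dataset()$broods)
})

test_that("observation window is half-open, idempotent and empty-safe", {
  p <- tiny_pecks(rep("S", 4), rep("M", 4),
                  time = c("07:59:59", "08:00:00", "13:59:59", "14:00:00"))
  f <- filter_observation_window(p)
  expect_equal(f$time, c("08:00:00", "13:59:59"))
  expect_equal(filter_observation_window(f), f)      # idempotent
  expect_equal(nrow(filter_observation_window(p[0, ])), 0)
  expect_error(filter_observation_window(p, "14:00:00", "08:00:00"),
               class = "kitepeck_argument_error")
})

test_that("phase assignment partitions junior ages into excluded/1/2/excluded", {
  expect_equal(assign_phase(5), "1")
  expect_equal(assign_phase(15), "2")
  expect_equal(assign_phase(c(0, 10, 11, 20, 21, -3)),
               c("excluded", "1", "2", "2", "excluded", "excluded"))
  # contiguous blocks over a 30-day range
  ph <- assign_phase(-4:25)
  runs <- rle(ph)$values
  expect_equal(runs, c("excluded", "1", "2", "excluded"))
})

test_that("age difference follows the sign convention and is antisymmetric", {
  h0 <- as.Date("2020-04-01")
  expect_equal(age_difference(h0, h0 + 3), -3L)    # attacker older
  expect_equal(age_difference(h0, h0), 0L)
  expect_equal(age_difference(h0 + 4, h0), 4L)     # attacker younger
  expect_error(age_difference(h0, h0, "B1", "B2"),
               class = "kitepeck_argument_error")
  # antisymmetry over all pairs of a generated brood
  br <- generate_brood(make_scenario(), seed = 42)
  for (i in 1:3) for (j in 1:3)
    expect_equal(age_difference(br$hatch_date[i], br$hatch_date[j]),
                 -age_difference(br$hatch_date[j], br$hatch_date[i]))
})

test_that("brood-day covariates carry ages, phase and biomass per covered day", {
  ds <- tiny_dataset()
  cov <- brood_day_covariates(ds)
  expect_equal(nrow(cov), 1)
  # 2020-04-10: S hatched 04-01 (age 9), M 04-02 (8), J 04-05 (5)
  expect_equal(cov$age_S, 9L)
  expect_equal(cov$age_M, 8L)
  expect_equal(cov$age_J, 5L)
  expect_equal(cov$phase, "1")
  expect_equal(cov$biomass_g, 40)
})
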