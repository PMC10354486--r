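# feeding bouts with recipients drawn from fixed or covariate-driven shares
make_bouts <- function(n_days = 60, per_day = 60, share = function(b) c(1, 1, 1) / 3,
                       broods = c("A1", "A2"), biomass = function(n) runif(n, 20, 150),
                       seed = 1) {
  set.seed(seed)
  rows <- list()
  for (br in broods) for (d in seq_len(n_days)) {
    b <- biomass(1)
    s <- share(b)
    n <- rpois(1, per_day)
    if (!n) next
    rows[[length(rows) + 1L]] <- data.frame(
      brood_id = br, date = as.Date("2020-04-01") + d,
      recipient_rank = sample(c("S", "M", "J"), n, TRUE, prob = s),
      biomass_g = b)
  }
  bouts <- do.call(rbind, rows)
  cov <- unique(bouts[, c("brood_id", "date", "biomass_g")])
  cov$age_S <- as.integer(cov$date - as.Date("2020-04-01"))  %% 20 + 1L
  ratios <- data.frame(brood_id = cov$brood_id, date = cov$date,
                       log_ratio = rnorm(nrow(cov), 0, 0.5))
  list(bouts = bouts, cov = cov, ratios = ratios)
}

test_that("daily peck log-ratio matches direct arithmetic and handles zeros", {
  cnt <- random_count_table()
  cnt$count <- c(6L, 1L, 2L, 1L, 1L, 4L)  # received M = 6+4, J = 1+1
  r <- daily_peck_log_ratio(cnt, c = 0.5)
  expect_equal(r$received_M, 10L)
  expect_equal(r$received_J, 2L)
  expect_equal(r$log_ratio, log(10.5 / 2.5))
  # symmetric day -> 0; all-zero day -> 0
  cnt$count <- c(5L, 5L, 0L, 0L, 0L, 0L)
  expect_equal(daily_peck_log_ratio(cnt, 0.5)$log_ratio, 0)
  cnt$count <- rep(0L, 6)
  expect_equal(daily_peck_log_ratio(cnt, 0.5)$log_ratio, 0)
  # worked value: 20 vs 2 with c = 0.5
  cnt$count <- c(20L, 2L, 0L, 0L, 0L, 0L)
  expect_equal(daily_peck_log_ratio(cnt, 0.5)$log_ratio, log(20.5 / 2.5),
               tolerance = 1e-12)
  expect_equal(round(daily_peck_log_ratio(cnt, 0.5)$log_ratio, 3), 2.104)
  # with no zero received totals c = 0 is allowed; with zeros it errors
  expect_equal(daily_peck_log_ratio(cnt, 0)$log_ratio, log(20 / 2))
  cnt$count <- c(20L, 0L, 0L, 0L, 0L, 0L)
  expect_error(daily_peck_log_ratio(cnt, c = 0), "c > 0",
               class = "kitepeck_argument_error")
  expect_error(daily_peck_log_ratio(cnt, c = -1), class = "kitepeck_argument_error")
})

test_that("null-effect bouts give near-uniform predicted shares everywhere", {
  mb <- make_bouts(share = function(b) c(1, 1, 1) / 3)
  fit <- fit_allocation_model(mb$bouts, mb$cov, mb$ratios)
  # in-sample mean predicted share matches observed share closely
  obs <- as.numeric(fit$observed_shares)
  sh <- predict_allocation_shares(fit)
  for (g in sh) {
    expect_true(all(abs(g$share_S + g$share_M + g$share_J - 1) < 1e-9))
    expect_true(all(abs(g$share_S - obs[1]) < 0.05))
    expect_true(all(abs(g$share_J - obs[3]) < 0.05))
  }
  expect_true(all(abs(obs - 1 / 3) < 0.02))
})

test_that("a junior share rising with biomass is recovered monotonically", {
  share <- function(b) {
    j <- 0.10 + 0.25 * stats::plogis((b - 85) / 20)
    c(0.55 * (1 - j), 0.45 * (1 - j), j)
  }
  mb <- make_bouts(share = share, seed = 2)
  fit <- fit_allocation_model(mb$bouts, mb$cov, mb$ratios)
  sh <- predict_allocation_shares(fit,
                                  biomass_grid = c(25, 140))
  expect_gt(sh$share_J[2], sh$share_J[1])
  truth <- t(vapply(c(25, 140), share, numeric(3)))
  expect_lt(mean(abs(as.matrix(sh[, c("share_S", "share_M", "share_J")]) - truth)),
            0.05)
})

test_that("broods with opposite baseline skews get opposite random intercepts", {
  share_a <- c(0.25, 0.55, 0.20)   # M-heavy
  share_b <- c(0.55, 0.25, 0.20)   # S-heavy
  mb <- make_bouts(broods = "A1", share = function(b) share_a, seed = 3)
  mb2 <- make_bouts(broods = "A2", share = function(b) share_b, seed = 4)
  bouts <- rbind(mb$bouts, mb2$bouts)
  cov <- rbind(mb$cov, mb2$cov)
  ratios <- rbind(mb$ratios, mb2$ratios)
  fit <- fit_allocation_model(bouts, cov, ratios)
  re <- stats::coef(fit$model)
  re_m <- re[grep("^s\\(brood_id\\)", names(re))]   # M-vs-S logit intercepts
  expect_equal(length(re_m), 2L)
  expect_gt(re_m[1], 0)   # A1 favours M relative to S
  expect_lt(re_m[2], 0)   # A2 the opposite
  # a category never fed is a named fit error
  bad <- bouts[bouts$recipient_rank != "J", ]
  expect_error(fit_allocation_model(bad, cov, ratios), "J",
               class = "kitepeck_fit_error")
})

test_that("permuting category labels permutes the predicted shares", {
  mb <- make_bouts(share = function(b) c(0.5, 0.3, 0.2), seed = 5)
  fit <- fit_allocation_model(mb$bouts, mb$cov, mb$ratios)
  swapped <- mb$bouts
  swapped$recipient_rank <- c(S = "S", M = "J", J = "M")[swapped$recipient_rank]
  fit2 <- fit_allocation_model(swapped, mb$cov, mb$ratios)
  g <- seq(30, 140, length.out = 5)
  p1 <- predict_allocation_shares(fit, biomass_grid = g)
  p2 <- predict_allocation_shares(fit2, biomass_grid = g)
  expect_equal(p1$share_S, p2$share_S, tolerance = 0.01)
  expect_equal(p1$share_M, p2$share_J, tolerance = 0.01)
  expect_equal(p1$share_J, p2$share_M, tolerance = 0.01)
})

test_that("posterior-approximation bands bracket the point shares", {
  mb <- make_bouts(n_days = 30, seed = 7)
  fit <- fit_allocation_model(mb$bouts, mb$cov, mb$ratios)
  g <- seq(30, 140, length.out = 8)
  sh <- predict_allocation_shares(fit, biomass_grid = g, n_sim = 200, seed = 1)
  for (k in c("S", "M", "J")) {
    expect_true(all(sh[[paste0("lo95_", k)]] <= sh[[paste0("share_", k)]] + 1e-9))
    expect_true(all(sh[[paste0("share_", k)]] <= sh[[paste0("hi95_", k)]] + 1e-9))
    expect_true(all(sh[[paste0("lo95_", k)]] >= 0 & sh[[paste0("hi95_", k)]] <= 1))
  }
  sh2 <- predict_allocation_shares(fit, biomass_grid = g, n_sim = 200, seed = 1)
  expect_identical(sh, sh2)
  # n_sim = 0 skips the bands
  expect_false("lo95_S" %in% names(predict_allocation_shares(fit, biomass_grid = g)))
})

test_that("extrapolation beyond the observed covariate range warns", {
  mb <- make_bouts(seed = 6)
  fit <- fit_allocation_model(mb$bouts, mb$cov, mb$ratios)
  expect_warning(predict_allocation_shares(fit, biomass_grid = c(50, 1e4)),
                 "extrapolation")
})
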