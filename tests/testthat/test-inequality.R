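iw <- desk_world(seed = 201, nrow = 6, ncol = 6, years = 2000:2002,
                 n_covariates = 2)
it <- desk_truth(iw, seed = 202, beta = c(0.4, -0.4))
id <- jitter_draws(iw, it, n_draws = 20, seed = 203)

test_that("a uniform rate aggregates to that rate at every level", {
  d <- as_prev_draws(array(0.07, c(36, 3, 4)), iw)
  for (lev in 0:2) {
    a <- aggregate_draws(d, iw, lev)
    expect_true(all(abs(a$summary$mean - 0.07) < 1e-12))
    expect_true(all(abs(a$rate_draws - 0.07) < 1e-12))
  }
})

test_that("unit rates are population-weighted cell means", {
  w <- desk_world(seed = 204, nrow = 2, ncol = 1, n_countries = 1,
                  admin1_per_country = 1, admin2_per_admin1 = 1,
                  years = 2000, n_covariates = 1)
  w$population[, 1] <- c(100, 300)
  arr <- array(c(0.1, 0.3), c(2, 1, 2))
  a <- aggregate_draws(as_prev_draws(arr, w), w, 2)
  expect_equal(a$summary$mean, 0.25, tolerance = 1e-12)
  expect_equal(a$summary$count_mean, 0.1 * 100 + 0.3 * 300,
               tolerance = 1e-12)
})

test_that("uncertainty intervals use linear-interpolation percentiles", {
  w <- desk_world(seed = 205, nrow = 1, ncol = 1, n_countries = 1,
                  admin1_per_country = 1, admin2_per_admin1 = 1,
                  years = 2000, n_covariates = 1)
  arr <- array(1:250, c(1, 1, 250))
  a <- aggregate_draws(as_prev_draws(arr, w, measure = "incidence"), w, 0)
  expect_equal(a$summary$lower, 7.225, tolerance = 1e-12)
  expect_equal(a$summary$upper, 243.775, tolerance = 1e-12)
})

test_that("admin counts are conserved up the hierarchy per draw", {
  for (lev in c(2L, 1L)) {
    a_lo <- aggregate_draws(id, iw, lev)
    a_hi <- aggregate_draws(id, iw, lev - 1L)
    units <- iw$admin$units
    parent <- units$parent_id[match(dimnames(a_lo$count_draws)[[1]],
                                    units$id)]
    for (yi in 1:3) {
      summed <- rowsum(a_lo$count_draws[, yi, ], parent)
      top <- a_hi$count_draws[rownames(summed), yi, ]
      expect_lt(max(abs(summed - top) / pmax(abs(top), 1e-300)), 1e-8)
    }
  }
})

test_that("deviations reproduce the printed worked example", {
  # a unit at 6.3 cases per child-year against a 4.0 national average
  w <- desk_world(seed = 206, nrow = 2, ncol = 1, n_countries = 1,
                  admin1_per_country = 1, admin2_per_admin1 = 1,
                  years = 2000, n_covariates = 1)
  w$admin$cell_admin2 <- c("A2_1", "A2_2")
  w$admin$units <- rbind(w$admin$units,
                         data.frame(id = "A2_2", level = 2L,
                                    parent_id = "A1_1"))
  w$population[, 1] <- c(100, 100)
  arr <- array(c(6.3, 1.7), c(2, 1, 3))  # national mean 4.0
  d <- as_prev_draws(arr, w, measure = "incidence")
  dev <- deviations(aggregate_draws(d, w, 2), aggregate_draws(d, w, 0), w)
  row <- dev$summary[dev$summary$unit == "A2_1", ]
  expect_equal(row$absolute, 2.3, tolerance = 1e-12)
  expect_equal(row$ratio, 6.3 / 4.0, tolerance = 1e-12)
  # relative deviation in percent, e.g. 0.80 vs 0.437 -> +83.1%
  expect_equal(100 * (0.80 / 0.437 - 1), 83.1, tolerance = 0.05)
})

test_that("a unit equal to its country has zero deviation", {
  d <- as_prev_draws(array(0.12, c(36, 3, 4)), iw)
  dev <- deviations(aggregate_draws(d, iw, 2), aggregate_draws(d, iw, 0),
                    iw)
  expect_true(all(abs(dev$summary$absolute) < 1e-12))
  expect_true(all(abs(dev$summary$ratio - 1) < 1e-12))
  expect_true(all(abs(dev$summary$relative_pct) < 1e-9))
})

test_that("gini matches its closed forms and the brute-force oracle", {
  expect_equal(gini(rep(3, 5), rep(1, 5)), 0)
  expect_equal(gini(c(0, 1), c(1, 1)), 0.5)
  expect_equal(gini(c(0, 5), c(2, 2)), 0.5)
  set.seed(31)
  for (i in 1:100) {
    n <- sample(3:50, 1)
    x <- rexp(n); p <- runif(n, 0.1, 10)
    w <- p / sum(p)
    mu <- sum(w * x)
    brute <- sum(outer(w, w) * abs(outer(x, x, "-"))) / (2 * mu)
    expect_equal(gini(x, p), brute, tolerance = 1e-12)
  }
})

test_that("gini is scale-invariant and bounded by (n-1)/n", {
  set.seed(32)
  x <- rgamma(12, 0.5); p <- runif(12)
  expect_equal(gini(3.7 * x, p), gini(x, p), tolerance = 1e-12)
  n <- 8
  extreme <- c(rep(0, n - 1), 1)
  expect_lte(gini(extreme, rep(1, n)), (n - 1) / n + 1e-12)
  expect_equal(gini(extreme, rep(1, n)), (n - 1) / n, tolerance = 1e-12)
  expect_error(gini(c(-1, 2), c(1, 1)), "non-negative")
  expect_equal(gini(c(0, 0), c(1, 1)), 0)
})

test_that("trend classification follows the annualised-change formula", {
  w <- desk_world(seed = 207, nrow = 2, ncol = 1, n_countries = 1,
                  admin1_per_country = 1, admin2_per_admin1 = 1,
                  years = c(2000, 2017), n_covariates = 1)
  w$admin$cell_admin2 <- c("A2_1", "A2_2")
  w$admin$units <- rbind(w$admin$units,
                         data.frame(id = "A2_2", level = 2L,
                                    parent_id = "A1_1"))
  arr <- array(NA_real_, c(2, 2, 3))
  arr[1, , ] <- 0.4                     # constant unit
  arr[2, 1, ] <- 0.4; arr[2, 2, ] <- 0.2  # halves over 17 years
  d <- as_prev_draws(arr, w, measure = "mortality")
  a <- aggregate_draws(d, w, 2)
  ch <- classify_change(a, 2000, 2017, threshold = 0.10)
  u <- ch$units
  expect_equal(u$mean_change[u$unit == "A2_1"], 0, tolerance = 1e-12)
  expect_equal(u$mean_change[u$unit == "A2_2"], 0.5^(1 / 17) - 1,
               tolerance = 1e-12)
  expect_equal(round(100 * u$mean_change[u$unit == "A2_2"], 2), -4.00)
  expect_equal(u$class, c("no decline", "no decline"))
  # total mode agrees in sign (changes below 1e-12 count as zero)
  cht <- classify_change(a, 2000, 2017, mode = "total")
  zsign <- function(x) sign(x) * (abs(x) > 1e-12)
  expect_true(all(zsign(cht$units$mean_change) == zsign(u$mean_change)))
})

test_that("share of declining units has a degenerate UI when unanimous", {
  w <- desk_world(seed = 208, nrow = 2, ncol = 1, n_countries = 1,
                  admin1_per_country = 1, admin2_per_admin1 = 1,
                  years = c(2000, 2001), n_covariates = 1)
  w$admin$cell_admin2 <- c("A2_1", "A2_2")
  w$admin$units <- rbind(w$admin$units,
                         data.frame(id = "A2_2", level = 2L,
                                    parent_id = "A1_1"))
  arr <- array(NA_real_, c(2, 2, 4))
  arr[, 1, ] <- 0.5
  arr[, 2, ] <- 0.5 * (1 - 0.12)
  d <- as_prev_draws(arr, w, measure = "mortality")
  ch <- classify_change(aggregate_draws(d, w, 2), 2000, 2001,
                        threshold = 0.10)
  expect_equal(unname(ch$share_declining), c(1, 1, 1))
  expect_equal(ch$units$class, c("declined", "declined"))
})

test_that("zero baselines are excluded with a count", {
  w <- desk_world(seed = 209, nrow = 2, ncol = 1, n_countries = 1,
                  admin1_per_country = 1, admin2_per_admin1 = 1,
                  years = c(2000, 2001), n_covariates = 1)
  w$admin$cell_admin2 <- c("A2_1", "A2_2")
  w$admin$units <- rbind(w$admin$units,
                         data.frame(id = "A2_2", level = 2L,
                                    parent_id = "A1_1"))
  arr <- array(0.3, c(2, 2, 3))
  arr[2, 1, ] <- 0
  d <- as_prev_draws(arr, w, measure = "mortality")
  ch <- classify_change(aggregate_draws(d, w, 2), 2000, 2001)
  expect_equal(ch$n_excluded, 3L)
})

test_that("top-risk units accumulate the requested population share", {
  w <- desk_world(seed = 210, nrow = 10, ncol = 1, n_countries = 1,
                  admin1_per_country = 1, admin2_per_admin1 = 1,
                  years = 2000, n_covariates = 1)
  w$admin$cell_admin2 <- paste0("A2_", 1:10)
  extra <- data.frame(id = paste0("A2_", 2:10), level = 2L,
                      parent_id = "A1_1")
  w$admin$units <- rbind(w$admin$units, extra)
  w$population[, 1] <- rep(100, 10)
  arr <- array(seq(0.01, 0.10, by = 0.01), c(10, 1, 2))
  a <- aggregate_draws(as_prev_draws(arr, w, measure = "mortality"), w, 2)
  top <- top_risk_units(a, 2000, fraction = 0.2)
  expect_equal(top$unit, c("A2_10", "A2_9"))   # top 2 by rate
  all_u <- top_risk_units(a, 2000, fraction = 1.0)
  expect_equal(nrow(all_u), 10L)
  one <- top_risk_units(a, 2000, fraction = 0.05)
  expect_equal(one$unit, "A2_10")              # boundary unit included
  expect_error(top_risk_units(a, 2000, fraction = 0), "fraction")
})
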