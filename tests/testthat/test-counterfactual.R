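# a small world with hand-set exposures for controlled scenarios
cf_world <- desk_world(seed = 301, nrow = 4, ncol = 4, n_countries = 1,
                       admin1_per_country = 1, admin2_per_admin1 = 2,
                       years = c(2000, 2017), n_covariates = 1)

make_rf <- function(name, group, rr, x2000, x2017, world = cf_world) {
  ncell <- world$grid$nrow * world$grid$ncol
  expo <- cbind(rep(x2000, ncell), rep(x2017, ncell))
  colnames(expo) <- as.character(world$years)
  structure(list(name = name, group = group, rr = rr, exposure = expo),
            class = "risk_factor")
}

make_mort <- function(rate, n_draws = 4, world = cf_world) {
  ncell <- world$grid$nrow * world$grid$ncol
  as_prev_draws(array(rate, c(ncell, 2, n_draws)), world,
                measure = "mortality")
}

test_that("the exposure scalar follows 1 + x(rr - 1)", {
  expect_equal(exposure_scalar(0, 2.0), 1)
  expect_equal(exposure_scalar(0.7, 1.0), 1)
  expect_equal(exposure_scalar(0.4, 2.0), 1.4, tolerance = 1e-15)
  expect_error(exposure_scalar(1.2, 2), "\\[0, 1\\]")
  expect_error(exposure_scalar(0.5, 0), "positive")
})

test_that("unchanged exposures avert nothing", {
  rfs <- list(make_rf("a", "protect", 2, 0.5, 0.5),
              make_rf("b", "prevent", 1.5, 0.3, 0.3))
  res <- averted_deaths(make_mort(0.004), cf_world, rfs)
  expect_true(all(abs(res$units$averted_mean) < 1e-10))
  expect_equal(unname(res$totals["averted"]), 0, tolerance = 1e-10)
})

test_that("a single risk factor matches the hand-computed s-ratio", {
  # x: 0.5 -> 0.25 at rr = 2 scales deaths by 1.5/1.25
  rf <- list(make_rf("a", "protect", 2, 0.5, 0.25))
  # choose a mortality rate so total observed deaths are ~1000: rate r with
  # sum(pop) * r = 1000
  rate <- 1000 / sum(cf_world$population[, 2])
  res <- averted_deaths(make_mort(rate), cf_world, rf)
  expect_equal(unname(res$totals["observed"]), 1000, tolerance = 1e-9)
  expect_equal(unname(res$totals["averted"]), 1000 * (1.5 / 1.25 - 1),
               tolerance = 1e-9)
  expect_equal(unname(res$totals["averted"]), 200, tolerance = 1e-6)
})

test_that("two risks combine multiplicatively, matching a brute-force oracle", {
  rf <- list(make_rf("a", "protect", 2.0, 0.5, 0.25),
             make_rf("b", "prevent", 1.4, 0.5, 0.25))
  rate <- 1000 / sum(cf_world$population[, 2])
  res <- averted_deaths(make_mort(rate), cf_world, rf)
  # brute-force product over factors, per cell
  s <- function(x, rr) 1 + x * (rr - 1)
  factor_comb <- (s(0.5, 2) / s(0.25, 2)) * (s(0.5, 1.4) / s(0.25, 1.4))
  expect_equal(unname(res$totals["averted"]), 1000 * (factor_comb - 1),
               tolerance = 1e-9)
  # single-group components
  expect_equal(unname(res$totals["averted_cgf"]),
               1000 * (s(0.5, 2) / s(0.25, 2) - 1), tolerance = 1e-9)
  expect_equal(unname(res$totals["averted_wash"]),
               1000 * (s(0.5, 1.4) / s(0.25, 1.4) - 1), tolerance = 1e-9)
  # combined exceeds each component but not their naive sum plus interaction
  expect_gt(res$totals["averted"],
            max(res$totals["averted_cgf"], res$totals["averted_wash"]))
})

test_that("swapping the two exposure years negates a single risk's averted count", {
  rf_fwd <- list(make_rf("a", "protect", 2, 0.5, 0.25))
  rf_rev <- list(make_rf("a", "protect", 2, 0.25, 0.5))
  rate <- 0.002
  fwd <- averted_deaths(make_mort(rate), cf_world, rf_fwd)
  # reversing the exposure trajectory changes the sign of the per-cell
  # scale factor's deviation from one: s0/s1 vs s1/s0
  rev <- averted_deaths(make_mort(rate), cf_world, rf_rev)
  s0 <- 1 + 0.5 * 1; s1 <- 1 + 0.25 * 1
  expect_equal(unname(fwd$totals["averted"]) /
                 unname(rev$totals["averted"]),
               (s0 / s1 - 1) / (s1 / s0 - 1), tolerance = 1e-9)
  expect_lt(rev$totals["averted"], 0)
})

test_that("averted deaths grow with the risk ratio", {
  rate <- 0.002
  prev_val <- -Inf
  for (rr in c(1.2, 1.6, 2.0, 3.0)) {
    res <- averted_deaths(make_mort(rate), cf_world,
                          list(make_rf("a", "protect", rr, 0.5, 0.25)))
    expect_gt(res$totals["averted"], prev_val)
    prev_val <- res$totals["averted"]
  }
})

test_that("small changes agree with the first-order linearization", {
  rate <- 0.002
  dx <- 0.01
  rr <- 1.02
  res <- averted_deaths(make_mort(rate), cf_world,
                        list(make_rf("a", "protect", rr, 0.05 + dx, 0.05)))
  obs <- unname(res$totals["observed"])
  linear <- obs * (rr - 1) * dx
  expect_equal(unname(res$totals["averted"]), linear, tolerance = 0.01)
})

test_that("treat-group factors are excluded unless requested", {
  rf <- list(make_rf("ors", "treat", 1.5, 0.8, 0.4),
             make_rf("a", "protect", 2, 0.5, 0.5))
  res <- averted_deaths(make_mort(0.002), cf_world, rf)
  expect_equal(unname(res$totals["averted"]), 0, tolerance = 1e-10)
  res_t <- averted_deaths(make_mort(0.002), cf_world, rf,
                          include_treat = TRUE)
  expect_gt(res_t$totals["averted"], 0)
})

test_that("attributable fractions follow 1 - 1/prod(s)", {
  expect_equal(attributable_fraction(
    list(make_rf("a", "protect", 4, 1, 1)), cf_world, 2017)$range[["max"]],
    0.75, tolerance = 1e-12)
  expect_equal(attributable_fraction(
    list(make_rf("a", "protect", 2, 0, 0)), cf_world, 2017)$range[["max"]],
    0, tolerance = 1e-12)
  # two risks with s = 2.0 and 1.25 -> PAF = 1 - 1/2.5 = 0.6
  two <- attributable_fraction(
    list(make_rf("a", "protect", 2, 1, 1),
         make_rf("b", "prevent", 1.25, 1, 1)), cf_world, 2017)
  expect_equal(unname(two$range), c(0.6, 0.6), tolerance = 1e-12)
  expect_true(all(two$cells >= 0 & two$cells < 1))
  expect_warning(attributable_fraction(
    list(make_rf("a", "protect", 0.8, 0.5, 0.5)), cf_world, 2017),
    "negative")
})

test_that("dominant drivers follow the dominance-share rule", {
  expect_equal(dominant_driver(90, 10, 100), "WASH")
  expect_equal(dominant_driver(10, 90, 100), "CGF")
  expect_equal(dominant_driver(50, 50, 100), "none")     # tie
  expect_equal(dominant_driver(30, 30, 100), "none")     # neither dominant
  expect_equal(dominant_driver(90, 10, -5), "none")      # no net reduction
  expect_equal(dominant_driver(c(90, 10), c(10, 90), c(100, 100)),
               c("WASH", "CGF"))
})
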