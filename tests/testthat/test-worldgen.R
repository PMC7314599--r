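test_that("degenerate 1x1 world has a single cell owned by one unit chain", {
  w <- generate_world(world_config(nrow = 1, ncol = 1, n_countries = 1,
                                   admin1_per_country = 1,
                                   admin2_per_admin1 = 1,
                                   years = 2000, n_covariates = 1), 1)
  expect_equal(nrow(w$admin$units), 3L)  # one unit per level
  expect_equal(w$admin$cell_admin2, "A2_1")
  expect_equal(w$admin$cell_country, "C1")
  expect_equal(dim(w$population), c(1L, 1L))
})

test_that("identical (config, seed) reproduce identical worlds and truths", {
  cfg <- world_config(nrow = 6, ncol = 6, years = 2000:2002,
                      n_covariates = 3)
  expect_identical(generate_world(cfg, 5), generate_world(cfg, 5))
  w <- generate_world(cfg, 5)
  expect_identical(simulate_truth(w, truth_params(), 9),
                   simulate_truth(w, truth_params(), 9))
  tr <- desk_truth(w)
  expect_identical(simulate_surveys(w, tr, survey_design(n_sources = 5), 3),
                   simulate_surveys(w, tr, survey_design(n_sources = 5), 3))
})

test_that("admin2 units partition the grid exactly", {
  w <- generate_world(world_config(nrow = 40, ncol = 40, n_countries = 3,
                                   admin1_per_country = 2,
                                   admin2_per_admin1 = 2,
                                   years = 2000, n_covariates = 1), 3)
  memb <- table(w$admin$cell_admin2)
  expect_equal(length(memb), 12L)              # 3 countries x 4 admin2
  expect_equal(sum(memb), 1600L)               # every cell exactly once
  # parent chains reach exactly one country
  ct <- cell_table(w)
  units <- w$admin$units
  for (a2 in unique(ct$admin2)) {
    a1 <- units$parent_id[match(a2, units$id)]
    co <- units$parent_id[match(a1, units$id)]
    expect_true(co %in% units$id[units$level == 0])
    expect_equal(unique(ct$country[ct$admin2 == a2]), co)
  }
})

test_that("invalid world configurations are rejected", {
  expect_error(world_config(nrow = 0), "positive")
  expect_error(world_config(n_countries = 0), "positive")
  expect_error(world_config(ncol = 2, n_countries = 3), "fewer columns")
})

test_that("zero-signal truth is exactly one half everywhere", {
  w <- desk_world(nrow = 4, ncol = 4, n_countries = 1, years = 2000:2001,
                  n_covariates = 2)
  tr <- simulate_truth(w, truth_params(beta = 0, intercept = 0,
                                       spatial_sd = 0, nugget_sd = 0), 1)
  expect_equal(unname(tr$prevalence),
               matrix(0.5, 16, 2), tolerance = 1e-15)
})

test_that("intercept-only truth matches the inverse logit", {
  w <- desk_world(nrow = 3, ncol = 3, n_countries = 1, years = 2000,
                  n_covariates = 1)
  tr <- simulate_truth(w, truth_params(beta = 0, intercept = -2.944,
                                       spatial_sd = 0, nugget_sd = 0), 1)
  expect_true(all(abs(tr$prevalence - 0.050) < 1e-3))
})

test_that("truth parameters are validated", {
  expect_error(truth_params(temporal_rho = 1), "strictly")
  expect_error(truth_params(spatial_sd = -1), "non-negative")
  expect_error(truth_params(spatial_range = 0), "positive")
})

test_that("GP realizations have the specified marginal variance", {
  w <- desk_world(nrow = 8, ncol = 8, n_countries = 1, years = 2000,
                  n_covariates = 1)
  fields <- vapply(1:500, function(i) {
    tr <- simulate_truth(w, truth_params(beta = 0, intercept = 0,
                                         spatial_range = 8, spatial_sd = 1,
                                         nugget_sd = 0), seed = i)
    tr$gp[, 1]
  }, numeric(64))
  v <- mean(apply(fields, 1, var))
  expect_gt(v, 0.85)
  expect_lt(v, 1.15)
})

test_that("spatial correlation decays below 0.2 beyond three ranges", {
  w <- desk_world(nrow = 12, ncol = 12, n_countries = 1, years = 2000,
                  n_covariates = 1)
  rng <- 2
  fields <- vapply(1:120, function(i) {
    tr <- simulate_truth(w, truth_params(beta = 0, intercept = 0,
                                         spatial_range = rng,
                                         spatial_sd = 1, nugget_sd = 0),
                         seed = 1000 + i)
    tr$gp[, 1]
  }, numeric(144))
  ct <- cell_table(w)
  d <- as.matrix(dist(cbind(ct$row, ct$col)))
  C <- cor(t(fields))
  far <- d > 3 * rng
  expect_lt(mean(C[far]), 0.2)
  near <- d > 0 & d <= 1
  expect_gt(mean(C[near]), 0.5)   # and decays from high short-range values
})

test_that("surveys with zero-prevalence truth record zero cases", {
  w <- desk_world(nrow = 4, ncol = 4, n_countries = 1, years = 2000:2001,
                  n_covariates = 1)
  tr <- flat_truth(w, 1e-12)
  sv <- simulate_surveys(w, tr, survey_design(n_sources = 5,
                                              clusters_per_source = 20), 2)
  expect_true(all(sv$n_cases == 0))
})

test_that("pooled cluster prevalence concentrates at the truth", {
  w <- desk_world(nrow = 6, ncol = 6, n_countries = 1, years = 2000,
                  n_covariates = 1)
  tr <- flat_truth(w, 0.2)
  sv <- simulate_surveys(w, tr,
                         survey_design(n_sources = 20,
                                       clusters_per_source = 500,
                                       children_per_cluster = 20), 11)
  frac <- sum(sv$n_cases) / sum(sv$n_children)
  expect_gte(frac, 0.195)
  expect_lte(frac, 0.205)
})

test_that("pooled prevalence converges to the population-weighted mean", {
  # law-of-large-numbers check on a heterogeneous truth, >= 2e5 children
  w <- desk_world(nrow = 6, ncol = 6, n_countries = 1, years = 2000,
                  n_covariates = 2)
  tr <- desk_truth(w, seed = 3, beta = c(0.4, -0.4), nugget_sd = 0.2)
  sv <- simulate_surveys(w, tr,
                         survey_design(n_sources = 10,
                                       clusters_per_source = 1200,
                                       children_per_cluster = 20,
                                       polygon_fraction = 0), 13)
  expect_gte(sum(sv$n_children), 2e5)
  target <- weighted.mean(tr$prevalence[, 1], w$population[, 1])
  frac <- sum(sv$n_cases) / sum(sv$n_children)
  expect_lt(abs(frac - target) / target, 0.01)
})

test_that("polygon records sample at the population-weighted mean prevalence", {
  w <- desk_world(nrow = 2, ncol = 1, n_countries = 1,
                  admin1_per_country = 1, admin2_per_admin1 = 1,
                  years = 2000, n_covariates = 1)
  w$population[] <- 100                      # equal population
  tr <- flat_truth(w, 0.5)
  tr$prevalence[, 1] <- c(0.1, 0.3)          # unit spans both cells
  w$admin$cell_admin2 <- rep("A2_1", 2)
  sv <- simulate_surveys(w, tr,
                         survey_design(n_sources = 10,
                                       clusters_per_source = 50,
                                       children_per_cluster = 200,
                                       polygon_fraction = 1), 5)
  expect_true(all(sv$geometry_kind == "polygon"))
  frac <- sum(sv$n_cases) / sum(sv$n_children)
  expect_lt(abs(frac - 0.2), 0.005)
})

test_that("zero envelope perturbation reproduces the truth aggregates", {
  w <- desk_world(nrow = 6, ncol = 6, years = 2000:2002, n_covariates = 2)
  tr <- desk_truth(w, beta = c(0.3, -0.3))
  nat <- simulate_national_inputs(w, tr, national_params(epsilon = 0), 2)
  ct <- cell_table(w)
  for (i in seq_len(nrow(nat$national))) {
    row <- nat$national[i, ]
    cells <- which(ct$country == row$country)
    yi <- match(row$year, w$years)
    expect_equal(row$envelope_prevalence,
                 weighted.mean(tr$prevalence[cells, yi],
                               w$population[cells, yi]),
                 tolerance = 1e-12)
  }
  # mortality envelope is exactly incidence envelope x CFR
  expect_lt(max(abs(nat$national$envelope_mortality -
                      nat$national$envelope_incidence * nat$national$cfr)),
            1e-9)
})

test_that("zero case-fatality gives a zero mortality envelope", {
  w <- desk_world(nrow = 4, ncol = 4, n_countries = 1, years = 2000:2001,
                  n_covariates = 1)
  tr <- desk_truth(w, beta = 0)
  nat <- simulate_national_inputs(w, tr,
                                  national_params(cfr_range = c(0, 0)), 2)
  expect_true(all(nat$national$envelope_mortality == 0))
  expect_error(national_params(cfr_range = c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("exposure trends follow the stated arithmetic in every cell", {
  w <- desk_world(nrow = 3, ncol = 3, n_countries = 1, years = 2000:2017,
                  n_covariates = 1)
  tr <- flat_truth(w, 0.05)
  rf <- data.frame(name = "x", group = "prevent", rr_min = 1.5,
                   rr_max = 1.5, x0_min = 0.6, x0_max = 0.6, trend = -0.02)
  nat <- simulate_national_inputs(
    w, tr, national_params(risk_factors = rf, exposure_spatial_amp = 0), 4)
  expo <- nat$risk_factors$x$exposure
  expect_equal(unname(expo[, "2000"]), rep(0.6, 9), tolerance = 1e-12)
  expect_equal(unname(expo[, "2017"]), rep(0.6 - 0.02 * 17, 9),
               tolerance = 1e-12)
})
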