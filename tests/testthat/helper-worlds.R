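# Shared fixtures, built in code. Sizes are kept small so each test file
# stands alone quickly; the acceptance file uses its own larger world.

desk_world <- function(seed = 42, nrow = 10, ncol = 12, n_countries = 3,
                       admin1_per_country = 2, admin2_per_admin1 = 2,
                       years = 2000:2005, n_covariates = 4, ...) {
  generate_world(world_config(nrow = nrow, ncol = ncol,
                              n_countries = n_countries,
                              admin1_per_country = admin1_per_country,
                              admin2_per_admin1 = admin2_per_admin1,
                              years = years, n_covariates = n_covariates,
                              ...),
                 seed = seed)
}

desk_truth <- function(world, seed = 7, ...) {
  args <- list(...)
  defaults <- list(beta = c(0.5, -0.3, 0.2, 0),
                   intercept = qlogis(0.06), spatial_range = 4,
                   spatial_sd = 0.5, temporal_rho = 0.9, nugget_sd = 0.1)
  defaults$beta <- rep_len(defaults$beta, length(world$covariates))
  defaults[names(args)] <- args
  simulate_truth(world, do.call(truth_params, defaults), seed = seed)
}

# Uniform prevalence truth (no covariate, GP or nugget signal).
flat_truth <- function(world, p, seed = 1) {
  simulate_truth(world,
                 truth_params(beta = 0, intercept = qlogis(p),
                              spatial_sd = 0, nugget_sd = 0),
                 seed = seed)
}

# A one-learner stack_result with a constant prediction everywhere; lets the
# geostatistical stage be tested with a fixed, known offset.
constant_stack <- function(world, records, p) {
  ncell <- world$grid$nrow * world$grid$ncol
  nyear <- length(world$years)
  structure(list(
    learners = "penalized-linear",
    oos = matrix(p, nrow(records), 1,
                 dimnames = list(NULL, "penalized-linear")),
    folds = rep_len(1:5, nrow(records)),
    surfaces = list("penalized-linear" = matrix(p, ncell, nyear)),
    seed = 0L), class = "stack_result")
}

# Cluster records drawn directly at given cells/years (bypasses the survey
# design when a test needs full control of the sampling locations).
direct_records <- function(world, truth, n_obs, n_children = 50, seed = 1,
                           n_sources = 10) {
  set.seed(seed)
  ncell <- world$grid$nrow * world$grid$ncol
  nyear <- length(world$years)
  cell <- sample(ncell, n_obs, replace = TRUE)
  yi <- sample(nyear, n_obs, replace = TRUE)
  p <- truth$prevalence[cbind(cell, yi)]
  data.frame(source_id = sprintf("S%02d", rep_len(seq_len(n_sources), n_obs)),
             year = world$years[yi], geometry_kind = "point", cell = cell,
             admin_unit_id = NA_character_, n_children = n_children,
             n_cases = rbinom(n_obs, n_children, p), weight = 1,
             stringsAsFactors = FALSE)
}

# Synthetic draw cube around a truth surface: logit-normal jitter per draw,
# for exercising raking/aggregation without a model fit.
jitter_draws <- function(world, truth, n_draws = 20, sd = 0.15, seed = 1) {
  set.seed(seed)
  ncell <- world$grid$nrow * world$grid$ncol
  nyear <- length(world$years)
  arr <- array(NA_real_, c(ncell, nyear, n_draws))
  for (k in seq_len(n_draws))
    arr[, , k] <- plogis(truth$logit +
                           matrix(rnorm(ncell * nyear, sd = sd),
                                  ncell, nyear))
  as_prev_draws(arr, world)
}
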