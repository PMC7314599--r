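#' Configure a synthetic survey world
#'
#' A world is a regular grid of cells partitioned into a three-level
#' administrative hierarchy (country > admin1 > admin2), carrying an under-5
#' population surface and a stack of standardized covariates. It is the
#' substrate on which prevalence truths, household surveys, and national
#' input tables are simulated.
#'
#' @param nrow,ncol grid dimensions (cells).
#' @param n_countries number of countries; countries are contiguous
#'   column bands of the grid.
#' @param admin1_per_country,admin2_per_admin1 units per parent; admin2 units
#'   are rectangular cell blocks, so every cell belongs to exactly one admin2.
#' @param years calendar years covered (default 2000--2017).
#' @param n_covariates number of covariate surfaces to generate.
#' @param cell_size cell edge length in degrees.
#' @param origin longitude/latitude of the north-west grid corner.
#' @param pop_meanlog,pop_sdlog lognormal parameters of the cell under-5
#'   population; the default sdlog gives the heavy right tail of settlement
#'   size distributions (a few urban cells dominate national counts).
#' @param pop_growth annual multiplicative population growth.
#' @param prop_time_varying fraction of covariates that carry a year trend.
#' @return a list of class \code{world_config}.
#' @export
world_config <- function(nrow = 20L, ncol = 20L,
                         n_countries = 3L,
                         admin1_per_country = 2L,
                         admin2_per_admin1 = 2L,
                         years = 2000:2017,
                         n_covariates = 5L,
                         cell_size = 0.1,
                         origin = c(lon = 0, lat = 0),
                         pop_meanlog = log(500),
                         pop_sdlog = 1.3,
                         pop_growth = 0.01,
                         prop_time_varying = 0.4) {
  nrow <- as.integer(nrow); ncol <- as.integer(ncol)
  n_countries <- as.integer(n_countries)
  admin1_per_country <- as.integer(admin1_per_country)
  admin2_per_admin1 <- as.integer(admin2_per_admin1)
  if (nrow < 1L || ncol < 1L)
    stop("grid dimensions must be positive", call. = FALSE)
  if (n_countries < 1L || admin1_per_country < 1L || admin2_per_admin1 < 1L)
    stop("admin unit counts must be positive", call. = FALSE)
  if (ncol < n_countries)
    stop("grid has fewer columns than countries", call. = FALSE)
  if (nrow < admin1_per_country)
    stop("grid has fewer rows than admin1 units per country", call. = FALSE)
  if (min(table(split_band(ncol, n_countries))) < admin2_per_admin1)
    stop("country column bands too narrow for the requested admin2 count",
         call. = FALSE)
  if (length(years) < 1L) stop("need at least one year", call. = FALSE)
  if (n_covariates < 1L) stop("need at least one covariate", call. = FALSE)
  structure(list(nrow = nrow, ncol = ncol, n_countries = n_countries,
                 admin1_per_country = admin1_per_country,
                 admin2_per_admin1 = admin2_per_admin1,
                 years = as.integer(years), n_covariates = n_covariates,
                 cell_size = cell_size, origin = origin,
                 pop_meanlog = pop_meanlog, pop_sdlog = pop_sdlog,
                 pop_growth = pop_growth,
                 prop_time_varying = prop_time_varying),
            class = "world_config")
}

# Partition 1..n into k contiguous bands as evenly as possible; returns the
# band index of each position.
split_band <- function(n, k) {
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(k), times = sizes)
}

#' Generate a synthetic world
#'
#' Deterministic for a fixed \code{(config, seed)} pair. Cells are indexed
#' row-major from the north-west corner. Countries are contiguous column
#' bands; admin1 units split each country into row bands; admin2 units split
#' each admin1 into column blocks, so the admin2 level partitions the grid
#' into rectangles. Population is lognormal (heavy-tailed, urban-like) with a
#' smooth annual growth trend. Covariates are smooth random surfaces (low
#' order cosine bases plus white noise), standardized to mean 0, sd 1 with
#' the standardization recorded.
#'
#' @param config a \code{\link{world_config}}.
#' @param seed integer RNG seed.
#' @return a list of class \code{world} with elements \code{grid},
#'   \code{years}, \code{admin} (units table and cell membership),
#'   \code{population} (cell x year matrix), \code{covariates} (named list of
#'   cell x year matrices) and \code{cov_standardization}.
#' @export
generate_world <- function(config, seed = 1L) {
  stopifnot(inherits(config, "world_config"))
  set.seed(as.integer(seed))
  nr <- config$nrow; nc <- config$ncol
  ncell <- nr * nc
  nyear <- length(config$years)

  # cell coordinates, row-major from NW corner
  row_of <- rep(seq_len(nr), each = nc)
  col_of <- rep(seq_len(nc), times = nr)

  # admin partition: country = column band, admin1 = row band within country,
  # admin2 = column block within the admin1 rectangle
  country_of_col <- split_band(nc, config$n_countries)
  admin1_of_row <- split_band(nr, config$admin1_per_country)
  cell_country <- country_of_col[col_of]
  cell_admin1_local <- admin1_of_row[row_of]
  cell_admin2_local <- integer(ncell)
  for (co in seq_len(config$n_countries)) {
    cols_in <- which(country_of_col == co)
    a2_of_col <- split_band(length(cols_in), config$admin2_per_admin1)
    idx <- cell_country == co
    cell_admin2_local[idx] <- a2_of_col[match(col_of[idx], cols_in)]
  }

  n_a1 <- config$n_countries * config$admin1_per_country
  cell_admin1 <- (cell_country - 1L) * config$admin1_per_country +
    cell_admin1_local
  cell_admin2 <- (cell_admin1 - 1L) * config$admin2_per_admin1 +
    cell_admin2_local
  n_a2 <- n_a1 * config$admin2_per_admin1

  units <- rbind(
    data.frame(id = paste0("C", seq_len(config$n_countries)), level = 0L,
               parent_id = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(id = paste0("A1_", seq_len(n_a1)), level = 1L,
               parent_id = paste0("C", rep(seq_len(config$n_countries),
                                           each = config$admin1_per_country)),
               stringsAsFactors = FALSE),
    data.frame(id = paste0("A2_", seq_len(n_a2)), level = 2L,
               parent_id = paste0("A1_", rep(seq_len(n_a1),
                                             each = config$admin2_per_admin1)),
               stringsAsFactors = FALSE)
  )

  # population: lognormal cell base, common growth trend
  base_pop <- stats::rlnorm(ncell, config$pop_meanlog, config$pop_sdlog)
  growth <- (1 + config$pop_growth)^(seq_len(nyear) - 1L)
  population <- outer(base_pop, growth)
  colnames(population) <- as.character(config$years)

  # covariates: smooth cosine surfaces + noise; some with linear year trends
  n_tv <- max(0L, round(config$prop_time_varying * config$n_covariates))
  covariates <- vector("list", config$n_covariates)
  names(covariates) <- sprintf("cov%02d", seq_len(config$n_covariates))
  standardization <- data.frame(name = names(covariates),
                                mean = NA_real_, sd = NA_real_,
                                time_varying = rep(c(TRUE, FALSE),
                                                   c(n_tv, config$n_covariates - n_tv)),
                                stringsAsFactors = FALSE)
  u <- (row_of - 0.5) / nr
  v <- (col_of - 0.5) / nc
  for (j in seq_len(config$n_covariates)) {
    amp <- stats::rnorm(6)
    freq <- sample(1:3, 4, replace = TRUE)
    phase <- stats::runif(4, 0, 2 * pi)
    surf <- amp[1] * cos(2 * pi * freq[1] * u + phase[1]) +
      amp[2] * cos(2 * pi * freq[2] * v + phase[2]) +
      amp[3] * cos(2 * pi * freq[3] * (u + v) + phase[3]) +
      amp[4] * cos(2 * pi * freq[4] * (u - v) + phase[4]) +
      amp[5] * u + amp[6] * v +
      stats::rnorm(ncell, sd = 0.3)
    if (standardization$time_varying[j]) {
      trend <- stats::rnorm(1, sd = 0.1)
      x <- outer(surf, rep(1, nyear)) +
        outer(rep(1, ncell), trend * (seq_len(nyear) - 1L)) +
        matrix(stats::rnorm(ncell * nyear, sd = 0.1), ncell, nyear)
    } else {
      x <- outer(surf, rep(1, nyear))
    }
    m <- mean(x); s <- stats::sd(as.vector(x))
    if (!is.finite(s) || s == 0) s <- 1
    x <- (x - m) / s
    colnames(x) <- as.character(config$years)
    covariates[[j]] <- x
    standardization$mean[j] <- m
    standardization$sd[j] <- s
  }

  w <- structure(list(
    grid = list(nrow = nr, ncol = nc, cell_size = config$cell_size,
                origin = config$origin),
    years = config$years,
    admin = list(units = units,
                 cell_country = paste0("C", cell_country),
                 cell_admin1 = paste0("A1_", cell_admin1),
                 cell_admin2 = paste0("A2_", cell_admin2)),
    population = population,
    covariates = covariates,
    cov_standardization = standardization,
    config = config, seed = as.integer(seed)
  ), class = "world")
  w
}

#' @export
print.world <- function(x, ...) {
  cat(sprintf("Synthetic world: %d x %d grid (%d cells), years %d-%d\n",
              x$grid$nrow, x$grid$ncol, n_cells(x),
              min(x$years), max(x$years)))
  tab <- table(x$admin$units$level)
  cat(sprintf("  admin: %d countries, %d admin1, %d admin2\n",
              tab["0"], tab["1"], tab["2"]))
  cat(sprintf("  covariates: %s\n", paste(names(x$covariates), collapse = ", ")))
  invisible(x)
}

n_cells <- function(world) world$grid$nrow * world$grid$ncol

#' Cell centre coordinates and admin membership
#'
#' @param world a \code{world}.
#' @return data.frame with one row per cell (row-major from the NW corner):
#'   row, col, lon, lat, country, admin1, admin2.
#' @export
cell_table <- function(world) {
  nr <- world$grid$nrow; nc <- world$grid$ncol
  row <- rep(seq_len(nr), each = nc)
  col <- rep(seq_len(nc), times = nr)
  data.frame(
    cell = seq_len(nr * nc), row = row, col = col,
    lon = world$grid$origin[[1]] + (col - 0.5) * world$grid$cell_size,
    lat = world$grid$origin[[2]] - (row - 0.5) * world$grid$cell_size,
    country = world$admin$cell_country,
    admin1 = world$admin$cell_admin1,
    admin2 = world$admin$cell_admin2,
    stringsAsFactors = FALSE
  )
}

#' Matern correlation with smoothness 3/2
#'
#' \eqn{\rho(d) = (1 + \sqrt{3} d/\ell)\exp(-\sqrt{3} d/\ell)}; fields drawn
#' from this kernel are once mean-square differentiable.
#'
#' @param d distances (same units as \code{range}).
#' @param range correlation length \eqn{\ell} > 0.
#' @export
matern32_cor <- function(d, range) {
  if (range <= 0) stop("range must be positive", call. = FALSE)
  a <- sqrt(3) * d / range
  (1 + a) * exp(-a)
}

# Cholesky factors of the separable space-time correlation used by both the
# generator and (via its own covariance assembly) the fitted model.
spatial_cormat <- function(world, range) {
  ct <- cell_table(world)
  d <- as.matrix(stats::dist(cbind(ct$row, ct$col)))
  matern32_cor(d, range)
}

ar1_cormat <- function(nyear, rho) {
  rho^abs(outer(seq_len(nyear), seq_len(nyear), "-"))
}

chol_jitter <- function(m, jitter = 1e-8) {
  ok <- FALSE; L <- NULL
  for (k in 0:6) {
    L <- tryCatch(chol(m + diag(jitter * 10^k, nrow(m))),
                  error = function(e) NULL)
    if (!is.null(L)) { ok <- TRUE; break }
  }
  if (!ok) stop("correlation matrix not positive definite", call. = FALSE)
  L
}

#' Parameters of a simulated prevalence truth
#'
#' @param beta covariate coefficients on the logit scale (recycled or named;
#'   length must match the world's covariate count when used).
#' @param intercept logit-scale intercept.
#' @param spatial_range Matern-3/2 correlation length, in cell widths.
#' @param spatial_sd marginal standard deviation of the space-time GP.
#' @param temporal_rho AR1 year-to-year correlation, in (-1, 1).
#' @param nugget_sd sd of iid cell-year logit noise.
#' @export
truth_params <- function(beta = 0.3, intercept = qlogis(0.04),
                         spatial_range = 6, spatial_sd = 0.5,
                         temporal_rho = 0.9, nugget_sd = 0.1) {
  if (abs(temporal_rho) >= 1)
    stop("temporal_rho must lie strictly in (-1, 1)", call. = FALSE)
  if (spatial_sd < 0 || nugget_sd < 0)
    stop("standard deviations must be non-negative", call. = FALSE)
  if (spatial_range <= 0)
    stop("spatial_range must be positive", call. = FALSE)
  list(beta = beta, intercept = intercept, spatial_range = spatial_range,
       spatial_sd = spatial_sd, temporal_rho = temporal_rho,
       nugget_sd = nugget_sd)
}

#' Simulate a prevalence truth surface
#'
#' logit(prevalence) = intercept + X beta + GP + nugget, where the GP is a
#' separable Matern-3/2(space) x AR1(time) field with the given marginal sd,
#' realized exactly by Cholesky factorization on the grid.
#'
#' @param world a \code{world}.
#' @param params see \code{\link{truth_params}}.
#' @param seed integer RNG seed.
#' @return list of class \code{truth}: \code{prevalence} and \code{logit}
#'   (cell x year), the GP component, and the generating parameters.
#' @export
simulate_truth <- function(world, params = truth_params(), seed = 1L) {
  stopifnot(inherits(world, "world"))
  params <- do.call(truth_params, params)   # re-validate
  set.seed(as.integer(seed))
  ncell <- n_cells(world); nyear <- length(world$years)

  beta <- rep_len(params$beta, length(world$covariates))
  lp <- matrix(params$intercept, ncell, nyear)
  for (j in seq_along(world$covariates))
    lp <- lp + beta[j] * world$covariates[[j]]

  gp <- matrix(0, ncell, nyear)
  if (params$spatial_sd > 0) {
    Ls <- chol_jitter(spatial_cormat(world, params$spatial_range))
    Lt <- if (nyear > 1L) chol_jitter(ar1_cormat(nyear, params$temporal_rho))
          else matrix(1, 1, 1)
    z <- matrix(stats::rnorm(ncell * nyear), ncell, nyear)
    gp <- params$spatial_sd * (t(Ls) %*% z %*% Lt)
  }
  nug <- if (params$nugget_sd > 0)
    matrix(stats::rnorm(ncell * nyear, sd = params$nugget_sd), ncell, nyear)
  else matrix(0, ncell, nyear)

  eta <- lp + gp + nug
  colnames(eta) <- as.character(world$years)
  structure(list(prevalence = stats::plogis(eta), logit = eta,
                 gp = gp, linear = lp, params = params,
                 seed = as.integer(seed)),
            class = "truth")
}

#' Survey sampling design
#'
#' @param n_sources number of survey sources; each source surveys one country
#'   in one year (uneven space-time coverage arises because not every
#'   country-year receives a source).
#' @param clusters_per_source clusters sampled per source.
#' @param children_per_cluster children examined per cluster.
#' @param polygon_fraction fraction of sources reporting polygon (admin2)
#'   geometry instead of cluster points.
#' @param year_coverage fraction of calendar years eligible to receive
#'   sources (coverage gaps in time).
#' @export
survey_design <- function(n_sources = 20L, clusters_per_source = 50L,
                          children_per_cluster = 20L,
                          polygon_fraction = 0.1,
                          year_coverage = 1) {
  if (polygon_fraction < 0 || polygon_fraction > 1)
    stop("polygon_fraction must lie in [0, 1]", call. = FALSE)
  if (year_coverage <= 0 || year_coverage > 1)
    stop("year_coverage must lie in (0, 1]", call. = FALSE)
  list(n_sources = as.integer(n_sources),
       clusters_per_source = as.integer(clusters_per_source),
       children_per_cluster = as.integer(children_per_cluster),
       polygon_fraction = polygon_fraction,
       year_coverage = year_coverage)
}

#' Simulate household-survey records
#'
#' Point records draw cluster locations within the source's country with
#' probability proportional to population; cases are Binomial(n, p) at the
#' cell-year truth prevalence. Polygon records reference an admin2 unit and
#' sample at its population-weighted mean prevalence.
#'
#' @param world a \code{world}; \code{truth} a \code{\link{simulate_truth}}
#'   result; \code{design} a \code{\link{survey_design}}.
#' @param truth a \code{truth} surface for the same world.
#' @param design a \code{survey_design}.
#' @param seed integer RNG seed.
#' @return data.frame of survey records (one row per cluster or polygon
#'   observation): source_id, year, geometry_kind, cell, admin_unit_id,
#'   n_children, n_cases, weight.
#' @export
simulate_surveys <- function(world, truth, design = survey_design(),
                             seed = 1L) {
  stopifnot(inherits(world, "world"), inherits(truth, "truth"))
  set.seed(as.integer(seed))
  countries <- world$admin$units$id[world$admin$units$level == 0L]
  nyear <- length(world$years)
  eligible_years <- sort(sample(seq_len(nyear),
                                max(1L, round(design$year_coverage * nyear))))
  n_poly <- round(design$polygon_fraction * design$n_sources)
  kind <- rep(c("polygon", "point"),
              c(n_poly, design$n_sources - n_poly))

  recs <- vector("list", design$n_sources)
  ct <- cell_table(world)
  for (s in seq_len(design$n_sources)) {
    co <- sample(countries, 1L)
    yi <- if (length(eligible_years) == 1L) eligible_years
          else sample(eligible_years, 1L)
    if (kind[s] == "point") {
      cells_in <- which(ct$country == co)
      pr <- world$population[cells_in, yi]
      cl <- sample(cells_in, design$clusters_per_source, replace = TRUE,
                   prob = pr / sum(pr))
      p <- truth$prevalence[cbind(cl, yi)]
      recs[[s]] <- data.frame(
        source_id = sprintf("S%03d", s), year = world$years[yi],
        geometry_kind = "point", cell = cl, admin_unit_id = NA_character_,
        n_children = design$children_per_cluster,
        n_cases = stats::rbinom(length(cl), design$children_per_cluster, p),
        weight = 1, stringsAsFactors = FALSE)
    } else {
      units2 <- unique(ct$admin2[ct$country == co])
      un <- sample(units2, min(length(units2), design$clusters_per_source),
                   replace = length(units2) < design$clusters_per_source)
      p <- vapply(un, function(u) {
        cells_u <- which(ct$admin2 == u)
        stats::weighted.mean(truth$prevalence[cells_u, yi],
                             world$population[cells_u, yi])
      }, numeric(1))
      nc_poly <- design$children_per_cluster * 5L  # polygons pool clusters
      recs[[s]] <- data.frame(
        source_id = sprintf("S%03d", s), year = world$years[yi],
        geometry_kind = "polygon", cell = NA_integer_, admin_unit_id = un,
        n_children = nc_poly,
        n_cases = stats::rbinom(length(un), nc_poly, p),
        weight = 1, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

#' Parameters for national inputs and risk factors
#'
#' @param cfr_range per-country case-fatality rate range (deaths per episode).
#' @param epsilon maximum relative perturbation of envelopes around the
#'   truth's national aggregates; 0 makes envelopes equal the truth exactly.
#' @param duration mean episode duration in days used to construct the
#'   incidence envelope from prevalence.
#' @param risk_factors data.frame(name, group, rr_min, rr_max, x0_min,
#'   x0_max, trend) describing exposure surfaces: a baseline drawn in
#'   \[x0_min, x0_max\] plus smooth spatial variation, linear yearly trend
#'   (negative = improving), clamped to \[0, 1\].
#' @param exposure_spatial_amp amplitude of the smooth spatial variation
#'   added to each exposure baseline; 0 gives spatially uniform exposures.
#' @export
national_params <- function(cfr_range = c(2e-4, 2e-3), epsilon = 0.05,
                            duration = 4.2, exposure_spatial_amp = 0.15,
                            risk_factors = data.frame(
                              name = c("stunting", "unimproved_water",
                                       "unimproved_sanitation", "no_ors"),
                              group = c("protect", "prevent", "prevent",
                                        "treat"),
                              rr_min = c(1.5, 1.2, 1.2, 1.1),
                              rr_max = c(2.5, 1.8, 1.8, 1.4),
                              x0_min = c(0.3, 0.3, 0.4, 0.5),
                              x0_max = c(0.6, 0.7, 0.8, 0.9),
                              trend = c(-0.012, -0.010, -0.012, -0.015),
                              stringsAsFactors = FALSE)) {
  if (any(cfr_range < 0) || any(cfr_range > 1))
    stop("case-fatality rates must lie in [0, 1]", call. = FALSE)
  if (epsilon < 0) stop("epsilon must be non-negative", call. = FALSE)
  list(cfr_range = cfr_range, epsilon = epsilon, duration = duration,
       exposure_spatial_amp = exposure_spatial_amp,
       risk_factors = risk_factors)
}

#' Simulate national envelopes, case-fatality rates and risk factors
#'
#' Envelopes are the truth's population-weighted national aggregates times a
#' (1 + U(-epsilon, epsilon)) perturbation, so raking has a known target;
#' the mortality envelope is exactly incidence envelope x CFR, and CFRs do
#' not vary subnationally.
#'
#' @param world,truth as elsewhere.
#' @param params see \code{\link{national_params}}.
#' @param seed integer RNG seed.
#' @return list with \code{national} (data.frame country, year,
#'   envelope_prevalence, envelope_incidence, envelope_mortality, cfr) and
#'   \code{risk_factors} (list of objects with name, group, rr, exposure
#'   cell x year matrix).
#' @export
simulate_national_inputs <- function(world, truth, params = national_params(),
                                     seed = 1L) {
  stopifnot(inherits(world, "world"), inherits(truth, "truth"))
  if (any(params$cfr_range < 0) || any(params$cfr_range > 1))
    stop("case-fatality rates must lie in [0, 1]", call. = FALSE)
  set.seed(as.integer(seed))
  ct <- cell_table(world)
  countries <- world$admin$units$id[world$admin$units$level == 0L]
  nyear <- length(world$years)

  rows <- list(); k <- 0L
  cfr_country <- stats::runif(length(countries), params$cfr_range[1],
                              params$cfr_range[2])
  names(cfr_country) <- countries
  for (co in countries) {
    cells_c <- which(ct$country == co)
    for (yi in seq_len(nyear)) {
      pop <- world$population[cells_c, yi]
      prev <- stats::weighted.mean(truth$prevalence[cells_c, yi], pop)
      inc <- prev * 365 / params$duration
      e1 <- stats::runif(1, -params$epsilon, params$epsilon)
      e2 <- stats::runif(1, -params$epsilon, params$epsilon)
      cfr <- cfr_country[[co]] * (1 - 0.01 * (yi - 1))  # slow secular decline
      env_inc <- inc * (1 + e2)
      k <- k + 1L
      rows[[k]] <- data.frame(
        country = co, year = world$years[yi],
        envelope_prevalence = prev * (1 + e1),
        envelope_incidence = env_inc,
        envelope_mortality = env_inc * cfr,
        cfr = cfr, stringsAsFactors = FALSE)
    }
  }
  national <- do.call(rbind, rows)
  rownames(national) <- NULL

  rf <- params$risk_factors
  ncell <- n_cells(world)
  u <- (ct$row - 0.5) / world$grid$nrow
  v <- (ct$col - 0.5) / world$grid$ncol
  risk_factors <- vector("list", nrow(rf))
  for (r in seq_len(nrow(rf))) {
    rr <- stats::runif(1, rf$rr_min[r], rf$rr_max[r])
    x0 <- stats::runif(1, rf$x0_min[r], rf$x0_max[r])
    surf <- params$exposure_spatial_amp *
      (cos(2 * pi * stats::runif(1) + 2 * pi * u) +
         cos(2 * pi * stats::runif(1) + 2 * pi * v))
    expo <- matrix(NA_real_, ncell, nyear)
    for (yi in seq_len(nyear))
      expo[, yi] <- pmin(1, pmax(0, x0 + surf + rf$trend[r] * (yi - 1)))
    colnames(expo) <- as.character(world$years)
    risk_factors[[r]] <- structure(
      list(name = rf$name[r], group = rf$group[r], rr = rr, exposure = expo),
      class = "risk_factor")
  }
  names(risk_factors) <- rf$name
  list(national = national, risk_factors = risk_factors)
}
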