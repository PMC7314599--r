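#' Pipeline configuration
#'
#' Bundles every stage's tunable with the analysis defaults: 250 posterior
#' draws, a 4.2-day mean episode duration, a VIF threshold of 3, five CV
#' folds, 2.5/97.5 percentile uncertainty intervals, a 10% decline
#' threshold and a 0.5 dominance share.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @param world a \code{\link{world_config}}.
#' @param truth \code{\link{truth_params}}.
#' @param design \code{\link{survey_design}}.
#' @param national \code{\link{national_params}}.
#' @param learners learner names for \code{\link{fit_stack}}.
#' @param n_draws posterior draws (default 250).
#' @param duration episode duration in days (default 4.2).
#' @param vif_threshold VIF filter threshold (default 3).
#' @param n_folds CV folds (default 5).
#' @param polygon_k pseudo-clusters per polygon record (default 10).
#' @param rake_exclude countries exempt from raking.
#' @param change_threshold decline threshold (default 0.10).
#' @param dominance_share dominant-driver share (default 0.5).
#' @param geo \code{\link{geo_config}}.
#' @param priors \code{\link{geo_priors}}.
#' @param run_cv whether to run cross-validation (slowest stage).
#' @param out_dir output directory (created if missing).
#' @export
pipeline_config <- function(seed = 1L,
                            world = world_config(),
                            truth = truth_params(),
                            design = survey_design(),
                            national = national_params(),
                            learners = c("penalized-linear",
                                         "tree-ensemble",
                                         "spline-additive"),
                            n_draws = 250L, duration = 4.2,
                            vif_threshold = 3, n_folds = 5L,
                            polygon_k = 10L,
                            rake_exclude = character(),
                            change_threshold = 0.10,
                            dominance_share = 0.5,
                            geo = geo_config(), priors = geo_priors(),
                            run_cv = FALSE,
                            out_dir = tempfile("geoburden_run_")) {
  list(seed = as.integer(seed), world = world, truth = truth,
       design = design, national = national, learners = learners,
       n_draws = as.integer(n_draws), duration = duration,
       vif_threshold = vif_threshold, n_folds = as.integer(n_folds),
       polygon_k = as.integer(polygon_k), rake_exclude = rake_exclude,
       change_threshold = change_threshold,
       dominance_share = dominance_share, geo = geo, priors = priors,
       run_cv = run_cv, out_dir = out_dir)
}

#' Run the full estimation pipeline
#'
#' Executes world generation, covariate preparation, stacking, the
#' geostatistical fit, posterior sampling, burden conversion and raking,
#' admin aggregation with inequality metrics, and the risk-factor
#' counterfactual, writing each stage's tabular outputs as CSV plus a JSON
#' manifest (seed, file list with MD5 hashes). Every output is recomputable
#' from the previous stage's files.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param quiet suppress stage messages.
#' @return invisible list with the in-memory stage objects and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  t0 <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  say("[worldgen] generating world, truth, surveys, national inputs")
  world <- stage("worldgen", generate_world(config$world, config$seed))
  truth <- stage("worldgen",
                 simulate_truth(world, config$truth, config$seed + 1L))
  surveys <- stage("worldgen",
                   simulate_surveys(world, truth, config$design,
                                    config$seed + 2L))
  nat <- stage("worldgen",
               simulate_national_inputs(world, truth, config$national,
                                        config$seed + 3L))
  write_surveys(surveys, file.path(config$out_dir, "surveys.csv"))
  utils::write.csv(nat$national,
                   file.path(config$out_dir, "national_inputs.csv"),
                   row.names = FALSE)
  write_admin_geojson(world, file.path(config$out_dir, "admin_units.geojson"))
  utils::write.csv(world$admin$units,
                   file.path(config$out_dir, "hierarchy.csv"),
                   row.names = FALSE)
  write_raster_csv(world$population, world,
                   file.path(config$out_dir, "population.csv"))
  utils::write.csv(
    data.frame(name = vapply(nat$risk_factors, `[[`, "", "name"),
               group = vapply(nat$risk_factors, `[[`, "", "group"),
               rr = vapply(nat$risk_factors, `[[`, 0, "rr")),
    file.path(config$out_dir, "risk_factors.csv"), row.names = FALSE)

  say("[covprep] VIF filter and polygon resampling")
  pts <- stage("covprep",
               resample_polygons(surveys, world, k = config$polygon_k,
                                 seed = config$seed + 4L))
  X <- stage("covprep", record_covariates(pts, world))
  vif <- stage("covprep", vif_filter(X, threshold = config$vif_threshold))
  utils::write.csv(data.frame(covariate = vif$retained),
                   file.path(config$out_dir, "covariates_retained.csv"),
                   row.names = FALSE)
  write_surveys(pts, file.path(config$out_dir, "surveys_points.csv"))

  say("[stacker] fitting %d learners", length(config$learners))
  st <- stage("stacker",
              fit_stack(pts, world, covariates = vif$retained,
                        n_folds = config$n_folds,
                        learners = config$learners,
                        seed = config$seed + 5L))
  oos_df <- data.frame(record = seq_len(nrow(st$oos)), fold = st$folds,
                       st$oos, check.names = FALSE)
  utils::write.csv(oos_df, file.path(config$out_dir, "stack_oos.csv"),
                   row.names = FALSE)

  say("[geomodel] fitting the space-time binomial model")
  fit <- stage("geomodel",
               fit_geostat(pts, world, st, priors = config$priors,
                           config = config$geo, seed = config$seed + 6L))
  say("[geomodel] sampling %d posterior draws", config$n_draws)
  prev <- stage("geomodel",
                sample_posterior(fit, n_draws = config$n_draws,
                                 seed = config$seed + 7L))

  say("[burden] converting and raking")
  prev_raked <- stage("burden",
                      rake(prev, world, nat$national, mode = "logit",
                           exclude = config$rake_exclude))
  inc <- stage("burden",
               prevalence_to_incidence(prev_raked$draws, config$duration))
  inc_raked <- stage("burden",
                     rake(inc, world, nat$national,
                          mode = "multiplicative",
                          exclude = config$rake_exclude))
  mort <- stage("burden", apply_cfr(inc_raked$draws, nat$national, world))
  mort_raked <- stage("burden",
                      rake(mort, world, nat$national,
                           mode = "multiplicative",
                           exclude = config$rake_exclude))
  factors <- rbind(prev_raked$factors, inc_raked$factors,
                   mort_raked$factors)
  utils::write.csv(factors, file.path(config$out_dir, "raking_factors.csv"),
                   row.names = FALSE)

  say("[inequality] aggregating and computing inequality metrics")
  aggs <- list()
  for (meas in c("prevalence", "incidence", "mortality")) {
    dr <- switch(meas, prevalence = prev_raked$draws,
                 incidence = inc_raked$draws, mortality = mort_raked$draws)
    aggs[[meas]] <- list(country = aggregate_draws(dr, world, 0L),
                         admin2 = aggregate_draws(dr, world, 2L))
  }
  utils::write.csv(do.call(rbind, lapply(aggs, function(a) a$admin2$summary)),
                   file.path(config$out_dir, "admin2_estimates.csv"),
                   row.names = FALSE)
  dev <- deviations(aggs$mortality$admin2, aggs$mortality$country, world)
  utils::write.csv(dev$summary, file.path(config$out_dir, "deviations.csv"),
                   row.names = FALSE)
  y0 <- world$years[1]; y1 <- world$years[length(world$years)]
  gini_tab <- do.call(rbind, lapply(c(y0, y1), function(y) {
    yi <- match(y, aggs$mortality$admin2$years)
    data.frame(year = y, measure = "mortality",
               gini = gini(rowMeans(aggs$mortality$admin2$rate_draws[, yi, ]),
                           aggs$mortality$admin2$population[, yi]))
  }))
  utils::write.csv(gini_tab, file.path(config$out_dir, "gini.csv"),
                   row.names = FALSE)
  chg <- classify_change(aggs$mortality$admin2, y0, y1,
                         threshold = config$change_threshold)
  utils::write.csv(chg$units,
                   file.path(config$out_dir, "change_classes.csv"),
                   row.names = FALSE)
  top <- top_risk_units(aggs$mortality$admin2, y1)
  utils::write.csv(top, file.path(config$out_dir, "top_risk_units.csv"),
                   row.names = FALSE)

  say("[counterfactual] risk-factor attribution")
  cf <- stage("counterfactual",
              averted_deaths(mort_raked$draws, world, nat$risk_factors,
                             year0 = y0, year1 = y1,
                             dominance_share = config$dominance_share))
  utils::write.csv(cf$units,
                   file.path(config$out_dir, "counterfactual_units.csv"),
                   row.names = FALSE)

  cvrep <- NULL
  if (isTRUE(config$run_cv)) {
    say("[validate] source-stratified cross-validation")
    cvrep <- cross_validate(pts, world, n_folds = config$n_folds,
                            learners = config$learners,
                            priors = config$priors, config = config$geo,
                            n_draws = min(100L, config$n_draws),
                            seed = config$seed + 8L)
    utils::write.csv(cvrep$folds,
                     file.path(config$out_dir, "cv_metrics.csv"),
                     row.names = FALSE)
  }

  files <- list.files(config$out_dir, full.names = TRUE)
  manifest <- list(
    seed = config$seed,
    created = format(t0, "%Y-%m-%d %H:%M:%S"),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    r_version = as.character(getRversion()),
    files = data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("pipeline complete: %d files in %s", length(files) + 1L,
      config$out_dir)
  invisible(list(world = world, truth = truth, surveys = surveys,
                 national = nat, vif = vif, stack = st, fit = fit,
                 prevalence = prev_raked, incidence = inc_raked,
                 mortality = mort_raked, aggregates = aggs,
                 deviations = dev, gini = gini_tab, change = chg,
                 top_risk = top, counterfactual = cf, cv = cvrep,
                 manifest = manifest, config = config))
}

survey_columns <- c("source_id", "year", "geometry_kind", "cell",
                    "admin_unit_id", "n_children", "n_cases", "weight")

#' Write survey records to CSV
#' @param records survey data.frame.
#' @param path output file.
#' @export
write_surveys <- function(records, path) {
  stopifnot(all(survey_columns %in% names(records)))
  utils::write.csv(records[, survey_columns], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Read and validate survey records
#'
#' Rejects files with missing required columns (naming the column) and rows
#' violating the record invariants (naming the data line number).
#'
#' @param path CSV written by \code{\link{write_surveys}}.
#' @return validated survey data.frame.
#' @export
read_surveys <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(survey_columns, names(d))
  if (length(missing))
    stop(sprintf("surveys file lacks required column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  d$admin_unit_id[d$admin_unit_id %in% c("", NA)] <- NA_character_
  bad <- which(d$n_cases > d$n_children | d$n_cases < 0 | d$n_children <= 0)
  if (length(bad))
    stop(sprintf("invalid survey rows (n_cases/n_children) on line %s",
                 paste(bad + 1L, collapse = ", ")), call. = FALSE)
  bad_geom <- which(!(d$geometry_kind %in% c("point", "polygon")))
  if (length(bad_geom))
    stop(sprintf("unknown geometry_kind on line %s",
                 paste(bad_geom + 1L, collapse = ", ")), call. = FALSE)
  bad_pt <- which(d$geometry_kind == "point" & is.na(d$cell))
  if (length(bad_pt))
    stop(sprintf("point record without a cell on line %s",
                 paste(bad_pt + 1L, collapse = ", ")), call. = FALSE)
  bad_pg <- which(d$geometry_kind == "polygon" & is.na(d$admin_unit_id))
  if (length(bad_pg))
    stop(sprintf("polygon record without an admin unit on line %s",
                 paste(bad_pg + 1L, collapse = ", ")), call. = FALSE)
  d
}

#' Write a cell-by-year surface as a long-format CSV raster
#'
#' Columns row, col, year, value; rows ordered row-major from the
#' north-west corner, year-major outer. Values are written with full
#' precision ("%.17g") so read-back is bit-identical.
#'
#' @param mat cell x year matrix.
#' @param world the world (grid shape and years).
#' @param path output file.
#' @export
write_raster_csv <- function(mat, world, path) {
  ctab <- cell_table(world)
  nyear <- ncol(mat)
  d <- data.frame(row = rep(ctab$row, nyear), col = rep(ctab$col, nyear),
                  year = rep(world$years[seq_len(nyear)],
                             each = nrow(mat)),
                  value = sprintf("%.17g", as.vector(mat)))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format CSV raster back to a cell-by-year matrix
#' @param path file written by \code{\link{write_raster_csv}}.
#' @param world the world it belongs to.
#' @export
read_raster_csv <- function(path, world) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cn in c("row", "col", "year", "value"))
    if (!cn %in% names(d))
      stop(sprintf("raster file lacks required column '%s'", cn),
           call. = FALSE)
  years <- sort(unique(d$year))
  nc <- world$grid$ncol
  cell <- (d$row - 1L) * nc + d$col
  m <- matrix(NA_real_, n_cells(world), length(years),
              dimnames = list(NULL, as.character(years)))
  m[cbind(cell, match(d$year, years))] <- as.numeric(d$value)
  m
}

#' Write a draw cube as CSV
#'
#' Long format (cell, year, draw, value) with "%.17g" values; round-trips
#' bit-identically through \code{\link{read_draws_csv}}.
#'
#' @param draws a \code{prev_draws}.
#' @param path output file.
#' @export
write_draws_csv <- function(draws, path) {
  stopifnot(inherits(draws, "prev_draws"))
  dm <- dim(draws$draws)
  d <- data.frame(
    cell = rep(seq_len(dm[1]), times = dm[2] * dm[3]),
    year = rep(rep(draws$years, each = dm[1]), times = dm[3]),
    draw = rep(seq_len(dm[3]), each = dm[1] * dm[2]),
    value = sprintf("%.17g", as.vector(draws$draws)))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a draw cube written by \code{\link{write_draws_csv}}
#' @param path CSV file.
#' @param measure measure tag to attach.
#' @param grid grid description (as in \code{world$grid}); optional.
#' @export
read_draws_csv <- function(path, measure = "prevalence", grid = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  years <- sort(unique(d$year))
  ncell <- max(d$cell); K <- max(d$draw)
  arr <- array(NA_real_, c(ncell, length(years), K),
               dimnames = list(NULL, as.character(years), NULL))
  arr[cbind(d$cell, match(d$year, years), d$draw)] <- as.numeric(d$value)
  new_draws(arr, measure = measure, years = years, grid = grid)
}

#' Write admin units as GeoJSON
#'
#' Every admin2 unit becomes a rectangular Polygon feature (the bounding box
#' of its cells, exact because units are rectangular blocks); country and
#' admin1 units are written with a null geometry and are linked through the
#' \code{parent_id} property.
#'
#' @param world the world.
#' @param path output file.
#' @export
write_admin_geojson <- function(world, path) {
  ctab <- cell_table(world)
  units <- world$admin$units
  cs <- world$grid$cell_size
  ox <- world$grid$origin[[1]]; oy <- world$grid$origin[[2]]
  features <- lapply(seq_len(nrow(units)), function(i) {
    u <- units[i, ]
    geom <- NULL
    if (u$level == 2L) {
      cells <- which(ctab$admin2 == u$id)
      r <- range(ctab$row[cells]); cl <- range(ctab$col[cells])
      # cell (row, col) spans lon [ox+(col-1)cs, ox+col cs],
      # lat [oy-row cs, oy-(row-1)cs]
      x0 <- ox + (cl[1] - 1) * cs; x1 <- ox + cl[2] * cs
      y0 <- oy - r[2] * cs; y1 <- oy - (r[1] - 1) * cs
      geom <- list(type = "Polygon",
                   coordinates = list(list(c(x0, y0), c(x1, y0),
                                           c(x1, y1), c(x0, y1),
                                           c(x0, y0))))
    }
    list(type = "Feature",
         properties = list(id = u$id, level = u$level,
                           parent_id = u$parent_id),
         geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = 10, null = "null")
  invisible(path)
}

#' Read an admin GeoJSON and validate the hierarchy
#'
#' @param path GeoJSON written by \code{\link{write_admin_geojson}}.
#' @return data.frame id, level, parent_id; errors name any unit whose
#'   parent is missing.
#' @export
read_admin_geojson <- function(path) {
  g <- jsonlite::read_json(path)
  units <- do.call(rbind, lapply(g$features, function(f)
    data.frame(id = f$properties$id, level = f$properties$level,
               parent_id = if (is.null(f$properties$parent_id))
                 NA_character_ else f$properties$parent_id,
               stringsAsFactors = FALSE)))
  need_parent <- units$level > 0L
  orphan <- need_parent & (is.na(units$parent_id) |
                             !(units$parent_id %in% units$id))
  if (any(orphan))
    stop(sprintf("admin unit(s) missing parent in hierarchy: %s",
                 paste(units$id[orphan], collapse = ", ")), call. = FALSE)
  units
}
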