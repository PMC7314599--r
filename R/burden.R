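#' Convert prevalence draws to incidence
#'
#' Point prevalence is converted to incidence (episodes per child-year) by
#' annualizing over the mean episode duration: incidence = prevalence x
#' 365 / duration, elementwise per draw. The default duration is 4.2 days;
#' 365 days per year is the annualization convention.
#'
#' @param draws a \code{prev_draws} object with measure "prevalence".
#' @param duration mean episode duration in days (> 0).
#' @return a \code{prev_draws} object with measure "incidence".
#' @export
prevalence_to_incidence <- function(draws, duration = 4.2) {
  stopifnot(inherits(draws, "prev_draws"))
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  out <- draws
  out$draws <- draws$draws * (365 / duration)
  out$measure <- "incidence"
  out
}

#' Convert incidence draws to mortality via case-fatality rates
#'
#' Multiplies incidence by the country- and year-specific case-fatality rate
#' (deaths per episode). CFRs do not vary subnationally: every cell of a
#' country shares its country-year CFR.
#'
#' @param draws incidence \code{prev_draws}.
#' @param national data.frame with columns country, year, cfr covering every
#'   country-year on the grid.
#' @param world the \code{world} providing cell-to-country membership.
#' @return a \code{prev_draws} object with measure "mortality" (deaths per
#'   child-year).
#' @export
apply_cfr <- function(draws, national, world) {
  stopifnot(inherits(draws, "prev_draws"), inherits(world, "world"))
  ctab <- cell_table(world)
  out <- draws
  for (yi in seq_along(draws$years)) {
    yr <- draws$years[yi]
    idx <- match(paste(ctab$country, yr),
                 paste(national$country, national$year))
    if (anyNA(idx)) {
      bad <- unique(ctab$country[is.na(idx)])
      stop(sprintf("missing case-fatality rate for %s in %d",
                   paste(bad, collapse = ", "), yr), call. = FALSE)
    }
    out$draws[, yi, ] <- draws$draws[, yi, ] * national$cfr[idx]
  }
  out$measure <- "mortality"
  out
}

# Population-weighted national aggregate of one draw surface for one year.
country_aggregate <- function(vals, pop, country) {
  num <- rowsum(vals * pop, country)
  den <- rowsum(pop, country)
  drop(num / den)
}

#' Rake draws to national envelopes
#'
#' Calibrates every draw so its population-weighted national aggregate
#' equals the national envelope, per country, year and draw. Multiplicative
#' mode solves factor = envelope / aggregate in closed form; logit mode
#' solves a monotone one-dimensional root for a logit-scale shift (bisection
#' until the aggregate matches the envelope to 1e-10), keeping prevalence in
#' \[0, 1\]. Prevalence should be raked in logit mode, incidence and mortality
#' multiplicatively.
#'
#' @param draws a \code{prev_draws} object.
#' @param world the world (population and country membership).
#' @param envelopes data.frame with columns country, year and the envelope
#'   column for this measure (\code{envelope_prevalence},
#'   \code{envelope_incidence} or \code{envelope_mortality}, resolved from
#'   \code{draws$measure}).
#' @param mode "logit" or "multiplicative"; default "logit" for prevalence
#'   and "multiplicative" otherwise.
#' @param exclude countries not raked (their factor is 1 / shift 0),
#'   mirroring envelope exclusions such as a country with implausible
#'   national estimates.
#' @return list with \code{draws} (raked) and \code{factors} (data.frame
#'   country, year, measure, draw, factor; logit mode stores the shift).
#' @export
rake <- function(draws, world, envelopes, mode = NULL, exclude = character()) {
  stopifnot(inherits(draws, "prev_draws"), inherits(world, "world"))
  if (is.null(mode))
    mode <- if (draws$measure == "prevalence") "logit" else "multiplicative"
  mode <- match.arg(mode, c("logit", "multiplicative"))
  env_col <- paste0("envelope_", draws$measure)
  if (!env_col %in% names(envelopes))
    stop(sprintf("envelopes lack column '%s'", env_col), call. = FALSE)

  ctab <- cell_table(world)
  countries <- sort(unique(ctab$country))
  country <- ctab$country
  K <- draws$n_draws
  out <- draws
  fac <- expand.grid(draw = seq_len(K), year = draws$years,
                     country = countries, KEEP.OUT.ATTRS = FALSE,
                     stringsAsFactors = FALSE)[, c("country", "year", "draw")]
  fac$measure <- draws$measure
  fac$factor <- NA_real_

  for (yi in seq_along(draws$years)) {
    yr <- draws$years[yi]
    ymatch <- match(yr, world$years)
    if (is.na(ymatch))
      stop(sprintf("draw year %d not present in world", yr), call. = FALSE)
    pop_yi <- world$population[, ymatch]
    env_idx <- match(paste(countries, yr),
                     paste(envelopes$country, envelopes$year))
    if (anyNA(env_idx))
      stop(sprintf("missing envelope for %s in %d",
                   paste(countries[is.na(env_idx)], collapse = ", "), yr),
           call. = FALSE)
    env <- envelopes[[env_col]][env_idx]
    names(env) <- countries
    for (k in seq_len(K)) {
      v <- draws$draws[, yi, k]
      agg <- country_aggregate(v, pop_yi, country)
      for (ci in seq_along(countries)) {
        co <- countries[ci]
        row <- which(fac$country == co & fac$year == yr & fac$draw == k)
        if (co %in% exclude) {
          fac$factor[row] <- if (mode == "multiplicative") 1 else 0
          next
        }
        cells_c <- country == co
        if (mode == "multiplicative") {
          if (agg[co] == 0 && env[co] != 0)
            stop(sprintf("zero national aggregate with nonzero envelope for %s in %d",
                         co, yr), call. = FALSE)
          f <- if (env[co] == 0 && agg[co] == 0) 1 else env[co] / agg[co]
          out$draws[cells_c, yi, k] <- v[cells_c] * f
          fac$factor[row] <- f
        } else {
          if (agg[co] == 0 && env[co] != 0)
            stop(sprintf("zero national aggregate with nonzero envelope for %s in %d",
                         co, yr), call. = FALSE)
          eta <- stats::qlogis(clamp_prob(v[cells_c], 1e-12))
          w_c <- pop_yi[cells_c] / sum(pop_yi[cells_c])
          g <- function(d) sum(w_c * stats::plogis(eta + d)) - env[co]
          lo <- -30; hi <- 30
          if (g(lo) > 0 || g(hi) < 0)
            stop(sprintf("envelope %g for %s in %d outside the attainable range",
                         env[co], co, yr), call. = FALSE)
          for (it in 1:200) {
            mid <- (lo + hi) / 2
            gm <- g(mid)
            if (abs(gm) <= 1e-12) break
            if (gm > 0) hi <- mid else lo <- mid
          }
          out$draws[cells_c, yi, k] <- stats::plogis(eta + mid)
          fac$factor[row] <- mid
        }
      }
    }
  }
  list(draws = out, factors = fac)
}

#' Population-weighted national aggregates of draws
#'
#' @param draws a \code{prev_draws}.
#' @param world the world.
#' @return array country x year x draw of population-weighted means.
#' @export
national_aggregates <- function(draws, world) {
  ctab <- cell_table(world)
  countries <- sort(unique(ctab$country))
  K <- draws$n_draws
  res <- array(NA_real_, c(length(countries), length(draws$years), K),
               dimnames = list(countries, as.character(draws$years), NULL))
  for (yi in seq_along(draws$years)) {
    ymatch <- match(draws$years[yi], world$years)
    pop <- world$population[, ymatch]
    for (k in seq_len(K))
      res[, yi, k] <- country_aggregate(draws$draws[, yi, k], pop,
                                        ctab$country)[countries]
  }
  res
}
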