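#' Population-weighted aggregation of draws to admin units
#'
#' For every draw, the unit rate is the population-weighted mean of its
#' cells' rates; counts are rate x under-5 population. Summaries (mean and
#' 2.5/97.5 percentile uncertainty intervals, linear-interpolation
#' quantiles) are taken across the draw distribution, so within-draw spatial
#' correlation is preserved. Units with zero population get an undefined
#' (NA) rate and zero count.
#'
#' @param draws a \code{prev_draws}.
#' @param world the world (population, hierarchy).
#' @param level admin level to aggregate to: 0 (country), 1 or 2.
#' @return object of class \code{agg_est}: \code{summary} data.frame (unit,
#'   level, year, measure, mean, lower, upper, count_mean, count_lower,
#'   count_upper, population) and \code{rate_draws} / \code{count_draws}
#'   arrays (unit x year x draw).
#' @export
aggregate_draws <- function(draws, world, level = 2L) {
  stopifnot(inherits(draws, "prev_draws"), inherits(world, "world"))
  level <- as.integer(level)
  if (!level %in% 0:2) stop("level must be 0, 1 or 2", call. = FALSE)
  ctab <- cell_table(world)
  memb <- switch(as.character(level), "0" = ctab$country,
                 "1" = ctab$admin1, "2" = ctab$admin2)
  units <- world$admin$units$id[world$admin$units$level == level]
  if (!all(memb %in% units))
    stop("grid cells reference units missing from the hierarchy",
         call. = FALSE)
  K <- draws$n_draws; nyear <- length(draws$years)
  rate <- array(NA_real_, c(length(units), nyear, K),
                dimnames = list(units, as.character(draws$years), NULL))
  count <- rate
  popu <- matrix(NA_real_, length(units), nyear,
                 dimnames = list(units, as.character(draws$years)))
  for (yi in seq_len(nyear)) {
    ymatch <- match(draws$years[yi], world$years)
    if (is.na(ymatch))
      stop(sprintf("draw year %d absent from world", draws$years[yi]),
           call. = FALSE)
    pop <- world$population[, ymatch]
    den <- rowsum(pop, memb)[units, 1]
    popu[, yi] <- den
    slab <- matrix(draws$draws[, yi, ], nrow = dim(draws$draws)[1])
    num <- rowsum(slab * pop, memb)[units, , drop = FALSE]
    r <- num / den
    r[den == 0, ] <- NA_real_
    rate[, yi, ] <- r
    cnt <- num
    cnt[den == 0, ] <- 0
    count[, yi, ] <- cnt
  }
  q <- function(a, p) apply(a, c(1, 2), stats::quantile, probs = p,
                            type = 7, names = FALSE, na.rm = FALSE)
  summary <- data.frame(
    unit = rep(units, nyear),
    level = level,
    year = rep(draws$years, each = length(units)),
    measure = draws$measure,
    mean = as.vector(apply(rate, c(1, 2), mean)),
    lower = as.vector(q(rate, 0.025)),
    upper = as.vector(q(rate, 0.975)),
    count_mean = as.vector(apply(count, c(1, 2), mean)),
    count_lower = as.vector(q(count, 0.025)),
    count_upper = as.vector(q(count, 0.975)),
    population = as.vector(popu),
    stringsAsFactors = FALSE)
  structure(list(summary = summary, rate_draws = rate, count_draws = count,
                 population = popu, level = level, years = draws$years,
                 measure = draws$measure),
            class = "agg_est")
}

#' @export
print.agg_est <- function(x, ...) {
  cat(sprintf("Aggregated %s estimates: %d level-%d units x %d years x %d draws\n",
              x$measure, dim(x$rate_draws)[1], x$level,
              dim(x$rate_draws)[2], dim(x$rate_draws)[3]))
  invisible(x)
}

# country id of each aggregated unit, walking the hierarchy upward
unit_country <- function(units, world) {
  tab <- world$admin$units
  vapply(units, function(u) {
    i <- match(u, tab$id)
    while (tab$level[i] > 0L) i <- match(tab$parent_id[i], tab$id)
    tab$id[i]
  }, character(1))
}

#' Deviations of units from their country average
#'
#' For each unit-year the absolute deviation (unit minus country, rate
#' units), the ratio unit/country, and the relative deviation
#' (ratio - 1, in percent) are computed, both on draw means and per draw
#' (so statements of the form "higher in every draw" are reproducible).
#'
#' @param agg_units an \code{agg_est} at level 1 or 2.
#' @param agg_country an \code{agg_est} at level 0 for the same draws.
#' @param world the world (for unit-to-country lookup).
#' @return object of class \code{deviation_records}: \code{summary}
#'   data.frame (unit, year, measure, absolute, ratio, relative_pct) and
#'   per-draw arrays \code{absolute_draws}, \code{ratio_draws}.
#' @export
deviations <- function(agg_units, agg_country, world) {
  stopifnot(inherits(agg_units, "agg_est"), inherits(agg_country, "agg_est"),
            agg_country$level == 0L)
  units <- dimnames(agg_units$rate_draws)[[1]]
  co <- unit_country(units, world)
  cr <- agg_country$rate_draws[co, , , drop = FALSE]
  abs_d <- agg_units$rate_draws - cr
  ratio_d <- agg_units$rate_draws / cr
  ratio_d[cr == 0] <- NA_real_
  nyear <- dim(abs_d)[2]
  mean_unit <- apply(agg_units$rate_draws, c(1, 2), mean)
  mean_ctry <- apply(cr, c(1, 2), mean)
  ratio <- mean_unit / mean_ctry
  ratio[mean_ctry == 0] <- NA_real_
  summary <- data.frame(
    unit = rep(units, nyear),
    country = rep(co, nyear),
    year = rep(agg_units$years, each = length(units)),
    measure = agg_units$measure,
    absolute = as.vector(mean_unit - mean_ctry),
    ratio = as.vector(ratio),
    relative_pct = as.vector(100 * (ratio - 1)),
    stringsAsFactors = FALSE)
  structure(list(summary = summary, absolute_draws = abs_d,
                 ratio_draws = ratio_d),
            class = "deviation_records")
}

#' Population-weighted Gini coefficient
#'
#' \eqn{G = \sum_i \sum_j w_i w_j |x_i - x_j| / (2\mu)} with \eqn{w} the
#' normalized population shares and \eqn{\mu = \sum w_i x_i}; 0 is perfect
#' equality, 1 maximum inequality. Computed by the sorted cumulative-share
#' identity (O(n log n)); \eqn{\mu = 0} returns 0 by convention.
#'
#' @param rates non-negative unit rates.
#' @param populations positive unit populations (weights).
#' @return Gini coefficient in \[0, 1\].
#' @export
gini <- function(rates, populations) {
  if (length(rates) != length(populations))
    stop("rates and populations differ in length", call. = FALSE)
  keep <- populations > 0
  rates <- rates[keep]; populations <- populations[keep]
  if (length(rates) == 0L) stop("no units with positive population",
                                call. = FALSE)
  if (any(rates < 0)) stop("rates must be non-negative", call. = FALSE)
  w <- populations / sum(populations)
  mu <- sum(w * rates)
  if (mu == 0) return(0)
  o <- order(rates)
  x <- rates[o]; w <- w[o]
  cw <- cumsum(w)
  # sum_i w_i x_i (2 F_i - w_i) - mu, with F_i the inclusive cumulative weight
  (sum(w * x * (2 * cw - w)) / mu) - 1
}

#' Classify units by their change in rate between two years
#'
#' Annualised mode computes \eqn{(x_1/x_0)^{1/(y_1-y_0)} - 1} per draw;
#' total mode computes \eqn{x_1/x_0 - 1}. A unit is classed as
#' "declined" when its mean change is at or below \code{-threshold};
#' the share of units declining is computed per draw and summarized by its
#' mean and 2.5/97.5 percentiles. Unit-draws with a zero baseline are
#' excluded (their count is reported).
#'
#' @param agg an \code{agg_est}.
#' @param year0,year1 baseline and comparison years (present in the draws).
#' @param threshold decline threshold on the chosen scale (default 0.10).
#' @param mode "annualised" (default, per-year rate of change) or "total".
#' @return object of class \code{change_classes}: \code{units} data.frame
#'   (unit, mean_change, class), \code{share_declining} (mean, lower,
#'   upper), \code{n_excluded}.
#' @export
classify_change <- function(agg, year0, year1, threshold = 0.10,
                            mode = c("annualised", "total")) {
  stopifnot(inherits(agg, "agg_est"))
  mode <- match.arg(mode)
  i0 <- match(year0, agg$years); i1 <- match(year1, agg$years)
  if (is.na(i0) || is.na(i1))
    stop("both years must be present in the aggregation", call. = FALSE)
  x0 <- agg$rate_draws[, i0, , drop = TRUE]
  x1 <- agg$rate_draws[, i1, , drop = TRUE]
  if (is.null(dim(x0))) { x0 <- matrix(x0, nrow = 1); x1 <- matrix(x1, nrow = 1) }
  span <- year1 - year0
  change <- if (mode == "annualised") (x1 / x0)^(1 / span) - 1
            else x1 / x0 - 1
  bad <- !is.finite(change)          # zero or NA baselines
  n_excluded <- sum(bad)
  change[bad] <- NA_real_
  mean_change <- rowMeans(change, na.rm = TRUE)
  cls <- ifelse(is.nan(mean_change), NA_character_,
                ifelse(mean_change <= -threshold, "declined", "no decline"))
  share_k <- apply(change, 2, function(ch)
    mean(ch <= -threshold, na.rm = TRUE))
  units <- dimnames(agg$rate_draws)[[1]]
  structure(list(
    units = data.frame(unit = units, mean_change = mean_change,
                       class = cls, stringsAsFactors = FALSE),
    share_declining = c(
      mean = mean(share_k),
      lower = stats::quantile(share_k, 0.025, type = 7, names = FALSE),
      upper = stats::quantile(share_k, 0.975, type = 7, names = FALSE)),
    threshold = threshold, mode = mode, years = c(year0, year1),
    n_excluded = n_excluded), class = "change_classes")
}

#' @export
print.change_classes <- function(x, ...) {
  cat(sprintf("Change %d-%d (%s, threshold %.0f%%): %.1f%% of units declining (95%% UI %.1f-%.1f)\n",
              x$years[1], x$years[2], x$mode, 100 * x$threshold,
              100 * x$share_declining["mean"],
              100 * x$share_declining["lower"],
              100 * x$share_declining["upper"]))
  invisible(x)
}

#' Units holding the highest-rate share of the population
#'
#' Sorts units by mean rate (descending; ties broken by larger population,
#' then unit id) and accumulates population until the requested share of the
#' total is first reached; the boundary unit is included.
#'
#' @param agg an \code{agg_est}.
#' @param year the year to rank on.
#' @param fraction population share in (0, 1] (default 0.20).
#' @return data.frame of the selected units (unit, rate, population,
#'   cumulative_share), highest rate first.
#' @export
top_risk_units <- function(agg, year, fraction = 0.20) {
  stopifnot(inherits(agg, "agg_est"))
  if (fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]", call. = FALSE)
  yi <- match(year, agg$years)
  if (is.na(yi)) stop("year not present in the aggregation", call. = FALSE)
  rate <- apply(agg$rate_draws[, yi, , drop = FALSE], 1, mean)
  pop <- agg$population[, yi]
  keep <- pop > 0
  if (!any(keep)) stop("no units with positive population", call. = FALSE)
  d <- data.frame(unit = names(rate)[keep], rate = rate[keep],
                  population = pop[keep], stringsAsFactors = FALSE)
  d <- d[order(-d$rate, -d$population, d$unit), ]
  d$cumulative_share <- cumsum(d$population) / sum(d$population)
  take <- which(d$cumulative_share >= fraction)[1]
  out <- d[seq_len(take), ]
  rownames(out) <- NULL
  out
}
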