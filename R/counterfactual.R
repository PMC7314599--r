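#' Population-average relative risk of a dichotomous exposure
#'
#' s = 1 + x (rr - 1): the factor by which the exposed proportion x of the
#' population scales the average risk relative to a fully unexposed
#' population. With a category list (proportions p_i and level risks rr_i),
#' s generalizes to sum(p_i rr_i).
#'
#' @param x exposed proportion(s) in \[0, 1\].
#' @param rr risk ratio for the exposed level (> 0).
#' @return scalar(s) s >= min(1, rr).
#' @export
exposure_scalar <- function(x, rr) {
  if (any(x < 0 | x > 1)) stop("exposure must lie in [0, 1]", call. = FALSE)
  if (any(!is.finite(rr)) || any(rr <= 0))
    stop("risk ratio must be finite and positive", call. = FALSE)
  1 + x * (rr - 1)
}

# product over risk factors of s at the given year (cell vector), for a
# subset of groups
risk_product <- function(risk_factors, yi, groups = NULL) {
  sel <- risk_factors
  if (!is.null(groups))
    sel <- Filter(function(r) r$group %in% groups, sel)
  if (length(sel) == 0L) return(NULL)
  Reduce(`*`, lapply(sel, function(r)
    exposure_scalar(r$exposure[, yi], r$rr)))
}

#' Deaths averted by risk-factor improvements
#'
#' Counterfactual analysis comparing deaths in the comparison year to the
#' scenario in which risk-factor exposures had stayed at their baseline-year
#' levels, with each factor acting independently: per cell and draw,
#' D_cf = D_obs x prod_r s_r(x_{r,y0}) / s_r(x_{r,y1}). Population and
#' mortality stay at their comparison-year levels. WASH-only (group
#' "prevent") and CGF-only (group "protect") decompositions restrict the
#' product to that group; treatment-group factors (e.g. ORS) are excluded
#' unless \code{include_treat = TRUE}. Results are computed per draw and
#' summarized by mean and 2.5/97.5 percentiles.
#'
#' @param mortality_draws mortality \code{prev_draws} (deaths per
#'   child-year) containing \code{year1}.
#' @param world the world.
#' @param risk_factors list of risk factors (name, group, rr, exposure
#'   cell x year matrix) as produced by
#'   \code{\link{simulate_national_inputs}}.
#' @param year0 baseline exposure year (default first world year).
#' @param year1 comparison year (default last world year).
#' @param include_treat include treatment-group factors in the combined
#'   scenario (default FALSE).
#' @param dominance_share see \code{\link{dominant_driver}}.
#' @return object of class \code{cf_result}: \code{units} data.frame per
#'   admin2 unit (observed/counterfactual/averted deaths with UIs, per-group
#'   averted, averted per 1000 children, attributable fraction, dominant
#'   driver), plus cell-level mean surfaces.
#' @export
averted_deaths <- function(mortality_draws, world, risk_factors,
                           year0 = NULL, year1 = NULL,
                           include_treat = FALSE, dominance_share = 0.5) {
  stopifnot(inherits(mortality_draws, "prev_draws"),
            inherits(world, "world"))
  if (mortality_draws$measure != "mortality")
    stop("draws must carry the mortality measure", call. = FALSE)
  if (is.null(year0)) year0 <- world$years[1]
  if (is.null(year1)) year1 <- world$years[length(world$years)]
  yi0 <- match(year0, world$years); yi1 <- match(year1, world$years)
  if (is.na(yi0) || is.na(yi1))
    stop(sprintf("exposure year %d missing from world",
                 c(year0, year1)[which(is.na(c(yi0, yi1)))[1]]),
         call. = FALSE)
  di1 <- match(year1, mortality_draws$years)
  if (is.na(di1))
    stop(sprintf("mortality draws lack year %d", year1), call. = FALSE)

  groups_all <- if (include_treat) c("protect", "prevent", "treat")
                else c("protect", "prevent")
  ratio_for <- function(groups) {
    s0 <- risk_product(risk_factors, yi0, groups)
    s1 <- risk_product(risk_factors, yi1, groups)
    if (is.null(s0)) rep(1, n_cells(world)) else s0 / s1
  }
  ratio_comb <- ratio_for(groups_all)
  ratio_wash <- ratio_for("prevent")
  ratio_cgf <- ratio_for("protect")

  pop <- world$population[, yi1]
  K <- mortality_draws$n_draws
  rate <- mortality_draws$draws[, di1, , drop = TRUE]
  if (is.null(dim(rate))) rate <- matrix(rate, ncol = K)
  d_obs <- rate * pop                       # cell x draw deaths
  averted_comb <- d_obs * (ratio_comb - 1)
  averted_wash <- d_obs * (ratio_wash - 1)
  averted_cgf <- d_obs * (ratio_cgf - 1)

  ctab <- cell_table(world)
  units <- sort(unique(ctab$admin2))
  agg_u <- function(m) rowsum(m, ctab$admin2)[units, , drop = FALSE]
  obs_u <- agg_u(d_obs)
  av_comb_u <- agg_u(averted_comb)
  av_wash_u <- agg_u(averted_wash)
  av_cgf_u <- agg_u(averted_cgf)
  pop_u <- drop(rowsum(pop, ctab$admin2))[units]

  qs <- function(m, p) apply(m, 1, stats::quantile, probs = p, type = 7,
                             names = FALSE)
  lab <- dominant_driver(rowMeans(av_wash_u), rowMeans(av_cgf_u),
                         rowMeans(av_comb_u), dominance_share)
  paf <- 1 - 1 / risk_product(risk_factors, yi1, groups_all)
  paf_u <- drop(rowsum(paf * pop, ctab$admin2))[units] / pop_u

  units_df <- data.frame(
    unit = units, year = year1,
    observed_deaths = rowMeans(obs_u),
    counterfactual_deaths = rowMeans(obs_u + av_comb_u),
    averted_mean = rowMeans(av_comb_u),
    averted_lower = qs(av_comb_u, 0.025),
    averted_upper = qs(av_comb_u, 0.975),
    averted_per_1000 = 1000 * rowMeans(av_comb_u) / pop_u,
    averted_wash = rowMeans(av_wash_u),
    averted_cgf = rowMeans(av_cgf_u),
    dominant_driver = lab,
    attributable_fraction = paf_u,
    population = pop_u,
    stringsAsFactors = FALSE)
  rownames(units_df) <- NULL

  structure(list(
    units = units_df,
    totals = c(observed = mean(colSums(d_obs)),
               averted = mean(colSums(averted_comb)),
               averted_lower = stats::quantile(colSums(averted_comb), 0.025,
                                               type = 7, names = FALSE),
               averted_upper = stats::quantile(colSums(averted_comb), 0.975,
                                               type = 7, names = FALSE),
               averted_wash = mean(colSums(averted_wash)),
               averted_cgf = mean(colSums(averted_cgf))),
    cell_averted_mean = rowMeans(averted_comb),
    years = c(year0, year1), include_treat = include_treat),
    class = "cf_result")
}

#' @export
print.cf_result <- function(x, ...) {
  cat(sprintf("Counterfactual (%d exposures vs %d): %.0f deaths averted (95%% UI %.0f-%.0f)\n",
              x$years[1], x$years[2], x$totals["averted"],
              x$totals["averted_lower"], x$totals["averted_upper"]))
  cat(sprintf("  WASH-only %.0f, CGF-only %.0f; observed deaths %.0f\n",
              x$totals["averted_wash"], x$totals["averted_cgf"],
              x$totals["observed"]))
  invisible(x)
}

#' Population attributable fraction
#'
#' PAF = 1 - 1 / prod_r s_r(x_r), per cell-year, under independent
#' dichotomous risk factors.
#'
#' @param risk_factors list of risk factors with exposure surfaces.
#' @param world the world (for years).
#' @param year the year to evaluate at.
#' @param groups restrict to these risk groups (default: protect and
#'   prevent).
#' @return list: \code{cells} (per-cell PAF), \code{range} (min, max).
#' @export
attributable_fraction <- function(risk_factors, world, year,
                                  groups = c("protect", "prevent")) {
  yi <- match(year, world$years)
  if (is.na(yi)) stop("year missing from world", call. = FALSE)
  harmful <- vapply(Filter(function(r) r$group %in% groups, risk_factors),
                    function(r) r$rr, numeric(1))
  if (any(harmful < 1))
    warning("risk ratio < 1 supplied as harmful; PAF may be negative",
            call. = FALSE)
  s <- risk_product(risk_factors, yi, groups)
  if (is.null(s)) s <- rep(1, n_cells(world))
  paf <- 1 - 1 / s
  list(cells = paf, range = c(min = min(paf), max = max(paf)))
}

#' Dominant risk-factor group behind averted deaths
#'
#' Labels each unit with the group whose single-group averted deaths exceed
#' \code{dominance_share} of the combined averted total; "none" when neither
#' exceeds the share, when the combined total is not positive, or on a tie.
#'
#' @param wash_averted,cgf_averted,combined_averted numeric vectors per
#'   unit.
#' @param dominance_share share of the combined total a single group must
#'   exceed (default 0.5).
#' @return character vector of labels in \{"WASH", "CGF", "none"\}.
#' @export
dominant_driver <- function(wash_averted, cgf_averted, combined_averted,
                            dominance_share = 0.5) {
  lab <- rep("none", length(combined_averted))
  pos <- combined_averted > 0
  wash_dom <- pos & wash_averted > dominance_share * combined_averted
  cgf_dom <- pos & cgf_averted > dominance_share * combined_averted
  tie <- wash_dom & cgf_dom & (wash_averted == cgf_averted)
  lab[wash_dom & !cgf_dom] <- "WASH"
  lab[cgf_dom & !wash_dom] <- "CGF"
  lab[wash_dom & cgf_dom & !tie] <-
    ifelse(wash_averted[wash_dom & cgf_dom & !tie] >
             cgf_averted[wash_dom & cgf_dom & !tie], "WASH", "CGF")
  lab
}
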