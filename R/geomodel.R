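#' Inference settings for the geostatistical model
#'
#' @param optim_maxit Nelder-Mead iteration cap for the hyperparameter
#'   search.
#' @param optim_reltol relative tolerance of the hyperparameter search.
#' @param newton_maxit,newton_tol inner Newton iterations for the latent
#'   field mode.
#' @param nugget_min lower bound on the nugget sd (numerical floor).
#' @param max_cells refuse posterior surface sampling beyond this many
#'   cell-years (dense conditional covariance).
#' @export
geo_config <- function(optim_maxit = 150L, optim_reltol = 1e-5,
                       newton_maxit = 50L, newton_tol = 1e-8,
                       nugget_min = 1e-3, max_cells = 6000L) {
  list(optim_maxit = as.integer(optim_maxit), optim_reltol = optim_reltol,
       newton_maxit = as.integer(newton_maxit), newton_tol = newton_tol,
       nugget_min = nugget_min, max_cells = as.integer(max_cells))
}

#' Hyperparameter priors
#'
#' Log-normal on the spatial range (centred, by default, on a quarter of the
#' longer grid side), half-normal on the spatial and nugget standard
#' deviations, uniform(-1, 1) on the AR1 year-to-year correlation.
#'
#' @param range_meanlog,range_sdlog log-normal parameters for the range; a
#'   \code{NULL} meanlog is resolved from the grid at fit time.
#' @param sd_scale half-normal scale for the spatial sd.
#' @param nugget_scale half-normal scale for the nugget sd.
#' @export
geo_priors <- function(range_meanlog = NULL, range_sdlog = 0.75,
                       sd_scale = 1, nugget_scale = 0.5) {
  list(range_meanlog = range_meanlog, range_sdlog = range_sdlog,
       sd_scale = sd_scale, nugget_scale = nugget_scale)
}

# Simplex weights via softmax with the first coordinate pinned at 0.
softmax_w <- function(a) {
  e <- exp(c(0, a) - max(0, a))
  e / sum(e)
}

# Estimate stacking weights on the simplex by binomial likelihood of the
# simplex-weighted OOS logits (out-of-sample, so the weights do not reward
# learner overfit).
estimate_stack_weights <- function(oos_logit, cases, n) {
  J <- ncol(oos_logit)
  if (J == 1L) return(stats::setNames(1, colnames(oos_logit)))
  nll <- function(a) {
    w <- softmax_w(a)
    p <- clamp_prob(stats::plogis(drop(oos_logit %*% w)))
    -sum(stats::dbinom(cases, n, p, log = TRUE))
  }
  opt <- stats::optim(rep(0, J - 1L), nll, method = "BFGS",
                      control = list(maxit = 200))
  stats::setNames(softmax_w(opt$par), colnames(oos_logit))
}

# Covariance of the latent field at the observation cell-years:
# sigma^2 * Matern32(space) * AR1(time) + tau^2 I.
obs_covariance <- function(dmat, dyr, theta) {
  theta$sd^2 * matern32_cor(dmat, theta$range) * theta$rho^dyr +
    diag(theta$nugget^2, nrow(dmat))
}

# Laplace approximation to the binomial-GP posterior at the observation
# sites (Newton iterations on the latent field with prior covariance Sigma
# and linear-predictor offset). Returns the mode, the Cholesky factor of
# B = I + W^1/2 Sigma W^1/2, and the approximate log marginal likelihood.
laplace_fit <- function(Sigma, off, cases, n, u0 = NULL,
                        maxit = 50L, tol = 1e-8) {
  m <- length(cases)
  u <- if (is.null(u0)) rep(0, m) else u0
  psi_of <- function(u, alpha) {
    eta <- off + u
    # stable log(1 + e^eta)
    l1pe <- ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30))))
    sum(cases * eta - n * l1pe) - 0.5 * sum(alpha * u)
  }
  L <- NULL; sW <- NULL
  alpha <- rep(0, m)
  psi_old <- -Inf
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- off + u
    p <- stats::plogis(eta)
    Wd <- pmax(n * p * (1 - p), 1e-12)
    sW <- sqrt(Wd)
    B <- diag(m) + (sW %o% sW) * Sigma
    L <- chol(B)
    b <- Wd * u + (cases - n * p)
    Sb <- Sigma %*% b
    a_new <- b - sW * backsolve(L, forwardsolve(t(L), sW * Sb))
    u_new <- drop(Sigma %*% a_new)
    # step-halving on the penalized log-likelihood
    step <- 1
    repeat {
      u_try <- u + step * (u_new - u)
      a_try <- alpha + step * (a_new - alpha)
      psi_try <- psi_of(u_try, a_try)
      if (is.finite(psi_try) && (psi_try >= psi_old - 1e-12 || step < 1e-4))
        break
      step <- step / 2
    }
    u <- u_try; alpha <- a_try
    if (abs(psi_try - psi_old) < tol * (abs(psi_old) + 1)) {
      converged <- TRUE
      psi_old <- psi_try
      break
    }
    psi_old <- psi_try
  }
  # refresh factor at the final mode
  eta <- off + u
  p <- stats::plogis(eta)
  Wd <- pmax(n * p * (1 - p), 1e-12)
  sW <- sqrt(Wd)
  L <- chol(diag(m) + (sW %o% sW) * Sigma)
  logmarg <- psi_old - sum(log(diag(L)))
  list(u = u, alpha = alpha, sW = sW, L = L, logmarg = logmarg,
       converged = converged, iterations = it)
}

theta_from_raw <- function(raw, nugget_min) {
  list(range = exp(raw[1]), sd = exp(raw[2]), rho = tanh(raw[3]),
       nugget = nugget_min + exp(raw[4]))
}

log_prior_theta <- function(theta, raw, priors) {
  # densities on the natural scale plus transform Jacobians
  lp <- stats::dlnorm(theta$range, priors$range_meanlog, priors$range_sdlog,
                      log = TRUE) + raw[1]
  lp <- lp - theta$sd^2 / (2 * priors$sd_scale^2) + raw[2]
  lp <- lp - theta$nugget^2 / (2 * priors$nugget_scale^2) + raw[4]
  lp <- lp + log1p(-tanh(raw[3])^2)  # uniform rho, Jacobian only
  lp
}

#' Fit the Bayesian binomial space-time geostatistical model
#'
#' The model is \eqn{y_c \sim Binomial(N_c, logit^{-1}(\eta_c))} with
#' \eqn{\eta = \sum_j w_j logit(g_j) + u(s,t)}, where the \eqn{g_j} are the
#' stacked learner prevalence surfaces, \eqn{w} lies on the simplex, and
#' \eqn{u} is a Matern-3/2(space) x AR1(time) Gaussian process plus an iid
#' nugget. Stacking weights are estimated from the learners' out-of-sample
#' predictions; GP hyperparameters by MAP over a Laplace-approximated
#' marginal likelihood; the latent field posterior is the resulting Gaussian
#' approximation at the observed cell-years (empirical Bayes: hyperparameter
#' uncertainty is not propagated into the draws).
#'
#' @param records point survey records with positive \code{n_children}.
#' @param world the \code{world} the records refer to.
#' @param stack a \code{\link{fit_stack}} result covering the records and
#'   all prediction cell-years.
#' @param priors see \code{\link{geo_priors}}.
#' @param config see \code{\link{geo_config}}.
#' @param seed integer seed (recorded; the fit itself is deterministic).
#' @return object of class \code{geofit}.
#' @export
fit_geostat <- function(records, world, stack, priors = geo_priors(),
                        config = geo_config(), seed = 1L) {
  stopifnot(inherits(world, "world"), inherits(stack, "stack_result"))
  if (any(records$geometry_kind != "point"))
    stop("polygon records present; run resample_polygons() first",
         call. = FALSE)
  if (any(records$n_children <= 0))
    stop("records must have positive n_children", call. = FALSE)

  w <- estimate_stack_weights(qlogis(stack$oos), records$n_cases,
                              records$n_children)
  offset_grid <- Reduce(`+`, Map(function(wj, s) wj * stats::qlogis(s),
                                 w, stack$surfaces))
  # Out-of-sample stacked logit per record: the second stage is fit against
  # predictions from models that never saw the record's fold, so the
  # residual field carries the learners' honest generalization error
  # (full-data surfaces would understate it and shrink the GP variance).
  oos_logit <- drop(stats::qlogis(stack$oos) %*% w)

  # aggregate records to distinct cell-years (shared latent value)
  yi <- match(records$year, world$years)
  key <- paste(records$cell, yi)
  agg <- rowsum(cbind(cases = records$n_cases, n = records$n_children,
                      off_n = oos_logit * records$n_children), key)
  ord <- match(rownames(agg), key)
  obs <- data.frame(cell = records$cell[ord], yi = yi[ord],
                    cases = agg[, "cases"], n = agg[, "n"])
  rownames(obs) <- NULL
  m <- nrow(obs)

  ctab <- cell_table(world)
  rc <- cbind(ctab$row[obs$cell], ctab$col[obs$cell])
  dmat <- as.matrix(stats::dist(rc))
  dyr <- abs(outer(obs$yi, obs$yi, "-"))
  # children-weighted mean OOS offset within each cell-year
  off_obs <- agg[, "off_n"] / agg[, "n"]
  # stage-one uncertainty: mean-square discrepancy between the full-data
  # stacked surface and the out-of-sample stacked prediction at the data
  # sites estimates the learner surfaces' own error variance, which the GP
  # does not carry; added to the predictive variance when sampling surfaces
  off_full_obs <- offset_grid[cbind(obs$cell, obs$yi)]
  offset_var <- stats::weighted.mean((off_full_obs - off_obs)^2, obs$n)

  if (is.null(priors$range_meanlog))
    priors$range_meanlog <- log(max(world$grid$nrow, world$grid$ncol) / 4)

  warm <- new.env()
  warm$u <- NULL
  neg_obj <- function(raw) {
    theta <- theta_from_raw(raw, config$nugget_min)
    if (theta$range > 20 * max(world$grid$nrow, world$grid$ncol) ||
        theta$sd > 25 || abs(theta$rho) > 1 - 1e-8) return(1e10)
    Sigma <- obs_covariance(dmat, dyr, theta)
    lf <- tryCatch(
      laplace_fit(Sigma, off_obs, obs$cases, obs$n, u0 = warm$u,
                  maxit = config$newton_maxit, tol = config$newton_tol),
      error = function(e) NULL)
    if (is.null(lf)) return(1e10)
    warm$u <- lf$u
    -(lf$logmarg + log_prior_theta(theta, raw, priors))
  }

  raw0 <- c(priors$range_meanlog, log(0.5), atanh(0.8), log(0.1))
  opt <- stats::optim(raw0, neg_obj, method = "Nelder-Mead",
                      control = list(maxit = config$optim_maxit,
                                     reltol = config$optim_reltol))
  theta <- theta_from_raw(opt$par, config$nugget_min)

  # curvature of the hyperparameter posterior at the MAP, for propagating
  # hyperparameter uncertainty into the surface draws
  hess <- tryCatch(stats::optimHess(opt$par, neg_obj), error = function(e) NULL)

  Sigma <- obs_covariance(dmat, dyr, theta)
  lf <- laplace_fit(Sigma, off_obs, obs$cases, obs$n, u0 = warm$u,
                    maxit = config$newton_maxit, tol = config$newton_tol)
  # posterior covariance of the latent field at observation sites:
  # S = Sigma - Sigma W^1/2 B^-1 W^1/2 Sigma
  V <- forwardsolve(t(lf$L), lf$sW * Sigma)
  S <- Sigma - crossprod(V)
  S <- (S + t(S)) / 2

  structure(list(
    w = w, theta = theta, obs = obs, offset_grid = offset_grid,
    off_obs = off_obs, offset_var = offset_var,
    u_hat = lf$u, post_cov = S,
    raw_map = opt$par, raw_hess = hess,
    dmat = dmat, dyr = dyr,
    logmarg = lf$logmarg,
    converged = opt$convergence == 0L && lf$converged,
    optim_value = opt$value, optim_counts = opt$counts,
    grid = world$grid, years = world$years,
    cell_rowcol = cbind(row = ctab$row, col = ctab$col),
    cell_admin = ctab[, c("country", "admin1", "admin2")],
    n_records = nrow(records), config = config, priors = priors,
    seed = as.integer(seed)
  ), class = "geofit")
}

#' @export
print.geofit <- function(x, ...) {
  cat("Binomial space-time geostatistical model (Laplace approximation)\n")
  cat(sprintf("  %d records at %d distinct cell-years on a %d x %d x %d grid\n",
              x$n_records, nrow(x$obs), x$grid$nrow, x$grid$ncol,
              length(x$years)))
  cat(sprintf("  stacking weights: %s\n",
              paste(sprintf("%s=%.3f", names(x$w), x$w), collapse = ", ")))
  cat(sprintf("  GP: range %.2f cells, sd %.3f, AR1 rho %.3f, nugget sd %.3f\n",
              x$theta$range, x$theta$sd, x$theta$rho, x$theta$nugget))
  cat(sprintf("  converged: %s\n", x$converged))
  invisible(x)
}

#' @export
summary.geofit <- function(object, ...) {
  structure(list(fit = object), class = "summary.geofit")
}

#' @export
print.summary.geofit <- function(x, ...) {
  print(x$fit)
  obs <- x$fit$obs
  p_hat <- stats::plogis(x$fit$off_obs + x$fit$u_hat)
  cat(sprintf("  observed prevalence: %.4f; fitted at obs sites: %.4f\n",
              sum(obs$cases) / sum(obs$n),
              stats::weighted.mean(p_hat, obs$n)))
  cat(sprintf("  approximate log marginal likelihood: %.2f\n", x$fit$logmarg))
  invisible(x)
}

#' @export
coef.geofit <- function(object, ...) {
  c(stats::setNames(object$w, paste0("w.", names(object$w))),
    range = object$theta$range, sd = object$theta$sd,
    rho = object$theta$rho, nugget = object$theta$nugget)
}

# Cross-covariance between all grid cell-years and the observation sites,
# and the grid's own covariance, under the fitted kernel. Grid points that
# coincide with observation sites share their latent value (the nugget term
# appears on the matching entries).
grid_cross_cov <- function(fit) {
  nr <- fit$grid$nrow; nc <- fit$grid$ncol
  ncell <- nr * nc; nyear <- length(fit$years)
  th <- fit$theta
  # grid-to-obs distances at cell level, expanded over years below
  dcell <- sqrt(outer(fit$cell_rowcol[, "row"],
                      fit$cell_rowcol[fit$obs$cell, "row"], "-")^2 +
                outer(fit$cell_rowcol[, "col"],
                      fit$cell_rowcol[fit$obs$cell, "col"], "-")^2)
  Cs <- matern32_cor(dcell, th$range)          # ncell x m
  m <- nrow(fit$obs)
  Sgo <- matrix(0, ncell * nyear, m)
  for (t in seq_len(nyear)) {
    rows <- (t - 1L) * ncell + seq_len(ncell)
    Sgo[rows, ] <- th$sd^2 * Cs *
      matrix(th$rho^abs(t - fit$obs$yi), ncell, m, byrow = TRUE)
  }
  # shared nugget where grid point == observation point
  idx_obs <- (fit$obs$yi - 1L) * ncell + fit$obs$cell
  Sgo[cbind(idx_obs, seq_len(m))] <- Sgo[cbind(idx_obs, seq_len(m))] +
    th$nugget^2
  list(Sgo = Sgo)
}

# Conditional joint draws of the latent field on the full grid for one
# hyperparameter value: Laplace posterior at the observation sites, then
# exact conditional simulation to every cell-year.
conditional_surface_draws <- function(fit, theta, K) {
  ncell <- fit$grid$nrow * fit$grid$ncol
  nyear <- length(fit$years)
  N <- ncell * nyear
  m <- nrow(fit$obs)

  if (identical(theta, fit$theta)) {
    u_hat <- fit$u_hat
    S <- fit$post_cov
  } else {
    Sigma <- obs_covariance(fit$dmat, fit$dyr, theta)
    lf <- laplace_fit(Sigma, fit$off_obs, fit$obs$cases, fit$obs$n,
                      u0 = fit$u_hat, maxit = fit$config$newton_maxit,
                      tol = fit$config$newton_tol)
    V <- forwardsolve(t(lf$L), lf$sW * Sigma)
    S <- Sigma - crossprod(V)
    S <- (S + t(S)) / 2
    u_hat <- lf$u
  }
  Ls <- chol_jitter(S)
  Uo <- u_hat + t(Ls) %*% matrix(stats::rnorm(m * K), m, K)

  tmp_fit <- fit
  tmp_fit$theta <- theta
  cc <- grid_cross_cov(tmp_fit)
  dgrid <- as.matrix(stats::dist(fit$cell_rowcol))
  Cs_gg <- matern32_cor(dgrid, theta$range)
  Ct <- theta$rho^abs(outer(seq_len(nyear), seq_len(nyear), "-"))
  Sgg <- theta$sd^2 * (Ct %x% Cs_gg) + diag(theta$nugget^2, N)

  Soo <- obs_covariance(fit$dmat, fit$dyr, theta)
  Loo <- chol_jitter(Soo)
  A <- t(backsolve(Loo, forwardsolve(t(Loo), t(cc$Sgo))))
  Cc <- Sgg - A %*% t(cc$Sgo)
  Cc <- (Cc + t(Cc)) / 2
  # stage-one (learner surface) error variance enters the prediction
  ov <- if (is.null(fit$offset_var)) 0 else fit$offset_var
  Cc <- Cc + diag(ov, N)
  Lc <- chol_jitter(Cc, jitter = 1e-6)

  A %*% Uo + t(Lc) %*% matrix(stats::rnorm(N * K), N, K)
}

# Draw hyperparameter vectors from a multivariate-t (df = 4) approximation
# of their posterior, centred at the MAP with scale from the inverse
# curvature. The heavier tails acknowledge the right skew of the
# variance-parameter posterior that a Gaussian at the mode misses. Falls
# back to the MAP when the curvature is unavailable.
draw_hyperparameters <- function(fit, n_hyper, df = 4) {
  if (n_hyper <= 1L || is.null(fit$raw_hess))
    return(list(fit$theta))
  H <- (fit$raw_hess + t(fit$raw_hess)) / 2
  ev <- eigen(H, symmetric = TRUE)
  vals <- pmax(ev$values, 1e-6 * max(abs(ev$values), 1))
  # scale = H^-1 via the repaired eigenvalues
  half <- ev$vectors %*% diag(1 / sqrt(vals), length(vals))
  p <- length(fit$raw_map)
  lapply(seq_len(n_hyper), function(i) {
    z <- stats::rnorm(p) * sqrt(df / stats::rchisq(1, df))
    raw <- fit$raw_map + drop(half %*% z)
    theta_from_raw(raw, fit$config$nugget_min)
  })
}

#' Joint posterior draws of the prevalence surface
#'
#' Draws the latent field at the observation sites from its Gaussian
#' (Laplace) posterior and extends each draw to every grid cell-year by
#' exact conditional simulation, so a draw index selects one coherent
#' surface across all cells and years. Hyperparameter uncertainty is
#' propagated by mixing the draws over \code{n_hyper} values sampled from
#' the Gaussian approximation of the hyperparameter posterior (the GP
#' variance parameters are weakly identified from cluster-level binomial
#' data, so conditioning on the MAP alone understates interval width).
#'
#' @param fit a \code{geofit}.
#' @param n_draws number of joint draws (default 250; must be >= 2).
#' @param seed integer RNG seed.
#' @param n_hyper number of hyperparameter values to mix over (default 8;
#'   1 conditions on the MAP estimate).
#' @return object of class \code{prev_draws}: array \code{cell x year x
#'   draw} of prevalence plus grid/year metadata.
#' @export
sample_posterior <- function(fit, n_draws = 250L, seed = 1L, n_hyper = 8L) {
  stopifnot(inherits(fit, "geofit"))
  if (n_draws < 2L)
    stop("n_draws must be at least 2 (intervals are undefined otherwise)",
         call. = FALSE)
  set.seed(as.integer(seed))
  ncell <- fit$grid$nrow * fit$grid$ncol
  nyear <- length(fit$years)
  N <- ncell * nyear
  if (N > fit$config$max_cells)
    stop(sprintf("grid has %d cell-years; exceeds max_cells = %d",
                 N, fit$config$max_cells), call. = FALSE)

  n_hyper <- max(1L, min(as.integer(n_hyper), n_draws))
  thetas <- draw_hyperparameters(fit, n_hyper)
  sizes <- rep(n_draws %/% length(thetas), length(thetas))
  extra <- n_draws %% length(thetas)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L

  Ug <- matrix(NA_real_, N, n_draws)
  at <- 0L
  for (i in seq_along(thetas)) {
    if (sizes[i] == 0L) next
    Ug[, at + seq_len(sizes[i])] <-
      conditional_surface_draws(fit, thetas[[i]], sizes[i])
    at <- at + sizes[i]
  }
  off <- as.vector(fit$offset_grid)
  P <- stats::plogis(off + Ug)
  draws <- array(P, dim = c(ncell, nyear, n_draws),
                 dimnames = list(NULL, as.character(fit$years), NULL))
  new_draws(draws, measure = "prevalence", years = fit$years,
            grid = fit$grid, seed = as.integer(seed))
}

#' Build a draw cube from an array
#'
#' Wraps a cell x year x draw array as a \code{prev_draws} object, e.g. for
#' feeding externally produced draws through the raking, aggregation and
#' counterfactual stages.
#'
#' @param arr numeric array \code{cell x year x draw}.
#' @param world the \code{world} the cells refer to.
#' @param measure "prevalence", "incidence" or "mortality".
#' @param years calendar years of the second dimension (default: the
#'   world's years).
#' @return a \code{prev_draws} object.
#' @export
as_prev_draws <- function(arr, world, measure = "prevalence",
                          years = world$years) {
  stopifnot(inherits(world, "world"), length(dim(arr)) == 3L)
  if (dim(arr)[1] != n_cells(world))
    stop("array's first dimension must match the world's cell count",
         call. = FALSE)
  if (dim(arr)[2] != length(years))
    stop("array's second dimension must match the years", call. = FALSE)
  dimnames(arr) <- list(NULL, as.character(years), NULL)
  new_draws(arr, measure = measure, years = years, grid = world$grid)
}

new_draws <- function(arr, measure, years, grid, seed = NA_integer_) {
  structure(list(draws = arr, measure = measure, years = years,
                 grid = grid, n_draws = dim(arr)[3], seed = seed),
            class = "prev_draws")
}

#' @export
print.prev_draws <- function(x, ...) {
  cat(sprintf("%s draws: %d cells x %d years x %d draws, mean %.4g\n",
              x$measure, dim(x$draws)[1], dim(x$draws)[2], x$n_draws,
              mean(x$draws)))
  invisible(x)
}

#' Posterior mean surface
#' @param draws a \code{prev_draws} object.
#' @return cell x year matrix of per-cell-year draw means.
#' @export
draw_mean <- function(draws) {
  stopifnot(inherits(draws, "prev_draws"))
  apply(draws$draws, c(1, 2), mean)
}

#' Pointwise uncertainty interval across draws
#' @param draws a \code{prev_draws} object.
#' @param probs two probabilities (default the 2.5th and 97.5th percentiles);
#'   linear-interpolation (type 7) quantiles.
#' @return list of two cell x year matrices, \code{lower} and \code{upper}.
#' @export
draw_interval <- function(draws, probs = c(0.025, 0.975)) {
  stopifnot(inherits(draws, "prev_draws"), length(probs) == 2L)
  lo <- apply(draws$draws, c(1, 2), stats::quantile, probs = probs[1],
              type = 7, names = FALSE)
  hi <- apply(draws$draws, c(1, 2), stats::quantile, probs = probs[2],
              type = 7, names = FALSE)
  list(lower = lo, upper = hi)
}

#' @export
predict.geofit <- function(object, type = c("response", "link"), ...) {
  type <- match.arg(type)
  ncell <- object$grid$nrow * object$grid$ncol
  nyear <- length(object$years)
  cc <- grid_cross_cov(object)
  Soo <- obs_covariance(as.matrix(stats::dist(
    object$cell_rowcol[object$obs$cell, , drop = FALSE])),
    abs(outer(object$obs$yi, object$obs$yi, "-")), object$theta)
  Loo <- chol_jitter(Soo)
  ug <- drop(cc$Sgo %*% backsolve(Loo, forwardsolve(t(Loo), object$u_hat)))
  eta <- as.vector(object$offset_grid) + ug
  out <- matrix(if (type == "response") stats::plogis(eta) else eta,
                ncell, nyear,
                dimnames = list(NULL, as.character(object$years)))
  out
}

#' @export
simulate.geofit <- function(object, nsim = 250L, seed = 1L, ...) {
  sample_posterior(object, n_draws = nsim, seed = seed)
}

#' @export
fitted.geofit <- function(object, ...) {
  stats::plogis(object$off_obs + object$u_hat)
}

#' @export
residuals.geofit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  p <- fitted(object)
  obs_rate <- object$obs$cases / object$obs$n
  r <- obs_rate - p
  if (type == "pearson")
    r <- (object$obs$cases - object$obs$n * p) /
      sqrt(object$obs$n * p * (1 - p))
  r
}

#' @export
plot.geofit <- function(x, year = NULL, ...) {
  mu <- predict(x)
  yi <- if (is.null(year)) ncol(mu) else match(year, x$years)
  z <- matrix(mu[, yi], x$grid$ncol, x$grid$nrow)  # transpose for image()
  graphics::image(seq_len(x$grid$ncol), seq_len(x$grid$nrow),
                  z[, rev(seq_len(x$grid$nrow)), drop = FALSE],
                  xlab = "column", ylab = "row (S to N)",
                  main = sprintf("Posterior mean prevalence, %s",
                                 x$years[yi]), ...)
  invisible(x)
}

#' Holdout-validation metrics
#'
#' Mean error (bias, observed minus predicted), root-mean-square error,
#' empirical coverage of the supplied 95\% prediction intervals, and Pearson
#' correlation between observed and predicted values.
#'
#' @param observed,predicted numeric vectors.
#' @param lower,upper prediction interval bounds (optional; coverage is NA
#'   without them).
#' @return named numeric vector: bias, rmse, coverage, correlation, n.
#' @export
cv_metrics <- function(observed, predicted, lower = NULL, upper = NULL) {
  err <- observed - predicted
  cov <- if (is.null(lower) || is.null(upper)) NA_real_
         else mean(observed >= lower & observed <= upper)
  corr <- if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) NA_real_
          else stats::cor(observed, predicted)
  c(bias = mean(err), rmse = sqrt(mean(err^2)), coverage = cov,
    correlation = corr, n = length(observed))
}

#' Source-stratified spatial cross-validation
#'
#' Folds hold out whole admin2-level groups of clusters; the full stacking +
#' geostatistical pipeline is refit on each training set and evaluated on
#' the held-out records. Coverage is measured against the posterior
#' predictive distribution of the cluster case fraction (binomial sampling
#' noise included).
#'
#' @param records point survey records.
#' @param world the world.
#' @param n_folds folds (default 5); admin2 groups are randomized to folds.
#' @param learners learner set for \code{\link{fit_stack}}.
#' @param priors,config passed to \code{\link{fit_geostat}}.
#' @param n_draws posterior draws per fold for the predictive intervals.
#' @param seed integer RNG seed.
#' @return object of class \code{cv_report}: per-fold and pooled metric
#'   table plus the per-record holdout table.
#' @export
cross_validate <- function(records, world, n_folds = 5L,
                           learners = c("penalized-linear", "tree-ensemble",
                                        "spline-additive"),
                           priors = geo_priors(), config = geo_config(),
                           n_draws = 100L, seed = 1L) {
  stopifnot(inherits(world, "world"))
  set.seed(as.integer(seed))
  ctab <- cell_table(world)
  grp <- ctab$admin2[records$cell]
  groups <- unique(grp)
  if (length(groups) < n_folds)
    stop("fewer distinct admin2 groups than folds", call. = FALSE)
  grp_fold <- stats::setNames(
    rep_len(seq_len(n_folds), length(groups))[sample(length(groups))],
    groups)
  fold <- unname(grp_fold[grp])

  per_rec <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    test <- fold == f
    if (!any(test)) {
      warning(sprintf("fold %d holds no records; skipped", f), call. = FALSE)
      next
    }
    tr_rec <- records[!test, , drop = FALSE]
    te_rec <- records[test, , drop = FALSE]
    st <- fit_stack(tr_rec, world, n_folds = min(n_folds, 5L),
                    learners = learners, seed = seed + f)
    gf <- fit_geostat(tr_rec, world, st, priors = priors, config = config,
                      seed = seed + f)
    dr <- sample_posterior(gf, n_draws = max(2L, n_draws), seed = seed + f)
    yi <- match(te_rec$year, world$years)
    pmat <- dr$draws[cbind(rep(te_rec$cell, dr$n_draws),
                           rep(yi, dr$n_draws),
                           rep(seq_len(dr$n_draws), each = nrow(te_rec)))]
    pmat <- matrix(pmat, nrow(te_rec), dr$n_draws)
    pred <- rowMeans(pmat)
    # posterior predictive case fraction per record
    ysim <- matrix(stats::rbinom(length(pmat),
                                 size = rep(te_rec$n_children, dr$n_draws),
                                 prob = pmat),
                   nrow(te_rec), dr$n_draws) / te_rec$n_children
    lo <- apply(ysim, 1, stats::quantile, probs = 0.025, type = 7,
                names = FALSE)
    hi <- apply(ysim, 1, stats::quantile, probs = 0.975, type = 7,
                names = FALSE)
    per_rec[[f]] <- data.frame(
      index = which(test), fold = f,
      observed = te_rec$n_cases / te_rec$n_children,
      predicted = pred, lower = lo, upper = hi,
      n_children = te_rec$n_children, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, per_rec)
  fold_metrics <- do.call(rbind, lapply(split(tab, tab$fold), function(d)
    c(fold = d$fold[1],
      cv_metrics(d$observed, d$predicted, d$lower, d$upper))))
  pooled <- cv_metrics(tab$observed, tab$predicted, tab$lower, tab$upper)
  structure(list(folds = as.data.frame(fold_metrics), pooled = pooled,
                 records = tab, n_folds = n_folds, seed = as.integer(seed)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Source-stratified cross-validation (%d folds, %d held-out records)\n",
              x$n_folds, nrow(x$records)))
  cat(sprintf("  pooled: bias %.4f, RMSE %.4f, 95%% coverage %.3f, correlation %.3f\n",
              x$pooled["bias"], x$pooled["rmse"], x$pooled["coverage"],
              x$pooled["correlation"]))
  invisible(x)
}
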