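#' Stacked generalization of component learners
#'
#' Fits a set of component learners (penalized linear, tree ensemble,
#' additive splines) to cluster-level prevalence data and produces, for every
#' record, an out-of-sample (OOS) prediction from a fit that excluded the
#' record's fold, plus a full-data prediction surface for every cell-year.
#' The OOS predictions are what the second-stage geostatistical model uses to
#' weight the learners; the full surfaces enter as its covariates.
#'
#' Folds are a random partition of survey sources (all records of a source
#' share a fold), mirroring source-stratified validation. Learners that fail
#' to fit are dropped with a warning; if all fail, an error is raised.
#'
#' @param records point survey records (run \code{\link{resample_polygons}}
#'   first if any polygon records are present).
#' @param world the \code{world} supplying covariate surfaces.
#' @param covariates names of covariates to use (default: all).
#' @param n_folds number of CV folds (default 5).
#' @param learners subset of \code{c("penalized-linear", "tree-ensemble",
#'   "spline-additive")}.
#' @param seed integer RNG seed.
#' @return object of class \code{stack_result}: \code{learners},
#'   \code{oos} (records x learners matrix of OOS prevalence predictions),
#'   \code{folds} (per-record fold id), \code{surfaces} (list of cell x year
#'   prevalence matrices, one per learner).
#' @export
fit_stack <- function(records, world, covariates = NULL, n_folds = 5L,
                      learners = c("penalized-linear", "tree-ensemble",
                                   "spline-additive"),
                      seed = 1L) {
  stopifnot(inherits(world, "world"))
  all_learners <- c("penalized-linear", "tree-ensemble", "spline-additive")
  if (length(learners) == 3L && identical(learners, all_learners)) {
    # default: use all
  } else {
    learners <- unname(vapply(learners, match.arg, character(1),
                              choices = all_learners))
  }
  if (length(learners) == 0L) stop("no learners requested", call. = FALSE)
  if (nrow(records) < n_folds)
    stop("fewer records than folds", call. = FALSE)
  set.seed(as.integer(seed))

  X <- record_covariates(records, world)
  if (!is.null(covariates)) X <- X[, covariates, drop = FALSE]
  sources <- unique(records$source_id)
  src_fold <- stats::setNames(
    rep_len(seq_len(n_folds), length(sources))[sample(length(sources))],
    sources)
  folds <- unname(src_fold[records$source_id])

  # grid design matrix, one block per year
  nyear <- length(world$years); ncell <- n_cells(world)
  grid_X <- do.call(rbind, lapply(seq_len(nyear), function(yi)
    vapply(world$covariates, function(m) m[, yi], numeric(ncell))))
  colnames(grid_X) <- names(world$covariates)
  if (!is.null(covariates)) grid_X <- grid_X[, covariates, drop = FALSE]

  fitters <- list(
    "penalized-linear" = fit_penalized_linear,
    "tree-ensemble" = fit_tree_ensemble,
    "spline-additive" = fit_spline_additive)[learners]

  oos <- matrix(NA_real_, nrow(records), length(learners),
                dimnames = list(NULL, learners))
  surfaces <- vector("list", length(learners))
  names(surfaces) <- learners
  ok <- rep(TRUE, length(learners))
  for (j in seq_along(learners)) {
    fit_fun <- fitters[[j]]
    res <- tryCatch({
      for (f in sort(unique(folds))) {
        tr <- folds != f
        set.seed(as.integer(seed) + f)  # same stream for identical learners
        model <- fit_fun(X[tr, , drop = FALSE], records$n_cases[tr],
                         records$n_children[tr])
        oos[!tr, j] <- model$predict(X[!tr, , drop = FALSE])
      }
      set.seed(as.integer(seed))
      full <- fit_fun(X, records$n_cases, records$n_children)
      pred <- full$predict(grid_X)
      surfaces[[j]] <- matrix(pred, ncell, nyear,
                              dimnames = list(NULL, as.character(world$years)))
      TRUE
    }, error = function(e) {
      warning(sprintf("learner '%s' failed and was dropped: %s",
                      learners[j], conditionMessage(e)), call. = FALSE)
      FALSE
    })
    ok[j] <- isTRUE(res)
  }
  if (!any(ok)) stop("all learners failed to fit", call. = FALSE)
  oos <- clamp_prob(oos[, ok, drop = FALSE])
  surfaces <- lapply(surfaces[ok], clamp_prob)
  structure(list(learners = learners[ok], oos = oos, folds = folds,
                 surfaces = surfaces, seed = as.integer(seed)),
            class = "stack_result")
}

#' @export
print.stack_result <- function(x, ...) {
  cat(sprintf("Stacked ensemble: %d learners, %d records, %d folds\n",
              length(x$learners), nrow(x$oos), length(unique(x$folds))))
  cat("  learners:", paste(x$learners, collapse = ", "), "\n")
  invisible(x)
}

clamp_prob <- function(p, eps = 1e-6) {
  out <- pmin(1 - eps, pmax(eps, p))
  attributes(out) <- attributes(p)
  out
}

# Each fitter returns list(predict = function(Xnew) -> prevalence in (0,1)).

# Elastic net on the exact binomial likelihood (two-column count response;
# an empirical-logit working response would be biased upward at the small
# per-cluster case counts typical of low-prevalence surveys); lambda by
# internal cross-validation.
fit_penalized_linear <- function(X, cases, n) {
  if (sum(cases) == 0 || sum(cases) == sum(n)) {
    p0 <- (sum(cases) + 0.5) / (sum(n) + 1)
    return(list(predict = function(Xnew) rep(p0, nrow(Xnew))))
  }
  y <- cbind(n - cases, cases)
  cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 0.5,
                          nfolds = 5)
  list(predict = function(Xnew)
    drop(stats::predict(cv, newx = as.matrix(Xnew), s = "lambda.min",
                        type = "response")))
}

# Probability forest on case/non-case expanded rows (two rows per cluster,
# weighted by case and non-case counts): robust to very unequal cluster
# sizes without assuming a rate-scale likelihood.
fit_tree_ensemble <- function(X, cases, n) {
  keep_pos <- cases > 0
  keep_neg <- (n - cases) > 0
  df <- data.frame(rbind(X[keep_pos, , drop = FALSE],
                         X[keep_neg, , drop = FALSE]))
  df$.y <- factor(rep(c("case", "none"), c(sum(keep_pos), sum(keep_neg))),
                  levels = c("none", "case"))
  w <- c(cases[keep_pos], (n - cases)[keep_neg])
  if (length(unique(df$.y)) < 2L) {
    p0 <- sum(cases) / sum(n)
    return(list(predict = function(Xnew) rep(p0, nrow(Xnew))))
  }
  rf <- ranger::ranger(.y ~ ., data = df, case.weights = w,
                       probability = TRUE, num.trees = 300,
                       min.node.size = 20, respect.unordered.factors = TRUE,
                       num.threads = 1, seed = 1L)
  list(predict = function(Xnew) {
    pr <- stats::predict(rf, data = data.frame(Xnew),
                         num.threads = 1)$predictions
    pr[, "case"]
  })
}

# Binomial GAM with thin-plate smooths on each covariate; smooth basis kept
# small so the fit stays fast at desk scale.
fit_spline_additive <- function(X, cases, n) {
  df <- data.frame(X)
  vars <- colnames(df)
  df$.cases <- cases
  df$.fails <- n - cases
  k <- max(4, min(8, floor(nrow(df) / (3 * length(vars)))))
  usable <- vars[vapply(df[vars], function(v) length(unique(v)) > k,
                        logical(1))]
  lin <- setdiff(vars, usable)
  rhs <- paste(c(sprintf("s(%s, k = %d)", usable, k), lin), collapse = " + ")
  if (rhs == "") rhs <- "1"
  form <- stats::as.formula(paste("cbind(.cases, .fails) ~", rhs))
  g <- mgcv::gam(form, family = stats::binomial(), data = df,
                 method = "REML")
  list(predict = function(Xnew)
    as.numeric(stats::predict(g, newdata = data.frame(Xnew),
                              type = "response")))
}
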