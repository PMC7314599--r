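#' Variance inflation factors
#'
#' VIF_j = 1/(1 - R^2_j) with R^2_j from the least-squares regression of
#' column j on all other columns (with intercept). A column that is constant,
#' or perfectly explained by the others, reports an infinite VIF.
#'
#' @param x numeric matrix (or data.frame) with at least two named columns
#'   and at least columns + 1 rows.
#' @return named numeric vector of VIF values (>= 1 or Inf).
#' @export
compute_vif <- function(x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (ncol(x) < 2L) stop("need at least two columns", call. = FALSE)
  if (nrow(x) < ncol(x) + 1L)
    stop("need at least columns + 1 rows for the VIF regressions",
         call. = FALSE)
  if (!all(is.finite(x))) stop("covariate matrix has non-finite entries",
                               call. = FALSE)
  vif <- vapply(seq_len(ncol(x)), function(j) {
    y <- x[, j]
    vy <- sum((y - mean(y))^2)
    if (vy == 0) return(Inf)
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), y)
    rss <- sum(fit$residuals^2)
    r2 <- 1 - rss / vy
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(x)
  vif
}

#' Iterative VIF covariate filter
#'
#' Recomputes all VIFs and drops the covariate with the largest value (ties
#' broken by alphabetical name order) until every remaining VIF is at or
#' below the threshold. At least one covariate is always retained.
#'
#' @param x covariate matrix with named columns.
#' @param threshold VIF threshold (default 3).
#' @return object of class \code{vif_report}: \code{retained} names,
#'   \code{dropped} names in drop order, \code{vif} final VIF values, and
#'   \code{history} (per-step VIF tables).
#' @export
vif_filter <- function(x, threshold = 3) {
  x <- as.matrix(x)
  if (ncol(x) == 0L) stop("empty covariate matrix", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  dropped <- character(0)
  history <- list()
  keep <- colnames(x)
  while (length(keep) > 1L) {
    vif <- compute_vif(x[, keep, drop = FALSE])
    history[[length(history) + 1L]] <- vif
    if (max(vif) <= threshold) break
    worst <- names(vif)[vif == max(vif)]
    worst <- sort(worst)[1L]           # alphabetical tie-break
    dropped <- c(dropped, worst)
    keep <- setdiff(keep, worst)
  }
  final <- if (length(keep) > 1L) compute_vif(x[, keep, drop = FALSE])
           else stats::setNames(1, keep)
  structure(list(retained = keep, dropped = dropped, vif = final,
                 threshold = threshold, history = history),
            class = "vif_report")
}

#' @export
print.vif_report <- function(x, ...) {
  cat(sprintf("VIF filter (threshold %g): retained %d, dropped %d\n",
              x$threshold, length(x$retained), length(x$dropped)))
  if (length(x$dropped))
    cat("  dropped (in order):", paste(x$dropped, collapse = ", "), "\n")
  print(round(x$vif, 3))
  invisible(x)
}

# Largest-remainder apportionment of integer `total` over `shares`
# (non-negative, summing to ~1). Deterministic: remainder ties go to the
# earlier index. Total always preserved.
largest_remainder <- function(total, shares) {
  shares <- shares / sum(shares)
  quota <- total * shares
  base <- floor(quota)
  rem <- quota - base
  need <- as.integer(round(total - sum(base)))
  if (need > 0) {
    ord <- order(-rem, seq_along(rem))
    base[ord[seq_len(need)]] <- base[ord[seq_len(need)]] + 1
  }
  as.integer(base)
}

#' Convert polygon survey records to point pseudo-clusters
#'
#' Each polygon (admin-unit) record is replaced by min(k, cells in unit)
#' point records at cells sampled without replacement with probability
#' proportional to population in the record's year. Children and cases are
#' apportioned over the sampled cells by their population shares using
#' largest-remainder rounding, preserving both totals; a cell's cases are
#' capped at its children, with any excess pushed deterministically to the
#' next cell with headroom.
#'
#' @param records survey data.frame as returned by
#'   \code{\link{simulate_surveys}} (point rows pass through unchanged).
#' @param world the \code{world} the records refer to.
#' @param k maximum pseudo-clusters per polygon record (default 10).
#' @param seed integer RNG seed.
#' @return data.frame of point records only.
#' @export
resample_polygons <- function(records, world, k = 10L, seed = 1L) {
  stopifnot(inherits(world, "world"))
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  ct <- cell_table(world)
  poly <- records[records$geometry_kind == "polygon", , drop = FALSE]
  pts <- records[records$geometry_kind == "point", , drop = FALSE]
  if (nrow(poly) == 0L) return(records)

  out <- vector("list", nrow(poly))
  for (i in seq_len(nrow(poly))) {
    rec <- poly[i, ]
    unit <- rec$admin_unit_id
    lvl <- world$admin$units$level[match(unit, world$admin$units$id)]
    cells_u <- switch(as.character(lvl),
                      "0" = which(ct$country == unit),
                      "1" = which(ct$admin1 == unit),
                      "2" = which(ct$admin2 == unit),
                      stop(sprintf("unknown admin unit '%s'", unit),
                           call. = FALSE))
    yi <- match(rec$year, world$years)
    pop <- world$population[cells_u, yi]
    if (sum(pop) <= 0)
      stop(sprintf("cannot resample polygon record: unit '%s' has zero population",
                   unit), call. = FALSE)
    m <- min(k, length(cells_u))
    sel <- if (length(cells_u) == 1L) cells_u
           else sample(cells_u, m, prob = pop / sum(pop))
    shares <- world$population[sel, yi]
    shares <- shares / sum(shares)
    nch <- largest_remainder(rec$n_children, shares)
    ncs <- largest_remainder(rec$n_cases, shares)
    # cap cases at children per pseudo-cluster, pushing excess forward
    over <- ncs - nch
    if (any(over > 0)) {
      excess <- sum(pmax(over, 0L))
      ncs <- pmin(ncs, nch)
      j <- 1L
      while (excess > 0L && j <= length(ncs)) {
        room <- nch[j] - ncs[j]
        add <- min(room, excess)
        ncs[j] <- ncs[j] + add
        excess <- excess - add
        j <- j + 1L
      }
    }
    keep_cells <- nch > 0L   # empty pseudo-clusters carry no information
    out[[i]] <- data.frame(
      source_id = rec$source_id, year = rec$year, geometry_kind = "point",
      cell = sel[keep_cells], admin_unit_id = NA_character_,
      n_children = nch[keep_cells], n_cases = ncs[keep_cells],
      weight = rec$weight, stringsAsFactors = FALSE)
  }
  res <- rbind(pts, do.call(rbind, out))
  rownames(res) <- NULL
  res
}

# Design matrix of world covariates at each record's cell-year.
record_covariates <- function(records, world) {
  if (any(records$geometry_kind != "point"))
    stop("records must be point records; run resample_polygons() first",
         call. = FALSE)
  yi <- match(records$year, world$years)
  X <- vapply(world$covariates,
              function(m) m[cbind(records$cell, yi)],
              numeric(nrow(records)))
  colnames(X) <- names(world$covariates)
  X
}
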