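#' Posterior total additive genetic values
#'
#' Per posterior draw and individual, the total additive genetic value
#' \eqn{u_i = a_i + g q_i}: the breeding value plus the immigrant-group
#' mean shift weighted by the individual's expected immigrant genome
#' fraction. All pedigree members (ancestors included) are covered.
#'
#' @param object a fitted [ggam()] model with `groups = TRUE`.
#' @param coefs optional coefficients table from [group_coefficients()];
#'   defaults to recomputing it from the fitted pedigree.
#' @return Matrix of posterior draws (rows) by pedigree individuals
#'   (columns) of \eqn{u_i}.
#' @export
total_values <- function(object, coefs = NULL) {
  stopifnot(inherits(object, "ggam"))
  if (is.null(object$draws$a)) stop("model has no breeding values")
  if (is.null(coefs)) coefs <- group_coefficients(object$design$pedigree)
  q <- coefs$q[match(colnames(object$draws$a), coefs$id)]
  if (anyNA(q)) stop("q undefined for some pedigree individuals")
  g <- group_effect(object)
  object$draws$a + outer(g, q)
}

#' Posterior trend slope of individual values on natal year
#'
#' Per posterior draw, the ordinary least-squares slope of individual
#' values on natal year across the focal individuals (individuals are the
#' regression units, so cohort sizes act as implicit weights).
#'
#' @param values draws-by-individuals matrix (e.g. breeding values
#'   `fit$draws$a`, or [total_values()] output), or a single numeric vector
#'   treated as one draw.
#' @param cohorts natal year for each column of `values`.
#' @return List with `slopes` (per-draw slope, latent units per year) and
#'   `prob_positive` (fraction of draws with positive slope).
#' @export
trend_slope <- function(values, cohorts) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1L)
  cohorts <- as.numeric(cohorts)
  if (length(cohorts) != ncol(values))
    stop("cohorts must match the columns of values")
  if (length(unique(cohorts)) < 2L)
    stop("trend slope needs at least two distinct cohorts")
  xc <- cohorts - mean(cohorts)
  w <- xc / sum(xc^2)
  slopes <- as.numeric(values %*% w)
  list(slopes = slopes, prob_positive = mean(slopes > 0))
}

#' Per-cohort posterior variance and skew
#'
#' Population moments (variance divides by \eqn{n}; skew is the moment
#' estimator, third central moment over variance^1.5) of individual values
#' within each cohort, per posterior draw. Skew is `NA` for cohorts with
#' fewer than 3 members.
#'
#' @param values draws-by-individuals matrix.
#' @param cohorts natal year per column.
#' @return List with draws-by-cohort matrices `var` and `skew` (columns
#'   named by cohort).
#' @export
cohort_moments <- function(values, cohorts) {
  if (is.null(dim(values))) values <- matrix(values, nrow = 1L)
  lev <- sort(unique(cohorts))
  S <- nrow(values)
  v <- matrix(NA_real_, S, length(lev), dimnames = list(NULL, lev))
  sk <- v
  for (k in seq_along(lev)) {
    cols <- which(cohorts == lev[k])
    m <- values[, cols, drop = FALSE]
    mu <- rowMeans(m)
    dev <- m - mu
    m2 <- rowMeans(dev^2)
    v[, k] <- m2
    if (length(cols) >= 3L) sk[, k] <- rowMeans(dev^3) / m2^1.5
  }
  list(var = v, skew = sk)
}

#' All posterior-derived trend and distribution statistics
#'
#' Convenience wrapper computing, over the focal phenotyped individuals,
#' the per-draw trend slopes of breeding value \eqn{a_i}, immigrant
#' genetic effect \eqn{g q_i} and total additive genetic value \eqn{u_i}
#' on natal year, and the per-cohort variance and skew of \eqn{a_i} and
#' \eqn{u_i} together with their pairwise-draw contrasts. All statistics
#' are computed on full posterior distributions, never on per-individual
#' posterior point estimates.
#'
#' @param object a fitted [ggam()] model with `groups = TRUE`.
#' @param ids focal individuals (default: all phenotyped individuals in
#'   the fitted observation table).
#' @return List of class `ggam_derived` with elements `slope_a`,
#'   `slope_gq`, `slope_u` (each a [trend_slope()] result), `moments_a`,
#'   `moments_u` ([cohort_moments()] results), `var_contrast` and
#'   `skew_contrast` (draws-by-cohort matrices of `u` minus `a`), plus the
#'   per-draw `u` and `a` matrices over the focal individuals and their
#'   cohorts.
#' @export
derived_posterior <- function(object, ids = NULL) {
  stopifnot(inherits(object, "ggam"))
  if (is.null(ids)) ids <- object$design$ids
  ped <- object$design$pedigree
  pos <- match(ids, ped$id)
  if (anyNA(pos)) stop("focal id(s) not in pedigree")
  cohorts <- ped$cohort[pos]

  coefs <- group_coefficients(ped)
  a <- object$draws$a[, pos, drop = FALSE]
  g <- group_effect(object)
  qv <- coefs$q[pos]
  gq <- outer(g, qv)
  u <- a + gq

  slope_a <- trend_slope(a, cohorts)
  slope_gq <- trend_slope(gq, cohorts)
  slope_u <- trend_slope(u, cohorts)
  moments_a <- cohort_moments(a, cohorts)
  moments_u <- cohort_moments(u, cohorts)

  out <- list(
    slope_a = slope_a, slope_gq = slope_gq, slope_u = slope_u,
    moments_a = moments_a, moments_u = moments_u,
    var_contrast = moments_u$var - moments_a$var,
    skew_contrast = moments_u$skew - moments_a$skew,
    a = a, u = u, g = g, q = qv, ids = ids, cohorts = cohorts
  )
  class(out) <- "ggam_derived"
  out
}

#' @export
print.ggam_derived <- function(x, ...) {
  cat(sprintf(
    paste0("Derived posterior over %d focal individuals, %d draws\n",
           "  slope of a on year: %.4f (P(>0) = %.3f)\n",
           "  slope of g*q on year: %.4f (P(>0) = %.3f)\n",
           "  slope of u on year: %.4f (P(>0) = %.3f)\n"),
    length(x$ids), length(x$g),
    mean(x$slope_a$slopes), x$slope_a$prob_positive,
    mean(x$slope_gq$slopes), x$slope_gq$prob_positive,
    mean(x$slope_u$slopes), x$slope_u$prob_positive))
  invisible(x)
}

#' Back-transform a latent genetic change onto the survival-probability scale
#'
#' Per posterior draw, evaluates the survival probability implied by the
#' latent linear predictor at two years, holding every other fixed-effect
#' variable at its observed mean, with the focal genetic component (the
#' cohort mean of \eqn{a_i}, \eqn{g q_i} or \eqn{u_i}) at its value in
#' each year's cohort, and returns the posterior distribution of the
#' change in probability. Brood and year random effects are set to zero
#' (conditional, not population-averaged, probabilities).
#'
#' @param object a fitted binomial [ggam()] model.
#' @param derived a [derived_posterior()] result from the same fit.
#' @param component `"a"`, `"gq"` or `"u"`.
#' @param years length-2 vector of natal years to contrast (default: first
#'   and last focal cohort).
#' @param sex `"F"` or `"M"`.
#' @return List with per-draw vectors `p_first`, `p_last`, `delta`
#'   (`p_last - p_first`) and the posterior mean and 95\% HPD of `delta`.
#' @export
backtransform <- function(object, derived, component = c("a", "gq", "u"),
                          years = NULL, sex = "F") {
  stopifnot(inherits(object, "ggam"), inherits(derived, "ggam_derived"))
  component <- match.arg(component)
  if (is.null(years))
    years <- range(derived$cohorts)
  focal <- switch(component, a = derived$a,
                  gq = derived$u - derived$a, u = derived$u)
  base <- baseline_eta(object, sex, include_q = component == "a")
  mean_at <- function(yr) {
    cols <- which(derived$cohorts == yr)
    if (length(cols) == 0L) stop("no focal individuals in cohort ", yr)
    rowMeans(focal[, cols, drop = FALSE])
  }
  p1 <- invlogit(base + mean_at(years[1L]))
  p2 <- invlogit(base + mean_at(years[2L]))
  delta <- p2 - p1
  list(p_first = p1, p_last = p2, delta = delta,
       mean = mean(delta), hpd = hpd95(delta))
}

# latent predictor at mean values of all modeled fixed-effect variables
# for a given sex, per draw. The focal component replaces its own term:
# when it carries the g*q part (components "gq" and "u") the q regression
# term is zeroed here; for component "a" it stays at mean q
baseline_eta <- function(object, sex, include_q) {
  X <- object$design$X
  xbar <- colMeans(X)
  if ("sexM" %in% names(xbar)) xbar[["sexM"]] <- as.numeric(sex == "M")
  if (!include_q && "q" %in% names(xbar)) xbar[["q"]] <- 0
  as.numeric(object$draws$beta %*% xbar)
}
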