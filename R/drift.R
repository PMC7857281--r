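#' Gene-drop neutral breeding values down a pedigree
#'
#' Simulates breeding values under pure drift on a fixed pedigree: every
#' founder (native and immigrant alike) draws from Normal(0, `V_A`), and
#' each non-founder is the mid-parent value plus a Mendelian sampling
#' deviation with variance `V_A` times the inbreeding-corrected scalar
#' \eqn{d_i = 0.5 - 0.25 (f_{sire} + f_{dam})}. An unknown single parent
#' contributes through a phantom unrelated founder whose value is drawn
#' fresh in every replicate. Columns are independent replicates; `V_A` may
#' be a vector giving one variance per replicate (the paired drift design).
#'
#' @param ped a `gg_pedigree`.
#' @param V_A positive scalar or vector of additive genetic variances.
#' @param n number of replicates (default `length(V_A)`).
#' @param mendelian if `FALSE`, the uncorrected Mendelian variance
#'   `V_A / 2` is used for every non-founder instead of the
#'   inbreeding-corrected form.
#' @return Matrix of simulated breeding values, pedigree individuals by
#'   replicates, rownames = ids.
#' @export
gene_drop <- function(ped, V_A, n = length(V_A), mendelian = TRUE) {
  stopifnot(inherits(ped, "gg_pedigree"))
  if (any(V_A <= 0)) stop("V_A must be positive")
  V_A <- rep_len(V_A, n)
  m <- nrow(ped)
  fd <- inbreeding_cpp(ped$sire_idx, ped$dam_idx)
  f <- fd$f
  sdA <- sqrt(V_A)
  out <- matrix(NA_real_, m, n, dimnames = list(ped$id, NULL))
  for (i in seq_len(m)) {
    s <- ped$sire_idx[i]
    d <- ped$dam_idx[i]
    if (s == 0L && d == 0L) {
      out[i, ] <- stats::rnorm(n, 0, sdA)
    } else {
      as_ <- if (s > 0L) out[s, ] else stats::rnorm(n, 0, sdA)
      ad_ <- if (d > 0L) out[d, ] else stats::rnorm(n, 0, sdA)
      di <- if (!mendelian) 0.5 else {
        0.5 - 0.25 * ((if (s > 0L) f[s] else 0) + (if (d > 0L) f[d] else 0))
      }
      out[i, ] <- 0.5 * (as_ + ad_) + stats::rnorm(n, 0, sqrt(di * V_A))
    }
  }
  out
}

#' Drift null test for the breeding-value trend
#'
#' Paired gene-dropping test of whether the estimated increase in mean
#' breeding value across cohorts exceeds what drift alone could produce on
#' the observed pedigree. For each retained posterior draw \eqn{s}, neutral
#' breeding values are gene-dropped with variance \eqn{V_A^{(s)}}, the
#' drift slope on natal year is computed over the same focal individuals,
#' and the paired difference \eqn{\Delta^{(s)} =
#' slope_a^{(s)} - slope_{drift}^{(s)}} is formed. The proportion of
#' positive differences is the posterior probability that the observed
#' trend exceeds drift.
#'
#' @param object a fitted [ggam()] model.
#' @param derived a [derived_posterior()] result from the same fit (for
#'   the focal individuals and their per-draw observed slopes).
#' @param seed integer seed for the gene-dropping randomness.
#' @param mendelian passed to [gene_drop()].
#' @return List of class `ggam_drift` with `prob_exceeds_drift`, per-draw
#'   `observed_slope`, `drift_slope` and `delta`, and the seed.
#' @export
drift_test <- function(object, derived, seed = 1L, mendelian = TRUE) {
  stopifnot(inherits(object, "ggam"), inherits(derived, "ggam_derived"))
  set.seed(seed)
  ped <- object$design$pedigree
  Va <- object$draws$V_A
  astar <- gene_drop(ped, Va, mendelian = mendelian)
  pos <- match(derived$ids, ped$id)
  drift_slopes <- trend_slope(t(astar[pos, , drop = FALSE]),
                              derived$cohorts)$slopes
  obs <- derived$slope_a$slopes
  delta <- obs - drift_slopes
  structure(list(
    prob_exceeds_drift = mean(delta > 0),
    observed_slope = obs, drift_slope = drift_slopes, delta = delta,
    seed = as.integer(seed)
  ), class = "ggam_drift")
}

#' @export
print.ggam_drift <- function(x, ...) {
  cat(sprintf(
    paste0("Gene-dropping drift null (%d paired draws)\n",
           "  mean observed slope: %.4f; mean drift slope: %.4f\n",
           "  P(observed trend exceeds drift) = %.3f\n"),
    length(x$delta), mean(x$observed_slope), mean(x$drift_slope),
    x$prob_exceeds_drift))
  invisible(x)
}
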