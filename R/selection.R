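#' Cohort-wise standardized selection gradients on juvenile survival
#'
#' Within each cohort, the selection gradient is the ordinary
#' least-squares slope of relative fitness (individual reproductive
#' success divided by the cohort mean) on juvenile survival standardized
#' to unit variance within the cohort. Cohorts with fewer than two
#' individuals, no variance in survival, or zero mean reproductive success
#' are skipped with a warning. The gradient is invariant to rescaling
#' reproductive success by a positive constant, and is positive whenever
#' non-survivors leave zero offspring and at least one survivor
#' reproduces.
#'
#' @param fitness data frame with columns `id`, `cohort`, `survival` (0/1)
#'   and `reproductive_success` (non-negative count of local offspring).
#' @return List of class `gg_selection` with `gradients` (data frame:
#'   cohort, n, gradient) and `grand_mean` across estimable cohorts.
#' @export
selection_gradient <- function(fitness) {
  need <- c("cohort", "survival", "reproductive_success")
  miss <- setdiff(need, names(fitness))
  if (length(miss) > 0L)
    stop("fitness table is missing column(s): ", paste(miss, collapse = ", "))
  if (any(fitness$reproductive_success < 0))
    stop("reproductive success must be non-negative")
  lev <- sort(unique(fitness$cohort))
  rows <- lapply(lev, function(co) {
    d <- fitness[fitness$cohort == co, ]
    if (nrow(d) < 2L || stats::var(d$survival) == 0 ||
        mean(d$reproductive_success) == 0) {
      warning("cohort ", co, " skipped (no estimable selection gradient)")
      return(NULL)
    }
    w <- d$reproductive_success / mean(d$reproductive_success)
    z <- (d$survival - mean(d$survival)) / stats::sd(d$survival)
    beta <- sum((z - mean(z)) * (w - mean(w))) / sum((z - mean(z))^2)
    data.frame(cohort = co, n = nrow(d), gradient = beta)
  })
  grad <- do.call(rbind, rows)
  if (is.null(grad)) stop("no cohort allows a selection gradient")
  structure(list(gradients = grad, grand_mean = mean(grad$gradient)),
            class = "gg_selection")
}

#' @export
print.gg_selection <- function(x, ...) {
  cat(sprintf(
    "Standardized selection gradients: %d cohorts, grand mean %.2f (range %.2f-%.2f)\n",
    nrow(x$gradients), x$grand_mean,
    min(x$gradients$gradient), max(x$gradients$gradient)))
  invisible(x)
}
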