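# a minimal hand-built fitted object for arithmetic checks
fake_fit <- function(a_draws, g_draws, q, ids, cohorts) {
  ped <- as_pedigree(data.frame(
    id = ids, sire = NA, dam = NA, cohort = cohorts, sex = "F",
    immigrant = q == 1, stringsAsFactors = FALSE))
  structure(list(
    draws = list(a = matrix(a_draws, nrow = length(g_draws),
                            dimnames = list(NULL, ids)),
                 beta = matrix(g_draws, ncol = 1,
                               dimnames = list(NULL, "q"))),
    design = list(pedigree = ped, ids = ids),
    family = "binomial"), class = "ggam")
}

test_that("total additive genetic values obey u = a + g q", {
  f <- fake_fit(a_draws = rep(0.2, 3), g_draws = -2.4,
                q = c(0.5, 0, 1), ids = c("i1", "n1", "m1"),
                cohorts = c(2L, 1L, 1L))
  u <- total_values(f, coefs = data.frame(id = c("i1", "n1", "m1"),
                                          q = c(0.5, 0, 1), f = 0))
  expect_equal(unname(u[1L, "i1"]), -1.0)       # 0.2 - 2.4 * 0.5
  expect_equal(unname(u[1L, "n1"]), 0.2)        # native founder: u = a
  expect_equal(unname(u[1L, "m1"]), 0.2 - 2.4)

  fit <- small_fit()
  u <- total_values(fit)
  co <- group_coefficients(fit$design$pedigree)
  gq <- outer(group_effect(fit), co$q[match(colnames(u), co$id)])
  expect_identical(u, fit$draws$a + gq) # u = a + g q, exactly

  fz <- fake_fit(a_draws = c(0.3, -0.1), g_draws = 0, q = c(1, 0.5),
                 ids = c("m1", "i1"), cohorts = c(1L, 2L))
  expect_equal(total_values(fz), fz$draws$a) # g = 0: u == a
})

test_that("trend slopes are individual-level OLS slopes", {
  expect_equal(trend_slope(rep(1.3, 10), rep(1:5, 2))$slopes, 0)
  ts <- trend_slope(c(0, 0, 1, 1), c(2000, 2000, 2001, 2001))
  expect_equal(ts$slopes, 1)
  expect_error(trend_slope(1:4, rep(2000, 4)), "two distinct cohorts")

  # oracle: lm() on a random draw
  set.seed(8)
  vals <- matrix(rnorm(300), 3)
  yrs <- sample(1993:2002, 100, replace = TRUE)
  ts <- trend_slope(vals, yrs)
  for (s in 1:3) {
    expect_equal(ts$slopes[s], unname(coef(lm(vals[s, ] ~ yrs))[2L]),
                 tolerance = 1e-10)
  }
})

test_that("cohort moments use population variance and moment skew", {
  cm <- cohort_moments(c(-1, 0, 1), rep(1L, 3))
  expect_equal(unname(cm$var[1L, 1L]), 2 / 3)
  expect_equal(unname(cm$skew[1L, 1L]), 0)

  cm <- cohort_moments(c(0, 0, 3), rep(1L, 3))
  expect_equal(unname(cm$var[1L, 1L]), 2)
  expect_equal(unname(cm$skew[1L, 1L]), 2 / 2^1.5) # = 0.7071
  expect_equal(unname(cm$skew[1L, 1L]), 0.7071, tolerance = 1e-4)

  cm2 <- cohort_moments(c(1, 2, 5, 0, 1), c(1L, 1L, 1L, 2L, 2L))
  expect_true(is.na(cm2$skew[1L, "2"])) # cohort of 2: skew undefined
  expect_false(is.na(cm2$var[1L, "2"]))
})

test_that("per-draw variance decomposition and slope additivity hold", {
  fit <- small_fit()
  der <- derived_posterior(fit)
  g <- der$g
  # var_u - var_a = g^2 var(q) + 2 g cov(a, q), population moments, per
  # draw and cohort
  for (co in unique(der$cohorts)) {
    cols <- which(der$cohorts == co)
    if (length(cols) < 2L) next
    qc <- der$q[cols]
    a <- der$a[, cols, drop = FALSE]
    vq <- mean((qc - mean(qc))^2)
    cov_aq <- as.numeric((a - rowMeans(a)) %*% (qc - mean(qc))) / length(qc)
    lhs <- der$var_contrast[, as.character(co)]
    expect_lt(max(abs(lhs - (g^2 * vq + 2 * g * cov_aq))), 1e-10)
  }
  expect_lt(max(abs(der$slope_u$slopes -
                      der$slope_a$slopes - der$slope_gq$slopes)), 1e-12)
  # derived statistics are computed from full posteriors: one value per draw
  expect_identical(length(der$slope_a$slopes), fit$n_draws)
})

test_that("zero group effect gives zero variance and skew contrasts", {
  ids6 <- letters[1:6]
  f <- fake_fit(a_draws = c(rnorm(12)), g_draws = c(0, 0),
                q = rep(0.5, 6), ids = ids6,
                cohorts = rep(1:2, each = 3L))
  f$design$ids <- ids6
  der <- derived_posterior(f, ids = ids6)
  expect_true(all(der$var_contrast == 0))
  expect_true(all(der$skew_contrast == 0))
})

test_that("back-transformation is the inverse logit of the latent change", {
  expect_equal(invlogit(0), 0.5)
  expect_equal(invlogit(1), 0.7311, tolerance = 1e-4)

  fit <- small_fit()
  der <- derived_posterior(fit)
  bt <- backtransform(fit, der, component = "a", sex = "F")
  # per draw the delta must be the difference of inverse logits of
  # baseline + cohort-mean breeding values
  yrs <- range(der$cohorts)
  base <- animalgg:::baseline_eta(fit, "F", include_q = TRUE)
  m1 <- rowMeans(der$a[, der$cohorts == yrs[1L], drop = FALSE])
  m2 <- rowMeans(der$a[, der$cohorts == yrs[2L], drop = FALSE])
  expect_equal(bt$delta, invlogit(base + m2) - invlogit(base + m1),
               tolerance = 1e-12)
  expect_true(all(bt$p_first > 0 & bt$p_first < 1))
  bt_m <- backtransform(fit, der, component = "u", sex = "M")
  expect_identical(length(bt_m$delta), fit$n_draws)
})
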