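test_that("Polya-Gamma augmentation draws have the exact PG(1, z) mean", {
  set.seed(1)
  for (z in c(0, 0.7, 2.5, 8)) {
    x <- animalgg:::rpg_cpp(rep(z, 5e4))
    m_true <- if (z == 0) 0.25 else tanh(z / 2) / (2 * z)
    expect_equal(mean(x), m_true, tolerance = 0.01)
    expect_true(all(x > 0))
  }
})

test_that("design builder centres covariates and maps random terms", {
  sim <- sim_nonextinct(3L, n_cohorts = 6L, cohort_size = 25L,
                        burnin_years = 6L)
  obs <- sim$observations
  ped <- prune_to_phenotyped(as_pedigree(sim$pedigree), obs$id)
  des <- build_design(obs, ped)
  expect_lt(abs(mean(des$X[, "cohort_c"])), 1e-12)
  expect_lt(abs(mean(des$X[, "clutch_date_c"])), 1e-12)
  expect_identical(colnames(des$X)[1L], "(Intercept)")
  expect_true(all(des$X[obs$sex == "F", "sexM"] == 0))
  expect_identical(nlevels(des$brood), length(unique(obs$brood_id)))
  expect_identical(levels(des$year), as.character(sort(unique(obs$cohort))))

  two <- obs[obs$brood_id == obs$brood_id[1L], ]
  expect_identical(nlevels(build_design(two, ped)$brood), 1L)

  bad <- obs
  bad$clutch_date[3L] <- NA
  expect_error(build_design(bad, ped), bad$id[3L])
  bad2 <- obs
  multi <- names(which(table(obs$brood_id) >= 2L))[1L]
  k <- which(bad2$brood_id == multi)[1L]
  bad2$cohort[k] <- bad2$cohort[k] + 1L
  expect_error(build_design(bad2, ped), "span multiple cohorts")
})

test_that("fit-time validation rejects unusable inputs", {
  sim <- sim_nonextinct(3L, n_cohorts = 6L, cohort_size = 25L,
                        burnin_years = 6L)
  obs <- sim$observations
  ped <- prune_to_phenotyped(as_pedigree(sim$pedigree), obs$id)
  obs_bad <- obs
  obs_bad$survival <- obs_bad$survival + 0.5
  expect_error(ggam(obs_bad, ped, chain = gg_chain(nitt = 20, burnin = 1)),
               "binary")
  obs_q0 <- obs
  obs_q0$q <- 0.3
  obs_q0$f <- 0
  expect_error(ggam(obs_q0, ped, chain = gg_chain(nitt = 20, burnin = 1)),
               "immigrant effect inestimable")
})

test_that("Gaussian variant reproduces mixed-model-equation BLUP", {
  rp <- random_pedigree(n = 20L, n_founders = 6L, p_half_unknown = 0,
                        seed = 5L)
  A <- tabular_A(rp)
  Va <- 0.5
  Ve <- 1
  set.seed(99)
  atrue <- as.vector(t(chol(Va * A)) %*% rnorm(20L))
  y <- 2 + atrue + rnorm(20L, 0, sqrt(Ve))
  obs <- data.frame(id = rp$id, y = y)
  oracle <- mme_blup(y, matrix(1, 20L, 1L), A, Va, Ve)
  fit <- ggam(obs, rp, fixed = y ~ 1, family = "gaussian",
              random = "animal", vc_fixed = list(animal = Va, residual = Ve),
              chain = gg_chain(nitt = 4000, burnin = 500, thin = 1, seed = 3))
  expect_lt(max(abs(colMeans(fit$draws$a) - oracle$a)), 0.05)
  expect_lt(abs(mean(fit$draws$beta) - oracle$beta), 0.05)
})

test_that("chains are exactly reproducible given the seed", {
  sim <- sim_nonextinct(5L, n_cohorts = 5L, cohort_size = 20L,
                        burnin_years = 5L)
  obs <- sim$observations
  ped <- prune_to_phenotyped(as_pedigree(sim$pedigree), obs$id)
  ch <- gg_chain(nitt = 150, burnin = 50, thin = 1, seed = 77)
  f1 <- suppressWarnings(ggam(obs, ped, chain = ch))
  f2 <- suppressWarnings(ggam(obs, ped, chain = ch))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(ggam(obs, ped,
                              chain = gg_chain(nitt = 150, burnin = 50,
                                               thin = 1, seed = 78)))
  expect_false(identical(f1$draws$V_A, f3$draws$V_A))
})

test_that("a null additive variance is recovered as near zero", {
  # needs several hundred observations: in very small binary datasets the
  # latent scale is so weakly identified that variance posteriors develop
  # extreme upper tails (quasi-separation)
  sim <- sim_nonextinct(21L, n_cohorts = 12L, cohort_size = 80L,
                        burnin_years = 10L, V_A = 0, g = 0)
  obs <- sim$observations
  ped <- prune_to_phenotyped(as_pedigree(sim$pedigree), obs$id)
  fit <- suppressWarnings(ggam(
    obs, ped, chain = gg_chain(nitt = 1500, burnin = 500, thin = 1,
                               seed = 9)))
  expect_lt(median(fit$draws$V_A), 0.19) # below the simulated brood variance
})

test_that("permuting phenotypes destroys the immigrant group effect", {
  sim <- sim_nonextinct(31L, n_cohorts = 10L, cohort_size = 60L)
  obs <- sim$observations
  ped <- prune_to_phenotyped(as_pedigree(sim$pedigree), obs$id)
  ch <- gg_chain(nitt = 900, burnin = 250, thin = 1, seed = 13)
  fit <- suppressWarnings(ggam(obs, ped, chain = ch))
  set.seed(4)
  obs_perm <- obs
  obs_perm$survival <- sample(obs_perm$survival)
  fit_perm <- suppressWarnings(ggam(obs_perm, ped, chain = ch))
  expect_lt(abs(mean(group_effect(fit_perm))),
            0.5 * abs(mean(group_effect(fit))))
})

test_that("heritability is the ratio to total latent variance", {
  fake <- structure(list(
    draws = list(V_A = c(1, 0.36), V_brood = c(0, 0.19),
                 V_year = c(0, 1.11)),
    family = "binomial"), class = "ggam")
  h2 <- heritability(fake)
  expect_equal(h2[1L], 0.5) # 1 / (1 + 0 + 0 + 1)
  # posterior-mean variance components of the field analysis give ~0.13
  expect_equal(h2[2L], 0.36 / 2.66, tolerance = 1e-12)
  expect_lt(abs(h2[2L] - 0.13), 0.01)

  fit <- small_fit()
  h2 <- heritability(fit)
  expect_true(all(h2 > 0 & h2 < 1))
})

test_that("the no-groups variant coincides with the groups model when g = 0", {
  # needs study-scale data: with only a few hundred binary observations
  # the two V_A posteriors still differ visibly through the uncertainty
  # in the (truly zero) group effect
  sim <- sim_nonextinct(41L, g = 0)
  obs <- sim$observations
  ped <- prune_to_phenotyped(as_pedigree(sim$pedigree), obs$id)
  ch <- gg_chain(nitt = 7000, burnin = 1500, thin = 2, seed = 15)
  f1 <- suppressWarnings(ggam(obs, ped, chain = ch))
  f0 <- suppressWarnings(ggam(obs, ped, groups = FALSE, chain = ch))
  expect_false("q" %in% colnames(f0$draws$beta))
  v1 <- mean(f1$draws$V_A)
  v0 <- mean(f0$draws$V_A)
  expect_lt(abs(v0 - v1) / v1, 0.1)
})

test_that("short chains trigger the autocorrelation warning", {
  sim <- sim_nonextinct(5L, n_cohorts = 5L, cohort_size = 20L,
                        burnin_years = 5L)
  obs <- sim$observations
  ped <- prune_to_phenotyped(as_pedigree(sim$pedigree), obs$id)
  expect_warning(
    ggam(obs, ped, chain = gg_chain(nitt = 120, burnin = 20, thin = 1,
                                    seed = 1)),
    "autocorrelation")
})

test_that("model methods behave on a fitted object", {
  fit <- small_fit()
  expect_s3_class(fit, "ggam")
  expect_named(coef(fit), colnames(fit$draws$beta))
  expect_output(print(fit), "animal model")
  sm <- summary(fit)
  expect_true("Heritability" %in% rownames(sm$variances))
  expect_output(print(sm), "Fixed effects")
  r <- residuals(fit)
  expect_equal(length(r), length(fit$design$y))
  expect_true(all(abs(r) <= 1))
  ys <- simulate(fit, nsim = 2, seed = 1)
  expect_true(all(unlist(ys) %in% 0:1))
  p <- predict(fit, newdata = fit$design$data[1:5, ], type = "response")
  expect_true(all(p > 0 & p < 1))
})
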