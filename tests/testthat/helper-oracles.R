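# Independent oracles used across the suite. These deliberately use
# different algorithms from the package implementation: the tabular method
# for relatedness/kinship, Monte-Carlo allele dropping for genetic-group
# coefficients, and directly solved mixed-model equations for BLUP.

# tabular-method additive relationship matrix (A_ii = 1 + f_i,
# A_ij = 0.5 (A_i,sire(j) + A_i,dam(j)))
tabular_A <- function(ped) {
  n <- nrow(ped)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- ped$sire_idx[i]
    d <- ped$dam_idx[i]
    for (j in seq_len(i - 1L)) {
      A[i, j] <- A[j, i] <-
        0.5 * ((if (s > 0) A[j, s] else 0) + (if (d > 0) A[j, d] else 0))
    }
    A[i, i] <- 1 + 0.5 * (if (s > 0 && d > 0) A[s, d] else 0)
  }
  A
}

# Monte-Carlo allele dropping: each individual carries 0, 1 or 2 copies of
# an "immigrant" allele; a parent with c copies transmits an immigrant
# allele with probability c/2; unknown parents transmit native alleles
allele_drop_q <- function(ped, groups = assign_groups(ped), reps = 2e5) {
  n <- nrow(ped)
  cnt <- matrix(0L, n, reps)
  for (i in seq_len(n)) {
    s <- ped$sire_idx[i]
    d <- ped$dam_idx[i]
    if (s == 0L && d == 0L) {
      cnt[i, ] <- if (groups[[ped$id[i]]] == "IMMIGRANT") 2L else 0L
    } else {
      from_s <- if (s > 0L) (stats::runif(reps) < cnt[s, ] / 2) else FALSE
      from_d <- if (d > 0L) (stats::runif(reps) < cnt[d, ] / 2) else FALSE
      cnt[i, ] <- as.integer(from_s) + as.integer(from_d)
    }
  }
  rowMeans(cnt) / 2
}

# random multi-generation pedigree with immigrant founders, occasional
# single unknown parents, and natural inbreeding through small size
random_pedigree <- function(n = 60L, n_founders = 10L, p_imm = 0.3,
                            p_half_unknown = 0.1, seed = 1L) {
  set.seed(seed)
  id <- sprintf("r%03d", seq_len(n))
  sex <- rep(c("F", "M"), length.out = n)[sample.int(n)]
  sire <- dam <- rep(NA_character_, n)
  cohort <- integer(n)
  imm <- logical(n)
  imm[seq_len(n_founders)] <- stats::runif(n_founders) < p_imm
  for (i in (n_founders + 1L):n) {
    males <- which(sex[seq_len(i - 1L)] == "M")
    females <- which(sex[seq_len(i - 1L)] == "F")
    if (length(males) == 0L || length(females) == 0L) {
      cohort[i] <- 0L
      next
    }
    s <- males[sample.int(length(males), 1L)]
    d <- females[sample.int(length(females), 1L)]
    if (stats::runif(1L) < p_half_unknown) {
      if (stats::runif(1L) < 0.5) s <- NA_integer_ else d <- NA_integer_
    }
    sire[i] <- if (is.na(s)) NA_character_ else id[s]
    dam[i] <- if (is.na(d)) NA_character_ else id[d]
    cohort[i] <- 1L + max(0L, cohort[s], cohort[d], na.rm = TRUE)
  }
  as_pedigree(data.frame(id = id, sire = sire, dam = dam, cohort = cohort,
                         sex = sex, immigrant = imm,
                         stringsAsFactors = FALSE))
}

# BLUP of breeding values from directly solved mixed-model equations
# (animal model y = X b + a + e, var(a) = Va A, var(e) = Ve I)
mme_blup <- function(y, X, A, Va, Ve) {
  n <- length(y)
  lam <- Ve / Va
  LHS <- rbind(cbind(crossprod(X), t(X)),
               cbind(X, diag(n) + solve(A) * lam))
  sol <- solve(LHS, c(crossprod(X, y), y))
  list(beta = sol[seq_len(ncol(X))], a = sol[-seq_len(ncol(X))])
}

# simulate, skipping the occasional stochastically extinct replicate
sim_nonextinct <- function(seed0, ...) {
  s <- seed0
  repeat {
    sim <- try(simulate_population(sim_config(seed = s, ...)), silent = TRUE)
    if (!inherits(sim, "try-error")) return(sim)
    s <- s + 1000L
  }
}

# small fitted model shared across derived/drift tests (computed once)
.test_cache <- new.env(parent = emptyenv())
small_fit <- function() {
  if (is.null(.test_cache$fit)) {
    sim <- sim_nonextinct(11L, n_cohorts = 8L, cohort_size = 40L,
                          burnin_years = 10L)
    obs <- sim$observations
    ped <- prune_to_phenotyped(as_pedigree(sim$pedigree), obs$id)
    fit <- suppressWarnings(ggam(
      obs, ped, chain = gg_chain(nitt = 700, burnin = 200, thin = 1,
                                 seed = 42)))
    .test_cache$fit <- fit
    .test_cache$sim <- sim
  }
  .test_cache$fit
}
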