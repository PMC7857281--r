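#' Priors for the genetic-groups animal model
#'
#' Fixed effects get independent normal priors with mean zero and large
#' variance (effectively flat). Variance-component priors are
#' parameter-expanded: each random-effect block enters the model as
#' \eqn{\alpha_x u_x} with working scale \eqn{\alpha_x \sim N(0, 1)} and
#' base variance \eqn{\tilde V_x \sim IG(1/2, s^2/2)}, so the reported
#' variance \eqn{V_x = \alpha_x^2 \tilde V_x} has an exact half-Cauchy
#' prior with scale \eqn{s} on its standard deviation. The expansion keeps
#' every conditional conjugate and decisively improves variance-component
#' mixing for binary traits.
#'
#' @param beta_var prior variance of each fixed effect (default `1e10`).
#' @param sd_scale scale \eqn{s} of the half-Cauchy prior on each random
#'   effect standard deviation (default 1).
#' @return List of class `gg_prior`.
#' @export
gg_prior <- function(beta_var = 1e10, sd_scale = 1) {
  if (beta_var <= 0 || sd_scale <= 0)
    stop("prior hyperparameters must be strictly positive")
  structure(list(beta_var = beta_var, sd_scale = sd_scale),
            class = "gg_prior")
}

#' MCMC chain settings
#'
#' @param nitt total number of MCMC iterations.
#' @param burnin iterations discarded before retention.
#' @param thin thinning interval (every `thin`-th post-burn-in draw kept).
#' @param seed integer seed; chains are exactly reproducible given the seed.
#' @return List of class `gg_chain`.
#' @export
gg_chain <- function(nitt = 7000L, burnin = 1000L, thin = 2L, seed = 1L) {
  nitt <- as.integer(nitt); burnin <- as.integer(burnin)
  thin <- as.integer(thin)
  if (nitt <= burnin || burnin < 0L || thin < 1L)
    stop("need nitt > burnin >= 0 and thin >= 1")
  structure(list(nitt = nitt, burnin = burnin, thin = thin,
                 seed = as.integer(seed)), class = "gg_chain")
}

default_fixed <- stats::as.formula(
  survival ~ q + f + cohort_c + clutch_date_c + sex)

#' Build the design bundle for the animal model
#'
#' Assembles the fixed-effect matrix (with year and clutch date centred and
#' sex as a single male-vs-female contrast) and the incidence maps for the
#' animal, natal-brood and cohort-year random effects. If `data` lacks `q`
#' and `f` columns they are computed from the pedigree with
#' [group_coefficients()].
#'
#' @param data observation table: one row per phenotyped individual with
#'   `id`, the response, `sex`, `clutch_date`, `brood_id`, `cohort`, and
#'   optionally `q` and `f`.
#' @param pedigree a `gg_pedigree` containing every observed id.
#' @param fixed fixed-effects formula; the default is
#'   `survival ~ q + f + cohort_c + clutch_date_c + sex`, where `cohort_c`
#'   and `clutch_date_c` are the centred year and clutch date.
#' @param random character subset of `c("animal", "brood", "year")`.
#' @return List of class `ggam_design`.
#' @export
build_design <- function(data, pedigree,
                         fixed = default_fixed,
                         random = c("animal", "brood", "year")) {
  stopifnot(inherits(pedigree, "gg_pedigree"))
  random <- match.arg(random, several.ok = TRUE)
  data <- as.data.frame(data)
  if (!"id" %in% names(data)) stop("observation table needs an 'id' column")
  bad <- setdiff(data$id, pedigree$id)
  if (length(bad) > 0L)
    stop("observed id(s) missing from pedigree: ",
         paste(utils::head(bad, 5L), collapse = ", "))

  if (!all(c("q", "f") %in% names(data))) {
    coefs <- group_coefficients(pedigree)
    m <- match(data$id, coefs$id)
    if (!"q" %in% names(data)) data$q <- coefs$q[m]
    if (!"f" %in% names(data)) data$f <- coefs$f[m]
  }
  if ("cohort" %in% names(data)) {
    data$cohort <- as.integer(data$cohort)
    data$cohort_c <- data$cohort - mean(data$cohort)
  }
  if ("clutch_date" %in% names(data))
    data$clutch_date_c <- data$clutch_date - mean(data$clutch_date)
  if ("sex" %in% names(data)) {
    if (!all(data$sex %in% c("F", "M") | is.na(data$sex)))
      stop("sex must be 'F' or 'M'")
    data$sex <- factor(data$sex, levels = c("F", "M"))
  }

  vars <- all.vars(fixed)
  miss <- setdiff(vars, names(data))
  if (length(miss) > 0L)
    stop("observation table lacks variable(s): ", paste(miss, collapse = ", "))
  na_row <- !stats::complete.cases(data[, vars, drop = FALSE])
  if (any(na_row))
    stop("missing covariate values for id(s): ",
         paste(utils::head(data$id[na_row], 10L), collapse = ", "))

  if (all(c("brood_id", "cohort") %in% names(data))) {
    spl <- tapply(data$cohort, data$brood_id,
                  function(z) length(unique(z)))
    if (any(spl > 1L))
      stop("brood(s) span multiple cohorts: ",
           paste(names(spl)[spl > 1L], collapse = ", "))
  }

  mf <- stats::model.frame(fixed, data = data, na.action = stats::na.fail)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  y <- stats::model.response(mf)

  des <- list(
    X = X, y = as.numeric(y), ids = data$id,
    anim = if ("animal" %in% random) match(data$id, pedigree$id) else NULL,
    brood = if ("brood" %in% random) factor(data$brood_id) else NULL,
    year = if ("year" %in% random) factor(data$cohort) else NULL,
    random = random, pedigree = pedigree, data = data,
    fixed = fixed, terms = attr(mf, "terms"),
    centres = c(cohort = if ("cohort" %in% names(data))
      mean(data$cohort) else NA_real_,
      clutch_date = if ("clutch_date" %in% names(data))
        mean(data$clutch_date) else NA_real_)
  )
  class(des) <- "ggam_design"
  des
}

#' Fit a Bayesian genetic-groups animal model
#'
#' Fits a univariate animal model for a binary fitness component on the
#' latent logit scale by Gibbs sampling with Polya-Gamma data augmentation.
#' The latent liability is
#' \deqn{l_i = x_i'\beta + a_i + b_{brood(i)} + c_{year(i)} + e_i}
#' with breeding values \eqn{a} having covariance \eqn{V_A A} (pedigree
#' relatedness \eqn{A}, entered through its sparse inverse), independent
#' brood and cohort-year effects, and an over-dispersion residual \eqn{e_i}
#' whose variance is fixed to 1 by convention so the latent scale is
#' identified; \eqn{\Pr(y_i = 1) = \mathrm{logit}^{-1}(l_i)}. The fixed
#' effects include the regression on the immigrant genetic-group
#' coefficient \eqn{q_i}, whose slope is the group effect \eqn{g} (the
#' immigrant-minus-native difference in mean additive genetic value, native
#' mean zero by convention). Breeding values are sampled for every pedigree
#' member, ancestors included.
#'
#' A Gaussian-response variant (`family = "gaussian"`, identity link,
#' residual variance sampled or fixed) is provided for validation against
#' mixed-model-equation BLUP on small pedigrees.
#'
#' @param data observation table (see [build_design()]).
#' @param pedigree a `gg_pedigree`.
#' @param fixed fixed-effects formula (default
#'   `survival ~ q + f + cohort_c + clutch_date_c + sex`).
#' @param groups if `FALSE`, the regression on `q` is omitted (no explicit
#'   immigrant effect; the model then assumes an unstructured base
#'   population).
#' @param family `"binomial"` (logit link, residual variance fixed to 1) or
#'   `"gaussian"`.
#' @param prior a [gg_prior()].
#' @param chain a [gg_chain()].
#' @param random random-effect terms to include.
#' @param vc_fixed optional named list fixing variance components instead of
#'   sampling them, e.g. `list(animal = 0.3, residual = 1)`; names from
#'   `animal`, `brood`, `year`, `residual` (residual only for the Gaussian
#'   family).
#' @param verbose print progress every 1000 iterations.
#' @return An object of class `ggam` with posterior draws in `$draws`
#'   (matrices `beta`, `a`, `b`, `yr`; vectors `V_A`, `V_brood`, `V_year`,
#'   and `V_res` for the Gaussian family), lag-1 autocorrelations in `$ac`,
#'   and the design. A warning is issued if the lag-1 autocorrelation of
#'   \eqn{V_A}, \eqn{g} or any fixed effect exceeds 0.05.
#' @export
ggam <- function(data, pedigree, fixed = default_fixed, groups = TRUE,
                 family = c("binomial", "gaussian"), prior = gg_prior(),
                 chain = gg_chain(), random = c("animal", "brood", "year"),
                 vc_fixed = NULL, verbose = FALSE) {
  family <- match.arg(family)
  stopifnot(inherits(prior, "gg_prior"), inherits(chain, "gg_chain"))
  if (!groups) fixed <- stats::update(fixed, . ~ . - q)
  des <- build_design(data, pedigree, fixed = fixed, random = random)

  if (family == "binomial" && !all(des$y %in% c(0, 1)))
    stop("binomial family requires a binary 0/1 response")
  if (groups && "q" %in% colnames(des$X) && stats::var(des$X[, "q"]) == 0)
    stop("immigrant effect inestimable: no variance in q among phenotyped individuals")

  fit <- gibbs_fit(des, prior, chain, family, vc_fixed, verbose)
  fit$call <- match.call()
  fit$groups <- groups
  fit
}

# core Gibbs sampler; all location effects are drawn jointly from one
# sparse Gaussian system so mixing is limited only by the variance updates
gibbs_fit <- function(des, prior, chain, family, vc_fixed, verbose) {
  set.seed(chain$seed)
  n <- length(des$y)
  X <- des$X
  p <- ncol(X)
  binom <- family == "binomial"

  use_a <- !is.null(des$anim)
  use_b <- !is.null(des$brood)
  use_y <- !is.null(des$year)
  nped <- if (use_a) nrow(des$pedigree) else 0L
  nb <- if (use_b) nlevels(des$brood) else 0L
  ny <- if (use_y) nlevels(des$year) else 0L

  blocks <- list(Matrix::Matrix(X, sparse = TRUE))
  prec <- list(Matrix::Diagonal(p, 1 / prior$beta_var))
  if (use_a) {
    ainv <- a_inverse(des$pedigree)
    blocks <- c(blocks, Matrix::sparseMatrix(
      i = seq_len(n), j = des$anim, x = 1, dims = c(n, nped)))
    prec <- c(prec, ainv$Ainv)
  }
  if (use_b) {
    blocks <- c(blocks, Matrix::sparseMatrix(
      i = seq_len(n), j = as.integer(des$brood), x = 1, dims = c(n, nb)))
    prec <- c(prec, Matrix::Diagonal(nb))
  }
  if (use_y) {
    blocks <- c(blocks, Matrix::sparseMatrix(
      i = seq_len(n), j = as.integer(des$year), x = 1, dims = c(n, ny)))
    prec <- c(prec, Matrix::Diagonal(ny))
  }
  if (binom) { # over-dispersion residual, variance fixed to 1
    blocks <- c(blocks, Matrix::Diagonal(n))
    prec <- c(prec, Matrix::Diagonal(n))
  }
  C <- do.call(cbind, blocks)
  d <- ncol(C)
  B <- methods::as(Matrix::forceSymmetric(do.call(Matrix::bdiag, prec)),
                   "CsparseMatrix")
  Bx_base <- B@x
  colind <- rep.int(seq_len(d), diff(B@p))
  idx_a <- if (use_a) which(colind > p & colind <= p + nped) else integer(0)
  idx_b <- if (use_b) {
    which(colind > p + nped & colind <= p + nped + nb)
  } else integer(0)
  idx_y <- if (use_y) {
    which(colind > p + nped + nb & colind <= p + nped + nb + ny)
  } else integer(0)
  ia <- if (use_a) (p + 1L):(p + nped) else integer(0)
  ib <- if (use_b) (p + nped + 1L):(p + nped + nb) else integer(0)
  iy <- if (use_y) (p + nped + nb + 1L):(p + nped + nb + ny) else integer(0)

  Ccol <- rep.int(seq_len(d), diff(C@p))
  Cx <- C@x
  kappa <- if (binom) des$y - 0.5 else des$y
  rhs0 <- as.numeric(Matrix::crossprod(C, kappa))

  # pattern template and precomputed index maps for fast assembly of the
  # posterior precision P = C' W C + B (W = diag of augmentation weights)
  Ptmp <- methods::as(Matrix::crossprod(C) + B, "CsparseMatrix")
  dkey <- function(i, j) (j - 1) * as.double(d) + i
  Pkey <- dkey(Ptmp@i + 1L, rep.int(seq_len(d), diff(Ptmp@p)))
  Btr <- methods::as(B, "TsparseMatrix")
  bmap <- match(dkey(Btr@i + 1L, Btr@j + 1L), Pkey) - 1L
  Crow0 <- C@i
  ordr <- order(Crow0)
  ebyrow <- split(ordr, Crow0[ordr])
  pl <- vector("list", length(ebyrow))
  for (k in seq_along(ebyrow)) {
    e <- ebyrow[[k]]
    cols <- Ccol[e]
    o <- order(cols)
    e <- e[o]
    cols <- cols[o]
    m <- length(e)
    u1 <- rep.int(seq_len(m), m - seq_len(m) + 1L)
    u2 <- unlist(lapply(seq_len(m), function(x) x:m), use.names = FALSE)
    pl[[k]] <- cbind(row = as.integer(names(ebyrow)[k]),
                     ea = e[u1], eb = e[u2],
                     key = dkey(cols[u1], cols[u2]))
  }
  pl <- do.call(rbind, pl)
  pair_a <- as.integer(pl[, "ea"]) - 1L
  pair_b <- as.integer(pl[, "eb"]) - 1L
  pair_row <- as.integer(pl[, "row"])
  pair_tar <- match(pl[, "key"], Pkey) - 1L
  npx <- length(Ptmp@x)
  rm(pl)

  anim_i <- if (use_a) des$anim else NULL
  brood_i <- if (use_b) as.integer(des$brood) else NULL
  year_i <- if (use_y) as.integer(des$year) else NULL
  ie <- if (binom) (p + nped + nb + ny + 1L):d else integer(0)

  # parameter expansion: each random-effect block enters the predictor as
  # alpha_x * u_x with u_x ~ N(0, Vt_x K^-1) and alpha_x ~ N(0, 1); the
  # reported variance is V_x = alpha_x^2 Vt_x and, with
  # Vt_x ~ IG(1/2, s^2/2), the implied prior on sd(V_x) is half-Cauchy(s)
  fixed_vc <- function(nm) !is.null(vc_fixed[[nm]])
  s2 <- prior$sd_scale^2
  alpha <- c(a = 1, b = 1, y = 1)
  Vt <- c(a = if (fixed_vc("animal")) vc_fixed$animal else 1,
          b = if (fixed_vc("brood")) vc_fixed$brood else 1,
          y = if (fixed_vc("year")) vc_fixed$year else 1)
  Ve <- if (fixed_vc("residual")) vc_fixed$residual else 1
  auxE <- 1
  px <- c(a = use_a && !fixed_vc("animal"),
          b = use_b && !fixed_vc("brood"),
          y = use_y && !fixed_vc("year"))
  colscale <- rep(1, d)

  eta <- rep(0, n)
  S <- (chain$nitt - chain$burnin) %/% chain$thin
  draws <- list(
    beta = matrix(NA_real_, S, p, dimnames = list(NULL, colnames(X))),
    V_A = if (use_a) numeric(S) else NULL,
    V_brood = if (use_b) numeric(S) else NULL,
    V_year = if (use_y) numeric(S) else NULL,
    V_res = if (!binom) numeric(S) else NULL,
    a = if (use_a) matrix(NA_real_, S, nped,
                          dimnames = list(NULL, des$pedigree$id)) else NULL,
    b = if (use_b) matrix(NA_real_, S, nb,
                          dimnames = list(NULL, levels(des$brood))) else NULL,
    yr = if (use_y) matrix(NA_real_, S, ny,
                           dimnames = list(NULL, levels(des$year))) else NULL
  )
  fitted_acc <- numeric(n)
  kept <- 0L
  ch <- NULL

  for (it in seq_len(chain$nitt)) {
    # (1) augmentation weights given the current predictor
    w <- if (binom) rpg_cpp(eta) else rep(1 / Ve, n)

    # (2) joint draw of all location effects on the working scale
    if (use_a) colscale[ia] <- alpha[["a"]]
    if (use_b) colscale[ib] <- alpha[["b"]]
    if (use_y) colscale[iy] <- alpha[["y"]]
    Bx <- Bx_base
    if (use_a) Bx[idx_a] <- Bx_base[idx_a] / Vt[["a"]]
    if (use_b) Bx[idx_b] <- Bx_base[idx_b] / Vt[["b"]]
    if (use_y) Bx[idx_y] <- Bx_base[idx_y] / Vt[["y"]]
    Cv <- Cx * colscale[Ccol]
    Ptmp@x <- assemble_precision_cpp(npx, bmap, Bx, pair_a, pair_b,
                                     pair_row, pair_tar, Cv, w)
    ch <- if (is.null(ch)) {
      Matrix::Cholesky(Ptmp, LDL = FALSE, super = FALSE)
    } else Matrix::.updateCHMfactor(ch, Ptmp, mult = 0)
    rhs <- colscale * rhs0
    if (!binom) rhs <- rhs / Ve
    mu <- Matrix::solve(ch, rhs, system = "A")
    z <- stats::rnorm(d)
    v <- Matrix::solve(ch, Matrix::solve(ch, z, system = "Lt"),
                       system = "Pt")
    theta <- as.numeric(mu) + as.numeric(v)

    beta <- theta[seq_len(p)]
    base <- as.numeric(X %*% beta)
    if (binom) base <- base + theta[ie]
    m_a <- if (use_a) theta[ia][anim_i] else NULL
    m_b <- if (use_b) theta[ib][brood_i] else NULL
    m_y <- if (use_y) theta[iy][year_i] else NULL

    # (3) working scales alpha_x drawn jointly given the block effects
    if (any(px)) {
      M <- cbind(a = if (px[["a"]]) m_a,
                 b = if (px[["b"]]) m_b,
                 y = if (px[["y"]]) m_y)
      others <- base
      if (use_a && !px[["a"]]) others <- others + alpha[["a"]] * m_a
      if (use_b && !px[["b"]]) others <- others + alpha[["b"]] * m_b
      if (use_y && !px[["y"]]) others <- others + alpha[["y"]] * m_y
      prec <- crossprod(M, M * w) + diag(ncol(M))
      lin <- as.numeric(crossprod(M, kappa - w * others))
      if (!binom) lin <- as.numeric(crossprod(M, (des$y - others))) / Ve
      R <- chol(prec)
      amean <- backsolve(R, backsolve(R, lin, transpose = TRUE))
      adraw <- amean + backsolve(R, stats::rnorm(ncol(M)))
      alpha[colnames(M)] <- adraw
    }
    eta <- base
    if (use_a) eta <- eta + alpha[["a"]] * m_a
    if (use_b) eta <- eta + alpha[["b"]] * m_b
    if (use_y) eta <- eta + alpha[["y"]] * m_y

    # (4) base variances of the expanded blocks (conjugate)
    if (px[["a"]]) {
      u <- theta[ia]
      qf <- sum(u * as.numeric(ainv$Ainv %*% u))
      Vt[["a"]] <- 1 / stats::rgamma(1L, (nped + 1) / 2,
                                     rate = qf / 2 + s2 / 2)
    }
    if (px[["b"]]) {
      u <- theta[ib]
      Vt[["b"]] <- 1 / stats::rgamma(1L, (nb + 1) / 2,
                                     rate = sum(u^2) / 2 + s2 / 2)
    }
    if (px[["y"]]) {
      u <- theta[iy]
      Vt[["y"]] <- 1 / stats::rgamma(1L, (ny + 1) / 2,
                                     rate = sum(u^2) / 2 + s2 / 2)
    }
    if (!binom && !fixed_vc("residual")) {
      r <- des$y - eta
      Ve <- 1 / stats::rgamma(1L, (n + 1) / 2, rate = sum(r^2) / 2 + 1 / auxE)
      auxE <- 1 / stats::rgamma(1L, 1, rate = 1 / Ve + 1 / s2)
    }

    if (it > chain$burnin && (it - chain$burnin) %% chain$thin == 0L) {
      kept <- kept + 1L
      draws$beta[kept, ] <- beta
      if (use_a) {
        draws$V_A[kept] <- alpha[["a"]]^2 * Vt[["a"]]
        draws$a[kept, ] <- alpha[["a"]] * theta[ia]
      }
      if (use_b) {
        draws$V_brood[kept] <- alpha[["b"]]^2 * Vt[["b"]]
        draws$b[kept, ] <- alpha[["b"]] * theta[ib]
      }
      if (use_y) {
        draws$V_year[kept] <- alpha[["y"]]^2 * Vt[["y"]]
        draws$yr[kept, ] <- alpha[["y"]] * theta[iy]
      }
      if (!binom) draws$V_res[kept] <- Ve
      fitted_acc <- fitted_acc + (if (binom) invlogit(eta) else eta)
    }
    if (verbose && it %% 1000L == 0L)
      message("iteration ", it, "/", chain$nitt)
  }

  ac <- c(
    if (use_a) c(V_A = lag1_ac(draws$V_A)),
    stats::setNames(apply(draws$beta, 2L, lag1_ac),
                    colnames(X))
  )
  high <- ac[!is.na(ac) & ac > 0.05]
  if (length(high) > 0L)
    warning("lag-1 autocorrelation exceeds 0.05 for: ",
            paste(sprintf("%s (%.2f)", names(high), high), collapse = ", "),
            "; consider a longer chain or more thinning")

  out <- list(
    draws = draws, design = des, prior = prior, chain = chain,
    family = family, ac = ac, fitted = fitted_acc / kept,
    n_draws = kept
  )
  class(out) <- "ggam"
  out
}

#' Posterior heritability on the latent scale
#'
#' Per posterior draw, \eqn{h^2 = V_A / (V_A + V_{brood} + V_{year} +
#' V_{res})}, where the residual variance is the fixed latent value 1 for
#' the binomial family (no link-variance term is added).
#'
#' @param object a fitted [ggam()] model.
#' @return Numeric vector of posterior draws of \eqn{h^2}.
#' @export
heritability <- function(object) {
  stopifnot(inherits(object, "ggam"))
  dr <- object$draws
  if (is.null(dr$V_A)) stop("model has no additive genetic variance")
  tot <- dr$V_A
  if (!is.null(dr$V_brood)) tot <- tot + dr$V_brood
  if (!is.null(dr$V_year)) tot <- tot + dr$V_year
  tot <- tot + if (object$family == "binomial") 1 else dr$V_res
  dr$V_A / tot
}

#' Extract the posterior draws of the immigrant group effect g
#'
#' @param object a fitted [ggam()] model with `groups = TRUE`.
#' @return Numeric vector of posterior draws of \eqn{g}.
#' @export
group_effect <- function(object) {
  stopifnot(inherits(object, "ggam"))
  if (!"q" %in% colnames(object$draws$beta))
    stop("model was fitted without an explicit immigrant effect")
  object$draws$beta[, "q"]
}

#' @export
print.ggam <- function(x, ...) {
  cat(sprintf(
    "Genetic-groups animal model (%s), %d observations, %d retained draws\n",
    x$family, length(x$design$y), x$n_draws))
  if (!is.null(x$draws$V_A))
    cat(sprintf("  posterior mean V_A = %.3f", mean(x$draws$V_A)))
  if ("q" %in% colnames(x$draws$beta))
    cat(sprintf(", g = %.3f", mean(x$draws$beta[, "q"])))
  cat("\n")
  invisible(x)
}

#' @export
coef.ggam <- function(object, ...) colMeans(object$draws$beta)

#' Summarize a fitted genetic-groups animal model
#'
#' @param object a fitted [ggam()] model.
#' @param ... unused.
#' @return A `summary.ggam` with per-parameter posterior mean, mode, 95\%
#'   highest-posterior-density interval, and (for fixed effects) the
#'   proportion of negative draws.
#' @export
summary.ggam <- function(object, ...) {
  dr <- object$draws
  row <- function(x) {
    iv <- hpd95(x)
    c(mean = mean(x), mode = post_mode(x), lower = iv[[1L]], upper = iv[[2L]])
  }
  vcs <- list()
  if (!is.null(dr$V_A)) vcs$`Additive genetic variance` <- row(dr$V_A)
  if (!is.null(dr$V_brood)) vcs$`Brood variance` <- row(dr$V_brood)
  if (!is.null(dr$V_year)) vcs$`Natal year (cohort) variance` <- row(dr$V_year)
  if (!is.null(dr$V_res)) vcs$`Residual variance` <- row(dr$V_res)
  if (!is.null(dr$V_A)) vcs$Heritability <- row(heritability(object))
  vc_tab <- do.call(rbind, vcs)
  fx <- t(apply(dr$beta, 2L, row))
  fx <- cbind(fx, `prop<0` = apply(dr$beta, 2L, function(z) mean(z < 0)))
  out <- list(variances = vc_tab, fixed = fx, ac = object$ac,
              n_draws = object$n_draws, family = object$family)
  class(out) <- "summary.ggam"
  out
}

#' @export
print.summary.ggam <- function(x, ...) {
  cat(sprintf("Posterior summaries (%d retained draws, %s family)\n",
              x$n_draws, x$family))
  cat("\nVariance components (latent scale; residual fixed to 1):\n")
  print(round(x$variances, 3))
  cat("\nFixed effects:\n")
  print(round(x$fixed, 3))
  invisible(x)
}

#' @export
predict.ggam <- function(object, newdata = NULL,
                         type = c("link", "response"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) return(object$fitted)
  newdata <- as.data.frame(newdata)
  cn <- object$design$centres
  if (!"cohort_c" %in% names(newdata) && "cohort" %in% names(newdata))
    newdata$cohort_c <- newdata$cohort - cn[["cohort"]]
  if (!"clutch_date_c" %in% names(newdata) &&
      "clutch_date" %in% names(newdata))
    newdata$clutch_date_c <- newdata$clutch_date - cn[["clutch_date"]]
  if ("sex" %in% names(newdata))
    newdata$sex <- factor(newdata$sex, levels = c("F", "M"))
  tt <- stats::delete.response(object$design$terms)
  X <- stats::model.matrix(tt, stats::model.frame(tt, newdata))
  eta <- X %*% t(object$draws$beta) # fixed effects only, random set to 0
  out <- if (type == "response" && object$family == "binomial")
    rowMeans(invlogit(eta)) else rowMeans(eta)
  as.numeric(out)
}

#' @export
residuals.ggam <- function(object, ...) {
  object$design$y - object$fitted
}

#' @export
simulate.ggam <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  des <- object$design
  n <- length(des$y)
  picks <- sample.int(object$n_draws, nsim, replace = TRUE)
  out <- matrix(NA_real_, n, nsim)
  for (k in seq_len(nsim)) {
    s <- picks[k]
    eta <- as.numeric(des$X %*% object$draws$beta[s, ])
    if (!is.null(des$anim)) eta <- eta + object$draws$a[s, des$anim]
    if (!is.null(des$brood))
      eta <- eta + object$draws$b[s, as.integer(des$brood)]
    if (!is.null(des$year))
      eta <- eta + object$draws$yr[s, as.integer(des$year)]
    if (object$family == "binomial") {
      eta <- eta + stats::rnorm(n) # over-dispersion residual, variance 1
      out[, k] <- stats::rbinom(n, 1L, invlogit(eta))
    } else {
      out[, k] <- eta + stats::rnorm(n, 0, sqrt(object$draws$V_res[s]))
    }
  }
  as.data.frame(out)
}

#' @export
plot.ggam <- function(x, ...) {
  dr <- x$draws
  series <- list()
  if (!is.null(dr$V_A)) series$V_A <- dr$V_A
  if (!is.null(dr$V_brood)) series$V_brood <- dr$V_brood
  if (!is.null(dr$V_year)) series$V_year <- dr$V_year
  if ("q" %in% colnames(dr$beta)) series$g <- dr$beta[, "q"]
  old <- graphics::par(mfrow = c(length(series), 2),
                       mar = c(3, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (nm in names(series)) {
    z <- series[[nm]]
    plot(z, type = "l", xlab = "", ylab = nm, main = "")
    hist(z, breaks = 40, main = "", xlab = nm)
  }
  invisible(x)
}
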