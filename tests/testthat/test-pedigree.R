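trio <- data.frame(
  id = c("o1", "s1", "d1"), sire = c("s1", NA, NA), dam = c("d1", NA, NA),
  cohort = c(2L, 1L, 1L), sex = c("F", "M", "F"),
  immigrant = c(FALSE, TRUE, FALSE), stringsAsFactors = FALSE
)

test_that("pedigree CSV reading sorts parents first and handles NA dialects", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(trio, path, row.names = FALSE, na = "")
  ped <- read_pedigree(path)
  expect_s3_class(ped, "gg_pedigree")
  expect_identical(nrow(ped), 3L)
  expect_identical(ped$id[3L], "o1") # founders first despite input order
  expect_true(all(ped$sire_idx[1:2] == 0L))

  # "NA" string dialect for unknown parents
  trio2 <- trio
  trio2$sire[2:3] <- "NA"
  trio2$dam[2:3] <- "NA"
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(trio2, path2, row.names = FALSE, na = "")
  expect_identical(read_pedigree(path2)$id, ped$id)
})

test_that("pedigree validation catches cycles, bad parents and bad flags", {
  cyc <- data.frame(id = c("A", "B"), sire = c("B", "A"), dam = c(NA, NA),
                    cohort = 1:2, sex = "M", immigrant = FALSE)
  expect_error(as_pedigree(cyc), "cycle")
  expect_error(as_pedigree(transform(trio, sire = c("ghost", NA, NA))),
               "unknown sire")
  expect_error(
    as_pedigree(data.frame(id = "A", sire = "A", dam = NA, cohort = 1,
                           sex = "F", immigrant = FALSE)),
    "own parent")
  expect_error(as_pedigree(transform(trio, immigrant = c(TRUE, FALSE, FALSE))),
               "non-founder")
  expect_error(as_pedigree(rbind(trio, trio)), "duplicated")
})

test_that("pruning returns exactly the ancestor closure", {
  ped <- as_pedigree(trio)
  expect_identical(nrow(prune_to_phenotyped(ped, "s1")), 1L)
  expect_identical(nrow(prune_to_phenotyped(ped, "o1")), 3L)
  expect_error(prune_to_phenotyped(ped, character(0)), "empty")
  expect_error(prune_to_phenotyped(ped, "nobody"), "not in pedigree")

  # brute-force ancestor walk oracle on random pedigrees
  for (seed in 1:5) {
    rp <- random_pedigree(n = 60L, seed = seed)
    focal <- sample(rp$id, 8L)
    anc <- character(0)
    stack <- focal
    while (length(stack) > 0L) {
      cur <- stack[1L]
      stack <- stack[-1L]
      if (cur %in% anc) next
      anc <- c(anc, cur)
      k <- match(cur, rp$id)
      stack <- c(stack, rp$sire[k], rp$dam[k])
      stack <- stack[!is.na(stack)]
    }
    pruned <- prune_to_phenotyped(rp, focal)
    expect_setequal(pruned$id, anc)
  }
})

test_that("group assignment covers exactly the founders", {
  ped <- random_pedigree(n = 50L, n_founders = 8L, seed = 3L)
  grp <- assign_groups(ped)
  founders <- ped$id[ped$sire_idx == 0L & ped$dam_idx == 0L]
  # note single-unknown-parent individuals are not founders
  expect_setequal(names(grp), founders)
  expect_identical(sum(grp == "IMMIGRANT"), sum(ped$immigrant))

  no_imm <- random_pedigree(n = 30L, p_imm = 0, seed = 4L)
  expect_true(all(assign_groups(no_imm) == "NATIVE"))
})

test_that("q and f are exact on textbook crosses", {
  ped <- as_pedigree(trio)
  co <- group_coefficients(ped)
  expect_equal(co$q[match("o1", co$id)], 0.5)
  expect_equal(co$f, rep(0, 3))

  # full sibs (outbred, q = 0.5 parents) mated: offspring q 0.5, f 0.25
  fs <- as_pedigree(data.frame(
    id = c("gs", "gd", "p1", "p2", "x"),
    sire = c(NA, NA, "gs", "gs", "p1"), dam = c(NA, NA, "gd", "gd", "p2"),
    cohort = c(1, 1, 2, 2, 3), sex = c("M", "F", "M", "F", "F"),
    immigrant = c(TRUE, FALSE, FALSE, FALSE, FALSE)))
  co <- group_coefficients(fs)
  expect_equal(co$q[match("x", co$id)], 0.5)
  expect_equal(co$f[match("x", co$id)], 0.25)
})

test_that("q and f are invariant to input row order and group-complementary", {
  rp <- random_pedigree(n = 80L, p_half_unknown = 0, seed = 7L)
  co <- group_coefficients(rp)
  perm <- as.data.frame(rp[, c("id", "sire", "dam", "cohort", "sex",
                               "immigrant")])
  set.seed(1)
  perm <- perm[sample.int(nrow(perm)), ]
  co2 <- group_coefficients(as_pedigree(perm))
  m <- match(co$id, co2$id)
  expect_equal(co$q, co2$q[m], tolerance = 1e-12)
  expect_equal(co$f, co2$f[m], tolerance = 1e-12)
  expect_true(all(co$q >= 0 & co$q <= 1))

  # two groups partition the genome: swapping labels gives 1 - q
  grp <- assign_groups(rp)
  swapped <- ifelse(grp == "IMMIGRANT", "NATIVE", "IMMIGRANT")
  names(swapped) <- names(grp)
  co_sw <- group_coefficients(rp, swapped)
  expect_equal(co_sw$q, 1 - co$q, tolerance = 1e-12)
})

test_that("f equals tabular-method kinship of the parents", {
  for (seed in 1:5) {
    rp <- random_pedigree(n = 100L, n_founders = 8L, seed = seed)
    A <- tabular_A(rp)
    co <- group_coefficients(rp)
    f_tab <- ifelse(rp$sire_idx > 0L & rp$dam_idx > 0L,
                    0.5 * A[cbind(pmax(rp$sire_idx, 1L),
                                  pmax(rp$dam_idx, 1L))], 0)
    expect_equal(co$f, f_tab, tolerance = 1e-12)
  }
})

test_that("q matches Monte-Carlo allele dropping on a random pedigree", {
  rp <- random_pedigree(n = 50L, seed = 13L)
  set.seed(99)
  q_mc <- allele_drop_q(rp, reps = 2e5)
  co <- group_coefficients(rp)
  expect_lt(max(abs(co$q - q_mc)), 0.005)
})

test_that("A-inverse obeys the Henderson construction", {
  single <- as_pedigree(data.frame(id = "z", sire = NA, dam = NA, cohort = 1,
                                   sex = "F", immigrant = FALSE))
  expect_equal(as.matrix(a_inverse(single)$Ainv), matrix(1), ignore_attr = TRUE)

  ped <- as_pedigree(trio)
  got <- as.matrix(a_inverse(ped)$Ainv)
  A3 <- tabular_A(ped)
  expect_equal(got, solve(A3), tolerance = 1e-12, ignore_attr = TRUE)

  for (seed in 1:5) {
    rp <- random_pedigree(n = 60L, seed = seed + 20L)
    Ainv <- as.matrix(a_inverse(rp)$Ainv)
    expect_lt(max(abs(Ainv %*% tabular_A(rp) - diag(nrow(rp)))), 1e-8)
  }
})

test_that("coefficient and A-inverse writers round-trip", {
  rp <- random_pedigree(n = 30L, seed = 31L)
  co <- group_coefficients(rp)
  dir <- withr::local_tempdir()
  write_coefficients(co, file.path(dir, "coef.csv"))
  back <- read.csv(file.path(dir, "coef.csv"), stringsAsFactors = FALSE)
  expect_equal(back$q, co$q, tolerance = 1e-12)

  ai <- a_inverse(rp)
  write_ainverse(ai, file.path(dir, "ainv.csv"),
                 file.path(dir, "ainv_idx.csv"))
  tri <- read.csv(file.path(dir, "ainv.csv"))
  idx <- read.csv(file.path(dir, "ainv_idx.csv"), stringsAsFactors = FALSE)
  expect_identical(idx$id, rp$id)
  M <- matrix(0, nrow(rp), nrow(rp))
  M[cbind(tri$i + 1L, tri$j + 1L)] <- tri$value
  M[upper.tri(M)] <- t(M)[upper.tri(M)]
  expect_equal(M, as.matrix(ai$Ainv), tolerance = 1e-12, ignore_attr = TRUE)
})
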