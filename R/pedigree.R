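#' Construct a validated, topologically sorted pedigree
#'
#' Builds a `gg_pedigree` from a data frame with columns `id`, `sire`, `dam`,
#' `cohort`, `sex` and `immigrant`. Unknown parents are encoded as `NA` or an
#' empty string. Rows are re-ordered so that parents always precede their
#' offspring (Kahn-style by generation, ties broken by input order, so the
#' result is deterministic and invariant to the input row order).
#'
#' Individuals with both parents unknown are pedigree founders; the
#' `immigrant` flag may be `TRUE` only for founders (immigrants arrive from
#' outside the population as adults of unknown parentage).
#'
#' @param df data frame with columns `id`, `sire`, `dam`, `cohort`, `sex`,
#'   `immigrant`.
#' @return An object of class `gg_pedigree`: a data frame in topological
#'   order with character `id`/`sire`/`dam`, integer `cohort`, character
#'   `sex` (`"F"`, `"M"` or `NA`), logical `immigrant`, and integer
#'   `sire_idx`/`dam_idx` columns (0 = unknown parent).
#' @seealso [read_pedigree()], [prune_to_phenotyped()], [assign_groups()],
#'   [group_coefficients()], [a_inverse()]
#' @export
as_pedigree <- function(df) {
  need <- c("id", "sire", "dam", "cohort", "sex", "immigrant")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("pedigree is missing column(s): ", paste(miss, collapse = ", "))

  blank_to_na <- function(x) {
    x <- as.character(x)
    x[!is.na(x) & (x == "" | toupper(x) == "NA")] <- NA_character_
    x
  }
  id <- blank_to_na(df$id)
  if (anyNA(id)) stop("pedigree contains missing ids")
  if (anyDuplicated(id)) {
    stop("duplicated pedigree id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  sire <- blank_to_na(df$sire)
  dam <- blank_to_na(df$dam)
  for (nm in c("sire", "dam")) {
    p <- if (nm == "sire") sire else dam
    bad <- setdiff(p[!is.na(p)], id)
    if (length(bad) > 0L)
      stop("pedigree references unknown ", nm, "(s): ",
           paste(bad, collapse = ", "))
  }
  self <- !is.na(sire) & sire == id | !is.na(dam) & dam == id
  if (any(self))
    stop("individual is its own parent: ", id[which(self)[1L]])

  sex <- toupper(blank_to_na(df$sex))
  sex[!is.na(sex) & !(sex %in% c("F", "M"))] <- NA_character_
  immigrant <- as.logical(df$immigrant)
  immigrant[is.na(immigrant)] <- FALSE
  founder <- is.na(sire) & is.na(dam)
  if (any(immigrant & !founder)) {
    stop("immigrant flag set for non-founder(s): ",
         paste(id[immigrant & !founder], collapse = ", "))
  }

  n <- length(id)
  sidx <- match(sire, id)
  didx <- match(dam, id)
  sidx[is.na(sidx)] <- 0L
  didx[is.na(didx)] <- 0L

  # generation-wise Kahn sort: place everyone whose parents are placed,
  # preserving input order within a round; leftovers imply a cycle
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ready <- which(!placed &
                     (sidx == 0L | placed[pmax(sidx, 1L)]) &
                     (didx == 0L | placed[pmax(didx, 1L)]))
    if (length(ready) == 0L) break
    ord <- c(ord, ready)
    placed[ready] <- TRUE
  }
  if (length(ord) < n) {
    # walk parent links among unplaced rows until one repeats
    cur <- which(!placed)[1L]
    seen <- integer(0)
    while (!(cur %in% seen)) {
      seen <- c(seen, cur)
      nxt <- c(sidx[cur], didx[cur])
      nxt <- nxt[nxt > 0L & !placed[pmax(nxt, 1L)]]
      cur <- nxt[1L]
    }
    stop("pedigree contains a cycle involving individual ", id[cur])
  }

  out <- data.frame(
    id = id[ord], sire = sire[ord], dam = dam[ord],
    cohort = as.integer(df$cohort)[ord], sex = sex[ord],
    immigrant = immigrant[ord], stringsAsFactors = FALSE
  )
  out$sire_idx <- ifelse(is.na(out$sire), 0L, match(out$sire, out$id))
  out$dam_idx <- ifelse(is.na(out$dam), 0L, match(out$dam, out$id))
  rownames(out) <- NULL
  class(out) <- c("gg_pedigree", "data.frame")
  out
}

#' Read a pedigree from CSV
#'
#' Reads a UTF-8 CSV with header columns `id`, `sire`, `dam`, `cohort`,
#' `sex`, `immigrant` (unknown parents empty or `"NA"`) and returns a
#' validated [as_pedigree()] object.
#'
#' @param path path to the pedigree CSV file.
#' @return A `gg_pedigree`.
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  as_pedigree(df)
}

#' @export
print.gg_pedigree <- function(x, ...) {
  nf <- sum(x$sire_idx == 0L & x$dam_idx == 0L)
  cat(sprintf(
    "Pedigree: %d individuals (%d founders, %d immigrant founders), cohorts %s-%s\n",
    nrow(x), nf, sum(x$immigrant),
    min(x$cohort, na.rm = TRUE), max(x$cohort, na.rm = TRUE)))
  invisible(x)
}

#' Prune a pedigree to phenotyped individuals and their ancestors
#'
#' Retains the ancestor closure of a set of phenotyped individuals: the
#' phenotyped individuals themselves plus every assigned ancestor to any
#' depth. All other individuals (including immigrants that left no
#' phenotyped descendants) are dropped, so founders retained after pruning
#' are exactly those that contributed to the phenotyped set.
#'
#' @param ped a `gg_pedigree`.
#' @param phenotyped_ids character vector of ids with phenotypes; must all
#'   be present in `ped`.
#' @return The pruned `gg_pedigree`.
#' @export
prune_to_phenotyped <- function(ped, phenotyped_ids) {
  stopifnot(inherits(ped, "gg_pedigree"))
  phenotyped_ids <- unique(as.character(phenotyped_ids))
  if (length(phenotyped_ids) == 0L) stop("empty set of phenotyped individuals")
  bad <- setdiff(phenotyped_ids, ped$id)
  if (length(bad) > 0L)
    stop("phenotyped id(s) not in pedigree: ", paste(bad, collapse = ", "))
  keep <- ped$id %in% phenotyped_ids
  # reverse topological sweep marks parents of every kept individual
  for (i in rev(seq_len(nrow(ped)))) {
    if (keep[i]) {
      if (ped$sire_idx[i] > 0L) keep[ped$sire_idx[i]] <- TRUE
      if (ped$dam_idx[i] > 0L) keep[ped$dam_idx[i]] <- TRUE
    }
  }
  out <- ped[keep, c("id", "sire", "dam", "cohort", "sex", "immigrant")]
  as_pedigree(out)
}

#' Assign pedigree founders to immigrant and native genetic groups
#'
#' Founders (individuals with both parents unknown) flagged as immigrants
#' form the IMMIGRANT group; all other founders form the NATIVE group.
#' Apply after [prune_to_phenotyped()] so that the immigrant group contains
#' only immigrants that contributed descendants to the phenotyped set.
#'
#' @param ped a `gg_pedigree`.
#' @return Named character vector over founder ids with values
#'   `"IMMIGRANT"` or `"NATIVE"`.
#' @export
assign_groups <- function(ped) {
  stopifnot(inherits(ped, "gg_pedigree"))
  founder <- ped$sire_idx == 0L & ped$dam_idx == 0L
  grp <- ifelse(ped$immigrant[founder], "IMMIGRANT", "NATIVE")
  names(grp) <- ped$id[founder]
  grp
}

#' Genetic-group and inbreeding coefficients
#'
#' Computes, for every pedigree individual, the expected immigrant-group
#' genome fraction \eqn{q_i} by the parental averaging recursion
#' (\eqn{q_i = (q_{sire} + q_{dam})/2}, immigrant founders 1, native
#' founders 0, an unknown single parent counting as a phantom native
#' founder with \eqn{q = 0}), and Wright's inbreeding coefficient
#' \eqn{f_i} (the kinship of the parents) by the exact Meuwissen-Luo
#' algorithm. Both are exact up to floating-point rounding.
#'
#' @param ped a `gg_pedigree`.
#' @param groups optional founder group assignment as returned by
#'   [assign_groups()]; defaults to `assign_groups(ped)`.
#' @return Data frame with columns `id`, `q`, `f` in pedigree order.
#' @export
group_coefficients <- function(ped, groups = NULL) {
  stopifnot(inherits(ped, "gg_pedigree"))
  if (is.null(groups)) groups <- assign_groups(ped)
  founder <- ped$sire_idx == 0L & ped$dam_idx == 0L
  miss <- setdiff(ped$id[founder], names(groups))
  if (length(miss) > 0L)
    stop("founders without group assignment: ", paste(miss, collapse = ", "))
  extra <- setdiff(names(groups), ped$id[founder])
  if (length(extra) > 0L)
    stop("group assignment for non-founder(s): ", paste(extra, collapse = ", "))

  n <- nrow(ped)
  q <- numeric(n)
  for (i in seq_len(n)) {
    if (founder[i]) {
      q[i] <- if (groups[[ped$id[i]]] == "IMMIGRANT") 1 else 0
    } else {
      qs <- if (ped$sire_idx[i] > 0L) q[ped$sire_idx[i]] else 0
      qd <- if (ped$dam_idx[i] > 0L) q[ped$dam_idx[i]] else 0
      q[i] <- (qs + qd) / 2
    }
  }
  fd <- inbreeding_cpp(ped$sire_idx, ped$dam_idx)
  data.frame(id = ped$id, q = q, f = fd$f, stringsAsFactors = FALSE)
}

#' Sparse inverse additive-relatedness matrix
#'
#' Assembles \eqn{A^{-1}} directly from the pedigree by the
#' Henderson-Quaas rules with inbreeding-corrected Mendelian-sampling
#' variances: \eqn{d_i = 0.5 - 0.25(f_{sire} + f_{dam})} when both parents
#' are known, \eqn{0.75 - 0.25 f_{known}} with one known parent, and 1 for
#' founders. The result satisfies \eqn{A^{-1} A = I} where \eqn{A} is the
#' additive (numerator) relationship matrix.
#'
#' @param ped a `gg_pedigree`.
#' @return List of class `gg_ainv` with elements `Ainv` (sparse symmetric
#'   `dsCMatrix` in pedigree order), `d` (Mendelian-sampling
#'   variance scalars) and `ids`.
#' @export
a_inverse <- function(ped) {
  stopifnot(inherits(ped, "gg_pedigree"))
  n <- nrow(ped)
  fd <- inbreeding_cpp(ped$sire_idx, ped$dam_idx)
  alpha <- 1 / fd$d
  s <- ped$sire_idx
  d <- ped$dam_idx
  i <- seq_len(n)

  ii <- i; jj <- i; xx <- alpha
  ks <- s > 0L
  kd <- d > 0L
  # parent-offspring
  ii <- c(ii, i[ks], i[kd]); jj <- c(jj, s[ks], d[kd])
  xx <- c(xx, -alpha[ks] / 2, -alpha[kd] / 2)
  # parent-parent
  ii <- c(ii, s[ks], d[kd]); jj <- c(jj, s[ks], d[kd])
  xx <- c(xx, alpha[ks] / 4, alpha[kd] / 4)
  both <- ks & kd
  ii <- c(ii, pmax(s[both], d[both])); jj <- c(jj, pmin(s[both], d[both]))
  xx <- c(xx, alpha[both] / 4)

  lower <- ii >= jj
  Ainv <- Matrix::sparseMatrix(
    i = c(ii[lower], jj[!lower]), j = c(jj[lower], ii[!lower]),
    x = c(xx[lower], xx[!lower]), dims = c(n, n), symmetric = TRUE
  )
  structure(list(Ainv = Ainv, d = fd$d, ids = ped$id), class = "gg_ainv")
}

#' @export
print.gg_ainv <- function(x, ...) {
  cat(sprintf("Inverse relatedness structure: %d x %d, %d stored entries\n",
              length(x$ids), length(x$ids), length(x$Ainv@x)))
  invisible(x)
}

#' Write genetic-group and inbreeding coefficients to CSV
#'
#' @param coefs data frame from [group_coefficients()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_coefficients <- function(coefs, path) {
  utils::write.csv(coefs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the sparse inverse relatedness matrix as coordinate text
#'
#' Emits the lower triangle of \eqn{A^{-1}} in `i j value` format with
#' 0-based indices, plus a companion id-index map CSV.
#'
#' @param ainv a `gg_ainv` from [a_inverse()].
#' @param path output path for the triplet file.
#' @param index_path output path for the id-index map.
#' @return `path`, invisibly.
#' @export
write_ainverse <- function(ainv, path, index_path = paste0(path, ".index.csv")) {
  stopifnot(inherits(ainv, "gg_ainv"))
  tri <- as(ainv$Ainv, "TsparseMatrix")
  keep <- tri@i >= tri@j
  df <- data.frame(i = tri@i[keep], j = tri@j[keep], value = tri@x[keep])
  df <- df[order(df$i, df$j), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(
    data.frame(index = seq_along(ainv$ids) - 1L, id = ainv$ids),
    index_path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
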