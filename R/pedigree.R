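#' Construct a pedigree
#'
#' Builds a validated, topologically sorted pedigree from animal/sire/dam id
#' vectors. Unknown parents are coded by `unknown` (default `"0"`; `NA` is
#' always accepted too). Parents referenced but not listed as animals are
#' either auto-added as founders (`add_founders = TRUE`) or raise an error.
#'
#' The returned object is a data frame with columns `animal`, `sire`, `dam`
#' (characters, `NA` for unknown parent) ordered so that parents precede
#' offspring, plus integer attributes `sire_idx`/`dam_idx` (0 = unknown) and
#' `input_order` mapping back to the original row order.
#'
#' @param animal,sire,dam character (or coercible) id vectors of equal length.
#' @param unknown token marking an unknown parent.
#' @param add_founders auto-add referenced-but-unlisted parents as founders.
#' @return An object of class `pedigree`.
#' @examples
#' ped <- pedigree(c("o", "s", "d"), c("s", "0", "0"), c("d", "0", "0"))
#' ped$animal  # founders first
#' @export
pedigree <- function(animal, sire, dam, unknown = "0", add_founders = FALSE) {
  animal <- as.character(animal)
  sire <- as.character(sire)
  dam <- as.character(dam)
  if (length(sire) != length(animal) || length(dam) != length(animal))
    stop("animal, sire and dam must have equal length")
  if (!is.na(unknown)) {
    sire[!is.na(sire) & sire == unknown] <- NA
    dam[!is.na(dam) & dam == unknown] <- NA
  }
  if (anyDuplicated(animal))
    stop("duplicate animal id: ", animal[duplicated(animal)][1L])
  self <- which(animal == sire | animal == dam)
  if (length(self))
    stop("pedigree cycle: animal ", animal[self[1L]], " is its own parent")

  parents <- unique(c(sire, dam))
  parents <- parents[!is.na(parents)]
  missing_par <- setdiff(parents, animal)
  if (length(missing_par)) {
    if (!add_founders)
      stop("parent id(s) absent from animal column: ",
           paste(head(missing_par, 5L), collapse = ", "),
           " (set add_founders = TRUE to add them as founders)")
    animal <- c(missing_par, animal)
    sire <- c(rep(NA_character_, length(missing_par)), sire)
    dam <- c(rep(NA_character_, length(missing_par)), dam)
  }

  n <- length(animal)
  idx <- function(x) {
    i <- match(x, animal)
    i[is.na(x)] <- 0L
    i
  }
  si <- idx(sire)
  di <- idx(dam)

  # Kahn topological sort; on failure name an animal on a cycle
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) if (p > 0L) {
      kids[[p]] <- c(kids[[p]], i)
      indeg[i] <- indeg[i] + 1L
    }
  }
  ord <- integer(n)
  nq <- length(which(indeg == 0L))
  ord[seq_len(nq)] <- which(indeg == 0L)
  done <- 0L
  while (done < nq) {
    done <- done + 1L
    v <- ord[done]
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) { nq <- nq + 1L; ord[nq] <- k }
    }
  }
  ord <- ord[seq_len(nq)]
  if (length(ord) < n) {
    bad <- setdiff(seq_len(n), ord)
    stop("pedigree cycle detected involving animal ", animal[bad[1L]])
  }

  out <- data.frame(animal = animal[ord], sire = sire[ord], dam = dam[ord],
                    stringsAsFactors = FALSE)
  remap <- match(seq_len(n), ord)  # old index -> new position
  si2 <- ifelse(si[ord] > 0L, remap[pmax(si[ord], 1L)], 0L)
  di2 <- ifelse(di[ord] > 0L, remap[pmax(di[ord], 1L)], 0L)
  attr(out, "sire_idx") <- as.integer(si2)
  attr(out, "dam_idx") <- as.integer(di2)
  attr(out, "input_order") <- order(ord)  # new position of each input row
  class(out) <- c("pedigree", "data.frame")
  out
}

#' @export
#' @method print pedigree
print.pedigree <- function(x, ...) {
  cat("Pedigree with", nrow(x), "animals (",
      sum(attr(x, "sire_idx") == 0L & attr(x, "dam_idx") == 0L),
      "founders ), parents-first order\n")
  print.data.frame(head(as.data.frame(x), 6L), row.names = FALSE)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Read / write a pedigree file
#'
#' Headered CSV or TSV with columns `animal,sire,dam` (delimiter inferred
#' from the extension, `.csv` = comma, otherwise tab).
#'
#' @param path file path.
#' @param unknown unknown-parent token (written for `NA` parents).
#' @param add_founders see [pedigree()].
#' @return `read_pedigree`: a [pedigree()]; `write_pedigree`: `path`,
#'   invisibly. Rows are written in the original input order.
#' @export
read_pedigree <- function(path, unknown = "0", add_founders = FALSE) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- read.table(path, header = TRUE, sep = sep, colClasses = "character")
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(d)))
    stop("pedigree file must have columns animal, sire, dam")
  pedigree(d$animal, d$sire, d$dam, unknown = unknown,
           add_founders = add_founders)
}

#' @rdname read_pedigree
#' @param ped a [pedigree()].
#' @export
write_pedigree <- function(ped, path, unknown = "0") {
  d <- as.data.frame(ped)[attr(ped, "input_order"), , drop = FALSE]
  d$sire[is.na(d$sire)] <- unknown
  d$dam[is.na(d$dam)] <- unknown
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  write.table(d, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Inbreeding coefficients
#'
#' Meuwissen & Luo style recursion over the sorted pedigree.
#' @param ped a [pedigree()].
#' @return named numeric vector of inbreeding coefficients.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  setNames(inbreeding_cpp(attr(ped, "sire_idx"), attr(ped, "dam_idx")),
           ped$animal)
}

.ancestral_closure <- function(ped, ids) {
  si <- attr(ped, "sire_idx"); di <- attr(ped, "dam_idx")
  keep <- logical(nrow(ped))
  keep[match(ids, ped$animal)] <- TRUE
  for (i in rev(seq_len(nrow(ped)))) {
    if (keep[i]) {
      if (si[i] > 0L) keep[si[i]] <- TRUE
      if (di[i] > 0L) keep[di[i]] <- TRUE
    }
  }
  which(keep)
}

#' Numerator relationship matrix
#'
#' Dense additive relationship matrix by the tabular method, computed over
#' the ancestral closure of `ids` and then sliced to `ids`. Accounts for
#' inbreeding by construction.
#'
#' @param ped a [pedigree()].
#' @param ids animals to keep (default all); order preserved in the result.
#' @return dense symmetric matrix with animal ids as dimnames.
#' @export
nrm <- function(ped, ids = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (is.null(ids)) ids <- ped$animal
  if (!length(ids)) stop("empty id subset")
  miss <- setdiff(ids, ped$animal)
  if (length(miss)) stop("ids not in pedigree: ", paste(head(miss), collapse = ", "))
  keep <- .ancestral_closure(ped, ids)
  si <- attr(ped, "sire_idx")[keep]
  di <- attr(ped, "dam_idx")[keep]
  remap <- integer(nrow(ped)); remap[keep] <- seq_along(keep)
  si <- ifelse(si > 0L, remap[pmax(si, 1L)], 0L)
  di <- ifelse(di > 0L, remap[pmax(di, 1L)], 0L)
  A <- tabular_a_cpp(as.integer(si), as.integer(di))
  dimnames(A) <- list(ped$animal[keep], ped$animal[keep])
  A[ids, ids, drop = FALSE]
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding (Mendelian sampling variances from
#' Meuwissen & Luo coefficients); the dense A is never formed.
#'
#' @param ped a [pedigree()].
#' @return sparse symmetric matrix (`dsCMatrix`) in pedigree order.
#' @export
nrm_inverse <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  si <- attr(ped, "sire_idx"); di <- attr(ped, "dam_idx")
  F <- inbreeding_cpp(si, di)
  Fs <- ifelse(si > 0L, F[pmax(si, 1L)], 0)
  Fd <- ifelse(di > 0L, F[pmax(di, 1L)], 0)
  d <- ifelse(si > 0L & di > 0L, 0.5 - 0.25 * (Fs + Fd),
       ifelse(si > 0L, 0.75 - 0.25 * Fs,
       ifelse(di > 0L, 0.75 - 0.25 * Fd, 1)))
  b <- 1 / d
  # vectorised triplet assembly of Henderson's contributions (both triangles
  # written explicitly; sparseMatrix sums duplicates)
  anim <- seq_len(n)
  hs <- si > 0L; hd <- di > 0L; both <- hs & hd
  ii <- c(anim, si[hs], di[hd])
  jj <- c(anim, si[hs], di[hd])
  xx <- c(b, 0.25 * b[hs], 0.25 * b[hd])
  ii <- c(ii, anim[hs], si[hs], anim[hd], di[hd])
  jj <- c(jj, si[hs], anim[hs], di[hd], anim[hd])
  xx <- c(xx, rep(-0.5 * b[hs], 2L), rep(-0.5 * b[hd], 2L))
  ii <- c(ii, si[both], di[both])
  jj <- c(jj, di[both], si[both])
  xx <- c(xx, rep(0.25 * b[both], 2L))
  M <- sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                    dimnames = list(ped$animal, ped$animal))
  forceSymmetric(M)
}

#' Export a sparse A-inverse as coordinate triplets
#'
#' Writes a headered TSV `(i, j, value)` of the lower triangle, with animal
#' ids as labels.
#' @param Ainv sparse symmetric matrix with dimnames.
#' @param path output path.
#' @export
write_nrm_inverse <- function(Ainv, path) {
  T <- as(as(tril(Ainv), "generalMatrix"), "TsparseMatrix")
  d <- data.frame(i = rownames(Ainv)[T@i + 1L], j = colnames(Ainv)[T@j + 1L],
                  value = T@x)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.chol_logdet <- function(Ch) {
  2 * as.numeric(determinant(Ch, logarithm = TRUE, sqrt = TRUE)$modulus)
}

#' Genotyped-block algebra from the sparse A-inverse
#'
#' For a partition of the pedigree into genotyped (block 1) and
#' non-genotyped (block 2) animals, computes from the sparse \eqn{A^{-1}}
#' alone: the dense genotyped block \eqn{A_{11}}, the projection
#' \eqn{A_{21} A_{11}^{-1}} (as a matrix; its transpose gives
#' \eqn{A_{11}^{-1} A_{12}}), and
#' \eqn{\log\det(A_{22} - A_{21} A_{11}^{-1} A_{12})}, the Schur term of the
#' determinant factorisation \eqn{\det A = \det A_{11} \cdot \det(\cdot)}.
#' The dense \eqn{A_{22}} is never formed.
#'
#' @param ped a [pedigree()].
#' @param genotyped character ids of the genotyped animals (block 1).
#' @param Ainv optionally a precomputed [nrm_inverse()] of `ped`.
#' @return list with `A11` (dense, dimnames = genotyped ids), `P21`
#'   (\eqn{A_{21}A_{11}^{-1}}, rows = non-genotyped in pedigree order),
#'   `project` (function `v -> A11^{-1} A12 v`), `schur_logdet`,
#'   `genotyped`, `nongenotyped`, and the index vectors `idx1`, `idx2`.
#' @export
a11_projection <- function(ped, genotyped, Ainv = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  if (!length(genotyped)) stop("genotyped set is empty")
  idx1 <- match(genotyped, ped$animal)
  if (anyNA(idx1)) stop("genotyped ids absent from pedigree")
  idx2 <- setdiff(seq_len(nrow(ped)), idx1)
  if (is.null(Ainv)) Ainv <- nrm_inverse(ped)
  B <- as(Ainv, "generalMatrix")
  n1 <- length(idx1); n2 <- length(idx2)
  if (n2 == 0L) {
    A11 <- as.matrix(solve(forceSymmetric(B)))[idx1, idx1, drop = FALSE]
    dimnames(A11) <- list(genotyped, genotyped)
    P21 <- matrix(0, 0, n1, dimnames = list(character(0), genotyped))
    return(list(A11 = A11, P21 = P21,
                project = function(v) crossprod(P21, v),
                schur_logdet = 0,
                genotyped = genotyped, nongenotyped = character(0),
                idx1 = idx1, idx2 = idx2))
  }
  B22 <- forceSymmetric(B[idx2, idx2, drop = FALSE])
  B21 <- B[idx2, idx1, drop = FALSE]
  Ch22 <- Cholesky(B22, LDL = FALSE, perm = TRUE)
  Y <- as.matrix(solve(Ch22, B21))            # B22^{-1} B21
  S <- as.matrix(B[idx1, idx1, drop = FALSE]) - as.matrix(t(B21)) %*% Y
  S <- (S + t(S)) / 2
  A11 <- tryCatch(chol2inv(chol(S)), error = function(e)
    stop("A11 numerically singular: ", conditionMessage(e)))
  dimnames(A11) <- list(genotyped, genotyped)
  P21 <- -Y                                   # A21 A11^{-1} = -B22^{-1} B21
  rownames(P21) <- ped$animal[idx2]
  colnames(P21) <- genotyped
  list(A11 = A11,
       P21 = P21,
       project = function(v) crossprod(P21, v),  # A11^{-1} A12 v
       schur_logdet = -.chol_logdet(Ch22),
       genotyped = genotyped, nongenotyped = ped$animal[idx2],
       idx1 = idx1, idx2 = idx2)
}
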