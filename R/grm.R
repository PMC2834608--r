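#' Genomic relationship matrix
#'
#' VanRaden-type marker relationship matrix from centered gene contents:
#' \deqn{G = (m - 1p')(m - 1p')' / s,\qquad s = \sum_j 2\rho_j(1-\rho_j),}
#' or, with explicit nonnegative per-locus weights \eqn{h_j} (e.g. squared
#' estimated SNP effects), \eqn{G = (m - 1p')\,\mathrm{diag}(h)\,(m - 1p')'}.
#' The default weights \eqn{h_j = 1/s} make \eqn{E[G(M)] = A} under the
#' marker model with founder allele frequencies \eqn{\rho}.
#'
#' @param gc a [gene_content()].
#' @param weights optional per-locus weights (length = loci).
#' @return dense symmetric matrix over the genotyped animals.
#' @export
grm <- function(gc, weights = NULL) {
  stopifnot(inherits(gc, "gene_content"))
  W <- sweep(unclass(gc), 2L, attr(gc, "p"))
  if (is.null(weights)) {
    s <- attr(gc, "s")
    if (s <= 0) stop("all loci monomorphic (s = 0)")
    G <- tcrossprod(W) / s
  } else {
    if (length(weights) != ncol(W) || any(weights < 0))
      stop("weights must be nonnegative, one per locus")
    G <- tcrossprod(W %*% diag(sqrt(weights), ncol(W)))
  }
  (G + t(G)) / 2
}

#' Extend a genomic relationship matrix to non-genotyped animals
#'
#' Dense materialisation of the pedigree extension
#' \deqn{G^* = \begin{pmatrix} G & G P' \\ P G &
#'   A_{22} - P (A_{11} - G) P' \end{pmatrix}, \quad P = A_{21}A_{11}^{-1},}
#' the conditional covariance of the genomic effect given the observed gene
#' contents. \eqn{G^*} equals \eqn{G} when every animal is genotyped and
#' \eqn{A} when none is. Intended for small problems and verification; the
#' estimation path only ever needs the sparse-inverse correction of
#' [hmat_inverse()], never this dense matrix.
#'
#' @param G genomic relationship matrix over the genotyped animals
#'   (dimnames = animal ids), e.g. from [grm()].
#' @param ped a [pedigree()] containing all animals.
#' @param proj optional [a11_projection()] for `rownames(G)`.
#' @return dense symmetric matrix over `c(genotyped, non-genotyped)` (block
#'   order: genotyped first).
#' @export
grm_extend <- function(G, ped, proj = NULL) {
  stopifnot(is.matrix(G), !is.null(rownames(G)))
  if (is.null(proj)) proj <- a11_projection(ped, rownames(G))
  g1 <- proj$genotyped; g2 <- proj$nongenotyped
  n1 <- length(g1); n2 <- length(g2)
  out <- matrix(0, n1 + n2, n1 + n2, dimnames = list(c(g1, g2), c(g1, g2)))
  out[seq_len(n1), seq_len(n1)] <- G
  if (n2) {
    P <- proj$P21
    PG <- P %*% G
    out[n1 + seq_len(n2), seq_len(n1)] <- PG
    out[seq_len(n1), n1 + seq_len(n2)] <- t(PG)
    A22 <- nrm(ped, g2)
    out[n1 + seq_len(n2), n1 + seq_len(n2)] <-
      A22 - P %*% (proj$A11 - G) %*% t(P)
  }
  (out + t(out)) / 2
}

#' Blend a genomic relationship matrix with the pedigree block
#'
#' \eqn{G_w = (1-w) G + w A_{11}}, the genotyped block of the combined
#' relationship matrix \eqn{H_w = (1-w)G^* + wA}; \eqn{w} is the relative
#' weight on the polygenic effect. \eqn{G_w} is positive definite for any
#' \eqn{w > 0} even when \eqn{G} is singular.
#'
#' @param G genomic relationship matrix (genotyped animals).
#' @param A11 matching pedigree relationship block.
#' @param w polygenic weight in \eqn{[0, 1]}.
#' @return `G_w` with attributes `chol` (upper factor) and `logdet`.
#' @export
grm_blend <- function(G, A11, w) {
  stopifnot(w >= 0, w <= 1, all(dim(G) == dim(A11)))
  Gw <- (1 - w) * G + w * A11
  Gw <- (Gw + t(Gw)) / 2
  R <- tryCatch(chol(Gw), error = function(e) {
    if (w == 0)
      stop("G is singular at w = 0; use a positive polygenic weight w")
    stop("G_w not positive definite: ", conditionMessage(e))
  })
  # chol() can slip through an exactly singular matrix on a pivot of order
  # sqrt(machine eps); a well-conditioned block sits orders of magnitude
  # above this threshold
  if (min(diag(R)) < 1e-6 * max(diag(R))) {
    if (w == 0)
      stop("G is singular at w = 0; use a positive polygenic weight w")
    stop("G_w numerically singular")
  }
  structure(Gw, chol = R, logdet = 2 * sum(log(diag(R))))
}

#' Inverse of the combined relationship matrix H_w
#'
#' The combined matrix \eqn{H_w = (1-w) G^* + w A} has the sparse-plus-block
#' inverse
#' \deqn{H_w^{-1} = A^{-1} + \begin{pmatrix} G_w^{-1} - A_{11}^{-1} & 0 \\
#'   0 & 0\end{pmatrix}}
#' (correction in the genotyped block only) and log-determinant
#' \eqn{\log\det H_w = \log\det G_w + \log\det(A_{22} - A_{21}A_{11}^{-1}A_{12})}.
#' Everything is computed from the sparse \eqn{A^{-1}} and dense
#' genotyped-block algebra; no dense \eqn{n \times n} matrix is formed.
#'
#' @param ped a [pedigree()] (defines the animal order of the result).
#' @param Gw blended matrix from [grm_blend()] (dimnames = genotyped ids).
#' @param proj optional [a11_projection()] for the genotyped set.
#' @param Ainv optional precomputed [nrm_inverse()].
#' @return list of class `hmat_inv`: `Hinv` (sparse, pedigree order),
#'   `logdet`, `matvec` (function computing \eqn{H_w^{-1} v}), `animals`,
#'   `genotyped`, `proj`, `Gw`.
#' @export
hmat_inverse <- function(ped, Gw, proj = NULL, Ainv = NULL) {
  g1 <- rownames(Gw)
  if (is.null(g1)) stop("Gw needs animal dimnames")
  if (is.null(Ainv)) Ainv <- nrm_inverse(ped)
  if (is.null(proj)) proj <- a11_projection(ped, g1, Ainv = Ainv)
  R <- attr(Gw, "chol")
  if (is.null(R)) R <- chol((Gw + t(Gw)) / 2)
  Gwinv <- chol2inv(R)
  Delta <- Gwinv - chol2inv(chol(proj$A11))
  Delta <- (Delta + t(Delta)) / 2
  idx1 <- proj$idx1
  n <- nrow(ped)
  Corr <- sparseMatrix(i = rep(idx1, length(idx1)),
                       j = rep(idx1, each = length(idx1)),
                       x = as.numeric(t(Delta)), dims = c(n, n),
                       dimnames = dimnames(Ainv))
  Hinv <- forceSymmetric(as(Ainv, "generalMatrix") + Corr)
  ld <- attr(Gw, "logdet")
  if (is.null(ld)) ld <- 2 * sum(log(diag(R)))
  structure(list(Hinv = Hinv,
                 logdet = ld + proj$schur_logdet,
                 matvec = function(v) as.numeric(Hinv %*% v),
                 animals = ped$animal, genotyped = g1,
                 proj = proj, Gw = Gw),
            class = "hmat_inv")
}

#' @export
#' @method print hmat_inv
print.hmat_inv <- function(x, ...) {
  cat("H_w inverse:", length(x$animals), "animals (",
      length(x$genotyped), "genotyped ), logdet(H_w) =",
      format(x$logdet, digits = 8), "\n")
  invisible(x)
}
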