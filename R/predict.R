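#' Predict breeding values for animals outside the estimation run
#'
#' Two routes for animals (index set 3) that were not part of the fitted
#' model:
#'
#' * `method = "extended"` re-solves the mixed-model equations over the full
#'   pedigree (original records, extra animals record-less) at the fitted
#'   variance components, with all relationship blocks rebuilt over the full
#'   animal set. Augmenting with record-less animals leaves the estimation
#'   animals' GEBVs unchanged (verified and reported via the
#'   `"augmentation_error"` attribute). PEVs are available.
#' * `method = "shortcut"` applies the genotyped-candidate shortcut
#'   \eqn{\hat{\bar g}_3 = G_{w,31} G_{w,11}^{-1} \hat{\bar g}_1} with
#'   \eqn{G_{w,31} = (1-w) G_{31} + w A_{31}}: only the cross-block of the
#'   genomic relationship matrix and pedigree relationships of the
#'   candidates to the genotyped estimation animals are needed — the
#'   candidate self-block is never formed. Exact when the candidates'
#'   pedigree ties to non-genotyped animals pass entirely through the
#'   genotyped set (\eqn{A_{32} - A_{31}A_{11}^{-1}A_{12} = 0}); requires
#'   genotypes for every candidate. Point predictions only (no PEV).
#'
#' @param object an `ssgblup` fit.
#' @param ids animals to predict.
#' @param newped pedigree containing both the estimation animals and `ids`;
#'   defaults to the fit's pedigree (then `ids` must already be in it).
#' @param genotypes gene contents for genotyped animals among `ids`
#'   (matrix coded -1/0/1, rownames = ids; same loci as the fit). Required
#'   for the shortcut.
#' @param method `"extended"` or `"shortcut"`.
#' @param check numerically verify the shortcut's exactness condition
#'   (builds a dense A over the full pedigree — small problems only) or, for
#'   the extended route, always on (cheap).
#' @param pev compute PEVs for the extended route.
#' @param ... unused.
#' @return data frame with columns `animal`, `gebv`, `pev` (`NA` for the
#'   shortcut), `method`.
#' @export
predict.ssgblup <- function(object, ids, newped = NULL, genotypes = NULL,
                            method = c("extended", "shortcut"),
                            check = FALSE, pev = FALSE, ...) {
  method <- match.arg(method)
  ped <- if (is.null(newped)) object$pedigree else newped
  stopifnot(inherits(ped, "pedigree"))
  ids <- as.character(ids)
  miss <- setdiff(ids, ped$animal)
  if (length(miss))
    stop("animal(s) absent from pedigree: ", paste(head(miss), collapse = ", "))
  if (method == "extended")
    .predict_extended(object, ped, ids, genotypes, check = TRUE, pev = pev)
  else
    .predict_shortcut(object, ped, ids, genotypes, check = check)
}

.combine_genotypes <- function(object, genotypes) {
  gc0 <- object$genotypes
  if (is.null(genotypes)) return(gc0)
  genotypes <- as.matrix(genotypes)
  if (is.null(gc0)) stop("the fitted model has no genotypes")
  if (!is.null(colnames(genotypes)) &&
      all(colnames(gc0) %in% colnames(genotypes)))
    genotypes <- genotypes[, colnames(gc0), drop = FALSE]
  if (ncol(genotypes) != ncol(gc0))
    stop("extra genotypes must cover the same loci as the fit")
  extra <- setdiff(rownames(genotypes), rownames(gc0))
  m <- rbind(unclass(gc0), genotypes[extra, , drop = FALSE])
  gene_content(m, rho = attr(gc0, "rho"))
}

.predict_extended <- function(object, ped, ids, genotypes, check, pev) {
  vc <- object$varcomp
  gc <- .combine_genotypes(object, genotypes)
  md0 <- object$internal$md
  # rebuild the MME over the extended pedigree with the original records
  rec_ids <- object$pedigree$animal[md0$Zi]
  md <- .mme_data(md0$y, md0$X, rec_ids, ped$animal)
  Ainv <- nrm_inverse(ped)
  if (is.null(gc) || vc$weight >= 1) {
    Kinv <- Ainv
    logdetK <- -.chol_logdet(Cholesky(Ainv, LDL = FALSE, perm = TRUE))
  } else {
    g1 <- intersect(ped$animal, rownames(gc))
    gc_use <- gene_content(unclass(gc)[g1, , drop = FALSE],
                           rho = attr(gc, "rho"))
    proj <- a11_projection(ped, g1, Ainv = Ainv)
    Gw <- grm_blend(grm(gc_use), proj$A11, vc$weight)
    hm <- hmat_inverse(ped, Gw, proj = proj, Ainv = Ainv)
    Kinv <- hm$Hinv
    logdetK <- hm$logdet
  }
  res <- .aireml(md, Kinv, logdetK,
                 fixed = list(sigma2_g = vc$sigma2_g, sigma2_e = vc$sigma2_e))
  u <- setNames(res$fit$u, ped$animal)
  if (check) {
    est <- intersect(object$pedigree$animal, ped$animal)
    aug_err <- max(abs(u[est] -
      setNames(object$breeding_values$gebv, object$pedigree$animal)[est]))
  } else aug_err <- NA_real_
  pv <- rep(NA_real_, length(ids))
  if (isTRUE(pev))
    pv <- .mme_pev(res$fit$Ch, md$p, md$q, vc$sigma2_e,
                   match(ids, ped$animal))
  structure(data.frame(animal = ids, gebv = as.numeric(u[ids]), pev = pv,
                       method = "extended", stringsAsFactors = FALSE),
            augmentation_error = aug_err)
}

.predict_shortcut <- function(object, ped, ids, genotypes, check) {
  if (is.null(object$genotypes))
    stop("shortcut prediction needs a genotyped model")
  gc0 <- object$genotypes
  g1 <- rownames(gc0)
  m3 <- if (!is.null(genotypes)) as.matrix(genotypes) else
    unclass(gc0)[intersect(ids, g1), , drop = FALSE]
  miss <- setdiff(ids, rownames(m3))
  if (length(miss))
    stop("missing genotypes for animal(s): ", paste(head(miss), collapse = ", "))
  m3 <- m3[ids, , drop = FALSE]
  if (!is.null(colnames(m3)) && all(colnames(gc0) %in% colnames(m3)))
    m3 <- m3[, colnames(gc0), drop = FALSE]
  if (ncol(m3) != ncol(gc0))
    stop("candidate genotypes must cover the same loci as the fit")
  p <- attr(gc0, "p"); s <- attr(gc0, "s")
  W1 <- sweep(unclass(gc0), 2L, p)
  W3 <- sweep(m3, 2L, p)
  G31 <- tcrossprod(W3, W1) / s

  # A31 over the full pedigree from n1 sparse solves against (A_all)^-1
  Ainv_all <- nrm_inverse(ped)
  Ch <- Cholesky(Ainv_all, LDL = FALSE, perm = TRUE)
  idx1 <- match(g1, ped$animal)
  idx3 <- match(ids, ped$animal)
  E <- sparseMatrix(i = idx1, j = seq_along(idx1), x = 1,
                    dims = c(nrow(ped), length(idx1)))
  Acols <- solve(Ch, E)                      # A_all[, genotyped]
  A31 <- as.matrix(Acols[idx3, , drop = FALSE])

  w <- object$varcomp$weight
  Gw31 <- (1 - w) * G31 + w * A31
  Rw <- attr(object$internal$Gw, "chol")
  u1 <- setNames(object$breeding_values$gebv,
                 object$pedigree$animal)[g1]
  gebv3 <- as.numeric(Gw31 %*% backsolve(Rw, backsolve(Rw, u1, transpose = TRUE)))

  if (check) {
    # exactness condition A32 - A31 A11^{-1} A12 = 0 (dense; small problems)
    Afull <- nrm(ped)
    est2 <- setdiff(object$pedigree$animal, g1)
    A32 <- Afull[ids, est2, drop = FALSE]
    A11 <- Afull[g1, g1, drop = FALSE]
    A12 <- Afull[g1, est2, drop = FALSE]
    cond <- max(abs(A32 - A31 %*% solve(A11, A12)))
    if (cond > 1e-6)
      warning(sprintf(
        "shortcut exactness condition violated (max |A32 - A31 A11^-1 A12| = %.3g); predictions are approximate",
        cond))
  }
  data.frame(animal = ids, gebv = gebv3, pev = NA_real_,
             method = "shortcut", stringsAsFactors = FALSE)
}
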