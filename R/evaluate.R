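# Three-method comparison on simulated data: one-step (ssGBLUP), pedigree
# BLUP, and the two-step genomic evaluation fitted to EBVs of genotyped
# animals only.

.sim_gene_content <- function(sim, animals, freqs = NULL) {
  if (is.null(freqs))
    freqs <- allele_freqs(sim$geno, ids = intersect(sim$groups$base_boars,
                                                    animals))
  gene_content(sim$geno[animals, , drop = FALSE], rho = freqs)
}

.drop_candidates <- function(sim) {
  keep <- !(sim$ped$animal %in% sim$groups$candidates)
  pedigree(sim$ped$animal[keep], sim$ped$sire[keep], sim$ped$dam[keep],
           unknown = NA)
}

#' Fit the one-step model to a simulated data set
#'
#' Convenience wrapper around [ssgblup()]: phenotypes `y ~ 1`, full
#' simulated pedigree, genotypes of all genotyped animals, allele
#' frequencies estimated from the genotyped base boars (the scheme's
#' frequency source) unless supplied.
#'
#' @param sim an [sim_breeding_program()] output.
#' @param weight polygenic weight.
#' @param include_candidates include the record-less genotyped candidates in
#'   the estimation run (`FALSE` gives the candidate-excluded variant, whose
#'   candidates must then be predicted with [predict.ssgblup()]).
#' @param freqs optional allele-frequency vector (per SNP).
#' @param genotyped optional subset of genotyped animal ids to use.
#' @param ... passed to [ssgblup()].
#' @return an `ssgblup` fit.
#' @export
fit_onestep <- function(sim, weight = 0.01, include_candidates = TRUE,
                        freqs = NULL, genotyped = NULL, ...) {
  stopifnot(inherits(sim, "ssgblup_sim"))
  ped <- if (include_candidates) sim$ped else .drop_candidates(sim)
  if (is.null(genotyped)) genotyped <- rownames(sim$geno)
  genotyped <- intersect(genotyped, ped$animal)
  if (is.null(freqs))
    freqs <- allele_freqs(sim$geno, ids = sim$groups$base_boars)
  gc <- .sim_gene_content(sim, genotyped, freqs)
  ssgblup(y ~ 1, sim$pheno, ped, genotypes = gc, weight = weight, ...)
}

#' Pedigree BLUP on a simulated data set
#'
#' Traditional EBVs from the numerator relationship matrix alone
#' (equivalently the one-step model at polygenic weight 1).
#' @inheritParams fit_onestep
#' @export
fit_ped <- function(sim, ...) {
  stopifnot(inherits(sim, "ssgblup_sim"))
  ssgblup(y ~ 1, sim$pheno, sim$ped, genotypes = NULL, ...)
}

#' Two-step genomic evaluation
#'
#' Fits the genotyped-animals-only model \eqn{y_{EBV} = 1\mu + g + \epsilon}
#' where \eqn{y_{EBV}} are the traditional (pedigree) EBVs of the genotyped
#' training animals, \eqn{Var(g) = \sigma^2 (0.99\,G + 0.01\,A_{11})} over
#' all genotyped animals (training + candidates), and the residual is iid.
#' Both components are estimated by REML; candidates are predicted through
#' their genomic relationships with the training set.
#'
#' @param sim an [sim_breeding_program()] output.
#' @param ped_fit a [fit_ped()] result supplying the EBVs.
#' @param freqs optional allele-frequency vector.
#' @param blend fixed blending constants `c(genomic, pedigree)`.
#' @param varcomp optional fixed components `list(sigma2_g =, sigma2_e =)`.
#' @return list with `gebv` (named, all genotyped animals), `varcomp`,
#'   `logLik`.
#' @export
fit_two_step <- function(sim, ped_fit, freqs = NULL, blend = c(0.99, 0.01),
                         varcomp = NULL) {
  stopifnot(inherits(sim, "ssgblup_sim"))
  cand <- sim$groups$candidates
  allg <- rownames(sim$geno)
  train <- setdiff(allg, cand)
  miss <- setdiff(cand, allg)
  if (length(miss))
    stop("candidate(s) lacking genotypes: ", paste(head(miss), collapse = ", "))
  ebv <- setNames(ped_fit$breeding_values$gebv, ped_fit$pedigree$animal)
  if (anyNA(ebv[train])) stop("EBVs missing for some training animals")
  if (is.null(freqs))
    freqs <- allele_freqs(sim$geno, ids = sim$groups$base_boars)
  ord <- c(train, cand)                     # genotyped block order
  gc <- .sim_gene_content(sim, ord, freqs)
  G <- grm(gc)
  A11 <- a11_projection(sim$ped, ord)$A11
  K <- blend[1L] * G + blend[2L] * A11
  K <- (K + t(K)) / 2
  R <- chol(K)
  Kinv <- Matrix(chol2inv(R), sparse = TRUE)
  logdetK <- 2 * sum(log(diag(R)))
  dat <- data.frame(animal = train, y = as.numeric(ebv[train]),
                    stringsAsFactors = FALSE)
  mp <- .model_parts(y ~ 1, dat, "animal")
  md <- .mme_data(mp$y, mp$X, mp$ids, ord)
  res <- .aireml(md, Kinv, logdetK, fixed = varcomp)
  list(gebv = setNames(res$fit$u, ord),
       varcomp = list(sigma2_g = res$sigma2_g, sigma2_e = res$sigma2_e),
       logLik = res$logLik)
}

#' Prediction accuracy against true breeding values
#'
#' Pearson correlation between predicted and true breeding values over a
#' target animal set (by default the ids shared by both inputs).
#'
#' @param gebv named numeric vector (or data frame with columns
#'   `animal`, `gebv`).
#' @param tbv named numeric vector of true breeding values.
#' @param ids target set (default: intersection).
#' @return the correlation (scalar).
#' @export
accuracy <- function(gebv, tbv, ids = NULL) {
  if (is.data.frame(gebv)) gebv <- setNames(gebv$gebv, gebv$animal)
  if (is.null(ids)) ids <- intersect(names(gebv), names(tbv))
  ids <- intersect(intersect(ids, names(gebv)), names(tbv))
  if (length(ids) < 3L) stop("fewer than 3 overlapping animals")
  cor(as.numeric(gebv[ids]), as.numeric(tbv[ids]))
}

#' Compare one-step, pedigree and two-step evaluations
#'
#' Runs the full accuracy experiment on one simulated data set: one-step
#' ssGBLUP (optionally also the candidate-excluded variant), pedigree BLUP,
#' and the two-step evaluation, reporting estimated variance components and
#' the correlation between predictions and true breeding values over the
#' selection candidates.
#'
#' @param sim an [sim_breeding_program()] output.
#' @param weight polygenic weight for the one-step runs.
#' @param onestep2 also run the variant that excludes candidate genotypes
#'   from estimation (candidates then predicted via the extended system).
#' @param pev passed to [ssgblup()] (PEVs are not needed for accuracies).
#' @return data frame with one row per method: `method`, `sigma2_g`,
#'   `sigma2_e`, `cor_tbv`; fits attached as attribute `"fits"`.
#' @export
compare_methods <- function(sim, weight = 0.01, onestep2 = TRUE, pev = FALSE) {
  stopifnot(inherits(sim, "ssgblup_sim"))
  cand <- sim$groups$candidates
  one <- fit_onestep(sim, weight = weight, pev = pev)
  pedf <- fit_ped(sim, pev = pev)
  two <- fit_two_step(sim, pedf)
  rows <- list(
    data.frame(method = "one-step",
               sigma2_g = one$varcomp$sigma2_g,
               sigma2_e = one$varcomp$sigma2_e,
               cor_tbv = accuracy(one$breeding_values, sim$tbv, cand)),
    data.frame(method = "ped",
               sigma2_g = pedf$varcomp$sigma2_g,
               sigma2_e = pedf$varcomp$sigma2_e,
               cor_tbv = accuracy(pedf$breeding_values, sim$tbv, cand)),
    data.frame(method = "two-step",
               sigma2_g = two$varcomp$sigma2_g,
               sigma2_e = two$varcomp$sigma2_e,
               cor_tbv = accuracy(two$gebv, sim$tbv, cand)))
  fits <- list(onestep = one, ped = pedf, twostep = two)
  if (onestep2) {
    one2 <- fit_onestep(sim, weight = weight, include_candidates = FALSE,
                        pev = pev)
    pr <- predict(one2, ids = cand, newped = sim$ped,
                  genotypes = sim$geno[cand, , drop = FALSE],
                  method = "extended")
    rows <- c(rows, list(
      data.frame(method = "one-step-2",
                 sigma2_g = one2$varcomp$sigma2_g,
                 sigma2_e = one2$varcomp$sigma2_e,
                 cor_tbv = accuracy(setNames(pr$gebv, pr$animal),
                                    sim$tbv, cand))))
    fits$onestep2 <- one2
  }
  out <- do.call(rbind, rows)
  attr(out, "fits") <- fits
  out
}

#' Sensitivity of the polygenic-weight estimate to allele frequencies
#'
#' Re-runs the one-step profile likelihood under different allele-frequency
#' sources for the scenario in which the base boars are *not* genotyped:
#' `"base"` = frequencies observed in the base boars (the 'true' base
#' frequencies), `"current"` = frequencies observed in the earliest
#' genotyped boar generation, `"gengler"` = mixed-model (GLS) estimates
#' using the pedigree. Reports the estimated weight and its interval per
#' mode; no further results — the point of the harness is to show where the
#' profile sends the weight.
#'
#' @param sim an [sim_breeding_program()] output.
#' @param w weight grid for [profile.ssgblup()].
#' @param modes subset of `c("base", "current", "gengler")`.
#' @return data frame: `mode`, `w_hat`, `ci_lower`, `ci_upper`.
#' @export
allele_freq_sensitivity <- function(sim, w = seq(0.01, 0.19, by = 0.02),
                                    modes = c("base", "current", "gengler")) {
  stopifnot(inherits(sim, "ssgblup_sim"))
  genotyped <- c(sim$groups$boars, sim$groups$candidates)  # base boars out
  gens <- as.integer(sub("^G(\\d+)_.*", "\\1", sim$groups$boars))
  first_gen_boars <- sim$groups$boars[gens == min(gens)]
  rows <- lapply(modes, function(mode) {
    freqs <- switch(mode,
      base = allele_freqs(sim$geno, ids = sim$groups$base_boars),
      current = allele_freqs(sim$geno, ids = first_gen_boars),
      gengler = allele_freqs(sim$geno[genotyped, , drop = FALSE],
                             method = "gengler", ped = sim$ped))
    fit <- fit_onestep(sim, weight = w[1L], freqs = freqs,
                       genotyped = genotyped, pev = FALSE)
    pr <- profile(fit, w = w)
    data.frame(mode = mode, w_hat = pr$w_hat, ci_lower = pr$ci[1L],
               ci_upper = pr$ci[2L], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
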