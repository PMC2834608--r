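# Shared fixtures and independent oracles, all generated in code.

# random valid pedigree: nf founders, each later animal gets two earlier
# parents (possibly unknown with prob p_unknown)
rand_ped <- function(n, nf = 5, p_unknown = 0) {
  an <- paste0("a", seq_len(n))
  si <- da <- rep(NA_character_, n)
  for (i in (nf + 1):n) {
    if (runif(1) >= p_unknown) si[i] <- an[sample.int(i - 1L, 1L)]
    if (runif(1) >= p_unknown) da[i] <- an[sample.int(i - 1L, 1L)]
  }
  pedigree(an, si, da, unknown = NA)
}

rand_gene_content <- function(ids, L, clamp = TRUE) {
  m <- matrix(sample(c(-1, 0, 1), length(ids) * L, replace = TRUE),
              length(ids), L, dimnames = list(ids, paste0("s", seq_len(L))))
  rho <- (colMeans(m) + 1) / 2
  if (clamp) rho <- pmin(pmax(rho, 1e-6), 1 - 1e-6)
  gene_content(m, rho = rho)
}

# gene dropping of identified founder alleles; returns realised IBD-sharing
# based relationship estimates, vectorised over nrep replicates.
# Output: list(a1, a2) matrices nrep x n of allele labels per animal.
gene_drop_alleles <- function(ped, nrep) {
  n <- nrow(ped)
  si <- attr(ped, "sire_idx"); di <- attr(ped, "dam_idx")
  a1 <- matrix(0L, nrep, n); a2 <- matrix(0L, nrep, n)
  lab <- 0L
  for (i in seq_len(n)) {
    if (si[i] == 0L) a1[, i] <- lab <- lab + 1L
    else {
      pick <- runif(nrep) < 0.5
      a1[, i] <- ifelse(pick, a1[, si[i]], a2[, si[i]])
    }
    if (di[i] == 0L) a2[, i] <- lab <- lab + 1L
    else {
      pick <- runif(nrep) < 0.5
      a2[, i] <- ifelse(pick, a1[, di[i]], a2[, di[i]])
    }
  }
  list(a1 = a1, a2 = a2)
}

# Monte-Carlo estimate of the additive relationship a_ij = 2 * kinship:
# probability that random alleles from i and j are identical by descent.
gene_drop_relationship <- function(drop, i, j) {
  with(drop, {
    if (i == j) {
      1 + rowMeans(cbind(a1[, i] == a2[, i]))
    } else {
      0.5 * ((a1[, i] == a1[, j]) + (a1[, i] == a2[, j]) +
             (a2[, i] == a1[, j]) + (a2[, i] == a2[, j]))
    }
  })
}

# gene dropping of biallelic contents from founder frequency rho (one locus
# per replicate column); returns content matrix n x ncols in {-1,0,1}
gene_drop_content <- function(ped, rho, ncols) {
  n <- nrow(ped)
  si <- attr(ped, "sire_idx"); di <- attr(ped, "dam_idx")
  h1 <- h2 <- matrix(0L, n, ncols)
  for (i in seq_len(n)) {
    h1[i, ] <- if (si[i] == 0L) rbinom(ncols, 1L, rho) else {
      pick <- runif(ncols) < 0.5
      ifelse(pick, h1[si[i], ], h2[si[i], ])
    }
    h2[i, ] <- if (di[i] == 0L) rbinom(ncols, 1L, rho) else {
      pick <- runif(ncols) < 0.5
      ifelse(pick, h1[di[i], ], h2[di[i], ])
    }
  }
  h1 + h2 - 1L
}

# dense GLS/BLUP oracle for y = X b + Z u + e, Var(u) = sg K, Var(e) = se I
dense_blup <- function(y, X, Z, K, sg, se) {
  V <- sg * Z %*% K %*% t(Z) + se * diag(length(y))
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u <- sg * K %*% t(Z) %*% Vi %*% (y - X %*% b)
  list(beta = as.numeric(b), u = as.numeric(u))
}

# dense REML log-likelihood (up to a parameter-free constant)
dense_reml_ll <- function(y, X, Z, K, sg, se) {
  V <- sg * Z %*% K %*% t(Z) + se * diag(length(y))
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  as.numeric(-0.5 * (determinant(V)$modulus +
                     determinant(t(X) %*% Vi %*% X)$modulus +
                     t(r) %*% Vi %*% r))
}

incidence_Z <- function(ids, animals) {
  Z <- matrix(0, length(ids), length(animals))
  Z[cbind(seq_along(ids), match(ids, animals))] <- 1
  Z
}

# small, fast simulator configuration for unit tests
tiny_sim_config <- function(...) {
  sim_config(n_chr = 4, chr_cM = 100, n_snp = 120, n_qtl = 40,
             base_ne = 20, base_generations = 8,
             n_boars = 6, n_sows = 30, n_offspring = 300,
             n_candidates = 12, phenotyped_males = 120, ...)
}
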