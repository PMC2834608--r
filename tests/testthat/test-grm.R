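test_that("genomic relationship matrix matches its defining sum", {
  m0 <- matrix(0, 1, 1, dimnames = list("a", "s1"))
  G0 <- grm(gene_content(m0, rho = 0.5))
  expect_equal(unname(G0), matrix(0, 1, 1))  # p = 0, s = 0.5

  set.seed(8)
  gc <- rand_gene_content(paste0("an", 1:5), 8)
  G <- grm(gc)
  p <- attr(gc, "p"); s <- attr(gc, "s")
  m <- unclass(gc)
  Go <- matrix(0, 5, 5)
  for (i in 1:5) for (k in 1:5)
    Go[i, k] <- sum((m[i, ] - p) * (m[k, ] - p)) / s
  expect_lt(max(abs(G - Go)), 1e-12)

  # identical genotype rows give identical G rows
  m2 <- rbind(m, an6 = m["an1", ])
  G2 <- grm(gene_content(m2, rho = attr(gc, "rho")))
  expect_equal(G2["an6", ], G2["an1", ], ignore_attr = TRUE)

  # explicit locus weights: default weights recover the 1/s form
  Gw <- grm(gc, weights = rep(1 / s, ncol(m)))
  expect_lt(max(abs(Gw - G)), 1e-12)
  expect_error(grm(gc, weights = rep(-1, ncol(m))), "nonnegative")
})

test_that("pedigree extension of G collapses to G and to A in the limits", {
  set.seed(15)
  ped <- rand_ped(15, nf = 5)
  g1 <- sample(ped$animal, 6)
  gc <- rand_gene_content(g1, 20)
  G <- grm(gc)
  A <- nrm(ped)

  # all animals genotyped: G* = G
  gc_all <- rand_gene_content(ped$animal, 20)
  G_all <- grm(gc_all)
  Gs_all <- grm_extend(G_all, ped)
  expect_equal(Gs_all[rownames(G_all), rownames(G_all)], G_all)

  # G = A11 exactly: the correction collapses and G* = A
  Gs_A <- grm_extend(A[g1, g1], ped)
  ord <- rownames(Gs_A)
  expect_lt(max(abs(Gs_A - A[ord, ord])), 1e-10)

  # genotyped-first block order with consistent cross-block
  Gs <- grm_extend(G, ped)
  expect_equal(rownames(Gs)[1:6], g1)
  P <- A[setdiff(ord, g1), g1] %*% solve(A[g1, g1])
  expect_lt(max(abs(Gs[setdiff(ord, g1), g1] - P %*% G)), 1e-10)
})

test_that("blending keeps the genotyped block positive definite", {
  set.seed(16)
  ped <- rand_ped(12, nf = 4)
  g1 <- sample(ped$animal, 5)
  A11 <- nrm(ped, g1)
  # external (base-population) frequencies: with sample frequencies the
  # columns are centred and 1 is in the null space of G, so G is singular
  m_ext <- matrix(sample(c(-1, 0, 1), 5 * 15, TRUE), 5, 15,
                  dimnames = list(g1, paste0("s", 1:15)))
  gc <- gene_content(m_ext, rho = runif(15, 0.25, 0.75))
  G <- grm(gc)

  expect_equal(unclass(grm_blend(G, A11, 1)), A11,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(unclass(grm_blend(G, A11, 0)), G,
               ignore_attr = TRUE, tolerance = 1e-12)

  # duplicate genotype rows make G singular; any w > 0 restores PD
  m <- unclass(gc); m[2, ] <- m[1, ]
  Gsing <- grm(gene_content(m, rho = attr(gc, "rho")))
  expect_error(grm_blend(Gsing, A11, 0), "singular")
  Gw <- grm_blend(Gsing, A11, 0.01)
  expect_true(is.matrix(attr(Gw, "chol")))
  expect_equal(attr(Gw, "logdet"),
               as.numeric(determinant(unclass(Gw))$modulus))
})

test_that("H_w inverse identity and determinant match dense algebra", {
  set.seed(17)
  ped <- rand_ped(20, nf = 6)
  g1 <- sample(ped$animal, 8)
  gc <- rand_gene_content(g1, 25)
  G <- grm(gc)
  proj <- a11_projection(ped, g1)
  A <- nrm(ped)

  # w = 1: the genotyped-block correction vanishes and H^-1 = A^-1 exactly
  hm1 <- hmat_inverse(ped, grm_blend(G, proj$A11, 1), proj = proj)
  expect_lt(max(abs(hm1$Hinv - nrm_inverse(ped))), 1e-10)

  w <- 0.05
  Gw <- grm_blend(G, proj$A11, w)
  hm <- hmat_inverse(ped, Gw, proj = proj)
  Gs <- grm_extend(G, ped, proj)
  ord <- rownames(Gs)
  Hw <- (1 - w) * Gs + w * A[ord, ord]
  expect_lt(max(abs(as.matrix(hm$Hinv)[ord, ord] %*% Hw - diag(20))), 1e-8)
  expect_lt(abs(hm$logdet - as.numeric(determinant(Hw)$modulus)), 1e-6)
  v <- rnorm(20)
  expect_equal(hm$matvec(v)[match(ord, ped$animal)],
               as.numeric(solve(Hw, v[match(ord, ped$animal)])),
               tolerance = 1e-8)

  # H_w is continuous in w
  hm2 <- hmat_inverse(ped, grm_blend(G, proj$A11, w + 1e-6), proj = proj)
  expect_lt(max(abs(hm2$Hinv - hm$Hinv)), 1e-3)
})

test_that("conditional moments of the genomic effect average correctly
           over observed genotypes (one locus, four animals)", {
  # s, d genotyped founders; o1 genotyped, o2 non-genotyped offspring.
  # Law of total variance: E over m_obs of [analytic G*_22] equals
  # E over m_obs of the true conditional second moment of the centred
  # content of o2 (both equal v * A_22 overall).
  ped <- pedigree(c("s", "d", "o1", "o2"),
                  c(NA, NA, "s", "s"), c(NA, NA, "d", "d"))
  rho <- 0.4; p <- 2 * rho - 1; s_norm <- 2 * rho * (1 - rho)
  g1 <- c("s", "d", "o1")
  set.seed(71)
  nrep <- 4000
  cont <- gene_drop_content(ped, rho, nrep)  # rows in ped order
  rownames(cont) <- ped$animal
  proj <- a11_projection(ped, g1)
  A <- nrm(ped)
  P <- proj$P21
  # analytic G*_22(m_obs) per replicate
  a22_base <- A["o2", "o2"] - P %*% proj$A11 %*% t(P)
  w1 <- (cont[g1, , drop = FALSE] - p) / sqrt(s_norm)
  gstar22 <- as.numeric(a22_base) + colSums((P %*% w1)^2)
  # true conditional second moment of the o2 content, by construction the
  # squared centred realisation averaged within observed configurations
  truth <- (cont["o2", ] - p)^2 / s_norm
  diff <- gstar22 - truth
  se <- sd(diff) / sqrt(nrep)
  expect_lt(abs(mean(diff)), 3 * se + 1e-12)
})
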