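make_toy <- function(n_animals = 20, n_rec = 30, n_geno = 8, L = 25,
                     nf = 6) {
  ped <- rand_ped(n_animals, nf = nf)
  g1 <- sample(ped$animal, n_geno)
  gc <- rand_gene_content(g1, L)
  dat <- data.frame(animal = sample(ped$animal, n_rec, replace = TRUE),
                    x = rnorm(n_rec))
  dat$y <- rnorm(n_rec, sd = 2)
  list(ped = ped, gc = gc, dat = dat)
}

dense_Hw <- function(toy, w) {
  Gs <- grm_extend(grm(toy$gc), toy$ped)
  A <- nrm(toy$ped)
  ord <- rownames(Gs)
  list(Hw = (1 - w) * Gs + w * A[ord, ord], ord = ord)
}

test_that("single-step MME solution equals the dense GLS/BLUP closed form", {
  set.seed(21)
  for (k in 1:4) {
    toy <- make_toy(n_rec = sample(20:50, 1))
    w <- runif(1, 0.02, 0.9)
    sg <- runif(1, 0.5, 3); se <- runif(1, 0.5, 3)
    dh <- dense_Hw(toy, w)
    X <- cbind(1, toy$dat$x)
    Z <- incidence_Z(toy$dat$animal, dh$ord)
    oracle <- dense_blup(toy$dat$y, X, Z, dh$Hw, sg, se)
    fit <- ssgblup(y ~ x, toy$dat, toy$ped, genotypes = toy$gc, weight = w,
                   varcomp = list(sigma2_g = sg, sigma2_e = se))
    u <- setNames(fit$breeding_values$gebv, fit$pedigree$animal)[dh$ord]
    expect_lt(max(abs(coef(fit) - oracle$beta)), 1e-8)
    expect_lt(max(abs(u - oracle$u)), 1e-8)
  }
})

test_that("with no genotypes the system is the classical animal model", {
  set.seed(22)
  toy <- make_toy()
  fit <- ssgblup(y ~ 1, toy$dat, toy$ped,
                 varcomp = list(sigma2_g = 1.5, sigma2_e = 2))
  A <- nrm(toy$ped)
  X <- matrix(1, nrow(toy$dat), 1)
  Z <- incidence_Z(toy$dat$animal, toy$ped$animal)
  oracle <- dense_blup(toy$dat$y, X, Z, A, 1.5, 2)
  expect_lt(max(abs(fit$breeding_values$gebv - oracle$u)), 1e-8)
})

test_that("extreme shrinkage sends all GEBVs to zero", {
  set.seed(23)
  toy <- make_toy()
  fit <- ssgblup(y ~ 1, toy$dat, toy$ped, genotypes = toy$gc, weight = 0.05,
                 varcomp = list(sigma2_g = 1e-10, sigma2_e = 1))
  expect_lt(max(abs(fit$breeding_values$gebv)), 1e-6)
})

test_that("a single record in a mean-only model is absorbed by the mean", {
  ped <- pedigree("a", NA_character_, NA_character_)
  dat <- data.frame(animal = "a", y = 3.7)
  fit <- ssgblup(y ~ 1, dat, ped, varcomp = list(sigma2_g = 1, sigma2_e = 1))
  expect_equal(fit$breeding_values$gebv, 0, tolerance = 1e-10)
})

test_that("half-sib group EBVs follow progeny means and PEVs reflect
           information content", {
  set.seed(24)
  sires <- c("s1", "s2")
  kids <- paste0("k", 1:20)
  ped <- pedigree(c(sires, "s3", kids),
                  c(NA, NA, NA, rep(sires, each = 10)),
                  rep(NA_character_, 23))
  dat <- data.frame(animal = kids,
                    y = rnorm(20, mean = rep(c(2, -2), each = 10)))
  fit <- ssgblup(y ~ 1, dat, ped, varcomp = list(sigma2_g = 1, sigma2_e = 2),
                 pev = TRUE)
  u <- setNames(fit$breeding_values$gebv, fit$pedigree$animal)
  pm <- tapply(dat$y, ped$sire[match(kids, ped$animal)], mean)
  expect_equal(order(pm), order(u[sires]))
  pv <- setNames(fit$breeding_values$pev, fit$pedigree$animal)
  # sire with 10 progeny records is better known than the no-record founder
  expect_lt(pv["s1"], pv["s3"])
  # recorded animal better known than its record-less sire? both have info;
  # check PEV of a recorded kid < PEV of the unrelated founder instead
  expect_lt(pv["k1"], pv["s3"])
  # PEV bounded by the prior genetic variance
  expect_true(all(pv > 0 & pv <= 1 * diag(nrm(ped))[names(pv)] + 1e-8))
})

test_that("REML log-likelihood equals the dense REML criterion up to a
           parameter-free constant and is permutation invariant", {
  set.seed(25)
  toy <- make_toy(n_rec = 30)
  w <- 0.1
  dh <- dense_Hw(toy, w)
  X <- cbind(1, toy$dat$x)
  Z <- incidence_Z(toy$dat$animal, dh$ord)
  pts <- rbind(c(1, 1), c(2, 0.5), c(0.5, 2), c(3, 3), c(1.3, 0.4))
  offs <- apply(pts, 1, function(p) {
    f <- ssgblup(y ~ x, toy$dat, toy$ped, genotypes = toy$gc, weight = w,
                 varcomp = list(sigma2_g = p[1], sigma2_e = p[2]))
    f$logLik - dense_reml_ll(toy$dat$y, X, Z, dh$Hw, p[1], p[2])
  })
  expect_lt(max(offs) - min(offs), 1e-6)

  # reordering the records leaves the likelihood unchanged
  perm <- sample(nrow(toy$dat))
  f1 <- ssgblup(y ~ x, toy$dat, toy$ped, genotypes = toy$gc, weight = w,
                varcomp = list(sigma2_g = 1, sigma2_e = 1))
  f2 <- ssgblup(y ~ x, toy$dat[perm, ], toy$ped, genotypes = toy$gc,
                weight = w, varcomp = list(sigma2_g = 1, sigma2_e = 1))
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-10)

  # a duplicated fixed-effect column is dropped with a warning, same logL
  dat2 <- toy$dat; dat2$x2 <- dat2$x
  expect_warning(
    f3 <- ssgblup(y ~ x + x2, dat2, toy$ped, genotypes = toy$gc, weight = w,
                  varcomp = list(sigma2_g = 1, sigma2_e = 1)),
    "rank deficient")
  expect_equal(f3$logLik, f1$logLik, tolerance = 1e-8)
})

test_that("AI-REML climbs the likelihood and agrees with a 2-D grid search", {
  set.seed(26)
  toy <- make_toy(n_rec = 40)
  w <- 0.1
  fit <- ssgblup(y ~ 1, toy$dat, toy$ped, genotypes = toy$gc, weight = w)
  init <- c(0.3, 0.7) * var(toy$dat$y)
  f0 <- ssgblup(y ~ 1, toy$dat, toy$ped, genotypes = toy$gc, weight = w,
                varcomp = list(sigma2_g = init[1], sigma2_e = init[2]))
  expect_gte(fit$logLik, f0$logLik)

  dh <- dense_Hw(toy, w)
  X <- matrix(1, nrow(toy$dat), 1)
  Z <- incidence_Z(toy$dat$animal, dh$ord)
  step <- 0.1
  gr <- expand.grid(sg = seq(step, 2 * var(toy$dat$y), by = step),
                    se = seq(step, 2 * var(toy$dat$y), by = step))
  ll <- mapply(function(a, b) dense_reml_ll(toy$dat$y, X, Z, dh$Hw, a, b),
               gr$sg, gr$se)
  best <- gr[which.max(ll), ]
  expect_lt(abs(fit$varcomp$sigma2_g - best$sg), step + 1e-9)
  expect_lt(abs(fit$varcomp$sigma2_e - best$se), step + 1e-9)
})

test_that("REML estimates are scale equivariant", {
  set.seed(27)
  toy <- make_toy(n_rec = 40)
  fit1 <- ssgblup(y ~ 1, toy$dat, toy$ped, genotypes = toy$gc, weight = 0.1)
  dat2 <- toy$dat; dat2$y <- 10 * dat2$y
  fit2 <- ssgblup(y ~ 1, dat2, toy$ped, genotypes = toy$gc, weight = 0.1)
  expect_equal(fit2$varcomp$sigma2_g, 100 * fit1$varcomp$sigma2_g,
               tolerance = 1e-4)
  expect_equal(fit2$varcomp$sigma2_e, 100 * fit1$varcomp$sigma2_e,
               tolerance = 1e-4)
})

test_that("profile over the polygenic weight reports grid, argmax and
           likelihood-drop interval", {
  set.seed(28)
  toy <- make_toy(n_rec = 45, n_geno = 10)
  fit <- ssgblup(y ~ 1, toy$dat, toy$ped, genotypes = toy$gc, weight = 0.05)
  expect_error(profile(fit, w = c(0.3, 0.1)), "increasing")
  pr <- profile(fit, w = c(0.05, 0.1, 0.2, 0.5))
  expect_equal(pr$grid$w, c(0.05, 0.1, 0.2, 0.5))
  expect_true(pr$w_hat >= pr$ci[1] && pr$w_hat <= pr$ci[2])
  # phenotypes are pure noise here: profile is flat, interval spans the grid
  expect_equal(pr$ci[2], 0.5)
  expect_equal(pr$ci[1], 0)  # lower boundary qualifies -> extended to 0
  expect_equal(unname(confint(pr)[1, ]), pr$ci)
})

test_that("phenotypes simulated from a fit reproduce its variance structure", {
  set.seed(29)
  toy <- make_toy(n_rec = 40)
  fit <- ssgblup(y ~ 1, toy$dat, toy$ped, genotypes = toy$gc, weight = 0.1,
                 varcomp = list(sigma2_g = 2, sigma2_e = 1))
  ys <- simulate(fit, nsim = 500, seed = 1)
  # per-record variance across replicates tracks the model's diagonal
  dh <- dense_Hw(toy, 0.1)
  Z <- incidence_Z(toy$dat$animal, dh$ord)
  expected <- diag(2 * Z %*% dh$Hw %*% t(Z) + 1 * diag(nrow(toy$dat)))
  got <- apply(ys, 1, var)
  expect_lt(mean(abs(got - expected) / expected), 0.2)
})
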