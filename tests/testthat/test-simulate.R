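test_that("configuration validates the mating arithmetic", {
  expect_error(sim_config(n_offspring = 14999), "litter")
  expect_error(sim_config(n_sows = 1500, n_offspring = 1500 * 5), "even")
  cfg <- sim_config(scale = 0.1)
  expect_equal(cfg$n_boars, 15)
  expect_equal(cfg$n_offspring, 1500)
  expect_equal(cfg$litter, 10)
})

test_that("meiosis respects the genetic map: fully linked loci co-segregate,
           unlinked loci do not", {
  set.seed(41)
  h1 <- matrix(sample(0:1, 2 * 6, TRUE), 2, 6)
  h2 <- 1 - h1
  # loci 1-2 at zero distance, locus 3 on a new chromosome
  rsw <- c(0.5, 0, 0.5, 0.5, 0, 0)
  g <- ssgblup:::drop_gametes_cpp(h1, h2, rep(1L, 500), rsw)
  expect_equal(g[, 1], g[, 2] * (h1[1, 2] == h1[1, 1]) +
                 (1 - g[, 2]) * (h1[1, 2] != h1[1, 1]))
  expect_equal(g[, 4], g[, 5], ignore_attr = TRUE)
})

test_that("drift erodes heterozygosity at the neutral rate", {
  # E[H_t] = H_0 (1 - 1/(2N))^t with H_0 = 0.5 for frequency-1/2 founders
  cfgs <- sim_config(n_chr = 2, chr_cM = 100, n_snp = 150, n_qtl = 10,
                     base_ne = 20, base_generations = 15,
                     n_boars = 10, n_sows = 50, n_offspring = 500,
                     n_candidates = 5, phenotyped_males = 100)
  hets <- sapply(1:5, function(s) {
    set.seed(1000 + s)
    base <- simulate_base(cfgs)
    f <- base$base_freqs
    mean(2 * f * (1 - f))
  })
  expected <- 0.5 * (1 - 1 / (2 * 20))^15
  se <- sd(hets) / sqrt(length(hets))
  expect_lt(abs(mean(hets) - expected), 3 * se + 0.01)
})

test_that("the generator is deterministic given the seed", {
  cfg <- tiny_sim_config()
  s1 <- sim_breeding_program(cfg, seed = 7)
  s2 <- sim_breeding_program(cfg, seed = 7)
  expect_identical(s1$geno, s2$geno)
  expect_identical(s1$pheno, s2$pheno)
  expect_identical(s1$tbv, s2$tbv)
  s3 <- sim_breeding_program(cfg, seed = 8)
  expect_false(identical(s1$pheno$y, s3$pheno$y))
  expect_error(sim_breeding_program(cfg), "seed")
})

test_that("the scheme produces the configured record and genotype counts,
           and selection acts on phenotype", {
  cfg <- tiny_sim_config()
  sim <- sim_breeding_program(cfg, seed = 9)
  expect_equal(nrow(sim$pheno), cfg$phenotyped_males * cfg$n_generations)
  # boars of the last three generations genotyped
  expect_equal(length(sim$groups$boars), 3 * cfg$n_boars)
  expect_equal(length(sim$groups$candidates), cfg$n_candidates)
  expect_equal(nrow(sim$geno),
               cfg$n_boars + 3 * cfg$n_boars + cfg$n_candidates)
  expect_true(all(sim$geno %in% c(-1, 0, 1)))
  expect_true(all(rownames(sim$geno) %in% sim$ped$animal))

  # selected boars (sires of generation g+1) beat their generation's mean
  for (g in 1:(cfg$n_generations - 1)) {
    recs <- sim$pheno[sim$pheno$generation == g, ]
    sires_next <- unique(sim$ped$sire[grepl(paste0("^G", g + 1, "_"),
                                            sim$ped$animal)])
    expect_gt(mean(recs$y[recs$animal %in% sires_next]), mean(recs$y))
  }
})

test_that("true breeding values are bookkept exactly and effects follow the
           configured gamma law", {
  cfg <- tiny_sim_config()
  sim <- sim_breeding_program(cfg, seed = 10)
  # recomputing TBV from stored QTL gene contents and effects is exact
  tbv2 <- as.numeric(sim$qtl_geno %*% sim$qtl$effect)
  expect_equal(unname(sim$tbv[rownames(sim$qtl_geno)]), tbv2,
               tolerance = 1e-12)
  # base-herd additive variance is rescaled onto the target exactly
  base_ids <- sim$ped$animal[grepl("^[BS]0_", sim$ped$animal)]
  expect_equal(var(sim$tbv[base_ids]), cfg$sigma2_g, tolerance = 1e-10)

  # signs balanced, all nonzero, |effect| has the right mean before scaling
  set.seed(11)
  cfg2 <- sim_config(n_qtl = 500)
  eff <- draw_qtl_effects(cfg2)
  expect_true(all(eff != 0))
  npos <- sum(eff > 0)
  expect_lt(abs(npos - 250), 3 * sqrt(500 * 0.25))
  mu <- cfg2$qtl_shape / cfg2$qtl_rate
  sdm <- sqrt(cfg2$qtl_shape) / cfg2$qtl_rate / sqrt(500)
  expect_lt(abs(mean(abs(eff)) - mu), 3 * sdm)
})

test_that("selection produces a positive genetic trend", {
  cfg <- tiny_sim_config()
  trends <- sapply(1:5, function(s) {
    sim <- sim_breeding_program(cfg, seed = 100 + s)
    gen_mean <- tapply(sim$tbv, sub("_.*", "", names(sim$tbv)), mean)
    gens <- paste0("G", 1:cfg$n_generations)
    mean(diff(gen_mean[gens]))
  })
  expect_gt(mean(trends), 0)
  # generation-1 phenotypic variance is near sigma2_g + sigma2_e
  sim <- sim_breeding_program(cfg, seed = 106)
  v1 <- var(sim$pheno$y[sim$pheno$generation == 1])
  expect_lt(abs(v1 - (cfg$sigma2_g + cfg$sigma2_e)) /
              (cfg$sigma2_g + cfg$sigma2_e), 0.35)
})

test_that("simulation outputs round-trip through the file formats", {
  cfg <- tiny_sim_config()
  sim <- sim_breeding_program(cfg, seed = 12)
  dir <- tempfile()
  write_sim(sim, dir)
  ped <- read_pedigree(file.path(dir, "pedigree.csv"))
  expect_equal(ped$animal, sim$ped$animal)
  rho <- read_allele_freqs(file.path(dir, "allele_freqs.tsv"))
  gc <- read_genotypes(file.path(dir, "genotypes.tsv"),
                       rho = pmin(pmax(rho, 1e-6), 1 - 1e-6))
  expect_equal(sort(rownames(gc)), sort(rownames(sim$geno)))
  pheno <- read.csv(file.path(dir, "phenotypes.csv"))
  expect_equal(pheno$y, sim$pheno$y)
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  unlink(dir, recursive = TRUE)
})
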