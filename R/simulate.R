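#' Configuration for the breeding-program simulator
#'
#' Defaults describe a simplified pig nucleus breeding program: a genome of
#' 10 chromosomes of 160 cM carrying 5000 equidistant SNPs and 500 QTL with
#' gamma-distributed effect sizes (|effect| ~ Gamma(shape 0.42, rate 5.4),
#' random sign); a base population bred by 50 generations of random mating
#' at effective size 100 (50 males, 50 females) and then expanded to 150
#' boars and 1500 sows; five generations in which the 150 boars are mated to
#' the 1500 sows to produce 15000 offspring (litters of 10, half male),
#' boars reselected on own phenotype (top 150) and sows at random;
#' phenotypes recorded on 7000 random males per generation (35000 records;
#' set `phenotype_all_males = TRUE` to record all 7500); genotyping of the
#' 150 base boars, the selected boars of the last three generations (450)
#' and 300 record-less generation-6 selection candidates. QTL effects are
#' rescaled so the base-generation additive variance equals `sigma2_g`
#' (default 4; residual 16, i.e. heritability 0.2). `scale` shrinks the
#' animal counts proportionally (e.g. `scale = 0.1` for a 1/10-scale run);
#' the genome is left untouched.
#'
#' @param n_chr,chr_cM,n_snp,n_qtl genome layout.
#' @param qtl_shape,qtl_rate gamma parameters for |QTL effect|.
#' @param base_ne,base_generations base-population drift phase.
#' @param n_boars,n_sows,n_offspring,n_generations breeding scheme.
#' @param n_candidates genotyped record-less selection candidates.
#' @param phenotyped_males phenotype records per generation (males).
#' @param phenotype_all_males record every male.
#' @param genotype_base_boars genotype the base boars (allele-frequency
#'   source).
#' @param sigma2_g,sigma2_e,mu phenotype model \eqn{y = \mu + TBV + e}.
#' @param scale proportional scaling of animal counts.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_chr = 10, chr_cM = 160, n_snp = 5000, n_qtl = 500,
                       qtl_shape = 0.42, qtl_rate = 5.4,
                       base_ne = 100, base_generations = 50,
                       n_boars = 150, n_sows = 1500, n_offspring = 15000,
                       n_generations = 5, n_candidates = 300,
                       phenotyped_males = 7000, phenotype_all_males = FALSE,
                       genotype_base_boars = TRUE,
                       sigma2_g = 4, sigma2_e = 16, mu = 10, scale = 1) {
  cfg <- list(n_chr = n_chr, chr_cM = chr_cM, n_snp = n_snp, n_qtl = n_qtl,
              qtl_shape = qtl_shape, qtl_rate = qtl_rate, base_ne = base_ne,
              base_generations = base_generations,
              n_boars = round(n_boars * scale),
              n_sows = round(n_sows * scale),
              n_offspring = round(n_offspring * scale),
              n_generations = n_generations,
              n_candidates = round(n_candidates * scale),
              phenotyped_males = round(phenotyped_males * scale),
              phenotype_all_males = phenotype_all_males,
              genotype_base_boars = genotype_base_boars,
              sigma2_g = sigma2_g, sigma2_e = sigma2_e, mu = mu)
  counts <- unlist(cfg[c("n_chr", "chr_cM", "n_snp", "n_qtl", "base_ne",
                         "base_generations", "n_boars", "n_sows",
                         "n_offspring", "n_generations", "n_candidates",
                         "phenotyped_males")])
  if (any(counts <= 0)) stop("all counts must be positive")
  if (cfg$base_ne %% 2L) stop("base_ne must be even (equal sex ratio)")
  if (cfg$n_offspring %% cfg$n_sows)
    stop("n_offspring must be n_sows * litter size (got ", cfg$n_offspring,
         " offspring for ", cfg$n_sows, " sows)")
  litter <- cfg$n_offspring / cfg$n_sows
  if (litter %% 2L)
    stop("litter size must be even so that half the offspring are male")
  cfg$litter <- litter
  structure(cfg, class = "sim_config")
}

# genome map: equidistant SNPs, uniform random QTL positions; switch
# probabilities between adjacent loci from Haldane's map function, 0.5 at
# chromosome starts (independent start per chromosome).
.sim_map <- function(cfg) {
  per_chr_snp <- diff(round(seq(0, cfg$n_snp, length.out = cfg$n_chr + 1)))
  per_chr_qtl <- diff(round(seq(0, cfg$n_qtl, length.out = cfg$n_chr + 1)))
  rows <- list()
  for (ch in seq_len(cfg$n_chr)) {
    k <- per_chr_snp[ch]
    snp_pos <- (seq_len(k) - 0.5) / k * cfg$chr_cM
    qtl_pos <- runif(per_chr_qtl[ch], 0, cfg$chr_cM)
    d <- rbind(data.frame(chr = ch, pos_cM = snp_pos, qtl = FALSE),
               data.frame(chr = ch, pos_cM = qtl_pos, qtl = TRUE))
    rows[[ch]] <- d[order(d$pos_cM), ]
  }
  map <- do.call(rbind, rows)
  map$locus <- ifelse(map$qtl,
                      paste0("qtl", cumsum(map$qtl) * map$qtl),
                      paste0("snp", cumsum(!map$qtl) * (!map$qtl)))
  rsw <- numeric(nrow(map))
  first <- !duplicated(map$chr)
  d_cM <- c(0, diff(map$pos_cM))
  rsw[!first] <- 0.5 * (1 - exp(-2 * d_cM[!first] / 100))
  rsw[first] <- 0.5
  map$rswitch <- rsw
  rownames(map) <- NULL
  map
}

#' Simulate the base population
#'
#' Unlinked founders at allele frequency 0.5 drift through
#' `base_generations` of discrete random mating at effective size `base_ne`
#' (half males, half females), with Haldane recombination along the genome
#' map; the final generation is then expanded (parents drawn with
#' replacement) into the generation-0 breeding herd of `n_boars` boars and
#' `n_sows` sows.
#'
#' @param cfg a [sim_config()].
#' @return list with haplotype matrices `h1`, `h2` (rows = boars then sows),
#'   `ids`, `sex`, the genome `map`, and `base_freqs` (second-allele
#'   frequency per locus in the generation-0 herd).
#' @export
simulate_base <- function(cfg) {
  map <- .sim_map(cfg)
  L <- nrow(map)
  rsw <- map$rswitch
  N <- cfg$base_ne
  nm <- N %/% 2L
  h1 <- matrix(rbinom(N * L, 1L, 0.5), N, L)
  h2 <- matrix(rbinom(N * L, 1L, 0.5), N, L)
  for (t in seq_len(cfg$base_generations)) {
    sires <- sample.int(nm, N, replace = TRUE)
    dams <- nm + sample.int(N - nm, N, replace = TRUE)
    nh1 <- drop_gametes_cpp(h1, h2, sires, rsw)
    nh2 <- drop_gametes_cpp(h1, h2, dams, rsw)
    h1 <- nh1; h2 <- nh2
  }
  nb <- cfg$n_boars; ns <- cfg$n_sows
  sires <- sample.int(nm, nb + ns, replace = TRUE)
  dams <- nm + sample.int(N - nm, nb + ns, replace = TRUE)
  g1 <- drop_gametes_cpp(h1, h2, sires, rsw)
  g2 <- drop_gametes_cpp(h1, h2, dams, rsw)
  ids <- c(sprintf("B0_%04d", seq_len(nb)), sprintf("S0_%04d", seq_len(ns)))
  list(h1 = g1, h2 = g2, ids = ids,
       sex = rep(c("M", "F"), c(nb, ns)),
       map = map,
       base_freqs = setNames(colMeans((g1 + g2) / 2), map$locus))
}

#' Draw QTL effect sizes
#'
#' |effect| ~ Gamma(`qtl_shape`, rate = `qtl_rate`), sign +/- with equal
#' probability. Rescaling to the target base-generation variance happens
#' inside [simulate_program()].
#'
#' @param cfg a [sim_config()].
#' @return numeric vector of signed effects, one per QTL.
#' @export
draw_qtl_effects <- function(cfg) {
  a <- rgamma(cfg$n_qtl, shape = cfg$qtl_shape, rate = cfg$qtl_rate)
  a * sample(c(-1, 1), cfg$n_qtl, replace = TRUE)
}

#' Run the breeding-program simulation
#'
#' Executes the selection scheme of [sim_config()] on a base population:
#' each generation every sow is mated to a random selected boar, litters of
#' fixed size with half the offspring male; males are phenotyped
#' (`phenotyped_males` random males, or all); the next generation's boars
#' are the top `n_boars` phenotyped males on own phenotype (ties broken by
#' id order) and the sows a random draw of females. Genotyping: base boars
#' (optional), selected boars of the last three generations, and
#' `n_candidates` record-less generation-`n_generations + 1` candidates.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (mandatory: the simulation is its own fixture
#'   generator and must be reproducible).
#' @param base optionally a precomputed [simulate_base()] output.
#' @return object of class `ssgblup_sim`: `ped` ([pedigree()]), `pheno`
#'   (data frame animal/y/sex/generation), `geno` (gene-content matrix
#'   -1/0/1 for all genotyped animals), `groups` (ids: `base_boars`,
#'   `boars`, `candidates`), `tbv` (named vector, all animals), `qtl_geno`
#'   (QTL allele dosage 0/1/2, all animals), `qtl` (truth table), `map`,
#'   `base_freqs`, `config`, `seed`.
#' @export
sim_breeding_program <- function(config = sim_config(), seed, base = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  cfg <- config
  if (is.null(base)) base <- simulate_base(cfg)
  map <- base$map
  rsw <- map$rswitch
  qtl_col <- which(map$qtl)
  snp_col <- which(!map$qtl)
  a <- draw_qtl_effects(cfg)

  tbv_of <- function(h1, h2) as.numeric((h1[, qtl_col, drop = FALSE] +
                                         h2[, qtl_col, drop = FALSE]) %*% a)
  # rescale effects so the generation-0 additive variance hits sigma2_g
  tbv0 <- tbv_of(base$h1, base$h2)
  v0 <- var(tbv0)
  if (v0 <= 0) stop("no additive variance at the QTL in the base herd")
  a <- a * sqrt(cfg$sigma2_g / v0)
  tbv0 <- tbv0 * sqrt(cfg$sigma2_g / v0)

  nb <- cfg$n_boars; ns <- cfg$n_sows
  boar_rows <- seq_len(nb)
  sow_rows <- nb + seq_len(ns)
  cur_h1 <- base$h1; cur_h2 <- base$h2
  cur_boars <- base$ids[boar_rows]; cur_sows <- base$ids[sow_rows]
  ped_an <- base$ids
  ped_si <- rep(NA_character_, nb + ns)
  ped_da <- rep(NA_character_, nb + ns)
  tbv <- setNames(tbv0, base$ids)
  pheno <- list()
  geno <- list()
  qtl_geno <- list(base = (base$h1 + base$h2)[, qtl_col, drop = FALSE])
  rownames(qtl_geno$base) <- base$ids
  boar_ids_genotyped <- character(0)
  if (cfg$genotype_base_boars)
    geno$base <- (base$h1 + base$h2 - 1)[boar_rows, snp_col, drop = FALSE]
  genotyped_gens <- seq(cfg$n_generations - 2L, cfg$n_generations)

  for (g in seq_len(cfg$n_generations)) {
    litter <- cfg$litter
    boar_assign <- sample.int(nb, ns, replace = TRUE)
    sire_idx <- rep(boar_assign, each = litter)          # rows in cur boars
    dam_idx <- rep(seq_len(ns), each = litter)
    noff <- ns * litter
    pat <- drop_gametes_cpp(cur_h1[boar_rows, , drop = FALSE],
                            cur_h2[boar_rows, , drop = FALSE], sire_idx, rsw)
    mat <- drop_gametes_cpp(cur_h1[sow_rows, , drop = FALSE],
                            cur_h2[sow_rows, , drop = FALSE], dam_idx, rsw)
    ids <- sprintf("G%d_%05d", g, seq_len(noff))
    sex <- rep(rep(c("M", "F"), each = litter / 2), ns)
    ped_an <- c(ped_an, ids)
    ped_si <- c(ped_si, cur_boars[sire_idx])
    ped_da <- c(ped_da, cur_sows[dam_idx])
    tbv_g <- setNames(tbv_of(pat, mat), ids)
    tbv <- c(tbv, tbv_g)
    qg <- (pat + mat)[, qtl_col, drop = FALSE]
    rownames(qg) <- ids
    qtl_geno[[paste0("gen", g)]] <- qg

    males <- which(sex == "M")
    rec <- if (cfg$phenotype_all_males) males else
      sort(sample(males, min(cfg$phenotyped_males, length(males))))
    y <- cfg$mu + tbv_g[rec] + rnorm(length(rec), sd = sqrt(cfg$sigma2_e))
    pheno[[g]] <- data.frame(animal = ids[rec], y = as.numeric(y),
                             sex = "M", generation = g,
                             stringsAsFactors = FALSE)

    # truncation selection of boars on own phenotype; random sows
    top <- rec[order(-y, rec)][seq_len(nb)]
    females <- which(sex == "F")
    sow_pick <- sort(sample(females, ns))
    sel <- c(top, sow_pick)
    cur_h1 <- pat[sel, , drop = FALSE]
    cur_h2 <- mat[sel, , drop = FALSE]
    cur_boars <- ids[top]; cur_sows <- ids[sow_pick]
    if (g %in% genotyped_gens) {
      geno[[paste0("gen", g)]] <-
        (pat[top, , drop = FALSE] + mat[top, , drop = FALSE] - 1)[,
          snp_col, drop = FALSE]
      rownames(geno[[paste0("gen", g)]]) <- ids[top]
      boar_ids_genotyped <- c(boar_ids_genotyped, ids[top])
    }
  }

  # generation n+1 selection candidates: genotyped, record-less
  nc <- cfg$n_candidates
  csire <- sample.int(nb, nc, replace = TRUE)
  cdam <- sample.int(ns, nc, replace = TRUE)
  cpat <- drop_gametes_cpp(cur_h1[seq_len(nb), , drop = FALSE],
                           cur_h2[seq_len(nb), , drop = FALSE], csire, rsw)
  cmat <- drop_gametes_cpp(cur_h1[nb + seq_len(ns), , drop = FALSE],
                           cur_h2[nb + seq_len(ns), , drop = FALSE], cdam, rsw)
  cand_ids <- sprintf("C%d_%04d", cfg$n_generations + 1L, seq_len(nc))
  ped_an <- c(ped_an, cand_ids)
  ped_si <- c(ped_si, cur_boars[csire])
  ped_da <- c(ped_da, cur_sows[cdam])
  tbv <- c(tbv, setNames(tbv_of(cpat, cmat), cand_ids))
  geno$cand <- (cpat + cmat - 1)[, snp_col, drop = FALSE]
  rownames(geno$cand) <- cand_ids
  qtl_geno$cand <- (cpat + cmat)[, qtl_col, drop = FALSE]
  rownames(qtl_geno$cand) <- cand_ids
  if (cfg$genotype_base_boars)
    rownames(geno$base) <- base$ids[boar_rows]

  gmat <- do.call(rbind, geno)
  colnames(gmat) <- map$locus[snp_col]
  ped <- pedigree(ped_an, ped_si, ped_da, unknown = NA)
  structure(list(
    ped = ped,
    pheno = do.call(rbind, pheno),
    geno = gmat,
    groups = list(base_boars = if (cfg$genotype_base_boars)
                    base$ids[boar_rows] else character(0),
                  boars = boar_ids_genotyped,
                  candidates = cand_ids),
    tbv = tbv,
    qtl_geno = {
      qg <- do.call(rbind, qtl_geno)
      colnames(qg) <- map$locus[qtl_col]
      qg
    },
    qtl = data.frame(locus = map$locus[qtl_col], chr = map$chr[qtl_col],
                     pos_cM = map$pos_cM[qtl_col], effect = a),
    map = map,
    base_freqs = base$base_freqs,
    config = cfg, seed = seed), class = "ssgblup_sim")
}

#' @export
#' @method print ssgblup_sim
print.ssgblup_sim <- function(x, ...) {
  cat("Breeding-program simulation (seed", x$seed, ")\n")
  cat(sprintf("  pedigree: %d animals; records: %d; genotyped: %d (%d candidates)\n",
              nrow(x$ped), nrow(x$pheno), nrow(x$geno),
              length(x$groups$candidates)))
  cat(sprintf("  genome: %d SNPs + %d QTL on %d chromosomes\n",
              sum(!x$map$qtl), sum(x$map$qtl), max(x$map$chr)))
  invisible(x)
}

#' Write simulation outputs to files
#'
#' Emits `pedigree.csv`, `genotypes.tsv` (0/1/2 dosage),
#' `phenotypes.csv`, `tbv.tsv`, `qtl.tsv`, `allele_freqs.tsv` and a
#' `manifest.yaml` with config and seed, in the formats the fitting
#' functions read back.
#' @param sim an `ssgblup_sim`.
#' @param dir output directory (created).
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(sim$ped, file.path(dir, "pedigree.csv"))
  d <- data.frame(animal = rownames(sim$geno), sim$geno + 1,
                  check.names = FALSE)
  write.table(d, file.path(dir, "genotypes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$pheno, file.path(dir, "phenotypes.csv"), sep = ",",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(animal = names(sim$tbv), tbv = as.numeric(sim$tbv)),
              file.path(dir, "tbv.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(sim$qtl, file.path(dir, "qtl.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  snp <- !sim$map$qtl
  write_allele_freqs(sim$base_freqs[snp], file.path(dir, "allele_freqs.tsv"))
  manifest <- c(list(seed = sim$seed), unclass(sim$config))
  if (requireNamespace("yaml", quietly = TRUE)) {
    writeLines(yaml::as.yaml(manifest), file.path(dir, "manifest.yaml"))
  } else {
    writeLines(paste(names(manifest), vapply(manifest, format, ""),
                     sep = ": "), file.path(dir, "manifest.yaml"))
  }
  invisible(dir)
}
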