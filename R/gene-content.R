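#' Gene-content matrix
#'
#' Wraps a genotyped-animals x loci matrix of gene contents coded
#' \eqn{-1/0/1} (the two homozygotes and the heterozygote) together with the
#' per-locus allele frequency \eqn{\rho_j} of the second allele. Stores the
#' centering values \eqn{p_j = 2(\rho_j - 1/2)} and the normaliser
#' \eqn{s = \sum_j 2\rho_j(1-\rho_j)}.
#'
#' Dosage input (`coding = "dosage"`, values 0/1/2 counting the second
#' allele) is converted by subtracting 1. Missing calls are mean-imputed per
#' locus with a warning (the model partitions animals as wholly genotyped or
#' not; sporadic missing calls must be resolved before construction). Loci
#' with \eqn{\rho} outside `[eps, 1-eps]` are monomorphic for practical
#' purposes and are dropped (`monomorphic = "drop"`) or raise an error.
#'
#' @param m numeric matrix, rows = animals (rownames = ids), cols = loci.
#' @param rho per-locus allele frequencies; default: observed frequencies.
#' @param coding `"content"` (-1/0/1) or `"dosage"` (0/1/2).
#' @param monomorphic `"drop"` or `"error"`.
#' @param eps frequency clamp tolerance.
#' @return object of class `gene_content`: the -1/0/1 matrix with
#'   attributes `rho`, `p`, `s`.
#' @export
gene_content <- function(m, rho = NULL, coding = c("content", "dosage"),
                         monomorphic = c("drop", "error"), eps = 1e-6) {
  coding <- match.arg(coding)
  monomorphic <- match.arg(monomorphic)
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (is.null(rownames(m))) stop("gene-content matrix needs animal rownames")
  if (coding == "dosage") m <- m - 1
  if (anyNA(m)) {
    warning(sum(is.na(m)), " missing genotype call(s) mean-imputed per locus")
    for (j in which(colSums(is.na(m)) > 0L)) {
      mj <- m[, j]
      mj[is.na(mj)] <- mean(mj, na.rm = TRUE)
      m[, j] <- mj
    }
  }
  obs <- m[!is.na(m)]
  if (!all(obs %in% c(-1, 0, 1) | abs(obs) <= 1))
    stop("gene contents must lie in [-1, 1] after coding")
  if (is.null(rho)) rho <- (colMeans(m) + 1) / 2
  if (length(rho) != ncol(m)) stop("rho length != number of loci")
  mono <- rho < eps | rho > 1 - eps
  if (any(mono)) {
    if (monomorphic == "error")
      stop(sum(mono), " monomorphic locus/loci (rho outside [eps, 1-eps])")
    m <- m[, !mono, drop = FALSE]
    rho <- rho[!mono]
  }
  if (!ncol(m)) stop("all loci monomorphic")
  structure(m, rho = as.numeric(rho), p = 2 * (as.numeric(rho) - 0.5),
            s = sum(2 * rho * (1 - rho)), class = c("gene_content", "matrix"))
}

#' @export
#' @method print gene_content
print.gene_content <- function(x, ...) {
  cat("Gene-content matrix:", nrow(x), "animals x", ncol(x), "loci, s =",
      format(attr(x, "s"), digits = 6), "\n")
  invisible(x)
}

#' Read / write genotype files
#'
#' Headered TSV, first column `animal`, remaining columns one per SNP;
#' values 0/1/2 allele dosage by default, or -1/0/1 directly.
#' @param path file path.
#' @param coding,rho,... passed to [gene_content()].
#' @export
read_genotypes <- function(path, coding = "dosage", rho = NULL, ...) {
  d <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- as.character(d[[1L]])
  gene_content(m, rho = rho, coding = coding, ...)
}

#' @rdname read_genotypes
#' @param gc a [gene_content()].
#' @export
write_genotypes <- function(gc, path, coding = c("dosage", "content")) {
  coding <- match.arg(coding)
  m <- unclass(gc)
  attributes(m)[c("rho", "p", "s")] <- NULL
  if (coding == "dosage") m <- m + 1
  d <- data.frame(animal = rownames(m), m, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an allele-frequency table (two-column TSV: snp, rho)
#' @param path file path.
#' @export
read_allele_freqs <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t")
  setNames(as.numeric(d[[2L]]), as.character(d[[1L]]))
}

#' @rdname read_allele_freqs
#' @param rho named frequency vector.
#' @export
write_allele_freqs <- function(rho, path) {
  write.table(data.frame(snp = names(rho), rho = as.numeric(rho)), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Estimate allele frequencies
#'
#' `method = "observed"`: allele frequency counted in the designated animal
#' subset (use the base/founder sample or the current sample by choosing
#' `ids`). `method = "gengler"`: per-locus generalised-least-squares
#' intercept of gene content regressed on the pedigree structure, i.e. the
#' GLS mean of the observed contents with covariance proportional to the
#' genotyped block of A — the mixed-model gene-content approach.
#'
#' @param m genotype matrix (-1/0/1, rownames = animal ids) or
#'   [gene_content()].
#' @param method `"observed"` or `"gengler"`.
#' @param ids animal subset to use (default: all rows of `m`).
#' @param ped pedigree (required for `"gengler"`).
#' @param eps clamp: frequencies forced into `[eps, 1-eps]`.
#' @return named vector of allele frequencies \eqn{\rho_j}.
#' @export
allele_freqs <- function(m, method = c("observed", "gengler"), ids = NULL,
                         ped = NULL, eps = 1e-6) {
  method <- match.arg(method)
  m <- as.matrix(m)
  if (!is.null(ids)) {
    miss <- setdiff(ids, rownames(m))
    if (length(miss)) stop("ids without genotypes: ", paste(head(miss), collapse = ", "))
    m <- m[ids, , drop = FALSE]
  }
  if (method == "observed") {
    rho <- (colMeans(m) + 1) / 2
  } else {
    if (is.null(ped)) stop("gengler method needs a pedigree")
    A11 <- a11_projection(ped, rownames(m))$A11
    wts <- solve(A11, rep(1, nrow(m)))          # A11^{-1} 1
    mu <- as.numeric(crossprod(wts, m)) / sum(wts)
    rho <- (mu + 1) / 2
  }
  setNames(pmin(pmax(rho, eps), 1 - eps), colnames(m))
}

#' Expected gene contents of non-genotyped animals
#'
#' Linear (BLUP-type) prediction of unobserved gene contents from observed
#' ones through the pedigree:
#' \eqn{E[M_{miss,j} | m_{obs}] = p_j 1 + A_{21} A_{11}^{-1} (m_{obs,j} - p_j 1)},
#' clamped to \eqn{[-1, 1]}.
#'
#' @param ped a [pedigree()].
#' @param gc a [gene_content()] for the genotyped animals.
#' @param proj optional precomputed [a11_projection()] for `rownames(gc)`.
#' @param all if `TRUE` (default) return all pedigree animals (observed rows
#'   unchanged); if `FALSE`, only the non-genotyped animals.
#' @return matrix of gene contents in pedigree order.
#' @export
impute_gene_content <- function(ped, gc, proj = NULL, all = TRUE) {
  stopifnot(inherits(gc, "gene_content"))
  if (is.null(proj)) proj <- a11_projection(ped, rownames(gc))
  p <- attr(gc, "p")
  W <- sweep(unclass(gc), 2L, p)               # m - 1 p'
  E <- proj$P21 %*% W
  E <- sweep(E, 2L, p, `+`)
  E[E > 1] <- 1; E[E < -1] <- -1
  colnames(E) <- colnames(gc)
  if (!all) return(E)
  out <- matrix(NA_real_, nrow(ped), ncol(gc),
                dimnames = list(ped$animal, colnames(gc)))
  out[rownames(gc), ] <- unclass(gc)
  if (nrow(E)) out[rownames(E), ] <- E
  out
}
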