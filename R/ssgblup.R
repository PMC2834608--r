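#' Fit a single-step genomic BLUP model
#'
#' Fits the animal model \eqn{y = X\beta + Z\bar g + e} in which the
#' combined genetic effect \eqn{\bar g = g + a} sums a genomic effect
#' (covariance \eqn{\sigma^2_g G^*}, the marker relationship matrix extended
#' to non-genotyped animals through the pedigree) and a residual polygenic
#' effect (covariance \eqn{\sigma^2_a A}). With \eqn{w} the relative
#' polygenic weight, \eqn{Var(\bar g) = \sigma^2_{\bar g} H_w},
#' \eqn{H_w = (1-w) G^* + w A}. Variance components
#' \eqn{(\sigma^2_{\bar g}, \sigma^2_e)} are estimated by AI-REML (with EM
#' fallback) at fixed `weight`; use [profile.ssgblup()] to estimate the
#' weight itself on a likelihood grid.
#'
#' With `genotypes = NULL` (or `weight = 1`) the model is ordinary pedigree
#' BLUP with \eqn{A}.
#'
#' @param formula phenotype model, e.g. `y ~ 1` or `y ~ herd + sex`.
#' @param data data frame with the model variables and an `id` column
#'   naming the animal of each record.
#' @param pedigree a [pedigree()] containing every animal (records may cover
#'   only a subset; record-less animals are predicted from relationships).
#' @param genotypes a [gene_content()] (rownames = genotyped animals, which
#'   must all appear in the pedigree), or `NULL` for pedigree-only BLUP.
#' @param weight polygenic weight \eqn{w \in (0, 1]} (default 0.01, a small
#'   polygenic remainder kept for invertibility and robustness).
#' @param id name of the animal-id column in `data`.
#' @param varcomp optional fixed components `list(sigma2_g =, sigma2_e =)`;
#'   skips REML.
#' @param pev compute prediction error variances: `TRUE`, `FALSE`, or `NULL`
#'   (auto: only when the pedigree has at most 2000 animals).
#' @param init optional REML starting values `c(sigma2_g, sigma2_e)`
#'   (default 0.3/0.7 of the phenotypic variance).
#' @param max_iter,tol_par,tol_ll AI-REML control.
#' @param verbose log REML iterations.
#' @return an object of class `ssgblup` with components `coefficients`,
#'   `breeding_values` (data frame: animal, gebv, pev), `varcomp`
#'   (`sigma2_g`, `sigma2_e`, `weight`), `logLik`, `fitted.values`,
#'   `residuals`, plus internal structures used by [predict.ssgblup()] and
#'   [profile.ssgblup()].
#' @seealso [profile.ssgblup()], [predict.ssgblup()], [sim_breeding_program()]
#' @examples
#' ped <- pedigree(c("s", "d", "o1", "o2"), c("0", "0", "s", "s"),
#'                 c("0", "0", "d", "d"))
#' dat <- data.frame(animal = c("o1", "o2"), y = c(1.2, 0.7))
#' fit <- ssgblup(y ~ 1, dat, ped, varcomp = list(sigma2_g = 1, sigma2_e = 2))
#' coef(fit)
#' breeding_values(fit)
#' @export
ssgblup <- function(formula, data, pedigree, genotypes = NULL, weight = 0.01,
                    id = "animal", varcomp = NULL, pev = NULL, init = NULL,
                    max_iter = 100L, tol_par = 1e-8, tol_ll = 1e-10,
                    verbose = FALSE) {
  stopifnot(inherits(pedigree, "pedigree"))
  if (weight <= 0 && is.null(genotypes))
    stop("pedigree-only model corresponds to weight = 1")
  mp <- .model_parts(formula, data, id)
  md <- .mme_data(mp$y, mp$X, mp$ids, pedigree$animal)
  Ainv <- nrm_inverse(pedigree)

  if (is.null(genotypes) || weight >= 1) {
    weight <- 1
    Kinv <- Ainv
    logdetK <- -.chol_logdet(Cholesky(Ainv, LDL = FALSE, perm = TRUE))
    proj <- NULL; Gw <- NULL; G <- NULL
  } else {
    stopifnot(inherits(genotypes, "gene_content"))
    miss <- setdiff(rownames(genotypes), pedigree$animal)
    if (length(miss))
      stop("genotyped animal(s) absent from pedigree: ",
           paste(head(miss), collapse = ", "))
    proj <- a11_projection(pedigree, rownames(genotypes), Ainv = Ainv)
    G <- grm(genotypes)
    Gw <- grm_blend(G, proj$A11, weight)
    hm <- hmat_inverse(pedigree, Gw, proj = proj, Ainv = Ainv)
    Kinv <- hm$Hinv
    logdetK <- hm$logdet
  }

  res <- .aireml(md, Kinv, logdetK, init = init, fixed = varcomp,
                 max_iter = max_iter, tol_par = tol_par, tol_ll = tol_ll,
                 verbose = verbose)
  fit <- res$fit
  if (is.null(pev)) pev <- md$q <= 2000L
  pev_vec <- rep(NA_real_, md$q)
  if (isTRUE(pev))
    pev_vec <- .mme_pev(fit$Ch, md$p, md$q, res$sigma2_e, seq_len(md$q))
  bv <- data.frame(animal = pedigree$animal, gebv = fit$u, pev = pev_vec,
                   stringsAsFactors = FALSE)
  fitted <- as.numeric(md$X %*% fit$beta) + fit$u[md$Zi]
  structure(list(
    call = match.call(),
    formula = formula,
    coefficients = setNames(fit$beta, colnames(md$X)),
    breeding_values = bv,
    varcomp = list(sigma2_g = res$sigma2_g, sigma2_e = res$sigma2_e,
                   weight = weight),
    logLik = res$logLik,
    fitted.values = fitted,
    residuals = md$y - fitted,
    iterations = res$iterations,
    reml = is.null(varcomp),
    pedigree = pedigree,
    genotypes = genotypes,
    internal = list(md = md, Kinv = Kinv, logdetK = logdetK, Ainv = Ainv,
                    proj = proj, G = G, Gw = Gw, Ch = fit$Ch, id = id,
                    init = init, max_iter = max_iter, tol_par = tol_par,
                    tol_ll = tol_ll)),
    class = "ssgblup")
}

#' Breeding values of a fitted model
#' @param object an `ssgblup` fit.
#' @return data frame with columns `animal`, `gebv`, `pev`.
#' @export
breeding_values <- function(object) {
  stopifnot(inherits(object, "ssgblup"))
  object$breeding_values
}

#' @export
#' @method print ssgblup
print.ssgblup <- function(x, ...) {
  cat("Single-step GBLUP fit",
      if (x$varcomp$weight >= 1) "(pedigree BLUP, w = 1)" else
        sprintf("(polygenic weight w = %g)", x$varcomp$weight), "\n")
  cat(sprintf("  records: %d   animals: %d   genotyped: %d\n",
              x$internal$md$n, x$internal$md$q,
              if (is.null(x$genotypes)) 0L else nrow(x$genotypes)))
  cat(sprintf("  sigma2_g = %.4f   sigma2_e = %.4f   (%s)\n",
              x$varcomp$sigma2_g, x$varcomp$sigma2_e,
              if (x$reml) sprintf("REML, %d iterations", x$iterations)
              else "fixed"))
  cat(sprintf("  REML logLik = %.4f\n", x$logLik))
  invisible(x)
}

#' @export
#' @method summary ssgblup
summary.ssgblup <- function(object, ...) {
  bv <- object$breeding_values
  structure(list(fit = object,
                 fixef = object$coefficients,
                 varcomp = object$varcomp,
                 logLik = object$logLik,
                 bv_summary = summary(bv$gebv),
                 pev_available = !all(is.na(bv$pev))),
            class = "summary.ssgblup")
}

#' @export
#' @method print summary.ssgblup
print.summary.ssgblup <- function(x, ...) {
  print(x$fit)
  cat("Fixed effects (BLUE):\n")
  print(x$fixef)
  cat("GEBV distribution:\n")
  print(x$bv_summary)
  if (!x$pev_available) cat("(prediction error variances not computed)\n")
  invisible(x)
}

#' @export
coef.ssgblup <- function(object, ...) object$coefficients

#' @export
fitted.ssgblup <- function(object, ...) object$fitted.values

#' @export
residuals.ssgblup <- function(object, ...) object$residuals

#' @export
logLik.ssgblup <- function(object, ...) {
  structure(object$logLik, df = 2L,
            nobs = object$internal$md$n - object$internal$md$p,
            class = "logLik")
}

#' Simulate phenotypes from a fitted single-step model
#'
#' Draws \eqn{y^* = X\hat\beta + Z\bar g^* + e^*} with
#' \eqn{\bar g^* \sim N(0, \hat\sigma^2_g H_w)} (sampled through the sparse
#' Cholesky factor of \eqn{H_w^{-1}}) and iid normal residuals.
#'
#' @param object an `ssgblup` fit.
#' @param nsim number of replicate phenotype vectors.
#' @param seed optional seed.
#' @param ... unused.
#' @return data frame of `nsim` simulated phenotype vectors.
#' @export
simulate.ssgblup <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  md <- object$internal$md
  Ch <- Cholesky(object$internal$Kinv, LDL = FALSE, perm = TRUE)
  mu <- as.numeric(md$X %*% object$coefficients)
  sg <- object$varcomp$sigma2_g; se <- object$varcomp$sigma2_e
  out <- replicate(nsim, {
    z <- rnorm(md$q)
    g <- sqrt(sg) *
      as.numeric(solve(Ch, solve(Ch, z, system = "Lt"), system = "Pt"))
    mu + g[md$Zi] + rnorm(md$n, sd = sqrt(se))
  })
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

#' Profile REML likelihood over the polygenic weight
#'
#' Re-estimates \eqn{(\sigma^2_g, \sigma^2_e)} by AI-REML at each grid value
#' of the polygenic weight \eqn{w} and records the profile REML
#' log-likelihood. The reported uncertainty interval is
#' \eqn{\{w : \log L(w) > \log L(\hat w) - c\}} with drop `ci_drop`
#' (default 3.84, the 95% quantile of \eqn{\chi^2(1)}), taken as the
#' min/max of qualifying grid points and extended to 0 when the lowest grid
#' point qualifies. Ties in the maximum resolve to the smallest `w`.
#'
#' @param fitted an `ssgblup` fit with genotypes.
#' @param w weight grid, strictly increasing, within (0, 1].
#' @param ci_drop log-likelihood drop defining the interval.
#' @param verbose print progress.
#' @param ... unused.
#' @return object of class `ssgblup_profile`: data frame `grid`
#'   (w, logL, sigma2_g, sigma2_e), `w_hat`, `ci`, `varcomp` at `w_hat`.
#' @export
profile.ssgblup <- function(fitted, w = seq(0.01, 0.19, by = 0.02),
                            ci_drop = 3.84, verbose = FALSE, ...) {
  object <- fitted
  if (is.null(object$genotypes))
    stop("profiling the polygenic weight needs a genotyped model")
  if (!length(w) || any(w <= 0) || any(w > 1) || is.unsorted(w, strictly = TRUE))
    stop("w must be strictly increasing values in (0, 1]")
  int <- object$internal
  ped <- object$pedigree
  rows <- vector("list", length(w))
  fails <- character(0)
  for (k in seq_along(w)) {
    rows[[k]] <- tryCatch({
      Gw <- grm_blend(int$G, int$proj$A11, w[k])
      hm <- hmat_inverse(ped, Gw, proj = int$proj, Ainv = int$Ainv)
      res <- .aireml(int$md, hm$Hinv, hm$logdet, init = int$init,
                     max_iter = int$max_iter, tol_par = int$tol_par,
                     tol_ll = int$tol_ll)
      if (verbose)
        message(sprintf("w = %.3f  logL = %.4f", w[k], res$logLik))
      data.frame(w = w[k], logL = res$logLik, sigma2_g = res$sigma2_g,
                 sigma2_e = res$sigma2_e)
    }, error = function(e) {
      fails <<- c(fails, sprintf("w = %g: %s", w[k], conditionMessage(e)))
      NULL
    })
  }
  grid <- do.call(rbind, rows)
  if (is.null(grid) || !nrow(grid))
    stop("REML failed at every grid point:\n", paste(fails, collapse = "\n"))
  if (length(fails))
    warning("REML failed at some grid points:\n", paste(fails, collapse = "\n"))
  best <- which(grid$logL >= max(grid$logL) - 1e-9)[1L]  # ties: smallest w
  keep <- grid$w[grid$logL > grid$logL[best] - ci_drop]
  ci <- c(min(keep), max(keep))
  if (ci[1L] <= min(grid$w) + 1e-12) ci[1L] <- 0  # boundary qualifies
  structure(list(grid = grid, w_hat = grid$w[best], ci = ci,
                 ci_drop = ci_drop,
                 varcomp = list(sigma2_g = grid$sigma2_g[best],
                                sigma2_e = grid$sigma2_e[best],
                                weight = grid$w[best])),
            class = "ssgblup_profile")
}

#' @export
#' @method print ssgblup_profile
print.ssgblup_profile <- function(x, ...) {
  cat("Profile REML likelihood over the polygenic weight w\n")
  print(x$grid, row.names = FALSE, digits = 6)
  cat(sprintf("w_hat = %g;  interval {w : logL > max - %.3g} = [%g, %g]\n",
              x$w_hat, x$ci_drop, x$ci[1L], x$ci[2L]))
  invisible(x)
}

#' @export
confint.ssgblup_profile <- function(object, parm, level, ...) {
  matrix(object$ci, 1L, dimnames = list("w", c("lower", "upper")))
}

#' @rdname profile.ssgblup
#' @param x an `ssgblup_profile`.
#' @export
plot.ssgblup_profile <- function(x, ...) {
  graphics::plot(x$grid$w, x$grid$logL, type = "b", pch = 16,
                 xlab = "polygenic weight w", ylab = "profile REML logL", ...)
  graphics::abline(h = max(x$grid$logL) - x$ci_drop, lty = 3)
  graphics::abline(v = x$w_hat, lty = 2, col = "grey50")
  invisible(x)
}

#' @export
plot.ssgblup <- function(x, ...) {
  graphics::plot(x$fitted.values, x$residuals, pch = 20,
                 xlab = "fitted", ylab = "residual", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
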