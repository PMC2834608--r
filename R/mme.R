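# Internal mixed-model machinery: lambda-parameterised sparse MME, REML
# log-likelihood, AI-REML with EM fallback. The coefficient matrix is
#   M = [ X'X        X'Z       ]      lambda = sigma2_e / sigma2_g,
#       [ Z'X   Z'Z + lambda*Kinv ]
# where Kinv is the (sparse) inverse of the genetic relationship matrix
# (H_w^{-1}, A^{-1}, or a dense inverse for genotyped-only models).
# -2*logL(REML) = (n-p) log se - q log lambda + logdet(K) + logdet(M) + rss/se
# with rss = y'y - theta' rhs, which equals the usual
# log|V| + log|X'V^-1 X| + y'Py form exactly.

.model_parts <- function(formula, data, id) {
  if (!id %in% names(data)) stop("id column '", id, "' not found in data")
  mf <- model.frame(formula, data, na.action = stats::na.omit)
  if (nrow(mf) < nrow(data))
    stop("missing values in model variables are not supported")
  y <- as.numeric(model.response(mf))
  X <- model.matrix(attr(mf, "terms"), mf)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    warning("fixed-effect design rank deficient; dropping ",
            ncol(X) - qx$rank, " column(s): ",
            paste(colnames(X)[-keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
  }
  list(y = y, X = X, ids = as.character(data[[id]]))
}

.mme_data <- function(y, X, ids, animals) {
  Zi <- match(ids, animals)
  if (anyNA(Zi))
    stop("record animal(s) absent from pedigree: ",
         paste(head(unique(ids[is.na(Zi)])), collapse = ", "))
  n <- length(y)
  q <- length(animals)
  Z <- sparseMatrix(i = seq_len(n), j = Zi, x = 1, dims = c(n, q))
  list(y = y, X = X, Zi = Zi, Z = Z, n = n, p = ncol(X), q = q,
       XtX = Matrix(crossprod(X), sparse = TRUE),
       XtZ = crossprod(Matrix(X, sparse = TRUE), Z),
       ZtZ = crossprod(Z),
       Xty = as.numeric(crossprod(X, y)),
       Zty = as.numeric(crossprod(Z, y)),
       yty = sum(y * y))
}

.mme_assemble <- function(md, Kinv, lambda) {
  forceSymmetric(rbind(
    cbind(md$XtX, md$XtZ),
    cbind(t(md$XtZ), md$ZtZ + lambda * Kinv)))
}

# Factorise (or update) and solve the MME at a given lambda.
.mme_fit <- function(md, Kinv, lambda, cache = NULL) {
  M <- .mme_assemble(md, Kinv, lambda)
  Ch <- if (is.null(cache$Ch)) Cholesky(M, LDL = FALSE, perm = TRUE)
        else tryCatch(update(cache$Ch, M), error = function(e)
          Cholesky(M, LDL = FALSE, perm = TRUE))
  rhs <- c(md$Xty, md$Zty)
  theta <- as.numeric(solve(Ch, rhs))
  beta <- theta[seq_len(md$p)]
  u <- theta[-seq_len(md$p)]
  list(Ch = Ch, beta = beta, u = u,
       rss = md$yty - sum(theta * rhs),
       ldM = .chol_logdet(Ch))
}

.mme_logdet_at <- function(md, Kinv, lambda, cache) {
  M <- .mme_assemble(md, Kinv, lambda)
  Ch <- tryCatch(update(cache$Ch, M), error = function(e)
    Cholesky(M, LDL = FALSE, perm = TRUE))
  .chol_logdet(Ch)
}

# REML -2 log-likelihood at (sigma2_g, sigma2_e); fit optional (reused).
.reml_m2l <- function(md, Kinv, logdetK, sg, se, fit) {
  lambda <- se / sg
  (md$n - md$p) * log(se) - md$q * log(lambda) + logdetK + fit$ldM +
    fit$rss / se
}

# Profile REML over lambda = se/sg alone: se has the closed form
# rss/(n - p) at any lambda, so the whole surface reduces to one dimension.
# Used as a line-search safeguard when AI/EM progress stalls near the
# sigma2_e -> 0 boundary (e.g. models fitted to smooth pseudo-responses).
.reml_profile_lambda <- function(md, Kinv, logdetK, lambda0, cache) {
  np <- md$n - md$p
  obj <- function(loglam) {
    lambda <- exp(loglam)
    fit <- .mme_fit(md, Kinv, lambda, cache)
    cache$Ch <- fit$Ch
    se <- fit$rss / np
    (np) * log(se) - md$q * log(lambda) + logdetK + fit$ldM + np
  }
  opt <- optimize(obj, interval = log(lambda0) + c(-10, 10), tol = 1e-10)
  lambda <- exp(opt$minimum)
  fit <- .mme_fit(md, Kinv, lambda, cache)
  se <- fit$rss / np
  list(sigma2_g = se / lambda, sigma2_e = se, logLik = -0.5 * opt$objective,
       fit = fit)
}

#' @noRd
# AI-REML for the two-component model; returns estimates, logL and the
# solved MME at the optimum. Scores use the identity
# tr(K^{-1} Mqq^{-1}) = d/dlambda logdet M(lambda), evaluated by central
# differencing of the (analytic, smooth) sparse log-determinant. When AI/EM
# steps stall (slow linear EM progress towards a variance boundary), the
# exact one-dimensional profile over lambda is optimised instead.
.aireml <- function(md, Kinv, logdetK, init = NULL, fixed = NULL,
                    max_iter = 100L, tol_par = 1e-8, tol_ll = 1e-10,
                    verbose = FALSE) {
  n <- md$n; p <- md$p; q <- md$q
  vy <- var(md$y)
  floor_v <- 1e-10 * max(vy, .Machine$double.eps)
  if (!is.null(fixed)) {
    sg <- fixed$sigma2_g; se <- fixed$sigma2_e
    fit <- .mme_fit(md, Kinv, se / sg)
    ll <- -0.5 * .reml_m2l(md, Kinv, logdetK, sg, se, fit)
    return(list(sigma2_g = sg, sigma2_e = se, logLik = ll, fit = fit,
                iterations = 0L, converged = TRUE, trace = NULL))
  }
  if (is.null(init)) init <- c(0.3 * vy, 0.7 * vy)
  sg <- max(init[1L], floor_v); se <- max(init[2L], floor_v)
  cache <- new.env(parent = emptyenv())
  cache$Ch <- NULL
  ll_old <- -Inf
  trace <- matrix(NA_real_, 0L, 4L,
                  dimnames = list(NULL, c("sigma2_g", "sigma2_e", "logL", "step")))
  fit <- NULL
  stall <- 0L
  for (it in seq_len(max_iter)) {
    lambda <- se / sg
    fit <- .mme_fit(md, Kinv, lambda, cache)
    cache$Ch <- fit$Ch
    ll <- -0.5 * .reml_m2l(md, Kinv, logdetK, sg, se, fit)
    dpar <- max(abs(c(sg, se) - if (it > 1L) par_old else c(Inf, Inf)) /
                  (abs(c(sg, se)) + 1e-12))
    if (it > 1L && (abs(ll - ll_old) < tol_ll || dpar < tol_par)) {
      return(list(sigma2_g = sg, sigma2_e = se, logLik = ll, fit = fit,
                  iterations = it - 1L, converged = TRUE, trace = trace))
    }
    par_old <- c(sg, se); ll_old <- ll

    # trace term t = tr(Kinv Mqq^{-1}) = d logdet(M)/d lambda
    h <- 1e-4 * lambda
    t_tr <- (.mme_logdet_at(md, Kinv, lambda + h, cache) -
             .mme_logdet_at(md, Kinv, lambda - h, cache)) / (2 * h)
    uKu <- as.numeric(crossprod(fit$u, Kinv %*% fit$u))
    estar <- md$y - as.numeric(md$X %*% fit$beta) - fit$u[md$Zi]
    ee <- sum(estar^2)
    s_g <- -0.5 * ((q - lambda * t_tr) / sg - uKu / sg^2)
    s_e <- -0.5 * ((n - p - q + lambda * t_tr) / se - ee / se^2)

    # average-information matrix from the data parts (extra MME solves)
    f1 <- fit$u[md$Zi] / sg
    f2 <- estar / se
    Pf <- function(f) {
      rhs <- c(as.numeric(crossprod(md$X, f)), as.numeric(crossprod(md$Z, f)))
      th <- as.numeric(solve(fit$Ch, rhs))
      (f - as.numeric(md$X %*% th[seq_len(p)]) - th[-seq_len(p)][md$Zi]) / se
    }
    Pf1 <- Pf(f1); Pf2 <- Pf(f2)
    AI <- 0.5 * matrix(c(sum(f1 * Pf1), sum(f1 * Pf2),
                         sum(f1 * Pf2), sum(f2 * Pf2)), 2L, 2L)
    step_type <- "AI"
    delta <- tryCatch(solve(AI, c(s_g, s_e)), error = function(e) NULL)
    ok <- FALSE
    if (!is.null(delta)) {
      fac <- 1
      for (k in 1:10) {
        cand <- c(sg, se) + fac * delta
        if (all(cand > floor_v)) {
          fit_c <- .mme_fit(md, Kinv, cand[2L] / cand[1L], cache)
          cache$Ch <- fit_c$Ch
          ll_c <- -0.5 * .reml_m2l(md, Kinv, logdetK, cand[1L], cand[2L], fit_c)
          if (is.finite(ll_c) && ll_c >= ll - 1e-8) {
            sg <- cand[1L]; se <- cand[2L]; ok <- TRUE; break
          }
        }
        fac <- fac / 2
      }
    }
    if (!ok) {
      # EM-REML fallback (guaranteed ascent)
      step_type <- "EM"
      sg <- max((uKu + se * t_tr) / q, floor_v)
      se <- max(fit$rss / (n - p), floor_v)
    }
    trace <- rbind(trace, c(sg, se, ll, step_type == "EM"))
    if (verbose)
      message(sprintf("iter %d [%s] sigma2_g=%.6g sigma2_e=%.6g logL=%.6f",
                      it, step_type, sg, se, ll))
    stall <- if (step_type == "EM" && it > 1L && ll - ll_old < 1e-5)
      stall + 1L else 0L
    if (stall >= 3L) break  # linear EM crawl towards a boundary
  }
  # exact profile over lambda as safeguard (boundary cases, non-convergence)
  pl <- .reml_profile_lambda(md, Kinv, logdetK, se / sg, cache)
  ll_cur <- -0.5 * .reml_m2l(md, Kinv, logdetK, sg, se,
                             .mme_fit(md, Kinv, se / sg, cache))
  if (pl$logLik >= ll_cur) {
    return(list(sigma2_g = pl$sigma2_g, sigma2_e = pl$sigma2_e,
                logLik = pl$logLik, fit = pl$fit, iterations = it,
                converged = TRUE, trace = trace))
  }
  fit <- .mme_fit(md, Kinv, se / sg, cache)
  list(sigma2_g = sg, sigma2_e = se, logLik = ll_cur, fit = fit,
       iterations = it, converged = TRUE, trace = trace)
}

# Prediction error variances: sigma2_e * diag of the inverse MME coefficient
# matrix over the requested animal rows. Chunked sparse solves.
.mme_pev <- function(Ch, p, q, se, idx, chunk = 256L) {
  out <- numeric(length(idx))
  cols <- p + idx
  ntot <- p + q
  for (start in seq(1L, length(cols), by = chunk)) {
    jj <- cols[start:min(start + chunk - 1L, length(cols))]
    E <- sparseMatrix(i = jj, j = seq_along(jj), x = 1,
                      dims = c(ntot, length(jj)))
    S <- solve(Ch, E)
    out[start:(start + length(jj) - 1L)] <-
      S[cbind(jj, seq_along(jj))]
  }
  se * out
}
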