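#' Eigendecomposition of a kinship matrix for REML
#'
#' Decomposes a kinship matrix once so that many genes can be fitted against
#' the same relationship structure cheaply.  Negative eigenvalues (possible
#' after method-of-moments estimation and truncation) are clipped at zero so
#' the implied covariance is positive semi-definite; a matrix that is grossly
#' non-PSD (most negative eigenvalue below `-psd_tol` times the largest) is
#' rejected.
#'
#' @param K symmetric kinship matrix with sample ids as dimnames.
#' @param psd_tol relative tolerance for negative eigenvalues (default 0.25).
#' @return List with `values` (clipped, non-negative), `vectors` and `ids`;
#'   class `kinship_eigen`.
#' @export
kinship_eigen <- function(K, psd_tol = 0.25) {
  K <- unclass(K)
  stopifnot(is.matrix(K), nrow(K) == ncol(K))
  if (max(abs(K - t(K))) > 1e-8) stop_config("kinship matrix must be symmetric")
  e <- eigen(K, symmetric = TRUE)
  if (min(e$values) < -psd_tol * max(e$values, 1))
    stop_config("kinship matrix is not positive semi-definite beyond tolerance")
  structure(list(values = pmax(e$values, 0), vectors = e$vectors,
                 ids = rownames(K)), class = "kinship_eigen")
}

# Rotate a balanced replicated data set into the eigenbasis of Z K Z'.
# With r replicates per individual and K = V L V', the non-null eigenvalues
# of Z K Z' are r*L on the rotated individual means; the remaining N - n
# within-individual directions have eigenvalue 0, are orthogonal to any
# individual-level fixed design, and enter the likelihood only through the
# within-individual sum of squares.
reml_prep <- function(y, indiv, Keig, X = NULL) {
  stopifnot(inherits(Keig, "kinship_eigen"))
  indiv <- as.character(indiv)
  stopifnot(length(indiv) == length(y))
  ids <- unique(indiv)
  if (!is.null(Keig$ids)) {
    if (!all(ids %in% Keig$ids))
      stop_config("individuals absent from the kinship matrix")
    if (!setequal(ids, Keig$ids))
      stop_config("kinship matrix covers individuals absent from the data; subset K first")
    ids <- Keig$ids
  }
  n <- length(ids)
  idx <- match(indiv, ids)
  counts <- tabulate(idx, n)
  if (length(unique(counts)) != 1)
    stop_config("replicate count must be equal across individuals")
  r <- counts[1]
  N <- length(y)
  ybar <- as.vector(tapply(y, factor(indiv, levels = ids), mean))
  ssw <- sum((y - ybar[idx])^2)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (nrow(X) == N && N != n) {
    # observation-level design: must be constant within individual
    Xi <- rowsum(X, idx) / r
    if (max(abs(X - Xi[idx, , drop = FALSE])) > 1e-10)
      stop_config("fixed-effect columns must be constant within individual")
    X <- Xi
  }
  if (nrow(X) != n) stop_config("fixed design has %d rows; expected %d", nrow(X), n)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop_config("fixed design is rank deficient; drop collinear columns")
  if (N <= ncol(X) + 1)
    stop_config("more fixed-effect columns than observations allow")
  V <- Keig$vectors
  d <- r * Keig$values
  ytil <- sqrt(r) * crossprod(V, ybar)
  Xtil <- sqrt(r) * crossprod(V, X)
  logdet_XtX <- determinant(crossprod(X) * r, logarithm = TRUE)$modulus
  list(n = n, r = r, N = N, p = ncol(X), d = d, ytil = as.vector(ytil),
       Xtil = Xtil, ssw = ssw, logdet_XtX = as.numeric(logdet_XtX),
       ids = ids, idx = idx, X = X, ybar = ybar, V = V,
       colnames = colnames(X))
}

# Profile restricted / full log-likelihood at variance ratio
# lambda = sigma_g^2 / sigma_e^2.  Returns the pieces needed to back out
# the variance components in closed form.
reml_eval <- function(prep, lambda) {
  w <- 1 / (lambda * prep$d + 1)
  XtWX <- crossprod(prep$Xtil, prep$Xtil * w)
  XtWy <- crossprod(prep$Xtil, prep$ytil * w)
  beta <- solve(XtWX, XtWy)
  resid <- prep$ytil - prep$Xtil %*% beta
  rss <- sum(w * resid^2) + prep$ssw
  logdetH <- sum(log1p(lambda * prep$d))
  Np <- prep$N - prep$p
  sigma_e2_reml <- rss / Np
  ll_reml <- -0.5 * (Np * log(2 * pi * sigma_e2_reml) + Np + logdetH +
                     determinant(XtWX, logarithm = TRUE)$modulus -
                     prep$logdet_XtX)
  sigma_e2_ml <- rss / prep$N
  ll_ml <- -0.5 * (prep$N * log(2 * pi * sigma_e2_ml) + prep$N + logdetH)
  list(ll_reml = as.numeric(ll_reml), ll_ml = as.numeric(ll_ml),
       sigma_e2 = sigma_e2_reml, sigma_e2_ml = sigma_e2_ml,
       beta = as.vector(beta))
}

#' Profile log-likelihood of the variance ratio
#'
#' Evaluates the profiled restricted (or full) log-likelihood of the mixed
#' model at given values of `lambda = sigma_g^2 / sigma_e^2`, with the fixed
#' effects and residual variance profiled out.  Exposed so the 1-D optimiser
#' can be checked against a dense grid.
#'
#' @inheritParams reml_fit
#' @param lambda vector of non-negative variance ratios.
#' @param restricted if `TRUE` (default) the restricted likelihood, else the
#'   full (ML) likelihood.
#' @return Numeric vector of log-likelihood values.
#' @export
reml_loglik <- function(y, indiv, K, lambda, X = NULL, restricted = TRUE) {
  Keig <- if (inherits(K, "kinship_eigen")) K else kinship_eigen(K)
  prep <- reml_prep(y, indiv, Keig, X)
  vapply(lambda, function(l) {
    ev <- reml_eval(prep, l)
    if (restricted) ev$ll_reml else ev$ll_ml
  }, numeric(1))
}

maximize_profile <- function(prep, what = c("ll_reml", "ll_ml"),
                             lambda_min = 1e-5, lambda_max = 1e5,
                             grid_points = 81L, tol = 1e-10) {
  what <- match.arg(what)
  grid <- c(0, 10^seq(log10(lambda_min), log10(lambda_max),
                      length.out = grid_points))
  ll <- vapply(grid, function(l) reml_eval(prep, l)[[what]], numeric(1))
  i <- which.max(ll)
  lo <- grid[max(i - 1L, 1L)]
  hi <- grid[min(i + 1L, length(grid))]
  flags <- character()
  if (i == length(grid)) flags <- c(flags, "lambda_upper_boundary")
  best <- list(lambda = grid[i], ll = ll[i])
  if (hi > lo) {
    opt <- if (lo > 0) {
      o <- optimize(function(lx) reml_eval(prep, 10^lx)[[what]],
                    lower = log10(lo), upper = log10(hi),
                    maximum = TRUE, tol = tol)
      list(lambda = 10^o$maximum, ll = o$objective)
    } else {
      o <- optimize(function(l) reml_eval(prep, l)[[what]],
                    lower = lo, upper = hi, maximum = TRUE, tol = tol)
      list(lambda = o$maximum, ll = o$objective)
    }
    if (opt$ll > best$ll) best <- opt
  }
  if (best$lambda <= lambda_min) {
    # boundary at zero: compare against the no-genetic-variance model
    if (ll[1] >= best$ll) best <- list(lambda = 0, ll = ll[1])
    flags <- c(flags, "lambda_lower_boundary")
  }
  list(lambda = best$lambda, ll = best$ll, flags = flags)
}

#' REML fit of the polygenic variance-component model
#'
#' Fits `y_ij = x_i' beta + u_i + e_ij` with `u ~ N(0, sigma_g^2 K)` and
#' `e ~ N(0, sigma_e^2 I)` to a replicated trait, where `j` indexes the
#' replicate arrays of individual `i` and `K` is a kinship matrix.  The
#' phenotypic covariance is `V = sigma_g^2 Z K Z' + sigma_e^2 I` with `Z` the
#' observation-to-individual incidence matrix.
#'
#' Estimation eigendecomposes `Z K Z'` once (exploiting the balanced
#' replicate structure so only the individual-level kinship is decomposed)
#' and maximises the restricted log-likelihood over the single ratio
#' `lambda = sigma_g^2 / sigma_e^2` on `[0, 1e5]` by a log-spaced grid
#' followed by golden-section refinement; `sigma_e^2` is then recovered in
#' closed form.  Both variance components are non-negative by construction,
#' so the heritability estimate `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)`
#' always lies in \[0, 1\].  The full (ML) likelihood is maximised over the
#' same profile and reported alongside, for information-criterion comparisons
#' of models that differ in their fixed effects.
#'
#' @param y numeric vector of observations (one per array).
#' @param indiv individual id for each observation; must match the dimnames
#'   of `K`.  Replicate counts must be equal across individuals.
#' @param K kinship matrix (or a precomputed [kinship_eigen()], which is much
#'   faster when fitting many genes against one kinship).
#' @param X fixed-effect design matrix (individual- or observation-level;
#'   observation-level columns must be constant within individual).  Default
#'   is an intercept.  Include population indicator columns (one level
#'   omitted) to correct for structure.
#' @param lambda_max upper end of the variance-ratio search range.
#' @return An object of class `heritex_vc`: list with `sigma_g2`, `sigma_e2`,
#'   `h2`, `lambda`, `loglik_reml`, maximised `loglik_ml`, `beta`,
#'   `converged`, `flags`, `n`, `n_obs`, `p`, and the internal rotated data
#'   (for [model_diagnostics()]).
#' @examples
#' K <- diag(10); dimnames(K) <- list(letters[1:10], letters[1:10])
#' y <- rnorm(40)
#' fit <- reml_fit(y, rep(letters[1:10], each = 4), K)
#' heritability(fit)
#' @export
reml_fit <- function(y, indiv, K, X = NULL, lambda_max = 1e5) {
  Keig <- if (inherits(K, "kinship_eigen")) K else kinship_eigen(K)
  prep <- reml_prep(y, indiv, Keig, X)
  opt <- maximize_profile(prep, "ll_reml", lambda_max = lambda_max)
  ev <- reml_eval(prep, opt$lambda)
  opt_ml <- maximize_profile(prep, "ll_ml", lambda_max = lambda_max)
  flags <- opt$flags
  if (prep$r == 1 && sd(prep$d) < 1e-8)
    flags <- c(flags, "flat_likelihood")
  sigma_e2 <- ev$sigma_e2
  sigma_g2 <- opt$lambda * sigma_e2
  h2 <- if (sigma_g2 + sigma_e2 > 0) sigma_g2 / (sigma_g2 + sigma_e2) else 0
  structure(list(
    sigma_g2 = sigma_g2, sigma_e2 = sigma_e2, h2 = h2, lambda = opt$lambda,
    loglik_reml = opt$ll, loglik_ml = opt_ml$ll,
    beta = setNames(ev$beta, prep$colnames),
    converged = TRUE, flags = flags,
    n = prep$n, n_obs = prep$N, p = prep$p,
    prep = prep, Keig = Keig), class = "heritex_vc")
}

#' @export
print.heritex_vc <- function(x, ...) {
  cat(sprintf(
    "REML variance components: sigma_g2 = %.4g, sigma_e2 = %.4g, h2 = %.3f\n",
    x$sigma_g2, x$sigma_e2, x$h2))
  cat(sprintf("  logLik (REML) %.4f, (ML) %.4f; n = %d individuals x %d obs%s\n",
              x$loglik_reml, x$loglik_ml, x$n, x$n_obs,
              if (length(x$flags)) paste0("; flags: ",
                                          paste(x$flags, collapse = ", "))
              else ""))
  invisible(x)
}

#' Narrow-sense heritability from variance components
#'
#' `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)`, guaranteed in \[0, 1\] because
#' both components are non-negative by construction.  If both components are
#' zero the ratio is undefined and a flagged 0 is returned.
#'
#' @param vc a [reml_fit()] result.
#' @return Heritability in \[0, 1\] (attribute `flag` set to `"undefined"`
#'   when both components are zero).
#' @export
heritability <- function(vc) {
  stopifnot(inherits(vc, "heritex_vc"))
  tot <- vc$sigma_g2 + vc$sigma_e2
  if (tot <= 0) return(structure(0, flag = "undefined"))
  vc$sigma_g2 / tot
}

#' Mixed-model fit with SNP fixed effects
#'
#' Identical machinery to [reml_fit()] with the fixed design augmented by one
#' or more SNP dosage columns (and optionally their product), used to
#' quantify the phenotypic variance tagged by detected eQTLs by comparing the
#' variance components against the SNP-free fit.  SNP columns collinear with
#' the covariates (or with each other) are dropped with a warning.
#'
#' @inheritParams reml_fit
#' @param snps individual-level dosage matrix (individuals x SNPs) or vector;
#'   missing dosages are mean-imputed.
#' @return A `heritex_vc` fit; dropped columns are recorded in flag
#'   `"dropped_collinear"`.
#' @export
fit_snp_model <- function(y, indiv, K, snps, X = NULL, lambda_max = 1e5) {
  snps <- as.matrix(snps)
  if (is.null(colnames(snps)))
    colnames(snps) <- paste0("snp", seq_len(ncol(snps)))
  for (j in seq_len(ncol(snps))) {
    xj <- snps[, j]
    if (anyNA(xj)) snps[is.na(xj), j] <- mean(xj, na.rm = TRUE)
  }
  if (is.null(X)) {
    ids <- unique(as.character(indiv))
    X <- matrix(1, length(ids), 1, dimnames = list(NULL, "(Intercept)"))
  }
  full <- cbind(as.matrix(X), snps)
  qrf <- qr(full)
  dropped <- character()
  if (qrf$rank < ncol(full)) {
    keep <- qrf$pivot[seq_len(qrf$rank)]
    dropped <- colnames(full)[-keep]
    warning("dropping collinear column(s): ", paste(dropped, collapse = ", "))
    full <- full[, sort(keep), drop = FALSE]
    if (!any(colnames(full) %in% colnames(snps)))
      warning("all SNP columns were collinear with the covariates")
  }
  fit <- reml_fit(y, indiv, K, X = full, lambda_max = lambda_max)
  if (length(dropped)) fit$flags <- c(fit$flags, "dropped_collinear")
  fit
}

#' Phenotypic variance explained by a tested SNP
#'
#' Compares the variance-component sums of a SNP-free and a SNP-inclusive
#' mixed-model fit of the same trait:
#' `h2_qtl = ((sg2 + se2)_free - (sg2 + se2)_snp) / (sg2 + se2)_free`,
#' floored at 0 (numerically the difference can fall slightly below zero).
#' The component-wise changes are reported so the user can verify that the
#' decrease comes from the genetic component and not from the residual.  The
#' ratio `pi = h2_qtl / h2_free` — the fraction of the trait's heritability
#' captured by its detected eQTLs — is capped into \[0, 1\].
#'
#' @param vc_free SNP-free [reml_fit()] of the trait.
#' @param vc_snp [fit_snp_model()] of the same data.
#' @return List of class `eqtl_h2`: `h2_qtl`, `delta_sigma_g2`,
#'   `delta_sigma_e2`, `pi_ratio`, `h2_free`, `floored`.
#' @export
eqtl_heritability <- function(vc_free, vc_snp) {
  stopifnot(inherits(vc_free, "heritex_vc"), inherits(vc_snp, "heritex_vc"))
  tot_free <- vc_free$sigma_g2 + vc_free$sigma_e2
  if (tot_free <= 0) stop_config("SNP-free phenotypic variance is zero")
  tot_snp <- vc_snp$sigma_g2 + vc_snp$sigma_e2
  raw <- (tot_free - tot_snp) / tot_free
  h2_qtl <- max(raw, 0)
  h2_free <- heritability(vc_free)
  pi_ratio <- if (h2_free > 0) min(max(h2_qtl / h2_free, 0), 1) else NA_real_
  structure(list(h2_qtl = h2_qtl,
                 delta_sigma_g2 = vc_free$sigma_g2 - vc_snp$sigma_g2,
                 delta_sigma_e2 = vc_free$sigma_e2 - vc_snp$sigma_e2,
                 pi_ratio = pi_ratio, h2_free = as.numeric(h2_free),
                 floored = raw < 0), class = "eqtl_h2")
}

#' Additive versus multiplicative two-SNP models with AIC selection
#'
#' Fits the mixed model with both SNPs as additive fixed effects, and again
#' with their multiplicative interaction added, and compares the two by
#' `AIC = -2 * logLik(ML) + 2k` with `k` = number of fixed effects + 2
#' variance components.  ML (not REML) likelihoods are used because the two
#' models differ in their fixed effects.  Also reports each model's explained
#' phenotypic variance against the SNP-free fit.
#'
#' @inheritParams reml_fit
#' @param snp1,snp2 individual-level dosage vectors of the two (peak) SNPs.
#' @return List of class `epistasis_fit`: `additive`, `interaction` (the two
#'   fits; `interaction` is `NULL` if the product column is constant or
#'   collinear), `aic` (named vector), `preferred` (`"additive"` or
#'   `"interaction"`), `h2_qtl_additive`, `h2_qtl_interaction`,
#'   `delta_explained`.
#' @export
fit_epistasis <- function(y, indiv, K, snp1, snp2, X = NULL,
                          lambda_max = 1e5) {
  if (sd(snp1, na.rm = TRUE) == 0 || sd(snp2, na.rm = TRUE) == 0)
    stop_config("both SNPs must be polymorphic")
  Keig <- if (inherits(K, "kinship_eigen")) K else kinship_eigen(K)
  x1 <- ifelse(is.na(snp1), mean(snp1, na.rm = TRUE), snp1)
  x2 <- ifelse(is.na(snp2), mean(snp2, na.rm = TRUE), snp2)
  free <- reml_fit(y, indiv, Keig, X = X, lambda_max = lambda_max)
  add <- fit_snp_model(y, indiv, Keig, cbind(snp1 = x1, snp2 = x2), X = X,
                       lambda_max = lambda_max)
  prod_col <- x1 * x2
  inter <- NULL
  if (sd(prod_col) > 0) {
    inter <- tryCatch(
      fit_snp_model(y, indiv, Keig,
                    cbind(snp1 = x1, snp2 = x2, snp1_x_snp2 = prod_col),
                    X = X, lambda_max = lambda_max),
      warning = function(w) NULL)
  }
  aic <- c(additive = -2 * add$loglik_ml + 2 * (add$p + 2))
  h2_add <- eqtl_heritability(free, add)$h2_qtl
  h2_int <- NA_real_
  if (!is.null(inter)) {
    aic <- c(aic, interaction = -2 * inter$loglik_ml + 2 * (inter$p + 2))
    h2_int <- eqtl_heritability(free, inter)$h2_qtl
  }
  preferred <- if (length(aic) == 2 && aic["interaction"] < aic["additive"])
    "interaction" else "additive"
  structure(list(additive = add, interaction = inter, free = free,
                 aic = aic, preferred = preferred,
                 h2_qtl_additive = h2_add, h2_qtl_interaction = h2_int,
                 delta_explained = if (is.na(h2_int)) NA_real_
                                   else h2_int - h2_add),
            class = "epistasis_fit")
}

#' Mixed-model diagnostics: fixed predictions versus random + residual
#'
#' After a fit, computes the BLUP of the polygenic values, forms the
#' fixed-effect predictions `x_i' beta` and the combined random-plus-residual
#' estimates `y - x_i' beta`, and tests for linear correlation between the
#' two.  In a well-specified model the correlation should be negligible; a
#' significant correlation indicates fixed effects missing from the model.
#'
#' @param vc a [reml_fit()] result (with its stored data).
#' @return List of class `vc_diagnostics`: `correlation`, `p_value`, `blup`
#'   (per-individual polygenic predictions), `flag` (`"significant"` when
#'   P < 0.05, `"undefined"` when the response or predictions are constant).
#' @export
model_diagnostics <- function(vc) {
  stopifnot(inherits(vc, "heritex_vc"))
  prep <- vc$prep
  fixed_i <- as.vector(prep$X %*% vc$beta)
  ebar <- prep$ybar - fixed_i
  w <- 1 / (vc$lambda * prep$d + 1)
  # BLUP: u_hat = lambda * K Z' H^{-1} (y - X beta), in the eigenbasis of K
  u_hat <- as.vector(prep$V %*% ((vc$lambda * prep$d * w) *
                                 crossprod(prep$V, ebar)))
  names(u_hat) <- prep$ids
  fixed_obs <- fixed_i[prep$idx]
  randresid <- prep$ybar[prep$idx] - fixed_obs  # individual-level signal
  if (sd(fixed_obs) < 1e-12 || sd(randresid) < 1e-12) {
    return(structure(list(correlation = NA_real_, p_value = NA_real_,
                          blup = u_hat, flag = "undefined"),
                     class = "vc_diagnostics"))
  }
  ct <- cor.test(fixed_i, ebar)
  structure(list(correlation = unname(ct$estimate), p_value = ct$p.value,
                 blup = u_hat,
                 flag = if (ct$p.value < 0.05) "significant" else "ok"),
            class = "vc_diagnostics")
}
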