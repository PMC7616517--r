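# Satterthwaite denominator degrees of freedom for lme4 fits.
#
# The approach is the classical one for REML mixed models: treat the
# variance parameters eta = (theta, sigma) as asymptotically normal with
# covariance A = 2 * H^-1, where H is the Hessian of the REML criterion in
# eta. For a contrast L of the fixed effects with variance f(eta) =
# L' C(eta) L, the Satterthwaite df are 2 f^2 / (g' A g) with g = df/deta.
# Multi-df F tests diagonalize L C L' and pool the per-component dfs.

# Rebuild the lmer deviance function (profiled over beta and sigma) from a
# fitted model. The model frame carries the factor contrasts, so the refit
# reproduces the original parameterization exactly.
devfun_from_fit <- function(model) {
  lme4::lmer(stats::formula(model), data = stats::model.frame(model),
             REML = lme4::isREML(model), devFunOnly = TRUE,
             control = lme4::lmerControl(calc.derivs = FALSE,
                                         check.rankX = "stop.deficient"))
}

# REML/ML criterion as a function of the *unprofiled* variance parameters
# eta = c(theta, sigma); used to get the curvature in sigma as well.
devfun_varpar <- function(varpar, devfun, reml) {
  nvp <- length(varpar)
  sigma2 <- varpar[nvp]^2
  theta <- varpar[-nvp]
  env <- environment(devfun)
  devfun(theta) # updates the penalized least squares structures in env
  n <- length(env$resp$y)
  p <- ncol(env$pp$X)
  dev <- env$pp$ldL2() + (env$resp$wrss() + env$pp$sqrL(1)) / sigma2 +
    (n - if (reml) p else 0) * log(2 * pi * sigma2)
  if (!reml) return(dev)
  dev + 2 * c(determinant(env$pp$RX())$modulus)
}

# vcov of the fixed effects at given variance parameters
covbeta_varpar <- function(varpar, devfun) {
  nvp <- length(varpar)
  sigma <- varpar[nvp]
  devfun(varpar[-nvp])
  env <- environment(devfun)
  sigma^2 * tcrossprod(as.matrix(env$pp$RXi()))
}

#' Satterthwaite preparation for a fitted mixed model
#'
#' Computes, once per model, everything the Satterthwaite approximation
#' needs: the asymptotic covariance `A` of the variance parameters
#' (2 x inverse Hessian of the REML/ML criterion) and the gradient of
#' `vcov(beta)` with respect to each variance parameter.
#'
#' @param model an `lmerMod` fit.
#' @return a list with `beta`, `vcov_beta`, `A`, `grad_vcov` (list of
#'   matrices), `sigma` and `varpar`.
#' @keywords internal
satterthwaite_prep <- function(model) {
  stopifnot(inherits(model, "lmerMod"))
  reml <- lme4::isREML(model)
  devfun <- devfun_from_fit(model)
  varpar <- c(lme4::getME(model, "theta"), stats::sigma(model))

  h <- numDeriv::hessian(devfun_varpar, varpar, devfun = devfun, reml = reml)
  A <- tryCatch(2 * solve(h), error = function(e) {
    warning("Hessian of the REML criterion is computationally singular; ",
            "using a pseudo-inverse (degrees of freedom may be unreliable)",
            call. = FALSE)
    sv <- svd(h)
    pos <- sv$d > max(sv$d) * 1e-10
    2 * sv$v[, pos, drop = FALSE] %*%
      (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  })
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    warning("covariance of variance parameters is not positive definite; ",
            "Satterthwaite df may be unreliable", call. = FALSE)

  jac <- numDeriv::jacobian(function(vp) as.vector(covbeta_varpar(vp, devfun)),
                            varpar)
  p <- length(lme4::fixef(model))
  grad_vcov <- lapply(seq_along(varpar), function(i) {
    matrix(jac[, i], nrow = p, ncol = p)
  })
  # restore the deviance-function environment to the fitted optimum
  devfun(varpar[-length(varpar)])

  list(beta = lme4::fixef(model),
       vcov_beta = as.matrix(stats::vcov(model)),
       A = A, grad_vcov = grad_vcov,
       sigma = stats::sigma(model), varpar = varpar)
}

# Satterthwaite df for a single contrast vector L
satterthwaite_df_1d <- function(prep, L) {
  f <- drop(t(L) %*% prep$vcov_beta %*% L)
  g <- vapply(prep$grad_vcov, function(J) drop(t(L) %*% J %*% L), numeric(1L))
  denom <- drop(t(g) %*% prep$A %*% g)
  if (denom <= 0) return(Inf)
  2 * f^2 / denom
}

#' t test of a single fixed-effect contrast with Satterthwaite df
#'
#' @param prep output of [satterthwaite_prep()].
#' @param L numeric contrast vector over the fixed effects.
#' @return one-row data.frame: estimate, SE, df, t, p.
#' @keywords internal
contest_1d <- function(prep, L) {
  est <- drop(crossprod(L, prep$beta))
  se <- sqrt(drop(t(L) %*% prep$vcov_beta %*% L))
  df <- satterthwaite_df_1d(prep, L)
  tval <- est / se
  data.frame(estimate = est, se = se, df = df, t = tval,
             p = 2 * stats::pt(abs(tval), df, lower.tail = FALSE))
}

#' F test of a multi-row contrast with pooled Satterthwaite df
#'
#' Diagonalizes `L vcov(beta) L'`, forms the sum of squared independent
#' t statistics, computes a Satterthwaite df for each component, and pools
#' them into a single denominator df matching the expected value of the F
#' distribution.
#'
#' @param prep output of [satterthwaite_prep()].
#' @param L contrast matrix (rows are contrasts) over the fixed effects.
#' @return one-row data.frame: F, ndf, ddf, p.
#' @keywords internal
contest_md <- function(prep, L) {
  if (is.vector(L)) L <- matrix(L, nrow = 1L)
  VLb <- L %*% prep$vcov_beta %*% t(L)
  eig <- eigen(VLb, symmetric = TRUE)
  tol <- max(eig$values) * 1e-8
  pos <- eig$values > tol
  q <- sum(pos)
  if (q < 1L) stop("contrast matrix has rank 0", call. = FALSE)
  PtL <- crossprod(eig$vectors[, pos, drop = FALSE], L)
  d <- eig$values[pos]
  t2 <- drop(PtL %*% prep$beta)^2 / d
  Fval <- sum(t2) / q

  nu <- vapply(seq_len(q), function(m) {
    Lm <- PtL[m, ]
    g <- vapply(prep$grad_vcov, function(J) drop(t(Lm) %*% J %*% Lm),
                numeric(1L))
    denom <- drop(t(g) %*% prep$A %*% g)
    if (denom <= 0) Inf else 2 * d[m]^2 / denom
  }, numeric(1L))

  ok <- nu > 2
  if (!any(ok)) {
    ddf <- Inf
  } else {
    E <- sum(nu[ok] / (nu[ok] - 2))
    ddf <- if (E > q) 2 * E / (E - q) else Inf
  }
  data.frame(F = Fval, ndf = q, ddf = ddf,
             p = stats::pf(Fval, q, ddf, lower.tail = FALSE))
}
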