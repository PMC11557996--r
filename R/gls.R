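# Phylogenetic GLS with maximum-likelihood Pagel's lambda.
#
# Estimation is by full ML (not REML) throughout, because AICc comparisons
# across models with different fixed effects are only valid under ML. The
# ML residual rate sigma2 = r' V^-1 r / n is reported as the rate of
# residual variance accumulation per unit branch-length time; coefficient
# standard errors use the unbiased rescaling n / (n - k), and coefficient
# p-values use Student's t with n - k degrees of freedom.

DEGEN_TOL <- 1e-20

new_fit_result <- function(model, coef_tab, lambda, lambda_estimated, sigma2,
                           loglik, n, vcov, correlation, taxa,
                           degenerate = FALSE) {
  k <- nrow(coef_tab)
  # AICc parameter count: regression coefficients + sigma2 (+ lambda when
  # it was estimated). Recorded in the result so reports are explicit about
  # the convention used.
  k_aicc <- k + 1L + as.integer(lambda_estimated)
  fit <- structure(list(
    model = model,
    coefficients = coef_tab,
    lambda = lambda,
    lambda_estimated = lambda_estimated,
    sigma2 = sigma2,
    loglik = loglik,
    n = n,
    k = k,
    k_aicc = k_aicc,
    aicc = if (is.finite(loglik) && n - k_aicc - 1 > 0)
      aicc(loglik, k_aicc, n) else NA_real_,
    r2 = NA_real_,
    vcov = vcov,
    correlation = correlation,
    taxa = taxa,
    degenerate = degenerate
  ), class = "pgls_fit")
  fit
}

coef_table <- function(beta, se, df, terms) {
  tval <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, Inf))
  pval <- 2 * pt(-abs(tval), df = df)
  data.frame(term = terms, estimate = beta, se = se, t = tval, p = pval,
             row.names = NULL, stringsAsFactors = FALSE)
}

check_xyC <- function(y, X, C) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X)))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(ncol(X) - 1)))[seq_len(ncol(X))]
  n <- length(y)
  if (nrow(X) != n) stop("rows of X do not match length of y", call. = FALSE)
  if (nrow(C) != n || ncol(C) != n)
    stop("covariance dimension does not match data", call. = FALSE)
  if (n <= ncol(X)) stop("need n > number of coefficients", call. = FALSE)
  if (anyNA(y) || anyNA(X)) stop("missing values in y or X", call. = FALSE)
  if (qr(X)$rank < ncol(X)) stop("singular design matrix", call. = FALSE)
  list(y = y, X = X, n = n, k = ncol(X))
}

# exact-fit detection: OLS residual mean square negligible relative to scale
is_degenerate_fit <- function(y, X) {
  b <- stats::lm.fit(X, y)
  mean(b$residuals^2) <= DEGEN_TOL * (mean(y^2) + 1)
}

degenerate_result <- function(y, X, C, model, correlation, lambda_estimated) {
  b <- stats::lm.fit(X, y)
  coefs <- coef_table(b$coefficients, rep(0, ncol(X)), length(y) - ncol(X),
                      colnames(X))
  warning("zero-residual fit: coefficients are exact, sigma2 = 0, ",
          "lambda reported at the lower bound", call. = FALSE)
  new_fit_result(model, coefs, lambda = 0, lambda_estimated = lambda_estimated,
                 sigma2 = 0, loglik = Inf, n = length(y),
                 vcov = matrix(0, ncol(X), ncol(X)), correlation = correlation,
                 taxa = rownames(C), degenerate = TRUE)
}

#' GLS fit under a lambda-scaled phylogenetic covariance, lambda held fixed
#'
#' Fits `y = X beta + e` with `e ~ N(0, sigma2 * V)` where
#' `V = lambda_transform(C, lambda)`, by maximum likelihood. `lambda = 0`
#' with a star-shaped (or any) covariance reduces to ordinary least squares;
#' `lambda = 1` is the full Brownian-motion structure.
#'
#' @param y numeric response vector, aligned to the taxa of `C`.
#' @param X design matrix (include the intercept column explicitly).
#' @param C phylogenetic covariance, e.g. from [vcv_matrix()].
#' @param lambda fixed Pagel's lambda in `[0, 1]`.
#' @param model optional label stored with the fit.
#' @param correlation label stored with the fit (`"independent"` marks an
#'   OLS fit for reporting purposes).
#' @return an object of class `"pgls_fit"`: coefficient table (estimate, SE,
#'   t, p), `lambda`, ML `sigma2`, `loglik`, `n`, `k`, `aicc` (parameter
#'   count = coefficients + sigma2), and the coefficient covariance `vcov`.
#' @export
gls_fit_fixed <- function(y, X, C, lambda, model = NULL,
                          correlation = "phylogenetic-lambda") {
  d <- check_xyC(y, X, C)
  if (length(lambda) != 1L || is.na(lambda) || lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]", call. = FALSE)
  model <- model %||% deparse(substitute(y))
  if (is_degenerate_fit(d$y, d$X))
    return(degenerate_result(d$y, d$X, C, model, correlation,
                             lambda_estimated = FALSE))
  res <- cpp_pgls_ml(d$y, d$X, unclass(C), grid = lambda, refine = FALSE,
                     tol = 1e-8)
  finish_fit(res, d, C, model, correlation, lambda_estimated = FALSE)
}

#' Phylogenetic GLS with jointly estimated Pagel's lambda
#'
#' Profiles the log-likelihood over lambda on a grid in `[0, 1]` followed by
#' a bounded golden-section refinement between the winning grid point's
#' neighbours; ties are broken toward the smaller lambda. The returned fit
#' maximises the likelihood jointly over the regression coefficients,
#' `sigma2` and `lambda`.
#'
#' @inheritParams gls_fit_fixed
#' @param grid lambda values to profile over (default `seq(0, 1, 0.01)`).
#' @param refine refine between grid neighbours of the winner (default TRUE).
#' @return an object of class `"pgls_fit"`; its AICc parameter count is the
#'   number of coefficients + 2 (sigma2 and lambda).
#' @export
fit_pgls <- function(y, X, C, grid = seq(0, 1, by = 0.01), refine = TRUE,
                     model = NULL, correlation = "phylogenetic-lambda") {
  d <- check_xyC(y, X, C)
  model <- model %||% deparse(substitute(y))
  if (is_degenerate_fit(d$y, d$X))
    return(degenerate_result(d$y, d$X, C, model, correlation,
                             lambda_estimated = TRUE))
  res <- cpp_pgls_ml(d$y, d$X, unclass(C), grid = as.numeric(grid),
                     refine = refine, tol = 1e-8)
  finish_fit(res, d, C, model, correlation, lambda_estimated = TRUE)
}

finish_fit <- function(res, d, C, model, correlation, lambda_estimated) {
  n <- d$n; k <- d$k
  # unbiased variance rescaling n / (n - k) for the reported SEs
  vcov <- res$cov_unscaled * res$sigma2 * n / (n - k)
  dimnames(vcov) <- list(colnames(d$X), colnames(d$X))
  coefs <- coef_table(drop(res$beta), sqrt(pmax(diag(vcov), 0)), n - k,
                      colnames(d$X))
  new_fit_result(model, coefs, lambda = res$lambda,
                 lambda_estimated = lambda_estimated, sigma2 = res$sigma2,
                 loglik = res$loglik, n = n, vcov = vcov,
                 correlation = correlation, taxa = rownames(C),
                 degenerate = isTRUE(res$degenerate))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Small-sample Akaike information criterion
#'
#' `AICc = -2 lnL + 2k + 2k(k+1)/(n - k - 1)`, where `k` counts *all*
#' estimated parameters (regression coefficients plus sigma2, plus lambda
#' when it was estimated).
#'
#' @param loglik maximised log-likelihood.
#' @param k total parameter count.
#' @param n sample size; requires `n - k - 1 > 0`.
#' @return the AICc value.
#' @export
aicc <- function(loglik, k, n) {
  if (n - k - 1 <= 0) stop("AICc undefined: n - k - 1 <= 0", call. = FALSE)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from a set of AICc values
#'
#' @param aiccs numeric vector (length >= 2) of finite AICc values.
#' @return weights summing to 1: `w_i = exp(-delta_i / 2) / sum(...)` with
#'   `delta_i = AICc_i - min(AICc)`.
#' @export
aicc_weights <- function(aiccs) {
  aiccs <- as.numeric(aiccs)
  if (length(aiccs) < 2) stop("need at least 2 AICc values", call. = FALSE)
  if (any(!is.finite(aiccs))) stop("non-finite AICc values", call. = FALSE)
  d <- aiccs - min(aiccs)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Likelihood-based coefficient of determination
#'
#' `R2 = 1 - exp(-(2/n) (lnL_fit - lnL_null))` against an intercept-only
#' null model fitted on the same taxa (with its own estimated lambda),
#' clipped to `[0, 1)`. No Nagelkerke maximum rescaling is applied.
#'
#' @param fit a `"pgls_fit"` for the model of interest.
#' @param null_fit a `"pgls_fit"` for the intercept-only model on the same
#'   data.
#' @param n sample size (defaults to `fit$n`).
#' @return the likelihood R-squared.
#' @export
likelihood_r2 <- function(fit, null_fit, n = fit$n) {
  if (fit$n != null_fit$n)
    stop("fits have different sample sizes", call. = FALSE)
  if (!is.null(fit$taxa) && !is.null(null_fit$taxa) &&
      !identical(fit$taxa, null_fit$taxa))
    stop("fits are not on the same taxa", call. = FALSE)
  if (is.infinite(fit$loglik)) return(1 - 1e-12)
  r2 <- 1 - exp(-(2 / n) * (fit$loglik - null_fit$loglik))
  min(max(r2, 0), 1 - 1e-12)
}

#' t-test for a difference between two fitted slopes
#'
#' Compares the same regression term across two fits of the same data (the
#' canonical use being the purely allometric OLS vs. PGLS fits):
#' `t = (b_a - b_b) / sqrt(SE_a^2 + SE_b^2)` with `df = n - k - 1`.
#'
#' @param fit_a,fit_b `"pgls_fit"` objects sharing the term and sample size.
#' @param term name of the coefficient to compare.
#' @return list with `t`, `df` and two-sided `p`.
#' @export
slope_difference_test <- function(fit_a, fit_b, term) {
  ca <- fit_a$coefficients; cb <- fit_b$coefficients
  if (!(term %in% ca$term) || !(term %in% cb$term))
    stop("term not present in both fits: ", term, call. = FALSE)
  if (fit_a$n != fit_b$n)
    stop("fits have different sample sizes", call. = FALSE)
  a <- ca[ca$term == term, ]; b <- cb[cb$term == term, ]
  df <- fit_a$n - fit_a$k - 1
  if (df <= 0) stop("non-positive degrees of freedom", call. = FALSE)
  se <- sqrt(a$se^2 + b$se^2)
  tval <- if (se > 0) (a$estimate - b$estimate) / se else 0
  list(t = tval, df = df, p = 2 * pt(-abs(tval), df = df))
}

#' Univariate Brownian-motion rate with measurement error
#'
#' Maximum-likelihood estimate of the rate of variance accumulation
#' (sigma-squared) of a single trait evolving by Brownian motion on the
#' phylogeny, with optional relative measurement error: the likelihood uses
#' covariance `sigma2 * C + diag((me_fraction * x)^2)`. With
#' `me_fraction = 0` the closed-form ML estimator is returned.
#'
#' @param x trait vector aligned to the taxa of `C` (length >= 3).
#' @param C phylogenetic covariance from [vcv_matrix()] (raw, lambda = 1).
#' @param me_fraction relative measurement error per observation (e.g. 0.01
#'   for 1 percent of the trait value); must be >= 0.
#' @return list of class `"bm_rate"`: `sigma2`, `mu` (root state),
#'   `me_fraction`, `loglik`.
#' @export
univariate_bm_rate <- function(x, C, me_fraction = 0) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3) stop("need at least 3 taxa", call. = FALSE)
  if (nrow(C) != n) stop("covariance dimension does not match x", call. = FALSE)
  if (me_fraction < 0) stop("me_fraction must be >= 0", call. = FALSE)
  C <- unclass(C)
  ones <- rep(1, n)

  closed <- local({
    Ci <- solve(C)
    mu <- drop(ones %*% Ci %*% x) / drop(ones %*% Ci %*% ones)
    r <- x - mu
    s2 <- drop(r %*% Ci %*% r) / n
    list(mu = mu, s2 = s2)
  })

  loglik_at <- function(s2) {
    Sigma <- s2 * C + diag((me_fraction * x)^2, n)
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) return(list(ll = -Inf, mu = NA_real_))
    logdet <- 2 * sum(log(diag(ch)))
    Si_x <- backsolve(ch, forwardsolve(t(ch), x))
    Si_1 <- backsolve(ch, forwardsolve(t(ch), ones))
    mu <- drop(crossprod(ones, Si_x)) / drop(crossprod(ones, Si_1))
    r <- x - mu
    Si_r <- backsolve(ch, forwardsolve(t(ch), r))
    ll <- -0.5 * (n * log(2 * pi) + logdet + drop(crossprod(r, Si_r)))
    list(ll = ll, mu = mu)
  }

  if (me_fraction == 0) {
    if (closed$s2 <= DEGEN_TOL * (mean(x^2) + 1))
      return(structure(list(sigma2 = 0, mu = closed$mu, me_fraction = 0,
                            loglik = Inf, degenerate = TRUE),
                       class = "bm_rate"))
    ll <- loglik_at(closed$s2)
    return(structure(list(sigma2 = closed$s2, mu = closed$mu, me_fraction = 0,
                          loglik = ll$ll, degenerate = FALSE),
                     class = "bm_rate"))
  }

  s0 <- max(closed$s2, 1e-12)
  opt <- optimize(function(ls) loglik_at(exp(ls))$ll,
                  interval = log(s0) + c(-12, 6), maximum = TRUE,
                  tol = 1e-10)
  # trait can be pure measurement error: check the sigma2 -> 0 boundary
  ll0 <- loglik_at(0)
  if (ll0$ll > opt$objective)
    return(structure(list(sigma2 = 0, mu = ll0$mu, me_fraction = me_fraction,
                          loglik = ll0$ll, degenerate = FALSE),
                     class = "bm_rate"))
  at <- loglik_at(exp(opt$maximum))
  structure(list(sigma2 = exp(opt$maximum), mu = at$mu,
                 me_fraction = me_fraction, loglik = opt$objective,
                 degenerate = FALSE),
            class = "bm_rate")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf("PGLS fit: %s  [%s]\n", x$model, x$correlation))
  cat(sprintf("  n = %d, lambda = %.4g%s, sigma2 = %.4g\n", x$n, x$lambda,
              if (x$lambda_estimated) " (ML)" else " (fixed)", x$sigma2))
  cat(sprintf("  logLik = %.4f, AICc = %.4f (k = %d)",
              x$loglik, x$aicc, x$k_aicc))
  if (is.finite(x$r2)) cat(sprintf(", R2 = %.3f", x$r2))
  cat("\n")
  tab <- x$coefficients
  tab$estimate <- signif(tab$estimate, 4)
  tab$se <- signif(tab$se, 3)
  tab$t <- signif(tab$t, 4)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  if (x$degenerate) cat("  (degenerate zero-residual fit)\n")
  invisible(x)
}

#' @export
print.bm_rate <- function(x, ...) {
  cat(sprintf("BM rate: sigma2 = %.4g (me = %g%%), mu = %.4g, logLik = %.4f\n",
              x$sigma2, 100 * x$me_fraction, x$mu, x$loglik))
  invisible(x)
}
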