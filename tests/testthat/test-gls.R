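make_star_C <- function(n, height = 1) {
  diag(height, n)
}

test_that("fixed-lambda GLS reproduces exact and hand-computed OLS", {
  C <- make_star_C(3)
  # exact line: zero residuals -> degenerate fit with exact coefficients
  expect_warning(
    f <- gls_fit_fixed(c(1, 2, 3), cbind(1, 0:2), C, lambda = 0),
    "zero-residual")
  expect_equal(f$coefficients$estimate, c(1, 1), tolerance = 1e-12)
  expect_equal(f$sigma2, 0)
  expect_equal(f$lambda, 0)
  expect_true(f$degenerate)

  f2 <- gls_fit_fixed(c(1, 2, 2), cbind(1, 0:2), C, lambda = 0)
  expect_equal(f2$coefficients$estimate, c(7 / 6, 0.5), tolerance = 1e-12)
})

test_that("GLS with lambda = 1 matches the dense-algebra oracle", {
  set.seed(21)
  tr <- ape::rtree(6)
  C <- vcv_matrix(tr, order = tr$tip.label)
  x <- rnorm(6)
  y <- 1 + 0.5 * x + rnorm(6, sd = 0.3)
  X <- cbind(`(Intercept)` = 1, x = x)
  f <- gls_fit_fixed(y, X, C, lambda = 1)
  o <- dense_gls(y, X, unclass(C), 1)
  expect_equal(f$coefficients$estimate, unname(o$beta), tolerance = 1e-10)
  expect_equal(f$sigma2, o$sigma2, tolerance = 1e-10)
  expect_equal(f$loglik, o$loglik, tolerance = 1e-8)
})

test_that("the independence model reproduces textbook OLS on any tree", {
  set.seed(31)
  for (rep in 1:5) {
    n <- 40
    tr <- ape::rtree(n)  # non-ultrametric, fossil-like tip depths
    d <- data.frame(species = tr$tip.label, x = rnorm(n))
    d$y <- 0.3 + 0.9 * d$x + rnorm(n, sd = 0.4)
    f <- pgls(y ~ x, d, tr, method = "ols")
    lmf <- stats::lm(y ~ x, d)
    expect_equal(f$coefficients$estimate, unname(coef(lmf)),
                 tolerance = 1e-10)
    expect_equal(f$sigma2, mean(residuals(lmf)^2), tolerance = 1e-10)
    expect_equal(f$correlation, "independent")
    # reported SEs use the unbiased n/(n-k) rescaling, so they match lm
    expect_equal(f$coefficients$se,
                 unname(sqrt(diag(vcov(lmf)))), tolerance = 1e-8)
  }
})

test_that("profiled lambda attains the grid maximum and beats endpoints", {
  cfg <- sim_config(n_tips = 60, lambda_resid = 0.6, seed = 41)
  tree <- simulate_tree(cfg)
  d <- simulate_allometric_dataset(tree, cfg)
  C <- vcv_matrix(tree, order = d$species)
  X <- cbind(1, d$log10_fl)
  f <- fit_pgls(d$log10_scl, X, C)
  for (l in seq(0, 1, 0.1)) {
    fl <- gls_fit_fixed(d$log10_scl, X, C, lambda = l)
    expect_gte(f$loglik, fl$loglik - 1e-6)
  }
})

test_that("lambda estimation recovers independent and Brownian residuals", {
  base <- sim_config(n_tips = 200, seed = 1)
  tree <- simulate_tree(base)
  hits0 <- hits1 <- 0L
  reps <- 40
  for (i in seq_len(reps)) {
    d0 <- simulate_allometric_dataset(
      tree, sim_config(n_tips = 200, lambda_resid = 0, seed = 100 + i))
    f0 <- pgls(log10_scl ~ log10_fl, d0, tree)
    hits0 <- hits0 + (f0$lambda < 0.2)
    d1 <- simulate_allometric_dataset(
      tree, sim_config(n_tips = 200, lambda_resid = 1, seed = 200 + i))
    f1 <- pgls(log10_scl ~ log10_fl, d1, tree)
    hits1 <- hits1 + (f1$lambda > 0.8)
  }
  expect_gte(hits0, ceiling(0.9 * reps))
  expect_gte(hits1, ceiling(0.9 * reps))
})

test_that("joint ML estimation agrees with an independent GLS implementation", {
  cfg <- sim_config(n_tips = 80, seed = 11)
  tree <- simulate_tree(cfg)
  d <- simulate_allometric_dataset(tree, cfg)
  f <- pgls(log10_scl ~ log10_fl, d, tree)
  rownames(d) <- d$species
  gf <- nlme::gls(log10_scl ~ log10_fl, data = d,
                  correlation = ape::corPagel(0.5, tree, form = ~species),
                  method = "ML")
  expect_equal(f$coefficients$estimate, unname(coef(gf)), tolerance = 1e-4)
  expect_equal(f$lambda,
               unname(coef(gf$modelStruct$corStruct, unconstrained = FALSE)),
               tolerance = 1e-3)
  expect_equal(f$loglik, as.numeric(logLik(gf)), tolerance = 1e-4)
})

test_that("exactly collinear data yield exact coefficients and a warning", {
  tr <- ape::rtree(10)
  C <- vcv_matrix(tr, order = tr$tip.label)
  x <- seq(1, 2, length.out = 10)
  expect_warning(f <- fit_pgls(2 + 3 * x, cbind(1, x), C), "zero-residual")
  expect_equal(f$coefficients$estimate, c(2, 3), tolerance = 1e-10)
  expect_equal(f$lambda, 0)
  expect_true(f$degenerate)
})

test_that("AICc matches its closed form and the AIC correction identity", {
  expect_equal(aicc(0, 2, 10), 4 + 12 / 7, tolerance = 1e-12)
  expect_equal(aicc(-10, 2, 100), 24 + 12 / 97, tolerance = 1e-12)
  expect_error(aicc(0, 3, 4), "n - k - 1")
  for (k in 2:4) {
    n <- 30
    expect_equal(aicc(-5, k, n) - (-2 * -5 + 2 * k),
                 2 * k * (k + 1) / (n - k - 1), tolerance = 1e-12)
  }
})

test_that("AICc weights match closed-form values", {
  expect_equal(round(aicc_weights(c(0, 2)), 4), c(0.7311, 0.2689))
  expect_equal(aicc_weights(c(5, 5)), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(round(aicc_weights(c(0, 2, 4)), 4), c(0.6652, 0.2447, 0.0900))
  expect_error(aicc_weights(c(0, Inf)), "non-finite")
  expect_error(aicc_weights(3), "at least 2")
})

test_that("likelihood R2 follows 1 - exp(-2 delta / n)", {
  mk <- function(ll, n) structure(list(loglik = ll, n = n, taxa = NULL),
                                  class = "pgls_fit")
  expect_equal(likelihood_r2(mk(-4, 10), mk(-4, 10)), 0)
  expect_equal(likelihood_r2(mk(1, 10), mk(-4, 10)), 1 - exp(-1),
               tolerance = 1e-12)
  expect_error(likelihood_r2(mk(1, 10), mk(0, 12)), "sample sizes")
  # strong-signal limit: near-zero residual variance drives R2 toward 1
  cfg <- sim_config(n_tips = 50, sigma2_resid = 1e-12, covariate_effect = 0,
                    seed = 51)
  tree <- simulate_tree(cfg)
  d <- simulate_allometric_dataset(tree, cfg)
  f <- pgls(log10_scl ~ log10_fl, d, tree)
  f0 <- pgls(log10_scl ~ 1, d, tree)
  expect_gt(likelihood_r2(f, f0), 0.999)
})

test_that("slope difference test matches its closed form", {
  fa <- fake_fit(c("(Intercept)", "x"), c(0, 0.9), c(0.1, 0.02),
                 c(1, 0), n = 201)
  fb <- fake_fit(c("(Intercept)", "x"), c(0, 1.0), c(0.1, 0.02),
                 c(1, 0), n = 201)
  res <- slope_difference_test(fa, fb, "x")
  expect_equal(res$df, 198)
  expect_equal(res$t, -0.1 / sqrt(2 * 0.02^2), tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(res$t), 198), tolerance = 1e-12)

  same <- slope_difference_test(fa, fa, "x")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(slope_difference_test(fa, fb, "z"), "not present")
})

test_that("BM rate: closed form on a star tree and constants", {
  C <- make_star_C(3)
  r <- univariate_bm_rate(c(1, 2, 3), C, me_fraction = 0)
  expect_equal(r$mu, 2)
  expect_equal(r$sigma2, 2 / 3, tolerance = 1e-12)

  rc <- univariate_bm_rate(c(5, 5, 5, 5), make_star_C(4), me_fraction = 0)
  expect_equal(rc$sigma2, 0)
  expect_error(univariate_bm_rate(c(1, 2, 3), C, me_fraction = -1), ">= 0")
  expect_error(univariate_bm_rate(c(1, 2), diag(2)), "at least 3")
})

test_that("BM rate with measurement error matches a 2-D grid-search oracle", {
  set.seed(61)
  tr <- ape::rtree(20)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  C <- unclass(vcv_matrix(tr, order = tr$tip.label))
  x <- drop(MASS::mvrnorm(1, rep(2, 20), 0.5 * C))
  est <- univariate_bm_rate(x, C, me_fraction = 0.01)

  dense_ll <- function(mu, s2) {
    Sigma <- s2 * C + diag((0.01 * x)^2)
    r <- x - mu
    -0.5 * (20 * log(2 * pi) +
              as.numeric(determinant(Sigma, logarithm = TRUE)$modulus) +
              drop(r %*% solve(Sigma) %*% r))
  }
  mus <- seq(min(x), max(x), length.out = 41)
  s2s <- exp(seq(log(est$sigma2 / 5), log(est$sigma2 * 5), length.out = 41))
  best <- c(NA, NA, -Inf)
  for (m in mus) for (s in s2s) {
    ll <- dense_ll(m, s)
    if (ll > best[3]) best <- c(m, s, ll)
  }
  # refine the grid once around the winner
  mus <- seq(best[1] - 0.1, best[1] + 0.1, length.out = 41)
  s2s <- seq(best[2] * 0.8, best[2] * 1.25, length.out = 81)
  for (m in mus) for (s in s2s) {
    ll <- dense_ll(m, s)
    if (ll > best[3]) best <- c(m, s, ll)
  }
  expect_lt(abs(est$sigma2 - best[2]), 1e-4)
  expect_gte(est$loglik, best[3] - 1e-6)
})
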