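# REML variance components, LRTs, heritability partition, scale conversion.

# independent restricted-likelihood oracle via error contrasts:
# ll = log N(A'y; 0, A'VA) for A spanning the null space of X'
remlOracle <- function(y, X, V) {
  X <- cbind(rep(1, length(y)), X)
  n <- length(y); p <- ncol(X)
  A <- qr.Q(qr(X), complete = TRUE)[, -(1:p), drop = FALSE]
  S <- t(A) %*% V %*% A
  z <- drop(t(A) %*% y)
  as.numeric(-0.5 * ((n - p) * log(2 * pi) + determinant(S)$modulus +
                       drop(z %*% solve(S, z))))
}

makeK <- function(n, seed = 1) {
  set.seed(seed)
  B <- matrix(rnorm(n * n), n)
  K <- tcrossprod(B) / n
  K <- K / mean(diag(K))
  dimnames(K) <- list(paste0("s", 1:n), paste0("s", 1:n))
  K
}

test_that("proportional components raise a collinearity error", {
  n <- 20
  I <- diag(n); dimnames(I) <- list(paste0("s", 1:n), paste0("s", 1:n))
  y <- rnorm(n)
  expect_error(fitVC(y, NULL, components = list(g = I, m = I)), "collinear")
})

test_that("single-component REML matches a brute-force grid search", {
  n <- 40
  K <- makeK(n, seed = 2)
  set.seed(3)
  g <- drop(chol(K + 1e-8 * diag(n)) %*% rnorm(n)) * sqrt(0.6)
  y <- 0.5 + g + rnorm(n, 0, sqrt(0.4))
  X <- NULL
  fit <- fitVC(y, X, components = list(g = K))
  # 2-d grid on (sigma2_g, sigma2_e), refined to 1e-3, using the
  # error-contrast oracle (independent of the package's REML formula)
  gridBest <- function(gs, es) {
    best <- c(NA, NA, -Inf)
    for (a in gs) for (b in es) {
      ll <- remlOracle(y, X, a * K + b * diag(n))
      if (ll > best[3]) best <- c(a, b, ll)
    }
    best
  }
  coarse <- gridBest(seq(0.01, 2, length.out = 30), seq(0.01, 2, length.out = 30))
  fine <- gridBest(seq(max(coarse[1] - 0.1, 0.001), coarse[1] + 0.1, by = 0.001),
                   seq(max(coarse[2] - 0.1, 0.001), coarse[2] + 0.1, by = 0.001))
  s2 <- varComponents(fit)
  expect_lt(abs(unname(s2["g"]) - fine[1]), 1e-3)  # 3-decimal agreement
  expect_lt(abs(unname(s2["e"]) - fine[2]), 1e-3)
  # and the fit's restricted log-likelihood agrees with the oracle
  expect_equal(fit@loglikREML,
               remlOracle(y, X, s2["g"] * K + s2["e"] * diag(n)),
               tolerance = 1e-6)
})

test_that("GLS fixed effects equal the weighted-least-squares closed form", {
  n <- 30
  K <- makeK(n, seed = 4)
  set.seed(5)
  X <- cbind(x1 = rnorm(n), x2 = rbinom(n, 1, 0.5))
  y <- drop(cbind(1, X) %*% c(0.3, 0.8, -0.5)) + rnorm(n)
  fit <- suppressWarnings(fitVC(y, X, components = list(g = K)))
  s2 <- varComponents(fit)
  V <- s2["g"] * K + s2["e"] * diag(n)
  Xi <- cbind(1, X)
  beta_wls <- solve(t(Xi) %*% solve(V, Xi), t(Xi) %*% solve(V, y))
  expect_equal(unname(fixedEffects(fit)), unname(drop(beta_wls)),
               tolerance = 1e-6)
})

test_that("REML estimates scale as c^2 when y is rescaled by c", {
  n <- 60
  K <- makeK(n, seed = 6)
  set.seed(7)
  y <- drop(chol(K + 1e-8 * diag(n)) %*% rnorm(n)) + rnorm(n)
  f1 <- suppressWarnings(fitVC(y, NULL, components = list(g = K)))
  f2 <- suppressWarnings(fitVC(3 * y, NULL, components = list(g = K)))
  expect_equal(unname(varComponents(f2)), 9 * unname(varComponents(f1)),
               tolerance = 1e-3)
})

test_that("returned optimum is at least as good as a surrounding 5x5 grid", {
  n <- 50
  K <- makeK(n, seed = 8)
  set.seed(9)
  y <- drop(chol(K + 1e-8 * diag(n)) %*% rnorm(n)) * 0.7 + rnorm(n)
  fit <- fitVC(y, NULL, components = list(g = K))
  s2 <- varComponents(fit)
  lls <- sapply(seq(0.8, 1.2, length.out = 5), function(fg)
    sapply(seq(0.8, 1.2, length.out = 5), function(fe)
      remlOracle(y, NULL, max(s2["g"] * fg, 1e-8) * K +
                   max(s2["e"] * fe, 1e-8) * diag(n))))
  expect_gte(fit@loglikREML + 1e-6, max(lls))
})

test_that("sigma2_m estimates sit at the zero boundary when truth is zero", {
  p <- simParams(n_subjects = 80, sigma2_m = 0, sigma2_e = 0.53)
  hits <- 0
  for (i in 1:50) {
    sim <- suppressMessages(simulateCohort(p, seed = 300 + i, genotypes = FALSE))
    yl <- attr(sim$cohort, "liability")
    fit <- suppressWarnings(
      fitVC(yl, NULL, components = list(g = sim$K, m = sim$M)))
    if (varComponents(fit)["m"] < 1e-4) hits <- hits + 1
  }
  expect_gt(hits, 25)  # majority of 50 replicates
})

test_that("boundary LRT mixture gives the textbook p-values", {
  mkfit <- function(ll, comps, fp) {
    K <- diag(4); dimnames(K) <- list(letters[1:4], letters[1:4])
    new("VCFit", sigma2 = setNames(rep(0.5, length(comps) + 1), c(comps, "e")),
        beta = c("(Intercept)" = 0), betaSE = c("(Intercept)" = 0.1),
        loglikREML = ll, loglikML = ll, converged = TRUE, n = 4L,
        components = setNames(lapply(comps, function(.) K), comps),
        fingerprint = fp)
  }
  full <- mkfit(-10, c("g", "m"), "fp1")
  red <- mkfit(-10, "g", "fp1")
  expect_equal(lrtVarComp(full, red)$p_value, 0.5)   # Lambda = 0
  red2 <- mkfit(-10 - 2.706 / 2, "g", "fp1")
  expect_equal(lrtVarComp(full, red2)$p_value, 0.05, tolerance = 1e-3)
  # clipped at zero when the reduced fit happens to score higher
  red3 <- mkfit(-9, "g", "fp1")
  expect_equal(lrtVarComp(full, red3)$lambda, 0)
  # mismatched data are refused
  red4 <- mkfit(-11, "g", "fp2")
  expect_error(lrtVarComp(full, red4), "fingerprint")
  # reduced model must drop exactly one component
  expect_error(lrtVarComp(full, full), "exactly one")
})

test_that("variance-component LRT holds its size under the null", {
  p <- simParams(n_subjects = 150, sigma2_m = 0, sigma2_e = 0.53)
  reps <- 120
  rej <- 0
  for (i in seq_len(reps)) {
    sim <- suppressMessages(simulateCohort(p, seed = 7000 + i, genotypes = FALSE))
    yl <- attr(sim$cohort, "liability")
    full <- suppressWarnings(
      fitVC(yl, NULL, components = list(g = sim$K, m = sim$M)))
    red <- suppressWarnings(fitVC(yl, NULL, components = list(g = sim$K)))
    if (lrtVarComp(full, red)$p_value < 0.05) rej <- rej + 1
  }
  ci_half <- 1.96 * sqrt(0.05 * 0.95 / reps)
  expect_gt(rej / reps, 0.05 - ci_half - 1e-9)
  expect_lt(rej / reps, 0.05 + ci_half + 1e-9)
})

test_that("heritability partition reproduces the component ratios", {
  K <- diag(4); dimnames(K) <- list(letters[1:4], letters[1:4])
  mk <- function(s2g, s2m, s2e) {
    new("VCFit", sigma2 = c(g = s2g, m = s2m, e = s2e),
        beta = c("(Intercept)" = 0), betaSE = c("(Intercept)" = 0.1),
        loglikREML = -1, loglikML = -1, converged = TRUE, n = 4L,
        components = list(g = K, m = K + diag(4)), fingerprint = "x")
  }
  # the published worked example: 0.08 / (0.08 + 0.47) ~ 15%
  rep1 <- heritabilityPartition(mk(0.47, 0.08, 0.45))
  expect_equal(rep1@mutation_share, 0.08 / (0.08 + 0.47), tolerance = 1e-12)
  expect_equal(round(100 * rep1@mutation_share), 15)
  expect_equal(rep1@h2_g, 0.47, tolerance = 1e-12)  # total is 1 here
  # degenerate and symmetric cases
  expect_equal(heritabilityPartition(mk(0.5, 0, 0.5))@mutation_share, 0)
  expect_equal(heritabilityPartition(mk(0.3, 0.3, 0.4))@mutation_share, 0.5)
  expect_true(is.na(heritabilityPartition(mk(0, 0, 1))@mutation_share))
})

test_that("observed-to-liability conversion matches the closed form", {
  # prevalence 1/2: multiplier 0.25 / phi(0)^2 = pi/2
  expect_equal(observedToLiability(1, 0.5), pi / 2, tolerance = 1e-10)
  expect_equal(observedToLiability(0, 0.3), 0)
  z <- dnorm(qnorm(1 - 0.185))
  expect_equal(observedToLiability(0.30, 0.185),
               0.30 * 0.185 * 0.815 / z^2, tolerance = 1e-12)
  expect_error(observedToLiability(0.5, 1.2), "prevalence")
})

test_that("non-PSD components are rejected", {
  n <- 10
  C <- diag(n); C[1, 2] <- C[2, 1] <- 2  # indefinite
  dimnames(C) <- list(paste0("s", 1:n), paste0("s", 1:n))
  expect_error(fitVC(rnorm(n), NULL, components = list(g = C)),
               "positive semi-definite")
})
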