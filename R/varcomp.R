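# Binary linear mixed model on the observed 0/1 scale:
#   y = X beta + u_g + u_m + e,
#   u_g ~ N(0, sigma2_g K), u_m ~ N(0, sigma2_m M), e ~ N(0, sigma2_e I),
# fitted by REML over the box-constrained variance components with analytic
# gradients and deterministic multi-start, plus boundary-corrected LRTs and
# a liability-scale conversion of the heritability partition.

.fingerprint <- function(y, X) {
  paste(length(y), format(sum(y), digits = 12), format(sum(y^2), digits = 12),
        ncol(X), format(sum(X^2), digits = 12), sep = "|")
}

# value and gradient of the negative restricted (or full ML) log-likelihood
# at theta = (sigma2 for each structured component, sigma2_e last)
.vcNegLL <- function(theta, y, X, Cs, reml = TRUE) {
  n <- length(y)
  p <- ncol(X)
  V <- diag(theta[length(theta)], n)
  for (i in seq_along(Cs)) V <- V + theta[i] * Cs[[i]]
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(list(value = 1e10, grad = rep(0, length(theta))))
  logdetV <- 2 * sum(log(diag(R)))
  Vi <- chol2inv(R)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  XtViX_inv <- tryCatch(solve(XtViX), error = function(e) NULL)
  if (is.null(XtViX_inv)) return(list(value = 1e10, grad = rep(0, length(theta))))
  Viy <- Vi %*% y
  beta <- XtViX_inv %*% crossprod(X, Viy)
  r <- y - X %*% beta
  Pr <- Vi %*% r  # = P y
  quad <- drop(crossprod(y, Pr))
  if (reml) {
    # Harville's error-contrast likelihood (includes the -log|X'X| constant,
    # matching log N(A'y; 0, A'VA) for any orthonormal contrast basis A)
    ld_xvx <- as.numeric(determinant(XtViX, logarithm = TRUE)$modulus)
    ld_xx <- as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)
    value <- 0.5 * ((n - p) * log(2 * pi) - ld_xx + logdetV + ld_xvx + quad)
    P <- Vi - ViX %*% XtViX_inv %*% t(ViX)
  } else {
    value <- 0.5 * (n * log(2 * pi) + logdetV + quad)
    P <- Vi
  }
  grad <- numeric(length(theta))
  for (i in seq_along(Cs)) {
    grad[i] <- 0.5 * (sum(P * Cs[[i]]) - drop(crossprod(Pr, Cs[[i]] %*% Pr)))
  }
  grad[length(theta)] <- 0.5 * (sum(diag(P)) - drop(crossprod(Pr)))
  list(value = as.numeric(value), grad = grad,
       beta = drop(beta), betaSE = sqrt(diag(XtViX_inv)))
}

.checkComponent <- function(C, nm) {
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), 1)
  if (min(ev) < -1e-6 * scale)
    stop("component '", nm, "' is not positive semi-definite (min eigenvalue ",
         format(min(ev), digits = 4), ")")
  invisible(TRUE)
}

#' Fit the variance-component mixed model by REML
#'
#' Estimates the variance components of V = sum_c sigma2_c C_c + sigma2_e I
#' by bounded quasi-Newton (L-BFGS-B) maximization of the restricted
#' likelihood, with four deterministic restarts from spread variance splits;
#' fixed effects are obtained by GLS at the optimum. The full ML
#' log-likelihood at the optimum is also recorded. Variance components are
#' box-constrained to be non-negative.
#'
#' @param y numeric response (the binary status, analyzed on the observed
#'   0/1 scale); names, if present, must match component subject ids.
#' @param X covariate matrix (without intercept; one is added), or NULL.
#' @param components named list of [StructuredCovariance-class] objects or
#'   plain symmetric matrices (e.g. `list(g = K, m = M)`).
#' @param method "REML" (default) or "ML".
#' @param restarts number of deterministic restarts (default 4).
#' @param tol relative convergence tolerance on the log-likelihood.
#' @return A [VCFit-class].
#' @export
fitVC <- function(y, X = NULL, components, method = c("REML", "ML"),
                  restarts = 4, tol = 1e-8) {
  method <- match.arg(method)
  n <- length(y)
  if (is.null(names(components)) || any(names(components) == ""))
    names(components) <- letters[6 + seq_along(components)]
  Cs <- lapply(components, function(C) {
    m <- if (is(C, "StructuredCovariance")) covMatrix(C) else as.matrix(C)
    stopifnot(nrow(m) == n)
    if (!is.null(names(y)) && !is.null(rownames(m))) {
      if (!all(names(y) %in% rownames(m)))
        stop("component subject ids do not cover y")
      m <- m[names(y), names(y)]
    }
    unname(m)
  })
  if (is.null(X)) X <- matrix(numeric(0), n, 0)
  X <- as.matrix(X)
  stopifnot(nrow(X) == n)
  X <- cbind("(Intercept)" = 1, X)
  if (qr(X)$rank < ncol(X)) stop("covariate matrix X is rank deficient")
  for (i in seq_along(Cs)) .checkComponent(Cs[[i]], names(components)[i])
  # collinear components (incl. vs identity) make the split non-identifiable
  vecs <- c(lapply(Cs, as.vector), list(as.vector(diag(n))))
  nm <- c(names(components), "identity")
  for (i in seq_len(length(vecs) - 1)) for (j in seq(i + 1, length(vecs))) {
    cs <- sum(vecs[[i]] * vecs[[j]]) /
      sqrt(sum(vecs[[i]]^2) * sum(vecs[[j]]^2))
    if (cs > 1 - 1e-8)
      stop("collinear components: '", nm[i], "' and '", nm[j],
           "' are proportional; the variance split is not identifiable")
  }
  vy <- var(y)
  if (vy <= 0) stop("y has no variance")
  k <- length(Cs)
  splits <- list(c(rep(1 / (k + 1), k), 1 / (k + 1)),
                 c(rep(0.05, k), 1 - 0.05 * k),
                 c(0.45, rep(0.1, max(k - 1, 0)), 1 - 0.45 - 0.1 * (k - 1)),
                 c(rep(0.3, k), 1 - 0.3 * k))
  splits <- lapply(splits[seq_len(min(max(restarts, 1), 4))],
                   function(s) pmax(s, 0.01) / sum(pmax(s, 0.01)))
  reml <- method == "REML"
  cache <- new.env()
  evalAt <- function(theta) {
    key <- paste(format(theta, digits = 17), collapse = ",")
    if (!identical(cache$key, key)) {
      cache$res <- .vcNegLL(theta, y, X, Cs, reml = reml)
      cache$key <- key
    }
    cache$res
  }
  lower <- c(rep(0, k), 1e-8 * vy)
  best <- NULL
  conv <- FALSE
  for (s in splits) {
    theta0 <- s * vy
    opt <- tryCatch(
      optim(theta0, fn = function(th) evalAt(th)$value,
            gr = function(th) evalAt(th)$grad,
            method = "L-BFGS-B", lower = lower, upper = rep(100 * vy, k + 1),
            control = list(factr = tol / .Machine$double.eps, maxit = 200)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value - 1e-10) best <- opt
    if (opt$convergence == 0) conv <- TRUE
  }
  if (is.null(best)) stop("variance-component optimization failed at every start")
  if (!conv) warning("variance-component fit did not converge after all restarts")
  theta <- pmax(best$par, 0)
  at <- .vcNegLL(theta, y, X, Cs, reml = reml)
  ll_reml <- -.vcNegLL(theta, y, X, Cs, reml = TRUE)$value
  ll_ml <- -.vcNegLL(theta, y, X, Cs, reml = FALSE)$value
  sigma2 <- setNames(theta, c(names(components), "e"))
  new("VCFit", sigma2 = sigma2,
      beta = setNames(at$beta, colnames(X)),
      betaSE = setNames(at$betaSE, colnames(X)),
      loglikREML = ll_reml, loglikML = ll_ml,
      converged = conv, n = as.integer(n),
      components = components, fingerprint = .fingerprint(y, X))
}

#' Likelihood-ratio test of one variance component
#'
#' Tests the boundary hypothesis sigma2_c = 0 by comparing the restricted
#' log-likelihoods of nested fits. Because the null value lies on the
#' boundary of the parameter space, the statistic Lambda = 2(ll_full -
#' ll_reduced), clipped at zero, is referred to the 50:50 mixture of a point
#' mass at 0 and chi-square(1): p = 0.5 Pr(chi2_1 >= Lambda).
#'
#' @param full,reduced [VCFit-class] objects on the same data; `reduced`
#'   must drop exactly one structured component of `full`.
#' @return list with `lambda` (the LRT statistic) and `p_value`.
#' @export
lrtVarComp <- function(full, reduced) {
  stopifnot(is(full, "VCFit"), is(reduced, "VCFit"))
  if (!identical(full@fingerprint, reduced@fingerprint))
    stop("fits are not on the same data (fingerprint mismatch)")
  dropped <- setdiff(names(full@components), names(reduced@components))
  if (length(dropped) != 1 ||
      length(full@components) != length(reduced@components) + 1)
    stop("reduced model must drop exactly one variance component of the full model")
  lambda <- max(0, 2 * (full@loglikREML - reduced@loglikREML))
  p <- 0.5 * pchisq(lambda, df = 1, lower.tail = FALSE)
  list(lambda = lambda, p_value = p, dropped = dropped)
}

#' Partition heritability from a fitted model
#'
#' h2_g = sigma2_g / sigma2_total and h2_m = sigma2_m / sigma2_total with
#' sigma2_total the sum of all components; the mutation share of total
#' heritability is h2_m / (h2_m + h2_g). With `scale = "liability"` both
#' heritabilities are converted from the observed 0/1 scale via
#' [observedToLiability()] (the share is a ratio and is scale-invariant).
#'
#' @param fit converged [VCFit-class] with components named `g` and/or `m`.
#' @param scale "observed" (default) or "liability".
#' @param prevalence trait prevalence, required for the liability scale.
#' @param lrt_p_g,lrt_p_m optional LRT p-values (from [lrtVarComp()]) to
#'   carry in the report.
#' @return A [HeritabilityReport-class].
#' @export
heritabilityPartition <- function(fit, scale = c("observed", "liability"),
                                  prevalence = NA_real_,
                                  lrt_p_g = NA_real_, lrt_p_m = NA_real_) {
  scale <- match.arg(scale)
  if (!fit@converged) warning("heritability partition from a non-converged fit")
  s2 <- varComponents(fit)
  tot <- sum(s2)
  h2g <- if ("g" %in% names(s2)) unname(s2["g"]) / tot else NA_real_
  h2m <- if ("m" %in% names(s2)) unname(s2["m"]) / tot else NA_real_
  if (scale == "liability") {
    if (!is.na(h2g)) h2g <- observedToLiability(h2g, prevalence)
    if (!is.na(h2m)) h2m <- observedToLiability(h2m, prevalence)
    # the conversion can exceed the [0,1] simplex for noisy estimates
    s <- sum(c(h2g, h2m), na.rm = TRUE)
    if (s > 1) {
      warning("liability-scale heritabilities exceed 1; rescaled to the simplex")
      if (!is.na(h2g)) h2g <- h2g / s
      if (!is.na(h2m)) h2m <- h2m / s
    }
  }
  denom <- sum(c(h2g, h2m), na.rm = TRUE)
  share <- if (is.na(h2m) || denom == 0) NA_real_ else h2m / denom
  if (!is.na(h2m) && h2m == 0 && denom > 0) share <- 0
  new("HeritabilityReport", h2_g = h2g, h2_m = h2m, mutation_share = share,
      lrt_p_g = lrt_p_g, lrt_p_m = lrt_p_m, scale = scale,
      prevalence = if (scale == "liability") prevalence else NA_real_)
}

#' Observed-scale to liability-scale heritability
#'
#' Dempster-Lerner conversion for a threshold trait:
#' h2_liab = h2_obs * p (1 - p) / z^2, where p is the prevalence and z the
#' standard-normal density at the threshold cutting the upper-p tail.
#'
#' @param h2_obs observed-scale (0/1) heritability.
#' @param prevalence trait prevalence, in (0, 1).
#' @return Liability-scale heritability.
#' @export
observedToLiability <- function(h2_obs, prevalence) {
  if (!is.finite(prevalence) || prevalence <= 0 || prevalence >= 1)
    stop("prevalence must be in (0, 1)")
  z <- dnorm(qnorm(prevalence, lower.tail = FALSE))
  h2_obs * prevalence * (1 - prevalence) / z^2
}
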