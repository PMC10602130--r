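# Joint fixed-effect models: multivariate logistic odds ratios with Wald
# 95% CIs, exhaustive BIC selection over race-by-SNP interaction subsets
# (BIC as a Bayes-factor approximation), Fisher's combined p, and cohort
# descriptive summaries.

#' Multivariate logistic regression with odds ratios
#'
#' Maximum-likelihood logistic fit (IRLS via `glm`). Each coefficient is
#' reported as OR = exp(beta) with Wald 95% CI exp(beta +/- 1.96 SE).
#' Perfect separation (diverging estimates) and rank deficiency are errors.
#'
#' @param y binary 0/1 response.
#' @param X covariate matrix or data.frame (no intercept; one is added).
#' @return list with `or_table` (term, beta, se, OR, ci95_low, ci95_high,
#'   p_wald), `loglik`, `k` (number of parameters), `n`, and the `glm` fit.
#' @export
fitLogistic <- function(y, X = NULL) {
  if (length(unique(y)) < 2) stop("y has no variation")
  n <- length(y)
  if (is.null(X)) X <- matrix(numeric(0), n, 0)
  X <- as.matrix(X)
  if (is.null(colnames(X)) && ncol(X))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  Xi <- cbind("(Intercept)" = 1, X)
  if (qr(Xi)$rank < ncol(Xi)) stop("covariate matrix is rank deficient")
  fit <- suppressWarnings(
    glm.fit(Xi, y, family = binomial(), control = list(maxit = 100)))
  beta <- fit$coefficients
  se <- sqrt(diag(chol2inv(fit$qr$qr[seq_len(ncol(Xi)), , drop = FALSE])))
  diverged <- !fit$converged | abs(beta) > 15 | se > 200
  if (any(diverged))
    stop("perfect separation detected for term(s): ",
         paste(names(beta)[diverged], collapse = ", "))
  z <- beta / se
  or_table <- data.frame(
    term = names(beta), beta = unname(beta), se = unname(se),
    OR = exp(unname(beta)),
    ci95_low = exp(unname(beta) - qnorm(0.975) * unname(se)),
    ci95_high = exp(unname(beta) + qnorm(0.975) * unname(se)),
    p_wald = 2 * pnorm(-abs(unname(z))), stringsAsFactors = FALSE)
  ll <- -fit$deviance / 2
  list(or_table = or_table, loglik = ll, k = ncol(Xi), n = n, fit = fit)
}

#' Exhaustive BIC selection over race-by-SNP interaction subsets
#'
#' Fits every subset of race-by-SNP interaction terms added to the base
#' additive model (main effects of race and all candidate SNPs are always
#' retained) and ranks models by BIC = -2 loglik + k log(n), the standard
#' large-sample approximation to Bayesian model comparison. Models with
#' perfect separation are flagged and excluded from the ranking.
#'
#' @param y binary 0/1 response.
#' @param base_terms covariate matrix always included (besides intercept,
#'   race and the SNP main effects); may be NULL.
#' @param snps matrix of candidate SNP dosages (<= 12 columns).
#' @param race character/factor race vector; coded 1 for "WE".
#' @return list with `table` (one row per subset: model id, interaction
#'   terms, loglik, k, n, BIC, separated flag), `best` (the minimum-BIC
#'   model id), `best_terms` and `fits` (per-model fitLogistic results).
#' @export
selectInteractionModel <- function(y, base_terms = NULL, snps, race) {
  snps <- as.matrix(snps)
  if (ncol(snps) && is.null(colnames(snps)))
    colnames(snps) <- paste0("snp", seq_len(ncol(snps)))
  k <- ncol(snps)
  if (k > 12) stop("at most 12 candidate SNPs (2^k subset enumeration)")
  race_num <- as.numeric(race == "WE")
  base <- cbind(base_terms, race = race_num, snps)
  subsets <- lapply(0:(2^k - 1), function(b) which(bitwAnd(b, 2^(seq_len(k) - 1)) > 0))
  rows <- vector("list", length(subsets))
  fits <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    sel <- subsets[[i]]
    inter <- if (length(sel)) {
      m <- snps[, sel, drop = FALSE] * race_num
      colnames(m) <- paste0("race:", colnames(snps)[sel])
      m
    } else NULL
    id <- if (length(sel)) paste(paste0("race:", colnames(snps)[sel]),
                                 collapse = "+") else "(no interactions)"
    f <- tryCatch(fitLogistic(y, cbind(base, inter)), error = function(e) e)
    if (inherits(f, "error")) {
      warning("model '", id, "' excluded: ", conditionMessage(f))
      rows[[i]] <- data.frame(model = id, n_interactions = length(sel),
                              loglik = NA_real_, k = NA_integer_,
                              n = length(y), BIC = NA_real_, separated = TRUE,
                              stringsAsFactors = FALSE)
    } else {
      fits[[i]] <- f
      rows[[i]] <- data.frame(model = id, n_interactions = length(sel),
                              loglik = f$loglik, k = f$k, n = f$n,
                              BIC = -2 * f$loglik + f$k * log(f$n),
                              separated = FALSE, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  ok <- !tab$separated
  if (!any(ok)) stop("every candidate model was excluded (separation)")
  best_i <- which(ok)[which.min(tab$BIC[ok])]
  names(fits) <- tab$model
  list(table = tab, best = tab$model[best_i],
       best_terms = subsets[[best_i]], fits = fits)
}

#' Fisher's method for combining p-values
#'
#' X = -2 sum(log p_i) referred to chi-square with 2k degrees of freedom.
#'
#' @param pvals numeric p-values in (0, 1].
#' @return Combined p-value.
#' @export
fishersMethod <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must be in (0, 1]")
  x <- -2 * sum(log(pvals))
  pchisq(x, df = 2 * length(pvals), lower.tail = FALSE)
}

#' Descriptive cohort summary
#'
#' Per-race and overall counts and percentages (1 decimal) of baseline (and,
#' when present, historical) inhibitor status and of each causative-mutation
#' category, the mutation-detection rate (share of subjects with an
#' identified lesion), and the 2x2 Pearson chi-square (no continuity
#' correction) for status by race.
#'
#' @param cohort validated cohort data.frame.
#' @param mutations validated mutation data.frame covering the cohort.
#' @return list with `status` (status-by-race breakdown with chi-square p),
#'   `mutations` (category breakdown), `detected_pct` (overall and per-race
#'   mutation-detection percentages) and `n`.
#' @export
cohortSummary <- function(cohort, mutations) {
  cohort <- validateCohort(cohort)
  if (!nrow(cohort)) stop("empty cohort")
  mutations <- validateMutations(mutations)
  missing <- setdiff(cohort$subject_id, mutations$subject_id)
  if (length(missing))
    stop("subject(s) missing mutation row: ", paste(head(missing, 3), collapse = ", "))
  mutations <- mutations[match(cohort$subject_id, mutations$subject_id), ]
  pct <- function(num, den) round(100 * num / den, 1)
  races <- c("BA", "WE")
  nr <- setNames(vapply(races, function(r) sum(cohort$race == r), numeric(1)), races)
  n <- nrow(cohort)
  statusRow <- function(col) {
    y <- cohort[[col]]
    counts <- vapply(races, function(r) sum(y[cohort$race == r] == 1, na.rm = TRUE),
                     numeric(1))
    tab <- rbind(cases = counts, noncases = nr - counts)
    p_chisq <- if (all(tab > 0) || all(colSums(tab) > 0))
      suppressWarnings(chisq.test(tab, correct = FALSE)$p.value) else NA_real_
    data.frame(status = col, n_BA = counts["BA"], pct_BA = pct(counts["BA"], nr["BA"]),
               n_WE = counts["WE"], pct_WE = pct(counts["WE"], nr["WE"]),
               n_total = sum(counts), pct_total = pct(sum(counts), n),
               chisq_p = p_chisq, row.names = NULL, stringsAsFactors = FALSE)
  }
  status <- statusRow("baseline_status")
  if ("historical_status" %in% names(cohort))
    status <- rbind(statusRow("historical_status"), status)
  cats <- mutationCategories()
  mut <- do.call(rbind, lapply(cats, function(cc) {
    counts <- vapply(races, function(r)
      sum(mutations$category[cohort$race == r] == cc), numeric(1))
    data.frame(category = cc, n_BA = counts["BA"], pct_BA = pct(counts["BA"], nr["BA"]),
               n_WE = counts["WE"], pct_WE = pct(counts["WE"], nr["WE"]),
               n_total = sum(counts), pct_total = pct(sum(counts), n),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  det <- mutations$category != "not_identified"
  detected <- c(
    BA = pct(sum(det & cohort$race == "BA"), nr["BA"]),
    WE = pct(sum(det & cohort$race == "WE"), nr["WE"]),
    total = pct(sum(det), n))
  list(status = status, mutations = mut, detected_pct = detected,
       n = c(nr, total = n))
}
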