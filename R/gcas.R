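# Gene-centric association scan (GCAS): per-SNP fixed-effect tests inside
# the fitted mixed model, SNP-to-gene assignment, and Bonferroni thresholds
# per gene and chip-wide on the -log10(p) scale.

#' Assign markers to candidate genes
#'
#' Applies a marker-to-gene map to a marker table. Assignment must be a
#' function: a marker mapped to two different genes is an error. Markers
#' absent from the map stay unassigned (NA gene) and are excluded from
#' per-gene test counts.
#'
#' @param markers marker data.frame (from [markerInfo()]) or a
#'   [GenotypeMatrix-class].
#' @param gene_map data.frame with columns marker_id, gene.
#' @return list with `markers` (the input with a `gene` column filled from
#'   the map) and `gene_counts` (named integer vector of SNPs per gene).
#' @export
assignSnpsToGenes <- function(markers, gene_map) {
  if (is(markers, "GenotypeMatrix")) markers <- markerInfo(markers)
  stopifnot(all(c("marker_id", "gene") %in% names(gene_map)))
  dup <- unique(gene_map$marker_id[duplicated(gene_map$marker_id)])
  conflicting <- dup[vapply(dup, function(m)
    length(unique(gene_map$gene[gene_map$marker_id == m])) > 1, logical(1))]
  if (length(conflicting))
    stop("marker(s) assigned to more than one gene: ",
         paste(head(conflicting, 5), collapse = ", "))
  gene_map <- gene_map[!duplicated(gene_map$marker_id), , drop = FALSE]
  markers$gene <- gene_map$gene[match(markers$id, gene_map$marker_id)]
  counts <- table(markers$gene[!is.na(markers$gene)])
  list(markers = markers,
       gene_counts = setNames(as.integer(counts), names(counts)))
}

#' Bonferroni threshold on the -log10(p) scale
#'
#' -log10(alpha / n_tests): the nominal significance level divided by the
#' number of tests. Reported thresholds are conventionally rounded half-up
#' to 2 decimals (e.g. 6.44 chip-wide for alpha 0.05 and 137,776 tests).
#'
#' @param alpha nominal significance level, in (0, 1).
#' @param n_tests number of tests (>= 1).
#' @param digits if non-NULL, round half-up to this many decimals.
#' @return The threshold (full precision unless `digits` is given).
#' @export
bonferroniNeglog10 <- function(alpha, n_tests, digits = NULL) {
  if (length(n_tests) != 1 || n_tests < 1) stop("n_tests must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  x <- -log10(alpha / n_tests)
  if (!is.null(digits)) x <- floor(x * 10^digits + 0.5) / 10^digits
  x
}

#' Per-SNP association scan within the mixed model
#'
#' Tests each QC-passed marker for a fixed effect on baseline status with
#' the covariates always included. Default mode `wald_fixed_V` holds the
#' covariance V at the null-model REML estimates and computes the GLS
#' slope and Wald z per SNP (score-style; fast). Mode `full_lrt` refits the
#' model by ML with and without the SNP and refers 2*(ll1 - ll0) to
#' chi-square(1). Monomorphic markers and markers collinear with the
#' covariates are skipped with a logged reason. The counted allele is
#' re-oriented to the minor allele in the combined sample, and per-race
#' minor-allele frequencies are recorded.
#'
#' @param y binary response vector, aligned to `G` subjects.
#' @param X covariate matrix (no intercept; one is added). Race is the
#'   conventional default covariate.
#' @param G [GenotypeMatrix-class].
#' @param nullFit [VCFit-class] fitted on (y, X) with the structured
#'   components (from [fitVC()]).
#' @param race optional race factor for per-race MAFs.
#' @param mode "wald_fixed_V" (default) or "full_lrt".
#' @return Association data.frame (one row per tested SNP) with columns
#'   marker_id, gene, chrom, pos, counted_allele, maf, maf_BA, maf_WE,
#'   beta, se, p_value, neglog10_p. Skipped markers are listed in
#'   attribute `skipped`.
#' @export
scanAssociation <- function(y, X = NULL, G, nullFit, race = NULL,
                            mode = c("wald_fixed_V", "full_lrt")) {
  mode <- match.arg(mode)
  stopifnot(is(nullFit, "VCFit"))
  d <- dosages(G)
  n <- length(y)
  stopifnot(nrow(d) == n)
  if (is.null(X)) X <- matrix(numeric(0), n, 0)
  X <- cbind("(Intercept)" = 1, as.matrix(X))
  info <- markerInfo(G)
  s2 <- varComponents(nullFit)
  V <- diag(unname(s2["e"]), n)
  for (nm in names(nullFit@components)) {
    C <- nullFit@components[[nm]]
    Cm <- if (is(C, "StructuredCovariance")) covMatrix(C) else as.matrix(C)
    V <- V + unname(s2[nm]) * unname(Cm)
  }
  R <- chol(V)
  fit0_ml <- if (mode == "full_lrt")
    fitVC(y, X[, -1, drop = FALSE], components = nullFit@components,
          method = "ML", restarts = 2) else NULL
  # whiten once: solve t(R) Z = A  =>  Z = R^-T A
  Xw <- backsolve(R, X, transpose = TRUE)
  yw <- backsolve(R, y, transpose = TRUE)
  qrX <- qr(Xw)
  rows <- vector("list", ncol(d))
  skipped <- character(0)
  for (j in seq_len(ncol(d))) {
    g <- d[, j]
    if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    p_all <- mean(g) / 2
    if (p_all <= 0 || p_all >= 1) {
      skipped <- c(skipped, paste0(info$id[j], ": monomorphic"))
      next
    }
    counted <- info$counted_allele[j]
    if (p_all > 0.5) {  # re-orient to the combined-sample minor allele
      g <- 2 - g
      p_all <- 1 - p_all
      counted <- info$other_allele[j]
    }
    gw <- backsolve(R, g, transpose = TRUE)
    resid_g <- qr.resid(qrX, gw)
    if (sum(resid_g^2) < 1e-10 * sum(gw^2)) {
      skipped <- c(skipped, paste0(info$id[j], ": collinear with covariates"))
      next
    }
    Z <- cbind(Xw, gw)
    fitls <- lm.fit(Z, yw)
    rss <- sum(fitls$residuals^2)
    beta <- fitls$coefficients[ncol(Z)]
    XtX_inv_jj <- 1 / sum(resid_g^2)
    se <- sqrt(XtX_inv_jj)  # V is held fixed: unit residual scale
    z <- beta / se
    if (mode == "wald_fixed_V") {
      p <- 2 * pnorm(-abs(z))
    } else {
      fit1 <- fitVC(y, cbind(X[, -1, drop = FALSE], snp = g),
                    components = nullFit@components, method = "ML",
                    restarts = 2)
      lam <- max(0, 2 * (fit1@loglikML - fit0_ml@loglikML))
      p <- max(pchisq(lam, df = 1, lower.tail = FALSE), .Machine$double.xmin)
    }
    maf_ba <- maf_we <- NA_real_
    if (!is.null(race)) {
      if (any(race == "BA")) maf_ba <- mean(g[race == "BA"]) / 2
      if (any(race == "WE")) maf_we <- mean(g[race == "WE"]) / 2
    }
    rows[[j]] <- data.frame(
      marker_id = info$id[j], gene = info$gene[j], chrom = info$chrom[j],
      pos = info$pos[j], counted_allele = counted, maf = p_all,
      maf_BA = maf_ba, maf_WE = maf_we, beta = unname(beta),
      se = unname(se), p_value = max(p, .Machine$double.xmin),
      stringsAsFactors = FALSE)
  }
  if (length(skipped)) message(length(skipped), " marker(s) skipped: ",
                               paste(head(skipped, 5), collapse = "; "))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- data.frame()
  if (nrow(out)) {
    out$neglog10_p <- -log10(out$p_value)
    rownames(out) <- NULL
  }
  attr(out, "skipped") <- skipped
  out
}

#' Flag significant associations against Bonferroni thresholds
#'
#' Adds per-gene and chip-wide -log10 thresholds and significance flags.
#' A SNP is gene-level significant iff its -log10(p) strictly exceeds
#' -log10(alpha / n_gene) for the n_gene QC-passed SNPs assigned to its
#' gene; chip-wide significance is analogous with `n_chipwide`. Equality
#' with a threshold counts as NOT significant. SNPs without a gene get an
#' NA gene-level flag but still receive the chip-wide flag.
#'
#' @param table association data.frame from [scanAssociation()].
#' @param alpha nominal level (default 0.05).
#' @param n_chipwide total number of tests for the chip-wide threshold.
#' @param gene_counts named vector of per-gene QC-passed SNP counts (from
#'   [assignSnpsToGenes()]).
#' @return The table with threshold and flag columns filled in.
#' @export
flagSignificant <- function(table, alpha = 0.05, n_chipwide,
                            gene_counts = NULL) {
  if (!nrow(table)) return(table)
  chip_thr <- bonferroniNeglog10(alpha, n_chipwide)
  table$chipwide_threshold_neglog10 <- chip_thr
  table$significant_chipwide <- table$neglog10_p > chip_thr
  gthr <- rep(NA_real_, nrow(table))
  if (!is.null(gene_counts) && !is.null(table$gene)) {
    has <- !is.na(table$gene) & table$gene %in% names(gene_counts)
    gthr[has] <- vapply(table$gene[has], function(g)
      bonferroniNeglog10(alpha, gene_counts[[g]]), numeric(1))
  }
  table$gene_threshold_neglog10 <- gthr
  table$significant_gene_level <- ifelse(is.na(gthr), NA,
                                         table$neglog10_p > gthr)
  table
}
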