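# The two structured covariance matrices of the mixed model: the empirical
# genomic relationship matrix (GRM) estimated from SNP dosages, and the
# shared-causative-mutation indicator matrix built from the F8 lesion table.
# A pedigree-based additive relationship matrix is provided as ground truth
# for the simulator and for validating the empirical GRM.

#' Empirical genomic relationship matrix (GRM)
#'
#' Per-marker-standardized estimator: with dosage g_il and counted-allele
#' sample frequency p_l over the L markers surviving the QC filters,
#' K_ij = (1/L) sum_l (g_il - 2 p_l)(g_jl - 2 p_l) / (2 p_l (1 - p_l)).
#' Missing dosages are mean-imputed to 2 p_l before centering. Markers are
#' dropped when their missing rate exceeds `max_missing`, their minor-allele
#' frequency is below `maf_min`, or they are monomorphic.
#'
#' @param G a [GenotypeMatrix-class].
#' @param maf_min minimum minor-allele frequency (default 0.01).
#' @param max_missing maximum per-marker missing rate (default 0.05).
#' @return A [StructuredCovariance-class] of kind "grm". The number of
#'   markers used is attached as attribute `n_markers`.
#' @export
computeGRM <- function(G, maf_min = 0.01, max_missing = 0.05) {
  d <- dosages(G)
  if (nrow(d) < 2) stop("need at least 2 subjects")
  miss <- colMeans(is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- miss <= max_missing & !is.na(maf) & maf >= maf_min & p > 0 & p < 1
  if (!any(keep)) stop("no informative markers after filtering")
  d <- d[, keep, drop = FALSE]
  p <- p[keep]
  L <- ncol(d)
  # mean-impute, center at 2p, scale by sqrt(2p(1-p))
  for (j in which(colSums(is.na(d)) > 0)) d[is.na(d[, j]), j] <- 2 * p[j]
  W <- sweep(d, 2, 2 * p, "-")
  W <- sweep(W, 2, sqrt(2 * p * (1 - p)), "/")
  K <- tcrossprod(W) / L
  out <- StructuredCovariance(K, "grm")
  attr(out, "n_markers") <- L
  out
}

#' Shared-causative-mutation covariance matrix
#'
#' Indicator matrix over subjects: at `allele` granularity M_ij = 1 iff
#' subjects i and j carry the identical F8 lesion (same `allele_id`); at
#' `category` granularity M_ij = 1 iff their lesions fall in the same broad
#' category. The diagonal is 1. Subjects whose mutation was not identified
#' share with no one at either granularity (their lesions are unknown and
#' almost surely distinct).
#'
#' @param muts validated mutation data.frame.
#' @param granularity "allele" (identical lesion; default) or "category".
#' @param subjects optional character vector selecting and ordering the
#'   modeled subjects; an absent subject is an error.
#' @return A [StructuredCovariance-class] of kind "mutation_sharing".
#' @export
mutationSharingMatrix <- function(muts, granularity = c("allele", "category"),
                                  subjects = NULL) {
  granularity <- match.arg(granularity)
  muts <- validateMutations(muts)
  if (!is.null(subjects)) {
    missing <- setdiff(subjects, muts$subject_id)
    if (length(missing))
      stop("subject(s) missing from mutation table: ",
           paste(head(missing, 5), collapse = ", "))
    muts <- muts[match(subjects, muts$subject_id), , drop = FALSE]
  }
  key <- if (granularity == "allele") muts$allele_id else muts$category
  # not_identified lesions are unknown: force per-subject unique keys
  ni <- muts$category == "not_identified"
  key[ni] <- paste0(".ni.", muts$subject_id[ni])
  M <- outer(key, key, "==") * 1
  dimnames(M) <- list(muts$subject_id, muts$subject_id)
  StructuredCovariance(M, "mutation_sharing")
}

#' Pedigree additive relationship matrix
#'
#' Recursive tabular method: entries are twice the kinship coefficient
#' (so full sibs 0.5, avuncular and grandparent-grandchild pairs 0.25,
#' non-inbred diagonal 1).
#'
#' @param ped data.frame with columns `id`, `sire`, `dam` (0 or NA for
#'   founders) and optionally `sex`.
#' @param subjects optional ids to subset/order the output (e.g. the
#'   in-sample subjects of a simulated pedigree).
#' @return A [StructuredCovariance-class] of kind "pedigree_kinship".
#' @export
pedigreeKinship <- function(ped, subjects = NULL) {
  ped <- as.data.frame(ped)
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  id <- as.character(ped$id)
  if (anyDuplicated(id)) stop("duplicate pedigree ids")
  fix0 <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == "0" | x == ""] <- NA
    x
  }
  sire <- fix0(ped$sire); dam <- fix0(ped$dam)
  unknown <- setdiff(c(sire, dam), c(id, NA))
  if (length(unknown)) stop("parent id(s) not in pedigree: ",
                            paste(unknown, collapse = ", "))
  # topological order: founders first; cycle => someone is their own ancestor
  n <- length(id)
  ord <- integer(0)
  placed <- logical(n); names(placed) <- id
  repeat {
    ready <- !placed & (is.na(sire) | placed[sire]) & (is.na(dam) | placed[dam])
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  if (length(ord) < n)
    stop("pedigree contains a cycle (an individual is its own ancestor)")
  A <- matrix(0, n, n, dimnames = list(id, id))
  for (k in ord) {
    f <- sire[k]; m <- dam[k]
    A[k, k] <- 1 + if (!is.na(f) && !is.na(m)) 0.5 * A[f, m] else 0
    done <- ord[seq_len(match(k, ord) - 1L)]
    if (length(done)) {
      contrib <- numeric(length(done))
      if (!is.na(f)) contrib <- contrib + 0.5 * A[f, done]
      if (!is.na(m)) contrib <- contrib + 0.5 * A[m, done]
      A[k, done] <- contrib
      A[done, k] <- contrib
    }
  }
  if (!is.null(subjects)) {
    missing <- setdiff(subjects, id)
    if (length(missing)) stop("subject(s) not in pedigree: ",
                              paste(head(missing, 5), collapse = ", "))
    A <- A[subjects, subjects, drop = FALSE]
  }
  StructuredCovariance(A, "pedigree_kinship")
}
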