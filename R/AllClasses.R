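#' @importFrom methods new validObject setValidity show is slot
#' @importFrom stats dnorm qnorm pnorm pchisq pnorm rbinom rnorm runif var
#'   optim glm glm.fit lm.fit binomial coef vcov logLik quantile cor sd rbeta
#'   setNames chisq.test na.omit model.matrix
#' @importFrom utils read.delim write.table head modifyList
NULL

#' Recognised causative F8 mutation categories
#'
#' The eight broad lesion classes used to type hemophilia-A-causing F8
#' mutations, plus `multiple` (two or more distinct lesions in one subject)
#' and `not_identified` (no lesion found by the sequencing/inversion assays).
#'
#' @return Character vector of valid category labels.
#' @export
mutationCategories <- function() {
  c("nonsense", "missense", "small_indel", "intron1_inv", "splice_site",
    "intron22_inv", "large_del_multi_exon", "large_del_le_1_exon",
    "multiple", "not_identified")
}

.covKinds <- c("grm", "mutation_sharing", "pedigree_kinship")

# ---------------------------------------------------------------------------
# GenotypeMatrix

#' GenotypeMatrix: subjects-by-markers dosage container
#'
#' Holds counted-allele dosages (0, 1, 2 or NA for missing) for a set of
#' subjects at a set of biallelic markers, together with per-marker metadata
#' (chromosome, 1-based position, counted/other allele, optional gene
#' assignment). Rows are subjects, columns are markers.
#'
#' @slot dosages numeric matrix, subjects x markers, entries in {0,1,2,NA};
#'   rownames are subject ids, colnames marker ids.
#' @slot markers data.frame with columns `id`, `chrom`, `pos`,
#'   `counted_allele`, `other_allele`, `gene`; one row per marker, in column
#'   order of `dosages`.
#' @export
setClass("GenotypeMatrix",
         representation(dosages = "matrix", markers = "data.frame"))

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosages
  m <- object@markers
  msgs <- character()
  if (is.null(rownames(d)) || anyDuplicated(rownames(d)))
    msgs <- c(msgs, "subject ids (rownames of dosages) must exist and be unique")
  if (is.null(colnames(d)) || anyDuplicated(colnames(d)))
    msgs <- c(msgs, "marker ids (colnames of dosages) must exist and be unique")
  req <- c("id", "chrom", "pos", "counted_allele", "other_allele", "gene")
  if (!all(req %in% names(m)))
    msgs <- c(msgs, paste("markers must have columns:", paste(req, collapse = ", ")))
  else {
    if (nrow(m) != ncol(d) || !identical(as.character(m$id), colnames(d)))
      msgs <- c(msgs, "markers$id must match dosage colnames in order")
    pos <- m$pos[!is.na(m$pos)]
    if (length(pos) && any(pos < 1))
      msgs <- c(msgs, "marker positions must be >= 1 (1-based)")
  }
  bad <- !(d %in% c(0, 1, 2) | is.na(d))
  if (any(bad))
    msgs <- c(msgs, "dosages must be 0, 1, 2 or NA")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param dosages numeric matrix (subjects x markers) of counted-allele
#'   counts; rownames = subject ids, colnames = marker ids.
#' @param markers optional data.frame of marker metadata; missing columns are
#'   filled with NA.
#' @return A [GenotypeMatrix-class] object.
#' @export
GenotypeMatrix <- function(dosages, markers = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(markers))
    markers <- data.frame(id = colnames(dosages))
  markers <- as.data.frame(markers)
  if (!"id" %in% names(markers)) markers$id <- colnames(dosages)
  for (col in c("chrom", "counted_allele", "other_allele", "gene"))
    if (!col %in% names(markers)) markers[[col]] <- NA_character_
  if (!"pos" %in% names(markers)) markers$pos <- NA_integer_
  markers <- markers[, c("id", "chrom", "pos", "counted_allele",
                         "other_allele", "gene")]
  rownames(markers) <- NULL
  new("GenotypeMatrix", dosages = dosages, markers = markers)
}

# ---------------------------------------------------------------------------
# StructuredCovariance

#' StructuredCovariance: a structured subject-by-subject covariance
#'
#' Symmetric positive semi-definite matrix over subjects used as a random
#' effect covariance in the mixed model: an empirical genomic relationship
#' matrix (`grm`), a shared-causative-mutation indicator matrix
#' (`mutation_sharing`), or a pedigree-derived additive relationship matrix
#' (`pedigree_kinship`, entries = 2x kinship coefficient).
#'
#' @slot matrix symmetric numeric matrix with subject ids as dimnames.
#' @slot kind one of "grm", "mutation_sharing", "pedigree_kinship".
#' @export
setClass("StructuredCovariance",
         representation(matrix = "matrix", kind = "character"))

setValidity("StructuredCovariance", function(object) {
  m <- object@matrix
  msgs <- character()
  if (nrow(m) != ncol(m)) msgs <- c(msgs, "matrix must be square")
  if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
    msgs <- c(msgs, "matrix needs identical row/col subject ids")
  if (!isSymmetric(unname(m), tol = 1e-8))
    msgs <- c(msgs, "matrix must be symmetric")
  if (any(diag(m) <= 0)) msgs <- c(msgs, "diagonal must be > 0")
  if (length(object@kind) != 1L || !object@kind %in% .covKinds)
    msgs <- c(msgs, paste("kind must be one of:", paste(.covKinds, collapse = ", ")))
  else if (object@kind == "mutation_sharing") {
    if (!all(m %in% c(0, 1)))
      msgs <- c(msgs, "mutation_sharing entries must be 0/1")
    if (any(diag(m) != 1))
      msgs <- c(msgs, "mutation_sharing diagonal must be exactly 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a StructuredCovariance
#'
#' @param matrix symmetric matrix with subject-id dimnames.
#' @param kind covariance kind; see [StructuredCovariance-class].
#' @return A [StructuredCovariance-class] object.
#' @export
StructuredCovariance <- function(matrix, kind) {
  matrix <- as.matrix(matrix)
  matrix <- (matrix + t(matrix)) / 2  # enforce exact symmetry
  new("StructuredCovariance", matrix = matrix, kind = kind)
}

# ---------------------------------------------------------------------------
# VCFit

#' VCFit: a fitted variance-component mixed model
#'
#' Result of [fitVC()]: REML (or ML) estimates of the variance components of
#' V = sigma2_g K + sigma2_m M + sigma2_e I (any subset of named structured
#' components plus a residual), GLS fixed effects at the optimum, and both
#' restricted and full log-likelihoods.
#'
#' @slot sigma2 named numeric vector of variance components; the residual is
#'   named "e", structured components keep their input names.
#' @slot beta,betaSE named numeric vectors of fixed effects and standard errors.
#' @slot loglikREML,loglikML numeric log-likelihoods at the optimum.
#' @slot converged logical convergence flag.
#' @slot n integer number of subjects.
#' @slot components named list of the structured covariance matrices used.
#' @slot fingerprint character checksum of (y, X) used for LRT pairing.
#' @export
setClass("VCFit",
         representation(sigma2 = "numeric", beta = "numeric",
                        betaSE = "numeric", loglikREML = "numeric",
                        loglikML = "numeric", converged = "logical",
                        n = "integer", components = "list",
                        fingerprint = "character"))

setValidity("VCFit", function(object) {
  msgs <- character()
  if (any(object@sigma2 < 0)) msgs <- c(msgs, "variance components must be >= 0")
  if (sum(object@sigma2) <= 0) msgs <- c(msgs, "total variance must be > 0")
  if (isTRUE(object@converged) && !is.finite(object@loglikREML))
    msgs <- c(msgs, "log-likelihood must be finite when converged")
  if (length(msgs)) msgs else TRUE
})

# ---------------------------------------------------------------------------
# HeritabilityReport

#' HeritabilityReport: heritability partition of a VCFit
#'
#' @slot h2_g,h2_m proportions of total variance from the polygenic and
#'   mutation-sharing components.
#' @slot mutation_share h2_m / (h2_m + h2_g); NA when both are zero.
#' @slot lrt_p_g,lrt_p_m boundary-corrected LRT p-values (NA if not computed).
#' @slot scale "observed" or "liability".
#' @slot prevalence trait prevalence used for liability conversion (NA on the
#'   observed scale).
#' @export
setClass("HeritabilityReport",
         representation(h2_g = "numeric", h2_m = "numeric",
                        mutation_share = "numeric", lrt_p_g = "numeric",
                        lrt_p_m = "numeric", scale = "character",
                        prevalence = "numeric"))

setValidity("HeritabilityReport", function(object) {
  msgs <- character()
  for (s in c("h2_g", "h2_m")) {
    v <- slot(object, s)
    if (!is.na(v) && (v < 0 || v > 1)) msgs <- c(msgs, paste(s, "must be in [0,1]"))
  }
  if (!is.na(object@h2_g) && !is.na(object@h2_m) &&
      object@h2_g + object@h2_m > 1 + 1e-8)
    msgs <- c(msgs, "h2_g + h2_m must be <= 1")
  ms <- object@mutation_share
  if (!is.na(ms) && (ms < 0 || ms > 1))
    msgs <- c(msgs, "mutation_share must be in [0,1]")
  if (!object@scale %in% c("observed", "liability"))
    msgs <- c(msgs, "scale must be 'observed' or 'liability'")
  if (length(msgs)) msgs else TRUE
})
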