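# Readers/writers for the tabular and genotype formats used by the pipeline.
# All tables are plain TSV; matrices carry a header row of subject ids;
# reports are JSON. Coordinates are 1-based (VCF convention); strand is not
# modeled, only the counted-allele label is stored.

.races <- c("BA", "WE")

#' Read a genotype dosage matrix
#'
#' Reads counted-allele dosages either from a VCF (GT field; counted allele =
#' ALT) or from a dosage TSV whose header row holds marker ids and whose
#' first column holds subject ids. Only biallelic records are kept:
#' multi-allelic VCF records are skipped with a warning.
#'
#' @param path input file.
#' @param format "vcf" or "dosage_tsv".
#' @return A [GenotypeMatrix-class].
#' @export
readGenotypes <- function(path, format = c("dosage_tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") .readGenotypesVcf(path) else .readGenotypesTsv(path)
}

.readGenotypesTsv <- function(path) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(tab[[1]])
  d <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(d) <- "double"
  rownames(d) <- ids
  ok <- d %in% c(0, 1, 2) | is.na(d)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf("non-{0,1,2} dosage at subject '%s', marker '%s'",
                 ids[bad[1]], colnames(d)[bad[2]]))
  }
  GenotypeMatrix(d)
}

.readGenotypesVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt)
  if (any(multi))
    warning(sum(multi), " multi-allelic VCF record(s) skipped")
  keep <- !multi
  if (!any(keep)) stop("no biallelic records in VCF")
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  count_alt <- function(g) {
    out <- rep(NA_real_, length(g))
    al <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)
    known <- !is.na(g) & !vapply(al, function(a) any(a == "."), logical(1))
    out[known] <- vapply(al[known], function(a) sum(a != "0"), numeric(1))
    out
  }
  d <- t(apply(gt, 1, count_alt))
  colnames(d) <- colnames(gt)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  markers <- data.frame(id = ids, chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]),
                        counted_allele = fix[, "ALT"],
                        other_allele = fix[, "REF"], gene = NA_character_,
                        stringsAsFactors = FALSE)
  d <- t(d)  # subjects x markers
  colnames(d) <- markers$id
  GenotypeMatrix(d, markers)
}

#' Write a genotype dosage TSV
#'
#' @param G a [GenotypeMatrix-class].
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeGenotypes <- function(G, path) {
  d <- dosages(G)
  out <- data.frame(subject_id = rownames(d), d, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.checkNoDupSubjects <- function(tab, what) {
  dup <- unique(tab$subject_id[duplicated(tab$subject_id)])
  if (length(dup))
    stop("duplicate subject id(s) in ", what, ": ", paste(dup, collapse = ", "))
}

#' Validate (and coerce) a cohort table
#'
#' A cohort table is a data.frame with columns `subject_id`,
#' `baseline_status` (0/1: inhibitor of any titer present at study entry),
#' `race` ("BA" or "WE"), optionally `historical_status` (0/1) and further
#' numeric covariate columns.
#'
#' @param tab data.frame.
#' @return The validated data.frame.
#' @export
validateCohort <- function(tab) {
  req <- c("subject_id", "baseline_status", "race")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("cohort table missing column(s): ", paste(miss, collapse = ", "))
  tab$subject_id <- as.character(tab$subject_id)
  .checkNoDupSubjects(tab, "cohort table")
  if (!all(tab$baseline_status %in% c(0, 1)))
    stop("baseline_status must be 0/1")
  if (any(is.na(tab$race)) || !all(tab$race %in% .races))
    stop("race must be one of: ", paste(.races, collapse = ", "))
  if ("historical_status" %in% names(tab) &&
      !all(tab$historical_status %in% c(0, 1) | is.na(tab$historical_status)))
    stop("historical_status must be 0/1 or NA")
  tab
}

#' Read a cohort TSV
#' @param path TSV with the columns described in [validateCohort()].
#' @return Validated cohort data.frame.
#' @export
readCohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  validateCohort(read.delim(path, stringsAsFactors = FALSE))
}

#' Validate a causative-mutation table
#'
#' One row per subject with columns `subject_id`, `category` (see
#' [mutationCategories()]) and `allele_id`, a non-empty string naming the
#' exact lesion (e.g. "I22INV"); subjects with `category = "not_identified"`
#' carry per-subject unique tokens.
#'
#' @param tab data.frame.
#' @return The validated data.frame.
#' @export
validateMutations <- function(tab) {
  req <- c("subject_id", "category", "allele_id")
  miss <- setdiff(req, names(tab))
  if (length(miss)) stop("mutation table missing column(s): ", paste(miss, collapse = ", "))
  tab$subject_id <- as.character(tab$subject_id)
  tab$allele_id <- as.character(tab$allele_id)
  .checkNoDupSubjects(tab, "mutation table")
  bad <- setdiff(unique(tab$category), mutationCategories())
  if (length(bad))
    stop("invalid mutation category '", bad[1], "'; valid categories are: ",
         paste(mutationCategories(), collapse = ", "))
  if (any(is.na(tab$allele_id) | tab$allele_id == ""))
    stop("allele_id must be non-empty")
  tab
}

#' Read a causative-mutation TSV
#' @param path TSV with columns subject_id, category, allele_id.
#' @return Validated mutation data.frame.
#' @export
readMutations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  validateMutations(read.delim(path, stringsAsFactors = FALSE))
}

#' Read a SNP-to-gene map TSV
#' @param path TSV with columns marker_id, gene.
#' @return data.frame with columns marker_id, gene.
#' @export
readGeneMap <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("marker_id", "gene") %in% names(tab)))
    stop("gene map must have columns marker_id, gene")
  tab
}

# ---------------------------------------------------------------------------
# association table / report writers

.assocCols <- c("marker_id", "gene", "chrom", "pos", "counted_allele",
                "maf", "maf_BA", "maf_WE", "beta", "se", "p_value",
                "neglog10_p", "gene_threshold_neglog10",
                "chipwide_threshold_neglog10", "significant_gene_level",
                "significant_chipwide")

#' Write an association table as TSV
#'
#' Columns are written in a fixed, deterministic order; p-values are written
#' in scientific notation with enough digits to round-trip.
#'
#' @param table association data.frame (from [scanAssociation()]).
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
writeAssociationTable <- function(table, path) {
  if (nrow(table) == 0) warning("writing empty association table (header only)")
  cols <- intersect(.assocCols, names(table))
  cols <- c(cols, setdiff(names(table), cols))
  out <- table[, cols, drop = FALSE]
  for (col in c("p_value"))
    if (col %in% names(out)) out[[col]] <- formatC(out[[col]], format = "e", digits = 12)
  for (col in names(out))
    if (is.numeric(out[[col]])) out[[col]] <- formatC(out[[col]], format = "g", digits = 13)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back an association TSV written by [writeAssociationTable()]
#' @param path TSV file.
#' @return data.frame with numeric columns restored.
#' @export
readAssociationTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  for (col in c("significant_gene_level", "significant_chipwide"))
    if (col %in% names(tab)) tab[[col]] <- as.logical(tab[[col]])
  tab
}

#' Write a model report (variance components + heritability) as JSON
#'
#' @param fit a [VCFit-class].
#' @param path output .json path.
#' @param report optional [HeritabilityReport-class] to embed.
#' @return Invisibly, `path`.
#' @export
writeReport <- function(fit, path, report = NULL) {
  s2 <- varComponents(fit)
  stopifnot(is(fit, "VCFit"))
  obj <- list(
    sigma2_g = unname(s2["g"]), sigma2_m = unname(s2["m"]),
    sigma2_e = unname(s2["e"]),
    fixed_effects = as.list(fixedEffects(fit)),
    fixed_effects_se = as.list(fit@betaSE),
    loglik_reml = fit@loglikREML, loglik_ml = fit@loglikML,
    converged = fit@converged, n_subjects = fit@n)
  if (!is.null(report)) {
    obj$heritability <- list(
      h2_g = report@h2_g, h2_m = report@h2_m,
      mutation_share = report@mutation_share,
      lrt_p_g = report@lrt_p_g, lrt_p_m = report@lrt_p_m,
      scale = report@scale, prevalence = report@prevalence)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Write / read a StructuredCovariance as TSV
#'
#' The TSV has a header row of subject ids and one labelled row per subject.
#'
#' @param x a [StructuredCovariance-class].
#' @param path TSV path.
#' @param kind covariance kind used when reading back.
#' @return `writeStructuredCovariance` returns `path` invisibly;
#'   `readStructuredCovariance` returns a [StructuredCovariance-class].
#' @export
writeStructuredCovariance <- function(x, path) {
  m <- covMatrix(x)
  out <- data.frame(subject_id = rownames(m),
                    formatC(m, format = "g", digits = 15),
                    check.names = FALSE)
  colnames(out) <- c("subject_id", colnames(m))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeStructuredCovariance
#' @export
readStructuredCovariance <- function(path, kind) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1]])
  StructuredCovariance(m, kind)
}

#' Join genotype, cohort and mutation inputs on subject id
#'
#' Subjects present in the genotypes but absent from the cohort table are
#' dropped with a logged count; subjects in the cohort but missing genotypes
#' or a mutation row raise an error. The returned pieces are aligned to the
#' cohort row order, so results do not depend on input file row order.
#'
#' @param G [GenotypeMatrix-class].
#' @param cohort validated cohort data.frame.
#' @param mutations validated mutation data.frame (optional).
#' @return list(G, cohort, mutations) aligned by subject.
#' @export
alignSubjects <- function(G, cohort, mutations = NULL) {
  cohort <- validateCohort(cohort)
  ids <- cohort$subject_id
  extra <- setdiff(subjectIds(G), ids)
  if (length(extra))
    message(length(extra), " genotyped subject(s) absent from cohort table dropped")
  missing_g <- setdiff(ids, subjectIds(G))
  if (length(missing_g))
    stop("cohort subject(s) missing genotypes: ", paste(head(missing_g, 5), collapse = ", "))
  G2 <- GenotypeMatrix(dosages(G)[ids, , drop = FALSE], markerInfo(G))
  if (!is.null(mutations)) {
    mutations <- validateMutations(mutations)
    missing_m <- setdiff(ids, mutations$subject_id)
    if (length(missing_m))
      stop("subject(s) missing mutation row: ", paste(head(missing_m, 5), collapse = ", "))
    mutations <- mutations[match(ids, mutations$subject_id), , drop = FALSE]
    rownames(mutations) <- NULL
  }
  list(G = G2, cohort = cohort, mutations = mutations)
}
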