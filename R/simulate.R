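# Synthetic cohort generator: pedigreed family structure with two ancestry
# groups, Mendelian gene-dropped genotypes with race-stratified founder
# allele frequencies, heterogeneous causative-F8-mutation assignment, and a
# binary phenotype from a liability with additive-polygenic, mutation-shared
# and residual components. Every draw is deterministic given (params, seed).

#' Simulation parameters with cohort-calibrated defaults
#'
#' Defaults emulate the structure of a North American hemophilia-A cohort:
#' 450 males, two self-reported ancestry groups (206 BA / 244 WE), roughly
#' 31\% of subjects with at least one close relative in-sample (sib and
#' avuncular pairs), a causative-mutation spectrum dominated by intron-22
#' inversions (41.6\%) and missense substitutions (21.6\%, drawn from 61
#' distinct alleles) with 9.8\% unidentified, liability-scale variance
#' components (0.47 polygenic, 0.08 mutation-shared, 0.45 residual), a WE
#' liability shift of -0.21, and an overall baseline-inhibitor prevalence of
#' 0.185.
#'
#' @param ... overrides for any default listed below.
#' @return Named list of validated simulation parameters.
#' @export
simParams <- function(...) {
  p <- list(
    n_subjects = 450,
    race_props = c(BA = 206 / 450, WE = 244 / 450),
    # fractions of subjects living in each family-unit type
    family_mix = c(singleton = 0.69, sib_pair = 0.2067, avuncular = 0.1033),
    n_genes = 25,
    snps_per_gene = 20,
    maf_range = c(0.05, 0.5),
    ancestry_restricted_frac = 0.10,
    fst = 0.1,
    rare_maf_range = c(0.001, 0.01),
    restricted_common_range = c(0.05, 0.30),
    category_freqs = c(
      intron22_inv = 0.416, missense = 0.216, not_identified = 0.098,
      nonsense = 0.27 / 7, small_indel = 0.27 / 7, intron1_inv = 0.27 / 7,
      splice_site = 0.27 / 7, large_del_multi_exon = 0.27 / 7,
      large_del_le_1_exon = 0.27 / 7, multiple = 0.27 / 7),
    n_missense_alleles = 61,
    sigma2_g = 0.47,
    sigma2_m = 0.08,
    sigma2_e = 0.45,
    beta_race_we = -0.21,
    prevalence = 0.185)
  p <- modifyList(p, list(...))
  stopifnot(p$n_subjects >= 2,
            abs(sum(p$race_props) - 1) < 1e-8,
            all(p$race_props >= 0),
            abs(sum(p$family_mix) - 1) < 1e-6,
            all(p$family_mix >= 0),
            all(p$maf_range > 0), all(p$maf_range <= 0.5),
            p$ancestry_restricted_frac >= 0, p$ancestry_restricted_frac <= 1,
            p$sigma2_g >= 0, p$sigma2_m >= 0, p$sigma2_e >= 0,
            p$prevalence > 0, p$prevalence < 1)
  freq <- p$category_freqs
  if (abs(sum(freq) - 1) > 1e-6) stop("category_freqs must sum to 1")
  bad <- setdiff(names(freq), mutationCategories())
  if (length(bad)) stop("unknown mutation category in category_freqs: ", bad[1])
  ms <- if ("missense" %in% names(freq)) freq[["missense"]] else 0
  if (ms > 0 && p$n_missense_alleles < 1)
    stop("need at least one distinct missense allele when missense frequency > 0")
  p
}

#' Simulate family structure and ancestry labels
#'
#' Draws family units (singletons, full-sib pairs, avuncular pairs) matching
#' the configured subject-fraction mix, assigns each family a self-reported
#' ancestry (BA/WE) and returns the full pedigree including unsampled
#' connecting parents. If the unit counts cannot exactly tile `n_subjects`,
#' the remainder becomes singletons and a message is logged.
#'
#' @param params from [simParams()].
#' @param seed integer RNG seed (mandatory).
#' @return data.frame pedigree: id, sire, dam (0 = founder), sex ("M"/"F"),
#'   race, family, in_sample.
#' @export
simulatePedigrees <- function(params = simParams(), seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  n <- params$n_subjects
  mix <- params$family_mix
  n_sib <- round(n * mix["sib_pair"] / 2)
  n_av <- round(n * mix["avuncular"] / 2)
  n_single <- n - 2 * n_sib - 2 * n_av
  if (n_single < 0) {  # mix incompatible with n: shrink pair counts
    message("family mix incompatible with n_subjects; adjusting last units")
    while (n_single < 0 && n_av > 0) { n_av <- n_av - 1; n_single <- n_single + 2 }
    while (n_single < 0 && n_sib > 0) { n_sib <- n_sib - 1; n_single <- n_single + 2 }
  }
  expected_single <- round(n * mix["singleton"])
  if (n_single != expected_single)
    message("adjusted singleton count to ", n_single, " to reach n = ", n)
  rows <- list()
  fam <- 0L
  add <- function(id, sire, dam, sex, fam, in_sample)
    data.frame(id = id, sire = sire, dam = dam, sex = sex,
               family = fam, in_sample = in_sample, stringsAsFactors = FALSE)
  for (i in seq_len(n_single)) {
    fam <- fam + 1L
    rows[[length(rows) + 1]] <-
      add(sprintf("F%04d_S1", fam), "0", "0", "M", fam, TRUE)
  }
  for (i in seq_len(n_sib)) {
    fam <- fam + 1L
    f <- sprintf("F%04d", fam)
    rows[[length(rows) + 1]] <- rbind(
      add(paste0(f, "_FA"), "0", "0", "M", fam, FALSE),
      add(paste0(f, "_MO"), "0", "0", "F", fam, FALSE),
      add(paste0(f, "_S1"), paste0(f, "_FA"), paste0(f, "_MO"), "M", fam, TRUE),
      add(paste0(f, "_S2"), paste0(f, "_FA"), paste0(f, "_MO"), "M", fam, TRUE))
  }
  for (i in seq_len(n_av)) {
    fam <- fam + 1L
    f <- sprintf("F%04d", fam)
    rows[[length(rows) + 1]] <- rbind(
      add(paste0(f, "_GF"), "0", "0", "M", fam, FALSE),
      add(paste0(f, "_GM"), "0", "0", "F", fam, FALSE),
      add(paste0(f, "_UN"), paste0(f, "_GF"), paste0(f, "_GM"), "M", fam, TRUE),
      add(paste0(f, "_FA"), paste0(f, "_GF"), paste0(f, "_GM"), "M", fam, FALSE),
      add(paste0(f, "_MO"), "0", "0", "F", fam, FALSE),
      add(paste0(f, "_NE"), paste0(f, "_FA"), paste0(f, "_MO"), "M", fam, TRUE))
  }
  ped <- do.call(rbind, rows)
  fam_race <- sample(names(params$race_props), fam, replace = TRUE,
                     prob = params$race_props)
  ped$race <- fam_race[ped$family]
  rownames(ped) <- NULL
  ped
}

#' Gene-drop genotypes down a pedigree
#'
#' Founders draw dosages Binomial(2, p_race) at race-specific counted-allele
#' frequencies; non-founders inherit one allele per parent uniformly at
#' random (Mendelian transmission). A configurable fraction of markers is
#' ancestry-restricted: common in one ancestry group, rare (< 0.01) in the
#' other. Markers are organised as `n_genes` genes of `snps_per_gene` SNPs
#' each and the gene label is recorded per marker.
#'
#' @param pedigree from [simulatePedigrees()].
#' @param params from [simParams()].
#' @param seed integer RNG seed.
#' @return A [GenotypeMatrix-class] for the in-sample subjects, with the
#'   founder allele-frequency table attached as attribute `founder_maf`.
#' @export
dropGenotypes <- function(pedigree, params = simParams(), seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  L <- params$n_genes * params$snps_per_gene
  gene <- rep(sprintf("GENE%02d", seq_len(params$n_genes)),
              each = params$snps_per_gene)
  chrom <- as.character(rep_len(1:22, params$n_genes))[match(gene, unique(gene))]
  pos <- 1e6 * as.integer(factor(gene)) + 1000 * sequence(rep(params$snps_per_gene, params$n_genes))
  ids <- sprintf("%s_snp%02d", gene, sequence(rep(params$snps_per_gene, params$n_genes)))
  p_base <- runif(L, params$maf_range[1], params$maf_range[2])
  if (any(p_base <= 0 | p_base > 0.5))
    stop("declared-polymorphic marker with MAF outside (0, 0.5]")
  # race-specific frequencies drift around the shared ancestral frequency
  # under the Balding-Nichols model with divergence `fst`
  drift <- function(p, F) {
    if (F <= 0) return(p)
    pmin(pmax(rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F),
              1e-4), 1 - 1e-4)
  }
  pBA <- drift(p_base, params$fst)
  pWE <- drift(p_base, params$fst)
  restricted <- runif(L) < params$ancestry_restricted_frac
  if (any(restricted)) {
    which_rare_ba <- restricted & (runif(L) < 0.5)
    which_rare_we <- restricted & !which_rare_ba
    pBA[which_rare_ba] <- runif(sum(which_rare_ba), params$rare_maf_range[1],
                                params$rare_maf_range[2])
    pWE[which_rare_ba] <- runif(sum(which_rare_ba),
                                params$restricted_common_range[1],
                                params$restricted_common_range[2])
    pWE[which_rare_we] <- runif(sum(which_rare_we), params$rare_maf_range[1],
                                params$rare_maf_range[2])
    pBA[which_rare_we] <- runif(sum(which_rare_we),
                                params$restricted_common_range[1],
                                params$restricted_common_range[2])
  }
  pmat <- rbind(BA = pBA, WE = pWE)
  ped <- pedigree
  dos <- matrix(NA_real_, nrow(ped), L, dimnames = list(ped$id, ids))
  founder <- ped$sire == "0" & ped$dam == "0"
  for (k in which(founder))
    dos[k, ] <- rbinom(L, 2, pmat[ped$race[k], ])
  # topological pass: parents always precede offspring in construction order
  for (k in which(!founder)) {
    df <- dos[ped$sire[k], ]
    dm <- dos[ped$dam[k], ]
    dos[k, ] <- rbinom(L, 1, df / 2) + rbinom(L, 1, dm / 2)
  }
  markers <- data.frame(id = ids, chrom = chrom, pos = as.integer(pos),
                        counted_allele = "A", other_allele = "G", gene = gene,
                        stringsAsFactors = FALSE)
  G <- GenotypeMatrix(dos[ped$in_sample, , drop = FALSE], markers)
  attr(G, "founder_maf") <- pmat
  G
}

#' Assign causative F8 mutations to simulated subjects
#'
#' One broad category is drawn per family from the configured frequencies
#' and shared by all sampled relatives (the familial lesion). Intron-22 and
#' intron-1 inversion carriers share the recurrent alleles "I22INV" /
#' "I1INV" cohort-wide; missense carriers draw a specific allele from the
#' configured pool of distinct substitutions; other identified categories get
#' family-unique lesion tokens; unidentified subjects get per-subject unique
#' tokens.
#'
#' @param pedigree from [simulatePedigrees()] (in-sample rows are used).
#' @param params from [simParams()].
#' @param seed integer RNG seed.
#' @return Validated mutation data.frame (subject_id, category, allele_id).
#' @export
assignMutations <- function(pedigree, params = simParams(), seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  freq <- params$category_freqs
  ms <- if ("missense" %in% names(freq)) freq[["missense"]] else 0
  if (ms > 0 && params$n_missense_alleles < 1)
    stop("need at least one distinct missense allele when missense frequency > 0")
  samp <- pedigree[pedigree$in_sample, , drop = FALSE]
  fams <- unique(samp$family)
  fam_cat <- sample(names(freq), length(fams), replace = TRUE, prob = freq)
  names(fam_cat) <- as.character(fams)
  fam_allele <- vapply(seq_along(fams), function(i) {
    switch(fam_cat[i],
           intron22_inv = "I22INV",
           intron1_inv = "I1INV",
           missense = sprintf("MS%03d", sample.int(params$n_missense_alleles, 1)),
           not_identified = NA_character_,
           sprintf("%s_f%04d", toupper(substr(fam_cat[i], 1, 4)), fams[i]))
  }, character(1))
  names(fam_allele) <- as.character(fams)
  cat_i <- fam_cat[as.character(samp$family)]
  allele <- fam_allele[as.character(samp$family)]
  ni <- cat_i == "not_identified"
  allele[ni] <- paste0("NID_", samp$id[ni])
  validateMutations(data.frame(subject_id = samp$id, category = unname(cat_i),
                               allele_id = unname(allele),
                               stringsAsFactors = FALSE))
}

#' Simulate the binary phenotype from a liability model
#'
#' Liability l = beta_race 1(WE) + g + m + e with g ~ N(0, sigma2_g K),
#' m built by drawing one N(0, sigma2_m) effect per distinct causative
#' allele and giving it to every carrier (so cov(m) = sigma2_m M exactly),
#' and e ~ N(0, sigma2_e I). Status is 1 when the liability exceeds the
#' upper-`prevalence` quantile of the theoretical marginal liability
#' distribution (normal approximation including the between-race variance of
#' the fixed part), so the prevalence is matched in expectation.
#'
#' @param K [StructuredCovariance-class], the (pedigree) relationship matrix
#'   of the sampled subjects.
#' @param M [StructuredCovariance-class], mutation-sharing matrix at allele
#'   granularity, same subjects and order.
#' @param race character vector ("BA"/"WE") aligned to K's subjects.
#' @param params from [simParams()].
#' @param seed integer RNG seed.
#' @return Cohort data.frame (subject_id, baseline_status, race) with the
#'   latent liability in attribute `liability`.
#' @export
simulatePhenotype <- function(K, M, race, params = simParams(), seed) {
  stopifnot(!missing(seed))
  set.seed(seed)
  Km <- covMatrix(K)
  Mm <- covMatrix(M)
  n <- nrow(Km)
  stopifnot(length(race) == n, nrow(Mm) == n,
            identical(subjectIds(K), subjectIds(M)))
  offdiag <- Km[upper.tri(Km)]
  if (!length(offdiag) || all(offdiag == 0)) {
    # diagonal K (all-singleton cohorts): no factorization needed
    g <- sqrt(diag(Km)) * rnorm(n) * sqrt(params$sigma2_g)
  } else {
    ev <- eigen(Km, symmetric = TRUE)
    if (min(ev$values) < -1e-6 * max(abs(ev$values)))
      stop("K is not positive semi-definite")
    g <- drop(ev$vectors %*% (sqrt(pmax(ev$values, 0)) * rnorm(n))) *
      sqrt(params$sigma2_g)
  }
  # one shared effect per block of identical rows of M (distinct lesion);
  # blocks are equivalence classes, so the first sharing partner indexes one
  first1 <- apply(Mm == 1, 1, which.max)
  block <- match(first1, unique(first1))
  u <- rnorm(max(block), 0, sqrt(params$sigma2_m))
  m <- u[block]
  e <- rnorm(n, 0, sqrt(params$sigma2_e))
  xb <- params$beta_race_we * (race == "WE")
  liab <- drop(xb + g + m + e)
  mu <- mean(xb)
  s2 <- params$sigma2_g * mean(diag(Km)) + params$sigma2_m + params$sigma2_e +
    mean((xb - mu)^2)
  thresh <- mu + qnorm(params$prevalence, lower.tail = FALSE) * sqrt(s2)
  cohort <- data.frame(subject_id = subjectIds(K),
                       baseline_status = as.integer(liab > thresh),
                       race = race, stringsAsFactors = FALSE)
  attr(cohort, "liability") <- liab
  attr(cohort, "threshold") <- thresh
  cohort
}

#' Simulate a complete analysis-ready cohort
#'
#' Orchestrates [simulatePedigrees()], [dropGenotypes()],
#' [assignMutations()], [mutationSharingMatrix()], [pedigreeKinship()] and
#' [simulatePhenotype()] into one bundle. Sub-steps use seeds derived
#' deterministically from `seed`.
#'
#' @param params from [simParams()].
#' @param seed integer RNG seed.
#' @param genotypes logical; set FALSE to skip gene-dropping when only the
#'   pedigree-based pipeline is needed.
#' @return list with pedigree, G (or NULL), cohort, mutations, K
#'   (pedigree_kinship), M (allele granularity), gene_map, params, seed.
#' @export
simulateCohort <- function(params = simParams(), seed, genotypes = TRUE) {
  stopifnot(!missing(seed))
  seed <- as.integer(seed)
  ped <- simulatePedigrees(params, seed = seed)
  ids <- ped$id[ped$in_sample]
  K <- pedigreeKinship(ped, subjects = ids)
  G <- if (genotypes) dropGenotypes(ped, params, seed = seed + 1L) else NULL
  muts <- assignMutations(ped, params, seed = seed + 2L)
  M <- mutationSharingMatrix(muts, granularity = "allele", subjects = ids)
  race <- ped$race[ped$in_sample]
  cohort <- simulatePhenotype(K, M, race, params, seed = seed + 3L)
  gene_map <- if (genotypes)
    data.frame(marker_id = markerInfo(G)$id, gene = markerInfo(G)$gene,
               stringsAsFactors = FALSE) else NULL
  list(pedigree = ped, G = G, cohort = cohort, mutations = muts, K = K,
       M = M, gene_map = gene_map, params = params, seed = seed)
}

#' Write a simulated cohort bundle to a directory
#'
#' Emits genotypes.tsv, cohort.tsv, mutations.tsv, gene_map.tsv, K.tsv,
#' M.tsv and params.json.
#'
#' @param sim from [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
writeSimBundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(sim$G))
    writeGenotypes(sim$G, file.path(dir, "genotypes.tsv"))
  write.table(sim$cohort, file.path(dir, "cohort.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$mutations, file.path(dir, "mutations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(sim$gene_map))
    write.table(sim$gene_map, file.path(dir, "gene_map.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  writeStructuredCovariance(sim$K, file.path(dir, "K.tsv"))
  writeStructuredCovariance(sim$M, file.path(dir, "M.tsv"))
  jsonlite::write_json(c(sim$params, list(seed = sim$seed)),
                       file.path(dir, "params.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
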