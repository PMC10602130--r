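# A deterministic synthetic cohort whose marginal composition matches the
# published descriptive statistics of a North American hemophilia-A cohort
# (450 males, 206 BA / 244 WE, 406 identified causative F8 mutations, 187
# intron-22 inversions, 97 missense carriers of 61 distinct alleles).
# Within-race cell assignments are synthetic: only the published margins are
# reproduced.

#' Reference cohort fixture (synthetic)
#'
#' Builds cohort and mutation tables reproducing the published marginal
#' counts of the motivating cohort: per-race sample sizes, baseline and
#' historical inhibitor proportions, the 90.2\% mutation-detection rate and
#' the intron-22-inversion and missense carrier counts. Cell-level
#' assignments (which subject is a case, which missense allele a carrier
#' holds) are deterministic synthetic constructions, not patient data.
#'
#' @return list with `cohort` and `mutations` data.frames (450 subjects).
#' @export
referenceCohort <- function() {
  counts <- list(
    BA = c(intron22_inv = 70, missense = 60, not_identified = 18,
           nonsense = 15, small_indel = 12, intron1_inv = 5, splice_site = 8,
           large_del_multi_exon = 8, large_del_le_1_exon = 6, multiple = 4),
    WE = c(intron22_inv = 117, missense = 37, not_identified = 26,
           nonsense = 16, small_indel = 13, intron1_inv = 5, splice_site = 9,
           large_del_multi_exon = 9, large_del_le_1_exon = 7, multiple = 5))
  stopifnot(sum(counts$BA) == 206, sum(counts$WE) == 244)
  n_cases <- c(BA = 44, WE = 39)        # 21.4% / 16.0% baseline
  n_hist <- c(BA = 72, WE = 65)         # 35.0% / 26.6% historical
  rows <- list()
  idx <- 0
  n_ms <- 0
  for (r in names(counts)) {
    cats <- rep(names(counts[[r]]), counts[[r]])
    nr <- length(cats)
    ids <- sprintf("%s%03d", r, seq_len(nr))
    allele <- character(nr)
    for (i in seq_len(nr)) {
      allele[i] <- switch(
        cats[i],
        intron22_inv = "I22INV",
        intron1_inv = "I1INV",
        missense = { n_ms <- n_ms + 1; sprintf("MS%03d", ((n_ms - 1) %% 61) + 1) },
        not_identified = paste0("NID_", ids[i]),
        paste0(toupper(substr(cats[i], 1, 4)), "_", ids[i]))
    }
    rows[[r]] <- data.frame(
      subject_id = ids,
      race = r,
      baseline_status = as.integer(seq_len(nr) <= n_cases[r]),
      historical_status = as.integer(seq_len(nr) <= n_hist[r]),
      category = cats, allele_id = allele, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(cohort = validateCohort(tab[, c("subject_id", "baseline_status",
                                       "historical_status", "race")]),
       mutations = validateMutations(tab[, c("subject_id", "category",
                                             "allele_id")]))
}
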