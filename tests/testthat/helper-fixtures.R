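# Small programmatic fixtures shared across test files.

toyGenotypes <- function() {
  d <- rbind(s1 = c(0, 2), s2 = c(2, 0), s3 = c(1, 1))
  colnames(d) <- c("m1", "m2")
  GenotypeMatrix(d, data.frame(id = c("m1", "m2"), chrom = c("1", "2"),
                               pos = c(100L, 200L), counted_allele = "A",
                               other_allele = "G", gene = NA_character_))
}

toyCohort <- function() {
  validateCohort(data.frame(
    subject_id = c("s1", "s2", "s3", "s4"),
    baseline_status = c(1, 0, 0, 1),
    race = c("BA", "BA", "WE", "WE"), stringsAsFactors = FALSE))
}

toyMutations <- function(ids = c("s1", "s2", "s3", "s4")) {
  validateMutations(data.frame(
    subject_id = ids,
    category = c("intron22_inv", "intron22_inv", "missense", "not_identified"),
    allele_id = c("I22INV", "I22INV", "p.R1966Q", paste0("NID_", ids[4])),
    stringsAsFactors = FALSE))
}

# tiny VCF text fixture; `triallelic` adds a multi-allelic record
writeToyVcf <- function(path, triallelic = FALSE) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##contig=<ID=1>",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "s1", "s2", "s3", sep = "\t"))
  rec <- function(pos, id, ref, alt, g1, g2, g3)
    paste("1", pos, id, ref, alt, ".", "PASS", ".", "GT", g1, g2, g3,
          sep = "\t")
  body <- c(rec(100, "rs1", "G", "A", "0/0", "0/1", "1/1"),
            rec(200, "rs2", "C", "T", "0/1", "0/1", "0/0"),
            rec(300, "rs3", "A", "G", "1|1", "0|0", "./."),
            rec(400, "rs4", "T", "C", "0/0", "0/0", "0/1"),
            rec(500, "rs5", "G", "C", "0/1", "0/0", "0/0"))
  if (triallelic)
    body[3] <- rec(300, "rs3", "A", "G,T", "1/2", "0/0", "0/1")
  writeLines(c(hdr, body), path)
  path
}

# small unstructured cohort for model tests: n subjects, a few sib pairs
smallSimParams <- function(n = 120, ...) {
  simParams(n_subjects = n, n_genes = 4, snps_per_gene = 5, ...)
}

# deterministic unrelated-cohort design matrix + binary outcome generator
simLogisticData <- function(n, beta, X, seed) {
  set.seed(seed)
  eta <- drop(cbind(1, X) %*% beta)
  rbinom(n, 1, plogis(eta))
}
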