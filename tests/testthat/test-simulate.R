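# Synthetic cohort generator: determinism, pedigree structure, Mendelian
# gene-dropping, mutation spectrum, liability-threshold phenotype.

test_that("the generator is deterministic given (params, seed)", {
  p <- smallSimParams(60)
  s1 <- suppressMessages(simulateCohort(p, seed = 9))
  s2 <- suppressMessages(simulateCohort(p, seed = 9))
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(dosages(s1$G), dosages(s2$G))
  expect_identical(s1$mutations, s2$mutations)
  # a different seed changes draws but not structural counts
  s3 <- suppressMessages(simulateCohort(p, seed = 10))
  expect_false(identical(s1$cohort$baseline_status, s3$cohort$baseline_status))
  expect_identical(dim(dosages(s1$G)), dim(dosages(s3$G)))
  expect_identical(table(s1$pedigree$family == s1$pedigree$family),
                   table(s3$pedigree$family == s3$pedigree$family))
})

test_that("all-singleton mix gives an identity relationship matrix", {
  p <- simParams(n_subjects = 20,
                 family_mix = c(singleton = 1, sib_pair = 0, avuncular = 0))
  ped <- simulatePedigrees(p, seed = 3)
  A <- covMatrix(pedigreeKinship(ped, subjects = ped$id[ped$in_sample]))
  expect_equal(unname(A), diag(20))
})

test_that("pure sib-pair mix with n=4 gives two 0.5-blocks", {
  p <- simParams(n_subjects = 4,
                 family_mix = c(singleton = 0, sib_pair = 1, avuncular = 0))
  ped <- simulatePedigrees(p, seed = 4)
  ids <- ped$id[ped$in_sample]
  expect_length(ids, 4)
  A <- covMatrix(pedigreeKinship(ped, subjects = ids))
  fams <- ped$family[ped$in_sample]
  same <- outer(fams, fams, "==")
  expect_equal(unname(A[same & upper.tri(A)]), rep(0.5, 2))
  expect_equal(unname(A[!same & upper.tri(A)]), rep(0, 4))
})

test_that("roughly 31% of default subjects have a relative in-sample", {
  p <- simParams()
  ped <- simulatePedigrees(p, seed = 5)
  samp <- ped[ped$in_sample, ]
  related <- ave(seq_len(nrow(samp)), samp$family, FUN = length) > 1
  expect_equal(mean(related), 0.31, tolerance = 0.02)
  expect_equal(nrow(samp), 450)
})

test_that("founder dosages match the binomial expectation at MAF 0.5", {
  p <- simParams(n_subjects = 10000, n_genes = 2, snps_per_gene = 2,
                 maf_range = c(0.5, 0.5), fst = 0,
                 ancestry_restricted_frac = 0,
                 family_mix = c(singleton = 1, sib_pair = 0, avuncular = 0))
  ped <- simulatePedigrees(p, seed = 6)
  G <- dropGenotypes(ped, p, seed = 7)
  expect_lt(max(abs(colMeans(dosages(G)) - 1)), 0.03)
})

test_that("offspring of two dosage-0 parents have dosage 0", {
  p <- simParams(n_subjects = 40,
                 family_mix = c(singleton = 0, sib_pair = 1, avuncular = 0),
                 n_genes = 2, snps_per_gene = 5)
  ped <- simulatePedigrees(p, seed = 8)
  G <- dropGenotypes(ped, p, seed = 9)
  # reconstruct parent dosages by re-running the founder draws is overkill:
  # instead check the Mendelian constraint via sib pairs sharing founders --
  # any marker where both parents are homozygous reference must give 0
  # offspring dosage; verify via the full pedigree drop made reproducible
  set.seed(9)  # same seed as dropGenotypes uses internally
  # direct property: dosages are always in {0,1,2}
  expect_true(all(dosages(G) %in% 0:2))
  # explicit two-zero-parent check on a hand-built pedigree
  ped2 <- data.frame(id = c("f", "m", "k"), sire = c("0", "0", "f"),
                     dam = c("0", "0", "m"), sex = c("M", "F", "M"),
                     family = 1, in_sample = c(FALSE, FALSE, TRUE),
                     race = "BA", stringsAsFactors = FALSE)
  p2 <- simParams(n_subjects = 2, maf_range = c(1e-6, 1e-5),
                  n_genes = 1, snps_per_gene = 20, fst = 0,
                  ancestry_restricted_frac = 0)
  G2 <- dropGenotypes(ped2, p2, seed = 10)  # founders ~ dosage 0 w.h.p.
  expect_true(all(dosages(G2) == 0))
})

test_that("mutation category frequencies match the configured spectrum", {
  p <- simParams(n_subjects = 10000,
                 family_mix = c(singleton = 1, sib_pair = 0, avuncular = 0))
  ped <- simulatePedigrees(p, seed = 11)
  muts <- assignMutations(ped, p, seed = 12)
  frac_i22 <- mean(muts$category == "intron22_inv")
  expect_equal(frac_i22, 0.416, tolerance = 0.02 / 0.416)  # +/- 0.02 absolute
  expect_lt(abs(frac_i22 - 0.416), 0.02)
  expect_lt(abs(mean(muts$category == "missense") - 0.216), 0.02)
  expect_lt(abs(mean(muts$category == "not_identified") - 0.098), 0.02)
  # all intron-22 inversions share the recurrent allele
  expect_equal(unique(muts$allele_id[muts$category == "intron22_inv"]),
               "I22INV")
  # not_identified tokens are subject-unique
  ni <- muts$allele_id[muts$category == "not_identified"]
  expect_false(anyDuplicated(ni) > 0)
})

test_that("relatives share the familial lesion; i22-only spectrum gives all-ones M", {
  p <- simParams(n_subjects = 40,
                 family_mix = c(singleton = 0, sib_pair = 1, avuncular = 0))
  ped <- simulatePedigrees(p, seed = 13)
  muts <- assignMutations(ped, p, seed = 14)
  samp <- ped[ped$in_sample, ]
  for (f in unique(samp$family)) {
    al <- muts$allele_id[muts$subject_id %in% samp$id[samp$family == f]]
    cat_f <- muts$category[muts$subject_id %in% samp$id[samp$family == f]]
    if (cat_f[1] != "not_identified") expect_equal(al[1], al[2])
  }
  p2 <- simParams(n_subjects = 12, category_freqs = c(intron22_inv = 1))
  ped2 <- simulatePedigrees(p2, seed = 15)
  muts2 <- assignMutations(ped2, p2, seed = 16)
  M <- covMatrix(mutationSharingMatrix(muts2, "allele"))
  expect_equal(unname(M), matrix(1, 12, 12))
})

test_that("liability threshold hits the target prevalence at large n", {
  p <- simParams(n_subjects = 4000,
                 family_mix = c(singleton = 1, sib_pair = 0, avuncular = 0))
  sim <- suppressMessages(simulateCohort(p, seed = 17, genotypes = FALSE))
  expect_lt(abs(mean(sim$cohort$baseline_status) - 0.185), 0.02)
  # degenerate: no variance components and no fixed effects -> constant y
  p0 <- simParams(n_subjects = 50, sigma2_g = 0, sigma2_m = 0, sigma2_e = 0,
                  beta_race_we = 0)
  sim0 <- suppressMessages(simulateCohort(p0, seed = 18, genotypes = FALSE))
  expect_length(unique(attr(sim0$cohort, "liability")), 1)
  expect_length(unique(sim0$cohort$baseline_status), 1)
})

test_that("the mutation component has covariance sigma2_m * M", {
  p <- simParams(n_subjects = 10)
  ped <- simulatePedigrees(p, seed = 19)
  ids <- ped$id[ped$in_sample]
  K <- pedigreeKinship(ped, subjects = ids)
  muts <- assignMutations(ped, p, seed = 20)
  M <- mutationSharingMatrix(muts, subjects = ids)
  # isolate m: set the other variance sources to zero
  p0 <- simParams(n_subjects = 10, sigma2_g = 0, sigma2_e = 0,
                  beta_race_we = 0)
  race <- ped$race[ped$in_sample]
  draws <- sapply(1:2000, function(i)
    attr(simulatePhenotype(K, M, race, p0, seed = 21000 + i), "liability"))
  emp <- tcrossprod(draws - rowMeans(draws)) / (ncol(draws) - 1)
  expected <- p0$sigma2_m * covMatrix(M)
  expect_lt(max(abs(emp - expected)), 0.1 * p0$sigma2_m + 0.01)
  # entrywise within 10% of sigma2_m on the block entries
  on_block <- covMatrix(M) == 1
  expect_lt(max(abs(emp[on_block] - p0$sigma2_m)), 0.1 * p0$sigma2_m)
})

test_that("the polygenic component has covariance sigma2_g * K", {
  p <- simParams(n_subjects = 8, sigma2_m = 0, sigma2_e = 0,
                 beta_race_we = 0,
                 family_mix = c(singleton = 0, sib_pair = 1, avuncular = 0))
  ped <- simulatePedigrees(p, seed = 22)
  ids <- ped$id[ped$in_sample]
  K <- pedigreeKinship(ped, subjects = ids)
  muts <- assignMutations(ped, p, seed = 23)
  M <- mutationSharingMatrix(muts, subjects = ids)
  race <- ped$race[ped$in_sample]
  draws <- sapply(1:2000, function(i)
    attr(simulatePhenotype(K, M, race, p, seed = 50000 + i), "liability"))
  emp <- tcrossprod(draws - rowMeans(draws)) / (ncol(draws) - 1)
  expect_lt(max(abs(emp - p$sigma2_g * covMatrix(K))), 0.1 * p$sigma2_g)
})

test_that("sim bundle round-trips through the plain-text formats", {
  p <- smallSimParams(30)
  sim <- suppressMessages(simulateCohort(p, seed = 24))
  dir <- withr::local_tempdir()
  writeSimBundle(sim, dir)
  expect_identical(dosages(readGenotypes(file.path(dir, "genotypes.tsv"))),
                   dosages(sim$G))
  expect_equal(readCohort(file.path(dir, "cohort.tsv")), sim$cohort,
               ignore_attr = TRUE)
  K2 <- readStructuredCovariance(file.path(dir, "K.tsv"), "pedigree_kinship")
  expect_equal(covMatrix(K2), covMatrix(sim$K), tolerance = 1e-12)
  prm <- jsonlite::read_json(file.path(dir, "params.json"))
  expect_equal(prm$sigma2_g, p$sigma2_g)
  expect_equal(prm$seed, 24)
})
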