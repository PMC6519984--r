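toy_pairs <- data.frame(pair_id = "pair1", mother_sample = "mom",
                        child_sample = "kid", stringsAsFactors = FALSE)

toy_genotypes <- function(mom_klass, kid_klass) {
  # allele combinations consistent with the requested classes (ref A, alt G)
  alleles <- list(wild_type = c("A", "A"), hetero_snp = c("A", "G"),
                  homo_snp = c("G", "G"))
  data.frame(sample_id = c("mom", "kid"), snp_id = "rs1",
             allele1 = c(alleles[[mom_klass]][1], alleles[[kid_klass]][1]),
             allele2 = c(alleles[[mom_klass]][2], alleles[[kid_klass]][2]),
             ref_allele = "A",
             klass = c(mom_klass, kid_klass), stringsAsFactors = FALSE)
}

toy_detection <- function(sample_id, curated = TRUE, psms = 3L) {
  data.frame(sample_id = sample_id, snp_id = "rs1", peptide = "HDDDDK",
             protein_id = "P1", is_variant = TRUE, psm_count = psms,
             curated = curated, stringsAsFactors = FALSE)
}

test_that("transfer requires detection in both and exactly one wild type", {
  # mother wild type, child heterozygous, detected in both: baby -> mother
  res <- infer_transfers(
    rbind(toy_detection("mom"), toy_detection("kid")),
    toy_genotypes("wild_type", "hetero_snp"), toy_pairs)
  expect_equal(nrow(res$events), 1L)
  expect_equal(res$events$direction, "baby_to_mother")
  expect_equal(res$events$donor_sample, "kid")
  expect_equal(res$events$recipient_klass, "wild_type")
  # both heterozygous: both genotypes explain the peptide, no event
  res2 <- infer_transfers(
    rbind(toy_detection("mom"), toy_detection("kid")),
    toy_genotypes("hetero_snp", "hetero_snp"), toy_pairs)
  expect_equal(nrow(res2$events), 0L)
  expect_equal(nrow(res2$unexplained), 0L)
  # both wild type, detected in mother only: unexplained, never an event
  res3 <- infer_transfers(toy_detection("mom"),
                          toy_genotypes("wild_type", "wild_type"),
                          toy_pairs)
  expect_equal(nrow(res3$events), 0L)
  expect_equal(nrow(res3$unexplained), 1L)
  expect_equal(res3$unexplained$sample_id, "mom")
  # carrier detected alone is simply endogenous: no event, no flag
  res4 <- infer_transfers(toy_detection("kid"),
                          toy_genotypes("wild_type", "homo_snp"),
                          toy_pairs)
  expect_equal(nrow(res4$events), 0L)
  expect_equal(nrow(res4$unexplained), 0L)
  # mother heterozygous carrier, child wild type: mother -> baby
  res5 <- infer_transfers(
    rbind(toy_detection("mom"), toy_detection("kid")),
    toy_genotypes("hetero_snp", "wild_type"), toy_pairs)
  expect_equal(res5$events$direction, "mother_to_baby")
})

test_that("recipient-side curation gates events; donor side only downgrades", {
  det <- rbind(toy_detection("mom", curated = FALSE),
               toy_detection("kid", curated = TRUE))
  gt <- toy_genotypes("wild_type", "hetero_snp")  # recipient is mom
  expect_equal(nrow(infer_transfers(det, gt, toy_pairs)$events), 0L)
  expect_equal(nrow(infer_transfers(det, gt, toy_pairs,
                                    require_curated = FALSE)$events), 1L)
  det2 <- rbind(toy_detection("mom", curated = TRUE),
                toy_detection("kid", curated = FALSE))
  ev <- infer_transfers(det2, gt, toy_pairs)$events
  expect_equal(nrow(ev), 1L)
  expect_false(ev$donor_curated)
  # minimum recipient PSM count is enforced
  det3 <- rbind(toy_detection("mom", psms = 1L), toy_detection("kid"))
  expect_equal(nrow(infer_transfers(det3, gt, toy_pairs,
                                    min_recipient_psms = 2L)$events), 0L)
})

test_that("contract errors: unknown samples and missing curation column", {
  det <- toy_detection("stranger")
  expect_error(infer_transfers(det, toy_genotypes("wild_type", "wild_type"),
                               toy_pairs), "absent from the pair manifest")
  det2 <- toy_detection("mom")
  det2$curated <- NULL
  expect_error(infer_transfers(det2,
                               toy_genotypes("wild_type", "hetero_snp"),
                               toy_pairs), "curated")
})

test_that("no inferred event ever has a non-wild-type recipient", {
  for (seed in 1:5) {
    cfg <- simulation_config(seed = seed, n_proteins = 40, n_snps = 80,
                             transfer_rate = 0.2,
                             flanking_ion_dropout = 0.2)
    sim <- simulate_study(cfg)
    cur <- curate_detections(sim$detections, sim$spectra)
    res <- infer_transfers(cur, sim$genotypes, sim$pairs)
    if (nrow(res$events) > 0) {
      expect_true(all(res$events$recipient_klass == "wild_type"))
      expect_true(all(res$events$donor_klass %in%
                        c("hetero_snp", "homo_snp")))
      expect_true(all(res$events$recipient_curated))
    }
  }
})

test_that("summaries count proteins per direction and find concordance", {
  pairs2 <- data.frame(pair_id = c("pair1", "pair2"),
                       mother_sample = c("m1", "m2"),
                       child_sample = c("c1", "c2"))
  ev <- data.frame(
    pair_id = c("pair1", "pair2", "pair1", "pair2", "pair1", "pair1",
                "pair2"),
    snp_id = paste0("rs", 1:7),
    peptide = c("PEPA", "PEPA2", "PEPB", "PEPB", "PEPC", "PEPD", "PEPE"),
    protein_id = c("GAA", "GAA", "HSPG2", "HSPG2", "SERPIN", "X1", "SERPIN"),
    direction = c("baby_to_mother", "baby_to_mother", "mother_to_baby",
                  "mother_to_baby", "baby_to_mother", "mother_to_baby",
                  "mother_to_baby"),
    stringsAsFactors = FALSE)
  s <- summarize_transfers(ev, pairs2)
  expect_equal(s$n_cases, 7L)
  expect_equal(s$n_unique_peptides, 6L)
  expect_equal(s$n_proteins, 4L)
  expect_equal(unname(s$direction_counts["baby_to_mother"]), 2L)
  expect_equal(unname(s$direction_counts["mother_to_baby"]), 3L)
  expect_setequal(s$concordant, c("GAA", "HSPG2"))
  expect_equal(s$discordant, "SERPIN")
  # empty input gives all-zero summary
  s0 <- summarize_transfers(ev[0, ], pairs2)
  expect_equal(s0$n_cases, 0L)
  expect_equal(unname(s0$direction_counts), c(0L, 0L))
})

test_that("GRAVY follows the Kyte-Doolittle table", {
  expect_equal(gravy_score("IIIII"), 4.5)
  expect_equal(gravy_score("R"), -4.5)
  # hand-computed mean for a mixed sequence
  expect_equal(gravy_score("ARNDC"), mean(c(1.8, -4.5, -3.5, -3.5, 2.5)))
})

test_that("property profiles cover every transferred protein", {
  proteome <- data.frame(protein_id = c("P1", "P2"),
                         gene_id = c("G1", "G2"),
                         sequence = c("AAAAAKNDDDDK", "MMMMMMRGGGGGGK"),
                         tags = "")
  ev <- data.frame(protein_id = c("P1", "P2"))
  areas <- data.frame(protein_id = c("P1", "P2"), area = c(10, 100))
  prof <- transfer_property_profile(ev, proteome, areas)
  expect_equal(prof$length, c(12L, 14L))
  expect_equal(prof$abundance_rank, c(2L, 1L))
  expect_equal(prof$gravy[1], gravy_score("AAAAAKNDDDDK"))
})
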