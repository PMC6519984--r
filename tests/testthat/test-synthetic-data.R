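test_that("generation is deterministic and seed-sensitive", {
  cfg <- simulation_config(seed = 1, n_proteins = 10, n_snps = 15)
  p1 <- generate_proteome(cfg)
  p2 <- generate_proteome(cfg)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 10L)
  cfg2 <- simulation_config(seed = 2, n_proteins = 10, n_snps = 15)
  expect_false(identical(generate_proteome(cfg2)$sequence, p1$sequence))
  # whole-study file output is byte-identical under the same seed
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_study(cfg, out_dir = d1)
  simulate_study(cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
})

test_that("proteome respects length range, alphabet and tissue tagging", {
  cfg <- simulation_config(seed = 3, n_proteins = 25,
                           protein_length_range = c(50, 50),
                           placenta_fraction = 0.2)
  p <- generate_proteome(cfg)
  expect_true(all(nchar(p$sequence) == 50))
  expect_equal(sum(p$tags == "tissue-enriched:placenta"), 5L)
  expect_true(all(strsplit(paste(p$sequence, collapse = ""), "")[[1]] %in%
                    c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                      "N", "P", "Q", "R", "S", "T", "V", "W", "Y")))
  expect_error(simulation_config(n_proteins = 0), "n_proteins")
  expect_error(simulation_config(alt_allele_freq = 1.5), "probability")
})

test_that("SAAV annotations are consistent with the proteome", {
  cfg <- simulation_config(seed = 4, n_proteins = 15, n_snps = 40,
                           ambiguous_fraction = 0.5)
  p <- generate_proteome(cfg)
  s <- generate_saav_table(p, cfg)
  expect_equal(nrow(s), 40L)
  expect_false(anyDuplicated(s$snp_id) > 0)
  seqs <- setNames(p$sequence, p$protein_id)
  expect_equal(unname(substring(seqs[s$protein_id], s$pos, s$pos)),
               s$ref_aa)
  expect_true(all(s$ref_aa != s$alt_aa))
  # the planted ambiguous fraction is exact
  ambig <- paste(s$ref_aa, s$alt_aa) %in% c("N D", "D N", "Q E", "E Q")
  expect_equal(sum(ambig), 20L)
  # degenerate and invalid sizes
  expect_equal(nrow(generate_saav_table(p, simulation_config(n_snps = 0))),
               0L)
  tiny <- data.frame(protein_id = "P", gene_id = "G", sequence = "AAAA",
                     tags = "")
  expect_error(
    generate_saav_table(tiny, simulation_config(seed = 1, n_snps = 10)),
    "exceeds")
})

test_that("family genotypes are Mendelian and frequency-driven", {
  cfg <- simulation_config(seed = 5, n_proteins = 10, n_snps = 30,
                           n_pairs = 3)
  p <- generate_proteome(cfg)
  s <- generate_saav_table(p, cfg)
  fam <- generate_family_genotypes(s, cfg)
  expect_equal(nrow(fam$pairs), 3L)
  expect_equal(nrow(fam$genotypes), 2L * 3L * 30L)
  # every child shares an allele with its mother, at every SNP
  for (p_ in seq_len(nrow(fam$pairs))) {
    m <- fam$genotypes[fam$genotypes$sample_id ==
                         fam$pairs$mother_sample[p_], ]
    k <- fam$genotypes[fam$genotypes$sample_id ==
                         fam$pairs$child_sample[p_], ]
    m <- m[order(m$snp_id), ]; k <- k[order(k$snp_id), ]
    ok <- vapply(seq_len(nrow(m)), function(i) {
      mendelian_check(m[i, ], k[i, ])
    }, logical(1))
    expect_true(all(ok))
  }
  # allele-frequency extremes collapse the genotype classes
  f0 <- generate_family_genotypes(s, simulation_config(
    seed = 6, alt_allele_freq = 0))
  expect_true(all(f0$genotypes$klass == "wild_type"))
  f1 <- generate_family_genotypes(s, simulation_config(
    seed = 6, alt_allele_freq = 1))
  expect_true(all(f1$genotypes$klass == "homo_snp"))
})

test_that("detections track allele dosage and saturate at p = 1", {
  cfg <- simulation_config(seed = 7, n_proteins = 30, n_snps = 60,
                           detection_prob_per_copy = 1, transfer_rate = 0)
  sim <- simulate_study(cfg)
  expect_equal(nrow(sim$truth), 0L)  # transfer_rate 0 plants nothing
  # every carrier of a producible variant peptide has the detection
  gk <- paste(sim$genotypes$sample_id, sim$genotypes$snp_id)
  dk <- paste(sim$detections$sample_id[sim$detections$is_variant],
              sim$detections$snp_id[sim$detections$is_variant])
  for (i in seq_len(nrow(sim$genotypes))) {
    g <- sim$genotypes[i, ]
    producible <- g$snp_id %in% sim$variant_db$snp_id
    if (producible && g$klass %in% c("hetero_snp", "homo_snp")) {
      expect_true(paste(g$sample_id, g$snp_id) %in% dk)
    }
  }
  # no variant detections in wild-type individuals without transfer
  wt <- gk[sim$genotypes$klass == "wild_type"]
  expect_length(intersect(dk, wt), 0)
})

test_that("planted transfers satisfy the donor/recipient genotype audit", {
  cfg <- simulation_config(seed = 8, n_proteins = 100, n_snps = 200,
                           detection_prob_per_copy = 1, transfer_rate = 0.3)
  sim <- simulate_study(cfg)
  expect_gt(nrow(sim$truth), 0)
  gk <- paste(sim$genotypes$sample_id, sim$genotypes$snp_id)
  rec_klass <- sim$genotypes$klass[match(
    paste(sim$truth$recipient_sample, sim$truth$snp_id), gk)]
  don_klass <- sim$genotypes$klass[match(
    paste(sim$truth$donor_sample, sim$truth$snp_id), gk)]
  expect_true(all(rec_klass == "wild_type"))
  expect_true(all(don_klass %in% c("hetero_snp", "homo_snp")))
  # each planted event appears as a detection in the recipient
  dk <- paste(sim$detections$sample_id, sim$detections$snp_id)
  expect_true(all(paste(sim$truth$recipient_sample, sim$truth$snp_id) %in%
                    dk))
})

test_that("detection probability is monotone in allele dosage", {
  cfg <- simulation_config(seed = 9, n_proteins = 300, n_snps = 1000,
                           protein_length_range = c(80, 120),
                           detection_prob_per_copy = 0.5, transfer_rate = 0)
  sim <- simulate_study(cfg)
  gt <- sim$genotypes
  gt <- gt[gt$snp_id %in% sim$variant_db$snp_id, ]
  alt <- sim$saav_table$alt_nt[match(gt$snp_id, sim$saav_table$snp_id)]
  dosage <- (gt$allele1 == alt) + (gt$allele2 == alt)
  dk <- paste(sim$detections$sample_id[sim$detections$is_variant],
              sim$detections$snp_id[sim$detections$is_variant])
  detected <- paste(gt$sample_id, gt$snp_id) %in% dk
  rate <- tapply(detected, dosage, mean)
  expect_true(rate[["1"]] > rate[["0"]])
  expect_true(rate[["2"]] > rate[["1"]])
})

test_that("spectrum stubs carry exact b/y m/z values", {
  cfg <- simulation_config(seed = 10, flanking_ion_dropout = 0)
  set.seed(1)
  sp <- generate_spectrum("AHDDDK", 2, cfg)
  # hand-computed from the residue mass table: b2 = A + H + proton,
  # y4 = D+D+D+K + water + proton
  b2 <- 71.03711 + 137.05891 + 1.007276
  y4 <- 3 * 115.02694 + 128.09496 + 18.010565 + 1.007276
  expect_true(any(abs(sp$peaks$mz - b2) < 1e-4))
  expect_true(any(abs(sp$peaks$mz - y4) < 1e-4))
  expect_true(all(sp$peaks$intensity > 0))
  expect_true(!is.unsorted(sp$peaks$mz))
  # dropout extremes drive the flanking check deterministically
  set.seed(2)
  sp0 <- generate_spectrum("AHDDDK", 2,
                           simulation_config(flanking_ion_dropout = 0))
  expect_true(flanking_ion_check(sp0)$pass)
  set.seed(2)
  sp1 <- generate_spectrum("AHDDDK", 2,
                           simulation_config(flanking_ion_dropout = 1))
  expect_false(flanking_ion_check(sp1)$pass)
  expect_error(generate_spectrum("AHDDDK", 9, cfg), "out of range")
})
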