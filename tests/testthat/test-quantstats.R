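test_that("top-3 protein area averages the most intense peptides", {
  expect_equal(top3_protein_area(c(10, 8, 6, 4)), 8)
  expect_equal(top3_protein_area(5), 5)
  expect_true(is.na(top3_protein_area(c(5, 4), require_three = TRUE)))
  expect_true(is.na(top3_protein_area(numeric(0))))
  # peptide area is the max over its PSMs
  df <- data.frame(peptide = c("A", "A", "A", "B"), area = c(3, 9, 1, 6))
  expect_equal(top3_protein_area(df), (9 + 6) / 2)
  # permutation invariance
  set.seed(41)
  x <- runif(10)
  expect_equal(top3_protein_area(x), top3_protein_area(sample(x)))
})

test_that("TMT quantification is median-of-normalized-PSM-ratios", {
  psms <- data.frame(
    protein_ids = c("P1", "P1", "P1", "P2", "P1;P2", "P2"),
    qvalue = c(0.001, 0.001, 0.001, 0.001, 0.001, 0.5),
    ref = c(1, 1, 1, 1, 1, 1),
    chA = c(1, 2, 4, 2, 100, 100))
  m <- tmt_protein_quant(psms, c("ref", "chA"), "ref")
  # shared PSM (row 5) and q-gated PSM (row 6) are excluded; channel
  # median over surviving ratios [1,2,4,2] is 2, so normalized P1 ratios
  # are [0.5,1,2] with median 1 -> log2 = 0
  expect_equal(unname(m["P1", "chA"]), 0)
  expect_equal(unname(m["P2", "chA"]), 0)
  # scale invariance: a global factor on a channel is removed
  psms2 <- psms
  psms2$chA <- psms2$chA * 7
  expect_equal(tmt_protein_quant(psms2, c("ref", "chA"), "ref"), m)
  # zero-reference PSMs are excluded and counted
  psms3 <- psms
  psms3$ref[2] <- 0
  m3 <- tmt_protein_quant(psms3, c("ref", "chA"), "ref")
  expect_equal(attr(m3, "n_excluded_zero_reference"), 1L)
})

test_that("replicate CV is sd over mean on linear ratios", {
  expect_equal(replicate_cv(c(9, 10, 11)), 10)
  expect_equal(replicate_cv(c(5, 5, 5)), 0)
  expect_true(is.na(replicate_cv(3)))
  expect_true(is.na(replicate_cv(c(-1, 1))))
})

test_that("within/between-set CVs recover injected replicate noise", {
  set.seed(42)
  n_pep <- 500
  # six standard replicates per set keep the small-sample bias of the
  # sd estimator below the assertion tolerance
  sets <- rep(c("set1", "set2", "set3"), each = 6)
  truth <- rlnorm(n_pep, 0, 0.5)
  sdlog <- sqrt(log(1 + 0.05^2))  # 5% CV on the linear scale
  x <- matrix(rlnorm(n_pep * 18, log(truth), sdlog), nrow = n_pep)
  cv <- within_between_set_cv(x, sets)
  expect_equal(cv$within_pct, 5, tolerance = 0.1)
  # between-set means carry noise sd/sqrt(3)
  expect_lt(cv$between_pct, cv$within_pct)
})

test_that("inter-individual CV ranking is order-stable", {
  m <- log2(rbind(flat = c(1, 1, 1, 1),
                  wide = c(0.5, 1, 2, 4),
                  mid = c(0.9, 1, 1.1, 1)))
  r <- interindividual_cv_rank(m)
  expect_equal(r$protein_id, c("wide", "mid", "flat"))
  expect_equal(r$cv_pct[3], 0)
  # hand-computed CV for the mid protein
  expect_equal(r$cv_pct[2], 100 * sd(c(0.9, 1, 1.1, 1)) /
                 mean(c(0.9, 1, 1.1, 1)))
  # permuting samples leaves the ranking unchanged
  r2 <- interindividual_cv_rank(m[, c(3, 1, 4, 2)])
  expect_equal(r, r2)
})

test_that("differential testing applies Welch t and BH jointly", {
  # identical groups yield nothing significant
  m <- matrix(rep(1:10, 6), nrow = 10,
              dimnames = list(paste0("p", 1:10), NULL))
  groups <- rep(c("a", "b"), each = 3)
  res <- differential_test(m + 0, groups)
  expect_false(any(res$significant))
  # BH agrees with the hand computation (p * n / rank, cummin from below)
  expect_equal(p.adjust(c(0.001, 0.01, 0.02, 0.9), "BH"),
               c(0.004, 0.02, 0.02 * 4 / 3, 0.9))
  # a strong planted shift is found
  set.seed(43)
  m2 <- matrix(rnorm(100 * 12, sd = 0.1), nrow = 100,
               dimnames = list(paste0("p", 1:100), NULL))
  g2 <- rep(c("a", "b"), each = 6)
  m2[1:5, g2 == "b"] <- m2[1:5, g2 == "b"] + 1
  res2 <- differential_test(m2, g2)
  expect_true(all(res2$significant[1:5]))
  expect_lt(sum(res2$significant[-(1:5)]), 3)
})

test_that("picked FDR keeps pair winners and matches the spec example", {
  # 4 targets (10, 8, 6, 4); the decoy at 7 beats its own target (6)
  scores <- data.frame(
    id = c("g1", "g2", "g3", "g4", "g3"),
    score = c(10, 8, 6, 4, 7),
    is_decoy = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  q <- picked_fdr(scores)
  expect_equal(q$id, c("g1", "g2", "g4"))
  # decoy at rank 3 gives FDR 1/2 above g4; monotone minimum applies
  expect_equal(q$q, c(0, 0, 1 / 3))
  # no surviving decoys: all q = 0
  clean <- data.frame(id = c("g1", "g2"), score = c(5, 3),
                      is_decoy = FALSE)
  expect_equal(picked_fdr(clean)$q, c(0, 0))
  # rank invariance under score doubling
  q2 <- picked_fdr(transform(scores, score = score * 2))
  expect_equal(q2$q, q$q)
  # unpaired decoys warn and act as their own pair
  expect_warning(picked_fdr(data.frame(
    id = c("g1", "gX"), score = c(5, 9), is_decoy = c(FALSE, TRUE))),
    "without a paired target")
})

test_that("picked FDR equals the exhaustive oracle on random small tables", {
  set.seed(44)
  for (i in 1:100) {
    n <- sample(1:6, 1)
    ids <- paste0("g", seq_len(n))
    has_decoy <- runif(n) < 0.6
    scores <- data.frame(id = ids, score = round(runif(n, 0, 20), 2),
                         is_decoy = FALSE)
    if (any(has_decoy)) {
      scores <- rbind(scores, data.frame(
        id = ids[has_decoy],
        score = round(runif(sum(has_decoy), 0, 20), 2), is_decoy = TRUE))
    }
    got <- picked_fdr(scores)
    want <- oracle_picked_fdr(scores)
    got <- got[order(got$id), ]
    want <- want[order(want$id), ]
    expect_equal(got$id, want$id, info = i)
    expect_equal(got$q, want$q, tolerance = 1e-12, info = i)
  }
})

test_that("picked FDR q-values are valid and monotone", {
  set.seed(45)
  scores <- rbind(
    data.frame(id = paste0("g", 1:50), score = runif(50, 0, 10),
               is_decoy = FALSE),
    data.frame(id = paste0("g", 1:50), score = runif(50, 0, 10),
               is_decoy = TRUE))
  q <- picked_fdr(scores)
  expect_true(all(q$q >= 0 & q$q <= 1))
  expect_true(!is.unsorted(q$q))  # sorted by decreasing score
})

test_that("protein-level score is -log10 of the best peptide q-value", {
  expect_equal(protein_level_score(0.01), 2)
  expect_equal(protein_level_score(1), 0)
  expect_equal(protein_level_score(c(0.5, 0.01, 0.9)), 2)
  # adding a worse peptide never lowers the score
  expect_gte(protein_level_score(c(0.01, 0.99)), protein_level_score(0.01))
  # q floored, no infinities
  expect_lt(protein_level_score(0), 16)
})

test_that("tissue-leakage summaries mirror the display conventions", {
  proteome <- data.frame(
    protein_id = paste0("P", 1:10), gene_id = paste0("G", 1:10),
    sequence = "AAAAAA",
    tags = c(rep("tissue-enriched:placenta", 8), "", ""))
  counts <- c(2, 1, 21, 0, 3, 2, 4, 2)
  det <- data.frame(sample_id = "mom1",
                    protein_id = paste0("P", 1:8)[counts > 0],
                    psm_count = counts[counts > 0])
  s <- tissue_leakage_summary(det, proteome, "placenta")
  expect_equal(s$per_sample$median_psms, 2)
  expect_equal(s$per_sample$min_psms, 0)
  expect_equal(s$per_sample$max_psms, 21)
  expect_equal(s$per_sample$n_proteins, 7L)
  # mother:child PSM ratio per pair
  pairs <- data.frame(pair_id = "pair1", mother_sample = "mom1",
                      child_sample = "kid1")
  det2 <- rbind(det, data.frame(sample_id = "kid1",
                                protein_id = c("P1", "P3"),
                                psm_count = c(5, 5)))
  s2 <- tissue_leakage_summary(det2, proteome, "placenta", pairs)
  expect_equal(s2$pair_ratio$ratio, sum(counts) / 10)
  expect_warning(tissue_leakage_summary(det, proteome, "kidney"),
                 "no proteins tagged")
})

test_that("fmol/uL converts to ng/mL through the protein molecular weight", {
  expect_equal(amount_to_concentration(1, 30000), 30)
  expect_equal(amount_to_concentration(0.5, 28000), 14)
  # bijective round trip
  x <- 0.67
  expect_equal(concentration_to_amount(amount_to_concentration(x, 28000),
                                       28000), x, tolerance = 1e-12)
  expect_error(amount_to_concentration(-1, 30000), "positive")
})

test_that("core-set intersection reports proteins seen in every set", {
  lists <- list(set1 = c("a", "b", "c"), set2 = c("b", "c", "d"),
                set3 = c("c", "b"))
  cs <- core_set(lists)
  expect_setequal(cs$core, c("b", "c"))
  expect_equal(cs$n_sets, 3L)
  expect_equal(unname(cs$per_set_counts), c(3L, 3L, 2L))
})
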