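# Synthetic mother-child plasma proteogenomics data: a mini-proteome,
# biallelic coding SNPs with protein-level SAAV annotations, Mendelian
# family genotypes, genotype-driven peptide detections with planted
# cross-placental transfer events, and fragment-spectrum stubs. Every
# generator draws from a sub-stream derived from the single top-level seed,
# so stages are independently reproducible and a full run is byte-identical
# under the same configuration.

#' Simulation configuration
#'
#' Parameters of the synthetic mother-child study. Defaults emulate the
#' design this package targets: two mother-newborn pairs, a mini-proteome
#' with a placenta-enriched subset, common biallelic coding SNPs, and
#' dosage-driven peptide detection with rare cross-placental transfer.
#'
#' @param seed top-level RNG seed (integer).
#' @param n_proteins number of synthetic proteins.
#' @param protein_length_range c(min, max) protein length in residues.
#' @param placenta_fraction fraction of proteins tagged
#'   `tissue-enriched:placenta`.
#' @param aa_freq optional named residue-frequency vector (default uniform
#'   over the 20 standard residues).
#' @param n_snps number of biallelic coding SNPs (one SAAV each).
#' @param alt_allele_freq population alternative-allele frequency.
#' @param ambiguous_fraction fraction of SAAVs deliberately planted as
#'   near-isobaric N<->D / Q<->E substitutions to exercise the curation
#'   filter.
#' @param n_pairs number of mother-child pairs.
#' @param detection_prob_per_copy probability that the peptide produced by
#'   one allele copy is detected in a sample. The default 0.65 reproduces
#'   the observed canonical co-detection rate in heterozygous carriers
#'   (a heterozygote's canonical peptide rides on a single reference
#'   allele copy).
#' @param transfer_rate probability that a variant peptide producible by
#'   only one member of a pair is planted in the other (wild-type) member.
#' @param transfer_psm_scale multiplicative scale on the PSM-count mean of
#'   transferred peptides relative to endogenous ones.
#' @param psm_mean,psm_dispersion negative-binomial mean and dispersion
#'   (`size`) of PSM counts per detected peptide (shifted to be >= 1).
#' @param flanking_ion_dropout probability that a generated variant
#'   spectrum lacks its flanking ions.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_proteins = 30L,
                              protein_length_range = c(120L, 400L),
                              placenta_fraction = 0.2,
                              aa_freq = NULL,
                              n_snps = 60L,
                              alt_allele_freq = 0.3,
                              ambiguous_fraction = 0.05,
                              n_pairs = 2L,
                              detection_prob_per_copy = 0.65,
                              transfer_rate = 0.1,
                              transfer_psm_scale = 1,
                              psm_mean = 4,
                              psm_dispersion = 2,
                              flanking_ion_dropout = 0) {
  assert_count(n_proteins, "n_proteins", min = 1L)
  assert_count(n_snps, "n_snps", min = 0L)
  assert_count(n_pairs, "n_pairs", min = 1L)
  assert_probability(placenta_fraction, "placenta_fraction")
  assert_probability(alt_allele_freq, "alt_allele_freq")
  assert_probability(ambiguous_fraction, "ambiguous_fraction")
  assert_probability(detection_prob_per_copy, "detection_prob_per_copy")
  assert_probability(transfer_rate, "transfer_rate")
  assert_probability(flanking_ion_dropout, "flanking_ion_dropout")
  if (length(protein_length_range) != 2L ||
      protein_length_range[1] > protein_length_range[2] ||
      protein_length_range[1] < 1L) {
    stop("protein_length_range must be c(min, max) with 1 <= min <= max",
         call. = FALSE)
  }
  if (psm_mean <= 0 || psm_dispersion <= 0) {
    stop("psm_mean and psm_dispersion must be positive", call. = FALSE)
  }
  if (!is.null(aa_freq)) {
    if (!setequal(names(aa_freq), STANDARD_AA) || any(aa_freq < 0)) {
      stop("aa_freq must be a non-negative vector named by the 20 standard ",
           "residues", call. = FALSE)
    }
  }
  structure(as.list(environment()), class = "simulation_config")
}

#' Generate a synthetic mini-proteome
#'
#' Random sequences over the 20 standard residues (uniform composition by
#' default), a configurable fraction tagged as placenta-enriched, and
#' deterministic under the configured seed.
#'
#' @param config a [simulation_config()].
#' @return proteome data.frame (`protein_id`, `gene_id`, `sequence`,
#'   `tags`).
#' @export
generate_proteome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(derive_seed(config$seed, 1L), {
    n <- config$n_proteins
    # index into the candidate lengths to avoid sample()'s scalar surprise
    # when the range is degenerate
    cand <- seq.int(config$protein_length_range[1],
                    config$protein_length_range[2])
    lens <- cand[sample.int(length(cand), n, replace = TRUE)]
    freq <- config$aa_freq %||%
      setNames(rep(1 / 20, 20), STANDARD_AA)
    seqs <- vapply(lens, function(L) {
      paste(sample(names(freq), L, replace = TRUE, prob = freq),
            collapse = "")
    }, character(1))
    n_plac <- round(config$placenta_fraction * n)
    tags <- character(n)
    if (n_plac > 0L) {
      tags[sample.int(n, n_plac)] <- "tissue-enriched:placenta"
    }
    data.frame(
      protein_id = sprintf("PROT%04d", seq_len(n)),
      gene_id = sprintf("GENE%04d", seq_len(n)),
      sequence = seqs, tags = tags, stringsAsFactors = FALSE)
  })
}

#' Generate SAAV annotations for a proteome
#'
#' Samples distinct (protein, position) sites, records the true reference
#' residue and a different alternative residue, and plants a configured
#' fraction of deliberately ambiguous N<->D / Q<->E substitutions (at
#' N/D/Q/E sites where available). Each record carries a distinct SNP id
#' and a reference/alternative nucleotide pair for the genotype layer.
#'
#' @param proteome proteome data.frame.
#' @param config a [simulation_config()].
#' @return SAAV data.frame (`snp_id`, `protein_id`, `pos`, `ref_aa`,
#'   `alt_aa`, `ref_nt`, `alt_nt`).
#' @export
generate_saav_table <- function(proteome, config) {
  stopifnot(inherits(config, "simulation_config"))
  n_snps <- config$n_snps
  total <- sum(nchar(proteome$sequence))
  if (n_snps > total) {
    stop("n_snps exceeds total residue count (", total, ")", call. = FALSE)
  }
  if (n_snps == 0L) {
    return(data.frame(snp_id = character(), protein_id = character(),
                      pos = integer(), ref_aa = character(),
                      alt_aa = character(), ref_nt = character(),
                      alt_nt = character()))
  }
  withr::with_seed(derive_seed(config$seed, 2L), {
    site_protein <- rep(proteome$protein_id, nchar(proteome$sequence))
    site_pos <- unlist(lapply(nchar(proteome$sequence), seq_len))
    AMBIG_PARTNER <- c(N = "D", D = "N", Q = "E", E = "Q")
    n_ambig <- round(config$ambiguous_fraction * n_snps)
    residue_at <- function(i) {
      substring(proteome$sequence[match(site_protein[i], proteome$protein_id)],
                site_pos[i], site_pos[i])
    }
    all_ref <- vapply(seq_along(site_protein), residue_at, character(1))
    ambig_pool <- which(all_ref %in% names(AMBIG_PARTNER))
    n_ambig <- min(n_ambig, length(ambig_pool))
    picked_ambig <- if (n_ambig > 0L) {
      sample(ambig_pool, n_ambig)
    } else integer(0)
    rest_pool <- setdiff(seq_along(site_protein), picked_ambig)
    picked_rest <- sample(rest_pool, n_snps - n_ambig)
    idx <- c(picked_ambig, picked_rest)
    ref_aa <- all_ref[idx]
    alt_aa <- character(n_snps)
    is_ambig <- seq_len(n_snps) <= n_ambig
    alt_aa[is_ambig] <- AMBIG_PARTNER[ref_aa[is_ambig]]
    alt_aa[!is_ambig] <- vapply(ref_aa[!is_ambig], function(r) {
      # avoid creating an accidental ambiguous class
      banned <- c(r, AMBIG_PARTNER[r])
      sample(setdiff(STANDARD_AA, banned[!is.na(banned)]), 1L)
    }, character(1))
    nt <- vapply(seq_len(n_snps), function(i) {
      sample(NUCLEOTIDES, 2L)
    }, character(2))
    out <- data.frame(
      snp_id = sprintf("rs%06d", seq_len(n_snps)),
      protein_id = site_protein[idx], pos = site_pos[idx],
      ref_aa = ref_aa, alt_aa = alt_aa,
      ref_nt = nt[1, ], alt_nt = nt[2, ], stringsAsFactors = FALSE)
    out <- out[order(out$protein_id, out$pos), , drop = FALSE]
    out$snp_id <- sprintf("rs%06d", seq_len(n_snps))
    rownames(out) <- NULL
    out
  })
}

#' Generate Mendelian mother-child genotypes
#'
#' For each SNP and pair, the mother's two alleles are drawn independently
#' with the configured alternative-allele frequency; a latent father
#' genotype is drawn the same way; the child inherits one allele picked at
#' random from the mother and one from the father. Only mother and child
#' calls are emitted, matching the study design (fathers were not
#' sampled). Every child therefore shares at least one allele with its
#' mother by construction.
#'
#' @param saav_table SAAV data.frame (supplies `snp_id`, `ref_nt`,
#'   `alt_nt`).
#' @param config a [simulation_config()].
#' @return list with `genotypes` (data.frame `sample_id`, `snp_id`,
#'   `allele1`, `allele2`, `ref_allele`, `klass`) and `pairs` (data.frame
#'   `pair_id`, `mother_sample`, `child_sample`).
#' @export
generate_family_genotypes <- function(saav_table, config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(derive_seed(config$seed, 3L), {
    pairs <- data.frame(
      pair_id = sprintf("pair%d", seq_len(config$n_pairs)),
      mother_sample = sprintf("pair%d_mother", seq_len(config$n_pairs)),
      child_sample = sprintf("pair%d_child", seq_len(config$n_pairs)),
      stringsAsFactors = FALSE)
    draw <- function(ref, alt) {
      if (runif(1) < config$alt_allele_freq) alt else ref
    }
    rows <- list()
    for (p in seq_len(config$n_pairs)) {
      for (s in seq_len(nrow(saav_table))) {
        ref <- saav_table$ref_nt[s]; alt <- saav_table$alt_nt[s]
        mother <- c(draw(ref, alt), draw(ref, alt))
        father <- c(draw(ref, alt), draw(ref, alt))
        child <- c(sample(mother, 1L), sample(father, 1L))
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = c(pairs$mother_sample[p], pairs$child_sample[p]),
          snp_id = saav_table$snp_id[s],
          allele1 = c(mother[1], child[1]), allele2 = c(mother[2], child[2]),
          ref_allele = ref, stringsAsFactors = FALSE)
      }
    }
    genotypes <- do.call(rbind, rows)
    genotypes$klass <- classify_genotype(genotypes$allele1,
                                         genotypes$allele2,
                                         genotypes$ref_allele)
    list(genotypes = genotypes, pairs = pairs)
  })
}

# PSM counts for a detected peptide: negative binomial shifted by one so a
# detection always has at least one supporting spectrum.
draw_psm_count <- function(n, mean, dispersion, scale = 1) {
  1L + rnbinom(n, size = dispersion, mu = max(mean * scale - 1, 1e-6))
}

#' Generate genotype-driven detections and planted transfer events
#'
#' A sample detects a variant peptide with probability
#' `1 - (1 - detection_prob_per_copy)^dosage` where dosage is its
#' alternative-allele count; canonical counterparts follow the same law on
#' the reference-allele dosage. With probability `transfer_rate`, a variant
#' peptide producible by exactly one member of a pair (the carrier) while
#' the other member is wild type is additionally planted in the wild-type
#' member's detections; these plantings are the ground truth returned as
#' `truth`. PSM counts are negative-binomial, MS1 areas log-normal. SNPs
#' whose substitution yields no valid tryptic variant peptide produce no
#' detections.
#'
#' @param proteome proteome data.frame.
#' @param saav_table SAAV data.frame.
#' @param family output of [generate_family_genotypes()].
#' @param config a [simulation_config()].
#' @return list with `detections` (data.frame `sample_id`, `peptide`,
#'   `protein_id`, `snp_id`, `is_variant`, `ref_aa`, `alt_aa`,
#'   `variant_pos`, `psm_count`, `ms1_area`, `spectrum_id`), `truth`
#'   (planted transfers: `pair_id`, `snp_id`, `peptide`, `protein_id`,
#'   `donor_sample`, `recipient_sample`, `direction`), and `variant_db`.
#' @export
generate_detections <- function(proteome, saav_table, family, config) {
  stopifnot(inherits(config, "simulation_config"))
  variant_db <- build_variant_db(proteome, saav_table)
  genotypes <- family$genotypes
  pairs <- family$pairs
  withr::with_seed(derive_seed(config$seed, 4L), {
    p_copy <- config$detection_prob_per_copy
    det_rows <- list()
    truth_rows <- list()
    add_detection <- function(sample_id, peptide, protein_id, snp_id,
                              is_variant, ref_aa, alt_aa, variant_pos,
                              psm_scale = 1) {
      det_rows[[length(det_rows) + 1L]] <<- data.frame(
        sample_id = sample_id, peptide = peptide, protein_id = protein_id,
        snp_id = snp_id, is_variant = is_variant, ref_aa = ref_aa,
        alt_aa = alt_aa, variant_pos = variant_pos,
        psm_count = draw_psm_count(1L, config$psm_mean,
                                   config$psm_dispersion, psm_scale),
        ms1_area = rlnorm(1L, meanlog = log(1e6), sdlog = 1),
        stringsAsFactors = FALSE)
    }
    gkey <- paste(genotypes$sample_id, genotypes$snp_id)
    dosage_of <- function(sample_id, s) {
      g <- genotypes[match(paste(sample_id, s$snp_id), gkey), ]
      sum(c(g$allele1, g$allele2) == s$alt_nt)
    }
    samples <- c(rbind(pairs$mother_sample, pairs$child_sample))
    # detection is a property of the (sample, peptide): SNPs sharing one
    # canonical tryptic peptide must not each get an independent draw
    canon_decided <- new.env(parent = emptyenv())
    for (si in seq_len(nrow(saav_table))) {
      s <- saav_table[si, ]
      vdb <- variant_db[variant_db$snp_id == s$snp_id, , drop = FALSE]
      if (nrow(vdb) == 0L) next  # substitution yields no variant peptide
      vpep <- vdb$peptide[1]
      vpos <- vdb$variant_pos[1]
      cpep <- vdb$canonical_peptide[1]
      for (smp in samples) {
        dos <- dosage_of(smp, s)
        if (dos > 0L && runif(1) < 1 - (1 - p_copy)^dos) {
          add_detection(smp, vpep, s$protein_id, s$snp_id, TRUE,
                        s$ref_aa, s$alt_aa, vpos)
        }
        ref_dos <- 2L - dos
        if (!is.na(cpep) && ref_dos > 0L) {
          ck <- paste(smp, cpep)
          if (is.null(canon_decided[[ck]])) {
            canon_decided[[ck]] <- runif(1) < 1 - (1 - p_copy)^ref_dos
            if (canon_decided[[ck]]) {
              add_detection(smp, cpep, s$protein_id, s$snp_id, FALSE,
                            s$ref_aa, s$alt_aa, NA_integer_)
            }
          }
        }
      }
      # transfer planting: exactly one member of a pair can produce the
      # variant peptide, the other is wild type at the SNP
      for (p in seq_len(nrow(pairs))) {
        dm <- dosage_of(pairs$mother_sample[p], s)
        dc <- dosage_of(pairs$child_sample[p], s)
        if (xor(dm > 0L, dc > 0L) && runif(1) < config$transfer_rate) {
          donor <- if (dm > 0L) pairs$mother_sample[p] else
            pairs$child_sample[p]
          recipient <- if (dm > 0L) pairs$child_sample[p] else
            pairs$mother_sample[p]
          direction <- if (dm > 0L) "mother_to_baby" else "baby_to_mother"
          add_detection(recipient, vpep, s$protein_id, s$snp_id, TRUE,
                        s$ref_aa, s$alt_aa, vpos,
                        psm_scale = config$transfer_psm_scale)
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            pair_id = pairs$pair_id[p], snp_id = s$snp_id, peptide = vpep,
            protein_id = s$protein_id, donor_sample = donor,
            recipient_sample = recipient, direction = direction,
            stringsAsFactors = FALSE)
        }
      }
    }
    empty_det <- data.frame(
      sample_id = character(), peptide = character(),
      protein_id = character(), snp_id = character(), is_variant = logical(),
      ref_aa = character(), alt_aa = character(), variant_pos = integer(),
      psm_count = integer(), ms1_area = numeric(),
      stringsAsFactors = FALSE)
    detections <- if (length(det_rows)) do.call(rbind, det_rows) else
      empty_det
    truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
      data.frame(pair_id = character(), snp_id = character(),
                 peptide = character(), protein_id = character(),
                 donor_sample = character(), recipient_sample = character(),
                 direction = character(), stringsAsFactors = FALSE)
    detections$spectrum_id <- ifelse(
      detections$is_variant,
      paste(detections$sample_id, detections$snp_id, sep = "."),
      NA_character_)
    rownames(detections) <- NULL
    list(detections = detections, truth = truth, variant_db = variant_db)
  })
}

#' Generate a fragment-spectrum stub
#'
#' Singly charged b/y ion series computed from the residue mass table with
#' log-normal intensities; with probability `flanking_ion_dropout` the
#' ions at the cleavage sites flanking `variant_pos` are omitted and the
#' spectrum is labelled `dropped = TRUE`. Flanking ions that survive are
#' drawn at elevated intensity, reflecting the favorable fragmentation the
#' curation rule relies on.
#'
#' @param peptide peptide sequence.
#' @param variant_pos 1-based substituted-residue position in the peptide.
#' @param config a [simulation_config()].
#' @param spectrum_id identifier stored in the stub.
#' @return spectrum list (`spectrum_id`, `peptide`, `variant_pos`,
#'   `precursor_charge`, `pepmass`, `peaks`, `dropped`).
#' @export
generate_spectrum <- function(peptide, variant_pos, config,
                              spectrum_id = peptide) {
  stopifnot(inherits(config, "simulation_config"))
  assert_sequence(peptide)
  n <- nchar(peptide)
  if (variant_pos < 1L || variant_pos > n) {
    stop("variant_pos out of range", call. = FALSE)
  }
  theo <- fragment_ions(peptide)
  flank_sites <- intersect(c(variant_pos - 1L, variant_pos),
                           seq_len(n - 1L))
  dropped <- runif(1) < config$flanking_ion_dropout
  keep <- if (dropped) !(theo$site %in% flank_sites) else
    rep(TRUE, nrow(theo))
  theo <- theo[keep, , drop = FALSE]
  intensity <- rlnorm(nrow(theo), meanlog = log(100), sdlog = 0.3)
  intensity[theo$site %in% flank_sites] <-
    intensity[theo$site %in% flank_sites] * 4
  o <- order(theo$mz)
  list(spectrum_id = spectrum_id, peptide = peptide,
       variant_pos = as.integer(variant_pos), precursor_charge = 2L,
       pepmass = (peptide_mass(peptide) + 2 * MASS_PROTON) / 2,
       peaks = data.frame(mz = theo$mz[o], intensity = intensity[o]),
       dropped = dropped)
}

#' Run the full synthetic-data generator
#'
#' Chains proteome, SAAV, genotype, detection and spectrum generation and
#' (optionally) writes the plain-file handoff formats to `out_dir`.
#'
#' @param config a [simulation_config()].
#' @param out_dir optional output directory; created if needed.
#' @return list with `proteome`, `saav_table`, `genotypes`, `pairs`,
#'   `detections`, `truth`, `variant_db`, `spectra`.
#' @export
simulate_study <- function(config = simulation_config(), out_dir = NULL) {
  proteome <- generate_proteome(config)
  saav_table <- generate_saav_table(proteome, config)
  family <- generate_family_genotypes(saav_table, config)
  det <- generate_detections(proteome, saav_table, family, config)
  spectra <- withr::with_seed(derive_seed(config$seed, 5L), {
    var_det <- det$detections[as.logical(det$detections$is_variant), ,
                              drop = FALSE]
    out <- lapply(seq_len(nrow(var_det)), function(i) {
      generate_spectrum(var_det$peptide[i], var_det$variant_pos[i], config,
                        spectrum_id = var_det$spectrum_id[i])
    })
    setNames(out, var_det$spectrum_id)
  })
  result <- list(proteome = proteome, saav_table = saav_table,
                 genotypes = family$genotypes, pairs = family$pairs,
                 detections = det$detections, truth = det$truth,
                 variant_db = det$variant_db, spectra = spectra)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_proteome_fasta(proteome, file.path(out_dir, "proteome.fasta"))
    write_tsv(saav_table, file.path(out_dir, "saav_table.tsv"))
    write_tsv(family$genotypes, file.path(out_dir, "genotypes.tsv"))
    write_tsv(family$pairs, file.path(out_dir, "pairs.tsv"))
    write_tsv(det$detections, file.path(out_dir, "detections.tsv"))
    write_tsv(det$truth, file.path(out_dir, "transfer_truth.tsv"))
    write_tsv(det$variant_db, file.path(out_dir, "variant_db.tsv"))
    write_mgf(spectra, file.path(out_dir, "spectra.mgf"))
  }
  result
}
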