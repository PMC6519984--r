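# Spectrum-level curation of variant peptide detections: removal of
# near-isobaric substitution classes and a flanking fragment-ion check
# that demands site-localizing evidence for the substituted residue, plus
# the heterozygote canonical co-detection rate.

AMBIGUOUS_PAIRS <- list(c("N", "D"), c("D", "N"), c("Q", "E"), c("E", "Q"))

#' Remove near-isobaric substitution classes
#'
#' N<->D (delta 0.98402 Da) and Q<->E (delta 0.98402 Da) substitutions are
#' indistinguishable from deamidation/isotope co-isolation artifacts at
#' typical MS2 accuracy, so detections in these classes are removed
#' wholesale. I<->L (mass-identical) removal is available behind a flag but
#' off by default. The filter partitions its input: `kept` and `removed`
#' are disjoint and their union is the input.
#'
#' @param detections data.frame with columns `ref_aa`, `alt_aa`.
#' @param remove_ile_leu logical; additionally remove I<->L.
#' @return list with data.frames `kept` and `removed`.
#' @export
ambiguous_substitution_filter <- function(detections,
                                          remove_ile_leu = FALSE) {
  stopifnot(all(c("ref_aa", "alt_aa") %in% names(detections)))
  pairs <- AMBIGUOUS_PAIRS
  if (remove_ile_leu) {
    pairs <- c(pairs, list(c("I", "L"), c("L", "I")))
  }
  tag <- paste(detections$ref_aa, detections$alt_aa)
  bad <- tag %in% vapply(pairs, paste, character(1), collapse = " ")
  list(kept = detections[!bad, , drop = FALSE],
       removed = detections[bad, , drop = FALSE])
}

#' Flanking fragment-ion check for a variant spectrum
#'
#' A single amino acid substitution is only site-localized when fragment
#' ions bracket the substituted residue. The check computes theoretical
#' singly charged b/y ions and passes a spectrum iff
#' (a) at least one matched ion cleaves immediately N-terminal to
#' `variant_pos` and at least one immediately C-terminal (either series),
#' matched within `tol_da`; when the variant residue is terminal, the
#' single interior flanking site must be matched by both a b- and a y-ion;
#' and (b) the summed intensity of the flanking matches exceeds the median
#' intensity of all matched fragment ions. Both parts can be toggled.
#'
#' @param spectrum list with `peptide`, `variant_pos`, and `peaks` (a
#'   data.frame with `mz`, `intensity`), as produced by
#'   [generate_spectrum()] or [read_mgf()].
#' @param tol_da absolute fragment m/z tolerance in Da (default 0.02).
#' @param either_side logical; relax rule (a) to require only one flanking
#'   site matched (default FALSE, i.e. both sides required).
#' @param check_intensity logical; apply rule (b).
#' @return list with `pass` (logical), `reason` (string), and `evidence`
#'   (data.frame of matched ions with a `flanking` flag).
#' @export
flanking_ion_check <- function(spectrum, tol_da = 0.02, either_side = FALSE,
                               check_intensity = TRUE) {
  pos <- spectrum$variant_pos
  pep <- spectrum$peptide
  if (is.null(pos) || is.na(pos)) {
    stop("spectrum has no variant_pos", call. = FALSE)
  }
  n <- nchar(pep)
  peaks <- spectrum$peaks
  if (is.null(peaks) || nrow(peaks) == 0L) {
    return(list(pass = FALSE, reason = "empty peak list",
                evidence = data.frame()))
  }
  theo <- fragment_ions(pep)
  match_idx <- vapply(theo$mz, function(mz) {
    d <- abs(peaks$mz - mz)
    i <- which.min(d)
    if (d[i] <= tol_da) i else NA_integer_
  }, integer(1))
  matched <- theo[!is.na(match_idx), , drop = FALSE]
  matched$mz_observed <- peaks$mz[match_idx[!is.na(match_idx)]]
  matched$intensity <- peaks$intensity[match_idx[!is.na(match_idx)]]
  # flanking cleavage sites: site pos-1 is immediately N-terminal to the
  # variant residue, site pos immediately C-terminal
  n_site <- pos - 1L
  c_site <- pos
  matched$flanking <- matched$site %in% c(n_site, c_site) &
    matched$site >= 1L & matched$site <= n - 1L
  if (pos == 1L || pos == n) {
    # terminal residue: single interior flanking site, needs both series
    site <- if (pos == 1L) 1L else n - 1L
    fl <- matched[matched$site == site, , drop = FALSE]
    rule_a <- all(c("b", "y") %in% fl$series)
  } else if (either_side) {
    rule_a <- any(matched$site == n_site) || any(matched$site == c_site)
  } else {
    rule_a <- any(matched$site == n_site) && any(matched$site == c_site)
  }
  if (!rule_a) {
    return(list(pass = FALSE, reason = "flanking ions not matched",
                evidence = matched))
  }
  if (check_intensity) {
    fl_sum <- sum(matched$intensity[matched$flanking])
    med <- median(matched$intensity)
    if (!(fl_sum > med)) {
      return(list(pass = FALSE,
                  reason = "flanking intensity below median of matches",
                  evidence = matched))
    }
  }
  list(pass = TRUE, reason = "ok", evidence = matched)
}

#' Curate a detection table against its spectra
#'
#' Applies the ambiguous-substitution filter and the flanking-ion check to
#' every variant detection, annotating `curated` (logical) and
#' `curation_reason`. Canonical (non-variant) detections pass through
#' untouched with `curated = TRUE`. Detections whose substitution class is
#' ambiguous are removed from the returned table (they are counted in the
#' attached summary).
#'
#' @param detections detection data.frame (needs `spectrum_id`, `ref_aa`,
#'   `alt_aa`, `is_variant`).
#' @param spectra named list of spectra keyed by spectrum id.
#' @param tol_da fragment match tolerance.
#' @param drop_ambiguous logical; remove ambiguous substitution classes.
#' @param either_side,check_intensity passed to [flanking_ion_check()].
#' @return detection data.frame with `curated` and `curation_reason`
#'   columns; attribute `curation_summary` carries counts.
#' @export
curate_detections <- function(detections, spectra, tol_da = 0.02,
                              drop_ambiguous = TRUE, either_side = FALSE,
                              check_intensity = TRUE) {
  det <- detections
  n_ambiguous <- 0L
  if (drop_ambiguous) {
    is_var <- as.logical(det$is_variant)
    var <- ambiguous_substitution_filter(det[is_var, , drop = FALSE])
    n_ambiguous <- nrow(var$removed)
    det <- rbind(det[!is_var, , drop = FALSE], var$kept)
  }
  det$curated <- TRUE
  det$curation_reason <- "not a variant"
  for (i in which(as.logical(det$is_variant))) {
    sid <- det$spectrum_id[i]
    sp <- spectra[[sid]]
    if (is.null(sp)) {
      det$curated[i] <- FALSE
      det$curation_reason[i] <- "no spectrum"
      next
    }
    res <- flanking_ion_check(sp, tol_da, either_side, check_intensity)
    det$curated[i] <- res$pass
    det$curation_reason[i] <- res$reason
  }
  rownames(det) <- NULL
  attr(det, "curation_summary") <- list(
    n_input = nrow(detections), n_ambiguous_removed = n_ambiguous,
    n_variant = sum(as.logical(det$is_variant)),
    n_curated = sum(det$curated[as.logical(det$is_variant)]))
  det
}

#' Heterozygote canonical co-detection rate
#'
#' Over all (sample, SAAV) combinations where the individual is
#' heterozygous and the variant peptide was detected: the percentage in
#' which the corresponding canonical (reference-allele) peptide was also
#' detected in the same sample. Pairs whose canonical counterpart is
#' undefined (allele-dependent digestion boundaries) are excluded. With no
#' qualifying heterozygous case the rate is undefined and reported as
#' `NA` with `n = 0`, never as 0%.
#'
#' @param detections detection data.frame (`sample_id`, `snp_id`,
#'   `peptide`, `is_variant`).
#' @param genotypes genotype data.frame (`sample_id`, `snp_id`, `klass`).
#' @param variant_db variant peptide database from [build_variant_db()]
#'   (supplies `canonical_peptide` per SNP).
#' @return list with `n_cases`, `n_codetected`, `pct` (one decimal or NA).
#' @export
heterozygote_canonical_rate <- function(detections, genotypes, variant_db) {
  var_det <- detections[as.logical(detections$is_variant), , drop = FALSE]
  key <- function(df) paste(df$sample_id, df$snp_id)
  klass <- genotypes$klass[match(key(var_det), key(genotypes))]
  var_det <- var_det[!is.na(klass) & klass == "hetero_snp", , drop = FALSE]
  counterpart <- variant_db$canonical_peptide[
    match(var_det$snp_id, variant_db$snp_id)]
  defined <- !is.na(counterpart)
  var_det <- var_det[defined, , drop = FALSE]
  counterpart <- counterpart[defined]
  if (nrow(var_det) == 0L) {
    return(list(n_cases = 0L, n_codetected = 0L, pct = NA_real_))
  }
  canon_key <- paste(detections$sample_id, detections$peptide)
  hit <- paste(var_det$sample_id, counterpart) %in% canon_key
  list(n_cases = nrow(var_det), n_codetected = sum(hit),
       pct = round(100 * mean(hit), 1))
}

# ---- MGF interchange --------------------------------------------------------

#' Read and write Mascot Generic Format spectra
#'
#' A minimal MGF dialect: `BEGIN IONS`/`END IONS` blocks with `TITLE`
#' (spectrum id), `PEPMASS`, `CHARGE`, optional `SEQ` and `VARIANTPOS`
#' annotation keys, and one `m/z intensity` pair per line. Unknown keys are
#' ignored on read.
#'
#' @param path MGF file path.
#' @return named list of spectra (each a list with `spectrum_id`,
#'   `peptide`, `variant_pos`, `precursor_charge`, `pepmass`, `peaks`).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (lines[i] == "BEGIN IONS") {
      sp <- list(spectrum_id = NA_character_, peptide = NA_character_,
                 variant_pos = NA_integer_, precursor_charge = NA_integer_,
                 pepmass = NA_real_)
      mz <- numeric(0); int <- numeric(0)
      i <- i + 1L
      while (lines[i] != "END IONS") {
        ln <- lines[i]
        if (grepl("^TITLE=", ln)) sp$spectrum_id <- sub("^TITLE=", "", ln)
        else if (grepl("^SEQ=", ln)) sp$peptide <- sub("^SEQ=", "", ln)
        else if (grepl("^VARIANTPOS=", ln)) {
          sp$variant_pos <- as.integer(sub("^VARIANTPOS=", "", ln))
        } else if (grepl("^PEPMASS=", ln)) {
          sp$pepmass <- as.numeric(strsplit(
            sub("^PEPMASS=", "", ln), "\\s+")[[1]][1])
        } else if (grepl("^CHARGE=", ln)) {
          sp$precursor_charge <- as.integer(gsub("[^0-9]", "", ln))
        } else if (grepl("^[0-9]", ln)) {
          xy <- as.numeric(strsplit(ln, "\\s+")[[1]])
          mz <- c(mz, xy[1]); int <- c(int, xy[2])
        }
        i <- i + 1L
      }
      o <- order(mz)
      sp$peaks <- data.frame(mz = mz[o], intensity = int[o])
      out[[sp$spectrum_id]] <- sp
    }
    i <- i + 1L
  }
  out
}

#' @rdname read_mgf
#' @param spectra named list of spectra.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", sp$spectrum_id), con)
    if (!is.na(sp$pepmass)) {
      writeLines(sprintf("PEPMASS=%.6f", sp$pepmass), con)
    }
    if (!is.na(sp$precursor_charge)) {
      writeLines(sprintf("CHARGE=%d+", sp$precursor_charge), con)
    }
    if (!is.na(sp$peptide)) writeLines(paste0("SEQ=", sp$peptide), con)
    if (!is.na(sp$variant_pos)) {
      writeLines(sprintf("VARIANTPOS=%d", sp$variant_pos), con)
    }
    writeLines(sprintf("%.6f %.2f", sp$peaks$mz, sp$peaks$intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}
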