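# Quantification and statistics conventions: top-3 MS1 protein areas,
# median PSM-ratio TMT quantification with per-channel median
# normalization, replicate CVs from pooled internal standards, Welch-t/BH
# differential testing, picked target-decoy FDR, best-peptide protein
# scores, tissue-leakage summaries and the fmol/uL -> ng/mL conversion.

#' Top-3 protein MS1 area
#'
#' Protein MS1 precursor area = mean of the three most intense peptide
#' areas, where each peptide's area is the highest area among its PSMs.
#' With fewer than three peptides the available ones are averaged (set
#' `require_three = TRUE` to return `NA` instead).
#'
#' @param peptide_areas either a numeric vector of per-peptide areas, or a
#'   data.frame with columns `peptide` and `area` (multiple PSM rows per
#'   peptide are reduced by max).
#' @param require_three logical; `NA` unless >= 3 peptides have areas.
#' @return protein area (numeric scalar), `NA` if no areas.
#' @examples
#' top3_protein_area(c(10, 8, 6, 4))  # 8
#' @export
top3_protein_area <- function(peptide_areas, require_three = FALSE) {
  if (is.data.frame(peptide_areas)) {
    peptide_areas <- tapply(peptide_areas$area, peptide_areas$peptide, max)
  }
  areas <- sort(as.numeric(peptide_areas), decreasing = TRUE)
  areas <- areas[!is.na(areas)]
  if (length(areas) == 0L) return(NA_real_)
  if (require_three && length(areas) < 3L) return(NA_real_)
  mean(areas[seq_len(min(3L, length(areas)))])
}

#' TMT protein quantification from PSM reporter intensities
#'
#' Per-PSM channel ratios against the pooled internal-standard channel,
#' per-channel median normalization (each channel's ratios divided by that
#' channel's median ratio), then protein values as the median of its PSM
#' ratios, returned as log2. Only PSMs mapping to a single protein and
#' passing the q-value gate contribute; PSMs with a zero internal-standard
#' intensity are excluded and counted.
#'
#' @param psms data.frame with `protein_ids` (";"-separated; shared PSMs
#'   have more than one id), `qvalue`, and one numeric column per channel.
#' @param channels character vector of channel column names.
#' @param internal_standard_channel name of the reference channel.
#' @param qvalue_max q-value gate (default 0.01).
#' @return matrix of log2 ratios, proteins x channels (reference channel
#'   excluded); attribute `n_excluded_zero_reference` counts dropped PSMs.
#' @export
tmt_protein_quant <- function(psms, channels, internal_standard_channel,
                              qvalue_max = 0.01) {
  stopifnot(internal_standard_channel %in% channels,
            all(channels %in% names(psms)))
  keep <- !grepl(";", psms$protein_ids) & psms$qvalue < qvalue_max
  psms <- psms[keep, , drop = FALSE]
  ref <- psms[[internal_standard_channel]]
  zero_ref <- is.na(ref) | ref <= 0
  psms <- psms[!zero_ref, , drop = FALSE]
  ref <- ref[!zero_ref]
  ratio_channels <- setdiff(channels, internal_standard_channel)
  ratios <- vapply(ratio_channels, function(ch) psms[[ch]] / ref,
                   numeric(nrow(psms)))
  ratios <- matrix(ratios, nrow = nrow(psms),
                   dimnames = list(NULL, ratio_channels))
  # per-channel median normalization
  med <- apply(ratios, 2L, median, na.rm = TRUE)
  ratios <- sweep(ratios, 2L, med, "/")
  proteins <- sort(unique(psms$protein_ids))
  out <- vapply(proteins, function(p) {
    apply(ratios[psms$protein_ids == p, , drop = FALSE], 2L, median,
          na.rm = TRUE)
  }, numeric(length(ratio_channels)))
  out <- matrix(out, nrow = length(ratio_channels),
                dimnames = list(ratio_channels, proteins))
  structure(log2(t(out)),
            n_excluded_zero_reference = sum(zero_ref))
}

#' Coefficient of variation of replicate measurements
#'
#' CV% = sd/mean x 100, computed on linear-scale ratios. Undefined (NA)
#' when fewer than two values or the mean is zero.
#'
#' @param values numeric vector of replicate values (linear scale).
#' @return CV in percent.
#' @examples
#' replicate_cv(c(9, 10, 11))  # 10
#' @export
replicate_cv <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) return(NA_real_)
  m <- mean(values)
  if (m == 0) return(NA_real_)
  100 * sd(values) / m
}

#' Within- and between-set CV from pooled internal standards
#'
#' The pooled internal standard is labeled in several channels of every
#' multiplex set. Within-set CV: per peptide and set, the CV across that
#' set's standard replicate channels, averaged over peptides and then
#' sets. Between-set CV: per peptide, the CV across the per-set mean
#' standard values, averaged over peptides.
#'
#' @param standard_values numeric array/matrix-like data.frame with one
#'   row per peptide; columns are internal-standard replicate channels,
#'   named by set via `set_of`.
#' @param set_of character/factor vector, one entry per column, giving the
#'   TMT set of that replicate channel.
#' @return list with `within_pct` and `between_pct`.
#' @export
within_between_set_cv <- function(standard_values, set_of) {
  x <- as.matrix(standard_values)
  stopifnot(ncol(x) == length(set_of))
  sets <- unique(set_of)
  per_set_cv <- vapply(sets, function(s) {
    cols <- x[, set_of == s, drop = FALSE]
    mean(apply(cols, 1L, replicate_cv), na.rm = TRUE)
  }, numeric(1))
  set_means <- vapply(sets, function(s) {
    rowMeans(x[, set_of == s, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(x)))
  between <- mean(apply(matrix(set_means, nrow = nrow(x)), 1L,
                        replicate_cv), na.rm = TRUE)
  list(within_pct = mean(per_set_cv, na.rm = TRUE), between_pct = between)
}

#' Rank proteins by inter-individual CV
#'
#' Per-protein CV across individuals computed on linear ratios (the input
#' matrix holds log2 ratios and is exponentiated first), sorted from high
#' to low; ties break by protein id. Sample order is irrelevant.
#'
#' @param quant_matrix proteins x samples matrix of log2 ratios.
#' @return data.frame `protein_id`, `cv_pct`, sorted descending.
#' @export
interindividual_cv_rank <- function(quant_matrix) {
  stopifnot(ncol(quant_matrix) >= 3L)
  linear <- 2^quant_matrix
  cv <- apply(linear, 1L, replicate_cv)
  out <- data.frame(protein_id = rownames(quant_matrix), cv_pct = cv,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$cv_pct, out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Two-group differential test with BH correction
#'
#' Welch's t-test (unequal variances) per protein row, Benjamini-Hochberg
#' q-values, and the significant set defined as p < alpha AND q < fdr.
#' Rows with zero variance in both groups and equal means get p = 1.
#'
#' @param quant_matrix proteins x samples matrix (log2 ratios).
#' @param groups two-level factor/character vector, one entry per column.
#' @param alpha p-value cutoff (default 0.01).
#' @param fdr BH q-value cutoff (default 0.01).
#' @return data.frame `protein_id`, `p`, `q`, `significant`.
#' @export
differential_test <- function(quant_matrix, groups, alpha = 0.01,
                              fdr = 0.01) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2L, length(groups) == ncol(quant_matrix))
  g1 <- groups == levels(groups)[1]
  p <- apply(quant_matrix, 1L, function(x) {
    a <- x[g1]; b <- x[!g1]
    if (sd(a, na.rm = TRUE) == 0 && sd(b, na.rm = TRUE) == 0) {
      return(if (isTRUE(all.equal(mean(a, na.rm = TRUE),
                                  mean(b, na.rm = TRUE)))) 1 else 0)
    }
    t.test(a, b, var.equal = FALSE)$p.value
  })
  q <- p.adjust(p, method = "BH")
  data.frame(protein_id = rownames(quant_matrix), p = p, q = q,
             significant = p < alpha & q < fdr,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Picked target-decoy FDR
#'
#' For each target/decoy pair only the higher-scoring member survives
#' (ties go to the target). Survivors are sorted by decreasing score; the
#' FDR at a score threshold is #decoys / #targets at or above it, and
#' q-values are the running minimum of FDR from the worst score upward.
#' Decoys without a paired target are treated as their own pair, with a
#' warning.
#'
#' @param scores data.frame with columns `id` (gene/protein identifier
#'   shared by a target and its decoy), `score` (higher is better), and
#'   `is_decoy` (logical).
#' @return data.frame of surviving targets: `id`, `score`, `q`.
#' @export
picked_fdr <- function(scores) {
  stopifnot(all(c("id", "score", "is_decoy") %in% names(scores)))
  targets <- scores[!scores$is_decoy, , drop = FALSE]
  decoys <- scores[scores$is_decoy, , drop = FALSE]
  if (any(!decoys$id %in% targets$id)) {
    warning(sum(!decoys$id %in% targets$id),
            " decoy(s) without a paired target; treated as their own pair")
  }
  survivors <- lapply(union(targets$id, decoys$id), function(id) {
    ts <- targets$score[targets$id == id]
    ds <- decoys$score[decoys$id == id]
    if (length(ts) == 0L) {
      data.frame(id = id, score = max(ds), is_decoy = TRUE)
    } else if (length(ds) == 0L || max(ts) >= max(ds)) {
      data.frame(id = id, score = max(ts), is_decoy = FALSE)
    } else {
      data.frame(id = id, score = max(ds), is_decoy = TRUE)
    }
  })
  surv <- do.call(rbind, survivors)
  surv <- surv[order(-surv$score), , drop = FALSE]
  # threshold semantics: tied scores form one threshold, so every member
  # of a tie group uses the counts at the end of the group
  n_decoy <- ave(cumsum(surv$is_decoy), surv$score,
                 FUN = function(x) x[length(x)])
  n_target <- ave(cumsum(!surv$is_decoy), surv$score,
                  FUN = function(x) x[length(x)])
  fdr <- ifelse(n_target == 0L, 1, n_decoy / pmax(n_target, 1L))
  fdr <- pmin(fdr, 1)
  q <- rev(cummin(rev(fdr)))
  out <- data.frame(id = surv$id, score = surv$score, q = q,
                    stringsAsFactors = FALSE)
  out <- out[!surv$is_decoy, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Best-peptide protein score
#'
#' Protein-level identity score = -log10 of the best (smallest) peptide
#' q-value, with q floored at 1e-15 to avoid infinities.
#'
#' @param peptide_qvalues numeric vector of the protein's peptide q-values.
#' @return protein score.
#' @examples
#' protein_level_score(c(0.01, 0.2))  # 2
#' @export
protein_level_score <- function(peptide_qvalues) {
  stopifnot(length(peptide_qvalues) >= 1L)
  -log10(max(min(peptide_qvalues, na.rm = TRUE), 1e-15))
}

#' Tissue-leakage protein summary
#'
#' Restricts detections to proteins tagged `tissue-enriched:<tissue>` and
#' reports, per sample, the number of such proteins detected and the
#' median and range of their PSM counts (proteins in the tag set but
#' undetected count as 0 PSMs). When a pair manifest is given, also the
#' mother:child ratio of summed PSM counts per pair.
#'
#' @param detections detection data.frame (`sample_id`, `protein_id`,
#'   `psm_count`).
#' @param proteome proteome data.frame with a `tags` column.
#' @param tissue tissue name, e.g. "placenta".
#' @param pairs optional pair manifest for mother:child ratios.
#' @return list with `tagged_proteins`, `per_sample` (data.frame
#'   `sample_id`, `n_proteins`, `median_psms`, `min_psms`, `max_psms`),
#'   and `pair_ratio` (data.frame, NULL without pairs).
#' @export
tissue_leakage_summary <- function(detections, proteome, tissue,
                                   pairs = NULL) {
  tag <- paste0("tissue-enriched:", tissue)
  tagged <- proteome$protein_id[vapply(strsplit(proteome$tags, ";"),
                                       function(t) tag %in% t, logical(1))]
  if (length(tagged) == 0L) {
    warning("no proteins tagged '", tag, "'")
    return(list(tagged_proteins = character(0),
                per_sample = data.frame(), pair_ratio = NULL))
  }
  det <- detections[detections$protein_id %in% tagged, , drop = FALSE]
  samples <- unique(detections$sample_id)
  per_sample <- do.call(rbind, lapply(samples, function(smp) {
    d <- det[det$sample_id == smp, , drop = FALSE]
    psms_per_protein <- setNames(rep(0L, length(tagged)), tagged)
    if (nrow(d) > 0L) {
      got <- tapply(d$psm_count, d$protein_id, sum)
      psms_per_protein[names(got)] <- got
    }
    data.frame(sample_id = smp,
               n_proteins = length(unique(d$protein_id)),
               median_psms = median(psms_per_protein),
               min_psms = min(psms_per_protein),
               max_psms = max(psms_per_protein),
               stringsAsFactors = FALSE)
  }))
  pair_ratio <- NULL
  if (!is.null(pairs)) {
    pair_ratio <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(p) {
      m <- sum(det$psm_count[det$sample_id == pairs$mother_sample[p]])
      c_ <- sum(det$psm_count[det$sample_id == pairs$child_sample[p]])
      data.frame(pair_id = pairs$pair_id[p], mother_psms = m,
                 child_psms = c_,
                 ratio = if (c_ > 0) m / c_ else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  list(tagged_proteins = tagged, per_sample = per_sample,
       pair_ratio = pair_ratio)
}

#' Convert a peptide concentration to protein mass concentration
#'
#' 1 fmol/uL equals 1 nmol/L, so ng/mL = fmol/uL x MW(Da) x 1e-3
#' (equivalently nM x MW in kDa).
#'
#' @param conc_fmol_per_ul peptide concentration in fmol/uL.
#' @param protein_mw_da molecular weight of the whole protein in Da.
#' @return concentration in ng/mL.
#' @examples
#' amount_to_concentration(1, 30000)  # 30 ng/mL
#' @export
amount_to_concentration <- function(conc_fmol_per_ul, protein_mw_da) {
  if (any(conc_fmol_per_ul <= 0) || any(protein_mw_da <= 0)) {
    stop("inputs must be positive", call. = FALSE)
  }
  conc_fmol_per_ul * protein_mw_da * 1e-3
}

#' @rdname amount_to_concentration
#' @param conc_ng_per_ml concentration in ng/mL.
#' @export
concentration_to_amount <- function(conc_ng_per_ml, protein_mw_da) {
  if (any(conc_ng_per_ml <= 0) || any(protein_mw_da <= 0)) {
    stop("inputs must be positive", call. = FALSE)
  }
  conc_ng_per_ml / (protein_mw_da * 1e-3)
}

#' Core set of proteins detected in every set
#'
#' Simple intersection report over per-set identification lists, the
#' gene-centric "detected in all N sets" logic.
#'
#' @param id_lists named list of character vectors (identifications per
#'   set).
#' @return list with `core` (intersection), `n_sets`, `per_set_counts`.
#' @export
core_set <- function(id_lists) {
  stopifnot(length(id_lists) >= 1L)
  list(core = Reduce(intersect, id_lists), n_sets = length(id_lists),
       per_set_counts = vapply(id_lists, length, integer(1)))
}
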