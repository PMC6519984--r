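# Cross-placental transfer inference: a curated variant peptide detected in
# an individual whose own genotype is wild type at the SNP, while the paired
# individual (mother or newborn) carries the alternative allele, implies the
# protein crossed the placenta from carrier to wild-type member.

#' Infer variant-protein transfer events between mother and child
#'
#' For every pair and SAAV: an event is emitted iff the variant peptide is
#' detected in both members, exactly one member is `wild_type` at the SNP,
#' and the other carries the alternative allele (`hetero_snp` or
#' `homo_snp`). The direction is carrier to wild-type member; direction is
#' a pure function of the genotype classes, never of abundance. Variant
#' detections in a wild-type individual with no carrier-side detection in
#' the partner are returned as unexplained detections (candidate false
#' positives), never as events.
#'
#' With `require_curated`, detections failing spectrum curation on the
#' recipient (wild-type) side drop the event — that is the side with no
#' DNA support, so it carries the whole evidential burden. A donor-side
#' curation failure only downgrades confidence (`donor_curated = FALSE`).
#'
#' @param detections detection data.frame; needs `sample_id`, `snp_id`,
#'   `peptide`, `protein_id`, `is_variant`, `psm_count`, and (when
#'   `require_curated`) a logical `curated` column from
#'   [curate_detections()].
#' @param genotypes genotype data.frame (`sample_id`, `snp_id`, `klass`).
#' @param pairs pair manifest (`pair_id`, `mother_sample`, `child_sample`).
#' @param require_curated logical; drop events whose recipient-side
#'   detection failed curation.
#' @param min_recipient_psms minimum PSM count on the recipient side
#'   (default 1; single-PSM evidence is admissible).
#' @return list with `events` (one row per transfer event) and
#'   `unexplained` (wild-type variant detections without a carrier
#'   counterpart).
#' @export
infer_transfers <- function(detections, genotypes, pairs,
                            require_curated = TRUE,
                            min_recipient_psms = 1L) {
  det <- detections[as.logical(detections$is_variant), , drop = FALSE]
  known <- c(pairs$mother_sample, pairs$child_sample)
  if (!all(det$sample_id %in% known)) {
    stop("detections contain samples absent from the pair manifest: ",
         paste(unique(setdiff(det$sample_id, known)), collapse = ", "),
         call. = FALSE)
  }
  if (require_curated && !("curated" %in% names(det))) {
    stop("require_curated = TRUE but detections carry no 'curated' column; ",
         "run curate_detections() first or set require_curated = FALSE",
         call. = FALSE)
  }
  if (!("curated" %in% names(det))) det$curated <- TRUE
  gkey <- paste(genotypes$sample_id, genotypes$snp_id)
  klass_of <- function(sample_id, snp_id) {
    k <- genotypes$klass[match(paste(sample_id, snp_id), gkey)]
    ifelse(is.na(k), "missing", k)
  }
  dkey <- paste(det$sample_id, det$snp_id)
  events <- list()
  unexplained <- list()
  for (p in seq_len(nrow(pairs))) {
    mother <- pairs$mother_sample[p]
    child <- pairs$child_sample[p]
    snp_ids <- unique(det$snp_id[det$sample_id %in% c(mother, child)])
    for (snp in snp_ids) {
      im <- match(paste(mother, snp), dkey)
      ic <- match(paste(child, snp), dkey)
      km <- klass_of(mother, snp)
      kc <- klass_of(child, snp)
      carrier <- c("hetero_snp", "homo_snp")
      in_both <- !is.na(im) && !is.na(ic)
      if (in_both && xor(km == "wild_type", kc == "wild_type") &&
          (km %in% carrier || kc %in% carrier)) {
        recip_is_mother <- km == "wild_type"
        ir <- if (recip_is_mother) im else ic
        id <- if (recip_is_mother) ic else im
        if (det$psm_count[ir] < min_recipient_psms) next
        if (require_curated && !det$curated[ir]) next
        events[[length(events) + 1L]] <- data.frame(
          pair_id = pairs$pair_id[p], snp_id = snp,
          peptide = det$peptide[id], protein_id = det$protein_id[id],
          donor_sample = if (recip_is_mother) child else mother,
          recipient_sample = if (recip_is_mother) mother else child,
          direction = if (recip_is_mother) "baby_to_mother" else
            "mother_to_baby",
          donor_klass = if (recip_is_mother) kc else km,
          recipient_klass = "wild_type",
          donor_psms = det$psm_count[id],
          recipient_psms = det$psm_count[ir],
          donor_curated = det$curated[id],
          recipient_curated = det$curated[ir],
          stringsAsFactors = FALSE)
      } else {
        # wild-type detections with no carrier-side partner detection
        for (side in list(list(im, km, mother), list(ic, kc, child))) {
          i <- side[[1]]; k <- side[[2]]; smp <- side[[3]]
          if (!is.na(i) && k == "wild_type") {
            partner <- setdiff(c(mother, child), smp)
            pk <- klass_of(partner, snp)
            pdet <- !is.na(match(paste(partner, snp), dkey))
            if (!(pk %in% carrier) || !pdet) {
              unexplained[[length(unexplained) + 1L]] <- data.frame(
                pair_id = pairs$pair_id[p], snp_id = snp,
                sample_id = smp, peptide = det$peptide[i],
                protein_id = det$protein_id[i],
                partner_klass = pk, partner_detected = pdet,
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
  }
  empty_events <- data.frame(
    pair_id = character(), snp_id = character(), peptide = character(),
    protein_id = character(), donor_sample = character(),
    recipient_sample = character(), direction = character(),
    donor_klass = character(), recipient_klass = character(),
    donor_psms = integer(), recipient_psms = integer(),
    donor_curated = logical(), recipient_curated = logical(),
    stringsAsFactors = FALSE)
  list(
    events = if (length(events)) do.call(rbind, events) else empty_events,
    unexplained = if (length(unexplained)) do.call(rbind, unexplained) else
      data.frame(pair_id = character(), snp_id = character(),
                 sample_id = character(), peptide = character(),
                 protein_id = character(), partner_klass = character(),
                 partner_detected = logical(), stringsAsFactors = FALSE))
}

#' Summarize transfer events
#'
#' Direction counts at the protein level, a per-protein direction table,
#' and the cross-pair concordance/discordance lists: a protein is
#' concordant when it has events in more than one pair, all in the same
#' direction, and discordant when the two pairs show opposite directions.
#' A "case" is one (pair, peptide, direction) combination.
#'
#' @param events event data.frame from [infer_transfers()].
#' @param pairs pair manifest.
#' @return list with `n_cases`, `n_unique_peptides`, `n_proteins`,
#'   `direction_counts` (unique proteins per direction), `protein_table`,
#'   `concordant`, `discordant`.
#' @export
summarize_transfers <- function(events, pairs) {
  if (nrow(events) == 0L) {
    return(list(n_cases = 0L, n_unique_peptides = 0L, n_proteins = 0L,
                direction_counts = c(baby_to_mother = 0L,
                                     mother_to_baby = 0L),
                protein_table = data.frame(protein_id = character(),
                                           direction = character(),
                                           n_pairs = integer()),
                concordant = character(0), discordant = character(0)))
  }
  cases <- unique(events[, c("pair_id", "peptide", "direction")])
  dir_counts <- vapply(c("baby_to_mother", "mother_to_baby"), function(d) {
    length(unique(events$protein_id[events$direction == d]))
  }, integer(1))
  pt <- unique(events[, c("protein_id", "direction", "pair_id")])
  protein_table <- aggregate(pair_id ~ protein_id + direction, pt,
                             FUN = function(x) length(unique(x)))
  names(protein_table)[3] <- "n_pairs"
  per_protein <- split(pt, pt$protein_id)
  concordant <- names(Filter(function(df) {
    length(unique(df$direction)) == 1L && length(unique(df$pair_id)) > 1L
  }, per_protein))
  discordant <- names(Filter(function(df) {
    length(unique(df$direction)) > 1L
  }, per_protein))
  list(n_cases = nrow(cases),
       n_unique_peptides = length(unique(events$peptide)),
       n_proteins = length(unique(events$protein_id)),
       direction_counts = dir_counts,
       protein_table = protein_table,
       concordant = concordant, discordant = discordant)
}

#' Physicochemical profile of transferred proteins
#'
#' GRAVY hydropathy, sequence length, predicted whole-protein pI, and
#' (when a quantification table is supplied) the abundance rank — the
#' descriptors used to ask whether transferred proteins stand out from the
#' rest of the detected proteome.
#'
#' @param events event data.frame.
#' @param proteome proteome data.frame.
#' @param protein_areas optional data.frame with `protein_id`, `area`
#'   (e.g. from [top3_protein_area()] per protein); rank 1 = most
#'   abundant.
#' @return data.frame with one row per transferred protein: `protein_id`,
#'   `gravy`, `length`, `pi`, `abundance_rank` (NA without quant).
#' @export
transfer_property_profile <- function(events, proteome,
                                      protein_areas = NULL) {
  ids <- unique(events$protein_id)
  seqs <- proteome$sequence[match(ids, proteome$protein_id)]
  rank_of <- rep(NA_integer_, length(ids))
  if (!is.null(protein_areas)) {
    ord <- protein_areas[order(-protein_areas$area), ]
    rank_of <- match(ids, ord$protein_id)
  }
  data.frame(
    protein_id = ids,
    gravy = vapply(seqs, gravy_score, numeric(1), USE.NAMES = FALSE),
    length = nchar(seqs),
    pi = vapply(seqs, predict_pi, numeric(1), USE.NAMES = FALSE),
    abundance_rank = rank_of,
    stringsAsFactors = FALSE)
}
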