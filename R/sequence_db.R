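# Tryptic peptide database construction: in-silico digestion, single amino
# acid variant (SAAV) peptide generation, and the FASTA/TSV interchange
# formats used between pipeline stages.

#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence C-terminally of lysine and arginine. By
#' default cleavage is suppressed when the following residue is proline
#' (the Keil rule), and only fully tryptic peptides are produced. Peptides
#' shorter than `min_length` or longer than `max_length` are dropped;
#' coordinates are 1-based inclusive.
#'
#' @param sequence protein sequence (standard residues, uppercase).
#' @param min_length minimum peptide length retained (default 6).
#' @param max_length maximum peptide length retained (default 50).
#' @param max_missed maximum number of missed cleavages (default 0).
#' @param proline_rule logical; suppress cleavage before proline.
#' @return data.frame with columns `peptide`, `start`, `end`,
#'   `missed_cleavages`.
#' @examples
#' digest("AAAKGGGGGG")   # AAAK is dropped (length 4 < 6)
#' @export
digest <- function(sequence, min_length = 6L, max_length = 50L,
                   max_missed = 0L, proline_rule = TRUE) {
  assert_sequence(sequence)
  assert_count(min_length, "min_length", min = 1L)
  assert_count(max_missed, "max_missed", min = 0L)
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  # cut after position i when aa[i] is K/R and not followed by P
  is_site <- aa %in% c("K", "R")
  if (proline_rule && n > 1L) {
    followed_by_p <- c(aa[-1] == "P", FALSE)
    is_site <- is_site & !followed_by_p
  }
  is_site[n] <- FALSE  # the chain end is a boundary regardless
  bounds <- c(0L, which(is_site), n)
  starts <- bounds[-length(bounds)] + 1L
  ends <- bounds[-1]
  base <- data.frame(start = starts, end = ends,
                     missed_cleavages = 0L, stringsAsFactors = FALSE)
  if (max_missed > 0L && nrow(base) > 1L) {
    extra <- list()
    for (k in seq_len(max_missed)) {
      idx <- seq_len(nrow(base) - k)
      if (length(idx) == 0L) break
      extra[[k]] <- data.frame(start = base$start[idx],
                               end = base$end[idx + k],
                               missed_cleavages = k)
    }
    base <- rbind(base, do.call(rbind, extra))
  }
  base$peptide <- substring(sequence, base$start, base$end)
  len <- base$end - base$start + 1L
  base <- base[len >= min_length & len <= max_length, , drop = FALSE]
  base <- base[order(base$start, base$end), , drop = FALSE]
  rownames(base) <- NULL
  base[, c("peptide", "start", "end", "missed_cleavages")]
}

#' Variant peptides from a single amino acid substitution
#'
#' Substitutes `alt_aa` at `pos` of the protein, re-digests the mutated
#' sequence, and returns the peptides that cover the substituted position
#' and do not occur among the canonical tryptic peptides. Cleavage-site
#' creation (alt is K/R) and destruction (ref is K/R) are handled by the
#' re-digestion itself. The annotated `ref_aa` must match the protein
#' sequence; a mismatch is a provenance error and is never silently fixed.
#'
#' @param sequence protein sequence.
#' @param pos 1-based residue position of the substitution.
#' @param ref_aa,alt_aa reference and alternative residues (single letters).
#' @param min_length,max_length,max_missed,proline_rule passed to
#'   [digest()].
#' @return data.frame of variant peptides (`peptide`, `start`, `end`,
#'   `missed_cleavages`, `variant_pos` = position of the substituted
#'   residue within the peptide); zero rows when no variant peptide of
#'   acceptable length covers the site.
#' @export
apply_saav <- function(sequence, pos, ref_aa, alt_aa, min_length = 6L,
                       max_length = 50L, max_missed = 0L,
                       proline_rule = TRUE) {
  assert_sequence(sequence)
  n <- nchar(sequence)
  if (pos < 1L || pos > n) {
    stop("pos out of range for protein of length ", n, call. = FALSE)
  }
  if (ref_aa == alt_aa) {
    stop("alt_aa equals ref_aa: not a variant", call. = FALSE)
  }
  found <- substring(sequence, pos, pos)
  if (found != ref_aa) {
    stop("provenance error: annotated ref_aa '", ref_aa, "' does not match ",
         "sequence residue '", found, "' at position ", pos, call. = FALSE)
  }
  mutated <- sequence
  substring(mutated, pos, pos) <- alt_aa
  canon <- digest(sequence, min_length, max_length, max_missed, proline_rule)
  vd <- digest(mutated, min_length, max_length, max_missed, proline_rule)
  vd <- vd[vd$start <= pos & vd$end >= pos, , drop = FALSE]
  vd <- vd[!(vd$peptide %in% canon$peptide), , drop = FALSE]
  vd$variant_pos <- pos - vd$start + 1L
  rownames(vd) <- NULL
  vd
}

#' Canonical counterpart of a variant peptide
#'
#' The fully tryptic reference-allele peptide covering the same SAAV
#' position. Defined only when the digestion boundaries agree between the
#' two alleles; when the substitution creates or destroys a cleavage site
#' the boundaries differ and there is no counterpart (`NA`).
#'
#' @inheritParams apply_saav
#' @return single peptide string, or `NA_character_` when no counterpart
#'   exists.
#' @export
canonical_counterpart <- function(sequence, pos, ref_aa, alt_aa,
                                  min_length = 6L, max_length = 50L,
                                  max_missed = 0L, proline_rule = TRUE) {
  vd <- apply_saav(sequence, pos, ref_aa, alt_aa, min_length, max_length,
                   max_missed, proline_rule)
  vd <- vd[vd$missed_cleavages == 0L, , drop = FALSE]
  if (nrow(vd) == 0L) return(NA_character_)
  canon <- digest(sequence, min_length, max_length, 0L, proline_rule)
  canon <- canon[canon$start <= pos & canon$end >= pos, , drop = FALSE]
  if (nrow(canon) == 0L) return(NA_character_)
  if (canon$start[1] == vd$start[1] && canon$end[1] == vd$end[1]) {
    return(canon$peptide[1])
  }
  NA_character_
}

#' Build a variant peptide database
#'
#' Applies every SAAV annotation to its protein and collects the variant
#' peptides, their canonical counterparts, and peptide masses — the
#' customized search-database construction step of the proteogenomics
#' pipeline.
#'
#' @param proteome data.frame with columns `protein_id`, `gene_id`,
#'   `sequence`, `tags` (see [read_proteome_fasta()]).
#' @param saav_table data.frame with columns `snp_id`, `protein_id`, `pos`,
#'   `ref_aa`, `alt_aa`.
#' @param min_length,max_length,max_missed,proline_rule digestion settings.
#' @return data.frame with one row per variant peptide: `snp_id`,
#'   `protein_id`, `pos`, `ref_aa`, `alt_aa`, `peptide`, `variant_pos`,
#'   `canonical_peptide` (NA when undefined), `mass`.
#' @export
build_variant_db <- function(proteome, saav_table, min_length = 6L,
                             max_length = 50L, max_missed = 0L,
                             proline_rule = TRUE) {
  stopifnot(all(c("snp_id", "protein_id", "pos", "ref_aa", "alt_aa") %in%
                  names(saav_table)))
  rows <- lapply(seq_len(nrow(saav_table)), function(i) {
    s <- saav_table[i, ]
    idx <- match(s$protein_id, proteome$protein_id)
    if (is.na(idx)) {
      stop("SAAV ", s$snp_id, " references unknown protein ", s$protein_id,
           call. = FALSE)
    }
    sequence <- proteome$sequence[idx]
    vd <- apply_saav(sequence, s$pos, s$ref_aa, s$alt_aa, min_length,
                     max_length, max_missed, proline_rule)
    if (nrow(vd) == 0L) return(NULL)
    counter <- canonical_counterpart(sequence, s$pos, s$ref_aa, s$alt_aa,
                                     min_length, max_length, max_missed,
                                     proline_rule)
    data.frame(snp_id = s$snp_id, protein_id = s$protein_id, pos = s$pos,
               ref_aa = s$ref_aa, alt_aa = s$alt_aa, peptide = vd$peptide,
               variant_pos = vd$variant_pos,
               canonical_peptide = counter,
               mass = vapply(vd$peptide, peptide_mass, numeric(1)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(snp_id = character(), protein_id = character(),
                      pos = integer(), ref_aa = character(),
                      alt_aa = character(), peptide = character(),
                      variant_pos = integer(),
                      canonical_peptide = character(), mass = numeric())
  }
  rownames(out) <- NULL
  out
}

# ---- interchange formats ----------------------------------------------------

#' Read/write the proteome FASTA dialect
#'
#' Headers follow `>protein_id gene=GENE tags=tag1;tag2`; sequences are
#' wrapped at 60 columns. Tags carry protein-class annotations such as
#' `tissue-enriched:placenta`.
#'
#' @param path FASTA file path.
#' @return data.frame with columns `protein_id`, `gene_id`, `sequence`,
#'   `tags` (semicolon-separated, possibly "").
#' @export
read_proteome_fasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  headers <- names(aas)
  parse_field <- function(h, key) {
    m <- regmatches(h, regexpr(paste0(key, "=\\S+"), h))
    if (length(m) == 0L) return("")
    sub(paste0("^", key, "="), "", m)
  }
  data.frame(
    protein_id = vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L),
    gene_id = vapply(headers, parse_field, character(1), "gene",
                     USE.NAMES = FALSE),
    sequence = unname(as.character(aas)),
    tags = vapply(headers, parse_field, character(1), "tags",
                  USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
}

#' @rdname read_proteome_fasta
#' @param proteome proteome data.frame.
#' @export
write_proteome_fasta <- function(proteome, path) {
  aas <- Biostrings::AAStringSet(proteome$sequence)
  names(aas) <- sprintf("%s gene=%s tags=%s", proteome$protein_id,
                        proteome$gene_id, proteome$tags)
  Biostrings::writeXStringSet(aas, path, width = 60L)
  invisible(path)
}

#' Read a SAAV annotation table
#'
#' Tab-separated with columns `snp_id`, `protein_id`, `pos`, `ref_aa`,
#' `alt_aa` (protein coordinates, 1-based).
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_saav_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("snp_id", "protein_id", "pos", "ref_aa", "alt_aa")
  if (!all(needed %in% names(df))) {
    stop("SAAV table must have columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  df$pos <- as.integer(df$pos)
  df
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
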