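# Genotype-call classification against the reference allele, Mendelian
# consistency checks for mother-child pairs, and genomic support accounting
# for detected variant peptides.

NUCLEOTIDES <- c("A", "C", "G", "T")

#' Classify a biallelic genotype against the reference allele
#'
#' `wild_type` when both alleles equal the reference nucleotide,
#' `hetero_snp` when exactly one differs, `homo_snp` when both differ;
#' missing alleles give `missing`. Vectorized and symmetric in allele
#' order.
#'
#' @param allele1,allele2 nucleotide characters (A/C/G/T) or NA.
#' @param ref_allele reference nucleotide.
#' @return character vector of classes.
#' @examples
#' classify_genotype("A", "G", "A")  # "hetero_snp"
#' @export
classify_genotype <- function(allele1, allele2, ref_allele) {
  n <- max(length(allele1), length(allele2), length(ref_allele))
  allele1 <- rep_len(allele1, n)
  allele2 <- rep_len(allele2, n)
  ref_allele <- rep_len(ref_allele, n)
  ok <- function(x) is.na(x) | x %in% NUCLEOTIDES
  if (!all(ok(allele1) & ok(allele2) & ok(ref_allele))) {
    stop("format error: alleles must be A, C, G, T or missing",
         call. = FALSE)
  }
  alt_count <- (allele1 != ref_allele) + (allele2 != ref_allele)
  out <- c("wild_type", "hetero_snp", "homo_snp")[alt_count + 1L]
  out[is.na(allele1) | is.na(allele2)] <- "missing"
  out
}

#' Mendelian consistency between a mother and child call
#'
#' Consistent when the child shares at least one allele with the mother at
#' the same SNP. Missing calls on either side are indeterminate (`NA`),
#' reported separately rather than counted as failures.
#'
#' @param mother,child single rows (lists/data.frames) with fields
#'   `snp_id`, `allele1`, `allele2`.
#' @return `TRUE`, `FALSE`, or `NA` (indeterminate).
#' @export
mendelian_check <- function(mother, child) {
  if (mother$snp_id != child$snp_id) {
    stop("mendelian_check: snp_id mismatch (", mother$snp_id, " vs ",
         child$snp_id, ")", call. = FALSE)
  }
  m <- c(mother$allele1, mother$allele2)
  k <- c(child$allele1, child$allele2)
  if (anyNA(m) || anyNA(k)) return(NA)
  any(k %in% m)
}

#' Genomic support for a detected variant peptide
#'
#' A variant peptide detection in a sample is genomically supported when
#' that sample's genotype carries the alternative allele (`hetero_snp` or
#' `homo_snp`). Detections in a `wild_type` individual are unsupported —
#' these are the cross-placental transfer candidates. Missing genotypes are
#' indeterminate (`NA`) and excluded from support percentages.
#'
#' @param klass genotype class vector (see [classify_genotype()]).
#' @return logical vector: supported / unsupported / `NA`.
#' @export
genomic_support <- function(klass) {
  out <- klass %in% c("hetero_snp", "homo_snp")
  out[klass == "missing" | is.na(klass)] <- NA
  out
}

#' Summarize genomic support over a detection table
#'
#' Joins variant detections to per-sample genotype calls and reports how
#' many are supported by the SNP-array genotype. The percentage is computed
#' over detections with non-missing genotypes only; it is reported both to
#' one decimal and rounded half-up to an integer for display (240 of 384
#' supported prints as 63%).
#'
#' @param detections data.frame with at least `sample_id`, `snp_id`,
#'   `is_variant`.
#' @param genotypes data.frame with `sample_id`, `snp_id`, `klass`.
#' @return list with `n_detections`, `n_supported`, `n_unsupported`,
#'   `n_missing`, `pct_supported` (one decimal), `pct_display` (integer).
#' @export
support_summary <- function(detections, genotypes) {
  det <- detections[as.logical(detections$is_variant), , drop = FALSE]
  key <- function(df) paste(df$sample_id, df$snp_id)
  klass <- genotypes$klass[match(key(det), key(genotypes))]
  supported <- genomic_support(klass)
  n_missing <- sum(is.na(supported))
  n_sup <- sum(supported, na.rm = TRUE)
  n_unsup <- sum(!supported, na.rm = TRUE)
  denom <- n_sup + n_unsup
  pct <- if (denom > 0) 100 * n_sup / denom else NA_real_
  list(n_detections = nrow(det), n_supported = n_sup,
       n_unsupported = n_unsup, n_missing = n_missing,
       pct_supported = round(pct, 1),
       pct_display = as.integer(round_half_up(pct)))
}

#' Read a genotype call table
#'
#' TSV with columns `sample_id`, `snp_id`, `allele1`, `allele2`,
#' `ref_allele`. The genotype class is (re)computed from the alleles, so a
#' stale or absent `klass` column is never trusted. Records with alleles
#' outside A/C/G/T (multi-allelic sites, indels) are rejected with a
#' warning: the pipeline is biallelic-SNP only.
#'
#' @param path TSV file path.
#' @return data.frame with a recomputed `klass` column.
#' @export
read_genotypes <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", "."))
  needed <- c("sample_id", "snp_id", "allele1", "allele2", "ref_allele")
  if (!all(needed %in% names(df))) {
    stop("genotype table must have columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  bad <- !(is.na(df$allele1) | df$allele1 %in% NUCLEOTIDES) |
    !(is.na(df$allele2) | df$allele2 %in% NUCLEOTIDES)
  if (any(bad)) {
    warning(sum(bad), " non-biallelic-SNP record(s) dropped")
    df <- df[!bad, , drop = FALSE]
  }
  df$klass <- classify_genotype(df$allele1, df$allele2, df$ref_allele)
  df
}

#' Minimal VCF genotype reader
#'
#' Reads biallelic SNP records from a VCF (plain text) and returns the
#' genotype table format used throughout the package. Only CHROM/POS/ID/
#' REF/ALT and the GT subfield of each sample column are used; phasing is
#' ignored, multi-allelic and non-SNP records are skipped with a warning.
#'
#' @param path VCF file path (uncompressed).
#' @return data.frame with `sample_id`, `snp_id`, `allele1`, `allele2`,
#'   `ref_allele`, `klass`.
#' @export
read_vcf_genotypes <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "##")]
  header <- strsplit(sub("^#", "", lines[1]), "\t")[[1]]
  samples <- header[-(1:9)]
  body <- lines[-1]
  body <- body[nzchar(body)]
  rows <- list()
  skipped <- 0L
  for (ln in body) {
    f <- strsplit(ln, "\t")[[1]]
    ref <- f[4]; alt <- f[5]
    if (nchar(ref) != 1L || nchar(alt) != 1L ||
        !ref %in% NUCLEOTIDES || !alt %in% NUCLEOTIDES) {
      skipped <- skipped + 1L
      next
    }
    gt_idx <- match("GT", strsplit(f[9], ":")[[1]])
    snp_id <- if (f[3] == ".") paste0(f[1], ":", f[2]) else f[3]
    for (si in seq_along(samples)) {
      gt <- strsplit(f[9L + si], ":")[[1]][gt_idx]
      codes <- strsplit(gt, "[/|]")[[1]]
      allele <- function(code) {
        if (code == ".") NA_character_ else c(ref, alt)[as.integer(code) + 1L]
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = samples[si], snp_id = snp_id,
        allele1 = allele(codes[1]), allele2 = allele(codes[2]),
        ref_allele = ref, stringsAsFactors = FALSE)
    }
  }
  if (skipped > 0L) warning(skipped, " non-biallelic-SNP record(s) skipped")
  df <- do.call(rbind, rows)
  df$klass <- classify_genotype(df$allele1, df$allele2, df$ref_allele)
  df
}
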