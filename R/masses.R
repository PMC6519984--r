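# Monoisotopic residue masses (Da), free side chains, and the Kyte-Doolittle
# hydropathy scale. Values are the standard unimod/IUPAC monoisotopic masses.

AA_MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

MASS_WATER <- 18.010565
MASS_PROTON <- 1.007276
MASS_CARBAMIDOMETHYL <- 57.02146

KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Monoisotopic peptide mass
#'
#' Sum of monoisotopic residue masses plus one water. Cysteines are treated
#' as carbamidomethylated (a fixed +57.02146 Da) by default, matching the
#' fixed-modification convention of the search settings this package
#' emulates.
#'
#' @param sequence peptide sequence (standard one-letter residues).
#' @param carbamidomethyl logical; add 57.02146 Da per cysteine.
#' @return monoisotopic mass in Da.
#' @examples
#' peptide_mass("GGGGGG")
#' peptide_mass("C") - peptide_mass("C", carbamidomethyl = FALSE)
#' @export
peptide_mass <- function(sequence, carbamidomethyl = TRUE) {
  assert_sequence(sequence)
  aa <- strsplit(sequence, "")[[1]]
  m <- sum(AA_MONO_MASS[aa]) + MASS_WATER
  if (carbamidomethyl) {
    m <- m + MASS_CARBAMIDOMETHYL * sum(aa == "C")
  }
  m
}

#' Singly charged b/y fragment ion series
#'
#' Theoretical 1+ b- and y-ion m/z values for every backbone cleavage site
#' of a peptide. Site `i` separates residues `i` and `i + 1`; the b-ion at
#' site `i` covers residues `1..i`, the y-ion covers `i+1..n`.
#'
#' @param sequence peptide sequence.
#' @param carbamidomethyl logical, fixed Cys modification.
#' @return data.frame with columns `ion` (e.g. "b2", "y4"), `series`,
#'   `site` (cleavage site index), `mz`.
#' @export
fragment_ions <- function(sequence, carbamidomethyl = TRUE) {
  assert_sequence(sequence)
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  if (n < 2L) {
    return(data.frame(ion = character(), series = character(),
                      site = integer(), mz = numeric()))
  }
  res <- unname(AA_MONO_MASS[aa])
  if (carbamidomethyl) res <- res + MASS_CARBAMIDOMETHYL * (aa == "C")
  cum <- cumsum(res)
  sites <- seq_len(n - 1L)
  b_mz <- cum[sites] + MASS_PROTON
  y_mz <- (cum[n] - cum[sites]) + MASS_WATER + MASS_PROTON
  data.frame(
    ion = c(paste0("b", sites), paste0("y", n - sites)),
    series = rep(c("b", "y"), each = n - 1L),
    site = c(sites, sites),
    mz = c(b_mz, y_mz),
    stringsAsFactors = FALSE
  )
}

#' GRAVY hydropathy score
#'
#' Mean Kyte-Doolittle hydropathy over all residues of a sequence; positive
#' values are hydrophobic, negative hydrophilic.
#'
#' @param sequence protein or peptide sequence.
#' @return mean hydropathy (dimensionless).
#' @examples
#' gravy_score("IIII") # 4.5, the scale maximum
#' @export
gravy_score <- function(sequence) {
  assert_sequence(sequence)
  mean(KYTE_DOOLITTLE[strsplit(sequence, "")[[1]]])
}
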