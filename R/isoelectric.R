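# Peptide isoelectric point prediction (Bjellqvist pK set, bisection on the
# net-charge curve) and mapping of pI onto high-resolution isoelectric
# focusing (HiRIEF) strip fractions, including condensed fraction pooling.

#' Bjellqvist pK table
#'
#' The pK values used by the Expasy Compute pI tool: side-chain pKs for
#' D/E/C/Y/K/R/H (with the C-terminal-residue variants for D and E) and
#' residue-specific alpha-amino pKs. Peptide-specific recalibrations used by
#' dedicated peptide pI predictors are deliberately not reproduced; this is
#' the composition-only protein model, documented as an approximation.
#'
#' @return list with elements `side` (named acidic/basic side-chain pKs),
#'   `side_cterm` (overrides when the residue is C-terminal), `nterm`
#'   (named by first residue, with `default`), `cterm` (alpha-carboxyl pK).
#' @export
pk_table_bjellqvist <- function() {
  list(
    side = c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00, H = 5.98,
             K = 10.00, R = 12.00),
    side_cterm = c(D = 4.55, E = 4.75),
    nterm = c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
              V = 7.44, E = 7.70, G = 7.50, default = 7.50),
    cterm = 3.55
  )
}

ACIDIC_AA <- c("D", "E", "C", "Y")
BASIC_AA <- c("H", "K", "R")

#' Net peptide charge at a given pH
#'
#' Henderson-Hasselbalch sum: each basic group contributes
#' `1 / (1 + 10^(pH - pK))`, each acidic group `-1 / (1 + 10^(pK - pH))`.
#' Groups are the alpha-amino and alpha-carboxyl termini plus ionizable
#' side chains. Cysteines are treated as carbamidomethylated, hence
#' non-ionizable, unless `free_cysteine = TRUE`.
#'
#' @param sequence peptide sequence.
#' @param ph pH value(s); vectorized.
#' @param pk_table pK set, see [pk_table_bjellqvist()].
#' @param free_cysteine logical; count Cys thiols as ionizable.
#' @return net charge in elementary charges, same length as `ph`.
#' @export
net_charge <- function(sequence, ph, pk_table = pk_table_bjellqvist(),
                       free_cysteine = FALSE) {
  assert_sequence(sequence)
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  acidic_pk <- numeric(0)
  basic_pk <- numeric(0)
  # termini
  nt <- pk_table$nterm[aa[1]]
  if (is.na(nt)) nt <- pk_table$nterm[["default"]]
  basic_pk <- c(basic_pk, unname(nt))
  acidic_pk <- c(acidic_pk, pk_table$cterm)
  # side chains
  for (i in seq_len(n)) {
    r <- aa[i]
    if (r == "C" && !free_cysteine) next
    pk <- if (i == n && r %in% names(pk_table$side_cterm)) {
      pk_table$side_cterm[[r]]
    } else if (r %in% names(pk_table$side)) {
      pk_table$side[[r]]
    } else {
      next
    }
    if (r %in% BASIC_AA) basic_pk <- c(basic_pk, pk)
    else acidic_pk <- c(acidic_pk, pk)
  }
  vapply(ph, function(p) {
    sum(1 / (1 + 10^(p - basic_pk))) - sum(1 / (1 + 10^(acidic_pk - p)))
  }, numeric(1))
}

#' Predict peptide isoelectric point
#'
#' Bisection on the net-charge curve over pH 0-14. The charge is strictly
#' decreasing in pH, so the zero crossing is unique; iteration stops when
#' `|charge| < tol` or the bracket is narrower than machine precision.
#'
#' @param sequence peptide sequence.
#' @param pk_table pK set.
#' @param tol charge tolerance for convergence (default 1e-4).
#' @param max_iter bisection iteration cap.
#' @param free_cysteine logical, see [net_charge()].
#' @return predicted pI in pH units.
#' @examples
#' predict_pi("LSEPAELTDAVK")  # acidic PSA peptide, ~4.1
#' @export
predict_pi <- function(sequence, pk_table = pk_table_bjellqvist(),
                       tol = 1e-4, max_iter = 200L, free_cysteine = FALSE) {
  lo <- 0; hi <- 14
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    q <- net_charge(sequence, mid, pk_table, free_cysteine)
    if (abs(q) < tol || (hi - lo) < 1e-12) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  stop("pI bisection did not converge for ", sequence, call. = FALSE)
}

#' HiRIEF strip configuration
#'
#' An immobilized pH-gradient strip eluted into `n_fractions` equal-width
#' fractions. The pH gradient is taken as linear across the strip (the
#' engineered design of commercial IPG strips in these ranges). An optional
#' `pooling_map` maps each fraction to a pool index for condensed analysis;
#' it must be a total, order-preserving surjection onto `1..max(pool)`.
#'
#' @param ph_lo,ph_hi strip pH bounds.
#' @param n_fractions number of eluted fractions (default 72).
#' @param pooling_map optional integer vector of length `n_fractions`.
#' @return object of class `strip_config`.
#' @export
strip_config <- function(ph_lo, ph_hi, n_fractions = 72L,
                         pooling_map = NULL) {
  if (!(ph_lo < ph_hi)) stop("ph_lo must be < ph_hi", call. = FALSE)
  assert_count(n_fractions, "n_fractions", min = 1L)
  if (!is.null(pooling_map)) {
    pooling_map <- as.integer(pooling_map)
    if (length(pooling_map) != n_fractions || anyNA(pooling_map)) {
      stop("pooling_map must assign every fraction", call. = FALSE)
    }
    if (is.unsorted(pooling_map)) {
      stop("pooling_map must be order-preserving", call. = FALSE)
    }
    if (!setequal(pooling_map, seq_len(max(pooling_map)))) {
      stop("pooling_map must be a surjection onto 1..n_pools", call. = FALSE)
    }
  }
  structure(list(ph_lo = ph_lo, ph_hi = ph_hi,
                 n_fractions = as.integer(n_fractions),
                 pooling_map = pooling_map),
            class = "strip_config")
}

#' Packaged HiRIEF strip presets
#'
#' The five strip ranges evaluated in plasma HiRIEF work (broad 3.0-10.0,
#' narrow 3.7-4.9, and the ultranarrow 3.7-4.05, 4.0-4.25, 4.2-4.45), each
#' eluted into 72 fractions.
#'
#' @param name one of "3-10", "3.7-4.9", "3.7-4.05", "4-4.25", "4.2-4.45".
#' @return a [strip_config()].
#' @export
strip_preset <- function(name = c("3-10", "3.7-4.9", "3.7-4.05", "4-4.25",
                                  "4.2-4.45")) {
  name <- match.arg(name)
  bounds <- switch(name,
    "3-10" = c(3.0, 10.0), "3.7-4.9" = c(3.7, 4.9),
    "3.7-4.05" = c(3.7, 4.05), "4-4.25" = c(4.0, 4.25),
    "4.2-4.45" = c(4.2, 4.45))
  strip_config(bounds[1], bounds[2], 72L)
}

#' Condensed 72-to-40 pooling preset
#'
#' Pools the 72 fractions of a broad-range strip into 40 analysis pools by
#' merging adjacent fractions at the strip extremes, where the peptide
#' density is lowest: fractions 1-24 are pooled in threes (pools 1-8),
#' 25-48 run singly (pools 9-32), and 49-72 are pooled in threes (pools
#' 33-40). The result keeps the densely populated acidic-to-neutral center
#' at full resolution while reducing instrument time.
#'
#' @return integer vector of length 72 mapping fraction to pool (max 40).
#' @export
pooling_preset_72_40 <- function() {
  map <- c(rep(1:8, each = 3L),        # fractions 1-24  -> pools 1-8
           8L + 1:24,                  # fractions 25-48 -> pools 9-32
           32L + rep(1:8, each = 3L))  # fractions 49-72 -> pools 33-40
  as.integer(map)
}

#' Map a pI onto a strip fraction
#'
#' Linear position mapping:
#' `fraction = clamp(ceil((pi - ph_lo) / (ph_hi - ph_lo) * n_fractions), 1,
#' n_fractions)` for pI inside the strip range; pI outside returns `NA`
#' ("out of strip"). Boundary ties resolve upward (ceil), except that
#' `pi == ph_lo` belongs to fraction 1.
#'
#' @param pi_value predicted isoelectric point(s); vectorized.
#' @param strip a [strip_config()].
#' @return integer fraction index, or `NA` when outside the strip.
#' @export
assign_fraction <- function(pi_value, strip) {
  stopifnot(inherits(strip, "strip_config"))
  frac <- ceiling((pi_value - strip$ph_lo) /
                    (strip$ph_hi - strip$ph_lo) * strip$n_fractions)
  frac <- pmin(pmax(frac, 1L), strip$n_fractions)
  frac[pi_value < strip$ph_lo | pi_value > strip$ph_hi] <- NA_integer_
  as.integer(frac)
}

#' Select target fractions for a peptide
#'
#' The assigned fraction of the peptide's predicted pI, plus/minus a
#' window, clamped to the strip bounds — the rational fraction-selection
#' step used to design targeted (MRM) analyses of specific peptides.
#'
#' @param sequence peptide sequence.
#' @param strip a [strip_config()].
#' @param window number of fractions either side (default 2).
#' @param pk_table pK set.
#' @return integer vector of fraction indices; empty (with a warning) when
#'   the peptide focuses outside the strip.
#' @export
select_target_fractions <- function(sequence, strip, window = 2L,
                                    pk_table = pk_table_bjellqvist()) {
  assert_count(window, "window", min = 0L)
  pi_value <- predict_pi(sequence, pk_table)
  centre <- assign_fraction(pi_value, strip)
  if (is.na(centre)) {
    warning("peptide pI ", round(pi_value, 2), " is outside the strip range")
    return(integer(0))
  }
  seq.int(max(1L, centre - window), min(strip$n_fractions, centre + window))
}

#' Apply a fraction pooling map
#'
#' @param fractions integer fraction indices.
#' @param strip a [strip_config()] whose `pooling_map` is set.
#' @return integer pool indices.
#' @export
apply_pooling <- function(fractions, strip) {
  stopifnot(inherits(strip, "strip_config"))
  if (is.null(strip$pooling_map)) {
    stop("strip has no pooling_map", call. = FALSE)
  }
  if (any(fractions < 1L | fractions > strip$n_fractions, na.rm = TRUE)) {
    stop("fraction index outside 1..n_fractions", call. = FALSE)
  }
  strip$pooling_map[fractions]
}
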