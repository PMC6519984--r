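# Independent brute-force oracles used to cross-check the implementation.
# Each oracle is written from the rule definition, never by calling the
# function it checks.

# Tryptic digestion: test every position against the cleavage rule, then
# assemble peptides between consecutive cut points.
oracle_digest <- function(sequence, min_length = 6L, max_length = 50L,
                          proline_rule = TRUE) {
  aa <- strsplit(sequence, "")[[1]]
  n <- length(aa)
  cuts <- integer(0)
  for (i in seq_len(n - 1L)) {
    if (aa[i] %in% c("K", "R")) {
      if (proline_rule && aa[i + 1L] == "P") next
      cuts <- c(cuts, i)
    }
  }
  bounds <- c(0L, cuts, n)
  peps <- character(0)
  for (j in seq_len(length(bounds) - 1L)) {
    s <- bounds[j] + 1L; e <- bounds[j + 1L]
    if (e - s + 1L >= min_length && e - s + 1L <= max_length) {
      peps <- c(peps, paste(aa[s:e], collapse = ""))
    }
  }
  peps
}

# pI by grid scan of the net-charge curve: a coarse pass over the full pH
# range followed by a 1e-4-step pass around the coarse minimum. The charge
# curve is monotone, so the coarse argmin brackets the crossing.
oracle_pi_grid <- function(sequence, step = 1e-4) {
  coarse <- seq(0, 14, by = 0.01)
  qc <- saavtrace::net_charge(sequence, coarse)
  centre <- coarse[which.min(abs(qc))]
  fine <- seq(max(0, centre - 0.02), min(14, centre + 0.02), by = step)
  qf <- saavtrace::net_charge(sequence, fine)
  fine[which.min(abs(qf))]
}

# Picked FDR by explicit enumeration: pick the winner of each pair, then
# for every survivor compute FDR at every possible score threshold and
# take the minimum over thresholds at or below its score.
oracle_picked_fdr <- function(scores) {
  ids <- unique(scores$id)
  winners <- do.call(rbind, lapply(ids, function(id) {
    sub <- scores[scores$id == id, ]
    ts <- sub[!sub$is_decoy, ]; ds <- sub[sub$is_decoy, ]
    if (nrow(ts) == 0L) {
      data.frame(id = id, score = max(ds$score), is_decoy = TRUE)
    } else if (nrow(ds) == 0L || max(ts$score) >= max(ds$score)) {
      data.frame(id = id, score = max(ts$score), is_decoy = FALSE)
    } else {
      data.frame(id = id, score = max(ds$score), is_decoy = TRUE)
    }
  }))
  thresholds <- sort(unique(winners$score))
  fdr_at <- vapply(thresholds, function(t) {
    nt <- sum(!winners$is_decoy & winners$score >= t)
    nd <- sum(winners$is_decoy & winners$score >= t)
    if (nt == 0L) 1 else min(nd / nt, 1)
  }, numeric(1))
  targets <- winners[!winners$is_decoy, , drop = FALSE]
  targets$q <- vapply(targets$score, function(s) {
    min(fdr_at[thresholds <= s])
  }, numeric(1))
  targets[order(-targets$score), c("id", "score", "q")]
}

# Allele-sharing oracle for mother-child consistency.
oracle_shares_allele <- function(m1, m2, c1, c2) {
  c1 %in% c(m1, m2) || c2 %in% c(m1, m2)
}

random_peptide <- function(len) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               len, replace = TRUE), collapse = "")
}

# A hand-built spectrum for a peptide: peaks at chosen theoretical ions.
spectrum_from_ions <- function(peptide, variant_pos, ions, intensities,
                               spectrum_id = "test") {
  theo <- saavtrace::fragment_ions(peptide)
  sel <- theo[match(ions, theo$ion), ]
  o <- order(sel$mz)
  list(spectrum_id = spectrum_id, peptide = peptide,
       variant_pos = as.integer(variant_pos), precursor_charge = 2L,
       pepmass = NA_real_,
       peaks = data.frame(mz = sel$mz[o], intensity = intensities[o]))
}
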