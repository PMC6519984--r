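---
title: "Variant peptides in plasma: detection, curation, and placental transfer inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variant peptides in plasma: detection, curation, and placental transfer inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saavtrace)
```

## The problem

A non-synonymous SNP changes one residue of a protein. When the resulting
single amino acid variant (SAAV) peptide is observed by mass spectrometry
in an individual's plasma, it ties that protein molecule to a genotype: a
person whose SNP-array genotype is homozygous reference (*wild type*)
cannot have produced the variant peptide themselves. In a mother–newborn
pair this turns SAAV peptides into traceable protein fingerprints: a
curated variant peptide found in the wild-type member of the pair, while
the other member carries the alternative allele, is evidence that the
protein crossed the placenta, and the genotype classes fix the direction
(carrier to wild-type member).

`saavtrace` implements this inference and every computational convention
around it: variant tryptic database construction, peptide isoelectric
point (pI) prediction with HiRIEF strip/fraction mapping, spectrum-level
curation of variant calls, genotype classification and genomic-support
accounting, and the quantification/FDR rules of the surrounding analysis.
A synthetic-data generator emulates the mother–child study design so that
the full pipeline is exercised end to end without any raw MS data.

## The transfer rule

For each pair and SNP, with the variant peptide detected (post-curation)
in **both** members:

* exactly one member is `wild_type` and the other carries the alternative
  allele (`hetero_snp` or `homo_snp`) → a **transfer event**, direction
  carrier → wild type;
* both members' genotypes explain the peptide → no event;
* a variant detection in a wild-type individual with no carrier-side
  detection in the partner → an **unexplained detection** (candidate false
  positive), never an event.

Direction is a pure function of the genotype classes; abundance plays no
role. The recipient side is the one without DNA support, so it carries the
evidential burden: when curation is required, a failed recipient spectrum
drops the event, whereas a failed donor spectrum only downgrades
confidence (`donor_curated = FALSE`). A minimum recipient PSM count is
configurable and defaults to 1, because single-PSM evidence is admissible
in this design.

Genotype classes follow the reference-allele rule: both alleles equal to
the reference → `wild_type`; one changed → `hetero_snp`; both changed →
`homo_snp`. Missing calls are excluded from denominators, never imputed.

## Curation of variant detections

Two independent guards reduce false SAAV discoveries:

1. **Ambiguous substitution classes.** N↔D and Q↔E substitutions differ by
   0.984 Da — the same shift as a deamidation or a co-isolated isotope
   peak — so all detections in these classes are removed wholesale.
   I↔L (mass-identical) removal is available behind a flag, default off.
2. **Flanking fragment ions.** A substitution is only site-localized when
   fragment ions bracket the variant residue. The check computes singly
   charged b/y series and passes a spectrum iff (a) at least one matched
   ion cleaves immediately N-terminal and one immediately C-terminal to
   the variant (for a terminal variant residue, the single interior
   flanking site must be matched by both a b- and a y-ion), within an
   absolute tolerance (0.02 Da default, matching fragment-level practice
   at typical MS2 resolution), and (b) the summed intensity of the
   flanking matches exceeds the median intensity of all matched ions.
   Both parts are individually toggleable, and an `--either-side` style
   relaxation exists for rule (a); the default requires both sides, the
   stricter reading. Only 1+ fragments are considered by default, which is
   appropriate for the simple stub spectra the generator produces.

Shrinking the tolerance can only remove matches, so a fail never becomes a
pass — this monotonicity is property-tested.

## Peptide pI and HiRIEF fraction mapping

Net charge is the Henderson–Hasselbalch sum over the termini and ionizable
side chains; pI is found by bisection on this strictly decreasing curve
(charge tolerance `1e-4`, cross-checked against a grid-scan oracle).
The pK set is the Bjellqvist set as used by the Expasy Compute pI tool,
including its position-aware refinements: residue-specific alpha-amino pK
values and C-terminal overrides for the D/E side chains. Cysteine is
treated as carbamidomethylated (non-ionizable), matching the fixed
modification of the search settings; a `free_cysteine` flag restores the
thiol.

A strip maps pI to fraction linearly —
`ceil((pi - ph_lo)/(ph_hi - ph_lo) * n_fractions)` clamped to
`1..n_fractions` — reflecting the engineered linear gradient of commercial
IPG strips in these ranges; boundary ties resolve upward. Five presets
cover the evaluated ranges (3.0–10.0, 3.7–4.9, 3.7–4.05, 4.0–4.25,
4.2–4.45; 72 fractions each) and a 72→40 pooling preset merges
low-density fractions at the strip extremes in threes while keeping the
center at full resolution.

**Known limitation.** Dedicated peptide pI predictors recalibrate the
protein-derived pK sets on peptide IEF data; that recalibration is not
reproduced here. For the acidic PSA peptide `LSEPAELTDAVK` the Bjellqvist
set predicts pI `r round(predict_pi("LSEPAELTDAVK"), 3)`, inside the
4.0–4.25 ultranarrow strip but roughly 0.02–0.03 pH units above what a
peptide-calibrated predictor yields. On a 0.25-pH, 72-fraction strip that
small offset is ~5 fractions (assigned fraction
`r assign_fraction(predict_pi("LSEPAELTDAVK"), strip_preset("4-4.25"))`
versus a targeted window of 30–35), so fraction-level agreement with
peptide-calibrated targeting should be expected only to within a few
fractions on ultranarrow strips. Composition alone does not determine pI
under this model: the terminal residues enter with their own pK values, so
the invariance that is property-tested is under permutations of the
*interior* residues.

## The synthetic-data generator

The generator emulates the study design, not mass spectra: two (by
default) mother–child pairs, a mini-proteome with a placenta-enriched
subset, biallelic coding SNPs annotated at protein coordinates, Mendelian
genotypes, and genotype-driven peptide detection lists with planted
transfer events and b/y fragment-spectrum stubs.

Defaults and their rationale:

* `n_pairs = 2` — the study design being emulated.
* `alt_allele_freq = 0.3` — a common-variant regime, appropriate for
  SNP-array content where most assayed coding SNPs are common.
* `detection_prob_per_copy = 0.65` — the probability that the peptide
  product of one allele copy is detected. A heterozygote's canonical
  peptide rides on a single reference copy, so this default reproduces
  the observed ~65% canonical co-detection rate in heterozygous carriers.
  Detection probability for dosage *d* is `1 - (1 - p)^d`, which makes
  expected detection monotone in allele dosage (property-tested).
  Detection is drawn once per (sample, peptide): SNPs that share a
  canonical tryptic peptide do not get independent draws.
* `transfer_rate = 0.1` — per (pair, SNP) probability that a variant
  peptide producible by exactly one member while the other is wild type
  is planted in the wild-type member's detections. Every planting is
  recorded as ground truth, which is what the recovery tests audit.
* PSM counts are negative-binomial (mean 4, dispersion 2), shifted by one
  so a detection always has a supporting spectrum; published analyses
  report only medians and ranges of real PSM counts, so the mean is set
  to a low single-digit value typical of low-abundance plasma peptides.
  Transferred peptides draw from the same distribution, scaled by a
  configurable factor that defaults to 1, since transferred proteins were
  not observed to stand out in abundance.
* MS1 areas are log-normal; amino-acid composition is uniform by default
  (a frequency vector can be supplied) — composition is irrelevant to the
  logic under test.
* The father is latent: his genotype is drawn to produce the child's
  second allele but never emitted, matching the sampled cohort.
* One variant per peptide; co-occurring SAAVs within one tryptic peptide
  are not simulated.

A single top-level seed drives everything; each stage draws from a derived
sub-stream, so stages are independently reproducible and a full run is
byte-identical under the same configuration.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: chimeric/co-isolated spectra, chromatographic
and labeling noise, peptide detectability differences, protein inference
ambiguity, linkage between SNPs, and SNP-array genotyping error. The
planted-truth recovery results certify the inference logic, not
field performance on raw MS data.

## Quantification and statistics conventions

* **Label-free protein area**: mean of the top three peptide areas, where
  a peptide's area is the highest of its PSM areas; with fewer than three
  peptides the available ones are averaged (a `require_three` flag returns
  `NA` instead).
* **Isobaric-label quantification**: per-PSM channel ratios against the
  pooled internal-standard channel, per-channel median normalization,
  protein value = median of its PSM ratios, log2 on output; only PSMs
  unique to one protein and passing `q < 0.01` contribute.
* **Replicate CVs**: CV% = sd/mean on linear ratios. Within-set = CV
  across a set's internal-standard replicate channels, averaged over
  peptides then sets; between-set = CV across per-set standard means,
  averaged over peptides. Note the small-sample bias of the sd estimator:
  with two or three replicates the expected sample CV is 80–89% of the
  true value, so recovery experiments here use six standards per set.
* **Differential testing**: Welch's t per protein, Benjamini–Hochberg
  q-values per comparison, significance = `p < 0.01` and `q < 0.01`.
* **Picked FDR**: each target/decoy pair contributes only its
  higher-scoring member (ties go to the target); FDR at a threshold is
  #decoys/#targets at or above it, with tied scores treated as a single
  threshold; q-values are the monotone minimum from the worst score up.
  Protein-level identity scores are −log10 of the best peptide q-value,
  floored at 1e-15.
* **Unit conversion**: 1 fmol/µL = 1 nmol/L, so ng/mL = fmol/µL × MW(Da)
  × 10⁻³.

## Numerical and design choices

* Digestion: cleavage C-terminal to K/R, suppressed before proline (the
  Keil rule, on by default and configurable); fully tryptic, missed
  cleavages default 0 (configurable); peptide length 6–50; coordinates
  1-based inclusive throughout. A SAAV whose annotated reference residue
  disagrees with the protein sequence is a provenance error and is never
  silently corrected.
* A canonical counterpart of a variant peptide exists only when digestion
  boundaries agree between alleles; site-creating or site-destroying
  substitutions have none, and such cases are excluded from co-detection
  denominators.
* Support percentages are computed over non-missing genotypes only and
  displayed both at one decimal and rounded half-up to an integer
  (240/384 = 62.5% prints as 63%).
* The heterozygote canonical co-detection rate is undefined (reported as
  `n = 0`, not 0%) when no heterozygous variant detections exist.
* A transfer "case" is one (pair × peptide × direction) combination;
  direction counts and cross-pair concordance/discordance are computed at
  protein level.
* Genotype input is assumed to be on the coding strand of the SAAV
  annotation; triallelic and indel records are rejected with a warning.

## Problem sizes used by the test suite

The planted-recovery experiments run two mother–child pairs over 600 SNPs
on a 150-protein proteome (noise-free recovery, exactness) and 1500 SNPs
on 300 proteins (dropout-rate recovery, ~90 planted events); oracle
comparisons use 1000 random sequences for digestion, 100 peptides for pI,
and all pair-table sizes up to six for picked FDR; CV recovery uses 2000
peptides. These sizes give binomial/oracle resolution appropriate to each
assertion while keeping a full run of suite plus acceptance script within
a couple of minutes on one core.

## Worked end-to-end example

```{r pipeline}
out <- file.path(tempdir(), "demo_run")
report <- run_all(run_config(
  out_dir = out, seed = 42,
  sim = simulation_config(n_proteins = 40, n_snps = 80,
                          detection_prob_per_copy = 1,
                          flanking_ion_dropout = 0,
                          ambiguous_fraction = 0, transfer_rate = 0.15)))
cat(report$summary, sep = "\n")
```

```{r events}
read.delim(file.path(out, "transfer_events.tsv"))[,
  c("pair_id", "snp_id", "direction", "donor_klass", "recipient_klass")]
```

On this noise-free configuration the inferred events coincide exactly with
the generator's planted truth (`transfer_truth.tsv` in the same
directory), which is the package's core correctness claim.
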