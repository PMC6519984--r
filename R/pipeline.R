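# End-to-end orchestration: simulate -> build-vardb -> pi-map -> genotype
# -> curate -> infer-transfer -> quantify -> report, with plain-file
# handoff (TSV/FASTA/MGF/JSON) between stages so every intermediate is
# inspectable and any stage can run from cached files.

#' Pipeline stage names, in execution order
#' @export
PIPELINE_STAGES <- c("simulate", "build_vardb", "pi_map", "genotype",
                     "curate", "infer_transfer", "quantify", "report")

#' Pipeline run configuration
#'
#' @param out_dir directory for all stage outputs.
#' @param seed top-level seed, forwarded to the simulation config.
#' @param sim a [simulation_config()]; its seed is overridden by `seed`.
#' @param strip strip preset name for pI mapping (see [strip_preset()]).
#' @param tol_da fragment-match tolerance for curation.
#' @param require_curated transfer inference flag.
#' @param min_recipient_psms transfer inference flag.
#' @param stages character vector of enabled stages (default all).
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, sim = simulation_config(),
                       strip = "3-10", tol_da = 0.02,
                       require_curated = TRUE, min_recipient_psms = 1L,
                       stages = PIPELINE_STAGES) {
  stopifnot(all(stages %in% PIPELINE_STAGES))
  sim$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 strip = strip, tol_da = tol_da,
                 require_curated = require_curated,
                 min_recipient_psms = min_recipient_psms, stages = stages),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order, writing each stage's outputs
#' under `config$out_dir` and reading stage inputs back from those files
#' (disabled stages reuse cached files from an earlier run). Returns and
#' writes a machine-readable run report with per-stage counts, the seed,
#' the package version and a configuration hash.
#'
#' @param config a [run_config()].
#' @return the run report (list), invisibly also written to
#'   `report.json` and `report.txt` in `out_dir`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  enabled <- function(stage) stage %in% config$stages
  report <- list(
    package_version = as.character(packageVersion("saavtrace")),
    seed = config$seed, config_hash = config_hash(unclass(config)),
    stages = list())
  run_stage <- function(stage, fn) {
    if (!enabled(stage)) {
      report$stages[[stage]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    res <- tryCatch(fn(), error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    report$stages[[stage]] <<- c(list(status = "ok"), res)
  }

  run_stage("simulate", function() {
    sim <- simulate_study(config$sim, out_dir = out)
    list(n_proteins = nrow(sim$proteome), n_snps = nrow(sim$saav_table),
         n_detections = nrow(sim$detections),
         n_planted_transfers = nrow(sim$truth))
  })

  run_stage("build_vardb", function() {
    proteome <- read_proteome_fasta(file.path(out, "proteome.fasta"))
    saav <- read_saav_table(file.path(out, "saav_table.tsv"))
    vdb <- build_variant_db(proteome, saav)
    write_tsv(vdb, file.path(out, "variant_db.tsv"))
    list(n_variant_peptides = nrow(vdb),
         n_with_canonical = sum(!is.na(vdb$canonical_peptide)))
  })

  run_stage("pi_map", function() {
    vdb <- read.delim(file.path(out, "variant_db.tsv"),
                      stringsAsFactors = FALSE)
    strip <- strip_preset(config$strip)
    if (nrow(vdb) > 0L) {
      vdb$pi <- vapply(vdb$peptide, predict_pi, numeric(1),
                       USE.NAMES = FALSE)
      vdb$fraction <- assign_fraction(vdb$pi, strip)
    }
    write_tsv(vdb, file.path(out, "pi_map.tsv"))
    list(n_peptides = nrow(vdb),
         n_out_of_strip = if (nrow(vdb)) sum(is.na(vdb$fraction)) else 0L)
  })

  run_stage("genotype", function() {
    genotypes <- read_genotypes(file.path(out, "genotypes.tsv"))
    detections <- read.delim(file.path(out, "detections.tsv"),
                             stringsAsFactors = FALSE)
    supp <- support_summary(detections, genotypes)
    supp
  })

  run_stage("curate", function() {
    detections <- read.delim(file.path(out, "detections.tsv"),
                             stringsAsFactors = FALSE)
    spectra <- read_mgf(file.path(out, "spectra.mgf"))
    cur <- curate_detections(detections, spectra, tol_da = config$tol_da)
    write_tsv(cur, file.path(out, "detections_curated.tsv"))
    attr(cur, "curation_summary")
  })

  run_stage("infer_transfer", function() {
    detections <- read.delim(file.path(out, "detections_curated.tsv"),
                             stringsAsFactors = FALSE)
    genotypes <- read_genotypes(file.path(out, "genotypes.tsv"))
    pairs <- read.delim(file.path(out, "pairs.tsv"),
                        stringsAsFactors = FALSE)
    res <- infer_transfers(detections, genotypes, pairs,
                           require_curated = config$require_curated,
                           min_recipient_psms = config$min_recipient_psms)
    write_tsv(res$events, file.path(out, "transfer_events.tsv"))
    write_tsv(res$unexplained, file.path(out, "unexplained.tsv"))
    summ <- summarize_transfers(res$events, pairs)
    list(n_events = nrow(res$events),
         n_unexplained = nrow(res$unexplained),
         n_cases = summ$n_cases,
         n_proteins_baby_to_mother =
           unname(summ$direction_counts["baby_to_mother"]),
         n_proteins_mother_to_baby =
           unname(summ$direction_counts["mother_to_baby"]),
         concordant_proteins = summ$concordant,
         discordant_proteins = summ$discordant)
  })

  run_stage("quantify", function() {
    detections <- read.delim(file.path(out, "detections.tsv"),
                             stringsAsFactors = FALSE)
    proteome <- read_proteome_fasta(file.path(out, "proteome.fasta"))
    pairs <- read.delim(file.path(out, "pairs.tsv"),
                        stringsAsFactors = FALSE)
    areas <- do.call(rbind, lapply(split(detections, detections$protein_id),
      function(d) data.frame(protein_id = d$protein_id[1],
                             area = top3_protein_area(
                               data.frame(peptide = d$peptide,
                                          area = d$ms1_area)))))
    write_tsv(areas, file.path(out, "protein_areas.tsv"))
    leak <- tissue_leakage_summary(detections, proteome, "placenta", pairs)
    write_tsv(leak$per_sample, file.path(out, "tissue_leakage.tsv"))
    list(n_quantified_proteins = nrow(areas),
         n_placenta_tagged = length(leak$tagged_proteins))
  })

  if (enabled("report")) {
    report$summary <- make_report(report)
    report$stages$report <- list(status = "ok")
  }
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  writeLines(report$summary %||% character(0),
             file.path(out, "report.txt"))
  report
}

#' Render human-readable summary lines from a run report
#'
#' @param report the in-progress report list from [run_all()].
#' @return character vector of summary lines.
#' @export
make_report <- function(report) {
  st <- report$stages
  fmt <- function(x) if (is.null(x) || is.na(x)) "NA" else format(x)
  lines <- character(0)
  if (!is.null(st$simulate) && st$simulate$status == "ok") {
    lines <- c(lines, sprintf(
      "simulated %s proteins, %s SNPs, %s detections, %s planted transfers",
      fmt(st$simulate$n_proteins), fmt(st$simulate$n_snps),
      fmt(st$simulate$n_detections), fmt(st$simulate$n_planted_transfers)))
  }
  if (!is.null(st$genotype) && st$genotype$status == "ok") {
    pct <- st$genotype$pct_supported
    lines <- c(lines, sprintf(
      "%s SAAV peptide detections, %s (%s) with genomic support",
      fmt(st$genotype$n_detections), fmt(st$genotype$n_supported),
      if (is.null(pct) || is.na(pct)) "NA" else sprintf("%.1f%%", pct)))
  }
  if (!is.null(st$curate) && st$curate$status == "ok") {
    lines <- c(lines, sprintf(
      "removed %s ambiguous substitutions; %s of %s variant detections passed curation",
      fmt(st$curate$n_ambiguous_removed), fmt(st$curate$n_curated),
      fmt(st$curate$n_variant)))
  }
  if (!is.null(st$infer_transfer) && st$infer_transfer$status == "ok") {
    it <- st$infer_transfer
    lines <- c(lines, sprintf(
      "%s transfer events: %s proteins baby->mother, %s mother->baby",
      fmt(it$n_events), fmt(it$n_proteins_baby_to_mother),
      fmt(it$n_proteins_mother_to_baby)))
  }
  if (length(lines) == 0L) lines <- "no stages produced output"
  lines
}
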