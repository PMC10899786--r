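# Pipeline orchestration: one declarative configuration drives the
# simulate / align / qc / call / tandem / incision / nucprox stages,
# each writing TSV outputs plus a JSON manifest with seeds and record
# counts, deterministically under fixed seeds.

#' Species presets for read length filtering
#'
#' Published XR-seq read length ranges (and the expected modal length
#' used to disambiguate bimodal score profiles) for the four species
#' most often profiled.
#'
#' @format named list of lists with `length_range` and
#'   `expected_length`.
#' @export
species_presets <- list(
  human       = list(length_range = c(22L, 30L), expected_length = 26L),
  arabidopsis = list(length_range = c(24L, 30L), expected_length = 26L),
  yeast       = list(length_range = c(22L, 25L), expected_length = 23L),
  ecoli       = list(length_range = c(11L, 13L), expected_length = 12L)
)

#' Default pipeline configuration
#'
#' @param outdir output directory.
#' @param seed master seed; every stage derives its randomness from it.
#' @param species preset name (see [species_presets]).
#' @param n_fragments simulated fragment count.
#' @param ... overrides passed to [sim_config()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(outdir = "xrlesion_out", seed = 1L,
                            species = "human", n_fragments = 2000L,
                            ...) {
  preset <- species_presets[[species]]
  if (is.null(preset)) stop("unknown species preset: ", species)
  sim <- sim_config(n_fragments = n_fragments, seed = seed,
                    length_range = preset$length_range, ...)
  structure(list(outdir = outdir, seed = as.integer(seed),
                 species = species, sim = sim,
                 length_range = preset$length_range,
                 expected_length = preset$expected_length,
                 tgg_motif = "TGG"),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a `sim`
#' block holds [sim_config()] overrides.
#'
#' @param path YAML file.
#' @return a `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_over <- y$sim
  args <- y[setdiff(names(y), "sim")]
  do.call(pipeline_config, c(args, sim_over))
}

#' Run the analysis pipeline on a synthetic fixture
#'
#' Stages: `simulate` (genome, reads, dyads, blacklist, truth),
#' `align` (internal placer on the simulated reads), `qc` (basic
#' filters, derived length range, TGG filter), `call` (position
#' matrices and enrichment calls, spectra), `tandem` (revertant calls on
#' reads the single-mismatch placer rejected), `incision`
#' (records, contribution decomposition, coupling regression with
#' shuffle control, HYV and composition profiles), `nucprox`
#' (blacklist-filtered dyad metaprofile with significance).  `all`
#' chains everything.  Every stage writes TSVs into `cfg$outdir` and
#' updates `manifest.json`.
#'
#' @param cfg a [pipeline_config()] object (or YAML path).
#' @param stage one of `simulate`, `all`.
#' @return invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(cfg, stage = c("all", "simulate")) {
  stage <- match.arg(stage)
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(
    utils::packageVersion("xrlesion")), seed = cfg$seed,
    species = cfg$species, counts = list())

  sim <- simulate_xrseq(cfg$sim)
  write_sim_outputs(sim, cfg$outdir)
  manifest$counts$simulated <- nrow(sim$reads)
  res <- list(sim = sim)
  if (stage == "simulate") {
    jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(res))
  }

  index <- build_index(sim$genome)
  aln <- align_reads(sim$reads$seq, index, ids = sim$reads$read_id)
  if (is.null(aln$reads)) stop("no read aligned; check the simulation")
  aln$reads$has_indel <- FALSE
  manifest$counts$aligned <- nrow(aln$reads)
  manifest$counts$unaligned <- nrow(aln$unaligned)
  write_tsv(aln$reads[, c("read_id", "contig", "start", "end", "strand",
                          "n_mismatches")],
            file.path(cfg$outdir, "alignments.tsv"))

  qc <- basic_filters(aln$reads, cfg$length_range)
  tf <- tgg_filter(qc$kept, sim$genome, motif = cfg$tgg_motif)
  qc$report <- rbind(
    qc$report[qc$report$rule != "retained" & qc$report$rule != "input", ],
    data.frame(rule = c("tgg_flank", "retained", "input"),
               count = c(nrow(tf$removed), nrow(tf$kept),
                         qc$report$count[qc$report$rule == "input"])))
  write_tsv(qc$report, file.path(cfg$outdir, "filter_report.tsv"))
  derived <- tryCatch(
    derive_length_range(tf$kept, expected_length = cfg$expected_length),
    error = function(e) cfg$length_range)
  manifest$counts$qc_retained <- nrow(tf$kept)
  manifest$derived_length_range <- as.integer(derived)
  kept <- tf$kept
  res$qc <- list(kept = kept, report = qc$report,
                 derived_length_range = derived)

  mm <- aln$mismatches[aln$mismatches$read_id %in% kept$read_id, ,
                       drop = FALSE]
  spectrum <- mismatch_spectrum(mm)
  ctxspec <- context_spectrum(mm)
  ctmm <- mm[mm$ref == "C" & mm$alt == "T" & !mm$is_tandem, , drop = FALSE]
  pm3 <- position_matrix(kept, ctmm, anchor = "3prime")
  calls <- call_enriched_positions(pm3)
  write_tsv(spectrum, file.path(cfg$outdir, "mismatch_spectrum.tsv"))
  write_tsv(ctxspec$contexts, file.path(cfg$outdir, "context_spectrum.tsv"))
  write_tsv(as.data.frame(pm3), file.path(cfg$outdir, "position_matrix_3prime.tsv"))
  write_tsv(calls, file.path(cfg$outdir, "enriched_positions.tsv"))
  manifest$dipyrimidine_fraction <- ctxspec$dipyrimidine_fraction
  res$call <- list(spectrum = spectrum, contexts = ctxspec,
                   position_matrix = pm3, calls = calls)

  multi <- unique(mm$read_id[duplicated(mm$read_id)])
  cand <- unique(c(aln$unaligned$read_id, multi))
  cand_seq <- sim$reads$seq[match(cand, sim$reads$read_id)]
  td <- tandem_pipeline(cand_seq, index, genome = sim$genome,
                        length_range = cfg$length_range,
                        motif = cfg$tgg_motif, ids = cand)
  manifest$counts$tandem_calls <- if (is.null(td$calls)) 0L else
    nrow(td$calls)
  if (!is.null(td$calls) && nrow(td$calls)) {
    write_tsv(td$calls, file.path(cfg$outdir, "tandem_calls.tsv"))
  }
  res$tandem <- td

  rec <- incision_records(kept, mm, kind = "single_CT")
  if (!is.null(td$records)) rec <- rbind(rec, td$records)
  write_tsv(rec, file.path(cfg$outdir, "incision_records.tsv"))
  contrib <- contribution_decomposition(rec)
  coup <- coupling_regression(rec, "d3_vs_d5")
  coupL <- coupling_regression(rec, "read_length_vs_d5")
  shuf <- shuffle_control(rec, seed = cfg$seed + 11L)
  coup_shuf <- coupling_regression(shuf, "d3_vs_d5")
  reg <- rbind(coup, coupL,
               transform(coup_shuf, target = "d3_vs_d5_shuffled"))
  write_tsv(reg, file.path(cfg$outdir, "coupling_regressions.tsv"))
  write_tsv(contrib$by_length, file.path(cfg$outdir, "contributions.tsv"))
  hyv <- hyv_profile(kept, sim$genome)
  comp <- composition_matrix(kept, sim$genome)
  write_tsv(hyv, file.path(cfg$outdir, "hyv_profile.tsv"))
  write_tsv(comp, file.path(cfg$outdir, "composition_matrix.tsv"))
  manifest$coupling_percent <- coup$coupling_percent
  manifest$contribution_5prime <- contrib$percent_5prime
  res$incision <- list(records = rec, contributions = contrib,
                       regressions = reg, hyv = hyv, composition = comp)

  dy <- blacklist_filter(sim$dyads, sim$blacklist)
  dp <- dyad_profile(rec, dy)
  prof <- bin_significance(dp)
  write_tsv(prof, file.path(cfg$outdir, "dyad_profile.tsv"))
  manifest$counts$dyads_used <- nrow(dy)
  res$nucprox <- list(profile = prof, dyad_profile = dp)

  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
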