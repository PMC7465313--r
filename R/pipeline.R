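## End-to-end orchestration: genome -> guide panel -> digestion/library ->
## simulated run -> QC -> allele phasing, with one global seed fanned out to
## per-stage seeds at fixed offsets so stages can be rerun in isolation, and
## a config hash echoed into every JSON artifact.

#' Pipeline run configuration
#'
#' @param genome_config A [synthetic_genome_config()].
#' @param guides Optional guide `data.frame`; when `NULL`, an excision panel
#'   is planned around the target-locus window with [plan_panel()].
#' @param sim Named list of [sim_config()] overrides.
#' @param qc Named list: `pass_q` (7), `min_mapq` (40), `min_coverage` (25),
#'   `bin_size` (1000), `window_mode` (`"cut_span"`).
#' @param phase Named list: `min_support` (5), `max_edit_fraction` (0.2).
#' @param seed Global seed; stage seeds are derived at fixed offsets
#'   (digest/library seed+1, sequencing seed+2).
#' @return Object of class `run_config`.
#' @export
run_config <- function(genome_config, guides = NULL, sim = list(),
                       qc = list(), phase = list(), seed = 1) {
  stopifnot(inherits(genome_config, "synthetic_genome_config"))
  qc <- utils::modifyList(list(pass_q = 7, min_mapq = 40, min_coverage = 25,
                               bin_size = 1000, window_mode = "cut_span"), qc)
  phase <- utils::modifyList(list(min_support = 5, max_edit_fraction = 0.2),
                             phase)
  structure(list(genome_config = genome_config, guides = guides, sim = sim,
                 qc = qc, phase = phase, seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass_deep(config), auto_unbox = TRUE,
                              digits = NA, null = "null", force = TRUE), tf)
  unname(tools::md5sum(tf))
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else x
}

write_json_artifact <- function(x, path, hash) {
  jsonlite::write_json(c(list(config_hash = hash), x), path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Run the full pipeline into an output directory
#'
#' Stages: make-genome, design, digest (+dephosphorylation, dA-tailing,
#' adapter ligation), simulate, qc, phase. Deterministic given the config
#' seed; every JSON artifact carries the config hash, and a machine-parsable
#' log records stage timings.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results and `paths`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  logf <- file.path(out_dir, "pipeline.log")
  cat(sprintf("stage\tstatus\tseconds\tconfig_hash=%s\n", hash), file = logf)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      cat(sprintf("%s\tfailed\t%.2f\n", name,
                  proc.time()[["elapsed"]] - t0), file = logf, append = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    dt <- proc.time()[["elapsed"]] - t0
    cat(sprintf("%s\tok\t%.2f\n", name, dt), file = logf, append = TRUE)
    message(sprintf("[capxcise] %s done in %.2fs", name, dt))
    res
  }
  paths <- list()

  gen <- stage("make-genome", {
    g <- make_genome(config$genome_config)
    paths$genome <- file.path(out_dir, "genome.fa")
    write_fasta(g$sequences, paths$genome)
    tp <- write_genome_truth(g$truth, file.path(out_dir, "genome"))
    paths$truth_json <- tp[["json"]]; paths$truth_bed <- tp[["bed"]]
    g
  })

  guides <- stage("design", {
    gd <- config$guides
    if (is.null(gd)) {
      tw <- gen$truth$target[gen$truth$target$haplotype == "A", ]
      roi <- list(contig = tw$contig, start = tw$window_start,
                  end = tw$window_end)
      gd <- plan_panel(roi, gen$sequences, "excision",
                       params = list(n_per_side = 2))
    }
    paths$guides <- file.path(out_dir, "guides.tsv")
    write_guides(gd, paths$guides)
    gd
  })

  simcfg <- do.call(sim_config, c(list(profile = "calibrated_run",
                                       seed = config$seed + 2L), config$sim))

  frags <- stage("digest", {
    f <- with_seed(config$seed + 1L, {
      f <- digest_genome(gen$sequences, guides)
      f <- dephosphorylate(f, simcfg$dephosphorylation_efficiency)
      f <- da_tail(f)
      ligate_adapters(f, simcfg)
    })
    validate_fragments(f, nchar(gen$sequences))
    paths$fragments_bed <- file.path(out_dir, "fragments.bed")
    utils::write.table(
      data.frame(f$template, f$start - 1L, f$end),
      paths$fragments_bed, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
    paths$fragments_json <- file.path(out_dir, "fragments.json")
    write_json_artifact(list(fragments = f), paths$fragments_json, hash)
    f
  })

  run <- stage("simulate", {
    r <- simulate_run(gen$sequences, frags, simcfg, truth = gen$truth)
    paths$fastq <- file.path(out_dir, "reads.fastq")
    write_fastq(r, paths$fastq)
    paths$paf <- file.path(out_dir, "truth.paf")
    write_paf(truth_paf(r), paths$paf)
    paths$reads_bed <- file.path(out_dir, "truth_reads.bed")
    write_truth_bed(r, paths$reads_bed)
    r
  })

  qc <- stage("qc", {
    windows <- target_windows(gen$sequences, guides,
                              mode = config$qc$window_mode)
    paf <- truth_paf(run)
    rs <- run_read_stats(run, pass_threshold = config$qc$pass_q)
    er <- enrichment_report(paf, windows)
    ot <- detect_offtargets(paf, windows,
                            min_coverage = config$qc$min_coverage,
                            min_mapq = config$qc$min_mapq,
                            bin_size = config$qc$bin_size)
    paths$qc_read_stats <- file.path(out_dir, "qc_read_stats.tsv")
    utils::write.table(rs, paths$qc_read_stats, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$qc_enrichment <- file.path(out_dir, "qc_enrichment.tsv")
    utils::write.table(er, paths$qc_enrichment, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$qc_offtargets <- file.path(out_dir, "qc_offtargets.tsv")
    utils::write.table(ot, paths$qc_offtargets, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$qc_json <- file.path(out_dir, "qc.json")
    write_json_artifact(list(windows = windows, read_stats = rs,
                             enrichment = er, offtargets = ot),
                        paths$qc_json, hash)
    list(windows = windows, read_stats = rs, enrichment = er, offtargets = ot)
  })

  alleles <- stage("phase", {
    on <- overlaps_windows(run$reads$contig, run$reads$start, run$reads$end,
                           qc$windows)
    reads <- stats::setNames(run$sequences[on], run$reads$id[on])
    al <- if (length(reads) >= config$phase$min_support) {
      phase_alleles(reads, motif = gen$truth$repeat_unit,
                    min_support = config$phase$min_support,
                    max_edit_fraction = config$phase$max_edit_fraction)
    } else NULL
    paths$alleles <- file.path(out_dir, "alleles.json")
    write_json_artifact(
      if (is.null(al)) list(alleles = NULL, zygosity = "ambiguous",
                            note = "too few on-target reads")
      else list(alleles = al$alleles, zygosity = al$zygosity,
                n_reads = al$n_reads),
      paths$alleles, hash)
    al
  })

  invisible(list(genome = gen, guides = guides, fragments = frags, run = run,
                 qc = qc, alleles = alleles, config_hash = hash,
                 paths = paths))
}
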