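# One-command orchestration: simulate (or load) -> align -> reconstruct ->
# damage -> liftover, with a JSON config, JSON-lines logging, and
# deterministic seeding. Identical config + seed gives byte-identical
# outputs.

#' Read a pipeline configuration (JSON)
#'
#' @param path JSON file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# derive the number of pairs needed for a target endogenous depth
pairs_for_depth <- function(depth, genome_length, read_len, endogenous_fraction) {
  as.integer(ceiling(depth * genome_length /
                       (2 * read_len * endogenous_fraction)))
}

#' Run the full reconstruction pipeline
#'
#' The configuration is a list (or path to a JSON file) with either a
#' `simulate` block (truth genome and library parameters; a diverged query
#' is generated) or an `inputs` block (`fastq` paths, `query` FASTA,
#' optional `annotation` TSV), plus optional `align` (preset name and
#' overrides), `call` (policy fields) and `seed`. All outputs are written
#' under `outdir`: reconstruction FASTA, per-site calls TSV, tally JSON,
#' damage report, feature report (when an annotation is present), and a
#' JSON-lines run log recording every parameter and the seed.
#'
#' @param config list or path to JSON config.
#' @param outdir output directory (created; overrides `config$outdir`).
#' @return Bundle list (objects + paths), invisibly.
#' @export
run_end_to_end <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_config(config)
  if (!is.list(config)) stop("config error: config must be a list or JSON path")
  has_sim <- !is.null(config$simulate)
  has_inputs <- !is.null(config$inputs)
  if (has_sim == has_inputs)
    stop("config error: exactly one of 'simulate' or 'inputs' is required")
  if (has_inputs) {
    inp <- config$inputs
    for (f in c("fastq1", "fastq2"))
      if (!is.null(inp[[f]]) && !file.exists(inp[[f]]))
        stop("config error: missing input file: ", inp[[f]])
    if (is.null(inp$query)) stop("config error: inputs$query is required")
    if (!file.exists(inp$query))
      stop("config error: missing input file: ", inp$query)
    if (!is.null(inp$annotation) && !file.exists(inp$annotation))
      stop("config error: missing input file: ", inp$annotation)
  }
  outdir <- outdir %||% config$outdir %||%
    file.path(tempdir(), paste0("mitoanchor_run_", format(Sys.time(), "%H%M%S")))
  created <- !dir.exists(outdir)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)

  log_lines <- character(0)
  log_event <- function(stage, ...) {
    entry <- list(stage = stage, ...)
    log_lines <<- c(log_lines,
                    jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA))
  }
  ok <- FALSE
  on.exit({
    if (!ok && created) unlink(outdir, recursive = TRUE) # no partial bundles
  })

  set.seed(seed)
  log_event("start", seed = seed, outdir = outdir)

  ann <- NULL
  if (has_sim) {
    s <- config$simulate
    truth_len <- as.integer(s$truth_length %||% 16000L)
    truth <- random_genome(truth_len, gc = s$gc %||% 0.45, id = "truth")
    query <- mutate_genome(truth, s$divergence %||% 0.05,
                           ts_tv_ratio = s$ts_tv_ratio %||% 2)
    query$id <- "query"
    rl <- as.integer(s$read_len %||% 150L)
    endo <- s$endogenous_fraction %||% 1
    n_pairs <- if (!is.null(s$n_pairs)) as.integer(s$n_pairs)
               else pairs_for_depth(s$depth %||% 20, truth_len, rl, endo)
    lp <- library_params(n_pairs = n_pairs, read_len = rl,
                         insert_mean = s$insert_mean %||% 100,
                         insert_sd = s$insert_sd %||% 40,
                         endogenous_fraction = endo,
                         seq_error = s$seq_error %||% 0, seed = seed)
    dmg <- if (!is.null(s$damage))
      damage_params(s$damage$d_max %||% 0.3, s$damage$decay %||% 0.5,
                    s$damage$floor %||% 0.01)
    lib <- simulate_library(truth, lp, damage = dmg,
                            background_length = as.integer(s$background_length %||% 50000L))
    write_fasta(truth, file.path(outdir, "truth.fasta"))
    write_fasta(query, file.path(outdir, "query.fasta"))
    write_library(lib, file.path(outdir, "reads"))
    reads <- c(lib$reads1, lib$reads2)
    log_event("simulate", truth_length = truth_len, n_pairs = n_pairs,
              divergence = s$divergence %||% 0.05, endogenous_fraction = endo,
              damage = if (is.null(dmg)) "off" else unclass(dmg))
  } else {
    inp <- config$inputs
    reads <- character(0)
    for (f in c(inp$fastq1, inp$fastq2)) reads <- c(reads, read_fastq(f))
    query <- read_fasta(inp$query, circular = TRUE)[[1L]]
    if (!is.null(inp$annotation)) ann <- read_annotation(inp$annotation)
    log_event("inputs", n_reads = length(reads), query = query$id,
              query_length = nchar(query$residues))
  }

  if (!length(reads))
    warning("no reads provided; reconstruction will be all N")

  preset_args <- config$align %||% list()
  preset <- do.call(align_preset,
                    c(list(name = preset_args$preset %||% "low"),
                      preset_args[setdiff(names(preset_args), "preset")]))
  aset <- align_library(reads, query, preset)
  write_alignments(aset, file.path(outdir, "alignments.tsv"))
  log_event("align", preset = preset$name, n_reads = aset$summary$n_reads,
            n_aligned = aset$summary$n_aligned,
            aligned_fraction = aset$summary$aligned_fraction)

  policy <- do.call(call_policy, config$call %||% list())
  pile <- build_pileup(aset, query)
  recon <- reconstruct(pile, query, policy,
                       provenance = list(preset = preset$name, seed = seed))
  write_reconstruction(recon, file.path(outdir, "reconstruction"))
  log_event("reconstruct", n_count = recon$tally$n_count,
            n_fraction = recon$tally$n_fraction,
            substituted = recon$tally$substituted)

  amb <- summarize_ambiguities(recon, query)
  dmg_report <- deamination_asymmetry(amb)
  write_damage_report(dmg_report, amb, file.path(outdir, "damage"))
  log_event("damage", n_consistent = dmg_report$n_consistent,
            n_other = dmg_report$n_other,
            asymmetry_ratio = dmg_report$asymmetry_ratio,
            binom_p = dmg_report$binom_p)

  missing_report <- NULL
  if (!is.null(ann)) {
    lifted <- liftover_annotation(ann, recon)
    missing_report <- feature_missingness(recon, lifted)
    write.table(missing_report$features, file.path(outdir, "features.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_feature_table(lifted, file.path(outdir, "reconstruction.tbl"))
    log_event("liftover", n_features = nrow(missing_report$features),
              n_fully_missing = missing_report$genome$n_fully_missing)
  }

  comp <- completeness_report(recon)
  jsonlite::write_json(list(completeness = unclass(comp),
                            alignment = aset$summary,
                            seed = seed, preset = preset$name,
                            policy = unclass(policy)),
                       file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_event("done")
  writeLines(unlist(log_lines), file.path(outdir, "run_log.jsonl"))
  ok <- TRUE
  invisible(list(outdir = outdir, reconstruction = recon, alignments = aset,
                 damage = dmg_report, completeness = comp,
                 missingness = missing_report,
                 truth = if (has_sim) truth else NULL,
                 query = query))
}
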