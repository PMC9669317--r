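# Orchestration: one command per analysis stage, driven by a config list or
# YAML file. Each run writes versioned TSV/FASTA reports plus a log naming
# the config hash and seed.

#' Assemble a pipeline run configuration
#'
#' @param input Path to the source FASTA (full-length 16S sequences).
#' @param universal Path to a universal database as SINTAX-annotated FASTA.
#' @param asvs,counts Paths to a short-read ASV FASTA and its count table.
#' @param out_dir Output directory (created if absent).
#' @param prefix Placeholder prefix.
#' @param thresholds A [threshold_table()].
#' @param classifier A [classifier_params()].
#' @param fwd,rev Amplicon primer strings (default 799F/1192R).
#' @param min_rel_abundance,id_cut Coverage-evaluation filters.
#' @param seed Integer seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(input = NULL, universal = NULL, asvs = NULL,
                       counts = NULL, out_dir = "ecotaxdb_out",
                       prefix = "ECO",
                       thresholds = threshold_table(),
                       classifier = classifier_params(),
                       fwd = standard_primers("799F"),
                       rev = standard_primers("1192R"),
                       min_rel_abundance = 1e-4, id_cut = 99.0,
                       seed = 1L) {
  structure(list(input = input, universal = universal, asvs = asvs,
                 counts = counts, out_dir = out_dir, prefix = prefix,
                 thresholds = thresholds, classifier = classifier,
                 fwd = fwd, rev = rev,
                 min_rel_abundance = min_rel_abundance, id_cut = id_cut,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Recognised keys mirror the [run_config()] arguments; threshold and
#' classifier sub-sections override individual defaults.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  thr <- do.call(threshold_table, as.list(y$thresholds %||% list()))
  cls <- do.call(classifier_params, as.list(y$classifier %||% list()))
  keep <- intersect(names(y), c("input", "universal", "asvs", "counts",
                                "out_dir", "prefix", "fwd", "rev",
                                "min_rel_abundance", "id_cut", "seed"))
  do.call(run_config, c(y[keep], list(thresholds = thr, classifier = cls)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

config_stamp <- function(config) {
  paste0("config_hash=", rlang::hash(config), " seed=", config$seed)
}

write_stamped_tsv <- function(df, path, config) {
  con <- file(path, "w")
  writeLines(paste0("# ", config_stamp(config)), con)
  close(con)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

require_inputs <- function(config, keys) {
  for (k in keys) {
    if (is.null(config[[k]])) abort(paste0("config is missing '", k, "'"))
    if (is.character(config[[k]]) && !file.exists(config[[k]])) {
      abort(paste0("input path does not exist: ", config[[k]]))
    }
  }
}

#' Run one pipeline stage
#'
#' Commands: `simulate` (write a synthetic universal database, query FASTA
#' and truth table), `build` (construct the reference database), `classify`,
#' `novelty`, `coverage`, `rates`, `resolution`, `survey`. Outputs are TSV
#' and FASTA files in `config$out_dir`, each stamped with the config hash
#' and seed; the config itself is echoed as YAML.
#'
#' @param command Stage name.
#' @param config A [run_config()].
#' @param verbose Print progress messages.
#' @return Invisible named list of the paths written.
#' @export
run_pipeline <- function(command, config, verbose = FALSE) {
  cmds <- c("simulate", "build", "classify", "novelty", "coverage",
            "rates", "resolution", "survey")
  if (!command %in% cmds) {
    abort(paste0("unknown command '", command, "'; expected one of: ",
                 paste(cmds, collapse = ", ")))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(...)
  op <- function(name) file.path(config$out_dir, name)
  # echo config
  cfg_path <- op("config.yaml")
  yaml::write_yaml(c(list(command = command, stamp = config_stamp(config)),
                     lapply(config, function(x) if (is.list(x)) unclass(x) else unclass(x))),
                   cfg_path)
  paths <- list(config = cfg_path)
  pair <- primer_pair(config$fwd, config$rev)

  if (command == "simulate") {
    sim <- simulate_reference(sim_spec(seed = config$seed,
                                       thresholds = config$thresholds))
    write_sintax_fasta(sim$universal, op("universal.fasta"))
    write_fasta(sim$queries, op("queries.fasta"), width = 0)
    write_stamped_tsv(sim$truth, op("truth.tsv"), config)
    amp <- simulate_amplicon_dataset(sim$universal, pair,
                                     sim_spec(seed = config$seed))
    write_fasta(amp$asvs, op("asvs.fasta"), width = 0)
    write_count_table(amp$counts, op("counts.tsv"))
    paths <- c(paths, list(universal = op("universal.fasta"),
                           queries = op("queries.fasta"),
                           truth = op("truth.tsv"),
                           asvs = op("asvs.fasta"), counts = op("counts.tsv")))
    say("simulate: wrote universal/queries/truth/asvs/counts")
    return(invisible(paths))
  }

  if (command == "simulate" || command %in% c("build")) {
    require_inputs(config, c("input", "universal"))
  }

  load_db <- function() read_sintax_fasta(config$universal)

  if (command == "build") {
    seqs <- read_fasta(config$input)
    universal <- load_db()
    built <- build_database(seqs, universal,
                            build_config(thresholds = config$thresholds,
                                         prefix = config$prefix))
    write_sintax_fasta(built$db, op("database.fasta"))
    write_qiime_taxonomy(built$db, op("database.qiime.tsv"))
    write_stamped_tsv(built$report, op("build_report.tsv"), config)
    write_stamped_tsv(
      select(built$db, -"sequence"), op("database.tsv"), config)
    say("build: ", nrow(built$db), " records")
    return(invisible(c(paths, list(database = op("database.fasta")))))
  }

  # remaining commands need a built database
  require_inputs(config, "universal")
  db <- load_db()

  if (command == "classify") {
    require_inputs(config, "asvs")
    asvs <- read_fasta(config$asvs)
    params <- config$classifier
    params$seed <- config$seed
    res <- classify(asvs, train_index(db, params), params)
    write_stamped_tsv(res, op("classifications.tsv"), config)
    return(invisible(c(paths, list(classifications = op("classifications.tsv")))))
  }
  if (command == "novelty") {
    nov <- taxonomy_novelty(db, prefix = config$prefix)
    out <- list(taxonomy = op("taxonomy_novelty.tsv"))
    write_stamped_tsv(nov, out$taxonomy, config)
    if (!is.null(config$input)) {
      # sequence novelty needs the universal db the records were mapped to
      uni <- read_sintax_fasta(config$input)
      seqnov <- sequence_novelty(db, uni, config$thresholds)
      out$sequence <- op("sequence_novelty.tsv")
      write_stamped_tsv(seqnov, out$sequence, config)
    }
    return(invisible(c(paths, out)))
  }
  if (command == "coverage") {
    require_inputs(config, c("asvs", "counts"))
    cov <- coverage_eval(read_fasta(config$asvs),
                         read_count_table(config$counts), db,
                         config$min_rel_abundance, config$id_cut)
    write_stamped_tsv(cov, op("coverage.tsv"), config)
    return(invisible(c(paths, list(coverage = op("coverage.tsv")))))
  }
  if (command == "rates") {
    require_inputs(config, "asvs")
    params <- config$classifier
    params$seed <- config$seed
    counts <- if (!is.null(config$counts)) read_count_table(config$counts)
    rates <- classification_rate(read_fasta(config$asvs), db, params,
                                 counts, config$min_rel_abundance)
    write_stamped_tsv(rates, op("rates.tsv"), config)
    return(invisible(c(paths, list(rates = op("rates.tsv")))))
  }
  if (command == "resolution") {
    params <- config$classifier
    params$seed <- config$seed
    params$strand <- "plus"
    ins <- extract_insilico_asvs(db, pair)
    res <- resolution_eval(ins, db, params)
    write_stamped_tsv(res, op("resolution.tsv"), config)
    return(invisible(c(paths, list(resolution = op("resolution.tsv")))))
  }
  if (command == "survey") {
    sv <- survey_database(db, pair)
    write_stamped_tsv(sv, op("survey.tsv"), config)
    summ <- attr(sv, "summary")
    if (!is.null(summ)) {
      write_stamped_tsv(summ, op("survey_by_taxon.tsv"), config)
    }
    return(invisible(c(paths, list(survey = op("survey.tsv")))))
  }
}
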