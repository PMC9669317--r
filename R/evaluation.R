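# Database evaluation: sequence/taxonomy novelty, high-identity coverage of
# short-read ASVs, classification rates, and in-silico amplicon resolution.

#' Per-rank sequence novelty of a database against a universal reference
#'
#' A record is novel at rank r when its best-hit identity against the
#' universal database falls below that rank's threshold; the novelty
#' categories are therefore nested (counts non-decreasing from phylum to
#' species). Uses the `best_hit_identity` column when present, otherwise
#' maps records against `universal` first.
#'
#' @param db Database tibble.
#' @param universal Universal reference tibble (`id`, `sequence`); only
#'   needed when `db` lacks `best_hit_identity`.
#' @param thresholds A [threshold_table()].
#' @param by_domain Split counts by the `domain` column.
#' @return Tibble of class `eco_novelty`: `rank`, `threshold`, `n_novel`,
#'   `pct_novel` (and `domain` when split).
#' @export
sequence_novelty <- function(db, universal = NULL,
                             thresholds = threshold_table(),
                             by_domain = FALSE) {
  if (is.null(db$best_hit_identity)) {
    if (is.null(universal)) {
      abort("db lacks best_hit_identity; supply a universal database")
    }
    db$best_hit_identity <- map_queries(db, universal)$identity
  }
  tally <- function(ids) {
    tibble(
      rank = threshold_ranks(),
      threshold = as.numeric(thresholds[threshold_ranks()]),
      n_novel = vapply(threshold_ranks(),
                       function(r) sum(ids < thresholds[[r]]), integer(1),
                       USE.NAMES = FALSE),
      pct_novel = 100 * vapply(threshold_ranks(),
                               function(r) mean(ids < thresholds[[r]]),
                               numeric(1), USE.NAMES = FALSE)
    )
  }
  out <- if (by_domain) {
    db |>
      group_by(.data$domain) |>
      dplyr::group_modify(~ tally(.x$best_hit_identity)) |>
      ungroup()
  } else {
    tally(db$best_hit_identity)
  }
  class(out) <- unique(c("eco_novelty", class(out)))
  out
}

#' Per-rank de novo taxonomy novelty of a completed database
#'
#' Counts, at each rank, distinct taxa (distinct lineages up to that rank)
#' whose name is a de novo placeholder, as a fraction of all distinct taxa
#' at the rank.
#'
#' @param db Completed database tibble.
#' @param prefix Placeholder prefix to recognise (NULL = any valid
#'   placeholder grammar).
#' @return Tibble of class `eco_novelty_taxa`: `rank`, `n_taxa`,
#'   `n_denovo`, `pct_denovo`.
#' @export
taxonomy_novelty <- function(db, prefix = NULL) {
  check_rank_cols(db)
  ranks <- tax_ranks()
  rows <- lapply(2:7, function(ri) {
    lineages <- distinct(db[ranks[seq_len(ri)]])
    denovo <- is_placeholder(lineages[[ranks[ri]]], prefix)
    tibble(rank = ranks[ri], n_taxa = nrow(lineages),
           n_denovo = sum(denovo),
           pct_denovo = 100 * mean(denovo))
  })
  out <- bind_rows(rows)
  class(out) <- unique(c("eco_novelty_taxa", class(out)))
  out
}

#' High-identity coverage of short-read ASV data by a database
#'
#' Per sample, ASVs at or above the relative-abundance floor are kept; the
#' reported fraction is the share of kept ASVs whose exhaustive top hit
#' against the database reaches the identity cut, and coverage is the summed
#' relative abundance the kept ASVs account for.
#'
#' @param asvs Tibble (`id`, `sequence`) of short-read ASVs.
#' @param counts Count tibble (`asv` + sample columns).
#' @param db Database tibble (`id`, `sequence`).
#' @param min_rel_abundance Per-sample relative-abundance floor (fraction).
#' @param id_cut High-identity threshold (percent).
#' @return Tibble of class `eco_coverage`: per sample `n_kept`,
#'   `frac_high_identity` (NA when no ASV is kept), `coverage`; summary
#'   mean/sd are stored in the `"summary"` attribute.
#' @export
coverage_eval <- function(asvs, counts, db, min_rel_abundance = 1e-4,
                          id_cut = 99.0) {
  hits <- map_queries(asvs, db)
  rel <- relative_abundances(counts) |>
    left_join(hits[c("query_id", "identity")], by = c(asv = "query_id"))
  per_sample <- rel |>
    filter(.data$count > 0, .data$rel_abundance >= min_rel_abundance) |>
    group_by(.data$sample) |>
    summarise(
      n_kept = n(),
      frac_high_identity = mean(.data$identity >= id_cut),
      coverage = sum(.data$rel_abundance)
    )
  # samples where nothing was kept are reported as missing, not dropped
  empty <- setdiff(setdiff(names(counts), "asv"), per_sample$sample)
  if (length(empty) > 0) {
    per_sample <- bind_rows(per_sample,
                            tibble(sample = empty, n_kept = 0L,
                                   frac_high_identity = NA_real_,
                                   coverage = NA_real_))
  }
  per_sample <- arrange(per_sample, .data$sample)
  attr(per_sample, "summary") <- tibble(
    mean_frac = mean(per_sample$frac_high_identity, na.rm = TRUE),
    sd_frac = sd(per_sample$frac_high_identity, na.rm = TRUE),
    mean_coverage = mean(per_sample$coverage, na.rm = TRUE),
    sd_coverage = sd(per_sample$coverage, na.rm = TRUE)
  )
  class(per_sample) <- unique(c("eco_coverage", class(per_sample)))
  per_sample
}

#' Genus- and species-level classification rates of ASV data
#'
#' Classifies ASVs with the bootstrap k-mer classifier and reports the
#' fraction reaching genus (resp. species) at the confidence cutoff. With a
#' count table, the abundance filter and the rates are applied per sample;
#' without one, the whole ASV set forms a single group.
#'
#' @param asvs Tibble (`id`, `sequence`).
#' @param db Completed database tibble, or a pre-built [train_index()].
#' @param params A [classifier_params()].
#' @param counts Optional count tibble for per-sample filtering.
#' @param min_rel_abundance Relative-abundance floor when `counts` given.
#' @return Tibble of class `eco_rates`: (`sample`,) `n_asvs`, `genus_rate`,
#'   `species_rate`.
#' @export
classification_rate <- function(asvs, db, params = classifier_params(),
                                counts = NULL, min_rel_abundance = 1e-4) {
  index <- if (inherits(db, "classifier_index")) db else train_index(db, params)
  cls <- classify(asvs, index, params)
  reached <- tibble(
    asv = cls$query_id,
    at_genus = !is.na(cls$genus),
    at_species = !is.na(cls$species)
  )
  if (is.null(counts)) {
    out <- tibble(n_asvs = nrow(reached),
                  genus_rate = mean(reached$at_genus),
                  species_rate = mean(reached$at_species))
  } else {
    out <- relative_abundances(counts) |>
      filter(.data$count > 0, .data$rel_abundance >= min_rel_abundance) |>
      left_join(reached, by = "asv") |>
      group_by(.data$sample) |>
      summarise(n_asvs = n(),
                genus_rate = mean(.data$at_genus),
                species_rate = mean(.data$at_species))
  }
  class(out) <- unique(c("eco_rates", class(out)))
  out
}

#' Extract the redundant in-silico amplicon ASV set from a database
#'
#' For every record, the amplicon primer pair is located (degenerate-exact,
#' outermost sites) and the inter-primer subsequence is emitted linked to its
#' parent record. Duplicated amplicon sequences are retained, one per parent
#' (a redundant set). Records lacking a site are flagged non-amplifiable.
#'
#' @param db Database tibble (`id`, `sequence`).
#' @param pair A [primer_pair()] (e.g. 799F/1192R).
#' @return Tibble: `parent_id`, `sequence` (NA when non-amplifiable),
#'   `amplifiable`.
#' @export
extract_insilico_asvs <- function(db, pair) {
  win <- trim_to_primer_window(db[c("id", "sequence")], pair)
  tibble(parent_id = win$id,
         sequence = ifelse(win$status == "ok", win$sequence, NA_character_),
         amplifiable = win$status == "ok")
}

#' Taxonomic resolution of in-silico amplicons
#'
#' Classifies each in-silico ASV against its source database and compares
#' the predicted genus and species names with the parent record's. A
#' prediction is correct when the rank name equals the parent's, wrong when
#' non-empty and different, and not classified when empty at that rank; the
#' three fractions partition unity.
#'
#' @param insilico Output of [extract_insilico_asvs()] (non-amplifiable rows
#'   are ignored).
#' @param db Completed database tibble.
#' @param params A [classifier_params()]. The study's in-silico evaluation
#'   classified on the plus strand; set `strand = "plus"` to mirror it.
#' @param by_family Also return a per-family breakdown (attribute
#'   `"by_family"`).
#' @return Tibble of class `eco_resolution`: `rank` (genus, species),
#'   `correct`, `wrong`, `not_classified` fractions and `n`.
#' @export
resolution_eval <- function(insilico, db, params = classifier_params(),
                            by_family = FALSE) {
  amp <- filter(insilico, .data$amplifiable)
  index <- train_index(db, params)
  queries <- tibble(id = amp$parent_id, sequence = amp$sequence)
  cls <- classify(queries, index, params)
  truth <- db[match(amp$parent_id, db$id), c("family", "genus", "species")]
  scored <- tibble(
    parent_id = amp$parent_id,
    family = truth$family,
    genus_true = truth$genus, species_true = truth$species,
    genus_pred = cls$genus, species_pred = cls$species
  )
  judge <- function(true, pred) {
    dplyr::case_when(
      is.na(pred) ~ "not_classified",
      pred == true ~ "correct",
      TRUE ~ "wrong"
    )
  }
  scored$genus_res <- judge(scored$genus_true, scored$genus_pred)
  scored$species_res <- judge(scored$species_true, scored$species_pred)
  frac_row <- function(res, rank) {
    tibble(rank = rank,
           correct = mean(res == "correct"),
           wrong = mean(res == "wrong"),
           not_classified = mean(res == "not_classified"),
           n = length(res))
  }
  out <- bind_rows(frac_row(scored$genus_res, "genus"),
                   frac_row(scored$species_res, "species"))
  if (by_family) {
    byfam <- scored |>
      group_by(.data$family) |>
      summarise(genus_correct = mean(.data$genus_res == "correct"),
                species_correct = mean(.data$species_res == "correct"),
                n = n())
    attr(out, "by_family") <- byfam
  }
  class(out) <- unique(c("eco_resolution", class(out)))
  out
}
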