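# Database construction: primer-window trimming, FL-ASV dereplication,
# threshold-based taxonomy inheritance, and de novo placeholder assignment.

#' Configuration for a database build
#'
#' @param thresholds A [threshold_table()].
#' @param prefix Placeholder-name prefix for de novo taxa.
#' @param trim_pair [primer_pair()] delimiting the retained gene window
#'   (default the near-full-length bacterial window, 27f/1391r).
#' @param min_length Minimum retained sequence length after trimming (bp).
#' @return A list of class `build_config`.
#' @export
build_config <- function(thresholds = threshold_table(),
                         prefix = "ECO",
                         trim_pair = primer_pair(standard_primers("27f"),
                                                 standard_primers("1391r")),
                         min_length = 0) {
  if (!nzchar(prefix)) abort("prefix must be non-empty")
  structure(list(thresholds = thresholds, prefix = prefix,
                 trim_pair = trim_pair, min_length = min_length),
            class = "build_config")
}

# locate a degenerate-exact primer site; returns IRanges-like tibble
find_primer_sites <- function(seq, primer) {
  hits <- Biostrings::matchPattern(primer, Biostrings::DNAString(seq),
                                   fixed = "subject")
  tibble(start = Biostrings::start(hits), end = Biostrings::end(hits))
}

#' Trim sequences to the window between two primer binding sites
#'
#' Locates the forward primer site (degenerate-exact match on the plus
#' strand) and the reverse-complemented reverse primer site, and returns the
#' subsequence strictly between them (both primer sequences excluded). With
#' multiple candidate sites the outermost pair is used (leftmost forward,
#' rightmost reverse). Sequences missing either site, with overlapping or
#' inverted sites, or with a window shorter than `min_length` are rejected
#' with a status flag rather than trimmed.
#'
#' @param seqs Tibble with columns `id`, `sequence` (plus-strand oriented).
#' @param pair A [primer_pair()].
#' @param min_length Minimum window length to keep.
#' @return Tibble: `id`, `sequence` (trimmed, NA when rejected), `status`
#'   (`"ok"`, `"missing_primer"`, `"inverted_sites"`, `"too_short"`).
#' @export
trim_to_primer_window <- function(seqs, pair, min_length = 0) {
  stopifnot(inherits(pair, "primer_pair"))
  rc_rev <- revcomp(pair$reverse)
  one <- function(id, s) {
    s <- clean_seq(s)
    f <- find_primer_sites(s, pair$forward)
    r <- find_primer_sites(s, rc_rev)
    if (nrow(f) == 0 || nrow(r) == 0) {
      return(tibble(id = id, sequence = NA_character_, status = "missing_primer"))
    }
    fs <- f[which.min(f$start), ]     # leftmost forward
    rs <- r[which.max(r$start), ]     # rightmost reverse
    from <- fs$end + 1L
    to <- rs$start - 1L
    if (from > to) {
      return(tibble(id = id, sequence = NA_character_, status = "inverted_sites"))
    }
    win <- substr(s, from, to)
    if (nchar(win) < min_length) {
      return(tibble(id = id, sequence = win, status = "too_short"))
    }
    tibble(id = id, sequence = win, status = "ok")
  }
  purrr::map2_dfr(seqs$id, seqs$sequence, one)
}

#' Dereplicate trimmed sequences into FL-ASV records
#'
#' Identical sequences collapse to one record whose abundance is the copy
#' count. Records are ordered by descending abundance (ties by first
#' occurrence) and assigned ids `FLASV1..FLASVn` in that order.
#'
#' @param seqs Character vector of trimmed sequences, or a tibble with a
#'   `sequence` column (one row per input copy).
#' @param id_prefix Record id prefix.
#' @return Database tibble: `id`, `sequence`, `abundance`.
#' @export
resolve_flasvs <- function(seqs, id_prefix = "FLASV") {
  if (is.data.frame(seqs)) seqs <- seqs$sequence
  if (length(seqs) == 0) abort("input must be non-empty")
  seqs <- clean_seq(seqs)
  first_seen <- match(unique(seqs), seqs)
  uniq <- seqs[sort(first_seen)]
  ab <- as.integer(table(factor(seqs, levels = uniq)))
  ord <- order(-ab, seq_along(uniq))
  tibble(
    id = paste0(id_prefix, seq_along(uniq)),
    sequence = uniq[ord],
    abundance = ab[ord]
  )
}

# empty provenance/rank scaffolding for a database tibble
add_empty_taxonomy <- function(db) {
  for (r in tax_ranks()) {
    db[[r]] <- NA_character_
    db[[paste0("prov_", r)]] <- "empty"
  }
  db
}

#' Inherit taxonomy from a universal reference database by identity thresholds
#'
#' Each record is mapped against the universal database with an exhaustive
#' [top_hit()] search; the hit's names are copied from the domain down to the
#' deepest rank whose identity threshold is met ([rank_for_identity()]). The
#' domain is always copied. Ranks that are empty in the hit itself stay empty
#' (to be filled de novo later).
#'
#' @param db Database tibble (`id`, `sequence`, ...).
#' @param universal Tibble: `id`, `sequence` + seven rank columns (NA = empty).
#' @param thresholds A [threshold_table()].
#' @return `db` with rank columns, `prov_*` flags (`"inherited"`/`"empty"`),
#'   `best_hit_identity` and `best_hit_ref`.
#' @export
inherit_taxonomy <- function(db, universal, thresholds = threshold_table()) {
  if (nrow(universal) == 0) abort("universal database must be non-empty")
  check_rank_cols(universal)
  db <- add_empty_taxonomy(db)
  hits <- map_queries(db, universal)
  ranks <- tax_ranks()
  for (i in seq_len(nrow(db))) {
    hit <- universal[match(hits$ref_id[i], universal$id), ]
    deep <- rank_for_identity(hits$identity[i], thresholds)
    n_copy <- if (deep == "none") 1L else match(deep, ranks)
    for (r in ranks[seq_len(n_copy)]) {
      nm <- hit[[r]]
      if (!is.na(nm) && nzchar(nm)) {
        db[[r]][i] <- nm
        db[[paste0("prov_", r)]][i] <- "inherited"
      }
    }
  }
  db$best_hit_identity <- hits$identity
  db$best_hit_ref <- hits$ref_id
  db
}

#' Complete a database with de novo placeholder taxa
#'
#' For each rank from phylum to species, records still lacking a name at that
#' rank are greedily clustered at the rank's identity threshold within groups
#' sharing identical taxonomy at all higher ranks. Processing in database
#' order, the first unassigned record seeds a cluster named
#' `<prefix>_<rank letter>_<seed ordinal>`; a later record joins the first
#' seed it matches at `global_identity >= threshold(rank)`, else seeds a new
#' cluster. Afterwards every record carries all seven ranks with provenance
#' flags.
#'
#' @param db Database tibble after [inherit_taxonomy()] (database order).
#' @param thresholds A [threshold_table()].
#' @param prefix Placeholder prefix.
#' @return Completed database tibble of class `taxdb`.
#' @export
assign_denovo_placeholders <- function(db, thresholds = threshold_table(),
                                       prefix = "ECO") {
  ranks <- tax_ranks()
  # domain fallback: records with no transferable hit at all still need a
  # domain; label them from the prefix (rare; only when hit domain was empty)
  no_dom <- is.na(db$domain)
  if (any(no_dom)) {
    db$domain[no_dom] <- paste0(prefix, "_domain")
    db$prov_domain[no_dom] <- "de_novo"
  }
  for (ri in 2:7) {
    r <- ranks[ri]
    above <- ranks[seq_len(ri - 1)]
    thr <- thresholds[[r]]
    parent_key <- do.call(paste, c(db[above], sep = "\r"))
    todo <- which(is.na(db[[r]]))
    for (key in unique(parent_key[todo])) {
      members <- todo[parent_key[todo] == key]
      seeds <- integer(0)    # row indices of cluster seeds, in creation order
      for (i in members) {
        joined <- FALSE
        for (s in seeds) {
          if (global_identity(db$sequence[i], db$sequence[s]) >= thr) {
            db[[r]][i] <- db[[r]][s]
            joined <- TRUE
            break
          }
        }
        if (!joined) {
          db[[r]][i] <- placeholder_name(prefix, r, i)
          seeds <- c(seeds, i)
        }
        db[[paste0("prov_", r)]][i] <- "de_novo"
      }
    }
  }
  new_taxdb(db)
}

# taxdb class: a tibble of reference records with completed taxonomy
new_taxdb <- function(db) {
  class(db) <- unique(c("taxdb", class(db)))
  db
}

#' Build a complete reference database from full-length 16S sequences
#'
#' Runs the full pipeline: primer-window trimming, FL-ASV dereplication,
#' identity-threshold taxonomy inheritance from a universal database, and de
#' novo placeholder completion. Deterministic for fixed inputs.
#'
#' @param seqs Tibble (`id`, `sequence`): oriented near-full-length 16S genes.
#' @param universal Tibble: `id`, `sequence` + seven rank columns.
#' @param config A [build_config()].
#' @return List of class `taxdb_build`: `db` (completed `taxdb` tibble) and
#'   `report` (per-stage counts tibble).
#' @export
build_database <- function(seqs, universal, config = build_config()) {
  trimmed <- trim_to_primer_window(seqs, config$trim_pair, config$min_length)
  kept <- filter(trimmed, .data$status == "ok")
  if (nrow(kept) == 0) abort("no sequences retained after primer trimming")
  db <- resolve_flasvs(kept$sequence)
  db <- inherit_taxonomy(db, universal, config$thresholds)
  db <- assign_denovo_placeholders(db, config$thresholds, config$prefix)
  denovo <- vapply(threshold_ranks(), function(r) {
    length(unique(db[[r]][db[[paste0("prov_", r)]] == "de_novo"]))
  }, integer(1))
  report <- bind_rows(
    tibble(stage = "input", metric = "sequences", value = nrow(seqs)),
    tibble(stage = "trim",
           metric = paste0("discarded_", unique(trimmed$status[trimmed$status != "ok"])),
           value = vapply(unique(trimmed$status[trimmed$status != "ok"]),
                          function(s) sum(trimmed$status == s), integer(1))),
    tibble(stage = "dereplicate", metric = "flasvs", value = nrow(db)),
    tibble(stage = "denovo", metric = paste0("denovo_", names(denovo)),
           value = unname(denovo))
  )
  structure(list(db = db, report = report), class = "taxdb_build")
}

#' @export
print.taxdb_build <- function(x, ...) {
  cat("<taxdb_build>", nrow(x$db), "reference records\n")
  print(x$report, n = Inf)
  invisible(x)
}

#' Tidy and summarise database build results
#'
#' `tidy()` returns the per-record database tibble; `glance()` a one-row
#' summary (record count, completeness, per-rank de novo taxa).
#'
#' @param x A `taxdb_build` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.taxdb_build <- function(x, ...) as_tibble(x$db)

#' @rdname tidy.taxdb_build
#' @export
glance.taxdb_build <- function(x, ...) {
  db <- x$db
  complete <- all(!is.na(as.matrix(db[tax_ranks()])))
  out <- tibble(n_records = nrow(db), complete = complete,
                mean_best_hit_identity = mean(db$best_hit_identity))
  for (r in threshold_ranks()) {
    out[[paste0("n_denovo_", r)]] <-
      length(unique(db[[r]][db[[paste0("prov_", r)]] == "de_novo"]))
  }
  out
}
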