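# Ecosystem-specific primer bias: overall weighted score (OWS) of a primer
# against a template, perfect/partial/poor categories, and whole-database
# surveys. The last five primer bases form the 3' region; penalties are
# 0.40 per non-3' mismatch, 1.00 per 3' mismatch, 3.00 for a terminal-base
# mismatch (replacing the generic 3' penalty), 1.00 per non-3' gap and 3.00
# per 3' gap.

#' Score a primer against a template sequence
#'
#' Finds the placement of the (IUPAC-degenerate) primer on the template —
#' primer fully aligned, template local, gaps allowed — that minimises the
#' overall weighted score, and returns the minimal score with its event
#' breakdown. A degenerate primer base matches any template base whose IUPAC
#' set intersects its own. When no placement scores at or below `ceiling`
#' the site is reported as absent (`no_site`).
#'
#' @param primer IUPAC DNA string, length >= 6, written 5' to 3'.
#' @param template ACGT (or IUPAC) DNA string longer than the primer.
#' @param ceiling Maximum OWS for a placement to count as a site.
#' @return One-row tibble: mismatch/gap counts by region, `ows`, `category`
#'   (`perfect`, `partial`, `poor`, or `no_site` with `ows = NA`), and the
#'   1-based template span of the placement.
#' @examples
#' score_primer("AACMGGATTAGATACCCKG",
#'               paste0("TTGA", "AACAGGATTAGATACCCGG", "CCTA"))
#' @export
score_primer <- function(primer, template, ceiling = 10) {
  primer <- clean_seq(primer)
  template <- clean_seq(template)
  if (nchar(primer) < 6) abort("primer must be at least 6 nt")
  if (nchar(template) <= nchar(primer)) {
    abort("template must be longer than the primer")
  }
  res <- .cpp_score_primer(primer, template)
  if (res$ows > ceiling) {
    return(tibble(non3_mismatches = NA_integer_,
                  three_prime_mismatches = NA_integer_,
                  last_base_mismatch = NA,
                  non3_gaps = NA_integer_, three_prime_gaps = NA_integer_,
                  ows = NA_real_, category = "no_site",
                  start = NA_integer_, end = NA_integer_))
  }
  tibble(non3_mismatches = res$non3_mismatches,
         three_prime_mismatches = res$three_prime_mismatches,
         last_base_mismatch = res$last_base_mismatch,
         non3_gaps = res$non3_gaps, three_prime_gaps = res$three_prime_gaps,
         ows = res$ows, category = categorize_ows(res$ows),
         start = res$start, end = res$end)
}

#' Categorise an overall weighted score
#'
#' Perfect hit: OWS of 0; partial hit: OWS in (0, 1\]; poor hit: OWS > 1.
#'
#' @param ows Numeric vector of scores (>= 0).
#' @return Character vector: `"perfect"`, `"partial"`, `"poor"`.
#' @examples
#' categorize_ows(c(0, 1, 1.4))
#' @export
categorize_ows <- function(ows) {
  if (any(ows < 0, na.rm = TRUE)) abort("ows must be >= 0")
  dplyr::case_when(
    is.na(ows) ~ NA_character_,
    ows == 0 ~ "perfect",
    ows <= 1 ~ "partial",
    TRUE ~ "poor"
  )
}

#' Survey primer-pair bias across a reference database
#'
#' Scores the forward primer against each record's plus strand and the
#' reverse primer against its reverse complement; the record's OWS is the
#' worse (maximum) of the two, so the primer with the highest score governs
#' the category. Records where either primer finds no site are tallied
#' separately as `no_site`.
#'
#' @param db Database tibble (`id`, `sequence`, optionally rank columns).
#' @param pair A [primer_pair()].
#' @param ceiling Per-primer OWS ceiling for site detection.
#' @param summary_rank Rank column for the per-taxon summary (NULL = none).
#' @return Tibble of class `eco_survey`: per record `fwd_ows`, `rev_ows`,
#'   `ows`, `category`; per-taxon category fractions in the `"summary"`
#'   attribute when `summary_rank` is available.
#' @export
survey_database <- function(db, pair, ceiling = 10, summary_rank = "phylum") {
  stopifnot(inherits(pair, "primer_pair"))
  score_one <- function(s) {
    fwd <- score_primer(pair$forward, s, ceiling)
    rev <- score_primer(pair$reverse, revcomp(s), ceiling)
    tibble(fwd_ows = fwd$ows, rev_ows = rev$ows)
  }
  per <- purrr::map_dfr(db$sequence, score_one)
  out <- tibble(id = db$id, fwd_ows = per$fwd_ows, rev_ows = per$rev_ows)
  out$ows <- pmax(out$fwd_ows, out$rev_ows)
  out$category <- ifelse(is.na(out$ows), "no_site", categorize_ows(out$ows))
  if (!is.null(summary_rank) && summary_rank %in% names(db)) {
    out[[summary_rank]] <- db[[summary_rank]]
    summ <- out |>
      group_by(.data[[summary_rank]]) |>
      summarise(n = n(),
                perfect = mean(.data$category == "perfect"),
                partial = mean(.data$category == "partial"),
                poor = mean(.data$category == "poor"),
                no_site = mean(.data$category == "no_site"))
    attr(out, "summary") <- summ
  }
  class(out) <- unique(c("eco_survey", class(out)))
  out
}
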