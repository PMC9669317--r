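# Pairwise global-alignment identity and exhaustive top-hit search.
#
# The identity definition is fixed: an optimal global alignment is computed
# under match +1, mismatch -1, gap open -2 (first gapped column), gap extend
# -1, and identity = 100 * matches / alignment columns with terminal-gap
# columns excluded from the denominator. Ties between equal-scoring
# alignments are resolved by a fixed traceback priority so results are
# deterministic.

check_dna <- function(x, what = "sequence") {
  if (length(x) == 0 || any(!nzchar(x))) {
    abort(paste0(what, " must be non-empty"))
  }
  if (any(grepl("[^ACGT]", x))) {
    abort(paste0(what, " must contain only A, C, G, T"))
  }
  invisible(x)
}

#' Percent identity under optimal global alignment
#'
#' @param a,b Non-empty ACGT strings.
#' @param details If `TRUE`, return a one-row tibble with the match and
#'   column counts alongside the identity.
#' @return Percent identity in \[0, 100\] (or a tibble when `details`).
#' @examples
#' global_identity("ACGTACGT", "ACGTACGT") # 100
#' @export
global_identity <- function(a, b, details = FALSE) {
  a <- clean_seq(a); b <- clean_seq(b)
  check_dna(a); check_dna(b)
  res <- .cpp_global_identity(a, b)
  if (!details) return(res$identity)
  tibble(identity = res$identity, matches = res$matches,
         columns = res$columns,
         terminal_gap_columns = res$terminal_gap_columns)
}

#' Exhaustive top-hit search against a reference set
#'
#' Every reference is aligned (no candidate rejection, emulating an
#' exhaustive `-maxaccepts 0 -maxrejects 0 -top_hit_only` search on the plus
#' strand); the reference with maximal identity wins, ties going to the
#' lowest reference index in database order.
#'
#' @param query Non-empty ACGT string (plus strand, co-oriented with refs).
#' @param refs Tibble with columns `id`, `sequence` (database order).
#' @param query_id Optional query identifier carried into the result.
#' @return One-row tibble: `query_id` (NA unless supplied), `ref_id`,
#'   `identity`, `tie_count`.
#' @export
top_hit <- function(query, refs, query_id = NA_character_) {
  if (nrow(refs) == 0) abort("refs must be non-empty")
  query <- clean_seq(query)
  check_dna(query, "query")
  ids <- .cpp_identity_many(query, refs$sequence)
  best <- max(ids)
  w <- which(ids == best)
  tibble(query_id = query_id, ref_id = refs$id[w[1]],
         identity = best, tie_count = length(w))
}

#' Map a set of queries to a reference database
#'
#' Vectorised [top_hit()]: one row per query, in query order.
#'
#' @param queries Tibble with columns `id`, `sequence`.
#' @param refs Tibble with columns `id`, `sequence`.
#' @return Tibble: `query_id`, `ref_id`, `identity`, `tie_count`.
#' @export
map_queries <- function(queries, refs) {
  purrr::map2_dfr(queries$sequence, queries$id,
                  function(s, i) top_hit(s, refs, query_id = i))
}
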