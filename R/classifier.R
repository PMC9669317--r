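# SINTAX-style bootstrap k-mer classifier. Each bootstrap iteration samples
# k-mers from the query with replacement; the reference sharing most sampled
# k-mers wins the iteration. Per-rank confidence is the fraction of
# iterations whose winner carries the candidate name at that rank.

#' Classifier parameters
#'
#' @param k K-mer size (>= 4).
#' @param iterations Bootstrap iterations.
#' @param draws K-mers sampled (with replacement) per iteration.
#' @param cutoff Confidence cutoff in \[0, 1\]; taxonomy is reported down to
#'   the deepest contiguous rank meeting the cutoff.
#' @param strand `"both"` classifies the query and its reverse complement
#'   and keeps the stronger result; `"plus"` uses the query as given.
#' @param seed Integer seed for the bootstrap sampler.
#' @return A list of class `classifier_params`.
#' @export
classifier_params <- function(k = 8, iterations = 100, draws = 32,
                              cutoff = 0.8, strand = c("both", "plus"),
                              seed = 1L) {
  strand <- match.arg(strand)
  if (k < 4) abort("k must be >= 4")
  if (cutoff < 0 || cutoff > 1) abort("cutoff must be in [0, 1]")
  structure(list(k = k, iterations = iterations, draws = draws,
                 cutoff = cutoff, strand = strand, seed = as.integer(seed)),
            class = "classifier_params")
}

# integer codes of all k-mers in a sequence (k-mers with non-ACGT dropped)
kmer_codes <- function(seq, k) {
  x <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T")) - 1L
  n <- length(x)
  if (n < k) return(integer(0))
  em <- sapply(seq_len(k), function(i) x[i:(n - k + i)])
  if (is.null(dim(em))) em <- matrix(em, nrow = 1)
  code <- as.vector(em %*% 4^((k - 1):0))
  code[!is.na(code)]
}

#' Train a k-mer classifier index on a completed database
#'
#' Stores the unique k-mer set of every record. Records shorter than `k`
#' are excluded with a warning.
#'
#' @param db Completed database tibble (`id`, `sequence`, seven ranks).
#' @param params A [classifier_params()].
#' @return A list of class `classifier_index`.
#' @export
train_index <- function(db, params = classifier_params()) {
  check_rank_cols(db)
  sets <- lapply(db$sequence, function(s) unique(kmer_codes(s, params$k)))
  short <- lengths(sets) == 0
  if (any(short)) {
    warn(paste0(sum(short), " record(s) shorter than k excluded from index"))
  }
  keep <- which(!short)
  sets <- sets[keep]
  # inverted index: k-mer code (as character key) -> record ordinals
  inv <- split(rep(seq_along(keep), lengths(sets)),
               as.character(unlist(sets)))
  structure(list(
    records = db[keep, c("id", tax_ranks())],
    kmer_sets = sets,
    inverted = inv,
    params = params
  ), class = "classifier_index")
}

# classify one strand of one query; returns list(candidate row, conf vector,
# n_winner_iters)
classify_strand <- function(qcodes, index, params) {
  n_rec <- nrow(index$records)
  B <- params$iterations
  if (length(qcodes) == 0) {
    return(list(conf = setNames(numeric(7), tax_ranks()), candidate = NA_integer_))
  }
  hit_lists <- index$inverted[as.character(qcodes)]
  wins <- integer(0)
  for (b in seq_len(B)) {
    sampled <- sample.int(length(qcodes), params$draws, replace = TRUE)
    recs <- unlist(hit_lists[sampled], use.names = FALSE)
    if (length(recs) == 0) next
    counts <- tabulate(recs, nbins = n_rec)
    wins <- c(wins, which.max(counts))   # ties -> lowest ordinal
  }
  if (length(wins) == 0) {
    return(list(conf = setNames(numeric(7), tax_ranks()), candidate = NA_integer_))
  }
  tab <- tabulate(wins, nbins = n_rec)
  cand <- which.max(tab)                 # modal winner, ties -> lowest ordinal
  conf <- vapply(tax_ranks(), function(r) {
    nm <- index$records[[r]][cand]
    sum(index$records[[r]][wins] == nm) / B
  }, numeric(1))
  list(conf = conf, candidate = cand)
}

#' Classify a query sequence
#'
#' Bootstrap k-mer classification against a trained index. The reported
#' taxonomy is the lineage of the modal winning reference, truncated at the
#' deepest contiguous rank whose confidence meets the cutoff. With
#' `strand = "both"` the query and its reverse complement are both
#' classified and the orientation with the larger summed rank confidence is
#' kept (ties favour the plus strand). Fully deterministic for a fixed
#' (query, index, params) triple.
#'
#' @param query ACGT string (length >= k) or tibble (`id`, `sequence`).
#' @param index A [train_index()] result.
#' @param params A [classifier_params()]; defaults to the index's own.
#' @param query_id Identifier carried into the result.
#' @return One-row tibble: `query_id`, `strand`, the seven reported rank
#'   names (NA beyond the truncation depth), `conf_*` per rank, and `depth`
#'   (number of reported ranks).
#' @export
classify <- function(query, index, params = index$params,
                     query_id = NA_character_) {
  if (is.data.frame(query)) {
    return(purrr::map2_dfr(query$sequence, query$id,
                           function(s, i) classify(s, index, params, i)))
  }
  query <- clean_seq(query)
  ranks <- tax_ranks()
  empty <- function(flag) {
    out <- tibble(query_id = query_id, strand = NA_character_)
    for (r in ranks) out[[r]] <- NA_character_
    for (r in ranks) out[[paste0("conf_", r)]] <- 0
    out$depth <- 0L
    out$flag <- flag
    out
  }
  if (nchar(query) < params$k) return(empty("query_shorter_than_k"))

  res <- withr::with_seed(params$seed, {
    qf <- unique(kmer_codes(query, params$k))
    plus <- classify_strand(qf, index, params)
    if (params$strand == "both") {
      qr <- unique(kmer_codes(revcomp(query), params$k))
      minus <- classify_strand(qr, index, params)
      if (sum(minus$conf) > sum(plus$conf)) {
        list(r = minus, strand = "minus")
      } else {
        list(r = plus, strand = "plus")
      }
    } else {
      list(r = plus, strand = "plus")
    }
  })
  if (is.na(res$r$candidate)) return(empty("no_shared_kmers"))

  conf <- res$r$conf
  names_full <- vapply(ranks, function(r) index$records[[r]][res$r$candidate],
                       character(1))
  meets <- conf >= params$cutoff
  depth <- if (all(meets)) 7L else (which(!meets)[1] - 1L)
  out <- tibble(query_id = query_id, strand = res$strand)
  for (i in seq_along(ranks)) {
    out[[ranks[i]]] <- if (i <= depth) unname(names_full[i]) else NA_character_
  }
  for (i in seq_along(ranks)) out[[paste0("conf_", ranks[i])]] <- unname(conf[i])
  out$depth <- depth
  out$flag <- "ok"
  out
}
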