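# Seeded simulators with planted ground truth: a universal reference set
# plus query sequences on a controlled divergence ladder, amplicon count
# tables, and primer-site perturbations with known expected OWS. All
# generators are deterministic under a fixed seed.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# one concrete realisation of a degenerate primer
realize_primer <- function(primer) {
  sets <- Biostrings::IUPAC_CODE_MAP[strsplit(primer, "")[[1]]]
  paste(vapply(strsplit(sets, ""), function(s) sample(s, 1), character(1)),
        collapse = "")
}

mutate_positions <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  }
  paste(ch, collapse = "")
}

#' Specification for the reference-set simulator
#'
#' Defines the study conditions the simulator emulates: a small universal
#' reference set organised into phyla/lineages, and ~200 query sequences
#' whose nearest-reference identity is planted between consecutive rank
#' thresholds so the deepest inheritable rank of every query is known.
#'
#' @param n_phyla Phyla in the universal set.
#' @param lineages_per_phylum Universal records (lineages) per phylum; each
#'   lineage carries unique names at every rank below phylum.
#' @param seq_len Length of the trimmed gene region (bp).
#' @param deepest_rank_counts Named integer vector: number of queries whose
#'   planted deepest inheritable rank is `species`, `genus`, ...,
#'   `phylum` or `none`.
#' @param thresholds A [threshold_table()].
#' @param band_margin Identities are planted at least this many percentage
#'   points inside the rank band, keeping alignment noise away from the
#'   threshold boundaries.
#' @param trim_pair Primer pair flanking the gene window in the emitted
#'   full-length queries.
#' @param amplicon_pair Amplicon primer pair planted inside the gene region.
#' @param copies_lambda Poisson rate for extra per-query copies (dereplication
#'   ground truth; 0 = all singletons).
#' @param n_samples,depth Samples and reads per sample for count simulation.
#' @param lognormal_meanlog,lognormal_sdlog Log-normal abundance parameters.
#' @param seed Integer seed.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(n_phyla = 4,
                     lineages_per_phylum = 2,
                     seq_len = 1300,
                     deepest_rank_counts = c(species = 120, genus = 40,
                                             family = 20, order = 10,
                                             class = 6, phylum = 4, none = 0),
                     thresholds = threshold_table(),
                     band_margin = 0.15,
                     trim_pair = primer_pair(standard_primers("27f"),
                                             standard_primers("1391r")),
                     amplicon_pair = primer_pair(standard_primers("799F"),
                                                 standard_primers("1192R")),
                     copies_lambda = 0.5,
                     n_samples = 6,
                     depth = 50000,
                     lognormal_meanlog = 0,
                     lognormal_sdlog = 1.5,
                     seed = 1L) {
  allowed <- c(rev(threshold_ranks()), "none")
  if (!all(names(deepest_rank_counts) %in% allowed)) {
    abort("deepest_rank_counts names must be species..phylum or none")
  }
  structure(list(
    n_phyla = n_phyla, lineages_per_phylum = lineages_per_phylum,
    seq_len = seq_len, deepest_rank_counts = deepest_rank_counts,
    thresholds = thresholds, band_margin = band_margin,
    trim_pair = trim_pair, amplicon_pair = amplicon_pair,
    copies_lambda = copies_lambda, n_samples = n_samples, depth = depth,
    lognormal_meanlog = lognormal_meanlog, lognormal_sdlog = lognormal_sdlog,
    seed = as.integer(seed)
  ), class = "sim_spec")
}

# identity band (lo, hi) targeted for a planted deepest rank
rank_band <- function(rank, thresholds) {
  thr <- c(none = 0, thresholds, top = 100)
  ranks <- c("none", names(thresholds))
  i <- match(rank, ranks)
  if (rank == "none") c(65, unname(thr["phylum"])) else
    c(unname(thr[ranks[i]]), unname(thr[c(ranks, "top")][i + 1]))
}

# layout of planted features inside the gene region
region_layout <- function(spec) {
  f_len <- nchar(spec$amplicon_pair$forward)
  r_len <- nchar(spec$amplicon_pair$reverse)
  f_start <- 151
  asv_len <- 390
  list(
    f = c(f_start, f_start + f_len - 1),
    asv = c(f_start + f_len, f_start + f_len + asv_len - 1),
    r = c(f_start + f_len + asv_len, f_start + f_len + asv_len + r_len - 1)
  )
}

#' Simulate a universal reference set and queries with planted novelty
#'
#' Generates one random ancestor per phylum (with concrete amplicon primer
#' sites implanted), derives universal lineages by substitution, and then
#' derives query sequences from random lineages with substitution counts
#' calibrated so each query's nearest-universal identity (verified with
#' [global_identity()]) falls inside its planted rank band; queries failing
#' verification are redrawn. Emitted queries are full-length (trim-primer
#' sites flanking the gene region) and optionally duplicated to plant
#' dereplication abundances.
#'
#' @param spec A [sim_spec()].
#' @return List of class `eco_sim`: `universal` (id, sequence, seven ranks),
#'   `queries` (id, sequence; full-length, one row per copy), `truth`
#'   (per unique query: parent, planted deepest rank, substitutions,
#'   verified identity, copies).
#' @export
simulate_reference <- function(spec = sim_spec()) {
  withr::with_seed(spec$seed, simulate_reference_impl(spec))
}

simulate_reference_impl <- function(spec) {
  L <- spec$seq_len
  lay <- region_layout(spec)
  if (lay$r[2] + 100 > L) abort("seq_len too short for the planted layout")
  protected <- c(seq(lay$f[1], lay$f[2]), seq(lay$r[1], lay$r[2]))
  free_pos <- setdiff(seq_len(L), protected)

  # universal lineages: per phylum one ancestor, lineages at ~12% divergence
  n_uni <- spec$n_phyla * spec$lineages_per_phylum
  uni <- vector("list", n_uni)
  tax <- vector("list", n_uni)
  k <- 0
  for (p in seq_len(spec$n_phyla)) {
    anc <- random_dna(L)
    anc <- paste0(
      substr(anc, 1, lay$f[1] - 1),
      realize_primer(spec$amplicon_pair$forward),
      substr(anc, lay$asv[1], lay$asv[2]),
      revcomp(realize_primer(spec$amplicon_pair$reverse)),
      substr(anc, lay$r[2] + 1, L)
    )
    for (l in seq_len(spec$lineages_per_phylum)) {
      k <- k + 1
      s <- if (l == 1) 0L else round(0.12 * L)
      uni[[k]] <- if (s == 0) anc else
        mutate_positions(anc, sample(free_pos, s))
      tax[[k]] <- tibble(
        domain = "Bacteria",
        phylum = paste0("Simphylum_", p),
        class = paste0("Simclass_", p, "_", l),
        order = paste0("Simorder_", p, "_", l),
        family = paste0("Simfamily_", p, "_", l),
        genus = paste0("Simgenus_", p, "_", l),
        species = paste0("Simspecies_", p, "_", l)
      )
    }
  }
  universal <- dplyr::bind_cols(
    tibble(id = paste0("UNI", seq_len(n_uni)),
           sequence = unlist(uni)),
    bind_rows(tax)
  )

  # queries on the divergence ladder
  counts <- spec$deepest_rank_counts[spec$deepest_rank_counts > 0]
  n_q <- sum(counts)
  truth <- vector("list", n_q)
  qseq <- character(n_q)
  qi <- 0
  seen <- new.env(hash = TRUE)
  for (rank in names(counts)) {
    band <- rank_band(rank, spec$thresholds)
    lo <- band[1] + spec$band_margin
    hi <- band[2] - spec$band_margin
    if (rank == "species") lo <- band[1] + spec$band_margin  # hi stays 100
    if (rank == "species") hi <- 100
    s_max <- floor(L * (1 - lo / 100))
    s_min <- ceiling(L * (1 - hi / 100))
    if (s_min > s_max) abort("identity band infeasible at this sequence length")
    for (q in seq_len(counts[[rank]])) {
      qi <- qi + 1
      ok <- FALSE
      for (try in 1:25) {
        parent <- sample.int(n_uni, 1)
        s <- if (s_min == s_max) s_min else sample(seq(s_min, s_max), 1)
        cand <- if (s == 0) universal$sequence[parent] else
          mutate_positions(universal$sequence[parent],
                           sample(free_pos, s))
        if (!is.null(seen[[cand]])) next
        ids <- .cpp_identity_many(cand, universal$sequence)
        best <- max(ids)
        verified <- rank_for_identity(best, spec$thresholds)
        if (verified == rank) {
          seen[[cand]] <- TRUE
          qseq[qi] <- cand
          truth[[qi]] <- tibble(
            query = paste0("Q", qi), parent = universal$id[which.max(ids)],
            deepest_rank = rank, n_subs = s, verified_identity = best
          )
          ok <- TRUE
          break
        }
      }
      if (!ok) abort("could not place a query inside its identity band")
    }
  }
  truth <- bind_rows(truth)

  # full-length queries: flank with trim-primer realisations; plant copies
  fwd_full <- realize_primer(spec$trim_pair$forward)
  rev_full <- revcomp(realize_primer(spec$trim_pair$reverse))
  lead <- random_dna(25)
  trail <- random_dna(25)
  copies <- 1L + stats::rpois(n_q, spec$copies_lambda)
  truth$copies <- copies
  full <- paste0(lead, fwd_full, qseq, rev_full, trail)
  queries <- tibble(
    id = paste0(rep(truth$query, copies), "_c",
                unlist(lapply(copies, seq_len))),
    sequence = rep(full, copies)
  )
  structure(list(universal = universal, queries = queries, truth = truth,
                 spec = spec),
            class = "eco_sim")
}

#' Simulate an amplicon dataset from a reference database
#'
#' Extracts the in-silico amplicon of every amplifiable record, dereplicates
#' them into ASVs, assigns each ASV a log-normal community abundance and
#' draws per-sample counts multinomially at the configured depth. Optionally
#' pins some ASVs to a planted (sub-filter) relative abundance.
#'
#' @param db Database tibble (`id`, `sequence`, rank columns optional).
#' @param pair Amplicon [primer_pair()].
#' @param spec A [sim_spec()] (samples, depth, log-normal parameters, seed).
#' @param noise_subs Substitutions added to each ASV copy (0 = error-free).
#' @param n_rare Number of ASVs pinned at `rare_rel_abundance`.
#' @param rare_rel_abundance Planted relative abundance for pinned ASVs.
#' @return List of class `eco_sim_amplicon`: `asvs` (id, sequence),
#'   `counts` (asv x samples), `truth` (asv, parents, planted abundance,
#'   flag for sub-filter planting).
#' @export
simulate_amplicon_dataset <- function(db, pair, spec = sim_spec(),
                                      noise_subs = 0, n_rare = 0,
                                      rare_rel_abundance = 5e-5) {
  withr::with_seed(spec$seed + 1L, {
    ins <- extract_insilico_asvs(db, pair)
    amp <- filter(ins, .data$amplifiable)
    if (nrow(amp) == 0) abort("no amplifiable records in db")
    seqs <- amp$sequence
    if (noise_subs > 0) {
      seqs <- vapply(seqs, function(s) {
        mutate_positions(s, sample.int(nchar(s), noise_subs))
      }, character(1), USE.NAMES = FALSE)
    }
    uniq <- unique(seqs)
    asvs <- tibble(id = paste0("ASV", seq_along(uniq)), sequence = uniq)
    parents <- vapply(uniq, function(u) {
      paste(amp$parent_id[seqs == u], collapse = ",")
    }, character(1), USE.NAMES = FALSE)
    p <- rlnorm(nrow(asvs), spec$lognormal_meanlog, spec$lognormal_sdlog)
    rare <- rep(FALSE, nrow(asvs))
    if (n_rare > 0) {
      rare_idx <- sample.int(nrow(asvs), min(n_rare, nrow(asvs)))
      rare[rare_idx] <- TRUE
      # pin after normalisation of the abundant part
      p[rare_idx] <- 0
    }
    p <- p / sum(p)
    if (any(rare)) {
      p[rare] <- rare_rel_abundance
      p[!rare] <- p[!rare] * (1 - sum(p[rare]))
    }
    counts <- tibble(asv = asvs$id)
    for (s in seq_len(spec$n_samples)) {
      counts[[paste0("S", s)]] <-
        as.integer(rmultinom(1, spec$depth, p))
    }
    truth <- tibble(asv = asvs$id, parents = parents,
                    planted_rel_abundance = p, planted_rare = rare)
    structure(list(asvs = asvs, counts = counts, truth = truth),
              class = "eco_sim_amplicon")
  })
}

# weighted mismatch cost of a primer over every placement with at most one
# gap; deliberately simple enumeration arithmetic, independent of the DP
# scorer, used to certify planted mutations
gapless_min_cost <- function(primer, template, max_gaps = 1) {
  m <- nchar(primer); n <- nchar(template)
  pmask <- Biostrings::IUPAC_CODE_MAP[strsplit(primer, "")[[1]]]
  pen <- c(rep(0.4, m - 5), rep(1, 4), 3)
  gap_pen <- c(rep(1, m - 5), rep(3, 5))
  tch <- strsplit(template, "")[[1]]
  mm_cost <- function(pidx, tidx) {
    keep <- tidx >= 1 & tidx <= n
    mism <- !stringr::str_detect(pmask[pidx[keep]],
                                 stringr::fixed(tch[tidx[keep]]))
    sum(pen[pidx[keep]][mism]) + sum(pen[pidx[!keep]])
  }
  best <- Inf
  if (n >= m) {
    for (off in 0:(n - m)) {
      best <- min(best, mm_cost(1:m, off + 1:m))
    }
  }
  if (max_gaps >= 1) {
    # one primer base gapped (deletion of a template base)
    for (off in 0:max(0, n - (m - 1))) {
      for (g in 1:m) {
        pidx <- setdiff(1:m, g)
        best <- min(best, gap_pen[g] + mm_cost(pidx, off + seq_len(m - 1)))
      }
    }
    # one extra template base between primer g and g+1
    if (n >= m + 1) {
      for (off in 0:(n - (m + 1))) {
        for (g in 1:(m - 1)) {
          ins <- if (g >= m - 4) 3 else 1
          tidx <- off + c(seq_len(g), g + 2:(m - g + 1))
          best <- min(best, ins + mm_cost(1:m, tidx))
        }
      }
    }
  }
  best
}

#' Plant primer-site mutations with known expected scores
#'
#' Injects a specified number of mismatches or gaps of a given positional
#' class into the forward-primer site of selected records, and records the
#' expected OWS from the penalty table. Mutated sites are guarded against
#' accidental cheaper placements (the surrounding sequence is rescanned with
#' an independent gapless cost check and the mutation redrawn when an
#' alternative placement would undercut the planted score).
#'
#' @param db Database tibble (`id`, `sequence`).
#' @param pair Amplicon [primer_pair()]; the forward primer site is mutated.
#' @param type One of `"non3_mismatch"`, `"three_prime_mismatch"`,
#'   `"last_base_mismatch"`, `"non3_gap"`, `"three_prime_gap"`.
#' @param n_records How many records to perturb (from the top).
#' @param count Mutations per perturbed record (1 for gap types).
#' @param seed Integer seed.
#' @return List of class `eco_sim_primer`: `db` (perturbed tibble), `truth`
#'   (id, type, count, expected forward-primer OWS).
#' @export
plant_primer_mutations <- function(db, pair,
                                   type = c("non3_mismatch",
                                            "three_prime_mismatch",
                                            "last_base_mismatch",
                                            "non3_gap", "three_prime_gap"),
                                   n_records = nrow(db), count = 1,
                                   seed = 1L) {
  type <- match.arg(type)
  if (grepl("gap", type) && count != 1) {
    abort("gap planting supports count = 1")
  }
  primer <- pair$forward
  m <- nchar(primer)
  pos_pool <- switch(type,
    non3_mismatch = seq_len(m - 5),
    three_prime_mismatch = seq(m - 4, m - 1),
    last_base_mismatch = m,
    non3_gap = seq_len(m - 5),
    three_prime_gap = seq(m - 4, m - 1)
  )
  if (count > length(pos_pool)) abort("count exceeds available positions")
  expected <- switch(type,
    non3_mismatch = 0.4 * count,
    three_prime_mismatch = 1.0 * count,
    last_base_mismatch = 3.0,
    non3_gap = 1.0,
    three_prime_gap = 3.0
  )
  pmask <- Biostrings::IUPAC_CODE_MAP[strsplit(primer, "")[[1]]]

  withr::with_seed(seed, {
    out <- db
    planted <- character(0)
    want <- min(n_records, nrow(db))
    for (i in seq_len(nrow(db))) {
      if (length(planted) >= want) break
      s <- out$sequence[i]
      site <- find_primer_sites(s, primer)
      if (nrow(site) == 0) abort("record lacks the forward primer site")
      st <- site$start[1]
      done <- FALSE
      for (try in 1:50) {
        pos <- if (length(pos_pool) == 1) pos_pool else
          sort(sample(pos_pool, count))
        ch <- strsplit(s, "")[[1]]
        if (grepl("mismatch", type)) {
          for (p in pos) {
            bad <- setdiff(c("A", "C", "G", "T"),
                           strsplit(pmask[[p]], "")[[1]])
            ch[st + p - 1] <- sample(bad, 1)
          }
          cand <- paste(ch, collapse = "")
        } else {
          cand <- paste(ch[-(st + pos - 1)], collapse = "")
        }
        # no placement with at most one gap may undercut the planted score
        guard <- gapless_min_cost(primer, cand)
        if (isTRUE(all.equal(guard, expected))) { done <- TRUE; break }
      }
      # a record whose flanking context always admits a cheaper placement is
      # skipped (rejection sampling); the next record is tried instead
      if (!done) next
      out$sequence[i] <- cand
      planted <- c(planted, out$id[i])
    }
    if (length(planted) == 0) {
      abort("could not plant the requested mutation in any record")
    }
    truth <- tibble(id = planted, type = type, count = count,
                    expected_ows = expected)
    structure(list(db = out, truth = truth), class = "eco_sim_primer")
  })
}
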