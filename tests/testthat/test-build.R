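# helpers to assemble templates around primer sites
flank_template <- function(core, pair, lead = "", trail = "") {
  paste0(lead, pair$forward, core, revcomp(pair$reverse), trail)
}

test_that("primer-window trimming extracts the inter-primer core", {
  pair <- primer_pair("ACGGATTCAGCT", "GGTCATTCCAAG")
  withr::with_seed(3, {
    core <- rand_dna(200)
    seqs <- tibble::tibble(
      id = c("full", "norev", "nofwd"),
      sequence = c(flank_template(core, pair, rand_dna(10), rand_dna(10)),
                   paste0(pair$forward, core),
                   paste0(core, revcomp(pair$reverse)))
    )
    out <- trim_to_primer_window(seqs, pair)
    expect_equal(out$sequence[1], core)
    expect_equal(out$status, c("ok", "missing_primer", "missing_primer"))

    # min-length rejection
    short <- tibble::tibble(id = "s", sequence = flank_template("ACGT", pair))
    expect_equal(trim_to_primer_window(short, pair, min_length = 10)$status,
                 "too_short")
    # overlapping/inverted sites: reverse site before forward site
    inv <- tibble::tibble(id = "i",
                          sequence = paste0(revcomp(pair$reverse), "AC",
                                            pair$forward, rand_dna(5)))
    expect_equal(trim_to_primer_window(inv, pair)$status, "inverted_sites")
  })
})

test_that("degenerate primer bases match every base in their IUPAC set", {
  pair <- primer_pair("AACMGGATTAGATACCCKG", "ACGTCATCCCCACCTTCC")
  withr::with_seed(4, {
    core <- rand_dna(120)
    for (mbase in c("A", "C")) {
      fwd <- sub("M", mbase, pair$forward)
      tpl <- tibble::tibble(id = "t",
                            sequence = paste0(fwd, core, revcomp(pair$reverse)))
      expect_equal(trim_to_primer_window(tpl, pair)$status, "ok")
      expect_equal(trim_to_primer_window(tpl, pair)$sequence, core)
    }
  })
})

test_that("trimming uses the outermost candidate sites", {
  pair <- primer_pair("ACGGATTCAGCT", "GGTCATTCCAAG")
  withr::with_seed(8, {
    inner <- rand_dna(30)
    # forward site appears twice; leftmost must win (reverse likewise rightmost)
    s <- paste0(pair$forward, "TTTT", pair$forward, inner,
                revcomp(pair$reverse), "AAAA", revcomp(pair$reverse))
    out <- trim_to_primer_window(tibble::tibble(id = "x", sequence = s), pair)
    expect_equal(out$sequence,
                 paste0("TTTT", pair$forward, inner, revcomp(pair$reverse), "AAAA"))
  })
})

test_that("FL-ASV dereplication counts copies and orders by abundance", {
  out <- resolve_flasvs(c("AAAA", "CCCC", "AAAA", "AAAA"))
  expect_equal(out$id, c("FLASV1", "FLASV2"))
  expect_equal(out$sequence, c("AAAA", "CCCC"))
  expect_equal(out$abundance, c(3L, 1L))

  # all-identical input collapses to one record
  one <- resolve_flasvs(rep("ACGTACGT", 7))
  expect_equal(nrow(one), 1)
  expect_equal(one$abundance, 7L)

  # abundance ties keep first-occurrence order
  tie <- resolve_flasvs(c("GGGG", "TTTT"))
  expect_equal(tie$sequence, c("GGGG", "TTTT"))

  # planted duplicates: record count equals distinct-string count
  withr::with_seed(12, {
    pool <- replicate(120, rand_dna(40))
    seqs <- sample(pool, 1000, replace = TRUE)
    expect_equal(nrow(resolve_flasvs(seqs)), length(unique(seqs)))
  })
  expect_error(resolve_flasvs(character(0)), "non-empty")
})

test_that("taxonomy inheritance copies names down to the identity-matched rank", {
  withr::with_seed(15, {
    L <- 1000
    ref <- rand_dna(L)
    universal <- toy_universal(c(ref, rand_dna(L)))
    # 96.0% -> genus; 100 -> species; 80.0% -> class. The 20%-divergent case
    # spaces its substitutions evenly so the gapless alignment stays optimal.
    ch <- strsplit(ref, "")[[1]]
    pos <- seq(1, L, by = 5)
    ch[pos] <- chartr("ACGT", "CGTA", ch[pos])
    qs <- tibble::tibble(
      id = c("q96", "q100", "q80"),
      sequence = c(mutate_seq(ref, 40), ref, paste(ch, collapse = ""))
    )
    out <- inherit_taxonomy(qs, universal)
    expect_equal(out$best_hit_identity, c(96, 100, 80))

    expect_equal(out$genus[1], "Genus1")
    expect_true(is.na(out$species[1]))
    expect_equal(out$prov_genus[1], "inherited")
    expect_equal(out$prov_species[1], "empty")

    expect_equal(out$species[2], "Spec1")

    expect_equal(out$class[3], "Cla1")
    expect_true(is.na(out$order[3]))
  })
})

test_that("inheritance leaves ranks empty when the hit itself lacks them", {
  withr::with_seed(16, {
    ref <- rand_dna(600)
    universal <- toy_universal(ref)
    universal$species <- NA_character_
    out <- inherit_taxonomy(tibble::tibble(id = "q", sequence = ref), universal)
    expect_true(is.na(out$species))
    expect_equal(out$prov_species, "empty")
    expect_equal(out$genus, "Genus1")
  })
})

test_that("de novo placeholders cluster greedily within the parent taxon", {
  withr::with_seed(18, {
    L <- 1000
    base <- rand_dna(L)
    # two records, same inherited family, 95% mutual identity, no genus/species
    db <- tibble::tibble(id = c("FLASV1", "FLASV2"),
                         sequence = c(base, mutate_seq(base, 50)),
                         abundance = c(2L, 1L))
    db <- add_fixed_taxonomy(db, family = "FamX")
    out <- assign_denovo_placeholders(db, prefix = "ECO")
    expect_equal(out$genus[1], "ECO_g_1")
    expect_equal(out$genus[2], "ECO_g_1")        # joined at 95 >= 94.5
    expect_equal(out$species, c("ECO_s_1", "ECO_s_2"))  # split at 95 < 98.7
    expect_equal(unique(out$prov_genus), "de_novo")

    # singleton record gains its own ordinal-numbered names
    single <- add_fixed_taxonomy(
      tibble::tibble(id = "FLASV1", sequence = rand_dna(300), abundance = 1L),
      family = "FamY")
    outs <- assign_denovo_placeholders(single, prefix = "ECO")
    expect_equal(outs$genus, "ECO_g_1")
    expect_equal(outs$species, "ECO_s_1")

    # different inherited families never share a de novo genus
    twofam <- tibble::tibble(id = c("FLASV1", "FLASV2"),
                             sequence = c(base, base),
                             abundance = c(1L, 1L))
    twofam <- add_fixed_taxonomy(twofam, family = c("FamA", "FamB"))
    out2 <- assign_denovo_placeholders(twofam, prefix = "ECO")
    expect_false(out2$genus[1] == out2$genus[2])
  })
})

test_that("build_database yields a complete, consistent, deterministic database", {
  withr::with_seed(23, {
    sim <- simulate_reference(sim_spec(
      seq_len = 900,
      deepest_rank_counts = c(species = 20, genus = 8, family = 4),
      seed = 101))
    built <- build_database(sim$queries, sim$universal, build_config())
    db <- built$db
    # completeness: no empty rank anywhere
    expect_false(any(is.na(as.matrix(db[tax_ranks()]))))
    # consistency: shared name at rank r implies shared names above r
    for (ri in 3:7) {
      r <- tax_ranks()[ri]
      above <- tax_ranks()[seq_len(ri - 1)]
      per_taxon <- dplyr::distinct(db[c(r, above)])
      expect_equal(anyDuplicated(per_taxon[[r]]), 0)
    }
    # determinism: byte-identical database files on rerun
    built2 <- build_database(sim$queries, sim$universal, build_config())
    f1 <- tempfile(); f2 <- tempfile()
    write_sintax_fasta(built$db, f1); write_sintax_fasta(built2$db, f2)
    expect_identical(readLines(f1), readLines(f2))
    # report covers the stages
    expect_true(all(c("input", "dereplicate") %in% built$report$stage))
  })
})

test_that("cluster members sit within the rank threshold of their seed", {
  withr::with_seed(29, {
    sim <- simulate_reference(sim_spec(
      seq_len = 900,
      deepest_rank_counts = c(species = 10, genus = 12, family = 6),
      seed = 55))
    db <- build_database(sim$queries, sim$universal, build_config())$db
    thr <- threshold_table()
    for (r in c("genus", "species")) {
      denovo <- db[db[[paste0("prov_", r)]] == "de_novo", ]
      for (taxon in unique(denovo[[r]])) {
        members <- denovo[denovo[[r]] == taxon, ]
        seed_ord <- parse_placeholder(taxon)$number
        seed_seq <- db$sequence[seed_ord]
        ids <- vapply(members$sequence,
                      function(s) global_identity(s, seed_seq),
                      numeric(1), USE.NAMES = FALSE)
        expect_true(all(ids >= thr[[r]]))
      }
    }
  })
})
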