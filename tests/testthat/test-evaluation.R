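test_that("sequence novelty counts records below each rank threshold", {
  db <- tibble::tibble(id = paste0("F", 1:4),
                       sequence = strrep("ACGT", 25),
                       best_hit_identity = c(99, 98, 90, 80))
  nov <- sequence_novelty(db)
  got <- setNames(nov$n_novel, nov$rank)
  expect_equal(got[["species"]], 3L)
  expect_equal(got[["genus"]], 2L)
  expect_equal(got[["family"]], 1L)
  expect_equal(got[["order"]], 1L)
  expect_equal(got[["class"]], 0L)
  expect_equal(nov$pct_novel[nov$rank == "species"], 75)

  db$best_hit_identity <- rep(100, 4)
  expect_true(all(sequence_novelty(db)$n_novel == 0))
  db$best_hit_identity <- rep(50, 4)
  expect_true(all(sequence_novelty(db)$n_novel == 4))
})

test_that("novelty counts are nested across ranks for random identities", {
  withr::with_seed(61, {
    for (i in 1:1000) {
      ids <- runif(sample(3:30, 1), 0, 100)
      db <- tibble::tibble(id = as.character(seq_along(ids)),
                           sequence = "ACGT", best_hit_identity = ids)
      nov <- sequence_novelty(db)
      expect_true(all(diff(nov$n_novel) >= 0))
    }
  })
})

test_that("taxonomy novelty counts distinct placeholder taxa per rank", {
  withr::with_seed(62, {
    db <- make_toy_db(10)
    # every species is a placeholder -> 100%
    db$species <- paste0("ECO_s_", 1:10)
    tn <- taxonomy_novelty(db)
    expect_equal(tn$pct_denovo[tn$rank == "species"], 100)
    # fully inherited db -> all zero
    db2 <- make_toy_db(10)
    expect_true(all(taxonomy_novelty(db2)$n_denovo == 0))
    # 2 placeholder genera among 10 -> 20%
    db3 <- make_toy_db(10)
    db3$genus[1:2] <- c("ECO_g_1", "ECO_g_2")
    tn3 <- taxonomy_novelty(db3)
    expect_equal(tn3$pct_denovo[tn3$rank == "genus"], 20)
  })
})

test_that("coverage evaluation filters by abundance and counts high-identity hits", {
  withr::with_seed(63, {
    L <- 500
    refs <- tibble::tibble(id = paste0("R", 1:3),
                           sequence = replicate(3, rand_dna(L)))
    # identities 100, 99.2 (4 subs), 97 (15 subs) against their own refs
    asvs <- tibble::tibble(
      id = paste0("A", 1:3),
      sequence = c(refs$sequence[1],
                   mutate_seq(refs$sequence[2], 4),
                   mutate_seq(refs$sequence[3], 15)))
    counts <- tibble::tibble(asv = asvs$id, S1 = c(4000L, 3000L, 3000L))
    cov <- coverage_eval(asvs, counts, refs)
    expect_equal(cov$frac_high_identity, 2 / 3)
    expect_equal(cov$coverage, 1)

    # an ASV at 0.005% relative abundance is excluded from both sets
    counts2 <- tibble::tibble(asv = asvs$id, S1 = c(199990L, 10L, 0L))
    cov2 <- coverage_eval(asvs, counts2, refs)
    expect_equal(cov2$n_kept, 1L)
    expect_equal(cov2$frac_high_identity, 1)
    expect_lt(cov2$coverage, 1)

    # every ASV present verbatim -> fraction 1
    asvs3 <- refs[c("id", "sequence")]
    names(asvs3) <- c("id", "sequence")
    counts3 <- tibble::tibble(asv = refs$id, S1 = c(10L, 10L, 10L))
    expect_equal(coverage_eval(asvs3, counts3, refs)$frac_high_identity, 1)
  })
})

test_that("coverage fractions are invariant under count rescaling", {
  withr::with_seed(64, {
    refs <- tibble::tibble(id = paste0("R", 1:4),
                           sequence = replicate(4, rand_dna(300)))
    asvs <- tibble::tibble(id = paste0("A", 1:4),
                           sequence = vapply(refs$sequence, mutate_seq,
                                             character(1), s = 2,
                                             USE.NAMES = FALSE))
    counts <- tibble::tibble(asv = asvs$id,
                             S1 = c(500L, 300L, 150L, 50L),
                             S2 = c(10L, 20L, 30L, 940L))
    c1 <- coverage_eval(asvs, counts, refs)
    counts10 <- counts
    counts10$S1 <- counts10$S1 * 10L
    counts10$S2 <- counts10$S2 * 10L
    c2 <- coverage_eval(asvs, counts10, refs)
    expect_equal(c1$frac_high_identity, c2$frac_high_identity)
    expect_equal(c1$coverage, c2$coverage)
  })
})

test_that("classification rate reflects the classifiable fraction", {
  withr::with_seed(65, {
    db <- make_toy_db(6, len = 250)
    idx <- train_index(db)
    verbatim <- db[c("id", "sequence")][1:6, ]
    r1 <- classification_rate(verbatim, idx)
    expect_equal(r1$genus_rate, 1)
    expect_equal(r1$species_rate, 1)

    unrelated <- tibble::tibble(id = paste0("U", 1:4),
                                sequence = replicate(4, strrep("AT", 60)))
    # mixed set of 10: 6 verbatim + 4 unrelated -> genus fraction 0.6
    mixed <- dplyr::bind_rows(verbatim, unrelated)
    rates <- classification_rate(mixed, idx)
    expect_equal(rates$genus_rate, 0.6)
  })
})

test_that("in-silico ASVs are extracted redundantly with parent links", {
  pair <- primer_pair("ACGGATTCAGCT", "GGTCATTCCAAG")
  withr::with_seed(66, {
    core <- rand_dna(120)
    db <- tibble::tibble(
      id = c("P1", "P2", "P3"),
      sequence = c(paste0(rand_dna(30), pair$forward, core,
                          revcomp(pair$reverse), rand_dna(30)),
                   paste0(rand_dna(10), pair$forward, core,
                          revcomp(pair$reverse), rand_dna(50)),
                   rand_dna(220)))
    ins <- extract_insilico_asvs(db, pair)
    expect_equal(ins$amplifiable, c(TRUE, TRUE, FALSE))
    # identical cores stay as two entries with distinct parents
    expect_equal(ins$sequence[1], core)
    expect_equal(ins$sequence[2], core)
    expect_equal(ins$parent_id, c("P1", "P2", "P3"))
  })
})

test_that("resolution evaluation partitions correctly / wrongly / unclassified", {
  pair <- primer_pair("ACGGATTCAGCT", "GGTCATTCCAAG")
  withr::with_seed(67, {
    # unique sub-regions: every in-silico ASV must be species-correct
    db <- make_toy_db(6, len = 40)
    db$sequence <- vapply(db$sequence, function(s) {
      paste0(rand_dna(20), pair$forward, rand_dna(90),
             revcomp(pair$reverse), rand_dna(20))
    }, character(1), USE.NAMES = FALSE)
    ins <- extract_insilico_asvs(db, pair)
    res <- resolution_eval(ins, db, classifier_params(strand = "plus"))
    expect_equal(res$correct[res$rank == "genus"], 1)
    expect_equal(res$correct[res$rank == "species"], 1)
    expect_equal(res$correct + res$wrong + res$not_classified, c(1, 1))

    # two species share one core: they cannot both be species-correct
    db2 <- db
    core <- rand_dna(90)
    shared <- paste0(pair$forward, core, revcomp(pair$reverse))
    db2$sequence[1] <- paste0(rand_dna(20), shared, rand_dna(20))
    db2$sequence[2] <- paste0(rand_dna(25), shared, rand_dna(15))
    ins2 <- extract_insilico_asvs(db2, pair)
    res2 <- resolution_eval(ins2, db2, classifier_params(strand = "plus"))
    expect_lte(res2$correct[res2$rank == "species"], (6 - 1) / 6)
    expect_equal(res2$correct + res2$wrong + res2$not_classified, c(1, 1),
                 tolerance = 1e-9)
  })
})
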