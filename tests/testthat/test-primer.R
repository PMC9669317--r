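# a 19-nt primer with low self-similarity so single planted events are the
# unambiguous optimum
P19 <- "ACGGATCACGTTAGCTGCA"

embed <- function(site, lead, trail) paste0(lead, site, trail)

test_that("the five penalty cases score exactly as specified", {
  lead <- "TTCCTTAACCTTGGAACCT"
  trail <- "TCCTATTCCAACCTTATCC"
  site <- strsplit(P19, "")[[1]]
  m <- length(site)

  # exact match -> 0, perfect
  s0 <- score_primer(P19, embed(P19, lead, trail))
  expect_equal(s0$ows, 0)
  expect_equal(s0$category, "perfect")

  # one substitution at primer position 5 (> 5 bases from the 3' end) -> 0.40
  x <- site; x[5] <- "C"
  s1 <- score_primer(P19, embed(paste(x, collapse = ""), lead, trail))
  expect_equal(s1$ows, 0.4)
  expect_equal(s1$non3_mismatches, 1L)
  expect_equal(s1$category, "partial")

  # one substitution at the third base from the 3' end (3', not terminal) -> 1.00
  x <- site; x[m - 2] <- "C"
  s2 <- score_primer(P19, embed(paste(x, collapse = ""), lead, trail))
  expect_equal(s2$ows, 1)
  expect_equal(s2$three_prime_mismatches, 1L)
  expect_equal(s2$category, "partial")

  # terminal-base mismatch -> 3.00 (replaces the generic 3' penalty)
  x <- site; x[m] <- "C"
  s3 <- score_primer(P19, embed(paste(x, collapse = ""), lead, trail))
  expect_equal(s3$ows, 3)
  expect_true(s3$last_base_mismatch)
  expect_equal(s3$three_prime_mismatches, 0L)
  expect_equal(s3$category, "poor")

  # single-base deletion at primer position 6 -> non-3' gap, 1.00
  x <- site[-6]
  s4 <- score_primer(P19, embed(paste(x, collapse = ""), lead, trail))
  expect_equal(s4$ows, 1)
  expect_equal(s4$non3_gaps, 1L)

  # single-base deletion at the third base from the 3' end -> 3' gap, 3.00
  x <- site[-(m - 2)]
  s5 <- score_primer(P19, embed(paste(x, collapse = ""), lead, trail))
  expect_equal(s5$ows, 3)
  expect_equal(s5$three_prime_gaps, 1L)
})

test_that("degenerate primer bases match their whole IUPAC set", {
  primer <- "AACMGGATTAGATACCCKG"   # 799F
  for (mb in c("A", "C")) for (kb in c("G", "T")) {
    site <- sub("M", mb, sub("K", kb, primer))
    s <- score_primer(primer, paste0("TTCCTTAACC", site, "TTGGAACCTT"))
    expect_equal(s$ows, 0)
    expect_equal(s$category, "perfect")
  }
  # a base outside the set is a mismatch
  site <- sub("M", "G", sub("K", "G", primer))
  s <- score_primer(primer, paste0("TTCCTTAACC", site, "TTGGAACCTT"))
  expect_gt(s$ows, 0)
})

test_that("score categories split at 0 and 1", {
  expect_equal(categorize_ows(0), "perfect")
  expect_equal(categorize_ows(0.4), "partial")
  expect_equal(categorize_ows(1), "partial")
  expect_equal(categorize_ows(1.4), "poor")
  expect_error(categorize_ows(-0.1), ">= 0")
})

test_that("a verbatim primer occurrence always scores zero", {
  withr::with_seed(71, {
    for (i in 1:40) {
      primer <- rand_iupac_primer(sample(10:20, 1), sample(0:3, 1))
      concrete <- vapply(strsplit(primer, "")[[1]], function(ch) {
        sample(strsplit(iupac_sets[[ch]], "")[[1]], 1)
      }, character(1))
      tpl <- paste0(rand_dna(40), paste(concrete, collapse = ""), rand_dna(40))
      expect_equal(score_primer(primer, tpl)$ows, 0)
    }
  })
})

test_that("minimal OWS equals the unbounded placement-enumeration oracle", {
  withr::with_seed(72, {
    for (i in 1:60) {
      primer <- rand_iupac_primer(sample(8:14, 1), sample(0:2, 1))
      tpl <- rand_dna(sample(30:60, 1))
      expect_equal(score_primer(primer, tpl, ceiling = Inf)$ows,
                   oracle_min_ows(primer, tpl))
    }
  })
})

test_that("scores grow additively as planted mismatches accumulate", {
  # one extra non-3' mismatch adds 0.40 as long as the planted site remains
  # the cheapest placement; contexts where an overlapping alternative would
  # undercut the planted score are redrawn (checked by a gapless offset scan
  # independent of the DP)
  gapless_min <- function(primer, tpl) {
    P <- strsplit(primer, "")[[1]]; Tt <- strsplit(tpl, "")[[1]]
    m <- length(P)
    pen <- c(rep(0.4, m - 5), rep(1, 4), 3)
    min(vapply(0:(length(Tt) - m), function(off) {
      mm <- !mapply(iupac_compatible, P, Tt[off + 1:m])
      sum(pen[mm])
    }, numeric(1)))
  }
  withr::with_seed(73, {
    done <- 0
    for (i in 1:200) {
      if (done >= 30) break
      primer <- rand_dna(14)
      site <- strsplit(primer, "")[[1]]
      lead <- rand_dna(20); trail <- rand_dna(20)
      x <- site
      pos <- sample(14 - 5, 2)
      scores <- numeric(3)
      ok <- TRUE
      for (k in 0:2) {
        if (k > 0) x[pos[k]] <- setdiff(c("A", "C", "G", "T"), x[pos[k]])[1]
        tpl <- embed(paste(x, collapse = ""), lead, trail)
        if (!isTRUE(all.equal(gapless_min(primer, tpl), 0.4 * k))) {
          ok <- FALSE
          break
        }
        scores[k + 1] <- score_primer(primer, tpl, ceiling = Inf)$ows
      }
      if (!ok) next
      expect_equal(scores, c(0, 0.4, 0.8))
      done <- done + 1
    }
    expect_gte(done, 30)
  })
})

test_that("database surveys take the worst primer and summarise per taxon", {
  pairx <- primer_pair(P19, "GGTCATTCCAAGCCTTAG")
  withr::with_seed(74, {
    core <- rand_dna(60)
    m <- nchar(P19)
    fwd_mut <- strsplit(P19, "")[[1]]; fwd_mut[3] <- "T"  # one non-3' mismatch
    mkrec <- function(fwd) {
      paste0(rand_dna(12), fwd, core, revcomp(pairx$reverse), rand_dna(12))
    }
    db <- make_toy_db(2, len = 40)
    db$sequence <- c(mkrec(P19), mkrec(paste(fwd_mut, collapse = "")))
    sv <- survey_database(db, pairx)
    expect_equal(sv$ows, c(0, 0.4))
    expect_equal(sv$category, c("perfect", "partial"))
    summ <- attr(sv, "summary")
    expect_equal(sort(unique(summ$phylum)), c("Phy1", "Phy2"))

    # a record with no usable site for either primer is tallied separately
    db2 <- make_toy_db(1, len = 40)
    db2$sequence <- strrep("AT", 60)
    sv2 <- survey_database(db2, pairx, ceiling = 2)
    expect_equal(sv2$category, "no_site")
  })
})

test_that("primer scoring rejects degenerate inputs", {
  expect_error(score_primer("ACGT", "ACGTACGTACGT"), "at least 6")
  expect_error(score_primer("ACGTACGT", "ACGT"), "longer than the primer")
  expect_error(primer_pair("ACG", "ACGTAA"), "at least 6")
  expect_error(primer_pair("ACGTAZ", "ACGTAA"), "non-IUPAC")
})
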