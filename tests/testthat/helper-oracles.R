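# Independent reference implementations used as oracles, written in plain R
# against the stated definitions (not ports of the package internals).

# Quadratic Gotoh DP with full matrices and explicit traceback.
# Scoring: match +1, mismatch -1, gap open -2, extend -1; identity =
# 100 * matches / columns excluding terminal-gap columns. Tie-breaks mirror
# the documented deterministic convention (predecessor and final-state
# priority M > X > Y).
oracle_global_identity <- function(a, b) {
  # byte-wise canonical argument order, mirroring the documented convention
  o <- sort(c(a, b), method = "radix")
  a <- o[1]; b <- o[2]
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  # lexicographic objective: score first, then terminal-gap columns (gap
  # moves on boundary rows/columns), encoded as score * W + bonus
  W <- 4 * (n + m + 2)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  PM <- PX <- PY <- matrix(0L, n + 1, m + 1)   # 1=M, 2=X, 3=Y
  M[1, 1] <- 0
  for (i in 2:(n + 1)) {
    X[i, 1] <- (if (i == 2) -2 * W else X[i - 1, 1] - W) + 1
    PX[i, 1] <- 2L
  }
  for (j in 2:(m + 1)) {
    Y[1, j] <- (if (j == 2) -2 * W else Y[1, j - 1] - W) + 1
    PY[1, j] <- 3L
  }
  pick <- function(vals) which.max(vals)   # first max: priority M > X > Y
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) W else -W
      v <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      k <- pick(v); M[i, j] <- v[k] + s; PM[i, j] <- k
      xb <- if (j == m + 1) 1L else 0L
      v <- c(M[i - 1, j] - 2 * W, X[i - 1, j] - W, Y[i - 1, j] - 2 * W)
      k <- pick(v); X[i, j] <- v[k] + xb; PX[i, j] <- k
      yb <- if (i == n + 1) 1L else 0L
      v <- c(M[i, j - 1] - 2 * W, X[i, j - 1] - 2 * W, Y[i, j - 1] - W)
      k <- pick(v); Y[i, j] <- v[k] + yb; PY[i, j] <- k
    }
  }
  st <- pick(c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1]))
  i <- n + 1; j <- m + 1
  cols <- character(0)
  while (i > 1 || j > 1) {
    if (st == 1) {
      cols <- c(if (A[i - 1] == B[j - 1]) "M" else "S", cols)
      st <- PM[i, j]; i <- i - 1; j <- j - 1
    } else if (st == 2) {
      cols <- c("X", cols); st <- PX[i, j]; i <- i - 1
    } else {
      cols <- c("Y", cols); st <- PY[i, j]; j <- j - 1
    }
  }
  gap <- cols %in% c("X", "Y")
  lead <- match(FALSE, gap) - 1
  if (is.na(lead)) return(0)             # all-gap alignment
  trail <- match(FALSE, rev(gap)) - 1
  denom <- length(cols) - lead - trail
  100 * sum(cols == "M") / denom
}

# IUPAC compatibility for the primer oracle
iupac_sets <- c(A = "A", C = "C", G = "G", T = "T",
                R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")
iupac_compatible <- function(p, t) {
  any(strsplit(iupac_sets[[p]], "")[[1]] %in% strsplit(iupac_sets[[t]], "")[[1]])
}

# Top-down memoised minimum-OWS over all placements (unbounded gaps).
# Minimum value is unique, so equality with the DP is well-posed.
oracle_min_ows <- function(primer, template) {
  P <- strsplit(primer, "")[[1]]; Tm <- strsplit(template, "")[[1]]
  m <- length(P); n <- length(Tm)
  mm_pen <- function(i) if (i == m) 3 else if (i > m - 5) 1 else 0.4
  del_pen <- function(i) if (i > m - 5) 3 else 1
  ins_pen <- function(i) if (i >= m - 4) 3 else 1
  memo <- new.env(hash = TRUE)
  # cost of aligning primer[i..m] given template consumed through j (free tail)
  rec <- function(i, j) {
    if (i > m) return(0)
    key <- paste(i, j)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    best <- Inf
    if (j < n) {
      sub <- if (iupac_compatible(P[i], Tm[j + 1])) 0 else mm_pen(i)
      best <- min(best, sub + rec(i + 1, j + 1))
      # extra template base sits between primer bases i-1 and i
      if (i >= 2 && i <= m) {
        best <- min(best, ins_pen(i - 1) + rec(i, j + 1))
      }
    }
    best <- min(best, del_pen(i) + rec(i + 1, j))
    memo[[key]] <- best
    best
  }
  min(vapply(0:n, function(j0) rec(1, j0), numeric(1)))
}

# Gapless + single-gap placement enumeration with event breakdown; used for
# targeted cases where the optimal placement provably needs at most one gap.
oracle_score_breakdown <- function(primer, template) {
  P <- strsplit(primer, "")[[1]]; Tm <- strsplit(template, "")[[1]]
  m <- length(P); n <- length(Tm)
  pen_of <- function(i) if (i == m) 3 else if (i > m - 5) 1 else 0.4
  best <- NULL
  consider <- function(cost, counts) {
    if (is.null(best) || cost < best$ows) best <<- c(list(ows = cost), counts)
  }
  count_mm <- function(pidx, tidx) {
    mm <- !mapply(iupac_compatible, P[pidx], Tm[tidx])
    list(cost = sum(vapply(pidx[mm], pen_of, numeric(1))),
         non3 = sum(pidx[mm] <= m - 5),
         tp = sum(pidx[mm] > m - 5 & pidx[mm] < m),
         last = any(pidx[mm] == m))
  }
  for (off in 0:(n - m)) {
    cm <- count_mm(1:m, off + 1:m)
    consider(cm$cost, list(non3_mismatches = cm$non3,
                           three_prime_mismatches = cm$tp,
                           last_base_mismatch = cm$last,
                           non3_gaps = 0L, three_prime_gaps = 0L))
  }
  # one primer-base gap (template base count m-1)
  if (n >= m - 1) {
    for (off in 0:(n - (m - 1))) {
      for (g in 1:m) {
        pidx <- setdiff(1:m, g)
        cm <- count_mm(pidx, off + seq_len(m - 1))
        gp <- if (g > m - 5) 3 else 1
        consider(cm$cost + gp,
                 list(non3_mismatches = cm$non3,
                      three_prime_mismatches = cm$tp,
                      last_base_mismatch = cm$last,
                      non3_gaps = as.integer(g <= m - 5),
                      three_prime_gaps = as.integer(g > m - 5)))
      }
    }
  }
  # one extra template base between primer g and g+1
  if (n >= m + 1) {
    for (off in 0:(n - (m + 1))) {
      for (g in 1:(m - 1)) {
        tidx <- off + c(seq_len(g), g + 2:(m - g + 1))
        cm <- count_mm(1:m, tidx)
        gp <- if (g >= m - 4) 3 else 1
        consider(cm$cost + gp,
                 list(non3_mismatches = cm$non3,
                      three_prime_mismatches = cm$tp,
                      last_base_mismatch = cm$last,
                      non3_gaps = as.integer(g < m - 4),
                      three_prime_gaps = as.integer(g >= m - 4)))
      }
    }
  }
  best
}

# random sequence helpers
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
rand_iupac_primer <- function(n, n_degen = 2) {
  base <- sample(c("A", "C", "G", "T"), n, TRUE)
  if (n_degen > 0) {
    pos <- sample(n, n_degen)
    base[pos] <- sample(c("R", "Y", "S", "W", "K", "M"), n_degen, TRUE)
  }
  paste(base, collapse = "")
}

# a tiny fully-annotated universal reference tibble for unit tests
toy_universal <- function(seqs, genus_prefix = "Genus") {
  n <- length(seqs)
  tibble::tibble(
    id = paste0("U", seq_len(n)), sequence = seqs,
    domain = "Bacteria", phylum = paste0("Phy", seq_len(n)),
    class = paste0("Cla", seq_len(n)), order = paste0("Ord", seq_len(n)),
    family = paste0("Fam", seq_len(n)),
    genus = paste0(genus_prefix, seq_len(n)),
    species = paste0("Spec", seq_len(n))
  )
}

# plant s substitutions into a sequence at distinct random positions
mutate_seq <- function(seq, s) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), s)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# a database tibble with fixed inherited taxonomy above genus and empty
# genus/species, provenance flags included
add_fixed_taxonomy <- function(db, family = "FamX") {
  db$domain <- "Bacteria"; db$phylum <- "PhyX"
  db$class <- "ClaX"; db$order <- "OrdX"
  db$family <- family
  db$genus <- NA_character_; db$species <- NA_character_
  for (r in tax_ranks()) {
    db[[paste0("prov_", r)]] <- ifelse(is.na(db[[r]]), "empty", "inherited")
  }
  db
}

# small fully-annotated database of random sequences for classifier and
# evaluation tests
make_toy_db <- function(n = 8, len = 300) {
  db <- tibble::tibble(id = paste0("FLASV", 1:n),
                       sequence = replicate(n, rand_dna(len)))
  db$domain <- "Bacteria"
  db$phylum <- paste0("Phy", rep(1:2, length.out = n))
  db$class <- paste0("Cla", rep(1:2, length.out = n))
  db$order <- paste0("Ord", rep(1:2, length.out = n))
  db$family <- paste0("Fam", rep(1:4, length.out = n))
  db$genus <- paste0("Gen", 1:n)
  db$species <- paste0("Spe", 1:n)
  db
}
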