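# File I/O: FASTA (plain, SINTAX-annotated), QIIME taxonomy TSV, count
# tables. Sequence containers are tibbles (id, sequence); Biostrings does the
# heavy lifting behind the surface.

# normalise a sequence on ingest: uppercase, RNA U -> T
clean_seq <- function(x) {
  chartr("U", "T", toupper(x))
}

#' Read and write FASTA files as tibbles
#'
#' Sequences are uppercased and U is mapped to T on ingest.
#'
#' @param path File path.
#' @return `read_fasta()`: tibble with columns `id`, `sequence`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  tibble(id = names(ss), sequence = clean_seq(as.character(ss)))
}

#' @rdname read_fasta
#' @param df Tibble with columns `id`, `sequence` (an `id` may carry a full
#'   SINTAX header).
#' @param width Line-wrap width in columns; `0` writes single-line records.
#' @export
write_fasta <- function(df, path, width = 80) {
  seqs <- df$sequence
  ids <- df$id
  lines <- character(0)
  for (i in seq_along(seqs)) {
    body <- if (width > 0) {
      starts <- seq(1, nchar(seqs[i]), by = width)
      substring(seqs[i], starts, pmin(starts + width - 1, nchar(seqs[i])))
    } else {
      seqs[i]
    }
    lines <- c(lines, paste0(">", ids[i]), body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read/write a reference database with SINTAX-annotated FASTA headers
#'
#' @param db A database tibble (columns `id`, `sequence`, seven ranks).
#' @param path File path.
#' @param width FASTA wrap width (0 = single line).
#' @return `read_sintax_fasta()`: tibble with `id`, `sequence` and the seven
#'   rank columns.
#' @export
write_sintax_fasta <- function(db, path, width = 0) {
  headers <- format_taxonomy(db, "sintax")
  write_fasta(tibble(id = headers, sequence = db$sequence), path, width = width)
}

#' @rdname write_sintax_fasta
#' @export
read_sintax_fasta <- function(path) {
  raw <- read_fasta(path)
  tax <- parse_taxonomy(raw$id, "sintax")
  dplyr::bind_cols(tax, raw["sequence"])
}

#' Read/write QIIME-style two-column taxonomy TSV
#'
#' @param db A database tibble with `id` and rank columns.
#' @param path File path.
#' @return `read_qiime_taxonomy()`: tibble `id` + seven rank columns.
#' @export
write_qiime_taxonomy <- function(db, path) {
  writeLines(format_taxonomy(db, "qiime"), path)
  invisible(path)
}

#' @rdname write_qiime_taxonomy
#' @export
read_qiime_taxonomy <- function(path) {
  parse_taxonomy(readLines(path), "qiime")
}

#' Read/write ASV count tables
#'
#' Count tables are TSV with an `asv` id column and one non-negative integer
#' column per sample.
#'
#' @param counts Tibble: `asv` column + sample columns.
#' @param path File path.
#' @return `read_count_table()`: the count tibble.
#' @export
write_count_table <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' @rdname write_count_table
#' @export
read_count_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Assemble and validate an amplicon dataset
#'
#' Couples ASV sequences with a per-sample count table and validates that
#' every ASV in the table has a sequence and that counts are non-negative.
#'
#' @param asvs Tibble with columns `id`, `sequence`.
#' @param counts Tibble with `asv` column and one column per sample.
#' @return A list of class `amplicon_dataset` with elements `asvs`, `counts`.
#' @export
amplicon_dataset <- function(asvs, counts) {
  if (!all(c("id", "sequence") %in% names(asvs))) {
    abort("asvs must have columns id, sequence")
  }
  if (!"asv" %in% names(counts)) abort("counts must have an asv column")
  if (!all(counts$asv %in% asvs$id)) {
    abort("every asv in the count table must exist in the ASV record set")
  }
  num <- as.matrix(counts[setdiff(names(counts), "asv")])
  if (any(num < 0) || any(num != floor(num))) {
    abort("counts must be non-negative integers")
  }
  structure(list(asvs = asvs, counts = counts), class = "amplicon_dataset")
}

#' Per-sample relative abundances of an amplicon dataset
#'
#' @param counts Count tibble (`asv` + sample columns).
#' @return Long tibble: `asv`, `sample`, `count`, `rel_abundance` (counts
#'   divided by the sample total).
#' @export
relative_abundances <- function(counts) {
  long <- tidyr::pivot_longer(counts, -"asv",
                              names_to = "sample", values_to = "count")
  long |>
    group_by(.data$sample) |>
    mutate(rel_abundance = .data$count / sum(.data$count)) |>
    ungroup()
}

#' Define a primer pair
#'
#' Both primers are written 5' to 3' on their own strand (the reverse primer
#' as ordered on the reverse strand). IUPAC degeneracy codes are allowed.
#'
#' @param forward,reverse IUPAC DNA strings, length >= 6.
#' @return A list of class `primer_pair`.
#' @examples
#' primer_pair("AACMGGATTAGATACCCKG", "ACGTCATCCCCACCTTCC") # 799F / 1192R
#' @export
primer_pair <- function(forward, reverse) {
  check_iupac <- function(x, what) {
    x <- clean_seq(x)
    if (nchar(x) < 6) abort(paste0(what, " primer must be at least 6 nt"))
    if (grepl("[^ACGTRYSWKMBDHVN]", x)) {
      abort(paste0(what, " primer contains non-IUPAC letters"))
    }
    x
  }
  structure(list(forward = check_iupac(forward, "forward"),
                 reverse = check_iupac(reverse, "reverse")),
            class = "primer_pair")
}

#' Common 16S rRNA gene primers
#'
#' A small catalogue of primer sequences used as defaults: 27f/1391r
#' (near-full-length bacterial trimming window), SSU1ArF/SSU1000ArR
#' (archaeal window), and 799F/1192R (the V5-V7 amplicon).
#'
#' @param name Primer name; omit to get the whole catalogue.
#' @return Named character vector, or a single primer string.
#' @export
standard_primers <- function(name = NULL) {
  cat16s <- c(
    "27f" = "AGAGTTTGATCMTGGCTCAG",
    "1391r" = "GACGGGCGGTGTGTRCA",
    "SSU1ArF" = "TCCGGTTGATCCYGCCGG",
    "SSU1000ArR" = "GGCCATGCACYWCYTCTC",
    "799F" = "AACMGGATTAGATACCCKG",
    "1192R" = "ACGTCATCCCCACCTTCC"
  )
  if (is.null(name)) return(cat16s)
  if (!name %in% names(cat16s)) abort(paste0("unknown primer: ", name))
  unname(cat16s[name])
}

# reverse complement for possibly-degenerate DNA strings
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
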