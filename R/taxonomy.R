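# Seven-rank taxonomy core: rank order, identity thresholds, placeholder
# grammar, and the SINTAX / QIIME taxonomy string dialects.

#' The seven taxonomic ranks, domain to species
#'
#' @return Character vector of rank names in hierarchical order.
#' @export
tax_ranks <- function() {
  c("domain", "phylum", "class", "order", "family", "genus", "species")
}

# single-letter rank codes used in SINTAX headers and placeholder names
rank_letters <- c(
  domain = "d", phylum = "p", class = "c", order = "o",
  family = "f", genus = "g", species = "s"
)

# ranks eligible for identity-threshold transfer and de novo placeholders
threshold_ranks <- function() tax_ranks()[-1]

#' Per-rank minimum identity thresholds for taxonomy transfer
#'
#' Minimum percent identity between a query and its closest reference for the
#' reference's name at a given rank to be transferable. Defaults are the
#' rank thresholds in wide use for 16S rRNA genes (species 98.7, genus 94.5,
#' family 86.5, order 82.0, class 78.5, phylum 75.0).
#'
#' @param phylum,class,order,family,genus,species Percent identities in
#'   (0, 100], strictly increasing from phylum to species.
#' @return Named numeric vector of class `threshold_table`.
#' @examples
#' threshold_table()
#' @export
threshold_table <- function(phylum = 75.0, class = 78.5, order = 82.0,
                            family = 86.5, genus = 94.5, species = 98.7) {
  tt <- c(phylum = phylum, class = class, order = order,
          family = family, genus = genus, species = species)
  if (any(!is.finite(tt)) || any(tt <= 0) || any(tt > 100)) {
    abort("thresholds must be finite values in (0, 100]")
  }
  if (any(diff(tt) <= 0)) {
    abort("thresholds must be strictly increasing from phylum to species")
  }
  structure(tt, class = c("threshold_table", "numeric"))
}

#' Deepest rank transferable at a given percent identity
#'
#' Returns the deepest rank whose threshold is met (boundary inclusive:
#' an identity exactly equal to a threshold is assignable at that rank), or
#' `"none"` when the identity falls below the phylum threshold.
#'
#' @param identity Numeric vector of percent identities in \[0, 100\].
#' @param thresholds A [threshold_table()].
#' @return Character vector: one of `"none"`, `"phylum"` ... `"species"`.
#' @examples
#' rank_for_identity(c(98.7, 94.4, 74.9))
#' @export
rank_for_identity <- function(identity, thresholds = threshold_table()) {
  if (any(!is.finite(identity)) || any(identity < 0) || any(identity > 100)) {
    abort("identity must be in [0, 100]")
  }
  ranks <- c("none", names(thresholds))
  idx <- vapply(identity, function(x) sum(x >= thresholds), integer(1))
  ranks[idx + 1L]
}

#' Build and parse de novo placeholder names
#'
#' Placeholder names follow the grammar `<prefix>_<rank letter>_<number>`,
#' e.g. `ECO_g_42` for a de novo genus seeded by database record 42.
#'
#' @param prefix Database prefix (non-empty, no underscores at the ends).
#' @param rank One of phylum...species.
#' @param number Positive integer, conventionally the seed record ordinal.
#' @return `placeholder_name()`: character. `parse_placeholder()`: a tibble
#'   with columns `prefix`, `rank`, `number` (NA rows for non-placeholders).
#'   `is_placeholder()`: logical.
#' @export
placeholder_name <- function(prefix, rank, number) {
  stopifnot(nzchar(prefix), rank %in% threshold_ranks())
  paste(prefix, rank_letters[[rank]], as.integer(number), sep = "_")
}

#' @rdname placeholder_name
#' @param x Character vector of taxon names.
#' @export
parse_placeholder <- function(x) {
  m <- stringr::str_match(x, "^(.*)_([pcofgs])_([0-9]+)$")
  tibble(
    name = x,
    prefix = m[, 2],
    rank = names(rank_letters)[match(m[, 3], rank_letters)],
    number = suppressWarnings(as.integer(m[, 4]))
  )
}

#' @rdname placeholder_name
#' @export
is_placeholder <- function(x, prefix = NULL) {
  p <- parse_placeholder(x)
  ok <- !is.na(p$rank)
  if (!is.null(prefix)) ok <- ok & !is.na(p$prefix) & p$prefix == prefix
  ok
}

# internal: validate a taxonomy tibble has the seven rank columns
check_rank_cols <- function(df) {
  missing <- setdiff(tax_ranks(), names(df))
  if (length(missing) > 0) {
    abort(paste0("missing rank columns: ", paste(missing, collapse = ", ")))
  }
  invisible(df)
}

#' Format seven-rank taxonomy paths as text lines
#'
#' Two dialects are supported: `"sintax"` emits
#' `id;tax=d:...,p:...,...,s:...;` (one token per filled rank), `"qiime"`
#' emits `id<TAB>d__...; p__...; ...; s__...`. Empty (NA) ranks are omitted;
#' ranks must be filled contiguously from the domain downward.
#'
#' @param db A tibble with columns `id` and the seven ranks (NA = empty).
#' @param dialect `"sintax"` or `"qiime"`.
#' @return Character vector of lines, one per record.
#' @seealso [parse_taxonomy()]
#' @export
format_taxonomy <- function(db, dialect = c("sintax", "qiime")) {
  dialect <- match.arg(dialect)
  check_rank_cols(db)
  ranks <- tax_ranks()
  mat <- as.matrix(db[ranks])
  filled <- !is.na(mat) & nzchar(mat)
  bad <- apply(filled, 1, function(f) any(diff(as.integer(f)) > 0))
  if (any(bad)) {
    abort("ranks must be filled contiguously from domain downward")
  }
  vapply(seq_len(nrow(db)), function(i) {
    f <- filled[i, ]
    toks <- mat[i, f]
    letters_i <- rank_letters[ranks][f]
    if (dialect == "sintax") {
      paste0(db$id[i], ";tax=",
             paste0(letters_i, ":", toks, collapse = ","), ";")
    } else {
      paste0(db$id[i], "\t",
             paste0(letters_i, "__", toks, collapse = "; "))
    }
  }, character(1))
}

#' Parse taxonomy lines back into a tibble
#'
#' Inverse of [format_taxonomy()]; `format -> parse -> format` is
#' byte-identical for valid inputs.
#'
#' @param lines Character vector of taxonomy lines.
#' @param dialect `"sintax"` or `"qiime"`.
#' @return Tibble with columns `id` and the seven ranks (NA where empty).
#' @export
parse_taxonomy <- function(lines, dialect = c("sintax", "qiime")) {
  dialect <- match.arg(dialect)
  parse_one <- function(line) {
    if (dialect == "sintax") {
      m <- stringr::str_match(line, "^(.*?);tax=(.*);$")
      if (is.na(m[1, 1])) abort(paste0("malformed sintax line: ", line))
      id <- m[1, 2]
      toks <- strsplit(m[1, 3], ",", fixed = TRUE)[[1]]
      parts <- stringr::str_match(toks, "^([dpcofgs]):(.*)$")
    } else {
      bits <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(bits) != 2) abort(paste0("malformed qiime line: ", line))
      id <- bits[1]
      toks <- strsplit(bits[2], "; ", fixed = TRUE)[[1]]
      parts <- stringr::str_match(toks, "^([dpcofgs])__(.*)$")
    }
    if (any(is.na(parts[, 1]))) abort(paste0("malformed taxonomy tokens in: ", line))
    vals <- setNames(rep(NA_character_, 7), tax_ranks())
    vals[names(rank_letters)[match(parts[, 2], rank_letters)]] <- parts[, 3]
    c(id = id, vals)
  }
  rows <- lapply(lines, parse_one)
  out <- as_tibble(do.call(rbind, rows))
  out
}

#' Effective sequencing concentration for a read-tag library fraction
#'
#' Size-corrected effective concentration used to pool size-fractionated
#' read-tag libraries at even coverage:
#' `C_seq = peak_molarity * (-0.0124 * (peak_size - 215) + 10.332)`.
#' The empirical size correction was calibrated for fractions of 500-950 bp;
#' a warning is emitted outside that range, and sizes large enough to drive
#' the correction factor non-positive are an error.
#'
#' @param peak_molarity Peak molarity in pmol/L (>= 0).
#' @param peak_size Mean fragment size in bp (> 0).
#' @return Effective concentration in pmol/L.
#' @examples
#' suppressWarnings(cseq_factor(1, 215)) # 10.332
#' @export
cseq_factor <- function(peak_molarity, peak_size) {
  if (any(peak_molarity < 0)) abort("peak_molarity must be >= 0")
  if (any(peak_size <= 0)) abort("peak_size must be > 0")
  fac <- -0.0124 * (peak_size - 215) + 10.332
  if (any(fac <= 0)) {
    abort("size correction factor is non-positive; formula not valid at this size")
  }
  if (any(peak_size < 500 | peak_size > 950)) {
    warn("peak_size outside the validated 500-950 bp range; extrapolating")
  }
  peak_molarity * fac
}
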