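#' Parse an AAindex1 flat file into a property table
#'
#' Reads physicochemical amino-acid property indices in the AAindex1 record
#' layout (`H` accession line, `D` description line, `I` header naming the
#' amino-acid order, two rows of ten values, records terminated by `//`).
#' Records in which any of the 20 values is missing (`NA` in the file) cannot
#' define a total ordering of the amino acids and are skipped; the number of
#' skipped records is attached as the `skipped` attribute and reported via a
#' message.
#'
#' @param path Path to an AAindex1-format text file.
#' @param quiet If `TRUE`, suppress the skipped-record message.
#'
#' @return A tibble with one row per usable index: `accession`,
#'   `description`, and one numeric column per amino acid (`A` ... `Y`,
#'   alphabetical one-letter order). Attribute `skipped` holds the count of
#'   records dropped for missing values.
#'
#' @examples
#' aa_file <- system.file("extdata", "aaindex_synthetic.txt", package = "fegs")
#' props <- read_aaindex(aa_file)
#' props$accession
#' @export
read_aaindex <- function(path, quiet = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("AAindex file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  # Split into records on terminator lines.
  rec_end <- which(trimws(lines) == "//")
  if (length(rec_end) == 0L) {
    abort("no '//'-terminated AAindex records found")
  }
  starts <- c(1L, utils::head(rec_end, -1L) + 1L)
  records <- purrr::map2(starts, rec_end, function(s, e) lines[s:(e - 1L)])

  skipped <- 0L
  rows <- list()
  for (rec in records) {
    if (all(trimws(rec) == "")) next
    parsed <- parse_aaindex_record(rec)
    if (anyNA(parsed$values)) {
      skipped <- skipped + 1L
      next
    }
    rows[[length(rows) + 1L]] <- tibble(
      accession = parsed$accession,
      description = parsed$description,
      !!!as.list(parsed$values[AMINO_ACIDS])
    )
  }
  out <- if (length(rows)) bind_rows(rows) else
    tibble(accession = character(), description = character())
  if (!quiet && skipped > 0L) {
    inform(sprintf("read_aaindex: skipped %d record(s) with missing values", skipped))
  }
  attr(out, "skipped") <- skipped
  out
}

# Parse one AAindex1 record (character vector of its lines, '//' excluded)
# into list(accession, description, values = named 20-vector, possibly NA).
parse_aaindex_record <- function(rec) {
  tag <- substr(rec, 1L, 1L)
  h <- which(tag == "H")
  if (length(h) == 0L) abort("AAindex record with no H (accession) line")
  accession <- trimws(sub("^H", "", rec[h[1L]]))
  d <- which(tag == "D")
  description <- if (length(d)) trimws(sub("^D", "", rec[d[1L]])) else ""

  i_line <- which(tag == "I")
  if (length(i_line) == 0L) {
    abort(paste0("AAindex record ", accession, ": no I (value header) line"))
  }
  i_line <- i_line[1L]
  header <- strsplit(trimws(sub("^I", "", rec[i_line])), "\\s+")[[1L]]
  pairs <- strsplit(header, "/", fixed = TRUE)
  if (length(pairs) != 10L || any(lengths(pairs) != 2L)) {
    abort(paste0("AAindex record ", accession, ": malformed I-line header"))
  }
  row1_aa <- map_chr(pairs, 1L)
  row2_aa <- map_chr(pairs, 2L)
  aa_order <- c(row1_aa, row2_aa)
  if (!setequal(aa_order, AMINO_ACIDS) || anyDuplicated(aa_order)) {
    abort(paste0("AAindex record ", accession,
                 ": I-line does not name the 20 standard amino acids"))
  }

  if (i_line + 2L > length(rec)) {
    abort(paste0("AAindex record ", accession, ": missing value rows"))
  }
  toks <- unlist(strsplit(trimws(rec[c(i_line + 1L, i_line + 2L)]), "\\s+"))
  toks <- toks[toks != ""]
  if (length(toks) != 20L) {
    abort(sprintf("AAindex record %s: expected 20 values, found %d",
                  accession, length(toks)))
  }
  vals <- suppressWarnings(as.numeric(ifelse(toks == "NA", NA, toks)))
  bad <- which(is.na(vals) & toks != "NA")
  if (length(bad)) {
    abort(sprintf("AAindex record %s: unparseable value '%s' (entry %d)",
                  accession, toks[bad[1L]], bad[1L]))
  }
  names(vals) <- aa_order
  list(accession = accession, description = description, values = vals)
}

#' Remove property indices with duplicated value vectors
#'
#' Among any group of indices whose 20 values are bitwise identical, only the
#' first in table order is retained. Equality is exact -- two indices
#' differing by any amount, however small, are both kept. Order of the
#' surviving rows preserves the input (database file) order, so the retained
#' set is deterministic.
#'
#' @param properties A property tibble as returned by [read_aaindex()].
#' @return The deduplicated property tibble.
#' @examples
#' aa_file <- system.file("extdata", "aaindex_synthetic.txt", package = "fegs")
#' dedupe_properties(read_aaindex(aa_file))
#' @export
dedupe_properties <- function(properties) {
  check_property_table(properties)
  vals <- as.matrix(properties[, AMINO_ACIDS])
  key <- apply(vals, 1L, function(v) paste(sprintf("%.17g", v), collapse = "|"))
  properties[!duplicated(key), , drop = FALSE]
}

#' Restrict a property table to a pinned accession list
#'
#' Given a plain-text file with one accession per line (blank lines and
#' `#` comments ignored), returns the matching rows in the order given by the
#' list, so a published property selection can be reproduced exactly.
#'
#' @param properties A property tibble as returned by [read_aaindex()].
#' @param id_file Path to the accession list.
#' @return The subset property tibble, ordered as in `id_file`.
#' @export
select_properties <- function(properties, id_file) {
  check_property_table(properties)
  ids <- readLines(id_file, warn = FALSE)
  ids <- trimws(ids)
  ids <- ids[ids != "" & !startsWith(ids, "#")]
  missing <- setdiff(ids, properties$accession)
  if (length(missing)) {
    abort(paste0("accessions not present in property table: ",
                 paste(missing, collapse = ", ")))
  }
  properties[match(ids, properties$accession), , drop = FALSE]
}

#' Order the 20 amino acids by one property index
#'
#' Sorts the amino acids by ascending property value; ties are broken by
#' ascending one-letter code so the resulting cone layout is reproducible.
#'
#' @param values Named numeric vector of 20 property values (names are the
#'   standard one-letter codes), or a single row of a property tibble.
#' @return Character vector: the 20 codes in ascending property order.
#' @examples
#' amino_acid_order(setNames(1:20, c("A","C","D","E","F","G","H","I","K","L",
#'                                   "M","N","P","Q","R","S","T","V","W","Y")))
#' @export
amino_acid_order <- function(values) {
  if (is.data.frame(values)) {
    if (nrow(values) != 1L) abort("pass a single property row")
    values <- unlist(values[, AMINO_ACIDS])
  }
  if (!setequal(names(values), AMINO_ACIDS)) {
    abort("values must be named by the 20 standard amino-acid codes")
  }
  values <- values[AMINO_ACIDS]
  if (any(!is.finite(values))) abort("property values must all be finite")
  AMINO_ACIDS[order(values, AMINO_ACIDS)]
}

check_property_table <- function(properties) {
  if (!is.data.frame(properties) ||
      !all(c("accession", AMINO_ACIDS) %in% names(properties))) {
    abort("expected a property tibble with 'accession' and 20 amino-acid columns")
  }
  if (anyDuplicated(properties$accession)) {
    abort("duplicate accessions in property table")
  }
  invisible(properties)
}

#' Generate a synthetic property set
#'
#' Draws `n` synthetic physicochemical indices (i.i.d. standard-normal values
#' per amino acid) in the same tabular layout as [read_aaindex()]. Because
#' the graphical curve depends only on the rank ordering of the 20 values,
#' random continuous draws give, with probability one, `n` distinct
#' orderings-wise usable properties. Intended for tests and desk-scale runs
#' where the curated AAindex database is not available; accessions are
#' prefixed `SYN` to flag their synthetic origin.
#'
#' @param n Number of indices.
#' @param seed Integer seed for reproducibility.
#' @return A property tibble with `n` rows.
#' @examples
#' synthetic_properties(5, seed = 1)
#' @export
synthetic_properties <- function(n = 158, seed = 1L) {
  stopifnot(n >= 1)
  withr_seed(seed, {
    vals <- matrix(stats::rnorm(20L * n), nrow = n,
                   dimnames = list(NULL, AMINO_ACIDS))
    tibble(
      accession = sprintf("SYN%04d", seq_len(n)),
      description = sprintf("synthetic property index %d", seq_len(n)),
      !!!as.data.frame(vals)
    )
  })
}

# Evaluate expr under a local RNG seed without disturbing the global stream.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
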