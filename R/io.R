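#' Read protein sequences from FASTA
#'
#' Sequences are uppercased and sanitized: under `policy = "strip"` (the
#' default) any residue outside the 20 standard one-letter codes -- ambiguity
#' codes (B, J, O, U, X, Z), gaps, stops -- is removed with a warning and
#' counted per record; under `policy = "reject"` the first non-standard
#' residue aborts, naming the record and position. Record ids are the first
#' whitespace-delimited token of the header.
#'
#' @param path FASTA file path.
#' @param policy `"strip"` or `"reject"`.
#' @return A tibble with columns `id`, `sequence`, `n_removed`.
#' @export
read_fasta <- function(path, policy = c("strip", "reject")) {
  policy <- match.arg(policy)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) abort(paste0("no sequences in FASTA file: ", path))
  ids <- stringr::str_split_i(names(set), "\\s+", 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    abort(paste0("duplicate FASTA ids: ", paste(dup, collapse = ", ")))
  }
  raw <- toupper(as.character(set))

  cleaned <- purrr::map2(raw, ids, function(s, id) {
    res <- strsplit(s, "", fixed = TRUE)[[1L]]
    ok <- res %in% AMINO_ACIDS
    if (policy == "reject" && !all(ok)) {
      bad <- which(!ok)[1L]
      abort(sprintf("record %s: non-standard residue '%s' at position %d",
                    id, res[bad], bad))
    }
    list(sequence = paste(res[ok], collapse = ""), n_removed = sum(!ok))
  })
  n_removed <- map_dbl(cleaned, "n_removed")
  seqs <- map_chr(cleaned, "sequence")
  if (any(n_removed > 0)) {
    warn(sprintf("stripped %d non-standard residue(s) from %d record(s)",
                 sum(n_removed), sum(n_removed > 0)))
  }
  empty <- ids[nchar(seqs) == 0L]
  if (length(empty)) {
    abort(paste0("empty sequence after sanitization: ",
                 paste(empty, collapse = ", ")))
  }
  tibble(id = unname(ids), sequence = unname(seqs),
         n_removed = as.integer(unname(n_removed)))
}

#' Write protein sequences to FASTA
#'
#' @param sequences Data frame with `id` and `sequence` columns.
#' @param path Output file path.
#' @param width Line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  check_sequence_table(sequences)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(sequences))) {
    writeLines(paste0(">", sequences$id[i]), con)
    s <- sequences$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
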