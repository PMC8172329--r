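#' Full descriptor vector of one protein sequence
#'
#' Concatenates, in order, the graphical block (one normalized leading
#' eigenvalue per property, see [graphical_features()]), the amino-acid
#' composition (20 values) and the dipeptide composition (400 values). With
#' the full 158-property configuration the result has 158 + 20 + 400 = 578
#' dimensions.
#'
#' @inheritParams graphical_features
#' @return Named numeric vector of length `nrow(properties) + 420`. Names
#'   follow the feature-table convention: `g001`, `g002`, ... for the
#'   graphical block, `aac_A` ... `aac_Y`, `dpc_AA` ... `dpc_YY`.
#' @export
fegs_vector <- function(sequence, properties, freq = c("count", "relative")) {
  freq <- match.arg(freq)
  g <- graphical_features(sequence, properties, freq)
  names(g) <- sprintf("g%03d", seq_along(g))
  a <- aac(sequence)
  names(a) <- paste0("aac_", AMINO_ACIDS)
  d <- dpc(sequence)
  names(d) <- paste0("dpc_", DIPEPTIDES)
  c(g, a, d)
}

#' Descriptor matrix for a set of protein sequences
#'
#' Applies [fegs_vector()] to every sequence of a dataset. Rows keep the
#' input order and each sequence is processed independently, so the result
#' does not depend on evaluation order.
#'
#' @param sequences A data frame with columns `id` (unique) and `sequence`,
#'   e.g. from [read_fasta()] or [simulate_proteins()].
#' @inheritParams graphical_features
#' @return A tibble with column `id` followed by one numeric column per
#'   feature (`g001`..., `aac_A`..., `dpc_AA`...); `nrow(properties) + 420`
#'   feature columns, 578 under the full 158-property configuration.
#' @examples
#' seqs <- simulate_proteins(3, length_range = c(30, 40), seed = 7)
#' feats <- fegs(seqs, synthetic_properties(5, seed = 1))
#' dim(feats)  # 3 x (1 + 5 + 20 + 400)
#' @export
fegs <- function(sequences, properties, freq = c("count", "relative")) {
  freq <- match.arg(freq)
  check_sequence_table(sequences)
  check_property_table(properties)
  rows <- purrr::map(sequences$sequence,
                     function(s) fegs_vector(s, properties, freq))
  mat <- do.call(rbind, rows)
  dplyr::bind_cols(tibble(id = sequences$id), as_tibble(mat))
}

check_sequence_table <- function(sequences) {
  if (!is.data.frame(sequences) ||
      !all(c("id", "sequence") %in% names(sequences))) {
    abort("sequences must be a data frame with 'id' and 'sequence' columns")
  }
  dup <- unique(sequences$id[duplicated(sequences$id)])
  if (length(dup)) {
    abort(paste0("duplicate sequence ids: ", paste(dup, collapse = ", ")))
  }
  invisible(sequences)
}

# Extract the numeric feature matrix (rownames = id) from a feature tibble.
feature_matrix <- function(features) {
  if (!is.data.frame(features) || !"id" %in% names(features)) {
    abort("features must be a data frame with an 'id' column")
  }
  m <- as.matrix(features[, setdiff(names(features), "id"), drop = FALSE])
  if (!is.numeric(m)) abort("non-numeric feature columns")
  rownames(m) <- features$id
  m
}

#' Write / read a feature table as CSV
#'
#' Plain CSV with a header row: `id` column followed by the feature columns.
#' Full double precision is preserved on write so a round trip is exact.
#'
#' @param features Feature tibble from [fegs()] or [fegs_pca()] scores.
#' @param path Output (input) file path.
#' @return `write_features()` returns `path` invisibly; `read_features()`
#'   returns the feature tibble.
#' @export
write_features <- function(features, path) {
  df <- as.data.frame(features)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  as_tibble(utils::read.csv(path, check.names = FALSE,
                            colClasses = c(id = "character")))
}
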