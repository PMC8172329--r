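#' Simulate random protein sequences
#'
#' Draws `n` sequences with lengths uniform on `length_range` and residues
#' i.i.d. from `composition` (uniform over the 20 standard amino acids by
#' default). Deterministic for a fixed seed, so the test suite and worked
#' examples never need a download.
#'
#' @param n Number of sequences.
#' @param length_range Integer length-2 vector, inclusive bounds on sequence
#'   length. Default `c(100, 200)`, bracketing typical single-domain
#'   proteins such as globins (~150 aa).
#' @param seed Integer seed.
#' @param composition Optional length-20 probability vector over the amino
#'   acids in alphabetical order (must sum to 1).
#' @param prefix Id prefix.
#' @return A tibble with columns `id` and `sequence`.
#' @examples
#' simulate_proteins(2, length_range = c(10, 12), seed = 42)
#' @export
simulate_proteins <- function(n, length_range = c(100L, 200L), seed = 1L,
                              composition = NULL, prefix = "seq") {
  stopifnot(n >= 1, length(length_range) == 2L,
            length_range[1L] >= 1, length_range[1L] <= length_range[2L])
  composition <- check_composition(composition)
  withr_seed(seed, {
    lens <- sample(length_range[1L]:length_range[2L], n, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(AMINO_ACIDS, L, replace = TRUE, prob = composition),
            collapse = "")
    }, character(1L))
    tibble(id = sprintf("%s%03d", prefix, seq_len(n)), sequence = seqs)
  })
}

#' Simulate protein families with known membership
#'
#' Draws one random ancestor per family ([simulate_proteins()] conditions),
#' then derives each member by substituting every site independently with
#' probability `divergence` (replacement drawn from `composition`). The
#' family of each member is recorded, giving a ground-truth taxonomy for
#' clustering evaluation. This emulates well-separated homologous families
#' with point substitutions only -- no indels, no site-rate variation, no
#' compositional bias between families.
#'
#' @param n_families Number of families.
#' @param n_per_family Members per family.
#' @param divergence Per-site substitution probability within a family,
#'   in \[0, 1). Default 0.1 (closely related members).
#' @inheritParams simulate_proteins
#' @return A tibble with columns `id`, `sequence`, `family`.
#' @export
simulate_protein_families <- function(n_families, n_per_family,
                                      divergence = 0.1,
                                      length_range = c(100L, 200L),
                                      seed = 1L, composition = NULL) {
  stopifnot(n_families >= 1, n_per_family >= 1,
            divergence >= 0, divergence < 1)
  composition <- check_composition(composition)
  ancestors <- simulate_proteins(n_families, length_range, seed,
                                 composition, prefix = "fam")
  withr_seed(seed + 1L, {
    rows <- purrr::map(seq_len(n_families), function(f) {
      anc <- strsplit(ancestors$sequence[f], "", fixed = TRUE)[[1L]]
      seqs <- vapply(seq_len(n_per_family), function(m) {
        hit <- stats::runif(length(anc)) < divergence
        anc[hit] <- sample(AMINO_ACIDS, sum(hit), replace = TRUE,
                           prob = composition)
        paste(anc, collapse = "")
      }, character(1L))
      tibble(id = sprintf("fam%02d_m%02d", f, seq_len(n_per_family)),
             sequence = seqs, family = sprintf("fam%02d", f))
    })
    bind_rows(rows)
  })
}

check_composition <- function(composition) {
  if (is.null(composition)) return(NULL)
  if (!is.numeric(composition) || length(composition) != 20L ||
      any(composition < 0) || abs(sum(composition) - 1) > 1e-8) {
    abort("composition must be 20 nonnegative values summing to 1")
  }
  composition
}
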