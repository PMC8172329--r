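#' Place the 20 amino acids and 400 pairs on a right circular cone
#'
#' Given an ordering of the 20 amino acids (typically ascending in one
#' physicochemical property, see [amino_acid_order()]), the k-th amino acid
#' is placed at angle \eqn{2\pi k/20} on the unit circle of the cone base
#' plane at height 1:
#' \deqn{\phi(\Omega_i) = (\cos(2\pi i/20), \sin(2\pi i/20), 1)}
#' and each ordered pair is placed a quarter of the way along the chord from
#' the first vertex to the second:
#' \deqn{\phi(\Omega_i\Omega_j) = \phi(\Omega_i) + \tfrac14(\phi(\Omega_j) - \phi(\Omega_i)).}
#' A pair of an amino acid with itself coincides with its vertex.
#'
#' @param order Character vector: a permutation of the 20 standard one-letter
#'   codes; element k gets cone index i = k.
#' @return An object of class `cone_embedding`: a list with `vertex` (20 x 3
#'   matrix, row names the codes) and `pair` (400 x 3 matrix, row names the
#'   two-letter pairs).
#' @examples
#' cone <- cone_embedding(sort(c("A","C","D","E","F","G","H","I","K","L",
#'                               "M","N","P","Q","R","S","T","V","W","Y")))
#' cone$vertex["Y", ]  # last in order -> angle 2*pi -> (1, 0, 1)
#' @export
cone_embedding <- function(order) {
  if (!is.character(order) || length(order) != 20L ||
      !setequal(order, AMINO_ACIDS) || anyDuplicated(order)) {
    abort("order must be a permutation of the 20 standard amino-acid codes")
  }
  i <- seq_len(20L)
  vertex <- cbind(x = cos(2 * pi * i / 20), y = sin(2 * pi * i / 20), z = 1)
  rownames(vertex) <- order

  first <- rep(seq_len(20L), each = 20L)
  second <- rep(seq_len(20L), times = 20L)
  pair <- vertex[first, , drop = FALSE] +
    (vertex[second, , drop = FALSE] - vertex[first, , drop = FALSE]) / 4
  rownames(pair) <- paste0(order[first], order[second])

  structure(list(vertex = vertex, pair = pair), class = "cone_embedding")
}

#' Extend the 3D graphical curve of a protein sequence
#'
#' Starting from the origin, the path point for residue i is
#' \deqn{\psi(S_i) = \psi(S_{i-1}) + \phi(s_i) +
#'   \sum_{\Omega_1\Omega_2} f_{\Omega_1\Omega_2}\,\phi(\Omega_1\Omega_2)}
#' where the sum runs over the 400 amino-acid pairs and
#' \eqn{f_{\Omega_1\Omega_2}} is the frequency of the pair among the
#' overlapping adjacent dipeptides of the prefix \eqn{s_1 \ldots s_i}.
#' `freq = "count"` uses raw occurrence counts (the default; the z-coordinate
#' then satisfies \eqn{z_i = i(i+1)/2} exactly); `freq = "relative"` divides
#' the counts by the number of windows \eqn{i - 1}.
#'
#' The naive sum over 400 pairs collapses to a running cumulative sum of the
#' mapped points of the dipeptides actually seen, so construction is O(N).
#'
#' @param sequence A single string over the 20 standard one-letter codes.
#' @param cone A [cone_embedding()].
#' @param freq Dipeptide frequency convention, `"count"` or `"relative"`.
#' @return An N x 3 matrix of path points (the implicit origin P0 is not a
#'   row), with attribute `sequence_length`.
#' @examples
#' cone <- cone_embedding(amino_acid_order(synthetic_properties(1)[1, ]))
#' protein_path("ACDKLM", cone)
#' @export
protein_path <- function(sequence, cone, freq = c("count", "relative")) {
  freq <- match.arg(freq)
  if (!inherits(cone, "cone_embedding")) abort("cone must be a cone_embedding")
  res <- sequence_residues(sequence)
  n <- length(res)

  steps <- cone$vertex[res, , drop = FALSE]          # phi(s_i) term, N x 3
  if (n >= 2L) {
    pair_ids <- paste0(res[-n], res[-1L])            # dipeptide entering at step i
    pair_pts <- cone$pair[pair_ids, , drop = FALSE]  # (N-1) x 3
    # cumulative count-weighted sum of mapped dipeptide points at each step
    cum_pairs <- apply(pair_pts, 2L, cumsum)
    if (n == 2L) cum_pairs <- matrix(cum_pairs, nrow = 1L)
    if (freq == "relative") cum_pairs <- cum_pairs / (seq_len(n - 1L))
    steps[-1L, ] <- steps[-1L, , drop = FALSE] + cum_pairs
  }
  path <- apply(steps, 2L, cumsum)
  if (n == 1L) path <- matrix(path, nrow = 1L)
  colnames(path) <- c("x", "y", "z")
  attr(path, "sequence_length") <- n
  path
}

#' Line/length (L/L) matrix of a graphical curve
#'
#' The (i, j) entry is the Euclidean (straight-line) distance between curve
#' points \eqn{P_i} and \eqn{P_j} divided by the arc length along the curve
#' between them (the sum of the edge lengths \eqn{|P_{k+1} - P_k|} for
#' \eqn{k = i, \ldots, j-1}). The matrix is symmetric and nonnegative with a
#' zero diagonal; off-diagonal entries lie in (0, 1] because a chord never
#' exceeds the path connecting its endpoints, and consecutive entries equal 1
#' exactly. The origin anchor P0 is not part of the curve and contributes no
#' row.
#'
#' @param path An N x 3 path matrix from [protein_path()], N >= 2.
#' @return An N x N numeric matrix.
#' @export
ll_matrix <- function(path) {
  if (!is.matrix(path) || ncol(path) != 3L) abort("path must be an N x 3 matrix")
  n <- nrow(path)
  if (n < 2L) abort("L/L matrix requires at least 2 path points")
  chord <- as.matrix(dist(path))
  edge <- sqrt(rowSums((path[-1L, , drop = FALSE] - path[-n, , drop = FALSE])^2))
  cum <- c(0, cumsum(edge))
  arc <- abs(outer(cum, cum, "-"))
  m <- chord / arc
  diag(m) <- 0
  dimnames(m) <- NULL
  m
}

#' Leading eigenvalue of a symmetric matrix
#'
#' Largest eigenvalue, computed with a dense symmetric eigensolver. For the
#' nonnegative symmetric L/L matrix this equals the spectral radius and lies
#' between the largest diagonal entry and the largest row sum (Perron
#' bounds).
#'
#' @param m A symmetric numeric matrix.
#' @return The largest eigenvalue (scalar).
#' @examples
#' leading_eigenvalue(matrix(c(0, 1, 1, 0), 2))  # 1
#' @export
leading_eigenvalue <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) abort("m must be square")
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m)))) {
    abort("m must be symmetric")
  }
  eigen(m, symmetric = TRUE, only.values = TRUE)$values[1L]
}

#' Graphical feature vector of one sequence
#'
#' For each property index: order the amino acids by ascending value, build
#' the cone, extend the 3D curve, form the L/L matrix, take its leading
#' eigenvalue, and normalize by the sequence length N to remove length bias.
#' The result is one number per property; with the full curated 158-property
#' configuration this is the 158-dimensional graphical block of the final
#' descriptor.
#'
#' @param sequence A single string over the 20 standard codes, length >= 2.
#' @param properties A property tibble ([read_aaindex()],
#'   [synthetic_properties()]).
#' @inheritParams protein_path
#' @return Named numeric vector, one entry per property accession.
#' @export
graphical_features <- function(sequence, properties,
                               freq = c("count", "relative")) {
  freq <- match.arg(freq)
  check_property_table(properties)
  res <- sequence_residues(sequence)
  n <- length(res)
  if (n < 2L) abort("graphical features require sequence length >= 2")
  vals <- as.matrix(properties[, AMINO_ACIDS])
  out <- vapply(seq_len(nrow(properties)), function(p) {
    ord <- amino_acid_order(stats::setNames(vals[p, ], AMINO_ACIDS))
    cone <- cone_embedding(ord)
    leading_eigenvalue(ll_matrix(protein_path(sequence, cone, freq))) / n
  }, numeric(1L))
  names(out) <- properties$accession
  out
}

# Split and validate a protein sequence string into residues.
sequence_residues <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence)) {
    abort("sequence must be a single string")
  }
  if (nchar(sequence) == 0L) abort("sequence must be nonempty")
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- which(!res %in% AMINO_ACIDS)
  if (length(bad)) {
    abort(sprintf("non-standard residue '%s' at position %d", res[bad[1L]], bad[1L]))
  }
  res
}
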