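#' Pairwise cosine distance matrix
#'
#' For row vectors x and y, d = 1 - x.y / (|x||y|), in [0, 2]; 0 between
#' positively proportional rows, 2 between antipodal ones. Rows of all zeros
#' have no direction and are rejected by name.
#'
#' @param features A feature tibble (`id` column + numeric columns), e.g.
#'   from [fegs()] or the `scores` of [fegs_pca()], or a plain numeric
#'   matrix with row names.
#' @return A [stats::dist] object labelled by sequence id.
#' @examples
#' m <- rbind(a = c(1, 0), b = c(2, 0), c = c(0, 1))
#' cosine_dist(m)  # a-b distance 0
#' @export
cosine_dist <- function(features) {
  x <- if (is.matrix(features)) features else feature_matrix(features)
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  norms <- sqrt(rowSums(x^2))
  zero <- which(norms == 0)
  if (length(zero)) {
    abort(paste0("all-zero feature row(s): ",
                 paste(rownames(x)[zero], collapse = ", ")))
  }
  sim <- tcrossprod(x / norms)
  d <- 1 - sim
  d[d < 0] <- 0          # guard rounding below 0 for identical directions
  diag(d) <- 0
  as.dist(d)
}

#' Agglomerative tree under single or complete linkage
#'
#' Standard agglomerative clustering on a distance matrix: at every step the
#' two clusters at minimal inter-cluster distance are merged, where the
#' inter-cluster distance is the minimum (single linkage) or maximum
#' (complete linkage) over cross-cluster pairs. Both linkages are monotone,
#' so merge heights never decrease.
#'
#' @param d A [stats::dist] object (e.g. from [cosine_dist()]).
#' @param method `"single"` or `"complete"`.
#' @return An object of class `fegs_tree` wrapping the [stats::hclust]
#'   result; supports [tidy()], [cut_tree()], [to_newick()] and `plot()`.
#' @export
linkage_tree <- function(d, method = c("single", "complete")) {
  method <- match.arg(method)
  if (!inherits(d, "dist")) abort("d must be a stats::dist object")
  if (attr(d, "Size") < 2L) abort("need at least 2 observations")
  h <- hclust(d, method = method)
  structure(list(hclust = h, method = method), class = "fegs_tree")
}

#' @export
print.fegs_tree <- function(x, ...) {
  cat(sprintf("<fegs_tree> %s linkage, %d leaves\n",
              x$method, length(x$hclust$labels %||% x$hclust$order)))
  invisible(x)
}

#' @export
plot.fegs_tree <- function(x, ...) {
  plot(ape::as.phylo(x$hclust), ...)
}

#' Merge table of an agglomerative tree
#'
#' @param x A `fegs_tree`.
#' @param ... Unused.
#' @return A tibble with one row per merge, in merge order: `step`,
#'   `height`, and the standard hclust child encoding (`left`, `right`:
#'   negative = leaf index, positive = earlier merge step).
#' @method tidy fegs_tree
#' @export
tidy.fegs_tree <- function(x, ...) {
  h <- x$hclust
  tibble(
    step = seq_len(nrow(h$merge)),
    height = h$height,
    left = h$merge[, 1L],
    right = h$merge[, 2L]
  )
}

#' Export a tree as a Newick string
#'
#' Branch lengths are derived from the ultrametric merge heights (each child
#' branch spans parent height minus child height; leaves sit at height 0),
#' then halved so leaf-to-leaf path length equals the merge height, the
#' usual dendrogram-to-phylogram convention. Labels containing Newick
#' metacharacters are quoted by the writer.
#'
#' @param tree A `fegs_tree`.
#' @param path Optional file path; when given the string is also written
#'   there.
#' @return The Newick string (invisibly if `path` is given).
#' @export
to_newick <- function(tree, path = NULL) {
  if (!inherits(tree, "fegs_tree")) abort("tree must be a fegs_tree")
  phy <- ape::as.phylo(tree$hclust)
  s <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Cut a tree into k flat clusters
#'
#' Undoes the last k - 1 merges of the agglomeration, yielding exactly k
#' non-empty clusters.
#'
#' @param tree A `fegs_tree`.
#' @param k Number of clusters, between 1 and the number of leaves.
#' @return A tibble with columns `id` and `cluster` (integer labels 1..k).
#' @export
cut_tree <- function(tree, k) {
  if (!inherits(tree, "fegs_tree")) abort("tree must be a fegs_tree")
  n <- length(tree$hclust$order)
  if (!is.numeric(k) || length(k) != 1L || k < 1L || k > n) {
    abort(sprintf("k must be in [1, %d]", n))
  }
  cl <- cutree(tree$hclust, k = k)
  tibble(id = names(cl) %||% as.character(seq_along(cl)),
         cluster = as.integer(cl))
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected pair-counting agreement (Hubert-Arabie): 1 for identical
#' partitions up to label renaming, about 0 for independent random
#' partitions, negative for less-than-chance agreement. Both arguments may
#' be label vectors (named or aligned by position) or `id`/`cluster` tibbles
#' as returned by [cut_tree()] or [read_labels()]; tibbles are matched by
#' `id` and must cover the same id set.
#'
#' @param p1,p2 Partitions to compare.
#' @return The ARI (scalar).
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b"))  # 1
#' @export
adjusted_rand_index <- function(p1, p2) {
  a <- partition_labels(p1)
  b <- partition_labels(p2)
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) {
      abort("partitions cover different id sets")
    }
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    abort("partitions have different sizes and no ids to match on")
  }
  mclust::adjustedRandIndex(a, b)
}

partition_labels <- function(p) {
  if (is.data.frame(p)) {
    if (!all(c("id", "cluster") %in% names(p))) {
      abort("partition data frames need 'id' and 'cluster' columns")
    }
    if (anyDuplicated(p$id)) abort("duplicate ids in partition")
    return(stats::setNames(as.character(p$cluster), p$id))
  }
  out <- as.character(p)
  names(out) <- names(p)
  out
}

#' Read a two-column taxonomic label file
#'
#' Whitespace-delimited text, one `id label` pair per line; `#` comments and
#' blank lines ignored.
#'
#' @param path File path.
#' @return A tibble with columns `id` and `cluster`.
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, header = FALSE, col.names = c("id", "cluster"),
                          colClasses = "character", comment.char = "#")
  if (anyDuplicated(df$id)) abort("duplicate ids in label file")
  as_tibble(df)
}
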