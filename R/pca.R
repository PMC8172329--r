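#' Principal-component reduction of a feature table
#'
#' Column-centers the feature matrix (optionally unit-variance scales it) and
#' projects onto the top principal components. Components are ordered by
#' decreasing explained variance; each component's sign is fixed so that its
#' largest-magnitude loading is positive, making scores reproducible across
#' platforms. When `n_components` is omitted, the smallest number of
#' components whose cumulative explained variance reaches `var_target` is
#' used.
#'
#' @param features Feature tibble from [fegs()] (column `id` + numeric
#'   columns).
#' @param n_components Number of components to keep; at most
#'   `min(N - 1, n_features)`. Default: smallest count reaching `var_target`.
#' @param var_target Cumulative explained-variance target in (0, 1] used when
#'   `n_components` is `NULL`. Default 0.95.
#' @param scale Unit-variance scale columns before projection (constant
#'   columns are left unscaled). Default `FALSE` (centering only).
#' @return An object of class `fegs_pca` with elements `scores` (tibble:
#'   `id`, `PC1`, ...), `sdev`, `rotation`, `center`, `n_components`,
#'   `prop_variance`. Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' seqs <- simulate_proteins(10, length_range = c(30, 40), seed = 3)
#' red <- fegs_pca(fegs(seqs, synthetic_properties(5, seed = 1)), n_components = 2)
#' glance(red)
#' @export
fegs_pca <- function(features, n_components = NULL, var_target = 0.95,
                     scale = FALSE) {
  x <- feature_matrix(features)
  max_comp <- min(nrow(x) - 1L, ncol(x))
  if (max_comp < 1L) abort("need at least 2 rows for PCA")
  const <- apply(x, 2L, function(v) stats::sd(v) == 0)
  scale_arg <- if (scale) !const else FALSE
  p <- prcomp(x, center = TRUE, scale. = scale_arg)

  var_prop <- p$sdev^2 / sum(p$sdev^2)
  if (is.null(n_components)) {
    if (!is.numeric(var_target) || var_target <= 0 || var_target > 1) {
      abort("var_target must be in (0, 1]")
    }
    n_components <- which(cumsum(var_prop) >= var_target - 1e-12)[1L]
    n_components <- min(n_components, max_comp)
  }
  if (n_components < 1L || n_components > max_comp) {
    abort(sprintf("n_components must be in [1, %d]", max_comp))
  }

  keep <- seq_len(n_components)
  rot <- p$rotation[, keep, drop = FALSE]
  # deterministic sign: largest-|loading| entry of each component positive
  flip <- vapply(keep, function(j) {
    v <- rot[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1L))
  flip[flip == 0] <- 1
  rot <- sweep(rot, 2L, flip, `*`)
  scores <- sweep(p$x[, keep, drop = FALSE], 2L, flip, `*`)

  structure(list(
    scores = dplyr::bind_cols(tibble(id = rownames(x)), as_tibble(scores)),
    sdev = p$sdev,
    rotation = rot,
    center = p$center,
    scale = p$scale,
    n_components = n_components,
    prop_variance = var_prop
  ), class = "fegs_pca")
}

#' @export
print.fegs_pca <- function(x, ...) {
  cat(sprintf(
    "<fegs_pca> %d sequences, %d component(s), %.1f%% variance explained\n",
    nrow(x$scores), x$n_components,
    100 * sum(x$prop_variance[seq_len(x$n_components)])))
  invisible(x)
}

#' Tidy per-component summary of a PCA reduction
#'
#' @param x A `fegs_pca` object.
#' @param ... Unused.
#' @return A tibble with one row per retained component: `component`,
#'   `std_dev`, `prop_variance`, `cum_variance`.
#' @method tidy fegs_pca
#' @export
tidy.fegs_pca <- function(x, ...) {
  k <- seq_len(x$n_components)
  tibble(
    component = k,
    std_dev = x$sdev[k],
    prop_variance = x$prop_variance[k],
    cum_variance = cumsum(x$prop_variance)[k]
  )
}

#' One-row summary of a PCA reduction
#'
#' @inheritParams tidy.fegs_pca
#' @return A one-row tibble: `n_sequences`, `n_components`,
#'   `variance_explained`.
#' @method glance fegs_pca
#' @export
glance.fegs_pca <- function(x, ...) {
  tibble(
    n_sequences = nrow(x$scores),
    n_components = x$n_components,
    variance_explained = sum(x$prop_variance[seq_len(x$n_components)])
  )
}

#' Score plot of a PCA reduction
#'
#' Scatter of the sequences on two principal components, axis labels
#' annotated with percent variance explained.
#'
#' @param object A `fegs_pca` object.
#' @param components Length-2 integer vector of components to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fegs_pca
#' @export
autoplot.fegs_pca <- function(object, components = c(1L, 2L), ...) {
  if (object$n_components < 2L) abort("score plot needs at least 2 components")
  cols <- paste0("PC", components)
  lab <- sprintf("%s (%.1f%%)", cols, 100 * object$prop_variance[components])
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data[[cols[1L]]], y = .data[[cols[2L]]])) +
    ggplot2::geom_point() +
    ggplot2::labs(x = lab[1L], y = lab[2L]) +
    ggplot2::theme_minimal()
}
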