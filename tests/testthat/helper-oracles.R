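# Independent brute-force oracles used to check the fast implementations.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

fixture_aaindex <- function() {
  system.file("extdata", "aaindex_synthetic.txt", package = "fegs")
}

fixture_properties <- function() {
  fegs::dedupe_properties(fegs::read_aaindex(fixture_aaindex(), quiet = TRUE))
}

random_sequence <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# Path recursion evaluated literally: at every step sum the frequency-weighted
# mapped points over all 400 dipeptides of the prefix.
slow_path <- function(sequence, cone, freq = "count") {
  res <- strsplit(sequence, "")[[1]]
  n <- length(res)
  prev <- c(0, 0, 0)
  out <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    pair_term <- c(0, 0, 0)
    if (i >= 2) {
      prefix_pairs <- paste0(res[1:(i - 1)], res[2:i])
      for (pp in rownames(cone$pair)) {
        f <- sum(prefix_pairs == pp)
        if (freq == "relative") f <- f / (i - 1)
        pair_term <- pair_term + f * cone$pair[pp, ]
      }
    }
    prev <- prev + cone$vertex[res[i], ] + pair_term
    out[i, ] <- prev
  }
  out
}

# L/L matrix recomputed pair by pair from definitions.
slow_ll <- function(path) {
  n <- nrow(path)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- min(i, j); b <- max(i, j)
    chord <- sqrt(sum((path[i, ] - path[j, ])^2))
    arc <- 0
    for (k in a:(b - 1)) arc <- arc + sqrt(sum((path[k + 1, ] - path[k, ])^2))
    m[i, j] <- chord / arc
  }
  m
}

# Power iteration: independent route to the largest eigenvalue of a
# nonnegative symmetric matrix.
power_eigenvalue <- function(m, iters = 10000, tol = 1e-13) {
  v <- rep(1, nrow(m)) / sqrt(nrow(m))
  lam <- 0
  for (i in seq_len(iters)) {
    w <- m %*% v
    lam_new <- sqrt(sum(w^2))
    v <- as.vector(w) / lam_new
    if (abs(lam_new - lam) < tol * max(1, abs(lam_new))) break
    lam <- lam_new
  }
  as.numeric(t(v) %*% m %*% v)
}

slow_cosine <- function(x) {
  n <- nrow(x)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- 1 - sum(x[i, ] * x[j, ]) /
      (sqrt(sum(x[i, ]^2)) * sqrt(sum(x[j, ]^2)))
  }
  diag(d) <- 0
  d
}

# O(N^3) agglomeration over an explicit cluster list; returns merge heights
# in merge order.
slow_linkage_heights <- function(d, method) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  link <- if (method == "single") min else max
  while (length(clusters) > 1) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      cd <- link(d[clusters[[i]], clusters[[j]]])
      if (cd < best) { best <- cd; bi <- i; bj <- j }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# Hubert-Arabie ARI from the pair-count contingency table.
slow_ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  index <- sum_comb(tab)
  row_c <- sum_comb(rowSums(tab))
  col_c <- sum_comb(colSums(tab))
  expected <- row_c * col_c / choose(n, 2)
  maxi <- (row_c + col_c) / 2
  (index - expected) / (maxi - expected)
}
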