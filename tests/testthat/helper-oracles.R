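# Independent brute-force oracles and fixture builders.  These stay
# deliberately naive (loops, enumeration, closed forms) so they cannot
# share a bug with the implementation paths they check.

# step-up BH by direct formula: padj_(i) = min_{j >= i} m * p_(j) / j
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[i] <- min(1, min(m * ps[i:m] / (i:m)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# TOM by triple loop
tom_oracle <- function(A) {
  p <- nrow(A)
  k <- rowSums(A) - diag(A)
  out <- diag(p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) next
    s <- 0
    for (u in seq_len(p)) if (u != i && u != j) s <- s + A[i, u] * A[u, j]
    out[i, j] <- (s + A[i, j]) / (min(k[i], k[j]) + 1 - A[i, j])
  }
  out
}

# shortest path by exhaustive simple-path enumeration on a small
# weighted edge list (from/to/weight data.frame, undirected)
path_oracle <- function(edges, nodes, from, to) {
  best <- Inf
  walk <- function(cur, seen, d) {
    if (cur == to) { best <<- min(best, d); return() }
    hit <- edges[edges$from == cur | edges$to == cur, , drop = FALSE]
    for (r in seq_len(nrow(hit))) {
      nxt <- if (hit$from[r] == cur) hit$to[r] else hit$from[r]
      if (nxt %in% seen) next
      walk(nxt, c(seen, nxt), d + hit$weight[r])
    }
  }
  walk(from, from, 0)
  best
}

# adjusted Rand index
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

# rows with EXACTLY the requested sample correlation matrix: build
# orthonormal columns perpendicular to the intercept, mix by chol(C)
expr_with_cor <- function(C, n, seed = 1) {
  set.seed(seed)
  p <- nrow(C)
  stopifnot(n > p + 1)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(n * p), n, p))))[, -1, drop = FALSE]
  X <- chol(C) |> t() |> (\(L) L %*% t(Q))()
  rownames(X) <- sprintf("F%02d", seq_len(p))
  X
}

exact_cor_pair <- function(r, n = 30, seed = 1) {
  X <- expr_with_cor(matrix(c(1, r, r, 1), 2), n, seed)
  list(x = X[1, ], y = X[2, ])
}

# two-block Gaussian expression fixture with planted factor structure
two_block_expr <- function(n_per = 40, n_samples = 60, within = 0.8,
                           seed = 1) {
  set.seed(seed)
  f1 <- rnorm(n_samples); f2 <- rnorm(n_samples)
  l <- sqrt(within)
  X <- rbind(
    l * matrix(f1, n_per, n_samples, byrow = TRUE),
    l * matrix(f2, n_per, n_samples, byrow = TRUE)) +
    sqrt(1 - within) * matrix(rnorm(2 * n_per * n_samples),
                              2 * n_per, n_samples)
  rownames(X) <- sprintf("B%03d", seq_len(2 * n_per))
  colnames(X) <- sprintf("S%03d", seq_len(n_samples))
  attr(X, "truth") <- rep(1:2, each = n_per)
  X
}

# small sample table with explicit censoring fields
tiny_samples <- function() {
  cov <- data.frame(
    sample_id = c("a", "b", "c", "d"),
    fetal_sex = c(0L, 1L, 0L, 1L),
    gestational_age = c(38, 39, 40, 39.5),
    birth_weight = c(3000, 3200, 2900, 3100),
    spontaneous_labor = c(TRUE, FALSE, TRUE, TRUE))
  ex <- data.frame(
    sample_id = rep(c("a", "b", "c", "d"), each = 2),
    compound = "PFX",
    source = rep(c("maternal", "fetal"), 4),
    value = c(3.2, 6.4, 2.0, 4.0, NA, 1.0, 1.5, NA),
    censor = c("quantified", "quantified", "quantified", "quantified",
               "below_lod", "quantified", "quantified", "below_loq"),
    lod = 1.0, loq = 0.8)
  sample_table(cov, ex)
}

# minimal expression study around tiny_samples()
tiny_study <- function(n_feat = 12, seed = 1) {
  set.seed(seed)
  counts <- matrix(rnbinom(n_feat * 4, mu = 50, size = 5), n_feat, 4,
                   dimnames = list(sprintf("T%03d", seq_len(n_feat)),
                                   c("a", "b", "c", "d")))
  tx2gene <- data.frame(
    transcript_id = rownames(counts),
    gene_id = sprintf("G%03d", rep(seq_len(ceiling(n_feat / 2)),
                                   each = 2))[seq_len(n_feat)])
  expression_study(counts, tx2gene, tiny_samples())
}
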