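test_that("network prefilter applies detection and variance rules", {
  set.seed(2)
  n <- 20
  counts <- rbind(
    sparse = c(rpois(2, 50), rep(0L, n - 2)),        # 10% detected
    flat   = rep(7L, n),                             # zero variance
    matrix(rnbinom(100 * n, mu = 60, size = 2), 100, n))
  rownames(counts)[3:102] <- sprintf("V%03d", 1:100)
  colnames(counts) <- sprintf("S%02d", 1:n)
  cov <- data.frame(sample_id = colnames(counts), fetal_sex = 0L,
                    gestational_age = 39, birth_weight = 3000,
                    spontaneous_labor = TRUE)
  ex <- data.frame(sample_id = colnames(counts)[1], compound = "PFX",
                   source = "maternal", value = 1,
                   censor = "quantified", lod = NA_real_,
                   loq = NA_real_)
  st <- expression_study(counts,
                         data.frame(transcript_id = rownames(counts),
                                    gene_id = rownames(counts)),
                         sample_table(cov, ex))
  expr <- prefilter_and_normalize(st, min_features = 10)
  expect_false("sparse" %in% rownames(expr))
  expect_false("flat" %in% rownames(expr))
  # brute-force filter reproduction
  keep <- rowMeans(counts > 0) >= 0.2
  v <- apply(vst_counts(counts[keep, ]), 1, var)
  expect_identical(rownames(expr), names(v)[v > quantile(v, 0.1)])
  expect_error(prefilter_and_normalize(st, min_features = 500),
               "survive")
})

test_that("latent-factor removal strips batch but protects exposures", {
  set.seed(8)
  n <- 80; p <- 150
  x <- rnorm(n)                              # exposure to protect
  batch <- rnorm(n)                          # orthogonal technical factor
  batch <- residuals(lm(batch ~ x))
  bx <- rnorm(p); bb <- rnorm(p)
  expr <- outer(bx, x) + outer(bb, batch) +
    matrix(rnorm(p * n, 0, 0.6), p, n)
  rownames(expr) <- sprintf("F%03d", 1:p)
  out <- remove_latent_factor(expr, cbind(x))
  r2_batch <- apply(out, 1, function(v) cor(v, batch)^2)
  expect_lt(median(r2_batch), 0.05)
  # the exposure effect itself is untouched: per-feature slopes on x
  # agree exactly before and after
  slope <- function(M) apply(M, 1, function(v) coef(lm(v ~ x))[2])
  expect_equal(slope(out), slope(expr), tolerance = 1e-6)
  # without a planted factor the data are left essentially unchanged
  expr2 <- outer(bx, x) + matrix(rnorm(p * n, 0, 0.6), p, n)
  out2 <- remove_latent_factor(expr2, cbind(x))
  r2_change <- 1 - apply(out2 - expr2, 1, var) / apply(expr2, 1, var)
  expect_lt(median(apply(out2 - expr2, 1, var) /
                     apply(expr2, 1, var)), 0.02)
})

test_that("signed adjacency hits its closed-form values", {
  # rows with exact pairwise correlations 1, -1, 0
  X <- expr_with_cor(diag(3), 12, seed = 3)
  dup <- rbind(a = X[1, ], b = X[1, ], c = -X[1, ], d = X[2, ])
  adj <- signed_adjacency(dup, 3)
  expect_equal(adj["a", "b"], 1)
  expect_equal(adj["a", "c"], 0)
  expect_equal(adj["a", "d"], 0.125)       # cor 0 -> (1/2)^3
  expect_true(all(adj >= 0 & adj <= 1))
  expect_equal(adj, t(adj))
})

test_that("TOM matches hand values and the triple-loop oracle", {
  # 3-node graph with all off-diagonal adjacency 0.5
  A3 <- matrix(0.5, 3, 3); diag(A3) <- 1
  expect_equal(tom_similarity(A3)[1, 2], 0.5)
  # isolated pair with unit adjacency
  A2 <- diag(4); A2[1, 2] <- A2[2, 1] <- 1
  expect_equal(tom_similarity(A2)[1, 2], 1)
  # random fixtures up to 50 nodes against the oracle
  set.seed(6)
  for (p in c(6, 17, 50)) {
    C <- cor(matrix(rnorm(p * 40), 40, p))
    A <- ((1 + C) / 2)^4; diag(A) <- 1
    tom <- tom_similarity(A)
    expect_equal(tom, tom_oracle(A), tolerance = 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_equal(tom, t(tom))
  }
})

test_that("soft powers come from the scale-free fit rule", {
  # single-module fixture with a heavy-tailed loading spectrum gives an
  # approximately scale-free connectivity distribution; the first three
  # powers passing fit >= 0.8 were recorded at fixture creation as
  # 5, 6, 7
  set.seed(44)
  n <- 80; p <- 120
  l <- rbeta(p, 1, 2.5)
  X <- outer(l, rnorm(n)) +
    sqrt(1 - l^2) * matrix(rnorm(p * n), p, n)
  rownames(X) <- sprintf("H%03d", 1:p)
  sel <- pick_soft_powers(X, candidates = 1:12, rsq_cut = 0.8)
  expect_equal(as.numeric(sel), c(5, 6, 7))
  fits <- attr(sel, "fits")
  expect_identical(as.numeric(sel),
                   as.numeric(fits$power[fits$fit >= 0.8][1:3]))
  # pure noise never approximates scale-free topology
  set.seed(10)
  noise <- matrix(rnorm(80 * 40), 80, 40)
  rownames(noise) <- sprintf("N%02d", 1:80)
  expect_error(pick_soft_powers(noise, candidates = 1:6,
                                rsq_cut = 0.99),
               "no candidate")
})

test_that("two planted blocks are recovered as exactly two modules", {
  X <- two_block_expr(n_per = 40, n_samples = 60, within = 0.8, seed = 1)
  adj <- signed_adjacency(X, 3)
  asg <- cluster_modules(1 - tom_similarity(adj), X,
                         list(power = 3, min_module_size = 30,
                              deep_split = 3, merge_cut_height = 0.20))
  labs <- asg$labels
  expect_equal(max(labs), 2)
  expect_gt(ari(attr(X, "truth"), labs), 0.95)
  # kME bounded, eigengenes unit norm, sign-aligned
  expect_true(all(abs(asg$kme) <= 1 + 1e-8))
  expect_equal(unname(rowSums(asg$eigengenes^2)), c(1, 1))
  for (k in 1:2)
    expect_gt(mean(asg$kme[labs == k, paste0("ME", k)]), 0)
})

test_that("correlated modules merge at the configured cut height", {
  # two blocks whose factors correlate ~0.8 -> eigengene cor ~0.8
  set.seed(12)
  n <- 60
  f1 <- rnorm(n); f2 <- 0.8 * f1 + sqrt(1 - 0.64) * rnorm(n)
  X <- rbind(outer(rep(0.9, 40), f1), outer(rep(0.9, 40), f2)) +
    matrix(rnorm(80 * n, 0, 0.4), 80, n)
  rownames(X) <- sprintf("M%03d", 1:80)
  colnames(X) <- sprintf("S%03d", 1:n)
  diss <- 1 - tom_similarity(signed_adjacency(X, 3))
  merged <- cluster_modules(diss, X,
                            list(power = 3, min_module_size = 30,
                                 deep_split = 3,
                                 merge_cut_height = 0.30))
  apart <- cluster_modules(diss, X,
                           list(power = 3, min_module_size = 30,
                                deep_split = 3,
                                merge_cut_height = 0.05))
  expect_equal(max(merged$labels), 1)
  expect_equal(max(apart$labels), 2)
})

test_that("deeper split levels cannot decrease the module count", {
  g <- suppressWarnings(generate_study(
    simulation_design(n_transcripts = 500, n_modules = 5,
                      outcome_modules = list(birth_weight = 1L,
                                             gestational_age = 2L),
                      batch_effect_range = c(0, 0),
                      seed = 14)))
  expr <- prefilter_and_normalize(filter_low_counts(g$study))
  diss <- 1 - tom_similarity(signed_adjacency(expr, 3))
  counts <- vapply(c(2, 3, 4), function(ds) {
    asg <- suppressWarnings(cluster_modules(
      diss, expr, list(power = 3, min_module_size = 30,
                       deep_split = ds, merge_cut_height = 0.15)))
    max(asg$labels)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("the eigengene is the leading variance direction", {
  X <- two_block_expr(n_per = 25, n_samples = 40, seed = 21)
  members <- 1:25
  e <- tptenet:::module_eigengene(X, members)
  Xs <- t(scale(t(X[members, ])))
  lead <- svd(Xs)$d[1]^2
  expect_equal(sum((Xs %*% e)^2), lead, tolerance = 1e-8)
  set.seed(3)
  for (i in 1:10) {
    v <- rnorm(40); v <- v / sqrt(sum(v^2))
    expect_lte(sum((Xs %*% v)^2), lead + 1e-8)
  }
})

test_that("the sweep covers the grid and pools top-kME hubs", {
  expect_equal(nrow(network_params_grid(c(3, 4, 5))), 144)
  expect_equal(nrow(network_params_grid(5, 30, 2, 0.15)), 1)
  X <- two_block_expr(n_per = 20, n_samples = 50, within = 0.8, seed = 9)
  grid <- network_params_grid(c(2, 3), min_module_size = 15,
                              deep_split = c(2, 3),
                              merge_cut_height = 0.2)
  sw <- run_sweep(X, grid, n_hubs = 10)
  expect_length(sw$assignments, 4)
  expect_true(all(sw$hubs %in% rownames(X)))
  # a module smaller than n_hubs contributes all its members
  asg <- sw$assignments[[1]]
  expect_identical(sort(module_hubs(asg, n_hubs = 100)),
                   sort(names(asg$labels)[asg$labels > 0]))
  # single-point grid
  sw1 <- run_sweep(X, network_params_grid(3, 15, 2, 0.2))
  expect_length(sw1$assignments, 1)
})
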