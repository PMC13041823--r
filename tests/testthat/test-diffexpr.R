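# shared small study with planted differential expression
de_fixture <- local({
  d <- simulation_design(n_transcripts = 600, n_modules = 4,
                         outcome_modules = list(birth_weight = 1L,
                                                gestational_age = 2L),
                         batch_effect_range = c(0, 0),
                         de = list(n_fetal = 10, n_maternal = 10,
                                   log2fc = 1.5),
                         seed = 42)
  g <- suppressWarnings(generate_study(d))
  study <- g$study
  study$samples <- impute_censored(study$samples)
  list(study = filter_low_counts(study), truth = g$truth, design = d)
})

de_exposure <- function(compound, source) {
  ex <- de_fixture$study$samples$exposures
  ex <- ex[ex$compound == compound & ex$source == source, ]
  setNames(zscore(log(ex$value)), ex$sample_id)
}

de_covariates <- function(ids) {
  cv <- de_fixture$study$samples$covariates
  cv <- cv[match(ids, cv$sample_id), ]
  cbind(sex = cv$fetal_sex, ga_z = zscore(cv$gestational_age))
}

test_that("BH adjustment equals the step-up formula", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(0.37), 0.37)        # m = 1
  set.seed(9)
  for (i in 1:5) {
    p <- runif(50)^2
    expect_equal(benjamini_hochberg(p), bh_oracle(p), tolerance = 1e-12)
  }
  # order invariance
  p <- runif(40)
  ord <- sample(40)
  expect_equal(benjamini_hochberg(p)[ord], benjamini_hochberg(p[ord]))
  # NAs excluded from the family
  p2 <- c(0.01, NA, 0.04)
  out <- benjamini_hochberg(p2)
  expect_true(is.na(out[2]))
  expect_equal(out[c(1, 3)], bh_oracle(c(0.01, 0.04)))
})

# pure-NB study (no latent factor structure) isolating the GLM engine
nb_fixture <- local({
  d <- simulation_design(n_transcripts = 700, n_modules = 2,
                         outcome_modules = list(birth_weight = 1L,
                                                gestational_age = 2L),
                         sigma_bio = 1e-6, sigma_flat = 1e-6,
                         sex_effect = 0, dispersion = 0.2,
                         batch_effect_range = c(0, 0),
                         de = list(n_fetal = 20, n_maternal = 0,
                                   log2fc = 1.5),
                         mediation = simulation_design()$mediation |>
                           modifyList(list(count = list(
                             birth_weight = list(
                               fetal = c(base = 0, slope = 0),
                               maternal = c(base = 0, slope = 0)),
                             gestational_age = list(
                               fetal = c(base = 0, slope = 0),
                               maternal = c(base = 0, slope = 0))))),
                         seed = 23)
  g <- generate_study(d)
  study <- g$study; study$samples <- impute_censored(study$samples)
  list(study = filter_low_counts(study), truth = g$truth)
})

test_that("NB Wald p-values are calibrated under the null", {
  st <- nb_fixture$study
  ex <- st$samples$exposures
  ex <- ex[ex$compound == "PFOS" & ex$source == "maternal", ]
  x <- setNames(zscore(log(ex$value)), ex$sample_id)
  set.seed(77)
  x_perm <- setNames(sample(x), names(x))   # break any real association
  de <- fit_nb_de(st, x_perm)
  expect_gt(stats::ks.test(de$p[!is.na(de$p)], "punif")$p.value, 0.01)
  expect_lt(sum(de$significant), 4)
})

test_that("planted log2 fold changes are recovered", {
  st <- nb_fixture$study
  ex <- st$samples$exposures
  ex <- ex[ex$compound == "PFBS" & ex$source == "fetal", ]
  x <- setNames(zscore(log(ex$value)), ex$sample_id)
  de <- fit_nb_de(st, x)
  tr <- nb_fixture$truth$de
  tr <- tr[tr$compound == "PFBS" & tr$source == "fetal", ]
  tr <- tr[tr$feature_id %in% de$feature_id, ]
  est <- de$log2fc[match(tr$feature_id, de$feature_id)]
  expect_lt(median(abs(est - tr$log2fc), na.rm = TRUE), 0.25)
  expect_gt(mean(tr$feature_id %in% de$feature_id[de$significant]), 0.6)
  # features meeting both thresholds are flagged, nothing else
  expect_identical(de$significant,
                   !is.na(de$padj) & de$padj < 0.10 & abs(de$log2fc) > 1)
})

test_that("gene aggregation dilutes antagonistic isoform effects", {
  d <- simulation_design(n_transcripts = 300, n_modules = 3,
                         outcome_modules = list(birth_weight = 1L,
                                                gestational_age = 2L),
                         isoform_probs = c(0, 1),      # all 2-isoform
                         antagonism_frac = 1,
                         batch_effect_range = c(0, 0),
                         de = list(n_fetal = 12, n_maternal = 0,
                                   log2fc = 1.5),
                         seed = 19)
  g <- suppressWarnings(generate_study(d))
  study <- g$study; study$samples <- impute_censored(study$samples)
  study <- filter_low_counts(study)
  x <- local({
    ex <- study$samples$exposures
    ex <- ex[ex$compound == "PFBS" & ex$source == "fetal", ]
    setNames(zscore(log(ex$value)), ex$sample_id)
  })
  tr <- g$truth$de[g$truth$de$compound == "PFBS", ]
  # antagonistic pairs cancel in the gene-level truth
  per_gene <- tapply(tr$log2fc,
                     g$truth$features$gene_id[match(tr$feature_id,
                       g$truth$features$feature_id)], sum)
  expect_true(all(abs(per_gene) < 1e-12))
  de_tx <- fit_nb_de(study, x)
  gene <- aggregate_to_gene(study)
  de_gene <- fit_nb_de(gene, x)
  genes <- unique(g$truth$features$gene_id[match(tr$feature_id,
                    g$truth$features$feature_id)])
  genes <- intersect(genes, de_gene$feature_id)
  for (gn in genes) {
    txs <- intersect(
      g$truth$features$feature_id[g$truth$features$gene_id == gn],
      de_tx$feature_id)
    if (length(txs) < 2) next
    expect_lt(abs(de_gene$log2fc[de_gene$feature_id == gn]),
              max(abs(de_tx$log2fc[match(txs, de_tx$feature_id)])))
  }
})

test_that("concordance enrichment matches hand arithmetic", {
  # construct tables realizing the 2x2 table [[10,10],[10,70]]
  n <- 100
  ids <- sprintf("F%03d", 1:n)
  sig_a <- c(rep(TRUE, 20), rep(FALSE, 80))    # explant-significant
  conc <- c(rep(TRUE, 10), rep(FALSE, 10), rep(TRUE, 10), rep(FALSE, 70))
  de_a <- data.frame(feature_id = ids,
                     log2fc = ifelse(sig_a, 2, ifelse(conc, 0.5, 0.2)),
                     p = ifelse(sig_a | conc, 0.01, 0.5))
  de_b <- data.frame(feature_id = ids, log2fc = 1,
                     p = ifelse(conc, 0.01, 0.5))
  out <- concordance_enrichment(de_a, de_b)
  expect_equal(unname(out$table["yes", "yes"]), 10)
  expect_equal(exp(out$log_odds), 7, tolerance = 1e-12)
  expect_equal(out$log_odds, log(7), tolerance = 1e-12)
  expect_equal(out$n_concordant, 20)
  # Fisher p against the hypergeometric oracle (two-sided by
  # probability-ordering, as fisher.test defines it)
  hyper <- dhyper(0:20, 20, 80, 20)
  p_or <- sum(hyper[hyper <= dhyper(10, 20, 80, 20) * (1 + 1e-7)])
  expect_equal(out$fisher_p, p_or, tolerance = 1e-8)
})

test_that("concordance separates real replication from independence", {
  set.seed(5)
  n <- 2000
  ids <- sprintf("F%04d", 1:n)
  de <- data.frame(feature_id = ids,
                   log2fc = rnorm(n, 0, 1.2), p = runif(n)^4)
  self <- concordance_enrichment(de, de)
  # every explant-significant feature is concordant with itself
  expect_equal(self$table["no", "yes"], 0)
  # an unrelated second study: concordance only through the shared
  # p_a < 0.05 margin, far below the self-replication extreme
  de_b <- data.frame(feature_id = ids,
                     log2fc = rnorm(n, 0, 1.2), p = runif(n)^4)
  null <- concordance_enrichment(de, de_b)
  expect_lt(null$log_odds, 0.5 * self$log_odds)
  expect_gt(self$log_odds, 2)
  # gene-level collapsing counts genes with a qualifying transcript
  tx2gene <- data.frame(transcript_id = ids,
                        gene_id = rep(sprintf("G%04d", 1:(n / 2)),
                                      each = 2))
  gcol <- concordance_enrichment(de, de_b, tx2gene = tx2gene)
  expect_equal(sum(gcol$table), n / 2)
})

test_that("cross-source LFC correlation is plain Pearson", {
  de1 <- data.frame(feature_id = letters[1:10], log2fc = rnorm(10),
                    p = 0.5)
  de2 <- de1
  expect_equal(lfc_cross_correlation(de1, de2), 1)
  de2$log2fc <- -de1$log2fc
  expect_equal(lfc_cross_correlation(de1, de2), -1)
  de2$log2fc <- rnorm(10)
  expect_equal(lfc_cross_correlation(de1, de2),
               cor(de1$log2fc, de2$log2fc))
  expect_warning(r <- lfc_cross_correlation(de1[1:2, ], de2[1:2, ]),
                 "fewer than 3")
  expect_true(is.na(r))
})
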