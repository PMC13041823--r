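# Small designs for speed; pool-exhaustion warnings are expected there
# and silenced.
small_design <- function(..., seed = 11) {
  simulation_design(n_samples = 124, n_transcripts = 200, n_modules = 4,
                    outcome_modules = list(birth_weight = 1L,
                                           gestational_age = 2L),
                    seed = seed, ...)
}

test_that("noiseless coupling makes fetal exactly TPTE x maternal", {
  d <- small_design(fetal_coupling = "noiseless",
                    censor_loq_frac = 0, censor_lod_frac = 0)
  expo <- simulate_exposures(d)
  ex <- expo$exposures
  for (cp in d$compounds$compound) {
    m <- ex$value[ex$compound == cp & ex$source == "maternal"]
    f <- ex$value[ex$compound == cp & ex$source == "fetal"]
    tpte <- d$compounds$tpte[d$compounds$compound == cp]
    expect_equal(f, tpte * m, tolerance = 1e-12)
  }
})

test_that("empirical TPTE converges to the design value", {
  d <- simulation_design(n_samples = 500, n_transcripts = 50,
                         n_modules = 2,
                         outcome_modules = list(birth_weight = 1L,
                                                gestational_age = 2L),
                         fetal_coupling = "noiseless",
                         censor_loq_frac = 0, censor_lod_frac = 0,
                         seed = 4)
  expo <- simulate_exposures(d)
  cov <- data.frame(sample_id = rownames(expo$xz$maternal),
                    fetal_sex = 0L, gestational_age = 39,
                    birth_weight = 3000, spontaneous_labor = TRUE)
  st <- impute_censored(sample_table(cov, expo$exposures))
  for (cp in d$compounds$compound)
    expect_equal(compute_tpte(st, cp),
                 d$compounds$tpte[d$compounds$compound == cp],
                 tolerance = 1e-12)
})

test_that("maternal-fetal correlation follows rho(TPTE)", {
  d <- simulation_design(
    n_samples = 500, n_transcripts = 50, n_modules = 2,
    outcome_modules = list(birth_weight = 1L, gestational_age = 2L),
    compounds = data.frame(compound = c("LOW", "HIGH"),
                           tpte = c(0.5, 2.5),
                           chain_length = c(8L, 4L)),
    rho = c(rho_high = 0.9, rho_low = 0),
    censor_loq_frac = 0, censor_lod_frac = 0, seed = 8)
  expo <- simulate_exposures(d)
  r_low <- cor(expo$xz$maternal[, "LOW"], expo$xz$fetal[, "LOW"])
  r_high <- cor(expo$xz$maternal[, "HIGH"], expo$xz$fetal[, "HIGH"])
  expect_lt(abs(r_low - 0.9), 0.08)
  expect_lt(abs(r_high), 0.15)
})

test_that("rho endpoints outside [0, 1] are rejected", {
  expect_error(small_design(rho = c(rho_high = 1.2, rho_low = 0)),
               "\\[0, 1\\]")
})

test_that("censoring flags the configured lower tail", {
  d <- small_design(censor_loq_frac = 0.1, censor_lod_frac = 0.05)
  ex <- simulate_exposures(d)$exposures
  one <- ex[ex$compound == "PFOS" & ex$source == "maternal", ]
  expect_lt(abs(mean(one$censor == "below_lod") - 0.05), 0.02)
  expect_lt(abs(mean(one$censor == "below_loq") - 0.10), 0.03)
  expect_true(all(is.na(one$value[one$censor != "quantified"])))
  expect_true(all(one$lod < one$loq))
})

test_that("generation is deterministic in the design seed", {
  d <- small_design(seed = 21)
  g1 <- suppressWarnings(generate_study(d))
  g2 <- suppressWarnings(generate_study(d))
  expect_identical(g1$study$counts, g2$study$counts)
  expect_identical(g1$truth$mediators, g2$truth$mediators)
  expect_identical(g1$study$samples$covariates,
                   g2$study$samples$covariates)
  g3 <- suppressWarnings(generate_study(small_design(seed = 22)))
  expect_false(identical(g1$study$counts, g3$study$counts))
})

test_that("counts follow the NB mean-variance relation", {
  # flat biology isolates the count-noise layer: across samples each
  # feature is iid NB around its baseline
  d <- simulation_design(
    n_samples = 400, n_transcripts = 150, n_modules = 2,
    outcome_modules = list(birth_weight = 1L, gestational_age = 2L),
    sigma_bio = 1e-6, sigma_flat = 1e-6, sex_effect = 0,
    batch_effect_range = c(0, 0),
    de = list(n_fetal = 0, n_maternal = 0, log2fc = 0),
    mediation = simulation_design()$mediation |>
      modifyList(list(count = list(
        birth_weight = list(fetal = c(base = 0, slope = 0),
                            maternal = c(base = 0, slope = 0)),
        gestational_age = list(fetal = c(base = 0, slope = 0),
                               maternal = c(base = 0, slope = 0))))),
    size_factor_range = c(1, 1), dispersion = 0.2, seed = 13)
  expo <- simulate_exposures(d)
  expr <- simulate_expression(d, expo)
  m <- rowMeans(expr$counts)
  v <- apply(expr$counts, 1, var)
  fit <- lm(I(v - m) ~ 0 + I(m^2))
  expect_equal(unname(coef(fit)), 0.2, tolerance = 0.15)
})

test_that("planted mediators carry a * b ground-truth ACME", {
  g <- generate_study(simulation_design(n_transcripts = 1600,
                                        n_modules = 8, seed = 11))
  tr <- g$truth$mediators
  expect_true(all(tr$feature_id %in% g$truth$features$feature_id))
  expect_equal(tr$acme, tr$a * tr$b, tolerance = 1e-12)
  # birth-weight fetal loading stratum rises with TPTE
  bwf <- tr[tr$outcome == "birth_weight" & tr$source == "fetal", ]
  l <- g$truth$features$loading[match(bwf$feature_id,
                                      g$truth$features$feature_id)]
  tpte <- g$compounds$tpte[match(bwf$compound, g$compounds$compound)]
  expect_gt(cor(tpte, l), 0.8)
  # gestational-age strata are flat and shared across sources
  ga <- tr[tr$outcome == "gestational_age", ]
  expect_identical(sort(unique(ga$feature_id[ga$source == "fetal"])),
                   sort(unique(ga$feature_id[ga$source == "maternal"])))
})

test_that("hub kME rank order is recovered from counts", {
  # batch-free so the check isolates the count-noise attenuation layer
  d <- simulation_design(n_transcripts = 1000, n_modules = 5,
                         outcome_modules = list(birth_weight = 1L,
                                                gestational_age = 2L),
                         batch_effect_range = c(0, 0),
                         seed = 31)
  expo <- simulate_exposures(d)
  expr <- simulate_expression(d, expo)
  vst <- vst_counts(expr$counts)
  ok_modules <- 0; n_modules <- 0
  for (k in seq_len(d$n_modules)) {
    members <- expr$features$module == k
    kme <- abs(cor(t(vst[members, ]), expr$factors[k, ]))
    hubs <- expr$features$hub[members]
    n_modules <- n_modules + 1
    # every designated hub outranks the median member
    if (min(rank(-kme)[hubs]) <= 10 &&
        all(kme[hubs] > median(kme)))
      ok_modules <- ok_modules + 1
  }
  expect_gte(ok_modules / n_modules, 0.95)
})

test_that("outcomes respond to their module factors", {
  d <- simulation_design(n_transcripts = 800, n_modules = 4,
                         outcome_modules = list(birth_weight = 1L,
                                                gestational_age = 2L),
                         seed = 17)
  expo <- simulate_exposures(d)
  expr <- suppressWarnings(simulate_expression(d, expo))
  cov <- simulate_outcomes(d, expo, expr)
  expect_true(all(cov$birth_weight > 0))
  expect_true(all(cov$gestational_age > 0))
  expect_gt(cor(cov$birth_weight, expr$factors[1, ]), 0.5)
  expect_gt(cor(cov$gestational_age, expr$factors[2, ]), 0.5)
  # birth weight and gestational age are correlated but distinct
  r <- cor(cov$birth_weight, cov$gestational_age)
  expect_gt(r, 0.15); expect_lt(r, 0.8)
})
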