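# Synthetic exposure-study generator.
#
# Generative model, briefly:
#   * maternal log concentrations are lognormal; fetal log concentrations
#     couple to maternal ones with correlation rho(TPTE) and are offset by
#     log(TPTE), so the empirical cord:maternal ratio tracks the design
#     TPTE and maternal-fetal correlation decays as transfer increases;
#   * transcript latent expression follows a module factor model
#     z = l*F + a*x + sqrt(1-l^2-a^2)*e on unit scale (exposure response
#     replaces idiosyncratic noise, so it does not dilute module
#     membership), scaled by a biological log-SD and read out as
#     negative-binomial counts;
#   * outcomes load on the factors of designated "outcome modules", so a
#     feature mediates exposure -> outcome iff it is exposure-responsive
#     (a != 0) inside an outcome module; its true mediated effect is
#     a * w * l (response x outcome weight x module loading);
#   * where mediators are drawn from controls the planted topology: for
#     birth weight the fetal loading stratum rises with TPTE (higher kME,
#     shorter hub distances, growing maternal-fetal separation), for
#     gestational age both strata are flat in TPTE.

#' Simulation design for a synthetic exposure study
#'
#' Defaults emulate the reference study conditions: 124 samples, eight
#' PFAS compounds with TPTE spanning 0.4-2.4 (inverse to carbon chain
#' length), maternal-fetal coupling rho(T) = 0.85 below T = 1 decaying to
#' 0.05 at T = 2, left-censoring of the lowest concentrations, 3,000
#' transcripts in 20 modules, NB dispersion 0.2, and planted
#' birth-weight-specific TPTE scaling of mediator placement.
#'
#' @param n_samples Number of samples.
#' @param compounds data.frame with `compound`, `tpte`, `chain_length`.
#' @param rho Maternal-fetal log-concentration correlation as a function
#'   of TPTE: piecewise-linear between `rho_high` (T <= 1) and `rho_low`
#'   (T >= 2).
#' @param fetal_coupling `"stochastic"` (default) or `"noiseless"`
#'   (fetal = TPTE x maternal exactly; used for ratio-recovery checks).
#' @param log_conc_mean,log_conc_sd Maternal log-concentration moments.
#' @param censor_loq_frac,censor_lod_frac Fractions of each
#'   compound-source distribution flagged below the LOQ / LOD.
#' @param n_transcripts,n_modules Expression dimensions.
#' @param outcome_modules List naming which modules drive each outcome.
#' @param hubs_per_module,hub_loadings Designated hub count per module and
#'   their (distinct) factor loadings.
#' @param loading_range Uniform range for non-hub member loadings.
#' @param sigma_bio Biological log-scale SD (natural log units).
#' @param sigma_flat,flat_frac A `flat_frac` fraction of features are
#'   weakly regulated background transcripts with biological log-SD
#'   `sigma_flat`, giving the broad variance spectrum real transcriptomes
#'   show (designated hubs and planted mediators, being regulated
#'   features by construction, are excluded from this set).
#' @param isoform_probs Probabilities of 1, 2, ... isoforms per gene.
#' @param antagonism_frac Fraction of multi-isoform differentially
#'   expressed genes whose isoforms receive opposite-sign effects.
#' @param base_log_mean_range Range (natural log) of baseline mean counts.
#' @param hub_base_log_mean_range Baseline range for designated hubs
#'   (upper expression range: low-abundance features cannot act as hubs
#'   because counting noise attenuates their eigengene correlation).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param size_factor_range Log-uniform range of sample size factors.
#' @param sex_effect Log-scale fetal-sex effect applied to a random 10%
#'   of features.
#' @param batch_effect_range Per-feature loading range (log scale,
#'   random sign) on one standard-normal technical batch factor; this is
#'   the latent technical variation the analysis pipeline estimates and
#'   removes.  Set to `c(0, 0)` for batch-free data.
#' @param de Differential-expression plant: features per compound-source
#'   combo (by source) and |log2FC| magnitude.
#' @param mediation Mediator plant: standardized exposure response `a`,
#'   per-outcome count rules `base + slope * TPTE` per source,
#'   loading-stratum centers (base/slope/max) per outcome and source,
#'   stratum half-width, and `shared_sources` flags (outcomes whose
#'   mediators respond to the combined maternal + fetal burden through
#'   one shared feature set per compound, as parturition-timing biology
#'   suggests, rather than source-specific sets).
#' @param outcome Outcome structural coefficients (module weight, direct
#'   effects per source, covariate effects, noise SD, output scaling).
#' @param seed Master seed; every stage derives its RNG stream from it.
#'
#' @return Object of class `simulation_design`.
#' @export
simulation_design <- function(
    n_samples = 124,
    compounds = data.frame(
      compound = c("PFOS", "PFDA", "PFUnDA", "PFNA",
                   "PFOA", "PFHxS", "PFBA", "PFBS"),
      tpte = c(0.40, 0.55, 0.65, 0.85, 1.10, 1.45, 2.05, 2.40),
      chain_length = c(8L, 10L, 11L, 9L, 8L, 6L, 4L, 4L)),
    rho = c(rho_high = 0.85, rho_low = 0.05),
    fetal_coupling = c("stochastic", "noiseless"),
    log_conc_mean = log(2), log_conc_sd = 0.6,
    censor_loq_frac = 0.10, censor_lod_frac = 0.05,
    n_transcripts = 3000, n_modules = 20,
    outcome_modules = list(birth_weight = 1L,
                           gestational_age = 2L),
    hubs_per_module = 5,
    hub_loadings = c(0.96, 0.95, 0.94, 0.93, 0.92),
    loading_range = c(0.30, 0.85),
    sigma_bio = 1.0,
    sigma_flat = 0.3, flat_frac = 0.2,
    isoform_probs = c(0.5, 0.3, 0.2),
    antagonism_frac = 0.2,
    base_log_mean_range = log(c(50, 2000)),
    hub_base_log_mean_range = log(c(300, 2000)),
    dispersion = 0.2,
    size_factor_range = c(0.7, 1.4),
    sex_effect = 0.15,
    batch_effect_range = c(0.3, 0.8),
    de = list(n_fetal = 6, n_maternal = 12, log2fc = 1.5),
    mediation = list(
      a = 0.55, a_shared = 0.5, halfwidth = 0.06,
      count = list(
        birth_weight = list(
          fetal = c(base = 4, slope = 20),
          maternal = c(base = 16, slope = 0)),
        gestational_age = list(
          fetal = c(base = 20, slope = 0),
          maternal = c(base = 20, slope = 0))),
      shared_sources = c(birth_weight = FALSE, gestational_age = TRUE),
      center = list(
        birth_weight = list(
          fetal = c(base = 0.46, slope = 0.16, max = 0.82),
          maternal = c(base = 0.58, slope = 0, max = 0.83)),
        gestational_age = list(
          fetal = c(base = 0.68, slope = 0, max = 0.72),
          maternal = c(base = 0.68, slope = 0, max = 0.72)))),
    outcome = list(module_weight = 0.9,
                   gamma_fetal = -0.03, gamma_maternal = -0.05,
                   sex_birth_weight = 0.25, sex_gestational_age = 0.15,
                   ga_on_bw = 0.30, noise_sd = 0.3,
                   bw_mean = 3030, bw_scale = 380,
                   ga_mean = 39, ga_scale = 1.3,
                   spontaneous_prob = 72 / 124, male_prob = 60 / 124),
    seed = 1L) {
  fetal_coupling <- match.arg(fetal_coupling)
  stopifnot(n_samples >= 4, n_transcripts >= 10, n_modules >= 2,
            dispersion > 0, length(hub_loadings) == hubs_per_module,
            all(diff(compounds$tpte) != 0),
            censor_loq_frac >= 0, censor_loq_frac < 1,
            censor_lod_frac >= 0, censor_lod_frac < censor_loq_frac + 1)
  if (anyDuplicated(compounds$compound)) stop("duplicate compound names")
  if (any(compounds$tpte <= 0)) stop("tpte must be positive")
  if (any(unlist(outcome_modules) > n_modules))
    stop("outcome_modules reference modules beyond n_modules")
  rho_vals <- if (is.numeric(rho)) rho else stop("rho must be numeric")
  if (any(rho_vals < 0 | rho_vals > 1))
    stop("rho endpoints must lie in [0, 1]")
  structure(list(
    n_samples = n_samples, compounds = compounds, rho = rho_vals,
    fetal_coupling = fetal_coupling, log_conc_mean = log_conc_mean,
    log_conc_sd = log_conc_sd, censor_loq_frac = censor_loq_frac,
    censor_lod_frac = censor_lod_frac, n_transcripts = n_transcripts,
    n_modules = n_modules, outcome_modules = outcome_modules,
    hubs_per_module = hubs_per_module, hub_loadings = hub_loadings,
    loading_range = loading_range, sigma_bio = sigma_bio,
    sigma_flat = sigma_flat, flat_frac = flat_frac,
    isoform_probs = isoform_probs, antagonism_frac = antagonism_frac,
    base_log_mean_range = base_log_mean_range,
    hub_base_log_mean_range = hub_base_log_mean_range,
    dispersion = dispersion,
    size_factor_range = size_factor_range, sex_effect = sex_effect,
    batch_effect_range = batch_effect_range,
    de = de, mediation = mediation, outcome = outcome,
    seed = as.integer(seed)), class = "simulation_design")
}

# piecewise-linear rho(T): rho_high for T <= 1, rho_low for T >= 2
design_rho <- function(design, tpte) {
  hi <- design$rho[["rho_high"]]; lo <- design$rho[["rho_low"]]
  r <- ifelse(tpte <= 1, hi,
              ifelse(tpte >= 2, lo, hi + (tpte - 1) * (lo - hi)))
  as.numeric(r)
}

#' Simulate maternal and fetal exposure concentrations
#'
#' Maternal log concentration is Normal(mu, sigma); fetal log
#' concentration is `log(TPTE) + mu + rho * (maternal - mu) +
#' sqrt(1 - rho^2) * sigma * eps`, so the maternal-fetal correlation
#' equals rho(TPTE).  The lowest `censor_lod_frac` of each
#' compound-source distribution is flagged below-LOD and the next slice up
#' to `censor_loq_frac` below-LOQ, with values blanked pending imputation.
#'
#' @param design A [simulation_design()].
#' @param sample_ids Optional sample IDs (defaults to S001...).
#' @return List with `exposures` (long data.frame as in
#'   [sample_table()]), and `xz`: list of maternal/fetal matrices of
#'   z-scored true log concentrations (samples x compounds) used to plant
#'   downstream effects.
#' @export
simulate_exposures <- function(design, sample_ids = NULL) {
  set.seed(design$seed + 1L)
  n <- design$n_samples
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(n))
  cps <- design$compounds
  rows <- list(); xz_m <- xz_f <- matrix(NA_real_, n, nrow(cps),
                                         dimnames = list(sample_ids,
                                                         cps$compound))
  for (k in seq_len(nrow(cps))) {
    tpte <- cps$tpte[k]
    r <- design_rho(design, tpte)
    if (r < 0 || r > 1) stop("rho outside [0, 1]")
    mu <- design$log_conc_mean; s <- design$log_conc_sd
    lm_ <- rnorm(n, mu, s)
    lf_ <- if (design$fetal_coupling == "noiseless") log(tpte) + lm_
           else log(tpte) + mu + r * (lm_ - mu) +
             sqrt(1 - r^2) * s * rnorm(n)
    xz_m[, k] <- zscore(lm_); xz_f[, k] <- zscore(lf_)
    for (src in c("maternal", "fetal")) {
      v <- exp(if (src == "maternal") lm_ else lf_)
      lod <- as.numeric(quantile(v, design$censor_lod_frac))
      loq <- as.numeric(quantile(v, design$censor_lod_frac +
                                    design$censor_loq_frac))
      censor <- rep("quantified", n)
      if (design$censor_lod_frac > 0) censor[v <= lod] <- "below_lod"
      if (design$censor_loq_frac > 0)
        censor[v <= loq & censor == "quantified"] <- "below_loq"
      v[censor != "quantified"] <- NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sample_ids, compound = cps$compound[k], source = src,
        value = v, censor = censor, lod = lod, loq = loq,
        stringsAsFactors = FALSE)
    }
  }
  list(exposures = do.call(rbind, rows),
       xz = list(maternal = xz_m, fetal = xz_f))
}

# allocate transcripts to modules; outcome modules get 6x weight so the
# mediator pool is deep enough for all compounds without feature reuse
module_sizes <- function(design) {
  w <- rep(1, design$n_modules)
  w[unique(unlist(design$outcome_modules))] <- 6
  sz <- floor(design$n_transcripts * w / sum(w))
  sz[1] <- sz[1] + design$n_transcripts - sum(sz)
  sz
}

linfun <- function(par, tpte) {
  v <- par[["base"]] + par[["slope"]] * tpte
  if ("max" %in% names(par)) v <- pmin(v, par[["max"]])
  v
}

#' Simulate modular negative-binomial expression with planted effects
#'
#' @param design A [simulation_design()].
#' @param exposures Output of [simulate_exposures()].
#' @return List: `counts` (transcripts x samples), `features`
#'   (feature_id, gene_id, module, loading, hub), `tx2gene`, `factors`
#'   (module x sample latent factors), `fetal_sex`, `mediators`,
#'   `de` (plant records), and `latent` (standardized latent expression
#'   used by [simulate_outcomes()]).
#' @export
simulate_expression <- function(design, exposures) {
  set.seed(design$seed + 2L)
  n <- design$n_samples
  sample_ids <- rownames(exposures$xz$maternal)
  if (any(unlist(design$isoform_probs) < 0))
    stop("degenerate isoform spec")
  if (diff(design$loading_range) <= 0)
    stop("degenerate loading spec")

  # gene/isoform architecture
  iso_p <- design$isoform_probs / sum(design$isoform_probs)
  n_iso <- integer(0)
  while (sum(n_iso) < design$n_transcripts)
    n_iso <- c(n_iso, sample(seq_along(iso_p), 200, TRUE, prob = iso_p))
  cum <- cumsum(n_iso)
  n_genes <- which(cum >= design$n_transcripts)[1]
  n_iso <- n_iso[seq_len(n_genes)]
  n_iso[n_genes] <- n_iso[n_genes] - (sum(n_iso) - design$n_transcripts)
  if (n_iso[n_genes] == 0) { n_genes <- n_genes - 1; n_iso <- n_iso[seq_len(n_genes)] }
  gene_id <- sprintf("G%05d", seq_len(n_genes))
  tx_gene <- rep(gene_id, n_iso)
  p <- length(tx_gene)
  feature_id <- sprintf("T%05d", seq_len(p))

  # module assignment at the gene level so isoforms co-localize
  sz <- module_sizes(design)
  gene_module <- integer(n_genes); tx_count <- 0L; m <- 1L; filled <- 0L
  ord <- sample.int(n_genes)  # random gene order
  for (g in ord) {
    gene_module[g] <- m
    filled <- filled + n_iso[g]
    if (filled >= sz[m] && m < design$n_modules) { m <- m + 1L; filled <- 0L }
  }
  module <- gene_module[match(tx_gene, gene_id)]

  # loadings: first hubs_per_module transcripts of each module are
  # designated hubs with fixed distinct loadings
  loading <- runif(p, design$loading_range[1], design$loading_range[2])
  hub <- logical(p)
  for (k in seq_len(design$n_modules)) {
    idx <- which(module == k)
    nh <- min(design$hubs_per_module, length(idx))
    pick <- idx[seq_len(nh)]
    loading[pick] <- design$hub_loadings[seq_len(nh)]
    hub[pick] <- TRUE
  }

  fetal_sex <- rbinom(n, 1, design$outcome$male_prob)
  Fmat <- matrix(rnorm(design$n_modules * n), design$n_modules, n,
                 dimnames = list(NULL, sample_ids))
  # outcome-module factors are made orthogonal (in sample) to every
  # exposure: the planted mediator set is only well defined when chance
  # factor-exposure correlation cannot induce module-wide mediation
  Xz <- cbind(exposures$xz$maternal, exposures$xz$fetal)
  Q <- qr.Q(qr(cbind(1, Xz)))
  for (k in unique(unlist(design$outcome_modules))) {
    f <- Fmat[k, ]
    f <- f - Q %*% crossprod(Q, f)
    Fmat[k, ] <- f / sd(f)
  }

  # plant mediators: exposure-responsive features inside outcome modules
  cps <- design$compounds; med <- design$mediation
  med_rows <- list()
  plants <- list()  # feature -> response terms added to the latent scale
  for (oc in names(design$outcome_modules)) {
    pool_mods <- design$outcome_modules[[oc]]
    shared <- isTRUE(med$shared_sources[[oc]])
    used <- character(0)
    # selection order must not encode TPTE: stratum over-subscription
    # spills late compounds outward, which would otherwise correlate
    # with transfer efficiency
    for (k in sample(nrow(cps))) {
      tpte <- cps$tpte[k]
      rho_k <- design_rho(design, tpte)
      srcs <- if (shared) "fetal" else c("fetal", "maternal")
      for (src in srcs) {
        cnt <- round(linfun(med$count[[oc]][[src]], tpte))
        ctr <- linfun(med$center[[oc]][[src]], tpte)
        cand <- which(module %in% pool_mods & !(feature_id %in% used) &
                        !hub)
        if (length(cand) < cnt) {
          warning("mediator pool exhausted for ", oc, "; planting ",
                  length(cand), " of ", cnt, " mediators for ",
                  cps$compound[k], "/", src)
          cnt <- length(cand)
        }
        if (cnt == 0) next
        band <- cand[abs(loading[cand] - ctr) <= med$halfwidth]
        pick <- if (length(band) >= cnt) sample(band, cnt) else
          cand[order(abs(loading[cand] - ctr))][seq_len(cnt)]
        used <- c(used, feature_id[pick])
        if (shared) {
          # one feature set responding to the combined burden, scaled so
          # the marginal per-source response stays a_shared at any
          # maternal-fetal correlation
          a_term <- med$a_shared / (1 + rho_k)
          a_marg <- med$a_shared
          for (s2 in c("fetal", "maternal"))
            med_rows[[length(med_rows) + 1L]] <- data.frame(
              compound = cps$compound[k], source = s2, outcome = oc,
              feature_id = feature_id[pick], a = a_marg,
              b = design$outcome$module_weight * loading[pick],
              stringsAsFactors = FALSE)
          plants[[length(plants) + 1L]] <- list(
            features = feature_id[pick], compound = cps$compound[k],
            sources = c("fetal", "maternal"), a_term = a_term,
            a_total = sqrt(2 * (1 + rho_k)) * a_term)
        } else {
          med_rows[[length(med_rows) + 1L]] <- data.frame(
            compound = cps$compound[k], source = src, outcome = oc,
            feature_id = feature_id[pick], a = med$a,
            b = design$outcome$module_weight * loading[pick],
            stringsAsFactors = FALSE)
          plants[[length(plants) + 1L]] <- list(
            features = feature_id[pick], compound = cps$compound[k],
            sources = src, a_term = med$a, a_total = med$a)
        }
      }
    }
  }
  mediators <- if (length(med_rows)) do.call(rbind, med_rows) else
    data.frame(compound = character(0), source = character(0),
               outcome = character(0), feature_id = character(0),
               a = numeric(0), b = numeric(0))
  mediators$acme <- mediators$a * mediators$b

  # plant differential expression in background (non-outcome) modules
  bg_mods <- setdiff(seq_len(design$n_modules),
                     unique(unlist(design$outcome_modules)))
  if (!length(bg_mods)) bg_mods <- seq_len(design$n_modules)
  de_rows <- list()
  hub_genes <- unique(tx_gene[hub])
  bg_genes <- setdiff(unique(tx_gene[module %in% bg_mods]), hub_genes)
  for (k in seq_len(nrow(cps))) for (src in c("fetal", "maternal")) {
    n_de <- design$de[[paste0("n_", src)]]
    if (n_de < 1) next
    gsel <- sample(bg_genes, min(n_de, length(bg_genes)))
    for (g in gsel) {
      txs <- which(tx_gene == g)
      sgn <- sample(c(-1, 1), 1)
      signs <- rep(sgn, length(txs))
      if (length(txs) > 1 && runif(1) < design$antagonism_frac)
        signs <- sgn * rep_len(c(1, -1), length(txs))
      de_rows[[length(de_rows) + 1L]] <- data.frame(
        compound = cps$compound[k], source = src,
        feature_id = feature_id[txs],
        log2fc = signs * design$de$log2fc, stringsAsFactors = FALSE)
    }
  }
  de <- if (length(de_rows)) do.call(rbind, de_rows) else
    data.frame(compound = character(0), source = character(0),
               feature_id = character(0), log2fc = numeric(0))

  # latent standardized expression z = l*F + a*x + noise, with the
  # exposure response replacing idiosyncratic noise (unit total variance,
  # so responsiveness does not dilute module membership)
  a_vec <- numeric(p)
  for (pl in plants)
    a_vec[match(pl$features, feature_id)] <- pl$a_total
  eps <- matrix(rnorm(p * n), p, n)
  latent <- loading * Fmat[module, , drop = FALSE] +
    sqrt(pmax(1 - loading^2 - a_vec^2, 0.05)) * eps
  for (pl in plants) {
    idx <- match(pl$features, feature_id)
    for (s2 in pl$sources) {
      x <- exposures$xz[[s2]][, pl$compound]
      latent[idx, ] <- latent[idx, ] +
        pl$a_term * matrix(x, length(idx), n, byrow = TRUE)
    }
  }
  dimnames(latent) <- list(feature_id, sample_ids)

  # assemble log-mean and sample NB counts
  base <- runif(p, design$base_log_mean_range[1],
                design$base_log_mean_range[2])
  base[hub] <- runif(sum(hub), design$hub_base_log_mean_range[1],
                     design$hub_base_log_mean_range[2])
  sig <- rep(design$sigma_bio, p)
  flat <- runif(p) < design$flat_frac & !hub &
    !(feature_id %in% mediators$feature_id)
  sig[flat] <- design$sigma_flat
  # designated hubs are high-amplitude drivers: larger biological
  # dynamic range, low technical susceptibility, high expression --
  # the profile that makes a feature a top-|kME| feature at all
  sig[hub] <- design$sigma_bio * 1.25
  sex_idx <- sample.int(p, round(0.1 * p))
  beta_sex <- numeric(p)
  beta_sex[sex_idx] <- design$sex_effect * sample(c(-1, 1),
                                                  length(sex_idx), TRUE)
  batch <- rnorm(n)
  beta_batch <- runif(p, design$batch_effect_range[1],
                      design$batch_effect_range[2]) *
    sample(c(-1, 1), p, TRUE)
  # a feature dominated by technical noise cannot be a top-|kME|
  # feature, so coherent hub ground truth requires low technical
  # susceptibility for designated hubs
  beta_batch[hub] <- runif(sum(hub), 0, design$batch_effect_range[1]) *
    sample(c(-1, 1), sum(hub), TRUE)
  log_mu <- base + sig * latent +
    outer(beta_sex, fetal_sex) + outer(beta_batch, batch)
  if (nrow(de)) {
    eff <- aggregate(log2fc ~ feature_id + compound + source, de, sum)
    for (i in seq_len(nrow(eff))) {
      j <- match(eff$feature_id[i], feature_id)
      x <- exposures$xz[[eff$source[i]]][, eff$compound[i]]
      log_mu[j, ] <- log_mu[j, ] + log(2) * eff$log2fc[i] * x
    }
  }
  sf <- exp(runif(n, log(design$size_factor_range[1]),
                  log(design$size_factor_range[2])))
  # expression ceiling keeps extreme effect x exposure draws within
  # integer count range
  mu <- pmin(sweep(exp(log_mu), 2, sf, "*"), 1e7)
  counts <- matrix(rnbinom(p * n, mu = mu, size = 1 / design$dispersion),
                   p, n, dimnames = list(feature_id, sample_ids))
  storage.mode(counts) <- "integer"

  list(counts = counts,
       features = data.frame(feature_id = feature_id, gene_id = tx_gene,
                             module = module, loading = loading,
                             hub = hub, stringsAsFactors = FALSE),
       tx2gene = data.frame(transcript_id = feature_id,
                            gene_id = tx_gene, stringsAsFactors = FALSE),
       factors = Fmat, fetal_sex = fetal_sex, size_factors = sf,
       mediators = mediators, de = de, latent = latent,
       batch = batch)
}

#' Simulate perinatal outcomes from exposures and expression
#'
#' Linear structural model: each outcome z-score is the sum of direct
#' exposure effects, loadings on its outcome-module factors (through
#' which all planted mediator paths run), covariate terms, and Gaussian
#' noise.  Birth weight additionally loads on the gestational-age score.
#'
#' @param design A [simulation_design()].
#' @param exposures Output of [simulate_exposures()].
#' @param expression Output of [simulate_expression()].
#' @return data.frame of covariates (sample_id, fetal_sex,
#'   gestational_age, birth_weight, spontaneous_labor).
#' @export
simulate_outcomes <- function(design, exposures, expression) {
  set.seed(design$seed + 3L)
  n <- design$n_samples
  oc <- design$outcome
  bad <- setdiff(expression$mediators$feature_id,
                 expression$features$feature_id)
  if (length(bad)) stop("mediator set references dropped features")
  xz <- exposures$xz
  direct <- oc$gamma_fetal * rowSums(xz$fetal) +
    oc$gamma_maternal * rowSums(xz$maternal)
  fac_sum <- function(mods)
    colSums(expression$factors[mods, , drop = FALSE])
  ga_z <- direct +
    oc$module_weight * fac_sum(design$outcome_modules$gestational_age) +
    oc$sex_gestational_age * expression$fetal_sex +
    rnorm(n, 0, oc$noise_sd)
  bw_z <- direct +
    oc$module_weight * fac_sum(design$outcome_modules$birth_weight) +
    oc$sex_birth_weight * expression$fetal_sex +
    oc$ga_on_bw * ga_z + rnorm(n, 0, oc$noise_sd)
  data.frame(
    sample_id = colnames(expression$counts),
    fetal_sex = expression$fetal_sex,
    gestational_age = oc$ga_mean + oc$ga_scale * ga_z,
    birth_weight = oc$bw_mean + oc$bw_scale * bw_z,
    spontaneous_labor = as.logical(rbinom(n, 1, oc$spontaneous_prob)),
    stringsAsFactors = FALSE)
}

#' Generate a complete synthetic study with ground truth
#'
#' Runs [simulate_exposures()], [simulate_expression()] and
#' [simulate_outcomes()] under seeds derived from the design's master
#' seed and assembles the package's standard containers.
#'
#' @param design A [simulation_design()].
#' @param dir Optional directory: when given, study files
#'   (via [write_study()]) and `truth.json` are written there.
#' @return List: `study` (transcript-level [expression_study()]),
#'   `compounds` ([compound_table()] with the design TPTEs), `truth`
#'   (ground-truth list: `features`, `mediators`, `de`).
#' @export
generate_study <- function(design, dir = NULL) {
  expo <- simulate_exposures(design)
  expr <- simulate_expression(design, expo)
  cov <- simulate_outcomes(design, expo, expr)
  samples <- sample_table(cov, expo$exposures)
  study <- expression_study(expr$counts, expr$tx2gene, samples,
                            level = "transcript")
  compounds <- compound_table(design$compounds$compound,
                              design$compounds$tpte,
                              design$compounds$chain_length)
  truth <- list(features = expr$features, mediators = expr$mediators,
                de = expr$de, seed = design$seed)
  if (!is.null(dir)) {
    write_study(study, dir, compounds = compounds)
    write_ground_truth(truth, file.path(dir, "truth.json"))
  }
  list(study = study, compounds = compounds, truth = truth)
}

#' Serialize / restore ground truth
#'
#' @param truth Ground-truth list from [generate_study()].
#' @param path JSON file path.
#' @return `write_ground_truth` returns `path` invisibly;
#'   `read_ground_truth` the restored list.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("features", "mediators", "de"))
    raw[[nm]] <- as.data.frame(raw[[nm]], stringsAsFactors = FALSE)
  raw$seed <- as.integer(raw$seed)
  raw
}
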