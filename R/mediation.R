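# Per-feature causal mediation of exposure -> outcome through transcript
# abundance.  Two OLS equations (mediator ~ x + C; outcome ~ x + m + C),
# quasi-Bayesian uncertainty by drawing both coefficient vectors from
# their asymptotic normal sampling distributions, ACME = a*b per draw.

ols_fit <- function(X, y) {
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("rank-deficient design in mediation model")
  cf <- qr.coef(qx, y)
  res <- y - X %*% cf
  s2 <- sum(res^2) / (length(y) - ncol(X))
  covm <- s2 * chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot)]
  list(coef = cf, cov = covm)
}

# deterministic per-string seed stream so results do not depend on the
# order features are processed in
string_seed <- function(s, base = 0L) {
  h <- Reduce(function(a, b) (a * 31 + b) %% 2147480009, utf8ToInt(s), 17)
  as.integer((h + as.numeric(base) * 7919) %% 2147483647)
}

#' Quasi-Bayesian causal mediation for a single mediator
#'
#' Fits `m ~ x + C` and `y ~ x + m + C` by OLS, draws both coefficient
#' vectors from their asymptotic normal distributions, and forms per-draw
#' ACME (`a * b`), ADE (`c'`) and total effect (`c' + a * b`).  Point
#' estimates are draw means; the 95% CI is the percentile interval; the
#' two-sided p-value is the Monte Carlo tail probability
#' `2 * min(Pr(ACME <= 0), Pr(ACME >= 0))`; a value of 0 means the
#' effect's sign was unanimous across draws, i.e. p is below the
#' `1 / n_sims` resolution.
#'
#' @param x Exposure (z-score scale; the effect contrast is one unit).
#' @param m Mediator values (variance-stabilized expression).
#' @param y Outcome (z-score scale).
#' @param covariates Optional matrix/data.frame of covariates.
#' @param n_sims Number of quasi-Bayesian draws (default 1000).
#' @param seed Optional RNG seed for the draws.
#' @return One-row data.frame: acme, ade, total_effect, prop_mediated,
#'   ci_low, ci_high (ACME), p, ade_var.
#' @export
fit_mediation <- function(x, m, y, covariates = NULL, n_sims = 1000,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (sd(m) == 0) {
    warning("zero-variance mediator skipped")
    return(NULL)
  }
  C <- if (is.null(covariates)) NULL else as.matrix(covariates)
  Xm <- cbind(1, x, C)
  Xy <- cbind(1, x, m, C)
  fm <- ols_fit(Xm, m)
  fy <- ols_fit(Xy, y)
  # draw only the coefficients that matter: a from the mediator model,
  # (c', b) jointly from the outcome model
  a_s <- fm$coef[2] + sqrt(fm$cov[2, 2]) * rnorm(n_sims)
  R <- chol(fy$cov[2:3, 2:3])
  cb <- matrix(rnorm(2 * n_sims), n_sims, 2) %*% R
  c_s <- fy$coef[2] + cb[, 1]; b_s <- fy$coef[3] + cb[, 2]
  acme_s <- a_s * b_s
  ade_s <- c_s
  tot_s <- acme_s + ade_s
  acme <- mean(acme_s); ade <- mean(ade_s); tot <- mean(tot_s)
  ci <- unname(quantile(acme_s, c(0.025, 0.975)))
  p <- min(1, 2 * min(mean(acme_s <= 0), mean(acme_s >= 0)))
  data.frame(acme = acme, ade = ade, total_effect = tot,
             prop_mediated = if (tot == 0) NA_real_ else acme / tot,
             ci_low = ci[1], ci_high = ci[2], p = p,
             ade_var = var(ade_s))
}

#' Transcriptome-wide mediation for one compound-source-outcome analysis
#'
#' Mediators are variance-stabilized counts ([vst_counts()]).  Covariates
#' follow the outcome: fetal sex plus gestational-age z-score for birth
#' weight, fetal sex alone for gestational age; gestational-age analyses
#' are restricted to births following spontaneous onset of labor.  The
#' exposure is the z-scored (imputed) concentration over samples with a
#' measurement.  BH adjustment runs over the features tested in this
#' analysis; a mediator is significant when `padj < fdr` and the 95% CI
#' excludes zero.
#'
#' @param study A count-filtered [expression_study()] (censoring already
#'   imputed via [impute_censored()]).
#' @param compound,source Exposure selector (`source` `"maternal"` or
#'   `"fetal"`).
#' @param outcome `"birth_weight"` or `"gestational_age"`.
#' @param n_sims Quasi-Bayesian draws per feature.
#' @param seed Master seed; each feature uses a stream derived from it
#'   and its feature ID, so results are order-invariant.
#' @param fdr BH threshold (default 0.05).
#' @param features Optional subset of feature IDs to test.
#' @param mediator_matrix Optional feature-by-sample matrix of
#'   already-normalized mediator values (e.g. latent-factor-corrected
#'   expression); by default the variance-stabilized counts are used.
#' @return data.frame with one row per tested feature: feature_id, acme,
#'   ade, total_effect, prop_mediated, ci_low, ci_high, p, padj,
#'   significant, ade_var; skipped features recorded in
#'   `attr(, "skipped")`.
#' @export
mediate_all <- function(study, compound, source,
                        outcome = c("birth_weight", "gestational_age"),
                        n_sims = 1000, seed = 1L, fdr = 0.05,
                        features = NULL, mediator_matrix = NULL) {
  outcome <- match.arg(outcome)
  cov <- study$samples$covariates
  ex <- study$samples$exposures
  ex <- ex[ex$compound == compound & ex$source == source &
             is.finite(ex$value), ]
  ids <- intersect(colnames(study$counts), ex$sample_id)
  if (outcome == "gestational_age") {
    sp <- cov$sample_id[cov$spontaneous_labor %in% TRUE]
    ids <- intersect(ids, sp)
  }
  if (length(ids) < 10)
    stop("fewer than 10 usable samples for ", compound, "/", source)
  cv <- cov[match(ids, cov$sample_id), ]
  x <- zscore(log(ex$value[match(ids, ex$sample_id)]))
  y <- if (outcome == "birth_weight") zscore(cv$birth_weight)
       else zscore(cv$gestational_age)
  C <- if (outcome == "birth_weight")
    cbind(sex = cv$fetal_sex, ga_z = zscore(cv$gestational_age))
  else cbind(sex = cv$fetal_sex)
  M <- if (is.null(mediator_matrix))
    vst_counts(study$counts)[, ids, drop = FALSE]
  else mediator_matrix[, ids, drop = FALSE]
  if (!is.null(features)) M <- M[rownames(M) %in% features, , drop = FALSE]
  rows <- vector("list", nrow(M))
  skipped <- character(0)
  for (j in seq_len(nrow(M))) {
    fid <- rownames(M)[j]
    r <- withCallingHandlers(
      tryCatch(fit_mediation(x, M[j, ], y, covariates = C,
                             n_sims = n_sims,
                             seed = string_seed(fid, seed)),
               error = function(e) NULL),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(r)) { skipped <- c(skipped, fid); next }
    r$feature_id <- fid
    rows[[j]] <- r
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no feature could be tested")
  out <- out[, c("feature_id", "acme", "ade", "total_effect",
                 "prop_mediated", "ci_low", "ci_high", "p", "ade_var")]
  out$padj <- benjamini_hochberg(out$p)
  out$significant <- !is.na(out$padj) & out$padj < fdr &
    sign(out$ci_low) == sign(out$ci_high)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Inverse-variance-weighted mean average direct effect
#'
#' Summarizes the ADE over a set of (significant) mediators using weights
#' `1 / Var(ADE draws)`, with a normal-approximation 95% CI.
#'
#' @param results Rows of a [mediate_all()] table (typically the
#'   significant subset).
#' @return List: estimate, ci (length-2), n.
#' @export
weighted_mean_ade <- function(results) {
  if (is.null(results) || !nrow(results)) {
    warning("no mediators supplied; weighted mean ADE undefined")
    return(list(estimate = NA_real_, ci = c(NA_real_, NA_real_), n = 0L))
  }
  w <- 1 / results$ade_var
  est <- sum(w * results$ade) / sum(w)
  se <- 1 / sqrt(sum(w))
  list(estimate = est, ci = est + c(-1, 1) * qnorm(0.975) * se,
       n = nrow(results))
}
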