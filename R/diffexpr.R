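# Negative-binomial differential expression against exposure z-scores.
#
# The engine is a plain NB Wald GLM: median-of-ratios size factors as
# offsets, per-feature dispersion estimated conditionally on the design
# by edgeR's empirical-Bayes machinery (tagwise, trend-shrunk, floored),
# and a quasi-likelihood Wald test on the exposure coefficient reported
# in log2 units (standard errors inflated by residual Pearson
# overdispersion, floored at 1, against a t reference with residual
# degrees of freedom).  No shrinkage of fold changes and no outlier
# replacement.  The IRLS itself runs through edgeR's Levenberg-damped
# fitter; Wald standard errors come from the information matrix at the
# fitted means.

estimate_dispersions <- function(counts, sf, X, min_dispersion = 1e-4) {
  d <- edgeR::estimateDisp(counts, design = X,
                           offset = matrix(log(sf), nrow(counts),
                                           ncol(counts), byrow = TRUE))
  pmax(d$tagwise.dispersion, min_dispersion)
}

# Wald SEs for the exposure coefficient: sqrt of the (2,2) entry of
# (X' W X)^{-1} with NB log-link IRLS weights w = mu / (1 + phi * mu)
nb_wald_se <- function(fitted, phi, X) {
  vapply(seq_len(nrow(fitted)), function(j) {
    w <- fitted[j, ] / (1 + phi[j] * fitted[j, ])
    info <- crossprod(X * sqrt(w))
    covm <- tryCatch(chol2inv(chol(info)), error = function(e) NULL)
    if (is.null(covm)) NA_real_ else sqrt(covm[2, 2])
  }, numeric(1))
}

#' Negative-binomial differential expression against an exposure z-score
#'
#' Fits, per feature, a log-link NB GLM of counts on the exposure z-score
#' plus covariates, with log size factors as offsets and per-feature
#' empirical-Bayes dispersion (tagwise, floored).  The exposure
#' coefficient is Wald-tested and
#' reported in log2 units per z-score unit.  Features whose fit fails
#' keep `NA` p-values and are excluded from the BH family.
#'
#' @param study An [expression_study()] (count-filtered).
#' @param exposure_z Named numeric vector of exposure z-scores (names =
#'   sample IDs) covering the study's samples.
#' @param covariates Optional data.frame/matrix of adjustment covariates
#'   (rows aligned to `names(exposure_z)`), e.g. fetal sex and
#'   gestational-age z-score.
#' @param fdr,lfc Significance thresholds: BH-adjusted p below `fdr`
#'   (default 0.10) and |log2FC| above `lfc` (default 1).
#' @param min_dispersion Dispersion floor (default 1e-4).
#' @return data.frame: feature_id, log2fc, se, wald_stat, p, padj,
#'   significant, converged.
#' @export
fit_nb_de <- function(study, exposure_z, covariates = NULL,
                      fdr = 0.10, lfc = 1, min_dispersion = 1e-4) {
  ids <- names(exposure_z)
  if (is.null(ids)) stop("exposure_z must be named by sample ID")
  ids <- intersect(colnames(study$counts), ids)
  if (length(ids) < 10) stop("need >= 10 samples with exposure")
  counts <- study$counts[, ids, drop = FALSE]
  x <- exposure_z[ids]
  X <- cbind(`(Intercept)` = 1, exposure = x)
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)[match(ids, names(exposure_z)), ,
                                drop = FALSE]
    X <- cbind(X, cv)
  }
  if (qr(X)$rank < ncol(X)) stop("singular design matrix")
  sf <- size_factors(counts)
  phi <- estimate_dispersions(counts, sf, X,
                               min_dispersion = min_dispersion)
  fit <- edgeR::glmFit(counts, design = X, dispersion = phi,
                       offset = log(sf), prior.count = 0)
  beta <- fit$coefficients[, 2]          # natural log scale
  se_ln <- nb_wald_se(fit$fitted.values, phi, X)
  # quasi-likelihood variance inflation: residual Pearson overdispersion
  # beyond the NB fit widens the standard error (floored at 1)
  mu <- fit$fitted.values
  x2 <- rowSums((counts - mu)^2 / (mu + phi * mu^2))
  ql <- pmax(x2 / (ncol(counts) - ncol(X)), 1)
  se_ln <- se_ln * sqrt(ql)
  log2fc <- beta / log(2)
  se <- se_ln / log(2)
  wald <- log2fc / se
  p <- 2 * pt(-abs(wald), df = ncol(counts) - ncol(X))
  padj <- benjamini_hochberg(p)
  out <- data.frame(feature_id = rownames(counts), log2fc = log2fc,
                    se = se, wald_stat = wald, p = p, padj = padj,
                    significant = !is.na(padj) & padj < fdr &
                      abs(log2fc) > lfc,
                    converged = !is.na(p), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Missing p-values are excluded from the family (they stay `NA` and do
#' not count toward m).
#'
#' @param p Vector of p-values in `[0, 1]`, `NA` allowed.
#' @return Adjusted p-values, capped at 1.
#' @export
benjamini_hochberg <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

collapse_to_genes <- function(de, tx2gene, sig) {
  g <- tx2gene$gene_id[match(de$feature_id, tx2gene$transcript_id)]
  split(sig, g)
}

#' Concordance enrichment between two differential-expression tables
#'
#' A feature is concordant when nominally significant (p < 0.05) with the
#' same direction of effect in both tables.  Enrichment of the concordant
#' set among features nominally significant with |log2FC| > 1 in `de_a`
#' (the experimental arm) is tested with Fisher's exact test over the
#' universe of features present in both tables.  With `tx2gene` supplied,
#' transcript-level tables are first collapsed to genes (a gene counts
#' when at least one of its transcripts meets the criteria in both
#' tables).
#'
#' @param de_a,de_b [fit_nb_de()]-style tables (`de_a` = experimental
#'   arm defining the enrichment set).
#' @param tx2gene Optional transcript-to-gene map for gene-level
#'   collapsing.
#' @return List: `log_odds` (Haldane-Anscombe +0.5 on zero cells),
#'   `fisher_p` (two-sided), `n_concordant`, `table` (2x2 matrix).
#' @export
concordance_enrichment <- function(de_a, de_b, tx2gene = NULL) {
  shared <- intersect(de_a$feature_id, de_b$feature_id)
  if (!length(shared)) stop("no shared features between tables")
  a <- de_a[match(shared, de_a$feature_id), ]
  b <- de_b[match(shared, de_b$feature_id), ]
  conc_tx <- !is.na(a$p) & !is.na(b$p) & a$p < 0.05 & b$p < 0.05 &
    sign(a$log2fc) == sign(b$log2fc)
  siga_tx <- !is.na(a$p) & a$p < 0.05 & abs(a$log2fc) > 1
  if (is.null(tx2gene)) {
    universe <- shared; conc <- conc_tx; siga <- siga_tx
  } else {
    g <- tx2gene$gene_id[match(shared, tx2gene$transcript_id)]
    universe <- unique(g)
    conc <- vapply(split(conc_tx, g)[universe], any, logical(1))
    siga <- vapply(split(siga_tx, g)[universe], any, logical(1))
  }
  if (!length(universe)) stop("empty feature universe")
  tab <- table(factor(conc, c(TRUE, FALSE)), factor(siga, c(TRUE, FALSE)))
  tab <- matrix(as.numeric(tab), 2, 2,
                dimnames = list(concordant = c("yes", "no"),
                                sig_a = c("yes", "no")))
  tt <- if (any(tab == 0)) tab + 0.5 else tab
  log_odds <- log((tt[1, 1] * tt[2, 2]) / (tt[1, 2] * tt[2, 1]))
  fisher_p <- fisher.test(round(tab))$p.value
  list(log_odds = unname(log_odds), fisher_p = fisher_p,
       n_concordant = sum(conc), table = tab)
}

#' Pearson correlation of log2 fold changes across exposure sources
#'
#' @param de_maternal,de_fetal Matched [fit_nb_de()] tables.
#' @return Pearson r over shared features with finite estimates, or `NA`
#'   (with a warning) below 3 pairs.
#' @export
lfc_cross_correlation <- function(de_maternal, de_fetal) {
  shared <- intersect(de_maternal$feature_id, de_fetal$feature_id)
  m <- de_maternal$log2fc[match(shared, de_maternal$feature_id)]
  f <- de_fetal$log2fc[match(shared, de_fetal$feature_id)]
  ok <- is.finite(m) & is.finite(f)
  if (sum(ok) < 3) {
    warning("fewer than 3 matched features with finite estimates")
    return(NA_real_)
  }
  cor(m[ok], f[ok])
}
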