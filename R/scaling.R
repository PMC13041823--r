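# TPTE-scaling regressions of network-mediation properties across
# compounds, and the hub-vs-DE mediation-strength comparison via
# bootstrapped one-way ANOVA + Tukey HSD.

#' Pearson correlation with regression summary
#'
#' @param x,y Paired numeric vectors (>= 3 finite pairs).
#' @return List: r, r_squared, p (two-sided t with n - 2 df, floored at
#'   machine precision), slope, slope_ci (normal-theory 95%), n.
#'   Zero variance in either variable returns `NA`s with a warning.
#' @export
pearson_with_p <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need >= 3 paired finite values")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, r_squared = NA_real_, p = NA_real_,
                slope = NA_real_, slope_ci = c(NA_real_, NA_real_),
                n = n))
  }
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.xmin))
  p <- max(2 * pt(-abs(tstat), n - 2), .Machine$double.xmin)
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2])
  se <- suppressWarnings(summary(fit))$coefficients[2, 2]
  ci <- slope + c(-1, 1) * qt(0.975, n - 2) * se
  list(r = r, r_squared = r^2, p = p, slope = slope, slope_ci = ci,
       n = n)
}

#' Regress network-mediation properties on TPTE across compounds
#'
#' For every property x source x outcome x level stratum with at least
#' three compounds, the compound-level summary value is regressed on the
#' compound's TPTE.
#'
#' @param properties data.frame with columns `compound`, `property`,
#'   `source`, `outcome`, `level`, `value` (compound-level summaries:
#'   mediator totals, iteration-mean peaks, LFC cross-correlations, ...).
#' @param compounds A [compound_table()].
#' @return data.frame (`scaling_result`): property, source, outcome,
#'   level, n_compounds, r, r_squared, p, slope, slope_lo, slope_hi.
#'   Strata with too few compounds are skipped with a warning.
#' @export
tpte_scaling <- function(properties, compounds) {
  req <- c("compound", "property", "source", "outcome", "level", "value")
  stopifnot(all(req %in% names(properties)))
  properties$tpte <- compounds$tpte[match(properties$compound,
                                          compounds$compound)]
  key <- interaction(properties$property, properties$source,
                     properties$outcome, properties$level, drop = TRUE)
  rows <- list()
  for (kk in levels(key)) {
    d <- properties[key == kk, ]
    d <- d[is.finite(d$value) & is.finite(d$tpte), ]
    if (nrow(d) < 3) {
      warning("skipping ", kk, ": fewer than 3 compounds")
      next
    }
    pw <- withCallingHandlers(
      pearson_with_p(d$tpte, d$value),
      warning = function(w) invokeRestart("muffleWarning"))
    rows[[kk]] <- data.frame(
      property = d$property[1], source = d$source[1],
      outcome = d$outcome[1], level = d$level[1],
      n_compounds = pw$n, r = pw$r, r_squared = pw$r_squared, p = pw$p,
      slope = pw$slope, slope_lo = pw$slope_ci[1],
      slope_hi = pw$slope_ci[2], stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(property = character(0), source = character(0),
               outcome = character(0), level = character(0),
               n_compounds = integer(0), r = numeric(0),
               r_squared = numeric(0), p = numeric(0),
               slope = numeric(0), slope_lo = numeric(0),
               slope_hi = numeric(0))
  rownames(out) <- NULL
  class(out) <- c("scaling_result", "data.frame")
  out
}

#' Categorize features for the hub-vs-DE mediation comparison
#'
#' Assigns each feature to `DE_significant` (passes the DE thresholds),
#' `hub_mediator` (consensus hub with significant mediation) or
#' `hub_nonmediator` (consensus hub without), attaching |ACME| from the
#' mediation table.  Features that are both DE-significant and hubs go
#' to the hub category (precedence configurable); features in no
#' category are excluded.
#'
#' @param de_table A [fit_nb_de()] table.
#' @param mediation_table A [mediate_all()] table on the same feature
#'   universe.
#' @param consensus_hubs Character vector of consensus hub feature IDs.
#' @param hub_precedence Give hubs precedence over DE for overlapping
#'   features (default TRUE).
#' @return data.frame: feature_id, category, abs_acme.
#' @export
categorize_features <- function(de_table, mediation_table,
                                consensus_hubs, hub_precedence = TRUE) {
  if (!setequal(de_table$feature_id, mediation_table$feature_id))
    stop("DE and mediation tables cover different feature universes")
  ids <- mediation_table$feature_id
  is_hub <- ids %in% consensus_hubs
  med_sig <- mediation_table$significant
  de_sig <- de_table$significant[match(ids, de_table$feature_id)]
  de_sig[is.na(de_sig)] <- FALSE
  category <- rep(NA_character_, length(ids))
  if (hub_precedence) {
    category[de_sig] <- "DE_significant"
    category[is_hub & !med_sig] <- "hub_nonmediator"
    category[is_hub & med_sig] <- "hub_mediator"
  } else {
    category[is_hub & !med_sig] <- "hub_nonmediator"
    category[is_hub & med_sig] <- "hub_mediator"
    category[de_sig] <- "DE_significant"
  }
  keep <- !is.na(category)
  data.frame(feature_id = ids[keep], category = category[keep],
             abs_acme = abs(mediation_table$acme[keep]),
             stringsAsFactors = FALSE)
}

tukey_pairwise <- function(samples) {
  k <- length(samples)
  ns <- lengths(samples)
  N <- sum(ns)
  means <- vapply(samples, mean, numeric(1))
  ssw <- sum(vapply(samples, function(v) sum((v - mean(v))^2),
                    numeric(1)))
  dfw <- N - k
  mse <- ssw / dfw
  grand <- sum(means * ns) / N
  ssb <- sum(ns * (means - grand)^2)
  fstat <- if (mse > 0) (ssb / (k - 1)) / mse else Inf
  pairs <- utils::combn(k, 2)
  pv <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    if (mse == 0) { pv[j] <- 1; next }
    q <- abs(means[i1] - means[i2]) /
      sqrt(mse / 2 * (1 / ns[i1] + 1 / ns[i2]))
    pv[j] <- ptukey(q, nmeans = k, df = dfw, lower.tail = FALSE)
  }
  list(pairs = pairs, p = pv, f = fstat, degenerate = mse == 0)
}

#' Bootstrapped Tukey HSD comparison of |ACME| categories
#'
#' Per bootstrap iteration, `n_per` observations are resampled with
#' replacement from each category, a one-way ANOVA is computed, and
#' pairwise Tukey HSD p-values are obtained from the studentized-range
#' distribution; pairwise p-values are averaged across iterations.
#' With `n_per = NULL` the full groups are used without resampling
#' (test mode; with `B = 1` this equals a direct Tukey HSD).
#'
#' @param groups Named list of numeric vectors (>= 2 groups of >= 2).
#' @param B Bootstrap iterations (default 1000).
#' @param n_per Resample size per group per iteration (default 100).
#' @param seed RNG seed.
#' @return List: `pairwise` (data.frame group1, group2, p), `anova_f`
#'   (mean F), `degenerate` (TRUE when all within-group variance was
#'   zero).
#' @export
bootstrap_tukey <- function(groups, B = 1000, n_per = 100, seed = 1L) {
  if (length(groups) < 2) stop("need >= 2 groups")
  if (any(lengths(groups) < 2)) stop("every group needs >= 2 values")
  set.seed(seed)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_along(groups))
  acc <- NULL; fs <- numeric(B); degen <- logical(B)
  for (b in seq_len(B)) {
    samples <- if (is.null(n_per)) groups else
      lapply(groups, function(v) sample(v, n_per, replace = TRUE))
    tk <- tukey_pairwise(samples)
    if (is.null(acc)) acc <- tk$p else acc <- acc + tk$p
    fs[b] <- tk$f; degen[b] <- tk$degenerate
  }
  tk0 <- tukey_pairwise(lapply(groups, identity))
  pairwise <- data.frame(group1 = nm[tk0$pairs[1, ]],
                         group2 = nm[tk0$pairs[2, ]],
                         p = acc / B, stringsAsFactors = FALSE)
  list(pairwise = pairwise, anova_f = mean(fs[is.finite(fs)]),
       degenerate = all(degen))
}
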