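#' Sample table: covariates plus per-compound exposure measurements
#'
#' Bundles perinatal covariates with long-format maternal/cord-blood
#' concentration measurements, including left-censoring flags and their
#' detection limits.
#'
#' @param covariates data.frame with columns `sample_id`, `fetal_sex`
#'   (0/1, 1 = male), `gestational_age` (weeks), `birth_weight` (grams),
#'   `spontaneous_labor` (logical).
#' @param exposures data.frame with columns `sample_id`, `compound`,
#'   `source` (`"maternal"` or `"fetal"`), `value` (concentration; `NA`
#'   when censored and not yet imputed), `censor` (one of `"quantified"`,
#'   `"below_loq"`, `"below_lod"`), `lod`, `loq` (detection limits, may be
#'   `NA` for quantified entries).
#'
#' @return An object of class `sample_table`.
#' @export
sample_table <- function(covariates, exposures) {
  req_cov <- c("sample_id", "fetal_sex", "gestational_age", "birth_weight",
               "spontaneous_labor")
  missing_cov <- setdiff(req_cov, names(covariates))
  if (length(missing_cov))
    stop("covariates lacks column(s): ", paste(missing_cov, collapse = ", "))
  req_exp <- c("sample_id", "compound", "source", "value", "censor",
               "lod", "loq")
  missing_exp <- setdiff(req_exp, names(exposures))
  if (length(missing_exp))
    stop("exposures lacks column(s): ", paste(missing_exp, collapse = ", "))
  covariates$sample_id <- as.character(covariates$sample_id)
  exposures$sample_id <- as.character(exposures$sample_id)
  if (anyDuplicated(covariates$sample_id))
    stop("duplicate sample IDs in covariates")
  if (!all(exposures$sample_id %in% covariates$sample_id))
    stop("exposure rows reference unknown sample IDs")
  if (!all(exposures$source %in% c("maternal", "fetal")))
    stop("exposure source must be 'maternal' or 'fetal'")
  if (!all(exposures$censor %in% c("quantified", "below_loq", "below_lod")))
    stop("censor flags must be quantified/below_loq/below_lod")
  ga <- covariates$gestational_age
  bw <- covariates$birth_weight
  if (any(!is.na(ga) & ga <= 0)) stop("gestational_age must be positive")
  if (any(!is.na(bw) & bw <= 0)) stop("birth_weight must be positive")
  bad <- !is.na(exposures$value) & exposures$value < 0
  if (any(bad)) stop("concentrations must be non-negative")
  structure(list(covariates = covariates, exposures = exposures),
            class = "sample_table")
}

#' @export
print.sample_table <- function(x, ...) {
  cat("sample_table:", nrow(x$covariates), "samples,",
      length(unique(x$exposures$compound)), "compounds,",
      nrow(x$exposures), "exposure measurements\n")
  invisible(x)
}

#' Number of samples in a sample table
#' @param samples A [sample_table()].
#' @return Integer sample count.
#' @export
n_samples <- function(samples) nrow(samples$covariates)

#' Expression study container
#'
#' A feature-by-sample integer count matrix with its transcript-to-gene
#' map and sample metadata.  Features are transcripts (`level =
#' "transcript"`) or aggregated genes (`level = "gene"`).
#'
#' @param counts Non-negative integer matrix, features in rows (rownames =
#'   feature IDs), samples in columns (colnames = sample IDs).
#' @param tx2gene data.frame with columns `transcript_id`, `gene_id`.
#' @param samples A [sample_table()]; every count column must match a
#'   sample record.
#' @param level `"transcript"` or `"gene"`.
#'
#' @return An object of class `expression_study`.
#' @export
expression_study <- function(counts, tx2gene, samples,
                             level = c("transcript", "gene")) {
  level <- match.arg(level)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry feature rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate feature IDs in counts")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!inherits(samples, "sample_table"))
    stop("samples must be a sample_table")
  unknown <- setdiff(colnames(counts), samples$covariates$sample_id)
  if (length(unknown))
    stop("count columns without sample records: ",
         paste(head(unknown, 5L), collapse = ", "))
  if (!all(c("transcript_id", "gene_id") %in% names(tx2gene)))
    stop("tx2gene needs columns transcript_id, gene_id")
  if (level == "gene" && !all(rownames(counts) %in% tx2gene$gene_id))
    stop("gene-level feature IDs must appear in tx2gene$gene_id")
  structure(list(counts = counts, tx2gene = tx2gene, samples = samples,
                 level = level),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study (", x$level, " level): ",
      nrow(x$counts), " features x ", ncol(x$counts), " samples\n", sep = "")
  invisible(x)
}

#' Compound table with transfer efficiencies
#'
#' @param compound Character vector of unique compound names.
#' @param tpte Positive transplacental transfer efficiencies
#'   (cord:maternal concentration ratio).
#' @param chain_length Optional integer carbon chain lengths (metadata).
#'
#' @return data.frame of class `compound_table`.
#' @export
compound_table <- function(compound, tpte, chain_length = NA_integer_) {
  if (anyDuplicated(compound)) stop("compound names must be unique")
  if (any(!is.finite(tpte)) || any(tpte <= 0)) stop("tpte must be > 0")
  out <- data.frame(compound = as.character(compound), tpte = tpte,
                    chain_length = chain_length,
                    stringsAsFactors = FALSE)
  class(out) <- c("compound_table", "data.frame")
  out
}

#' Impute left-censored concentrations
#'
#' Replaces below-LOQ values by LOQ/2 and below-LOD values by LOD/2, the
#' standard convention for left-censored exposure biomarkers; quantified
#' values and all flags are left untouched.
#'
#' @param samples A [sample_table()].
#' @return A [sample_table()] with imputed `value`s.
#' @export
impute_censored <- function(samples) {
  ex <- samples$exposures
  loq_idx <- ex$censor == "below_loq"
  lod_idx <- ex$censor == "below_lod"
  bad <- (loq_idx & !is.finite(ex$loq)) | (lod_idx & !is.finite(ex$lod))
  if (any(bad)) {
    b <- ex[bad, , drop = FALSE][1L, ]
    stop("censored entry with missing limit: sample ", b$sample_id,
         ", compound ", b$compound, " (", b$source, ")")
  }
  ex$value[loq_idx] <- ex$loq[loq_idx] / 2
  ex$value[lod_idx] <- ex$lod[lod_idx] / 2
  samples$exposures <- ex
  samples
}

#' Transplacental transfer efficiency for one compound
#'
#' TPTE is the mean over samples of the cord(fetal):maternal concentration
#' ratio, using samples with both measurements available (after censoring
#' imputation).  Samples with a zero maternal concentration are excluded
#' with a warning.
#'
#' @param samples A [sample_table()] (run [impute_censored()] first when
#'   censored entries are present).
#' @param compound Compound name.
#' @return Mean fetal/maternal ratio (dimensionless).
#' @export
compute_tpte <- function(samples, compound) {
  ex <- samples$exposures[samples$exposures$compound == compound, ,
                          drop = FALSE]
  if (!nrow(ex)) stop("no measurements for compound ", compound)
  mat <- ex[ex$source == "maternal", c("sample_id", "value")]
  fet <- ex[ex$source == "fetal", c("sample_id", "value")]
  m <- merge(mat, fet, by = "sample_id", suffixes = c("_m", "_f"))
  m <- m[is.finite(m$value_m) & is.finite(m$value_f), , drop = FALSE]
  zero <- m$value_m == 0
  if (any(zero)) {
    warning(sum(zero), " sample(s) with zero maternal concentration ",
            "excluded for ", compound)
    m <- m[!zero, , drop = FALSE]
  }
  if (!nrow(m)) stop("no valid maternal-fetal pairs for ", compound)
  mean(m$value_f / m$value_m)
}

#' Empirical TPTE table over all compounds
#'
#' @param samples A [sample_table()].
#' @param override Optional named numeric vector of cohort-level TPTE
#'   values to use instead of the empirical ratio (the study design may
#'   reuse previously published cohort estimates).
#' @param chain_length Optional named integer vector of chain lengths.
#' @return A [compound_table()].
#' @export
tpte_table <- function(samples, override = NULL, chain_length = NULL) {
  compounds <- sort(unique(samples$exposures$compound))
  tpte <- vapply(compounds, function(cp) {
    if (!is.null(override) && cp %in% names(override)) override[[cp]]
    else compute_tpte(samples, cp)
  }, numeric(1))
  cl <- if (is.null(chain_length)) NA_integer_ else
    unname(chain_length[compounds])
  compound_table(compounds, tpte, cl)
}

#' Z-score a numeric vector
#'
#' Centers to mean 0 and scales to sample standard deviation 1
#' (denominator n - 1).
#'
#' @param values Numeric vector with at least two finite values.
#' @return Standardized vector.
#' @export
zscore <- function(values) {
  ok <- is.finite(values)
  if (sum(ok) < 2) stop("zscore needs at least 2 finite values")
  s <- sd(values[ok])
  if (!is.finite(s) || s == 0) stop("zscore undefined for zero variance")
  (values - mean(values[ok])) / s
}

#' Aggregate transcript counts to gene level
#'
#' Gene counts are the per-sample sum of member transcript counts; column
#' order is preserved and total counts per sample are conserved exactly.
#'
#' @param study Transcript-level [expression_study()] whose features are
#'   all present in `tx2gene`.
#' @return Gene-level [expression_study()].
#' @export
aggregate_to_gene <- function(study) {
  if (study$level != "transcript")
    stop("aggregate_to_gene expects a transcript-level study")
  map <- setNames(as.character(study$tx2gene$gene_id),
                  as.character(study$tx2gene$transcript_id))
  missing <- setdiff(rownames(study$counts), names(map))
  if (length(missing))
    stop("transcripts absent from tx2gene: ",
         paste(head(missing, 10L), collapse = ", "))
  genes <- map[rownames(study$counts)]
  # keep genes in order of first appearance
  gene_counts <- rowsum(study$counts, group = genes, reorder = FALSE)
  expression_study(gene_counts, study$tx2gene, study$samples, level = "gene")
}

#' Drop features with insufficient counts
#'
#' Retains features with at least `min_count` reads in at least
#' `min_samples` samples, preserving row order.
#'
#' @param study An [expression_study()].
#' @param min_count Minimum read count (default 5).
#' @param min_samples Minimum number of samples reaching it (default 3).
#' @return Filtered [expression_study()].
#' @export
filter_low_counts <- function(study, min_count = 5, min_samples = 3) {
  keep <- rowSums(study$counts >= min_count) >= min_samples
  if (!any(keep)) stop("no features pass the count filter")
  study$counts <- study$counts[keep, , drop = FALSE]
  study
}
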