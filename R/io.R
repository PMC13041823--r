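# On-disk layout (one directory per study):
#   counts.tsv      feature_id + one column per sample (integer counts)
#   tx2gene.tsv     transcript_id, gene_id
#   samples.csv     sample covariates
#   exposures.csv   long table: sample_id, compound, source, value,
#                   censor, lod, loq  (missing values are empty fields)
#   compounds.csv   compound, tpte, chain_length (optional)

fmt_num <- function(x) {
  # 17 significant digits: doubles round-trip through text bit-exactly
  ifelse(is.na(x), "", sprintf("%.17g", x))
}

#' Write an expression study to a directory
#'
#' @param study An [expression_study()].
#' @param dir Output directory (created if needed).
#' @param compounds Optional [compound_table()] written alongside.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir, compounds = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cnt <- data.frame(feature_id = rownames(study$counts),
                    study$counts, check.names = FALSE)
  write.table(cnt, file.path(dir, "counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(study$tx2gene, file.path(dir, "tx2gene.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cov <- study$samples$covariates
  cov$gestational_age <- fmt_num(cov$gestational_age)
  cov$birth_weight <- fmt_num(cov$birth_weight)
  write.csv(cov, file.path(dir, "samples.csv"), row.names = FALSE,
            quote = FALSE, na = "")
  ex <- study$samples$exposures
  ex$value <- fmt_num(ex$value)
  ex$lod <- fmt_num(ex$lod)
  ex$loq <- fmt_num(ex$loq)
  write.csv(ex, file.path(dir, "exposures.csv"), row.names = FALSE,
            quote = FALSE, na = "")
  if (!is.null(compounds))
    write.csv(compounds, file.path(dir, "compounds.csv"),
              row.names = FALSE, na = "")
  writeLines(study$level, file.path(dir, "level.txt"))
  invisible(dir)
}

#' Read an expression study from a directory written by [write_study()]
#'
#' @param dir Study directory.
#' @return List with elements `study` ([expression_study()]) and
#'   `compounds` ([compound_table()] or `NULL`).
#' @export
read_study <- function(dir) {
  cnt <- read.delim(file.path(dir, "counts.tsv"), check.names = FALSE)
  counts <- as.matrix(cnt[, -1, drop = FALSE])
  rownames(counts) <- cnt$feature_id
  storage.mode(counts) <- "integer"
  tx2gene <- read.delim(file.path(dir, "tx2gene.tsv"),
                        colClasses = "character")
  cov <- read.csv(file.path(dir, "samples.csv"),
                  colClasses = c(sample_id = "character"))
  cov$spontaneous_labor <- as.logical(cov$spontaneous_labor)
  ex <- read.csv(file.path(dir, "exposures.csv"),
                 colClasses = c(sample_id = "character"))
  level <- readLines(file.path(dir, "level.txt"))[1]
  samples <- sample_table(cov, ex)
  compounds <- NULL
  cf <- file.path(dir, "compounds.csv")
  if (file.exists(cf)) {
    cc <- read.csv(cf)
    compounds <- compound_table(cc$compound, cc$tpte, cc$chain_length)
  }
  list(study = expression_study(counts, tx2gene, samples, level = level),
       compounds = compounds)
}
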