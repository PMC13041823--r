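# End-to-end orchestration: simulate -> prepare -> DE -> mediation ->
# network sweep -> topology -> TPTE scaling -> hub-vs-DE comparison,
# with a manifest (config hash, per-stage seeds, file checksums) and
# checksum-based stage resumption.

#' Analysis configuration
#'
#' Thresholds and sweep settings for [run_pipeline()].  Defaults follow
#' the package's standard analysis: DE calls at BH FDR < 0.10 with
#' |log2FC| > 1, mediation calls at BH FDR < 0.05 with a 95% CI
#' excluding zero, adjacency floor 0.10, scale-free fit cut 0.85,
#' transcript powers 3,4,5 / gene powers 14,15,16, 1000 quasi-Bayesian
#' draws, and Tukey bootstrap 1000 x 100.  `grid = "demo"` sweeps a
#' reduced 12-combination grid (2 powers x 2 sizes x 1 split x 3
#' merges); `grid = "full"` the complete 144-combination grid.
#'
#' @param de_fdr,de_lfc,mediation_fdr,adjacency_floor,scale_free_cut
#'   Analysis thresholds.
#' @param powers_transcript,powers_gene Soft-thresholding power triplets.
#' @param grid `"demo"`, `"full"`, or a data.frame of grid rows from
#'   [network_params_grid()] for a custom sweep.
#' @param n_sims Quasi-Bayesian draws per mediation fit.
#' @param bootstrap_B,bootstrap_n Tukey bootstrap settings.
#' @param n_hubs Hubs per module per iteration.
#' @param kde_min_values Minimum path count for a KDE-mode peak.
#' @param seed Master seed; per-stage seeds derive from it.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(de_fdr = 0.10, de_lfc = 1,
                            mediation_fdr = 0.05,
                            adjacency_floor = 0.10,
                            scale_free_cut = 0.85,
                            powers_transcript = c(3, 4, 5),
                            powers_gene = c(14, 15, 16),
                            grid = c("demo", "full"),
                            n_sims = 1000,
                            bootstrap_B = 1000, bootstrap_n = 100,
                            n_hubs = 10, kde_min_values = 3,
                            seed = 1L) {
  if (!is.data.frame(grid)) grid <- match.arg(grid)
  structure(list(de_fdr = de_fdr, de_lfc = de_lfc,
                 mediation_fdr = mediation_fdr,
                 adjacency_floor = adjacency_floor,
                 scale_free_cut = scale_free_cut,
                 powers_transcript = powers_transcript,
                 powers_gene = powers_gene, grid = grid,
                 n_sims = n_sims, bootstrap_B = bootstrap_B,
                 bootstrap_n = bootstrap_n, n_hubs = n_hubs,
                 kde_min_values = kde_min_values,
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Build the sweep grid implied by a configuration
#'
#' @param config An [analysis_config()].
#' @param level `"transcript"` or `"gene"` (selects the power triplet).
#' @return data.frame as from [network_params_grid()].
#' @export
config_grid <- function(config, level = "transcript") {
  if (is.data.frame(config$grid)) return(config$grid)
  powers <- if (level == "transcript") config$powers_transcript
            else config$powers_gene
  if (config$grid == "full")
    network_params_grid(powers)
  else
    network_params_grid(powers[1:2], min_module_size = c(30, 50),
                        deep_split = 3,
                        merge_cut_height = c(0.15, 0.20, 0.25))
}

#' Validate a configuration (or a configuration YAML file)
#'
#' @param config An [analysis_config()], a plain list, or a path to a
#'   YAML file of configuration fields.
#' @return List: `ok`, `errors` (character), `grid_size` (full-grid
#'   product).  Schema violations are itemized, not raised.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- do.call(analysis_config,
                      yaml::read_yaml(config))
  }
  if (!inherits(config, "analysis_config"))
    config <- do.call(analysis_config, config)
  errors <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond))
    errors <<- c(errors, msg)
  chk(is.numeric(config$de_fdr) && config$de_fdr > 0 &&
        config$de_fdr < 1, "de_fdr must lie in (0, 1)")
  chk(config$mediation_fdr > 0 && config$mediation_fdr < 1,
      "mediation_fdr must lie in (0, 1)")
  chk(config$adjacency_floor >= 0 && config$adjacency_floor < 1,
      "adjacency_floor must lie in [0, 1)")
  chk(config$scale_free_cut > 0 && config$scale_free_cut <= 1,
      "scale_free_cut must lie in (0, 1]")
  chk(all(config$powers_transcript == round(config$powers_transcript)) &&
        all(config$powers_transcript > 0),
      "powers must be positive integers")
  chk(length(config$seed) == 1 && is.finite(config$seed),
      "seed is required")
  chk(config$n_sims >= 100, "n_sims must be >= 100")
  grid_size <- nrow(network_params_grid(config$powers_transcript))
  list(ok = !length(errors), errors = errors, grid_size = grid_size)
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(as.character(jsonlite::toJSON(
    config[order(names(config))], auto_unbox = TRUE, digits = NA)), tf)
  unname(tools::md5sum(tf))
}

write_result_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v)
    ifelse(is.na(v), NA, sprintf("%.12g", v)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# exposure z-scores (log scale, imputed) for one compound-source over
# the samples carrying a measurement
exposure_zscores <- function(samples, compound, source) {
  ex <- samples$exposures
  ex <- ex[ex$compound == compound & ex$source == source &
             is.finite(ex$value), ]
  setNames(zscore(log(ex$value)), ex$sample_id)
}

# sample-by-variable matrix of all exposure z-scores (complete cases)
exposure_matrix <- function(samples, ids) {
  ex <- samples$exposures
  combos <- unique(ex[, c("compound", "source")])
  out <- matrix(NA_real_, length(ids), nrow(combos),
                dimnames = list(ids, paste(combos$compound,
                                           combos$source, sep = "_")))
  for (i in seq_len(nrow(combos))) {
    z <- exposure_zscores(samples, combos$compound[i], combos$source[i])
    out[intersect(ids, names(z)), i] <- z[intersect(ids, names(z))]
  }
  out[is.na(out)] <- 0  # absent measurements carry no protected signal
  out
}

#' Run the full analysis pipeline on a (synthetic) study
#'
#' Executes all stages in dependency order under one configuration,
#' writing per-stage TSV/JSON outputs and a manifest (config hash,
#' per-stage seeds, file checksums) under `outdir`.  With `resume =
#' TRUE`, stages whose outputs exist with checksums matching the
#' manifest are skipped and reloaded; a corrupted or missing output
#' forces re-execution of its stage.
#'
#' @param design A [simulation_design()] for the synthetic study.
#' @param config An [analysis_config()].
#' @param outdir Run directory.
#' @param resume Reuse up-to-date stage outputs (default TRUE).
#' @return Invisible list with all in-memory stage results: `study`,
#'   `compounds`, `truth`, `de`, `mediation`, `sweeps`, `topology`,
#'   `properties`, `scaling`, `comparison`, `manifest`.
#' @export
run_pipeline <- function(design = simulation_design(),
                         config = analysis_config(),
                         outdir, resume = TRUE) {
  val <- validate_config(config)
  if (!val$ok) stop("invalid config:\n  ",
                    paste(val$errors, collapse = "\n  "))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  man_path <- file.path(outdir, "manifest.json")
  manifest <- if (resume && file.exists(man_path))
    jsonlite::read_json(man_path, simplifyVector = TRUE)
  else list(config_hash = config_hash(config),
            seed = config$seed, stages = list())
  if (!identical(manifest$config_hash, config_hash(config))) {
    manifest <- list(config_hash = config_hash(config),
                     seed = config$seed, stages = list())
  }
  save_manifest <- function() jsonlite::write_json(
    manifest, man_path, auto_unbox = TRUE, digits = NA)
  stage_fresh <- function(name, files) {
    st <- manifest$stages[[name]]
    if (is.null(st)) return(FALSE)
    paths <- file.path(outdir, files)
    all(file.exists(paths)) &&
      identical(unname(tools::md5sum(paths)), unname(unlist(st$md5)))
  }
  record_stage <- function(name, files, seed) {
    paths <- file.path(outdir, files)
    manifest$stages[[name]] <<- list(
      files = files, md5 = as.list(unname(tools::md5sum(paths))),
      seed = seed, status = "done")
    save_manifest()
  }

  # --- simulate ----------------------------------------------------------
  study_files <- file.path("study", c("counts.tsv", "tx2gene.tsv",
                                      "samples.csv", "exposures.csv",
                                      "compounds.csv", "truth.json"))
  if (stage_fresh("simulate", study_files)) {
    sr <- read_study(file.path(outdir, "study"))
    sim <- list(study = sr$study, compounds = sr$compounds,
                truth = read_ground_truth(
                  file.path(outdir, "study", "truth.json")))
  } else {
    sim <- generate_study(design, dir = file.path(outdir, "study"))
    record_stage("simulate", study_files, design$seed)
  }
  study <- filter_low_counts(impute_censored_study(sim$study))
  compounds <- sim$compounds
  combos <- expand.grid(compound = compounds$compound,
                        source = c("fetal", "maternal"),
                        stringsAsFactors = FALSE)
  cov <- study$samples$covariates
  outcomes <- c("birth_weight", "gestational_age")

  # --- normalized expression with one latent technical factor removed ---
  # (per outcome sample set; the estimated factor also serves as the
  # technical covariate in the differential-expression models)
  exprs <- list(); ruv <- list()
  for (oc in outcomes) {
    ids <- colnames(study$counts)
    if (oc == "gestational_age")
      ids <- intersect(ids,
                       cov$sample_id[cov$spontaneous_labor %in% TRUE])
    sub <- study
    sub$counts <- study$counts[, ids, drop = FALSE]
    expr <- prefilter_and_normalize(sub)
    expr <- remove_latent_factor(expr,
                                 exposure_matrix(study$samples, ids))
    exprs[[oc]] <- expr
    ruv[[oc]] <- setNames(as.numeric(attr(expr, "factor")), ids)
  }

  # --- differential expression ------------------------------------------
  de_files <- file.path("de", sprintf("de_transcript_%s_%s.tsv",
                                      combos$compound, combos$source))
  dir.create(file.path(outdir, "de"), showWarnings = FALSE)
  de <- list()
  if (stage_fresh("de", de_files)) {
    for (i in seq_len(nrow(combos)))
      de[[paste(combos$compound[i], combos$source[i], sep = "_")]] <-
        read.delim(file.path(outdir, de_files[i]))
  } else {
    for (i in seq_len(nrow(combos))) {
      key <- paste(combos$compound[i], combos$source[i], sep = "_")
      x <- exposure_zscores(study$samples, combos$compound[i],
                            combos$source[i])
      ids <- intersect(colnames(study$counts), names(x))
      cv <- cov[match(ids, cov$sample_id), ]
      de[[key]] <- fit_nb_de(
        study, x[ids],
        covariates = cbind(sex = cv$fetal_sex,
                           ga_z = zscore(cv$gestational_age),
                           ruv = ruv$birth_weight[ids]),
        fdr = config$de_fdr, lfc = config$de_lfc)
      write_result_tsv(de[[key]], file.path(outdir, de_files[i]))
    }
    record_stage("de", de_files, config$seed)
  }

  # --- mediation ---------------------------------------------------------
  med_grid <- merge(combos, data.frame(outcome = outcomes), by = NULL)
  med_files <- file.path("mediation",
                         sprintf("mediation_%s_%s_%s.tsv",
                                 med_grid$compound, med_grid$source,
                                 med_grid$outcome))
  dir.create(file.path(outdir, "mediation"), showWarnings = FALSE)
  med <- list()
  if (stage_fresh("mediate", med_files)) {
    for (i in seq_len(nrow(med_grid)))
      med[[paste(med_grid$compound[i], med_grid$source[i],
                 med_grid$outcome[i], sep = "_")]] <-
        read.delim(file.path(outdir, med_files[i]))
  } else {
    for (i in seq_len(nrow(med_grid))) {
      key <- paste(med_grid$compound[i], med_grid$source[i],
                   med_grid$outcome[i], sep = "_")
      med[[key]] <- mediate_all(study, med_grid$compound[i],
                                med_grid$source[i],
                                outcome = med_grid$outcome[i],
                                n_sims = config$n_sims,
                                seed = config$seed,
                                fdr = config$mediation_fdr,
                                mediator_matrix =
                                  exprs[[med_grid$outcome[i]]])
      write_result_tsv(med[[key]], file.path(outdir, med_files[i]))
    }
    record_stage("mediate", med_files, config$seed)
  }

  # --- network sweep (per outcome sample set) ---------------------------
  grid <- config_grid(config, "transcript")
  sweeps <- list()
  for (oc in outcomes)
    sweeps[[oc]] <- run_sweep(exprs[[oc]], grid,
                              n_hubs = config$n_hubs)
  hub_file <- "network/consensus_hubs.tsv"
  dir.create(file.path(outdir, "network"), showWarnings = FALSE)
  write_result_tsv(data.frame(outcome = rep(outcomes, vapply(
    sweeps, function(s) length(s$hubs), integer(1))),
    feature_id = unlist(lapply(sweeps, `[[`, "hubs"))),
    file.path(outdir, hub_file))
  record_stage("network", hub_file, config$seed)

  # --- topology ----------------------------------------------------------
  sig_meds <- function(oc) {
    rows <- list()
    for (i in seq_len(nrow(combos))) {
      key <- paste(combos$compound[i], combos$source[i], oc, sep = "_")
      tab <- med[[key]]
      sig <- tab$feature_id[tab$significant %in% TRUE]
      if (length(sig))
        rows[[key]] <- data.frame(feature_id = sig,
                                  compound = combos$compound[i],
                                  source = combos$source[i],
                                  stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(feature_id = character(0), compound = character(0),
                 source = character(0))
  }
  topo <- list()
  for (oc in outcomes)
    topo[[oc]] <- suppressWarnings(summarize_topology(
      exprs[[oc]], sweeps[[oc]], sig_meds(oc),
      min_adjacency = config$adjacency_floor,
      min_values = config$kde_min_values))
  topo_files <- sprintf("topology/units_%s.tsv", outcomes)
  dir.create(file.path(outdir, "topology"), showWarnings = FALSE)
  for (i in seq_along(outcomes))
    write_result_tsv(topo[[outcomes[i]]]$units,
                     file.path(outdir, topo_files[i]))
  record_stage("topology", topo_files, config$seed)

  # --- scaling -----------------------------------------------------------
  properties <- assemble_properties(med, topo, de, combos, outcomes)
  scaling <- suppressWarnings(tpte_scaling(properties, compounds))
  dir.create(file.path(outdir, "scaling"), showWarnings = FALSE)
  write_result_tsv(properties, file.path(outdir,
                                         "scaling/properties.tsv"))
  write_result_tsv(scaling, file.path(outdir, "scaling/scaling.tsv"))
  fig_summary <- scaling[, c("property", "source", "outcome", "slope",
                             "slope_lo", "slope_hi", "p")]
  fig_summary$significant <- fig_summary$p < 0.05
  jsonlite::write_json(fig_summary,
                       file.path(outdir, "scaling/summary.json"),
                       dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  record_stage("scaling",
               c("scaling/properties.tsv", "scaling/scaling.tsv",
                 "scaling/summary.json"), config$seed)

  # --- hub-vs-DE comparison (birth weight, pooled over combos) ----------
  cats <- list()
  for (i in seq_len(nrow(combos))) {
    key_de <- paste(combos$compound[i], combos$source[i], sep = "_")
    key_med <- paste(key_de, "birth_weight", sep = "_")
    de_tab <- de[[key_de]]; med_tab <- med[[key_med]]
    shared <- intersect(de_tab$feature_id, med_tab$feature_id)
    cats[[key_de]] <- categorize_features(
      de_tab[de_tab$feature_id %in% shared, ],
      med_tab[med_tab$feature_id %in% shared, ],
      sweeps$birth_weight$hubs)
  }
  cats <- do.call(rbind, cats)
  groups <- split(cats$abs_acme, cats$category)
  groups <- groups[lengths(groups) >= 2]
  comparison <- NULL
  if (length(groups) >= 2) {
    comparison <- bootstrap_tukey(groups, B = config$bootstrap_B,
                                  n_per = config$bootstrap_n,
                                  seed = config$seed)
    write_result_tsv(comparison$pairwise,
                     file.path(outdir, "scaling/comparison.tsv"))
    record_stage("compare", "scaling/comparison.tsv", config$seed)
  }

  invisible(list(study = study, compounds = compounds,
                 truth = sim$truth, de = de, mediation = med,
                 sweeps = sweeps, topology = topo,
                 properties = properties, scaling = scaling,
                 comparison = comparison, categories = cats,
                 manifest = man_path))
}

# study-level wrapper: impute censored concentrations inside the
# embedded sample table
impute_censored_study <- function(study) {
  study$samples <- impute_censored(study$samples)
  study
}

# compound-level property table feeding the TPTE scaling regressions
assemble_properties <- function(med, topo, de, combos, outcomes) {
  rows <- list()
  for (oc in outcomes) {
    for (i in seq_len(nrow(combos))) {
      key <- paste(combos$compound[i], combos$source[i], oc, sep = "_")
      tab <- med[[key]]
      rows[[paste0("count_", key)]] <- data.frame(
        compound = combos$compound[i], property = "mediator_count",
        source = combos$source[i], outcome = oc, level = "transcript",
        value = sum(tab$significant %in% TRUE),
        stringsAsFactors = FALSE)
    }
    summ <- topo[[oc]]$summary
    if (!is.null(summ)) for (j in seq_len(nrow(summ))) {
      base <- data.frame(compound = summ$compound[j],
                         source = summ$source[j], outcome = oc,
                         level = "transcript", stringsAsFactors = FALSE)
      rows[[paste0("pk_", oc, j)]] <- cbind(
        base, property = "peak_kme", value = summ$peak_kme[j])
      rows[[paste0("pd_", oc, j)]] <- cbind(
        base, property = "peak_distance", value = summ$peak_distance[j])
      rows[[paste0("ct_", oc, j)]] <- cbind(
        base, property = "centrality", value = -summ$peak_distance[j])
    }
    comp <- topo[[oc]]$compartmentalization
    if (!is.null(comp)) for (j in seq_len(nrow(comp)))
      rows[[paste0("cp_", oc, j)]] <- data.frame(
        compound = comp$compound[j], property = "compartmentalization",
        source = "both", outcome = oc, level = "transcript",
        value = comp$compartmentalization[j], stringsAsFactors = FALSE)
  }
  for (cp in unique(combos$compound)) {
    dm <- de[[paste(cp, "maternal", sep = "_")]]
    df <- de[[paste(cp, "fetal", sep = "_")]]
    if (!is.null(dm) && !is.null(df))
      rows[[paste0("xc_", cp)]] <- data.frame(
        compound = cp, property = "lfc_cross_correlation",
        source = "both", outcome = "none", level = "transcript",
        value = suppressWarnings(lfc_cross_correlation(dm, df)),
        stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[, c("compound", "property", "source", "outcome", "level",
                 "value")]
  rownames(out) <- NULL
  out
}
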