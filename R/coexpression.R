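# Signed weighted co-expression networks with a parameter sweep.
#
# Clustering is a "static-cut-lite": the average-linkage TOM-dissimilarity
# dendrogram is cut at a height quantile controlled by the deep-split
# level ({2, 3, 4} -> {0.97, 0.95, 0.92}); deeper split levels cut lower
# and can only refine the partition, so the module count is monotone in
# deep_split by construction.  Clusters below the minimum size are left
# unassigned, and eigengene-based merging recombines near-duplicate
# modules.  This reproduces the deeper-split -> more-modules behaviour of
# hybrid dynamic tree cutting without its full machinery; exact equality
# with that algorithm is a non-goal.

#' Prefilter counts and return normalized expression for network analysis
#'
#' Retains features detected (nonzero) in at least `min_detect_prop` of
#' samples, applies the variance-stabilizing transform, then drops
#' features whose variance is not above the `var_quantile` quantile of
#' feature variances.
#'
#' @param study A count-filtered [expression_study()].
#' @param min_detect_prop Detection fraction (default 0.20).
#' @param var_quantile Variance quantile floor (default 0.10).
#' @param min_features Minimum surviving features (default 50).
#' @return Feature-by-sample matrix of transformed expression.
#' @export
prefilter_and_normalize <- function(study, min_detect_prop = 0.2,
                                    var_quantile = 0.1,
                                    min_features = 50) {
  counts <- study$counts
  keep <- rowMeans(counts > 0) >= min_detect_prop
  expr <- vst_counts(counts[keep, , drop = FALSE])
  v <- apply(expr, 1, var)
  expr <- expr[v > quantile(v, var_quantile), , drop = FALSE]
  if (nrow(expr) < min_features)
    stop("fewer than ", min_features, " features survive prefiltering")
  expr
}

#' Remove one latent factor of technical variation
#'
#' Estimates the factor as the first principal component of the residuals
#' of expression regressed on the exposure design (so exposure-associated
#' variation cannot leak into it), then removes it from each feature
#' while protecting the exposure terms
#' (via [limma::removeBatchEffect()]).
#'
#' @param expr Feature-by-sample expression matrix.
#' @param exposures Sample-by-variable matrix of exposure z-scores whose
#'   associated variation must be preserved.
#' @return Corrected expression matrix and the factor in
#'   `attr(, "factor")`.
#' @export
remove_latent_factor <- function(expr, exposures) {
  X <- cbind(1, as.matrix(exposures))
  P <- X %*% solve(crossprod(X)) %*% t(X)
  R <- expr - expr %*% P
  w <- svd(R, nu = 0, nv = 1)$v[, 1]
  out <- limma::removeBatchEffect(expr, covariates = w,
                                  design = X)
  attr(out, "factor") <- w
  out
}

scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < n_bins) return(0)
  cuts <- cut(k, breaks = n_bins)
  dk <- tapply(k, cuts, mean)
  pk <- tapply(k, cuts, length) / length(k)
  ok <- !is.na(dk) & pk > 0
  if (sum(ok) < 3) return(0)
  fit <- lm(log10(pk[ok]) ~ log10(dk[ok]))
  r2 <- summary(fit)$r.squared
  -sign(coef(fit)[2]) * r2
}

#' Select soft-thresholding powers by scale-free topology fit
#'
#' For each candidate power the signed adjacency is formed, per-node
#' connectivity computed, and the signed scale-free fit index
#' `-sign(slope) * R^2` of `log10 p(k)` on `log10 mean(k)` over 10
#' connectivity bins evaluated.  The first `n_powers` integers reaching
#' `rsq_cut` are returned (fewer, with a warning, when fewer pass).
#'
#' @param expr Feature-by-sample expression matrix.
#' @param candidates Ascending integer candidate powers.
#' @param rsq_cut Fit threshold (default 0.85).
#' @param n_powers How many powers to return (default 3).
#' @return Integer vector of selected powers; the per-candidate fit table
#'   is attached as `attr(, "fits")`.
#' @export
pick_soft_powers <- function(expr, candidates = 1:20, rsq_cut = 0.85,
                             n_powers = 3) {
  cm <- cor(t(expr))
  fits <- vapply(candidates, function(beta) {
    a <- ((1 + cm) / 2)^beta
    scale_free_fit(rowSums(a) - 1)
  }, numeric(1))
  tab <- data.frame(power = candidates, fit = fits)
  pass <- candidates[fits >= rsq_cut]
  if (!length(pass)) {
    stop("no candidate power reaches scale-free fit ", rsq_cut, ":\n",
         paste(sprintf("  power %d: %.3f", tab$power, tab$fit),
               collapse = "\n"))
  }
  if (length(pass) < n_powers)
    warning("only ", length(pass), " power(s) reach fit ", rsq_cut)
  sel <- pass[seq_len(min(n_powers, length(pass)))]
  attr(sel, "fits") <- tab
  sel
}

#' Signed adjacency matrix
#'
#' `a_ij = ((1 + cor_ij) / 2)^power` with unit diagonal; anticorrelated
#' features get near-zero adjacency.
#'
#' @param expr Feature-by-sample expression matrix.
#' @param power Soft-thresholding power.
#' @return Feature-by-feature adjacency in `[0, 1]`; the Pearson
#'   correlation matrix is attached as `attr(, "cor")`.
#' @export
signed_adjacency <- function(expr, power) {
  if (ncol(expr) < 3) stop("need >= 3 samples")
  cm <- cor(t(expr))
  a <- ((1 + cm) / 2)^power
  diag(a) <- 1
  attr(a, "cor") <- cm
  a
}

#' Topological overlap from an adjacency matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' the sum over shared neighbours `u != i, j` and `k` the off-diagonal
#' row sums; diagonal 1.
#'
#' @param adjacency Symmetric adjacency with unit diagonal.
#' @return TOM similarity matrix.
#' @export
tom_similarity <- function(adjacency) {
  A <- adjacency
  attr(A, "cor") <- NULL
  S <- A %*% A
  k <- rowSums(A) - 1
  num <- S - A              # = sum_{u != i,j} a_iu a_uj + a_ij
  den <- outer(k, k, pmin) + 1 - A
  tom <- num / den
  diag(tom) <- 1
  tom
}

# ---- clustering ----------------------------------------------------------

cut_quantile <- function(deep_split) {
  q <- c(`2` = 0.97, `3` = 0.95, `4` = 0.92)[as.character(deep_split)]
  if (is.na(q)) stop("deep_split must be one of 2, 3, 4")
  unname(q)
}

cluster_from_hc <- function(hc, expr, params) {
  h_cut <- as.numeric(quantile(hc$height,
                               cut_quantile(params$deep_split)))
  labels0 <- cutree(hc, h = h_cut)
  labels <- integer(length(labels0))
  kidx <- 0L
  for (cl in sort(unique(labels0))) {
    members <- which(labels0 == cl)
    if (length(members) >= params$min_module_size) {
      kidx <- kidx + 1L
      labels[members] <- kidx
    }
  }
  if (kidx == 0L)
    warning("no cluster reaches min_module_size; all features unassigned")
  labels
}

module_eigengene <- function(expr, members) {
  Xm <- expr[members, , drop = FALSE]
  Xm <- (Xm - rowMeans(Xm)) / apply(Xm, 1, sd)
  e <- svd(Xm, nu = 0, nv = 1)$v[, 1]
  if (mean(cor(t(Xm), e)) < 0) e <- -e
  e
}

compute_assignment <- function(expr, labels, params,
                               pam_kme = 0.6) {
  mods <- sort(unique(labels[labels > 0]))
  if (!length(mods)) {
    return(structure(list(labels = setNames(labels, rownames(expr)),
                          eigengenes = NULL, kme = NULL, params = params),
                     class = "module_assignment"))
  }
  E <- t(vapply(mods, function(k)
    module_eigengene(expr, which(labels == k)), numeric(ncol(expr))))
  # PAM-lite: pull unassigned stragglers into the module they clearly
  # belong to (|kME| above pam_kme), as hybrid tree cutting does
  if (any(labels == 0) && nrow(E)) {
    km0 <- abs(cor(t(expr[labels == 0, , drop = FALSE]), t(E)))
    best <- max.col(km0, ties.method = "first")
    take <- km0[cbind(seq_len(nrow(km0)), best)] >= pam_kme
    labels[which(labels == 0)[take]] <- mods[best[take]]
    E <- t(vapply(mods, function(k)
      module_eigengene(expr, which(labels == k)), numeric(ncol(expr))))
  }
  # eigengene-based merging: merge pairs with cor >= 1 - merge_cut_height
  repeat {
    if (nrow(E) < 2) break
    cc <- cor(t(E)); diag(cc) <- -Inf
    mx <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    if (cc[mx[1], mx[2]] < 1 - params$merge_cut_height) break
    keep <- mods[mx[1]]; drop <- mods[mx[2]]
    labels[labels == drop] <- keep
    mods <- sort(unique(labels[labels > 0]))
    E <- t(vapply(mods, function(k)
      module_eigengene(expr, which(labels == k)), numeric(ncol(expr))))
  }
  # renumber by decreasing size
  ord <- order(-tabulate(match(labels, mods), length(mods)))
  relab <- integer(max(mods)); relab[mods[ord]] <- seq_along(mods)
  labels[labels > 0] <- relab[labels[labels > 0]]
  mods <- seq_along(ord)
  E <- E[ord, , drop = FALSE]
  rownames(E) <- paste0("ME", mods)
  colnames(E) <- colnames(expr)
  kme <- cor(t(expr), t(E))
  dimnames(kme) <- list(rownames(expr), rownames(E))
  structure(list(labels = setNames(labels, rownames(expr)),
                 eigengenes = E, kme = kme, params = params),
            class = "module_assignment")
}

#' Cluster features into co-expression modules
#'
#' Average-linkage hierarchical clustering of TOM dissimilarity with the
#' static-cut-lite described in the package's methods vignette, a
#' kME-based reassignment of unassigned stragglers (|kME| >= 0.6 to
#' their best module), module eigengenes (unit-norm first principal
#' component of standardized member expression, sign-aligned so the mean
#' member kME is non-negative), eigengene-based merging at correlation
#' `>= 1 - merge_cut_height`, and kME recomputation after merging.
#'
#' @param diss_tom TOM dissimilarity matrix (`1 - TOM`).
#' @param expr The expression matrix the TOM was built from.
#' @param params List with `power`, `min_module_size`, `deep_split`
#'   (2, 3 or 4) and `merge_cut_height`.
#' @return `module_assignment`: feature labels (0 = unassigned),
#'   eigengene matrix (module x sample), kME matrix (feature x module),
#'   and the parameters used.
#' @export
cluster_modules <- function(diss_tom, expr, params) {
  hc <- hclust(as.dist(diss_tom), method = "average")
  labels <- cluster_from_hc(hc, expr, params)
  compute_assignment(expr, labels, params)
}

#' Parameter grid for the network sweep
#'
#' @param powers Soft-thresholding powers (3 selected via
#'   [pick_soft_powers()] or supplied directly, e.g. 3,4,5 at transcript
#'   level and 14,15,16 at gene level).
#' @param min_module_size,deep_split,merge_cut_height Grid levels; the
#'   defaults span the full 144-combination grid.
#' @return data.frame with one row per parameter combination.
#' @export
network_params_grid <- function(powers,
                                min_module_size = c(30, 50, 75, 100),
                                deep_split = c(2, 3, 4),
                                merge_cut_height = c(0.15, 0.20, 0.25,
                                                     0.30)) {
  expand.grid(power = powers, min_module_size = min_module_size,
              deep_split = deep_split,
              merge_cut_height = merge_cut_height,
              KEEP.OUT.ATTRS = FALSE)
}

#' Top-|kME| hub features of one module assignment
#'
#' @param assignment A `module_assignment`.
#' @param n_hubs Hubs per module (default 10); modules smaller than
#'   `n_hubs` contribute all their members.  Ties in |kME| break
#'   lexicographically by feature ID.
#' @return Character vector of hub feature IDs.
#' @export
module_hubs <- function(assignment, n_hubs = 10) {
  labs <- assignment$labels
  out <- character(0)
  for (k in sort(unique(labs[labs > 0]))) {
    ids <- names(labs)[labs == k]
    kv <- abs(assignment$kme[ids, paste0("ME", k)])
    ord <- ids[order(-kv, ids)]
    out <- c(out, ord[seq_len(min(n_hubs, length(ord)))])
  }
  unique(out)
}

#' Run the co-expression parameter sweep
#'
#' One module assignment per grid row; adjacency, TOM and the dendrogram
#' are shared across rows with the same power.  Consensus hubs are the
#' union over (module, iteration) of the top-`n_hubs` |kME| features.
#'
#' @param expr Feature-by-sample expression matrix.
#' @param grid data.frame from [network_params_grid()].
#' @param n_hubs Hubs per module per iteration (default 10).
#' @return `sweep_result`: list of assignments (one per grid row, `NULL`
#'   where an iteration failed), the grid, consensus `hubs`, and a log of
#'   failed iterations.
#' @export
run_sweep <- function(expr, grid, n_hubs = 10) {
  if (!nrow(grid)) stop("empty parameter grid")
  assignments <- vector("list", nrow(grid))
  failures <- character(0)
  for (beta in unique(grid$power)) {
    adj <- signed_adjacency(expr, beta)
    hc <- hclust(as.dist(1 - tom_similarity(adj)), method = "average")
    for (i in which(grid$power == beta)) {
      params <- as.list(grid[i, ])
      res <- tryCatch({
        labels <- cluster_from_hc(hc, expr, params)
        compute_assignment(expr, labels, params)
      }, error = function(e) {
        failures <<- c(failures,
                       sprintf("iteration %d: %s", i, conditionMessage(e)))
        NULL
      })
      assignments[[i]] <- res
    }
  }
  hubs <- sort(unique(unlist(lapply(assignments, function(a)
    if (!is.null(a)) module_hubs(a, n_hubs)))))
  structure(list(assignments = assignments, grid = grid, hubs = hubs,
                 failures = failures), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("sweep_result:", nrow(x$grid), "iterations,",
      length(x$hubs), "consensus hubs\n")
  invisible(x)
}
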