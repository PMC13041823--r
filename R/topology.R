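# Edge-weighted topology of module graphs: hubs by eigenvector
# centrality, Dijkstra shortest paths with 1/|r| edge weights, KDE-mode
# peak distances for fetal vs maternal mediators, and their absolute
# difference (maternal-fetal compartmentalization).

#' Build the weighted graph of one module
#'
#' Edges are kept where the signed adjacency reaches `min_adjacency`
#' (default 0.1) and carry two weights: the adjacency itself (centrality
#' weight) and `1 / |cor|` (distance weight).  Retained signed-network
#' edges have strong positive correlation, so `|cor|` equals `cor` up to
#' a guard against small negatives.
#'
#' @param expr_members Expression matrix restricted to module members.
#' @param power Soft-thresholding power for the adjacency.
#' @param min_adjacency Adjacency floor below which edges are removed.
#' @return igraph graph with vertex names and edge attributes
#'   `centrality` and `distance`.
#' @export
build_module_graph <- function(expr_members, power, min_adjacency = 0.1) {
  if (nrow(expr_members) < 2) stop("need >= 2 module members")
  adj <- signed_adjacency(expr_members, power)
  cm <- attr(adj, "cor")
  ids <- rownames(expr_members)
  keep <- which(adj >= min_adjacency & upper.tri(adj), arr.ind = TRUE)
  if (!nrow(keep))
    warning("module graph has no edges at adjacency floor ",
            min_adjacency)
  edges <- data.frame(from = ids[keep[, 1]], to = ids[keep[, 2]],
                      centrality = adj[keep],
                      distance = 1 / abs(cm[keep]),
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = ids))
}

#' Hub of a module graph by eigenvector centrality
#'
#' Power iteration (tolerance 1e-10, at most 10,000 iterations) on the
#' centrality-weight matrix of the largest connected component; ties
#' resolve to the lexicographically smallest vertex name.
#'
#' @param graph A [build_module_graph()] graph.
#' @return Hub vertex name.
#' @export
find_hub <- function(graph) {
  if (igraph::ecount(graph) == 0) stop("graph has no edges")
  comp <- igraph::components(graph)
  big <- which.max(comp$csize)
  sub <- igraph::induced_subgraph(
    graph, which(comp$membership == big))
  A <- as.matrix(igraph::as_adjacency_matrix(sub, attr = "centrality",
                                             sparse = FALSE))
  n <- nrow(A)
  v <- rep(1 / sqrt(n), n)
  for (it in seq_len(10000)) {
    w <- A %*% v
    w <- w / sqrt(sum(w^2))
    if (max(abs(w - v)) < 1e-10) { v <- w; break }
    v <- w
  }
  v <- as.numeric(v)
  cand <- rownames(A)[v >= max(v) - 1e-8]
  sort(cand)[1]
}

#' Shortest-path distances from the hub to mediators
#'
#' Dijkstra on the `distance` (= `1/|r|`) edge weights.  Mediators absent
#' from the graph or unreachable from the hub are excluded and counted.
#'
#' @param graph A [build_module_graph()] graph.
#' @param hub Hub vertex name (see [find_hub()]).
#' @param mediator_ids Mediator feature IDs.
#' @return List: `distances` (named numeric), `n_unreachable`,
#'   `n_absent`.
#' @export
hub_distances <- function(graph, hub, mediator_ids) {
  present <- intersect(mediator_ids, igraph::V(graph)$name)
  n_absent <- length(mediator_ids) - length(present)
  if (!length(present))
    return(list(distances = numeric(0), n_unreachable = 0L,
                n_absent = n_absent))
  d <- igraph::distances(graph, v = hub, to = present,
                         weights = igraph::E(graph)$distance,
                         algorithm = "dijkstra")[1, ]
  finite <- is.finite(d)
  list(distances = d[finite], n_unreachable = sum(!finite),
       n_absent = n_absent)
}

#' Mode of a Gaussian kernel density estimate
#'
#' Silverman's rule-of-thumb bandwidth, 512-point grid spanning
#' `[min - 3h, max + 3h]`; the peak is the arg-max grid point (first,
#' i.e. smallest, on ties).  Degenerate inputs (single value, zero
#' spread) return that value.
#'
#' @param values Numeric vector.
#' @return Peak location, or `NA` for empty input.
#' @export
kde_mode <- function(values) {
  x <- values[is.finite(values)]
  if (!length(x)) return(NA_real_)
  if (length(x) == 1 || sd(x) == 0) return(x[1])
  den <- density(x, bw = "nrd0", n = 512, cut = 3)
  den$x[which.max(den$y)]
}

# peak statistic with the documented fallback: KDE mode needs >= 3
# values, otherwise the median is used and the unit flagged degenerate
peak_stat <- function(values, min_values = 3) {
  v <- values[is.finite(values)]
  if (!length(v)) return(c(NA_real_, NA))
  if (length(v) < min_values) return(c(median(v), 1))
  c(kde_mode(v), 0)
}

#' Topology summary over a network sweep for one outcome
#'
#' For every sweep iteration and module, builds the module graph with
#' that iteration's power, finds its hub, and computes -- per compound
#' and exposure source -- the peak (KDE-mode) hub-to-mediator distance
#' and peak mediator |kME|, restricted to significant mediators assigned
#' to that module.  Compartmentalization is `|D_f - D_m|` per
#' module-iteration unit with both sources present.  Unit-level rows are
#' aggregated to compound(-source) mean and standard error.
#'
#' @param expr Expression matrix the sweep ran on (for the outcome's
#'   sample set).
#' @param sweep A [run_sweep()] result.
#' @param mediators data.frame of significant mediators with columns
#'   `feature_id`, `compound`, `source`.
#' @param min_adjacency Edge floor for module graphs (default 0.1).
#' @param min_values Minimum path-length count for a KDE mode (default
#'   3; below it the median is used and the unit flagged).
#' @return List: `units` (per iteration x module x compound x source),
#'   `compartment_units`, `summary` (per compound x source), and
#'   `compartmentalization` (per compound).  Compounds contributing no
#'   units are reported missing with a warning.
#' @export
summarize_topology <- function(expr, sweep, mediators,
                               min_adjacency = 0.1, min_values = 3) {
  stopifnot(all(c("feature_id", "compound", "source") %in%
                  names(mediators)))
  units <- list()
  for (i in seq_along(sweep$assignments)) {
    asg <- sweep$assignments[[i]]
    if (is.null(asg)) next
    labs <- asg$labels
    for (k in sort(unique(labs[labs > 0]))) {
      members <- names(labs)[labs == k]
      med_k <- mediators[mediators$feature_id %in% members, ,
                         drop = FALSE]
      if (!nrow(med_k)) next
      g <- tryCatch(
        suppressWarnings(build_module_graph(
          expr[members, , drop = FALSE], asg$params$power,
          min_adjacency)),
        error = function(e) NULL)
      if (is.null(g) || igraph::ecount(g) == 0) next
      hub <- find_hub(g)
      d_all <- igraph::distances(g, v = hub,
                                 weights = igraph::E(g)$distance,
                                 algorithm = "dijkstra")[1, ]
      kv <- abs(asg$kme[members, paste0("ME", k)])
      names(kv) <- members
      for (cp in unique(med_k$compound))
        for (src in unique(med_k$source[med_k$compound == cp])) {
          ids <- med_k$feature_id[med_k$compound == cp &
                                    med_k$source == src]
          d <- d_all[ids]; d <- d[is.finite(d)]
          ps <- peak_stat(d, min_values)
          pk <- peak_stat(kv[ids], min_values)
          units[[length(units) + 1L]] <- data.frame(
            iteration = i, module = k, compound = cp, source = src,
            n_mediators = length(ids), n_distances = length(d),
            peak_distance = ps[1], peak_kme = pk[1],
            degenerate = ps[2] == 1, stringsAsFactors = FALSE)
        }
    }
  }
  units <- if (length(units)) do.call(rbind, units) else
    data.frame(iteration = integer(0), module = integer(0),
               compound = character(0), source = character(0),
               n_mediators = integer(0), n_distances = integer(0),
               peak_distance = numeric(0), peak_kme = numeric(0),
               degenerate = logical(0))
  # compartmentalization per module-iteration unit with both sources
  comp_units <- NULL
  if (nrow(units)) {
    wide <- merge(
      units[units$source == "fetal",
            c("iteration", "module", "compound", "peak_distance")],
      units[units$source == "maternal",
            c("iteration", "module", "compound", "peak_distance")],
      by = c("iteration", "module", "compound"),
      suffixes = c("_f", "_m"))
    if (nrow(wide)) {
      wide$compartmentalization <- abs(wide$peak_distance_f -
                                         wide$peak_distance_m)
      comp_units <- wide
    }
  }
  agg <- function(df, value, by) {
    if (is.null(df) || !nrow(df)) return(NULL)
    sp <- split(df[[value]], df[by], drop = TRUE)
    keys <- do.call(rbind, strsplit(names(sp), "\\."))
    out <- data.frame(keys, stringsAsFactors = FALSE)
    names(out) <- by
    out$mean <- vapply(sp, mean, numeric(1))
    out$se <- vapply(sp, function(v)
      if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
      numeric(1))
    out$n_units <- vapply(sp, length, integer(1))
    rownames(out) <- NULL
    out
  }
  summary_dist <- agg(units, "peak_distance", c("compound", "source"))
  summary_kme <- agg(units, "peak_kme", c("compound", "source"))
  summ <- NULL
  if (!is.null(summary_dist)) {
    summ <- summary_dist
    names(summ)[names(summ) == "mean"] <- "peak_distance"
    names(summ)[names(summ) == "se"] <- "peak_distance_se"
    summ$peak_kme <- summary_kme$mean
    summ$peak_kme_se <- summary_kme$se
  }
  comp <- agg(comp_units, "compartmentalization", "compound")
  if (!is.null(comp))
    names(comp)[names(comp) == "mean"] <- "compartmentalization"
  missing_cp <- setdiff(unique(mediators$compound),
                        if (is.null(summ)) character(0) else
                          unique(summ$compound))
  if (length(missing_cp))
    warning("no contributing module-iteration units for: ",
            paste(missing_cp, collapse = ", "))
  list(units = units, compartment_units = comp_units,
       summary = summ, compartmentalization = comp)
}
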