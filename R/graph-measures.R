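# weighted shortest-path lengths use Ew as-is by default (the convention of
# the toolchain these analyses are usually run in); inverse_weight treats
# stronger ties as shorter
edge_lengths <- function(net) {
  ew <- igraph::E(net$graph)$Ew
  if (net$config$weighted_distance == "inverse_weight") 1 / ew else ew
}

#' Network-level measures
#'
#' Computes the whole-graph summary of a referral network: order and size,
#' weak/strong component counts, global clustering (transitivity of the
#' undirected projection), density `m / (n (n - 1))`, diameter and average
#' path length (unweighted hops and weighted, finite ordered pairs only),
#' radius (minimum unweighted out-eccentricity over vertices with out-degree
#' > 0), global efficiency (mean of `1/d` over ordered pairs, 0 when
#' unreachable) and the articulation points of the undirected projection.
#'
#' @param net A [build_referral_network()] result.
#' @return A one-row tibble (glance-style); the articulation points are in a
#'   list-column `articulation_points`.
#' @export
network_measures <- function(net) {
  g <- net$graph
  n <- igraph::gorder(g)
  if (n == 0) abort("Empty network.")
  if (n == 1) {
    warn("Single-vertex network: path-based measures are degenerate.")
  }
  len <- edge_lengths(net)
  gu <- igraph::as_undirected(g, mode = "collapse")

  d_un <- igraph::distances(g, mode = "out", weights = NA)
  d_w <- igraph::distances(g, mode = "out", weights = len)
  off <- !diag(n)
  finite_un <- is.finite(d_un) & off
  finite_w <- is.finite(d_w) & off

  out_deg <- igraph::degree(g, mode = "out")
  ecc_un <- apply(d_un, 1, function(r) {
    r <- r[is.finite(r) & r > 0]
    if (length(r) == 0) 0 else max(r)
  })

  tibble::tibble(
    n_vertices = n,
    n_edges = igraph::gsize(g),
    weak_components = igraph::count_components(g, mode = "weak"),
    strong_components = igraph::count_components(g, mode = "strong"),
    global_clustering = igraph::transitivity(gu, type = "global"),
    density = igraph::gsize(g) / (n * (n - 1)),
    diameter_unweighted = if (any(finite_un)) max(d_un[finite_un]) else NA_real_,
    diameter_weighted = if (any(finite_w)) max(d_w[finite_w]) else NA_real_,
    radius = if (any(out_deg > 0)) min(ecc_un[out_deg > 0]) else NA_real_,
    avg_path_length_unweighted = if (any(finite_un)) mean(d_un[finite_un]) else NA_real_,
    avg_path_length_weighted = if (any(finite_w)) mean(d_w[finite_w]) else NA_real_,
    global_efficiency_unweighted = if (n > 1) {
      mean(ifelse(finite_un, 1 / d_un, 0)[off])
    } else 0,
    global_efficiency_weighted = if (n > 1) {
      mean(ifelse(finite_w, 1 / d_w, 0)[off])
    } else 0,
    n_articulation_points = length(articulation_vertices(net)),
    articulation_points = list(articulation_vertices(net))
  )
}

#' Articulation points of the undirected projection
#'
#' Vertices whose removal increases the number of connected components.
#'
#' @param net A `"referral_network"`.
#' @return Character vector of physician ids, sorted.
#' @export
articulation_vertices <- function(net) {
  gu <- igraph::as_undirected(net$graph, mode = "collapse")
  sort(names(igraph::articulation_points(gu)))
}

#' Vertex-level measures
#'
#' One row per network physician with the raw (untransformed) measures:
#' referrals made/received and in-window follow-ups (from the builder),
#' unweighted and Ew-weighted degrees, local clustering coefficient
#' (unweighted transitivity, 0 below degree 2; weighted by Barrat's
#' formulation), local efficiency (global efficiency of the subgraph induced
#' by a vertex's neighbours), closeness in/out over reachable vertices only,
#' betweenness (directed, ordered pairs; weighted uses Ew as length),
#' unweighted out-eccentricity, PageRank (damping 0.85 on Ew), subgraph
#' centrality (diagonal of the matrix exponential of the undirected
#' unweighted adjacency), Kleinberg authority/hub scores (principal singular
#' directions of the Ew-weighted adjacency, max-1 scaled) and diversity
#' (Shannon entropy of incident combined edge weights over `log(degree)`;
#' `NA` at degree 0, 0 at degree 1).
#'
#' @param net A [build_referral_network()] result.
#' @return A tibble, one row per vertex, first column `physician_id`.
#' @export
vertex_measures <- function(net) {
  g <- net$graph
  if (igraph::gorder(g) == 0) abort("Empty network.")
  # the iterative eigensolvers (PageRank, HITS) draw random start vectors;
  # pin the RNG locally so repeated calls agree to the last bit
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(1L)
  len <- edge_lengths(net)
  gu <- igraph::as_undirected(g, mode = "collapse",
                              edge.attr.comb = list(Ew = "sum", "ignore"))
  wu <- igraph::E(gu)$Ew

  hits <- igraph::hits_scores(g, weights = igraph::E(g)$Ew, scale = TRUE)

  clo_in_un <- igraph::closeness(g, mode = "in", weights = NA, normalized = TRUE)
  clo_out_un <- igraph::closeness(g, mode = "out", weights = NA, normalized = TRUE)
  clo_in_w <- igraph::closeness(g, mode = "in", weights = len, normalized = TRUE)
  clo_out_w <- igraph::closeness(g, mode = "out", weights = len, normalized = TRUE)

  ecc <- vapply(seq_len(igraph::gorder(g)), function(i) {
    d <- igraph::distances(g, v = i, mode = "out", weights = NA)
    d <- d[is.finite(d) & d > 0]
    if (length(d) == 0) 0 else max(d)
  }, numeric(1))

  loc_clust <- igraph::transitivity(gu, type = "local", isolates = "zero")
  loc_clust_w <- igraph::transitivity(gu, type = "barrat", weights = wu,
                                      isolates = "zero")

  tibble::tibble(
    physician_id = igraph::V(g)$name,
    referrals_made = igraph::V(g)$referrals_made,
    referrals_received = igraph::V(g)$referrals_received,
    follow_ups = igraph::V(g)$follow_ups,
    degree_in = unname(igraph::degree(g, mode = "in")),
    degree_in_w = unname(igraph::strength(g, mode = "in",
                                          weights = igraph::E(g)$Ew)),
    degree_out = unname(igraph::degree(g, mode = "out")),
    degree_out_w = unname(igraph::strength(g, mode = "out",
                                           weights = igraph::E(g)$Ew)),
    clustering = unname(loc_clust),
    clustering_w = unname(ifelse(is.nan(loc_clust_w), 0, loc_clust_w)),
    local_efficiency = unname(igraph::local_efficiency(g, weights = NA,
                                                       mode = "all")),
    local_efficiency_w = unname(igraph::local_efficiency(g, weights = len,
                                                         mode = "all")),
    closeness_in = unname(clo_in_un),
    closeness_in_w = unname(clo_in_w),
    closeness_out = unname(clo_out_un),
    closeness_out_w = unname(clo_out_w),
    betweenness = unname(igraph::betweenness(g, directed = TRUE, weights = NA)),
    betweenness_w = unname(igraph::betweenness(g, directed = TRUE,
                                               weights = len)),
    eccentricity = ecc,
    pagerank = unname(igraph::page_rank(g, damping = 0.85,
                                        weights = igraph::E(g)$Ew)$vector),
    subgraph_centrality = unname(igraph::subgraph_centrality(gu, diag = FALSE)),
    authority = unname(hits$authority),
    hub = unname(hits$hub),
    diversity = vertex_diversity(gu, wu)
  )
}

# Shannon-entropy diversity of incident combined weights on the undirected
# projection: NA at degree 0, 0 at degree 1
vertex_diversity <- function(gu, weights) {
  deg <- igraph::degree(gu)
  div <- suppressWarnings(igraph::diversity(gu, weights = weights))
  out <- unname(div)
  out[deg == 0] <- NA_real_
  out[deg == 1] <- 0
  out
}

#' Z-score a metrics table over an included physician subset
#'
#' Expresses each measure in standard deviations above or below the mean of
#' the analyzed group: `z = (x - mean) / sd`, with mean and *sample* sd
#' (denominator `n - 1`) computed over `included` only. Columns that are
#' constant on the subset are returned as zeros with a warning. `NA` cells
#' stay `NA`.
#'
#' @param metrics Tibble from [vertex_measures()] (or any tibble whose first
#'   column is `physician_id` and whose remaining columns are numeric).
#' @param included Character vector of physician ids defining the analyzed
#'   group (e.g. the network minus low-productivity physicians). Default: all.
#' @return A tibble of the same shape restricted to `included`, with the
#'   numeric columns replaced by Z-scores.
#' @export
zscore_metrics <- function(metrics, included = metrics$physician_id) {
  included <- intersect(metrics$physician_id, included)
  if (length(included) == 0) abort("`included` selects no physicians.")
  sub <- dplyr::filter(metrics, .data$physician_id %in% included)
  num_cols <- names(sub)[vapply(sub, is.numeric, logical(1))]
  constant <- character(0)
  for (col in num_cols) {
    x <- sub[[col]]
    m <- mean(x, na.rm = TRUE)
    s <- sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      constant <- c(constant, col)
      sub[[col]] <- ifelse(is.na(x), NA_real_, 0)
    } else {
      sub[[col]] <- (x - m) / s
    }
  }
  if (length(constant) > 0) {
    warn(paste0("Constant column(s) set to zero Z-scores: ",
                paste(constant, collapse = ", ")))
  }
  sub
}

#' Write vertex measures or a network report
#'
#' @param metrics A [vertex_measures()] tibble (raw or Z-scored).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  readr::write_csv(metrics, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @param report A [network_measures()] tibble.
#' @export
write_network_report <- function(report, path) {
  out <- as.list(report)
  out$articulation_points <- report$articulation_points[[1]]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
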