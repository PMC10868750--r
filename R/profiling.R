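#' Profiling dimension specifications
#'
#' The three managerial constructs into which vertex measures are grouped,
#' with their candidate metrics, the subset actually clustered (after
#' correlation pruning the closely correlated candidates are represented by
#' one member) and the descriptive metrics reported alongside:
#'
#' * `patient_follow_up` — clustered: referrals made, referrals received,
#'   follow-up consultations; descriptive: unweighted/weighted degree-in and
#'   degree-out.
#' * `relationship_with_authorities` — clustered: Kleinberg authority and hub
#'   scores.
#' * `centrality` — clustered: weighted closeness-out, weighted closeness-in,
#'   eccentricity, PageRank; descriptive: subgraph centrality, unweighted and
#'   weighted betweenness.
#'
#' @return A named list of specs, each a list with `name`,
#'   `candidate_metrics`, `clustering_metrics`, `descriptive_metrics`.
#' @export
dimension_specs <- function() {
  list(
    patient_follow_up = list(
      name = "patient_follow_up",
      candidate_metrics = c("referrals_made", "referrals_received",
                            "follow_ups", "degree_in", "degree_in_w",
                            "degree_out", "degree_out_w"),
      clustering_metrics = c("referrals_made", "referrals_received",
                             "follow_ups"),
      descriptive_metrics = c("degree_in", "degree_in_w", "degree_out",
                              "degree_out_w")
    ),
    relationship_with_authorities = list(
      name = "relationship_with_authorities",
      candidate_metrics = c("authority", "hub"),
      clustering_metrics = c("authority", "hub"),
      descriptive_metrics = character(0)
    ),
    centrality = list(
      name = "centrality",
      candidate_metrics = c("closeness_in_w", "closeness_out_w",
                            "eccentricity", "pagerank",
                            "subgraph_centrality", "betweenness",
                            "betweenness_w"),
      clustering_metrics = c("closeness_out_w", "closeness_in_w",
                             "eccentricity", "pagerank"),
      descriptive_metrics = c("subgraph_centrality", "betweenness",
                              "betweenness_w")
    )
  )
}

#' Clustering configuration
#'
#' @param k_min,k_max Range of cluster counts examined (defaults 2 and 10).
#' @param k_selection `"silhouette"` (argmax of mean silhouette width, ties to
#'   the smaller k), `"elbow"` is reported via the WSS curve but selection
#'   still uses the silhouette, or `"fixed"` to force `fixed_k`.
#' @param fixed_k Named integer vector of forced cluster counts per dimension
#'   (e.g. `c(centrality = 3)`), used when `k_selection = "fixed"`.
#' @param n_restarts Random K-means initializations per k (best
#'   within-cluster sum of squares kept).
#' @param seed Seed for the restarts.
#' @param standardize_inputs Cluster on Z-scored inputs instead of the raw
#'   untransformed values. Default `FALSE`: clustering is performed on the
#'   original scales, with the caveat that K-means is then dominated by the
#'   largest-scale variable.
#' @param pearson_prune_threshold Absolute Pearson correlation above which a
#'   candidate pair is considered redundant.
#' @return A list with class `"clustering_config"`.
#' @export
clustering_config <- function(k_min = 2L, k_max = 10L,
                              k_selection = c("silhouette", "elbow", "fixed"),
                              fixed_k = NULL,
                              n_restarts = 25L, seed = 1L,
                              standardize_inputs = FALSE,
                              pearson_prune_threshold = 0.8) {
  k_selection <- match.arg(k_selection)
  if (k_min < 2) abort("`k_min` must be at least 2.")
  if (k_max < k_min) abort("`k_max` must be >= `k_min`.")
  if (pearson_prune_threshold <= 0 || pearson_prune_threshold >= 1) {
    abort("`pearson_prune_threshold` must lie strictly between 0 and 1.")
  }
  structure(
    list(k_min = as.integer(k_min), k_max = as.integer(k_max),
         k_selection = k_selection, fixed_k = fixed_k,
         n_restarts = as.integer(n_restarts), seed = as.integer(seed),
         standardize_inputs = isTRUE(standardize_inputs),
         pearson_prune_threshold = pearson_prune_threshold),
    class = "clustering_config"
  )
}

#' Drop metrics that are nearly collinear
#'
#' Greedy elimination: while any pair of retained metrics has absolute
#' Pearson correlation above the threshold, take the worst (largest |r|)
#' pair and drop the member with the larger mean absolute correlation to all
#' other retained metrics. Deterministic given the input.
#'
#' @param metrics Tibble of raw vertex measures.
#' @param candidates Character vector of candidate metric columns.
#' @param threshold Absolute correlation threshold (default 0.8).
#' @return A list with `retained`, `dropped`, and the correlation matrix
#'   `cor_matrix`.
#' @export
prune_correlated <- function(metrics, candidates,
                             threshold = 0.8) {
  stopifnot(all(candidates %in% names(metrics)))
  x <- as.matrix(metrics[candidates])
  cm <- suppressWarnings(cor(x, use = "pairwise.complete.obs"))
  cm[is.na(cm)] <- 0
  greedy_prune(cm, candidates, threshold)
}

# greedy elimination on a given correlation matrix (separated so the rule can
# be exercised on any matrix directly)
greedy_prune <- function(cm, candidates, threshold) {
  retained <- candidates
  dropped <- character(0)
  repeat {
    if (length(retained) <= 1) break
    sub <- abs(cm[retained, retained, drop = FALSE])
    diag(sub) <- 0
    if (max(sub) <= threshold) break
    worst <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    pair <- retained[worst]
    mean_abs <- rowMeans(sub[pair, , drop = FALSE])
    victim <- pair[which.max(mean_abs)]
    retained <- setdiff(retained, victim)
    dropped <- c(dropped, victim)
  }
  if (length(retained) == 1 && length(candidates) > 1) {
    warn("All candidate metrics mutually collinear; one retained.")
  }
  list(retained = retained, dropped = dropped, cor_matrix = cm)
}

#' Select the number of clusters
#'
#' Runs K-means for each k in `[k_min, k_max]` and picks the k maximizing the
#' mean silhouette width (ties broken toward the smaller k). The
#' within-cluster sum of squares (WSS, elbow) curve is returned for
#' inspection. A `"fixed"` selection honours `config$fixed_k`.
#'
#' @param data Numeric matrix or data frame of clustering inputs (raw values
#'   unless `config$standardize_inputs`).
#' @param config A [clustering_config()].
#' @param dimension Optional dimension name, used to look up `fixed_k`.
#' @return A list with `k`, and a `diagnostics` tibble (`k`,
#'   `mean_silhouette`, `wss`).
#' @export
select_k <- function(data, config = clustering_config(), dimension = NULL) {
  x <- prepare_cluster_input(data, config)
  n_distinct_rows <- nrow(unique(as.data.frame(x)))
  if (n_distinct_rows <= config$k_min) {
    abort("Fewer distinct rows than `k_min`: cannot select a cluster count.")
  }
  k_max <- min(config$k_max, n_distinct_rows - 1L)
  ks <- seq.int(config$k_min, k_max)
  d <- dist(x)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(config$seed)
  diag <- purrr::map_dfr(ks, function(k) {
    fit <- kmeans(x, centers = k, nstart = config$n_restarts,
                  iter.max = 50)
    sil <- cluster::silhouette(fit$cluster, d)
    tibble::tibble(k = k, mean_silhouette = mean(sil[, "sil_width"]),
                   wss = fit$tot.withinss)
  })
  k <- if (config$k_selection == "fixed") {
    if (is.null(config$fixed_k)) abort("`fixed_k` not supplied for fixed selection.")
    kk <- if (!is.null(dimension) && !is.null(names(config$fixed_k))) {
      config$fixed_k[[dimension]]
    } else {
      config$fixed_k[[1]]
    }
    as.integer(kk)
  } else {
    diag$k[which.max(diag$mean_silhouette)]
  }
  list(k = k, diagnostics = diag)
}

prepare_cluster_input <- function(data, config) {
  x <- as.matrix(as.data.frame(data))
  storage.mode(x) <- "double"
  # impute missing cells with the column mean of the analyzed set
  for (j in seq_len(ncol(x))) {
    miss <- is.na(x[, j])
    if (any(miss)) x[miss, j] <- mean(x[, j], na.rm = TRUE)
  }
  if (config$standardize_inputs) x <- scale(x)
  x
}

#' K-means clustering of one profiling dimension
#'
#' Clusters the raw (untransformed) metric values with `n_restarts` random
#' initializations, keeping the best within-cluster sum of squares.
#' Deterministic given `config$seed`. Missing cells are imputed with the
#' column mean and flagged. Centroids are returned both on the raw scale and
#' expressed in Z units (standard deviations from the analyzed-set mean) for
#' labeling and reporting.
#'
#' @param data Numeric data frame/matrix of the clustering metrics for the
#'   included physicians (rows aligned with `ids`).
#' @param k Number of clusters.
#' @param config A [clustering_config()].
#' @param ids Optional row identifiers (physician ids).
#' @return A list with `cluster` (integer vector), `centroids_raw`,
#'   `centroids_z` (tibbles with `cluster`, `n` and one column per metric),
#'   `wss`, `imputed` (logical matrix of imputed cells).
#' @export
cluster_dimension <- function(data, k, config = clustering_config(),
                              ids = NULL) {
  x_raw <- as.matrix(as.data.frame(data))
  storage.mode(x_raw) <- "double"
  imputed <- is.na(x_raw)
  x <- prepare_cluster_input(data, config)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(config$seed)
  fit <- kmeans(x, centers = k, nstart = config$n_restarts, iter.max = 50)
  x_imp <- prepare_cluster_input(data, clustering_config(standardize_inputs = FALSE))
  mu <- colMeans(x_imp)
  s <- apply(x_imp, 2, sd)
  s[s == 0] <- 1
  agg <- function(mat) {
    out <- tibble::as_tibble(mat) |>
      dplyr::mutate(cluster = fit$cluster) |>
      dplyr::group_by(.data$cluster) |>
      dplyr::summarise(dplyr::across(dplyr::everything(), mean),
                       n = dplyr::n(), .groups = "drop")
    out
  }
  centroids_raw <- agg(x_imp)
  centroids_z <- agg(sweep(sweep(x_imp, 2, mu), 2, s, "/"))
  list(
    cluster = unname(fit$cluster),
    ids = ids,
    centroids_raw = centroids_raw,
    centroids_z = centroids_z,
    wss = fit$tot.withinss,
    imputed = imputed
  )
}

#' Label thresholds for cluster semantics
#'
#' Defaults reproduce the published worked example (see
#' [example_centroid_table()]): a cluster whose mean hub Z-score is at least
#' `hub_seeks` is "seeks_authorities"; otherwise authority Z at least
#' `authority_is` makes it "is_authority"; follow-up intensity is "strong" at
#' or above `followup_strong` and "weak" at or below `followup_weak`; care is
#' "prevalent" (rather than "shared") when both referral Z-scores are at or
#' below `prevalent_max`.
#'
#' @export
label_thresholds <- function(hub_seeks = 1, authority_is = 0.1,
                             followup_strong = 1, followup_weak = -0.5,
                             prevalent_max = -0.8) {
  list(hub_seeks = hub_seeks, authority_is = authority_is,
       followup_strong = followup_strong, followup_weak = followup_weak,
       prevalent_max = prevalent_max)
}

#' Assign semantic labels to cluster centroids
#'
#' Operates on centroids expressed in Z units.
#'
#' * `centrality`: a composite
#'   `mean(z(pagerank), z(subgraph_centrality), z(betweenness),
#'   z(closeness_in)) - mean(z(eccentricity), z(closeness_out))` ranks the
#'   clusters; the highest becomes `"central"`, the lowest `"peripheral"`,
#'   every other `"intermediate"`. An exact tie is broken deterministically:
#'   the larger cluster is demoted to `"intermediate"`, with a warning.
#' * `relationship_with_authorities`: hub Z at or above the `hub_seeks`
#'   threshold gives `"seeks_authorities"`; else authority Z at or above
#'   `authority_is` gives `"is_authority"`; else `"balanced"`.
#' * `patient_follow_up`: intensity from the follow-up Z (strong / moderate /
#'   weak); sharing is `"prevalent"` when both referral Z-scores are at or
#'   below `prevalent_max`, else `"shared"`; combined as e.g.
#'   `"strong_prevalent"`.
#'
#' @param centroids_z Tibble of cluster centroids in Z units. Columns used:
#'   centrality - `pagerank`, `subgraph_centrality`, `betweenness`,
#'   `closeness_in`, `eccentricity`, `closeness_out` (weighted closeness
#'   columns `closeness_in_w`/`closeness_out_w` are accepted equivalently);
#'   authorities - `authority`, `hub`; follow-up - `referrals_made`,
#'   `referrals_received`, `follow_ups`. A column `n` (cluster size) is used
#'   for tie-breaks.
#' @param dimension One of `"centrality"`, `"relationship_with_authorities"`,
#'   `"patient_follow_up"`.
#' @param thresholds A [label_thresholds()] list.
#' @return Character vector of labels, one per centroid row.
#' @examples
#' tab <- example_centroid_table()
#' cent <- tab[tab$dimension == "centrality", ]
#' label_clusters(cent, "centrality")
#' @export
label_clusters <- function(centroids_z, dimension,
                           thresholds = label_thresholds()) {
  cz <- tibble::as_tibble(centroids_z)
  pick <- function(...) {
    for (nm in c(...)) if (nm %in% names(cz)) return(cz[[nm]])
    abort(paste0("Centroid table lacks a required column (tried: ",
                 paste(c(...), collapse = ", "), ")."))
  }
  if (dimension == "centrality") {
    composite <- rowMeans(cbind(pick("pagerank"),
                                pick("subgraph_centrality"),
                                pick("betweenness"),
                                pick("closeness_in", "closeness_in_w"))) -
      rowMeans(cbind(pick("eccentricity"),
                     pick("closeness_out", "closeness_out_w")))
    labels <- rep("intermediate", length(composite))
    hi <- which(composite == max(composite))
    lo <- which(composite == min(composite))
    if (length(hi) > 1 || length(lo) > 1) {
      warn("Tie on the centrality composite; larger cluster kept intermediate.")
      n <- pick("n")
      hi <- hi[order(n[hi])][1]
      lo <- lo[order(n[lo])][1]
    }
    labels[hi] <- "central"
    labels[lo] <- "peripheral"
    labels
  } else if (dimension == "relationship_with_authorities") {
    hub <- pick("hub")
    auth <- pick("authority")
    dplyr::case_when(
      hub >= thresholds$hub_seeks ~ "seeks_authorities",
      auth >= thresholds$authority_is ~ "is_authority",
      TRUE ~ "balanced"
    )
  } else if (dimension == "patient_follow_up") {
    fu <- pick("follow_ups")
    made <- pick("referrals_made")
    rec <- pick("referrals_received")
    intensity <- dplyr::case_when(
      fu >= thresholds$followup_strong ~ "strong",
      fu <= thresholds$followup_weak ~ "weak",
      TRUE ~ "moderate"
    )
    sharing <- ifelse(made <= thresholds$prevalent_max &
                        rec <= thresholds$prevalent_max,
                      "prevalent", "shared")
    paste(intensity, sharing, sep = "_")
  } else {
    abort(paste0("Unknown dimension: ", dimension))
  }
}

#' Profile physicians in the three dimensions
#'
#' End-to-end profiling: for each dimension, prune nearly collinear
#' candidates, select k (silhouette unless fixed), cluster the raw values of
#' the included physicians, express centroids in Z units and attach semantic
#' labels.
#'
#' @param metrics Raw [vertex_measures()] tibble.
#' @param included Physician ids to profile (the analyzed group after
#'   exclusions). Default: all rows of `metrics`.
#' @param config A [clustering_config()].
#' @param thresholds A [label_thresholds()] list.
#' @return A list of class `"physician_profiles"` with `assignments` (tibble:
#'   `physician_id`, then per dimension `<dim>_cluster` and `<dim>_label`),
#'   `dimensions` (per-dimension list with pruning result, k diagnostics,
#'   centroids raw/Z and labels).
#' @export
profile_physicians <- function(metrics, included = metrics$physician_id,
                               config = clustering_config(),
                               thresholds = label_thresholds()) {
  specs <- dimension_specs()
  sub <- metrics |>
    dplyr::filter(.data$physician_id %in% included) |>
    dplyr::arrange(.data$physician_id)
  zs <- zscore_metrics(sub)
  assignments <- tibble::tibble(physician_id = sub$physician_id)
  dims <- list()
  for (spec in specs) {
    # pruning over the full candidate list is reported as a diagnostic; the
    # clustered set itself is the dimension's declared (post-pruning) default
    pruned <- prune_correlated(sub, spec$candidate_metrics,
                               config$pearson_prune_threshold)
    data <- sub[spec$clustering_metrics]
    sel <- select_k(data, config, dimension = spec$name)
    cl <- cluster_dimension(data, sel$k, config, ids = sub$physician_id)
    # centroid Z table for labeling: mean Z (analyzed-group scale) of both
    # clustered and descriptive metrics per cluster
    label_cols <- intersect(unique(c(spec$candidate_metrics,
                                     "subgraph_centrality", "betweenness")),
                            names(zs))
    cz <- zs[label_cols] |>
      dplyr::mutate(cluster = cl$cluster) |>
      dplyr::group_by(.data$cluster) |>
      dplyr::summarise(dplyr::across(dplyr::everything(),
                                     ~ mean(.x, na.rm = TRUE)),
                       n = dplyr::n(), .groups = "drop")
    labels <- label_clusters(cz, spec$name, thresholds)
    assignments[[paste0(spec$name, "_cluster")]] <- cl$cluster
    assignments[[paste0(spec$name, "_label")]] <-
      labels[match(cl$cluster, cz$cluster)]
    dims[[spec$name]] <- list(
      spec = spec, pruning = pruned, k = sel$k,
      k_diagnostics = sel$diagnostics,
      centroids_raw = cl$centroids_raw,
      centroids_z = cz, labels = labels, wss = cl$wss
    )
  }
  structure(list(assignments = assignments, dimensions = dims,
                 config = config),
            class = "physician_profiles")
}

#' @export
print.physician_profiles <- function(x, ...) {
  cat("<physician_profiles>", nrow(x$assignments), "physicians\n")
  for (nm in names(x$dimensions)) {
    d <- x$dimensions[[nm]]
    cat("  ", nm, ": k = ", d$k, " [",
        paste(d$labels, collapse = ", "), "]\n", sep = "")
  }
  invisible(x)
}

#' Write profile assignments / centroid tables to CSV
#'
#' @param profiles A `"physician_profiles"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  stopifnot(inherits(profiles, "physician_profiles"))
  readr::write_csv(profiles$assignments, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_profiles_csv
#' @export
write_centroids_csv <- function(profiles, path) {
  stopifnot(inherits(profiles, "physician_profiles"))
  tabs <- purrr::imap_dfr(profiles$dimensions, function(d, nm) {
    d$centroids_z |>
      dplyr::mutate(dimension = nm,
                    label = d$labels[match(.data$cluster, d$centroids_z$cluster)]) |>
      tidyr::pivot_longer(cols = -c("dimension", "cluster", "n", "label"),
                          names_to = "metric", values_to = "z")
  })
  readr::write_csv(tabs, path, progress = FALSE)
  invisible(path)
}
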