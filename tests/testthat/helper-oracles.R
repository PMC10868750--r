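# Brute-force graph oracles, independent of igraph: Floyd-Warshall distances,
# shortest-path counting by distance-layer DP, and the derived measures.

fw_distances <- function(W) {
  # W: n x n matrix of edge lengths, Inf where no edge
  n <- nrow(W)
  D <- W
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

count_shortest_paths <- function(A, D) {
  # A: adjacency (logical), D: unweighted distance matrix
  n <- nrow(A)
  S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    S[s, s] <- 1
    ds <- D[s, ]
    for (dd in sort(unique(ds[is.finite(ds) & ds > 0]))) {
      for (t in which(ds == dd)) {
        S[s, t] <- sum(S[s, which(A[, t] & ds == dd - 1)])
      }
    }
  }
  S
}

oracle_closeness <- function(D) {
  n <- nrow(D)
  vapply(seq_len(n), function(v) {
    d <- D[v, -v]
    r <- sum(is.finite(d))
    if (r == 0) NaN else r / sum(d[is.finite(d)])
  }, numeric(1))
}

oracle_betweenness <- function(A, D) {
  n <- nrow(A)
  S <- count_shortest_paths(A, D)
  vapply(seq_len(n), function(v) {
    tot <- 0
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (s != t && s != v && t != v && is.finite(D[s, t]) &&
            D[s, v] + D[v, t] == D[s, t]) {
          tot <- tot + S[s, v] * S[v, t] / S[s, t]
        }
      }
    }
    tot
  }, numeric(1))
}

oracle_eccentricity <- function(D) {
  vapply(seq_len(nrow(D)), function(v) {
    d <- D[v, ]
    d <- d[is.finite(d) & d > 0]
    if (length(d) == 0) 0 else max(d)
  }, numeric(1))
}

oracle_global_efficiency <- function(D) {
  n <- nrow(D)
  if (n < 2) return(0)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_components <- function(A, mode = c("weak", "strong")) {
  mode <- match.arg(mode)
  n <- nrow(A)
  R <- if (mode == "weak") A | t(A) else A
  W <- matrix(Inf, n, n)
  W[R] <- 1
  D <- fw_distances(W)
  reach <- is.finite(D)
  conn <- if (mode == "weak") reach else reach & t(reach)
  length(unique(apply(conn, 1, function(r) paste(which(r), collapse = ","))))
}

random_digraph <- function(n, p) {
  A <- matrix(stats::runif(n * n) < p, n, n)
  diag(A) <- FALSE
  A
}

# assemble a referral_network-shaped object from an edge tibble (or adjacency
# matrix), bypassing the claims layer, for pure graph-measure tests
toy_network <- function(edges, extra_vertices = character(0),
                        config = study_config()) {
  if (is.matrix(edges)) {
    idx <- which(edges != 0, arr.ind = TRUE)
    ids <- if (nrow(edges) <= 26) {
      LETTERS[seq_len(nrow(edges))]
    } else {
      sprintf("V%02d", seq_len(nrow(edges)))
    }
    edges <- tibble::tibble(
      source_physician = ids[idx[, 1]],
      target_physician = ids[idx[, 2]],
      referral_count = 1L,
      Ew = 1
    )
  }
  if (!"Ew" %in% names(edges)) edges$Ew <- 1
  if (!"referral_count" %in% names(edges)) edges$referral_count <- 1L
  ids <- sort(unique(c(edges$source_physician, edges$target_physician,
                       extra_vertices)))
  vertices <- tibble::tibble(
    physician_id = ids, specialty = "generic", age = NA_real_,
    municipality = NA_character_, consultations = 0L,
    Vw = 1 / length(ids), follow_ups = 0L, n_patients = 1L,
    referrals_made = 0L, referrals_received = 0L, low_productivity = FALSE
  )
  g <- igraph::graph_from_data_frame(
    dplyr::rename(edges, from = "source_physician", to = "target_physician"),
    directed = TRUE, vertices = vertices
  )
  structure(list(graph = g, vertices = vertices, edges = edges,
                 events = edges[0, ], excluded = vertices[0, ],
                 productivity = vertices[0, ], config = config),
            class = "referral_network")
}

adjacency_of <- function(net) {
  as.matrix(igraph::as_adjacency_matrix(net$graph, sparse = FALSE)) > 0
}
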