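#' Worked-example summary counts from a published ambulatory network
#'
#' Headline counts reported by a large published patient-sharing analysis of
#' an ambulatory care network (roster of 4,554 office-based physicians over a
#' 13.5-month window), used in the package's worked examples and consistency
#' checks: roster size, physicians isolated from the referral graph,
#' physicians flagged for low consultation productivity, and the resulting
#' graph order and size.
#'
#' @return A named list: `n_roster`, `n_isolated`, `n_low_productivity`,
#'   `n_vertices`, `n_edges`.
#' @export
example_network_counts <- function() {
  list(
    n_roster = 4554L,
    n_isolated = 15L,
    n_low_productivity = 577L,
    n_vertices = 4539L,
    n_edges = 1160346L
  )
}

#' Exclusion-ledger arithmetic
#'
#' Derives the analysis-set sizes implied by a roster and its exclusions:
#' isolated physicians leave the network entirely (physicians that are both
#' isolated and low-productivity are counted as isolated, since that
#' exclusion is applied first); low-productivity physicians stay in the
#' network but leave the vertex-level analysis set.
#'
#' @param n_roster Roster headcount.
#' @param n_isolated Physicians with no referrals made or received.
#' @param n_low_productivity Physicians below the productivity threshold.
#' @param n_overlap Physicians counted in both exclusion groups.
#' @return A tibble with `n_vertices` (network order), `n_profiled`
#'   (vertex-level analysis set) and `low_productivity_share` (fraction of
#'   the roster).
#' @examples
#' exclusion_ledger(4554, 15, 577)
#' @export
exclusion_ledger <- function(n_roster, n_isolated, n_low_productivity,
                             n_overlap = 0L) {
  if (n_overlap > min(n_isolated, n_low_productivity)) {
    abort("`n_overlap` cannot exceed either exclusion count.")
  }
  tibble::tibble(
    n_roster = as.integer(n_roster),
    n_isolated = as.integer(n_isolated),
    n_low_productivity = as.integer(n_low_productivity),
    n_vertices = as.integer(n_roster - n_isolated),
    n_profiled = as.integer(n_roster - n_isolated -
                              (n_low_productivity - n_overlap)),
    low_productivity_share = n_low_productivity / n_roster
  )
}

#' Worked-example cluster centroid table
#'
#' The twelve K-means cluster centroids (in Z units, i.e. standard deviations
#' from the analyzed-group mean) and cluster sizes reported by the same
#' published analysis behind [example_network_counts()], spanning the three
#' profiling dimensions. Used as the golden input for [label_clusters()]: the
#' default thresholds must reproduce the published semantic labels for all
#' twelve rows.
#'
#' @return A tibble with `dimension`, `cluster`, `n`, the centroid Z columns
#'   (`NA` where a metric does not belong to a dimension) and the
#'   `published_label`.
#' @export
example_centroid_table <- function() {
  dplyr::bind_rows(
    tibble::tibble(
      dimension = "centrality",
      cluster = 1:3,
      n = c(1768L, 1258L, 951L),
      closeness_out_w = c(-0.1, 0.6, -0.7),
      closeness_in_w = c(-0.2, -0.6, 1.1),
      eccentricity = c(-0.7, 1.5, -0.6),
      pagerank = c(-0.3, -0.7, 1.4),
      subgraph_centrality = c(-0.3, -0.6, 1.3),
      betweenness = c(-0.3, -0.5, 1.2),
      betweenness_w = c(-0.1, 0.0, 0.1),
      published_label = c("intermediate", "peripheral", "central")
    ),
    tibble::tibble(
      dimension = "relationship_with_authorities",
      cluster = 1:4,
      n = c(233L, 883L, 2828L, 33L),
      authority = c(-0.04, 0.15, -0.04, 0.10),
      hub = c(2.1, 0.5, -0.4, 6.9),
      published_label = c("seeks_authorities", "is_authority", "balanced",
                          "seeks_authorities")
    ),
    tibble::tibble(
      dimension = "patient_follow_up",
      cluster = 1:5,
      n = c(64L, 1502L, 293L, 455L, 1663L),
      referrals_made = c(4.7, -0.6, -0.9, 1.3, 0.2),
      referrals_received = c(4.5, -0.6, -1.0, 1.3, 0.2),
      follow_ups = c(4.4, -0.6, 1.2, 1.1, -0.1),
      degree_in = c(0.1, 0.0, -0.8, 0.2, 0.1),
      degree_in_w = c(0.2, -0.1, -0.5, 0.3, 0.1),
      degree_out = c(0.1, 0.0, -0.8, 0.2, 0.1),
      degree_out_w = c(4.7, -0.6, -0.9, 1.3, 0.2),
      published_label = c("strong_shared", "weak_shared", "strong_prevalent",
                          "strong_shared", "moderate_shared")
    )
  )
}
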