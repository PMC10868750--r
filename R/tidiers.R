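#' Tidy and glance methods
#'
#' broom-style accessors: `tidy()` returns the per-unit table of a result
#' (edges of a network, cells of a contingency analysis, members of a
#' partition, physicians of a profile set); `glance()` returns a one-row
#' summary.
#'
#' @param x The object.
#' @param ... Unused.
#' @return A tibble.
#' @name ambnet-tidiers
NULL

#' @rdname ambnet-tidiers
#' @exportS3Method broom::tidy
tidy.referral_network <- function(x, ...) {
  x$edges
}

#' @rdname ambnet-tidiers
#' @exportS3Method broom::glance
glance.referral_network <- function(x, ...) {
  tibble::tibble(
    n_vertices = nrow(x$vertices),
    n_edges = nrow(x$edges),
    n_referral_events = sum(x$edges$referral_count),
    n_isolated_excluded = nrow(x$excluded),
    n_low_productivity = sum(x$vertices$low_productivity)
  )
}

#' @rdname ambnet-tidiers
#' @exportS3Method broom::tidy
tidy.contingency_analysis <- function(x, ...) {
  rn <- rownames(x$observed) %||% as.character(seq_len(nrow(x$observed)))
  cn <- colnames(x$observed) %||% as.character(seq_len(ncol(x$observed)))
  tidyr::expand_grid(row = rn, column = cn) |>
    dplyr::mutate(
      observed = as.vector(t(x$observed)),
      expected = as.vector(t(x$expected)),
      residual = as.vector(t(x$residuals)),
      tier = as.vector(t(x$tiers)),
      direction = as.vector(t(x$directions))
    )
}

#' @rdname ambnet-tidiers
#' @exportS3Method broom::glance
glance.contingency_analysis <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 n = sum(x$observed))
}

#' @rdname ambnet-tidiers
#' @exportS3Method broom::tidy
tidy.community_partition <- function(x, ...) {
  x$membership
}

#' @rdname ambnet-tidiers
#' @exportS3Method broom::glance
glance.community_partition <- function(x, ...) {
  tibble::tibble(n_communities = x$n_communities,
                 codelength = x$codelength,
                 modularity = x$modularity)
}

#' @rdname ambnet-tidiers
#' @exportS3Method broom::tidy
tidy.physician_profiles <- function(x, ...) {
  x$assignments
}

#' @rdname ambnet-tidiers
#' @exportS3Method broom::glance
glance.physician_profiles <- function(x, ...) {
  tibble::tibble(
    n_physicians = nrow(x$assignments),
    k_centrality = x$dimensions$centrality$k,
    k_authorities = x$dimensions$relationship_with_authorities$k,
    k_follow_up = x$dimensions$patient_follow_up$k
  )
}

#' @rdname ambnet-tidiers
#' @exportS3Method broom::tidy
tidy.group_comparison <- function(x, ...) {
  x$summaries
}

#' @rdname ambnet-tidiers
#' @exportS3Method broom::glance
glance.group_comparison <- function(x, ...) {
  tibble::tibble(test = x$test, statistic = x$statistic, p_value = x$p_value)
}
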