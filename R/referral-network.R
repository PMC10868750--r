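#' Extract referral events from visit records
#'
#' A referral event links physician `vi` to physician `vj` whenever the same
#' patient has a visit to `vi` followed by a visit to a *different* physician
#' `vj` with an inter-visit gap inside the inclusive referral window
#' (default 7-45 days). By default every qualifying ordered visit pair counts
#' (the literal reading of the window rule, robust to row order);
#' `config$consecutive_only` restricts to consecutive visits and
#' `config$unique_patients` collapses multiple events of one patient between
#' the same pair of physicians.
#'
#' @param visits Visit tibble (`patient_id`, `physician_id`, `visit_date`).
#' @param config A [study_config()].
#' @return A tibble of events: `patient_id`, `source_physician`,
#'   `target_physician`, `source_date`, `target_date`, `gap_days`, sorted
#'   deterministically.
#' @export
extract_referrals <- function(visits, config = study_config()) {
  pairs <- visit_pairs(visits, config) |>
    dplyr::filter(.data$physician_id.x != .data$physician_id.y)
  out <- pairs |>
    dplyr::transmute(
      patient_id = .data$patient_id,
      source_physician = .data$physician_id.x,
      target_physician = .data$physician_id.y,
      source_date = .data$visit_date.x,
      target_date = .data$visit_date.y,
      gap_days = .data$gap_days
    )
  if (config$unique_patients) {
    out <- out |>
      dplyr::group_by(.data$patient_id, .data$source_physician,
                      .data$target_physician) |>
      dplyr::slice_min(.data$source_date, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  dplyr::arrange(out, .data$patient_id, .data$source_date, .data$target_date,
                 .data$source_physician, .data$target_physician)
}

# all ordered same-patient visit pairs with in-window gap (any physician pair);
# consecutive_only pairs only temporally adjacent visits of the patient
visit_pairs <- function(visits, config) {
  v <- visits |>
    dplyr::select("patient_id", "physician_id", "visit_date") |>
    dplyr::arrange(.data$patient_id, .data$visit_date, .data$physician_id)
  if (config$consecutive_only) {
    paired <- v |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::mutate(
        physician_id.y = dplyr::lead(.data$physician_id),
        visit_date.y = dplyr::lead(.data$visit_date)
      ) |>
      dplyr::ungroup() |>
      dplyr::filter(!is.na(.data$physician_id.y)) |>
      dplyr::rename(physician_id.x = "physician_id", visit_date.x = "visit_date")
  } else {
    paired <- dplyr::inner_join(v, v, by = "patient_id",
                                relationship = "many-to-many") |>
      dplyr::filter(.data$visit_date.y >= .data$visit_date.x) |>
      dplyr::filter(!(.data$visit_date.y == .data$visit_date.x &
                        .data$physician_id.y <= .data$physician_id.x))
  }
  paired |>
    dplyr::mutate(gap_days = as.integer(.data$visit_date.y - .data$visit_date.x)) |>
    dplyr::filter(.data$gap_days >= config$referral_min_gap,
                  .data$gap_days <= config$referral_max_gap)
}

#' Count in-window follow-up consultations per physician
#'
#' A follow-up consultation is an ordered same-patient, same-physician visit
#' pair whose gap lies in the same inclusive window used for referrals
#' (the window is symmetric with the referral definition and configurable).
#'
#' @inheritParams extract_referrals
#' @return A tibble `physician_id`, `follow_ups` covering every physician that
#'   appears in `visits` (zero when none).
#' @export
count_follow_ups <- function(visits, config = study_config()) {
  pairs <- visit_pairs(visits, config) |>
    dplyr::filter(.data$physician_id.x == .data$physician_id.y)
  counts <- pairs |>
    dplyr::count(physician_id = .data$physician_id.x, name = "follow_ups")
  visits |>
    dplyr::distinct(.data$physician_id) |>
    dplyr::left_join(counts, by = "physician_id") |>
    dplyr::mutate(follow_ups = as.integer(tidyr::replace_na(.data$follow_ups, 0L))) |>
    dplyr::arrange(.data$physician_id)
}

#' Vertex weights: each physician's share of all consultations
#'
#' The vertex weight factors as (physician's share of their specialty's
#' consultations) x (specialty's share of all consultations), which telescopes
#' to consultations(vi) / total consultations. Both forms are implemented; the
#' product form requires the roster for specialty lookup and agrees with the
#' ratio to machine precision.
#'
#' @param visits Visit tibble.
#' @param physicians Roster tibble (`physician_id`, `specialty`); weights are
#'   returned for every roster physician (zero consultations give weight 0).
#' @param method `"ratio"` (direct) or `"product"` (two-factor form).
#' @return A tibble `physician_id`, `consultations`, `Vw`; `sum(Vw) == 1`.
#' @export
vertex_weights <- function(visits, physicians, method = c("ratio", "product")) {
  method <- match.arg(method)
  total <- nrow(visits)
  if (total == 0) abort("No consultations: vertex weights are undefined.")
  counts <- visits |>
    dplyr::count(.data$physician_id, name = "consultations")
  out <- physicians |>
    dplyr::select("physician_id", "specialty") |>
    dplyr::left_join(counts, by = "physician_id") |>
    dplyr::mutate(consultations = as.integer(tidyr::replace_na(.data$consultations, 0L)))
  if (method == "ratio") {
    out <- dplyr::mutate(out, Vw = .data$consultations / total)
  } else {
    out <- out |>
      dplyr::group_by(.data$specialty) |>
      dplyr::mutate(spec_total = sum(.data$consultations)) |>
      dplyr::ungroup() |>
      dplyr::mutate(
        Vw = ifelse(.data$spec_total == 0, 0,
                    (.data$consultations / .data$spec_total) *
                      (.data$spec_total / total))
      ) |>
      dplyr::select(-"spec_total")
  }
  out |>
    dplyr::select("physician_id", "consultations", "Vw") |>
    dplyr::arrange(.data$physician_id)
}

#' Edge weights: referrals normalized by the source's patient base
#'
#' For every ordered physician pair with at least one referral event,
#' `Ew = referral_count / (distinct patients with at least one visit to the
#' source physician)`. The denominator counts patients, not consultations.
#'
#' @param events Referral events from [extract_referrals()].
#' @param visits The same visit tibble the events were extracted from.
#' @return A tibble `source_physician`, `target_physician`, `referral_count`,
#'   `Ew`, with `Ew > 0` for every materialized edge.
#' @export
edge_weights <- function(events, visits) {
  patients_per_doc <- visits |>
    dplyr::distinct(.data$physician_id, .data$patient_id) |>
    dplyr::count(.data$physician_id, name = "n_patients")
  out <- events |>
    dplyr::count(.data$source_physician, .data$target_physician,
                 name = "referral_count") |>
    dplyr::left_join(patients_per_doc,
                     by = c(source_physician = "physician_id"))
  if (any(is.na(out$n_patients) | out$n_patients == 0)) {
    abort("Impossible state: an edge source has no attended patients in `visits`.")
  }
  out |>
    dplyr::mutate(Ew = .data$referral_count / .data$n_patients) |>
    dplyr::select("source_physician", "target_physician", "referral_count", "Ew") |>
    dplyr::arrange(.data$source_physician, .data$target_physician)
}

#' Flag physicians with low consultation productivity
#'
#' A physician is flagged when their consultation count is *strictly* below
#' `productivity_factor` times the consultations expected for their specialty,
#' where expected = specialty consultations / specialty roster headcount
#' (including physicians with zero visits).
#'
#' @param visits Visit tibble.
#' @param physicians Roster tibble.
#' @param config A [study_config()]; supplies `productivity_factor`.
#' @return A tibble `physician_id`, `specialty`, `consultations`,
#'   `specialty_expected`, `low_productivity`.
#' @export
flag_low_productivity <- function(visits, physicians, config = study_config()) {
  if (any(is.na(physicians$specialty) | physicians$specialty == "")) {
    warn("Physicians with empty specialty are skipped in productivity flagging.")
  }
  counts <- visits |>
    dplyr::count(.data$physician_id, name = "consultations")
  physicians |>
    dplyr::select("physician_id", "specialty") |>
    dplyr::filter(!is.na(.data$specialty), .data$specialty != "") |>
    dplyr::left_join(counts, by = "physician_id") |>
    dplyr::mutate(consultations = as.integer(tidyr::replace_na(.data$consultations, 0L))) |>
    dplyr::group_by(.data$specialty) |>
    dplyr::mutate(specialty_expected = sum(.data$consultations) / dplyr::n()) |>
    dplyr::ungroup() |>
    dplyr::mutate(low_productivity = .data$consultations <
                    config$productivity_factor * .data$specialty_expected) |>
    dplyr::arrange(.data$physician_id)
}

#' Build the directed weighted referral network
#'
#' Runs the full construction: referral events, edge weights, vertex weights,
#' follow-up counts and productivity flags, and assembles an igraph object
#' over the physicians with at least one incoming or outgoing referral.
#' Isolated physicians (no referrals either way) are listed in the exclusion
#' report; low-productivity physicians are *retained* in the network (they are
#' excluded only from vertex-level profiling downstream).
#'
#' @param visits,physicians Claims tibbles.
#' @param config A [study_config()].
#' @return An object of class `"referral_network"`: a list with `graph`
#'   (igraph, edge attributes `referral_count`/`Ew`, vertex attributes
#'   `specialty`, `Vw`, `consultations`, `follow_ups`, `n_patients`,
#'   `referrals_made`, `referrals_received`, `low_productivity`), tibbles
#'   `vertices`, `edges`, `events`, `excluded` (isolated physicians), and the
#'   `config`.
#' @examples
#' fix <- small_worked_fixture()
#' net <- build_referral_network(fix$visits, fix$physicians)
#' igraph::gorder(net$graph)
#' @export
build_referral_network <- function(visits, physicians, config = study_config()) {
  events <- extract_referrals(visits, config)
  if (nrow(events) == 0) {
    abort("No referral events in the window: the network would be empty.")
  }
  edges <- edge_weights(events, visits)
  vw <- vertex_weights(visits, physicians)
  fu <- count_follow_ups(visits, config)
  prod <- flag_low_productivity(visits, physicians, config)
  patients_per_doc <- visits |>
    dplyr::distinct(.data$physician_id, .data$patient_id) |>
    dplyr::count(.data$physician_id, name = "n_patients")

  made <- events |>
    dplyr::count(physician_id = .data$source_physician, name = "referrals_made")
  received <- events |>
    dplyr::count(physician_id = .data$target_physician, name = "referrals_received")

  active_ids <- sort(union(edges$source_physician, edges$target_physician))
  vertices <- physicians |>
    dplyr::filter(.data$physician_id %in% active_ids) |>
    dplyr::left_join(vw, by = "physician_id") |>
    dplyr::left_join(fu, by = "physician_id") |>
    dplyr::left_join(patients_per_doc, by = "physician_id") |>
    dplyr::left_join(made, by = "physician_id") |>
    dplyr::left_join(received, by = "physician_id") |>
    dplyr::left_join(dplyr::select(prod, "physician_id", "low_productivity"),
                     by = "physician_id") |>
    dplyr::mutate(dplyr::across(c("follow_ups", "n_patients", "referrals_made",
                                  "referrals_received"),
                                ~ as.integer(tidyr::replace_na(.x, 0L))),
                  low_productivity = tidyr::replace_na(.data$low_productivity, FALSE)) |>
    dplyr::arrange(.data$physician_id)

  excluded <- physicians |>
    dplyr::filter(!.data$physician_id %in% active_ids) |>
    dplyr::left_join(vw, by = "physician_id") |>
    dplyr::mutate(reason = "no referrals made or received") |>
    dplyr::arrange(.data$physician_id)

  g <- igraph::graph_from_data_frame(
    d = dplyr::rename(edges, from = "source_physician", to = "target_physician"),
    directed = TRUE,
    vertices = vertices
  )

  structure(
    list(graph = g, vertices = vertices, edges = edges, events = events,
         excluded = excluded, productivity = prod, config = config),
    class = "referral_network"
  )
}

#' @export
print.referral_network <- function(x, ...) {
  cat("<referral_network>\n")
  cat("  vertices:", nrow(x$vertices), " edges:", nrow(x$edges),
      " referral events:", sum(x$edges$referral_count), "\n")
  cat("  isolated physicians excluded:", nrow(x$excluded), "\n")
  cat("  low-productivity (retained here):",
      sum(x$vertices$low_productivity), "\n")
  invisible(x)
}

#' Export a referral network
#'
#' `write_network_graphml()` writes the igraph object (with all vertex and
#' edge attributes) as GraphML; `write_network_edges()` writes the edge list
#' as CSV; `write_exclusion_report()` writes the isolated-physician report.
#'
#' @param net A `"referral_network"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  stopifnot(inherits(net, "referral_network"))
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_edges <- function(net, path) {
  stopifnot(inherits(net, "referral_network"))
  readr::write_csv(net$edges, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_exclusion_report <- function(net, path) {
  stopifnot(inherits(net, "referral_network"))
  readr::write_csv(net$excluded, path, progress = FALSE)
  invisible(path)
}
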