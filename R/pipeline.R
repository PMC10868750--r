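#' Run the full referral-network analysis pipeline
#'
#' Orchestrates simulate (optional) -> validate -> build -> measure ->
#' profile -> communities -> associate, applying the exclusion sequencing of
#' the design: physicians with no referrals either way are dropped before any
#' measure; low-productivity physicians are kept for the network-level
#' measures and community detection but excluded from Z-scoring, profiling
#' and the association analyses. A physician that is both isolated and
#' low-productivity is counted as isolated. Fully deterministic given
#' `config$seed`.
#'
#' @param visits,physicians,patients Claims tibbles; leave `NULL` to simulate
#'   a dataset with [simulate_claims()] under `simulate_args`.
#' @param config A [study_config()].
#' @param clustering A [clustering_config()]; its seed is derived from
#'   `config$seed` when left at `NULL`.
#' @param thresholds A [label_thresholds()] list.
#' @param simulate_args List of arguments forwarded to [simulate_claims()]
#'   when no data are given.
#' @return A list of class `"amb_report"`: `network_measures` (one-row
#'   tibble), `vertex_quantiles` (Z-score five-number summary per measure),
#'   `profiles` (a `"physician_profiles"`), `partition`, `communities`
#'   (characterization tibble), `profile_by_specialty` and
#'   `profile_by_profile` (lists of `"contingency_analysis"`),
#'   `comorbidity_by_profile` (list of `"group_comparison"`), `exclusions`
#'   (ledger tibble), `truth` (when simulated), plus the inputs and
#'   intermediate objects (`net`, `vertex_metrics`, `vertex_z`).
#' @examples
#' \donttest{
#' rep <- run_pipeline(config = study_config(seed = 7),
#'                     simulate_args = list(n_patients = 300))
#' rep$network_measures$density
#' }
#' @export
run_pipeline <- function(visits = NULL, physicians = NULL, patients = NULL,
                         config = study_config(),
                         clustering = NULL,
                         thresholds = label_thresholds(),
                         simulate_args = list()) {
  log <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    inform(paste0("[ambnet] ", msg))
  }
  truth <- NULL
  if (is.null(visits)) {
    args <- utils::modifyList(
      list(seed = stage_seed(config, "simulate"), config = config),
      simulate_args
    )
    sim <- do.call(simulate_claims, args)
    visits <- sim$visits
    physicians <- sim$physicians
    patients <- sim$patients
    truth <- sim$truth
    note("simulate: ", nrow(visits), " visits, ", nrow(physicians),
         " physicians, ", nrow(patients), " patients")
  }
  if (is.null(clustering)) {
    clustering <- clustering_config(seed = stage_seed(config, "profile"))
  }

  val <- validate_claims(visits, physicians, patients)
  if (!val$is_valid) {
    abort("Stage `validate` failed: inconsistent claims tables (see validate_claims()).")
  }
  note("validate: ", nrow(visits), " visit rows pass cross-checks")

  net <- build_referral_network(visits, physicians, config)
  note("build: ", nrow(net$vertices), " vertices, ", nrow(net$edges),
       " edges, ", nrow(net$excluded), " isolated excluded")

  nm <- network_measures(net)
  vm <- vertex_measures(net)

  low_ids <- net$vertices$physician_id[net$vertices$low_productivity]
  included <- setdiff(net$vertices$physician_id, low_ids)
  if (length(included) < 3) abort("Stage `measure` failed: analysis set too small.")
  vz <- suppressWarnings(zscore_metrics(vm, included))
  note("measure: ", length(included), " physicians in the vertex-level set (",
       length(low_ids), " low-productivity excluded)")

  vertex_quantiles <- vz |>
    dplyr::select(-"physician_id") |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "measure",
                        values_to = "z") |>
    dplyr::group_by(.data$measure) |>
    dplyr::summarise(
      min = min(.data$z, na.rm = TRUE),
      p25 = quantile(.data$z, 0.25, na.rm = TRUE),
      median = median(.data$z, na.rm = TRUE),
      p75 = quantile(.data$z, 0.75, na.rm = TRUE),
      max = max(.data$z, na.rm = TRUE),
      .groups = "drop"
    )

  profiles <- profile_physicians(vm, included, clustering, thresholds)
  note("profile: k = ",
       paste(vapply(profiles$dimensions, function(d) d$k, integer(1)),
             collapse = "/"))

  partition <- detect_communities(net, seed = stage_seed(config, "communities"))
  low_frac <- partition$membership |>
    dplyr::mutate(low = .data$physician_id %in% low_ids) |>
    dplyr::group_by(.data$community) |>
    dplyr::summarise(n = dplyr::n(), low_share = mean(.data$low), .groups = "drop")
  reported_communities <- low_frac$community[low_frac$low_share <= 0.5]
  note("communities: ", partition$n_communities, " detected, ",
       length(reported_communities), " reported after the low-productivity filter")

  communities <- characterize_communities(partition, physicians, profiles,
                                          alpha = config$alpha)

  # association layer over the profiled physicians
  pa <- profiles$assignments |>
    dplyr::left_join(physicians, by = "physician_id")
  dims <- c("centrality", "relationship_with_authorities", "patient_follow_up")
  # degenerate tables (a dimension collapsing to one label on tiny inputs)
  # are skipped rather than failing the stage
  try_or_null <- function(expr) {
    tryCatch(suppressWarnings(expr), error = function(e) NULL)
  }
  profile_by_specialty <- purrr::compact(
    purrr::map(setNames(dims, dims), function(d) {
      try_or_null(contingency_analysis(
        table(pa$specialty, pa[[paste0(d, "_label")]])))
    })
  )
  pairs <- utils::combn(dims, 2, simplify = FALSE)
  names(pairs) <- vapply(pairs, paste, collapse = "_x_",
                         FUN.VALUE = character(1))
  profile_by_profile <- purrr::compact(
    purrr::map(pairs, function(pr) {
      try_or_null(contingency_analysis(
        table(pa[[paste0(pr[1], "_label")]], pa[[paste0(pr[2], "_label")]])))
    })
  )

  burden <- physician_comorbidity_burden(visits, patients) |>
    dplyr::inner_join(profiles$assignments, by = "physician_id")
  comorbidity_by_profile <- purrr::compact(
    purrr::map(setNames(dims, dims), function(d) {
      try_or_null(compare_groups(burden, "comorbidity_per_100",
                                 paste0(d, "_label"),
                                 test = "kruskal_wallis"))
    })
  )
  note("associate: ", length(profile_by_specialty) +
         length(profile_by_profile) + length(comorbidity_by_profile),
       " association analyses")

  n_overlap <- sum(net$excluded$physician_id %in%
                     net$productivity$physician_id[net$productivity$low_productivity])
  exclusions <- exclusion_ledger(
    n_roster = nrow(physicians),
    n_isolated = nrow(net$excluded),
    n_low_productivity = sum(net$productivity$low_productivity),
    n_overlap = n_overlap
  )

  nm$n_communities <- partition$n_communities

  structure(
    list(
      network_measures = nm,
      vertex_quantiles = vertex_quantiles,
      profiles = profiles,
      partition = partition,
      reported_communities = reported_communities,
      communities = communities,
      profile_by_specialty = profile_by_specialty,
      profile_by_profile = profile_by_profile,
      comorbidity_by_profile = comorbidity_by_profile,
      exclusions = exclusions,
      net = net,
      vertex_metrics = vm,
      vertex_z = vz,
      truth = truth,
      config = config,
      log = log
    ),
    class = "amb_report"
  )
}

#' Comorbidity burden of each physician's patient panel
#'
#' Chronic comorbidities per 100 distinct patients attended.
#'
#' @param visits Visit tibble.
#' @param patients Patient tibble with `comorbidity_count`.
#' @return A tibble `physician_id`, `n_patients`, `comorbidity_per_100`.
#' @export
physician_comorbidity_burden <- function(visits, patients) {
  visits |>
    dplyr::distinct(.data$physician_id, .data$patient_id) |>
    dplyr::inner_join(patients, by = "patient_id") |>
    dplyr::group_by(.data$physician_id) |>
    dplyr::summarise(
      n_patients = dplyr::n(),
      comorbidity_per_100 = 100 * sum(.data$comorbidity_count) / dplyr::n(),
      .groups = "drop"
    )
}

#' @export
print.amb_report <- function(x, ...) {
  cat("<amb_report>\n")
  cat("  network :", x$network_measures$n_vertices, "vertices,",
      x$network_measures$n_edges, "edges, density",
      sprintf("%.2f%%", 100 * x$network_measures$density), "\n")
  cat("  profiles:", nrow(x$profiles$assignments), "physicians profiled\n")
  cat("  communities:", x$partition$n_communities,
      sprintf("(modularity = %.3f)", x$partition$modularity), "\n")
  invisible(x)
}

#' Render an analysis report to files
#'
#' Writes the machine-readable JSON and/or a human-readable Markdown digest
#' (network table, Z-score quantiles, centroid tables with labels,
#' contingency analyses with directional residual marks and footnote-style
#' tiers, community composition, exclusion ledger).
#'
#' @param report An `"amb_report"`.
#' @param dir Output directory (created if needed).
#' @param formats Subset of `c("json", "markdown")`.
#' @return Character vector of files written, invisibly.
#' @export
render_report <- function(report, dir, formats = c("json", "markdown")) {
  stopifnot(inherits(report, "amb_report"))
  bad <- setdiff(formats, c("json", "markdown"))
  if (length(bad) > 0) {
    abort(paste0("Unknown format(s): ", paste(bad, collapse = ", "),
                 ". Supported: json, markdown."))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  if ("json" %in% formats) {
    path <- file.path(dir, "report.json")
    jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                         digits = NA)
    written <- c(written, path)
  }
  if ("markdown" %in% formats) {
    path <- file.path(dir, "report.md")
    writeLines(report_to_markdown(report), path)
    written <- c(written, path)
  }
  invisible(written)
}

report_to_list <- function(report) {
  ca_list <- function(ca) {
    list(statistic = ca$statistic, df = ca$df, p_value = ca$p_value,
         cells = tidy(ca))
  }
  list(
    network_measures = {
      nm <- as.list(report$network_measures)
      nm$articulation_points <- report$network_measures$articulation_points[[1]]
      nm
    },
    vertex_quantiles = report$vertex_quantiles,
    profile_assignments = report$profiles$assignments,
    centroids = purrr::imap(report$profiles$dimensions, function(d, nm) {
      list(k = d$k, centroids_z = d$centroids_z, labels = d$labels)
    }),
    partition = list(n_communities = report$partition$n_communities,
                     codelength = report$partition$codelength,
                     modularity = report$partition$modularity,
                     membership = report$partition$membership),
    reported_communities = report$reported_communities,
    communities = report$communities,
    profile_by_specialty = purrr::map(report$profile_by_specialty, ca_list),
    profile_by_profile = purrr::map(report$profile_by_profile, ca_list),
    comorbidity_by_profile = purrr::map(report$comorbidity_by_profile,
                                        function(gc) {
                                          list(test = gc$test,
                                               statistic = gc$statistic,
                                               p_value = gc$p_value,
                                               summaries = gc$summaries)
                                        }),
    exclusions = report$exclusions,
    log = report$log
  )
}

fmt_n <- function(n) format(n, big.mark = ",", trim = TRUE)
fmt_pct <- function(p) sprintf("%.1f%%", 100 * p)

report_to_markdown <- function(report) {
  out <- c("# Ambulatory referral network analysis", "")
  nm <- report$network_measures
  out <- c(out, "## Network-level measures", "",
           paste0("- Vertices: ", fmt_n(nm$n_vertices)),
           paste0("- Edges: ", fmt_n(nm$n_edges)),
           paste0("- Density: ", fmt_pct(nm$density)),
           paste0("- Weak / strong components: ", nm$weak_components, " / ",
                  nm$strong_components),
           paste0("- Clustering coefficient: ",
                  sprintf("%.3f", nm$global_clustering)),
           paste0("- Diameter: ", nm$diameter_unweighted, " (unweighted); ",
                  sprintf("%.3f", nm$diameter_weighted), " (weighted)"),
           paste0("- Average path length: ",
                  sprintf("%.3f", nm$avg_path_length_unweighted),
                  " (unweighted); ",
                  sprintf("%.3f", nm$avg_path_length_weighted), " (weighted)"),
           paste0("- Global efficiency: ",
                  sprintf("%.3f", nm$global_efficiency_unweighted),
                  " (unweighted); ",
                  sprintf("%.3f", nm$global_efficiency_weighted), " (weighted)"),
           paste0("- Articulation points: ", nm$n_articulation_points),
           paste0("- Communities: ", nm$n_communities,
                  sprintf(" (modularity = %.3f)", report$partition$modularity)),
           "")
  out <- c(out, "## Vertex-level Z-score quantiles", "",
           "| Measure | Min | P25 | Median | P75 | Max |",
           "|---|---|---|---|---|---|",
           purrr::pmap_chr(report$vertex_quantiles, function(measure, min, p25,
                                                            median, p75, max) {
             sprintf("| %s | %.2f | %.2f | %.2f | %.2f | %.2f |",
                     measure, min, p25, median, p75, max)
           }), "")
  out <- c(out, "## Physician profiles (cluster centroids, Z units)", "")
  for (nmd in names(report$profiles$dimensions)) {
    d <- report$profiles$dimensions[[nmd]]
    out <- c(out, paste0("### Dimension: ", nmd, " (k = ", d$k, ")"), "")
    cz <- d$centroids_z
    metric_cols <- setdiff(names(cz), c("cluster", "n"))
    out <- c(out,
             paste0("| Cluster | n | ",
                    paste(metric_cols, collapse = " | "), " | Label |"),
             paste0("|", paste(rep("---", length(metric_cols) + 3),
                               collapse = "|"), "|"),
             vapply(seq_len(nrow(cz)), function(i) {
               paste0("| ", cz$cluster[i], " | ", fmt_n(cz$n[i]), " | ",
                      paste(sprintf("%+.1f", as.numeric(cz[i, metric_cols])),
                            collapse = " | "),
                      " | ", d$labels[i], " |")
             }, character(1)), "")
  }
  ca_md <- function(ca, title) {
    cells <- tidy(ca)
    mark <- ifelse(cells$tier == "ns", "",
                   paste0(ifelse(cells$direction == "above", "↑", "↓"),
                          " (", cells$tier, ")"))
    c(paste0("### ", title), "",
      sprintf("Chi-square = %.2f, df = %d, p = %.3g", ca$statistic, ca$df,
              ca$p_value), "",
      "| Row | Column | Observed | Expected | Residual | Mark |",
      "|---|---|---|---|---|---|",
      sprintf("| %s | %s | %s | %.1f | %+.2f | %s |",
              cells$row, cells$column, fmt_n(cells$observed), cells$expected,
              cells$residual, mark), "")
  }
  out <- c(out, "## Profiles by specialty", "",
           unlist(purrr::imap(report$profile_by_specialty, function(ca, nmd) {
             ca_md(ca, paste0("Specialty x ", nmd))
           })))
  out <- c(out, "## Profiles by profiles", "",
           unlist(purrr::imap(report$profile_by_profile, function(ca, nmd) {
             ca_md(ca, nmd)
           })))
  out <- c(out, "## Comorbidity burden by profile", "")
  for (nmd in names(report$comorbidity_by_profile)) {
    gc <- report$comorbidity_by_profile[[nmd]]
    out <- c(out, paste0("### ", nmd), "",
             sprintf("Kruskal-Wallis chi-square = %.2f, p = %.3g",
                     gc$statistic, gc$p_value), "",
             "| Profile | n | Median per 100 | P25 | P75 |",
             "|---|---|---|---|---|",
             sprintf("| %s | %s | %.0f | %.0f | %.0f |",
                     gc$summaries$group, fmt_n(gc$summaries$n),
                     gc$summaries$median, gc$summaries$q1, gc$summaries$q3),
             "")
  }
  ex <- report$exclusions
  out <- c(out, "## Exclusion ledger", "",
           paste0("- Roster: ", fmt_n(ex$n_roster)),
           paste0("- Isolated (no referrals either way): ", fmt_n(ex$n_isolated)),
           paste0("- Low consultation productivity: ",
                  fmt_n(ex$n_low_productivity), " (",
                  fmt_pct(ex$low_productivity_share), " of roster)"),
           paste0("- Network vertices: ", fmt_n(ex$n_vertices)),
           paste0("- Vertex-level analysis set: ", fmt_n(ex$n_profiled)),
           "")
  out
}
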