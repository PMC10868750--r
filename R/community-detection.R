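#' Detect medical communities with the map equation (Infomap)
#'
#' Two-level flow-based community detection on the directed graph, with Ew as
#' edge (flow) weights and Vw as vertex weights, via igraph's Infomap
#' implementation. Deterministic given `seed` and `trials`. The returned
#' partition carries the optimizer's description length (codelength, bits)
#' and the directed weighted Newman modularity of the partition.
#'
#' @param net A [build_referral_network()] result (needs at least one edge).
#' @param seed Integer seed.
#' @param trials Number of optimization attempts (best kept).
#' @return A list of class `"community_partition"`: `membership` tibble
#'   (`physician_id`, `community` with ids contiguous from 1),
#'   `n_communities`, `codelength`, `modularity`.
#' @export
detect_communities <- function(net, seed = 1L, trials = 10L) {
  g <- net$graph
  if (igraph::gsize(g) < 1) abort("Cannot detect communities on an edgeless network.")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  cm <- igraph::cluster_infomap(g,
                                e.weights = igraph::E(g)$Ew,
                                v.weights = igraph::V(g)$Vw,
                                nb.trials = as.integer(trials))
  memb <- igraph::membership(cm)
  # contiguous ids ordered by decreasing community size, ties by first member
  sizes <- sort(table(memb), decreasing = TRUE)
  remap <- setNames(seq_along(sizes), names(sizes))
  community <- unname(remap[as.character(memb)])
  membership <- tibble::tibble(physician_id = igraph::V(g)$name,
                               community = as.integer(community))
  structure(
    list(
      membership = membership,
      n_communities = length(sizes),
      codelength = igraph::code_len(cm),
      modularity = partition_modularity(net, membership)
    ),
    class = "community_partition"
  )
}

#' @export
print.community_partition <- function(x, ...) {
  cat("<community_partition>", x$n_communities, "communities",
      sprintf("(modularity = %.3f, codelength = %.3f bits)\n",
              x$modularity, x$codelength))
  invisible(x)
}

#' Directed weighted Newman modularity of a partition
#'
#' `Q = (1/W) * sum over same-community edges of [w_ij - s_out(i) s_in(j) / W]`
#' where `W` is the total edge weight and `s_out`/`s_in` are weighted out- and
#' in-strengths. The all-in-one partition has `Q = 0` by construction.
#' Unweighted and/or undirected variants are available for comparison.
#'
#' @param net A `"referral_network"`.
#' @param membership Tibble `physician_id`, `community` covering every vertex.
#' @param weighted Use Ew (default) or unit weights.
#' @param directed Directed formula (default) or the undirected Newman form
#'   on the collapsed projection.
#' @return Modularity value (dimensionless).
#' @export
partition_modularity <- function(net, membership, weighted = TRUE,
                                 directed = TRUE) {
  g <- if (directed) net$graph else {
    igraph::as_undirected(net$graph, mode = "collapse",
                          edge.attr.comb = list(Ew = "sum", "ignore"))
  }
  ids <- igraph::V(g)$name
  comm <- membership$community[match(ids, membership$physician_id)]
  if (any(is.na(comm))) abort("`membership` must cover every network vertex.")
  w <- if (weighted) igraph::E(g)$Ew else rep(1, igraph::gsize(g))
  W <- sum(w)
  if (W == 0) abort("Zero total edge weight: modularity undefined.")
  el <- igraph::as_edgelist(g, names = FALSE)
  if (directed) {
    s_out <- igraph::strength(g, mode = "out", weights = w)
    s_in <- igraph::strength(g, mode = "in", weights = w)
    same <- comm[el[, 1]] == comm[el[, 2]]
    q_obs <- sum(w[same]) / W
    q_exp <- 0
    for (cc in unique(comm)) {
      idx <- which(comm == cc)
      q_exp <- q_exp + sum(s_out[idx]) * sum(s_in[idx]) / W^2
    }
    q_obs - q_exp
  } else {
    igraph::modularity(g, comm, weights = w)
  }
}

#' Two-level map-equation description length of a partition
#'
#' Evaluates the average per-step description length (in bits) of a random
#' walk on the directed Ew-weighted graph under a given two-level partition,
#' using stationary visit rates from PageRank-style smart teleportation
#' (teleportation probability 0.15, proportional to Vw when available). Used
#' to compare candidate partitions: a structured partition should never
#' describe the walk worse than the all-in-one module.
#'
#' @param net A `"referral_network"`.
#' @param membership Tibble `physician_id`, `community`.
#' @param teleport Teleportation probability of the walk.
#' @return Codelength in bits.
#' @export
map_equation_codelength <- function(net, membership, teleport = 0.15) {
  g <- net$graph
  ids <- igraph::V(g)$name
  comm <- membership$community[match(ids, membership$physician_id)]
  if (any(is.na(comm))) abort("`membership` must cover every network vertex.")
  n <- length(ids)
  w <- igraph::E(g)$Ew
  vw <- igraph::V(g)$Vw
  if (is.null(vw) || any(is.na(vw)) || sum(vw) == 0) vw <- rep(1 / n, n)
  vw <- vw / sum(vw)
  p <- igraph::page_rank(g, damping = 1 - teleport, weights = w,
                         personalized = vw)$vector
  el <- igraph::as_edgelist(g, names = FALSE)
  out_str <- igraph::strength(g, mode = "out", weights = w)
  # per-step flow i -> j: follow an out-link with prob (1 - teleport) (dangling
  # vertices teleport fully), teleport lands proportionally to vw
  follow <- ifelse(out_str[el[, 1]] > 0, (1 - teleport), 0)
  q_flow <- p[el[, 1]] * follow * w / out_str[el[, 1]]

  entropy_bits <- function(x) {
    x <- x[x > 0]
    -sum(x * log2(x))
  }
  modules <- sort(unique(comm))
  m_vw <- vapply(modules, function(mm) sum(vw[comm == mm]), numeric(1))
  cross <- comm[el[, 1]] != comm[el[, 2]]
  # module exit flow: link flow leaving the module + teleportation leaving it
  q_exit <- vapply(seq_along(modules), function(k) {
    mm <- modules[k]
    link_out <- sum(q_flow[cross & comm[el[, 1]] == mm])
    tele_out <- sum((p * ifelse(out_str > 0, teleport, 1))[comm == mm]) *
      (1 - m_vw[k])
    link_out + tele_out
  }, numeric(1))

  # L(M) = q * H(Q) + sum_m p_m * H(P_m)
  q_all <- sum(q_exit)
  index_term <- if (q_all > 0) q_all * entropy_bits(q_exit / q_all) else 0
  module_terms <- vapply(seq_along(modules), function(k) {
    probs <- c(q_exit[k], p[comm == modules[k]])
    tot <- sum(probs)
    if (tot <= 0) return(0)
    tot * entropy_bits(probs / tot)
  }, numeric(1))
  index_term + sum(module_terms)
}

#' Characterize detected communities
#'
#' Per community: size, specialty and municipality composition, and (when
#' profiles are given) the mix of profile labels in each dimension. Every
#' composition is cross-tabulated against the rest of the network and marked
#' with adjusted standardized residual significance tiers.
#'
#' @param partition A `"community_partition"`.
#' @param physicians Roster tibble.
#' @param profiles Optional `"physician_profiles"` object.
#' @param alpha Significance level for the over/under-representation marks.
#' @return A tibble with one row per (community, variable, level):
#'   `community`, `variable`, `level`, `n`, `share`, `residual`, `tier`,
#'   `direction`, `significant`.
#' @export
characterize_communities <- function(partition, physicians, profiles = NULL,
                                     alpha = 0.05) {
  memb <- partition$membership
  base <- memb |>
    dplyr::left_join(physicians, by = "physician_id")
  vars <- list(specialty = base$specialty)
  if (!all(is.na(base$municipality))) vars$municipality <- base$municipality
  if (!is.null(profiles)) {
    pa <- profiles$assignments
    base2 <- dplyr::left_join(memb, pa, by = "physician_id")
    for (d in c("centrality", "relationship_with_authorities",
                "patient_follow_up")) {
      col <- paste0(d, "_label")
      if (col %in% names(base2)) vars[[d]] <- base2[[col]]
    }
  }
  purrr::imap_dfr(vars, function(v, nm) {
    keep <- !is.na(v)
    tab <- table(community = base$community[keep], level = v[keep])
    if (nrow(tab) < 2 || ncol(tab) < 2) {
      counts <- as.data.frame(tab, stringsAsFactors = FALSE)
      return(tibble::tibble(
        community = as.integer(counts$community),
        variable = nm, level = counts$level, n = counts$Freq,
        share = counts$Freq / sum(counts$Freq),
        residual = 0, tier = "ns", direction = NA_character_,
        significant = FALSE
      ))
    }
    ca <- contingency_analysis(unclass(tab))
    cells <- tidy(ca)
    cells |>
      dplyr::group_by(.data$row) |>
      dplyr::mutate(share = .data$observed / sum(.data$observed)) |>
      dplyr::ungroup() |>
      dplyr::transmute(
        community = as.integer(.data$row),
        variable = nm,
        level = .data$column,
        n = .data$observed,
        share = .data$share,
        residual = .data$residual,
        tier = .data$tier,
        direction = .data$direction,
        significant = abs(.data$residual) >= qnorm(1 - alpha / 2)
      )
  })
}

#' Write a community partition / community profiles
#'
#' @param partition A `"community_partition"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_partition_csv <- function(partition, path) {
  stopifnot(inherits(partition, "community_partition"))
  readr::write_csv(partition$membership, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_partition_csv
#' @param profiles_tbl Output of [characterize_communities()].
#' @export
write_community_profiles <- function(profiles_tbl, path) {
  jsonlite::write_json(profiles_tbl, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
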