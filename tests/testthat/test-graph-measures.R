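test_that("network-level measures are exact on canonical small graphs", {
  # complete directed graph on 3 vertices
  k3 <- toy_network(tibble::tibble(
    source_physician = c("A", "A", "B", "B", "C", "C"),
    target_physician = c("B", "C", "A", "C", "A", "B")
  ))
  nm <- network_measures(k3)
  expect_equal(nm$density, 1)
  expect_equal(nm$diameter_unweighted, 1)
  expect_equal(nm$avg_path_length_unweighted, 1)

  # directed 3-cycle
  cyc <- toy_network(tibble::tibble(
    source_physician = c("A", "B", "C"),
    target_physician = c("B", "C", "A")
  ))
  nm2 <- network_measures(cyc)
  expect_equal(nm2$density, 0.5)
  expect_equal(nm2$diameter_unweighted, 2)
  expect_equal(nm2$strong_components, 1)

  # path A -> B -> C
  pth <- toy_network(tibble::tibble(
    source_physician = c("A", "B"), target_physician = c("B", "C")
  ))
  nm3 <- network_measures(pth)
  expect_equal(nm3$weak_components, 1)
  expect_equal(nm3$strong_components, 3)
  expect_equal(nm3$global_efficiency_unweighted, (1 + 1 + 0.5) / 6)
  # radius ignores vertices with zero out-degree (C here)
  expect_equal(nm3$radius, 1)
})

test_that("path measures match brute-force oracles on random small digraphs", {
  set.seed(4242)
  for (rep in 1:60) {
    n <- sample(2:6, 1)
    A <- random_digraph(n, sample(c(0.2, 0.35, 0.5), 1))
    if (sum(A) == 0) next
    net <- toy_network(A * 1)
    ids <- sort(LETTERS[1:n][rowSums(A) + colSums(A) > 0])
    keep <- match(ids, LETTERS[1:n])
    A <- A[keep, keep, drop = FALSE]
    n <- nrow(A)
    W <- matrix(Inf, n, n); W[A] <- 1
    D <- fw_distances(W)

    vm <- vertex_measures(net)
    expect_equal(vm$closeness_out, oracle_closeness(D))
    expect_equal(vm$closeness_in, oracle_closeness(fw_distances(t(W))))
    expect_equal(vm$betweenness, oracle_betweenness(A, D))
    expect_equal(vm$eccentricity, oracle_eccentricity(D))

    nm <- network_measures(net)
    expect_equal(nm$global_efficiency_unweighted, oracle_global_efficiency(D))
    expect_equal(nm$weak_components, oracle_components(A, "weak"))
    expect_equal(nm$strong_components, oracle_components(A, "strong"))
  }
})

test_that("vertex measures match closed forms on hand-solvable graphs", {
  # mutual dyad: symmetry forces equal PageRank
  dyad <- toy_network(tibble::tibble(source_physician = c("A", "B"),
                                     target_physician = c("B", "A")))
  vm <- vertex_measures(dyad)
  expect_equal(vm$pagerank, c(0.5, 0.5))

  # A -> C, B -> C: C is the sole authority, A and B the hubs
  star <- toy_network(tibble::tibble(source_physician = c("A", "B"),
                                     target_physician = c("C", "C")))
  vm2 <- vertex_measures(star)
  expect_equal(vm2$authority, c(0, 0, 1), tolerance = 1e-10)
  expect_equal(vm2$hub, c(1, 1, 0), tolerance = 1e-10)

  # vertex isolated in the projection has subgraph centrality exp(0) = 1
  iso <- toy_network(tibble::tibble(source_physician = "A",
                                    target_physician = "B"),
                     extra_vertices = "Z")
  vm3 <- vertex_measures(iso)
  expect_equal(vm3$subgraph_centrality[vm3$physician_id == "Z"], 1)
  expect_true(is.na(vm3$diversity[vm3$physician_id == "Z"]))

  # star of mutual dyads: center lies on all 6 ordered leaf pairs
  hub <- toy_network(tibble::tibble(
    source_physician = c("X", "X", "X", "A", "B", "C"),
    target_physician = c("A", "B", "C", "X", "X", "X")
  ))
  vm4 <- vertex_measures(hub)
  expect_equal(vm4$betweenness[vm4$physician_id == "X"], 6)
  expect_equal(vm4$diversity[vm4$physician_id == "A"], 0)
})

test_that("PageRank and HITS satisfy their fixed points", {
  set.seed(99)
  A <- random_digraph(15, 0.25)
  while (any(rowSums(A) + colSums(A) == 0)) A <- random_digraph(15, 0.25)
  net <- toy_network(A * 1)
  g <- net$graph
  n <- igraph::gorder(g)
  vm <- vertex_measures(net)
  expect_equal(sum(vm$pagerank), 1, tolerance = 1e-12)

  # direct linear solve of the PageRank system (dangling mass spread uniformly)
  M <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  rs <- rowSums(M)
  P <- M / ifelse(rs == 0, 1, rs)
  P[rs == 0, ] <- 1 / n
  d <- 0.85
  pr <- solve(t(diag(n) - d * P), rep((1 - d) / n, n))
  pr <- pr / sum(pr)
  ids <- match(vm$physician_id, igraph::V(g)$name)
  expect_equal(vm$pagerank, unname(pr[ids]), tolerance = 1e-10)

  # HITS fixed point: a proportional to t(A) h, h proportional to A a
  a <- vm$authority
  h <- vm$hub
  Ao <- M[ids, ids]
  a2 <- as.vector(t(Ao) %*% h)
  h2 <- as.vector(Ao %*% a)
  expect_equal(a / max(a), a2 / max(a2), tolerance = 1e-8)
  expect_equal(h / max(h), h2 / max(h2), tolerance = 1e-8)
})

test_that("articulation points are exactly the component-increasing vertices", {
  pth <- toy_network(tibble::tibble(source_physician = c("A", "B"),
                                    target_physician = c("B", "C")))
  expect_equal(articulation_vertices(pth), "B")
  tri <- toy_network(tibble::tibble(source_physician = c("A", "B", "C"),
                                    target_physician = c("B", "C", "A")))
  expect_equal(articulation_vertices(tri), character(0))
  two_tri <- toy_network(tibble::tibble(
    source_physician = c("A", "B", "X", "X", "C", "D"),
    target_physician = c("B", "X", "A", "C", "D", "X")
  ))
  expect_equal(articulation_vertices(two_tri), "X")

  # exhaustive vertex-removal oracle on random graphs
  set.seed(777)
  for (rep in 1:20) {
    n <- sample(4:6, 1)
    A <- random_digraph(n, 0.3)
    if (sum(A) == 0) next
    net <- toy_network(A * 1)
    gu <- igraph::as_undirected(net$graph, mode = "collapse")
    base <- igraph::count_components(gu)
    listed <- articulation_vertices(net)
    for (v in igraph::V(gu)$name) {
      after <- igraph::count_components(igraph::delete_vertices(gu, v))
      expect_equal(v %in% listed, after > base)
    }
  }
})

test_that("Z-scoring uses the sample SD over the included subset only", {
  tab <- tibble::tibble(physician_id = c("A", "B", "C", "D"),
                        m1 = c(1, 2, 3, 100), m2 = c(5, 5, 5, 9))
  z <- suppressWarnings(zscore_metrics(tab, included = c("A", "B", "C")))
  expect_equal(z$m1, c(-1, 0, 1))
  expect_warning(zscore_metrics(tab[1:3, ]), "Constant")
  z2 <- suppressWarnings(zscore_metrics(tab[1:3, ]))
  expect_equal(z2$m2, c(0, 0, 0))

  sim <- default_sim()
  net <- build_referral_network(sim$visits, sim$physicians, sim$config)
  vm <- vertex_measures(net)
  vz <- suppressWarnings(zscore_metrics(vm))
  means <- colMeans(dplyr::select(vz, -"physician_id"), na.rm = TRUE)
  expect_true(all(abs(means) < 1e-9))
  sds <- apply(dplyr::select(vz, -"physician_id"), 2,
               function(x) sd(x, na.rm = TRUE))
  expect_true(all(abs(sds[sds > 0] - 1) < 1e-9))
  expect_error(zscore_metrics(vm, included = "nobody"), "no physicians")
})
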