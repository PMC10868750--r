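two_block_net <- function(p_in = 0.9, bridge = TRUE, n_block = 10, seed = 1) {
  set.seed(seed)
  ids <- sprintf("V%02d", 1:(2 * n_block))
  block <- rep(1:2, each = n_block)
  edges <- NULL
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i != j && block[i] == block[j] && stats::runif(1) < p_in) {
        edges <- rbind(edges, c(ids[i], ids[j]))
      }
    }
  }
  edges <- tibble::tibble(source_physician = edges[, 1],
                          target_physician = edges[, 2], Ew = 1,
                          referral_count = 1L)
  if (bridge) {
    edges <- dplyr::add_row(edges, source_physician = ids[1],
                            target_physician = ids[n_block + 1],
                            Ew = 0.05, referral_count = 1L)
  }
  list(net = toy_network(edges), block = block, ids = ids)
}

test_that("a single dense clique is one community", {
  k <- toy_network(tibble::tibble(
    source_physician = rep(LETTERS[1:5], each = 4),
    target_physician = unlist(lapply(LETTERS[1:5], function(x) setdiff(LETTERS[1:5], x)))
  ))
  part <- detect_communities(k, seed = 1)
  expect_equal(part$n_communities, 1)
  expect_equal(glance(part)$n_communities, 1)
})

test_that("two dense blocks joined by one weak edge are split at the blocks", {
  tb <- two_block_net()
  part <- detect_communities(tb$net, seed = 1)
  expect_equal(part$n_communities, 2)
  memb <- part$membership$community[match(tb$ids, part$membership$physician_id)]
  expect_equal(ari(memb, tb$block), 1)
})

test_that("detection is reproducible bit for bit given seed and trials", {
  tb <- two_block_net()
  p1 <- detect_communities(tb$net, seed = 9, trials = 10)
  p2 <- detect_communities(tb$net, seed = 9, trials = 10)
  expect_identical(p1$membership, p2$membership)
  expect_identical(p1$codelength, p2$codelength)
})

test_that("planted communities in synthetic claims are recovered at low leak", {
  sim <- simulate_claims(inter_community_leak = 0.02, seed = 404)
  net <- build_referral_network(sim$visits, sim$physicians, sim$config)
  part <- detect_communities(net, seed = 1)
  m <- dplyr::inner_join(part$membership, sim$truth$physicians,
                         by = "physician_id")
  expect_gte(ari(m$community.x, m$community.y), 0.9)
})

test_that("modularity matches its closed forms and the undirected cross-check", {
  tb <- two_block_net(p_in = 1, bridge = FALSE) # two equal complete cliques
  net <- tb$net
  all_one <- tibble::tibble(physician_id = tb$ids, community = 1L)
  expect_equal(partition_modularity(net, all_one), 0, tolerance = 1e-12)

  blocks <- tibble::tibble(physician_id = tb$ids, community = tb$block)
  # two disconnected equal-weight modules: Q = 1 - 2 * (1/2)^2 = 0.5
  expect_equal(partition_modularity(net, blocks), 0.5, tolerance = 1e-6)

  # random partitions of a random graph hover around zero (the exact mean is
  # O(1/n) below zero from the same-vertex strength terms)
  set.seed(12)
  A <- random_digraph(40, 0.3)
  rnet <- toy_network(A * 1)
  ids <- rnet$vertices$physician_id
  qs <- replicate(200, {
    partition_modularity(rnet, tibble::tibble(
      physician_id = ids, community = sample(1:3, length(ids), replace = TRUE)))
  })
  expect_lt(abs(mean(qs)), 0.05)

  # directed-unweighted agrees with igraph's undirected modularity on a
  # symmetric graph (every edge reciprocated)
  sym <- toy_network(tibble::tibble(
    source_physician = c("A", "B", "B", "C", "C", "D", "D", "A"),
    target_physician = c("B", "A", "C", "B", "D", "C", "A", "D")
  ))
  part2 <- tibble::tibble(physician_id = c("A", "B", "C", "D"),
                          community = c(1L, 1L, 2L, 2L))
  gu <- igraph::as_undirected(sym$graph, mode = "collapse")
  expect_equal(
    partition_modularity(sym, part2, weighted = FALSE),
    igraph::modularity(gu, part2$community),
    tolerance = 1e-12
  )
  expect_error(partition_modularity(net, all_one[-1, ]), "cover")
})

test_that("the detected partition describes the walk better than one module", {
  tb <- two_block_net()
  part <- detect_communities(tb$net, seed = 2)
  l_detected <- map_equation_codelength(tb$net, part$membership)
  l_one <- map_equation_codelength(
    tb$net, tibble::tibble(physician_id = tb$ids, community = 1L))
  expect_lte(l_detected, l_one)
})

test_that("detected modularity beats random same-size partitions", {
  tb <- two_block_net()
  part <- detect_communities(tb$net, seed = 3)
  q_det <- part$modularity
  memb <- part$membership
  set.seed(77)
  q_rand <- replicate(200, {
    shuffled <- memb
    shuffled$community <- sample(shuffled$community)
    partition_modularity(tb$net, shuffled)
  })
  expect_gte(mean(q_det > q_rand), 0.99)
})

test_that("community characterization flags planted specialty segregation", {
  # toy roster: community 1 is exactly all pediatricians
  ph <- tibble::tibble(
    physician_id = sprintf("D%02d", 1:40),
    specialty = rep(c("pediatrics", "cardiology"), each = 20),
    age = 50, municipality = rep(c("M1", "M2"), each = 20)
  )
  part <- structure(list(membership = tibble::tibble(
    physician_id = ph$physician_id,
    community = rep(c(1L, 2L), each = 20)
  ), n_communities = 2L, codelength = NA_real_, modularity = NA_real_),
  class = "community_partition")
  prof <- characterize_communities(part, ph)
  peds <- prof[prof$community == 1 & prof$variable == "specialty" &
                 prof$level == "pediatrics", ]
  expect_equal(peds$share, 1)
  expect_equal(peds$direction, "above")
  expect_true(peds$significant)

  # uniform mix: no significant marks
  ph2 <- ph
  ph2$specialty <- rep(c("pediatrics", "cardiology"), times = 20)
  prof2 <- characterize_communities(part, ph2)
  expect_false(any(prof2$significant[prof2$variable == "specialty"]))
})
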