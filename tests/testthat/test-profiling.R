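# construct columns with exact sample correlations via orthonormal bases
exact_cor_data <- function(R, n = 60) {
  p <- ncol(R)
  set.seed(10)
  Z <- matrix(stats::rnorm(n * p), n, p)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Q <- qr.Q(qr(Z))
  X <- Q %*% chol(R)
  as.data.frame(scale(X))
}

test_that("correlation pruning follows the greedy worst-pair rule", {
  perfect <- tibble::tibble(a = 1:20, b = 2 * (1:20) + 5, c = stats::rnorm(20))
  pr <- prune_correlated(perfect, c("a", "b", "c"), threshold = 0.8)
  expect_length(intersect(c("a", "b"), pr$retained), 1)
  expect_true("c" %in% pr$retained)

  low <- exact_cor_data(diag(3))
  names(low) <- c("a", "b", "c")
  pr2 <- prune_correlated(tibble::as_tibble(low), c("a", "b", "c"), 0.8)
  expect_setequal(pr2$retained, c("a", "b", "c"))

  # r(AB)=.95, r(AC)=.90, r(BC)=.10: worst pair AB, A has the larger mean |r|
  # (this correlation pattern is not jointly realizable as data, so the rule
  # is exercised on the matrix directly)
  R <- matrix(c(1, .95, .90,
                .95, 1, .10,
                .90, .10, 1), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  pr3 <- ambnet:::greedy_prune(R, c("A", "B", "C"), 0.8)
  expect_equal(pr3$dropped, "A")
  expect_setequal(pr3$retained, c("B", "C"))

  # the same trace from actual data with a realizable pattern
  R2 <- matrix(c(1, .95, .90,
                 .95, 1, .75,
                 .90, .75, 1), 3, 3)
  dat <- exact_cor_data(R2)
  names(dat) <- c("A", "B", "C")
  pr5 <- prune_correlated(tibble::as_tibble(dat), c("A", "B", "C"), 0.8)
  expect_equal(pr5$dropped, "A")
  expect_setequal(pr5$retained, c("B", "C"))

  all_col <- tibble::tibble(a = 1:10, b = 2 * (1:10), c = 3 * (1:10))
  expect_warning(pr4 <- prune_correlated(all_col, c("a", "b", "c"), 0.8),
                 "collinear")
  expect_length(pr4$retained, 1)
})

test_that("silhouette-based selection finds planted blob counts", {
  set.seed(5)
  two <- data.frame(x = c(stats::rnorm(40, 0, 0.2), stats::rnorm(40, 10, 0.2)))
  sel2 <- select_k(two, clustering_config(seed = 5, n_restarts = 10))
  expect_equal(sel2$k, 2)

  three <- data.frame(
    x = c(stats::rnorm(30, 0, .3), stats::rnorm(30, 8, .3), stats::rnorm(30, 0, .3)),
    y = c(stats::rnorm(30, 0, .3), stats::rnorm(30, 0, .3), stats::rnorm(30, 8, .3))
  )
  sel3 <- select_k(three, clustering_config(seed = 5, n_restarts = 10))
  expect_equal(sel3$k, 3)
  expect_named(sel3$diagnostics, c("k", "mean_silhouette", "wss"))

  same <- data.frame(x = rep(1, 30))
  expect_error(select_k(same, clustering_config()), "distinct rows")

  fixed <- select_k(three, clustering_config(
    k_selection = "fixed", fixed_k = c(centrality = 5), seed = 1,
    n_restarts = 5), dimension = "centrality")
  expect_equal(fixed$k, 5)
})

test_that("K-means clustering is deterministic and exact on point masses", {
  pts <- data.frame(x = rep(c(0, 10, 20), each = 10) + 0,
                    y = rep(c(5, -5, 0), each = 10))
  cl <- cluster_dimension(pts, 3, clustering_config(seed = 2))
  expect_equal(cl$wss, 0)
  expect_setequal(cl$centroids_raw$x, c(0, 10, 20))
  cl2 <- cluster_dimension(pts, 3, clustering_config(seed = 2))
  expect_identical(cl$cluster, cl2$cluster)

  # row-order invariance up to cluster relabeling
  set.seed(1)
  perm <- sample(nrow(pts))
  cl3 <- cluster_dimension(pts[perm, ], 3, clustering_config(seed = 2))
  expect_equal(ari(cl$cluster[perm], cl3$cluster), 1)
})

test_that("well-separated planted clusters are recovered almost perfectly", {
  set.seed(31)
  truth <- rep(1:5, each = 40)
  centers <- matrix(stats::rnorm(15, sd = 12), 5, 3) # >= 4 SD separation
  dat <- centers[truth, ] + matrix(stats::rnorm(200 * 3), 200, 3)
  cl <- cluster_dimension(as.data.frame(dat), 5,
                          clustering_config(seed = 3, n_restarts = 25))
  expect_gte(ari(truth, cl$cluster), 0.95)
})

test_that("default thresholds reproduce the published example labels", {
  tab <- example_centroid_table()
  for (dim in unique(tab$dimension)) {
    sub <- tab[tab$dimension == dim, ]
    expect_equal(label_clusters(sub, dim), sub$published_label,
                 info = dim)
  }
})

test_that("centrality label ties break toward the larger cluster", {
  cz <- tibble::tibble(
    cluster = 1:2, n = c(10L, 30L),
    pagerank = c(1, 1), subgraph_centrality = c(1, 1),
    betweenness = c(1, 1), closeness_in_w = c(1, 1),
    eccentricity = c(-1, -1), closeness_out_w = c(-1, -1)
  )
  expect_warning(lab <- label_clusters(cz, "centrality"), "Tie")
  expect_equal(lab[2], "intermediate")
  expect_error(label_clusters(cz[, 1:3], "centrality"), "lacks")
  expect_error(label_clusters(cz, "nonsense"), "Unknown dimension")
})

test_that("end-to-end profiling recovers the planted archetype separation", {
  rep <- default_report()
  tr <- rep$truth$physicians
  m <- dplyr::inner_join(tr, rep$profiles$assignments, by = "physician_id")
  sp <- m[m$archetype == "strong_prevalent", ]
  expect_gte(mean(sp$patient_follow_up_label == "strong_prevalent"), 0.9)
  # physicians excluded for low productivity carry no assignment
  low <- rep$net$vertices$physician_id[rep$net$vertices$low_productivity]
  expect_false(any(rep$profiles$assignments$physician_id %in% low))
  expect_true(all(!is.na(m$centrality_label)))
})
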