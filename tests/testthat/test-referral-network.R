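cfg <- study_config()

mk_visits <- function(...) {
  # mk_visits("p1", "A", 0, "p1", "B", 10, ...) with day offsets
  v <- matrix(c(...), ncol = 3, byrow = TRUE)
  tibble::tibble(
    patient_id = v[, 1],
    physician_id = v[, 2],
    visit_date = as.Date("2021-06-01") + as.integer(v[, 3]),
    satisfaction = NA_real_
  )
}

test_that("the referral window is inclusive and pairs all qualifying visits", {
  ev <- extract_referrals(mk_visits("p1", "A", 0, "p1", "B", 10), cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$source_physician, "A")
  expect_equal(ev$gap_days, 10L)

  outside <- extract_referrals(
    mk_visits("p1", "A", 0, "p1", "B", 6, "p2", "A", 0, "p2", "B", 46), cfg)
  expect_equal(nrow(outside), 0)

  bounds <- extract_referrals(
    mk_visits("p1", "A", 0, "p1", "B", 7, "p2", "A", 0, "p2", "B", 45), cfg)
  expect_equal(sort(bounds$gap_days), c(7L, 45L))

  # all-pairs rule: three visits give three ordered pairs
  chain <- extract_referrals(mk_visits("p1", "A", 0, "p1", "B", 10,
                                       "p1", "C", 20), cfg)
  expect_equal(
    dplyr::arrange(chain, .data$gap_days)[, c("source_physician",
                                              "target_physician", "gap_days")],
    tibble::tibble(source_physician = c("A", "B", "A"),
                   target_physician = c("B", "C", "C"),
                   gap_days = c(10L, 10L, 20L))
  )
  # consecutive-only variant keeps just the two adjacent pairs
  cons <- extract_referrals(mk_visits("p1", "A", 0, "p1", "B", 10,
                                      "p1", "C", 20),
                            study_config(consecutive_only = TRUE))
  expect_equal(nrow(cons), 2)
  # same-day visits to two physicians are gap 0, never a referral
  expect_equal(nrow(extract_referrals(mk_visits("p1", "A", 0, "p1", "B", 0),
                                      cfg)), 0)
})

test_that("unique_patients collapses event multiplicity per physician pair", {
  v <- mk_visits("p1", "A", 0, "p1", "B", 10, "p1", "A", 50, "p1", "B", 60)
  expect_equal(nrow(extract_referrals(v, cfg)), 3) # A->B, A->B, B->A
  uq <- extract_referrals(v, study_config(unique_patients = TRUE))
  expect_equal(nrow(uq), 2)
})

test_that("follow-up counting matches brute force over same-physician pairs", {
  expect_equal(count_follow_ups(mk_visits("p1", "A", 0, "p1", "A", 20),
                                cfg)$follow_ups, 1L)
  expect_equal(count_follow_ups(mk_visits("p1", "A", 0, "p1", "A", 3),
                                cfg)$follow_ups, 0L)
  # three visits: pairs 0-10, 10-20, 0-20 all in window
  expect_equal(count_follow_ups(mk_visits("p1", "A", 0, "p1", "A", 10,
                                          "p1", "A", 20), cfg)$follow_ups, 3L)
})

test_that("vertex weights are consultation shares and both forms agree", {
  v <- dplyr::bind_rows(
    mk_visits("p1", "A", 0)[rep(1, 50), ],
    mk_visits("p2", "B", 0)[rep(1, 950), ]
  )
  ph <- tibble::tibble(physician_id = c("A", "B"),
                       specialty = c("s1", "s2"))
  vw <- vertex_weights(v, ph)
  expect_equal(vw$Vw[vw$physician_id == "A"], 0.05)
  expect_equal(sum(vw$Vw), 1)

  solo <- vertex_weights(mk_visits("p1", "A", 0), ph[1, ])
  expect_equal(solo$Vw, 1)

  sim <- default_sim()
  ratio <- vertex_weights(sim$visits, sim$physicians, method = "ratio")
  prod <- vertex_weights(sim$visits, sim$physicians, method = "product")
  expect_equal(ratio$Vw, prod$Vw, tolerance = 1e-15)
  expect_equal(sum(ratio$Vw), 1, tolerance = 1e-12)

  expect_error(vertex_weights(mk_visits("p1", "A", 0)[0, ], ph), "undefined")
})

test_that("edge weights normalize referral counts by the source's patient base", {
  v <- dplyr::bind_rows(
    mk_visits("p1", "A", 0, "p1", "B", 10),
    tibble::tibble(patient_id = sprintf("q%02d", 1:99), physician_id = "A",
                   visit_date = as.Date("2021-06-01"), satisfaction = NA_real_)
  )
  ev <- extract_referrals(v, cfg)
  ew <- edge_weights(ev, v)
  expect_equal(ew$Ew, 1 / 100)

  v1 <- mk_visits("p1", "A", 0, "p1", "B", 10)
  expect_equal(edge_weights(extract_referrals(v1, cfg), v1)$Ew, 1)
})

test_that("low productivity is a strict-inequality threshold on specialty expectation", {
  # 10 physicians, 1000 consultations -> expected 100, threshold 20
  ph <- tibble::tibble(physician_id = sprintf("D%02d", 1:10), specialty = "s")
  counts <- c(19, 20, rep(120, 7), 121) # totals 1000
  v <- tibble::tibble(
    patient_id = "p1",
    physician_id = rep(ph$physician_id, times = counts),
    visit_date = as.Date("2021-06-01"), satisfaction = NA_real_
  )
  fl <- flag_low_productivity(v, ph, cfg)
  expect_equal(sum(v$physician_id %in% ph$physician_id), 1000)
  expect_equal(fl$specialty_expected, rep(100, 10))
  expect_true(fl$low_productivity[fl$consultations == 19])
  expect_false(fl$low_productivity[fl$consultations == 20][1])
  # equal volumes: threshold is 0.2 x own volume, nobody flagged
  v_eq <- tibble::tibble(patient_id = "p1",
                         physician_id = rep(ph$physician_id, each = 10),
                         visit_date = as.Date("2021-06-01"),
                         satisfaction = NA_real_)
  expect_false(any(flag_low_productivity(v_eq, ph, cfg)$low_productivity))
  # zero-visit roster physicians enter the specialty headcount
  ph2 <- dplyr::add_row(ph, physician_id = "D11", specialty = "s")
  fl2 <- flag_low_productivity(v, ph2, cfg)
  expect_equal(fl2$specialty_expected[1], 1000 / 11)
})

test_that("network construction excludes isolated physicians and keeps low producers", {
  fix <- small_worked_fixture()
  ph <- dplyr::add_row(fix$physicians, physician_id = "E",
                       specialty = "cardiology", age = 55, municipality = "M1")
  v <- dplyr::add_row(fix$visits, patient_id = "p9", physician_id = "E",
                      visit_date = as.Date("2021-06-01"), satisfaction = NA_real_)
  net <- build_referral_network(v, ph, cfg)
  expect_equal(nrow(net$vertices), 4)
  expect_equal(net$excluded$physician_id, "E")
  expect_equal(net$excluded$reason, "no referrals made or received")
  expect_error(
    build_referral_network(mk_visits("p1", "A", 0), fix$physicians[1, ], cfg),
    "No referral events"
  )
  g <- glance(net)
  expect_equal(g$n_vertices, 4)
  expect_equal(g$n_isolated_excluded, 1)
  expect_equal(tidy(net), net$edges)
})

test_that("the network is invariant to visit row order", {
  sim <- default_sim()
  net1 <- build_referral_network(sim$visits, sim$physicians, sim$config)
  set.seed(1)
  shuffled <- sim$visits[sample(nrow(sim$visits)), ]
  net2 <- build_referral_network(shuffled, sim$physicians, sim$config)
  expect_equal(net1$edges, net2$edges)
  expect_equal(net1$vertices, net2$vertices)
  expect_equal(net1$events, net2$events)
})

test_that("edge counts, events and weighted out-degree obey the accounting identities", {
  sim <- default_sim()
  net <- build_referral_network(sim$visits, sim$physicians, sim$config)
  expect_equal(sum(net$edges$referral_count), nrow(net$events))
  # weighted out-degree == referrals made / distinct patients, per physician
  sums <- net$edges |>
    dplyr::group_by(physician_id = .data$source_physician) |>
    dplyr::summarise(out_w = sum(.data$Ew), made = sum(.data$referral_count),
                     .groups = "drop") |>
    dplyr::left_join(net$vertices, by = "physician_id")
  expect_equal(sums$out_w, sums$made / sums$n_patients, tolerance = 1e-12)
  expect_equal(sums$made, sums$referrals_made)
  # vertex weights over the full roster sum to 1
  expect_equal(sum(vertex_weights(sim$visits, sim$physicians)$Vw), 1,
               tolerance = 1e-12)
})

test_that("widening the window never removes edges or referrals", {
  sim <- default_sim()
  narrow <- build_referral_network(sim$visits, sim$physicians, sim$config)
  wide_cfg <- study_config(referral_min_gap = 1, referral_max_gap = 60)
  wide <- build_referral_network(sim$visits, sim$physicians, wide_cfg)
  joined <- dplyr::left_join(
    narrow$edges, wide$edges,
    by = c("source_physician", "target_physician"), suffix = c("_n", "_w")
  )
  expect_false(any(is.na(joined$referral_count_w)))
  expect_true(all(joined$referral_count_w >= joined$referral_count_n))
})
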