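#' Specialty archetype for the synthetic claims generator
#'
#' An archetype describes how physicians of one specialty behave: how many
#' there are, how busy they are, how strongly their patients return to them,
#' how often they hand patients on, what share of them act as referral magnets
#' (authorities), how attractive they are as referral targets, and how
#' comorbid their typical patient is.
#'
#' @param specialty Specialty name (non-empty string).
#' @param n_physicians Number of physicians of this specialty.
#' @param mean_visits Relative consultation volume of one physician; index
#'   visits are allocated proportionally to this value.
#' @param follow_up_rate Probability that, after a visit, the patient returns
#'   to the same physician (chain continuation).
#' @param referral_out_rate Probability that, after a visit, the patient is
#'   handed on to a different physician.
#' @param authority_share Fraction of the specialty's physicians designated as
#'   referral magnets; they attract referrals with a multiplier (default x5 in
#'   [simulate_claims()]).
#' @param comorbidity_mean Mean chronic-condition count of the patients this
#'   specialty attracts.
#' @param referral_in_weight Baseline attractiveness as a referral target
#'   (before the authority multiplier). Below 1 models specialties whose
#'   patient base rarely arrives by referral (e.g. pediatrics, where children
#'   are followed longitudinally rather than referred in from adult care).
#'
#' @return A one-row tibble.
#' @export
specialty_archetype <- function(specialty, n_physicians, mean_visits,
                                follow_up_rate, referral_out_rate,
                                authority_share, comorbidity_mean,
                                referral_in_weight = 1) {
  if (!nzchar(specialty)) abort("`specialty` must be a non-empty string.")
  if (n_physicians < 0) abort("`n_physicians` must be non-negative.")
  if (mean_visits < 0 || referral_in_weight < 0 || comorbidity_mean < 0) {
    abort("Rates and volumes must be non-negative.")
  }
  probs <- c(follow_up_rate, referral_out_rate, authority_share)
  if (any(probs < 0) || any(probs > 1)) {
    abort("`follow_up_rate`, `referral_out_rate` and `authority_share` must lie in [0, 1].")
  }
  if (follow_up_rate + referral_out_rate > 1) {
    abort("`follow_up_rate` + `referral_out_rate` must not exceed 1.")
  }
  tibble::tibble(
    specialty = specialty,
    n_physicians = as.integer(n_physicians),
    mean_visits = mean_visits,
    follow_up_rate = follow_up_rate,
    referral_out_rate = referral_out_rate,
    authority_share = authority_share,
    comorbidity_mean = comorbidity_mean,
    referral_in_weight = referral_in_weight
  )
}

#' Default archetype mix
#'
#' A desk-scale mix of five specialties (~50 physicians) chosen to span the
#' behavioural space the profiling stage must resolve: longitudinal
#' low-sharing pediatricians, authority-rich internists and cardiologists,
#' hub-like family physicians who mostly hand patients on, and peripheral
#' surgeons who neither refer nor follow up much.
#'
#' @return A tibble of archetypes, one row per specialty.
#' @export
default_archetypes <- function() {
  dplyr::bind_rows(
    specialty_archetype("pediatrics", 10, 500, 0.80, 0.02, 0.00, 0.4,
                        referral_in_weight = 0.1),
    specialty_archetype("internal_medicine", 10, 400, 0.30, 0.35, 0.30, 3.0),
    specialty_archetype("cardiology", 10, 400, 0.35, 0.30, 0.30, 3.5,
                        referral_in_weight = 1.5),
    specialty_archetype("family_medicine", 10, 350, 0.10, 0.60, 0.00, 1.5,
                        referral_in_weight = 0.8),
    specialty_archetype("general_surgery", 10, 150, 0.10, 0.05, 0.05, 2.0,
                        referral_in_weight = 1.2)
  )
}

# gap draw: in-window uniform, with a noise fraction outside [min,max]
draw_gaps <- function(n, min_gap, max_gap, noise_frac) {
  noise <- runif(n) < noise_frac
  gaps <- sample(seq.int(min_gap, max_gap), n, replace = TRUE)
  if (any(noise)) {
    out_pool <- c(seq.int(1L, min_gap - 1L), seq.int(max_gap + 1L, 120L))
    gaps[noise] <- sample(out_pool, sum(noise), replace = TRUE)
  }
  gaps
}

#' Generate a synthetic claims dataset with planted structure
#'
#' Simulates visit-level claims with known ground truth so every downstream
#' stage (network construction, measures, profiling, community detection,
#' associations) can be tested for recovery. Physicians are partitioned into
#' territorial communities; each patient belongs to a home community and
#' produces care episodes: an index visit followed by a chain of follow-up
#' visits (same physician) and referral visits (another physician, within the
#' home community with probability `1 - inter_community_leak`, preferentially
#' landing on designated authorities). Gaps are drawn inside the referral
#' window except for a configurable noise fraction. Patient comorbidity counts
#' are negative-binomial with mean tied to the archetypes of the physicians
#' actually visited.
#'
#' @param archetypes Tibble of [specialty_archetype()] rows.
#' @param n_communities Number of territorial blocks.
#' @param inter_community_leak Probability that an index or referral visit
#'   leaves the patient's home community.
#' @param n_patients Number of patients.
#' @param seed Integer seed; identical seed and settings give identical output.
#' @param episodes_per_patient Mean number of care episodes per patient
#'   (Poisson).
#' @param noise_frac Fraction of follow-on gaps drawn outside the referral
#'   window (in 1-6 or 46-120 days), exercising the window filter.
#' @param authority_multiplier Referral-attraction multiplier for designated
#'   authorities.
#' @param max_chain Maximum visits per episode.
#' @param config A [study_config()]; provides the study window and the
#'   referral-gap window.
#' @param comorbidity_size Negative-binomial size (dispersion) parameter.
#'
#' @return A list of class `"synthetic_claims"` with elements `visits`,
#'   `physicians`, `patients` (the three claims tibbles), `truth` (list with
#'   per-physician `community`/`archetype` and per-patient `home_community`),
#'   and `events` (the generator's own log of follow-up and referral moves,
#'   with `gap_days`, `in_window` and `cross_community` flags).
#' @examples
#' sim <- simulate_claims(n_patients = 100, seed = 1)
#' nrow(sim$visits)
#' @export
simulate_claims <- function(archetypes = default_archetypes(),
                            n_communities = 4,
                            inter_community_leak = 0.05,
                            n_patients = 2000,
                            seed = 1,
                            episodes_per_patient = 5,
                            noise_frac = 0.1,
                            authority_multiplier = 5,
                            max_chain = 6,
                            config = study_config(seed = seed),
                            comorbidity_size = 2) {
  if (n_patients < 1) abort("`n_patients` must be at least 1.")
  if (n_communities < 1) abort("`n_communities` must be at least 1.")
  if (inter_community_leak < 0 || inter_community_leak > 1) {
    abort("`inter_community_leak` must lie in [0, 1].")
  }
  n_phys_total <- sum(archetypes$n_physicians)
  if (n_phys_total < 1) abort("Empty cohort: archetypes contain no physicians.")

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  # ---- roster: communities round-robin within specialty so each block mixes
  phys <- archetypes |>
    dplyr::rowwise() |>
    dplyr::mutate(ids = list(seq_len(.data$n_physicians))) |>
    dplyr::ungroup() |>
    tidyr::unnest("ids") |>
    dplyr::mutate(
      physician_id = sprintf("D%03d", dplyr::row_number()),
      community = ((.data$ids - 1L) %% n_communities) + 1L,
      age = round(runif(dplyr::n(), 30, 75))
    )
  # authority designation: top authority_share per specialty (deterministic)
  phys <- phys |>
    dplyr::group_by(.data$specialty) |>
    dplyr::mutate(is_authority = dplyr::row_number() <= round(.data$authority_share[1] *
                                                                dplyr::n())) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      attract = .data$referral_in_weight *
        ifelse(.data$is_authority, authority_multiplier, 1),
      municipality = paste0("M", .data$community)
    )

  physicians <- dplyr::select(phys, "physician_id", "specialty", "age",
                              "municipality")

  idx_weight <- phys$mean_visits
  ref_weight <- phys$attract
  comm <- phys$community
  fup_rate <- phys$follow_up_rate
  ref_rate <- phys$referral_out_rate
  como_mean <- phys$comorbidity_mean
  n_phys <- nrow(phys)

  span <- as.integer(config$study_end - config$study_start)
  index_span <- max(span - 160L, 1L)
  home <- sample.int(n_communities, n_patients, replace = TRUE)

  pick_physician <- function(home_comm, weights, exclude = integer(0)) {
    leak <- runif(1) < inter_community_leak
    pool <- if (leak) which(comm != home_comm) else which(comm == home_comm)
    pool <- setdiff(pool, exclude)
    if (length(pool) == 0) { # fall back to the other side (rare)
      pool <- setdiff(if (leak) which(comm == home_comm) else which(comm != home_comm),
                      exclude)
    }
    if (length(pool) == 0) return(NA_integer_)
    if (length(pool) == 1) return(pool)
    sample(pool, 1, prob = weights[pool])
  }

  # per-patient episode simulation; indices into phys rows.
  # preallocated buffers (grown geometrically) keep this linear in visit count
  cap_v <- as.integer(n_patients * episodes_per_patient * (max_chain + 2) + 64)
  visit_pat <- visit_doc <- visit_day <- integer(cap_v)
  ev_pat <- ev_src <- ev_tgt <- ev_gap <- integer(cap_v)
  ev_type <- character(cap_v)
  ev_cross <- logical(cap_v)
  nv <- 0L
  ne <- 0L
  grow <- function() { # double every buffer when capacity is hit
    pad_i <- integer(cap_v)
    visit_pat <<- c(visit_pat, pad_i); visit_doc <<- c(visit_doc, pad_i)
    visit_day <<- c(visit_day, pad_i)
    ev_pat <<- c(ev_pat, pad_i); ev_src <<- c(ev_src, pad_i)
    ev_tgt <<- c(ev_tgt, pad_i); ev_gap <<- c(ev_gap, pad_i)
    ev_type <<- c(ev_type, character(cap_v))
    ev_cross <<- c(ev_cross, logical(cap_v))
    cap_v <<- cap_v * 2L
  }
  push_visit <- function(i, p, d) {
    if (nv + 1L > cap_v) grow()
    nv <<- nv + 1L
    visit_pat[nv] <<- i; visit_doc[nv] <<- p; visit_day[nv] <<- d
  }
  push_event <- function(i, s, t, g, type, cross) {
    if (ne + 1L > cap_v) grow()
    ne <<- ne + 1L
    ev_pat[ne] <<- i; ev_src[ne] <<- s; ev_tgt[ne] <<- t; ev_gap[ne] <<- g
    ev_type[ne] <<- type; ev_cross[ne] <<- cross
  }

  n_ep <- rpois(n_patients, episodes_per_patient)
  for (i in seq_len(n_patients)) {
    if (n_ep[i] == 0) next
    # each patient keeps a usual (primary) physician; loyalty across episodes
    # follows that physician's follow-up propensity, so patients of strongly
    # longitudinal physicians return to them rather than re-enter at random
    primary <- pick_physician(home[i], idx_weight)
    if (is.na(primary)) next
    # episodes are scheduled sequentially with inter-episode gaps beyond the
    # referral window, so visit pairs across unrelated episodes never fall
    # inside it; the realized episode count is capped by the study span
    cursor <- sample.int(min(90L, index_span), 1) - 1L
    for (ep in seq_len(n_ep[i])) {
      d <- cursor
      if (d > index_span) break
      p <- if (runif(1) < fup_rate[primary]) {
        primary
      } else {
        pick_physician(home[i], idx_weight)
      }
      if (is.na(p)) next
      seen <- p
      push_visit(i, p, d)
      steps <- 1L
      while (steps < max_chain) {
        u <- runif(1)
        if (u < fup_rate[p]) {
          gap <- draw_gaps(1, config$referral_min_gap, config$referral_max_gap,
                           noise_frac)
          d2 <- d + gap
          if (d2 > span) break
          push_visit(i, p, d2)
          push_event(i, p, p, gap, "follow_up", FALSE)
          d <- d2
        } else if (u < fup_rate[p] + ref_rate[p]) {
          q <- pick_physician(home[i], ref_weight, exclude = seen)
          if (is.na(q)) break
          gap <- draw_gaps(1, config$referral_min_gap, config$referral_max_gap,
                           noise_frac)
          d2 <- d + gap
          if (d2 > span) break
          push_visit(i, q, d2)
          push_event(i, p, q, gap, "referral", comm[q] != home[i])
          p <- q; seen <- c(seen, q); d <- d2
        } else break
        steps <- steps + 1L
      }
      cursor <- d + config$referral_max_gap + 1L + sample.int(90L, 1)
    }
  }
  if (nv == 0L) abort("Simulation produced no visits; increase scale.")
  visit_pat <- visit_pat[seq_len(nv)]
  visit_doc <- visit_doc[seq_len(nv)]
  visit_day <- visit_day[seq_len(nv)]
  ev_pat <- ev_pat[seq_len(ne)]
  ev_src <- ev_src[seq_len(ne)]
  ev_tgt <- ev_tgt[seq_len(ne)]
  ev_gap <- ev_gap[seq_len(ne)]
  ev_type <- ev_type[seq_len(ne)]
  ev_cross <- ev_cross[seq_len(ne)]

  visits <- tibble::tibble(
    patient_id = sprintf("P%05d", visit_pat),
    physician_id = phys$physician_id[visit_doc],
    visit_date = config$study_start + visit_day,
    satisfaction = round(pmin(10, pmax(0, stats::rnorm(length(visit_pat), 9.6, 0.8))), 1)
  )

  # comorbidity: NB with mean tied to archetypes of the physicians visited
  pat_mean <- tapply(como_mean[visit_doc], visit_pat, mean)
  mu <- rep(mean(como_mean), n_patients)
  mu[as.integer(names(pat_mean))] <- pat_mean
  patients <- tibble::tibble(
    patient_id = sprintf("P%05d", seq_len(n_patients)),
    comorbidity_count = rnbinom(n_patients, size = comorbidity_size, mu = mu),
    home_community = home
  )

  truth_phys <- tibble::tibble(
    physician_id = phys$physician_id,
    specialty = phys$specialty,
    community = phys$community,
    archetype = dplyr::case_when(
      phys$is_authority ~ "authority",
      phys$follow_up_rate >= 0.6 & phys$referral_out_rate <= 0.2 ~ "strong_prevalent",
      phys$referral_out_rate >= 0.5 ~ "hub",
      TRUE ~ "weak_shared"
    )
  )

  events <- tibble::tibble(
    patient_id = sprintf("P%05d", ev_pat),
    type = ev_type,
    source_physician = phys$physician_id[ev_src],
    target_physician = phys$physician_id[ev_tgt],
    gap_days = ev_gap,
    in_window = ev_gap >= config$referral_min_gap & ev_gap <= config$referral_max_gap,
    cross_community = ev_cross
  )

  structure(
    list(
      visits = visits,
      physicians = physicians,
      patients = dplyr::select(patients, "patient_id", "comorbidity_count"),
      truth = list(
        physicians = truth_phys,
        patients = dplyr::select(patients, "patient_id", "home_community")
      ),
      events = events,
      config = config
    ),
    class = "synthetic_claims"
  )
}

#' @export
print.synthetic_claims <- function(x, ...) {
  cat("<synthetic_claims>\n")
  cat("  physicians:", nrow(x$physicians), " patients:", nrow(x$patients),
      " visits:", nrow(x$visits), "\n")
  cat("  planted communities:", length(unique(x$truth$physicians$community)), "\n")
  invisible(x)
}

#' Write the planted ground truth to JSON
#'
#' @param sim A `"synthetic_claims"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_planted_truth <- function(sim, path) {
  stopifnot(inherits(sim, "synthetic_claims"))
  jsonlite::write_json(sim$truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Hand-worked miniature claims dataset
#'
#' Ten visits by three patients to four physicians, small enough that every
#' referral event, edge weight and vertex weight can be enumerated by hand.
#' Used as a cross-module golden test: the expected tables returned here were
#' derived manually from the referral-window definition, not computed by the
#' package.
#'
#' Day offsets from the study start: p1 visits A(0), B(10), A(30); p2 visits
#' A(0), C(6), C(51); p3 visits D(0), B(45), C(45), D(100). With the inclusive
#' 7-45 day window this induces referral events A->B (gap 10), B->A (20),
#' D->B (45), D->C (45); follow-ups A (30) and C (45); the gap-6 and gap-51
#' pairs fall outside the window.
#'
#' @return A list with `visits`, `physicians`, `patients`,
#'   `expected_events`, `expected_edges` (with hand-computed `Ew`),
#'   `expected_vertex_weights` and `expected_follow_ups`.
#' @export
small_worked_fixture <- function() {
  start <- as.Date("2021-04-01")
  day <- function(d) start + d
  visits <- tibble::tibble(
    patient_id  = c("p1", "p1", "p1", "p2", "p2", "p2", "p3", "p3", "p3", "p3"),
    physician_id = c("A", "B", "A", "A", "C", "C", "D", "B", "C", "D"),
    visit_date  = day(c(0, 10, 30, 0, 6, 51, 0, 45, 45, 100)),
    satisfaction = NA_real_
  )
  physicians <- tibble::tibble(
    physician_id = c("A", "B", "C", "D"),
    specialty = c("cardiology", "cardiology", "pediatrics", "pediatrics"),
    age = c(50, 42, 38, 61),
    municipality = c("M1", "M1", "M2", "M2")
  )
  patients <- tibble::tibble(
    patient_id = c("p1", "p2", "p3"),
    comorbidity_count = c(2L, 0L, 1L)
  )
  expected_events <- tibble::tibble(
    patient_id = c("p1", "p1", "p3", "p3"),
    source_physician = c("A", "B", "D", "D"),
    target_physician = c("B", "A", "B", "C"),
    gap_days = c(10L, 20L, 45L, 45L)
  )
  expected_edges <- tibble::tibble(
    source_physician = c("A", "B", "D", "D"),
    target_physician = c("B", "A", "B", "C"),
    referral_count = c(1L, 1L, 1L, 1L),
    # distinct patients: A {p1,p2}=2, B {p1,p3}=2, D {p3}=1
    Ew = c(1 / 2, 1 / 2, 1 / 1, 1 / 1)
  )
  expected_vertex_weights <- tibble::tibble(
    physician_id = c("A", "B", "C", "D"),
    consultations = c(3L, 2L, 3L, 2L),
    Vw = c(0.3, 0.2, 0.3, 0.2)
  )
  expected_follow_ups <- tibble::tibble(
    physician_id = c("A", "B", "C", "D"),
    follow_ups = c(1L, 0L, 1L, 0L)
  )
  list(
    visits = visits,
    physicians = physicians,
    patients = patients,
    expected_events = expected_events,
    expected_edges = expected_edges,
    expected_vertex_weights = expected_vertex_weights,
    expected_follow_ups = expected_follow_ups
  )
}
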