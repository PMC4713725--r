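make_match <- function(a, b, day_a = 1, day_b = 8) {
  match_sessions(a, b, dendrite_id = "d", day_a = day_a, day_b = day_b)
}

test_that("turnover fractions divide by the prior session count", {
  m <- make_match(seq(1, 19, 2), c(seq(1, 17, 2), 24, 27)) # 10 -> 1 elim, 2 formed
  expect_equal(length(m$eliminated), 1)
  expect_equal(length(m$formed), 2)
  expect_equal(turnover_fractions(m),
               c(elimination = 0.10, formation = 0.20))
  ident <- make_match(c(1, 2), c(1, 2))
  expect_equal(turnover_fractions(ident), c(elimination = 0, formation = 0))
  empty <- make_match(numeric(0), c(1))
  expect_warning(tf <- turnover_fractions(empty), "undefined")
  expect_true(all(is.na(tf)))
})

test_that("normalization pins the first interval at exactly 100", {
  expect_identical(normalize_to_baseline(c(0.08, 0.06, 0.04)), c(100, 75, 50))
  expect_identical(normalize_to_baseline(c(0.2, 0.2, 0.2)), c(100, 100, 100))
  expect_warning(out <- normalize_to_baseline(c(0, 0.1)), "undefined")
  expect_true(all(is.na(out)))
})

test_that("per-dendrite normalization differs from mouse-level unless baselines agree", {
  # two dendrites of one mouse: elimination series (0.2, 0.1) and (0.1, 0.1)
  d1 <- c(0.2, 0.1); d2 <- c(0.1, 0.1)
  per_dendrite <- (normalize_to_baseline(d1) + normalize_to_baseline(d2)) / 2
  mouse_level <- normalize_to_baseline((d1 + d2) / 2)
  expect_equal(per_dendrite, c(100, 75))
  expect_equal(mouse_level, c(100, 200 / 3), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(per_dendrite[2], mouse_level[2])))
  # with equal baselines the two orders coincide
  d3 <- c(0.2, 0.05)
  expect_equal((normalize_to_baseline(d1) + normalize_to_baseline(d3)) / 2,
               normalize_to_baseline((d1 + d3) / 2))
})

test_that("preexisting survival counts continuous presence from session 1", {
  lin <- tibble::tibble(first_session = c(rep(1L, 10), 3L),
                        last_session = c(rep(7L, 8), 2L, 2L, 5L))
  s <- preexisting_survival(lin, 7)
  expect_equal(s[1], 1)
  expect_equal(s[3], 0.8)  # 2 of 10 first-session spines gone before session 3
  expect_true(all(diff(s) <= 0))
  empty <- tibble::tibble(first_session = 2L, last_session = 3L)
  expect_warning(out <- preexisting_survival(empty, 7), "undefined")
  expect_true(all(is.na(out)))
})

test_that("gained survival follows the index-interval cohort", {
  lin <- tibble::tibble(first_session = c(1L, rep(3L, 5)),
                        last_session = c(7L, 7L, 7L, 7L, 4L, 3L))
  g <- gained_survival(lin, index_session = 3, n_sessions = 7)
  expect_true(all(is.na(g[1:2])))
  expect_equal(g[3], 1)
  expect_equal(g[7], 0.6)  # 3 of the 5 gained spines reach the last session
  expect_true(all(diff(g[3:7]) <= 0))
  expect_warning(gained_survival(lin[1, ], 3, 7), "undefined")
})

test_that("transient fraction counts single-session newcomers", {
  lin <- tibble::tibble(first_session = c(1L, 2L, 3L, 4L, 5L),
                        last_session = c(7L, 7L, 3L, 6L, 7L))
  expect_equal(transient_fraction(lin, 7), 0.25) # 1 of 4 births is transient
  persistent <- tibble::tibble(first_session = c(2L, 3L), last_session = c(4L, 7L))
  expect_equal(transient_fraction(persistent, 7), 0)
  expect_warning(transient_fraction(lin[1, ], 7), "undefined")
})

test_that("mouse aggregation is an unweighted mean that skips undefined dendrites", {
  series <- tibble::tibble(
    dendrite_id = c("d1", "d2", "d3", "d1", "d2", "d3"),
    mouse_id = "m1", group = "g",
    metric = rep(c("elimination_fraction", "transient_fraction"), each = 3),
    session_day = c(8, 8, 8, NA, NA, NA),
    value = c(0.1, 0.3, NA, NA, NA, NA))
  agg <- aggregate_per_mouse(series)
  expect_equal(agg$value[agg$metric == "elimination_fraction"], 0.2)
  expect_equal(agg$n_dendrites[agg$metric == "elimination_fraction"], 2)
  # all dendrites undefined -> mouse excluded for that metric
  expect_false("transient_fraction" %in% agg$metric)
})

test_that("two-stage aggregation equals the hand-computed two-stage mean", {
  # 2 mice x 2 dendrites with elimination 0.1/0.3 and 0.2/0.4:
  # mouse means 0.2, 0.3; group mean of mouse means = 0.25
  series <- tibble::tibble(
    dendrite_id = paste0("d", 1:4),
    mouse_id = rep(c("m1", "m2"), each = 2), group = "g",
    metric = "elimination_fraction", session_day = 8,
    value = c(0.1, 0.3, 0.2, 0.4))
  agg <- aggregate_per_mouse(series)
  expect_equal(sort(agg$value), c(0.2, 0.3))
  expect_equal(mean(agg$value), 0.25)
})

test_that("simulated turnover recovers the generative elimination probability", {
  # no formation: every interval's elimination fraction estimates p_elim
  p <- sim_params(n_mice = 5, dendrites_per_mouse = 60,
                  p_elim_per_week = 0.2, p_elim_new_per_week = 0.2,
                  formation_rate_per_um_per_week = 0, lateral_fraction = 1,
                  seed = 300)
  cohort <- simulate_cohort(list(g = p))
  tracking <- track_cohort(cohort$annotations, cohort$session_days)
  first <- tracking$matches[tracking$matches$day_a == 1 & tracking$matches$n_a > 0, ]
  est <- first$n_eliminated / first$n_a
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.2), 3 * se)
})

test_that("tracked survival and transience match closed-form hazard products", {
  p <- sim_params(n_mice = 5, dendrites_per_mouse = 60,
                  p_elim_per_week = 0.1, p_elim_new_per_week = 0.5,
                  formation_rate_per_um_per_week = 0.05, lateral_fraction = 1,
                  seed = 301)
  cohort <- simulate_cohort(list(g = p))
  tracking <- track_cohort(cohort$annotations, cohort$session_days)
  series <- compute_metrics(tracking, cohort$dendrites)
  S <- length(cohort$session_days)
  expected <- expected_preexisting_survival(p)
  surv <- series[series$metric == "preexisting_survival" & !is.na(series$value), ]
  for (t in 2:S) {
    at_t <- surv$value[surv$session_day == cohort$session_days[t]]
    se <- sd(at_t) / sqrt(length(at_t))
    expect_lt(abs(mean(at_t) - expected[t]), 3 * se)
  }
  tf <- series$value[series$metric == "transient_fraction"]
  tf <- tf[!is.na(tf)]
  se <- sd(tf) / sqrt(length(tf))
  expect_lt(abs(mean(tf) - 0.5), 3 * se)
})

test_that("end-to-end parameter recovery on a preset-sized cohort", {
  # 5 mice x 10 dendrites: the study-sized design recovers its own
  # generative elimination, gained survival and transience within 3 SE
  p <- sim_params(seed = 888, lateral_fraction = 1)
  cohort <- simulate_cohort(list(g = p))
  tracking <- track_cohort(cohort$annotations, cohort$session_days)
  series <- compute_metrics(tracking, cohort$dendrites)

  first_elim <- tracking$matches[tracking$matches$day_a == 1 &
                                   tracking$matches$n_a > 0, ]
  est <- first_elim$n_eliminated / first_elim$n_a
  expect_lt(abs(mean(est) - p$p_elim_per_week),
            3 * sd(est) / sqrt(length(est)))

  gs <- series$value[series$metric == "gained_survival" &
                       series$session_day == 43 & !is.na(series$value)]
  expect_lt(abs(mean(gs) - expected_gained_survival_final(p, 3)),
            3 * sd(gs) / sqrt(length(gs)))

  tf <- series$value[series$metric == "transient_fraction"]
  tf <- tf[!is.na(tf)]
  expect_lt(abs(mean(tf) - p$p_elim_new_per_week),
            3 * sd(tf) / sqrt(length(tf)))
})

test_that("bookkeeping identity holds on every tracked dendrite", {
  cohort <- make_test_cohort(seed = 17)
  tracking <- track_cohort(cohort$annotations, cohort$session_days)
  m <- tracking$matches
  expect_identical(m$n_b, m$n_a - m$n_eliminated + m$n_formed)
})

test_that("normalization after aggregation replaces the per-dendrite default", {
  cohort <- make_test_cohort(seed = 23)
  tracking <- track_cohort(cohort$annotations, cohort$session_days)
  mouse <- aggregate_per_mouse(compute_metrics(tracking, cohort$dendrites))
  renorm <- normalize_after_aggregation(mouse)
  ne <- renorm[renorm$metric == "normalized_elimination", ]
  firsts <- ne$value[ne$session_day == min(ne$session_day)]
  expect_true(all(firsts == 100))
})
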