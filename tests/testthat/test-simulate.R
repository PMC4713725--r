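test_that("parameter validation rejects malformed designs", {
  expect_error(sim_params(session_days = c(1, 8, 8)), "strictly increasing")
  expect_error(sim_params(p_elim_per_week = 1.2), "\\[0, 1\\]")
  expect_error(sim_params(dendrite_length_um = c(35, 25)), "interval")
  expect_error(sim_params(formation_rate_per_um_per_week = -1), ">= 0")
})

test_that("EE schedule declines the mature elimination probability, clamped at 0", {
  p <- sim_params(p_elim_per_week = 0.06, ee_start_day = 8,
                  ee_elim_decline_per_week = 0.02,
                  ee_new_spine_stabilization = 0.1)
  probs <- function(day) spinedyn:::interval_elim_probs(p, day)
  expect_equal(probs(1)[["mature"]], 0.06)     # pre-EE interval
  expect_equal(probs(1)[["new"]], 0.30)
  expect_equal(probs(8)[["mature"]], 0.04)
  expect_equal(probs(15)[["mature"]], 0.02)
  expect_equal(probs(22)[["mature"]], 0)
  expect_equal(probs(36)[["mature"]], 0)       # floored, never negative
  expect_equal(probs(8)[["new"]], 0.1)
})

test_that("frozen dynamics: no formation, no elimination keeps every track full-span", {
  p <- sim_params(formation_rate_per_um_per_week = 0, p_elim_per_week = 0,
                  p_elim_new_per_week = 0, seed = 11)
  d <- simulate_dendrite(p, "d1")
  expect_true(all(d$tracks$birth_session == 1L))
  expect_true(all(is.na(d$tracks$death_session)))
  counts <- table(d$annotations$session)
  expect_true(length(unique(as.integer(counts))) <= 1)
  expect_equal(length(counts), length(p$session_days))
})

test_that("forced extinction: p_elim 1 and no formation empties session 2 onward", {
  p <- sim_params(formation_rate_per_um_per_week = 0, p_elim_per_week = 1,
                  p_elim_new_per_week = 1, seed = 12)
  d <- simulate_dendrite(p, "d1")
  expect_true(all(d$annotations$session == 1L))
  expect_true(all(d$tracks$death_session == 1L))
})

test_that("initial spine count is Poisson with mean density x length", {
  p <- sim_params(dendrite_length_um = c(30, 30), baseline_density_per_um = 0.4,
                  session_days = c(1, 8), formation_rate_per_um_per_week = 0,
                  p_elim_per_week = 0, p_elim_new_per_week = 0,
                  lateral_fraction = 1, seed = NA)
  set.seed(2024)
  counts <- replicate(10000, nrow(simulate_dendrite(p, "d", use_seed = FALSE)$tracks))
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 12), 3 * se)
})

test_that("track invariants hold: spans, bounds, jitter within 3 sigma", {
  cohort <- make_test_cohort(seed = 77)
  trk <- cohort$tracks
  pos <- cohort$positions
  S <- length(cohort$session_days)
  dead <- trk[!is.na(trk$death_session), ]
  expect_true(all(dead$birth_session <= dead$death_session))
  # positions exist exactly for the alive span
  spans <- tapply(pos$session, pos$spine_id, function(s) c(min(s), max(s), length(s)))
  for (id in trk$spine_id) {
    sp <- spans[[id]]
    last <- ifelse(is.na(trk$death_session[trk$spine_id == id]), S,
                   trk$death_session[trk$spine_id == id])
    expect_equal(sp[1], trk$birth_session[trk$spine_id == id])
    expect_equal(sp[2], last)
    expect_equal(sp[3], sp[2] - sp[1] + 1)
  }
  lens <- cohort$dendrites$dendrite_length_um[
    match(pos$dendrite_id, cohort$dendrites$dendrite_id)]
  expect_true(all(pos$position_um >= 0 & pos$position_um <= lens))
  expect_true(all(lens >= 25 & lens <= 35))
  # consecutive observations of one spine within 3 * jitter SD
  sigma <- cohort$params_by_group[[1]]$position_jitter_um
  jumps <- pos |>
    dplyr::arrange(spine_id, session) |>
    dplyr::group_by(spine_id) |>
    dplyr::summarise(j = max(abs(diff(position_um)), 0), .groups = "drop")
  expect_true(all(jumps$j <= 3 * sigma + 1e-12))
})

test_that("annotated positions respect the minimum separation", {
  cohort <- make_test_cohort(seed = 5)
  sep <- cohort$params_by_group[[1]]$min_separation_um
  gaps <- cohort$annotations |>
    dplyr::group_by(dendrite_id, session) |>
    dplyr::summarise(gap = if (dplyr::n() > 1) min(diff(sort(position_um))) else Inf,
                     .groups = "drop")
  expect_true(all(gaps$gap >= sep - 1e-12))
})

test_that("count conservation holds exactly on the ground-truth log", {
  cohort <- make_test_cohort(seed = 9)
  S <- length(cohort$session_days)
  for (dd in unique(cohort$tracks$dendrite_id)) {
    trk <- cohort$tracks[cohort$tracks$dendrite_id == dd, ]
    alive <- function(t) sum(trk$birth_session <= t &
                               (is.na(trk$death_session) | trk$death_session >= t))
    for (t in seq_len(S - 1)) {
      births <- sum(trk$birth_session == t + 1)
      deaths <- sum(!is.na(trk$death_session) & trk$death_session == t)
      expect_identical(alive(t + 1), alive(t) - deaths + births)
    }
  }
})

test_that("identical seeds give bit-identical cohorts; duplicate labels error", {
  p <- sim_params(n_mice = 2, dendrites_per_mouse = 3, seed = 123)
  c1 <- simulate_cohort(list(a = p))
  c2 <- simulate_cohort(list(a = p))
  expect_identical(c1$annotations, c2$annotations)
  expect_identical(c1$tracks, c2$tracks)
  expect_error(simulate_cohort(stats::setNames(list(p, p), c("a", "a"))),
               "uniquely named")
})

test_that("lateral thinning: annotated count matches lateral_fraction x true count", {
  p <- sim_params(n_mice = 5, dendrites_per_mouse = 20, lateral_fraction = 0.6,
                  seed = 31)
  cohort <- simulate_cohort(list(g = p))
  n_true <- nrow(cohort$tracks)
  n_ann <- sum(cohort$tracks$is_lateral)
  se <- sqrt(n_true * 0.6 * 0.4)
  expect_lt(abs(n_ann - 0.6 * n_true), 3 * se)
})

test_that("balanced birth and death rates give a flat mean density", {
  # stationarity: formation rate x length = p_elim x expected count, all
  # spines under the same hazard
  p <- sim_params(n_mice = 10, dendrites_per_mouse = 100,
                  dendrite_length_um = c(30, 30),
                  baseline_density_per_um = 0.4,
                  p_elim_per_week = 0.1, p_elim_new_per_week = 0.1,
                  formation_rate_per_um_per_week = 0.04,
                  lateral_fraction = 1, seed = 210)
  cohort <- simulate_cohort(list(g = p))
  dens <- cohort$annotations |>
    dplyr::count(dendrite_id, session_day) |>
    dplyr::mutate(density = n / 30)
  fit <- summary(stats::lm(density ~ session_day, data = dens))
  expect_gt(fit$coefficients["session_day", "Pr(>|t|)"], 0.01)
})

test_that("declining EE hazard yields non-increasing weekly elimination counts", {
  p <- sim_params(n_mice = 10, dendrites_per_mouse = 100, ee_start_day = 8,
                  ee_elim_decline_per_week = 0.01,
                  ee_new_spine_stabilization = 0.15, seed = 400)
  cohort <- simulate_cohort(list(g = p))
  deaths <- cohort$tracks[!is.na(cohort$tracks$death_session), ]
  weekly <- table(factor(deaths$death_session, levels = 1:6))
  # expectation is non-increasing; allow 2 SE of Poisson noise per week
  for (k in 2:6) {
    slack <- 2 * sqrt(weekly[k - 1] + 1)
    expect_lt(weekly[k], weekly[k - 1] + slack)
  }
  expect_lt(weekly[6], weekly[1]) # overall decline is substantial
})

test_that("low new-spine stabilization lowers first-EE-week cohort survival", {
  presets <- cohort_presets(seed = 55, groups = c("control-EE", "deltaE9-EE"))
  for (g in names(presets)) {
    presets[[g]]$n_mice <- 10
    presets[[g]]$dendrites_per_mouse <- 100
  }
  cohort <- simulate_cohort(presets)
  S <- length(cohort$session_days)
  surv <- function(g) {
    trk <- cohort$tracks[cohort$tracks$group == g & cohort$tracks$birth_session == 3, ]
    mean(is.na(trk$death_session))
  }
  expect_gt(surv("control-EE"), surv("deltaE9-EE"))
  # and both near their closed-form hazard products
  expect_lt(abs(surv("control-EE") -
                  expected_gained_survival_final(presets[["control-EE"]], 3)), 0.05)
  expect_lt(abs(surv("deltaE9-EE") -
                  expected_gained_survival_final(presets[["deltaE9-EE"]], 3)), 0.05)
})
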