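# Birth-death simulator for spines along a dendrite.
#
# Spines live at fixed "base" positions along the dendrite; each imaging
# session observes the base position plus truncated Gaussian jitter. Base
# positions are kept at least min_separation_um + 3 * position_jitter_um
# apart, so annotated positions within a session are always separated by
# at least min_separation_um, and an observation of one spine can never fall
# within the matching tolerance of a different spine (the jitter moves each
# observation by at most 1.5 * position_jitter_um).

# Truncated normal: N(0, sd) conditioned on |x| <= 1.5 sd, by resampling.
rtnorm_trunc <- function(n, sd) {
  if (sd == 0 || n == 0) return(numeric(n))
  x <- rnorm(n, 0, sd)
  bad <- abs(x) > 1.5 * sd
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), 0, sd)
    bad <- abs(x) > 1.5 * sd
  }
  x
}

# Draw up to n base positions on [0, L], each >= sep from `existing` and
# from each other. Rejection sampling, at most `max_tries` draws per spine;
# spines that cannot be placed are dropped (count returned).
place_positions <- function(n, length_um, sep, existing = numeric(),
                            max_tries = 100L) {
  placed <- numeric(0)
  skipped <- 0L
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      x <- runif(1, 0, length_um)
      if (all(abs(x - c(existing, placed)) >= sep)) {
        placed <- c(placed, x)
        ok <- TRUE
        break
      }
    }
    if (!ok) skipped <- skipped + 1L
  }
  list(positions = placed, skipped = skipped)
}

#' Simulate spine dynamics on one dendrite
#'
#' Runs the weekly birth--death process for a single dendrite and returns
#' both the ground truth (spine tracks with birth/death sessions and
#' per-session positions) and the observable (per-session annotations of the
#' laterally protruding spines only, with positional jitter).
#'
#' The initial spine count is Poisson with mean
#' `baseline_density_per_um * length`; initial spines count as mature. In
#' each inter-session interval every spine is eliminated independently --
#' with the new-spine probability if it formed in the previous interval,
#' with the (possibly EE-adjusted) mature probability otherwise -- and new
#' spines form as a Poisson count with mean
#' `formation_rate_per_um_per_week * length`, placed uniformly subject to
#' the minimum-separation rule (also against spines present in the previous
#' session, so a newborn is never confusable with a spine that just
#' disappeared).
#'
#' @param params a [sim_params()] object. If `params$seed` is not `NA` the
#'   RNG is seeded before simulating; inside [simulate_cohort()] the seed is
#'   applied once per group instead.
#' @param dendrite_id,mouse_id,group_label identifier tokens carried into
#'   the output tables.
#' @param use_seed seed the RNG from `params$seed` (default `TRUE` when a
#'   seed is set).
#'
#' @return A list with class `spine_dendrite`:
#' \describe{
#'   \item{tracks}{tibble, one row per spine: `spine_id`, `dendrite_id`,
#'     `birth_session`, `death_session` (`NA` if alive at the end),
#'     `is_lateral`, `base_position_um`.}
#'   \item{positions}{tibble of ground-truth per-session positions for every
#'     spine (lateral or not) while alive.}
#'   \item{annotations}{tibble of observed annotations (lateral spines
#'     only): `group`, `mouse_id`, `dendrite_id`, `session`, `session_day`,
#'     `position_um`, `lateral`, `dendrite_length_um`.}
#'   \item{length_um}{sampled dendrite length.}
#'   \item{n_skipped}{spines dropped because no position satisfying the
#'     separation rule was found within the attempt budget.}
#' }
#' @seealso [simulate_cohort()]
#' @export
#' @examples
#' d <- simulate_dendrite(sim_params(seed = 7), "d1")
#' head(d$annotations)
simulate_dendrite <- function(params, dendrite_id, mouse_id = "m1",
                              group_label = "group",
                              use_seed = !is.na(params$seed)) {
  params <- validate_sim_params(params)
  if (use_seed && !is.na(params$seed)) set.seed(params$seed)

  days <- params$session_days
  n_sessions <- length(days)
  L <- runif(1, params$dendrite_length_um[1], params$dendrite_length_um[2])
  sigma <- params$position_jitter_um
  sep_base <- params$min_separation_um + 3 * sigma

  n_skipped <- 0L
  init <- place_positions(rpois(1, params$baseline_density_per_um * L), L, sep_base)
  n_skipped <- n_skipped + init$skipped

  # per-spine state vectors
  base_pos <- init$positions
  birth <- rep(1L, length(base_pos))
  death <- rep(NA_integer_, length(base_pos))

  for (k in seq_len(n_sessions - 1)) {
    probs <- interval_elim_probs(params, days[k])
    alive <- which(is.na(death))
    if (length(alive)) {
      p_die <- ifelse(birth[alive] == k & birth[alive] > 1L, probs[["new"]],
                      probs[["mature"]])
      # initial spines (birth session 1) are mature even in the first interval
      dies <- runif(length(alive)) < p_die
      death[alive[dies]] <- k
    }
    survivors <- which(is.na(death))
    nb <- rpois(1, params$formation_rate_per_um_per_week * L)
    if (nb > 0) {
      # separation against every spine present at session k or k+1
      present <- unique(c(base_pos[survivors], base_pos[which(death == k)]))
      born <- place_positions(nb, L, sep_base, existing = present)
      n_skipped <- n_skipped + born$skipped
      if (length(born$positions)) {
        base_pos <- c(base_pos, born$positions)
        birth <- c(birth, rep(k + 1L, length(born$positions)))
        death <- c(death, rep(NA_integer_, length(born$positions)))
      }
    }
  }

  n_spines <- length(base_pos)
  if (n_spines == 0) {
    tracks <- tibble::tibble(
      spine_id = character(), dendrite_id = character(),
      birth_session = integer(), death_session = integer(),
      is_lateral = logical(), base_position_um = numeric())
    positions <- tibble::tibble(
      spine_id = character(), dendrite_id = character(), session = integer(),
      session_day = numeric(), position_um = numeric())
  } else {
    is_lat <- runif(n_spines) < params$lateral_fraction
    spine_id <- sprintf("%s_s%03d", dendrite_id, seq_len(n_spines))
    tracks <- tibble::tibble(
      spine_id = spine_id, dendrite_id = dendrite_id,
      birth_session = birth, death_session = death,
      is_lateral = is_lat, base_position_um = base_pos)
    last <- ifelse(is.na(death), n_sessions, death)
    rows <- rep.int(seq_len(n_spines), last - birth + 1L)
    sess <- unlist(lapply(seq_len(n_spines),
                          function(i) seq.int(birth[i], last[i])))
    obs <- pmin(pmax(base_pos[rows] + rtnorm_trunc(length(rows), sigma), 0), L)
    positions <- tibble::tibble(
      spine_id = spine_id[rows], dendrite_id = dendrite_id,
      session = as.integer(sess), session_day = days[sess],
      position_um = obs)
  }

  lat_ids <- tracks$spine_id[tracks$is_lateral]
  ann <- positions[positions$spine_id %in% lat_ids,
                   c("dendrite_id", "session", "session_day", "position_um")]
  annotations <- tibble::tibble(
    group = group_label, mouse_id = mouse_id,
    dendrite_id = ann$dendrite_id, session = ann$session,
    session_day = ann$session_day, position_um = ann$position_um,
    lateral = TRUE, dendrite_length_um = L)

  structure(
    list(tracks = tracks, positions = positions, annotations = annotations,
         length_um = L, n_skipped = n_skipped,
         session_days = days),
    class = "spine_dendrite")
}

#' Simulate a multi-group cohort
#'
#' Generates all mice and dendrites for each experimental group and collects
#' annotations, ground-truth tracks and the birth/death event log into one
#' bundle. Each group's RNG stream is seeded once from its own
#' `params$seed`, so two groups with identical parameters (including the
#' seed) yield identical data, and repeated calls are bit-identical.
#'
#' @param params_by_group named list of [sim_params()]; names are the group
#'   labels and must be unique.
#' @return An object of class `spine_cohort`: a list with tibbles
#'   `annotations`, `tracks` (with `mouse_id`, `group` columns), `positions`,
#'   `events` (ground-truth log: one `birth` row per spine and one `death`
#'   row for spines that disappeared during the experiment, with session
#'   index and day), `dendrites` (per-dendrite length), and the input
#'   `params_by_group`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_presets(seed = 3, groups = c("control-SC")))
#' dplyr::count(cohort$annotations, session_day)
simulate_cohort <- function(params_by_group) {
  stopifnot(is.list(params_by_group), length(params_by_group) >= 1)
  labels <- names(params_by_group)
  if (is.null(labels) || any(labels == "") || anyDuplicated(labels)) {
    stop("params_by_group must be a uniquely named list of sim_params",
         call. = FALSE)
  }
  ann <- list(); trk <- list(); pos <- list(); dend <- list()
  for (g in labels) {
    p <- validate_sim_params(params_by_group[[g]])
    if (!is.na(p$seed)) set.seed(p$seed)
    for (m in seq_len(p$n_mice)) {
      mouse_id <- sprintf("%s_m%02d", g, m)
      pm <- p
      if (p$frailty_sd > 0) {
        # mouse-level multiplicative frailty on rates, clamped to [0, 1]
        f <- exp(rnorm(1, 0, p$frailty_sd))
        pm$p_elim_per_week <- min(1, p$p_elim_per_week * f)
        pm$p_elim_new_per_week <- min(1, p$p_elim_new_per_week * f)
        pm$formation_rate_per_um_per_week <- p$formation_rate_per_um_per_week * f
      }
      for (d in seq_len(p$dendrites_per_mouse)) {
        dendrite_id <- sprintf("%s_d%02d", mouse_id, d)
        sim <- simulate_dendrite(pm, dendrite_id, mouse_id = mouse_id,
                                 group_label = g, use_seed = FALSE)
        ann[[dendrite_id]] <- sim$annotations
        if (nrow(sim$tracks)) {
          trk[[dendrite_id]] <- dplyr::mutate(sim$tracks, mouse_id = mouse_id,
                                              group = g)
        }
        pos[[dendrite_id]] <- sim$positions
        dend[[dendrite_id]] <- tibble::tibble(
          group = g, mouse_id = mouse_id, dendrite_id = dendrite_id,
          dendrite_length_um = sim$length_um, n_skipped = sim$n_skipped)
      }
    }
  }
  tracks <- dplyr::bind_rows(trk)
  days <- params_by_group[[1]]$session_days
  events <- cohort_event_log(tracks, days)
  structure(
    list(annotations = dplyr::bind_rows(ann), tracks = tracks,
         positions = dplyr::bind_rows(pos), events = events,
         dendrites = dplyr::bind_rows(dend),
         session_days = days, params_by_group = params_by_group),
    class = "spine_cohort")
}

# Ground-truth event log: one birth row per spine, one death row per spine
# that disappeared before the last session. `death_session = k` means last
# seen at session k, i.e. absent from session k + 1 onward; the death event
# is logged at the first session of absence.
cohort_event_log <- function(tracks, session_days) {
  if (is.null(tracks) || nrow(tracks) == 0) {
    return(tibble::tibble(spine_id = character(), dendrite_id = character(),
                          event = character(), session = integer(),
                          session_day = numeric()))
  }
  births <- tibble::tibble(
    spine_id = tracks$spine_id, dendrite_id = tracks$dendrite_id,
    event = "birth", session = tracks$birth_session,
    session_day = session_days[tracks$birth_session])
  dead <- tracks[!is.na(tracks$death_session), ]
  deaths <- tibble::tibble(
    spine_id = dead$spine_id, dendrite_id = dead$dendrite_id,
    event = "death", session = dead$death_session + 1L,
    session_day = session_days[dead$death_session + 1L])
  dplyr::arrange(dplyr::bind_rows(births, deaths), .data$dendrite_id,
                 .data$session, .data$event, .data$spine_id)
}

#' @export
print.spine_cohort <- function(x, ...) {
  cat("<spine_cohort>\n")
  cat(sprintf("  groups: %s\n", paste(names(x$params_by_group), collapse = ", ")))
  cat(sprintf("  %d dendrites, %d ground-truth spines, %d annotation rows\n",
              nrow(x$dendrites), nrow(x$tracks), nrow(x$annotations)))
  cat(sprintf("  sessions on days: %s\n", paste(x$session_days, collapse = ", ")))
  invisible(x)
}
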