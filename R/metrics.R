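# Turnover and survival metrics.
#
# All metrics are computed per dendrite first and aggregated to the mouse by
# an unweighted mean; group statistics then operate on mouse values (N = the
# number of mice). Undefined values (zero denominators) propagate as NA and
# are excluded from aggregation rather than imputed as zero.

#' Per-interval turnover fractions
#'
#' Fraction of spines eliminated and formed between two consecutive
#' sessions, relative to the spine count of the earlier session.
#'
#' @param match a [match_sessions()] result.
#' @param prior_count spine count of the earlier session; defaults to the
#'   count observed in `match`.
#' @return named numeric `c(elimination = ..., formation = ...)`; both `NA`
#'   (with a warning) when `prior_count` is 0.
#' @export
#' @examples
#' m <- match_sessions(c(1, 3, 5), c(1, 3, 7), dendrite_id = "d",
#'                     day_a = 1, day_b = 8)
#' turnover_fractions(m)
turnover_fractions <- function(match, prior_count = match$n_a) {
  stopifnot(inherits(match, "match_result"))
  if (prior_count == 0) {
    warning("turnover undefined: no spines in the earlier session", call. = FALSE)
    return(c(elimination = NA_real_, formation = NA_real_))
  }
  c(elimination = length(match$eliminated) / prior_count,
    formation = length(match$formed) / prior_count)
}

#' Normalize an interval series to its first value (= 100)
#'
#' Expresses per-interval turnover relative to the baseline interval (the
#' one between the first and second imaging sessions): each value is scaled
#' by `100 / x[1]`, so the first interval equals 100 exactly.
#'
#' @param x numeric per-interval series.
#' @return numeric series of the same length; all `NA` (with a warning) when
#'   the baseline value is missing or not positive.
#' @export
#' @examples
#' normalize_to_baseline(c(0.08, 0.06, 0.04))
normalize_to_baseline <- function(x) {
  if (length(x) == 0) return(x)
  if (is.na(x[1]) || x[1] <= 0) {
    warning("normalization undefined: first-interval value is zero or missing",
            call. = FALSE)
    return(rep(NA_real_, length(x)))
  }
  # ratio first: x[1] / x[1] is exactly 1, so the baseline is exactly 100
  100 * (x / x[1])
}

#' Survival of spines present at the first session
#'
#' For each session, the fraction of first-session spines that have remained
#' continuously present up to that session.
#'
#' @param lineages a [build_lineages()] table for one unit (dendrite or the
#'   pooled lineages of one mouse).
#' @param n_sessions number of imaging sessions.
#' @return numeric vector over sessions, starting at 1 and non-increasing;
#'   all `NA` (with a warning) when no spine was present at the first
#'   session.
#' @export
preexisting_survival <- function(lineages, n_sessions) {
  pre <- lineages[lineages$first_session == 1L, ]
  if (nrow(pre) == 0) {
    warning("preexisting survival undefined: no spines at the first session",
            call. = FALSE)
    return(rep(NA_real_, n_sessions))
  }
  vapply(seq_len(n_sessions),
         function(t) mean(pre$last_session >= t), numeric(1))
}

#' Survival of spines gained in an index interval
#'
#' Tracks the fate of spines first observed at `index_session` (i.e. formed
#' during the interval ending there -- typically the first week of enriched
#' housing, or the matching week under standard housing): for each session
#' from `index_session` onward, the fraction still present.
#'
#' @param lineages a [build_lineages()] table for one unit.
#' @param index_session session index at which the gained spines are first
#'   observed.
#' @param n_sessions number of imaging sessions.
#' @return numeric vector over sessions (values before `index_session` are
#'   `NA`); all `NA` with a warning when no spine was gained in the index
#'   interval.
#' @export
gained_survival <- function(lineages, index_session, n_sessions) {
  stopifnot(index_session >= 2, index_session <= n_sessions)
  born <- lineages[lineages$first_session == index_session, ]
  out <- rep(NA_real_, n_sessions)
  if (nrow(born) == 0) {
    warning("gained survival undefined: no spines formed in the index interval",
            call. = FALSE)
    return(out)
  }
  for (t in index_session:n_sessions) {
    out[t] <- mean(born$last_session >= t)
  }
  out
}

#' Fraction of transient spines among those newly formed
#'
#' A transient spine is a newly formed spine that does not survive more than
#' one week, i.e. is observed at exactly one session. The denominator is
#' restricted to spines formed at sessions where one more session follows
#' (a spine formed at the final session cannot be classified and is
#' excluded).
#'
#' @param lineages a [build_lineages()] table for one unit.
#' @param n_sessions number of imaging sessions.
#' @param window_sessions sessions whose newly formed spines are considered;
#'   default all assessable ones (`2:(n_sessions - 1)`).
#' @return scalar fraction in `[0, 1]`, or `NA` with a warning when no spine
#'   formed inside the window.
#' @export
transient_fraction <- function(lineages, n_sessions,
                               window_sessions = seq(2L, n_sessions - 1L)) {
  stopifnot(all(window_sessions >= 2), all(window_sessions < n_sessions))
  born <- lineages[lineages$first_session %in% window_sessions, ]
  if (nrow(born) == 0) {
    warning("transient fraction undefined: no spines formed in the window",
            call. = FALSE)
    return(NA_real_)
  }
  mean(born$last_session == born$first_session)
}

#' All panel metrics for every dendrite
#'
#' Computes, per dendrite, the complete set of quantities plotted in
#' longitudinal spine studies: density per um of dendrite, relative density
#' (% of the baseline-session mean), raw and normalized elimination and
#' formation fractions, preexisting-spine survival, gained-spine survival
#' from an index interval, and the transient fraction.
#'
#' @param tracking a [track_cohort()] result.
#' @param dendrites per-dendrite table with `dendrite_id` and
#'   `dendrite_length_um` (e.g. `cohort$dendrites`, or derived from an
#'   annotation table carrying that column).
#' @param baseline_sessions sessions averaged into the density baseline
#'   (default the two pre-manipulation sessions, 1 and 2; use `1` for a
#'   single-session baseline).
#' @param index_session session at which gained spines are first observed
#'   (default 3: formed during the interval between sessions 2 and 3, the
#'   first week after a manipulation starting at session 2).
#' @return long-format tibble: `dendrite_id`, `mouse_id`, `group`, `metric`,
#'   `session_day` (`NA` for the scalar transient fraction), `value`.
#'   Metrics: `density_per_um`, `relative_density`, `elimination_fraction`,
#'   `formation_fraction`, `normalized_elimination`, `normalized_formation`
#'   (interval metrics are reported at the day the interval ends),
#'   `preexisting_survival`, `gained_survival`, `transient_fraction`.
#' @export
compute_metrics <- function(tracking, dendrites,
                            baseline_sessions = c(1L, 2L),
                            index_session = 3L) {
  stopifnot(inherits(tracking, "spine_tracking"))
  days <- tracking$session_days
  S <- length(days)
  stopifnot(all(baseline_sessions %in% seq_len(S)), index_session <= S)
  rows <- list()
  emit <- function(dendrite_id, mouse_id, group, metric, session_day, value) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      dendrite_id = dendrite_id, mouse_id = mouse_id, group = group,
      metric = metric, session_day = session_day, value = value)
  }
  mt <- tracking$matches
  for (dd in unique(mt$dendrite_id)) {
    m_d <- mt[mt$dendrite_id == dd, ]
    m_d <- m_d[order(m_d$day_a), ]
    lin <- tracking$lineages[tracking$lineages$dendrite_id == dd, ]
    mouse <- if ("mouse_id" %in% names(m_d)) m_d$mouse_id[1] else NA_character_
    group <- if ("group" %in% names(m_d)) m_d$group[1] else NA_character_
    len <- dendrites$dendrite_length_um[match(dd, dendrites$dendrite_id)]

    counts <- c(m_d$n_a, m_d$n_b[nrow(m_d)])
    density <- counts / len
    emit(dd, mouse, group, "density_per_um", days, density)
    base <- mean(density[baseline_sessions])
    rel <- if (base > 0) 100 * density / base else rep(NA_real_, S)
    emit(dd, mouse, group, "relative_density", days, rel)

    elim <- ifelse(m_d$n_a > 0, m_d$n_eliminated / m_d$n_a, NA_real_)
    form <- ifelse(m_d$n_a > 0, m_d$n_formed / m_d$n_a, NA_real_)
    emit(dd, mouse, group, "elimination_fraction", days[-1], elim)
    emit(dd, mouse, group, "formation_fraction", days[-1], form)
    norm_or_na <- function(x) {
      if (length(x) == 0 || is.na(x[1]) || x[1] <= 0) rep(NA_real_, length(x))
      else 100 * (x / x[1])
    }
    emit(dd, mouse, group, "normalized_elimination", days[-1], norm_or_na(elim))
    emit(dd, mouse, group, "normalized_formation", days[-1], norm_or_na(form))

    pre <- lin[lin$first_session == 1L, ]
    surv <- if (nrow(pre)) {
      vapply(seq_len(S), function(t) mean(pre$last_session >= t), numeric(1))
    } else rep(NA_real_, S)
    emit(dd, mouse, group, "preexisting_survival", days, surv)

    born <- lin[lin$first_session == index_session, ]
    gs <- rep(NA_real_, S)
    if (nrow(born)) {
      for (t in index_session:S) gs[t] <- mean(born$last_session >= t)
    }
    emit(dd, mouse, group, "gained_survival", days, gs)

    newly <- lin[lin$first_session >= 2L & lin$first_session < S, ]
    tf <- if (nrow(newly)) mean(newly$last_session == newly$first_session) else NA_real_
    emit(dd, mouse, group, "transient_fraction", NA_real_, tf)
  }
  dplyr::bind_rows(rows)
}

#' Normalize turnover after per-mouse aggregation
#'
#' Alternative to the default per-dendrite normalization: recomputes
#' `normalized_elimination` and `normalized_formation` from the
#' mouse-aggregated raw fractions, scaling each mouse's series by
#' `100 / first-interval value`. With few spines per dendrite the
#' per-dendrite ratios are noisy (and dendrites with a zero first-interval
#' fraction drop out); normalizing the mouse means avoids both effects.
#'
#' @param mouse_series output of [aggregate_per_mouse()].
#' @return `mouse_series` with the two normalized metrics replaced.
#' @export
normalize_after_aggregation <- function(mouse_series) {
  out <- mouse_series[!(mouse_series$metric %in%
                          c("normalized_elimination", "normalized_formation")), ]
  for (met in c("elimination_fraction", "formation_fraction")) {
    raw <- mouse_series[mouse_series$metric == met, ]
    norm <- raw |>
      dplyr::group_by(.data$mouse_id, .data$group) |>
      dplyr::arrange(.data$session_day, .by_group = TRUE) |>
      dplyr::mutate(value = if (.data$value[1] > 0) {
        100 * (.data$value / .data$value[1])
      } else NA_real_) |>
      dplyr::ungroup()
    norm$metric <- sub("_fraction", "", paste0("normalized_", met))
    norm <- norm[!is.na(norm$value), ]
    out <- dplyr::bind_rows(out, norm)
  }
  out
}

#' Aggregate dendrite metrics to the mouse
#'
#' Unweighted mean across a mouse's dendrites, per metric and session.
#' Undefined dendrite values are skipped; a mouse is excluded for a metric
#' and session when all of its dendrites are undefined there.
#'
#' @param dendrite_series long-format output of [compute_metrics()].
#' @return long-format tibble: `mouse_id`, `group`, `metric`, `session_day`,
#'   `value`, `n_dendrites` (number of dendrites contributing).
#' @export
aggregate_per_mouse <- function(dendrite_series) {
  out <- dendrite_series |>
    dplyr::group_by(.data$mouse_id, .data$group, .data$metric,
                    .data$session_day) |>
    dplyr::summarise(
      n_dendrites = sum(!is.na(.data$value)),
      value = if (any(!is.na(.data$value))) {
        mean(.data$value, na.rm = TRUE)
      } else NA_real_,
      .groups = "drop")
  out <- out[!is.na(out$value), ]
  out[, c("mouse_id", "group", "metric", "session_day", "value", "n_dendrites")]
}
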