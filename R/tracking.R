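# Spine identity across sessions: the same-spine rule.
#
# Two observations in consecutive sessions are candidates for the same spine
# if their positions along the dendrite differ by at most the tolerance
# (default 0.5 um). Among all maximum-cardinality matchings under that
# constraint we return the one with minimal total absolute displacement;
# for points on a line with |.| cost an optimal non-crossing matching always
# exists, so a dynamic program over the two sorted position lists finds it
# in O(n * m). Ties are broken deterministically in favour of pairing the
# smaller position in session a, then the smaller position in session b.

# Core matcher on two sorted numeric vectors. Returns 2-column index matrix
# (i into a, j into b) of the optimal matching, in increasing order.
match_sorted <- function(a, b, tol) {
  n <- length(a); m <- length(b)
  if (n == 0 || m == 0) return(matrix(integer(0), ncol = 2))
  # card[i, j], cost[i, j]: best over suffixes a[i..n], b[j..m]
  card <- matrix(0L, n + 1, m + 1)
  cost <- matrix(0, n + 1, m + 1)
  for (i in n:1) {
    for (j in m:1) {
      bc <- card[i + 1, j]; bk <- cost[i + 1, j]        # skip a[i]
      if (card[i, j + 1] > bc ||
          (card[i, j + 1] == bc && cost[i, j + 1] < bk)) {
        bc <- card[i, j + 1]; bk <- cost[i, j + 1]      # skip b[j]
      }
      d <- abs(a[i] - b[j])
      if (d <= tol) {
        mc <- card[i + 1, j + 1] + 1L
        mk <- cost[i + 1, j + 1] + d
        if (mc > bc || (mc == bc && mk < bk)) { bc <- mc; bk <- mk }
      }
      card[i, j] <- bc; cost[i, j] <- bk
    }
  }
  # Reconstruct from the front, preferring a match whenever it attains the
  # optimum (yields the smallest-position_a / smallest-position_b tie-break).
  pairs <- matrix(integer(0), ncol = 2)
  i <- 1L; j <- 1L
  while (i <= n && j <= m) {
    d <- abs(a[i] - b[j])
    if (d <= tol &&
        card[i, j] == card[i + 1, j + 1] + 1L &&
        abs(cost[i, j] - (cost[i + 1, j + 1] + d)) < 1e-12) {
      pairs <- rbind(pairs, c(i, j))
      i <- i + 1L; j <- j + 1L
    } else if (card[i, j] == card[i + 1, j] &&
               abs(cost[i, j] - cost[i + 1, j]) < 1e-12 &&
               (a[i] <= b[j] ||
                !(card[i, j] == card[i, j + 1] &&
                  abs(cost[i, j] - cost[i, j + 1]) < 1e-12))) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  pairs
}

#' Match spine annotations of two consecutive sessions
#'
#' Applies the same-spine rule between two sessions of one dendrite: spines
#' whose positions differ by at most `tolerance_um` may be the same spine;
#' the returned correspondence is the maximum-cardinality matching of
#' minimal total displacement. Positions of session `a` left unmatched are
#' classified as eliminated, unmatched positions of session `b` as formed.
#'
#' @param a,b annotations of the same dendrite at two sessions: data frames
#'   with columns `dendrite_id`, `session_day` and `position_um` (one row
#'   per spine; non-lateral spines are expected to have been filtered out
#'   at load time), or bare numeric position vectors.
#' @param tolerance_um matching tolerance along the dendrite (um).
#' @param dendrite_id,day_a,day_b identifiers, required only when `a`/`b`
#'   are bare numeric vectors.
#' @return An object of class `match_result`: list with `dendrite_id`,
#'   `day_a`, `day_b`, `n_a`, `n_b`, `stable` (tibble with `position_a`,
#'   `position_b`), `eliminated` and `formed` (numeric positions). The
#'   partition invariants (every input position appears exactly once across
#'   stable + eliminated resp. stable + formed; every stable pair within
#'   tolerance) are asserted before returning.
#' @export
#' @examples
#' m <- match_sessions(c(1.0, 5.0), c(1.3, 5.0, 9.0),
#'                     dendrite_id = "d1", day_a = 1, day_b = 8)
#' m$stable
#' m$formed
match_sessions <- function(a, b, tolerance_um = 0.5,
                           dendrite_id = NULL, day_a = NULL, day_b = NULL) {
  take <- function(x, day) {
    if (is.numeric(x) && is.null(dim(x))) {
      list(pos = as.numeric(x), dendrite = dendrite_id, day = day)
    } else {
      stopifnot(all(c("dendrite_id", "session_day", "position_um") %in% names(x)))
      dd <- unique(x$dendrite_id); day0 <- unique(x$session_day)
      if (length(dd) > 1 || length(day0) > 1) {
        stop("annotation table must contain a single dendrite and session",
             call. = FALSE)
      }
      list(pos = as.numeric(x$position_um),
           dendrite = if (length(dd)) dd else dendrite_id,
           day = if (length(day0)) day0 else day)
    }
  }
  A <- take(a, day_a); B <- take(b, day_b)
  if (!is.null(A$dendrite) && !is.null(B$dendrite) &&
      !identical(A$dendrite, B$dendrite)) {
    stop("cannot match sessions from different dendrites: ",
         A$dendrite, " vs ", B$dendrite, call. = FALSE)
  }
  stopifnot(tolerance_um >= 0)

  oa <- order(A$pos); ob <- order(B$pos)
  sa <- A$pos[oa]; sb <- B$pos[ob]
  pairs <- match_sorted(sa, sb, tolerance_um)

  stable <- tibble::tibble(position_a = sa[pairs[, 1]],
                           position_b = sb[pairs[, 2]])
  eliminated <- if (nrow(pairs)) sa[-pairs[, 1]] else sa
  formed <- if (nrow(pairs)) sb[-pairs[, 2]] else sb

  res <- structure(
    list(dendrite_id = A$dendrite %||% B$dendrite,
         day_a = A$day, day_b = B$day,
         n_a = length(sa), n_b = length(sb),
         stable = stable, eliminated = as.numeric(eliminated),
         formed = as.numeric(formed), tolerance_um = tolerance_um),
    class = "match_result")
  assert_match_partition(res, sa, sb)
  res
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Partition + tolerance invariants; internal consistency check on every
# match_result.
assert_match_partition <- function(m, sa, sb) {
  ok <- identical(sort(c(m$stable$position_a, m$eliminated)), sort(sa)) &&
    identical(sort(c(m$stable$position_b, m$formed)), sort(sb)) &&
    all(abs(m$stable$position_a - m$stable$position_b) <= m$tolerance_um + 1e-12)
  if (!ok) stop("internal error: matching violates the partition invariant",
                call. = FALSE)
  invisible(m)
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %s: day %s -> %s\n",
              x$dendrite_id %||% "?", format(x$day_a), format(x$day_b)))
  cat(sprintf("  %d -> %d spines: %d stable, %d eliminated, %d formed (tol %g um)\n",
              x$n_a, x$n_b, nrow(x$stable), length(x$eliminated),
              length(x$formed), x$tolerance_um))
  invisible(x)
}

#' Chain matches into spine lineages
#'
#' Builds spine identities over the whole imaging period by chaining the
#' stable pairs of consecutive-session matches. A lineage is a maximal chain
#' of stable pairs: it starts when a spine is first observed, and ends as
#' soon as the spine is absent from a session -- a later spine at the same
#' position starts a new lineage (no gap bridging, consistent with the
#' definition of formed/eliminated relative to the previous session).
#'
#' @param matches list of [match_sessions()] results for consecutive session
#'   pairs of one dendrite, in session order (match `k` must end at the day
#'   match `k + 1` starts).
#' @return tibble with one row per lineage: `lineage_id`, `dendrite_id`,
#'   `first_session`, `last_session` (1-based indices into the session
#'   sequence), `n_sessions` and a `positions_um` list-column with the
#'   observed position at each session of the lineage.
#' @export
build_lineages <- function(matches) {
  stopifnot(length(matches) >= 1,
            all(vapply(matches, inherits, logical(1), "match_result")))
  dendrite <- matches[[1]]$dendrite_id
  for (k in seq_along(matches)) {
    if (!identical(matches[[k]]$dendrite_id, dendrite)) {
      stop("matches mix dendrites", call. = FALSE)
    }
    if (k > 1 && !isTRUE(all.equal(matches[[k - 1]]$day_b, matches[[k]]$day_a))) {
      stop("matches must cover consecutive session pairs in order; pair ", k,
           " starts at day ", matches[[k]]$day_a, " but pair ", k - 1,
           " ended at day ", matches[[k - 1]]$day_b, call. = FALSE)
    }
  }
  n_sessions <- length(matches) + 1L

  open_pos <- numeric(0)   # current position of each open lineage
  open_first <- integer(0)
  open_hist <- list()
  closed <- list()
  close_lineage <- function(first, hist, last) {
    closed[[length(closed) + 1L]] <<- list(first = first, last = last,
                                           positions = hist)
  }

  # session 1: every position opens a lineage
  m1 <- matches[[1]]
  start1 <- sort(c(m1$stable$position_a, m1$eliminated))
  open_pos <- start1
  open_first <- rep(1L, length(start1))
  open_hist <- as.list(start1)

  for (k in seq_along(matches)) {
    m <- matches[[k]]
    # map stable position_a -> position_b (positions are unique per session)
    idx <- match(round(open_pos, 9), round(m$stable$position_a, 9))
    survives <- !is.na(idx)
    for (w in which(!survives)) {
      close_lineage(open_first[w], open_hist[[w]], k)
    }
    new_pos <- m$stable$position_b[idx[survives]]
    open_hist <- lapply(seq_along(which(survives)), function(z) {
      c(open_hist[which(survives)][[z]], new_pos[z])
    })
    open_first <- open_first[survives]
    open_pos <- new_pos
    # formed spines open new lineages at session k + 1
    f <- sort(m$formed)
    if (length(f)) {
      open_pos <- c(open_pos, f)
      open_first <- c(open_first, rep(k + 1L, length(f)))
      open_hist <- c(open_hist, as.list(f))
    }
  }
  for (w in seq_along(open_pos)) {
    close_lineage(open_first[w], open_hist[[w]], n_sessions)
  }

  if (!length(closed)) {
    return(tibble::tibble(lineage_id = character(), dendrite_id = character(),
                          first_session = integer(), last_session = integer(),
                          n_sessions = integer(), positions_um = list()))
  }
  out <- tibble::tibble(
    dendrite_id = dendrite %||% NA_character_,
    first_session = vapply(closed, function(l) l$first, integer(1)),
    last_session = vapply(closed, function(l) l$last, integer(1)),
    positions_um = lapply(closed, function(l) l$positions))
  out <- dplyr::arrange(out, .data$first_session,
                        vapply(out$positions_um, function(p) p[1], numeric(1)))
  out$lineage_id <- sprintf("%s_L%03d", out$dendrite_id, seq_len(nrow(out)))
  out$n_sessions <- out$last_session - out$first_session + 1L
  out[, c("lineage_id", "dendrite_id", "first_session", "last_session",
          "n_sessions", "positions_um")]
}

#' Track every dendrite of an annotation table
#'
#' Convenience driver: splits an annotation table by dendrite, matches each
#' consecutive session pair with [match_sessions()] and chains lineages with
#' [build_lineages()]. Sessions absent for a dendrite are treated as empty
#' (all spines eliminated / formed around them).
#'
#' @param annotations annotation table (e.g. `cohort$annotations` or
#'   [read_annotations()]): columns `group`, `mouse_id`, `dendrite_id`,
#'   `session_day`, `position_um` (lateral spines only).
#' @param session_days the full imaging schedule; defaults to the sorted
#'   unique `session_day` values present.
#' @param tolerance_um matching tolerance (um).
#' @return list with class `spine_tracking`: `matches` (tibble of
#'   per-interval counts: `n_a`, `n_b`, `n_stable`, `n_eliminated`,
#'   `n_formed`), `lineages` (row-bound [build_lineages()] output with
#'   `group` and `mouse_id` attached), `session_days`, `tolerance_um`.
#' @export
track_cohort <- function(annotations, session_days = NULL, tolerance_um = 0.5) {
  stopifnot(all(c("dendrite_id", "session_day", "position_um") %in%
                  names(annotations)))
  if (is.null(session_days)) {
    session_days <- sort(unique(annotations$session_day))
  }
  meta_cols <- intersect(c("group", "mouse_id"), names(annotations))
  match_rows <- list(); lineage_rows <- list()
  for (dd in unique(annotations$dendrite_id)) {
    ann_d <- annotations[annotations$dendrite_id == dd, ]
    meta <- ann_d[1, meta_cols, drop = FALSE]
    ms <- vector("list", length(session_days) - 1L)
    for (k in seq_len(length(session_days) - 1L)) {
      pa <- ann_d$position_um[ann_d$session_day == session_days[k]]
      pb <- ann_d$position_um[ann_d$session_day == session_days[k + 1]]
      ms[[k]] <- match_sessions(pa, pb, tolerance_um, dendrite_id = dd,
                                day_a = session_days[k],
                                day_b = session_days[k + 1])
    }
    match_rows[[dd]] <- tibble::tibble(
      dendrite_id = dd,
      day_a = vapply(ms, function(m) m$day_a, numeric(1)),
      day_b = vapply(ms, function(m) m$day_b, numeric(1)),
      n_a = vapply(ms, function(m) m$n_a, integer(1)),
      n_b = vapply(ms, function(m) m$n_b, integer(1)),
      n_stable = vapply(ms, function(m) nrow(m$stable), integer(1)),
      n_eliminated = vapply(ms, function(m) length(m$eliminated), integer(1)),
      n_formed = vapply(ms, function(m) length(m$formed), integer(1)))
    lin <- build_lineages(ms)
    if (nrow(lin)) {
      for (cc in meta_cols) lin[[cc]] <- meta[[cc]]
      lineage_rows[[dd]] <- lin
    }
    if (ncol(meta)) {
      for (cc in meta_cols) match_rows[[dd]][[cc]] <- meta[[cc]]
    }
  }
  structure(
    list(matches = dplyr::bind_rows(match_rows),
         lineages = dplyr::bind_rows(lineage_rows),
         session_days = session_days, tolerance_um = tolerance_um),
    class = "spine_tracking")
}

#' Score tracked lineages against simulator ground truth
#'
#' Compares lineages reconstructed from annotations with the simulator's
#' event log, restricted to lateral spines (the only ones annotated). Each
#' ground-truth spine contributes one birth event and, if it disappeared,
#' one death event; an event is recovered when some lineage of the same
#' dendrite starts (resp. ends) at the same session with the same observed
#' position.
#'
#' @param cohort a [simulate_cohort()] bundle.
#' @param tracking a [track_cohort()] result on `cohort$annotations`.
#' @return list: `n_events`, `n_recovered`, `agreement` (fraction), and the
#'   per-event tibble `events`.
#' @export
score_tracking <- function(cohort, tracking) {
  stopifnot(inherits(cohort, "spine_cohort"), inherits(tracking, "spine_tracking"))
  lat <- cohort$tracks[cohort$tracks$is_lateral, ]
  pos <- cohort$positions
  n_sessions <- length(cohort$session_days)

  key <- function(dendrite, session, position) {
    paste(dendrite, session, round(position, 9), sep = "|")
  }
  lin <- tracking$lineages
  lin_first_pos <- vapply(lin$positions_um, function(p) p[1], numeric(1))
  lin_last_pos <- vapply(lin$positions_um, function(p) p[length(p)], numeric(1))
  start_keys <- key(lin$dendrite_id, lin$first_session, lin_first_pos)
  end_keys <- key(lin$dendrite_id, lin$last_session, lin_last_pos)

  truth_pos_at <- function(ids, sessions) {
    i <- match(paste(ids, sessions), paste(pos$spine_id, pos$session))
    pos$position_um[i]
  }
  births <- tibble::tibble(
    spine_id = lat$spine_id, dendrite_id = lat$dendrite_id, event = "birth",
    session = lat$birth_session,
    position_um = truth_pos_at(lat$spine_id, lat$birth_session))
  dead <- lat[!is.na(lat$death_session), ]
  deaths <- tibble::tibble(
    spine_id = dead$spine_id, dendrite_id = dead$dendrite_id, event = "death",
    session = dead$death_session,
    position_um = truth_pos_at(dead$spine_id, dead$death_session))
  births$recovered <- key(births$dendrite_id, births$session,
                          births$position_um) %in% start_keys
  # a death at session k means the lineage must end at session k; spines
  # alive at the end must belong to a lineage ending at the final session
  deaths$recovered <- key(deaths$dendrite_id, deaths$session,
                          deaths$position_um) %in% end_keys
  alive <- lat[is.na(lat$death_session), ]
  survivals <- tibble::tibble(
    spine_id = alive$spine_id, dendrite_id = alive$dendrite_id,
    event = "alive_at_end", session = n_sessions,
    position_um = truth_pos_at(alive$spine_id, n_sessions))
  survivals$recovered <- key(survivals$dendrite_id, survivals$session,
                             survivals$position_um) %in% end_keys

  events <- dplyr::bind_rows(births, deaths, survivals)
  list(n_events = nrow(events), n_recovered = sum(events$recovered),
       agreement = mean(events$recovered), events = events)
}
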