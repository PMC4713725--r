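# Independent oracles used across the suite.

# Exhaustive-search matcher: enumerates every one-to-one matching between
# positions a and b that respects the tolerance, and returns the
# maximum-cardinality, minimum-total-displacement optimum. Exponential in
# principle; intended for instances with <= 8 positions per session.
brute_force_match <- function(a, b, tol) {
  n <- length(a); m <- length(b)
  best <- list(card = -1L, cost = Inf, pairs = NULL)
  used <- logical(m)
  pairs <- matrix(integer(0), ncol = 2)
  recurse <- function(i, card, cost, pairs) {
    if (i > n) {
      if (card > best$card ||
          (card == best$card && cost < best$cost - 1e-12)) {
        best <<- list(card = card, cost = cost, pairs = pairs)
      }
      return(invisible(NULL))
    }
    recurse(i + 1L, card, cost, pairs)  # leave a[i] unmatched
    for (j in seq_len(m)) {
      if (!used[j] && abs(a[i] - b[j]) <= tol) {
        used[j] <<- TRUE
        recurse(i + 1L, card + 1L, cost + abs(a[i] - b[j]),
                rbind(pairs, c(i, j)))
        used[j] <<- FALSE
      }
    }
  }
  recurse(1L, 0L, 0, pairs)
  best
}

# Closed-form expected survival of a first-session (mature) spine up to each
# session, from the weekly elimination schedule: the product of per-interval
# survival probabilities. Recomputes the EE schedule from first principles.
expected_preexisting_survival <- function(params) {
  days <- params$session_days
  S <- length(days)
  surv <- numeric(S)
  surv[1] <- 1
  for (k in seq_len(S - 1)) {
    p <- params$p_elim_per_week
    if (!is.na(params$ee_start_day) && days[k] >= params$ee_start_day) {
      weeks <- floor((days[k] - params$ee_start_day) / 7) + 1
      p <- p - weeks * params$ee_elim_decline_per_week
    }
    p <- min(max(p, 0), 1)
    surv[k + 1] <- surv[k] * (1 - p)
  }
  surv
}

# Closed-form expected survival to the final session of a spine first seen
# at index_session: new-spine hazard in its first interval, mature hazard
# afterwards.
expected_gained_survival_final <- function(params, index_session) {
  days <- params$session_days
  S <- length(days)
  p_at <- function(k, new) {
    ee <- !is.na(params$ee_start_day) && days[k] >= params$ee_start_day
    if (new) {
      if (ee && !is.na(params$ee_new_spine_stabilization)) {
        params$ee_new_spine_stabilization
      } else params$p_elim_new_per_week
    } else {
      p <- params$p_elim_per_week
      if (ee) {
        p <- p - (floor((days[k] - params$ee_start_day) / 7) + 1) *
          params$ee_elim_decline_per_week
      }
      min(max(p, 0), 1)
    }
  }
  s <- 1 - p_at(index_session, new = TRUE)
  if (index_session + 1 <= S - 1) {
    for (k in seq(index_session + 1, S - 1)) s <- s * (1 - p_at(k, new = FALSE))
  }
  s
}

# Small simulated cohort used by several tests: one group, default dynamics.
make_test_cohort <- function(n_mice = 2, dendrites_per_mouse = 5, seed = 101,
                             ...) {
  simulate_cohort(list(
    grp = sim_params(n_mice = n_mice, dendrites_per_mouse = dendrites_per_mouse,
                     seed = seed, ...)))
}
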