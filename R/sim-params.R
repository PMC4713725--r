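#' Simulation parameters for one experimental group
#'
#' Bundles the study-design numbers that drive the spine birth--death
#' simulator: cohort sizes, imaging schedule, baseline density, weekly
#' elimination/formation rates, the enriched-environment (EE) schedule and
#' observation noise. Defaults describe a typical chronic-imaging design:
#' weekly sessions on days 1, 8, ..., 43, 4--6 mice per group, 8--12 apical
#' dendrites of 25--35 um per mouse, and only laterally protruding spines
#' annotated.
#'
#' Elimination is modelled per weekly interval as a Bernoulli event, matching
#' the granularity at which turnover is observable. Spines formed in the
#' immediately preceding interval die with `p_elim_new_per_week` in their
#' first interval (newly formed spines are less stable than mature ones);
#' all older spines die with `p_elim_per_week`. From `ee_start_day` onward
#' the EE regime applies: the mature elimination probability declines by
#' `ee_elim_decline_per_week` for every EE interval (floored at 0), and the
#' new-spine elimination probability is replaced by
#' `ee_new_spine_stabilization` (stabilization of gained spines).
#'
#' @param n_mice mice per group.
#' @param dendrites_per_mouse dendrites imaged per mouse.
#' @param dendrite_length_um length 2 interval (um); each dendrite's length
#'   is drawn uniformly from it.
#' @param session_days strictly increasing imaging days.
#' @param baseline_density_per_um expected initial spine density (spines/um).
#' @param p_elim_per_week weekly elimination probability of mature spines.
#' @param p_elim_new_per_week weekly elimination probability of spines in
#'   their first interval after formation.
#' @param formation_rate_per_um_per_week expected formations per um per week.
#' @param ee_start_day day EE housing starts, or `NA` for standard housing
#'   throughout.
#' @param ee_elim_decline_per_week additive weekly decrease of
#'   `p_elim_per_week` under EE (probabilities are clamped to `[0, 1]`).
#' @param ee_new_spine_stabilization replacement for `p_elim_new_per_week`
#'   under EE, or `NA` to keep the standard value.
#' @param lateral_fraction probability that a spine protrudes laterally and
#'   is therefore annotated.
#' @param position_jitter_um scale (um) of per-session positional noise;
#'   noise is truncated at 1.5 scale units so two observations of the same
#'   spine in consecutive sessions differ by at most `3 * position_jitter_um`.
#' @param min_separation_um minimum separation between annotated positions
#'   within one session (um); keeps the same-spine rule well posed.
#' @param frailty_sd standard deviation of a mouse-level log-normal
#'   multiplicative frailty applied to elimination probabilities and the
#'   formation rate (0 = independent dendrites, the default).
#' @param seed integer seed making a cohort reproducible, or `NA` to draw
#'   from the current RNG stream.
#'
#' @return An object of class `sim_params` (a named list).
#' @seealso [cohort_presets()], [simulate_dendrite()], [simulate_cohort()]
#' @export
#' @examples
#' p <- sim_params(seed = 1)
#' p$session_days
sim_params <- function(n_mice = 5,
                       dendrites_per_mouse = 10,
                       dendrite_length_um = c(25, 35),
                       session_days = c(1, 8, 15, 22, 29, 36, 43),
                       baseline_density_per_um = 0.40,
                       p_elim_per_week = 0.06,
                       p_elim_new_per_week = 0.30,
                       formation_rate_per_um_per_week = 0.032,
                       ee_start_day = NA_real_,
                       ee_elim_decline_per_week = 0,
                       ee_new_spine_stabilization = NA_real_,
                       lateral_fraction = 0.6,
                       position_jitter_um = 0.1,
                       min_separation_um = 0.6,
                       frailty_sd = 0,
                       seed = NA_integer_) {
  p <- list(
    n_mice = n_mice,
    dendrites_per_mouse = dendrites_per_mouse,
    dendrite_length_um = as.numeric(dendrite_length_um),
    session_days = as.numeric(session_days),
    baseline_density_per_um = baseline_density_per_um,
    p_elim_per_week = p_elim_per_week,
    p_elim_new_per_week = p_elim_new_per_week,
    formation_rate_per_um_per_week = formation_rate_per_um_per_week,
    ee_start_day = as.numeric(ee_start_day),
    ee_elim_decline_per_week = ee_elim_decline_per_week,
    ee_new_spine_stabilization = as.numeric(ee_new_spine_stabilization),
    lateral_fraction = lateral_fraction,
    position_jitter_um = position_jitter_um,
    min_separation_um = min_separation_um,
    frailty_sd = frailty_sd,
    seed = seed
  )
  class(p) <- "sim_params"
  validate_sim_params(p)
}

validate_sim_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid sim_params: ", msg, call. = FALSE)
  chk(length(p$dendrite_length_um) == 2 && all(p$dendrite_length_um > 0) &&
        p$dendrite_length_um[1] <= p$dendrite_length_um[2],
      "dendrite_length_um must be a positive interval c(lo, hi)")
  chk(length(p$session_days) >= 2 && all(diff(p$session_days) > 0),
      "session_days must be strictly increasing with >= 2 sessions")
  chk(p$n_mice >= 1 && p$dendrites_per_mouse >= 1, "cohort sizes must be >= 1")
  chk(p$baseline_density_per_um >= 0, "baseline_density_per_um must be >= 0")
  for (nm in c("p_elim_per_week", "p_elim_new_per_week", "lateral_fraction")) {
    chk(p[[nm]] >= 0 && p[[nm]] <= 1, paste(nm, "must be in [0, 1]"))
  }
  if (!is.na(p$ee_new_spine_stabilization)) {
    chk(p$ee_new_spine_stabilization >= 0 && p$ee_new_spine_stabilization <= 1,
        "ee_new_spine_stabilization must be in [0, 1] or NA")
  }
  chk(p$formation_rate_per_um_per_week >= 0, "formation rate must be >= 0")
  chk(p$position_jitter_um >= 0, "position_jitter_um must be >= 0")
  chk(p$min_separation_um >= 0, "min_separation_um must be >= 0")
  chk(p$frailty_sd >= 0, "frailty_sd must be >= 0")
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  %d mice x %d dendrites, length U(%g, %g) um\n",
              x$n_mice, x$dendrites_per_mouse,
              x$dendrite_length_um[1], x$dendrite_length_um[2]))
  cat(sprintf("  sessions on days: %s\n", paste(x$session_days, collapse = ", ")))
  cat(sprintf("  density %g/um; p_elim %g, p_elim_new %g, formation %g/um/wk\n",
              x$baseline_density_per_um, x$p_elim_per_week,
              x$p_elim_new_per_week, x$formation_rate_per_um_per_week))
  if (!is.na(x$ee_start_day)) {
    cat(sprintf("  EE from day %g: elim decline %g/wk, new-spine elim -> %s\n",
                x$ee_start_day, x$ee_elim_decline_per_week,
                ifelse(is.na(x$ee_new_spine_stabilization), "unchanged",
                       format(x$ee_new_spine_stabilization))))
  } else {
    cat("  standard housing throughout\n")
  }
  invisible(x)
}

#' Shipped group presets
#'
#' Parameter presets for the five experimental groups of the emulated study
#' design: control and amyloid-model (`deltaE9`) mice under standard caging
#' (SC) or enriched environment (EE), plus a rescued amyloid-model group
#' (anti-inflammatory treatment during EE). Under EE, control mice show a
#' gradual weekly decline in mature-spine elimination and stabilization of
#' newly gained spines (hence rising density and higher gained-spine
#' survival); the amyloid-model EE preset lacks both effects; the rescued
#' preset restores them.
#'
#' @param seed base integer seed; preset `i` receives `seed + i - 1`.
#' @param groups which presets to return.
#' @return Named list of [sim_params()] objects.
#' @export
#' @examples
#' names(cohort_presets(seed = 1))
cohort_presets <- function(seed = 1L,
                           groups = c("control-SC", "control-EE", "deltaE9-SC",
                                      "deltaE9-EE", "deltaE9-EE-rescued")) {
  groups <- match.arg(groups, several.ok = TRUE)
  base <- function(s, ...) sim_params(seed = s, ...)
  all <- list(
    "control-SC" = function(s) base(s),
    "control-EE" = function(s) base(s, ee_start_day = 8,
                                    ee_elim_decline_per_week = 0.01,
                                    ee_new_spine_stabilization = 0.15),
    "deltaE9-SC" = function(s) base(s),
    "deltaE9-EE" = function(s) base(s, ee_start_day = 8,
                                    ee_elim_decline_per_week = 0,
                                    ee_new_spine_stabilization = NA),
    "deltaE9-EE-rescued" = function(s) base(s, ee_start_day = 8,
                                            ee_elim_decline_per_week = 0.01,
                                            ee_new_spine_stabilization = 0.15)
  )
  out <- list()
  for (i in seq_along(groups)) {
    out[[groups[i]]] <- all[[groups[i]]](as.integer(seed) + i - 1L)
  }
  out
}

# Elimination probabilities applicable to the interval that starts at
# `start_day`, under the (possibly absent) EE schedule. Returns
# c(mature = ..., new = ...), both clamped to [0, 1].
interval_elim_probs <- function(p, start_day) {
  mature <- p$p_elim_per_week
  newp <- p$p_elim_new_per_week
  if (!is.na(p$ee_start_day) && start_day >= p$ee_start_day) {
    n_ee <- floor((start_day - p$ee_start_day) / 7) + 1
    mature <- mature - n_ee * p$ee_elim_decline_per_week
    if (!is.na(p$ee_new_spine_stabilization)) newp <- p$ee_new_spine_stabilization
  }
  c(mature = min(max(mature, 0), 1), new = min(max(newp, 0), 1))
}
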