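# Annotation tables on disk.
#
# CSV dialect: comma separated, UTF-8, header required. Columns:
#   group, mouse_id, dendrite_id, session_day, spine_position_um, lateral
# plus optional dendrite_length_um. `lateral` is logical (TRUE/FALSE or
# 0/1). Only laterally protruding spines enter the analysis; the filter is
# applied once, at load time.

required_annotation_cols <- c("group", "mouse_id", "dendrite_id",
                              "session_day", "spine_position_um", "lateral")

#' Read a spine annotation table
#'
#' Reads and validates per-session spine annotations, dropping non-lateral
#' spines (which cannot be scored reliably in z). Validation errors name the
#' offending data row.
#'
#' @param path CSV file.
#' @param keep_non_lateral keep rows with `lateral = FALSE` (default drops
#'   them).
#' @return tibble with columns `group`, `mouse_id`, `dendrite_id`,
#'   `session`, `session_day`, `position_um`, `lateral` (and
#'   `dendrite_length_um` when present in the file). `session` is the
#'   1-based index of `session_day` within the file's sorted schedule.
#' @export
read_annotations <- function(path, keep_non_lateral = FALSE) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required_annotation_cols, names(raw))
  if (length(missing)) {
    stop("annotation file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad_row <- function(cond, what) {
    if (any(cond, na.rm = TRUE) || anyNA(cond)) {
      rows <- which(cond | is.na(cond))
      stop("annotation file ", path, ": ", what, " in data row(s) ",
           paste(head(rows, 5), collapse = ", "),
           if (length(rows) > 5) " ..." else "", call. = FALSE)
    }
  }
  pos <- suppressWarnings(as.numeric(raw$spine_position_um))
  bad_row(is.na(pos), "non-numeric spine_position_um")
  bad_row(pos < 0, "negative spine_position_um")
  day <- suppressWarnings(as.numeric(raw$session_day))
  bad_row(is.na(day), "non-numeric session_day")
  lat <- raw$lateral
  if (is.character(lat)) lat <- toupper(trimws(lat)) %in% c("TRUE", "T", "1")
  lat <- as.logical(lat)
  bad_row(is.na(lat), "unparseable lateral flag")
  if ("dendrite_length_um" %in% names(raw)) {
    len <- suppressWarnings(as.numeric(raw$dendrite_length_um))
    bad_row(is.na(len), "non-numeric dendrite_length_um")
    bad_row(pos > len, "spine_position_um beyond dendrite length")
  }
  out <- tibble::tibble(
    group = as.character(raw$group), mouse_id = as.character(raw$mouse_id),
    dendrite_id = as.character(raw$dendrite_id),
    session_day = day, position_um = pos, lateral = lat)
  if ("dendrite_length_um" %in% names(raw)) {
    out$dendrite_length_um <- as.numeric(raw$dendrite_length_um)
  }
  if (!keep_non_lateral) out <- out[out$lateral, ]
  schedule <- sort(unique(out$session_day))
  out$session <- match(out$session_day, schedule)
  out[, c("group", "mouse_id", "dendrite_id", "session", "session_day",
          "position_um", "lateral",
          intersect("dendrite_length_um", names(out)))]
}

#' Write a cohort's annotations / ground-truth events to CSV
#'
#' `write_annotations()` writes the observable annotation table (one row per
#' annotated spine per session); `write_events()` writes the ground-truth
#' birth/death log of a simulated cohort, which exists only for synthetic
#' data.
#'
#' @param cohort a [simulate_cohort()] bundle.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_annotations <- function(cohort, path) {
  stopifnot(inherits(cohort, "spine_cohort"))
  ann <- cohort$annotations
  out <- data.frame(
    group = ann$group, mouse_id = ann$mouse_id, dendrite_id = ann$dendrite_id,
    session_day = ann$session_day, spine_position_um = ann$position_um,
    lateral = ann$lateral, dendrite_length_um = ann$dendrite_length_um)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
write_events <- function(cohort, path) {
  stopifnot(inherits(cohort, "spine_cohort"))
  ev <- cohort$events
  write.csv(as.data.frame(ev), path, row.names = FALSE)
  invisible(path)
}

#' Study design: groups, schedule and analysis windows
#'
#' Collects everything [run_report()] needs: the per-group simulation
#' parameters (or, in principle, annotation sources), the imaging schedule,
#' which sessions form the density baseline, and which session indexes the
#' gained-spine survival and transient-spine analyses.
#'
#' @param groups named list of [sim_params()] objects.
#' @param baseline_sessions sessions averaged into the density baseline.
#' @param index_session session at which gained spines (formed during the
#'   preceding interval) are first observed; default: the first session
#'   after one full week under the manipulation (i.e. session 3 when the
#'   manipulation starts at session 2).
#' @param tolerance_um matching tolerance passed to the tracker.
#' @return object of class `study_design`.
#' @export
study_design <- function(groups, baseline_sessions = c(1L, 2L),
                         index_session = 3L, tolerance_um = 0.5) {
  stopifnot(is.list(groups), length(groups) >= 1,
            all(vapply(groups, inherits, logical(1), "sim_params")))
  days <- groups[[1]]$session_days
  for (g in groups) {
    if (!identical(g$session_days, days)) {
      stop("all groups must share the same session schedule", call. = FALSE)
    }
  }
  stopifnot(all(baseline_sessions %in% seq_along(days)),
            index_session >= 2, index_session <= length(days))
  structure(
    list(groups = groups, session_days = days,
         baseline_sessions = as.integer(baseline_sessions),
         index_session = as.integer(index_session),
         tolerance_um = tolerance_um),
    class = "study_design")
}

#' Read a study design from a YAML config
#'
#' The config maps group labels either to a shipped preset name (string) or
#' to a table of [sim_params()] arguments; top-level keys
#' `baseline_sessions`, `index_session` and `tolerance_um` are optional. A
#' commented example ships in `inst/extdata/demo_design.yaml`.
#'
#' @param path YAML file.
#' @param seed base seed assigned to groups lacking an explicit one
#'   (group `i` gets `seed + i - 1`).
#' @return a [study_design()].
#' @export
#' @examples
#' cfg <- system.file("extdata", "demo_design.yaml", package = "spinedyn")
#' design <- read_study_design(cfg, seed = 1)
#' names(design$groups)
read_study_design <- function(path, seed = 1L) {
  cfg <- yaml::read_yaml(path)
  stopifnot(!is.null(cfg$groups), length(cfg$groups) >= 1)
  groups <- list()
  for (i in seq_along(cfg$groups)) {
    label <- names(cfg$groups)[i]
    spec <- cfg$groups[[i]]
    if (is.character(spec) && length(spec) == 1) {
      groups[[label]] <- cohort_presets(seed = as.integer(seed) + i - 1L,
                                        groups = spec)[[spec]]
    } else {
      if (is.null(spec$seed)) spec$seed <- as.integer(seed) + i - 1L
      groups[[label]] <- do.call(sim_params, spec)
    }
  }
  study_design(
    groups,
    baseline_sessions = as.integer(cfg$baseline_sessions %||% c(1L, 2L)),
    index_session = as.integer(cfg$index_session %||% 3L),
    tolerance_um = cfg$tolerance_um %||% 0.5)
}
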