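# End-to-end report: simulate -> track -> metrics -> statistics -> figures.

#' Run the full analysis pipeline on a study design
#'
#' One call reproducing the standard panel structure of a longitudinal
#' spine-plasticity experiment on simulated cohorts: simulates every group,
#' tracks spine identities, computes dendrite- and mouse-level metrics,
#' runs the group comparisons (extra sum-of-squares F tests on the
#' longitudinal metrics; one-way ANOVA with Newman-Keuls, or a t test for
#' two groups, on endpoint metrics), and writes `series.csv`, `reports.csv`
#' and one figure per panel. Deterministic given `seed`.
#'
#' @param design a [study_design()].
#' @param seed integer seed; group `i` is simulated with `seed + i - 1`
#'   unless its `sim_params` carries an explicit seed and `seed` is `NULL`.
#' @param out_dir output directory (created if needed), or `NULL` to skip
#'   writing files.
#' @param make_figures write the panel figures (PDF via ggplot2).
#' @return invisibly, a list: `cohort`, `tracking`, `dendrite_series`,
#'   `mouse_series` (long-format tibbles), `reports` (tibble of test
#'   results), `files` (paths written).
#' @export
run_report <- function(design, seed = NULL, out_dir = NULL,
                       make_figures = TRUE) {
  stopifnot(inherits(design, "study_design"))
  groups <- design$groups
  if (!is.null(seed)) {
    for (i in seq_along(groups)) groups[[i]]$seed <- as.integer(seed) + i - 1L
  }
  cohort <- simulate_cohort(groups)
  tracking <- track_cohort(cohort$annotations,
                           session_days = design$session_days,
                           tolerance_um = design$tolerance_um)
  dendrite_series <- compute_metrics(
    tracking, cohort$dendrites,
    baseline_sessions = design$baseline_sessions,
    index_session = design$index_session)
  mouse_series <- aggregate_per_mouse(dendrite_series)
  reports <- report_statistics(mouse_series, design)

  files <- character(0)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    series_path <- file.path(out_dir, "series.csv")
    series_out <- rbind(
      cbind(level = "dendrite",
            as.data.frame(dendrite_series[, c("dendrite_id", "mouse_id",
                                              "group", "metric",
                                              "session_day", "value")]) |>
        stats::setNames(c("unit_id", "mouse_id", "group", "metric",
                          "session_day", "value"))),
      cbind(level = "mouse",
            data.frame(unit_id = mouse_series$mouse_id,
                       mouse_id = mouse_series$mouse_id,
                       group = mouse_series$group,
                       metric = mouse_series$metric,
                       session_day = mouse_series$session_day,
                       value = mouse_series$value)))
    write.csv(series_out, series_path, row.names = FALSE)
    reports_path <- file.path(out_dir, "reports.csv")
    write.csv(as.data.frame(reports), reports_path, row.names = FALSE)
    files <- c(series_path, reports_path)
    if (make_figures) {
      files <- c(files, report_figures(mouse_series, out_dir))
    }
  }
  invisible(list(cohort = cohort, tracking = tracking,
                 dendrite_series = dendrite_series,
                 mouse_series = mouse_series, reports = reports,
                 files = files))
}

# Group-comparison statistics on mouse-level series. Longitudinal metrics
# get pairwise extra-SS F tests on the line fits; endpoint metrics (values
# at the final session, and the scalar transient fraction) get one-way
# ANOVA + Newman-Keuls across all groups (a t test when only two).
report_statistics <- function(mouse_series, design) {
  rows <- list()
  add <- function(metric, rep, extra = NULL) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      metric = metric, test = rep$test_name,
      groups = paste(rep$groups_compared, collapse = " vs "),
      statistic = rep$statistic,
      df1 = rep$df[1], df2 = if (length(rep$df) > 1) rep$df[2] else NA_real_,
      p_value = rep$p_value,
      significant_05 = rep$significant_05, significant_01 = rep$significant_01,
      note = rep$note %||% NA_character_)
  }
  labels <- unique(mouse_series$group)
  final_day <- max(design$session_days)

  longitudinal <- c("relative_density", "normalized_elimination",
                    "normalized_formation", "preexisting_survival")
  for (met in longitudinal) {
    d <- mouse_series[mouse_series$metric == met & !is.na(mouse_series$value), ]
    for (i in seq_along(labels)) {
      for (j in seq_len(i - 1L)) {
        dd <- d[d$group %in% c(labels[i], labels[j]), ]
        if (length(unique(dd$group)) < 2 || nrow(dd) < 8) next
        add(met, trend_f_test(dd))
      }
    }
  }

  endpoint_samples <- function(met, day = NULL) {
    d <- mouse_series[mouse_series$metric == met, ]
    d <- if (is.null(day)) d[is.na(d$session_day), ]
    else d[!is.na(d$session_day) & d$session_day == day, ]
    d <- d[!is.na(d$value), ]
    split(d$value, factor(d$group, levels = labels))
  }
  endpoints <- list(
    gained_survival = final_day,
    preexisting_survival = final_day,
    transient_fraction = NULL)
  for (met in names(endpoints)) {
    samples <- endpoint_samples(met, endpoints[[met]])
    samples <- samples[vapply(samples, length, integer(1)) >= 2]
    if (length(samples) >= 3) {
      an <- one_way_anova(samples)
      add(met, an)
      nk <- newman_keuls(samples, anova = an)
      for (z in seq_len(nrow(nk))) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          metric = met, test = "newman_keuls",
          groups = paste(nk$group_a[z], "vs", nk$group_b[z]),
          statistic = nk$q[z], df1 = nk$r[z], df2 = an$df_within,
          p_value = nk$p_value[z],
          significant_05 = isTRUE(nk$significant[z]),
          significant_01 = NA, note = if (nk$sealed[z]) "sealed" else NA_character_)
      }
    } else if (length(samples) == 2) {
      add(met, two_tailed_t_test(samples[[1]], samples[[2]],
                                 labels = names(samples)))
    }
  }
  dplyr::bind_rows(rows)
}

# Panel figures: group mean +/- SEM over sessions for the longitudinal
# metrics, and a per-mouse dot plot for the transient fraction.
report_figures <- function(mouse_series, out_dir) {
  panels <- c("relative_density", "elimination_fraction", "formation_fraction",
              "preexisting_survival", "gained_survival", "transient_fraction")
  paths <- character(0)
  for (met in panels) {
    d <- mouse_series[mouse_series$metric == met & !is.na(mouse_series$value), ]
    if (!nrow(d)) next
    if (met == "transient_fraction") {
      p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$value)) +
        ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.7) +
        ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                              linewidth = 0.3) +
        ggplot2::labs(y = "transient fraction", x = NULL)
    } else {
      sm <- d |>
        dplyr::group_by(.data$group, .data$session_day) |>
        dplyr::summarise(mean = mean(.data$value),
                         sem = sd(.data$value) / sqrt(dplyr::n()),
                         .groups = "drop")
      p <- ggplot2::ggplot(sm, ggplot2::aes(x = .data$session_day,
                                            y = .data$mean,
                                            colour = .data$group)) +
        ggplot2::geom_line() + ggplot2::geom_point() +
        ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                            ymax = .data$mean + .data$sem),
                               width = 1) +
        ggplot2::labs(x = "day", y = gsub("_", " ", met))
    }
    path <- file.path(out_dir, paste0(met, ".pdf"))
    suppressWarnings(ggplot2::ggsave(path, p, width = 5, height = 3.5))
    paths <- c(paths, path)
  }
  paths
}
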