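#' Validated study configuration
#'
#' Builds a validated configuration for a simulated training study from a
#' YAML file or an equivalent nested list. Top-level keys: `seed` (integer),
#' `protocol` (arguments to [protocol_config()], excluding `direction`),
#' `criteria` (arguments to [rejection_criteria()]), and `cohort` (a list of
#' subjects, each with `id`, `group` (`"up"` or `"down"`) and any
#' [learner_params()] arguments). Unknown keys anywhere are rejected so a
#' typo cannot silently fall back to a default.
#'
#' @param x Path to a YAML file, or a nested list with the same structure.
#' @return An object of class `study_config`: `seed`, `protocol_args`,
#'   `criteria`, and `cohort` (named list with `group` and `learner` per
#'   subject).
#' @export
study_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  allowed_top <- c("seed", "protocol", "criteria", "cohort")
  check_keys(cfg, allowed_top, "top level")
  if (is.null(cfg$seed) || cfg$seed != as.integer(cfg$seed)) {
    stop("config field 'seed' must be an integer", call. = FALSE)
  }
  proto <- cfg$protocol %||% list()
  check_keys(proto, setdiff(names(formals(protocol_config)),
                            c("direction", "criteria")), "protocol")
  crit_args <- cfg$criteria %||% list()
  check_keys(crit_args, names(formals(rejection_criteria)), "criteria")
  criteria <- do.call(rejection_criteria, crit_args)

  if (is.null(cfg$cohort) || length(cfg$cohort) == 0) {
    stop("config field 'cohort' must list at least one subject", call. = FALSE)
  }
  learner_keys <- names(formals(learner_params))
  cohort <- list()
  for (subj in cfg$cohort) {
    check_keys(subj, c("id", "group", learner_keys), "cohort entry")
    if (is.null(subj$id)) stop("cohort entry lacks 'id'", call. = FALSE)
    if (is.null(subj$group) || !subj$group %in% c("up", "down")) {
      stop(sprintf("cohort entry '%s': 'group' must be \"up\" or \"down\"",
                   subj$id), call. = FALSE)
    }
    lp <- subj[intersect(names(subj), learner_keys)]
    if (!is.null(lp$artifact_rates)) lp$artifact_rates <- unlist(lp$artifact_rates)
    if (!is.null(lp$power_trends)) {
      lp$power_trends <- lapply(lp$power_trends, unlist)
    }
    cohort[[subj$id]] <- list(group = subj$group,
                              learner = do.call(learner_params, lp))
  }
  structure(list(seed = as.integer(cfg$seed), protocol_args = proto,
                 criteria = criteria, cohort = cohort),
            class = "study_config")
}

check_keys <- function(x, allowed, where) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0) {
    stop(sprintf("unknown config key(s) at %s: %s", where,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

study_protocol <- function(cfg, direction = "up") {
  do.call(protocol_config,
          c(cfg$protocol_args, list(direction = direction,
                                    criteria = cfg$criteria)))
}

run_filename <- function(subject, session, run) {
  sprintf("sub-%s_ses-%02d_run-%d.edf", subject, session, run)
}

#' Simulate a study and write it to disk
#'
#' Simulates every run of every subject and session in the configuration
#' and writes one EDF file per run plus a JSON sidecar (same basename,
#' `.json`) holding the ground truth: the coupling actually used, the run
#' seed, and artifact event onsets. A `manifest.csv` indexes all runs.
#' Per-run seeds are drawn once from the master seed, so the output is
#' reproducible bit-for-bit (summaries) and within 16-bit quantization
#' (EDF) from config + seed.
#'
#' @param cfg A [study_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest tibble (subject, group, session, run, file,
#'   coupling_true, seed), invisibly.
#' @export
simulate_study <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "study_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  proto <- study_protocol(cfg)
  set.seed(cfg$seed)
  n_subj <- length(cfg$cohort)
  seeds <- array(sample.int(2^31 - 1,
                            n_subj * proto$n_sessions * proto$runs_per_session),
                 dim = c(n_subj, proto$n_sessions, proto$runs_per_session))
  rows <- list()
  for (si in seq_len(n_subj)) {
    id <- names(cfg$cohort)[si]
    entry <- cfg$cohort[[si]]
    for (s in seq_len(proto$n_sessions)) {
      for (r in seq_len(proto$runs_per_session)) {
        rec <- simulate_run(entry$learner, s, r, proto$run_s, proto$fs,
                            seed = seeds[si, s, r])
        fn <- run_filename(id, s, r)
        write_edf(rec, file.path(out_dir, fn))
        sidecar <- list(subject = id, group = entry$group, session = s,
                        run = r, seed = seeds[si, s, r],
                        coupling_true = rec$meta$coupling_true,
                        blink_onsets = rec$meta$artifact_events$blink_onsets,
                        muscle_onsets = rec$meta$artifact_events$muscle_onsets)
        jsonlite::write_json(sidecar, file.path(out_dir, sub("\\.edf$", ".json", fn)),
                             auto_unbox = TRUE, digits = NA)
        rows[[length(rows) + 1]] <- tibble::tibble(
          subject = id, group = entry$group, session = s, run = r,
          file = fn, coupling_true = rec$meta$coupling_true,
          seed = seeds[si, s, r])
      }
    }
  }
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Process a directory of simulated runs into per-run summaries
#'
#' Reads every run listed in the manifest, applies the offline pipeline
#' ([process_run()]) and returns one summary row per run. The number of
#' produced summaries is reconciled against the manifest: a missing or
#' unreadable run is an error, never silently dropped.
#'
#' @param in_dir Directory written by [simulate_study()].
#' @param config A [protocol_config()] used for the offline analysis.
#' @param out_csv Optional path; when given the summary table is also
#'   written as CSV.
#' @return Tibble with (group, subject, session, run, summaries).
#' @export
process_runs <- function(in_dir, config = protocol_config(), out_csv = NULL) {
  manifest_path <- file.path(in_dir, "manifest.csv")
  if (!file.exists(manifest_path)) {
    stop("no manifest.csv in ", in_dir, call. = FALSE)
  }
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    rec <- read_recording(file.path(in_dir, m$file))
    rec$meta$coupling_true <- m$coupling_true
    cbind(group = m$group, subject = m$subject, session = m$session,
          run = m$run, process_run(rec, config))
  })
  out <- tibble::as_tibble(dplyr::bind_rows(rows))
  if (nrow(out) != nrow(manifest)) {
    stop(sprintf("summary count mismatch: %d runs expected, %d produced",
                 nrow(manifest), nrow(out)), call. = FALSE)
  }
  if (!is.null(out_csv)) utils::write.csv(out, out_csv, row.names = FALSE)
  out
}

#' Fit the trend models for each group of a summary table
#'
#' Runs [fit_trend()] per group for the requested outcome and assembles a
#' flat results table (group, effect, F, df, MSE, p) mirroring the usual
#' mixed-model ANOVA layout, plus the fixed-slope estimates.
#'
#' @param summaries Summary tibble from [process_runs()] or
#'   [run_training()]`$dataset` (or a path to such a CSV).
#' @param outcome Outcome column (default `"band_imcoh"`).
#' @param out_dir Optional directory; when given, the ANOVA table and slope
#'   table are written as CSV and a JSON report.
#' @return List with `trends` (named list of `trend_result` per group),
#'   `anova_table`, `slope_table`.
#' @export
analyze_summaries <- function(summaries, outcome = "band_imcoh",
                              out_dir = NULL) {
  if (is.character(summaries)) {
    summaries <- utils::read.csv(summaries, stringsAsFactors = FALSE)
  }
  groups <- unique(summaries$group)
  trends <- lapply(stats::setNames(groups, groups), function(g) {
    fit_trend(summaries[summaries$group == g, ], outcome)
  })
  anova_table <- dplyr::bind_rows(lapply(groups, function(g) {
    av <- trends[[g]]$anova
    if (is.null(av)) return(NULL)
    dplyr::bind_cols(tibble::tibble(group = g), av)
  }))
  slope_table <- dplyr::bind_rows(lapply(groups, function(g) {
    sl <- trends[[g]]$slopes
    if (is.null(sl)) {
      ts <- trends[[g]]$two_stage
      sl <- tibble::tibble(
        term = c("session", "run"),
        estimate = c(ts$session$mean_slope, ts$run$mean_slope),
        se = c(ts$session$se, ts$run$se))
    }
    dplyr::bind_cols(tibble::tibble(group = g), sl)
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(anova_table, file.path(out_dir, paste0("trend_anova_", outcome, ".csv")),
                     row.names = FALSE)
    utils::write.csv(slope_table, file.path(out_dir, paste0("trend_slopes_", outcome, ".csv")),
                     row.names = FALSE)
    jsonlite::write_json(
      list(outcome = outcome, anova = anova_table, slopes = slope_table),
      file.path(out_dir, paste0("trend_report_", outcome, ".json")),
      dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  list(trends = trends, anova_table = anova_table, slope_table = slope_table)
}

#' Training-curve summaries with within-subject error bars
#'
#' Aggregates a summary table into the two standard training views:
#' by run (within-session changes, averaged over sessions) and by session
#' (between-session changes, averaged over runs), per group, each with
#' Cousineau-Morey standard errors across subjects.
#'
#' @param summaries Summary tibble from [process_runs()].
#' @param outcome Outcome column (default `"band_imcoh"`).
#' @return List of two tibbles, `by_run` and `by_session`, with columns
#'   `group`, the condition (`run` or `session`), `mean`, `se`.
#' @export
training_curves <- function(summaries, outcome = "band_imcoh") {
  curve <- function(cond) {
    dplyr::bind_rows(lapply(unique(summaries$group), function(g) {
      d <- summaries[summaries$group == g, ]
      m <- tapply(d[[outcome]], list(d$subject, d[[cond]]), mean)
      tibble::tibble(group = g,
                     !!cond := as.numeric(colnames(m)),
                     mean = unname(colMeans(m)),
                     se = unname(cousineau_morey_se(m)))
    }))
  }
  list(by_run = curve("run"), by_session = curve("session"))
}

#' Plot training curves
#'
#' Line plots of the by-run and by-session training curves from
#' [training_curves()], with Cousineau-Morey error bars, one colour per
#' group. Requires ggplot2.
#'
#' @param summaries Summary tibble from [process_runs()].
#' @param outcome Outcome column.
#' @return A list of two ggplot objects, `by_run` and `by_session`.
#' @export
plot_training_curves <- function(summaries, outcome = "band_imcoh") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_training_curves requires ggplot2", call. = FALSE)
  }
  curves <- training_curves(summaries, outcome)
  mk <- function(d, xvar, xlab) {
    ggplot2::ggplot(d, ggplot2::aes(x = .data[[xvar]], y = .data$mean,
                                    colour = .data$group)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se),
                             width = 0.15) +
      ggplot2::labs(x = xlab, y = outcome, colour = "group") +
      ggplot2::theme_minimal()
  }
  list(by_run = mk(curves$by_run, "run", "run (1 = baseline)"),
       by_session = mk(curves$by_session, "session", "training session"))
}
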