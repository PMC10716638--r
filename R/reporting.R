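# Figures, the end-to-end pipeline, and report serialisation.

#' Plot fixation-proportion curves
#'
#' Mean curves with transparent standard-error ribbons over the analysis
#' window, one colour per named curve, with an optional vertical marker at
#' a detected divergence onset and a dashed reference line at 0.50.
#'
#' @param ... Named [proportion_curves()] objects (the names label the
#'   legend); alternatively a single named list of them.
#' @param window Window in ms to display.
#' @param onset_ms Optional detected onset to mark; `NA` draws no marker.
#' @return A ggplot object.
#' @export
plot_curves <- function(..., window = c(-1000, 1500), onset_ms = NA) {
  curves <- list(...)
  if (length(curves) == 1 && !inherits(curves[[1]], "proportion_curves") &&
      is.list(curves[[1]])) {
    curves <- curves[[1]]
  }
  if (!length(curves)) stop("no curves to plot", call. = FALSE)
  if (is.null(names(curves)) || any(!nzchar(names(curves)))) {
    names(curves) <- vapply(curves, function(cv) cv$contrast, "")
  }
  df <- dplyr::bind_rows(lapply(names(curves), function(nm) {
    s <- curves[[nm]]$summary
    s$curve <- nm
    s
  }))
  df <- df[df$bin_start_ms >= window[1] & df$bin_start_ms < window[2], ]
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_start_ms,
                                         y = .data$mean,
                                         colour = .data$curve,
                                         fill = .data$curve)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Time from verb onset (ms)",
                  y = "Fixation proportion",
                  colour = NULL, fill = NULL) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
  if (!is.na(onset_ms)) {
    gg <- gg + ggplot2::geom_vline(xintercept = onset_ms,
                                   linetype = "dotted")
  }
  gg
}

# The five analyses of the study design: the egocentric contrast on all,
# mismatch-only and match-only gendered trials, and the target-pair
# contrast on gendered and neutral trials.
study_contrasts <- function() {
  tibble::tibble(
    analysis = c("egocentric_all", "egocentric_mismatch", "egocentric_match",
                 "targets_gendered", "targets_neutral"),
    contrast = c(rep("compatible_vs_incompatible", 3),
                 rep("targets_vs_distractors", 2)),
    subset = c("all_gendered", "gender_mismatch", "gender_match",
               "all_gendered", "neutral")
  )
}

#' Run the full analysis pipeline
#'
#' Executes all five study contrasts (egocentric compatible-vs-incompatible
#' on all, mismatch-only and match-only gendered trials; targets-vs-
#' distractors on gendered and on neutral trials) plus comprehension
#' accuracy, either on supplied files or on a freshly simulated experiment,
#' and optionally writes the JSON report, per-bin CSVs and figures. Reports
#' carry no timestamps or hostnames, so identical inputs give identical
#' reports.
#'
#' @param design A design tibble, or path to a design CSV.
#' @param table A binned fixation table, or path to its CSV. When both
#'   `design` and `table` are `NULL`, an experiment is simulated from
#'   `sim` with seed `seed`.
#' @param sim A [sim_config()] for the simulated-input case.
#' @param seed Root seed for simulation and the bootstrap.
#' @param criterion An [onset_criterion()].
#' @param n_boot Bootstrap resamples per contrast.
#' @param out_dir Optional output directory for `report.json`, per-bin CSVs
#'   and figures.
#' @param make_figures Write one figure per analysis when `out_dir` is set.
#' @return Object of class `analysis_report`: provenance, per-analysis
#'   `divergence_result`s, comprehension accuracy, and the parameter echo.
#' @export
run_pipeline <- function(design = NULL, table = NULL, sim = sim_config(),
                         seed = sim$seed, criterion = onset_criterion(),
                         n_boot = 2000, out_dir = NULL, make_figures = FALSE) {
  if (is.character(design)) design <- read_design(design)
  if (is.character(table)) table <- read_binned_table(table)
  if (is.null(design) && is.null(table)) {
    provenance <- list(source = "simulation", config = unclass(sim),
                       seed = seed)
    design <- build_design(sim, seed = seed)
    table <- simulate_gaze(design, sim, seed = seed + 1L)$table
  } else if (is.null(design) || is.null(table)) {
    stop("supply both design and table, or neither (for simulation)",
         call. = FALSE)
  } else {
    provenance <- list(source = "files", seed = seed)
  }

  plan <- study_contrasts()
  results <- vector("list", nrow(plan))
  names(results) <- plan$analysis
  for (i in seq_len(nrow(plan))) {
    boot <- bootstrap_config(n_boot = n_boot, seed = seed + i)
    results[[i]] <- tryCatch(
      run_contrast(table, plan$contrast[i], plan$subset[i], criterion, boot),
      error = function(e) stop("analysis '", plan$analysis[i], "': ",
                               conditionMessage(e), call. = FALSE))
  }

  report <- structure(
    list(
      provenance = provenance,
      package_version = as.character(utils::packageVersion("gazediv")),
      criterion = unclass(criterion),
      n_boot = n_boot,
      comprehension = comprehension_accuracy(design),
      results = results
    ),
    class = "analysis_report"
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    jsonlite::write_json(report_body(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
    for (nm in names(results)) {
      readr::write_csv(results[[nm]]$bins,
                       file.path(out_dir, paste0("bins_", nm, ".csv")),
                       progress = FALSE)
    }
    if (make_figures) {
      for (i in seq_len(nrow(plan))) {
        sel <- select_trials(table, plan$subset[i])
        spec <- contrast_spec(plan$contrast[i])
        curves <- proportion_curves(sel, spec)
        flipped <- flip_curves(curves)
        labs <- curve_labels(plan$contrast[i])
        args <- stats::setNames(list(curves, flipped), labs)
        gg <- plot_curves(args, onset_ms = results[[i]]$onset_ms)
        ggplot2::ggsave(file.path(out_dir, paste0("fig_", plan$analysis[i], ".pdf")),
                        gg, width = 7, height = 4.5)
      }
    }
  }
  report
}

curve_labels <- function(contrast_name) {
  if (contrast_name == "compatible_vs_incompatible") {
    c("participant-compatible target", "participant-incompatible target")
  } else {
    c("targets", "distractors")
  }
}

# The complementary curve of a contrast (B vs A): proportions mirror around
# 0.5 where defined, so the pair plots like the study's two-line figures.
flip_curves <- function(curves) {
  flipped <- curves
  flipped$P <- 1 - curves$P
  flipped$summary <- summarise_curves(flipped$P, curves$bins)
  flipped$contrast <- paste0(curves$contrast, " (complement)")
  flipped
}

# Plain-list body used for JSON serialisation and report validation.
report_body <- function(report) {
  list(
    provenance = report$provenance,
    package_version = report$package_version,
    criterion = report$criterion,
    n_boot = report$n_boot,
    comprehension_accuracy = report$comprehension$overall,
    results = lapply(report$results, function(r) {
      list(
        contrast = r$contrast,
        subset = r$subset,
        onset_ms = r$onset_ms,
        mean_divergence_ms = r$mean_divergence_ms,
        ci_low_ms = r$ci_low_ms,
        ci_high_ms = r$ci_high_ms,
        detection_rate = r$detection_rate,
        n_trials = as.list(r$n_trials)
      )
    })
  )
}

#' Validate the structure of an analysis report
#'
#' Structural schema check: required top-level fields, the five named
#' analyses, and per-analysis numeric fields (NA allowed where no onset was
#' detected).
#'
#' @param report An `analysis_report` or the parsed JSON body.
#' @return `TRUE` invisibly; errors name the first violated field.
#' @export
validate_report <- function(report) {
  body <- if (inherits(report, "analysis_report")) report_body(report) else report
  need <- c("provenance", "package_version", "criterion", "n_boot",
            "comprehension_accuracy", "results")
  missing <- setdiff(need, names(body))
  if (length(missing)) {
    stop("report is missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  want <- study_contrasts()$analysis
  missing <- setdiff(want, names(body$results))
  if (length(missing)) {
    stop("report is missing analysis result(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (nm in want) {
    r <- body$results[[nm]]
    for (f in c("contrast", "subset", "onset_ms", "mean_divergence_ms",
                "ci_low_ms", "ci_high_ms", "detection_rate")) {
      if (!f %in% names(r)) {
        stop("analysis '", nm, "' is missing field '", f, "'", call. = FALSE)
      }
    }
    dr <- r$detection_rate
    if (!is.numeric(dr) || is.na(dr) || dr < 0 || dr > 1) {
      stop("analysis '", nm, "' has invalid detection_rate", call. = FALSE)
    }
  }
  acc <- body$comprehension_accuracy
  if (!is.numeric(acc) || is.na(acc) || acc < 0 || acc > 1) {
    stop("comprehension_accuracy must lie in [0, 1]", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("<analysis_report>", x$provenance$source, "data;",
      sprintf("comprehension accuracy %.1f%%\n", 100 * x$comprehension$overall))
  for (nm in names(x$results)) {
    r <- x$results[[nm]]
    if (is.na(r$onset_ms)) {
      cat(sprintf("  %-20s no divergence point (detection rate %.3f)\n",
                  nm, r$detection_rate))
    } else {
      cat(sprintf("  %-20s onset %g ms; bootstrap mean %.0f ms, CI [%g, %g]\n",
                  nm, r$onset_ms, r$mean_divergence_ms, r$ci_low_ms,
                  r$ci_high_ms))
    }
  }
  invisible(x)
}
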