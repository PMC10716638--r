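#' @importFrom rlang .data
#' @importFrom stats rbinom rnorm runif sd setNames quantile pt
#' @importFrom utils head
NULL

# Bin lattice helpers -------------------------------------------------------

#' Left edges of the 50 ms bin lattice for an analysis window
#'
#' Bins are half-open intervals `[start, start + bin_ms)` identified by their
#' left edge in ms relative to verb onset. The default window spans 1000 ms
#' before to 1500 ms after verb onset, i.e. edges -1000, -950, ..., +1450.
#'
#' @param window Length-2 numeric, window in ms relative to verb onset.
#' @param bin_ms Bin width in ms.
#' @return Integer vector of bin left edges.
#' @export
bin_lattice <- function(window = c(-1000, 1500), bin_ms = 50) {
  stopifnot(length(window) == 2, window[1] < window[2], bin_ms > 0)
  if ((window[2] - window[1]) %% bin_ms != 0 || window[1] %% bin_ms != 0) {
    stop("analysis window [", window[1], ", ", window[2],
         "] does not sit on the ", bin_ms, " ms bin lattice", call. = FALSE)
  }
  as.integer(seq(window[1], window[2] - bin_ms, by = bin_ms))
}

gendered_cells <- function() {
  tibble::tibble(
    role       = c("target", "target", "distractor", "distractor"),
    stereotype = c("masculine", "feminine", "masculine", "feminine")
  )
}

# Fixation reports -----------------------------------------------------------

fixation_report_cols <- c("participant", "trial", "start", "end", "x", "y", "blink")

#' Read a fixation report
#'
#' Reads a delimited fixation report with one row per fixation (or blink)
#' event. Required columns: `participant`, `trial`, `start`, `end` (trial
#' time in ms), `x`, `y` (screen px, origin top-left), `blink` (0/1). Blink
#' rows carry no usable coordinates and are never assigned to an interest
#' area.
#'
#' @param path Path to a comma-delimited UTF-8 file with a header row.
#' @return A tibble of fixation events ordered by (participant, trial, start).
#' @export
read_fixation_report <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(fixation_report_cols, names(raw))
  if (length(missing)) {
    stop("fixation report is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  num_cols <- c("start", "end", "x", "y", "blink")
  for (col in num_cols) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !(is.na(raw[[col]]) & col %in% c("x", "y")))
    if (length(bad)) {
      stop("non-numeric value in column '", col, "' at data line ",
           bad[1], ": '", raw[[col]][bad[1]], "'", call. = FALSE)
    }
    raw[[col]] <- vals
  }
  events <- tibble::tibble(
    participant_id = raw$participant,
    trial_id       = raw$trial,
    start_ms       = raw$start,
    end_ms         = raw$end,
    x              = raw$x,
    y              = raw$y,
    is_blink       = raw$blink != 0
  )
  bad <- which(events$end_ms <= events$start_ms)
  if (length(bad)) {
    stop("fixation event at data line ", bad[1],
         " has end <= start (", events$end_ms[bad[1]], " <= ",
         events$start_ms[bad[1]], ")", call. = FALSE)
  }
  dplyr::arrange(events, .data$participant_id, .data$trial_id, .data$start_ms)
}

#' Write a fixation report
#'
#' Inverse of [read_fixation_report()]; round-trips losslessly.
#'
#' @param events Tibble of fixation events.
#' @param path Output path.
#' @export
write_fixation_report <- function(events, path) {
  out <- tibble::tibble(
    participant = events$participant_id,
    trial       = events$trial_id,
    start       = events$start_ms,
    end         = events$end_ms,
    x           = events$x,
    y           = events$y,
    blink       = as.integer(events$is_blink)
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# Design tables --------------------------------------------------------------

design_scalar_cols <- c(
  "participant_id", "participant_gender", "list_id", "item_id", "item_type",
  "speaker_gender", "referent_stereotype", "verb_onset_ms", "verb_offset_ms",
  "target_onset_ms", "sentence_duration_ms", "comprehension_correct"
)
ia_field_cols <- c("label", "role", "stereotype", "center_x", "center_y",
                   "width", "height")

ia_cols <- function() {
  unlist(lapply(1:4, function(i) paste0("ia", i, "_", ia_field_cols)))
}

#' Validate a trial design table
#'
#' Checks the per-trial invariants: timing order
#' `verb_onset < verb_offset < target_onset < sentence_duration`, positive
#' interest-area sizes, and -- on gendered trials -- that the four interest
#' areas cover exactly the four (role x stereotype) cells
#' {target, distractor} x {masculine, feminine}.
#'
#' @param design A design tibble as returned by [read_design()] or
#'   [build_design()].
#' @return The design, invisibly; errors describe the first offending trial.
#' @export
validate_design <- function(design) {
  missing <- setdiff(c(design_scalar_cols, ia_cols()), names(design))
  if (length(missing)) {
    stop("design table is missing column(s): ",
         paste(head(missing, 8), collapse = ", "), call. = FALSE)
  }
  bad <- which(!(design$verb_onset_ms < design$verb_offset_ms &
                 design$verb_offset_ms < design$target_onset_ms &
                 design$target_onset_ms < design$sentence_duration_ms))
  if (length(bad)) {
    stop("design row ", bad[1],
         ": timing must satisfy verb_onset < verb_offset < target_onset ",
         "< sentence_duration", call. = FALSE)
  }
  for (i in 1:4) {
    w <- design[[paste0("ia", i, "_width")]]
    h <- design[[paste0("ia", i, "_height")]]
    if (any(w <= 0 | h <= 0)) {
      stop("interest area ", i, " has non-positive width/height", call. = FALSE)
    }
  }
  gendered <- which(design$item_type == "gendered")
  if (length(gendered)) {
    if (!all(design$referent_stereotype[gendered] %in% c("masculine", "feminine"))) {
      stop("gendered trials must have referent_stereotype masculine/feminine",
           call. = FALSE)
    }
    cells <- gendered_cells()
    want <- sort(paste(cells$role, cells$stereotype))
    for (r in gendered) {
      got <- sort(paste(
        unlist(design[r, paste0("ia", 1:4, "_role")]),
        unlist(design[r, paste0("ia", 1:4, "_stereotype")])
      ))
      if (!identical(got, want)) {
        stop("gendered trial row ", r, " does not have exactly one interest ",
             "area per (role x stereotype) cell; got: ",
             paste(got, collapse = ", "), call. = FALSE)
      }
    }
  }
  invisible(design)
}

#' Read a trial design table
#'
#' One row per trial. Scalar columns describe the participant, list, item,
#' condition, and critical-word timings; the four interest areas are
#' flattened as labelled column groups `ia1_*` ... `ia4_*` with fields
#' label, role, stereotype, center_x, center_y, width, height.
#'
#' @param path Path to a comma-delimited design file.
#' @return A validated design tibble.
#' @export
read_design <- function(path) {
  design <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  design$comprehension_correct <- as.logical(design$comprehension_correct)
  validate_design(design)
  design
}

#' Write a trial design table
#'
#' @param design Design tibble.
#' @param path Output path.
#' @export
write_design <- function(design, path) {
  validate_design(design)
  out <- design
  out$comprehension_correct <- as.integer(out$comprehension_correct)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Interest areas of one design row in long form
#'
#' @param trial One row of a design tibble.
#' @return Tibble with one row per interest area.
#' @export
trial_interest_areas <- function(trial) {
  stopifnot(nrow(trial) == 1)
  one <- function(i) {
    tibble::tibble(
      label      = trial[[paste0("ia", i, "_label")]],
      role       = trial[[paste0("ia", i, "_role")]],
      stereotype = trial[[paste0("ia", i, "_stereotype")]],
      center_x   = trial[[paste0("ia", i, "_center_x")]],
      center_y   = trial[[paste0("ia", i, "_center_y")]],
      width      = trial[[paste0("ia", i, "_width")]],
      height     = trial[[paste0("ia", i, "_height")]]
    )
  }
  dplyr::bind_rows(lapply(1:4, one))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Binned fixation tables ------------------------------------------------------

binned_cols <- c(
  "participant_id", "participant_gender", "trial_id", "item_type",
  "speaker_gender", "referent_stereotype", "bin_start_ms", "object_label",
  "role", "stereotype", "fixated"
)

#' Validate a binned fixation table
#'
#' Enforces the table invariants: bins on the 50 ms lattice of `window`,
#' exactly four object rows per (participant, trial, bin), no duplicate
#' (participant, trial, bin, object) rows, and at most one object fixated
#' per (participant, trial, bin) -- gaze is mutually exclusive.
#'
#' @param table Binned fixation tibble.
#' @param window,bin_ms Expected bin lattice.
#' @return The table, invisibly.
#' @export
validate_binned_table <- function(table, window = c(-1000, 1500), bin_ms = 50) {
  missing <- setdiff(binned_cols, names(table))
  if (length(missing)) {
    stop("binned table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(table) == 0) return(invisible(table))
  lattice <- bin_lattice(window, bin_ms)
  off <- setdiff(unique(table$bin_start_ms), lattice)
  if (length(off)) {
    stop("bin_start_ms value(s) off the ", bin_ms, " ms lattice of [",
         window[1], ", ", window[2], "): ",
         paste(head(off, 5), collapse = ", "), call. = FALSE)
  }
  if (!all(table$fixated %in% c(0L, 1L))) {
    stop("fixated must be 0/1", call. = FALSE)
  }
  key <- paste(table$participant_id, table$trial_id, table$bin_start_ms)
  okey <- paste(key, table$object_label)
  if (anyDuplicated(okey)) {
    stop("duplicate (participant, trial, bin, object) row(s), e.g. ",
         okey[which(duplicated(okey))[1]], call. = FALSE)
  }
  per_bin <- table(key)
  if (any(per_bin != 4L)) {
    bad <- names(per_bin)[which(per_bin != 4L)[1]]
    stop("every (trial, bin) needs exactly four object rows; (", bad,
         ") has ", per_bin[bad], call. = FALSE)
  }
  nfix <- rowsum(table$fixated, key)
  if (any(nfix > 1L)) {
    bad <- rownames(nfix)[which(nfix > 1L)[1]]
    stop("more than one object fixated in bin (", bad,
         "): gaze must be mutually exclusive", call. = FALSE)
  }
  invisible(table)
}

#' Write / read a binned fixation table
#'
#' Lossless CSV round trip with deterministic row order
#' (participant, trial, bin, object).
#'
#' @param table Binned fixation tibble satisfying the table invariants.
#' @param path File path.
#' @param window,bin_ms Expected bin lattice.
#' @return `read_binned_table()` returns the validated tibble.
#' @export
write_binned_table <- function(table, path, window = c(-1000, 1500), bin_ms = 50) {
  validate_binned_table(table, window, bin_ms)
  out <- dplyr::arrange(table, .data$participant_id, .data$trial_id,
                        .data$bin_start_ms, .data$object_label)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_binned_table
#' @export
read_binned_table <- function(path, window = c(-1000, 1500), bin_ms = 50) {
  table <- readr::read_csv(
    path,
    col_types = readr::cols(
      bin_start_ms = readr::col_integer(),
      fixated = readr::col_integer(),
      .default = readr::col_character()
    ),
    progress = FALSE
  )
  validate_binned_table(table, window, bin_ms)
  table
}
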