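# Binomial bin coding, role mapping, trial selection, proportion curves.

#' Code fixation events binomially into 50 ms bins
#'
#' Time-locks each trial's fixation events to its verb onset and codes, for
#' each 50 ms bin and each of the four interest areas, whether the gaze was
#' inside that area for a strict majority of the bin (> 25 ms of a 50 ms
#' bin; ties broken to 0). Blinks and gaze outside every interest area
#' contribute 0 to all objects but remain in the data as all-zero bins.
#'
#' @param events Fixation events as from [read_fixation_report()].
#' @param design Trial design as from [read_design()] or [build_design()];
#'   events and design are joined on (participant_id, trial_id).
#' @param window,bin_ms Analysis window in ms relative to verb onset and bin
#'   width.
#' @return A binned fixation table (see [validate_binned_table()]).
#' @export
bin_fixations <- function(events, design, window = c(-1000, 1500), bin_ms = 50) {
  validate_design(design)
  lattice <- bin_lattice(window, bin_ms)
  dkey <- paste(design$participant_id, design$trial_id)
  ekey <- paste(events$participant_id, events$trial_id)
  orphans <- setdiff(unique(ekey), dkey)
  if (length(orphans)) {
    stop("fixation events reference trial(s) absent from the design: ",
         paste(head(orphans, 5), collapse = "; "), call. = FALSE)
  }

  rows <- vector("list", nrow(design))
  for (r in seq_len(nrow(design))) {
    trial <- design[r, ]
    ias <- trial_interest_areas(trial)
    ev <- events[ekey == dkey[r] & !events$is_blink, ]
    # per-object per-bin gaze occupancy in ms
    occ <- matrix(0, nrow = length(lattice), ncol = 4)
    if (nrow(ev)) {
      s_rel <- ev$start_ms - trial$verb_onset_ms
      e_rel <- ev$end_ms - trial$verb_onset_ms
      inside <- function(x, y, ia) {
        !is.na(x) & !is.na(y) &
          abs(x - ia$center_x) <= ia$width / 2 &
          abs(y - ia$center_y) <= ia$height / 2
      }
      for (k in seq_len(nrow(ev))) {
        obj <- which(vapply(seq_len(4), function(i)
          inside(ev$x[k], ev$y[k], ias[i, ]), logical(1)))
        if (!length(obj)) next
        overlap <- pmin(e_rel[k], lattice + bin_ms) - pmax(s_rel[k], lattice)
        occ[, obj[1]] <- occ[, obj[1]] + pmax(overlap, 0)
      }
    }
    fix <- (occ > bin_ms / 2) * 1L
    rows[[r]] <- tibble::tibble(
      participant_id      = trial$participant_id,
      participant_gender  = trial$participant_gender,
      trial_id            = trial$trial_id,
      item_type           = trial$item_type,
      speaker_gender      = trial$speaker_gender,
      referent_stereotype = trial$referent_stereotype,
      bin_start_ms        = rep(lattice, times = 4),
      object_label        = rep(ias$label, each = length(lattice)),
      role                = rep(ias$role, each = length(lattice)),
      stereotype          = rep(ias$stereotype, each = length(lattice)),
      fixated             = as.integer(fix)
    )
  }
  table <- dplyr::bind_rows(rows)
  validate_binned_table(table, window, bin_ms)
  table
}

#' Map a trial's objects to analysis roles and compatibility flags
#'
#' On gendered trials each object is a target or distractor with a masculine
#' or feminine stereotype. An object is participant-compatible when its
#' stereotype matches the participant's gender (masculine objects for male
#' participants, feminine for female) and speaker-compatible when it matches
#' the speaker's gender; the two flags are independent. Neutral trials get
#' `NA` compatibility, which is not an error.
#'
#' @param trial One design row.
#' @param participant_gender "male" or "female"; defaults to the trial's own.
#' @return Tibble: object_label, role, stereotype, participant_compatible,
#'   speaker_compatible.
#' @export
assign_roles <- function(trial, participant_gender = trial$participant_gender) {
  ias <- trial_interest_areas(trial)
  out <- tibble::tibble(
    object_label = ias$label,
    role         = ias$role,
    stereotype   = ias$stereotype
  )
  if (trial$item_type == "gendered") {
    out$participant_compatible <- stereotype_matches(out$stereotype, participant_gender)
    out$speaker_compatible <- stereotype_matches(out$stereotype, trial$speaker_gender)
  } else {
    out$participant_compatible <- NA
    out$speaker_compatible <- NA
  }
  out
}

stereotype_matches <- function(stereotype, gender) {
  (stereotype == "masculine" & gender == "male") |
    (stereotype == "feminine" & gender == "female")
}

#' Select the trial subset for an analysis
#'
#' Subsets: `all_gendered` (every gendered trial), `gender_match`
#' (participant and speaker share a gender), `gender_mismatch` (they
#' differ), `neutral`. Match and mismatch partition the gendered trials.
#'
#' @param table Binned fixation table.
#' @param subset One of `"all_gendered"`, `"gender_match"`,
#'   `"gender_mismatch"`, `"neutral"`.
#' @return The filtered table, with attribute `n_trials` = named count of
#'   retained trials per participant.
#' @export
select_trials <- function(table,
                          subset = c("all_gendered", "gender_match",
                                     "gender_mismatch", "neutral")) {
  subset <- match.arg(subset)
  keep <- switch(subset,
    all_gendered    = table$item_type == "gendered",
    gender_match    = table$item_type == "gendered" &
                      table$participant_gender == table$speaker_gender,
    gender_mismatch = table$item_type == "gendered" &
                      table$participant_gender != table$speaker_gender,
    neutral         = table$item_type == "neutral"
  )
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("subset '", subset, "' selects no trials", call. = FALSE)
  }
  counts <- tapply(out$trial_id, out$participant_id,
                   function(x) length(unique(x)))
  attr(out, "n_trials") <- counts
  out
}

# Contrasts -------------------------------------------------------------------

#' Define a fixation contrast
#'
#' A contrast names two disjoint object sets A and B; curves report the
#' proportion of looks to A out of looks to A or B, so 0.50 is the exact
#' null. Built-in contrasts:
#' \describe{
#'   \item{`targets_vs_distractors`}{A = both targets, B = both distractors.}
#'   \item{`compatible_vs_incompatible`}{A = the target whose stereotype
#'     matches the participant's gender, B = the other target (gendered
#'     trials only).}
#' }
#'
#' @param name Contrast name.
#' @return An object of class `contrast_spec`.
#' @export
contrast_spec <- function(name = c("targets_vs_distractors",
                                   "compatible_vs_incompatible")) {
  name <- match.arg(name)
  spec <- switch(name,
    targets_vs_distractors = list(
      set_a = function(tab) tab$role == "target",
      set_b = function(tab) tab$role == "distractor",
      default_subset = "all_gendered"
    ),
    compatible_vs_incompatible = list(
      set_a = function(tab) tab$role == "target" &
        stereotype_matches(tab$stereotype, tab$participant_gender),
      set_b = function(tab) tab$role == "target" &
        !stereotype_matches(tab$stereotype, tab$participant_gender) &
        tab$stereotype %in% c("masculine", "feminine"),
      default_subset = "all_gendered"
    )
  )
  structure(c(list(name = name), spec), class = "contrast_spec")
}

# Per-trial A/B look counts on the bin lattice, as matrices used by both the
# observed curves and the bootstrap resampler.
contrast_counts <- function(table, contrast, window = c(-1000, 1500), bin_ms = 50) {
  stopifnot(inherits(contrast, "contrast_spec"))
  lattice <- bin_lattice(window, bin_ms)
  in_a <- contrast$set_a(table)
  in_b <- contrast$set_b(table)
  if (any(in_a & in_b)) stop("contrast sets A and B overlap", call. = FALSE)

  trial_key <- paste(table$participant_id, table$trial_id, sep = "\r")
  trials <- !duplicated(trial_key)
  tkeys <- trial_key[trials]
  n_tr <- length(tkeys)
  ti <- match(trial_key, tkeys)
  if (any(rowsum(as.integer(in_a), ti) == 0L) ||
      any(rowsum(as.integer(in_b), ti) == 0L)) {
    stop("contrast '", contrast$name,
         "' is empty on one side for some selected trial", call. = FALSE)
  }
  bi <- match(table$bin_start_ms, lattice)
  if (anyNA(bi)) stop("table bins off the analysis lattice", call. = FALSE)

  acc <- function(mask) {
    m <- matrix(0L, n_tr, length(lattice))
    sel <- which(mask & table$fixated == 1L)
    if (length(sel)) {
      idx <- cbind(ti[sel], bi[sel])
      # at most one object fixated per (trial, bin), so plain assignment is a sum
      m[idx] <- m[idx] + 1L
    }
    m
  }
  meta <- table[trials, c("participant_id", "item_type"), drop = FALSE]
  list(
    A = acc(in_a), B = acc(in_b), bins = lattice,
    participant = meta$participant_id,
    stratum = paste(meta$participant_id, meta$item_type, sep = "\r"),
    participants = unique(meta$participant_id)
  )
}

# Pool per-trial counts to per-participant proportion matrix P (participants
# x bins); denominator "ab" uses looks to A or B only, "all" uses all trials.
pool_proportions <- function(counts, denominator = c("ab", "all")) {
  denominator <- match.arg(denominator)
  parts <- counts$participants
  nb <- length(counts$bins)
  P <- matrix(NA_real_, length(parts), nb,
              dimnames = list(parts, counts$bins))
  N <- matrix(0L, length(parts), nb, dimnames = dimnames(P))
  for (i in seq_along(parts)) {
    rows <- which(counts$participant == parts[i])
    a <- colSums(counts$A[rows, , drop = FALSE])
    b <- colSums(counts$B[rows, , drop = FALSE])
    denom <- if (denominator == "ab") a + b else rep(length(rows), nb)
    P[i, ] <- ifelse(denom > 0, a / denom, NA_real_)
    N[i, ] <- denom
  }
  list(P = P, N = N)
}

#' Fixation-proportion curves for a contrast
#'
#' For each participant and 50 ms bin, computes the proportion of looks to
#' contrast set A out of looks to A or B, pooling the participant's selected
#' trials (items are aggregated over). The per-bin grand mean and standard
#' error (sd / sqrt(n participants)) summarise the group curve; bins where a
#' participant has no informative looks are undefined for that participant
#' and drop out of that bin's n.
#'
#' @param table Binned fixation table, already restricted with
#'   [select_trials()].
#' @param contrast A [contrast_spec()] or contrast name.
#' @param window,bin_ms Bin lattice of the table.
#' @param denominator `"ab"` (default; looks to A or B, so 0.50 is the exact
#'   null) or `"all"` (all selected trials, counting bins with no A/B look
#'   in the denominator).
#' @return Object of class `proportion_curves`: participant x bin matrix
#'   `P`, informative-count matrix `N`, bin edges, and a `summary` tibble
#'   (bin_start_ms, mean, se, n).
#' @export
proportion_curves <- function(table, contrast, window = c(-1000, 1500),
                              bin_ms = 50, denominator = c("ab", "all")) {
  if (is.character(contrast)) contrast <- contrast_spec(contrast)
  counts <- contrast_counts(table, contrast, window, bin_ms)
  pooled <- pool_proportions(counts, denominator)
  structure(
    list(
      P = pooled$P, N = pooled$N, bins = counts$bins,
      contrast = contrast$name,
      summary = summarise_curves(pooled$P, counts$bins)
    ),
    class = "proportion_curves"
  )
}

summarise_curves <- function(P, bins) {
  n <- colSums(!is.na(P))
  m <- colMeans(P, na.rm = TRUE)
  s <- apply(P, 2, sd, na.rm = TRUE)
  tibble::tibble(
    bin_start_ms = bins,
    mean = unname(ifelse(n > 0, m, NA_real_)),
    se = unname(ifelse(n > 1, s / sqrt(n), NA_real_)),
    n = as.integer(unname(n))
  )
}

#' @export
print.proportion_curves <- function(x, ...) {
  cat("<proportion_curves> contrast:", x$contrast, "\n",
      nrow(x$P), "participants x", length(x$bins), "bins [",
      min(x$bins), ",", max(x$bins) + diff(x$bins[1:2]), ") ms\n")
  invisible(x)
}

#' Comprehension-question accuracy
#'
#' @param design Trial design with `comprehension_correct` flags.
#' @return List with `overall` (proportion correct in \[0, 1\]) and
#'   `by_participant` tibble.
#' @export
comprehension_accuracy <- function(design) {
  if (anyNA(design$comprehension_correct)) {
    bad <- design$trial_id[is.na(design$comprehension_correct)]
    stop("comprehension_correct missing for trial(s): ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  by_p <- dplyr::summarise(
    dplyr::group_by(design, .data$participant_id),
    accuracy = mean(.data$comprehension_correct), .groups = "drop"
  )
  list(overall = mean(design$comprehension_correct), by_participant = by_p)
}
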