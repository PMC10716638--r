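# Synthetic experiment generator: counterbalanced 2x2 stereotype design plus
# a Markov gaze process with a known true divergence time.

#' Simulation configuration
#'
#' Defines a synthetic visual-world experiment mirroring the reference
#' design: 32 participants (half male) over 4 counterbalanced lists, 56
#' trials each (28 gendered crossing speaker gender x referent stereotype
#' with 7 trials per cell, plus 28 neutral), fixations over 50 ms bins from
#' 1000 ms before to 1500 ms after verb onset.
#'
#' Gaze is a per-trial Markov chain over the four objects plus a "none"
#' state. Each bin the current state persists with probability `stay_prob`;
#' otherwise a new state is drawn from the current mixture: `p_offscreen`
#' to none, and of the on-screen mass a target-pair share that equals
#' `baseline_pref` before `true_onset_ms` and ramps linearly to
#' `asymptote_pref` over `ramp_duration_ms`. Within the target pair the
#' participant-compatible target's share is 0.5 plus `egocentric_effect`
#' scaled by the same ramp (0 reproduces the observed null of no egocentric
#' preference).
#'
#' @param n_participants Number of participants (half male, half female);
#'   must be divisible by `n_lists`.
#' @param n_lists Number of counterbalanced stimulus lists.
#' @param n_gendered,n_neutral Trials per participant of each item type;
#'   `n_gendered` must be divisible by 4 (the speaker x referent cells).
#' @param window,bin_ms Bin lattice in ms relative to verb onset.
#' @param baseline_pref Pre-onset P(looks to the target pair | on-screen).
#' @param true_onset_ms First bin (ms after verb onset) at which the target
#'   mixture departs from baseline; the ground-truth divergence point.
#' @param ramp_duration_ms Time over which the mixture ramps from baseline
#'   to asymptote.
#' @param asymptote_pref Asymptotic P(looks to targets | on-screen); 0.5
#'   means no effect.
#' @param stay_prob Per-bin probability of keeping the current gaze state
#'   (0.85 per 50 ms bin gives a mean dwell near 300 ms).
#' @param p_offscreen Probability that a refreshed gaze state is "none"
#'   (blink or gaze outside all interest areas).
#' @param egocentric_effect Extra within-target share for the
#'   participant-compatible target at asymptote (0 = no egocentric
#'   prediction).
#' @param comprehension_error_rate Per-trial probability of an incorrect
#'   comprehension answer.
#' @param seed Default RNG seed used when a function is not given one.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 32,
                       n_lists = 4,
                       n_gendered = 28,
                       n_neutral = 28,
                       window = c(-1000, 1500),
                       bin_ms = 50,
                       baseline_pref = 0.5,
                       true_onset_ms = 500,
                       ramp_duration_ms = 100,
                       asymptote_pref = 0.75,
                       stay_prob = 0.85,
                       p_offscreen = 0.10,
                       egocentric_effect = 0,
                       comprehension_error_rate = 0.01,
                       seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_lists = as.integer(n_lists),
    n_gendered = as.integer(n_gendered),
    n_neutral = as.integer(n_neutral),
    window = window, bin_ms = bin_ms,
    baseline_pref = baseline_pref,
    true_onset_ms = true_onset_ms,
    ramp_duration_ms = ramp_duration_ms,
    asymptote_pref = asymptote_pref,
    stay_prob = stay_prob,
    p_offscreen = p_offscreen,
    egocentric_effect = egocentric_effect,
    comprehension_error_rate = comprehension_error_rate,
    seed = as.integer(seed)
  )
  probs <- c(cfg$baseline_pref, cfg$asymptote_pref, cfg$stay_prob,
             cfg$p_offscreen, cfg$comprehension_error_rate)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$asymptote_pref < 0.5) {
    stop("asymptote_pref must be >= 0.5", call. = FALSE)
  }
  if (cfg$egocentric_effect < 0 || cfg$egocentric_effect > 0.5) {
    stop("egocentric_effect must lie in [0, 0.5]", call. = FALSE)
  }
  if (cfg$n_participants %% cfg$n_lists != 0) {
    stop("n_participants must be divisible by n_lists", call. = FALSE)
  }
  if (cfg$n_participants %% 2 != 0) {
    stop("n_participants must be even (half male, half female)", call. = FALSE)
  }
  if (cfg$n_gendered %% 4 != 0) {
    stop("n_gendered must be divisible by the 4 speaker x referent cells",
         call. = FALSE)
  }
  if (cfg$true_onset_ms %% cfg$bin_ms != 0) {
    stop("true_onset_ms must sit on the bin lattice", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# Sentence-timing statistics (ms): per-speaker means/SDs of sentence
# duration, verb onset/offset and target onset matching the recorded
# stimulus set that the simulator emulates. Durations are generated as
# verb onset + verb length + offset-to-target gap + target-to-end gap so
# the timing order invariant holds by construction.
timing_stats <- list(
  male   = list(verb_onset = c(1621, 414), verb_len = c(360, 60),
                offset_to_target = c(761, 80), target_to_end = c(663, 80)),
  female = list(verb_onset = c(1532, 357), verb_len = c(375, 60),
                offset_to_target = c(789, 80), target_to_end = c(656, 80))
)

rtrunc_norm <- function(n, mean, sd, lower) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lower)) {
    x[bad] <- rnorm(sum(bad), mean[bad], sd[bad])
  }
  x
}

# Four corner positions on a 1024 x 768 screen for 300 x 300 interest areas.
corner_positions <- function() {
  tibble::tibble(
    center_x = c(212, 812, 212, 812),
    center_y = c(184, 184, 584, 584)
  )
}

#' Build a counterbalanced trial design
#'
#' Emits one row per (participant, trial). Participants are split evenly
#' over the lists with genders balanced within list; a Latin-square rotation
#' assigns each gendered item one of the four speaker-gender x
#' referent-stereotype versions per list, giving exactly
#' `n_gendered / 4` trials per cell for every participant. Verb and target
#' timings are drawn per trial from truncated normals matching the stimulus
#' statistics the generator emulates, and always satisfy
#' verb onset < verb offset < target onset < sentence end.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return A validated design tibble (see [validate_design()]).
#' @export
build_design <- function(config = sim_config(), seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  force(config)
  set.seed(seed)
  n_p <- config$n_participants
  lists <- ((seq_len(n_p) - 1) %% config$n_lists) + 1
  genders <- ifelse(((seq_len(n_p) - 1) %/% config$n_lists) %% 2 == 0,
                    "male", "female")
  cells <- tibble::tibble(
    speaker_gender      = c("male", "male", "female", "female"),
    referent_stereotype = c("masculine", "feminine", "feminine", "masculine")
  )
  corners <- corner_positions()

  per_participant <- function(p) {
    list_id <- lists[p]
    pid <- sprintf("p%02d", p)
    n_g <- config$n_gendered
    n_n <- config$n_neutral
    version <- ((seq_len(n_g) + list_id) %% 4) + 1
    neutral_speaker <- ifelse((seq_len(n_n) + list_id) %% 2 == 0,
                              "male", "female")
    item_type <- c(rep("gendered", n_g), rep("neutral", n_n))
    speaker <- c(cells$speaker_gender[version], neutral_speaker)
    referent <- c(cells$referent_stereotype[version], rep("n/a", n_n))
    item_id <- c(sprintf("g%02d", seq_len(n_g)), sprintf("n%02d", seq_len(n_n)))
    n_t <- n_g + n_n

    ts <- lapply(speaker, function(sp) timing_stats[[sp]])
    verb_onset <- round(rtrunc_norm(n_t, vapply(ts, function(t) t$verb_onset[1], 0),
                                    vapply(ts, function(t) t$verb_onset[2], 0), 200))
    verb_len <- round(rtrunc_norm(n_t, vapply(ts, function(t) t$verb_len[1], 0),
                                  vapply(ts, function(t) t$verb_len[2], 0), 80))
    to_target <- round(rtrunc_norm(n_t, vapply(ts, function(t) t$offset_to_target[1], 0),
                                   vapply(ts, function(t) t$offset_to_target[2], 0), 80))
    to_end <- round(rtrunc_norm(n_t, vapply(ts, function(t) t$target_to_end[1], 0),
                                vapply(ts, function(t) t$target_to_end[2], 0), 80))

    d <- tibble::tibble(
      participant_id = pid,
      participant_gender = genders[p],
      list_id = list_id,
      item_id = item_id,
      trial_id = sprintf("t%02d", seq_len(n_t)),
      item_type = item_type,
      speaker_gender = speaker,
      referent_stereotype = referent,
      verb_onset_ms = verb_onset,
      verb_offset_ms = verb_onset + verb_len,
      target_onset_ms = verb_onset + verb_len + to_target,
      sentence_duration_ms = verb_onset + verb_len + to_target + to_end,
      comprehension_correct = runif(n_t) >= config$comprehension_error_rate
    )
    # four interest areas per trial, corner placement shuffled per trial
    lab_g <- c("target_masc", "target_fem", "distr_masc", "distr_fem")
    lab_n <- c("target_1", "target_2", "distr_1", "distr_2")
    roles <- c("target", "target", "distractor", "distractor")
    stereo_g <- c("masculine", "feminine", "masculine", "feminine")
    slots <- t(vapply(seq_len(n_t), function(r) sample.int(4), integer(4)))
    for (i in 1:4) {
      d[[paste0("ia", i, "_label")]] <-
        ifelse(d$item_type == "gendered", lab_g[i], lab_n[i])
      d[[paste0("ia", i, "_role")]] <- roles[i]
      d[[paste0("ia", i, "_stereotype")]] <-
        ifelse(d$item_type == "gendered", stereo_g[i], "neutral")
      d[[paste0("ia", i, "_center_x")]] <- corners$center_x[slots[, i]]
      d[[paste0("ia", i, "_center_y")]] <- corners$center_y[slots[, i]]
      d[[paste0("ia", i, "_width")]] <- 300
      d[[paste0("ia", i, "_height")]] <- 300
    }
    d
  }

  design <- dplyr::bind_rows(lapply(seq_len(n_p), per_participant))
  validate_design(design)
  design
}

# Target-pair mixture share at bin left edge t (ms relative to verb onset):
# baseline before the true onset, then a linear ramp that reaches asymptote
# after ramp_duration_ms. The ramp fraction at the onset bin itself is
# bin_ms / ramp_duration, so the mixture departs from baseline AT the onset
# bin, making the ground-truth divergence bin unambiguous.
ramp_fraction <- function(t, config) {
  ifelse(t < config$true_onset_ms, 0,
         pmin(1, (t - config$true_onset_ms + config$bin_ms) /
                max(config$ramp_duration_ms, config$bin_ms)))
}

target_mixture <- function(t, config) {
  f <- ramp_fraction(t, config)
  config$baseline_pref + f * (config$asymptote_pref - config$baseline_pref)
}

#' Simulate binned gaze for a design
#'
#' Runs the Markov gaze process (see [sim_config()]) independently for every
#' trial and emits a binned fixation table plus the generating ground truth.
#' States are the four objects and "none"; the refresh mixture allocates
#' `p_offscreen` to none and splits the rest between the target and
#' distractor pairs according to the ramped target share, with the
#' within-pair split 0.5/0.5 for distractors and (0.5 + ramped egocentric
#' effect) in favour of the participant-compatible target.
#'
#' @param design Design tibble from [build_design()].
#' @param config The [sim_config()] used to build it.
#' @param seed RNG seed (defaults to `config$seed + 1`).
#' @return List: `table` (binned fixation table), `ground_truth` (list with
#'   per-contrast true divergence bin and the generating parameters).
#' @export
simulate_gaze <- function(design, config = sim_config(), seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  force(design)  # a design built in the call must not reseed the RNG later
  set.seed(seed)
  lattice <- bin_lattice(config$window, config$bin_ms)
  nb <- length(lattice)
  n_t <- nrow(design)

  gendered <- design$item_type == "gendered"
  # state codes: 1 = compatible target (target_1 on neutral trials),
  # 2 = other target, 3/4 = distractors, 5 = none
  ego <- ifelse(gendered, config$egocentric_effect, 0)

  m <- target_mixture(lattice, config)       # per-bin target-pair share
  f <- ramp_fraction(lattice, config)        # per-bin egocentric ramp
  states <- matrix(0L, n_t, nb)
  prev <- integer(n_t)
  on_screen <- 1 - config$p_offscreen
  for (j in seq_len(nb)) {
    ego_j <- 0.5 + ego * f[j]
    c1 <- on_screen * m[j] * ego_j
    c2 <- on_screen * m[j]
    c3 <- c2 + on_screen * (1 - m[j]) * 0.5
    c4 <- on_screen
    u <- runif(n_t)
    draw <- 1L + (u > c1) + (u > c2) + (u > c3) + (u > c4)
    if (j == 1) {
      states[, j] <- draw
    } else {
      keep <- runif(n_t) < config$stay_prob
      states[, j] <- ifelse(keep, prev, draw)
    }
    prev <- states[, j]
  }

  # map state codes to per-trial object labels
  compat_target <- ifelse(gendered,
                          ifelse(design$participant_gender == "male",
                                 "target_masc", "target_fem"),
                          "target_1")
  other_target <- ifelse(gendered,
                         ifelse(design$participant_gender == "male",
                                "target_fem", "target_masc"),
                         "target_2")
  d1 <- ifelse(gendered, "distr_masc", "distr_1")
  d2 <- ifelse(gendered, "distr_fem", "distr_2")
  state_labels <- cbind(compat_target, other_target, d1, d2, "")

  obj_labels <- c("target_masc", "target_fem", "distr_masc", "distr_fem")
  neu_labels <- c("target_1", "target_2", "distr_1", "distr_2")
  fixated_label <- state_labels[cbind(rep(seq_len(n_t), nb),
                                      as.vector(states))]
  lab_mat <- matrix(fixated_label, n_t, nb)

  per_obj <- function(i) {
    lab <- ifelse(gendered, obj_labels[i], neu_labels[i])
    tibble::tibble(
      participant_id      = rep(design$participant_id, each = nb),
      participant_gender  = rep(design$participant_gender, each = nb),
      trial_id            = rep(design$trial_id, each = nb),
      item_type           = rep(design$item_type, each = nb),
      speaker_gender      = rep(design$speaker_gender, each = nb),
      referent_stereotype = rep(design$referent_stereotype, each = nb),
      bin_start_ms        = rep(lattice, times = n_t),
      object_label        = rep(lab, each = nb),
      role                = rep(c("target", "target", "distractor", "distractor")[i], n_t * nb),
      stereotype          = rep(ifelse(gendered,
                                       c("masculine", "feminine", "masculine", "feminine")[i],
                                       "neutral"), each = nb),
      fixated             = as.integer(as.vector(t(lab_mat)) == rep(lab, each = nb))
    )
  }
  table <- dplyr::bind_rows(lapply(1:4, per_obj))

  ground_truth <- list(
    targets_vs_distractors = if (config$asymptote_pref > config$baseline_pref)
      config$true_onset_ms else NA_real_,
    compatible_vs_incompatible = if (config$egocentric_effect > 0)
      config$true_onset_ms else NA_real_,
    config = unclass(config), seed = seed
  )
  list(table = table, ground_truth = ground_truth)
}

#' Simulate a complete experiment to disk
#'
#' Builds the design, simulates gaze, and writes `design.csv`,
#' `binned.csv` and `ground_truth.json` into `dir`. Outputs are
#' byte-identical for identical (config, seed).
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param seed Root seed; the design uses `seed` and the gaze process
#'   `seed + 1`.
#' @return Invisibly, the named vector of file paths.
#' @export
simulate_experiment <- function(config = sim_config(), dir, seed = config$seed) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir, call. = FALSE)
  }
  design <- build_design(config, seed = seed)
  sim <- simulate_gaze(design, config, seed = seed + 1L)
  paths <- c(
    design = file.path(dir, "design.csv"),
    binned = file.path(dir, "binned.csv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  write_design(design, paths[["design"]])
  write_binned_table(sim$table, paths[["binned"]], config$window, config$bin_ms)
  jsonlite::write_json(sim$ground_truth, paths[["ground_truth"]],
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(paths)
}

#' Expand a binned table back into per-bin fixation events
#'
#' Thin adapter for exercising the event-level reader and [bin_fixations()]:
#' each fixated bin becomes one 50 ms fixation event at the centre of its
#' object's interest area, in absolute trial time. Binning these events
#' reproduces the table exactly (a full-bin fixation is always a strict
#' majority of the bin).
#'
#' @param table Binned fixation table.
#' @param design Matching design tibble.
#' @return Fixation-event tibble as from [read_fixation_report()].
#' @export
binned_to_events <- function(table, design) {
  fix <- table[table$fixated == 1L, , drop = FALSE]
  dkey <- paste(design$participant_id, design$trial_id)
  ri <- match(paste(fix$participant_id, fix$trial_id), dkey)
  if (anyNA(ri)) stop("binned table references trials absent from design",
                      call. = FALSE)
  cx <- cy <- numeric(nrow(fix))
  for (i in 1:4) {
    hit <- design[ri, paste0("ia", i, "_label"), drop = TRUE] == fix$object_label
    cx[hit] <- design[ri, paste0("ia", i, "_center_x"), drop = TRUE][hit]
    cy[hit] <- design[ri, paste0("ia", i, "_center_y"), drop = TRUE][hit]
  }
  bin_ms <- 50L
  ev <- tibble::tibble(
    participant_id = fix$participant_id,
    trial_id = fix$trial_id,
    start_ms = fix$bin_start_ms + design$verb_onset_ms[ri],
    end_ms = fix$bin_start_ms + bin_ms + design$verb_onset_ms[ri],
    x = cx, y = cy,
    is_blink = FALSE
  )
  dplyr::arrange(ev, .data$participant_id, .data$trial_id, .data$start_ms)
}
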