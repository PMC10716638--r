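# Shared fixtures: a desk-scale simulation config, hand-built binned rows,
# and brute-force oracles kept independent of the implementation under test.

tiny_config <- function(...) {
  sim_config(n_participants = 8, n_gendered = 8, n_neutral = 8, ...)
}

tiny_experiment <- function(seed = 42, ...) {
  cfg <- tiny_config(...)
  design <- build_design(cfg, seed = seed)
  sim <- simulate_gaze(design, cfg, seed = seed + 1L)
  list(config = cfg, design = design, table = sim$table,
       ground_truth = sim$ground_truth)
}

# Four object rows for one (participant, trial, bin); `fixate` names the
# fixated object label or NA for an all-zero bin.
bin_rows <- function(participant, trial, bin, fixate = NA,
                     participant_gender = "male", speaker_gender = "male",
                     item_type = "gendered",
                     referent_stereotype = "masculine") {
  labels <- c("target_masc", "target_fem", "distr_masc", "distr_fem")
  tibble::tibble(
    participant_id = participant,
    participant_gender = participant_gender,
    trial_id = trial,
    item_type = item_type,
    speaker_gender = speaker_gender,
    referent_stereotype = referent_stereotype,
    bin_start_ms = as.integer(bin),
    object_label = labels,
    role = c("target", "target", "distractor", "distractor"),
    stereotype = c("masculine", "feminine", "masculine", "feminine"),
    fixated = as.integer(!is.na(fixate) & labels == fixate)
  )
}

# One single-trial design row with known interest areas and timings.
hand_design_row <- function(participant = "p01", trial = "t01",
                            participant_gender = "male",
                            speaker_gender = "male",
                            item_type = "gendered",
                            verb_onset = 1500) {
  d <- tibble::tibble(
    participant_id = participant,
    participant_gender = participant_gender,
    list_id = 1L,
    item_id = "g01",
    trial_id = trial,
    item_type = item_type,
    speaker_gender = speaker_gender,
    referent_stereotype = if (item_type == "gendered") "masculine" else "n/a",
    verb_onset_ms = verb_onset,
    verb_offset_ms = verb_onset + 360,
    target_onset_ms = verb_onset + 1100,
    sentence_duration_ms = verb_onset + 1800,
    comprehension_correct = TRUE
  )
  labels <- if (item_type == "gendered") {
    c("target_masc", "target_fem", "distr_masc", "distr_fem")
  } else {
    c("target_1", "target_2", "distr_1", "distr_2")
  }
  stereo <- if (item_type == "gendered") {
    c("masculine", "feminine", "masculine", "feminine")
  } else rep("neutral", 4)
  cx <- c(212, 812, 212, 812)
  cy <- c(184, 184, 584, 584)
  for (i in 1:4) {
    d[[paste0("ia", i, "_label")]] <- labels[i]
    d[[paste0("ia", i, "_role")]] <- c("target", "target",
                                       "distractor", "distractor")[i]
    d[[paste0("ia", i, "_stereotype")]] <- stereo[i]
    d[[paste0("ia", i, "_center_x")]] <- cx[i]
    d[[paste0("ia", i, "_center_y")]] <- cy[i]
    d[[paste0("ia", i, "_width")]] <- 300
    d[[paste0("ia", i, "_height")]] <- 300
  }
  d
}

# Brute-force onset oracle: first index i such that sig[i .. i+k-1] are all
# TRUE (equivalently, the first bin of the first run of >= k significant
# bins); NA when no such window exists.
brute_onset_index <- function(sig, k) {
  n <- length(sig)
  if (n >= k) {
    for (i in seq_len(n - k + 1)) {
      if (all(sig[i:(i + k - 1)])) return(i)
    }
  }
  NA_integer_
}
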