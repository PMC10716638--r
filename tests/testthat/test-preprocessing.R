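test_that("a 500 ms fixation inside one interest area fills ten bins", {
  design <- hand_design_row(verb_onset = 1500)
  # centred in target_masc's area (212, 184), spanning verb-relative 0..500
  events <- tibble::tibble(
    participant_id = "p01", trial_id = "t01",
    start_ms = 1500, end_ms = 2000, x = 212, y = 184, is_blink = FALSE
  )
  tab <- bin_fixations(events, design)
  fix <- tab[tab$fixated == 1L, ]
  expect_equal(unique(fix$object_label), "target_masc")
  expect_equal(sort(fix$bin_start_ms), seq(0L, 450L, by = 50L))
  others <- tab[tab$object_label != "target_masc", ]
  expect_true(all(others$fixated == 0L))
})

test_that("blinks and out-of-area gaze code as zero everywhere", {
  design <- hand_design_row()
  blink <- tibble::tibble(
    participant_id = "p01", trial_id = "t01",
    start_ms = 500, end_ms = 3300, x = NA_real_, y = NA_real_, is_blink = TRUE
  )
  tab <- bin_fixations(blink, design)
  expect_true(all(tab$fixated == 0L))
  expect_equal(nrow(tab), 4 * 50)

  centre_gaze <- tibble::tibble(
    participant_id = "p01", trial_id = "t01",
    start_ms = 500, end_ms = 3300, x = 512, y = 384, is_blink = FALSE
  )
  expect_true(all(bin_fixations(centre_gaze, design)$fixated == 0L))
})

test_that("bin coding follows the strict-majority rule", {
  design <- hand_design_row(verb_onset = 1500)
  partial <- function(ms_inside) tibble::tibble(
    participant_id = "p01", trial_id = "t01",
    start_ms = 1500 + (50 - ms_inside), end_ms = 2000,
    x = 212, y = 184, is_blink = FALSE
  )
  bin0 <- function(tab) tab$fixated[tab$bin_start_ms == 0L &
                                    tab$object_label == "target_masc"]
  expect_equal(bin0(bin_fixations(partial(20), design)), 0L)  # minority
  expect_equal(bin0(bin_fixations(partial(25), design)), 0L)  # tie -> 0
  expect_equal(bin0(bin_fixations(partial(26), design)), 1L)  # majority
})

test_that("bin coding is invariant to splitting a fixation into sub-events", {
  design <- hand_design_row(verb_onset = 1500)
  whole <- tibble::tibble(
    participant_id = "p01", trial_id = "t01",
    start_ms = 1530, end_ms = 2230, x = 212, y = 184, is_blink = FALSE
  )
  parts <- tibble::tibble(
    participant_id = "p01", trial_id = "t01",
    start_ms = c(1530, 1765, 2100), end_ms = c(1765, 2100, 2230),
    x = 212, y = 184, is_blink = FALSE
  )
  expect_equal(bin_fixations(parts, design), bin_fixations(whole, design))
})

test_that("orphan trials in the event stream are reported", {
  design <- hand_design_row()
  events <- tibble::tibble(
    participant_id = "p01", trial_id = "t99",
    start_ms = 0, end_ms = 100, x = 212, y = 184, is_blink = FALSE
  )
  expect_error(bin_fixations(events, design), "t99")
})

test_that("binned tables survive the event-level round trip", {
  exp <- tiny_experiment(seed = 9)
  events <- binned_to_events(exp$table, exp$design)
  rebinned <- bin_fixations(events, exp$design)
  canon <- function(tab) as.data.frame(
    dplyr::arrange(tab, participant_id, trial_id, bin_start_ms, object_label))
  expect_equal(canon(rebinned), canon(exp$table))
})

test_that("role assignment sets both compatibility flags independently", {
  male_speaker <- hand_design_row(participant_gender = "male",
                                  speaker_gender = "male")
  roles <- assign_roles(male_speaker)
  tie <- roles[roles$object_label == "target_masc", ]
  expect_true(tie$participant_compatible)
  expect_true(tie$speaker_compatible)

  as_female <- assign_roles(male_speaker, participant_gender = "female")
  expect_false(as_female$participant_compatible[
    as_female$object_label == "target_masc"])
  expect_true(as_female$participant_compatible[
    as_female$object_label == "target_fem"])
  # male speaker, female participant: speaker flag unchanged
  expect_true(as_female$speaker_compatible[
    as_female$object_label == "target_masc"])

  neutral <- assign_roles(hand_design_row(item_type = "neutral"))
  expect_true(all(is.na(neutral$participant_compatible)))
  expect_true(all(is.na(neutral$speaker_compatible)))
})

test_that("trial subsets partition as designed", {
  exp <- tiny_experiment(seed = 3)
  all_g <- select_trials(exp$table, "all_gendered")
  match_g <- select_trials(exp$table, "gender_match")
  mismatch_g <- select_trials(exp$table, "gender_mismatch")
  neutral <- select_trials(exp$table, "neutral")

  key <- function(tab) sort(unique(paste(tab$participant_id, tab$trial_id)))
  expect_equal(sort(c(key(match_g), key(mismatch_g))), key(all_g))
  expect_length(intersect(key(match_g), key(mismatch_g)), 0)

  expect_true(all(attr(all_g, "n_trials") == 8))
  expect_true(all(attr(mismatch_g, "n_trials") == 4))
  expect_true(all(attr(neutral, "n_trials") == 8))

  gendered_only <- exp$table[exp$table$item_type == "gendered", ]
  expect_error(select_trials(gendered_only, "neutral"), "no trials")
})

test_that("with the reference design, subsets retain 28 and 14 trials", {
  design <- build_design(sim_config(), seed = 21)
  sim <- simulate_gaze(design, sim_config(), seed = 22)
  expect_true(all(attr(select_trials(sim$table, "all_gendered"),
                       "n_trials") == 28))
  expect_true(all(attr(select_trials(sim$table, "gender_mismatch"),
                       "n_trials") == 14))
})

test_that("proportion curves match hand arithmetic on a tiny fixture", {
  # two participants, two trials each, two bins; targets_vs_distractors
  tab <- dplyr::bind_rows(
    bin_rows("p01", "t01", 0, fixate = "target_masc"),
    bin_rows("p01", "t01", 50, fixate = "distr_fem"),
    bin_rows("p01", "t02", 0, fixate = "target_fem"),
    bin_rows("p01", "t02", 50, fixate = NA),
    bin_rows("p02", "t01", 0, fixate = "distr_masc"),
    bin_rows("p02", "t01", 50, fixate = "distr_masc"),
    bin_rows("p02", "t02", 0, fixate = "target_masc"),
    bin_rows("p02", "t02", 50, fixate = "target_fem")
  )
  cv <- proportion_curves(tab, "targets_vs_distractors", window = c(0, 100))
  # p01: bin 0 -> 2 target looks / 2; bin 50 -> 0 target / 1 informative
  # p02: bin 0 -> 1/2; bin 50 -> 1/2
  expect_equal(unname(cv$P["p01", ]), c(1, 0))
  expect_equal(unname(cv$P["p02", ]), c(0.5, 0.5))
  expect_equal(cv$summary$mean, c(0.75, 0.25))
  expect_equal(cv$summary$n, c(2L, 2L))
  expect_equal(cv$summary$se, c(sd(c(1, 0.5)) / sqrt(2),
                                sd(c(0, 0.5)) / sqrt(2)))
})

test_that("an undefined bin drops out of that bin's participant count", {
  tab <- dplyr::bind_rows(
    bin_rows("p01", "t01", 0, fixate = "target_masc"),
    bin_rows("p01", "t01", 50, fixate = NA),      # no informative look
    bin_rows("p02", "t01", 0, fixate = "distr_masc"),
    bin_rows("p02", "t01", 50, fixate = "target_fem")
  )
  cv <- proportion_curves(tab, "targets_vs_distractors", window = c(0, 100))
  expect_true(is.na(cv$P["p01", "50"]))
  expect_equal(cv$summary$n, c(2L, 1L))
})

test_that("complementary contrasts mirror around 0.5", {
  exp <- tiny_experiment(seed = 13)
  sel <- select_trials(exp$table, "all_gendered")
  fwd <- proportion_curves(sel, "targets_vs_distractors")
  swapped <- contrast_spec("targets_vs_distractors")
  tmp <- swapped$set_a; swapped$set_a <- swapped$set_b; swapped$set_b <- tmp
  rev <- proportion_curves(sel, swapped)
  both <- fwd$P + rev$P
  expect_true(all(abs(both[!is.na(both)] - 1) < 1e-12))
})

test_that("the all-trials denominator counts uninformative bins", {
  tab <- dplyr::bind_rows(
    bin_rows("p01", "t01", 0, fixate = "target_masc"),
    bin_rows("p01", "t02", 0, fixate = NA)
  )
  ab <- proportion_curves(tab, "targets_vs_distractors", window = c(0, 50))
  all_den <- proportion_curves(tab, "targets_vs_distractors",
                               window = c(0, 50), denominator = "all")
  expect_equal(unname(ab$P["p01", 1]), 1)
  expect_equal(unname(all_den$P["p01", 1]), 0.5)
})

test_that("comprehension accuracy averages the per-trial flags", {
  d <- dplyr::bind_rows(lapply(1:4, function(i)
    hand_design_row(trial = paste0("t0", i))))
  expect_equal(comprehension_accuracy(d)$overall, 1)
  d$comprehension_correct[2] <- FALSE
  acc <- comprehension_accuracy(d)
  expect_equal(acc$overall, 0.75)
  expect_equal(acc$by_participant$accuracy, 0.75)
  d$comprehension_correct[3] <- NA
  expect_error(comprehension_accuracy(d), "t03")
})
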