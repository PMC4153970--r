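## Committed item banks. These are hand-authored, calibrated to be
## plausible for a mild-to-moderate AD population on the standard-normal
## latent disability scale; they are synthetic and are NOT estimates from
## any clinical database.

#' Default 13-component item bank
#'
#' A full synthetic ADAS-cog-style bank: six task-based components with
#' binary pass/fail items, three word-recall trials plus delayed recall
#' (binomial over 10 words), word recognition (binomial over 12 words
#' with an upper asymptote), number cancellation (generalized Poisson
#' over 0-40 points) and four rater-assessed five-category components.
#' Study variant masks emulate a pooled multi-study database: some studies
#' add delayed recall and/or number cancellation, some exclude naming or
#' recognition, one stores recognition truncated at 12 out of 24
#' judgements, and one administers recognition as three repeated trials.
#'
#' @return An [item_bank()].
#' @export
default_item_bank <- function() {
  bin <- function(id, comp, a, b, c = 0)
    item_spec(id, comp, "binary3pl", a = a, b = b, c = c)
  items <- bind_rows(
    ## commands: 5 tasks of increasing difficulty
    bin("cmd_fist", "commands", 1.0, -2.0, 0.01),
    bin("cmd_ceiling", "commands", 1.1, -0.9, 0.02),
    bin("cmd_pencil", "commands", 1.2, 0.2, 0.02),
    bin("cmd_watch", "commands", 1.1, 1.2, 0.03),
    bin("cmd_tap_shoulder", "commands", 0.9, 2.2, 0.10),
    ## construction: circle to cube
    bin("con_circle", "construction", 1.0, 2.6, 0.02),
    bin("con_rectangles", "construction", 1.2, 1.4, 0.05),
    bin("con_rhombus", "construction", 1.1, 0.6, 0.12),
    bin("con_cube", "construction", 0.9, -0.3, 0.20),
    ## ideational praxis: 5 steps
    bin("ide_fold", "ideational_praxis", 1.2, 1.6, 0.02),
    bin("ide_insert", "ideational_praxis", 1.3, 1.2, 0.02),
    bin("ide_seal", "ideational_praxis", 1.2, 0.8, 0.05),
    bin("ide_address", "ideational_praxis", 1.1, 0.9, 0.08),
    bin("ide_stamp", "ideational_praxis", 1.0, 1.1, 0.05),
    ## naming objects & fingers: 12 representative tasks
    bin("nam_flower", "naming", 1.3, 1.8, 0.01),
    bin("nam_bed", "naming", 1.4, 2.0, 0.01),
    bin("nam_whistle", "naming", 1.2, 1.0, 0.03),
    bin("nam_pencil", "naming", 1.4, 2.2, 0.01),
    bin("nam_rattle", "naming", 1.0, 0.6, 0.05),
    bin("nam_mask", "naming", 1.1, 0.8, 0.04),
    bin("nam_scissors", "naming", 1.3, 1.9, 0.01),
    bin("nam_comb", "naming", 1.3, 2.1, 0.01),
    bin("nam_wallet", "naming", 1.2, 1.5, 0.02),
    bin("nam_harmonica", "naming", 0.9, 0.4, 0.06),
    bin("nam_stethoscope", "naming", 0.8, 0.2, 0.08),
    bin("nam_fingers", "naming", 1.2, 1.7, 0.02),
    ## orientation: 8 binary facts
    bin("ori_person", "orientation", 1.4, 3.0, 0.01),
    bin("ori_year", "orientation", 1.5, 0.6, 0.02),
    bin("ori_month", "orientation", 1.5, 1.0, 0.02),
    bin("ori_day_week", "orientation", 1.4, 0.9, 0.03),
    bin("ori_date", "orientation", 1.3, 0.4, 0.05),
    bin("ori_season", "orientation", 1.2, 1.3, 0.05),
    bin("ori_time_day", "orientation", 1.1, 1.6, 0.05),
    bin("ori_place", "orientation", 1.4, 1.5, 0.02),
    ## word recall: three trials with learning, delayed recall
    item_spec("wrc_trial1", "word_recall", "binomial_words",
              a = 1.2, b = -1.6, c = 0.10, n_words = 10),
    item_spec("wrc_trial2", "word_recall", "binomial_words",
              a = 1.3, b = -1.0, c = 0.06, n_words = 10),
    item_spec("wrc_trial3", "word_recall", "binomial_words",
              a = 1.3, b = -0.7, c = 0.05, n_words = 10),
    item_spec("dwr", "delayed_word_recall", "binomial_words",
              a = 1.8, b = -0.8, c = 0.04, n_words = 10),
    ## word recognition: 12 words, guessing floor and ceiling
    item_spec("wrg", "word_recognition", "word_recognition",
              a = 1.0, b = 0.1, c = 0.08, d = 0.92, n_words = 12),
    ## number cancellation: points 0-40
    item_spec("nc", "number_cancellation", "gen_poisson_count",
              a = 0.9, b = 1.8, d = 30, delta = 0.15, max_count = 40),
    ## rater-assessed components: 5 ordered categories each
    item_spec("rat_comprehension", "comprehension", "ordered_categorical",
              a = 0.9, thresholds = c(0.9, 2.0, 3.0, 3.9)),
    item_spec("rat_spoken_language", "spoken_language", "ordered_categorical",
              a = 0.8, thresholds = c(1.1, 2.2, 3.2, 4.1)),
    item_spec("rat_remembering", "remembering", "ordered_categorical",
              a = 0.9, thresholds = c(0.3, 1.6, 2.8, 3.8)),
    item_spec("rat_word_finding", "word_finding", "ordered_categorical",
              a = 1.0, thresholds = c(0.5, 1.7, 2.9, 3.9))
  )
  ## variant machinery: repeated recognition trials and truncated storage
  items <- bind_rows(
    items,
    item_spec("wrg_rep1", "word_recognition", "word_recognition",
              a = 0.9, b = 0.0, c = 0.08, d = 0.92, n_words = 12),
    item_spec("wrg_rep2", "word_recognition", "word_recognition",
              a = 1.0, b = 0.2, c = 0.07, d = 0.92, n_words = 12),
    item_spec("wrg_rep3", "word_recognition", "word_recognition",
              a = 1.1, b = 0.35, c = 0.06, d = 0.92, n_words = 12),
    item_spec("wrg_trunc", "word_recognition", "word_recognition",
              a = 1.0, b = 0.1, c = 0.08, d = 0.92, n_words = 24,
              max_count = 12)
  )
  core11 <- items$item_id[!items$component %in%
                            c("delayed_word_recall", "number_cancellation") &
                            !grepl("^wrg_", items$item_id)]
  plus_dwr <- c(core11, "dwr")
  plus_dwr_nc <- c(plus_dwr, "nc")
  no <- function(ids, drop) setdiff(ids, drop)
  naming_ids <- items$item_id[items$component == "naming"]
  variants <- list(
    STUDY_A = plus_dwr_nc,
    STUDY_B = no(plus_dwr, c(naming_ids, "wrg")),
    STUDY_C = no(plus_dwr, "wrg"),
    STUDY_D = c(no(core11, "wrg"), "wrg_rep1", "wrg_rep2", "wrg_rep3"),
    STUDY_E = c(no(core11, "wrg"), "wrg_rep1", "wrg_rep2", "wrg_rep3"),
    STUDY_F = no(plus_dwr, c(naming_ids, "wrg")),
    STUDY_G = c(no(plus_dwr_nc, "wrg"), "wrg_trunc"),
    STUDY_H = c(no(plus_dwr_nc, "wrg"), "wrg_trunc")
  )
  item_bank(items, study_variants = variants)
}

#' Reduced 20-item bank
#'
#' A lighter calibrated bank spanning every model family, used for
#' desk-scale simulation studies where the full bank is unnecessarily
#' expensive. Synthetic calibration, as for [default_item_bank()].
#'
#' @return An [item_bank()].
#' @export
reduced_item_bank <- function() {
  bin <- function(id, comp, a, b, c = 0)
    item_spec(id, comp, "binary3pl", a = a, b = b, c = c)
  items <- bind_rows(
    bin("ori_year", "orientation", 1.5, 0.6, 0.02),
    bin("ori_month", "orientation", 1.5, 1.0, 0.02),
    bin("ori_date", "orientation", 1.3, 0.4, 0.05),
    bin("ori_place", "orientation", 1.4, 1.5, 0.02),
    bin("cmd_pencil", "commands", 1.2, 0.2, 0.02),
    bin("cmd_watch", "commands", 1.1, 1.2, 0.03),
    bin("ide_seal", "ideational_praxis", 1.2, 0.8, 0.05),
    bin("ide_address", "ideational_praxis", 1.1, 0.9, 0.08),
    bin("nam_whistle", "naming", 1.2, 1.0, 0.03),
    bin("nam_rattle", "naming", 1.0, 0.6, 0.05),
    bin("con_rhombus", "construction", 1.1, 0.6, 0.12),
    item_spec("wrc_trial1", "word_recall", "binomial_words",
              a = 1.2, b = -1.6, c = 0.10, n_words = 10),
    item_spec("wrc_trial2", "word_recall", "binomial_words",
              a = 1.3, b = -1.0, c = 0.06, n_words = 10),
    item_spec("wrc_trial3", "word_recall", "binomial_words",
              a = 1.3, b = -0.7, c = 0.05, n_words = 10),
    item_spec("dwr", "delayed_word_recall", "binomial_words",
              a = 1.8, b = -0.8, c = 0.04, n_words = 10),
    item_spec("wrg", "word_recognition", "word_recognition",
              a = 1.0, b = 0.1, c = 0.08, d = 0.92, n_words = 12),
    item_spec("nc", "number_cancellation", "gen_poisson_count",
              a = 0.9, b = 1.8, d = 30, delta = 0.15, max_count = 40),
    item_spec("rat_comprehension", "comprehension", "ordered_categorical",
              a = 0.9, thresholds = c(0.9, 2.0, 3.0, 3.9)),
    item_spec("rat_remembering", "remembering", "ordered_categorical",
              a = 0.9, thresholds = c(0.3, 1.6, 2.8, 3.8)),
    item_spec("rat_word_finding", "word_finding", "ordered_categorical",
              a = 1.0, thresholds = c(0.5, 1.7, 2.9, 3.9))
  )
  item_bank(items)
}

#' Default multi-study baseline composition
#'
#' Eight synthetic studies totalling 2,744 subjects whose variant masks
#' (in [default_item_bank()]) differ in the additional and excluded
#' components, mirroring the heterogeneity of pooled trial databases.
#'
#' @return Tibble with `study_id` and `n`.
#' @export
default_baseline_studies <- function() {
  tibble(study_id = c("STUDY_A", "STUDY_B", "STUDY_C", "STUDY_D", "STUDY_E",
                      "STUDY_F", "STUDY_G", "STUDY_H"),
         n = c(819, 157, 412, 216, 202, 137, 492, 309))
}
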