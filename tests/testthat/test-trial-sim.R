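test_that("trial simulation is seed-deterministic and respects the design", {
  bank <- mixed_toy_bank()
  des <- trial_design(50, default_progression_params(), bank, seed = 123)
  t1 <- simulate_trial(des)
  t2 <- simulate_trial(des)
  expect_identical(t1$responses, t2$responses)
  expect_identical(t1$truth, t2$truth)
  ## byte-identical CSV round trip
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_responses(t1$responses, p1)
  write_responses(t2$responses, p2)
  expect_identical(readLines(p1), readLines(p2))
  ## one record per subject-visit-item, balanced arms
  expect_equal(nrow(t1$responses), 50 * 7 * nrow(bank$items))
  expect_equal(sum(t1$truth$x_grp), 25)
  ## all values within support
  expect_silent(cogirt:::validate_responses(t1$responses, bank))
})

test_that("baseline multi-study simulation emulates variant heterogeneity", {
  bank <- default_item_bank()
  expect_equal(nrow(simulate_baseline_studies(
    bank, tibble::tibble(study_id = character(), n = integer()))), 0)
  studies <- default_baseline_studies()
  expect_equal(sum(studies$n), 2744)
  resp <- simulate_baseline_studies(bank, studies, seed = 77)
  expect_gt(nrow(resp), 1e5) # item-level records at scale
  ## variant masks respected: STUDY_B administers no naming items
  b_items <- unique(resp$item_id[resp$study_id == "STUDY_B"])
  expect_false(any(grepl("^nam_", b_items)))
  expect_true("nc" %in% resp$item_id[resp$study_id == "STUDY_A"])
  ## truncated recognition variant stays within its bound
  g <- resp[resp$study_id == "STUDY_G" & resp$item_id == "wrg_trunc", ]
  expect_true(all(g$value <= 12))
  expect_error(simulate_baseline_studies(
    bank, tibble::tibble(study_id = "S?", n = 5), seed = 1),
    "unknown study variant")
  tr <- attr(resp, "truth")
  expect_equal(nrow(tr), 2744)
})

test_that("random-effect draws reproduce the requested correlation", {
  bank <- one_item_bank()
  p <- progression_params(0.9, 0.35, 0.68, 0.39, rho = 0.54)
  des <- trial_design(10000, p, bank, schedule_months = c(0, 6), seed = 9)
  tr <- simulate_trial(des)
  r <- cor(tr$truth$eta1, tr$truth$eta2)
  expect_lt(abs(r - 0.54), 3 / sqrt(10000) * (1 - 0.54^2) * 1.5)
  expect_lt(abs(sd(tr$truth$eta1) - 0.68), 0.03)
  expect_lt(abs(sd(tr$truth$eta2) - 0.39), 0.02)
})

test_that("null trials leave the arms statistically indistinguishable", {
  bank <- one_item_bank()
  des <- trial_design(2000, default_progression_params(beta_drug = 0),
                      bank, seed = 31)
  tr <- simulate_trial(des)
  final <- tr$truth$d0 + tr$truth$slope * 1.5
  expect_gt(t.test(final ~ tr$truth$arm)$p.value, 0.01)
  ## zero variance: identical latent paths
  des0 <- trial_design(30, progression_params(0.9, 0.3, 0, 0, 0), bank,
                       seed = 5)
  tr0 <- simulate_trial(des0)
  expect_equal(var(tr0$truth$d0), 0)
  expect_equal(var(tr0$truth$slope), 0)
})

test_that("dropout truncates follow-up monotonically", {
  bank <- mixed_toy_bank()
  hz <- hazard_spec("constant", theta3 = 0)
  des <- trial_design(120, default_progression_params(0), bank,
                      hazard = hz, seed = 10)
  tr <- simulate_trial(des)
  expect_gt(sum(!is.na(tr$dropout$first_missed_months)), 0)
  joined <- dplyr::left_join(tr$responses,
                             tr$dropout, by = "subject_id")
  expect_true(all(is.na(joined$first_missed_months) |
                    joined$time_months < joined$first_missed_months))
  ## first missed is the next scheduled visit after last seen
  d <- tr$dropout[!is.na(tr$dropout$first_missed_months), ]
  sched <- des$schedule_months
  expect_true(all(vapply(seq_len(nrow(d)), function(i) {
    nxt <- sched[sched > d$last_seen_months[i]][1]
    d$first_missed_months[i] == nxt
  }, TRUE)))
})

test_that("total score maps items deterministically with hand-computed fixture", {
  bank <- mixed_toy_bank()
  ## three subjects, one visit, worked by hand:
  ## components: task (2 binary, failures), recall (n=10, errors),
  ## recognition (errors), cancellation (binned points), rater (category)
  resp <- tibble::tibble(
    subject_id = rep(c("s1", "s2", "s3"), each = 6),
    time_months = 0,
    item_id = rep(c("bin1", "bin2", "rec1", "wrg1", "nc1", "ord1"), 3),
    value = c(0L, 0L, 0L, 0L, 35L, 0L,     # best possible
              1L, 1L, 10L, 12L, 5L, 4L,    # worst possible
              1L, 0L, 4L, 6L, 22L, 2L))
  tot <- total_score(resp, bank)
  ## s1: 0 failures + 0 + 0 + bin(35 -> 0) + 0 = 0
  ## s2: 2 + 10 + 12 + bin(5 -> 5) + 4 = 33 (map maximum)
  ## s3: 1 + 4 + 6 + bin(22 -> 2) + 2 = 15
  expect_equal(tot$total[match(c("s1", "s2", "s3"), tot$subject_id)],
               c(0, 33, 15))
  expect_equal(bank$score_map$total_max, 33)
  ## missing component prorates: drop the rater item of s3
  resp2 <- resp[!(resp$subject_id == "s3" & resp$item_id == "ord1"), ]
  tot2 <- total_score(resp2, bank)
  s3 <- tot2[tot2$subject_id == "s3", ]
  expect_equal(s3$n_component_missing, 1)
  expect_equal(s3$total, round(13 * 33 / 29)) # prorated to the full range
})

test_that("expected total scores rise with progression", {
  bank <- reduced_item_bank()
  des <- trial_design(200, default_progression_params(0), bank, seed = 15)
  tr <- simulate_trial(des)
  tot <- total_score(tr$responses, bank)
  mns <- tot |> dplyr::group_by(time_months) |>
    dplyr::summarise(m = mean(total), .groups = "drop")
  expect_gt(coef(lm(m ~ time_months, mns))[2], 0)
  ## monotone in expectation: first vs last visit clearly ordered
  expect_gt(mns$m[nrow(mns)], mns$m[1])
})
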