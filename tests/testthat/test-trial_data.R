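test_that("session logs validate their invariants", {
  expect_s3_class(make_log(c("A", "B"), c("pull", "non_pull"),
                           reward = c(1L, 0L)), "session_log")
  # a non-pull trial cannot carry an outcome
  expect_error(make_log("A", "non_pull", reward = 1L), "non-pull")
  expect_error(make_log("A", "non_pull", reward = 0L, punishment = 1L),
               "non-pull")
  # ordering invariants
  expect_error(sessionLog(data.frame(trial_index = c(1L, 0L), session_id = 0L,
                                     tone = "A", action = "non_pull",
                                     reward = 0L, punishment = 0L,
                                     early_pull = 0L)),
               "strictly increasing")
  expect_error(sessionLog(data.frame(trial_index = 0:1, session_id = c(1L, 0L),
                                     tone = "A", action = "non_pull",
                                     reward = 0L, punishment = 0L,
                                     early_pull = 0L)),
               "non-decreasing")
})

test_that("CSV and JSON round-trips are the identity on valid logs", {
  log <- random_log(40L, seed = 11)
  for (ext in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    writeTrials(log, path)
    back <- readTrials(path, task_label = taskLabel(log))
    expect_equal(as.data.frame(back), as.data.frame(log))
    expect_identical(taskLabel(back), taskLabel(log))
  }
})

test_that("reading rejects malformed and invalid files with line context", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("trial_index,session_id,tone,action,reward,punishment,early_pull",
               "0,0,A,pull,1,0,0",
               "x,0,B,pull,1,0,0"), path)
  expect_error(readTrials(path), "line 3")
  writeLines(c("trial_index,session_id,tone,action,reward,punishment,early_pull",
               "0,0,A,non_pull,1,0,0"), path)
  expect_error(readTrials(path), "non-pull")
})

test_that("a header-only file reads as an empty log", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("trial_index,session_id,tone,action,reward,punishment,early_pull",
             path)
  expect_identical(nTrials(readTrials(path)), 0L)
})

test_that("early-pull exclusion drops exactly the flagged trials and is idempotent", {
  log <- make_log(rep("B", 10L), rep(c("pull", "non_pull"), 5L),
                  early_pull = c(1L, 1L, rep(0L, 8L)))
  out <- excludeEarlyPulls(log)
  expect_identical(nTrials(out), 8L)
  expect_true(all(out$early_pull == 0L))
  expect_identical(as.data.frame(excludeEarlyPulls(out)), as.data.frame(out))
  # all early -> empty; none early -> identity
  all_early <- make_log(rep("A", 3L), rep("non_pull", 3L), early_pull = 1L)
  expect_identical(nTrials(excludeEarlyPulls(all_early)), 0L)
  expect_identical(as.data.frame(excludeEarlyPulls(excludeEarlyPulls(log))),
                   as.data.frame(excludeEarlyPulls(log)))
})

test_that("sessions truncate at the planned-reward fraction", {
  # rewards on every trial, 10 planned, 60% -> keep the 5 trials before the
  # 6th reward
  log <- make_log(rep("B", 10L), rep("pull", 10L), reward = 1L)
  expect_identical(nTrials(truncateAtRewardFraction(log, 10L)), 5L)
  # threshold never reached -> session kept whole
  dry <- make_log(rep("B", 6L), rep("non_pull", 6L), reward = 0L)
  expect_identical(nTrials(truncateAtRewardFraction(dry, 10L)), 6L)
  # fraction 1 with more planned than delivered -> unchanged
  expect_identical(nTrials(truncateAtRewardFraction(log, 100L, fraction = 1)),
                   10L)
  # applied per session: second session truncates independently
  two <- make_log(rep("B", 8L), rep("pull", 8L), reward = 1L,
                  session_id = rep(0:1, each = 4L))
  out <- truncateAtRewardFraction(two, 4L, fraction = 0.5)
  expect_identical(as.integer(table(out$session_id)), c(1L, 1L))
  expect_error(truncateAtRewardFraction(log, 10L, fraction = 0), "fraction")
  expect_error(truncateAtRewardFraction(log, 10L, fraction = 1.2), "fraction")
})

test_that("lever-pull rate counts pulls per tone after early-pull exclusion", {
  log <- make_log(c(rep("B", 8L), rep("A", 4L)),
                  c(rep("pull", 6L), rep("non_pull", 2L), "pull",
                    rep("non_pull", 3L)))
  expect_equal(leverPullRate(log, "B"), 0.75)
  expect_equal(leverPullRate(log, "A"), 0.25)
  all_pull <- make_log(rep("A", 5L), rep("pull", 5L))
  expect_equal(leverPullRate(all_pull, "A"), 1.0)
  expect_error(leverPullRate(all_pull, "B"), "undefined")
  # invariance to within-tone trial reordering
  perm <- log[order(log$action), ]
  perm$trial_index <- seq_len(nrow(perm)) - 1L
  perm <- sessionLog(as.data.frame(perm), taskLabel(log))
  expect_equal(leverPullRate(perm, "B"), leverPullRate(log, "B"))
})

test_that("moving average uses growing prefixes and preserves length", {
  expect_equal(movingAverage(c(1, 1, 0), window = 2L), c(1, 1, 0.5))
  expect_equal(movingAverage(rep(1, 25L), window = 10L), rep(1, 25L))
  x <- rep(c(1, 0), 30L)
  expect_equal(unique(movingAverage(x, 10L)[10:60]), 0.5)
  expect_length(movingAverage(runif(37L), 10L), 37L)
  expect_error(movingAverage(x, 0L), "window")
  log <- make_log(c("A", "A", "B", "A"),
                  c("pull", "pull", "pull", "non_pull"))
  expect_equal(movingAverageChoice(log, "A", 2L), c(1, 1, 0.5))
})

test_that("learning criterion needs two consecutive strict threshold sessions", {
  expect_identical(thresholdSessionsMet(rbind(c(0.4, 0.7), c(0.3, 0.8))),
                   list(met = TRUE, index = 2L))
  expect_identical(thresholdSessionsMet(rbind(c(0.4, 0.7), c(0.6, 0.8)))$met,
                   FALSE)
  # exactly 0.5 does not qualify (strict inequalities)
  expect_false(thresholdSessionsMet(rbind(c(0.5, 0.8), c(0.4, 0.8),
                                          c(0.5, 0.8)))$met)
  expect_false(thresholdSessionsMet(rbind(c(0.4, 0.5), c(0.4, 0.5)))$met)
  out <- thresholdSessionsMet(rbind(c(0.6, 0.6), c(0.4, 0.7), c(0.45, 0.55)))
  expect_identical(out, list(met = TRUE, index = 3L))
})
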