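test_that("schedules satisfy the protocol invariants in both conditions", {
  for (cond in c("AB", "YN")) {
    s <- build_schedule(rb_structure, cond, seed = 7)
    expect_silent(validate_session(s))
    tr <- s$trials
    expect_equal(nrow(tr), 600L)
    expect_true(all(table(tr$block) == 100L))
    expect_identical(tr$phase == "train", tr$block <= 5L)

    train_q <- tr$question[tr$phase == "train"]
    test_q <- tr$question[tr$phase == "test"]
    if (cond == "AB") {
      expect_true(all(train_q %in% c("A|B", "C|D")))
      expect_true(all(test_q == "B|C"))
    } else {
      expect_true(all(train_q %in% paste0("is:", c("A", "B", "C", "D"))))
      expect_true(all(test_q %in% c("is:B", "is:C")))
      # target labels balanced within rounding over training
      targets <- table(sub("^is:", "", train_q))
      expect_true(max(targets) - min(targets) <= 2)
    }
    # block 6 holds only B/C stimuli; 250 trials per trained contrast
    expect_true(all(tr$true_category[tr$block == 6] %in% c("B", "C")))
    expect_equal(sum(tr$true_category[tr$phase == "train"] %in% c("A", "B")),
                 250L)
    # every stimulus unique, so train and test sets are disjoint
    expect_equal(anyDuplicated(paste(tr$dim1, tr$dim2)), 0L)
  }
})

test_that("schedules are deterministic under a fixed seed", {
  a <- build_schedule(ii_structure, "YN", seed = 11)
  b <- build_schedule(ii_structure, "YN", seed = 11)
  c <- build_schedule(ii_structure, "YN", seed = 12)
  expect_identical(a$trials, b$trials)
  expect_false(identical(a$trials, c$trials))
})

test_that("session CSV round-trips exactly and rejects malformed files", {
  s <- sim_session("RB", "YN", "within", seed = 21)
  path <- withr::local_tempfile(fileext = ".csv")
  write_session_csv(s, path)
  back <- read_session_csv(path)
  expect_identical(back$participant_id, s$participant_id)
  expect_identical(back$condition, s$condition)
  expect_identical(back$structure_kind, s$structure_kind)
  expect_equal(back$trials, s$trials)

  lines <- readLines(path)

  short <- withr::local_tempfile(fileext = ".csv")
  writeLines(lines[1:600], short)  # header + 599 rows
  expect_error(read_session_csv(short), "600 trials expected")

  bad_field <- withr::local_tempfile(fileext = ".csv")
  broken <- lines
  broken[5] <- sub(",[^,]*$", "", broken[5])  # drop last field of row 4
  writeLines(broken, bad_field)
  expect_error(read_session_csv(bad_field), "line 5")

  bad_fb <- withr::local_tempfile(fileext = ".csv")
  fb <- lines
  # flip feedback_given on a test-phase row (line 601 is trial 600)
  fb[601] <- sub(",0$", ",1", fb[601])
  writeLines(fb, bad_fb)
  expect_error(read_session_csv(bad_fb), "feedback_given")
})

test_that("cohorts round-trip through a directory with manifest", {
  sessions <- list(sim_session("RB", "AB", "within", seed = 31),
                   sim_session("RB", "AB", "between", seed = 32))
  cohort <- new_cohort(sessions, metadata = list(tag = "fixture"))
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_cohort(dir)
  expect_equal(length(back$sessions), 2L)
  expect_identical(back$metadata$tag, "fixture")
  expect_identical(
    vapply(back$sessions, function(x) x$agent$representation, character(1)),
    c("within", "between"))
  expect_equal(back$sessions[[1]]$trials, sessions[[1]]$trials)

  expect_error(new_cohort(list(sessions[[1]], sessions[[1]])), "unique")
  expect_error(read_cohort(file.path(dir, "nope")), "not found")
})
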