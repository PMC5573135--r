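test_that("cross-validation classifies agents to their generating representation", {
  w <- crossvalidate_participant(sim_session("RB", "YN", "within", seed = 61))
  expect_identical(w$verdict, "within")
  expect_lt(w$density_fit$test_rmsd, w$boundary_fit$test_rmsd)

  b <- crossvalidate_participant(sim_session("RB", "YN", "between", seed = 62))
  expect_identical(b$verdict, "between")
  expect_lt(b$boundary_fit$test_rmsd, b$density_fit$test_rmsd)

  w2 <- crossvalidate_participant(sim_session("II", "AB", "within", seed = 63))
  expect_identical(w2$verdict, "within")
  b2 <- crossvalidate_participant(sim_session("II", "AB", "between", seed = 64))
  expect_identical(b2$verdict, "between")
})

test_that("equal generalization errors resolve to the simpler boundary model", {
  expect_identical(catrep:::verdict_from_rmsd(0.2, 0.2), "between")
  expect_identical(catrep:::verdict_from_rmsd(0.19, 0.2), "within")
})

test_that("test predictions never touch the fitted parameters", {
  s <- sim_session("RB", "AB", "within", seed = 65)
  fit <- crossvalidate_participant(s)
  snapshot_d <- unserialize(serialize(fit$density_fit$params, NULL))
  snapshot_b <- unserialize(serialize(fit$boundary_fit$params, NULL))
  test_trials <- s$trials[s$trials$phase == "test", ]
  invisible(model_predictions(s, fit$density_fit$params, test_trials))
  invisible(model_predictions(s, fit$boundary_fit$params, test_trials))
  expect_identical(fit$density_fit$params, snapshot_d)
  expect_identical(fit$boundary_fit$params, snapshot_b)
  # and the whole procedure is deterministic
  expect_identical(crossvalidate_participant(s)$density_fit$test_rmsd,
                   fit$density_fit$test_rmsd)
})

test_that("participants with unfittable test-relevant categories are excluded", {
  s <- sim_session("RB", "YN", "within", seed = 66)
  # starve the B density: answer "no" to every is:B probe in the fit window
  starved <- s
  idx <- which(starved$trials$trial %in% 301:500 &
                 starved$trials$question == "is:B")
  starved$trials$response[idx] <- "no"
  starved$trials$implied_category[idx] <- "A"
  starved$trials$correct[idx] <-
    as.integer(starved$trials$true_category[idx] == "A")
  fit <- crossvalidate_participant(starved)
  expect_true(fit$excluded)
  expect_true(is.na(fit$verdict))
  expect_match(paste(fit$flags, collapse = " "), "B")

  # starving only the A density restricts the alpha fit but does not exclude
  starved_a <- s
  idx <- which(starved_a$trials$trial %in% 301:500 &
                 starved_a$trials$question == "is:A")
  starved_a$trials$response[idx] <- "no"
  starved_a$trials$implied_category[idx] <- "B"
  starved_a$trials$correct[idx] <-
    as.integer(starved_a$trials$true_category[idx] == "B")
  fit_a <- crossvalidate_participant(starved_a)
  expect_false(fit_a$excluded)
  expect_identical(fit_a$verdict, "within")
  expect_match(paste(fit_a$flags, collapse = " "), "A")
})

test_that("cohort classification summarizes counts, RMSDs, and recovery", {
  cohort <- simulate_cohort("RB", "YN", n_within = 4, n_between = 4, seed = 13)
  cl <- classify_cohort(cohort)
  expect_equal(cl$counts$n, 8L)
  expect_equal(cl$counts$n_within + cl$counts$n_between, 8L)
  expect_gte(cl$recovery_rate, 7 / 8)
  # selection consistency: within each verdict group the selected model's
  # mean generalization RMSD is the smaller one
  for (grp in unique(cl$rmsd_summary$group)) {
    sub <- cl$rmsd_summary[cl$rmsd_summary$group == grp, ]
    if (any(is.na(sub$mean_rmsd))) next
    selected <- ifelse(grp == "within", "density", "boundary")
    expect_lt(sub$mean_rmsd[sub$model == selected],
              sub$mean_rmsd[sub$model != selected])
  }
  # single-participant cohort still yields a complete table
  solo <- new_cohort(cohort$sessions[1])
  cl1 <- classify_cohort(solo)
  expect_equal(nrow(cl1$rmsd_summary), 4L)

  # serialized fits carry the documented schema fields
  path <- withr::local_tempfile(fileext = ".json")
  write_fits_json(cl, path)
  fits <- jsonlite::read_json(path)
  expect_length(fits, 8L)
  expect_setequal(
    names(fits[[1]]),
    c("participant_id", "condition", "structure", "verdict",
      "true_representation", "excluded", "flags", "density", "boundary"))
  expect_true(is.numeric(fits[[1]]$density$test_rmsd))
  expect_identical(fits[[1]]$density$params$model, "density")
})
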