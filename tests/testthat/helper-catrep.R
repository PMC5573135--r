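# Shared fixtures: all test data is generated in code.

rb_structure <- category_structure("RB")
ii_structure <- category_structure("II")

# Fill a schedule's responses from an explicit choice policy.
# `choose(pair, x, phase, true_label)` must return a label from `pair`.
respond_with_policy <- function(schedule, choose) {
  tr <- schedule$trials
  for (i in seq_len(nrow(tr))) {
    pair <- catrep:::question_pair(tr$question[i], tr$phase[i])
    chosen <- choose(pair, c(tr$dim1[i], tr$dim2[i]), tr$phase[i],
                     tr$true_category[i])
    stopifnot(chosen %in% pair)
    tr$response[i] <- if (schedule$condition == "AB") chosen else {
      if (chosen == sub("^is:", "", tr$question[i])) "yes" else "no"
    }
    tr$implied_category[i] <- chosen
    tr$correct[i] <- as.integer(chosen == tr$true_category[i])
    tr$feedback_given[i] <- as.integer(tr$phase[i] == "train")
  }
  schedule$trials <- tr
  validate_session(schedule)
  schedule
}

# One simulated session, memoised per (kind, condition, representation, seed)
# so several test files can share the fixture without re-simulating.
.session_cache <- new.env(parent = emptyenv())
sim_session <- function(kind = "RB", condition = "YN",
                        representation = "within", seed = 1, ...) {
  key <- paste(kind, condition, representation, seed, ...)
  if (is.null(.session_cache[[key]])) {
    structure_obj <- if (kind == "RB") rb_structure else ii_structure
    schedule <- build_schedule(structure_obj, condition, seed = seed)
    agent <- agent_config(representation, seed = seed + 1000L, ...)
    .session_cache[[key]] <- simulate_session(schedule, agent)
  }
  .session_cache[[key]]
}

block_means <- function(session) {
  tapply(session$trials$correct, session$trials$block, mean)
}
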