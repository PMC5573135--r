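# Contrast partner of a label within the trained pairs (A-B, C-D) or at
# test (B-C). A "no" response to "Is this an X?" implies the partner.
partner_label <- function(label, phase) {
  if (phase == "test") {
    return(switch(label, B = "C", C = "B",
                  stop("test trials only involve B and C.", call. = FALSE)))
  }
  switch(label, A = "B", B = "A", C = "D", D = "C",
         stop("unknown label: ", label, call. = FALSE))
}

# Ordered pair of labels a question contrasts: "A|B" -> c("A","B"),
# "is:B" at test -> c("B","C").
question_pair <- function(question, phase) {
  if (grepl("^is:", question)) {
    target <- sub("^is:", "", question)
    c(target, partner_label(target, phase))
  } else {
    strsplit(question, "|", fixed = TRUE)[[1]]
  }
}

is_category_response <- function(response, condition) {
  if (condition == "AB") response %in% cat_labels else response %in% c("yes", "no")
}

# Category implied by a raw response token given the question.
implied_from_response <- function(response, question, phase, condition) {
  if (!is_category_response(response, condition)) return(NA_character_)
  if (condition == "AB") return(response)
  target <- sub("^is:", "", question)
  if (response == "yes") target else partner_label(target, phase)
}

#' Build a 600-trial session schedule
#'
#' Lays out one participant's session: 5 training blocks of 100 trials
#' contrasting A with B and C with D (with feedback), followed by a
#' 100-trial transfer test contrasting B with C (no feedback). Stimuli come
#' from [sample_stimuli()] with the default (125, 175, 175, 125) counts, so
#' each stimulus is seen exactly once and the training and test stimulus
#' sets are disjoint. In the `"AB"` (classification) condition every trial
#' carries a pair question (`A|B`, `C|D`, or `B|C` at test); in the `"YN"`
#' (concept) condition every trial names a single target category
#' (`is:A`, ...), with target labels and yes/no ground truth crossed evenly
#' within rounding. Questions and categories are equally likely throughout.
#'
#' @param structure A `category_structure`.
#' @param condition `"AB"` (classification) or `"YN"` (concept / Yes-No).
#' @param seed Integer seed; schedules are deterministic given
#'   (structure, condition, seed).
#' @param participant_id Optional id string; defaults to a name derived
#'   from the arguments.
#' @return A `catrep_session` object with empty responses. The trial table
#'   has columns `trial`, `block`, `phase`, `question`, `dim1`, `dim2`,
#'   `true_category`, `response` (`"none"` until simulated or collected),
#'   `implied_category`, `correct`, `feedback_given`.
#' @export
build_schedule <- function(structure, condition = c("AB", "YN"), seed = 1L,
                           participant_id = NULL) {
  condition <- match.arg(condition)
  validate_category_structure(structure)
  if (is.null(participant_id)) {
    participant_id <- sprintf("%s_%s_s%d", structure$kind, condition, seed)
  }
  sub_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, 2))
  stimuli <- sample_stimuli(structure, seed = sub_seeds[1])

  by_cat <- split(stimuli, stimuli$category)
  take <- function(lab, n) by_cat[[lab]][seq_len(n), , drop = FALSE]
  drop_first <- function(lab, n) by_cat[[lab]][-seq_len(n), , drop = FALSE]

  train <- rbind(take("A", 125), take("B", 125), take("C", 125), take("D", 125))
  test <- rbind(drop_first("B", 125), drop_first("C", 125))

  # Target assignment for the Yes/No condition: within each true category,
  # ceiling(n/2) trials name the category itself (ground truth "yes") and
  # the rest name its contrast partner ("no").
  assign_targets <- function(df, phase) {
    unsplit_parts <- lapply(split(df, df$category), function(part) {
      lab <- part$category[1]
      n <- nrow(part)
      n_yes <- ceiling(n / 2)
      part$target <- c(rep(lab, n_yes),
                       rep(partner_label(lab, phase), n - n_yes))
      part
    })
    do.call(rbind, unsplit_parts)
  }

  if (condition == "AB") {
    train$question <- ifelse(train$category %in% c("A", "B"), "A|B", "C|D")
    test$question <- "B|C"
  } else {
    train <- assign_targets(train, "train")
    test <- assign_targets(test, "test")
    train$question <- paste0("is:", train$target)
    test$question <- paste0("is:", test$target)
    train$target <- NULL
    test$target <- NULL
  }

  train <- withr::with_seed(sub_seeds[2], {
    train <- train[sample.int(nrow(train)), , drop = FALSE]
    test <- test[sample.int(nrow(test)), , drop = FALSE]
    list(train = train, test = test)
  })
  test <- train$test
  train <- train$train

  trials <- data.frame(
    trial = 1:600,
    block = rep(1:6, each = 100),
    phase = rep(c("train", "test"), c(500, 100)),
    question = c(train$question, test$question),
    dim1 = c(train$dim1, test$dim1),
    dim2 = c(train$dim2, test$dim2),
    true_category = c(train$category, test$category),
    response = "none",
    implied_category = NA_character_,
    correct = NA_integer_,
    feedback_given = 0L,
    stringsAsFactors = FALSE
  )

  session <- structure(
    list(participant_id = participant_id, condition = condition,
         structure_kind = structure$kind, seed = seed, trials = trials,
         agent = NULL),
    class = "catrep_session"
  )
  validate_session(session)
  session
}

#' Validate a session against the protocol invariants
#'
#' Checks the full trial-table contract: 600 trials in 6 blocks of 100;
#' training confined to blocks 1-5; training questions contrast only A-B or
#' C-D (250 trials each) and test questions only B-C; every stimulus unique,
#' with disjoint training and test sets; feedback given exactly on answered
#' training trials; and, where responses are present, implied categories and
#' correctness consistent with the question semantics.
#'
#' @param session A `catrep_session`.
#' @return The session, invisibly; stops with a message naming the violated
#'   invariant otherwise.
#' @export
validate_session <- function(session) {
  if (!inherits(session, "catrep_session")) {
    stop("not a catrep_session object.", call. = FALSE)
  }
  tr <- session$trials
  fail <- function(...) stop("session invariant violated: ", sprintf(...),
                             call. = FALSE)
  if (nrow(tr) != 600L) fail("600 trials expected, got %d", nrow(tr))
  if (!identical(tr$trial, 1:600)) fail("trial index must run 1..600")
  if (!all(table(tr$block) == 100L) || !setequal(unique(tr$block), 1:6)) {
    fail("each of blocks 1-6 must contain exactly 100 trials")
  }
  if (!identical(tr$phase == "train", tr$block <= 5L)) {
    fail("phase must be train exactly on blocks 1-5")
  }
  if (!session$condition %in% c("AB", "YN")) fail("unknown condition")
  q_is_pair <- grepl("^[A-D]\\|[A-D]$", tr$question)
  q_is_target <- grepl("^is:[A-D]$", tr$question)
  if (session$condition == "AB" && !all(q_is_pair)) {
    fail("AB condition requires pair questions on every trial")
  }
  if (session$condition == "YN" && !all(q_is_target)) {
    fail("YN condition requires target questions on every trial")
  }
  for (i in seq_len(600)) {
    pair <- question_pair(tr$question[i], tr$phase[i])
    if (tr$phase[i] == "train") {
      if (!setequal(pair, c("A", "B")) && !setequal(pair, c("C", "D"))) {
        fail("training questions may only contrast A-B or C-D (trial %d)", i)
      }
    } else if (!setequal(pair, c("B", "C"))) {
      fail("test questions may only contrast B-C (trial %d)", i)
    }
    if (!tr$true_category[i] %in% pair) {
      fail("true category outside the questioned pair (trial %d)", i)
    }
  }
  train_pair_ab <- sum(tr$true_category[tr$phase == "train"] %in% c("A", "B"))
  if (train_pair_ab != 250L) {
    fail("training must hold 250 A-B and 250 C-D trials, got %d A-B",
         train_pair_ab)
  }
  key <- paste(tr$dim1, tr$dim2)
  if (anyDuplicated(key) > 0L) fail("every stimulus must occur exactly once")
  answered <- vapply(tr$response, is_category_response,
                     logical(1), condition = session$condition)
  expected_fb <- as.integer(tr$phase == "train" & answered)
  if (!identical(as.integer(tr$feedback_given), expected_fb)) {
    fail("feedback_given must be 1 exactly on answered training trials")
  }
  for (i in which(answered)) {
    implied <- implied_from_response(tr$response[i], tr$question[i],
                                     tr$phase[i], session$condition)
    if (!identical(tr$implied_category[i], implied)) {
      fail("implied_category inconsistent with response (trial %d)", i)
    }
    if (!identical(as.integer(tr$correct[i]),
                   as.integer(implied == tr$true_category[i]))) {
      fail("correct flag inconsistent with implied category (trial %d)", i)
    }
  }
  invisible(session)
}

#' @export
print.catrep_session <- function(x, ...) {
  answered <- sum(x$trials$response != "none")
  cat(sprintf(
    "<catrep_session> %s | %s structure, %s condition, seed %d | %d/600 responses\n",
    x$participant_id, x$structure_kind, x$condition, x$seed, answered))
  if (!is.null(x$agent)) {
    cat(sprintf("  simulated agent: %s representation (alpha = %g)\n",
                x$agent$representation, x$agent$alpha_agent))
  }
  invisible(x)
}

#' Bundle sessions into a cohort
#'
#' @param sessions List of `catrep_session` objects with unique
#'   participant ids.
#' @param metadata Free-form named list of tags.
#' @return A `catrep_cohort` object.
#' @export
new_cohort <- function(sessions, metadata = list()) {
  ids <- vapply(sessions, function(s) s$participant_id, character(1))
  if (anyDuplicated(ids) > 0L) {
    stop("participant ids must be unique within a cohort.", call. = FALSE)
  }
  structure(list(sessions = sessions, metadata = metadata),
            class = "catrep_cohort")
}

#' @export
print.catrep_cohort <- function(x, ...) {
  conds <- table(vapply(x$sessions, function(s) s$condition, character(1)))
  cat(sprintf("<catrep_cohort> %d sessions (%s)\n", length(x$sessions),
              paste(names(conds), conds, sep = ": ", collapse = ", ")))
  invisible(x)
}
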