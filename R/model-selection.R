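# Smallest generalization error wins; a tie goes to the boundary model,
# which is nested in the density model and has half its parameters.
verdict_from_rmsd <- function(density_rmsd, boundary_rmsd) {
  if (density_rmsd < boundary_rmsd) "within" else "between"
}

# Cross-validated model selection: both observer models are fitted to the
# last 200 training trials, their parameters are frozen, and the model with
# the smaller generalization RMSD on the transfer test wins. Using the
# generalization error (rather than the training fit) is what makes the
# comparison fair: the boundary model is nested in the density model and
# would always lose on training error.

#' Per-trial model predictions
#'
#' Builds the prediction series of a fitted model over a set of trials:
#' for each answered trial, the region probability of the questioned pair's
#' first label X (Yes/No: the named target; A/B: the left label of the pair
#' question), its complement, and the 0/1 indicator that the implied
#' response was X. Density predictions use the density ratio at training
#' and test alike; boundary predictions use the trained bound during
#' training and the combined-bounds rule at test. Trials whose pair
#' involves a category the density model could not fit are dropped and
#' recorded in the `"dropped"` attribute.
#'
#' @param session A `catrep_session`.
#' @param params A `density_params` or `boundary_params` object.
#' @param trials Trial-table subset to predict (default: all trials).
#' @return Data frame `trial`, `x_label`, `p_cx`, `p_cy`, `y`, with
#'   attribute `dropped` (character vector of unfittable labels, if any).
#' @export
model_predictions <- function(session, params, trials = session$trials) {
  answered <- vapply(trials$response, is_category_response, logical(1),
                     condition = session$condition)
  trials <- trials[answered, , drop = FALSE]
  is_density <- inherits(params, "density_params")
  out <- list()
  dropped <- character(0)
  for (grp in split(trials, list(trials$question, trials$phase), drop = TRUE)) {
    pair <- question_pair(grp$question[1], grp$phase[1])
    stim <- cbind(grp$dim1, grp$dim2)
    p_cx <- if (is_density) {
      tryCatch(density_region_prob(params, stim, pair),
               catrep_underdetermined_category = function(e) {
                 dropped <<- union(dropped, e$labels)
                 NULL
               })
    } else if (grp$phase[1] == "train") {
      boundary_region_prob_train(params, stim, pair)
    } else {
      p_b <- boundary_region_prob_test(params, stim)
      if (pair[1] == "B") p_b else 1 - p_b
    }
    if (is.null(p_cx)) next
    out[[length(out) + 1L]] <- data.frame(
      trial = grp$trial, x_label = pair[1], p_cx = p_cx, p_cy = 1 - p_cx,
      y = as.numeric(grp$implied_category == pair[1]),
      stringsAsFactors = FALSE
    )
  }
  res <- if (length(out) > 0L) do.call(rbind, out) else {
    data.frame(trial = integer(0), x_label = character(0),
               p_cx = numeric(0), p_cy = numeric(0), y = numeric(0))
  }
  res <- res[order(res$trial), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "dropped") <- dropped
  res
}

#' Classify one participant's representation by cross-validation
#'
#' Fits the within-category (density) and between-category (boundary)
#' models to the fit window (default trials 301-500, the last 200 training
#' trials), fits each model's decision noise alpha by least squares on the
#' same window conditional on the representational parameters, then --
#' without refitting anything -- predicts the transfer test (block 6) and
#' computes each model's generalization RMSD. The verdict is `"within"`
#' when the density model generalizes strictly better, `"between"`
#' otherwise (ties go to the simpler boundary model). Participants whose
#' density model cannot be fitted for category B or C (fewer than 3 usable
#' trials) or whose bounds are non-identifiable are marked excluded, with
#' the reason in `flags`; an unfittable A or D density only restricts the
#' training trials usable for the alpha fit and is flagged, not excluding.
#'
#' @param session A complete `catrep_session`.
#' @param fit_window Integer trial indices fitted on (default 301:500).
#' @return A `fit_classification` object: participant metadata, per-model
#'   `params` / `train_sse` / `test_rmsd`, `verdict`
#'   (`"within"`/`"between"`/`NA` if excluded), `excluded`, and `flags`.
#' @export
crossvalidate_participant <- function(session, fit_window = 301:500) {
  validate_session(session)
  flags <- character(0)
  excluded <- FALSE

  density_params <- tryCatch(
    fit_density_params(session, trial_window = fit_window),
    catrep_underdetermined_category = function(e) e
  )
  if (inherits(density_params, "condition")) {
    labels <- density_params$labels
    flags <- c(flags, paste0("underdetermined density category: ",
                             paste(labels, collapse = ", ")))
    if (any(labels %in% c("B", "C"))) {
      excluded <- TRUE
      density_params <- NULL
    } else {
      density_params <- fit_density_params(
        session, trial_window = fit_window,
        categories = setdiff(cat_labels, labels)
      )
    }
  }
  boundary_params <- tryCatch(
    fit_boundary_params(session, trial_window = fit_window),
    catrep_nonidentifiable_bound = function(e) {
      flags <<- c(flags, conditionMessage(e))
      excluded <<- TRUE
      NULL
    }
  )

  window_trials <- session$trials[session$trials$trial %in% fit_window, ,
                                  drop = FALSE]
  test_trials <- session$trials[session$trials$phase == "test", , drop = FALSE]

  fit_one <- function(params) {
    if (is.null(params)) return(NULL)
    train_preds <- model_predictions(session, params, window_trials)
    if (length(attr(train_preds, "dropped")) > 0L) {
      flags <<- c(flags, paste0("alpha fitted without pair(s) of: ",
                                paste(attr(train_preds, "dropped"),
                                      collapse = ", ")))
    }
    af <- fit_alpha(train_preds$p_cx, train_preds$p_cy, train_preds$y)
    params$alpha <- af$alpha
    test_preds <- model_predictions(session, params, test_trials)
    p_resp <- decision_prob(test_preds$p_cx, test_preds$p_cy, params$alpha)
    list(params = params, train_sse = af$sse,
         test_rmsd = rmsd(test_preds$y, p_resp), n_test = nrow(test_preds))
  }

  density_fit <- if (excluded) NULL else fit_one(density_params)
  boundary_fit <- if (excluded) NULL else fit_one(boundary_params)

  verdict <- if (excluded) NA_character_ else {
    verdict_from_rmsd(density_fit$test_rmsd, boundary_fit$test_rmsd)
  }
  structure(list(
    participant_id = session$participant_id,
    condition = session$condition,
    structure_kind = session$structure_kind,
    true_representation = if (!is.null(session$agent)) {
      session$agent$representation
    } else NA_character_,
    density_fit = density_fit, boundary_fit = boundary_fit,
    verdict = verdict, excluded = excluded, flags = flags
  ), class = "fit_classification")
}

#' @export
print.fit_classification <- function(x, ...) {
  if (x$excluded) {
    cat(sprintf("<fit_classification> %s: EXCLUDED (%s)\n", x$participant_id,
                paste(x$flags, collapse = "; ")))
  } else {
    cat(sprintf(
      "<fit_classification> %s: %s (density RMSD %.3f vs boundary RMSD %.3f)\n",
      x$participant_id, x$verdict, x$density_fit$test_rmsd,
      x$boundary_fit$test_rmsd))
  }
  invisible(x)
}

#' Classify a cohort and summarize by verdict, model, and condition
#'
#' Runs [crossvalidate_participant()] on every session (or accepts a list
#' of ready classifications) and tabulates: verdict counts and proportions
#' per condition; the mean generalization RMSD for each
#' (verdict group x model x condition) cell, in the layout of the
#' published summary tables; and, when ground-truth agent tags are present,
#' the model-recovery rate.
#'
#' @param cohort A `catrep_cohort`, or a list of `fit_classification`s.
#' @param fit_window Passed to [crossvalidate_participant()].
#' @return A `cohort_classification` object: `participants` (one row per
#'   participant), `counts` (per condition), `rmsd_summary` (long format:
#'   condition, verdict group, model, mean RMSD, n), `recovery_rate`
#'   (`NA` without ground truth), and the full `classifications` list.
#' @export
classify_cohort <- function(cohort, fit_window = 301:500) {
  classifications <- if (inherits(cohort, "catrep_cohort")) {
    if (length(cohort$sessions) == 0L) {
      stop("empty cohort: no sessions to classify.", call. = FALSE)
    }
    lapply(cohort$sessions, crossvalidate_participant, fit_window = fit_window)
  } else {
    stopifnot(all(vapply(cohort, inherits, logical(1), "fit_classification")))
    cohort
  }
  participants <- do.call(rbind, lapply(classifications, function(f) {
    data.frame(
      participant_id = f$participant_id, condition = f$condition,
      structure = f$structure_kind, verdict = f$verdict,
      density_rmsd = if (is.null(f$density_fit)) NA_real_ else f$density_fit$test_rmsd,
      boundary_rmsd = if (is.null(f$boundary_fit)) NA_real_ else f$boundary_fit$test_rmsd,
      true_representation = f$true_representation,
      excluded = f$excluded, stringsAsFactors = FALSE
    )
  }))
  usable <- participants[!participants$excluded, , drop = FALSE]
  if (nrow(usable) == 0L) {
    stop("all participants were excluded; nothing to classify.", call. = FALSE)
  }
  counts <- do.call(rbind, lapply(split(participants, participants$condition),
                                  function(part) {
    ok <- part[!part$excluded, , drop = FALSE]
    data.frame(
      condition = part$condition[1],
      n = nrow(ok),
      n_within = sum(ok$verdict == "within"),
      n_between = sum(ok$verdict == "between"),
      prop_within = mean(ok$verdict == "within"),
      n_excluded = sum(part$excluded),
      stringsAsFactors = FALSE
    )
  }))
  rownames(counts) <- NULL
  cells <- expand.grid(condition = unique(usable$condition),
                       group = c("between", "within"),
                       model = c("boundary", "density"),
                       stringsAsFactors = FALSE)
  rmsd_summary <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- usable[usable$condition == cells$condition[i] &
                    usable$verdict == cells$group[i], , drop = FALSE]
    col <- paste0(cells$model[i], "_rmsd")
    data.frame(condition = cells$condition[i], group = cells$group[i],
               model = cells$model[i],
               mean_rmsd = if (nrow(sub) > 0L) mean(sub[[col]]) else NA_real_,
               n = nrow(sub), stringsAsFactors = FALSE)
  }))
  recovery_rate <- if (all(is.na(usable$true_representation))) NA_real_ else {
    mean(usable$verdict == usable$true_representation, na.rm = TRUE)
  }
  structure(list(participants = participants, counts = counts,
                 rmsd_summary = rmsd_summary, recovery_rate = recovery_rate,
                 classifications = classifications),
            class = "cohort_classification")
}

#' @export
print.cohort_classification <- function(x, ...) {
  cat("<cohort_classification>\n")
  print(x$counts, row.names = FALSE)
  if (!is.na(x$recovery_rate)) {
    cat(sprintf("model-recovery rate: %.3f\n", x$recovery_rate))
  }
  invisible(x)
}

serialize_params <- function(params) {
  if (is.null(params)) return(NULL)
  if (inherits(params, "density_params")) {
    list(model = "density", mode = params$mode, alpha = params$alpha,
         categories = lapply(params$categories, function(est) {
           lapply(est, function(v) if (is.matrix(v)) as.vector(v) else v)
         }))
  } else {
    list(model = "boundary", axis = params$axis, alpha = params$alpha,
         pairs = params$pairs)
  }
}

#' Serialize fitted classifications to JSON
#'
#' Schema per participant: `participant_id`, `condition`, `structure`,
#' `verdict`, `excluded`, `flags`, and per model the fitted parameters
#' (with covariance matrices flattened column-major), alpha, training SSE
#' and test RMSD.
#'
#' @param classifications A `cohort_classification` or list of
#'   `fit_classification`s.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fits_json <- function(classifications, path) {
  if (inherits(classifications, "cohort_classification")) {
    classifications <- classifications$classifications
  }
  payload <- lapply(classifications, function(f) {
    fit_payload <- function(fit) {
      if (is.null(fit)) return(NULL)
      list(params = serialize_params(fit$params), alpha = fit$params$alpha,
           train_sse = fit$train_sse, test_rmsd = fit$test_rmsd,
           fit_window = "trials 301-500")
    }
    list(participant_id = f$participant_id, condition = f$condition,
         structure = f$structure_kind, verdict = f$verdict,
         true_representation = f$true_representation,
         excluded = f$excluded, flags = f$flags,
         density = fit_payload(f$density_fit),
         boundary = fit_payload(f$boundary_fit))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
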