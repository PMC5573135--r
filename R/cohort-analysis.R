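# Group-level descriptives: blockwise accuracy curves, generalization-RMSD
# summaries, verdict proportions, and the pooled two-proportion z test used
# to compare the share of within-category learners across conditions.

#' Blockwise mean accuracy with between-subject SEM
#'
#' Computes each participant's per-block accuracy (correct responses over
#' answered trials), then aggregates per group: mean, between-subject
#' standard error of the mean (`sd / sqrt(n)`), and n. Grouping is by
#' condition, optionally crossed with the model-selection verdict (the
#' layout of the accuracy-by-best-fitting-model figures); verdict grouping
#' requires `classifications`, and excluded participants are omitted with
#' a warning.
#'
#' @param cohort A `catrep_cohort`.
#' @param group_by `"condition"` or `c("condition", "verdict")`.
#' @param classifications A `cohort_classification`, required when grouping
#'   by verdict.
#' @return Data frame with the grouping columns plus `block`,
#'   `mean_accuracy`, `sem`, `n`.
#' @export
block_accuracy <- function(cohort, group_by = "condition",
                           classifications = NULL) {
  stopifnot(inherits(cohort, "catrep_cohort"),
            all(group_by %in% c("condition", "verdict")))
  per_session <- do.call(rbind, lapply(cohort$sessions, function(s) {
    tr <- s$trials
    answered <- vapply(tr$response, is_category_response, logical(1),
                       condition = s$condition)
    tr <- tr[answered, , drop = FALSE]
    acc <- tapply(tr$correct, tr$block, mean)
    data.frame(participant_id = s$participant_id, condition = s$condition,
               block = as.integer(names(acc)), accuracy = as.numeric(acc),
               stringsAsFactors = FALSE)
  }))
  if ("verdict" %in% group_by) {
    if (is.null(classifications)) {
      stop("grouping by verdict requires `classifications`.", call. = FALSE)
    }
    part <- classifications$participants
    if (any(part$excluded)) {
      warning(sum(part$excluded),
              " excluded participant(s) omitted from accuracy grouping.")
    }
    per_session <- merge(per_session,
                         part[!part$excluded, c("participant_id", "verdict")],
                         by = "participant_id")
  }
  keys <- c(group_by, "block")
  split_key <- interaction(per_session[keys], drop = TRUE)
  out <- do.call(rbind, lapply(split(per_session, split_key), function(g) {
    row <- g[1, keys, drop = FALSE]
    row$mean_accuracy <- mean(g$accuracy)
    row$sem <- if (nrow(g) > 1L) stats::sd(g$accuracy) / sqrt(nrow(g)) else 0
    row$n <- nrow(g)
    row
  }))
  out <- out[order(out[[group_by[1]]], out$block), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pooled two-proportion z test
#'
#' `z = (k1/n1 - k2/n2) / sqrt(phat (1 - phat) (1/n1 + 1/n2))` with the
#' pooled proportion `phat = (k1 + k2) / (n1 + n2)`. No continuity
#' correction is applied. Used to compare the proportion of participants
#' best fit by the density model across training conditions.
#'
#' @param k1,n1 Successes and size of group 1.
#' @param k2,n2 Successes and size of group 2.
#' @return The z statistic (signed; antisymmetric under swapping groups).
#' @export
#' @examples
#' round(two_proportion_z(21, 31, 12, 30), 2)
two_proportion_z <- function(k1, n1, k2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  phat <- (k1 + k2) / (n1 + n2)
  if (phat <= 0 || phat >= 1) {
    stop("undefined variance: pooled proportion is 0 or 1.", call. = FALSE)
  }
  (k1 / n1 - k2 / n2) / sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
}

#' Assemble the full analysis report for a cohort
#'
#' Bundles everything the group-level analysis produces: blockwise accuracy
#' (by condition, and by condition x verdict), the verdict counts and
#' proportions per condition, the generalization-RMSD summary table, the
#' model-recovery rate for synthetic cohorts, and -- when the cohort holds
#' exactly two conditions -- the pooled two-proportion z comparing the
#' share of within-category verdicts (conditions ordered YN first, so the
#' sign matches "concept training yields more within-category learners").
#' The bundle is deterministic for a fixed cohort (no timestamps).
#'
#' @param cohort A `catrep_cohort`.
#' @param classifications Optional precomputed `cohort_classification`
#'   (computed via [classify_cohort()] if omitted).
#' @return A `catrep_report` object (a named list; see [write_report()]).
#' @export
reproduce_report <- function(cohort, classifications = NULL) {
  if (is.null(classifications)) classifications <- classify_cohort(cohort)
  counts <- classifications$counts
  z_tests <- NULL
  if (nrow(counts) == 2L) {
    ord <- order(match(counts$condition, c("YN", "AB")))
    a <- counts[ord[1], ]
    b <- counts[ord[2], ]
    z <- two_proportion_z(a$n_within, a$n, b$n_within, b$n)
    z_tests <- data.frame(
      comparison = paste0("prop_within: ", a$condition, " vs ", b$condition),
      k1 = a$n_within, n1 = a$n, k2 = b$n_within, n2 = b$n,
      z = z, p_two_sided = 2 * stats::pnorm(-abs(z)),
      stringsAsFactors = FALSE
    )
  }
  report <- list(
    metadata = list(
      n_sessions = length(cohort$sessions),
      conditions = sort(unique(counts$condition)),
      structures = sort(unique(classifications$participants$structure)),
      cohort_metadata = cohort$metadata
    ),
    counts = counts,
    rmsd_summary = classifications$rmsd_summary,
    block_accuracy = block_accuracy(cohort, "condition"),
    block_accuracy_by_verdict = block_accuracy(
      cohort, c("condition", "verdict"), classifications),
    recovery_rate = classifications$recovery_rate,
    z_tests = z_tests
  )
  class(report) <- "catrep_report"
  report
}

#' Write a report bundle to disk
#'
#' Emits `report.json` (full bundle), `block_accuracy.csv` and
#' `rmsd_summary.csv` into `dir`. The JSON layout is described by the
#' schema shipped at `system.file("extdata", "report-schema.json",
#' package = "catrep")`; [validate_report()] checks a bundle against it.
#'
#' @param report A `catrep_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "catrep_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE, na = "null")
  utils::write.csv(report$block_accuracy,
                   file.path(dir, "block_accuracy.csv"), row.names = FALSE)
  utils::write.csv(report$rmsd_summary,
                   file.path(dir, "rmsd_summary.csv"), row.names = FALSE)
  invisible(dir)
}

#' Validate a report against the shipped schema
#'
#' Structural check of a report bundle (in memory, or a `report.json` file)
#' against the field/type schema at `inst/extdata/report-schema.json`:
#' every required field must be present with the declared JSON type.
#'
#' @param report A `catrep_report`, a list parsed from `report.json`, or a
#'   path to one.
#' @return `TRUE` invisibly; stops listing the violations otherwise.
#' @export
validate_report <- function(report) {
  if (is.character(report) && length(report) == 1L) {
    report <- jsonlite::read_json(report, simplifyVector = FALSE)
  }
  schema <- jsonlite::read_json(
    system.file("extdata", "report-schema.json", package = "catrep"),
    simplifyVector = FALSE
  )
  json_type <- function(x) {
    if (is.null(x)) "null"
    else if (is.list(x) && (length(x) == 0L || is.null(names(x)))) "array"
    else if (is.list(x)) "object"
    else if (is.data.frame(x)) "array"
    else if (is.numeric(x)) "number"
    else if (is.character(x)) "string"
    else if (is.logical(x)) "boolean"
    else "unknown"
  }
  problems <- character(0)
  for (field in names(schema$required)) {
    want <- schema$required[[field]]
    if (!field %in% names(report)) {
      problems <- c(problems, paste0("missing field: ", field))
    } else {
      got <- if (is.data.frame(report[[field]])) "array" else {
        json_type(report[[field]])
      }
      ok <- got %in% unlist(want) ||
        ("null" %in% unlist(want) && is.null(report[[field]]))
      if (!ok) {
        problems <- c(problems, sprintf("field %s: expected %s, got %s",
                                        field, paste(unlist(want),
                                                     collapse = "|"), got))
      }
    }
  }
  if (length(problems) > 0L) {
    stop("report does not match schema:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Plot blockwise accuracy curves
#'
#' Line-and-point plot of a [block_accuracy()] table with +/- 1 SEM error
#' bars, one line per condition (faceted by verdict when present).
#' Requires ggplot2.
#'
#' @param accuracy_table Output of [block_accuracy()].
#' @return A ggplot object.
#' @export
plot_block_accuracy <- function(accuracy_table) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotting requires the ggplot2 package.", call. = FALSE)
  }
  p <- ggplot2::ggplot(accuracy_table,
                       ggplot2::aes(x = block, y = mean_accuracy,
                                    colour = condition, group = condition)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = mean_accuracy - sem,
                                        ymax = mean_accuracy + sem),
                           width = 0.15) +
    ggplot2::scale_x_continuous(breaks = 1:6) +
    ggplot2::labs(x = "Block (6 = transfer test)", y = "Mean accuracy") +
    ggplot2::theme_minimal()
  if ("verdict" %in% names(accuracy_table)) {
    p <- p + ggplot2::facet_wrap(~verdict)
  }
  p
}
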